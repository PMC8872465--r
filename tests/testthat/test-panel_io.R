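test_that("sirna_panel validates lengths, alphabet, and complementarity", {
  p <- tiny_panel(3)
  expect_s3_class(p, "sirna_panel")
  expect_equal(nrow(p), 3L)
  expect_equal(p$guide_core, substr(p$guide, 1, 19))
  # DNA T is normalized to U
  g <- gsub("U", "T", p$guide[1])
  p2 <- sirna_panel("x", g, p$passenger[1])
  expect_equal(p2$guide, p$guide[1])
  # broken complementarity names the offender
  expect_error(sirna_panel("bad1", p$guide[1], p$guide[1]),
               "reverse complement.*bad1")
  expect_error(sirna_panel(c("a", "a"), p$guide[1:2], p$passenger[1:2]),
               "duplicate")
  expect_error(sirna_panel("s", substr(p$guide[1], 1, 20), p$passenger[1]),
               "length")
})

test_that("panel I/O round-trips through TSV and FASTA", {
  p <- tiny_panel(4)
  for (ext in c(".tsv", ".fa")) {
    f <- tempfile(fileext = ext)
    write_panel(p, f)
    back <- read_panel(f)
    expect_equal(back$id, p$id)
    expect_equal(back$guide, p$guide)
    expect_equal(back$passenger, p$passenger)
  }
  # CSV dialect detection
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,guide,passenger",
               paste(p$id, p$guide, p$passenger, sep = ",")), f)
  expect_equal(read_panel(f)$guide, p$guide)
  # unpaired FASTA record
  f2 <- tempfile(fileext = ".fa")
  writeLines(c(">solo_guide", p$guide[1]), f2)
  expect_error(read_panel(f2), "unpaired")
})

test_that("activity tables are typed, validated, and cross-checked", {
  p <- generate_panel(simulation_params(n_sirnas = 26, seed = 3))
  act <- simulate_activities(p, simulation_params(n_sirnas = 26, seed = 3))
  expect_equal(nrow(act), 26L * 2L * 4L)  # 208 rows
  f <- tempfile(fileext = ".tsv")
  write_activities(act, f)
  back <- read_activities(f, panel = p)
  expect_equal(back$activity_pct, act$activity_pct, tolerance = 1e-12)

  df <- as.data.frame(act)
  expect_error(activity_table(rbind(df, df[1, ])), "duplicate")
  df2 <- df; df2$activity_pct[1] <- -1
  expect_error(activity_table(df2), "non-negative")
  df3 <- df; df3$assay[1] <- "XX"
  expect_error(activity_table(df3), "unknown assay")
  df4 <- df; df4$sirna_id[1] <- "ghost"
  expect_error(activity_table(df4, panel = p), "absent.*ghost")
})

test_that("functional rules evaluate the four predicates", {
  # U at 1, C at 19, 7 A/U in 1-7, max G/C run 7
  rep1 <- check_functional_rules("UUAUAAUGGCCGGCAUCGC")
  expect_true(rep1$overall)
  # all G: only rule ii holds
  repG <- check_functional_rules(strrep("G", 19))
  expect_false(repG$rule_i_5prime_AU)
  expect_true(repG$rule_ii_pos19_GC)
  expect_false(repG$rule_iii_AU_rich_seed_side)
  expect_false(repG$rule_iv_no_long_GC_stretch)
  expect_false(repG$overall)
  # G/C run of 10 at positions 2-11 trips rule iv
  rep2 <- check_functional_rules("AGCGCGCGCGCAAAAAAAC")
  expect_false(rep2$rule_iv_no_long_GC_stretch)
  # a run of exactly 8 is still allowed ("longer than 8" rejected)
  rep3 <- check_functional_rules("AGCGCGCGCAAAAAAAAAC")
  expect_true(rep3$rule_iv_no_long_GC_stretch)
})

test_that("rule iii variants read different windows", {
  # G at 1, then A,U,A,U in 2-5, A at 6-7: 1-7 has 6 A/U; 2-7 has 6
  g <- paste0("GAUAUAA", strrep("A", 11), "C")
  expect_true(check_functional_rules(g, "fig1b")$rule_iii_AU_rich_seed_side)
  # 4 A/U at 1,2,3,4 but only 3 in 2-7
  g2 <- paste0("UUUAGGG", strrep("A", 11), "C")
  expect_true(check_functional_rules(g2, "fig1b")$rule_iii_AU_rich_seed_side)
  expect_false(check_functional_rules(g2, "results")$rule_iii_AU_rich_seed_side)
})

test_that("rule ii on the guide equals G/C at the passenger 5' end", {
  p <- generate_panel(simulation_params(n_sirnas = 30, seed = 8,
                                        enforce_rules = FALSE))
  for (i in seq_len(nrow(p))) {
    rep <- check_functional_rules(p$guide_core[i])
    pass5 <- substr(p$passenger[i], 1, 1)
    expect_equal(rep$rule_ii_pos19_GC, pass5 %in% c("G", "C"))
  }
})
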