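test_that("stack_sums matches the embedded table on single and summed stacks", {
  tab <- nn_parameter_table()
  lut <- raw_nn_lookup()
  # single-stack identity (Freier 1986 GC stack)
  expect_equal(stack_sums("GC", tab),
               c(dH = lut$dH[["GC"]], dS = lut$dS[["GC"]]))
  # manual summation: GC + CA + AU
  expect_equal(stack_sums("GCAU", tab),
               c(dH = lut$dH[["GC"]] + lut$dH[["CA"]] + lut$dH[["AU"]],
                 dS = lut$dS[["GC"]] + lut$dS[["CA"]] + lut$dS[["AU"]]))
})

test_that("stack_sums is additive over any split point", {
  tab <- nn_parameter_table()
  set.seed(11)
  for (i in 1:50) {
    len <- sample(3:19, 1)
    s <- random_rna(len)
    ks <- 2:(len - 1)
    k <- ks[sample.int(length(ks), 1)]
    left <- substr(s, 1, k)
    right <- substr(s, k, len)
    expect_equal(stack_sums(s, tab),
                 stack_sums(left, tab) + stack_sums(right, tab))
  }
})

test_that("stack_sums rejects bad input", {
  expect_error(stack_sums("A"), "no stack")
  expect_error(stack_sums("ACGX"), "non-ACGU")
  # DNA T is normalized, not rejected
  expect_equal(stack_sums("GCAT"), stack_sums("GCAU"))
})

test_that("nn_parameter_table validates its invariants", {
  tab <- nn_parameter_table()
  expect_length(tab$dH, 16L)
  expect_true(all(tab$dH < 0) && all(tab$dS < 0))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("stack\tdH_kcal\tdS_cal", "AA\t-6.6\t-18.4"), bad)
  expect_error(nn_parameter_table(bad), "exactly the 16")
})

test_that("tm_from_sums evaluates the duplex formula", {
  # direct evaluation: 1000*(-50)/(-10.8 - 130 + 1.987*ln(2.5e-5)) - 273.15 - 16.6
  expect_equal(tm_from_sums(-50, -130), 19.17, tolerance = 0.01 / 19.17)
  expect_equal(tm_from_sums(-50, -130),
               1000 * (-50) / (-10.8 - 130 + 1.987 * log(2.5e-5)) -
                 273.15 - 16.6)
  # salt term is analytically +16.6 per decade of [Na+]
  for (dH in c(-30, -80)) {
    d <- tm_from_sums(dH, -100, thermo_conditions(Na = 1.0)) -
      tm_from_sums(dH, -100, thermo_conditions(Na = 0.1))
    expect_equal(d, 16.6)
  }
  # Ct = 4 M removes the concentration term
  expect_equal(tm_from_sums(-60, -150, thermo_conditions(Ct = 4)),
               1000 * (-60) / (-10.8 - 150) - 273.15 - 16.6)
  expect_error(tm_from_sums(-10, -1.987 * log(2.5e-5) + 10.8),
               "singular")
})

test_that("melting_temperature composes the two operations and is local", {
  tab <- nn_parameter_table()
  ss <- stack_sums("GCGC", tab)
  expect_identical(melting_temperature("GCGC"),
                   tm_from_sums(ss[["dH"]], ss[["dS"]]))
  # value of a subsequence does not depend on its flanking context
  expect_equal(melting_temperature("ACGU"),
               melting_temperature(substr("GGACGUCC", 3, 6)))
  expect_equal(melting_temperature("ACGUACGU"), oracle_tm("ACGUACGU"))
})

test_that("melting_temperature agrees with the naive oracle on random input", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_rna(sample(2:19, 1))
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 1e-9)
  }
})

test_that("subregion_tm_matrix fills exactly the length >= min_len cells", {
  m2 <- subregion_tm_matrix("GC")
  expect_equal(sum(!is.na(m2)), 1L)
  expect_equal(m2[1, 2], melting_temperature("GC"))

  g <- "AUGGCUACAUCGGAUAUGC"
  m <- subregion_tm_matrix(g)
  expect_equal(sum(!is.na(m)), choose(19, 2))  # 171
  expect_equal(m["2", "5"], melting_temperature(substr(g, 2, 5)))
  expect_true(all(is.na(m[lower.tri(m, diag = TRUE)])))
  expect_error(subregion_tm_matrix("A"), "shorter")
  expect_error(subregion_tm_matrix("ACGU", min_len = 1), "min_len")
})

test_that("Tm matrix cells are invariant to changes outside the subregion", {
  set.seed(5)
  g1 <- random_rna(19)
  # mutate positions outside [8..12]
  g2 <- paste0(random_rna(7), substr(g1, 8, 12), random_rna(7))
  m1 <- subregion_tm_matrix(g1)
  m2 <- subregion_tm_matrix(g2)
  expect_equal(m1["8", "12"], m2["8", "12"])
  expect_equal(m1["9", "11"], m2["9", "11"])
})

test_that("write_tm_matrix/read_matrix_tsv round-trips", {
  m <- subregion_tm_matrix("AUGGCUACAUCGGAUAUGC")
  f <- tempfile(fileext = ".tsv")
  write_tm_matrix(m, f)
  back <- read_matrix_tsv(f)
  expect_equal(back, unclass(m), tolerance = 1e-12, ignore_attr = TRUE)
})
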