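# Independent oracles and in-code fixtures. Everything here deliberately
# avoids the package's own computation paths: the Tm oracle reads the raw
# parameter TSV and loops; the Pearson oracle is the textbook sum formula.

raw_nn_lookup <- function() {
  path <- system.file("extdata", "freier1986_rna_nn.tsv", package = "sirscan")
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  list(dH = setNames(df$dH_kcal, df$stack),
       dS = setNames(df$dS_cal, df$stack))
}

# naive loop + direct formula evaluation
oracle_tm <- function(seq, Ct = 1e-4, Na = 0.1, A = -10.8, R = 1.987) {
  lut <- raw_nn_lookup()
  dH <- 0
  dS <- 0
  for (i in seq_len(nchar(seq) - 1L)) {
    st <- substr(seq, i, i + 1L)
    dH <- dH + lut$dH[[st]]
    dS <- dS + lut$dS[[st]]
  }
  1000 * dH / (A + dS + R * log(Ct / 4)) - 273.15 + 16.6 * log10(Na)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# deterministic hand-built panel: guides chosen to satisfy panel invariants
# (not necessarily the functional rules)
tiny_panel <- function(n = 4L, seed = 7L, core_len = 19L) {
  set.seed(seed)
  cores <- replicate(n, random_rna(core_len))
  sirna_panel(paste0("t", seq_len(n)),
              paste0(cores, "UU"),
              paste0(vapply(cores, sirscan:::rna_revcomp, ""), "UU"))
}

# activity table built from an arbitrary per-siRNA SM vector at one conc
activities_from <- function(panel, sm, concentration = 50) {
  activity_table(data.frame(
    sirna_id = rep(panel$id, 2L),
    assay = rep(c("SM", "CM"), each = nrow(panel)),
    concentration_nM = concentration,
    activity_pct = c(sm, rep(5, nrow(panel)))), panel = panel)
}
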