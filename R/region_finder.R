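#' Configuration for the resampling procedure
#'
#' Controls the repeated random subsampling that localizes the subregions
#' responsible for the off-target effect: in each replicate a subset of
#' siRNAs is drawn without replacement, the subregion correlation map is
#' rebuilt on the subset, and the start/end positions of the top-ranked
#' region(s) of the requested correlation sign are recorded.
#'
#' @param n_reps Number of replicates (default 1000).
#' @param subset_size siRNAs per draw (default 13, half of the 26-siRNA
#'   panel; `choose(26, 13)` = 10,400,600 possible draws).
#' @param top_k How many top-ranked regions to record per replicate (the
#'   reported analyses use 1 and 10).
#' @param sign `"negative"` (r most negative with luciferase activity, i.e.
#'   stability promoting silencing) or `"positive"`.
#' @param seed RNG seed; replicate i's draw depends only on (seed, i), so
#'   partial re-execution reproduces the same subsets.
#' @param assay,concentration Activity selector.
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(n_reps = 1000L, subset_size = 13L, top_k = 1L,
                            sign = c("negative", "positive"), seed = 1L,
                            assay = "SM", concentration = 50) {
  sign <- match.arg(sign)
  n_reps <- as.integer(n_reps)
  subset_size <- as.integer(subset_size)
  top_k <- as.integer(top_k)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (subset_size < 3L) stop("subset too small for correlation (< 3)")
  if (top_k < 1L) stop("top_k must be >= 1")
  structure(list(n_reps = n_reps, subset_size = subset_size, top_k = top_k,
                 sign = sign, seed = as.integer(seed), assay = assay,
                 concentration = concentration),
            class = "sampling_config")
}

# replicate-local RNG: depends only on (seed, i); restores the caller's RNG
with_rep_seed <- function(seed, i, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((as.integer(seed) %% 1000000L) * 2039L + as.integer(i))
  force(expr)
}

#' Rank subregions of a correlation map
#'
#' Orders defined cells by r (ascending for `sign = "negative"`, so the most
#' negative region is rank 1; descending for `"positive"`). Ties are broken
#' deterministically: shorter region first, then smaller start position.
#'
#' @param cmap A `correlation_map` (or any start-by-end matrix of r values).
#' @param sign `"negative"` or `"positive"`.
#' @return A data frame (x, y, r) in rank order.
#' @export
rank_regions <- function(cmap, sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  idx <- which(!is.na(cmap), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("all cells undefined")
  df <- data.frame(x = as.integer(idx[, 1]), y = as.integer(idx[, 2]),
                   r = cmap[idx])
  key <- if (sign == "negative") df$r else -df$r
  df <- df[order(key, df$y - df$x, df$x), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Localize responsible regions by repeated random subsampling
#'
#' For each of `cfg$n_reps` replicates, draws `cfg$subset_size` siRNAs
#' uniformly without replacement, recomputes every subregion's Pearson r on
#' the subset, and records the start (x) and end (y) positions of the
#' `cfg$top_k` top-ranked regions of the requested sign. The aggregated
#' position histograms peak at the region(s) whose thermodynamic stability
#' most consistently tracks the activity.
#'
#' @param panel A [sirna_panel()].
#' @param activities An `activity_table`.
#' @param cfg A [sampling_config()].
#' @param cond,table Thermodynamic settings for the Tm features.
#' @param features Optional precomputed [panel_tm_features()] cache (used by
#'   the pipeline driver to avoid recomputing Tm matrices).
#' @return A list of class `sampling_summary`: `start_hist` and `end_hist`
#'   (integer counts per position 1..L), `region_hist` (data frame x, y,
#'   count, only visited regions), `modal_region` (x, y of the most frequent
#'   top region, ties broken by shorter length then smaller x), and `config`.
#' @export
sampling_frequencies <- function(panel, activities, cfg = sampling_config(),
                                 cond = thermo_conditions(),
                                 table = nn_parameter_table(),
                                 features = NULL) {
  stopifnot(inherits(cfg, "sampling_config"))
  n <- nrow(panel)
  if (cfg$subset_size > n) stop("subset_size exceeds panel size")
  feats <- features %||% panel_tm_features(panel, cond, table)
  a <- activity_vector(panel, activities, cfg$assay, cfg$concentration)
  L <- feats$L
  rx <- feats$regions$x
  ry <- feats$regions$y
  len_key <- ry - rx
  start_hist <- integer(L)
  end_hist <- integer(L)
  region_counts <- integer(nrow(feats$regions))
  for (i in seq_len(cfg$n_reps)) {
    sub <- with_rep_seed(cfg$seed, i, sample.int(n, cfg$subset_size))
    r <- suppressWarnings(
      as.vector(stats::cor(a[sub], feats$tm[sub, , drop = FALSE])))
    r[!is.finite(r)] <- NA
    key <- if (cfg$sign == "negative") r else -r
    ord <- order(key, len_key, rx, na.last = NA)
    top <- ord[seq_len(min(cfg$top_k, length(ord)))]
    region_counts[top] <- region_counts[top] + 1L
    start_hist <- start_hist + tabulate(rx[top], nbins = L)
    end_hist <- end_hist + tabulate(ry[top], nbins = L)
  }
  visited <- which(region_counts > 0L)
  region_hist <- data.frame(x = rx[visited], y = ry[visited],
                            count = region_counts[visited])
  best <- visited[order(-region_counts[visited], len_key[visited],
                        rx[visited])][1L]
  structure(
    list(start_hist = stats::setNames(start_hist, 1:L),
         end_hist = stats::setNames(end_hist, 1:L),
         region_hist = region_hist,
         modal_region = c(x = rx[best], y = ry[best]),
         config = cfg),
    class = "sampling_summary")
}

#' Train/validation correlation distributions for a region
#'
#' Repeatedly partitions the panel into disjoint training and validation
#' halves (for a 26-siRNA panel, 13 + 13), computes the absolute Pearson
#' correlation between the region's Tm and the activity in each half, and
#' compares the two distributions with a Student's t-test. Near-identical
#' training and validation distributions indicate the region's correlation
#' generalizes rather than reflecting a few influential siRNAs.
#'
#' @param panel,activities,cond,table,features As in
#'   [sampling_frequencies()].
#' @param region Integer vector `c(x, y)`, a defined subregion of the guide
#'   core.
#' @param cfg A [sampling_config()]; `subset_size` is the training-set size
#'   and the validation set is its complement.
#' @return A list of class `split_correlations`: `region`, `train_r`,
#'   `valid_r` (|r| per replicate), `t_stat`, `p_value`, `config`.
#' @export
split_correlations <- function(panel, activities, region,
                               cfg = sampling_config(),
                               cond = thermo_conditions(),
                               table = nn_parameter_table(),
                               features = NULL) {
  feats <- features %||% panel_tm_features(panel, cond, table)
  tm <- region_feature(feats, region)
  a <- activity_vector(panel, activities, cfg$assay, cfg$concentration)
  n <- nrow(panel)
  if (cfg$subset_size >= n - 2L) {
    stop("config error: validation half needs at least 3 siRNAs")
  }
  train_r <- numeric(cfg$n_reps)
  valid_r <- numeric(cfg$n_reps)
  for (i in seq_len(cfg$n_reps)) {
    tr <- with_rep_seed(cfg$seed, i, sample.int(n, cfg$subset_size))
    va <- setdiff(seq_len(n), tr)
    train_r[i] <- abs(pearson(tm[tr], a[tr]))
    valid_r[i] <- abs(pearson(tm[va], a[va]))
  }
  tt <- student_t_test(train_r, valid_r)
  structure(list(region = c(x = region[1L], y = region[2L]),
                 train_r = train_r, valid_r = valid_r,
                 t_stat = tt[["t"]], p_value = tt[["p"]], config = cfg),
            class = "split_correlations")
}

# per-siRNA Tm feature for one region from a panel_tm_features cache
region_feature <- function(feats, region) {
  j <- which(feats$regions$x == region[1L] & feats$regions$y == region[2L])
  if (length(j) != 1L) {
    stop("region (", region[1L], ",", region[2L], ") is not defined")
  }
  feats$tm[, j]
}

#' Integrated two-region correlation
#'
#' Evaluates whether combining the thermodynamic profiles of two subregions
#' (the stability-promoting seed subregion and the stability-opposing
#' non-seed subregion) tracks the off-target effect better than the first
#' region alone. Three combination schemes are provided because the source
#' analyses do not pin one down:
#' \itemize{
#'   \item `tm_difference` (default): per-siRNA feature Tm(A) - Tm(B), the
#'     natural composite when the two regions act with opposite signs;
#'   \item `tm_product`: per-siRNA feature Tm(A) * Tm(B);
#'   \item `r_product`: per replicate, |r(A) * r(B)| — the literal product of
#'     the two correlation coefficients (which can never exceed either
#'     factor when both |r| < 1).
#' }
#' Per replicate the combined |r| is computed on training and validation
#' halves as in [split_correlations()], and each arm is compared against the
#' single-region |r| of `regionA` with a Student's t-test.
#'
#' @inheritParams split_correlations
#' @param regionA,regionB Integer `c(x, y)` regions (e.g. `c(2, 5)` and
#'   `c(9, 14)`).
#' @param scheme Combination scheme, see above.
#' @return A list of class `combined_correlations` with train/valid combined
#'   and single-region |r| vectors, per-arm t statistics and p values, and
#'   the scheme.
#' @export
combined_region_correlation <- function(panel, activities, regionA, regionB,
                                        scheme = c("tm_difference",
                                                   "tm_product", "r_product"),
                                        cfg = sampling_config(),
                                        cond = thermo_conditions(),
                                        table = nn_parameter_table(),
                                        features = NULL) {
  scheme <- match.arg(scheme)
  feats <- features %||% panel_tm_features(panel, cond, table)
  tmA <- region_feature(feats, regionA)
  tmB <- region_feature(feats, regionB)
  a <- activity_vector(panel, activities, cfg$assay, cfg$concentration)
  n <- nrow(panel)
  if (cfg$subset_size >= n - 2L) {
    stop("config error: validation half needs at least 3 siRNAs")
  }
  combo <- switch(scheme,
                  tm_difference = tmA - tmB,
                  tm_product = tmA * tmB,
                  r_product = NULL)
  arm_r <- function(idx) {
    single <- abs(pearson(tmA[idx], a[idx]))
    comb <- if (scheme == "r_product") {
      abs(pearson(tmA[idx], a[idx]) * pearson(tmB[idx], a[idx]))
    } else {
      abs(pearson(combo[idx], a[idx]))
    }
    c(single = single, combined = comb)
  }
  train <- matrix(NA_real_, cfg$n_reps, 2,
                  dimnames = list(NULL, c("single", "combined")))
  valid <- train
  for (i in seq_len(cfg$n_reps)) {
    tr <- with_rep_seed(cfg$seed, i, sample.int(n, cfg$subset_size))
    va <- setdiff(seq_len(n), tr)
    train[i, ] <- arm_r(tr)
    valid[i, ] <- arm_r(va)
  }
  tt_train <- student_t_test(train[, "combined"], train[, "single"])
  tt_valid <- student_t_test(valid[, "combined"], valid[, "single"])
  structure(
    list(regionA = c(x = regionA[1L], y = regionA[2L]),
         regionB = c(x = regionB[1L], y = regionB[2L]),
         scheme = scheme,
         train_combined_r = train[, "combined"],
         train_single_r = train[, "single"],
         valid_combined_r = valid[, "combined"],
         valid_single_r = valid[, "single"],
         t_train = tt_train[["t"]], p_train = tt_train[["p"]],
         t_valid = tt_valid[["t"]], p_valid = tt_valid[["p"]],
         config = cfg),
    class = "combined_correlations")
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic equal-variance two-sample t statistic with a two-sided p value
#' from the t distribution on `length(a) + length(b) - 2` degrees of
#' freedom. Degenerate inputs: zero pooled variance with equal means gives
#' `t = 0, p = 1`; with unequal means, `t = +/-Inf, p = 0`. Set
#' `welch = TRUE` for the unequal-variance variant.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch approximation instead of pooled variance.
#' @return Named numeric vector `c(t = ..., p = ..., df = ...)`.
#' @examples
#' student_t_test(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247
#' @export
student_t_test <- function(a, b, welch = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b))
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    se <- sqrt(se2)
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  }
  if (se == 0) {
    if (dm == 0) return(c(t = 0, p = 1, df = df))
    return(c(t = sign(dm) * Inf, p = 0, df = df))
  }
  t <- dm / se
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, p = p, df = df)
}

#' Exact binomial coefficient
#'
#' Number of distinct k-subsets of n elements, computed with the exact
#' multiplicative algorithm (every intermediate division is exact). Errors
#' if the result exceeds 2^53, past which doubles can no longer represent
#' integers exactly.
#'
#' @param n,k Non-negative integers with `k <= n`.
#' @return The exact count as a double (integer-valued).
#' @examples
#' count_subsets(26, 13)  # 10400600 possible half-panel draws
#' @export
count_subsets <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L)
  n <- as.numeric(n); k <- as.numeric(k)
  if (n < 0 || k < 0 || n != floor(n) || k != floor(k)) {
    stop("n and k must be non-negative integers")
  }
  if (k > n) stop("k must not exceed n")
  k <- min(k, n - k)
  acc <- 1
  for (i in seq_len(k)) {
    acc <- acc * (n - k + i) / i  # exact: C(n-k+i, i) is an integer
    if (acc > 2^53) stop("result exceeds exact double range (2^53)")
  }
  acc
}
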