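#' Pearson product-moment correlation
#'
#' Direct implementation of the sample Pearson coefficient; returns `NA` when
#' either variable has zero variance (such cells are excluded from region
#' ranking).
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return The correlation coefficient, or `NA_real_` if undefined.
#' @examples
#' pearson(c(1, 2, 3), c(2, 4, 7))
#' @export
pearson <- function(xs, ys) {
  stopifnot(is.numeric(xs), is.numeric(ys))
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("need at least 3 observations")
  dx <- xs - mean(xs)
  dy <- ys - mean(ys)
  sx <- sum(dx * dx)
  sy <- sum(dy * dy)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sx * sy)
}

# Region enumeration and per-siRNA Tm feature matrix.
# Returns list(regions = data.frame(x, y), tm = n x K matrix) with one
# column per subregion [x..y] of the guide core, in column-major (x fast)
# upper-triangle order.
panel_tm_features <- function(panel, cond = thermo_conditions(),
                              table = nn_parameter_table(), min_len = 2L,
                              core_length = 19L) {
  stopifnot(inherits(panel, "sirna_panel"))
  L <- core_length
  idx <- which(upper.tri(matrix(0, L, L)) &
                 (col(matrix(0, L, L)) - row(matrix(0, L, L)) + 1L) >= min_len,
               arr.ind = TRUE)
  regions <- data.frame(x = idx[, "row"], y = idx[, "col"])
  ord <- order(regions$x, regions$y)
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  tm <- t(vapply(panel$guide_core, function(g) {
    m <- subregion_tm_matrix(g, cond = cond, table = table, min_len = min_len)
    m[cbind(regions$x, regions$y)]
  }, numeric(nrow(regions)), USE.NAMES = FALSE))
  rownames(tm) <- panel$id
  colnames(tm) <- paste0(regions$x, "-", regions$y)
  list(regions = regions, tm = tm, L = L)
}

# activity vector aligned to panel order for one (assay, concentration)
activity_vector <- function(panel, activities, assay, concentration) {
  sel <- activities$assay == assay &
    activities$concentration_nM == concentration
  sub <- activities[sel, , drop = FALSE]
  a <- sub$activity_pct[match(panel$id, sub$sirna_id)]
  if (anyNA(a)) {
    stop("missing activity for (", assay, ", ", concentration, " nM), id(s): ",
         paste(panel$id[is.na(a)], collapse = ", "))
  }
  a
}

#' Subregion Tm vs activity correlation map
#'
#' For every defined guide-core subregion `[x..y]`, computes the Pearson
#' correlation between the per-siRNA Tm of that subregion and the per-siRNA
#' relative luciferase activity at one (assay, concentration). The sign
#' convention is Tm-versus-relative-luciferase-activity: since low activity
#' means strong silencing, a *negative* r means that subregion stability
#' *promotes* the silencing (off-target) effect.
#'
#' @param panel A [sirna_panel()].
#' @param activities An `activity_table` covering every panel id at the
#'   requested assay/concentration.
#' @param assay `"CM"` or `"SM"`.
#' @param concentration Concentration in nM.
#' @param cond,table,min_len Passed to [subregion_tm_matrix()].
#' @param method `"pearson"` (default, used for all reported maps) or
#'   `"spearman"`.
#' @param features Optional precomputed [panel_tm_features()] result (an
#'   internal cache used by the resampling driver).
#' @return A `correlation_map`: an L x L matrix of r values (start x on rows,
#'   end y on columns, `NA` where undefined) with attributes `assay`,
#'   `concentration`, `n`, `method`.
#' @export
correlation_map <- function(panel, activities, assay = "SM",
                            concentration = 50,
                            cond = thermo_conditions(),
                            table = nn_parameter_table(), min_len = 2L,
                            method = c("pearson", "spearman"),
                            features = NULL) {
  method <- match.arg(method)
  if (nrow(panel) < 3L) stop("need at least 3 siRNAs to correlate")
  feats <- features %||% panel_tm_features(panel, cond, table, min_len)
  a <- activity_vector(panel, activities, assay, concentration)
  r <- suppressWarnings(
    as.vector(stats::cor(a, feats$tm, method = method)))
  r[!is.finite(r)] <- NA_real_
  L <- feats$L
  m <- matrix(NA_real_, L, L, dimnames = list(start = 1:L, end = 1:L))
  m[cbind(feats$regions$x, feats$regions$y)] <- r
  structure(m, assay = assay, concentration = concentration,
            n = nrow(panel), method = method,
            class = c("correlation_map", "matrix"))
}

#' Export a correlation map
#'
#' Writes the map as a TSV matrix with start position x on rows (vertical
#' axis) and end position y on columns, plus an optional JSON summary of the
#' five most positive and five most negative regions. In rendered heatmaps
#' red conventionally marks positive r with relative luciferase activity
#' (stability opposing silencing) and blue negative r (stability promoting
#' silencing).
#'
#' @param cmap A `correlation_map`.
#' @param path Output TSV path.
#' @param summary_path Optional JSON path for the top-region summary.
#' @param digits Decimal places for the TSV (default 6).
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(cmap, path, summary_path = NULL, digits = 6) {
  stopifnot(inherits(cmap, "correlation_map"))
  if (all(is.na(cmap))) stop("correlation map has no defined cells")
  write_tm_matrix(round(unclass(cmap), digits), path)
  if (!is.null(summary_path)) {
    top_pos <- rank_regions(cmap, sign = "positive")
    top_neg <- rank_regions(cmap, sign = "negative")
    take <- function(df) {
      df <- utils::head(df, 5L)
      df$r <- round(df$r, 6)
      df
    }
    jsonlite::write_json(
      list(assay = attr(cmap, "assay"),
           concentration_nM = attr(cmap, "concentration"),
           n = attr(cmap, "n"), method = attr(cmap, "method"),
           top_positive = take(top_pos), top_negative = take(top_neg)),
      summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back an exported map/matrix TSV
#' @param path TSV written by [write_tm_matrix()] or [export_heatmap()].
#' @return A numeric matrix with start rows and end columns.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
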