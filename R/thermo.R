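#' Nearest-neighbor thermodynamic parameter table
#'
#' Loads a table of RNA/RNA Watson-Crick dinucleotide stacking parameters
#' (enthalpy in kcal/mol, entropy in cal/(mol K)). The packaged default is the
#' Freier et al. (1986) set measured in 1 M NaCl, the classic parameterization
#' for RNA duplex stability; any delimited file with columns
#' `stack`, `dH_kcal`, `dS_cal` and exactly 16 ACGU dinucleotide rows can be
#' substituted.
#'
#' @param path Path to a tab-delimited parameter file. `NULL` (default) loads
#'   the packaged Freier 1986 table.
#' @param source_tag Free-text label identifying the parameter set; defaults
#'   to the file base name.
#'
#' @return An object of class `nn_table`: a list with `dH` and `dS` (named
#'   numeric vectors keyed by 5'->3' dinucleotide) and `source_tag`.
#' @examples
#' tab <- nn_parameter_table()
#' tab$dH[["GC"]]
#' @export
nn_parameter_table <- function(path = NULL, source_tag = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "freier1986_rna_nn.tsv",
                        package = "sirscan", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("nearest-neighbor parameter file not found: ", path)
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  required <- c("stack", "dH_kcal", "dS_cal")
  if (!all(required %in% names(df))) {
    stop("parameter file must have columns: ", paste(required, collapse = ", "))
  }
  df$stack <- toupper(gsub("T", "U", df$stack, fixed = TRUE))
  expected <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                              paste0))
  if (anyDuplicated(df$stack) || !setequal(df$stack, expected)) {
    stop("parameter table must contain exactly the 16 ACGU dinucleotide stacks")
  }
  if (any(df$dH_kcal >= 0) || any(df$dS_cal >= 0)) {
    stop("all Watson-Crick RNA stacks must have dH < 0 and dS < 0")
  }
  structure(
    list(dH = stats::setNames(df$dH_kcal, df$stack),
         dS = stats::setNames(df$dS_cal, df$stack),
         source_tag = source_tag %||%
           tools::file_path_sans_ext(basename(path))),
    class = "nn_table")
}

#' Thermodynamic conditions for Tm calculation
#'
#' Bundles the constants of the nearest-neighbor melting-temperature formula
#' for a non-self-complementary duplex:
#' \deqn{T_m = \frac{1000\,\Delta H}{A + \Delta S + R \ln(C_t/4)} - 273.15
#'       + 16.6 \log_{10}[\mathrm{Na}^+]}
#' with \eqn{\Delta H} in kcal/mol and \eqn{\Delta S}, \eqn{A}, \eqn{R} in
#' cal/(mol K).
#'
#' @param Ct Total strand concentration in mol/L (default 1e-4, i.e. 100 uM).
#' @param Na Sodium ion concentration in mol/L (default 0.1, i.e. 100 mM).
#' @param A Helix initiation constant in cal/(mol K) (default -10.8).
#' @param R Gas constant in cal/(K mol) (default 1.987).
#' @return An object of class `thermo_conditions`.
#' @examples
#' thermo_conditions()                # assay defaults
#' thermo_conditions(Na = 1.0)       # 1 M salt
#' @export
thermo_conditions <- function(Ct = 1e-4, Na = 0.1, A = -10.8, R = 1.987) {
  stopifnot(is.numeric(Ct), length(Ct) == 1L, Ct > 0,
            is.numeric(Na), length(Na) == 1L, Na > 0,
            is.numeric(A), length(A) == 1L,
            is.numeric(R), length(R) == 1L, R > 0)
  structure(list(Ct = Ct, Na = Na, A = A, R = R),
            class = "thermo_conditions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uppercase, T->U, validate ACGU alphabet. Returns a character vector of
# single nucleotides.
normalize_rna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("sequence must be a single character string")
  }
  s <- strsplit(toupper(gsub("T", "U", seq, fixed = TRUE)), "")[[1L]]
  bad <- setdiff(unique(s), c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop("sequence contains non-ACGU symbol(s): ", paste(bad, collapse = ", "))
  }
  s
}

#' Sum of nearest-neighbor stacking terms
#'
#' Sums dinucleotide stacking enthalpies and entropies over all consecutive
#' base pairs of `seq` (paired with its perfect complement). The helix
#' initiation constant is *not* included here; it enters only in the Tm
#' formula.
#'
#' @param seq RNA string (5'->3', alphabet ACGU; T is accepted and read as U),
#'   length >= 2.
#' @param table An [nn_parameter_table()].
#' @return Named numeric vector `c(dH = ..., dS = ...)` with dH in kcal/mol
#'   and dS in cal/(mol K).
#' @examples
#' stack_sums("GCAU")
#' @export
stack_sums <- function(seq, table = nn_parameter_table()) {
  s <- normalize_rna(seq)
  n <- length(s)
  if (n < 2L) stop("no stack: sequence must be at least 2 nt long")
  stacks <- paste0(s[-n], s[-1L])
  c(dH = sum(table$dH[stacks]), dS = sum(table$dS[stacks]))
}

#' Melting temperature from enthalpy/entropy sums
#'
#' Evaluates the duplex Tm formula (see [thermo_conditions()]): natural log in
#' the strand-concentration term, base-10 log in the salt correction.
#'
#' @param dH Summed stacking enthalpy, kcal/mol.
#' @param dS Summed stacking entropy, cal/(mol K).
#' @param cond A [thermo_conditions()] object.
#' @return Tm in degrees Celsius.
#' @examples
#' tm_from_sums(-50, -130)  # ~19.17 C at the default conditions
#' @export
tm_from_sums <- function(dH, dS, cond = thermo_conditions()) {
  stopifnot(inherits(cond, "thermo_conditions"))
  denom <- cond$A + dS + cond$R * log(cond$Ct / 4)
  if (any(denom == 0)) stop("singular conditions: A + dS + R*ln(Ct/4) is zero")
  1000 * dH / denom - 273.15 + 16.6 * log10(cond$Na)
}

#' Melting temperature of an RNA duplex
#'
#' Nearest-neighbor Tm of `seq` paired with its perfect complement:
#' the composition of [stack_sums()] and [tm_from_sums()].
#'
#' @inheritParams stack_sums
#' @inheritParams tm_from_sums
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature("ACGUACGU")
#' @export
melting_temperature <- function(seq, cond = thermo_conditions(),
                                table = nn_parameter_table()) {
  ss <- stack_sums(seq, table)
  tm_from_sums(ss[["dH"]], ss[["dS"]], cond)
}

#' All-subregion Tm matrix of a guide-strand core
#'
#' Computes Tm for every contiguous subregion `[x..y]` of the guide core
#' (positions 1-based from the guide 5' end), the quantity scanned against
#' reporter activity. A single nucleotide has no stack, so only regions of
#' length >= `min_len` (>= 2) are defined; the matrix is strictly
#' upper-triangular with start position x on rows and end position y on
#' columns, `NA` elsewhere. For a 19-nt core and `min_len = 2` exactly
#' `choose(19, 2) = 171` cells are defined.
#'
#' @param guide_core RNA string, the paired duplex core (positions 1-19 of a
#'   21-nt guide; overhangs excluded).
#' @inheritParams melting_temperature
#' @param min_len Minimum subregion length (default 2).
#' @return A `tm_matrix`: an L x L numeric matrix with attributes `L` and
#'   `guide_core`, rows named by start position, columns by end position.
#' @examples
#' m <- subregion_tm_matrix("AUGGCUACAUCGGAUAUGC")
#' m["2", "5"]  # Tm of guide positions 2-5
#' @export
subregion_tm_matrix <- function(guide_core, cond = thermo_conditions(),
                                table = nn_parameter_table(), min_len = 2L) {
  s <- normalize_rna(guide_core)
  L <- length(s)
  if (min_len < 2L) stop("min_len must be >= 2 (single nt has no stack)")
  if (L < min_len) stop("guide core shorter than min_len")
  # cumulative stack sums give any subregion in O(1)
  stacks <- paste0(s[-L], s[-1L])
  cumH <- c(0, cumsum(table$dH[stacks]))
  cumS <- c(0, cumsum(table$dS[stacks]))
  m <- matrix(NA_real_, L, L, dimnames = list(start = 1:L, end = 1:L))
  for (x in 1:(L - min_len + 1L)) {
    y <- (x + min_len - 1L):L
    dH <- cumH[y] - cumH[x]
    dS <- cumS[y] - cumS[x]
    m[x, y] <- tm_from_sums(dH, dS, cond)
  }
  structure(m, L = L, guide_core = paste(s, collapse = ""),
            class = c("tm_matrix", "matrix"))
}

#' Export a Tm matrix as TSV
#'
#' Writes the matrix with start position x on rows (vertical axis) and end
#' position y on columns, undefined cells empty. Values are written at full
#' precision; use `digits` to round for display.
#'
#' @param m A `tm_matrix` (or correlation map matrix).
#' @param path Output file path.
#' @param digits Optional rounding for display; `NULL` keeps full precision.
#' @return `path`, invisibly.
#' @export
write_tm_matrix <- function(m, path, digits = NULL) {
  x <- unclass(m)
  attr(x, "L") <- NULL
  attr(x, "guide_core") <- NULL
  if (!is.null(digits)) x <- round(x, digits)
  df <- data.frame(start = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  names(df) <- c("start", colnames(x) %||% seq_len(ncol(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
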