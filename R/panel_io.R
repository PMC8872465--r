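#' @importFrom Biostrings readBStringSet RNAStringSet writeXStringSet
NULL

# reverse complement of an RNA string (base semantics, A<->U, C<->G)
rna_revcomp <- function(seq) {
  s <- normalize_rna(seq)
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  paste(rev(unname(comp[s])), collapse = "")
}

#' Construct and validate an siRNA panel
#'
#' An siRNA duplex is stored as two 5'->3' strands of `duplex_length`
#' nucleotides (default 21): a guide and a passenger with 2-nt 3' overhangs.
#' Positions are numbered 1-based from the guide 5' end; the paired core is
#' guide positions 1-19, and the passenger's first 19 nt must be the reverse
#' complement of that core.
#'
#' @param id Character vector of unique siRNA labels.
#' @param guide,passenger Character vectors of RNA strings (T accepted,
#'   normalized to U).
#' @param duplex_length Expected strand length (default 21).
#' @param core_length Length of the paired core (default 19).
#' @return A data frame of class `sirna_panel` with columns `id`, `guide`,
#'   `passenger`, `guide_core`.
#' @examples
#' g <- "AUGGCUACAUCGGAUAUGCUU"
#' sirna_panel("si1", g, paste0(sirscan:::rna_revcomp(substr(g, 1, 19)), "UU"))
#' @export
sirna_panel <- function(id, guide, passenger, duplex_length = 21L,
                        core_length = 19L) {
  stopifnot(length(id) == length(guide), length(guide) == length(passenger))
  if (anyDuplicated(id)) stop("duplicate siRNA id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  guide <- vapply(guide, function(s) paste(normalize_rna(s), collapse = ""),
                  "", USE.NAMES = FALSE)
  passenger <- vapply(passenger,
                      function(s) paste(normalize_rna(s), collapse = ""),
                      "", USE.NAMES = FALSE)
  bad_len <- nchar(guide) != duplex_length | nchar(passenger) != duplex_length
  if (any(bad_len)) {
    stop("strand length differs from ", duplex_length, " nt for id(s): ",
         paste(id[bad_len], collapse = ", "))
  }
  core <- substr(guide, 1L, core_length)
  expected_pass_core <- vapply(core, rna_revcomp, "", USE.NAMES = FALSE)
  bad_comp <- substr(passenger, 1L, core_length) != expected_pass_core
  if (any(bad_comp)) {
    stop("passenger core is not the reverse complement of the guide core ",
         "for id(s): ", paste(id[bad_comp], collapse = ", "))
  }
  structure(
    data.frame(id = as.character(id), guide = guide, passenger = passenger,
               guide_core = core, stringsAsFactors = FALSE),
    class = c("sirna_panel", "data.frame"))
}

#' Read an siRNA panel
#'
#' Two dialects are supported: a delimited table (TSV or CSV, auto-detected)
#' with columns `id`, `guide`, `passenger`; or a FASTA file with paired
#' records whose headers carry `_guide` / `_passenger` suffixes on a shared
#' id.
#'
#' @param path Input file.
#' @param dialect `"auto"` (by extension), `"table"`, or `"fasta"`.
#' @inheritParams sirna_panel
#' @return A validated [sirna_panel()].
#' @export
read_panel <- function(path, dialect = c("auto", "table", "fasta"),
                       duplex_length = 21L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("fa", "fasta", "fna")) "fasta" else "table"
  }
  if (dialect == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    nm <- names(seqs)
    role <- ifelse(grepl("_guide$", nm), "guide",
                   ifelse(grepl("_passenger$", nm), "passenger", NA))
    if (anyNA(role)) {
      stop("FASTA headers must end in _guide or _passenger: ",
           paste(nm[is.na(role)], collapse = ", "))
    }
    base <- sub("_(guide|passenger)$", "", nm)
    ids <- unique(base)
    g <- as.character(seqs)[match(paste0(ids, "_guide"), nm)]
    p <- as.character(seqs)[match(paste0(ids, "_passenger"), nm)]
    if (anyNA(g) || anyNA(p)) {
      stop("unpaired FASTA record(s) for id(s): ",
           paste(ids[is.na(g) | is.na(p)], collapse = ", "))
    }
    sirna_panel(ids, g, p, duplex_length = duplex_length)
  } else {
    sep <- detect_sep(path)
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "#")
    need <- c("id", "guide", "passenger")
    if (!all(need %in% names(df))) {
      stop("panel table must have columns: ", paste(need, collapse = ", "))
    }
    sirna_panel(df$id, df$guide, df$passenger, duplex_length = duplex_length)
  }
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write an siRNA panel
#'
#' @param panel A [sirna_panel()].
#' @param path Output path; `.fa`/`.fasta` writes paired FASTA, anything else
#'   a TSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "sirna_panel"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "fna")) {
    seqs <- Biostrings::RNAStringSet(
      stats::setNames(c(rbind(panel$guide, panel$passenger)),
                      c(rbind(paste0(panel$id, "_guide"),
                              paste0(panel$id, "_passenger")))))
    Biostrings::writeXStringSet(seqs, path)
  } else {
    utils::write.table(panel[, c("id", "guide", "passenger")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a relative luciferase activity table
#'
#' Expects a delimited file with header columns `sirna_id`, `assay`
#' (`CM` = complete-match on-target reporter, `SM` = seed-match off-target
#' reporter), `concentration_nM`, and `activity_pct` (relative luciferase
#' activity as percent of the non-targeting control; low values mean strong
#' silencing).
#'
#' @param path Input TSV/CSV.
#' @param panel Optional [sirna_panel()] to cross-check ids against.
#' @return A data frame of class `activity_table`.
#' @export
read_activities <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  activity_table(df, panel = panel)
}

#' @rdname read_activities
#' @param df Data frame with the columns above.
#' @export
activity_table <- function(df, panel = NULL) {
  need <- c("sirna_id", "assay", "concentration_nM", "activity_pct")
  if (!all(need %in% names(df))) {
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$sirna_id <- as.character(df$sirna_id)
  bad_assay <- setdiff(unique(df$assay), c("CM", "SM"))
  if (length(bad_assay) > 0L) {
    stop("unknown assay label(s): ", paste(bad_assay, collapse = ", "))
  }
  df$concentration_nM <- as.numeric(df$concentration_nM)
  df$activity_pct <- as.numeric(df$activity_pct)
  if (anyNA(df$activity_pct) || any(df$activity_pct < 0)) {
    stop("activities must be non-negative numbers")
  }
  key <- paste(df$sirna_id, df$assay, df$concentration_nM)
  if (anyDuplicated(key)) {
    stop("duplicate (id, assay, concentration) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(df$sirna_id), panel$id)
    if (length(unknown) > 0L) {
      stop("activity id(s) absent from the panel: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(df, class = c("activity_table", "data.frame"))
}

#' Write an activity table
#' @param activities An `activity_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_activities <- function(activities, path) {
  utils::write.table(activities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check the functional-siRNA sequence rules
#'
#' Evaluates the four empirical design rules for siRNAs functional in
#' mammalian cells on one guide strand (positions 1-based from the guide 5'
#' end, core positions 1-19):
#' \itemize{
#'   \item rule i: A/U at guide position 1 (unstable guide 5' terminus);
#'   \item rule ii: G/C at guide position 19 (equivalently G/C at the
#'     passenger 5' end, by core complementarity);
#'   \item rule iii: at least 4 A/U residues in the 5'-terminal 7 nt of the
#'     guide (variant `"fig1b"`, positions 1-7, the default) or at least 4
#'     A/U in positions 2-7 (variant `"results"`);
#'   \item rule iv: no G/C run of 9 or more consecutive nucleotides in the
#'     core.
#' }
#'
#' @param guide Guide strand (21 nt) or guide core (>= 19 nt); only positions
#'   1-19 are inspected.
#' @param variant Which published phrasing of rule iii to apply.
#' @return A list of class `rule_report` with the four per-rule logicals and
#'   `overall` (their conjunction).
#' @examples
#' check_functional_rules("UUAUAAUGGCCGGCAUCGC")
#' @export
check_functional_rules <- function(guide, variant = c("fig1b", "results")) {
  variant <- match.arg(variant)
  s <- normalize_rna(guide)
  if (length(s) < 19L) stop("guide must be at least 19 nt")
  core <- s[1:19]
  au <- core %in% c("A", "U")
  gc <- core %in% c("G", "C")
  rule_i <- au[1L]
  rule_ii <- gc[19L]
  rule_iii <- if (variant == "fig1b") sum(au[1:7]) >= 4L else sum(au[2:7]) >= 4L
  runs <- rle(gc)
  rule_iv <- !any(runs$values & runs$lengths >= 9L)
  structure(
    list(rule_i_5prime_AU = rule_i,
         rule_ii_pos19_GC = rule_ii,
         rule_iii_AU_rich_seed_side = rule_iii,
         rule_iv_no_long_GC_stretch = rule_iv,
         overall = rule_i && rule_ii && rule_iii && rule_iv,
         variant = variant),
    class = "rule_report")
}

#' @export
print.rule_report <- function(x, ...) {
  cat("Functional siRNA rule report (variant:", x$variant, ")\n")
  for (nm in c("rule_i_5prime_AU", "rule_ii_pos19_GC",
               "rule_iii_AU_rich_seed_side", "rule_iv_no_long_GC_stretch")) {
    cat(sprintf("  %-28s %s\n", nm, if (x[[nm]]) "PASS" else "FAIL"))
  }
  cat("  overall:", if (x$overall) "PASS" else "FAIL", "\n")
  invisible(x)
}
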