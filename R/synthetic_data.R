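#' Parameters for the synthetic siRNA panel generator
#'
#' Describes the simulated world used to exercise the pipeline in place of a
#' real reporter-assay dataset: a panel of rule-compliant siRNAs whose
#' seed-match (SM, off-target) activity is a linear function of two planted
#' subregion stabilities plus Gaussian noise, and whose complete-match (CM,
#' on-target) activity is uniformly strong with no sequence dependence.
#'
#' SM activity at concentration c is
#' `clamp(beta0 + s(c) * (beta_neg * (Tm(region_neg) - center_neg) +
#' beta_pos * (Tm(region_pos) - center_pos)) + N(0, sigma), 0, 120)`,
#' where `s(c)` is `conc_scale`. The centering constants are fixed reference
#' means of the planted-region Tm over rule-compliant random cores; they keep
#' `beta0` interpretable as the mean SM activity and do not change any
#' correlation. CM activity is `clamp(cm_mean_by_conc(c) + N(0, cm_sigma),
#' 0, 120)`: near-complete silencing at 5/50 nM, partial at 0.5 nM, none at
#' 0.05 nM.
#'
#' @param n_sirnas Panel size (default 26).
#' @param seed RNG seed.
#' @param enforce_rules Reject candidate cores until all four functional
#'   rules pass (default TRUE).
#' @param overhang 2-nt 3' overhang appended to both strands (default "UU").
#' @param region_neg,region_pos Planted subregions `c(x, y)`: stability of
#'   `region_neg` (default 2-5) lowers SM activity (promotes the off-target
#'   effect); stability of `region_pos` (default 9-14) raises it.
#' @param beta0 Baseline SM activity, percent (default 55).
#' @param beta_neg,beta_pos Effect sizes in percent per degree C (defaults
#'   -1.3 and +1.1; see the package vignette for the calibration rationale).
#' @param sigma SM Gaussian noise sd, percent (default 13).
#' @param conc_scale Named multipliers on both effect sizes per
#'   concentration (defaults: 0 at 0.05 nM, 0.3 at 0.5 nM, 1 at 5 and
#'   50 nM).
#' @param cm_mean_by_conc Named CM baseline means, percent (defaults 100,
#'   30, 8, 5 at 0.05/0.5/5/50 nM).
#' @param cm_sigma CM noise sd, percent (default 5).
#' @param center_neg,center_pos Tm centering constants, degrees C.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_sirnas = 26L, seed = 1L,
                              enforce_rules = TRUE, overhang = "UU",
                              region_neg = c(2L, 5L),
                              region_pos = c(9L, 14L),
                              beta0 = 55, beta_neg = -1.3, beta_pos = 1.1,
                              sigma = 13,
                              conc_scale = c("0.05" = 0, "0.5" = 0.3,
                                             "5" = 1, "50" = 1),
                              cm_mean_by_conc = c("0.05" = 100, "0.5" = 30,
                                                  "5" = 8, "50" = 5),
                              cm_sigma = 5,
                              center_neg = -26, center_pos = 19) {
  stopifnot(n_sirnas >= 3L, beta_neg < 0, beta_pos > 0, sigma >= 0,
            cm_sigma >= 0, nchar(overhang) == 2L)
  check_region <- function(reg) {
    stopifnot(length(reg) == 2L, reg[1L] >= 1L, reg[2L] <= 19L,
              reg[2L] - reg[1L] + 1L >= 2L)
  }
  check_region(region_neg)
  check_region(region_pos)
  stopifnot(setequal(names(conc_scale), names(cm_mean_by_conc)))
  structure(list(n_sirnas = as.integer(n_sirnas), seed = as.integer(seed),
                 enforce_rules = isTRUE(enforce_rules), overhang = overhang,
                 region_neg = as.integer(region_neg),
                 region_pos = as.integer(region_pos),
                 beta0 = beta0, beta_neg = beta_neg, beta_pos = beta_pos,
                 sigma = sigma, conc_scale = conc_scale,
                 cm_mean_by_conc = cm_mean_by_conc, cm_sigma = cm_sigma,
                 center_neg = center_neg, center_pos = center_pos),
            class = "simulation_params")
}

#' Generate a rule-compliant synthetic siRNA panel
#'
#' Draws 19-nt guide cores uniformly over ACGU with rejection sampling until
#' all four functional-siRNA rules pass (when `enforce_rules`), derives the
#' passenger strand as the reverse complement of the core, and appends the
#' 2-nt 3' overhang to both strands. Seeded and reproducible.
#'
#' @param params A [simulation_params()].
#' @param max_tries Rejection budget per siRNA (default 10000).
#' @return A [sirna_panel()] with ids `si01`, `si02`, ...
#' @examples
#' panel <- generate_panel(simulation_params(n_sirnas = 5, seed = 42))
#' @export
generate_panel <- function(params = simulation_params(), max_tries = 10000L) {
  stopifnot(inherits(params, "simulation_params"))
  nt <- c("A", "C", "G", "U")
  cores <- character(params$n_sirnas)
  with_rep_seed(params$seed, 0L, {
    for (i in seq_len(params$n_sirnas)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        core <- paste(sample(nt, 19L, replace = TRUE), collapse = "")
        if (!params$enforce_rules ||
            check_functional_rules(core)$overall) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("rejection budget exceeded while sampling siRNA ", i)
      cores[i] <- core
    }
  })
  guide <- paste0(cores, params$overhang)
  passenger <- paste0(vapply(cores, rna_revcomp, "", USE.NAMES = FALSE),
                      params$overhang)
  sirna_panel(sprintf("si%02d", seq_len(params$n_sirnas)), guide, passenger)
}

#' Simulate CM/SM reporter activities for a panel
#'
#' Produces the full 2-assay x 4-concentration activity table under the
#' model described in [simulation_params()]. All activities are clamped to
#' \[0, 120\] percent of the non-targeting control.
#'
#' @param panel A [sirna_panel()].
#' @param params A [simulation_params()].
#' @param cond,table Thermodynamic settings for the planted-region Tm.
#' @return An `activity_table`.
#' @export
simulate_activities <- function(panel, params = simulation_params(),
                                cond = thermo_conditions(),
                                table = nn_parameter_table()) {
  stopifnot(inherits(panel, "sirna_panel"), inherits(params, "simulation_params"))
  sub_tm <- function(region) {
    vapply(panel$guide_core, function(g) {
      melting_temperature(substr(g, region[1L], region[2L]), cond, table)
    }, 0, USE.NAMES = FALSE)
  }
  tm_neg <- sub_tm(params$region_neg) - params$center_neg
  tm_pos <- sub_tm(params$region_pos) - params$center_pos
  concs <- as.numeric(names(params$conc_scale))
  n <- nrow(panel)
  rows <- vector("list", 2L * length(concs))
  k <- 0L
  for (ci in seq_along(concs)) {
    cname <- names(params$conc_scale)[ci]
    s <- params$conc_scale[[cname]]
    sm_mu <- params$beta0 +
      s * (params$beta_neg * tm_neg + params$beta_pos * tm_pos)
    sm <- with_rep_seed(params$seed, 1000L + ci,
                        sm_mu + stats::rnorm(n, 0, params$sigma))
    cm <- with_rep_seed(params$seed, 2000L + ci,
                        params$cm_mean_by_conc[[cname]] +
                          stats::rnorm(n, 0, params$cm_sigma))
    clamp <- function(v) pmin(pmax(v, 0), 120)
    k <- k + 1L
    rows[[k]] <- data.frame(sirna_id = panel$id, assay = "SM",
                            concentration_nM = concs[ci],
                            activity_pct = clamp(sm))
    k <- k + 1L
    rows[[k]] <- data.frame(sirna_id = panel$id, assay = "CM",
                            concentration_nM = concs[ci],
                            activity_pct = clamp(cm))
  }
  activity_table(do.call(rbind, rows), panel = panel)
}

#' Simulate a ready-to-analyze dataset on disk
#'
#' Writes a panel (TSV and FASTA), an activity table (TSV), and a JSON file
#' recording the ground-truth generator parameters, in the exact dialects
#' the readers accept.
#'
#' @param params A [simulation_params()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_dataset <- function(params = simulation_params(), outdir = ".") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  panel <- generate_panel(params)
  activities <- simulate_activities(panel, params)
  paths <- list(
    panel_tsv = file.path(outdir, "panel.tsv"),
    panel_fasta = file.path(outdir, "panel.fa"),
    activities_tsv = file.path(outdir, "activities.tsv"),
    truth_json = file.path(outdir, "ground_truth.json"))
  write_panel(panel, paths$panel_tsv)
  write_panel(panel, paths$panel_fasta)
  write_activities(activities, paths$activities_tsv)
  truth <- unclass(params)
  truth$conc_scale <- as.list(params$conc_scale)
  truth$cm_mean_by_conc <- as.list(params$cm_mean_by_conc)
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
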