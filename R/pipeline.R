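#' End-to-end run configuration
#'
#' Exactly one of `panel_path`+`activities_path` (analyze user data) or
#' `simulate` (a [simulation_params()] object; generate then analyze) must
#' be supplied. The seed is propagated to every stochastic stage.
#'
#' @param panel_path,activities_path Input files for user data.
#' @param simulate A [simulation_params()] for synthetic data.
#' @param outdir Output directory.
#' @param assays Named list mapping assay to the concentrations (nM)
#'   analyzed; the default mirrors the reported analysis: SM at 5 and 50 nM
#'   (where the off-target effect is measurable), CM at all four.
#' @param n_reps,subset_size,top_ks Resampling settings.
#' @param seed Master seed.
#' @param regions_of_interest List of `c(x, y)` regions for the
#'   train/validation split analysis (defaults: 2-5, 2-8, 8-14, 9-14).
#' @param combined_pairs List of `list(A =, B =, scheme =)` two-region
#'   comparisons (default: 2-5 with 9-14 and 2-8 with 9-14, `tm_difference`
#'   scheme).
#' @param cond,table Thermodynamic settings.
#' @param verbose Print stage-labeled progress.
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel_path = NULL, activities_path = NULL,
                       simulate = NULL, outdir = "sirscan_out",
                       assays = list(SM = c(5, 50),
                                     CM = c(0.05, 0.5, 5, 50)),
                       n_reps = 1000L, subset_size = 13L, top_ks = c(1L, 10L),
                       seed = 1L,
                       regions_of_interest = list(c(2L, 5L), c(2L, 8L),
                                                  c(8L, 14L), c(9L, 14L)),
                       combined_pairs = list(
                         list(A = c(2L, 5L), B = c(9L, 14L),
                              scheme = "tm_difference"),
                         list(A = c(2L, 8L), B = c(9L, 14L),
                              scheme = "tm_difference")),
                       cond = thermo_conditions(),
                       table = nn_parameter_table(), verbose = TRUE) {
  have_paths <- !is.null(panel_path) || !is.null(activities_path)
  if (have_paths && !is.null(simulate)) {
    stop("config error: supply either input paths or a simulate block, not both")
  }
  if (!have_paths && is.null(simulate)) {
    stop("config error: supply input paths or a simulate block")
  }
  if (have_paths && (is.null(panel_path) || is.null(activities_path))) {
    stop("config error: both panel_path and activities_path are required")
  }
  structure(list(panel_path = panel_path, activities_path = activities_path,
                 simulate = simulate, outdir = outdir, assays = assays,
                 n_reps = as.integer(n_reps),
                 subset_size = as.integer(subset_size),
                 top_ks = as.integer(top_ks), seed = as.integer(seed),
                 regions_of_interest = regions_of_interest,
                 combined_pairs = combined_pairs, cond = cond, table = table,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

stage_log <- function(cfg, stage, ...) {
  if (cfg$verbose) message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the siRNA panel and activity table, then per
#' analyzed (assay, concentration): writes every siRNA's subregion Tm
#' matrix, the correlation map TSV + top-region JSON, resampling position
#' histograms for both correlation signs and every `top_k`, and (for SM
#' assays) train/validation split summaries for the regions of interest and
#' the configured two-region combinations. A `manifest.json` listing every
#' output with the embedded configuration is written last; all files are
#' timestamp-free so identical configs produce byte-identical output.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the panel, activities, per-analysis
#'   results, and the manifest path.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage_log(cfg, "init", "effective seed: ", cfg$seed)
  if (!is.null(cfg$simulate)) {
    stage_log(cfg, "simulate", "generating ", cfg$simulate$n_sirnas,
              " rule-compliant siRNAs")
    ds <- simulate_dataset(cfg$simulate, file.path(cfg$outdir, "data"))
    panel <- read_panel(ds$panel_tsv)
    activities <- read_activities(ds$activities_tsv, panel = panel)
    # outdir-relative paths keep the manifest byte-identical across runs
    inputs <- lapply(ds, function(p) file.path("data", basename(p)))
  } else {
    stage_log(cfg, "load", cfg$panel_path)
    panel <- read_panel(cfg$panel_path)
    activities <- read_activities(cfg$activities_path, panel = panel)
    inputs <- list(panel = cfg$panel_path, activities = cfg$activities_path)
  }
  stage_log(cfg, "rules", "checking functional rules")
  rules <- lapply(panel$guide_core, check_functional_rules)
  rules_df <- data.frame(
    id = panel$id,
    do.call(rbind, lapply(rules, function(r)
      as.data.frame(r[c("rule_i_5prime_AU", "rule_ii_pos19_GC",
                        "rule_iii_AU_rich_seed_side",
                        "rule_iv_no_long_GC_stretch", "overall")]))))
  utils::write.table(rules_df, file.path(cfg$outdir, "rule_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log(cfg, "thermo", "computing subregion Tm matrices")
  feats <- panel_tm_features(panel, cfg$cond, cfg$table)
  tm_dir <- file.path(cfg$outdir, "tm_matrices")
  dir.create(tm_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(panel))) {
    write_tm_matrix(
      subregion_tm_matrix(panel$guide_core[i], cfg$cond, cfg$table),
      file.path(tm_dir, paste0(panel$id[i], ".tsv")), digits = 2)
  }
  outputs <- c(list(rule_report = "rule_report.tsv"),
               stats::setNames(
                 as.list(file.path("tm_matrices", paste0(panel$id, ".tsv"))),
                 paste0("tm_", panel$id)))
  results <- list()
  for (assay in names(cfg$assays)) {
    for (conc in cfg$assays[[assay]]) {
      tag <- paste0(assay, "_", gsub("\\.", "p", format(conc)), "nM")
      stage_log(cfg, "scan", tag)
      cmap <- correlation_map(panel, activities, assay, conc,
                              cfg$cond, cfg$table, features = feats)
      map_tsv <- paste0("corrmap_", tag, ".tsv")
      map_json <- paste0("corrmap_", tag, ".json")
      export_heatmap(cmap, file.path(cfg$outdir, map_tsv),
                     file.path(cfg$outdir, map_json))
      outputs[[map_tsv]] <- map_tsv
      outputs[[map_json]] <- map_json
      res <- list(cmap = cmap)
      stage_log(cfg, "resample", tag)
      for (sign in c("negative", "positive")) {
        for (tk in cfg$top_ks) {
          scfg <- sampling_config(cfg$n_reps, cfg$subset_size, tk, sign,
                                  cfg$seed, assay, conc)
          summ <- sampling_frequencies(panel, activities, scfg,
                                       cfg$cond, cfg$table, features = feats)
          hist_tsv <- paste0("sampling_", tag, "_", sign, "_top", tk, ".tsv")
          write_sampling_summary(summ, file.path(cfg$outdir, hist_tsv))
          outputs[[hist_tsv]] <- hist_tsv
          res[[paste0(sign, "_top", tk)]] <- summ
        }
      }
      if (assay == "SM") {
        stage_log(cfg, "split", tag)
        scfg <- sampling_config(cfg$n_reps, cfg$subset_size, 1L, "negative",
                                cfg$seed, assay, conc)
        splits <- lapply(cfg$regions_of_interest, function(reg)
          split_correlations(panel, activities, reg, scfg,
                             cfg$cond, cfg$table, features = feats))
        combos <- lapply(cfg$combined_pairs, function(pair)
          combined_region_correlation(panel, activities, pair$A, pair$B,
                                      pair$scheme, scfg,
                                      cfg$cond, cfg$table, features = feats))
        split_json <- paste0("split_", tag, ".json")
        write_split_summary(splits, combos,
                            file.path(cfg$outdir, split_json), scfg)
        outputs[[split_json]] <- split_json
        res$splits <- splits
        res$combined <- combos
      }
      results[[tag]] <- res
    }
  }
  manifest <- list(
    tool = "sirscan",
    config = serializable_config(cfg),
    inputs = lapply(inputs, as.character),
    outputs = outputs)
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage_log(cfg, "done", "manifest: ", manifest_path)
  invisible(list(panel = panel, activities = activities, results = results,
                 manifest = manifest_path))
}

serializable_config <- function(cfg) {
  out <- unclass(cfg)
  out$cond <- unclass(cfg$cond)
  out$table <- cfg$table$source_tag
  out$simulate <- if (!is.null(cfg$simulate)) {
    s <- unclass(cfg$simulate)
    s$conc_scale <- as.list(cfg$simulate$conc_scale)
    s$cm_mean_by_conc <- as.list(cfg$simulate$cm_mean_by_conc)
    s
  }
  out$verbose <- NULL
  out$outdir <- NULL  # location-independent manifest
  out
}

# TSV: position, start_count, end_count; config echoed in a header comment
write_sampling_summary <- function(summ, path) {
  cfg <- summ$config
  header <- sprintf(
    "# sampling summary: n_reps=%d subset_size=%d top_k=%d sign=%s seed=%d assay=%s conc=%snM modal_region=%d-%d",
    cfg$n_reps, cfg$subset_size, cfg$top_k, cfg$sign, cfg$seed, cfg$assay,
    format(cfg$concentration), summ$modal_region[["x"]],
    summ$modal_region[["y"]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df <- data.frame(position = as.integer(names(summ$start_hist)),
                   start_count = as.integer(summ$start_hist),
                   end_count = as.integer(summ$end_hist))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_split_summary <- function(splits, combos, path, scfg) {
  sum_split <- function(s) list(
    region = paste0(s$region[["x"]], "-", s$region[["y"]]),
    train_mean_abs_r = mean(s$train_r),
    train_median_abs_r = stats::median(s$train_r),
    valid_mean_abs_r = mean(s$valid_r),
    valid_median_abs_r = stats::median(s$valid_r),
    t_stat = s$t_stat, p_value = s$p_value)
  sum_combo <- function(s) list(
    regionA = paste0(s$regionA[["x"]], "-", s$regionA[["y"]]),
    regionB = paste0(s$regionB[["x"]], "-", s$regionB[["y"]]),
    scheme = s$scheme,
    train_mean_abs_r_combined = mean(s$train_combined_r),
    train_mean_abs_r_single = mean(s$train_single_r),
    valid_mean_abs_r_combined = mean(s$valid_combined_r),
    valid_mean_abs_r_single = mean(s$valid_single_r),
    t_train = s$t_train, p_train = s$p_train,
    t_valid = s$t_valid, p_valid = s$p_valid)
  jsonlite::write_json(
    list(config = unclass(scfg),
         single_regions = lapply(splits, sum_split),
         combined_regions = lapply(combos, sum_combo)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
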