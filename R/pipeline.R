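required_panel_cols <- c("subject_id", "dataset_id", "sex", "baseline_age",
                         "time", "visit_index")

#' Validate input panels against the pipeline's contracts
#'
#' Fatal problems (missing required columns) raise an error naming the
#' column. Non-fatal findings are listed with counts: subjects with
#' non-monotone visit times, subjects failing the >= 2 observations /
#' >= 1.5 years follow-up rule, duplicated (subject, time) rows and unknown
#' measure types in the metadata.
#'
#' @param panel long-format panel (data frame or TSV path).
#' @param metadata optional measures metadata (data frame or TSV path) with
#'   columns `measure` and `type` in `{cortical, subcortical, ventricle}`.
#' @return Object of class `validation_report`: list with `fatal` (always
#'   `FALSE` on return) and `findings` (data frame `check`, `count`).
#' @export
validate_inputs <- function(panel, metadata = NULL) {
  if (is.character(panel)) panel <- read_panel(panel)
  missing_cols <- setdiff(required_panel_cols, names(panel))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  findings <- list()
  by_subj <- split(panel$time, panel$subject_id)
  nonmono <- sum(vapply(by_subj, function(tt) any(diff(tt) <= 0), logical(1)))
  if (nonmono) findings$non_monotone_times <- nonmono
  short <- sum(vapply(by_subj, function(tt)
    length(tt) < 2 || (max(tt) - min(tt)) < 1.5, logical(1)))
  if (short) findings$below_min_followup <- short
  dup <- sum(duplicated(panel[, c("subject_id", "time")]))
  if (dup) findings$duplicated_subject_time <- dup
  if (!is.null(metadata)) {
    if (is.character(metadata)) metadata <- read_panel(metadata)
    if (!all(c("measure", "type") %in% names(metadata)))
      stop("metadata must have `measure` and `type` columns", call. = FALSE)
    unk <- sum(!metadata$type %in% c("cortical", "subcortical", "ventricle"))
    if (unk) findings$unknown_measure_type <- unk
  }
  structure(list(fatal = FALSE,
                 findings = data.frame(check = names(findings),
                                       count = as.integer(unlist(findings)))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x$findings)) cat("Validation: no findings\n")
  else { cat("Validation findings:\n"); print(x$findings, row.names = FALSE) }
  invisible(x)
}

write_stage_tsv <- function(x, path, stage, seed) {
  write_panel(x, path, provenance = c(stage = stage, seed = seed,
                                      version = as.character(utils::packageVersion("longchange"))))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in order: simulate (synthetic cohort) ->
#' harmonize (baseline z-scoring, memory composite, residualization, brain
#' deviation scores) -> changescore (change table) -> assoc (per-region
#' change-change associations with FDR) -> dimred (correlation, PCA,
#' consensus clustering) -> twosource (moment sweeps). Outputs are TSVs
#' under `out_dir`, each with a provenance comment line (stage, seed,
#' version); identical config and seed give byte-identical numeric outputs.
#'
#' @param config list with elements `seed` (integer), `out_dir`, `cohort`
#'   (a [cohort_config()] or arguments for one), `B` (bootstrap replicates,
#'   >= 99), `stages` (character subset of
#'   `c("simulate","harmonize","changescore","assoc","dimred","twosource")`),
#'   `K_max`, `cluster_reps`, and `twosource` (a [two_source_params()]).
#' @return Invisible list of stage outputs (also written to `out_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(seed = 1L, out_dir = "results", B = 199, K_max = 4,
         cluster_reps = 50,
         stages = c("simulate", "harmonize", "changescore", "assoc",
                    "dimred", "twosource")),
    config)
  if (cfg$B < 99) stop("B must be >= 99", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  on <- function(s) s %in% cfg$stages
  need <- function(x, stage, dep)
    if (is.null(x)) stop(sprintf("stage '%s' needs output of stage '%s'", stage, dep),
                         call. = FALSE)

  if (on("simulate")) {
    cc <- if (inherits(cfg$cohort, "cohort_config")) cfg$cohort
    else do.call(cohort_config, utils::modifyList(list(seed = cfg$seed),
                                                  as.list(cfg$cohort %||% list())))
    out$cohort <- generate_cohort(cc)
    out$cohort_config <- cc
    write_stage_tsv(out$cohort$brain_panel, file.path(cfg$out_dir, "brain_panel.tsv"),
                    "simulate", cfg$seed)
    write_stage_tsv(out$cohort$memory_panel, file.path(cfg$out_dir, "memory_panel.tsv"),
                    "simulate", cfg$seed)
    write_stage_tsv(out$cohort$truth, file.path(cfg$out_dir, "truth.tsv"),
                    "simulate", cfg$seed)
  }
  if (on("harmonize")) {
    need(out$cohort, "harmonize", "simulate")
    mem <- baseline_zscore(out$cohort$memory_panel)
    tests <- panel_measures(mem)
    mem$memory <- NA_real_
    for (d in unique(mem$dataset_id)) {
      in_d <- mem$dataset_id == d
      base <- mem[in_d & mem$visit_index == 1L, ]
      cm <- pca_composite(base[, tests, drop = FALSE])
      mem$memory[in_d] <- predict_composite(cm, mem[in_d, tests, drop = FALSE])
    }
    out$memory_adj <- residualize_memory(mem)
    out$brain_devs <- brain_deviation_scores(out$cohort$brain_panel)
    write_stage_tsv(out$brain_devs, file.path(cfg$out_dir, "brain_deviations.tsv"),
                    "harmonize", cfg$seed)
  }
  if (on("changescore")) {
    need(out$brain_devs, "changescore", "harmonize")
    out$change_table <- build_change_table(out$brain_devs, out$memory_adj,
                                           subjects = out$cohort$truth)
    write_stage_tsv(out$change_table, file.path(cfg$out_dir, "change_table.tsv"),
                    "changescore", cfg$seed)
  }
  if (on("assoc")) {
    need(out$change_table, "assoc", "changescore")
    out$regions <- regional_associations(out$change_table, B = cfg$B,
                                         seed = cfg$seed)
    write_stage_tsv(out$regions, file.path(cfg$out_dir, "regions_results.tsv"),
                    "assoc", cfg$seed)
  }
  if (on("dimred")) {
    need(out$change_table, "dimred", "changescore")
    regs <- region_cols(out$change_table)
    out$correlation <- change_correlation(out$change_table, regs)
    out$pca <- pca_summary(out$correlation$matrix)
    out$clusters <- consensus_cluster(out$change_table, regs,
                                      K_max = min(cfg$K_max, length(regs) - 1),
                                      reps = cfg$cluster_reps,
                                      null_reps = cfg$cluster_reps,
                                      seed = cfg$seed)
    write_stage_tsv(out$clusters$stats, file.path(cfg$out_dir, "cluster_stats.tsv"),
                    "dimred", cfg$seed)
    write_stage_tsv(data.frame(region = names(out$clusters$assignments),
                               cluster = out$clusters$assignments),
                    file.path(cfg$out_dir, "clusters.tsv"), "dimred", cfg$seed)
  }
  if (on("twosource")) {
    ts <- cfg$twosource %||% two_source_params(n = 400, reps = 50)
    out$sweeps <- rbind(
      moment_sweep(ts, "dispersion", c(0.5, 1, 2) * ts$brain_aging$omega,
                   seed = cfg$seed),
      moment_sweep(ts, "mean", ts$brain_aging$xi + c(-0.15, 0, 0.15),
                   seed = cfg$seed + 100),
      moment_sweep(ts, "skewness", c(0, -3, -6), seed = cfg$seed + 200))
    write_stage_tsv(out$sweeps, file.path(cfg$out_dir, "sweep_summary.tsv"),
                    "twosource", cfg$seed)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
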