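# Typed conditions so the CLI can map failures to exit codes.
validation_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = "nitrisip_validation_error"))
}
stage_error <- function(stage, parent_msg) {
  stop(errorCondition(sprintf("stage '%s' failed: %s", stage, parent_msg),
                      class = "nitrisip_stage_error"))
}

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()].
#' Unknown keys are rejected; the full configuration is echoed into the
#' run report for provenance.  All randomness in a run derives from the
#' single `seed`, split deterministically per stage.
#'
#' @param preset Scenario preset for the simulate stage ("CK", "WI1",
#'   "WI2").
#' @param seed Root integer seed.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, in order, from
#'   `simulate`, `sip_quant`, `partition`, `classify`, `stats`.
#' @param gradients,slurry,totals,asv_counts Input table paths (only used
#'   when the simulate stage is disabled).
#' @param V,m Slurry soil water volume (L) and dry mass (kg).
#' @param qc_r2 QC threshold on rate-fit r-squared.
#' @param window_mode,threshold,estimator,n_boot Heavy-window and
#'   labeled-proportion options (see [quantify_labeling()]).
#' @param alpha,correction,mapping Enrichment-test options (see
#'   [classify_table()]).
#' @param ace_baseline Subtract the acetylene background before
#'   partitioning.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "CK", seed = 1L, out_dir = tempfile("nitrisip_"),
                            stages = c("simulate", "sip_quant", "partition",
                                       "classify", "stats"),
                            gradients = NULL, slurry = NULL, totals = NULL,
                            asv_counts = NULL,
                            V = 0.005, m = 0.0095, qc_r2 = 0.9,
                            window_mode = "adaptive", threshold = 1.725,
                            estimator = "normalized_excess", n_boot = 1000L,
                            alpha = 0.05, correction = "none",
                            mapping = "mechanistic", ace_baseline = FALSE) {
  known <- c("simulate", "sip_quant", "partition", "classify", "stats")
  bad <- setdiff(stages, known)
  if (length(bad)) validation_error("unknown stage(s): %s",
                                    paste(bad, collapse = ", "))
  if (!preset %in% c("CK", "WI1", "WI2")) {
    validation_error("unknown preset: %s", preset)
  }
  if (alpha <= 0 || alpha >= 1) validation_error("alpha outside (0, 1)")
  if (!"simulate" %in% stages) {
    for (p in c("gradients", "slurry", "totals", "asv_counts")) {
      v <- get(p)
      if (is.null(v)) validation_error("path `%s` required when simulate stage is disabled", p)
    }
  }
  structure(list(preset = preset, seed = as.integer(seed), out_dir = out_dir,
                 stages = stages, gradients = gradients, slurry = slurry,
                 totals = totals, asv_counts = asv_counts, V = V, m = m,
                 qc_r2 = qc_r2, window_mode = window_mode,
                 threshold = threshold, estimator = estimator,
                 n_boot = as.integer(n_boot), alpha = alpha,
                 correction = correction, mapping = mapping,
                 ace_baseline = isTRUE(ace_baseline)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) validation_error("unknown config key(s): %s",
                                    paste(bad, collapse = ", "))
  do.call(pipeline_config, x)
}

#' Validate pipeline input tables
#'
#' Schema and sanity checks on the four input tables: required columns,
#' non-negative copies/counts, strictly increasing slurry time points per
#' series, and replicate balance.  Issues are returned, not thrown.
#'
#' @param gradients,slurry,totals,asv_counts data.frames (or NULL to
#'   skip).
#' @return data.frame with columns `table, row, column, problem`
#'   (zero rows when everything is well-formed).
#' @export
validate_inputs <- function(gradients = NULL, slurry = NULL, totals = NULL,
                            asv_counts = NULL) {
  issues <- list()
  add <- function(tab, row, col, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(
      table = tab, row = row, column = col, problem = problem,
      stringsAsFactors = FALSE)
  }
  need_cols <- function(d, tab, cols) {
    miss <- setdiff(cols, names(d))
    for (m in miss) add(tab, NA_integer_, m, "missing column")
    length(miss) == 0L
  }
  if (!is.null(gradients) &&
      need_cols(gradients, "gradients",
                c("gene", "isotope", "replicate", "fraction",
                  "density_g_ml", "copies"))) {
    bad <- which(gradients$copies < 0)
    for (b in bad) add("gradients", b, "copies", "negative copies")
    if (!all(gradients$isotope %in% c("12C", "13C"))) {
      add("gradients", NA_integer_, "isotope", "isotope not 12C/13C")
    }
  }
  if (!is.null(slurry) &&
      need_cols(slurry, "slurry",
                c("soil", "substrate", "inhibitor_combo", "analyte",
                  "replicate", "time_h", "conc_mgN_L"))) {
    bad <- which(slurry$conc_mgN_L < 0)
    for (b in bad) add("slurry", b, "conc_mgN_L", "negative concentration")
    key <- interaction(slurry$soil, slurry$substrate,
                       slurry$inhibitor_combo, slurry$analyte,
                       slurry$replicate, drop = TRUE)
    for (d in split(seq_len(nrow(slurry)), key)) {
      tt <- slurry$time_h[d]
      dup <- d[which(duplicated(tt))]
      for (b in dup) add("slurry", b, "time_h", "duplicated time point")
      if (!length(dup) && is.unsorted(tt, strictly = FALSE)) {
        add("slurry", d[1], "time_h", "times not sorted")
      }
    }
  }
  if (!is.null(totals) &&
      need_cols(totals, "totals", c("gene", "treatment", "copies_per_g"))) {
    bad <- which(totals$copies_per_g < 0)
    for (b in bad) add("totals", b, "copies_per_g", "negative abundance")
  }
  if (!is.null(asv_counts) &&
      need_cols(asv_counts, "asv_counts",
                c("asv_id", "context", "isotope", "replicate", "count"))) {
    bad <- which(asv_counts$count < 0 |
                   asv_counts$count != round(asv_counts$count))
    for (b in bad) add("asv_counts", b, "count", "count not a non-negative integer")
    tab <- table(asv_counts$asv_id, asv_counts$isotope, asv_counts$context)
    if (length(tab) && length(unique(as.vector(tab))) > 1L) {
      add("asv_counts", NA_integer_, "replicate", "unbalanced replicates")
    }
  }
  if (!length(issues)) {
    return(data.frame(table = character(0), row = integer(0),
                      column = character(0), problem = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, sip_quant, partition,
#' classify, stats), writing each stage's tables under
#' `config$out_dir` and a consolidated `report.json`.  A stage failure
#' aborts the run with a typed error naming the stage.  The report embeds
#' the configuration, package version and seed; given identical
#' configuration and seed the report is byte-identical between runs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    package = "nitrisip",
    version = as.character(utils::packageVersion("nitrisip")),
    seed = config$seed,
    config = unclass(config),
    stages = list(), warnings = character(0), tables = list())
  run_stage <- function(stage, expr) {
    say("[%s] running", stage)
    r <- tryCatch(expr, error = function(e) {
      if (inherits(e, "nitrisip_validation_error")) stop(e)
      stage_error(stage, conditionMessage(e))
    })
    report$stages[[stage]] <<- "ok"
    r
  }
  dat <- NULL
  if ("simulate" %in% config$stages) {
    dat <- run_stage("simulate", make_scenario(
      config$preset, seed = config$seed, out_dir = config$out_dir))
  } else {
    dat <- run_stage("load", list(
      gradients = read_tsv(config$gradients),
      slurry = read_tsv(config$slurry),
      totals = read_tsv(config$totals),
      asv_counts = read_tsv(config$asv_counts)))
  }
  issues <- validate_inputs(dat$gradients, dat$slurry, dat$totals,
                            dat$asv_counts)
  if (nrow(issues)) {
    validation_error("input validation failed: %s",
                     paste(sprintf("%s[%s].%s: %s", issues$table,
                                   issues$row, issues$column,
                                   issues$problem), collapse = "; "))
  }
  if ("sip_quant" %in% config$stages) {
    est <- run_stage("sip_quant", quantify_labeling(
      dat$gradients, dat$totals, window_mode = config$window_mode,
      threshold = config$threshold, estimator = config$estimator,
      n_boot = config$n_boot, seed = child_seed(config$seed, 10)))
    write_tsv(est, file.path(config$out_dir, "label_estimates.tsv"))
    report$tables$label_estimates <- est
    if (any(!is.na(est$flag) & est$flag == "empty_window")) {
      report$warnings <- c(report$warnings,
                           paste("empty heavy window for gene(s):",
                                 paste(est$gene[!is.na(est$flag) &
                                                  est$flag == "empty_window"],
                                       collapse = ", ")))
    }
  }
  if ("partition" %in% config$stages) {
    pot <- run_stage("partition", estimate_potentials(
      dat$slurry, V = config$V, m = config$m, qc_r2 = config$qc_r2,
      ace_baseline = config$ace_baseline))
    write_tsv(pot$fits, file.path(config$out_dir, "potentials.tsv"))
    part <- pot$partition
    part_df <- data.frame(
      quantity = c("Np_AOA", "Np_AOB", "Np_comammox_alone",
                   "Np_AOA_plus_AOB", "Np_comammox_coexist",
                   "pct_U_AOA_plus_AOB", "pct_U_comammox",
                   "pct_I_AOA", "pct_I_AOB", "pct_I_comammox",
                   "delta_AB", "delta_C"),
      value = c(part$Np_AOA, part$Np_AOB, part$Np_comammox_alone,
                part$Np_AOA_plus_AOB, part$Np_comammox_coexist,
                part$pct_scheme_U[["AOA_plus_AOB"]],
                part$pct_scheme_U[["comammox_coexist"]],
                part$pct_scheme_I[["AOA"]], part$pct_scheme_I[["AOB"]],
                part$pct_scheme_I[["comammox_alone"]],
                part$delta_AB, part$delta_C),
      stringsAsFactors = FALSE)
    write_tsv(part_df, file.path(config$out_dir, "partition.tsv"))
    report$tables$partition <- part_df
    report$tables$interactions <- interaction_report(list(part))
    if (any(!pot$partition$qc)) {
      report$warnings <- c(report$warnings,
                           paste("rate fits failing QC in arm(s):",
                                 paste(names(part$qc)[!part$qc],
                                       collapse = ", ")))
    }
    if (length(part$flags)) {
      report$warnings <- c(report$warnings, part$flags)
    }
    report$tables$potentials_by_arm <- pot$fits
  }
  if ("classify" %in% config$stages) {
    cls <- run_stage("classify", classify_table(
      dat$asv_counts, alpha = config$alpha,
      correction = config$correction, mapping = config$mapping))
    write_tsv(cls$calls, file.path(config$out_dir, "metabolic_calls.tsv"))
    jsonlite::write_json(as.list(cls$class_counts),
                         file.path(config$out_dir, "class_counts.json"),
                         auto_unbox = TRUE)
    report$tables$class_counts <- as.list(cls$class_counts)
  }
  if ("stats" %in% config$stages &&
      !is.null(report$tables$potentials_by_arm)) {
    st <- run_stage("stats", {
      fits <- report$tables$potentials_by_arm
      fits$arm <- paste(fits$inhibitor_combo, fits$analyte, sep = "|")
      keep <- fits$arm %in% PARTITION_ARMS$key
      compare_groups(fits[keep, ], "Np", "arm", alpha = config$alpha)
    })
    write_tsv(st$table, file.path(config$out_dir, "stats_report.tsv"))
    report$tables$stats <- st$table
    report$tables$anova <- st$anova[c("F", "df_between", "df_within", "p")]
  }
  path <- file.path(config$out_dir, "report.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  say("report written to %s", path)
  invisible(report)
}
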