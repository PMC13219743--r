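#' Scenario presets
#'
#' Three soil scenarios spanning the qualitative regimes of interest:
#' `CK` (unfertilized control: comammox and AOB contribute comparably, no
#' comammox coexistence boost), `WI1` (long-term fertilization, AOB
#' dominant) and `WI2` (high organic input: AOB dominant, strong 13C
#' labeling of AOA and comammox, and a comammox coexistence boost > 1).
#' All presets carry `interaction_ab < 1`: the combined AOA+AOB potential
#' falls short of the sum of the single-guild potentials.
#'
#' @param preset One of "CK", "WI1", "WI2".
#' @return Named list with `label_truth`, `guild_rates`,
#'   `inhibitor_design` components.
#' @export
scenario_preset <- function(preset = c("CK", "WI1", "WI2")) {
  preset <- match.arg(preset)
  gc <- c(AOA = 0.40, AOB = 0.50, comammox = 0.55)
  ae <- c(AOA = 1, AOB = 1, comammox = 1)
  pars <- switch(preset,
    CK = list(p = c(AOA = 0.50, AOB = 0.10, comammox = 0.45),
              tot = c(AOA = 5e7, AOB = 2e7, comammox = 4e7),
              rates = guild_rates(aoa_rate = 0.0060, aob_rate = 0.0386,
                                  comammox_rate = 0.0283,
                                  interaction_ab = 0.7,
                                  comammox_coexistence_boost = 1.0,
                                  background_rate = 0.001)),
    WI1 = list(p = c(AOA = 0.55, AOB = 0.50, comammox = 0.40),
               tot = c(AOA = 3e7, AOB = 6e7, comammox = 2e7),
               rates = guild_rates(aoa_rate = 0.0080, aob_rate = 0.0600,
                                   comammox_rate = 0.0200,
                                   interaction_ab = 0.7,
                                   comammox_coexistence_boost = 1.0,
                                   background_rate = 0.001)),
    WI2 = list(p = c(AOA = 0.803, AOB = 0.60, comammox = 0.642),
               tot = c(AOA = 2e7, AOB = 8e7, comammox = 1e7),
               rates = guild_rates(aoa_rate = 0.0070, aob_rate = 0.0800,
                                   comammox_rate = 0.0250,
                                   interaction_ab = 0.7,
                                   comammox_coexistence_boost = 1.6,
                                   background_rate = 0.001)))
  list(preset = preset,
       label_truth = label_truth(gc, ae, pars$p, pars$tot),
       guild_rates = pars$rates,
       inhibitor_design = inhibitor_design())
}

#' Serialize scenario ground truth to JSON
#'
#' @param truth A `scenario_truth` list as returned in
#'   `make_scenario()$truth`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_scenario_truth <- function(truth, path) {
  x <- list(preset = truth$preset, seed = truth$seed,
            label_truth = as.data.frame(truth$label_truth),
            guild_rates = unclass(truth$guild_rates),
            inhibitor_design = list(
              inhibitors = rownames(truth$inhibitor_design),
              targets = colnames(truth$inhibitor_design),
              efficacy = unname(unclass(truth$inhibitor_design))),
            asv_classes = truth$asv_classes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read scenario ground truth back from JSON
#'
#' Inverse of [write_scenario_truth()]; the round trip is lossless.
#'
#' @param path File path to read.
#' @return A `scenario_truth` list.
#' @export
read_scenario_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lt <- label_truth(
    stats::setNames(x$label_truth$gc_content, x$label_truth$gene),
    stats::setNames(x$label_truth$atom_excess, x$label_truth$gene),
    stats::setNames(x$label_truth$labeled_proportion, x$label_truth$gene),
    stats::setNames(x$label_truth$total_copies, x$label_truth$gene))
  gr <- do.call(guild_rates, as.list(x$guild_rates))
  eff <- matrix(unlist(x$inhibitor_design$efficacy),
                nrow = length(x$inhibitor_design$inhibitors),
                dimnames = list(x$inhibitor_design$inhibitors,
                                x$inhibitor_design$targets))
  structure(list(preset = x$preset, seed = x$seed, label_truth = lt,
                 guild_rates = gr, inhibitor_design = inhibitor_design(eff),
                 asv_classes = as.data.frame(x$asv_classes)),
            class = "scenario_truth")
}

#' Generate a complete synthetic dataset for one scenario
#'
#' Runs the gradient, slurry and ASV-count simulators for a preset soil
#' scenario and returns the tables together with the machine-readable
#' ground truth used to generate them.  All randomness derives
#' deterministically from `seed`.
#'
#' @param preset One of "CK", "WI1", "WI2".
#' @param seed Integer root seed.
#' @param out_dir Optional directory; when given, writes `gradients.tsv`,
#'   `slurry.tsv`, `totals.tsv`, `asv_counts.tsv` and `truth.json`.
#' @param gradient_protocol,slurry_protocol Protocol overrides.
#' @param n_asv_per_class ASVs planted per metabolic class.
#' @param fold_change,dispersion ASV count simulator parameters.
#' @return List with elements `gradients`, `slurry`, `totals`,
#'   `asv_counts` (data.frames) and `truth` (a `scenario_truth` list).
#' @export
make_scenario <- function(preset = c("CK", "WI1", "WI2"), seed = 1L,
                          out_dir = NULL,
                          gradient_protocol = nitrisip::gradient_protocol(),
                          slurry_protocol = nitrisip::slurry_protocol(
                            measurement_sd = 0.02),
                          n_asv_per_class = c(both = 15, inorganic_only = 15,
                                              organic_only = 15,
                                              unlabeled = 105),
                          fold_change = 8, dispersion = 0.1) {
  preset <- match.arg(preset)
  sc <- scenario_preset(preset)
  gradients <- simulate_gradient(sc$label_truth, gradient_protocol,
                                 seed = child_seed(seed, 1))
  slurry <- simulate_slurry_experiment(
    sc$guild_rates, sc$inhibitor_design, slurry_protocol,
    soil = preset, substrate = "13C-Urea", seed = child_seed(seed, 2))
  asv_classes <- plant_asv_classes(n_asv_per_class,
                                   seed = child_seed(seed, 3))
  asv_counts <- simulate_asv_counts(asv_classes, fold_change, dispersion,
                                    seed = child_seed(seed, 4))
  totals <- data.frame(gene = sc$label_truth$gene, treatment = preset,
                       copies_per_g = sc$label_truth$total_copies,
                       stringsAsFactors = FALSE)
  truth <- structure(list(preset = preset, seed = as.integer(seed),
                          label_truth = sc$label_truth,
                          guild_rates = sc$guild_rates,
                          inhibitor_design = sc$inhibitor_design,
                          asv_classes = asv_classes),
                     class = "scenario_truth")
  out <- list(gradients = gradients, slurry = slurry, totals = totals,
              asv_counts = asv_counts, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(gradients, file.path(out_dir, "gradients.tsv"))
    write_tsv(slurry, file.path(out_dir, "slurry.tsv"))
    write_tsv(totals, file.path(out_dir, "totals.tsv"))
    write_tsv(asv_counts, file.path(out_dir, "asv_counts.tsv"))
    write_scenario_truth(truth, file.path(out_dir, "truth.json"))
  }
  out
}

#' Linear microcosm NH4+/NO3- trend table (smoke-test aid)
#'
#' A deliberately simple linear-trend generator for 0-28 day microcosm
#' ammonium/nitrate curves, useful for smoke tests of table plumbing; no
#' kinetic model is implied.
#'
#' @param days Sampling days.
#' @param nh4_start,nh4_slope,no3_start,no3_slope Linear parameters
#'   (mg N/kg and mg N/kg/day).
#' @param sd Additive Gaussian noise SD.
#' @param n_replicates Replicates.
#' @param seed Integer seed or NULL.
#' @return data.frame with columns `analyte, replicate, day, conc_mgN_kg`.
#' @export
simulate_microcosm_trend <- function(days = c(0, 7, 14, 21, 28),
                                     nh4_start = 20, nh4_slope = -0.5,
                                     no3_start = 5, no3_slope = 0.6,
                                     sd = 0.5, n_replicates = 3L,
                                     seed = NULL) {
  with_seed(seed, {
    grid <- expand.grid(analyte = c("NH4", "NO3"),
                        replicate = seq_len(n_replicates), day = days,
                        stringsAsFactors = FALSE)
    base <- ifelse(grid$analyte == "NH4",
                   nh4_start + nh4_slope * grid$day,
                   no3_start + no3_slope * grid$day)
    grid$conc_mgN_kg <- pmax(0, base + stats::rnorm(nrow(grid), 0, sd))
    grid[order(grid$analyte, grid$replicate, grid$day), ]
  })
}
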