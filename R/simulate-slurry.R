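#' Inhibitor combinations used in the partition assay
#'
#' The assay arms of the multi-inhibitor design: no inhibitor, NaClO3
#' alone (NO2- accumulation = combined AOA+AOB; NO3- increase = comammox in
#' the presence of active AOA/AOB), NaClO3+Sim (AOB alone), NaClO3+DMPP
#' (AOA alone), NaClO3+Sim+DMPP (comammox alone) and acetylene (background
#' control).
#'
#' @return Named list of character vectors of inhibitor names.
#' @export
assay_combos <- function() {
  list(none = character(0),
       NaClO3 = "NaClO3",
       `NaClO3+Sim` = c("NaClO3", "Sim"),
       `NaClO3+DMPP` = c("NaClO3", "DMPP"),
       `NaClO3+Sim+DMPP` = c("NaClO3", "Sim", "DMPP"),
       Ace = "Ace")
}

combo_label <- function(combo) {
  if (length(combo) == 0) "none" else paste(sort_inhib(combo), collapse = "+")
}

sort_inhib <- function(combo) combo[order(match(combo, INHIBITORS))]

# Surviving activity fraction of a target process under a combination of
# inhibitors: independent suppression, survival = prod(1 - efficacy).
survival_fraction <- function(design, combo, target) {
  if (length(combo) == 0) return(1)
  prod(1 - design[combo, target])
}

#' Effective linear production rates under an inhibitor combination
#'
#' Deterministic core of the slurry simulator.  The nitrite production
#' rate is the sum of the surviving AOA and AOB ammonia-oxidation rates
#' (the interaction multiplier applies only when both guilds are fully
#' unsuppressed), attenuated by surviving NOB activity (active NOB
#' convert NO2- to NO3- so nitrite does not accumulate), plus the
#' heterotrophic background.  The nitrate production rate is the surviving
#' comammox rate (the coexistence boost applies only when AOA and AOB are
#' both unsuppressed) plus the NOB-converted share of nitrite production.
#'
#' @param rates A [guild_rates()] object.
#' @param design An [inhibitor_design()].
#' @param combo Character vector of inhibitor names (possibly empty).
#' @return Named list with elements `NO2` and `NO3` (mg N/L/h).
#' @export
effective_rates <- function(rates, design, combo) {
  stopifnot(inherits(rates, "guild_rates"),
            inherits(design, "inhibitor_design"))
  unknown <- setdiff(combo, INHIBITORS)
  if (length(unknown)) {
    stopf("unknown inhibitor(s) in combo: %s", paste(unknown, collapse = ", "))
  }
  s_aoa <- survival_fraction(design, combo, "AOA")
  s_aob <- survival_fraction(design, combo, "AOB")
  s_cmx <- survival_fraction(design, combo, "comammox")
  s_nob <- survival_fraction(design, combo, "NOB")
  both_active <- s_aoa >= 1 - 1e-12 && s_aob >= 1 - 1e-12
  ao <- rates$aoa_rate * s_aoa + rates$aob_rate * s_aob
  if (both_active) ao <- ao * rates$interaction_ab
  cmx <- rates$comammox_rate * s_cmx
  if (both_active) cmx <- cmx * rates$comammox_coexistence_boost
  list(NO2 = ao * (1 - s_nob) + rates$background_rate,
       NO3 = cmx + ao * s_nob)
}

#' Simulate shaken-slurry NO2-/NO3- time series
#'
#' Concentrations follow `intercept + rate_eff * t` plus additive Gaussian
#' measurement noise, with `rate_eff` from [effective_rates()].  Negative
#' noisy concentrations are clamped to zero and flagged.
#'
#' @param rates A [guild_rates()] object.
#' @param design An [inhibitor_design()].
#' @param protocol A [slurry_protocol()].
#' @param combo Character vector of inhibitor names.
#' @param soil,substrate Labels carried through to the output table.
#' @param seed Integer seed or NULL.
#' @return A data.frame of class `slurry_table` with columns
#'   `soil, substrate, inhibitor_combo, analyte, replicate, time_h,
#'   conc_mgN_L, clamped`.
#' @export
simulate_slurry <- function(rates, design = inhibitor_design(),
                            protocol = slurry_protocol(),
                            combo = character(0),
                            soil = "soil", substrate = "substrate",
                            seed = NULL) {
  stopifnot(inherits(protocol, "slurry_protocol"))
  eff <- effective_rates(rates, design, combo)
  lbl <- combo_label(combo)
  times <- protocol$sample_times
  with_seed(seed, {
    rows <- list()
    for (analyte in c("NO2", "NO3")) {
      rate <- eff[[analyte]]
      icpt <- if (analyte == "NO2") protocol$no2_initial else protocol$no3_initial
      for (r in seq_len(protocol$n_replicates)) {
        conc <- icpt + rate * times
        if (protocol$measurement_sd > 0) {
          conc <- conc + stats::rnorm(length(times), 0, protocol$measurement_sd)
        }
        clamped <- conc < 0
        conc[clamped] <- 0
        rows[[length(rows) + 1L]] <- data.frame(
          soil = soil, substrate = substrate, inhibitor_combo = lbl,
          analyte = analyte, replicate = r, time_h = times,
          conc_mgN_L = conc, clamped = clamped, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("slurry_table", "data.frame")
    out
  })
}

#' Simulate the full multi-inhibitor slurry experiment
#'
#' Runs [simulate_slurry()] for every assay arm of [assay_combos()].
#'
#' @inheritParams simulate_slurry
#' @param combos Named list of inhibitor combinations (default
#'   [assay_combos()]).
#' @return A `slurry_table` data.frame covering all arms.
#' @export
simulate_slurry_experiment <- function(rates, design = inhibitor_design(),
                                       protocol = slurry_protocol(),
                                       combos = assay_combos(),
                                       soil = "soil", substrate = "substrate",
                                       seed = NULL) {
  with_seed(seed, {
    out <- do.call(rbind, lapply(combos, function(cb) {
      simulate_slurry(rates, design, protocol, cb, soil, substrate,
                      seed = NULL)
    }))
    rownames(out) <- NULL
    class(out) <- c("slurry_table", "data.frame")
    out
  })
}
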