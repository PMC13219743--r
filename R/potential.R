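#' Fit the linear production rate of a slurry time series
#'
#' Ordinary least squares of concentration on time.  The slope is the
#' production rate R (mg N/L/h); r-squared is the squared Pearson
#' correlation and gates QC at the configured threshold.  A constant
#' concentration series has an undefined correlation; it is reported as
#' `r_squared = 0` with a flag (and passes a zero slope through).
#'
#' @param time_h Sampling times, hours (>= 3, strictly increasing).
#' @param conc Concentrations, mg N/L.
#' @param qc_r2 QC threshold on r-squared (default 0.9).
#' @return An object of class `rate_fit`: list with `R` (slope),
#'   `intercept`, `r_squared`, `qc_pass`, `n_points`, `flag`.
#' @export
fit_rate <- function(time_h, conc, qc_r2 = 0.9) {
  if (length(time_h) < 3L) stopf("need >= 3 time points")
  if (length(conc) != length(time_h)) stopf("time and concentration lengths differ")
  if (any(diff(time_h) <= 0)) stopf("times must be strictly increasing")
  if (stats::var(time_h) == 0) stopf("constant time vector")
  fit <- stats::lm(conc ~ time_h)
  slope <- unname(stats::coef(fit)[2])
  icpt <- unname(stats::coef(fit)[1])
  flag <- NA_character_
  if (stats::var(conc) == 0) {
    slope <- 0; r2 <- 0; flag <- "constant_concentration"
  } else {
    r2 <- stats::cor(time_h, conc)^2
  }
  structure(list(R = slope, intercept = icpt, r_squared = r2,
                 qc_pass = r2 >= qc_r2, n_points = length(time_h),
                 flag = flag),
            class = "rate_fit")
}

#' Nitrification potential from a fitted rate
#'
#' Converts a slurry production rate into a soil nitrification potential:
#' `Np = R * (0.1 + V) / m * 24` where R is the rate of increase of
#' NO2--N or NO3--N (mg/L/h), 0.1 L is the buffer volume, V (L) the water
#' volume of the soil subsample, m (kg) its dry mass and 24 converts to a
#' daily rate.  Units: mg N per kg dry soil per day.
#'
#' @param fit A [fit_rate()] result, or a bare numeric rate R.
#' @param V Soil water volume, L (>= 0).
#' @param m Soil dry mass, kg (> 0).
#' @return An object of class `potential_assay`: list with `Np`, `R`,
#'   `V`, `m`, `r_squared`, `qc_pass`, `background_subtracted`, `flag`.
#' @export
nitrification_potential <- function(fit, V, m) {
  assert_scalar_num(V, "V", lo = 0)
  assert_scalar_num(m, "m", lo = 0, strict_lo = TRUE)
  if (inherits(fit, "rate_fit")) {
    R <- fit$R; r2 <- fit$r_squared; qc <- fit$qc_pass; flag <- fit$flag
  } else {
    R <- as.numeric(fit); r2 <- NA_real_; qc <- NA; flag <- NA_character_
  }
  structure(list(Np = R * (0.1 + V) / m * 24, R = R, V = V, m = m,
                 r_squared = r2, qc_pass = qc,
                 background_subtracted = FALSE, flag = flag),
            class = "potential_assay")
}

#' Subtract the acetylene background control from a potential
#'
#' Acetylene-treated slurries measure background (heterotrophic)
#' production; subtracting them isolates autotrophic nitrification.
#' Negative net potentials are retained and flagged, never clamped here.
#'
#' @param assay A `potential_assay`.
#' @param ace_control Matched acetylene-control `potential_assay`.
#' @return The assay with `Np` replaced by `Np - Np_ace`,
#'   `background_subtracted = TRUE`, and a `negative_net` flag when the
#'   result is below zero.
#' @export
subtract_background <- function(assay, ace_control) {
  stopifnot(inherits(assay, "potential_assay"),
            inherits(ace_control, "potential_assay"))
  out <- assay
  out$Np <- assay$Np - ace_control$Np
  out$background_subtracted <- TRUE
  if (ace_control$Np == 0) {
    out$flag <- "zero_background"
  } else if (out$Np < 0) {
    out$flag <- "negative_net"
  }
  out
}

# The five (combo, analyte) arms that the partition needs, mapped to the
# named potentials they measure.
PARTITION_ARMS <- data.frame(
  key = c("NaClO3|NO2", "NaClO3|NO3", "NaClO3+Sim|NO2",
          "NaClO3+DMPP|NO2", "NaClO3+Sim+DMPP|NO3"),
  name = c("AOA_plus_AOB", "comammox_coexist", "AOB", "AOA",
           "comammox_alone"),
  stringsAsFactors = FALSE)

#' Partition nitrification potential among guilds
#'
#' Maps the five assay arms to named potentials and computes percentage
#' contributions under two schemes.  Scheme U (uninhibited ammonia
#' oxidizers) splits the total between the combined \[AOA+AOB\] potential
#' (NO2- accumulation under NaClO3) and the \[comammox\] potential (NO3-
#' increase under NaClO3, AOA/AOB active).  Scheme I (fully resolved)
#' splits between AOA (NaClO3+DMPP), AOB (NaClO3+Sim) and comammox alone
#' (all three inhibitors).  Two interaction indices are reported:
#' `delta_AB = Np\[AOA+AOB\] - (Np_AOA + Np_AOB)` (negative = antagonism
#' between the two guilds) and `delta_C = Np\[comammox\] -
#' Np_comammox_alone` (positive = coexistence with active AOA/AOB boosts
#' comammox).
#'
#' Negative input potentials are floored at zero for the percentage
#' computation only (with a warning); the stored potentials keep their
#' sign.
#'
#' @param assays Named list of `potential_assay` objects; names are
#'   `"<combo>|<analyte>"` keys, e.g. `"NaClO3+Sim|NO2"`.  All five
#'   partition arms must be present.
#' @param soil,substrate Labels carried into the result.
#' @return An object of class `partition_result`: list with the five
#'   potentials (`Np_AOA`, `Np_AOB`, `Np_comammox_alone`,
#'   `Np_AOA_plus_AOB`, `Np_comammox_coexist`), `pct_scheme_U`,
#'   `pct_scheme_I`, `delta_AB`, `delta_C`, `qc` (named logical),
#'   `flags`.
#' @export
partition_contributions <- function(assays, soil = NA, substrate = NA) {
  miss <- setdiff(PARTITION_ARMS$key, names(assays))
  if (length(miss)) {
    arm <- PARTITION_ARMS$name[match(miss, PARTITION_ARMS$key)]
    stopf("missing assay arm(s): %s (needed for %s)",
          paste(miss, collapse = ", "), paste(arm, collapse = ", "))
  }
  np <- vapply(PARTITION_ARMS$key, function(k) assays[[k]]$Np, numeric(1))
  names(np) <- PARTITION_ARMS$name
  qc <- vapply(PARTITION_ARMS$key, function(k) isTRUE(assays[[k]]$qc_pass),
               logical(1))
  names(qc) <- PARTITION_ARMS$name
  flags <- character(0)
  if (any(np < 0)) {
    warning("negative potential(s) floored at 0 for percentage computation: ",
            paste(names(np)[np < 0], collapse = ", "), call. = FALSE)
    flags <- c(flags, paste0("negative:", paste(names(np)[np < 0],
                                                collapse = ",")))
  }
  pos <- pmax(np, 0)
  pct_of <- function(parts) {
    tot <- sum(parts)
    if (tot <= 0) return(stats::setNames(rep(NA_real_, length(parts)),
                                         names(parts)))
    100 * parts / tot
  }
  pct_U <- pct_of(pos[c("AOA_plus_AOB", "comammox_coexist")])
  pct_I <- pct_of(pos[c("AOA", "AOB", "comammox_alone")])
  if (anyNA(pct_U)) flags <- c(flags, "scheme_U_undefined")
  if (anyNA(pct_I)) flags <- c(flags, "scheme_I_undefined")
  structure(list(soil = soil, substrate = substrate,
                 Np_AOA = np[["AOA"]], Np_AOB = np[["AOB"]],
                 Np_comammox_alone = np[["comammox_alone"]],
                 Np_AOA_plus_AOB = np[["AOA_plus_AOB"]],
                 Np_comammox_coexist = np[["comammox_coexist"]],
                 pct_scheme_U = pct_U, pct_scheme_I = pct_I,
                 delta_AB = np[["AOA_plus_AOB"]] -
                   (np[["AOA"]] + np[["AOB"]]),
                 delta_C = np[["comammox_coexist"]] -
                   np[["comammox_alone"]],
                 qc = qc, flags = flags),
            class = "partition_result")
}

#' Estimate and partition potentials from a slurry table
#'
#' Fits per-replicate rates for every (combo, analyte) arm, averages the
#' replicate potentials (standard deviation propagated), optionally
#' subtracts the acetylene background, and partitions the result.
#'
#' @param slurry A `slurry_table` data.frame (schema as written by
#'   [simulate_slurry()]; a `soil`/`substrate` pair is processed at a
#'   time).
#' @param V,m Soil water volume (L) and dry mass (kg) of the slurry
#'   subsample.
#' @param qc_r2 QC threshold on per-replicate fits.
#' @param ace_baseline If TRUE, subtract the matched acetylene-arm
#'   potential from every arm before partitioning.
#' @return List with `fits` (per replicate data.frame: combo, analyte,
#'   replicate, R, r_squared, qc_pass, Np), `assays` (named list of mean
#'   `potential_assay`s with `Np_sd` attached) and `partition`
#'   (a `partition_result`).
#' @export
estimate_potentials <- function(slurry, V, m, qc_r2 = 0.9,
                                ace_baseline = FALSE) {
  need <- c("inhibitor_combo", "analyte", "replicate", "time_h",
            "conc_mgN_L")
  miss <- setdiff(need, names(slurry))
  if (length(miss)) stopf("slurry table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  soil <- if ("soil" %in% names(slurry)) slurry$soil[1] else NA
  substrate <- if ("substrate" %in% names(slurry)) slurry$substrate[1] else NA
  key <- interaction(slurry$inhibitor_combo, slurry$analyte,
                     slurry$replicate, drop = TRUE)
  fits <- do.call(rbind, lapply(split(slurry, key), function(d) {
    d <- d[order(d$time_h), ]
    f <- fit_rate(d$time_h, d$conc_mgN_L, qc_r2)
    pa <- nitrification_potential(f, V, m)
    data.frame(inhibitor_combo = d$inhibitor_combo[1],
               analyte = d$analyte[1], replicate = d$replicate[1],
               R = f$R, r_squared = f$r_squared, qc_pass = f$qc_pass,
               Np = pa$Np, stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  arm_key <- paste(fits$inhibitor_combo, fits$analyte, sep = "|")
  assays <- lapply(split(fits, arm_key), function(d) {
    pa <- nitrification_potential(mean(d$R), V, m)
    pa$Np_sd <- stats::sd(d$Np)
    pa$r_squared <- mean(d$r_squared)
    pa$qc_pass <- all(d$qc_pass)
    pa
  })
  if (ace_baseline) {
    for (an in c("NO2", "NO3")) {
      ace_key <- paste("Ace", an, sep = "|")
      if (!ace_key %in% names(assays)) {
        stopf("ace_baseline requested but no acetylene arm for %s", an)
      }
      for (k in names(assays)) {
        if (endsWith(k, paste0("|", an)) && k != ace_key) {
          assays[[k]] <- subtract_background(assays[[k]], assays[[ace_key]])
        }
      }
    }
  }
  part <- partition_contributions(assays, soil, substrate)
  list(fits = fits, assays = assays, partition = part)
}

#' Summarize guild interactions across partition results
#'
#' Tabulates, per soil/substrate, the interaction indices and the comammox
#' share under the two schemes, and classifies each index as synergy,
#' additivity or antagonism.  The additivity band is `tolerance_frac`
#' times the scheme total (default 5%).
#'
#' @param results List of `partition_result` objects.
#' @param tolerance_frac Additivity tolerance as a fraction of the total.
#' @return data.frame with columns `soil, substrate, delta_AB, delta_C,
#'   ab_interaction, comammox_interaction, comammox_share_U,
#'   comammox_share_I`.
#' @export
interaction_report <- function(results, tolerance_frac = 0.05) {
  if (!length(results)) stopf("need >= 1 partition result")
  classify <- function(delta, total) {
    tol <- tolerance_frac * total
    if (abs(delta) <= tol) "additivity"
    else if (delta > 0) "synergy" else "antagonism"
  }
  out <- do.call(rbind, lapply(results, function(r) {
    tot_I <- sum(pmax(c(r$Np_AOA, r$Np_AOB, r$Np_comammox_alone), 0))
    tot_U <- sum(pmax(c(r$Np_AOA_plus_AOB, r$Np_comammox_coexist), 0))
    data.frame(soil = r$soil, substrate = r$substrate,
               delta_AB = r$delta_AB, delta_C = r$delta_C,
               ab_interaction = classify(r$delta_AB, tot_I),
               comammox_interaction = classify(r$delta_C, tot_U),
               comammox_share_U = unname(r$pct_scheme_U["comammox_coexist"]),
               comammox_share_I = unname(r$pct_scheme_I["comammox_alone"]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
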