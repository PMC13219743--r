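#' Gradient fractionation protocol
#'
#' Describes how a CsCl buoyant-density gradient is fractionated and
#' quantified: the number of fractions, the density span of the gradient,
#' the within-population density spread of DNA, and the multiplicative
#' lognormal qPCR noise level.  Fractions are numbered densest-first
#' (fraction 1 is the bottom of the tube), with densities assigned at the
#' midpoints of a uniform density grid.
#'
#' @param n_fractions Number of fractions collected (default 15).
#' @param density_min,density_max Density span of the gradient in g/ml
#'   (defaults 1.690 and 1.760).
#' @param peak_sd Standard deviation (g/ml) of the Gaussian buoyant-density
#'   distribution of a DNA population (default 0.006).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   qPCR noise (default 0.05; 0 gives noise-free profiles).
#' @param n_replicates Biological replicates per isotope (default 3).
#' @param densest_first Logical; number fractions from the dense end
#'   (default TRUE, matching bottom-collected fractionation).
#' @return An object of class `gradient_protocol`.
#' @export
gradient_protocol <- function(n_fractions = 15L,
                              density_min = 1.690, density_max = 1.760,
                              peak_sd = 0.006, noise_cv = 0.05,
                              n_replicates = 3L, densest_first = TRUE) {
  assert_scalar_num(n_fractions, "n_fractions", lo = 3)
  assert_scalar_num(density_min, "density_min", lo = 0)
  assert_scalar_num(density_max, "density_max")
  if (density_max <= density_min) stopf("density_max must exceed density_min")
  assert_scalar_num(peak_sd, "peak_sd", lo = 0, strict_lo = TRUE)
  assert_scalar_num(noise_cv, "noise_cv", lo = 0)
  assert_scalar_num(n_replicates, "n_replicates", lo = 1)
  structure(list(n_fractions = as.integer(n_fractions),
                 density_min = density_min, density_max = density_max,
                 peak_sd = peak_sd, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 densest_first = isTRUE(densest_first)),
            class = "gradient_protocol")
}

#' Fraction densities implied by a gradient protocol
#'
#' Bin midpoints of the uniform density grid, ordered by fraction index.
#'
#' @param protocol A [gradient_protocol()].
#' @return Numeric vector of length `n_fractions`; with `densest_first`
#'   the densities are strictly decreasing in fraction index.
#' @export
fraction_densities <- function(protocol) {
  edges <- seq(protocol$density_min, protocol$density_max,
               length.out = protocol$n_fractions + 1L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  if (protocol$densest_first) rev(mids) else mids
}

# Bin edges per fraction (list of c(lo, hi)), same order as densities.
fraction_edges <- function(protocol) {
  edges <- seq(protocol$density_min, protocol$density_max,
               length.out = protocol$n_fractions + 1L)
  lo <- edges[-length(edges)]; hi <- edges[-1L]
  if (protocol$densest_first) { lo <- rev(lo); hi <- rev(hi) }
  cbind(lo = lo, hi = hi)
}

GENES <- c("AOA", "AOB", "comammox")
INHIBITORS <- c("NaClO3", "Sim", "DMPP", "Ace")
TARGETS <- c("AOA", "AOB", "comammox", "NOB")

#' Ground-truth labeling state of the amoA-carrying populations
#'
#' Per gene (AOA, AOB and comammox amoA), the GC content of the population's
#' DNA, the 13C atom fraction excess of the labeled subpopulation, the true
#' proportion of the population that is labeled, and the total gene copy
#' number per gram dry soil.
#'
#' @param gc_content Named numeric vector (names AOA/AOB/comammox) of GC
#'   fractions in \[0, 1\].
#' @param atom_excess Named numeric vector of 13C atom fraction excess of the
#'   labeled subpopulation, in \[0, 1\].
#' @param labeled_proportion Named numeric vector of true labeled
#'   proportions, in \[0, 1\].
#' @param total_copies Named numeric vector of total gene copies per g dry
#'   soil, all > 0.
#' @return An object of class `label_truth` (a data.frame keyed by gene).
#' @export
label_truth <- function(gc_content, atom_excess, labeled_proportion,
                        total_copies) {
  pick <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 3), GENES)
    if (!all(GENES %in% names(x))) {
      stopf("`%s` must be named with all of: %s", name,
            paste(GENES, collapse = ", "))
    }
    as.numeric(x[GENES])
  }
  out <- data.frame(gene = GENES,
                    gc_content = pick(gc_content, "gc_content"),
                    atom_excess = pick(atom_excess, "atom_excess"),
                    labeled_proportion = pick(labeled_proportion,
                                              "labeled_proportion"),
                    total_copies = pick(total_copies, "total_copies"),
                    stringsAsFactors = FALSE)
  for (col in c("gc_content", "atom_excess", "labeled_proportion")) {
    if (any(out[[col]] < 0 | out[[col]] > 1)) {
      stopf("`%s` entries must lie in [0, 1]", col)
    }
  }
  if (any(out$total_copies <= 0)) stopf("`total_copies` must be > 0")
  class(out) <- c("label_truth", "data.frame")
  out
}

#' True process rates of the nitrifier guilds in a slurry assay
#'
#' Ground-truth linear production rates used by the slurry simulator:
#' ammonia-oxidation (nitrite production) rates of AOA and AOB, the nitrate
#' production rate of comammox, and two interaction multipliers.
#' `interaction_ab` scales the combined AOA+AOB rate relative to the sum of
#' the single-guild rates (values < 1 emulate antagonism between the two
#' guilds); `comammox_coexistence_boost` scales the comammox rate when both
#' AOA and AOB are active (values > 1 emulate facilitation of comammox by
#' the ammonia oxidizers).
#'
#' @param aoa_rate,aob_rate NO2- production rates, mg N/L/h.
#' @param comammox_rate NO3- production rate of comammox, mg N/L/h.
#' @param interaction_ab Multiplier on the combined AOA+AOB rate (default 1).
#' @param comammox_coexistence_boost Multiplier on the comammox rate when
#'   AOA and AOB are both uninhibited (default 1).
#' @param background_rate Heterotrophic background NO2- production,
#'   mg N/L/h (default 0).
#' @return An object of class `guild_rates`.
#' @export
guild_rates <- function(aoa_rate, aob_rate, comammox_rate,
                        interaction_ab = 1, comammox_coexistence_boost = 1,
                        background_rate = 0) {
  for (nm in c("aoa_rate", "aob_rate", "comammox_rate", "background_rate")) {
    assert_scalar_num(get(nm), nm, lo = 0)
  }
  assert_scalar_num(interaction_ab, "interaction_ab", lo = 0, strict_lo = TRUE)
  assert_scalar_num(comammox_coexistence_boost, "comammox_coexistence_boost",
                    lo = 0, strict_lo = TRUE)
  structure(list(aoa_rate = aoa_rate, aob_rate = aob_rate,
                 comammox_rate = comammox_rate,
                 interaction_ab = interaction_ab,
                 comammox_coexistence_boost = comammox_coexistence_boost,
                 background_rate = background_rate),
            class = "guild_rates")
}

#' Inhibitor efficacy design
#'
#' A matrix of suppression fractions (0 = no effect, 1 = complete
#' inhibition) for each inhibitor against each target process.  The default
#' design encodes the operational assumptions of the multi-inhibitor
#' partition: NaClO3 blocks nitrite oxidation by NOB, simvastatin (Sim)
#' blocks AOA, DMPP blocks AOB, and acetylene (Ace) blocks all autotrophic
#' ammonia oxidation (AOA, AOB and comammox).  Entries are continuous so
#' incomplete or non-specific inhibition can be explored.
#'
#' @param efficacy Optional numeric matrix with rownames from
#'   NaClO3/Sim/DMPP/Ace and colnames from AOA/AOB/comammox/NOB; missing
#'   cells default to 0.  When omitted, the perfect-specificity default is
#'   returned.
#' @return An object of class `inhibitor_design` (4 x 4 matrix).
#' @export
inhibitor_design <- function(efficacy = NULL) {
  m <- matrix(0, nrow = length(INHIBITORS), ncol = length(TARGETS),
              dimnames = list(INHIBITORS, TARGETS))
  if (is.null(efficacy)) {
    m["NaClO3", "NOB"] <- 1
    m["Sim", "AOA"] <- 1
    m["DMPP", "AOB"] <- 1
    m["Ace", c("AOA", "AOB", "comammox")] <- 1
  } else {
    if (!is.matrix(efficacy) || is.null(rownames(efficacy)) ||
        is.null(colnames(efficacy))) {
      stopf("`efficacy` must be a matrix with inhibitor rownames and target colnames")
    }
    bad_r <- setdiff(rownames(efficacy), INHIBITORS)
    bad_c <- setdiff(colnames(efficacy), TARGETS)
    if (length(bad_r)) stopf("unknown inhibitor(s): %s", paste(bad_r, collapse = ", "))
    if (length(bad_c)) stopf("unknown target(s): %s", paste(bad_c, collapse = ", "))
    if (any(efficacy < 0 | efficacy > 1)) stopf("efficacies must lie in [0, 1]")
    m[rownames(efficacy), colnames(efficacy)] <- efficacy
  }
  structure(m, class = c("inhibitor_design", "matrix"))
}

#' Shaken-slurry assay protocol
#'
#' Sampling design and physical constants of the shaken soil-slurry
#' nitrification-potential assay: sampling times, the fixed 0.1 L buffer
#' volume, the water volume carried by the soil subsample, its dry mass,
#' and the additive Gaussian measurement noise of the colorimetric
#' NO2-/NO3- assays.
#'
#' @param sample_times Sampling times in hours, strictly increasing
#'   (default `c(2, 4, 8, 20, 22, 24)`).
#' @param soil_water_volume Water volume V of the soil subsample, L.
#' @param soil_dry_mass Dry mass m of the soil subsample, kg.
#' @param measurement_sd Additive Gaussian noise SD on concentrations,
#'   mg N/L.
#' @param n_replicates Biological replicates (default 3).
#' @param no2_initial,no3_initial Initial concentrations (intercepts),
#'   mg N/L.
#' @return An object of class `slurry_protocol`.  The buffer volume is
#'   fixed at 0.1 L.
#' @export
slurry_protocol <- function(sample_times = c(2, 4, 8, 20, 22, 24),
                            soil_water_volume = 0.005,
                            soil_dry_mass = 0.0095,
                            measurement_sd = 0, n_replicates = 3L,
                            no2_initial = 0.05, no3_initial = 0.5) {
  if (length(sample_times) < 2L || any(diff(sample_times) <= 0)) {
    stopf("`sample_times` must be >= 2 strictly increasing times")
  }
  assert_scalar_num(soil_water_volume, "soil_water_volume", lo = 0)
  assert_scalar_num(soil_dry_mass, "soil_dry_mass", lo = 0, strict_lo = TRUE)
  assert_scalar_num(measurement_sd, "measurement_sd", lo = 0)
  assert_scalar_num(n_replicates, "n_replicates", lo = 1)
  structure(list(sample_times = as.numeric(sample_times),
                 buffer_volume = 0.1,
                 soil_water_volume = soil_water_volume,
                 soil_dry_mass = soil_dry_mass,
                 measurement_sd = measurement_sd,
                 n_replicates = as.integer(n_replicates),
                 no2_initial = no2_initial, no3_initial = no3_initial),
            class = "slurry_protocol")
}
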