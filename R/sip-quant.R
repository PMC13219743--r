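#' Construct a matched 12C/13C gradient pair for one gene
#'
#' Bundles the replicate 12C and 13C fraction profiles of a single gene
#' (from a long `gradient_table`) with the analysis fraction range.  The
#' analysis range defaults to fractions 2-14, the window in which gradient
#' fractions are routinely quantified by qPCR.
#'
#' @param gradients A `gradient_table` data.frame (see
#'   [simulate_gradient()] for the schema).
#' @param gene Gene label to extract.
#' @param analysis_range Length-2 integer vector of fraction indices.
#' @return An object of class `gradient_pair`.
#' @export
gradient_pair <- function(gradients, gene,
                          analysis_range = c(2L, 14L)) {
  stopifnot(is.data.frame(gradients))
  need <- c("gene", "isotope", "replicate", "fraction", "density_g_ml",
            "copies")
  miss <- setdiff(need, names(gradients))
  if (length(miss)) stopf("gradient table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  d <- gradients[gradients$gene == gene, , drop = FALSE]
  if (!nrow(d)) stopf("gene %s not present in gradient table", gene)
  if (!all(c("12C", "13C") %in% d$isotope)) {
    stopf("gene %s: both 12C and 13C profiles are required", gene)
  }
  if (any(d$copies < 0)) stopf("gene %s: negative copy numbers", gene)
  split_profiles <- function(iso) {
    di <- d[d$isotope == iso, , drop = FALSE]
    lapply(split(di, di$replicate), function(p) {
      p <- p[order(p$fraction), c("fraction", "density_g_ml", "copies")]
      if (nrow(p) < 3L) stopf("profile with < 3 fractions")
      dd <- diff(p$density_g_ml)
      if (!(all(dd > 0) || all(dd < 0))) {
        stopf("gene %s: densities not strictly monotone in fraction index",
              gene)
      }
      p
    })
  }
  p12 <- split_profiles("12C")
  p13 <- split_profiles("13C")
  ref <- p12[[1]]$density_g_ml
  for (p in c(p12, p13)) {
    if (length(p$density_g_ml) != length(ref) ||
        any(abs(p$density_g_ml - ref) > 1e-6)) {
      stopf("gene %s: replicate fraction grids do not match", gene)
    }
  }
  structure(list(gene = gene, profiles_12C = p12, profiles_13C = p13,
                 fractions = p12[[1]]$fraction,
                 densities = ref,
                 analysis_range = as.integer(analysis_range)),
            class = "gradient_pair")
}

#' Normalize a fraction profile to relative abundances
#'
#' Restricts a profile to the analysis fraction range and divides by the
#' total copies within it, yielding per-fraction relative abundances that
#' sum to one.
#'
#' @param profile data.frame with columns `fraction` and `copies` (e.g. an
#'   element of `gradient_pair$profiles_13C`).
#' @param range Length-2 fraction index interval.
#' @return Named numeric vector (names = fraction indices) summing to 1.
#' @export
normalize_profile <- function(profile, range = c(2L, 14L)) {
  keep <- profile$fraction >= range[1] & profile$fraction <= range[2]
  x <- profile$copies[keep]
  if (any(x < 0)) stopf("negative copies in profile")
  tot <- sum(x)
  if (tot <= 0) stopf("all-zero profile within analysis range: failed gradient")
  stats::setNames(x / tot, profile$fraction[keep])
}

# Per-replicate relative-abundance matrices over the analysis range.
rel_abundance_matrix <- function(pair, isotope) {
  profs <- if (isotope == "13C") pair$profiles_13C else pair$profiles_12C
  do.call(rbind, lapply(profs, normalize_profile, range = pair$analysis_range))
}

#' Define the heavy-fraction window of a gradient pair
#'
#' In `fixed` mode the heavy window is every analysis-range fraction whose
#' density is at least `threshold` (default 1.725 g/ml, typical SIP
#' practice).  In `adaptive` mode it is the operational definition used
#' when comparing against the unlabeled control: among fractions strictly
#' denser than the 12C modal fraction, the longest contiguous run in which
#' the mean 13C relative abundance exceeds the mean 12C relative
#' abundance.  The 12C modal fraction itself is never included; the window
#' may be empty (no detectable enrichment).
#'
#' @param pair A [gradient_pair()].
#' @param mode "fixed" or "adaptive".
#' @param threshold Density threshold (g/ml) for fixed mode.
#' @return Integer vector of fraction indices (possibly empty).
#' @export
define_heavy_window <- function(pair, mode = c("fixed", "adaptive"),
                                threshold = 1.725) {
  mode <- match.arg(mode)
  rng <- pair$analysis_range
  keep <- pair$fractions >= rng[1] & pair$fractions <= rng[2]
  fr <- pair$fractions[keep]
  dens <- pair$densities[keep]
  if (mode == "fixed") return(fr[dens >= threshold])
  m12 <- colMeans(rel_abundance_matrix(pair, "12C"))
  m13 <- colMeans(rel_abundance_matrix(pair, "13C"))
  modal <- which.max(m12)
  cand <- which(dens > dens[modal])
  if (!length(cand)) return(integer(0))
  hit <- m13[cand] > m12[cand]
  if (!any(hit)) return(integer(0))
  # longest contiguous run of candidate fractions with 13C excess;
  # ties broken toward the run with the larger summed excess
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx_true <- which(runs$values)
  best <- NULL; best_len <- -1L; best_excess <- -Inf
  for (k in idx_true) {
    span <- cand[starts[k]:ends[k]]
    excess <- sum(m13[span] - m12[span])
    if (runs$lengths[k] > best_len ||
        (runs$lengths[k] == best_len && excess > best_excess)) {
      best <- span; best_len <- runs$lengths[k]; best_excess <- excess
    }
  }
  fr[best]
}

# Per-replicate sums of relative abundance over the heavy window.
window_sums <- function(pair, window, isotope) {
  m <- rel_abundance_matrix(pair, isotope)
  cols <- colnames(m) %in% as.character(window)
  if (!any(cols)) return(rep(0, nrow(m)))
  rowSums(m[, cols, drop = FALSE])
}

p_hat_from_sums <- function(S13, S12, estimator) {
  if (estimator == "raw_excess") return(clamp(S13 - S12, 0, 1))
  if (S12 >= 1 - 1e-9) return(NA_real_)  # undefined; caller flags
  clamp((S13 - S12) / (1 - S12), 0, 1)
}

#' Estimate the 13C-labeled proportion of a population
#'
#' Compares mean heavy-window relative abundance between the 13C and 12C
#' treatments.  With `S13` and `S12` the replicate means of the summed
#' heavy-window relative abundances, the `raw_excess` estimator is
#' `clamp(S13 - S12, 0, 1)` and the default `normalized_excess` estimator
#' is `clamp((S13 - S12) / (1 - S12), 0, 1)`.  The normalized form is
#' unbiased when the labeled DNA falls entirely inside the window, because
#' a labeled proportion p removes mass p from the light region of the 13C
#' profile: S13 = p + (1 - p) * S12.  A percentile bootstrap over
#' replicates supplies the confidence interval.
#'
#' @param pair A [gradient_pair()].
#' @param window Integer vector of heavy-window fraction indices (e.g.
#'   from [define_heavy_window()]).
#' @param estimator "normalized_excess" (default) or "raw_excess".
#' @param n_boot Bootstrap resamples for the CI (0 disables).
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap, or NULL.
#' @return An object of class `label_estimate`: list with `gene`,
#'   `heavy_window`, `p_hat`, `ci_low`, `ci_high`, `S13`, `S12`,
#'   `estimator`, `flag` (NA or a reason string).
#' @export
labeled_proportion <- function(pair, window,
                               estimator = c("normalized_excess",
                                             "raw_excess"),
                               n_boot = 1000L, conf = 0.95, seed = NULL) {
  estimator <- match.arg(estimator)
  rng <- pair$analysis_range
  if (length(window) && any(window < rng[1] | window > rng[2])) {
    stopf("window must lie within the analysis fraction range %d-%d",
          rng[1], rng[2])
  }
  if (!length(window)) {
    return(structure(list(gene = pair$gene, heavy_window = integer(0),
                          p_hat = 0, ci_low = 0, ci_high = 0,
                          S13 = 0, S12 = 0, estimator = estimator,
                          flag = "empty_window"),
                     class = "label_estimate"))
  }
  s13 <- window_sums(pair, window, "13C")
  s12 <- window_sums(pair, window, "12C")
  S13 <- mean(s13); S12 <- mean(s12)
  p_hat <- p_hat_from_sums(S13, S12, estimator)
  flag <- NA_character_
  if (is.na(p_hat)) { p_hat <- 0; flag <- "window_saturated" }
  ci <- c(p_hat, p_hat)
  if (n_boot > 0 && length(s13) > 1 && length(s12) > 1 && is.na(flag)) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        b13 <- mean(sample(s13, replace = TRUE))
        b12 <- mean(sample(s12, replace = TRUE))
        v <- p_hat_from_sums(b13, b12, estimator)
        if (is.na(v)) p_hat else v
      }, numeric(1))
    })
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a), type = 7))
  }
  structure(list(gene = pair$gene, heavy_window = as.integer(window),
                 p_hat = p_hat, ci_low = ci[1], ci_high = ci[2],
                 S13 = S13, S12 = S12, estimator = estimator, flag = flag),
            class = "label_estimate")
}

#' 13C-labeled absolute abundance
#'
#' The labeled proportion multiplied by the total gene abundance, giving
#' copies per gram dry soil attributable to the 13C-labeled subpopulation.
#'
#' @param estimate A `label_estimate` (or a bare numeric proportion).
#' @param total_copies Total gene copies per g dry soil (>= 0).
#' @return Labeled abundance, copies per g dry soil.
#' @export
labeled_abundance <- function(estimate, total_copies) {
  assert_scalar_num(total_copies, "total_copies", lo = 0)
  p <- if (inherits(estimate, "label_estimate")) estimate$p_hat
       else as.numeric(estimate)
  p * total_copies
}

#' Significance of heavy-window 13C enrichment
#'
#' Two-sided two-sample t-test on per-replicate heavy-window relative
#' abundance sums, 13C vs 12C.  When both groups are constant with equal
#' values the test is degenerate and `p = 1` is returned with a flag.
#'
#' @param pair A [gradient_pair()].
#' @param window Heavy-window fraction indices.
#' @param mode "student" (pooled variance, default) or "welch".
#' @return List with `t`, `df`, `p_value`, `flag`.
#' @export
enrichment_significance <- function(pair, window,
                                    mode = c("student", "welch")) {
  mode <- match.arg(mode)
  s13 <- window_sums(pair, window, "13C")
  s12 <- window_sums(pair, window, "12C")
  if (length(s13) < 2L) stopf("need >= 2 replicates for isotope 13C")
  if (length(s12) < 2L) stopf("need >= 2 replicates for isotope 12C")
  tt <- two_sample_t(s13, s12, mode = mode)
  list(t = tt$t, df = tt$df, p_value = tt$p, flag = tt$flag)
}

#' Quantify 13C labeling for every gene in a gradient table
#'
#' High-level wrapper: builds a [gradient_pair()] per gene, defines the
#' heavy window, estimates the labeled proportion with a bootstrap CI,
#' tests enrichment significance and multiplies by total abundance.
#'
#' @param gradients A `gradient_table` data.frame.
#' @param totals data.frame with columns `gene` and `copies_per_g`.
#' @param window_mode "fixed" or "adaptive" (see [define_heavy_window()]).
#' @param threshold Fixed-mode density threshold, g/ml.
#' @param estimator Passed to [labeled_proportion()].
#' @param analysis_range Fraction interval analysed.
#' @param n_boot,conf Bootstrap settings.
#' @param seed Integer seed for bootstrap resampling.
#' @return data.frame of class `label_estimates` with one row per gene:
#'   `gene, window, p_hat, ci_low, ci_high, p_value, total_copies,
#'   labeled_abundance, flag`.
#' @export
quantify_labeling <- function(gradients, totals = NULL,
                              window_mode = c("adaptive", "fixed"),
                              threshold = 1.725,
                              estimator = "normalized_excess",
                              analysis_range = c(2L, 14L),
                              n_boot = 1000L, conf = 0.95, seed = NULL) {
  window_mode <- match.arg(window_mode)
  genes <- unique(gradients$gene)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    pair <- gradient_pair(gradients, g, analysis_range)
    win <- define_heavy_window(pair, window_mode, threshold)
    est <- labeled_proportion(pair, win, estimator, n_boot, conf,
                              seed = child_seed(seed, i))
    pv <- if (length(win) &&
              length(pair$profiles_12C) > 1 &&
              length(pair$profiles_13C) > 1) {
      enrichment_significance(pair, win)$p_value
    } else NA_real_
    tot <- if (!is.null(totals)) {
      tc <- totals$copies_per_g[match(g, totals$gene)]
      if (is.na(tc)) stopf("gene %s missing from totals table", g)
      tc
    } else NA_real_
    data.frame(gene = g,
               window = paste(est$heavy_window, collapse = ","),
               p_hat = est$p_hat, ci_low = est$ci_low,
               ci_high = est$ci_high, p_value = pv,
               total_copies = tot,
               labeled_abundance = if (is.na(tot)) NA_real_
                                   else labeled_abundance(est, tot),
               flag = est$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("label_estimates", "data.frame")
  out
}
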