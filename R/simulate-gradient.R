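#' Buoyant density of unlabeled DNA from GC content
#'
#' Classical empirical relation between GC content and CsCl buoyant
#' density, d0 = 1.660 + 0.098 * GC (g/ml).
#'
#' @param gc_content GC fraction in \[0, 1\].
#' @return Buoyant density in g/ml.
#' @export
buoyant_density_gc <- function(gc_content) 1.660 + 0.098 * gc_content

# Full 13C labeling shifts DNA buoyant density by ~0.036 g/ml; partial
# labeling is scaled linearly by atom fraction excess.
FULL_LABEL_SHIFT <- 0.036

#' Density shift of 13C-labeled DNA
#'
#' @param atom_excess 13C atom fraction excess in \[0, 1\].
#' @return Density shift in g/ml (`0.036 * atom_excess`).
#' @export
label_density_shift <- function(atom_excess) FULL_LABEL_SHIFT * atom_excess

# Expected fraction-wise mass of a (1-p, p) two-Gaussian mixture, using the
# closed-form normal CDF over each fraction's density bin.
mixture_bin_mass <- function(edges, d_unlabeled, d_labeled, p, sd) {
  m12 <- stats::pnorm(edges[, "hi"], d_unlabeled, sd) -
    stats::pnorm(edges[, "lo"], d_unlabeled, sd)
  m13 <- stats::pnorm(edges[, "hi"], d_labeled, sd) -
    stats::pnorm(edges[, "lo"], d_labeled, sd)
  (1 - p) * m12 + p * m13
}

#' Simulate matched 12C/13C density-gradient qPCR profiles
#'
#' Generates, for each gene and isotope treatment, replicate profiles of
#' gene copies per gradient fraction.  The unlabeled population peaks at
#' the GC-determined density `1.660 + 0.098 * GC`; the labeled
#' subpopulation is shifted up by `0.036 * atom_excess` g/ml.  Expected
#' copies in a fraction are the total copy number times the integral of
#' the two-component Gaussian mixture (weights `1 - p`, `p`) over the
#' fraction's density bin; observed copies multiply this by lognormal
#' noise with the protocol's CV.  12C-substrate profiles use `p = 0`
#' (no labeling).
#'
#' @param truth A [label_truth()] object.
#' @param protocol A [gradient_protocol()].
#' @param seed Integer seed (or NULL to use the current RNG stream).
#' @return A data.frame of class `gradient_table` with columns
#'   `gene, isotope, replicate, fraction, density_g_ml, copies`.
#' @export
simulate_gradient <- function(truth, protocol = gradient_protocol(),
                              seed = NULL) {
  stopifnot(inherits(truth, "label_truth"),
            inherits(protocol, "gradient_protocol"))
  dens <- fraction_densities(protocol)
  edges <- fraction_edges(protocol)
  # lognormal with mean 1 and the requested CV
  sdlog <- sqrt(log(1 + protocol$noise_cv^2))
  meanlog <- -sdlog^2 / 2
  with_seed(seed, {
    rows <- list()
    for (g in seq_len(nrow(truth))) {
      tr <- truth[g, ]
      d0 <- buoyant_density_gc(tr$gc_content)
      d1 <- d0 + label_density_shift(tr$atom_excess)
      if (tr$labeled_proportion > 0 && d1 > protocol$density_max) {
        stopf(paste0("labeled peak density %.4f g/ml for gene %s exceeds ",
                     "density_max %.4f: protocol/truth mismatch"),
              d1, tr$gene, protocol$density_max)
      }
      for (iso in c("12C", "13C")) {
        p <- if (iso == "13C") tr$labeled_proportion else 0
        mu <- tr$total_copies *
          mixture_bin_mass(edges, d0, d1, p, protocol$peak_sd)
        for (r in seq_len(protocol$n_replicates)) {
          noise <- if (protocol$noise_cv > 0) {
            stats::rlnorm(length(mu), meanlog, sdlog)
          } else rep(1, length(mu))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = tr$gene, isotope = iso, replicate = r,
            fraction = seq_along(mu), density_g_ml = dens,
            copies = mu * noise, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("gradient_table", "data.frame")
    out
  })
}
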