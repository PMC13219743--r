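# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths.

# Mass of the (1-p, p) two-Gaussian buoyant-density mixture over [lo, hi],
# by adaptive quadrature on the density function itself.
oracle_mixture_mass <- function(lo, hi, d0, d1, p, sd) {
  f <- function(x) (1 - p) * dnorm(x, d0, sd) + p * dnorm(x, d1, sd)
  integrate(f, lo, hi, rel.tol = 1e-10)$value
}

# Closed-form simple linear regression (textbook formulas).
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- cor(x, y)^2
  list(slope = b, intercept = a, r2 = r2)
}

# Brute-force Duncan range rule: enumerate every stretch of the ordered
# means, declare homogeneous stretches top-down, and read pairwise
# decisions off the containment relation.  Independent of the package's
# stepwise implementation (direct recursive definition).
oracle_duncan_pairs <- function(means_sorted, ranges) {
  k <- length(means_sorted)
  homogeneous <- list()
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      inside <- any(vapply(homogeneous, function(h) {
        h[1] <= i && j <= h[2]
      }, logical(1)))
      if (inside || (means_sorted[i] - means_sorted[j]) <= ranges[span]) {
        homogeneous <- c(homogeneous, list(c(i, j)))
      }
    }
  }
  sig <- matrix(FALSE, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    covered <- any(vapply(homogeneous, function(h) {
      h[1] <= i && j <= h[2]
    }, logical(1)))
    sig[i, j] <- sig[j, i] <- !covered
  }
  sig
}

# A minimal gradient pair built directly (bypassing the simulator) from
# per-fraction copies, densest fraction first on a uniform grid.
manual_pair <- function(copies_12C, copies_13C, gene = "AOA",
                        density_min = 1.690, density_max = 1.760,
                        analysis_range = c(1L, length(copies_12C[[1]]))) {
  n <- length(copies_12C[[1]])
  edges <- seq(density_min, density_max, length.out = n + 1)
  dens <- rev((edges[-1] + edges[-(n + 1)]) / 2)
  rows <- list()
  for (r in seq_along(copies_12C)) {
    rows[[length(rows) + 1]] <- data.frame(
      gene = gene, isotope = "12C", replicate = r, fraction = 1:n,
      density_g_ml = dens, copies = copies_12C[[r]])
  }
  for (r in seq_along(copies_13C)) {
    rows[[length(rows) + 1]] <- data.frame(
      gene = gene, isotope = "13C", replicate = r, fraction = 1:n,
      density_g_ml = dens, copies = copies_13C[[r]])
  }
  gradient_pair(do.call(rbind, rows), gene, analysis_range)
}
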