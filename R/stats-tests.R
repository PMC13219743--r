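#' One-way fixed-effects analysis of variance
#'
#' Classical decomposition of the total sum of squares into between- and
#' within-group components, computed from first principles.  The
#' mean-squared error is returned because Duncan's range test reuses it.
#'
#' @param groups Named list of numeric vectors (at least 2 groups, each
#'   with at least 2 values).
#' @return List with `F`, `df_between`, `df_within`, `p`, `MSE`,
#'   `group_means`, `group_n`, `grand_mean`, `flag`.  When every group
#'   has zero internal variance the decomposition is degenerate and
#'   flagged; equal means then give `F = 0, p = 1`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stopf("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stopf("every group needs >= 2 values")
  means <- vapply(groups, mean, numeric(1))
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- sum(n) - length(groups)
  mse <- ssw / dfw
  flag <- NA_character_
  if (ssw == 0) {
    flag <- "zero_within_variance"
    if (ssb == 0) {
      Fstat <- 0; p <- 1
    } else {
      Fstat <- Inf; p <- 0
    }
  } else {
    Fstat <- (ssb / dfb) / mse
    p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  list(F = Fstat, df_between = dfb, df_within = dfw, p = p, MSE = mse,
       group_means = means, group_n = n, grand_mean = grand, flag = flag)
}

#' Independent two-sample t-test
#'
#' Student's pooled-variance test (default) or Welch's test with
#' Satterthwaite degrees of freedom, computed from first principles.
#' When both samples have zero variance and equal means the statistic is
#' degenerate; `t = 0, p = 1` is returned with a flag.
#'
#' @param x,y Numeric samples (each >= 2 values).
#' @param mode "student" or "welch".
#' @return List with `t`, `df`, `p`, `flag`.
#' @export
two_sample_t <- function(x, y, mode = c("student", "welch")) {
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stopf("each sample needs >= 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  dm <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (dm == 0) {
      return(list(t = 0, df = nx + ny - 2, p = 1, flag = "zero_variance"))
    }
    return(list(t = sign(dm) * Inf, df = nx + ny - 2, p = 0,
                flag = "zero_variance"))
  }
  if (mode == "student") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- dm / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), flag = NA_character_)
}

# Probability that the range of k iid standard normals is <= w.
normal_range_cdf <- function(w, k) {
  if (w <= 0) return(0)
  f <- function(z) {
    k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10,
                   subdivisions = 400L)$value
}

# CDF of the studentized range with k groups and df error degrees of
# freedom: the range CDF mixed over the scaled-chi distribution of the
# pooled SD estimate.
studentized_range_cdf <- function(q, k, df) {
  if (q <= 0) return(0)
  if (!is.finite(df) || df > 5000) return(normal_range_cdf(q, k))
  log_c <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
  fs <- function(s) exp(log_c + (df - 1) * log(s) - df * s^2 / 2)
  integrand <- function(s) {
    vapply(s, function(si) fs(si) * normal_range_cdf(q * si, k), numeric(1))
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                   subdivisions = 200L)$value
}

#' Quantile of the studentized range distribution
#'
#' Upper quantile computed by numerical integration of the studentized
#' range CDF (the normal-range probability mixed over the chi
#' distribution of the pooled standard deviation) and root finding.
#'
#' @param prob Cumulative probability in (0, 1) (e.g. 0.95 for the 5%
#'   critical value).
#' @param k Number of groups spanned (>= 2).
#' @param df Error degrees of freedom (>= 1; `Inf` gives the normal-range
#'   limit).
#' @return The quantile q with `P(Q <= q) = prob`.
#' @export
studentized_range_quantile <- function(prob, k, df) {
  if (prob <= 0 || prob >= 1) stopf("prob must lie in (0, 1)")
  if (k < 2) stopf("k must be >= 2")
  if (df < 1) stopf("df must be >= 1")
  key <- sprintf("%.10g|%d|%.10g", prob, as.integer(k), df)
  hit <- .q_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- function(q) studentized_range_cdf(q, k, df) - prob
  hi <- 10
  while (f(hi) < 0 && hi < 1e4) hi <- hi * 2
  if (f(hi) < 0) stopf("studentized range quantile search failed to bracket (prob=%g, k=%d, df=%g)",
                       prob, k, df)
  val <- stats::uniroot(f, c(1e-8, hi), tol = 1e-7)$root
  .q_cache[[key]] <- val
  val
}

# quantile memoization (the integration is the expensive part)
.q_cache <- new.env(parent = emptyenv())

# Duncan's stepwise range rule on sorted means.  Returns the logical
# significance matrix over groups in *sorted* (descending mean) order.
duncan_decisions <- function(means_sorted, ranges) {
  k <- length(means_sorted)
  sig <- matrix(FALSE, k, k)
  nonsig_cover <- matrix(FALSE, k, k)  # [i, j]: stretch i..j declared homogeneous
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      covered <- FALSE
      if (span < k) {
        for (a in seq_len(k)) {
          for (b in seq_len(k)) {
            if (nonsig_cover[a, b] && a <= i && j <= b) covered <- TRUE
          }
        }
      }
      if (covered) {
        nonsig_cover[i, j] <- TRUE
        next
      }
      if (means_sorted[i] - means_sorted[j] > ranges[span]) {
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        nonsig_cover[i, j] <- TRUE
      }
    }
  }
  sig
}

# Insert-and-absorb compact letter display from a logical significance
# matrix (TRUE = pair differs).  Returns a character vector of letter
# strings, one per group, in the matrix's group order.
compact_letter_display <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # stable letter order: columns sorted by their first (highest-mean) member
  ord <- order(vapply(cols, min, numeric(1)))
  cols <- cols[ord]
  letters_used <- letters[seq_along(cols)]
  vapply(seq_len(k), function(g) {
    paste0(letters_used[vapply(cols, function(col) g %in% col, logical(1))],
           collapse = "")
  }, character(1))
}

#' Duncan's multiple range test with compact letter display
#'
#' Post-hoc comparison of group means after a one-way ANOVA.  Means are
#' sorted in descending order; a stretch of p consecutive ordered means is
#' tested against the critical range `R_p = q(1 - alpha_p, p, df_within) *
#' sqrt(MSE / n_h)` where the protection level is
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` and `n_h` is the harmonic mean
#' group size.  The standard stepwise rule applies: no pair inside a
#' stretch already declared homogeneous is tested.  Letters are assigned
#' by the insert-and-absorb algorithm; groups share a letter exactly when
#' they are not significantly different.  Ties in means are broken by
#' group label order, making the display deterministic.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @param anova Optional precomputed [one_way_anova()] result.
#' @return An object of class `duncan_mrt`: list with `display`
#'   (data.frame: group, mean, n, letters, ordered by descending mean),
#'   `significant` (named logical matrix in display order), `ranges`
#'   (critical ranges indexed by span), `alpha`, `MSE`, `df_within`,
#'   `n_harmonic`, `balanced`.
#' @export
duncan_mrt <- function(groups, alpha = 0.05, anova = NULL) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  av <- anova %||% one_way_anova(groups)
  if (av$df_within < 1) stopf("df_within < 1")
  n <- av$group_n
  n_h <- length(n) / sum(1 / n)
  balanced <- length(unique(n)) == 1L
  means <- av$group_means
  # descending means; ties broken by label order for determinism
  ord <- order(-means, names(means))
  ms <- means[ord]
  k <- length(ms)
  ranges <- rep(NA_real_, k)
  for (span in 2:k) {
    alpha_p <- 1 - (1 - alpha)^(span - 1)
    q <- studentized_range_quantile(1 - alpha_p, span, av$df_within)
    ranges[span] <- q * sqrt(av$MSE / n_h)
  }
  sig <- duncan_decisions(ms, ranges)
  dimnames(sig) <- list(names(ms), names(ms))
  letters_vec <- compact_letter_display(sig)
  display <- data.frame(group = names(ms), mean = unname(ms),
                        n = unname(n[ord]), letters = letters_vec,
                        stringsAsFactors = FALSE)
  structure(list(display = display, significant = sig, ranges = ranges,
                 alpha = alpha, MSE = av$MSE, df_within = av$df_within,
                 n_harmonic = n_h, balanced = balanced),
            class = "duncan_mrt")
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df = %d, MSE = %g)\n",
              x$alpha, x$df_within, x$MSE))
  print(x$display, row.names = FALSE)
  invisible(x)
}

#' Grouped comparison report
#'
#' Convenience wrapper producing the ANOVA table and Duncan letters for a
#' response measured across treatment groups, as commonly reported for
#' functional gene abundances.
#'
#' @param data data.frame containing the response and grouping columns.
#' @param response,group Column names.
#' @param alpha Significance level.
#' @param log_transform If TRUE, analyse `log10(response)`.
#' @return List with `anova`, `duncan` and `table` (per-group mean, n,
#'   letters).
#' @export
compare_groups <- function(data, response, group, alpha = 0.05,
                           log_transform = FALSE) {
  if (!all(c(response, group) %in% names(data))) {
    stopf("columns %s and %s must exist", response, group)
  }
  y <- data[[response]]
  if (log_transform) {
    if (any(y <= 0)) stopf("log transform requires positive responses")
    y <- log10(y)
  }
  groups <- split(y, data[[group]])
  av <- one_way_anova(groups)
  dc <- duncan_mrt(groups, alpha, anova = av)
  list(anova = av, duncan = dc, table = dc$display)
}
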