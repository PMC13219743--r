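ASV_CLASSES <- c("both", "inorganic_only", "organic_only", "unlabeled")

#' Plant a set of ASVs with known metabolic classes
#'
#' Builds the per-ASV ground truth consumed by [simulate_asv_counts()]:
#' each ASV gets a metabolic class and a baseline mean abundance drawn
#' log-uniformly between `mean_lo` and `mean_hi`.
#'
#' @param n_per_class Named or unnamed counts per class; a single number is
#'   recycled over all four classes (both, inorganic_only, organic_only,
#'   unlabeled).
#' @param mean_lo,mean_hi Range of baseline mean counts.
#' @param seed Integer seed or NULL.
#' @return data.frame with columns `asv_id, class, base_mean`.
#' @export
plant_asv_classes <- function(n_per_class = 20L, mean_lo = 50, mean_hi = 500,
                              seed = NULL) {
  if (length(n_per_class) == 1L && is.null(names(n_per_class))) {
    n_per_class <- stats::setNames(rep(n_per_class, 4), ASV_CLASSES)
  }
  if (!all(names(n_per_class) %in% ASV_CLASSES)) {
    stopf("classes must be among: %s", paste(ASV_CLASSES, collapse = ", "))
  }
  cls <- rep(names(n_per_class), times = n_per_class)
  with_seed(seed, {
    data.frame(asv_id = sprintf("ASV_%04d", seq_along(cls)),
               class = cls,
               base_mean = exp(stats::runif(length(cls),
                                            log(mean_lo), log(mean_hi))),
               stringsAsFactors = FALSE)
  })
}

# Is an ASV of `class` 13C-enriched in `context`?
class_enriched_in <- function(class, context) {
  switch(context,
         no_inhibitor = class %in% c("both", "inorganic_only"),
         ace = class %in% c("both", "organic_only"),
         stopf("unknown context: %s", context))
}

#' Simulate heavy-fraction ASV count tables
#'
#' Draws negative-binomial counts for each ASV in each (context, isotope,
#' replicate) cell.  The 13C mean is `fold_change` times the 12C mean in
#' the `no_inhibitor` context for classes both/inorganic_only, and in the
#' `ace` (acetylene, autotrophy blocked) context for classes
#' both/organic_only; unlabeled ASVs have equal means everywhere.  The NB
#' size parameter is `1/dispersion`; `dispersion = 0` gives deterministic
#' rounded means.
#'
#' @param asv_classes data.frame from [plant_asv_classes()].
#' @param fold_change Planted 13C/12C mean ratio for enriched cells (> 1).
#' @param dispersion NB dispersion (>= 0; variance = mu + dispersion*mu^2).
#' @param n_replicates Replicates per cell.
#' @param contexts Contexts to simulate.
#' @param seed Integer seed or NULL.
#' @return data.frame of class `asv_count_table` with columns
#'   `asv_id, context, isotope, replicate, count`.
#' @export
simulate_asv_counts <- function(asv_classes, fold_change = 8,
                                dispersion = 0.1, n_replicates = 3L,
                                contexts = c("no_inhibitor", "ace"),
                                seed = NULL) {
  stopifnot(is.data.frame(asv_classes),
            all(c("asv_id", "class", "base_mean") %in% names(asv_classes)))
  if (!all(asv_classes$class %in% ASV_CLASSES)) {
    stopf("classes must be among: %s", paste(ASV_CLASSES, collapse = ", "))
  }
  if (dispersion < 0) stopf("`dispersion` must be >= 0")
  assert_scalar_num(fold_change, "fold_change", lo = 1)
  draw <- function(mu, n) {
    if (dispersion == 0) round(rep(mu, n))
    else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  }
  with_seed(seed, {
    rows <- list()
    for (ctx in contexts) {
      for (i in seq_len(nrow(asv_classes))) {
        a <- asv_classes[i, ]
        enr <- class_enriched_in(a$class, ctx)
        for (iso in c("12C", "13C")) {
          mu <- a$base_mean * if (iso == "13C" && enr) fold_change else 1
          rows[[length(rows) + 1L]] <- data.frame(
            asv_id = a$asv_id, context = ctx, isotope = iso,
            replicate = seq_len(n_replicates),
            count = draw(mu, n_replicates), stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("asv_count_table", "data.frame")
    out
  })
}
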