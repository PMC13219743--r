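#' Per-ASV differential 13C-enrichment test
#'
#' Tests each ASV for differential abundance between 13C and 12C heavy
#' fractions within one context.  Counts are total-count normalized (each
#' replicate library scaled to the mean library size), log-transformed
#' with a pseudocount of 1, and compared by a two-sample t-test.  The
#' enrichment call is one-sided: an ASV is flagged significant only when
#' its 13C mean exceeds its 12C mean *and* the (optionally BH-adjusted)
#' two-sided p-value is below `alpha` — depletion has no meaning for
#' isotope labeling.
#'
#' @param counts An `asv_count_table` data.frame restricted to one
#'   context (columns `asv_id, isotope, replicate, count`).
#' @param alpha Significance level in (0, 1).
#' @param correction "none" (default) or "BH".
#' @return data.frame with columns `asv_id, mean_12C, mean_13C, log2fc,
#'   statistic, p_value, p_adj, significant`.
#' @export
differential_enrichment <- function(counts, alpha = 0.05,
                                    correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  need <- c("asv_id", "isotope", "replicate", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stopf("count table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stopf("counts must be non-negative integers")
  }
  # library sizes per (isotope, replicate) sample
  samp <- paste(counts$isotope, counts$replicate, sep = ".")
  libsize <- tapply(counts$count, samp, sum)
  if (any(libsize <= 0)) stopf("library size must be > 0 for every sample")
  scale <- mean(libsize) / libsize
  norm <- counts$count * scale[samp]
  lognorm <- log2(norm + 1)
  by_asv <- split(data.frame(isotope = counts$isotope, y = lognorm,
                             raw = counts$count,
                             stringsAsFactors = FALSE),
                  counts$asv_id)
  rows <- lapply(names(by_asv), function(id) {
    d <- by_asv[[id]]
    x13 <- d$y[d$isotope == "13C"]; x12 <- d$y[d$isotope == "12C"]
    if (length(x13) < 2L || length(x12) < 2L) {
      stopf("ASV %s: >= 2 replicates required per isotope", id)
    }
    tt <- two_sample_t(x13, x12, mode = "student")
    data.frame(asv_id = id,
               mean_12C = mean(d$raw[d$isotope == "12C"]),
               mean_13C = mean(d$raw[d$isotope == "13C"]),
               log2fc = mean(x13) - mean(x12),
               statistic = tt$t, p_value = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "BH") stats::p.adjust(out$p_value, "BH")
               else out$p_value
  out$significant <- out$log2fc > 0 & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Metabolic-capability class from two enrichment flags
#'
#' Maps significant 13C enrichment in the uninhibited context
#' (`sig_no_inhibitor`) and the acetylene context (`sig_ace`) to a
#' metabolic class.  Under the default `mechanistic` mapping, enrichment
#' with autotrophy intact and under acetylene (autotrophy blocked) implies
#' both inorganic and organic carbon metabolism; enrichment only without
#' inhibitor implies inorganic metabolism; enrichment only under
#' acetylene implies organic metabolism; no enrichment means unlabeled.
#' The `literal` mapping swaps the two exclusive classes, reproducing a
#' reading in which enrichment restricted to the inhibitor-free soil is
#' taken as organic capacity.
#'
#' @param sig_no_inhibitor,sig_ace Logical enrichment flags (vectorized).
#' @param mapping "mechanistic" (default) or "literal".
#' @return Character vector of classes in
#'   `{both, inorganic_only, organic_only, unlabeled}`.
#' @export
classify_metabolism <- function(sig_no_inhibitor, sig_ace,
                                mapping = c("mechanistic", "literal")) {
  mapping <- match.arg(mapping)
  exclusive_no_inhib <- if (mapping == "mechanistic") "inorganic_only"
                        else "organic_only"
  exclusive_ace <- if (mapping == "mechanistic") "organic_only"
                   else "inorganic_only"
  ifelse(sig_no_inhibitor & sig_ace, "both",
    ifelse(sig_no_inhibitor, exclusive_no_inhib,
      ifelse(sig_ace, exclusive_ace, "unlabeled")))
}

#' Classify every ASV across the two inhibitor contexts
#'
#' Runs [differential_enrichment()] in the `no_inhibitor` and `ace`
#' contexts and combines the per-context flags through
#' [classify_metabolism()].
#'
#' @param counts An `asv_count_table` covering both contexts, or a list
#'   with elements `no_inhibitor` and `ace`.
#' @param alpha,correction Passed to [differential_enrichment()].
#' @param mapping Passed to [classify_metabolism()].
#' @return List with `calls` (data.frame: asv_id, p_no_inhib, p_ace,
#'   sig_no_inhib, sig_ace, class) and `class_counts` (named integer
#'   vector over the four classes).
#' @export
classify_table <- function(counts, alpha = 0.05,
                           correction = c("none", "BH"),
                           mapping = c("mechanistic", "literal")) {
  correction <- match.arg(correction)
  mapping <- match.arg(mapping)
  if (is.data.frame(counts)) {
    if (!"context" %in% names(counts)) stopf("count table lacks `context`")
    counts <- split(counts, counts$context)
  }
  if (!all(c("no_inhibitor", "ace") %in% names(counts))) {
    stopf("both contexts (no_inhibitor, ace) are required")
  }
  de_ni <- differential_enrichment(counts$no_inhibitor, alpha, correction)
  de_ace <- differential_enrichment(counts$ace, alpha, correction)
  if (!setequal(de_ni$asv_id, de_ace$asv_id)) {
    stopf("contexts cover different ASV sets")
  }
  de_ace <- de_ace[match(de_ni$asv_id, de_ace$asv_id), ]
  calls <- data.frame(asv_id = de_ni$asv_id,
                      p_no_inhib = de_ni$p_adj, p_ace = de_ace$p_adj,
                      sig_no_inhib = de_ni$significant,
                      sig_ace = de_ace$significant,
                      stringsAsFactors = FALSE)
  calls$class <- classify_metabolism(calls$sig_no_inhib, calls$sig_ace,
                                     mapping)
  cc <- table(factor(calls$class, levels = ASV_CLASSES))
  list(calls = calls,
       class_counts = stats::setNames(as.integer(cc), names(cc)))
}
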