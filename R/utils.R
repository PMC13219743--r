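# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a root seed, staying inside 32-bit
# integer range.  Deterministic, collision-free for offset < 1000.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf,
                              strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name)
  }
  if (x < lo || x > hi || (strict_lo && x <= lo)) {
    stopf("`%s` = %g is outside its valid range", name, x)
  }
  invisible(x)
}

assert_fraction <- function(x, name) assert_scalar_num(x, name, 0, 1)

# Write a data.frame as TSV with a fixed, locale-independent format.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
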