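#' @keywords internal
"_PACKAGE"

# All randomness in the package flows through with_seed()/derive_seed():
# functions take an integer seed, scope it locally, and restore the caller's
# RNG state afterwards, so no exported function leaks global random state.

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous global
#' RNG state on exit.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed from a parent seed and a stream index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(2L)) s <- (s * 48271) %% m
  as.integer((s + as.numeric(stream) * 2654435) %% m)
}

# Round-half-up to the nearest integer (R's round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

assert_scalar_pct <- function(x, name, upper = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and >= 0", name), call. = FALSE)
  }
  if (!is.null(upper) && any(x > upper)) {
    stop(sprintf("'%s' must be <= %s", name, upper), call. = FALSE)
  }
  invisible(x)
}

# Canonical GTDB rank order used throughout.
RANKS7 <- c("domain", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIXES <- c(d = "domain", p = "phylum", c = "class", o = "order",
                   f = "family", g = "genus", s = "species")
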