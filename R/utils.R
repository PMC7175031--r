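# Shared internal helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals (ensemble noise,
#' weight initialization, fixture generation) never disturb the caller's
#' random stream.
#'
#' @param seed integer seed, or `NULL` to run without reseeding.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a bounded child seed from a base seed and stream indices; keeps
# per-slice / per-subject noise streams independent yet reproducible.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) s <- (s * 48271 + as.double(k) * 7919 + 1) %% 2147483647
  as.integer(s)
}

# Row standardization with population (1/n) variance, so that the mean
# product of two standardized rows is exactly their Pearson correlation.
standardize_rows <- function(mat, on_constant = c("error", "zero"),
                             what = "row") {
  on_constant <- match.arg(on_constant)
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  ctr <- mat - mu
  s <- sqrt(rowMeans(ctr^2))
  bad <- s < 1e-300 | !is.finite(s)
  if (any(bad)) {
    if (on_constant == "error") {
      stop(sprintf("zero-variance %s(s): %s", what,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    s[bad] <- 1
    ctr[bad, ] <- 0
  }
  ctr / s
}

# Pearson correlation with the convention that zero-variance inputs give 0.
safe_pearson <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sa <- sqrt(mean(a^2)); sb <- sqrt(mean(b^2))
  if (sa < 1e-300 || sb < 1e-300) return(0)
  mean(a * b) / (sa * sb)
}

stop_shape <- function(msg) stop(msg, call. = FALSE)
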