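#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded at `seed`, then
#' restores whatever global RNG state existed before the call. All samplers
#' in this package go through this helper, so a single integer seed threaded
#' through a spec reproduces every draw without leaking state into the
#' caller's session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Draw from a normal truncated at mean +/- trunc*sd (inverse-CDF method).
rtruncnorm3 <- function(n, mean, sd, trunc = 3) {
  if (sd <= 0) return(rep(mean, n))
  lo <- stats::pnorm(-trunc)
  hi <- stats::pnorm(trunc)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

# 4-neighbour dilation of a logical matrix by one pixel (used for adjacency
# queries between compartments; no wrap-around).
dilate4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  out[-1, ]  <- out[-1, ]  | mask[-nr, ]
  out[-nr, ] <- out[-nr, ] | mask[-1, ]
  out[, -1]  <- out[, -1]  | mask[, -nc]
  out[, -nc] <- out[, -nc] | mask[, -1]
  out
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field, n = length(x)) {
  if (!is.numeric(x) || length(x) != n || anyNA(x) || any(!is.finite(x)) ||
      any(x <= 0)) {
    stop_field(field, sprintf("must be %d strictly positive finite value(s)", n))
  }
  invisible(x)
}
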