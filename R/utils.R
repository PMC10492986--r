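#' @keywords internal
"_PACKAGE"

# input-validation helpers used across modules ---------------------------------

stop_validation <- function(...) {
  stop(structure(
    class = c("bodycomp3_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_estimation <- function(...) {
  stop(structure(
    class = c("bodycomp3_estimation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_validation(name, " must be finite and > 0")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_validation(name, " must be finite and >= 0")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample skewness
#'
#' Moment-based sample skewness \eqn{g_1 = m_3 / m_2^{3/2}}, the definition
#' used by Stata's \code{summarize, detail} and its \code{lnskew0} command.
#'
#' @param x numeric vector, length >= 3, non-constant for a meaningful value.
#' @return scalar skewness.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop_validation("need at least 3 finite values for skewness")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^3) / m2^1.5
}

# deterministic sub-seed derivation: keep results < 2^31 and positive
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}
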