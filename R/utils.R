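#' @keywords internal
"_PACKAGE"

# Argument checking helpers kept deliberately small: fail early, name the field.

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_arg("`%s` must be a single integer >= %d (got %s)", name, min,
             paste(format(x), collapse = ","))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_arg("`%s` must be in [%g, %g]", name, lo, hi)
  as.numeric(x)
}

#' Sample skewness (g1) and excess kurtosis (g2)
#'
#' Moment-based sample skewness \eqn{g_1 = m_3 / m_2^{3/2}} and excess
#' kurtosis \eqn{g_2 = m_4 / m_2^2 - 3}, with `NA` returned for degenerate
#' (zero-variance or n < 2) input rather than `NaN`.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return a single numeric value, `NA` if undefined.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' @rdname sample_skewness
#' @export
sample_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}
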