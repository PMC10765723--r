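#' Smoothness-priors detrending
#'
#' Removes the slow aperiodic trend from a series by subtracting the
#' regularised trend `tau` that solves `(I + lambda^2 t(D2) D2) tau = z`,
#' where `D2` is the second-difference operator. Large `lambda` keeps only
#' near-linear trends; `lambda = 0` reproduces the input as trend (output
#' identically zero).
#'
#' @param z Numeric vector, at least 3 points.
#' @param lambda Smoothing parameter (dimensionless), default 500 as is
#'   conventional for RR-interval detrending before short-term DFA.
#' @return `z - trend`, same length as `z`.
#' @export
smoothness_priors_detrend <- function(z, lambda = 500) {
  z <- as.numeric(z)
  n <- length(z)
  if (n < 3) stop("smoothness-priors detrending needs at least 3 points", call. = FALSE)
  if (lambda == 0) return(numeric(n))
  D <- Matrix::bandSparse(n - 2, n, k = 0:2, diagonals = list(
    rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)
  ))
  M <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D)
  trend <- Matrix::solve(M, z)
  as.numeric(z - trend)
}
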