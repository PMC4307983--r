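#' Hill activation function
#'
#' `hill_act(x, K, n) = x^n / (K^n + x^n)`, clamped to 0 for `x <= 0`.
#' `hill_rep(x, K, n) = K^n / (K^n + x^n)` is its repressive mirror and
#' equals 1 at `x = 0`.
#'
#' @param x input concentration (nM), vectorized.
#' @param K half-activation (or half-repression) constant (nM).
#' @param n Hill coefficient (>= 1).
#' @return numeric vector in `[0, 1]`.
#' @export
hill_act <- function(x, K, n) {
  x <- pmax(x, 0)
  xn <- x^n
  xn / (K^n + xn)
}

#' @rdname hill_act
#' @export
hill_rep <- function(x, K, n) {
  x <- pmax(x, 0)
  K^n / (K^n + x^n)
}
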