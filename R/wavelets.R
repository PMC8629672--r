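#' Mother wavelet functions
#'
#' Evaluates the mother wavelet \eqn{\psi(x)}. Two admissible families are
#' shipped: the Mexican hat \eqn{\psi(x) = (1 - x^2)\,e^{-x^2/2}} (the second
#' derivative of a Gaussian, the customary choice in fuzzy wavelet networks)
#' and the real Morlet \eqn{\psi(x) = \cos(5x)\,e^{-x^2/2}} with the standard
#' center frequency 5.
#'
#' @param x Numeric vector, finite.
#' @param family `"mexican_hat"` or `"morlet"`.
#' @return \eqn{\psi(x)}, same length as `x`.
#' @examples
#' mother_wavelet(0)          # 1
#' mother_wavelet(1)          # 0
#' mother_wavelet(2)          # -3 exp(-2)
#' @export
mother_wavelet <- function(x, family = "mexican_hat") {
  switch(family,
    mexican_hat = (1 - x^2) * exp(-x^2 / 2),
    morlet = cos(5 * x) * exp(-x^2 / 2),
    stop(sprintf("unknown wavelet family '%s'", family), call. = FALSE))
}

# dpsi/dx, needed by the analytic gradients
mother_wavelet_deriv <- function(x, family = "mexican_hat") {
  switch(family,
    mexican_hat = x * (x^2 - 3) * exp(-x^2 / 2),
    morlet = -(5 * sin(5 * x) + x * cos(5 * x)) * exp(-x^2 / 2),
    stop(sprintf("unknown wavelet family '%s'", family), call. = FALSE))
}

#' Numerical admissibility check for a wavelet
#'
#' A mother wavelet is admissible when
#' \eqn{C_\psi = \int_0^\infty |\hat\psi(\omega)| / \omega \, d\omega}
#' is finite, which for integrable wavelets is equivalent to
#' \eqn{\hat\psi(0) = \int \psi(x) dx = 0} (zero mean). The check estimates
#' \eqn{\hat\psi} by quadrature on a wide frequency grid and tests both that
#' the mean is (numerically) zero and that the low-frequency tail of
#' \eqn{|\hat\psi(\omega)|/\omega} does not diverge under grid refinement.
#'
#' @param family A family name accepted by [mother_wavelet()], or a function
#'   \eqn{\psi(x)} to test directly.
#' @param x_half Half-width of the spatial integration window.
#' @return `TRUE` if admissible, `FALSE` otherwise.
#' @examples
#' check_admissibility("mexican_hat")   # TRUE
#' check_admissibility(function(x) rep(1, length(x)))  # FALSE: nonzero mean
#' @export
check_admissibility <- function(family = "mexican_hat", x_half = 40) {
  psi <- if (is.function(family)) family else
    function(x) mother_wavelet(x, family)
  xs <- seq(-x_half, x_half, length.out = 16384L)
  dx <- xs[2] - xs[1]
  fx <- psi(xs)
  l1 <- sum(abs(fx)) * dx
  if (!is.finite(l1) || l1 == 0) return(FALSE)
  # hat(psi)(0) relative to L1 mass: zero mean <=> C_psi < Inf
  mean_rel <- abs(sum(fx) * dx) / l1
  if (mean_rel > 1e-4) return(FALSE)
  # C_psi by quadrature: |hat(psi)(w)|/w on a wide grid must stay summable
  # near w = 0 as the grid is refined near the origin.
  psi_hat <- function(w) {
    vapply(w, function(wi) abs(sum(fx * exp(-1i * wi * xs)) * dx), 0)
  }
  cpsi <- function(w_lo) {
    w <- exp(seq(log(w_lo), log(50), length.out = 600L))
    integrand <- psi_hat(w) / w
    sum(0.5 * (integrand[-1] + integrand[-length(w)]) * diff(w))
  }
  c1 <- cpsi(1e-2); c2 <- cpsi(1e-4)
  is.finite(c2) && (c2 - c1) < 1 # refined tail adds only a bounded amount
}

#' Dilated, translated wavelet activation
#'
#' Computes \eqn{\psi((x - b)/a)}, optionally scaled by the energy-normalizing
#' prefactor \eqn{|a|^{-1/2}} when `config$normalize_wavelet` is `TRUE`.
#'
#' @param x Input value(s).
#' @param b Translation.
#' @param a Dilation, `|a| >= config$a_min`.
#' @param config An [fwn_config()] supplying family, normalization and floor.
#' @return Activation value(s).
#' @export
wavelet_activation <- function(x, b, a, config) {
  if (any(abs(a) < config$a_min))
    stop(sprintf("wavelet_activation: |a| < a_min = %g (dilation floor)",
                 config$a_min), call. = FALSE)
  out <- mother_wavelet((x - b) / a, config$wavelet_family)
  if (config$normalize_wavelet) out <- out / sqrt(abs(a))
  out
}
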