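# Rate-coding information measures: closed-form mean Fisher information
# over a fixed firing-rate interval, its Q10, and the information lower
# bound.

#' Specification of a Fisher-information computation
#'
#' @param A Slope of the square-root f-I fit (> 0).
#' @param f_min,f_max Firing-rate interval in Hz (0 < f_min < f_max). The
#'   interval is a convention: Q10 conclusions are independent of it (the
#'   closed forms are proportional to A^4 for both noise models). Default
#'   [10, 300] Hz.
#' @param noise `"poisson"` or `"gaussian"`.
#' @param b Poisson counting-bin duration (cancels from every Q10).
#' @param sigma2 Gaussian rate variance (cancels from every Q10).
#' @return A `fisher_spec` list.
#' @export
fisher_spec <- function(A, f_min = 10, f_max = 300,
                        noise = c("poisson", "gaussian"), b = 1,
                        sigma2 = 1) {
  noise <- match.arg(noise)
  if (A <= 0) stop("A must be > 0")
  if (f_min <= 0 || f_min >= f_max)
    stop("need 0 < f_min < f_max")
  if (b <= 0 || sigma2 <= 0) stop("b and sigma2 must be > 0")
  structure(list(A = A, f_min = f_min, f_max = f_max, noise = noise,
                 b = b, sigma2 = sigma2), class = "fisher_spec")
}

#' Mean Fisher information over a firing-rate interval
#'
#' Closed forms for the square-root transfer function `f = A sqrt(I-I0)`,
#' averaged over the current interval mapping onto `[f_min, f_max]`:
#' Poisson noise `<J_P> = A^4 / (2 f_max f_min (f_max + f_min))`;
#' Gaussian noise
#' `<J_G> = A^4 ln(f_max/f_min) / (2 sigma2 (f_max^2 - f_min^2))`.
#' Both are independent of the threshold `I0`, and both agree with direct
#' quadrature of `J(I)` over the corresponding current interval (the
#' factor 1/2 in the Gaussian form is required by that consistency; a
#' commonly quoted variant omits it, which only rescales the measure and
#' cancels from every Q10).
#'
#' @param spec A [fisher_spec()].
#' @return Mean Fisher information (scalar).
#' @examples
#' mean_fisher(fisher_spec(1, 1, 2))  # 1/12
#' @export
mean_fisher <- function(spec) {
  stopifnot(inherits(spec, "fisher_spec"))
  A <- spec$A; fmin <- spec$f_min; fmax <- spec$f_max
  if (spec$noise == "poisson") {
    A^4 / (2 * fmax * fmin * (fmax + fmin))
  } else {
    A^4 * log(fmax / fmin) / (2 * spec$sigma2 * (fmax^2 - fmin^2))
  }
}

#' Temperature coefficient of mean Fisher information
#'
#' Because only the slope A is temperature dependent in the closed forms,
#' `Q10(<J>) = Q10(A)^4` for both noise models.
#'
#' @param q10_slope Q10 of the f-I slope (> 0).
#' @return `q10_slope^4`.
#' @export
fisher_q10 <- function(q10_slope) {
  if (any(q10_slope <= 0)) stop("q10_slope must be > 0")
  q10_slope^4
}

#' Lower bound on the information transmitted by the rate code
#'
#' `C_low = ln( integral sqrt(J(I) / (2 pi e)) dI )` over the current
#' interval `[I_min, I_max]` obtained by inverting the square-root fit at
#' `f_min` and `f_max` (`I = I0 + (f/A)^2`). `J(I)` is `(f')^2/f` for
#' Poisson noise and `(f')^2/sigma2` for Gaussian noise. The integral is
#' evaluated by adaptive quadrature; the bound is invariant under constant
#' shifts of the current axis (i.e. under `I0`).
#'
#' @param spec A [fisher_spec()].
#' @param I0 Threshold of the square-root fit (default 0; the result does
#'   not depend on it).
#' @return `C_low` in nats.
#' @export
information_lower_bound <- function(spec, I0 = 0) {
  stopifnot(inherits(spec, "fisher_spec"))
  A <- spec$A
  i_min <- I0 + (spec$f_min / A)^2
  i_max <- I0 + (spec$f_max / A)^2
  if (i_max <= i_min) stop("empty integration interval")
  f <- function(I) A * sqrt(I - I0)
  fp <- function(I) A / 2 / sqrt(I - I0)
  J <- if (spec$noise == "poisson") function(I) fp(I)^2 / f(I)
       else function(I) fp(I)^2 / spec$sigma2
  val <- integrate(function(I) sqrt(J(I) / (2 * pi * exp(1))),
                   i_min, i_max, rel.tol = 1e-10)$value
  log(val)
}
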