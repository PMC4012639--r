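# Model core: Connor-Stevens parameters, gating kinetics, and Q10-based
# temperature scaling.

#' Connor-Stevens neuron parameters
#'
#' Bundle of the biophysical parameters of the single-compartment
#' Connor-Stevens model at its reference temperature: peak conductances
#' (mS/mm^2), reversal potentials (mV), membrane capacitance (nF/mm^2) and
#' the reference temperature itself (degrees C). Defaults are the standard
#' parameter set defined at 18 C. The membrane capacitance is not part of
#' that printed set; the conventional specific capacitance of 1 uF/cm^2
#' (10 nF/mm^2) is adopted and exposed here.
#'
#' Units are mutually consistent: mS/mm^2 * mV = uA/mm^2 and
#' uA/mm^2 / (nF/mm^2) = mV/ms.
#'
#' @param g_L,g_Na,g_K,g_A Peak conductances in mS/mm^2 (leak, sodium,
#'   delayed-rectifier potassium, A-type potassium). Must be >= 0.
#' @param E_L,E_Na,E_K,E_A Reversal potentials in mV.
#' @param C_m Membrane capacitance in nF/mm^2.
#' @param T0 Reference temperature in degrees C at which the parameters are
#'   defined.
#' @return An object of class `cs_neuron_params`.
#' @examples
#' p <- cs_neuron_params()
#' p$g_Na
#' @export
cs_neuron_params <- function(g_L = 0.003, g_Na = 1.2, g_K = 0.2,
                             g_A = 0.477, E_L = -17, E_Na = 55, E_K = -72,
                             E_A = -75, C_m = 10, T0 = 18) {
  g <- c(g_L = g_L, g_Na = g_Na, g_K = g_K, g_A = g_A)
  if (any(!is.finite(g)) || any(g < 0))
    stop("peak conductances must be finite and >= 0")
  if (C_m <= 0) stop("C_m must be > 0")
  structure(list(g_L = g_L, g_Na = g_Na, g_K = g_K, g_A = g_A,
                 E_L = E_L, E_Na = E_Na, E_K = E_K, E_A = E_A,
                 C_m = C_m, T0 = T0),
            class = "cs_neuron_params")
}

#' @export
print.cs_neuron_params <- function(x, ...) {
  cat("Connor-Stevens parameters @", x$T0, "C\n")
  cat(sprintf("  gbar (mS/mm^2): L=%.4g Na=%.4g K=%.4g A=%.4g\n",
              x$g_L, x$g_Na, x$g_K, x$g_A))
  cat(sprintf("  E (mV): L=%.4g Na=%.4g K=%.4g A=%.4g   C_m=%.4g nF/mm^2\n",
              x$E_L, x$E_Na, x$E_K, x$E_A, x$C_m))
  invisible(x)
}

#' Gating-variable kinetics of the Connor-Stevens model
#'
#' Evaluates the voltage-dependent kinetics of all five gating variables at
#' the 18 C reference temperature. For the sodium gates m and h and the
#' delayed-rectifier gate n the opening and closing rates alpha and beta
#' (ms^-1) are returned together with the derived steady state
#' `x_inf = alpha/(alpha+beta)` and time constant `tau = 1/(alpha+beta)`
#' (ms). For the A-current gates a and b the steady state and time constant
#' are defined directly. The removable singularities of `alpha_m` (at
#' -29.7 mV) and `alpha_n` (at -45.7 mV) are evaluated by their first-order
#' series expansion when within 1e-6 mV of the singular voltage.
#'
#' @param V Membrane voltage(s) in mV; must be finite.
#' @return A named list of numeric vectors: `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, and `x_inf`/`tau_x` for all five gates.
#' @examples
#' gating_rates(-29.7)$alpha_m  # 3.8, the analytic limit
#' @export
gating_rates <- function(V) {
  if (any(!is.finite(V))) stop("V must be finite")
  lin_over_expm1 <- function(c0, u, k) {
    out <- numeric(length(u))
    sing <- abs(u) < 1e-6
    out[sing] <- (c0 / k) * (1 + 0.5 * k * u[sing])
    out[!sing] <- c0 * u[!sing] / (1 - exp(-k * u[!sing]))
    out
  }
  alpha_m <- lin_over_expm1(0.38, V + 29.7, 0.1)
  beta_m <- 15.2 * exp(-0.0556 * (V + 54.7))
  alpha_h <- 0.266 * exp(-0.05 * (V + 48))
  beta_h <- 3.8 / (1 + exp(-0.1 * (V + 18)))
  alpha_n <- lin_over_expm1(0.02, V + 45.7, 0.1)
  beta_n <- 0.25 * exp(-0.0125 * (V + 55.7))
  tau_a <- 0.3632 + 1.158 / (1 + exp(0.0497 * (V + 55.96)))
  a_inf <- (0.0761 * exp(0.0314 * (V + 94.22)) /
              (1 + exp(0.0346 * (V + 1.17))))^(1 / 3)
  tau_b <- 1.24 + 2.678 / (1 + exp(0.0624 * (V + 50)))
  b_inf <- (1 / (1 + exp(0.0688 * (V + 53.3))))^4
  list(alpha_m = alpha_m, beta_m = beta_m,
       m_inf = alpha_m / (alpha_m + beta_m),
       tau_m = 1 / (alpha_m + beta_m),
       alpha_h = alpha_h, beta_h = beta_h,
       h_inf = alpha_h / (alpha_h + beta_h),
       tau_h = 1 / (alpha_h + beta_h),
       alpha_n = alpha_n, beta_n = beta_n,
       n_inf = alpha_n / (alpha_n + beta_n),
       tau_n = 1 / (alpha_n + beta_n),
       a_inf = a_inf, tau_a = tau_a,
       b_inf = b_inf, tau_b = tau_b)
}

# canonical ordering of the nine temperature-dependence parameters
Q10_PARAM_NAMES <- c("g_L", "g_Na", "g_K", "g_A", "m", "h", "n", "a", "b")

#' Temperature coefficients of the model parameters
#'
#' A `q10_set` holds the nine Q10 values that define one model on the
#' temperature-dependence grid: one per peak conductance (leak, Na, K, A)
#' and one per gating variable (m, h, n, a, b; shared by the gate's opening
#' and closing rates). Physiological ranges are [1.2, 2.0] for conductances
#' and [2.0, 4.0] for gating rates.
#'
#' @param g_L,g_Na,g_K,g_A Conductance Q10s.
#' @param m,h,n,a,b Gating-rate Q10s.
#' @param check One of `"physiological"` (enforce the ranges above),
#'   `"positive"` (only require > 0) or `"none"`.
#' @return Named numeric vector of class `q10_set`, ordered
#'   (g_L, g_Na, g_K, g_A, m, h, n, a, b).
#' @export
q10_set <- function(g_L = 1.5, g_Na = 1.5, g_K = 1.5, g_A = 1.5,
                    m = 3, h = 3, n = 3, a = 3, b = 3,
                    check = c("physiological", "positive", "none")) {
  check <- match.arg(check)
  q <- c(g_L = g_L, g_Na = g_Na, g_K = g_K, g_A = g_A,
         m = m, h = h, n = n, a = a, b = b)
  if (check != "none") {
    if (any(!is.finite(q)) || any(q <= 0)) stop("Q10 values must be > 0")
    if (check == "physiological") {
      gq <- q[1:4]; rq <- q[5:9]
      if (any(gq < 1.2 - 1e-12) || any(gq > 2.0 + 1e-12))
        stop("conductance Q10s must lie in [1.2, 2.0]")
      if (any(rq < 2.0 - 1e-12) || any(rq > 4.0 + 1e-12))
        stop("gating Q10s must lie in [2.0, 4.0]")
    }
  }
  structure(q, class = "q10_set")
}

as_q10_set <- function(x, check = "positive") {
  if (inherits(x, "q10_set")) return(x)
  x <- unlist(x)
  if (length(x) != 9) stop("expected nine Q10 values")
  if (is.null(names(x)) || !all(Q10_PARAM_NAMES %in% names(x)))
    names(x) <- Q10_PARAM_NAMES
  do.call(q10_set, c(as.list(x[Q10_PARAM_NAMES]), list(check = check)))
}

#' Scale the model to a target temperature
#'
#' Applies the three temperature dependencies of the model for a change
#' `dT = T - T0`: every peak conductance is multiplied by its
#' `Q10^(dT/10)`; every reversal potential is scaled by the Nernst ratio
#' `(1 + dT/(T0 + 273.15))`; and each gate's opening and closing rates are
#' multiplied by that gate's `Q10^(dT/10)` (equivalently, its time constant
#' is divided by the same factor while the steady state is unchanged).
#'
#' @param params A [cs_neuron_params()] object at reference temperature.
#' @param q10s A [q10_set()] (or coercible vector).
#' @param dT Temperature difference in degrees C relative to `params$T0`.
#' @return A list with `params` (the scaled [cs_neuron_params()], with
#'   attribute `temperature` set to `T0 + dT`), `rate_factors` (named
#'   multipliers for the gates m, h, n, a, b) and `dT`.
#' @examples
#' sc <- temperature_scale(cs_neuron_params(), q10_set(), dT = 10)
#' sc$params$E_Na  # 55 * (1 + 10/291.15)
#' @export
temperature_scale <- function(params, q10s, dT) {
  stopifnot(inherits(params, "cs_neuron_params"), is.finite(dT))
  q <- as_q10_set(q10s)
  f <- dT / 10
  nernst <- 1 + dT / (params$T0 + 273.15)
  scaled <- params
  scaled$g_L <- params$g_L * unname(q["g_L"])^f
  scaled$g_Na <- params$g_Na * unname(q["g_Na"])^f
  scaled$g_K <- params$g_K * unname(q["g_K"])^f
  scaled$g_A <- params$g_A * unname(q["g_A"])^f
  scaled$E_L <- params$E_L * nernst
  scaled$E_Na <- params$E_Na * nernst
  scaled$E_K <- params$E_K * nernst
  scaled$E_A <- params$E_A * nernst
  attr(scaled, "temperature") <- params$T0 + dT
  list(params = scaled,
       rate_factors = c(m = unname(q["m"])^f, h = unname(q["h"])^f,
                        n = unname(q["n"])^f, a = unname(q["a"])^f,
                        b = unname(q["b"])^f),
       dT = dT)
}
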