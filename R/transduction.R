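# Reverse-engineering the mechanotransduction sigmoid: representative
# receptor responses, composition with spike generation, best-fit
# transduction parameters and their temperature coefficients.

#' Three-parameter sigmoid response
#'
#' The same functional form serves the receptor rate-level curve rho
#' (saturation in Hz) and the transduction curve theta (saturation in
#' uA/mm^2): `sat / (1 + exp(-(I_dB - i50) / width))`.
#'
#' @param sat Saturation level (> 0): firing rate (Hz) for rho, current
#'   (uA/mm^2) for theta.
#' @param i50 Half-maximum sound intensity (dB SPL).
#' @param width Dynamic-range width (dB, > 0).
#' @return A `sigmoid_response` object (callable via [sigmoid_eval()]).
#' @export
sigmoid_response <- function(sat, i50, width) {
  if (sat <= 0 || width <= 0) stop("sat and width must be > 0")
  structure(list(sat = sat, i50 = i50, width = width),
            class = "sigmoid_response")
}

#' Evaluate a sigmoid response
#' @param resp A [sigmoid_response()].
#' @param i_db Sound intensities in dB SPL.
#' @return Response values.
#' @export
sigmoid_eval <- function(resp, i_db) {
  resp$sat / (1 + exp(-(i_db - resp$i50) / resp$width))
}

#' Analytic slope of a sigmoid response
#' @param resp A [sigmoid_response()].
#' @param i_db Sound intensities in dB SPL.
#' @return d(response)/d(i_db); equals `sat/(4 width)` at `i50`.
#' @export
sigmoid_slope <- function(resp, i_db) {
  e <- exp(-(i_db - resp$i50) / resp$width)
  resp$sat * e / (resp$width * (1 + e)^2)
}

#' Representative receptor-response configuration
#'
#' Median cold-temperature receptor-response parameters together with their
#' median Q10s and the median cold temperature; used to infer the
#' representative rate-level curve at arbitrary temperatures via
#' `p(T) = p_cold * Q10(p)^((T - t_cold)/10)`.
#'
#' The shipped defaults are provisional, documented stand-ins (not
#' measured medians): cold saturation 300 Hz, half-max 55 dB SPL, width
#' 4 dB at 22 C, with Q10s 1.4 (saturation), 1.0 (half-max) and 0.8
#' (width) — the rate and width temperature dependencies sit near the
#' centre of the experimentally reported compensated range, and the
#' half-max is temperature invariant.
#'
#' @param t_cold Median cold temperature (degrees C).
#' @param cold A [sigmoid_response()] of cold-median parameters.
#' @param q10 Named vector of Q10s for `sat`, `i50`, `width`.
#' @return A `representative_config`.
#' @export
representative_config <- function(t_cold = 22,
                                  cold = sigmoid_response(300, 55, 4),
                                  q10 = c(sat = 1.4, i50 = 1.0,
                                          width = 0.8)) {
  if (any(q10 <= 0)) stop("Q10s must be > 0")
  structure(list(t_cold = t_cold, cold = cold, q10 = q10),
            class = "representative_config")
}

#' Representative receptor response at a target temperature
#' @param config A [representative_config()].
#' @param temperature Target temperature (degrees C).
#' @return A [sigmoid_response()] with each parameter scaled by
#'   `Q10^((T - t_cold)/10)`.
#' @export
representative_response <- function(config, temperature) {
  f <- (temperature - config$t_cold) / 10
  sigmoid_response(config$cold$sat * config$q10[["sat"]]^f,
                   config$cold$i50 * config$q10[["i50"]]^f,
                   config$cold$width * config$q10[["width"]]^f)
}

#' Compose a transduction curve with square-root spike generation
#'
#' Evaluates the cascade `r(I_dB) = A sqrt(theta(I_dB) - I0)` where the
#' transduction current exceeds the firing threshold, and 0 elsewhere.
#'
#' @param fit List with `A` and `I0` (square-root f-I fit).
#' @param theta A [sigmoid_response()] transduction curve.
#' @param i_db Sound-intensity grid (dB SPL).
#' @return Firing rates (Hz), nondecreasing in `i_db`.
#' @export
compose_response <- function(fit, theta, i_db) {
  if (fit$A <= 0) stop("A must be > 0")
  ic <- sigmoid_eval(theta, i_db)
  ifelse(ic > fit$I0, fit$A * sqrt(pmax(ic - fit$I0, 0)), 0)
}

#' Reverse-engineer the transduction sigmoid for one spike-generation model
#'
#' Finds the transduction parameters (saturation current, half-max
#' intensity, dynamic-range width) whose composition with the given
#' square-root f-I fit best matches a target rate-level curve, by bounded
#' nonlinear least squares on the discretized intensity grid with
#' multi-start (best of >= 5 deterministic starts retained).
#'
#' Bounds keep theta inside the regime where spike generation was
#' characterized: saturation current in (0, 0.6] uA/mm^2 (the simulated
#' current range), half-max in [0, 120] dB, width in (0, 40] dB.
#'
#' @param fit List with `A` and `I0`.
#' @param target A [sigmoid_response()] (the representative receptor
#'   response) or a numeric vector of target rates on `i_db`.
#' @param i_db Evaluation grid; default 32-88 dB SPL in 1 dB steps
#'   (the experimental stimulus range).
#' @param n_starts Number of multi-starts (>= 5 recommended).
#' @param ic_max Upper bound of the saturation current.
#' @return List with `theta` (the best [sigmoid_response()]),
#'   `r_squared`, `sse` and `starts_used`.
#' @export
fit_transduction <- function(fit, target, i_db = 32:88, n_starts = 5,
                             ic_max = 0.6) {
  r_target <- if (inherits(target, "sigmoid_response"))
    sigmoid_eval(target, i_db) else as.numeric(target)
  stopifnot(length(r_target) == length(i_db))
  r_max_feasible <- if (ic_max > fit$I0) fit$A * sqrt(ic_max - fit$I0)
                    else 0
  if (r_max_feasible < 0.5 * max(r_target))
    stop("composed model cannot reach 50% of the target saturation ",
         "for any feasible transduction curve")
  lower <- c(1e-4, 0, 0.05)
  upper <- c(ic_max, 120, 40)
  obj <- function(p) {
    th <- list(sat = p[1], i50 = p[2], width = p[3])
    class(th) <- "sigmoid_response"
    sum((r_target - compose_response(fit, th, i_db))^2)
  }
  # deterministic start set spanning the box
  half_idx <- which.min(abs(r_target - max(r_target) / 2))
  i50_0 <- i_db[half_idx]
  ic_0 <- min(ic_max, max(2e-4, fit$I0 + (max(r_target) / fit$A)^2))
  starts <- rbind(
    c(ic_0, i50_0, 4),
    c(ic_0, i50_0, 10),
    c(min(ic_max, ic_0 * 1.5), i50_0 + 5, 2),
    c(max(lower[1], ic_0 * 0.5), i50_0 - 5, 6),
    c(ic_max * 0.9, i50_0, 20))
  if (n_starts > nrow(starts)) {
    extra <- n_starts - nrow(starts)
    grid <- cbind(seq(lower[1] * 2, upper[1], length.out = extra),
                  seq(max(lower[2], min(i_db)), min(upper[2], max(i_db)),
                      length.out = extra),
                  seq(1, upper[3] / 2, length.out = extra))
    starts <- rbind(starts, grid)
  }
  starts <- starts[seq_len(max(n_starts, 5)), , drop = FALSE]
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[k, ], lower), upper)
    res <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) stop("all optimisation starts failed")
  ss_tot <- sum((r_target - mean(r_target))^2)
  r2 <- if (ss_tot > 0) 1 - best$value / ss_tot else NA_real_
  list(theta = sigmoid_response(best$par[1], best$par[2], best$par[3]),
       r_squared = r2, sse = best$value, starts_used = nrow(starts))
}

#' Temperature coefficients of reverse-engineered transduction curves
#'
#' For each spike-generation model (rows of cold/hot square-root fits),
#' fits the transduction sigmoid against the representative receptor
#' response at the cold and hot temperatures and computes the Q10 of each
#' transduction parameter. Models whose fits fail are excluded and
#' counted.
#'
#' @param fits_cold,fits_hot Data frames with columns `A` and `I0`, one
#'   row per model (cold fits at `T_cold`, hot fits at `T_hot`).
#' @param config A [representative_config()].
#' @param T_cold,T_hot Temperatures of the two fit sets.
#' @param i_db Intensity grid.
#' @param r2_min Fits below this R^2 are treated as failed.
#' @return List with `q10` (data.frame: per-model Q10 of `sat`, `i50`,
#'   `width`, plus cold/hot R^2), `summary` (median, quartiles and full
#'   range per parameter; whiskers cover all data), and `n_failed`.
#' @export
transduction_q10_distribution <- function(fits_cold, fits_hot,
                                          config = representative_config(),
                                          T_cold = 18, T_hot = 28,
                                          i_db = 32:88, r2_min = 0) {
  stopifnot(nrow(fits_cold) == nrow(fits_hot))
  rho_c <- representative_response(config, T_cold)
  rho_h <- representative_response(config, T_hot)
  dT <- T_hot - T_cold
  n <- nrow(fits_cold)
  res <- data.frame(model = seq_len(n), q10_sat = NA_real_,
                    q10_i50 = NA_real_, q10_width = NA_real_,
                    r2_cold = NA_real_, r2_hot = NA_real_)
  n_failed <- 0
  for (i in seq_len(n)) {
    fc <- list(A = fits_cold$A[i], I0 = fits_cold$I0[i])
    fh <- list(A = fits_hot$A[i], I0 = fits_hot$I0[i])
    ok <- tryCatch({
      tc <- fit_transduction(fc, rho_c, i_db)
      th <- fit_transduction(fh, rho_h, i_db)
      if (tc$r_squared < r2_min || th$r_squared < r2_min)
        stop("fit quality below threshold")
      res$q10_sat[i] <- q10_of(tc$theta$sat, th$theta$sat, dT)
      res$q10_i50[i] <- q10_of(tc$theta$i50, th$theta$i50, dT)
      res$q10_width[i] <- q10_of(tc$theta$width, th$theta$width, dT)
      res$r2_cold[i] <- tc$r_squared
      res$r2_hot[i] <- th$r_squared
      TRUE
    }, error = function(e) FALSE)
    if (!ok) n_failed <- n_failed + 1
  }
  summarise <- function(v) {
    v <- v[is.finite(v)]
    c(median = median(v), q25 = quantile(v, 0.25, names = FALSE),
      q75 = quantile(v, 0.75, names = FALSE), min = min(v), max = max(v))
  }
  summary <- rbind(sat = summarise(res$q10_sat),
                   i50 = summarise(res$q10_i50),
                   width = summarise(res$q10_width))
  list(q10 = res, summary = as.data.frame(summary), n_failed = n_failed)
}
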