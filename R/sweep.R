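# Sweep metrics: Q10 quantification, the RMSD robustness score, the
# factorial Q10 grid, the sweep driver, perturbed reference models and
# global RMSD minimization by a genetic algorithm.

#' Temperature coefficient of an observable
#'
#' `Q10(x) = (x_hot / x_cold)^(10 / dT)`: the factor by which `x` changes
#' per 10 degrees C of heating.
#'
#' @param x_cold,x_hot Observable at the two temperatures (> 0).
#' @param dT Temperature difference in degrees C (non-zero).
#' @return Q10 value(s).
#' @examples
#' q10_of(100, 150, 10)  # 1.5
#' q10_of(100, 150, 5)   # 2.25
#' @export
q10_of <- function(x_cold, x_hot, dT) {
  if (any(dT == 0)) stop("dT must be non-zero")
  if (any(x_cold <= 0) || any(x_hot <= 0))
    stop("Q10 requires positive observables")
  (x_hot / x_cold)^(10 / dT)
}

#' Normalized RMSD between cold and hot f-I curves
#'
#' Root-mean-squared difference of the firing rates across all amplitudes
#' (zero-rate entries included), normalized by the mean rate at the colder
#' temperature. This is the temperature-robustness score: an RMSD of 0.5
#' corresponds to an average relative rate change of 50%, roughly a Q10 of
#' 1.5.
#'
#' @param f_cold,f_hot Firing-rate vectors of equal length (Hz).
#' @return The RMSD (dimensionless, >= 0).
#' @examples
#' rmsd(c(10, 20), c(20, 30))  # sqrt(100)/15
#' @export
rmsd <- function(f_cold, f_hot) {
  if (length(f_cold) != length(f_hot) || length(f_cold) < 1)
    stop("rate vectors must have equal length >= 1")
  m <- mean(f_cold)
  if (m <= 0) stop("degenerate normalization: mean cold rate is zero")
  sqrt(mean((f_cold - f_hot)^2)) / m
}

#' Full factorial grid over the nine Q10 parameters
#'
#' Each parameter is sampled in `steps` evenly spaced values within its
#' physiological interval: [1.2, 2.0] for the four conductance Q10s and
#' [2.0, 4.0] for the five gating-rate Q10s. The fixed parameter ordering
#' is (g_L, g_Na, g_K, g_A, m, h, n, a, b) and enumeration follows
#' [expand.grid()] convention: the first parameter varies fastest. The
#' index <-> parameter mapping is a bijection (see [grid_point()],
#' [grid_index()]).
#'
#' @param steps Values per parameter (default 4; 2 or 3 give reduced smoke
#'   grids). May also be a length-9 vector.
#' @param conduct_range,rate_range Sampling intervals.
#' @return A `q10_grid` object with `values` (list of 9 numeric vectors),
#'   `steps` and `n` (= prod(steps)).
#' @export
q10_grid <- function(steps = 4, conduct_range = c(1.2, 2),
                     rate_range = c(2, 4)) {
  if (length(steps) == 1) steps <- rep(steps, 9)
  stopifnot(length(steps) == 9, all(steps >= 1))
  vals <- vector("list", 9)
  names(vals) <- Q10_PARAM_NAMES
  for (i in 1:9) {
    r <- if (i <= 4) conduct_range else rate_range
    vals[[i]] <- if (steps[i] == 1) mean(r)
                 else seq(r[1], r[2], length.out = steps[i])
  }
  structure(list(values = vals, steps = steps, n = prod(steps)),
            class = "q10_grid")
}

#' @export
print.q10_grid <- function(x, ...) {
  cat("Q10 grid:", paste(x$steps, collapse = "x"), "=", x$n, "models\n")
  invisible(x)
}

#' Grid point at a linear index
#' @param grid A [q10_grid()].
#' @param index Integer in `1..grid$n`.
#' @return The [q10_set()] at that index.
#' @export
grid_point <- function(grid, index) {
  stopifnot(index >= 1, index <= grid$n)
  k <- index - 1
  q <- numeric(9)
  for (j in 1:9) {
    s <- grid$steps[j]
    q[j] <- grid$values[[j]][(k %% s) + 1]
    k <- k %/% s
  }
  names(q) <- Q10_PARAM_NAMES
  structure(q, class = "q10_set")
}

#' Linear index of a grid point
#' @param grid A [q10_grid()].
#' @param q A [q10_set()] whose values lie on the grid.
#' @return Integer index such that `grid_point(grid, i)` equals `q`.
#' @export
grid_index <- function(grid, q) {
  idx <- 0
  mult <- 1
  for (j in 1:9) {
    pos <- which(abs(grid$values[[j]] - q[[j]]) < 1e-9)
    if (length(pos) != 1) stop("value off-grid for parameter ",
                               Q10_PARAM_NAMES[j])
    idx <- idx + (pos - 1) * mult
    mult <- mult * grid$steps[j]
  }
  idx + 1
}

# all grid coordinates as an n x 9 matrix of values (expand.grid order)
grid_matrix <- function(grid) {
  as.matrix(do.call(expand.grid, c(grid$values,
                                   list(KEEP.OUT.ATTRS = FALSE))))
}

#' Run the temperature-robustness sweep
#'
#' For every Q10 combination on the grid, computes the f-I curves at the
#' cold and hot temperatures, the RMSD, the square-root fit parameters and
#' their Q10s, the spiking-cost Q10 (sodium load per spike, and the
#' potassium variant), the resting potential and resting costs at both
#' temperatures with their Q10s, and the Fisher-information Q10
#' (`Q10(A)^4`). When the cold temperature equals the reference
#' temperature the cold curve is Q10-independent and computed once.
#' Resting-state quantities depend only on the conductance Q10s and are
#' cached per conductance combination. Per-model failures are recorded in
#' the `note` column rather than aborting the sweep.
#'
#' @param grid A [q10_grid()].
#' @param params Reference [cs_neuron_params()].
#' @param protocol A [stimulus_protocol()].
#' @param T_cold,T_hot Temperatures in degrees C (defaults 18 and 28).
#' @param dt Integration step (ms).
#' @param indices Optional subset of grid indices (chunked execution).
#' @param use_table Use the gating lookup table in the integrator.
#' @param progress Print progress every 1000 models.
#' @return A `sweep_table`: data.frame with one row per model and
#'   attributes `grid`, `protocol`, `temperatures`, `dt` and
#'   `config_hash`.
#' @export
run_sweep <- function(grid, params = cs_neuron_params(),
                      protocol = stimulus_protocol(), T_cold = 18,
                      T_hot = 28, dt = 0.01, indices = NULL,
                      use_table = TRUE, progress = FALSE) {
  if (is.null(indices)) indices <- seq_len(grid$n)
  dT <- T_hot - T_cold
  cold_fixed <- abs(T_cold - params$T0) < 1e-12
  cold_fi <- NULL
  if (cold_fixed)
    cold_fi <- compute_fi_curve(params, q10_set(), T_cold, protocol, dt,
                                use_table = use_table)
  rest_cache <- new.env(parent = emptyenv())
  cols <- c("index", paste0("q10_", Q10_PARAM_NAMES), "rmsd", "A_cold",
            "I0_cold", "r2_cold", "A_hot", "I0_hot", "r2_hot", "q10_A",
            "q10_I0", "q10_spike_cost", "q10_spike_cost_k", "v_rest_cold",
            "v_rest_hot", "i_na_rest_cold", "i_na_rest_hot", "q10_rest_na",
            "q10_rest_k", "q10_fisher", "gate_min", "gate_max")
  n <- length(indices)
  mat <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  notes <- rep(NA_character_, n)
  for (ii in seq_len(n)) {
    i <- indices[ii]
    q <- grid_point(grid, i)
    row <- tryCatch(
      sweep_record(i, q, params, protocol, T_cold, T_hot, dt, cold_fi,
                   rest_cache, use_table),
      error = function(e) {
        notes[ii] <<- conditionMessage(e)
        c(index = i, setNames(as.numeric(q),
                              paste0("q10_", Q10_PARAM_NAMES)))
      })
    mat[ii, names(row)] <- row
    if (progress && ii %% 1000 == 0)
      message("sweep: ", ii, "/", n)
  }
  tab <- as.data.frame(mat)
  tab$note <- notes
  cfg <- list(grid_steps = grid$steps, params = unclass(params),
              protocol = unclass(protocol), T_cold = T_cold,
              T_hot = T_hot, dt = dt)
  structure(tab, class = c("sweep_table", "data.frame"), grid = grid,
            protocol = protocol, temperatures = c(T_cold, T_hot), dt = dt,
            params = params, config_hash = rlang::hash(cfg))
}

# one sweep row as a named numeric vector
sweep_record <- function(i, q, params, protocol, T_cold, T_hot, dt,
                         cold_fi, rest_cache, use_table) {
  if (is.null(cold_fi))
    cold_fi <- compute_fi_curve(params, q, T_cold, protocol, dt,
                                use_table = use_table)
  hot_fi <- compute_fi_curve(params, q, T_hot, protocol, dt,
                             use_table = use_table)
  dT <- T_hot - T_cold
  r <- rmsd(cold_fi$rate, hot_fi$rate)
  fc <- attr(cold_fi, "fit", exact = TRUE); fh <- attr(hot_fi, "fit", exact = TRUE)
  q10_A <- if (!is.null(fc) && !is.null(fh)) q10_of(fc$A, fh$A, dT)
           else NA_real_
  q10_I0 <- if (!is.null(fc) && !is.null(fh) && fc$I0 > 0 && fh$I0 > 0)
    q10_of(fc$I0, fh$I0, dT) else NA_real_

  ec <- attr(cold_fi, "energy"); eh <- attr(hot_fi, "energy")
  lc <- ifelse(ec$n_spikes > 0, ec$na_load / ec$n_spikes, NA_real_)
  lh <- ifelse(eh$n_spikes > 0, eh$na_load / eh$n_spikes, NA_real_)
  kc <- ifelse(ec$n_spikes > 0, ec$k_load / ec$n_spikes, NA_real_)
  kh <- ifelse(eh$n_spikes > 0, eh$k_load / eh$n_spikes, NA_real_)
  q10_cost <- suppressWarnings(spiking_cost_q10(lc, lh, dT))
  q10_cost_k <- suppressWarnings(spiking_cost_q10(kc, kh, dT))

  key <- paste(round(q[1:4], 9), collapse = "|")
  rest <- rest_cache[[key]]
  if (is.null(rest)) {
    cold_r <- resting_costs(temperature_scale(params, q,
                                              T_cold - params$T0)$params)
    hot_r <- resting_costs(temperature_scale(params, q,
                                             T_hot - params$T0)$params)
    rest <- list(cold = cold_r, hot = hot_r,
                 q10_na = q10_of(abs(cold_r$i_na_rest),
                                 abs(hot_r$i_na_rest), dT),
                 q10_k = q10_of(abs(cold_r$i_k_rest),
                                abs(hot_r$i_k_rest), dT))
    rest_cache[[key]] <- rest
  }

  c(index = i,
    setNames(as.numeric(q), paste0("q10_", Q10_PARAM_NAMES)),
    rmsd = r,
    A_cold = if (is.null(fc)) NA_real_ else fc$A,
    I0_cold = if (is.null(fc)) NA_real_ else fc$I0,
    r2_cold = if (is.null(fc)) NA_real_ else fc$r_squared,
    A_hot = if (is.null(fh)) NA_real_ else fh$A,
    I0_hot = if (is.null(fh)) NA_real_ else fh$I0,
    r2_hot = if (is.null(fh)) NA_real_ else fh$r_squared,
    q10_A = q10_A, q10_I0 = q10_I0,
    q10_spike_cost = q10_cost, q10_spike_cost_k = q10_cost_k,
    v_rest_cold = rest$cold$v_r, v_rest_hot = rest$hot$v_r,
    i_na_rest_cold = rest$cold$i_na_rest,
    i_na_rest_hot = rest$hot$i_na_rest,
    q10_rest_na = rest$q10_na, q10_rest_k = rest$q10_k,
    q10_fisher = q10_A^4,
    gate_min = min(attr(cold_fi, "gate_min"), attr(hot_fi, "gate_min")),
    gate_max = max(attr(cold_fi, "gate_max"), attr(hot_fi, "gate_max")))
}

#' Write a sweep table plus its provenance sidecar
#' @param sweep A `sweep_table`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(sweep), file.path(dir, "sweep.csv"),
            row.names = FALSE)
  side <- list(config_hash = attr(sweep, "config_hash"),
               temperatures = attr(sweep, "temperatures"),
               dt = attr(sweep, "dt"),
               grid_steps = attr(sweep, "grid")$steps,
               n_models = nrow(sweep))
  jsonlite::write_json(side, file.path(dir, "sweep_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Perturbed reference models for robustness checks
#'
#' Returns the 24 alternative parameter sets with peak conductances
#' perturbed by the given factor: 8 models with one conductance lowered or
#' raised, plus 16 models with every sign combination applied to all four
#' conductances. The unperturbed reference is not included.
#'
#' @param params Reference [cs_neuron_params()].
#' @param factor Relative perturbation in (0, 1); default 0.2.
#' @return List of 24 [cs_neuron_params()], named by their perturbation
#'   pattern.
#' @export
perturbed_reference_models <- function(params = cs_neuron_params(),
                                       factor = 0.2) {
  if (factor <= 0 || factor >= 1)
    stop("factor must lie strictly in (0, 1)")
  gs <- c("g_L", "g_Na", "g_K", "g_A")
  out <- list()
  for (g in gs) {
    for (s in c(-1, 1)) {
      p <- params
      p[[g]] <- params[[g]] * (1 + s * factor)
      out[[paste0(g, ifelse(s > 0, "+", "-"))]] <- p
    }
  }
  signs <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1),
                       s4 = c(-1, 1))
  for (k in seq_len(nrow(signs))) {
    p <- params
    for (j in 1:4) p[[gs[j]]] <- params[[gs[j]]] *
        (1 + signs[k, j] * factor)
    out[[paste0("all", paste0(ifelse(signs[k, ] > 0, "+", "-"),
                              collapse = ""))]] <- p
  }
  out
}

#' RMSD objective for a given reference model
#'
#' Builds a memoised objective function mapping a [q10_set()] (or plain
#' 9-vector in canonical order) to the RMSD between the cold and hot f-I
#' curves. The cold curve is computed once when `T_cold` equals the
#' reference temperature.
#'
#' @inheritParams run_sweep
#' @return A function `f(q) -> RMSD`.
#' @export
make_rmsd_objective <- function(params = cs_neuron_params(),
                                protocol = stimulus_protocol(),
                                T_cold = 18, T_hot = 28, dt = 0.01,
                                use_table = TRUE) {
  cold_fixed <- abs(T_cold - params$T0) < 1e-12
  cold_fi <- if (cold_fixed)
    compute_fi_curve(params, q10_set(), T_cold, protocol, dt,
                     use_table = use_table, energy = FALSE)
  cache <- new.env(parent = emptyenv())
  function(q) {
    q <- as_q10_set(q)
    key <- paste(signif(q, 12), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cf <- if (cold_fixed) cold_fi
          else compute_fi_curve(params, q, T_cold, protocol, dt,
                                use_table = use_table, energy = FALSE)
    hf <- compute_fi_curve(params, q, T_hot, protocol, dt,
                           use_table = use_table, energy = FALSE)
    val <- rmsd(cf$rate, hf$rate)
    cache[[key]] <- val
    val
  }
}

#' Minimize an objective over the Q10 box by a genetic algorithm
#'
#' Elitist generational GA with binary encoding: each of the nine
#' parameters is discretized to `bits` bits within its bounds, individuals
#' are selected by binary tournament, recombined by single-point crossover
#' on the concatenated bit string, and mutated by per-bit flips. The two
#' best individuals survive unchanged each generation. Defaults follow the
#' published search settings (population 1000, 150 generations, 8-bit
#' discretization, uniformly random initial population); smaller budgets
#' are used for smoke runs. Objective evaluations are memoised across the
#' run, which the discretization makes very effective once the population
#' converges.
#'
#' @param objective Function of a 9-vector (canonical parameter order)
#'   returning the scalar to minimize, e.g. from
#'   [make_rmsd_objective()].
#' @param lower,upper Bounds (length 9, canonical order); defaults are the
#'   physiological box.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param pop_size,generations,bits GA settings.
#' @param p_crossover,p_mutation Crossover probability and per-bit
#'   mutation probability (default 1/(9*bits)).
#' @return List with `par` (best [q10_set()]), `value`, `history` (best
#'   value per generation) and `n_evaluated` (distinct objective
#'   evaluations).
#' @export
minimize_rmsd <- function(objective, lower = NULL, upper = NULL, seed = 1,
                          pop_size = 1000, generations = 150, bits = 8,
                          p_crossover = 0.9, p_mutation = NULL) {
  if (is.null(lower)) lower <- c(rep(1.2, 4), rep(2, 5))
  if (is.null(upper)) upper <- c(rep(2, 4), rep(4, 5))
  stopifnot(length(lower) == 9, length(upper) == 9, all(upper > lower))
  if (pop_size < 2 || generations < 1) stop("empty search budget")
  if (is.null(p_mutation)) p_mutation <- 1 / (9 * bits)
  set.seed(seed)
  L <- 9L * bits
  pow2 <- 2^((bits - 1):0)
  denom <- 2^bits - 1
  decode <- function(pop) {
    # pop: pop_size x L 0/1 Gray-coded matrix -> pop_size x 9 parameters
    # (Gray code avoids Hamming cliffs between adjacent values)
    vals <- matrix(0, nrow(pop), 9)
    for (j in 1:9) {
      g <- pop[, ((j - 1) * bits + 1):(j * bits), drop = FALSE]
      b <- g
      for (k in 2:bits) b[, k] <- (b[, k - 1] + g[, k]) %% 2
      vals[, j] <- lower[j] + (b %*% pow2) / denom * (upper[j] - lower[j])
    }
    vals
  }
  cache <- new.env(parent = emptyenv())
  eval_pop <- function(vals) {
    apply(vals, 1, function(v) {
      key <- paste(signif(v, 12), collapse = "|")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      out <- objective(v)
      cache[[key]] <- out
      out
    })
  }
  pop <- matrix(sample(0:1, pop_size * L, replace = TRUE), pop_size, L)
  history <- numeric(generations)
  best_par <- NULL; best_val <- Inf
  for (gen in seq_len(generations)) {
    vals <- decode(pop)
    fit <- eval_pop(vals)
    ord <- order(fit)
    if (fit[ord[1]] < best_val) {
      best_val <- fit[ord[1]]
      best_par <- vals[ord[1], ]
    }
    history[gen] <- best_val
    if (gen == generations) break
    elite <- pop[ord[1:2], , drop = FALSE]
    # binary tournament selection
    n_child <- pop_size - 2
    i1 <- sample.int(pop_size, n_child, replace = TRUE)
    i2 <- sample.int(pop_size, n_child, replace = TRUE)
    parents <- ifelse(fit[i1] <= fit[i2], i1, i2)
    j1 <- sample.int(pop_size, n_child, replace = TRUE)
    j2 <- sample.int(pop_size, n_child, replace = TRUE)
    mates <- ifelse(fit[j1] <= fit[j2], j1, j2)
    children <- matrix(0L, n_child, L)
    for (k in seq_len(n_child)) {
      a <- pop[parents[k], ]; b <- pop[mates[k], ]
      if (runif(1) < p_crossover) {
        take_b <- runif(L) < 0.5  # uniform crossover
        a[take_b] <- b[take_b]
      }
      children[k, ] <- a
    }
    flips <- matrix(runif(n_child * L) < p_mutation, n_child, L)
    children[flips] <- 1L - children[flips]
    pop <- rbind(elite, children)
  }
  names(best_par) <- Q10_PARAM_NAMES
  list(par = structure(best_par, class = "q10_set"), value = best_val,
       history = history, n_evaluated = length(ls(cache)))
}
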