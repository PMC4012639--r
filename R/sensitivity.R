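# Grid-based elementary-effects sensitivity analysis (impact scores) and
# impact-ordered dimensional stacking.

# Resolve (values, steps, param_names) from either a sweep_table +
# observable column or explicit arguments.
resolve_grid_values <- function(x, observable = NULL, steps = NULL,
                                param_names = NULL) {
  if (inherits(x, "sweep_table")) {
    grid <- attr(x, "grid")
    if (is.null(observable)) stop("observable column name required")
    vals <- x[[observable]][order(x$index)]
    if (length(vals) != grid$n)
      stop("sweep table is not a complete factorial grid")
    list(values = vals, steps = grid$steps, names = Q10_PARAM_NAMES,
         observable = observable)
  } else {
    vals <- as.numeric(x)
    if (is.null(steps)) stop("steps required for plain value vectors")
    if (length(vals) != prod(steps))
      stop("length(values) must equal prod(steps)")
    if (is.null(param_names)) param_names <- paste0("p", seq_along(steps))
    list(values = vals, steps = steps, names = param_names,
         observable = if (is.null(observable)) "x" else observable)
  }
}

#' Impact scores: grid-based global sensitivity analysis
#'
#' For each parameter, collects the point-wise changes of the observable
#' between neighbouring grid points in ascending parameter order, across
#' all combinations of the other parameters ((steps-1) * steps^(K-1)
#' differences per parameter). The impact is the median of this difference
#' distribution; the 25th/75th percentiles serve as error bars, and an
#' impact is flagged reliable when both percentiles share its sign.
#' Impacts are normalized so that their absolute values sum to one (unless
#' all raw medians are zero, which is flagged). Differences involving
#' missing records are dropped and the dropped fraction reported.
#'
#' @param x A `sweep_table` (with `observable` naming a column) or a plain
#'   numeric vector of grid values in enumeration order (first parameter
#'   fastest), with `steps` giving the grid shape.
#' @param observable Column name (sweep input) or label.
#' @param steps,param_names For plain vectors: values per dimension and
#'   parameter names.
#' @return An `impact_table` data.frame with columns `parameter`,
#'   `impact` (signed, normalized), `impact_raw` (median difference),
#'   `q25`, `q75`, `reliable`, `n_pairs`, `dropped_frac`; attribute
#'   `normalized` is FALSE when all medians were zero.
#' @export
impact_scores <- function(x, observable = NULL, steps = NULL,
                          param_names = NULL) {
  g <- resolve_grid_values(x, observable, steps, param_names)
  K <- length(g$steps)
  if (all(g$steps < 2)) stop("impact scores need >= 2 steps somewhere")
  if (mean(is.na(g$values)) > 0.01)
    warning("more than 1% of records are missing")
  arr <- array(g$values, dim = g$steps)
  med <- q25 <- q75 <- n_pairs <- dropped <- numeric(K)
  for (j in seq_len(K)) {
    if (g$steps[j] < 2) next  # singleton dimension: no differences
    d <- apply(arr, setdiff(seq_len(K), j), diff)
    d <- as.numeric(d)
    n_tot <- length(d)
    d <- d[is.finite(d)]
    dropped[j] <- 1 - length(d) / n_tot
    n_pairs[j] <- length(d)
    med[j] <- median(d)
    q25[j] <- quantile(d, 0.25, names = FALSE)
    q75[j] <- quantile(d, 0.75, names = FALSE)
  }
  s <- sum(abs(med))
  normalized <- s > 0
  impact <- if (normalized) med / s else med
  reliable <- impact != 0 & sign(q25) == sign(med) & sign(q75) == sign(med)
  structure(data.frame(parameter = g$names, impact = impact,
                       impact_raw = med, q25 = q25, q75 = q75,
                       reliable = reliable, n_pairs = n_pairs,
                       dropped_frac = dropped),
            class = c("impact_table", "data.frame"),
            observable = g$observable, normalized = normalized)
}

#' Dimensional stacking of a factorial grid into a 2D image
#'
#' Maps the K-dimensional grid onto a two-dimensional pixel array by
#' recursively nesting the parameter axes. With `order = "by_impact"`
#' (requires `impacts`) parameters are ranked by |impact| (ties broken by
#' the fixed parameter ordering) and assigned alternately to the two image
#' dimensions, starting with the horizontal axis and with the
#' highest-impact parameters on the outermost (largest-scale) axes. An
#' explicit character vector of parameter names (outermost first) is
#' honoured as given.
#'
#' @inheritParams impact_scores
#' @param order `"by_impact"` or a character vector of parameter names.
#' @param impacts An `impact_table` (required for `"by_impact"`).
#' @return A `stack_image`: list with `image` (matrix, rows = vertical
#'   axis), `x_params`, `y_params` (outermost first), `x_steps`,
#'   `y_steps`, and the full axis `order`. Pixel <-> grid-point mapping is
#'   a bijection; see [stack_pixel_to_coords()] and
#'   [stack_coords_to_pixel()].
#' @export
dimensional_stack <- function(x, observable = NULL, order = "by_impact",
                              impacts = NULL, steps = NULL,
                              param_names = NULL) {
  g <- resolve_grid_values(x, observable, steps, param_names)
  K <- length(g$steps)
  if (identical(order, "by_impact")) {
    if (is.null(impacts))
      impacts <- impact_scores(x, observable, steps, param_names)
    rank <- order(-abs(impacts$impact), seq_len(K))
    ord_names <- impacts$parameter[rank]
  } else {
    ord_names <- order
  }
  if (!all(ord_names %in% g$names) || length(ord_names) != K ||
      anyDuplicated(ord_names))
    stop("order must be a permutation of the grid parameters")
  ord_idx <- match(ord_names, g$names)
  x_sel <- ord_idx[seq(1, K, by = 2)]  # horizontal axis, outermost first
  y_sel <- if (K >= 2) ord_idx[seq(2, K, by = 2)] else integer(0)

  # coordinates (0-based) of every grid point, enumeration order
  n <- prod(g$steps)
  coords <- matrix(0L, n, K)
  k <- 0:(n - 1)
  for (j in seq_len(K)) {
    coords[, j] <- k %% g$steps[j]
    k <- k %/% g$steps[j]
  }
  mixed_radix <- function(sel) {
    # outermost first = most significant
    pos <- rep(0L, n)
    for (j in sel) pos <- pos * g$steps[j] + coords[, j]
    pos
  }
  col <- mixed_radix(x_sel)
  row <- if (length(y_sel)) mixed_radix(y_sel) else rep(0L, n)
  ncol_img <- prod(g$steps[x_sel])
  nrow_img <- if (length(y_sel)) prod(g$steps[y_sel]) else 1L
  img <- matrix(NA_real_, nrow_img, ncol_img)
  img[cbind(row + 1L, col + 1L)] <- g$values
  structure(list(image = img, x_params = g$names[x_sel],
                 y_params = g$names[y_sel], x_steps = g$steps[x_sel],
                 y_steps = g$steps[y_sel], order = ord_names,
                 steps = g$steps, param_names = g$names,
                 observable = g$observable),
            class = "stack_image")
}

#' Grid coordinates of one image pixel
#' @param stack A `stack_image`.
#' @param row,col 1-based pixel position.
#' @return Named integer vector of 1-based step indices per parameter.
#' @export
stack_pixel_to_coords <- function(stack, row, col) {
  decode <- function(pos, params, steps) {
    out <- integer(length(params))
    for (j in rev(seq_along(params))) {  # innermost = least significant
      out[j] <- pos %% steps[j]
      pos <- pos %/% steps[j]
    }
    names(out) <- params
    out
  }
  cx <- decode(col - 1L, stack$x_params, stack$x_steps)
  cy <- decode(row - 1L, stack$y_params, stack$y_steps)
  full <- c(cx, cy)
  full[stack$param_names] + 1L
}

#' Image pixel of one grid point
#' @param stack A `stack_image`.
#' @param coords Named (or canonically ordered) 1-based step indices.
#' @return List with `row` and `col` (1-based).
#' @export
stack_coords_to_pixel <- function(stack, coords) {
  if (!is.null(names(coords))) coords <- coords[stack$param_names]
  coords0 <- as.integer(coords) - 1L
  names(coords0) <- stack$param_names
  encode <- function(params, steps) {
    pos <- 0L
    for (j in seq_along(params)) pos <- pos * steps[j] +
        coords0[[params[j]]]
    pos
  }
  list(row = encode(stack$y_params, stack$y_steps) + 1L,
       col = encode(stack$x_params, stack$x_steps) + 1L)
}

#' Export an impact table as CSV
#' @param impacts An `impact_table`.
#' @param path Output file.
#' @export
write_impacts_csv <- function(impacts, path) {
  write.csv(as.data.frame(impacts), path, row.names = FALSE)
  invisible(path)
}
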