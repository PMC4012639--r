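# Impact scores and dimensional stacking, checked against brute-force
# enumeration on small analytic grids.

# brute-force elementary effects on an arbitrary small grid
brute_impacts <- function(values, steps) {
  K <- length(steps)
  coords <- as.matrix(do.call(expand.grid,
                              lapply(steps, function(s) seq_len(s))))
  raw <- numeric(K)
  per <- vector("list", K)
  for (j in seq_len(K)) {
    diffs <- c()
    for (r in seq_len(nrow(coords))) {
      if (coords[r, j] < steps[j]) {
        up <- coords[r, ]
        up[j] <- up[j] + 1
        idx_lo <- sum((coords[r, ] - 1) * cumprod(c(1, steps))[1:K]) + 1
        idx_hi <- sum((up - 1) * cumprod(c(1, steps))[1:K]) + 1
        diffs <- c(diffs, values[idx_hi] - values[idx_lo])
      }
    }
    per[[j]] <- diffs
    raw[j] <- median(diffs)
  }
  s <- sum(abs(raw))
  list(impact = if (s > 0) raw / s else raw, raw = raw, per = per)
}

test_that("impact scores match brute-force enumeration on analytic grids", {
  steps <- c(3, 4)
  grid <- expand.grid(p1 = 1:3, p2 = seq(0, 3, length.out = 4))
  # additive observable with opposite-sign coefficients
  v <- 2.5 * grid$p1 - 1.5 * grid$p2
  got <- impact_scores(v, steps = steps)
  want <- brute_impacts(v, steps)
  expect_equal(got$impact, want$impact, tolerance = 1e-12)
  expect_equal(got$impact_raw, want$raw)
  expect_equal(got$n_pairs, c(2 * 4, 3 * 3))

  # nonlinear observable, exact brute-force agreement
  v2 <- sin(grid$p1) * exp(0.3 * grid$p2) + grid$p1^2
  got2 <- impact_scores(v2, steps = steps)
  want2 <- brute_impacts(v2, steps)
  expect_equal(got2$impact, want2$impact, tolerance = 1e-12)
  expect_equal(got2$q25,
               sapply(want2$per, quantile, 0.25, names = FALSE))
  expect_equal(got2$q75,
               sapply(want2$per, quantile, 0.75, names = FALSE))
})

test_that("observable linear in one parameter gets impact (1, 0, ...)", {
  steps <- c(3, 3, 2)
  grid <- expand.grid(a = 1:3, b = 1:3, c = 1:2)
  v <- 4 * grid$a
  imp <- impact_scores(v, steps = steps)
  expect_equal(imp$impact, c(1, 0, 0))
  expect_true(imp$reliable[1])
  expect_false(any(imp$reliable[2:3]))
})

test_that("impacts are antisymmetric and normalized", {
  steps <- c(4, 4)
  set.seed(5)
  v <- rnorm(prod(steps))
  a <- impact_scores(v, steps = steps)
  b <- impact_scores(-v, steps = steps)
  expect_equal(a$impact, -b$impact)
  expect_equal(a$q25, -b$q75)
  expect_equal(a$q75, -b$q25)
  expect_equal(sum(abs(a$impact)), 1, tolerance = 1e-12)
})

test_that("strictly monotone observables give reliable signed impacts", {
  steps <- c(3, 3)
  grid <- expand.grid(a = 1:3, b = 1:3)
  set.seed(8)
  v <- 5 * grid$a + rnorm(9, sd = 0.1)  # strictly increasing in a
  imp <- impact_scores(v, steps = steps)
  expect_gt(imp$impact[1], 0)
  expect_true(imp$reliable[1])
})

test_that("missing records are dropped and reported", {
  steps <- c(3, 3)
  v <- as.numeric(1:9)
  v[5] <- NA
  imp <- suppressWarnings(impact_scores(v, steps = steps))
  # the centre point participates in 2 of 6 differences per dimension
  expect_equal(imp$dropped_frac, c(2 / 6, 2 / 6))
  expect_equal(imp$n_pairs, c(4, 4))
})

test_that("all-zero medians are flagged unnormalized", {
  steps <- c(2, 2)
  v <- c(0, 1, 1, 0)  # antisymmetric: both medians zero
  imp <- impact_scores(v, steps = steps)
  expect_false(attr(imp, "normalized"))
  expect_equal(imp$impact, c(0, 0))
})

test_that("dimensional stacking matches hand enumeration on 2x2", {
  v <- c(11, 21, 12, 22)  # value = 10*p1 + p2 at (p1,p2) in {1,2}^2
  st <- dimensional_stack(v, steps = c(2, 2), order = c("p1", "p2"))
  # p1 on the horizontal axis, p2 vertical: image[row=p2, col=p1]
  expect_equal(dim(st$image), c(2, 2))
  expect_equal(st$image, matrix(c(11, 12, 21, 22), 2, 2))
  expect_equal(st$x_params, "p1")
  expect_equal(st$y_params, "p2")
})

test_that("pixel <-> coordinate mapping is a bijection", {
  steps <- c(3, 2, 4, 2)
  set.seed(3)
  v <- rnorm(prod(steps))
  st <- dimensional_stack(v, steps = steps,
                          order = c("p3", "p1", "p4", "p2"))
  expect_equal(prod(dim(st$image)), prod(steps))
  expect_false(anyNA(st$image))
  seen <- character(0)
  for (k in 1:200) {
    row <- sample.int(nrow(st$image), 1)
    col <- sample.int(ncol(st$image), 1)
    cd <- stack_pixel_to_coords(st, row, col)
    px <- stack_coords_to_pixel(st, cd)
    expect_equal(px$row, row)
    expect_equal(px$col, col)
    # pixel value equals the grid value at those coordinates
    lin <- sum((cd - 1) * cumprod(c(1, steps))[1:4]) + 1
    expect_equal(st$image[row, col], v[lin])
    seen <- c(seen, paste(cd, collapse = ","))
  }
  # by-impact ordering assigns the largest |impact| to the outer x axis
  grid <- expand.grid(p1 = 1:3, p2 = 1:2, p3 = 1:4, p4 = 1:2)
  v2 <- 10 * grid$p3 + grid$p1
  st2 <- dimensional_stack(v2, steps = steps)
  expect_equal(st2$x_params[1], "p3")
  expect_equal(st2$y_params[1], "p1")
})

test_that("constant observables give constant images", {
  st <- dimensional_stack(rep(7, 8), steps = c(2, 2, 2),
                          order = c("p1", "p2", "p3"))
  expect_true(all(st$image == 7))
  expect_error(dimensional_stack(rep(1, 8), steps = c(2, 2, 2),
                                 order = c("p1", "nope", "p3")),
               "permutation")
})
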