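test_that("sigmoid_g is the piecewise-linear sigmoid", {
  expect_equal(sigmoid_g(0.083), 0)        # boundary of the zero branch
  expect_equal(sigmoid_g(0.633), 1)        # alpha_u = alpha_l + 0.55
  expect_equal(sigmoid_g((0.083 + 0.633) / 2), 0.5)
  expect_equal(sigmoid_g(-5), 0)
  expect_equal(sigmoid_g(5), 1)
  # vectorized, monotone
  s <- seq(-1, 2, by = 0.01)
  g <- sigmoid_g(s)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 1))
  expect_error(sigmoid_g(0.5, 0.7, 0.3), "alpha_l")
})

test_that("radius conversions reproduce the published values", {
  expect_equal(sheet_to_grid(0.55, 48), 26.4)
  expect_equal(sheet_to_grid(0.03, 48), 1.44)
  expect_equal(sheet_to_grid(1, 25), 25)
  expect_equal(grid_to_cortex_mm(26.4), 9.9)
  expect_equal(grid_to_cortex_mm(1.44), 0.54)
  expect_equal(grid_to_cortex_mm(0), 0)
})

test_that("count_excitatory_neighbors enumerates lattice offsets", {
  expect_equal(count_excitatory_neighbors(1.44), 8L)
  expect_equal(count_excitatory_neighbors(0.5), 0L)
  expect_equal(count_excitatory_neighbors(1.0), 4L)
  # brute force for a larger radius
  brute <- function(r) {
    cnt <- 0
    for (di in -10:10) for (dj in -10:10) {
      if ((di != 0 || dj != 0) && sqrt(di^2 + dj^2) <= r) cnt <- cnt + 1
    }
    cnt
  }
  for (r in c(2, 2.9, 4.1)) expect_equal(count_excitatory_neighbors(r), brute(r))
})

test_that("lissom_params enforces the published constraints", {
  p <- lissom_params()
  expect_equal(c(p$p, p$q, p$r_scale), c(1.5, 1.1, 1.1))
  expect_equal(c(p$eta_A, p$eta_E), c(0.3, 0.25))
  expect_equal(c(p$eta_I_initial, p$eta_I_late), c(0.25, 0.5))
  expect_equal(c(p$rad_A, p$rad_E, p$rad_I), c(1, 0.03, 0.55))
  expect_error(lissom_params(rad_A = 0.5, rad_I = 0.55), "rad_A")
  expect_error(lissom_params(p = 1.0, r_scale = 1.1), "r_scale")
  expect_error(lissom_params(alpha_l = 0.7, alpha_u = 0.6), "alpha_l")
  # eta_I schedule: 0.25 at 499, 0.5 at 500
  expect_equal(eta_I_at(p, 499), 0.25)
  expect_equal(eta_I_at(p, 500), 0.5)
})

test_that("init_lissom normalizes weights, is deterministic, anchors the apex", {
  st <- toy_lissom_state(seed = 7)
  for (f in c("A", "E", "I")) {
    rs <- rowSums(st[[f]])
    expect_equal(rs[st$inmask], rep(1, sum(st$inmask)), tolerance = 1e-12)
  }
  st2 <- toy_lissom_state(seed = 7)
  expect_identical(st$A, st2$A)
  expect_identical(st$I, st2$I)
  # apex-adjacent neuron is centered within 2 retinal px of the origin
  mask <- make_boundary_mask(c(6, 6))
  stm <- init_lissom(toy_lissom_params(), mask = mask)
  apex_j <- min(stm$cj[stm$inmask])
  rows_in <- which(stm$inmask & stm$cj == apex_j)
  apex_n <- rows_in[which.min(abs(stm$ci[rows_in] - 3.5))]
  ret_center <- c((5 + 1) / 2, (5 + 1) / 2)
  expect_lt(sqrt(sum((stm$centers[apex_n, ] - ret_center)^2)), 2)
})

test_that("initial_response applies g to the afferent drive (brute force oracle)", {
  st <- toy_lissom_state(seed = 3)
  x <- make_bar(c(5, 5), bar_spec(0, 3, aspect_ratio = 0.5))
  y <- initial_response(st, x)
  xv <- as.numeric(unclass(x))
  for (n in seq_len(36)) {
    expect_equal(y[st$ci[n], st$cj[n]],
                 sigmoid_g(sum(st$A[n, ] * xv)))
  }
  # blank input gives zero activity
  expect_equal(sum(initial_response(st, stimulus_image(matrix(0, 5, 5)))), 0)
  # uniform weights fully covered by a bright region drive to 1
  st$A[1, ] <- 1 / 25
  y <- initial_response(st, stimulus_image(matrix(1, 5, 5)))
  expect_equal(y[1, 1], 1)
})

test_that("settle obeys laterals-off limit and stays in range", {
  st <- toy_lissom_state(seed = 5, q = 0, r_scale = 0.0, p = 1.5)
  # q = r = 0: settled = g(p * afferent drive), independent of steps
  x <- make_bar(c(5, 5), bar_spec(90, 3, aspect_ratio = 0.5))
  xv <- as.numeric(unclass(x))
  y1 <- settle(st, x, steps = 1)
  y9 <- settle(st, x, steps = 9)
  expect_equal(y1, y9)
  expect_equal(as.vector(y9), sigmoid_g(1.5 * drop(st$A %*% xv)) * st$inmask)
  # activities within [0, 1] during settling with laterals on
  st2 <- toy_lissom_state(seed = 5)
  y <- settle(st2, x, steps = 7)
  expect_true(all(y >= 0 & y <= 1))
})

test_that("settle matches a hand-computed one-step toy", {
  # 1-pixel retina, 2x1 cortex, hand-set weights
  p <- lissom_params(retina_shape = c(1, 1), cortex_shape = c(2, 1),
                     init_rad_A = 2, settle_steps = 1, rng_seed = 1)
  st <- init_lissom(p, mask = matrix(TRUE, 2, 1))
  st$A <- matrix(c(1, 1), 2, 1)
  st$E <- diag(2) * 1
  st$I <- matrix(c(0, 1, 1, 0), 2, 2)
  st$L <- NULL   # invalidate the cached lateral matrix
  x <- 1
  # y0 = g(1) = 1 for both neurons
  # step: g(1.5*1 + 1.1*1*1 - 1.1*1*1) = g(1.5) = 1
  y <- settle(st, matrix(1, 1, 1), steps = 1)
  expect_equal(as.vector(y), c(1, 1))
  # stronger inhibition shuts activity down
  st$I <- matrix(c(0, 1, 1, 0), 2, 2) * 3
  st$L <- NULL
  # g(1.5 - 1.1*3) = 0
  y <- settle(st, matrix(1, 1, 1), steps = 1)
  expect_equal(as.vector(y), c(0, 0))
})

test_that("hebbian_update follows the normalized Hebbian rule", {
  # toy case: w = (0.5, 0.5), P = (1, 0), eta * y = 1 -> w' = (0.75, 0.25)
  W <- matrix(c(0.5, 0.5), 1, 2)
  S <- matrix(TRUE, 1, 2)
  W2 <- hebbian_update(W, S, y = 1, P = c(1, 0), eta = 1)
  expect_equal(drop(W2), c(0.75, 0.25))
  # y = 0 leaves weights untouched
  W3 <- hebbian_update(W, S, y = 0, P = c(1, 0), eta = 1)
  expect_identical(W3, W)
  # post-update rows sum to 1 within 1e-9
  set.seed(2)
  S <- matrix(runif(50) < 0.6, 5, 10)
  S[1, 1] <- TRUE  # guarantee nonempty rows
  W <- matrix(0, 5, 10); W[S] <- runif(sum(S)); W <- W / rowSums(W)
  W4 <- hebbian_update(W, S, y = runif(5), P = runif(10), eta = 0.3)
  expect_equal(rowSums(W4), rep(1, 5), tolerance = 1e-9)
  # updates stay within support
  expect_true(all(W4[!S] == 0))
})

test_that("grow_radii grows to the printed bounds and renormalizes", {
  p <- lissom_params(rng_seed = 2)
  st <- init_lissom(p)
  expect_equal(unname(st$bounds), c(25, 1.44, 26.4))
  st$t <- 2000L  # past every schedule end (afferent growth is deferred)
  set.seed(99)
  st2 <- grow_radii(st)
  expect_equal(unname(st2$radii), c(25, 1.44, 26.4))
  # non-decreasing radii along the schedule
  radii <- sapply(c(0, 100, 300, 450, 900, 1200, 1500), function(t) {
    s <- st; s$t <- as.integer(t); grow_radii(s)$radii
  })
  expect_true(all(apply(radii, 1, function(r) all(diff(r) >= 0))))
  # weights renormalized after recruitment
  rs <- rowSums(st2$A)
  expect_equal(rs[st2$inmask], rep(1, sum(st2$inmask)), tolerance = 1e-9)
  rs <- rowSums(st2$I)
  expect_equal(rs[st2$inmask], rep(1, sum(st2$inmask)), tolerance = 1e-9)
})

test_that("train_lissom: determinism, resumability, conservation, inert boundary", {
  bars <- suppressWarnings(enumerate_bar_set(c(5, 5), n_rotations = 3,
                                             n_dilations = 2, aspect = 0.5,
                                             length_min = 2, length_max = 3.5))
  mask <- matrix(TRUE, 6, 6); mask[1, 1] <- mask[6, 6] <- FALSE
  st <- init_lissom(toy_lissom_params(seed = 11), mask = mask)
  a <- train_lissom(st, bars, 12)
  b <- train_lissom(st, bars, 12)
  expect_identical(a$A, b$A)
  expect_identical(a$I, b$I)
  # resumable: 5 + 7 equals 12 straight
  c1 <- train_lissom(st, bars, 5)
  c2 <- train_lissom(c1, bars, 7)
  expect_equal(c2$A, a$A, tolerance = 1e-14)
  expect_equal(c2$E, a$E, tolerance = 1e-14)
  expect_equal(c2$I, a$I, tolerance = 1e-14)
  # 0 iterations: unchanged weights
  z <- train_lissom(st, bars, 0)
  expect_equal(z$A, st$A)
  # conservation: weight sums 1 +- 1e-9 after every iteration (checked at end
  # and at the midpoint state)
  for (s in list(c1, a)) {
    for (f in c("A", "E", "I")) {
      expect_equal(rowSums(s[[f]])[s$inmask], rep(1, sum(s$inmask)),
                   tolerance = 1e-9)
    }
  }
  # boundary inertness: out-of-mask neurons have zero weights and activity
  out_n <- which(!a$inmask)
  expect_true(all(a$A[out_n, ] == 0))
  expect_true(all(a$E[out_n, ] == 0))
  expect_true(all(a$E[, out_n] == 0))   # no outgoing laterals either
  y <- settle(a, bars[[1]])
  expect_true(all(y[!a$mask] == 0))
  # metrics recorded per iteration
  expect_equal(a$metrics$iteration, 1:12)
})

test_that("apply_retinal_lesion zeroes the lesioned circle", {
  disc <- make_lesioned_disc(c(25, 25), lesion_spec(9.2, 0))
  sp <- lesion_spec(9.2, 3.4)
  les <- apply_retinal_lesion(disc, sp)
  # composition with make_lesioned_disc is idempotent
  expect_equal(unclass(les), unclass(make_lesioned_disc(c(25, 25), sp)))
  expect_equal(unclass(apply_retinal_lesion(les, sp)), unclass(les))
  # lesion covering nothing active leaves the image unchanged
  ring <- make_ring(c(25, 25), radius = 8, thickness = 1)
  expect_equal(unclass(apply_retinal_lesion(ring, lesion_spec(9.2, 3.4))),
               unclass(ring))
  # lesioned pixel count equals the brute-force circle count
  xs <- rep(seq_len(25) - 13, each = 25); ys <- rep(13 - seq_len(25), 25)
  incirc <- sum(sqrt(xs^2 + ys^2) <= 3.4)
  expect_equal(sum(disc) - sum(les), incirc)
})
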