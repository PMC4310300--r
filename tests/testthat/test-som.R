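# small random instances with brute-force oracles
brute_winner <- function(state, v) {
  best <- NULL; best_d <- Inf
  for (i in seq_len(state$grid[1])) for (j in seq_len(state$grid[2])) {
    if (!state$mask[i, j]) next
    n <- (i - 1) * state$grid[2] + j    # row-major node index
    d <- sum((state$W[n, ] - v)^2)
    if (d < best_d) { best_d <- d; best <- c(i, j) }
  }
  best
}

test_that("find_winner matches an exhaustive per-node distance loop", {
  set.seed(42)
  for (rep in 1:5) {
    st <- som_state(c(3, 3), input_dim = 6, seed = rep)
    v <- runif(6)
    expect_equal(find_winner(st, v), brute_winner(st, v))
  }
  # exact-match node wins with distance 0
  st <- som_state(c(3, 3), input_dim = 6, seed = 1)
  v <- st$W[5, ]   # node (2, 2) in row-major order
  expect_equal(find_winner(st, v), c(2, 2))
  # a masked-out node at distance 0 is never returned
  mask <- matrix(TRUE, 3, 3); mask[2, 2] <- FALSE
  stm <- som_state(c(3, 3), input_dim = 6, mask = mask, seed = 1)
  stm$W[5, ] <- v
  w <- find_winner(stm, v)
  expect_false(all(w == c(2, 2)))
  expect_error(som_state(c(2, 2), 4, mask = matrix(FALSE, 2, 2)), "empty mask")
})

test_that("update_weights applies the Gaussian neighborhood rule exactly", {
  # hand-computed 3x3 toy: eta_max = 0.5, sigma = 1, winner (2, 2)
  st <- som_state(c(3, 3), input_dim = 2, seed = 3)
  v <- c(1, 0)
  st2 <- update_weights(st, v, c(2, 2), eta_max = 0.5, sigma = 1)
  for (i in 1:3) for (j in 1:3) {
    n <- (i - 1) * 3 + j
    eta <- 0.5 * exp(-((i - 2)^2 + (j - 2)^2) / 2)
    expect_equal(st2$W[n, ], st$W[n, ] + eta * (v - st$W[n, ]),
                 info = sprintf("node (%d,%d)", i, j))
  }
  # winner with eta_max = 1 lands exactly on v
  st3 <- update_weights(st, v, c(2, 2), eta_max = 1, sigma = 1)
  expect_equal(st3$W[5, ], v)
  # hard cutoff zeroes the far tail
  st4 <- update_weights(st, v, c(1, 1), eta_max = 0.5, sigma = 0.3,
                        cutoff_sigma = 3)
  expect_equal(st4$W[9, ], st$W[9, ])  # node (3,3), distance > 3 sigma
  expect_error(update_weights(st, v, c(2, 2), sigma = 0), "sigma")
  # masked nodes never move
  mask <- matrix(TRUE, 3, 3); mask[3, 1] <- FALSE
  stm <- som_state(c(3, 3), input_dim = 2, mask = mask, seed = 3)
  stm2 <- update_weights(stm, v, c(2, 2))
  expect_identical(stm2$W[7, ], stm$W[7, ])
})

test_that("som_response equals elementwise brute-force evaluation", {
  st <- som_state(c(3, 4), input_dim = 5, sigma = 0.8, seed = 9)
  v <- runif(5)
  y <- som_response(st, v)
  for (i in 1:3) for (j in 1:4) {
    n <- (i - 1) * 4 + j
    expect_equal(y[i, j], exp(-sum((st$W[n, ] - v)^2) / (2 * 0.8^2)))
  }
  # W = v responds 1; responses decrease with distance
  st$W[1, ] <- v
  y <- som_response(st, v)
  expect_equal(y[1, 1], 1)
  expect_true(all(y <= 1 & y > 0))
})

test_that("train_som is deterministic, resumable, and keeps weights in the hull", {
  dataset <- suppressWarnings(enumerate_bar_set(c(15, 15), n_rotations = 3,
                                                n_dilations = 4))
  st0 <- som_state(c(4, 4), input_dim = 225, seed = 2)
  a <- train_som(st0, dataset, epochs = 3, shuffle_seed = 2)
  b <- train_som(st0, dataset, epochs = 3, shuffle_seed = 2)
  expect_identical(a$W, b$W)
  # epochs = 0 leaves the state unchanged
  z <- train_som(st0, dataset, epochs = 0)
  expect_identical(z$W, st0$W)
  # convex hull: inputs are in [0,1], initial weights in [0,1], eta <= 1
  expect_true(all(a$W >= 0 & a$W <= 1))
  # winner log covers every presentation
  expect_equal(nrow(a$winner_log), 3 * length(dataset))
  # masked nodes' weights bit-identical through training
  mask <- matrix(TRUE, 4, 4); mask[1, 4] <- FALSE
  stm <- som_state(c(4, 4), input_dim = 225, mask = mask, seed = 2)
  am <- train_som(stm, dataset, epochs = 3, shuffle_seed = 2)
  expect_identical(am$W[4, ], stm$W[4, ])  # node (1,4), row-major index 4
})

test_that("1D topographic ordering emerges on scalar inputs", {
  # classical sanity check: a 1 x k SOM on scalars in [0,1] orders its
  # weights monotonically along the grid
  set.seed(31)
  dataset <- lapply(runif(60), function(x) x)
  st <- som_state(c(1, 8), input_dim = 1, eta_max = 0.5, sigma = 2,
                  eta_min = 0.02, sigma_min = 0.5, schedule_epochs = 15,
                  seed = 4)
  st <- train_som(st, dataset, epochs = 15, shuffle_seed = 4)
  w <- drop(st$W)
  expect_true(all(diff(w) > 0) || all(diff(w) < 0))
})

test_that("axis_orthogonality recovers constructed geometries", {
  grid <- expand.grid(dilation_level = 1:5, rotation_deg = seq(0, 160, 40))
  # perfect Cartesian product: dilation along columns, rotation along rows
  wm <- data.frame(rotation_deg = grid$rotation_deg,
                   dilation_level = grid$dilation_level,
                   row = as.integer(factor(grid$rotation_deg)),
                   col = grid$dilation_level)
  expect_equal(axis_orthogonality(wm), 90)
  # both features on the same axis
  wm2 <- wm
  wm2$row <- wm2$col <- wm$col + as.integer(factor(wm$rotation_deg)) * 6
  expect_equal(axis_orthogonality(wm2), 0, tolerance = 1e-4)
  # degenerate log errors
  wm3 <- wm; wm3$row <- 1; wm3$col <- 1
  expect_error(axis_orthogonality(wm3), "degenerate")
})

test_that("winner_reassignment_rate counts changed winners", {
  a <- data.frame(input = 1:4, row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  b <- a; b$row[2] <- 9
  expect_equal(winner_reassignment_rate(a, a), 0)
  expect_equal(winner_reassignment_rate(a, b), 0.25)
})
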