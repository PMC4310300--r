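#' Kohonen self-organizing map with an optional cortical boundary
#'
#' A 2-D competitive network: every output node `(i, j)` holds a weight
#' vector of the input dimension. For each presented input the in-mask node
#' whose weights are nearest in Euclidean distance wins, and all in-mask
#' nodes move toward the input with a Gaussian neighborhood factor
#' `eta_ij = eta_max * exp(-((i-k)^2 + (j-l)^2) / (2 sigma^2))` around the
#' winner `(k, l)`. The node output used for response maps is
#' `y_ij = exp(-||W_ij - V||^2 / (2 sigma^2))`.
#'
#' Masked-out nodes (outside the cortical boundary) never win and are never
#' updated.
#'
#' @name som
NULL

#' Initialize a SOM state
#'
#' Weights are uniform random in \[0, 1\] per component, seeded. Node order
#' is row-major: node index `n = (row - 1) * ncol + col`.
#'
#' @param grid `c(rows, cols)` output grid.
#' @param input_dim input vector length (number of stimulus pixels).
#' @param mask logical `rows x cols` matrix of available nodes (default all).
#' @param eta_max learning-rate ceiling.
#' @param sigma Gaussian neighborhood width, grid units. Shared between the
#'   update neighborhood and the response function.
#' @param eta_min,sigma_min optional schedule floors: when
#'   `schedule_epochs > 0`, `eta_max` and `sigma` decay linearly from their
#'   initial values to these floors over `schedule_epochs` epochs and are
#'   then held. Defaults (`NULL`) keep both constant.
#' @param schedule_epochs schedule horizon in epochs (0 = constant).
#' @param seed RNG seed for the weight initialization.
#' @export
som_state <- function(grid, input_dim, mask = NULL, eta_max = 0.5,
                      sigma = 1.5, eta_min = NULL, sigma_min = NULL,
                      schedule_epochs = 0, seed = 1) {
  rows <- grid[1]; cols <- grid[2]
  if (is.null(mask)) mask <- matrix(TRUE, rows, cols)
  stopifnot(nrow(mask) == rows, ncol(mask) == cols)
  if (!any(mask)) stop("empty mask: no available nodes")
  set.seed(seed)
  n <- rows * cols
  W <- matrix(stats::runif(n * input_dim), n, input_dim)
  # row-major node coordinates
  node_row <- rep(seq_len(rows), each = cols)
  node_col <- rep(seq_len(cols), times = rows)
  in_mask <- mask[cbind(node_row, node_col)]
  structure(list(W = W, grid = c(rows, cols), mask = mask,
                 node_row = node_row, node_col = node_col, in_mask = in_mask,
                 eta_max = eta_max, sigma = sigma,
                 eta_min = if (is.null(eta_min)) eta_max else eta_min,
                 sigma_min = if (is.null(sigma_min)) sigma else sigma_min,
                 schedule_epochs = schedule_epochs,
                 epoch = 0L, seed = seed),
            class = "som_state")
}

# schedule values at a fractional position f in [0, 1] through the
# schedule horizon: linear from start to floor, then held
som_schedule <- function(state, f) {
  f <- min(max(f, 0), 1)
  list(eta_max = state$eta_max + f * (state$eta_min - state$eta_max),
       sigma = state$sigma + f * (state$sigma_min - state$sigma))
}

as_input_vector <- function(v) {
  if (inherits(v, "stimulus_image")) as.numeric(t(unclass(v))) else as.numeric(v)
}

#' Find the winning node for an input
#'
#' Returns the in-mask node minimizing Euclidean distance to the input;
#' ties break lexicographically by (row, col).
#'
#' @param state a [som_state()].
#' @param v input vector or [stimulus_image()].
#' @return `c(row, col)` of the winner.
#' @export
find_winner <- function(state, v) {
  v <- as_input_vector(v)
  stopifnot(length(v) == ncol(state$W))
  d2 <- som_dist2(state, v)
  d2[!state$in_mask] <- Inf
  n <- which.min(d2)  # row-major order = lexicographic (row, col)
  c(state$node_row[n], state$node_col[n])
}

# squared Euclidean distances of every node's weights to v (BLAS-backed;
# clamped at 0 against cancellation)
som_dist2 <- function(state, v) {
  d2 <- rowSums(state$W * state$W) - 2 * drop(state$W %*% v) + sum(v * v)
  pmax(d2, 0)
}

#' Competitive update around a winner
#'
#' Moves every in-mask node toward the input with the Gaussian neighborhood
#' rate centered on the winner. Out-of-mask nodes are untouched. An optional
#' hard cutoff zeroes the rate beyond `cutoff_sigma * sigma` grid units.
#'
#' @inheritParams find_winner
#' @param winner `c(row, col)` winning node (must be in-mask).
#' @param eta_max,sigma update parameters (default from state).
#' @param cutoff_sigma optional hard neighborhood cutoff in units of sigma
#'   (`Inf` = none).
#' @return updated [som_state()].
#' @export
update_weights <- function(state, v, winner, eta_max = state$eta_max,
                           sigma = state$sigma, cutoff_sigma = Inf) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (!state$mask[winner[1], winner[2]]) stop("winner must be inside the mask")
  v <- as_input_vector(v)
  d2 <- (state$node_row - winner[1])^2 + (state$node_col - winner[2])^2
  eta <- eta_max * exp(-d2 / (2 * sigma^2))
  if (is.finite(cutoff_sigma)) eta[d2 > (cutoff_sigma * sigma)^2] <- 0
  eta[!state$in_mask] <- 0
  upd <- eta > 0
  if (any(upd)) {
    e <- eta[upd]
    state$W[upd, ] <- (1 - e) * state$W[upd, , drop = FALSE] + e %o% v
  }
  state
}

#' Gaussian response of all nodes to an input
#'
#' `y_ij = exp(-||W_ij - V||^2 / (2 sigma^2))` for in-mask nodes, 0 outside.
#'
#' @inheritParams find_winner
#' @param sigma response width (defaults to the neighborhood sigma).
#' @return numeric `rows x cols` activity matrix with values in \[0, 1\].
#' @export
som_response <- function(state, v, sigma = state$sigma) {
  v <- as_input_vector(v)
  dif <- state$W - matrix(v, nrow(state$W), length(v), byrow = TRUE)
  d2 <- rowSums(dif * dif)
  y <- exp(-d2 / (2 * sigma^2))
  y[!state$in_mask] <- 0
  matrix(y, state$grid[1], state$grid[2], byrow = TRUE)
}

#' Train a SOM on a stimulus set
#'
#' Runs `epochs` epochs; each epoch presents every input once in seeded
#' random order, applying [find_winner()] + [update_weights()]. The epoch
#' counter persists in the state, so calling `train_som` again continues
#' the learning schedule where it stopped.
#'
#' @inheritParams find_winner
#' @param dataset list of stimulus images (e.g. [enumerate_bar_set()]).
#' @param epochs number of passes over the dataset.
#' @param shuffle_seed base seed for the presentation order (combined with
#'   the epoch number so runs are resumable).
#' @return updated state; the component `winner_log` holds a data frame of
#'   (epoch, input, rotation_deg, dilation_level, row, col) with the winner
#'   of every presentation, most recent training call appended.
#' @export
train_som <- function(state, dataset, epochs = 10, shuffle_seed = state$seed) {
  stopifnot(length(dataset) > 0)
  vs <- lapply(dataset, as_input_vector)
  stopifnot(length(unique(lengths(vs))) == 1, length(vs[[1]]) == ncol(state$W))
  specs <- attr(dataset, "specs")
  logs <- list()
  n_per_epoch <- length(vs)
  for (e in seq_len(epochs)) {
    epoch <- state$epoch + 1L
    set.seed((shuffle_seed * 10007 + epoch) %% .Machine$integer.max)
    ord <- sample(length(vs))
    win <- matrix(0L, length(vs), 2)
    horizon <- state$schedule_epochs * n_per_epoch
    for (idx in seq_along(ord)) {
      k <- ord[idx]
      # per-presentation annealing over the schedule horizon
      f <- if (horizon <= 1) 1 else
        ((epoch - 1) * n_per_epoch + idx - 1) / (horizon - 1)
      sch <- som_schedule(state, f)
      wkl <- find_winner(state, vs[[k]])
      state <- update_weights(state, vs[[k]], wkl,
                              eta_max = sch$eta_max, sigma = sch$sigma)
      win[k, ] <- wkl
    }
    lg <- data.frame(epoch = epoch, input = seq_along(vs),
                     row = win[, 1], col = win[, 2])
    if (!is.null(specs)) {
      lg$rotation_deg <- specs$rotation_deg
      lg$dilation_level <- specs$dilation_level
    }
    logs[[e]] <- lg
    state$epoch <- epoch
  }
  state$winner_log <- rbind(state$winner_log, do.call(rbind, logs))
  state
}

#' Winner map of a dataset (no learning)
#'
#' @inheritParams train_som
#' @return data frame of (input, row, col) plus spec columns if available.
#' @export
som_winner_map <- function(state, dataset) {
  win <- t(vapply(dataset, function(v) find_winner(state, v), integer(2)))
  out <- data.frame(input = seq_along(dataset), row = win[, 1], col = win[, 2])
  specs <- attr(dataset, "specs")
  if (!is.null(specs)) {
    out$rotation_deg <- specs$rotation_deg
    out$dilation_level <- specs$dilation_level
  }
  out
}

#' Orthogonality of the rotation and dilation axes of a winner map
#'
#' Quantifies how orthogonally the two stimulus features are laid out on
#' the output sheet. At every cell of the rotation x dilation feature grid
#' the local dilation-step displacement `u = w(rot, dil+1) - w(rot, dil)`
#' and rotation-step displacement `v = w(rot+1, dil) - w(rot, dil)` of the
#' winner positions are compared; the angle between them (degrees in
#' \[0, 90\]) is averaged over all cells where both are nonzero, weighted
#' by `|u||v|`. A Cartesian product layout scores 90; both features on one
#' axis score 0. The local formulation matters because bar rotation is a
#' circular feature (0 = 180 degrees): a well-organized map embeds the
#' feature grid as a polar fan (dilation radial, rotation angular), which
#' is locally orthogonal everywhere even though no single global pair of
#' axes exists.
#'
#' @param winner_map data frame with columns row, col, rotation_deg,
#'   dilation_level covering a full Cartesian grid of the two features
#'   (e.g. the final epoch of `state$winner_log`, or [som_winner_map()]).
#' @export
axis_orthogonality <- function(winner_map) {
  rots <- sort(unique(winner_map$rotation_deg))
  dils <- sort(unique(winner_map$dilation_level))
  pos <- function(r, d) {
    k <- winner_map$rotation_deg == r & winner_map$dilation_level == d
    c(winner_map$row[k][1], winner_map$col[k][1])
  }
  W <- array(NA_real_, c(length(rots), length(dils), 2))
  for (a in seq_along(rots)) for (d in seq_along(dils)) {
    W[a, d, ] <- pos(rots[a], dils[d])
  }
  num <- 0; den <- 0; any_disp <- FALSE
  for (a in seq_len(length(rots) - 1)) {
    for (d in seq_len(length(dils) - 1)) {
      u <- W[a, d + 1, ] - W[a, d, ]
      v <- W[a + 1, d, ] - W[a, d, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu > 0 || nv > 0) any_disp <- TRUE
      if (nu > 0 && nv > 0) {
        ang <- acos(min(abs(sum(u * v)) / (nu * nv), 1)) * 180 / pi
        num <- num + nu * nv * ang
        den <- den + nu * nv
      }
    }
  }
  if (!any_disp || den == 0) {
    stop("degenerate winner log: all winners identical")
  }
  num / den
}

#' Winner reassignment rate between two winner maps
#'
#' Fraction of inputs whose winning node differs between two winner maps of
#' the same dataset; the stability statistic used to declare convergence.
#'
#' @param map_a,map_b data frames with columns input, row, col.
#' @export
winner_reassignment_rate <- function(map_a, map_b) {
  stopifnot(nrow(map_a) == nrow(map_b))
  a <- map_a[order(map_a$input), ]
  b <- map_b[order(map_b$input), ]
  mean(a$row != b$row | a$col != b$col)
}
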