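#' LISSOM cortical sheet
#'
#' The LISSOM (laterally interconnected synergetically self-organizing map)
#' sheet models one hemisphere's V1 as a grid of neurons, each with three
#' projection fields: afferent weights `A` from the retina, short-range
#' lateral excitatory weights `E` and long-range lateral inhibitory weights
#' `I` from other cortical neurons. For a presented retinal image `x` the
#' initial activity is driven purely by the afferents,
#'
#'   `y_ij = g(sum_ab A_ij,ab x_ab)`
#'
#' after which activity settles under the lateral dynamics
#'
#'   `y_ij(t) = g(p sum A x + q sum E_ij,kl y_kl(t-1) - r sum I_ij,kl y_kl(t-1))`
#'
#' with `g` a piecewise-linear sigmoid and `p, q, r` scaling factors. All
#' three weight fields learn with a divisively normalized Hebbian rule; each
#' field's radius grows from a small initial value toward its bound over the
#' first part of training. A complex-log boundary mask restricts the
#' available cortical area, and afferent centers are initialized with a
#' rough polar retinotopy about the mask's foveal apex.
#'
#' @name lissom
NULL

#' Piecewise-linear sigmoid
#'
#' 0 below `alpha_l`, 1 above `alpha_u`, linear in between.
#'
#' @param s input drive (vector ok).
#' @param alpha_l,alpha_u lower and upper thresholds, `alpha_l < alpha_u`.
#' @export
sigmoid_g <- function(s, alpha_l = 0.083, alpha_u = 0.083 + 0.55) {
  if (alpha_l >= alpha_u) stop("alpha_l must be < alpha_u")
  pmin(pmax((s - alpha_l) / (alpha_u - alpha_l), 0), 1)
}

#' LISSOM model parameters
#'
#' Defaults reproduce the published parameter set for the retinotopic-map
#' simulation: scaling factors `p = 1.5`, `q = 1.1`, `r_scale = 1.1`
#' (`r_scale` is the inhibitory scaling factor, renamed from `r` to avoid
#' collision with eccentricity), learning rates `eta_A = 0.3`,
#' `eta_E = 0.25`, `eta_I` 0.25 initially and 0.5 from iteration 500
#' onward, and radius bounds in normalized sheet units (source sheet width
#' = 1): afferent 1 (25 retinal grid units), excitatory 0.03 (1.44 cortical
#' grid units), inhibitory 0.55 (26.4 cortical grid units).
#'
#' The map develops correctly only if the afferent radius and afferent
#' scaling exceed their inhibitory counterparts (`rad_A > rad_I`,
#' `p > r_scale`), which lets activity spread into the area admitted by the
#' boundary.
#'
#' @param p,q,r_scale afferent / excitatory / inhibitory scaling factors.
#' @param eta_A,eta_E afferent and excitatory learning rates.
#' @param eta_I_initial,eta_I_late inhibitory learning rate before and from
#'   `eta_I_switch_iter`.
#' @param eta_I_switch_iter iteration at which `eta_I` switches.
#' @param rad_A,rad_E,rad_I radius bounds in sheet units of the source
#'   sheet (retina for `rad_A`, cortex for the laterals).
#' @param alpha_l,alpha_u sigmoid thresholds.
#' @param settle_steps settling iterations per presented input (with early
#'   exit once the largest activity change drops below 1e-4).
#' @param retina_shape,cortex_shape grid sizes `c(h, w)`.
#' @param init_rad_A initial afferent radius, retinal grid units. The
#'   small anatomically restricted receptive field anchors each neuron to
#'   its initial retinotopic position; see the methods vignette for the
#'   calibration behind the default.
#' @param init_rad_E initial excitatory radius, cortical grid units;
#'   `NULL` starts it at its (already short-range) bound, so local
#'   excitatory smoothing is present from the first iteration — without it
#'   early settling amplifies afferent noise instead of the retinotopic
#'   signal.
#' @param init_rad_I initial inhibitory radius, cortical grid units;
#'   `NULL` = a quarter of its bound.
#' @param growth_end iteration by which all radii reach their bounds
#'   (linear growth).
#' @param aff_growth_start iteration at which the afferent radius starts
#'   growing toward its full-retina bound (lateral radii grow from
#'   iteration 0). Holding the afferent support at its small initial
#'   radius while the lateral circuitry matures preserves the anatomical
#'   retinotopic scaffold; the late growth still provides the spread the
#'   wide afferent bound exists for.
#' @param aff_growth_end iteration by which the afferent radius reaches
#'   its bound.
#' @param radius_step iterations between radius increments: radii grow
#'   along the linear schedule in discrete steps of this many iterations
#'   (support recomputation is the dominant cost of a training iteration).
#' @param init_jitter standard deviation (retinal pixels) of the Gaussian
#'   scatter added to the initial afferent centers: the pre-training
#'   retinotopy laid down by molecular gradients / retinal waves is coarse,
#'   and stimulus-driven training refines it. Kept below `init_rad_A` so
#'   the correct position stays inside each neuron's support.
#' @param mm_per_grid_unit cortical magnification calibration; 0.375 mm per
#'   cortical grid unit reproduces the printed radius-to-mm conversions
#'   (26.4 -> 9.9 mm, 1.44 -> 0.54 mm).
#' @param rng_seed seed; all randomness in [init_lissom()] and
#'   [train_lissom()] derives from it.
#' @export
lissom_params <- function(p = 1.5, q = 1.1, r_scale = 1.1,
                          eta_A = 0.3, eta_E = 0.25,
                          eta_I_initial = 0.25, eta_I_late = 0.5,
                          eta_I_switch_iter = 500,
                          rad_A = 1, rad_E = 0.03, rad_I = 0.55,
                          alpha_l = 0.083, alpha_u = 0.083 + 0.55,
                          settle_steps = 9,
                          retina_shape = c(25, 25), cortex_shape = c(48, 48),
                          init_rad_A = 2.5, init_rad_E = NULL,
                          init_rad_I = NULL,
                          growth_end = 200, aff_growth_start = 900,
                          aff_growth_end = 1350, radius_step = 10,
                          init_jitter = 1,
                          mm_per_grid_unit = 0.375,
                          rng_seed = 1) {
  stopifnot(rad_A > 0, rad_E > 0, rad_I > 0)
  if (alpha_l >= alpha_u) stop("alpha_l must be < alpha_u")
  if (rad_A <= rad_I) stop("rad_A must exceed rad_I (sheet units)")
  if (p <= r_scale) stop("p must exceed r_scale")
  structure(as.list(environment()), class = "lissom_params")
}

#' Sheet-unit radius to source-grid units
#'
#' Radii are specified as fractions of the source sheet width; on an
#' `n`-wide grid a sheet radius `s` spans `s * n` grid units.
#'
#' @param radius_sheet radius in sheet units (> 0).
#' @param grid_width source grid width in units.
#' @export
sheet_to_grid <- function(radius_sheet, grid_width) {
  stopifnot(radius_sheet > 0)
  radius_sheet * grid_width
}

#' Cortical grid units to millimeters
#'
#' @param radius_grid length in cortical grid units.
#' @param mm_per_grid_unit calibration (default 0.375 mm/unit; see
#'   [lissom_params()]).
#' @export
grid_to_cortex_mm <- function(radius_grid, mm_per_grid_unit = 0.375) {
  radius_grid * mm_per_grid_unit
}

#' Number of lattice neighbors within an excitatory radius
#'
#' Counts integer offsets `(di, dj) != (0, 0)` with
#' `sqrt(di^2 + dj^2) <= rad_E_grid`. At the published excitatory radius of
#' 1.44 grid units each neuron excites its 8 Moore neighbors.
#'
#' @param rad_E_grid excitatory radius in grid units (> 0).
#' @export
count_excitatory_neighbors <- function(rad_E_grid) {
  stopifnot(rad_E_grid > 0)
  m <- ceiling(rad_E_grid)
  off <- expand.grid(di = -m:m, dj = -m:m)
  sum(sqrt(off$di^2 + off$dj^2) <= rad_E_grid) - 1L
}

# per-iteration derived seed (< 2^31) so training is resumable: iteration t
# always consumes the same random numbers regardless of checkpointing
iter_seed <- function(seed, t) {
  (abs(seed) %% 100000L) * 20011 + t
}

# radius value at iteration t under the linear growth schedule
radius_at <- function(r0, r_bound, t, growth_end) {
  r0 + (r_bound - r0) * min(max(t, 0) / growth_end, 1)
}

#' Initialize a LISSOM state
#'
#' Afferent receptive-field centers implement the rough initial retinotopy
#' assumed to be laid down by molecular gradients / retinal waves before
#' stimulus-driven refinement: the cortical neuron at polar position
#' `(rho, phi)` about the mask's foveal apex (leftmost in-mask column,
#' middle row) is centered on the retinal point with eccentricity
#' `rho / rho_max * (retinal half-width)` and angle `phi`. Weights within
#' each initial support are uniform random, divisively normalized to sum 1
#' per neuron per projection.
#'
#' @param params a [lissom_params()].
#' @param mask logical cortical mask (default: the complex-log boundary for
#'   `a = 1` on `cortex_shape`); pass `matrix(TRUE, h, w)` for an
#'   unconstrained sheet.
#' @return an object of class `lissom_state`. Cortical and retinal grids
#'   are flattened column-major.
#' @export
init_lissom <- function(params = lissom_params(), mask = NULL) {
  hc <- params$cortex_shape[1]; wc <- params$cortex_shape[2]
  hr <- params$retina_shape[1]; wr <- params$retina_shape[2]
  if (is.null(mask)) mask <- make_boundary_mask(c(hc, wc))
  stopifnot(nrow(mask) == hc, ncol(mask) == wc)
  if (!any(mask)) stop("empty mask")
  n_c <- hc * wc; n_r <- hr * wr
  ci <- rep(seq_len(hc), times = wc)   # row of cortical neuron (column-major)
  cj <- rep(seq_len(wc), each = hc)
  inmask <- as.vector(mask)
  # foveal apex: leftmost column containing an in-mask cell, middle row
  apex_j <- min(cj[inmask])
  apex_i <- (hc + 1) / 2
  rho <- sqrt((ci - apex_i)^2 + (cj - apex_j)^2)
  phi <- atan2(apex_i - ci, cj - apex_j)   # y upward = decreasing row
  rho_max <- max(rho[inmask])
  r_px <- rho / rho_max * (wr - 1) / 2
  ret_ci <- (hr + 1) / 2 - r_px * sin(phi)
  ret_cj <- (wr + 1) / 2 + r_px * cos(phi)
  set.seed(params$rng_seed)
  jit <- if (is.null(params$init_jitter)) 0 else params$init_jitter
  ret_ci <- ret_ci + stats::rnorm(n_c, 0, jit)
  ret_cj <- ret_cj + stats::rnorm(n_c, 0, jit)
  centers <- cbind(row = pmin(pmax(ret_ci, 1), hr),
                   col = pmin(pmax(ret_cj, 1), wr))
  ri <- rep(seq_len(hr), times = wr)
  rj <- rep(seq_len(wr), each = hr)
  # fixed distance tables: afferent center -> retinal pixel, cortex -> cortex
  D_A <- sqrt(outer(centers[, 1], ri, "-")^2 + outer(centers[, 2], rj, "-")^2)
  D_C <- sqrt(outer(ci, ci, "-")^2 + outer(cj, cj, "-")^2)
  bounds <- c(A = sheet_to_grid(params$rad_A, wr),
              E = sheet_to_grid(params$rad_E, wc),
              I = sheet_to_grid(params$rad_I, wc))
  radii <- c(A = min(params$init_rad_A, bounds[["A"]]),
             E = if (is.null(params$init_rad_E)) bounds[["E"]] else
               min(params$init_rad_E, bounds[["E"]]),
             I = if (is.null(params$init_rad_I)) bounds[["I"]] / 4 else
               min(params$init_rad_I, bounds[["I"]]))
  radii0 <- radii
  col_inm <- rep(inmask, each = n_c)
  sup <- list(A = D_A <= radii[["A"]] & inmask,
              E = D_C <= radii[["E"]] & inmask & col_inm,
              I = D_C <= radii[["I"]] & inmask & col_inm)
  st <- structure(list(params = params, mask = mask, inmask = inmask,
                       ci = ci, cj = cj, centers = centers,
                       D_A = D_A, D_C = D_C,
                       bounds = bounds, radii = radii, radii0 = radii0,
                       sup = sup, t = 0L,
                       metrics = NULL),
                  class = "lissom_state")
  set.seed(params$rng_seed)
  st$A <- init_field(sup$A, n_c)
  st$E <- init_field(sup$E, n_c)
  st$I <- init_field(sup$I, n_c)
  st$L <- params$q * st$E - params$r_scale * st$I
  st
}

# random normalized weight matrix on a logical support (rows = postsynaptic)
init_field <- function(support, n_rows) {
  W <- matrix(0, n_rows, ncol(support))
  idx <- which(support)
  W[idx] <- stats::runif(length(idx))
  normalize_rows(W)
}

# divisive normalization of each nonempty row to sum 1
normalize_rows <- function(W, rows = NULL) {
  if (is.null(rows)) {
    rs <- rowSums(W)
    ok <- rs > 0
    W[ok, ] <- W[ok, , drop = FALSE] / rs[ok]
  } else {
    rs <- rowSums(W[rows, , drop = FALSE])
    ok <- rs > 0
    W[rows[ok], ] <- W[rows[ok], , drop = FALSE] / rs[ok]
  }
  W
}

# column-major flattening of a retinal image
as_retina_vector <- function(x, params) {
  if (inherits(x, "stimulus_image") || is.matrix(x)) {
    stopifnot(nrow(x) == params$retina_shape[1],
              ncol(x) == params$retina_shape[2])
    as.numeric(unclass(x))
  } else {
    as.numeric(x)
  }
}

#' Afferent-only response
#'
#' Activity before lateral settling: `y = g(A x)` for in-mask neurons.
#'
#' @param state a `lissom_state`.
#' @param x retinal image or flattened vector.
#' @return cortical activity matrix (`cortex_shape`).
#' @export
initial_response <- function(state, x) {
  x <- as_retina_vector(x, state$params)
  p <- state$params
  y <- sigmoid_g(drop(state$A %*% x), p$alpha_l, p$alpha_u)
  y[!state$inmask] <- 0
  matrix(y, p$cortex_shape[1], p$cortex_shape[2])
}

#' Settle activity under the lateral dynamics
#'
#' Starting from the afferent-only response, iterates
#' `y <- g(p A x + q E y - r I y)` for up to `steps` steps, with the
#' afferent term held fixed (the input does not change during a
#' presentation) and early exit when the largest activity change falls
#' below 1e-4. Lateral sums read presynaptic activity.
#'
#' @inheritParams initial_response
#' @param steps settling steps (default `params$settle_steps`).
#' @return settled cortical activity matrix.
#' @export
settle <- function(state, x, steps = state$params$settle_steps) {
  x <- as_retina_vector(x, state$params)
  p <- state$params
  Y <- settle_core(state, state$A %*% x, steps)
  matrix(drop(Y), p$cortex_shape[1], p$cortex_shape[2])
}

# shared settling loop; AX = afferent drive (n_cortex x m), one column per
# input. The combined lateral matrix q E - r I halves the per-step matmuls;
# it is cached in state$L by init/train (anything that edits E or I by hand
# must NULL it out).
settle_core <- function(state, AX, steps) {
  p <- state$params
  Y <- sigmoid_g(AX, p$alpha_l, p$alpha_u)
  if (steps > 0) {
    aff <- p$p * AX
    L <- if (!is.null(state$L)) state$L else
      p$q * state$E - p$r_scale * state$I
    for (s in seq_len(steps)) {
      Y_new <- sigmoid_g(aff + L %*% Y, p$alpha_l, p$alpha_u)
      if (any(!is.finite(Y_new))) stop("non-finite activity during settling")
      d <- max(abs(Y_new - Y))
      Y <- Y_new
      if (d < 1e-4) break
    }
  }
  Y[!state$inmask, ] <- 0
  Y
}

# settle a whole batch of inputs at once (X: n_retina x m)
settle_batch <- function(state, X, steps = state$params$settle_steps) {
  settle_core(state, state$A %*% X, steps)
}

#' Normalized Hebbian weight update
#'
#' For every postsynaptic neuron with activity `y_i > 0`:
#' `w' = (w + eta * y_i * P) / sum(w + eta * y_i * P)`, the sum running over
#' the neuron's support. Neurons with `y_i = 0` are untouched (their
#' normalized weights are already a fixed point). The same rule serves the
#' afferent field (`P` = retinal input) and both lateral fields (`P` =
#' settled cortical activity).
#'
#' @param W weight matrix (rows = postsynaptic neurons), rows summing to 1.
#' @param support logical matrix marking each row's support.
#' @param y postsynaptic activity vector.
#' @param P presynaptic activity vector (length `ncol(W)`).
#' @param eta learning rate (>= 0).
#' @export
hebbian_update <- function(W, support, y, P, eta) {
  stopifnot(eta >= 0, length(y) == nrow(W), length(P) == ncol(W))
  hebb_fast(W, support, y, P, eta)$W
}

# shared implementation; also returns the Frobenius norm of the change and
# the updated row set. When support = NULL the support is inferred from
# W > 0 (exact: weights are strictly positive on their support).
hebb_fast <- function(W, support, y, P, eta) {
  act <- which(y > 0)
  if (length(act) == 0 || eta == 0) return(list(W = W, dnorm = 0, act = act))
  Wa0 <- W[act, , drop = FALSE]
  dW <- (eta * y[act]) %o% P
  if (is.null(support)) dW[Wa0 == 0] <- 0
  else dW[!support[act, , drop = FALSE]] <- 0
  rs <- rowSums(Wa0) + rowSums(dW)
  zero <- rs <= 0
  Wa <- Wa0 + dW
  if (any(zero)) {
    warning("all-zero weight row(s) after update; left unchanged")
    Wa[zero, ] <- Wa0[zero, , drop = FALSE]
    rs[zero] <- 1
  }
  Wa <- Wa / rs
  W[act, ] <- Wa
  list(W = W, dnorm = sqrt(sum((Wa - Wa0)^2)), act = act)
}

#' Grow projection radii along their schedule
#'
#' Each projection's radius grows linearly from its initial value to its
#' bound over the first `growth_end` iterations and is then capped. Newly
#' recruited connections (support cells entering the growing radius) get
#' small random weights (uniform, scaled to a tenth of the neuron's mean
#' existing weight) and the field is renormalized.
#'
#' @inheritParams initial_response
#' @return updated state (radii for iteration `state$t`).
#' @export
grow_radii <- function(state) {
  p <- state$params
  step <- if (is.null(p$radius_step)) 1 else p$radius_step
  t_eff <- floor(state$t / step) * step   # discrete growth steps
  ags <- if (is.null(p$aff_growth_start)) 0 else p$aff_growth_start
  age <- if (is.null(p$aff_growth_end)) p$growth_end else p$aff_growth_end
  new_r <- c(A = radius_at(state$radii0[["A"]], state$bounds[["A"]],
                           t_eff - ags, age - ags),
             E = radius_at(state$radii0[["E"]], state$bounds[["E"]],
                           t_eff, p$growth_end),
             I = radius_at(state$radii0[["I"]], state$bounds[["I"]],
                           t_eff, p$growth_end))
  if (all(new_r <= state$radii + 1e-12)) return(state)
  n_c <- length(state$inmask)
  inm <- state$inmask
  col_inm <- rep(inm, each = n_c)
  lateral_changed <- FALSE
  if (new_r[["A"]] > state$radii[["A"]]) {
    sup_new <- state$D_A <= new_r[["A"]] & inm
    state$A <- recruit(state$A, sup_new, state$sup$A)
    state$sup$A <- sup_new
  }
  if (new_r[["E"]] > state$radii[["E"]]) {
    sup_new <- state$D_C <= new_r[["E"]] & inm & col_inm
    state$E <- recruit(state$E, sup_new, state$sup$E)
    state$sup$E <- sup_new
    lateral_changed <- TRUE
  }
  if (new_r[["I"]] > state$radii[["I"]]) {
    sup_new <- state$D_C <= new_r[["I"]] & inm & col_inm
    state$I <- recruit(state$I, sup_new, state$sup$I)
    state$sup$I <- sup_new
    lateral_changed <- TRUE
  }
  if (lateral_changed && !is.null(state$L)) {
    state$L <- state$params$q * state$E - state$params$r_scale * state$I
  }
  state$radii <- new_r
  state
}

# give new support cells small random weights, then renormalize
recruit <- function(W, support_new, support_old) {
  idx <- which(support_new & !support_old)
  if (length(idx) > 0) {
    n <- nrow(W)
    rows <- ((idx - 1) %% n) + 1
    # seed weights carry ~1% of the row mass: new connections only become
    # strong if Hebbian correlation grows them
    cnt <- pmax(rowSums(support_old), 1)
    W[idx] <- stats::runif(length(idx)) * 0.01 / cnt[rows]
    W <- normalize_rows(W, rows = unique(rows))
  }
  W
}

# support masks at the current radii (cached in state$sup by grow_radii)
current_supports <- function(state) state$sup

#' Inhibitory learning rate at an iteration
#'
#' 0.25 before `eta_I_switch_iter`, 0.5 from it onward (published schedule).
#'
#' @param params a [lissom_params()].
#' @param t iteration (1-based).
#' @export
eta_I_at <- function(params, t) {
  if (t >= params$eta_I_switch_iter) params$eta_I_late else params$eta_I_initial
}

#' Train a LISSOM on a stimulus set
#'
#' Per iteration: draw a random stimulus, compute the afferent response,
#' settle under the lateral dynamics, apply the normalized Hebbian update
#' to all three fields (with the inhibitory rate switching at iteration
#' `eta_I_switch_iter`), and advance the radius growth schedule. Each
#' iteration reseeds from `(rng_seed, t)`, so training is resumable:
#' training 200 then 700 iterations is bit-identical to 900 straight.
#'
#' @inheritParams initial_response
#' @param dataset list of retinal stimulus images.
#' @param iterations number of training iterations.
#' @return updated state; `state$metrics` accumulates per-iteration mean
#'   in-mask activity and weight-change norms.
#' @export
train_lissom <- function(state, dataset, iterations) {
  stopifnot(length(dataset) > 0)
  p <- state$params
  xs <- lapply(dataset, as_retina_vector, params = p)
  # deep-copy the weight fields once: the compiled Hebbian kernel updates
  # rows in place, so the caller's state must keep its own matrices
  state$A <- state$A + 0; state$E <- state$E + 0; state$I <- state$I + 0
  state$L <- p$q * state$E - p$r_scale * state$I
  met <- matrix(0, iterations, 9,
                dimnames = list(NULL, c("iteration", "mean_activity",
                                        "dW_aff", "dW_exc", "dW_inh",
                                        "eta_I", "rad_A", "rad_E", "rad_I")))
  for (it in seq_len(iterations)) {
    t <- state$t + 1L
    set.seed(iter_seed(p$rng_seed, t))
    state$t <- t
    state <- grow_radii(state)
    x <- xs[[sample.int(length(xs), 1)]]
    y <- drop(settle_core(state, state$A %*% x, p$settle_steps))
    eI <- eta_I_at(p, t)
    act <- which(y > 0)
    d_aff <- hebb_inplace(state$A, act, y, x, p$eta_A)
    d_exc <- hebb_inplace(state$E, act, y, y, p$eta_E)
    d_inh <- hebb_inplace(state$I, act, y, y, eI)
    if (length(act) > 0) {
      lateral_rows_inplace(state$L, state$E, state$I, act, p$q, p$r_scale)
    }
    met[it, ] <- c(t, mean(y[state$inmask]), d_aff, d_exc, d_inh,
                   eI, state$radii)
  }
  state$metrics <- rbind(state$metrics, as.data.frame(met))
  state
}

#' Apply a retinal lesion to an input image
#'
#' Forces pixels inside the lesion circle to 0 (a de-activated retinal
#' region); used to train / probe the network under lesion conditions.
#'
#' @param x retinal [stimulus_image()].
#' @param lesion a [lesion_spec()] (its `lesion_center` / `lesion_radius`
#'   define the de-activated circle).
#' @export
apply_retinal_lesion <- function(x, lesion) {
  stopifnot(inherits(lesion, "lesion_spec"))
  h <- nrow(x); w <- ncol(x)
  co <- pixel_coords(c(h, w))
  dl <- sqrt((co$x - lesion$lesion_center[1])^2 +
               (co$y - lesion$lesion_center[2])^2)
  px <- unclass(x)
  px[dl <= lesion$lesion_radius] <- 0
  stimulus_image(px)
}

#' Excitatory weight spread of one neuron
#'
#' How far neuron `(i, j)`'s excitatory weight mass reaches. The default
#' `"rms"` method returns the weight-weighted RMS distance
#' `sqrt(sum(w d^2) / sum(w))`, a continuous effective radius that can
#' resolve redistribution within the short excitatory support. The
#' `"threshold"` method returns the largest distance to a presynaptic
#' neuron whose weight exceeds `thresh` x the maximum weight; note it
#' saturates at the excitatory radius bound (1.41 grid units for the
#' 8-neighbor support) as soon as any diagonal weight clears the
#' threshold.
#'
#' @inheritParams initial_response
#' @param i,j cortical grid position (row, column).
#' @param method `"rms"` or `"threshold"`.
#' @param thresh relative weight threshold for the threshold method.
#' @export
excitatory_spread <- function(state, i, j, method = c("rms", "threshold"),
                              thresh = 0.05) {
  method <- match.arg(method)
  hc <- state$params$cortex_shape[1]
  n <- (j - 1) * hc + i
  w <- state$E[n, ]
  if (max(w) <= 0) return(0)
  d <- state$D_C[n, ]
  if (method == "rms") {
    sqrt(sum(w * d^2) / sum(w))
  } else {
    above <- w > thresh * max(w)
    if (!any(above)) return(0)
    max(d[above])
  }
}
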