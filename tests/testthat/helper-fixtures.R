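# Shared fixtures, built in code at test time.

# tiny LISSOM parameter set: 5x5 retina, 6x6 cortex, quick settling
toy_lissom_params <- function(seed = 7, ...) {
  lissom_params(retina_shape = c(5, 5), cortex_shape = c(6, 6),
                init_rad_A = 2, growth_end = 20, radius_step = 1,
                settle_steps = 3, rng_seed = seed, ...)
}

toy_lissom_state <- function(seed = 7, mask = matrix(TRUE, 6, 6), ...) {
  init_lissom(toy_lissom_params(seed = seed, ...), mask = mask)
}

# straight-loop LISSOM iteration: an independent reference implementation
# (explicit per-neuron loops, no matrix algebra) used as the oracle for one
# full response -> settle -> update cycle
reference_lissom_iteration <- function(state, x_img, settle_steps = 2,
                                       eta_I = NULL) {
  p <- state$params
  hc <- p$cortex_shape[1]; wc <- p$cortex_shape[2]
  hr <- p$retina_shape[1]; wr <- p$retina_shape[2]
  x <- matrix(as.numeric(unclass(x_img)), hr, wr)
  if (is.null(eta_I)) eta_I <- p$eta_I_initial
  g <- function(s) {
    if (s <= p$alpha_l) 0
    else if (s >= p$alpha_u) 1
    else (s - p$alpha_l) / (p$alpha_u - p$alpha_l)
  }
  nidx <- function(i, j) (j - 1) * hc + i   # column-major, as the package
  ridx <- function(a, b) (b - 1) * hr + a
  y0 <- matrix(0, hc, wc)
  for (i in seq_len(hc)) for (j in seq_len(wc)) {
    if (!state$mask[i, j]) next
    s <- 0
    for (a in seq_len(hr)) for (b in seq_len(wr)) {
      s <- s + state$A[nidx(i, j), ridx(a, b)] * x[a, b]
    }
    y0[i, j] <- g(s)
  }
  y <- y0
  for (step in seq_len(settle_steps)) {
    y_new <- matrix(0, hc, wc)
    for (i in seq_len(hc)) for (j in seq_len(wc)) {
      if (!state$mask[i, j]) next
      n <- nidx(i, j)
      aff <- 0
      for (a in seq_len(hr)) for (b in seq_len(wr)) {
        aff <- aff + state$A[n, ridx(a, b)] * x[a, b]
      }
      exc <- 0; inh <- 0
      for (k in seq_len(hc)) for (l in seq_len(wc)) {
        m <- nidx(k, l)
        exc <- exc + state$E[n, m] * y[k, l]
        inh <- inh + state$I[n, m] * y[k, l]
      }
      y_new[i, j] <- g(p$p * aff + p$q * exc - p$r_scale * inh)
    }
    d <- max(abs(y_new - y))
    y <- y_new
    if (d < 1e-4) break   # same early exit as the package settling loop
  }
  upd <- function(W, y_post, P, eta) {
    W2 <- W
    for (n in seq_len(nrow(W))) {
      yi <- y_post[n]
      if (yi <= 0) next
      wn <- W[n, ]
      neww <- wn
      for (m in seq_len(length(wn))) {
        if (wn[m] > 0) neww[m] <- wn[m] + eta * yi * P[m]
      }
      W2[n, ] <- neww / sum(neww)
    }
    W2
  }
  yv <- as.vector(y)
  list(y0 = y0, y = y,
       A = upd(state$A, yv, as.vector(x), p$eta_A),
       E = upd(state$E, yv, yv, p$eta_E),
       I = upd(state$I, yv, yv, eta_I))
}
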