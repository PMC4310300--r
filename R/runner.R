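#' Experiment runner
#'
#' Orchestrates the six experiments end to end (stimuli -> train ->
#' analyze) with a single config object, writing a self-describing run
#' directory: config copy, log, metrics CSVs, figure-style PNG panels and a
#' JSON manifest. Config files are JSON.
#'
#' @name runner
NULL

experiment_names <- c("som_basic", "som_bounded", "lissom_bounded",
                      "lissom_unbounded", "lissom_species", "lissom_lesion")

#' Build an experiment configuration
#'
#' Defaults reproduce the published setups: `som_basic` trains a 12x12 SOM
#' for 10 epochs on the 144-bar set rasterized at 81x81; `som_bounded`
#' uses a 13x25 input and a boundary-masked 24x48 output; the `lissom_*`
#' experiments use the published LISSOM parameter set on a 25x25 retina
#' and 48x48 cortex for 900 iterations. `n_iterations` / `n_epochs` can be
#' scaled down for smoke runs.
#'
#' @param experiment one of som_basic, som_bounded, lissom_bounded,
#'   lissom_unbounded, lissom_species, lissom_lesion.
#' @param seed RNG seed recorded in every output manifest.
#' @param out_dir run directory.
#' @param n_epochs SOM training epochs.
#' @param n_iterations LISSOM training iterations.
#' @param a complex-log species constant.
#' @param lissom list of overrides passed to [lissom_params()].
#' @export
experiment_config <- function(experiment, seed = 1, out_dir = tempfile("run"),
                              n_epochs = 10, n_iterations = 900, a = 1,
                              lissom = list()) {
  if (!experiment %in% experiment_names) {
    stop(sprintf("unknown experiment '%s'; valid names: %s", experiment,
                 paste(experiment_names, collapse = ", ")))
  }
  structure(list(experiment = experiment, seed = seed, out_dir = out_dir,
                 n_epochs = n_epochs, n_iterations = n_iterations, a = a,
                 lissom = lissom),
            class = "experiment_config")
}

#' Validate a configuration
#'
#' Returns a character vector of constraint violations (empty = valid):
#' the sheet-unit radius and scaling-factor orderings required for map
#' formation (`rad_A > rad_I`, `p > r_scale`), the sigmoid threshold order,
#' and grid/radius consistency.
#'
#' @param config an [experiment_config()].
#' @export
validate_config <- function(config) {
  v <- character()
  lp <- config$lissom
  g <- function(nm, def) if (!is.null(lp[[nm]])) lp[[nm]] else def
  rad_A <- g("rad_A", 1); rad_E <- g("rad_E", 0.03); rad_I <- g("rad_I", 0.55)
  p <- g("p", 1.5); r_scale <- g("r_scale", 1.1)
  al <- g("alpha_l", 0.083); au <- g("alpha_u", 0.633)
  if (!(rad_A > rad_I)) v <- c(v, "rad_A must be greater than rad_I")
  if (!(p > r_scale)) v <- c(v, "p must be greater than r_scale")
  if (!(al < au)) v <- c(v, "alpha_l must be less than alpha_u")
  if (any(c(rad_A, rad_E, rad_I) <= 0)) v <- c(v, "all radii must be > 0")
  cortex <- g("cortex_shape", c(48, 48))
  if (rad_I * cortex[2] > cortex[2]) {
    v <- c(v, "inhibitory radius exceeds the cortical sheet")
  }
  v
}

run_log <- function(dir) {
  function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = file.path(dir, "run.log"), append = TRUE, sep = "")
  }
}

save_panel <- function(path, img, main = "") {
  grDevices::png(path, width = 480, height = 480)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  graphics::image(t(unclass(img))[, rev(seq_len(nrow(img))), drop = FALSE],
                  axes = FALSE, main = main,
                  col = grDevices::gray.colors(64, 0, 1))
  graphics::par(op)
  grDevices::dev.off()
}

#' Run an experiment end to end
#'
#' Executes the named experiment and writes its artifacts under
#' `config$out_dir`: `config.json`, `run.log`, metrics CSVs, figure-style
#' PNG panels named after the corresponding result figures, and
#' `manifest.json` listing every produced file together with the seed.
#' Rerunning from the copied config reproduces the metrics exactly.
#'
#' @param config an [experiment_config()].
#' @return the run directory, invisibly; the computed result objects are
#'   attached as the attribute `"results"`.
#' @export
run_experiment <- function(config) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    stop(paste(c("invalid config:", viol), collapse = "\n  "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- run_log(config$out_dir)
  log("experiment %s, seed %d", config$experiment, config$seed)
  res <- switch(config$experiment,
                som_basic = exp_som(config, bounded = FALSE, log = log),
                som_bounded = exp_som(config, bounded = TRUE, log = log),
                lissom_bounded = exp_lissom(config, bounded = TRUE, log = log),
                lissom_unbounded = exp_lissom(config, bounded = FALSE,
                                              log = log),
                lissom_species = exp_species(config, log = log),
                lissom_lesion = exp_lesion(config, log = log))
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  jsonlite::write_json(list(experiment = config$experiment,
                            seed = config$seed, files = files),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  out <- config$out_dir
  attr(out, "results") <- res
  invisible(out)
}

exp_som <- function(config, bounded, log) {
  if (bounded) {
    grid_in <- c(13, 25); grid_out <- c(24, 48)
    mask <- make_boundary_mask(grid_out, map_params(a = config$a))
  } else {
    grid_in <- c(81, 81); grid_out <- c(12, 12)
    mask <- NULL
  }
  bars <- enumerate_bar_set(grid_in)
  log("generated %d bar stimuli on %dx%d", length(bars), grid_in[1],
      grid_in[2])
  st <- som_state(grid_out, input_dim = prod(grid_in), mask = mask,
                  eta_max = 0.5, sigma = max(grid_out) / 2,
                  eta_min = 0.05, sigma_min = 1,
                  schedule_epochs = config$n_epochs, seed = config$seed)
  st <- train_som(st, bars, epochs = config$n_epochs,
                  shuffle_seed = config$seed)
  wl <- st$winner_log[st$winner_log$epoch == st$epoch, ]
  utils::write.csv(wl, file.path(config$out_dir, "winner_log.csv"),
                   row.names = FALSE)
  ortho <- axis_orthogonality(wl)
  log("axis orthogonality %.1f deg", ortho)
  utils::write.csv(data.frame(metric = "axis_orthogonality_deg",
                              value = ortho),
                   file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  resp <- som_response(st, bars[[1]])
  save_panel(file.path(config$out_dir,
                       if (bounded) "fig6_response.png" else
                         "fig4_response.png"),
             resp, "SOM response, first bar")
  list(state = st, orthogonality = ortho, winner_log = wl)
}

exp_lissom <- function(config, bounded, log) {
  lp <- do.call(lissom_params, c(config$lissom, list(rng_seed = config$seed)))
  mask <- if (bounded) {
    make_boundary_mask(lp$cortex_shape, map_params(a = config$a))
  } else {
    matrix(TRUE, lp$cortex_shape[1], lp$cortex_shape[2])
  }
  st <- init_lissom(lp, mask)
  bars <- enumerate_bar_set(lp$retina_shape)
  log("training LISSOM (%s) for %d iterations",
      if (bounded) "bounded" else "unbounded", config$n_iterations)
  st <- train_lissom(st, bars, config$n_iterations)
  utils::write.csv(st$metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  am <- meridional_preference(st)
  pm <- probe_point_map(st)
  mono <- map_monotonicity(pm, am)
  log("Spearman ecc~col %.3f, angle~row %.3f", mono$ecc_col, mono$angle_row)
  utils::write.csv(am, file.path(config$out_dir, "angle_map.csv"),
                   row.names = FALSE)
  utils::write.csv(pm, file.path(config$out_dir, "point_map.csv"),
                   row.names = FALSE)
  hist <- angle_histogram(am, st$mask)
  utils::write.csv(hist, file.path(config$out_dir, "angle_histogram.csv"),
                   row.names = FALSE)
  pref_img <- matrix(am$pref_angle / 180, lp$cortex_shape[1],
                     lp$cortex_shape[2])
  pref_img[is.na(pref_img)] <- 0
  save_panel(file.path(config$out_dir,
                       if (bounded) "fig8_preference.png" else
                         "fig13_preference.png"),
             pref_img, "meridional angle preference")
  list(state = st, angle_map = am, point_map = pm, monotonicity = mono,
       histogram = hist)
}

exp_species <- function(config, log) {
  species <- c("squirrel-monkey" = 1, "owl-monkey" = 2.5, "cat" = 4)
  rows <- lapply(names(species), function(sp) {
    mask <- make_boundary_mask(c(48, 48), map_params(a = species[[sp]]))
    write_mask_csv(mask, file.path(config$out_dir,
                                   sprintf("mask_a%.1f.csv", species[[sp]])))
    save_panel(file.path(config$out_dir,
                         sprintf("fig14_%s.png", gsub("-", "_", sp))),
               mask * 1, sprintf("%s (a = %g)", sp, species[[sp]]))
    data.frame(species = sp, a = species[[sp]],
               interior_fraction = mean(mask),
               foveal_indentation = mask_foveal_indentation(mask))
  })
  tab <- do.call(rbind, rows)
  log("species masks: indentation %s",
      paste(sprintf("%.3f", tab$foveal_indentation), collapse = ", "))
  utils::write.csv(tab, file.path(config$out_dir, "species.csv"),
                   row.names = FALSE)
  list(species = tab)
}

#' Lesion recovery protocol
#'
#' Runs the retinal-lesion plasticity experiment on a trained network: a
#' filled disc probes the map; the lesioned disc (the same disc with an
#' inactive circular region) defines the lesion projection zone (LPZ) as
#' the cortical cells active for the intact disc (pre-recovery baseline)
#' but silent for the lesioned one; training then continues on the
#' lesioned input alone. The LPZ is measured at each checkpoint against
#' the fixed pre-recovery baseline, and the excitatory weight spread
#' ([excitatory_spread()]) is tracked for one neuron deep inside the
#' initial LPZ and one active neuron just outside it.
#'
#' @param state trained `lissom_state`.
#' @param disc_radius radius of the probe disc, retinal pixels.
#' @param lesion_radius,lesion_center lesion geometry (retinal pixels /
#'   stimulus coordinates).
#' @param checkpoints recovery iterations at which the LPZ is measured
#'   (0 = before recovery).
#' @param threshold activity threshold for [lpz_area()].
#' @return list: `lpz` (data frame iteration/lpz_area), `spread` (data
#'   frame for the inside/outside neurons before and after recovery),
#'   `state` (post-recovery network), `inside`, `outside` (chosen neuron
#'   positions, NULL if the initial LPZ is empty or tiny).
#' @export
lesion_recovery <- function(state, disc_radius = 10, lesion_radius = 3.5,
                            lesion_center = c(6, 0),
                            checkpoints = c(0, 100, 200), threshold = 0.1) {
  p <- state$params
  spec <- lesion_spec(disc_radius, lesion_radius, lesion_center = lesion_center)
  disc <- make_lesioned_disc(p$retina_shape, lesion_spec(disc_radius, 0))
  lesioned <- make_lesioned_disc(p$retina_shape, spec)
  base_ref <- settle(state, disc)   # fixed pre-recovery baseline
  a0 <- settle(state, lesioned)
  lpz0 <- base_ref >= threshold & a0 < threshold
  inside <- outside <- NULL
  sp_in0 <- sp_out0 <- NA_real_
  if (sum(lpz0) >= 3) {
    lpz_idx <- which(lpz0, arr.ind = TRUE)
    act_idx <- which(base_ref >= threshold & !lpz0, arr.ind = TRUE)
    dmat <- outer(lpz_idx[, 1], act_idx[, 1], "-")^2 +
      outer(lpz_idx[, 2], act_idx[, 2], "-")^2
    inside <- lpz_idx[which.max(apply(dmat, 1, min)), ]
    outside <- act_idx[which.min(apply(dmat, 2, min)), ]
    sp_in0 <- excitatory_spread(state, inside[1], inside[2])
    sp_out0 <- excitatory_spread(state, outside[1], outside[2])
  }
  cur <- state
  done <- 0
  rows <- list()
  acts <- list()
  for (cp in sort(unique(checkpoints))) {
    if (cp > done) {
      cur <- train_lissom(cur, list(lesioned), cp - done)
      done <- cp
    }
    a_les <- settle(cur, lesioned)
    acts[[as.character(cp)]] <- a_les
    rows[[length(rows) + 1]] <- data.frame(
      iteration = cp, lpz_area = lpz_area(a_les, base_ref, threshold))
  }
  spread <- NULL
  if (!is.null(inside)) {
    spread <- data.frame(
      neuron = c("inside", "outside"),
      row = c(inside[1], outside[1]), col = c(inside[2], outside[2]),
      spread_before = c(sp_in0, sp_out0),
      spread_after = c(excitatory_spread(cur, inside[1], inside[2]),
                       excitatory_spread(cur, outside[1], outside[2])))
  }
  list(lpz = do.call(rbind, rows), spread = spread, state = cur,
       inside = inside, outside = outside, activities = acts,
       initial_lpz = lpz0)
}

exp_lesion <- function(config, log, base_state = NULL) {
  lp <- do.call(lissom_params, c(config$lissom, list(rng_seed = config$seed)))
  if (is.null(base_state)) {
    mask <- make_boundary_mask(lp$cortex_shape, map_params(a = config$a))
    st <- init_lissom(lp, mask)
    bars <- suppressWarnings(enumerate_bar_set(lp$retina_shape))
    log("training base map for %d iterations", config$n_iterations)
    st <- train_lissom(st, bars, config$n_iterations)
  } else {
    st <- base_state
  }
  # small lesion: compact cortical footprint within the excitatory range;
  # large lesion: footprint far beyond it
  res_small <- lesion_recovery(st, lesion_radius = 1.4,
                               lesion_center = c(5, -5))
  res_large <- lesion_recovery(st, lesion_radius = 3.5,
                               lesion_center = c(6, 0))
  for (nm in c("small", "large")) {
    res <- if (nm == "small") res_small else res_large
    log("%s lesion LPZ: %s", nm, paste(res$lpz$lpz_area, collapse = " -> "))
    utils::write.csv(res$lpz,
                     file.path(config$out_dir, sprintf("lpz_area_%s.csv", nm)),
                     row.names = FALSE)
    for (cp in names(res$activities)) {
      save_panel(file.path(config$out_dir,
                           sprintf("fig15_%s_iter%s.png", nm, cp)),
                 res$activities[[cp]],
                 sprintf("%s lesion response, iter %s", nm, cp))
    }
    if (!is.null(res$spread)) {
      utils::write.csv(res$spread,
                       file.path(config$out_dir,
                                 sprintf("excitatory_spread_%s.csv", nm)),
                       row.names = FALSE)
    }
  }
  list(state = st, small = res_small, large = res_large)
}
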