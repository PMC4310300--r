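#' Retinotopic map analysis
#'
#' Turns trained networks into quantitative retinotopic maps: point-probe
#' positional maps, meridional preference/selectivity (doubled-angle
#' circular statistics), RMS error against the complex-log reference, angle
#' histograms, and lesion projection zone (LPZ) measurement.
#'
#' @name analysis
NULL

# degrees-per-retinal-pixel scale for a params' retina
retina_deg_scale <- function(params, ecc_max = 4) {
  ecc_max / ((params$retina_shape[2] - 1) / 2)
}

#' Point-probe retinotopic map (positional part)
#'
#' Presents a single-pixel probe at every retinal position, settles the
#' network, and assigns each cortical neuron the activity-weighted average
#' of the probe positions that activate it. Neurons whose activity never
#' reaches `threshold` (a fraction of the global maximum response) are
#' flagged unresponsive and carry no preferred position.
#'
#' @param state a trained `lissom_state`.
#' @param threshold responsiveness threshold, fraction of the maximum
#'   activity over all probes.
#' @param ecc_max eccentricity of the retinal half-width in degrees.
#' @return data frame, one row per cortical neuron (column-major order):
#'   row, col, in_mask, responsive, pref_x, pref_y (degrees),
#'   pref_ecc (degrees), pref_theta (radians, meridional angle).
#' @export
probe_point_map <- function(state, threshold = 0.1, ecc_max = 4) {
  p <- state$params
  hr <- p$retina_shape[1]; wr <- p$retina_shape[2]
  n_r <- hr * wr
  X <- diag(n_r)  # one unit probe per retinal pixel, column-major order
  Y <- settle_batch(state, X)          # n_cortex x n_probes
  ymax <- max(Y)
  if (ymax <= 0) stop("network is unresponsive to every point probe")
  thr <- threshold * ymax
  # probe coordinates in degrees (pixel centers, origin center, y up)
  ri <- rep(seq_len(hr), times = wr)
  rj <- rep(seq_len(wr), each = hr)
  sc <- ecc_max / ((wr - 1) / 2)
  px <- (rj - (wr + 1) / 2) * sc
  py <- ((hr + 1) / 2 - ri) * sc
  Yt <- Y
  Yt[Yt < thr] <- 0
  tot <- rowSums(Yt)
  responsive <- tot > 0 & state$inmask
  pref_x <- ifelse(responsive, drop(Yt %*% px) / tot, NA_real_)
  pref_y <- ifelse(responsive, drop(Yt %*% py) / tot, NA_real_)
  data.frame(row = state$ci, col = state$cj, in_mask = state$inmask,
             responsive = responsive,
             pref_x = pref_x, pref_y = pref_y,
             pref_ecc = sqrt(pref_x^2 + pref_y^2),
             pref_theta = atan2(pref_y, pref_x))
}

#' Meridional preference and selectivity (angular part)
#'
#' Presents bars at each rotation (summing responses over a dilation
#' sweep) and computes, per neuron, the doubled-angle vector average of
#' the tuning curve `R(theta)`:
#' preference `= arg(sum R exp(i 2 theta)) / 2` (degrees in \[0, 180)),
#' selectivity `= |sum R exp(i 2 theta)| / sum R` in \[0, 1\]. The doubled
#' angle handles the 180-degree period of bar orientation. Neurons with no
#' response at any rotation are unresponsive.
#'
#' @inheritParams probe_point_map
#' @param rotations_deg bar rotations in degrees.
#' @param n_dilations dilation sweep size per rotation (linear spacing).
#' @return data frame per cortical neuron: row, col, in_mask, responsive,
#'   pref_angle (degrees in \[0,180)), selectivity, total_response.
#' @export
meridional_preference <- function(state, rotations_deg = seq(0, 160, by = 20),
                                  n_dilations = 16) {
  p <- state$params
  grid <- p$retina_shape
  n_c <- length(state$inmask)
  Rsum <- matrix(0, n_c, length(rotations_deg))
  bars <- enumerate_bar_set(grid, n_rotations = 1, n_dilations = n_dilations)
  lengths_px <- attr(bars, "specs")$length_px
  for (k in seq_along(rotations_deg)) {
    X <- vapply(lengths_px, function(L) {
      as.numeric(unclass(make_bar(grid, bar_spec(rotations_deg[k], L))))
    }, numeric(prod(grid)))
    Y <- settle_batch(state, X)
    Rsum[, k] <- rowSums(Y)
  }
  stats <- doubled_angle_stats(Rsum, rotations_deg)
  responsive <- stats$total > 0 & state$inmask
  data.frame(row = state$ci, col = state$cj, in_mask = state$inmask,
             responsive = responsive,
             pref_angle = ifelse(responsive, stats$preference, NA_real_),
             selectivity = ifelse(responsive, stats$selectivity, NA_real_),
             total_response = stats$total)
}

#' Doubled-angle circular statistics of an orientation tuning curve
#'
#' For response rows `R` over angles with a 180-degree period:
#' preference `= arg(sum R exp(i 2 theta)) / 2` mapped to \[0, 180)
#' degrees, selectivity `= |sum R exp(i 2 theta)| / sum R`. A tuning curve
#' concentrated on one angle has selectivity 1; a uniform curve (or one
#' split between orthogonal angles) has selectivity 0.
#'
#' @param R matrix of nonnegative responses, one row per unit, one column
#'   per angle.
#' @param angles_deg angles of the columns, degrees.
#' @return list of vectors `preference` (degrees), `selectivity`, `total`.
#' @export
doubled_angle_stats <- function(R, angles_deg) {
  R <- matrix(R, ncol = length(angles_deg))
  th2 <- 2 * angles_deg * pi / 180
  zr <- drop(R %*% cos(th2))
  zi <- drop(R %*% sin(th2))
  tot <- rowSums(R)
  pref <- ((atan2(zi, zr) / 2) * 180 / pi + 180) %% 180
  list(preference = ifelse(tot > 0, pref, NA_real_),
       selectivity = ifelse(tot > 0, sqrt(zr^2 + zi^2) / tot, NA_real_),
       total = tot)
}

#' RMS error per pixel between two cortical images
#'
#' Both images are max-normalized to \[0, 1\]; the error is the root mean
#' square difference over in-mask pixels. Used to compare the developed
#' map's response with the complex-log transform of the matching input.
#'
#' @param model_img,reference_img same-size matrices.
#' @param mask optional logical matrix restricting the comparison.
#' @export
rms_error_per_pixel <- function(model_img, reference_img, mask = NULL) {
  m <- unclass(model_img); r <- unclass(reference_img)
  if (!all(dim(m) == dim(r))) stop("image shapes differ")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  if (max(m) > 0) m <- m / max(m)
  if (max(r) > 0) r <- r / max(r)
  sqrt(mean((m[mask] - r[mask])^2))
}

#' Histogram of preferred meridional angles
#'
#' Counts responsive neurons inside a region per preferred-angle bin
#' (9 bins of 20 degrees spanning \[0, 180)); also reported as area
#' fractions of the responsive in-region population.
#'
#' @param map output of [meridional_preference()].
#' @param region logical cortical matrix (e.g. the boundary mask).
#' @param bin_width bin width in degrees.
#' @return data frame: bin_lo, bin_hi, count, fraction.
#' @export
angle_histogram <- function(map, region, bin_width = 20) {
  inr <- region[cbind(map$row, map$col)] & map$responsive
  breaks <- seq(0, 180, by = bin_width)
  cnt <- table(cut(map$pref_angle[inr], breaks, right = FALSE,
                   include.lowest = TRUE))
  n <- sum(inr)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = as.integer(cnt),
             fraction = if (n > 0) as.integer(cnt) / n else NA_real_)
}

#' Area fraction of the central-angle bins
#'
#' Fraction of responsive in-region neurons preferring angles in the
#' central band (default 60-120 degrees, around the horizontal meridian at
#' 90 degrees bar rotation). A sheet developed without the complex-log
#' boundary allocates more area to these central angles than a bounded one.
#'
#' @inheritParams angle_histogram
#' @param central range of central angles in degrees.
#' @export
central_angle_fraction <- function(map, region, central = c(60, 120)) {
  h <- angle_histogram(map, region)
  sum(h$fraction[h$bin_lo >= central[1] & h$bin_hi <= central[2]])
}

#' Lesion projection zone area
#'
#' Number of cortical neurons active (>= `threshold`) in the reference
#' response (same network, unlesioned input) but silent (< `threshold`)
#' under the lesioned input.
#'
#' @param activity cortical response to the lesioned input.
#' @param reference_activity response of the same network to the
#'   unlesioned input.
#' @param threshold absolute activity threshold.
#' @export
lpz_area <- function(activity, reference_activity, threshold = 0.1) {
  sum(reference_activity >= threshold & activity < threshold)
}

#' Monotonicity of the developed retinotopic map
#'
#' Spearman rank correlations quantifying the headline organization: over
#' responsive in-mask neurons, preferred eccentricity against cortical
#' column index (nasotemporal axis) and preferred meridional angle against
#' cortical row index (dorsoventral axis). Absolute values are reported
#' alongside signed ones since axis orientation is a convention.
#'
#' @param point_map output of [probe_point_map()].
#' @param angle_map output of [meridional_preference()].
#' @return list with `ecc_col` and `angle_row` signed Spearman
#'   correlations.
#' @export
map_monotonicity <- function(point_map, angle_map) {
  pm <- point_map[point_map$responsive, ]
  am <- angle_map[angle_map$responsive, ]
  list(ecc_col = stats::cor(pm$pref_ecc, pm$col, method = "spearman"),
       angle_row = stats::cor(am$pref_angle, am$row, method = "spearman"))
}

#' RMS error of the developed map against the complex-log reference
#'
#' Builds an input family (rings of increasing radius, bars of fixed
#' length at the 9 rotations, or vertical bars of increasing length),
#' computes the network's settled response to the linearly spaced family
#' members and the complex-log transform of the exponentially spaced
#' counterparts (the logarithmic eccentricity compression the linear model
#' approximates), and returns the mean RMS error per pixel over the
#' family, restricted to the mask.
#'
#' @inheritParams probe_point_map
#' @param family one of "rings", "rotations", "dilations".
#' @param n number of family members.
#' @param params complex-log [map_params()] for the reference.
#' @export
rms_vs_complexlog <- function(state, family = c("rings", "rotations",
                                                "dilations"),
                              n = 5, params = map_params()) {
  family <- match.arg(family)
  p <- state$params
  grid <- p$retina_shape
  half <- (min(grid) - 1) / 2
  if (family == "rings") {
    lin <- seq(2, half - 1, length.out = n)
    expo <- exp(seq(log(2), log(half - 1), length.out = n))
    model_in <- lapply(lin, function(rr) make_ring(grid, rr))
    ref_in <- lapply(expo, function(rr) make_ring(grid, rr))
  } else if (family == "rotations") {
    L <- 0.7 * min(grid)
    rot <- seq(0, 160, length.out = n)
    model_in <- lapply(rot, function(a) make_bar(grid, bar_spec(a, L)))
    ref_in <- model_in
  } else {
    lmin <- 5; lmax <- 0.95 * min(grid)
    lin <- seq(lmin, lmax, length.out = n)
    expo <- exp(seq(log(lmin), log(lmax), length.out = n))
    model_in <- lapply(lin, function(L) make_bar(grid, bar_spec(0, L)))
    ref_in <- lapply(expo, function(L) make_bar(grid, bar_spec(0, L)))
  }
  errs <- vapply(seq_len(n), function(k) {
    y <- settle(state, model_in[[k]])
    ref <- suppressWarnings(
      transform_image(ref_in[[k]], params, out_grid = p$cortex_shape))
    rms_error_per_pixel(y, ref, mask = state$mask)
  }, numeric(1))
  mean(errs)
}
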