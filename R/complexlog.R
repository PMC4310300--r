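#' Complex-logarithmic retino-cortical transform
#'
#' The analytic approximation of the primate retinotopic map takes a point
#' of the visual field, `x + iy = r exp(i theta)` (eccentricity `r` degrees,
#' meridional angle `theta`), to the cortical point
#'
#'   `u + iv = log(x + iy + a)`
#'
#' where `a > 0` is a species constant. Eccentricity then varies mainly
#' along the nasotemporal axis `u` and meridional angle along the
#' dorsoventral axis `v`, so rotations and dilations of a centered pattern
#' become approximate translations along `v` and `u` respectively. The image
#' of the vertical retinal line through the origin (`x = 0`),
#' `u = log sqrt(a^2 + (a tan v)^2)`, bounds the cortical sheet on its
#' foveal side and is used as the boundary constraint of both models.
#'
#' @name complexlog
NULL

#' Parameters of the complex-log map
#'
#' @param a positive species constant. 1 approximates the squirrel monkey;
#'   2.5 the owl monkey; 4 the cat.
#' @param ecc_max maximum modeled eccentricity in visual degrees (the
#'   models cover the central 4 degrees).
#' @export
map_params <- function(a = 1, ecc_max = 4) {
  stopifnot(a > 0, ecc_max > 0)
  structure(list(a = a, ecc_max = ecc_max), class = "map_params")
}

#' Species presets for the map constant
#'
#' @param species one of `"squirrel-monkey"` (a = 1), `"owl-monkey"`
#'   (a = 2.5), `"cat"` (a = 4).
#' @export
species_params <- function(species = c("squirrel-monkey", "owl-monkey", "cat")) {
  species <- match.arg(species)
  map_params(a = switch(species, "squirrel-monkey" = 1,
                        "owl-monkey" = 2.5, "cat" = 4))
}

#' Forward retino-cortical mapping of a point
#'
#' @param x,y visual-field Cartesian coordinates in degrees (may be vectors).
#' @param params a [map_params()].
#' @return list with components `u`, `v`; `v` lies in `(-pi, pi]`.
#' @export
forward_map <- function(x, y, params = map_params()) {
  zx <- x + params$a
  if (any(zx == 0 & y == 0)) stop("singular point: x + a and y are both 0")
  list(u = 0.5 * log(zx^2 + y^2), v = atan2(y, zx))
}

#' Foveal boundary curve of the cortical sheet
#'
#' The `u` coordinate of the image of the vertical retinal line `x = 0` at
#' dorsoventral coordinate `v`: `u = log sqrt(a^2 + (a tan v)^2)`, defined
#' for `|v| < pi/2`. Equals `forward_map(0, a * tan(v))`.
#'
#' @param v dorsoventral coordinate(s), radians, `|v| < pi/2`.
#' @inheritParams forward_map
#' @export
boundary_u <- function(v, params = map_params()) {
  if (any(abs(v) >= pi / 2)) stop("|v| must be < pi/2")
  log(params$a) - log(cos(v))
}

# default cortical window: the image of the eccentricity disc r <= ecc_max.
# v spans the meridional extent at the boundary points (0, +-ecc_max);
# u spans apex (log a) to the far point (ecc_max, 0).
default_uv_window <- function(params) {
  vmax <- atan(params$ecc_max / params$a)
  list(u_range = c(log(params$a), log(params$a + params$ecc_max)),
       v_range = c(-vmax, vmax))
}

# affine pixel-center maps between grid indices and (u, v); row 1 = v_max
uv_of_cell <- function(grid, u_range, v_range) {
  h <- grid[1]; w <- grid[2]
  u <- u_range[1] + (seq_len(w) - 1) / (w - 1) * diff(u_range)
  v <- v_range[2] - (seq_len(h) - 1) / (h - 1) * diff(v_range)
  list(u = u, v = v)  # u by column, v by row
}

#' Rasterize the boundary mask of available cortical neurons
#'
#' Cells of an `h x w` cortical grid are mapped affinely onto a `(u, v)`
#' window (column -> u, row -> v, top row at `v_max`); a cell is inside the
#' sheet iff `u >= boundary_u(v)` and `u <= max(u_range)`. The default
#' window is the image of the modeled eccentricity disc:
#' `v in [-atan(ecc_max/a), +atan(ecc_max/a)]`,
#' `u in [log a, log(a + ecc_max)]`, which makes masks for different
#' species constants genuinely different in shape.
#'
#' @param grid `c(h, w)` cortical grid.
#' @inheritParams forward_map
#' @param u_range,v_range optional window overrides; `v_range` must lie
#'   inside `(-pi/2, pi/2)`.
#' @return logical `h x w` matrix (`TRUE` = inside the sheet), with the
#'   window stored in attributes `u_range`, `v_range`.
#' @export
make_boundary_mask <- function(grid, params = map_params(),
                               u_range = NULL, v_range = NULL) {
  win <- default_uv_window(params)
  if (is.null(u_range)) u_range <- win$u_range
  if (is.null(v_range)) v_range <- win$v_range
  if (any(abs(v_range) >= pi / 2)) stop("v_range must lie inside (-pi/2, pi/2)")
  uv <- uv_of_cell(grid, u_range, v_range)
  bu <- boundary_u(uv$v, params)
  inside <- outer(bu, uv$u, FUN = function(b, u) u >= b & u <= u_range[2])
  if (!any(inside)) stop("empty boundary mask")
  structure(inside, u_range = u_range, v_range = v_range, a = params$a)
}

#' Transform a retinal stimulus image into cortical coordinates
#'
#' Forward-scatters every active retinal pixel through [forward_map()] and
#' bins the results onto the cortical grid with the same `(u, v)` window
#' affine used by [make_boundary_mask()]. Retinal pixel coordinates are
#' scaled so the retinal half-width equals `ecc_max` degrees. Only the right
#' hemifield (`x >= 0`) is modeled (one hemisphere's V1); active pixels
#' with `x < 0` are dropped with a warning.
#'
#' @param img retinal [stimulus_image()].
#' @inheritParams make_boundary_mask
#' @param out_grid `c(h, w)` cortical output grid.
#' @return binary cortical [stimulus_image()].
#' @export
transform_image <- function(img, params = map_params(), out_grid = c(48, 48),
                            u_range = NULL, v_range = NULL) {
  win <- default_uv_window(params)
  if (is.null(u_range)) u_range <- win$u_range
  if (is.null(v_range)) v_range <- win$v_range
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, out_grid[1], out_grid[2])
  act <- which(unclass(img) > 0, arr.ind = TRUE)
  if (nrow(act) > 0) {
    x_px <- act[, 2] - (w + 1) / 2
    y_px <- (h + 1) / 2 - act[, 1]
    scale <- params$ecc_max / ((min(h, w) - 1) / 2)
    left <- x_px < 0
    if (any(left)) {
      warning(sprintf("%d active left-hemifield pixels (x < 0) ignored",
                      sum(left)))
    }
    x <- x_px[!left] * scale
    y <- y_px[!left] * scale
    if (length(x) > 0) {
      uv <- forward_map(x, y, params)
      j <- round((uv$u - u_range[1]) / diff(u_range) * (out_grid[2] - 1) + 1)
      i <- round((v_range[2] - uv$v) / diff(v_range) * (out_grid[1] - 1) + 1)
      ok <- i >= 1 & i <= out_grid[1] & j >= 1 & j <= out_grid[2]
      out[cbind(i[ok], j[ok])] <- 1
    }
  }
  stimulus_image(out)
}

#' Foveal indentation depth of a boundary mask
#'
#' Curvature proxy for the foveal boundary: the depth (in columns, as a
#' fraction of grid width) of the concave indentation carved out of the
#' sheet's left edge by the boundary curve. Larger species constants `a`
#' flatten the foveal boundary, so the proxy decreases with `a`.
#'
#' @param mask a mask from [make_boundary_mask()].
#' @export
mask_foveal_indentation <- function(mask) {
  first_in <- apply(mask, 1, function(r) {
    k <- which(r); if (length(k)) k[1] else NA_integer_
  })
  rng <- range(first_in, na.rm = TRUE)
  (rng[2] - rng[1]) / (ncol(mask) - 1)
}

#' Write a boundary mask as CSV of 0/1
#'
#' @inheritParams mask_foveal_indentation
#' @param path output path.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.table(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                     path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
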