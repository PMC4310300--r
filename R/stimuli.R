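#' Stimulus images
#'
#' All model inputs are synthesized in-package as binary grayscale images on a
#' square (or rectangular) pixel grid. The coordinate convention used
#' throughout is: pixel-center coordinates, origin at the image center,
#' x rightward, y upward. For an `h x w` grid, the pixel in row `i`, column
#' `j` (1-based, row 1 at the top) has coordinates
#' `x = j - (w + 1)/2`, `y = (h + 1)/2 - i`.
#'
#' Eccentricity in visual degrees is obtained by scaling pixel radii so that
#' the retinal half-width corresponds to `ecc_max` degrees (4 degrees by
#' default, the modeled central visual field).
#'
#' @param pixels numeric matrix with values in \[0, 1\].
#' @return `stimulus_image()` returns an object of class `"stimulus_image"`:
#'   a numeric matrix with the class attribute set, carrying its grid
#'   geometry implicitly via `dim()`.
#' @export
stimulus_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixel values must be numeric")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1)) {
    stop("all intensities must be finite and in [0, 1]")
  }
  structure(pixels, class = c("stimulus_image", "matrix", "array"))
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image %d x %d, %d active px, sum %.3f>\n",
              nrow(x), ncol(x), sum(x > 0), sum(x)))
  invisible(x)
}

# pixel-center coordinates for an h x w grid (y upward, origin at center)
pixel_coords <- function(grid) {
  h <- grid[1]; w <- grid[2]
  xs <- matrix(rep(seq_len(w) - (w + 1) / 2, each = h), h, w)
  ys <- matrix(rep((h + 1) / 2 - seq_len(h), times = w), h, w)
  list(x = xs, y = ys)
}

#' Bar stimulus specification
#'
#' A filled rectangle of a given length (long side, pixels), aspect ratio
#' (width/length), rotation (degrees counterclockwise from vertical) and
#' dilation level (index into an enumerated dilation sweep).
#'
#' @param rotation_deg rotation in degrees, `0 <= rotation_deg < 180`.
#' @param length long-side length in pixels (> 0).
#' @param aspect_ratio width/length, > 0; the models use 0.1.
#' @param dilation_level positive integer label for the dilation sweep.
#' @export
bar_spec <- function(rotation_deg, length, aspect_ratio = 0.1,
                     dilation_level = 1L) {
  stopifnot(aspect_ratio > 0, length > 0)
  if (rotation_deg < 0 || rotation_deg >= 180) {
    stop("rotation_deg must lie in [0, 180)")
  }
  structure(list(rotation_deg = rotation_deg, length = length,
                 aspect_ratio = aspect_ratio,
                 dilation_level = as.integer(dilation_level)),
            class = "bar_spec")
}

#' Rasterize a filled rectangular bar
#'
#' Binary rasterization by a point-in-rotated-rectangle test on pixel
#' centers; no anti-aliasing. The bar is centered at the image center; at
#' rotation 0 its long axis is vertical, and rotation is counterclockwise.
#'
#' @param grid `c(h, w)` grid size in pixels.
#' @param spec a [bar_spec()].
#' @return a binary [stimulus_image()].
#' @export
make_bar <- function(grid, spec) {
  stopifnot(inherits(spec, "bar_spec"))
  L <- spec$length
  W <- spec$aspect_ratio * L
  # the bar must fit at every rotation of this dilation level
  circum <- sqrt((L / 2)^2 + (W / 2)^2)
  half_min <- (min(grid) - 1) / 2
  if (circum > half_min + 1e-9) {
    stop(sprintf(
      "bar of dilation level %d (length %.2f px) exceeds the %dx%d grid at some rotation",
      spec$dilation_level, L, grid[1], grid[2]))
  }
  co <- pixel_coords(grid)
  th <- spec$rotation_deg * pi / 180
  # rotate pixel coordinates by -theta into the bar frame (long axis = y)
  xr <-  cos(th) * co$x + sin(th) * co$y
  yr <- -sin(th) * co$x + cos(th) * co$y
  px <- (abs(xr) <= W / 2) & (abs(yr) <= L / 2)
  stimulus_image(matrix(as.numeric(px), grid[1], grid[2]))
}

#' Enumerate the rotation x dilation bar set
#'
#' Builds the full training set of rotated/dilated bars: `n_rotations`
#' rotations from 0 to 180 degrees exclusive (step `180/n_rotations`) crossed
#' with `n_dilations` lengths between `length_min` and `length_max`. Lengths
#' are linearly spaced for model training; `spacing = "exponential"`
#' geometrically spaces the same endpoints, the convention used when
#' constructing complex-log reference inputs.
#'
#' Default length endpoints: the smallest length whose width rounds to at
#' least one pixel at the given aspect ratio, and 0.95 x the smaller grid
#' dimension (so every rotation fits).
#'
#' @inheritParams make_bar
#' @param n_rotations,n_dilations sweep sizes (>= 1).
#' @param aspect width/length aspect ratio.
#' @param spacing `"linear"` or `"exponential"` dilation spacing.
#' @param length_min,length_max dilation sweep endpoints in pixels.
#' @return list of [stimulus_image()]s with attribute `"specs"`, a data frame
#'   of (rotation_deg, dilation_level, length_px).
#' @export
enumerate_bar_set <- function(grid, n_rotations = 9, n_dilations = 16,
                              aspect = 0.1,
                              spacing = c("linear", "exponential"),
                              length_min = NULL, length_max = NULL) {
  spacing <- match.arg(spacing)
  stopifnot(n_rotations >= 1, n_dilations >= 1)
  if (is.null(length_min)) length_min <- ceiling(0.5 / aspect)
  if (is.null(length_max)) {
    # 0.95 x the smaller grid dimension, capped so every rotation fits
    length_max <- min(0.95 * min(grid),
                      (min(grid) - 1) / sqrt(1 + aspect^2))
  }
  if (length_max < length_min) stop("length_max < length_min")
  lengths <- if (n_dilations == 1) {
    length_max
  } else if (spacing == "linear") {
    seq(length_min, length_max, length.out = n_dilations)
  } else {
    exp(seq(log(length_min), log(length_max), length.out = n_dilations))
  }
  rotations <- seq(0, 180 - 180 / n_rotations, by = 180 / n_rotations)
  specs <- expand.grid(dilation_level = seq_len(n_dilations),
                       rotation_deg = rotations)
  specs$length_px <- lengths[specs$dilation_level]
  imgs <- vector("list", nrow(specs))
  for (k in seq_len(nrow(specs))) {
    imgs[[k]] <- make_bar(grid, bar_spec(specs$rotation_deg[k],
                                         specs$length_px[k], aspect,
                                         specs$dilation_level[k]))
  }
  keys <- vapply(imgs, function(im) paste(which(im > 0), collapse = ","), "")
  if (anyDuplicated(keys)) {
    d <- which(duplicated(keys) | duplicated(keys, fromLast = TRUE))
    warning(sprintf(
      "duplicate rasterizations among bar specs (rows %s of the spec table)",
      paste(d, collapse = ", ")))
  }
  attr(imgs, "specs") <- specs[, c("rotation_deg", "dilation_level", "length_px")]
  imgs
}

#' Rasterize a circular ring (annulus)
#'
#' A pixel is active iff its center-distance to the image center is within
#' `thickness/2` of `radius`.
#'
#' @inheritParams make_bar
#' @param radius ring radius in pixels (> 0).
#' @param thickness radial thickness in pixels.
#' @export
make_ring <- function(grid, radius, thickness = 1) {
  if (radius <= 0) stop("radius must be > 0")
  if (radius + thickness / 2 > (min(grid) - 1) / 2) {
    stop("ring does not fit in grid")
  }
  co <- pixel_coords(grid)
  d <- sqrt(co$x^2 + co$y^2)
  stimulus_image(matrix(as.numeric(abs(d - radius) <= thickness / 2),
                        grid[1], grid[2]))
}

#' Single-pixel point probe
#'
#' Unit impulse at the pixel whose center is nearest to `(x, y)` (stimulus
#' coordinates: origin at center, y upward). Off-center ties are broken
#' toward the lower row, then the lower column, so the probing grid is
#' deterministic.
#'
#' @inheritParams make_bar
#' @param x,y requested position in pixel-center coordinates.
#' @export
make_point <- function(grid, x, y) {
  h <- grid[1]; w <- grid[2]
  j <- x + (w + 1) / 2
  i <- (h + 1) / 2 - y
  # nearest pixel center; .5 ties resolve toward the lower index
  ri <- if (abs(i - floor(i)) == 0.5) floor(i) else round(i)
  rj <- if (abs(j - floor(j)) == 0.5) floor(j) else round(j)
  if (ri < 1 || ri > h || rj < 1 || rj > w) {
    stop(sprintf("point (%.2f, %.2f) lies outside the %dx%d grid", x, y, h, w))
  }
  px <- matrix(0, h, w)
  px[ri, rj] <- 1
  stimulus_image(px)
}

#' Lesion specification
#'
#' A filled disc input with a circular inactive (lesioned) region. The
#' lesion must lie strictly inside the disc.
#'
#' @param disc_center,lesion_center length-2 centers `(x, y)` in pixel-center
#'   coordinates.
#' @param disc_radius,lesion_radius radii in pixels.
#' @export
lesion_spec <- function(disc_radius, lesion_radius,
                        disc_center = c(0, 0), lesion_center = c(0, 0)) {
  stopifnot(disc_radius > 0, lesion_radius >= 0)
  if (lesion_radius >= disc_radius) stop("lesion_radius must be < disc_radius")
  off <- sqrt(sum((lesion_center - disc_center)^2))
  if (off + lesion_radius > disc_radius) {
    stop("lesion region must lie inside the disc")
  }
  structure(list(disc_center = disc_center, disc_radius = disc_radius,
                 lesion_center = lesion_center, lesion_radius = lesion_radius),
            class = "lesion_spec")
}

#' Filled disc with a circular lesion
#'
#' Disc of 1s (pixel-center distance to `disc_center` <= `disc_radius`) with
#' the lesion region (distance to `lesion_center` <= `lesion_radius`) set
#' to 0. The lesioned area models a retinal region with no input activity.
#'
#' @inheritParams make_bar
#' @param spec a [lesion_spec()].
#' @export
make_lesioned_disc <- function(grid, spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  co <- pixel_coords(grid)
  dd <- sqrt((co$x - spec$disc_center[1])^2 + (co$y - spec$disc_center[2])^2)
  dl <- sqrt((co$x - spec$lesion_center[1])^2 + (co$y - spec$lesion_center[2])^2)
  px <- (dd <= spec$disc_radius) &
    !(spec$lesion_radius > 0 & dl <= spec$lesion_radius)
  stimulus_image(matrix(as.numeric(px), grid[1], grid[2]))
}

#' Write / read a stimulus as plain-text PGM (P2)
#'
#' 8-bit grayscale, text encoded; intensities in \[0,1\] are scaled to 0..255.
#'
#' @param img a [stimulus_image()].
#' @param path file path.
#' @export
write_pgm <- function(img, path) {
  v <- as.integer(round(t(unclass(img)) * 255))  # row-major, top row first
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
  write(v, con, ncolumns = 16)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)]) / maxv
  stimulus_image(matrix(vals, h, w, byrow = TRUE))
}

#' Write a stimulus set as PGMs plus a CSV manifest
#'
#' @param imgs list of images from [enumerate_bar_set()].
#' @param dir output directory (created if needed).
#' @export
write_stimulus_set <- function(imgs, dir) {
  specs <- attr(imgs, "specs")
  if (is.null(specs)) {
    specs <- data.frame(rotation_deg = NA_real_,
                        dilation_level = seq_along(imgs),
                        length_px = NA_real_)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs$filename <- sprintf("stim_%03d.pgm", seq_along(imgs))
  for (k in seq_along(imgs)) {
    write_pgm(imgs[[k]], file.path(dir, specs$filename[k]))
  }
  utils::write.csv(specs[, c("filename", "rotation_deg", "dilation_level",
                             "length_px")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
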