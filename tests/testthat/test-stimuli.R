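test_that("make_bar rasterizes binary centered rectangles with the expected symmetries", {
  img <- make_bar(c(81, 81), bar_spec(40, 40))
  expect_s3_class(img, "stimulus_image")
  expect_true(all(unclass(img) %in% c(0, 1)))
  expect_equal(dim(img), c(81, 81))

  # rotation 0 vs 90: transposes of each other
  b0 <- make_bar(c(41, 41), bar_spec(0, 30))
  b90 <- make_bar(c(41, 41), bar_spec(90, 30))
  expect_equal(unclass(b90), t(unclass(b0)))

  # 180 - theta is the horizontal mirror of theta
  for (th in c(20, 50, 110)) {
    a <- unclass(make_bar(c(41, 41), bar_spec(th, 30)))
    b <- unclass(make_bar(c(41, 41), bar_spec(180 - th, 30)))
    expect_equal(b, a[, rev(seq_len(41))], info = paste("theta =", th))
  }

  # deterministic rasterization
  expect_identical(make_bar(c(41, 41), bar_spec(70, 25)),
                   make_bar(c(41, 41), bar_spec(70, 25)))

  # active pixel count non-decreasing in dilation level (brute force count)
  lens <- seq(5, 76, length.out = 16)
  for (rot in c(0, 40, 100)) {
    counts <- vapply(lens, function(L) {
      sum(make_bar(c(81, 81), bar_spec(rot, L)) > 0)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0), info = paste("rot =", rot))
  }

  # bar exceeding the grid errors, naming the dilation level
  expect_error(make_bar(c(25, 25), bar_spec(0, 40, dilation_level = 13)),
               "dilation level 13")
})

test_that("enumerate_bar_set builds the full rotation x dilation training set", {
  set <- suppressWarnings(enumerate_bar_set(c(81, 81)))
  expect_length(set, 144)   # 9 rotations x 16 dilations
  specs <- attr(set, "specs")
  expect_equal(sort(unique(specs$rotation_deg)), seq(0, 160, by = 20))
  expect_equal(sort(unique(specs$dilation_level)), 1:16)

  # linear spacing: consecutive length differences constant to +-1 px
  lens <- sort(unique(specs$length_px))
  expect_length(lens, 16)
  expect_lt(diff(range(diff(lens))), 1 + 1e-9)

  # exponential spacing shares endpoints, constant ratio
  set_e <- suppressWarnings(enumerate_bar_set(c(81, 81), spacing = "exponential"))
  lens_e <- sort(unique(attr(set_e, "specs")$length_px))
  expect_equal(range(lens_e), range(lens))
  expect_equal(diff(log(lens_e)), rep(diff(log(lens_e))[1], 15))

  # singleton enumeration equals make_bar
  one <- enumerate_bar_set(c(41, 41), n_rotations = 1, n_dilations = 1)
  expect_length(one, 1)
  sp <- attr(one, "specs")
  expect_equal(unclass(one[[1]]),
               unclass(make_bar(c(41, 41), bar_spec(sp$rotation_deg, sp$length_px))))
})

test_that("make_ring produces annuli with the expected geometry", {
  r <- make_ring(c(25, 25), radius = 5, thickness = 1)
  m <- unclass(r)
  # 4-fold rotational symmetry
  rot90 <- t(m)[, rev(seq_len(25))]
  expect_equal(m, rot90)

  # rings with separated radii are disjoint (pixel-wise check)
  r2 <- make_ring(c(25, 25), radius = 8, thickness = 1)
  expect_equal(sum(unclass(r) * unclass(r2)), 0)

  # thick ring degenerates to a filled disc
  disc <- make_ring(c(25, 25), radius = 4, thickness = 10)
  ref <- make_lesioned_disc(c(25, 25), lesion_spec(9, 0))
  expect_equal(unclass(disc), unclass(ref))

  expect_error(make_ring(c(25, 25), radius = 0), "radius")
})

test_that("make_point places a single unit impulse deterministically", {
  p <- make_point(c(25, 25), 0, 0)
  expect_equal(sum(p), 1)
  expect_equal(which(unclass(p) == 1, arr.ind = TRUE)[1, ], c(row = 13, col = 13))

  # reflection in y mirrors vertically
  a <- unclass(make_point(c(25, 25), 3, 7))
  b <- unclass(make_point(c(25, 25), 3, -7))
  expect_equal(b, a[rev(seq_len(25)), ])

  # off-center positions activate the nearest pixel; exactly one pixel
  for (xy in list(c(0.4, 0.4), c(-1.6, 2.2), c(3.5, -3.5))) {
    img <- make_point(c(25, 25), xy[1], xy[2])
    expect_equal(sum(img > 0), 1)
  }
  expect_error(make_point(c(25, 25), 30, 0), "outside")
})

test_that("make_lesioned_disc subtracts the lesion from the disc", {
  # degenerate lesion: plain filled disc
  d0 <- make_lesioned_disc(c(25, 25), lesion_spec(8, 0))
  expect_gt(sum(d0), 0)

  # active count = disc count - lesion count (brute force)
  sp <- lesion_spec(8.3, 3.3)
  les <- make_lesioned_disc(c(25, 25), sp)
  co_count <- function(rad) {
    xs <- rep(seq_len(25) - 13, each = 25); ys <- rep(13 - seq_len(25), 25)
    sum(sqrt(xs^2 + ys^2) <= rad)
  }
  expect_equal(sum(les), co_count(8.3) - co_count(3.3))

  # concentric lesioned disc equals the matching annulus (non-integer radii
  # so no pixel sits exactly on either circle)
  ring <- make_ring(c(25, 25), radius = (8.3 + 3.3) / 2, thickness = 8.3 - 3.3)
  expect_equal(unclass(les), unclass(ring))

  expect_error(lesion_spec(5, 6), "lesion_radius")
  expect_error(lesion_spec(5, 2, lesion_center = c(4, 0)), "inside")
})

test_that("PGM round trip and stimulus-set manifest work", {
  img <- make_bar(c(25, 25), bar_spec(40, 15))
  f <- tempfile(fileext = ".pgm")
  write_pgm(img, f)
  back <- read_pgm(f)
  expect_equal(unclass(back), unclass(img))

  dir <- tempfile("stimset")
  set <- suppressWarnings(enumerate_bar_set(c(25, 25), n_rotations = 2,
                                            n_dilations = 3))
  write_stimulus_set(set, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6)
  expect_true(all(file.exists(file.path(dir, man$filename))))
})
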