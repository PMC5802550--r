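test_that("images round-trip losslessly at native bit depth", {
  px16 <- matrix(sample.int(65536, 200, replace = TRUE) - 1L, 10, 20)
  img <- channel_image(px16, channel = "DAPI", bit_depth = 16)
  tf <- withr::local_tempfile(fileext = ".tiff")
  write_image(img, tf)
  back <- read_image(tf, channel = "DAPI")
  expect_equal(back$pixels, px16, ignore_attr = TRUE)
  expect_equal(back$bit_depth, 16L)

  px8 <- matrix(sample.int(256, 100, replace = TRUE) - 1L, 10, 10)
  pf <- withr::local_tempfile(fileext = ".png")
  write_image(channel_image(px8, bit_depth = 8), pf)
  back8 <- read_image(pf)
  expect_equal(back8$pixels, px8, ignore_attr = TRUE)
  expect_equal(back8$bit_depth, 8L)
})

test_that("RGB input splits into labelled channels and bad files error cleanly", {
  arr <- array(runif(60), dim = c(5, 4, 3))
  pf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, pf)
  chans <- read_image(pf, channel_map = c(R = "Ki67", G = "PanNeu", B = "DAPI"))
  expect_named(chans, c("Ki67", "PanNeu", "DAPI"))
  expect_s3_class(chans$DAPI, "channel_image")

  tf <- withr::local_tempfile(fileext = ".tiff")
  writeLines("not a tiff", tf)
  expect_error(read_image(tf), "failed to read")
  expect_error(read_image("no/such/file.tiff"), "does not exist")
})

test_that("background subtraction clips at zero and checks shapes", {
  a <- flat_image8(100)
  bg <- channel_image(matrix(20, 20, 20), channel = "test", bit_depth = 8)
  expect_true(all(subtract_background(a, bg)$pixels == 80))
  big_bg <- channel_image(matrix(200, 20, 20), channel = "test", bit_depth = 8)
  expect_true(all(subtract_background(a, big_bg)$pixels == 0))
  expect_true(all(subtract_background(a, a)$pixels == 0))
  expect_true(subtract_background(a, bg)$background_subtracted)
  wrong <- channel_image(matrix(1, 5, 5), channel = "test", bit_depth = 8)
  expect_error(subtract_background(a, wrong), "mismatch")
})

test_that("8-bit conversion maps endpoints exactly and is idempotent", {
  img16 <- channel_image(matrix(c(0, 65535, 32768, 257), 2, 2), bit_depth = 16)
  g8 <- to_grayscale8(img16)
  expect_equal(g8$bit_depth, 8L)
  expect_equal(g8$pixels[1, 1], 0)
  expect_equal(g8$pixels[2, 1], 255)
  expect_equal(g8$pixels[2, 2], 1)  # 257/65535*255 = 0.99988 -> rounds up
  img8 <- flat_image8(123)
  expect_identical(to_grayscale8(img8)$pixels, img8$pixels)
})

test_that("ROI polygons compute areas and round-trip through JSON and CSV", {
  sq <- roi_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                    label = "r1", zone = "VZ", pixel_size_um = 0.5)
  expect_equal(sq$area_px2, 100)
  expect_equal(sq$area_um2, 25)
  expect_error(roi_polygon(cbind(c(0, 1), c(0, 1))), "3")

  tri <- roi_polygon(cbind(c(2, 8, 2), c(2, 2, 9)), label = "t", zone = "CZ")
  for (ext in c(".json", ".csv")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_rois(list(sq, tri), tf)
    back <- read_rois(tf, pixel_size_um = 0.5)
    labs <- vapply(back, function(r) r$label, character(1))
    expect_setequal(labs, c("r1", "t"))
    got <- back[[which(labs == "r1")]]
    expect_equal(got$vertices, sq$vertices, ignore_attr = TRUE)
    expect_equal(got$zone, "VZ")
  }
})

test_that("mean ROI intensity matches pixel enumeration and is translation-invariant", {
  img <- flat_image8(42, 30, 30)
  roi <- roi_polygon(cbind(c(4.5, 24.5, 24.5, 4.5), c(4.5, 4.5, 24.5, 24.5)),
                     label = "sq", zone = "other")
  m <- mean_roi_intensity(img, roi)
  expect_equal(m$mean_intensity, 42)
  expect_equal(m$n_pixels, 400L)

  # random image: brute-force enumeration over interior pixel centers
  set.seed(4)
  px <- matrix(sample.int(256, 900, replace = TRUE) - 1, 30, 30)
  rimg <- flat_image8(0, 30, 30); rimg$pixels <- px
  got <- mean_roi_intensity(rimg, roi)
  acc <- c(); np <- 0
  for (ix in 0:29) for (iy in 0:29) {
    if (ix > 4.5 && ix < 24.5 && iy > 4.5 && iy < 24.5) {
      acc <- c(acc, px[iy + 1, ix + 1]); np <- np + 1
    }
  }
  expect_equal(got$n_pixels, np)
  expect_equal(got$mean_intensity, mean(acc))

  # joint translation of image and ROI leaves the mean unchanged
  sh <- matrix(0, 30, 30); sh[, 4:30] <- px[, 1:27]
  simg <- flat_image8(0, 30, 30); simg$pixels <- sh
  sroi <- roi_polygon(sweep(roi$vertices, 2, c(3, 0), "+"), label = "sq")
  expect_equal(mean_roi_intensity(simg, sroi)$mean_intensity, got$mean_intensity)

  # enforced preconditions
  raw16 <- channel_image(px, bit_depth = 16)
  expect_error(mean_roi_intensity(raw16, roi), "8-bit")
  no_bg <- channel_image(px, bit_depth = 8)
  expect_error(mean_roi_intensity(no_bg, roi), "background")
  out_roi <- roi_polygon(cbind(c(20, 40, 40, 20), c(20, 20, 40, 40)))
  expect_error(mean_roi_intensity(img, out_roi), "outside")
})

test_that("shoelace area agrees with pixel counting within the discretization bound", {
  set.seed(11)
  for (i in 1:5) {
    cx <- runif(1, 30, 50); cy <- runif(1, 30, 50); rad <- runif(1, 10, 20)
    th <- sort(runif(8, 0, 2 * pi))
    v <- cbind(cx + rad * cos(th), cy + rad * sin(th))  # convex-ish polygon
    roi <- roi_polygon(v)
    mask <- orgcyto:::roi_pixel_mask(roi, c(80, 80))
    per <- sum(sqrt(rowSums((v - v[c(2:nrow(v), 1), ])^2)))
    expect_lt(abs(sum(mask) - roi$area_px2), 2 * per)
  }
})

test_that("random ROI sampling places disjoint in-mask squares deterministically", {
  mask <- matrix(FALSE, 100, 100); mask[10:90, 10:90] <- TRUE
  expect_length(sample_random_rois(mask, 25, 0, pixel_size_um = 1), 0)

  rois <- sample_random_rois(mask, 100, 10, pixel_size_um = 1, seed = 3)
  expect_length(rois, 10)
  # all inside the mask, pairwise disjoint
  for (r in rois) {
    expect_true(all(r$vertices >= 9 & r$vertices <= 90))
  }
  corners <- t(vapply(rois, function(r) r$vertices[1, ], numeric(2)))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_true(max(abs(corners[i, ] - corners[j, ])) >= 10)
  }
  again <- sample_random_rois(mask, 100, 10, pixel_size_um = 1, seed = 3)
  expect_identical(vapply(again, function(r) r$vertices[1, 1], numeric(1)),
                   vapply(rois, function(r) r$vertices[1, 1], numeric(1)))

  # a mask that fits exactly one square forces its placement
  tight <- matrix(FALSE, 20, 20); tight[5:9, 7:11] <- TRUE
  one <- sample_random_rois(tight, 25, 1, pixel_size_um = 1, seed = 1)
  expect_equal(one[[1]]$vertices[1, ], c(x = 6, y = 4), ignore_attr = TRUE)
  expect_error(sample_random_rois(tight, 25, 2, pixel_size_um = 1, seed = 1,
                                  max_tries = 200),
               "could only place")
})
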