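test_that("rosette point patterns respect zone placement and determinism", {
  cfg <- simulation_config(seed = 42, phenotype = "control")
  expect_equal(nrow(simulate_rosette_points(
    simulation_config(seed = 1, n_proliferating = 0))), 0L)

  all_vz <- simulate_rosette_points(
    simulation_config(seed = 3, n_proliferating = 100, dispersion_fraction = 0))
  expect_true(all(all_vz$zone == "VZ"))

  # zone containment by explicit radius check across seeds
  for (s in 1:10) {
    cfg_s <- simulation_config(seed = s, phenotype = "disease",
                               n_proliferating = 60)
    pts <- simulate_rosette_points(cfg_s)
    r <- sqrt((pts$x - cfg_s$center[1])^2 + (pts$y - cfg_s$center[2])^2)
    expect_true(all(r[pts$zone == "VZ"] >= cfg_s$lumen_radius_px - 1e-9))
    expect_true(all(r[pts$zone == "VZ"] <= cfg_s$vz_outer_radius_px + 1e-9))
    expect_true(all(r[pts$dispersed] >= cfg_s$vz_outer_radius_px - 1e-9))
    expect_true(all(r <= cfg_s$cz_outer_radius_px + 1e-9))
  }

  # byte-identical reruns, and no effect on the global RNG stream
  set.seed(777); before <- runif(1)
  a <- simulate_rosette_points(cfg)
  b <- simulate_rosette_points(cfg)
  expect_identical(a, b)
  set.seed(777); expect_identical(runif(1), before)

  expect_error(simulation_config(lumen_radius_px = 300), "radii")
  expect_error(simulation_config(dispersion_fraction = 1.5), "dispersion_fraction")
})

test_that("mean MST edge length grows with dispersion", {
  # Monotone over the low-to-high range; at fixed total cell number the
  # fully dispersed pattern is denser in the outer zones than a 0.75
  # split, so the very top of the range is not ordered and is checked
  # only against the compact extreme.
  fracs <- c(0, 0.25, 0.5, 0.75)
  means <- sapply(fracs, function(f) {
    mean(sapply(1:50, function(s) {
      pts <- simulate_rosette_points(
        simulation_config(seed = s, n_proliferating = 40, dispersion_fraction = f))
      mst_summary(pts)$mean_edge_px
    }))
  })
  expect_true(all(diff(means) > 0))
  full <- mean(sapply(1:50, function(s) {
    mst_summary(simulate_rosette_points(
      simulation_config(seed = s, n_proliferating = 40,
                        dispersion_fraction = 1)))$mean_edge_px
  }))
  expect_gt(full, means[1])
})

test_that("fully dispersed patterns have longer MST edges than compact ones", {
  wins <- sum(sapply(1:100, function(s) {
    m1 <- mst_summary(simulate_rosette_points(
      simulation_config(seed = s, n_proliferating = 500,
                        dispersion_fraction = 1)))$mean_edge_px
    m0 <- mst_summary(simulate_rosette_points(
      simulation_config(seed = s, n_proliferating = 500,
                        dispersion_fraction = 0)))$mean_edge_px
    m1 > m0
  }))
  expect_gte(wins, 95)
})

test_that("rendering is deterministic and detection recovers planted blobs", {
  cfg <- simulation_config(seed = 5, noise_sd = 0)
  pts <- data.frame(x = c(50, 150, 250, 350, 450), y = c(60, 160, 260, 360, 460))
  img <- render_channel(pts, cfg)
  expect_s3_class(img, "channel_image")
  det <- detect_nuclei(img)
  expect_equal(nrow(det), 5L)
  d <- sqrt((sort(det$x) - sort(pts$x))^2 + (sort(det$y) - sort(pts$y))^2)
  expect_true(all(d <= 1))

  # empty input -> constant background (plus nothing else)
  blank <- render_channel(pts[0, ], simulation_config(seed = 1, noise_sd = 0))
  expect_equal(length(unique(as.vector(blank$pixels))), 1L)

  out <- data.frame(x = 1e5, y = 1e5)
  expect_error(render_channel(out, cfg), "outside")

  cfg_n <- simulation_config(seed = 9)
  expect_identical(render_channel(pts, cfg_n)$pixels,
                   render_channel(pts, cfg_n)$pixels)
})

test_that("render/detect round trip recovers well-separated points precisely", {
  cfg <- simulation_config(seed = 1, noise_sd = 0.01)
  # separation 24 px = 12 x blob sigma
  grid <- expand.grid(x = seq(20, 480, by = 24), y = seq(20, 480, by = 24))
  set.seed(2)
  planted <- grid[sample(nrow(grid), 200), ]
  det <- detect_nuclei(render_channel(planted, cfg))
  expect_equal(nrow(det), 200L)
  d2 <- vapply(seq_len(nrow(planted)), function(i) {
    min((det$x - planted$x[i])^2 + (det$y - planted$y[i])^2)
  }, numeric(1))
  expect_lte(sqrt(mean(d2)), 1)               # centroid RMSE
  expect_gte(mean(sqrt(d2) <= 2), 0.98)       # recovery within 2 px
})

test_that("interneuron angles follow the concentration parameter", {
  # degenerate concentration: angles collapse to 0
  tight <- simulate_interneurons(
    simulation_config(seed = 2, orientation_kappa = 1e6, n_interneurons = 50))
  expect_true(all(tight$true_deviation_deg < 1))
  expect_true(all(tight$true_deviation_deg >= 0))

  # kappa = 0: uniform on [0, 90]; KS against uniform non-significant mostly
  nonsig <- sum(sapply(1:100, function(s) {
    cells <- simulate_interneurons(
      simulation_config(seed = s, orientation_kappa = 0, n_interneurons = 500),
      min_separation_px = 0)
    stats::ks.test(cells$true_deviation_deg, "punif", 0, 90)$p.value > 0.05
  }))
  expect_gte(nonsig, 90)

  expect_true(all(tight$long_axis_deg >= 0 & tight$long_axis_deg < 180))
})

test_that("study-sized orientation groups separate with high power", {
  hits <- sum(sapply(1:20, function(s) {
    ctrl <- simulate_interneurons(
      simulation_config(seed = s, phenotype = "control", n_interneurons = 770),
      min_separation_px = 0)
    dis <- simulate_interneurons(
      simulation_config(seed = s + 5000, phenotype = "disease",
                        n_interneurons = 547),
      min_separation_px = 0)
    tidy(ks_two_sample(ctrl$true_deviation_deg,
                       dis$true_deviation_deg))$p.value < 1e-4
  }))
  expect_equal(hits, 20L)
})

test_that("expression simulator plants the requested correlation structure", {
  ex <- simulate_expression(seed = 1)
  expect_equal(dim(ex$values), c(100L, 61L))
  expect_true(all(as.matrix(ex$values[, -1]) >= 0))
  expect_equal(sum(!is.na(ex$truth$module)), 30L)

  # identical seeds give identical tables
  expect_identical(simulate_expression(seed = 7)$values,
                   simulate_expression(seed = 7)$values)

  # module of size 1 has no within-module pairs
  ex1 <- simulate_expression(n_genes = 10, n_modules = 2, module_size = 1, seed = 2)
  tt <- tidy(pairwise_correlation(ex1$values))
  mi <- ex1$truth$module[match(tt$gene_i, ex1$truth$gene)]
  mj <- ex1$truth$module[match(tt$gene_j, ex1$truth$gene)]
  expect_equal(sum(!is.na(mi) & !is.na(mj) & mi == mj), 0L)

  # realized within-module correlation near the target in the correlated arm
  corr_samples <- ex$samples$sample_id[ex$samples$condition == "NCC"]
  cs <- pairwise_correlation(ex$values, samples = corr_samples)
  tt <- tidy(cs)
  mi <- ex$truth$module[match(tt$gene_i, ex$truth$gene)]
  mj <- ex$truth$module[match(tt$gene_j, ex$truth$gene)]
  within <- !is.na(mi) & !is.na(mj) & mi == mj
  expect_gte(median(tt$r[within]), 0.9)

  # decorrelated arm: |r| > 0.9 pairs no more frequent than the null expects
  dec_samples <- ex$samples$sample_id[ex$samples$condition == "NPC"]
  n_fp <- sum(sapply(1:5, function(s) {
    exs <- simulate_expression(seed = 100 + s)
    css <- pairwise_correlation(exs$values,
                                samples = exs$samples$sample_id[exs$samples$condition == "NPC"])
    sum(abs(tidy(css)$r) > 0.9)
  }))
  # with n = 30 samples, P(|r| > 0.9) is astronomically small; allow a stray pair
  expect_lte(n_fp, 1)

  expect_error(simulate_expression(n_genes = 10, n_modules = 3, module_size = 5),
               "exceed")
  expect_error(simulate_expression(within_module_r = 1.2), "within_module_r")
})
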