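test_that("noise estimate is the MAD-consistent baseline scale", {
  expect_equal(estimate_noise(rep(5, 100)), 0)
  expect_equal(estimate_noise(rep(0, 100)), 0)
  set.seed(10)
  x <- rnorm(1e5)
  expect_equal(estimate_noise(x), 1, tolerance = 0.02)
  x_spiked <- x
  x_spiked[123] <- 1e4
  expect_equal(estimate_noise(x_spiked), estimate_noise(x), tolerance = 0.05)
})

test_that("peak detection finds a 10-sigma Gaussian and rejects 2-sigma", {
  axis <- seq(495, 505, length.out = 1001)
  centre <- 500.0
  # deterministic triangular-ripple noise floor with known robust scale;
  # long enough that a narrow peak cannot move the baseline estimate
  noise <- rep_len(c(-1, -0.5, 0, 0.5, 1), 1001)
  sigma_hat <- estimate_noise(noise)
  expect_equal(sigma_hat, 1.4826)
  gauss <- function(a) a * sigma_hat * exp(-(axis - centre)^2 / (2 * 0.02^2))
  peaks <- detect_peaks(axis, noise + gauss(10), snr_min = 3)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$mz, centre, tolerance = diff(axis)[1])
  expect_true(peaks$snr >= 3)
  # the ripple maxima themselves stay below threshold
  expect_equal(nrow(detect_peaks(axis, noise, snr_min = 3)), 0)

  expect_equal(nrow(detect_peaks(axis, noise + gauss(2), snr_min = 3)), 0)
  expect_equal(nrow(detect_peaks(axis, rep(0, 1001), snr_min = 3)), 0)
})

test_that("stochastic 10-sigma peaks are found once and centred across seeds", {
  axis <- seq(499, 501, length.out = 101)
  for (s in c(3, 7, 14, 21, 42)) {
    set.seed(s)
    noise <- rnorm(101, 0, 1)
    sigma_hat <- estimate_noise(noise)
    y <- noise + 10 * sigma_hat * exp(-(axis - 500)^2 / (2 * 0.04^2))
    peaks <- detect_peaks(axis, y, snr_min = 3)
    expect_equal(nrow(peaks), 1)
    expect_equal(peaks$mz, 500, tolerance = diff(axis)[1])
  }
})

test_that("common axis merges within tolerance and splits beyond it", {
  pl <- function(mz) tibble::tibble(mz = mz, intensity = 1)
  # 0.004 at m/z 500 is 8 ppm: merged
  merged <- build_common_axis(list(pl(500.000), pl(500.004)), ppm_tol = 10)
  expect_length(merged, 1)
  # 0.010 at m/z 500 is 20 ppm: split
  split <- build_common_axis(list(pl(500.000), pl(500.010)), ppm_tol = 10)
  expect_length(split, 2)
  # identical peak lists collapse to that list
  base <- sort(runif(30, 100, 1000))
  ax <- build_common_axis(list(pl(base), pl(base)), ppm_tol = 10)
  expect_equal(ax, base)
})

test_that("common axis is invariant to run order", {
  set.seed(4)
  lists <- lapply(1:4, function(i) {
    tibble::tibble(mz = sort(runif(40, 100, 1000)) * (1 + rnorm(1, 0, 3) * 1e-6),
                   intensity = rexp(40))
  })
  a <- build_common_axis(lists, 10)
  b <- build_common_axis(rev(lists), 10)
  expect_equal(a, b)
})

test_that("recalibration recovers constructed global shifts", {
  set.seed(5)
  axis <- sort(runif(50, 100, 1000))
  shifted <- tibble::tibble(mz = axis * (1 + 5e-6), intensity = 1)
  rec <- recalibrate_run(shifted, axis, ppm_tol = 10)
  expect_equal(attr(rec, "offset_ppm"), 5, tolerance = 0.1 / 5)
  expect_equal(rec$mz, axis, tolerance = 1e-7)

  noisy <- tibble::tibble(mz = axis * (1 + (5 + rnorm(50)) * 1e-6),
                          intensity = 1)
  rec2 <- recalibrate_run(noisy, axis, ppm_tol = 10)
  expect_lt(abs(attr(rec2, "offset_ppm") - 5), 1)

  # already on-axis: identity
  onaxis <- tibble::tibble(mz = axis, intensity = 1)
  rec3 <- recalibrate_run(onaxis, axis, ppm_tol = 10)
  expect_equal(attr(rec3, "offset_ppm"), 0)
  expect_equal(rec3$mz, axis)

  # re-matching after correction loses no previously matched peak
  j_before <- abs(1e6 * (noisy$mz - axis) / axis) <= 10
  j_after <- abs(1e6 * (rec2$mz - axis) / axis) <= 10
  expect_true(all(j_after[j_before]))

  # fewer than 3 matches: zero offset with warning
  few <- tibble::tibble(mz = axis[1:2], intensity = 1)
  expect_warning(rec4 <- recalibrate_run(few, axis * (1 + 8e-6), 10),
                 "zero offset")
  expect_equal(attr(rec4, "offset_ppm"), 0)
})

test_that("rasterisation maps, drops and sums as specified", {
  axis <- c(200, 500, 800)
  run <- msi_run(matrix(c(1, 2, 3), 1, 3), data.frame(x = 0L, y = 0L),
                 axis, "r", "s")
  out <- rasterize_runs(list(run), axis, 10)[[1]]
  expect_equal(out$intensities, matrix(c(1, 2, 3), 1, 3), ignore_attr = TRUE)

  # a column 15 ppm off-axis is dropped
  run2 <- msi_run(matrix(c(1, 2), 1, 2),
                  data.frame(x = 0L, y = 0L),
                  c(200, 500 * (1 + 15e-6)), "r", "s")
  out2 <- rasterize_runs(list(run2), axis, 10)[[1]]
  expect_equal(out2$intensities, matrix(c(1, 0, 0), 1, 3),
               ignore_attr = TRUE)

  # two run columns colliding onto one axis entry are summed
  run3 <- msi_run(matrix(c(4, 6), 1, 2),
                  data.frame(x = 0L, y = 0L),
                  c(500 * (1 - 3e-6), 500 * (1 + 3e-6)), "r", "s")
  out3 <- rasterize_runs(list(run3), axis, 10)[[1]]
  expect_equal(out3$intensities, matrix(c(0, 10, 0), 1, 3),
               ignore_attr = TRUE)
})

test_that("recalibrate + rasterize recovers >= 99% of true assignments at 3 ppm jitter", {
  cfg <- sim_config(n_slides = 3, cores_per_slide = 8, tumour_fraction = 0.5,
                    n_features = 40, n_markers = 4, ppm_jitter_sd = 3,
                    noise_sd = 0.2, seed = 21)
  sim <- simulate_dataset(cfg)
  peaklists <- lapply(sim$runs, function(r) {
    tibble::tibble(mz = r$axis, intensity = colMeans(r$intensities))
  })
  axis <- build_common_axis(peaklists, 10)
  recal <- lapply(sim$runs, recalibrate_run_matrix, axis = axis, ppm_tol = 10)
  rast <- rasterize_runs(recal, axis, 10)
  # true feature f of each run should land on the axis entry nearest true_mz
  truth_idx <- msitma:::nearest_index(sim$truth$true_mz, axis)
  recovered <- vapply(seq_along(rast), function(i) {
    run_idx <- msitma:::nearest_index(recal[[i]]$axis, axis)
    mean(run_idx == truth_idx)
  }, numeric(1))
  expect_true(all(recovered >= 0.99))
})

test_that("segmentation matches the generator tissue mask and is deterministic", {
  cfg <- sim_config(n_slides = 1, cores_per_slide = 9, tumour_fraction = 0.5,
                    n_features = 15, n_markers = 2, snr_floor = 1,
                    noise_sd = 0.2, seed = 13)
  sim <- simulate_dataset(cfg)
  run <- sim$runs[[1]]
  seg <- segment_kmeans(run, k = 2, seed = 1)
  truth_mask <- sim$truth$pixel_core[[run$run_id]]$core_id != "background"
  expect_equal(seg$tissue_mask, truth_mask)
  seg2 <- segment_kmeans(run, k = 2, seed = 1)
  expect_identical(seg$cluster, seg2$cluster)
  expect_error(segment_kmeans(tiny_run(m = 3), k = 5),
               "clusters")
})

test_that("spatial filter applies the occupancy and localisation rules", {
  set.seed(6)
  m <- 200
  tissue <- rep(c(TRUE, FALSE), each = m / 2)
  X <- matrix(0, m, 3)
  X[tissue, 1] <- rbinom(m / 2, 1, 0.8) * runif(m / 2, 50, 100)  # marker
  X[3, 2] <- 5                                   # single-pixel speckle
  X[, 3] <- runif(m, 10, 11)                     # spatially uniform
  run <- msi_run(X, data.frame(x = seq_len(m) - 1L, y = rep(0L, m)),
                 c(200, 500, 800), "r", "s")
  res <- spatial_filter_features(run, tissue, min_fraction = 0.05)
  expect_equal(res$retained, c(TRUE, FALSE, FALSE))
  expect_true(res$on_off_ratio[1] == Inf)
  expect_equal(res$on_off_ratio[3], 1, tolerance = 0.05)
})

test_that("reference scaling equalises reference medians with unit-mean scalars", {
  set.seed(7)
  mk_run <- function(id, scale) {
    msi_run(matrix(scale * rep(c(10, 20, 30), each = 4), 4, 3),
            data.frame(x = 0:3, y = rep(0L, 4)), c(100, 200, 300), id, id)
  }
  a <- mk_run("A", 1); b <- mk_run("B", 2)
  masks <- list(rep(TRUE, 4), rep(TRUE, 4))
  out <- reference_intensity_scale(list(a, b), masks)
  expect_equal(unname(out$scalars), c(4 / 3, 2 / 3))
  meds <- vapply(out$runs, function(r) median(tic(r)), numeric(1))
  expect_equal(meds[1], meds[2])
  # relative intensities within a run unchanged
  expect_equal(out$runs[[1]]$intensities / a$intensities,
               matrix(4 / 3, 4, 3), ignore_attr = TRUE)

  # three runs with batch factors {0.5, 1, 2}: post-scaling CV < 1e-6
  runs3 <- list(mk_run("A", 0.5), mk_run("B", 1), mk_run("C", 2))
  out3 <- reference_intensity_scale(runs3, rep(masks[1], 3))
  meds3 <- vapply(out3$runs, function(r) median(tic(r)), numeric(1))
  expect_lt(sd(meds3) / mean(meds3), 1e-6)

  # commutes with relabelling of runs
  out_rev <- reference_intensity_scale(rev(runs3), rep(masks[1], 3))
  expect_equal(unname(rev(out_rev$scalars)), unname(out3$scalars))

  expect_error(reference_intensity_scale(list(a), list(rep(FALSE, 4))),
               "A")
})

test_that("median fold change normalisation satisfies its defining property", {
  set.seed(8)
  X <- matrix(rexp(30 * 12, 1 / 100), 30, 12)
  out <- median_fold_change_normalize(X)
  ref <- out$reference
  mfc_after <- apply(out$X, 1, function(s) {
    pos <- s > 0 & ref > 0
    median(s[pos] / ref[pos])
  })
  expect_equal(mfc_after, rep(1, 30), tolerance = 1e-12)

  # pure dilution: spectrum = 3 x reference is mapped onto the reference
  X2 <- rbind(ref, 3 * ref, ref, ref)
  out2 <- median_fold_change_normalize(X2, reference = ref)
  expect_equal(out2$factors, c(1, 3, 1, 1))
  expect_equal(out2$X[2, ], ref, ignore_attr = TRUE)

  # renormalising against the stored reference is the identity
  out3 <- median_fold_change_normalize(out$X, reference = ref)
  expect_equal(out3$factors, rep(1, 30), tolerance = 1e-12)

  # disjoint support: factor 1 with a warning
  X4 <- rbind(c(1, 1, 0, 0), c(0, 0, 2, 2), c(0, 0, 3, 3))
  expect_warning(out4 <- median_fold_change_normalize(
    X4, reference = c(0, 0, 1, 1)), "no positive feature")
  expect_equal(out4$factors, c(1, 2, 3))
})
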