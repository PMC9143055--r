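#' Preprocessing configuration
#'
#' Collects the tunable parameters of the pixel-to-matrix preprocessing
#' stage. Defaults: SNR threshold 3 (a common peak-picking convention; the
#' threshold is instrument-dependent and deliberately exposed), ppm matching
#' tolerance 10 (the tolerance used throughout for peak alignment and axis
#' sharing), k-means with k = 4 clusters (tumour, stroma, tissue background,
#' slide background), background clusters flagged below 20% of the median
#' pixel TIC, and spatial occupancy floor of 1% of tissue pixels.
#'
#' @param snr_min minimum peak signal-to-noise ratio.
#' @param ppm_tol ppm tolerance for peak matching and axis construction.
#' @param kmeans_k number of k-means clusters for ROI segmentation.
#' @param kmeans_seed seed for the k-means initialisation.
#' @param background_tic_fraction clusters whose mean pixel TIC falls below
#'   this fraction of the brightest cluster's mean TIC are flagged as
#'   background.
#' @param spatial_filter_min_fraction minimum fraction of tissue pixels in
#'   which a feature must be non-zero to survive the spatial filter.
#' @return a validated `preprocess_config` list.
#' @export
preprocess_config <- function(snr_min = 3, ppm_tol = 10, kmeans_k = 4,
                              kmeans_seed = 1,
                              background_tic_fraction = 0.2,
                              spatial_filter_min_fraction = 0.01) {
  assert_scalar_number(snr_min, "snr_min", min = 0, strict_min = TRUE)
  assert_scalar_number(ppm_tol, "ppm_tol", min = 0, strict_min = TRUE)
  assert_count(kmeans_k, "kmeans_k", min = 2L)
  assert_scalar_number(background_tic_fraction, "background_tic_fraction",
                       min = 0)
  assert_scalar_number(spatial_filter_min_fraction,
                       "spatial_filter_min_fraction", min = 0)
  structure(list(snr_min = snr_min, ppm_tol = ppm_tol,
                 kmeans_k = as.integer(kmeans_k),
                 kmeans_seed = kmeans_seed,
                 background_tic_fraction = background_tic_fraction,
                 spatial_filter_min_fraction = spatial_filter_min_fraction),
            class = "preprocess_config")
}

#' Robust noise scale of a spectrum
#'
#' Estimates the noise level as 1.4826 times the median absolute deviation
#' from the spectrum median, computed over the baseline only (intensities
#' below the median), so that peaks — which live far above the median — do
#' not inflate the estimate. For Gaussian noise the estimate is consistent
#' for the noise sd.
#'
#' @param x numeric intensity vector (one spectrum).
#' @return non-negative noise scale; 0 for a constant (e.g. all-zero)
#'   spectrum.
#' @export
estimate_noise <- function(x) {
  if (length(x) == 0) abort("empty spectrum.", class = "msitma_validation_error")
  med <- median(x)
  baseline <- x[x < med]
  if (length(baseline) == 0) return(0)
  1.4826 * median(med - baseline)
}

#' SNR-based peak detection on a profile spectrum
#'
#' Finds local maxima whose intensity exceeds `snr_min` times the robust
#' noise scale of the spectrum ([estimate_noise()]). Each peak's centroid
#' m/z is refined as the intensity-weighted mean over the contiguous bins
#' around the apex that stay above half the apex intensity; apexes whose
#' half-maximum supports overlap are merged into one peak (the tallest
#' apex wins), so noise riding on a broad peak does not split it.
#'
#' @param mz mass axis of the profile spectrum.
#' @param intensity intensity vector, same length as `mz`.
#' @param snr_min minimum signal-to-noise ratio (default 3).
#' @return a peak-list tibble with columns `mz`, `intensity` (apex), `snr`,
#'   sorted by m/z; zero rows when nothing exceeds the threshold.
#' @export
detect_peaks <- function(mz, intensity, snr_min = 3) {
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have the same length.",
          class = "msitma_validation_error")
  }
  n <- length(intensity)
  empty <- tibble::tibble(mz = numeric(0), intensity = numeric(0),
                          snr = numeric(0))
  if (n < 3) return(empty)
  noise <- estimate_noise(intensity)
  if (noise <= 0) return(empty)
  left <- c(-Inf, intensity[-n])
  right <- c(intensity[-1], -Inf)
  apex <- which(intensity > left & intensity >= right &
                  intensity / noise >= snr_min)
  if (length(apex) == 0) return(empty)
  support <- t(vapply(apex, function(i) {
    half <- intensity[i] / 2
    lo <- i; while (lo > 1 && intensity[lo - 1] >= half) lo <- lo - 1
    hi <- i; while (hi < n && intensity[hi + 1] >= half) hi <- hi + 1
    c(lo, hi)
  }, numeric(2)))
  # apexes sharing overlapping half-maximum support are one peak: keep the
  # tallest (noise riding on a broad peak must not split it)
  ord <- order(support[, 1])
  group <- integer(length(apex))
  g <- 0L; cur_hi <- -Inf
  for (r in ord) {
    if (support[r, 1] > cur_hi) { g <- g + 1L; cur_hi <- support[r, 2] }
    else cur_hi <- max(cur_hi, support[r, 2])
    group[r] <- g
  }
  res <- lapply(split(seq_along(apex), group), function(members) {
    i <- apex[members[which.max(intensity[apex[members]])]]
    lo <- min(support[members, 1]); hi <- max(support[members, 2])
    w <- intensity[lo:hi]
    c(mz = sum(mz[lo:hi] * w) / sum(w), intensity = intensity[i],
      snr = intensity[i] / noise)
  })
  out <- tibble::as_tibble(do.call(rbind, res))
  out[order(out$mz), ]
}

#' Build a common mass axis across runs
#'
#' Pools the peak centroids of all runs, sorts them, and merges them by a
#' greedy single-linkage walk: the running cluster is closed whenever the
#' next centroid is farther than `ppm_tol` (relative to the running
#' intensity-weighted cluster mean) from the cluster mean, or would stretch
#' the cluster span beyond `ppm_tol`. Each cluster contributes one axis
#' entry: its intensity-weighted mean m/z. Because peaks are pooled and
#' sorted first, the result does not depend on run order.
#'
#' @param run_peaklists list of peak-list tibbles (`mz`, `intensity`).
#' @param ppm_tol ppm tolerance (default 10).
#' @return strictly increasing numeric mass axis.
#' @export
build_common_axis <- function(run_peaklists, ppm_tol = 10) {
  if (length(run_peaklists) == 0) {
    abort("need at least one run peak list.", class = "msitma_validation_error")
  }
  pooled <- dplyr::bind_rows(lapply(run_peaklists, function(p) {
    tibble::tibble(mz = p$mz,
                   intensity = if ("intensity" %in% names(p)) p$intensity else 1)
  }))
  if (nrow(pooled) == 0) return(numeric(0))
  pooled <- pooled[order(pooled$mz), ]
  mzs <- pooled$mz
  w <- pmax(pooled$intensity, .Machine$double.eps)
  axis <- numeric(0)
  c_start <- 1L
  c_wsum <- w[1]
  c_mean <- mzs[1]
  for (i in seq_along(mzs)[-1]) {
    tol <- c_mean * ppm_tol * 1e-6
    if ((mzs[i] - c_mean) > tol || (mzs[i] - mzs[c_start]) > tol) {
      axis <- c(axis, c_mean)
      c_start <- i; c_wsum <- w[i]; c_mean <- mzs[i]
    } else {
      c_wsum <- c_wsum + w[i]
      c_mean <- c_mean + w[i] * (mzs[i] - c_mean) / c_wsum
    }
  }
  axis <- c(axis, c_mean)
  validate_mass_axis(axis)
  axis
}

#' Estimate and remove a run's global mass-axis offset
#'
#' Matches each peak to its nearest common-axis entry within `ppm_tol`,
#' takes the median relative deviation of the matches as the run's global
#' ppm offset, and divides every m/z by `1 + offset * 1e-6`. With fewer than
#' 3 matched peaks the offset cannot be estimated robustly: a warning is
#' emitted and a zero offset applied.
#'
#' @param peaklist peak-list tibble (`mz`, `intensity`, ...).
#' @param axis common mass axis.
#' @param ppm_tol ppm matching tolerance (default 10).
#' @return the recalibrated peak list, with the estimated offset (ppm)
#'   attached as attribute `offset_ppm`.
#' @export
recalibrate_run <- function(peaklist, axis, ppm_tol = 10) {
  validate_mass_axis(axis)
  mzs <- peaklist$mz
  if (length(mzs) == 0) {
    out <- peaklist; attr(out, "offset_ppm") <- 0; return(out)
  }
  j <- nearest_index(mzs, axis)
  dev_ppm <- 1e6 * (mzs - axis[j]) / axis[j]
  matched <- abs(dev_ppm) <= ppm_tol
  if (sum(matched) < 3) {
    warn("fewer than 3 peaks matched the common axis; applying zero offset.")
    offset <- 0
  } else {
    offset <- median(dev_ppm[matched])
  }
  out <- peaklist
  out$mz <- mzs / (1 + offset * 1e-6)
  attr(out, "offset_ppm") <- offset
  out
}

#' Recalibrate a run matrix's own axis against the common axis
#'
#' Convenience wrapper for matrix-level (already centroided) runs: treats the
#' run's axis entries, weighted by their mean intensity across pixels, as the
#' run's peak list, estimates the global ppm offset as in
#' [recalibrate_run()], and returns the run with a corrected axis.
#'
#' @param run an `msi_run`.
#' @param axis common mass axis.
#' @param ppm_tol ppm tolerance.
#' @return the run with recalibrated axis and attribute `offset_ppm`.
#' @export
recalibrate_run_matrix <- function(run, axis, ppm_tol = 10) {
  validate_msi_run(run)
  pl <- tibble::tibble(mz = run$axis, intensity = colMeans(run$intensities))
  rec <- recalibrate_run(pl, axis, ppm_tol)
  run$axis <- rec$mz
  attr(run, "offset_ppm") <- attr(rec, "offset_ppm")
  run
}

#' Rasterise recalibrated runs onto the common mass axis
#'
#' Assigns each run-axis entry (i.e. each detected centroid column) to its
#' nearest common-axis entry within `ppm_tol`; entries with no match are
#' dropped, collisions onto the same common-axis entry are summed, and
#' features absent from a run are zero-filled. The result is the single
#' `M x N` data matrix per run on which all downstream stages operate.
#'
#' @param runs list of recalibrated `msi_run` objects.
#' @param axis common mass axis (length `N`).
#' @param ppm_tol ppm tolerance (default 10).
#' @return list of `msi_run` objects all sharing `axis`.
#' @export
rasterize_runs <- function(runs, axis, ppm_tol = 10) {
  validate_mass_axis(axis)
  lapply(runs, function(run) {
    validate_msi_run(run)
    j <- nearest_index(run$axis, axis)
    ok <- 1e6 * abs(run$axis - axis[j]) / axis[j] <= ppm_tol
    new <- matrix(0, nrow = nrow(run$intensities), ncol = length(axis))
    if (any(ok)) {
      src <- which(ok)
      for (grp in split(src, j[ok])) {
        dest <- j[grp[1]]
        new[, dest] <- rowSums(run$intensities[, grp, drop = FALSE])
      }
    }
    msi_run(new, run$coords, axis, run$run_id, run$slide_id,
            run$pixel_size_um)
  })
}

#' k-means segmentation of an MSI run
#'
#' Clusters the pixel spectra with k-means (deterministic under `seed`) on
#' the `log1p` intensity scale, which stabilises the variance while keeping
#' both the intensity contrast that separates tissue from slide background
#' and the compositional contrast that separates tissue types. Background
#' clusters are then flagged as those whose mean raw pixel TIC falls below
#' `background_tic_fraction` of the global median pixel TIC. With k = 4 the
#' clusters typically resolve tumour, stroma, tissue background, and slide
#' background; k = 2 suffices for a plain tissue/background split. The
#' background rule is relative to the brightest cluster rather than the
#' median pixel, so it remains correct on slides where background pixels
#' are the majority.
#'
#' @param run an `msi_run`.
#' @param k number of clusters (`k <= M`).
#' @param seed integer seed for the k-means initialisation.
#' @param background_tic_fraction background-flagging threshold, relative
#'   to the brightest cluster's mean TIC (default 0.2).
#' @return a `segmentation_map`: list with `cluster` (per-pixel integer
#'   label in 1..k), `centers` (k x N matrix of cluster centroid spectra on
#'   the `log1p` scale), `background_clusters` (integer set), and
#'   `tissue_mask` (logical, `!cluster %in% background_clusters`).
#' @export
segment_kmeans <- function(run, k = 4, seed = 1,
                           background_tic_fraction = 0.2) {
  validate_msi_run(run)
  m <- nrow(run$intensities)
  if (m < k) {
    abort(sprintf("cannot form %d clusters from %d pixels.", k, m),
          class = "msitma_validation_error")
  }
  tics <- tic(run)
  fit <- with_seed(seed, kmeans(log1p(run$intensities), centers = k,
                                nstart = 5, iter.max = 100))
  cluster_tic <- vapply(seq_len(k), function(cl) mean(tics[fit$cluster == cl]),
                        numeric(1))
  bg <- which(cluster_tic < background_tic_fraction * max(cluster_tic))
  structure(list(cluster = fit$cluster, centers = fit$centers,
                 background_clusters = bg,
                 tissue_mask = !(fit$cluster %in% bg)),
            class = "segmentation_map")
}

#' Spatial plausibility filter for features
#'
#' Drops ion images that are unlikely to be genuine tissue signal: features
#' non-zero in fewer than `min_fraction` of tissue pixels (speckle), and
#' features whose mean intensity on tissue does not exceed their mean
#' intensity off tissue (signal not localised to tissue). A feature with no
#' off-tissue signal at all has an infinite on/off ratio and is retained
#' whenever it passes the occupancy rule.
#'
#' @param run an `msi_run`.
#' @param tissue_mask logical vector over pixels (`TRUE` = tissue).
#' @param min_fraction occupancy floor (default 0.01).
#' @return tibble with one row per feature: `feature`, `mz`, `occupancy`,
#'   `on_off_ratio`, `retained`.
#' @export
spatial_filter_features <- function(run, tissue_mask, min_fraction = 0.01) {
  validate_msi_run(run)
  if (!any(tissue_mask)) {
    abort("tissue mask is empty.", class = "msitma_validation_error")
  }
  on <- run$intensities[tissue_mask, , drop = FALSE]
  off <- run$intensities[!tissue_mask, , drop = FALSE]
  occupancy <- colMeans(on > 0)
  on_mean <- colMeans(on)
  off_mean <- if (nrow(off) > 0) colMeans(off) else rep(0, ncol(on))
  ratio <- ifelse(off_mean > 0, on_mean / off_mean,
                  ifelse(on_mean > 0, Inf, 0))
  tibble::tibble(feature = seq_along(run$axis), mz = run$axis,
                 occupancy = occupancy, on_off_ratio = ratio,
                 retained = occupancy >= min_fraction & ratio > 1)
}

#' Reference-core intensity scaling across runs
#'
#' Removes run-to-run global intensity (batch) differences using the
#' reference kidney core present on every slide: each run is multiplied by
#' one scalar proportional to the inverse of the median TIC over its
#' reference-core pixels, with the scalars normalised to mean 1 so the
#' overall intensity scale of the dataset is preserved. After scaling, the
#' reference-core median TICs of all runs are equal (to float precision),
#' and relative intensities within each run are untouched.
#'
#' @param runs list of `msi_run` objects.
#' @param reference_masks list (same length/order) of logical pixel masks
#'   selecting each run's reference-core pixels.
#' @return list with `runs` (scaled) and `scalars` (named per run).
#' @export
reference_intensity_scale <- function(runs, reference_masks) {
  stopifnot(length(runs) == length(reference_masks))
  meds <- vapply(seq_along(runs), function(i) {
    run <- runs[[i]]
    validate_msi_run(run)
    mask <- reference_masks[[i]]
    if (!any(mask)) {
      abort(sprintf("reference_intensity_scale: slide '%s' has an empty reference mask.",
                    run$slide_id),
            class = "msitma_validation_error")
    }
    median(tic(run)[mask])
  }, numeric(1))
  if (any(meds <= 0)) {
    abort("reference_intensity_scale: a slide has zero reference-core TIC.",
          class = "msitma_validation_error")
  }
  inv <- 1 / meds
  scalars <- inv / mean(inv)
  runs <- lapply(seq_along(runs), function(i) {
    run <- runs[[i]]
    run$intensities <- run$intensities * scalars[i]
    run
  })
  names(scalars) <- vapply(runs, `[[`, character(1), "run_id")
  list(runs = runs, scalars = scalars)
}

#' Median fold change normalisation
#'
#' Corrects dilution-like global intensity differences between spectra: each
#' spectrum is divided by the median of its feature-wise ratios to a
#' reference spectrum, taken over the features where both are positive. The
#' default reference is the feature-wise median spectrum of the input. After
#' normalisation, each spectrum's median fold change against the reference
#' equals exactly 1. A spectrum sharing no positive feature with the
#' reference is left unchanged (factor 1) with a warning.
#'
#' @param X spectra as a numeric matrix (rows = spectra) or a list of
#'   numeric vectors.
#' @param reference optional reference spectrum; defaults to the feature-wise
#'   median of `X`. Pass the returned reference to renormalise new spectra
#'   on the same scale.
#' @return list with `X` (normalised, same shape as input), `factors`
#'   (per-spectrum dilution factors), and `reference`.
#' @export
median_fold_change_normalize <- function(X, reference = NULL) {
  was_list <- is.list(X) && !is.data.frame(X)
  mat <- if (was_list) do.call(rbind, X) else as.matrix(X)
  if (is.null(reference)) reference <- apply(mat, 2, median)
  if (length(reference) != ncol(mat)) {
    abort("reference length must equal the number of features.",
          class = "msitma_validation_error")
  }
  factors <- vapply(seq_len(nrow(mat)), function(i) {
    pos <- mat[i, ] > 0 & reference > 0
    if (!any(pos)) {
      warn(sprintf("spectrum %d shares no positive feature with the reference; factor 1.", i))
      return(1)
    }
    median(mat[i, pos] / reference[pos])
  }, numeric(1))
  out <- mat / factors
  if (was_list) out <- lapply(seq_len(nrow(out)), function(i) unname(out[i, ]))
  list(X = out, factors = factors, reference = reference)
}
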