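#' Configuration for the synthetic TMA generator
#'
#' Bundles and validates every knob of the synthetic multi-slide TMA MSI
#' simulator. The defaults describe the bundled demonstration dataset: three
#' slides of 43 annotated cores each (~130 cores), an 8:1 tumour:normal
#' imbalance, a 60-peak panel of which 5 markers carry a 2-fold
#' (`marker_log2_effect = 1`) tumour/normal intensity difference, log-normal
#' multiplicative pixel noise of sd 0.3 (natural-log scale), per-slide batch
#' factors of log-sd 0.3, and a run-specific mass-axis shift of sd 2 ppm.
#'
#' @param n_slides number of slides (one MSI run per slide).
#' @param cores_per_slide annotated (tumour/normal) cores per slide; every
#'   slide additionally carries one reference kidney core.
#' @param tumour_fraction fraction of annotated cores that are tumour, in
#'   (0, 1). The default 8/9 gives the 8:1 imbalance typical of archival
#'   breast TMA cohorts.
#' @param n_features number of true peaks in the panel.
#' @param n_markers number of class-discriminating marker features
#'   (`n_markers <= n_features`).
#' @param marker_log2_effect log2 fold change of marker intensity in tumour
#'   relative to normal cores.
#' @param slide_batch_sd sd (natural-log scale) of the per-slide
#'   multiplicative batch factor; 0 disables batch effects.
#' @param ppm_jitter_sd sd of the per-run global mass-axis shift, in ppm.
#' @param noise_sd sd (natural-log scale) of the multiplicative log-normal
#'   pixel noise; 0 gives the deterministic noise-free limit.
#' @param core_radius_px radius of each circular core, in pixels.
#' @param pixel_size_um pixel size in micrometres (default 85).
#' @param snr_floor scale of the background (non-tissue) noise intensities.
#' @param ffpe_retention fraction of fresh-frozen peaks surviving the FFPE
#'   simulation of [simulate_ffpe_from_ff()].
#' @param seed mandatory integer seed; identical seed and configuration give
#'   a bit-identical dataset.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_slides = 3, cores_per_slide = 43,
                       tumour_fraction = 8 / 9, n_features = 60,
                       n_markers = 5, marker_log2_effect = 1,
                       slide_batch_sd = 0.3, ppm_jitter_sd = 2,
                       noise_sd = 0.3, core_radius_px = 2,
                       pixel_size_um = 85, snr_floor = 1,
                       ffpe_retention = 158 / 908, seed = NULL) {
  cfg <- list(
    n_slides = assert_count(n_slides, "n_slides"),
    cores_per_slide = assert_count(cores_per_slide, "cores_per_slide"),
    tumour_fraction = tumour_fraction,
    n_features = assert_count(n_features, "n_features"),
    n_markers = assert_count(n_markers, "n_markers", min = 0L),
    marker_log2_effect = assert_scalar_number(marker_log2_effect,
                                              "marker_log2_effect"),
    slide_batch_sd = assert_scalar_number(slide_batch_sd, "slide_batch_sd",
                                          min = 0),
    ppm_jitter_sd = assert_scalar_number(ppm_jitter_sd, "ppm_jitter_sd",
                                         min = 0),
    noise_sd = assert_scalar_number(noise_sd, "noise_sd", min = 0),
    core_radius_px = assert_count(core_radius_px, "core_radius_px"),
    pixel_size_um = assert_scalar_number(pixel_size_um, "pixel_size_um",
                                         min = 0, strict_min = TRUE),
    snr_floor = assert_scalar_number(snr_floor, "snr_floor", min = 0),
    ffpe_retention = ffpe_retention,
    seed = seed)
  assert_scalar_number(tumour_fraction, "tumour_fraction")
  if (tumour_fraction <= 0 || tumour_fraction >= 1) {
    abort("`tumour_fraction` must lie strictly between 0 and 1.",
          class = "msitma_config_error")
  }
  assert_scalar_number(ffpe_retention, "ffpe_retention")
  if (ffpe_retention <= 0 || ffpe_retention > 1) {
    abort("`ffpe_retention` must lie in (0, 1].",
          class = "msitma_config_error")
  }
  if (cfg$n_markers > cfg$n_features) {
    abort("`n_markers` must not exceed `n_features`.",
          class = "msitma_config_error")
  }
  if (is.null(seed)) {
    abort("`seed` is mandatory in a simulation configuration.",
          class = "msitma_config_error")
  }
  cfg$seed <- assert_count(seed, "seed", min = 0L)
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-slide TMA MSI dataset with known ground truth
#'
#' Generates one MSI run per slide: cores laid out on a grid (each slide's
#' annotated tumour/normal cores plus one reference kidney core), surrounded
#' by background pixels whose intensities are pure noise at the `snr_floor`
#' scale. Tissue pixel intensities are a per-class template times a per-slide
#' multiplicative batch factor times log-normal pixel noise; tumour cores
#' carry `2^marker_log2_effect` times the normal intensity on the marker
#' features (applied before batch factors and noise). Each run observes the
#' true m/z values through its own global ppm shift, emulating run-to-run
#' mass-axis drift.
#'
#' Class counts are deterministic given the configuration:
#' `round(tumour_fraction * cores_per_slide)` tumour cores per slide. Patients
#' hold 1-3 cores each, never straddle slides or classes.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{runs}{list of `msi_run`, one per slide, on run-specific axes.}
#'     \item{cores}{annotation tibble: `core_id`, `slide_id`, `patient_id`,
#'       `label` (`"tumour"`, `"normal"`, `"reference"`), `x_center`,
#'       `y_center`, `radius_px`.}
#'     \item{truth}{ground truth: `marker_indices`, `true_effects` (log2),
#'       `slide_factors`, `true_mz`, `core_labels`, per-run `pixel_core`
#'       tibbles mapping each pixel to its core id or `"background"`, and the
#'       noise-free class `templates`.}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  nf <- cfg$n_features
  # true peak centres: uniform over the DESI metabolite/lipid range, kept at
  # least 0.5 Th apart so 10 ppm windows never overlap between features
  true_mz <- sort(runif(nf, 100, 1000))
  while (any(diff(true_mz) < 0.5)) {
    true_mz <- sort(runif(nf, 100, 1000))
  }
  base <- exp(runif(nf, log(50), log(500)))   # per-feature baseline intensity
  marker_indices <- sort(sample.int(nf, cfg$n_markers))
  effects <- rep(cfg$marker_log2_effect, cfg$n_markers)

  templates <- list(
    normal = base,
    tumour = {
      t <- base
      t[marker_indices] <- t[marker_indices] * 2^effects
      t
    },
    # kidney reference tissue: its own fixed profile, shared across slides
    reference = base * exp(runif(nf, -0.5, 0.5)))

  slide_factors <- exp(rnorm(cfg$n_slides, 0, cfg$slide_batch_sd))
  run_ppm <- rnorm(cfg$n_slides, 0, cfg$ppm_jitter_sd)

  n_tum <- round(cfg$tumour_fraction * cfg$cores_per_slide)
  n_norm <- cfg$cores_per_slide - n_tum
  if (n_tum < 1 || n_norm < 1) {
    abort("tumour_fraction and cores_per_slide leave a class empty.",
          class = "msitma_config_error")
  }

  runs <- vector("list", cfg$n_slides)
  cores_list <- vector("list", cfg$n_slides)
  pixel_core <- vector("list", cfg$n_slides)
  patient_counter <- 0L

  for (s in seq_len(cfg$n_slides)) {
    slide_id <- sprintf("S%02d", s)
    labels <- c(rep("tumour", n_tum), rep("normal", n_norm))
    labels <- sample(labels)                     # shuffle grid placement
    labels <- c(labels, "reference")
    n_cores <- length(labels)

    # grid layout: square-ish arrangement, one cell per core
    cell <- 2L * cfg$core_radius_px + 3L
    ncol_grid <- ceiling(sqrt(n_cores))
    nrow_grid <- ceiling(n_cores / ncol_grid)
    width <- ncol_grid * cell
    height <- nrow_grid * cell
    centers <- tibble::tibble(
      idx = seq_len(n_cores),
      x_center = ((seq_len(n_cores) - 1L) %% ncol_grid) * cell +
        cfg$core_radius_px + 1L,
      y_center = ((seq_len(n_cores) - 1L) %/% ncol_grid) * cell +
        cfg$core_radius_px + 1L)

    core_ids <- ifelse(labels == "reference",
                       sprintf("%s_REF", slide_id),
                       sprintf("%s_C%03d", slide_id, seq_len(n_cores)))

    # patients: 1-3 cores each, within slide and class
    patient_ids <- character(n_cores)
    for (lab in c("tumour", "normal")) {
      idx <- which(labels == lab)
      i <- 1L
      while (i <= length(idx)) {
        take <- min(sample.int(3L, 1L), length(idx) - i + 1L)
        patient_counter <- patient_counter + 1L
        patient_ids[idx[i:(i + take - 1L)]] <- sprintf("P%03d", patient_counter)
        i <- i + take
      }
    }
    patient_ids[labels == "reference"] <- sprintf("%s_REFPAT", slide_id)

    # full rectangular pixel grid
    coords <- expand.grid(x = 0:(width - 1L), y = 0:(height - 1L))
    coords <- tibble::tibble(x = as.integer(coords$x),
                             y = as.integer(coords$y))
    m <- nrow(coords)

    # nearest core centre within radius -> core; otherwise background
    dx <- outer(coords$x, centers$x_center, "-")
    dy <- outer(coords$y, centers$y_center, "-")
    d2 <- dx^2 + dy^2
    nearest <- max.col(-d2, ties.method = "first")
    in_core <- d2[cbind(seq_len(m), nearest)] <= cfg$core_radius_px^2
    pix_core <- ifelse(in_core, core_ids[nearest], "background")

    inten <- matrix(cfg$snr_floor * rexp(m * cfg$n_features),
                    nrow = m, ncol = cfg$n_features)
    for (ci in seq_len(n_cores)) {
      rows <- which(pix_core == core_ids[ci])
      tmpl <- templates[[labels[ci]]] * slide_factors[s]
      noise <- if (cfg$noise_sd > 0) {
        matrix(exp(rnorm(length(rows) * cfg$n_features, 0, cfg$noise_sd)),
               nrow = length(rows))
      } else 1
      inten[rows, ] <- rep(tmpl, each = length(rows)) * noise
    }

    run_axis <- true_mz * (1 + run_ppm[s] * 1e-6)
    runs[[s]] <- msi_run(inten, coords, run_axis, run_id = slide_id,
                         slide_id = slide_id,
                         pixel_size_um = cfg$pixel_size_um)
    cores_list[[s]] <- tibble::tibble(
      core_id = core_ids, slide_id = slide_id, patient_id = patient_ids,
      label = labels, x_center = centers$x_center,
      y_center = centers$y_center, radius_px = cfg$core_radius_px)
    pixel_core[[s]] <- tibble::tibble(x = coords$x, y = coords$y,
                                      core_id = pix_core)
  }

  cores <- dplyr::bind_rows(cores_list)
  names(pixel_core) <- vapply(runs, `[[`, character(1), "run_id")
  truth <- list(
    marker_indices = marker_indices,
    true_effects = effects,
    slide_factors = setNames(slide_factors,
                             vapply(runs, `[[`, character(1), "slide_id")),
    true_mz = true_mz,
    core_labels = setNames(cores$label, cores$core_id),
    pixel_core = pixel_core,
    templates = templates,
    run_ppm = setNames(run_ppm,
                       vapply(runs, `[[`, character(1), "run_id")))
  list(runs = runs, cores = cores, truth = truth)
}

#' Simulate FFPE peak loss from a fresh-frozen peak list
#'
#' Formalin fixation and paraffin embedding deplete much of the metabolome
#' observable by DESI; only a fraction of fresh-frozen (FF) peaks survive,
#' and surviving (phospho)lipid signals in the 600-900 m/z range are
#' attenuated. This helper draws a uniform subset of
#' `round(retention * n)` peaks, perturbs each surviving m/z by an
#' independent ppm offset, and multiplies lipid-range intensities by
#' `lipid_attenuation^(1 - retention)` so that the attenuation strength grows
#' with the simulated processing loss and the identity case (`retention = 1`,
#' `ppm_jitter_sd = 0`) returns the input unchanged.
#'
#' @param ff_peaks peak-list tibble with columns `mz`, `intensity` (and
#'   optionally `snr`).
#' @param retention fraction of peaks retained, in (0, 1].
#' @param ppm_jitter_sd sd of the per-peak m/z perturbation, in ppm.
#' @param seed integer seed.
#' @param lipid_attenuation base intensity attenuation factor for 600-900 m/z
#'   peaks at full peak loss (default 0.3).
#' @return a peak-list tibble of `round(retention * nrow(ff_peaks))` rows,
#'   sorted by m/z.
#' @export
simulate_ffpe_from_ff <- function(ff_peaks, retention, ppm_jitter_sd, seed,
                                  lipid_attenuation = 0.3) {
  if (!is.data.frame(ff_peaks) || !all(c("mz", "intensity") %in% names(ff_peaks))) {
    abort("`ff_peaks` must be a data frame with columns `mz` and `intensity`.",
          class = "msitma_config_error")
  }
  if (retention <= 0 || retention > 1) {
    abort("`retention` must lie in (0, 1].", class = "msitma_config_error")
  }
  assert_scalar_number(ppm_jitter_sd, "ppm_jitter_sd", min = 0)
  n <- nrow(ff_peaks)
  if (n == 0) return(tibble::as_tibble(ff_peaks))
  with_seed(seed, {
    keep <- sort(sample.int(n, round(retention * n)))
    out <- tibble::as_tibble(ff_peaks[keep, , drop = FALSE])
    if (ppm_jitter_sd > 0) {
      out$mz <- out$mz * (1 + rnorm(nrow(out), 0, ppm_jitter_sd) * 1e-6)
    }
    atten <- lipid_attenuation^(1 - retention)
    lipid <- out$mz >= 600 & out$mz <= 900
    out$intensity[lipid] <- out$intensity[lipid] * atten
    out[order(out$mz), , drop = FALSE]
  })
}

#' Simulate a per-core feature table directly
#'
#' A light-weight companion to [simulate_dataset()]: skips the pixel level
#' and draws per-core averaged spectra straight from the class templates with
#' log-normal core-level noise and per-slide batch factors. Useful for
#' studying the classification and feature-selection stages at larger core
#' and feature counts than the full spatial simulator needs.
#'
#' @param n_cores total number of annotated cores.
#' @param n_features,n_markers,marker_log2_effect,tumour_fraction,
#'   slide_batch_sd,noise_sd,seed as in [sim_config()]; `noise_sd` here is
#'   the core-level (not pixel-level) log-normal sd.
#' @param n_slides number of slides the cores are spread over.
#' @return a list with `table` (a core feature table as used by
#'   [cross_validate()]: `X`, `y`, `slide_ids`, `patient_ids`, `axis`) and
#'   `truth` (`marker_indices`).
#' @export
simulate_core_table <- function(n_cores = 150, n_features = 200,
                                n_markers = 5, marker_log2_effect = 1,
                                tumour_fraction = 8 / 9, n_slides = 3,
                                slide_batch_sd = 0.2, noise_sd = 0.3,
                                seed = 1) {
  with_seed(seed, {
    base <- exp(runif(n_features, log(50), log(500)))
    markers <- sort(sample.int(n_features, n_markers))
    n_tum <- round(tumour_fraction * n_cores)
    y <- c(rep(1L, n_tum), rep(0L, n_cores - n_tum))
    slide_ids <- sprintf("S%02d", sample.int(n_slides, n_cores, replace = TRUE))
    sf <- setNames(exp(rnorm(n_slides, 0, slide_batch_sd)),
                   sprintf("S%02d", seq_len(n_slides)))
    X <- matrix(rep(base, each = n_cores), n_cores, n_features)
    X[y == 1L, markers] <- X[y == 1L, markers] * 2^marker_log2_effect
    X <- X * sf[slide_ids] *
      matrix(exp(rnorm(n_cores * n_features, 0, noise_sd)), n_cores)
    table <- core_feature_table(
      X, y, slide_ids = slide_ids,
      patient_ids = sprintf("P%03d", seq_len(n_cores)),
      axis = sort(runif(n_features, 100, 1000)))
    list(table = table, truth = list(marker_indices = markers))
  })
}
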