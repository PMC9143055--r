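#' Assign pixels to TMA cores
#'
#' Each pixel belongs to the nearest core centre provided it lies within
#' that core's radius and (if a tissue mask is given) on tissue; otherwise
#' it is background. Ties in distance are broken toward the
#' lexicographically lower `core_id`, so no pixel ever lands in two cores.
#' Overlapping core discs are resolved by the nearest-centre rule with a
#' warning.
#'
#' @param run an `msi_run`.
#' @param cores annotation tibble for this slide with columns `core_id`,
#'   `x_center`, `y_center`, `radius_px`.
#' @param tissue_mask optional logical vector over the run's pixels;
#'   off-tissue pixels are background regardless of geometry.
#' @return character vector over pixels: a `core_id` or `"background"`.
#' @export
assign_pixels_to_cores <- function(run, cores, tissue_mask = NULL) {
  validate_msi_run(run)
  stopifnot(all(c("core_id", "x_center", "y_center", "radius_px") %in%
                  names(cores)))
  cores <- cores[order(cores$core_id), ]
  m <- nrow(run$coords)
  if (any(cores$x_center < min(run$coords$x)) ||
      any(cores$x_center > max(run$coords$x)) ||
      any(cores$y_center < min(run$coords$y)) ||
      any(cores$y_center > max(run$coords$y))) {
    abort("core centres must lie within the pixel grid.",
          class = "msitma_validation_error")
  }
  dx <- outer(run$coords$x, cores$x_center, "-")
  dy <- outer(run$coords$y, cores$y_center, "-")
  d2 <- dx^2 + dy^2
  # overlap check: does any pixel fall within two core radii?
  within <- sweep(d2, 2, cores$radius_px^2, "<=")
  if (any(rowSums(within) > 1)) {
    warn("overlapping core discs; resolving by nearest centre.")
  }
  nearest <- max.col(-d2, ties.method = "first")  # cores sorted by id
  in_core <- d2[cbind(seq_len(m), nearest)] <=
    cores$radius_px[nearest]^2
  if (!is.null(tissue_mask)) in_core <- in_core & tissue_mask
  ifelse(in_core, cores$core_id[nearest], "background")
}

#' Average per-core spectra
#'
#' Collapses pixel spectra to one arithmetic mean spectrum per core — the
#' representation used for all predictive modelling — and joins the core
#' annotations. Cores listed in the annotation but left without any
#' assigned pixel are excluded with a warning.
#'
#' @param run an `msi_run`.
#' @param assignment per-pixel core ids from [assign_pixels_to_cores()].
#' @param cores annotation tibble (`core_id`, `slide_id`, `patient_id`,
#'   `label`).
#' @return a core-table tibble: `core_id`, `slide_id`, `patient_id`,
#'   `label`, `n_pixels`, and a `spectrum` list-column; the shared mass axis
#'   is attached as attribute `axis`.
#' @export
average_core_spectra <- function(run, assignment, cores) {
  validate_msi_run(run)
  stopifnot(length(assignment) == nrow(run$intensities))
  keep <- assignment != "background"
  if (!any(keep)) {
    abort("no pixels assigned to any core.", class = "msitma_validation_error")
  }
  sums <- rowsum(run$intensities[keep, , drop = FALSE], assignment[keep])
  counts <- table(assignment[keep])[rownames(sums)]
  means <- sums / as.numeric(counts)
  missing <- setdiff(cores$core_id, rownames(means))
  if (length(missing) > 0) {
    warn(sprintf("cores with no assigned pixels excluded: %s",
                 paste(missing, collapse = ", ")))
  }
  present <- cores[cores$core_id %in% rownames(means), , drop = FALSE]
  out <- tibble::tibble(
    core_id = present$core_id,
    slide_id = present$slide_id,
    patient_id = present$patient_id,
    label = present$label,
    n_pixels = as.integer(counts[present$core_id]),
    spectrum = lapply(present$core_id, function(id) unname(means[id, ])))
  attr(out, "axis") <- run$axis
  out
}

#' Combine per-run core tables
#'
#' @param core_tables list of core tables sharing one mass axis.
#' @return a single core table with the common `axis` attribute.
#' @export
bind_core_tables <- function(core_tables) {
  axis <- attr(core_tables[[1]], "axis")
  out <- dplyr::bind_rows(core_tables)
  if (anyDuplicated(out$core_id)) {
    abort("duplicate core_id across slides.", class = "msitma_validation_error")
  }
  attr(out, "axis") <- axis
  out
}

# ---- affine registration ---------------------------------------------------

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(r + 1):(r + n)])
  }
  img <- apply(img, 2, pad_conv)
  t(apply(img, 1, pad_conv))
}

# bilinear sample of image `img` at (x, y) in 1-based matrix coordinates
# (x = column, y = row); outside pixels read as 0
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(xx, yy) {
    ok <- xx >= 1 & xx <= w & yy >= 1 & yy <= h
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  val(x0, y0) * (1 - fx) * (1 - fy) + val(x0 + 1, y0) * fx * (1 - fy) +
    val(x0, y0 + 1) * (1 - fx) * fy + val(x0 + 1, y0 + 1) * fx * fy
}

#' Affine co-registration of two binary masks by gradient descent
#'
#' Estimates the 2x3 affine transform `A = [L | t]` that minimises the mean
#' squared difference between the fixed mask and the warped moving mask,
#' where each fixed-frame pixel `p` reads the moving image at `L p + t`
#' (the resampling map; a moving mask whose content sits 5 px left of the
#' fixed content is recovered with `t` close to (-5, 0)). Both masks are
#' Gaussian-smoothed on a coarse-to-fine sigma schedule so the loss has
#' usable gradients; each level runs first-order descent steps along the
#' damped Gauss-Newton direction of the squared loss (analytic Jacobian of
#' the bilinear warp) with backtracking step halving, so the loss is
#' non-increasing over accepted iterations. If the loss stays above its
#' initial value for 50 consecutive accepted iterations the routine
#' declares divergence and returns the identity with a warning.
#'
#' The typical use is aligning a total-ion-count tissue mask from MSI with
#' the tissue mask of the corresponding optical (H&E) image.
#'
#' @param fixed,moving binary (0/1) image matrices of equal size.
#' @param n_iters iterations per smoothing level (default 200).
#' @param sigmas decreasing Gaussian smoothing schedule in pixels.
#' @return an `affine_params` object: list with `A` (2x3 matrix), `loss`
#'   (final smoothed-mask loss), `converged`.
#' @export
register_affine <- function(fixed, moving, n_iters = 200,
                            sigmas = c(6, 3, 1.5)) {
  if (!any(fixed > 0) || !any(moving > 0)) {
    abort("both masks must be non-empty.", class = "msitma_validation_error")
  }
  stopifnot(all(dim(fixed) == dim(moving)))
  h <- nrow(fixed); w <- ncol(fixed)
  grid <- expand.grid(x = seq_len(w), y = seq_len(h))
  gx <- grid$x; gy <- grid$y
  # centre coordinates so rotation/scale act about the image centre
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- gx - cx; ys <- gy - cy

  theta <- c(1, 0, 0, 1, 0, 0)  # a11 a12 a21 a22 tx ty
  identity_theta <- theta
  diverged <- FALSE

  for (sigma in sigmas) {
    f <- gaussian_blur(fixed, sigma)
    mv <- gaussian_blur(moving, sigma)
    # image gradients of the smoothed moving mask (central differences)
    gxm <- (cbind(mv[, -1], mv[, w]) - cbind(mv[, 1], mv[, -w])) / 2
    gym <- (rbind(mv[-1, ], mv[h, ]) - rbind(mv[1, ], mv[-h, ])) / 2
    fvec <- f[cbind(gy, gx)]

    warp_xy <- function(th) {
      list(x = th[1] * xs + th[2] * ys + th[5] + cx,
           y = th[3] * xs + th[4] * ys + th[6] + cy)
    }
    loss_at <- function(th) {
      wp <- warp_xy(th)
      mean((bilinear_sample(mv, wp$x, wp$y) - fvec)^2)
    }
    cur_loss <- loss_at(theta)
    init_loss <- cur_loss
    bad_streak <- 0L
    for (it in seq_len(n_iters)) {
      wp <- warp_xy(theta)
      wv <- bilinear_sample(mv, wp$x, wp$y)
      r <- wv - fvec
      dgx <- bilinear_sample(gxm, wp$x, wp$y)
      dgy <- bilinear_sample(gym, wp$x, wp$y)
      J <- cbind(dgx * xs, dgx * ys, dgy * xs, dgy * ys, dgx, dgy)
      grad <- drop(crossprod(J, r))
      if (sqrt(sum(grad^2)) < 1e-10) break
      # damped Gauss-Newton step: rescales the ill-conditioned mix of
      # linear-part and translation parameters automatically
      JtJ <- crossprod(J)
      diag(JtJ) <- diag(JtJ) * (1 + 1e-3) + 1e-12
      delta <- tryCatch(solve(JtJ, grad), error = function(e) grad)
      accepted <- FALSE
      step <- 1
      for (half in 1:30) {
        cand <- theta - step * delta
        cand_loss <- loss_at(cand)
        if (cand_loss < cur_loss) {
          theta <- cand; cur_loss <- cand_loss
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
      bad_streak <- if (cur_loss > init_loss) bad_streak + 1L else 0L
      if (bad_streak >= 50L) { diverged <- TRUE; break }
    }
    if (diverged) break
  }

  if (diverged) {
    warn("registration diverged; returning identity transform.")
    theta <- identity_theta
  }
  # convert centre-referenced parameters to a plain 2x3 matrix in image
  # coordinates: p_fixed = L %*% p_moving + t
  L <- matrix(theta[1:4], 2, 2, byrow = TRUE)
  t_img <- c(theta[5] + cx, theta[6] + cy) - L %*% c(cx, cy)
  A <- cbind(L, t_img)
  dimnames(A) <- list(c("x", "y"), c("x", "y", "t"))
  final <- {
    f <- gaussian_blur(fixed, tail(sigmas, 1))
    mv <- gaussian_blur(moving, tail(sigmas, 1))
    wp <- list(x = theta[1] * xs + theta[2] * ys + theta[5] + cx,
               y = theta[3] * xs + theta[4] * ys + theta[6] + cy)
    mean((bilinear_sample(mv, wp$x, wp$y) - f[cbind(gy, gx)])^2)
  }
  structure(list(A = A, loss = final, converged = !diverged),
            class = "affine_params")
}

#' Apply an affine transform to a binary mask
#'
#' Warps `moving` into the fixed frame under the transform returned by
#' [register_affine()] (nearest-neighbour resampling of the inverse map).
#'
#' @param params an `affine_params` object.
#' @param moving binary image matrix.
#' @return warped binary matrix of the same size.
#' @export
warp_mask <- function(params, moving) {
  A <- params$A
  h <- nrow(moving); w <- ncol(moving)
  grid <- expand.grid(x = seq_len(w), y = seq_len(h))
  xw <- A[1, 1] * grid$x + A[1, 2] * grid$y + A[1, 3]
  yw <- A[2, 1] * grid$x + A[2, 2] * grid$y + A[2, 3]
  v <- bilinear_sample(moving, xw, yw)
  out <- matrix(0, nrow = h, ncol = w)
  out[cbind(grid$y, grid$x)] <- as.numeric(v >= 0.5)
  out
}

#' Match two mass axes within a ppm tolerance
#'
#' One-to-one greedy matching: all cross-axis pairs within `ppm_tol` are
#' enumerated and accepted in order of increasing ppm distance, each peak
#' being used at most once. The shared fraction is reported relative to the
#' smaller axis — the convention under which, e.g., 41 matches against a
#' 158-entry axis give 26%.
#'
#' @param axis_a,axis_b strictly increasing mass axes.
#' @param ppm_tol ppm tolerance (default 10).
#' @return list with `pairs` (tibble `index_a`, `index_b`, `mz_a`, `mz_b`,
#'   `ppm`) and `shared_fraction` = matched pairs / smaller axis size.
#' @export
match_peak_axes <- function(axis_a, axis_b, ppm_tol = 10) {
  validate_mass_axis(axis_a)
  validate_mass_axis(axis_b)
  empty <- list(pairs = tibble::tibble(index_a = integer(0),
                                       index_b = integer(0),
                                       mz_a = numeric(0), mz_b = numeric(0),
                                       ppm = numeric(0)),
                shared_fraction = if (min(length(axis_a), length(axis_b)) == 0)
                  NaN else 0)
  if (length(axis_a) == 0 || length(axis_b) == 0) return(empty)
  # candidate pairs: for each a, the b entries within tolerance
  cand <- lapply(seq_along(axis_a), function(i) {
    tol <- axis_a[i] * ppm_tol * 1e-6 * 1.001  # pad; exact test below
    lo <- findInterval(axis_a[i] - tol, axis_b) + 1L
    hi <- findInterval(axis_a[i] + tol, axis_b)
    if (hi < lo) return(NULL)
    j <- lo:hi
    d <- ppm_dist(axis_a[i], axis_b[j])
    keep <- d <= ppm_tol
    if (!any(keep)) return(NULL)
    cbind(i = i, j = j[keep], d = d[keep])
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand[, "d"], cand[, "i"], cand[, "j"]), , drop = FALSE]
  used_a <- logical(length(axis_a)); used_b <- logical(length(axis_b))
  sel <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; sel[r] <- TRUE
    }
  }
  hit <- cand[sel, , drop = FALSE]
  hit <- hit[order(hit[, "i"]), , drop = FALSE]
  pairs <- tibble::tibble(index_a = as.integer(hit[, "i"]),
                          index_b = as.integer(hit[, "j"]),
                          mz_a = axis_a[hit[, "i"]], mz_b = axis_b[hit[, "j"]],
                          ppm = hit[, "d"])
  list(pairs = pairs,
       shared_fraction = nrow(pairs) / min(length(axis_a), length(axis_b)))
}
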