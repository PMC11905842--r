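#' Mask-normalised low-frequency intensity correction
#'
#' Removes smooth residual field-inhomogeneity from a masked scan by
#' normalized convolution: the masked signal and the mask are smoothed with
#' the same Gaussian kernel, their ratio gives a low-frequency gain field
#' restricted to the brain, the original signal is divided by that field, and
#' the result is rescaled by one scalar so its mean over the mask equals the
#' input mean over the mask. Voxels outside the mask are zero. On a constant
#' image the correction is the identity; tissue-scale contrast is untouched
#' because only components below the kernel scale survive in the field.
#'
#' @param vol a non-negative `scalar_volume` (typically the masked
#'   T2-weighted scan).
#' @param mask the brain [binary_mask()] on the same grid.
#' @param sigma_mm Gaussian standard deviation in millimetres.
#' @param epsilon positive guard for the divisions.
#' @return The corrected `scalar_volume`.
#' @export
correct_intensity <- function(vol, mask, sigma_mm = 2, epsilon = 1e-6) {
  stop_if_grid_mismatch(vol, mask, "volume and mask")
  if (sigma_mm <= 0) abort("`sigma_mm` must be positive")
  m <- mask$values > 0L
  if (!any(m)) abort("`mask` is empty")
  if (any(vol$values[m] < 0)) abort("`vol` must be non-negative inside the mask")
  sigma_vox <- sigma_mm / vol$grid$spacing
  s <- smooth_gaussian(vol$values * m, sigma_vox)
  w <- smooth_gaussian(m * 1.0, sigma_vox)
  field <- s / pmax(w, epsilon)
  corrected <- (vol$values / pmax(field, epsilon)) * m
  mean_in <- mean(vol$values[m])
  mean_out <- mean(corrected[m])
  if (mean_out > 0) corrected <- corrected * (mean_in / mean_out)
  scalar_volume(corrected, vol$grid)
}

#' Non-linear intensity matching between co-registered scans
#'
#' Estimates a monotone piecewise-linear intensity mapping from a source scan
#' onto a target scan: 100,000 voxel locations are sampled uniformly; the
#' source samples are sorted and cut into consecutive batches of 29 (the
#' trailing partial batch is dropped); for each batch the median of the
#' co-located target values is computed, the sample pair whose target value
#' is closest to that median is found, and that pair's source intensity
#' becomes a control point mapped to the batch median. Target ordinates are
#' made non-decreasing (cumulative maximum) so the mapping is monotone;
#' extrapolation clamps to the end values.
#'
#' @param source,target `scalar_volume`s on one grid (rigidly aligned
#'   upstream).
#' @param n_samples voxel locations to sample.
#' @param batch batch size for the quantile grouping.
#' @param seed integer seed.
#' @param mask optional [binary_mask()] restricting the sampled locations.
#' @return An object of class `intensity_mapping` with a tibble of control
#'   points; apply it with [apply_mapping()].
#' @export
match_intensity <- function(source, target, n_samples = 100000L, batch = 29L,
                            seed = 1L, mask = NULL) {
  stop_if_grid_mismatch(source, target, "source and target")
  if (n_samples < batch) abort("`n_samples` must be at least one batch")
  set.seed(seed)
  pool <- if (is.null(mask)) seq_along(source$values) else which(mask$values > 0L)
  locs <- sample(pool, n_samples, replace = n_samples > length(pool))
  sv <- source$values[locs]
  tv <- target$values[locs]
  if (max(sv) - min(sv) < .Machine$double.eps) {
    warn("constant source image: degenerate single-point mapping")
    cp <- tibble(source = sv[1], target = median(tv))
    return(structure(list(control_points = cp), class = "intensity_mapping"))
  }
  ord <- order(sv)
  sv <- sv[ord]
  tv <- tv[ord]
  n_batches <- length(sv) %/% batch
  grp <- rep(seq_len(n_batches), each = batch)
  keep <- seq_len(n_batches * batch)
  sv <- sv[keep]
  tv <- tv[keep]
  src_pts <- numeric(n_batches)
  tgt_pts <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    i <- which(grp == b)
    med <- median(tv[i])
    pick <- i[which.min(abs(tv[i] - med))]
    src_pts[b] <- sv[pick]
    tgt_pts[b] <- med
  }
  ord2 <- order(src_pts)
  src_pts <- src_pts[ord2]
  tgt_pts <- cummax(tgt_pts[ord2])
  dup <- !duplicated(src_pts)
  cp <- tibble(source = src_pts[dup], target = tgt_pts[dup])
  structure(list(control_points = cp), class = "intensity_mapping")
}

#' @rdname match_intensity
#' @param mapping an `intensity_mapping`.
#' @param vol the `scalar_volume` to transform.
#' @export
apply_mapping <- function(mapping, vol) {
  cp <- mapping$control_points
  if (nrow(cp) == 1) {
    vol$values[] <- cp$target[1]
    return(vol)
  }
  vol$values[] <- approx(cp$source, cp$target, xout = as.vector(vol$values),
                         rule = 2)$y
  vol
}

#' Combine the scans of one session
#'
#' Matches every scan's intensity distribution onto the first scan of the
#' session (the reference) and returns the voxel-wise arithmetic mean. The
#' result depends on which scan comes first; callers choose the reference by
#' ordering the input.
#'
#' @param volumes list of `scalar_volume`s on one grid (>= 1).
#' @param seed integer seed for the matching subsample.
#' @param n_samples,batch passed to [match_intensity()].
#' @return A `scalar_volume`.
#' @export
combine_session <- function(volumes, seed = 1L, n_samples = 100000L, batch = 29L) {
  if (length(volumes) == 0) abort("`volumes` must contain at least one scan")
  ref <- volumes[[1]]
  if (length(volumes) == 1) return(ref)
  acc <- ref$values
  for (k in 2:length(volumes)) {
    stop_if_grid_mismatch(ref, volumes[[k]], "session scans")
    mp <- match_intensity(volumes[[k]], ref, n_samples, batch, seed = seed + k)
    acc <- acc + apply_mapping(mp, volumes[[k]])$values
  }
  scalar_volume(acc / length(volumes), ref$grid)
}
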