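#' Voxel grid geometry
#'
#' A `vox_grid` records the geometry shared by all volumes of one scanning
#' session: the number of voxels per axis, the voxel size in millimetres, and
#' the orientation of the voxel axes relative to the canonical
#' right/anterior/superior (RAS) anatomical frame. Orientation is stored as an
#' axis permutation plus per-axis flip flags; `perm[a]` names the RAS world
#' axis that voxel axis `a` runs along, and `flip[a]` indicates it runs in the
#' negative world direction.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, millimetres per voxel (all > 0).
#'   A scalar is recycled to the three axes.
#' @param perm permutation of `1:3` mapping voxel axes to world axes.
#' @param flip logical vector of length 3, per-axis direction flips.
#' @return An object of class `vox_grid`.
#' @examples
#' vox_grid(c(64, 64, 64), 0.5)
#' @export
vox_grid <- function(dims, spacing = 1, perm = 1:3, flip = c(FALSE, FALSE, FALSE)) {
  dims <- as.integer(dims)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(dims) != 3 || any(dims < 1)) {
    abort("`dims` must be 3 integers >= 1")
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive reals")
  }
  check_perm(perm)
  structure(
    list(dims = dims, spacing = as.numeric(spacing),
         perm = as.integer(perm), flip = as.logical(flip)),
    class = "vox_grid"
  )
}

check_perm <- function(perm) {
  if (length(perm) != 3 || !setequal(perm, 1:3)) {
    abort("`perm` must be a permutation of 1:3")
  }
  invisible(perm)
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @rdname vox_grid
#' @param x object to test.
#' @export
is_vox_grid <- function(x) inherits(x, "vox_grid")

#' Test two grids for compatibility
#'
#' Dims must match exactly; spacings within 1e-6 mm. Every multi-volume
#' operation in the package calls this before touching voxel data, because
#' registration and resampling happen upstream of the package.
#'
#' @param a,b `vox_grid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
grids_compatible <- function(a, b) {
  identical(a$dims, b$dims) && all(abs(a$spacing - b$spacing) < 1e-6)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  ga <- if (is_vox_grid(a)) a else a$grid
  gb <- if (is_vox_grid(b)) b else b$grid
  if (!grids_compatible(ga, gb)) {
    abort(sprintf("%s are on different grids (dims or spacing mismatch)", what))
  }
  invisible(TRUE)
}

#' Voxel volume in cubic millimetres
#' @param grid a `vox_grid`.
#' @return scalar, mm^3 per voxel.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Scalar and label volumes
#'
#' `scalar_volume()` wraps a 3D array of finite real intensities (the carrier
#' for T1-weighted, T2-weighted and bias-field images); `label_volume()` wraps
#' a 3D array of non-negative integer labels (0 = unlabeled background).
#' `binary_mask()` is a label volume restricted to values {0, 1}.
#'
#' @param values numeric 3D array (scalar) or integer-valued 3D array (labels).
#' @param grid a `vox_grid` whose dims match `dim(values)`; a bare grid built
#'   from `dim(values)` at `spacing` is created when omitted.
#' @param spacing used only when `grid` is missing.
#' @return An object of class `scalar_volume` or `label_volume` (binary masks
#'   carry the extra class `binary_mask`), a list with elements `values` and
#'   `grid`.
#' @examples
#' v <- scalar_volume(array(rnorm(8^3), c(8, 8, 8)), spacing = 0.5)
#' m <- binary_mask(array(0L, c(8, 8, 8)), v$grid)
#' @export
scalar_volume <- function(values, grid = NULL, spacing = 1) {
  if (length(dim(values)) != 3) abort("`values` must be a 3D array")
  if (any(!is.finite(values))) abort("scalar volumes must be finite everywhere")
  grid <- grid %||% vox_grid(dim(values), spacing)
  if (!identical(as.integer(dim(values)), grid$dims)) {
    abort("value count does not match the grid dims")
  }
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "scalar_volume")
}

#' @rdname scalar_volume
#' @export
label_volume <- function(values, grid = NULL, spacing = 1) {
  if (length(dim(values)) != 3) abort("`values` must be a 3D array")
  if (any(!is.finite(values)) || any(values != round(values)) || any(values < 0)) {
    abort("labels must be finite non-negative integers")
  }
  grid <- grid %||% vox_grid(dim(values), spacing)
  if (!identical(as.integer(dim(values)), grid$dims)) {
    abort("label count does not match the grid dims")
  }
  storage.mode(values) <- "integer"
  structure(list(values = values, grid = grid), class = "label_volume")
}

#' @rdname scalar_volume
#' @export
binary_mask <- function(values, grid = NULL, spacing = 1) {
  lv <- label_volume(values, grid, spacing)
  if (any(lv$values > 1L)) abort("a binary mask may only contain 0 and 1")
  class(lv) <- c("binary_mask", class(lv))
  lv
}

#' @rdname scalar_volume
#' @export
tissue_map <- function(values, grid = NULL, spacing = 1) {
  lv <- label_volume(values, grid, spacing)
  if (any(lv$values > 3L)) {
    abort("tissue maps use codes 0 (background), 1 (CSF), 2 (GM), 3 (WM)")
  }
  class(lv) <- c("tissue_map", class(lv))
  lv
}

is_volume <- function(x) inherits(x, c("scalar_volume", "label_volume"))

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %d x %d x %d, range [%.4g, %.4g]\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<%s> %d x %d x %d, %d labeled voxels, %d distinct labels\n",
              class(x)[1], dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values > 0L), length(setdiff(unique(as.vector(x$values)), 0L))))
  invisible(x)
}

flip_axis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Reorient a volume
#'
#' Permutes and flips the voxel axes, e.g. to bring manually positioned
#' hemisphere scans into one common orientation before any multi-volume step.
#' New axis `a` of the output is old axis `perm[a]`, reversed when `flip[a]`
#' is `TRUE`. Dims, spacing and the grid orientation record are permuted
#' consistently; the voxel count is conserved.
#'
#' @param vol a `scalar_volume` or `label_volume`.
#' @param perm permutation of `1:3`.
#' @param flip logical vector of length 3.
#' @return A volume of the same kind.
#' @seealso [reorient_inverse()] for the inverse transform parameters.
#' @export
reorient <- function(vol, perm, flip = c(FALSE, FALSE, FALSE)) {
  if (!is_volume(vol)) abort("`vol` must be a scalar or label volume")
  check_perm(perm)
  a <- aperm(vol$values, perm)
  for (ax in which(flip)) a <- flip_axis(a, ax)
  g <- vol$grid
  newflip <- xor(g$flip[perm], flip)
  grid <- vox_grid(g$dims[perm], g$spacing[perm], perm = g$perm[perm], flip = newflip)
  out <- vol
  out$values <- a
  out$grid <- grid
  out
}

#' @rdname reorient
#' @return `reorient_inverse()` returns `list(perm, flip)` such that applying
#'   it after `(perm, flip)` restores the original volume.
#' @export
reorient_inverse <- function(perm, flip = c(FALSE, FALSE, FALSE)) {
  check_perm(perm)
  inv <- order(perm)
  list(perm = inv, flip = flip[inv])
}
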