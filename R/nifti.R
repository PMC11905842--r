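ORIENT_LETTERS <- list(
  R = c(1L, 1L), L = c(1L, -1L),
  A = c(2L, 1L), P = c(2L, -1L),
  S = c(3L, 1L), I = c(3L, -1L)
)

orient_from_code <- function(code) {
  letters3 <- strsplit(code, "")[[1]]
  if (length(letters3) != 3 || !all(letters3 %in% names(ORIENT_LETTERS))) {
    abort(sprintf("unrecognised orientation code '%s'", code))
  }
  m <- vapply(letters3, function(l) ORIENT_LETTERS[[l]], integer(2))
  perm <- m[1, ]
  if (!setequal(perm, 1:3)) abort(sprintf("degenerate orientation '%s'", code))
  list(perm = as.integer(perm), flip = m[2, ] < 0)
}

orient_to_code <- function(perm, flip) {
  pos <- c("R", "A", "S")
  neg <- c("L", "P", "I")
  paste(ifelse(flip, neg[perm], pos[perm]), collapse = "")
}

#' Read a NIfTI volume
#'
#' Reads a single-file NIfTI image into a [scalar_volume()] or
#' [label_volume()]. The grid is populated from the header: dims and voxel
#' spacing from `pixdim`, orientation (axis permutation + flips relative to
#' RAS) from the closest-axis decomposition of the affine.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expect `"scalar"` or `"label"`. Requesting labels from a file with
#'   non-integer data is an error.
#' @return A `scalar_volume` or `label_volume`.
#' @export
read_volume <- function(path, expect = c("scalar", "label")) {
  expect <- match.arg(expect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) abort("expected a 3D single-frame NIfTI image")
  aff <- RNifti::xform(img)
  if (abs(det(aff[1:3, 1:3])) < 1e-12) abort("degenerate affine in NIfTI header")
  ori <- orient_from_code(RNifti::orientation(img))
  grid <- vox_grid(dim(img), RNifti::pixdim(img), perm = ori$perm, flip = ori$flip)
  arr <- array(as.vector(img), dim(img))
  if (expect == "scalar") {
    scalar_volume(arr, grid)
  } else {
    if (any(arr != round(arr))) {
      abort(sprintf("label volume expected but %s contains non-integer values", path))
    }
    label_volume(arr, grid)
  }
}

#' Write a volume as NIfTI
#'
#' Scalars are stored as 32-bit floats, labels as 32-bit integers (lossless
#' for every label id used by the pipeline). The header encodes the grid
#' spacing and orientation.
#'
#' @param vol a `scalar_volume` or `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!is_volume(vol)) abort("`vol` must be a scalar or label volume")
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: %s", dir))
  g <- vol$grid
  datatype <- if (inherits(vol, "label_volume")) "int32" else "float"
  # affine: voxel axis a advances along world axis perm[a], negated when flipped
  aff <- matrix(0, 4, 4)
  for (a in 1:3) {
    aff[g$perm[a], a] <- (if (g$flip[a]) -1 else 1) * g$spacing[a]
  }
  aff[4, 4] <- 1
  vals <- vol$values
  if (inherits(vol, "label_volume")) storage.mode(vals) <- "integer"
  attr(vals, "pixdim") <- g$spacing
  img <- RNifti::asNifti(vals, internal = FALSE)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
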