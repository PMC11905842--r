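# Separable neighborhood filters on 3D arrays, implemented as banded kernel
# matrices applied along each axis in turn (zero boundary). Fast enough for
# the package's grid sizes and exactly reproducible.

axis_kernel_matrix <- function(n, taps, offsets) {
  m <- matrix(0, n, n)
  for (t in seq_along(offsets)) {
    i <- seq_len(n)
    j <- i + offsets[t]
    ok <- j >= 1 & j <= n
    m[cbind(i[ok], j[ok])] <- m[cbind(i[ok], j[ok])] + taps[t]
  }
  m
}

apply_axis_filter <- function(arr, axis, taps, offsets) {
  d <- dim(arr)
  ord <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, ord)
  dim(a) <- c(d[axis], prod(d[-axis]))
  a <- axis_kernel_matrix(d[axis], taps, offsets) %*% a
  dim(a) <- d[ord]
  aperm(a, order(ord))
}

sep_filter <- function(arr, taps_list, offsets_list) {
  for (axis in 1:3) {
    arr <- apply_axis_filter(arr, axis, taps_list[[axis]], offsets_list[[axis]])
  }
  arr
}

# Gaussian smoothing with per-axis sigma in voxels, kernel truncated at 4 sigma,
# taps normalised to unit sum (so constants are preserved away from borders).
gaussian_taps <- function(sigma_vox) {
  if (sigma_vox <= 0) return(list(taps = 1, offsets = 0L))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  off <- seq.int(-r, r)
  taps <- dnorm(off, sd = sigma_vox)
  list(taps = taps / sum(taps), offsets = off)
}

smooth_gaussian <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  tl <- lapply(sigma_vox, gaussian_taps)
  sep_filter(arr, lapply(tl, `[[`, "taps"), lapply(tl, `[[`, "offsets"))
}

# Count of TRUE/nonzero values in the centered (2r+1)^3 box around each voxel,
# clipped at the borders.
box_count <- function(arr, r) {
  taps <- rep(1, 2 * r + 1)
  off <- seq.int(-r, r)
  storage.mode(arr) <- "double"
  out <- sep_filter(arr, list(taps, taps, taps), list(off, off, off))
  round(out)
}

# Unnormalised Gaussian vote weights exp(-d^2 / (2 sigma^2)) accumulated over
# the centered (2r+1)^3 neighborhood (separable in the squared distance).
gauss_vote_filter <- function(arr, r, sigma) {
  off <- seq.int(-r, r)
  taps <- exp(-off^2 / (2 * sigma^2))
  storage.mode(arr) <- "double"
  sep_filter(arr, list(taps, taps, taps), list(off, off, off))
}
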