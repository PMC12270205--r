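# Gradient-based 3D saliency: voxelwise magnitude of the derivative of the
# predicted brain age with respect to the input intensities (first-order
# Taylor importance), Gaussian smoothing, group means, difference maps, and
# atlas-region summaries.

# Separable Gaussian smoothing with reflecting boundaries. sigma = 0 is the
# identity.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

reflect_index <- function(i, n) {
  # reflect about the edges (1 and n), period 2n - 2
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  j <- ifelse(j < 0L, j + 2L * n - 2L, j)
  ifelse(j < n, j + 1L, 2L * n - j - 1L)
}

smooth_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  for (o in seq(-r, r)) {
    idx <- reflect_index(seq_len(n) + o, n)
    shifted <- switch(axis,
                      vol[idx, , , drop = FALSE],
                      vol[, idx, , drop = FALSE],
                      vol[, , idx, drop = FALSE])
    out <- out + kernel[o + r + 1L] * shifted
  }
  out
}

#' Gaussian smoothing of a 3D map
#'
#' Separable Gaussian filter with reflecting boundary handling, which
#' preserves the map total exactly for symmetric kernels up to the reflected
#' mass at the edges. `sigma = 0` returns the input unchanged.
#'
#' @param vol 3D array.
#' @param sigma Smoothing width in voxels.
#' @return Smoothed 3D array.
#' @export
gaussian_smooth_3d <- function(vol, sigma) {
  stopifnot(length(dim(vol)) == 3L, sigma >= 0)
  if (sigma == 0) return(vol)
  k <- gaussian_kernel_1d(sigma)
  for (axis in 1:3) vol <- smooth_axis(vol, k, axis)
  vol
}

#' Gradient saliency map for one scan
#'
#' Backpropagates the scalar brain-age output to the input voxels in
#' evaluation mode, takes the absolute value (importance ranking; set
#' `signed = TRUE` to keep signs), and applies Gaussian smoothing of width
#' `sigma` voxels. The network's head is a single scalar, so the gradient
#' target is that output; for hypothetical multi-output heads the
#' maximal-activation output would be selected.
#'
#' @param model A trained [build_model()] object.
#' @param volume 3D array (one scan) or a 1 x n_voxels matrix.
#' @param dims Spatial dimensions.
#' @param sigma Gaussian smoothing width in voxels (0 = no smoothing).
#' @param signed Keep the gradient sign instead of taking magnitudes.
#' @return A 3D array of class `saliency_volume` aligned to the input grid.
#' @export
saliency_volume <- function(model, volume, dims = dim(volume), sigma = 2,
                            signed = FALSE) {
  if (is.matrix(volume)) {
    stopifnot(nrow(volume) == 1L, ncol(volume) == prod(dims))
    x <- matrix(as.vector(volume), ncol = 1L)
  } else {
    stopifnot(length(dim(volume)) == 3L)
    dims <- dim(volume)
    x <- matrix(as.vector(volume), ncol = 1L)
  }
  fw <- net_forward(model, x, dims, 1L, training = FALSE)
  bw <- net_backward(fw$model, fw$state, 1, input_grad = TRUE)
  g <- array(bw$dx[, 1L], dims)
  if (!signed) g <- abs(g)
  g <- gaussian_smooth_3d(g, sigma)
  structure(g, class = c("saliency_volume", class(g)), sigma = sigma)
}

#' Voxelwise mean of saliency maps
#'
#' @param maps List of equally shaped 3D saliency arrays.
#' @return Their voxelwise arithmetic mean.
#' @export
group_mean_saliency <- function(maps) {
  if (!length(maps)) stop("empty list of saliency maps")
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), d)) stop("saliency maps must share a shape")
  }
  out <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  structure(out, class = c("saliency_volume", class(out)))
}

#' Signed difference of two mean saliency maps
#'
#' `A - B` voxelwise: positive values mark voxels with stronger saliency in
#' group A (e.g., the co-pathology subgroup) than in group B (e.g., the CU
#' reference).
#'
#' @param mean_a,mean_b Equally shaped 3D arrays.
#' @return Signed 3D difference array.
#' @export
difference_map <- function(mean_a, mean_b) {
  if (!identical(dim(mean_a), dim(mean_b))) stop("shape mismatch")
  structure(unclass(mean_a) - unclass(mean_b),
            class = c("saliency_volume", "array"))
}

#' Per-region mean saliency
#'
#' Averages map values within each labeled atlas region; background (label 0)
#' is excluded.
#'
#' @param map 3D array (saliency or difference map).
#' @param atlas A [synth_atlas()]-style atlas (list with integer `labels`
#'   array and `regions` data frame) on the same grid.
#' @return Data frame: region id, name, n_voxels, mean_saliency.
#' @export
region_summary <- function(map, atlas) {
  stopifnot(identical(dim(map), dim(atlas$labels)))
  lab <- as.vector(atlas$labels)
  v <- as.vector(map)
  keep <- lab > 0L
  sums <- tapply(v[keep], lab[keep], sum)
  counts <- tapply(v[keep], lab[keep], length)
  ids <- as.integer(names(sums))
  nm <- atlas$regions$name[match(ids, atlas$regions$id)]
  data.frame(id = ids, name = nm, n_voxels = as.integer(counts),
             mean_saliency = as.numeric(sums / counts),
             stringsAsFactors = FALSE)
}
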