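#' Voxel indices of a named ROI
#'
#' @param vol an [activity_volume()] with labels.
#' @param name ROI name in `vol$rois`.
#' @return integer linear voxel indices.
#' @export
roi_voxels <- function(vol, name) {
  if (!name %in% names(vol$rois))
    stop("unknown ROI '", name, "'; available: ",
         paste(names(vol$rois), collapse = ", "))
  r <- vol$rois[[name]]
  if (!is.null(r$voxels)) return(as.integer(r$voxels))
  which(vol$labels == r$label)
}

# mean / sd of image values over voxel indices
.roi_stats <- function(image, idx) {
  v <- as.numeric(image)[idx]
  c(mean = mean(v), sd = sd(v))
}

#' Normalised root-mean-square error
#'
#' `sqrt(sum((x - x_true)^2)) / sqrt(sum(x_true^2))`.
#'
#' @param x,x_true images (arrays or vectors) on the same grid.
#' @return dimensionless NRMSE.
#' @export
nrmse <- function(x, x_true) {
  x <- as.numeric(x); x_true <- as.numeric(x_true)
  if (length(x) != length(x_true)) stop("image sizes differ")
  denom <- sqrt(sum(x_true^2))
  if (denom == 0) stop("all-zero truth image")
  sqrt(sum((x - x_true)^2)) / denom
}

#' Contrast recovery coefficient
#'
#' `CRC(%) = ((mu_rod - mu_bck) / mu_bck) / (C - 1) * 100`, 100 percent for
#' perfect recovery of the true rod-to-background ratio `C`.
#'
#' @param image reconstructed image (array or vector).
#' @param rod,bck voxel indices of the rod/lesion and background ROIs.
#' @param C true concentration ratio (> 1).
#' @return CRC in percent.
#' @export
crc <- function(image, rod, bck, C) {
  stopifnot(C > 1)
  mu_r <- .roi_stats(image, rod)["mean"]
  mu_b <- .roi_stats(image, bck)["mean"]
  if (mu_b == 0) stop("zero-mean background ROI")
  unname(((mu_r - mu_b) / mu_b) / (C - 1) * 100)
}

#' Contrast-to-noise ratio
#'
#' `|mu_roi - mu_bck| / sigma_bck`.
#'
#' @inheritParams crc
#' @param roi voxel indices of the target ROI.
#' @return dimensionless CNR.
#' @export
cnr <- function(image, roi, bck) {
  s <- .roi_stats(image, bck)
  if (s["sd"] == 0) stop("zero background standard deviation")
  unname(abs(.roi_stats(image, roi)["mean"] - s["mean"]) / s["sd"])
}

#' Noise coefficient
#'
#' `NC(%) = sigma_bck / mu_bck * 100`.
#'
#' @inheritParams crc
#' @return NC in percent.
#' @export
nc <- function(image, bck) {
  s <- .roi_stats(image, bck)
  if (s["mean"] == 0) stop("zero-mean background ROI")
  unname(s["sd"] / s["mean"] * 100)
}

#' CRC-NC curve over reconstruction iterations
#'
#' @param images list of image vectors/arrays (one per iteration).
#' @inheritParams crc
#' @return data frame with one `(iteration, nc, crc)` row per image.
#' @export
crc_nc_curve <- function(images, rod, bck, C) {
  stopifnot(length(images) >= 1)
  data.frame(iteration = seq_along(images),
             nc = vapply(images, nc, numeric(1), bck = bck),
             crc = vapply(images, crc, numeric(1), rod = rod, bck = bck,
                          C = C))
}

#' Uptake ratio
#'
#' Mean counts in a VOI over mean counts in the reference VOI (an 8-mm
#' sphere in the healthy cerebellum for the brain studies).
#'
#' @inheritParams crc
#' @param voi,ref voxel indices.
#' @return dimensionless UR.
#' @export
uptake_ratio <- function(image, voi, ref) {
  mu_ref <- .roi_stats(image, ref)["mean"]
  if (mu_ref == 0) stop("zero-mean reference VOI")
  unname(.roi_stats(image, voi)["mean"] / mu_ref)
}

#' Inter-hemispheric asymmetry index
#'
#' `(mu_left - mu_right) / mu_right`, signed.
#'
#' @inheritParams crc
#' @param left,right voxel indices of the paired VOIs.
#' @return dimensionless AI.
#' @export
asymmetry_index <- function(image, left, right) {
  mu_r <- .roi_stats(image, right)["mean"]
  if (mu_r == 0) stop("zero-mean right VOI")
  unname((.roi_stats(image, left)["mean"] - mu_r) / mu_r)
}

#' Iteration with the maximum CNR
#'
#' @inheritParams crc_nc_curve
#' @param roi voxel indices of the target ROI.
#' @return 1-based iteration index (earliest on ties).
#' @export
best_cnr_iteration <- function(images, roi, bck) {
  stopifnot(length(images) >= 1)
  which.max(vapply(images, cnr, numeric(1), roi = roi, bck = bck))
}
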