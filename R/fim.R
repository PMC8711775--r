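#' Fisher-information column image
#'
#' For the linear Poisson model the Fisher information matrix is
#' `J = A^T diag(1/ybar) A` with `ybar` the mean projection of a uniform
#' object.  The column for a target voxel `l`, rearranged on the object
#' grid, visualises the weighted correlation between the system response to
#' the target voxel and to every other voxel: its spread measures spatial
#' resolution, its peak the information collected about the target.
#'
#' @param srm a [build_srm()] result.
#' @param ybar mean projections of the uniform object (a `projection_set`
#'   or bin vector); bins with `ybar == 0` are excluded.
#' @param target world 3-vector (mm, snapped to the nearest mask voxel) or
#'   a mask-column index.
#' @return an object of class `fim_image`: `$values` (3-D array), `$peak`,
#'   `$target_ijk` (1-based grid indices).
#' @export
fim_column <- function(srm, ybar, target) {
  yb <- if (inherits(ybar, "projection_set")) ybar$values else
    as.numeric(ybar)
  if (length(yb) != nrow(srm$A)) stop("ybar length does not match srm rows")
  if (length(target) == 3) {
    ctr <- .grid_centers(srm$grid, srm$mask_idx)
    l <- which.min(colSums((t(ctr) - as.numeric(target))^2))
    if (sqrt(sum((ctr[l, ] - target)^2)) > srm$grid$voxel * 2)
      stop("target point lies outside the masked FOV")
  } else {
    l <- as.integer(target)
    if (l < 1 || l > ncol(srm$A)) stop("target column index out of range")
  }
  al <- srm$A[, l]
  w <- ifelse(yb > 0, al / yb, 0)
  J <- as.numeric(Matrix::crossprod(srm$A, w))
  arr <- array(0, srm$grid$n)
  arr[srm$mask_idx] <- J
  vox <- srm$mask_idx[l]
  n <- srm$grid$n
  ijk <- c((vox - 1) %% n[1], ((vox - 1) %/% n[1]) %% n[2],
           (vox - 1) %/% (n[1] * n[2])) + 1L
  structure(list(values = arr, grid = srm$grid, peak = J[l],
                 target_col = l, target_ijk = ijk),
            class = "fim_image")
}

# FWHM of a sampled 1-D profile by linear interpolation of the
# half-maximum crossings on both sides of the peak
.profile_fwhm <- function(pos, vals, peak_at = which.max(vals)) {
  pk <- vals[peak_at]
  if (pk <= 0) stop("profile has a nonpositive peak")
  half <- pk / 2
  cross <- function(side) {
    idx <- if (side < 0) seq(peak_at, 1) else seq(peak_at, length(vals))
    below <- which(vals[idx] < half)
    if (!length(below))
      stop("profile never falls below half maximum within the grid")
    b <- idx[below[1]]; a <- b - side   # last sample still above half
    pos[a] + (half - vals[a]) * (pos[b] - pos[a]) / (vals[b] - vals[a])
  }
  abs(cross(+1) - cross(-1))
}

#' Full width at half maximum of a profile
#'
#' For a `fim_image`, extracts the 1-D profile through the target voxel
#' along the requested direction; a plain numeric profile can be supplied
#' with its sample positions.
#'
#' @param x a `fim_image` or a numeric profile.
#' @param direction `"lateral"` (x), `"ventrodorsal"` (y) or
#'   `"craniocaudal"` (z).
#' @param pos sample positions (mm) when `x` is a numeric profile.
#' @return FWHM in mm.
#' @export
profile_fwhm <- function(x, direction = c("lateral", "ventrodorsal",
                                          "craniocaudal"), pos = NULL) {
  if (is.numeric(x)) {
    if (is.null(pos)) pos <- seq_along(x)
    return(.profile_fwhm(pos, x))
  }
  stopifnot(inherits(x, "fim_image"))
  direction <- match.arg(direction)
  ijk <- x$target_ijk
  ax <- .grid_axes(x$grid)
  v <- switch(direction,
              lateral = x$values[, ijk[2], ijk[3]],
              ventrodorsal = x$values[ijk[1], , ijk[3]],
              craniocaudal = x$values[ijk[1], ijk[2], ])
  d <- switch(direction, lateral = 1L, ventrodorsal = 2L,
              craniocaudal = 3L)
  .profile_fwhm(ax[[d]], v, peak_at = ijk[d])
}

#' Ratio of FIM image peaks
#'
#' @param image_a,image_b `fim_image`s for the same target voxel and grid.
#' @return `peak(a) / peak(b)`.
#' @export
peak_ratio <- function(image_a, image_b) {
  stopifnot(inherits(image_a, "fim_image"), inherits(image_b, "fim_image"))
  if (!identical(image_a$target_ijk, image_b$target_ijk))
    stop("FIM images target different voxels")
  if (image_b$peak == 0) stop("zero peak in the reference image")
  image_a$peak / image_b$peak
}
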