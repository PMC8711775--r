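#' Acquisition settings
#'
#' Converts activity concentrations into emitted photons.  When the phantom
#' carries a `total_photons` normalisation that takes precedence; otherwise
#' activity x imaging time x photon yield is used (0.885 photons per decay
#' for the 140.5-keV Tc-99m emission).
#'
#' @param time_min imaging time in minutes.
#' @param yield photons per decay.
#' @param total_photons override: total emitted photons, distributed
#'   proportionally to activity.
#' @return a list of class `acquisition`.
#' @export
acquisition <- function(time_min = 30, yield = 0.885, total_photons = NULL) {
  structure(list(time_min = time_min, yield = yield,
                 total_photons = total_photons), class = "acquisition")
}

# emitted photons per voxel for a phantom under an acquisition
.emitted_photons <- function(vol, acq) {
  act <- as.numeric(vol$activity)
  tp <- acq$total_photons %||% vol$total_photons
  if (!is.null(tp)) return(tp * act / sum(act))
  t_s <- acq$time_min * 60
  switch(vol$units,
         uCi_per_mL = act * (vol$grid$voxel^3 / 1000) * .bq_per_uci * t_s *
           acq$yield,
         mCi_total_scaled = act * 1000 * .bq_per_uci * t_s * acq$yield,
         act)  # "relative": unit emitters
}

#' Forward-project a phantom through a system matrix
#'
#' Mean projections `ybar = A x` with `x` the per-voxel emitted photons.
#'
#' @param srm a [build_srm()] result.
#' @param vol an [activity_volume()] on the same grid.
#' @param acq an [acquisition()].
#' @return an object of class `projection_set` holding the mean bin values.
#' @export
forward_project <- function(srm, vol, acq = acquisition()) {
  if (!identical(vol$grid$n, srm$grid$n) ||
      !isTRUE(all.equal(vol$grid$voxel, srm$grid$voxel)))
    stop("phantom grid does not match the system matrix grid")
  x <- .emitted_photons(vol, acq)[srm$mask_idx]
  ybar <- as.numeric(srm$A %*% x)
  structure(list(values = ybar, bins = srm$bins, n_bins = nrow(srm$A),
                 counts = FALSE, acquisition = acq, seed = NULL),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat("projection set:", x$n_bins, "bins,",
      if (x$counts) "Poisson counts" else "mean intensities",
      sprintf("(total %.4g)", sum(x$values)), "\n")
  invisible(x)
}

#' Add Poisson counting noise to mean projections
#'
#' @param mean_ps a mean-intensity `projection_set`.
#' @param seed RNG seed; the caller's RNG state is preserved.
#' @return a counts-mode `projection_set`.
#' @export
add_poisson <- function(mean_ps, seed = 1L) {
  stopifnot(inherits(mean_ps, "projection_set"))
  if (any(!is.finite(mean_ps$values)) || any(mean_ps$values < 0))
    stop("mean projections must be finite and nonnegative")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  out <- mean_ps
  out$values <- as.numeric(rpois(length(mean_ps$values), mean_ps$values))
  out$counts <- TRUE
  out$seed <- seed
  out
}

#' Extract one MCE's projection image
#'
#' @param ps a `projection_set`.
#' @param mce MCE index.
#' @param layer DOI layer (0-based) or `NULL` to sum layers.
#' @return a `nu x nv` matrix.
#' @export
projection_image <- function(ps, mce = 1L, layer = NULL) {
  b <- ps$bins
  per <- b$nu * b$nv * b$n_lay
  v <- ps$values[(mce - 1) * per + seq_len(per)]
  arr <- array(v, c(b$n_lay, b$nv, b$nu))  # layer fastest, then v, then u
  img <- if (is.null(layer)) apply(arr, c(3, 2), sum) else
    t(arr[layer + 1L, , ])
  img
}

#' Render the projection of an exact point source through one MCE
#'
#' High-resolution mean projection of an off-grid point, for aperture
#' footprint studies: a lofthole projects a disc, a micro-slit a line
#' segment oriented with its rotation, a micro-ring a narrow annulus.
#'
#' @param helmet,det helmet and detector.
#' @param aperture an [aperture_spec()].
#' @param source_position world 3-vector (mm), inside the FOV.
#' @param mce MCE index to project through.
#' @param supersample sub-targets per pixel side.
#' @param options a [response_options()].
#' @return a `n_pix x n_pix` matrix of mean detection probabilities.
#' @export
render_point_projection <- function(helmet, det = detector_spec(), aperture,
                                    source_position, mce = 1L,
                                    supersample = 3L,
                                    options = response_options()) {
  if (sum(source_position^2) > helmet$fov_radius^2)
    stop("source outside the FOV")
  cpp_render_point_projection(as.numeric(source_position),
                              .mce_matrix(helmet, mce)[1, ],
                              .ap_params(aperture),
                              .det_list(det, helmet$f),
                              as.integer(supersample), unclass(options))
}
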