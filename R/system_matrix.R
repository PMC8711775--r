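#' Object-space voxel grid
#'
#' The standard grid is 96 x 96 x 96 voxels of 2 mm, centred on the FOV
#' centre: voxel centres lie at `((i + 0.5) - n/2) * voxel` per axis
#' (0-based i).
#'
#' @param n voxel counts, scalar or length-3 (x, y, z).
#' @param voxel isotropic voxel size in mm.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(n = 96L, voxel = 2) {
  n <- as.integer(rep(n, length.out = 3))
  stopifnot(all(n >= 1), voxel > 0)
  structure(list(n = n, voxel = voxel), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume grid:", paste(x$n, collapse = " x "), "voxels of", x$voxel,
      "mm\n")
  invisible(x)
}

# per-axis voxel-centre coordinates
.grid_axes <- function(grid) {
  lapply(grid$n, function(n) ((seq_len(n) - 0.5) - n / 2) * grid$voxel)
}

# n_voxels x 3 matrix of voxel centres for linear indices idx (column-major)
.grid_centers <- function(grid, idx = NULL) {
  ax <- .grid_axes(grid)
  if (is.null(idx)) idx <- seq_len(prod(grid$n))
  i <- (idx - 1L) %% grid$n[1]
  j <- ((idx - 1L) %/% grid$n[1]) %% grid$n[2]
  k <- (idx - 1L) %/% (grid$n[1] * grid$n[2])
  cbind(ax[[1]][i + 1L], ax[[2]][j + 1L], ax[[3]][k + 1L])
}

# 1-based index of the grid-centre voxel on each axis
.grid_center_index <- function(grid) floor(grid$n / 2) + 1L

#' Ray-tracing and detector-response options
#'
#' @param penetration model tungsten edge penetration (`FALSE` treats the
#'   aperture as a binary open/blocked mask).
#' @param detector_absorption model CZT absorption per DOI layer with the
#'   oblique chord length (`FALSE` assumes a perfect detector and implies a
#'   single collapsed bin per pixel).
#' @param collapse_doi sum the DOI layers into a single bin per pixel.
#' @param floor drop response entries below this detection probability.
#' @param object_attenuation `"none"` or `"water"` (uniform water inside the
#'   FOV sphere, one chord per voxel-MCE pair).
#' @param fov_radius FOV sphere radius in mm.
#' @param energy_kev working energy for the water attenuation table.
#' @return a list of class `response_options`.
#' @export
response_options <- function(penetration = TRUE, detector_absorption = TRUE,
                             collapse_doi = FALSE, floor = 1e-12,
                             object_attenuation = c("none", "water"),
                             fov_radius = 100, energy_kev = 140) {
  object_attenuation <- match.arg(object_attenuation)
  if (!detector_absorption) collapse_doi <- TRUE
  structure(list(penetration = penetration,
                 detector_abs = detector_absorption,
                 collapse_doi = collapse_doi, floor = floor,
                 mu_obj = if (object_attenuation == "water")
                   water_mu(energy_kev) else 0,
                 fov_radius = fov_radius),
            class = "response_options")
}

# detector descriptor for the C++ kernels; window = number of central
# full-resolution pixels per side kept (NULL = all), bin = binning factor
.det_list <- function(det, f, window = NULL, bin = 1L) {
  stopifnot(det$n_pix_u == det$n_pix_v)
  np <- det$n_pix_u
  w <- if (is.null(window)) np else as.integer(window)
  stopifnot(w >= bin, w <= np, w %% bin == 0)
  i0 <- as.integer((np - w) / 2)
  list(n_pix = np, pitch = det$pitch, f = f,
       n_lay = det$n_doi_layers, lay_t = det$layer_thickness,
       mu_det = det$mu_czt, iu0 = i0, iv0 = i0,
       nu = as.integer(w / bin), nv = as.integer(w / bin),
       bin = as.integer(bin))
}

#' Assign an aperture to every MCE of a helmet
#'
#' @param helmet a [build_helmet()] result.
#' @param x an [aperture_spec()] used for every MCE, or one of the variant
#'   names accepted by [aperture_defaults()], or `"lofthole_3type"` for the
#'   combined three-diameter lofthole collimator (0.5 / 1.5 / 3 mm loftholes
#'   assigned cyclically around each ring with a per-ring phase offset), or
#'   a list of `aperture_spec`s with an `assignment` attribute (integer per
#'   MCE).
#' @param seed seed for the random micro-slit rotation assignment.
#' @param mu_w tungsten attenuation override passed to the variant table.
#' @return an object of class `aperture_set` holding the per-MCE parameter
#'   matrix used by the ray tracer.
#' @export
aperture_set <- function(helmet, x, seed = 1L, mu_w = tungsten_mu(140)) {
  n <- nrow(helmet$mces)
  half_module <- 10
  if (is.character(x) && length(x) == 1 && x == "lofthole_3type") {
    specs <- lapply(c(0.5, 1.5, 3.0), function(d)
      aperture_spec("lofthole", diameter = d, mu_w = mu_w))
    ring <- helmet$mces$ring
    assignment <- integer(n)
    for (r in unique(ring)) {
      sel <- which(ring == r)
      assignment[sel] <- ((seq_along(sel) - 1 + r) %% 3) + 1L
    }
    params <- t(vapply(assignment, function(a)
      .ap_params(specs[[a]], half_module), numeric(12)))
    label <- "lofthole_3type"
  } else {
    if (is.character(x)) {
      label <- x
      x <- aperture_defaults(x, mu_w = mu_w)
    } else label <- x$kind
    stopifnot(inherits(x, "aperture_spec"))
    specs <- list(x)
    assignment <- rep(1L, n)
    base <- .ap_params(x, half_module)
    params <- matrix(base, n, 12, byrow = TRUE)
    if (x$kind == "micro_slit")
      params[, 11] <- assign_slit_rotations(n, seed) * pi / 180
  }
  structure(list(specs = specs, assignment = assignment, params = params,
                 label = label, seed = seed), class = "aperture_set")
}

.apset_params <- function(apset, idx = NULL) {
  if (is.null(idx)) apset$params else apset$params[idx, , drop = FALSE]
}

#' Single-voxel system sensitivity
#'
#' Sums the detection probability of photons emitted at the given points
#' over every MCE, pixel and DOI layer: the per-voxel column sum of the
#' system response matrix, computed without materialising the matrix.
#'
#' @param helmet,det,apset helmet, detector and [aperture_set()].
#' @param points n x 3 matrix (or 3-vector) of world coordinates, mm.
#' @param options a [response_options()].
#' @param percent return percentages instead of probabilities.
#' @return numeric vector of sensitivities, with the per-MCE breakdown in
#'   `attr(, "per_mce")`.
#' @export
point_sensitivity <- function(helmet, det = detector_spec(), apset, points,
                              options = response_options(), percent = FALSE) {
  points <- rbind(points)
  res <- cpp_point_sensitivity(points, .mce_matrix(helmet),
                               .apset_params(apset),
                               .det_list(det, helmet$f),
                               unclass(options))
  out <- res$total * if (percent) 100 else 1
  attr(out, "per_mce") <- res$per_mce * if (percent) 100 else 1
  out
}

#' Response column of a single voxel
#'
#' The point response function (PRF): the sparse column of the system
#' response matrix for one source position.  Bin ordering is MCE-major,
#' then detector pixel (u-major), then DOI layer.
#'
#' @inheritParams point_sensitivity
#' @param point source position, 3-vector (mm).
#' @param grid optional [volume_grid()]; if supplied the point must lie
#'   inside it.
#' @param window,bin optional central pixel window (full-resolution pixels
#'   per side) and binning factor.
#' @return a [Matrix::sparseVector-class] of detection probabilities.
#' @export
voxel_response <- function(helmet, det = detector_spec(), apset, point,
                           grid = NULL, options = response_options(),
                           window = NULL, bin = 1L) {
  point <- as.numeric(point)
  if (!is.null(grid)) {
    half <- grid$n * grid$voxel / 2
    if (any(abs(point) > half))
      stop("point lies outside the volume grid")
  }
  tr <- cpp_response_csc(rbind(point), .mce_matrix(helmet),
                         .apset_params(apset),
                         .det_list(det, helmet$f, window, bin),
                         unclass(options))
  Matrix::sparseVector(tr$x, tr$i + 1L, tr$nrow)
}

#' Streaming forward projection of weighted source points
#'
#' Accumulates `sum_i w_i a(., i)` over all detector bins without storing
#' the response matrix; used for mean projections of smooth objects (e.g.
#' the uniform-FOV object feeding Fisher-information images).
#'
#' @inheritParams point_sensitivity
#' @param points n x 3 source positions (mm).
#' @param weights per-point emission weights.
#' @param window,bin optional central pixel window and binning factor.
#' @return dense numeric bin vector (MCE-major, pixel u-major, DOI layer).
#' @export
project_points <- function(helmet, det = detector_spec(), apset, points,
                           weights = rep(1, nrow(rbind(points))),
                           options = response_options(), window = NULL,
                           bin = 1L) {
  points <- rbind(points)
  stopifnot(length(weights) == nrow(points))
  cpp_accumulate_bins(points, as.numeric(weights), .mce_matrix(helmet),
                      .apset_params(apset),
                      .det_list(det, helmet$f, window, bin),
                      unclass(options))
}

#' Build a sparse system response matrix
#'
#' Voxel-driven assembly: for every voxel centre in the (masked) grid, rays
#' are traced to every detector pixel centre of every MCE; each entry is
#' the product of the pixel solid-angle fraction, the tungsten transmission,
#' the per-DOI-layer CZT absorption along the oblique chord and (optionally)
#' uniform water attenuation in the object.
#'
#' @inheritParams voxel_response
#' @param grid a [volume_grid()].
#' @param mask logical array on the grid, or integer voxel indices, or
#'   `NULL` for all voxels inside the FOV sphere.
#' @param max_nnz resource guard: the build refuses if a pilot extrapolation
#'   estimates more stored entries than this.
#' @return an object of class `srm` wrapping a `dgCMatrix` (`$A`, bins x
#'   voxels) plus the grid, mask and bin-layout metadata.
#' @export
build_srm <- function(helmet, det = detector_spec(), apset,
                      grid = volume_grid(), mask = NULL,
                      options = response_options(), window = NULL, bin = 1L,
                      max_nnz = 3e8) {
  if (is.null(mask)) {
    ctr <- .grid_centers(grid)
    mask_idx <- which(rowSums(ctr^2) <= options$fov_radius^2)
  } else if (is.logical(mask) || is.array(mask)) {
    mask_idx <- which(as.logical(mask))
  } else mask_idx <- as.integer(mask)
  if (!length(mask_idx)) stop("empty voxel mask")
  centers <- .grid_centers(grid, mask_idx)
  dl <- .det_list(det, helmet$f, window, bin)
  # pilot estimate of the stored-entry count
  pilot <- centers[unique(round(seq(1, nrow(centers),
                                    length.out = min(8, nrow(centers))))), ,
                   drop = FALSE]
  pt <- cpp_response_csc(pilot, .mce_matrix(helmet),
                         .apset_params(apset), dl, unclass(options))
  est <- length(pt$x) / nrow(pilot) * nrow(centers)
  if (est > max_nnz)
    stop("estimated ", format(est, big.mark = ","), " stored entries exceed ",
         "max_nnz = ", format(max_nnz, big.mark = ","),
         "; coarsen the grid, restrict the mask, or bin/window the detector")
  tr <- cpp_response_csc(centers, .mce_matrix(helmet),
                         .apset_params(apset), dl, unclass(options))
  A <- methods::new("dgCMatrix", i = tr$i, p = tr$p, x = tr$x,
                    Dim = c(tr$nrow, tr$ncol))
  nlay <- if (options$collapse_doi) 1L else dl$n_lay
  structure(list(A = A, grid = grid, mask_idx = mask_idx,
                 det = det, options = options,
                 bins = list(n_mce = nrow(helmet$mces), nu = dl$nu,
                             nv = dl$nv, n_lay = nlay, bin = dl$bin,
                             iu0 = dl$iu0, f = dl$f,
                             ordering = "mce-major, pixel u-major, layer"),
                 aperture = apset$label,
                 n_mce = nrow(helmet$mces)),
            class = "srm")
}

#' @export
print.srm <- function(x, ...) {
  cat("system response matrix:", nrow(x$A), "bins x", ncol(x$A), "voxels, ",
      format(length(x$A@x), big.mark = ","), "stored entries\n")
  cat("  aperture:", x$aperture, "; DOI layers per pixel:", x$bins$n_lay,
      "\n")
  invisible(x)
}

#' Per-voxel sensitivity map from a system matrix
#'
#' Column sums of the stored matrix, arranged on the grid.
#'
#' @param srm an [build_srm()] result.
#' @return an object of class `sensitivity_map`: the 3-D `$values` array
#'   (zero outside the mask) on `$grid`.
#' @export
sensitivity_map <- function(srm) {
  v <- Matrix::colSums(srm$A)
  arr <- array(0, srm$grid$n)
  arr[srm$mask_idx] <- v
  structure(list(values = arr, grid = srm$grid, mask_idx = srm$mask_idx),
            class = "sensitivity_map")
}

#' Format sensitivities as percentages
#' @param x sensitivity values (probabilities).
#' @param digits significant digits.
#' @export
as_percent <- function(x, digits = 3) signif(100 * x, digits)

#' 1-D sensitivity profile through the FOV centre
#'
#' @param map a [sensitivity_map()].
#' @param axis `"craniocaudal"` (z), `"lateral"` (x) or `"ventrodorsal"`
#'   (y).
#' @return data frame with the axis coordinate (mm) and the sensitivity.
#' @export
sensitivity_profiles <- function(map,
                                 axis = c("craniocaudal", "lateral",
                                          "ventrodorsal")) {
  axis <- match.arg(axis)
  ic <- .grid_center_index(map$grid)
  ax <- .grid_axes(map$grid)
  v <- switch(axis,
              lateral = map$values[, ic[2], ic[3]],
              ventrodorsal = map$values[ic[1], , ic[3]],
              craniocaudal = map$values[ic[1], ic[2], ])
  d <- switch(axis, lateral = 1L, ventrodorsal = 2L, craniocaudal = 3L)
  data.frame(position_mm = ax[[d]], sensitivity = v)
}

#' Aperture signal-to-noise ratio under a uniform FOV source
#'
#' Rays are traced from every (strided) voxel centre inside the FOV sphere
#' to every detector pixel centre of one MCE.  Rays with zero tungsten path
#' are signal and count 1; penetrating rays are noise and contribute their
#' transmission `exp(-mu_w x)`.  The ratio of the two sums quantifies the
#' degree of aperture edge penetration.
#'
#' @param helmet,det helmet and detector.
#' @param aperture an [aperture_spec()].
#' @param grid source grid (defaults to the standard 96^3 x 2 mm grid).
#' @param stride source-voxel stride along each axis.
#' @param mce index of the MCE to trace (the metric is invariant under
#'   rigid rotation of the system; defaults to the top-cover module).
#' @return the SNR (possibly `Inf` when no ray penetrates), with the ray
#'   classification counts as attributes.
#' @export
aperture_snr <- function(helmet, det = detector_spec(), aperture,
                         grid = volume_grid(), stride = 4L, mce = 1L) {
  stopifnot(inherits(aperture, "aperture_spec"), stride >= 1)
  ax <- .grid_axes(grid)
  keep <- lapply(seq_len(3), function(d) seq(1, grid$n[d], by = stride))
  pts <- as.matrix(expand.grid(ax[[1]][keep[[1]]], ax[[2]][keep[[2]]],
                               ax[[3]][keep[[3]]]))
  pts <- pts[rowSums(pts^2) <= helmet$fov_radius^2, , drop = FALSE]
  res <- cpp_aperture_snr(pts, .mce_matrix(helmet, mce)[1, ],
                          .ap_params(aperture), .det_list(det, helmet$f))
  if (res$noise_sum == 0) {
    warning("no penetrating rays; aperture SNR is infinite")
    out <- Inf
  } else out <- res$n_signal / res$noise_sum
  attributes(out) <- c(attributes(out),
                       res[c("n_signal", "noise_sum", "n_noise",
                             "n_blocked")],
                       list(n_sources = nrow(pts)))
  out
}

#' Save / load a system response matrix as plain text
#'
#' The matrix is stored as a tab-separated triplet table written with full
#' double precision (so the round trip is bit exact) next to a JSON
#' metadata sidecar describing the grid, mask, bin layout and options.
#'
#' @param srm an `srm` object.
#' @param basename path prefix; writes `<basename>.tsv` and
#'   `<basename>.json`.
#' @return `save_srm` returns `basename` invisibly; `load_srm` returns the
#'   reconstructed `srm`.
#' @export
save_srm <- function(srm, basename) {
  A <- methods::as(srm$A, "TsparseMatrix")
  con <- file(paste0(basename, ".tsv"), "w")
  writeLines(sprintf("%d\t%d\t%.17g", A@i + 1L, A@j + 1L, A@x), con)
  close(con)
  meta <- list(nrow = nrow(srm$A), ncol = ncol(srm$A),
               grid_n = srm$grid$n, grid_voxel = srm$grid$voxel,
               mask_idx = srm$mask_idx, bins = srm$bins,
               aperture = srm$aperture, n_mce = srm$n_mce,
               options = unclass(srm$options),
               det = unclass(srm$det))
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basename)
}

#' @rdname save_srm
#' @export
load_srm <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"),
                              simplifyVector = TRUE)
  tab <- read.table(paste0(basename, ".tsv"), sep = "\t",
                    colClasses = c("integer", "integer", "numeric"))
  A <- Matrix::sparseMatrix(i = tab[[1]], j = tab[[2]], x = tab[[3]],
                            dims = c(meta$nrow, meta$ncol))
  det <- do.call(detector_spec, meta$det[c("n_pix_u", "n_pix_v", "pitch",
                                           "thickness", "n_doi_layers",
                                           "layer_thickness", "mu_czt")])
  opts <- structure(meta$options, class = "response_options")
  structure(list(A = A, grid = volume_grid(meta$grid_n, meta$grid_voxel),
                 mask_idx = as.integer(meta$mask_idx), det = det,
                 options = opts, bins = meta$bins,
                 aperture = meta$aperture, n_mce = meta$n_mce),
            class = "srm")
}
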