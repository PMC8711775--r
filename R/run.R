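#' Read and write activity/image volumes as NIfTI
#'
#' The affine encodes the isotropic voxel size with the origin at the
#' volume centre.
#'
#' @param x 3-D array or [activity_volume()].
#' @param path output `.nii` / `.nii.gz` path (use `.nii` for text-free
#'   archival pipelines).
#' @param voxel voxel size in mm (taken from the volume when available).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   list with the array and its [volume_grid()].
#' @export
write_volume <- function(x, path, voxel = 2) {
  arr <- if (inherits(x, "activity_volume")) x$activity else x
  if (inherits(x, "activity_volume")) voxel <- x$grid$voxel
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  voxel <- RNifti::pixdim(img)[1]
  list(array = arr, grid = volume_grid(dim(arr), voxel))
}

#' Load and validate a run configuration
#'
#' Configurations are YAML (or JSON) with sections `geometry`, `detector`,
#' `aperture`, `grid`, `acquisition`, `recon` and an optional `scale`
#' section; missing optional fields fall back to the published defaults.
#'
#' @param path YAML/JSON file path.
#' @return validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg configuration list.
#' @export
validate_config <- function(cfg) {
  for (sec in c("geometry", "aperture"))
    if (is.null(cfg[[sec]]))
      stop("configuration is missing the required '", sec, "' section")
  defaults <- default_config()
  cfg <- modifyList(defaults, cfg)
  if (!is.null(cfg$geometry$ring_counts) &&
      sum(unlist(cfg$geometry$ring_counts)) != cfg$geometry$n_mce)
    stop("geometry$ring_counts must sum to n_mce")
  structure(cfg, class = "run_config")
}

#' Default run configuration
#' @export
default_config <- function() {
  list(geometry = list(support_radius_mm = 196, focal_distance_mm = 183.23,
                       mf_denominator = 12, n_mce = 502L,
                       neck_arc_deg = 180, ring_counts = NULL),
       detector = list(),
       aperture = list(variant = "ring_250", seed = 1L),
       grid = list(n = 96L, voxel = 2),
       acquisition = list(time_min = 30, yield = 0.885),
       recon = list(n_subsets = 8L, n_iter = 50L),
       scale = list(n_mce = NULL, window = NULL, bin = 1L),
       seed = 1L)
}

#' Ring-proportional MCE subsampling
#'
#' Keeps approximately `n_target` MCEs, thinning each ring evenly, for
#' desk-scale studies.
#'
#' @param helmet a helmet.
#' @param n_target approximate number of MCEs to keep.
#' @return a reduced `helmet`.
#' @export
scale_helmet <- function(helmet, n_target) {
  n <- nrow(helmet$mces)
  if (n_target >= n) return(helmet)
  frac <- n_target / n
  keep <- unlist(lapply(split(seq_len(n), helmet$mces$ring), function(idx) {
    k <- max(1L, round(length(idx) * frac))
    idx[unique(round(seq(1, length(idx), length.out = k)))]
  }), use.names = FALSE)
  out <- helmet
  out$mces <- helmet$mces[sort(keep), , drop = FALSE]
  rownames(out$mces) <- NULL
  out$ring_counts <- as.integer(table(factor(out$mces$ring,
                                             levels = seq_along(helmet$ring_counts) - 1L)))
  out
}

# md5 of a serialised object, for cache keys and manifests
.object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

.build_from_config <- function(cfg) {
  geo <- do.call(helmet_config, cfg$geometry)
  helmet <- build_helmet(geo)
  if (!is.null(cfg$scale$n_mce))
    helmet <- scale_helmet(helmet, cfg$scale$n_mce)
  det <- do.call(detector_spec, cfg$detector)
  apset <- aperture_set(helmet, cfg$aperture$variant,
                        seed = cfg$aperture$seed %||% 1L)
  grid <- volume_grid(unlist(cfg$grid$n), cfg$grid$voxel)
  list(helmet = helmet, det = det, apset = apset, grid = grid)
}

#' Run one of the standard design studies
#'
#' Orchestrates phantom generation, system-matrix construction, forward
#' projection, reconstruction and metric evaluation for one study, writing
#' intermediates and a manifest when `out_dir` is given.
#'
#' @param cfg a [validate_config()] result (or plain list).
#' @param study one of `"sensitivity"`, `"aperture_snr"`, `"fim"`,
#'   `"point_projections"`, `"defrise"`, `"hotrod20"`, `"hotrod5"`,
#'   `"brain_noiseless"`, `"brain_lesions"`.
#' @param out_dir optional output directory for artifacts.
#' @param seed global RNG seed for the noisy studies.
#' @return a named list of results (study-dependent).
#' @export
run_experiment <- function(cfg = default_config(),
                           study = c("sensitivity", "aperture_snr", "fim",
                                     "point_projections", "defrise",
                                     "hotrod20", "hotrod5",
                                     "brain_noiseless", "brain_lesions"),
                           out_dir = NULL, seed = NULL) {
  study <- match.arg(study)
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  seed <- seed %||% cfg$seed
  parts <- .build_from_config(cfg)
  helmet <- parts$helmet; det <- parts$det
  apset <- parts$apset; grid <- parts$grid
  res <- switch(study,
    sensitivity = {
      pts <- rbind(c(0, 0, 0))
      prof <- lapply(c(lateral = 1, ventrodorsal = 2, craniocaudal = 3),
                     function(d) {
                       p <- matrix(0, 11, 3)
                       p[, d] <- seq(-50, 50, by = 10)
                       s <- point_sensitivity(helmet, det, apset, p,
                                              percent = TRUE)
                       data.frame(position_mm = p[, d], sensitivity_pct = s)
                     })
      list(central_pct = point_sensitivity(helmet, det, apset, pts,
                                           percent = TRUE),
           profiles = prof)
    },
    aperture_snr = {
      spec <- if (length(apset$specs) == 1) apset$specs[[1]] else
        apset$specs[[1]]
      list(snr = aperture_snr(helmet, det, spec, grid,
                              stride = cfg$scale$stride %||% 4L))
    },
    fim = {
      srm <- build_srm(helmet, det, apset, grid,
                       options = response_options(collapse_doi = TRUE),
                       window = cfg$scale$window, bin = cfg$scale$bin)
      yb <- forward_project(srm, uniform_fov(grid,
                                             helmet$fov_radius))
      fi <- fim_column(srm, yb, c(0, 0, 0))
      list(fim = fi,
           fwhm = c(lateral = profile_fwhm(fi, "lateral"),
                    craniocaudal = profile_fwhm(fi, "craniocaudal")))
    },
    point_projections = {
      spec <- apset$specs[[1]]
      imgs <- lapply(list(c(-2, 0, 0), c(2, 0, 0)), function(p)
        render_point_projection(helmet, det, spec, p))
      list(images = imgs, combined = imgs[[1]] + imgs[[2]])
    },
    defrise = .study_recon(helmet, det, apset, grid, cfg, seed,
                           phantom = defrise_phantom(grid), noisy = FALSE),
    hotrod20 = .study_recon(helmet, det, apset, grid, cfg, seed,
                            phantom = hot_rod_phantom(grid, s_b = 20),
                            noisy = TRUE),
    hotrod5 = .study_recon(helmet, det, apset, grid, cfg, seed,
                           phantom = hot_rod_phantom(grid, s_b = 5),
                           noisy = TRUE),
    brain_noiseless = .study_recon(helmet, det, apset, grid, cfg, seed,
                                   phantom = brain_phantom(grid),
                                   noisy = FALSE, n_iter_default = 500L),
    brain_lesions = .study_recon(helmet, det, apset, grid, cfg, seed,
                                 phantom = brain_phantom(grid,
                                                         lesions = TRUE),
                                 noisy = TRUE, n_iter_default = 50L,
                                 postfilter = 6))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(study = study, seed = seed,
                     config_hash = .object_hash(unclass(cfg)),
                     n_mce = nrow(helmet$mces),
                     grid = list(n = grid$n, voxel = grid$voxel),
                     aperture = apset$label,
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$recon))
      write_volume(res$recon$image, file.path(out_dir, "recon.nii"),
                   voxel = grid$voxel)
    if (!is.null(res$metrics))
      write.table(res$metrics, file.path(out_dir, "metrics.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

# shared phantom -> SRM -> projection -> OSEM -> metrics pipeline
.study_recon <- function(helmet, det, apset, grid, cfg, seed, phantom,
                         noisy, n_iter_default = NULL, postfilter = NULL) {
  # reconstruct on the bounding sphere of the phantom support (plus margin)
  # so cold gaps inside the object are part of the unknown image
  active <- phantom$activity > 0
  if (!is.null(phantom$labels)) active <- active | phantom$labels > 0
  ctr <- .grid_centers(grid)
  rmax <- sqrt(max(rowSums(ctr[which(active), , drop = FALSE]^2)))
  mask <- which(rowSums(ctr^2) <= (rmax + 2 * grid$voxel)^2)
  srm <- build_srm(helmet, det, apset, grid, mask = mask,
                   options = response_options(collapse_doi = TRUE),
                   window = cfg$scale$window, bin = cfg$scale$bin)
  acq <- do.call(acquisition, cfg$acquisition)
  ybar <- forward_project(srm, phantom, acq)
  y <- if (noisy) add_poisson(ybar, seed) else ybar
  n_iter <- cfg$recon$n_iter %||% n_iter_default %||% 50L
  truth <- .emitted_photons(phantom, acq)[srm$mask_idx]
  rec <- osem(y, srm, n_subsets = cfg$recon$n_subsets, n_iter = n_iter,
              truth = truth)
  stop_it <- stopping_iteration(rec$trace$nrmse,
                                if (noisy) "noisy_min" else
                                  "noiseless_plateau")
  img <- rec$image
  if (!is.null(postfilter))
    img <- gaussian_post_filter(img, postfilter, grid$voxel)
  metrics <- NULL
  rod_names <- names(phantom$rois)[vapply(phantom$rois, function(r)
    r$role %in% c("rod", "lesion"), logical(1))]
  if (length(rod_names) && "background" %in% names(phantom$rois)) {
    bck <- roi_voxels(phantom, "background")
    metrics <- do.call(rbind, lapply(rod_names, function(nm) {
      rv <- roi_voxels(phantom, nm)
      data.frame(roi = nm,
                 crc = crc(rec$image, rv, bck,
                           phantom$rois[[nm]]$true_ratio),
                 cnr = cnr(rec$image, rv, bck),
                 nc = nc(rec$image, bck))
    }))
  }
  list(phantom = phantom, srm_summary = dim(srm$A), recon = rec,
       stopping_iteration = stop_it, image = img, metrics = metrics)
}
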