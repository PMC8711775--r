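#' Activity volume container
#'
#' A 3-D activity field on a [volume_grid()], with optional integer VOI
#' labels and named ROI definitions.
#'
#' @param grid a [volume_grid()].
#' @param activity 3-D nonnegative array matching the grid.
#' @param labels optional 3-D integer array (0 = unlabeled).
#' @param rois named list mapping ROI names to `list(label, role)`.
#' @param total_photons optional emitted-photon normalisation.
#' @param units unit tag for the activity values.
#' @return an object of class `activity_volume`.
#' @export
activity_volume <- function(grid, activity, labels = NULL, rois = list(),
                            total_photons = NULL, units = "relative") {
  activity <- array(activity, grid$n)
  if (any(activity < 0)) stop("activity must be nonnegative")
  if (!is.null(labels)) labels <- array(as.integer(labels), grid$n)
  structure(list(grid = grid, activity = activity, labels = labels,
                 rois = rois, total_photons = total_photons, units = units),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  cat("activity volume on", paste(x$grid$n, collapse = "x"), "grid;",
      sum(x$activity > 0), "active voxels;", length(x$rois), "ROIs\n")
  invisible(x)
}

# coordinate arrays (same shape as the volume) for rasterisation
.coord_arrays <- function(grid) {
  ax <- .grid_axes(grid)
  list(x = array(rep(ax[[1]], times = grid$n[2] * grid$n[3]), grid$n),
       y = array(rep(rep(ax[[2]], each = grid$n[1]), times = grid$n[3]),
                 grid$n),
       z = array(rep(ax[[3]], each = grid$n[1] * grid$n[2]), grid$n))
}

#' Defrise disk phantom
#'
#' A uniform-activity sphere cut into transaxial disks of equal thickness
#' and spacing along the craniocaudal (z) axis, used to probe axial
#' sampling completeness.  With the default phase (slab boundaries at
#' z = 0) the 160-mm sphere yields 14 nonempty disks.
#'
#' @param grid a [volume_grid()].
#' @param sphere_diameter sphere diameter, mm.
#' @param disk_thickness disk thickness and spacing, mm.
#' @return an [activity_volume()] with unit disk activity.
#' @export
defrise_phantom <- function(grid = volume_grid(), sphere_diameter = 160,
                            disk_thickness = 6) {
  co <- .coord_arrays(grid)
  r2 <- co$x^2 + co$y^2 + co$z^2
  act <- as.numeric(r2 <= (sphere_diameter / 2)^2 &
                      floor(co$z / disk_thickness) %% 2 == 0)
  activity_volume(grid, act, units = "relative")
}

# triangular rod lattice (pitch twice the diameter) clipped to one quadrant
# sector of the cylinder, with a one-diameter clear margin everywhere
.sector_rods <- function(diameter, cyl_radius, sector, margin = diameter) {
  pitch <- 2 * diameter
  rmax <- cyl_radius - margin
  rows <- seq(-ceiling(rmax / (pitch * sqrt(3) / 2)),
              ceiling(rmax / (pitch * sqrt(3) / 2)))
  pts <- do.call(rbind, lapply(rows, function(r) {
    y <- r * pitch * sqrt(3) / 2
    x <- (seq(-ceiling(rmax / pitch), ceiling(rmax / pitch)) +
            (r %% 2) / 2) * pitch
    cbind(x, y)
  }))
  a0 <- (sector - 1) * pi / 2 + 0.15      # angular margin off the axes
  a1 <- sector * pi / 2 - 0.15
  ang <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  rr <- sqrt(rowSums(pts^2))
  pts[rr <= rmax & rr >= margin + diameter / 2 & ang >= a0 & ang <= a1, ,
      drop = FALSE]
}

#' Hot-rod resolution phantom
#'
#' Four quadrant groups of hot rods (one diameter per group, centre-to-
#' centre spacing twice the diameter) inside a uniform background cylinder
#' along z.  Rod-to-background concentration ratio equals `s_b`; the total
#' activity is then scaled to `total_mci` (rods + background).
#'
#' @param grid a [volume_grid()].
#' @param s_b signal-to-background concentration ratio (20 or 5).
#' @param rod_diameters rod diameters per sector, mm.
#' @param cylinder_diameter,cylinder_length background cylinder, mm.
#' @param total_mci total activity after scaling (1.5 mCi reproduces the
#'   20:1 protocol of 1 mCi rods + 0.5 mCi background at the default
#'   geometry; 3 mCi the 5:1 protocol).
#' @return an [activity_volume()] with ROIs: one rod per group (the rod
#'   nearest the axis) and the central 8 x 8 voxel background column.
#' @export
hot_rod_phantom <- function(grid = volume_grid(), s_b = 20,
                            rod_diameters = c(4, 6, 8, 10),
                            cylinder_diameter = 160, cylinder_length = 80,
                            total_mci = if (s_b == 20) 1.5 else 3) {
  stopifnot(s_b > 1, length(rod_diameters) <= 4)
  co <- .coord_arrays(grid)
  in_cyl <- co$x^2 + co$y^2 <= (cylinder_diameter / 2)^2 &
    abs(co$z) <= cylinder_length / 2
  act <- array(0, grid$n)
  act[in_cyl] <- 1
  labels <- array(0L, grid$n)
  rois <- list()
  for (q in seq_along(rod_diameters)) {
    d <- rod_diameters[q]
    ctrs <- .sector_rods(d, cylinder_diameter / 2, q)
    if (!nrow(ctrs)) stop("no rods fit in sector ", q)
    ctrs <- ctrs[order(rowSums(ctrs^2)), , drop = FALSE]
    for (i in seq_len(nrow(ctrs))) {
      rod <- (co$x - ctrs[i, 1])^2 + (co$y - ctrs[i, 2])^2 <= (d / 2)^2 &
        abs(co$z) <= cylinder_length / 2
      act[rod] <- s_b
      labels[rod] <- if (i == 1) q else 20L + q
    }
    # ROI: the rod of this group nearest the central axis
    rois[[paste0("rod_", d, "mm")]] <-
      list(label = q, role = "rod", diameter = d, true_ratio = s_b,
           center = ctrs[1, ], centers = ctrs)
  }
  # central 8 x 8 voxel background column through the cylinder length
  ic <- .grid_center_index(grid)
  bck <- array(FALSE, grid$n)
  bck[ic[1] + (-4:3), ic[2] + (-4:3), ] <- TRUE
  bck <- bck & in_cyl & act == 1          # background only, no rod voxels
  labels[bck] <- 30L
  rois[["background"]] <- list(label = 30L, role = "background_rod")
  labels[in_cyl & labels == 0L] <- 31L    # remaining background cylinder
  act <- act * (total_mci / sum(act))     # concentration ratio, then total
  activity_volume(grid, act, labels, rois, units = "mCi_total_scaled")
}

# default anatomy table for the parametric two-hemisphere brain stand-in:
# per functional region a mirrored ellipsoidal VOI (centre for the right
# hemisphere; x is mirrored for the left) with baseline perfusion and an
# ictal (left) asymmetry.  Concentrations are uCi/mL.
.brain_regions <- function(white = 0.056) {
  g <- white   # gray-matter regions are expressed relative to white matter
  tab <- data.frame(
    name = c("TPo", "TL", "TM", "Frontal", "Parietal", "Occipital",
             "Insula", "CN", "LN", "Thalamus", "Cerebellum", "Brainstem",
             "ACing", "PCing", "Sensorimotor", "Visual"),
    cx = c(38, 52, 28, 30, 34, 24, 30, 12, 22, 10, 24, 6, 8, 8, 28, 12),
    cy = c(52, 28, 34, 62, -42, -66, 20, 26, 12, -8, -52, -28, 48, -36,
           -6, -58),
    cz = c(-22, -14, -20, 18, 34, 2, 2, 12, 2, 4, -44, -28, 20, 24, 44, 6),
    rx = c(9, 14, 9, 16, 14, 12, 7, 6, 8, 7, 16, 6, 6, 6, 10, 8),
    ry = c(11, 18, 11, 18, 16, 12, 10, 9, 9, 8, 16, 9, 8, 8, 12, 10),
    rz = c(9, 12, 8, 14, 12, 10, 10, 7, 7, 7, 12, 10, 7, 7, 9, 8),
    ur_right = c(1.00, 1.02, 0.98, 1.05, 1.03, 1.08, 0.96, 0.98, 1.00,
                 0.97, 1.00, 0.92, 1.00, 1.02, 1.05, 1.10),
    ai = c(0.25, 0.14, 0.20, 0.03, 0.02, 0.01, 0.09, 0.05, 0.04, 0.03,
           -0.02, 0.00, 0.06, 0.02, 0.01, 0.00))
  # scale gray-matter baselines so the left (ictal) TPo lands at 0.07 uCi/mL
  base <- g * tab$ur_right
  tab$conc_right <- base * 0.07 / (base[1] * (1 + tab$ai[1]))
  tab$conc_left <- tab$conc_right * (1 + tab$ai)
  tab
}

#' Parametric ictal brain perfusion phantom
#'
#' A synthetic stand-in for an ictal (left-hemisphere) brain perfusion
#' pattern: 16 functional regions lateralised into 32 ellipsoidal VOIs
#' inside a two-hemisphere head ellipsoid filled with white matter at
#' 0.056 uCi/mL.  The left temporo-polar region (TPo) carries the ictal
#' focus at ~0.07 uCi/mL.  The reference VOI is an 8-mm sphere in the right
#' cerebellum.  Optional spherical lesions of 5/6/7/8 mm diameter at
#' lesion-to-white-matter contrasts 3 : 2.5 : 2 : 1.5 are placed in the
#' TPo / TL / TM / TL of the ictal hemisphere.
#'
#' @param grid a [volume_grid()].
#' @param white_matter background concentration, uCi/mL.
#' @param lesions add the four low-contrast focal lesions.
#' @param total_photons emitted-photon normalisation (default 2e9).
#' @param regions optional replacement region table (see source for the
#'   expected columns).
#' @return an [activity_volume()] with labelled VOIs and lesion ROIs.
#' @export
brain_phantom <- function(grid = volume_grid(), white_matter = 0.056,
                          lesions = FALSE, total_photons = 2e9,
                          regions = .brain_regions(white_matter)) {
  co <- .coord_arrays(grid)
  head <- (co$x / 72)^2 + (co$y / 88)^2 + (co$z / 66)^2 <= 1
  act <- array(0, grid$n)
  act[head] <- white_matter
  labels <- array(0L, grid$n)
  labels[head] <- 999L                     # white matter / head
  rois <- list(white_matter = list(label = 999L, role = "reference"))
  lab <- 0L
  for (i in seq_len(nrow(regions))) {
    for (side in c("right", "left")) {
      sgn <- if (side == "right") 1 else -1
      inside <- ((co$x - sgn * regions$cx[i]) / regions$rx[i])^2 +
        ((co$y - regions$cy[i]) / regions$ry[i])^2 +
        ((co$z - regions$cz[i]) / regions$rz[i])^2 <= 1
      inside <- inside & head
      lab <- lab + 1L
      conc <- regions[[paste0("conc_", side)]][i]
      act[inside] <- conc
      labels[inside] <- lab
      rois[[paste0(regions$name[i], "_", side)]] <-
        list(label = lab, role = paste0("voi_", side),
             region = regions$name[i], concentration = conc)
    }
  }
  # 8-mm reference sphere in the right cerebellum
  cb <- regions[regions$name == "Cerebellum", ]
  ref <- (co$x - cb$cx)^2 + (co$y - cb$cy)^2 + (co$z - cb$cz)^2 <= 4^2
  lab <- lab + 1L
  labels[ref] <- lab
  rois[["reference_cerebellum"]] <- list(label = lab, role = "reference")
  if (lesions) {
    les <- data.frame(name = c("lesion_1", "lesion_2", "lesion_3",
                               "lesion_4"),
                      region = c("TPo", "TL", "TM", "TL"),
                      d = c(5, 6, 7, 8), contrast = c(3, 2.5, 2, 1.5),
                      dz = c(0, 8, 0, -10))
    for (i in seq_len(nrow(les))) {
      rg <- regions[regions$name == les$region[i], ]
      cx <- -rg$cx                        # ictal (left) hemisphere
      inside <- (co$x - cx)^2 + (co$y - rg$cy)^2 +
        (co$z - (rg$cz + les$dz[i]))^2 <= (les$d[i] / 2)^2
      if (any(labels[inside] == rois$reference_cerebellum$label))
        stop("lesion ", les$name[i], " overlaps the reference region")
      prev <- rois[vapply(rois, function(r) r$role == "lesion", logical(1))]
      for (p in prev)
        if (any(inside & labels == p$label))
          stop("lesion ", les$name[i], " overlaps ", p$region)
      lab <- lab + 1L
      act[inside] <- white_matter * les$contrast[i]
      labels[inside] <- lab
      rois[[les$name[i]]] <- list(label = lab, role = "lesion",
                                  region = les$region[i],
                                  diameter = les$d[i],
                                  true_ratio = les$contrast[i])
    }
  }
  activity_volume(grid, act, labels, rois, total_photons = total_photons,
                  units = "uCi_per_mL")
}

#' Point-source activity volume
#'
#' @param grid a [volume_grid()].
#' @param positions n x 3 matrix of source positions (mm), snapped to the
#'   nearest voxel centres.
#' @param strengths per-source activities.
#' @param fov_radius positions must lie inside this sphere.
#' @return an [activity_volume()]; total activity equals
#'   `sum(strengths)`.
#' @export
point_sources <- function(grid = volume_grid(), positions,
                          strengths = rep(1, nrow(rbind(positions))),
                          fov_radius = 100) {
  positions <- rbind(positions)
  act <- array(0, grid$n)
  if (nrow(positions)) {
    if (any(rowSums(positions^2) > fov_radius^2))
      stop("point source outside the FOV sphere")
    ax <- .grid_axes(grid)
    for (i in seq_len(nrow(positions))) {
      ijk <- vapply(1:3, function(d)
        which.min(abs(ax[[d]] - positions[i, d])), integer(1))
      act[ijk[1], ijk[2], ijk[3]] <- act[ijk[1], ijk[2], ijk[3]] +
        strengths[i]
    }
  }
  activity_volume(grid, act, units = "relative")
}

#' Uniform activity inside the FOV sphere
#'
#' @param grid a [volume_grid()].
#' @param fov_radius FOV sphere radius, mm.
#' @param value voxel activity value.
#' @return an [activity_volume()].
#' @export
uniform_fov <- function(grid = volume_grid(), fov_radius = 100, value = 1) {
  co <- .coord_arrays(grid)
  act <- value * (co$x^2 + co$y^2 + co$z^2 <= fov_radius^2)
  activity_volume(grid, act, units = "relative")
}
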