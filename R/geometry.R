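#' Pixelated CZT detector specification
#'
#' Describes one detector module: an 80 x 80 pixel CZT crystal of 250 um
#' pitch and 5 mm thickness read out as five non-overlapping 1-mm
#' depth-of-interaction (DOI) layers.
#'
#' @param n_pix_u,n_pix_v pixel counts along the two detector axes.
#' @param pitch pixel pitch in mm.
#' @param thickness crystal thickness in mm.
#' @param n_doi_layers number of DOI layers.
#' @param layer_thickness DOI layer thickness in mm.
#' @param mu_czt linear attenuation of CZT at the working energy, mm^-1
#'   (0.354 at 140 keV).
#' @return an object of class `detector_spec`.
#' @examples
#' det <- detector_spec()
#' det$n_pix_u * det$pitch  # 20 mm active width
#' @export
detector_spec <- function(n_pix_u = 80L, n_pix_v = 80L, pitch = 0.25,
                          thickness = 5, n_doi_layers = 5L,
                          layer_thickness = 1, mu_czt = 0.354) {
  stopifnot(n_pix_u >= 1, n_pix_v >= 1, pitch > 0, thickness > 0,
            n_doi_layers >= 1, layer_thickness > 0, mu_czt > 0)
  if (abs(n_doi_layers * layer_thickness - thickness) > 1e-9)
    stop("DOI layers must tile the crystal thickness: n_doi_layers * ",
         "layer_thickness != thickness")
  structure(list(n_pix_u = as.integer(n_pix_u), n_pix_v = as.integer(n_pix_v),
                 pitch = pitch, thickness = thickness,
                 n_doi_layers = as.integer(n_doi_layers),
                 layer_thickness = layer_thickness, mu_czt = mu_czt),
            class = "detector_spec")
}

#' Helmet configuration
#'
#' Geometry parameters of the spherical compound-eye helmet.  The default
#' generator arranges 502 MCEs in 18 rings: a hemispherical section of 345
#' modules (11 full rings plus one top-cover module at the pole) and a neck
#' section of 157 modules over 7 partial rings spanning 180 degrees of
#' azimuth, leaving the frontal opening free.
#'
#' The focal distance (aperture plane to FOV centre) is 183.23 mm and the
#' image distance is its 1/12, fixing the 1:12 minification.  The 196-mm
#' support radius is retained as a nominal mounting value only.
#'
#' @param support_radius_mm nominal support sphere radius (informational).
#' @param focal_distance_mm aperture-plane-to-FOV-centre distance D_a.
#' @param mf_denominator minification denominator; image distance is
#'   `focal_distance_mm / mf_denominator`.
#' @param ring_counts optional integer vector of per-ring MCE counts
#'   (length 19: top cover, 11 full rings, 7 neck rings).  `NULL` engages
#'   the default circumference-proportional generator.
#' @param neck_arc_deg azimuthal arc covered by the neck rings.
#' @param n_mce total number of MCEs (must match `ring_counts` if given).
#' @param fov_radius_mm radius of the spherical field of view.
#' @return a list of class `helmet_config`.
#' @export
helmet_config <- function(support_radius_mm = 196, focal_distance_mm = 183.23,
                          mf_denominator = 12, ring_counts = NULL,
                          neck_arc_deg = 180, n_mce = 502L,
                          fov_radius_mm = 100) {
  structure(list(support_radius_mm = support_radius_mm,
                 focal_distance_mm = focal_distance_mm,
                 mf_denominator = mf_denominator,
                 ring_counts = ring_counts,
                 neck_arc_deg = neck_arc_deg,
                 n_mce = as.integer(n_mce),
                 fov_radius_mm = fov_radius_mm),
            class = "helmet_config")
}

# largest-remainder apportionment of `total` proportional to `weights`,
# clipped to per-ring capacities
.apportion <- function(total, weights, capacity) {
  raw <- total * weights / sum(weights)
  n <- pmin(floor(raw), capacity)
  while (sum(n) < total) {
    room <- which(n < capacity)
    if (!length(room)) stop("ring capacities cannot accommodate the modules")
    k <- room[which.max((raw - n)[room])]
    n[k] <- n[k] + 1L
  }
  as.integer(n)
}

# Largest module count a ring can hold without footprint collisions.
# Adjacent squares on a ring are mutually rotated by the angular pitch
# delta, so the required centre spacing grows beyond the 20-mm module
# width: s_req = 10 (1 + cos delta + sin delta) / cos(delta / 2).
.ring_capacity <- function(psi_deg, r_det, arc = 2 * pi) {
  for (n in 200:1) {
    delta <- arc / n
    spacing <- 2 * r_det * sinpi(psi_deg / 180) * sin(delta / 2)
    s_req <- 10 * (1 + cos(delta) + sin(delta)) / cos(delta / 2)
    if (spacing >= s_req) return(n)
  }
  1L
}

# default 19-element ring-count vector (top cover, 11 full, 7 neck)
.default_ring_counts <- function(n_hemi = 345L, n_neck = 157L,
                                 psi_full = 6 + (0:10) * 8.4,
                                 psi_neck = 98.4 + (0:6) * 8.4,
                                 r_det = 198.5) {
  cap_full <- vapply(psi_full, .ring_capacity, integer(1), r_det = r_det)
  cap_neck <- vapply(psi_neck, .ring_capacity, integer(1), r_det = r_det,
                     arc = pi)
  full <- .apportion(n_hemi - 1L, sinpi(psi_full / 180), cap_full)
  neck <- .apportion(n_neck, sinpi(psi_neck / 180), cap_neck)
  list(counts = c(1L, full, neck), psi = c(0, psi_full, psi_neck))
}

#' Build the helmet geometry
#'
#' Places every MCE on the focal sphere of radius `focal_distance_mm`, with
#' its axis pointing at the FOV centre, and attaches an orthonormal in-plane
#' basis.  Full rings are azimuthally staggered by half a pitch between
#' neighbours; neck rings cover only the rear 180 degrees.
#'
#' @param config a [helmet_config()].
#' @return an object of class `helmet` with a per-MCE pose table `$mces`
#'   (ring index, azimuth, aperture centre, axis and in-plane basis) and the
#'   derived distances `$D_a` (focal) and `$f` (image).
#' @examples
#' h <- build_helmet()
#' nrow(h$mces)  # 502
#' @export
build_helmet <- function(config = helmet_config()) {
  stopifnot(inherits(config, "helmet_config"), config$focal_distance_mm > 0)
  def <- .default_ring_counts()
  if (is.null(config$ring_counts)) {
    counts <- def$counts
  } else {
    counts <- as.integer(config$ring_counts)
    if (length(counts) != length(def$counts))
      stop("ring_counts must have ", length(def$counts), " entries ",
           "(top cover, 11 full rings, 7 neck rings)")
  }
  if (sum(counts) != config$n_mce)
    stop("ring_counts sum to ", sum(counts), ", expected n_mce = ",
         config$n_mce)
  psi <- def$psi
  D_a <- config$focal_distance_mm
  n_rings <- length(counts)
  rows <- vector("list", n_rings)
  for (r in seq_len(n_rings)) {
    n <- counts[r]
    if (n == 0L) next
    if (r == 1L) {
      az <- 0
    } else if (r <= 12L) {           # full rings, half-pitch stagger
      pitch <- 360 / n
      az <- (seq_len(n) - 1) * pitch + (r %% 2) * pitch / 2
    } else {                          # neck rings over the rear arc
      arc <- config$neck_arc_deg
      pitch <- arc / n
      # quarter-pitch stagger keeps every module strictly inside the arc
      az <- (seq_len(n) - 0.5 + 0.25 * (r %% 2)) * pitch
    }
    rows[[r]] <- data.frame(ring = r - 1L, colatitude_deg = psi[r],
                            azimuth_deg = az %% 360)
  }
  mces <- do.call(rbind, rows)
  th <- mces$colatitude_deg * pi / 180
  ph <- mces$azimuth_deg * pi / 180
  u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))  # outward unit
  center <- D_a * u
  axis <- -u
  # v basis: along the meridian toward the pole; x-hat at the pole itself
  zhat <- matrix(rep(c(0, 0, 1), each = nrow(u)), ncol = 3)
  v <- zhat - u * drop(u %*% c(0, 0, 1))
  deg <- sqrt(rowSums(v^2)) < 1e-9
  v[deg, ] <- matrix(rep(c(1, 0, 0), each = sum(deg)), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  uvec <- cbind(v[, 2] * u[, 3] - v[, 3] * u[, 2],
                v[, 3] * u[, 1] - v[, 1] * u[, 3],
                v[, 1] * u[, 2] - v[, 2] * u[, 1])  # u = v x w
  mces <- cbind(mces,
                setNames(as.data.frame(center), c("cx", "cy", "cz")),
                setNames(as.data.frame(axis), c("ax", "ay", "az")),
                setNames(as.data.frame(uvec), c("ux", "uy", "uz")),
                setNames(as.data.frame(v), c("vx", "vy", "vz")),
                setNames(as.data.frame(u), c("wx", "wy", "wz")))
  mces$aperture_id <- 1L
  structure(list(config = config, mces = mces, ring_counts = counts,
                 D_a = D_a, f = D_a / config$mf_denominator,
                 fov_radius = config$fov_radius_mm),
            class = "helmet")
}

#' @export
print.helmet <- function(x, ...) {
  cat("compound-eye helmet:", nrow(x$mces), "MCEs in",
      sum(x$ring_counts > 0) - 1L, "rings plus a top cover\n")
  cat("  focal distance ", x$D_a, " mm, image distance ", signif(x$f, 6),
      " mm (1:", x$config$mf_denominator, " minification)\n", sep = "")
  invisible(x)
}

# n_mce x 12 pose matrix [centre, u, v, w] consumed by the C++ kernels
.mce_matrix <- function(helmet, idx = seq_len(nrow(helmet$mces))) {
  m <- helmet$mces[idx, , drop = FALSE]
  as.matrix(m[, c("cx", "cy", "cz", "ux", "uy", "uz",
                  "vx", "vy", "vz", "wx", "wy", "wz")])
}

#' Rigid transform between the world frame and an MCE-local frame
#'
#' The local frame has its origin at the aperture centre, +w along the
#' module axis toward the detector and u/v spanning the aperture plane.
#'
#' @param helmet a [build_helmet()] result.
#' @param i MCE index (row of `helmet$mces`).
#' @return a list with `to_local(p)` and `to_world(p)` functions operating
#'   on 3-vectors or n x 3 matrices, plus the rotation `R` (rows u, v, w)
#'   and `origin`.
#' @export
mce_frame <- function(helmet, i) {
  stopifnot(inherits(helmet, "helmet"), i >= 1, i <= nrow(helmet$mces))
  m <- .mce_matrix(helmet, i)
  origin <- m[1, 1:3]
  R <- rbind(m[1, 4:6], m[1, 7:9], m[1, 10:12])
  if (abs(det(R) - 1) > 1e-6) stop("degenerate MCE basis")
  list(origin = origin, R = R,
       to_local = function(p) {
         p <- rbind(p)
         t(R %*% (t(p) - origin))
       },
       to_world = function(p) {
         p <- rbind(p)
         t(crossprod(R, t(p)) + origin)
       })
}

#' World coordinates of detector pixel centres
#'
#' Pixel indices are 0-based, matching the detector readout convention; the
#' centre of pixel `(iu, iv)` in DOI layer `k` lies at depth
#' `(k + 0.5) * layer_thickness` behind the detector entrance face, which
#' sits at local `w = f`.
#'
#' @param helmet,i helmet and MCE index.
#' @param det a [detector_spec()].
#' @param iu,iv pixel indices in `[0, n_pix)`.
#' @param layer DOI layer index in `[0, n_doi_layers)`.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
pixel_center <- function(helmet, i, det = detector_spec(), iu, iv,
                         layer = 0L) {
  if (any(iu < 0 | iu >= det$n_pix_u | iv < 0 | iv >= det$n_pix_v))
    stop("pixel index out of range")
  if (any(layer < 0 | layer >= det$n_doi_layers))
    stop("DOI layer index out of range")
  fr <- mce_frame(helmet, i)
  loc <- cbind((iu + 0.5 - det$n_pix_u / 2) * det$pitch,
               (iv + 0.5 - det$n_pix_v / 2) * det$pitch,
               helmet$f + (layer + 0.5) * det$layer_thickness)
  fr$to_world(loc)
}

#' Export the helmet layout as a plain-text table
#'
#' One MCE per row: ring, azimuth, aperture-centre xyz, axis xyz and the
#' aperture assignment.
#'
#' @param helmet a helmet.
#' @param file destination path; `NULL` returns the data frame.
#' @export
helmet_table <- function(helmet, file = NULL) {
  tab <- helmet$mces[, c("ring", "azimuth_deg", "cx", "cy", "cz",
                         "ax", "ay", "az", "aperture_id")]
  if (is.null(file)) return(tab)
  write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
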