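#' Parametric tungsten aperture
#'
#' All apertures are carved out of a 20-mm tungsten slab split into an upper
#' thickness `t_u` (detector side) and a lower thickness `t_l` (object side)
#' about the aperture plane.  The open channel is the union of a lower
#' frustum flaring toward the object with acceptance half-angle(s) `alpha`,
#' the opening in the aperture plane, and an upper frustum flaring toward
#' the detector with exit half-angle(s) `beta`; all half-angles are measured
#' from the aperture axis.
#'
#' Loftholes have a circular knife-edge opening with square channel
#' cross-sections away from the plane (the disc constraint expands at
#' `sqrt(2) tan` so the square profile dominates off-plane).  Micro-slits
#' have a rectangular `w x l` opening with independent angles along the
#' short and long directions; the opening and lower profile are rotated by
#' `theta` about the axis while the upper channel is clipped to the square
#' module footprint.  Micro-rings have an annular opening between an outer
#' cone and a central plug.
#'
#' @param kind one of `"lofthole"`, `"micro_slit"`, `"micro_ring"`.
#' @param ... kind-specific parameters, see Details.
#' @param t_u,t_l tungsten above / below the aperture plane, mm (must sum
#'   to 20).
#' @param mu_w tungsten attenuation at the working energy, mm^-1.
#'
#' @details Kind-specific parameters:
#' \describe{
#'   \item{lofthole}{`diameter` (mm), `alpha`, `beta` (deg).}
#'   \item{micro_slit}{`width`, `length` (mm, `length/width >= 10`),
#'     `alpha_short`, `beta_short`, `alpha_long`, `beta_long` (deg),
#'     `theta` (deg, rotation of opening and lower profile).}
#'   \item{micro_ring}{`r_outer`, `r_inner` (mm), `alpha`, `beta` (deg).}
#' }
#' @return an object of class `aperture_spec`.
#' @examples
#' open_area(aperture_spec("lofthole", diameter = 1))
#' @export
aperture_spec <- function(kind = c("lofthole", "micro_slit", "micro_ring"),
                          ..., t_u = NULL, t_l = NULL,
                          mu_w = tungsten_mu(140)) {
  kind <- match.arg(kind)
  p <- list(...)
  chk_angle <- function(a, nm) {
    if (is.null(a) || a <= 0 || a >= 90)
      stop(nm, " must be a half-angle in (0, 90) degrees")
    a
  }
  spec <- switch(kind,
    lofthole = {
      d <- p$diameter %||% 1
      stopifnot(d > 0)
      list(diameter = d,
           alpha = chk_angle(p$alpha %||% 27.3, "alpha"),
           beta = chk_angle(p$beta %||% 29.4, "beta"),
           t_u = t_u %||% 11, t_l = t_l %||% 9)
    },
    micro_slit = {
      w <- p$width %||% 0.25
      l <- p$length %||% 5
      stopifnot(w > 0, l > 0)
      if (l / w < 10)
        stop("micro-slit requires length/width >= 10 (got ", l / w, ")")
      list(width = w, length = l,
           alpha_short = chk_angle(p$alpha_short %||% 27.3, "alpha_short"),
           beta_short = chk_angle(p$beta_short %||% 29.4, "beta_short"),
           alpha_long = chk_angle(p$alpha_long %||% 35.3, "alpha_long"),
           beta_long = chk_angle(p$beta_long %||% 22.6, "beta_long"),
           theta = p$theta %||% 0,
           t_u = t_u %||% 9, t_l = t_l %||% 11)
    },
    micro_ring = {
      ro <- p$r_outer %||% 3.75
      ri <- p$r_inner %||% 3.5
      if (!(ro > ri && ri > 0)) stop("micro-ring requires r_outer > r_inner > 0")
      list(r_outer = ro, r_inner = ri,
           alpha = chk_angle(p$alpha %||% 36.3, "alpha"),
           beta = chk_angle(p$beta %||% 32.7, "beta"),
           t_u = t_u %||% 7, t_l = t_l %||% 13)
    })
  if (abs(spec$t_u + spec$t_l - 20) > 1e-9)
    stop("t_u + t_l must equal the 20-mm slab thickness")
  structure(c(list(kind = kind, mu_w = mu_w), spec), class = "aperture_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published default aperture variants
#'
#' @param variant one of `"lofthole_0.5"`, `"lofthole_1.0"`,
#'   `"lofthole_1.5"`, `"lofthole_3.0"`, `"slit_250x5"`, `"slit_150x6"`,
#'   `"ring_250"`.
#' @param mu_w optional tungsten attenuation override, mm^-1.
#' @return an [aperture_spec()].
#' @export
aperture_defaults <- function(variant, mu_w = tungsten_mu(140)) {
  tab <- list(
    lofthole_0.5 = function() aperture_spec("lofthole", diameter = 0.5,
                                            mu_w = mu_w),
    lofthole_1.0 = function() aperture_spec("lofthole", diameter = 1,
                                            mu_w = mu_w),
    lofthole_1.5 = function() aperture_spec("lofthole", diameter = 1.5,
                                            mu_w = mu_w),
    lofthole_3.0 = function() aperture_spec("lofthole", diameter = 3,
                                            mu_w = mu_w),
    slit_250x5 = function() aperture_spec("micro_slit", width = 0.25,
                                          length = 5, beta_long = 22.6,
                                          mu_w = mu_w),
    slit_150x6 = function() aperture_spec("micro_slit", width = 0.15,
                                          length = 6, beta_long = 21.1,
                                          mu_w = mu_w),
    ring_250 = function() aperture_spec("micro_ring", mu_w = mu_w))
  if (!variant %in% names(tab))
    stop("unknown aperture variant '", variant, "'; valid variants: ",
         paste(names(tab), collapse = ", "))
  tab[[variant]]()
}

#' Geometric open area of an aperture
#'
#' @param a an [aperture_spec()].
#' @return open area in mm^2.
#' @export
open_area <- function(a) {
  stopifnot(inherits(a, "aperture_spec"))
  switch(a$kind,
         lofthole = pi * a$diameter^2 / 4,
         micro_slit = a$width * a$length,
         micro_ring = pi * (a$r_outer^2 - a$r_inner^2))
}

#' Randomly permuted micro-slit rotation angles
#'
#' Returns a seeded random permutation of the regular grid
#' `k * 360 / n`, `k = 0 .. n-1` (increment 360/502 ~ 0.717 degrees for the
#' full helmet).  The multiset of angles is exact; only their assignment to
#' MCEs is randomised.
#'
#' @param n number of slits.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return numeric vector of angles in degrees.
#' @export
assign_slit_rotations <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  angles <- (seq_len(n) - 1) * 360 / n
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  angles[sample.int(n)]
}

# 12-element parameter row consumed by the C++ kernels:
# [kind, t_u, t_l, mu_w, kind-specific x 7, half_module]
.ap_params <- function(a, half_module = 10) {
  stopifnot(inherits(a, "aperture_spec"))
  tand <- function(x) tan(x * pi / 180)
  spec <- switch(a$kind,
    lofthole = c(0, a$diameter / 2, tand(a$alpha), tand(a$beta), 0, 0, 0, 0),
    micro_slit = c(1, a$width / 2, a$length / 2, tand(a$alpha_short),
                   tand(a$beta_short), tand(a$alpha_long), tand(a$beta_long),
                   a$theta * pi / 180),
    micro_ring = c(2, a$r_outer, a$r_inner, tand(a$alpha), tand(a$beta),
                   0, 0, 0))
  c(spec[1], a$t_u, a$t_l, a$mu_w, spec[2:8], half_module)
}

#' Tungsten chord length of a ray through an aperture
#'
#' Computes the total path inside tungsten for rays crossing the collimator
#' slab, either exactly (analytic intersection of the ray with the channel
#' solid, the production method) or by fixed-step midpoint marching (the
#' step-controlled oracle).
#'
#' @param a an [aperture_spec()].
#' @param origin,target ray endpoints, 3-vectors or n x 3 matrices.  By
#'   default these are aperture-local coordinates (aperture centre at the
#'   origin, +w toward the detector); supply `frame` (from [mce_frame()])
#'   to pass world coordinates.
#' @param frame optional MCE frame used to transform world coordinates.
#' @param method `"analytic"` or `"march"`.
#' @param step marching step in mm (ignored for the analytic method).
#' @param half_module half-width of the module footprint used to clip the
#'   micro-slit upper channel, mm.
#' @return numeric vector of chord lengths in mm.
#' @export
path_length_in_tungsten <- function(a, origin, target, frame = NULL,
                                    method = c("analytic", "march"),
                                    step = 0.025, half_module = 10) {
  method <- match.arg(method)
  origin <- rbind(origin); target <- rbind(target)
  stopifnot(nrow(origin) == nrow(target), step > 0)
  if (any(rowSums((origin - target)^2) == 0))
    stop("ray origin and target coincide")
  if (!is.null(frame)) {
    origin <- frame$to_local(origin)
    target <- frame$to_local(target)
  }
  cpp_tungsten_path(origin, target, .ap_params(a, half_module),
                    if (method == "analytic") 0L else 1L, step)
}

#' Ray transmission through an aperture
#'
#' `exp(-mu_w * x)` with `x` the tungsten chord; exactly 1 for rays fully
#' inside the open channel.
#'
#' @inheritParams path_length_in_tungsten
#' @return transmitted fraction in `[0, 1]`.
#' @export
transmission <- function(a, origin, target, frame = NULL,
                         method = c("analytic", "march"), step = 0.025,
                         half_module = 10) {
  x <- path_length_in_tungsten(a, origin, target, frame, method, step,
                               half_module)
  ifelse(x <= 0, 1, exp(-a$mu_w * x))
}

#' Classify a ray as signal, noise or blocked
#'
#' Signal rays traverse the open channel without attenuation; noise rays
#' penetrate tungsten with transmission above the full-slab floor
#' `exp(-mu_w * 20)`; the rest are blocked.
#'
#' @inheritParams path_length_in_tungsten
#' @param floor transmission floor separating noise from blocked.
#' @return character vector in `c("signal", "noise", "blocked")`.
#' @export
classify_ray <- function(a, origin, target, frame = NULL,
                         floor = exp(-a$mu_w * 20), half_module = 10) {
  tr <- transmission(a, origin, target, frame, half_module = half_module)
  ifelse(tr == 1, "signal", ifelse(tr > floor, "noise", "blocked"))
}

#' @export
print.aperture_spec <- function(x, ...) {
  cat("aperture:", x$kind, "\n")
  nm <- setdiff(names(x), c("kind"))
  for (f in nm) cat("  ", f, " = ", format(x[[f]], digits = 5), "\n", sep = "")
  invisible(x)
}
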