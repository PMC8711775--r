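#' Partition MCEs into OSEM subsets
#'
#' MCEs are taken in ring-major, azimuth-sorted order (the helmet's native
#' ordering) and dealt round-robin, so each subset sees a near-uniform
#' angular distribution and consecutive modules of a ring land in different
#' subsets.
#'
#' @param helmet a helmet (or an integer MCE count).
#' @param n_subsets number of subsets.
#' @return integer vector of subset indices (1-based), one per MCE.
#' @export
subset_partition <- function(helmet, n_subsets) {
  n <- if (inherits(helmet, "helmet")) nrow(helmet$mces) else
    as.integer(helmet)
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  if (n_subsets > n) stop("more subsets than MCEs")
  (seq_len(n) - 1L) %% as.integer(n_subsets) + 1L
}

#' Ordered-subset expectation maximisation reconstruction
#'
#' Standard multiplicative OSEM: for each subset `s`,
#' `x <- x / (A_s^T 1) * A_s^T (y_s / (A_s x))`, with 0/0 ratio bins
#' treated as 0.  Subsets are visited in fixed ascending order; voxels with
#' zero total sensitivity are frozen at zero.
#'
#' @param y a `projection_set` (or bin-value vector) matching `srm`.
#' @param srm a [build_srm()] result.
#' @param n_subsets subset count (the MCE partition must admit it).
#' @param n_iter full iterations to run.
#' @param init initial image vector over the mask voxels (default uniform
#'   1); must be strictly positive where sensitivity is nonzero.
#' @param truth optional [activity_volume()] (or mask-voxel vector) used to
#'   record a per-iteration NRMSE trace.  The truth is compared on the
#'   emitted-photon scale of `y` when it is an `activity_volume` and `acq`
#'   is supplied.
#' @param acq acquisition used to scale `truth` (defaults to unit scale).
#' @param subsets optional per-MCE subset assignment (default round-robin).
#' @param track_loglik record the Poisson log-likelihood each iteration
#'   (costs one extra full forward projection per iteration).
#' @param keep_iterations integer iterations whose image vectors are kept
#'   in the result (for CRC-NC curves).
#' @return an object of class `recon_result`: `$image` (3-D array),
#'   `$x` (mask-voxel vector), `$trace` (data frame with `nrmse`,
#'   `loglik`), `$kept` (list of stored iterations).
#' @export
osem <- function(y, srm, n_subsets = 8L, n_iter = 10L, init = NULL,
                 truth = NULL, acq = NULL, subsets = NULL,
                 track_loglik = FALSE, keep_iterations = integer(0)) {
  yv <- if (inherits(y, "projection_set")) y$values else as.numeric(y)
  A <- srm$A
  if (length(yv) != nrow(A)) stop("projection length does not match srm rows")
  n_mce <- srm$n_mce
  per_mce <- nrow(A) / n_mce
  if (is.null(subsets)) subsets <- subset_partition(n_mce, n_subsets)
  if (length(subsets) != n_mce) stop("subset assignment length != MCE count")
  row_mce <- rep(seq_len(n_mce), each = per_mce)
  sens <- Matrix::colSums(A)
  dead <- sens == 0
  if (any(dead))
    warning(sum(dead), " voxels have zero sensitivity and stay frozen at 0")
  x <- init %||% rep(1, ncol(A))
  if (length(x) != ncol(A)) stop("init length does not match voxel count")
  if (any(x < 0) || any(x[!dead] <= 0))
    stop("init must be strictly positive on voxels with sensitivity")
  x[dead] <- 0
  xt <- NULL
  if (!is.null(truth)) {
    xt <- if (inherits(truth, "activity_volume")) {
      e <- .emitted_photons(truth, acq %||% acquisition(total_photons =
                                                          sum(truth$activity)))
      if (is.null(acq) && is.null(truth$total_photons))
        e <- as.numeric(truth$activity)
      e[srm$mask_idx]
    } else as.numeric(truth)
  }
  As <- lapply(seq_len(max(subsets)), function(s) {
    rows <- which(row_mce %in% which(subsets == s))
    list(A = A[rows, , drop = FALSE], y = yv[rows])
  })
  norms <- lapply(As, function(s) Matrix::colSums(s$A))
  trace <- data.frame(iteration = seq_len(n_iter), nrmse = NA_real_,
                      loglik = NA_real_)
  kept <- list()
  for (it in seq_len(n_iter)) {
    for (s in seq_along(As)) {
      yh <- as.numeric(As[[s]]$A %*% x)
      ratio <- ifelse(yh > 0, As[[s]]$y / yh, 0)
      upd <- as.numeric(Matrix::crossprod(As[[s]]$A, ratio))
      ok <- norms[[s]] > 0 & !dead
      x[ok] <- x[ok] * upd[ok] / norms[[s]][ok]
    }
    if (!is.null(xt)) trace$nrmse[it] <- nrmse(x, xt)
    if (track_loglik) {
      yh <- as.numeric(A %*% x)
      pos <- yh > 0
      trace$loglik[it] <- sum(yv[pos] * log(yh[pos]) - yh[pos]) -
        sum(yh[!pos])
    }
    if (it %in% keep_iterations) kept[[as.character(it)]] <- x
  }
  img <- array(0, srm$grid$n)
  img[srm$mask_idx] <- x
  structure(list(image = img, x = x, trace = trace, kept = kept,
                 grid = srm$grid, mask_idx = srm$mask_idx,
                 settings = list(n_subsets = n_subsets, n_iter = n_iter)),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat("OSEM reconstruction:", x$settings$n_iter, "iterations,",
      x$settings$n_subsets, "subsets\n")
  if (!all(is.na(x$trace$nrmse)))
    cat("  final NRMSE:", signif(tail(x$trace$nrmse, 1), 4), "\n")
  invisible(x)
}

#' Stopping iteration from an NRMSE trace
#'
#' Noisy reconstructions stop at the NRMSE minimum; noiseless ones at the
#' first iteration where the NRMSE change falls below 0.1 per mille
#' (1e-4) in absolute value.
#'
#' @param trace numeric NRMSE values per iteration (or a `recon_result`).
#' @param mode `"noisy_min"` or `"noiseless_plateau"`.
#' @param tol plateau threshold on `|delta NRMSE|`.
#' @return the 1-based stopping iteration.
#' @export
stopping_iteration <- function(trace, mode = c("noisy_min",
                                               "noiseless_plateau"),
                               tol = 1e-4) {
  if (inherits(trace, "recon_result")) trace <- trace$trace$nrmse
  mode <- match.arg(mode)
  if (!length(trace) || all(is.na(trace))) stop("empty NRMSE trace")
  if (mode == "noisy_min") return(which.min(trace))
  if (length(trace) == 1) return(1L)
  d <- abs(diff(trace))
  hit <- which(d < tol)
  if (!length(hit)) {
    warning("NRMSE plateau not reached; returning the last iteration")
    return(length(trace))
  }
  hit[1] + 1L
}

#' Separable 3-D Gaussian post-filter
#'
#' @param image 3-D array (or `recon_result`).
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_mm isotropic voxel size.
#' @return the filtered array (kernel normalised to unit sum, so interior
#'   mass is preserved).
#' @export
gaussian_post_filter <- function(image, fwhm_mm = 6, voxel_mm = 2) {
  if (inherits(image, "recon_result")) image <- image$image
  if (fwhm_mm <= 0) stop("fwhm must be positive")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  n <- dim(image)
  smooth_axis <- function(a, d) {
    m <- n[d]
    K <- matrix(0, m, m)
    for (i in seq_len(m)) {
      j <- pmax(1, pmin(m, i + (-r:r)))
      for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + k[t]
    }
    ap <- aperm(a, c(d, setdiff(1:3, d)))
    res <- K %*% matrix(ap, m)
    aperm(array(res, dim(ap)), order(c(d, setdiff(1:3, d))))
  }
  a <- image
  for (d in 1:3) a <- smooth_axis(a, d)
  a
}
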