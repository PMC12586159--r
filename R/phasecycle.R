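#' Percent-change profiles across the six phases
#'
#' Normalizes per-phase maps voxel-wise to their across-phase mean:
#' `100 * (m_k - mbar) / mbar`. Voxels with non-positive mean (or outside
#' the validity mask) are invalid; valid profiles are zero-mean by
#' construction.
#'
#' @param maps array `(x, y, z, 6)` of per-phase mobility (or FA) maps.
#' @param valid optional logical volume restricting the computation.
#' @return list with `pc` (x,y,z,6 percent-change array, `NA` where
#'   invalid) and `valid`.
#' @export
percent_change <- function(maps, valid = NULL) {
  stopifnot(length(dim(maps)) == 4, dim(maps)[4] == 6)
  d3 <- dim(maps)[1:3]
  m <- matrix(maps, prod(d3), 6)
  mbar <- rowMeans(m)
  ok <- mbar > 0
  if (!is.null(valid)) ok <- ok & as.logical(valid)
  pc <- matrix(NA_real_, prod(d3), 6)
  pc[ok, ] <- 100 * (m[ok, , drop = FALSE] - mbar[ok]) / mbar[ok]
  list(pc = array(pc, c(d3, 6)), valid = array(ok, d3))
}

#' Voxel-wise single-cycle sinusoid fit of phase profiles
#'
#' Fits `y_k = a sin(2 pi k/6) + b cos(2 pi k/6)`, `k = 0..5`, by closed-form
#' least squares (the basis is orthogonal over the six phases with squared
#' norm 3; no offset term because the profiles are zero-mean by
#' construction). Amplitude `A = sqrt(a^2 + b^2)`, phase `theta = atan2(b,
#' a)`, `R^2 = 1 - SS_res/SS_tot` (0 when `SS_tot = 0`). The gated
#' amplitude zeroes voxels with `R^2 < 0.5`, representing the absence of a
#' coherent oscillation.
#'
#' @param profiles matrix `(n, 6)` or array `(x, y, z, 6)` of zero-mean
#'   percent-change profiles; rows with non-finite values are invalid.
#' @return list of vectors/volumes `amplitude`, `phase`, `r2`,
#'   `gated_amplitude` (each `NA` where invalid).
#' @export
sine_fit <- function(profiles) {
  d <- dim(profiles)
  vol <- length(d) == 4
  m <- if (vol) matrix(profiles, prod(d[1:3]), 6) else as.matrix(profiles)
  stopifnot(ncol(m) == 6)
  k <- 0:5
  sb <- sin(2 * pi * k / 6)
  cb <- cos(2 * pi * k / 6)
  ok <- rowSums(!is.finite(m)) == 0
  a <- bcoef <- r2 <- rep(NA_real_, nrow(m))
  a[ok] <- as.numeric(m[ok, , drop = FALSE] %*% sb) / 3
  bcoef[ok] <- as.numeric(m[ok, , drop = FALSE] %*% cb) / 3
  fit <- outer(a[ok], sb) + outer(bcoef[ok], cb)
  ss_res <- rowSums((m[ok, , drop = FALSE] - fit)^2)
  ss_tot <- rowSums(m[ok, , drop = FALSE]^2)  # profiles are zero-mean
  r2ok <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
  r2[ok] <- r2ok
  amplitude <- sqrt(a^2 + bcoef^2)
  phase <- atan2(bcoef, a)
  gated <- ifelse(!is.na(r2) & r2 < 0.5, 0, amplitude)
  shape <- function(v) if (vol) array(v, d[1:3]) else v
  list(amplitude = shape(amplitude), phase = shape(phase),
       r2 = shape(r2), gated_amplitude = shape(gated))
}

#' ROI summaries of phase-cycle oscillations
#'
#' Returns (a) the realigned mean profile: each voxel's 6-vector circularly
#' shifted so its maximum sits at index 1, then averaged over the ROI (the
#' index-1 value is flagged for exclusion from plots, since realignment
#' makes it the maximum by construction); (b) the coherent-voxel fraction,
#' voxels with `R^2 > 0.5`; (c) the ROI-mean driving amplitude, the
#' per-voxel max - min of the profile.
#'
#' @param pc percent-change array `(x, y, z, 6)` (or matrix n x 6).
#' @param fits a [sine_fit()] result on the same profiles.
#' @param roi logical volume (or row mask) selecting the ROI.
#' @return list with `realigned_mean` (6-vector, attribute
#'   `discard_index = 1`), `coherent_fraction`, `driving_amplitude`,
#'   `mean_gated_amplitude`, `n_voxels`.
#' @export
phase_summaries <- function(pc, fits, roi) {
  d <- dim(pc)
  m <- if (length(d) == 4) matrix(pc, prod(d[1:3]), 6) else as.matrix(pc)
  roi <- as.logical(roi)
  sel <- which(roi & rowSums(!is.finite(m)) == 0)
  if (length(sel) == 0) stop("empty ROI", call. = FALSE)
  prof <- m[sel, , drop = FALSE]
  shifted <- t(vapply(seq_len(nrow(prof)), function(i) {
    p <- prof[i, ]
    j <- which.max(p)
    p[((seq_len(6) - 1 + (j - 1)) %% 6) + 1]
  }, numeric(6)))
  realigned <- colMeans(shifted)
  attr(realigned, "discard_index") <- 1L
  r2 <- as.numeric(fits$r2)[sel]
  gated <- as.numeric(fits$gated_amplitude)[sel]
  list(realigned_mean = realigned,
       coherent_fraction = mean(r2 > 0.5),
       driving_amplitude = mean(apply(prof, 1, max) - apply(prof, 1, min)),
       mean_gated_amplitude = mean(gated),
       n_voxels = length(sel))
}
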