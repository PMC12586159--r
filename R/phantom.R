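#' Specify a synthetic CSF mobility phantom
#'
#' A phantom is a CSF-bright, tissue-suppressed volume containing simple
#' geometric CSF compartments (ellipsoidal blobs for ventricle-like spaces,
#' tubes for subarachnoid and perivascular channels), each carrying a
#' ground-truth mobility tensor and optional cardiac/respiratory modulation
#' of that tensor.
#'
#' @param grid_shape integer vector of 3 voxel counts (each >= 8).
#' @param voxel_size isotropic voxel size in mm.
#' @param structures list of [csf_structure()] specifications.
#' @param csf_signal CSF signal amplitude in arbitrary units; tissue and
#'   blood are fully suppressed (signal 0 outside structures).
#' @param noise_sd per-channel s.d. of the complex Gaussian noise added in
#'   k-space (magnitude images therefore carry Rician noise). Default
#'   `csf_signal / 50`, i.e. a reference SNR of 50.
#' @param seed integer seed for phantom-level randomness.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size, structures,
                         csf_signal = 1000, noise_sd = csf_signal / 50,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            voxel_size > 0, csf_signal > 0, noise_sd >= 0,
            length(structures) >= 1)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size,
                 structures = structures,
                 csf_signal = csf_signal,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specify one CSF compartment of a phantom
#'
#' @param kind `"ellipsoid"` (center + semi-axes) or `"tube"` (segment
#'   endpoints + radius). All geometry in mm, world coordinates with the
#'   voxel (0,0,0) center at the origin (diagonal RAS affine).
#' @param center,axes ellipsoid center and semi-axis lengths (mm).
#' @param p1,p2,radius tube endpoints and radius (mm).
#' @param base_mobility mean eigenvalue of the ground-truth tensor, mm^2/s.
#' @param fa target fractional anisotropy in `[0, 1)`; 0 gives an isotropic
#'   tensor.
#' @param axis principal direction (unit vector) when `fa > 0`; defaults to
#'   the tube axis for tubes and +z for ellipsoids.
#' @param cardiac_amp,resp_amp fractional modulation amplitudes of the
#'   tensor over the cardiac/respiratory cycle (e.g. 0.032 for 3.2%).
#' @param spatial_phase phase offset (radians) of the oscillation for this
#'   structure.
#' @return an object of class `csf_structure`.
#' @export
csf_structure <- function(kind = c("ellipsoid", "tube"),
                          center = NULL, axes = NULL,
                          p1 = NULL, p2 = NULL, radius = NULL,
                          base_mobility, fa = 0, axis = NULL,
                          cardiac_amp = 0, resp_amp = 0, spatial_phase = 0) {
  kind <- match.arg(kind)
  stopifnot(base_mobility >= 0, fa >= 0, fa < 1,
            cardiac_amp >= 0, cardiac_amp <= 0.5,
            resp_amp >= 0, resp_amp <= 0.5)
  if (kind == "ellipsoid") {
    stopifnot(length(center) == 3, length(axes) == 3, all(axes > 0))
  } else {
    stopifnot(length(p1) == 3, length(p2) == 3, radius > 0)
    if (is.null(axis)) {
      axis <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    }
  }
  if (is.null(axis)) axis <- c(0, 0, 1)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = kind, center = center, axes = axes,
                 p1 = p1, p2 = p2, radius = radius,
                 base_mobility = base_mobility, fa = fa, axis = axis,
                 cardiac_amp = cardiac_amp, resp_amp = resp_amp,
                 spatial_phase = spatial_phase),
            class = "csf_structure")
}

#' Eigenvalues of an axially symmetric tensor with given mean and FA
#'
#' Inverts the (mean eigenvalue, fractional anisotropy) pair under the
#' axially symmetric convention `lambda2 = lambda3`:
#' `delta = fa / sqrt(3 - 2 fa^2)`, eigenvalues
#' `mean * (1 + 2 delta, 1 - delta, 1 - delta)`. For `fa < 1` all
#' eigenvalues are strictly positive.
#'
#' @param mean_eig mean eigenvalue (mm^2/s).
#' @param fa fractional anisotropy in `[0, 1)`.
#' @return numeric vector of 3 eigenvalues, decreasing.
#' @export
eigenvalues_from_metrics <- function(mean_eig, fa) {
  stopifnot(mean_eig >= 0, fa >= 0, fa < 1)
  delta <- fa / sqrt(3 - 2 * fa^2)
  mean_eig * c(1 + 2 * delta, 1 - delta, 1 - delta)
}

#' Fractional anisotropy of an eigenvalue triple
#'
#' `FA = sqrt(3/2) * sqrt(sum((l - lbar)^2)) / sqrt(sum(l^2))`, defined as 0
#' when all eigenvalues are 0.
#'
#' @param l numeric vector of 3 eigenvalues.
#' @return FA in `[0, 1]`.
#' @export
fa_of_eigenvalues <- function(l) {
  ss <- sum(l^2)
  if (ss == 0) return(0)
  lbar <- mean(l)
  sqrt(3 / 2) * sqrt(sum((l - lbar)^2) / ss)
}

## tensor (6-component) for one structure
structure_tensor6 <- function(st) {
  l <- eigenvalues_from_metrics(st$base_mobility, st$fa)
  a <- st$axis
  m <- diag(rep(l[2], 3)) + (l[1] - l[2]) * (a %*% t(a))
  mat_to_tensor6(m)
}

## world coordinates (mm) of voxel centers, 0-based indices times voxel size
voxel_grid_mm <- function(grid_shape, voxel_size) {
  lapply(grid_shape, function(n) (seq_len(n) - 1) * voxel_size)
}

structure_mask <- function(st, grid_shape, voxel_size) {
  co <- voxel_grid_mm(grid_shape, voxel_size)
  X <- array(rep(co[[1]], times = grid_shape[2] * grid_shape[3]), grid_shape)
  Y <- array(rep(rep(co[[2]], each = grid_shape[1]), times = grid_shape[3]),
             grid_shape)
  Z <- array(rep(co[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  lim <- (grid_shape - 1) * voxel_size
  if (st$kind == "ellipsoid") {
    lo <- st$center - st$axes; hi <- st$center + st$axes
    if (any(lo < 0) || any(hi > lim)) {
      stop("structure extends outside the phantom grid", call. = FALSE)
    }
    ((X - st$center[1]) / st$axes[1])^2 +
      ((Y - st$center[2]) / st$axes[2])^2 +
      ((Z - st$center[3]) / st$axes[3])^2 <= 1
  } else {
    lo <- pmin(st$p1, st$p2) - st$radius; hi <- pmax(st$p1, st$p2) + st$radius
    if (any(lo < 0) || any(hi > lim)) {
      stop("structure extends outside the phantom grid", call. = FALSE)
    }
    d <- st$p2 - st$p1
    len2 <- sum(d^2)
    t_ <- ((X - st$p1[1]) * d[1] + (Y - st$p1[2]) * d[2] +
             (Z - st$p1[3]) * d[3]) / len2
    t_ <- pmin(pmax(t_, 0), 1)
    (X - st$p1[1] - t_ * d[1])^2 + (Y - st$p1[2] - t_ * d[2])^2 +
      (Z - st$p1[3] - t_ * d[3])^2 <= st$radius^2
  }
}

#' Generate a phantom with ground truth
#'
#' Rasterizes all structures onto the voxel grid (later structures win where
#' they overlap), assigns each in-structure voxel its ground-truth mobility
#' tensor, CSF signal amplitude and modulation parameters, and stores the
#' per-structure masks for downstream ROI analysis.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth` with elements `tensor0`
#'   (x,y,z,6 array, component order Dxx,Dxy,Dxz,Dyy,Dyz,Dzz), `signal`,
#'   `structure_masks`, `modulation` (list of `A_c`, `A_r`, `psi` volumes),
#'   `csf_mask`, and the originating `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  tensor0 <- array(0, c(gs, 6))
  signal <- array(0, gs)
  A_c <- array(0, gs); A_r <- array(0, gs); psi <- array(0, gs)
  masks <- vector("list", length(spec$structures))
  claim <- array(FALSE, gs)
  ## rasterize in reverse so the later structure wins, then re-derive the
  ## (disjoint) masks front-to-back
  for (i in rev(seq_along(spec$structures))) {
    st <- spec$structures[[i]]
    m <- structure_mask(st, gs, spec$voxel_size) & !claim
    claim <- claim | m
    masks[[i]] <- m
    t6 <- structure_tensor6(st)
    idx <- which(m)
    for (k in 1:6) {
      comp <- tensor0[, , , k]
      comp[idx] <- t6[k]
      tensor0[, , , k] <- comp
    }
    signal[idx] <- spec$csf_signal
    A_c[idx] <- st$cardiac_amp
    A_r[idx] <- st$resp_amp
    psi[idx] <- st$spatial_phase
  }
  structure(list(tensor0 = tensor0, signal = signal,
                 structure_masks = masks,
                 modulation = list(A_c = A_c, A_r = A_r, psi = psi),
                 csf_mask = claim, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  gs <- x$spec$grid_shape
  cat(sprintf("CSF mobility phantom: %d x %d x %d voxels @ %.2f mm\n",
              gs[1], gs[2], gs[3], x$spec$voxel_size))
  cat(sprintf("  %d structure(s), %d CSF voxels, signal %.0f a.u., noise sd %.1f\n",
              length(x$structure_masks), sum(x$csf_mask),
              x$spec$csf_signal, x$spec$noise_sd))
  invisible(x)
}

#' Per-voxel modulation factor at given physiological phases
#'
#' The ground-truth tensor oscillates multiplicatively:
#' `D(phi_c, phi_r) = D0 * (1 + A_c sin(2 pi phi_c + psi)
#'                            + A_r sin(2 pi phi_r + psi))`.
#' The scaling preserves tensor shape (FA and orientation are unchanged).
#'
#' @param truth a [make_phantom()] result.
#' @param cardiac_phase,resp_phase phases in `[0, 1)`.
#' @return numeric volume of scale factors.
#' @keywords internal
modulation_scale <- function(truth, cardiac_phase, resp_phase) {
  s <- 1 + truth$modulation$A_c * sin(2 * pi * cardiac_phase + truth$modulation$psi) +
    truth$modulation$A_r * sin(2 * pi * resp_phase + truth$modulation$psi)
  if (any(s[truth$csf_mask] <= 0)) {
    stop("modulation amplitudes too large: non-positive tensor scaling",
         call. = FALSE)
  }
  s
}

#' Modulated ground-truth tensor volume
#'
#' @inheritParams modulation_scale
#' @return an (x,y,z,6) tensor array.
#' @export
modulate_tensors <- function(truth, cardiac_phase, resp_phase) {
  stopifnot(inherits(truth, "phantom_truth"),
            cardiac_phase >= 0, cardiac_phase < 1,
            resp_phase >= 0, resp_phase < 1)
  s <- modulation_scale(truth, cardiac_phase, resp_phase)
  out <- truth$tensor0
  for (k in 1:6) out[, , , k] <- out[, , , k] * s
  out
}

#' Generate quasi-periodic physiological traces with ground-truth peaks
#'
#' Emulates the recorded pulse-unit and respiration-belt signals: inter-peak
#' intervals are Gaussian around the nominal period with coefficient of
#' variation `jitter`, and the trace between peaks is a raised cosine of the
#' intra-cycle phase (maxima exactly at the peaks). Ground-truth peak times
#' are stored so peak detection can be tested against truth.
#'
#' @param duration trace length in seconds (must cover the scan).
#' @param cardiac_rate,resp_rate nominal rates in Hz; respiration must be
#'   slower than the heart.
#' @param jitter coefficient of variation of inter-peak intervals, `[0, 0.5)`.
#' @param seed integer seed.
#' @param sample_rate trace sampling rate in Hz.
#' @return an object of class `physio_traces` with `time`, `cardiac`,
#'   `respiratory`, `cardiac_peaks`, `resp_peaks`, `sample_rate`.
#' @export
make_physio_traces <- function(duration, cardiac_rate = 1.0, resp_rate = 0.25,
                               jitter = 0.05, seed = 1L, sample_rate = 100) {
  stopifnot(duration > 0, cardiac_rate > 0, resp_rate > 0,
            jitter >= 0, jitter < 0.5)
  if (resp_rate >= cardiac_rate) {
    stop("respiratory rate must be below cardiac rate", call. = FALSE)
  }
  gen_peaks <- function(rate, sub) {
    period <- 1 / rate
    n <- ceiling(duration * rate) + 10L
    set.seed(seed_substream(seed, sub))
    iv <- stats::rnorm(n, period, jitter * period)
    iv <- pmax(iv, 0.2 * period)
    pk <- cumsum(c(0, iv))
    pk[pk < duration]
  }
  cp <- gen_peaks(cardiac_rate, "cardiac_peaks")
  rp <- gen_peaks(resp_rate, "resp_peaks")
  t_ <- seq(0, duration, by = 1 / sample_rate)
  t_ <- t_[t_ < duration]  # trace covers [0, duration)
  trace_from_peaks <- function(pk) {
    phi <- phase_from_peaks(t_, pk)
    cos(2 * pi * phi)
  }
  structure(list(time = t_,
                 cardiac = trace_from_peaks(cp),
                 respiratory = trace_from_peaks(rp),
                 cardiac_peaks = cp, resp_peaks = rp,
                 sample_rate = sample_rate, duration = duration),
            class = "physio_traces")
}

## intra-cycle phase by linear interpolation between consecutive peaks;
## outside the recorded peak range the cycle is extrapolated periodically
## with the median inter-peak interval
phase_from_peaks <- function(t_, peaks) {
  stopifnot(length(peaks) >= 2, all(diff(peaks) > 0))
  med <- stats::median(diff(peaks))
  ext <- c(peaks[1] - med * ceiling(max(0, peaks[1] - min(t_)) / med + 1):1,
           peaks,
           peaks[length(peaks)] + med * 1:ceiling(max(0, max(t_) - peaks[length(peaks)]) / med + 1))
  i <- findInterval(t_, ext)
  lo <- ext[i]; hi <- ext[i + 1]
  ((t_ - lo) / (hi - lo)) %% 1
}

#' Apply Rician magnitude noise to a noiseless image
#'
#' Adds independent Gaussian noise of s.d. `sd` to the real and imaginary
#' channels and takes the magnitude, the noise model of magnitude MRI.
#'
#' @param img numeric array (noiseless magnitude).
#' @param sd per-channel noise s.d.
#' @param seed integer seed.
#' @return numeric array of noisy magnitudes.
#' @export
add_rician_noise <- function(img, sd, seed = 1L) {
  set.seed(seed_substream(seed, "rician"))
  n <- length(img)
  sqrt((img + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
}
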