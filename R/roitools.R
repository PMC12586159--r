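#' CSF mask configuration
#'
#' @param csf_threshold reference-signal threshold, a.u. (150 default).
#' @param max_change maximal tolerated absolute percent change in mobility
#'   in any provided change volume (50 default).
#' @param remove_lonely drop voxels with no in-mask neighbors.
#' @param connectivity neighborhood for the lonely-voxel rule: 6, 18 or 26.
#' @return an object of class `mask_config`.
#' @export
mask_config <- function(csf_threshold = 150, max_change = 50,
                        remove_lonely = TRUE, connectivity = 26L) {
  stopifnot(csf_threshold > 0, max_change > 0,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(csf_threshold = csf_threshold, max_change = max_change,
                 remove_lonely = remove_lonely,
                 connectivity = as.integer(connectivity)),
            class = "mask_config")
}

neighbor_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  ord <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[ord == 1, , drop = FALSE],
         "18" = off[ord <= 2, , drop = FALSE],
         "26" = off)
}

## number of TRUE neighbors of each voxel under the given connectivity
neighbor_count <- function(mask, connectivity) {
  d <- dim(mask)
  cnt <- array(0L, d)
  num <- array(as.integer(mask), d)
  offs <- neighbor_offsets(connectivity)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    src <- list(seq_len(d[1]) + o[1], seq_len(d[2]) + o[2], seq_len(d[3]) + o[3])
    ok <- lapply(seq_len(3), function(i) src[[i]] >= 1 & src[[i]] <= d[i])
    dst <- lapply(seq_len(3), function(i) seq_len(d[i])[ok[[i]]])
    srcc <- lapply(seq_len(3), function(i) src[[i]][ok[[i]]])
    cnt[dst[[1]], dst[[2]], dst[[3]]] <- cnt[dst[[1]], dst[[2]], dst[[3]]] +
      num[srcc[[1]], srcc[[2]], srcc[[3]]]
  }
  cnt
}

#' CSF mask from the reference scan and change maps
#'
#' Applies the three masking rules in order: (1) keep voxels whose
#' reference (non-motion-sensitized) signal is at least the threshold; (2)
#' drop voxels whose absolute percent change in mobility exceeds
#' `max_change` in any provided change volume (noise-dominated voxels);
#' (3) drop 'lonely' voxels with no remaining in-mask neighbors. Rules 1
#' and 2 are pointwise and commute; the lonely rule runs last in a single
#' pass.
#'
#' @param reference reference magnitude volume, a.u.
#' @param change_volumes list of percent-change volumes (e.g. max absolute
#'   change per driving force); may be empty.
#' @param cfg a [mask_config()].
#' @return logical volume.
#' @export
csf_mask <- function(reference, change_volumes = list(), cfg = mask_config()) {
  mask <- reference >= cfg$csf_threshold
  for (cv in change_volumes) {
    mask <- mask & !(abs(cv) > cfg$max_change & !is.na(cv))
  }
  if (isTRUE(cfg$remove_lonely)) {
    mask <- mask & neighbor_count(mask, cfg$connectivity) > 0
  }
  mask
}

#' Ridge filter configuration
#'
#' @param mode `"frangi"` or `"meijering"`.
#' @param sigmas smoothing scales in mm (default 0.6, 0.8, 1.0).
#' @param vesselness_constant Frangi's alpha and beta (0.5 default).
#' @param threshold vesselness cutoff for the segmented mask, as a fraction
#'   of the maximum response.
#' @return an object of class `ridge_config`.
#' @export
ridge_config <- function(mode = c("frangi", "meijering"),
                         sigmas = c(0.6, 0.8, 1.0),
                         vesselness_constant = 0.5, threshold = 0.25) {
  mode <- match.arg(mode)
  stopifnot(all(sigmas > 0), vesselness_constant > 0, threshold >= 0)
  structure(list(mode = mode, sigmas = sigmas,
                 vesselness_constant = vesselness_constant,
                 threshold = threshold),
            class = "ridge_config")
}

## Hessian (6 components, scale-normalized by sigma^2) of a Gaussian-smoothed
## volume; spacing in mm
hessian3 <- function(vol, sigma_mm, voxel_size) {
  s <- gauss_smooth3(vol, sigma_mm / voxel_size)
  d <- dim(vol)
  cd <- function(x, axis) {  # central first difference, replicate edges
    hi <- lo <- seq_len(d[axis])
    hi <- pmin(hi + 1L, d[axis]); lo <- pmax(lo - 1L, 1L)
    idx_hi <- idx_lo <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_hi[[axis]] <- hi; idx_lo[[axis]] <- lo
    (x[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]], drop = FALSE] -
       x[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]], drop = FALSE]) / (2 * voxel_size)
  }
  g1 <- cd(s, 1); g2 <- cd(s, 2); g3 <- cd(s, 3)
  list(xx = cd(g1, 1), xy = cd(g1, 2), xz = cd(g1, 3),
       yy = cd(g2, 2), yz = cd(g2, 3), zz = cd(g3, 3),
       norm = sigma_mm^2)
}

#' Multiscale Hessian ridge filter (Frangi / Meijering) for 3D volumes
#'
#' Computes the Hessian eigenvalues at each scale (sigma^2-normalized
#' Gaussian derivatives) and the bright-tube vesselness. Frangi mode uses
#' the plate/blob/structure terms with `alpha = beta = vesselness_constant`
#' and per-scale `c` set to half the maximal Hessian norm; Meijering mode
#' uses the neuriteness variant (modified eigenvalues with alpha = -1/3).
#' The response is the maximum over scales; the segmented mask thresholds
#' it at `threshold * max(response)`.
#'
#' @param volume 3D numeric array.
#' @param voxel_size isotropic voxel size, mm.
#' @param cfg a [ridge_config()].
#' @return list with `response` (vesselness volume, 0..1-scaled per mode)
#'   and `mask`.
#' @export
ridge_filter <- function(volume, voxel_size, cfg = ridge_config()) {
  stopifnot(length(dim(volume)) == 3)
  if (length(voxel_size) > 1 && diff(range(voxel_size)) > 1e-9) {
    stop("anisotropic voxels: resample to isotropic before ridge filtering",
         call. = FALSE)
  }
  voxel_size <- voxel_size[1]
  d <- dim(volume)
  nvox <- prod(d)
  best <- array(0, d)
  for (sg in cfg$sigmas) {
    H <- hessian3(volume, sg, voxel_size)
    ## eigenvalues of the symmetric 3x3 Hessian per voxel, |l1|<=|l2|<=|l3|
    ev <- sym3_eigvals(H$xx * H$norm, H$xy * H$norm, H$xz * H$norm,
                       H$yy * H$norm, H$yz * H$norm, H$zz * H$norm)
    ord <- t(apply(abs(ev), 1, order))
    l1 <- ev[cbind(seq_len(nvox), ord[, 1])]
    l2 <- ev[cbind(seq_len(nvox), ord[, 2])]
    l3 <- ev[cbind(seq_len(nvox), ord[, 3])]
    if (cfg$mode == "frangi") {
      a2 <- 2 * cfg$vesselness_constant^2
      S <- sqrt(l1^2 + l2^2 + l3^2)
      cc <- max(S) / 2
      if (cc == 0) cc <- 1
      Ra <- abs(l2) / pmax(abs(l3), .Machine$double.xmin)
      Rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), .Machine$double.xmin)
      v <- (1 - exp(-Ra^2 / a2)) * exp(-Rb^2 / a2) *
        (1 - exp(-S^2 / (2 * cc^2)))
      v[l2 > 0 | l3 > 0] <- 0  # bright tubes: both large eigenvalues negative
    } else {
      ## Meijering neuriteness: modified eigenvalues, alpha = -1/3
      m1 <- l1 - (l2 + l3) / 3
      m2 <- l2 - (l1 + l3) / 3
      m3 <- l3 - (l1 + l2) / 3
      mm <- pmin(m1, m2, m3)
      lmin <- min(mm)
      v <- if (lmin < 0) ifelse(mm < 0, mm / lmin, 0) else rep(0, nvox)
    }
    best <- pmax(best, array(v, d))
  }
  mask <- best > cfg$threshold * max(best)
  if (max(best) == 0) mask <- array(FALSE, d)
  list(response = best, mask = mask)
}

## closed-form eigenvalues of many symmetric 3x3 matrices (vectorized,
## trigonometric method); returns n x 3, unordered
sym3_eigvals <- function(xx, xy, xz, yy, yz, zz) {
  n <- length(xx)
  p1 <- xy^2 + xz^2 + yz^2
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  out <- matrix(0, n, 3)
  diagm <- p < 1e-300
  if (any(!diagm)) {
    i <- which(!diagm)
    bxx <- (xx[i] - q[i]) / p[i]; byy <- (yy[i] - q[i]) / p[i]
    bzz <- (zz[i] - q[i]) / p[i]
    bxy <- xy[i] / p[i]; bxz <- xz[i] / p[i]; byz <- yz[i] / p[i]
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[i] + 2 * p[i] * cos(phi)
    e3 <- q[i] + 2 * p[i] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[i] - e1 - e3
    out[i, ] <- cbind(e1, e2, e3)
  }
  if (any(diagm)) {
    i <- which(diagm)
    out[i, ] <- cbind(xx[i], yy[i], zz[i])
  }
  out
}

## exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
## separable 1-D lower envelopes per axis; f is +Inf off the seed set
edt1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0) return(f)
  v <- integer(length(fin)); z <- numeric(length(fin) + 1)
  k <- 1L; v[1] <- fin[1]; z[1] <- -Inf; z[2] <- Inf
  for (qi in fin[-1]) {
    repeat {
      s <- ((f[qi] + qi^2) - (f[v[k]] + v[k]^2)) / (2 * qi - 2 * v[k])
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- qi; z[k] <- s; z[k + 1] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (qi in seq_len(n)) {
    while (z[k + 1] < qi) k <- k + 1L
    d[qi] <- (qi - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform of a 3D mask
#'
#' Distance (mm) from every voxel to the nearest `TRUE` voxel.
#'
#' @param mask logical 3D array (must contain at least one `TRUE`).
#' @param voxel_size isotropic voxel size, mm.
#' @return numeric volume of distances in mm.
#' @export
distance_transform <- function(mask, voxel_size) {
  stopifnot(any(mask))
  d <- dim(mask)
  f <- array(ifelse(mask, 0, Inf), d)
  for (axis in 1:3) {
    f <- apply(f, setdiff(1:3, axis), edt1d)
    ## apply returns the swept axis first; restore the original order
    f <- aperm(f, order(c(axis, setdiff(1:3, axis))))
  }
  sqrt(f) * voxel_size
}

#' Concentric dilation rims around a vessel mask
#'
#' Inflates the vessel by Euclidean distance: rim `k` holds the CSF voxels
#' whose distance to the vessel lies in `((k-1) step, k step]`, for
#' `k = 1..floor(max_dist/step)` (defaults 0.17 mm steps up to 3.00 mm,
#' 17 rims). Euclidean distance is used rather than iterated
#' structuring-element dilation, which would distort sub-voxel steps
#' towards Chebyshev distance.
#'
#' @param vessel_mask logical vessel volume.
#' @param voxel_size isotropic voxel size, mm.
#' @param csf logical CSF mask restricting the rims.
#' @param mobility,fa optional maps averaged per rim.
#' @param step rim width, mm (must be >= voxel size).
#' @param max_dist outer radius, mm.
#' @return object of class `rim_profile`: data frame with `rim`,
#'   `distance_mm` (outer edge), `n_voxels`, `mobility_mean`, `fa_mean`;
#'   attribute `rim_index` holds the per-voxel rim labels (0 = none).
#' @export
dilation_rims <- function(vessel_mask, voxel_size, csf,
                          mobility = NULL, fa = NULL,
                          step = 0.17, max_dist = 3.00) {
  if (!any(vessel_mask)) stop("empty vessel mask", call. = FALSE)
  if (step < voxel_size) {
    stop("rim step must be at least one voxel", call. = FALSE)
  }
  n_rims <- floor(max_dist / step + 1e-9)
  dist <- distance_transform(vessel_mask, voxel_size)
  rim_idx <- array(0L, dim(vessel_mask))
  inside <- dist > 0 & dist <= n_rims * step & csf
  rim_idx[inside] <- pmin(ceiling(dist[inside] / step - 1e-12), n_rims)
  out <- data.frame(rim = seq_len(n_rims),
                    distance_mm = step * seq_len(n_rims))
  out$n_voxels <- vapply(seq_len(n_rims), function(k) sum(rim_idx == k), integer(1))
  stat <- function(map, k) {
    if (is.null(map) || out$n_voxels[k] == 0) NA_real_ else
      mean(map[rim_idx == k])
  }
  out$mobility_mean <- vapply(seq_len(n_rims), function(k) stat(mobility, k), numeric(1))
  out$fa_mean <- vapply(seq_len(n_rims), function(k) stat(fa, k), numeric(1))
  structure(out, class = c("rim_profile", "data.frame"), rim_index = rim_idx)
}

#' ROI mean, s.d. and normal-approximation confidence half-width
#'
#' `CI = 1.96 * sd / sqrt(n)`. With a single observation the s.d. and CI
#' are undefined and flagged `NA`.
#'
#' @param map numeric volume (or vector of per-individual values).
#' @param mask logical selector (default all).
#' @return list with `mean`, `sd`, `ci_halfwidth`, `n`.
#' @export
roi_stats <- function(map, mask = NULL) {
  x <- if (is.null(mask)) as.numeric(map) else map[as.logical(mask)]
  if (length(x) == 0) stop("empty mask", call. = FALSE)
  n <- length(x)
  s <- if (n > 1) stats::sd(x) else NA_real_
  list(mean = mean(x), sd = s,
       ci_halfwidth = if (n > 1) 1.96 * s / sqrt(n) else NA_real_,
       n = n)
}

#' Nonparametric group comparisons
#'
#' `paired_multi` runs a Friedman test across >= 3 paired conditions;
#' `paired_two` a two-sided Wilcoxon signed-rank test (exact for n <= 25
#' without ties/zeros); `independent_two` a two-sided Mann-Whitney U test
#' (exact for small samples without ties). Bonferroni correction
#' multiplies p by `correction`, capped at 1.
#'
#' @param samples for `paired_multi` a matrix (rows = subjects, cols =
#'   conditions); otherwise a list of two numeric vectors.
#' @param design `"paired_multi"`, `"paired_two"` or `"independent_two"`.
#' @param correction Bonferroni multiplier m (number of comparisons).
#' @return list with `statistic`, `p_value`, `p_adjusted`, `method`.
#' @export
nonparam_tests <- function(samples,
                           design = c("paired_multi", "paired_two", "independent_two"),
                           correction = 1L) {
  design <- match.arg(design)
  res <- switch(design,
    paired_multi = {
      m <- as.matrix(samples)
      stopifnot(nrow(m) >= 3, ncol(m) >= 3)
      ft <- stats::friedman.test(m)
      list(statistic = unname(ft$statistic), p_value = ft$p.value,
           method = "Friedman")
    },
    paired_two = {
      stopifnot(length(samples) == 2, length(samples[[1]]) >= 3,
                length(samples[[1]]) == length(samples[[2]]))
      dif <- samples[[1]] - samples[[2]]
      if (all(dif == 0)) {
        warning("zero-variance paired differences: p = 1 by convention")
        list(statistic = 0, p_value = 1, method = "Wilcoxon signed-rank")
      } else {
        wt <- stats::wilcox.test(samples[[1]], samples[[2]], paired = TRUE,
                                 exact = length(dif) <= 25, correct = FALSE)
        list(statistic = unname(wt$statistic), p_value = wt$p.value,
             method = "Wilcoxon signed-rank")
      }
    },
    independent_two = {
      stopifnot(length(samples) == 2, length(samples[[1]]) >= 3,
                length(samples[[2]]) >= 3)
      wt <- stats::wilcox.test(samples[[1]], samples[[2]],
                               exact = length(samples[[1]]) + length(samples[[2]]) <= 50,
                               correct = FALSE)
      list(statistic = unname(wt$statistic), p_value = wt$p.value,
           method = "Mann-Whitney U")
    })
  res$p_adjusted <- min(1, res$p_value * correction)
  res
}

#' Stimulation-response metrics
#'
#' Percent mobility change between stimulation-on and -off conditions per
#' ROI, `100 * (mean_on - mean_off) / mean_off`, and the BOLD amplitude of
#' the averaged stimulation blocks:
#' `100 * (mean(dynamics 15-20) - mean(dynamics 5-10)) / mean(dynamics
#' 5-10)` (1-based inclusive dynamic indices, blocks averaged first).
#'
#' @param mobility_on,mobility_off aligned mobility maps.
#' @param roi_active,roi_control logical ROIs (e.g. z > 7 cluster and
#'   z < 1 control region).
#' @param bold_timeseries matrix of 3 stimulation blocks x 20 dynamics.
#' @return list with `active_change_pct`, `control_change_pct`,
#'   `bold_amplitude_pct`.
#' @export
stim_response <- function(mobility_on, mobility_off, roi_active, roi_control,
                          bold_timeseries) {
  stopifnot(all(dim(mobility_on) == dim(mobility_off)))
  bm <- as.matrix(bold_timeseries)
  if (!all(dim(bm) == c(3, 20))) {
    stop("bold_timeseries must be 3 blocks x 20 dynamics", call. = FALSE)
  }
  pct <- function(roi) {
    off <- mean(mobility_off[as.logical(roi)])
    100 * (mean(mobility_on[as.logical(roi)]) - off) / off
  }
  avg <- colMeans(bm)
  base <- mean(avg[5:10]); peak <- mean(avg[15:20])
  list(active_change_pct = pct(roi_active),
       control_change_pct = pct(roi_control),
       bold_amplitude_pct = 100 * (peak - base) / base)
}
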