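#' Fit the per-voxel CSF mobility tensor
#'
#' Inverts the motion-encoding signal model: for direction `g_i`,
#' `S_i = S_0 exp(-b g_i' D g_i)`, so `g_i' D g_i = -ln(S_i/S_0)/b`. The six
#' dual-axis directions give a full-rank 6 x 6 linear system solved exactly
#' per voxel (plain log-linear least squares; with 6 equations and 6
#' unknowns it reproduces noiseless data to machine precision). Voxels with
#' reference signal below `s0_threshold`, or with any non-positive signal,
#' are marked invalid. Negative eigenvalues are clamped to zero and
#' flagged: the model asserts a positive (semi)definite tensor but noise
#' can violate it.
#'
#' @param volumes magnitude array `(x, y, z, 7)`: reference then the six
#'   encoded subscans, mutually aligned.
#' @param directions 6 x 3 matrix of unit encoding directions
#'   (default [encoding_directions()]).
#' @param b effective encoding weight, s/mm^2.
#' @param s0_threshold reference-signal validity threshold, a.u.
#' @return an object of class `tensor_field`: per-voxel tensor components
#'   `D` (x,y,z,6; order Dxx,Dxy,Dxz,Dyy,Dyz,Dzz), eigenvalue maps
#'   `evals` (x,y,z,3; decreasing), `mobility` (mean eigenvalue, mm^2/s),
#'   `fa`, principal orientation `e1` (x,y,z,3), `valid` and `clamped`
#'   masks.
#' @export
fit_tensor <- function(volumes, directions = encoding_directions()$directions,
                       b, s0_threshold = 150) {
  stopifnot(length(dim(volumes)) == 4, dim(volumes)[4] == 7, b > 0,
            nrow(directions) == 6, ncol(directions) == 3)
  A <- t(apply(directions, 1, design_row))
  if (qr(A)$rank < 6) {
    stop("rank-deficient direction set: tensor not identifiable", call. = FALSE)
  }
  Ainv <- solve(A)
  d3 <- dim(volumes)[1:3]
  nvox <- prod(d3)
  S <- matrix(volumes, nvox, 7)
  valid <- S[, 1] >= s0_threshold & apply(S > 0, 1, all)
  D6 <- matrix(0, nvox, 6)
  if (any(valid)) {
    Y <- -log(S[valid, 2:7, drop = FALSE] / S[valid, 1]) / b
    D6[valid, ] <- Y %*% t(Ainv)
  }
  evals <- matrix(0, nvox, 3)
  e1 <- matrix(0, nvox, 3)
  clamped <- logical(nvox)
  for (i in which(valid)) {
    eg <- eigen(tensor6_to_mat(D6[i, ]), symmetric = TRUE)
    l <- eg$values
    if (any(l < 0)) {
      clamped[i] <- TRUE
      l <- pmax(l, 0)
    }
    evals[i, ] <- l
    v <- eg$vectors[, 1]
    ## sign convention: non-negative z, then y, then x
    s <- sign(v[3])
    if (s == 0) s <- sign(v[2])
    if (s == 0) s <- sign(v[1])
    if (s == 0) s <- 1
    e1[i, ] <- v * s
  }
  mobility <- rowMeans(evals)
  fa <- fa_map_from_evals(evals)
  structure(list(D = array(D6, c(d3, 6)),
                 evals = array(evals, c(d3, 3)),
                 mobility = array(mobility, d3),
                 fa = array(fa, d3),
                 e1 = array(e1, c(d3, 3)),
                 valid = array(valid, d3),
                 clamped = array(clamped, d3),
                 b = b, directions = directions,
                 s0_threshold = s0_threshold),
            class = "tensor_field")
}

## vectorized FA over an n x 3 eigenvalue matrix
fa_map_from_evals <- function(evals) {
  ss <- rowSums(evals^2)
  lbar <- rowMeans(evals)
  fa <- sqrt(3 / 2) * sqrt(rowSums((evals - lbar)^2) / pmax(ss, .Machine$double.xmin))
  fa[ss == 0] <- 0
  fa
}

#' @export
print.tensor_field <- function(x, ...) {
  n <- sum(x$valid)
  cat(sprintf("CSF mobility tensor field: %s voxels, %d valid (b = %g s/mm^2)\n",
              paste(dim(x$valid), collapse = " x "), n, x$b))
  if (n > 0) {
    cat(sprintf("  mobility %.4f +/- %.4f mm^2/s, FA %.3f +/- %.3f, %d clamped\n",
                mean(x$mobility[x$valid]), stats::sd(x$mobility[x$valid]),
                mean(x$fa[x$valid]), stats::sd(x$fa[x$valid]),
                sum(x$clamped)))
  }
  invisible(x)
}

#' @export
summary.tensor_field <- function(object, ...) {
  v <- object$valid
  out <- list(n_valid = sum(v), n_clamped = sum(object$clamped),
              mobility = summary(object$mobility[v]),
              fa = summary(object$fa[v]))
  class(out) <- "summary.tensor_field"
  out
}

#' @export
print.summary.tensor_field <- function(x, ...) {
  cat(sprintf("valid voxels: %d (clamped: %d)\nmobility (mm^2/s):\n",
              x$n_valid, x$n_clamped))
  print(x$mobility)
  cat("FA:\n")
  print(x$fa)
  invisible(x)
}

#' Derived maps of a tensor field with a physiological mobility cutoff
#'
#' Returns the mobility (mean eigenvalue), FA and principal-orientation
#' maps, excluding from the validity mask voxels whose mobility exceeds the
#' cutoff (default 0.15 mm^2/s, removing unphysiologically mobile
#' noise-dominated voxels).
#'
#' @param field a [fit_tensor()] result.
#' @param cutoff mobility cutoff, mm^2/s.
#' @return list with `mobility`, `fa`, `orientation`, `valid`.
#' @export
tensor_metrics <- function(field, cutoff = 0.15) {
  stopifnot(inherits(field, "tensor_field"))
  valid <- field$valid & field$mobility <= cutoff
  list(mobility = field$mobility, fa = field$fa,
       orientation = field$e1, valid = valid)
}
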