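#' Reconstruction configuration
#'
#' @param mode `"zero_fill"` (inverse centered FFT of the mask-filled
#'   k-space) or `"tv"` (proximal-gradient solve with total variation along
#'   the phase dimension).
#' @param lambda temporal-TV regularization weight, applied on data
#'   normalized to unit peak magnitude (0.005 default, 0.002 for the
#'   patient-protocol setting).
#' @param iterations proximal-gradient iterations (30 default).
#' @param step gradient step; default `1/L` with `L = 2` the Lipschitz
#'   constant of the squared data term under the unitary transform.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(mode = c("zero_fill", "tv"), lambda = 0.005,
                         iterations = 30L, step = NULL) {
  mode <- match.arg(mode)
  stopifnot(lambda >= 0, iterations >= 1)
  structure(list(mode = mode, lambda = lambda,
                 iterations = as.integer(iterations),
                 step = step %||% 0.5),
            class = "recon_config")
}

## zero-filled inverse transform of one phase
zf_one <- function(ksp, mask3) {
  ifft_centered(ksp * mask3)
}

expand_mask <- function(mask, nx) {
  array(rep(as.numeric(mask), each = nx), c(nx, dim(mask)))
}

## cyclic forward difference along the 4th (phase) dimension
tdiff <- function(x) {
  x[, , , c(2:dim(x)[4], 1), drop = FALSE] - x
}
## adjoint of tdiff (negative cyclic backward difference)
tdiff_adj <- function(u) {
  u[, , , c(dim(u)[4], 1:(dim(u)[4] - 1)), drop = FALSE] - u
}

## proximal operator of alpha * sum |cyclic diff| via Chambolle-type dual
## projected gradient; complex-modulus (isotropic in re/im) penalty
prox_tv_cyclic <- function(z, alpha, inner = 60L) {
  if (alpha <= 0) return(z)
  u <- array(0 + 0i, dim(z))
  tau <- 0.25  # 1 / ||D||^2 for the cyclic difference operator
  for (it in seq_len(inner)) {
    x <- z - tdiff_adj(u)
    u <- u + tau * tdiff(x)
    mag <- pmax(1, Mod(u) / alpha)
    u <- u / mag
  }
  z - tdiff_adj(u)
}

tv_objective <- function(x, y, mask4, lambda) {
  resid <- mask4 * apply_fft4(x) - y
  sum(Mod(resid)^2) + lambda * sum(Mod(tdiff(x)))
}

apply_fft4 <- function(x) {
  out <- x
  for (p in seq_len(dim(x)[4])) out[, , , p] <- fft_centered(x[, , , p])
  out
}
apply_ifft4 <- function(x) {
  out <- x
  for (p in seq_len(dim(x)[4])) out[, , , p] <- ifft_centered(x[, , , p])
  out
}

#' Reconstruct per-phase volumes from binned k-space
#'
#' Zero-fill mode inverts the centered unitary transform with unsampled
#' points at zero. TV mode minimizes
#' `sum_p ||M_p F x_p - y_p||^2 + lambda * sum |x_{p+1} - x_p|` (cyclic in
#' the phase index, complex-modulus differences) by proximal gradient from
#' the zero-fill initialization with a fixed iteration count; the data are
#' normalized to unit peak zero-fill magnitude so `lambda` is scale-free,
#' and the result is rescaled back. Deterministic throughout.
#'
#' @param binned a [bin_kspace()] result.
#' @param cfg a [recon_config()].
#' @return magnitude array `(nx, ky, kz, 6)`, with attribute `objective`
#'   (per-iteration objective values) in TV mode.
#' @export
reconstruct <- function(binned, cfg = recon_config()) {
  stopifnot(inherits(binned, "binned_kspace"))
  nx <- binned$dims[1]
  empty <- which(vapply(binned$mask, function(m) !any(m), logical(1)))
  if (length(empty)) {
    stop(sprintf("empty phase dataset(s): %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  d4 <- c(nx, binned$grid, 6L)
  y <- array(0 + 0i, d4)
  mask4 <- array(0, d4)
  for (p in 1:6) {
    m3 <- expand_mask(binned$mask[[p]], nx)
    mask4[, , , p] <- m3
    y[, , , p] <- binned$kspace[[p]] * m3
  }
  x <- apply_ifft4(y)  # zero-fill init
  if (cfg$mode == "zero_fill") {
    return(Mod(x))
  }
  scale <- max(Mod(x))
  if (scale == 0) scale <- 1
  y <- y / scale; x <- x / scale
  obj <- numeric(cfg$iterations + 1L)
  obj[1] <- tv_objective(x, y, mask4, cfg$lambda)
  for (it in seq_len(cfg$iterations)) {
    grad <- 2 * apply_ifft4(mask4 * (mask4 * apply_fft4(x) - y))
    x <- prox_tv_cyclic(x - cfg$step * grad, cfg$step * cfg$lambda)
    obj[it + 1L] <- tv_objective(x, y, mask4, cfg$lambda)
  }
  out <- Mod(x) * scale
  attr(out, "objective") <- obj
  out
}

#' Reconstruct an image series for all seven subscans
#'
#' @param binned_list list of 7 [bin_kspace()] results (reference first).
#' @param cfg a [recon_config()].
#' @return an object of class `image_series`: magnitude array
#'   `(nx, ky, kz, subscan 1..7, phase 1..6)`.
#' @export
reconstruct_series <- function(binned_list, cfg = recon_config()) {
  stopifnot(length(binned_list) == 7)
  first <- reconstruct(binned_list[[1]], cfg)
  out <- array(0, c(dim(first)[1:3], 7L, 6L))
  out[, , , 1, ] <- first
  for (s in 2:7) out[, , , s, ] <- reconstruct(binned_list[[s]], cfg)
  structure(out, class = "image_series")
}

#' Combined (phase-collapsed) reconstruction of one subscan
#'
#' Averages all shots' samples per profile irrespective of phase - the
#' static CSF image - and inverts the transform.
#'
#' @param subscan a [simulate_subscan()] result.
#' @param assignment optional [assign_bins()] result restricting the shots.
#' @return magnitude volume.
#' @export
reconstruct_static <- function(subscan, assignment = NULL) {
  sched <- subscan$schedule
  grid <- sched$grid
  nx <- subscan$dims[1]
  ksum <- matrix(0 + 0i, nx, grid[1] * grid[2])
  cnt <- integer(grid[1] * grid[2])
  shots <- if (is.null(assignment)) seq_along(sched$shots) else assignment$shot
  for (k in shots) {
    pr <- sched$profiles[sched$shots[[k]]$profile_indices, , drop = FALSE]
    lin <- pr[, 1] + 1L + grid[1] * pr[, 2]
    for (j in seq_along(lin)) {
      ksum[, lin[j]] <- ksum[, lin[j]] + subscan$shots[[k]][, j]
      cnt[lin[j]] <- cnt[lin[j]] + 1L
    }
  }
  ksum <- ksum / rep(pmax(cnt, 1L), each = nx)
  Mod(ifft_centered(array(ksum, c(nx, grid[1], grid[2]))))
}
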