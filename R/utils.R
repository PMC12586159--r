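#' Derive a named sub-stream seed from a master seed
#'
#' All stochastic stages (phantom noise, sampling pattern, acquisition noise,
#' random binning) draw their seed from one master seed through named
#' sub-streams, so a single integer reproduces a full pipeline run while the
#' stages stay statistically independent.
#'
#' @param seed master integer seed.
#' @param name character name of the sub-stream, e.g. `"pattern"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
seed_substream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

## circular shift of an array along every dimension
arr_circshift <- function(x, shifts) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(seq_along(d), function(i) {
    s <- shifts[i] %% d[i]
    if (s == 0) seq_len(d[i]) else c((d[i] - s + 1):d[i], seq_len(d[i] - s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fftshift_nd  <- function(x) arr_circshift(x, floor(dim2(x) / 2))
ifftshift_nd <- function(x) arr_circshift(x, ceiling(dim2(x) / 2))

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Centered unitary discrete Fourier transform
#'
#' Forward/inverse DFT with the zero-frequency sample at index
#' `floor(N/2)` (0-based) on every axis and `1/sqrt(N)` normalization, so
#' Parseval's identity holds exactly and `ifft_centered(fft_centered(x)) == x`.
#'
#' @param x numeric or complex array.
#' @return complex array of the same dimensions.
#' @export
fft_centered <- function(x) {
  fftshift_nd(stats::fft(ifftshift_nd(x))) / sqrt(prod(dim2(x)))
}

#' @rdname fft_centered
#' @export
ifft_centered <- function(x) {
  fftshift_nd(stats::fft(ifftshift_nd(x), inverse = TRUE)) / sqrt(prod(dim2(x)))
}

## 3x3 symmetric tensor packing: (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)
tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

mat_to_tensor6 <- function(m) c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])

## row-wise design for g' D g with the 6-component packing above
design_row <- function(g) {
  c(g[1]^2, 2 * g[1] * g[2], 2 * g[1] * g[3], g[2]^2, 2 * g[2] * g[3], g[3]^2)
}

## separable 1-D convolution of a 3-D array along one axis, replicate padding
conv_axis <- function(x, kernel, axis) {
  d <- dim(x)
  half <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  for (j in seq_along(kernel)) {
    off <- j - 1L - half
    src <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[axis]] <- src
    out <- out + kernel[j] * x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out
}

gauss_kernel <- function(sigma_vox) {
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

gauss_smooth3 <- function(x, sigma_vox) {
  k <- gauss_kernel(sigma_vox)
  conv_axis(conv_axis(conv_axis(x, k, 1L), k, 2L), k, 3L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
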