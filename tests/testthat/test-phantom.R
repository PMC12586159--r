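test_that("isotropic structures carry lambda*I tensors inside the mask", {
  tr <- iso_phantom(mob = 0.02)
  m <- tr$structure_masks[[1]]
  expect_gt(sum(m), 0)
  D <- matrix(tr$tensor0, length(m), 6)
  expect_equal(max(abs(D[m, c(1, 4, 6)] - 0.02)), 0)
  expect_equal(max(abs(D[m, c(2, 3, 5)])), 0)
  expect_equal(max(abs(D[!m, ])), 0)
})

test_that("axially symmetric spectrum inverts the (mean, FA) pair", {
  ## independent oracle: solve for the axially symmetric eigenvalues by
  ## root-finding on the FA formula, lambda = m * (1 + 2d, 1 - d, 1 - d)
  oracle <- function(mean_eig, fa) {
    d <- stats::uniroot(function(dl) fa_ref(c(1 + 2 * dl, 1 - dl, 1 - dl)) - fa,
                        c(0, 1 - 1e-12), tol = 1e-14)$root
    mean_eig * c(1 + 2 * d, 1 - d, 1 - d)
  }
  for (case in list(c(0.015, 0.716), c(0.041, 0.3), c(0.02, 0.9))) {
    l_pkg <- eigenvalues_from_metrics(case[1], case[2])
    l_ref <- oracle(case[1], case[2])
    expect_equal(l_pkg, l_ref, tolerance = 1e-9)
    expect_equal(mean(l_pkg), case[1], tolerance = 1e-12)
    expect_equal(fa_ref(l_pkg), case[2], tolerance = 1e-10)
  }
})

test_that("tube tensors have the principal axis along the tube and round-trip metrics", {
  tr <- tube_phantom(mob = 0.015, fa = 0.716)
  m <- which(tr$structure_masks[[1]])
  D6 <- matrix(tr$tensor0, length(tr$csf_mask), 6)
  for (i in m[c(1, length(m) %/% 2, length(m))]) {
    eg <- eigen(matrix(c(D6[i, 1], D6[i, 2], D6[i, 3],
                         D6[i, 2], D6[i, 4], D6[i, 5],
                         D6[i, 3], D6[i, 5], D6[i, 6]), 3), symmetric = TRUE)
    expect_equal(mean(eg$values), 0.015, tolerance = 1e-12)
    expect_equal(fa_ref(eg$values), 0.716, tolerance = 1e-10)
    expect_equal(abs(eg$vectors[3, 1]), 1, tolerance = 1e-10)
    expect_true(all(eg$values >= -1e-15))
  }
})

test_that("random specs always yield symmetric PSD tensors and FA/mean round-trip", {
  set.seed(42)
  for (rep in 1:10) {
    fa <- runif(1, 0, 0.95)
    mob <- runif(1, 0.005, 0.08)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    tr <- make_phantom(phantom_spec(
      c(16, 16, 16), 0.5,
      list(csf_structure("ellipsoid", center = rep(3.5, 3), axes = rep(2, 3),
                         base_mobility = mob, fa = fa, axis = ax))))
    i <- which(tr$structure_masks[[1]])[1]
    D6 <- matrix(tr$tensor0, 16^3, 6)[i, ]
    M <- matrix(c(D6[1], D6[2], D6[3], D6[2], D6[4], D6[5],
                  D6[3], D6[5], D6[6]), 3)
    expect_equal(M, t(M))
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-15))
    expect_equal(mean(ev), mob, tolerance = 1e-10)
    expect_equal(fa_ref(ev), fa, tolerance = 1e-10)
  }
})

test_that("structures outside the grid raise a geometry error", {
  expect_error(
    make_phantom(phantom_spec(
      c(16, 16, 16), 0.5,
      list(csf_structure("ellipsoid", center = c(7, 7, 7), axes = c(2, 2, 2),
                         base_mobility = 0.02)))),
    "outside")
  expect_error(
    make_phantom(phantom_spec(
      c(16, 16, 16), 0.5,
      list(csf_structure("tube", p1 = c(4, 4, -1), p2 = c(4, 4, 6),
                         radius = 1, base_mobility = 0.02)))),
    "outside")
})

test_that("tensor modulation is multiplicative, shape-preserving and centered", {
  tr <- tube_phantom(cardiac_amp = 0.032, resp_amp = 0)
  ## zero amplitudes: identity at any phase
  tr0 <- tube_phantom(cardiac_amp = 0, resp_amp = 0)
  expect_identical(modulate_tensors(tr0, 0.3, 0.7), tr0$tensor0)
  ## 3.2% cardiac amplitude at quarter phase scales by exactly 1.032
  Dm <- modulate_tensors(tr, 0.25, 0)
  m <- rep(tr$structure_masks[[1]], 6)
  expect_equal(Dm[m], (tr$tensor0 * 1.032)[m], tolerance = 1e-12)
  ## mean over 6 equally spaced phases returns D0 (sin sums to zero exactly)
  acc <- array(0, dim(tr$tensor0))
  for (k in 0:5) acc <- acc + modulate_tensors(tr, k / 6, 0)
  acc <- acc / 6
  rel <- max(abs(acc[m] - tr$tensor0[m])) / max(abs(tr$tensor0))
  expect_lt(rel, 0.032^2 / 2)
})

test_that("excessive modulation amplitudes raise an error", {
  tr <- make_phantom(phantom_spec(
    c(16, 16, 16), 0.5,
    list(csf_structure("ellipsoid", center = rep(3.5, 3), axes = rep(2, 3),
                       base_mobility = 0.02, cardiac_amp = 0.5,
                       resp_amp = 0.5, spatial_phase = 0))))
  ## both sinusoids at their minimum: scale hits zero
  expect_error(modulate_tensors(tr, 0.75, 0.75), "amplitudes too large")
})

test_that("physiological traces: exact peaks without jitter, counts, CV with jitter", {
  ph <- make_physio_traces(10, 1, 0.25, jitter = 0, seed = 1)
  expect_equal(ph$cardiac_peaks, 0:9)
  ph330 <- make_physio_traces(330, 1, 0.25, jitter = 0, seed = 1)
  expect_true(length(ph330$cardiac_peaks) %in% c(330, 331))
  ## coefficient of variation of inter-peak intervals tracks the jitter
  phj <- make_physio_traces(330, 1, 0.25, jitter = 0.05, seed = 7)
  iv <- diff(phj$cardiac_peaks)
  cv <- sd(iv) / mean(iv)
  expect_lt(abs(cv - 0.05) / 0.05, 0.20)
  expect_error(make_physio_traces(10, 0.25, 1), "respiratory")
})

test_that("identical seeds give bit-identical phantoms and traces", {
  s <- phantom_spec(c(16, 16, 16), 0.5,
                    list(csf_structure("ellipsoid", center = rep(3.5, 3),
                                       axes = rep(2, 3), base_mobility = 0.02)),
                    seed = 9)
  expect_identical(make_phantom(s), make_phantom(s))
  expect_identical(make_physio_traces(50, seed = 5), make_physio_traces(50, seed = 5))
  expect_false(identical(make_physio_traces(50, seed = 5)$cardiac_peaks,
                         make_physio_traces(50, seed = 6)$cardiac_peaks))
})

test_that("background stays below the CSF threshold after Rician noise", {
  tr <- iso_phantom(noise_sd = 20)
  expect_equal(max(tr$signal[!tr$csf_mask]), 0)
  noisy <- add_rician_noise(tr$signal, 20, seed = 3)
  expect_lt(max(noisy[!tr$csf_mask]), 0.15 * 1000)
  expect_gt(min(noisy[tr$csf_mask]), 150)
})
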