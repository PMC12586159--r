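test_that("CSF mask applies threshold, change-exclusion and lonely-voxel rules", {
  set.seed(21)
  d <- c(20, 20, 20)
  struct <- array(FALSE, d); struct[8:12, 8:12, 8:12] <- TRUE
  ref <- array(0, d); ref[struct] <- 1000
  noisy <- add_rician_noise(ref, 20, seed = 2)
  m <- csf_mask(noisy, list(), mask_config())
  expect_equal(m, struct)
  ## a voxel with 60% change in one dataset is excluded
  change <- array(0, d); change[10, 10, 10] <- 60
  m2 <- csf_mask(noisy, list(array(0, d), change), mask_config())
  expect_false(m2[10, 10, 10])
  expect_equal(sum(m2), sum(struct) - 1)
  ## an isolated bright voxel is lonely and removed
  ref2 <- ref; ref2[2, 2, 2] <- 1000
  m3 <- csf_mask(ref2, list(), mask_config())
  expect_false(m3[2, 2, 2])
  expect_equal(m3, struct)
  ## with the lonely rule off it stays
  expect_true(csf_mask(ref2, list(), mask_config(remove_lonely = FALSE))[2, 2, 2])
})

test_that("threshold and change rules commute; lonely removal is last", {
  set.seed(4)
  d <- c(12, 12, 12)
  ref <- array(runif(prod(d), 0, 400), d)
  cvs <- list(array(runif(prod(d), 0, 80), d), array(runif(prod(d), 0, 80), d))
  m_fwd <- csf_mask(ref, cvs, mask_config())
  m_rev <- csf_mask(ref, rev(cvs), mask_config())
  expect_identical(m_fwd, m_rev)
  ## manual composition: pointwise rules then a single lonely pass
  base <- ref >= 150 & !(abs(cvs[[1]]) > 50) & !(abs(cvs[[2]]) > 50)
  lonely <- csfmobility:::neighbor_count(base, 26L) == 0
  expect_identical(m_fwd, base & !lonely)
})

test_that("ridge filters: zero on uniform volumes, tube beats sphere, centerline recall", {
  d <- c(24, 24, 24)
  vx <- 0.45
  uni <- array(7, d)
  expect_equal(max(ridge_filter(uni, vx)$response), 0)
  expect_error(ridge_filter(uni, c(0.4, 0.4, 0.8)), "anisotropic")
  ## bright tube along z vs bright sphere of equal peak intensity
  co <- (seq_len(24) - 1) * vx
  X <- array(rep(co, 24 * 24), d)
  Y <- array(rep(rep(co, each = 24), 24), d)
  Z <- array(rep(co, each = 24 * 24), d)
  tube <- exp(-((X - 5.4)^2 + (Y - 5.4)^2) / (2 * 0.45^2))
  sphere <- exp(-((X - 5.4)^2 + (Y - 5.4)^2 + (Z - 5.4)^2) / (2 * 0.45^2))
  rt <- ridge_filter(tube * 100, vx)
  rs <- ridge_filter(sphere * 100, vx)
  ctr_line <- abs(X - 5.4) < 0.01 & abs(Y - 5.4) < 0.01 & Z > 2 & Z < 8.5
  expect_gt(median(rt$response[ctr_line]), rs$response[13, 13, 13])
  ## 1-voxel-radius tube: at least 90% of interior centerline segmented
  hard_tube <- array(0, d)
  hard_tube[(X - 5.4)^2 + (Y - 5.4)^2 <= 0.46^2] <- 100
  rh <- ridge_filter(hard_tube, vx, ridge_config(threshold = 0.25))
  interior <- ctr_line & Z > 3 & Z < 7.5
  expect_gte(mean(rh$mask[interior]), 0.9)
  ## meijering mode also responds to the tube and not to uniformity
  rm_ <- ridge_filter(hard_tube, vx, ridge_config(mode = "meijering"))
  expect_gt(median(rm_$response[interior]), 0)
  expect_equal(max(ridge_filter(uni, vx, ridge_config(mode = "meijering"))$response), 0)
})

test_that("distance transform matches brute force on random masks", {
  set.seed(8)
  d <- c(9, 10, 11)
  for (rep in 1:3) {
    mask <- array(runif(prod(d)) < 0.04, d)
    if (!any(mask)) mask[5, 5, 5] <- TRUE
    dt <- distance_transform(mask, 0.7)
    seeds <- which(mask, arr.ind = TRUE)
    idx <- which(array(TRUE, d), arr.ind = TRUE)
    brute <- apply(idx, 1, function(p) {
      sqrt(min(colSums((t(seeds) - p)^2))) * 0.7
    })
    expect_equal(as.numeric(dt), brute, tolerance = 1e-12)
  }
})

test_that("dilation rims partition the in-range shell with 17 default rims", {
  d <- c(24, 24, 24)
  vessel <- array(FALSE, d); vessel[12, 12, 4:20] <- TRUE
  csf <- array(TRUE, d)
  mob <- array(0.03, d)
  rp <- dilation_rims(vessel, voxel_size = 0.17, csf = csf, mobility = mob,
                      step = 0.17, max_dist = 3.00)
  expect_equal(nrow(rp), 17)
  expect_equal(rp$distance_mm[17], 2.89, tolerance = 1e-9)
  rim_idx <- attr(rp, "rim_index")
  ## pairwise disjoint by construction; union equals the in-range shell
  dt <- distance_transform(vessel, 0.17)
  shell <- dt > 0 & dt <= 17 * 0.17 & csf
  expect_equal(rim_idx > 0, shell)
  expect_equal(sum(rp$n_voxels), sum(shell))
  ## uniform mobility: every populated rim reports the same mean
  expect_true(all(abs(rp$mobility_mean[rp$n_voxels > 0] - 0.03) < 1e-12))
  expect_error(dilation_rims(array(FALSE, d), 0.17, csf), "empty vessel")
  expect_error(dilation_rims(vessel, 0.5, csf, step = 0.17), "at least one voxel")
})

test_that("ROI statistics and confidence intervals", {
  s <- roi_stats(1:8)
  expect_equal(s$mean, 4.5)
  expect_equal(s$sd, 2.449, tolerance = 1e-3)
  expect_equal(s$ci_halfwidth, 1.96 * s$sd / sqrt(8))
  expect_equal(s$ci_halfwidth, 1.697, tolerance = 1e-3)
  cst <- roi_stats(rep(3, 10))
  expect_equal(cst$ci_halfwidth, 0)
  expect_true(is.na(roi_stats(5)$ci_halfwidth))
  expect_error(roi_stats(array(1, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), "empty")
})

test_that("exact nonparametric tests match brute-force enumeration", {
  ## Mann-Whitney: fully separated groups of 8, p = 2 / choose(16, 8)
  r <- nonparam_tests(list(1:8, 101:108), design = "independent_two")
  expect_equal(r$p_value, 2 / choose(16, 8), tolerance = 1e-12)
  ## brute-force enumeration oracle for small random samples
  mw_exact <- function(x, y) {
    pooled <- c(x, y); n <- length(x)
    combs <- utils::combn(length(pooled), n)
    U_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
    Us <- apply(combs, 2, function(ix) {
      sum(rank(pooled)[ix]) - n * (n + 1) / 2
    })
    mu <- n * length(y) / 2
    mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  }
  set.seed(13)
  for (rep in 1:5) {
    x <- round(rnorm(6, 0, 10), 2); y <- round(rnorm(6, 5, 10), 2)
    if (any(duplicated(c(x, y)))) next
    r <- nonparam_tests(list(x, y), design = "independent_two")
    expect_equal(r$p_value, mw_exact(x, y), tolerance = 1e-9)
  }
  ## Wilcoxon signed-rank: all-positive distinct differences, n = 9 -> p = 2/2^9
  w <- nonparam_tests(list(cumsum(1:9), rep(0, 9)), design = "paired_two")
  expect_equal(w$p_value, 2 / 2^9, tolerance = 1e-12)
  ## sign-flip enumeration oracle
  sr_exact <- function(d) {
    n <- length(d); rk <- rank(abs(d))
    W_obs <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% rk
    mu <- n * (n + 1) / 4
    mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
  }
  set.seed(14)
  for (rep in 1:5) {
    d <- round(rnorm(8, 1.5, 2), 2)
    if (any(d == 0) || any(duplicated(abs(d)))) next
    r <- nonparam_tests(list(d, rep(0, 8)), design = "paired_two")
    expect_equal(r$p_value, sr_exact(d), tolerance = 1e-9)
  }
})

test_that("Friedman gate, Bonferroni correction and degenerate cases", {
  set.seed(6)
  m <- matrix(rnorm(30), 10, 3)
  m[, 1] <- m[, 1] + 3
  fr <- nonparam_tests(m, design = "paired_multi")
  expect_lt(fr$p_value, 0.05)
  expect_equal(fr$method, "Friedman")
  r <- nonparam_tests(list(1:5 + c(0.5, 0.7, 0.9, 1.1, 1.3), 1:5),
                      design = "paired_two", correction = 3)
  expect_equal(r$p_adjusted, min(1, r$p_value * 3))
  b <- nonparam_tests(list(c(1.5, 2.5, 3.5, 10), c(0, 1, 2, 3)),
                      design = "independent_two", correction = 3)
  expect_lte(b$p_adjusted, 1)
  expect_equal(round(min(1, 0.02 * 3), 10), 0.06)
  expect_warning(nonparam_tests(list(1:5, 1:5), design = "paired_two"),
                 "zero-variance")
})

test_that("stimulation response percent changes and BOLD amplitude", {
  d <- c(10, 10, 10)
  off <- array(0.03, d)
  roi_a <- array(FALSE, d); roi_a[2:4, 2:4, 2:4] <- TRUE
  roi_c <- array(FALSE, d); roi_c[7:9, 7:9, 7:9] <- TRUE
  bold_flat <- matrix(100, 3, 20)
  r0 <- stim_response(off, off, roi_a, roi_c, bold_flat)
  expect_equal(r0$active_change_pct, 0)
  expect_equal(r0$control_change_pct, 0)
  ## +1.2% mobility in the active ROI only
  on <- off
  on[roi_a] <- off[roi_a] * 1.012
  r1 <- stim_response(on, off, roi_a, roi_c, bold_flat)
  expect_equal(r1$active_change_pct, 1.2, tolerance = 1e-9)
  expect_equal(r1$control_change_pct, 0)
  ## BOLD: baseline 100 over dynamics 5-10, plateau 102 over 15-20 -> 2%
  ts <- matrix(100, 3, 20)
  ts[, 15:20] <- 102
  r2 <- stim_response(off, off, roi_a, roi_c, ts)
  expect_equal(r2$bold_amplitude_pct, 2, tolerance = 1e-12)
  expect_error(stim_response(off, off, roi_a, roi_c, matrix(1, 3, 19)), "3 blocks")
})
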