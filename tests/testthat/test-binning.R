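test_that("peak detection recovers cosine peaks including the boundary peak", {
  ph <- make_physio_traces(10, 1, 0.25, jitter = 0, seed = 1)
  pk <- detect_peaks(ph$cardiac, ph$time)
  expect_length(pk, 10)
  expect_true(all(abs(pk - 0:9) <= 1 / ph$sample_rate))
})

test_that("peak detection matches ground truth on jittered traces without spurious peaks", {
  ph <- make_physio_traces(320, 1, 0.25, jitter = 0.05, seed = 7)
  pk <- detect_peaks(ph$cardiac, ph$time)
  expect_equal(length(pk), length(ph$cardiac_peaks))
  offs <- vapply(pk, function(p) min(abs(p - ph$cardiac_peaks)), numeric(1))
  expect_true(all(offs <= 1 / ph$sample_rate))
})

test_that("flat traces raise a signal-quality error", {
  expect_error(detect_peaks(rep(1, 100), seq(0, 9.9, 0.1)), "signal-quality")
})

test_that("every phase belongs to exactly two half-open windows", {
  ## spot values from the window construction
  expect_equal(csfmobility:::bin_memberships(0)[1, ], c(1L, 2L))
  expect_equal(csfmobility:::bin_memberships(0.5)[1, ], c(4L, 5L))
  ## exactly two memberships for every phase including the window edges
  edges <- c(0, 1 / 6, 2 / 6, 3 / 6, 4 / 6, 5 / 6, 1 - 1e-12)
  mem_e <- csfmobility:::bin_memberships(edges)
  expect_true(all(mem_e[, 1] != mem_e[, 2]))
  ## away from representable-boundary values the memberships agree with a
  ## direct window test (at the edges the two computations may round the
  ## same boundary differently, but both give two adjacent windows)
  set.seed(9)
  phis <- runif(500, 0, 1)
  mem <- csfmobility:::bin_memberships(phis)
  centers <- (0:5) / 6
  for (i in seq_along(phis)) {
    direct <- which(vapply(centers, function(ct) {
      d <- (phis[i] - ct) %% 1
      d < 1 / 6 || d >= 5 / 6
    }, logical(1)))
    expect_setequal(mem[i, ], direct)
    expect_length(unique(mem[i, ]), 2)
  }
})

test_that("uniform phases occupy each dataset at one third", {
  set.seed(3)
  sch <- list(shots = lapply(1:10000, function(k) list(start_time = (k - 1) * 3.4)))
  asg <- assign_bins(NULL, sch, "random", seed = 17)
  occ <- vapply(1:6, function(b) sum(asg$bin1 == b | asg$bin2 == b), numeric(1))
  expect_true(all(abs(occ / 10000 - 1 / 3) < 0.02))
  ## reproducible under the same seed, different under another
  asg2 <- assign_bins(NULL, sch, "random", seed = 17)
  expect_identical(asg$phi, asg2$phi)
  expect_false(identical(asg$phi, assign_bins(NULL, sch, "random", seed = 18)$phi))
})

test_that("cardiac phases interpolate between peaks; out-of-range shots are dropped", {
  sch <- list(shots = lapply(c(0.5, 1.25, 3.9), function(t) list(start_time = t)))
  asg <- assign_bins(c(0, 1, 2, 3), sch, "cardiac")
  expect_equal(asg$phi, c(0.5, 0.25))  # 3.9 s is beyond the last peak
  expect_equal(attr(asg, "n_dropped"), 1)
  expect_warning(assign_bins(c(1, 2), list(shots = list(list(start_time = 0.5),
                                                        list(start_time = 1.5))),
                             "cardiac"),
                 "dropped")
})

test_that("binned k-space conserves samples with multiplicity two", {
  tr <- iso_phantom(n = 16)
  cfg <- full_cfg(16, tse = 32)
  pat <- make_pattern(cfg)
  sch <- make_shot_schedule(pat, cfg, n_repeats = 2)
  traces <- make_physio_traces(length(sch$shots) * 3.4 + 10, jitter = 0.05, seed = 2)
  sub <- simulate_subscan(tr, traces, sch, 0, cfg)
  asg <- assign_bins(traces$cardiac_peaks, sch, "cardiac")
  bn <- bin_kspace(sub, asg)
  total_samples <- sum(lengths(lapply(sch$shots[asg$shot], `[[`, "profile_indices")))
  expect_equal(sum(vapply(bn$mult, sum, numeric(1))), 2 * total_samples)
  ## union of the six masks equals the sampled pattern
  union_mask <- Reduce(`|`, bn$mask)
  expect_equal(union_mask, pattern_mask(pat))
})

test_that("single shots and disjoint shots pass through bit-identically", {
  tr <- iso_phantom(n = 16)
  cfg <- full_cfg(16, tse = 64)
  pat <- make_pattern(cfg)
  sch <- make_shot_schedule(pat, cfg)  # 4 disjoint shots of 64 profiles
  traces <- make_physio_traces(length(sch$shots) * 3.4 + 10, seed = 1)
  sub <- simulate_subscan(tr, traces, sch, 0, cfg)
  ## force all shots into known bins via constructed phases
  asg <- data.frame(shot = seq_along(sch$shots),
                    time = vapply(sch$shots, `[[`, numeric(1), "start_time"),
                    phi = 0, bin1 = 3L, bin2 = 4L)
  asg$bin1[1] <- 3L; asg$bin2[1] <- 4L
  bn <- bin_kspace(sub, asg[1, , drop = FALSE])
  ## dataset 3 mask is exactly shot 1's profiles
  pr <- sch$profiles[sch$shots[[1]]$profile_indices, , drop = FALSE]
  expect_equal(sum(bn$mask[[3]]), nrow(pr))
  expect_true(all(bn$mask[[3]][cbind(pr[, 1] + 1, pr[, 2] + 1)]))
  ## disjoint shots: no averaging, values identical to the raw samples
  bn_all <- bin_kspace(sub, asg)
  k3 <- matrix(bn_all$kspace[[3]], 16)
  for (k in seq_along(sch$shots)) {
    prk <- sch$profiles[sch$shots[[k]]$profile_indices, , drop = FALSE]
    lin <- prk[, 1] + 1 + 16 * prk[, 2]
    expect_identical(k3[, lin], sub$shots[[k]])
  }
})

test_that("cardiac and respiratory binnings relabel the same sample set", {
  tr <- iso_phantom(n = 16)
  cfg <- full_cfg(16, tse = 32)
  pat <- make_pattern(cfg)
  sch <- make_shot_schedule(pat, cfg, n_repeats = 3)
  traces <- make_physio_traces(length(sch$shots) * 3.4 + 10, jitter = 0.05, seed = 4)
  sub <- simulate_subscan(tr, traces, sch, 0, cfg)
  bc <- bin_kspace(sub, assign_bins(traces$cardiac_peaks, sch, "cardiac"))
  br <- bin_kspace(sub, assign_bins(traces$resp_peaks, sch, "respiratory"))
  expect_equal(sum(vapply(bc$mult, sum, numeric(1))),
               sum(vapply(br$mult, sum, numeric(1))))
  ## accumulated k-space weighted by multiplicity is identical
  wsum <- function(bn) Reduce(`+`, lapply(1:6, function(b) {
    bn$kspace[[b]] * csfmobility:::expand_mask(bn$mult[[b]], 16)
  }))
  expect_equal(wsum(bc), wsum(br), tolerance = 1e-12)
})
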