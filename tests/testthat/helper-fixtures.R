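# shared fixture builders; everything is generated in code at test time

# single isotropic ellipsoid phantom (geometry scales with the grid)
iso_phantom <- function(mob = 0.02, noise_sd = 0, n = 24, seed = 1) {
  ext <- (n - 1) * 0.45
  make_phantom(phantom_spec(
    c(n, n, n), 0.45,
    list(csf_structure("ellipsoid", center = rep(0.3 * ext, 3),
                       axes = rep(0.18 * ext, 3), base_mobility = mob)),
    noise_sd = noise_sd, seed = seed))
}

# anisotropic tube along +z (geometry scales with the grid)
tube_phantom <- function(mob = 0.015, fa = 0.716, noise_sd = 0, n = 24,
                         cardiac_amp = 0, resp_amp = 0, seed = 1) {
  ext <- (n - 1) * 0.45
  make_phantom(phantom_spec(
    c(n, n, n), 0.45,
    list(csf_structure("tube", p1 = c(0.45, 0.45, 0.2) * ext,
                       p2 = c(0.45, 0.45, 0.8) * ext,
                       radius = 0.11 * ext, base_mobility = mob, fa = fa,
                       cardiac_amp = cardiac_amp, resp_amp = resp_amp)),
    noise_sd = noise_sd, seed = seed))
}

# full-sampling acquisition config matched to an n^3 phantom
full_cfg <- function(n = 24, tse = 64, noise_sd = 0, seed = 1, b = 10) {
  acquisition_config(grid = c(n, n), acs_size = 9L, accel_target = 1,
                     tse_factor = tse, noise_sd = noise_sd, b_value = b,
                     seed = seed)
}

# simulate all 7 subscans noiselessly and reconstruct statically
static_volumes <- function(truth, cfg, n_repeats = 1) {
  pat <- make_pattern(cfg)
  sch <- make_shot_schedule(pat, cfg, n_repeats = n_repeats)
  dur <- 7 * length(sch$shots) * cfg$TR * n_repeats + 20
  traces <- make_physio_traces(dur, seed = 1)
  enc <- simulate_acquisition(truth, traces, pat, cfg, n_repeats = n_repeats)
  d <- dim(truth$signal)
  vols <- array(0, c(d, 7))
  for (s in 1:7) vols[, , , s] <- reconstruct_static(enc$subscans[[s]])
  list(vols = vols, enc = enc, traces = traces, pattern = pat)
}

# synthetic encoded signal matrix for a single tensor (no imaging chain)
signals_for_tensor <- function(D, b = 10, s0 = 1000,
                               dirs = encoding_directions()$directions) {
  atten <- vapply(seq_len(6), function(i) {
    g <- dirs[i, ]
    exp(-b * drop(t(g) %*% D %*% g))
  }, numeric(1))
  c(s0, s0 * atten)
}

# (2,2,2,7) volume set in which every voxel carries one tensor's signals
vols_for <- function(D, b = 10, s0 = 1000) {
  s <- signals_for_tensor(D, b = b, s0 = s0)
  vols <- array(0, c(2, 2, 2, 7))
  for (i in 1:7) vols[, , , i] <- s[i]
  vols
}

# independent FA implementation for oracle use in tests
fa_ref <- function(l) {
  if (sum(l^2) == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((l - mean(l))^2)) / sqrt(sum(l^2))
}

# random rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
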