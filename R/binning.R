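#' Detect physiological peaks in a recorded trace
#'
#' Finds local maxima above an adaptive prominence threshold (half the
#' median candidate prominence) and enforces a minimum inter-peak distance
#' of 0.4 times the median candidate period, keeping the higher peak on
#' conflicts. Endpoints can be peaks. Mirrors automatic R-wave /
#' respiration-peak detection on recorded traces.
#'
#' @param values numeric trace samples.
#' @param times sample times in seconds (same length).
#' @return strictly increasing peak times.
#' @export
detect_peaks <- function(values, times) {
  stopifnot(length(values) == length(times), length(values) >= 3)
  rng <- max(values) - min(values)
  if (!is.finite(rng) || rng < 1e-12 * max(1, abs(max(values)))) {
    stop("signal-quality error: trace is flat, no peaks detectable",
         call. = FALSE)
  }
  v <- c(-Inf, values, -Inf)
  cand <- which(v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
                  v[2:(length(v) - 1)] >= v[3:length(v)])
  ## prominence: drop to the lowest saddle separating the peak from any
  ## higher terrain on either side
  n <- length(values)
  prom <- vapply(cand, function(i) {
    vi <- values[i]
    ## scan outward to the nearest point at least as high; the saddle is the
    ## minimum en route (incremental, no prefix copies)
    base_l <- base_r <- NULL
    if (i > 1) {
      j <- i - 1L; mn <- values[j]
      while (j > 1L && values[j] < vi) { j <- j - 1L; mn <- min(mn, values[j]) }
      base_l <- mn
    }
    if (i < n) {
      j <- i + 1L; mn <- values[j]
      while (j < n && values[j] < vi) { j <- j + 1L; mn <- min(mn, values[j]) }
      base_r <- mn
    }
    bases <- c(base_l, base_r)
    if (length(bases) == 0) bases <- min(values)
    vi - max(bases)
  }, numeric(1))
  thr <- 0.5 * stats::median(prom[prom > 0])
  keep <- cand[prom >= thr & prom > 0]
  if (length(keep) >= 3) {
    med_period <- stats::median(diff(times[keep]))
    min_dist <- 0.4 * med_period
    ## value-ordered greedy with bucketed neighbor lookup (O(n))
    ord <- keep[order(values[keep], decreasing = TRUE)]
    buckets <- new.env(hash = TRUE)
    sel <- numeric(length(ord)); nsel <- 0L
    for (i in ord) {
      ti <- times[i]
      b <- floor(ti / min_dist)
      near <- unlist(mget(as.character(c(b - 1, b, b + 1)), envir = buckets,
                          ifnotfound = list(NULL)), use.names = FALSE)
      if (is.null(near) || all(abs(ti - near) >= min_dist)) {
        nsel <- nsel + 1L; sel[nsel] <- ti
        key <- as.character(b)
        buckets[[key]] <- c(buckets[[key]], ti)
      }
    }
    pk <- sort(sel[seq_len(nsel)])
  } else {
    pk <- times[keep]
  }
  ## a candidate at the very last sample with the signal still rising and
  ## below the level of the other peaks is a truncated cycle, not a peak
  if (length(pk) > 1 && pk[length(pk)] == times[length(times)]) {
    n <- length(values)
    if (values[n - 1] < values[n] &&
        values[n] < max(values[times %in% pk[-length(pk)]]) - 1e-12) {
      pk <- pk[-length(pk)]
    }
  }
  if (length(pk) < 2) {
    stop("signal-quality error: fewer than 2 peaks detected", call. = FALSE)
  }
  pk
}

## the six half-open phase windows of width 1/3 centered at (k-1)/6; every
## phase falls in exactly two of them
bin_memberships <- function(phi) {
  j <- floor(6 * (phi %% 1)) %% 6
  cbind(j + 1L, (j + 1L) %% 6L + 1L)
}

#' Assign each TSE shot to phase datasets
#'
#' The shot phase is `(t_shot - previous peak) / (next peak - previous
#' peak)`. The six phase datasets come from two-step three-phase binning
#' with a one-sixth phase shift between the steps: windows of width 1/3
#' centered at multiples of 1/6 (half-open, wrapped modulo 1), so every
#' shot belongs to exactly two of the six datasets. `force = "random"`
#' draws uniform pseudo-phases (seeded) and applies the identical windowing
#' as the negative control.
#'
#' @param peaks strictly increasing peak times (ignored for random mode).
#' @param schedule a [make_shot_schedule()] result.
#' @param force `"cardiac"`, `"respiratory"` or `"random"`.
#' @param seed integer seed (random mode).
#' @return an object of class `phase_assignment`: data frame with `shot`,
#'   `time`, `phi`, `bin1`, `bin2` for retained shots; attribute
#'   `n_dropped` counts shots outside the peak range.
#' @export
assign_bins <- function(peaks, schedule, force = c("cardiac", "respiratory", "random"),
                        seed = 1L) {
  force <- match.arg(force)
  t_shots <- vapply(schedule$shots, `[[`, numeric(1), "start_time")
  n <- length(t_shots)
  dropped <- logical(n)
  if (force == "random") {
    set.seed(seed_substream(seed, "random_binning"))
    phi <- stats::runif(n)
  } else {
    stopifnot(length(peaks) >= 2, all(diff(peaks) > 0))
    dropped <- t_shots < peaks[1] | t_shots >= peaks[length(peaks)]
    if (any(t_shots < peaks[1])) {
      warning(sprintf("%d shot(s) before the first %s peak dropped",
                      sum(t_shots < peaks[1]), force))
    }
    phi <- rep(NA_real_, n)
    ok <- !dropped
    i <- findInterval(t_shots[ok], peaks)
    phi[ok] <- (t_shots[ok] - peaks[i]) / (peaks[i + 1] - peaks[i])
  }
  keep <- !dropped
  mem <- bin_memberships(phi[keep])
  out <- data.frame(shot = which(keep), time = t_shots[keep],
                    phi = phi[keep] %% 1, bin1 = mem[, 1], bin2 = mem[, 2])
  structure(out, class = c("phase_assignment", "data.frame"),
            force = force, n_dropped = sum(dropped))
}

#' Combine the k-space samples of each phase dataset
#'
#' Each of the six datasets accumulates the samples of its member shots;
#' where the same (ky, kz) profile was acquired by several member shots the
#' complex samples are averaged (variance-optimal for equal noise). Binary
#' sampling masks and per-profile multiplicities are recorded.
#'
#' @param subscan a [simulate_subscan()] result.
#' @param assignment a [assign_bins()] result for the same schedule.
#' @return an object of class `binned_kspace`: lists `kspace` (6 complex
#'   (nx, ky, kz) arrays), `mask`, `mult`, plus `dims` and `grid`.
#' @export
bin_kspace <- function(subscan, assignment) {
  stopifnot(inherits(subscan, "subscan_kspace"))
  sched <- subscan$schedule
  grid <- sched$grid
  nx <- subscan$dims[1]
  ksum <- lapply(1:6, function(i) matrix(0 + 0i, nx, grid[1] * grid[2]))
  cnt <- lapply(1:6, function(i) matrix(0L, grid[1], grid[2]))
  for (r in seq_len(nrow(assignment))) {
    k <- assignment$shot[r]
    pr <- sched$profiles[sched$shots[[k]]$profile_indices, , drop = FALSE]
    cols <- cbind(pr[, 1] + 1L, pr[, 2] + 1L)
    lin <- cols[, 1] + grid[1] * (cols[, 2] - 1L)
    m <- subscan$shots[[k]]
    w <- rep(1L, length(lin))
    if (anyDuplicated(lin)) {
      ## a shot may revisit a profile when the schedule wraps repeats
      g <- split(seq_along(lin), lin)
      lin <- as.integer(names(g))
      w <- lengths(g)
      m <- vapply(g, function(ix) rowSums(m[, ix, drop = FALSE]),
                  complex(nx))
      cols <- cbind((lin - 1L) %% grid[1] + 1L, (lin - 1L) %/% grid[1] + 1L)
    }
    for (b in c(assignment$bin1[r], assignment$bin2[r])) {
      ksum[[b]][, lin] <- ksum[[b]][, lin] + m
      cnt[[b]][cols] <- cnt[[b]][cols] + w
    }
  }
  kspace <- vector("list", 6)
  for (b in 1:6) {
    acc <- ksum[[b]] / rep(pmax(c(cnt[[b]]), 1L), each = nx)
    kspace[[b]] <- array(acc, c(nx, grid[1], grid[2]))
  }
  structure(list(kspace = kspace,
                 mask = lapply(cnt, function(m) m > 0),
                 mult = cnt, dims = subscan$dims, grid = grid,
                 direction_index = subscan$direction_index),
            class = "binned_kspace")
}

#' Bin a full seven-subscan acquisition by one driving force
#'
#' Detects peaks on the requested trace channel (or draws random
#' pseudo-phases), assigns each subscan's shots to phase datasets using its
#' own schedule, and bins its k-space.
#'
#' @param data an [simulate_acquisition()] result.
#' @param traces the [make_physio_traces()] used for simulation (cardiac /
#'   respiratory modes).
#' @param force `"cardiac"`, `"respiratory"` or `"random"`.
#' @param seed integer seed for random mode.
#' @param use_truth_peaks if `TRUE` use the stored ground-truth peak times,
#'   otherwise run [detect_peaks()] on the trace.
#' @return list of 7 [bin_kspace()] results (reference first).
#' @export
bin_acquisition <- function(data, traces, force = c("cardiac", "respiratory", "random"),
                            seed = 1L, use_truth_peaks = FALSE) {
  force <- match.arg(force)
  stopifnot(inherits(data, "encoded_data"))
  peaks <- NULL
  if (force != "random") {
    channel <- if (force == "cardiac") traces$cardiac else traces$respiratory
    peaks <- if (use_truth_peaks) truth_peaks(traces, force) else
      detect_peaks(channel, traces$time)
  }
  lapply(seq_along(data$subscans), function(i) {
    sub <- data$subscans[[i]]
    asg <- assign_bins(peaks, sub$schedule, force,
                       seed = seed_substream(seed, paste0("bins_sub", i)))
    bin_kspace(sub, asg)
  })
}
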