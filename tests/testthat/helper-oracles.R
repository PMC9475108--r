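# Independent brute-force oracles used to freeze expected values.  These
# deliberately avoid the package's own code paths.

# mean/sd by explicit accumulation
oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + abs(v - m)^2
  sqrt(s / (length(x) - 1))
}

oracle_range <- function(x) {
  mx <- -Inf; mn <- Inf
  for (v in x) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  mx - mn
}

# per-value clipped bin assignment
oracle_hist_counts <- function(x, bin_width, clip) {
  nbins <- round(2 * clip / bin_width)
  counts <- integer(nbins)
  for (v in x) {
    if (v < -clip) v <- -clip
    if (v > clip) v <- clip
    b <- floor((v + clip) / bin_width) + 1
    if (b > nbins) b <- nbins
    if (b < 1) b <- 1
    counts[b] <- counts[b] + 1
  }
  counts
}

# threshold-crossing scan of the linear interpolant on a dense grid
oracle_edge_count <- function(t, v, thr, min_sep) {
  dense_t <- seq(t[1], t[length(t)], length.out = 20L * length(t))
  dense_v <- approx(t, v, xout = dense_t)$y
  above <- dense_v >= thr
  cross <- which(!above[-length(above)] & above[-1])
  times <- dense_t[cross]
  if (length(times) <= 1) return(length(times))
  kept <- times[1]; last <- times[1]
  for (tc in times[-1]) {
    if (tc - last >= min_sep) { kept <- c(kept, tc); last <- tc }
  }
  length(kept)
}

# one-to-one nearest pairing over the full distance matrix
oracle_pair <- function(ref, obs, max_off) {
  if (!length(ref) || !length(obs)) {
    return(data.frame(t_ref = numeric(0), t_obs = numeric(0)))
  }
  d <- abs(outer(obs, ref, "-"))
  pairs <- data.frame(t_ref = numeric(0), t_obs = numeric(0))
  used_o <- logical(length(obs)); used_r <- logical(length(ref))
  repeat {
    d2 <- d
    d2[used_o, ] <- Inf
    d2[, used_r] <- Inf
    if (all(!is.finite(d2)) || min(d2) > max_off) break
    # smallest |offset|; ties toward earlier observed then earlier reference
    idx <- which(d2 == min(d2), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    o <- idx[1, 1]; r <- idx[1, 2]
    used_o[o] <- TRUE; used_r[r] <- TRUE
    pairs <- rbind(pairs, data.frame(t_ref = ref[r], t_obs = obs[o]))
  }
  pairs[order(pairs$t_ref), , drop = FALSE]
}

# compare two recording bundles field by field (ignoring transient attrs)
expect_bundle_equal <- function(a, b) {
  for (nm in c("audio_stream", "eeg_stream")) {
    expect_identical(is.null(a[[nm]]), is.null(b[[nm]]))
    if (!is.null(a[[nm]])) {
      expect_identical(a[[nm]]$timestamps, b[[nm]]$timestamps)
      expect_identical(a[[nm]]$values, b[[nm]]$values)
      expect_identical(a[[nm]]$clock_id, b[[nm]]$clock_id)
      expect_equal(a[[nm]]$nominal_rate, b[[nm]]$nominal_rate)
    }
  }
  expect_identical(a$marker_stream$timestamps, b$marker_stream$timestamps)
  expect_identical(a$marker_stream$labels, b$marker_stream$labels)
  expect_identical(names(a$offsets), names(b$offsets))
  for (k in names(a$offsets)) {
    expect_identical(a$offsets[[k]]$times, b$offsets[[k]]$times)
    expect_identical(a$offsets[[k]]$offsets, b$offsets[[k]]$offsets)
  }
  expect_equal(a$seed, b$seed)
  if (!is.null(a$ground_truth)) {
    expect_equal(a$ground_truth$onsets, b$ground_truth$onsets)
    expect_equal(a$ground_truth$playout_delay, b$ground_truth$playout_delay)
  }
}
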