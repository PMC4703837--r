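# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths they check.

# Audic-Claverie lower-tail p by direct term summation of the closed
# form P(k | x) = (x+k)! / (x! k! 2^(x+k+1)), via the exact recurrence
# t_k = t_{k-1} * (x + k) / (2 k), t_0 = 2^-(x+1).
ac_lower_oracle <- function(x, y) {
  t <- 2^-(x + 1)
  s <- t
  if (y >= 1) {
    for (k in seq_len(y)) {
      t <- t * (x + k) / (2 * k)
      s <- s + t
    }
  }
  s
}

ac_upper_oracle <- function(x, y) {
  if (y == 0) return(1)
  1 - ac_lower_oracle(x, y - 1)
}

# Hypergeometric tail by explicit enumeration with choose().
hyper_oracle <- function(k, K, N, n, upper = TRUE) {
  j <- 0:n
  pmf <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  if (upper) sum(pmf[j >= k]) else sum(pmf[j <= k])
}

# Sweep-line interval union on a single scaffold (0-based half-open).
union_oracle <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  rs <- starts[1]; re <- ends[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= re) {            # overlap or bookended
      re <- max(re, ends[i])
    } else {
      out_s <- c(out_s, rs); out_e <- c(out_e, re)
      rs <- starts[i]; re <- ends[i]
    }
  }
  cbind(start = c(out_s, rs), end = c(out_e, re))
}

# Chain-stitching by a literal walk: merge consecutive sorted peaks
# while the gap is <= d.
stitch_oracle <- function(starts, ends, d) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  rs <- starts[1]; re <- ends[1]; members <- 1L
  out <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - re <= d) {
      re <- max(re, ends[i]); members <- members + 1L
    } else {
      out <- rbind(out, c(rs, re, members))
      rs <- starts[i]; re <- ends[i]; members <- 1L
    }
  }
  out <- rbind(out, c(rs, re, members))
  colnames(out) <- c("start", "end", "n_members")
  out
}

# Naive per-gene window extraction for the TSS profile matrix.
profile_oracle <- function(track, tss, flank, bin) {
  nb <- 2L * (flank %/% bin)
  out <- matrix(0, nrow(tss), nb)
  for (g in seq_len(nrow(tss))) {
    for (b in seq_len(nb)) {
      ws <- tss$tss[g] - flank + (b - 1L) * bin
      we <- ws + bin
      if (ws < 0) { out[g, b] <- NA; next }
      acc <- 0
      tr <- track[track$scaffold == tss$scaffold[g], , drop = FALSE]
      for (i in seq_len(nrow(tr))) {
        ov <- min(we, tr$end[i]) - max(ws, tr$start[i])
        if (ov > 0) acc <- acc + ov * tr$value[i]
      }
      out[g, b] <- acc / bin
    }
  }
  minus <- tss$strand == "-"
  if (any(minus)) out[minus, ] <- out[minus, nb:1, drop = FALSE]
  out
}

# Per-base majority state per bin for a segmentation on one scaffold.
bin_majority_oracle <- function(seg, L, bin, states, unmodified) {
  base <- rep(unmodified, L)
  for (i in seq_len(nrow(seg))) {
    idx <- (seg$start[i] + 1):min(seg$end[i], L)
    base[idx] <- seg$state[i]
  }
  n_bins <- ceiling(L / bin)
  out <- character(n_bins)
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1) * bin + 1):min(b * bin, L)
    tallies <- table(factor(base[idx], levels = states))
    out[b] <- states[which.max(tallies)]   # which.max: first = priority order
  }
  out
}
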