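# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (from-scratch recomputation, exhaustive search,
# permutation) and share no code with the implementation they check.

# Exhaustive-search Ward agglomeration: at every step recompute, for every
# cluster pair, the increase in within-cluster sum of squares that merging
# them would cause, and merge the minimizing pair. Returns the merge heights
# (delta-SSE) and the partition at every k.
ward_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  sse <- function(idx) {
    if (length(idx) == 1L) return(0)
    xm <- x[idx, , drop = FALSE]
    sum(sweep(xm, 2, colMeans(xm))^2)
  }
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  memb <- seq_len(n)
  partitions[[n]] <- memb
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- sse(c(clusters[[i]], clusters[[j]])) -
          sse(clusters[[i]]) - sse(clusters[[j]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    memb <- integer(n)
    for (c in seq_along(clusters)) memb[clusters[[c]]] <- c
    partitions[[length(clusters)]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a set partition (relabel clusters by first appearance)
canon_partition <- function(m) {
  match(m, unique(m))
}

# Permutation oracle for Tukey HSD adjusted p values: the adjusted p of a
# pair is the probability, under label permutation, that the *maximum*
# studentized pairwise statistic exceeds the pair's observed statistic.
tukey_permutation_oracle <- function(values, groups, B = 4000) {
  groups <- factor(groups)
  lv <- levels(groups)
  pairs <- t(combn(lv, 2))
  stat <- function(v, g) {
    ni <- tapply(v, g, length)
    mi <- tapply(v, g, mean)
    s2 <- sum(tapply(v, g, function(z) sum((z - mean(z))^2))) /
      (length(v) - nlevels(g))
    q <- numeric(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      q[p] <- abs(mi[a] - mi[b]) / sqrt(s2 / 2 * (1 / ni[a] + 1 / ni[b]))
    }
    q
  }
  q_obs <- stat(values, groups)
  exceed <- numeric(length(q_obs))
  for (b in seq_len(B)) {
    q_max <- max(stat(values, sample(groups)))
    exceed <- exceed + (q_max >= q_obs)
  }
  data.frame(stage_a = pairs[, 1], stage_b = pairs[, 2],
             p_perm = exceed / B)
}

# three-stage regime plan used by several tests
tiny_plan <- function(n = 2) {
  data.frame(stage = c("P2-P3", "P7", "P21-P23"), n = n,
             stringsAsFactors = FALSE)
}

# build a bare ap_waveform object from a voltage vector
raw_waveform <- function(v, dt) {
  structure(list(voltage = v, time_step = dt, peak_index = which.max(v)),
            class = "ap_waveform")
}
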