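# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive algorithms (exhaustive scans/enumeration),
# not the package's code paths.

# all strict local maxima of a series (plateau midpoints), naive scan
oracle_local_maxima <- function(x) {
  n <- length(x)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j <= n - 1L && x[j + 1L] == x[i]) j <- j + 1L
      if (j <= n - 1L && x[j + 1L] < x[i]) idx <- c(idx, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

# topographic prominence of peak at index k, naive definition
oracle_prominence <- function(x, k) {
  h <- x[k]
  left <- x[seq_len(k - 1L)]
  higher_l <- which(left > h)
  lmin <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(k - 1L)]) else
    if (k > 1L) min(left) else h
  right <- x[(k + 1L):length(x)]
  higher_r <- which(right > h)
  rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else
    min(right)
  h - max(lmin, rmin)
}

# exhaustive maximum-amplitude-first SE selection: enumerate every subset of
# supra-threshold peaks whose pairwise spacing exceeds `spacing`, and return
# the one whose height sequence (sorted descending) is lexicographically
# largest.  Heights are assumed distinct.
oracle_classify_times <- function(times, heights, spacing = 160,
                                  frac = 1 / 3) {
  thr <- max(heights) * frac
  keep <- heights >= thr
  times <- times[keep]; heights <- heights[keep]
  n <- length(times)
  best <- NULL; best_key <- NULL
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) >= 2L) {
      d <- diff(sort(times[sel]))
      if (any(d <= spacing)) next
    }
    key <- sort(heights[sel], decreasing = TRUE)
    better <- is.null(best_key)
    if (!better) {
      m <- max(length(key), length(best_key))
      a <- c(key, rep(-Inf, m - length(key)))
      b <- c(best_key, rep(-Inf, m - length(best_key)))
      cmp <- which(a != b)
      better <- length(cmp) > 0 && a[cmp[1]] > b[cmp[1]]
    }
    if (better) { best <- sel; best_key <- key }
  }
  sort(times[best])
}

# mSE chain grouping by definition: maximal runs of the time-sorted peak
# sequence with consecutive gaps < gap; emit runs with >= 2 distinct cells
oracle_chain_groups <- function(peak_times, cell_ids, gap = 10) {
  ord <- order(peak_times)
  pt <- peak_times[ord]; cid <- cell_ids[ord]
  groups <- list(); cur <- 1L
  for (i in seq_along(pt)[-1]) {
    if (pt[i] - pt[i - 1L] < gap) cur <- c(cur, i) else {
      groups[[length(groups) + 1L]] <- cur; cur <- i
    }
  }
  groups[[length(groups) + 1L]] <- cur
  keep <- vapply(groups, function(g)
    length(g) >= 2L && length(unique(cid[g])) >= 2L, TRUE)
  lapply(groups[keep], function(g) sort(ord[g]))
}

# literal 2^n enumeration of the signed-rank two-sided exact p-value
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# literal choose(N, n2) enumeration of the rank-sum two-sided exact p-value
oracle_ranksum_p <- function(g1, g2) {
  r <- rank(c(g1, g2))
  n1 <- length(g1); n2 <- length(g2)
  r2_obs <- sum(r[n1 + seq_len(n2)])
  sums <- combn(r, n2, sum)
  min(1, 2 * min(mean(sums <= r2_obs + 1e-9), mean(sums >= r2_obs - 1e-9)))
}
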