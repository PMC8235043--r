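# Independent test oracles, deliberately implemented differently from the
# package code paths they check.

# Brute-force event error classification on explicit frame sets. Events are
# recovered as maximal runs via scanning, overlaps via set intersection,
# and every class condition is spelled out with plain loops.
oracle_score_events <- function(gt, pred) {
  frame_sets <- function(sig) {
    sets <- list()
    cur <- integer()
    for (i in seq_along(sig)) {
      if (sig[i]) {
        cur <- c(cur, i)
      } else if (length(cur)) {
        sets[[length(sets) + 1L]] <- cur
        cur <- integer()
      }
    }
    if (length(cur)) sets[[length(sets) + 1L]] <- cur
    sets
  }
  G <- frame_sets(gt)
  P <- frame_sets(pred)
  overlaps <- function(a, b) length(intersect(a, b)) > 0
  n_over_g <- vapply(G, function(g) sum(vapply(P, overlaps, logical(1), g)), integer(1))
  n_over_p <- vapply(P, function(p) sum(vapply(G, overlaps, logical(1), p)), integer(1))
  cnt <- list(D = 0, F = 0, FM = 0, M = 0, C = 0,
              I_prime = 0, F_prime = 0, FM_prime = 0, M_prime = 0)
  for (i in seq_along(G)) {
    ps <- which(vapply(P, overlaps, logical(1), G[[i]]))
    if (length(ps) == 0) { cnt$D <- cnt$D + 1; next }
    frag <- length(ps) >= 2
    merg <- any(n_over_p[ps] >= 2)
    if (frag && merg) cnt$FM <- cnt$FM + 1
    else if (frag) cnt$F <- cnt$F + 1
    else if (merg) cnt$M <- cnt$M + 1
    else cnt$C <- cnt$C + 1
  }
  for (j in seq_along(P)) {
    gs <- which(vapply(G, overlaps, logical(1), P[[j]]))
    if (length(gs) == 0) { cnt$I_prime <- cnt$I_prime + 1; next }
    merg <- length(gs) >= 2
    frag <- any(n_over_g[gs] >= 2)
    if (frag && merg) cnt$FM_prime <- cnt$FM_prime + 1
    else if (merg) cnt$M_prime <- cnt$M_prime + 1
    else if (frag) cnt$F_prime <- cnt$F_prime + 1
  }
  cnt$E_total <- length(G)
  cnt$R_total <- length(P)
  cnt
}

expect_counts_equal <- function(got, want) {
  expect_equal(as.numeric(unlist(unclass(got))[names(unlist(want))]),
               as.numeric(unlist(want)),
               ignore_attr = TRUE)
}

# barycentric point-in-triangle oracle (inclusive boundary)
oracle_in_triangle <- function(px, py, a, b, c, eps = 1e-9) {
  den <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  l1 <- ((b[2] - c[2]) * (px - c[1]) + (c[1] - b[1]) * (py - c[2])) / den
  l2 <- ((c[2] - a[2]) * (px - c[1]) + (a[1] - c[1]) * (py - c[2])) / den
  l3 <- 1 - l1 - l2
  l1 >= -eps && l2 >= -eps && l3 >= -eps
}

# all binary signals of length n with at most k maximal runs of ones
all_signals <- function(n, k) {
  out <- list()
  for (code in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    r <- rle(bits)
    if (sum(r$values) <= k) out[[length(out) + 1L]] <- bits
  }
  out
}

# random signal with up to k events on n frames
random_signal <- function(n, k) {
  sig <- rep(FALSE, n)
  for (i in seq_len(sample.int(k + 1L, 1L) - 1L)) {
    a <- sample.int(n, 1L)
    b <- min(n, a + sample.int(max(1L, n %/% k), 1L) - 1L)
    sig[a:b] <- TRUE
  }
  sig
}
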