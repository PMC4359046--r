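# Naive straight-line reference implementation of the whole cross-map
# pipeline: explicit double loops, no precomputed distance table, no C++.
# Deliberately written in the dumbest possible style so it can serve as an
# independent oracle for the fast path.

ref_embed <- function(v, E, tau) {
  v <- as.numeric(v)
  N <- length(v)
  first <- (E - 1) * tau + 1
  pts <- matrix(NA_real_, nrow = N - first + 1, ncol = E)
  times <- integer(N - first + 1)
  row <- 0
  for (t in first:N) {
    row <- row + 1
    for (j in 0:(E - 1)) pts[row, j + 1] <- v[t - j * tau]
    times[row] <- t
  }
  list(points = pts, time = times)
}

ref_dist <- function(p1, p2) sqrt(sum((p1 - p2)^2))

# per-window rho for one library size; mirrors the documented conventions:
# k = E + 1 neighbours, ties by earlier time, exponential weights with the
# uniform rule at d1 = 0, targets with invalid tau_p shift skipped, Pearson
# per window with < 3 pairs -> NA and zero variance -> 0.
ref_window_rhos <- function(x, y, E, tau, tau_p, L, theiler = 0) {
  xv <- as.numeric(x)
  emb <- ref_embed(y, E, tau)
  P <- nrow(emb$points)
  k <- E + 1
  n_win <- P - L + 1
  rhos <- rep(NA_real_, n_win)
  for (s in 1:n_win) {
    win <- s:(s + L - 1)
    obs <- c(); pred <- c()
    for (i in win) {
      ti <- emb$time[i]
      if (ti - tau_p < 1 || ti - tau_p > length(xv)) next
      cand <- c()
      for (j in win) {
        if (abs(emb$time[j] - ti) <= theiler) next
        tj <- emb$time[j]
        if (tj - tau_p < 1 || tj - tau_p > length(xv)) next
        cand <- c(cand, j)
      }
      if (length(cand) < k) next
      dd <- sapply(cand, function(j) ref_dist(emb$points[i, ], emb$points[j, ]))
      ord <- order(dd, emb$time[cand])
      sel <- cand[ord][1:k]
      dsel <- dd[ord][1:k]
      if (dsel[1] == 0) {
        w <- as.numeric(dsel == 0)
      } else {
        w <- exp(-dsel / dsel[1])
      }
      w <- w / sum(w)
      pred <- c(pred, sum(w * xv[emb$time[sel] - tau_p]))
      obs <- c(obs, xv[ti - tau_p])
    }
    if (length(obs) < 3) next
    if (stats::sd(obs) == 0 || stats::sd(pred) == 0) rhos[s] <- 0
    else rhos[s] <- stats::cor(obs, pred)
  }
  rhos
}

ref_mean_rho <- function(x, y, E, tau, tau_p, L, theiler = 0) {
  r <- ref_window_rhos(x, y, E, tau, tau_p, L, theiler)
  if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
}
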