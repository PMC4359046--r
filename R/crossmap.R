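#' Library window over a shadow manifold
#'
#' A library is a contiguous window of manifold points used as the basis of
#' cross-map prediction; its size L is the quantity whose increase drives
#' convergence. A library must hold at least E + 2 points: E + 1 simplex
#' neighbours plus the held-out target.
#'
#' @param start 1-based offset of the first manifold point in the window.
#' @param size number of consecutive points, L.
#' @param m the manifold the window indexes into (for bounds checking).
#' @return list of class `ccm_library` with `start` and `size`.
#' @export
ccm_library <- function(start, size, m) {
  start <- as.integer(start); size <- as.integer(size)
  P <- nrow(m$points)
  if (start < 1L || start + size - 1L > P)
    stop(sprintf("library [%d, %d] outside manifold of %d points",
                 start, start + size - 1L, P))
  if (size < m$E + 2L)
    stop(sprintf("library size %d too small: need at least E + 2 = %d points",
                 size, m$E + 2L))
  structure(list(start = start, size = size), class = "ccm_library")
}

#' Rank library neighbours of a manifold point
#'
#' Returns the k nearest library points to the target point, excluding the
#' target itself (and any point within the Theiler window around it), ranked
#' by manifold distance with ties broken toward the earlier time index.
#'
#' @param d distance matrix from [manifold_distances()].
#' @param m the manifold (supplies time tags).
#' @param target manifold row index of the target point.
#' @param lib a [ccm_library()].
#' @param k number of neighbours.
#' @param theiler temporal exclusion radius (index units) around the target;
#'   0 excludes only the target itself.
#' @return data.frame with columns `index`, `time`, `distance`, k rows,
#'   sorted ascending by distance.
#' @export
neighbor_rank <- function(d, m, target, lib, k, theiler = 0) {
  idx <- seq.int(lib$start, lib$start + lib$size - 1L)
  idx <- idx[abs(m$time[idx] - m$time[target]) > theiler]
  if (length(idx) < k)
    stop(sprintf(
      "cannot rank %d neighbours: library leaves only %d candidates (need L >= %d)",
      k, length(idx), k + 1L + 2L * theiler))
  dd <- d[target, idx]
  ord <- order(dd, m$time[idx])[seq_len(k)]
  data.frame(index = idx[ord], time = m$time[idx[ord]], distance = dd[ord])
}

#' Exponential simplex-projection weights
#'
#' Converts ranked neighbour distances into the exponential weights of
#' simplex projection: `u_i = exp(-d_i / d_1)` with `d_1` the nearest
#' distance, normalised to sum to one. When the nearest distance is exactly
#' zero the kernel is undefined, so weights are uniform over all
#' zero-distance neighbours and zero elsewhere.
#'
#' @param distances nonnegative distances sorted ascending, length >= 1.
#' @return weight vector of the same length, nonnegative, summing to 1.
#' @examples
#' exp_weights(c(1, 2))       # ~ (0.731, 0.269)
#' exp_weights(c(0, 0, 5))    # (0.5, 0.5, 0)
#' @export
exp_weights <- function(distances) {
  if (length(distances) < 1) stop("need at least one distance")
  if (any(distances < 0) || is.unsorted(distances))
    stop("distances must be nonnegative and sorted ascending")
  if (distances[1] == 0) {
    w <- as.numeric(distances == 0)
    return(w / sum(w))
  }
  u <- exp(-distances / distances[1])
  u / sum(u)
}

#' Cross-map prediction of a single held-out point
#'
#' Uses the shadow manifold of the putative effect (M_y) to predict one
#' held-out observation of the putative cause X. The E + 1 nearest library
#' neighbours of M_y's point at time t (the target itself excluded) supply
#' exponential weights, and the prediction is the weighted average
#' `sum(w_i * X(t_i - tau_p))`, compared against the observed `X(t - tau_p)`.
#' A positive tau_p means the cause is assumed to precede the effect by
#' tau_p sampling steps.
#'
#' @param my shadow manifold of the effect series Y.
#' @param x the cause series X (numeric or [ccm_series()]).
#' @param lib a [ccm_library()] on `my`.
#' @param t time tag (1-based series index) of the manifold point to hold
#'   out; must lie inside the library's span.
#' @param tau_p assumed causal lag, integer >= 0.
#' @param theiler Theiler exclusion radius, default 0.
#' @return list of class `ccm_prediction`: `t`, `observed`, `predicted`,
#'   `neighbors` (data.frame of time, distance, weight).
#' @export
crossmap_point <- function(my, x, lib, t, tau_p = 0, theiler = 0) {
  xv <- as.numeric(x)
  target <- match(t, my$time)
  span <- seq.int(lib$start, lib$start + lib$size - 1L)
  if (is.na(target) || !(target %in% span))
    stop("t = ", t, " is not a manifold time inside the library span")
  if (t - tau_p < 1 || t - tau_p > length(xv))
    stop("tau_p = ", tau_p, " pushes the target index out of range")
  k <- my$E + 1L
  d <- manifold_distances(my)
  # candidates must themselves have a valid tau_p-shifted observation
  ok_time <- my$time[span] - tau_p >= 1 & my$time[span] - tau_p <= length(xv)
  nb <- neighbor_rank_valid(d, my, target, span[ok_time], k, theiler)
  w <- exp_weights(nb$distance)
  pred <- sum(w * xv[nb$time - tau_p])
  structure(list(t = t, observed = xv[t - tau_p], predicted = pred,
                 neighbors = cbind(nb, weight = w)),
            class = "ccm_prediction")
}

# neighbour ranking over an explicit candidate index set
neighbor_rank_valid <- function(d, m, target, idx, k, theiler) {
  idx <- idx[abs(m$time[idx] - m$time[target]) > theiler]
  if (length(idx) < k)
    stop(sprintf("cannot rank %d neighbours from %d candidates (need L >= %d)",
                 k, length(idx), k + 1L))
  dd <- d[target, idx]
  ord <- order(dd, m$time[idx])[seq_len(k)]
  data.frame(index = idx[ord], time = m$time[idx[ord]], distance = dd[ord])
}

#' Cross-map predictive skill (rho_ccm)
#'
#' Pearson correlation between held-out observations and their cross-mapped
#' predictions. With fewer than 3 pairs the skill is undefined (NA, flagged);
#' if either side has zero variance the skill is defined as 0 with a
#' `zero_variance` flag rather than NaN, so parameter optimization never has
#' to propagate missing objective values.
#'
#' @param observed,predicted paired numeric vectors.
#' @return a number with attribute `flag` in `"ok"`, `"zero_variance"`,
#'   `"undefined"`.
#' @export
ccm_skill <- function(observed, predicted) {
  keep <- is.finite(observed) & is.finite(predicted)
  o <- observed[keep]; p <- predicted[keep]
  if (length(o) < 3)
    return(structure(NA_real_, flag = "undefined"))
  if (stats::sd(o) == 0 || stats::sd(p) == 0) {
    warning("zero variance in observed or predicted values; rho_ccm set to 0")
    return(structure(0, flag = "zero_variance"))
  }
  structure(stats::cor(o, p), flag = "ok")
}

#' Sliding-window cross-map sweep over library sizes
#'
#' The workhorse of the causality test `x -> y`. The effect series y is
#' embedded into its shadow manifold M_y; for each library size L in
#' `lib_sizes`, every contiguous window of L manifold points (stride 1) is
#' taken as a library, each point in the window is held out in turn and
#' predicted from its E + 1 nearest within-window neighbours, and one
#' rho_ccm is computed per window. The per-L skill is the mean over windows.
#' A systematic increase of this skill with L — convergence — is the
#' operational criterion that x causally influences y.
#'
#' Targets whose tau_p-shifted index falls outside the series are skipped
#' and counted (never silently dropped); windows with fewer than 3 usable
#' pairs get an undefined (NA) rho.
#'
#' @param x putative cause series (the one predicted).
#' @param y putative effect series (the one embedded).
#' @param E embedding dimension (>= 2).
#' @param tau coordinate lag, default 1.
#' @param tau_p assumed causal lag (>= 0), default 0.
#' @param lib_sizes increasing vector of library sizes; values are clipped
#'   to the feasible range `[max(E + 2, 3 + 2 * theiler), P]` and
#'   deduplicated. `NULL` uses the default ladder from [default_grid()].
#' @param theiler Theiler exclusion radius, default 0.
#' @return object of class `ccm_result`: `direction` (e.g. "y xmap x"),
#'   `tests` ("x -> y"), `E`, `tau`, `tau_p`, `summary` (data.frame L,
#'   n_windows, rho, n_skipped), `windows` (data.frame L, window_start,
#'   rho), flags.
#' @export
cross_map_skill <- function(x, y, E, tau = 1, tau_p = 0, lib_sizes = NULL,
                            theiler = 0) {
  tau_p <- as.integer(tau_p)
  if (is.na(tau_p) || tau_p < 0) stop("tau_p must be an integer >= 0")
  my <- embed_series(y, E = E, tau = tau)
  d <- manifold_distances(my)
  sweep_from_dist(d, my, as.numeric(x), tau_p, lib_sizes, theiler,
                  x_name = series_name(x), y_name = series_name(y))
}

# internal: run the sweep given precomputed distances (shared with optimize)
sweep_from_dist <- function(d, my, xv, tau_p, lib_sizes, theiler,
                            x_name, y_name) {
  P <- nrow(my$points)
  k <- my$E + 1L
  if (k > 63L) stop("E too large: at most 62 supported")
  L_min <- max(my$E + 2L, 3L + 2L * theiler)
  if (is.null(lib_sizes)) lib_sizes <- default_lib_sizes(my$n_series, my$E, my$tau)
  lib_sizes <- sort(unique(as.integer(lib_sizes)))
  lib_sizes <- lib_sizes[lib_sizes >= L_min & lib_sizes <= P]
  if (!length(lib_sizes))
    stop(sprintf("no feasible library sizes in [%d, %d]", L_min, P))

  win_list <- vector("list", length(lib_sizes))
  summ <- data.frame(L = lib_sizes, n_windows = NA_integer_,
                     rho = NA_real_, n_skipped = NA_integer_,
                     n_zero_variance = NA_integer_)
  for (i in seq_along(lib_sizes)) {
    L <- lib_sizes[i]
    res <- cpp_window_sweep(d, my$time, xv, k, tau_p, L, as.integer(theiler))
    win_list[[i]] <- data.frame(L = L, window_start = seq_len(P - L + 1L),
                                rho = res$rho)
    summ$n_windows[i] <- P - L + 1L
    summ$rho[i] <- if (all(is.na(res$rho))) NA_real_ else
      mean(res$rho, na.rm = TRUE)
    summ$n_skipped[i] <- sum(res$skipped)
    summ$n_zero_variance[i] <- sum(res$zero_variance)
  }
  structure(list(
    direction = sprintf("%s xmap %s", y_name, x_name),
    tests = sprintf("%s -> %s", x_name, y_name),
    E = my$E, tau = my$tau, tau_p = tau_p, theiler = theiler,
    summary = summ,
    windows = do.call(rbind, win_list)
  ), class = "ccm_result")
}

#' @export
print.ccm_result <- function(x, ...) {
  cat(sprintf("<ccm_result> %s (tests %s)  E = %d, tau = %d, tau_p = %d\n",
              x$direction, x$tests, x$E, x$tau, x$tau_p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Assess convergence of cross-map skill with library size
#'
#' Convergence — a systematic increase of rho_ccm with L — is the practical
#' criterion for causality: non-causal curves are flat, causal ones rise.
#' The statistic reported is `delta_rho = rho(L_max) - rho(L_min)` together
#' with the relative difference `delta_rho / max(abs(rho(L_max)), eps)`.
#' The boolean verdict requires both a rise of at least `delta_min` and a
#' terminal skill of at least `rho_min`; both thresholds are configurable
#' defaults, since the underlying criterion is qualitative.
#'
#' @param result a [cross_map_skill()] result with >= 2 library sizes.
#' @param delta_min minimum rise in rho, default 0.1.
#' @param rho_min minimum terminal rho, default 0.2.
#' @param eps floor for the relative-difference denominator, default 1e-6.
#' @return list of class `ccm_convergence`: `delta_rho`, `relative_diff`,
#'   `converged`, `rho_Lmin`, `rho_Lmax`, `L_min`, `L_max`, `direction`.
#' @export
assess_convergence <- function(result, delta_min = 0.1, rho_min = 0.2,
                               eps = 1e-6) {
  stopifnot(inherits(result, "ccm_result"))
  s <- result$summary[!is.na(result$summary$rho), , drop = FALSE]
  if (nrow(s) < 2)
    stop("need rho at >= 2 library sizes to assess convergence")
  r0 <- s$rho[1]; r1 <- s$rho[nrow(s)]
  delta <- r1 - r0
  structure(list(
    delta_rho = delta,
    relative_diff = delta / max(abs(r1), eps),
    converged = (delta >= delta_min) && (r1 >= rho_min),
    rho_Lmin = r0, rho_Lmax = r1,
    L_min = s$L[1], L_max = s$L[nrow(s)],
    direction = result$direction, tests = result$tests
  ), class = "ccm_convergence")
}

#' @export
print.ccm_convergence <- function(x, ...) {
  cat(sprintf(
    "<ccm_convergence> %s (tests %s)\n  rho: %.3f (L=%d) -> %.3f (L=%d), delta = %.3f, rel = %.3f\n  converged: %s\n",
    x$direction, x$tests, x$rho_Lmin, x$L_min, x$rho_Lmax, x$L_max,
    x$delta_rho, x$relative_diff, x$converged))
  invisible(x)
}
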