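#' Time-delay embedding: reconstruct a shadow manifold
#'
#' Builds the lagged-coordinate point cloud of a single time series. The
#' point tagged with time index t (1-based) is the E-vector
#' `(X(t), X(t - tau), ..., X(t - (E-1) tau))`, so the first valid point sits
#' at `t = (E-1) * tau + 1` and the manifold has `N - (E-1) * tau` points in
#' increasing time order. For the series 1,2,3,4 with E = 2, tau = 1 the
#' manifold traces the path (2,1) -> (3,2) -> (4,3). Under Takens' theorem
#' this shadow is, generically, a diffeomorphic image of the full system
#' attractor, which is what licenses cross-mapping between variables of the
#' same system.
#'
#' @param x a [ccm_series()] or numeric vector, length N.
#' @param E embedding dimension, integer >= 2.
#' @param tau lag between embedding coordinates in index units (>= 1). This
#'   is a separate knob from the causal lag `tau_p` and is not optimized.
#' @return an object of class `shadow_manifold`: list with `points`
#'   (P x E matrix, rows in time order), `time` (1-based series index of each
#'   row's leading coordinate), `E`, `tau`, `n_series`, `name`.
#' @examples
#' m <- embed_series(c(1, 2, 3, 4), E = 2)
#' m$points   # rows (2,1), (3,2), (4,3)
#' @export
embed_series <- function(x, E, tau = 1) {
  E <- as.integer(E); tau <- as.integer(tau)
  if (is.na(E) || E < 2) stop("E must be an integer >= 2")
  if (is.na(tau) || tau < 1) stop("tau must be an integer >= 1")
  v <- as.numeric(x)
  N <- length(v)
  min_n <- (E - 1L) * tau + 1L
  if (N < min_n)
    stop(sprintf(
      "insufficient length: series has %d points but embedding with E = %d, tau = %d needs at least %d",
      N, E, tau, min_n))
  times <- seq.int(min_n, N)
  pts <- vapply(0:(E - 1L), function(j) v[times - j * tau],
                numeric(length(times)))
  if (length(times) == 1L) pts <- matrix(pts, nrow = 1L)
  structure(list(points = pts, time = times, E = E, tau = tau,
                 n_series = N, name = series_name(x)),
            class = "shadow_manifold")
}

#' @export
print.shadow_manifold <- function(x, ...) {
  cat(sprintf(
    "<shadow_manifold of '%s'> %d points in %d dimensions (E = %d, tau = %d)\n",
    x$name, nrow(x$points), ncol(x$points), x$E, x$tau))
  invisible(x)
}

#' Pairwise Euclidean distances between manifold points
#'
#' Computed once per (E, tau) and reused across every library window and
#' every causal lag tau_p, since neither changes the manifold geometry.
#'
#' @param m a [embed_series()] shadow manifold with at least 2 points.
#' @return a symmetric P x P matrix with zero diagonal and attribute
#'   `metric = "euclidean"`.
#' @export
manifold_distances <- function(m) {
  stopifnot(inherits(m, "shadow_manifold"))
  if (nrow(m$points) < 2) stop("need at least 2 manifold points")
  d <- as.matrix(stats::dist(m$points, method = "euclidean"))
  dimnames(d) <- NULL
  attr(d, "metric") <- "euclidean"
  d
}
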