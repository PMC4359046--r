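# Tuning-parameter selection for CCM: the embedding dimension E and the
# causal lag tau_p are chosen by cyclic coordinate descent on cross-validated
# predictive skill; the exhaustive (E, tau_p) surface is the audit path and
# the input to the sensitivity heatmap.

#' Default parameter grid for a series of length N
#'
#' Intelligent defaults: E ranges from 2 to `min(10, floor(sqrt(N)))`, tau_p
#' from 0 to `min(10, floor(N / 5))`, and for each E about 8 library sizes
#' are spaced evenly from `L_min = max(E + 2, 10)` up to the full manifold
#' size. The method is designed for series of 25 or more observations;
#' between 10 and 24 points a grid is still produced with a warning, and
#' below 10 points the request is refused.
#'
#' @param N series length.
#' @param tau coordinate lag the grid will be used with, default 1.
#' @param n_lib number of library sizes in the ladder, default 8.
#' @return list of class `ccm_grid`: `E` (integer vector), `tau_p` (integer
#'   vector), `N`, `tau`, `n_lib`.
#' @export
default_grid <- function(N, tau = 1, n_lib = 8) {
  N <- as.integer(N)
  if (N < 10)
    stop("series of length ", N, " is too short: the method is intended for ",
         ">= 25 observations (hard floor 10)")
  if (N < 25)
    warning("series of length ", N, " is below the recommended minimum of 25 ",
            "observations; results will be unreliable")
  E_max <- min(10L, floor(sqrt(N)))
  if (E_max < 2L) E_max <- 2L
  structure(list(E = 2:E_max,
                 tau_p = 0:min(10L, N %/% 5L),
                 N = N, tau = as.integer(tau), n_lib = as.integer(n_lib)),
            class = "ccm_grid")
}

#' @export
print.ccm_grid <- function(x, ...) {
  cat(sprintf("<ccm_grid> N = %d: E in {%s}, tau_p in {%s}, %d library sizes\n",
              x$N, paste(range(x$E), collapse = ".."),
              paste(range(x$tau_p), collapse = ".."), x$n_lib))
  invisible(x)
}

#' Default ladder of library sizes
#'
#' About `n` sizes spaced evenly from `max(E + 2, 10)` to the manifold point
#' count `N - (E - 1) * tau`.
#' @param N series length.
#' @param E embedding dimension.
#' @param tau coordinate lag.
#' @param n number of sizes.
#' @return increasing integer vector (possibly shorter than `n` after
#'   deduplication).
#' @export
default_lib_sizes <- function(N, E, tau = 1, n = 8) {
  P <- N - (E - 1L) * tau
  L_min <- max(E + 2L, 10L)
  if (P < L_min) stop(sprintf(
    "manifold of %d points cannot host a library of %d (series too short for E = %d)",
    P, L_min, E))
  sort(unique(as.integer(round(seq(L_min, P, length.out = n)))))
}

# internal: memoised objective over the grid. The objective for a cell
# (E, tau_p) is the max over the library-size ladder of the mean windowed
# rho_ccm -- the plateau value of the convergence curve. Distances are
# computed once per E and shared across all tau_p.
make_objective <- function(x, y, grid, theiler = 0) {
  xv <- as.numeric(x)
  x_name <- series_name(x); y_name <- series_name(y)
  dist_cache <- new.env(parent = emptyenv())
  val_cache <- new.env(parent = emptyenv())

  get_dist <- function(E) {
    key <- as.character(E)
    if (is.null(dist_cache[[key]])) {
      my <- embed_series(y, E = E, tau = grid$tau)
      dist_cache[[key]] <- list(my = my, d = manifold_distances(my))
    }
    dist_cache[[key]]
  }

  function(E, tau_p) {
    key <- paste(E, tau_p)
    if (!is.null(val_cache[[key]])) return(val_cache[[key]])
    val <- tryCatch({
      dd <- get_dist(E)
      Ls <- default_lib_sizes(grid$N, E, grid$tau, grid$n_lib)
      res <- sweep_from_dist(dd$d, dd$my, xv, tau_p, Ls, theiler,
                             x_name, y_name)
      if (all(is.na(res$summary$rho))) NA_real_
      else max(res$summary$rho, na.rm = TRUE)
    }, error = function(e) NA_real_)
    val_cache[[key]] <- val
    val
  }
}

#' Optimize E and tau_p by cyclic coordinate descent
#'
#' Runs cyclic coordinate descent from a small deterministic set of starting
#' cells (the four corners of the grid plus its centre, the first being the
#' simplest cell: smallest E, smallest tau_p). Each run alternately
#' line-searches the E axis with tau_p fixed, then the tau_p axis with E
#' fixed, each by a full scan, and stops when a complete cycle changes
#' nothing or after `max_cycles` cycles; the best run wins. Multiple starts
#' cost little (cell evaluations are memoised) and guard against the
#' axis-aligned local optima that a rough skill landscape can produce. The
#' objective for a cell is the maximum over the library-size ladder of the
#' mean windowed rho_ccm for the test `x -> y` (cross-validated, per
#' [cross_map_skill()]). Ties are broken toward smaller E, then smaller
#' tau_p, preferring simpler embeddings. Infeasible cells (series too short
#' for the embedding, or no defined skill) are treated as missing and never
#' selected over a defined value.
#'
#' @param x putative cause series.
#' @param y putative effect series (embedded).
#' @param grid a [default_grid()], or `NULL` to build one from the data.
#' @param theiler Theiler exclusion radius, default 0.
#' @param max_cycles cycle cap, default 10.
#' @return list of class `ccm_descent`: `E_star`, `tau_p_star`, `value`,
#'   `trajectory` (data.frame cycle, E, tau_p, value), `n_evaluated`.
#' @export
coordinate_descent <- function(x, y, grid = NULL, theiler = 0,
                               max_cycles = 10) {
  if (is.null(grid)) grid <- default_grid(length(y))
  obj <- make_objective(x, y, grid, theiler)
  descend_grid(obj, grid$E, grid$tau_p, max_cycles)
}

# pure multi-start cyclic coordinate descent over a memoisable objective;
# separated from the CCM objective so the search logic is testable on
# analytic functions. Starts: the four grid corners plus the centre cell.
descend_grid <- function(obj, E_vals, tp_vals, max_cycles = 10) {
  Emin <- min(E_vals); Emax <- max(E_vals)
  tmin <- min(tp_vals); tmax <- max(tp_vals)
  mid <- function(v) v[(length(v) + 1L) %/% 2L]
  starts <- unique(list(c(Emin, tmin), c(Emin, tmax), c(Emax, tmin),
                        c(Emax, tmax), c(mid(E_vals), mid(tp_vals))))
  best <- NULL
  for (st in starts) {
    run <- descend_once(obj, E_vals, tp_vals, st[1], st[2], max_cycles)
    if (is.null(best)) { best <- run; next }
    if (is.na(best$value) && !is.na(run$value)) { best <- run; next }
    if (!is.na(run$value) && !is.na(best$value) &&
        (run$value > best$value ||
         (run$value == best$value &&
          (run$E_star < best$E_star ||
           (run$E_star == best$E_star &&
            run$tau_p_star < best$tau_p_star)))))
      best <- run
  }
  if (is.na(best$value))
    stop("no feasible (E, tau_p) cell: every evaluation was undefined")
  best$n_evaluated <- NULL  # memoised across starts; count not meaningful
  best
}

# one descent run from a given start
descend_once <- function(obj, E_vals, tp_vals, E_start, tp_start,
                         max_cycles = 10) {
  E_cur <- E_start; tp_cur <- tp_start
  v_cur <- obj(E_cur, tp_cur)
  traj <- data.frame(cycle = 0L, E = E_cur, tau_p = tp_cur, value = v_cur)
  n_eval <- 1L

  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    # full scan of one axis with the other fixed; strict improvement keeps
    # the incumbent on ties, so earlier (smaller) values win
    for (axis in c("E", "tau_p")) {
      vals <- if (axis == "E") E_vals else tp_vals
      for (v in vals) {
        Ei <- if (axis == "E") v else E_cur
        tpi <- if (axis == "tau_p") v else tp_cur
        fi <- obj(Ei, tpi)
        n_eval <- n_eval + 1L
        better <- !is.na(fi) && (is.na(v_cur) || fi > v_cur)
        if (better) {
          E_cur <- Ei; tp_cur <- tpi; v_cur <- fi; changed <- TRUE
        }
      }
      traj <- rbind(traj, data.frame(cycle = cycle, E = E_cur,
                                     tau_p = tp_cur, value = v_cur))
    }
    if (!changed) break
  }
  structure(list(E_star = E_cur, tau_p_star = tp_cur, value = v_cur,
                 trajectory = traj, n_evaluated = n_eval),
            class = "ccm_descent")
}

#' @export
print.ccm_descent <- function(x, ...) {
  cat(sprintf("<ccm_descent> optimum E* = %d, tau_p* = %d, max rho_ccm = %.4f\n",
              x$E_star, x$tau_p_star, x$value))
  invisible(x)
}

#' Exhaustive (E, tau_p) sensitivity surface
#'
#' Evaluates the max-over-L rho_ccm for every grid cell — the audit path for
#' the coordinate-descent optimum and the data behind the sensitivity
#' heatmap. Infeasible cells are reported as NA (missing), never as 0.
#' The surface optimum is the argmax with ties broken toward smaller E,
#' then smaller tau_p, the same rule the descent uses.
#'
#' @inheritParams coordinate_descent
#' @return list of class `ccm_surface`: `surface` (data.frame E, tau_p,
#'   max_rho), `E_star`, `tau_p_star`, `value`, `direction`, `tests`.
#' @export
full_surface <- function(x, y, grid = NULL, theiler = 0) {
  if (is.null(grid)) grid <- default_grid(length(y))
  obj <- make_objective(x, y, grid, theiler)
  cells <- expand.grid(E = grid$E, tau_p = grid$tau_p,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$tau_p, cells$E), , drop = FALSE]
  cells$max_rho <- mapply(obj, cells$E, cells$tau_p)
  rownames(cells) <- NULL
  if (all(is.na(cells$max_rho)))
    stop("no feasible (E, tau_p) cell: every evaluation was undefined")
  ok <- which(!is.na(cells$max_rho))
  # argmax with deterministic ties toward smaller E then smaller tau_p
  best <- ok[order(-cells$max_rho[ok], cells$E[ok], cells$tau_p[ok])][1]
  structure(list(surface = cells,
                 E_star = cells$E[best], tau_p_star = cells$tau_p[best],
                 value = cells$max_rho[best],
                 direction = sprintf("%s xmap %s", series_name(y),
                                     series_name(x)),
                 tests = sprintf("%s -> %s", series_name(x),
                                 series_name(y))),
            class = "ccm_surface")
}

#' @export
print.ccm_surface <- function(x, ...) {
  cat(sprintf(
    "<ccm_surface> %s (tests %s): %d cells, optimum E* = %d, tau_p* = %d, max rho = %.4f\n",
    x$direction, x$tests, nrow(x$surface), x$E_star, x$tau_p_star, x$value))
  invisible(x)
}

#' Whitney bounds on the dimensionality of the causal system
#'
#' If `E_star` is the optimal embedding dimension, Whitney's embedding
#' theorem brackets the dimensionality of the full causal system generically
#' between `(E_star - 1) / 2` (rounded up) and `E_star`, inclusive.
#'
#' @param E_star optimal embedding dimension, integer >= 2.
#' @return named integer vector `c(lower, upper)`.
#' @examples
#' whitney_bounds(3)  # c(lower = 1, upper = 3)
#' @export
whitney_bounds <- function(E_star) {
  E_star <- as.integer(E_star)
  if (is.na(E_star) || E_star < 2) stop("E_star must be an integer >= 2")
  c(lower = as.integer(ceiling((E_star - 1) / 2)), upper = E_star)
}
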