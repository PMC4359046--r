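# End-to-end driver and visualization. Direction labels always state both
# the mapping and the causal hypothesis it tests ("y xmap x (tests x -> y)")
# because the inversion -- the effect's manifold cross-maps the cause -- is
# the single most common source of confusion when reading CCM output.

#' Run the full CCM pipeline on a pair of series
#'
#' For each requested direction: build the default parameter grid, optimize
#' (E, tau_p) by coordinate descent (optionally evaluating the exhaustive
#' sensitivity surface as an audit), compute the convergence curve at the
#' optimum, and assess convergence. With `out_prefix` set, writes tidy TSVs
#' (per-window skill, per-L summary, surface), convergence-curve and
#' surface plots (PDF + PNG), a human-readable summary with per-direction
#' verdicts and Whitney bounds, and a log echoing the fully resolved
#' configuration.
#'
#' @param x,y the two series ([ccm_series()] or numeric); alternatively
#'   give `input`.
#' @param input path to a delimited file read with [read_series()].
#' @param columns length-2 selector (names or positions) of the x and y
#'   columns of `input`.
#' @param E,tau_p fixed tuning parameters; `NULL` (default) optimizes them.
#' @param tau coordinate lag, default 1.
#' @param lib_sizes library-size ladder for the final convergence curve;
#'   `NULL` uses [default_lib_sizes()].
#' @param theiler Theiler exclusion radius, default 0.
#' @param direction `"both"`, `"xy"` (test x -> y only) or `"yx"`.
#' @param surface evaluate the exhaustive (E, tau_p) surface, default TRUE.
#' @param delta_min,rho_min convergence thresholds, see
#'   [assess_convergence()].
#' @param out_prefix path prefix for output files, or `NULL` for no files.
#' @param make_plots write figures (requires `out_prefix`).
#' @param grid optional [default_grid()] override.
#' @return list of class `ccm_run`: per direction a list with `result`
#'   (the [cross_map_skill()] curve), `convergence`, `descent`, `surface`,
#'   `whitney`; plus `config` (fully resolved) and `files` (paths written).
#' @export
run_ccm <- function(x = NULL, y = NULL, input = NULL, columns = NULL,
                    E = NULL, tau = 1, tau_p = NULL, lib_sizes = NULL,
                    theiler = 0, direction = c("both", "xy", "yx"),
                    surface = TRUE, delta_min = 0.1, rho_min = 0.2,
                    out_prefix = NULL, make_plots = !is.null(out_prefix),
                    grid = NULL) {
  direction <- match.arg(direction)
  if (!is.null(input)) {
    cols <- read_series(input, columns = columns)
    if (length(cols) < 2)
      stop("input must provide at least 2 usable columns, got ",
           length(cols))
    x <- cols[[1]]; y <- cols[[2]]
  }
  if (is.null(x) || is.null(y)) stop("supply x and y, or an input file")
  if (!inherits(x, "ccm_series")) x <- ccm_series(x, "x")
  if (!inherits(y, "ccm_series")) y <- ccm_series(y, "y")
  if (length(x) != length(y))
    stop("the two series must have equal length (got ", length(x), " and ",
         length(y), ")")
  if (length(x) < 10)
    stop("series too short (", length(x), " points): need at least 10, ",
         "and >= 25 is recommended")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant column: a series with zero variance cannot be ",
         "embedded or predicted")

  if (is.null(grid)) grid <- default_grid(length(x), tau = tau)
  dirs <- switch(direction, both = c("xy", "yx"), xy = "xy", yx = "yx")

  run_one <- function(cause, effect) {
    out <- list()
    if (is.null(E) || is.null(tau_p)) {
      out$descent <- coordinate_descent(cause, effect, grid, theiler)
      E_use <- if (is.null(E)) out$descent$E_star else E
      tp_use <- if (is.null(tau_p)) out$descent$tau_p_star else tau_p
    } else {
      E_use <- E; tp_use <- tau_p
    }
    if (surface) out$surface <- full_surface(cause, effect, grid, theiler)
    out$result <- cross_map_skill(cause, effect, E = E_use, tau = tau,
                                  tau_p = tp_use, lib_sizes = lib_sizes,
                                  theiler = theiler)
    out$convergence <- assess_convergence(out$result, delta_min, rho_min)
    out$whitney <- whitney_bounds(E_use)
    out$E <- E_use; out$tau_p <- tp_use
    out
  }

  res <- list()
  if ("xy" %in% dirs) res$xy <- run_one(x, y)
  if ("yx" %in% dirs) res$yx <- run_one(y, x)

  config <- list(x = series_name(x), y = series_name(y), n = length(x),
                 E = E, tau = tau, tau_p = tau_p,
                 lib_sizes = lib_sizes, theiler = theiler,
                 direction = direction, surface = surface,
                 delta_min = delta_min, rho_min = rho_min,
                 grid_E = grid$E, grid_tau_p = grid$tau_p,
                 n_lib = grid$n_lib, out_prefix = out_prefix)
  res$config <- config
  class(res) <- "ccm_run"

  if (!is.null(out_prefix))
    res$files <- write_ccm_outputs(res, out_prefix, make_plots)
  res
}

#' @export
print.ccm_run <- function(x, ...) {
  cat("<ccm_run>\n")
  for (d in intersect(c("xy", "yx"), names(x))) {
    cv <- x[[d]]$convergence
    wb <- x[[d]]$whitney
    cat(sprintf(
      "  %s (tests %s): E* = %d, tau_p* = %d, rho(Lmax) = %.3f, delta = %.3f -> %s\n",
      cv$direction, cv$tests, x[[d]]$E, x[[d]]$tau_p, cv$rho_Lmax,
      cv$delta_rho,
      if (cv$converged) "CONVERGED (causal signal)" else "no convergence"))
    cat(sprintf("    Whitney bounds on system dimensionality: [%d, %d]\n",
                wb["lower"], wb["upper"]))
  }
  invisible(x)
}

# internal: write every table, figure, summary and log for a finished run
write_ccm_outputs <- function(run, prefix, make_plots) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  files <- character()
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    path
  }
  dirs <- intersect(c("xy", "yx"), names(run))

  win <- do.call(rbind, lapply(dirs, function(d) {
    r <- run[[d]]$result
    cbind(direction = r$direction, E = r$E, tau = r$tau, tau_p = r$tau_p,
          r$windows)
  }))
  files["windows"] <- tsv(win, paste0(prefix, "_windows.tsv"))

  curve <- do.call(rbind, lapply(dirs, function(d) {
    r <- run[[d]]$result
    cbind(direction = r$direction, E = r$E, tau = r$tau, tau_p = r$tau_p,
          r$summary)
  }))
  files["convergence"] <- tsv(curve, paste0(prefix, "_convergence.tsv"))

  surf <- do.call(rbind, lapply(dirs, function(d) {
    s <- run[[d]]$surface
    if (is.null(s)) return(NULL)
    cbind(direction = s$direction, s$surface[c("E", "tau_p", "max_rho")])
  }))
  if (!is.null(surf))
    files["surface"] <- tsv(surf[c("E", "tau_p", "direction", "max_rho")],
                            paste0(prefix, "_surface.tsv"))

  lines <- c("CCM run summary", "===============", "")
  for (d in dirs) {
    cv <- run[[d]]$convergence; wb <- run[[d]]$whitney
    lines <- c(lines,
      sprintf("%s (tests %s)", cv$direction, cv$tests),
      sprintf("  E* = %d, tau_p* = %d", run[[d]]$E, run[[d]]$tau_p),
      sprintf("  rho_ccm: %.4f at L = %d -> %.4f at L = %d",
              cv$rho_Lmin, cv$L_min, cv$rho_Lmax, cv$L_max),
      sprintf("  delta rho = %.4f, relative difference = %.4f",
              cv$delta_rho, cv$relative_diff),
      sprintf("  verdict: %s",
              if (cv$converged) "CONVERGED - consistent with a causal effect"
              else "no convergence - no evidence of a causal effect"),
      sprintf("  Whitney bounds on causal-system dimensionality: [%d, %d]",
              wb["lower"], wb["upper"]),
      "")
  }
  writeLines(lines, paste0(prefix, "_summary.txt"))
  files["summary"] <- paste0(prefix, "_summary.txt")

  cfg <- run$config
  cfg_lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s: %s", k, if (is.null(v)) "auto" else
      paste(format(v), collapse = " "))
  }, character(1))
  writeLines(c("resolved configuration", cfg_lines),
             paste0(prefix, "_log.txt"))
  files["log"] <- paste0(prefix, "_log.txt")

  if (make_plots) {
    p <- plot_convergence(lapply(dirs, function(d) run[[d]]$result))
    files <- c(files, save_figure(p, paste0(prefix, "_convergence")))
    for (d in dirs) {
      if (is.null(run[[d]]$surface)) next
      ps <- plot_surface(run[[d]]$surface)
      files <- c(files, save_figure(ps, paste0(prefix, "_surface_", d)))
    }
  }
  files
}

#' Plot convergence curves (rho_ccm versus library size)
#'
#' One line per direction, labelled with both the mapping and the causal
#' hypothesis it tests; y-limits fixed to \[-0.1, 1.05\] so flat null curves
#' and converging causal curves are visually comparable across runs.
#'
#' @param results a single [cross_map_skill()] result or a list of them.
#' @return a ggplot object.
#' @export
plot_convergence <- function(results) {
  if (inherits(results, "ccm_result")) results <- list(results)
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no results to plot")
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(L = r$summary$L, rho = r$summary$rho,
               direction = sprintf("%s (tests %s)", r$direction, r$tests))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$rho,
                                   colour = .data$direction)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_cartesian(ylim = c(-0.1, 1.05)) +
    ggplot2::labs(x = "library size L",
                  y = expression(rho["ccm"]),
                  colour = NULL,
                  title = "Convergence of cross-map skill with library size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot the (E, tau_p) sensitivity surface as a heatmap
#'
#' Infeasible cells are rendered as missing (grey), never as zero; the
#' optimum cell is outlined.
#'
#' @param surface a [full_surface()] result.
#' @return a ggplot object.
#' @export
plot_surface <- function(surface) {
  stopifnot(inherits(surface, "ccm_surface"))
  df <- surface$surface
  opt <- df[df$E == surface$E_star & df$tau_p == surface$tau_p_star, ,
            drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau_p, y = .data$E,
                                   fill = .data$max_rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = opt, fill = NA, colour = "black",
                       linewidth = 0.9) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  limits = range(df$max_rho, na.rm = TRUE)) +
    ggplot2::labs(x = expression(tau[p]), y = "E",
                  fill = expression(max ~ rho["ccm"]),
                  title = sprintf("%s (tests %s)", surface$direction,
                                  surface$tests)) +
    ggplot2::theme_minimal()
}

#' Save a figure in vector and raster formats
#'
#' Writes `<base>.pdf` and `<base>.png`.
#'
#' @param plot a ggplot object.
#' @param base path without extension.
#' @param width,height inches.
#' @return character vector of the two paths written, invisibly.
#' @export
save_figure <- function(plot, base, width = 6.5, height = 4.5) {
  dir.create(dirname(base), showWarnings = FALSE, recursive = TRUE)
  paths <- c(pdf = paste0(base, ".pdf"), png = paste0(base, ".png"))
  ggplot2::ggsave(paths[["pdf"]], plot, width = width, height = height)
  ggplot2::ggsave(paths[["png"]], plot, width = width, height = height,
                  dpi = 150)
  invisible(paths)
}
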