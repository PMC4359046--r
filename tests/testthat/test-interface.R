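make_fixture <- function(dir, seed = 4) {
  pp <- predator_prey(seed = seed)
  f <- file.path(dir, "fixture.csv")
  utils::write.csv(data.frame(time = seq(0, by = 0.5, length.out = 60),
                              prey = as.numeric(pp$prey),
                              predator = as.numeric(pp$predator)),
                   f, row.names = FALSE)
  f
}

test_that("full run produces tables, figures, summary and log", {
  dir <- withr::local_tempdir()
  f <- make_fixture(dir)
  prefix <- file.path(dir, "out", "run1")
  # small explicit grid keeps the example quick while exercising all parts
  grid <- structure(list(E = 2:3, tau_p = 0:1, N = 60, tau = 1L, n_lib = 5L),
                    class = "ccm_grid")
  run <- run_ccm(input = f, out_prefix = prefix, grid = grid)

  expect_s3_class(run, "ccm_run")
  for (d in c("xy", "yx")) {
    expect_s3_class(run[[d]]$result, "ccm_result")
    expect_s3_class(run[[d]]$convergence, "ccm_convergence")
    expect_s3_class(run[[d]]$surface, "ccm_surface")
    expect_named(run[[d]]$whitney, c("lower", "upper"))
  }
  expect_true(file.exists(paste0(prefix, "_windows.tsv")))
  expect_true(file.exists(paste0(prefix, "_convergence.tsv")))
  expect_true(file.exists(paste0(prefix, "_surface.tsv")))
  expect_true(file.exists(paste0(prefix, "_summary.txt")))
  expect_true(file.exists(paste0(prefix, "_log.txt")))
  expect_true(file.exists(paste0(prefix, "_convergence.pdf")))
  expect_true(file.exists(paste0(prefix, "_convergence.png")))
  expect_true(file.exists(paste0(prefix, "_surface_xy.pdf")))
  expect_true(file.exists(paste0(prefix, "_surface_yx.png")))

  # the tables carry the exact numbers of the in-memory results
  curve <- utils::read.delim(paste0(prefix, "_convergence.tsv"))
  xy <- curve[curve$direction == run$xy$result$direction, ]
  expect_equal(xy$rho, run$xy$result$summary$rho, tolerance = 1e-12)
  # both directions present with the mapping-labelled direction strings
  expect_setequal(unique(curve$direction),
                  c(run$xy$result$direction, run$yx$result$direction))
  # surface table matches the evaluated surface
  surf <- utils::read.delim(paste0(prefix, "_surface.tsv"))
  expect_equal(nrow(surf), 2 * nrow(run$xy$surface$surface))
})

test_that("single-direction runs evaluate only that direction", {
  pp <- predator_prey(seed = 6)
  grid <- structure(list(E = 2:3, tau_p = 0L, N = 60, tau = 1L, n_lib = 4L),
                    class = "ccm_grid")
  run <- run_ccm(x = pp$prey, y = pp$predator, direction = "xy",
                 surface = FALSE, grid = grid)
  expect_true(!is.null(run$xy))
  expect_null(run$yx)
  expect_match(run$xy$result$tests, "prey -> predator")
})

test_that("degenerate inputs fail with distinct actionable messages", {
  ok <- ccm_series(sin(1:30), "s")
  expect_error(run_ccm(x = ok, y = ccm_series(rep(1, 30))),
               "constant column")
  expect_error(run_ccm(x = ccm_series(1:5), y = ccm_series(2:6)),
               "too short")
  expect_error(run_ccm(x = ok, y = ccm_series(sin(1:31))), "equal length")
  expect_error(run_ccm(), "supply x and y")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,x", "2,y"), bad)
  expect_error(run_ccm(input = bad), "non-numeric")
  one <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a", "1", "2", "3"), one)
  expect_error(run_ccm(input = one), "at least 2 usable columns")
})

test_that("re-running an identical configuration is bit-reproducible", {
  dir <- withr::local_tempdir()
  pp <- predator_prey(seed = 11)
  grid <- structure(list(E = 2:3, tau_p = 0:1, N = 60, tau = 1L, n_lib = 4L),
                    class = "ccm_grid")
  p1 <- file.path(dir, "a"); p2 <- file.path(dir, "b")
  run_ccm(x = pp$prey, y = pp$predator, out_prefix = p1, make_plots = FALSE,
          grid = grid)
  run_ccm(x = pp$prey, y = pp$predator, out_prefix = p2, make_plots = FALSE,
          grid = grid)
  for (suffix in c("_windows.tsv", "_convergence.tsv", "_surface.tsv",
                   "_summary.txt")) {
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
  }
})

test_that("convergence plot carries both direction labels and y-limits", {
  pp <- predator_prey(seed = 2)
  r1 <- cross_map_skill(pp$predator, pp$prey, E = 3)
  r2 <- cross_map_skill(pp$prey, pp$predator, E = 3)
  p <- plot_convergence(list(r1, r2))
  expect_s3_class(p, "ggplot")
  labs <- unique(p$data$direction)
  expect_length(labs, 2)
  expect_true(any(grepl("tests predator -> prey", labs)))
  expect_true(any(grepl("tests prey -> predator", labs)))
  # single-result call still plots
  expect_s3_class(plot_convergence(r1), "ggplot")
  expect_error(plot_convergence(list()), "no results")
})

test_that("surface heatmap outlines the optimum and keeps NAs missing", {
  sim <- coupled_logistic(n = 60, seed = 13)
  grid <- structure(list(E = c(2, 3, 40), tau_p = 0:1, N = 60, tau = 1L,
                         n_lib = 4L), class = "ccm_grid")
  s <- full_surface(sim$x, sim$y, grid)
  p <- plot_surface(s)
  expect_s3_class(p, "ggplot")
  expect_true(any(is.na(p$data$max_rho)))   # infeasible cells stay missing
  # the outlined cell is the argmax of the plotted matrix
  plotted <- p$data
  best <- plotted[which.max(plotted$max_rho), ]
  expect_equal(best$E, s$E_star)
  expect_equal(best$tau_p, s$tau_p_star)
})

test_that("figures are written in vector and raster formats", {
  dir <- withr::local_tempdir()
  pp <- predator_prey(seed = 5)
  p <- plot_convergence(cross_map_skill(pp$predator, pp$prey, E = 3))
  paths <- save_figure(p, file.path(dir, "fig"))
  expect_true(file.exists(paths[["pdf"]]))
  expect_true(file.exists(paths[["png"]]))
})
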