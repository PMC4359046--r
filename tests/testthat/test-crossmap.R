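# helper: a deterministic chaotic series for self-map checks
logistic_series <- function(n, x0 = 0.31, r = 3.9) {
  v <- numeric(n + 100)
  v[1] <- x0
  for (t in seq_len(n + 99)) v[t + 1] <- r * v[t] * (1 - v[t])
  ccm_series(v[101:(n + 100)], "logis")
}

test_that("neighbour ranking excludes the target and breaks ties by time", {
  # square manifold: points at (0,0), (1,0), (0,1), (1,1) by construction
  m <- structure(list(points = rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                      time = 1:4, E = 2L, tau = 1L, n_series = 5L,
                      name = "toy"),
                 class = "shadow_manifold")
  d <- manifold_distances(m)
  lib <- ccm_library(1, 4, m)
  nb <- neighbor_rank(d, m, target = 1, lib, k = 3)
  expect_equal(nb$index[1:2], c(2, 3))  # equidistant: earlier time first
  expect_equal(nb$distance, c(1, 1, sqrt(2)))
  expect_false(1 %in% nb$index)
  expect_error(neighbor_rank(d, m, 1, lib, k = 4), "cannot rank")
})

test_that("neighbour ranking matches an exhaustive sort on a random manifold", {
  set.seed(19)
  m <- embed_series(rnorm(23), E = 3)  # 21 points
  d <- manifold_distances(m)
  lib <- ccm_library(1, 20, m)
  nb <- neighbor_rank(d, m, target = 5, lib, k = 4)
  cand <- setdiff(1:20, 5)
  ord <- cand[order(d[5, cand], m$time[cand])]
  expect_equal(nb$index, ord[1:4])
  expect_equal(nb$distance, d[5, ord[1:4]])
})

test_that("exponential weights follow exp(-d/d1) with degenerate-zero rule", {
  expect_equal(exp_weights(c(2, 2, 2)), rep(1 / 3, 3))
  u <- exp(-c(1, 2))
  expect_equal(exp_weights(c(1, 2)), u / sum(u))
  expect_equal(exp_weights(c(1, 2)), c(0.7310586, 0.2689414),
               tolerance = 1e-6)
  expect_equal(exp_weights(c(0, 0, 5)), c(0.5, 0.5, 0))
  expect_error(exp_weights(numeric(0)), "at least one")
  expect_error(exp_weights(c(2, 1)), "sorted")
})

test_that("weights are a convex combination; predictions stay in range", {
  set.seed(23)
  for (rep in 1:10) {
    dd <- sort(abs(rnorm(5)))
    w <- exp_weights(dd)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  # a convex combination of observations cannot leave their range
  s <- logistic_series(80)
  my <- embed_series(s, E = 2)
  lib <- ccm_library(1, nrow(my$points), my)
  preds <- vapply(my$time[3:60], function(t)
    crossmap_point(my, s, lib, t)$predicted, numeric(1))
  expect_true(all(preds >= min(s) & preds <= max(s)))
})

test_that("cross-map of a constant cause returns the constant", {
  y <- logistic_series(40)
  x <- ccm_series(rep(2.5, 40), "const")
  my <- embed_series(y, E = 2)
  lib <- ccm_library(1, nrow(my$points), my)
  p <- crossmap_point(my, x, lib, t = 10, tau_p = 0)
  expect_equal(p$predicted, 2.5)
  expect_equal(p$observed, 2.5)
  expect_equal(sum(p$neighbors$weight), 1, tolerance = 1e-9)
})

test_that("single-point cross-map matches the naive reference", {
  set.seed(5)
  sim <- coupled_logistic(n = 30, beta_xy = 0.3, seed = 77)
  E <- 2; tau_p <- 0
  my <- embed_series(sim$y, E = E)
  L <- nrow(my$points)
  lib <- ccm_library(1, L, my)
  # reference: recompute weights by hand for one target
  emb <- ref_embed(as.numeric(sim$y), E, 1)
  xv <- as.numeric(sim$x)
  t <- 15
  i <- match(t, emb$time)
  cand <- setdiff(seq_len(L), i)
  dd <- sapply(cand, function(j)
    ref_dist(emb$points[i, ], emb$points[j, ]))
  ord <- order(dd, emb$time[cand])
  sel <- cand[ord][1:(E + 1)]
  w <- exp(-dd[ord][1:(E + 1)] / dd[ord][1])
  w <- w / sum(w)
  expected <- sum(w * xv[emb$time[sel]])
  p <- crossmap_point(my, sim$x, lib, t = t, tau_p = tau_p)
  expect_equal(p$predicted, expected, tolerance = 1e-12)
})

test_that("predictive skill is Pearson correlation with flagged edge cases", {
  expect_equal(as.numeric(ccm_skill(1:5, 1:5)), 1)
  expect_equal(as.numeric(ccm_skill(1:5, -(1:5))), -1)
  expect_equal(as.numeric(ccm_skill(c(1, 2, 3, 4), c(1, 2, 2, 5))),
               0.8944272, tolerance = 1e-6)
  expect_warning(z <- ccm_skill(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_equal(as.numeric(z), 0)
  expect_identical(attr(z, "flag"), "zero_variance")
  expect_identical(attr(ccm_skill(1:2, 1:2), "flag"), "undefined")
})

test_that("window sweep: window counts and the single-window limit", {
  s <- logistic_series(40)
  x <- logistic_series(40)
  P <- 39  # manifold points at E = 2
  r <- cross_map_skill(x, s, E = 2, lib_sizes = c(20, P))
  expect_equal(r$summary$n_windows, c(P - 20 + 1, 1))
  expect_equal(nrow(r$windows[r$windows$L == P, ]), 1)
  # with a single window the mean equals that window's rho
  expect_equal(r$summary$rho[2], r$windows$rho[r$windows$L == P])
  expect_error(cross_map_skill(x, s, E = 2, lib_sizes = 500),
               "no feasible")
})

test_that("self cross-map skill of deterministic chaos approaches 1", {
  s <- logistic_series(150)
  r <- cross_map_skill(s, s, E = 2, lib_sizes = c(20, 60, 149))
  expect_true(all(diff(r$summary$rho) > 0))
  expect_gt(r$summary$rho[3], 0.95)
})

test_that("skill rises with library size under unidirectional forcing", {
  sim <- coupled_logistic(n = 200, beta_xy = 0.32, beta_yx = 0, seed = 11)
  r <- cross_map_skill(sim$x, sim$y, E = 2, lib_sizes = c(20, 150))
  expect_gt(r$summary$rho[2], r$summary$rho[1])
})

test_that("full pipeline equals the naive double-loop reference", {
  set.seed(31)
  for (rep in 1:3) {
    sim <- coupled_logistic(n = 45, beta_xy = 0.35, noise_sd = 0.01,
                            seed = 400 + rep)
    E <- 2 + (rep %% 2); tau_p <- rep %% 2
    r <- cross_map_skill(sim$x, sim$y, E = E, tau_p = tau_p,
                         lib_sizes = c(12, 25))
    for (L in c(12, 25)) {
      ref <- ref_window_rhos(sim$x, sim$y, E, 1, tau_p, L)
      got <- r$windows$rho[r$windows$L == L]
      expect_equal(got, ref, tolerance = 1e-10)
    }
  }
})

test_that("direction asymmetry under unidirectional forcing", {
  hits <- 0
  for (s in 1:10) {
    sim <- coupled_logistic(n = 200, beta_xy = 0.32, beta_yx = 0, seed = s)
    true_dir <- cross_map_skill(sim$x, sim$y, E = 2, lib_sizes = c(20, 190))
    false_dir <- cross_map_skill(sim$y, sim$x, E = 2, lib_sizes = c(20, 190))
    if (true_dir$summary$rho[2] > false_dir$summary$rho[2]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("tau_p shifts skip out-of-range targets without silent drops", {
  s <- logistic_series(30)
  x <- logistic_series(30)
  r <- cross_map_skill(x, s, E = 2, tau_p = 5, lib_sizes = 29)
  # manifold times 2..5 shift below 1 and must be counted
  expect_equal(r$summary$n_skipped, 4)
  expect_equal(r$summary$n_windows, 1)
})

test_that("convergence assessment computes delta and verdict", {
  mk <- function(rhos, Ls) {
    structure(list(direction = "b xmap a", tests = "a -> b",
                   summary = data.frame(L = Ls, rho = rhos)),
              class = "ccm_result")
  }
  flat <- assess_convergence(mk(c(0.05, 0.05, 0.05), c(10, 20, 30)))
  expect_equal(flat$delta_rho, 0)
  expect_false(flat$converged)
  ramp <- assess_convergence(mk(c(0.2, 0.6, 0.9), c(10, 20, 30)))
  expect_equal(ramp$delta_rho, 0.7)
  expect_true(ramp$converged)
  # high but flat: no convergence, the causal criterion is the rise
  high <- assess_convergence(mk(c(0.85, 0.88, 0.9), c(10, 20, 30)))
  expect_false(high$converged)
  expect_error(assess_convergence(mk(0.5, 10)), ">= 2 library sizes")
})

test_that("independent white noise rarely passes the convergence test", {
  falses <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- ccm_series(rnorm(100), "wn1")
    y <- ccm_series(rnorm(100), "wn2")
    r <- cross_map_skill(x, y, E = 2, lib_sizes = c(10, 40, 70, 99))
    if (!assess_convergence(r)$converged) falses <- falses + 1
  }
  expect_gte(falses, 9)
})
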