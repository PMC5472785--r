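test_that("KS divergence has its analytic values and symmetry", {
  a <- exp_wtd(1); b <- exp_wtd(2)
  expect_equal(ks_divergence(a, a), 0)
  # sup |e^-t - e^-2t| = 1/4 at t = ln 2
  expect_equal(ks_divergence(a, b), 0.25, tolerance = 0.01)
  expect_equal(ks_divergence(a, b), ks_divergence(b, a))
  expect_error(ks_divergence(a, unif_wtd(2)), "different grids")
})

test_that("on a tree the update is plain kernel density estimation", {
  # path graph: every node has a single eligible parent, every beta = 1,
  # so the update is the histogram of observed TDOAs -- independent of the
  # (deliberately wrong) input guess
  g <- new_graph(4, cbind(1:3, 2:4))
  s <- sample_from_times(c(0, 0.9, 2.0, 2.4), c(0, 1.1, 1.8, 3.0))
  cfg <- estimator_config(kernel = "dirac", nbins = 50, tau_max = 5)
  guess1 <- wtd_parametric("exponential", list(mean = 1), tau_max = 5,
                           nbins = 50)
  guess2 <- wtd_parametric("uniform", list(min = 0, max = 5), tau_max = 5,
                           nbins = 50)
  up1 <- redistribute_update(guess1, g, s, cfg)
  up2 <- redistribute_update(guess2, g, s, cfg)
  expect_equal(up1$dens, up2$dens, tolerance = 1e-12)
  d_obs <- c(0.9, 1.1, 2.0 - 0.9, 1.8 - 1.1, 2.4 - 2.0, 3.0 - 1.8)
  hist_mass <- tabulate(floor(d_obs / 0.1 + 1e-9) + 1, 50) / length(d_obs)
  expect_equal(up1$dens * 0.1, hist_mass, tolerance = 1e-12)

  # single cascade, single link, Dirac kernel: a unit atom at the TDOA
  g1 <- new_graph(2, rbind(c(1, 2)))
  s1 <- sample_from_times(c(0, 1.23))
  up <- redistribute_update(guess1, g1, s1, cfg)
  expect_equal(sum(up$dens > 0), 1)
  expect_equal(up$breaks[which(up$dens > 0)], 1.2, tolerance = 1e-9)
})

test_that("the true density is a fixed point of the update (two-parent toy)", {
  # source 1, node 3 exposed to the competing risks of 1 and 2: branch and
  # chord terms both active; at large C the update applied to the truth
  # must return the truth up to discretisation error
  g <- new_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  truth <- exp_wtd(1, tau_max = 15, nbins = 300)
  model <- new_stn(g, truth)
  set.seed(41)
  s <- generate_cascade_sample(model, 1e5, sources = rep(1L, 1e5))
  cfg <- estimator_config(kernel = "dirac", nbins = 300, tau_max = 15)
  up <- redistribute_update(truth, g, s, cfg)
  expect_lt(ks_divergence(up, truth), 0.01)
})

test_that("every iterate conserves mass and stays a valid density", {
  inst <- random_instance(n = 5, C = 10, seed = 51)
  cfg <- estimator_config(h = 0.05, nbins = 100, max_iter = 5, eps = 1e-12)
  fit <- estimate_wtds(inst$sample, inst$graph, cfg)
  w <- fit$wtds
  dx <- w$breaks[2] - w$breaks[1]
  expect_equal(sum(w$dens * dx) + w$tail, 1, tolerance = 1e-9)
  expect_true(all(w$dens >= 0))
  # a huge threshold stops after exactly one update
  fit1 <- estimate_wtds(inst$sample, inst$graph,
                        estimator_config(eps = 10, nbins = 100))
  expect_equal(fit1$n_iter, 1)
  expect_true(fit1$converged)
})

test_that("estimates converge to the truth and improve with sample size", {
  m <- generate_benchmark(benchmark_spec(
    "ring-lattice", n = 8, degree = 4,
    wtd = list(family = "exponential", params = list(mean = 1)), seed = 61))
  ks_at <- function(C, seed) {
    set.seed(seed)
    s <- generate_cascade_sample(m, C)
    fit <- estimate_wtds(s, m$graph,
                         estimator_config(h = 1e-3, nbins = 150,
                                          tau_max = tmax))
    ks_divergence(fit$wtds, truth_grid)
  }
  tmax <- 12
  truth_grid <- wtd_parametric("exponential", list(mean = 1), tau_max = tmax,
                               nbins = 150)
  err_small <- mean(vapply(1:3, function(r) ks_at(100, 600 + r), 0))
  err_big <- mean(vapply(1:3, function(r) ks_at(1500, 700 + r), 0))
  expect_lt(err_big, err_small)
  expect_lt(err_big, 0.05)
})

test_that("pooled estimates are invariant to node relabelling", {
  m <- generate_benchmark(benchmark_spec(
    "ring-lattice", n = 6, degree = 4,
    wtd = list(family = "gaussian", params = list(mean = 2, sd = 0.5)),
    seed = 71))
  set.seed(72)
  s <- generate_cascade_sample(m, 50)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)   # relabel nodes
  s_perm <- new_cascade_sample(lapply(s$cascades, function(d) {
    t <- numeric(6); t[perm] <- d$t
    new_cascade(perm[d$source], t)
  }))
  g_perm <- new_graph(6, cbind(perm[m$graph$edges[, 1]],
                               perm[m$graph$edges[, 2]]))
  cfg <- estimator_config(nbins = 80, tau_max = 10)
  f1 <- estimate_wtds(s, m$graph, cfg)
  f2 <- estimate_wtds(s_perm, g_perm, cfg)
  expect_equal(f1$wtds$dens, f2$wtds$dens, tolerance = 1e-12)
})

test_that("bootstrap bands behave at the degenerate level and are seeded", {
  g <- new_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  truth <- wtd_parametric("exponential", list(mean = 1), tau_max = 10,
                          nbins = 60)
  set.seed(81)
  s <- generate_cascade_sample(new_stn(g, truth), 60,
                               sources = rep(1L, 60))
  fit <- estimate_wtds(s, g, estimator_config(nbins = 60, tau_max = 10))
  expect_error(bootstrap_bands(s, g, fit$wtds, B = 1), "at least 2")
  b0 <- bootstrap_bands(s, g, fit$wtds, B = 5, level = 0)
  expect_identical(b0$lower, fit$wtds$dens)
  expect_identical(b0$upper, fit$wtds$dens)
  b1 <- bootstrap_bands(s, g, fit$wtds, B = 4, level = 0.8, seed = 9,
                        config = estimator_config(max_iter = 10))
  b2 <- bootstrap_bands(s, g, fit$wtds, B = 4, level = 0.8, seed = 9,
                        config = estimator_config(max_iter = 10))
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_true(all(b1$upper >= b1$lower))
})

test_that("bootstrap bands cover the truth at roughly the nominal level", {
  g <- new_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  truth <- wtd_parametric("gaussian", list(mean = 2, sd = 0.5),
                          tau_max = 6, nbins = 50)
  set.seed(91)
  s <- generate_cascade_sample(new_stn(g, truth), 300,
                               sources = rep(1L, 300))
  cfg <- estimator_config(h = 0.02, nbins = 50, tau_max = 6, max_iter = 20)
  fit <- estimate_wtds(s, g, cfg)
  band <- bootstrap_bands(s, g, fit$wtds, B = 100, level = 0.8,
                          config = cfg, seed = 92)
  covered <- truth$dens >= band$lower - 1e-12 & truth$dens <= band$upper + 1e-12
  # coverage is meaningful where the density carries mass; in the far tails
  # both band and truth are numerically zero-vs-tiny
  support <- truth$dens > 0.01 * max(truth$dens)
  expect_gte(mean(covered[support]), 0.7)   # level - 0.1
})
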