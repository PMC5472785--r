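e1 <- exp_wtd(1)

test_that("cascade log-likelihood matches hand-computed closed forms", {
  # single risk s -> v at TDOA 1, unit-rate exponential: log psi(1) = -1
  g2 <- new_graph(2, rbind(c(1, 2)))
  expect_equal(cascade_loglik(g2, e1, cascade_from_times(c(0, 1))), -1,
               tolerance = 0.02)

  # star s -> {a, b}: independent risks add, -(0.5 + 2)
  gs <- new_graph(3, rbind(c(1, 2), c(1, 3)))
  expect_equal(cascade_loglik(gs, e1, cascade_from_times(c(0, 0.5, 2))),
               -2.5, tolerance = 0.02)

  # triangle s -> a -> b with chord s -> b, t_a = 1, t_b = 3:
  # log(lam_sb + lam_ab) + logS_sb(3) + logS_ab(2) + log lam_sa(1) + logS_sa(1)
  # = log 2 - 6 for unit-rate exponentials
  gt <- new_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(cascade_loglik(gt, e1, cascade_from_times(c(0, 1, 3))),
               log(2) - 6, tolerance = 0.03)

  # a node with no eligible in-neighbour makes the cascade impossible
  expect_identical(cascade_loglik(g2, e1, cascade_from_times(c(1, 0))), -Inf)
})

test_that("total log-likelihood is additive and propagates -Inf", {
  g <- new_graph(3, rbind(c(1, 2), c(2, 3)))
  d <- cascade_from_times(c(0, 1, 2.5))
  one <- cascade_loglik(g, e1, d)
  s5 <- new_cascade_sample(rep(list(d), 5))
  expect_equal(total_loglik(g, e1, s5), 5 * one, tolerance = 1e-9)
  bad <- sample_from_times(c(0, 1, 2.5), c(2.5, 1, 0))
  expect_identical(total_loglik(g, e1, bad), -Inf)
})

test_that("two-node likelihood exponentiates to the waiting-time density", {
  g2 <- new_graph(2, rbind(c(1, 2)))
  for (d in c(0.3, 1, 2.7)) {
    ll <- cascade_loglik(g2, e1, cascade_from_times(c(0, d)))
    expect_equal(exp(ll), exp(-d), tolerance = 0.02)
  }
})

test_that("branching coefficients are normalised hazard shares", {
  # single eligible parent: beta = 1
  g <- new_graph(3, rbind(c(1, 2), c(2, 3)))
  bc <- branching_coefficients(g, e1, cascade_from_times(c(0, 1, 2)))
  expect_equal(bc$beta, c(1, 1))

  # two parents, identical density, equal TDOAs: symmetry gives 1/2 each
  gs <- new_graph(4, rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
  bc2 <- branching_coefficients(gs, e1, cascade_from_times(c(0, 1, 1, 2)))
  expect_equal(bc2$beta[bc2$v == 4], c(0.5, 0.5))

  # constant hazards 1 and 3: beta = 1/4 and 3/4 at any TDOAs (per-link mode)
  gp <- new_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  wtds <- list("1->2" = e1, "1->3" = e1, "2->3" = exp_wtd(3))
  for (tb in c(1.5, 2.2, 4)) {
    bc3 <- branching_coefficients(gp, wtds, cascade_from_times(c(0, 1, tb)))
    expect_equal(bc3$beta[bc3$v == 3], c(0.25, 0.75), tolerance = 0.01)
  }

  # normalisation invariant on random instances
  for (seed in 1:5) {
    inst <- random_instance(n = 5, C = 2, seed = seed)
    for (d in inst$sample$cascades) {
      bc <- branching_coefficients(inst$graph, inst$wtd, d)
      sums <- tapply(bc$beta, bc$v, sum)
      expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
    }
  }
})

test_that("marginal gains are incremental and exactly antisymmetric", {
  inst <- random_instance(n = 5, C = 3, seed = 11)
  g <- inst$graph
  s <- inst$sample
  # a link whose tail never precedes its head contributes nothing
  t1 <- s$cascades[[1]]$t
  # build a cascade set where (u0, v0) is never eligible
  u0 <- which.max(t1)
  v0 <- s$cascades[[1]]$source
  never <- all(vapply(s$cascades, function(d) d$t[u0] >= d$t[v0], TRUE))
  if (never && !graph_has_edge(g, u0, v0))
    expect_identical(marginal_gain(g, inst$wtd, s, u0, v0), 0)

  # add-gain then remove-gain of the same link negate exactly
  for (u in 1:5) for (v in 1:5) {
    if (u == v || graph_has_edge(g, u, v)) next
    add <- marginal_gain(g, inst$wtd, s, u, v)
    rem <- marginal_gain(graph_add(g, u, v), inst$wtd, s, u, v)
    if (is.finite(add)) expect_equal(rem, -add, tolerance = 1e-9)
    break
  }
})

test_that("incremental marginal gain equals brute-force likelihood difference", {
  for (seed in 1:30) {
    inst <- random_instance(n = 5, C = 3, seed = 100 + seed)
    g <- inst$graph
    s <- inst$sample
    base <- oracle_total_loglik(g, inst$wtd, s)
    set.seed(seed)
    for (rep in 1:3) {
      u <- sample.int(5, 1); v <- sample.int(5, 1)
      if (u == v) next
      gain <- marginal_gain(g, inst$wtd, s, u, v)
      flipped <- if (graph_has_edge(g, u, v)) graph_remove(g, u, v)
                 else graph_add(g, u, v)
      brute <- oracle_total_loglik(flipped, inst$wtd, s) - base
      if (is.finite(gain) && is.finite(brute)) {
        expect_equal(gain, brute, tolerance = 1e-9)
      } else {
        expect_identical(is.finite(gain), is.finite(brute))
        if (!is.finite(brute)) expect_equal(sign(gain), sign(brute))
      }
    }
  }
})
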