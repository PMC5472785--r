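make_posterior <- function(cand, freq, n) {
  structure(list(candidates = cand, freq = freq, config = sampler_config(),
                 n = n),
            class = "stn_link_posterior")
}

test_that("ROC and PR areas hit their closed-form extremes", {
  truth <- new_graph(6, rbind(c(1, 2), c(2, 3), c(3, 4)))
  cand <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6))
  perfect <- make_posterior(cand, c(1, 0.9, 0.8, 0.2, 0.1, 0), 6)
  ev <- pr_roc(perfect, truth)
  expect_equal(ev$auroc, 1)
  expect_equal(ev$aupr, 1)
  inverted <- make_posterior(cand, c(0, 0.1, 0.2, 0.8, 0.9, 1), 6)
  expect_equal(pr_roc(inverted, truth)$auroc, 0)
  expect_error(pr_roc(perfect, new_graph(6, matrix(0L, 0, 2))), "no links")
})

test_that("random scores give AUROC near one half", {
  set.seed(201)
  n <- 150
  cand <- candidate_links(sample_from_times(seq(0, 1, length.out = n)))
  keep <- sample.int(nrow(cand), 1e4)
  cand <- cand[keep, ]
  truth <- new_graph(n, cand[sample.int(nrow(cand), 500), ])
  post <- make_posterior(cand, runif(nrow(cand)), n)
  expect_lt(abs(pr_roc(post, truth)$auroc - 0.5), 0.05)
})

test_that("our AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(211)
  n <- 40
  cand <- candidate_links(sample_from_times(seq(0, 1, length.out = n)))
  truth <- new_graph(n, cand[sample.int(nrow(cand), 100), ])
  scores <- runif(nrow(cand))
  post <- make_posterior(cand, scores, n)
  labels <- paste(cand[, 1], cand[, 2]) %in%
    paste(truth$edges[, 1], truth$edges[, 2])
  ref <- suppressMessages(pROC::auc(pROC::roc(
    labels, scores, quiet = TRUE, direction = "<",
    levels = c(FALSE, TRUE))))
  expect_equal(pr_roc(post, truth)$auroc, as.numeric(ref), tolerance = 1e-9)
})

test_that("break-even point is precision = recall at the true link count", {
  truth <- new_graph(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  cand <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6))
  perfect <- make_posterior(cand, 6:1 / 6, 6)
  expect_equal(as.numeric(break_even_point(perfect, truth)), 1)
  # exactly half of the top-L correct
  half <- make_posterior(cand, c(1, 0.9, 0.1, 0.05, 0.8, 0.7), 6)
  expect_equal(as.numeric(break_even_point(half, truth)), 0.5)
})

test_that("the BEP is the PR-curve / diagonal intersection", {
  set.seed(221)
  for (rep in 1:5) {
    n <- 25
    cand <- candidate_links(sample_from_times(seq(0, 1, length.out = n)))
    L <- 60
    truth <- new_graph(n, cand[sample.int(nrow(cand), L), ])
    post <- make_posterior(cand, runif(nrow(cand)), n)  # distinct scores a.s.
    bep <- as.numeric(break_even_point(post, truth))
    pr <- pr_roc(post, truth)$pr
    gap <- pr$precision - pr$recall
    i <- max(which(gap >= 0))
    # linear interpolation of the crossing of precision(recall) with y = x
    if (i < nrow(pr) && gap[i] > 0) {
      lambda <- gap[i] / (gap[i] - gap[i + 1])
      cross <- pr$recall[i] + lambda * (pr$recall[i + 1] - pr$recall[i])
    } else {
      cross <- pr$recall[i]
    }
    expect_lt(abs(bep - cross), 1.5 / L)
  }
})

test_that("spreading-tree entropy matches its closed forms and bounds", {
  e1 <- exp_wtd(1)
  # tree-compatible cascade: a single eligible parent everywhere, H = 0
  chain <- new_stn(new_graph(3, rbind(c(1, 2), c(2, 3))), e1)
  expect_equal(inferential_complexity(chain, cascade_from_times(c(0, 1, 2))),
               0)
  # one node with k equally weighted parents: H = log k
  k <- 4
  star_in <- new_stn(new_graph(k + 2,
                               rbind(cbind(1, 2:(k + 1)),
                                     cbind(2:(k + 1), k + 2))), e1)
  d <- cascade_from_times(c(0, rep(1, k), 3))
  expect_equal(inferential_complexity(star_in, d), log(k), tolerance = 1e-9)
  # bounds: 0 <= H <= sum_v log(#eligible parents)
  for (seed in 1:5) {
    inst <- random_instance(n = 5, C = 2, seed = 300 + seed)
    m <- new_stn(inst$graph, inst$wtd)
    for (casc in inst$sample$cascades) {
      H <- inferential_complexity(m, casc)
      bc <- branching_coefficients(inst$graph, inst$wtd, casc)
      expect_gte(H, 0)
      expect_lte(H, sum(log(tapply(bc$beta, bc$v, length))) + 1e-9)
    }
  }
})

test_that("entropy equals the enumerated diffusion-tree distribution entropy", {
  e1 <- exp_wtd(1)
  for (seed in 1:5) {
    inst <- random_instance(n = 4, C = 1, seed = 310 + seed)
    H <- inferential_complexity(new_stn(inst$graph, inst$wtd),
                                inst$sample$cascades[[1]])
    H_oracle <- oracle_tree_entropy(inst$graph, inst$wtd,
                                    inst$sample$cascades[[1]])
    expect_equal(H, H_oracle, tolerance = 1e-9)
  }
})

test_that("critical sample size scans the grid with degenerate thresholds", {
  spec <- benchmark_spec("ring-lattice", n = 8, degree = 4, seed = 321)
  fast <- sampler_config(burn_in = 5, lag = 2, M = 50)
  # threshold 0 is met by the first grid point
  c0 <- critical_sample_size(spec, "auroc", threshold = 0,
                             C_grid = c(4, 8), replicates = 1,
                             sampler = fast, seed = 1)
  expect_equal(as.numeric(c0), 4)
  expect_false(attr(c0, "flagged"))
  # an unattainable threshold exhausts the grid
  cInf <- critical_sample_size(spec, "bep", threshold = 1.01,
                               C_grid = c(4, 8), replicates = 1,
                               sampler = fast, seed = 1)
  expect_identical(as.numeric(cInf), Inf)
  expect_true(attr(cInf, "flagged"))
  expect_error(critical_sample_size(spec, "auroc", C_grid = integer(0)),
               "empty")
})

test_that("accuracy means are (weakly) monotone in the sample size", {
  spec <- benchmark_spec("erdos-renyi", n = 20, degree = 4, seed = 331)
  scan <- critical_sample_size(spec, "auroc", threshold = 2,
                               C_grid = c(5, 20, 80), replicates = 4,
                               sampler = sampler_config(M = 100), seed = 2)
  means <- attr(scan, "means")
  expect_equal(length(means), 3)
  expect_true(all(diff(means) > -0.02))
  expect_gt(means[3], means[1])
})
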