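# Fixtures built in code and independent oracles used across the suite.

# finely binned parametric densities for near-analytic assertions
exp_wtd <- function(rate = 1, tau_max = 25, nbins = 2500)
  wtd_parametric("exponential", list(rate = rate), tau_max = tau_max,
                 nbins = nbins)

unif_wtd <- function(max = 2, nbins = 2000)
  wtd_parametric("uniform", list(min = 0, max = max), tau_max = max,
                 nbins = nbins)

# near-degenerate density: all mass in the bin containing `at`
dirac_wtd <- function(at, tau_max = 2 * at, nbins = 20000) {
  breaks <- seq(0, tau_max, length.out = nbins + 1)
  mass <- numeric(nbins)
  mass[min(floor(at / (breaks[2])) + 1, nbins)] <- 1
  wtd_from_mass(mass, breaks)
}

cascade_from_times <- function(t) new_cascade(which(t == 0)[1], t)

sample_from_times <- function(...) {
  new_cascade_sample(lapply(list(...), cascade_from_times))
}

# --- independent oracle: naive likelihood from first principles ------------
# direct transcription of the competing-risks formula, structured differently
# from the package path (explicit double loop over the edge matrix).
oracle_cascade_loglik <- function(graph, wtd, cascade) {
  t <- cascade$t
  ll <- 0
  for (v in seq_len(graph$n)) {
    if (v == cascade$source || is.na(t[v])) next
    hsum <- 0
    ssum <- 0
    found <- FALSE
    for (i in seq_len(nrow(graph$edges))) {
      if (graph$edges[i, 2] != v) next
      u <- graph$edges[i, 1]
      if (is.na(t[u]) || t[u] >= t[v]) next
      found <- TRUE
      d <- t[v] - t[u]
      hsum <- hsum + wtd_hazard(wtd, d)
      ssum <- ssum + log(max(wtd_survival(wtd, d), 1e-12))
    }
    if (!found) return(-Inf)
    ll <- ll + log(hsum) + ssum
  }
  ll
}

oracle_total_loglik <- function(graph, wtd, sample) {
  sum(vapply(sample$cascades, function(d)
    oracle_cascade_loglik(graph, wtd, d), 0))
}

# exhaustive posterior over the 2^K graphs spanned by a candidate set
oracle_enumerate_posterior <- function(sample, wtd, candidates) {
  K <- nrow(candidates)
  configs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), K)))
  ll <- apply(configs, 1, function(on) {
    g <- new_graph(sample$n, candidates[on, , drop = FALSE])
    oracle_total_loglik(g, wtd, sample)
  })
  w <- exp(ll - max(ll[is.finite(ll)]))
  w[!is.finite(ll)] <- 0
  probs <- w / sum(w)
  list(configs = configs, probs = probs,
       link_marginals = as.vector(probs %*% configs))
}

# exhaustive spreading-tree entropy: enumerate one-parent-per-node
# assignments weighted by the product of branch hazards
oracle_tree_entropy <- function(graph, wtd, cascade) {
  t <- cascade$t
  parents <- list()
  nodes <- setdiff(which(!is.na(t)), cascade$source)
  for (v in nodes) {
    par <- graph$edges[graph$edges[, 2] == v, 1]
    par <- par[!is.na(t[par]) & t[par] < t[v]]
    stopifnot(length(par) > 0)
    parents[[as.character(v)]] <- par
  }
  grids <- expand.grid(parents)
  w <- apply(grids, 1, function(row) {
    prod(vapply(seq_along(nodes), function(i)
      wtd_hazard(wtd, t[nodes[i]] - t[as.integer(row[i])]), 0))
  })
  p <- w / sum(w)
  -sum(ifelse(p > 0, p * log(p), 0))
}

# random small instance: connected-enough graph + consistent cascades
random_instance <- function(n = 5, C = 3, seed = 1) {
  set.seed(seed)
  wtd <- exp_wtd(1)
  repeat {
    edges <- which(matrix(runif(n * n) < 0.5, n, n) &
                     !diag(TRUE, n), arr.ind = TRUE)
    g <- new_graph(n, edges)
    model <- try(new_stn(g, wtd), silent = TRUE)
    ok <- TRUE
    cascades <- vector("list", C)
    for (c in seq_len(C)) {
      src <- sample.int(n, 1)
      t <- try(simulate_cascade(model, src), silent = TRUE)
      if (inherits(t, "try-error")) { ok <- FALSE; break }
      cascades[[c]] <- t
    }
    if (ok) return(list(graph = g, wtd = wtd,
                        sample = new_cascade_sample(cascades)))
  }
}
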