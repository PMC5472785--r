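#' Gibbs sampler configuration
#'
#' @param burn_in number of initial sweeps discarded.
#' @param lag sweeps between retained samples.
#' @param M number of retained samples.
#' @param seed optional integer seed for the sampler's RNG stream.
#' @return an object of class `stn_sampler_config`.
#' @export
sampler_config <- function(burn_in = 10, lag = 10, M = 200, seed = NULL) {
  stopifnot(burn_in >= 1, lag >= 1, M >= 1)
  structure(list(burn_in = as.integer(burn_in), lag = as.integer(lag),
                 M = as.integer(M), seed = seed),
            class = "stn_sampler_config")
}

#' Candidate links of a cascade sample
#'
#' All ordered pairs `(u, v)` with `t_u < t_v` in at least one cascade.  Any
#' other pair is never eligible in any cascade, contributes nothing to any
#' likelihood, and is fixed absent.
#'
#' @param sample an `stn_cascade_sample`.
#' @return integer matrix with columns `u`, `v`, in lexicographic order.
#' @export
candidate_links <- function(sample) {
  n <- sample$n
  any_lt <- matrix(FALSE, n, n)
  for (d in sample$cascades) {
    t <- d$t
    ok <- outer(t, t, function(a, b) !is.na(a) & !is.na(b) & a < b)
    any_lt <- any_lt | ok
  }
  diag(any_lt) <- FALSE
  idx <- which(any_lt, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("u", "v")
  unname(idx)
  matrix(as.integer(idx), ncol = 2, dimnames = list(NULL, c("u", "v")))
}

# CSR cache of per-candidate eligible (cascade, hazard, log-survival) data.
# Shared waiting-time density only: lookups are vectorised over all pairs.
likelihood_cache <- function(sample, wtd, candidates) {
  K <- nrow(candidates)
  C <- length(sample)
  ks <- cs <- list()
  ds <- list()
  for (c in seq_len(C)) {
    t <- sample$cascades[[c]]$t
    src <- sample$cascades[[c]]$source
    tu <- t[candidates[, 1]]
    tv <- t[candidates[, 2]]
    el <- which(!is.na(tu) & !is.na(tv) & tu < tv & candidates[, 2] != src)
    ks[[c]] <- el
    cs[[c]] <- rep.int(c, length(el))
    ds[[c]] <- tv[el] - tu[el]
  }
  k_all <- unlist(ks); c_all <- unlist(cs); d_all <- unlist(ds)
  o <- order(k_all)
  k_all <- k_all[o]; c_all <- c_all[o]; d_all <- d_all[o]
  lam <- wtd_hazard(wtd, d_all)
  logS <- log(pmax(wtd_survival(wtd, d_all), .stn_s_floor))
  cnt <- tabulate(k_all, nbins = K)
  ptr <- cumsum(c(0L, cnt))
  logS_sum <- numeric(K)
  if (length(k_all)) {
    agg <- rowsum(logS, k_all)
    logS_sum[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(ptr = as.integer(ptr), casc = as.integer(c_all - 1L), lam = lam,
       vnode = as.integer(candidates[, 2] - 1L), logS_sum = logS_sum,
       C = C)
}

#' Gibbs sampling of time-aggregated graph configurations
#'
#' Systematic heat-bath sweeps over the candidate links: each link indicator
#' is resampled from its full conditional
#' `P(present | rest) = 1 / (1 + exp(-delta))`, with `delta` the
#' add-direction marginal gain of the link in the current configuration.
#' The chain starts from the all-candidates-present graph (which has finite
#' likelihood by construction); after `burn_in` sweeps every `lag`-th sweep
#' is retained until `M` samples are collected.  The per-link presence
#' frequency over the retained samples is the posterior link score.
#'
#' Requires a single shared waiting-time density (the homogeneous population
#' assumption under which all topology-inference experiments run).
#'
#' @param sample an `stn_cascade_sample`.
#' @param wtds an `stn_wtd`, or an `stn_model` in shared mode.
#' @param config a [sampler_config()].
#' @param candidates optional candidate-link matrix (defaults to
#'   [candidate_links()] of the sample).
#' @param keep_samples also return the retained indicator samples (a
#'   `K x M` 0/1 matrix), for diagnostics on small instances.
#' @return an object of class `stn_link_posterior`: list with `candidates`,
#'   `freq`, `config`, `n` (and `samples` if requested).
#' @export
gibbs_sample <- function(sample, wtds, config = sampler_config(),
                         candidates = NULL, keep_samples = FALSE) {
  if (inherits(wtds, "stn_model")) {
    if (!wtds$shared)
      stop("gibbs_sample needs a single shared waiting-time density")
    wtds <- wtds$wtds
  }
  if (!inherits(wtds, "stn_wtd"))
    stop("gibbs_sample needs a single shared waiting-time density")
  if (is.null(candidates)) candidates <- candidate_links(sample)
  K <- nrow(candidates)
  if (K == 0) stop("no candidate links: every pair of arrivals is tied")
  if (!is.null(config$seed)) set.seed(config$seed)
  cache <- likelihood_cache(sample, wtds, candidates)
  sweep_order <- sample.int(K) - 1L
  res <- cpp_gibbs(K, cache$ptr, cache$casc, cache$lam, cache$vnode,
                   cache$logS_sum, sample$n, cache$C, sweep_order,
                   config$burn_in, config$lag, config$M, keep_samples)
  out <- list(candidates = candidates, freq = res$freq, config = config,
              n = sample$n)
  if (keep_samples) out$samples <- res$samples
  structure(out, class = "stn_link_posterior")
}

#' @export
print.stn_link_posterior <- function(x, ...) {
  cat(sprintf("<stn_link_posterior> %d candidate links, M = %d retained samples\n",
              nrow(x$candidates), x$config$M))
  invisible(x)
}

#' Rank candidate links by posterior frequency
#'
#' Descending presence frequency; ties are broken by the add-direction
#' marginal gain at the posterior-mode graph (when `wtds` and `sample` are
#' supplied), then lexicographically.
#'
#' @param posterior an `stn_link_posterior`.
#' @param wtds,sample optional; enable the marginal-gain tie-break.
#' @return data.frame with columns `u`, `v`, `score`, ordered by rank.
#' @export
rank_links <- function(posterior, wtds = NULL, sample = NULL) {
  cand <- posterior$candidates
  f <- posterior$freq
  tie <- numeric(nrow(cand))
  if (!is.null(wtds) && !is.null(sample) && anyDuplicated(f)) {
    mode_graph <- posterior_mode_graph(posterior)
    dup <- f %in% f[duplicated(f)]
    for (i in which(dup)) {
      g <- if (graph_has_edge(mode_graph, cand[i, 1], cand[i, 2]))
        graph_remove(mode_graph, cand[i, 1], cand[i, 2]) else mode_graph
      tie[i] <- add_gain(g, wtds, sample, cand[i, 1], cand[i, 2])
    }
    tie[!is.finite(tie)] <- sign(tie[!is.finite(tie)]) * .Machine$double.xmax
  }
  o <- order(-f, -tie, cand[, 1], cand[, 2])
  data.frame(u = cand[o, 1], v = cand[o, 2], score = f[o])
}

#' Posterior-mode graph (majority vote over retained samples)
#'
#' @param posterior an `stn_link_posterior`.
#' @param threshold presence-frequency cut (default 0.5).
#' @return an `stn_graph` with the links whose frequency exceeds the cut.
#' @export
posterior_mode_graph <- function(posterior, threshold = 0.5) {
  keep <- posterior$freq > threshold
  new_graph(posterior$n, posterior$candidates[keep, , drop = FALSE])
}
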