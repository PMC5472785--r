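#' Waiting-time estimator configuration
#'
#' @param h smoothing-kernel bandwidth applied to the branch-atom component
#'   of the self-consistent update.
#' @param kernel `"gaussian"` or `"dirac"` (no smoothing; exact atoms).
#' @param eps convergence threshold on the Kolmogorov-Smirnov divergence
#'   between successive iterates.
#' @param max_iter iteration cap; hitting it flags non-convergence.
#' @param pooling `"shared"` (one density pooled over all links, the
#'   homogeneous population assumption) or `"per-link"`.
#' @param first_guess optional `stn_wtd`, or `list(family=, params=)` for
#'   [wtd_parametric()]; default is an exponential with mean equal to the
#'   mean observed time difference of arrival.
#' @param nbins number of grid bins.
#' @param tau_max grid upper end; default 1.5 x the largest eligible TDOA.
#' @return an object of class `stn_estimator_config`.
#' @export
estimator_config <- function(h = 0.05, kernel = c("gaussian", "dirac"),
                             eps = 1e-3, max_iter = 100,
                             pooling = c("shared", "per-link"),
                             first_guess = NULL, nbins = 200,
                             tau_max = NULL) {
  stopifnot(h >= 0, eps > 0, max_iter >= 1)
  structure(list(h = h, kernel = match.arg(kernel), eps = eps,
                 max_iter = as.integer(max_iter),
                 pooling = match.arg(pooling), first_guess = first_guess,
                 nbins = as.integer(nbins), tau_max = tau_max),
            class = "stn_estimator_config")
}

# flat table of eligible (link, cascade) observations for a fixed graph:
# one row per graph link (u,v) and cascade with t_u < t_v.
eligible_pairs <- function(sample, graph) {
  e <- graph$edges
  tmat <- vapply(sample$cascades, `[[`, numeric(sample$n), "t")
  tu <- tmat[e[, 1], , drop = FALSE]
  tv <- tmat[e[, 2], , drop = FALSE]
  el <- which(!is.na(tu) & !is.na(tv) & tu < tv)   # column-major (link, c)
  if (length(el) == 0) return(NULL)
  link <- (el - 1L) %% nrow(e) + 1L
  data.frame(link = link, c = (el - 1L) %/% nrow(e) + 1L,
             v = e[link, 2], d = tv[el] - tu[el])
}

# branching coefficients for all eligible pairs from the current densities;
# wtds: stn_wtd (shared) or named list keyed "u->v".
pairs_beta <- function(pairs, graph, wtds, n) {
  if (inherits(wtds, "stn_wtd")) {
    lam <- wtd_hazard(wtds, pairs$d)
  } else {
    keys <- paste0(graph$edges[pairs$link, 1], "->",
                   graph$edges[pairs$link, 2])
    lam <- numeric(nrow(pairs))
    for (k in unique(keys)) {
      i <- keys == k
      lam[i] <- wtd_hazard(wtds[[k]], pairs$d[i])
    }
  }
  gid <- (pairs$c - 1) * n + pairs$v
  A <- rowsum(lam, gid)
  Aof <- A[match(gid, as.numeric(rownames(A))), 1]
  beta <- ifelse(Aof > 0, lam / pmax(Aof, .stn_s_floor), NA)
  if (anyNA(beta)) {
    cnt <- rowsum(rep(1, length(gid)), gid)
    beta[is.na(beta)] <- 1 / cnt[match(gid, as.numeric(rownames(cnt))), 1][is.na(beta)]
  }
  beta
}

# one redistribute-to-the-right update of a single pooled density from the
# subset of eligible pairs in `pairs`, using the current density `cur` both
# for the branching weights (computed by the caller) and the chord term.
update_one_density <- function(pairs, beta, cur, h, kernel) {
  nb <- wtd_nbins(cur)
  dx <- wtd_dx(cur)
  b <- wtd_bin(cur, pairs$d)
  s_edges <- wtd_surv_edges(cur)

  # branch component: mass beta at the observed TDOA, kernel-smoothed
  branch <- numeric(nb)
  in_grid <- b <= nb
  if (any(in_grid)) {
    agg <- rowsum(beta[in_grid], b[in_grid])
    branch[as.integer(rownames(agg))] <- agg[, 1]
  }
  branch_tail <- sum(beta[!in_grid])
  branch <- smooth_mass(branch, dx, h, kernel)

  # chord component: (1 - beta) x current density truncated to (d, Inf) and
  # renormalised by S(d); cumulative weights make this O(n + nb).
  # S(d) below the floor means the current density has no mass beyond d:
  # that censored mass goes to the tail atom.
  sd <- s_edges[b]
  w <- (1 - beta) / pmax(sd, .stn_s_floor)
  starved <- sd <= .stn_s_floor
  chord_tail_extra <- sum((1 - beta)[starved & in_grid])
  w[starved] <- 0
  chord <- numeric(nb)
  chord_tail <- chord_tail_extra
  if (any(in_grid)) {
    W <- numeric(nb)
    agg <- rowsum(w[in_grid], b[in_grid])
    W[as.integer(rownames(agg))] <- agg[, 1]
    cumW <- cumsum(W)
    chord <- cur$dens * dx * cumW
    chord_tail <- chord_tail + cur$tail * cumW[nb]
  }
  # a TDOA beyond the grid censors entirely into the tail atom
  chord_tail <- chord_tail + sum(1 - beta[!in_grid])

  mass <- branch + chord
  wtd_from_mass(mass, cur$breaks, tail = branch_tail + chord_tail, h = h)
}

#' One self-consistent redistribute-to-the-right update of the densities
#'
#' For every eligible link/cascade pair (`t_u < t_v`), the unit observation
#' mass is split by the branching coefficient `beta_uv` computed from the
#' *current* densities: a branch atom `beta_uv` placed at the TDOA `d_uv`
#' (then convolved with the smoothing kernel), plus a chord contribution
#' `1 - beta_uv` distributed as the current density truncated to
#' `(d_uv, Inf)` and renormalised by `S(d_uv)` (the redistribute-to-the-right
#' imputation of the right-censored waiting time).  The result is normalised
#' to unit mass.  On a tree (every `beta = 1`) the update is exactly the
#' kernel density estimate of the observed TDOAs, independent of the input.
#'
#' @param wtds current `stn_wtd` (shared) or named list keyed `"u->v"`.
#' @param graph the fixed `stn_graph`.
#' @param sample an `stn_cascade_sample`.
#' @param config an [estimator_config()] (kernel, bandwidth, pooling).
#' @return updated densities, same shape as `wtds`.
#' @export
redistribute_update <- function(wtds, graph, sample,
                                config = estimator_config()) {
  pairs <- eligible_pairs(sample, graph)
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no eligible link/cascade pair; nothing to estimate from")
  beta <- pairs_beta(pairs, graph, wtds, sample$n)
  if (inherits(wtds, "stn_wtd")) {
    update_one_density(pairs, beta, wtds, config$h, config$kernel)
  } else {
    keys <- paste0(graph$edges[pairs$link, 1], "->",
                   graph$edges[pairs$link, 2])
    out <- wtds
    for (k in unique(keys)) {
      i <- keys == k
      out[[k]] <- update_one_density(pairs[i, , drop = FALSE], beta[i],
                                     wtds[[k]], config$h, config$kernel)
    }
    out
  }
}

first_guess_density <- function(config, pairs, breaks) {
  fg <- config$first_guess
  nb <- length(breaks) - 1
  if (inherits(fg, "stn_wtd")) {
    if (length(fg$breaks) != nb + 1 || max(abs(fg$breaks - breaks)) > 1e-9)
      stop("first_guess density must live on the estimation grid")
    return(fg)
  }
  if (is.list(fg))
    return(wtd_parametric(fg$family, fg$params %||% list(),
                          tau_max = breaks[nb + 1], nbins = nb))
  wtd_parametric("exponential", list(mean = mean(pairs$d)),
                 tau_max = breaks[nb + 1], nbins = nb)
}

#' Self-consistent estimation of waiting-time densities
#'
#' Iterates [redistribute_update()] from the first-guess density until the
#' Kolmogorov-Smirnov divergence between successive iterates falls below
#' `eps` (synchronous updates: branching weights and chord terms in one
#' sweep all come from the previous iterate), or the iteration cap is hit
#' (flagged, not an error).
#'
#' @inheritParams redistribute_update
#' @return an object of class `stn_wtd_fit`: list with `wtds` (shared
#'   `stn_wtd` or per-link named list), `trace` (per-iteration KS
#'   divergences), `converged`, `n_iter`, `breaks`.
#' @export
estimate_wtds <- function(sample, graph, config = estimator_config()) {
  pairs <- eligible_pairs(sample, graph)
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no eligible link/cascade pair; nothing to estimate from")
  tau_max <- config$tau_max %||% (1.5 * max(pairs$d))
  breaks <- seq(0, tau_max, length.out = config$nbins + 1)
  guess <- first_guess_density(config, pairs, breaks)
  cur <- if (config$pooling == "shared") {
    guess
  } else {
    keys <- paste0(graph$edges[, 1], "->", graph$edges[, 2])
    stats::setNames(rep(list(guess), nrow(graph$edges)), keys)
  }
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    nxt <- redistribute_update(cur, graph, sample, config)
    ks <- if (inherits(nxt, "stn_wtd")) {
      ks_divergence(nxt, cur)
    } else {
      max(vapply(names(nxt), function(k) ks_divergence(nxt[[k]], cur[[k]]), 0))
    }
    trace <- c(trace, ks)
    cur <- nxt
    if (ks < config$eps) { converged <- TRUE; break }
  }
  structure(list(wtds = cur, trace = trace, converged = converged,
                 n_iter = length(trace), breaks = breaks, config = config),
            class = "stn_wtd_fit")
}

#' @export
print.stn_wtd_fit <- function(x, ...) {
  cat(sprintf("<stn_wtd_fit> %s density, %d iterations, %sconverged (last KS = %.2e)\n",
              if (inherits(x$wtds, "stn_wtd")) "shared" else "per-link",
              x$n_iter, if (x$converged) "" else "NOT ",
              x$trace[length(x$trace)]))
  invisible(x)
}

#' Parametric bootstrap confidence bands for an estimated density
#'
#' Simulates `B` cascade samples from the fitted model `(graph, wtds)`,
#' keeping the observed sources fixed (the design is part of the data),
#' re-runs the estimator on each, and returns per-bin percentile bands at
#' the given level.  `level = 0` degenerates to the point estimate.
#' Shared-density mode only.
#'
#' @param sample the observed `stn_cascade_sample` (sets C).
#' @param graph the inferred/true `stn_graph`.
#' @param wtds the fitted shared `stn_wtd`.
#' @param B number of bootstrap replicates (>= 2).
#' @param level band level in `[0, 1)` (e.g. 0.9).
#' @param config an [estimator_config()]; the grid is pinned to `wtds`.
#' @param seed optional integer seed.
#' @return an object of class `stn_band`: list with `breaks`, `lower`,
#'   `upper`, `point` (per-bin density values), `level`, `B`.
#' @export
bootstrap_bands <- function(sample, graph, wtds, B, level = 0.9,
                            config = estimator_config(), seed = NULL) {
  if (!inherits(wtds, "stn_wtd"))
    stop("bootstrap_bands supports the shared-density mode")
  if (B < 2) stop("need at least 2 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  nb <- wtd_nbins(wtds)
  config$nbins <- nb
  config$tau_max <- wtds$breaks[nb + 1]
  config$pooling <- "shared"
  if (level <= 0) {
    return(structure(list(breaks = wtds$breaks, lower = wtds$dens,
                          upper = wtds$dens, point = wtds$dens,
                          level = 0, B = B),
                     class = "stn_band"))
  }
  model <- new_stn(graph, wtds)
  sources <- vapply(sample$cascades, `[[`, 0L, "source")
  dens <- matrix(NA_real_, nrow = B, ncol = nb)
  for (b in seq_len(B)) {
    sb <- generate_cascade_sample(model, length(sample), sources = sources)
    fit <- estimate_wtds(sb, graph, config)
    dens[b, ] <- fit$wtds$dens
  }
  alpha <- (1 - level) / 2
  structure(list(breaks = wtds$breaks,
                 lower = apply(dens, 2, quantile, probs = alpha),
                 upper = apply(dens, 2, quantile, probs = 1 - alpha),
                 point = wtds$dens, level = level, B = B),
            class = "stn_band")
}
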