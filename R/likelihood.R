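#' Log-likelihood of one cascade under a graph and waiting-time densities
#'
#' Competing-risks form: a link `(u, v)` of the graph is *eligible* in a
#' cascade iff `t_u < t_v` (exact ties are non-informative and excluded).
#' Each informed non-source node `v` contributes
#' `log sum_u lambda_uv(d_uv) + sum_u log S_uv(d_uv)` over its eligible
#' in-neighbours, where `d_uv = t_v - t_u` is the time difference of arrival:
#' the hazard sum is the superposed rate at which some neighbour first
#' informs `v` at exactly `t_v`, and every eligible link also survives
#' (does not fire) before `t_v`.  A non-source node with no eligible
#' in-neighbour makes the cascade impossible: the function returns `-Inf`.
#'
#' @param graph an `stn_graph`.
#' @param wtds an `stn_wtd` (shared for all links), a named list keyed
#'   `"u->v"`, or an `stn_model`.
#' @param cascade an `stn_cascade`.
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
cascade_loglik <- function(graph, wtds, cascade) {
  inn <- in_neighbors(graph)
  t <- cascade$t
  ll <- 0
  for (v in seq_len(graph$n)) {
    if (v == cascade$source || is.na(t[v])) next
    par <- inn[[v]]
    par <- par[!is.na(t[par]) & t[par] < t[v]]
    if (length(par) == 0) return(-Inf)
    d <- t[v] - t[par]
    lam <- vapply(seq_along(par), function(i)
      wtd_hazard(resolve_wtd(wtds, par[i], v), d[i]), 0)
    s <- vapply(seq_along(par), function(i)
      wtd_survival(resolve_wtd(wtds, par[i], v), d[i]), 0)
    ll <- ll + log(sum(lam)) + sum(log(pmax(s, .stn_s_floor)))
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

#' Total log-likelihood of a cascade sample
#'
#' Sum of [cascade_loglik()] over the independent cascades; `-Inf`
#' propagates.
#'
#' @inheritParams cascade_loglik
#' @param sample an `stn_cascade_sample`.
#' @return scalar log-likelihood.
#' @export
total_loglik <- function(graph, wtds, sample) {
  tot <- 0
  for (d in sample$cascades) {
    tot <- tot + cascade_loglik(graph, wtds, d)
    if (!is.finite(tot)) return(-Inf)
  }
  tot
}

#' Branching coefficients of a cascade
#'
#' `beta_uv` is the posterior probability that `u` was the first to inform
#' `v`, given the cascade: by the superposition of the independent per-link
#' risk processes it is the hazard share
#' `beta_uv = lambda_uv(d_uv) / sum_w lambda_wv(d_wv)` over `v`'s eligible
#' in-neighbours.  If all hazards at a node vanish the mass is spread
#' uniformly over the eligible parents (with a warning).
#'
#' @inheritParams cascade_loglik
#' @return data.frame with columns `u`, `v`, `d`, `beta`, one row per
#'   eligible link; `sum(beta)` is 1 within each informed non-source `v`.
#' @export
branching_coefficients <- function(graph, wtds, cascade) {
  inn <- in_neighbors(graph)
  t <- cascade$t
  rows <- vector("list", graph$n)
  warned <- FALSE
  for (v in seq_len(graph$n)) {
    if (v == cascade$source || is.na(t[v])) next
    par <- inn[[v]]
    par <- par[!is.na(t[par]) & t[par] < t[v]]
    if (length(par) == 0)
      stop("node ", v, " has no eligible in-neighbour; graph incompatible ",
           "with cascade")
    d <- t[v] - t[par]
    lam <- vapply(seq_along(par), function(i)
      wtd_hazard(resolve_wtd(wtds, par[i], v), d[i]), 0)
    if (sum(lam) == 0) {
      if (!warned) {
        warning("all hazards zero at node ", v,
                "; using uniform branching over eligible parents")
        warned <- TRUE
      }
      beta <- rep(1 / length(par), length(par))
    } else {
      beta <- lam / sum(lam)
    }
    rows[[v]] <- data.frame(u = par, v = v, d = d, beta = beta)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marginal gain of flipping one link
#'
#' The change in [total_loglik()] when link `(u, v)` is added (if absent) or
#' removed (if present).  Computed incrementally: only node `v`'s terms in
#' cascades with `t_u < t_v` are touched, so the cost is `O(C deg(v))`
#' instead of a full likelihood recomputation.  Removing the last eligible
#' parent of `v` in some cascade yields `-Inf`; adding a first parent yields
#' `+Inf`.
#'
#' @inheritParams total_loglik
#' @param u,v link endpoints.
#' @return scalar gain (possibly `+Inf` / `-Inf`).
#' @export
marginal_gain <- function(graph, wtds, sample, u, v) {
  if (graph_has_edge(graph, u, v)) {
    -add_gain(graph_remove(graph, u, v), wtds, sample, u, v)
  } else {
    add_gain(graph, wtds, sample, u, v)
  }
}

# gain of adding absent link (u, v) to `graph`
add_gain <- function(graph, wtds, sample, u, v) {
  inn <- in_neighbors(graph)
  par0 <- inn[[v]]
  w_uv <- resolve_wtd(wtds, u, v)
  gain <- 0
  for (casc in sample$cascades) {
    t <- casc$t
    if (v == casc$source || is.na(t[v]) || is.na(t[u]) || t[u] >= t[v]) next
    d <- t[v] - t[u]
    lam_new <- wtd_hazard(w_uv, d)
    par <- par0[!is.na(t[par0]) & t[par0] < t[v]]
    A <- if (length(par)) sum(vapply(seq_along(par), function(i)
      wtd_hazard(resolve_wtd(wtds, par[i], v), t[v] - t[par[i]]), 0)) else 0
    dl <- if (A <= 0) {
      if (lam_new > 0) Inf else 0
    } else {
      log1p(lam_new / A)
    }
    gain <- gain + dl + log(max(wtd_survival(w_uv, d), .stn_s_floor))
    if (gain == Inf) return(Inf)
  }
  gain
}
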