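#' Benchmark STN specification
#'
#' Describes a synthetic benchmark: a time-aggregated topology family crossed
#' with a waiting-time density family.  Undirected topologies are doubled
#' into two directed links per tie, each resolving to the same density
#' (shared mode) or to densities recycled over links (per-link mode, for
#' heterogeneous small-network experiments).
#'
#' @param topology `"erdos-renyi"`, `"ring-lattice"`, `"scale-free"`, or
#'   `"edges"` (explicit undirected edge list in `edges`).
#' @param n number of nodes.
#' @param degree target mean degree.  For `erdos-renyi` and `scale-free`
#'   this is the undirected mean degree before doubling (`scale-free`
#'   attaches `degree/2` links per new node); for `ring-lattice` it is the
#'   incident directed-link count of the doubled graph (a multiple of 4),
#'   so `n = 8, degree = 4` yields the 16-link double-directed ring.
#' @param wtd a `list(family=, params=)` as for [wtd_parametric()], an
#'   `stn_wtd`, or an unnamed list of either (recycled over links).
#' @param edges explicit undirected edge matrix for `topology = "edges"`.
#' @param nbins,tau_max grid resolution passed to [wtd_parametric()].
#' @param seed integer seed baked into the spec; generation is reproducible.
#' @return an object of class `stn_benchmark_spec`.
#' @export
benchmark_spec <- function(topology = c("erdos-renyi", "ring-lattice",
                                        "scale-free", "edges"),
                           n = 100, degree = 6,
                           wtd = list(family = "gaussian",
                                      params = list(mean = 2, sd = 0.5)),
                           edges = NULL, nbins = 400, tau_max = NULL,
                           seed = 1L) {
  topology <- match.arg(topology)
  structure(list(topology = topology, n = n, degree = degree, wtd = wtd,
                 edges = edges, nbins = nbins, tau_max = tau_max,
                 seed = seed),
            class = "stn_benchmark_spec")
}

as_wtd_spec <- function(x, nbins, tau_max) {
  if (inherits(x, "stn_wtd")) return(x)
  wtd_parametric(x$family, x$params %||% list(), tau_max = tau_max,
                 nbins = nbins)
}

#' Generate a benchmark STN model
#'
#' Draws the time-aggregated topology (resampling up to 100 times until the
#' doubled directed graph is strongly connected), doubles each undirected tie
#' into two directed links, and attaches discretised waiting-time densities.
#'
#' @param spec an [benchmark_spec()].
#' @return an `stn_model` (shared density unless `spec$wtd` is an unnamed
#'   list of several specs).
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "stn_benchmark_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  und <- switch(spec$topology,
    "erdos-renyi" = {
      p <- spec$degree / (n - 1)
      for (try in 1:100) {
        g <- igraph::sample_gnp(n, p)
        if (igraph::is_connected(g)) break
        g <- NULL
      }
      if (is.null(g)) stop("could not draw a connected Erdos-Renyi graph")
      igraph::as_edgelist(g)
    },
    "ring-lattice" = {
      # degree counts incident directed links of the doubled graph (in +
      # out), so each node ties to degree/4 nearest neighbours per side:
      # degree 4 on 8 nodes gives the 16-double-directed-link benchmark
      k <- spec$degree / 4
      if (k != round(k) || k < 1)
        stop("ring-lattice degree must be a positive multiple of 4")
      el <- NULL
      for (j in seq_len(k))
        el <- rbind(el, cbind(seq_len(n), (seq_len(n) + j - 1) %% n + 1))
      el
    },
    "scale-free" = {
      m <- max(1, round(spec$degree / 2))
      g <- igraph::sample_pa(n, m = m, directed = FALSE)
      igraph::as_edgelist(g)
    },
    "edges" = {
      if (is.null(spec$edges)) stop("explicit topology needs `edges`")
      spec$edges
    })
  und <- matrix(as.integer(und), ncol = 2)
  und <- und[und[, 1] != und[, 2], , drop = FALSE]
  dir_edges <- rbind(und, und[, 2:1, drop = FALSE])
  graph <- new_graph(n, dir_edges)
  gg <- igraph::graph_from_edgelist(graph$edges, directed = TRUE)
  if (igraph::vcount(gg) < n)
    gg <- igraph::add_vertices(gg, n - igraph::vcount(gg))
  if (!igraph::is_connected(gg, mode = "strong"))
    stop("benchmark topology is not strongly connected")

  w <- spec$wtd
  per_link <- is.list(w) && is.null(names(w)) && !inherits(w, "stn_wtd")
  if (!per_link) {
    wtds <- as_wtd_spec(w, spec$nbins, spec$tau_max)
  } else {
    base <- lapply(w, as_wtd_spec, nbins = spec$nbins, tau_max = spec$tau_max)
    # all densities must share one grid: rebuild on the widest grid
    tmax <- max(vapply(base, function(b) b$breaks[length(b$breaks)], 0))
    base <- lapply(w, as_wtd_spec, nbins = spec$nbins, tau_max = tmax)
    idx <- rep_len(seq_along(base), nrow(graph$edges))
    wtds <- base[idx]
    names(wtds) <- paste0(graph$edges[, 1], "->", graph$edges[, 2])
  }
  model <- new_stn(graph, wtds)
  model$spec <- spec
  model
}

# one sampled weight per directed link per cascade, as an E x C matrix
sample_link_weights <- function(model, C) {
  E <- nrow(model$graph$edges)
  if (model$shared) {
    matrix(wtd_sample(model$wtds, E * C), nrow = E)
  } else {
    keys <- paste0(model$graph$edges[, 1], "->", model$graph$edges[, 2])
    t(vapply(keys, function(k) wtd_sample(model$wtds[[k]], C), numeric(C)))
  }
}

# single-source shortest paths for all cascades at once: repeated edge
# relaxation (Bellman-Ford) vectorised over the cascade dimension.
arrival_times <- function(edges, W, sources, n) {
  C <- length(sources)
  t <- matrix(Inf, nrow = n, ncol = C)
  t[cbind(sources, seq_len(C))] <- 0
  E <- nrow(edges)
  repeat {
    changed <- FALSE
    for (e in seq_len(E)) {
      cand <- t[edges[e, 1], ] + W[e, ]
      v <- edges[e, 2]
      upd <- cand < t[v, ]
      if (any(upd)) {
        t[v, upd] <- cand[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  t
}

#' Simulate one diffusion cascade on an STN
#'
#' Draws one waiting time per link from its waiting-time density and sets
#' every node's diffusive arrival time to its shortest-path distance from the
#' source under those weights.  This is exactly the first-arrival process of
#' an SI broadcast on the STN: each link's first usable activation after its
#' tail node is informed follows the link's (length-biased) waiting-time law,
#' independently across links.
#'
#' @param model an `stn_model`.
#' @param source source node id.
#' @return an `stn_cascade`.
#' @export
simulate_cascade <- function(model, source) {
  t <- arrival_times(model$graph$edges, sample_link_weights(model, 1),
                     source, model$graph$n)[, 1]
  if (any(!is.finite(t)))
    stop("node(s) unreachable from the source; the model is not connected")
  new_cascade(source, t)
}

#' Simulate a sample of independent cascades
#'
#' Sources are drawn uniformly at random (or given); cascades are mutually
#' independent.
#'
#' @param model an `stn_model`.
#' @param C number of cascades.
#' @param sources optional integer vector of sources (length `C`).
#' @return an `stn_cascade_sample`.
#' @export
generate_cascade_sample <- function(model, C, sources = NULL) {
  stopifnot(C >= 1)
  n <- model$graph$n
  if (is.null(sources)) sources <- sample.int(n, C, replace = TRUE)
  t <- arrival_times(model$graph$edges, sample_link_weights(model, C),
                     sources, n)
  if (any(!is.finite(t)))
    stop("node(s) unreachable from a source; the model is not connected")
  new_cascade_sample(lapply(seq_len(C), function(c)
    new_cascade(sources[c], t[, c])))
}

#' Replay a cascade on a raw temporal event list
#'
#' Temporal breadth-first sweep: events are processed in `(t, input order)`;
#' an event `(u, v, t)` informs `v` at time `t` if `u` was informed at or
#' before `t` and `v` is still ignorant.  Undirected events work in both
#' directions.  Nodes never reached get `NA` arrival (partial cascades are
#' allowed in replay mode).  Arrival times are reported relative to `t0`.
#'
#' @param events an `stn_events`.
#' @param source source node id (informed at absolute time `t0`).
#' @param t0 absolute start time inside the observation window.
#' @return an `stn_cascade` with `NA` for unreached nodes.
#' @export
replay_cascade_on_events <- function(events, source, t0 = 0) {
  if (t0 < events$window[1] || t0 > events$window[2])
    stop("t0 outside the observation window")
  ev <- events$events
  ord <- order(ev$t)            # stable: ties keep input order
  informed <- rep(NA_real_, events$n)
  informed[source] <- t0
  for (i in ord) {
    t <- ev$t[i]
    if (t < t0) next
    u <- ev$u[i]; v <- ev$v[i]
    if (!is.na(informed[u]) && informed[u] <= t && is.na(informed[v]))
      informed[v] <- t
    if (!events$directed &&
        !is.na(informed[v]) && informed[v] <= t && is.na(informed[u]))
      informed[u] <- t
  }
  new_cascade(source, informed - t0)
}

#' Synthesise a temporal event list from an STN model
#'
#' Generates, for each link independently, a renewal event sequence on
#' `[0, T_w]` whose inter-event times are drawn from the link's IET density.
#' Used to check that replay on synthesised events matches direct cascade
#' simulation in distribution.
#'
#' @param model an `stn_model` whose densities are interpreted as IET laws.
#' @param T_w window length.
#' @param equilibrium start each sequence at a stationary (length-biased)
#'   first event so that replay from any `t0` sees equilibrium waits.
#' @return an `stn_events` (directed).
#' @export
synthesize_events <- function(model, T_w, equilibrium = TRUE) {
  edges <- model$graph$edges
  rows <- list()
  for (e in seq_len(nrow(edges))) {
    w <- resolve_wtd(model, edges[e, 1], edges[e, 2])
    iet <- new_iet(w$breaks, w$dens / (1 - w$tail))
    t <- if (equilibrium)
      wtd_sample(length_biased_wtd(iet), 1) else wtd_sample(w, 1)
    ts <- numeric(0)
    while (t <= T_w) {
      ts <- c(ts, t)
      t <- t + wtd_sample(w, 1)
    }
    if (length(ts))
      rows[[length(rows) + 1]] <-
        data.frame(t = ts, u = edges[e, 1], v = edges[e, 2])
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$t), ]
  rownames(ev) <- NULL
  new_events(ev, window = c(0, T_w), directed = TRUE)
}
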