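#' Temporal event list
#'
#' Raw temporal network: instantaneous directed (or undirected) contact events
#' `(u, v, t)` inside an observation window `[0, T_w]`.
#'
#' @param events data.frame with columns `t`, `u`, `v` (times numeric, node
#'   ids dense positive integers).
#' @param window observation window `c(0, T_w)`; defaults to `c(0, max(t))`.
#' @param directed logical; undirected events are interpreted as usable in
#'   both directions during replay/projection.
#' @return an object of class `stn_events`.
#' @export
new_events <- function(events, window = NULL, directed = FALSE) {
  stopifnot(is.data.frame(events), all(c("t", "u", "v") %in% names(events)))
  if (any(!is.finite(events$t)) || any(events$t < 0))
    stop("event times must be finite and >= 0")
  if (any(events$u < 1) || any(events$v < 1) ||
      any(events$u != round(events$u)) || any(events$v != round(events$v)))
    stop("node ids must be positive integers")
  if (is.null(window)) window <- c(0, max(events$t, 0))
  if (any(events$t > window[2])) stop("event times exceed the window")
  structure(list(events = events[, c("t", "u", "v")],
                 window = window, directed = directed,
                 n = max(events$u, events$v)),
            class = "stn_events")
}

#' Time-aggregated directed graph
#'
#' @param n number of nodes (ids `1..n`).
#' @param edges two-column integer matrix of directed links `(u, v)`; no
#'   self-loops, duplicates dropped.
#' @return an object of class `stn_graph`.
#' @export
new_graph <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1) || any(edges > n)) stop("edge endpoints out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(n = as.integer(n), edges = edges), class = "stn_graph")
}

#' @export
print.stn_graph <- function(x, ...) {
  cat(sprintf("<stn_graph> %d nodes, %d directed links\n", x$n, nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(g_or_edges, n) {
  e <- if (inherits(g_or_edges, "stn_graph")) g_or_edges$edges else g_or_edges
  (e[, 1] - 1) * n + e[, 2]
}

#' Test, add, or remove a single directed link
#' @param g an `stn_graph`.
#' @param u,v link endpoints.
#' @return `graph_has_edge` returns a logical; `graph_add` / `graph_remove`
#'   return the modified graph.
#' @export
graph_has_edge <- function(g, u, v) {
  any(g$edges[, 1] == u & g$edges[, 2] == v)
}

#' @rdname graph_has_edge
#' @export
graph_add <- function(g, u, v) new_graph(g$n, rbind(g$edges, c(u, v)))

#' @rdname graph_has_edge
#' @export
graph_remove <- function(g, u, v) {
  keep <- !(g$edges[, 1] == u & g$edges[, 2] == v)
  new_graph(g$n, g$edges[keep, , drop = FALSE])
}

# list of in-neighbour integer vectors, indexed by node
in_neighbors <- function(g) {
  out <- vector("list", g$n)
  for (i in seq_len(nrow(g$edges)))
    out[[g$edges[i, 2]]] <- c(out[[g$edges[i, 2]]], g$edges[i, 1])
  out
}

#' Stochastic temporal network model
#'
#' The tuple to be inferred: a time-aggregated graph plus waiting-time
#' densities, either one shared density for every link (the homogeneous
#' population assumption) or a per-link named list keyed `"u->v"`.
#'
#' @param graph an `stn_graph`.
#' @param wtds an `stn_wtd` (shared mode) or named list of `stn_wtd` with one
#'   entry per link.
#' @return an object of class `stn_model`.
#' @export
new_stn <- function(graph, wtds) {
  shared <- inherits(wtds, "stn_wtd")
  if (!shared) {
    need <- paste0(graph$edges[, 1], "->", graph$edges[, 2])
    if (!all(need %in% names(wtds)))
      stop("every link needs a resolvable density; missing: ",
           paste(head(setdiff(need, names(wtds)), 3), collapse = ", "))
  }
  structure(list(graph = graph, wtds = wtds, shared = shared),
            class = "stn_model")
}

#' @export
print.stn_model <- function(x, ...) {
  cat(sprintf("<stn_model> %d nodes, %d links, %s waiting-time density\n",
              x$graph$n, nrow(x$graph$edges),
              if (x$shared) "shared" else "per-link"))
  invisible(x)
}

#' Resolve the waiting-time density of one link
#' @param model an `stn_model`, an `stn_wtd` (treated as shared), or a named
#'   list of densities.
#' @param u,v link endpoints.
#' @return an `stn_wtd`.
#' @export
resolve_wtd <- function(model, u, v) {
  if (inherits(model, "stn_model")) {
    if (model$shared) return(model$wtds)
    return(model$wtds[[paste0(u, "->", v)]])
  }
  if (inherits(model, "stn_wtd")) return(model)
  model[[paste0(u, "->", v)]]
}

#' Diffusion cascade
#'
#' One observation: the source node and the diffusive arrival time of every
#' node (`t[source] = 0`).  `NA` arrival marks a node never reached (only
#' produced by window-truncated replay).
#'
#' @param source source node id.
#' @param t numeric arrival-time vector over the node universe.
#' @return an object of class `stn_cascade`.
#' @export
new_cascade <- function(source, t) {
  if (is.na(t[source]) || abs(t[source]) > 1e-12)
    stop("arrival time of the source must be 0")
  if (any(t < 0, na.rm = TRUE)) stop("arrival times must be >= 0")
  structure(list(source = as.integer(source), t = as.numeric(t)),
            class = "stn_cascade")
}

#' Sample of independent cascades over a common node universe
#' @param cascades list of `stn_cascade`.
#' @return an object of class `stn_cascade_sample`; `length()` gives C.
#' @export
new_cascade_sample <- function(cascades) {
  if (length(cascades) < 1) stop("need at least one cascade")
  n <- length(cascades[[1]]$t)
  for (d in cascades)
    if (length(d$t) != n) stop("cascades reference different node universes")
  structure(list(cascades = cascades, n = n), class = "stn_cascade_sample")
}

#' @export
length.stn_cascade_sample <- function(x) length(x$cascades)

#' @export
print.stn_cascade_sample <- function(x, ...) {
  cat(sprintf("<stn_cascade_sample> C = %d cascades on %d nodes\n",
              length(x), x$n))
  invisible(x)
}

#' Fit an STN model to a raw temporal event list
#'
#' Projects the events onto time-aggregated links, extracts each link's
#' inter-event times (gaps between successive activations), fits a
#' kernel-smoothed histogram IET density per link, and converts it to the
#' link's waiting-time density by the length-biased transform
#' ([length_biased_wtd()]).  Links with fewer than two events have no IET
#' sample; with `pool = TRUE` they fall back to the density pooled over all
#' links, otherwise fitting fails.
#'
#' @param events an `stn_events`.
#' @param h kernel bandwidth for the IET histogram smoothing.
#' @param nbins number of grid bins.
#' @param tau_max grid upper end; default 1.5 x the largest observed IET.
#' @param pool fall back to the pooled IET density for data-poor links.
#' @return an `stn_model` in per-link mode.
#' @export
fit_stn_from_events <- function(events, h = 0.05, nbins = 200,
                                tau_max = NULL, pool = TRUE) {
  ev <- events$events
  if (!events$directed) {
    sw <- ev$u > ev$v
    ev[sw, c("u", "v")] <- ev[sw, c("v", "u")]
  }
  key <- paste0(ev$u, "->", ev$v)
  by_link <- split(ev$t, key)
  iets <- lapply(by_link, function(ts) diff(sort(ts)))
  all_iets <- unlist(iets, use.names = FALSE)
  if (length(all_iets) < 1)
    stop("no link carries two events; cannot form an IET sample")
  if (is.null(tau_max)) tau_max <- 1.5 * max(all_iets)
  breaks <- seq(0, tau_max, length.out = nbins + 1)
  dx <- breaks[2] - breaks[1]

  fit_one <- function(x) {
    b <- pmin(floor(x / dx + 1e-9) + 1L, nbins)
    mass <- numeric(nbins)
    tab <- table(b)
    mass[as.integer(names(tab))] <- as.integer(tab)
    mass <- smooth_mass(mass, dx, h)
    new_iet(breaks, mass / sum(mass) / dx)
  }
  pooled <- fit_one(all_iets)

  links <- do.call(rbind, strsplit(names(by_link), "->", fixed = TRUE))
  links <- matrix(as.integer(links), ncol = 2)
  wtds <- vector("list", length(by_link))
  for (i in seq_along(by_link)) {
    if (length(iets[[i]]) >= 1) {
      wtds[[i]] <- length_biased_wtd(fit_one(iets[[i]]))
    } else if (pool) {
      wtds[[i]] <- length_biased_wtd(pooled)
    } else {
      stop("link ", names(by_link)[i],
           " has no IET sample and pooling is disabled")
    }
  }
  names(wtds) <- names(by_link)
  if (!events$directed) {
    rev_links <- links[, 2:1, drop = FALSE]
    rev_names <- paste0(rev_links[, 1], "->", rev_links[, 2])
    rev_wtds <- wtds
    names(rev_wtds) <- rev_names
    wtds <- c(wtds, rev_wtds)
    links <- rbind(links, rev_links)
  }
  new_stn(new_graph(events$n, links), wtds)
}
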