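#' Precision-recall and ROC curves of a link posterior against the truth
#'
#' Candidate links are ranked by posterior frequency and swept over score
#' thresholds; areas are trapezoidal.  By default the negative class is the
#' candidate non-links only: pairs that are never ordered in any cascade are
#' structurally undecidable and would inflate the ROC area
#' (`negatives = "all-pairs"` restores the all-`n(n-1)`-pairs convention).
#' True links missing from the candidate set count as positives that are
#' never retrieved.
#'
#' @param posterior an `stn_link_posterior`.
#' @param truth the true `stn_graph` (same node universe).
#' @param negatives `"candidates"` or `"all-pairs"`.
#' @return list with `roc` (data.frame `fpr`, `tpr`), `pr` (data.frame
#'   `recall`, `precision`), `auroc`, `aupr`.
#' @export
pr_roc <- function(posterior, truth, negatives = c("candidates", "all-pairs")) {
  negatives <- match.arg(negatives)
  n <- posterior$n
  P <- nrow(truth$edges)
  if (P == 0) stop("truth graph has no links")
  cand_keys <- edge_keys(posterior$candidates, n)
  true_keys <- edge_keys(truth, n)
  scores <- posterior$freq
  labels <- cand_keys %in% true_keys
  missed <- setdiff(true_keys, cand_keys)
  if (length(missed)) {
    scores <- c(scores, rep(-Inf, length(missed)))
    labels <- c(labels, rep(TRUE, length(missed)))
  }
  Nn <- if (negatives == "candidates") sum(!labels) else n * (n - 1) - P
  o <- order(-scores)
  scores <- scores[o]; labels <- labels[o]
  grp <- cumsum(!duplicated(scores))        # threshold groups (ties pooled)
  tp <- cumsum(labels); fp <- cumsum(!labels)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / Nn)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  rec <- tp / P
  prec <- tp / (tp + fp)
  rec2 <- c(0, rec); prec2 <- c(prec[1], prec)
  aupr <- sum(diff(rec2) * (head(prec2, -1) + prec2[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = rec2, precision = prec2),
       auroc = auroc, aupr = aupr)
}

#' Break-even point of a link ranking
#'
#' Takes the top-`L` ranked candidate links, `L` being the number of true
#' links, and returns the precision at that cut — which there equals the
#' recall, i.e. the operating point where false positives balance false
#' negatives (the intersection of the PR curve with the unit-square
#' diagonal).
#'
#' @inheritParams pr_roc
#' @return scalar precision; attribute `truncated` flags the case of fewer
#'   candidates than `L`.
#' @export
break_even_point <- function(posterior, truth) {
  L <- nrow(truth$edges)
  if (L == 0) stop("truth graph has no links")
  rk <- rank_links(posterior)
  take <- min(L, nrow(rk))
  top <- rk[seq_len(take), , drop = FALSE]
  hits <- edge_keys(as.matrix(top[, c("u", "v")]), posterior$n) %in%
    edge_keys(truth, posterior$n)
  bep <- sum(hits) / L
  attr(bep, "truncated") <- take < L
  bep
}

#' Inferential complexity of a cascade (spreading-tree entropy)
#'
#' The entropy, in nats, of the posterior distribution over diffusion trees
#' compatible with the cascade.  Under dyadic independence the tree
#' posterior factorises over per-node parent choices with the branching
#' coefficients as weights, so
#' `H = sum_v H(beta_.v) = -sum_v sum_u beta_uv log beta_uv`
#' over informed non-source nodes.  `H = 0` iff the cascade is
#' tree-compatible (one eligible parent everywhere); a node with `k`
#' equally weighted parents contributes `log k`.
#'
#' @param model an `stn_model` (or pass `graph`/`wtds` via ...).
#' @param cascade an `stn_cascade` with finite likelihood on the model.
#' @return scalar entropy in nats.
#' @export
inferential_complexity <- function(model, cascade) {
  bc <- branching_coefficients(model$graph, model, cascade)
  plogp <- ifelse(bc$beta > 0, bc$beta * log(bc$beta), 0)
  -sum(plogp)
}

#' Mean relative inferential complexity of a cascade sample
#'
#' Average over cascades of `H / (n - 1)` — the tree entropy normalised per
#' non-source node.
#'
#' @param model an `stn_model`.
#' @param sample an `stn_cascade_sample`.
#' @return scalar.
#' @export
mean_relative_complexity <- function(model, sample) {
  h <- vapply(sample$cascades, function(d)
    inferential_complexity(model, d), 0)
  mean(h) / (model$graph$n - 1)
}

#' Critical sample size of a benchmark for a target accuracy
#'
#' For each sample size `C` in the grid (ascending), regenerates the
#' benchmark, simulates `C` cascades, runs Gibbs topology inference with the
#' true shared density supplied, and records the chosen metric; returns the
#' smallest `C` whose replicate-mean metric reaches the threshold.  An
#' exhausted grid returns `Inf` with attribute `flagged = TRUE`.
#'
#' @param spec a [benchmark_spec()].
#' @param metric `"auroc"`, `"aupr"`, or `"bep"`.
#' @param threshold target value in `(0, 1]`.
#' @param C_grid ascending integer vector of sample sizes.
#' @param replicates independent realisations per grid point.
#' @param sampler a [sampler_config()].
#' @param seed integer seed for the scan.
#' @return smallest adequate `C` (or `Inf`); attribute `means` holds the
#'   replicate-mean metric per evaluated grid point.
#' @export
critical_sample_size <- function(spec, metric = c("auroc", "aupr", "bep"),
                                 threshold = 0.95, C_grid,
                                 replicates = 3,
                                 sampler = sampler_config(), seed = 1) {
  metric <- match.arg(metric)
  if (length(C_grid) == 0) stop("empty sample-size grid")
  stopifnot(threshold >= 0)   # > 1 allowed: unattainable, flagged Inf
  C_grid <- sort(unique(as.integer(C_grid)))
  means <- numeric(0)
  for (C in C_grid) {
    vals <- vapply(seq_len(replicates), function(r) {
      s <- seed + 1000L * r + C
      sp <- spec; sp$seed <- s
      model <- generate_benchmark(sp)
      set.seed(s + 1L)
      samp <- generate_cascade_sample(model, C)
      cfg <- sampler; cfg$seed <- s + 2L
      post <- gibbs_sample(samp, model$wtds, cfg)
      switch(metric,
             auroc = pr_roc(post, model$graph)$auroc,
             aupr = pr_roc(post, model$graph)$aupr,
             bep = as.numeric(break_even_point(post, model$graph)))
    }, 0)
    means <- c(means, mean(vals))
    names(means)[length(means)] <- as.character(C)
    if (mean(vals) >= threshold) {
      out <- C
      attr(out, "means") <- means
      attr(out, "flagged") <- FALSE
      return(out)
    }
  }
  out <- Inf
  attr(out, "means") <- means
  attr(out, "flagged") <- TRUE
  out
}
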