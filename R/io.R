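#' Read a temporal contact list
#'
#' Whitespace/tab-separated rows `t u v` (SocioPatterns-style), optional
#' header.  Arbitrary string node ids are mapped to dense internal integers
#' `1..n`; the mapping is attached as attribute `id_map` (data.frame
#' `id`, `internal`) and used by [write_contacts()] to restore labels.
#'
#' @param path input file.
#' @param directed logical passed to [new_events()].
#' @return an `stn_events`.
#' @export
read_contacts <- function(path, directed = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty contact file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (suppressWarnings(is.na(as.numeric(toks[[1]][1])))) start <- 2L
  if (start > length(lines)) stop("contact file has a header but no rows")
  n_tok <- lengths(toks[start:length(toks)])
  if (any(n_tok != 3))
    stop("malformed row at line ", start - 1L + which(n_tok != 3)[1],
         ": expected 't u v'")
  m <- do.call(rbind, toks[start:length(toks)])
  t <- suppressWarnings(as.numeric(m[, 1]))
  if (any(is.na(t)))
    stop("malformed time at line ", start - 1L + which(is.na(t))[1])
  if (any(t < 0)) stop("negative event times are not allowed")
  ids <- unique(c(rbind(m[, 2], m[, 3])))   # order of first appearance
  u <- match(m[, 2], ids)
  v <- match(m[, 3], ids)
  ev <- new_events(data.frame(t = t, u = u, v = v), directed = directed)
  attr(ev, "id_map") <- data.frame(id = ids, internal = seq_along(ids),
                                   stringsAsFactors = FALSE)
  ev
}

#' Write a temporal contact list
#'
#' Inverse of [read_contacts()]: rows `t u v`, tab-separated, original node
#' labels restored from the `id_map` attribute when present.
#'
#' @param events an `stn_events`.
#' @param path output file.
#' @export
write_contacts <- function(events, path) {
  map <- attr(events, "id_map")
  lab <- function(x) if (is.null(map)) as.character(x) else map$id[x]
  lines <- sprintf("%s\t%s\t%s", fmt_num(events$events$t),
                   lab(events$events$u), lab(events$events$v))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cascade sample from CSV
#'
#' Columns `cascade_id,node,arrival_time`.  Each cascade's source is the row
#' with arrival time 0 (exactly one required).  Nodes missing from a cascade
#' get `NA` arrival.
#'
#' @param path input CSV.
#' @param n optional node-universe size (default: largest node id seen).
#' @return an `stn_cascade_sample`.
#' @export
read_cascades <- function(path, n = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cascade_id", "node", "arrival_time")
  if (!all(need %in% names(df)))
    stop("cascade file needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$arrival_time)))
    stop("arrival times must be finite")
  if (any(df$arrival_time < 0)) stop("negative arrival times are not allowed")
  if (is.null(n)) n <- max(df$node)
  cascades <- lapply(split(df, df$cascade_id), function(g) {
    src <- g$node[g$arrival_time == 0]
    if (length(src) == 0) stop("cascade ", g$cascade_id[1], " has no source ",
                               "(no row with arrival time 0)")
    if (length(src) > 1) stop("cascade ", g$cascade_id[1],
                              " has multiple zero-arrival rows")
    t <- rep(NA_real_, n)
    t[g$node] <- g$arrival_time
    new_cascade(src, t)
  })
  new_cascade_sample(unname(cascades))
}

#' Write a cascade sample to CSV
#'
#' @param sample an `stn_cascade_sample`.
#' @param path output CSV.
#' @export
write_cascades <- function(sample, path) {
  rows <- lapply(seq_along(sample$cascades), function(i) {
    d <- sample$cascades[[i]]
    ok <- !is.na(d$t)
    data.frame(cascade_id = i, node = which(ok), arrival_time = d$t[ok])
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("cascade_id,node,arrival_time", con)
  writeLines(sprintf("%d,%d,%s", df$cascade_id, df$node,
                     fmt_num(df$arrival_time)), con)
  invisible(path)
}

#' Write ranked edge scores
#'
#' TSV `u v score`, one row per candidate link in rank order.
#'
#' @param posterior an `stn_link_posterior`.
#' @param path output file.
#' @export
write_edge_scores <- function(posterior, path) {
  rk <- rank_links(posterior)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("u\tv\tscore", con)
  if (nrow(rk))
    writeLines(sprintf("%d\t%d\t%s", rk$u, rk$v, fmt_num(rk$score)), con)
  invisible(path)
}

#' Read an edge list (optionally scored)
#'
#' TSV with columns `u v` or `u v score` and a header.
#'
#' @param path input file.
#' @param n optional node count.
#' @return an `stn_graph`.
#' @export
read_edges <- function(path, n = NULL) {
  df <- utils::read.table(path, header = TRUE)
  if (is.null(n)) n <- max(df[[1]], df[[2]])
  new_graph(n, cbind(df[[1]], df[[2]]))
}

#' Write / read a binned density
#'
#' TSV `bin_left bin_right density` with a `# tail=... h=...` comment line;
#' full `%.17g` precision makes the round trip bit-exact.
#'
#' @param wtd an `stn_wtd`.
#' @param path file path.
#' @return `read_density` returns an `stn_wtd`.
#' @export
write_density <- function(wtd, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tail=%s h=%s", fmt_num(wtd$tail), fmt_num(wtd$h)),
             con)
  writeLines("bin_left\tbin_right\tdensity", con)
  nb <- wtd_nbins(wtd)
  writeLines(sprintf("%s\t%s\t%s", fmt_num(wtd$breaks[-(nb + 1)]),
                     fmt_num(wtd$breaks[-1]), fmt_num(wtd$dens)), con)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  tail_mass <- 0; h <- NA_real_
  if (length(meta)) {
    mt <- regmatches(meta[1], regexec("tail=([^ ]+) h=([^ ]+)", meta[1]))[[1]]
    if (length(mt) == 3) {
      tail_mass <- as.numeric(mt[2])
      h <- suppressWarnings(as.numeric(mt[3]))
    }
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE)
  new_wtd(c(df$bin_left, df$bin_right[nrow(df)]), df$density,
          tail = tail_mass, h = h)
}

# shortest decimal representation that round-trips a double exactly
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  ok <- !is.na(x) & suppressWarnings(as.numeric(short)) == x
  out[ok] <- short[ok]
  out[is.na(x)] <- "NA"
  out
}
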