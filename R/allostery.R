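#' Dynamic cross-correlation matrix of residue motions
#'
#' With displacement `dr_i(t) = r_i(t) - <r_i>`, the normalized covariance
#' is `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` (3-vector dot
#' product, averaged over frames). Frames are assumed pre-superposed (see
#' [rmsd_series()] / [superpose_kabsch()]). Zero-variance nodes get `NA`
#' rows/columns and a warning; graphs exclude them.
#'
#' @param traj trajectory (post-transient, superposed).
#' @param node_rule `"CA"` (one CA per residue) or `"centroid"` (heavy-atom
#'   centroid per residue).
#' @return object of class `correlation_matrix`: `nodes` (data frame chain,
#'   residue) and `C`.
#' @export
correlation_matrix <- function(traj, node_rule = c("CA", "centroid")) {
  node_rule <- match.arg(node_rule)
  top <- traj$topology
  key <- paste(top$chain_id, top$residue_number)
  ukey <- unique(key)
  nodes <- data.frame(
    chain = sub(" .*", "", ukey),
    residue = as.integer(sub(".* ", "", ukey)),
    stringsAsFactors = FALSE)
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames")
  node_xyz <- function(fr) {
    if (node_rule == "CA") {
      ca <- which(top$name == "CA")
      pos <- fr[ca, , drop = FALSE]
      rownames(pos) <- key[ca]
      pos[ukey, , drop = FALSE]
    } else {
      heavy <- top$element != "H"
      t(vapply(ukey, function(k) {
        ii <- which(key == k & heavy)
        colMeans(fr[ii, , drop = FALSE])
      }, numeric(3)))
    }
  }
  n <- length(ukey)
  X <- array(NA_real_, c(nf, n, 3))
  for (t in seq_len(nf)) X[t, , ] <- node_xyz(traj$frames[[t]])
  for (d in 1:3) X[, , d] <- sweep(X[, , d], 2, colMeans(X[, , d]))
  num <- crossprod(X[, , 1]) + crossprod(X[, , 2]) + crossprod(X[, , 3])
  num <- num / nf
  v <- diag(num)
  zero_var <- v <= 0
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance node(s) excluded from correlations")
  denom <- sqrt(outer(v, v))
  C <- num / denom
  C[zero_var, ] <- NA_real_; C[, zero_var] <- NA_real_
  diag(C)[!zero_var] <- 1
  dimnames(C) <- list(ukey, ukey)
  structure(list(nodes = nodes, C = C), class = "correlation_matrix")
}

#' Contact-filtered allosteric communication graph
#'
#' Edge (i, j) is retained iff the minimum heavy-atom distance between
#' residues i and j in the (frame-averaged) structure is at most
#' `contact_cutoff` and `|C_ij| >= 1e-6`; the edge weight is `-log |C_ij|`,
#' so strongly correlated contacts are cheap to traverse.
#'
#' @param C a [correlation_matrix()].
#' @param avg_traj a single-frame trajectory (or any trajectory; frame 1 is
#'   used) supplying the average structure consistent with the nodes.
#' @param contact_cutoff contact distance (Angstroms), default 4.5.
#' @return object of class `allosteric_graph`: `nodes` (character ids
#'   "chain residue"), `edges` (data frame `from`, `to`, `weight`),
#'   `contact_cutoff`.
#' @export
build_graph <- function(C, avg_traj, contact_cutoff = 4.5) {
  stopifnot(inherits(C, "correlation_matrix"))
  top <- avg_traj$topology
  fr <- avg_traj$frames[[1]]
  key <- paste(top$chain_id, top$residue_number)
  ids <- rownames(C$C)
  heavy <- top$element != "H"
  coord_by_node <- lapply(ids, function(k) fr[key == k & heavy, , drop = FALSE])
  n <- length(ids)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(n - 1L)) {
    a <- coord_by_node[[i]]
    for (j in (i + 1L):n) {
      cij <- C$C[i, j]
      if (is.na(cij) || abs(cij) < 1e-6) next
      b <- coord_by_node[[j]]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      if (min(d2) <= contact_cutoff^2) {
        from <- c(from, i); to <- c(to, j)
        w <- c(w, -log(min(abs(cij), 1)))
      }
    }
  }
  structure(list(nodes = ids,
                 edges = data.frame(from = ids[from], to = ids[to],
                                    weight = w, stringsAsFactors = FALSE),
                 contact_cutoff = contact_cutoff),
            class = "allosteric_graph")
}

#' Build an allosteric graph directly from node ids and weighted edges
#' @param nodes character node ids.
#' @param edges data frame `from`, `to`, `weight` (non-negative).
#' @param contact_cutoff bookkeeping value (Angstroms).
#' @return an `allosteric_graph`.
#' @export
allosteric_graph <- function(nodes, edges, contact_cutoff = NA_real_) {
  if (any(edges$weight < 0)) stop("edge weights must be non-negative")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  structure(list(nodes = nodes, edges = edges, contact_cutoff = contact_cutoff),
            class = "allosteric_graph")
}

graph_adjacency <- function(g) {
  adj <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (k in seq_len(nrow(g$edges))) {
    f <- g$edges$from[k]; t <- g$edges$to[k]; w <- g$edges$weight[k]
    adj[[f]] <- rbind(adj[[f]], data.frame(to = t, w = w))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = f, w = w))
  }
  lapply(adj, function(a) if (is.null(a)) data.frame(to = character(0),
                                                     w = numeric(0)) else
    a[order(a$to), , drop = FALSE])
}

graph_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = data.frame(name = g$nodes))
  ig
}

dist_from <- function(g, node) {
  ig <- graph_igraph(g)
  d <- igraph::distances(ig, v = node, weights = igraph::E(ig)$weight)
  stats::setNames(as.numeric(d), colnames(d))
}

#' Minimum-weight allosteric path
#'
#' Dijkstra shortest path between two residues; among equal-weight optima
#' the lexicographically smallest node sequence is returned. An unreachable
#' sink yields a "no path" result (a broken allosteric signal), not an error.
#'
#' @param g an `allosteric_graph`.
#' @param source,sink node ids ("chain residue").
#' @return list with `nodes` (path sequence, `NULL` if none), `weight`
#'   (`Inf` if none), `reachable`.
#' @export
shortest_path <- function(g, source, sink) {
  if (!(source %in% g$nodes) || !(sink %in% g$nodes))
    stop("source/sink not in graph")
  if (source == sink)
    return(list(nodes = source, weight = 0, reachable = TRUE))
  ds <- dist_from(g, source)
  if (!is.finite(ds[[sink]]))
    return(list(nodes = NULL, weight = Inf, reachable = FALSE))
  dt <- dist_from(g, sink)
  opt <- ds[[sink]]
  adj <- graph_adjacency(g)
  # greedy reconstruction: always step to the smallest-id neighbour that
  # stays on an optimal path -> lexicographically smallest optimum
  path <- source; u <- source; du <- 0
  while (u != sink) {
    nb <- adj[[u]]
    ok <- which(abs(du + nb$w + dt[nb$to] - opt) < 1e-9 &
                abs(ds[nb$to] - (du + nb$w)) < 1e-9)
    v <- nb$to[ok][order(nb$to[ok])][1]
    du <- du + nb$w[ok][order(nb$to[ok])][1]
    path <- c(path, v)
    u <- v
  }
  list(nodes = path, weight = opt, reachable = TRUE)
}

#' Bounded-suboptimal allosteric path enumeration
#'
#' Enumerates every simple path from source to sink whose total weight is
#' within `delta` of the optimum, up to `max_paths`, by best-first search
#' with the admissible lower bound `weight so far + Dijkstra distance to the
#' sink`. Paths are returned sorted by weight, ties lexicographically.
#'
#' @param g an `allosteric_graph`.
#' @param source,sink node ids.
#' @param delta suboptimality tolerance (weight units), default 1.0.
#' @param max_paths cap on returned paths, default 50.
#' @return object of class `path_set`: `source`, `sink`, `optimal_weight`,
#'   `paths` (list of `list(nodes, weight)`), `delta`, `node_degeneracy`
#'   (named counts of paths through each node).
#' @export
suboptimal_paths <- function(g, source, sink, delta = 1.0, max_paths = 50L) {
  if (delta < 0) stop("delta must be >= 0")
  sp <- shortest_path(g, source, sink)
  if (!sp$reachable) stop("no path from ", source, " to ", sink)
  opt <- sp$weight
  bound_max <- opt + delta + 1e-12
  dt <- dist_from(g, sink)
  adj <- graph_adjacency(g)
  # frontier of partial simple paths, expanded in lower-bound order
  frontier <- list(list(nodes = source, w = 0, lb = dt[[source]]))
  found <- list()
  while (length(frontier)) {
    lbs <- vapply(frontier, function(p) p$lb, numeric(1))
    k <- which.min(lbs)
    cur <- frontier[[k]]
    frontier[[k]] <- NULL
    if (cur$lb > bound_max) next
    u <- cur$nodes[length(cur$nodes)]
    if (u == sink) {
      found[[length(found) + 1L]] <- list(nodes = cur$nodes, weight = cur$w)
      next
    }
    nb <- adj[[u]]
    for (e in seq_len(nrow(nb))) {
      v <- nb$to[e]
      if (v %in% cur$nodes) next
      w2 <- cur$w + nb$w[e]
      lb2 <- w2 + dt[[v]]
      if (!is.finite(lb2) || lb2 > bound_max) next
      frontier[[length(frontier) + 1L]] <-
        list(nodes = c(cur$nodes, v), w = w2, lb = lb2)
    }
    if (length(found) >= max_paths) break
  }
  ord <- order(vapply(found, function(p) p$weight, numeric(1)),
               vapply(found, function(p) paste(p$nodes, collapse = "\r"),
                      character(1)))
  found <- found[ord]
  if (length(found) > max_paths) found <- found[seq_len(max_paths)]
  degen <- table(unlist(lapply(found, function(p) unique(p$nodes))))
  structure(list(source = source, sink = sink, optimal_weight = opt,
                 paths = found, delta = delta,
                 node_degeneracy = stats::setNames(as.integer(degen),
                                                   names(degen))),
            class = "path_set")
}

#' Export a path set as a table
#' @param ps a `path_set`.
#' @return data frame `rank`, `weight`, `nodes` (semicolon-joined).
#' @export
paths_as_table <- function(ps) {
  data.frame(
    rank = seq_along(ps$paths),
    weight = vapply(ps$paths, function(p) p$weight, numeric(1)),
    nodes = vapply(ps$paths, function(p) paste(p$nodes, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
}
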