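#' Dynamical cross-correlation matrix
#'
#' Computes the normalized covariance of Calpha displacements,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, where `dr_i` is the
#' displacement of position i from its mean over the analysed frames.
#' Values lie in [-1, 1]: +1 for perfectly correlated motion along the same
#' direction, -1 for anticorrelated motion.
#'
#' @param x a superposed [coord_ensemble()] with at least 2 frames.
#' @return a `dccm_matrix`: list with `matrix` (N x N, unit diagonal),
#'   `n_frames`, `segment` (frame-label range). Zero-variance positions get
#'   `NA` rows/columns with a warning and are excluded downstream.
#' @export
dccm <- function(x) {
  f <- n_frames(x)
  if (f < 2L) stop("dccm needs at least 2 frames")
  n <- n_positions(x)
  xc <- sweep(x$xyz, 2L, colMeans(x$xyz))
  m <- crossprod(xc) / f
  xs <- seq(1L, 3L * n, 3L)
  num <- m[xs, xs] + m[xs + 1L, xs + 1L] + m[xs + 2L, xs + 2L]
  msf <- diag(num)
  cc <- num / sqrt(outer(msf, msf))
  frozen <- msf <= 0
  if (any(frozen)) {
    warning(sum(frozen), " zero-variance position(s) marked NA in DCCM")
    cc[frozen, ] <- NA_real_
    cc[, frozen] <- NA_real_
  }
  diag(cc)[!frozen] <- 1
  structure(
    list(matrix = cc, n_frames = f,
         segment = range(if (is.numeric(x$labels)) x$labels else
           seq_len(f))),
    class = "dccm_matrix")
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat(sprintf("<dccm_matrix> %d x %d over %d frames\n",
              nrow(x$matrix), ncol(x$matrix), x$n_frames))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dccm_matrix <- function(x, ...) {
  n <- nrow(x$matrix)
  out <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  out$correlation <- as.vector(t(x$matrix))
  dplyr::filter(out, .data$i < .data$j)
}

# Per-frame N x N minimum distance over each residue's representative atoms
# (Calpha and, when present, the side-chain atom).
residue_min_dist <- function(x, f) {
  ca <- frame_coords(x, f)
  if (is.null(x$cb)) return(as.matrix(dist(ca)))
  cb <- frame_coords(x, f, "cb")
  d <- as.matrix(dist(rbind(ca, cb)))
  n <- nrow(ca)
  pmin(d[1:n, 1:n], d[1:n, n + 1:n], d[n + 1:n, 1:n], d[n + 1:n, n + 1:n])
}

#' Contact adjacency from a trajectory
#'
#' Two residues are adjacent when their closest heavy atoms lie within
#' `cutoff` in at least `occupancy` of the frames (the boundary occupancy is
#' inclusive). Distances use each residue's representative atoms (Calpha and
#' the representative side-chain atom when present). Sequence neighbors
#' `|i - j| <= exclude_neighbors` are excluded, preventing trivial
#' backbone-dominated network paths.
#'
#' @param x a [coord_ensemble()].
#' @param cutoff distance cutoff in Angstrom (default 4.5).
#' @param occupancy minimum fraction of frames in contact (default 0.75).
#' @param exclude_neighbors sequence-neighbor exclusion width (default 1).
#' @return a `contact_adjacency`: list with `matrix` (N x N logical, zero
#'   diagonal), `occupancy_matrix` (fraction of frames in contact), `cutoff`,
#'   `occupancy`.
#' @export
contact_adjacency <- function(x, cutoff = 4.5, occupancy = 0.75,
                              exclude_neighbors = 1L) {
  f <- n_frames(x)
  n <- n_positions(x)
  occ <- matrix(0, n, n)
  for (k in seq_len(f)) occ <- occ + (residue_min_dist(x, k) < cutoff)
  occ <- occ / f
  adj <- occ >= occupancy
  idx <- abs(outer(seq_len(n), seq_len(n), `-`)) <= exclude_neighbors
  adj[idx] <- FALSE
  diag(occ) <- 0
  structure(list(matrix = adj, occupancy_matrix = occ, cutoff = cutoff,
                 occupancy = occupancy),
            class = "contact_adjacency")
}

#' Build a contact-filtered correlation-weighted network
#'
#' Nodes are residues; an edge is drawn for each contact pair and weighted by
#' `w_ij = -log(|C_ij|)`, so strong (anti)correlation gives a short
#' "communication distance". `|C|` is floored at `cap_floor`, capping weights
#' at `w_max = -log(cap_floor)` (~13.8 by default); capped edges are flagged.
#' Community detection later uses `|C|` as edge affinity while path lengths
#' use `w`; the signed correlation is retained for reporting.
#'
#' @param cc a `dccm_matrix` (or plain N x N correlation matrix).
#' @param adjacency a `contact_adjacency` (or N x N logical matrix).
#' @param cap_floor floor applied to `|C|` (default 1e-6).
#' @return a `dynamic_network`: list with `edges` (tibble: i, j,
#'   correlation, abs_c, weight, capped), `graph` (igraph, weight attributes
#'   `w` and `affinity`), `n_nodes`.
#' @export
build_network <- function(cc, adjacency, cap_floor = 1e-6) {
  m <- if (inherits(cc, "dccm_matrix")) cc$matrix else as.matrix(cc)
  adj <- if (inherits(adjacency, "contact_adjacency")) adjacency$matrix else
    as.matrix(adjacency)
  stopifnot(identical(dim(m), dim(adj)))
  n <- nrow(m)
  keep <- which(adj & upper.tri(adj), arr.ind = TRUE)
  corr <- m[keep]
  ok <- !is.na(corr)
  keep <- keep[ok, , drop = FALSE]; corr <- corr[ok]
  edges <- tibble(i = keep[, 1L], j = keep[, 2L], correlation = corr,
                  abs_c = abs(corr),
                  weight = -log(pmax(abs(corr), cap_floor)),
                  capped = abs(corr) < cap_floor)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$i, edges$j),
                           w = edges$weight, affinity = pmax(edges$abs_c,
                                                             cap_floor))
  structure(list(edges = edges, graph = g, n_nodes = n),
            class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(sprintf("<dynamic_network> %d nodes, %d edges\n", x$n_nodes,
              nrow(x$edges)))
  invisible(x)
}

#' Girvan-Newman community detection with split weight conventions
#'
#' Repeatedly removes the edge with the highest weighted edge betweenness
#' (edge weights `w = -log|C|` act as distances), tracking the component
#' partition after every removal and returning the partition of maximum
#' modularity, where modularity is computed on the *original* graph with
#' `|C|` contact affinities as edge strengths. Ties in edge betweenness are
#' broken by lowest edge index for determinism. Disconnected components are
#' handled naturally (they are separate communities from the start).
#'
#' @param net a `dynamic_network`.
#' @return a `community_partition`: list with `membership` (integer vector,
#'   1-based, relabeled in order of first appearance), `modularity`,
#'   `n_communities`.
#' @export
detect_communities <- function(net) {
  g0 <- net$graph
  n <- net$n_nodes
  if (igraph::ecount(g0) == 0L) {
    memb <- seq_len(n)
    return(structure(list(membership = memb, modularity = 0,
                          n_communities = n),
                     class = "community_partition"))
  }
  aff <- igraph::E(g0)$affinity
  best_memb <- igraph::components(g0)$membership
  best_mod <- igraph::modularity(g0, best_memb, weights = aff)
  g <- g0
  while (igraph::ecount(g) > 0L) {
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$w)
    g <- igraph::delete_edges(g, which.max(eb))  # first max: lowest index
    memb <- igraph::components(g)$membership
    mod <- igraph::modularity(g0, memb, weights = aff)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_memb <- memb
    }
  }
  relabel <- match(best_memb, unique(best_memb))
  structure(list(membership = relabel, modularity = best_mod,
                 n_communities = length(unique(relabel))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities (modularity %.3f)\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Weighted betweenness, inter-community junctions and critical nodes
#'
#' Node betweenness counts weighted shortest paths (Dijkstra over
#' `w = -log|C|`) through each node. Critical nodes are nodes incident to
#' inter-community edges whose betweenness exceeds the given quantile among
#' such boundary nodes — the residues occurring in a majority of shortest
#' paths that connect different communities. Junction widths report, per
#' community pair, the summed betweenness of the edges joining them.
#'
#' @param net a `dynamic_network`.
#' @param partition a `community_partition` (or integer membership vector).
#' @param quantile betweenness quantile among boundary nodes above which a
#'   node is called critical (default 0.5, i.e. "majority").
#' @return list with `nodes` (tibble: node, community, betweenness,
#'   boundary, critical), `junctions` (tibble: community_a, community_b,
#'   n_edges, edge_betweenness).
#' @export
betweenness_and_critical_nodes <- function(net, partition, quantile = 0.5) {
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else as.integer(partition)
  g <- net$graph
  btw <- igraph::betweenness(g, weights = igraph::E(g)$w)
  edges <- net$edges
  inter <- memb[edges$i] != memb[edges$j]
  boundary <- sort(unique(c(edges$i[inter], edges$j[inter])))
  thr <- if (length(boundary)) stats::quantile(btw[boundary], quantile) else
    Inf
  nodes <- tibble(node = seq_len(net$n_nodes), community = memb,
                  betweenness = unname(btw),
                  boundary = seq_len(net$n_nodes) %in% boundary)
  nodes$critical <- nodes$boundary & nodes$betweenness >= thr
  junctions <- if (any(inter)) {
    ebtw <- igraph::edge_betweenness(g, weights = igraph::E(g)$w)
    tibble(community_a = pmin(memb[edges$i], memb[edges$j])[inter],
           community_b = pmax(memb[edges$i], memb[edges$j])[inter],
           eb = ebtw[inter]) |>
      dplyr::group_by(.data$community_a, .data$community_b) |>
      dplyr::summarise(n_edges = dplyr::n(),
                       edge_betweenness = sum(.data$eb), .groups = "drop")
  } else {
    tibble(community_a = integer(), community_b = integer(),
           n_edges = integer(), edge_betweenness = numeric())
  }
  list(nodes = nodes, junctions = junctions)
}

#' Optimal and suboptimal paths between two nodes
#'
#' Finds the Dijkstra-optimal path under the `w` weights, then enumerates
#' *all* simple paths whose total weight is within `tolerance` of the
#' optimum, by depth-first search pruned with exact distance-to-sink lower
#' bounds.
#'
#' @param net a `dynamic_network`.
#' @param from,to node indices.
#' @param tolerance admissible excess weight over the optimum (default 0).
#' @return list with `optimal` (node vector), `optimal_weight`, and `paths`
#'   (tibble: path list-column, weight, sorted by weight then node order);
#'   `NULL` optimal and a zero-row `paths` tibble when no path exists.
#' @export
network_paths <- function(net, from, to, tolerance = 0) {
  g <- net$graph
  w <- igraph::E(g)$w
  d_to_sink <- igraph::distances(g, v = igraph::V(g), to = to, weights = w)[, 1L]
  if (!is.finite(d_to_sink[from])) {
    return(list(optimal = NULL, optimal_weight = Inf,
                paths = tibble(path = list(), weight = numeric())))
  }
  opt_w <- d_to_sink[from]
  budget <- opt_w + tolerance + 1e-9
  adj <- lapply(seq_len(net$n_nodes), function(v) {
    es <- igraph::incident(g, v)
    ends <- igraph::ends(g, es)
    nb <- ifelse(ends[, 1L] == v, ends[, 2L], ends[, 1L])
    list(nb = as.integer(nb), w = igraph::E(g)$w[as.integer(es)])
  })
  found <- list()
  visit <- function(v, acc, path) {
    if (v == to) {
      found[[length(found) + 1L]] <<- list(path = path, weight = acc)
      return()
    }
    nbs <- adj[[v]]
    for (k in seq_along(nbs$nb)) {
      u <- nbs$nb[k]
      wa <- acc + nbs$w[k]
      if (u %in% path) next
      if (wa + d_to_sink[u] > budget) next
      visit(u, wa, c(path, u))
    }
  }
  visit(from, 0, from)
  weights <- vapply(found, function(p) p$weight, numeric(1))
  ord <- order(weights, vapply(found, function(p)
    paste(sprintf("%06d", p$path), collapse = ""), ""))
  paths <- tibble(path = lapply(found[ord], function(p) p$path),
                  weight = weights[ord])
  list(optimal = paths$path[[1L]], optimal_weight = paths$weight[[1L]],
       paths = paths)
}

#' Write a dynamic network as edge-list TSV
#'
#' @param net a `dynamic_network`.
#' @param partition optional `community_partition`.
#' @param betweenness optional result of [betweenness_and_critical_nodes()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_network_tsv <- function(net, path, partition = NULL,
                              betweenness = NULL) {
  e <- net$edges
  if (!is.null(partition)) {
    memb <- partition$membership
    e$community_i <- memb[e$i]
    e$community_j <- memb[e$j]
  }
  if (!is.null(betweenness)) {
    e$betweenness_i <- betweenness$nodes$betweenness[e$i]
    e$betweenness_j <- betweenness$nodes$betweenness[e$j]
  }
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
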