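# Fixtures and independent oracles shared across the suite. Everything is
# built in code at test time; no binary data.

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, b = 10, type = "ATOM", alt = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, paste0(" ", elety), alt, resid, chain, resno,
          x, y, z, occ, b)
}

# Small hand-written PDB: one chain, CA (+ optional CB) per residue.
write_tiny_pdb <- function(path, coords, resnos = seq_len(nrow(coords)),
                           resids = rep("ALA", nrow(coords)), chain = "A",
                           cb = NULL, b = rep(10, nrow(coords)),
                           extra_lines = character(0)) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(coords))) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line(serial, "CA", resids[i], chain,
                                    resnos[i], coords[i, 1], coords[i, 2],
                                    coords[i, 3], b = b[i]))
    if (!is.null(cb)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "CB", resids[i], chain,
                                      resnos[i], cb[i, 1], cb[i, 2],
                                      cb[i, 3], b = b[i]))
    }
  }
  writeLines(c(lines, extra_lines, "END"), path)
  path
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# Build a dynamic_network directly from an edge list with given |C| values.
toy_network <- function(n, edges, corr = 0.9) {
  cc <- diag(1, n)
  adj <- matrix(FALSE, n, n)
  if (length(corr) == 1L) corr <- rep(corr, nrow(edges))
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[i, j] <- adj[j, i] <- TRUE
    cc[i, j] <- cc[j, i] <- corr[r]
  }
  build_network(cc, adj)
}

# Exhaustive best 2-partition by modularity (|C| affinities), plus the
# trivial single-community partition, on a small network.
best_two_partition_modularity <- function(net) {
  g <- net$graph
  aff <- igraph::E(g)$affinity
  n <- net$n_nodes
  best <- igraph::modularity(g, rep(1L, n), weights = aff)
  best_memb <- rep(1L, n)
  for (mask in 1:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1)]) + 1L
    memb[1] <- 1L
    m <- igraph::modularity(g, memb, weights = aff)
    if (m > best) {
      best <- m
      best_memb <- memb
    }
  }
  list(modularity = best, membership = best_memb)
}

# All simple paths between two nodes with their total weights, by
# unpruned recursive enumeration (independent of the package's DFS).
enumerate_simple_paths <- function(net, from, to) {
  e <- net$edges
  nb <- lapply(seq_len(net$n_nodes), function(v) {
    rows <- which(e$i == v | e$j == v)
    data.frame(u = ifelse(e$i[rows] == v, e$j[rows], e$i[rows]),
               w = e$weight[rows])
  })
  out <- list()
  rec <- function(v, acc, path) {
    if (v == to) {
      out[[length(out) + 1L]] <<- list(path = path, weight = acc)
      return()
    }
    for (r in seq_len(nrow(nb[[v]]))) {
      u <- nb[[v]]$u[r]
      if (u %in% path) next
      rec(u, acc + nb[[v]]$w[r], c(path, u))
    }
  }
  rec(from, 0, from)
  out
}

# Node betweenness by brute-force shortest-path enumeration with
# fractional counting (each of k shortest s-t paths contributes 1/k).
brute_betweenness <- function(net) {
  n <- net$n_nodes
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- enumerate_simple_paths(net, s, t)
    if (!length(ps)) next
    w <- vapply(ps, function(p) p$weight, numeric(1))
    sp <- ps[w <= min(w) + 1e-9]
    for (p in sp) {
      mid <- setdiff(p$path, c(s, t))
      btw[mid] <- btw[mid] + 1 / length(sp)
    }
  }
  btw
}

# Two k-cliques joined by a single bridge edge (nodes k and k+1).
clique_bridge_edges <- function(k = 5L) {
  e1 <- t(combn(1:k, 2))
  e2 <- t(combn(k + (1:k), 2))
  rbind(e1, e2, c(k, k + 1L))
}

expect_same_partition <- function(a, b) {
  expect_equal(match(a, unique(a)), match(b, unique(b)))
}
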