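# Brute-force oracles, deliberately independent of the package's compiled
# bond-counting / local-delta code paths. Only for small lattices.

# unordered in-bounds neighbor pairs by type, plus per-type counts
oracle_pair_counts <- function(lattice) {
  d <- lattice$dims
  pairs <- matrix(0, 5, 5, dimnames = list(0:4, 0:4))
  types <- setNames(numeric(5), 0:4)
  off <- neighbor_offsets()
  for (z in 0:(d[3] - 1)) for (y in 0:(d[2] - 1)) for (x in 0:(d[1] - 1)) {
    t1 <- site_type(lattice, c(x, y, z))
    types[t1 + 1] <- types[t1 + 1] + 1
    for (k in 1:26) {
      p <- c(x, y, z) + off[k, ]
      if (any(p < 0) || any(p >= d)) next
      later <- p[3] > z || (p[3] == z && (p[2] > y || (p[2] == y && p[1] > x)))
      if (!later) next
      t2 <- site_type(lattice, p)
      a <- min(t1, t2) + 1; b <- max(t1, t2) + 1
      pairs[a, b] <- pairs[a, b] + 1
    }
  }
  pairs[lower.tri(pairs)] <- t(pairs)[lower.tri(pairs)]
  list(pairs = pairs, types = types)
}

# energy as minus the sum of bond-breaking works over every neighbor pair
oracle_bond_sum <- function(lattice, model) {
  pc <- oracle_pair_counts(lattice)$pairs[1:4, 1:4]
  keep <- upper.tri(pc, diag = TRUE)
  -sum(model$eps[keep] * pc[keep])
}

# interfacial/cohesion decomposition computed from the oracle counts
oracle_total_energy <- function(lattice, model) {
  pc <- oracle_pair_counts(lattice)
  p <- pc$pairs[1:4, 1:4]
  het <- upper.tri(p)
  sum(model$gamma[het] * p[het]) - 13 * sum(diag(model$eps) * pc$types[1:4])
}

# swap energy difference by full recomputation of the total energy
oracle_delta_full <- function(lattice, a, b, model) {
  ta <- site_type(lattice, a); tb <- site_type(lattice, b)
  after <- lattice_set(lattice_set(lattice, a, tb), b, ta)
  total_energy(after, model)$E_total - total_energy(lattice, model)$E_total
}

# random lattice whose non-medium content stays >= 2 sites from the boundary
random_interior_lattice <- function(dims, types = 0:3,
                                    prob = c(0.4, 0.4, 0.1, 0.1)) {
  lat <- tme_lattice(dims)
  g <- as.matrix(expand.grid(x = 2:(dims[1] - 3), y = 2:(dims[2] - 3),
                             z = 2:(dims[3] - 3)))
  lattice_set(lat, g, sample(types, nrow(g), replace = TRUE, prob = prob))
}

# a random Moore-adjacent interior pair with different types (NULL if none)
random_valid_swap <- function(lattice) {
  d <- lattice$dims
  off <- neighbor_offsets()
  for (i in 1:500) {
    a <- c(sample(2:(d[1] - 3), 1), sample(2:(d[2] - 3), 1),
           sample(2:(d[3] - 3), 1))
    b <- a + off[sample.int(26, 1), ]
    if (any(b < 2) || any(b >= d - 2)) next
    if (site_type(lattice, a) != site_type(lattice, b)) return(list(a = a, b = b))
  }
  NULL
}

# cluster sizes via igraph connected components (independent of the C++ BFS)
oracle_cluster_sizes <- function(lattice, types = c(2L, 3L)) {
  cells <- lattice_sites(lattice, types = types)
  n <- nrow(cells)
  if (n == 0) return(integer(0))
  xyz <- as.matrix(cells[, c("x", "y", "z")])
  edges <- NULL
  if (n > 1) {
    for (i in 1:(n - 1)) {
      cheb <- pmax(abs(xyz[(i + 1):n, 1] - xyz[i, 1]),
                   abs(xyz[(i + 1):n, 2] - xyz[i, 2]),
                   abs(xyz[(i + 1):n, 3] - xyz[i, 3]))
      j <- which(cheb == 1) + i
      if (length(j)) edges <- rbind(edges, cbind(i, j))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  sort(igraph::components(g)$csize, decreasing = TRUE)
}

tiny_model <- function(eps10, ET = 1) interaction_model(eps10, ET = ET)

set1_model <- function() tme_preset("set1")$model
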