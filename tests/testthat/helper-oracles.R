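# Brute-force reference implementations used as independent oracles.
# These deliberately use naive algorithms and plain R, not the package's
# compiled code paths.

# Connected-component partition via union-find over all voxel pairs.
bf_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  co <- arrayInd(idx, d)
  n <- length(idx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      dd <- abs(co[a, ] - co[b, ])
      linked <- if (connectivity == 6) sum(dd) == 1 else all(dd <= 1)
      if (linked) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(idx, roots)
}

# Background cavity filling by iterative flood from the border (6-conn).
bf_fill <- function(mask) {
  d <- dim(mask)
  border <- array(FALSE, d)
  border[1, , ] <- border[d[1], , ] <- TRUE
  border[, 1, ] <- border[, d[2], ] <- TRUE
  border[, , 1] <- border[, , d[3]] <- TRUE
  outside <- border & !mask
  repeat {
    grown <- outside
    # 6-neighbour growth by shifting along each axis
    grown[-1, , ] <- grown[-1, , ] | outside[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | outside[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | outside[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | outside[, -1, ]
    grown[, , -1] <- grown[, , -1] | outside[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | outside[, , -1]
    grown <- grown & !mask
    if (identical(grown, outside)) break
    outside <- grown
  }
  mask | !(mask | outside)
}

# Exhaustive minimum-variance h-subset search (raw MCD values).
bf_mcd <- function(x, support_fraction = 0.6) {
  n <- length(x)
  h <- max(2L, as.integer(ceiling(support_fraction * n)))
  subsets <- utils::combn(n, h)
  vars <- apply(subsets, 2, function(s) stats::var(x[s]))
  best <- which.min(vars)
  s <- x[subsets[, best]]
  list(mu = mean(s), sigma_raw = stats::sd(s))
}

# Dijkstra oracle over the 26-neighbour weighted voxel graph via igraph,
# using a virtual source attached to all seed voxels with zero-cost edges.
igraph_geodesic <- function(seed, domain) {
  d <- dim(seed)
  trav <- seed | domain
  n <- prod(d)
  offsets <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  # keep one direction per pair for an undirected graph
  keep <- with(offsets, dk > 0 | (dk == 0 & dj > 0) | (dk == 0 & dj == 0 & di > 0))
  offsets <- offsets[keep, ]
  idx <- which(trav)
  co <- arrayInd(idx, d)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  lind <- function(co3) co3[, 1] + d[1] * (co3[, 2] - 1 + d[2] * (co3[, 3] - 1))
  for (r in seq_len(nrow(offsets))) {
    off <- as.integer(offsets[r, ])
    nb <- sweep(co, 2, off, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_idx <- lind(nb[ok, , drop = FALSE])
    ok2 <- trav[nb_idx]
    from <- c(from, idx[ok][ok2])
    to <- c(to, nb_idx[ok2])
    w <- c(w, rep(sqrt(sum(off^2)), sum(ok2)))
  }
  seeds <- which(seed)
  src <- n + 1L
  g <- igraph::make_empty_graph(n = n + 1L, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to), weight = w)
  g <- igraph::add_edges(g, rbind(rep(src, length(seeds)), seeds),
                         weight = rep(0, length(seeds)))
  dist <- as.numeric(igraph::distances(g, v = src, weights = igraph::E(g)$weight))
  out <- array(Inf, d)
  out[trav] <- dist[which(trav)]
  out
}

# A small random logical array with reproducible content.
random_mask <- function(d, p = 0.3, seed = 1) {
  set.seed(seed)
  array(stats::runif(prod(d)) < p, dim = d)
}
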