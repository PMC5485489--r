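# Brute-force reference implementations, written independently of the
# package's computation paths (plain adjacency-matrix BFS and exhaustive
# path enumeration). Used to verify every topological index on small graphs.

adj_matrix <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  storage.mode(A) <- "integer"
  A
}

# hop counts from source s by hand-rolled BFS; unreachable = NA
oracle_bfs <- function(A, s) {
  n <- nrow(A)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer(0)
    for (v in frontier) {
      for (u in which(A[v, ] == 1L)) {
        if (is.na(dist[u])) {
          dist[u] <- d
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_dist_matrix <- function(g) {
  A <- adj_matrix(g)
  t(vapply(seq_len(nrow(A)), function(s) oracle_bfs(A, s), integer(nrow(A))))
}

# enumerate every shortest s-t path (as vectors of node indices)
enumerate_shortest_paths <- function(A, dist_s, s, t) {
  if (is.na(dist_s[t])) return(list())
  extend <- function(path) {
    v <- path[length(path)]
    if (v == s) return(list(rev(path)))
    preds <- which(A[v, ] == 1L & dist_s == dist_s[v] - 1L)
    out <- list()
    for (u in preds) out <- c(out, extend(c(path, u)))
    out
  }
  extend(t)
}

# Btwn(v) over unordered pairs {s,t}, endpoints excluded
oracle_betweenness <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  btwn <- rep(0, n)
  for (s in seq_len(n)) {
    dist_s <- oracle_bfs(A, s)
    for (t in seq_len(n)) {
      if (t <= s || is.na(dist_s[t])) next
      paths <- enumerate_shortest_paths(A, dist_s, s, t)
      sigma <- length(paths)
      if (sigma == 0) next
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        btwn[interior] <- btwn[interior] + 1 / sigma
      }
    }
  }
  setNames(btwn, igraph::V(g)$name)
}

oracle_clustering <- function(g) {
  A <- adj_matrix(g)
  cc <- vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  setNames(cc, igraph::V(g)$name)
}

oracle_eccentricity <- function(g) {
  D <- oracle_dist_matrix(g)
  setNames(apply(D, 1, max), igraph::V(g)$name)
}

oracle_avg_distance <- function(g, diameter = NULL) {
  D <- oracle_dist_matrix(g)
  if (any(is.na(D))) {
    dg <- if (is.null(diameter)) max(D, na.rm = TRUE) else diameter
    D[is.na(D)] <- dg
  }
  setNames(rowSums(D) / (nrow(D) - 1), igraph::V(g)$name)
}

# coreness by definition: largest k whose iteratively-pruned k-core keeps v
oracle_coreness <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  core <- rep(0L, n)
  for (k in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- as.numeric(A %*% alive)
      drop <- alive & deg < k
      if (!any(drop)) break
      alive[drop] <- FALSE
    }
    if (!any(alive)) break
    core[alive] <- k
  }
  setNames(core, igraph::V(g)$name)
}

oracle_leading_eigen <- function(g) {
  A <- adj_matrix(g)
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  list(vector = setNames(v, igraph::V(g)$name), lambda = e$values[1])
}

# named random G(n, p) graph with a fixed seed
rand_gnp <- function(n, p, seed, connected = FALSE) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
      if (!connected || igraph::is_connected(g)) return(g)
    }
  })
}

named_graph <- function(make, prefix = "n") {
  g <- make
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(igraph::vcount(g)))
  g
}

nmi <- function(a, b) igraph::compare(as.integer(factor(a)),
                                      as.integer(factor(b)), method = "nmi")
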