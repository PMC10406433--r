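# Independent brute-force oracles used to validate the package's fast paths.
# These deliberately use naive explicit loops, not the package internals.

# minimum interatomic distance between two coordinate sets under cubic
# minimum-image convention
oracle_min_dist <- function(A, B, L = NULL) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- A[i, ] - B[j, ]
      if (!is.null(L)) d <- d - L * round(d / L)
      best <- min(best, sqrt(sum(d^2)))
    }
  }
  best
}

# chain adjacency of an ensemble by brute force
oracle_adjacency <- function(ensemble, cutoff) {
  ch <- levels(ensemble$atoms$chain)
  n <- length(ch)
  L <- if (ensemble$periodic) ensemble$box else NULL
  X <- ensemble$coords[[1]]
  A <- matrix(FALSE, n, n)
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      du <- X[ensemble$atoms$chain == ch[u], , drop = FALSE]
      dv <- X[ensemble$atoms$chain == ch[v], , drop = FALSE]
      A[u, v] <- A[v, u] <- oracle_min_dist(du, dv, L) <= cutoff
    }
  }
  A
}

# connected components by union-find
oracle_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u < v && adj[u, v]) {
        ru <- find(u)
        rv <- find(v)
        if (ru != rv) parent[rv] <- ru
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# ordinary least squares by the closed-form normal equations
oracle_ols <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

# mass-weighted radius of gyration by direct summation
oracle_rg <- function(X, m) {
  cm <- c(sum(X[, 1] * m), sum(X[, 2] * m), sum(X[, 3] * m)) / sum(m)
  s <- 0
  for (i in seq_len(nrow(X)))
    s <- s + m[i] * sum((X[i, ] - cm)^2)
  sqrt(s / sum(m))
}

# polygon area (shoelace) and perimeter from vertices
oracle_polygon <- function(V) {
  n <- nrow(V)
  j <- c(2:n, 1)
  area <- abs(sum(V[, 1] * V[j, 2] - V[j, 1] * V[, 2])) / 2
  perim <- sum(sqrt(rowSums((V[j, ] - V)^2)))
  c(area = area, perimeter = perim)
}

# a random crowded scene with uncontrolled contacts (for oracle equivalence)
random_scene <- function(n_chains, atoms_per_chain, L, seed) {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(seq_len(n_chains), function(u)
    data.frame(chain = sprintf("R%02d", u), element = "C",
               resid = seq_len(atoms_per_chain) - 1L, restype = "G")))
  # chains as loose random-walk blobs scattered in the box
  coords <- do.call(rbind, lapply(seq_len(n_chains), function(u) {
    origin <- runif(3, 0, L)
    steps <- matrix(rnorm(3 * atoms_per_chain, sd = 0.15), ncol = 3)
    sweep(apply(steps, 2, cumsum), 2, origin, "+") %% L
  }))
  chain_ensemble(atoms, coords, box = L, periodic = TRUE)
}
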