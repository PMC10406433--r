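# Tunable hierarchical cluster-cluster aggregation. Every intermediate
# cluster is steered onto the scaling law N = (Rg/a)^df (prefactor 1), with
# the placement radius clamped to the geometrically feasible contact range:
# with prefactor 1 and low df the law is unattainable below a small cluster
# size, and the construction converges onto it as soon as geometry allows.

# grow one subcluster by particle-cluster aggregation
.pca_grow <- function(n, radii, a, df, max_try = 1e4) {
  X <- matrix(0, 1, 3)
  if (n == 1) return(X)
  X <- rbind(X, c(radii[1] + radii[2], 0, 0))
  if (n == 2) return(sweep(X, 2, colMeans(X)))
  for (k in 3:n) {
    N <- k - 1
    X <- sweep(X, 2, colMeans(X))
    rg_t <- a * k^(1 / df)
    rg_c <- .rg_points(X)
    g2 <- (k^2 * rg_t^2 - N * k * rg_c^2) / N
    gam <- if (g2 > 0) sqrt(g2) else 0
    d <- sqrt(rowSums(X^2))
    touch <- radii[1:N] + radii[k]
    gmin <- min(abs(d - touch))
    gmax <- max(d + touch)
    gam <- min(max(gam, gmin), gmax)
    tol <- 1e-9 * a
    cand <- which(abs(d - gam) <= touch + tol & d + touch >= gam - tol)
    if (!length(cand))
      stop("no feasible anchor while growing subcluster (k = ", k, ")")
    placed <- FALSE
    for (t in seq_len(max_try)) {
      ip <- if (length(cand) == 1L) cand else sample(cand, 1L)
      p <- X[ip, ]
      dp <- sqrt(sum(p^2))
      rc <- touch[ip]
      # intersection circle of spheres |x| = gam and |x - p| = rc
      cosb <- min(1, max(-1, (dp^2 + gam^2 - rc^2) / (2 * dp * gam)))
      e1 <- p / dp
      tmp <- .rand_unit()
      e2 <- tmp - sum(tmp * e1) * e1
      if (sum(e2^2) < 1e-12) next
      e2 <- e2 / sqrt(sum(e2^2))
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      ang <- stats::runif(1, 0, 2 * pi)
      sinb <- sqrt(max(0, 1 - cosb^2))
      x <- gam * (cosb * e1 + sinb * (cos(ang) * e2 + sin(ang) * e3))
      dd <- sqrt(rowSums(sweep(X, 2, x)^2))
      if (all(dd >= (radii[1:N] + radii[k]) * (1 - 1e-3))) {
        X <- rbind(X, x)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("particle placement exhausted ", max_try, " attempts at k = ", k,
           "; consider relaxing d_f or polydispersity")
  }
  sweep(X, 2, colMeans(X))
}

# minimum of (pairwise distance - contact distance) between two radius-tagged
# point sets; zero at exact touching contact, negative on overlap
.contact_gap <- function(A, ra, B, rb) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  gap <- sqrt(pmax(d2, 0)) - outer(ra, rb, "+")
  min(gap)
}

# merge two clusters at center-of-mass separation gam with exact touching
# contact, found by root-finding on a rotation angle of the second cluster
.cca_merge <- function(X1, r1, X2, r2, gam, max_dir = 200L) {
  X1 <- sweep(X1, 2, colMeans(X1))
  X2 <- sweep(X2, 2, colMeans(X2))
  for (t in seq_len(max_dir)) {
    u <- .rand_unit()
    B0 <- X2 %*% t(.rand_rotation())
    axis <- .rand_unit()
    gap <- function(th) {
      B <- sweep(B0 %*% t(.rot_matrix(axis, th)), 2, gam * u, "+")
      .contact_gap(X1, r1, B, r2)
    }
    th <- seq(0, 2 * pi, length.out = 25L)
    gv <- vapply(th, gap, numeric(1))
    if (all(gv > 0) || all(gv <= 0)) next
    lo <- NA
    for (j in seq_along(th)[-1]) {
      if (gv[j - 1] > 0 && gv[j] <= 0) { lo <- th[j - 1]; hi <- th[j]; break }
      if (gv[j - 1] <= 0 && gv[j] > 0) { lo <- th[j]; hi <- th[j - 1]; break }
    }
    if (is.na(lo)) next
    root <- stats::uniroot(gap, sort(c(lo, hi)), tol = 1e-12)$root
    B <- sweep(B0 %*% t(.rot_matrix(axis, root)), 2, gam * u, "+")
    if (.contact_gap(X1, r1, B, r2) >= -1e-3 * min(c(r1, r2)))
      return(rbind(X1, B))
  }
  stop("cluster-cluster sticking search exhausted; ",
       "consider relaxing d_f or polydispersity")
}

#' Build a fractal aggregate with prescribed fractal dimension
#'
#' Hierarchical tunable cluster-cluster aggregation: primary particles are
#' first grown into subclusters of about `sqrt(N)` particles
#' (particle-cluster stage), which are then pairwise merged
#' (cluster-cluster stage). At every sticking event the center-of-mass
#' separation is solved from the mass-size scaling law
#' \eqn{N = (R_g/a)^{d_f}} with prefactor \eqn{k_f = 1} (`a` is the mean
#' primary-particle radius), so the prescribed fractal dimension holds at all
#' scales rather than only asymptotically. Particles touch exactly at contact
#' (relative overlap tolerance 1e-3) and the contact graph is connected by
#' construction.
#'
#' @param N number of primary particles.
#' @param radii particle radii, nm: a scalar (monodisperse) or length-`N`
#'   vector.
#' @param d_f target fractal dimension, in (1, 3].
#' @param seed integer RNG seed; identical seeds give identical geometries.
#' @return An object of class `aggregate_geometry`: list with `centers`
#'   (N x 3 matrix, nm), `radii`, `d_f`, `k_f` (fixed 1), `seed` and
#'   `subclusters`, a data frame of (N, Rg) records for every intermediate
#'   cluster built along the way.
#' @examples
#' agg <- build_aggregate(64, radii = 1.6, d_f = 2.42, seed = 7)
#' fit_mass_size(data.frame(R = agg$subclusters$Rg, M = agg$subclusters$N))
#' @export
build_aggregate <- function(N, radii, d_f, seed) {
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  if (d_f <= 1 || d_f > 3) stop("d_f must be in (1, 3]")
  if (length(radii) == 1L) radii <- rep(radii, N)
  if (length(radii) != N) stop("radii must be scalar or length N")
  if (any(radii <= 0)) stop("radii must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  a <- mean(radii)
  if (N == 1) {
    return(structure(list(centers = matrix(0, 1, 3), radii = radii,
                          d_f = d_f, k_f = 1, seed = seed,
                          subclusters = data.frame(N = 1, Rg = 0)),
                     class = "aggregate_geometry"))
  }
  m <- max(2L, as.integer(round(sqrt(N))))
  sizes <- rep(m, N %/% m)
  if (N %% m) sizes <- c(sizes, N %% m)
  # assign radii to subclusters in order
  split_idx <- split(seq_len(N), rep(seq_along(sizes), sizes))
  subs <- vector("list", length(sizes))
  for (s in seq_along(sizes))
    subs[[s]] <- list(X = .pca_grow(sizes[s], radii[split_idx[[s]]], a, d_f),
                      r = radii[split_idx[[s]]])
  recs <- data.frame(N = sizes,
                     Rg = vapply(subs, function(s) .rg_points(s$X), numeric(1)))
  while (length(subs) > 1) {
    ord <- order(vapply(subs, function(s) nrow(s$X), integer(1)))
    i <- ord[1]; j <- ord[2]
    s1 <- subs[[j]]; s2 <- subs[[i]]
    N1 <- nrow(s1$X); N2 <- nrow(s2$X); Nn <- N1 + N2
    rg_t <- a * Nn^(1 / d_f)
    g2 <- Nn^2 / (N1 * N2) *
      (rg_t^2 - (N1 * .rg_points(s1$X)^2 + N2 * .rg_points(s2$X)^2) / Nn)
    gam <- if (g2 > 0) sqrt(g2) else 0
    reach <- max(sqrt(rowSums(sweep(s1$X, 2, colMeans(s1$X))^2))) +
      max(sqrt(rowSums(sweep(s2$X, 2, colMeans(s2$X))^2))) + max(s1$r) + max(s2$r)
    gam <- min(gam, reach * (1 - 1e-9))
    merged <- .cca_merge(s1$X, s1$r, s2$X, s2$r, gam)
    subs[[j]] <- list(X = merged, r = c(s1$r, s2$r))
    subs[[i]] <- NULL
    recs <- rbind(recs, data.frame(N = Nn, Rg = .rg_points(merged)))
  }
  centers <- sweep(subs[[1]]$X, 2, colMeans(subs[[1]]$X))
  structure(list(centers = centers, radii = subs[[1]]$r, d_f = d_f, k_f = 1,
                 seed = seed, subclusters = recs),
            class = "aggregate_geometry")
}

#' @export
print.aggregate_geometry <- function(x, ...) {
  cat(sprintf("fractal aggregate: %d particles, target d_f = %.3f (k_f = 1), seed %d\n",
              nrow(x$centers), x$d_f, x$seed))
  invisible(x)
}

#' Estimate the fractal dimension of an aggregate
#'
#' Mass-radius regression: the cumulative particle count within radius `r`,
#' averaged over interior reference particles, scales as \eqn{r^{d_f}}.
#' Centers are restricted to particles within `center_fraction` of the
#' maximal center-of-mass distance, and the count radius never exceeds any
#' center's distance to the aggregate envelope, which suppresses the
#' finite-size edge truncation that biases the naive estimator.
#'
#' @param geometry an `aggregate_geometry` (or any list with `centers` and
#'   `radii`).
#' @param n_shells number of logarithmic radial shells for the regression.
#' @param center_fraction interior-region fraction for reference particles.
#' @return Estimated fractal dimension (regression slope).
#' @export
measure_df <- function(geometry, n_shells = 20, center_fraction = 0.5) {
  X <- geometry$centers
  if (nrow(X) < 32) stop("need at least 32 particles")
  a <- mean(geometry$radii)
  cm <- colMeans(X)
  dcm <- sqrt(rowSums(sweep(X, 2, cm)^2))
  rmax_a <- max(dcm)
  ctr <- which(dcm <= center_fraction * rmax_a)
  if (length(ctr) < 16) ctr <- order(dcm)[seq_len(min(16, nrow(X)))]
  D <- .cross_dist_pbc(X, X[ctr, , drop = FALSE], NULL)
  rhi <- min(rmax_a - dcm[ctr])
  if (rhi <= 2 * a * 1.05) stop("insufficient radial range for a mass-radius fit")
  rs <- exp(seq(log(2 * a), log(rhi), length.out = n_shells))
  Nr <- vapply(rs, function(r) mean(colSums(D <= r)), numeric(1))
  fit <- stats::lm(log10(Nr) ~ log10(rs))
  unname(stats::coef(fit)[2])
}

#' Conformer library for atomistic decoration
#'
#' @param conformers a list of single-chain snapshots (each with `coords` in
#'   nm and `elements`; see [get_chain()] and [gen_polymer()]).
#' @return An object of class `conformer_library` with per-conformer Rg.
#' @export
conformer_library <- function(conformers) {
  if (!length(conformers)) stop("empty conformer library")
  rg <- vapply(conformers, radius_of_gyration, numeric(1))
  if (any(rg <= 0)) stop("conformer Rg must be positive")
  structure(list(conformers = conformers, rg = rg), class = "conformer_library")
}

#' Decorate a fractal aggregate with atomistic conformers
#'
#' Replaces every spherical primary particle by a chain conformer whose
#' radius of gyration is nearest the particle radius (random tie-breaking),
#' randomly rotated and translated so the conformer's center of mass
#' coincides with the particle center.
#'
#' @param geometry an `aggregate_geometry`.
#' @param library a [conformer_library()].
#' @param seed integer RNG seed.
#' @param rg_tolerance maximal relative |Rg - r| / r for an acceptable
#'   conformer (default 0.25).
#' @return A single-frame [chain_ensemble()] with one chain per particle
#'   (open boundary).
#' @export
decorate <- function(geometry, library, seed, rg_tolerance = 0.25) {
  stopifnot(inherits(library, "conformer_library"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  np <- nrow(geometry$centers)
  atoms <- vector("list", np)
  coords <- vector("list", np)
  for (i in seq_len(np)) {
    r <- geometry$radii[i]
    mis <- abs(library$rg - r) / r
    if (min(mis) > rg_tolerance)
      stop(sprintf(paste0("no conformer within %.0f%% of particle %d ",
                          "(radius %.3f nm; nearest library Rg %.3f nm)"),
                   100 * rg_tolerance, i, r, library$rg[which.min(mis)]))
    cand <- which(mis <= min(mis) + 1e-12)
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    conf <- library$conformers[[pick]]
    m <- atomic_mass(conf$elements)
    X <- conf$coords %*% t(.rand_rotation())
    X <- sweep(X, 2, colSums(X * m) / sum(m))              # COM to origin
    X <- sweep(X, 2, geometry$centers[i, ], "+")
    chain_id <- sprintf("C%04d", i)
    na <- nrow(X)
    atoms[[i]] <- data.frame(chain = chain_id, element = conf$elements,
                             resid = if (!is.null(conf$resid)) conf$resid else seq_len(na) - 1L,
                             restype = if (!is.null(conf$restype)) conf$restype else rep("G", na))
    coords[[i]] <- X
  }
  chain_ensemble(do.call(rbind, atoms), do.call(rbind, coords),
                 box = NA_real_, periodic = FALSE)
}
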