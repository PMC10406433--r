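# Seeded generators producing inputs with known ground truth for every
# analysis path. Each generator attaches its planted parameters as the
# "ground_truth" attribute (written as a sidecar JSON by write_fixture()).

.ground_truth <- function(x, truth) {
  attr(x, "ground_truth") <- truth
  x
}

#' Planted ground truth of a generated fixture
#' @param x a fixture produced by one of the `gen_*()` generators.
#' @return The list of planted parameters.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

# local pseudo-atom geometry: residue bead plus 3 satellites (4 atoms/residue)
.residue_atoms <- function(center) {
  o1 <- c(0.08, 0.05, 0)
  o2 <- c(-0.05, 0.08, 0.03)
  o3 <- c(0, -0.05, -0.09)
  rbind(center, center + o1, center + o2, center + o3)
}

#' Generate a self-avoiding polymer conformer
#'
#' A bead-per-residue self-avoiding walk (bond 0.38 nm, excluded distance
#' 0.35 nm between non-bonded beads) expanded to 4 pseudo-atoms per residue
#' (carbon radii). `compact` mode confines the walk to a sphere sized so the
#' radius of gyration falls below the disordered-coil reference
#' [random_coil_rg()]; `extended` mode uses a persistent (small-turn) walk
#' whose Rg lies well above it.
#'
#' @param N_res residue count (>= 2).
#' @param compactness_mode `"compact"` or `"extended"`.
#' @param seed integer RNG seed.
#' @return A single-chain snapshot: list with `coords` (nm), `elements`,
#'   `resid`, `restype`; ground truth records the mode and coil reference.
#' @export
gen_polymer <- function(N_res, compactness_mode = c("compact", "extended"),
                        seed) {
  compactness_mode <- match.arg(compactness_mode)
  if (N_res < 2) stop("N_res must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bond <- 0.38
  excl <- 0.35
  coil <- random_coil_rg(N_res)
  r_conf <- if (compactness_mode == "compact") coil else Inf
  for (restart in 1:200) {
    beads <- matrix(0, N_res, 3)
    dir <- .rand_unit()
    ok <- TRUE
    for (i in 2:N_res) {
      placed <- FALSE
      for (t in 1:60) {
        step <- if (compactness_mode == "extended") {
          # persistent walk: perturb the previous direction within ~30 deg
          d <- dir + 0.3 * .rand_unit()
          d / sqrt(sum(d^2))
        } else .rand_unit()
        cand <- beads[i - 1, ] + bond * step
        if (sqrt(sum(cand^2)) > r_conf) next
        if (i > 2) {
          dd <- sqrt(rowSums(sweep(beads[1:(i - 2), , drop = FALSE], 2, cand)^2))
          if (min(dd) < excl) next
        }
        beads[i, ] <- cand
        dir <- step
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      X <- do.call(rbind, lapply(seq_len(N_res),
                                 function(i) .residue_atoms(beads[i, ])))
      snap <- list(coords = X, elements = rep("C", 4 * N_res),
                   resid = rep(seq_len(N_res) - 1L, each = 4L),
                   restype = rep("A", 4 * N_res))
      return(.ground_truth(snap, list(kind = "polymer", N_res = N_res,
                                      mode = compactness_mode, seed = seed,
                                      coil_rg = coil,
                                      rg = radius_of_gyration(snap))))
    }
  }
  stop("self-avoiding walk failed after 200 restarts")
}

# rigid blob template: octahedron + center, radius 0.1 nm
.blob_template <- function() {
  rbind(c(0, 0, 0),
        0.1 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
}

# relax chain centers so edges sit at `d_edge` and non-edges beyond `d_far`
.relax_centers <- function(adj, L, d_edge, d_far, iters = 600) {
  n <- nrow(adj)
  lo <- 0.15 * L
  hi <- 0.85 * L
  P <- matrix(stats::runif(3 * n, lo, hi), n, 3)
  for (it in seq_len(iters)) {
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        dv <- P[v, ] - P[u, ]
        d <- sqrt(sum(dv^2))
        if (d < 1e-9) { P[v, ] <- P[v, ] + 0.1 * .rand_unit(); next }
        if (adj[u, v]) {
          shift <- 0.3 * (d - d_edge) / d * dv
          P[u, ] <- P[u, ] + shift / 2
          P[v, ] <- P[v, ] - shift / 2
        } else if (d < d_far * 1.08) {
          shift <- 0.3 * (d - d_far * 1.08) / d * dv
          P[u, ] <- P[u, ] + shift / 2
          P[v, ] <- P[v, ] - shift / 2
        }
      }
    }
    P[P < lo] <- lo + (lo - P[P < lo]) * 0.5
    P[P > hi] <- hi - (P[P > hi] - hi) * 0.5
  }
  P
}

#' Generate a crowded multi-chain scene with a planted contact graph
#'
#' Places `n_chains` rigid pseudo-atomic chains in a cubic periodic box so
#' that chain pairs joined by an edge of `planted_adjacency` have minimum
#' interatomic distance at most 0.3 nm while all other pairs stay at least
#' 0.6 nm apart -- margins on both sides of the standard 0.35 nm contact
#' cutoff, so descriptor results are robust to the exact cutoff. Each chain
#' is a small core blob plus one "arm" of atoms reaching toward the contact
#' midpoint for every planted partner; atom counts are padded (coincident
#' core atoms) so all chains have equal length. Construction is verified by
#' brute force and retried from new layouts before failing.
#'
#' @param n_chains chain count.
#' @param L cubic box edge, nm.
#' @param planted_adjacency symmetric logical/0-1 matrix, `n_chains` square;
#'   realizable graphs keep vertex degrees modest (<= ~5).
#' @param seed integer RNG seed.
#' @return A [chain_ensemble()] (single frame) whose ground truth stores the
#'   planted adjacency.
#' @export
gen_scene <- function(n_chains, L, planted_adjacency, seed) {
  adj <- planted_adjacency
  if (!is.matrix(adj) || nrow(adj) != n_chains || ncol(adj) != n_chains)
    stop("planted_adjacency must be an n_chains x n_chains matrix")
  adj <- adj != 0
  if (!isTRUE(all(adj == t(adj))) || any(diag(adj)))
    stop("planted_adjacency must be symmetric with an empty diagonal")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d_edge <- 1.2
  d_far <- 1.7
  if (L < 4) stop("box too small for the placement margins")
  blob <- .blob_template()
  for (attempt in 1:20) {
    P <- .relax_centers(adj, L, d_edge, d_far)
    # build chains: core blob + one arm per planted partner
    chain_atoms <- vector("list", n_chains)
    for (u in seq_len(n_chains)) {
      X <- sweep(blob, 2, P[u, ], "+")
      for (v in which(adj[u, ])) {
        mid <- (P[u, ] + P[v, ]) / 2
        dir <- (mid - P[u, ]) / sqrt(sum((mid - P[u, ])^2))
        reach <- sqrt(sum((mid - P[u, ])^2)) - 0.1   # tip 0.1 nm short of mid
        steps <- seq(0.25, reach, by = 0.22)
        if (!length(steps) || max(steps) < reach - 1e-9)
          steps <- c(steps, reach)
        arm <- sweep(outer(steps, dir), 2, P[u, ], "+")
        X <- rbind(X, arm)
      }
      chain_atoms[[u]] <- X
    }
    namax <- max(vapply(chain_atoms, nrow, integer(1)))
    for (u in seq_len(n_chains)) {
      deficit <- namax - nrow(chain_atoms[[u]])
      if (deficit > 0)
        chain_atoms[[u]] <- rbind(chain_atoms[[u]],
                                  matrix(P[u, ], deficit, 3, byrow = TRUE))
    }
    # brute-force verification of planted margins
    ok <- TRUE
    for (u in seq_len(n_chains - 1)) {
      for (v in (u + 1):n_chains) {
        dmin <- min(.cross_dist_pbc(chain_atoms[[u]], chain_atoms[[v]], L))
        if (adj[u, v] && dmin > 0.3) { ok <- FALSE; break }
        if (!adj[u, v] && dmin < 0.6) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      atoms <- do.call(rbind, lapply(seq_len(n_chains), function(u) {
        data.frame(chain = sprintf("C%02d", u), element = "C",
                   resid = seq_len(namax) - 1L, restype = "G")
      }))
      ens <- chain_ensemble(atoms, do.call(rbind, chain_atoms), box = L,
                            periodic = TRUE)
      return(.ground_truth(ens, list(kind = "scene", n_chains = n_chains,
                                     L = L, seed = seed, adjacency = adj)))
    }
  }
  stop("could not realize the planted contact graph after 20 layouts; ",
       "is the graph geometrically realizable at these margins?")
}

#' Generate a FRAP recovery curve with known parameters
#'
#' Samples \eqn{C(t) = 1 - a e^{-t/\tau_a} - b e^{-t/\tau_b}} on an
#' acquisition-style schedule (frame spacing doubling in four blocks, like
#' time-lapse imaging that records densely right after the bleach) with
#' additive Gaussian noise.
#'
#' @param a,b amplitudes (>= 0).
#' @param tau_a,tau_b recovery times, s.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param n_points number of frames (default 32).
#' @param seed integer RNG seed.
#' @param t_max last frame time, s (default 1200 = 20 min).
#' @return A [recovery_curve()] with planted parameters as ground truth.
#' @export
gen_frap <- function(a, b, tau_a, tau_b, noise_sigma = 0, n_points = 32,
                     seed, t_max = 1200) {
  if (a < 0 || b < 0 || tau_a <= 0 || tau_b <= 0)
    stop("amplitudes must be >= 0 and recovery times > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nb <- ceiling(n_points / 4)
  dt0 <- t_max / (nb * 15)     # blocks at dt, 2dt, 4dt, 8dt
  t <- cumsum(rep(c(1, 2, 4, 8) * dt0, each = nb))[seq_len(n_points)]
  y <- .frap_model(t, a, b, tau_a, tau_b) +
    stats::rnorm(n_points, 0, noise_sigma)
  curve <- recovery_curve(t, y, "center")
  t_half <- if (a + b > 0) frap_half_time(list(a = a, b = b, tau_a = tau_a,
                                               tau_b = tau_b)) else NA_real_
  .ground_truth(curve, list(kind = "frap", a = a, b = b, tau_a = tau_a,
                            tau_b = tau_b, noise_sigma = noise_sigma,
                            seed = seed, t_half = t_half))
}

#' Generate an MSD series with known diffusion coefficient
#'
#' \eqn{MSD(\tau) = c + 6 D \tau} with optional additive Gaussian noise.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param c intercept, nm^2.
#' @param t_max largest lag, ns.
#' @param noise_sigma noise standard deviation, nm^2.
#' @param seed integer RNG seed.
#' @param dt lag spacing, ns.
#' @param window fit window passed through to [msd_series()].
#' @return An [msd_series()] with planted D as ground truth.
#' @export
gen_msd <- function(D, c = 0, t_max = 50, noise_sigma = 0, seed, dt = 0.5,
                    window = c(20, 40)) {
  if (D < 0) stop("D must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lag <- seq(dt, t_max, by = dt)
  # MSD slope in nm^2/ns is 6 D with D converted from um^2/s
  msd <- c + (D / .msd_slope_to_um2s) * lag +
    stats::rnorm(length(lag), 0, noise_sigma)
  msd <- pmax(msd, 0)
  series <- msd_series(lag, msd, window = window)
  .ground_truth(series, list(kind = "msd", D = D, c = c,
                             noise_sigma = noise_sigma, seed = seed))
}

#' Generate a pressure-fluctuation series with known viscosity
#'
#' Six independent pressure components are drawn as sums of
#' Ornstein-Uhlenbeck processes whose autocorrelation is a planted
#' multi-exponential \eqn{C(t) = \sum_k V_k e^{-t/\tau_k}} with
#' \eqn{\sum_k V_k \tau_k} chosen so that the Green-Kubo integral equals the
#' target viscosity.
#'
#' @param eta_target shear viscosity to plant, mPa s.
#' @param V box volume, nm^3.
#' @param T temperature, K.
#' @param dt sampling step, ps (default 0.01, i.e. 10 fs output).
#' @param length series length (default 1e6, i.e. 10 ns).
#' @param taus correlation times of the ACF components, ps.
#' @param weights fraction of the Green-Kubo integral carried by each
#'   component.
#' @param seed integer RNG seed.
#' @return A [pressure_series()] with the planted viscosity as ground truth.
#' @export
gen_pressure <- function(eta_target, V, T, dt = 0.01, length = 1e6,
                         taus = c(0.2, 1.0), weights = c(0.8, 0.2), seed) {
  .stopifnot_scalar_pos(eta_target, "eta_target")
  if (base::length(taus) != base::length(weights) || any(taus <= 0) ||
      any(weights < 0) || sum(weights) <= 0)
    stop("taus and weights must match, with positive taus and weights")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- as.integer(length)
  w <- weights / sum(weights)
  I_tot <- eta_target / (.gk_factor / T * V)       # bar^2 ps
  vars <- w * I_tot / taus
  P <- matrix(0, n, 6)
  for (j in 1:6) {
    x <- numeric(n)
    for (k in seq_along(taus)) {
      rho <- exp(-dt / taus[k])
      eps <- stats::rnorm(n, 0, sqrt(vars[k] * (1 - rho^2)))
      eps[1] <- stats::rnorm(1, 0, sqrt(vars[k]))
      x <- x + as.numeric(stats::filter(eps, rho, method = "recursive"))
    }
    P[, j] <- x
  }
  series <- pressure_series((0:(n - 1)) * dt, P, V, T)
  .ground_truth(series, list(kind = "pressure", eta = eta_target, V = V,
                             T = T, taus = taus, weights = w, seed = seed))
}
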