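#' Radius of gyration of a chain snapshot
#'
#' Mass-weighted radius of gyration about the center of mass.
#'
#' @param snapshot a single-chain snapshot as returned by [get_chain()], or
#'   any list with `coords` (n x 3 matrix, nm) and `elements`.
#' @param masses optional per-atom masses (Da) overriding the element lookup.
#' @return Rg in nm.
#' @examples
#' radius_of_gyration(list(coords = rbind(c(0, 0, 0), c(2, 0, 0)),
#'                         elements = c("C", "C")))  # 1.0
#' @export
radius_of_gyration <- function(snapshot, masses = NULL) {
  X <- snapshot$coords
  if (is.null(dim(X))) X <- matrix(X, ncol = 3)
  if (is.null(masses)) masses <- atomic_mass(snapshot$elements)
  if (length(masses) != nrow(X)) stop("one mass per atom required")
  if (sum(masses) <= 0) stop("total mass must be positive")
  cm <- colSums(X * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(X, 2, cm)^2)) / sum(masses))
}

#' Random-coil radius of gyration of a disordered chain
#'
#' Empirical polymer scaling for intrinsically disordered proteins:
#' \eqn{R_g = 0.254 \, N^{0.522}} nm, with `N` the residue count.
#'
#' @param N residue count (>= 1); vectorized.
#' @return Rg in nm.
#' @examples
#' random_coil_rg(80)  # ~2.50 nm
#' @export
random_coil_rg <- function(N) {
  if (any(N < 1)) stop("N must be >= 1")
  .coil_R0 * N^.coil_nu
}

# union-of-spheres volume by voxel counting; X nm coords, r per-atom radii
.union_sphere_volume <- function(X, r, spacing) {
  lo <- apply(X - r, 2, min) - spacing
  hi <- apply(X + r, 2, max) + spacing
  nx <- ceiling((hi - lo) / spacing)
  # voxel center coordinates along each axis
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(nx[k]) - 0.5) * spacing)
  occ <- array(FALSE, dim = nx)
  for (i in seq_len(nrow(X))) {
    rng <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - X[i, k]) <= r[i])
    })
    if (any(lengths(rng) == 0)) next
    dx2 <- (ax[[1]][rng[[1]]] - X[i, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - X[i, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - X[i, 3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r[i]^2
    occ[rng[[1]], rng[[2]], rng[[3]]] <- occ[rng[[1]], rng[[2]], rng[[3]]] | inside
  }
  sum(occ) * spacing^3
}

# Kirkwood hydrodynamic radius: 1/Rh = (1/N^2) sum_{i != j} 1/r_ij
.kirkwood_rh <- function(X) {
  n <- nrow(X)
  if (n < 2) stop("Kirkwood estimator needs >= 2 atoms")
  D <- as.matrix(stats::dist(X))
  inv <- 1 / D[upper.tri(D)]
  1 / (2 * sum(inv) / n^2)
}

#' Compactness (volume fraction) of a chain conformer
#'
#' Compactness `phi` is the ratio of the van der Waals volume (union of
#' atomic Bondi spheres, computed by voxel counting at `grid_spacing`) to the
#' hydrodynamic volume \eqn{(4/3)\pi R_h^3}. The hydrodynamic radius comes
#' either from the Kirkwood double-sum approximation
#' \eqn{R_h^{-1} = N^{-2} \sum_{i \ne j} r_{ij}^{-1}} (default) or from an
#' empirical ratio to the radius of gyration, \eqn{R_h = R_g / \rho} with
#' `rg_rh_ratio` \eqn{= \rho}.
#'
#' @param snapshot a single-chain snapshot (see [get_chain()]).
#' @param grid_spacing voxel edge for the van der Waals volume, nm.
#' @param rh_method `"kirkwood"` or `"empirical"`.
#' @param rg_rh_ratio Rg/Rh ratio for the empirical estimator (default 1.3,
#'   typical of disordered chains).
#' @param radii optional per-atom van der Waals radii (nm) overriding the
#'   Bondi lookup.
#' @return An object of class `compactness_result`: list with `V_vdw` (nm^3),
#'   `V_h` (nm^3), `R_h` (nm), `Rg` (nm) and `phi`. A warning is raised if
#'   the estimators combine to `phi > 1`.
#' @export
compactness <- function(snapshot, grid_spacing = 0.05,
                        rh_method = c("kirkwood", "empirical"),
                        rg_rh_ratio = 1.3, radii = NULL) {
  rh_method <- match.arg(rh_method)
  .stopifnot_scalar_pos(grid_spacing, "grid_spacing")
  X <- snapshot$coords
  if (is.null(dim(X))) X <- matrix(X, ncol = 3)
  if (is.null(radii)) radii <- vdw_radius(snapshot$elements)
  if (length(radii) == 1L) radii <- rep(radii, nrow(X))
  V_vdw <- .union_sphere_volume(X, radii, grid_spacing)
  Rg <- radius_of_gyration(snapshot)
  R_h <- if (nrow(X) == 1L) {
    radii[1]
  } else if (rh_method == "kirkwood") {
    .kirkwood_rh(X)
  } else {
    Rg / rg_rh_ratio
  }
  V_h <- 4 / 3 * pi * R_h^3
  phi <- V_vdw / V_h
  if (phi > 1)
    warning("compactness estimate exceeds 1 (phi = ", format(phi),
            "); check the Rh estimator")
  structure(list(V_vdw = V_vdw, V_h = V_h, R_h = R_h, Rg = Rg, phi = phi),
            class = "compactness_result")
}

#' @export
print.compactness_result <- function(x, ...) {
  cat(sprintf("compactness: phi = %.4f (V_vdw = %.3f nm^3, V_h = %.3f nm^3, Rg = %.3f nm)\n",
              x$phi, x$V_vdw, x$V_h, x$Rg))
  invisible(x)
}

#' Molar concentration of chains in a cubic box
#'
#' \eqn{C = n / (N_A L^3)}, reported in mM.
#'
#' @param n_chains number of chains (>= 1).
#' @param L cubic box edge, nm.
#' @return Concentration in mM.
#' @examples
#' box_concentration(24, 18)  # ~6.8 mM
#' @export
box_concentration <- function(n_chains, L) {
  if (any(n_chains < 1)) stop("n_chains must be >= 1")
  .stopifnot_scalar_pos(L, "L")
  n_chains * .conc_mM_per_inv_nm3 / L^3
}

#' Size-normalized configurational entropy difference upon mutation
#'
#' Configurational entropies of chains with different atom counts are not
#' directly comparable; the difference is taken per degree of freedom and
#' rescaled to the mutant's count:
#' \deqn{\Delta S = \left[\frac{S_{mut}}{3N_{mut}-6} - \frac{S_{wt}}{3N_{wt}-6}\right](3N_{mut}-6),}
#' and reported as \eqn{T \Delta S} in kcal/mol.
#'
#' @param S_mut,S_wt configurational entropies, kJ/mol/K.
#' @param N_mut,N_wt atom counts (>= 3).
#' @param T temperature, K (default 310).
#' @return \eqn{T \Delta S} in kcal/mol.
#' @export
entropy_mutation_difference <- function(S_mut, N_mut, S_wt, N_wt, T = 310) {
  if (N_mut < 3 || N_wt < 3) stop("atom counts must be >= 3")
  .stopifnot_scalar_pos(T, "T")
  dof_mut <- 3 * N_mut - 6
  dof_wt <- 3 * N_wt - 6
  dS <- (S_mut / dof_mut - S_wt / dof_wt) * dof_mut   # kJ/mol/K
  dS * T / 4.184                                       # kcal/mol
}
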