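#' Fractal scaling parameters of a condensate-forming molecule
#'
#' Bundles the four quantities that fully parameterize the iterative fractal
#' cluster-assembly model: the compactness (volume fraction) `phi`, defined as
#' the ratio of a molecule's van der Waals volume to its hydrodynamic
#' (apparent) volume; the interaction valency `n`, the average number of
#' simultaneously bound partners per molecule (an ensemble average, so not
#' necessarily an integer); the monomer apparent radius `R0` in nm; and the
#' monomer mass `M0` in kDa.
#'
#' @param phi compactness (volume fraction), in (0, 1].
#' @param n interaction valency, > 0; may be non-integer.
#' @param R0 monomer apparent radius, nm. A natural choice is the ensemble
#'   average radius of gyration of the monomer.
#' @param M0 monomer mass, kDa.
#' @return An object of class `scaling_params`.
#' @examples
#' scaling_params(phi = 0.638, n = 3.76, R0 = 1.60, M0 = 9.06)
#' @export
scaling_params <- function(phi, n, R0 = 1.0, M0 = 1.0) {
  .stopifnot_scalar_pos(phi, "phi")
  .stopifnot_scalar_pos(n, "n")
  .stopifnot_scalar_pos(R0, "R0")
  .stopifnot_scalar_pos(M0, "M0")
  if (phi > 1) stop("`phi` is a volume fraction and must be <= 1")
  structure(list(phi = phi, n = n, R0 = R0, M0 = M0), class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("scaling parameters: phi = %.4g, n = %.4g, R0 = %.4g nm, M0 = %.4g kDa\n",
              x$phi, x$n, x$R0, x$M0))
  cat(sprintf("  fractal dimension d_f = %.4f\n", fractal_dimension(x)))
  invisible(x)
}

#' Fractal dimension from compactness and valency
#'
#' The fractal dimension of the condensate is completely determined by the
#' molecular compactness `phi` and interaction valency `n`:
#' \deqn{d_f = 3 \ln(n+1) / \ln((n+1)/\phi).}
#' It is the exact slope of the log mass vs log size recursion of the
#' iterative assembly model, equals 3 when `phi = 1` (space filling), and is
#' strictly increasing in both parameters.
#'
#' @param params a [scaling_params()] object, or the compactness `phi` if `n`
#'   is given separately.
#' @param n interaction valency (only when `params` is given as `phi`).
#' @return The fractal dimension, a number in (0, 3].
#' @examples
#' fractal_dimension(scaling_params(phi = 0.638, n = 3.76)) # ~2.33
#' fractal_dimension(0.5, n = 1)                            # exactly 1.5
#' @export
fractal_dimension <- function(params, n = NULL) {
  if (!inherits(params, "scaling_params")) params <- scaling_params(params, n)
  if ((params$n + 1) / params$phi <= 1)
    stop("degenerate parameters: (n + 1)/phi must exceed 1")
  3 * log(params$n + 1) / log((params$n + 1) / params$phi)
}

.c0_mM <- function(params) {
  V0 <- 4 / 3 * pi * params$R0^3
  .conc_mM_per_inv_nm3 / V0
}

#' Iterate the fractal cluster-assembly recursion
#'
#' Starting from the monomer (iteration `i = 0`), each iteration groups
#' `n + 1` clusters of the previous generation into a new cluster that they
#' fill with volume fraction `phi`. The closed-form recursion gives, at
#' iteration `i`: molecule count \eqn{N_i = (n+1)^i}, apparent volume
#' \eqn{V_i = V_0 ((n+1)/\phi)^i}, radius \eqn{R_i = R_0 ((n+1)/\phi)^{i/3}},
#' mass \eqn{M_i = M_0 (n+1)^i} and effective molar concentration
#' \eqn{C_i = C_0 \phi^i} where \eqn{V_0 = (4/3)\pi R_0^3} and
#' \eqn{C_0 = 1/(N_A V_0)}.
#'
#' With non-integer valency (an ensemble average) the molecule counts are in
#' general non-integer; see [round_count()] for display.
#'
#' @param params a [scaling_params()] object.
#' @param i_max largest iteration index (>= 0).
#' @return A data frame of class `iteration_table` with columns `i`, `N`, `V`
#'   (nm^3), `R` (nm), `M` (kDa) and `C` (mM), one row per iteration
#'   `0..i_max`.
#' @examples
#' iterate_assembly(scaling_params(phi = 2/3, n = 4, R0 = 1.6, M0 = 9.06), 3)
#' @export
iterate_assembly <- function(params, i_max) {
  stopifnot(inherits(params, "scaling_params"))
  if (!is.numeric(i_max) || length(i_max) != 1L || i_max < 0 ||
      i_max != round(i_max))
    stop("`i_max` must be a non-negative integer")
  i <- 0:i_max
  g <- (params$n + 1) / params$phi   # per-iteration volume growth factor
  V0 <- 4 / 3 * pi * params$R0^3
  out <- data.frame(
    i = i,
    N = (params$n + 1)^i,
    V = V0 * g^i,
    R = params$R0 * g^(i / 3),
    M = params$M0 * (params$n + 1)^i,
    C = .c0_mM(params) * params$phi^i
  )
  class(out) <- c("iteration_table", "data.frame")
  out
}

#' Round a (generally non-integer) molecule count for display
#'
#' @param N numeric molecule counts from [iterate_assembly()].
#' @return integer counts (round half to even).
#' @export
round_count <- function(N) as.integer(round(N))

#' Fit the mass-size power law
#'
#' Ordinary least squares of `log10(M)` on `log10(R)`. On points generated by
#' [iterate_assembly()] the fit is exact and the slope equals the fractal
#' dimension; on measured cluster data it estimates it.
#'
#' @param points a data frame or matrix with columns `R` (nm) and `M` (kDa),
#'   or an `iteration_table`.
#' @return An object of class `power_law_fit` with fields `A` (slope = fractal
#'   dimension), `B` (intercept, log10 kDa at R = 1 nm) and `r2`.
#' @examples
#' fit_mass_size(iterate_assembly(scaling_params(0.638, 3.76, 1.6, 9.06), 5))
#' @export
fit_mass_size <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("R", "M") %in% names(points)))
    stop("`points` must have columns R and M")
  if (nrow(points) < 2) stop("need at least 2 points")
  if (any(points$R <= 0) || any(points$M <= 0))
    stop("R and M must be positive")
  if (length(unique(points$R)) < 2)
    stop("need at least 2 distinct R values")
  x <- log10(points$R)
  y <- log10(points$M)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(A = unname(stats::coef(fit)[2]),
                 B = unname(stats::coef(fit)[1]),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("mass-size power law: slope A (= d_f) = %.4f, intercept B = %.4f, r2 = %.6f\n",
              x$A, x$B, x$r2))
  invisible(x)
}

#' Invert a mass-size fit to compactness and valency
#'
#' Exact inverse of the forward map realized by [iterate_assembly()] +
#' [fit_mass_size()]: given the fitted slope `A` and intercept `B` together
#' with the monomer mass and van der Waals volume, recovers
#' \eqn{R_0 = 10^{(\log_{10} M_0 - B)/A}},
#' \eqn{\phi = V_{vdw} / ((4/3)\pi R_0^3)} and
#' \eqn{n = \exp(A \ln(1/\phi)/(3 - A)) - 1}.
#'
#' @param fit a `power_law_fit` (or a list with fields `A` and `B`).
#' @param M0 monomer mass, kDa.
#' @param V_vdw monomer van der Waals volume, nm^3.
#' @return A [scaling_params()] object.
#' @examples
#' p <- scaling_params(0.638, 3.76, R0 = 1.60, M0 = 9.06)
#' f <- fit_mass_size(iterate_assembly(p, 5))
#' invert_fit(f, M0 = 9.06, V_vdw = 0.638 * 4 / 3 * pi * 1.60^3)
#' @export
invert_fit <- function(fit, M0, V_vdw) {
  .stopifnot_scalar_pos(M0, "M0")
  .stopifnot_scalar_pos(V_vdw, "V_vdw")
  A <- fit$A
  B <- fit$B
  if (A <= 0 || A >= 3)
    stop("slope A must lie in (0, 3); got ", format(A))
  R0 <- 10^((log10(M0) - B) / A)
  phi <- V_vdw / (4 / 3 * pi * R0^3)
  if (phi <= 0 || phi > 1 + 1e-9)
    stop("recovered phi = ", format(phi),
         " outside (0, 1]: fit and vdW volume are inconsistent")
  phi <- min(phi, 1)
  n <- exp(A * log(1 / phi) / (3 - A)) - 1
  scaling_params(phi = phi, n = n, R0 = R0, M0 = M0)
}

#' Effective concentration at a given cluster size
#'
#' A hallmark of fractal organization is scale-dependent density: the
#' effective molar concentration of molecules inside a cluster of radius `R`
#' decays as a power law with exponent `d_f - 3`,
#' \eqn{C(R) = C_0 (R/R_0)^{d_f - 3}}, so condensates can combine high local
#' and low global concentration.
#'
#' @param params a [scaling_params()] object.
#' @param R cluster radius (nm), `R >= R0`; vectorized.
#' @return Effective molar concentration, mM.
#' @export
concentration_at_size <- function(params, R) {
  stopifnot(inherits(params, "scaling_params"))
  if (any(R < params$R0 * (1 - 1e-12)))
    stop("R must be >= R0 (", format(params$R0), " nm)")
  df <- fractal_dimension(params)
  .c0_mM(params) * (R / params$R0)^(df - 3)
}

#' Compactness-valency iso-curve at fixed condensate size and concentration
#'
#' For a condensate of fixed radius `R` and effective molar concentration `C`,
#' solves for each valency on `n_grid` the compactness `phi` under the fractal
#' model. The monomer apparent radius is tied to `phi` through the monomer van
#' der Waals volume, \eqn{R_0(\phi) = (3 V_{vdw} / (4\pi\phi))^{1/3}}, so the
#' curve depends on the molecule only through `M0` (or an explicit `V_vdw`).
#' Along a fixed (R, C) curve the compactness decreases non-linearly with
#' increasing valency.
#'
#' @param R condensate radius, nm (1 um = 1000 nm).
#' @param C effective molar concentration, mM.
#' @param M0 monomer mass, kDa; used to estimate the monomer van der Waals
#'   volume (~1.21 nm^3/kDa from typical protein density) when `V_vdw` is not
#'   given.
#' @param n_grid valencies at which to solve, all > 0.
#' @param V_vdw optional monomer van der Waals volume, nm^3.
#' @return A data frame with columns `n` and `phi`; `phi` is `NA` where no
#'   compactness in (0, 1] meets the demand.
#' @export
isocurve_phi_of_n <- function(R, C, M0, n_grid, V_vdw = NULL) {
  .stopifnot_scalar_pos(R, "R")
  .stopifnot_scalar_pos(C, "C")
  .stopifnot_scalar_pos(M0, "M0")
  if (any(n_grid <= 0)) stop("n_grid must be positive")
  if (is.null(V_vdw)) V_vdw <- .vdw_nm3_per_kda * M0
  conc <- function(phi, n) {
    R0 <- (3 * V_vdw / (4 * pi * phi))^(1 / 3)
    if (R < R0) return(NA_real_)
    df <- 3 * log(n + 1) / log((n + 1) / phi)
    (.conc_mM_per_inv_nm3 * phi / V_vdw) * (R / R0)^(df - 3)
  }
  phi_lo <- 1e-4
  phi <- vapply(n_grid, function(n) {
    f <- function(p) {
      v <- conc(p, n)
      if (is.na(v)) return(NA_real_)
      v - C
    }
    flo <- f(phi_lo)
    fhi <- f(1)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
    stats::uniroot(f, c(phi_lo, 1), tol = 1e-12)$root
  }, numeric(1))
  data.frame(n = n_grid, phi = phi)
}

#' Flory-Stockmayer percolation threshold
#'
#' Critical bond (contact) probability above which a system-spanning network
#' forms, for monomers each able to form `n` bonds:
#' \eqn{p_{crit} = 1/(n - 1)}.
#'
#' @param n number of bonds per monomer (valency), > 1; vectorized.
#' @return A data frame with columns `n`, `p_crit` and logical `clipped`
#'   flagging thresholds above 1 (never reachable: no percolation for
#'   n <= 2 at p <= 1).
#' @export
percolation_threshold <- function(n) {
  if (any(!is.finite(n)) || any(n <= 1))
    stop("valency must exceed 1 for a finite percolation threshold")
  p <- 1 / (n - 1)
  data.frame(n = n, p_crit = p, clipped = p > 1)
}
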