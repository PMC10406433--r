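#' Mean-square displacement series
#'
#' @param lag lag times, ns, strictly increasing.
#' @param msd mean-square displacements, nm^2, non-negative.
#' @param window fit window `c(t_lo, t_hi)` in ns. The defaults used for the
#'   crowded 24-copy systems are 20--40 ns; single-molecule analyses typically
#'   use 5--15 ns.
#' @return An object of class `msd_series`.
#' @export
msd_series <- function(lag, msd, window = c(20, 40)) {
  if (length(lag) != length(msd)) stop("lag and msd must have equal length")
  if (any(diff(lag) <= 0)) stop("lags must be strictly increasing")
  if (any(msd < 0)) stop("msd must be non-negative")
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be c(t_lo, t_hi) with t_lo < t_hi")
  structure(list(lag = lag, msd = msd, window = window), class = "msd_series")
}

#' Diffusion coefficient from an MSD fit
#'
#' Least-squares fit of `msd = c + 6 D tau` inside the fit window, with the
#' slope converted from nm^2/ns to um^2/s.
#'
#' @param series an [msd_series()].
#' @return List with `D` (um^2/s), `intercept` (nm^2) and `n_points`.
#' @export
fit_msd_diffusion <- function(series) {
  stopifnot(inherits(series, "msd_series"))
  sel <- series$lag >= series$window[1] & series$lag <= series$window[2]
  if (sum(sel) < 3) stop("fewer than 3 MSD points inside the fit window")
  fit <- stats::lm(series$msd[sel] ~ series$lag[sel])
  slope <- unname(stats::coef(fit)[2])            # nm^2 / ns
  list(D = slope * .msd_slope_to_um2s, intercept = unname(stats::coef(fit)[1]),
       n_points = sum(sel))
}

#' Finite-size correction of a diffusion coefficient
#'
#' Diffusion coefficients measured under cubic periodic boundaries
#' underestimate the infinite-dilution value due to hydrodynamic
#' self-interaction with periodic images. The correction is
#' \deqn{D_t = D_t^{PBC} + k_B T \xi / (6 \pi \eta L)}
#' with \eqn{\xi = 2.837297} for a cubic lattice.
#'
#' @param D_PBC diffusion coefficient under PBC, um^2/s.
#' @param T temperature, K.
#' @param eta shear viscosity of the medium, mPa s.
#' @param L box edge, nm.
#' @return Corrected diffusion coefficient, um^2/s.
#' @export
pbc_correct_diffusion <- function(D_PBC, T, eta, L) {
  .stopifnot_scalar_pos(T, "T")
  .stopifnot_scalar_pos(eta, "eta")
  .stopifnot_scalar_pos(L, "L")
  if (D_PBC < 0) stop("D_PBC must be non-negative")
  D_PBC + .yeh_hummer_factor * T / (eta * L)
}

#' Pressure-tensor fluctuation series
#'
#' Holds the six independent deviatoric pressure components
#' \eqn{P_{xy}, P_{xz}, P_{yz}, (P_{xx}-P_{yy})/2, (P_{xx}-P_{zz})/2,
#' (P_{yy}-P_{zz})/2}
#' sampled at a uniform time step, plus the box volume and temperature needed
#' by the Green-Kubo relation.
#'
#' @param time time stamps, ps, uniformly spaced.
#' @param P numeric matrix with 6 columns (bar), one row per time.
#' @param V box volume, nm^3.
#' @param T temperature, K.
#' @return An object of class `pressure_series`.
#' @export
pressure_series <- function(time, P, V, T) {
  P <- as.matrix(P)
  if (ncol(P) != 6) stop("six pressure components required")
  if (nrow(P) != length(time)) stop("one time stamp per row required")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) stop("time step must be uniform")
  .stopifnot_scalar_pos(V, "V")
  .stopifnot_scalar_pos(T, "T")
  structure(list(time = time, P = P, V = V, T = T, dt = dt[1]),
            class = "pressure_series")
}

# FFT autocorrelation with unbiased normalization, lags 0..lag_max
.acf_unbiased <- function(x, lag_max) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, rep(0, m - n)))
  s <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / m
  s[1:(lag_max + 1)] / (n - 0:lag_max)
}

# Double-exponential tail fit a*exp(-t/b) + cc*exp(-t/d). Decay times are
# bounded by the fit window: slower components are not identifiable from it
# and, fitted to the correlated ACF noise floor, they blow up the
# extrapolated integral.
.fit_acf_tail <- function(tt, C, dcap) {
  C0 <- max(abs(C[1]), 1e-300)
  span <- diff(range(tt))
  # log-linear anchor on the clearly positive early tail
  pos <- which(C > C0 * 1e-3)
  anchor <- c(C0, span / 4)
  if (length(pos) >= 3) {
    lf <- stats::lm(log(C[pos]) ~ tt[pos])
    sl <- unname(stats::coef(lf)[2])
    if (is.finite(sl) && sl < 0)
      anchor <- c(exp(unname(stats::coef(lf)[1])), min(max(-1 / sl, 1e-3), dcap))
  }
  starts <- list(c(anchor[1], anchor[2], 0, min(2 * anchor[2], dcap)),
                 c(0.7 * C0, span / 4, 0.3 * C0, span),
                 c(0.5 * C0, span / 8, 0.5 * C0, span / 2),
                 c(C0, span / 2, 0, span))
  best <- NULL
  for (st in starts) {
    f <- try(minpack.lm::nlsLM(
      C ~ a * exp(-t / b) + cc * exp(-t / d),
      data = data.frame(t = tt, C = C),
      start = list(a = st[1], b = min(max(st[2], 1e-3), dcap),
                   cc = st[3], d = min(max(st[4], 1e-3), dcap)),
      lower = c(-Inf, 1e-3, -Inf, 1e-3),
      upper = c(Inf, dcap, Inf, dcap),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(f, "try-error")) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(cf = stats::coef(f), rss = rss)
  }
  if (is.null(best)) {
    # stable single-exponential fallback from the log-linear anchor
    return(c(a = anchor[1], b = anchor[2], cc = 0, d = 1e-3))
  }
  best$cf
}

#' Green-Kubo shear viscosity from pressure fluctuations
#'
#' For each deviatoric pressure component the autocorrelation function is
#' estimated (FFT, unbiased normalization) and integrated: numerically on
#' `[0, t_numeric]` (trapezoid) and analytically from `t_numeric` to infinity
#' using a double-exponential fit of the tail on the `t_fit` window:
#' \eqn{\eta_{ij} = V/(k_B T) \int_0^\infty C_{ij}(t) dt}. The six components
#' are statistically equivalent, so the tail *shape* is fitted on their
#' pooled (averaged) autocorrelation, which suppresses the correlated noise
#' floor of the individual estimates; each component then scales that shape
#' to its own tail by least squares and is integrated separately. The
#' reported viscosity is the mean over the six per-component values
#' (averaging after integration).
#'
#' @param series a [pressure_series()].
#' @param t_numeric end of the numerically integrated range, ps.
#' @param t_fit tail-fit window `c(lo, hi)`, ps.
#' @return An object of class `viscosity_fit`: list with `eta` (mPa s),
#'   `eta_components` (length 6), `tail_fit` (pooled shape coefficients
#'   a, b, cc, d) and `tail_scales` (per-component shape amplitudes).
#' @export
green_kubo_viscosity <- function(series, t_numeric = 1, t_fit = c(1, 5)) {
  stopifnot(inherits(series, "pressure_series"))
  if (max(series$time) < t_fit[2])
    stop("series shorter than the tail-fit window")
  dt <- series$dt
  lag_max <- min(ceiling(t_fit[2] / dt), nrow(series$P) - 1L)
  tt <- (0:lag_max) * dt
  unit <- .gk_factor / series$T * series$V
  acfs <- vapply(1:6, function(j) .acf_unbiased(series$P[, j], lag_max),
                 numeric(lag_max + 1L))
  i_fit <- tt >= t_fit[1] & tt <= t_fit[2]
  cf <- .fit_acf_tail(tt[i_fit], rowMeans(acfs)[i_fit], dcap = t_fit[2])
  if (is.null(cf)) stop("pooled tail fit failed to converge")
  shape <- cf[["a"]] * exp(-tt[i_fit] / cf[["b"]]) +
    cf[["cc"]] * exp(-tt[i_fit] / cf[["d"]])
  I_shape <- cf[["a"]] * cf[["b"]] * exp(-t_numeric / cf[["b"]]) +
    cf[["cc"]] * cf[["d"]] * exp(-t_numeric / cf[["d"]])
  i_num <- tt <= t_numeric
  scales <- numeric(6)
  etas <- numeric(6)
  for (j in 1:6) {
    I_num <- pracma::trapz(tt[i_num], acfs[i_num, j])
    scales[j] <- sum(acfs[i_fit, j] * shape) / sum(shape^2)
    etas[j] <- unit * (I_num + scales[j] * I_shape)
  }
  structure(list(eta = mean(etas), eta_components = etas, tail_fit = cf,
                 tail_scales = scales),
            class = "viscosity_fit")
}

#' @export
print.viscosity_fit <- function(x, ...) {
  cat(sprintf("Green-Kubo viscosity: eta = %.4f mPa s (components %s)\n",
              x$eta, paste(sprintf("%.3f", x$eta_components), collapse = ", ")))
  invisible(x)
}

#' Integrate an explicitly known pressure autocorrelation function
#'
#' Companion to [green_kubo_viscosity()] for analytic checks: applies the same
#' trapezoid + fitted-tail integration to a directly supplied autocorrelation
#' curve instead of estimating it from a pressure series.
#'
#' @param t lag times, ps.
#' @param C autocorrelation values, bar^2.
#' @param V box volume, nm^3.
#' @param T temperature, K.
#' @param t_numeric,t_fit as in [green_kubo_viscosity()].
#' @return Viscosity in mPa s.
#' @export
viscosity_from_acf <- function(t, C, V, T, t_numeric = 1, t_fit = c(1, 5)) {
  .stopifnot_scalar_pos(V, "V")
  .stopifnot_scalar_pos(T, "T")
  i_num <- t <= t_numeric
  I_num <- pracma::trapz(t[i_num], C[i_num])
  i_fit <- t >= t_fit[1] & t <= t_fit[2]
  cf <- .fit_acf_tail(t[i_fit], C[i_fit], dcap = t_fit[2])
  if (is.null(cf)) stop("tail fit failed to converge")
  I_tail <- cf[["a"]] * cf[["b"]] * exp(-t_numeric / cf[["b"]]) +
    cf[["cc"]] * cf[["d"]] * exp(-t_numeric / cf[["d"]])
  .gk_factor / T * V * (I_num + I_tail)
}

#' Rescale a diffusion coefficient to experimental solvent viscosity
#'
#' \eqn{D_{pred} = D_t \, \eta_{sim} / \eta_{expt}} maps a value obtained in a
#' simulated solvent to the viscosity of the real one (0.69 mPa s for water
#' with 0.1 M salt at 310 K).
#'
#' @param D_t corrected diffusion coefficient, um^2/s.
#' @param eta_sim simulated solvent viscosity, mPa s.
#' @param eta_expt experimental solvent viscosity, mPa s (default 0.69).
#' @return Predicted diffusion coefficient, um^2/s.
#' @export
rescale_diffusion <- function(D_t, eta_sim, eta_expt = 0.69) {
  .stopifnot_scalar_pos(eta_sim, "eta_sim")
  .stopifnot_scalar_pos(eta_expt, "eta_expt")
  D_t * eta_sim / eta_expt
}
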