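#' @title 15N spin-relaxation analysis
#' @description Monoexponential decay fitting for R1 and R1rho intensity
#'   series, conversion of R1rho to R2 with the spin-lock tilt-angle
#'   (resonance-offset) correction, heteronuclear NOE ratios with error
#'   propagation, Monte Carlo rate errors, and effective rotational
#'   correlation times from the R2/R1 ratio.
#' @name relaxation_suite
NULL

# gyromagnetic ratios (rad s^-1 T^-1); only their ratio is used
.GAMMA_H <- 267.52218744e6
.GAMMA_N <- -27.116e6

#' Spectrometer context for relaxation analysis
#'
#' @param proton_mhz proton Larmor frequency in MHz (e.g. 700).
#' @return List with \code{proton_mhz} and the 15N Larmor frequency
#'   \code{nu_n_hz} in Hz, derived via the gyromagnetic-ratio magnitudes.
#' @export
spectrometer_context <- function(proton_mhz) {
  stopifnot(proton_mhz > 0)
  nu_n <- proton_mhz * 1e6 * abs(.GAMMA_N / .GAMMA_H)
  ratio <- nu_n / (proton_mhz * 1e6)
  stopifnot(abs(ratio - 0.10137) / 0.10137 < 1e-3)
  list(proton_mhz = proton_mhz, nu_n_hz = nu_n)
}

#' Sampling time grids for relaxation decays
#'
#' The default relaxation delay grids: 40, 88, 136, 192, 288, 392, 592,
#' 688, 792 and 992 ms for R1, and 30, 60, 120, 150, 180 and 210 ms for
#' R1rho.
#' @param experiment \code{"r1"} or \code{"r1rho"}.
#' @return numeric vector of times in seconds.
#' @export
relaxation_time_grid <- function(experiment = c("r1", "r1rho")) {
  experiment <- match.arg(experiment)
  switch(experiment,
         r1    = c(40, 88, 136, 192, 288, 392, 592, 688, 792, 992) / 1000,
         r1rho = c(30, 60, 120, 150, 180, 210) / 1000)
}

#' Fit a monoexponential relaxation decay
#'
#' Least-squares fit of \eqn{I(t) = I_0 e^{-R t}}. Initialization is
#' deterministic: \eqn{I_0} from the maximum intensity and \eqn{R} from a
#' log-linear regression on the positive intensities, refined by
#' Levenberg-Marquardt. A fitted negative rate is flagged, not clipped.
#'
#' @param times time points in seconds (>= 3, strictly increasing).
#' @param intensities peak intensities (arbitrary units).
#' @return List of class \code{"decay_fit"} with \code{I0}, \code{R}
#'   (s^-1), \code{I0_err}, \code{R_err} (asymptotic standard errors),
#'   \code{cov} (2x2 covariance), \code{residuals}, \code{flagged_negative}.
#' @export
fit_exponential_decay <- function(times, intensities) {
  stopifnot(length(times) >= 3L, all(diff(times) > 0),
            length(intensities) == length(times))
  pos <- intensities > 0
  if (sum(pos) < 2L) stop("fewer than 2 positive intensities; cannot initialize")
  init_fit <- stats::lm(log(intensities[pos]) ~ times[pos])
  R0 <- -unname(stats::coef(init_fit)[2])
  I00 <- max(intensities)
  model <- function(p, t) p[1] * exp(-p[2] * t)
  res_fn <- function(p) intensities - model(p, times)
  fit <- minpack.lm::nls.lm(par = c(I00, R0), fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 5))
    stop(sprintf("decay fit did not converge (info=%d; init I0=%.4g R=%.4g)",
                 fit$info, I00, R0))
  p <- fit$par
  dof <- length(times) - 2L
  s2 <- if (dof > 0) sum(fit$fvec^2) / dof else 0
  covmat <- tryCatch(s2 * solve(fit$hessian), error = function(e)
    matrix(NA_real_, 2, 2))
  structure(list(I0 = p[1], R = p[2],
                 I0_err = sqrt(abs(covmat[1, 1])),
                 R_err = sqrt(abs(covmat[2, 2])),
                 cov = covmat, residuals = fit$fvec,
                 flagged_negative = p[2] < -sqrt(.Machine$double.eps)),
            class = "decay_fit")
}

#' Convert R1rho to R2 with the spin-lock tilt-angle correction
#'
#' \eqn{R_2 = R_{1\rho} + (R_{1\rho} - R_1)\tan^2\theta} with tilt angle
#' \eqn{\theta = \arctan(\Delta\nu/\nu_1)}, where \eqn{\Delta\nu} is the
#' resonance offset and \eqn{\nu_1} the spin-lock field strength (both Hz).
#' On resonance (\eqn{\Delta\nu = 0}) this reduces to \eqn{R_2 = R_{1\rho}}.
#'
#' @param r1,r1rho rates in s^-1 (vectorized).
#' @param offset_hz resonance offset \eqn{\Delta\nu} in Hz.
#' @param spinlock_hz spin-lock field strength \eqn{\nu_1} in Hz
#'   (default 1433).
#' @return R2 in s^-1.
#' @export
r2_from_r1rho <- function(r1, r1rho, offset_hz, spinlock_hz = 1433) {
  stopifnot(spinlock_hz > 0, all(is.finite(r1)), all(is.finite(r1rho)))
  if (any(abs(offset_hz) / spinlock_hz > 3))
    warning("offset exceeds 3x the spin-lock field; correction unreliable at large tilt")
  theta <- atan(offset_hz / spinlock_hz)
  r1rho + (r1rho - r1) * tan(theta)^2
}

#' Heteronuclear NOE with noise propagation
#'
#' NOE = I_sat / I_ref from interleaved spectra recorded with and without
#' proton saturation; the uncertainty propagates the spectral noise of
#' both peak heights.
#'
#' @param i_sat,i_ref peak intensities with / without saturation.
#' @param noise_sd spectral noise standard deviation (same units).
#' @return List with \code{noe}, \code{noe_err}, and \code{unreliable}
#'   (TRUE when |I_ref| is within 3 noise sd of zero).
#' @export
het_noe <- function(i_sat, i_ref, noise_sd) {
  if (any(i_ref == 0)) stop("reference intensity is zero")
  noe <- i_sat / i_ref
  err <- abs(noe) * sqrt((noise_sd / i_sat)^2 + (noise_sd / i_ref)^2)
  list(noe = noe, noe_err = err, unreliable = abs(i_ref) < 3 * noise_sd)
}

#' Monte Carlo error of a fitted relaxation rate
#'
#' Refits \code{n_runs} copies of the decay with Gaussian noise (sd =
#' \code{noise_sd}) added independently to each intensity, and returns the
#' standard deviation of the fitted rates. Reproducible for a fixed seed.
#'
#' @param times,intensities the decay series.
#' @param noise_sd spectral noise sd (intensity units).
#' @param n_runs number of Monte Carlo runs (default 100).
#' @param seed integer RNG seed (required).
#' @return List with \code{R_sd}, \code{rates} (fitted rates per run),
#'   \code{n_failed}.
#' @export
monte_carlo_errors <- function(times, intensities, noise_sd, n_runs = 100L,
                               seed) {
  stopifnot(n_runs >= 2L, noise_sd >= 0, !missing(seed))
  set.seed(as.integer(seed))
  rates <- rep(NA_real_, n_runs)
  for (k in seq_len(n_runs)) {
    pert <- intensities + stats::rnorm(length(intensities), 0, noise_sd)
    f <- tryCatch(fit_exponential_decay(times, pert), error = function(e) NULL)
    if (!is.null(f)) rates[k] <- f$R
  }
  n_failed <- sum(is.na(rates))
  if (n_failed > 0.2 * n_runs)
    stop(sprintf("%d of %d Monte Carlo refits failed", n_failed, n_runs))
  list(R_sd = stats::sd(rates, na.rm = TRUE), rates = rates,
       n_failed = n_failed)
}

#' Effective rotational correlation time from the R2/R1 ratio
#'
#' In the absence of slow (micro-millisecond) exchange the ratio R2/R1
#' yields an effective residue-specific reorientational tumbling time that
#' is independent of the motional amplitude:
#' \eqn{\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6 R_2/R_1 - 7}}, with
#' \eqn{\nu_N} the 15N resonance frequency in Hz. When the radicand is
#' negative (R2/R1 < 7/6, the fast limit) the value is absent.
#'
#' @param r1,r2 rates in s^-1 (vectorized).
#' @param ctx a [spectrometer_context()].
#' @return List with \code{tau_c} (seconds; NA in the fast limit) and
#'   \code{fast_limit} (logical).
#' @export
tumbling_time <- function(r1, r2, ctx) {
  stopifnot(all(r1 > 0))
  radicand <- 6 * r2 / r1 - 7
  fast <- radicand < 0
  tau <- ifelse(fast, NA_real_, sqrt(pmax(radicand, 0)) / (4 * pi * ctx$nu_n_hz))
  list(tau_c = tau, fast_limit = fast)
}

#' Chain-average tumbling time
#'
#' Two conventions are exposed: the mean of per-residue tau_c over residues
#' passing the radicand check (\code{"per_residue"}), and tau_c of the
#' chain-averaged rates (\code{"mean_rates"}). The two typically differ by
#' about a percent on disordered chains.
#'
#' @param r1,r2 per-residue rates in s^-1.
#' @param ctx a [spectrometer_context()].
#' @param method averaging convention.
#' @return tau_c in seconds.
#' @export
chain_tumbling_time <- function(r1, r2, ctx,
                                method = c("per_residue", "mean_rates")) {
  method <- match.arg(method)
  if (method == "per_residue") {
    tt <- tumbling_time(r1, r2, ctx)
    mean(tt$tau_c, na.rm = TRUE)
  } else {
    tumbling_time(mean(r1), mean(r2), ctx)$tau_c
  }
}

#' Per-residue relaxation records from decay tables
#'
#' Convenience pipeline: fits R1 and R1rho decays per residue, applies the
#' offset correction to obtain R2, optionally computes NOEs and Monte
#' Carlo errors, and extracts tumbling times.
#'
#' @param r1_decays,r1rho_decays \code{long_table}s (series_key = residue,
#'   x = time s, y = intensity).
#' @param offsets_hz named numeric vector of per-residue resonance offsets
#'   (names = residue numbers); residues absent default to 0 Hz.
#' @param spinlock_hz spin-lock strength in Hz.
#' @param ctx a [spectrometer_context()].
#' @param noise_sd spectral noise sd for Monte Carlo errors (NULL to skip).
#' @param n_runs Monte Carlo runs.
#' @param seed RNG seed (required when \code{noise_sd} given).
#' @return data.frame: residue, R1, R1_err, R1rho, R1rho_err, R2, tau_c_ns,
#'   fast_limit.
#' @export
relaxation_records <- function(r1_decays, r1rho_decays, offsets_hz = NULL,
                               spinlock_hz = 1433, ctx = spectrometer_context(700),
                               noise_sd = NULL, n_runs = 100L, seed = NULL) {
  residues <- intersect(unique(r1_decays$series_key),
                        unique(r1rho_decays$series_key))
  out <- lapply(residues, function(res) {
    d1 <- r1_decays[r1_decays$series_key == res, ]
    dr <- r1rho_decays[r1rho_decays$series_key == res, ]
    f1 <- fit_exponential_decay(d1$x, d1$y)
    fr <- fit_exponential_decay(dr$x, dr$y)
    e1 <- f1$R_err; er <- fr$R_err
    if (!is.null(noise_sd)) {
      stopifnot(!is.null(seed))
      e1 <- monte_carlo_errors(d1$x, d1$y, noise_sd, n_runs,
                               seed = seed + as.integer(as.numeric(res)))$R_sd
      er <- monte_carlo_errors(dr$x, dr$y, noise_sd, n_runs,
                               seed = seed + as.integer(as.numeric(res)) + 1L)$R_sd
    }
    off <- if (!is.null(offsets_hz) && res %in% names(offsets_hz))
      offsets_hz[[res]] else 0
    r2 <- r2_from_r1rho(f1$R, fr$R, off, spinlock_hz)
    tt <- tumbling_time(f1$R, r2, ctx)
    data.frame(residue = as.numeric(res), R1 = f1$R, R1_err = e1,
               R1rho = fr$R, R1rho_err = er, R2 = r2,
               tau_c_ns = tt$tau_c * 1e9, fast_limit = tt$fast_limit)
  })
  do.call(rbind, out)
}
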