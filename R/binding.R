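#' @title 1:1 binding models: SPR kinetics, steady state, and
#'   depletion-corrected isotherms
#' @description Forward model and global fits for 1:1 Langmuir interaction
#'   kinetics measured by surface plasmon resonance, steady-state
#'   (equilibrium response) fits, and equilibrium binding isotherms with
#'   explicit ligand depletion as measured by microscale thermophoresis.
#' @name binding_affinity
NULL

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Association phase (t <= t_a): \eqn{R(t) = R_{eq}(1 - e^{-k_{obs} t})}
#' with \eqn{k_{obs} = k_a C + k_d} and
#' \eqn{R_{eq} = C R_{max}/(C + K_D)}, \eqn{K_D = k_d/k_a}.
#' Dissociation phase (t > t_a): \eqn{R(t) = R(t_a) e^{-k_d (t - t_a)}}.
#'
#' @param ka association rate constant (M^-1 s^-1).
#' @param kd dissociation rate constant (s^-1).
#' @param rmax maximal response (RU).
#' @param conc analyte concentration (M).
#' @param times time points (s).
#' @param t_a association end time (s), default 120.
#' @return response in RU at each time point.
#' @export
model_sensorgram <- function(ka, kd, rmax, conc, times, t_a = 120) {
  stopifnot(ka > 0, kd >= 0, rmax > 0, conc >= 0)
  kobs <- ka * conc + kd
  req <- ka * conc * rmax / kobs
  r_ta <- req * (1 - exp(-kobs * t_a))
  ifelse(times <= t_a,
         req * (1 - exp(-kobs * times)),
         r_ta * exp(-kd * (times - t_a)))
}

#' Global kinetic fit of a 1:1 interaction model
#'
#' Fits association and dissociation phases of all concentration series
#' simultaneously, sharing ka and kd (and Rmax unless
#' \code{share_rmax = FALSE}). Initialization is deterministic: kd from a
#' log-linear regression on the dissociation tails, per-curve kobs from
#' single-exponential association fits, and ka from the slope of kobs
#' versus concentration. KD = kd/ka is reported with a delta-method
#' standard error.
#'
#' @param data data.frame with columns \code{conc} (M), \code{time} (s),
#'   \code{response} (RU).
#' @param t_a association end time (s).
#' @param share_rmax share one Rmax across curves (default TRUE).
#' @return list of class \code{"kinetic_fit"}: \code{ka}, \code{kd},
#'   \code{rmax} (vector if per-curve), \code{KD}, \code{ka_err},
#'   \code{kd_err}, \code{KD_err}, \code{kobs}, \code{req} (per
#'   concentration), \code{residual_sd}, \code{warning} (character or NA).
#' @export
fit_kinetic_1to1 <- function(data, t_a = 120, share_rmax = TRUE) {
  stopifnot(all(c("conc", "time", "response") %in% names(data)))
  concs <- sort(unique(data$conc))
  if (length(concs) < 2L) stop("global kinetic fit needs >= 2 concentrations")
  if (!any(data$time > t_a)) stop("no dissociation phase present")

  # --- deterministic initialization ---
  kd0s <- vapply(concs, function(cc) {
    d <- data[data$conc == cc & data$time > t_a & data$response > 0, ]
    if (nrow(d) < 3L) return(NA_real_)
    -unname(stats::coef(stats::lm(log(d$response) ~ d$time))[2])
  }, numeric(1))
  kd0 <- stats::median(kd0s, na.rm = TRUE)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- 1e-3
  # kobs from the half-rise time of each association curve
  kobs0 <- vapply(concs, function(cc) {
    d <- data[data$conc == cc & data$time <= t_a, ]
    plateau <- max(d$response)
    if (plateau <= 0) return(NA_real_)
    t_half <- suppressWarnings(min(d$time[d$response >= plateau / 2 &
                                            d$time > 0]))
    if (!is.finite(t_half)) return(NA_real_)
    log(2) / t_half
  }, numeric(1))
  ok <- is.finite(kobs0) & kobs0 > 0
  ka0 <- NA_real_
  if (sum(ok) >= 2L)
    ka0 <- unname(stats::coef(stats::lm(kobs0[ok] ~ concs[ok]))[2])
  if (!is.finite(ka0) || ka0 <= 0)
    ka0 <- max(kobs0[ok][which.max(concs[ok])] / max(concs[ok]),
               kd0 / stats::median(concs), 1e-6, na.rm = TRUE)
  rmax0 <- max(data$response) * 1.2

  n_rmax <- if (share_rmax) 1L else length(concs)
  # parameters on log scale for positivity
  res_fn <- function(lp) {
    ka <- exp(lp[1]); kd <- exp(lp[2]); rmax <- exp(lp[-(1:2)])
    unlist(lapply(seq_along(concs), function(i) {
      d <- data[data$conc == concs[i], ]
      rm_i <- if (share_rmax) rmax[1] else rmax[i]
      d$response - model_sensorgram(ka, kd, rm_i, concs[i], d$time, t_a)
    }))
  }
  # deterministic multi-start over a small (ka, kd) factor grid guards
  # against local minima when the initializer is far off
  starts <- expand.grid(fka = c(1, 0.1, 10), fkd = c(1, 0.1, 10))
  fit <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- log(c(ka0 * starts$fka[s], kd0 * starts$fkd[s],
                  rep(rmax0, n_rmax)))
    cand <- minpack.lm::nls.lm(par = par0, fn = res_fn,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-14, ptol = 1e-14))
    if (cand$info == 0) next
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  if (is.null(fit))
    stop(sprintf("kinetic fit did not converge (init ka=%.3g kd=%.3g)", ka0, kd0))
  ka <- exp(fit$par[1]); kd <- exp(fit$par[2]); rmax <- exp(fit$par[-(1:2)])
  dof <- max(nrow(data) - length(fit$par), 1L)
  s2 <- sum(fit$fvec^2) / dof
  covl <- tryCatch(s2 * solve(fit$hessian), error = function(e)
    matrix(NA_real_, length(fit$par), length(fit$par)))
  # delta method back to natural scale: se(x) = x * se(log x)
  ka_err <- ka * sqrt(abs(covl[1, 1]))
  kd_err <- kd * sqrt(abs(covl[2, 2]))
  # KD = kd/ka; var(log KD) = var(log kd) + var(log ka) - 2 cov
  vlogKD <- covl[2, 2] + covl[1, 1] - 2 * covl[1, 2]
  KD <- kd / ka
  KD_err <- KD * sqrt(abs(vlogKD))
  warn <- NA_character_
  if (kd < 1e-8) warn <- "no measurable dissociation decay; kd non-identifiable"
  if (all(concs > 100 * KD) || all(concs < KD / 100))
    warn <- "concentration series far from KD; fit poorly identifiable"
  structure(list(ka = ka, kd = kd, rmax = rmax, KD = KD,
                 ka_err = ka_err, kd_err = kd_err, KD_err = KD_err,
                 kobs = ka * concs + kd,
                 req = concs * (if (share_rmax) rmax[1] else rmax) / (concs + KD),
                 conc = concs, residual_sd = sqrt(s2), warning = warn),
            class = "kinetic_fit")
}

#' Steady-state (equilibrium response) fit
#'
#' Extracts the equilibrium response Req per concentration as the mean
#' response over the last \code{plateau_window} seconds of the association
#' phase, requiring the response to vary by less than 5% across the
#' window, and fits \eqn{R_{eq} = R_{max} C/(C + K_D)}.
#'
#' @param data sensorgram data.frame (\code{conc}, \code{time},
#'   \code{response}).
#' @param t_a association end time (s).
#' @param plateau_window window length before t_a used as plateau (s).
#' @return list: \code{KD}, \code{rmax}, \code{KD_err}, \code{rmax_err},
#'   \code{req} (data.frame conc/req), \code{excluded} concentrations.
#' @export
fit_steady_state <- function(data, t_a = 120, plateau_window = 20) {
  concs <- sort(unique(data$conc))
  req <- excluded <- numeric(0)
  keep <- logical(length(concs))
  reqs <- rep(NA_real_, length(concs))
  for (i in seq_along(concs)) {
    d <- data[data$conc == concs[i] & data$time <= t_a &
                data$time >= t_a - plateau_window, ]
    if (!nrow(d)) next
    spread <- diff(range(d$response))
    lvl <- mean(d$response)
    if (lvl > 0 && spread / lvl < 0.05) { keep[i] <- TRUE; reqs[i] <- lvl }
  }
  if (any(!keep))
    warning("curve(s) excluded (plateau criterion unmet): ",
            paste(concs[!keep], collapse = ", "))
  concs_k <- concs[keep]; reqs_k <- reqs[keep]
  if (length(concs_k) < 2L) stop("steady-state fit needs >= 2 plateaued concentrations")
  par0 <- log(c(KD = stats::median(concs_k), rmax = max(reqs_k) * 1.5))
  res_fn <- function(lp)
    reqs_k - exp(lp[2]) * concs_k / (concs_k + exp(lp[1]))
  fit <- minpack.lm::nls.lm(par = par0, fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  KD <- unname(exp(fit$par[1])); rmax <- unname(exp(fit$par[2]))
  dof <- max(length(reqs_k) - 2L, 1L)
  s2 <- sum(fit$fvec^2) / dof
  covl <- tryCatch(s2 * solve(fit$hessian), error = function(e)
    matrix(NA_real_, 2, 2))
  list(KD = KD, rmax = rmax,
       KD_err = KD * sqrt(abs(covl[1, 1])),
       rmax_err = rmax * sqrt(abs(covl[2, 2])),
       req = data.frame(conc = concs_k, req = reqs_k),
       excluded = concs[!keep])
}

#' Fraction bound with ligand depletion
#'
#' Exact 1:1 equilibrium solution used when the labeled species
#' concentration is not negligible relative to KD:
#' \deqn{FB = \frac{(L_0 + T_0 + K_D) - \sqrt{(L_0 + T_0 + K_D)^2 -
#'   4 L_0 T_0}}{2 L_0}}
#' As \eqn{L_0 \to 0} this reduces to the hyperbolic
#' \eqn{T_0/(T_0 + K_D)}.
#'
#' @param t0 titrant concentrations (M).
#' @param l0 labeled-species concentration (M).
#' @param kd_m dissociation constant (M).
#' @return fraction bound in \[0, 1\].
#' @export
fraction_bound <- function(t0, l0, kd_m) {
  stopifnot(l0 > 0, kd_m >= 0, all(t0 >= 0))
  s <- l0 + t0 + kd_m
  fb <- (s - sqrt(pmax(s^2 - 4 * l0 * t0, 0))) / (2 * l0)
  pmin(pmax(fb, 0), 1)
}

#' Fit a depletion-corrected equilibrium binding isotherm
#'
#' Fits \eqn{S(T_0) = S_{free} + (S_{bound} - S_{free}) FB(T_0; L_0, K_D)}
#' to a dose-response series (e.g. a 16-point two-fold dilution ladder
#' against 10 nM labeled species). The signal-to-noise ratio is the fitted
#' amplitude over the residual standard deviation.
#'
#' @param t0 titrant concentrations (M).
#' @param signal per-point signal (arbitrary units).
#' @param l0 labeled-species concentration (M), default 10e-9.
#' @return list of class \code{"isotherm_fit"}: \code{KD}, \code{KD_err},
#'   \code{s_free}, \code{s_bound}, \code{fb} (per point),
#'   \code{signal_to_noise}, \code{low_confidence}.
#' @export
fit_equilibrium_isotherm <- function(t0, signal, l0 = 10e-9) {
  stopifnot(length(t0) == length(signal), l0 > 0)
  if (length(t0) < 8L) stop("isotherm fit needs >= 8 points")
  pos <- t0[t0 > 0]
  if (max(pos) / min(pos) < 100) stop("titrant range must span >= 100-fold")
  ord <- order(t0)
  s_lo <- mean(signal[ord][seq_len(2)])
  s_hi <- mean(signal[rev(ord)][seq_len(2)])
  kd0 <- stats::median(t0[t0 > 0])
  par0 <- c(log(kd0), s_lo, s_hi)
  res_fn <- function(p)
    signal - (p[2] + (p[3] - p[2]) * fraction_bound(t0, l0, exp(p[1])))
  fit <- minpack.lm::nls.lm(par = par0, fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  KD <- exp(fit$par[1]); s_free <- fit$par[2]; s_bound <- fit$par[3]
  dof <- max(length(t0) - 3L, 1L)
  resid_sd <- sqrt(sum(fit$fvec^2) / dof)
  covl <- tryCatch(sum(fit$fvec^2) / dof * solve(fit$hessian),
                   error = function(e) matrix(NA_real_, 3, 3))
  amp <- abs(s_bound - s_free)
  snr <- if (resid_sd > 0) amp / resid_sd else Inf
  structure(list(KD = KD, KD_err = KD * sqrt(abs(covl[1, 1])),
                 s_free = s_free, s_bound = s_bound,
                 fb = fraction_bound(t0, l0, KD),
                 signal_to_noise = snr,
                 low_confidence = is.finite(snr) && snr < 3),
            class = "isotherm_fit")
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param ka association rate constant (M^-1 s^-1), must be positive.
#' @param kd dissociation rate constant (s^-1).
#' @return KD = kd/ka in M.
#' @export
kd_from_rates <- function(ka, kd) {
  if (any(ka <= 0)) stop("ka must be positive")
  kd / ka
}
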