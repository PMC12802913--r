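#' Unit bond-vector time series
#'
#' Carrier for per-residue N-H orientation series, the input to the
#' relaxometry chain. Times are in seconds (SI units are used throughout the
#' spin-physics layer).
#'
#' @param residue_id integer residue id.
#' @param vectors n_frames x 3 matrix of unit vectors.
#' @param dt frame spacing, seconds.
#' @return object of class \code{"vector_series"}.
#' @export
vector_series <- function(residue_id, vectors, dt) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L) .stopf("vectors must be an n x 3 matrix")
  if (!.is_scalar(dt) || dt <= 0) .stopf("dt must be a positive time in seconds")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-6))
    .stopf("vectors must be unit length (max |norm-1| = %.2e)", max(abs(nrm - 1)))
  structure(list(residue_id = as.integer(residue_id), vectors = vectors, dt = dt),
            class = "vector_series")
}

#' @export
print.vector_series <- function(x, ...) {
  cat(sprintf("vector_series: residue %d, %d frames, dt = %.3g ps\n",
              x$residue_id, nrow(x$vectors), x$dt * 1e12))
  invisible(x)
}

#' Chunk-averaged P2 orientational autocorrelation function
#'
#' Computes C(tau) = < P2( u(t) . u(t+tau) ) >, the correlation kernel of
#' dipole-dipole relaxation, with P2(x) = (3x^2 - 1)/2. The series is split
#' into \code{n_chunks} equal segments; C(tau) is computed per chunk (all valid
#' time origins, evaluated exactly via FFT of the six quadratic components
#' u_a u_b) and averaged across chunks, with the standard error across chunks
#' reported per lag. Chunking both tempers slow-convergence bias and yields an
#' honest uncertainty estimate.
#'
#' @param series a \code{\link{vector_series}}.
#' @param n_chunks number of equal-length chunks (default 20).
#' @param max_lag_fraction lags are limited to this fraction of the chunk
#'   length, in (0, 1].
#' @return object of class \code{"corr_fn"}: \code{lags} (seconds),
#'   \code{values}, \code{se}, \code{n_chunks}.
#' @export
p2_autocorrelation <- function(series, n_chunks = 20, max_lag_fraction = 0.5) {
  stopifnot(inherits(series, "vector_series"))
  if (!.is_count(n_chunks)) .stopf("n_chunks must be a positive integer")
  if (!.is_scalar(max_lag_fraction) || max_lag_fraction <= 0 || max_lag_fraction > 1)
    .stopf("max_lag_fraction must lie in (0, 1]")
  n <- nrow(series$vectors)
  if (n < 2L * n_chunks)
    .stopf("series has %d frames; need at least 2 per chunk (%d chunks)", n, n_chunks)
  len <- n %/% n_chunks
  max_lag <- floor(max_lag_fraction * (len - 1L))
  if (max_lag < 1L) .stopf("chunks of %d frames are too short for the requested lags", len)
  cmat <- matrix(NA_real_, n_chunks, max_lag + 1L)
  for (k in seq_len(n_chunks)) {
    idx <- ((k - 1L) * len + 1L):(k * len)
    cmat[k, ] <- .p2_acf(series$vectors[idx, , drop = FALSE], max_lag)
  }
  values <- colMeans(cmat)
  se <- if (n_chunks > 1L) apply(cmat, 2L, stats::sd) / sqrt(n_chunks)
        else rep(NA_real_, max_lag + 1L)
  structure(list(lags = (0:max_lag) * series$dt, values = values, se = se,
                 n_chunks = n_chunks),
            class = "corr_fn")
}

# exact all-origin P2 autocorrelation of one chunk:
# P2(u.u') = (3/2) sum_ab (u_a u_b)(u'_a u'_b) - 1/2
.p2_acf <- function(v, max_lag) {
  n <- nrow(v)
  comps <- cbind(v[, 1]^2, v[, 2]^2, v[, 3]^2,
                 v[, 1] * v[, 2], v[, 1] * v[, 3], v[, 2] * v[, 3])
  w <- c(1, 1, 1, 2, 2, 2)
  raw <- numeric(max_lag + 1L)
  for (j in 1:6) raw <- raw + w[j] * .lagged_sums_fft(comps[, j], max_lag)
  counts <- n - 0:max_lag
  1.5 * raw / counts - 0.5
}

#' Fit a sum of up to three exponentials to a correlation function
#'
#' Weighted nonlinear least squares of C(t) = sum_i A_i exp(-t / tau_i) with
#' A_i >= 0, sum A_i <= 1, tau_i > 0, started from several log-spaced
#' time-constant triplets; the best start is kept (lowest weighted residual,
#' ties broken by the smallest sum |log tau_i| for reproducibility). Models
#' with 1 .. \code{n_exp} components are fitted and the component count is
#' chosen by BIC on the weighted residuals, which suppresses spurious
#' slow components that would otherwise inflate J(0) out of sampling noise
#' in the correlation tail. Components with fitted amplitude below
#' \code{prune_tol} are pruned. A plateau is representable as a component
#' with tau at the upper bound (10^4 x the maximum lag). Any amplitude
#' deficit 1 - sum A_i is reported as an unresolved fast component
#' (\code{fast_deficit}).
#'
#' @param corr a \code{\link{p2_autocorrelation}} result, or a list with
#'   \code{lags} and \code{values} (and optionally \code{se}).
#' @param n_exp maximum number of components (default 3).
#' @param prune_tol amplitude below which a component is dropped.
#' @return object of class \code{"triexp_fit"}: \code{A}, \code{tau}
#'   (ascending, seconds), \code{residual} (weighted RSS), \code{fast_deficit}.
#' @export
fit_triexponential <- function(corr, n_exp = 3, prune_tol = 1e-4) {
  t <- corr$lags; y <- corr$values
  if (length(t) < 10L) .stopf("need at least 10 lag points to fit")
  se <- corr$se
  wts <- if (!is.null(se) && all(is.finite(se[-1])) && any(se > 0)) {
    floorv <- 0.2 * stats::median(se[se > 0])
    1 / pmax(se, floorv)^2
  } else rep(1, length(t))
  tmax <- max(t); tmin <- max(min(t[t > 0]), tmax * 1e-6)
  npt <- length(t)
  base_taus <- list(c(0.01, 0.1, 1), c(0.001, 0.03, 1), c(0.1, 1, 10),
                    c(0.01, 0.3, 30), c(0.05, 0.5, 5), c(0.002, 0.2, 100))
  fit_k <- function(k) {
    lo <- c(rep(0, k), rep(log(tmin / 10), k))
    hi <- c(rep(1.2, k), rep(log(tmax * 1e4), k))
    obj <- function(p) {
      a <- p[1:k]; tau <- exp(p[(k + 1):(2 * k)])
      pred <- rowSums(exp(outer(t, -1 / tau)) * rep(a, each = npt))
      sum(wts * (y - pred)^2) + 1e4 * max(0, sum(a) - 1)^2
    }
    fits <- list()
    for (bt in base_taus) {
      p0 <- c(rep(max(y[1], 0.5) / k, k), log(bt[seq_len(k)] * tmax))
      f <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B", lower = lo,
                                 upper = hi, control = list(maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
    if (!length(fits)) return(NULL)
    vals <- vapply(fits, `[[`, numeric(1), "value")
    best <- which(vals <= min(vals) * (1 + 1e-9))
    if (length(best) > 1L) {
      tie <- vapply(fits[best], function(f) sum(abs(f$par[(k + 1):(2 * k)])),
                    numeric(1))
      best <- best[which.min(tie)]
    } else best <- best[1]
    fits[[best]]
  }
  cand <- list()
  for (k in seq_len(n_exp)) {
    f <- fit_k(k)
    if (is.null(f)) next
    rss <- max(f$value, .Machine$double.xmin)
    cand[[length(cand) + 1L]] <-
      list(k = k, par = f$par, rss = f$value,
           bic = npt * log(rss / npt) + 2 * k * log(npt))
  }
  if (!length(cand)) .stopf("multi-exponential fit failed to converge from all starts")
  pick <- cand[[which.min(vapply(cand, `[[`, numeric(1), "bic"))]]
  k <- pick$k
  a <- pick$par[1:k]; tau <- exp(pick$par[(k + 1):(2 * k)])
  keep <- a >= prune_tol
  if (!any(keep)) keep <- which.max(a)
  a <- a[keep]; tau <- tau[keep]
  # a component slower than the lag window whose amplitude is within the
  # chunk-sampling noise of the correlation tail is not resolvable from the
  # data; keeping it would inject an arbitrary A*tau product into J(0)
  if (!is.null(se) && any(is.finite(se)) && length(a) > 1L) {
    tail_se <- stats::median(se[t >= 0.75 * tmax], na.rm = TRUE)
    if (is.finite(tail_se) && tail_se > 0) {
      drop <- tau > tmax & a < 2 * tail_se
      if (any(drop) && !all(drop)) { a <- a[!drop]; tau <- tau[!drop] }
    }
  }
  o <- order(tau); a <- a[o]; tau <- tau[o]
  if (sum(a) > 1) a <- a / sum(a)          # enforce the sum constraint exactly
  pred <- rowSums(exp(outer(t, -1 / tau)) * rep(a, each = length(t)))
  structure(list(A = a, tau = tau,
                 residual = sum(wts * (y - pred)^2),
                 fast_deficit = max(0, 1 - sum(a))),
            class = "triexp_fit")
}

#' @export
print.triexp_fit <- function(x, ...) {
  cat("multi-exponential fit:\n")
  for (i in seq_along(x$A))
    cat(sprintf("  A = %.4f  tau = %.4g ns\n", x$A[i], x$tau[i] * 1e9))
  cat(sprintf("  fast deficit = %.4f, weighted RSS = %.3g\n",
              x$fast_deficit, x$residual))
  invisible(x)
}

#' Spectral-density model from amplitudes and correlation times
#'
#' Combines internal correlation times with overall tumbling as
#' 1/tau_eff = 1/tau_i + 1/tau_rot (the analytic consequence of multiplying
#' the internal correlation function by exp(-t/tau_rot)) and represents
#' J(omega) = (2/5) sum_i A_i tau_eff_i / (1 + (omega tau_eff_i)^2).
#'
#' @param amplitudes nonnegative amplitudes A_i.
#' @param times internal correlation times tau_i, seconds (Inf = plateau).
#' @param tau_rot overall tumbling time, seconds; Inf leaves internal motion
#'   untouched.
#' @return object of class \code{"spectral_density_model"}.
#' @export
spectral_density_model <- function(amplitudes, times, tau_rot = Inf) {
  if (length(amplitudes) != length(times)) .stopf("amplitudes and times differ in length")
  if (any(amplitudes < 0)) .stopf("amplitudes must be nonnegative")
  if (any(times <= 0)) .stopf("correlation times must be positive")
  if (tau_rot <= 0) .stopf("tau_rot must be positive")
  tau_eff <- 1 / (1 / times + 1 / tau_rot)
  structure(list(A = amplitudes, tau_eff = tau_eff, tau_rot = tau_rot,
                 tau_internal = times),
            class = "spectral_density_model")
}

#' Reintroduce overall tumbling into a fitted internal correlation function
#'
#' @param fit a \code{\link{fit_triexponential}} result.
#' @param tau_rot overall rotational correlation time, seconds. The nucleosome
#'   default used throughout this package is 163.4 ns.
#' @return a \code{\link{spectral_density_model}}.
#' @export
apply_tumbling <- function(fit, tau_rot = 163.4e-9) {
  stopifnot(inherits(fit, "triexp_fit"))
  spectral_density_model(fit$A, fit$tau, tau_rot)
}

#' Evaluate a spectral density J(omega)
#'
#' @param model a \code{\link{spectral_density_model}}.
#' @param omega angular frequency(ies), rad/s.
#' @return J(omega) in seconds/radian; J(0) = (2/5) sum A_i tau_eff_i.
#' @export
spectral_density <- function(model, omega) {
  stopifnot(inherits(model, "spectral_density_model"))
  vapply(omega, function(w)
    (2 / 5) * sum(model$A * model$tau_eff / (1 + (w * model$tau_eff)^2)),
    numeric(1))
}

#' Spin-system constants for an amide 15N-1H pair
#'
#' Defaults follow field practice for backbone amides at a 600 MHz instrument:
#' r_NH = 1.02 Angstrom, 15N CSA = -172 ppm, gamma_H = 2.6752e8 and
#' gamma_N = -2.7126e7 rad s^-1 T^-1; the 15N Larmor frequency is derived from
#' the 1H frequency by the gyromagnetic-ratio quotient unless given. All
#' values are overridable and are carried in every relaxation record.
#'
#' @param freq_h_mhz 1H spectrometer frequency, MHz.
#' @param r_nh N-H bond length, Angstrom.
#' @param csa_ppm 15N chemical shift anisotropy, ppm.
#' @param gamma_h,gamma_n gyromagnetic ratios, rad s^-1 T^-1.
#' @param nu_n_hz 15N frequency in Hz (optional override).
#' @return object of class \code{"spin_constants"} with the Larmor angular
#'   frequencies and the dipolar (\code{d}) and CSA (\code{c}) interaction
#'   constants.
#' @export
spin_constants <- function(freq_h_mhz = 600.13, r_nh = 1.02, csa_ppm = -172,
                           gamma_h = 2.6752e8, gamma_n = -2.7126e7,
                           nu_n_hz = NULL) {
  hbar <- 1.054571817e-34
  mu0_4pi <- 1e-7
  nu_h <- freq_h_mhz * 1e6
  nu_n <- nu_n_hz %||% (nu_h * abs(gamma_n) / abs(gamma_h))
  if (abs(nu_n / nu_h - abs(gamma_n / gamma_h)) > 0.01 * abs(gamma_n / gamma_h))
    .stopf("nu_N is inconsistent with the gyromagnetic ratios (>1%% off)")
  r_m <- r_nh * 1e-10
  omega_h <- 2 * pi * nu_h
  omega_n <- 2 * pi * nu_n
  d <- mu0_4pi * hbar * abs(gamma_h) * abs(gamma_n) / r_m^3
  cc <- omega_n * abs(csa_ppm) * 1e-6 / sqrt(3)
  structure(list(freq_h_mhz = freq_h_mhz, nu_h = nu_h, nu_n = nu_n,
                 omega_h = omega_h, omega_n = omega_n,
                 gamma_h = gamma_h, gamma_n = gamma_n,
                 r_nh = r_nh, csa_ppm = csa_ppm, d = d, c = cc),
            class = "spin_constants")
}

#' 15N relaxation rates and NOE from a spectral density
#'
#' Standard dipolar + CSA expressions with
#' d = (mu0/4pi) hbar gamma_H gamma_N / r_NH^3 and c = omega_N * CSA / sqrt(3):
#' \deqn{R1 = (d^2/4)[J(wH-wN) + 3 J(wN) + 6 J(wH+wN)] + c^2 J(wN)}
#' \deqn{R2 = (d^2/8)[4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN)]
#'           + (c^2/6)[4 J(0) + 3 J(wN)]}
#' \deqn{NOE = 1 + (d^2/4)(gH/gN)[6 J(wH+wN) - J(wH-wN)] / R1}
#'
#' @param model a \code{\link{spectral_density_model}}.
#' @param constants a \code{\link{spin_constants}}.
#' @param include_high_freq if FALSE the high-frequency terms J(wH-wN), J(wH)
#'   and J(wH+wN) are set to zero; in that limit the R2/R1 inversion to tau_c
#'   is an exact algebraic identity for a rigid rotor.
#' @param residue_id optional residue id carried into the record.
#' @return one-row data.frame of class \code{"relaxation_record"} with columns
#'   \code{residue_id}, \code{R1}, \code{R2}, \code{NOE}, \code{tau_c} (the
#'   R2/R1-derived effective correlation time, seconds; NA when undefined) and
#'   \code{tau_c_defined}.
#' @export
relaxation_rates <- function(model, constants = spin_constants(),
                             include_high_freq = TRUE, residue_id = NA_integer_) {
  stopifnot(inherits(model, "spectral_density_model"),
            inherits(constants, "spin_constants"))
  wh <- constants$omega_h; wn <- constants$omega_n
  J0 <- spectral_density(model, 0)
  Jn <- spectral_density(model, wn)
  if (include_high_freq) {
    Jhmn <- spectral_density(model, wh - wn)
    Jh <- spectral_density(model, wh)
    Jhpn <- spectral_density(model, wh + wn)
  } else Jhmn <- Jh <- Jhpn <- 0
  d2 <- constants$d^2; c2 <- constants$c^2
  R1 <- (d2 / 4) * (Jhmn + 3 * Jn + 6 * Jhpn) + c2 * Jn
  R2 <- (d2 / 8) * (4 * J0 + Jhmn + 3 * Jn + 6 * Jh + 6 * Jhpn) +
        (c2 / 6) * (4 * J0 + 3 * Jn)
  NOE <- if (R1 > 0)
    1 + (d2 / 4) * (constants$gamma_h / constants$gamma_n) * (6 * Jhpn - Jhmn) / R1
  else NA_real_
  tc <- tau_c_from_rates(R1, R2, nu_n = constants$nu_n)
  out <- data.frame(residue_id = residue_id, R1 = R1, R2 = R2, NOE = NOE,
                    tau_c = tc$tau_c, tau_c_defined = tc$defined)
  class(out) <- c("relaxation_record", class(out))
  out
}

#' Residue-wise rotational correlation time from computed rates
#'
#' Thin wrapper around \code{\link{tau_c_from_rates}} taking the 15N frequency
#' from the spin constants. Returns NA with \code{defined = FALSE} (never an
#' error) when R2/R1 <= 7/6.
#'
#' @param record a \code{\link{relaxation_rates}} record (or anything with
#'   columns R1, R2).
#' @param constants a \code{\link{spin_constants}}.
#' @return a \code{tau_c_result} list, see \code{\link{tau_c_from_rates}}.
#' @export
residue_tau_c <- function(record, constants = spin_constants()) {
  tau_c_from_rates(record$R1, record$R2, nu_n = constants$nu_n)
}

#' Compare computed and measured relaxation parameters
#'
#' Pairwise-complete comparison over shared residues: per-residue differences
#' and the Pearson correlation, the quantity used to judge how well simulated
#' residue-wise tumbling times track the experimental ones.
#'
#' @param computed,measured data.frames with \code{residue_id} and the column
#'   named in \code{value}.
#' @param value which column to compare (default \code{"tau_c"}).
#' @return list with \code{table} (residue_id, computed, measured, delta) and
#'   \code{pearson_r}.
#' @export
compare_to_experiment <- function(computed, measured, value = "tau_c") {
  a <- computed[, c("residue_id", value)]
  b <- measured[, c("residue_id", value)]
  names(a)[2] <- "computed"; names(b)[2] <- "measured"
  m <- merge(a, b, by = "residue_id")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) .stopf("need at least 3 shared residues; got %d", nrow(m))
  m$delta <- m$computed - m$measured
  list(table = m[order(m$residue_id), ],
       pearson_r = stats::cor(m$computed, m$measured))
}

#' Full relaxometry chain from a bond-vector series
#'
#' Convenience pipeline: chunk-averaged P2 autocorrelation, multi-exponential
#' fit, tumbling reintroduction, and relaxation rates.
#'
#' @param series a \code{\link{vector_series}}.
#' @param tau_rot overall tumbling time, seconds (default 163.4 ns; use Inf
#'   for internal motion only).
#' @param constants a \code{\link{spin_constants}}.
#' @param n_chunks,max_lag_fraction passed to \code{\link{p2_autocorrelation}}.
#' @return a \code{relaxation_record} (see \code{\link{relaxation_rates}}).
#' @export
relaxation_from_vectors <- function(series, tau_rot = 163.4e-9,
                                    constants = spin_constants(),
                                    n_chunks = 20, max_lag_fraction = 0.5) {
  corr <- p2_autocorrelation(series, n_chunks = n_chunks,
                             max_lag_fraction = max_lag_fraction)
  fit <- fit_triexponential(corr)
  model <- apply_tumbling(fit, tau_rot)
  relaxation_rates(model, constants, residue_id = series$residue_id)
}
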