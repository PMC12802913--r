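#' Construct / read / write peak tables
#'
#' A peak table holds one row per backbone amide resonance: residue id and
#' name, 1H and 15N chemical shifts (ppm), an optional intensity and a missing
#' flag (prolines have no backbone amide; overlapped or exchange-broadened
#' peaks can be missing too).
#'
#' @param residue_id integer ids (unique).
#' @param shift_H_ppm,shift_N_ppm chemical shifts, ppm.
#' @param residue_name three- or one-letter residue names.
#' @param intensity optional peak intensities.
#' @param missing_flag logical; TRUE marks an absent peak.
#' @return data.frame of class \code{"peak_table"}.
#' @export
peak_table <- function(residue_id, shift_H_ppm, shift_N_ppm,
                       residue_name = NA_character_, intensity = NA_real_,
                       missing_flag = FALSE) {
  if (anyDuplicated(residue_id)) .stopf("residue_id values must be unique")
  out <- data.frame(residue_id = as.integer(residue_id),
                    residue_name = residue_name,
                    shift_H_ppm = shift_H_ppm, shift_N_ppm = shift_N_ppm,
                    intensity = intensity, missing_flag = missing_flag)
  class(out) <- c("peak_table", class(out))
  out
}

#' @rdname peak_table
#' @param path CSV path with columns residue, shift_H_ppm, shift_N_ppm.
#' @export
read_peak_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d)[names(d) == "residue"] <- "residue_id"
  peak_table(d$residue_id, d$shift_H_ppm, d$shift_N_ppm,
             residue_name = d$residue_name %||% NA_character_,
             intensity = d$intensity %||% NA_real_,
             missing_flag = d$missing_flag %||% FALSE)
}

#' @rdname peak_table
#' @param table a peak table.
#' @export
write_peak_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Chemical shift perturbations between two peak tables
#'
#' Combined amide perturbation
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (w_N \Delta\delta_N)^2}}
#' with the nitrogen weight defaulting to 0.154. Matching is by residue id,
#' never row order; residues missing from either table (or flagged missing)
#' are emitted with \code{missing_flag = TRUE} and an NA perturbation rather
#' than being dropped.
#'
#' @param a,b peak tables.
#' @param nitrogen_weight scaling of the 15N shift difference.
#' @return data.frame with residue_id, delta_H, delta_N, csp, missing_flag.
#' @export
csp <- function(a, b, nitrogen_weight = 0.154) {
  m <- merge(a[, c("residue_id", "shift_H_ppm", "shift_N_ppm", "missing_flag")],
             b[, c("residue_id", "shift_H_ppm", "shift_N_ppm", "missing_flag")],
             by = "residue_id", all = TRUE, suffixes = c("_a", "_b"))
  m$missing_flag <- is.na(m$shift_H_ppm_a) | is.na(m$shift_H_ppm_b) |
    (m$missing_flag_a %in% TRUE) | (m$missing_flag_b %in% TRUE)
  if (all(m$missing_flag)) .stopf("the two peak tables share no observed residues")
  m$delta_H <- m$shift_H_ppm_b - m$shift_H_ppm_a
  m$delta_N <- m$shift_N_ppm_b - m$shift_N_ppm_a
  m$csp <- sqrt(m$delta_H^2 + (nitrogen_weight * m$delta_N)^2)
  m$csp[m$missing_flag] <- NA_real_
  out <- m[order(m$residue_id),
           c("residue_id", "delta_H", "delta_N", "csp", "missing_flag")]
  rownames(out) <- NULL
  out
}

#' Fit a single-exponential intensity decay
#'
#' Least-squares fit of I(t) = I0 exp(-R t), two free parameters and no
#' offset, to peak intensity versus relaxation-delay data. Duplicate delays
#' enter as independent points, so their scatter feeds the residual variance
#' that scales the parameter covariance; sigma_R is the usual
#' covariance-based standard error.
#'
#' @param delays relaxation delays, seconds (duplicates allowed). May also be
#'   a data.frame with columns \code{delay_s} and \code{intensity}.
#' @param intensities peak intensities (positive).
#' @return object of class \code{"rate_fit"}: \code{R} (s^-1), \code{sigma_R},
#'   \code{I0}, \code{residuals}, \code{boundary_flag} (TRUE when the data do
#'   not decay and R is pinned at 0).
#' @export
fit_decay <- function(delays, intensities = NULL) {
  if (is.data.frame(delays)) {
    intensities <- delays$intensity
    delays <- delays$delay_s
  }
  if (length(delays) != length(intensities)) .stopf("delays and intensities differ in length")
  if (length(unique(delays)) < 4L) .stopf("need at least 4 distinct delays")
  if (any(intensities <= 0)) .stopf("intensities must be positive for a log-scale decay fit")
  d <- data.frame(t = delays, I = intensities)
  lf <- stats::lm(log(I) ~ t, data = d)
  r0 <- -unname(stats::coef(lf)[2])
  if (!is.finite(r0) || r0 <= 0) {
    return(structure(list(R = 0, sigma_R = NA_real_, I0 = mean(intensities),
                          residuals = intensities - mean(intensities),
                          boundary_flag = TRUE),
                     class = "rate_fit"))
  }
  fit <- tryCatch(
    stats::nls(I ~ I0 * exp(-R * t), data = d,
               start = list(I0 = exp(unname(stats::coef(lf)[1])), R = r0),
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e)
      .stopf("decay fit failed to converge (%s); delays: %s", conditionMessage(e),
             paste(signif(delays, 4), collapse = ", ")))
  sm <- summary(fit)$coefficients
  structure(list(R = unname(sm["R", "Estimate"]),
                 sigma_R = unname(sm["R", "Std. Error"]),
                 I0 = unname(sm["I0", "Estimate"]),
                 residuals = stats::residuals(fit),
                 boundary_flag = FALSE),
            class = "rate_fit")
}

#' Rotational correlation time from R2/R1
#'
#' Inverts the rate ratio to the effective rotational correlation time
#' \deqn{\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6 R_2/R_1 - 7}}
#' with first-order error propagation: the relative errors of R1 and R2 are
#' combined into the ratio error, then
#' sigma_tau = 3 sigma_ratio / (4 pi nu_N sqrt(6 ratio - 7)). A ratio at or
#' below 7/6 yields \code{defined = FALSE} (tau_c = 0 exactly at 7/6), never
#' an exception.
#'
#' @param R1,R2 rates (s^-1) or \code{\link{fit_decay}} results.
#' @param nu_n 15N resonance frequency, Hz.
#' @param sigma_R1,sigma_R2 rate standard errors (taken from rate fits when
#'   those are supplied).
#' @return object of class \code{"tau_c_result"}: \code{tau_c} and
#'   \code{sigma_tau_c} (seconds), \code{ratio}, \code{defined}.
#' @export
tau_c_from_rates <- function(R1, R2, nu_n, sigma_R1 = 0, sigma_R2 = 0) {
  if (inherits(R1, "rate_fit")) { sigma_R1 <- R1$sigma_R %||% 0; R1 <- R1$R }
  if (inherits(R2, "rate_fit")) { sigma_R2 <- R2$sigma_R %||% 0; R2 <- R2$R }
  if (!.is_scalar(nu_n) || nu_n <= 0) .stopf("nu_n must be a positive frequency in Hz")
  if (!is.finite(R1) || R1 <= 0)
    return(structure(list(tau_c = NA_real_, sigma_tau_c = NA_real_,
                          ratio = NA_real_, defined = FALSE),
                     class = "tau_c_result"))
  ratio <- R2 / R1
  if (ratio < 7 / 6)
    return(structure(list(tau_c = NA_real_, sigma_tau_c = NA_real_,
                          ratio = ratio, defined = FALSE),
                     class = "tau_c_result"))
  rad <- 6 * ratio - 7
  tau <- sqrt(rad) / (4 * pi * nu_n)
  s1 <- if (is.na(sigma_R1)) 0 else sigma_R1
  s2 <- if (is.na(sigma_R2)) 0 else sigma_R2
  sigma_ratio <- ratio * sqrt((s2 / R2)^2 + (s1 / R1)^2)
  sigma_tau <- if (rad > 0) 3 * sigma_ratio / ((4 * pi * nu_n) * sqrt(rad)) else Inf
  if (sigma_ratio == 0) sigma_tau <- 0
  # at ratio exactly 7/6 the radicand vanishes: tau_c = 0 is reported but the
  # result is still flagged undefined (the inversion has no sensitivity there)
  structure(list(tau_c = tau, sigma_tau_c = sigma_tau, ratio = ratio,
                 defined = ratio > 7 / 6),
            class = "tau_c_result")
}

#' @export
print.tau_c_result <- function(x, ...) {
  if (isTRUE(x$defined))
    cat(sprintf("tau_c = %.4g ns +/- %.3g ns (R2/R1 = %.4g)\n",
                x$tau_c * 1e9, x$sigma_tau_c * 1e9, x$ratio))
  else
    cat(sprintf("tau_c undefined (R2/R1 = %s <= 7/6)\n",
                if (is.na(x$ratio)) "NA" else sprintf("%.4g", x$ratio)))
  invisible(x)
}

#' Read an intensity-vs-delay series from long-format CSV
#'
#' Columns: \code{residue}, \code{delay_s}, \code{intensity}.
#'
#' @param path CSV path.
#' @return data.frame split-able by residue; feed each residue's rows to
#'   \code{\link{fit_decay}}.
#' @export
read_intensity_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "delay_s", "intensity")
  miss <- setdiff(need, names(d))
  if (length(miss)) .stopf("intensity CSV lacks column(s): %s", paste(miss, collapse = ", "))
  d
}
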