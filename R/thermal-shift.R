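#' Read / write melt curves
#'
#' Melt curves are long-format data.frames with columns \code{temperature_C}
#' (strictly increasing within each replicate), \code{rfu} (raw fluorescence)
#' and \code{replicate}.
#'
#' @param path CSV path.
#' @return melt-curve data.frame.
#' @export
read_melt_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "rfu")
  miss <- setdiff(need, names(d))
  if (length(miss)) .stopf("melt CSV lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(d$replicate)) d$replicate <- 1L
  d
}

#' @rdname read_melt_curves
#' @param curves a melt-curve data.frame.
#' @export
write_melt_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

.check_melt_grid <- function(temps) {
  if (length(temps) < 2L) .stopf("melt curve needs at least 2 points")
  if (any(diff(temps) <= 0)) .stopf("temperature grid must be strictly increasing")
}

#' Min-max normalize melt-curve fluorescence
#'
#' Per replicate, (RFU - RFU_min) / (RFU_max - RFU_min): the minimum raw
#' value maps to 0 and the maximum to 1, so constant offsets and positive
#' scalings of the raw signal cancel.
#'
#' @param curves melt-curve data.frame.
#' @return same shape with an added \code{norm} column.
#' @export
normalize_curve <- function(curves) {
  if (is.null(curves$replicate)) curves$replicate <- 1L
  out <- lapply(split(curves, curves$replicate), function(d) {
    d <- d[order(d$temperature_C), , drop = FALSE]
    .check_melt_grid(d$temperature_C)
    rng <- range(d$rfu)
    if (diff(rng) <= 0) .stopf("flat fluorescence curve cannot be normalized")
    d$norm <- (d$rfu - rng[1]) / (rng[2] - rng[1])
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Temperature derivative of the normalized fluorescence
#'
#' Forward difference (f(T_{i+1}) - f(T_i)) / (T_{i+1} - T_i), with the value
#' assigned to the T_{i+1} grid point. On a symmetric transition this
#' assignment biases the peak about half a grid step high; the convention is
#' kept as is and documented rather than replaced by a centred difference.
#'
#' @param norm output of \code{\link{normalize_curve}} (needs \code{norm}).
#' @return data.frame with \code{temperature_C} (assigned points),
#'   \code{dnorm_dT}, \code{replicate}; one row fewer per replicate.
#' @export
derivative_curve <- function(norm) {
  if (is.null(norm$norm)) .stopf("normalize the curve first (no 'norm' column)")
  if (is.null(norm$replicate)) norm$replicate <- 1L
  out <- lapply(split(norm, norm$replicate), function(d) {
    d <- d[order(d$temperature_C), , drop = FALSE]
    if (nrow(d) < 2L) {
      .warnf("replicate %s has a single point; empty derivative", d$replicate[1])
      return(data.frame(temperature_C = numeric(0), dnorm_dT = numeric(0),
                        replicate = d$replicate[0]))
    }
    data.frame(temperature_C = d$temperature_C[-1L],
               dnorm_dT = diff(d$norm) / diff(d$temperature_C),
               replicate = d$replicate[-1L])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# topographic prominence of interior local maxima; a run of equal values
# higher than both flanking values (a plateau, which symmetric transitions
# sampled symmetrically produce) counts as one peak at its first point
.find_peaks <- function(x) {
  n <- length(x)
  empty <- data.frame(idx = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3L) return(empty)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  k <- length(r$values)
  isp <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
      isp <- c(isp, starts[j])
  }
  if (!length(isp)) return(empty)
  prom <- vapply(isp, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > h)
    key_l <- if (length(higher_l)) min(x[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    right <- x[(i + 1L):n]
    higher_r <- which(right > h)
    key_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else min(right)
    h - max(key_l, key_r)
  }, numeric(1))
  data.frame(idx = isp, height = x[isp], prominence = prom)
}

#' Melting temperatures from a derivative curve
#'
#' Peaks of d(normalized fluorescence)/dT mark the melting transitions; they
#' are ranked by topographic prominence, transitions below
#' \code{min_prominence} are dropped (an attenuated second step too small to
#' measure yields a single Tm), and up to \code{max_peaks} are reported in
#' ascending temperature order, per replicate. No smoothing is applied by
#' default; \code{smooth = TRUE} applies a 3-point moving average first.
#'
#' @param deriv output of \code{\link{derivative_curve}}.
#' @param max_peaks maximum transitions reported (default 2: the biphasic
#'   nucleosome disassembly case).
#' @param min_prominence prominence threshold on the derivative scale.
#' @param smooth 3-point moving average before peak picking.
#' @return data.frame of class \code{"tm_report"}: \code{replicate},
#'   \code{tm_C}, \code{prominence}, \code{height}; zero rows when no peak
#'   clears the threshold.
#' @export
find_tm <- function(deriv, max_peaks = 2, min_prominence = 0.05,
                    smooth = FALSE) {
  if (is.null(deriv$dnorm_dT)) .stopf("input must be a derivative curve")
  if (is.null(deriv$replicate)) deriv$replicate <- 1L
  out <- lapply(split(deriv, deriv$replicate), function(d) {
    d <- d[order(d$temperature_C), , drop = FALSE]
    y <- d$dnorm_dT
    if (smooth && length(y) >= 3L)
      y <- stats::filter(y, rep(1 / 3, 3), sides = 2) |> as.numeric() |>
        (\(v) { v[is.na(v)] <- y[is.na(v)]; v })()
    pk <- .find_peaks(y)
    pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
    pk <- pk[order(-pk$prominence), , drop = FALSE]
    pk <- utils::head(pk, max_peaks)
    pk <- pk[order(d$temperature_C[pk$idx]), , drop = FALSE]
    data.frame(replicate = rep(d$replicate[1], nrow(pk)),
               tm_C = d$temperature_C[pk$idx],
               prominence = pk$prominence, height = pk$height)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("tm_report", class(out))
  out
}

#' Aggregate melting temperatures across replicates
#'
#' Transitions are matched across replicates by nearest-temperature pairing:
#' pooled Tm values are clustered greedily in ascending order, starting a new
#' transition whenever a value falls more than \code{match_window} from the
#' running cluster mean. Each matched transition is summarised by its mean,
#' sample standard deviation (NA for a single member) and replicate count;
#' spurious extra peaks simply form low-count clusters that the caller can
#' inspect.
#'
#' @param report a \code{\link{find_tm}} result (or any data.frame with
#'   \code{replicate} and \code{tm_C}).
#' @param match_window maximum distance to the cluster mean, deg C.
#' @return data.frame: \code{transition}, \code{mean_tm_C}, \code{sd_tm_C},
#'   \code{n_replicates}.
#' @export
aggregate_replicates <- function(report, match_window = 3) {
  if (!nrow(report)) .stopf("empty Tm report")
  v <- report$tm_C[order(report$tm_C)]
  rep_id <- report$replicate[order(report$tm_C)]
  cl <- integer(length(v)); cl[1] <- 1L
  csum <- v[1]; cn <- 1L
  for (i in seq_along(v)[-1]) {
    if (abs(v[i] - csum / cn) <= match_window) {
      cl[i] <- cl[i - 1L]; csum <- csum + v[i]; cn <- cn + 1L
    } else {
      cl[i] <- cl[i - 1L] + 1L; csum <- v[i]; cn <- 1L
    }
  }
  agg <- lapply(split(seq_along(v), cl), function(ii) {
    data.frame(mean_tm_C = mean(v[ii]),
               sd_tm_C = if (length(ii) > 1L) stats::sd(v[ii]) else NA_real_,
               n_replicates = length(unique(rep_id[ii])))
  })
  out <- do.call(rbind, agg)
  out <- cbind(transition = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  if (length(unique(out$n_replicates)) > 1L)
    message("replicates disagree on the number of transitions; check n_replicates")
  out
}

#' One-call Tm extraction from raw curves
#'
#' Normalize, differentiate, pick peaks and aggregate replicates.
#'
#' @param curves raw melt-curve data.frame.
#' @inheritParams find_tm
#' @return list with \code{per_replicate} (Tm report) and \code{summary}
#'   (aggregated transitions).
#' @export
melt_analysis <- function(curves, max_peaks = 2, min_prominence = 0.05,
                          smooth = FALSE) {
  rep_tm <- find_tm(derivative_curve(normalize_curve(curves)),
                    max_peaks = max_peaks, min_prominence = min_prominence,
                    smooth = smooth)
  list(per_replicate = rep_tm,
       summary = if (nrow(rep_tm)) aggregate_replicates(rep_tm) else rep_tm)
}
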