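#' Bound/unbound state series
#'
#' @param times_ns frame timestamps, ns (uniform spacing).
#' @param state character vector, \code{"bound"} or \code{"unbound"}.
#' @param threshold_used unbound-classification threshold that produced the
#'   series (fraction of tail residues), if any.
#' @param meta free-form metadata (e.g. generator ground truth).
#' @return object of class \code{"bound_state_series"}.
#' @export
bound_state_series <- function(times_ns, state, threshold_used = NA_real_,
                               meta = list()) {
  state <- as.character(state)
  if (length(times_ns) != length(state)) .stopf("times and states differ in length")
  if (!all(state %in% c("bound", "unbound")))
    .stopf("states must be 'bound' or 'unbound'")
  structure(list(times_ns = times_ns, state = state,
                 threshold_used = threshold_used, meta = meta),
            class = "bound_state_series")
}

#' @export
print.bound_state_series <- function(x, ...) {
  cat(sprintf("bound_state_series: %d frames, %.1f%% bound\n",
              length(x$state), 100 * mean(x$state == "bound")))
  invisible(x)
}

# shared frame filter: drop the burn-in, then stride
.analysis_frames <- function(traj, stride_ns, burn_in_ns) {
  if (stride_ns < traj$frame_interval)
    .stopf("stride (%g ns) is smaller than the frame interval (%g ns)",
           stride_ns, traj$frame_interval)
  times <- frame_times(traj)
  keep <- which(times >= burn_in_ns)
  if (!length(keep)) .stopf("burn-in of %g ns leaves no frames", burn_in_ns)
  k <- max(1L, as.integer(round(stride_ns / traj$frame_interval)))
  keep[seq(1L, length(keep), by = k)]
}

# per-frame pair counts between two heavy-atom index sets, aggregated by a
# grouping of the first set's atoms; strict < cutoff. Exact all-pairs search.
.pair_counts <- function(traj, idx_a, idx_b, cutoff, frames, group_a, group_b = NULL) {
  ga <- sort(unique(group_a)); gb <- if (is.null(group_b)) 1L else sort(unique(group_b))
  out <- array(0L, c(length(frames), length(ga), length(gb)))
  ia <- match(group_a, ga)
  ib <- if (is.null(group_b)) rep(1L, length(idx_b)) else match(group_b, gb)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    pa <- traj$coords[f, idx_a, , drop = FALSE]; dim(pa) <- c(length(idx_a), 3L)
    pb <- traj$coords[f, idx_b, , drop = FALSE]; dim(pb) <- c(length(idx_b), 3L)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      tab <- table(factor(ia[hit[, 1]], levels = seq_along(ga)),
                   factor(ib[hit[, 2]], levels = seq_along(gb)))
      out[fi, , ] <- out[fi, , ] + as.integer(tab)
    }
  }
  dimnames(out) <- list(NULL, as.character(ga), as.character(gb))
  out
}

#' Tail-DNA contact timeline
#'
#' A tail residue is in contact in a frame when at least one of its heavy
#' atoms lies strictly within \code{cutoff} of any heavy DNA atom (the 4
#' Angstrom nonhydrogen-pair rule). Frames before \code{burn_in_ns} are
#' excluded and the remaining frames strided to \code{stride_ns}.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param tail_sel,dna_sel selections (expression, ids or
#'   \code{atom_selection}); must be disjoint; hydrogens are ignored.
#' @param cutoff contact cutoff, Angstrom (strict \code{<}).
#' @param stride_ns analysis stride, ns.
#' @param burn_in_ns equilibration time excluded from analysis, ns.
#' @return object of class \code{"contact_timeline"}: \code{residues},
#'   \code{times_ns}, logical \code{in_contact} (frame x residue), integer
#'   \code{counts} of atom pairs in contact.
#' @export
residue_dna_contacts <- function(traj, tail_sel, dna_sel, cutoff = 4.0,
                                 stride_ns = 1.0, burn_in_ns = 200) {
  stopifnot(inherits(traj, "trajectory"))
  ia <- .resolve_selection(traj, tail_sel)
  ib <- .resolve_selection(traj, dna_sel)
  if (!length(ia) || !length(ib)) .stopf("empty tail or DNA selection")
  ia <- ia[traj$atoms$is_heavy[ia]]
  ib <- ib[traj$atoms$is_heavy[ib]]
  if (!length(ia) || !length(ib)) .stopf("selections contain no heavy atoms")
  if (length(intersect(ia, ib))) .stopf("tail and DNA selections overlap")
  frames <- .analysis_frames(traj, stride_ns, burn_in_ns)
  grp <- traj$atoms$residue_id[ia]
  counts3 <- .pair_counts(traj, ia, ib, cutoff, frames, grp)
  counts <- counts3[, , 1, drop = TRUE]
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(frames))
  residues <- sort(unique(grp))
  structure(list(residues = residues,
                 times_ns = frame_times(traj)[frames],
                 in_contact = counts >= 1L,
                 counts = counts, cutoff = cutoff),
            class = "contact_timeline")
}

#' Per-frame fraction of tail residues in DNA contact
#'
#' @param timeline a \code{\link{residue_dna_contacts}} result.
#' @return numeric vector, one fraction per analyzed frame.
#' @export
bound_fraction <- function(timeline) {
  stopifnot(inherits(timeline, "contact_timeline"))
  rowMeans(timeline$in_contact)
}

#' Classify frames as tail-bound or tail-unbound
#'
#' A frame is unbound when no more than \code{floor(threshold * n_residues)}
#' tail residues maintain DNA contact (the "no more than 10 percent" rule;
#' for a 36-residue tail that is <= 3 contacting residues), otherwise bound.
#'
#' @param timeline a \code{\link{residue_dna_contacts}} result.
#' @param unbound_threshold fraction in (0, 1).
#' @return a \code{\link{bound_state_series}}.
#' @export
classify_bound_state <- function(timeline, unbound_threshold = 0.10) {
  stopifnot(inherits(timeline, "contact_timeline"))
  if (unbound_threshold <= 0 || unbound_threshold >= 1)
    .stopf("unbound_threshold must lie in (0, 1)")
  nres <- length(timeline$residues)
  thr <- floor(unbound_threshold * nres + 1e-9)
  ncon <- rowSums(timeline$in_contact)
  bound_state_series(timeline$times_ns,
                     ifelse(ncon <= thr, "unbound", "bound"),
                     threshold_used = unbound_threshold)
}

#' Binding/unbinding events and residence times
#'
#' Run-length encodes the state series into episodes. Bound episodes shorter
#' than \code{min_residence_ns} are, by default, merged into the flanking
#' unbound time before events are counted (set \code{count_short_events =
#' TRUE} to retain them), reflecting the view that sub-threshold touches have
#' not established stable DNA interactions. An unbinding event is a
#' bound-to-unbound transition. The episode reaching the final frame is
#' flagged end-truncated (its duration is censored) and excluded from
#' residence statistics.
#'
#' @param states a \code{\link{bound_state_series}}.
#' @param min_residence_ns residence filter, ns (default 50).
#' @param count_short_events keep sub-threshold bound episodes in the event
#'   count.
#' @return list with \code{episodes} (state, start_ns, end_ns, duration_ns,
#'   end_truncated, counted), \code{n_binding}, \code{n_unbinding},
#'   \code{residence_ns} (filtered bound durations), \code{frames_bound},
#'   \code{frames_unbound}.
#' @export
extract_events <- function(states, min_residence_ns = 50,
                           count_short_events = FALSE) {
  stopifnot(inherits(states, "bound_state_series"))
  s <- states$state
  n <- length(s)
  if (n < 2L) .stopf("need at least 2 frames to extract events")
  dt <- if (n > 1L) diff(states$times_ns[1:2]) else 1
  r <- rle(s)
  if (!count_short_events && any(r$values == "bound" & r$lengths * dt < min_residence_ns)) {
    keep_end <- cumsum(r$lengths)
    final <- r$values
    short <- r$values == "bound" & r$lengths * dt < min_residence_ns &
      keep_end != n               # the censored final episode is never filtered
    final[short] <- "unbound"
    s2 <- inverse.rle(list(lengths = r$lengths, values = final))
    r <- rle(s2)
  } else s2 <- s
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ep <- data.frame(state = r$values,
                   start_ns = states$times_ns[starts],
                   end_ns = states$times_ns[ends] + dt,
                   duration_ns = r$lengths * dt,
                   end_truncated = ends == n)
  ep$counted <- ep$state == "bound" & !ep$end_truncated &
    ep$duration_ns >= min_residence_ns
  trans <- paste(utils::head(r$values, -1L), utils::tail(r$values, -1L))
  res <- ep$duration_ns[ep$counted]
  if (!length(res) && min_residence_ns > 0)
    .warnf("no bound episode passed the %g ns residence filter", min_residence_ns)
  list(episodes = ep,
       n_binding = sum(trans == "unbound bound"),
       n_unbinding = sum(trans == "bound unbound"),
       residence_ns = res,
       frames_bound = sum(s == "bound"),
       frames_unbound = sum(s == "unbound"))
}

#' Ensemble dissociation constant and standard binding free energy
#'
#' Kd is the ratio of unbound to bound frame counts over all analyzed frames
#' (no residence filtering), and Delta G0 = R T ln Kd in kcal/mol, negative
#' when the bound state dominates. With zero frames in either state the
#' result is flagged undefined and the counts are reported; no infinities are
#' emitted.
#'
#' @param states a \code{\link{bound_state_series}}.
#' @param temperature temperature, K (310 K, the simulation thermostat, by
#'   default).
#' @return list with \code{Kd}, \code{deltaG0_kcal_mol}, \code{frames_bound},
#'   \code{frames_unbound}, \code{temperature}, \code{defined}.
#' @export
binding_thermodynamics <- function(states, temperature = 310) {
  stopifnot(inherits(states, "bound_state_series"))
  nb <- sum(states$state == "bound")
  nu <- sum(states$state == "unbound")
  if (nb == 0L || nu == 0L) {
    return(list(Kd = NA_real_, deltaG0_kcal_mol = NA_real_,
                frames_bound = nb, frames_unbound = nu,
                temperature = temperature, defined = FALSE))
  }
  kd <- nu / nb
  list(Kd = kd, deltaG0_kcal_mol = .R_KCAL * temperature * log(kd),
       frames_bound = nb, frames_unbound = nu,
       temperature = temperature, defined = TRUE)
}

#' Mean tail contacts per DNA base pair
#'
#' Counts heavy-atom tail-DNA contact pairs per frame and aggregates them to
#' the base-pair index of the DNA atom, so the two paired nucleotides of a
#' duplex pool into one bin; reported as the mean count per analyzed frame.
#' The default pairing maps DNA residue i of a 2N-nucleotide duplex (both
#' strands numbered consecutively) to base pair min(i, 2N+1-i).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param tail_sel,dna_sel selections as in
#'   \code{\link{residue_dna_contacts}}.
#' @param bp_pairing named integer vector mapping DNA residue id (as a name)
#'   to base-pair index; NULL uses the default duplex rule over the DNA
#'   selection's residues.
#' @param cutoff,stride_ns,burn_in_ns as in
#'   \code{\link{residue_dna_contacts}}.
#' @return list with \code{bp} (data.frame bp_index, mean_contacts),
#'   \code{residue_bp} (tail residue x bp matrix of mean contacts) and
#'   \code{n_frames}.
#' @export
per_bp_contact_map <- function(traj, tail_sel, dna_sel, bp_pairing = NULL,
                               cutoff = 4.0, stride_ns = 1.0, burn_in_ns = 200) {
  stopifnot(inherits(traj, "trajectory"))
  ia <- .resolve_selection(traj, tail_sel)
  ib <- .resolve_selection(traj, dna_sel)
  if (!length(ia) || !length(ib)) .stopf("empty tail or DNA selection")
  ia <- ia[traj$atoms$is_heavy[ia]]
  ib <- ib[traj$atoms$is_heavy[ib]]
  dna_res <- traj$atoms$residue_id[ib]
  if (is.null(bp_pairing)) {
    ids <- sort(unique(dna_res))
    n2 <- length(ids)
    bp_pairing <- stats::setNames(pmin(seq_len(n2), n2 + 1L - seq_len(n2)), ids)
  }
  hit <- match(as.character(dna_res), names(bp_pairing))
  if (anyNA(hit))
    .stopf("DNA residue(s) %s absent from the base-pair pairing map",
           paste(unique(dna_res[is.na(hit)]), collapse = ", "))
  bp_of_atom <- unname(bp_pairing[hit])
  frames <- .analysis_frames(traj, stride_ns, burn_in_ns)
  counts <- .pair_counts(traj, ia, ib, cutoff, frames,
                         group_a = traj$atoms$residue_id[ia],
                         group_b = bp_of_atom)
  mean_mat <- apply(counts, c(2, 3), mean)
  n_bp <- max(bp_pairing)
  bp_means <- numeric(n_bp)
  present <- as.integer(dimnames(counts)[[3]])
  bp_means[present] <- colSums(mean_mat)
  list(bp = data.frame(bp_index = seq_len(n_bp), mean_contacts = unname(bp_means)),
       residue_bp = mean_mat, n_frames = length(frames))
}
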