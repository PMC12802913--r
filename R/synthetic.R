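# Synthetic-input generators. Every generator is deterministic given its
# seed, uses no global random state, and embeds its ground-truth parameters
# in the returned object so downstream tests never re-derive them.

#' Specification objects for the synthetic generators
#'
#' Plain validated parameter lists. Times are in seconds (matching the
#' spin-physics layer); temperatures in degrees Celsius.
#'
#' @param tau_c isotropic tumbling correlation time, s.
#' @param dt frame spacing, s.
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @return a spec list of the matching class.
#' @export
rotdiff_spec <- function(tau_c, dt, n_frames, seed = 1L) {
  stopifnot(.is_scalar(tau_c) || identical(tau_c, Inf), tau_c > 0,
            .is_scalar(dt), dt > 0, .is_count(n_frames), n_frames >= 2)
  structure(list(tau_c = tau_c, dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)), class = "rotdiff_spec")
}

#' @rdname rotdiff_spec
#' @param half_angle cone half-angle, degrees, in (0, 90].
#' @param tau_internal effective internal correlation time, s.
#' @export
cone_spec <- function(half_angle, tau_internal, dt, n_frames, seed = 1L) {
  stopifnot(.is_scalar(half_angle), .is_scalar(tau_internal), tau_internal > 0,
            .is_scalar(dt), dt > 0, .is_count(n_frames), n_frames >= 2)
  if (half_angle <= 0 || half_angle > 90)
    .stopf("half_angle must lie in (0, 90] degrees")
  structure(list(half_angle = half_angle, tau_internal = tau_internal,
                 dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)), class = "cone_spec")
}

#' @rdname rotdiff_spec
#' @param k_on,k_off binding / unbinding rate constants, s^-1.
#' @export
two_state_spec <- function(k_on, k_off, dt, n_frames, seed = 1L) {
  stopifnot(is.numeric(k_on), k_on >= 0, is.numeric(k_off), k_off >= 0,
            .is_scalar(dt), dt > 0, .is_count(n_frames), n_frames >= 2)
  structure(list(k_on = k_on, k_off = k_off, dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "two_state_spec")
}

#' @rdname rotdiff_spec
#' @param transitions data.frame with columns \code{tm} (deg C), \code{width}
#'   (deg C, > 0), \code{amplitude} (>= 0).
#' @param t_start,t_end,t_step temperature grid, deg C.
#' @param noise_sd Gaussian noise s.d. on the normalized-fluorescence scale.
#' @param n_replicates replicate curves (distinct sub-seeds).
#' @export
melt_spec <- function(transitions, t_start = 25, t_end = 95, t_step = 1,
                      noise_sd = 0, seed = 1L, n_replicates = 1L) {
  stopifnot(is.data.frame(transitions),
            all(c("tm", "width", "amplitude") %in% names(transitions)),
            all(transitions$width > 0), all(transitions$amplitude >= 0),
            .is_scalar(t_step), t_step > 0, noise_sd >= 0,
            .is_count(n_replicates))
  tms <- sort(transitions$tm)
  if (length(tms) > 1L && any(diff(tms) < 2 * t_step))
    .warnf("melt transitions closer than 2 grid steps may merge into one peak")
  structure(list(transitions = transitions, t_start = t_start, t_end = t_end,
                 t_step = t_step, noise_sd = noise_sd, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "melt_spec")
}

# ---------------------------------------------------------------------------

#' Unit vectors under isotropic rotational diffusion
#'
#' Small-step rotational random walk on the unit sphere: at each step the
#' vector is rotated about a uniformly random perpendicular axis by an angle
#' drawn from N(0, sd = sqrt(4 D dt)) with D = 1/(6 tau_c), then renormalized.
#' In the small-step limit the P2 autocorrelation decays as exp(-t/tau_c).
#' \code{tau_c = Inf} yields a static vector (D = 0).
#'
#' @param spec a \code{\link{rotdiff_spec}}.
#' @param residue_id residue id stamped on the series.
#' @return a \code{\link{vector_series}} with ground truth in
#'   \code{attr(, "truth")}.
#' @export
gen_rotdiff_vectors <- function(spec, residue_id = 1L) {
  stopifnot(inherits(spec, "rotdiff_spec"))
  n <- spec$n_frames
  if (is.infinite(spec$tau_c)) {
    v <- matrix(rep(c(0, 0, 1), each = n), ncol = 3L)
    out <- vector_series(residue_id, v, spec$dt)
    attr(out, "truth") <- list(tau_c = Inf)
    return(out)
  }
  D <- 1 / (6 * spec$tau_c)
  step_var <- 4 * D * spec$dt
  if (step_var > 0.1)
    .stopf(paste("dt is too coarse: per-step angular variance %.3g rad^2 > 0.1;",
                 "reduce dt below %.3g s"), step_var, 0.1 / (4 * D))
  v <- withr::with_seed(spec$seed, .rot_walk(n, sqrt(step_var)))
  out <- vector_series(residue_id, v, spec$dt)
  attr(out, "truth") <- list(tau_c = spec$tau_c, D = D)
  out
}

# random walk core: pre-draws all randomness, then a tight sequential loop
.rot_walk <- function(n, step_sd, start = c(0, 0, 1), confine_cos = -1) {
  g <- matrix(stats::rnorm(3L * n), ncol = 3L)
  delta <- stats::rnorm(n, 0, step_sd)
  cd <- cos(delta); sd_ <- sin(delta)
  v <- matrix(NA_real_, n, 3L)
  u <- start / sqrt(sum(start^2))
  v[1L, ] <- u
  for (i in 2L:n) {
    gi <- g[i, ]
    a <- gi - sum(gi * u) * u          # tangent-plane direction
    na <- sqrt(sum(a * a))
    if (na < 1e-12) { v[i, ] <- u; next }
    a <- a / na
    axu <- c(a[2] * u[3] - a[3] * u[2],  # a x u
             a[3] * u[1] - a[1] * u[3],
             a[1] * u[2] - a[2] * u[1])
    w <- cd[i] * u + sd_[i] * axu
    w <- w / sqrt(sum(w * w))
    # optional cone confinement about +z: reject moves leaving the cap
    if (w[3] >= confine_cos) u <- w
    v[i, ] <- u
  }
  v
}

#' Unit vectors under restricted (cone) internal motion
#'
#' Rotational random walk confined to a cone of given half-angle about the z
#' axis (moves leaving the cap are rejected, so the stationary distribution is
#' uniform over the spherical cap). The long-time P2 plateau is S^2 with the
#' generalized order parameter S = cos(theta0) (1 + cos(theta0)) / 2.
#' \code{tau_internal} is the effective internal correlation time; the wobble
#' diffusion coefficient is derived from it via the diffusion-in-a-cone
#' closed form, so the decay of C(t) - S^2 integrates to
#' tau_internal (1 - S^2).
#'
#' @param spec a \code{\link{cone_spec}}.
#' @param residue_id residue id stamped on the series.
#' @return a \code{\link{vector_series}}; \code{attr(, "truth")} carries
#'   \code{S2}, \code{tau_internal} and the wobble diffusion coefficient.
#' @export
gen_cone_vectors <- function(spec, residue_id = 1L) {
  stopifnot(inherits(spec, "cone_spec"))
  theta0 <- spec$half_angle * pi / 180
  x0 <- cos(theta0)
  S <- x0 * (1 + x0) / 2
  Dw <- .cone_dw(theta0, spec$tau_internal)
  step_var <- 4 * Dw * spec$dt
  if (step_var > 0.1)
    .stopf("dt too coarse for the requested cone motion (step variance %.3g rad^2 > 0.1)",
           step_var)
  v <- withr::with_seed(spec$seed,
                        .rot_walk(spec$n_frames, sqrt(step_var), confine_cos = x0))
  out <- vector_series(residue_id, v, spec$dt)
  attr(out, "truth") <- list(S = S, S2 = S^2, tau_internal = spec$tau_internal,
                             D_wobble = Dw, half_angle = spec$half_angle)
  out
}

# Effective-time relation for diffusion in a cone (Lipari & Szabo 1981):
# D_w tau_eff (1 - S^2) is a closed form in x0 = cos(theta0); invert for D_w.
.cone_dw <- function(theta0, tau_eff) {
  x0 <- cos(theta0)
  S <- x0 * (1 + x0) / 2
  lhs <- -x0^2 * (1 + x0)^2 * (log((1 + x0) / 2) + (1 - x0) / 2) / (2 * (1 - x0)) +
    (1 - x0) * (6 + 8 * x0 - x0^2 - 12 * x0^3 - 7 * x0^4) / 24
  lhs / (tau_eff * (1 - S^2))
}

#' Two-state Markov bound/unbound timeline
#'
#' Alternating bound and unbound sojourns with per-step leave probabilities
#' 1 - exp(-k dt); sojourn lengths are geometric, which is exactly the
#' distribution of the frame-by-frame chain, drawn in vectorized blocks. The
#' initial state is sampled from the stationary distribution unless fixed.
#'
#' @param spec a \code{\link{two_state_spec}}.
#' @param start \code{"stationary"}, \code{"bound"} or \code{"unbound"}.
#' @return a \code{\link{bound_state_series}} whose \code{meta} stores the
#'   ground-truth rates.
#' @export
gen_two_state_timeline <- function(spec, start = c("stationary", "bound", "unbound")) {
  stopifnot(inherits(spec, "two_state_spec"))
  start <- match.arg(start)
  n <- spec$n_frames
  p_leave <- c(bound = 1 - exp(-spec$k_off * spec$dt),
               unbound = 1 - exp(-spec$k_on * spec$dt))
  states <- withr::with_seed(spec$seed, {
    cur <- switch(start,
      stationary = if (stats::runif(1) <
                       spec$k_on / max(spec$k_on + spec$k_off, .Machine$double.xmin))
        "bound" else "unbound",
      bound = "bound", unbound = "unbound")
    out <- character(0)
    while (length(out) < n) {
      p <- p_leave[[cur]]
      len <- if (p <= 0) n - length(out) else stats::rgeom(1L, p) + 1L
      out <- c(out, rep(cur, min(len, n - length(out))))
      cur <- if (cur == "bound") "unbound" else "bound"
    }
    out
  })
  dt_ns <- spec$dt * 1e9
  bound_state_series(times_ns = (seq_len(n) - 1) * dt_ns, state = states,
                     meta = list(k_on = spec$k_on, k_off = spec$k_off,
                                 dt = spec$dt, seed = spec$seed,
                                 stationary_unbound = if (spec$k_on + spec$k_off > 0)
                                   spec$k_off / (spec$k_on + spec$k_off) else NA_real_))
}

#' Toy nucleosome trajectory with scripted tail binding
#'
#' Pseudo-atom fixture for the contact pipeline: a static single-bead-per-
#' nucleotide "DNA" lattice (chain B) plus a tail chain (chain A, one bead per
#' residue). In frames scripted bound, half of the tail beads sit 3 Angstrom
#' above a DNA bead (inside the 4 Angstrom contact cutoff with margin); when
#' unbound every bead is at least 10 Angstrom away. The scripted state is
#' stored per frame, so contact classification can be checked exactly.
#'
#' @param timeline a \code{\link{bound_state_series}} (the script).
#' @param n_tail_beads tail length in beads (>= 10, so the 10 percent
#'   unbound rule has usable granularity).
#' @param seed integer seed (reserved; the construction is deterministic).
#' @return a \code{\link{trajectory}} with \code{attr(, "scripted_state")}.
#' @export
gen_toy_nucleosome_traj <- function(timeline, n_tail_beads = 36, seed = 1L) {
  stopifnot(inherits(timeline, "bound_state_series"))
  if (!.is_count(n_tail_beads) || n_tail_beads < 10)
    .stopf("n_tail_beads must be >= 10 (contact-threshold granularity)")
  n_tail <- as.integer(n_tail_beads)
  n_dna <- n_tail + 4L
  spacing <- 3.4
  nfr <- length(timeline$state)
  dna <- cbind(x = (seq_len(n_dna) - 1) * spacing, y = 0, z = 0)
  n_contact <- ceiling(n_tail / 2)
  co <- array(NA_real_, c(nfr, n_tail + n_dna, 3L))
  for (f in seq_len(nfr)) {
    bound <- timeline$state[f] == "bound"
    z <- if (bound) c(rep(3.0, n_contact), rep(8.0, n_tail - n_contact))
         else rep(10.0, n_tail)
    tail <- cbind((seq_len(n_tail) - 1) * spacing + spacing, 0, z)
    co[f, , ] <- rbind(tail, dna)
  }
  atoms <- rbind(
    .bead_atoms(n_tail, chain = "A", residue_name = "TLB"),
    within(.bead_atoms(n_dna, chain = "B", element = "P", name = "P",
                       residue_name = "DNB"), atom_id <- atom_id + n_tail)
  )
  dt_ns <- if (length(timeline$times_ns) > 1)
    diff(timeline$times_ns[1:2]) else 1
  tr <- trajectory(atoms, co, frame_interval = dt_ns,
                   origin_time = timeline$times_ns[1])
  attr(tr, "scripted_state") <- timeline$state
  tr
}

#' Synthetic melt curves as sums of logistic transitions
#'
#' f(T) = sum_k A_k / (1 + exp(-(T - Tm_k) / w_k)) plus additive Gaussian
#' noise; replicates use distinct sub-seeds derived from the spec seed.
#'
#' @param spec a \code{\link{melt_spec}}.
#' @return a melt-curve data.frame (columns \code{temperature_C}, \code{rfu},
#'   \code{replicate}) with \code{attr(, "truth")} carrying the transition
#'   table and the noiseless curve.
#' @export
gen_melt_curve <- function(spec) {
  stopifnot(inherits(spec, "melt_spec"))
  temps <- seq(spec$t_start, spec$t_end, by = spec$t_step)
  clean <- rowSums(vapply(seq_len(nrow(spec$transitions)), function(k) {
    tr <- spec$transitions[k, ]
    tr$amplitude / (1 + exp(-(temps - tr$tm) / tr$width))
  }, numeric(length(temps))))
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    noise <- if (spec$noise_sd > 0)
      withr::with_seed(.seed_stream(spec$seed, r),
                       stats::rnorm(length(temps), 0, spec$noise_sd))
    else 0
    data.frame(temperature_C = temps, rfu = clean + noise, replicate = r)
  })
  out <- do.call(rbind, reps)
  attr(out, "truth") <- list(transitions = spec$transitions, clean = clean,
                             temperatures = temps)
  out
}

#' Paired peak tables with known shift perturbations
#'
#' Returns the base table and a copy shifted by the stated per-residue
#' perturbations, with the ground truth attached: the fixture for chemical
#' shift perturbation analysis.
#'
#' @param base a \code{\link{peak_table}}.
#' @param perturbations data.frame with columns \code{residue_id},
#'   \code{d_h}, \code{d_n} (ppm shifts applied to 1H and 15N).
#' @param nitrogen_weight weight used for the ground-truth combined CSP.
#' @return list \code{a} (base), \code{b} (perturbed), \code{truth}
#'   (residue_id, d_h, d_n, csp).
#' @export
gen_peak_tables <- function(base, perturbations, nitrogen_weight = 0.154) {
  stopifnot(inherits(base, "peak_table"),
            all(c("residue_id", "d_h", "d_n") %in% names(perturbations)))
  if (anyDuplicated(perturbations$residue_id))
    .stopf("perturbations must list each residue at most once")
  b <- base
  i <- match(perturbations$residue_id, b$residue_id)
  if (anyNA(i)) .stopf("perturbed residue(s) absent from the base table")
  b$shift_H_ppm[i] <- b$shift_H_ppm[i] + perturbations$d_h
  b$shift_N_ppm[i] <- b$shift_N_ppm[i] + perturbations$d_n
  truth <- data.frame(residue_id = base$residue_id, d_h = 0, d_n = 0)
  truth$d_h[i] <- perturbations$d_h
  truth$d_n[i] <- perturbations$d_n
  truth$csp <- sqrt(truth$d_h^2 + (nitrogen_weight * truth$d_n)^2)
  list(a = base, b = b, truth = truth)
}
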