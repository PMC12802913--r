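#' Dynamic cross-correlation matrix of residue displacements
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>) with dr the displacement
#' of each residue's representative atom from its trajectory mean; +1 marks
#' fully correlated motion, -1 anticorrelated. The trajectory should already
#' be superposed on the rigid core so overall tumbling does not masquerade as
#' correlated internal motion. The selection must resolve to exactly one atom
#' per residue (C-alpha for proteins, the bead itself for toy systems).
#'
#' @param traj a \code{\link{trajectory}} (>= 10 frames).
#' @param selection representative-atom selection (default "name CA").
#' @return symmetric matrix of class \code{"dccm_matrix"} with residue-id
#'   dimnames; zero-variance residues give NA rows flagged by a warning.
#' @export
dccm <- function(traj, selection = "name CA") {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 10L) .stopf("need at least 10 frames for a DCCM")
  idx <- .resolve_selection(traj, selection)
  if (!length(idx)) .stopf("empty selection")
  res <- traj$atoms$residue_id[idx]
  if (anyDuplicated(res))
    .stopf("selection must resolve to one representative atom per residue")
  nfr <- n_frames(traj); nr <- length(idx)
  # displacement components, frame x residue, mean-centred per residue
  dx <- traj$coords[, idx, 1, drop = TRUE]; dim(dx) <- c(nfr, nr)
  dy <- traj$coords[, idx, 2, drop = TRUE]; dim(dy) <- c(nfr, nr)
  dz <- traj$coords[, idx, 3, drop = TRUE]; dim(dz) <- c(nfr, nr)
  dx <- sweep(dx, 2L, colMeans(dx)); dy <- sweep(dy, 2L, colMeans(dy))
  dz <- sweep(dz, 2L, colMeans(dz))
  cov <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / nfr
  v <- diag(cov)
  zero <- v <= 0
  if (any(zero)) .warnf("%d residue(s) have zero displacement variance; entries set NA",
                        sum(zero))
  den <- sqrt(outer(v, v))
  cc <- cov / den
  cc[zero, ] <- NA_real_; cc[, zero] <- NA_real_
  diag(cc)[!zero] <- 1
  dimnames(cc) <- list(res, res)
  class(cc) <- c("dccm_matrix", class(cc))
  cc
}

#' Radius of gyration per frame
#'
#' Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i ); the unweighted mode
#' sets all masses to 1.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param selection atoms to include.
#' @param mass_weighted use atomic masses (default TRUE).
#' @return numeric vector of per-frame Rg, Angstrom.
#' @export
radius_of_gyration <- function(traj, selection = "all", mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- .resolve_selection(traj, selection)
  if (!length(idx)) .stopf("empty selection")
  m <- if (mass_weighted) traj$atoms$mass[idx] else rep(1, length(idx))
  if (anyNA(m)) .stopf("missing atomic masses; use mass_weighted = FALSE or supply masses")
  w <- m / sum(m)
  vapply(seq_len(n_frames(traj)), function(f) {
    p <- traj$coords[f, idx, , drop = TRUE]
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
    com <- colSums(p * w)
    d <- sweep(p, 2L, com)
    sqrt(sum(w * rowSums(d * d)))
  }, numeric(1))
}

#' Residue-residue contact probability map
#'
#' Probability, over analyzed frames, that a residue pair is in contact via
#' either a heavy-atom distance criterion (default < 4 Angstrom) or a
#' geometric hydrogen-bond proxy (donor-heavy to acceptor-heavy distance <
#' 3.5 Angstrom and donor-H-acceptor angle > 120 degrees; N/O donors carrying
#' an H within 1.3 Angstrom, N/O acceptors). Pairs of adjacent residues
#' (|i - j| <= \code{mask_neighbors}) are masked to NA, since trivially
#' touching neighbours carry no ensemble information.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param selection residues considered (all their atoms).
#' @param criterion \code{"distance"} or \code{"hbond"}.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @param hb_dist,hb_angle H-bond proxy parameters (Angstrom, degrees).
#' @param mask_neighbors sequence-separation mask (default 1).
#' @param stride_ns,burn_in_ns frame filter as in
#'   \code{\link{residue_dna_contacts}} (defaults analyse every frame).
#' @return symmetric residue x residue probability matrix.
#' @export
contact_probability_map <- function(traj, selection = "all",
                                    criterion = c("distance", "hbond"),
                                    cutoff = 4.0, hb_dist = 3.5, hb_angle = 120,
                                    mask_neighbors = 1,
                                    stride_ns = traj$frame_interval,
                                    burn_in_ns = 0) {
  stopifnot(inherits(traj, "trajectory"))
  criterion <- match.arg(criterion)
  idx <- .resolve_selection(traj, selection)
  if (!length(idx)) .stopf("empty selection")
  frames <- .analysis_frames(traj, stride_ns, burn_in_ns)
  at <- traj$atoms[idx, , drop = FALSE]
  res <- sort(unique(at$residue_id))
  nr <- length(res)
  hits <- matrix(0L, nr, nr, dimnames = list(res, res))
  if (criterion == "distance") {
    hv <- idx[at$is_heavy]
    grp <- match(traj$atoms$residue_id[hv], res)
    for (f in frames) {
      p <- traj$coords[f, hv, , drop = TRUE]; dim(p) <- c(length(hv), 3L)
      d2 <- outer(rowSums(p^2), rowSums(p^2), `+`) - 2 * tcrossprod(p)
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      hit <- hit[grp[hit[, 1]] != grp[hit[, 2]], , drop = FALSE]
      if (nrow(hit)) {
        pr <- unique(cbind(grp[hit[, 1]], grp[hit[, 2]]))
        seen <- matrix(FALSE, nr, nr)
        seen[pr] <- TRUE
        hits <- hits + (seen | t(seen))
      }
    }
  } else {
    hyd <- idx[!at$is_heavy]
    if (!length(hyd))
      .stopf("no hydrogens present; use criterion = \"distance\" instead")
    pol <- idx[at$is_heavy & at$element %in% c("N", "O")]
    if (!length(pol)) .stopf("no N/O atoms available for the H-bond proxy")
    grp_pol <- match(traj$atoms$residue_id[pol], res)
    for (f in frames) {
      pp <- traj$coords[f, pol, , drop = TRUE]; dim(pp) <- c(length(pol), 3L)
      ph <- traj$coords[f, hyd, , drop = TRUE]; dim(ph) <- c(length(hyd), 3L)
      # attach each H to its nearest polar heavy atom within 1.3 A (the donor)
      dh2 <- outer(rowSums(ph^2), rowSums(pp^2), `+`) - 2 * tcrossprod(ph, pp)
      don_of_h <- apply(dh2, 1L, which.min)
      bonded <- dh2[cbind(seq_along(don_of_h), don_of_h)] < 1.3^2
      seen <- matrix(FALSE, nr, nr)
      for (h in which(bonded)) {
        dform <- don_of_h[h]
        da2 <- rowSums(sweep(pp, 2L, pp[dform, ])^2)
        cand <- which(da2 < hb_dist^2 & seq_along(pol) != dform &
                        grp_pol != grp_pol[dform])
        for (acc in cand) {
          v1 <- pp[dform, ] - ph[h, ]; v2 <- pp[acc, ] - ph[h, ]
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang > hb_angle) {
            i <- grp_pol[dform]; j <- grp_pol[acc]
            seen[i, j] <- seen[j, i] <- TRUE
          }
        }
      }
      hits <- hits + seen
    }
  }
  prob <- hits / length(frames)
  sep <- abs(outer(res, res, `-`))
  prob[sep <= mask_neighbors] <- NA_real_
  prob
}

#' Read / write interaction edge tables
#'
#' TSV with columns residue_a, residue_b, probability, class: the format of
#' hand-converted residue-interaction-network exports.
#'
#' @param path file path.
#' @return data.frame edge table.
#' @export
read_edge_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_a", "residue_b", "probability")
  miss <- setdiff(need, names(d))
  if (length(miss)) .stopf("edge table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(d$class)) d$class <- NA_character_
  .validate_edges(d)
  d
}

#' @rdname read_edge_table
#' @param edges an edge table data.frame.
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.validate_edges <- function(edges) {
  if (!nrow(edges)) return(invisible(edges))
  if (any(edges$probability < 0 | edges$probability > 1))
    .stopf("edge probabilities must lie in [0, 1]")
  if (any(edges$residue_a == edges$residue_b))
    .stopf("self-edges are not allowed")
  key <- paste(pmin(edges$residue_a, edges$residue_b),
               pmax(edges$residue_a, edges$residue_b),
               edges$class %||% "")
  if (anyDuplicated(key))
    .stopf("duplicated edge row(s): %s (no silent double-counting)",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  invisible(edges)
}

#' Node degrees over an interaction edge table
#'
#' degree(v) = sum of the probability scores of all edges incident to v;
#' highly connected residues are those with many probable noncovalent
#' interactions. Edges may be filtered by interaction class first.
#'
#' @param edges edge table (residue_a, residue_b, probability, class).
#' @param classes optional interaction classes to keep.
#' @return named numeric vector of degrees, over every residue in the table
#'   (zero for residues whose edges were all filtered out).
#' @export
node_degree <- function(edges, classes = NULL) {
  .validate_edges(edges)
  all_res <- sort(unique(c(edges$residue_a, edges$residue_b)))
  if (!is.null(classes)) edges <- edges[edges$class %in% classes, , drop = FALSE]
  deg <- stats::setNames(numeric(length(all_res)), all_res)
  if (nrow(edges)) {
    for (side in c("residue_a", "residue_b")) {
      s <- tapply(edges$probability, edges[[side]], sum)
      deg[names(s)] <- deg[names(s)] + s
    }
  }
  deg
}

#' Threshold a contact-probability map into an edge table
#'
#' @param prob matrix from \code{\link{contact_probability_map}}.
#' @param min_probability drop edges below this probability.
#' @param class label stored in the class column.
#' @return edge table data.frame.
#' @export
edges_from_probability_map <- function(prob, min_probability = 0,
                                       class = "contact") {
  res <- as.integer(rownames(prob))
  ut <- which(upper.tri(prob) & !is.na(prob) & prob > min_probability,
              arr.ind = TRUE)
  data.frame(residue_a = res[ut[, 1]], residue_b = res[ut[, 2]],
             probability = prob[ut], class = class)
}
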