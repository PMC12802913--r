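#' Build a trajectory object
#'
#' The minimal trajectory container shared by all trajectory-consuming stages:
#' an atom table plus an ordered stack of coordinate frames. Coordinates are in
#' Angstrom; times at the interface are in nanoseconds.
#'
#' @param atoms data.frame with columns \code{atom_id}, \code{name},
#'   \code{element}, \code{residue_id}, \code{residue_name}, \code{chain_id}.
#'   Columns \code{is_heavy} and \code{mass} are derived if absent.
#' @param coords numeric array of dimension (frame, atom, 3), in Angstrom.
#' @param frame_interval time between saved frames, ns.
#' @param origin_time time of the first frame, ns.
#' @return an object of class \code{"trajectory"}.
#' @export
trajectory <- function(atoms, coords, frame_interval, origin_time = 0) {
  stopifnot(is.data.frame(atoms))
  req <- c("atom_id", "name", "element", "residue_id", "residue_name", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) .stopf("atom table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$atom_id)) .stopf("atom_id values must be unique")
  if (length(dim(coords)) == 2L) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    .stopf("coords must be a (frame x atom x 3) array")
  if (dim(coords)[2] != nrow(atoms))
    .stopf("coords have %d atoms but the atom table has %d",
           dim(coords)[2], nrow(atoms))
  if (!.is_scalar(frame_interval) || frame_interval <= 0)
    .stopf("frame_interval must be a positive number of nanoseconds")
  if (is.null(atoms$is_heavy)) atoms$is_heavy <- toupper(atoms$element) != "H"
  if (is.null(atoms$mass)) {
    atoms$mass <- unname(.ELEMENT_MASS[toupper(atoms$element)])
  }
  structure(list(atoms = atoms, coords = coords,
                 frame_interval = frame_interval,
                 origin_time = origin_time,
                 superposed = FALSE),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %g ns%s\n",
              n_frames(x), nrow(x$atoms), x$frame_interval,
              if (isTRUE(x$superposed)) " (superposed)" else ""))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame times of a trajectory, ns
#' @param traj a trajectory.
#' @return numeric vector of frame timestamps.
#' @export
frame_times <- function(traj) {
  traj$origin_time + (seq_len(n_frames(traj)) - 1L) * traj$frame_interval
}

# ---------------------------------------------------------------------------
# Reading

#' Read a structure (topology plus one coordinate set) from a PDB file
#'
#' Parsing is delegated to \pkg{bio3d}. When the PDB element column is absent
#' the element is inferred from the atom name using the PDB naming convention
#' (so \code{" CA "} inside a protein residue is carbon, not calcium).
#'
#' @param path path to a PDB file.
#' @param format only \code{"pdb"} is supported.
#' @return list with \code{atoms} (data.frame of atom records) and
#'   \code{coords} (n_atoms x 3 matrix, first model).
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(tolower(format), "pdb")
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  atline <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atline)) .stopf("no ATOM/HETATM records in %s", path)
  bad <- which(atline & nchar(lines) < 54)
  if (length(bad))
    .stopf("malformed ATOM record at line %d of %s (coordinates truncated)",
           bad[1], path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- .atoms_from_bio3d(pdb$atom)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  list(atoms = atoms, coords = xyz)
}

.atoms_from_bio3d <- function(at) {
  elem <- at$elesy
  if (is.null(elem)) elem <- rep("", nrow(at))
  elem <- trimws(elem)
  need <- is.na(elem) | elem == ""
  if (any(need)) elem[need] <- .infer_element(at$elety[need], at$resid[need])
  elem <- toupper(elem)
  data.frame(
    atom_id = at$eleno,
    name = trimws(at$elety),
    element = elem,
    residue_id = at$resno,
    residue_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    is_heavy = elem != "H",
    mass = unname(.ELEMENT_MASS[elem]),
    stringsAsFactors = FALSE
  )
}

#' Read trajectory frames
#'
#' Supports multi-model PDB, DCD (both via \pkg{bio3d}) and the plain-text
#' fixture format written by \code{\link{write_traj_fixture}}. Timestamps
#' embedded in binary formats are ignored: the frame interval always comes
#' from the \code{frame_interval} argument (or, for the text fixture, from its
#' header), so synthetic fixtures and real data behave identically.
#'
#' @param path file path.
#' @param format one of \code{"pdb"}, \code{"dcd"}, \code{"fixture"};
#'   \code{"auto"} guesses from the file extension.
#' @param atoms atom table (required for \code{"dcd"} and \code{"fixture"};
#'   for PDB it is read from the file).
#' @param frame_interval ns between frames (ignored for the fixture format,
#'   which carries it in its header).
#' @param origin_time time of the first frame, ns.
#' @return a \code{\link{trajectory}}.
#' @export
read_frames <- function(path, format = c("auto", "pdb", "dcd", "fixture", "xtc"),
                        atoms = NULL, frame_interval = 1, origin_time = 0) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd", xtc = "xtc", "fixture")
  }
  if (format == "xtc")
    .stopf("XTC reading is not supported; convert to DCD or multi-model PDB")
  if (!file.exists(path)) .stopf("no such file: %s", path)
  switch(format,
    pdb = {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      at <- .atoms_from_bio3d(pdb$atom)
      xyz <- pdb$xyz
      nfr <- nrow(xyz)
      co <- array(NA_real_, c(nfr, nrow(at), 3L))
      for (f in seq_len(nfr)) co[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
      trajectory(at, co, frame_interval, origin_time)
    },
    dcd = {
      if (is.null(atoms)) .stopf("DCD input needs an `atoms` topology table")
      xyz <- bio3d::read.dcd(path, verbose = FALSE)
      nat <- ncol(xyz) / 3L
      if (nat != nrow(atoms))
        .stopf("topology has %d atoms but DCD frames have %d", nrow(atoms), nat)
      co <- array(NA_real_, c(nrow(xyz), nat, 3L))
      for (f in seq_len(nrow(xyz))) co[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
      trajectory(atoms, co, frame_interval, origin_time)
    },
    fixture = .read_fixture(path, atoms, origin_time)
  )
}

# Text fixture format: header "n_atoms n_frames frame_interval_ns", then one
# whitespace-separated x y z triple per atom per frame. Diffable and
# language-neutral.
.read_fixture <- function(path, atoms, origin_time) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- scan(con, what = double(), n = 3L, quiet = TRUE)
  if (length(hdr) != 3L) .stopf("fixture %s: malformed header", path)
  nat <- as.integer(hdr[1]); nfr <- as.integer(hdr[2]); dt <- hdr[3]
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != nat * nfr * 3L)
    .stopf("fixture %s: expected %d coordinates, found %d (truncated file?)",
           path, nat * nfr * 3L, length(vals))
  if (!is.null(atoms) && nrow(atoms) != nat)
    .stopf("topology has %d atoms but fixture frames have %d", nrow(atoms), nat)
  if (is.null(atoms)) atoms <- .bead_atoms(nat)
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  co <- array(NA_real_, c(nfr, nat, 3L))
  for (f in seq_len(nfr)) co[f, , ] <- m[((f - 1L) * nat + 1L):(f * nat), ]
  trajectory(atoms, co, dt, origin_time)
}

# generic pseudo-atom table for bead systems lacking a topology
.bead_atoms <- function(n, chain = "A", name = "CA", element = "C",
                        residue_name = "BEA", first_resid = 1L) {
  data.frame(
    atom_id = seq_len(n), name = name, element = element,
    residue_id = seq.int(first_resid, length.out = n),
    residue_name = residue_name, chain_id = chain,
    is_heavy = element != "H", mass = unname(.ELEMENT_MASS[element]),
    stringsAsFactors = FALSE
  )
}

#' Write a trajectory in the plain-text fixture format
#'
#' @param traj a trajectory.
#' @param path output path.
#' @param digits coordinate precision (decimal digits).
#' @return \code{path}, invisibly.
#' @export
write_traj_fixture <- function(traj, path, digits = 6) {
  nat <- nrow(traj$atoms); nfr <- n_frames(traj)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d %.10g", nat, nfr, traj$frame_interval), con)
  for (f in seq_len(nfr)) {
    m <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
    writeLines(apply(round(m, digits), 1L,
                     function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                       collapse = " ")), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom selection mini-language

#' Select atoms with a small expression language
#'
#' Supported primitives: \code{chain <id>}, \code{resid <ranges>} (e.g.
#' \code{resid 1-36} or \code{resid 2,5,9-12}), \code{name <list>} (e.g.
#' \code{name CA,N}), \code{heavy}, \code{hydrogen}, \code{all}; combined with
#' \code{and} / \code{or} (\code{and} binds tighter) and parentheses.
#'
#' @param traj a trajectory.
#' @param expression selection expression.
#' @return object of class \code{"atom_selection"}: list with the
#'   \code{expression}, the sorted \code{atom_ids} and their row \code{idx}.
#' @export
select_atoms <- function(traj, expression) {
  stopifnot(inherits(traj, "trajectory"))
  toks <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$atoms <- traj$atoms; st$expr <- expression
  keep <- .sel_expr(st)
  if (st$pos <= length(st$toks$text))
    .stopf("selection syntax error near '%s' (position %d) in \"%s\"",
           st$toks$text[st$pos], st$toks$at[st$pos], expression)
  idx <- which(keep)
  if (!length(idx)) .warnf("selection \"%s\" matched no atoms", expression)
  structure(list(expression = expression,
                 atom_ids = traj$atoms$atom_id[idx],
                 idx = idx),
            class = "atom_selection")
}

.sel_tokenize <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L)
    .stopf("selection expression must be a single string")
  m <- gregexpr("\\(|\\)|[^\\s()]+", expression, perl = TRUE)[[1]]
  if (m[1] == -1L) .stopf("empty selection expression")
  list(text = regmatches(expression, gregexpr("\\(|\\)|[^\\s()]+", expression, perl = TRUE))[[1]],
       at = as.integer(m))
}

.sel_peek <- function(st) if (st$pos <= length(st$toks$text)) st$toks$text[st$pos] else NA_character_
.sel_take <- function(st) { t <- .sel_peek(st); st$pos <- st$pos + 1L; t }
.sel_fail <- function(st, what) {
  tok <- .sel_peek(st)
  pos <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else nchar(st$expr) + 1L
  .stopf("selection syntax error: expected %s %s(position %d) in \"%s\"",
         what, if (is.na(tok)) "at end " else sprintf("near '%s' ", tok), pos, st$expr)
}

.sel_expr <- function(st) {
  v <- .sel_term(st)
  while (identical(tolower(.sel_peek(st)), "or")) { .sel_take(st); v <- v | .sel_term(st) }
  v
}

.sel_term <- function(st) {
  v <- .sel_factor(st)
  while (identical(tolower(.sel_peek(st)), "and")) { .sel_take(st); v <- v & .sel_factor(st) }
  v
}

.sel_factor <- function(st) {
  tok <- .sel_peek(st)
  if (is.na(tok)) .sel_fail(st, "a selection term")
  if (tok == "(") {
    .sel_take(st)
    v <- .sel_expr(st)
    if (!identical(.sel_peek(st), ")")) .sel_fail(st, "')'")
    .sel_take(st)
    return(v)
  }
  at <- st$atoms
  switch(tolower(.sel_take(st)),
    chain = {
      arg <- .sel_peek(st); if (is.na(arg)) .sel_fail(st, "a chain id")
      .sel_take(st)
      at$chain_id %in% strsplit(arg, ",")[[1]]
    },
    resid = {
      arg <- .sel_peek(st); if (is.na(arg)) .sel_fail(st, "residue ids")
      .sel_take(st)
      ids <- .parse_ranges(arg)
      if (is.null(ids)) .sel_fail(st, "residue ids like 1-36 or 2,5")
      at$residue_id %in% ids
    },
    name = {
      arg <- .sel_peek(st); if (is.na(arg)) .sel_fail(st, "atom names")
      .sel_take(st)
      toupper(at$name) %in% toupper(strsplit(arg, ",")[[1]])
    },
    heavy = at$is_heavy,
    hydrogen = !at$is_heavy,
    all = rep(TRUE, nrow(at)),
    { st$pos <- st$pos - 1L; .sel_fail(st, "a selection keyword") }
  )
}

.parse_ranges <- function(arg) {
  parts <- strsplit(arg, ",")[[1]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("^-?\\d+--?\\d+$", p)) {
      ab <- as.integer(strsplit(sub("(?<=\\d)-", ";", p, perl = TRUE), ";")[[1]])
      out <- c(out, seq.int(ab[1], ab[2]))
    } else if (grepl("^-?\\d+$", p)) {
      out <- c(out, as.integer(p))
    } else return(NULL)
  }
  out
}

.resolve_selection <- function(traj, sel) {
  if (inherits(sel, "atom_selection")) {
    if (!all(sel$atom_ids %in% traj$atoms$atom_id))
      .stopf("selection refers to atom ids not present in this trajectory")
    match(sel$atom_ids, traj$atoms$atom_id)
  } else if (is.character(sel)) {
    select_atoms(traj, sel)$idx
  } else if (is.numeric(sel)) {
    idx <- match(as.integer(sel), traj$atoms$atom_id)
    if (anyNA(idx)) .stopf("unknown atom id(s) in selection")
    idx
  } else .stopf("selection must be an expression, atom ids, or an atom_selection")
}

# ---------------------------------------------------------------------------
# Superposition

#' Superpose trajectory frames onto a reference frame
#'
#' Each frame is rigidly transformed by the least-squares rotation and
#' translation (Kabsch, with the determinant sign fix so reflections are never
#' applied) computed on the selected atoms, mirroring the usual alignment of
#' nucleosome trajectories on histone-core C-alpha atoms before tail analysis.
#'
#' @param traj a trajectory.
#' @param reference_frame frame index used as reference (default 1), or an
#'   n_sel x 3 matrix of reference coordinates for the selection.
#' @param selection selection expression / \code{atom_selection} / atom ids;
#'   needs at least 3 non-collinear atoms.
#' @return the trajectory with transformed coordinates, \code{superposed =
#'   TRUE}, and a per-frame \code{rmsd} (Angstrom, over the selection).
#' @export
superpose <- function(traj, reference_frame = 1L, selection = "all") {
  stopifnot(inherits(traj, "trajectory"))
  idx <- .resolve_selection(traj, selection)
  if (length(idx) < 3L) .stopf("superposition needs at least 3 selected atoms")
  if (is.matrix(reference_frame)) {
    ref <- reference_frame
    if (nrow(ref) != length(idx) || ncol(ref) != 3L)
      .stopf("reference matrix must be n_selected x 3")
  } else {
    ref <- traj$coords[reference_frame, idx, , drop = TRUE]
  }
  refc <- colMeans(ref)
  refm <- sweep(ref, 2L, refc)
  if (svd(refm)$d[2] < 1e-8 * max(svd(refm)$d[1], 1))
    .stopf("degenerate (collinear) reference selection")
  nfr <- n_frames(traj)
  rmsd <- numeric(nfr)
  for (f in seq_len(nfr)) {
    p <- traj$coords[f, idx, , drop = TRUE]
    pc <- colMeans(p)
    rot <- .kabsch(sweep(p, 2L, pc), refm)
    moved <- sweep(traj$coords[f, , , drop = TRUE], 2L, pc) %*% rot
    traj$coords[f, , ] <- sweep(moved, 2L, refc, `+`)
    d <- sweep(traj$coords[f, idx, , drop = TRUE], 2L, refc, `-`) - refm
    rmsd[f] <- sqrt(mean(rowSums(d * d)))
  }
  traj$superposed <- TRUE
  traj$rmsd <- rmsd
  traj
}

# ---------------------------------------------------------------------------
# N-H bond vectors

#' Extract backbone amide N-H unit-vector series
#'
#' Returns, per residue, the unit vector from the backbone nitrogen to its
#' amide proton at every frame: the orientation series that drives 15N
#' dipole-dipole relaxation. Prolines (no amide proton) are reported as absent
#' with a message, not an error.
#'
#' @param traj a trajectory; it should already be superposed on the rigid core
#'   (asserted via \code{require_superposed}).
#' @param residues residue ids to extract.
#' @param chain restrict to one chain id (default: any).
#' @param require_superposed error if the trajectory is not marked superposed.
#' @return named list of \code{\link{vector_series}} (names are residue ids);
#'   skipped prolines are listed in \code{attr(, "skipped")}.
#' @export
extract_nh_vectors <- function(traj, residues, chain = NULL,
                               require_superposed = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (require_superposed && !isTRUE(traj$superposed))
    .stopf("trajectory is not superposed; align on the rigid core first or set require_superposed = FALSE")
  at <- traj$atoms
  if (!is.null(chain)) at <- at[at$chain_id %in% chain, , drop = FALSE]
  dt_s <- traj$frame_interval * 1e-9
  out <- list(); skipped <- integer(0)
  for (r in residues) {
    rows <- at[at$residue_id == r, , drop = FALSE]
    if (!nrow(rows)) .stopf("residue %d not found", r)
    if (toupper(rows$residue_name[1]) == "PRO") {
      message(sprintf("residue %d is a proline (no amide proton); skipped", r))
      skipped <- c(skipped, r)
      next
    }
    n_row <- rows[toupper(rows$name) == "N", , drop = FALSE]
    h_row <- rows[toupper(rows$name) %in% c("H", "HN", "H1"), , drop = FALSE]
    if (!nrow(n_row)) .stopf("residue %d lacks a backbone N atom", r)
    if (!nrow(h_row)) .stopf("residue %d lacks an amide H atom", r)
    ni <- match(n_row$atom_id[1], traj$atoms$atom_id)
    hi <- match(h_row$atom_id[1], traj$atoms$atom_id)
    v <- traj$coords[, hi, , drop = TRUE] - traj$coords[, ni, , drop = TRUE]
    if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
    v <- v / sqrt(rowSums(v * v))
    out[[as.character(r)]] <- vector_series(r, v, dt_s)
  }
  attr(out, "skipped") <- skipped
  out
}
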