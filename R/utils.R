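# Internal helpers shared across modules.

# gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.98720425e-3

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

.is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# atomic masses (Da) for the elements that occur in protein/DNA systems;
# unknown elements fall back to NA and are rejected by mass-weighted ops
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938, "NA" = 22.990,
  K = 39.098, CL = 35.45, CA = 40.078
)

# Infer the element from a PDB atom name when no element column is present.
# For standard residues the first alphabetic character of the stripped name is
# the element (" CA " in a protein residue is an alpha carbon, not calcium);
# lone metal/ion atoms are recognised by their residue name matching the atom.
.infer_element <- function(name, residue_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  res <- toupper(trimws(residue_name))
  out <- character(length(nm))
  ion <- nm == res & nm %in% c("FE", "ZN", "MG", "MN", "NA", "K", "CL", "CA")
  out[ion] <- nm[ion]
  out[!ion] <- substr(nm[!ion], 1L, 1L)
  out
}

# Kabsch least-squares rotation mapping centred point set p onto centred q,
# with the determinant sign fix so reflections are never returned.
.kabsch <- function(p, q) {
  cmat <- crossprod(p, q)            # 3x3
  sv <- svd(cmat)
  d <- sign(det(sv$u) * det(sv$v))
  if (!is.finite(d) || d == 0) d <- 1
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# Lagged product-sums of a series via FFT, returned for lags 0..max_lag.
.lagged_sums_fft <- function(x, max_lag) {
  n <- length(x)
  nf <- stats::nextn(2L * n, factors = 2L)
  f <- stats::fft(c(x, numeric(nf - n)))
  a <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / nf
  a[seq_len(max_lag + 1L)]
}

.seed_stream <- function(seed, k) {
  # derived sub-seed that stays inside the 32-bit integer range
  as.integer((as.double(seed) * 48271 + k * 65537) %% 2147483647)
}
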