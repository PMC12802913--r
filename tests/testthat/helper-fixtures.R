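# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# minimal multi-model PDB text for a 1-residue, 3-atom system
make_tiny_pdb <- function(path, models = list(
                            rbind(c(0, 0, 0), c(0, 0, 1.02), c(1.4, 0, 0)))) {
  atom_line <- function(id, name, x, res = "ALA", elem = "") {
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            id, name, res, 1L, x[1], x[2], x[3], elem)
  }
  lines <- character(0)
  for (m in seq_along(models)) {
    xyz <- models[[m]]
    lines <- c(lines, sprintf("MODEL %8d", m),
               atom_line(1L, " N", xyz[1, ], elem = "N"),
               atom_line(2L, " H", xyz[2, ], elem = "H"),
               atom_line(3L, " CA", xyz[3, ]),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# bead trajectory with explicit coordinates: coords list of (n_atom x 3)
make_bead_traj <- function(coord_list, chain = "A", frame_interval = 1,
                           element = "C") {
  n <- nrow(coord_list[[1]])
  co <- array(NA_real_, c(length(coord_list), n, 3L))
  for (f in seq_along(coord_list)) co[f, , ] <- coord_list[[f]]
  trajectory(taildyn:::.bead_atoms(n, chain = chain, element = element),
             co, frame_interval = frame_interval)
}

# rate evaluation written independently of relaxation_rates(), symbol by
# symbol, used as the oracle for the spin-physics formulas
oracle_rates <- function(tau_eff, amps = 1, freq_h_mhz = 600.13, r_nh = 1.02,
                         csa_ppm = -172, gamma_h = 2.6752e8, gamma_n = -2.7126e7) {
  hbar <- 1.054571817e-34
  nu_h <- freq_h_mhz * 1e6
  nu_n <- nu_h * abs(gamma_n) / gamma_h
  wh <- 2 * pi * nu_h
  wn <- 2 * pi * nu_n
  J <- function(w) 0.4 * sum(amps * tau_eff / (1 + (w * tau_eff)^2))
  d <- 1e-7 * hbar * gamma_h * abs(gamma_n) / (r_nh * 1e-10)^3
  cc <- wn * abs(csa_ppm) * 1e-6 / sqrt(3)
  R1 <- d^2 / 4 * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + cc^2 * J(wn)
  R2 <- d^2 / 8 * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) + 6 * J(wh + wn)) +
    cc^2 / 6 * (4 * J(0) + 3 * J(wn))
  list(R1 = R1, R2 = R2, nu_n = nu_n)
}

# base peak table used by CSP fixtures
base_peaks <- function(n = 10) {
  peak_table(seq_len(n), shift_H_ppm = 8 + seq_len(n) / 20,
             shift_N_ppm = 115 + seq_len(n), residue_name = "ALA")
}
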