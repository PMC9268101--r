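# Bundled physical-constant tables. All table values are configuration, not
# code: each constant is documented here with its source convention, and the
# descriptor functions look values up by element / bond type at run time.

# Bondi van der Waals radii (Angstrom). Bondi, J. Phys. Chem. 68 (1964) 441.
vdw_radii <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

# Single-bond covalent radii (Angstrom), Cordero et al., Dalton Trans. 2008.
# Reference bond lengths r_ij are taken as the sum of the two covalent radii;
# the bond-order correction c_ij (0 / 0.1 / 0.2 / 0.3 Angstrom for single /
# aromatic / double / triple) is subtracted from r_ij to give the effective
# bond length b_ij used by the surface-area overlap formula.
covalent_radii <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                    F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                    I = 1.39)

bond_order_correction <- function(order) {
  # single 0, aromatic 0.1, double 0.2, triple 0.3 (Angstrom)
  c(`1` = 0, `1.5` = 0.1, `2` = 0.2, `3` = 0.3)[as.character(order)]
}

# Principal quantum number of the valence shell, by element.
principal_quantum_number <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2,
                              P = 3, S = 3, Cl = 3, Br = 4, I = 5)

# Valence electron counts.
valence_electrons <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
                       P = 5, S = 6, Cl = 7, Br = 7, I = 7)

# Bond dipole moments (Debye), keyed by sorted element pair and bond order.
# Documented stand-in assembled from standard bond-moment compilations
# (Smyth, "Dielectric Behavior and Structure", and common textbook tables);
# aromatic bonds take the single-bond value. Unknown bond types contribute 0
# (with a one-time warning from the descriptor).
bond_dipole_table <- local({
  k <- function(e1, e2, order) paste(sort(c(e1, e2))[1], sort(c(e1, e2))[2],
                                     format(order), sep = "|")
  tab <- new.env(parent = emptyenv())
  set <- function(e1, e2, order, mu) assign(k(e1, e2, order), mu, envir = tab)
  set("C", "C", 1, 0);    set("C", "C", 1.5, 0); set("C", "C", 2, 0)
  set("C", "C", 3, 0)
  set("C", "H", 1, 0.30)
  set("C", "N", 1, 0.22); set("C", "N", 1.5, 0.22)
  set("C", "N", 2, 1.90); set("C", "N", 3, 3.50)
  set("C", "O", 1, 0.74); set("C", "O", 1.5, 0.74); set("C", "O", 2, 2.30)
  set("C", "S", 1, 0.90); set("C", "S", 1.5, 0.90); set("C", "S", 2, 2.60)
  set("C", "F", 1, 1.41); set("C", "Cl", 1, 1.46)
  set("Br", "C", 1, 1.38); set("C", "I", 1, 1.19)
  set("H", "N", 1, 1.31); set("H", "O", 1, 1.51); set("H", "S", 1, 0.68)
  set("N", "N", 1, 0); set("N", "N", 1.5, 0); set("N", "N", 2, 0)
  set("N", "O", 1, 0.30); set("N", "O", 1.5, 0.30); set("N", "O", 2, 2.00)
  set("O", "S", 2, 2.80); set("O", "O", 1, 0)
  list(get = function(e1, e2, order) {
    key <- k(e1, e2, order)
    if (exists(key, envir = tab, inherits = FALSE)) get(key, envir = tab)
    else NA_real_
  })
})

# Lennard-Jones well depths (kcal/mol) and minimum-energy radii (Angstrom)
# per element, UFF-flavoured values for the steric probe field. Combined by
# Lorentz-Berthelot rules: r_min,ij = R_i + R_probe, eps_ij = sqrt(e_i e_p).
lj_params <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  eps = c(0.030, 0.105, 0.069, 0.060, 0.050, 0.305, 0.274, 0.227,
          0.389, 0.550),
  rmin = c(1.20, 1.70, 1.625, 1.48, 1.30, 2.10, 2.00, 1.75, 1.85, 1.98))

# Coulomb conversion constant, kcal*Angstrom/(mol*e^2).
coulomb_constant <- 332.0637

# Gasteiger-Marsili PEOE electronegativity polynomials chi(q) = a + b q + c q^2
# (Tetrahedron 36 (1980) 3219), keyed by element and hybridization.
gasteiger_params <- data.frame(
  key = c("H", "C.3", "C.2", "C.1", "N.3", "N.2", "N.1",
          "O.3", "O.2", "F", "Cl", "Br", "I", "S.3"),
  a = c(7.17, 7.98, 8.79, 10.39, 11.54, 12.87, 15.68,
        14.18, 17.07, 14.66, 11.00, 10.08, 9.90, 10.14),
  b = c(6.24, 9.18, 9.32, 9.45, 10.82, 11.15, 11.70,
        12.92, 13.79, 13.85, 9.69, 8.47, 7.96, 9.13),
  c = c(-0.56, 1.88, 1.51, 0.73, 1.36, 0.85, -0.27,
        1.39, 0.47, 2.31, 1.35, 1.16, 0.96, 1.38))
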