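test_that("topological distance matrix matches the BFS oracle", {
  chain <- parse_smiles("CCC")
  expect_equal(topological_distance_matrix(chain)[1, 3], 2)
  benz <- parse_smiles("c1ccccc1")
  expect_equal(topological_distance_matrix(benz)[1, 4], 3)
  for (g in fixture_graphs()) {
    expect_equal(topological_distance_matrix(g), oracle_distances(g),
                 info = g$id)
  }
  two <- molgraph(data.frame(element = c("C", "C"), charge = 0L,
                             aromatic = FALSE, nH = 3L),
                  data.frame(i = 1L, j = 2L, order = 1))
  expect_silent(topological_distance_matrix(two))
})

test_that("detour matrix equals the exhaustive path-enumeration oracle", {
  # acyclic identity
  butane <- parse_smiles("CCCC")
  expect_identical(detour_matrix(butane),
                   topological_distance_matrix(butane))
  # benzene: adjacent 5, meta 4, para 3 (the two ring arcs)
  benz <- parse_smiles("c1ccccc1")
  Dt <- detour_matrix(benz)
  expect_equal(Dt[1, 2], 5)
  expect_equal(Dt[1, 3], 4)
  expect_equal(Dt[1, 4], 3)
  expect_equal(Dt, oracle_detour(benz))
  # fused bicyclic
  naph <- parse_smiles("c1ccc2ccccc2c1")
  expect_equal(detour_matrix(naph), oracle_detour(naph))
  # entrywise >= distance on all fixtures; equality iff acyclic
  for (g in fixture_graphs()) {
    if (n_atoms(g) > 16) next  # oracle enumeration cost
    Dt <- detour_matrix(g)
    D <- topological_distance_matrix(g)
    expect_true(all(Dt >= D), info = g$id)
    acyclic <- n_bonds(g) == n_atoms(g) - 1L
    expect_identical(all(Dt == D), acyclic, info = g$id)
  }
  expect_error(detour_matrix(parse_smiles("c1ccccc1"), max_atoms = 3),
               "max_atoms")
})

test_that("distance/detour eigenvector descriptor matches its oracle", {
  # acyclic graph: quotient matrix is all-ones off-diagonal, the smallest
  # eigenvalue is degenerate and the coefficient sum vanishes -> NaN
  pentane <- parse_smiles("CCCCC")
  expect_warning(v <- ve3sign_d_dt(pentane), "NaN")
  expect_true(is.nan(v))
  expect_true(is.nan(oracle_ve3sign(pentane)))
  # vertex-transitive ring: same degeneracy
  expect_warning(expect_true(is.nan(ve3sign_d_dt(parse_smiles("c1ccccc1")))))
  # non-degenerate fixtures agree with the independent eigen oracle
  for (g in fixture_graphs()) {
    if (n_atoms(g) > 16) next
    v <- suppressWarnings(ve3sign_d_dt(g))
    o <- oracle_ve3sign(g)
    if (is.nan(o)) expect_true(is.nan(v), info = g$id)
    else expect_equal(v, o, tolerance = 1e-8, info = g$id)
  }
})

test_that("intrinsic states reproduce the printed reference values", {
  # pyridine-type =N-: 3.00, tertiary amine >N-: 2.00, ether -O-: 3.50
  py <- parse_smiles("c1ccncc1")
  expect_equal(estate_intrinsic(py)[py$atoms$element == "N"], 3.00)
  tert <- parse_smiles("CN(C)C")
  expect_equal(estate_intrinsic(tert)[tert$atoms$element == "N"], 2.00)
  eth <- parse_smiles("COC")
  expect_equal(estate_intrinsic(eth)[eth$atoms$element == "O"], 3.50)
  # hydrogens in the filled graph: delta = delta_v = N = 1 -> I = 5
  gh <- hfill(parse_smiles("C"))
  expect_equal(estate_intrinsic(gh)[gh$atoms$element == "H"], rep(5, 4))
  expect_error(estate_intrinsic(molgraph(
    data.frame(element = "Xx", charge = 0L, aromatic = FALSE, nH = 0L),
    data.frame(i = integer(), j = integer(), order = numeric()))), "Xx")
})

test_that("Burden matrix follows the published weighting rule literally", {
  # ethane, H-filled: 8 atoms, C-C bond order 1 (no terminal heavy atom in
  # the H-filled sense: both carbons have degree 4); C-H bonds get +0.001
  eth <- hfill(parse_smiles("CC"))
  w <- estate_intrinsic(eth)
  B <- burden_matrix(eth, w)
  expect_equal(diag(B), w)
  expect_equal(B[1, 2], 1)            # C-C, neither terminal
  expect_equal(B[1, 3], 1 + 0.001)    # C-H, H terminal
  expect_equal(B[3, 4], 0.001)        # H...H not bonded
  expect_true(isSymmetric(B))
  # aromatic bond entry is 1.5 (+0.001 only when an endpoint is terminal)
  benz <- hfill(parse_smiles("c1ccccc1"))
  Bb <- burden_matrix(benz, estate_intrinsic(benz))
  expect_equal(Bb[1, 2], 1.5)
  expect_error(burden_matrix(eth, w[-1]), "length")
})

test_that("Burden eigenvalue descriptor matches a dense eigen oracle", {
  # 3x3 analytic check: second-smallest eigenvalue of a hand-built matrix
  M <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  expect_equal(sort(eigen(M, symmetric = TRUE)$values)[2], 2)
  for (g in fixture_graphs()) {
    expect_equal(spmin2_bh_s(g), oracle_burden_second_smallest(g),
                 tolerance = 1e-9, info = g$id)
  }
})

test_that("atomic logP contributions sum to the reference whole-molecule logP", {
  smis <- fixture_molecules()
  for (nm in names(smis)) {
    g <- parse_smiles(smis[[nm]], id = nm)
    lp <- atomic_logp(g)
    expect_equal(sum(lp$logp_h), unname(rdkit_logp_reference[[nm]]),
                 tolerance = 1e-3, info = nm)
    expect_equal(nrow(lp), n_atoms(g), info = nm)
  }
  # benzene: six identical aromatic-CH contributions
  benz <- parse_smiles("c1ccccc1")
  expect_equal(unique(atomic_logp(benz)$type), "C18")
  # methane carbon: its bundled-table value (C1 plus 4 H1)
  meth <- atomic_logp(parse_smiles("C"))
  expect_equal(meth$logp, 0.1441)
  expect_equal(meth$logp_h, 0.1441 + 4 * 0.1230)
})

test_that("van der Waals surface areas follow the overlap formula", {
  # isolated atom: full sphere
  iso <- molgraph(data.frame(element = "C", charge = 0L, aromatic = FALSE,
                             nH = 0L),
                  data.frame(i = integer(), j = integer(), order = numeric()))
  expect_equal(vdw_surface_area(iso), 4 * pi * 1.70^2)
  # ethane carbons: hand-evaluated formula with the bundled constants
  eth <- parse_smiles("CC")
  R <- 1.70; rij <- 0.76 + 0.76  # covalent radii sum, single bond (c = 0)
  dij <- min(max(abs(R - R), rij), 2 * R)
  expected <- 4 * pi * R^2 - pi * R * (R^2 - (R - dij)^2) / dij
  expect_equal(vdw_surface_area(eth), rep(expected, 2))
  # VSA is non-negative and positive in total for every fixture
  for (g in fixture_graphs()) {
    v <- vdw_surface_area(g)
    expect_true(all(v >= 0), info = g$id)
    expect_gt(sum(v), 0)
  }
})

test_that("P_VSA bin sums the right atoms", {
  # all atomic logP outside (0, 0.25] -> 0 (ethane: C1+3H = 0.513)
  expect_equal(p_vsa_logp_5(parse_smiles("CC")), 0)
  # brute-force filter-and-sum oracle on the fixtures
  for (g in fixture_graphs()) {
    lp <- atomic_logp(g)$logp_h
    vsa <- vdw_surface_area(g)
    expect_equal(p_vsa_logp_5(g), sum(vsa[lp > 0 & lp <= 0.25]), info = g$id)
  }
})

test_that("edge-adjacency eigenvalue descriptor matches oracles", {
  # two adjacent bonds with dipoles mu1, mu2: eigenvalues of [[m1,1],[1,m2]]
  w <- molgraph(data.frame(element = c("O", "C", "N"), charge = 0L,
                           aromatic = FALSE, nH = c(1L, 2L, 2L)),
                data.frame(i = c(1L, 2L), j = c(2L, 3L), order = 1))
  mu1 <- 0.74; mu2 <- 0.22  # C-O and C-N single-bond dipoles
  lam <- sort(eigen(matrix(c(mu1, 1, 1, mu2), 2, 2))$values,
              decreasing = TRUE)
  expect_equal(eig02_ea_dm(w), lam[2])
  # all dipoles zero (alkane): second-largest eigenvalue of the plain
  # edge-adjacency matrix
  hexane <- parse_smiles("CCCCCC")
  m <- n_bonds(hexane)
  E <- matrix(0, m, m)
  for (p in 1:(m - 1)) for (q in (p + 1):m) {
    if (length(intersect(c(hexane$bonds$i[p], hexane$bonds$j[p]),
                         c(hexane$bonds$i[q], hexane$bonds$j[q]))) > 0) {
      E[p, q] <- E[q, p] <- 1
    }
  }
  expect_equal(eig02_ea_dm(hexane),
               sort(eigen(E, symmetric = TRUE)$values, decreasing = TRUE)[2])
  expect_error(eig02_ea_dm(parse_smiles("CC")), "2 bonds")
})

test_that("acceptor typing and the distance-nine pair count behave", {
  # two terminal hydroxyls separated by nine bonds -> exactly one pair
  diol <- parse_smiles("OCCCCCCCCO")
  expect_equal(topological_distance_matrix(diol)[1, 10], 9)
  expect_equal(cats2d_09_aa(diol), 1L)
  # single acceptor and no acceptor
  expect_equal(cats2d_09_aa(parse_smiles("CCCCCCCCCCO")), 0L)
  expect_equal(cats2d_09_aa(parse_smiles("c1ccccc1")), 0L)
  # pyrrole-type and amide nitrogens are excluded
  acc <- acceptor_atoms(parse_smiles("c1cc[nH]c1"))
  expect_false(any(acc))
  am <- parse_smiles("CC(=O)NC")
  expect_equal(which(acceptor_atoms(am)), 3L)  # carbonyl O only
  # brute-force equality on every fixture
  for (g in fixture_graphs()) {
    expect_equal(cats2d_09_aa(g), oracle_cats_count(g), info = g$id)
  }
})

test_that("all five descriptors are invariant under atom reordering", {
  set.seed(101)
  graphs <- fixture_graphs()
  graphs <- graphs[vapply(graphs, n_atoms, 0L) <= 14]
  for (g in graphs) {
    ref <- suppressWarnings(descriptor_vector(g))
    for (rep in 1:5) {
      perm <- sample(n_atoms(g))
      gp <- permute_molgraph(g, perm)
      got <- suppressWarnings(descriptor_vector(gp))
      for (d in names(ref)) {
        if (is.nan(ref[[d]])) expect_true(is.nan(got[[d]]), info = g$id)
        else expect_equal(got[[d]], ref[[d]], tolerance = 1e-8,
                          info = paste(g$id, d))
      }
    }
  }
})

test_that("descriptor_vector is deterministic and names errors", {
  g <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O", id = "aspirin")
  v1 <- descriptor_vector(g)
  v2 <- descriptor_vector(g)
  expect_identical(v1, v2)
  expect_named(v1, c("VE3sign_D_Dt", "SpMin2_Bh_s", "P_VSA_logP_5",
                     "Eig02_EA_dm", "CATS2D_09_AA"))
  suppressWarnings(expect_error(descriptor_vector(parse_smiles("CC")),
                                "Eig02_EA_dm"))
})
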