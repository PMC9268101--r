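toy_molecule <- function(xyz, q = NULL, id = "toy") {
  n <- nrow(xyz)
  atoms <- data.frame(element = "C", charge = 0L, aromatic = FALSE, nH = 0L,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (!is.null(q)) atoms$q <- q
  bonds <- if (n > 1) data.frame(i = 1:(n - 1), j = 2:n, order = 1)
  else data.frame(i = integer(), j = integer(), order = numeric())
  molgraph(atoms, bonds, id = id)
}

test_that("grid construction covers the bounding box plus margin", {
  m <- toy_molecule(matrix(0, 1, 3))
  g <- build_grid(m, spacing = 1.4, margin = 3)
  expect_true(all(g$dims >= 5))          # ceil(6/1.4) + 1 = 5 points per axis
  pts <- grid_points(g)
  expect_true(all(apply(pts, 2, min) <= -3))
  expect_true(all(apply(pts, 2, max) >= 3))
  # two molecules: grid covers both
  m2 <- toy_molecule(matrix(c(5, 5, 5), 1, 3))
  g2 <- build_grid(list(m, m2), spacing = 1.4, margin = 3)
  pts2 <- grid_points(g2)
  expect_true(all(apply(pts2, 2, max) >= 8))
  # halving the spacing multiplies the point count by ~8
  g3 <- build_grid(list(m, m2), spacing = 0.7, margin = 3)
  expect_gt(prod(g3$dims) / prod(g2$dims), 6)
  expect_lt(prod(g3$dims) / prod(g2$dims), 10)
  expect_error(build_grid(parse_smiles("C")), "coordinates")
})

test_that("steric field matches the Lennard-Jones closed form", {
  m <- toy_molecule(matrix(0, 1, 3))
  g <- build_grid(m, spacing = 1.4, margin = 2.8)  # grid point at the atom
  E <- steric_field(m, g, cap = 30)
  pts <- grid_points(g)
  at_centre <- which(rowSums(abs(pts)) < 1e-9)
  expect_length(at_centre, 1L)
  expect_equal(E[at_centre], 30)  # singularity clamped to +cap
  # minimum energy at r = r_min equals -sqrt(eps_C * eps_probe)
  rmin <- 1.70 + 1.73
  eps <- sqrt(0.105 * 0.105)
  d <- sqrt(rowSums(pts^2))
  lj <- function(r) eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  expect_equal(E[d > 0.1], pmin(pmax(lj(d[d > 0.1]), -30), 30),
               tolerance = 1e-10)
  expect_gte(min(E), -eps - 1e-12)
  # decay: a 20 A distant atom contributes essentially nothing
  far <- toy_molecule(matrix(c(20, 0, 0), 1, 3))
  expect_lt(max(abs(steric_field(far, g))), 1e-3)
})

test_that("electrostatic field uses the distance-dependent dielectric", {
  m <- toy_molecule(matrix(0, 1, 3), q = 1)
  g <- build_grid(m, spacing = 1.4, margin = 3)
  E <- electrostatic_field(m, g, cap = 1e6)
  pts <- grid_points(g)
  d2 <- rowSums(pts^2)
  keep <- d2 > 1e-9
  expect_equal(E[keep], 332.0637 / d2[keep], tolerance = 1e-6)
  # net-zero symmetric pair, probe equidistant -> 0
  pair <- toy_molecule(matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                       q = c(1, -1))
  gp <- build_grid(pair, spacing = 1, margin = 2)
  Ep <- electrostatic_field(pair, gp)
  mid <- grid_points(gp)[, 1] == 0
  expect_true(any(mid))
  expect_equal(Ep[mid], rep(0, sum(mid)), tolerance = 1e-10)
  # all charges zero -> zero field
  z <- toy_molecule(matrix(rnorm(9), 3, 3), q = rep(0, 3))
  expect_equal(max(abs(electrostatic_field(z, build_grid(z)))), 0)
})

test_that("both field types are translation covariant", {
  set.seed(60)
  xyz <- matrix(runif(12, -1, 1), 4, 3)
  q <- runif(4, -0.3, 0.3)
  m <- toy_molecule(xyz, q)
  g <- build_grid(m, spacing = 1.4, margin = 3)
  shift <- c(2.5, -1.0, 3.0)
  m2 <- toy_molecule(sweep(xyz, 2, -shift), q)
  g2 <- g; g2$origin <- g$origin + shift
  expect_equal(steric_field(m, g), steric_field(m2, g2), tolerance = 1e-8)
  expect_equal(electrostatic_field(m, g), electrostatic_field(m2, g2),
               tolerance = 1e-8)
})

test_that("column filtering drops flat columns and records the mask", {
  set.seed(61)
  M1 <- matrix(rnorm(40), 4, 10)
  M1[, 3] <- 5                      # constant column
  blk <- assemble_and_filter(list(steric = M1),
                             build_grid(toy_molecule(matrix(0, 1, 3))),
                             min_sd = 0.05)
  expect_false(blk$mask$steric[3])
  expect_equal(ncol(blk$X), 9L)
  # min_sd = 0 keeps everything
  blk0 <- assemble_and_filter(list(steric = M1),
                              build_grid(toy_molecule(matrix(0, 1, 3))),
                              min_sd = 0)
  expect_equal(ncol(blk0$X), 10L)
  # identical molecules: everything dropped -> error
  flat <- matrix(1, 3, 8)
  expect_error(assemble_and_filter(list(steric = flat),
                                   build_grid(toy_molecule(matrix(0, 1, 3)))),
               "dropped")
})

test_that("NIPALS PLS reduces to OLS at full rank", {
  set.seed(62)
  n <- 12; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1, -2, 0.5, 1.5)) + rnorm(n, 0, 0.2)
  pls <- qsar_pls(X, y, ncomp = p)
  ols <- qsar_mlr(X, y = y)
  expect_equal(fitted(pls), unname(fitted(ols)), tolerance = 1e-8)
  # rank-1 construction recovered by one component
  t1 <- rnorm(n); p1 <- rnorm(p)
  X1 <- tcrossprod(t1, p1)
  y1 <- 2 * t1
  pls1 <- qsar_pls(X1, y1, ncomp = 1)
  expect_equal(pls1$R2, 1, tolerance = 1e-10)
  # y orthogonal to all columns -> error (no usable direction)
  X0 <- matrix(rep(c(1, -1), 6), 12, 1)
  y0 <- rep(0, 12)
  expect_error(qsar_pls(X0, y0, ncomp = 1), "orthogonal")
  expect_error(qsar_pls(X, y, ncomp = 50), "ncomp")
})

test_that("PLS LOO Q2 behaves like a cross-validated statistic", {
  set.seed(63)
  n <- 16
  # low-rank predictors (3 latent factors), the regime PLS is built for
  scores <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(rnorm(3 * 30), 3, 30)
  X <- scores %*% load + matrix(rnorm(n * 30, 0, 0.05), n, 30)
  y <- drop(scores %*% c(2, -1, 1)) + rnorm(n, 0, 0.05)
  r2 <- qsar_pls(X, y, ncomp = 3)$R2
  q2 <- loo_q2_pls(X, y, ncomp = 3)$Q2
  expect_lte(q2, r2)
  expect_gt(q2, 0.5)   # strong low-rank signal survives LOO
  # permuted responses: no predictive power on average
  q2_perm <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    loo_q2_pls(X, sample(y), ncomp = 2)$Q2
  }, 0)
  expect_lt(mean(q2_perm), 0.2)
})

test_that("contour export back-maps coefficients through the mask", {
  set.seed(64)
  n <- 10
  grid <- build_grid(toy_molecule(matrix(0, 1, 3)), spacing = 2, margin = 2)
  npts <- prod(grid$dims)
  ste <- matrix(rnorm(n * npts, sd = 0.3), n, npts)
  ele <- matrix(rnorm(n * npts, sd = 0.3), n, npts)
  ste[, 5] <- 0  # flat -> dropped
  blk <- assemble_and_filter(list(steric = ste, electrostatic = ele), grid)
  # response driven by one retained steric column
  drive <- which(blk$field == "steric")[3]
  y <- blk$X[, drive] + rnorm(n, 0, 0.01)
  pls <- qsar_pls(blk, y, ncomp = 2)
  cc <- contour_coefficients(pls)
  expect_equal(nrow(cc), ncol(blk$X))
  expect_false(5 %in% cc$point[cc$field == "steric"])
  top <- which.max(abs(cc$coefficient))
  expect_equal(top, drive)
  expect_gt(cc$coefficient[top], 0)
  # single-field model exports only that field
  blk1 <- assemble_and_filter(list(electrostatic = ele), grid)
  pls1 <- qsar_pls(blk1, y, ncomp = 1)
  expect_true(all(contour_coefficients(pls1)$field == "electrostatic"))
})

test_that("Gasteiger charges are sensible and conserved", {
  m <- parse_smiles("CCO")
  q <- gasteiger_charges(m)
  expect_length(q, 3L)
  expect_equal(sum(q), 0, tolerance = 1e-8)   # neutral molecule
  # before H folding, oxygen is the most negative centre
  q_raw <- gasteiger_charges(m, fold_hydrogens = FALSE)
  expect_lt(q_raw[3], 0)
  expect_lt(q_raw[3], q_raw[1])
  # charge conservation for an ion
  ion <- parse_smiles("C[N+](C)(C)C")
  expect_equal(sum(gasteiger_charges(ion)), 1, tolerance = 1e-8)
})
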