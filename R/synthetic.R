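#' Specification for the synthetic 2D dataset generator
#'
#' The reference 54-compound antagonist set exists only as printed figures,
#' so end-to-end testing uses synthetic molecules with the same statistical
#' structure: drug-like graphs on quinazoline / benzoxazole-like scaffolds
#' with varied substituents, and activities generated as the published
#' linear function of the five model descriptors plus Gaussian noise with
#' sigma 0.30 log units (the reported training RMSE).
#'
#' @param n_compounds number of molecules (default 54).
#' @param beta named true coefficient vector including `(Intercept)`
#'   (default: the published model coefficients).
#' @param sigma activity noise standard deviation in log units (default 0.30).
#' @param seed integer seed (required).
#' @param min_ic50_span minimum IC50 spread in orders of magnitude before
#'   the generator resamples substituents (default 3, matching the reported
#'   0.43-684 uM range).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 54L,
                           beta = coef(published_tlr7_model()),
                           sigma = 0.30, seed, min_ic50_span = 3) {
  if (missing(seed)) stop("synthetic_spec requires an explicit integer seed")
  stopifnot(n_compounds >= 10L, sigma >= 0)
  structure(list(n_compounds = as.integer(n_compounds), beta = beta,
                 sigma = sigma, seed = as.integer(seed),
                 min_ic50_span = min_ic50_span),
            class = "synthetic_spec")
}

# Scaffold templates; each %s slot receives a parenthesised substituent.
# The set was calibrated once (seeds 1-10) so that every one of the five
# model descriptors varies enough to matter at the reported noise level
# (sigma 0.30): nitrogen-bicyclic cores with piperazines give the bulk of
# the surface-area and dipole spread, the near-symmetric bis-morpholine
# supplies the strongly negative tail of the distance/detour eigenvector
# descriptor, and the saturated piperidine-amine scaffold spreads the
# Burden-matrix eigenvalue.
synthetic_scaffolds <- c(
  quinazoline_piperazine = "c1cc2ncnc(N3CCN%sCC3)c2cc1%s",
  benzoxazole_piperazine = "c1cc2nc(N3CCN%sCC3)oc2cc1%s",
  phenyl_piperazine = "c1ccc(N2CCN%sCC2)cc1%s",
  quinoline_piperazine = "c1cc2cccnc2c(N3CCN%sCC3)c1%s",
  bis_morpholine = "O1CCN(CC1)c1ccc(N2CCOCC2)cc1%s",
  piperidine_amine = "C1CCN(CCN(C)C)CC1%s")

scaffold_weights <- c(0.25, 0.20, 0.15, 0.10, 0.18, 0.12)

slot_counts <- c(quinazoline_piperazine = 2L, benzoxazole_piperazine = 2L,
                 phenyl_piperazine = 2L, quinoline_piperazine = 2L,
                 bis_morpholine = 1L, piperidine_amine = 1L)

# "quiet" fragments vary size and halogen/nitrile dipoles without touching
# the P_VSA bin; "active" fragments carry hydrogen-bond acceptors at chain
# depths that create acceptor pairs at topological distance nine on these
# scaffolds (weights favour the multi-hit tails)
synthetic_fragments_quiet <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC",
                               "CCCCCCCC", "CCF", "CCCF", "CCCl", "CCC#N",
                               "CCCC#N")
synthetic_fragments_active <- c("CCCCOC", "CCCC(=O)C", "CCCC(=O)OC",
                                "CCCCN(C)C", "CCCOC", "CCCN(C)C",
                                "CCOCCOC", "CCOC", "CCN(C)C")
active_weights <- c(3, 3, 3, 2, 2, 2, 1, 1, 1) / 18
active_fraction <- 0.8

build_synthetic_molecule <- function(k) {
  sc_name <- sample(names(synthetic_scaffolds), 1L, prob = scaffold_weights)
  tpl <- synthetic_scaffolds[[sc_name]]
  nslots <- slot_counts[[sc_name]]
  subs <- vapply(seq_len(nslots), function(s) {
    if (stats::runif(1) < active_fraction)
      sprintf("(%s)", sample(synthetic_fragments_active, 1L,
                             prob = active_weights))
    else sprintf("(%s)", sample(synthetic_fragments_quiet, 1L))
  }, "")
  smi <- do.call(sprintf, as.list(c(tpl, subs)))
  parse_smiles(smi, id = sprintf("syn_%02d", k))
}

#' Generate a synthetic 2D-QSAR dataset
#'
#' Assembles `n_compounds` molecules by seeded random substituent attachment
#' on the bundled scaffolds, computes the five model descriptors, and draws
#' activities `pIC50 = intercept + X beta + N(0, sigma^2)`. The molecule set
#' is resampled (deterministically, from the same stream) until the implied
#' IC50 values span at least `min_ic50_span` orders of magnitude and the
#' descriptor matrix is full rank.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `molecules` (list of `molgraph`), `descriptors`
#'   (data.frame, id + five columns), `activities` (data.frame id, IC50_uM,
#'   pIC50, class), `truth` (list: beta, sigma, seed).
#' @export
generate_2d_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  d_names <- setdiff(names(spec$beta), "(Intercept)")
  target_median <- -0.85  # median pIC50 of a set spanning the reference
                          # 0.43-684 uM activity window
  for (attempt in 1:25) {
    mols <- vector("list", spec$n_compounds)
    k <- 0L
    while (k < spec$n_compounds) {
      g <- tryCatch(build_synthetic_molecule(k + 1L),
                    warning = function(w) NULL,
                    error = function(e) NULL)
      if (is.null(g)) next
      dv <- tryCatch(suppressWarnings(descriptor_vector(g)),
                     error = function(e) NULL)
      if (is.null(dv) || anyNA(dv) || any(!is.finite(dv))) next
      k <- k + 1L
      attr(g, "descriptors") <- dv
      mols[[k]] <- g
    }
    X <- do.call(rbind, lapply(mols, attr, "descriptors"))
    rownames(X) <- vapply(mols, function(g) g$id, "")
    mu <- drop(cbind(1, X[, d_names]) %*% spec$beta[c("(Intercept)", d_names)])
    # the reference compounds' descriptor location is unknowable (appendix
    # images only), so the linear predictor's median is anchored inside the
    # reference activity window; the shift is folded into the effective
    # intercept reported in truth$beta
    shift <- target_median - stats::median(mu)
    y <- mu + shift + stats::rnorm(spec$n_compounds, 0, spec$sigma)
    span_ok <- diff(range(y)) >= spec$min_ic50_span
    rank_ok <- qr(cbind(1, X))$rank == ncol(X) + 1L
    classes_ok <- length(unique(classify_activity(ic50_from_pic50(y)))) == 4L
    if (span_ok && rank_ok && classes_ok) break
  }
  if (!(span_ok && rank_ok && classes_ok))
    stop("could not generate a dataset with the required activity spread; ",
         "try another seed")
  beta_eff <- spec$beta
  beta_eff[["(Intercept)"]] <- beta_eff[["(Intercept)"]] + shift
  ic50 <- ic50_from_pic50(y)
  desc <- cbind(data.frame(id = rownames(X)), as.data.frame(X))
  rownames(desc) <- NULL
  act <- data.frame(id = rownames(X), IC50_uM = ic50, pIC50 = y,
                    class = classify_activity(ic50))
  list(molecules = mols, descriptors = desc, activities = act,
       truth = list(beta = beta_eff, sigma = spec$sigma, seed = spec$seed,
                    intercept_shift = shift))
}

#' Decoy descriptor columns for selection benchmarks
#'
#' Generates `n_decoys` additional columns as random smooth functions of the
#' true descriptors plus noise, rescaled to unit variance; any decoy with
#' absolute correlation above `max_cor` against an existing column is
#' redrawn, so a plain collinearity prefilter cannot remove them trivially.
#'
#' @param X numeric matrix/data.frame of true descriptors.
#' @param n_decoys number of decoy columns (default 15).
#' @param max_cor redraw threshold (default 0.95).
#' @param noise_sd standard deviation of the additive noise relative to the
#'   unit-variance smooth component (default 2: decoys resemble correlated
#'   but mostly-noise alternative descriptors, as in a large real descriptor
#'   block).
#' @param seed integer seed.
#' @return data.frame with columns `decoy_01`, ...
#' @export
decoy_descriptors <- function(X, n_decoys = 15L, max_cor = 0.95,
                              noise_sd = 2, seed) {
  if (missing(seed)) stop("decoy_descriptors requires an explicit seed")
  X <- as.matrix(X)
  set.seed(seed)
  n <- nrow(X)
  Z <- scale(X)
  out <- matrix(0, n, n_decoys)
  have <- Z
  for (j in seq_len(n_decoys)) {
    for (try in 1:50) {
      w <- stats::rnorm(ncol(Z), 0, 0.5)
      src <- drop(Z %*% w)
      bent <- drop(scale(sin(src) + 0.3 * src^2))
      cand <- drop(scale(bent + stats::rnorm(n, 0, noise_sd)))
      if (max(abs(stats::cor(cand, have))) < max_cor) break
    }
    out[, j] <- cand
    have <- cbind(have, cand)
  }
  colnames(out) <- sprintf("decoy_%02d", seq_len(n_decoys))
  as.data.frame(out)
}

#' Generate an aligned 3D toy dataset
#'
#' Rigid pseudo-molecules sharing one fixed 8-atom geometry (a seeded random
#' arrangement in a 4 Angstrom box) with per-molecule random partial charges
#' in +/-0.3 e. Activities are a linear function of the electrostatic field
#' at three designated grid points plus Gaussian noise. Because all
#' molecules share the geometry, the steric block is constant and carries no
#' signal - only the electrostatic field discriminates, mirroring a pure
#' charge-variation design.
#'
#' @param n number of molecules (>= 10).
#' @param seed integer seed.
#' @param sigma activity noise standard deviation (default 0.1).
#' @param spacing,margin grid geometry (defaults 1.4 / 3.0 Angstrom).
#' @return list with `molecules`, `grid`, `block` (a `field_block` of the
#'   electrostatic and steric fields), `y`, `truth` (designated column
#'   indices within the block, their coefficients, sigma, seed).
#' @export
generate_3d_toy <- function(n = 30L, seed, sigma = 0.1,
                            spacing = 1.4, margin = 3.0) {
  if (missing(seed)) stop("generate_3d_toy requires an explicit seed")
  stopifnot(n >= 10L)
  set.seed(seed)
  n_at <- 8L
  xyz <- matrix(stats::runif(3 * n_at, -2, 2), ncol = 3)
  mols <- vector("list", n)
  for (m in seq_len(n)) {
    q <- stats::runif(n_at, -0.3, 0.3)
    atoms <- data.frame(element = "C", charge = 0L, aromatic = FALSE,
                        nH = 0L, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        q = q)
    bonds <- data.frame(i = 1:(n_at - 1L), j = 2:n_at, order = 1)
    mols[[m]] <- molgraph(atoms, bonds, id = sprintf("toy_%02d", m))
  }
  grid <- build_grid(mols, spacing = spacing, margin = margin)
  ele <- t(vapply(mols, function(g) electrostatic_field(g, grid),
                  numeric(prod(grid$dims))))
  ste <- t(vapply(mols, function(g) steric_field(g, grid),
                  numeric(prod(grid$dims))))
  block <- assemble_and_filter(list(steric = ste, electrostatic = ele), grid)
  # three designated signal columns: spread across the retained block
  ncols <- ncol(block$X)
  sel <- unique(round(c(0.2, 0.5, 0.8) * ncols))
  sel <- pmax(pmin(sel, ncols), 1L)
  coefs <- c(1.0, -0.8, 0.5)[seq_along(sel)]
  y <- drop(block$X[, sel, drop = FALSE] %*% coefs) +
    stats::rnorm(n, 0, sigma)
  list(molecules = mols, grid = grid, block = block, y = y,
       truth = list(columns = sel, coefficients = coefs, sigma = sigma,
                    seed = seed))
}

#' Bundled fixture molecules
#'
#' A fixed, versioned set of 20 drug-like SMILES used throughout the test
#' suite as descriptor oracles: it covers acyclic, monocyclic and fused
#' bicyclic topologies and N/O/S/halogen chemistry.
#'
#' @return named character vector of SMILES.
#' @export
fixture_molecules <- function() {
  c(ethanol = "CCO",
    isopentane = "CC(C)CC",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    naphthalene = "c1ccc2ccccc2c1",
    indole = "c1ccc2c(c1)cc[nH]2",
    quinazoline = "c1ccc2c(c1)cncn2",
    methylbenzoxazole = "Cc1nc2ccccc2o1",
    diamine_chain = "CN(C)CCCN",
    benzamide = "NC(=O)c1ccccc1",
    ethyl_propanoate = "CCOC(=O)CC",
    pyridine = "c1ccncc1",
    chlorobenzoic_acid = "OC(=O)c1ccc(Cl)cc1",
    acetanilide = "CC(=O)Nc1ccccc1",
    methylpiperazinyl_quinazoline = "CN1CCN(CC1)c1ncnc2ccccc12",
    benzoxazole_amine = "COc1ccc2nc(CCCN(C)C)oc2c1",
    ibuprofen = "CC(C(=O)O)c1ccc(CC(C)C)cc1",
    phenethylamine = "NCCc1ccccc1",
    triethylene_glycol = "OCCOCCOCCO",
    thioanisole = "CSc1ccccc1",
    benzotrifluoride = "FC(F)(F)c1ccccc1")
}
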