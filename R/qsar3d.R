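#' Shared rectangular field grid
#'
#' Regular grid enclosing the union bounding box of a set of pre-aligned 3D
#' molecules plus a margin on every side.
#'
#' @param molecules list of `molgraph` objects with 3D coordinates.
#' @param spacing grid spacing in Angstrom (default 1.4).
#' @param margin extension beyond the bounding box on each side (default 3).
#' @return object of class `field_grid` with `origin`, `spacing`, `dims` and
#'   a `points()` accessor via [grid_points()].
#' @export
build_grid <- function(molecules, spacing = 1.4, margin = 3.0) {
  if (inherits(molecules, "molgraph")) molecules <- list(molecules)
  stopifnot(spacing > 0)
  coords <- do.call(rbind, lapply(molecules, function(g) {
    if (!has_coords(g)) stop("molecule '", g$id, "' has no 3D coordinates")
    as.matrix(g$atoms[, c("x", "y", "z")])
  }))
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "field_grid")
}

#' Coordinates of all grid points
#'
#' @param grid a `field_grid`.
#' @return matrix (n_points x 3) in x-fastest order.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(d)
    grid$origin[d] + grid$spacing * (seq_len(grid$dims[d]) - 1L))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid %dx%dx%d, spacing %.2f A, origin (%.2f, %.2f, %.2f)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Gasteiger-Marsili partial charges
#'
#' Iterative partial equalization of orbital electronegativity (PEOE) on the
#' hydrogen-filled graph, using the bundled electronegativity polynomials;
#' hybridization is inferred from bond orders. Returns heavy-atom charges
#' with the attached hydrogens' charges folded in when `fold_hydrogens`.
#'
#' @param g a `molgraph`.
#' @param iterations damping iterations (default 6).
#' @param fold_hydrogens add each H charge onto its heavy atom.
#' @return numeric vector of partial charges (e).
#' @export
gasteiger_charges <- function(g, iterations = 6L, fold_hydrogens = TRUE) {
  gh <- hfill(g)
  n <- nrow(gh$atoms)
  el <- gh$atoms$element
  orders <- adjacency_order(gh)
  key <- vapply(seq_len(n), function(a) {
    e <- el[a]
    if (e %in% c("H", "F", "Cl", "Br", "I")) return(e)
    omax <- if (any(orders[a, ] > 0)) max(orders[a, ]) else 1
    ndbl <- sum(orders[a, ] == 2)
    hyb <- if (omax >= 3 || ndbl >= 2) "1" else if (omax == 2 || gh$atoms$aromatic[a]) "2" else "3"
    paste(e, hyb, sep = ".")
  }, "")
  idx <- match(key, gasteiger_params$key)
  if (anyNA(idx)) {
    # fall back to the sp3 row of the element where a hybrid is missing
    fb <- match(paste0(el, ".3"), gasteiger_params$key)
    idx[is.na(idx)] <- fb[is.na(idx)]
  }
  if (anyNA(idx))
    stop("no Gasteiger parameters for atom type(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  a_p <- gasteiger_params$a[idx]
  b_p <- gasteiger_params$b[idx]
  c_p <- gasteiger_params$c[idx]
  chi_plus <- a_p + b_p + c_p
  chi_plus[el == "H"] <- 20.02   # Gasteiger's special cation value for H
  q <- as.numeric(gh$atoms$charge)
  nb <- lapply(seq_len(n), function(a) which(orders[a, ] > 0))
  damp <- 1
  for (it in seq_len(iterations)) {
    damp <- damp * 0.5
    chi <- a_p + b_p * q + c_p * q^2
    dq <- numeric(n)
    for (a in seq_len(n)) {
      for (b in nb[[a]]) {
        if (chi[b] > chi[a])
          dq[a] <- dq[a] + (chi[b] - chi[a]) / chi_plus[a] * damp
        else
          dq[a] <- dq[a] - (chi[a] - chi[b]) / chi_plus[b] * damp
      }
    }
    q <- q + dq
  }
  if (!fold_hydrogens) return(q)
  n_heavy <- nrow(g$atoms)
  out <- q[seq_len(n_heavy)]
  if (n > n_heavy) {
    owner <- rep(seq_len(n_heavy), g$atoms$nH)
    for (hh in seq_along(owner))
      out[owner[hh]] <- out[owner[hh]] + q[n_heavy + hh]
  }
  out
}

# partial charges for field work: explicit `q` column wins, else Gasteiger
resolve_charges <- function(g, charge_fun = gasteiger_charges) {
  if ("q" %in% names(g$atoms) && !anyNA(g$atoms$q)) return(g$atoms$q)
  charge_fun(g)
}

#' Steric (Lennard-Jones) probe field
#'
#' 6-12 Lennard-Jones interaction energy of a carbon probe atom at every
#' grid point, summed over the molecule's heavy atoms with Lorentz-Berthelot
#' combination of the bundled per-element parameters, truncated to
#' `[-cap, cap]` kcal/mol.
#'
#' @param molecule a `molgraph` with 3D coordinates.
#' @param grid a `field_grid`.
#' @param probe_radius probe minimum-energy radius (Angstrom, default 1.73).
#' @param probe_eps probe well depth (kcal/mol, default 0.105, carbon).
#' @param cap truncation threshold (kcal/mol, default 30).
#' @return numeric vector over grid points.
#' @export
steric_field <- function(molecule, grid, probe_radius = 1.73,
                         probe_eps = 0.105, cap = 30.0) {
  if (!has_coords(molecule))
    stop("molecule '", molecule$id, "' has no 3D coordinates")
  pts <- grid_points(grid)
  xyz <- as.matrix(molecule$atoms[, c("x", "y", "z")])
  el <- molecule$atoms$element
  li <- match(el, lj_params$element)
  if (anyNA(li))
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unique(el[is.na(li)]), collapse = ", "))
  rmin <- lj_params$rmin[li] + probe_radius
  eps <- sqrt(lj_params$eps[li] * probe_eps)
  E <- numeric(nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    d2 <- (pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
      (pts[, 3] - xyz[a, 3])^2
    d2 <- pmax(d2, 1e-6)
    sr6 <- (rmin[a]^2 / d2)^3
    E <- E + eps[a] * (sr6^2 - 2 * sr6)
  }
  pmin(pmax(E, -cap), cap)
}

#' Electrostatic probe field
#'
#' Coulomb interaction energy of a unit positive point charge at every grid
#' point with the molecule's partial charges, using the distance-dependent
#' dielectric `epsilon(r) = r`:
#' `E = sum_i 332.0637 q_i q_probe / r_i^2`, truncated to `[-cap, cap]`.
#'
#' @param molecule a `molgraph` with 3D coordinates; partial charges are
#'   taken from the `q` atom column when present, otherwise computed by
#'   `charge_fun`.
#' @param grid a `field_grid`.
#' @param probe_charge probe charge in e (default +1).
#' @param cap truncation threshold (kcal/mol, default 30).
#' @param charge_fun charge assignment hook (default [gasteiger_charges()]).
#' @return numeric vector over grid points.
#' @export
electrostatic_field <- function(molecule, grid, probe_charge = 1,
                                cap = 30.0, charge_fun = gasteiger_charges) {
  if (!has_coords(molecule))
    stop("molecule '", molecule$id, "' has no 3D coordinates")
  q <- resolve_charges(molecule, charge_fun)
  pts <- grid_points(grid)
  xyz <- as.matrix(molecule$atoms[, c("x", "y", "z")])
  E <- numeric(nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    d2 <- (pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
      (pts[, 3] - xyz[a, 3])^2
    d2 <- pmax(d2, 1e-6)
    # epsilon(r) = r  =>  E = k q q_p / r^2
    E <- E + coulomb_constant * q[a] * probe_charge / d2
  }
  pmin(pmax(E, -cap), cap)
}

#' Assemble per-molecule field rows and drop near-constant grid columns
#'
#' Stacks field vectors (one per molecule) into a molecules-by-gridpoints
#' block per field type and removes columns whose standard deviation is
#' below `min_sd` (they carry no discriminating signal and destabilize PLS).
#' The retained-column mask is recorded per field for contour back-mapping.
#'
#' @param blocks named list of numeric matrices (e.g. `steric`,
#'   `electrostatic`), each n_molecules x n_gridpoints.
#' @param grid the `field_grid` the columns refer to.
#' @param min_sd column standard-deviation threshold (default 0.05).
#' @return object of class `field_block`: list with `X` (combined filtered
#'   matrix), `field` (column field labels), `point` (column grid-point
#'   indices), `mask` (per-field logical keep vectors), `grid`.
#' @export
assemble_and_filter <- function(blocks, grid, min_sd = 0.05) {
  stopifnot(is.list(blocks), length(blocks) >= 1L, !is.null(names(blocks)))
  n <- nrow(blocks[[1]])
  if (n < 2L) stop("need at least 2 molecules")
  Xs <- list(); fields <- character(); points <- integer(); mask <- list()
  for (fname in names(blocks)) {
    M <- blocks[[fname]]
    if (nrow(M) != n) stop("field blocks disagree on molecule count")
    sd_col <- apply(M, 2, stats::sd)
    keep <- sd_col >= min_sd
    mask[[fname]] <- keep
    if (any(keep)) {
      Xs[[fname]] <- M[, keep, drop = FALSE]
      fields <- c(fields, rep(fname, sum(keep)))
      points <- c(points, which(keep))
    }
  }
  if (length(fields) == 0L)
    stop("all grid columns dropped (min_sd = ", min_sd,
         "); molecules may be identical")
  structure(list(X = do.call(cbind, Xs), field = fields, point = points,
                 mask = mask, grid = grid),
            class = "field_block")
}

#' @export
print.field_block <- function(x, ...) {
  cat(sprintf("<field_block: %d molecules x %d retained columns (%s)>\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s %d", names(x$mask),
                            vapply(x$mask, sum, 0L)), collapse = ", ")))
  invisible(x)
}

#' Partial least squares regression (NIPALS)
#'
#' Fits a PLS1 model of the response on a (typically wide) predictor block
#' using the NIPALS algorithm on centered data. With as many components as
#' the rank of the centered predictors, PLS predictions coincide with the
#' OLS fit.
#'
#' @param x a `field_block` or numeric matrix.
#' @param y response vector.
#' @param ncomp number of latent components.
#' @param ... unused.
#' @return object of class `qsar_pls` with scores, loadings, weights, the
#'   regression coefficient vector on the original columns, `fitted`, `R2`.
#' @export
qsar_pls <- function(x, y, ncomp = 2L, ...) {
  block <- NULL
  if (inherits(x, "field_block")) { block <- x; X <- x$X } else X <- as.matrix(x)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (ncomp > min(n - 1L, ncol(X)))
    stop("ncomp must be <= min(n - 1, ncol(X)) = ", min(n - 1L, ncol(X)))
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean); f <- y - y_mean
  W <- matrix(0, ncol(X), ncomp); P <- matrix(0, ncol(X), ncomp)
  Tm <- matrix(0, n, ncomp); b <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) { ncomp <- a - 1L; break }
    w <- w / wn
    t <- drop(E %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    b[a] <- sum(t * f) / tt
    E <- E - tcrossprod(t, p)
    f <- f - b[a] * t
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t
  }
  if (ncomp == 0L) stop("response is orthogonal to all predictors")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  b <- b[seq_len(ncomp)]
  # coefficients on original (centered) X: B = W (P'W)^-1 b
  B <- drop(W %*% solve(crossprod(P, W), b))
  fitted <- drop(sweep(X, 2, x_mean) %*% B) + y_mean
  tss <- sum((y - mean(y))^2)
  structure(list(ncomp = ncomp, weights = W, loadings = P, scores = Tm,
                 coef = B, x_mean = x_mean, y_mean = y_mean,
                 fitted = fitted, y = y,
                 R2 = 1 - sum((y - fitted)^2) / tss,
                 block = block),
            class = "qsar_pls")
}

#' @export
print.qsar_pls <- function(x, ...) {
  cat(sprintf("PLS field model: %d component(s), %d columns, training R2 %.3f\n",
              x$ncomp, length(x$coef), x$R2))
  invisible(x)
}

#' @export
coef.qsar_pls <- function(object, ...) object$coef

#' @export
fitted.qsar_pls <- function(object, ...) object$fitted

#' @export
predict.qsar_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- if (inherits(newdata, "field_block")) newdata$X else as.matrix(newdata)
  drop(sweep(X, 2, object$x_mean) %*% object$coef) + object$y_mean
}

#' Leave-one-out Q2 of a PLS field model
#'
#' Each molecule is predicted by a PLS model refitted without it;
#' `Q2 = 1 - PRESS/TSS`.
#'
#' @param x a `field_block` or numeric matrix.
#' @param y response vector (n >= 4).
#' @param ncomp number of latent components.
#' @return list with `Q2`, `PRESS` and the out-of-fold `predictions`.
#' @export
loo_q2_pls <- function(x, y, ncomp = 2L) {
  X <- if (inherits(x, "field_block")) x$X else as.matrix(x)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 molecules for LOO")
  preds <- vapply(seq_len(n), function(i) {
    fit <- qsar_pls(X[-i, , drop = FALSE], y[-i],
                    ncomp = min(ncomp, n - 2L))
    predict(fit, X[i, , drop = FALSE])
  }, 0)
  press <- sum((y - preds)^2)
  list(Q2 = 1 - press / sum((y - mean(y))^2), PRESS = press,
       predictions = preds)
}

#' Contour coefficients of a PLS field model
#'
#' Maps the PLS regression coefficients back through the column-filter mask
#' to grid-point coordinates, one row per retained column, for contour-style
#' visualization (positive coefficients mark regions where a larger field
#' value increases predicted activity).
#'
#' @param model a `qsar_pls` fitted on a `field_block`.
#' @param grid optional `field_grid` override (default: the block's grid).
#' @return data.frame (x, y, z, field, coefficient).
#' @export
contour_coefficients <- function(model, grid = NULL) {
  block <- model$block
  if (is.null(block))
    stop("model was not fitted on a field_block; no grid mapping available")
  if (is.null(grid)) grid <- block$grid
  pts <- grid_points(grid)
  out <- data.frame(x = pts[block$point, 1], y = pts[block$point, 2],
                    z = pts[block$point, 3], field = block$field,
                    coefficient = model$coef)
  rownames(out) <- NULL
  out
}
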