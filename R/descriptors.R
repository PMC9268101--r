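#' Topological distance matrix
#'
#' Matrix of shortest-path lengths (in bonds) between all heavy-atom pairs of
#' a connected, hydrogen-depleted molecular graph.
#'
#' @param g a `molgraph`.
#' @return symmetric integer matrix with zero diagonal.
#' @export
topological_distance_matrix <- function(g) {
  if (!is_connected_graph(g))
    stop("distance matrix needs a connected graph ('", g$id, "')")
  D <- igraph::distances(as_igraph(g))
  dimnames(D) <- NULL
  D
}

#' Detour matrix (longest simple paths)
#'
#' Matrix of the longest simple (vertex-disjoint) path length, in bonds,
#' between all heavy-atom pairs. Longest-path search is exponential in the
#' worst case, so molecules above `max_atoms` heavy atoms are refused; raise
#' the cap explicitly for larger (sparse) molecules. For acyclic graphs the
#' detour matrix equals the distance matrix.
#'
#' @param g a `molgraph`.
#' @param max_atoms heavy-atom cap (default 60).
#' @return symmetric integer matrix with zero diagonal.
#' @export
detour_matrix <- function(g, max_atoms = 60L) {
  n <- nrow(g$atoms)
  if (!is_connected_graph(g))
    stop("detour matrix needs a connected graph ('", g$id, "')")
  if (n > max_atoms)
    stop("molecule '", g$id, "' has ", n, " heavy atoms; detour matrix is ",
         "exponential - raise max_atoms to override")
  ig <- as_igraph(g)
  # acyclic shortcut: tree detour == distance
  if (nrow(g$bonds) == n - 1L) return(topological_distance_matrix(g))

  adj <- lapply(igraph::adjacent_vertices(ig, seq_len(n)), as.integer)
  Dt <- matrix(0L, n, n)
  # biconnected-component pruning is unnecessary at these sizes; plain DFS
  # over simple paths, updating the best length for every vertex reached.
  for (s in seq_len(n - 1L)) {
    visited <- logical(n)
    visited[s] <- TRUE
    best <- Dt[s, ]
    dfs <- function(v, depth) {
      for (w in adj[[v]]) {
        if (!visited[w]) {
          d <- depth + 1L
          if (d > best[w]) best[w] <<- d
          visited[w] <<- TRUE
          dfs(w, d)
          visited[w] <<- FALSE
        }
      }
    }
    dfs(s, 0L)
    Dt[s, ] <- best
    Dt[, s] <- best
  }
  diag(Dt) <- 0L
  Dt
}

#' Distance/detour quotient eigenvector-sum descriptor (VE3-type, signed)
#'
#' Builds the distance/detour quotient matrix (off-diagonal entries: shortest
#' path length divided by longest simple path length; diagonal zero), takes
#' the eigenvector belonging to the smallest (most negative) eigenvalue, and
#' returns `n/10 * log10 |sum of its coefficients|` where `n` is the heavy
#' atom count. The "signed" variant keeps the eigenvector coefficients signed
#' when summing; the eigenvector's arbitrary global sign is fixed by making
#' its largest-magnitude coefficient positive. If the coefficient sum is
#' numerically zero the descriptor is undefined and `NaN` is returned with a
#' warning.
#'
#' @param g a `molgraph`.
#' @param max_atoms passed to [detour_matrix()].
#' @return numeric scalar (dimensionless), possibly `NaN`.
#' @export
ve3sign_d_dt <- function(g, max_atoms = 60L) {
  n <- nrow(g$atoms)
  if (n < 2L) stop("descriptor needs at least 2 heavy atoms")
  D <- topological_distance_matrix(g)
  Dt <- detour_matrix(g, max_atoms = max_atoms)
  Q <- D / Dt
  diag(Q) <- 0
  ev <- eigen(Q, symmetric = TRUE)
  vec <- ev$vectors[, n]   # eigenvalues are sorted decreasing; last = smallest
  vec <- vec * sign(vec[which.max(abs(vec))])
  s <- sum(vec)
  if (abs(s) < 1e-12) {
    warning("VE3sign_D_Dt undefined (eigenvector coefficient sum is zero) ",
            "for '", g$id, "'; returning NaN")
    return(NaN)
  }
  n / 10 * log10(abs(s))
}

#' Kier-Hall intrinsic state values
#'
#' Per-atom electrotopological intrinsic state
#' `I = ((2/N)^2 * delta_v + 1) / delta`, where `delta` is the count of sigma
#' electrons (heavy-atom connections), `delta_v` the valence electron count
#' minus attached hydrogens, and `N` the principal quantum number. Reference
#' points: pyridine-type N 3.00, tertiary amine N 2.00, ether O 3.50.
#' Explicit hydrogen atoms (in hydrogen-filled graphs) take
#' `delta = delta_v = N = 1`, giving `I = 5`.
#'
#' @param g a `molgraph` (hydrogen-depleted or hydrogen-filled).
#' @return numeric vector of intrinsic states, one per atom of `g`.
#' @export
estate_intrinsic <- function(g) {
  el <- g$atoms$element
  unknown <- setdiff(unique(el), names(principal_quantum_number))
  if (length(unknown) > 0L)
    stop("no principal quantum number for element(s): ",
         paste(unknown, collapse = ", "))
  N <- principal_quantum_number[el]
  zv <- valence_electrons[el]
  delta <- heavy_degree(g)
  # count explicit H neighbours as hydrogens, not heavy connections
  is_h <- el == "H"
  if (any(is_h)) {
    # recompute: delta excludes H neighbours; delta_v subtracts H neighbours
    nH_explicit <- integer(nrow(g$atoms))
    heavy_deg <- integer(nrow(g$atoms))
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      if (is_h[j]) nH_explicit[i] <- nH_explicit[i] + 1L
      else heavy_deg[i] <- heavy_deg[i] + 1L
      if (is_h[i]) nH_explicit[j] <- nH_explicit[j] + 1L
      else heavy_deg[j] <- heavy_deg[j] + 1L
    }
    delta <- heavy_deg
    dv <- zv - (g$atoms$nH + nH_explicit)
    delta[is_h] <- 1L
    dv[is_h] <- 1
    N[is_h] <- 1
  } else {
    dv <- zv - g$atoms$nH
  }
  delta_eff <- pmax(delta, 1L)  # isolated atoms (e.g. methane C): delta 1
  unname(((2 / N)^2 * dv + 1) / delta_eff)
}

#' Burden matrix
#'
#' Square symmetric matrix over the atoms of `g` with the atomic weights
#' `omega` on the diagonal; bonded pairs carry the bond order (1, 1.5, 2, 3),
#' plus 0.001 when either atom of the bond is terminal; non-bonded pairs
#' carry 0.001. (This is the literal published form of the weighting; note
#' that the classical Burden convention scales bonded entries by 0.1, which
#' is deliberately not done here.)
#'
#' @param g a `molgraph` (typically hydrogen-filled, see [hfill()]).
#' @param weights per-atom diagonal weights, length `nrow(g$atoms)`.
#' @return symmetric numeric matrix.
#' @export
burden_matrix <- function(g, weights) {
  n <- nrow(g$atoms)
  if (length(weights) != n)
    stop("weight vector length ", length(weights), " != atom count ", n)
  B <- matrix(0.001, n, n)
  deg <- heavy_degree(g)   # in an H-filled graph H atoms count as vertices
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    v <- g$bonds$order[k] + if (deg[i] == 1L || deg[j] == 1L) 0.001 else 0
    B[i, j] <- v; B[j, i] <- v
  }
  diag(B) <- weights
  B
}

#' Second-smallest eigenvalue of the intrinsic-state Burden matrix
#'
#' Builds the Burden matrix of the hydrogen-filled graph weighted by the
#' Kier-Hall intrinsic state and returns its second-smallest eigenvalue
#' (`SpMin2`-type BCUT descriptor).
#'
#' @param g a `molgraph` (hydrogen-depleted input; hydrogens are filled in).
#' @return numeric scalar.
#' @export
spmin2_bh_s <- function(g) {
  gh <- hfill(g)
  if (nrow(gh$atoms) < 2L) stop("descriptor needs at least 2 atoms after H-fill")
  B <- burden_matrix(gh, estate_intrinsic(gh))
  ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
  ev[2]
}

#' Per-atom van der Waals surface area
#'
#' Labute-style approximate exposed sphere area per heavy atom:
#' `VSA_i = 4 pi R_i^2 - pi R_i * sum_j a_ij (R_j^2 - (R_i - d_ij)^2) / d_ij`
#' where the sum runs over bonded neighbours, `R` are Bondi radii, and the
#' effective bond length `d_ij = min(max(|R_i - R_j|, b_ij), R_i + R_j)` with
#' `b_ij = r_ij - c_ij` (reference bond length minus the bond-order
#' correction). Values are clamped at zero; an isolated atom returns the full
#' sphere area.
#'
#' @param g a `molgraph` (heavy atoms only; implicit hydrogens ignored).
#' @return numeric vector, Angstrom^2.
#' @export
vdw_surface_area <- function(g) {
  el <- g$atoms$element
  missing_r <- setdiff(unique(el), names(vdw_radii))
  if (length(missing_r) > 0L)
    stop("no van der Waals radius for element(s): ",
         paste(missing_r, collapse = ", "))
  R <- vdw_radii[el]
  vsa <- 4 * pi * R^2
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    rij <- covalent_radii[[el[i]]] + covalent_radii[[el[j]]]
    bij <- rij - bond_order_correction(g$bonds$order[k])
    dij <- min(max(abs(R[i] - R[j]), bij), R[i] + R[j])
    vsa[i] <- vsa[i] - pi * R[i] * (R[j]^2 - (R[i] - dij)^2) / dij
    vsa[j] <- vsa[j] - pi * R[j] * (R[i]^2 - (R[j] - dij)^2) / dij
  }
  unname(pmax(vsa, 0))
}

#' P_VSA-style descriptor: surface area of mildly lipophilic atoms
#'
#' Sum of per-atom van der Waals surface area over heavy atoms whose atomic
#' logP contribution (attached hydrogens folded in) falls in the left-open
#' bin (0, 0.25]. Returns 0 when no atom qualifies.
#'
#' @param g a `molgraph`.
#' @return numeric scalar, Angstrom^2.
#' @export
p_vsa_logp_5 <- function(g) {
  lp <- atomic_logp(g)$logp_h
  vsa <- vdw_surface_area(g)
  sum(vsa[lp > 0 & lp <= 0.25])
}

#' Second-largest eigenvalue of the dipole-weighted edge-adjacency matrix
#'
#' Builds the bond-by-bond edge-adjacency matrix (entry 1 when two bonds
#' share an atom) with each bond's dipole moment (Debye, bundled table) on
#' the diagonal, and returns the second-largest eigenvalue. Bond types absent
#' from the dipole table contribute 0 with a warning.
#'
#' @param g a `molgraph` with at least 2 bonds.
#' @return numeric scalar.
#' @export
eig02_ea_dm <- function(g) {
  m <- nrow(g$bonds)
  if (m < 2L) stop("descriptor needs at least 2 bonds ('", g$id, "')")
  E <- matrix(0, m, m)
  for (p in seq_len(m - 1L)) {
    for (q in (p + 1L):m) {
      share <- length(intersect(c(g$bonds$i[p], g$bonds$j[p]),
                                c(g$bonds$i[q], g$bonds$j[q]))) > 0L
      if (share) { E[p, q] <- 1; E[q, p] <- 1 }
    }
  }
  el <- g$atoms$element
  mu <- numeric(m)
  for (k in seq_len(m)) {
    v <- bond_dipole_table$get(el[g$bonds$i[k]], el[g$bonds$j[k]],
                               g$bonds$order[k])
    if (is.na(v)) {
      warning(sprintf("no bond dipole for %s-%s order %s; using 0",
                      el[g$bonds$i[k]], el[g$bonds$j[k]],
                      format(g$bonds$order[k])))
      v <- 0
    }
    mu[k] <- v
  }
  diag(E) <- mu
  ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)[2]
}

#' Hydrogen-bond acceptor flags (CATS-style typing)
#'
#' An atom counts as an acceptor when it is oxygen or nitrogen with an
#' available lone pair: pyrrole-type aromatic nitrogens (ring N carrying an H
#' or three connections) and amide nitrogens (N bonded to a carbonyl carbon)
#' are excluded, as are positively charged N/O.
#'
#' @param g a `molgraph`.
#' @return logical vector over heavy atoms.
#' @export
acceptor_atoms <- function(g) {
  nb <- atom_context(g)
  n <- nrow(g$atoms)
  out <- logical(n)
  for (a in seq_len(n)) {
    el <- g$atoms$element[a]
    if (!(el %in% c("N", "O")) || g$atoms$charge[a] > 0L) next
    if (el == "O") { out[a] <- TRUE; next }
    deg <- if (is.null(nb[[a]])) 0L else nrow(nb[[a]])
    if (g$atoms$aromatic[a] && (g$atoms$nH[a] > 0L || deg >= 3L)) next
    amide <- FALSE
    if (!is.null(nb[[a]])) {
      for (k in seq_len(nrow(nb[[a]]))) {
        ci <- nb[[a]]$idx[k]
        if (g$atoms$element[ci] == "C" && has_double_to(g, ci, nb, "O"))
          amide <- TRUE
      }
    }
    out[a] <- !amide
  }
  out
}

#' CATS2D acceptor-acceptor pair count at topological distance nine
#'
#' Number of unordered acceptor-acceptor heavy-atom pairs whose shortest-path
#' distance is exactly nine bonds.
#'
#' @param g a `molgraph`.
#' @return non-negative integer.
#' @export
cats2d_09_aa <- function(g) {
  acc <- which(acceptor_atoms(g))
  if (length(acc) < 2L) return(0L)
  D <- topological_distance_matrix(g)
  sum(D[acc, acc][upper.tri(D[acc, acc])] == 9L)
}

#' The five model descriptors for one molecule
#'
#' Assembles the descriptor vector of the published five-descriptor potency
#' model: `VE3sign_D_Dt`, `SpMin2_Bh_s`, `P_VSA_logP_5`, `Eig02_EA_dm` and
#' `CATS2D_09_AA`. Errors from the individual descriptors are re-raised with
#' the descriptor name attached.
#'
#' @param g a `molgraph`.
#' @param max_atoms detour-matrix heavy-atom cap.
#' @return named numeric vector of length 5.
#' @export
descriptor_vector <- function(g, max_atoms = 60L) {
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, " failed for '", g$id, "': ", conditionMessage(e),
           call. = FALSE))
  }
  c(VE3sign_D_Dt = wrap("VE3sign_D_Dt", ve3sign_d_dt(g, max_atoms)),
    SpMin2_Bh_s = wrap("SpMin2_Bh_s", spmin2_bh_s(g)),
    P_VSA_logP_5 = wrap("P_VSA_logP_5", p_vsa_logp_5(g)),
    Eig02_EA_dm = wrap("Eig02_EA_dm", eig02_ea_dm(g)),
    CATS2D_09_AA = wrap("CATS2D_09_AA", as.numeric(cats2d_09_aa(g))))
}

#' Descriptor table for a set of molecules
#'
#' @param graphs list of `molgraph` objects.
#' @param max_atoms detour-matrix heavy-atom cap.
#' @return data.frame with column `id` plus the five descriptor columns.
#' @export
descriptor_table <- function(graphs, max_atoms = 60L) {
  rows <- lapply(graphs, function(g) {
    v <- descriptor_vector(g, max_atoms = max_atoms)
    cbind(data.frame(id = g$id), as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
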