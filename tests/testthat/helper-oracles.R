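# Independent oracles used across the descriptor tests. These deliberately
# avoid the package's own graph machinery: plain-R breadth-first search,
# exhaustive path enumeration and direct dense eigendecompositions on
# matrices constructed here from the atom/bond tables.

# adjacency list straight from the bond table
oracle_adj <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# BFS shortest-path oracle
oracle_distances <- function(g) {
  n <- nrow(g$atoms)
  adj <- oracle_adj(g)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (dist[w] > dist[v] + 1) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

# exhaustive simple-path enumeration for the longest-path (detour) oracle
oracle_detour <- function(g) {
  n <- nrow(g$atoms)
  adj <- oracle_adj(g)
  best <- matrix(0, n, n)
  walk <- function(path) {
    v <- path[length(path)]
    s <- path[1]
    len <- length(path) - 1L
    if (len > best[s, v]) best[s, v] <<- len
    for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
  }
  for (s in seq_len(n)) walk(s)
  pmax(best, t(best))
}

# brute-force acceptor pair count at a given topological distance
oracle_cats_count <- function(g, dist = 9) {
  acc <- which(qsarligand::acceptor_atoms(g))
  if (length(acc) < 2) return(0L)
  D <- oracle_distances(g)
  cnt <- 0L
  for (a in seq_along(acc)) {
    for (b in seq_along(acc)) {
      if (b > a && D[acc[a], acc[b]] == dist) cnt <- cnt + 1L
    }
  }
  cnt
}

# independent construction of the distance/detour quotient descriptor
oracle_ve3sign <- function(g) {
  D <- oracle_distances(g)
  Dt <- oracle_detour(g)
  Q <- D / Dt
  diag(Q) <- 0
  n <- nrow(Q)
  ev <- eigen(Q, symmetric = TRUE)
  vec <- ev$vectors[, which.min(ev$values)]
  vec <- vec * sign(vec[which.max(abs(vec))])
  s <- sum(vec)
  if (abs(s) < 1e-12) return(NaN)
  n / 10 * log10(abs(s))
}

# independent Burden-matrix construction for the eigenvalue descriptor
oracle_burden_second_smallest <- function(g) {
  gh <- qsarligand::hfill(g)
  w <- qsarligand::estate_intrinsic(gh)
  n <- nrow(gh$atoms)
  deg <- integer(n)
  for (k in seq_len(nrow(gh$bonds))) {
    deg[gh$bonds$i[k]] <- deg[gh$bonds$i[k]] + 1L
    deg[gh$bonds$j[k]] <- deg[gh$bonds$j[k]] + 1L
  }
  B <- matrix(0.001, n, n)
  for (k in seq_len(nrow(gh$bonds))) {
    i <- gh$bonds$i[k]; j <- gh$bonds$j[k]
    v <- gh$bonds$order[k]
    if (deg[i] == 1L || deg[j] == 1L) v <- v + 0.001
    B[i, j] <- v; B[j, i] <- v
  }
  diag(B) <- w
  sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)[2]
}

# apply a random atom permutation to a molgraph
permute_molgraph <- function(g, perm) {
  inv <- order(perm)
  atoms <- g$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- g$bonds
  bonds$i <- inv[g$bonds$i]
  bonds$j <- inv[g$bonds$j]
  qsarligand::molgraph(atoms, bonds, id = g$id)
}

# whole-molecule Crippen logP reference values, computed once with RDKit
# 2024.09.2 (Chem.Crippen.MolLogP) on the fixture SMILES and frozen here
rdkit_logp_reference <- c(
  ethanol = -0.0014,
  isopentane = 2.0524,
  aspirin = 1.3101,
  naphthalene = 2.8398,
  indole = 2.1679,
  quinazoline = 1.6298,
  methylbenzoxazole = 2.1362,
  diamine_chain = -0.1032,
  benzamide = 0.7855,
  ethyl_propanoate = 0.9595,
  pyridine = 1.0816,
  chlorobenzoic_acid = 2.0382,
  acetanilide = 1.6450,
  methylpiperazinyl_quinazoline = 1.3816,
  benzoxazole_amine = 2.3306,
  ibuprofen = 3.0732,
  phenethylamine = 1.1878,
  triethylene_glycol = -0.9958,
  thioanisole = 2.4085,
  benzotrifluoride = 2.7054)

fixture_graphs <- function() {
  smis <- qsarligand::fixture_molecules()
  lapply(names(smis), function(nm) qsarligand::parse_smiles(smis[[nm]], id = nm))
}
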