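#' Molecular graph container
#'
#' A `molgraph` is the package's lightweight molecule representation: a heavy
#' atom table, a bond table and a compound id. Hydrogens are kept implicit as
#' per-atom counts (`nH`); [hfill()] expands them into explicit atoms when a
#' descriptor is defined on the hydrogen-filled graph.
#'
#' @param atoms data.frame with columns `element` (symbol), `charge` (formal
#'   charge, integer), `aromatic` (logical), `nH` (attached hydrogen count);
#'   optional columns `x`, `y`, `z` (coordinates, Angstrom) and `q` (partial
#'   charge, e).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 1.5, 2 or 3; 1.5 marks aromatic bonds).
#' @param id compound label.
#' @return An object of class `molgraph`.
#' @examples
#' m <- parse_smiles("CCO")
#' n_atoms(m)
#' @export
molgraph <- function(atoms, bonds, id = "mol") {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("element", "charge", "aromatic", "nH") %in% names(atoms)))
  if (nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  stopifnot(all(c("i", "j", "order") %in% names(bonds)))
  n <- nrow(atoms)
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond atom index out of range for molecule '", id, "'")
    if (any(bonds$i == bonds$j))
      stop("self-bond in molecule '", id, "'")
    if (!all(bonds$order %in% c(1, 1.5, 2, 3)))
      stop("bond orders must be 1, 1.5, 2 or 3")
  }
  g <- structure(list(atoms = atoms, bonds = bonds, id = as.character(id)),
                 class = "molgraph")
  if (n > 1L && !is_connected_graph(g))
    stop("molecule '", id, "' is disconnected after hydrogen suppression ",
         "(multi-fragment inputs are rejected)")
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph '%s': %d heavy atoms, %d bonds%s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              if (has_coords(x)) ", 3D" else ""))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g a `molgraph`.
#' @return integer count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' Number of bonds in a molecular graph
#' @param g a `molgraph`.
#' @return integer count.
#' @export
n_bonds <- function(g) nrow(g$bonds)

has_coords <- function(g) {
  all(c("x", "y", "z") %in% names(g$atoms)) && !anyNA(g$atoms$x)
}

# igraph view of the heavy-atom skeleton (edge attribute `order` preserved)
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  if (nrow(g$bonds) > 0L)
    ig <- igraph::add_edges(ig, rbind(g$bonds$i, g$bonds$j),
                            order = g$bonds$order)
  ig
}

is_connected_graph <- function(g) {
  if (nrow(g$atoms) <= 1L) return(TRUE)
  igraph::is_connected(as_igraph(g))
}

# Symmetric heavy-atom adjacency matrix; entries carry the bond order.
adjacency_order <- function(g) {
  n <- nrow(g$atoms)
  A <- matrix(0, n, n)
  if (nrow(g$bonds) > 0L) {
    idx <- cbind(g$bonds$i, g$bonds$j)
    A[idx] <- g$bonds$order
    A[idx[, c(2, 1), drop = FALSE]] <- g$bonds$order
  }
  A
}

# heavy-atom degree of every atom
heavy_degree <- function(g) {
  n <- nrow(g$atoms)
  d <- integer(n)
  if (nrow(g$bonds) > 0L) {
    t1 <- tabulate(g$bonds$i, n)
    t2 <- tabulate(g$bonds$j, n)
    d <- t1 + t2
  }
  d
}

#' Expand implicit hydrogens into explicit atoms
#'
#' Returns a hydrogen-filled copy of the graph: one extra atom per implicit
#' hydrogen, bonded to its heavy atom with a single bond. Heavy atoms keep
#' their original indices; hydrogens are appended after them.
#'
#' @param g a `molgraph`.
#' @return a `molgraph` whose `atoms` include explicit H (with `nH = 0`).
#' @export
hfill <- function(g) {
  nh <- g$atoms$nH
  n <- nrow(g$atoms)
  n_new <- sum(nh)
  if (n_new == 0L) return(g)
  h_atoms <- data.frame(element = rep("H", n_new),
                        charge = 0L, aromatic = FALSE, nH = 0L)
  owner <- rep(seq_len(n), nh)
  atoms <- g$atoms[, c("element", "charge", "aromatic", "nH")]
  atoms$nH <- 0L
  atoms <- rbind(atoms, h_atoms)
  bonds <- rbind(g$bonds[, c("i", "j", "order")],
                 data.frame(i = owner, j = n + seq_len(n_new), order = 1))
  structure(list(atoms = atoms, bonds = bonds, id = g$id), class = "molgraph")
}

# Molecular formula-ish summary used in error messages
atom_counts <- function(g) {
  tab <- table(g$atoms$element)
  paste(sprintf("%s%d", names(tab), as.integer(tab)), collapse = "")
}
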