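#' Parse a SMILES string into a molecular graph
#'
#' A self-contained SMILES reader covering the organic subset (B, C, N, O, P,
#' S, F, Cl, Br, I and their aromatic forms), bracket atoms with explicit
#' hydrogen counts and formal charges, branches, ring-bond closures
#' (including `%nn`), and explicit bond symbols `-`, `=`, `#`, `:` (`/` and
#' `\` are read as single bonds; stereochemistry is ignored). Atom order
#' follows input order. Aromaticity is taken from the lowercase notation; an
#' unspecified bond between two aromatic atoms is perceived as aromatic
#' (order 1.5) when it lies on a ring, and single otherwise (biphenyl-type
#' links). Implicit hydrogens on organic-subset atoms are filled to the
#' element's default valence, counting aromatic bonds as 1.5.
#'
#' @param text a single SMILES string, optionally with leading/trailing
#'   whitespace.
#' @param id compound label attached to the result.
#' @return a [molgraph()].
#' @examples
#' parse_smiles("c1ccccc1", id = "benzene")
#' @export
parse_smiles <- function(text, id = "mol") {
  s <- trimws(text)
  if (!nzchar(s)) stop("empty SMILES string")

  organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  arom_ok <- c("b", "c", "n", "o", "p", "s")
  two_letter <- c("Cl", "Br")

  atoms <- list()   # each: list(element, charge, aromatic, nH) nH NA=implicit
  bonds <- list()   # each: list(i, j, sym) sym "" for unspecified
  prev_stack <- integer()    # open-branch return points
  prev <- 0L                 # last atom emitted
  pending <- ""              # bond symbol awaiting next atom
  rings <- list()            # ring-closure table: num -> list(atom, sym)

  add_atom <- function(element, aromatic, charge = 0L, nH = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
                                         aromatic = aromatic, nH = nH)
    cur <- length(atoms)
    if (prev > 0L) {
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = cur, sym = pending)
    }
    pending <<- ""
    prev <<- cur
    invisible(cur)
  }

  close_ring <- function(num, pos) {
    key <- as.character(num)
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      sym <- pending
      if (sym == "" && open$sym != "") sym <- open$sym
      if (open$sym != "" && pending != "" && open$sym != pending)
        stop(sprintf("SMILES parse error at position %d: conflicting bond symbols on ring closure %s", pos, key))
      if (open$atom == prev)
        stop(sprintf("SMILES parse error at position %d: ring bond to self", pos))
      bonds[[length(bonds) + 1L]] <<- list(i = open$atom, j = prev, sym = sym)
      rings[[key]] <<- NULL
      pending <<- ""
    } else {
      rings[[key]] <<- list(atom = prev, sym = pending)
      pending <<- ""
    }
  }

  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    rest2 <- substr(s, i, i + 1L)
    if (ch == " ") {
      i <- i + 1L
    } else if (ch == ".") {
      stop(sprintf("SMILES parse error at position %d: multi-fragment input ('.') rejected", i))
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "/" = "-", "\\" = "-", ch)
      i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L)
        stop(sprintf("SMILES parse error at position %d: branch before any atom", i))
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L)
        stop(sprintf("SMILES parse error at position %d: unmatched ')'", i))
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch == "%") {
      num <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", num))
        stop(sprintf("SMILES parse error at position %d: bad %% ring number", i))
      if (prev == 0L)
        stop(sprintf("SMILES parse error at position %d: ring closure before any atom", i))
      close_ring(as.integer(num), i)
      i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      if (prev == 0L)
        stop(sprintf("SMILES parse error at position %d: ring closure before any atom", i))
      close_ring(as.integer(ch), i)
      i <- i + 1L
    } else if (ch == "[") {
      close_pos <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (close_pos < 0L)
        stop(sprintf("SMILES parse error at position %d: unterminated '['", i))
      body <- substr(s, i + 1L, i + close_pos - 2L)
      # [isotope? symbol chirality? Hcount? charge?]
      m <- regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?([+-][0-9]*|\\+*|-*)$",
                   body)
      parts <- regmatches(body, m)[[1]]
      if (length(parts) == 0L)
        stop(sprintf("SMILES parse error at position %d: cannot read bracket atom '[%s]'", i, body))
      sym <- parts[3]
      aromatic <- sym %in% arom_ok
      element <- if (aromatic) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)) else sym
      nH <- if (parts[5] == "") 0L else if (parts[6] == "") 1L else as.integer(parts[6])
      chg_s <- parts[7]
      charge <- 0L
      if (grepl("^[+-][0-9]+$", chg_s)) {
        charge <- as.integer(chg_s)
      } else if (grepl("^\\++$", chg_s) && nzchar(chg_s)) {
        charge <- nchar(chg_s)
      } else if (grepl("^-+$", chg_s) && nzchar(chg_s)) {
        charge <- -nchar(chg_s)
      }
      add_atom(element, aromatic, as.integer(charge), nH)
      i <- i + close_pos
    } else if (rest2 %in% two_letter) {
      add_atom(rest2, FALSE)
      i <- i + 2L
    } else if (ch %in% organic) {
      add_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% arom_ok) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else {
      stop(sprintf("SMILES parse error at position %d: unexpected token '%s'", i, ch))
    }
  }
  if (length(prev_stack) > 0L)
    stop("SMILES parse error: unclosed branch '('")
  if (length(rings) > 0L)
    stop(sprintf("SMILES parse error: unclosed ring bond(s) %s",
                 paste(names(rings), collapse = ", ")))
  if (length(atoms) == 0L) stop("SMILES parse error: no atoms")

  at <- data.frame(element = vapply(atoms, `[[`, "", "element"),
                   charge = vapply(atoms, `[[`, 0L, "charge"),
                   aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
                   nH = vapply(atoms, `[[`, NA_integer_, "nH"))
  bd <- if (length(bonds) == 0L) {
    data.frame(i = integer(), j = integer(), order = numeric())
  } else {
    data.frame(i = vapply(bonds, `[[`, 0L, "i"),
               j = vapply(bonds, `[[`, 0L, "j"),
               sym = vapply(bonds, `[[`, "", "sym"))
  }

  bd <- perceive_bond_orders(at, bd)
  at$nH <- fill_implicit_h(at, bd)
  molgraph(at, bd, id = id)
}

# Resolve bond symbols to numeric orders. Unspecified bonds between two
# aromatic atoms are aromatic (1.5) when they lie on a cycle (non-bridge),
# single otherwise; explicit ':' forces aromatic.
perceive_bond_orders <- function(at, bd) {
  if (nrow(bd) == 0L)
    return(data.frame(i = integer(), j = integer(), order = numeric()))
  order <- rep(NA_real_, nrow(bd))
  order[bd$sym == "-"] <- 1
  order[bd$sym == "="] <- 2
  order[bd$sym == "#"] <- 3
  order[bd$sym == ":"] <- 1.5
  unspec <- is.na(order)
  if (any(unspec)) {
    both_arom <- at$aromatic[bd$i] & at$aromatic[bd$j]
    cand <- unspec & both_arom
    if (any(cand)) {
      ig <- igraph::make_empty_graph(n = nrow(at), directed = FALSE)
      ig <- igraph::add_edges(ig, rbind(bd$i, bd$j))
      br <- igraph::bridges(ig)
      is_bridge <- logical(nrow(bd))
      is_bridge[as.integer(br)] <- TRUE
      order[cand & !is_bridge] <- 1.5
      order[cand & is_bridge] <- 1
    }
    order[is.na(order)] <- 1
  }
  data.frame(i = bd$i, j = bd$j, order = order)
}

default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)

# Implicit H for organic-subset atoms (bracket atoms keep their explicit nH).
fill_implicit_h <- function(at, bd) {
  n <- nrow(at)
  bsum <- numeric(n)
  if (nrow(bd) > 0L) {
    for (k in seq_len(nrow(bd))) {
      bsum[bd$i[k]] <- bsum[bd$i[k]] + bd$order[k]
      bsum[bd$j[k]] <- bsum[bd$j[k]] + bd$order[k]
    }
  }
  nH <- at$nH
  for (a in seq_len(n)) {
    if (!is.na(nH[a])) next
    dv <- default_valence[[at$element[a]]]
    if (is.null(dv)) dv <- 0
    nH[a] <- max(0L, as.integer(floor(dv - bsum[a] + 1e-9)))
  }
  nH
}

#' Serialize a molecular graph back to (non-canonical) SMILES
#'
#' Writes atoms in a depth-first order starting from atom 1. Used for
#' round-trip checks and for writing the synthetic dataset; makes no attempt
#' at canonicalization.
#'
#' @param g a `molgraph`.
#' @return a SMILES string.
#' @export
write_smiles <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) stop("empty graph")
  A <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    A[[i]] <- c(A[[i]], k); A[[j]] <- c(A[[j]], k)
  }
  other <- function(k, a) if (g$bonds$i[k] == a) g$bonds$j[k] else g$bonds$i[k]
  visited_atom <- logical(n)
  visited_bond <- logical(max(1L, nrow(g$bonds)))
  ring_num <- 0L
  ring_open <- rep(NA_integer_, max(1L, nrow(g$bonds)))

  bond_sym <- function(k) {
    o <- g$bonds$order[k]
    if (o == 2) "=" else if (o == 3) "#" else ""
  }
  atom_token <- function(a) {
    el <- g$atoms$element[a]
    sym <- if (g$atoms$aromatic[a]) tolower(el) else el
    ok_organic <- el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I") &&
      g$atoms$charge[a] == 0L
    if (ok_organic && !g$atoms$aromatic[a]) return(sym)
    if (ok_organic && g$atoms$aromatic[a] && el %in% c("C", "N", "O", "S") &&
        !(el == "N" && g$atoms$nH[a] > 0L)) return(sym)
    chg <- g$atoms$charge[a]
    chg_s <- ""
    if (chg > 0L) chg_s <- paste0("+", if (chg > 1L) chg else "")
    if (chg < 0L) chg_s <- paste0("-", if (chg < -1L) -chg else "")
    h <- g$atoms$nH[a]
    h_s <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    paste0("[", sym, h_s, chg_s, "]")
  }

  # pre-pass: identify ring-closure bonds via DFS spanning tree
  tree_bond <- logical(max(1L, nrow(g$bonds)))
  st <- c(1L); seen <- logical(n); seen[1L] <- TRUE
  while (length(st) > 0L) {
    a <- st[length(st)]; st <- st[-length(st)]
    for (k in A[[a]]) {
      b <- other(k, a)
      if (!seen[b]) { seen[b] <- TRUE; tree_bond[k] <- TRUE; st <- c(st, b) }
    }
  }
  ring_bonds <- which(!tree_bond & seq_along(tree_bond) <= nrow(g$bonds))
  ring_label <- integer(max(1L, nrow(g$bonds)))
  ring_label[ring_bonds] <- seq_along(ring_bonds)

  emit <- function(a, from_bond) {
    out <- character()
    if (!is.na(from_bond)) out <- c(out, bond_sym(from_bond))
    out <- c(out, atom_token(a))
    visited_atom[a] <<- TRUE
    for (k in A[[a]]) {
      if (ring_label[k] > 0L) {
        lbl <- ring_label[k]
        pre <- if (is.na(ring_open[k])) bond_sym(k) else ""
        num_s <- if (lbl > 9L) sprintf("%%%02d", lbl) else as.character(lbl)
        out <- c(out, pre, num_s)
        ring_open[k] <<- a
      }
    }
    kids <- Filter(function(k) ring_label[k] == 0L && !visited_bond[k] &&
                     !visited_atom[other(k, a)], A[[a]])
    for (idx in seq_along(kids)) {
      k <- kids[[idx]]
      b <- other(k, a)
      if (visited_atom[b]) next
      visited_bond[k] <<- TRUE
      sub <- emit(b, k)
      if (idx < length(kids)) sub <- c("(", sub, ")")
      out <- c(out, sub)
    }
    out
  }
  paste(emit(1L, NA_integer_), collapse = "")
}

#' Read a SMILES file
#'
#' One molecule per line; an optional second, tab-separated field is used as
#' the compound id (otherwise ids are `mol_1`, `mol_2`, ...). Blank lines and
#' lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return list of [molgraph()] objects.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    id <- if (length(f) >= 2L && nzchar(f[2])) f[2] else sprintf("mol_%d", k)
    out[[k]] <- parse_smiles(f[1], id = id)
  }
  out
}
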