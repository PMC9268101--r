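#' Read a V2000 SDF/MOL file
#'
#' Parses every record of a V2000 structure-data file into a [molgraph()]
#' with 3D coordinates. The record name (first line of each molfile block) is
#' used as the compound id; empty names fall back to `mol_<k>`. Explicit
#' hydrogens in the file are folded into the heavy-atom `nH` counts so that
#' the returned graphs are hydrogen-depleted, as all 2D descriptors expect;
#' bond order 4 (aromatic) is mapped to 1.5.
#'
#' @param path file path.
#' @return list of `molgraph` objects with `x`, `y`, `z` atom columns.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list())
  # split into records on "$$$$"
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    block <- block[!(trimws(block) == "$$$$")]
    if (all(!nzchar(trimws(block)))) next
    g <- tryCatch(parse_molblock(block, r),
                  error = function(e) stop("SDF record ", r, ": ",
                                           conditionMessage(e), call. = FALSE))
    out[[length(out) + 1L]] <- g
  }
  out
}

parse_molblock <- function(block, record_index) {
  if (length(block) < 4L) stop("truncated molfile block")
  name <- trimws(block[1])
  counts <- block[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 0L)
    stop("malformed counts line: '", counts, "'")
  if (length(block) < 4L + na + nb) stop("atom/bond block shorter than counts line")
  at_lines <- block[4L + seq_len(na)]
  bd_lines <- if (nb > 0L) block[4L + na + seq_len(nb)] else character()
  x <- as.numeric(substr(at_lines, 1, 10))
  y <- as.numeric(substr(at_lines, 11, 20))
  z <- as.numeric(substr(at_lines, 21, 30))
  element <- trimws(substr(at_lines, 31, 33))
  chg_code <- suppressWarnings(as.integer(substr(at_lines, 37, 39)))
  chg_code[is.na(chg_code)] <- 0L
  # molfile charge codes: 1:+3 2:+2 3:+1 4:radical 5:-1 6:-2 7:-3
  charge <- integer(na)
  charge[chg_code %in% 1:3] <- 4L - chg_code[chg_code %in% 1:3]
  charge[chg_code %in% 5:7] <- 4L - chg_code[chg_code %in% 5:7]
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("unreadable atom coordinates")
  i <- integer(nb); j <- integer(nb); ord <- numeric(nb)
  if (nb > 0L) {
    i <- as.integer(substr(bd_lines, 1, 3))
    j <- as.integer(substr(bd_lines, 4, 6))
    code <- as.integer(substr(bd_lines, 7, 9))
    if (anyNA(i) || anyNA(j) || anyNA(code)) stop("unreadable bond block")
    ord <- ifelse(code == 4L, 1.5, as.numeric(code))
  }
  # M  CHG overrides
  for (ln in block[grepl("^M  CHG", block)]) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    nset <- f[1]
    for (k in seq_len(nset)) charge[f[2 * k]] <- f[2 * k + 1L]
  }
  atoms <- data.frame(element = element, charge = charge,
                      aromatic = FALSE, nH = 0L, x = x, y = y, z = z)
  bonds <- data.frame(i = i, j = j, order = ord)
  # mark aromatic atoms from 1.5-order bonds
  ar <- unique(c(bonds$i[bonds$order == 1.5], bonds$j[bonds$order == 1.5]))
  atoms$aromatic[ar] <- TRUE
  g <- suppress_hydrogens(atoms, bonds)
  if (!nzchar(name)) name <- sprintf("mol_%d", record_index)
  molgraph(g$atoms, g$bonds, id = name)
}

# Fold explicit H atoms into heavy-atom nH counts, then add implicit H for
# heavy atoms still below default valence (molfiles usually carry explicit H
# when written with 3D coordinates, but 2D files may not).
suppress_hydrogens <- function(atoms, bonds) {
  is_h <- atoms$element == "H"
  if (any(is_h)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (is_h[i] && !is_h[j]) atoms$nH[j] <- atoms$nH[j] + 1L
      if (is_h[j] && !is_h[i]) atoms$nH[i] <- atoms$nH[i] + 1L
    }
    keep <- which(!is_h)
    remap <- match(seq_len(nrow(atoms)), keep)
    bonds <- bonds[!is_h[bonds$i] & !is_h[bonds$j], , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL; rownames(bonds) <- NULL
  } else {
    # no explicit H anywhere: fill to default valence
    bsum <- numeric(nrow(atoms))
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$i[k]] <- bsum[bonds$i[k]] + bonds$order[k]
      bsum[bonds$j[k]] <- bsum[bonds$j[k]] + bonds$order[k]
    }
    for (a in seq_len(nrow(atoms))) {
      dv <- default_valence[[atoms$element[a]]]
      if (!is.null(dv))
        atoms$nH[a] <- max(0L, as.integer(floor(dv - bsum[a] - atoms$charge[a] * 0 + 1e-9)))
    }
  }
  list(atoms = atoms, bonds = bonds)
}

#' Write molecular graphs to a V2000 SDF file
#'
#' Explicit hydrogens are not written; coordinates default to zero when the
#' graph carries none. Aromatic bonds are written with the V2000 aromatic
#' bond code 4.
#'
#' @param graphs a `molgraph` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(graphs, path) {
  if (inherits(graphs, "molgraph")) graphs <- list(graphs)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in graphs) {
    at <- g$atoms
    if (!all(c("x", "y", "z") %in% names(at))) at$x <- at$y <- at$z <- 0
    at$x[is.na(at$x)] <- 0; at$y[is.na(at$y)] <- 0; at$z[is.na(at$z)] <- 0
    writeLines(c(g$id, "  qsarligand", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(g$bonds)), con)
    for (a in seq_len(nrow(at))) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         at$x[a], at$y[a], at$z[a], at$element[a]), con)
    }
    for (k in seq_len(nrow(g$bonds))) {
      code <- if (g$bonds$order[k] == 1.5) 4L else as.integer(g$bonds$order[k])
      writeLines(sprintf("%3d%3d%3d  0", g$bonds$i[k], g$bonds$j[k], code), con)
    }
    chg <- which(at$charge != 0L)
    if (length(chg) > 0L) {
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, at$charge[chg]),
                               collapse = "")), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
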