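#' Molecular topology
#'
#' A `topology` is the coordinate-independent frame of reference for all
#' selections: a table of atoms (identifier, name, element, residue, chain)
#' plus the ordered list of chain labels. Atom identifiers are 0-based and
#' contiguous; residues are identified by `(chain_id, residue_index)` using
#' the source file's own (1-based) numbering, which is never renumbered so
#' that author residue numbering (e.g. R87, A455, Q725) survives round trips.
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`, `element`,
#'   `residue_index`, `residue_name`, `chain_id`.
#' @param xyz optional n_atoms x 3 matrix of reference coordinates (Angstrom).
#' @return An object of class `topology` with elements `atoms`, `chains`
#'   and (optionally) `xyz`.
#' @export
topology <- function(atoms, xyz = NULL) {
  req <- c("atom_id", "atom_name", "element", "residue_index",
           "residue_name", "chain_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("topology atoms table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty topology: zero atoms")
  atoms <- as.data.frame(atoms[, req], stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$atom_id) ||
      !identical(sort(atoms$atom_id), 0:(nrow(atoms) - 1L))) {
    atoms$atom_id <- 0:(nrow(atoms) - 1L)
  }
  chains <- unique(as.character(atoms$chain_id))
  obj <- list(atoms = atoms, chains = chains)
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    stopifnot(nrow(xyz) == nrow(atoms), ncol(xyz) == 3)
    dimnames(xyz) <- NULL
    obj$xyz <- xyz
  }
  class(obj) <- "topology"
  obj
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d chain(s) [%s]\n",
              n_atoms(x), nrow(residue_table(x)), length(x$chains),
              paste(x$chains, collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a `topology`.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Unique residues of a topology, in atom order
#'
#' @param top a `topology`.
#' @return data.frame with `chain_id`, `residue_index`, `residue_name`.
#' @export
residue_table <- function(top) {
  a <- top$atoms
  key <- paste(a$chain_id, a$residue_index, sep = "\r")
  keep <- !duplicated(key)
  data.frame(chain_id = a$chain_id[keep],
             residue_index = a$residue_index[keep],
             residue_name = a$residue_name[keep],
             stringsAsFactors = FALSE)
}

# Element from an atom name when the file does not state it: strip digits
# and primes, then take a leading two-letter element if recognised, else the
# first letter.
infer_element <- function(atom_name) {
  two_letter <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA2", "SE")
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  el <- substr(nm, 1, 1)
  first2 <- substr(nm, 1, 2)
  # names like "CA" (alpha carbon) must stay carbon; only map true ions
  el[first2 %in% c("CL", "BR", "SE") & nchar(nm) == 2] <-
    first2[first2 %in% c("CL", "BR", "SE") & nchar(nm) == 2]
  el[el == ""] <- "X"
  el
}

#' Van der Waals radii used for surface-area calculations
#'
#' Fixed element radius table (Angstrom): C 1.70, N 1.55, O 1.52, S 1.80;
#' anything else (including pseudo-atoms) falls back to `default_radius`.
#' Versioned with the package so computed areas are stable across releases.
#'
#' @param elements character vector of element symbols.
#' @param default_radius radius (Angstrom) for unknown elements.
#' @return numeric vector of radii.
#' @export
element_radii <- function(elements, default_radius = 1.70) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- unname(tab[toupper(elements)])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("%d atom(s) with unknown element assigned default radius %.2f A",
                    sum(unknown), default_radius))
    r[unknown] <- default_radius
  }
  r
}

#' Read a topology from a PDB or GRO file
#'
#' PDB files are parsed with \pkg{bio3d}; GRO files with a built-in reader.
#' PDB records with blank chain identifiers are assigned a single default
#' chain label `"A"`. Elements absent from the file are inferred from atom
#' names. Reference coordinates (first model/frame) are kept in `$xyz`,
#' converted to Angstrom (GRO files are in nm).
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @return a [topology()].
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") return(read_gro_topology(path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  if (nrow(a) == 0) stop("empty topology: zero atoms in ", path)
  chain <- as.character(a$chain)
  chain[is.na(chain) | chain == "" | chain == " "] <- "A"
  el <- as.character(a$elesy)
  bad <- is.na(el) | trimws(el) == ""
  el[bad] <- infer_element(a$elety[bad])
  atoms <- data.frame(atom_id = 0:(nrow(a) - 1L),
                      atom_name = trimws(a$elety),
                      element = trimws(el),
                      residue_index = as.integer(a$resno),
                      residue_name = trimws(a$resid),
                      chain_id = chain,
                      stringsAsFactors = FALSE)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  topology(atoms, xyz = xyz)
}

# GRO fixed-column reader. Coordinates are nm in the file; converted to
# Angstrom here. GRO carries no chain labels: all atoms go to chain "A".
read_gro_topology <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("failed to parse GRO '", path,
                              "': fewer than 3 lines")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat) || nat < 1) stop("failed to parse GRO '", path,
                                  "': bad atom count at line 2")
  if (length(lines) < 2 + nat) stop("failed to parse GRO '", path,
                                    "': truncated at line ", length(lines))
  al <- lines[3:(2 + nat)]
  resno <- as.integer(substr(al, 1, 5))
  resnm <- trimws(substr(al, 6, 10))
  atnm <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  if (anyNA(resno) || anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("failed to parse GRO '", path, "': malformed atom line ",
         2 + which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))[1])
  }
  atoms <- data.frame(atom_id = 0:(nat - 1L),
                      atom_name = atnm,
                      element = infer_element(atnm),
                      residue_index = resno,
                      residue_name = resnm,
                      chain_id = "A",
                      stringsAsFactors = FALSE)
  topology(atoms, xyz = cbind(x, y, z) * 10)
}

# Write a topology + one or more coordinate frames as a (multi-frame) GRO
# file, in nm. Used for fixtures and round-trip tests.
write_gro <- function(top, xyz, path, title = "trajcomp") {
  if (is.matrix(xyz)) xyz <- list(xyz)
  a <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in xyz) {
    writeLines(title, con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residue_index %% 100000L, a$residue_name,
                       a$atom_name, (a$atom_id + 1L) %% 100000L,
                       fr[, 1] / 10, fr[, 2] / 10, fr[, 3] / 10), con)
    writeLines("   0.00000   0.00000   0.00000", con)
  }
  invisible(path)
}
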