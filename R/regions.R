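#' Named residue regions
#'
#' A `region_spec` names a set of residues, each identified by
#' `(chain_id, residue_index)`. Regions drive every selection in the
#' package: interface partners (e.g. an active C-terminal region versus the
#' rest of the complex), superposition fit sets, and per-region summaries
#' of fluctuation profiles.
#'
#' @param name region name.
#' @param members data.frame with columns `chain_id` and `residue_index`.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(name, members) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  stopifnot(all(c("chain_id", "residue_index") %in% names(members)))
  if (nrow(members) == 0) stop("region '", name, "' has no members")
  members$chain_id <- as.character(members$chain_id)
  members$residue_index <- as.integer(members$residue_index)
  members <- members[!duplicated(paste(members$chain_id,
                                       members$residue_index)), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(name = name,
                 members = members[, c("chain_id", "residue_index")]),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("region '%s': %d residue(s) on chain(s) %s\n", x$name,
              nrow(x$members), paste(unique(x$members$chain_id),
                                     collapse = ", ")))
  invisible(x)
}

#' Build a region from "CHAIN:first-last" range strings
#'
#' @param name region name.
#' @param ranges character vector like `c("A:1-50", "B:10-20", "B:35")`.
#' @return a [region_spec()].
#' @export
region_from_ranges <- function(name, ranges) {
  parts <- lapply(ranges, function(r) {
    m <- regmatches(r, regexec("^\\s*([^:]+):(\\d+)(?:-(\\d+))?\\s*$", r))[[1]]
    if (length(m) == 0) stop("bad region range '", r,
                             "'; expected CHAIN:first-last")
    lo <- as.integer(m[3])
    hi <- if (m[4] == "") lo else as.integer(m[4])
    data.frame(chain_id = m[2], residue_index = lo:hi,
               stringsAsFactors = FALSE)
  })
  region_spec(name, do.call(rbind, parts))
}

#' Read a region configuration file
#'
#' Structured-text (YAML) mapping of region name to a list of
#' `"CHAIN:first-last"` residue ranges.
#'
#' @param path YAML file path.
#' @return named list of [region_spec()].
#' @export
load_regions <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    region_from_ranges(nm, unlist(cfg[[nm]]))
  })
  names(out) <- names(cfg)
  out
}

#' Region covering every residue of a topology
#' @param top a [topology()].
#' @param name region name.
#' @export
region_all <- function(top, name = "all") {
  region_spec(name, residue_table(top)[, c("chain_id", "residue_index")])
}

#' Region covering one whole chain
#' @param top a [topology()].
#' @param chain chain label.
#' @param name region name (defaults to the chain label).
#' @export
region_chain <- function(top, chain, name = chain) {
  rt <- residue_table(top)
  rt <- rt[rt$chain_id == chain, , drop = FALSE]
  if (nrow(rt) == 0) stop("chain '", chain, "' not in topology")
  region_spec(name, rt[, c("chain_id", "residue_index")])
}

#' Complement of a region within a topology
#'
#' All residues of the topology not in `region` — e.g. "rest of complex"
#' opposite a detachable region.
#'
#' @param top a [topology()].
#' @param region a [region_spec()].
#' @param name name of the complement region.
#' @export
region_complement <- function(top, region, name = paste0("not_", region$name)) {
  rt <- residue_table(top)
  key <- paste(rt$chain_id, rt$residue_index)
  inkey <- paste(region$members$chain_id, region$members$residue_index)
  keep <- rt[!(key %in% inkey), , drop = FALSE]
  if (nrow(keep) == 0) stop("complement of region '", region$name,
                            "' is empty")
  region_spec(name, keep[, c("chain_id", "residue_index")])
}

# Validate that every member exists in the topology; returns invisibly or
# stops with the first offending member.
check_region <- function(top, region) {
  rt <- residue_table(top)
  key <- paste(rt$chain_id, rt$residue_index)
  mkey <- paste(region$members$chain_id, region$members$residue_index)
  bad <- which(!(mkey %in% key))
  if (length(bad) > 0) {
    stop("region '", region$name, "' member not in topology: chain ",
         region$members$chain_id[bad[1]], " residue ",
         region$members$residue_index[bad[1]])
  }
  invisible(TRUE)
}

#' Atom indices belonging to a region
#'
#' @param top a [topology()].
#' @param region a [region_spec()], or NULL for all atoms.
#' @param atoms which atoms: `"heavy"` (non-hydrogen), `"ca"` (alpha
#'   carbons), or `"all"`.
#' @return integer vector of 1-based row indices into `top$atoms`.
#' @export
region_atoms <- function(top, region = NULL, atoms = c("heavy", "ca", "all")) {
  atoms <- match.arg(atoms)
  a <- top$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(region)) {
    check_region(top, region)
    key <- paste(a$chain_id, a$residue_index)
    mkey <- paste(region$members$chain_id, region$members$residue_index)
    sel <- key %in% mkey
  }
  if (atoms == "heavy") sel <- sel & toupper(a$element) != "H"
  if (atoms == "ca") sel <- sel & a$atom_name == "CA"
  which(sel)
}

# One selected atom per residue (default Calpha; falls back to the first
# heavy atom of any residue lacking one). Returns list(idx, map) where map
# is the residue_index_map data.frame aligned with idx.
residue_representatives <- function(top, region = NULL, atom_name = "CA") {
  a <- top$atoms
  sel <- if (is.null(region)) rep(TRUE, nrow(a)) else {
    check_region(top, region)
    paste(a$chain_id, a$residue_index) %in%
      paste(region$members$chain_id, region$members$residue_index)
  }
  rt <- residue_table(top)
  if (!is.null(region)) {
    key <- paste(rt$chain_id, rt$residue_index)
    rt <- rt[key %in% paste(region$members$chain_id,
                            region$members$residue_index), , drop = FALSE]
  }
  akey <- paste(a$chain_id, a$residue_index)
  idx <- integer(nrow(rt))
  for (r in seq_len(nrow(rt))) {
    rows <- which(akey == paste(rt$chain_id[r], rt$residue_index[r]) & sel)
    ca <- rows[a$atom_name[rows] == atom_name]
    if (length(ca) >= 1) {
      idx[r] <- ca[1]
    } else {
      heavy <- rows[toupper(a$element[rows]) != "H"]
      idx[r] <- if (length(heavy) >= 1) heavy[1] else rows[1]
    }
  }
  list(idx = idx,
       map = rt[, c("chain_id", "residue_index")])
}

# Rows of a residue_index_map that fall inside a region.
map_region_rows <- function(map, region) {
  paste(map$chain_id, map$residue_index) %in%
    paste(region$members$chain_id, region$members$residue_index)
}
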