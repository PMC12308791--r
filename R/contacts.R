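#' Count heavy-atom contacts between two atom sets in one frame
#'
#' Number of atom pairs `(i in set_a, j in set_b)` with distance at or
#' below `cutoff` (default 5 A, the usual heavy-atom contact criterion).
#' Uses a cell-list spatial grid but is contractually equal to the
#' all-pairs answer. Hydrogens are expected to be filtered upstream (see
#' [region_atoms()] with `atoms = "heavy"`).
#'
#' @param xyz n_atoms x 3 coordinate matrix (Angstrom).
#' @param set_a,set_b disjoint integer vectors of 1-based atom indices.
#' @param cutoff contact distance cutoff in Angstrom.
#' @return integer contact count; an empty set gives 0 with a warning.
#' @export
count_contacts <- function(xyz, set_a, set_b, cutoff = 5.0) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    warning("empty atom set in count_contacts; returning 0")
    return(0L)
  }
  if (length(intersect(set_a, set_b)) > 0) {
    stop("count_contacts atom sets must be disjoint")
  }
  cpp_count_contacts(xyz, as.integer(set_a) - 1L, as.integer(set_b) - 1L,
                     cutoff)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by deterministic sphere sampling (golden-spiral point
#' set, default 960 points per atom) with probe radius 1.4 A and the
#' package's fixed element radius table ([element_radii()]).
#'
#' @param xyz n x 3 coordinates (Angstrom).
#' @param elements element symbol per atom.
#' @param probe_radius probe radius, Angstrom.
#' @param n_points sphere sample points per atom (>= 960 recommended).
#' @return numeric vector of per-atom areas (A^2).
#' @export
sasa <- function(xyz, elements, probe_radius = 1.4, n_points = 960L) {
  stopifnot(nrow(xyz) == length(elements))
  cpp_sasa(as.matrix(xyz), element_radii(elements), probe_radius,
           as.integer(n_points))
}

#' Buried interface area between two atom sets in one frame
#'
#' Half the solvent-accessible surface area lost on forming the two-set
#' complex from its separated parts:
#' `(SASA(a alone) + SASA(b alone) - SASA(a u b)) / 2`.
#'
#' @param xyz full-system n x 3 coordinates (Angstrom).
#' @param set_a,set_b 1-based atom indices of the two sides.
#' @param elements element symbol per atom (length `nrow(xyz)`).
#' @param probe_radius probe radius (default 1.4 A).
#' @param n_points sphere sample points per atom (default 960).
#' @return interface area in A^2 (>= 0 up to sampling noise).
#' @export
interface_area <- function(xyz, set_a, set_b, elements,
                           probe_radius = 1.4, n_points = 960L) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    warning("empty atom set in interface_area; returning 0")
    return(0)
  }
  xyz <- as.matrix(xyz)
  r <- element_radii(elements)
  s_a <- sum(cpp_sasa(xyz[set_a, , drop = FALSE], r[set_a], probe_radius,
                      n_points))
  s_b <- sum(cpp_sasa(xyz[set_b, , drop = FALSE], r[set_b], probe_radius,
                      n_points))
  un <- c(set_a, set_b)
  s_ab <- sum(cpp_sasa(xyz[un, , drop = FALSE], r[un], probe_radius,
                       n_points))
  (s_a + s_b - s_ab) / 2
}

#' Per-frame interface area and contact count for two regions
#'
#' Computes, over the pooled ensemble, the heavy-atom contact count (every
#' frame) and the buried interface area (every `area_stride`-th frame,
#' default every frame) between two disjoint residue regions, plus their
#' means and standard deviations.
#'
#' @param ens a [trajectory_ensemble()].
#' @param region_a,region_b disjoint [region_spec()]s.
#' @param cutoff heavy-atom contact cutoff (default 5 A).
#' @param probe_radius SASA probe radius (default 1.4 A).
#' @param n_points SASA sphere points per atom (default 960).
#' @param area_stride compute area on every `area_stride`-th frame.
#' @return object of class `interface_result` with `nc_series`,
#'   `area_series`, `area_frames` (frame indices of the area series) and
#'   the summary statistics `nc_mean`, `nc_sd`, `area_mean`, `area_sd`.
#' @export
interface_timeseries <- function(ens, region_a, region_b, cutoff = 5.0,
                                 probe_radius = 1.4, n_points = 960L,
                                 area_stride = 1L) {
  idx_a <- region_atoms(ens$topology, region_a, atoms = "heavy")
  idx_b <- region_atoms(ens$topology, region_b, atoms = "heavy")
  if (length(intersect(idx_a, idx_b)) > 0) {
    stop("regions '", region_a$name, "' and '", region_b$name,
         "' overlap; interface regions must be disjoint")
  }
  nf <- n_frames(ens)
  el <- ens$topology$atoms$element
  nc <- integer(nf)
  for (f in seq_len(nf)) {
    nc[f] <- count_contacts(frame_xyz(ens, f), idx_a, idx_b, cutoff)
  }
  area_frames <- seq(1L, nf, by = area_stride)
  area <- vapply(area_frames, function(f) {
    interface_area(frame_xyz(ens, f), idx_a, idx_b, el, probe_radius,
                   n_points)
  }, 0.0)
  structure(list(region_a = region_a$name, region_b = region_b$name,
                 nc_series = nc, area_series = area,
                 area_frames = area_frames,
                 nc_mean = mean(nc), nc_sd = stats::sd(nc),
                 area_mean = mean(area),
                 area_sd = if (length(area) > 1) stats::sd(area) else 0),
            class = "interface_result")
}

#' @export
print.interface_result <- function(x, ...) {
  cat(sprintf("interface %s/%s: Nc = %.1f +- %.1f, area = %.1f +- %.1f A^2 (%d frames)\n",
              x$region_a, x$region_b, x$nc_mean,
              ifelse(is.na(x$nc_sd), 0, x$nc_sd), x$area_mean,
              ifelse(is.na(x$area_sd), 0, x$area_sd), length(x$nc_series)))
  invisible(x)
}

#' Percent change of a variant value relative to wild type
#'
#' `100 * (variant - wt) / wt`, the convention used for reporting
#' interface area and contact-count changes (e.g. -17 means a 17 percent
#' decrease relative to wild type).
#'
#' @param variant_value,wt_value numeric scalars; `wt_value` must be
#'   non-zero.
#' @return percent change.
#' @export
percent_change <- function(variant_value, wt_value) {
  if (any(wt_value == 0)) {
    stop("percent change undefined: wild-type value is 0")
  }
  100 * (variant_value - wt_value) / wt_value
}

# Hydrogens attached to a donor heavy atom: same residue, element H,
# within 1.25 A in the reference (first) frame.
attached_hydrogens <- function(ens, donor_idx) {
  a <- ens$topology$atoms
  xyz <- frame_xyz(ens, 1)
  hyd <- which(toupper(a$element) == "H" &
                 a$chain_id == a$chain_id[donor_idx] &
                 a$residue_index == a$residue_index[donor_idx])
  if (length(hyd) == 0) return(integer(0))
  d <- sqrt(rowSums((xyz[hyd, , drop = FALSE] -
                       matrix(xyz[donor_idx, ], length(hyd), 3,
                              byrow = TRUE))^2))
  hyd[d <= 1.25]
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' A bond exists in a frame iff the donor-acceptor distance is at most
#' `d_cutoff` and the D-H...A angle is at least `angle_cutoff` (defaults
#' 3.5 A, 150 degrees). In `"heavy"` mode (for topologies without
#' hydrogens) the criterion is distance-only at `heavy_d_cutoff`
#' (default 3.0 A). One result per donor/acceptor pair bound in at least
#' one frame; occupancy is the bound-frame fraction.
#'
#' @param ens a [trajectory_ensemble()].
#' @param donors,acceptors 1-based atom indices of donor heavy atoms and
#'   acceptor atoms.
#' @param d_cutoff donor-acceptor distance cutoff (Angstrom).
#' @param angle_cutoff D-H...A angle cutoff (degrees).
#' @param mode `"strict"` (needs attached hydrogens) or `"heavy"`.
#' @param heavy_d_cutoff distance-only cutoff for `"heavy"` mode.
#' @return list of `hbond_result` objects, each with `donor_atom`,
#'   `hydrogen_atom` (NA in heavy mode), `acceptor_atom`, `occupancy` and
#'   logical `per_frame`.
#' @export
hbond_occupancy <- function(ens, donors, acceptors, d_cutoff = 3.5,
                            angle_cutoff = 150, mode = c("strict", "heavy"),
                            heavy_d_cutoff = 3.0) {
  mode <- match.arg(mode)
  nf <- n_frames(ens)
  a <- ens$topology$atoms
  results <- list()
  for (don in donors) {
    hyds <- if (mode == "strict") attached_hydrogens(ens, don) else NA_integer_
    if (mode == "strict" && length(hyds) == 0) {
      stop("donor atom ", a$atom_name[don], " (chain ", a$chain_id[don],
           " residue ", a$residue_index[don],
           ") has no attached hydrogen; use mode = 'heavy'")
    }
    for (acc in acceptors) {
      if (acc == don) next
      dvec <- ens$coords[, acc, , drop = FALSE] -
        ens$coords[, don, , drop = FALSE]
      dda <- sqrt(rowSums(matrix(dvec, nf, 3)^2))
      if (mode == "heavy") {
        per_frame <- dda <= heavy_d_cutoff
        best_h <- NA_integer_
      } else {
        per_frame <- rep(FALSE, nf)
        best_h <- hyds[1]
        best_occ <- -1
        for (h in hyds) {
          hd <- matrix(ens$coords[, don, , drop = FALSE] -
                         ens$coords[, h, , drop = FALSE], nf, 3)
          ha <- matrix(ens$coords[, acc, , drop = FALSE] -
                         ens$coords[, h, , drop = FALSE], nf, 3)
          cosang <- rowSums(hd * ha) /
            (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
          ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          pf <- dda <= d_cutoff & ang >= angle_cutoff
          if (mean(pf) > best_occ) {
            best_occ <- mean(pf)
            per_frame <- pf
            best_h <- h
          }
        }
      }
      if (any(per_frame)) {
        results[[length(results) + 1L]] <- structure(
          list(donor_atom = don, hydrogen_atom = best_h,
               acceptor_atom = acc, occupancy = mean(per_frame),
               per_frame = per_frame),
          class = "hbond_result")
      }
    }
  }
  results
}

#' @export
print.hbond_result <- function(x, ...) {
  cat(sprintf("H-bond donor #%d -> acceptor #%d: occupancy %.1f%%\n",
              x$donor_atom, x$acceptor_atom, 100 * x$occupancy))
  invisible(x)
}

#' Shortest van der Waals contacts between two residues
#'
#' All heavy-atom pairs of the two residues whose minimum distance over
#' the ensemble is at most `cutoff`, sorted ascending by that minimum; the
#' mean distance is taken over the frames where the pair is within the
#' cutoff.
#'
#' @param ens a [trajectory_ensemble()].
#' @param residue_a,residue_b residues as `c(chain_id, residue_index)`.
#' @param cutoff van der Waals contact cutoff (default 4.5 A).
#' @return data.frame with atom indices/names, `min_distance`,
#'   `mean_distance` and `n_within` (frames within cutoff), possibly
#'   zero rows.
#' @export
vdw_contacts <- function(ens, residue_a, residue_b, cutoff = 4.5) {
  a <- ens$topology$atoms
  pick <- function(res) {
    rows <- which(a$chain_id == as.character(res[[1]]) &
                    a$residue_index == as.integer(res[[2]]) &
                    toupper(a$element) != "H")
    if (length(rows) == 0) {
      stop("residue ", res[[1]], ":", res[[2]], " not found (or no heavy atoms)")
    }
    rows
  }
  ia <- pick(residue_a)
  ib <- pick(residue_b)
  X <- ens$coords[, , 1, drop = FALSE]; dim(X) <- dim(X)[1:2]
  Y <- ens$coords[, , 2, drop = FALSE]; dim(Y) <- dim(Y)[1:2]
  Z <- ens$coords[, , 3, drop = FALSE]; dim(Z) <- dim(Z)[1:2]
  st <- cpp_pair_distance_stats(X, Y, Z, ia - 1L, ib - 1L, cutoff)
  st$i <- st$i + 1L
  st$j <- st$j + 1L
  st <- st[st$min_distance <= cutoff, , drop = FALSE]
  st <- st[order(st$min_distance, st$i, st$j), , drop = FALSE]
  data.frame(atom_i = st$i, atom_i_name = a$atom_name[st$i],
             atom_j = st$j, atom_j_name = a$atom_name[st$j],
             min_distance = st$min_distance,
             mean_distance = st$mean_distance,
             n_within = st$n_within,
             stringsAsFactors = FALSE, row.names = NULL)
}
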