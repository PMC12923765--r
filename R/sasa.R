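#' Van der Waals radii (Angstroms)
#'
#' Bondi radii for the elements occurring in protein/lipid heavy-atom work,
#' used by the Shrake-Rupley quadrature.
#' @return named numeric vector.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    "NA" = 2.27, MG = 1.73, ZN = 1.39, CA = 2.31, FE = 1.63, MN = 1.61)
}

# deterministic quasi-uniform sphere points (Fibonacci / golden-spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by Shrake-Rupley quadrature
#'
#' Each atom is expanded by the probe radius and sampled at `n_points`
#' quasi-uniform sphere points; a point is accessible if it lies outside
#' every other expanded atom. Area per atom is the accessible fraction of
#' the expanded-sphere area.
#'
#' @param coords `n x 3` coordinates (Angstroms).
#' @param elements element symbols, matched against [vdw_radii()].
#' @param probe probe radius (Angstroms), default 1.4 (water).
#' @param n_points quadrature points per atom, default 960.
#' @return numeric vector of per-atom SASA (Angstroms^2).
#' @export
sasa_shrake_rupley <- function(coords, elements, probe = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  radii_tab <- vdw_radii()
  el <- toupper(elements)
  unknown <- setdiff(unique(el), names(radii_tab))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- unname(radii_tab[el]) + probe
  pts <- sphere_points(n_points)
  area <- numeric(n)
  if (n == 1L) return(4 * pi * r^2)
  d2_all <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2_all[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (!length(nb)) { area[i] <- 4 * pi * r[i]^2; next }
    p <- pts * r[i]
    p <- sweep(p, 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (p[acc, 1] - coords[j, 1])^2 + (p[acc, 2] - coords[j, 2])^2 +
            (p[acc, 3] - coords[j, 3])^2
      acc[acc] <- d2 >= r[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  area
}

topology_coords_groups <- function(topology, group) {
  if (is.data.frame(group)) {
    idx <- unlist(lapply(seq_len(nrow(group)), function(k)
      which(topology$chain_id == group$chain[k] &
            topology$residue_number == group$residue[k])))
    sort(unique(idx))
  } else {
    sort(unique(as.integer(group)))
  }
}

#' Buried interface area between two residue groups
#'
#' BSA = (SASA(A) + SASA(B) - SASA(A union B)) / 2, each term from the
#' Shrake-Rupley quadrature over heavy atoms (probe 1.4 Angstroms, 960
#' points). Non-negative up to quadrature noise; zero when the groups are
#' beyond contact range.
#'
#' @param coords one frame's `n x 3` coordinates (Angstroms).
#' @param topology topology data frame of the trajectory.
#' @param group_a,group_b disjoint groups: either data frames with columns
#'   `chain`, `residue`, or integer atom-index vectors.
#' @param probe probe radius (Angstroms).
#' @param n_points quadrature points per atom.
#' @return buried area (Angstroms^2).
#' @export
buried_interface_area <- function(coords, topology, group_a, group_b,
                                  probe = 1.4, n_points = 960L) {
  ia <- topology_coords_groups(topology, group_a)
  ib <- topology_coords_groups(topology, group_b)
  if (!length(ia) || !length(ib)) stop("groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  heavy <- which(topology$element != "H")
  ia <- intersect(ia, heavy); ib <- intersect(ib, heavy)
  sasa_of <- function(idx)
    sum(sasa_shrake_rupley(coords[idx, , drop = FALSE],
                           topology$element[idx], probe, n_points))
  (sasa_of(ia) + sasa_of(ib) - sasa_of(c(ia, ib))) / 2
}
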