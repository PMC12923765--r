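#' Lipid species codes
#'
#' 3-character topology residue names for the bilayer species and the
#' corresponding full names.
#' @keywords internal
LIPID_RESNAMES <- c(DPC = "DOPC", DPS = "DOPS", PIP = "PIP2")

lipid_rows <- function(top) top$residue_name %in% names(LIPID_RESNAMES)

phosphate_rows <- function(top) lipid_rows(top) & top$name == "P"

#' Assign bilayer leaflets for one frame
#'
#' The bilayer normal is z. The midplane is the mean phosphate z over all
#' lipids; a lipid's leaflet is the sign of its phosphate z relative to the
#' midplane. Each leaflet's reference phosphate plane is the mean phosphate
#' z of its PC and PS lipids only (PIP2 is excluded, since PIP2 protrusion
#' is measured against the PC/PS plane). The holo leaflet is the one whose
#' plane lies nearer the mean z of protein atoms.
#'
#' @param traj trajectory containing lipid pseudo-molecules (chain "M",
#'   residue names DPC/DPS/PIP, phosphate atom "P") and protein atoms.
#' @param frame 1-based frame index.
#' @return object of class `membrane_frame`: `leaflet_of_lipid` (named
#'   "upper"/"lower" per lipid residue number), `phosphate_plane_z`
#'   (named upper/lower), `midplane_z`, `holo_leaflet`.
#' @export
assign_leaflets <- function(traj, frame = 1L) {
  top <- traj$topology
  fr <- traj$frames[[frame]]
  ph <- which(phosphate_rows(top))
  if (length(ph) < 2L) stop("need at least 2 lipid phosphates")
  z <- fr[ph, 3]
  mid <- mean(z)
  side <- ifelse(z > mid, "upper", "lower")
  if (length(unique(side)) < 2L)
    stop("all phosphates on one side of the midplane; not a bilayer")
  is_pcps <- top$residue_name[ph] %in% c("DPC", "DPS")
  plane <- c(upper = mean(z[side == "upper" & is_pcps]),
             lower = mean(z[side == "lower" & is_pcps]))
  if (any(is.na(plane))) stop("a leaflet has no PC/PS phosphate")
  prot <- which(!lipid_rows(top) & top$residue_name != "ATP")
  holo <- if (length(prot)) {
    pz <- mean(fr[prot, 3])
    names(which.min(abs(plane - pz)))
  } else "upper"
  structure(list(
    leaflet_of_lipid = stats::setNames(side, top$residue_number[ph]),
    phosphate_plane_z = plane, midplane_z = mid, holo_leaflet = holo),
    class = "membrane_frame")
}

#' Residue depth profile relative to the holo phosphate plane
#'
#' Per frame and residue, the deviation is the z of the most membrane-ward
#' sidechain heavy atom minus the holo leaflet's PC/PS phosphate plane z,
#' with the sign flipped on the lower leaflet so positive always points
#' away from the membrane centre (toward water); negative means inserted.
#'
#' @param traj trajectory with membrane and protein.
#' @param residues data frame with columns `chain`, `residue`.
#' @param transient_fraction initial fraction of frames to skip.
#' @return data frame `chain`, `residue`, `mean_depth`, `sd_depth`,
#'   `n_frames` (depths in Angstroms).
#' @export
depth_profile <- function(traj, residues, transient_fraction = 0) {
  top <- traj$topology
  nf <- n_frames(traj)
  use <- seq.int(floor(nf * transient_fraction) + 1L, nf)
  sidechain <- !(top$name %in% c("N", "CA", "C", "O")) & top$element != "H"
  idx_list <- lapply(seq_len(nrow(residues)), function(k) {
    ii <- which(top$chain_id == residues$chain[k] &
                top$residue_number == residues$residue[k] & sidechain)
    if (!length(ii))
      stop("residue ", residues$chain[k], ":", residues$residue[k],
           " has no sidechain heavy atoms in topology")
    ii
  })
  devs <- matrix(NA_real_, length(use), nrow(residues))
  for (t in seq_along(use)) {
    mf <- assign_leaflets(traj, use[t])
    plane <- mf$phosphate_plane_z[[mf$holo_leaflet]]
    sgn <- if (mf$holo_leaflet == "upper") 1 else -1
    fr <- traj$frames[[use[t]]]
    for (k in seq_along(idx_list)) {
      zk <- fr[idx_list[[k]], 3]
      # most membrane-ward atom: minimum signed deviation
      devs[t, k] <- min(sgn * (zk - plane))
    }
  }
  data.frame(chain = residues$chain, residue = residues$residue,
             mean_depth = colMeans(devs), sd_depth = apply(devs, 2, stats::sd),
             n_frames = length(use), stringsAsFactors = FALSE)
}

#' PIP2 head-group protrusion distribution
#'
#' Elevation of each holo-leaflet PIP2 phosphate above the holo PC/PS
#' phosphate plane (sign-corrected per leaflet; positive = toward water),
#' pooled over post-transient frames. Apo-leaflet PIP2 is excluded.
#'
#' @param traj trajectory.
#' @param transient_fraction initial fraction of frames to skip.
#' @return list with `elevations` (numeric vector, Angstroms), `mean`, `sd`,
#'   `n_pip2` (holo-leaflet PIP2 count in the last frame analysed).
#' @export
pip2_protrusion <- function(traj, transient_fraction = 0) {
  top <- traj$topology
  nf <- n_frames(traj)
  use <- seq.int(floor(nf * transient_fraction) + 1L, nf)
  pip_ph <- which(phosphate_rows(top) & top$residue_name == "PIP")
  if (!length(pip_ph)) stop("no PIP2 lipids in topology")
  elev <- numeric(0); n_holo <- 0L
  for (t in use) {
    mf <- assign_leaflets(traj, t)
    plane <- mf$phosphate_plane_z[[mf$holo_leaflet]]
    sgn <- if (mf$holo_leaflet == "upper") 1 else -1
    lip_ids <- as.character(top$residue_number[pip_ph])
    in_holo <- mf$leaflet_of_lipid[lip_ids] == mf$holo_leaflet
    if (!any(in_holo)) next
    z <- traj$frames[[t]][pip_ph[in_holo], 3]
    elev <- c(elev, sgn * (z - plane))
    n_holo <- sum(in_holo)
  }
  if (!length(elev)) stop("no PIP2 in the holo leaflet")
  list(elevations = elev, mean = mean(elev), sd = stats::sd(elev),
       n_pip2 = n_holo)
}

min_image <- function(dx, L) dx - L * round(dx / L)

#' Radial distribution function between two atom selections
#'
#' `g(r)` from minimum-image pair distances, normalized per frame by the
#' spherical-shell volume `4 pi r^2 dr` and the ideal-gas pair density
#' `N_a N_b / V` (self-pairs excluded when the selections overlap), averaged
#' over frames.
#'
#' @param traj trajectory with a periodic box.
#' @param sel_a,sel_b integer atom-index vectors.
#' @param r_max histogram range (Angstroms), default 12; must not exceed half
#'   the smallest box edge.
#' @param bin_width bin width (Angstroms), default 0.1.
#' @return object of class `rdf_result`: `r_centers`, `g`, `n_pairs`,
#'   `bin_width`.
#' @export
rdf <- function(traj, sel_a, sel_b, r_max = 12, bin_width = 0.1) {
  if (!length(sel_a) || !length(sel_b)) stop("empty selection")
  if (is.null(traj$box)) stop("rdf requires a periodic box")
  L <- traj$box
  if (r_max > min(L) / 2) stop("r_max exceeds half the smallest box edge")
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  n_self <- length(intersect(sel_a, sel_b))
  n_pairs <- length(sel_a) * length(sel_b) - n_self
  if (n_pairs <= 0) stop("no distinct pairs between selections")
  V <- prod(L)
  for (t in seq_len(n_frames(traj))) {
    fr <- traj$frames[[t]]
    a <- fr[sel_a, , drop = FALSE]; b <- fr[sel_b, , drop = FALSE]
    dx <- min_image(outer(a[, 1], b[, 1], "-"), L[1])
    dy <- min_image(outer(a[, 2], b[, 2], "-"), L[2])
    dz <- min_image(outer(a[, 3], b[, 3], "-"), L[3])
    d <- sqrt(dx^2 + dy^2 + dz^2)
    if (n_self) d[cbind(match(intersect(sel_a, sel_b), sel_a),
                        match(intersect(sel_a, sel_b), sel_b))] <- Inf
    keep <- d > 0 & d < r_max
    if (any(keep))
      counts <- counts + tabulate(ceiling(d[keep] / bin_width), nbins = nb)
  }
  r_lo <- edges[-length(edges)]; r_hi <- edges[-1]
  shell_vol <- 4 / 3 * pi * (r_hi^3 - r_lo^3)
  ideal <- n_frames(traj) * n_pairs / V * shell_vol
  structure(list(r_centers = (r_lo + r_hi) / 2, g = counts / ideal,
                 n_pairs = n_pairs, bin_width = bin_width,
                 raw_counts = counts, n_frames = n_frames(traj)),
            class = "rdf_result")
}

#' PIP2-to-ATP coordination distance series
#'
#' Per frame, the minimum-image distance from each PIP2's named head-group
#' atom (by convention the 3-position inositol hydroxyl oxygen) to the ATP
#' gamma-phosphate atom, and the minimum over PIP2 molecules.
#'
#' @param traj trajectory containing PIP2 lipids and an ATP residue.
#' @param pip2_atom PIP2 atom name, default `"O3"`.
#' @param atp_atom ATP atom name, default `"PG"` (P-gamma).
#' @return list with `min_distance` (per frame, Angstroms) and `per_pip2`
#'   (frames x PIP2 matrix, columns named by lipid residue number).
#' @export
coordination_series <- function(traj, pip2_atom = "O3", atp_atom = "PG") {
  top <- traj$topology
  ip <- which(top$residue_name == "PIP" & top$name == pip2_atom)
  ia <- which(top$residue_name == "ATP" & top$name == atp_atom)
  if (!length(ia))
    stop("ATP atom '", atp_atom, "' absent; ATP atoms present: ",
         paste(top$name[top$residue_name == "ATP"], collapse = ", "))
  if (!length(ip))
    stop("PIP2 atom '", pip2_atom, "' absent; PIP2 atoms present: ",
         paste(unique(top$name[top$residue_name == "PIP"]), collapse = ", "))
  L <- traj$box
  per <- t(vapply(traj$frames, function(fr) {
    dvec <- sweep(fr[ip, , drop = FALSE], 2, fr[ia[1], ], "-")
    if (!is.null(L)) for (d in 1:3) dvec[, d] <- min_image(dvec[, d], L[d])
    sqrt(rowSums(dvec^2))
  }, numeric(length(ip))))
  if (length(ip) == 1L) per <- matrix(per, ncol = 1L)
  colnames(per) <- top$residue_number[ip]
  list(min_distance = apply(per, 1, min), per_pip2 = per)
}

#' Default membrane anchor-point residues
#'
#' The three anchor clusters of the catalytic subunit: C2 loops
#' (R349, R412, K413), the kinase N-lobe kalpha1-kalpha2 loop
#' (K723, K724, D725), and the C-lobe kalpha12 WIF motif
#' (W1057, I1058, F1059).
#'
#' @param chain chain id of the catalytic subunit.
#' @return data frame `anchor`, `chain`, `residue`.
#' @export
anchor_points <- function(chain = "A") {
  data.frame(
    anchor = rep(c("C2", "N-lobe", "C-lobe"), each = 3L),
    chain = chain,
    residue = c(349L, 412L, 413L, 723L, 724L, 725L, 1057L, 1058L, 1059L),
    stringsAsFactors = FALSE)
}
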