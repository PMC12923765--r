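#' Synthetic fixture generators
#'
#' These generators produce toy inputs carrying the statistical structure the
#' analysis stages assume: a two-state (telegraph) latch distance, residue
#' motions with a prescribed correlation matrix, a planar three-species
#' bilayer with planted anchor depths and PIP2 protrusion, somatic mutation
#' catalogs with planted co-occurring / mutually exclusive doublets, and
#' candidate pocket records straddling every screening boundary. All are
#' deterministic under a fixed seed.
#'
#' @name synthetic
NULL

#' Two-state latch simulation configuration
#'
#' @param n_frames number of frames.
#' @param dt frame spacing (ns).
#' @param bound_mean,released_mean well centres of the latch distance (Angstroms);
#'   defaults 3.5 and 12 mirror a formed salt bridge versus a released latch.
#' @param well_sd within-well SD (Angstroms).
#' @param switch_rate_on rate of released -> bound switching (per ns).
#' @param switch_rate_off rate of bound -> released switching (per ns).
#' @param seed RNG seed.
#' @return config list of class `latch_sim_config`.
#' @export
latch_sim_config <- function(n_frames = 5000L, dt = 0.2,
                             bound_mean = 3.5, released_mean = 12,
                             well_sd = 0.5,
                             switch_rate_on = 0.01, switch_rate_off = 0.01,
                             seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (bound_mean <= 0 || released_mean <= 0) stop("well means must be positive")
  if (released_mean <= bound_mean) stop("released_mean must exceed bound_mean")
  if (switch_rate_on < 0 || switch_rate_off < 0) stop("rates must be >= 0")
  if (well_sd < 0) stop("well_sd must be >= 0")
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 bound_mean = bound_mean, released_mean = released_mean,
                 well_sd = well_sd, switch_rate_on = switch_rate_on,
                 switch_rate_off = switch_rate_off, seed = as.integer(seed)),
            class = "latch_sim_config")
}

two_atom_topology <- function() {
  data.frame(serial = 1:2, name = "CA", residue_name = "GLY",
             chain_id = "A", residue_number = 1:2, element = "C",
             stringsAsFactors = FALSE)
}

#' Generate a telegraph-process latch trajectory
#'
#' Two pseudo-atoms whose separation follows a continuous-time two-state
#' Markov (telegraph) process sampled at the frame times: exponential waiting
#' times with the configured switching rates, within-state distances
#' Normal(state mean, well_sd) clipped to be positive. The process starts in
#' the bound state.
#'
#' @param cfg a [latch_sim_config()].
#' @return list with `trajectory` and `truth` (data frame `frame`, `time`,
#'   `state` in "bound"/"released") plus `occupancy_released`, the realised
#'   fraction of released frames.
#' @export
gen_latch_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "latch_sim_config"))
  set.seed(cfg$seed)
  times <- (seq_len(cfg$n_frames) - 1L) * cfg$dt
  total_t <- times[length(times)]
  # event-driven simulation of the telegraph process
  state <- integer(cfg$n_frames)  # 0 bound, 1 released
  cur <- 0L; t_cur <- 0; i <- 1L
  while (i <= cfg$n_frames) {
    rate <- if (cur == 0L) cfg$switch_rate_off else cfg$switch_rate_on
    wait <- if (rate > 0) stats::rexp(1L, rate) else Inf
    t_next <- t_cur + wait
    covered <- which(times >= t_cur & times < t_next)
    covered <- covered[covered >= i]
    if (length(covered)) {
      state[covered] <- cur
      i <- max(covered) + 1L
    }
    if (t_next > total_t && i > cfg$n_frames) break
    cur <- 1L - cur
    t_cur <- t_next
  }
  d <- stats::rnorm(cfg$n_frames,
                    mean = ifelse(state == 1L, cfg$released_mean, cfg$bound_mean),
                    sd = cfg$well_sd)
  d <- pmax(d, 1e-6)
  frames <- lapply(d, function(di)
    rbind(c(0, 0, 0), c(di, 0, 0)))
  traj <- trajectory(two_atom_topology(), frames, frame_times = times)
  truth <- data.frame(frame = seq_len(cfg$n_frames), time = times,
                      state = ifelse(state == 1L, "released", "bound"),
                      stringsAsFactors = FALSE)
  list(trajectory = traj, truth = truth,
       occupancy_released = mean(state == 1L))
}

#' Correlated-motion simulation configuration
#'
#' @param target_correlation symmetric positive-semidefinite matrix with unit
#'   diagonal; the node-node displacement correlation to plant.
#' @param n_frames number of frames.
#' @param displacement_sd scalar displacement SD (Angstroms).
#' @param base_geometry `n x 3` matrix of rest positions (Angstroms); default
#'   a 10-Angstrom-spaced line so nodes do not overlap.
#' @param seed RNG seed.
#' @return config list of class `correlation_sim_config`.
#' @export
correlation_sim_config <- function(target_correlation, n_frames = 2000L,
                                   displacement_sd = 1, base_geometry = NULL,
                                   seed = 1L) {
  C <- as.matrix(target_correlation)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-10)
    stop("target_correlation must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-10)
    stop("target_correlation must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target_correlation is not positive semidefinite; smallest eigenvalue ",
         format(min(ev)))
  n <- nrow(C)
  if (is.null(base_geometry))
    base_geometry <- cbind(10 * (seq_len(n) - 1), 0, 0)
  if (nrow(base_geometry) != n) stop("base_geometry must have one row per node")
  structure(list(n_nodes = n, n_frames = as.integer(n_frames),
                 target_correlation = C, displacement_sd = displacement_sd,
                 base_geometry = base_geometry, seed = as.integer(seed)),
            class = "correlation_sim_config")
}

#' Generate a trajectory with planted displacement correlations
#'
#' Per frame, scalar node displacements are drawn from a zero-mean
#' multivariate normal with the configured correlation (via the symmetric
#' matrix square root) and the same scalar is added to all three coordinates
#' of the node, so scalar-displacement correlations carry over exactly to the
#' 3-vector dot-product correlation estimator.
#'
#' @param cfg a [correlation_sim_config()].
#' @return a [trajectory()] with one CA pseudo-atom per node.
#' @export
gen_correlated_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "correlation_sim_config"))
  set.seed(cfg$seed)
  es <- eigen(cfg$target_correlation, symmetric = TRUE)
  sqrtC <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  z <- matrix(stats::rnorm(cfg$n_frames * cfg$n_nodes), cfg$n_frames)
  s <- cfg$displacement_sd * (z %*% sqrtC)       # n_frames x n_nodes
  frames <- lapply(seq_len(cfg$n_frames), function(t)
    cfg$base_geometry + s[t, ])                  # same scalar on x, y, z
  top <- data.frame(serial = seq_len(cfg$n_nodes), name = "CA",
                    residue_name = "GLY", chain_id = "A",
                    residue_number = seq_len(cfg$n_nodes), element = "C",
                    stringsAsFactors = FALSE)
  trajectory(top, frames)
}

#' Bilayer simulation configuration
#'
#' Defaults follow the study bilayer: 700 lipids of DOPC:DOPS:PIP2 at a
#' 28:6:1 molar ratio on a 153.5 x 153.5 Angstrom lateral cell, split evenly
#' between leaflets.
#'
#' @param total_lipids total lipid count.
#' @param molar_ratio positive integer triple PC:PS:PIP2.
#' @param leaflet_split fraction of each species in the upper leaflet.
#' @param lateral_box lateral cell lengths (Angstroms).
#' @param planted_anchor_depths named numeric: protein residue number ->
#'   signed depth (Angstroms) relative to the upper phosphate plane
#'   (negative = inserted).
#' @param planted_pip2_protrusion PIP2 phosphate elevation above the PC/PS
#'   phosphate plane (Angstroms).
#' @param n_frames number of frames.
#' @param jitter_sd per-frame Gaussian jitter SD on bead z (Angstroms).
#' @param leaflet_offset half bilayer thickness: phosphate planes sit at
#'   +/- this z (Angstroms).
#' @param atp_xyz optional coordinate triple for an ATP gamma-phosphate bead.
#' @param seed RNG seed.
#' @return config list of class `bilayer_sim_config`.
#' @export
bilayer_sim_config <- function(total_lipids = 700L, molar_ratio = c(28L, 6L, 1L),
                               leaflet_split = 0.5, lateral_box = c(153.5, 153.5),
                               planted_anchor_depths = numeric(),
                               planted_pip2_protrusion = 0,
                               n_frames = 100L, jitter_sd = 0.7,
                               leaflet_offset = 20, atp_xyz = NULL,
                               seed = 1L) {
  if (length(molar_ratio) != 3L || any(molar_ratio <= 0))
    stop("molar_ratio must be a positive triple")
  if (any(lateral_box <= 0)) stop("lateral_box must be positive")
  if (total_lipids < 2) stop("need at least 2 lipids")
  structure(list(total_lipids = as.integer(total_lipids),
                 molar_ratio = molar_ratio, leaflet_split = leaflet_split,
                 lateral_box = lateral_box,
                 planted_anchor_depths = planted_anchor_depths,
                 planted_pip2_protrusion = planted_pip2_protrusion,
                 n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 leaflet_offset = leaflet_offset, atp_xyz = atp_xyz,
                 seed = as.integer(seed)),
            class = "bilayer_sim_config")
}

#' Split a total into counts at a molar ratio
#'
#' Largest-remainder apportionment: exact when the total is divisible by the
#' ratio sum, otherwise rounded with the exact total preserved.
#'
#' @param total total count.
#' @param ratio positive numeric vector.
#' @return integer vector summing to `total`.
#' @export
ratio_counts <- function(total, ratio) {
  share <- total * ratio / sum(ratio)
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0) {
    order_rem <- order(share - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a planar pseudo-bilayer system
#'
#' Lipids are 3-bead pseudo-molecules (phosphate bead "P" at the leaflet
#' plane plus two tail beads toward the midplane) on a lattice; no energetics.
#' PIP2 phosphates are displaced outward by the planted protrusion. Protein
#' anchor beads (chain "A", atom "CB") are placed at the planted depths
#' relative to the upper leaflet's mean PC/PS phosphate plane, so the upper
#' leaflet is the holo (protein-bearing) leaflet.
#'
#' @param cfg a [bilayer_sim_config()].
#' @return list with `trajectory`, `composition` (named counts DOPC, DOPS,
#'   PIP2) and `truth` (planted depths/protrusion).
#' @export
gen_membrane_system <- function(cfg) {
  stopifnot(inherits(cfg, "bilayer_sim_config"))
  set.seed(cfg$seed)
  counts <- ratio_counts(cfg$total_lipids, cfg$molar_ratio)
  names(counts) <- c("DOPC", "DOPS", "PIP2")
  species <- rep(c("DPC", "DPS", "PIP"), counts)
  n_lip <- length(species)
  # split each species across leaflets so both leaflets carry all species
  leaflet <- integer(n_lip)
  per_species_upper <- round(counts * cfg$leaflet_split)
  idx_by_sp <- split(seq_len(n_lip), species)[unique(species)]
  sp_names <- c(DPC = "DOPC", DPS = "DOPS", PIP = "PIP2")
  for (sp in names(idx_by_sp)) {
    ii <- idx_by_sp[[sp]]
    k <- per_species_upper[[sp_names[[sp]]]]
    leaflet[ii[seq_len(min(k, length(ii)))]] <- 1L   # 1 upper, 0 lower
  }
  # lattice placement per leaflet
  place <- function(n, lx, ly) {
    side <- ceiling(sqrt(n))
    if (side < 1) return(matrix(numeric(0), ncol = 2))
    gx <- (seq_len(side) - 0.5) * lx / side
    gy <- (seq_len(side) - 0.5) * ly / side
    g <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n), , drop = FALSE]
    g
  }
  max_side <- ceiling(sqrt(max(sum(leaflet == 1L), sum(leaflet == 0L))))
  if (max_side > 0 && min(cfg$lateral_box) / max_side < 2)
    stop("lattice too small for lipid count: spacing below 2 Angstroms")
  xy <- matrix(0, n_lip, 2)
  for (lf in c(1L, 0L)) {
    ii <- which(leaflet == lf)
    ii <- sample(ii)                       # randomise species over sites
    xy[ii, ] <- place(length(ii), cfg$lateral_box[1], cfg$lateral_box[2])
  }
  z_plane <- ifelse(leaflet == 1L, cfg$leaflet_offset, -cfg$leaflet_offset)
  outward <- ifelse(leaflet == 1L, 1, -1)
  z_head0 <- z_plane + outward * ifelse(species == "PIP",
                                        cfg$planted_pip2_protrusion, 0)
  # topology: 3 beads per lipid, then protein anchors, then optional ATP
  lip_top <- data.frame(
    serial = seq_len(3L * n_lip),
    name = rep(c("P", "C2", "C3"), n_lip),
    residue_name = rep(species, each = 3L),
    chain_id = "M",
    residue_number = rep(seq_len(n_lip), each = 3L),
    element = rep(c("P", "C", "C"), n_lip),
    stringsAsFactors = FALSE)
  anchors <- cfg$planted_anchor_depths
  anchor_res <- as.integer(names(anchors))
  prot_top <- if (length(anchors)) data.frame(
    serial = 3L * n_lip + seq_along(anchors),
    name = "CB", residue_name = "ALA", chain_id = "A",
    residue_number = anchor_res, element = "C", stringsAsFactors = FALSE)
  atp_top <- if (!is.null(cfg$atp_xyz)) data.frame(
    serial = 3L * n_lip + length(anchors) + 1L,
    name = "PG", residue_name = "ATP", chain_id = "X",
    residue_number = 1L, element = "P", stringsAsFactors = FALSE)
  top <- rbind(lip_top, prot_top, atp_top)
  box <- c(cfg$lateral_box, 4 * cfg$leaflet_offset)
  n_at <- nrow(top)
  base <- matrix(0, n_at, 3)
  li <- seq_len(n_lip)
  base[3 * li - 2L, ] <- cbind(xy, z_head0)                       # P bead
  base[3 * li - 1L, ] <- cbind(xy, z_plane - outward * 5)          # tails
  base[3 * li, ]      <- cbind(xy, z_plane - outward * 10)
  if (length(anchors)) {
    ax <- cbind(cfg$lateral_box[1] / 2 + 5 * seq_along(anchors),
                cfg$lateral_box[2] / 2,
                cfg$leaflet_offset + unname(anchors))
    base[3L * n_lip + seq_along(anchors), ] <- ax
  }
  if (!is.null(cfg$atp_xyz))
    base[n_at, ] <- cfg$atp_xyz
  frames <- lapply(seq_len(cfg$n_frames), function(t) {
    fr <- base
    fr[, 3] <- fr[, 3] + stats::rnorm(n_at, sd = cfg$jitter_sd)
    fr
  })
  traj <- trajectory(top, frames, box = box)
  list(trajectory = traj, composition = counts,
       truth = list(anchor_depths = anchors,
                    pip2_protrusion = cfg$planted_pip2_protrusion,
                    leaflet = ifelse(leaflet == 1L, "upper", "lower")))
}

#' Mutation-catalog simulation configuration
#'
#' @param n_samples cohort size.
#' @param gene gene symbol.
#' @param position_frequencies named numeric: protein position -> marginal
#'   mutation probability per sample (in (0,1)).
#' @param planted_doublets data frame with columns `posA`, `posB`,
#'   `joint_mode` ("cooccur" or "exclusive") and `strength` in `[0,1]`.
#' @param vaf_distribution mean and sd of the (truncated-normal) VAF.
#' @param nonsense_fraction probability a generated record is a nonsense
#'   mutation rather than missense.
#' @param seed RNG seed.
#' @return config list of class `catalog_sim_config`.
#' @export
catalog_sim_config <- function(n_samples = 1000L, gene = "PIK3CA",
                               position_frequencies,
                               planted_doublets = NULL,
                               vaf_distribution = c(mean = 0.3, sd = 0.1),
                               nonsense_fraction = 0,
                               seed = 1L) {
  p <- position_frequencies
  if (is.null(names(p)) || any(p <= 0) || any(p >= 1))
    stop("position_frequencies must be named with values in (0,1)")
  if (!is.null(planted_doublets)) {
    need <- c("posA", "posB", "joint_mode", "strength")
    if (!all(need %in% names(planted_doublets)))
      stop("planted_doublets needs columns ", paste(need, collapse = ", "))
    ref <- c(planted_doublets$posA, planted_doublets$posB)
    if (!all(as.character(ref) %in% names(p)))
      stop("planted pairs must reference declared positions")
  }
  structure(list(n_samples = as.integer(n_samples), gene = gene,
                 position_frequencies = p, planted_doublets = planted_doublets,
                 vaf_distribution = vaf_distribution,
                 nonsense_fraction = nonsense_fraction, seed = as.integer(seed)),
            class = "catalog_sim_config")
}

#' Generate a MAF-like somatic mutation catalog
#'
#' Positions are per-sample Bernoulli draws at the configured marginal
#' frequencies. For each planted pair the two positions are drawn jointly
#' from a 2x2 distribution with the marginals preserved and the joint
#' probability moved toward `min(pA, pB)` (cooccur) or toward 0 (exclusive)
#' by the planted strength. VAFs are normal truncated to (0, 1].
#'
#' @param cfg a [catalog_sim_config()].
#' @return list with `catalog` (data frame: sample_id, gene,
#'   protein_position, protein_change, variant_class, vaf) and `truth`
#'   (planted pairs with their achieved joint probabilities).
#' @export
gen_mutation_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "catalog_sim_config"))
  set.seed(cfg$seed)
  p <- cfg$position_frequencies
  positions <- as.integer(names(p))
  n <- cfg$n_samples
  m <- matrix(0L, n, length(p), dimnames = list(NULL, names(p)))
  planted_pos <- character(0)
  truth <- NULL
  if (!is.null(cfg$planted_doublets)) {
    pd <- cfg$planted_doublets
    truth <- pd
    truth$p11 <- NA_real_
    for (k in seq_len(nrow(pd))) {
      a <- as.character(pd$posA[k]); b <- as.character(pd$posB[k])
      pa <- p[[a]]; pb <- p[[b]]
      indep <- pa * pb
      p11 <- if (pd$joint_mode[k] == "cooccur")
        indep + pd$strength[k] * (min(pa, pb) - indep)
      else indep * (1 - pd$strength[k])
      probs <- c(p11, pa - p11, pb - p11, 1 - pa - pb + p11)
      if (any(probs < -1e-12))
        stop("planted pair (", a, ",", b, ") leaves invalid joint probabilities")
      probs <- pmax(probs, 0)
      draw <- sample.int(4L, n, replace = TRUE, prob = probs)
      m[, a] <- as.integer(draw %in% c(1L, 2L))
      m[, b] <- as.integer(draw %in% c(1L, 3L))
      truth$p11[k] <- p11
      planted_pos <- c(planted_pos, a, b)
    }
  }
  for (j in setdiff(names(p), planted_pos))
    m[, j] <- stats::rbinom(n, 1L, p[[j]])
  idx <- which(m == 1L, arr.ind = TRUE)
  if (!nrow(idx)) {
    catalog <- data.frame(sample_id = character(0), gene = character(0),
                          protein_position = integer(0),
                          protein_change = character(0),
                          variant_class = character(0), vaf = numeric(0))
    return(list(catalog = catalog, truth = truth, indicator = m))
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pos <- positions[idx[, 2]]
  n_rec <- nrow(idx)
  vm <- cfg$vaf_distribution[["mean"]]; vs <- cfg$vaf_distribution[["sd"]]
  vaf <- stats::rnorm(n_rec, vm, vs)
  bad <- which(vaf <= 0 | vaf > 1)
  while (length(bad)) {
    vaf[bad] <- stats::rnorm(length(bad), vm, vs)
    bad <- bad[vaf[bad] <= 0 | vaf[bad] > 1]
  }
  nonsense <- stats::runif(n_rec) < cfg$nonsense_fraction
  catalog <- data.frame(
    sample_id = sprintf("S%05d", idx[, 1]),
    gene = cfg$gene,
    protein_position = pos,
    protein_change = ifelse(nonsense, paste0("Q", pos, "*"),
                            paste0("A", pos, "V")),
    variant_class = ifelse(nonsense, "nonsense", "missense"),
    vaf = vaf,
    stringsAsFactors = FALSE)
  list(catalog = catalog, truth = truth, indicator = m)
}

#' Generate candidate pocket records spanning the screening boundaries
#'
#' The first six records are constructed to sit on each side of every filter
#' boundary (druggability probability 0.5, the 14-residue size threshold,
#' and single-domain versus interdomain lining); further records are random.
#'
#' @param n number of records (>= 0).
#' @param seed RNG seed.
#' @param annotation a [domain_annotation()] the lining residues are drawn
#'   from; default [p110a_domains()].
#' @return data frame of pocket records (`pocket_id`,
#'   `druggability_probability`, `lining_residues` as semicolon-joined
#'   `chain:resnum`, `volume`, `source_frame`).
#' @export
gen_pocket_records <- function(n, seed = 1L, annotation = p110a_domains()) {
  if (n < 0) stop("n must be >= 0")
  set.seed(seed)
  empty <- data.frame(pocket_id = character(0),
                      druggability_probability = numeric(0),
                      lining_residues = character(0), volume = numeric(0),
                      source_frame = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  lining <- function(domains, k) {
    per <- ratio_counts(k, rep(1, length(domains)))
    res <- unlist(lapply(seq_along(domains), function(i) {
      row <- annotation[annotation$domain == domains[i], ]
      seq(row$start, length.out = per[i])
    }))
    ch <- annotation$chain[1]
    paste(paste0(ch, ":", res), collapse = ";")
  }
  fixed <- data.frame(
    pocket_id = paste0("P", 1:6),
    druggability_probability = c(0.6, 0.5, 0.7, 0.7, 0.8, 0.45),
    lining_residues = c(
      lining("kinase", 20),          # passes everything
      lining("kinase", 20),          # p = 0.5 exactly -> rejected
      lining("kinase", 13),          # too small
      lining("kinase", 14),          # at the size boundary -> retained
      lining(c("C2", "helical"), 20),# 50/50 interdomain split
      lining("helical", 18)),        # p below threshold
    volume = c(450, 430, 180, 210, 520, 400),
    source_frame = 1:6,
    stringsAsFactors = FALSE)
  if (n <= 6) return(fixed[seq_len(n), , drop = FALSE])
  extra_n <- n - 6L
  doms <- annotation$domain
  extra <- data.frame(
    pocket_id = paste0("P", 7:n),
    druggability_probability = stats::runif(extra_n, 0.2, 0.9),
    lining_residues = vapply(seq_len(extra_n), function(i) {
      k <- sample(8:24, 1)
      d <- sample(doms, sample(1:2, 1))
      lining(d, k)
    }, character(1)),
    volume = stats::runif(extra_n, 100, 700),
    source_frame = 7:n,
    stringsAsFactors = FALSE)
  rbind(fixed, extra)
}

#' Write a mutation catalog as a MAF-like TSV
#' @param catalog catalog data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) write_table(catalog, path, "tsv")

#' Read a MAF-like TSV mutation catalog
#' @param path TSV with columns sample_id, gene, protein_position,
#'   protein_change, variant_class, vaf.
#' @return catalog data frame.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "protein_position", "variant_class", "vaf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog lacks columns: ", paste(miss, collapse = ", "))
  df
}
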