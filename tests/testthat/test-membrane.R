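toy_bilayer <- function(pip_shift = 0, protein_z = NULL) {
  # 4 lipids: DPC up, DPS up, DPC down, PIP down(+shift applied to PIP z)
  species <- c("DPC", "DPS", "DPC", "PIP")
  zs <- c(20, 20, -20, -20 - pip_shift)
  top <- do.call(rbind, lapply(seq_along(species), function(i)
    data.frame(serial = 3 * i - 2:0, name = c("P", "C2", "C3"),
               residue_name = species[i], chain_id = "M", residue_number = i,
               element = c("P", "C", "C"), stringsAsFactors = FALSE)))
  coords <- do.call(rbind, lapply(seq_along(species), function(i) {
    s <- sign(zs[i])
    rbind(c(10 * i, 0, zs[i]), c(10 * i, 0, zs[i] - s * 5),
          c(10 * i, 0, zs[i] - s * 10))
  }))
  if (!is.null(protein_z)) {
    top <- rbind(top, data.frame(serial = nrow(top) + 1L, name = "CB",
                                 residue_name = "ALA", chain_id = "A",
                                 residue_number = 100L, element = "C",
                                 stringsAsFactors = FALSE))
    coords <- rbind(coords, c(5, 5, protein_z))
  }
  trajectory(top, list(coords), box = c(60, 60, 80))
}

test_that("leaflet assignment finds planes, midplane and the holo leaflet", {
  mf <- assign_leaflets(toy_bilayer(protein_z = 18))
  expect_equal(unname(mf$phosphate_plane_z), c(20, -20))
  expect_equal(mf$midplane_z, 0)
  expect_equal(mf$holo_leaflet, "upper")
  expect_equal(unname(mf$leaflet_of_lipid), c("upper", "upper", "lower", "lower"))
  mf2 <- assign_leaflets(toy_bilayer(protein_z = -15))
  expect_equal(mf2$holo_leaflet, "lower")
})

test_that("PIP2 phosphates do not move the reference plane", {
  mf <- assign_leaflets(toy_bilayer(pip_shift = 3, protein_z = 18))
  expect_equal(unname(mf$phosphate_plane_z["lower"]), -20)
})

test_that("all phosphates on one side is rejected", {
  tb <- toy_bilayer()
  up <- tb$frames[[1]]; up[, 3] <- abs(up[, 3])
  expect_error(assign_leaflets(trajectory(tb$topology, list(up), box = tb$box)),
               "one side")
})

test_that("planted anchor depths are recovered within 0.3 A", {
  mem <- gen_membrane_system(bilayer_sim_config(
    total_lipids = 140, n_frames = 300,
    planted_anchor_depths = c("349" = -4, "1057" = 5),
    seed = 61))
  prof <- depth_profile(mem$trajectory,
                        data.frame(chain = "A", residue = c(349L, 1057L)))
  expect_lt(abs(prof$mean_depth[1] - (-4)), 0.3)
  expect_lt(abs(prof$mean_depth[2] - 5), 0.3)
  # a bead planted at the plane reads ~0
  mem0 <- gen_membrane_system(bilayer_sim_config(
    total_lipids = 140, n_frames = 300,
    planted_anchor_depths = c("726" = 0), seed = 62))
  p0 <- depth_profile(mem0$trajectory, data.frame(chain = "A", residue = 726L))
  expect_lt(abs(p0$mean_depth), 0.3)
})

test_that("depth and protrusion are invariant under a global z shift", {
  mem <- gen_membrane_system(bilayer_sim_config(
    total_lipids = 70, n_frames = 20, planted_anchor_depths = c("349" = -3),
    planted_pip2_protrusion = 2, seed = 63))
  shifted <- trajectory(mem$trajectory$topology,
                        lapply(mem$trajectory$frames, function(fr) {
                          fr[, 3] <- fr[, 3] + 13.7; fr
                        }), box = mem$trajectory$box)
  p1 <- depth_profile(mem$trajectory, data.frame(chain = "A", residue = 349L))
  p2 <- depth_profile(shifted, data.frame(chain = "A", residue = 349L))
  expect_equal(p2$mean_depth, p1$mean_depth, tolerance = 1e-9)
  e1 <- pip2_protrusion(mem$trajectory)$mean
  e2 <- pip2_protrusion(shifted)$mean
  expect_equal(e2, e1, tolerance = 1e-9)
})

test_that("planted PIP2 protrusion (the ~3 A mechanism) is recovered", {
  mem3 <- gen_membrane_system(bilayer_sim_config(
    total_lipids = 140, n_frames = 300,
    planted_anchor_depths = c("349" = -2),
    planted_pip2_protrusion = 3, seed = 64))
  pr <- pip2_protrusion(mem3$trajectory)
  expect_lt(abs(pr$mean - 3), 0.3)
  mem0 <- gen_membrane_system(bilayer_sim_config(
    total_lipids = 140, n_frames = 300,
    planted_anchor_depths = c("349" = -2),
    planted_pip2_protrusion = 0, seed = 65))
  expect_lt(abs(pip2_protrusion(mem0$trajectory)$mean), 0.3)
})

test_that("only holo-leaflet PIP2 enters the protrusion distribution", {
  mem <- gen_membrane_system(bilayer_sim_config(
    total_lipids = 70, n_frames = 5, planted_anchor_depths = c("349" = -2),
    planted_pip2_protrusion = 3, seed = 66))
  pr <- pip2_protrusion(mem$trajectory)
  n_pip_total <- sum(mem$trajectory$topology$residue_name == "PIP" &
                       mem$trajectory$topology$name == "P")
  expect_lt(pr$n_pip2, n_pip_total)   # apo-leaflet PIP2 excluded
  expect_equal(length(pr$elevations), pr$n_pip2 * 5)
})

test_that("RDF of an ideal gas is flat at 1 and conserves pair counts", {
  set.seed(67)
  n_at <- 600L; L <- 34
  top <- data.frame(serial = 1:n_at, name = "AR", residue_name = "GAS",
                    chain_id = "G", residue_number = 1:n_at, element = "C",
                    stringsAsFactors = FALSE)
  frames <- lapply(1:120, function(t) matrix(runif(3 * n_at, 0, L), n_at))
  traj <- trajectory(top, frames, box = c(L, L, L))
  r <- rdf(traj, 1:n_at, 1:n_at, r_max = 8.5, bin_width = 0.2)
  sel <- r$r_centers > 2.5 & r$r_centers < 8.5
  expect_lt(max(abs(r$g[sel] - 1)), 0.05)
  # conservation: integral of g * 4 pi r^2 rho dr equals the raw pair count
  rho <- r$n_pairs / (L^3)
  integral <- sum(r$g * 4 * pi * r$r_centers^2 * r$bin_width) * rho *
    length(frames)
  expect_lt(abs(integral - sum(r$raw_counts)) / sum(r$raw_counts), 0.01)
  # doubled bin width conserves the same total count
  r2 <- rdf(traj, 1:n_at, 1:n_at, r_max = 8.5, bin_width = 0.4)
  expect_lt(abs(sum(r2$raw_counts) - sum(r$raw_counts)) / sum(r$raw_counts),
            0.01)
  expect_error(rdf(traj, 1:5, 1:5, r_max = 20), "half")
  expect_error(rdf(traj, integer(0), 1:5), "empty")
})

test_that("RDF of a fixed pair occupies the single bin containing d", {
  top <- data.frame(serial = 1:2, name = "P", residue_name = "GAS",
                    chain_id = "G", residue_number = 1:2, element = "P",
                    stringsAsFactors = FALSE)
  traj <- trajectory(top, list(rbind(c(0, 0, 0), c(5.03, 0, 0))),
                     box = c(40, 40, 40))
  r <- rdf(traj, 1L, 2L, r_max = 10, bin_width = 0.1)
  occ <- which(r$raw_counts > 0)
  expect_length(occ, 1L)
  expect_true(r$r_centers[occ] > 4.95 && r$r_centers[occ] < 5.15)
})

test_that("coordination series reports min distance over PIP2 molecules", {
  mk <- function(pip_xyz) {
    n_pip <- nrow(pip_xyz)
    top <- rbind(
      do.call(rbind, lapply(seq_len(n_pip), function(i)
        data.frame(serial = i, name = "O3", residue_name = "PIP",
                   chain_id = "M", residue_number = i, element = "O",
                   stringsAsFactors = FALSE))),
      data.frame(serial = n_pip + 1L, name = "PG", residue_name = "ATP",
                 chain_id = "X", residue_number = 1L, element = "P",
                 stringsAsFactors = FALSE))
    trajectory(top, list(rbind(pip_xyz, c(0, 0, 0))), box = c(60, 60, 60))
  }
  one <- coordination_series(mk(matrix(c(5, 0, 0), 1)))
  expect_equal(one$min_distance, 5)
  two <- coordination_series(mk(rbind(c(6, 0, 0), c(0, 9, 0))))
  expect_equal(two$min_distance, 6)
  expect_equal(dim(two$per_pip2), c(1L, 2L))
  expect_error(coordination_series(mk(matrix(c(5, 0, 0), 1)),
                                   atp_atom = "PB"), "PB")
})

test_that("an approach trajectory yields a monotone-decreasing series", {
  n_pip <- 1L
  top <- rbind(
    data.frame(serial = 1L, name = "O3", residue_name = "PIP",
               chain_id = "M", residue_number = 1L, element = "O",
               stringsAsFactors = FALSE),
    data.frame(serial = 2L, name = "PG", residue_name = "ATP",
               chain_id = "X", residue_number = 1L, element = "P",
               stringsAsFactors = FALSE))
  ds <- seq(10, 5, length.out = 20)
  frames <- lapply(ds, function(d) rbind(c(d, 0, 0), c(0, 0, 0)))
  cs <- coordination_series(trajectory(top, frames, box = c(50, 50, 50)))
  expect_equal(cs$min_distance, ds)
  expect_true(all(diff(cs$min_distance) < 0))
})
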