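#' Optimal superposition by the Kabsch algorithm
#'
#' Least-squares proper rotation and translation mapping `mobile` onto
#' `reference` over `fit_indices`, with reflection correction (determinant
#' forced to +1). RMSD is computed over the fit set after the transform.
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstroms).
#' @param fit_indices atom indices used for the fit (default: all).
#' @return object of class `superpose_result`: `rotation` (3x3, proper),
#'   `translation` (length-3), `rmsd` (Angstroms). Transformed coordinates
#'   are `mobile %*% rotation + translation` (rows).
#' @export
superpose_kabsch <- function(mobile, reference, fit_indices = NULL) {
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3L) stop("need at least 3 fit atoms")
  A <- mobile[fit_indices, , drop = FALSE]
  B <- reference[fit_indices, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("fit sets differ in length")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv_a <- svd(A0)$d
  if (sv_a[2] < 1e-10 * max(sv_a[1], 1))   # rank < 2: collinear point set
    stop("degenerate (collinear) fit geometry")
  H <- crossprod(A0, B0)                       # 3x3
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # row-vector convention
  t_vec <- cb - as.numeric(ca %*% R)
  fitted <- sweep(A %*% R, 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superpose_result")
}

apply_superpose <- function(coords, sp) {
  sweep(coords %*% sp$rotation, 2, sp$translation, "+")
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is superposed on the reference over `fit_indices`, then RMSD
#' is measured over `measure_indices`. Distinct fit and measure sets enable
#' "superpose on the catalytic subunit, measure the regulatory subunit".
#'
#' @param traj trajectory.
#' @param reference_frame 1-based frame index of the reference.
#' @param fit_indices atom indices for the superposition.
#' @param measure_indices atom indices for the RMSD (default `fit_indices`).
#' @return numeric RMSD per frame (Angstroms).
#' @export
rmsd_series <- function(traj, reference_frame = 1L, fit_indices = NULL,
                        measure_indices = NULL) {
  ref <- traj$frames[[reference_frame]]
  if (is.null(fit_indices)) fit_indices <- seq_len(n_atoms(traj))
  if (is.null(measure_indices)) measure_indices <- fit_indices
  vapply(traj$frames, function(fr) {
    sp <- superpose_kabsch(fr, ref, fit_indices)
    moved <- apply_superpose(fr[measure_indices, , drop = FALSE], sp)
    sqrt(mean(rowSums((moved - ref[measure_indices, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Root-mean-square fluctuation profile
#'
#' When `fit_indices` is given, all frames are iteratively superposed onto
#' the running mean structure until the mean moves by less than `tol`
#' (max 20 iterations; non-convergence warns and proceeds). With
#' `fit_indices = NULL` the trajectory is taken as pre-aligned and no
#' fitting is done. `RMSF_i = sqrt(mean_t |r_i(t) - mean_r_i|^2)`; with
#' `group_by_residue` the atomic values are averaged per residue.
#'
#' @param traj trajectory (post-transient frames only; subset first).
#' @param fit_indices atom indices for the superposition, or `NULL`.
#' @param group_by_residue average per residue (default TRUE).
#' @param tol mean-structure convergence threshold (Angstroms).
#' @return data frame `chain`, `residue`, `rmsf` (per residue), or with an
#'   `atom` column when `group_by_residue = FALSE`.
#' @export
rmsf_profile <- function(traj, fit_indices = NULL, group_by_residue = TRUE,
                         tol = 1e-6) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  frames <- traj$frames
  if (!is.null(fit_indices)) {
    mean_s <- frames[[1]]
    for (it in seq_len(20L)) {
      frames <- lapply(frames, function(fr)
        apply_superpose(fr, superpose_kabsch(fr, mean_s, fit_indices)))
      new_mean <- Reduce(`+`, frames) / length(frames)
      delta <- sqrt(max(rowSums((new_mean - mean_s)^2)))
      mean_s <- new_mean
      if (delta < tol) break
    }
    if (delta >= tol)
      warning("mean structure not converged after 20 iterations (delta = ",
              format(delta), " A); proceeding with last mean")
  }
  mean_s <- Reduce(`+`, frames) / length(frames)
  msd <- Reduce(`+`, lapply(frames, function(fr) rowSums((fr - mean_s)^2))) /
    length(frames)
  rmsf <- sqrt(msd)
  top <- traj$topology
  if (!group_by_residue)
    return(data.frame(chain = top$chain_id, residue = top$residue_number,
                      atom = top$name, rmsf = rmsf, stringsAsFactors = FALSE))
  key <- paste(top$chain_id, top$residue_number)
  agg <- tapply(rmsf, key, mean)
  first <- !duplicated(key)
  ord_key <- key[first]
  data.frame(chain = top$chain_id[first], residue = top$residue_number[first],
             rmsf = as.numeric(agg[ord_key]), stringsAsFactors = FALSE)
}

#' Pairwise-RMSD ensemble clustering with a medoid representative
#'
#' Computes the all-pairs optimally-superposed RMSD matrix over
#' `fit_indices`, clusters by average-linkage agglomeration cut at the RMSD
#' `cutoff`, and reports the medoid (minimum summed RMSD to its cluster) of
#' the most populated cluster as the representative conformation. Frames are
#' strided down to at most `max_cluster_frames` before clustering; ties are
#' broken by the lowest frame index.
#'
#' @param traj trajectory.
#' @param fit_indices atom indices for superposition (default: all).
#' @param cutoff linkage cut height (Angstroms), default 2.0.
#' @param max_cluster_frames stride bound, default 500.
#' @return object of class `cluster_result`: `labels` (per clustered frame),
#'   `frame_index` (original indices of clustered frames), `cluster_sizes`,
#'   `representative_frame` (original index), `linkage_cutoff`, `stride`.
#' @export
cluster_frames <- function(traj, fit_indices = NULL, cutoff = 2.0,
                           max_cluster_frames = 500L) {
  nf <- n_frames(traj)
  stride <- max(1L, ceiling(nf / max_cluster_frames))
  idx <- seq(1L, nf, by = stride)
  m <- length(idx)
  if (m == 1L)
    return(structure(list(labels = 1L, frame_index = idx,
                          cluster_sizes = 1L, representative_frame = idx[1],
                          linkage_cutoff = cutoff, stride = stride),
                     class = "cluster_result"))
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    r <- superpose_kabsch(traj$frames[[idx[j]]], traj$frames[[idx[i]]],
                          fit_indices)$rmsd
    D[i, j] <- r; D[j, i] <- r
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- stats::cutree(hc, h = cutoff)
  sizes <- tabulate(labels)
  biggest <- which(sizes == max(sizes))
  # tie between equally populated clusters: the one containing the earliest frame
  if (length(biggest) > 1L)
    biggest <- biggest[which.min(vapply(biggest, function(b)
      min(which(labels == b)), integer(1)))]
  members <- which(labels == biggest)
  med <- if (length(members) == 1L) members else
    members[which.min(rowSums(D[members, members, drop = FALSE]))]
  structure(list(labels = labels, frame_index = idx, cluster_sizes = sizes,
                 representative_frame = idx[med], linkage_cutoff = cutoff,
                 stride = stride),
            class = "cluster_result")
}

#' Backbone atom indices of a trajectory
#' @param traj trajectory.
#' @return integer indices of N, CA, C, O atoms.
#' @export
backbone_indices <- function(traj)
  which(traj$topology$name %in% c("N", "CA", "C", "O"))
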