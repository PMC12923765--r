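#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
KB_KCAL <- 0.0019872041

#' Two-dimensional potential of mean force over distance coordinates
#'
#' Histograms the aligned post-transient samples of two distance series on a
#' regular grid and Boltzmann-inverts the bin probabilities:
#' `dG(i,j) = -kT log(count(i,j)/n)`, shifted so the minimum over occupied
#' bins is exactly 0. Unoccupied bins are undefined (`NA`), not capped.
#'
#' @param s1,s2 [distance_series()] of equal length with identical
#'   post-transient windows (axes D1 and D2).
#' @param bin_width bin width on both axes (Angstroms), default 0.5.
#' @param temperature temperature (K), default 310.
#' @return object of class `pmf_grid`: `d1_edges`, `d2_edges`, `counts`,
#'   `free_energy` (kcal/mol, `NA` where unoccupied), `kT`, `n_samples`.
#' @export
compute_pmf2d <- function(s1, s2, bin_width = 0.5, temperature = 310) {
  if (length(s1$values) != length(s2$values))
    stop("series have different lengths")
  if (s1$transient_cut_frame != s2$transient_cut_frame)
    stop("series have different transient windows")
  if (bin_width <= 0) stop("bin_width must be positive")
  x <- analyzed_values(s1); y <- analyzed_values(s2)
  n <- length(x)
  if (n == 0) stop("no samples")
  edges_for <- function(v) {
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling(max(v) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    seq(lo, hi, by = bin_width)
  }
  d1_edges <- edges_for(x); d2_edges <- edges_for(y)
  ix <- findInterval(x, d1_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, d2_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(d1_edges) - 1L, length(d2_edges) - 1L)
  tab <- table(ix, iy)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  kT <- KB_KCAL * temperature
  fe <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0
  fe[occ] <- -kT * log(counts[occ] / n)
  fe <- fe - min(fe, na.rm = TRUE)
  structure(list(d1_edges = d1_edges, d2_edges = d2_edges, counts = counts,
                 free_energy = fe, kT = kT, n_samples = n),
            class = "pmf_grid")
}

#' Marginal 1D free-energy profile of a PMF grid
#'
#' Sums the bin probabilities over the other axis, Boltzmann-inverts, and
#' re-shifts to a minimum of 0.
#'
#' @param grid a `pmf_grid`.
#' @param axis 1 (profile along D1) or 2 (along D2).
#' @return list with `edges`, `centers`, `counts`, `free_energy`.
#' @export
marginal_pmf <- function(grid, axis = 1) {
  stopifnot(inherits(grid, "pmf_grid"), axis %in% c(1, 2))
  cnt <- if (axis == 1) rowSums(grid$counts) else colSums(grid$counts)
  edges <- if (axis == 1) grid$d1_edges else grid$d2_edges
  fe <- rep(NA_real_, length(cnt))
  occ <- cnt > 0
  fe[occ] <- -grid$kT * log(cnt[occ] / grid$n_samples)
  fe <- fe - min(fe, na.rm = TRUE)
  list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
       counts = cnt, free_energy = fe)
}

#' Export a PMF grid as a long-format table
#'
#' One row per bin: `d1_center`, `d2_center`, `count`, `dG` (empty where the
#' bin is unoccupied).
#'
#' @param grid a `pmf_grid`.
#' @return data frame.
#' @export
pmf_as_table <- function(grid) {
  c1 <- (grid$d1_edges[-1] + grid$d1_edges[-length(grid$d1_edges)]) / 2
  c2 <- (grid$d2_edges[-1] + grid$d2_edges[-length(grid$d2_edges)]) / 2
  data.frame(d1_center = rep(c1, times = length(c2)),
             d2_center = rep(c2, each = length(c1)),
             count = as.integer(grid$counts),
             dG = as.numeric(grid$free_energy))
}
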