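#' Define an interface latch
#'
#' A latch is a named residue-pair reaction coordinate: the distance between
#' two atom selections, with a formation cutoff. Charged pairs conventionally
#' use `sidechain-charge-group` selections with minimum-distance aggregation;
#' backbone-type pairs use `single-atom:CA`.
#'
#' @param name latch label, e.g. `"K379(nSH2)-E545(HD)"`.
#' @param sel_a,sel_b [residue_selector()]s for the two partners.
#' @param contact_cutoff formation cutoff (Angstroms); distances at or below
#'   it count the latch as formed. Default 4.0.
#' @return object of class `latch_definition`.
#' @export
latch_definition <- function(name, sel_a, sel_b, contact_cutoff = 4.0) {
  stopifnot(inherits(sel_a, "residue_selector"),
            inherits(sel_b, "residue_selector"))
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  structure(list(name = name, sel_a = sel_a, sel_b = sel_b,
                 contact_cutoff = contact_cutoff),
            class = "latch_definition")
}

set_distance <- function(fr, ia, ib) {
  a <- fr[ia, , drop = FALSE]
  b <- fr[ib, , drop = FALSE]
  if (isTRUE(attr(ia, "centroid"))) a <- matrix(colMeans(a), 1)
  if (isTRUE(attr(ib, "centroid"))) b <- matrix(colMeans(b), 1)
  # min over all cross pairs
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Per-frame latch distance series
#'
#' The per-frame value is the minimum pairwise distance between the two atom
#' sets (centroid selections contribute their virtual site). No periodic
#' imaging is applied: these are protein-internal distances.
#'
#' @param traj trajectory.
#' @param latch a [latch_definition()].
#' @return object of class `distance_series` with fields `latch`, `values`
#'   (Angstroms per frame), `frame_times`, `transient_cut_frame` (frames
#'   before and including this index are excluded from statistics; 0 = none).
#' @export
distance_series <- function(traj, latch) {
  ia <- resolve_selection(traj, latch$sel_a)
  ib <- resolve_selection(traj, latch$sel_b)
  vals <- vapply(traj$frames, set_distance, numeric(1), ia = ia, ib = ib)
  structure(list(latch = latch, values = vals,
                 frame_times = traj$frame_times, transient_cut_frame = 0L),
            class = "distance_series")
}

#' Exclude the initial transient from a distance series
#'
#' Marks the equilibration window so statistics skip it; raw values are kept.
#' The cut is given either as a fraction of frames or, when frame times are
#' present, as a time in ns (the study convention is to discard the first
#' 200 ns of a 1 microsecond run, i.e. fraction 0.2).
#'
#' @param series a [distance_series()].
#' @param fraction fraction of frames to drop, in `[0, 1)`.
#' @param time alternative: drop all frames with time <= `time` ns.
#' @return the series with `transient_cut_frame` set.
#' @export
exclude_transient <- function(series, fraction = NULL, time = NULL) {
  n <- length(series$values)
  if (!is.null(time)) {
    if (is.null(series$frame_times))
      stop("series has no frame times; use fraction")
    cut <- sum(series$frame_times <= time)
  } else {
    if (is.null(fraction)) stop("give fraction or time")
    if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
    cut <- floor(n * fraction)
  }
  if (cut >= n) stop("transient cut removes every frame")
  series$transient_cut_frame <- as.integer(cut)
  series
}

analyzed_values <- function(series) {
  series$values[(series$transient_cut_frame + 1L):length(series$values)]
}

#' Occupancy and distribution summary of a latch distance
#'
#' Statistics are computed over post-transient frames; `formed_fraction` is
#' the fraction of those frames at or below the latch cutoff. `initial_value`
#' is the frame-1 distance (the simulation starting point, pre-transient by
#' definition).
#'
#' @param series a [distance_series()].
#' @return data frame row: latch, mean, sd, median, q05, q95,
#'   formed_fraction, initial_value, n_frames.
#' @export
occupancy_summary <- function(series) {
  v <- analyzed_values(series)
  if (!length(v)) stop("no post-transient frames")
  q <- unname(stats::quantile(v, c(0.05, 0.5, 0.95), type = 7))
  data.frame(
    latch = series$latch$name,
    mean = mean(v), sd = stats::sd(v),
    median = q[2], q05 = q[1], q95 = q[3],
    formed_fraction = mean(v <= series$latch$contact_cutoff),
    initial_value = series$values[1],
    n_frames = length(v),
    stringsAsFactors = FALSE)
}

#' Standard PI3K-alpha interface latch set
#'
#' The salt-bridge and packing pairs followed at the nSH2/helical/C2/kinase
#' interfaces: K379(nSH2)-545(HD) (reaction coordinate D1),
#' F934(KD)-K942(KD) (D2), 345(nSH2)-K942(KD), 453(C2)-K942(KD),
#' 453(C2)-{K567,R574,K575}(iSH2), 93(ABD)-E710(KD), 93(ABD)-F119(ABD),
#' 1043-W1051 (KD), Q809-G946 (KD), and R88(ABD)-{D746,D743}(KD).
#' Charged partners use charge-group atoms; aromatic/backbone partners use
#' CA. `chain_catalytic`/`chain_regulatory` name the p110a and p85a chains.
#'
#' @param chain_catalytic chain id of p110a.
#' @param chain_regulatory chain id of p85a.
#' @param contact_cutoff formation cutoff (Angstroms).
#' @return list of [latch_definition()]s.
#' @export
pi3k_latches <- function(chain_catalytic = "A", chain_regulatory = "B",
                         contact_cutoff = 4.0) {
  cg <- function(ch, res) residue_selector(ch, res, "sidechain-charge-group")
  ca <- function(ch, res) residue_selector(ch, res, "single-atom:CA")
  A <- chain_catalytic; B <- chain_regulatory
  defs <- list(
    list("K379(nSH2)-545(HD)",  cg(B, 379),  cg(A, 545)),
    list("F934(KD)-K942(KD)",   ca(A, 934),  ca(A, 942)),
    list("345(nSH2)-K942(KD)",  cg(B, 345),  cg(A, 942)),
    list("453(C2)-K942(KD)",    cg(A, 453),  cg(A, 942)),
    list("453(C2)-K567(iSH2)",  cg(A, 453),  cg(B, 567)),
    list("453(C2)-R574(iSH2)",  cg(A, 453),  cg(B, 574)),
    list("453(C2)-K575(iSH2)",  cg(A, 453),  cg(B, 575)),
    list("93(ABD)-E710(KD)",    cg(A, 93),   cg(A, 710)),
    list("93(ABD)-F119(ABD)",   ca(A, 93),   ca(A, 119)),
    list("1043(KD)-W1051(KD)",  ca(A, 1043), ca(A, 1051)),
    list("Q809(KD)-G946(KD)",   ca(A, 809),  ca(A, 946)),
    list("R88(ABD)-D746(KD)",   cg(A, 88),   cg(A, 746)),
    list("R88(ABD)-D743(KD)",   cg(A, 88),   cg(A, 743)))
  lapply(defs, function(d)
    latch_definition(d[[1]], d[[2]], d[[3]], contact_cutoff))
}
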