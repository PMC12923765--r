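#' Pocket screening configuration
#'
#' The cryptic-pocket screen retains a candidate iff its druggability
#' probability strictly exceeds `min_probability` (default 0.5), it has at
#' least `min_residues` lining residues (default 14), and a single domain
#' contributes at least `interdomain_max_share` of the lining (default 0.5;
#' pockets where no domain dominates are classed interdomain-spanning and
#' removed). Optionally, pockets whose dominant domain is in
#' `exclude_domains` (e.g. cavities within ABD, C2 or nSH2) are removed.
#'
#' @param min_probability strict lower bound on druggability probability.
#' @param min_residues minimum lining-residue count.
#' @param interdomain_max_share minimum dominant-domain share.
#' @param domain_annotation a [domain_annotation()].
#' @param exclude_domains character vector of dominant domains to drop.
#' @return config list of class `pocket_filter_config`.
#' @export
pocket_filter_config <- function(min_probability = 0.5, min_residues = 14L,
                                 domain_annotation = p110a_domains(),
                                 interdomain_max_share = 0.5,
                                 exclude_domains = character()) {
  if (min_probability < 0 || min_probability > 1)
    stop("min_probability must be in [0,1]")
  if (min_residues < 1) stop("min_residues must be >= 1")
  structure(list(min_probability = min_probability,
                 min_residues = as.integer(min_residues),
                 interdomain_max_share = interdomain_max_share,
                 domain_annotation = domain_annotation,
                 exclude_domains = exclude_domains),
            class = "pocket_filter_config")
}

parse_lining <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  cr <- strsplit(parts, ":", fixed = TRUE)
  data.frame(chain = vapply(cr, `[`, character(1), 1),
             residue = as.integer(vapply(cr, `[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

#' Screen candidate pocket records
#'
#' Applies the cryptic-pocket rules of [pocket_filter_config()] and reports
#' a rejection reason list per removed record. Lining residues that map to
#' no annotated domain count as "unassigned"; records whose lining could not
#' be mapped at all are flagged, not silently dropped.
#'
#' @param records data frame of pocket records as produced by
#'   [gen_pocket_records()] or [read_pocket_table()].
#' @param cfg a [pocket_filter_config()].
#' @return list with `retained` (data frame, plus `dominant_domain` and
#'   `dominant_share` columns), `rejected` (same columns plus `reasons`,
#'   semicolon-joined), and `flagged` (pocket ids with unmapped lining).
#' @export
filter_pockets <- function(records, cfg) {
  stopifnot(inherits(cfg, "pocket_filter_config"))
  n <- nrow(records)
  reasons <- vector("list", n)
  dominant <- character(n); share <- numeric(n); nres <- integer(n)
  flagged <- character(0)
  for (k in seq_len(n)) {
    lin <- parse_lining(records$lining_residues[k])
    nres[k] <- nrow(lin)
    doms <- map_residue_domain(cfg$domain_annotation, lin$chain, lin$residue)
    if (all(doms == "unassigned"))
      flagged <- c(flagged, records$pocket_id[k])
    tab <- sort(table(doms), decreasing = TRUE)
    dominant[k] <- names(tab)[1]
    share[k] <- tab[[1]] / nrow(lin)
    r <- character(0)
    if (!(records$druggability_probability[k] > cfg$min_probability))
      r <- c(r, sprintf("probability not > %g", cfg$min_probability))
    if (nres[k] < cfg$min_residues)
      r <- c(r, sprintf("fewer than %d lining residues", cfg$min_residues))
    if (share[k] < cfg$interdomain_max_share)
      r <- c(r, "interdomain-spanning (no dominant domain)")
    if (dominant[k] %in% cfg$exclude_domains)
      r <- c(r, sprintf("within excluded domain %s", dominant[k]))
    reasons[[k]] <- r
  }
  out <- records
  out$n_lining_residues <- nres
  out$dominant_domain <- dominant
  out$dominant_share <- share
  keep <- lengths(reasons) == 0L
  rejected <- out[!keep, , drop = FALSE]
  rejected$reasons <- vapply(reasons[!keep], paste, character(1),
                             collapse = "; ")
  list(retained = out[keep, , drop = FALSE], rejected = rejected,
       flagged = flagged)
}

#' Read a pocket record table (TSV)
#'
#' Columns: `pocket_id`, `druggability_probability`, `lining_residues`
#' (semicolon-joined `chain:resnum`), optional `volume`, `source_frame`.
#'
#' @param path TSV path.
#' @return data frame of pocket records.
#' @export
read_pocket_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pocket_id", "druggability_probability", "lining_residues")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pocket table lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}
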