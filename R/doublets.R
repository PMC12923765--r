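#' Prefilter a mutation catalog
#'
#' Removes records below the VAF floor, and (optionally) excludes from
#' per-gene doublet counting every sample that carries a nonsense mutation
#' in that gene — the convention for testing same-gene double missense
#' mutations, where a truncating co-mutation voids the doublet.
#'
#' @param catalog MAF-like data frame (`sample_id`, `gene`,
#'   `protein_position`, `variant_class`, `vaf`).
#' @param vaf_min minimum variant allele frequency, default 0.05.
#' @param drop_nonsense_cohabitants exclude nonsense-carrying samples per
#'   gene (default TRUE).
#' @return list with `catalog` (filtered) and `audit` (counts:
#'   `vaf_removed`, `nonsense_samples_excluded`, `records_in_excluded_samples`).
#' @export
prefilter_catalog <- function(catalog, vaf_min = 0.05,
                              drop_nonsense_cohabitants = TRUE) {
  low <- catalog$vaf < vaf_min
  out <- catalog[!low, , drop = FALSE]
  n_excl_samples <- 0L; n_excl_records <- 0L
  if (drop_nonsense_cohabitants && nrow(out)) {
    bad_key <- unique(paste(out$gene, out$sample_id)[out$variant_class ==
                                                       "nonsense"])
    key <- paste(out$gene, out$sample_id)
    drop <- key %in% bad_key
    n_excl_samples <- length(bad_key)
    n_excl_records <- sum(drop)
    out <- out[!drop, , drop = FALSE]
  }
  list(catalog = out,
       audit = list(vaf_removed = sum(low),
                    nonsense_samples_excluded = n_excl_samples,
                    records_in_excluded_samples = n_excl_records))
}

#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' `OR = ad/bc`; when any cell is zero, 0.5 is added to every cell.
#'
#' @param a,b,c,d counts: both mutated, A only, B only, neither.
#' @return odds ratio.
#' @export
odds_ratio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5
                              c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

#' Pairwise same-gene doublet association tests
#'
#' For every position pair of the gene co-mutated in at least one sample, a
#' 2x2 table over gene-mutant samples is tested with a two-sided Fisher
#' exact test; odds ratios use the Haldane-Anscombe correction; q-values are
#' Benjamini-Hochberg across all tested pairs. A pair is called
#' co-occurring if `q < alpha` and OR > 1, mutually exclusive if `q < alpha`
#' and OR < 1, else null.
#'
#' @param catalog (prefiltered) mutation catalog.
#' @param gene gene symbol.
#' @param alpha FDR level, default 0.05.
#' @param mt_procedure multiplicity procedure for [stats::p.adjust()],
#'   default `"BH"`.
#' @return data frame of class `doublet_tests`: posA, posB, n_both, n_a_only,
#'   n_b_only, n_neither, odds_ratio, p_value, q_value, call.
#' @export
doublet_tests <- function(catalog, gene, alpha = 0.05, mt_procedure = "BH") {
  rec <- catalog[catalog$gene == gene, , drop = FALSE]
  if (!nrow(rec)) stop("no records for gene ", gene)
  samples <- unique(rec$sample_id)
  n <- length(samples)
  pos <- sort(unique(rec$protein_position))
  m <- matrix(FALSE, n, length(pos), dimnames = list(samples, pos))
  m[cbind(match(rec$sample_id, samples),
          match(rec$protein_position, pos))] <- TRUE
  both <- crossprod(m)                     # co-mutation counts
  pairs <- which(upper.tri(both) & both >= 1, arr.ind = TRUE)
  if (!nrow(pairs))
    return(structure(data.frame(posA = integer(0), posB = integer(0),
                                n_both = integer(0), n_a_only = integer(0),
                                n_b_only = integer(0), n_neither = integer(0),
                                odds_ratio = numeric(0), p_value = numeric(0),
                                q_value = numeric(0), call = character(0)),
                     class = c("doublet_tests", "data.frame"),
                     n_gene_mutant = n))
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    a <- both[i, j]
    b <- sum(m[, i]) - a
    c_ <- sum(m[, j]) - a
    d <- n - a - b - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    data.frame(posA = pos[i], posB = pos[j], n_both = a, n_a_only = b,
               n_b_only = c_, n_neither = d,
               odds_ratio = odds_ratio(a, b, c_, d), p_value = p)
  })
  res <- do.call(rbind, res)
  res$q_value <- stats::p.adjust(res$p_value, method = mt_procedure)
  res$call <- ifelse(res$q_value < alpha & res$odds_ratio > 1, "co-occurring",
              ifelse(res$q_value < alpha & res$odds_ratio < 1,
                     "mutually-exclusive", "null"))
  structure(res, class = c("doublet_tests", "data.frame"), n_gene_mutant = n)
}

#' Driver-tier classification of a mutated position
#'
#' Validated positions (present in the validated-driver list) are strong
#' drivers when mutated in at least 10 percent of gene-mutant tumors, weak
#' drivers otherwise. Unvalidated positions are strong latent drivers at
#' 1 percent or more, weak latent drivers otherwise.
#'
#' @param position protein position.
#' @param frequency fraction of gene-mutant tumors carrying it, in `[0,1]`.
#' @param validated_list integer vector of validated driver positions.
#' @return list: `position`, `frequency`, `in_validated_list`, `tier`.
#' @export
classify_mutation <- function(position, frequency, validated_list) {
  if (frequency < 0 || frequency > 1) stop("frequency must be in [0,1]")
  inlist <- position %in% validated_list
  tier <- if (inlist) {
    if (frequency >= 0.10) "strong driver" else "weak driver"
  } else {
    if (frequency >= 0.01) "strong latent driver" else "weak latent driver"
  }
  list(position = position, frequency = frequency,
       in_validated_list = inlist, tier = tier)
}

#' Driver labels for every mutated position of a gene
#'
#' Frequencies are computed over gene-mutant samples (samples with at least
#' one record in the gene), matching the tier definitions.
#'
#' @param catalog mutation catalog.
#' @param gene gene symbol.
#' @param validated_list integer vector of validated driver positions.
#' @return data frame `position`, `frequency`, `in_validated_list`, `tier`.
#' @export
driver_labels <- function(catalog, gene, validated_list) {
  rec <- catalog[catalog$gene == gene, , drop = FALSE]
  if (!nrow(rec)) stop("no records for gene ", gene)
  n <- length(unique(rec$sample_id))
  by_pos <- tapply(rec$sample_id, rec$protein_position,
                   function(s) length(unique(s)))
  pos <- as.integer(names(by_pos))
  out <- do.call(rbind, lapply(seq_along(pos), function(k) {
    cl <- classify_mutation(pos[k], by_pos[[k]] / n, validated_list)
    data.frame(position = cl$position, frequency = cl$frequency,
               in_validated_list = cl$in_validated_list, tier = cl$tier,
               stringsAsFactors = FALSE)
  }))
  out
}

tier_rank <- c("strong driver" = 1L, "weak driver" = 2L,
               "strong latent driver" = 3L, "weak latent driver" = 4L)

tier_short <- c("strong driver" = "strong driver",
                "weak driver" = "weak driver",
                "strong latent driver" = "strong latent",
                "weak latent driver" = "weak latent")

#' Annotate doublets with their constituents' driver tiers
#'
#' Adds per-position tiers and a symmetric combination class such as
#' `"strong driver + strong latent"` (ordered by tier strength, so the class
#' does not depend on position order).
#'
#' @param tests a [doublet_tests()] result.
#' @param labels a [driver_labels()] table covering every tested position.
#' @return the tests data frame with `tier_a`, `tier_b`, `combination`.
#' @export
label_doublets <- function(tests, labels) {
  lk <- stats::setNames(labels$tier, labels$position)
  missing <- setdiff(unique(c(tests$posA, tests$posB)), labels$position)
  if (length(missing))
    stop("no driver label for position(s): ", paste(missing, collapse = ", "))
  ta <- unname(lk[as.character(tests$posA)])
  tb <- unname(lk[as.character(tests$posB)])
  comb <- vapply(seq_along(ta), function(k) {
    pair <- c(ta[k], tb[k])
    pair <- pair[order(tier_rank[pair])]
    paste(tier_short[pair], collapse = " + ")
  }, character(1))
  tests$tier_a <- ta
  tests$tier_b <- tb
  tests$combination <- comb
  tests
}
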