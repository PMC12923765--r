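#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one frame; a file without MODEL records is a
#' single-frame trajectory. Topology (atom names, residues, chains) is taken
#' from the first model and must be identical across models. Author residue
#' numbering is preserved. Alternate locations other than 'A'/blank are
#' dropped with a warning reporting the count.
#'
#' @param path PDB file path.
#' @return a [trajectory()].
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    counts <- mapply(function(s, e) sum(atom_lines[s:e]), model_starts, model_ends)
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1])[1]
      stop("atom count mismatch: model ", bad, " has ", counts[bad],
           " atoms, model 1 has ", counts[1])
    }
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB ", path, ": ",
                             conditionMessage(e)))
  atoms <- pdb$atom
  keep <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning("dropped ", n_dropped, " alternate-location atom records (altloc != 'A')")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  elem <- atoms$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(atoms))
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- infer_element(atoms$elety[blank])
  topology <- data.frame(
    serial = atoms$eleno,
    name = atoms$elety,
    residue_name = atoms$resid,
    chain_id = ifelse(is.na(atoms$chain), " ", atoms$chain),
    residue_number = atoms$resno,
    element = toupper(trimws(elem)),
    stringsAsFactors = FALSE)
  if (any(is.na(topology$residue_number)))
    stop("unparsable residue numbers in ", path)
  atom_cols <- function(i) c(3L * i - 2L, 3L * i - 1L, 3L * i)
  keep_idx <- which(keep)
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    fr <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    fr[keep_idx, , drop = FALSE]
  })
  trajectory(topology[keep_idx, , drop = FALSE], frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj trajectory.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb_models <- function(traj, path) {
  top <- traj$topology
  xyz <- do.call(rbind, lapply(traj$frames, function(fr) as.numeric(t(fr))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(top)),
                   eleno = top$serial, elety = top$name,
                   resid = top$residue_name, chain = top$chain_id,
                   resno = top$residue_number,
                   elesy = top$element)
  invisible(path)
}

#' Domain annotation tables
#'
#' An annotation maps inclusive residue ranges of a chain to named domains.
#' `p110a_domains()` and `p85a_domains()` ship the standard PI3K-alpha
#' subunit boundaries (ABD 16-105, RBD 187-289, C2 330-487, helical 517-694,
#' kinase 695-1068 on the catalytic subunit; SH3 3-79, BH 113-301,
#' nSH2 333-428, iSH2 431-598, cSH2 624-718 on the regulatory subunit).
#'
#' @param entries data frame with columns `domain`, `chain`, `start`, `end`.
#' @return object of class `domain_annotation` (a validated data frame).
#' @export
domain_annotation <- function(entries) {
  required <- c("domain", "chain", "start", "end")
  if (!all(required %in% names(entries)))
    stop("annotation needs columns: ", paste(required, collapse = ", "))
  entries <- entries[required]
  if (any(entries$start > entries$end))
    stop("annotation has start > end")
  key <- paste(entries$chain, entries$domain)
  if (anyDuplicated(key))
    stop("duplicate domain name within a chain")
  class(entries) <- c("domain_annotation", "data.frame")
  entries
}

#' @rdname domain_annotation
#' @param chain chain identifier the catalytic subunit occupies.
#' @export
p110a_domains <- function(chain = "A") {
  domain_annotation(data.frame(
    domain = c("ABD", "RBD", "C2", "helical", "kinase"),
    chain = chain,
    start = c(16L, 187L, 330L, 517L, 695L),
    end = c(105L, 289L, 487L, 694L, 1068L),
    stringsAsFactors = FALSE))
}

#' @rdname domain_annotation
#' @export
p85a_domains <- function(chain = "B") {
  domain_annotation(data.frame(
    domain = c("SH3", "BH", "nSH2", "iSH2", "cSH2"),
    chain = chain,
    start = c(3L, 113L, 333L, 431L, 624L),
    end = c(79L, 301L, 428L, 598L, 718L),
    stringsAsFactors = FALSE))
}

#' Read a domain annotation from TSV
#'
#' Expects tab-separated columns `domain`, `chain`, `start`, `end`.
#' @param path TSV path.
#' @return a [domain_annotation()].
#' @export
read_domain_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  domain_annotation(df)
}

#' Map residues to domains
#'
#' @param annotation a [domain_annotation()].
#' @param chain chain id vector.
#' @param residue residue number vector (recycled against `chain`).
#' @return character vector of domain names, `"unassigned"` where no range
#'   covers the residue.
#' @export
map_residue_domain <- function(annotation, chain, residue) {
  n <- max(length(chain), length(residue))
  chain <- rep_len(chain, n); residue <- rep_len(residue, n)
  vapply(seq_len(n), function(i) {
    hit <- annotation$chain == chain[i] &
      annotation$start <= residue[i] & annotation$end >= residue[i]
    if (any(hit)) annotation$domain[which(hit)[1]] else "unassigned"
  }, character(1))
}

#' Residue selector
#'
#' Maps a (chain, residue) pair to atoms via a rule:
#' \describe{
#'   \item{all-heavy}{every non-hydrogen atom of the residue}
#'   \item{backbone}{N, CA, C, O}
#'   \item{sidechain-charge-group}{the charged-group heavy atoms:
#'     Lys NZ; Arg NH1, NH2, NE; Asp OD1, OD2; Glu OE1, OE2; His ND1, NE2}
#'   \item{single-atom:<NAME>}{the named atom}
#'   \item{centroid}{virtual site at the unweighted mean of all heavy atoms}
#' }
#'
#' @param chain_id chain identifier.
#' @param residue_number author residue number.
#' @param atom_rule one of the rules above (default `"all-heavy"`).
#' @return object of class `residue_selector`.
#' @export
residue_selector <- function(chain_id, residue_number, atom_rule = "all-heavy") {
  ok <- atom_rule %in% c("all-heavy", "backbone", "sidechain-charge-group",
                         "centroid") || startsWith(atom_rule, "single-atom:")
  if (!ok) stop("unknown atom_rule: ", atom_rule)
  structure(list(chain_id = chain_id,
                 residue_number = as.integer(residue_number),
                 atom_rule = atom_rule),
            class = "residue_selector")
}

charge_group_atoms <- list(
  LYS = "NZ", ARG = c("NH1", "NH2", "NE"), ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), HSD = c("ND1", "NE2"),
  HSE = c("ND1", "NE2"))

#' Resolve a residue selector to atom indices
#'
#' Deterministic: indices are returned in topology order. For the `centroid`
#' rule the returned indices are all heavy atoms of the residue, with
#' attribute `centroid = TRUE`; distance code treats them as one virtual site.
#'
#' @param traj trajectory (or anything with a `$topology`).
#' @param sel a [residue_selector()].
#' @return integer atom indices into the topology.
#' @export
resolve_selection <- function(traj, sel) {
  top <- traj$topology
  in_res <- which(top$chain_id == sel$chain_id &
                  top$residue_number == sel$residue_number)
  if (!length(in_res))
    stop("residue ", sel$chain_id, ":", sel$residue_number,
         " not found in topology")
  heavy <- in_res[top$element[in_res] != "H"]
  rule <- sel$atom_rule
  idx <- if (rule == "all-heavy") {
    heavy
  } else if (rule == "backbone") {
    in_res[top$name[in_res] %in% c("N", "CA", "C", "O")]
  } else if (rule == "sidechain-charge-group") {
    res_name <- toupper(top$residue_name[in_res[1]])
    wanted <- charge_group_atoms[[res_name]]
    if (is.null(wanted))
      stop("no charge-group rule for residue type ", res_name,
           "; available atoms: ", paste(top$name[in_res], collapse = ", "))
    in_res[top$name[in_res] %in% wanted]
  } else if (rule == "centroid") {
    heavy
  } else {                                   # single-atom:<NAME>
    nm <- sub("^single-atom:", "", rule)
    in_res[top$name[in_res] == nm]
  }
  if (!length(idx))
    stop("atom rule '", rule, "' matched nothing for ",
         sel$chain_id, ":", sel$residue_number,
         "; available atoms: ", paste(top$name[in_res], collapse = ", "))
  idx <- sort(as.integer(idx))
  if (rule == "centroid") attr(idx, "centroid") <- TRUE
  idx
}

#' Write a homogeneous record table
#'
#' Writes a data frame as CSV, TSV or JSON (array of row objects) with a
#' header, deterministic column order, and floats at 6 significant digits.
#'
#' @param rows data frame (possibly zero rows).
#' @param path output path.
#' @param format one of `"csv"`, `"tsv"`, `"json"`.
#' @return invisibly, `path`.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  num <- vapply(rows, is.double, logical(1))
  rows[num] <- lapply(rows[num], signif, digits = 6)
  if (format == "json") {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    utils::write.table(rows, path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
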