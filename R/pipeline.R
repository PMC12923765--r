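#' Run the analysis pipeline from a single configuration
#'
#' The configuration (a list, or a path to a YAML file) declares an output
#' directory, one seed for all randomness, a transient fraction, and an
#' ordered list of stage blocks. Each block is a list with a `stage` field
#' and stage parameters; stages execute in declared order, write their
#' tables under the output directory, and a `manifest.json` records the
#' package version, seed, per-stage parameters, input-file checksums and
#' every output written. Any stage failure aborts with the stage named.
#'
#' Supported stages:
#' \describe{
#'   \item{simulate_latch}{[gen_latch_trajectory()]; params of
#'     [latch_sim_config()] plus `id` to name the trajectory.}
#'   \item{simulate_membrane}{[gen_membrane_system()]; params of
#'     [bilayer_sim_config()] plus `id`.}
#'   \item{latch}{distance/occupancy tables for latch definitions on a
#'     trajectory (`traj` = stage id or PDB path; `latches` = list of blocks
#'     with name, chain_a, res_a, rule_a, chain_b, res_b, rule_b, cutoff).}
#'   \item{pmf}{2D PMF over two latches defined as in `latch`.}
#'   \item{rmsf}{per-residue RMSF after iterative superposition.}
#'   \item{paths}{correlation matrix, contact graph and bounded-suboptimal
#'     paths between `source` and `sink` ("chain:res").}
#'   \item{membrane}{anchor depth profile and PIP2 protrusion.}
#'   \item{pockets}{[filter_pockets()] on a pocket TSV (`input`) or
#'     [gen_pocket_records()] (`n`).}
#'   \item{doublets}{prefilter + [doublet_tests()] + tier labels on a
#'     MAF-like TSV (`input`) or a generated catalog.}
#' }
#'
#' @param config list or YAML path.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config needs output_dir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  transient <- if (is.null(config$transient_fraction)) 0.2 else
    config$transient_fraction
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  known <- c("simulate_latch", "simulate_membrane", "latch", "pmf", "rmsf",
             "paths", "membrane", "pockets", "doublets")
  for (b in stages) {
    if (is.null(b$stage)) stop("every stage block needs a 'stage' field")
    if (!b$stage %in% known)
      stop("unknown stage '", b$stage, "'; known: ",
           paste(known, collapse = ", "))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  manifest <- list(package = "pi3kdyn",
                   version = as.character(utils::packageVersion("pi3kdyn")),
                   seed = seed, transient_fraction = transient,
                   stages = list(), inputs = list(), outputs = character(0))
  out_path <- function(name) file.path(config$output_dir, name)
  note_input <- function(path) {
    manifest$inputs[[path]] <<- if (file.exists(path))
      unname(tools::md5sum(path)) else NA_character_
  }
  note_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, basename(path))
  }
  get_traj <- function(ref) {
    if (!is.null(env[[ref]])) return(env[[ref]])
    note_input(ref)
    read_pdb_models(ref)
  }
  latch_from_block <- function(lb) {
    latch_definition(
      lb$name,
      residue_selector(lb$chain_a, lb$res_a,
                       if (is.null(lb$rule_a)) "sidechain-charge-group" else lb$rule_a),
      residue_selector(lb$chain_b, lb$res_b,
                       if (is.null(lb$rule_b)) "sidechain-charge-group" else lb$rule_b),
      if (is.null(lb$cutoff)) 4.0 else lb$cutoff)
  }
  series_for <- function(traj, lb) {
    s <- distance_series(traj, latch_from_block(lb))
    exclude_transient(s, fraction = transient)
  }
  for (si in seq_along(stages)) {
    b <- stages[[si]]
    set.seed(seed + si)
    res <- tryCatch(switch(
      b$stage,
      simulate_latch = {
        id <- if (is.null(b$id)) "latch_sim" else b$id
        args <- b[setdiff(names(b), c("stage", "id"))]
        args$seed <- seed + si
        sim <- do.call(gen_latch_trajectory, list(do.call(latch_sim_config, args)))
        env[[id]] <- sim$trajectory
        p <- out_path(paste0(id, "_truth.tsv"))
        write_table(sim$truth, p, "tsv"); note_output(p)
        list(id = id, occupancy_released = sim$occupancy_released)
      },
      simulate_membrane = {
        id <- if (is.null(b$id)) "membrane_sim" else b$id
        args <- b[setdiff(names(b), c("stage", "id"))]
        args$seed <- seed + si
        if (!is.null(args$planted_anchor_depths))
          args$planted_anchor_depths <- unlist(args$planted_anchor_depths)
        sim <- do.call(gen_membrane_system, list(do.call(bilayer_sim_config, args)))
        env[[id]] <- sim$trajectory
        p <- out_path(paste0(id, "_composition.csv"))
        write_table(data.frame(species = names(sim$composition),
                               count = as.integer(sim$composition)), p)
        note_output(p)
        list(id = id, composition = as.list(sim$composition))
      },
      latch = {
        traj <- get_traj(b$traj)
        rows <- do.call(rbind, lapply(b$latches, function(lb)
          occupancy_summary(series_for(traj, lb))))
        p <- out_path(if (is.null(b$out)) "latch_occupancy.csv" else b$out)
        write_table(rows, p); note_output(p)
        list(n_latches = nrow(rows))
      },
      pmf = {
        traj <- get_traj(b$traj)
        s1 <- series_for(traj, b$d1); s2 <- series_for(traj, b$d2)
        grid <- compute_pmf2d(s1, s2,
                              bin_width = if (is.null(b$bin_width)) 0.5 else b$bin_width,
                              temperature = if (is.null(b$temperature)) 310 else b$temperature)
        p <- out_path(if (is.null(b$out)) "pmf.csv" else b$out)
        write_table(pmf_as_table(grid), p); note_output(p)
        list(n_samples = grid$n_samples, kT = grid$kT)
      },
      rmsf = {
        traj <- get_traj(b$traj)
        nf <- n_frames(traj)
        use <- seq.int(floor(nf * transient) + 1L, nf)
        prof <- rmsf_profile(subset_frames(traj, use),
                             fit_indices = backbone_indices(traj))
        p <- out_path(if (is.null(b$out)) "rmsf.csv" else b$out)
        write_table(prof, p); note_output(p)
        list(n_residues = nrow(prof))
      },
      paths = {
        traj <- get_traj(b$traj)
        C <- correlation_matrix(traj)
        avg <- trajectory(traj$topology,
                          list(Reduce(`+`, traj$frames) / n_frames(traj)))
        g <- build_graph(C, avg,
                         contact_cutoff = if (is.null(b$contact_cutoff)) 4.5
                         else b$contact_cutoff)
        src <- sub(":", " ", b$source); snk <- sub(":", " ", b$sink)
        ps <- suboptimal_paths(g, src, snk,
                               delta = if (is.null(b$delta)) 1.0 else b$delta,
                               max_paths = if (is.null(b$max_paths)) 50L
                               else b$max_paths)
        p <- out_path(if (is.null(b$out)) "paths.csv" else b$out)
        write_table(paths_as_table(ps), p); note_output(p)
        p2 <- out_path("path_node_degeneracy.csv")
        write_table(data.frame(node = names(ps$node_degeneracy),
                               n_paths = as.integer(ps$node_degeneracy)), p2)
        note_output(p2)
        list(optimal_weight = ps$optimal_weight, n_paths = length(ps$paths))
      },
      membrane = {
        traj <- get_traj(b$traj)
        res <- if (is.null(b$residues)) {
          ap <- anchor_points()
          data.frame(chain = ap$chain, residue = ap$residue)
        } else do.call(rbind, lapply(b$residues, as.data.frame))
        have <- vapply(seq_len(nrow(res)), function(k)
          any(traj$topology$chain_id == res$chain[k] &
              traj$topology$residue_number == res$residue[k]), logical(1))
        prof <- depth_profile(traj, res[have, , drop = FALSE],
                              transient_fraction = transient)
        p <- out_path(if (is.null(b$out)) "anchor_depths.csv" else b$out)
        write_table(prof, p); note_output(p)
        pr <- pip2_protrusion(traj, transient_fraction = transient)
        p2 <- out_path("pip2_protrusion.csv")
        write_table(data.frame(mean = pr$mean, sd = pr$sd, n = length(pr$elevations)),
                    p2); note_output(p2)
        list(protrusion_mean = pr$mean)
      },
      pockets = {
        recs <- if (!is.null(b$input)) { note_input(b$input)
                                         read_pocket_table(b$input) }
                else gen_pocket_records(if (is.null(b$n)) 12L else b$n,
                                        seed = seed + si)
        cfg <- pocket_filter_config()
        fp <- filter_pockets(recs, cfg)
        p <- out_path("pockets_retained.csv"); write_table(fp$retained, p)
        note_output(p)
        p2 <- out_path("pockets_rejected.csv"); write_table(fp$rejected, p2)
        note_output(p2)
        list(n_retained = nrow(fp$retained), n_rejected = nrow(fp$rejected))
      },
      doublets = {
        cat0 <- if (!is.null(b$input)) { note_input(b$input)
                                         read_catalog(b$input) }
                else stop("doublets stage needs 'input'")
        pf <- prefilter_catalog(cat0,
                                vaf_min = if (is.null(b$vaf_min)) 0.05 else b$vaf_min)
        tests <- doublet_tests(pf$catalog, b$gene,
                               alpha = if (is.null(b$alpha)) 0.05 else b$alpha)
        labs <- driver_labels(pf$catalog, b$gene,
                              validated_list = if (is.null(b$validated)) integer(0)
                              else as.integer(unlist(b$validated)))
        tests <- label_doublets(tests, labs)
        p <- out_path(if (is.null(b$out)) "doublets.csv" else b$out)
        write_table(as.data.frame(tests), p); note_output(p)
        list(n_pairs = nrow(tests),
             n_significant = sum(tests$call != "null"))
      }),
      error = function(e) stop("stage ", si, " (", b$stage, ") failed: ",
                               conditionMessage(e), call. = FALSE))
    manifest$stages[[si]] <- list(stage = b$stage, params = b, result = res)
  }
  mp <- out_path("manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
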