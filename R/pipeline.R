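#' Run the analysis pipeline from a config
#'
#' Orchestrates the stages in dependency order — trajectory input (read or
#' synthetic), fluctuation summaries, PCA, hydrogen bonds, contacts,
#' microswitch panel, C-alpha and dihedral MI, network — writing delimited
#' text tables plus a JSON manifest recording parameters, the seed, input
#' digests and per-output md5 sums.  Re-running an identical config
#' reproduces identical outputs byte for byte.
#'
#' The config (YAML file or list) has top-level fields `output_dir`,
#' `stages` (subset of `simulate`, `fluct`, `pca`, `hbonds`, `contacts`,
#' `microswitch`, `mi_calpha`, `mi_dihedral`, `network`), `seed`,
#' `inputs` (per-condition lists of PDB paths; omit when simulating),
#' `reference` (PDB path for rmsd microswitches), `regions` (named
#' residue-id ranges `from`/`to`), `simulate` (arguments of
#' [gen_gaussian_traj()] plus `replicates`), and `parameters` (stage
#' parameter overrides; see `inst/extdata/default_config.yaml` for the
#' shipped defaults).
#'
#' @param config path to a YAML file or an equivalent nested list.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` in `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- .validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$output_dir, "pipeline.log")
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(line, "\n", sep = "", file = logf, append = TRUE)
    message(line)
  }
  outputs <- character(0)
  emit <- function(obj, name) {
    path <- file.path(cfg$output_dir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  emit_matrix <- function(m, name) {
    path <- file.path(cfg$output_dir, name)
    utils::write.table(format(m, digits = 10), path, sep = "\t",
                       quote = FALSE, col.names = NA)
    outputs <<- c(outputs, path)
    path
  }

  stage_done <- character(0)
  manifest <- list(package = "mdmi",
                   version = as.character(utils::packageVersion("mdmi")),
                   seed = cfg$seed, parameters = cfg$parameters,
                   stages = cfg$stages)

  ## ---- inputs ----
  ensembles <- list()
  if ("simulate" %in% cfg$stages) {
    sim <- cfg$simulate
    reps <- sim$replicates %||% 1L
    for (r in seq_len(reps)) {
      g <- gen_gaussian_traj(
        n_res = sim$n_res, n_frames = sim$n_frames,
        sigma = sim$sigma %||% 0.5,
        blocks = sim$blocks %||% list(),
        res_names = sim$res_names %||% "ALA",
        seed = cfg$seed + r)
      path <- file.path(cfg$output_dir,
                        sprintf("synthetic_rep%d.pdb", r))
      write_pdb_trajectory(g$trajectory, path)
      outputs <- c(outputs, path)
      ensembles$synthetic <- c(ensembles$synthetic, path)
    }
    log_msg("simulate: wrote ", reps, " synthetic replicate(s)")
    stage_done <- c(stage_done, "simulate")
  }
  if (!is.null(cfg$inputs)) ensembles <- utils::modifyList(ensembles, cfg$inputs)

  analysis_stages <- setdiff(cfg$stages, "simulate")
  if (length(analysis_stages) > 0L && length(ensembles) == 0L)
    stop("validation failure: analysis stages requested but no inputs")

  trajs_by_cond <- lapply(ensembles, function(paths)
    lapply(paths, read_pdb_trajectory, quiet = TRUE))
  reference <- if (!is.null(cfg$reference))
    read_pdb_trajectory(cfg$reference, quiet = TRUE) else NULL
  pars <- cfg$parameters

  for (cond in names(trajs_by_cond)) {
    ens <- trajs_by_cond[[cond]]
    ca <- select_atoms(ens[[1L]], name = "CA")

    if ("fluct" %in% analysis_stages) {
      prof <- rmsf_profile(ens, sel = ca)
      emit(as.data.frame(prof), paste0(cond, "_rmsf.tsv"))
      for (r in seq_along(ens)) {
        rs <- rmsd_series(ens[[r]], align_sel = ca, label = "All")
        emit(data.frame(time_ns = rs$time_ns, rmsd = rs$values),
             sprintf("%s_rmsd_rep%d.tsv", cond, r))
      }
      log_msg("fluct[", cond, "]: RMSF over ", attr(prof, "n_frames"),
              " pooled frames")
      stage_done <- c(stage_done, "fluct")
    }
    if ("pca" %in% analysis_stages) {
      model <- fit_pca(ens, sel = ca)
      emit(data.frame(mode = seq_along(model$values),
                      eigenvalue = model$values,
                      cumulative = model$cumulative),
           paste0(cond, "_pca_eigenvalues.tsv"))
      for (pc in 1:2) {
        pr <- project_pc(pool_align(ens, align_sel = ca), model, pc)
        emit(data.frame(frame = seq_along(pr$values), projection = pr$values),
             sprintf("%s_pc%d_projection.tsv", cond, pc))
      }
      log_msg("pca[", cond, "]: PC1-5 cumulative ",
              sprintf("%.3f", model$cumulative[min(5L, length(model$values))]))
      stage_done <- c(stage_done, "pca")
    }
    if ("hbonds" %in% analysis_stages && has_hydrogens(ens[[1L]])) {
      hb <- hbond_table(ens, hbond_criteria(
        angle_min = pars$hbond$angle_min, dist_max = pars$hbond$dist_max,
        min_freq = pars$hbond$min_freq))
      emit(hb$records, paste0(cond, "_hbonds.tsv"))
      emit(hb$by_residue, paste0(cond, "_hbond_residues.tsv"))
      log_msg("hbonds[", cond, "]: ", nrow(hb$records), " surviving bonds")
      stage_done <- c(stage_done, "hbonds")
    }
    if ("contacts" %in% analysis_stages) {
      cm <- contact_map(ens, cutoff = pars$contact$cutoff,
                        persistence = pars$contact$persistence)
      emit_matrix(cm$fraction, paste0(cond, "_contact_fraction.tsv"))
      emit(contact_pairs(cm), paste0(cond, "_contacts.tsv"))
      stage_done <- c(stage_done, "contacts")
    }
    if ("microswitch" %in% analysis_stages && !is.null(reference)) {
      defs <- default_microswitches()
      defs <- Filter(function(d) {
        ok <- tryCatch({
          if (d$kind == "distance") atom_pair_series(ens[[1L]], d)
          else motif_rmsd_series(ens[[1L]], d, reference)
          TRUE
        }, error = function(e) FALSE)
        ok
      }, defs)
      if (length(defs) > 0L) {
        panel <- microswitch_panel(ens, defs, reference)
        emit(panel$summary, paste0(cond, "_microswitches.tsv"))
        stage_done <- c(stage_done, "microswitch")
      }
    }
    if (any(c("mi_calpha", "network") %in% analysis_stages)) {
      mim <- mi_matrix_calpha(ens, sel = ca,
                              bin_tol = pars$binning$tol,
                              min_sep = pars$network$min_sep)
      if ("mi_calpha" %in% analysis_stages) {
        emit_matrix(mim$matrix, paste0(cond, "_mi_calpha.tsv"))
        emit(aggregate_mi(mim, "residue_mean"),
             paste0(cond, "_mi_mean.tsv"))
        log_msg("mi_calpha[", cond, "]: mean off-diagonal ",
                sprintf("%.4f bits",
                        mean(mim$matrix[upper.tri(mim$matrix)])))
        stage_done <- c(stage_done, "mi_calpha")
      }
      if ("network" %in% analysis_stages) {
        dm <- distance_matrix(ens)
        rg <- build_graph(mim, dm, network_config(
          mi_threshold = pars$network$mi_threshold,
          dist_cutoff = pars$network$dist_cutoff,
          min_sep = pars$network$min_sep))
        emit(rg$edges, paste0(cond, "_network_edges.tsv"))
        cent <- merge(degree_centrality(rg), betweenness_centrality(rg),
                      by = "residue", sort = FALSE)
        emit(cent, paste0(cond, "_centrality.tsv"))
        log_msg("network[", cond, "]: ", nrow(rg$edges), " edges")
        stage_done <- c(stage_done, "network")
      }
    }
    if ("mi_dihedral" %in% analysis_stages) {
      rs <- rotamer_states_all(ens[[1L]])
      usable <- vapply(rs$states, ncol, integer(1)) > 0L
      if (any(usable)) {
        mim_d <- mi_matrix_dihedral(rs$states, rs$residues,
                                    min_sep = pars$dihedral$min_sep)
        emit_matrix(mim_d$matrix, paste0(cond, "_mi_dihedral.tsv"))
        stage_done <- c(stage_done, "mi_dihedral")
      }
    }
  }

  manifest$stages_completed <- unique(stage_done)
  manifest$outputs <- lapply(outputs, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p))))
  manifest$input_digests <- if (length(ensembles) > 0L)
    lapply(ensembles, function(paths)
      lapply(paths, function(p) unname(tools::md5sum(p)))) else list()
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_msg("done: ", length(outputs), " output file(s)")
  invisible(manifest)
}

## defaults mirror the shipped thresholds; every entry overridable
.default_parameters <- function() {
  list(
    hbond = list(angle_min = 120, dist_max = 2.5, min_freq = 0.001),
    contact = list(cutoff = 6.0, persistence = 0.75),
    binning = list(tol = 0.02),
    network = list(mi_threshold = 0.25, dist_cutoff = 6.0, min_sep = 6L),
    dihedral = list(min_sep = 5L),
    microswitch = list(ionic_lock = 10.5, yy_gate = 14.6, npxxy = 2.0,
                       pif = 2.2)
  )
}

.validate_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$output_dir))
    stop("validation failure: config needs output_dir")
  if (is.null(cfg$stages) || length(cfg$stages) == 0L)
    stop("validation failure: config needs at least one stage")
  known <- c("simulate", "fluct", "pca", "hbonds", "contacts",
             "microswitch", "mi_calpha", "mi_dihedral", "network")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0L)
    stop("validation failure: unknown stage(s) ", paste(bad, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$parameters <- utils::modifyList(.default_parameters(),
                                      cfg$parameters %||% list())
  if ("simulate" %in% cfg$stages) {
    if (is.null(cfg$simulate$n_res) || is.null(cfg$simulate$n_frames))
      stop("validation failure: simulate stage needs n_res and n_frames")
  }
  for (paths in cfg$inputs)
    for (p in paths)
      if (!file.exists(p))
        stop("validation failure: input file not found: ", p)
  if (!is.null(cfg$reference) && !file.exists(cfg$reference))
    stop("validation failure: reference file not found: ", cfg$reference)
  cfg
}
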