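# End-to-end analysis pipeline: time filter -> contacts/distances ->
# bound partition -> landscapes + basins -> microstates -> model
# classification -> depths -> H-bonds -> secondary structure -> contact
# maps -> report.

# FNV-1a 32-bit hash; used to stamp outputs with the configuration so
# mismatched re-use is detectable without extra dependencies.
fnv1a32 <- function(text) {
  bytes <- utf8ToInt(enc2utf8(text))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); avoids 32-bit integer limits
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 10))
}

.stage <- function(name, expr, log) {
  log("stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a trajectory file
#'
#' Executes every stage of the standard analysis on a multi-model PDB
#' trajectory and writes deterministic TSV/JSON reports into `out_dir`.
#' Identical input, configuration and package version produce
#' byte-identical outputs.
#'
#' @param traj_path Multi-model PDB trajectory.
#' @param config An `analysis_config`, or a path to a JSON config file.
#' @param out_dir Output directory (created if missing).
#' @param reference Optional `n x 3` reference coordinates for peptide
#'   heavy-atom RMSD; defaults to the first analysed frame.
#' @param log_file Optional log file (log always goes to stderr too).
#' @return A `pipeline_report` (list of the main result tables), invisibly.
#' @export
run_full_pipeline <- function(traj_path, config = analysis_config(),
                              out_dir, reference = NULL, log_file = NULL) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- if (!is.null(log_file)) file(log_file, "wb") else NULL
  if (!is.null(log_con)) on.exit(close(log_con))
  log <- function(...) {
    msg <- paste0(..., collapse = "")
    message("[membind] ", msg)
    if (!is.null(log_con)) writeLines(paste0("[membind] ", msg), log_con)
  }
  chash <- config_hash(config)
  log("config hash ", chash)

  map <- attr(config, "region_map") %||% default_region_map()
  traj <- .stage("read", read_pdb_multimodel(traj_path, map,
                                             config$frame_spacing), log)
  traj <- .stage("time-filter", {
    out <- withCallingHandlers(
      filter_time_window(traj, config$equilibration_discard, Inf),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!length(out$frames)) {
      stop("no frames left after discarding the first ",
           config$equilibration_discard, " ns")
    }
    out
  }, log)
  sys <- traj$topology

  cf <- .stage("contacts", contact_fractions(traj, config), log)
  bound <- partition_bound(traj, config, n_contacts = cf$n_contacts)
  cf_bound <- if (any(bound)) {
    contact_fractions(traj, config, bound_only = TRUE)
  } else NULL
  dist <- .stage("distance", vapply(traj$frames, function(f)
    peptide_bilayer_distance(sys, f), numeric(1)), log)

  grid <- .stage("fel", compute_fel_2d(dist, cf$n_contacts,
                                       config$fel_bins_distance,
                                       config$fel_bins_contacts,
                                       "distance", "contacts", config), log)
  basins <- .stage("basins", find_basins(grid, config$basin_min_depth_kT,
                                         config$basin_min_separation_bins),
                   log)

  ss <- .stage("secstruct", secstruct_trajectory(traj), log)
  feats <- .stage("features", frame_features(traj, config, ss = ss), log)
  labels <- .stage("classify", classify_binding_model(feats, config), log)

  pep <- sys$idx$peptide_heavy
  if (is.null(reference)) reference <- traj$frames[[1]]$coords[pep, ,
                                                               drop = FALSE]
  rmsd <- .stage("rmsd", vapply(traj$frames, function(f)
    kabsch_rmsd(reference, f$coords[pep, , drop = FALSE]), numeric(1)), log)

  micro <- .stage("microstates", {
    out <- list()
    for (b in basins$basins$label) {
      members <- which(basins$sample_basin == b)
      if (length(members) < 2) next
      pb <- suppressWarnings(
        per_basin_fel(traj, members, reference, config, basin_label = b,
                      ss = ss[members, , drop = FALSE]))
      out[[b]] <- pb$microstates
    }
    if (length(out)) do.call(rbind, out) else NULL
  }, log)

  depths <- .stage("depths", {
    d <- vapply(traj$frames, function(f) residue_depths(sys, f, config),
                numeric(length(sys$peptide_residues)))
    rowMeans(d)
  }, log)

  hb <- .stage("hbonds", hbond_summaries(traj, config), log)
  cmap <- .stage("contact-map", residue_contact_map(traj, config), log)
  lr <- top_longrange_pairs(cmap, 10, config)
  ssf <- grouped_fractions(ss)

  per_frame <- data.frame(
    frame = seq_along(traj$frames), time = frame_times(traj),
    distance = dist, n_contacts = cf$n_contacts, bound = bound,
    beta = apply(ss, 1, beta_content), rmsd = rmsd,
    basin = basins$sample_basin, model = labels)
  basin_tab <- basins$basins
  basin_tab$dG_kT <- basin_relative_free_energy(basin_tab$population + 0,
                                                config)
  per_res <- data.frame(
    residue = sys$peptide_residues,
    region = region_of(sys$region_map, sys$peptide_residues),
    contact_fraction = as.numeric(cf$fraction),
    contact_fraction_bound = if (!is.null(cf_bound))
      as.numeric(cf_bound$fraction) else NA_real_,
    mean_depth = as.numeric(depths),
    hbond_membrane = hb$per_residue$membrane,
    hbond_water = hb$per_residue$water,
    unstructured = ssf$unstructured, beta = ssf$beta, helix = ssf$helix)

  hdr <- function(path) file.path(out_dir, path)
  write_table(per_frame, hdr("per_frame.tsv"))
  write_table(per_res, hdr("per_residue.tsv"))
  write_fel(grid, hdr("fel_distance_contacts.tsv"))
  write_table(project_fel_1d(grid, "x"), hdr("fel_distance_1d.tsv"))
  write_table(basin_tab, hdr("basins.tsv"))
  if (!is.null(micro)) write_table(micro, hdr("microstates.tsv"))
  write_matrix(cmap, hdr("contact_map.tsv"))
  write_table(lr, hdr("longrange_pairs.tsv"))
  meta <- list(config_hash = chash, config = unclass(config),
               n_frames = length(traj$frames),
               package_version = as.character(utils::packageVersion("membind")))
  jsonlite::write_json(meta, hdr("run_meta.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  log("done: ", length(traj$frames), " frames analysed")
  report <- list(per_frame = per_frame, per_residue = per_res,
                 fel = grid, basins = basin_tab, microstates = micro,
                 contact_map = cmap, longrange = lr, config_hash = chash)
  class(report) <- "pipeline_report"
  invisible(report)
}
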