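# Bound/unbound partition, per-frame features, the four-binding-model
# classifier, and per-basin landscapes with microstates.

#' Per-frame features for classification
#'
#' Computes, for every frame: perpendicular peptide-bilayer distance,
#' contact counts (pairs and contacting residues), beta and helix content,
#' NT helix fraction, deepest residue depth, and the buried-residue
#' fraction (depth < 0) of each region.
#'
#' @param traj A `trajectory`.
#' @param config An `analysis_config`.
#' @param ss Optional precomputed assignment matrix from
#'   [secstruct_trajectory()].
#' @return Data frame, one row per frame.
#' @export
frame_features <- function(traj, config = analysis_config(), ss = NULL) {
  sys <- traj$topology
  map <- sys$region_map
  if (is.null(ss)) ss <- secstruct_trajectory(traj)
  regions <- region_of(map, sys$peptide_residues)
  helix_classes <- c("G", "H", "I")
  nt_res <- regions == "NT"
  rows <- lapply(seq_along(traj$frames), function(fi) {
    fr <- traj$frames[[fi]]
    cc <- count_contacts(sys, fr, config)
    depths <- residue_depths(sys, fr, config)
    buried <- depths < 0
    by_region <- tapply(buried, regions, mean)
    ssf <- ss[fi, ]
    data.frame(
      frame = fi,
      time = fr$time,
      distance = peptide_bilayer_distance(sys, fr),
      n_contacts = cc$n_contacts,
      n_contact_residues = sum(cc$residue_contact),
      beta = mean(ssf == "E"),
      helix = mean(ssf %in% helix_classes),
      nt_helix = mean(ssf[nt_res] %in% helix_classes),
      min_depth = min(depths),
      buried_NT = unname(by_region["NT"]),
      buried_CHC = unname(by_region["CHC"]),
      buried_CL = unname(by_region["CL"]),
      buried_CT = unname(by_region["CT"]))
  })
  do.call(rbind, rows)
}

#' Bound/unbound partition of a trajectory
#'
#' A frame is bound when it has at least one peptide-bilayer heavy-atom
#' contact (`n_contacts > 0`), unbound otherwise.
#'
#' @param traj A `trajectory`.
#' @param config An `analysis_config`.
#' @param n_contacts Optional precomputed per-frame contact counts.
#' @return Logical vector, `TRUE` for bound frames.
#' @export
partition_bound <- function(traj, config = analysis_config(),
                            n_contacts = NULL) {
  if (is.null(n_contacts)) {
    n_contacts <- vapply(traj$frames, function(f)
      count_contacts(traj$topology, f, config)$n_contacts, numeric(1))
  }
  n_contacts > 0
}

#' Classify frames into the four binding models
#'
#' Rule cascade (first match wins) on per-frame features:
#' \describe{
#'   \item{unbound}{no peptide-bilayer contact.}
#'   \item{model4}{at least half of CHC and of CT residues buried
#'     (depth < 0), beta content < 10\% and helix content < 10\% -- the
#'     deeply inserted random-coil state.}
#'   \item{model3}{at least half of CT buried and beta content in
#'     [10\%, 30\%) -- moderately beta-rich, C-terminus inserted.}
#'   \item{model1}{beta content in [30\%, 50\%], buried residues only in
#'     CT, and 2-15 contacting residues -- beta-rich, C-terminal anchor.}
#'   \item{model2}{NT helix fraction >= 20\%, no residue deeper than
#'     -0.2 nm, 2-15 contacting residues -- helical N-terminus lying on
#'     the surface.}
#'   \item{unclassified}{any remaining bound frame.}
#' }
#'
#' @param features Data frame from [frame_features()] (or one row).
#' @param config An `analysis_config`.
#' @return Character vector of labels.
#' @export
classify_binding_model <- function(features, config = analysis_config()) {
  need <- c("n_contacts", "n_contact_residues", "beta", "helix", "nt_helix",
            "min_depth", "buried_NT", "buried_CHC", "buried_CL", "buried_CT")
  missing_f <- setdiff(need, names(features))
  if (length(missing_f)) {
    stop("missing classifier feature(s): ", paste(missing_f, collapse = ", "))
  }
  cr <- config$contact_residues_range
  vapply(seq_len(nrow(features)), function(r) {
    f <- features[r, ]
    if (f$n_contacts == 0) return("unbound")
    if (f$buried_CHC >= 0.5 && f$buried_CT >= 0.5 &&
        f$beta < 0.10 && f$helix < 0.10) return("model4")
    if (f$buried_CT >= 0.5 && f$beta >= 0.10 && f$beta < 0.30) {
      return("model3")
    }
    if (f$beta >= 0.30 && f$beta <= 0.50 &&
        f$buried_NT == 0 && f$buried_CHC == 0 && f$buried_CL == 0 &&
        f$n_contact_residues >= cr[1] && f$n_contact_residues <= cr[2]) {
      return("model1")
    }
    if (f$nt_helix >= config$model2_nt_helix_min &&
        f$min_depth > config$model2_max_burial &&
        f$n_contact_residues >= cr[1] && f$n_contact_residues <= cr[2]) {
      return("model2")
    }
    "unclassified"
  }, character(1))
}

#' Per-basin free-energy landscape over (RMSD, beta content)
#'
#' Restricts the ensemble to a basin's member frames, computes heavy-atom
#' RMSD to a reference conformation and per-frame beta content, builds the
#' 2D landscape, and extracts microstates (sub-basins). Microstates are
#' grouped by mean beta content: group "1" at or above the configured
#' threshold, group "2" below, giving labels like `"c1"`, `"c2"`.
#'
#' @param traj A `trajectory`.
#' @param member_frames Frame indices belonging to the basin.
#' @param reference `n x 3` reference coordinates of the peptide heavy
#'   atoms (e.g. frame 1), nm.
#' @param config An `analysis_config`.
#' @param basin_label Basin letter used as the microstate label prefix.
#' @param ss Optional precomputed assignment matrix.
#' @return List: `grid` (`fel_grid`), `microstates` (data frame),
#'   `frame_microstate` (label per member frame), `rmsd`, `beta`.
#' @export
per_basin_fel <- function(traj, member_frames, reference,
                          config = analysis_config(), basin_label = "x",
                          ss = NULL) {
  if (!length(member_frames)) stop("basin has no member frames")
  if (length(member_frames) < 10) {
    warning("basin has only ", length(member_frames), " member frames")
  }
  sys <- traj$topology
  pep <- sys$idx$peptide_heavy
  rmsd <- vapply(member_frames, function(fi)
    kabsch_rmsd(reference, traj$frames[[fi]]$coords[pep, , drop = FALSE]),
    numeric(1))
  if (is.null(ss)) ss <- secstruct_trajectory(traj, frames = member_frames)
  beta <- apply(ss, 1, beta_content)
  grid <- compute_fel_2d(rmsd, beta, config$fel_bins_rmsd,
                         config$fel_bins_beta, "rmsd", "beta", config)
  bs <- find_basins(grid, config$basin_min_depth_kT,
                    config$basin_min_separation_bins)
  micro <- bs$basins
  mean_beta <- vapply(micro$label, function(l)
    mean(beta[bs$sample_basin == l]), numeric(1))
  group <- ifelse(mean_beta >= config$microstate_beta_threshold, "1", "2")
  micro$mean_beta <- mean_beta
  micro$microstate <- paste0(basin_label, group)
  frame_micro <- micro$microstate[match(bs$sample_basin, micro$label)]
  list(grid = grid, microstates = micro, frame_microstate = frame_micro,
       rmsd = rmsd, beta = beta)
}
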