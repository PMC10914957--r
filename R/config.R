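# Analysis configuration: every numeric criterion of the pipeline in one
# place, so no stage hard-codes a threshold.

#' Default residue-region map for the 40-residue peptide
#'
#' Regions follow the standard functional division of amyloid-beta (1-40):
#' hydrophilic N-terminus NT (residues 1-16), central hydrophobic core CHC
#' (17-21), central loop CL (22-29) and hydrophobic C-terminus CT (30-40).
#'
#' @return A `region_map` data frame with columns `label`, `first`, `last`.
#' @export
default_region_map <- function() {
  region_map(data.frame(
    label = c("NT", "CHC", "CL", "CT"),
    first = c(1L, 17L, 22L, 30L),
    last  = c(16L, 21L, 29L, 40L),
    stringsAsFactors = FALSE
  ))
}

#' Construct and validate a region map
#'
#' Regions must partition residues `1..n` contiguously and in order.
#'
#' @param df Data frame with columns `label`, `first`, `last`.
#' @return Validated `region_map`.
#' @export
region_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("label", "first", "last") %in% names(df)))
  df$first <- as.integer(df$first)
  df$last <- as.integer(df$last)
  if (df$first[1] != 1L) stop("region map must start at residue 1")
  if (nrow(df) > 1 && any(df$first[-1] != df$last[-nrow(df)] + 1L)) {
    stop("regions must be contiguous and ordered")
  }
  if (any(df$last < df$first)) stop("region with last < first")
  class(df) <- c("region_map", "data.frame")
  df
}

#' Region label of a peptide residue
#'
#' @param map A `region_map`.
#' @param residue Residue index (1-based). Must lie inside the map.
#' @return Character vector of region labels.
#' @export
region_of <- function(map, residue) {
  residue <- as.integer(residue)
  n_max <- max(map$last)
  if (any(residue < 1L | residue > n_max)) {
    stop("residue index outside region map (1..", n_max, "): ",
         paste(residue[residue < 1L | residue > n_max], collapse = ", "))
  }
  idx <- findInterval(residue, map$first)
  as.character(map$label[idx])
}

#' Analysis configuration
#'
#' Collects every numeric criterion used by the pipeline. Defaults implement
#' the standard analysis protocol: 0.5 nm heavy-atom contact cutoff, 0.3 nm
#' donor-acceptor / 20 degree hydrogen-bond criterion, 2.0 nm membrane
#' half-thickness, 343 K, and a 200 ns equilibration discard.
#'
#' @param contact_cutoff Heavy-atom contact cutoff, nm (closed comparison,
#'   i.e. a pair exactly at the cutoff counts).
#' @param hbond_da_cutoff Donor-acceptor heavy-atom distance cutoff, nm.
#' @param hbond_angle_cutoff H-bond angle cutoff, degrees.
#' @param hbond_angle_convention `"donor"` compares the angle between the
#'   D->H and D->A vectors against the cutoff (VMD-style); `"dha"` instead
#'   requires the D-H...A angle to be at least `180 - cutoff` degrees.
#' @param met_sulfur_acceptor Should methionine SD count as an acceptor?
#' @param half_thickness Membrane half thickness, nm.
#' @param temperature Analysis temperature, K.
#' @param kB Boltzmann constant, kcal/(mol K).
#' @param fel_bins_distance Distance bin width for landscapes, nm.
#' @param fel_bins_contacts Contact-count bin width for landscapes.
#' @param fel_bins_rmsd RMSD bin width, nm.
#' @param fel_bins_beta Beta-content bin width (fraction).
#' @param basin_min_depth_kT Minimum depth below the shallowest saddle-free
#'   reference (global minimum + depth) for a local minimum to count as a
#'   basin, in kT.
#' @param basin_min_separation_bins Minimum Chebyshev grid separation between
#'   retained basin minima.
#' @param microstate_beta_threshold Mean beta content separating high-beta
#'   ("x1") from low-beta ("x2") microstate groups.
#' @param equilibration_discard Initial trajectory time to discard, ns.
#' @param longrange_min_separation Minimum `|i - j|` for a residue pair to
#'   count as long-range.
#' @param frame_spacing Time between trajectory frames when the format
#'   carries no time stamps (multi-model PDB), ns.
#' @param model2_nt_helix_min Minimum NT helix fraction for binding model 2.
#' @param model2_max_burial Deepest allowed residue depth (nm) for binding
#'   model 2 (surface-lying N-terminus).
#' @param contact_residues_range Allowed number of membrane-contacting
#'   residues for binding models 1 and 2 (inclusive).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(contact_cutoff = 0.5,
                            hbond_da_cutoff = 0.3,
                            hbond_angle_cutoff = 20,
                            hbond_angle_convention = c("donor", "dha"),
                            met_sulfur_acceptor = FALSE,
                            half_thickness = 2.0,
                            temperature = 343,
                            kB = KB_KCAL,
                            fel_bins_distance = 0.05,
                            fel_bins_contacts = 10,
                            fel_bins_rmsd = 0.05,
                            fel_bins_beta = 0.025,
                            basin_min_depth_kT = 1.0,
                            basin_min_separation_bins = 2L,
                            microstate_beta_threshold = 0.20,
                            equilibration_discard = 200,
                            longrange_min_separation = 3L,
                            frame_spacing = 1,
                            model2_nt_helix_min = 0.20,
                            model2_max_burial = -0.2,
                            contact_residues_range = c(2L, 15L)) {
  hbond_angle_convention <- match.arg(hbond_angle_convention)
  cfg <- list(
    contact_cutoff = contact_cutoff,
    hbond_da_cutoff = hbond_da_cutoff,
    hbond_angle_cutoff = hbond_angle_cutoff,
    hbond_angle_convention = hbond_angle_convention,
    met_sulfur_acceptor = isTRUE(met_sulfur_acceptor),
    half_thickness = half_thickness,
    temperature = temperature,
    kB = kB,
    fel_bins_distance = fel_bins_distance,
    fel_bins_contacts = fel_bins_contacts,
    fel_bins_rmsd = fel_bins_rmsd,
    fel_bins_beta = fel_bins_beta,
    basin_min_depth_kT = basin_min_depth_kT,
    basin_min_separation_bins = as.integer(basin_min_separation_bins),
    microstate_beta_threshold = microstate_beta_threshold,
    equilibration_discard = equilibration_discard,
    longrange_min_separation = as.integer(longrange_min_separation),
    frame_spacing = frame_spacing,
    model2_nt_helix_min = model2_nt_helix_min,
    model2_max_burial = model2_max_burial,
    contact_residues_range = as.integer(contact_residues_range)
  )
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("contact_cutoff", "hbond_da_cutoff", "half_thickness",
           "temperature", "kB", "fel_bins_distance", "fel_bins_contacts",
           "fel_bins_rmsd", "fel_bins_beta", "frame_spacing")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive scalar")
    }
  }
  if (cfg$hbond_angle_cutoff <= 0 || cfg$hbond_angle_cutoff >= 180) {
    stop("hbond_angle_cutoff must lie in (0, 180)")
  }
  if (cfg$equilibration_discard < 0) stop("equilibration_discard must be >= 0")
  if (cfg$longrange_min_separation < 1) {
    stop("longrange_min_separation must be >= 1")
  }
  invisible(cfg)
}

#' Read an analysis configuration from a JSON file
#'
#' Unknown keys are rejected to catch typos. A region map may be supplied
#' under key `"regions"` as a list of `{label, first, last}` records; it is
#' returned in the `region_map` attribute.
#'
#' @param path JSON file whose keys mirror [analysis_config()] arguments.
#' @return `analysis_config`, possibly with attribute `region_map`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  regions <- NULL
  if (!is.null(raw$regions)) {
    regions <- region_map(as.data.frame(raw$regions))
    raw$regions <- NULL
  }
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- do.call(analysis_config, raw)
  if (!is.null(regions)) attr(cfg, "region_map") <- regions
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-26s %s\n", f, paste(format(x[[f]]), collapse = " ")))
  }
  invisible(x)
}
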