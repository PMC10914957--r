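# Core domain types: structured system topology, frames, trajectories.

#' Build an atom-record table
#'
#' @param serial Unique positive integer atom serials.
#' @param name Atom names (PDB conventions).
#' @param residue_index 1-based residue indices.
#' @param residue_name Residue names (three-letter amino acids, POPC, POPS,
#'   CHOL/CHL1, water and ion names).
#' @param mass Optional masses (amu); inferred from the element if missing.
#' @param group Optional group labels; inferred from `residue_name` if
#'   missing.
#' @return Data frame of atom records with `element`, `element_class`,
#'   `mass` and `group` filled in.
#' @export
atom_records <- function(serial, name, residue_index, residue_name,
                         mass = NULL, group = NULL) {
  n <- length(serial)
  if (length(residue_name) == 1) residue_name <- rep(residue_name, n)
  stopifnot(length(name) == n, length(residue_index) == n,
            length(residue_name) == n)
  serial <- as.integer(serial)
  if (anyDuplicated(serial)) stop("atom serials must be unique")
  if (any(serial < 1L)) stop("atom serials must be >= 1")
  element <- infer_element(name, residue_name)
  if (is.null(mass)) mass <- element_mass(element)
  if (any(mass <= 0)) stop("atom masses must be positive")
  if (is.null(group)) group <- infer_group(residue_name)
  if (!all(group %in% GROUP_LEVELS)) {
    stop("invalid group label(s): ",
         paste(setdiff(unique(group), GROUP_LEVELS), collapse = ", "))
  }
  data.frame(
    serial = serial, name = as.character(name), element = element,
    element_class = ifelse(element == "H", "hydrogen", "heavy"),
    mass = as.numeric(mass),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    group = group, stringsAsFactors = FALSE
  )
}

#' Assemble a structured system from atom records
#'
#' Groups atoms into peptide / per-species lipid / water / ion, attaches
#' region labels to peptide residues, and precomputes the heavy-atom index
#' sets used throughout the pipeline. The "bilayer" selection is the union
#' of the three lipid groups; water and ions are excluded from it.
#'
#' @param atoms Atom-record data frame from [atom_records()].
#' @param map Region map; defaults to [default_region_map()].
#' @return A `structured_system`.
#' @export
build_system <- function(atoms, map = default_region_map()) {
  if (!all(c("serial", "name", "group", "mass", "element_class") %in%
           names(atoms))) {
    atoms <- atom_records(atoms$serial, atoms$name, atoms$residue_index,
                          atoms$residue_name, atoms$mass, atoms$group)
  }
  pep <- atoms$group == "peptide"
  pep_res <- sort(unique(atoms$residue_index[pep]))
  if (length(pep_res)) {
    out_of_map <- pep_res[pep_res < 1L | pep_res > max(map$last)]
    if (length(out_of_map)) {
      stop("peptide residue(s) outside region map: ",
           paste(out_of_map, collapse = ", "))
    }
  }
  region <- rep(NA_character_, nrow(atoms))
  region[pep] <- region_of(map, atoms$residue_index[pep])
  atoms$region <- region
  heavy <- atoms$element_class == "heavy"
  sys <- list(
    atoms = atoms,
    region_map = map,
    peptide_residues = pep_res,
    idx = list(
      peptide = which(pep),
      peptide_heavy = which(pep & heavy),
      bilayer = which(atoms$group %in% LIPID_GROUPS),
      bilayer_heavy = which(atoms$group %in% LIPID_GROUPS & heavy),
      water = which(atoms$group == "water"),
      ion = which(atoms$group == "ion")
    )
  )
  class(sys) <- "structured_system"
  sys
}

#' @export
print.structured_system <- function(x, ...) {
  tab <- table(factor(x$atoms$group, levels = GROUP_LEVELS))
  cat("<structured_system> ", nrow(x$atoms), " atoms\n", sep = "")
  for (g in names(tab)) if (tab[[g]] > 0) cat("  ", g, ": ", tab[[g]], "\n",
                                              sep = "")
  invisible(x)
}

#' Construct a trajectory frame
#'
#' @param coords Numeric `n x 3` matrix of coordinates, nm.
#' @param box Length-3 orthorhombic box edge lengths, nm.
#' @param time Time stamp, ns.
#' @return A `frame`.
#' @export
new_frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box edges must be 3 positive numbers")
  if (time < 0) stop("frame time must be >= 0")
  structure(list(coords = coords, box = box, time = time), class = "frame")
}

#' Construct a trajectory ensemble
#'
#' @param topology A `structured_system`.
#' @param frames List of `frame` objects with non-decreasing times and atom
#'   counts matching the topology.
#' @param label Free-text label.
#' @return A `trajectory`.
#' @export
new_trajectory <- function(topology, frames, label = "") {
  stopifnot(inherits(topology, "structured_system"))
  n_atoms <- nrow(topology$atoms)
  times <- vapply(frames, function(f) f$time, numeric(1))
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != n_atoms) {
      stop("frame ", i, " has ", nrow(frames[[i]]$coords),
           " atoms; topology has ", n_atoms)
    }
  }
  if (length(times) > 1 && any(diff(times) < 0)) {
    stop("frame times must be non-decreasing")
  }
  structure(list(topology = topology, frames = frames, label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  times <- frame_times(x)
  cat("<trajectory> ", length(x$frames), " frames, ",
      nrow(x$topology$atoms), " atoms",
      if (nzchar(x$label)) paste0(", '", x$label, "'") else "", "\n", sep = "")
  if (length(times)) cat("  time ", min(times), " .. ", max(times), " ns\n",
                         sep = "")
  invisible(x)
}

#' Frame time stamps of a trajectory
#' @param traj A `trajectory`.
#' @return Numeric vector of times (ns).
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, function(f) f$time, numeric(1))
}

#' Restrict a trajectory to a time window
#'
#' Keeps frames with `t_min <= time <= t_max` (both bounds inclusive),
#' preserving order. Used to discard the equilibration transient before
#' analysis. An empty result is returned with a warning so callers can
#' decide whether that is fatal.
#'
#' @param traj A `trajectory`.
#' @param t_min,t_max Window bounds, ns.
#' @return A `trajectory` with the retained frames.
#' @export
filter_time_window <- function(traj, t_min, t_max) {
  if (t_min > t_max) stop("t_min must be <= t_max")
  times <- frame_times(traj)
  keep <- times >= t_min & times <= t_max
  if (!any(keep)) {
    warning("time window [", t_min, ", ", t_max, "] selects no frames")
  }
  out <- traj
  out$frames <- traj$frames[keep]
  out
}
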