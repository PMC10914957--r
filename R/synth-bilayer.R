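# Synthetic bilayer: two leaflets of coarse pseudo-lipids on jittered
# lattices. Headgroup heavy atoms (phosphate-like acceptor cluster) sit at
# bilayer_center +- half_thickness; tail atoms fill the interior. The
# default composition is 54 POPC / 18 POPS / 18 CHOL per leaflet
# (POPC:POPS:CHOL = 3:1:1, 180 lipids in total).

# Per-species atom templates: name, element-implied mass, and offsets
# (dx, dy, dzh) where dzh is the offset from the headgroup plane toward
# the solvent (+) or the bilayer center (-).
.LIPID_TEMPLATE <- list(
  POPC = data.frame(
    name = c("NC", "P", "OP1", "OP2", "OP3", "OP4", "C1", "C2", "C3"),
    dx = c(0, 0, 0.16, -0.16, 0.16, -0.16, 0, 0.05, -0.05),
    dy = c(0, 0, 0.16, 0.16, -0.16, -0.16, 0, 0.05, -0.05),
    dzh = c(0.12, 0, 0, 0, 0, 0, -0.6, -1.2, -1.7),
    stringsAsFactors = FALSE),
  POPS = data.frame(
    name = c("N", "HN1", "P", "OP1", "OP2", "OP3", "OP4", "C1", "C2", "C3"),
    dx = c(0.10, 0.10, 0, 0.16, -0.16, 0.16, -0.16, 0, 0.05, -0.05),
    dy = c(0, 0, 0, 0.16, 0.16, -0.16, -0.16, 0, 0.05, -0.05),
    dzh = c(0.10, 0.20, 0, 0, 0, 0, 0, -0.6, -1.2, -1.7),
    stringsAsFactors = FALSE),
  CHOL = data.frame(
    name = c("O3", "HO3", "C1", "C2", "C3", "C4"),
    dx = c(0, 0, 0, 0.05, -0.05, 0),
    dy = c(0, 0, 0, 0.05, 0.05, -0.05),
    dzh = c(0, 0.10, -0.4, -0.8, -1.2, -1.6),
    stringsAsFactors = FALSE)
)

#' Build a synthetic two-leaflet bilayer
#'
#' Pseudo-lipids are placed on a square lattice per leaflet with a small
#' lateral jitter; the two leaflets mirror each other exactly, so the
#' bilayer center of mass sits at `center_z` by symmetry. The box is sized
#' by the lattice unless overridden.
#'
#' @param per_leaflet Named counts per leaflet,
#'   `c(POPC = 54, POPS = 18, CHOL = 18)` by default.
#' @param spacing Lattice spacing, nm.
#' @param center_z Bilayer center height, nm.
#' @param half_thickness Headgroup-plane offset from the center, nm.
#' @param box_z Box height, nm.
#' @param box_xy Optional lateral box edges; must fit the lattice.
#' @param jitter Lateral jitter SD, nm (truncated at 2.5 SD so head
#'   clusters keep covering the plane).
#' @param seed RNG seed (species layout and jitter).
#' @param resid_start First residue index for the lipids.
#' @return List: `records`, `coords`, `box`, `center_z`, `surface_z`,
#'   `species` (per lipid), `lipid_first_atom` (row of each lipid's first
#'   atom).
#' @export
build_bilayer <- function(per_leaflet = c(POPC = 54, POPS = 18, CHOL = 18),
                          spacing = 0.65, center_z = 4.0,
                          half_thickness = 2.0, box_z = 14,
                          box_xy = NULL, jitter = 0.02, seed = 1,
                          resid_start = 41L) {
  stopifnot(all(per_leaflet >= 0))
  n_leaf <- sum(per_leaflet)
  if (n_leaf == 0) stop("empty bilayer")
  nx <- ceiling(sqrt(n_leaf))
  ny <- ceiling(n_leaf / nx)
  if (!is.null(box_xy)) {
    if (box_xy[1] < nx * spacing || box_xy[2] < ny * spacing) {
      stop("too many lipids for the requested box: need ",
           nx * spacing, " x ", ny * spacing, " nm")
    }
    bx <- box_xy[1]; by <- box_xy[2]
  } else {
    bx <- nx * spacing; by <- ny * spacing
  }
  set.seed(seed)
  species <- sample(rep(names(per_leaflet), times = per_leaflet))
  sites <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  sites <- sites[seq_len(n_leaf), , drop = FALSE]
  jx <- pmin(pmax(stats::rnorm(n_leaf, 0, jitter), -2.5 * jitter),
             2.5 * jitter)
  jy <- pmin(pmax(stats::rnorm(n_leaf, 0, jitter), -2.5 * jitter),
             2.5 * jitter)
  cx <- (sites$ix + 0.5) * spacing + jx
  cy <- (sites$iy + 0.5) * spacing + jy

  rows <- list()
  resid <- resid_start - 1L
  lipid_first_atom <- integer(0)
  n_atoms <- 0L
  all_species <- character(0)
  for (leaflet in c(1, -1)) {
    z_head <- center_z + leaflet * half_thickness
    for (l in seq_len(n_leaf)) {
      sp <- species[l]
      tmpl <- .LIPID_TEMPLATE[[sp]]
      resid <- resid + 1L
      lipid_first_atom <- c(lipid_first_atom, n_atoms + 1L)
      all_species <- c(all_species, sp)
      rows[[length(rows) + 1]] <- data.frame(
        residue_index = resid, residue_name = sp, name = tmpl$name,
        x = cx[l] + tmpl$dx, y = cy[l] + tmpl$dy,
        z = z_head + leaflet * tmpl$dzh, stringsAsFactors = FALSE)
      n_atoms <- n_atoms + nrow(tmpl)
    }
  }
  tab <- do.call(rbind, rows)
  rec <- atom_records(seq_len(nrow(tab)), tab$name, tab$residue_index,
                      tab$residue_name)
  list(records = rec, coords = as.matrix(tab[, c("x", "y", "z")]),
       box = c(bx, by, box_z), center_z = center_z,
       surface_z = center_z + half_thickness,
       species = all_species, lipid_first_atom = lipid_first_atom)
}
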