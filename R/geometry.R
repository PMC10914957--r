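# PBC-aware geometry: minimum-image distances, centers of mass, contacts,
# insertion depths, contact maps, Kabsch RMSD.
#
# The membrane normal is the z axis throughout (standard bilayer-builder
# convention); "perpendicular" distances are z-component distances.

#' Minimum-image distance under an orthorhombic box
#'
#' @param p,q Length-3 coordinate vectors, nm.
#' @param box Length-3 box edges, nm.
#' @return Euclidean distance to the nearest periodic image, nm.
#' @export
min_image_distance <- function(p, q, box) {
  d <- p - q
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# All pairwise min-image distances between coordinate sets a (n x 3) and
# b (m x 3); returns an n x m matrix. O(n*m) memory -- callers keep sets small
# or go through the cell list.
pairwise_min_image <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Mass-weighted center of mass of an atom subset
#'
#' The subset is assumed whole (not split across periodic boundaries); the
#' pipeline requires whole-molecule input and does not re-wrap.
#'
#' @param system A `structured_system`.
#' @param frame A `frame`.
#' @param index Atom indices (row positions in the atom table).
#' @return Length-3 position, nm.
#' @export
center_of_mass <- function(system, frame, index) {
  if (!length(index)) stop("center_of_mass of an empty atom subset")
  m <- system$atoms$mass[index]
  colSums(frame$coords[index, , drop = FALSE] * m) / sum(m)
}

#' Perpendicular peptide-bilayer center-of-mass distance
#'
#' @param system A `structured_system` with nonempty peptide and lipid
#'   groups.
#' @param frame A `frame`.
#' @return `|z_COM(peptide) - z_COM(bilayer)|` in nm.
#' @export
peptide_bilayer_distance <- function(system, frame) {
  zp <- center_of_mass(system, frame, system$idx$peptide)[3]
  zb <- center_of_mass(system, frame, system$idx$bilayer)[3]
  unname(abs(zp - zb))
}

#' Per-residue insertion depths
#'
#' Depth of a residue is its perpendicular COM distance from the bilayer COM
#' minus the membrane half thickness; negative values are buried below the
#' bilayer surface.
#'
#' @param system A `structured_system`.
#' @param frame A `frame`.
#' @param config An `analysis_config` (uses `half_thickness`).
#' @return Named numeric vector, one depth (nm) per peptide residue.
#' @export
residue_depths <- function(system, frame, config = analysis_config()) {
  zb <- center_of_mass(system, frame, system$idx$bilayer)[3]
  at <- system$atoms
  pep <- system$idx$peptide
  res <- at$residue_index[pep]
  mz <- at$mass[pep] * frame$coords[pep, 3]
  z_res <- rowsum(mz, res) / rowsum(at$mass[pep], res)
  depths <- abs(z_res[, 1] - zb) - config$half_thickness
  names(depths) <- rownames(z_res)
  depths
}

# Wrap coordinates into [0, box) per dimension.
.wrap <- function(x, box) {
  x - rep(box, each = nrow(x)) * floor(x / rep(box, each = nrow(x)))
}

# Cell-list pair search: returns for selections a, b the number of pairs with
# min-image distance <= cutoff and a logical flag per atom of `a` that has at
# least one such pair. Cells are at least `cutoff` wide so only the 27
# neighbouring cells need scanning.
cell_list_contacts <- function(coords_a, coords_b, box, cutoff) {
  na <- nrow(coords_a)
  wa <- .wrap(coords_a, box)
  wb <- .wrap(coords_b, box)
  nc <- pmax(1L, as.integer(floor(box / cutoff)))
  cell_of <- function(w) {
    ix <- pmin(nc[1] - 1L, as.integer(floor(w[, 1] / (box[1] / nc[1]))))
    iy <- pmin(nc[2] - 1L, as.integer(floor(w[, 2] / (box[2] / nc[2]))))
    iz <- pmin(nc[3] - 1L, as.integer(floor(w[, 3] / (box[3] / nc[3]))))
    list(ix = ix, iy = iy, iz = iz,
         id = ix + nc[1] * (iy + nc[2] * iz))
  }
  ca <- cell_of(wa)
  cb <- cell_of(wb)
  b_by_cell <- split(seq_len(nrow(wb)), cb$id)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  n_pairs <- 0L
  a_hit <- logical(na)
  for (cid in unique(ca$id)) {
    a_idx <- which(ca$id == cid)
    cx <- cid %% nc[1]
    cy <- (cid %/% nc[1]) %% nc[2]
    cz <- cid %/% (nc[1] * nc[2])
    nx <- (cx + off[, 1]) %% nc[1]
    ny <- (cy + off[, 2]) %% nc[2]
    nz <- (cz + off[, 3]) %% nc[3]
    nb_ids <- unique(nx + nc[1] * (ny + nc[2] * nz))
    b_idx <- unlist(b_by_cell[as.character(nb_ids)], use.names = FALSE)
    if (!length(b_idx)) next
    d <- pairwise_min_image(wa[a_idx, , drop = FALSE],
                            wb[b_idx, , drop = FALSE], box)
    hit <- d <= cutoff
    n_pairs <- n_pairs + sum(hit)
    a_hit[a_idx] <- a_hit[a_idx] | (rowSums(hit) > 0)
  }
  list(n_pairs = n_pairs, a_has_contact = a_hit)
}

# Brute-force O(n*m) reference used as the second route of the dual contact
# check; kept simple on purpose.
brute_force_contacts <- function(coords_a, coords_b, box, cutoff) {
  d <- pairwise_min_image(coords_a, coords_b, box)
  hit <- d <= cutoff
  list(n_pairs = sum(hit), a_has_contact = rowSums(hit) > 0)
}

#' Count heavy-atom contacts between two selections in one frame
#'
#' A contact is a pair of heavy atoms, one from each selection, whose
#' minimum-image distance is at most `contact_cutoff` (closed comparison: a
#' pair exactly at the cutoff counts). Hydrogens in either selection are
#' ignored. Per-residue flags are reported for the peptide residues present
#' in `selection_a`.
#'
#' @param system A `structured_system`.
#' @param frame A `frame`.
#' @param config An `analysis_config`.
#' @param selection_a,selection_b Disjoint atom index vectors; defaults are
#'   peptide heavy atoms vs bilayer heavy atoms.
#' @param method `"cell"` (cell list, default) or `"brute"` (O(n*m)
#'   reference path).
#' @return List with `n_contacts`, `residue_contact` (named logical per
#'   residue of selection_a) and `atom_contact` (per atom of selection_a).
#' @export
count_contacts <- function(system, frame, config = analysis_config(),
                           selection_a = system$idx$peptide_heavy,
                           selection_b = system$idx$bilayer_heavy,
                           method = c("cell", "brute")) {
  method <- match.arg(method)
  if (length(intersect(selection_a, selection_b))) {
    stop("contact selections must be disjoint")
  }
  heavy <- system$atoms$element_class == "heavy"
  selection_a <- selection_a[heavy[selection_a]]
  selection_b <- selection_b[heavy[selection_b]]
  fun <- if (method == "cell") cell_list_contacts else brute_force_contacts
  res <- fun(frame$coords[selection_a, , drop = FALSE],
             frame$coords[selection_b, , drop = FALSE],
             frame$box, config$contact_cutoff)
  res_idx <- system$atoms$residue_index[selection_a]
  per_res <- tapply(res$a_has_contact, res_idx, any)
  list(n_contacts = res$n_pairs,
       residue_contact = per_res,
       atom_contact = res$a_has_contact)
}

#' Per-residue membrane contact fractions over an ensemble
#'
#' Fraction of frames in which each peptide residue has at least one heavy
#' atom within the contact cutoff of the bilayer. With `bound_only = TRUE`
#' only frames with at least one peptide-bilayer contact enter the
#' denominator.
#'
#' @param traj A `trajectory`.
#' @param config An `analysis_config`.
#' @param bound_only Restrict to bound frames?
#' @return List: `fraction` (named per residue), `mean` (all-residue mean),
#'   `n_frames_used`, and the per-frame matrices `residue_contact` and
#'   vector `n_contacts`.
#' @export
contact_fractions <- function(traj, config = analysis_config(),
                              bound_only = FALSE) {
  if (!length(traj$frames)) stop("contact_fractions on an empty ensemble")
  sys <- traj$topology
  per_frame <- lapply(traj$frames, function(f)
    count_contacts(sys, f, config))
  flags <- do.call(rbind, lapply(per_frame, function(r)
    as.logical(r$residue_contact)))
  colnames(flags) <- names(per_frame[[1]]$residue_contact)
  n_contacts <- vapply(per_frame, function(r) r$n_contacts, numeric(1))
  use <- if (bound_only) n_contacts > 0 else rep(TRUE, length(n_contacts))
  if (!any(use)) stop("no frames available (bound_only selected none)")
  frac <- colMeans(flags[use, , drop = FALSE])
  list(fraction = frac, mean = mean(frac), n_frames_used = sum(use),
       residue_contact = flags, n_contacts = n_contacts)
}

#' Intra-peptide residue-residue contact probability map
#'
#' Two residues are in contact in a frame when any of their heavy atoms lie
#' within the contact cutoff (minimum image). Probabilities average the
#' per-frame indicator over the ensemble; the diagonal is forced to 1.
#'
#' @param traj A `trajectory`.
#' @param config An `analysis_config`.
#' @param frames Optional subset of frame indices.
#' @return Symmetric `n_res x n_res` probability matrix.
#' @export
residue_contact_map <- function(traj, config = analysis_config(),
                                frames = NULL) {
  sys <- traj$topology
  pep <- sys$idx$peptide_heavy
  res <- sys$atoms$residue_index[pep]
  res_levels <- sort(unique(res))
  ind <- outer(res, res_levels, "==") * 1
  if (is.null(frames)) frames <- seq_along(traj$frames)
  acc <- matrix(0, length(res_levels), length(res_levels))
  for (fi in frames) {
    d <- pairwise_min_image(traj$frames[[fi]]$coords[pep, , drop = FALSE],
                            traj$frames[[fi]]$coords[pep, , drop = FALSE],
                            traj$frames[[fi]]$box)
    adj <- (d <= config$contact_cutoff) * 1
    rr <- t(ind) %*% adj %*% ind
    acc <- acc + (rr > 0)
  }
  p <- acc / length(frames)
  diag(p) <- 1
  dimnames(p) <- list(res_levels, res_levels)
  p
}

#' Top long-range residue pairs of a contact map
#'
#' Ranks pairs with `|i - j| >= longrange_min_separation` by contact
#' probability; ties break by `(i, j)` lexicographic order, so the ranking
#' is deterministic.
#'
#' @param map Symmetric contact probability matrix.
#' @param k Number of pairs to return (all available pairs if larger).
#' @param config An `analysis_config`.
#' @return Data frame `i`, `j`, `probability`, sorted.
#' @export
top_longrange_pairs <- function(map, k, config = analysis_config()) {
  n <- nrow(map)
  idx <- which(upper.tri(map), arr.ind = TRUE)
  sep <- abs(idx[, 1] - idx[, 2])
  keep <- sep >= config$longrange_min_separation
  idx <- idx[keep, , drop = FALSE]
  p <- map[idx]
  ord <- order(-p, idx[, 1], idx[, 2])
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(i = as.integer(idx[ord, 1]), j = as.integer(idx[ord, 2]),
             probability = p[ord])
}

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Superposes `coords` onto `reference` with the optimal proper rotation
#' (determinant +1; the reflection case is handled by flipping the smallest
#' singular direction) and translation, then reports the RMSD.
#'
#' @param reference,coords `n x 3` coordinate matrices, equal `n >= 3`.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(reference, coords) {
  if (!identical(dim(reference), dim(coords))) {
    stop("coordinate sets differ in size: ", nrow(reference), " vs ",
         nrow(coords))
  }
  if (nrow(reference) < 3) stop("need at least 3 atoms for superposition")
  p <- sweep(coords, 2, colMeans(coords))
  q <- sweep(reference, 2, colMeans(reference))
  if (qr(p)$rank < 2 || qr(q)$rank < 2) {
    stop("collinear coordinates: superposition is degenerate")
  }
  s <- svd(t(p) %*% q)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  pr <- p %*% t(rot)
  sqrt(mean(rowSums((pr - q)^2)))
}
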