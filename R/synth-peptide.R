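# Synthetic peptide construction: ideal-geometry backbone chaining (NeRF)
# for helix/strand/coil templates, rigid sheet assembly for beta-rich
# conformations, and smooth-path coil conformations.
#
# Ideal backbone geometry (nm / degrees): N-CA 0.1458, CA-C 0.1525,
# C-N 0.1329, C=O 0.1231; angles N-CA-C 111.0, CA-C-N 116.2, C-N-CA 121.7,
# CA-C-O 120.5; omega 180. Template dihedrals: helix (-57, -47), strand
# (-139, 135), coil drawn from broad basins.

.BOND_N_CA <- 0.1458
.BOND_CA_C <- 0.1525
.BOND_C_N <- 0.1329
.BOND_C_O <- 0.1231
.ANG_N_CA_C <- 111.0
.ANG_CA_C_N <- 116.2
.ANG_C_N_CA <- 121.7
.ANG_CA_C_O <- 120.5

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
.unit <- function(v) v / sqrt(sum(v * v))

# Natural-extension reference frame: place atom d bonded to c with the given
# bond length, angle b-c-d and torsion a-b-c-d (degrees).
.place_nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

.TEMPLATE_DIHEDRALS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135)
)

.SITE_ATOMS <- list(
  R = c("NH1", "HH11"), K = c("NZ", "HZ1"), D = "OD1", E = "OE1",
  N = c("OD1", "ND2", "HD21"), Q = c("OE1", "NE2", "HE21"), H = "NE2",
  S = c("OG", "HG"), T = c("OG1", "HG1"), Y = c("OH", "HH"),
  W = c("NE1", "HE1"), M = "SD"
)

# Side-chain site positions relative to CA/CB.
.site_positions <- function(letter, ca, cb) {
  sites <- .SITE_ATOMS[[letter]]
  if (is.null(sites)) return(NULL)
  u <- .unit(cb - ca)
  ref <- if (abs(u[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  w <- .unit(.cross3(u, ref))
  pos <- list()
  if (letter %in% c("N", "Q")) {
    acc <- cb + 0.20 * u + 0.15 * w
    dn <- cb + 0.20 * u - 0.15 * w
    pos[[sites[1]]] <- acc
    pos[[sites[2]]] <- dn
    pos[[sites[3]]] <- dn + 0.101 * .unit(dn - cb)
  } else {
    d <- cb + 0.24 * u
    pos[[sites[1]]] <- d
    if (length(sites) > 1) pos[[sites[2]]] <- d + 0.101 * u
  }
  pos
}

# Append one residue's atoms (given backbone positions) to the growing
# coordinate table.
.emit_residue <- function(acc, i, letter, n, ca, c, o, h, cb, extra_u = NULL) {
  add <- function(name, p) {
    acc[[length(acc) + 1]] <<- data.frame(
      residue_index = i, letter = letter, name = name,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }
  add("N", n)
  if (!is.null(h)) add("H", h)
  add("CA", ca)
  add("C", c)
  add("O", o)
  if (letter != "G") {
    add("CB", cb)
    sp <- .site_positions(letter, ca, cb)
    for (nm in names(sp)) add(nm, sp[[nm]])
  }
  acc
}

# amide H on the bisector-opposed direction (matches the DSSP
# reconstruction, so explicit and reconstructed hydrogens agree)
.amide_h <- function(c_prev, n, ca) {
  bis <- .unit(c_prev - n) + .unit(ca - n)
  n - 0.101 * .unit(bis)
}

.cb_position <- function(n, c, ca) {
  .place_nerf(n, c, ca, 0.1530, 110.6, 122.5)
}

# Build a chain with per-residue (phi, psi) by ideal-geometry chaining.
# Returns a coordinate table (residue_index, letter, name, x, y, z).
.build_chain <- function(letters_vec, phi, psi, resid_start = 1L) {
  n_res <- length(letters_vec)
  stopifnot(length(phi) == n_res, length(psi) == n_res)
  N <- CA <- C <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND_N_CA, 0, 0)
  ang <- .ANG_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + .BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- .place_nerf(N[i, ], CA[i, ], C[i, ], .BOND_C_N,
                              .ANG_CA_C_N, psi[i])
    CA[i + 1, ] <- .place_nerf(CA[i, ], C[i, ], N[i + 1, ], .BOND_N_CA,
                               .ANG_C_N_CA, 180)
    C[i + 1, ] <- .place_nerf(C[i, ], N[i + 1, ], CA[i + 1, ], .BOND_CA_C,
                              .ANG_N_CA_C, phi[i + 1])
  }
  acc <- list()
  for (i in seq_len(n_res)) {
    o_tor <- if (i < n_res) {
      # O trans to the next amide nitrogen
      NULL
    } else NULL
    if (i < n_res) {
      O <- .place_nerf(N[i + 1, ], CA[i, ], C[i, ], .BOND_C_O,
                       .ANG_CA_C_O, 180)
    } else {
      O <- .place_nerf(N[i, ], CA[i, ], C[i, ], .BOND_C_O, .ANG_CA_C_O,
                       psi[i] + 180)
    }
    H <- if (i > 1) .amide_h(C[i - 1, ], N[i, ], CA[i, ]) else
      N[1, ] + 0.101 * .unit(N[1, ] - CA[1, ])  # N-terminal amide H
    CB <- .cb_position(N[i, ], C[i, ], CA[i, ])
    acc <- .emit_residue(acc, resid_start + i - 1L, letters_vec[i],
                         N[i, ], CA[i, ], C[i, ], O, H, CB)
  }
  do.call(rbind, acc)
}

#' Build an ideal-geometry peptide
#'
#' Backbone (N, CA, C, O), amide hydrogens and a pseudo side chain (CB
#' carrying the residue's side-chain mass, plus explicit donor/acceptor
#' sites for R, K, E, D, N, Q, H, S, T, Y, W and M) are chained with ideal
#' bond geometry and template dihedrals: helix (-57, -47), strand
#' (-139, 135), coil drawn from broad Ramachandran basins (seeded).
#'
#' @param sequence One-letter sequence string (default the 40-residue
#'   amyloid-beta sequence).
#' @param ss_template Per-residue template, values in
#'   `c("helix", "strand", "coil")`; recycled if scalar.
#' @param seed RNG seed for coil dihedrals.
#' @return List: `table` (atom coordinate table), `records` (atom records),
#'   `coords` (matrix, nm), `sequence`.
#' @export
build_peptide <- function(sequence = AB40_SEQUENCE, ss_template = "coil",
                          seed = 1) {
  letters_vec <- strsplit(sequence, "")[[1]]
  bad <- !letters_vec %in% names(.AA_THREE)
  if (any(bad)) stop("unknown residue letter(s): ",
                     paste(unique(letters_vec[bad]), collapse = ", "))
  n <- length(letters_vec)
  ss_template <- rep(ss_template, length.out = n)
  set.seed(seed)
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    t <- ss_template[i]
    if (t %in% names(.TEMPLATE_DIHEDRALS)) {
      phi[i] <- .TEMPLATE_DIHEDRALS[[t]]["phi"]
      psi[i] <- .TEMPLATE_DIHEDRALS[[t]]["psi"]
    } else if (t == "coil") {
      # broad polyproline-II / extended-ish basin, no regular pattern
      phi[i] <- stats::runif(1, -150, -60)
      psi[i] <- stats::runif(1, 60, 170)
    } else {
      stop("unknown ss_template value: ", t)
    }
  }
  tab <- .build_chain(letters_vec, phi, psi)
  peptide_from_table(tab)
}

#' Convert a coordinate table into records + coordinate matrix
#' @param tab Table from the internal builders.
#' @return List: `table`, `records`, `coords`, `sequence`.
#' @keywords internal
peptide_from_table <- function(tab) {
  res_letters <- tapply(tab$letter, tab$residue_index, `[`, 1)
  resname <- unname(.AA_THREE[tab$letter])
  mass <- element_mass(infer_element(tab$name))
  # CB pseudo-atom carries the residue side-chain mass net of the explicit
  # site atoms
  for (i in unique(tab$residue_index)) {
    sel <- tab$residue_index == i
    letter <- tab$letter[sel][1]
    if (letter == "G") next
    site_mass <- sum(mass[sel & tab$name %in% .SITE_ATOMS[[letter]]])
    cb <- which(sel & tab$name == "CB")
    mass[cb] <- max(12.011, .SIDECHAIN_MASS[[letter]] - site_mass)
  }
  rec <- atom_records(seq_len(nrow(tab)), tab$name, tab$residue_index,
                      resname, mass = mass)
  list(table = tab, records = rec,
       coords = as.matrix(tab[, c("x", "y", "z")]),
       sequence = paste(res_letters, collapse = ""))
}

# ---- rigid strand assembly -------------------------------------------------

.rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a),
                               cos(a)), 3, 3, byrow = TRUE)
.rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0,
                               cos(a)), 3, 3, byrow = TRUE)
.rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0,
                               1), 3, 3, byrow = TRUE)

.apply_rigid <- function(xyz, R, t = c(0, 0, 0), center = NULL) {
  m <- as.matrix(xyz)
  if (is.null(center)) center <- colMeans(m)
  sweep(sweep(m, 2, center) %*% t(R), 2, -(center + t))
}

# Canonical segment: built with uniform template dihedrals, then aligned
# so the CA axis runs along +x with the CA centroid at the origin.
.canonical_segment <- function(letters_vec, resid_start = 1L,
                               template = "strand") {
  d <- .TEMPLATE_DIHEDRALS[[template]]
  tab <- .build_chain(letters_vec,
                      rep(d["phi"], length(letters_vec)),
                      rep(d["psi"], length(letters_vec)), resid_start)
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  ca <- xyz[tab$name == "CA", , drop = FALSE]
  axis <- .unit(ca[nrow(ca), ] - ca[1, ])
  # rotate axis onto +x
  v <- .cross3(axis, c(1, 0, 0))
  s <- sqrt(sum(v^2)); cth <- axis[1]
  R <- if (s < 1e-12) diag(3) else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, colMeans(xyz[tab$name == "CA", , drop = FALSE]))
  tab$x <- xyz[, 1]; tab$y <- xyz[, 2]; tab$z <- xyz[, 3]
  tab
}

.canonical_strand <- function(letters_vec, resid_start = 1L) {
  .canonical_segment(letters_vec, resid_start, "strand")
}

# Calibrated inter-strand placements (see data-raw/calibrate-sheet.R): the
# transform mapping a canonical strand onto its neighbour so that
# Kabsch-Sander backbone hydrogen bonds form.
#   parallel:      translate by (dx, dy, dz)
#   antiparallel:  rotate pi about z (chain reverses), then translate
.SHEET_PARALLEL_OFFSET <- c(0.00, 0.36, -0.32)
.SHEET_ANTI_ROT <- "z"
.SHEET_ANTI_OFFSET <- c(-0.03, 0.36, -0.14)

# Place coil residues along straight segments between anchor points. `dirs`
# orients carbonyls/amides away from partners so no spurious H-bond forms.
.linker_residues <- function(letters_vec, resid, p_from, p_to) {
  n <- length(resid)
  acc <- list()
  f <- .unit(p_to - p_from)
  ref <- if (abs(f[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- .unit(.cross3(f, ref))
  w <- .unit(.cross3(f, u))
  for (k in seq_len(n)) {
    ca <- p_from + (p_to - p_from) * k / (n + 1)
    sgn <- if (k %% 2 == 0) 1 else -1
    N <- ca - 0.12 * f + 0.03 * sgn * w
    C <- ca + 0.12 * f - 0.03 * sgn * w
    O <- C + 0.1231 * sgn * w
    H <- N - 0.101 * sgn * w
    CB <- ca + 0.153 * u
    acc <- .emit_residue(acc, resid[k], letters_vec[k], N, ca, C, O, H, CB)
  }
  if (length(acc)) do.call(rbind, acc) else NULL
}

#' Assemble a multi-strand sheet conformation
#'
#' Strand segments are built with ideal strand dihedrals, rigidly stacked
#' with calibrated offsets so that inter-strand backbone hydrogen bonds
#' satisfy the Kabsch-Sander criterion, and joined by straight coil
#' linkers. Residues outside all segments before the first / after the
#' last strand are laid out as leading/trailing coil.
#'
#' @param sequence One-letter sequence.
#' @param strands List of `c(first, last)` residue ranges (ordered,
#'   non-overlapping, separated by at least one linker residue).
#' @param stacking `"parallel"` (all strands same direction) or
#'   `"antiparallel"` (alternating; two strands give a hairpin).
#' @return List as from [build_peptide()].
#' @export
build_sheet_peptide <- function(sequence = AB40_SEQUENCE, strands,
                                stacking = c("parallel", "antiparallel")) {
  stacking <- match.arg(stacking)
  letters_vec <- strsplit(sequence, "")[[1]]
  n <- length(letters_vec)
  pieces <- list()
  prev_end_pt <- NULL
  prev_end_res <- 0L
  for (k in seq_along(strands)) {
    rng <- strands[[k]]
    seg <- .canonical_strand(letters_vec[rng[1]:rng[2]], rng[1])
    xyz <- as.matrix(seg[, c("x", "y", "z")])
    if (stacking == "parallel") {
      xyz <- sweep(xyz, 2, -(k - 1) * .SHEET_PARALLEL_OFFSET)
    } else {
      if (k %% 2 == 0) {
        R <- switch(.SHEET_ANTI_ROT, z = .rot_z(pi), y = .rot_y(pi))
        xyz <- xyz %*% t(R)
        xyz <- sweep(xyz, 2, -c(.SHEET_ANTI_OFFSET[1], 0,
                                .SHEET_ANTI_OFFSET[3]))
      }
      xyz <- sweep(xyz, 2, -c(0, (k - 1) * .SHEET_ANTI_OFFSET[2], 0))
    }
    seg$x <- xyz[, 1]; seg$y <- xyz[, 2]; seg$z <- xyz[, 3]
    # linker from previous residue range
    first_ca <- xyz[seg$name == "CA", , drop = FALSE][1, ]
    if (rng[1] > prev_end_res + 1L) {
      link_res <- (prev_end_res + 1L):(rng[1] - 1L)
      from <- if (is.null(prev_end_pt)) {
        first_ca + c(-0.35 * length(link_res), 0.3, 0.25)
      } else prev_end_pt
      pieces[[length(pieces) + 1]] <-
        .linker_residues(letters_vec[link_res], link_res, from, first_ca)
    }
    pieces[[length(pieces) + 1]] <- seg
    prev_end_pt <- xyz[seg$name == "CA", , drop = FALSE][sum(seg$name == "CA"), ]
    prev_end_res <- rng[2]
  }
  if (prev_end_res < n) {
    link_res <- (prev_end_res + 1L):n
    to <- prev_end_pt + c(0.35 * length(link_res), -0.3, 0.25)
    pieces[[length(pieces) + 1]] <-
      .linker_residues(letters_vec[link_res], link_res, prev_end_pt, to)
  }
  tab <- do.call(rbind, pieces)
  tab <- tab[order(tab$residue_index,
                   match(tab$name, unique(tab$name))), , drop = FALSE]
  tab <- tab[order(tab$residue_index), , drop = FALSE]
  rownames(tab) <- NULL
  peptide_from_table(tab)
}

#' Ideal antiparallel beta-hairpin
#'
#' Two antiparallel strands joined by a two-residue turn; a convenience
#' wrapper around [build_sheet_peptide()].
#'
#' @param sequence One-letter sequence.
#' @param strand_len Residues per strand.
#' @param turn_start First residue of strand 1 (leading residues become
#'   coil).
#' @return List as from [build_peptide()].
#' @export
build_hairpin <- function(sequence = substr(AB40_SEQUENCE, 1, 17),
                          strand_len = 7, turn_start = 1L) {
  n <- nchar(sequence)
  s1 <- c(turn_start, turn_start + strand_len - 1L)
  s2_first <- s1[2] + 3L
  s2 <- c(s2_first, min(n, s2_first + strand_len - 1L))
  build_sheet_peptide(sequence, list(s1, s2), stacking = "antiparallel")
}

# Coil conformation following a given CA path (n x 3); used for the
# deeply-inserted unstructured templates where no regular secondary
# structure must appear.
.path_conformation <- function(letters_vec, ca_path, resid_start = 1L) {
  n <- length(letters_vec)
  stopifnot(nrow(ca_path) == n)
  acc <- list()
  for (i in seq_len(n)) {
    f <- if (i < n) .unit(ca_path[min(i + 1, n), ] - ca_path[i, ]) else
      .unit(ca_path[i, ] - ca_path[i - 1, ])
    ref <- if (abs(f[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    u <- .unit(.cross3(f, ref))
    w <- .unit(.cross3(f, u))
    sgn <- if (i %% 2 == 0) 1 else -1
    ca <- ca_path[i, ]
    N <- ca - 0.12 * f + 0.03 * sgn * w
    C <- ca + 0.12 * f - 0.03 * sgn * w
    O <- C + 0.1231 * sgn * w
    H <- N - 0.101 * sgn * w
    CB <- ca + 0.153 * u
    acc <- .emit_residue(acc, resid_start + i - 1L, letters_vec[i],
                         N, ca, C, O, H, CB)
  }
  do.call(rbind, acc)
}
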