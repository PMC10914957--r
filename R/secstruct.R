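# DSSP-style secondary-structure assignment (Kabsch-Sander backbone
# hydrogen bonds), mapped to the seven classes E, B, H, G, I, T, C.
#
# Missing amide hydrogens are reconstructed 0.101 nm from N along the
# direction opposed to the bisector of the C(i-1)->N and CA->N bonds.

.KS_Q <- 0.084 * 332  # 27.888 kcal/mol * Angstrom, Kabsch-Sander coupling
.KS_EMAX <- -0.5      # kcal/mol bond threshold

# Extract per-residue backbone coordinate arrays; errors name the residue
# that lacks a backbone atom.
.backbone_coords <- function(system, frame) {
  at <- system$atoms
  pep <- system$idx$peptide
  res_ids <- system$peptide_residues
  n <- length(res_ids)
  pick <- function(atom_name) {
    out <- matrix(NA_real_, n, 3)
    sel <- pep[at$name[pep] == atom_name]
    ridx <- match(at$residue_index[sel], res_ids)
    out[ridx, ] <- frame$coords[sel, , drop = FALSE]
    out
  }
  bb <- list(N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"))
  for (a in names(bb)) {
    miss <- which(is.na(bb[[a]][, 1]))
    if (length(miss)) {
      stop("residue ", res_ids[miss[1]], " is missing backbone atom ", a)
    }
  }
  # amide H: use an explicit one when present, otherwise reconstruct
  h <- matrix(NA_real_, n, 3)
  sel <- pep[at$name[pep] %in% c("H", "HN")]
  if (length(sel)) {
    ridx <- match(at$residue_index[sel], res_ids)
    h[ridx, ] <- frame$coords[sel, , drop = FALSE]
  }
  for (i in 2:n) {
    if (is.na(h[i, 1])) {
      u1 <- bb$C[i - 1, ] - bb$N[i, ]
      u2 <- bb$CA[i, ] - bb$N[i, ]
      u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
      bis <- u1 + u2
      h[i, ] <- bb$N[i, ] - 0.101 * bis / sqrt(sum(bis^2))
    }
  }
  bb$H <- h
  bb
}

# Kabsch-Sander backbone H-bond matrix: hb[i, j] is TRUE when the carbonyl
# of residue i accepts a hydrogen bond from the amide of residue j.
.ks_hbond_matrix <- function(bb) {
  n <- nrow(bb$N)
  ang <- function(m) m * 10  # nm -> Angstrom
  dmat <- function(a, b) {
    d2 <- 0
    for (k in 1:3) d2 <- d2 + outer(ang(a)[, k], ang(b)[, k], "-")^2
    sqrt(d2)
  }
  r_on <- dmat(bb$O, bb$N)
  r_ch <- dmat(bb$C, bb$H)
  r_oh <- dmat(bb$O, bb$H)
  r_cn <- dmat(bb$C, bb$N)
  e <- .KS_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  e[!is.finite(e)] <- 0
  hb <- e < .KS_EMAX
  hb[is.na(hb)] <- FALSE           # residue 1 may lack an amide H
  sep <- abs(row(hb) - col(hb))
  hb[sep < 2] <- FALSE             # exclude self and bonded neighbours
  hb
}

#' Assign secondary structure to one frame
#'
#' DSSP-style assignment from Kabsch-Sander backbone hydrogen bonds
#' (electrostatic energy below -0.5 kcal/mol): two consecutive n->n+4 turns
#' give H, n->n+3 G, n->n+5 I; bridge patterns give E (ladders) or B
#' (isolated bridges); hydrogen-bonded turns give T; everything else C.
#' Priority on conflict: H, E, B, G, I, T.
#'
#' @param system A `structured_system` whose peptide has backbone N, CA, C,
#'   O atoms for every residue.
#' @param frame A `frame`.
#' @return Character vector of classes, one per peptide residue.
#' @export
assign_secstruct <- function(system, frame) {
  bb <- .backbone_coords(system, frame)
  hb <- .ks_hbond_matrix(bb)
  n <- nrow(hb)
  turn <- function(len) {
    t <- rep(FALSE, n)
    i <- seq_len(max(0, n - len))
    t[i] <- hb[cbind(i, i + len)]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  helix_mask <- function(t, len) {
    m <- rep(FALSE, n)
    for (i in seq_len(n - len)) {
      if (i >= 2 && t[i - 1] && t[i]) m[i:(i + len - 1)] <- TRUE
    }
    m
  }
  h4 <- helix_mask(t4, 4)
  h3 <- helix_mask(t3, 3)
  h5 <- helix_mask(t5, 5)

  # bridges
  bridge <- matrix(FALSE, n, n)
  par_bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1)) {
    for (j in seq_len(n)) {
      if (j < i + 3) next
      if (j < 2 || j > n - 1) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (i >= 2 && j <= n - 1 && hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) {
        bridge[i, j] <- bridge[j, i] <- TRUE
        if (par) par_bridge[i, j] <- par_bridge[j, i] <- TRUE
      }
    }
  }
  in_bridge <- rowSums(bridge) > 0
  # ladder: a bridge (i, j) extends when an adjacent bridge (i+-1, j-+1) or
  # (i+-1, j+-1) exists; extended bridges are E, isolated ones B
  in_ladder <- rep(FALSE, n)
  br <- which(bridge & upper.tri(bridge), arr.ind = TRUE)
  if (nrow(br)) {
    has <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && bridge[i, j]
    for (r in seq_len(nrow(br))) {
      i <- br[r, 1]; j <- br[r, 2]
      ext <- has(i + 1, j + 1) || has(i - 1, j - 1) ||
        has(i + 1, j - 1) || has(i - 1, j + 1)
      if (ext) in_ladder[c(i, j)] <- TRUE
    }
  }

  ss <- rep("C", n)
  ss[h4] <- "H"
  free <- ss == "C"
  ss[free & in_ladder] <- "E"
  free <- ss == "C"
  ss[free & in_bridge] <- "B"
  free <- ss == "C"
  ss[free & h3] <- "G"
  free <- ss == "C"
  ss[free & h5] <- "I"
  # hydrogen-bonded turn interiors
  t_mask <- rep(FALSE, n)
  for (len in c(3, 4, 5)) {
    t <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(len)]]
    for (i in which(t)) {
      t_mask[(i + 1):(i + len - 1)] <- TRUE
    }
  }
  free <- ss == "C"
  ss[free & t_mask] <- "T"
  names(ss) <- system$peptide_residues
  ss
}

#' Secondary structure for every frame of a trajectory
#'
#' @param traj A `trajectory`.
#' @param frames Optional frame-index subset.
#' @return Character matrix, frames in rows, residues in columns.
#' @export
secstruct_trajectory <- function(traj, frames = NULL) {
  if (is.null(frames)) frames <- seq_along(traj$frames)
  out <- t(vapply(frames, function(fi)
    assign_secstruct(traj$topology, traj$frames[[fi]]),
    character(length(traj$topology$peptide_residues))))
  rownames(out) <- frames
  out
}

#' Grouped secondary-structure fractions
#'
#' Collapses the seven classes into the standard three groups: unstructured
#' (C + T + B), beta (E) and helix (G + H + I), per residue over an
#' ensemble of assignments. The three fractions sum to 1 for every residue.
#'
#' @param assignments Character matrix from [secstruct_trajectory()] (or a
#'   single assignment vector).
#' @return Data frame `residue`, `unstructured`, `beta`, `helix`.
#' @export
grouped_fractions <- function(assignments) {
  if (is.null(dim(assignments))) assignments <- matrix(assignments, nrow = 1)
  groups <- list(unstructured = c("C", "T", "B"), beta = "E",
                 helix = c("G", "H", "I"))
  res <- colnames(assignments) %||% seq_len(ncol(assignments))
  out <- data.frame(residue = as.integer(res))
  for (g in names(groups)) {
    out[[g]] <- colMeans(matrix(assignments %in% groups[[g]],
                                nrow = nrow(assignments)))
  }
  out
}

#' Beta-sheet content of one assignment
#'
#' @param assignment Character vector of per-residue classes.
#' @return Fraction of residues assigned E.
#' @export
beta_content <- function(assignment) {
  mean(assignment == "E")
}
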