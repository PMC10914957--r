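# Geometric hydrogen-bond detection.
#
# Criterion: donor-acceptor heavy-atom minimum-image distance <= 0.3 nm and
# angle between the D->H and D->A vectors <= 20 degrees (closed cutoffs).
# An alternative D-H...A >= 160 degree convention is switchable in config.

# Bonded-hydrogen name patterns: donor heavy atom "Xsuffix" binds hydrogens
# named "H<suffix><digit?>" or "H<fullname><digit?>"; a bare backbone or
# water donor additionally accepts H, HN, H1..H3, HW1/HW2.
.match_bonded_h <- function(donor_name, h_names) {
  rest <- sub("^[A-Z]", "", donor_name)
  pats <- c(paste0("^H", rest, "[0-9]?$"), paste0("^H", donor_name, "[0-9]?$"))
  if (rest == "") pats <- c(pats, "^(H|HN|H[0-9]|HW[0-9])$")
  hit <- rep(FALSE, length(h_names))
  for (p in pats) hit <- hit | grepl(p, h_names)
  which(hit)
}

.SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1"
)
.SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)
# mandatory donors: chemistry guarantees an attached hydrogen
.MANDATORY_DONOR <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                         ASN = "ND2", GLN = "NE2", TRP = "NE1")

#' Build the donor/acceptor table for a system
#'
#' Rule-based assignment: peptide backbone N-H donors and carbonyl O
#' acceptors; side-chain N/O donors and acceptors by residue type; water O
#' as double donor and acceptor; every lipid oxygen as acceptor, with
#' N-H (POPS amine) and O-H (cholesterol hydroxyl) lipid donors where a
#' bonded hydrogen resolves. Bonded hydrogens are resolved by atom-name
#' convention, with a distance fallback (< 0.12 nm) when a reference frame
#' is supplied. Methionine SD is excluded as an acceptor unless
#' `config$met_sulfur_acceptor` is set (weak acceptor; standard practice).
#'
#' @param system A `structured_system`.
#' @param frame Optional `frame` for distance-based hydrogen resolution.
#' @param config An `analysis_config`.
#' @return List with data frames `donors` (`d_idx`, `h_idx`, ...) and
#'   `acceptors` (`a_idx`, ...).
#' @export
build_da_table <- function(system, frame = NULL,
                           config = analysis_config()) {
  at <- system$atoms
  donors <- list()
  acceptors <- list()
  add_donor <- function(d, h) donors[[length(donors) + 1]] <<- c(d, h)
  add_acceptor <- function(a) acceptors[[length(acceptors) + 1]] <<- a

  by_res <- split(seq_len(nrow(at)), at$residue_index)
  for (res_atoms in by_res) {
    grp <- at$group[res_atoms[1]]
    rn <- toupper(at$residue_name[res_atoms[1]])
    nm <- at$name[res_atoms]
    hs <- res_atoms[at$element[res_atoms] == "H"]
    h_names <- at$name[hs]
    resolve_h <- function(d_local) {
      d_idx <- res_atoms[d_local]
      hit <- .match_bonded_h(nm[d_local], h_names)
      if (!length(hit) && !is.null(frame) && length(hs)) {
        dd <- vapply(hs, function(h) min_image_distance(
          frame$coords[d_idx, ], frame$coords[h, ], frame$box), numeric(1))
        hit <- which(dd < 0.12)
      }
      hs[hit]
    }
    if (grp == "peptide") {
      for (k in seq_along(nm)) {
        a_nm <- nm[k]
        if (a_nm == "N") {
          for (h in resolve_h(k)) add_donor(res_atoms[k], h)
        } else if (a_nm %in% c("O", "OXT")) {
          add_acceptor(res_atoms[k])
        } else if (a_nm %in% (.SIDECHAIN_DONORS[[rn]] %||% character(0))) {
          h_found <- resolve_h(k)
          if (length(h_found)) {
            for (h in h_found) add_donor(res_atoms[k], h)
          } else if (a_nm %in% (.MANDATORY_DONOR[[rn]] %||% character(0))) {
            stop("donor atom ", a_nm, " of residue ", rn, " ",
                 at$residue_index[res_atoms[k]], " has no resolvable hydrogen")
          }
        }
        if (a_nm %in% (.SIDECHAIN_ACCEPTORS[[rn]] %||% character(0))) {
          # His N accepts only when it carries no hydrogen
          if (!(rn == "HIS" && length(.match_bonded_h(a_nm, h_names)))) {
            add_acceptor(res_atoms[k])
          }
        }
        if (a_nm == "SD" && rn == "MET" && config$met_sulfur_acceptor) {
          add_acceptor(res_atoms[k])
        }
      }
    } else if (grp == "water") {
      o_local <- which(at$element[res_atoms] == "O")
      for (k in o_local) {
        h_found <- resolve_h(k)
        if (length(h_found) < 2) {
          stop("water oxygen (residue ", at$residue_index[res_atoms[k]],
               ") did not resolve two hydrogens")
        }
        for (h in h_found) add_donor(res_atoms[k], h)
        add_acceptor(res_atoms[k])
      }
    } else if (grp %in% LIPID_GROUPS) {
      for (k in seq_along(nm)) {
        el <- at$element[res_atoms[k]]
        if (el == "O") {
          add_acceptor(res_atoms[k])
          for (h in resolve_h(k)) add_donor(res_atoms[k], h)
        } else if (el == "N") {
          for (h in resolve_h(k)) add_donor(res_atoms[k], h)
        }
      }
    }
  }
  d <- if (length(donors)) do.call(rbind, donors) else
    matrix(integer(0), ncol = 2)
  a <- if (length(acceptors)) unlist(acceptors) else integer(0)
  list(
    donors = data.frame(
      d_idx = d[, 1], h_idx = d[, 2],
      residue = at$residue_index[d[, 1]], name = at$name[d[, 1]],
      group = at$group[d[, 1]], stringsAsFactors = FALSE),
    acceptors = data.frame(
      a_idx = a, residue = at$residue_index[a], name = at$name[a],
      group = at$group[a], stringsAsFactors = FALSE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.partner_class_of <- function(donor_group, acceptor_group) {
  other <- ifelse(donor_group == "peptide", acceptor_group, donor_group)
  out <- c(lipid_POPC = "POPC", lipid_POPS = "POPS", lipid_CHOL = "CHOL",
           water = "water", peptide = "peptide", ion = "ion")[other]
  out[donor_group == "peptide" & acceptor_group == "peptide"] <- "peptide"
  unname(out)
}

#' Detect hydrogen bonds in one frame
#'
#' Evaluates every donor-hydrogen/acceptor combination of the table against
#' the geometric criterion. Pairs within one residue are excluded;
#' peptide-internal pairs additionally require a sequence separation of at
#' least 2 residues. By default only pairs with a peptide partner are
#' reported (those are what the downstream summaries consume).
#'
#' @param system A `structured_system`.
#' @param frame A `frame`.
#' @param config An `analysis_config`.
#' @param table Donor/acceptor table from [build_da_table()].
#' @param peptide_only Keep only bonds with at least one peptide partner?
#' @return Data frame of hydrogen-bond records.
#' @export
detect_hbonds <- function(system, frame, config = analysis_config(),
                          table = build_da_table(system, frame, config),
                          peptide_only = TRUE) {
  don <- table$donors
  acc <- table$acceptors
  empty <- data.frame(donor_res = integer(0), donor_atom = character(0),
                      donor_group = character(0), acceptor_res = integer(0),
                      acceptor_atom = character(0),
                      acceptor_group = character(0),
                      partner_class = character(0),
                      distance = numeric(0), angle = numeric(0))
  if (!nrow(don) || !nrow(acc)) return(empty)
  if (peptide_only) {
    keep_d <- don$group == "peptide"
    keep_a <- acc$group == "peptide"
    # donor x acceptor pairs with a peptide side: evaluate peptide donors
    # against all acceptors and non-peptide donors against peptide acceptors
    cand <- rbind(
      expand.grid(d = which(keep_d), a = seq_len(nrow(acc))),
      expand.grid(d = which(!keep_d), a = which(keep_a))
    )
  } else {
    cand <- expand.grid(d = seq_len(nrow(don)), a = seq_len(nrow(acc)))
  }
  if (!nrow(cand)) return(empty)
  di <- don$d_idx[cand$d]; hi <- don$h_idx[cand$d]; ai <- acc$a_idx[cand$a]
  same_atom <- di == ai
  same_res <- don$residue[cand$d] == acc$residue[cand$a]
  pep_pair <- don$group[cand$d] == "peptide" & acc$group[cand$a] == "peptide"
  sep_ok <- !pep_pair | abs(don$residue[cand$d] - acc$residue[cand$a]) >= 2
  keep <- !same_atom & !same_res & sep_ok
  cand <- cand[keep, , drop = FALSE]
  di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]
  if (!nrow(cand)) return(empty)
  box <- frame$box
  mi <- function(v) v - rep(box, each = nrow(v)) * round(v / rep(box, each = nrow(v)))
  da <- mi(frame$coords[ai, , drop = FALSE] - frame$coords[di, , drop = FALSE])
  dist <- sqrt(rowSums(da * da))
  # closed cutoffs with a 1e-9 guard so exactly-at-boundary geometry is
  # kept despite floating-point representation
  close <- dist <= config$hbond_da_cutoff + 1e-9
  if (!any(close)) return(empty)
  cand <- cand[close, , drop = FALSE]
  di <- di[close]; hi <- hi[close]; ai <- ai[close]
  da <- da[close, , drop = FALSE]; dist <- dist[close]
  dh <- mi(frame$coords[hi, , drop = FALSE] - frame$coords[di, , drop = FALSE])
  if (config$hbond_angle_convention == "donor") {
    cosang <- rowSums(dh * da) /
      (sqrt(rowSums(dh * dh)) * pmax(dist, 1e-12))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok <- ang <= config$hbond_angle_cutoff + 1e-9
  } else {
    ha <- mi(frame$coords[ai, , drop = FALSE] - frame$coords[hi, , drop = FALSE])
    cosang <- rowSums(-dh * ha) /
      (sqrt(rowSums(dh * dh)) * pmax(sqrt(rowSums(ha * ha)), 1e-12))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok <- ang >= 180 - config$hbond_angle_cutoff - 1e-9
  }
  if (!any(ok)) return(empty)
  cd <- cand$d[ok]; ca <- cand$a[ok]
  data.frame(
    donor_res = don$residue[cd], donor_atom = don$name[cd],
    donor_group = don$group[cd],
    acceptor_res = acc$residue[ca], acceptor_atom = acc$name[ca],
    acceptor_group = acc$group[ca],
    partner_class = .partner_class_of(don$group[cd], acc$group[ca]),
    distance = dist[ok], angle = ang[ok], stringsAsFactors = FALSE)
}

#' Per-residue hydrogen-bond summaries over an ensemble
#'
#' Mean hydrogen-bond counts per frame and peptide residue, split by
#' partner class (POPC, POPS, CHOL, water, peptide) and by the aggregates
#' membrane (the three lipid classes) and water. Both donated and accepted
#' bonds count toward a residue; peptide-internal bonds count toward both
#' participating residues under class `peptide`.
#'
#' @param traj A `trajectory`.
#' @param config An `analysis_config`.
#' @param table Optional precomputed donor/acceptor table.
#' @param frames Optional frame-index subset.
#' @return List: `per_residue` (data frame of mean counts), `per_frame`
#'   (totals by class per frame), `records` (all bond records with a
#'   `frame` column).
#' @export
hbond_summaries <- function(traj, config = analysis_config(), table = NULL,
                            frames = NULL) {
  if (!length(traj$frames)) stop("hbond_summaries on an empty ensemble")
  sys <- traj$topology
  if (is.null(table)) table <- build_da_table(sys, traj$frames[[1]], config)
  if (is.null(frames)) frames <- seq_along(traj$frames)
  classes <- c("POPC", "POPS", "CHOL", "water", "peptide")
  res_ids <- sys$peptide_residues
  counts <- matrix(0, length(res_ids), length(classes),
                   dimnames = list(res_ids, classes))
  per_frame <- matrix(0, length(frames), length(classes),
                      dimnames = list(NULL, classes))
  all_records <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    rec <- detect_hbonds(sys, traj$frames[[frames[k]]], config, table)
    if (nrow(rec)) {
      rec$frame <- frames[k]
      all_records[[k]] <- rec
      for (r in seq_len(nrow(rec))) {
        cls <- rec$partner_class[r]
        if (!cls %in% classes) next
        per_frame[k, cls] <- per_frame[k, cls] + 1
        pep_res <- unique(c(
          if (rec$donor_group[r] == "peptide") rec$donor_res[r],
          if (rec$acceptor_group[r] == "peptide") rec$acceptor_res[r]))
        for (pr in pep_res) {
          counts[as.character(pr), cls] <- counts[as.character(pr), cls] + 1
        }
      }
    }
  }
  per_res <- as.data.frame(counts / length(frames))
  per_res <- cbind(residue = as.integer(rownames(counts)), per_res)
  per_res$membrane <- per_res$POPC + per_res$POPS + per_res$CHOL
  rownames(per_res) <- NULL
  pf <- as.data.frame(per_frame)
  pf$membrane <- pf$POPC + pf$POPS + pf$CHOL
  pf <- cbind(frame = frames, pf)
  records <- if (length(rec_l <- Filter(Negate(is.null), all_records))) {
    do.call(rbind, rec_l)
  } else NULL
  list(per_residue = per_res, per_frame = pf, records = records)
}

#' Rank hydrogen-bond types by frequency
#'
#' A type is the triple (donor atom name, acceptor atom name, partner
#' class). Ties break lexicographically, so the ranking is deterministic.
#'
#' @param records Bond records (e.g. from [hbond_summaries()]).
#' @param k Number of types to return.
#' @return Data frame `donor_atom`, `acceptor_atom`, `partner_class`,
#'   `count`, sorted by descending count.
#' @export
top_hbond_types <- function(records, k) {
  if (k <= 0) stop("k must be positive")
  if (is.null(records) || !nrow(records)) {
    return(data.frame(donor_atom = character(0), acceptor_atom = character(0),
                      partner_class = character(0), count = integer(0)))
  }
  key <- paste(records$donor_atom, records$acceptor_atom,
               records$partner_class, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  df <- data.frame(donor_atom = parts[, 1], acceptor_atom = parts[, 2],
                   partner_class = parts[, 3], count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$donor_atom, df$acceptor_atom,
                 df$partner_class), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}
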