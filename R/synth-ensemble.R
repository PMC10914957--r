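# Ground-truth binding-ensemble generator.
#
# Conformations are laid out in "depth space": z = 0 is the upper bilayer
# surface, positive z is solvent. Each model template plants per-region
# insertion depths and a secondary-structure template chosen so that the
# analysis modules recover the intended classifier label with margin:
# depths that must stay buried are planted at most -0.25 nm, depths that
# must stay solvated at least +0.5 nm above any contact-generating height,
# and the per-frame rigid-body noise is truncated so it cannot cross those
# margins.

#' Specification for a synthetic binding ensemble
#'
#' @param model_template One of `model1`..`model4`, `unbound`, `mixture`.
#' @param n_frames Number of frames.
#' @param seed RNG seed; same seed, same ensemble (bit-identical).
#' @param com_distance Peptide-bilayer COM distance for unbound poses, nm.
#' @param noise_sd Rigid-body positional noise SD per frame, nm.
#' @param noise_trunc Truncation of the noise, nm (keeps planted margins).
#' @param rotate Apply a random rotation about z per frame?
#' @param planted_hbonds List of `c(residue = <int>, species = <chr>)`
#'   hydrogen bonds posed to satisfy the detection criterion in every
#'   bound frame.
#' @param mixture_bound_fraction Exact bound fraction for `mixture`.
#' @param per_leaflet,spacing,half_thickness,box_z Bilayer geometry, see
#'   [build_bilayer()].
#' @param frame_spacing Frame time spacing, ns.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(model_template = c("model1", "model2", "model3",
                                              "model4", "unbound",
                                              "mixture"),
                           n_frames = 200, seed = 1,
                           com_distance = 5.0,
                           noise_sd = 0.05, noise_trunc = 0.1,
                           rotate = TRUE,
                           planted_hbonds = list(),
                           mixture_bound_fraction = 0.5,
                           per_leaflet = c(POPC = 54, POPS = 18, CHOL = 18),
                           spacing = 0.65, half_thickness = 2.0,
                           box_z = 14, frame_spacing = 1) {
  model_template <- match.arg(model_template)
  stopifnot(n_frames >= 1, noise_sd >= 0, noise_trunc >= 0,
            com_distance > 0,
            mixture_bound_fraction >= 0, mixture_bound_fraction <= 1)
  if (com_distance + 1 > box_z / 2) {
    stop("com_distance too large for the box (minimum-image safety)")
  }
  structure(list(model_template = model_template, n_frames = n_frames,
                 seed = seed, com_distance = com_distance,
                 noise_sd = noise_sd, noise_trunc = noise_trunc,
                 rotate = rotate, planted_hbonds = planted_hbonds,
                 mixture_bound_fraction = mixture_bound_fraction,
                 per_leaflet = per_leaflet, spacing = spacing,
                 half_thickness = half_thickness, box_z = box_z,
                 frame_spacing = frame_spacing),
            class = "synthetic_spec")
}

# Archimedean spiral CA path: compact lateral footprint with successive
# windings separated by ~0.65 nm so path segments never stack on top of
# each other (no spurious backbone hydrogen bonds).
.spiral_path <- function(n, depths, center = c(0, 0), r0 = 0.5,
                         step = 0.36, growth = 0.103) {
  th <- numeric(n); r <- numeric(n)
  th[1] <- 0; r[1] <- r0
  for (i in seq_len(n - 1)) {
    th[i + 1] <- th[i] + step / r[i]
    r[i + 1] <- r0 + growth * th[i + 1]
  }
  cbind(center[1] + r * cos(th), center[2] + r * sin(th), depths)
}

.recenter_xy <- function(tab) {
  ca <- tab$name == "CA"
  tab$x <- tab$x - mean(tab$x[ca])
  tab$y <- tab$y - mean(tab$y[ca])
  tab
}

.shift_z <- function(tab, rows, dz) {
  tab$z[rows] <- tab$z[rows] + dz
  tab
}

# depth of each residue's CA in a conformation table
.ca_depths <- function(tab) {
  ca <- tab[tab$name == "CA", ]
  stats::setNames(ca$z, ca$residue_index)
}

.letters40 <- function() strsplit(AB40_SEQUENCE, "")[[1]]

# model 1: flat three-strand parallel sheet well above the surface
# (beta-rich), C-terminal tail spiralling down so only CT residues are
# buried and a handful contact the membrane.
.conf_model1 <- function() {
  lv <- .letters40()
  conf <- build_sheet_peptide(AB40_SEQUENCE,
                              list(c(3, 9), c(13, 19), c(23, 29)),
                              stacking = "parallel")
  tab <- conf$table
  sheet_rows <- tab$residue_index <= 29
  ca_sheet <- sheet_rows & tab$name == "CA"
  tab$z <- tab$z - mean(tab$z[ca_sheet]) + 1.25
  # rebuild the tail along a descending spiral, routed clear of the sheet
  depths_ct <- c(0.9, 0.55, 0.3, 0.15, 0.05, -0.03, -0.1, -0.15, -0.19,
                 -0.21, -0.22)
  max_x <- max(tab$x[sheet_rows])
  tail_tab <- .path_conformation(lv[30:40],
                                 .spiral_path(11, depths_ct,
                                              center = c(max_x + 1.3, 0)),
                                 resid_start = 30L)
  tab <- rbind(tab[tab$residue_index < 30, ], tail_tab)
  list(tab = .recenter_xy(tab),
       planted_depth = c(rep(1.25, 29), depths_ct),
       # strand truth covers the ladder interiors; the first/last residue
       # of each ideal strand is a turn/bridge edge, not E
       ss_template = ifelse(seq_len(40) %in% c(4:8, 14:18, 24:28),
                            "strand", "coil"))
}

# model 2: two N-terminal helices lying on the surface, everything else
# arcing into solution; no residue buried deeper than the surface layer.
.conf_model2 <- function() {
  lv <- .letters40()
  h1 <- .canonical_segment(lv[2:9], 2L, "helix")
  h2 <- .canonical_segment(lv[11:16], 11L, "helix")
  depth_helix <- 0.18
  h1$z <- h1$z - mean(h1$z[h1$name == "CA"]) + depth_helix
  h2$z <- h2$z - mean(h2$z[h2$name == "CA"]) + depth_helix
  h1$x <- h1$x - 1.3
  h2$x <- h2$x + 1.3
  ca9 <- unlist(h1[h1$residue_index == 9 & h1$name == "CA",
                   c("x", "y", "z")])
  ca11 <- unlist(h2[h2$residue_index == 11 & h2$name == "CA",
                    c("x", "y", "z")])
  r1 <- .linker_residues(lv[1], 1L, ca9 * 0 + c(h1$x[1] - 0.8, 0.4, 1.8),
                         unlist(h1[h1$name == "CA", c("x", "y", "z")][1, ]))
  lk <- .linker_residues(lv[10], 10L, ca9 + c(0.2, 0.4, 0.9),
                         ca11 + c(-0.2, 0.4, 0.9))
  ca16 <- unlist(h2[h2$residue_index == 16 & h2$name == "CA",
                    c("x", "y", "z")])
  tail_depths <- c(seq(1.1, 1.5, length.out = 12), rep(1.5, 12))
  tail <- .path_conformation(lv[17:40],
                             .spiral_path(24, tail_depths,
                                          center = ca16[1:2] + c(1.0, -0.5)),
                             resid_start = 17L)
  tab <- rbind(r1, h1, lk, h2, tail)
  # truth marks only the helix interiors: ideal-geometry fragment edges are
  # not 4-helix residues by construction
  list(tab = .recenter_xy(tab),
       planted_depth = c(1.0, rep(depth_helix, 8), 1.0,
                         rep(depth_helix, 6), tail_depths),
       ss_template = c("coil", "coil", rep("helix", 6), "coil", "coil",
                       "coil", rep("helix", 4), "coil", rep("coil", 24)))
}

# model 3: moderately beta-rich two-strand sheet lying near the surface,
# most of CT buried inside the membrane.
.conf_model3 <- function() {
  lv <- .letters40()
  conf <- build_sheet_peptide(AB40_SEQUENCE, list(c(3, 7), c(11, 15)),
                              stacking = "parallel")
  tab <- conf$table
  keep <- tab$residue_index <= 15
  ca_sheet <- keep & tab$name == "CA"
  tab$z <- tab$z - mean(tab$z[ca_sheet]) + 0.5
  tab <- tab[keep, ]
  max_x <- max(tab$x)
  mid_depths <- c(0.4, 0.35, 0.3, 0.3, 0.3, 0.35,           # 16-21 on surface
                  0.5, 0.7, 0.9, 0.9, 0.9, 0.7, 0.5, 0.3)   # 22-29 loop up
  mid_center <- c(max_x + 1.4, 1.0)
  mid <- .path_conformation(lv[16:29],
                            .spiral_path(14, mid_depths, center = mid_center),
                            resid_start = 16L)
  depths_ct <- c(0.1, -0.1, -0.3, -0.45, -0.55, -0.65, -0.7, -0.7,
                 -0.65, -0.6, -0.55)
  tail <- .path_conformation(lv[30:40],
                             .spiral_path(11, depths_ct,
                                          center = mid_center + c(0, -2.3)),
                             resid_start = 30L)
  tab <- rbind(tab, mid, tail)
  list(tab = .recenter_xy(tab),
       planted_depth = c(rep(0.5, 15), mid_depths, depths_ct),
       ss_template = ifelse(seq_len(40) %in% c(4:6, 12:14),
                            "strand", "coil"))
}

# model 4: fully unstructured; CHC and CT buried, NT and CL in solution.
.conf_model4 <- function() {
  lv <- .letters40()
  depths <- c(seq(1.2, 0.7, length.out = 13),          # 1-13 NT high
              0.4, 0.0, -0.25,                         # 14-16 descend
              rep(-0.45, 5),                           # 17-21 CHC buried
              -0.1, 0.3, 0.6, 0.8, 0.8, 0.6, 0.3, 0.0, # 22-29 CL loop out
              rep(-0.55, 11))                          # 30-40 CT buried
  p1 <- .spiral_path(16, depths[1:16], center = c(-1.9, 0.4))
  p2 <- .spiral_path(13, depths[17:29], center = c(0.7, -1.2))
  p3 <- .spiral_path(11, depths[30:40], center = c(1.4, 1.3))
  tab <- .path_conformation(lv, rbind(p1, p2, p3))
  list(tab = .recenter_xy(tab), planted_depth = depths,
       ss_template = rep("coil", 40))
}

# unbound: compact coil far above the surface; the exact COM distance is
# set by the caller.
.conf_unbound <- function() {
  lv <- .letters40()
  depths <- 0.25 * sin(seq_len(40) / 3)
  tab <- .path_conformation(lv, .spiral_path(40, depths))
  list(tab = .recenter_xy(tab), planted_depth = depths,
       ss_template = rep("coil", 40))
}

.model_conformation <- function(model) {
  switch(model,
         model1 = .conf_model1(), model2 = .conf_model2(),
         model3 = .conf_model3(), model4 = .conf_model4(),
         unbound = .conf_unbound(),
         stop("unknown model template: ", model))
}

# donor atoms (heavy, hydrogen) used to pose a planted hydrogen bond
.planted_donor_atoms <- function(letter) {
  sites <- .SITE_ATOMS[[letter]]
  if (!is.null(sites)) {
    if (letter %in% c("N", "Q")) return(sites[2:3])
    if (length(sites) == 2) return(sites)
  }
  c("N", "H")
}

#' Generate a synthetic binding ensemble with planted ground truth
#'
#' Builds the bilayer and the template conformation, poses the peptide in
#' every frame (random z-rotation plus truncated Gaussian rigid-body
#' noise), optionally relocates one lipid headgroup oxygen per planted
#' hydrogen bond so the geometric criterion is met exactly, and returns
#' the trajectory together with the planted truth.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `trajectory` and `truth` (`model`, `bound`, `distance`
#'   per frame; `planted_depth`, `ss_template` per residue;
#'   `planted_hbonds`).
#' @export
generate_binding_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$model_template != "unbound") {
    confs <- list()
    if (spec$model_template == "mixture") {
      confs$bound <- .conf_model1()
      confs$unbound <- .conf_unbound()
    } else {
      confs$bound <- .model_conformation(spec$model_template)
    }
  } else {
    confs <- list(unbound = .conf_unbound())
  }
  for (nm in names(confs)) {
    if (any(confs[[nm]]$planted_depth < -spec$half_thickness)) {
      stop("template plants residues deeper than the bilayer midplane")
    }
  }
  bil <- build_bilayer(per_leaflet = spec$per_leaflet,
                       spacing = spec$spacing,
                       half_thickness = spec$half_thickness,
                       box_z = spec$box_z, seed = spec$seed)
  pep_conf <- confs[[1]]
  pep_rec <- peptide_from_table(pep_conf$tab)$records
  n_pep <- nrow(pep_rec)
  bil_rec <- bil$records
  bil_rec$serial <- bil_rec$serial + n_pep
  recs <- rbind(pep_rec, bil_rec)
  sys <- build_system(recs)
  set.seed(spec$seed + 1L)

  # frame -> conformation assignment
  n <- spec$n_frames
  which_conf <- rep("bound", n)
  if (spec$model_template == "unbound") which_conf <- rep("unbound", n)
  if (spec$model_template == "mixture") {
    n_bound <- round(spec$mixture_bound_fraction * n)
    which_conf <- rep("unbound", n)
    which_conf[sample.int(n, n_bound)] <- "bound"
  }

  center_xy <- bil$box[1:2] / 2
  truncn <- function(k) pmin(pmax(stats::rnorm(k, 0, spec$noise_sd),
                                  -spec$noise_trunc), spec$noise_trunc)
  frames <- vector("list", n)
  dist_truth <- numeric(n)
  model_truth <- character(n)
  for (f in seq_len(n)) {
    cf <- confs[[which_conf[f]]]
    xyz <- as.matrix(cf$tab[, c("x", "y", "z")])
    if (spec$rotate) {
      th <- stats::runif(1, 0, 2 * pi)
      R <- .rot_z(th)
      ctr <- colMeans(xyz)
      xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, -ctr)
    }
    shift <- c(center_xy, bil$surface_z) + truncn(3)
    if (which_conf[f] == "unbound") {
      # exact COM placement before noise
      m <- pep_rec$mass
      z_com <- sum(m * xyz[, 3]) / sum(m)
      shift[3] <- bil$center_z + spec$com_distance - z_com + truncn(1)[1] *
        (spec$noise_sd > 0)
    }
    xyz <- sweep(xyz, 2, -shift)
    coords <- rbind(xyz, bil$coords)
    # pose planted hydrogen bonds (bound frames only)
    if (which_conf[f] == "bound" && length(spec$planted_hbonds)) {
      for (hb in spec$planted_hbonds) {
        r <- as.integer(hb[["residue"]])
        sp_name <- hb[["species"]]
        letter <- substr(AB40_SEQUENCE, r, r)
        dn <- .planted_donor_atoms(letter)
        di <- which(pep_rec$residue_index == r & pep_rec$name == dn[1])
        hi <- which(pep_rec$residue_index == r & pep_rec$name == dn[2])
        if (!length(di) || !length(hi)) {
          stop("residue ", r, " has no donor site for a planted H-bond")
        }
        u <- .unit(coords[hi, ] - coords[di, ])
        target <- coords[di, ] + 0.28 * u
        cand <- which(bil$species == sp_name)
        if (!length(cand)) stop("no ", sp_name, " lipid to accept the bond")
        acc_name <- if (sp_name == "CHOL") "O3" else "OP1"
        acc_rows <- n_pep + vapply(cand, function(l) {
          first <- bil$lipid_first_atom[l]
          tmpl <- .LIPID_TEMPLATE[[sp_name]]
          first + match(acc_name, tmpl$name) - 1L
        }, integer(1))
        # upper leaflet, laterally nearest
        upper <- bil$coords[acc_rows - n_pep, 3] > bil$center_z
        acc_rows <- acc_rows[upper]
        lat <- sqrt((bil$coords[acc_rows - n_pep, 1] - target[1])^2 +
                      (bil$coords[acc_rows - n_pep, 2] - target[2])^2)
        coords[acc_rows[which.min(lat)], ] <- target
      }
    }
    frames[[f]] <- new_frame(coords, bil$box,
                             time = (f - 1) * spec$frame_spacing)
    m_all <- recs$mass
    pep_i <- seq_len(n_pep)
    bil_i <- (n_pep + 1):nrow(recs)
    z_p <- sum(m_all[pep_i] * coords[pep_i, 3]) / sum(m_all[pep_i])
    z_b <- sum(m_all[bil_i] * coords[bil_i, 3]) / sum(m_all[bil_i])
    dist_truth[f] <- abs(z_p - z_b)
    model_truth[f] <- if (which_conf[f] == "unbound") "unbound" else
      if (spec$model_template == "mixture") "model1" else spec$model_template
  }
  traj <- new_trajectory(sys, frames,
                         label = paste0("synthetic-", spec$model_template))
  truth <- list(model = model_truth, bound = which_conf == "bound",
                distance = dist_truth,
                planted_depth = pep_conf$planted_depth,
                ss_template = pep_conf$ss_template,
                planted_hbonds = spec$planted_hbonds,
                spec = spec)
  list(trajectory = traj, truth = truth)
}
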