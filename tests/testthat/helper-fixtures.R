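# Shared fixtures and independent oracles, built in code at test time.

# random two-group heavy-atom system in a periodic box
random_contact_system <- function(n_a = 250, n_b = 250, box = c(4, 4, 4),
                                  seed = 1, straddle = 0) {
  set.seed(seed)
  coords_a <- cbind(runif(n_a, 0, box[1]), runif(n_a, 0, box[2]),
                    runif(n_a, 0, box[3]))
  coords_b <- cbind(runif(n_b, 0, box[1]), runif(n_b, 0, box[2]),
                    runif(n_b, 0, box[3]))
  if (straddle > 0) {
    # place pairs just below / above / exactly at the cutoff
    d <- rep(c(0.499, 0.501, 0.5), length.out = straddle)
    for (k in seq_len(straddle)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      coords_b[k, ] <- (coords_a[k, ] + d[k] * u) %% box
    }
  }
  rec <- atom_records(
    seq_len(n_a + n_b),
    name = rep("CA", n_a + n_b),
    residue_index = c(((seq_len(n_a) - 1) %% 40) + 1L,
                      40L + seq_len(n_b)),
    residue_name = c(rep("ALA", n_a), rep("POPC", n_b)))
  sys <- build_system(rec)
  list(system = sys,
       frame = new_frame(rbind(coords_a, coords_b), box),
       a = seq_len(n_a), b = n_a + seq_len(n_b))
}

# 27-periodic-image brute force distance (points wrapped into the box
# first; +-1 images then cover every case)
image27_distance <- function(p, q, box) {
  p <- p %% box
  q <- q %% box
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- p - (q + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# explicit-loop contact count (independent of both package routes)
loop_count_contacts <- function(coords_a, coords_b, box, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(coords_a))) {
    for (j in seq_len(nrow(coords_b))) {
      if (image27_distance(coords_a[i, ], coords_b[j, ], box) <= cutoff) {
        n <- n + 1L
      }
    }
  }
  n
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rotation-space minimisation oracle for the Kabsch RMSD: coarse Euler-angle
# grid followed by local refinement; never uses the SVD route.
grid_rmsd_oracle <- function(reference, coords) {
  p <- sweep(coords, 2, colMeans(coords))
  q <- sweep(reference, 2, colMeans(reference))
  rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
             sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
             -sy, cy * sx, cy * cx), 3, 3, byrow = TRUE)
  }
  f <- function(a) sqrt(mean(rowSums((p %*% t(rot(a)) - q)^2)))
  gr <- seq(0, 2 * pi, length.out = 13)[-13]
  gr2 <- seq(-pi / 2, pi / 2, length.out = 7)
  best <- Inf; best_a <- c(0, 0, 0)
  for (a1 in gr) for (a2 in gr2) for (a3 in gr) {
    v <- f(c(a1, a2, a3))
    if (v < best) { best <- v; best_a <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best_a, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  opt$value
}

# direct hydrogen-bond criterion re-evaluation, written independently of
# detect_hbonds (scalar loops, explicit trig)
oracle_hbonds <- function(system, frame, config, table) {
  out <- list()
  for (d in seq_len(nrow(table$donors))) {
    for (a in seq_len(nrow(table$acceptors))) {
      di <- table$donors$d_idx[d]; hi <- table$donors$h_idx[d]
      ai <- table$acceptors$a_idx[a]
      if (di == ai) next
      if (table$donors$residue[d] == table$acceptors$residue[a]) next
      pep_pair <- table$donors$group[d] == "peptide" &&
        table$acceptors$group[a] == "peptide"
      if (pep_pair &&
          abs(table$donors$residue[d] - table$acceptors$residue[a]) < 2) next
      dist <- image27_distance(frame$coords[di, ], frame$coords[ai, ],
                               frame$box)
      if (dist > config$hbond_da_cutoff) next
      vh <- frame$coords[hi, ] - frame$coords[di, ]
      va <- frame$coords[ai, ] - frame$coords[di, ]
      va <- va - frame$box * round(va / frame$box)
      ang <- acos(max(-1, min(1, sum(vh * va) /
                                (sqrt(sum(vh^2)) * sqrt(sum(va^2)))))) *
        180 / pi
      if (ang <= config$hbond_angle_cutoff) {
        out[[length(out) + 1]] <- c(di, ai)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = 2)
}

# minimal donor/acceptor playground: one serine (backbone + OG donor) and
# k lipid-like acceptor oxygens at given positions
hbond_playground <- function(acceptor_pos, box = c(6, 6, 6),
                             donor_o = c(3, 3, 3), donor_h = NULL) {
  if (is.null(donor_h)) donor_h <- donor_o + c(0.1, 0, 0)
  k <- nrow(acceptor_pos)
  rec <- atom_records(
    seq_len(5 + k),
    name = c("N", "CA", "C", "OG", "HG", rep("OP1", k)),
    residue_index = c(rep(1L, 5), 41L + seq_len(k)),
    residue_name = c(rep("SER", 5), rep("POPC", k)))
  sys <- build_system(rec)
  coords <- rbind(donor_o + c(-0.4, 0.3, 0), donor_o + c(-0.25, 0.1, 0),
                  donor_o + c(-0.45, -0.1, 0), donor_o, donor_h,
                  acceptor_pos)
  list(system = sys, frame = new_frame(coords, box))
}

quiet_config <- function(...) analysis_config(equilibration_discard = 0, ...)

cached_ensemble <- local({
  cache <- list()
  function(model, n_frames = 20, seed = 11, ...) {
    key <- paste(model, n_frames, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_binding_ensemble(
        synthetic_spec(model, n_frames = n_frames, seed = seed, ...))
    }
    cache[[key]]
  }
})
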