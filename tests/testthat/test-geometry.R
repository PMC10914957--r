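test_that("minimum-image distance wraps correctly", {
  box <- c(6, 6, 6)
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), box), 0)
  expect_equal(min_image_distance(c(0, 0, 0), c(0, 0, 5.4), box), 0.6)
  # against the 27-image brute force
  set.seed(42)
  for (k in 1:200) {
    box_k <- runif(3, 2, 8)
    p <- runif(3, -5, 15); q <- runif(3, -5, 15)
    expect_equal(min_image_distance(p, q, box_k),
                 image27_distance(p, q, box_k), tolerance = 1e-12)
  }
})

test_that("center of mass is mass-weighted and equivariant", {
  rec <- atom_records(1:2, c("CA", "CA"), 1:2, "GLY", mass = c(1, 3))
  sys <- build_system(rec)
  fr <- new_frame(rbind(c(0, 0, 0), c(0, 0, 4)), c(10, 10, 10))
  expect_equal(center_of_mass(sys, fr, 1:2), c(0, 0, 3))
  fr_eq <- new_frame(rbind(c(0, 0, 1), c(0, 0, 3)), c(10, 10, 10))
  rec_eq <- atom_records(1:2, c("CA", "CA"), 1:2, "GLY")
  expect_equal(center_of_mass(build_system(rec_eq), fr_eq, 1:2), c(0, 0, 2))
  shifted <- new_frame(fr$coords + rep(c(1, 2, 3), each = 2), fr$box)
  expect_equal(center_of_mass(sys, shifted, 1:2),
               center_of_mass(sys, fr, 1:2) + c(1, 2, 3))
  expect_error(center_of_mass(sys, fr, integer(0)), "empty")
})

test_that("peptide-bilayer distance matches planted placements", {
  ens <- generate_binding_ensemble(
    synthetic_spec("unbound", n_frames = 2, seed = 1, com_distance = 3.2,
                   noise_sd = 0))
  d <- peptide_bilayer_distance(ens$trajectory$topology,
                                ens$trajectory$frames[[1]])
  expect_equal(d, 3.2, tolerance = 1e-6)
  ens2 <- generate_binding_ensemble(
    synthetic_spec("unbound", n_frames = 1, seed = 1, com_distance = 5.01,
                   noise_sd = 0))
  expect_equal(peptide_bilayer_distance(ens2$trajectory$topology,
                                        ens2$trajectory$frames[[1]]),
               5.01, tolerance = 1e-6)
})

test_that("residue depths obey the half-thickness identity", {
  cfg <- quiet_config()
  # two residues: one 2.5 nm above the bilayer COM, one 1.5 nm above
  rec <- atom_records(1:4, c("CA", "CA", "P", "P"),
                      c(1L, 2L, 41L, 42L), c("ALA", "ALA", "POPC", "POPC"))
  sys <- build_system(rec)
  fr <- new_frame(rbind(c(0, 0, 4.5), c(0, 0, 3.5), c(0, 0, 2), c(0, 0, 2)),
                  c(10, 10, 10))
  d <- residue_depths(sys, fr, cfg)
  expect_equal(unname(d["1"]), 0.5)
  expect_equal(unname(d["2"]), -0.5)
  # identity: depth + half_thickness == |dz| exactly
  zb <- 2
  expect_equal(unname(d) + cfg$half_thickness, abs(c(4.5, 3.5) - zb))
  # planted model-3 frame: at least half of CT buried
  ens <- cached_ensemble("model3")
  dd <- residue_depths(ens$trajectory$topology, ens$trajectory$frames[[1]],
                       cfg)
  ct <- as.character(30:40)
  expect_gte(mean(dd[ct] < 0), 0.5)
})

test_that("contact counting honours the closed cutoff and heavy atoms", {
  cfg <- quiet_config()
  place <- function(d, name_b = "C1") {
    rec <- atom_records(1:2, c("CA", name_b), c(1L, 41L), c("ALA", "POPC"))
    sys <- build_system(rec)
    fr <- new_frame(rbind(c(1, 1, 1), c(1, 1, 1 + d)), c(8, 8, 8))
    count_contacts(sys, fr, cfg, selection_a = 1L, selection_b = 2L)
  }
  expect_equal(place(0.49)$n_contacts, 1)
  expect_equal(place(0.51)$n_contacts, 0)
  expect_equal(place(0.50)$n_contacts, 1)   # closed cutoff
  # hydrogen near a lipid atom contributes nothing
  rec <- atom_records(1:3, c("CA", "HA", "C1"), c(1L, 1L, 41L),
                      c("ALA", "ALA", "POPC"))
  sys <- build_system(rec)
  fr <- new_frame(rbind(c(1, 1, 1), c(1, 1, 2.8), c(1, 1, 3)), c(8, 8, 8))
  r <- count_contacts(sys, fr, cfg, selection_a = 1:2, selection_b = 3L)
  expect_equal(r$n_contacts, 0)
  expect_error(count_contacts(sys, fr, cfg, 1:2, 2:3), "disjoint")
})

test_that("cell list and brute force agree exactly, incl. straddling pairs", {
  cfg <- quiet_config()
  for (seed in 1:12) {
    s <- random_contact_system(120, 120, box = runif(3, 3, 5), seed = seed,
                               straddle = 9)
    cell <- count_contacts(s$system, s$frame, cfg, s$a, s$b, method = "cell")
    brute <- count_contacts(s$system, s$frame, cfg, s$a, s$b,
                            method = "brute")
    expect_identical(cell$n_contacts, brute$n_contacts)
    expect_identical(cell$atom_contact, brute$atom_contact)
  }
  # symmetry and an independent explicit-loop check on one small system
  s <- random_contact_system(25, 30, box = c(3, 3, 3), seed = 99,
                             straddle = 6)
  ab <- count_contacts(s$system, s$frame, cfg, s$a, s$b)
  ba <- count_contacts(s$system, s$frame, cfg, s$b, s$a)
  expect_identical(ab$n_contacts, ba$n_contacts)
  expect_identical(ab$n_contacts,
                   loop_count_contacts(s$frame$coords[s$a, ],
                                       s$frame$coords[s$b, ],
                                       s$frame$box, cfg$contact_cutoff))
  # monotone in the cutoff
  n_prev <- -1L
  for (cut in c(0.3, 0.5, 0.8)) {
    n_cut <- count_contacts(s$system, s$frame, quiet_config(contact_cutoff = cut),
                            s$a, s$b)$n_contacts
    expect_gte(n_cut, n_prev)
    n_prev <- n_cut
  }
})

test_that("contact fractions average per-frame flags", {
  cfg <- quiet_config()
  rec <- atom_records(1:2, c("CA", "P"), c(1L, 41L), c("ALA", "POPC"))
  sys <- build_system(rec)
  near <- new_frame(rbind(c(1, 1, 1), c(1, 1, 1.3)), c(8, 8, 8))
  far <- new_frame(rbind(c(1, 1, 1), c(1, 1, 4)), c(8, 8, 8))
  traj <- new_trajectory(sys, list(near, far, far, far))
  cf <- contact_fractions(traj, cfg)
  expect_equal(unname(cf$fraction["1"]), 0.25)
  # bound-only restriction uses only the contacting frame
  cfb <- contact_fractions(traj, cfg, bound_only = TRUE)
  expect_equal(unname(cfb$fraction["1"]), 1)
  expect_equal(cfb$n_frames_used, 1)
  # a planted anchor residue touches in every frame of a bound ensemble
  ens <- cached_ensemble("model1")
  cf2 <- contact_fractions(ens$trajectory, cfg)
  expect_equal(unname(cf2$fraction["40"]), 1)
})

test_that("residue contact map is symmetric with a near-diagonal chain band", {
  cfg <- quiet_config()
  ext <- build_peptide(AB40_SEQUENCE, "strand")
  sys <- build_system(ext$records)
  traj <- new_trajectory(sys, list(new_frame(ext$coords + 30, c(60, 60, 60))))
  m <- residue_contact_map(traj, cfg)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 1))
  # extended chain: neighbours touch, long-range pairs do not
  expect_true(all(m[cbind(1:39, 2:40)] == 1))
  far <- abs(row(m) - col(m)) >= 4
  expect_equal(max(m[far]), 0)
  # planted hairpin: anti-diagonal pairing band
  h <- build_hairpin()
  sysh <- build_system(h$records)
  mh <- residue_contact_map(
    new_trajectory(sysh, list(new_frame(h$coords + 30, c(60, 60, 60)))), cfg)
  pairs <- cbind(2:6, 15:11)  # strand1 vs reversed strand2
  expect_true(all(mh[pairs] == 1))
})

test_that("top long-range pairs are ranked with deterministic ties", {
  cfg <- quiet_config()
  m <- diag(40)
  m[2, 30] <- m[30, 2] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.95  # |i-j| = 2: excluded at min separation 3
  m[5, 10] <- m[10, 5] <- 0.4
  m[6, 11] <- m[11, 6] <- 0.4
  top <- top_longrange_pairs(m, 3, cfg)
  expect_equal(unlist(top[1, c("i", "j")]), c(i = 2, j = 30))
  expect_false(any(top$i == 1 & top$j == 3))
  # tie broken lexicographically
  expect_equal(unlist(top[2, c("i", "j")]), c(i = 5, j = 10))
  expect_equal(unlist(top[3, c("i", "j")]), c(i = 6, j = 11))
  # k larger than available pairs returns all
  expect_lte(nrow(top_longrange_pairs(m, 1e6, cfg)), sum(upper.tri(m)))
})

test_that("Kabsch RMSD is exact under rigid motion and matches grid oracle", {
  set.seed(7)
  ref <- matrix(rnorm(30), 10, 3)
  expect_lt(kabsch_rmsd(ref, ref), 1e-10)
  for (seed in 1:5) {
    rot <- random_rotation(seed)
    moved <- ref %*% t(rot) + rep(runif(3, -2, 2), each = 10)
    expect_lt(kabsch_rmsd(ref, moved), 1e-9)
    # invariance of the value itself under motion of either argument
    set.seed(seed + 100)
    other <- ref + matrix(rnorm(30, sd = 0.05), 10, 3)
    v1 <- kabsch_rmsd(ref, other)
    v2 <- kabsch_rmsd(ref %*% t(rot), other %*% t(random_rotation(seed + 5)))
    expect_equal(v1, v2, tolerance = 1e-9)
  }
  # displaced-atom toy case vs rotation-grid oracle
  for (seed in 1:3) {
    set.seed(seed)
    coords <- ref
    coords[1, ] <- coords[1, ] + rnorm(3, sd = 0.3)
    expect_equal(kabsch_rmsd(ref, coords), grid_rmsd_oracle(ref, coords),
                 tolerance = 1e-3)
  }
  expect_error(kabsch_rmsd(ref, ref[1:5, ]), "differ in size")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch_rmsd(line, line), "collinear")
})
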