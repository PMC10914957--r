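test_that("free energies follow -kT ln P with a zero minimum", {
  cfg <- quiet_config()
  # all samples in one bin
  g1 <- compute_fel_2d(rep(1, 50), rep(2, 50), 0.05, 1, config = cfg)
  expect_equal(sum(g1$occupied), 1)
  expect_equal(g1$G[g1$occupied], 0)
  expect_true(all(is.na(g1$G[!g1$occupied])))
  # two equally occupied bins: both G = 0 after the shift
  g2 <- compute_fel_2d(c(rep(0.1, 30), rep(0.9, 30)), rep(0, 60), 0.5, 1,
                       config = cfg)
  expect_equal(unname(g2$G[g2$occupied]), c(0, 0))
  # closed form: counts n1, n2 give dG = ln(n1/n2) exactly
  n1 <- 2000L; n2 <- 700L
  g3 <- compute_fel_2d(c(rep(0.1, n1), rep(0.9, n2)), rep(0, n1 + n2),
                       0.5, 1, config = cfg)
  dg <- max(g3$G, na.rm = TRUE)
  expect_equal(dg, log(n1 / n2), tolerance = 1e-12)
  # probabilities are duplication invariant
  g4 <- compute_fel_2d(rep(c(rep(0.1, n1), rep(0.9, n2)), 2),
                       rep(0, 2 * (n1 + n2)), 0.5, 1, config = cfg)
  expect_equal(g4$P[g4$occupied], g3$P[g3$occupied])
  expect_equal(sum(g3$P), 1)
})

test_that("kT to kcal/mol conversion uses k = 0.0019872 at T = 343 K", {
  cfg <- quiet_config()
  dg_kcal <- basin_relative_free_energy(c(exp(1) * 1000, 1000), cfg,
                                        unit = "kcal")
  expect_equal(dg_kcal[1], 0)
  expect_equal(dg_kcal[2], 0.0019872 * 343, tolerance = 1e-4)
  expect_equal(dg_kcal[2], 0.6816, tolerance = 1e-3)
})

test_that("1D projection finds the planted mixture minima", {
  cfg <- quiet_config()
  x <- sample_two_state_cv(c(2.65, 3.45), c(0.1, 0.1), c(0.5, 0.5),
                           n = 1e5, seed = 5)
  prof <- project_fel_1d(x, width = cfg$fel_bins_distance, config = cfg)
  # deepest bin on each side of the midpoint between the wells
  left <- prof$mid < 3.05
  m1 <- prof$mid[left][which.min(prof$G[left])]
  m2 <- prof$mid[!left][which.min(prof$G[!left])]
  expect_lt(abs(m1 - 2.65), cfg$fel_bins_distance + 1e-9)
  expect_lt(abs(m2 - 3.45), cfg$fel_bins_distance + 1e-9)
  # single Gaussian: minimum at the mean within one bin
  x1 <- sample_two_state_cv(3.0, 0.1, 1, n = 5e4, seed = 6)
  p1 <- project_fel_1d(x1, width = 0.05, config = cfg)
  expect_lt(abs(p1$mid[which.min(p1$G)] - 3.0), 0.05 + 1e-9)
  # uniform sample: flat profile at large n
  set.seed(8)
  pu <- project_fel_1d(runif(1e6, 0, 1), width = 0.1, config = cfg)
  expect_lt(max(pu$G, na.rm = TRUE) - min(pu$G, na.rm = TRUE), 0.2)
})

test_that("basin detection separates the planted two-Gaussian wells", {
  cfg <- quiet_config()
  x <- sample_two_state_cv(c(2.65, 3.45), c(0.1, 0.1), c(0.5, 0.5),
                           n = 2e4, seed = 9)
  set.seed(10)
  y <- rnorm(length(x), 10, 2)
  grid <- compute_fel_2d(x, y, 0.05, 1.0, "distance", "y", cfg)
  bs <- find_basins(grid, cfg$basin_min_depth_kT,
                    cfg$basin_min_separation_bins)
  expect_equal(nrow(bs$basins), 2)
  expect_lt(abs(sort(bs$basins$x)[1] - 2.65), 0.05 + 1e-9)
  expect_lt(abs(sort(bs$basins$x)[2] - 3.45), 0.05 + 1e-9)
  # labels ordered by descending distance coordinate
  expect_gt(bs$basins$x[bs$basins$label == "a"],
            bs$basins$x[bs$basins$label == "b"])
  # member assignment partitions the samples
  expect_false(anyNA(bs$sample_basin))
  expect_equal(sum(bs$basins$population), length(x))
  # single Gaussian: one basin
  g1 <- compute_fel_2d(sample_two_state_cv(3, 0.1, 1, 2e4, seed = 11),
                       rnorm(2e4), 0.05, 1.0, config = cfg)
  expect_equal(nrow(find_basins(g1, 1, 2)$basins), 1)
})

test_that("coarser grids never create additional basins", {
  cfg <- quiet_config()
  x <- sample_two_state_cv(c(2.65, 3.45), c(0.1, 0.1), c(0.5, 0.5),
                           n = 2e4, seed = 12)
  set.seed(13)
  y <- rnorm(length(x), 5, 1)
  n_prev <- Inf
  for (w in c(0.05, 0.1, 0.2, 0.5)) {
    g <- compute_fel_2d(x, y, w, 1.0, config = cfg)
    nb <- nrow(find_basins(g, cfg$basin_min_depth_kT,
                           cfg$basin_min_separation_bins)$basins)
    expect_lte(nb, n_prev)
    n_prev <- nb
  }
})

test_that("relative basin free energies mask empty basins", {
  cfg <- quiet_config()
  expect_equal(basin_relative_free_energy(c(100, 100), cfg), c(0, 0))
  dg <- basin_relative_free_energy(c(exp(1) * 500, 500), cfg)
  expect_equal(dg, c(0, 1), tolerance = 1e-12)
  dg0 <- basin_relative_free_energy(c(10, 0, 5), cfg)
  expect_true(is.na(dg0[2]))
  expect_equal(dg0[1], 0)  # most populated basin is always the zero point
  expect_error(basin_relative_free_energy(c(0, 0), cfg), "not all zero")
})

test_that("bound partition and planted fractions agree exactly", {
  cfg <- quiet_config()
  mix <- cached_ensemble("mixture", n_frames = 16, seed = 21)
  pb <- partition_bound(mix$trajectory, cfg)
  expect_identical(pb, mix$truth$bound)
  expect_equal(mean(pb), 0.5)
  # n_contacts = 0 <=> unbound; 1 contact suffices for bound
  feats <- data.frame(n_contacts = c(0, 1), n_contact_residues = c(0, 1),
                      beta = 0, helix = 0, nt_helix = 0, min_depth = 1,
                      buried_NT = 0, buried_CHC = 0, buried_CL = 0,
                      buried_CT = 0)
  lab <- classify_binding_model(feats, cfg)
  expect_equal(lab[1], "unbound")
  expect_false(lab[2] == "unbound")
})

test_that("classifier is total, deterministic, and needs its features", {
  cfg <- quiet_config()
  expect_error(classify_binding_model(data.frame(n_contacts = 1), cfg),
               "missing classifier feature")
  ens <- cached_ensemble("model3", n_frames = 8)
  f <- frame_features(ens$trajectory, cfg)
  l1 <- classify_binding_model(f, cfg)
  l2 <- classify_binding_model(f, cfg)
  expect_identical(l1, l2)
  expect_true(all(l1 %in% c("model1", "model2", "model3", "model4",
                            "unbound", "unclassified")))
  expect_true(all(l1 == "model3"))
})

test_that("per-basin landscapes split planted conformers into microstates", {
  cfg <- quiet_config()
  mix <- cached_ensemble("mixture", n_frames = 16, seed = 21)
  ref_frame <- which(mix$truth$bound)[1]
  pep <- mix$trajectory$topology$idx$peptide_heavy
  ref <- mix$trajectory$frames[[ref_frame]]$coords[pep, ]
  pb <- per_basin_fel(mix$trajectory, seq_along(mix$trajectory$frames),
                      ref, cfg, basin_label = "c")
  # two conformers: beta-rich sheet vs coil
  expect_setequal(unique(pb$frame_microstate), c("c1", "c2"))
  hi <- pb$microstates$microstate[pb$microstates$mean_beta >= 0.2]
  expect_true(all(hi == "c1"))
  # homogeneous members give a single microstate
  one <- generate_binding_ensemble(
    synthetic_spec("model1", n_frames = 6, seed = 2, noise_sd = 0,
                   rotate = FALSE))
  ref1 <- one$trajectory$frames[[1]]$coords[
    one$trajectory$topology$idx$peptide_heavy, ]
  pb1 <- suppressWarnings(
    per_basin_fel(one$trajectory, 1:6, ref1, cfg, basin_label = "a"))
  expect_equal(nrow(pb1$microstates), 1)
  expect_error(per_basin_fel(one$trajectory, integer(0), ref1, cfg),
               "no member frames")
})
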