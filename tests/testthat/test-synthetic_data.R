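test_that("ideal-geometry chaining produces correct bonds and helix rise", {
  p <- build_peptide(AB40_SEQUENCE, "coil", seed = 4)
  at <- p$records
  # every residue carries the five backbone/amide atoms
  for (nm in c("N", "CA", "C", "O", "H")) {
    expect_equal(sum(at$name == nm), 40)
  }
  # peptide-bond C-N distances at ideal geometry
  cn <- vapply(1:39, function(i) {
    ci <- which(at$residue_index == i & at$name == "C")
    ni <- which(at$residue_index == i + 1 & at$name == "N")
    sqrt(sum((p$coords[ci, ] - p$coords[ni, ])^2))
  }, numeric(1))
  expect_true(all(abs(cn - 0.1329) < 1e-4))
  # helix rise per residue along the helix axis ~ 0.15 nm
  h <- build_peptide(substr(AB40_SEQUENCE, 1, 14), "helix")
  ca <- h$coords[h$records$name == "CA", ]
  axis <- ca[14, ] - ca[1, ]
  axis <- axis / sqrt(sum(axis^2))
  rises <- (ca[-1, ] - ca[-14, ]) %*% axis
  expect_lt(abs(mean(rises) - 0.15), 0.02)
  expect_error(build_peptide("AXZ"), "unknown residue")
})

test_that("bilayer builder places the planted composition symmetrically", {
  bil <- build_bilayer()
  tab <- table(bil$records$residue_name[!duplicated(bil$records$residue_index)])
  expect_equal(unname(tab[c("POPC", "POPS", "CHOL")]),
               c(108, 36, 36), ignore_attr = TRUE)
  # COM at the bilayer center by mirror symmetry
  com_z <- sum(bil$records$mass * bil$coords[, 3]) / sum(bil$records$mass)
  expect_equal(com_z, bil$center_z, tolerance = 1e-6)
  # headgroup phosphate plane sits at +- half thickness
  heads <- bil$records$name == "P"
  expect_true(all(abs(abs(bil$coords[heads, 3] - bil$center_z) - 2.0) < 0.1))
  expect_error(build_bilayer(box_xy = c(2, 2)), "too many lipids")
})

test_that("ensembles are reproducible bit for bit from the seed", {
  s <- synthetic_spec("model2", n_frames = 3, seed = 42)
  e1 <- generate_binding_ensemble(s)
  e2 <- generate_binding_ensemble(s)
  expect_identical(e1$trajectory$frames[[3]]$coords,
                   e2$trajectory$frames[[3]]$coords)
  expect_identical(e1$truth, e2$truth)
  # written logs are byte-identical too
  lad <- make_ladder(343, 500, 4)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_exchange_log(generate_exchange_log(lad, 100, 0.3, seed = 5), f1)
  write_exchange_log(generate_exchange_log(lad, 100, 0.3, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted model-1 geometry buries only the C-terminus", {
  cfg <- quiet_config()
  ens <- cached_ensemble("model1")
  sys <- ens$trajectory$topology
  for (fi in c(1, 7)) {
    d <- residue_depths(sys, ens$trajectory$frames[[fi]], cfg)
    buried <- as.integer(names(d)[d < 0])
    expect_true(all(buried >= 30))
    expect_gte(length(buried), 1)
  }
  # beta template ~40%
  ss <- assign_secstruct(sys, ens$trajectory$frames[[1]])
  expect_gte(beta_content(ss), 0.30)
  expect_lte(beta_content(ss), 0.50)
})

test_that("unbound ensembles at 5 nm never touch the bilayer", {
  cfg <- quiet_config()
  ens <- generate_binding_ensemble(
    synthetic_spec("unbound", n_frames = 5, seed = 8, com_distance = 5))
  for (f in ens$trajectory$frames) {
    expect_equal(count_contacts(ens$trajectory$topology, f,
                                cfg)$n_contacts, 0)
  }
})

test_that("mixture ensembles recover the planted bound fraction exactly", {
  cfg <- quiet_config()
  ens <- cached_ensemble("mixture", n_frames = 16, seed = 21)
  pb <- partition_bound(ens$trajectory, cfg)
  expect_equal(mean(pb), 0.5)
  expect_identical(pb, ens$truth$bound)
})

test_that("planted hydrogen bonds are detected in every bound frame", {
  cfg <- quiet_config()
  ens <- generate_binding_ensemble(
    synthetic_spec("model3", n_frames = 6, seed = 13,
                   planted_hbonds = list(c(residue = 5, species = "POPS"),
                                         c(residue = 28, species = "POPC"))))
  tab <- build_da_table(ens$trajectory$topology,
                        ens$trajectory$frames[[1]], cfg)
  hits <- vapply(ens$trajectory$frames, function(f) {
    rec <- detect_hbonds(ens$trajectory$topology, f, cfg, tab)
    sum(rec$donor_res == 5 & rec$partner_class == "POPS") >= 1 &&
      sum(rec$donor_res == 28 & rec$partner_class == "POPC") >= 1
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("mixture CV closed form: mode weights give the analytic dG", {
  x <- sample_two_state_cv(c(0, 3), c(0.2, 0.2), c(exp(1), 1), n = 1e5,
                           seed = 31)
  comp <- attr(x, "components")
  dg <- -log(sum(comp == 2) / sum(comp == 1))
  expect_lt(abs(dg - 1), 0.05)
  # degenerate weights: all samples from mode 1
  x1 <- sample_two_state_cv(c(0, 3), c(0.2, 0.2), c(1, 0), n = 100, seed = 1)
  expect_true(all(attr(x1, "components") == 1))
  expect_error(sample_two_state_cv(0, -1, 1, 10), "positive")
  # requesting burial below the midplane errors
  expect_error(generate_binding_ensemble(
    synthetic_spec("model1", n_frames = 1, half_thickness = 0.1)), "deeper")
})
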