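test_that("donor/acceptor table encodes standard chemistry", {
  cfg <- quiet_config()
  # full arginine: guanidinium contributes 5 (N, H) donor pairs + backbone
  rec <- atom_records(
    1:15,
    c("N", "H", "CA", "C", "O", "CB", "NE", "HE", "NH1", "HH11", "HH12",
      "NH2", "HH21", "HH22", "HB1"),
    rep(1L, 15), "ARG")
  tab <- build_da_table(build_system(rec), config = cfg)
  side <- tab$donors[tab$donors$name != "N", ]
  expect_equal(nrow(side), 5)
  expect_setequal(unique(side$name), c("NE", "NH1", "NH2"))
  # water: two donors, one acceptor
  recw <- atom_records(1:3, c("O", "H1", "H2"), rep(50L, 3), "TIP3")
  tw <- build_da_table(build_system(recw), config = cfg)
  expect_equal(nrow(tw$donors), 2)
  expect_equal(nrow(tw$acceptors), 1)
  # alanine: no side-chain donors or acceptors
  reca <- atom_records(1:6, c("N", "H", "CA", "C", "O", "CB"), rep(1L, 6),
                       "ALA")
  ta <- build_da_table(build_system(reca), config = cfg)
  expect_equal(nrow(ta$donors), 1)       # backbone N-H only
  expect_equal(ta$acceptors$name, "O")   # backbone carbonyl only
  # mandatory donor without a resolvable hydrogen errors
  reck <- atom_records(1:6, c("N", "H", "CA", "C", "O", "NZ"), rep(1L, 6),
                       "LYS")
  expect_error(build_da_table(build_system(reck), config = cfg), "NZ")
  # Met sulfur acceptor is off by default, switchable
  recm <- atom_records(1:6, c("N", "H", "CA", "C", "O", "SD"), rep(1L, 6),
                       "MET")
  expect_false("SD" %in% build_da_table(build_system(recm),
                                        config = cfg)$acceptors$name)
  cfg_s <- quiet_config(met_sulfur_acceptor = TRUE)
  expect_true("SD" %in% build_da_table(build_system(recm),
                                       config = cfg_s)$acceptors$name)
})

test_that("detection honours both closed cutoffs", {
  cfg <- quiet_config()
  at_geom <- function(dist, angle_deg) {
    # acceptor in the xz-plane at the requested D-A distance and angle
    # from the D->H direction (+x)
    a <- c(3, 3, 3) + dist * c(cos(angle_deg * pi / 180), 0,
                               sin(angle_deg * pi / 180))
    pg <- hbond_playground(matrix(a, 1, 3))
    detect_hbonds(pg$system, pg$frame, cfg,
                  build_da_table(pg$system, pg$frame, cfg))
  }
  expect_equal(nrow(at_geom(0.29, 0)), 1)
  expect_equal(nrow(at_geom(0.31, 0)), 0)
  expect_equal(nrow(at_geom(0.29, 25)), 0)
  expect_equal(nrow(at_geom(0.30, 0)), 1)    # boundary distance counts
  expect_equal(nrow(at_geom(0.29, 20)), 1)   # boundary angle counts
  # monotone in both cutoffs
  n1 <- nrow(at_geom(0.29, 15))
  cfg_tight <- quiet_config(hbond_da_cutoff = 0.25, hbond_angle_cutoff = 10)
  pg <- hbond_playground(matrix(c(3.29, 3, 3.05), 1, 3))
  n_tight <- nrow(detect_hbonds(pg$system, pg$frame, cfg_tight,
                                build_da_table(pg$system, pg$frame,
                                               cfg_tight)))
  n_loose <- nrow(detect_hbonds(pg$system, pg$frame, cfg,
                                build_da_table(pg$system, pg$frame, cfg)))
  expect_gte(n_loose, n_tight)
})

test_that("alternative D-H...A angle convention is switchable", {
  cfg_dha <- quiet_config(hbond_angle_convention = "dha")
  # acceptor along the D->H axis: D-H...A angle is 180 degrees
  pg <- hbond_playground(matrix(c(3.28, 3, 3), 1, 3))
  rec <- detect_hbonds(pg$system, pg$frame, cfg_dha,
                       build_da_table(pg$system, pg$frame, cfg_dha))
  expect_equal(nrow(rec), 1)
})

test_that("detector matches direct criterion re-evaluation on random geometry", {
  cfg <- quiet_config()
  set.seed(31)
  for (rep in 1:10) {
    # 10 random acceptors scattered within 0.45 nm of the donor
    pos <- matrix(rep(c(3, 3, 3), each = 10), 10, 3) +
      matrix(runif(30, -0.45, 0.45), 10, 3)
    pg <- hbond_playground(pos)
    tab <- build_da_table(pg$system, pg$frame, cfg)
    got <- detect_hbonds(pg$system, pg$frame, cfg, tab)
    want <- oracle_hbonds(pg$system, pg$frame, cfg, tab)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      got_keys <- sort(paste(got$donor_atom, got$acceptor_res))
      want_keys <- sort(paste(pg$system$atoms$name[want[, 1]],
                              pg$system$atoms$residue_index[want[, 2]]))
      expect_identical(got_keys, want_keys)
    }
  }
})

test_that("per-residue summaries split by partner class consistently", {
  cfg <- quiet_config()
  ens <- generate_binding_ensemble(
    synthetic_spec("model2", n_frames = 6, seed = 3,
                   planted_hbonds = list(c(residue = 5, species = "POPS"))))
  hb <- hbond_summaries(ens$trajectory, cfg)
  r5 <- hb$per_residue[hb$per_residue$residue == 5, ]
  expect_gte(r5$membrane, 1.0)
  # membrane-class sums: per-residue means add up to per-frame totals
  # (each membrane bond involves exactly one peptide residue)
  expect_equal(sum(hb$per_residue$membrane), mean(hb$per_frame$membrane))
  expect_equal(sum(hb$per_residue$water), mean(hb$per_frame$water))
  # partner classes partition the records
  expect_true(all(hb$records$partner_class %in%
                    c("POPC", "POPS", "CHOL", "water", "peptide")))
})

test_that("no-hydrogen-contact frames give all-zero summaries", {
  cfg <- quiet_config()
  ens <- generate_binding_ensemble(
    synthetic_spec("unbound", n_frames = 2, seed = 4))
  hb <- hbond_summaries(ens$trajectory, cfg)
  expect_equal(sum(hb$per_residue$membrane), 0)
})

test_that("hydrogen-bond type ranking is deterministic", {
  rec <- data.frame(
    donor_atom = c(rep("NH1", 5), "NZ", "OG"),
    acceptor_atom = c(rep("OP1", 5), "OP1", "OP2"),
    partner_class = c(rep("POPS", 5), "POPC", "POPC"),
    stringsAsFactors = FALSE)
  top <- top_hbond_types(rec, 2)
  expect_equal(top$donor_atom[1], "NH1")
  expect_equal(top$count[1], 5)
  # ties lexicographic
  expect_equal(top$donor_atom[2], "NZ")
  expect_equal(nrow(top_hbond_types(rec, 10)), 3)
  expect_error(top_hbond_types(rec, 0), "positive")
})
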