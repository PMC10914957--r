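make_toy_traj <- function(n_frames = 3, n_atoms = 10, seed = 2) {
  set.seed(seed)
  rec <- atom_records(seq_len(n_atoms),
                      rep(c("N", "CA", "C", "O", "CB"), 2),
                      rep(1:2, each = 5), rep(c("ALA", "LEU"), each = 5))
  sys <- build_system(rec)
  frames <- lapply(seq_len(n_frames), function(i)
    new_frame(matrix(runif(n_atoms * 3, 0, 5), n_atoms, 3), c(6, 6, 9),
              time = i - 1))
  new_trajectory(sys, frames)
}

test_that("multi-model PDB round-trips structure and coordinates", {
  traj <- make_toy_traj()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_multimodel(traj, f)
  rt <- read_pdb_multimodel(f)
  expect_length(rt$frames, 3)
  expect_equal(nrow(rt$topology$atoms), 10)
  # format precision: 1e-3 Angstrom = 1e-4 nm
  for (i in 1:3) {
    expect_lt(max(abs(rt$frames[[i]]$coords - traj$frames[[i]]$coords)),
              1e-4 + 1e-12)
  }
  # CRYST1 60 x 60 x 90 A -> 6 x 6 x 9 nm
  expect_equal(rt$frames[[1]]$box, c(6, 6, 9))
  # read-write-read is a fixed point
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_multimodel(rt, f2)
  rt2 <- read_pdb_multimodel(f2)
  expect_identical(rt2$frames[[2]]$coords, rt$frames[[2]]$coords)
})

test_that("PDB reader rejects broken files with informative errors", {
  traj <- make_toy_traj()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_multimodel(traj, f)
  lines <- readLines(f)
  # drop one atom from model 2
  atom_lines <- grep("^ATOM", lines)
  writeLines(lines[-atom_lines[15]], f)
  expect_error(read_pdb_multimodel(f), "model 2")
  # no CRYST1
  writeLines(lines[-1], f)
  expect_error(read_pdb_multimodel(f), "CRYST1")
  # triclinic box
  lines[1] <- sub("90.00  90.00  90.00", "90.00  90.00  60.00", lines[1])
  writeLines(lines, f)
  expect_error(read_pdb_multimodel(f), "orthorhombic")
})

test_that("GRO files round-trip at format precision", {
  traj <- make_toy_traj(n_frames = 1)
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro(traj$topology, traj$frames[[1]], f)
  g <- read_gro(f)
  expect_equal(nrow(g$system$atoms), 10)
  expect_lt(max(abs(g$frame$coords - traj$frames[[1]]$coords)), 5e-4)
  expect_equal(g$frame$box, c(6, 6, 9))
  # bit-identical second write
  f2 <- withr::local_tempfile(fileext = ".gro")
  write_gro(g$system, g$frame, f2)
  g2 <- read_gro(f2)
  expect_identical(g2$frame$coords, g$frame$coords)
  # truncated file
  writeLines(readLines(f)[1:4], f)
  expect_error(read_gro(f), "truncated")
})

test_that("exchange log parsing, replay, and validation", {
  f <- withr::local_tempfile(fileext = ".log")
  writeLines(c("# comment", "2 0 1 1", "4 1 2 0", "6 1 2 1"), f)
  log <- read_exchange_log(f)
  expect_equal(log$n_replicas, 3)
  expect_equal(nrow(log$attempts), 3)
  # replica 0 takes rung 1 after the first accepted swap, then rung 2
  expect_equal(log$replica_rung_series[1, ], c(1L, 1L, 2L))
  # replay conserves the rung multiset at every time
  for (k in seq_len(ncol(log$replica_rung_series))) {
    expect_setequal(log$replica_rung_series[, k], 0:2)
  }
  writeLines(c("2 0 1 1", "100 0 2 1"), f)
  expect_error(read_exchange_log(f), "line 2")
  writeLines(character(0), f)
  empty <- read_exchange_log(f)
  expect_equal(nrow(empty$attempts), 0)
  # round trip through write_exchange_log
  lg <- generate_exchange_log(make_ladder(300, 400, 4), 50, 0.5, seed = 3)
  writeLines(character(0), f)
  write_exchange_log(lg, f)
  lg2 <- read_exchange_log(f)
  expect_identical(lg2$attempts$accepted, lg$attempts$accepted)
  expect_identical(lg2$replica_rung_series, lg$replica_rung_series)
})

test_that("write_table is deterministic and handles empty input", {
  df <- data.frame(residue = 1:3, fraction = c(1 / 3, 2 / 3, 0.123456789))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, f1)
  write_table(df, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(readLines(f1)[1], "residue\tfraction")
  write_table(df[0, ], f1)
  expect_identical(readLines(f1), "residue\tfraction")
  write_table(df, f1, format = "json")
  back <- jsonlite::fromJSON(f1)
  expect_equal(back$residue, 1:3)
})
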