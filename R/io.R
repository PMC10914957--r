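# Structure / trajectory / table / exchange-log I/O.
#
# The native trajectory format is multi-model PDB: plain text, universally
# writable, and sufficient for desk-scale synthetic ensembles. Coordinates
# are Angstrom on disk and nm in memory.

.pdb_atom_line <- function(serial, name, resname, resid, x, y, z) {
  # PDB fixed columns; coordinates in Angstrom
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("ATOM  %5d %s %-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000, nm, substr(resname, 1, 4), "A", resid %% 10000,
          x, y, z)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_multimodel <- function(traj, path) {
  at <- traj$topology$atoms
  box <- traj$frames[[1]]$box * 10
  lines <- character(0)
  header <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1], box[2], box[3], 90, 90, 90)
  con <- file(path, "wb")  # "wb" keeps line endings platform-independent
  on.exit(close(con))
  writeLines(header, con)
  for (m in seq_along(traj$frames)) {
    xyz <- traj$frames[[m]]$coords * 10
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(.pdb_atom_line(at$serial, at$name, at$residue_name,
                              at$residue_index, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL records delimit frames; a CRYST1 record is required (the
#' analysis is PBC-aware throughout) and must describe an orthorhombic box.
#' Every model must repeat the atom order of model 1. Frame times are
#' assigned as `(i - 1) * frame_spacing`.
#'
#' @param path PDB file.
#' @param map Region map for the peptide.
#' @param frame_spacing Time between models, ns.
#' @return A `trajectory`.
#' @export
read_pdb_multimodel <- function(path, map = default_region_map(),
                                frame_spacing = 1) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cry)) stop("PDB file has no CRYST1 record; box is required")
  box_a <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                        substr(cry[1], 25, 33)))
  angles <- as.numeric(c(substr(cry[1], 34, 40), substr(cry[1], 41, 47),
                         substr(cry[1], 48, 54)))
  if (any(abs(angles - 90) > 1e-3)) {
    stop("triclinic box rejected: only orthorhombic boxes are supported")
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    model_id <- rep(1L, sum(is_atom))
  } else {
    model_of_line <- findInterval(seq_along(lines), model_starts)
    model_id <- model_of_line[is_atom]
    if (any(model_id == 0L)) stop("ATOM records before the first MODEL")
  }
  al <- lines[is_atom]
  serial <- as.integer(substr(al, 7, 11))
  name <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 21))
  resid <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  n_models <- max(model_id)
  first <- model_id == 1L
  n_atoms <- sum(first)
  recs <- atom_records(serial[first], name[first], resid[first],
                       resname[first])
  sys <- build_system(recs, map)
  frames <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    sel <- model_id == m
    if (sum(sel) != n_atoms) {
      stop("model ", m, " has ", sum(sel), " atoms; model 1 has ", n_atoms)
    }
    if (!identical(name[sel], name[first]) ||
        !identical(resid[sel], resid[first])) {
      stop("model ", m, " atom order differs from model 1")
    }
    frames[[m]] <- new_frame(cbind(x[sel], y[sel], z[sel]) / 10, box_a / 10,
                             time = (m - 1) * frame_spacing)
  }
  new_trajectory(sys, frames, label = basename(path))
}

#' Read a GRO structure file
#'
#' @param path GRO file (fixed-column single-frame format, nm units).
#' @param map Region map.
#' @return List with elements `system` and `frame`.
#' @export
read_gro <- function(path, map = default_region_map()) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom-count line")
  if (length(lines) < 3 + n) stop("truncated GRO file: expected ", n, " atoms")
  al <- lines[3:(2 + n)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                              "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3])) stop("malformed GRO box line")
  recs <- atom_records(seq_len(n), name, resid, resname)
  sys <- build_system(recs, map)
  list(system = sys, frame = new_frame(cbind(x, y, z), box[1:3], time = 0))
}

#' Write a GRO structure file
#'
#' @param system A `structured_system`.
#' @param frame A `frame`.
#' @param path Output file.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(system, frame, path, title = "membind") {
  at <- system$atoms
  xyz <- frame$coords
  lines <- c(
    title,
    sprintf("%5d", nrow(at)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            at$residue_index %% 100000, substr(at$residue_name, 1, 5),
            substr(at$name, 1, 5), at$serial %% 100000,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a replica-exchange attempt log
#'
#' The log dialect is defined by this package (see README): whitespace
#' delimited lines `time_ps i j accepted` where `i`, `j` are adjacent
#' temperature-rung indices (0-based) and `accepted` is 0/1. Lines starting
#' with `#` are comments. The per-replica temperature-rung series is
#' reconstructed by replaying accepted swaps from the identity permutation
#' (replica r starts on rung r).
#'
#' @param path Log file.
#' @return An `exchange_log`: list with `n_replicas`, `attempts` (data frame
#'   `time`, `i`, `j`, `accepted`) and `replica_rung_series` (matrix, one row
#'   per replica, one column per attempt, rung occupied *after* the attempt).
#' @export
read_exchange_log <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(structure(list(n_replicas = 0L,
                          attempts = data.frame(time = numeric(0),
                                                i = integer(0), j = integer(0),
                                                accepted = logical(0)),
                          replica_rung_series = NULL),
                     class = "exchange_log"))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad_len <- vapply(parts, length, integer(1)) != 4L
  if (any(bad_len)) stop("malformed exchange-log line ", ln[which(bad_len)[1]])
  m <- matrix(as.numeric(unlist(parts)), ncol = 4, byrow = TRUE)
  att <- data.frame(time = m[, 1], i = as.integer(m[, 2]),
                    j = as.integer(m[, 3]), accepted = m[, 4] != 0)
  non_adj <- att$j != att$i + 1L
  if (any(non_adj)) {
    stop("non-adjacent replica pair at line ", ln[which(non_adj)[1]],
         ": (", att$i[which(non_adj)[1]], ", ", att$j[which(non_adj)[1]], ")")
  }
  new_exchange_log(att, max(att$j) + 1L)
}

#' Construct an exchange log from an attempt table
#'
#' Replays accepted swaps from the identity permutation to reconstruct the
#' per-replica temperature-rung series.
#'
#' @param attempts Data frame `time`, `i`, `j`, `accepted`.
#' @param n_replicas Number of replicas.
#' @return An `exchange_log`.
#' @export
new_exchange_log <- function(attempts, n_replicas) {
  n_rep <- as.integer(n_replicas)
  # replay: rung_of[r] = rung currently held by replica r
  rung_of <- seq_len(n_rep) - 1L
  series <- matrix(0L, nrow = n_rep, ncol = nrow(attempts))
  for (k in seq_len(nrow(attempts))) {
    if (attempts$accepted[k]) {
      ra <- which(rung_of == attempts$i[k])
      rb <- which(rung_of == attempts$j[k])
      rung_of[c(ra, rb)] <- rung_of[c(rb, ra)]
    }
    series[, k] <- rung_of
  }
  structure(list(n_replicas = n_rep, attempts = attempts,
                 replica_rung_series = series),
            class = "exchange_log")
}

#' Write a replica-exchange attempt log
#'
#' @param log An `exchange_log` (or a data frame of attempts plus
#'   `n_replicas`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_exchange_log <- function(log, path) {
  att <- log$attempts
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# time_ps i j accepted", con)
  writeLines(sprintf("%.6g %d %d %d", att$time, att$i, att$j,
                     as.integer(att$accepted)), con)
  invisible(path)
}

.format_cell <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- formatC(x, format = "g", digits = 6)
    out[is.na(x)] <- "NA"
    out
  } else {
    as.character(x)
  }
}

#' Write a result table deterministically
#'
#' Column order follows the input; doubles are printed with 6 significant
#' digits so repeated runs produce byte-identical files.
#'
#' @param records Data frame (possibly zero rows).
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "json") {
    out <- records
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
    }
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         digits = NA, auto_unbox = TRUE)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(records), collapse = "\t"), con)
  if (nrow(records)) {
    cols <- lapply(records, .format_cell)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write a dense matrix (e.g. a 40 x 40 contact map) as TSV
#'
#' @param mat Numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(apply(mat, 1, function(r)
    paste(formatC(r, format = "g", digits = 6), collapse = "\t")), con)
  invisible(path)
}
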