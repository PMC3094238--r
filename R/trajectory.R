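#' Read a coordinate trajectory
#'
#' Reads a multi-model PDB or a (possibly multi-frame) GRO file into a list
#' of trajectory frames. PDB coordinates are in Angstrom and converted to
#' nm; GRO coordinates are read as nm. Frame times are taken from
#' `REMARK ... TIME = <t> PS` records (PDB) or a `t= <t>` tag in the title
#' line (GRO); frames without a time stamp get their 0-based frame index in
#' ps.
#'
#' @param path Path to a `.pdb` or `.gro` file; the dialect is chosen by
#'   extension, falling back to content sniffing.
#' @param n_atoms Expected number of atoms per frame; a frame with a
#'   different count is an error.
#' @return List of frames, each a list with `time` (ps) and `coords`
#'   (`n_atoms` x 3 matrix, nm).
#' @export
read_trajectory <- function(path, n_atoms) {
  if (!file.exists(path)) stop_validation("trajectory file not found: ", path)
  n_atoms <- as.integer(n_atoms)
  lines <- readLines(path, warn = FALSE)
  is_gro <- grepl("\\.gro$", path, ignore.case = TRUE) ||
    (!any(grepl("^(ATOM  |HETATM|MODEL )", lines)) &&
       length(lines) >= 2 &&
       !is.na(suppressWarnings(as.integer(trimws(lines[2])))))
  frames <- if (is_gro) .read_gro(lines, n_atoms) else .read_pdb(lines, n_atoms)
  if (length(frames) == 0) stop("no frames found in ", path)
  # fill missing times with the frame index in ps
  for (k in seq_along(frames)) {
    if (is.na(frames[[k]]$time)) frames[[k]]$time <- k - 1
  }
  frames
}

.parse_num <- function(s, what) {
  v <- suppressWarnings(as.numeric(s))
  if (anyNA(v)) stop("unparseable ", what, " record")
  v
}

.read_pdb <- function(lines, natoms) {
  frames <- list()
  cur <- NULL
  cur_time <- NA_real_
  flush <- function() {
    if (is.null(cur) || length(cur) == 0) return()
    if (length(cur) != natoms)
      stop(sprintf("frame %d has %d atoms, expected %d",
                   length(frames) + 1L, length(cur), natoms))
    frames[[length(frames) + 1L]] <<-
      list(time = cur_time, coords = do.call(rbind, cur) / 10)  # A -> nm
    cur <<- NULL
    cur_time <<- NA_real_
  }
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (rec == "MODEL ") {
      flush()
      cur <- list()
    } else if (rec == "ENDMDL") {
      if (is.null(cur)) cur <- list()
      flush()
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      if (is.null(cur)) cur <- list()
      x <- .parse_num(substr(ln, 31, 38), "PDB coordinate")
      y <- .parse_num(substr(ln, 39, 46), "PDB coordinate")
      z <- .parse_num(substr(ln, 47, 54), "PDB coordinate")
      cur[[length(cur) + 1L]] <- c(x, y, z)
    } else if (rec == "REMARK") {
      m <- regmatches(ln, regexec("TIME\\s*=?\\s*([-0-9.eE+]+)", ln))[[1]]
      if (length(m) == 2) cur_time <- as.numeric(m[2])
    }
  }
  flush()
  frames
}

.read_gro <- function(lines, natoms) {
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "" && pos == length(lines)) break
    title <- lines[pos]
    if (pos + 1L > length(lines)) stop("truncated GRO frame header")
    n <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n)) stop("unparseable GRO atom count at line ", pos + 1L)
    if (n != natoms)
      stop(sprintf("frame %d has %d atoms, expected %d",
                   length(frames) + 1L, n, natoms))
    if (pos + 1L + n + 1L > length(lines)) stop("truncated GRO frame")
    body <- lines[(pos + 2L):(pos + 1L + n)]
    xyz <- t(vapply(body, function(ln) {
      c(.parse_num(substr(ln, 21, 28), "GRO coordinate"),
        .parse_num(substr(ln, 29, 36), "GRO coordinate"),
        .parse_num(substr(ln, 37, 44), "GRO coordinate"))
    }, numeric(3), USE.NAMES = FALSE))
    tm <- NA_real_
    m <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    frames[[length(frames) + 1L]] <- list(time = tm, coords = xyz)
    pos <- pos + 2L + n + 1L  # title, count, atoms, box line
  }
  frames
}

#' Write a trajectory as multi-model PDB
#'
#' Writes frames as `MODEL`/`ENDMDL` blocks with coordinates converted from
#' nm to Angstrom. Atom and residue names/numbers come from the topology
#' (0-based internal indices become 1-based in the file). Each model carries
#' a `REMARK   6 TIME = <t> PS` record so that times round-trip through
#' [read_trajectory()].
#'
#' @param frames List of frames as returned by [read_trajectory()] or
#'   [sample_frames()].
#' @param top Matching `fda_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(frames, top, path) {
  a <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (nrow(fr$coords) != nrow(a))
      stop_validation("frame atom count does not match topology")
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("REMARK   6 TIME = %.6f PS", fr$time), con)
    ang <- fr$coords * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s%3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      a$index + 1L, substr(a$name, 1, 4), substr(a$resname, 1, 3),
      a$resid + 1L, ang[, 1], ang[, 2], ang[, 3], 1.00, 0.00), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as multi-frame GRO
#'
#' Fixed-column GRO with coordinates in nm (three decimals) and the frame
#' time in the title line (`t= <t>`); velocities are not written. A dummy
#' zero box line terminates each frame.
#'
#' @inheritParams write_trajectory_pdb
#' @return `path`, invisibly.
#' @export
write_trajectory_gro <- function(frames, top, path) {
  a <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    if (nrow(fr$coords) != nrow(a))
      stop_validation("frame atom count does not match topology")
    writeLines(sprintf("pairforce t= %.6f", fr$time), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid + 1L, substr(a$resname, 1, 5),
                       substr(a$name, 1, 5), a$index + 1L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines("   0.00000   0.00000   0.00000", con)
  }
  invisible(path)
}

#' Write per-atom values into the b-factor column of a PDB file
#'
#' Copies the reference PDB verbatim, replacing only the b-factor columns
#' (61-66, `%6.2f`) of `ATOM`/`HETATM` records with the supplied per-atom
#' values. This is the standard route for colour-coding a per-atom
#' projection of force changes onto a structure. With `scaling = "minmax"`
#' the values are mapped affinely from `[min, max]` to `[0, 99.99]` (all
#' zero if the values are constant); with `scaling = "none"` a value that
#' does not fit the fixed-width field is an error.
#'
#' @param reference_pdb Path to the reference PDB.
#' @param values Non-negative per-atom scalars, one per atom record of each
#'   model.
#' @param out Output path.
#' @param scaling `"none"` or `"minmax"`.
#' @return `out`, invisibly.
#' @export
write_pdb_bfactors <- function(reference_pdb, values, out,
                               scaling = c("none", "minmax")) {
  scaling <- match.arg(scaling)
  if (!file.exists(reference_pdb))
    stop_validation("reference PDB not found: ", reference_pdb)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop_validation("b-factor values must be finite and non-negative")
  lines <- readLines(reference_pdb, warn = FALSE)
  is_atom <- substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")
  n_rec <- sum(is_atom)
  nv <- length(values)
  if (n_rec == 0) stop_validation("reference PDB has no atom records")
  if (n_rec %% nv != 0)
    stop_validation(sprintf(
      "value count (%d) does not match PDB atom count (%d)", nv, n_rec))
  v <- if (scaling == "minmax") {
    rng <- range(values)
    if (rng[2] > rng[1]) (values - rng[1]) / (rng[2] - rng[1]) * 99.99
    else rep(0, nv)
  } else values
  if (any(v > 999.99))
    stop_validation("value not representable in %6.2f; use scaling = \"minmax\"")
  field <- sprintf("%6.2f", v)
  field <- rep_len(field, n_rec)  # same values in every model
  idx <- which(is_atom)
  for (q in seq_along(idx)) {
    ln <- lines[idx[q]]
    if (nchar(ln) < 66) ln <- formatC(ln, width = -66)
    substr(ln, 61, 66) <- field[q]
    lines[idx[q]] <- ln
  }
  writeLines(lines, out)
  invisible(out)
}
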