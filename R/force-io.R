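# Binary force-trajectory format, little-endian throughout:
#   header: magic "FDA1", u32 format version (=1), u32 n_atoms,
#           u8 syntax mode (0 = atom, 1 = residue)
#   block:  f64 time (ps), u32 n_entries, then n_entries x
#           (u64 packed pair index i*N + j with i < j,
#            f64 signed scalar force, u8 interaction-type code)
# Entries inside a block are sorted by (index, type), which makes equal
# trajectories byte-identical on disk.

.u32_raw <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0 | x >= 2^32)) stop("u32 overflow")
  as.raw(c(x %% 256, (x %/% 256) %% 256,
           (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

.u64_raw <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0 | x >= 2^53)) stop("pair index overflow")
  c(.u32_raw(x %% 2^32), .u32_raw(x %/% 2^32))
}

.raw_uint <- function(r) sum(as.numeric(r) * 256^(seq_along(r) - 1))

.read_n <- function(con, n, what, block = NULL) {
  r <- readBin(con, "raw", n = n)
  if (length(r) < n) {
    loc <- if (is.null(block)) "" else sprintf(" in block %d", block)
    stop("truncated force trajectory: incomplete ", what, loc)
  }
  r
}

#' Write a force trajectory to the binary format
#'
#' Serializes a [force_trajectory()] to the sparse little-endian block
#' format (see the package vignette for the byte layout): a fixed header
#' followed by one data block per writing step, each block holding the
#' packed atom-pair index, the signed scalar force and the interaction
#' type of every nonzero entry. The writer emits entries in canonical
#' (pair, type) order, so `write(read(f))` reproduces `f` byte for byte.
#'
#' @param traj A `force_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_force_trajectory()], [dump_ascii()]
#' @export
write_force_trajectory <- function(traj, path) {
  if (!inherits(traj, "force_trajectory"))
    stop_validation("traj must be a force_trajectory")
  N <- traj$n_atoms
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("FDA1"), con)
  writeBin(.u32_raw(1), con)
  writeBin(.u32_raw(N), con)
  writeBin(as.raw(if (traj$syntax == "residue") 1L else 0L), con)
  for (b in traj$blocks) {
    writeBin(writeBin(b$time, raw(), size = 8, endian = "little"), con)
    ne <- length(b$i)
    writeBin(.u32_raw(ne), con)
    if (ne > 0) {
      idx <- as.numeric(b$i) * N + as.numeric(b$j)
      ord <- order(idx, b$type)
      payload <- raw(ne * 17L)
      off <- 0L
      for (q in ord) {
        payload[off + 1:8] <- .u64_raw(idx[q])
        payload[off + 9:16] <- writeBin(b$force[q], raw(), size = 8,
                                        endian = "little")
        payload[off + 17L] <- as.raw(b$type[q])
        off <- off + 17L
      }
      writeBin(payload, con)
    }
  }
  invisible(path)
}

#' Read a binary force trajectory
#'
#' Exact inverse of [write_force_trajectory()]. A wrong magic number, an
#' unknown interaction-type code or a truncated block is an error (the
#' block index is named for truncation).
#'
#' @param path Path to a binary force-trajectory file.
#' @return A `force_trajectory`.
#' @export
read_force_trajectory <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4 || rawToChar(magic) != "FDA1")
    stop("bad magic: not a force-trajectory file")
  version <- .raw_uint(.read_n(con, 4, "version"))
  if (version != 1) stop("unsupported format version ", version)
  N <- as.integer(.raw_uint(.read_n(con, 4, "n_atoms")))
  if (N <= 0) stop("invalid n_atoms in header")
  mode_byte <- .read_n(con, 1, "syntax mode")
  syntax <- if (as.integer(mode_byte) == 1L) "residue" else "atom"
  blocks <- list()
  kb <- 0L
  repeat {
    tr <- readBin(con, "raw", n = 8)
    if (length(tr) == 0) break
    kb <- kb + 1L
    if (length(tr) < 8)
      stop("truncated force trajectory: incomplete time in block ", kb)
    time <- readBin(tr, "double", size = 8, endian = "little")
    ne <- .raw_uint(.read_n(con, 4, "entry count", kb))
    if (ne > 0) {
      payload <- .read_n(con, ne * 17, "entries", kb)
      m <- matrix(payload, nrow = 17)
      idx <- vapply(seq_len(ne), function(q) .raw_uint(m[1:8, q]), 0)
      force <- readBin(as.raw(m[9:16, ]), "double", n = ne, size = 8,
                       endian = "little")
      type <- as.integer(m[17, ])
      if (!all(type %in% interaction_types()))
        stop("unknown interaction-type code in block ", kb)
      i <- as.integer(idx %/% N)
      j <- as.integer(idx %% N)
      blocks[[kb]] <- pairwise_forces(time, i, j, type, force)
    } else {
      blocks[[kb]] <- pairwise_forces(time)
    }
  }
  force_trajectory(blocks, N, syntax)
}

#' Dump a binary force trajectory to ASCII
#'
#' Writes one line per stored entry — `time i j force type-name`,
#' whitespace-separated, floats at full round-trip precision (17
#' significant digits) — preceded by comment lines carrying the header.
#' The output can be re-read with [read_force_ascii()] without loss.
#'
#' @param path_in Binary force-trajectory file.
#' @param path_out ASCII output path.
#' @return `path_out`, invisibly.
#' @export
dump_ascii <- function(path_in, path_out) {
  traj <- read_force_trajectory(path_in)
  con <- file(path_out, "w")
  on.exit(close(con))
  writeLines(c("# pairforce ASCII force trajectory",
               sprintf("# n_atoms = %d", traj$n_atoms),
               sprintf("# syntax = %s", traj$syntax),
               "# columns: time_ps i j force_kJ_mol_nm type"), con)
  for (b in traj$blocks) {
    if (length(b$i) == 0) {
      writeLines(sprintf("# empty block t = %.17g", b$time), con)
    } else {
      writeLines(sprintf("%.17g %d %d %.17g %s", b$time, b$i, b$j,
                         b$force, .type_name(b$type)), con)
    }
  }
  invisible(path_out)
}

#' Read an ASCII force-trajectory dump
#'
#' Parses the format written by [dump_ascii()] back into a
#' `force_trajectory`. Consecutive lines sharing a time stamp form one
#' block; `# empty block` markers restore blocks without entries.
#'
#' @param path ASCII dump path.
#' @return A `force_trajectory`.
#' @export
read_force_ascii <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  gethdr <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*=", key), lines, value = TRUE)
    if (length(m) == 0) stop("ASCII dump missing header field ", key)
    trimws(sub(".*=", "", m[1]))
  }
  N <- as.integer(gethdr("n_atoms"))
  syntax <- gethdr("syntax")
  times <- numeric()
  rows <- list()
  for (ln in lines) {
    if (grepl("^#\\s*empty block", ln)) {
      t <- as.numeric(sub(".*t\\s*=\\s*", "", ln))
      times <- c(times, t)
      rows[length(times)] <- list(NULL)
      next
    }
    if (grepl("^\\s*(#|$)", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 5) stop("unparseable ASCII dump line: ", ln)
    t <- as.numeric(f[1])
    if (length(times) == 0 || t != times[length(times)]) {
      times <- c(times, t)
      rows[length(times)] <- list(NULL)
    }
    k <- length(times)
    rows[[k]] <- rbind(rows[[k]],
                       data.frame(i = as.integer(f[2]), j = as.integer(f[3]),
                                  force = as.numeric(f[4]),
                                  type = .type_code(f[5])))
  }
  blocks <- lapply(seq_along(times), function(k) {
    r <- rows[[k]]
    if (is.null(r)) pairwise_forces(times[k])
    else pairwise_forces(times[k], r$i, r$j, r$type, r$force)
  })
  force_trajectory(blocks, N, syntax)
}
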