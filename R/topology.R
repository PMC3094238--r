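#' Read a force-field topology
#'
#' Parses the sectioned plain-text topology format holding the force-field
#' side of a force distribution analysis: per-atom charges and
#' Lennard-Jones parameters, bonded terms (harmonic bonds and angles,
#' periodic proper dihedrals) and the non-bonded exclusion list. Improper
#' dihedrals are not part of the format: they cannot be cast into a
#' pair-wise representation and are excluded from the analysis.
#'
#' The format has sections `[atoms]`, `[bonds]`, `[angles]`, `[dihedrals]`
#' and `[exclusions]`, whitespace-separated fields, `#` comments, and
#' 0-based atom indices:
#'
#' ```
#' [atoms]
#' # index name residue_index residue_name charge(e) sigma(nm) epsilon(kJ/mol)
#' 0 C1 0 RES  0.2 0.15 0.0
#' [bonds]
#' # i j b0(nm) kb(kJ/mol/nm^2)
#' 0 1 0.15 10000
#' ```
#'
#' If the file has no `[exclusions]` section, first- (1-2) and second-
#' neighbour (1-3) pairs are derived from the bond list and recorded as
#' exclusions; the returned object carries `attr(, "auto_exclusions") =
#' TRUE` in that case. An explicit exclusions section must contain every
#' 1-2 and 1-3 pair — a file that omits some is rejected rather than
#' silently completed.
#'
#' @param path Path to a topology file.
#' @return An object of class `fda_topology`: a list with data frames
#'   `atoms` (`index`, `name`, `resid`, `resname`, `charge`, `sigma`,
#'   `epsilon`), `bonds` (`i`, `j`, `b0`, `kb`), `angles` (`i`, `j`, `k`,
#'   `theta0`, `ktheta`), `dihedrals` (`i`, `j`, `k`, `l`, `kphi`, `mult`,
#'   `phase`) and `exclusions` (`i`, `j` with `i < j`).
#' @seealso [write_topology()]
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop_validation("topology file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  section <- NA_character_
  rows <- list(atoms = list(), bonds = list(), angles = list(),
               dihedrals = list(), exclusions = list())
  seen <- character()
  fields_per <- c(atoms = 7L, bonds = 4L, angles = 5L,
                  dihedrals = 7L, exclusions = 2L)
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (txt == "") next
    m <- regmatches(txt, regexec("^\\[\\s*([a-z]+)\\s*\\]$", txt))[[1]]
    if (length(m) == 2) {
      section <- m[2]
      if (!section %in% names(rows))
        stop(sprintf("line %d: unknown topology section [%s]", ln, section))
      seen <- union(seen, section)
      next
    }
    if (is.na(section))
      stop(sprintf("line %d: data before any section header", ln))
    f <- strsplit(txt, "\\s+")[[1]]
    if (length(f) != fields_per[[section]])
      stop(sprintf("line %d: expected %d fields in [%s], got %d",
                   ln, fields_per[[section]], section, length(f)))
    rows[[section]][[length(rows[[section]]) + 1L]] <- f
  }
  if (!"atoms" %in% seen) stop("topology has no [atoms] section")

  as_num <- function(x, what, ln = NULL) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("unparseable numeric field in ", what)
    v
  }
  mat <- function(sec) do.call(rbind, rows[[sec]])

  a <- mat("atoms")
  atoms <- data.frame(
    index = as.integer(as_num(a[, 1], "[atoms]")),
    name = a[, 2],
    resid = as.integer(as_num(a[, 3], "[atoms]")),
    resname = a[, 4],
    charge = as_num(a[, 5], "[atoms]"),
    sigma = as_num(a[, 6], "[atoms]"),
    epsilon = as_num(a[, 7], "[atoms]"),
    stringsAsFactors = FALSE)

  bonds <- if (length(rows$bonds)) {
    b <- mat("bonds")
    data.frame(i = as.integer(as_num(b[, 1], "[bonds]")),
               j = as.integer(as_num(b[, 2], "[bonds]")),
               b0 = as_num(b[, 3], "[bonds]"),
               kb = as_num(b[, 4], "[bonds]"))
  } else data.frame(i = integer(), j = integer(),
                    b0 = numeric(), kb = numeric())

  angles <- if (length(rows$angles)) {
    b <- mat("angles")
    data.frame(i = as.integer(as_num(b[, 1], "[angles]")),
               j = as.integer(as_num(b[, 2], "[angles]")),
               k = as.integer(as_num(b[, 3], "[angles]")),
               theta0 = as_num(b[, 4], "[angles]"),
               ktheta = as_num(b[, 5], "[angles]"))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    theta0 = numeric(), ktheta = numeric())

  dihedrals <- if (length(rows$dihedrals)) {
    b <- mat("dihedrals")
    data.frame(i = as.integer(as_num(b[, 1], "[dihedrals]")),
               j = as.integer(as_num(b[, 2], "[dihedrals]")),
               k = as.integer(as_num(b[, 3], "[dihedrals]")),
               l = as.integer(as_num(b[, 4], "[dihedrals]")),
               kphi = as_num(b[, 5], "[dihedrals]"),
               mult = as.integer(as_num(b[, 6], "[dihedrals]")),
               phase = as_num(b[, 7], "[dihedrals]"))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), kphi = numeric(), mult = integer(),
                    phase = numeric())

  auto <- !"exclusions" %in% seen
  exclusions <- if (!auto && length(rows$exclusions)) {
    b <- mat("exclusions")
    ei <- as.integer(as_num(b[, 1], "[exclusions]"))
    ej <- as.integer(as_num(b[, 2], "[exclusions]"))
    data.frame(i = pmin(ei, ej), j = pmax(ei, ej))
  } else data.frame(i = integer(), j = integer())
  if (auto) exclusions <- derive_exclusions(bonds)

  top <- structure(list(atoms = atoms, bonds = bonds, angles = angles,
                        dihedrals = dihedrals,
                        exclusions = unique(exclusions)),
                   class = "fda_topology",
                   auto_exclusions = auto)
  validate_topology(top)
  top
}

#' Derive bonded exclusions from a bond list
#'
#' Returns all 1-2 (directly bonded) and 1-3 (bonded to a common atom)
#' pairs, the pairs conventionally excluded from non-bonded evaluation.
#'
#' @param bonds Data frame with columns `i`, `j`.
#' @return Data frame with columns `i`, `j` (`i < j`), one row per pair.
#' @export
derive_exclusions <- function(bonds) {
  if (nrow(bonds) == 0) return(data.frame(i = integer(), j = integer()))
  p12 <- data.frame(i = pmin(bonds$i, bonds$j), j = pmax(bonds$i, bonds$j))
  # 1-3: two bonds sharing an atom connect their outer atoms
  adj <- split(c(bonds$j, bonds$i), c(bonds$i, bonds$j))
  p13 <- list()
  for (centre in names(adj)) {
    nb <- sort(unique(adj[[centre]]))
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      p13[[centre]] <- data.frame(i = cmb[1, ], j = cmb[2, ])
    }
  }
  out <- unique(rbind(p12, do.call(rbind, p13)))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Validate a topology
#'
#' Checks the structural invariants of a topology: contiguous 0-based atom
#' indices, non-decreasing residue indices, all bonded-term references in
#' range with distinct atoms, positive `sigma`, non-negative `epsilon`,
#' `kb` and `ktheta`, dihedral multiplicity at least 1, and an exclusion
#' list covering every 1-2 and 1-3 pair.
#'
#' @param top An `fda_topology` object.
#' @return The topology, invisibly; signals a validation error otherwise.
#' @export
validate_topology <- function(top) {
  a <- top$atoms
  n <- nrow(a)
  if (n == 0) stop_validation("topology has no atoms")
  if (!identical(a$index, seq_len(n) - 1L))
    stop_validation("atom indices must be contiguous and 0-based")
  if (is.unsorted(a$resid))
    stop_validation("residue_index must be non-decreasing over atom_index")
  if (any(a$sigma <= 0)) stop_validation("sigma must be > 0")
  if (any(a$epsilon < 0)) stop_validation("epsilon must be >= 0")

  chk_idx <- function(idx, what) {
    if (length(idx) && (any(idx < 0) || any(idx >= n)))
      stop_validation(what, " references atom index outside 0..", n - 1)
  }
  b <- top$bonds
  chk_idx(c(b$i, b$j), "bond")
  if (any(b$i == b$j)) stop_validation("bond with i == j")
  if (any(b$kb < 0)) stop_validation("kb must be >= 0")
  g <- top$angles
  chk_idx(c(g$i, g$j, g$k), "angle")
  if (any(g$i == g$j | g$j == g$k | g$i == g$k))
    stop_validation("angle with repeated atom")
  if (any(g$ktheta < 0)) stop_validation("ktheta must be >= 0")
  d <- top$dihedrals
  chk_idx(c(d$i, d$j, d$k, d$l), "dihedral")
  dup <- apply(cbind(d$i, d$j, d$k, d$l), 1,
               function(r) anyDuplicated(r) > 0)
  if (any(dup)) stop_validation("dihedral with repeated atom")
  if (any(d$mult < 1)) stop_validation("dihedral multiplicity must be >= 1")
  e <- top$exclusions
  chk_idx(c(e$i, e$j), "exclusion")
  if (any(e$i == e$j)) stop_validation("exclusion with i == j")

  need <- derive_exclusions(top$bonds)
  if (nrow(need)) {
    have <- paste(e$i, e$j)
    miss <- !paste(need$i, need$j) %in% have
    if (any(miss))
      stop_validation("exclusion list is missing bonded (1-2/1-3) pair(s): ",
                      paste(need$i[miss], need$j[miss],
                            sep = "-", collapse = ", "))
  }
  invisible(top)
}

#' Write a topology file
#'
#' Inverse of [read_topology()]; the written file round-trips through the
#' parser.
#'
#' @param top An `fda_topology` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  fmt <- function(x) sprintf("%.17g", x)
  out <- c("[atoms]",
           "# index name resid resname charge sigma epsilon")
  a <- top$atoms
  out <- c(out, sprintf("%d %s %d %s %s %s %s", a$index, a$name, a$resid,
                        a$resname, fmt(a$charge), fmt(a$sigma),
                        fmt(a$epsilon)))
  if (nrow(top$bonds)) {
    b <- top$bonds
    out <- c(out, "[bonds]",
             sprintf("%d %d %s %s", b$i, b$j, fmt(b$b0), fmt(b$kb)))
  }
  if (nrow(top$angles)) {
    g <- top$angles
    out <- c(out, "[angles]",
             sprintf("%d %d %d %s %s", g$i, g$j, g$k, fmt(g$theta0),
                     fmt(g$ktheta)))
  }
  if (nrow(top$dihedrals)) {
    d <- top$dihedrals
    out <- c(out, "[dihedrals]",
             sprintf("%d %d %d %d %s %d %s", d$i, d$j, d$k, d$l,
                     fmt(d$kphi), d$mult, fmt(d$phase)))
  }
  e <- top$exclusions
  out <- c(out, "[exclusions]")
  if (nrow(e)) out <- c(out, sprintf("%d %d", e$i, e$j))
  writeLines(out, path)
  invisible(path)
}

#' @export
print.fda_topology <- function(x, ...) {
  cat(sprintf(paste0("<fda_topology> %d atoms, %d residues, %d bonds, ",
                     "%d angles, %d dihedrals, %d exclusions\n"),
              nrow(x$atoms), length(unique(x$atoms$resid)), nrow(x$bonds),
              nrow(x$angles), nrow(x$dihedrals), nrow(x$exclusions)))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top An `fda_topology` object.
#' @return Integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)
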