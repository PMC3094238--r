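#' Interaction type codes
#'
#' Pair-wise forces are tagged with the interaction type they stem from so
#' that the contribution of every potential can be analyzed separately.
#' Improper dihedrals and mesh-based long-range electrostatics have no code:
#' neither can be cast into a pair-wise representation and both are excluded
#' from the analysis.
#'
#' @return Named integer vector mapping type names to their binary codes:
#'   `BOND = 1`, `ANGLE = 2`, `DIHEDRAL = 3`, `COULOMB = 4`, `LJ = 5`.
#' @export
#' @examples
#' interaction_types()
interaction_types <- function() {
  c(BOND = 1L, ANGLE = 2L, DIHEDRAL = 3L, COULOMB = 4L, LJ = 5L)
}

.type_name <- function(code) {
  tt <- interaction_types()
  out <- names(tt)[match(code, tt)]
  if (anyNA(out)) stop("unknown interaction-type code: ",
                       paste(unique(code[is.na(out)]), collapse = ", "))
  out
}

.type_code <- function(name) {
  tt <- interaction_types()
  out <- unname(tt[match(toupper(name), names(tt))])
  if (anyNA(out)) stop("unknown interaction type: ",
                       paste(unique(name[is.na(out)]), collapse = ", "))
  out
}

# validation errors get their own condition class so the CLI can map them
# to a distinct exit code
stop_validation <- function(...) {
  stop(structure(class = c("pairforce_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Construct a sparse pair-wise force matrix
#'
#' One frame (or one output-averaging interval) of pair-wise forces. Entries
#' are sparse: only pairs with a nonzero force of a given interaction type
#' are stored. Forces are signed scalar norms of the pair force vector;
#' positive means repulsive (pushing the two atoms apart), negative
#' attractive. Entries are kept sorted by (i, j, type) so that equal
#' matrices have identical representations.
#'
#' @param time Time stamp in ps (start of the averaging interval).
#' @param i,j 0-based atom indices with `i < j` element-wise.
#' @param type Interaction type, as integer codes or names
#'   (see [interaction_types()]).
#' @param force Signed scalar forces in kJ mol^-1 nm^-1.
#' @return An object of class `pairwise_forces`: a list with fields `time`,
#'   `i`, `j`, `type`, `force`.
#' @export
pairwise_forces <- function(time, i = integer(), j = integer(),
                            type = integer(), force = numeric()) {
  i <- as.integer(i); j <- as.integer(j)
  if (is.character(type)) type <- .type_code(type)
  type <- as.integer(type)
  force <- as.numeric(force)
  n <- length(i)
  if (length(j) != n || length(type) != n || length(force) != n)
    stop_validation("i, j, type, force must have equal length")
  if (n > 0) {
    if (any(i >= j)) stop_validation("pair indices must satisfy i < j")
    if (any(i < 0)) stop_validation("atom indices are 0-based and non-negative")
    if (!all(is.finite(force))) stop_validation("forces must be finite")
    if (!all(type %in% interaction_types()))
      stop_validation("unknown interaction-type code")
    ord <- order(i, j, type)
    i <- i[ord]; j <- j[ord]; type <- type[ord]; force <- force[ord]
  }
  structure(list(time = as.numeric(time), i = i, j = j,
                 type = type, force = force),
            class = "pairwise_forces")
}

#' @export
print.pairwise_forces <- function(x, ...) {
  cat(sprintf("<pairwise_forces> t = %g ps, %d entries\n",
              x$time, length(x$i)))
  if (length(x$i) > 0) {
    df <- data.frame(i = x$i, j = x$j, type = .type_name(x$type),
                     force = x$force)
    print(utils::head(df, 10))
    if (nrow(df) > 10) cat("...\n")
  }
  invisible(x)
}

#' Construct a force trajectory
#'
#' A time-ordered sequence of sparse pair-wise force matrices together with
#' the header information needed to interpret them (number of atoms and
#' whether pair indices refer to atoms or residues).
#'
#' @param blocks List of [pairwise_forces()] objects, time-ordered.
#' @param n_atoms Number of atoms (or residues in residue mode) the pair
#'   indices refer to.
#' @param syntax Either `"atom"` or `"residue"`.
#' @return An object of class `force_trajectory` with fields `n_atoms`,
#'   `syntax`, `blocks`.
#' @export
force_trajectory <- function(blocks, n_atoms, syntax = c("atom", "residue")) {
  syntax <- match.arg(syntax)
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms <= 0) stop_validation("n_atoms must be > 0")
  if (!is.list(blocks)) stop_validation("blocks must be a list")
  for (b in blocks) {
    if (!inherits(b, "pairwise_forces"))
      stop_validation("every block must be a pairwise_forces object")
    if (length(b$j) > 0 && max(b$j) >= n_atoms)
      stop_validation("pair index exceeds n_atoms")
  }
  structure(list(n_atoms = n_atoms, syntax = syntax, blocks = blocks),
            class = "force_trajectory")
}

#' @export
print.force_trajectory <- function(x, ...) {
  cat(sprintf("<force_trajectory> %d atoms (%s syntax), %d blocks\n",
              x$n_atoms, x$syntax, length(x$blocks)))
  invisible(x)
}

# one scalar key per (i, j, type) entry; exact for n_atoms up to ~2.3e7
.entry_key <- function(i, j, type, n_atoms) {
  (as.numeric(i) * n_atoms + as.numeric(j)) * 8 + as.numeric(type)
}

.key_decode <- function(key, n_atoms) {
  pair <- key %/% 8
  list(i = as.integer(pair %/% n_atoms),
       j = as.integer(pair %% n_atoms),
       type = as.integer(key %% 8))
}
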