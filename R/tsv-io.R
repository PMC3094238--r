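# Plain-text exchange formats for analysis results. Every file starts
# with '#%' header comments carrying the object class and its metadata,
# followed by a tab-separated table at full float precision, so files
# round-trip exactly and downstream tools can parse them trivially.

.tsv_header <- function(class, meta) {
  c(sprintf("#%%pairforce %s", class),
    sprintf("#%%%s = %s", names(meta), vapply(meta, as.character, "")))
}

.fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

.write_table <- function(df, path, class, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(class, meta), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, .fmt_full)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write an analysis object as annotated TSV
#'
#' Serializes averaged force matrices, standard-error matrices, delta
#' maps and residue matrices to a tab-separated file with `#%` metadata
#' headers. [read_forces_tsv()] restores the object exactly.
#'
#' @param x An `avg_forces`, `stderr_forces`, `delta_forces` or
#'   `residue_forces` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forces_tsv <- function(x, path) {
  if (inherits(x, "avg_forces")) {
    .write_table(as.data.frame(x), path, "avg_forces",
                 list(n_atoms = attr(x, "n_atoms"),
                      n_blocks = attr(x, "n_blocks")))
  } else if (inherits(x, "stderr_forces")) {
    .write_table(as.data.frame(x), path, "stderr_forces",
                 list(n_atoms = attr(x, "n_atoms"),
                      n_runs = attr(x, "n_runs")))
  } else if (inherits(x, "delta_forces")) {
    .write_table(as.data.frame(x), path, "delta_forces",
                 list(n_atoms = attr(x, "n_atoms"),
                      kind = attr(x, "kind"),
                      n_dropped = attr(x, "n_dropped")))
  } else if (inherits(x, "residue_forces")) {
    .write_table(as.data.frame(x), path, "residue_forces",
                 list(n_residues = attr(x, "n_residues"),
                      mode = attr(x, "mode")))
  } else stop_validation("unsupported object for TSV export")
}

#' Read an annotated TSV analysis file
#'
#' @param path File written by [write_forces_tsv()].
#' @return The original object with class and metadata restored.
#' @export
read_forces_tsv <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#%", lines, value = TRUE)
  if (length(hdr) == 0) stop_validation("not a pairforce TSV file")
  class_ln <- grep("^#%pairforce ", hdr, value = TRUE)
  if (length(class_ln) == 0) stop_validation("not a pairforce TSV file")
  cls <- trimws(sub("^#%pairforce ", "", class_ln[1]))
  meta <- list()
  for (m in grep("^#%[a-z_]+ =", hdr, value = TRUE)) {
    key <- trimws(sub("^#%([a-z_]+) =.*", "\\1", m))
    meta[[key]] <- trimws(sub("^#%[a-z_]+ = ", "", m))
  }
  body <- lines[!grepl("^#", lines)]
  cols <- strsplit(body[1], "\t")[[1]]
  df <- if (length(body) > 1) {
    parts <- strsplit(body[-1], "\t")
    m <- do.call(rbind, parts)
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- cols
    for (cn in cols) {
      out[[cn]] <- if (cn %in% c("i", "j", "type", "u", "v"))
        as.integer(out[[cn]]) else as.numeric(out[[cn]])
    }
    out
  } else {
    out <- as.data.frame(stats::setNames(
      lapply(cols, function(cn)
        if (cn %in% c("i", "j", "type", "u", "v")) integer() else numeric()),
      cols))
    out
  }
  switch(cls,
    avg_forces = structure(df, class = c("avg_forces", "data.frame"),
                           n_atoms = as.integer(meta$n_atoms),
                           n_blocks = as.integer(meta$n_blocks)),
    stderr_forces = structure(df, class = c("stderr_forces", "data.frame"),
                              n_atoms = as.integer(meta$n_atoms),
                              n_runs = as.integer(meta$n_runs)),
    delta_forces = structure(df, class = c("delta_forces", "data.frame"),
                             n_atoms = as.integer(meta$n_atoms),
                             kind = meta$kind,
                             n_dropped = as.integer(meta$n_dropped)),
    residue_forces = structure(df, class = c("residue_forces",
                                             "data.frame"),
                               n_residues = as.integer(meta$n_residues),
                               mode = meta$mode),
    stop_validation("unknown pairforce TSV class: ", cls))
}

#' Write a force network as TSV
#'
#' @param edges Edge list from [extract_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("node_i\tnode_j\tweight", con)
  if (nrow(edges))
    writeLines(sprintf("%d\t%d\t%.17g", edges$node_i, edges$node_j,
                       edges$weight), con)
  invisible(path)
}

#' Write a force network as a DOT graph
#'
#' Undirected graph; edge labels carry the signed weight, suitable for
#' rendering strain-propagation pathways with graphviz.
#'
#' @param edges Edge list from [extract_network()].
#' @param path Output path.
#' @param name Graph name.
#' @return `path`, invisibly.
#' @export
write_network_dot <- function(edges, path, name = "force_network") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("graph %s {", name), con)
  if (nrow(edges))
    writeLines(sprintf("  n%d -- n%d [label=\"%.6g\"];", edges$node_i,
                       edges$node_j, edges$weight), con)
  writeLines("}", con)
  invisible(path)
}
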