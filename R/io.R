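# Plain-text serialization: dense matrices with a one-line header, edge
# lists and subject tables as TSV, run summaries as JSON.

#' Write / read a connectome as a dense delimited matrix file
#'
#' The first line is a header `# ptenet connectome weight_kind=<kind> n=<n>`;
#' the remaining lines are the tab-separated weight matrix at full double
#' precision, so write followed by read is the identity.
#'
#' @param cn A `connectome`.
#' @param path Output file.
#' @return `write_connectome` returns `path` invisibly; `read_connectome`
#'   returns a `connectome`.
#' @export
write_connectome <- function(cn, path) {
  stopifnot(inherits(cn, "connectome"))
  header <- sprintf("# ptenet connectome weight_kind=%s n=%d",
                    cn$weight_kind, nrow(cn$weights))
  lines <- apply(cn$weights, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("^# ptenet connectome weight_kind=(\\w+) n=(\\d+)$",
                          header))[[1]]
  if (length(m) != 3) {
    stop("malformed connectome header in ", path, ": ", header)
  }
  kind <- m[2]
  n <- as.integer(m[3])
  w <- as.matrix(read.table(path, skip = 1, sep = "\t", header = FALSE))
  dimnames(w) <- NULL
  if (nrow(w) != ncol(w) || nrow(w) != n) {
    stop("connectome in ", path, " is not a square ", n, " x ", n, " matrix")
  }
  connectome(w, kind)
}

#' Export a significant network in BrainNet Viewer format
#'
#' Writes `<prefix>.node` (six whitespace-separated columns: x, y, z, color,
#' size, label; size is the node strength) and `<prefix>.edge` (the N x N
#' weight matrix over the network's nodes), the plain-text formats the
#' viewer documents.
#'
#' @param net A `significant_network`.
#' @param coords Numeric matrix `n_nodes_total` x 3 of node coordinates
#'   (rows indexed by 0-based node id + 1).
#' @param path_prefix Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
export_brainnet <- function(net, coords, path_prefix) {
  stopifnot(inherits(net, "significant_network"), is.matrix(coords),
            ncol(coords) == 3)
  if (nrow(coords) < net$n_nodes_total) {
    stop("coords has ", nrow(coords), " rows but the network spans ",
         net$n_nodes_total, " nodes")
  }
  node_path <- paste0(path_prefix, ".node")
  edge_path <- paste0(path_prefix, ".edge")
  nodes <- net$nodes
  if (!length(nodes)) {
    warning("empty network: writing empty .node/.edge files")
    writeLines(character(0), node_path)
    writeLines(character(0), edge_path)
    return(invisible(c(node = node_path, edge = edge_path)))
  }
  strength <- node_strength(net)[nodes + 1L]
  node_df <- data.frame(x = coords[nodes + 1L, 1], y = coords[nodes + 1L, 2],
                        z = coords[nodes + 1L, 3], color = 1,
                        size = strength, label = paste0("n", nodes))
  write.table(node_df, node_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  k <- length(nodes)
  adj <- matrix(0, k, k)
  pos <- match(net$edges$source, nodes)
  tgt <- match(net$edges$target, nodes)
  adj[cbind(pos, tgt)] <- net$edges$t
  write.table(adj, edge_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}

#' Write a simulated cohort to disk as plain text
#'
#' One `<subject>.tsv` matrix file (nodes x samples, with a `# fs=<Hz>`
#' header line) per subject, a `subjects.tsv` table, and the ground-truth
#' edge lists of both groups.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ts in cohort$series) {
    path <- file.path(dir, paste0(ts$subject_id, ".tsv"))
    lines <- apply(ts$data, 1, function(r) {
      paste(sprintf("%.10g", r), collapse = "\t")
    })
    writeLines(c(sprintf("# fs=%g", ts$fs), lines), path)
  }
  write.table(cohort$subjects, file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (grp in c("control", "patient")) {
    sp <- cohort[[paste0("spec_", grp)]]
    write.table(sp$edges, file.path(dir, paste0("truth_", grp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a source time-series matrix written by [write_cohort()]
#'
#' @param path A per-subject `.tsv` file with a `# fs=<Hz>` header.
#' @param subject_id Subject id to attach (defaults to the file name).
#' @return A `source_ts`.
#' @export
read_source_ts <- function(path, subject_id = NULL) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("^# fs=([0-9.eE+-]+)$", header))[[1]]
  if (length(m) != 2) stop("malformed time-series header in ", path)
  data <- as.matrix(read.table(path, skip = 1, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  if (is.null(subject_id)) {
    subject_id <- sub("\\.tsv$", "", basename(path))
  }
  structure(list(data = data, fs = as.numeric(m[2]), subject_id = subject_id),
            class = "source_ts")
}
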