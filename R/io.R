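# Plain-text persistence for every pipeline artifact. All files are
# tab-separated or CSV with '.' decimals, vertex indices are written
# 0-based (documented in each header line), and floating point uses 17
# significant digits so that a write/read round trip is exact.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_tsv_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# matrix ", nrow(m), " x ", ncol(m)), con)
  apply(m, 1, function(r) writeLines(paste(fmt_num(r), collapse = "\t"), con))
  invisible(path)
}

read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  do.call(rbind, lapply(strsplit(lines, "\t"), as.numeric))
}

#' Write / read a surface graph as plain text
#'
#' The graph becomes four pieces inside `dir`: `coords.csv` (vertex
#' coordinates in mm), `edges.tsv` (0-based vertex pairs with lengths),
#' and one 0/1 single-column file per mask (`mask_<name>.txt`).
#'
#' @param graph A `surface_graph`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly. `read_surface_graph()` returns the rebuilt
#'   `surface_graph`.
#' @export
write_surface_graph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- data.frame(vertex = seq_len(graph$n_vertices) - 1L,
                   ap = graph$coords[, 1], dv = graph$coords[, 2])
  write.csv(co, file.path(dir, "coords.csv"), row.names = FALSE)
  ed <- data.frame(a = graph$edges[, 1] - 1L, b = graph$edges[, 2] - 1L,
                   length_mm = fmt_num(graph$edge_lengths))
  utils::write.table(ed, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (nm in names(graph$masks))
    writeLines(as.character(as.integer(graph$masks[[nm]])),
               file.path(dir, paste0("mask_", nm, ".txt")))
  invisible(dir)
}

#' @rdname write_surface_graph
#' @export
read_surface_graph <- function(dir) {
  co <- read.csv(file.path(dir, "coords.csv"))
  ed <- utils::read.table(file.path(dir, "edges.tsv"), sep = "\t",
                          header = TRUE)
  masks <- list()
  for (f in list.files(dir, pattern = "^mask_.*\\.txt$")) {
    nm <- sub("^mask_(.*)\\.txt$", "\\1", f)
    masks[[nm]] <- as.logical(as.integer(readLines(file.path(dir, f))))
  }
  coords <- cbind(ap = co$ap, dv = co$dv)
  structure(list(
    n_vertices = nrow(co),
    coords = coords,
    edges = cbind(ed$a + 1L, ed$b + 1L),
    edge_lengths = as.numeric(ed$length_mm),
    masks = masks[c("hemisphere", "frontal_roi", "parietal_roi", "other")],
    spacing_mm = NA_real_,
    seed = NA_integer_
  ), class = "surface_graph")
}

#' Write / read a time-series matrix (vertices x timepoints TSV)
#'
#' @param ts A `timeseries_matrix`.
#' @param path Output file.
#' @return `path` invisibly; `read_timeseries()` the rebuilt object.
#' @export
write_timeseries <- function(ts, path) {
  con <- file(path, "w")
  writeLines(c(paste0("# timeseries subject=", ts$subject_id),
               paste0("# vertex_ids_0based\t",
                      paste(ts$vertex_ids - 1L, collapse = "\t"))), con)
  close(con)
  con <- file(path, "a")
  on.exit(close(con))
  apply(ts$values, 1, function(r)
    writeLines(paste(fmt_num(r), collapse = "\t"), con))
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  subject <- sub("^# timeseries subject=", "", lines[1])
  vids <- as.integer(strsplit(lines[2], "\t")[[1]][-1]) + 1L
  vals <- do.call(rbind, lapply(strsplit(lines[-(1:2)], "\t"), as.numeric))
  timeseries_matrix(vals, vids, subject)
}

#' Write / read a dense connectome (TSV matrix + JSON sidecar)
#'
#' @param conn A `dense_connectome`.
#' @param path Output file; the sidecar is `<path>.json`.
#' @return `path` invisibly; `read_connectome()` the rebuilt object.
#' @export
write_connectome <- function(conn, path) {
  write_tsv_matrix(conn$values, path)
  jsonlite::write_json(list(vertex_ids_0based = conn$vertex_ids - 1L),
                       paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dense_connectome_object(read_tsv_matrix(path),
                          side$vertex_ids_0based + 1L)
}

#' Write / read a parcellation (two CSVs + JSON metadata)
#'
#' `<stem>_labels.csv` holds (vertex, label); `<stem>_exemplars.csv`
#' holds (cluster, exemplar_vertex); `<stem>_meta.json` the run metadata
#' (preference, damping, iterations, convergence). Vertices 0-based.
#'
#' @param p A `parcellation`.
#' @param stem Output path stem.
#' @return `stem` invisibly; `read_parcellation()` the rebuilt object.
#' @export
write_parcellation <- function(p, stem) {
  write.csv(data.frame(vertex = p$vertex_ids - 1L, label = p$label_of),
            paste0(stem, "_labels.csv"), row.names = FALSE)
  write.csv(data.frame(cluster = seq_len(p$n_clusters),
                       exemplar_vertex = p$exemplar_vertices - 1L),
            paste0(stem, "_exemplars.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(preference = p$preference, damping = p$damping,
         iterations = p$iterations, converged = p$converged,
         n_clusters = p$n_clusters),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(stem) {
  lab <- read.csv(paste0(stem, "_labels.csv"))
  exm <- read.csv(paste0(stem, "_exemplars.csv"))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  vertex_ids <- lab$vertex + 1L
  structure(list(
    label_of = lab$label,
    exemplar_of = match(exm$exemplar_vertex + 1L, vertex_ids),
    exemplar_vertices = exm$exemplar_vertex + 1L,
    n_clusters = meta$n_clusters,
    vertex_ids = vertex_ids,
    preference = meta$preference,
    damping = meta$damping,
    converged = meta$converged,
    iterations = meta$iterations
  ), class = "parcellation")
}

#' Write a dendrogram as JSON merges and Newick
#'
#' @param d A `connectional_dendrogram`.
#' @param stem Output path stem (`<stem>.json`, `<stem>.nwk`).
#' @return `stem`, invisibly.
#' @export
write_dendrogram <- function(d, stem) {
  jsonlite::write_json(
    list(axis = d$axis, metric = d$metric,
         leaf_ids_0based = d$leaf_ids - 1L, merges = d$merges),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  phy <- ape::as.phylo(d$hclust)
  phy$tip.label <- as.character(d$leaf_ids - 1L)
  ape::write.tree(phy, paste0(stem, ".nwk"))
  invisible(stem)
}

#' Write a branch solution as CSV
#'
#' @param b A `branch_solution`.
#' @param path Output CSV with (exemplar_vertex 0-based, branch).
#' @return `path`, invisibly.
#' @export
write_branches <- function(b, path) {
  write.csv(data.frame(exemplar_vertex = b$leaf_ids - 1L,
                       branch = as.integer(b$branch_of)),
            path, row.names = FALSE)
  invisible(path)
}
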