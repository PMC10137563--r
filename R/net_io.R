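#' Read a weighted network into a symmetric adjacency matrix
#'
#' Supported formats:
#'
#' * `"tsv_edgelist"` — whitespace/tab-separated `i j weight` rows
#'   (weight optional, defaulting to 1); an optional header line is
#'   detected and skipped;
#' * `"gml"` — GML graph files (parsed by igraph); unweighted edges get
#'   weight 1;
#' * `"pajek_net"` — Pajek `.net` files (parsed by igraph), negative
#'   weights preserved;
#' * `"csv_adjacency"` — a dense square CSV matrix (no row names; a
#'   header row is optional).
#'
#' Node ids may be strings or integers; rows/columns of the returned
#' matrix are ordered by sorted id (numeric sort when all ids are
#' numeric), recorded in the `"node_ids"` attribute and the dimnames.
#' Duplicate edges are accepted only when their weights agree; an edge
#' listed in both orientations with conflicting weights is an error
#' rather than being silently averaged.
#'
#' @param path Input file.
#' @param format One of the formats above; the default guesses from the
#'   file extension (`.gml`, `.net`, `.csv`, else TSV edge list).
#' @return Symmetric numeric matrix with `"node_ids"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("1\t2\t1", "2\t3\t-1", "1\t3\t2"), tf)
#' read_network(tf)
#' @export
read_network <- function(path, format = c("guess", "tsv_edgelist", "gml",
                                          "pajek_net", "csv_adjacency")) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gml = "gml", net = "pajek_net",
                     csv = "csv_adjacency", "tsv_edgelist")
  }
  switch(format,
    tsv_edgelist = read_tsv_edgelist(path),
    gml = read_igraph_format(path, "gml"),
    pajek_net = read_igraph_format(path, "pajek"),
    csv_adjacency = read_csv_adjacency(path))
}

read_tsv_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^[#]|^(from|node_i|source|i)\\b",
                             lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) {
    A <- matrix(numeric(0), 0, 0)
    attr(A, "node_ids") <- character(0)
    return(A)
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("edge-list lines need at least two fields (i, j[, weight])",
         call. = FALSE)
  i <- vapply(parts, `[`, "", 1L)
  j <- vapply(parts, `[`, "", 2L)
  w <- vapply(parts, function(p)
    if (length(p) >= 3L) as.numeric(p[3]) else 1, numeric(1))
  if (any(!is.finite(w)))
    stop("edge weights must be finite numbers", call. = FALSE)
  edgelist_to_adjacency(i, j, w)
}

edgelist_to_adjacency <- function(i, j, w) {
  ids <- unique(c(i, j))
  num <- suppressWarnings(as.numeric(ids))
  ids <- if (!anyNA(num)) ids[order(num)] else sort(ids)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  seen <- new.env(hash = TRUE)
  ii <- match(i, ids); jj <- match(j, ids)
  for (e in seq_along(ii)) {
    a <- min(ii[e], jj[e]); b <- max(ii[e], jj[e])
    key <- paste0(a, ":", b)
    prev <- seen[[key]]
    if (!is.null(prev) && prev != w[e])
      stop(sprintf("conflicting weights for edge (%s, %s): %g vs %g",
                   ids[a], ids[b], prev, w[e]), call. = FALSE)
    seen[[key]] <- w[e]
    A[a, b] <- w[e]
    A[b, a] <- w[e]
  }
  attr(A, "node_ids") <- ids
  A
}

read_igraph_format <- function(path, igraph_format) {
  g <- igraph::read_graph(path, format = igraph_format)
  g <- igraph::as_undirected(g, mode = "collapse")
  nm <- igraph::vertex_attr_names(g)
  ids <- if ("name" %in% nm) igraph::V(g)$name
         else if ("id" %in% nm) as.character(igraph::V(g)$id)
         else as.character(seq_len(igraph::vcount(g)))
  A <- graph_to_adjacency(g)
  num <- suppressWarnings(as.numeric(ids))
  ord <- if (!anyNA(num)) order(num) else order(ids)
  A <- A[ord, ord, drop = FALSE]
  dimnames(A) <- list(ids[ord], ids[ord])
  attr(A, "node_ids") <- ids[ord]
  A
}

read_csv_adjacency <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, ",")[[1]][1])))
  M <- as.matrix(utils::read.csv(path, header = has_header))
  storage.mode(M) <- "double"
  if (nrow(M) != ncol(M))
    stop("CSV adjacency matrix must be square", call. = FALSE)
  if (!isSymmetric(unname(M), tol = 0))
    stop("CSV adjacency matrix must be exactly symmetric", call. = FALSE)
  ids <- as.character(seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  attr(M, "node_ids") <- ids
  M
}

#' Write a weighted network to disk
#'
#' `"tsv_edgelist"` writes a header plus one `i j weight` row per
#' unordered pair with nonzero weight (`i < j`, 1-based ids), weights at
#' full double precision so a write/read round trip is exact.
#' `"csv_adjacency"` writes the dense matrix as CSV without a header.
#'
#' @param A Symmetric numeric matrix.
#' @param path Output file.
#' @param format `"tsv_edgelist"` (default) or `"csv_adjacency"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(A, path, format = c("tsv_edgelist",
                                              "csv_adjacency")) {
  format <- match.arg(format)
  if (format == "csv_adjacency") {
    lines <- apply(A, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(lines, path)
    return(invisible(path))
  }
  up <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  lines <- c("node_i\tnode_j\tweight",
             sprintf("%d\t%d\t%.17g", up[, 1], up[, 2], A[up]))
  writeLines(lines, path)
  invisible(path)
}
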