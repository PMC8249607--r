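#' Read a multilayer network from disk
#'
#' Two on-disk formats are supported. `"json"` is a single file holding
#' node count, node types and per-layer edge lists. `"edgelist"` is a JSON
#' sidecar (same header fields) whose layers point at one TSV edge list
#' each (`src<TAB>dst<TAB>weight`, `#` comments, 1-based node IDs, weight
#' column optional and defaulting to 1). Node IDs are 1-based in files and
#' internally.
#'
#' @param path path to the JSON file (or edge-list sidecar).
#' @param format `"json"` or `"edgelist"`.
#' @return a [multilayer_network()].
#' @export
read_network <- function(path, format = c("json", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("parse error in %s: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  n <- doc$n_nodes
  if (is.null(n) || n < 1) stop(sprintf("%s: missing or invalid n_nodes", path))
  types <- as.character(unlist(doc$node_types))
  if (length(types) != n)
    stop(sprintf("%s: node_types has length %d, expected %d",
                 path, length(types), n))
  layers <- lapply(seq_along(doc$layers), function(k) {
    ld <- doc$layers[[k]]
    edges <- if (format == "json") {
      do.call(rbind, lapply(ld$edges, function(e) {
        if (length(e) < 2) stop(sprintf("%s: layer %d has a malformed edge",
                                        path, k))
        c(e[[1]], e[[2]], if (length(e) >= 3) e[[3]] else 1)
      }))
    } else {
      f <- file.path(dirname(path), ld$edges_file)
      read_edge_tsv(f, k)
    }
    A <- matrix(0, n, n)
    if (!is.null(edges) && nrow(edges) > 0) {
      src <- as.integer(edges[, 1]); dst <- as.integer(edges[, 2])
      bad <- which(src < 1 | src > n | dst < 1 | dst > n)
      if (length(bad))
        stop(sprintf("%s: layer %d edge %d has node ID out of range 1..%d",
                     path, k, bad[1], n))
      A[cbind(dst, src)] <- as.numeric(edges[, 3])
    }
    ly <- layer(A, sigma = ld$sigma %||% 1, delay = ld$delay %||% 0,
                label = ld$label %||% "")
    if (isTRUE(ld$undirected) && max(abs(A - t(A))) > 1e-12)
      stop(sprintf("%s: layer %d declared undirected but weights asymmetric",
                   path, k))
    ly
  })
  multilayer_network(n, types, layers)
}

read_edge_tsv <- function(f, k) {
  if (!file.exists(f)) stop(sprintf("edge list not found: %s", f))
  lines <- readLines(f)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) return(matrix(numeric(0), 0, 3))
  out <- matrix(NA_real_, length(keep), 3)
  for (r in seq_along(keep)) {
    fields <- strsplit(lines[keep[r]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop(sprintf("%s line %d: expected src<TAB>dst[<TAB>weight]",
                   f, keep[r]))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals[1:2])))
      stop(sprintf("%s line %d: non-numeric node ID", f, keep[r]))
    out[r, ] <- c(vals[1], vals[2], if (length(vals) >= 3) vals[3] else 1)
  }
  out
}

#' Write a multilayer network to disk
#'
#' Inverse of [read_network()]; weights are written with full precision so
#' that integer and dyadic-rational weights round-trip exactly.
#'
#' @param net a [multilayer_network()].
#' @param path output path (JSON file, or edge-list sidecar whose TSV files
#'   are written next to it).
#' @param format `"json"` or `"edgelist"`.
#' @export
write_network <- function(net, path, format = c("json", "edgelist")) {
  format <- match.arg(format)
  edge_rows <- function(A) {
    idx <- which(A != 0, arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    lapply(seq_len(nrow(idx)), function(r)
      list(idx[r, "col"], idx[r, "row"], A[idx[r, "row"], idx[r, "col"]]))
  }
  doc <- list(n_nodes = net$n_nodes, node_types = as.list(net$node_types))
  if (format == "json") {
    doc$layers <- lapply(net$layers, function(ly)
      list(label = ly$label, sigma = ly$sigma, delay = ly$delay,
           edges = edge_rows(ly$adjacency)))
  } else {
    base <- sub("\\.json$", "", basename(path))
    doc$layers <- lapply(seq_along(net$layers), function(k) {
      ly <- net$layers[[k]]
      fn <- sprintf("%s_layer%d.tsv", base, k)
      rows <- edge_rows(ly$adjacency)
      lines <- c("# src\tdst\tweight",
                 vapply(rows, function(e)
                   sprintf("%d\t%d\t%s", e[[1]], e[[2]],
                           format(e[[3]], digits = 17)), character(1)))
      writeLines(lines, file.path(dirname(path), fn))
      list(label = ly$label, sigma = ly$sigma, delay = ly$delay,
           edges_file = fn)
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
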