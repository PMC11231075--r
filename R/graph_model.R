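#' Construct a bipartite MPX cell graph
#'
#' One Molecular Pixelation cell is a bipartite graph: A-pixels and
#' B-pixels are the two node classes, and every antibody-oligonucleotide
#' molecule contributes to the count of an (A-pixel, B-pixel, marker) edge.
#'
#' @param cell_id Cell identifier (string).
#' @param edges A data.frame with columns `upia` (A-pixel id), `upib`
#'   (B-pixel id), `marker`, `count`. Rows sharing (upia, upib, marker)
#'   are aggregated by summing counts.
#' @param panel Optional `mpx_panel`; if given, markers are validated
#'   against it.
#' @return An object of class `mpx_bipartite` with fields `cell_id`,
#'   `edges` (aggregated), `a_nodes`, `b_nodes`.
#' @export
mpx_bipartite <- function(cell_id, edges, panel = NULL) {
  req <- c("upia", "upib", "marker", "count")
  missing <- setdiff(req, names(edges))
  if (length(missing)) {
    stop("edge table missing column(s): ", paste(missing, collapse = ", "))
  }
  edges <- edges[req]
  edges$upia <- as.character(edges$upia)
  edges$upib <- as.character(edges$upib)
  edges$marker <- as.character(edges$marker)
  bad <- which(!is.finite(edges$count) | edges$count <= 0 |
                 edges$count != round(edges$count))
  if (length(bad)) {
    stop("edge counts must be positive integers; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(edges$marker), panel$marker)
    if (length(unknown)) {
      stop("marker(s) not in panel: ", paste(unknown, collapse = ", "))
    }
  }
  if (nrow(edges)) {
    agg <- stats::aggregate(count ~ upia + upib + marker, data = edges, FUN = sum)
    agg <- agg[order(agg$upia, agg$upib, agg$marker), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- edges
  }
  structure(list(cell_id = as.character(cell_id),
                 edges = agg,
                 a_nodes = sort(unique(agg$upia)),
                 b_nodes = sort(unique(agg$upib))),
            class = "mpx_bipartite")
}

#' @export
print.mpx_bipartite <- function(x, ...) {
  cat(sprintf("<mpx_bipartite> cell %s: %d A-pixels, %d B-pixels, %d edges, %d molecules\n",
              x$cell_id, length(x$a_nodes), length(x$b_nodes),
              nrow(x$edges), sum(x$edges$count)))
  invisible(x)
}

#' Read per-cell bipartite graphs from a delimited edge list
#'
#' The edge-list dialect is a plain delimited table (comma for `.csv`,
#' tab for `.tsv`) with header columns `cell_id`, `upia`, `upib`,
#' `marker`, `count`. Rows with identical (cell, A-pixel, B-pixel,
#' marker) are aggregated by summing their counts.
#'
#' @param path Path to the edge-list file.
#' @param panel An `mpx_panel`; every marker in the table must be in it.
#' @return A named list of `mpx_bipartite`, one per distinct `cell_id`.
#' @export
read_cell_edge_list <- function(path, panel) {
  stopifnot(inherits(panel, "mpx_panel"))
  tab <- read_delimited(path, required = c("cell_id", "upia", "upib",
                                           "marker", "count"))
  if (!nrow(tab)) return(structure(list(), names = character()))
  unknown <- setdiff(unique(as.character(tab$marker)), panel$marker)
  if (length(unknown)) {
    stop("marker(s) not in panel: ", paste(unknown, collapse = ", "))
  }
  bad <- which(!is.finite(tab$count) | tab$count <= 0)
  if (length(bad)) {
    stop("non-positive count at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  cells <- split(tab, as.character(tab$cell_id))
  out <- lapply(names(cells), function(cid) {
    mpx_bipartite(cid, cells[[cid]], panel = panel)
  })
  names(out) <- names(cells)
  out
}

#' Write cell graphs to the edge-list dialect
#'
#' @param cells A list of `mpx_bipartite` objects.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_cell_edge_list <- function(cells, path) {
  if (inherits(cells, "mpx_bipartite")) cells <- list(cells)
  tabs <- lapply(cells, function(g) {
    cbind(data.frame(cell_id = rep(g$cell_id, nrow(g$edges))), g$edges)
  })
  write_delimited(do.call(rbind, tabs), path)
}

#' Project a bipartite cell graph onto its A-nodes
#'
#' Two A-pixels become adjacent iff they share at least one B-pixel; the
#' projected graph is simple and unweighted. Marker counts move from the
#' bipartite edges onto the A-nodes: `counts[v, m]` is the sum of counts
#' of marker-`m` edges incident to A-pixel `v`, so per-marker totals are
#' conserved by the projection.
#'
#' @param g An `mpx_bipartite`.
#' @param largest_component If `TRUE` (default), keep only the largest
#'   connected component of the projection (the random-walk scores are
#'   ill-defined across components); the number of dropped A-nodes is
#'   recorded in the result and reported via `message()`.
#' @return An object of class `mpx_anode`: fields `cell_id`, `graph`
#'   (an undirected simple [igraph::graph]), `nodes`, `counts`
#'   (nodes x markers integer matrix), `dropped_nodes`.
#' @export
project_to_anodes <- function(g, largest_component = TRUE) {
  stopifnot(inherits(g, "mpx_bipartite"))
  a <- g$a_nodes
  markers <- sort(unique(g$edges$marker))
  counts <- matrix(0L, nrow = length(a), ncol = length(markers),
                   dimnames = list(a, markers))
  if (nrow(g$edges)) {
    idx <- cbind(match(g$edges$upia, a), match(g$edges$marker, markers))
    for (r in seq_len(nrow(g$edges))) {
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] +
        as.integer(g$edges$count[r])
    }
  }
  # adjacency: A-pixels sharing >= 1 B-pixel
  pairs <- unique(g$edges[c("upia", "upib")])
  by_b <- split(pairs$upia, pairs$upib)
  edge_keys <- unique(unlist(lapply(by_b, function(as_) {
    if (length(as_) < 2) return(character())
    as_ <- sort(as_)
    cmb <- utils::combn(as_, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE))
  graph <- igraph::make_empty_graph(n = length(a), directed = FALSE)
  graph <- igraph::set_vertex_attr(graph, "name", value = a)
  if (length(edge_keys)) {
    ends <- do.call(rbind, strsplit(edge_keys, "\r", fixed = TRUE))
    graph <- igraph::add_edges(graph, rbind(ends[, 1], ends[, 2]))
  }
  dropped <- 0L
  if (largest_component && length(a)) {
    comp <- igraph::components(graph)
    if (comp$no > 1) {
      keep <- which(comp$membership == which.max(comp$csize))
      dropped <- length(a) - length(keep)
      message(sprintf("cell %s: dropped %d A-node(s) outside the largest component",
                      g$cell_id, dropped))
      graph <- igraph::induced_subgraph(graph, keep)
      counts <- counts[igraph::V(graph)$name, , drop = FALSE]
    }
  }
  structure(list(cell_id = g$cell_id,
                 graph = graph,
                 nodes = igraph::V(graph)$name,
                 counts = counts,
                 dropped_nodes = dropped),
            class = "mpx_anode")
}

#' @export
print.mpx_anode <- function(x, ...) {
  cat(sprintf("<mpx_anode> cell %s: %d A-nodes, %d edges, %d markers\n",
              x$cell_id, length(x$nodes), igraph::ecount(x$graph),
              ncol(x$counts)))
  invisible(x)
}

#' Per-marker molecule totals of an A-node graph
#'
#' @param an An `mpx_anode`.
#' @return Named integer vector of per-marker totals.
#' @export
marker_totals <- function(an) {
  stopifnot(inherits(an, "mpx_anode"))
  colSums(an$counts)
}
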