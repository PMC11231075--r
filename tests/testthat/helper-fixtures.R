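# Shared fixtures: all built in code at test time.

# A-node graph assembled directly from an igraph and a count matrix,
# bypassing the bipartite projection (for oracle tests on known graphs).
make_anode <- function(graph, counts, cell_id = "t") {
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = paste0("v", seq_len(igraph::vcount(graph))))
  }
  stopifnot(identical(rownames(counts), igraph::V(graph)$name))
  structure(list(cell_id = cell_id, graph = graph,
                 nodes = igraph::V(graph)$name,
                 counts = counts, dropped_nodes = 0L),
            class = "mpx_anode")
}

count_matrix <- function(x, nodes, marker = "M") {
  matrix(as.integer(x), ncol = 1, dimnames = list(nodes, marker))
}

# two 4-cliques joined by a single bridge edge
barbell_graph <- function() {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(4, 5))
  igraph::set_vertex_attr(g, "name", value = paste0("v", 1:8))
}

small_panel <- function() {
  mpx_panel(c("CD50", "CD162", "CD37", "mIgG1", "mIgG2a", "mIgG2b"),
            isotype_markers = c("mIgG1", "mIgG2a", "mIgG2b"))
}

study_panel <- function() {
  mpx_panel(c("CD50", "CD162", "CD37", "CD44", "CD18", "CD45", "CD82",
              "B2M", "mIgG2b", "mIgG1", "mIgG2a"),
            isotype_markers = c("mIgG2b", "mIgG1", "mIgG2a"))
}

# random connected G(n, p) graph
random_connected_graph <- function(n, p = 0.25) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      return(igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n))))
    }
  }
}

adjusted_field <- function(values, nodes = paste0("v", seq_along(values)),
                           cell_id = "t", marker = "M") {
  mpx_scores(stats::setNames(values, nodes), cell_id, marker, "adjusted")
}

raw_field <- function(values, nodes = paste0("v", seq_along(values)),
                      cell_id = "t", marker = "M") {
  mpx_scores(stats::setNames(values, nodes), cell_id, marker, "raw")
}

# full adjustment pipeline on a raw vector
adjust_vector <- function(x) {
  as.numeric(signed_log(standardize_energy(normalize_signed(raw_field(x)))))
}

# dense linear-solve oracle for personalized PageRank:
# w = alpha e (I - (1-alpha) P)^-1, floor applied afterwards
ppr_dense_oracle <- function(an, focal, alpha, floor_ = 0) {
  P <- as.matrix(mpxassort:::transition_matrix(an))
  n <- nrow(P)
  e <- as.numeric(an$nodes == focal)
  w <- solve(diag(n) - (1 - alpha) * t(P), alpha * e)
  w <- stats::setNames(w, an$nodes)
  if (floor_ > 0) {
    w[w < floor_] <- 0
    w <- w / sum(w)
  }
  w
}

# edge-end Pearson oracle for global degree-weighted assortativity
global_assortativity_oracle <- function(graph, x) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  stats::cor(c(x[el[, 1]], x[el[, 2]]), c(x[el[, 2]], x[el[, 1]]))
}

# inclusion-exclusion long form of the multiple-site similarity numerator
multisite_long_form <- function(sets) {
  sets <- lapply(sets, unique)
  t_ <- length(sets)
  size_sum <- sum(lengths(sets))
  if (size_sum == 0) return(0)
  num <- 0
  for (k in 2:t_) {
    for (idx in utils::combn(t_, k, simplify = FALSE)) {
      num <- num + (-1)^k * length(Reduce(intersect, sets[idx]))
    }
  }
  (t_ / (t_ - 1)) * num / size_sum
}

# U-statistic enumeration oracle for the two-sided rank-sum p-value:
# counts pairs x > y (+1/2 per tie) over all regroupings of the pooled data
rank_sum_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- abs(u_stat(a, b) - n_a * length(b) / 2)
  subsets <- utils::combn(length(pooled), n_a, simplify = FALSE)
  stats <- vapply(subsets, function(s) {
    abs(u_stat(pooled[s], pooled[-s]) - n_a * length(b) / 2)
  }, numeric(1))
  mean(stats >= obs - 1e-9)
}
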