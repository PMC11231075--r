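#' Pairwise protein colocalization of two adjusted score fields
#'
#' Spearman rank correlation (average ranks for ties) of the two adjusted
#' local assortativity fields of one cell. If either field is all zeros
#' (a filtered or uniformly mixed marker) the score is defined as exactly
#' 0, avoiding the degenerate-correlation edge case.
#'
#' @param x,y Adjusted `mpx_scores` from the same cell with identical
#'   node order.
#' @return A number in `[-1, 1]`.
#' @export
pairwise_colocalization <- function(x, y) {
  stopifnot(inherits(x, "mpx_scores"), inherits(y, "mpx_scores"),
            score_stage(x) == "adjusted", score_stage(y) == "adjusted")
  if (length(x) != length(y) || !identical(names(x), names(y))) {
    stop("score fields are not aligned on the same node set")
  }
  xv <- as.numeric(x); yv <- as.numeric(y)
  if (all(xv == 0) || all(yv == 0)) return(0)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(0)  # constant non-zero field
  stats::cor(xv, yv, method = "spearman")
}

#' All pairwise colocalization records of one cell
#'
#' @param cell_scores Named list of adjusted `mpx_scores` for one cell
#'   (as returned by [score_cell()]).
#' @param markers Marker subset to pair; defaults to all scored markers.
#' @return A data.frame with columns `cell_id`, `marker_1`, `marker_2`
#'   (lexicographically ordered within each pair), `order` (2), `score`;
#'   one row per unordered pair.
#' @export
colocalization_matrix <- function(cell_scores, markers = names(cell_scores)) {
  missing <- setdiff(markers, names(cell_scores))
  if (length(missing)) stop("no scores for marker(s): ",
                            paste(missing, collapse = ", "))
  markers <- sort(markers)
  if (length(markers) < 2) {
    return(data.frame(cell_id = character(), marker_1 = character(),
                      marker_2 = character(), order = integer(),
                      score = numeric()))
  }
  cmb <- utils::combn(markers, 2)
  cid <- attr(cell_scores[[markers[1]]], "cell_id")
  data.frame(cell_id = cid,
             marker_1 = cmb[1, ],
             marker_2 = cmb[2, ],
             order = 2L,
             score = apply(cmb, 2, function(p) {
               pairwise_colocalization(cell_scores[[p[1]]], cell_scores[[p[2]]])
             }))
}

#' Nodes with positive adjusted score
#'
#' The assortative region of a marker: nodes with adjusted score strictly
#' greater than zero. Zeros (uniform mixing or filtered markers) are
#' excluded.
#'
#' @param x An adjusted `mpx_scores`.
#' @return Character vector of node ids.
#' @export
positive_node_set <- function(x) {
  stopifnot(inherits(x, "mpx_scores"), score_stage(x) == "adjusted")
  names(x)[as.numeric(x) > 0]
}

#' Multiple-site similarity of T node sets
#'
#' The ecology-derived overlap measure
#' `C = (T / (T - 1)) * (1 - |union| / sum of sizes)`, which reduces to
#' the Sorensen index `2|A ∩ B| / (|A| + |B|)` at `T = 2`. Empty
#' families (all sets empty) score 0.
#'
#' @param sets A list of `T >= 2` vectors (node-id sets).
#' @return A number in `[0, 1]`.
#' @export
multisite_similarity <- function(sets) {
  if (length(sets) < 2) stop("multiple-site similarity requires T >= 2 sets")
  sets <- lapply(sets, unique)
  size_sum <- sum(lengths(sets))
  if (size_sum == 0) return(0)
  t_ <- length(sets)
  union_size <- length(unique(unlist(sets, use.names = FALSE)))
  (t_ / (t_ - 1)) * (1 - union_size / size_sum)
}

#' Higher-order colocalization of a marker tuple in one cell
#'
#' Applies the multiple-site similarity to the positive-score node sets
#' of the markers. Markers zeroed by the upstream filters contribute
#' empty sets and therefore drag the score down.
#'
#' @param cell_scores Named list of adjusted `mpx_scores` for one cell.
#' @param markers Character vector of `k >= 2` marker names (the method's
#'   use case is `k >= 3`; `k = 2` gives the Sorensen index of the
#'   positive sets, not the pairwise Spearman score).
#' @return One-row data.frame with columns `cell_id`, `markers`
#'   (sorted, `+`-joined), `order`, `score`.
#' @export
higher_order_colocalization <- function(cell_scores, markers) {
  if (length(markers) < 2) stop("need at least 2 markers")
  missing <- setdiff(markers, names(cell_scores))
  if (length(missing)) stop("no scores for marker(s): ",
                            paste(missing, collapse = ", "))
  markers <- sort(markers)
  sets <- lapply(cell_scores[markers], positive_node_set)
  data.frame(cell_id = attr(cell_scores[[markers[1]]], "cell_id"),
             markers = paste(markers, collapse = "+"),
             order = length(markers),
             score = multisite_similarity(sets))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration over all assignments of the pooled ranks when both
#' groups have fewer than 20 observations (ties handled by average
#' ranks and enumeration of the actual rank multiset); tie-corrected
#' normal approximation otherwise.
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
rank_sum_p <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1 || n_b < 1) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  n <- n_a + n_b
  if (n_a < 20 && n_b < 20 && choose(n, n_a) <= 5e5) {
    obs <- sum(r[seq_len(n_a)])
    mu <- n_a * (n + 1) / 2
    combs <- utils::combn(n, n_a)
    stat <- abs(colSums(matrix(r[combs], nrow = n_a)) - mu)
    # two-sided: rank-sum assignments at least as extreme as observed
    mean(stat >= abs(obs - mu) - 1e-9)
  } else {
    u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
    mu_u <- n_a * n_b / 2
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (u - mu_u) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Significance-dot category of a p-value
#'
#' The dot nomenclature of differential colocalization displays:
#' 0 dots for `p > 0.01`, 1 for `0.001 < p <= 0.01`, 2 for
#' `0.0001 < p <= 0.001`, 3 for `p <= 0.0001`.
#'
#' @param p p-value(s).
#' @return Integer vector of 0-3.
#' @export
p_value_dots <- function(p) {
  vapply(p, function(pi) {
    if (pi <= 1e-4) 3L else if (pi <= 1e-3) 2L else if (pi <= 1e-2) 1L else 0L
  }, integer(1))
}

#' Differential colocalization between two samples
#'
#' Compares the per-cell colocalization scores of one marker combination
#' between two samples: reports `mean_a - mean_b` and a two-sided
#' Wilcoxon rank-sum p-value with its dot category.
#'
#' @param scores_a,scores_b Numeric vectors of per-cell colocalization
#'   scores (>= 2 cells each).
#' @param markers Marker combination label (character vector or
#'   `+`-joined string).
#' @return One-row data.frame: `markers`, `order`, `mean_a`, `mean_b`,
#'   `mean_diff`, `p_value`, `dots`.
#' @export
differential_colocalization <- function(scores_a, scores_b, markers) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    stop("need at least 2 cells per sample")
  }
  if (length(markers) > 1) markers <- paste(sort(markers), collapse = "+")
  p <- rank_sum_p(scores_a, scores_b)
  data.frame(markers = markers,
             order = length(strsplit(markers, "+", fixed = TRUE)[[1]]),
             mean_a = mean(scores_a),
             mean_b = mean(scores_b),
             mean_diff = mean(scores_a) - mean(scores_b),
             p_value = p,
             dots = p_value_dots(p))
}
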