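#' Configuration for local assortativity scoring
#'
#' @param restart_probability Teleport probability of the personalized
#'   random walk back to the focal node, in `[0, 1)`. The complement is
#'   the continuation probability of the walk (0.15 matches the common
#'   0.85 damping convention). Larger values localize the score more
#'   tightly around the focal node.
#' @param weight_floor After convergence, personalized-PageRank weights
#'   below this value are truncated to zero and the vector renormalized;
#'   this sparsifies the walk distribution so remote nodes do not
#'   contribute. Must be `< 1`.
#' @param vertex_threshold A marker must have non-zero counts on strictly
#'   more than this many A-nodes to be scored (default 10).
#' @param isotype_filter_enabled Whether the per-cell isotype noise floor
#'   is applied (requires at least one isotype control in the panel).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Iteration cap of the power iteration.
#' @return A list of class `assort_config`.
#' @export
assort_config <- function(restart_probability = 0.15,
                          weight_floor = 1e-4,
                          vertex_threshold = 10L,
                          isotype_filter_enabled = TRUE,
                          tol = 1e-13,
                          max_iter = 10000L) {
  stopifnot(restart_probability >= 0, restart_probability < 1,
            weight_floor >= 0, weight_floor < 1,
            vertex_threshold >= 0, tol > 0, max_iter >= 1)
  structure(list(restart_probability = restart_probability,
                 weight_floor = weight_floor,
                 vertex_threshold = as.integer(vertex_threshold),
                 isotype_filter_enabled = isotype_filter_enabled,
                 tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "assort_config")
}

# Row-stochastic transition matrix of the simple random walk on an
# mpx_anode graph (sparse).
transition_matrix <- function(an) {
  A <- igraph::as_adjacency_matrix(an$graph, sparse = TRUE)
  d <- Matrix::rowSums(A)
  if (any(d == 0)) stop("graph has isolated node(s); project with largest_component = TRUE")
  Matrix::Diagonal(x = 1 / d) %*% A
}

# Personalized-PageRank weights for all focal nodes at once: row l of the
# returned matrix is the walk distribution personalized on node l.
# Iterates W <- alpha I + (1 - alpha) W P. For restart 0 the plain
# iteration oscillates on bipartite graphs, so the lazy half-step
# (I + P)/2 is used there; it has the same fixed point.
ppr_matrix <- function(an, cfg) {
  n <- length(an$nodes)
  P <- transition_matrix(an)
  alpha <- cfg$restart_probability
  lazy <- alpha == 0
  W <- diag(1, n)
  for (it in seq_len(cfg$max_iter)) {
    step <- as.matrix(W %*% P)
    if (lazy) step <- (W + step) / 2
    W_new <- alpha * diag(1, n) + (1 - alpha) * step
    resid <- max(rowSums(abs(W_new - W)))
    W <- W_new
    if (resid < cfg$tol) {
      dimnames(W) <- list(an$nodes, an$nodes)
      return(apply_weight_floor(W, cfg$weight_floor))
    }
  }
  stop(sprintf("personalized PageRank did not converge in %d iterations (L1 residual %.3e)",
               cfg$max_iter, resid))
}

apply_weight_floor <- function(W, floor_) {
  if (floor_ > 0) {
    W[W < floor_] <- 0
    W <- W / rowSums(W)
  }
  W
}

#' Personalized-PageRank weights for one focal node
#'
#' Power iteration of the walk that at each step teleports back to the
#' focal node with probability `restart_probability` and otherwise moves
#' to a uniformly random neighbor. After convergence, weights below
#' `weight_floor` are zeroed and the vector renormalized to sum 1.
#'
#' @param an A connected `mpx_anode` graph.
#' @param focal_node Node name (A-pixel id) in `an`.
#' @param cfg An [assort_config()].
#' @return Named non-negative weight vector over the nodes, summing to 1.
#' @export
personalized_pagerank <- function(an, focal_node, cfg = assort_config()) {
  stopifnot(inherits(an, "mpx_anode"))
  if (!focal_node %in% an$nodes) stop("focal node not in graph: ", focal_node)
  n <- length(an$nodes)
  P <- transition_matrix(an)
  alpha <- cfg$restart_probability
  lazy <- alpha == 0
  e <- w <- stats::setNames(numeric(n), an$nodes)
  e[focal_node] <- 1
  w[focal_node] <- 1
  for (it in seq_len(cfg$max_iter)) {
    step <- as.numeric(w %*% P)
    if (lazy) step <- (w + step) / 2
    w_new <- alpha * e + (1 - alpha) * step
    resid <- sum(abs(w_new - w))
    w <- stats::setNames(w_new, an$nodes)
    if (resid < cfg$tol) {
      if (cfg$weight_floor > 0) {
        w[w < cfg$weight_floor] <- 0
        w <- w / sum(w)
      }
      return(w)
    }
  }
  stop(sprintf("personalized PageRank did not converge in %d iterations (L1 residual %.3e)",
               cfg$max_iter, resid))
}

# Degree-weighted edge-end mean and variance of a node attribute. These
# are the moments over the 2m edge ends of the graph.
edge_end_moments <- function(an, x) {
  d <- igraph::degree(an$graph)
  mu <- sum(d * x) / sum(d)
  sigma2 <- sum(d * x^2) / sum(d) - mu^2
  list(mu = mu, sigma2 = max(sigma2, 0))
}

#' Score-field constructor
#'
#' A score field holds one real value per A-node of one cell for one
#' marker, at one stage of the adjustment pipeline.
#'
#' @param values Named numeric vector aligned with the A-node graph.
#' @param cell_id,marker Identifiers.
#' @param stage One of `"raw"`, `"normalized"`, `"standardized"`,
#'   `"adjusted"`.
#' @return An object of class `mpx_scores` (a named numeric vector with
#'   attributes).
#' @export
mpx_scores <- function(values, cell_id, marker, stage) {
  stage <- match.arg(stage, c("raw", "normalized", "standardized", "adjusted"))
  structure(values, cell_id = cell_id, marker = marker, stage = stage,
            class = "mpx_scores")
}

score_stage <- function(s) attr(s, "stage")

#' @export
print.mpx_scores <- function(x, ...) {
  cat(sprintf("<mpx_scores> cell %s, marker %s, stage %s, %d nodes\n",
              attr(x, "cell_id"), attr(x, "marker"), attr(x, "stage"),
              length(x)))
  print(utils::head(unclass(x)), ...)
  invisible(x)
}

#' Raw per-node local assortativity of one marker
#'
#' Reweights the global degree-weighted assortativity of the marker-count
#' attribute with the personalized random-walk distribution of each focal
#' node: with edge-end moments `mu_e`, `sigma_e^2` of the attribute `x`
#' and walk weights `w(l)`, the score of focal node `l` is
#' `(sum_v w_v(l) x_v (sum_{u~v} x_u / d_v) - mu_e^2) / sigma_e^2`.
#' A constant attribute (zero edge-end variance) yields the all-zero
#' field, the score of uniform mixing.
#'
#' @param an A connected `mpx_anode`.
#' @param marker Marker name (column of `an$counts`).
#' @param cfg An [assort_config()].
#' @param W Optional precomputed personalized-PageRank matrix from the
#'   same graph and config (rows = focal nodes); pass it when scoring
#'   many markers of one cell to avoid recomputation.
#' @return An `mpx_scores` with `stage = "raw"`.
#' @export
raw_local_assortativity <- function(an, marker, cfg = assort_config(), W = NULL) {
  stopifnot(inherits(an, "mpx_anode"))
  if (!marker %in% colnames(an$counts)) stop("unknown marker: ", marker)
  x <- as.numeric(an$counts[, marker])
  names(x) <- an$nodes
  mom <- edge_end_moments(an, x)
  if (mom$sigma2 <= 0) {
    return(mpx_scores(stats::setNames(numeric(length(x)), an$nodes),
                      an$cell_id, marker, "raw"))
  }
  if (is.null(W)) W <- ppr_matrix(an, cfg)
  A <- igraph::as_adjacency_matrix(an$graph, sparse = TRUE)
  d <- igraph::degree(an$graph)
  nb_mean <- as.numeric(A %*% x) / d     # mean attribute over neighbors
  contrib <- x * nb_mean
  raw <- (as.numeric(W %*% contrib) - mom$mu^2) / mom$sigma2
  mpx_scores(stats::setNames(raw, an$nodes), an$cell_id, marker, "raw")
}

#' Signed normalization of raw scores (f)
#'
#' Divides each positive score by the sum of all positive scores and each
#' negative score by the sum of absolute negative scores, so each sign
#' block sums to +1 / -1 and zero stays the fixed point of uniform
#' mixing. An all-zero field maps to itself.
#'
#' @param s An `mpx_scores` with `stage = "raw"`.
#' @return An `mpx_scores` with `stage = "normalized"`.
#' @export
normalize_signed <- function(s) {
  stopifnot(inherits(s, "mpx_scores"), score_stage(s) == "raw")
  x <- as.numeric(s)
  out <- x
  pos <- sum(x[x > 0])
  neg <- sum(abs(x[x < 0]))
  if (pos > 0) out[x > 0] <- x[x > 0] / pos
  if (neg > 0) out[x < 0] <- x[x < 0] / neg
  mpx_scores(stats::setNames(out, names(s)), attr(s, "cell_id"),
             attr(s, "marker"), "normalized")
}

#' Unit-energy standardization of normalized scores (g)
#'
#' Divides the field by its Euclidean norm `sqrt(sum x^2)` (the spread
#' about the zero center of the signed-normalized field), so the output
#' has unit sum of squares; an all-zero field maps to itself. Together
#' with the signed log this bounds every adjusted score in
#' `[-ln 2, ln 2]`.
#'
#' @param s An `mpx_scores` with `stage = "normalized"`.
#' @return An `mpx_scores` with `stage = "standardized"`.
#' @export
standardize_energy <- function(s) {
  stopifnot(inherits(s, "mpx_scores"), score_stage(s) == "normalized")
  x <- as.numeric(s)
  nrm <- sqrt(sum(x^2))
  out <- if (nrm > 0) x / nrm else x
  mpx_scores(stats::setNames(out, names(s)), attr(s, "cell_id"),
             attr(s, "marker"), "standardized")
}

#' Signed log transform (h)
#'
#' Maps each standardized value `z` to `sign(z) * log(|z| + 1)` (natural
#' log). Strictly increasing, odd, and fixing zero; because `|z| <= 1`
#' componentwise after unit-energy standardization, the output lies in
#' `[-ln 2, ln 2]`. The result is the adjusted local assortativity.
#'
#' @param s An `mpx_scores` with `stage = "standardized"`.
#' @return An `mpx_scores` with `stage = "adjusted"`.
#' @export
signed_log <- function(s) {
  stopifnot(inherits(s, "mpx_scores"), score_stage(s) == "standardized")
  x <- as.numeric(s)
  out <- sign(x) * log(abs(x) + 1)
  mpx_scores(stats::setNames(out, names(s)), attr(s, "cell_id"),
             attr(s, "marker"), "adjusted")
}

#' Per-cell isotype noise floor
#'
#' The threshold is the maximum per-cell molecule total over the panel's
#' isotype control markers; markers whose own total falls below it carry
#' too little signal over background to be scored.
#'
#' @param an An `mpx_anode`.
#' @param panel An `mpx_panel` with at least one isotype marker.
#' @return Integer threshold.
#' @export
isotype_threshold <- function(an, panel) {
  stopifnot(inherits(an, "mpx_anode"), inherits(panel, "mpx_panel"))
  iso <- isotype_markers(panel)
  if (!length(iso)) stop("panel has no isotype control markers")
  totals <- vapply(iso, function(m) {
    if (m %in% colnames(an$counts)) sum(an$counts[, m]) else 0L
  }, numeric(1))
  as.integer(max(totals))
}

#' Adjusted local assortativity of one marker in one cell
#'
#' Applies the per-cell filters, then the full adjustment pipeline
#' h(g(f(raw))). A marker is zeroed out (all-zero adjusted field) when
#' its molecule total is below the cell's isotype threshold, or when it
#' has non-zero counts on no more than `vertex_threshold` A-nodes.
#'
#' @inheritParams raw_local_assortativity
#' @param panel An `mpx_panel` (needed when the isotype filter is on).
#' @return An `mpx_scores` with `stage = "adjusted"`. The attribute
#'   `"filtered"` records the reason (`"isotype"`, `"vertex"`, or `NA`).
#' @export
adjusted_local_assortativity <- function(an, marker, cfg = assort_config(),
                                         panel = NULL, W = NULL) {
  stopifnot(inherits(an, "mpx_anode"))
  if (!marker %in% colnames(an$counts)) stop("unknown marker: ", marker)
  x <- an$counts[, marker]
  zero_field <- function(reason) {
    s <- mpx_scores(stats::setNames(numeric(length(an$nodes)), an$nodes),
                    an$cell_id, marker, "adjusted")
    attr(s, "filtered") <- reason
    s
  }
  if (cfg$isotype_filter_enabled) {
    if (is.null(panel)) stop("isotype filter enabled but no panel supplied")
    if (sum(x) < isotype_threshold(an, panel)) return(zero_field("isotype"))
  }
  if (sum(x > 0) <= cfg$vertex_threshold) return(zero_field("vertex"))
  s <- signed_log(standardize_energy(normalize_signed(
    raw_local_assortativity(an, marker, cfg, W = W))))
  attr(s, "filtered") <- NA_character_
  s
}

#' Adjusted scores for every marker of one cell
#'
#' Computes the personalized-PageRank matrix once and reuses it across
#' markers.
#'
#' @param an An `mpx_anode`.
#' @param panel An `mpx_panel`; markers absent from the cell's counts get
#'   all-zero fields.
#' @param cfg An [assort_config()].
#' @return Named list of adjusted `mpx_scores`, one per panel marker.
#' @export
score_cell <- function(an, panel, cfg = assort_config()) {
  stopifnot(inherits(an, "mpx_anode"), inherits(panel, "mpx_panel"))
  W <- ppr_matrix(an, cfg)
  out <- lapply(panel$marker, function(m) {
    if (!m %in% colnames(an$counts)) {
      s <- mpx_scores(stats::setNames(numeric(length(an$nodes)), an$nodes),
                      an$cell_id, m, "adjusted")
      attr(s, "filtered") <- "absent"
      return(s)
    }
    adjusted_local_assortativity(an, m, cfg, panel = panel, W = W)
  })
  names(out) <- panel$marker
  out
}

#' Permutation-null correction of an adjusted field
#'
#' Optional abundance-bias correction: the marker's node-count vector is
#' permuted uniformly at random across nodes `n_perm` times, the adjusted
#' field recomputed per permutation, and the per-node permutation mean
#' subtracted from the observed field. `n_perm = 0` returns the observed
#' field unchanged.
#'
#' @inheritParams adjusted_local_assortativity
#' @param n_perm Number of permutations (>= 0).
#' @param seed Integer seed; the correction is reproducible.
#' @return An `mpx_scores` (stage `"adjusted"`) of corrected values.
#' @export
permutation_null <- function(an, marker, cfg = assort_config(), panel = NULL,
                             n_perm = 100L, seed = 1L) {
  observed <- adjusted_local_assortativity(an, marker, cfg, panel = panel)
  if (n_perm == 0 || !is.na(attr(observed, "filtered"))) return(observed)
  W <- ppr_matrix(an, cfg)
  n <- length(an$nodes)
  perm_sum <- numeric(n)
  an_perm <- an
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    an_perm$counts[, marker] <- an$counts[sample.int(n), marker]
    s <- signed_log(standardize_energy(normalize_signed(
      raw_local_assortativity(an_perm, marker, cfg, W = W))))
    perm_sum <- perm_sum + as.numeric(s)
  }
  corrected <- as.numeric(observed) - perm_sum / n_perm
  out <- mpx_scores(stats::setNames(corrected, an$nodes), an$cell_id,
                    marker, "adjusted")
  attr(out, "filtered") <- attr(observed, "filtered")
  out
}
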