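test_that("personalized PageRank matches limits and the dense-solve oracle", {
  # pure-teleport limit: nearly all weight on the focal node
  g <- igraph::make_graph(~ a - b, b - c)
  an <- make_anode(g, count_matrix(c(0, 0, 0), c("a", "b", "c")))
  w <- personalized_pagerank(an, "b",
                             assort_config(restart_probability = 0.999999,
                                           weight_floor = 0))
  expect_equal(unname(w["b"]), 1, tolerance = 1e-5)

  # path graph, restart 0.5: dense linear solve
  w <- personalized_pagerank(an, "b", assort_config(restart_probability = 0.5,
                                                    weight_floor = 0))
  expect_equal(w, ppr_dense_oracle(an, "b", 0.5), tolerance = 1e-10)

  # restart 0 on a connected non-bipartite graph: degree-proportional
  g2 <- igraph::make_graph(~ a - b, b - c, c - a, c - d)
  an2 <- make_anode(g2, count_matrix(rep(0, 4), c("a", "b", "c", "d")))
  w2 <- personalized_pagerank(an2, "a", assort_config(restart_probability = 0,
                                                      weight_floor = 0))
  d <- igraph::degree(g2)
  expect_equal(w2, d / sum(d), tolerance = 1e-10, ignore_attr = TRUE)

  # random graphs against the dense oracle, with and without the floor
  set.seed(42)
  for (rep in 1:5) {
    gr <- random_connected_graph(sample(5:15, 1), 0.4)
    nn <- igraph::vcount(gr)
    anr <- make_anode(gr, count_matrix(rep(0, nn), igraph::V(gr)$name))
    focal <- sample(igraph::V(gr)$name, 1)
    for (floor_ in c(0, 0.01)) {
      cfg <- assort_config(restart_probability = 0.15, weight_floor = floor_)
      w <- personalized_pagerank(anr, focal, cfg)
      expect_equal(w, ppr_dense_oracle(anr, focal, 0.15, floor_),
                   tolerance = 1e-10)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= 0))
    }
  }

  # all focal nodes at once agree with the one-node routine
  W <- mpxassort:::ppr_matrix(an, assort_config(restart_probability = 0.3,
                                                weight_floor = 0))
  for (v in an$nodes) {
    expect_equal(W[v, ],
                 personalized_pagerank(an, v,
                                       assort_config(restart_probability = 0.3,
                                                     weight_floor = 0)),
                 tolerance = 1e-10)
  }
})

test_that("raw local assortativity has the global limit and zero-variance convention", {
  # constant attribute -> all-zero field
  g <- barbell_graph()
  an <- make_anode(g, count_matrix(rep(3, 8), igraph::V(g)$name))
  s <- raw_local_assortativity(an, "M")
  expect_true(all(as.numeric(s) == 0))

  # restart 0: every node equals the global degree-weighted assortativity
  set.seed(11)
  for (rep in 1:5) {
    gr <- random_connected_graph(sample(10:30, 1))
    nn <- igraph::vcount(gr)
    x <- sample(0:8, nn, replace = TRUE)
    anr <- make_anode(gr, count_matrix(x, igraph::V(gr)$name))
    s <- raw_local_assortativity(anr, "M",
                                 assort_config(restart_probability = 0,
                                               weight_floor = 0))
    r_global <- global_assortativity_oracle(gr, x)
    expect_equal(as.numeric(s), rep(r_global, nn), tolerance = 1e-8)
  }
})

test_that("barbell with one labelled clique scores positive inside the cliques", {
  g <- barbell_graph()
  x <- c(5, 5, 5, 5, 0, 0, 0, 0)
  an <- make_anode(g, count_matrix(x, igraph::V(g)$name))
  cfg <- assort_config(restart_probability = 0.85, weight_floor = 0)
  s <- raw_local_assortativity(an, "M", cfg)
  # interior of the labelled clique is homogeneous and high: assortative.
  # The zero clique is homogeneous too but scores negative: the covariance
  # form sees x_i * x_j = 0 below the squared edge-end mean.
  expect_true(all(as.numeric(s)[1:3] > 0))
  expect_true(all(as.numeric(s)[1:3] > as.numeric(s)[6:8]))

  # brute-force re-implementation of the same score from the dense oracle
  mom <- mpxassort:::edge_end_moments(an, x)
  d <- igraph::degree(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nb_mean <- as.numeric(A %*% x) / d
  brute <- vapply(an$nodes, function(v) {
    w <- ppr_dense_oracle(an, v, 0.85)
    (sum(w * x * nb_mean) - mom$mu^2) / mom$sigma2
  }, numeric(1))
  expect_equal(as.numeric(s), unname(brute), tolerance = 1e-9)
})

test_that("signed normalization rescales each sign block to unit mass", {
  expect_equal(as.numeric(normalize_signed(raw_field(c(2, -1, -1, 0)))),
               c(1, -0.5, -0.5, 0))
  expect_equal(as.numeric(normalize_signed(raw_field(c(0, 0, 0)))),
               c(0, 0, 0))
  expect_equal(as.numeric(normalize_signed(raw_field(c(3, 1)))),
               c(0.75, 0.25))
  # negatives only
  expect_equal(as.numeric(normalize_signed(raw_field(c(-3, -1)))),
               c(-0.75, -0.25))
})

test_that("unit-energy standardization divides by the Euclidean norm", {
  s <- normalize_signed(raw_field(c(2, -1, -1, 0)))
  z <- standardize_energy(s)
  expect_equal(as.numeric(z), c(1, -0.5, -0.5, 0) / sqrt(1.5),
               tolerance = 1e-12)
  expect_equal(sum(as.numeric(z)^2), 1, tolerance = 1e-12)
  z0 <- standardize_energy(normalize_signed(raw_field(c(0, 0))))
  expect_equal(as.numeric(z0), c(0, 0))
})

test_that("signed log is odd, monotone, and hits the ln-2 bound at unit components", {
  to_std <- function(x) mpx_scores(stats::setNames(x, paste0("v", seq_along(x))),
                                   "t", "M", "standardized")
  expect_equal(as.numeric(signed_log(to_std(c(0, 1, -1)))),
               c(0, log(2), -log(2)))
  expect_equal(as.numeric(signed_log(to_std(c(0.81650, -0.40825, -0.40825, 0)))),
               c(0.59688, -0.34237, -0.34237, 0), tolerance = 1e-4)
  # odd and strictly increasing
  z <- seq(-1, 1, by = 0.05)
  h <- as.numeric(signed_log(to_std(z)))
  expect_equal(h, -rev(h))
  expect_true(all(diff(h) > 0))
})

test_that("adjusted scores are bounded and all-zero fields are fixed points", {
  set.seed(99)
  for (rep in 1:20) {
    x <- stats::rnorm(sample(5:50, 1), sd = 10)
    out <- adjust_vector(x)
    expect_true(all(out >= -log(2) - 1e-12 & out <= log(2) + 1e-12))
  }
  expect_equal(adjust_vector(rep(0, 7)), rep(0, 7))
})

test_that("isotype threshold is the max per-cell isotype total", {
  panel <- small_panel()
  g <- barbell_graph()
  counts <- matrix(0L, 8, 6,
                   dimnames = list(igraph::V(g)$name, panel$marker))
  counts[, "mIgG1"] <- c(5L, rep(0L, 7))   # total 5
  counts[, "mIgG2a"] <- rep(1L, 8)         # total 8 (isotype max)
  counts[, "mIgG2b"] <- c(3L, 4L, rep(0L, 6))  # total 7
  an <- make_anode(g, counts)
  expect_equal(isotype_threshold(an, panel), 8L)
  counts[, c("mIgG1", "mIgG2a", "mIgG2b")] <- 0L
  expect_equal(isotype_threshold(make_anode(g, counts), panel), 0L)
  expect_error(isotype_threshold(an, mpx_panel("CD50")), "isotype")
})

test_that("filters zero out weak markers and composition matches hand-chaining", {
  panel <- small_panel()
  set.seed(4)
  cfg_sim <- synthetic_cell_config(panel, n_a_pixels = 80, n_b_pixels = 160,
                                   baseline_rate = 2, isotype_rate = 0.1)
  an <- suppressMessages(project_to_anodes(simulate_cell(cfg_sim, "c", seed = 4)))
  cfg <- assort_config()

  # marker total below the isotype threshold -> zero field
  an_low <- an
  thr <- isotype_threshold(an, panel)
  keep <- which(an_low$counts[, "CD50"] > 0)[seq_len(max(0, thr - 1))]
  an_low$counts[, "CD50"] <- 0L
  an_low$counts[keep[!is.na(keep)], "CD50"] <- 1L
  stopifnot(sum(an_low$counts[, "CD50"]) < thr)
  s <- adjusted_local_assortativity(an_low, "CD50", cfg, panel)
  expect_true(all(as.numeric(s) == 0))
  expect_equal(attr(s, "filtered"), "isotype")

  # present on exactly vertex_threshold nodes -> still zero (strictly more required)
  an_v <- an
  an_v$counts[, "CD162"] <- 0L
  an_v$counts[seq_len(10), "CD162"] <- 50L  # high total, few vertices
  s <- adjusted_local_assortativity(an_v, "CD162", cfg, panel)
  expect_true(all(as.numeric(s) == 0))
  expect_equal(attr(s, "filtered"), "vertex")
  # one more vertex passes
  an_v$counts[11, "CD162"] <- 50L
  s <- adjusted_local_assortativity(an_v, "CD162", cfg, panel)
  expect_false(all(as.numeric(s) == 0))

  # passing marker equals the hand-composed pipeline
  s <- adjusted_local_assortativity(an, "CD50", cfg, panel)
  expect_true(is.na(attr(s, "filtered")))
  byhand <- signed_log(standardize_energy(normalize_signed(
    raw_local_assortativity(an, "CD50", cfg))))
  expect_equal(as.numeric(s), as.numeric(byhand), tolerance = 1e-12)
})

test_that("permutation null is seeded, reproducible, and near-zero for uniform markers", {
  panel <- small_panel()
  cfg_sim <- synthetic_cell_config(panel, n_a_pixels = 60, n_b_pixels = 120,
                                   baseline_rate = 3)
  an <- suppressMessages(project_to_anodes(simulate_cell(cfg_sim, "c", seed = 8)))
  cfg <- assort_config()
  obs <- adjusted_local_assortativity(an, "CD50", cfg, panel)
  # disabled path returns the observed field
  expect_equal(as.numeric(permutation_null(an, "CD50", cfg, panel, n_perm = 0)),
               as.numeric(obs))
  c1 <- permutation_null(an, "CD50", cfg, panel, n_perm = 10, seed = 21)
  c2 <- permutation_null(an, "CD50", cfg, panel, n_perm = 10, seed = 21)
  expect_identical(as.numeric(c1), as.numeric(c2))
  # uniform marker: the correction is small relative to the score scale
  expect_lt(mean(abs(as.numeric(c1) - as.numeric(obs))), log(2) / 2)
})
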