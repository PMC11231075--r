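#' Configuration of a synthetic MPX cell
#'
#' Describes one simulated cell: A-pixels are placed uniformly on the
#' unit sphere (the cell surface); each B-pixel attaches to the
#' `mean_b_degree` A-pixels nearest a random anchor point, which makes
#' the A-node projection locally connected. Polarity is planted as a
#' contiguous spherical cap: the `cap_fraction` of A-pixels nearest a
#' random pole, shared by all polarized markers of the cell
#' (co-polarization). Marker molecule counts are Poisson per A-node with
#' the cap rate multiplied by `enrichment_fold` and the outside rate
#' scaled down so the expected per-cell total is independent of the
#' fold: polarization redistributes abundance, it does not inflate it.
#'
#' @param panel An `mpx_panel`.
#' @param n_a_pixels,n_b_pixels Numbers of A- and B-pixels (defaults 300
#'   and 600, a desk-scale version of MPX pixel counts).
#' @param mean_b_degree A-pixels attached per B-pixel (default 5).
#' @param baseline_rate Expected molecule count per A-node for each
#'   non-isotype marker; scalar or vector named by marker (default 1).
#' @param isotype_rate Expected count per A-node for isotype controls
#'   (default 0.05, a low uniform background).
#' @param polarized_markers Markers co-enriched on the polar cap; must be
#'   non-isotype panel markers.
#' @param cap_fraction Fraction of A-pixels in the polar cap, in (0, 1).
#' @param enrichment_fold Rate multiplier inside the cap (>= 1; 1 means
#'   no polarization).
#' @return A list of class `synthetic_cell_config`.
#' @export
synthetic_cell_config <- function(panel,
                                  n_a_pixels = 300L,
                                  n_b_pixels = 600L,
                                  mean_b_degree = 5L,
                                  baseline_rate = 1,
                                  isotype_rate = 0.05,
                                  polarized_markers = character(),
                                  cap_fraction = 0.2,
                                  enrichment_fold = 1) {
  stopifnot(inherits(panel, "mpx_panel"),
            n_a_pixels >= 10, n_b_pixels >= 1, mean_b_degree >= 1,
            cap_fraction > 0, cap_fraction < 1, enrichment_fold >= 1,
            isotype_rate >= 0)
  markers <- panel$marker
  rates <- stats::setNames(rep_len(baseline_rate, nrow(panel)), markers)
  if (!is.null(names(baseline_rate))) {
    rates[names(baseline_rate)] <- baseline_rate
  }
  rates[panel$is_isotype] <- isotype_rate
  if (any(rates < 0)) stop("rates must be non-negative")
  bad <- intersect(polarized_markers, isotype_markers(panel))
  if (length(bad)) stop("isotype controls cannot be polarized: ",
                        paste(bad, collapse = ", "))
  if (length(setdiff(polarized_markers, markers))) {
    stop("polarized markers must be in the panel")
  }
  structure(list(panel = panel,
                 n_a_pixels = as.integer(n_a_pixels),
                 n_b_pixels = as.integer(n_b_pixels),
                 mean_b_degree = as.integer(mean_b_degree),
                 rates = rates,
                 polarized_markers = polarized_markers,
                 cap_fraction = cap_fraction,
                 enrichment_fold = enrichment_fold),
            class = "synthetic_cell_config")
}

# n points uniform on the unit sphere
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  th <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Simulate one MPX cell graph
#'
#' @param cfg A [synthetic_cell_config()].
#' @param cell_id Cell identifier.
#' @param seed Integer seed; the same seed yields a byte-identical edge
#'   list.
#' @param max_retries Geometry draws producing a disconnected A-node
#'   projection are redrawn (with a derived seed) up to this many times
#'   before erroring.
#' @return An `mpx_bipartite`.
#' @export
simulate_cell <- function(cfg, cell_id = "cell_1", seed = 1L,
                          max_retries = 10L) {
  stopifnot(inherits(cfg, "synthetic_cell_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  for (try_ in 0:max_retries) {
    set.seed((as.integer(seed) + 7919L * try_) %% .Machine$integer.max)
    g <- simulate_cell_once(cfg, cell_id)
    an <- suppressMessages(project_to_anodes(g, largest_component = FALSE))
    if (!length(an$nodes)) next
    comp <- igraph::components(an$graph)
    # a handful of straggler pixels with too few molecules to link up is
    # normal; trim to the largest component as MPX preprocessing does,
    # but redraw if it covers less than 80% of the molecule-bearing pixels
    if (max(comp$csize) >= 0.8 * length(an$nodes)) {
      keep <- an$nodes[comp$membership == which.max(comp$csize)]
      edges <- g$edges[g$edges$upia %in% keep, , drop = FALSE]
      return(mpx_bipartite(cell_id, edges, panel = cfg$panel))
    }
  }
  stop(sprintf("could not draw a connected projection for cell %s in %d tries",
               cell_id, max_retries + 1))
}

simulate_cell_once <- function(cfg, cell_id) {
  n_a <- cfg$n_a_pixels
  pts <- runif_sphere(n_a)
  a_ids <- sprintf("%s_A%04d", cell_id, seq_len(n_a))

  # B-pixels: each picks a random anchor and bonds the mean_b_degree
  # nearest A-pixels, giving shared-B cliques that tile the surface
  anchors <- runif_sphere(cfg$n_b_pixels)
  k <- min(cfg$mean_b_degree, n_a)
  incid <- lapply(seq_len(cfg$n_b_pixels), function(b) {
    d2 <- colSums((t(pts) - anchors[b, ])^2)
    order(d2)[seq_len(k)]
  })
  # incident B-pixels per A-pixel
  b_of_a <- vector("list", n_a)
  for (b in seq_along(incid)) {
    for (v in incid[[b]]) b_of_a[[v]] <- c(b_of_a[[v]], b)
  }
  covered <- which(lengths(b_of_a) > 0)

  # polar cap shared by all polarized markers
  pole <- runif_sphere(1)
  n_cap <- max(1L, round(cfg$cap_fraction * n_a))
  d2pole <- colSums((t(pts) - pole[1, ])^2)
  in_cap <- seq_len(n_a) %in% order(d2pole)[seq_len(n_cap)]

  markers <- names(cfg$rates)
  f <- cfg$enrichment_fold
  # conserve the expected total: scale so n*lambda is fold-invariant
  c_scale <- n_a / (n_a + (f - 1) * n_cap)
  uncovered <- setdiff(seq_len(n_a), covered)
  flat_b <- unlist(b_of_a)
  off <- cumsum(c(0L, lengths(b_of_a)))
  lens <- lengths(b_of_a)
  rows <- vector("list", length(markers))
  for (mi in seq_along(markers)) {
    m <- markers[mi]
    lam <- rep(cfg$rates[[m]], n_a)
    if (m %in% cfg$polarized_markers && f > 1) {
      lam <- cfg$rates[[m]] * c_scale * ifelse(in_cap, f, 1)
    }
    cnt <- stats::rpois(n_a, lam)
    if (length(uncovered)) cnt[uncovered] <- 0L
    v_idx <- rep.int(seq_len(n_a), cnt)
    if (!length(v_idx)) next
    # each molecule lands on a uniformly random incident B-pixel
    pick <- ceiling(stats::runif(length(v_idx)) * lens[v_idx])
    b_idx <- flat_b[off[v_idx] + pick]
    key <- v_idx * (cfg$n_b_pixels + 1) + b_idx
    tb <- table(key)
    kk <- as.numeric(names(tb))
    rows[[mi]] <- data.frame(
      upia = a_ids[kk %/% (cfg$n_b_pixels + 1)],
      upib = sprintf("%s_B%04d", cell_id, kk %% (cfg$n_b_pixels + 1)),
      marker = m,
      count = as.integer(tb))
  }
  edges <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(edges)) {
    edges <- data.frame(upia = character(), upib = character(),
                        marker = character(), count = integer())
  }
  mpx_bipartite(cell_id, edges, panel = cfg$panel)
}

#' Simulate a population of cells
#'
#' Cells are independent draws with per-cell seeds derived from the
#' master seed, so populations are reproducible and individual cells can
#' be regenerated in isolation.
#'
#' @param cfg A [synthetic_cell_config()].
#' @param n_cells Number of cells (>= 1).
#' @param condition Condition label propagated to the sample sheet.
#' @param seed Master integer seed.
#' @return A named list of `mpx_bipartite`; the attribute
#'   `"sample_sheet"` is a data.frame (cell_id, condition, seed).
#' @export
simulate_population <- function(cfg, n_cells, condition = "control",
                                seed = 1L) {
  stopifnot(n_cells >= 1)
  seeds <- (as.integer(seed) + 1000003L * seq_len(n_cells)) %%
    .Machine$integer.max
  ids <- sprintf("%s_%03d", condition, seq_len(n_cells))
  cells <- lapply(seq_len(n_cells), function(i) {
    simulate_cell(cfg, cell_id = ids[i], seed = seeds[i])
  })
  names(cells) <- ids
  attr(cells, "sample_sheet") <- data.frame(cell_id = ids,
                                            condition = condition,
                                            seed = seeds)
  cells
}
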