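#' @title File-based analysis pipeline
#' @description Each stage reads and writes plain delimited tables so the
#'   stages are independently runnable and testable: `run_simulate` writes
#'   an edge list, panel, and sample sheet; `run_score` turns edge lists
#'   into per-node adjusted-score tables; `run_coloc` turns score tables
#'   into pairwise / higher-order colocalization tables; `run_diff`
#'   contrasts two conditions. Every output carries a provenance header
#'   line `# mpxassort config <md5>` hashing the stage configuration.
#' @name pipeline
NULL

config_hash <- function(...) {
  dump <- paste(utils::capture.output(utils::str(list(...))), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(dump, f)
  unname(tools::md5sum(f))
}

write_stage_table <- function(tab, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mpxassort config %s", hash), con)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(tab, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a labelled synthetic dataset to disk
#'
#' @param cfg A [synthetic_cell_config()].
#' @param n_cells Cells per condition.
#' @param conditions Named list: condition label -> list of config
#'   overrides (e.g. `list(stimulated = list(enrichment_fold = 8))`).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Paths of the written files (edge list, panel, sample sheet).
#' @export
run_simulate <- function(cfg, n_cells, conditions = list(control = list()),
                         out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg, n_cells, conditions, seed)
  all_cells <- list()
  sheets <- list()
  for (i in seq_along(conditions)) {
    cond <- names(conditions)[i]
    cfg_i <- utils::modifyList(cfg, conditions[[i]])
    class(cfg_i) <- class(cfg)
    pop <- simulate_population(cfg_i, n_cells, condition = cond,
                               seed = (as.integer(seed) + 17L * i) %%
                                 .Machine$integer.max)
    all_cells <- c(all_cells, pop)
    sheets[[i]] <- attr(pop, "sample_sheet")
  }
  edge_path <- file.path(out_dir, "edges.csv")
  write_cell_edge_list(all_cells, edge_path)
  panel_path <- file.path(out_dir, "panel.csv")
  write_delimited(as.data.frame(cfg$panel), panel_path)
  sheet_path <- file.path(out_dir, "samples.csv")
  write_stage_table(do.call(rbind, sheets), sheet_path, hash)
  invisible(c(edges = edge_path, panel = panel_path, samples = sheet_path))
}

#' Score all cells of an edge list
#'
#' Reads the cells, projects each to its largest-component A-node graph,
#' applies the isotype and vertex filters, and writes the adjusted
#' per-node scores as a long table (cell_id, marker, node_id,
#' adjusted_score). Filter outcomes are logged via `message()`.
#'
#' @param edge_path,panel_path Input files.
#' @param out_path Output score table path.
#' @param cfg An [assort_config()].
#' @return The output path, invisibly.
#' @export
run_score <- function(edge_path, panel_path, out_path,
                      cfg = assort_config()) {
  panel <- read_panel(panel_path)
  cells <- read_cell_edge_list(edge_path, panel)
  hash <- config_hash(cfg)
  tabs <- lapply(cells, function(g) {
    an <- project_to_anodes(g)
    scores <- score_cell(an, panel, cfg)
    for (m in names(scores)) {
      why <- attr(scores[[m]], "filtered")
      if (!is.na(why)) {
        message(sprintf("cell %s: marker %s zeroed (%s filter)",
                        g$cell_id, m, why))
      }
    }
    do.call(rbind, lapply(names(scores), function(m) {
      data.frame(cell_id = g$cell_id, marker = m,
                 node_id = names(scores[[m]]),
                 adjusted_score = as.numeric(scores[[m]]))
    }))
  })
  write_stage_table(do.call(rbind, tabs), out_path, hash)
  invisible(out_path)
}

# Rebuild per-cell mpx_scores lists from a long score table
read_score_table <- function(path) {
  tab <- read_delimited(path, required = c("cell_id", "marker", "node_id",
                                           "adjusted_score"))
  lapply(split(tab, tab$cell_id), function(ct) {
    fields <- lapply(split(ct, ct$marker), function(mt) {
      mpx_scores(stats::setNames(mt$adjusted_score, mt$node_id),
                 mt$cell_id[1], mt$marker[1], "adjusted")
    })
    fields
  })
}

#' Colocalization tables from a score table
#'
#' @param score_path Score table written by [run_score()].
#' @param out_path Output path for the long colocalization table
#'   (cell_id, markers, order, score).
#' @param markers Marker subset for pairwise analysis (default: all).
#' @param tuples Optional list of character vectors (k >= 3) for
#'   higher-order colocalization.
#' @return The output path, invisibly.
#' @export
run_coloc <- function(score_path, out_path, markers = NULL, tuples = list()) {
  per_cell <- read_score_table(score_path)
  hash <- config_hash(markers, tuples)
  tabs <- lapply(per_cell, function(fields) {
    ms <- if (is.null(markers)) names(fields) else markers
    pw <- colocalization_matrix(fields, ms)
    pw <- data.frame(cell_id = pw$cell_id,
                     markers = paste(pw$marker_1, pw$marker_2, sep = "+"),
                     order = pw$order, score = pw$score)
    ho <- do.call(rbind, lapply(tuples, function(tp) {
      higher_order_colocalization(fields, tp)
    }))
    rbind(pw, ho)
  })
  write_stage_table(do.call(rbind, tabs), out_path, hash)
  invisible(out_path)
}

#' Differential colocalization between two conditions
#'
#' @param coloc_path Colocalization table from [run_coloc()].
#' @param sheet_path Sample sheet (cell_id, condition).
#' @param out_path Output path for the differential table.
#' @param condition_a,condition_b Condition labels to contrast
#'   (`mean_a - mean_b`).
#' @return The output path, invisibly.
#' @export
run_diff <- function(coloc_path, sheet_path, out_path,
                     condition_a, condition_b) {
  coloc <- read_delimited(coloc_path, required = c("cell_id", "markers",
                                                   "order", "score"))
  sheet <- read_delimited(sheet_path, required = c("cell_id", "condition"))
  if (!all(c(condition_a, condition_b) %in% sheet$condition)) {
    stop("contrast references unknown condition label(s)")
  }
  hash <- config_hash(condition_a, condition_b)
  res <- lapply(split(coloc, coloc$markers), function(mt) {
    a <- mt$score[sheet$condition[match(mt$cell_id, sheet$cell_id)] == condition_a]
    b <- mt$score[sheet$condition[match(mt$cell_id, sheet$cell_id)] == condition_b]
    if (length(a) < 2 || length(b) < 2) {
      stop("contrast needs at least 2 cells per arm for ", mt$markers[1])
    }
    differential_colocalization(a, b, mt$markers[1])
  })
  write_stage_table(do.call(rbind, res), out_path, hash)
  invisible(out_path)
}
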