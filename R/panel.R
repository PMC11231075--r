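#' Construct an antibody panel manifest
#'
#' The panel names every marker that may appear in an edge list and flags
#' which markers are isotype controls. Isotype controls carry no specific
#' epitope; their per-cell molecule totals set the noise floor used by
#' [isotype_threshold()].
#'
#' @param markers Character vector of unique marker names.
#' @param isotype_markers Character vector, subset of `markers`, naming the
#'   isotype controls. May be empty only when isotype filtering is disabled
#'   downstream.
#' @return An object of class `mpx_panel`: a data.frame with columns
#'   `marker` and `is_isotype`.
#' @examples
#' mpx_panel(c("CD50", "CD162", "mIgG1"), isotype_markers = "mIgG1")
#' @export
mpx_panel <- function(markers, isotype_markers = character()) {
  markers <- as.character(markers)
  isotype_markers <- as.character(isotype_markers)
  if (anyDuplicated(markers)) {
    stop("panel marker names must be unique; duplicated: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  missing <- setdiff(isotype_markers, markers)
  if (length(missing)) {
    stop("isotype markers not present in panel: ",
         paste(missing, collapse = ", "))
  }
  panel <- data.frame(marker = markers,
                      is_isotype = markers %in% isotype_markers,
                      stringsAsFactors = FALSE)
  class(panel) <- c("mpx_panel", "data.frame")
  panel
}

#' Read a panel manifest from a delimited file
#'
#' Expects a header with columns `marker` and `is_isotype` (logical or
#' `"true"`/`"false"`). The delimiter is inferred from the file extension
#' (`.csv` comma, `.tsv` tab).
#'
#' @param path Path to the manifest file.
#' @return An `mpx_panel`.
#' @export
read_panel <- function(path) {
  tab <- read_delimited(path, required = c("marker", "is_isotype"))
  iso <- tolower(trimws(as.character(tab$is_isotype)))
  if (!all(iso %in% c("true", "false", "t", "f", "1", "0"))) {
    stop("column 'is_isotype' must be logical (true/false)")
  }
  mpx_panel(tab$marker,
            isotype_markers = tab$marker[iso %in% c("true", "t", "1")])
}

#' @export
print.mpx_panel <- function(x, ...) {
  cat(sprintf("<mpx_panel> %d markers (%d isotype controls)\n",
              nrow(x), sum(x$is_isotype)))
  invisible(x)
}

#' @rdname mpx_panel
#' @param panel An `mpx_panel`.
#' @export
isotype_markers <- function(panel) {
  stopifnot(inherits(panel, "mpx_panel"))
  panel$marker[panel$is_isotype]
}

# Delimiter from extension; comma unless the file is .tsv/.txt (tab).
read_delimited <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  tab
}

write_delimited <- function(tab, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
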