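#' Read a probe-by-sample counts table
#'
#' Reads a counts table exported by a targeted-panel instrument or saved as a
#' plain delimited file. Two dialects are supported:
#'
#' * `"delimited"`: the first row is a header (`probe id column`, then one
#'   column per sample) and every following row is a probe with its counts.
#' * `"instrument"`: zero or more free-form metadata rows precede the counts
#'   block; rows are skipped until the first row whose first cell equals
#'   `sentinel` (default `"Sample Name"`), which is taken as the header row.
#'
#' `"auto"` tries the delimited layout first and falls back to the instrument
#' layout when the first cell of the file matches `sentinel` or the header
#' row cannot be interpreted as `probe id + samples`.
#'
#' Files ending in `.xlsx`/`.xls` are read from the first sheet; `.csv` uses a
#' comma, anything else a tab separator.
#'
#' Counts must be non-negative integers (numerics within `1e-9` of an integer
#' are accepted and rounded); probe and sample identifiers must be unique.
#' Row and column order are preserved exactly as in the file.
#'
#' @param path Path to the counts file.
#' @param dialect One of `"auto"`, `"delimited"`, `"instrument"`.
#' @param sentinel First cell of the header row in the instrument dialect.
#'
#' @return A tibble: first column `probe_id`, one numeric column per sample.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("probe_id,S1,S2", "GENE1,1,2", "GENE2,3,4"), f)
#' read_counts(f)
#' @export
read_counts <- function(path, dialect = c("auto", "delimited", "instrument"),
                        sentinel = "Sample Name") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("Counts file not found: %s", path))
  cells <- read_cells(path)
  if (nrow(cells) < 2L || ncol(cells) < 2L) {
    abort(sprintf("File '%s' does not contain a counts block (need a header row plus probe rows).", path))
  }
  header_row <- 1L
  if (dialect == "instrument") {
    header_row <- find_sentinel_row(cells, sentinel, path)
  } else if (dialect == "auto" && !is_counts_header(cells, 1L)) {
    # not an obvious delimited layout: look for the instrument sentinel, but
    # fall back to row 1 so malformed delimited files get a specific error
    header_row <- tryCatch(find_sentinel_row(cells, sentinel, path),
                           error = function(e) 1L)
  }
  block <- cells[header_row:nrow(cells), , drop = FALSE]
  # drop all-empty trailing columns some spreadsheet exports carry
  keep <- colSums(!is.na(block) & block != "") > 0
  block <- block[, keep, drop = FALSE]
  sample_ids <- as.character(block[1L, -1L])
  probe_ids <- as.character(block[-1L, 1L])
  raw <- block[-1L, -1L, drop = FALSE]
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    abort(sprintf("Non-numeric count '%s' for probe '%s', sample '%s' in %s.",
                  raw[bad[[1L]], bad[[2L]]], probe_ids[bad[[1L]]],
                  sample_ids[bad[[2L]]], path))
  }
  rownames(num) <- probe_ids
  colnames(num) <- sample_ids
  counts <- matrix_to_counts_tbl(coerce_integer_counts(num))
  counts_tbl_to_matrix(counts)  # validates uniqueness / non-negativity
  counts
}

# Read any supported file into a character cell matrix (no header handling).
read_cells <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    df <- readxl::read_excel(path, col_names = FALSE, col_types = "text",
                             .name_repair = "minimal")
    m <- as.matrix(df)
  } else {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    # rows may be ragged (metadata lines before the counts block), so the
    # column count must come from the widest row, not the first
    nf <- max(utils::count.fields(path, sep = delim, quote = "\""), na.rm = TRUE)
    df <- utils::read.table(path, sep = delim, quote = "\"", header = FALSE,
                            colClasses = "character", fill = TRUE,
                            col.names = paste0("V", seq_len(nf)),
                            comment.char = "", stringsAsFactors = FALSE)
    m <- as.matrix(df)
    m[m == ""] <- NA_character_
  }
  if (length(m) == 0L) abort(sprintf("File '%s' is empty.", path))
  m
}

is_counts_header <- function(cells, row) {
  if (nrow(cells) <= row) return(FALSE)
  body_first <- cells[(row + 1L):nrow(cells), -1L, drop = FALSE][1L, ]
  vals <- suppressWarnings(as.numeric(body_first))
  # header row itself must not be numeric and the row below it must be
  header_vals <- suppressWarnings(as.numeric(cells[row, -1L]))
  all(!is.na(vals)) && all(is.na(header_vals))
}

find_sentinel_row <- function(cells, sentinel, path) {
  first_col <- trimws(ifelse(is.na(cells[, 1L]), "", cells[, 1L]))
  hit <- which(tolower(first_col) == tolower(sentinel))
  if (length(hit) == 0L) {
    # fall back: first row followed only by numeric rows
    for (r in seq_len(nrow(cells) - 1L)) {
      if (is_counts_header(cells, r) &&
          all(apply(cells[(r + 1L):nrow(cells), -1L, drop = FALSE], 1L,
                    function(x) !anyNA(suppressWarnings(as.numeric(x)))))) {
        return(r)
      }
    }
    abort(sprintf(
      "Counts block not found in '%s': no row starts with sentinel '%s' and no header/numeric block was detected.",
      path, sentinel))
  }
  hit[[1L]]
}

#' Read a sample annotation table
#'
#' A delimited (or xlsx) file whose first column is the sample identifier and
#' whose remaining columns are categorical labels (e.g. treatment group) used
#' to colour the PCA and annotate the heatmap.
#'
#' @param path Path to the annotation file (header row required).
#' @return A tibble with first column `sample_id` and character label columns.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  cells <- read_cells(path)
  if (nrow(cells) < 2L) abort(sprintf("Annotation file '%s' has no data rows.", path))
  out <- as_tibble(as.data.frame(cells[-1L, , drop = FALSE],
                                 stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  colnames(out) <- as.character(cells[1L, ])
  colnames(out)[1L] <- "sample_id"
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.character))
  if (anyDuplicated(out$sample_id)) {
    dup <- unique(out$sample_id[duplicated(out$sample_id)])
    abort(sprintf("Duplicated sample id(s) in annotation: %s",
                  paste(dup, collapse = ", ")))
  }
  out
}

#' Write the cleaned (control-free) counts matrix
#'
#' Writes the counts table with all control probes removed, ready for
#' downstream analyses. The file round-trips through [read_counts()] to the
#' identical control-free matrix.
#'
#' @param counts Counts tibble (see [read_counts()]).
#' @param controls A [control_spec()] naming the probes to drop.
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_clean_counts <- function(counts, controls, path) {
  m <- counts_tbl_to_matrix(counts)
  controls <- validate_controls(controls, rownames(m))
  keep <- setdiff(rownames(m), c(controls$positive_ids, controls$negative_ids))
  if (length(keep) == 0L) {
    abort("Nothing to export: every probe is a control probe.")
  }
  out <- dplyr::filter(counts, counts[[1L]] %in% keep)
  write_table(out, path)
  invisible(path)
}

write_table <- function(df, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}
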