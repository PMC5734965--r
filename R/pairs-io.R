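#' Read a name-pair table
#'
#' Reads a CSV or TSV table of drug-name pairs: one row per (local
#' proprietary name, look-alike overseas name) pair, optionally annotated
#' with generic names, a previously printed match value, and a printed risk
#' rating. This is the dialect written by [write_pairs()] and shipped as the
#' packaged registry fixture (see [gotr_pairs()]).
#'
#' @param path File path.
#' @param dialect `"auto"` (sniff the delimiter from the header line),
#'   `"csv"` or `"tsv"`. UTF-8 only.
#' @return A tibble with columns `row_id` (int), `generic_name`,
#'   `local_proprietary`, `overseas_similar`, `overseas_generic` (chr),
#'   `match_percent` (dbl, NA when the cell is blank), `risk` (chr, possibly
#'   NA). Missing optional columns are created; `row_id` defaults to the row
#'   number.
#' @export
read_pairs <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Pair table not found: %s", path))
  }
  if (dialect == "auto") {
    head_lines <- readLines(path, n = 20L, encoding = "UTF-8")
    head_lines <- head_lines[!startsWith(head_lines, "#")]
    if (length(head_lines) == 0L) {
      abort(sprintf("Pair table %s has no header line.", path))
    }
    dialect <- if (grepl("\t", head_lines[1L])) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  # '#' lines are config-echo headers written by the command-line front end
  raw <- reader(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE, show_col_types = FALSE
  )
  required <- c("local_proprietary", "overseas_similar")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "Pair table %s lacks required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("generic_name", "overseas_generic", "risk")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  n <- nrow(raw)
  row_id <- if ("row_id" %in% names(raw)) {
    ids <- suppressWarnings(as.integer(raw$row_id))
    if (anyNA(ids)) {
      abort(sprintf(
        "Unparseable row_id at data row(s): %s",
        paste(which(is.na(ids)), collapse = ", ")
      ))
    }
    if (anyDuplicated(ids)) {
      abort(sprintf(
        "Duplicate row_id value(s): %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")
      ))
    }
    ids
  } else {
    seq_len(n)
  }
  mp <- rep(NA_real_, n)
  if ("match_percent" %in% names(raw)) {
    cell <- trimws(raw$match_percent)
    has <- !is.na(cell) & nzchar(cell)
    val <- suppressWarnings(as.numeric(cell[has]))
    if (anyNA(val)) {
      abort(sprintf(
        "Unparseable match_percent at data row(s): %s",
        paste(which(has)[is.na(val)], collapse = ", ")
      ))
    }
    if (any(val < 0 | val > 100)) {
      abort(sprintf(
        "match_percent outside [0, 100] at data row(s): %s",
        paste(which(has)[val < 0 | val > 100], collapse = ", ")
      ))
    }
    mp[has] <- val
  }
  blank_name <- !nzchar(trimws(ifelse(is.na(raw$local_proprietary), "", raw$local_proprietary))) |
    !nzchar(trimws(ifelse(is.na(raw$overseas_similar), "", raw$overseas_similar)))
  if (any(blank_name)) {
    abort(sprintf(
      "Empty name(s) at data row(s): %s",
      paste(which(blank_name), collapse = ", ")
    ))
  }
  tibble(
    row_id = row_id,
    generic_name = raw$generic_name,
    local_proprietary = raw$local_proprietary,
    overseas_similar = raw$overseas_similar,
    overseas_generic = raw$overseas_generic,
    match_percent = mp,
    risk = raw$risk
  )
}

#' Write a name-pair table
#'
#' Writes the CSV/TSV dialect read back by [read_pairs()]; missing match
#' values round-trip as blank cells.
#'
#' @param data Data frame of pairs (any columns; the standard ones first).
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(data, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(data))
  if (dialect == "tsv") {
    readr::write_tsv(data, path, na = "", progress = FALSE)
  } else {
    readr::write_csv(data, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Read a formulary list
#'
#' One name per line; blank lines and `#` comments (whole-line or trailing)
#' are ignored.
#'
#' @param path File path.
#' @return Character vector of names as written (not canonicalized).
#' @export
read_formulary <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Formulary not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' The packaged 100-pair GOTR look-alike table
#'
#' One hundred drug proprietary names approved by the Iranian General Office
#' of Trademarks Registry (GOTR, the registry that approved drug trade names
#' 2010-2014), each paired with an overseas look-alike name with a different
#' indication, together with the match value and risk rating printed in the
#' published audit of that registry. Row 1 (AXAR/RAXAR) carries no printed
#' match value and its `match_percent` is NA; the other 99 rows are valued.
#' Printed ratings are 92 High and 8 Medium. Names are stored exactly as
#' printed (trademark glyphs, hyphens); canonical forms are added so the
#' transcription is auditable.
#'
#' @return A tibble of 100 rows: the [read_pairs()] columns plus
#'   `local_canonical` and `overseas_canonical`.
#' @examples
#' gotr_pairs()
#' @export
gotr_pairs <- function() {
  path <- system.file("extdata", "gotr_pairs.csv", package = "lasamatch", mustWork = TRUE)
  out <- read_pairs(path, dialect = "csv")
  out$local_canonical <- canonicalize(out$local_proprietary)
  out$overseas_canonical <- canonicalize(out$overseas_similar)
  out
}
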