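#' Score every pair in a name-pair table
#'
#' The main verb of the package: takes a pair table (as from [read_pairs()],
#' [gotr_pairs()] or [generate_cohort()]), computes the spatial-coding match
#' value of each pair under one convention, and returns the table with
#' computed columns appended. Rows whose names cannot be canonicalized are an
#' error naming the row.
#'
#' @param data Data frame with the two name columns.
#' @param params A [match_params()] convention bundle.
#' @param name_cols Length-2 character vector naming the columns holding the
#'   first (stored-word by default) and second name of each pair.
#' @return `data` with columns `percent` (computed match percentage), `band`
#'   (ordered risk factor) and `convention` (fingerprint string) appended.
#' @examples
#' score_pairs(gotr_pairs()[1:5, ])
#' @export
score_pairs <- function(data, params = match_params(),
                        name_cols = c("local_proprietary", "overseas_similar")) {
  stopifnot(is.data.frame(data), length(name_cols) == 2L)
  if (nrow(data) == 0L) {
    abort("Pair table is empty; nothing to score.")
  }
  missing_cols <- setdiff(name_cols, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Name column(s) not found: %s", paste(missing_cols, collapse = ", ")))
  }
  a <- as.character(data[[name_cols[1L]]])
  b <- as.character(data[[name_cols[2L]]])
  pct <- match_percent(a, b, params)
  out <- as_tibble(data)
  out$percent <- pct
  out$band <- classify_risk(pct)
  out$convention <- params_fingerprint(params)
  out
}

#' Screen a candidate name against a formulary
#'
#' Scores a proposed proprietary name against every name on a formulary and
#' ranks the matches, the screening step a naming authority would apply
#' before approving a new trade name. Sorting is by match percentage
#' descending, ties broken lexicographically on the formulary name.
#'
#' @param candidate The proposed name (label; canonicalized internally).
#' @param formulary Character vector of formulary names, or a data frame
#'   with a `name` column (as from [read_formulary()]).
#' @param top_k Number of rows to return; values beyond the formulary size
#'   return the full ranking. Default `Inf` (full ranking).
#' @param params A [match_params()] convention bundle. The candidate plays
#'   the role `params$word_role` assigns to the first name.
#' @return Tibble: `rank`, `formulary_name`, `percent`, `band`,
#'   `convention`.
#' @examples
#' screen_name("LOPRAX", c("LOPROX", "AXAR"))
#' @export
screen_name <- function(candidate, formulary, top_k = Inf, params = match_params()) {
  if (is.data.frame(formulary)) {
    if (!"name" %in% names(formulary)) {
      abort("A formulary data frame needs a `name` column.")
    }
    formulary <- as.character(formulary$name)
  }
  formulary <- formulary[!is.na(formulary) & nzchar(trimws(formulary))]
  if (length(formulary) == 0L) {
    abort("Formulary is empty.")
  }
  if (!is.numeric(top_k) || length(top_k) != 1L || is.na(top_k) || top_k < 1) {
    abort("`top_k` must be a single number >= 1.")
  }
  cand <- canonicalize(candidate)
  pct <- match_percent(rep(cand, length(formulary)), formulary, params)
  out <- tibble(
    formulary_name = formulary,
    percent = pct,
    band = classify_risk(pct)
  )
  out <- arrange(out, desc(.data$percent), .data$formulary_name)
  out <- mutate(out, rank = row_number(), convention = params_fingerprint(params))
  k <- min(nrow(out), top_k)
  select(
    out[seq_len(k), ],
    "rank", "formulary_name", "percent", "band", "convention"
  )
}
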