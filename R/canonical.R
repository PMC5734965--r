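#' Reduce a drug-name label to its canonical letter sequence
#'
#' Proprietary-name labels as found on formularies and registry tables carry
#' trademark glyphs, hyphens, digits and mixed case ("OVUSTOP-H®",
#' "Depo-Gestrone"). The match-value computation operates on letter nodes
#' only, so a label is canonicalized by upper-casing and dropping every
#' character outside A-Z.
#'
#' @param raw_label Character vector of labels as supplied.
#' @return Character vector of canonical names (uppercase A-Z only).
#'   A label with no letters at all is an error naming the offending label.
#' @examples
#' canonicalize(c("TINYPHEN®", "Ary-Tac®", "OVUSTOP-H®"))
#' @export
canonicalize <- function(raw_label) {
  if (length(raw_label) == 0L) {
    abort("`raw_label` must contain at least one label.")
  }
  if (!is.character(raw_label) || anyNA(raw_label)) {
    abort("`raw_label` must be a character vector without NA.")
  }
  out <- gsub("[^A-Z]", "", toupper(raw_label))
  bad <- !nzchar(out)
  if (any(bad)) {
    abort(sprintf(
      "Label%s with no A-Z letters cannot be canonicalized: %s",
      if (sum(bad) > 1L) "s" else "",
      paste0('"', raw_label[bad], '"', collapse = ", ")
    ))
  }
  out
}

#' Construct a canonical name with letter-occurrence tokens
#'
#' A canonical name is an ordered sequence of letter tokens. Each token
#' carries its letter and a 1-based occurrence index (the k-th appearance of
#' the letter so far), so that repeated letters form distinct comparison
#' channels: the two A's of "FARALEX" are the tokens (A,1) and (A,2).
#'
#' @param raw_label A single label (any decoration; canonicalized internally).
#' @return An object of class `lasa_name`: list with `raw_label`, `canonical`,
#'   `letters` (character vector), `occurrence` (integer vector) and `length`.
#' @examples
#' canonical_name("FARALEX®")
#' @export
canonical_name <- function(raw_label) {
  if (length(raw_label) != 1L) {
    abort("`canonical_name()` takes a single label; see `canonicalize()` for vectors.")
  }
  canon <- canonicalize(raw_label)
  letters_vec <- strsplit(canon, "", fixed = TRUE)[[1]]
  occ <- occurrence_index(letters_vec)
  structure(
    list(
      raw_label = raw_label,
      canonical = canon,
      letters = letters_vec,
      occurrence = occ,
      length = length(letters_vec)
    ),
    class = "lasa_name"
  )
}

# k for the k-th appearance of each letter, in reading order
occurrence_index <- function(letters_vec) {
  as.integer(stats::ave(seq_along(letters_vec), letters_vec, FUN = seq_along))
}

#' @export
print.lasa_name <- function(x, ...) {
  cat("<lasa_name> ", x$canonical, " (", x$length, " letters",
    if (!identical(x$raw_label, x$canonical)) paste0(', from "', x$raw_label, '"'),
    ")\n",
    sep = ""
  )
  invisible(x)
}

# Accept either a lasa_name or a raw label wherever a name is expected
as_lasa_name <- function(x) {
  if (inherits(x, "lasa_name")) x else canonical_name(x)
}
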