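# Sequence and substitution-table input/output.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (one or more sequences).
#' @return Tibble with columns `id` (first word of the header) and
#'   `residues`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    id = vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1),
    residues = unname(as.character(aa))
  )
}

#' Write protein sequences to FASTA
#'
#' @param protein Tibble with columns `id` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(protein, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(protein$residues, protein$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Parse a compact substitution string
#'
#' Turns strings like `"E334V"` into their components.
#'
#' @param x Character vector of `<ref><position><alt>` strings.
#' @return Tibble with columns `ref`, `position`, `alt`.
#' @examples
#' parse_aas(c("E334V", "T392I"))
#' @export
parse_aas <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))
  bad <- lengths(m) != 4
  if (any(bad)) {
    stop("cannot parse substitution string(s): ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    ref = vapply(m, `[`, character(1), 2),
    position = as.integer(vapply(m, `[`, character(1), 3)),
    alt = vapply(m, `[`, character(1), 4)
  )
}

#' Read a substitution table
#'
#' Reads a TSV/CSV of amino-acid substitutions with columns `protein_id`,
#' `position`, `ref`, `alt` (or a single compact `aas` column like
#' `"E334V"`), plus one label column per endpoint with values 1/0,
#' resistant/nonresistant, or TRUE/FALSE.
#'
#' @param path File path; the delimiter is chosen from the extension
#'   (`.csv` is comma-separated, anything else tab-separated).
#' @return Tibble of substitution records.
#' @export
read_substitutions <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  x <- reader(path, show_col_types = FALSE, progress = FALSE)
  if ("aas" %in% names(x) && !all(c("position", "ref", "alt") %in% names(x))) {
    parsed <- parse_aas(x$aas)
    x <- dplyr::bind_cols(dplyr::select(x, -"aas"), parsed)
  }
  need <- setdiff(c("position", "ref", "alt"), names(x))
  if (length(need) > 0) {
    stop("substitution table ", path, " lacks column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x$position <- as.integer(x$position)
  x
}

#' Write a substitution table
#'
#' @param records Tibble of substitution records.
#' @param path Output path (`.csv` writes comma-separated, else TSV).
#' @return `path`, invisibly.
#' @export
write_substitutions <- function(records, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(records, path)
  } else {
    readr::write_tsv(records, path)
  }
  invisible(path)
}
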