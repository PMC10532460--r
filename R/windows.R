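# Substitution-centered peptide windows.

#' Extract one mutant peptide window
#'
#' Cuts a window of nominal odd `length` out of the protein, centered on
#' the substituted position, and applies the alternate residue at the
#' center. Near a terminus the window is truncated asymmetrically (never
#' padded), and `center_offset` keeps pointing at the substituted residue.
#'
#' @param sequence Protein sequence as a one-letter string.
#' @param position 1-based substitution position.
#' @param ref Reference residue expected at `position` (checked).
#' @param alt Alternate residue (must differ from `ref`).
#' @param length Nominal window length: odd, between 3 and 31.
#' @return A list with `window` (mutant string), `center_offset` (0-based
#'   index of the substituted residue) and `actual_length`.
#' @examples
#' extract_window("ACDEFGHIKLM", 6, "G", "W", 5)  # "EFWHI", offset 2
#' @export
extract_window <- function(sequence, position, ref, alt, length) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  .check_window_length(length)
  n <- nchar(sequence)
  position <- as.integer(position)
  if (is.na(position) || position < 1 || position > n) {
    stop("substitution position ", position, " out of range 1..", n,
         call. = FALSE)
  }
  at <- substr(sequence, position, position)
  if (!identical(at, ref)) {
    stop("reference mismatch at position ", position, ": sequence has '",
         at, "', record says '", ref, "'", call. = FALSE)
  }
  if (identical(ref, alt)) {
    stop("ref and alt are identical at position ", position, call. = FALSE)
  }
  if (!alt %in% AA_CODES) {
    stop("nonstandard alternate residue '", alt, "' at position ", position,
         call. = FALSE)
  }
  flank <- (as.integer(length) - 1L) %/% 2L
  lo <- max(1L, position - flank)
  hi <- min(n, position + flank)
  win <- substr(sequence, lo, hi)
  off <- position - lo
  substr(win, off + 1L, off + 1L) <- alt
  list(window = win, center_offset = off, actual_length = nchar(win))
}

.check_window_length <- function(length) {
  if (length(length) != 1 || is.na(length) || length %% 2 != 1 ||
      length < 3 || length > 31) {
    stop("window length must be an odd integer between 3 and 31, got ",
         length, call. = FALSE)
  }
  invisible(TRUE)
}

#' Build mutant peptide windows for a table of substitutions
#'
#' Data-frame-first worker behind dataset construction: one window per
#' substitution record, deterministic and order-preserving. Label columns
#' present in `records` are carried through untouched.
#'
#' @param records Data frame with columns `position`, `ref`, `alt`,
#'   optionally `protein_id` and per-endpoint label columns.
#' @param protein Protein sequence string, or a one-row data frame with
#'   columns `id` and `residues` (as returned by [read_protein_fasta()]).
#' @param length Nominal window length (odd, 3-31).
#' @return A tibble with `window`, `center_offset`, `actual_length`,
#'   `nominal_length` plus all input columns.
#' @export
peptide_windows <- function(records, protein, length) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("empty substitution table", call. = FALSE)
  seq_str <- .protein_string(protein)
  .check_sequence(seq_str)
  .check_window_length(length)
  need <- setdiff(c("position", "ref", "alt"), names(records))
  if (length(need) > 0) {
    stop("substitution table lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(records[c("position", "alt")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (position, alt) record(s) retained",
            call. = FALSE)
  }
  w <- purrr::pmap(
    list(records$position, records$ref, records$alt),
    function(p, r, a) extract_window(seq_str, p, r, a, length)
  )
  out <- tibble::as_tibble(records)
  out$window <- purrr::map_chr(w, "window")
  out$center_offset <- purrr::map_int(w, ~ as.integer(.x$center_offset))
  out$actual_length <- purrr::map_int(w, ~ as.integer(.x$actual_length))
  out$nominal_length <- as.integer(length)
  out
}

.protein_string <- function(protein) {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1, "residues" %in% names(protein))
    protein$residues
  } else {
    stopifnot(is.character(protein), length(protein) == 1)
    protein
  }
}

.check_sequence <- function(seq_str) {
  if (nchar(seq_str) == 0) stop("empty protein sequence", call. = FALSE)
  chars <- unique(strsplit(seq_str, "")[[1]])
  bad <- setdiff(chars, AA_CODES)
  if (length(bad) > 0) {
    stop("nonstandard residue(s) in protein sequence: ",
         paste(bad, collapse = ", "),
         " (U, O, X and ambiguity codes are not supported)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a labeled window dataset for one endpoint
#'
#' Wraps [peptide_windows()] and attaches the binary label of the chosen
#' endpoint as a `label` column (1 = resistant). The returned tibble
#' carries `endpoint`, `nominal_length`, `positives` and `negatives`
#' attributes.
#'
#' @inheritParams peptide_windows
#' @param endpoint Name of the label column in `records`.
#' @return A tibble of labeled windows (class `spr_dataset`).
#' @export
build_dataset <- function(records, protein, endpoint, length) {
  stopifnot(is.character(endpoint), length(endpoint) == 1)
  if (!endpoint %in% names(records)) {
    stop("unknown endpoint '", endpoint, "'; available label columns: ",
         paste(setdiff(names(records),
                       c("protein_id", "position", "ref", "alt")),
               collapse = ", "), call. = FALSE)
  }
  lab <- .as_binary_label(records[[endpoint]], endpoint)
  out <- peptide_windows(records, protein, length)
  out$label <- lab
  attr(out, "endpoint") <- endpoint
  attr(out, "positives") <- sum(lab == 1L)
  attr(out, "negatives") <- sum(lab == 0L)
  class(out) <- c("spr_dataset", class(out))
  out
}

.as_binary_label <- function(x, endpoint) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("endpoint '", endpoint, "' has non-binary values", call. = FALSE)
    }
    return(as.integer(x))
  }
  v <- tolower(trimws(as.character(x)))
  map <- c("1" = 1L, "0" = 0L, "resistant" = 1L, "nonresistant" = 0L,
           "non-resistant" = 0L, "susceptible" = 0L, "true" = 1L,
           "false" = 0L)
  out <- unname(map[v])
  if (anyNA(out)) {
    stop("endpoint '", endpoint, "' has unrecognized label value(s): ",
         paste(unique(v[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}
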