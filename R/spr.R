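# The structure-property relationship (SPR) classifier: a naive-Bayes-like
# scorer over MNA descriptor sets with empirical Pa/Pi calibration.
#
# For a class A (here: drug-resistant) and a query structure described by
# m known descriptors D_i:
#   S0 = 2 P(A) - 1,          P(A)    = Nk / N
#   S  = sin( mean_i asin(2 P(A|D_i) - 1) ),  P(A|D_i) = Nik / Ni
#   B  = (S - S0) / (1 - S S0)
# Probabilities are plain frequency ratios without smoothing; descriptors
# never seen in training are excluded from the mean and surfaced as the
# applicability-domain count. Pa and Pi are mid-rank empirical CDF values
# of B among the leave-one-out scores of the positive and negative
# training structures.

# ---- low-level score -------------------------------------------------------

# B-score from conditional probabilities p (descriptors known to the
# model) and prior share nk/n. Guards: m = 0 gives B = 0; S == S0 gives
# B = 0; the result is clamped to [-1, 1].
.b_from_p <- function(p, nk, n) {
  s0 <- 2 * nk / n - 1
  m <- length(p)
  if (m == 0) {
    return(list(S0k = s0, Sk = NA_real_, Bk = 0, m = 0L))
  }
  s <- sin(mean(asin(pmin(1, pmax(-1, 2 * p - 1)))))
  b <- if (isTRUE(all.equal(s, s0)) || s == s0) {
    0
  } else if (abs(1 - s * s0) < .Machine$double.eps) {
    sign(s)
  } else {
    (s - s0) / (1 - s * s0)
  }
  list(S0k = s0, Sk = s, Bk = max(-1, min(1, b)), m = m)
}

#' B-score of a query descriptor set
#'
#' @param query Character vector of descriptor strings, or an `mna_set`.
#' @param model A fitted `spr_model` (or its bare counts).
#' @return A list with `S0k`, `Sk`, `Bk`, `m` (query descriptors known to
#'   the model) and `n_new` (query descriptors never seen in training).
#' @export
b_score <- function(query, model) {
  d <- if (inherits(query, "mna_set")) query$descriptors else unique(query)
  idx <- match(d, model$descriptors)
  known <- which(!is.na(idx))
  p <- model$Nik[idx[known]] / model$Ni[idx[known]]
  out <- .b_from_p(p, model$Nk, model$N)
  out$n_new <- length(d) - length(known)
  out
}

# ---- fitting ---------------------------------------------------------------

# internal: counts + LOO calibration from per-structure descriptor sets
.spr_fit_sets <- function(sets, labels, level, nominal_length, endpoint) {
  stopifnot(length(sets) == length(labels))
  labels <- as.integer(labels)
  n <- length(sets)
  nk <- sum(labels == 1L)
  if (nk == 0L || nk == n) {
    stop("training needs at least one structure of each class (got ",
         nk, " positives of ", n, ")", call. = FALSE)
  }
  universe <- .sort_bytes(unique(unlist(sets, use.names = FALSE)))
  ids <- lapply(sets, match, table = universe)
  nd <- length(universe)
  Ni <- tabulate(unlist(ids, use.names = FALSE), nd)
  Nik <- tabulate(unlist(ids[labels == 1L], use.names = FALSE), nd)

  # leave-one-out scores by count decrement / restore
  loo <- numeric(n)
  for (s in seq_len(n)) {
    id <- ids[[s]]
    y <- labels[s]
    ni <- Ni[id] - 1L
    nik <- Nik[id] - y
    stopifnot(all(ni >= 0), all(nik >= 0), all(nik <= ni))
    keep <- ni > 0L
    loo[s] <- .b_from_p(nik[keep] / ni[keep], nk - y, n - 1L)$Bk
  }

  structure(
    list(
      descriptors = universe, Ni = Ni, Nik = Nik, N = n, Nk = nk,
      level = as.integer(level),
      nominal_length = as.integer(nominal_length),
      endpoint = endpoint,
      loo_scores = loo, labels = labels,
      calib = list(pos = sort(loo[labels == 1L]),
                   neg = sort(loo[labels == 0L]))
    ),
    class = "spr_model"
  )
}

#' Fit an SPR model
#'
#' Builds mutant peptide graphs from labeled windows, generates MNA
#' descriptor sets at the chosen level, tallies the training counts, and
#' computes the leave-one-out B-score calibration tables that back the
#' Pa/Pi estimates.
#'
#' @param windows Labeled windows: a tibble from [build_dataset()], or
#'   from [peptide_windows()] together with `endpoint` naming a binary
#'   label column.
#' @param endpoint Label column to model (default the `label` column set
#'   by [build_dataset()]).
#' @param level MNA descriptor level (0-15).
#' @return An object of class `spr_model`.
#' @seealso [predict.spr_model()], [loo_auc()], [tidy.spr_model()]
#' @export
spr_fit <- function(windows, endpoint = "label", level = 2L) {
  stopifnot(is.data.frame(windows))
  if (!endpoint %in% names(windows)) {
    stop("unknown endpoint '", endpoint, "'", call. = FALSE)
  }
  labels <- .as_binary_label(windows[[endpoint]], endpoint)
  graphs <- purrr::map(windows$window, peptide_graph)
  sets <- .mna_sets_multi(graphs, level)[[as.character(level)]]
  ep_name <- if (identical(endpoint, "label")) {
    attr(windows, "endpoint") %||% "label"
  } else {
    endpoint
  }
  .spr_fit_sets(sets, labels, level,
                nominal_length = windows$nominal_length[1] %||% NA_integer_,
                endpoint = ep_name)
}

#' @export
print.spr_model <- function(x, ...) {
  cat("<spr_model> endpoint '", x$endpoint, "': N = ", x$N, " (", x$Nk,
      " resistant), ", length(x$descriptors),
      " descriptors, MNA level ", x$level,
      ", window length ", x$nominal_length, "\n", sep = "")
  cat("  LOO AUC: ", format(auc_mw(x$loo_scores, x$labels), digits = 4),
      "\n", sep = "")
  invisible(x)
}

# ---- prediction ------------------------------------------------------------

# mid-rank empirical CDF helpers
.pa_of <- function(b, pos) {
  (sum(pos < b) + 0.5 * sum(pos == b)) / length(pos)
}
.pi_of <- function(b, neg) {
  (sum(neg > b) + 0.5 * sum(neg == b)) / length(neg)
}

#' Predict drug resistance for new structures
#'
#' Scores each query structure against the fitted counts and calibrates
#' the B-score into `Pa` (estimate that the substitution is resistant) and
#' `Pi` (estimate that it is not), the mid-rank fractions of positive
#' leave-one-out scores below B and of negative scores above B. The
#' default decision rule is `Pa > Pi`. The count of query descriptors
#' never seen in training (`n_new_descriptors`) approximates the
#' applicability domain; a query with no known descriptor is flagged
#' `out_of_domain`.
#'
#' @param object A fitted `spr_model`.
#' @param newdata Windows tibble (with a `window` column), a list of
#'   `mol_graph` objects, a list of descriptor sets, or a path to an SD
#'   file.
#' @param ... Unused.
#' @return A tibble with one row per query: `B`, `Pa`, `Pi`,
#'   `n_descriptors`, `n_new_descriptors`, `out_of_domain`.
#' @export
predict.spr_model <- function(object, newdata, ...) {
  sets <- .as_descriptor_sets(newdata, object$level)
  rows <- purrr::map(sets, function(d) {
    sc <- b_score(d, object)
    tibble::tibble(
      B = sc$Bk,
      Pa = .pa_of(sc$Bk, object$calib$pos),
      Pi = .pi_of(sc$Bk, object$calib$neg),
      n_descriptors = sc$m + sc$n_new,
      n_new_descriptors = sc$n_new,
      out_of_domain = sc$m == 0L
    )
  })
  dplyr::bind_rows(rows)
}

.as_descriptor_sets <- function(newdata, level) {
  if (is.character(newdata) && length(newdata) == 1 &&
      file.exists(newdata)) {
    newdata <- read_sdf(newdata)
  }
  if (is.data.frame(newdata)) {
    stopifnot("window" %in% names(newdata))
    newdata <- purrr::map(newdata$window, peptide_graph)
  }
  stopifnot(is.list(newdata))
  if (all(purrr::map_lgl(newdata, inherits, "mol_graph"))) {
    return(.mna_sets_multi(newdata, level)[[as.character(level)]])
  }
  purrr::map(newdata, function(s) {
    if (inherits(s, "mna_set")) s$descriptors else unique(as.character(s))
  })
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy an SPR model: per-descriptor training counts
#'
#' @param x A fitted `spr_model`.
#' @param ... Unused.
#' @return A tibble with `descriptor`, `n_with` (structures containing
#'   it), `n_with_positive`, and the conditional probability `p_cond`.
#' @method tidy spr_model
#' @export
tidy.spr_model <- function(x, ...) {
  tibble::tibble(
    descriptor = x$descriptors,
    n_with = x$Ni,
    n_with_positive = x$Nik,
    p_cond = x$Nik / x$Ni
  )
}

#' One-row model summary
#'
#' @param x A fitted `spr_model`.
#' @param ... Unused.
#' @return A tibble with training-set sizes, model coordinates and the
#'   leave-one-out AUC.
#' @method glance spr_model
#' @export
glance.spr_model <- function(x, ...) {
  tibble::tibble(
    n = x$N, n_positive = x$Nk, n_negative = x$N - x$Nk,
    n_descriptors = length(x$descriptors),
    level = x$level, window_length = x$nominal_length,
    endpoint = x$endpoint,
    loo_auc = auc_mw(x$loo_scores, x$labels)
  )
}

# ---- serialization ---------------------------------------------------------

#' Save an SPR model as portable JSON
#'
#' @param model A fitted `spr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
spr_model_write <- function(model, path) {
  stopifnot(inherits(model, "spr_model"))
  payload <- list(
    format = "sprpep-model", version = 1L,
    endpoint = model$endpoint, level = model$level,
    nominal_length = model$nominal_length,
    N = model$N, Nk = model$Nk,
    descriptors = model$descriptors, Ni = model$Ni, Nik = model$Nik,
    # scores as %.17g strings so the reload is bit-exact
    loo_scores = sprintf("%.17g", model$loo_scores), labels = model$labels
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an SPR model saved by [spr_model_write()]
#'
#' @param path JSON file path.
#' @return An `spr_model`.
#' @export
spr_model_read <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "sprpep-model")) {
    stop(path, " is not an sprpep model file", call. = FALSE)
  }
  labels <- as.integer(p$labels)
  loo <- as.numeric(p$loo_scores)
  structure(
    list(
      descriptors = as.character(p$descriptors),
      Ni = as.integer(p$Ni), Nik = as.integer(p$Nik),
      N = as.integer(p$N), Nk = as.integer(p$Nk),
      level = as.integer(p$level),
      nominal_length = as.integer(p$nominal_length),
      endpoint = p$endpoint,
      loo_scores = loo, labels = labels,
      calib = list(pos = sort(loo[labels == 1L]),
                   neg = sort(loo[labels == 0L]))
    ),
    class = "spr_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
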