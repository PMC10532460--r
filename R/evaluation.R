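# Model evaluation: AUC, cross-validation, confusion metrics, threshold
# scans and the window-length x descriptor-level grid search.

#' Mann-Whitney AUC
#'
#' Fraction of (positive, negative) pairs where the positive scores
#' higher, ties counted half, computed from average ranks.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return The AUC as a single number.
#' @examples
#' auc_mw(c(3, 2, 1), c(1, 0, 1))  # 0.5
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out AUC of an SPR model configuration
#'
#' Fits the model (counts plus the decrement-based leave-one-out scores)
#' and returns the AUC of the LOO B-scores against the labels.
#'
#' @inheritParams spr_fit
#' @return The LOO AUC.
#' @export
loo_auc <- function(windows, endpoint = "label", level = 2L) {
  m <- spr_fit(windows, endpoint = endpoint, level = level)
  auc_mw(m$loo_scores, m$labels)
}

#' Stratified k-fold cross-validated AUC
#'
#' Structures are assigned to k folds separately within each class with a
#' seeded shuffle (remainders distributed round-robin), a model is
#' refitted without each fold, held-out structures are B-scored, and one
#' AUC is computed over all pooled held-out scores. With `k = N` this is
#' exactly leave-one-out.
#'
#' @inheritParams spr_fit
#' @param k Number of folds (default 20).
#' @param seed Integer seed for the fold shuffle.
#' @return The pooled cross-validated AUC.
#' @export
kfold_auc <- function(windows, endpoint = "label", level = 2L, k = 20L,
                      seed = 1L) {
  stopifnot(is.data.frame(windows))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  labels <- .as_binary_label(windows[[endpoint]], endpoint)
  graphs <- purrr::map(windows$window, peptide_graph)
  sets <- .mna_sets_multi(graphs, level)[[as.character(level)]]
  n <- length(sets)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cls in c(1L, 0L)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  scores <- numeric(n)
  for (f in sort(unique(fold))) {
    test <- fold == f
    fit <- .spr_fit_sets(sets[!test], labels[!test], level,
                         nominal_length = NA_integer_, endpoint = endpoint)
    scores[test] <- vapply(sets[test],
                           function(d) b_score(d, fit)$Bk, numeric(1))
  }
  auc_mw(scores, labels)
}

#' Sensitivity, specificity and balanced accuracy
#'
#' @param tp,fp,tn,fn Confusion-matrix counts (vectorized).
#' @return Tibble with `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP) and `balanced_accuracy`, their mean.
#' @examples
#' confusion_metrics(78, 102, 87, 4)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  if (any(tp + fn == 0) || any(tn + fp == 0)) {
    stop("confusion matrix has an empty class margin", call. = FALSE)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2)
}

#' Threshold scan of prediction results
#'
#' Tabulates confusion counts and metrics over decision rules: the
#' default `Pa > Pi` plus fixed Pa cut-offs.
#'
#' @param predictions Tibble with `Pa` and `Pi` columns (as returned by
#'   [predict.spr_model()]).
#' @param labels Binary truth labels, one per prediction row.
#' @param cutoffs Numeric Pa cut-offs to scan (default 0.3 to 0.9).
#' @return Tibble with one row per rule: `rule`, `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
threshold_scan <- function(predictions, labels,
                           cutoffs = seq(0.3, 0.9, by = 0.1)) {
  stopifnot(all(c("Pa", "Pi") %in% names(predictions)))
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(predictions))
  rules <- c(list(`Pa > Pi` = predictions$Pa > predictions$Pi),
             stats::setNames(
               purrr::map(cutoffs, ~ predictions$Pa > .x),
               sprintf("Pa > %.1f", cutoffs)
             ))
  purrr::imap(rules, function(pred_pos, nm) {
    tp <- sum(pred_pos & labels == 1L)
    fp <- sum(pred_pos & labels == 0L)
    tn <- sum(!pred_pos & labels == 0L)
    fn <- sum(!pred_pos & labels == 1L)
    # unlike confusion_metrics(), the scan tolerates single-class input
    # (a margin-less ratio is NA rather than an error)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    tibble::tibble(rule = nm, TP = tp, FP = fp, TN = tn, FN = fn,
                   sensitivity = sens, specificity = spec,
                   balanced_accuracy = (sens + spec) / 2)
  }) |> dplyr::bind_rows()
}

#' Grid search over window length and MNA level
#'
#' Builds one training set per window length, evaluates the leave-one-out
#' AUC of every (length, level, endpoint) combination, and selects the
#' cell with the highest AUC averaged over endpoints (ties broken by
#' smaller level, then smaller length). Descriptors are generated once
#' per length and reused across levels.
#'
#' @param records Substitution table with one label column per endpoint.
#' @param protein Protein sequence string or one-row tibble.
#' @param endpoints Character vector of label columns to model.
#' @param lengths Odd window lengths to scan (default 3 to 31).
#' @param levels MNA levels to scan (default 1 to 15).
#' @return An object of class `spr_grid`: list with `cells` (tibble:
#'   `length`, `level`, `endpoint`, `auc`), `summary` (mean AUC per
#'   cell) and `best` (one-row tibble).
#' @export
spr_grid <- function(records, protein, endpoints,
                     lengths = seq(3L, 31L, by = 2L), levels = 1:15) {
  stopifnot(length(endpoints) >= 1)
  labs <- lapply(endpoints, function(e) .as_binary_label(records[[e]], e))
  names(labs) <- endpoints
  cells <- list()
  for (len in lengths) {
    w <- peptide_windows(records, protein, len)
    graphs <- purrr::map(w$window, peptide_graph)
    sets_by_level <- .mna_sets_multi(graphs, levels)
    for (lv in levels) {
      sets <- sets_by_level[[as.character(lv)]]
      for (e in endpoints) {
        fit <- .spr_fit_sets(sets, labs[[e]], lv, len, e)
        cells[[length(cells) + 1L]] <- tibble::tibble(
          length = as.integer(len), level = as.integer(lv), endpoint = e,
          auc = auc_mw(fit$loo_scores, fit$labels)
        )
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  summary <- cells |>
    dplyr::group_by(.data$length, .data$level) |>
    dplyr::summarise(avg_auc = mean(.data$auc), .groups = "drop")
  best <- summary |>
    dplyr::arrange(dplyr::desc(.data$avg_auc), .data$level, .data$length) |>
    dplyr::slice(1)
  structure(list(cells = cells, summary = summary, best = best),
            class = "spr_grid")
}

#' @export
print.spr_grid <- function(x, ...) {
  cat("<spr_grid> ", nrow(x$summary), " cells over ",
      length(unique(x$cells$endpoint)), " endpoint(s)\n", sep = "")
  cat("  best: length ", x$best$length, ", level ", x$best$level,
      ", mean AUC ", format(x$best$avg_auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a grid-search result
#'
#' @param x An `spr_grid`.
#' @param ... Unused.
#' @return The long cell tibble (`length`, `level`, `endpoint`, `auc`).
#' @method tidy spr_grid
#' @export
tidy.spr_grid <- function(x, ...) x$cells

#' One-row grid-search summary
#'
#' @param x An `spr_grid`.
#' @param ... Unused.
#' @return The best cell with its mean AUC.
#' @method glance spr_grid
#' @export
glance.spr_grid <- function(x, ...) x$best
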