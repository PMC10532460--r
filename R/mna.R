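# Multilevel Neighborhoods of Atoms (MNA) descriptors.
#
# The level-0 descriptor of an atom is its mark: "-" when the atom is not
# in a ring, then the element symbol, then a "[+n]"/"[-n]" suffix only for
# non-zero formal charge. The level-k descriptor is mark(D1 D2 ... Dd)
# where the Di are the level-(k-1) descriptors of the immediate neighbors,
# concatenated in byte-wise lexicographic order. Bond types never enter.

# byte-wise lexicographic helpers (stringi with an explicit C locale:
# descriptor strings can exceed what sort(method = "radix") handles)
.sort_bytes <- function(x) stringi::stri_sort(x, locale = "C")
.order_bytes <- function(x) stringi::stri_order(x, locale = "C")

#' Atom mark (level-0 MNA descriptor)
#'
#' @param element Element symbol(s).
#' @param charge Integer formal charge(s) (default 0).
#' @param in_ring Logical: is the atom part of a cycle?
#' @return Character vector of marks, e.g. `"-C"`, `"C"`, `"-O[-1]"`.
#' @examples
#' atom_mark("C", 0, FALSE)   # "-C"
#' atom_mark("O", -1, FALSE)  # "-O[-1]"
#' @export
atom_mark <- function(element, charge = 0L, in_ring = FALSE) {
  paste0(
    ifelse(in_ring, "", "-"),
    element,
    ifelse(charge != 0, sprintf("[%+d]", as.integer(charge)), "")
  )
}

# per-atom MNA descriptor strings at one level (iterative, memoized by
# level: level k is assembled from the stored level k-1 strings)
.mna_atom_strings <- function(graph, level) {
  stopifnot(inherits(graph, "mol_graph"))
  if (length(level) != 1 || is.na(level) || level < 0 || level > 15) {
    stop("MNA level must be between 0 and 15, got ", level, call. = FALSE)
  }
  if (anyNA(graph$atoms$in_ring)) graph <- perceive_rings(graph)
  n <- nrow(graph$atoms)
  nb <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  marks <- atom_mark(graph$atoms$element, graph$atoms$charge,
                     graph$atoms$in_ring)
  s <- marks
  lv <- 0L
  while (lv < level) {
    # rank the current strings once; neighbors are then ordered by rank,
    # which equals byte-wise lexicographic order of the strings
    u <- .sort_bytes(unique(s))
    r <- match(s, u)
    s_new <- character(n)
    for (a in seq_len(n)) {
      nbr <- nb[[a]]
      if (length(nbr) == 0) {
        s_new[a] <- paste0(marks[a], "()")
      } else {
        s_new[a] <- paste0(
          marks[a], "(",
          paste(s[nbr[order(r[nbr])]], collapse = ""), ")"
        )
      }
    }
    s <- s_new
    lv <- lv + 1L
  }
  s
}

#' MNA descriptor of one atom
#'
#' @param graph A `mol_graph` (ring flags are computed if absent).
#' @param atom_index 1-based atom index.
#' @param level Descriptor level, 0 to 15.
#' @return The descriptor string.
#' @examples
#' methane <- mol_graph(data.frame(element = c("C", "H", "H", "H", "H")),
#'                      data.frame(i = 1, j = 2:5))
#' mna_descriptor(methane, 1, 1)  # "-C(-H-H-H-H)"
#' @export
mna_descriptor <- function(graph, atom_index, level) {
  stopifnot(inherits(graph, "mol_graph"))
  atom_index <- as.integer(atom_index)
  if (is.na(atom_index) || atom_index < 1 || atom_index > nrow(graph$atoms)) {
    stop("atom index out of range", call. = FALSE)
  }
  .mna_atom_strings(graph, level)[atom_index]
}

#' Unique MNA descriptors of a structure at one level
#'
#' A structure is represented by the set of distinct descriptor strings
#' over its atoms; the classifier consumes this set, while per-descriptor
#' multiplicities are retained for diagnostics only.
#'
#' @inheritParams mna_descriptor
#' @return An object of class `mna_set`: list with `level`, `descriptors`
#'   (sorted unique strings) and `counts` (named integer multiplicities).
#' @examples
#' methane <- mol_graph(data.frame(element = c("C", "H", "H", "H", "H")),
#'                      data.frame(i = 1, j = 2:5))
#' descriptor_set(methane, 1)$descriptors
#' @export
descriptor_set <- function(graph, level) {
  s <- .mna_atom_strings(graph, level)
  u <- .sort_bytes(unique(s))
  structure(
    list(level = as.integer(level), descriptors = u,
         counts = stats::setNames(tabulate(match(s, u), length(u)), u)),
    class = "mna_set"
  )
}

#' @export
print.mna_set <- function(x, ...) {
  cat("<mna_set> level ", x$level, ": ", length(x$descriptors),
      " unique descriptors\n", sep = "")
  utils::head(x$descriptors, 5) |>
    paste(collapse = " ") |> cat("...\n")
  invisible(x)
}

# descriptor sets for a list of graphs at each requested level, computed
# in one sweep per graph so level k reuses the level k-1 strings
.mna_sets_multi <- function(graphs, levels) {
  levels <- sort(unique(as.integer(levels)))
  stopifnot(all(levels >= 0), all(levels <= 15))
  out <- stats::setNames(
    lapply(levels, function(l) vector("list", length(graphs))),
    as.character(levels)
  )
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    if (anyNA(g$atoms$in_ring)) g <- perceive_rings(g)
    n <- nrow(g$atoms)
    nb <- vector("list", n)
    if (nrow(g$bonds) > 0) {
      for (k in seq_len(nrow(g$bonds))) {
        i <- g$bonds$i[k]; j <- g$bonds$j[k]
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
    marks <- atom_mark(g$atoms$element, g$atoms$charge, g$atoms$in_ring)
    s <- marks
    lv <- 0L
    repeat {
      if (lv %in% levels) {
        out[[as.character(lv)]][[gi]] <- .sort_bytes(unique(s))
      }
      if (lv >= max(levels)) break
      u <- .sort_bytes(unique(s))
      r <- match(s, u)
      s_new <- character(n)
      for (a in seq_len(n)) {
        nbr <- nb[[a]]
        s_new[a] <- if (length(nbr) == 0) {
          paste0(marks[a], "()")
        } else {
          paste0(marks[a], "(",
                 paste(s[nbr[order(r[nbr])]], collapse = ""), ")")
        }
      }
      s <- s_new
      lv <- lv + 1L
    }
  }
  out
}

#' Write a descriptor dump
#'
#' One line per structure: the sorted unique descriptor strings separated
#' by tabs. Useful for diffing runs and for applicability-domain reports.
#'
#' @param sets List of `mna_set` objects (or plain character vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_dump <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    d <- if (inherits(s, "mna_set")) s$descriptors else s
    paste(d, collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
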