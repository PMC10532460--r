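# Molecular graphs of peptides: explicit-hydrogen structural formulas.

#' Construct a molecular graph
#'
#' A `mol_graph` is an explicit-hydrogen structural formula: a simple
#' undirected graph of atoms with elements, formal charges and a derived
#' in-ring flag, plus bond orders (kept for file fidelity; descriptor
#' generation ignores them) and free-text SD annotation tags.
#'
#' @param atoms Tibble or data frame with columns `element` (one of C, N,
#'   O, S, H) and optionally `charge` (integer, default 0) and `name`.
#' @param bonds Tibble or data frame with columns `i`, `j` (1-based atom
#'   indices) and optionally `order` (1 or 2, default 1).
#' @param tags Named list or character vector of SD data items.
#' @param perceive_rings If `TRUE` (default), compute the `in_ring` flag.
#' @return An object of class `mol_graph`.
#' @examples
#' m <- mol_graph(data.frame(element = c("C", "H", "H", "H", "H")),
#'                data.frame(i = 1, j = 2:5))
#' m
#' @export
mol_graph <- function(atoms, bonds, tags = list(), perceive_rings = TRUE) {
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) == 0) stop("a molecular graph needs at least one atom")
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  bad <- setdiff(unique(atoms$element), names(ATOM_VALENCE))
  if (length(bad) > 0) {
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(bonds)) bonds <- tibble::tibble(i = integer(), j = integer())
  bonds <- tibble::as_tibble(bonds)
  if (nrow(bonds) > 0) {
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$i == bonds$j)) stop("self-loop bond", call. = FALSE)
    if (any(bonds$i < 1 | bonds$j < 1 | bonds$i > nrow(atoms) |
            bonds$j > nrow(atoms))) {
      stop("bond index out of range", call. = FALSE)
    }
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
  } else {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  }
  g <- structure(list(atoms = atoms, bonds = bonds, tags = as.list(tags)),
                 class = "mol_graph")
  if (perceive_rings) g <- perceive_rings(g) else g$atoms$in_ring <- NA
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", molecular_formula(x), ": ",
      nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds, ",
      sum(x$atoms$in_ring %in% TRUE), " in rings\n", sep = "")
  if (length(x$tags) > 0) {
    cat("  tags: ",
        paste(names(x$tags), unlist(x$tags), sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Flag atoms that lie on a cycle
#'
#' Sets `in_ring = TRUE` for every atom that lies on at least one simple
#' cycle, via bridge detection: an atom is in a ring exactly when it has an
#' incident edge that is not a bridge. Idempotent.
#'
#' @param graph A `mol_graph`.
#' @return The graph with an updated `in_ring` column.
#' @export
perceive_rings <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  n <- nrow(graph$atoms)
  in_ring <- rep(FALSE, n)
  if (nrow(graph$bonds) > 0) {
    ig <- igraph::graph_from_edgelist(
      cbind(graph$bonds$i, graph$bonds$j), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    br <- igraph::bridges(ig)
    cyc <- igraph::E(ig)[setdiff(seq_len(igraph::ecount(ig)), as.integer(br))]
    ends <- igraph::ends(ig, cyc)
    in_ring[unique(as.integer(ends))] <- TRUE
  }
  graph$atoms$in_ring <- in_ring
  graph
}

#' Assemble the molecular graph of a peptide
#'
#' Joins residue templates N-to-C with peptide bonds: each bond formation
#' removes the carboxyl OH (one O, one H) of residue i and one amine H of
#' residue i+1 (net loss of one water per bond) and adds the C-N amide
#' bond. Termini stay free and neutral (NH2 / COOH).
#'
#' @param residues Peptide as a one-letter string (e.g. `"GAW"`), or a
#'   one-row data frame with a `window` column as produced by
#'   [peptide_windows()] (its provenance columns become SD tags).
#' @param tags Optional named list of SD tags to attach.
#' @return A `mol_graph` with ring flags computed.
#' @examples
#' peptide_graph("GG")   # diglycine: 17 atoms
#' @export
peptide_graph <- function(residues, tags = list()) {
  if (is.data.frame(residues)) {
    stopifnot(nrow(residues) == 1, "window" %in% names(residues))
    tags <- c(tags, .window_tags(residues))
    residues <- residues$window
  }
  stopifnot(is.character(residues), length(residues) == 1)
  if (nchar(residues) == 0) stop("empty peptide window", call. = FALSE)
  codes <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(codes), AA_CODES)
  if (length(bad) > 0) {
    stop("nonstandard residue(s) in peptide: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_res <- length(codes)
  elem <- character(0); chg <- integer(0); nm <- character(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  offset <- 0L
  prev_c <- NA_integer_  # carbonyl C of the previous residue (new index)
  for (r in seq_len(n_res)) {
    tpl <- residue_template(codes[r])
    keep <- rep(TRUE, nrow(tpl$atoms))
    if (r < n_res) keep[c(tpl$oxt_idx, tpl$oxt_h_idx)] <- FALSE
    if (r > 1) keep[tpl$n_h_idx] <- FALSE
    remap <- cumsum(keep)
    remap[!keep] <- NA_integer_
    sel <- which(keep)
    elem <- c(elem, tpl$atoms$element[sel])
    chg <- c(chg, tpl$atoms$charge[sel])
    nm <- c(nm, paste0(tpl$atoms$name[sel], "_", r))
    kb <- keep[tpl$bonds$i] & keep[tpl$bonds$j]
    bi <- c(bi, offset + remap[tpl$bonds$i[kb]])
    bj <- c(bj, offset + remap[tpl$bonds$j[kb]])
    bo <- c(bo, tpl$bonds$order[kb])
    if (r > 1) {  # peptide bond C(prev)-N(this)
      bi <- c(bi, prev_c)
      bj <- c(bj, offset + remap[tpl$n_idx])
      bo <- c(bo, 1L)
    }
    prev_c <- offset + remap[tpl$c_idx]
    offset <- offset + length(sel)
  }
  mol_graph(
    atoms = tibble::tibble(name = nm, element = elem, charge = chg),
    bonds = tibble::tibble(i = bi, j = bj, order = bo),
    tags = tags
  )
}

# tags recorded for a window row when it is turned into an SD record
.window_tags <- function(row) {
  pick <- function(col) {
    if (col %in% names(row)) as.character(row[[col]]) else NULL
  }
  tg <- list(GENE = pick("protein_id"), POSITION = pick("position"),
             REF_AA = pick("ref"), ALT_AA = pick("alt"),
             NOMINAL_LENGTH = pick("nominal_length"),
             CENTER_OFFSET = pick("center_offset"))
  tg[!vapply(tg, is.null, logical(1))]
}

#' Molecular formula of a graph
#'
#' @param graph A `mol_graph`.
#' @return Formula string in Hill order (C, H, then alphabetical).
#' @examples
#' molecular_formula(peptide_graph("G"))  # "C2H5NO2"
#' @export
molecular_formula <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  cnt <- table(graph$atoms$element)
  els <- names(cnt)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(cnt[ord] > 1, cnt[ord], ""), collapse = "")
}

#' Check valences of every atom
#'
#' Verifies that the bond-order sum of each atom matches the neutral
#' valence of its element (C4, N3, O2, S2, H1), adjusted by formal charge.
#'
#' @param graph A `mol_graph`.
#' @return `TRUE` invisibly; errors with the offending atom otherwise.
#' @export
check_valences <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  n <- nrow(graph$atoms)
  deg <- numeric(n)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      deg[graph$bonds$i[k]] <- deg[graph$bonds$i[k]] + graph$bonds$order[k]
      deg[graph$bonds$j[k]] <- deg[graph$bonds$j[k]] + graph$bonds$order[k]
    }
  }
  want <- ATOM_VALENCE[graph$atoms$element] + graph$atoms$charge
  bad <- which(deg != want)
  if (length(bad) > 0) {
    stop("valence mismatch at atom ", bad[1], " (",
         graph$atoms$element[bad[1]], ": bond order sum ", deg[bad[1]],
         ", expected ", want[bad[1]], ")", call. = FALSE)
  }
  invisible(TRUE)
}
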