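# SD file input/output: MOL V3000 (read/write) and V2000 (read).
#
# Hand-written on purpose: the records must round-trip losslessly together
# with their annotation tags (POSITION, GENE, REF_AA, ALT_AA, EFFECT,
# NOMINAL_LENGTH, CENTER_OFFSET), and V3000 connection tables are written.
# Coordinates are all zero: these are connectivity-only structures.

SDF_TAGS <- c("POSITION", "GENE", "REF_AA", "ALT_AA", "EFFECT",
              "NOMINAL_LENGTH", "CENTER_OFFSET")

#' Write molecular graphs as an SD file (MOL V3000)
#'
#' Each record is a V3000 connection table followed by the graph's tags as
#' SD data items and the `$$$$` separator. Writing an empty list produces
#' an empty file with zero records.
#'
#' @param graphs List of `mol_graph` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(graphs, path) {
  stopifnot(is.list(graphs))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  for (g in graphs) {
    stopifnot(inherits(g, "mol_graph"))
    writeLines(.mol_v3000_block(g), con)
    for (tg in names(g$tags)) {
      writeLines(c(paste0(">  <", tg, ">"), as.character(g$tags[[tg]]), ""),
                 con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

.mol_v3000_block <- function(g) {
  na <- nrow(g$atoms); nb <- nrow(g$bonds)
  atom_lines <- sprintf(
    "M  V30 %d %s 0 0 0 0%s",
    seq_len(na), g$atoms$element,
    ifelse(g$atoms$charge != 0, sprintf(" CHG=%d", g$atoms$charge), "")
  )
  bond_lines <- if (nb > 0) {
    sprintf("M  V30 %d %d %d %d", seq_len(nb), g$bonds$order,
            g$bonds$i, g$bonds$j)
  } else character(0)
  c(
    if (!is.null(g$tags$MOLNAME)) as.character(g$tags$MOLNAME) else "",
    "  sprpep          0D",
    "",
    "  0  0  0     0  0  0  0  0  0999 V3000",
    "M  V30 BEGIN CTAB",
    sprintf("M  V30 COUNTS %d %d 0 0 0", na, nb),
    "M  V30 BEGIN ATOM",
    atom_lines,
    "M  V30 END ATOM",
    if (nb > 0) c("M  V30 BEGIN BOND", bond_lines, "M  V30 END BOND"),
    "M  V30 END CTAB",
    "M  END"
  )
}

#' Read an SD file into molecular graphs
#'
#' Parses both V2000 and V3000 connection tables. Hydrogens left implicit
#' in the file are added to complete neutral valences; ring flags are
#' perceived after reading. `tag_map` renames foreign tag names onto the
#' package convention, e.g. `c(POSITION = "AAS_pos")` reads the file's
#' `AAS_pos` items as `POSITION`.
#'
#' @param path SD file path.
#' @param tag_map Optional named character vector: names are canonical tag
#'   names, values the tag names used in the file.
#' @param required_tags Character vector of tags that must be present on
#'   every record when `strict = TRUE`.
#' @param strict If `TRUE`, a record missing a required tag is an error.
#' @return List of `mol_graph` objects.
#' @export
read_sdf <- function(path, tag_map = NULL,
                     required_tags = c("EFFECT"), strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(list())
  recs <- split(lines, cumsum(dplyr::lag(lines == "$$$$", default = FALSE)))
  recs <- Filter(function(r) any(nzchar(setdiff(r, "$$$$"))), recs)
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    g <- tryCatch(
      .parse_sdf_record(recs[[k]], tag_map),
      error = function(e) {
        stop("SD record ", k, " of ", path, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (strict) {
      missing_tags <- setdiff(required_tags, names(g$tags))
      if (length(missing_tags) > 0) {
        stop("SD record ", k, " of ", path, " lacks required tag(s): ",
             paste(missing_tags, collapse = ", "), call. = FALSE)
      }
    }
    out[[k]] <- g
  }
  out
}

.parse_sdf_record <- function(rl, tag_map) {
  rl <- rl[rl != "$$$$"]
  m_end <- which(trimws(rl) == "M  END" | trimws(rl) == "M END")
  if (length(m_end) == 0) stop("malformed connection table: no 'M  END'")
  ct <- rl[seq_len(m_end[1])]
  if (length(ct) < 4) stop("connection table too short")
  version <- if (any(grepl("V30", ct[4])) ||
                 any(startsWith(ct, "M  V30"))) "V3000" else "V2000"
  parsed <- if (version == "V3000") .parse_v3000(ct) else .parse_v2000(ct)

  # data items
  tags <- list()
  i <- m_end[1] + 1L
  while (i <= length(rl)) {
    ln <- rl[i]
    tg <- regmatches(ln, regexec("^>.*<([^>]+)>", ln))[[1]]
    if (length(tg) == 2) {
      val <- character(0)
      i <- i + 1L
      while (i <= length(rl) && nzchar(rl[i]) && !startsWith(rl[i], ">")) {
        val <- c(val, rl[i])
        i <- i + 1L
      }
      tags[[tg[2]]] <- paste(val, collapse = "\n")
    } else {
      i <- i + 1L
    }
  }
  if (!is.null(tag_map)) {
    for (canon in names(tag_map)) {
      if (tag_map[[canon]] %in% names(tags) && !canon %in% names(tags)) {
        tags[[canon]] <- tags[[tag_map[[canon]]]]
        tags[[tag_map[[canon]]]] <- NULL
      }
    }
  }
  title <- trimws(ct[1])
  if (nzchar(title) && is.null(tags$MOLNAME)) tags$MOLNAME <- title

  g <- .fill_implicit_h(parsed$atoms, parsed$bonds)
  mol_graph(g$atoms, g$bonds, tags = tags)
}

.parse_v3000 <- function(ct) {
  v30 <- sub("^M  V30 ", "", ct[startsWith(ct, "M  V30")])
  counts <- v30[startsWith(v30, "COUNTS")]
  if (length(counts) == 0) stop("V3000 block without COUNTS line")
  cnt <- as.integer(strsplit(trimws(counts[1]), "\\s+")[[1]][2:3])
  na <- cnt[1]; nb <- cnt[2]
  a0 <- which(v30 == "BEGIN ATOM"); a1 <- which(v30 == "END ATOM")
  if (length(a0) == 0 || length(a1) == 0) stop("V3000 block without ATOM block")
  atom_lines <- v30[seq(a0[1] + 1L, a1[1] - 1L)]
  if (length(atom_lines) != na) stop("ATOM block length disagrees with COUNTS")
  elem <- character(na); chg <- integer(na); idx <- integer(na)
  for (k in seq_len(na)) {
    f <- strsplit(trimws(atom_lines[k]), "\\s+")[[1]]
    idx[k] <- as.integer(f[1])
    elem[k] <- f[2]
    chg[k] <- 0L
    chg_f <- grep("^CHG=", f, value = TRUE)
    if (length(chg_f) > 0) chg[k] <- as.integer(sub("^CHG=", "", chg_f[1]))
  }
  if (!identical(sort(idx), seq_len(na))) stop("non-contiguous atom indices")
  ord <- order(idx)
  atoms <- tibble::tibble(element = elem[ord], charge = chg[ord])

  bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  if (nb > 0) {
    b0 <- which(v30 == "BEGIN BOND"); b1 <- which(v30 == "END BOND")
    if (length(b0) == 0) stop("COUNTS declares bonds but no BOND block found")
    bond_lines <- v30[seq(b0[1] + 1L, b1[1] - 1L)]
    if (length(bond_lines) != nb) {
      stop("BOND block length disagrees with COUNTS")
    }
    bf <- t(vapply(strsplit(trimws(bond_lines), "\\s+"),
                   function(f) as.integer(f[2:4]), integer(3)))
    bonds <- tibble::tibble(i = bf[, 2], j = bf[, 3], order = bf[, 1])
  }
  list(atoms = atoms, bonds = bonds)
}

.parse_v2000 <- function(ct) {
  counts <- ct[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("malformed V2000 counts line")
  if (length(ct) < 4 + na + nb) stop("V2000 block shorter than counts declare")
  elem <- character(na); chg <- integer(na)
  # old-style charge column codes: 1..3 -> +3..+1, 5..7 -> -1..-3
  old_chg <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (k in seq_len(na)) {
    ln <- ct[4 + k]
    el <- trimws(substr(ln, 32, 34))
    if (!nzchar(el)) {  # tolerate loosely formatted test files
      el <- strsplit(trimws(ln), "\\s+")[[1]][4]
    }
    elem[k] <- el
    cc <- trimws(substr(ln, 37, 39))
    chg[k] <- if (cc %in% names(old_chg)) old_chg[[cc]] else 0L
  }
  bi <- bj <- bo <- integer(nb)
  for (k in seq_len(nb)) {
    ln <- ct[4 + na + k]
    bi[k] <- as.integer(substr(ln, 1, 3))
    bj[k] <- as.integer(substr(ln, 4, 6))
    bo[k] <- as.integer(substr(ln, 7, 9))
  }
  # M  CHG property lines supersede the atom-block charge column
  chg_lines <- ct[startsWith(ct, "M  CHG")]
  if (length(chg_lines) > 0) {
    chg[] <- 0L
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      n_pairs <- f[1]
      for (p in seq_len(n_pairs)) {
        chg[f[2 * p]] <- f[2 * p + 1]
      }
    }
  }
  list(atoms = tibble::tibble(element = elem, charge = chg),
       bonds = tibble::tibble(i = bi, j = bj, order = bo))
}

# add hydrogens to fill neutral (charge-adjusted) valences
.fill_implicit_h <- function(atoms, bonds) {
  bad <- setdiff(unique(atoms$element), names(ATOM_VALENCE))
  if (length(bad) > 0) {
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  n <- nrow(atoms)
  deg <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    deg[bonds$i[k]] <- deg[bonds$i[k]] + bonds$order[k]
    deg[bonds$j[k]] <- deg[bonds$j[k]] + bonds$order[k]
  }
  nh <- ATOM_VALENCE[atoms$element] + atoms$charge - deg
  nh[atoms$element == "H"] <- 0
  to_add <- which(nh > 0)
  if (length(to_add) > 0) {
    extra <- sum(nh[to_add])
    atoms <- dplyr::bind_rows(
      atoms,
      tibble::tibble(element = rep("H", extra), charge = 0L)
    )
    h_idx <- n + seq_len(extra)
    heavy <- rep(to_add, nh[to_add])
    bonds <- dplyr::bind_rows(
      bonds,
      tibble::tibble(i = heavy, j = h_idx, order = 1L)
    )
  }
  list(atoms = atoms, bonds = bonds)
}

#' Turn labeled windows into tagged molecular graphs
#'
#' @param windows Tibble from [peptide_windows()] or [build_dataset()].
#' @param endpoint Optional endpoint name; when given, each record gets an
#'   `EFFECT` tag (1 = resistant, 0 = non-resistant).
#' @return List of `mol_graph` objects ready for [write_sdf()].
#' @export
window_graphs <- function(windows, endpoint = NULL) {
  stopifnot(is.data.frame(windows))
  labels <- NULL
  if (!is.null(endpoint)) {
    if (identical(endpoint, "label") && "label" %in% names(windows)) {
      labels <- windows$label
    } else {
      if (!endpoint %in% names(windows)) {
        stop("unknown endpoint '", endpoint, "'", call. = FALSE)
      }
      labels <- .as_binary_label(windows[[endpoint]], endpoint)
    }
  }
  purrr::map(seq_len(nrow(windows)), function(r) {
    row <- windows[r, ]
    tg <- .window_tags(row)
    if (!is.null(labels)) tg$EFFECT <- as.character(labels[r])
    peptide_graph(row$window, tags = tg)
  })
}
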