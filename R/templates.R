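# Residue templates: free neutral amino acids with explicit hydrogens.
#
# Each template is defined by its heavy-atom skeleton (PDB-style atom names,
# elements implied by the first letter) plus bond orders; hydrogens are added
# programmatically to complete neutral valences (C4, N3, O2, S2). Aromatic and
# amide systems are stored in a fixed Kekule form. Histidine is the
# N-epsilon-2 H tautomer; Asp/Glu/Lys/Arg are neutral; Cys carries a free
# thiol. These conventions make descriptor generation deterministic.

#' @keywords internal
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# neutral valences of the peptide atom alphabet
ATOM_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, H = 1L)

# bond helper: from, to, order
.bd <- function(a, b, o = 1L) list(a = a, b = b, o = as.integer(o))

# Side-chain definitions. Atom elements are the first letter of the name.
# Backbone atoms N, CA, C, O, OXT and their bonds are shared by all residues.
.side_chains <- function() {
  list(
    G = list(atoms = character(), bonds = list()),
    A = list(atoms = "CB", bonds = list(.bd("CA", "CB"))),
    V = list(atoms = c("CB", "CG1", "CG2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG1"), .bd("CB", "CG2"))),
    L = list(atoms = c("CB", "CG", "CD1", "CD2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "CD1"), .bd("CG", "CD2"))),
    I = list(atoms = c("CB", "CG1", "CG2", "CD1"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG1"),
                          .bd("CB", "CG2"), .bd("CG1", "CD1"))),
    S = list(atoms = c("CB", "OG"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "OG"))),
    T = list(atoms = c("CB", "OG1", "CG2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "OG1"), .bd("CB", "CG2"))),
    C = list(atoms = c("CB", "SG"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "SG"))),
    M = list(atoms = c("CB", "CG", "SD", "CE"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "SD"), .bd("SD", "CE"))),
    D = list(atoms = c("CB", "CG", "OD1", "OD2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "OD1", 2L), .bd("CG", "OD2"))),
    N = list(atoms = c("CB", "CG", "OD1", "ND2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "OD1", 2L), .bd("CG", "ND2"))),
    E = list(atoms = c("CB", "CG", "CD", "OE1", "OE2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                          .bd("CD", "OE1", 2L), .bd("CD", "OE2"))),
    Q = list(atoms = c("CB", "CG", "CD", "OE1", "NE2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                          .bd("CD", "OE1", 2L), .bd("CD", "NE2"))),
    K = list(atoms = c("CB", "CG", "CD", "CE", "NZ"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                          .bd("CD", "CE"), .bd("CE", "NZ"))),
    R = list(atoms = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                          .bd("CD", "NE"), .bd("NE", "CZ"),
                          .bd("CZ", "NH1", 2L), .bd("CZ", "NH2"))),
    H = list(atoms = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "ND1"), .bd("ND1", "CE1", 2L),
                          .bd("CE1", "NE2"), .bd("NE2", "CD2"),
                          .bd("CD2", "CG", 2L))),
    F = list(atoms = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "CD1", 2L), .bd("CD1", "CE1"),
                          .bd("CE1", "CZ", 2L), .bd("CZ", "CE2"),
                          .bd("CE2", "CD2", 2L), .bd("CD2", "CG"))),
    Y = list(atoms = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "CD1", 2L), .bd("CD1", "CE1"),
                          .bd("CE1", "CZ", 2L), .bd("CZ", "CE2"),
                          .bd("CE2", "CD2", 2L), .bd("CD2", "CG"),
                          .bd("CZ", "OH"))),
    W = list(atoms = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                       "CZ2", "CZ3", "CH2"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "CD1", 2L), .bd("CD1", "NE1"),
                          .bd("NE1", "CE2"), .bd("CE2", "CD2"),
                          .bd("CD2", "CG"), .bd("CD2", "CE3", 2L),
                          .bd("CE3", "CZ3"), .bd("CZ3", "CH2", 2L),
                          .bd("CH2", "CZ2"), .bd("CZ2", "CE2", 2L))),
    P = list(atoms = c("CB", "CG", "CD"),
             bonds = list(.bd("CA", "CB"), .bd("CB", "CG"),
                          .bd("CG", "CD"), .bd("CD", "N")))
  )
}

# cache of processed templates
.template_env <- new.env(parent = emptyenv())

#' Residue template of one standard amino acid
#'
#' Returns the free neutral amino acid as an explicit-hydrogen molecular
#' graph, plus the anchor atom indices used when residues are condensed
#' into a peptide (backbone N, carbonyl C, the carboxyl OH oxygen and its
#' hydrogen, and one amine hydrogen).
#'
#' @param code One-letter amino-acid code (one of the 20 standard residues).
#' @return A list with elements `atoms` (tibble: `name`, `element`,
#'   `charge`), `bonds` (tibble: `i`, `j`, `order`), and integer anchor
#'   indices `n_idx`, `c_idx`, `oxt_idx`, `oxt_h_idx`, `n_h_idx`.
#' @examples
#' tpl <- residue_template("G")
#' nrow(tpl$atoms)  # 10 atoms in glycine
#' @export
residue_template <- function(code) {
  stopifnot(is.character(code), length(code) == 1)
  if (!code %in% AA_CODES) {
    stop("unknown or nonstandard residue code: '", code,
         "' (only the 20 standard one-letter codes are supported)",
         call. = FALSE)
  }
  key <- paste0("tpl_", code)
  if (!is.null(.template_env[[key]])) return(.template_env[[key]])

  sc <- .side_chains()[[code]]
  heavy_names <- c("N", "CA", "C", "O", "OXT", sc$atoms)
  heavy_elem <- substr(heavy_names, 1, 1)
  bonds <- c(list(.bd("N", "CA"), .bd("CA", "C"),
                  .bd("C", "O", 2L), .bd("C", "OXT")),
             sc$bonds)
  idx <- stats::setNames(seq_along(heavy_names), heavy_names)
  bi <- vapply(bonds, function(b) idx[[b$a]], integer(1))
  bj <- vapply(bonds, function(b) idx[[b$b]], integer(1))
  bo <- vapply(bonds, function(b) b$o, integer(1))

  # fill hydrogens to neutral valence
  deg <- numeric(length(heavy_names))
  for (k in seq_along(bi)) {
    deg[bi[k]] <- deg[bi[k]] + bo[k]
    deg[bj[k]] <- deg[bj[k]] + bo[k]
  }
  n_h <- ATOM_VALENCE[heavy_elem] - deg
  if (any(n_h < 0)) {
    stop("internal error: over-valent heavy atom in template ", code)
  }
  names_all <- heavy_names
  elem_all <- heavy_elem
  h_of <- integer(0)  # heavy-atom index of each hydrogen
  for (a in seq_along(heavy_names)) {
    if (n_h[a] > 0) {
      hn <- paste0("H", heavy_names[a], seq_len(n_h[a]))
      names_all <- c(names_all, hn)
      elem_all <- c(elem_all, rep("H", n_h[a]))
      h_of <- c(h_of, rep(a, n_h[a]))
    }
  }
  h_idx <- seq.int(length(heavy_names) + 1L, length.out = length(h_of))
  bi <- c(bi, h_of)
  bj <- c(bj, h_idx)
  bo <- c(bo, rep(1L, length(h_of)))

  tpl <- list(
    code = code,
    atoms = tibble::tibble(name = names_all, element = elem_all,
                           charge = 0L),
    bonds = tibble::tibble(i = as.integer(bi), j = as.integer(bj),
                           order = as.integer(bo)),
    n_idx = idx[["N"]],
    c_idx = idx[["C"]],
    oxt_idx = idx[["OXT"]],
    oxt_h_idx = h_idx[match(idx[["OXT"]], h_of)],
    n_h_idx = h_idx[match(idx[["N"]], h_of)]
  )
  .template_env[[key]] <- tpl
  tpl
}

# molecular formula of a residue template (used by tests and diagnostics)
.template_formula_counts <- function(code) {
  tpl <- residue_template(code)
  table(tpl$atoms$element)
}
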