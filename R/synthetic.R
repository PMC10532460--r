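# Synthetic study-condition generator: a protein plus labeled
# substitutions with a plantable, learnable sequence-context signal.
#
# The defaults emulate the real training conditions the package targets:
# one kinase-sized protein (1130 residues), 660 substitutions of which a
# 84/660 fraction is resistant, and a contextual signal in which a motif
# residue within two positions of the substitution raises the resistance
# probability. signal_strength = 0.68 is the strongest motif-label
# coupling compatible with that prevalence under this motif geometry
# (see the methods vignette).

#' Simulate a protein sequence
#'
#' Residues are drawn independently and uniformly from the 20 standard
#' codes (or from approximate natural vertebrate frequencies).
#'
#' @param seq_length Number of residues (at least 31).
#' @param seed Integer seed; the result is reproducible per seed.
#' @param composition `"uniform"` (default) or `"natural"`.
#' @param id Sequence identifier.
#' @return One-row tibble with `id` and `residues`.
#' @export
simulate_protein <- function(seq_length = 1130L, seed = 1L,
                             composition = c("uniform", "natural"),
                             id = "synthetic_protein") {
  composition <- match.arg(composition)
  stopifnot(seq_length >= 31)
  prob <- if (composition == "uniform") {
    rep(1 / 20, 20)
  } else {
    # approximate residue frequencies in vertebrate proteomes
    c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047, G = 0.074,
      H = 0.026, I = 0.068, K = 0.058, L = 0.099, M = 0.025, N = 0.045,
      P = 0.039, Q = 0.034, R = 0.042, S = 0.058, T = 0.051, V = 0.073,
      W = 0.013, Y = 0.033)[AA_CODES]
  }
  res <- withr::with_seed(seed, {
    sample(AA_CODES, seq_length, replace = TRUE, prob = prob)
  })
  tibble::tibble(id = id, residues = paste(res, collapse = ""))
}

#' Simulate labeled substitution data
#'
#' Samples substitution positions without replacement, draws an alternate
#' residue for each, and assigns binary resistance labels. In `"motif"`
#' mode a substitution whose flanking context (within `motif_radius`
#' positions on either side, the center excluded since it is mutated)
#' contains at least one motif residue is labeled resistant with
#' probability `signal_strength`; other substitutions use a baseline
#' probability derived so the expected positive fraction equals
#' `positive_fraction`. In `"none"` mode labels are independent of
#' context. In motif mode the alternate residue is drawn from the
#' non-reference residues excluding the motif residues, so the planted
#' context signal stays confined to the flanks.
#'
#' @param n_substitutions Number of substitution records.
#' @param positive_fraction Expected fraction labeled resistant.
#' @param seq_length Protein length passed to [simulate_protein()].
#' @param signal_mode `"motif"` (default) or `"none"`.
#' @param motif_residues Residues whose flanking presence carries signal.
#' @param motif_radius Context half-width in residues.
#' @param signal_strength Resistance probability given a motif context.
#' @param endpoint Name of the label column in the output.
#' @param composition Residue composition of the protein.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return List with `protein` (one-row tibble) and `substitutions`
#'   (tibble: `protein_id`, `position`, `ref`, `alt`, label column).
#' @export
simulate_resistance_data <- function(n_substitutions = 660L,
                                     positive_fraction = 84 / 660,
                                     seq_length = 1130L,
                                     signal_mode = c("motif", "none"),
                                     motif_residues = "W",
                                     motif_radius = 2L,
                                     signal_strength = 0.68,
                                     endpoint = "resistance",
                                     composition = "uniform",
                                     seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(positive_fraction > 0, positive_fraction < 1,
            motif_radius >= 0, n_substitutions >= 2)
  if (n_substitutions > seq_length) {
    stop("n_substitutions exceeds the number of positions", call. = FALSE)
  }
  protein <- simulate_protein(seq_length, seed = seed,
                              composition = composition)
  seq_chr <- strsplit(protein$residues, "")[[1]]

  baseline <- positive_fraction
  if (signal_mode == "motif") {
    # theoretical motif-context prevalence under the chosen composition;
    # feasibility is judged here so the error is deterministic
    p_res <- if (identical(composition, "uniform")) {
      length(motif_residues) / 20
    } else {
      stop("motif mode currently assumes uniform composition", call. = FALSE)
    }
    q <- 1 - (1 - p_res)^(2 * motif_radius)
    baseline <- (positive_fraction - q * signal_strength) / (1 - q)
    if (baseline < -1e-8) {
      stop("infeasible parameters: motif prevalence ", signif(q, 3),
           " times signal_strength ", signal_strength,
           " already exceeds positive_fraction ",
           signif(positive_fraction, 3), call. = FALSE)
    }
    baseline <- max(0, baseline)
  }

  withr::with_seed(seed + 1L, {
    positions <- sort(sample.int(seq_length, n_substitutions))
    ref <- seq_chr[positions]
    alt_pool <- if (signal_mode == "motif") {
      setdiff(AA_CODES, motif_residues)
    } else {
      AA_CODES
    }
    alt <- vapply(ref, function(r) {
      sample(setdiff(alt_pool, r), 1)
    }, character(1), USE.NAMES = FALSE)
    if (signal_mode == "motif") {
      has_motif <- vapply(positions, function(p) {
        fl <- setdiff(seq(max(1, p - motif_radius),
                          min(seq_length, p + motif_radius)), p)
        any(seq_chr[fl] %in% motif_residues)
      }, logical(1))
      p_lab <- ifelse(has_motif, signal_strength, baseline)
    } else {
      p_lab <- rep(positive_fraction, n_substitutions)
    }
    labels <- stats::rbinom(n_substitutions, 1L, p_lab)
  })

  subs <- tibble::tibble(
    protein_id = protein$id, position = positions, ref = ref, alt = alt
  )
  subs[[endpoint]] <- as.integer(labels)
  list(protein = protein, substitutions = subs)
}
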