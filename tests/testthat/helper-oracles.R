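# Independent oracles used by the tests. Deliberately naive: plain
# recursion, pair enumeration and refit-from-scratch, sharing no code
# with the implementation they check.

# adjacency list of a mol_graph
oracle_neighbors <- function(graph) {
  n <- nrow(graph$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# naive recursive MNA descriptor (exponential, small inputs only)
oracle_mna <- function(graph, atom, level, nb = oracle_neighbors(graph)) {
  mk <- paste0(
    ifelse(graph$atoms$in_ring[atom], "", "-"),
    graph$atoms$element[atom],
    ifelse(graph$atoms$charge[atom] != 0,
           sprintf("[%+d]", graph$atoms$charge[atom]), "")
  )
  if (level == 0) return(mk)
  sub <- vapply(nb[[atom]], function(b) oracle_mna(graph, b, level - 1, nb),
                character(1))
  paste0(mk, "(", paste(sort(sub, method = "radix"), collapse = ""), ")")
}

oracle_mna_set <- function(graph, level) {
  nb <- oracle_neighbors(graph)
  s <- vapply(seq_len(nrow(graph$atoms)),
              function(a) oracle_mna(graph, a, level, nb), character(1))
  sort(unique(s), method = "radix")
}

# ring atoms by edge-removal reachability: an edge lies on a cycle iff
# its endpoints stay connected without it; ring atoms are the endpoints
# of such edges
oracle_ring_atoms <- function(graph) {
  n <- nrow(graph$atoms)
  bonds <- graph$bonds
  reachable <- function(from, to, skip) {
    seen <- rep(FALSE, n); seen[from] <- TRUE
    queue <- from
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(nrow(bonds))) {
        if (k == skip) next
        w <- if (bonds$i[k] == v) bonds$j[k] else if (bonds$j[k] == v)
          bonds$i[k] else next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[to]
  }
  in_ring <- rep(FALSE, n)
  for (k in seq_len(nrow(bonds))) {
    if (reachable(bonds$i[k], bonds$j[k], skip = k)) {
      in_ring[c(bonds$i[k], bonds$j[k])] <- TRUE
    }
  }
  in_ring
}

# AUC by exhaustive pair enumeration
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# leave-one-out by full refit per held-out structure
oracle_loo_scores <- function(sets, labels, level = 0L) {
  vapply(seq_along(sets), function(s) {
    fit <- sprpep:::.spr_fit_sets(sets[-s], labels[-s], level, NA_integer_,
                                  "oracle")
    b_score(sets[[s]], fit)$Bk
  }, numeric(1))
}

# random connected multigraph-free atom graph (chemically meaningless on
# purpose: descriptors must not care)
random_graph <- function(n_atoms = sample(4:9, 1), p_extra = 0.3,
                         charged = TRUE) {
  els <- sample(c("C", "N", "O", "S", "H"), n_atoms, replace = TRUE)
  chg <- if (charged) sample(c(-1L, 0L, 0L, 0L, 1L), n_atoms, replace = TRUE)
         else rep(0L, n_atoms)
  bonds <- NULL
  for (v in seq_len(n_atoms)[-1]) {
    bonds <- rbind(bonds, c(sample(v - 1L, 1), v))
  }
  if (n_atoms >= 3 && stats::runif(1) < p_extra) {
    cand <- t(utils::combn(n_atoms, 2))
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    cand <- cand[!paste(cand[, 1], cand[, 2]) %in% key, , drop = FALSE]
    if (nrow(cand) > 0) {
      pick <- cand[sample(nrow(cand), 1), , drop = FALSE]
      bonds <- rbind(bonds, pick)
    }
  }
  mol_graph(data.frame(element = els, charge = chg),
            data.frame(i = bonds[, 1], j = bonds[, 2]))
}

# small labeled descriptor-set fixture with overlapping vocabularies
toy_sets <- function(n = 20, n_pos = 7, vocab = letters[1:10], seed = 42) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n), function(i) {
      sort(sample(vocab, sample(3:6, 1)))
    })
    labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    # give positives a slight vocabulary bias so scores spread out
    sets[seq_len(n_pos)] <- lapply(sets[seq_len(n_pos)], function(s) {
      sort(unique(c(s, sample(c("a", "b"), 1))))
    })
    list(sets = sets, labels = labels)
  })
}
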