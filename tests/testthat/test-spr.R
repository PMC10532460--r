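# The Bayes-like scorer: counts, B-scores, LOO calibration, prediction.

test_that("training counts are plain frequency tallies", {
  sets <- list(c("a", "b"), c("a"), c("b", "c"), c("c"))
  labels <- c(1L, 1L, 0L, 0L)
  fit <- sprpep:::.spr_fit_sets(sets, labels, 0L, NA_integer_, "toy")
  expect_identical(fit$N, 4L)
  expect_identical(fit$Nk, 2L)
  expect_identical(fit$descriptors, c("a", "b", "c"))
  expect_identical(fit$Ni, c(2L, 2L, 2L))
  expect_identical(fit$Nik, c(2L, 1L, 0L))
  expect_error(
    sprpep:::.spr_fit_sets(sets, c(0L, 0L, 0L, 0L), 0L, NA_integer_, "x"),
    "each class"
  )
})

test_that("b_score reproduces hand-evaluated cases", {
  # N = 4, Nk = 2 so S0 = 0; P = 0.75 and 0.25 cancel in arcsine space
  fit <- list(descriptors = c("p75", "p25"), Ni = c(4L, 4L),
              Nik = c(3L, 1L), N = 4L, Nk = 2L)
  sc <- b_score(c("p75", "p25"), fit)
  expect_equal(sc$Sk, 0, tolerance = 1e-12)
  expect_identical(sc$Bk, 0)

  # a single descriptor with P(A|D) = 1 drives S to 1 and B to 1
  fit2 <- list(descriptors = "d", Ni = 2L, Nik = 2L, N = 6L, Nk = 2L)
  sc2 <- b_score("d", fit2)
  expect_equal(sc2$Bk, 1)

  # descriptors at the prior leave B at 0
  fit3 <- list(descriptors = c("x", "y"), Ni = c(4L, 2L), Nik = c(2L, 1L),
               N = 8L, Nk = 4L)
  expect_identical(b_score(c("x", "y"), fit3)$Bk, 0)

  # a query with no known descriptor is flagged, B = 0
  sc4 <- b_score(c("zz"), fit2)
  expect_identical(sc4$Bk, 0)
  expect_identical(sc4$m, 0L)
  expect_identical(sc4$n_new, 1L)
})

test_that("decrement-based LOO equals refit-from-scratch LOO exactly", {
  toy <- toy_sets(n = 20, n_pos = 7)
  fit <- sprpep:::.spr_fit_sets(toy$sets, toy$labels, 0L, NA_integer_, "toy")
  expect_identical(fit$loo_scores,
                   oracle_loo_scores(toy$sets, toy$labels))
  expect_length(fit$calib$pos, 7)
  expect_length(fit$calib$neg, 13)
})

test_that("identical structures collapse to one LOO score per class", {
  sets <- c(rep(list(c("a", "b")), 4), rep(list(c("c", "d")), 6))
  labels <- c(rep(1L, 4), rep(0L, 6))
  fit <- sprpep:::.spr_fit_sets(sets, labels, 0L, NA_integer_, "toy")
  expect_length(unique(fit$loo_scores[labels == 1L]), 1)
  expect_length(unique(fit$loo_scores[labels == 0L]), 1)
  expect_gt(fit$loo_scores[1], fit$loo_scores[10])
})

test_that("label inversion flips the sign of every B-score", {
  toy <- toy_sets(n = 18, n_pos = 6, seed = 9)
  fit_pos <- sprpep:::.spr_fit_sets(toy$sets, toy$labels, 0L, NA_integer_, "a")
  fit_neg <- sprpep:::.spr_fit_sets(toy$sets, 1L - toy$labels, 0L,
                                    NA_integer_, "a")
  for (q in toy$sets[c(1, 5, 12)]) {
    expect_equal(b_score(q, fit_neg)$Bk, -b_score(q, fit_pos)$Bk,
                 tolerance = 1e-12)
  }
  expect_equal(fit_neg$loo_scores, -fit_pos$loo_scores, tolerance = 1e-12)
})

test_that("B stays in [-1, 1] on fuzzed count configurations", {
  withr::with_seed(77, {
    for (rep in 1:200) {
      nd <- sample(1:6, 1)
      n <- sample(2:30, 1)
      nk <- sample(seq_len(n - 1), 1)
      ni <- sample(seq_len(n), nd, replace = TRUE)
      nik <- vapply(ni, function(x) sample(0:min(x, nk), 1), integer(1))
      fit <- list(descriptors = paste0("d", seq_len(nd)),
                  Ni = ni, Nik = nik, N = n, Nk = nk)
      b <- b_score(paste0("d", seq_len(nd)), fit)$Bk
      expect_true(b >= -1 && b <= 1)
    }
  })
})

test_that("prediction calibrates B into monotone Pa/Pi with domain flags", {
  toy <- toy_sets(n = 24, n_pos = 8, seed = 3)
  fit <- sprpep:::.spr_fit_sets(toy$sets, toy$labels, 0L, NA_integer_, "toy")
  hi <- predict(fit, list(structure(list(descriptors = c("a", "b")),
                                    class = "mna_set")))
  expect_true(hi$Pa >= 0 && hi$Pa <= 1 && hi$Pi >= 0 && hi$Pi <= 1)
  # a B above every calibration score gives the extreme Pa/Pi
  fit_x <- fit
  fit_x$calib <- list(pos = c(-0.5, -0.2, 0.1), neg = c(-0.9, -0.6, -0.4))
  p_hi <- sprpep:::.pa_of(0.9, fit_x$calib$pos)
  p_lo <- sprpep:::.pi_of(0.9, fit_x$calib$neg)
  expect_identical(p_hi, 1)
  expect_identical(p_lo, 0)

  # monotonicity of the mid-rank CDFs
  bs <- seq(-1, 1, by = 0.05)
  pas <- vapply(bs, sprpep:::.pa_of, numeric(1), pos = fit$calib$pos)
  pis <- vapply(bs, sprpep:::.pi_of, numeric(1), neg = fit$calib$neg)
  expect_true(all(diff(pas) >= 0))
  expect_true(all(diff(pis) <= 0))
  expect_true(all(pas >= 0 & pas <= 1 & pis >= 0 & pis <= 1))

  # unseen-only query: flagged out of domain
  unk <- predict(fit, list(c("nope1", "nope2")))
  expect_identical(unk$B, 0)
  expect_identical(unk$n_new_descriptors, 2L)
  expect_true(unk$out_of_domain)
  expect_identical(unk$n_descriptors, 2L)
})

test_that("prediction with own-structure exclusion reproduces calibration", {
  toy <- toy_sets(n = 15, n_pos = 5, seed = 21)
  fit <- sprpep:::.spr_fit_sets(toy$sets, toy$labels, 0L, NA_integer_, "toy")
  for (s in c(2, 9, 15)) {
    refit <- sprpep:::.spr_fit_sets(toy$sets[-s], toy$labels[-s], 0L,
                                    NA_integer_, "toy")
    expect_identical(b_score(toy$sets[[s]], refit)$Bk, fit$loo_scores[s])
  }
})

test_that("a fitted model round-trips through JSON serialization", {
  sim <- simulate_resistance_data(n_substitutions = 60, seq_length = 200,
                                  positive_fraction = 0.3,
                                  signal_strength = 0.5, seed = 4)
  ds <- build_dataset(sim$substitutions, sim$protein, "resistance", 3)
  model <- spr_fit(ds, level = 1)
  path <- withr::local_tempfile(fileext = ".json")
  spr_model_write(model, path)
  back <- spr_model_read(path)
  expect_identical(back$descriptors, model$descriptors)
  expect_identical(back$Ni, model$Ni)
  expect_identical(back$Nik, model$Nik)
  expect_identical(back$loo_scores, model$loo_scores)
  expect_identical(back$labels, model$labels)
  expect_identical(back$level, model$level)
  expect_identical(back$nominal_length, model$nominal_length)
  q <- ds[3, ]
  expect_identical(predict(back, q), predict(model, q))
})

test_that("tidy and glance expose counts and model coordinates", {
  toy <- toy_sets(n = 16, n_pos = 6, seed = 2)
  fit <- sprpep:::.spr_fit_sets(toy$sets, toy$labels, 2L, 5L, "imatinib")
  td <- tidy(fit)
  expect_identical(td$descriptor, fit$descriptors)
  expect_identical(td$p_cond, fit$Nik / fit$Ni)
  gl <- glance(fit)
  expect_identical(gl$n, 16L)
  expect_identical(gl$endpoint, "imatinib")
  expect_identical(gl$level, 2L)
  expect_identical(gl$window_length, 5L)
})
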