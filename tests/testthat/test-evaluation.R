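test_that("modified z-score follows the median/MAD formula", {
  # matrix of 1..400: median 200.5, MAD 100
  e <- new_energy_matrix(matrix(as.numeric(1:400), 20, 20))
  expect_equal(modified_zscore(e, c("A", "A")), (1 - 200.5) / 100)
  # entry at the median scores 0
  v <- unclass(e)
  pair_at_median <- which(v == 200, arr.ind = TRUE)
  aa <- aa_alphabet()
  expect_equal(modified_zscore(e, c(aa[pair_at_median[1]], aa[pair_at_median[2]])),
               -0.5 / 100)
  # random matrices match an independent median/MAD recomputation
  set.seed(12)
  for (k in 1:20) {
    m <- new_energy_matrix(matrix(stats::rnorm(400), 20, 20))
    pair <- sample(aa, 2, replace = TRUE)
    v <- as.numeric(unclass(m))
    want <- (unclass(m)[pair[1], pair[2]] - stats::median(v)) /
      stats::median(abs(v - stats::median(v)))
    expect_equal(modified_zscore(m, pair), want, tolerance = 1e-12)
  }
  # degenerate constant matrix
  expect_warning(z <- modified_zscore(new_energy_matrix(matrix(1, 20, 20)),
                                      c("A", "V")), "undefined")
  expect_true(is.na(z))
})

test_that("native identification ranks by a full-sort oracle with lexicographic ties", {
  aa <- aa_alphabet()
  set.seed(23)
  for (k in 1:25) {
    e <- new_energy_matrix(matrix(stats::rnorm(400), 20, 20))
    native <- sample(aa, 2, replace = TRUE)
    res <- identify_native(e, native)
    v <- unclass(e)
    # oracle: order all 400 energies ascending, find native position
    flat <- expand.grid(i = 1:20, j = 1:20)
    flat$e <- v[cbind(flat$i, flat$j)]
    flat <- flat[order(flat$e, flat$i, flat$j), ]
    want_rank <- which(flat$i == match(native[1], aa) &
                         flat$j == match(native[2], aa))
    expect_equal(res$rank, want_rank)
    expect_equal(res$identified, want_rank == 1L)
    expect_equal(v[res$best_i, res$best_j], min(v))
  }
  # unique minimum at the native pair
  e <- new_energy_matrix(matrix(0, 20, 20) + 1)
  em <- unclass(e); em["K", "E"] <- -5
  e <- new_energy_matrix(em)
  res <- identify_native(e, c("K", "E"))
  expect_true(res$identified); expect_equal(res$rank, 1L)
  # constant matrix: lexicographic tie-break, A-A wins
  cst <- new_energy_matrix(matrix(2, 20, 20))
  expect_true(identify_native(cst, c("A", "A"))$identified)
  expect_false(identify_native(cst, c("A", "R"))$identified)
})

test_that("enrichment is the identified fraction over 1/400", {
  res_all <- tibble::tibble(identified = rep(TRUE, 10))
  expect_equal(enrichment(res_all), 400)
  res_none <- tibble::tibble(identified = rep(FALSE, 10))
  expect_equal(enrichment(res_none), 0)
  # a predictor stuck on one pair identifies at the native frequency f
  set.seed(9)
  f <- 0.08
  natives <- stats::rbinom(10000, 1, f) == 1
  expect_equal(enrichment(tibble::tibble(identified = natives)), 400 * f,
               tolerance = 0.08)
  # uniformly random predictor -> enrichment ~ 1
  rand <- stats::runif(10000) < 1 / 400
  expect_equal(enrichment(tibble::tibble(identified = rand)), 1, tolerance = 0.45)
})

test_that("coupling sweep recovers perfect and inverted correlations", {
  pm <- random_planted_model(3, j_sd = 1)
  ens <- generate_planted_ensemble(pm, n_matches = 4000, seed = 11)
  sce <- symmetrize(sce_matrix(ens, flat_background()))
  aa <- aa_alphabet()
  set.seed(2)
  pairs <- tibble::tibble(aa_i = sample(aa, 15, TRUE), aa_j = sample(aa, 15, TRUE))
  pairs <- dplyr::distinct(pairs)
  exp_tab <- pairs
  exp_tab$energy <- unclass(sce)[cbind(match(pairs$aa_i, aa), match(pairs$aa_j, aa))]
  sweep <- coupling_sweep(ens, flat_background(),
                          list(list(max_matches = n_matches(ens))), exp_tab)
  expect_equal(sweep$r, 1, tolerance = 1e-9)
  exp_tab$energy <- -exp_tab$energy
  sweep2 <- coupling_sweep(ens, flat_background(),
                           list(list(max_matches = n_matches(ens))), exp_tab)
  expect_equal(sweep2$r, -1, tolerance = 1e-9)
  # fewer than 3 overlapping pairs -> NA flagged
  sweep3 <- coupling_sweep(ens, flat_background(),
                           list(list(max_matches = 10)), exp_tab[1:2, ])
  expect_true(is.na(sweep3$r) || sweep3$n_matches == 10)
})

test_that("heterotypic experimental pairs use the symmetrized energy", {
  pm <- random_planted_model(5, j_sd = 1.2)
  ens <- generate_planted_ensemble(pm, n_matches = 3000, seed = 13)
  sce <- sce_matrix(ens, flat_background())
  sym <- symmetrize(sce)
  tab <- tibble::tibble(aa_i = c("K", "E", "L"), aa_j = c("E", "K", "V"))
  tab$energy <- unclass(sym)[cbind(aa_index(tab$aa_i), aa_index(tab$aa_j))]
  sw <- coupling_sweep(ens, flat_background(),
                       list(list(max_matches = 3000)), tab)
  expect_equal(sw$r, 1, tolerance = 1e-9)
})

test_that("AUC equals the all-pairs U statistic and behaves at the limits", {
  # 6-model hand example
  score <- c(3, 2.5, 2, 1.5, 1, 0.5)
  quality <- c(60, 55, 45, 58, 30, 20)
  roc <- roc_auc(score, quality, threshold = 50, direction = "ge")
  # oracle: count concordant pairs over all (pos, neg) pairs
  pos <- which(quality >= 50); neg <- which(quality < 50)
  u <- 0
  for (p in pos) for (q in neg) {
    u <- u + (score[p] > score[q]) + 0.5 * (score[p] == score[q])
  }
  expect_equal(roc$auc, u / (length(pos) * length(neg)))
  # perfect separation
  expect_equal(roc_auc(c(4, 3, 2, 1), c(80, 70, 20, 10), 50)$auc, 1)
  # complement symmetry without ties
  set.seed(17)
  s <- stats::rnorm(50); q <- stats::rnorm(50)
  expect_equal(roc_auc(s, q, 0)$auc + roc_auc(-s, q, 0)$auc, 1, tolerance = 1e-12)
  # label-independent scores at large n -> ~0.5
  s2 <- stats::rnorm(4000); q2 <- stats::rnorm(4000)
  expect_equal(roc_auc(s2, q2, 0)$auc, 0.5, tolerance = 0.05)
  # RMSD-style direction: low quality values are positives
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 2, 8, 9), 5, direction = "le")$auc, 1)
  # degenerate class
  expect_warning(r0 <- roc_auc(1:3, c(1, 2, 3), 0), "empty")
  expect_true(is.na(r0$auc))
})

test_that("AUC agrees with pROC on random data", {
  set.seed(31)
  s <- stats::rnorm(300)
  lab <- stats::rbinom(300, 1, plogis(s))
  got <- roc_auc(s, lab, threshold = 1)$auc
  want <- as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                         direction = "<", levels = c(0, 1))))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("model scoring is deterministic and flags empty contact sets", {
  db <- fixture_db(8, seed = 3, sigma = 4)
  bg <- flat_background()
  lib <- toy_rotamer_library(2)
  cp <- contact_potential(null_contact_records(500, seed = 5))
  s <- db[[1]]
  sc1 <- score_model(s, db, bg, lib, cp, flank = 1, cd_min = 0.1)
  sc2 <- score_model(s, db, bg, lib, cp, flank = 1, cd_min = 0.1)
  expect_identical(sc1, sc2)
  expect_gt(sc1$n_contacts, 0)
  expect_true(is.finite(sc1$mean_sce))
  # impossible CD threshold -> flagged
  none <- score_model(s, db, bg, lib, cp, flank = 1, cd_min = 1.1)
  expect_true(none$flagged)
  expect_true(is.na(none$mean_sce))
})

test_that("alternating model selection spans best and worst", {
  models <- tibble::tibble(model = letters[1:7], quality = c(10, 70, 40, 90, 20, 60, 50))
  sel <- select_models_alternating(models, n = 4)
  expect_equal(sel$quality, c(90, 10, 70, 20))
  sel_all <- select_models_alternating(models, n = 99)
  expect_setequal(sel_all$model, models$model)
})
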