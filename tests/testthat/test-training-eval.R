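test_that("negative sampling is disjoint, exact and seed-sensitive", {
  # 4 drugs, 5 of the 6 unordered pairs positive: the last pair is forced
  pos <- pair_dataset(c("a", "a", "a", "b", "b"), c("b", "c", "d", "c", "d"),
                      rep(1, 5))
  expect_warning(ds <- sample_negatives(pos, ratio = 1, rng_seed = 1),
                 "only 1")
  neg <- ds[ds$label == 0, ]
  expect_equal(nrow(neg), 1L)
  expect_setequal(c(neg$drug1, neg$drug2), c("c", "d"))

  drugs <- sprintf("d%03d", 1:100)
  set.seed(8)
  i <- sample(100, 200, TRUE); j <- sample(100, 200, TRUE)
  ok <- i < j
  pos2 <- unique(data.frame(drug1 = drugs[i[ok]], drug2 = drugs[j[ok]]))
  pos2 <- pair_dataset(pos2$drug1, pos2$drug2, rep(1, nrow(pos2)))
  d1 <- sample_negatives(pos2, 1, rng_seed = 1, drugs = drugs)
  d2 <- sample_negatives(pos2, 1, rng_seed = 2, drugs = drugs)
  k1 <- with(d1[d1$label == 0, ], paste(drug1, drug2))
  k2 <- with(d2[d2$label == 0, ], paste(drug1, drug2))
  kp <- with(pos2, paste(drug1, drug2))
  expect_length(k1, nrow(pos2))
  expect_length(k2, nrow(pos2))
  expect_length(intersect(k1, kp), 0)
  expect_length(intersect(k2, kp), 0)
  expect_false(setequal(k1, k2))
})

test_that("rank AUC equals the brute-force concordance oracle", {
  set.seed(9)
  for (i in 1:10) {
    n <- 60
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2) # coarse scores force ties
    expect_equal(auc_score(y, s), auc_oracle(y, s), tolerance = 1e-9)
  }
  expect_true(is.na(auc_score(rep(1, 5), runif(5))))
})

test_that("classification metrics cover perfect and chance predictions", {
  y <- rep(c(0, 1), 10)
  perfect <- classification_metrics(y, y)
  expect_equal(unlist(perfect), c(accuracy = 1, auc = 1, f1 = 1))
  flat <- classification_metrics(y, rep(0.5, 20))
  expect_equal(flat$accuracy, 0.5) # 0.5 is classified negative
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$f1, 0)
})

test_that("stratified folds preserve the label ratio within one pair", {
  y <- c(rep(1, 33), rep(0, 67))
  fold <- smilegnn:::stratified_folds(y, 5, rng_seed = 3)
  for (k in 1:5) {
    expect_lte(abs(sum(y[fold == k] == 1) - 33 / 5), 1)
    expect_lte(abs(sum(y[fold == k] == 0) - 67 / 5), 1)
  }
})

test_that("training reduces the loss and is bit-reproducible", {
  sim <- small_sim(seed = 21)
  st <- struct_for(sim)
  cfg <- desk_config(5, epochs = 5, batch_size = 256)
  m1 <- train(sim$kg, st, sim$pairs, cfg)
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- train(sim$kg, st, sim$pairs, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # scoring is symmetric in pair order
  p1 <- predict(m1, data.frame(drug1 = sim$pairs$drug1[1:5],
                               drug2 = sim$pairs$drug2[1:5]))
  p2 <- predict(m1, data.frame(drug1 = sim$pairs$drug2[1:5],
                               drug2 = sim$pairs$drug1[1:5]))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("cross-validation evaluates held-out folds with stratification", {
  sim <- small_sim(seed = 22)
  st <- struct_for(sim)
  cfg <- desk_config(5, epochs = 4, batch_size = 256, n_folds = 3)
  ev <- evaluate_cv(sim$kg, st, sim$pairs, cfg)
  expect_equal(nrow(ev$per_fold), 3L)
  expect_true(all(ev$per_fold$auc >= 0 & ev$per_fold$auc <= 1))
  expect_equal(unname(ev$mean["auc"]), mean(ev$per_fold$auc))
})

test_that("novel-pair ranking filters, sorts and removes known positives", {
  sim <- small_sim(seed = 23)
  st <- struct_for(sim)
  m <- train(sim$kg, st, sim$pairs, desk_config(5, epochs = 6, batch_size = 256))
  drugs <- sim$latent$drugs
  cand <- expand.grid(drug1 = drugs[1:12], drug2 = drugs[1:12],
                      stringsAsFactors = FALSE)
  cand <- cand[cand$drug1 < cand$drug2, ]
  known <- sim$pairs[sim$pairs$label == 1, ]
  rk <- rank_novel_pairs(m, cand, known, threshold = 0.5)
  if (nrow(rk) > 1) expect_true(all(diff(rk$score) <= 0))
  expect_length(intersect(paste(rk$drug1, rk$drug2),
                          paste(known$drug1, known$drug2)), 0)
  expect_true(all(rk$score > 0.5))
  # exhaustive oracle: score everything, drop known, filter, sort
  sc <- predict(m, cand)
  keep <- !(paste(pmin(cand$drug1, cand$drug2), pmax(cand$drug1, cand$drug2))
            %in% paste(pmin(known$drug1, known$drug2),
                       pmax(known$drug1, known$drug2)))
  oracle <- cand[keep, ][order(-sc[keep]), ][sc[keep][order(-sc[keep])] > 0.5, ]
  expect_equal(rk[, c("drug1", "drug2")], oracle[, c("drug1", "drug2")],
               ignore_attr = TRUE)
  # all candidates known -> empty result
  expect_equal(nrow(rank_novel_pairs(m, known, known)), 0L)
  # threshold filter keeps strict exceedances in order
  top <- rank_novel_pairs(m, cand, known, threshold = 0, top_k = 3)
  expect_equal(nrow(top), 3L)
})

test_that("grid search picks the highest-AUC configuration", {
  sim <- simulate_dataset(simulation_config(n_drugs = 100,
                                            n_other_entities = 200,
                                            n_clusters = 6, seed = 24))
  st <- struct_for(sim)
  good <- desk_config(5, epochs = 12, batch_size = 256, n_folds = 2)
  sabotaged <- desk_config(5, epochs = 1, batch_size = 256, n_folds = 2,
                           learning_rate = 1e-12)
  gs <- grid_search(list(sabotaged, good), sim$kg, st, sim$pairs)
  expect_equal(gs$best_index, 2L)
  expect_equal(gs$results$auc[gs$best_index],
               max(gs$results$auc))
  single <- grid_search(list(good), sim$kg, st, sim$pairs)
  expect_equal(single$best_index, 1L)
})

test_that("configs round-trip through YAML with overrides", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("batch_size: 2048", "learning_rate: 0.02", "embed_dim: 32"), tf)
  cfg <- read_train_config(tf, seed = 42)
  expect_equal(cfg$batch_size, 2048L)
  expect_equal(cfg$learning_rate, 0.02)
  expect_equal(cfg$embed_dim, 32L)
  expect_equal(cfg$seed, 42L)
})
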