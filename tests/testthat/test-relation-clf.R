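test_that("training refuses single-label sets and validates inputs", {
  toy <- trained_toy()
  pos <- toy$train_ex[vapply(toy$train_ex, `[[`, "", "label") == "positive"]
  expect_error(train_relation_model(pos, toy$dev_ex, toy$config, toy$tokenizer),
               "single label")
  expect_error(train_relation_model(list(), toy$dev_ex, toy$config, toy$tokenizer),
               "empty")
  expect_error(train_relation_model(toy$train_ex, list(), toy$config, toy$tokenizer),
               "development")
})

test_that("the trained fixture clearly beats chance on the planted-cue task", {
  toy <- trained_toy()
  best <- toy$fit$history[toy$fit$history$epoch == toy$fit$best_epoch, ]
  expect_gte(best$f1, 0.5)          # small 50-doc fixture; the full-scale
                                    # acceptance run asserts the 0.9 bound
})

# shared single-sentence separable world for the surface-cue invariants
separable_world <- function() {
  cached_fixture("separable_world", function() {
    syn <- generate_corpus(separable_config(n_docs = 150L))
    parts <- split_documents(syn$corpus, c(0.6, 0.4, 0), seed = 3,
                             names = c("train", "dev", "x"))
    tok <- build_vocab(vapply(parts$train, `[[`, "", "text"))
    list(parts = parts, tok = tok)
  })
}

test_that("marking and masking both reach F1 >= 0.9 on the surface-cue task", {
  w <- separable_world()
  for (scheme in c("mark", "mask")) {
    mcfg <- tiny_model_config(scheme = scheme, d_model = 32L, d_ff = 64L,
                              epochs = 10L)
    tr <- build_examples(lapply(w$parts$train, filter_for_prediction), mcfg, w$tok)
    dv <- build_examples(lapply(w$parts$dev, filter_for_prediction), mcfg, w$tok)
    fit <- train_relation_model(tr, dv, mcfg, w$tok)
    expect_gte(max(fit$history$f1), 0.9)
  }
})

test_that("label permutation collapses dev F1 to chance level", {
  w <- separable_world()
  mcfg <- tiny_model_config(scheme = "mark", d_model = 32L, d_ff = 64L,
                            epochs = 10L)
  tr <- build_examples(lapply(w$parts$train, filter_for_prediction), mcfg, w$tok)
  dv <- build_examples(lapply(w$parts$dev, filter_for_prediction), mcfg, w$tok)
  labs <- vapply(tr, `[[`, "", "label")
  set.seed(5)
  labs <- sample(labs)
  for (i in seq_along(tr)) tr[[i]]$label <- labs[i]
  fit <- train_relation_model(tr, dv, mcfg, w$tok)
  base <- mean(vapply(dv, `[[`, "", "label") == "positive")
  all_pos_f1 <- 2 * base / (1 + base)     # F1 of the all-positive guesser
  expect_lte(max(fit$history$f1), all_pos_f1 + 0.05)
})

test_that("epochs = 1 returns the first epoch; ties break earliest", {
  toy <- trained_toy()
  cfg <- toy$config; cfg$epochs <- 1L
  fit <- train_relation_model(toy$train_ex[1:60], toy$dev_ex[1:40], cfg,
                              toy$tokenizer)
  expect_equal(fit$best_epoch, 1L)
  expect_equal(nrow(fit$history), 1L)
})

test_that("training is reproducible for a fixed seed", {
  toy <- trained_toy()
  cfg <- toy$config; cfg$epochs <- 2L
  f1 <- train_relation_model(toy$train_ex[1:50], toy$dev_ex[1:30], cfg,
                             toy$tokenizer)
  f2 <- train_relation_model(toy$train_ex[1:50], toy$dev_ex[1:30], cfg,
                             toy$tokenizer)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$encoder$params, f2$model$encoder$params)
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 1L
  f3 <- train_relation_model(toy$train_ex[1:50], toy$dev_ex[1:30], cfg2,
                             toy$tokenizer)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("predict_pairs is deterministic, duplicates agree, empty input works", {
  toy <- trained_toy()
  expect_equal(nrow(predict_pairs(toy$model, list())), 0)
  ex <- toy$dev_ex[[1]]
  p <- predict_pairs(toy$model, list(ex, ex))
  expect_equal(p$score[1], p$score[2])
  expect_true(all(p$score >= 0 & p$score <= 1))
  expect_equal(p$label, ifelse(p$score >= 0.5, "positive", "negative"))
})

test_that("an example longer than the model MSL is rejected", {
  toy <- trained_toy()
  ex <- toy$dev_ex[[1]]
  ex$ids <- rep(ex$ids, 4)[seq_len(toy$config$msl + 4)]
  expect_error(predict_pairs(toy$model, list(ex)), "MSL")
})

test_that("an overfit toy model scores its own training example positive", {
  toy <- trained_toy()
  labs <- vapply(toy$train_ex, `[[`, "", "label")
  pos_ex <- toy$train_ex[labs == "positive"][1:3]
  p <- predict_pairs(toy$model, pos_ex)
  expect_true(all(p$score > 0.5))
})

test_that("evaluate_pairs counts the confusion matrix on unordered pairs", {
  preds <- data.frame(doc_id = "d", e1 = c("T1", "T3", "T5"),
                      e2 = c("T2", "T4", "T6"),
                      score = c(0.9, 0.8, 0.1),
                      label = c("positive", "positive", "negative"))
  gold <- data.frame(doc_id = "d", e1 = c("T2", "T3", "T6"),
                     e2 = c("T1", "T4", "T5"),   # swapped order on purpose
                     label = c("positive", "negative", "positive"))
  rep <- evaluate_pairs(preds, gold)
  expect_equal(c(rep$tp, rep$fp, rep$fn), c(1, 1, 1))
  expect_equal(rep$precision, 0.5)
  expect_equal(rep$recall, 0.5)
  expect_equal(rep$f1, 0.5)

  perfect <- preds
  perfect$label <- c("positive", "negative", "positive")
  expect_equal(evaluate_pairs(perfect, gold)$f1, 1)
  none <- preds; none$label <- "negative"
  repn <- evaluate_pairs(none, gold)
  expect_equal(repn$recall, 0); expect_equal(repn$f1, 0)
  expect_error(evaluate_pairs(preds[1:2, ], gold), "universes differ")
})

test_that("evaluate_pairs equals a brute-force count on randomized instances", {
  set.seed(8)
  for (rep_i in 1:10) {
    n <- sample(3:12, 1)
    gold <- data.frame(doc_id = "d", e1 = paste0("T", seq_len(n) * 2 - 1),
                       e2 = paste0("T", seq_len(n) * 2),
                       label = sample(c("positive", "negative"), n, TRUE))
    preds <- gold
    preds$score <- runif(n)
    preds$label <- ifelse(preds$score >= 0.5, "positive", "negative")
    r <- evaluate_pairs(preds, gold)
    tp <- sum(preds$label == "positive" & gold$label == "positive")
    fp <- sum(preds$label == "positive" & gold$label == "negative")
    fn <- sum(preds$label == "negative" & gold$label == "positive")
    expect_equal(c(r$tp, r$fp, r$fn), c(tp, fp, fn))
  }
})

test_that("grid_search repeats with distinct seeds and survives failing cells", {
  toy <- trained_toy()
  small_tr <- toy$train_ex[1:60]
  small_dv <- toy$dev_ex[1:40]
  cfg <- toy$config; cfg$epochs <- 1L
  # repeats = 1: sd reported as 0
  rep1 <- grid_search(small_tr, small_dv, list(cfg), repeats = 1,
                      toy$tokenizer)
  expect_equal(rep1$cells$sd_f1, 0)
  expect_equal(nrow(rep1$runs), 1)

  # an untrainable lr = 0 cell loses to a working one (separable world)
  w <- separable_world()
  good <- tiny_model_config(d_model = 32L, d_ff = 64L, epochs = 6L)
  tr <- build_examples(lapply(w$parts$train, filter_for_prediction), good, w$tok)
  dv <- build_examples(lapply(w$parts$dev, filter_for_prediction), good, w$tok)
  dead <- good; dead$lr <- 0
  rep2 <- grid_search(tr, dv, list(dead, good), repeats = 1, w$tok)
  expect_equal(rep2$best, 2L)
  expect_gt(rep2$cells$mean_f1[2], rep2$cells$mean_f1[1])

  # a cell whose training errors is recorded, the grid continues
  broken <- good; broken$msl <- 16L       # examples exceed this msl
  rep3 <- grid_search(tr, dv, list(broken, good), repeats = 1, w$tok)
  expect_false(is.na(rep3$cells$error[1]))
  expect_equal(rep3$best, 2L)
  # two repeats: mean/sd over both runs
  rep4 <- grid_search(small_tr, small_dv, list(cfg), repeats = 2,
                      toy$tokenizer)
  expect_equal(rep4$cells$n_ok, 2)
  expect_equal(nrow(rep4$runs), 2)
})

test_that("model save/load round-trips weights, config and predictions", {
  toy <- trained_toy()
  dir <- withr::local_tempdir()
  save_model(toy$model, dir, toy$tokenizer)
  back <- load_model(dir)
  expect_equal(back$config$msl, toy$config$msl)
  p1 <- predict_pairs(toy$model, toy$dev_ex[1:5])
  p2 <- predict_pairs(back, toy$dev_ex[1:5])
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
  tok2 <- load_model_tokenizer(dir)
  expect_identical(tok2$vocab, toy$tokenizer$vocab)
  path <- file.path(dir, "preds.tsv")
  write_predictions(p1, path)
  expect_equal(nrow(utils::read.delim(path)), 5)
})

test_that("model_config presets carry the published hyper-parameters", {
  ref <- model_config(preset = "reference")
  expect_equal(ref$msl, 128L)
  expect_equal(ref$lr, 3e-6)
  expect_equal(ref$epochs, 11L)
  expect_equal(ref$batch_size, 5L)
  base <- model_config(preset = "baseline")
  expect_equal(base$lr, 5e-6)
  expect_equal(base$epochs, 12L)
  # explicit arguments beat the preset
  custom <- model_config(lr = 1e-3, preset = "reference")
  expect_equal(custom$lr, 1e-3)
  expect_equal(custom$epochs, 11L)
})
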