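# Attribution methods checked against closed forms and brute-force oracles
# on small inputs, then against planted cues through the trained fixture.

test_that("path integration is exact for linear functions with zero baseline", {
  set.seed(3)
  w <- matrix(rnorm(12), 3, 4)
  grad_fn <- function(x) w                       # f(x) = sum(w * x)
  x1 <- matrix(rnorm(12), 3, 4)
  attr <- integrated_gradients_core(grad_fn, x1 * 0, x1, steps = 8)
  expect_equal(attr, w * x1, tolerance = 1e-12)
})

test_that("baseline equal to the input gives all-zero attributions", {
  toy <- trained_toy()
  ex <- toy$dev_ex[[1]]
  fwd <- encoder_forward(toy$model$encoder, ex$ids, keep_cache = TRUE)
  acts <- fwd$cache$layer_out[[2]]
  grad_fn <- function(a) {
    f <- encoder_forward_from(toy$model$encoder, a, 1, keep_cache = TRUE)
    dlog <- f$probs[2] * (c(0, 1) - f$probs)
    encoder_backward_to(toy$model$encoder, f, dlog, length(ex$ids))
  }
  attr <- integrated_gradients_core(grad_fn, acts, acts, steps = 8)
  expect_equal(attr, acts * 0)
})

test_that("LIG satisfies completeness within 1% at 256 steps on the trained model", {
  toy <- trained_toy()
  gold <- vapply(toy$dev_ex, `[[`, "", "label")
  ex <- toy$dev_ex[gold == "positive"][[1]]
  for (layer in c(0L, 1L, 2L)) {
    vec <- layer_integrated_gradients(toy$model, ex,
                                      attrib_config(layer = layer, steps = 256L))
    delta <- vec$completeness$delta
    expect_gt(abs(delta), 1e-4)   # non-degenerate check
    expect_lt(abs(vec$completeness$sum - delta) / abs(delta), 0.01)
  }
})

test_that("sampled Shapley values match exact enumeration on small inputs", {
  toy <- trained_toy()
  ex <- small_example(toy)                      # <= 8 players, 2^8 coalitions
  players <- which(!ex$special)
  n <- length(players)
  expect_lte(n, 8)
  value <- function(present) {
    ids <- ex$ids
    ids[setdiff(players, present)] <- 1L
    encoder_forward(toy$model$encoder, ids)$probs[2]
  }
  # exact Shapley by enumeration over all coalitions of the other players
  exact <- numeric(n)
  other_sets <- function(i) {
    rest <- setdiff(seq_len(n), i)
    unlist(lapply(0:length(rest), function(k)
      utils::combn(rest, k, simplify = FALSE)), recursive = FALSE)
  }
  for (i in seq_len(n)) {
    contrib <- 0
    for (S in other_sets(i)) {
      w <- factorial(length(S)) * factorial(n - length(S) - 1) / factorial(n)
      contrib <- contrib +
        w * (value(players[c(S, i)]) - value(players[S]))
    }
    exact[i] <- contrib
  }
  vec <- shapley_values(toy$model, ex,
                        attrib_config(method = "SHAP", samples = 400L, seed = 9L))
  est <- vec$scores[players]
  # Monte-Carlo error: a few standard errors of the permutation estimate
  expect_lt(max(abs(est - exact)), 0.05)
  # efficiency holds exactly for permutation sampling
  expect_equal(sum(vec$scores), value(players) - value(integer(0)),
               tolerance = 1e-10)
})

test_that("constant value function gives zero Shapley values", {
  toy <- trained_toy()
  ex <- toy$dev_ex[[1]]
  # degenerate model: zero decision weights => constant probabilities
  flat <- toy$model
  flat$encoder$params$Wc[] <- 0
  flat$encoder$params$bc[] <- 0
  vec <- shapley_values(flat, ex, attrib_config(method = "SHAP", samples = 20L))
  expect_equal(vec$scores, numeric(length(ex$ids)), tolerance = 1e-12)
})

test_that("Shapley sampling is seed-deterministic and boundary flag changes players", {
  toy <- trained_toy()
  ex <- toy$dev_ex[[2]]
  cfg <- attrib_config(method = "SHAP", samples = 10L, seed = 4L)
  v1 <- shapley_values(toy$model, ex, cfg)
  v2 <- shapley_values(toy$model, ex, cfg)
  expect_identical(v1$scores, v2$scores)
  cfgb <- attrib_config(method = "SHAP", samples = 10L, seed = 4L,
                        include_boundary = TRUE)
  vb <- shapley_values(toy$model, ex, cfgb)
  cls <- which(ex$tokens == "[CLS]")
  expect_equal(v1$scores[cls], 0)
  expect_false(vb$scores[cls] == 0)
})

test_that("heuristics remove rule-targeted tokens and respect order", {
  toy <- trained_toy()
  gold <- vapply(toy$dev_ex, `[[`, "", "label")
  ex <- toy$dev_ex[gold == "positive"][[1]]
  scores <- seq_along(ex$ids) * 0.01
  vec <- structure(list(scores = scores, method = "LIG", layer = 1L,
                        example = ex), class = "attribution_vector")
  # empty rule list: identity
  same <- apply_heuristics(vec, ex, rules = character())
  expect_identical(same$scores, scores)
  filt <- apply_heuristics(vec, ex, rules = default_heuristics(),
                           doc = toy$dev_docs[[ex$doc_id]])
  expect_true(all(is.infinite(filt$scores[ex$special])))
  expect_true(all(is.infinite(filt$scores[ex$in_e1 | ex$in_e2])))
  expect_error(apply_heuristics(vec, ex, rules = c("bogus")), "unknown")
})

test_that("the top-scoring focus-entity token loses to the runner-up after filtering", {
  toy <- trained_toy()
  gold <- vapply(toy$dev_ex, `[[`, "", "label")
  ex <- toy$dev_ex[gold == "positive"][[1]]
  scores <- rep(0.1, length(ex$ids))
  scores[which(ex$in_e1 & !ex$special)[1]] <- 10      # entity token on top
  runner <- which(!ex$special & !ex$in_e1 & !ex$in_e2 & !is.na(ex$start))[1]
  scores[runner] <- 5
  vec <- structure(list(scores = scores, method = "LIG", layer = 1L,
                        example = ex), class = "attribution_vector")
  filt <- apply_heuristics(vec, ex, rules = c("special", "focus_entities"))
  sel <- select_trigger(filt, ex)
  expect_equal(sel$start, min(ex$start[ex$word_id == ex$word_id[runner]],
                              na.rm = TRUE))
})

test_that("select_trigger picks the argmax, breaks ties leftmost, merges word pieces", {
  tok <- fixture_tokenizer(extra = "they cointeract strongly")
  txt <- "ABC1 and XYZ2 cointeract strongly."
  ann <- paste0("T1\tGene_or_gene_product 0 4\tABC1\n",
                "T2\tGene_or_gene_product 9 13\tXYZ2\n")
  doc <- read_standoff(txt, ann, "wm")
  # force the cue word to split into pieces by dropping it from the vocab
  tok2 <- wp_tokenizer(setdiff(tok$vocab[-seq_len(tok$n_special)],
                               "cointeract"))
  ex <- build_example(doc, list(e1 = "T1", e2 = "T2", label = "positive"),
                      tiny_model_config(), tok2)
  pieces <- which(grepl("^##", ex$tokens))
  expect_gt(length(pieces), 0)
  scores <- rep(0, length(ex$ids))
  scores[pieces[1]] <- 1                       # winning sub-token
  vec <- structure(list(scores = scores, method = "LIG", layer = 0L,
                        example = ex), class = "attribution_vector")
  sel <- select_trigger(vec, ex)
  expect_identical(substring(txt, sel$start + 1, sel$end), "cointeract")

  # tie-break: two equal maxima -> leftmost eligible token wins
  scores2 <- rep(0, length(ex$ids))
  free <- which(!ex$special & !is.na(ex$start))
  scores2[free[c(2, 4)]] <- 3
  vec2 <- structure(list(scores = scores2, method = "LIG", layer = 0L,
                         example = ex), class = "attribution_vector")
  sel2 <- select_trigger(vec2, ex)
  expect_equal(sel2$start, min(ex$start[ex$word_id == ex$word_id[free[2]]],
                               na.rm = TRUE))
  # all tokens removed: error
  vec3 <- vec2; vec3$scores <- rep(-Inf, length(ex$ids))
  expect_error(select_trigger(vec3, ex), "no surviving token")
})

test_that("hyphen tokens survive the default heuristics", {
  syn <- generate_corpus(synth_config(n_docs = 40, seed = 66))
  docs <- lapply(syn$corpus, filter_for_prediction)
  tok <- build_vocab(vapply(docs, `[[`, "", "text"))
  exs <- build_examples(docs, tiny_model_config(), tok)
  hy <- NULL
  for (ex in exs)
    if (ex$label == "positive" && "-" %in% ex$tokens[!ex$special]) { hy <- ex; break }
  expect_false(is.null(hy))                     # fusion template guarantees one
  scores <- rep(1, length(hy$ids))
  vec <- structure(list(scores = scores, method = "LIG", layer = 1L,
                        example = hy), class = "attribution_vector")
  filt <- apply_heuristics(vec, hy, default_heuristics(),
                           doc = docs[[hy$doc_id]])
  hyph <- which(hy$tokens == "-" & !hy$special)
  expect_true(all(is.finite(filt$scores[hyph])))
  # purely numeric tokens are removed, punctuation retained
  num <- which(grepl("^[0-9]+$", hy$tokens))
  if (length(num)) expect_true(all(is.infinite(filt$scores[num])))
})

test_that("triggers are emitted only for positive predictions (gating)", {
  toy <- trained_toy()
  preds <- predict_pairs(toy$model, toy$dev_ex)
  trig <- detect_triggers(toy$model, toy$dev_ex,
                          attrib_config(layer = 1L, steps = 8L),
                          toy$dev_docs)
  pos_keys <- paste(preds$doc_id, pmin(preds$e1, preds$e2),
                    pmax(preds$e1, preds$e2))[preds$label == "positive"]
  trig_keys <- paste(trig$doc_id, pmin(trig$e1, trig$e2),
                     pmax(trig$e1, trig$e2))
  expect_true(all(trig_keys %in% pos_keys))
  neg_model <- toy$model
  neg_model$encoder$params$bc <- c(50, -50)     # forces negative labels
  expect_equal(nrow(detect_triggers(neg_model, toy$dev_ex[1:5],
                                    attrib_config(steps = 8L))), 0)
})

test_that("a layer sweep plus two SHAP runs yields n_layers + 3 prediction sets", {
  toy <- trained_toy()
  gold <- vapply(toy$dev_ex, `[[`, "", "label")
  exs <- toy$dev_ex[gold == "positive"][1:3]
  sets <- trigger_prediction_sets(toy$model, exs,
                                  attrib_config(steps = 8L, samples = 8L),
                                  toy$dev_docs)
  expect_length(sets, toy$model$config$n_layers + 1L + 2L)   # 5 for 2 layers
  expect_named(sets, c("LIG_layer0", "LIG_layer1", "LIG_layer2",
                       "SHAP_without_boundary", "SHAP_with_boundary"))
})

test_that("detected triggers are deterministic for fixed weights and seed", {
  toy <- trained_toy()
  gold <- vapply(toy$dev_ex, `[[`, "", "label")
  exs <- toy$dev_ex[gold == "positive"][1:4]
  cfg <- attrib_config(layer = 1L, steps = 8L)
  t1 <- detect_triggers(toy$model, exs, cfg, toy$dev_docs)
  t2 <- detect_triggers(toy$model, exs, cfg, toy$dev_docs)
  expect_identical(t1, t2)
})

test_that("baseline matcher finds lexicon cues inside windows only", {
  tok <- fixture_tokenizer()
  doc <- minimal_doc()
  ex <- build_example(doc, list(e1 = "T1", e2 = "T2", label = "positive"),
                      tiny_model_config(), tok)
  hits <- baseline_trigger_match(ex, c("binds"), window_size = 3, doc)
  expect_equal(nrow(hits), 1)
  expect_identical(substring(doc$text, hits$start + 1, hits$end), "binds")
  # empty lexicon: no result
  expect_equal(nrow(baseline_trigger_match(ex, character(), 3, doc)), 0)
  # overlapping items: longest-first, reported once
  hits2 <- baseline_trigger_match(ex, c("bind", "binds"), 3, doc)
  expect_equal(nrow(hits2), 1)
  expect_identical(substring(doc$text, hits2$start + 1, hits2$end), "binds")
})

test_that("a too-small window cannot reach the cue", {
  tok <- build_vocab("ABC1 word word word word binds word word word word XYZ2")
  txt <- "ABC1 aa bb cc dd binds ee ff gg hh XYZ2."
  s2 <- regexpr("XYZ2", txt) - 1L
  ann <- paste0("T1\tGene_or_gene_product 0 4\tABC1\n",
                sprintf("T2\tGene_or_gene_product %d %d\tXYZ2\n", s2, s2 + 4))
  doc <- read_standoff(txt, ann, "win")
  ex <- build_example(doc, list(e1 = "T1", e2 = "T2", label = "negative"),
                      tiny_model_config(msl = 32L), tok)
  near <- baseline_trigger_match(ex, c("binds"), window_size = 5, doc)
  far <- baseline_trigger_match(ex, c("binds"), window_size = 2, doc)
  expect_equal(nrow(near), 1)
  expect_equal(nrow(far), 0)
  expect_error(baseline_trigger_match(ex, c("binds"), 0, doc), "window_size")
})

test_that("triggers render as standoff-style annotations", {
  toy <- trained_toy()
  gold <- vapply(toy$dev_ex, `[[`, "", "label")
  exs <- toy$dev_ex[gold == "positive"][1:4]
  trig <- detect_triggers(toy$model, exs, attrib_config(layer = 1L, steps = 8L),
                          toy$dev_docs)
  if (nrow(trig)) {
    ann <- triggers_as_standoff(trig, toy$dev_docs)
    expect_true(all(names(ann) %in% names(toy$dev_docs)))
    first <- strsplit(ann[[1]], "\n")[[1]][1]
    expect_match(first, "^T1\tTrigger [0-9]+ [0-9]+\t")
    # the standoff surface slice matches the reported trigger text
    expect_match(first, paste0("\t", trig$text[trig$doc_id == names(ann)[1]][1], "$"))
  } else succeed()
})
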