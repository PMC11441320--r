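#' Synthetic corpus configuration
#'
#' The generator emulates the statistical shape of the annotated corpus:
#' multi-sentence abstracts, 2–40 protein mentions per document, positive
#' pairs signalled by an explicit cue from a trigger lexicon, a small
#' cross-sentence fraction (default 0.04, matching the >96% intra-sentence
#' statistic), distractor verbs on negative pairs, Blocklisted filler
#' mentions and Equiv alias groups. Text is templated pseudo-English;
#' protein names are synthetic alphanumerics (three letters + digit) so no
#' real gene symbols leak into tests.
#'
#' @param n_docs number of documents.
#' @param sentences integer range `c(min, max)` of sentences per document.
#' @param vocab_size size of the synthetic protein-name vocabulary.
#' @param mentions allowed range of mentions per document, within
#'   `[2, 40]`.
#' @param positive_rate probability that a sentence slot states a positive
#'   pair.
#' @param cross_sentence_frac fraction of positive relations realized
#'   across two sentences.
#' @param trigger_lexicon cue words/phrases planted on positive pairs.
#' @param distractor_lexicon verbs planted on negative pairs.
#' @param blocklist_rate probability a filler mention is Blocklisted.
#' @param equiv_rate probability a positive pair carries an Equiv alias.
#' @param seed integer seed; a fixed seed yields byte-identical corpora.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_docs = 200L, sentences = c(3L, 6L),
                         vocab_size = 60L, mentions = c(2L, 40L),
                         positive_rate = 0.4, cross_sentence_frac = 0.04,
                         trigger_lexicon = default_trigger_lexicon(),
                         distractor_lexicon = default_distractor_lexicon(),
                         blocklist_rate = 0.05, equiv_rate = 0.1, seed = 1L) {
  stopifnot(length(sentences) == 2, sentences[1] >= 1,
            sentences[2] >= sentences[1])
  if (mentions[1] < 2 || mentions[2] > 40 || mentions[1] > mentions[2])
    stop("mention range must lie within [2, 40]")
  for (fr in c(positive_rate, cross_sentence_frac, blocklist_rate, equiv_rate))
    if (fr < 0 || fr > 1) stop("rates must be fractions in [0, 1]")
  structure(list(n_docs = as.integer(n_docs), sentences = as.integer(sentences),
                 vocab_size = as.integer(vocab_size),
                 mentions = as.integer(mentions),
                 positive_rate = positive_rate,
                 cross_sentence_frac = cross_sentence_frac,
                 trigger_lexicon = trigger_lexicon,
                 distractor_lexicon = distractor_lexicon,
                 blocklist_rate = blocklist_rate, equiv_rate = equiv_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_trigger_lexicon <- function() {
  c("binds", "interacts with", "forms a complex with", "associates with",
    "co-purifies with")
}

#' @rdname synth_config
#' @export
default_distractor_lexicon <- function() {
  c("regulates", "phosphorylates", "activates", "inhibits", "degrades")
}

synth_contexts <- function() {
  c("in vitro", "in yeast cells", "in the nucleus", "under stress conditions",
    "in this study")
}

synth_filler_verbs <- function() {
  c("was expressed", "was detected", "was purified", "accumulated",
    "was upregulated")
}

#' Generate a synthetic standoff corpus with planted triggers
#'
#' Every positive pair co-occurs with a cue from the trigger lexicon:
#' either a verbal cue between the two mentions, a hyphenated fusion
#' (`the A-B complex`, whose hyphen and the word `complex` form an
#' alternative-span group), or — for the cross-sentence fraction — a
#' two-sentence complex statement. Negative pairs co-occur with
#' distractor verbs. The gold side records every planted relation's
#' trigger span(s), Equiv-expanded, for use as a trigger-evaluation
#' oracle.
#'
#' @param config a [synth_config].
#' @return list with `corpus` (named list of [standoff_document]s) and
#'   `gold` (data.frame `doc_id`, `e1`, `e2`, `start`, `end`, one row per
#'   alternative trigger span per positive pair) and `meta` (data.frame
#'   with per-relation `cross_sentence` flags).
#' @export
generate_corpus <- function(config) {
  if (config$cross_sentence_frac > 0 && config$sentences[2] < 2)
    stop("infeasible config: cross-sentence relations require documents with >= 2 sentences")
  with_seed(config$seed, {
    protein_names <- synth_protein_names(config$vocab_size)
    docs <- vector("list", config$n_docs)
    golds <- list(); metas <- list()
    for (i in seq_len(config$n_docs)) {
      g <- generate_document(sprintf("synth%04d", i), config, protein_names)
      docs[[i]] <- g$doc
      golds[[i]] <- g$gold
      metas[[i]] <- g$meta
    }
    names(docs) <- vapply(docs, `[[`, "", "doc_id")
    gold <- do.call(rbind, golds)
    if (is.null(gold))
      gold <- data.frame(doc_id = character(), e1 = character(),
                         e2 = character(), start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
    meta <- do.call(rbind, metas)
    if (is.null(meta))
      meta <- data.frame(doc_id = character(), rel = character(),
                         cross_sentence = logical(), stringsAsFactors = FALSE)
    rownames(gold) <- rownames(meta) <- NULL
    list(corpus = docs, gold = gold, meta = meta)
  })
}

synth_protein_names <- function(n) {
  pool <- character(0)
  while (length(pool) < n) {
    cand <- paste0(paste(sample(LETTERS, 3, replace = TRUE), collapse = ""),
                   sample(1:9, 1))
    pool <- unique(c(pool, cand))
  }
  pool[seq_len(n)]
}

generate_document <- function(doc_id, cfg, protein_names) {
  buf <- character(); cursor <- 0L
  ents <- list(); rels <- list(); attrs <- list(); equivs <- list()
  gold <- list(); meta <- list()
  queue <- sample(protein_names)

  add_str <- function(s) {
    buf[[length(buf) + 1L]] <<- s
    st <- cursor
    cursor <<- cursor + nchar(s)
    c(st, cursor)
  }
  next_name <- function() {
    if (!length(queue)) queue <<- sample(protein_names)
    nm <- queue[1]; queue <<- queue[-1]
    nm
  }
  add_mention <- function(name) {
    sp <- add_str(name)
    id <- paste0("T", length(ents) + 1L)
    ents[[id]] <<- list(id = id, start = sp[1], end = sp[2], text = name)
    id
  }
  add_relation <- function(a, b, spans, cross = FALSE) {
    rid <- paste0("R", length(rels) + 1L)
    rels[[rid]] <<- list(id = rid, arg1 = a, arg2 = b)
    for (sp in spans)
      gold[[length(gold) + 1L]] <<- data.frame(
        doc_id = doc_id, e1 = a, e2 = b, start = sp[1], end = sp[2],
        stringsAsFactors = FALSE)
    meta[[length(meta) + 1L]] <<- data.frame(
      doc_id = doc_id, rel = rid, cross_sentence = cross,
      stringsAsFactors = FALSE)
    rid
  }
  ctx <- function() sample(synth_contexts(), 1)

  n_s <- sample(seq(cfg$sentences[1], cfg$sentences[2]), 1)
  others <- c(neg = 0.3, fillm = 0.2, plain = 0.1)
  probs <- c(pos = cfg$positive_rate,
             others / sum(others) * (1 - cfg$positive_rate))
  n_mentions <- 0L
  slot <- 1L
  while (slot <= n_s) {
    if (slot > 1L) add_str(" ")
    type <- if (slot == 1L) {
      if (stats::runif(1) < cfg$positive_rate) "pos" else "neg"
    } else sample(names(probs), 1, prob = probs)
    cost <- switch(type, pos = 3L, neg = 2L, fillm = 1L, plain = 0L)
    if (n_mentions + cost > cfg$mentions[2]) type <- "plain"

    if (type == "pos") {
      cross <- stats::runif(1) < cfg$cross_sentence_frac && slot + 1L <= n_s
      a_nm <- next_name(); b_nm <- next_name()
      if (cross) {
        a_id <- add_mention(a_nm)
        add_str(" forms a stable ")
        sp1 <- add_str("complex")
        add_str(". The ")
        sp2 <- add_str("complex")
        add_str(" also contains ")
        b_id <- add_mention(b_nm)
        add_str(".")
        add_relation(a_id, b_id, list(sp1, sp2), cross = TRUE)
        n_mentions <- n_mentions + 2L
        slot <- slot + 2L
        next
      }
      fusion <- stats::runif(1) < 0.2
      if (fusion) {
        add_str("The ")
        a_id <- add_mention(a_nm)
        hyph <- add_str("-")
        b_id <- add_mention(b_nm)
        add_str(" ")
        cue <- add_str("complex")
        add_str(paste0(" was purified ", ctx(), "."))
        add_relation(a_id, b_id, list(hyph, cue))
        n_mentions <- n_mentions + 2L
      } else {
        a_id <- add_mention(a_nm)
        add_str(" ")
        cue <- add_str(sample(cfg$trigger_lexicon, 1))
        add_str(" ")
        b_id <- add_mention(b_nm)
        alias <- stats::runif(1) < cfg$equiv_rate &&
          n_mentions + 3L <= cfg$mentions[2]
        b2_id <- NULL
        if (alias) {
          add_str(" (")
          b2_id <- add_mention(next_name())
          add_str(")")
        }
        add_str(paste0(" ", ctx(), "."))
        add_relation(a_id, b_id, list(cue))
        n_mentions <- n_mentions + 2L
        if (alias) {
          equivs[[length(equivs) + 1L]] <- c(b_id, b2_id)
          # Equiv expansion makes (a, alias) positive too; record its trigger
          gold[[length(gold) + 1L]] <- data.frame(
            doc_id = doc_id, e1 = a_id, e2 = b2_id,
            start = cue[1], end = cue[2], stringsAsFactors = FALSE)
          n_mentions <- n_mentions + 1L
        }
      }
    } else if (type == "neg") {
      a_id <- add_mention(next_name())
      add_str(" ")
      add_str(sample(cfg$distractor_lexicon, 1))
      add_str(" ")
      b_id <- add_mention(next_name())
      add_str(paste0(" ", ctx(), "."))
      n_mentions <- n_mentions + 2L
    } else if (type == "fillm") {
      a_id <- add_mention(next_name())
      add_str(paste0(" ", sample(synth_filler_verbs(), 1), " ", ctx(), "."))
      if (stats::runif(1) < cfg$blocklist_rate)
        attrs[[length(attrs) + 1L]] <- list(
          id = paste0("A", length(attrs) + 1L), name = "Blocklisted",
          target = a_id)
      n_mentions <- n_mentions + 1L
    } else {
      add_str("The measurements were consistent across replicates.")
    }
    slot <- slot + 1L
  }

  text <- paste(buf, collapse = "")
  entities <- data.frame(
    id = vapply(ents, `[[`, "", "id"),
    type = "Gene_or_gene_product",
    start = vapply(ents, function(e) as.integer(e$start), 0L),
    end = vapply(ents, function(e) as.integer(e$end), 0L),
    text = vapply(ents, `[[`, "", "text"),
    fragments = I(lapply(ents, function(e)
      matrix(c(as.integer(e$start), as.integer(e$end)), 1, 2))),
    stringsAsFactors = FALSE, row.names = NULL)
  relations <- if (length(rels)) data.frame(
    id = vapply(rels, `[[`, "", "id"), type = "Complex_formation",
    arg1 = vapply(rels, `[[`, "", "arg1"),
    arg2 = vapply(rels, `[[`, "", "arg2"),
    stringsAsFactors = FALSE, row.names = NULL) else empty_relations()
  attributes <- if (length(attrs)) data.frame(
    id = vapply(attrs, `[[`, "", "id"),
    name = vapply(attrs, `[[`, "", "name"),
    target = vapply(attrs, `[[`, "", "target"), value = "",
    stringsAsFactors = FALSE, row.names = NULL) else empty_attributes()

  doc <- standoff_document(doc_id, text, entities, relations, attributes,
                           equivs)
  gold_df <- if (length(gold)) do.call(rbind, gold) else
    data.frame(doc_id = character(), e1 = character(), e2 = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  meta_df <- if (length(meta)) do.call(rbind, meta) else
    data.frame(doc_id = character(), rel = character(),
               cross_sentence = logical(), stringsAsFactors = FALSE)
  list(doc = doc, gold = gold_df, meta = meta_df)
}

#' Write a synthetic corpus plus its gold-trigger TSV
#' @param synth result of [generate_corpus].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synth_corpus <- function(synth, dir) {
  write_standoff_dir(synth$corpus, dir)
  utils::write.table(synth$gold, file.path(dir, "gold_triggers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' End-to-end synthetic recovery harness
#'
#' Runs the whole pipeline on a generated corpus: generate, split
#' (train/dev), filter to the prediction regime, build examples, train the
#' classifier, evaluate pair predictions on dev, detect triggers for the
#' gold-positive dev pairs, and score them against the planted spans.
#'
#' @param config a [synth_config].
#' @param mcfg a [model_config].
#' @param acfg an [attrib_config].
#' @param split_fractions train/dev fractions (length 2, summing to 1).
#' @param shuffle_train_labels permute the training labels (negative
#'   control; dev gold stays intact).
#' @param verbose print per-epoch training metrics.
#' @return list with `pair` (a `pair_eval_report`), `trigger` (a
#'   `trigger_eval_report`, penalizing), `trigger_nonpen` (non-penalizing),
#'   `triggers` (emitted spans), `predictions` (dev pair predictions),
#'   `model`, `tokenizer`, `history`, `base_rate` (positive fraction of
#'   the dev pairs), `dev_docs` and `dev_examples`.
#' @export
end_to_end_recovery <- function(config,
                                mcfg = model_config(
                                  msl = 24L, d_model = 48L, n_layers = 2L,
                                  n_heads = 4L, d_ff = 96L, lr = 2e-3,
                                  batch_size = 8L, epochs = 12L),
                                acfg = attrib_config(layer = 0L, steps = 32L),
                                split_fractions = c(0.7, 0.3),
                                shuffle_train_labels = FALSE,
                                verbose = FALSE) {
  synth <- generate_corpus(config)
  parts <- split_documents(synth$corpus, c(split_fractions, 0),
                           seed = config$seed,
                           names = c("train", "dev", "unused"))
  train_docs <- lapply(parts$train, filter_for_prediction)
  dev_docs <- lapply(parts$dev, filter_for_prediction)

  tokenizer <- build_vocab(vapply(train_docs, `[[`, "", "text"))
  train_ex <- build_examples(train_docs, mcfg, tokenizer)
  dev_ex <- build_examples(dev_docs, mcfg, tokenizer)
  if (shuffle_train_labels) {
    labels <- vapply(train_ex, `[[`, "", "label")
    labels <- with_seed(config$seed + 7L, sample(labels))
    for (i in seq_along(train_ex)) train_ex[[i]]$label <- labels[i]
  }

  fit <- train_relation_model(train_ex, dev_ex, mcfg, tokenizer,
                              verbose = verbose)
  preds <- predict_pairs(fit$model, dev_ex)
  gold <- examples_gold(dev_ex)
  pair_rep <- evaluate_pairs(preds, gold)

  pos_ex <- dev_ex[gold$label == "positive"]
  triggers <- detect_triggers(fit$model, pos_ex, acfg, dev_docs)
  gkey <- paste(synth$gold$doc_id, pair_key(synth$gold$e1, synth$gold$e2))
  ekey <- vapply(pos_ex, function(ex)
    paste(ex$doc_id, pair_key(ex$e1, ex$e2)), "")
  gold_spans <- synth$gold[gkey %in% ekey, , drop = FALSE]
  trig_rep <- evaluate_triggers(triggers, gold_spans, penalize_alternatives = TRUE)
  trig_rep_np <- evaluate_triggers(triggers, gold_spans,
                                   penalize_alternatives = FALSE)

  list(pair = pair_rep, trigger = trig_rep, trigger_nonpen = trig_rep_np,
       triggers = triggers, predictions = preds, model = fit$model,
       tokenizer = tokenizer, history = fit$history,
       base_rate = mean(gold$label == "positive"),
       dev_docs = dev_docs, dev_examples = dev_ex)
}
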