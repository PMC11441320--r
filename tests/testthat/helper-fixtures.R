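# Shared fixtures: tiny documents, tokenizers and a cached trained model so
# the expensive training runs happen once per test session.

minimal_doc <- function() {
  read_standoff(
    "MDC1 binds APC.",
    paste0("T1\tGene_or_gene_product 0 4\tMDC1\n",
           "T2\tComplex 11 14\tAPC\n",
           "R1\tComplex_formation Arg1:T1 Arg2:T2\n"),
    doc_id = "mini")
}

# two proteins + one chemical + equiv alias, for filtering/pair tests
mixed_doc <- function() {
  read_standoff(
    "ABC1 binds XYZ2 (XY2) and dexamethasone activates QRS3.",
    paste0("T1\tGene_or_gene_product 0 4\tABC1\n",
           "T2\tGene_or_gene_product 11 15\tXYZ2\n",
           "T3\tGene_or_gene_product 17 20\tXY2\n",
           "T4\tChemical 26 39\tdexamethasone\n",
           "T5\tGene_or_gene_product 50 54\tQRS3\n",
           "R1\tComplex_formation Arg1:T1 Arg2:T2\n",
           "*\tEquiv T2 T3\n"),
    doc_id = "mixed")
}

fixture_tokenizer <- function(extra = character()) {
  build_vocab(c("ABC1 binds XYZ2 in vitro .",
                "QRS3 regulates MDC1 under stress .",
                "the complex was purified and contains proteins",
                extra))
}

tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(msl = 24L, d_model = 16L, n_layers = 2L, n_heads = 2L,
         d_ff = 32L, lr = 2e-3, batch_size = 8L, epochs = 4L, seed = 42L),
    list(...))
  do.call(model_config, args)
}

# perfectly separable single-sentence world: one pair per document, cue or
# distractor always between the mentions, no cross-sentence confusion
separable_config <- function(n_docs = 80L, seed = 19L) {
  synth_config(n_docs = n_docs, sentences = c(1L, 1L), positive_rate = 0.5,
               cross_sentence_frac = 0, equiv_rate = 0, blocklist_rate = 0,
               seed = seed)
}

# session-level cache for expensive fixtures
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, fn) {
  if (!exists(key, .fixture_cache)) assign(key, fn(), .fixture_cache)
  get(key, .fixture_cache)
}

# a small trained model on a separable planted-cue corpus, shared across
# attribution and classifier tests
trained_toy <- function() {
  cached_fixture("trained_toy", function() {
    cfg <- synth_config(n_docs = 50, sentences = c(2L, 4L), seed = 7)
    syn <- generate_corpus(cfg)
    parts <- split_documents(syn$corpus, c(0.75, 0.25, 0), seed = 2,
                             names = c("train", "dev", "x"))
    train_docs <- lapply(parts$train, filter_for_prediction)
    dev_docs <- lapply(parts$dev, filter_for_prediction)
    tokenizer <- build_vocab(vapply(train_docs, `[[`, "", "text"))
    mcfg <- model_config(msl = 24L, d_model = 48L, n_layers = 2L,
                         n_heads = 4L, d_ff = 96L, lr = 2e-3,
                         batch_size = 8L, epochs = 10L, seed = 42L)
    train_ex <- build_examples(train_docs, mcfg, tokenizer)
    dev_ex <- build_examples(dev_docs, mcfg, tokenizer)
    fit <- train_relation_model(train_ex, dev_ex, mcfg, tokenizer)
    list(fit = fit, model = fit$model, tokenizer = tokenizer, config = mcfg,
         train_ex = train_ex, dev_ex = dev_ex, synth = syn,
         dev_docs = dev_docs)
  })
}

# a one-sentence document encoded with the toy model's tokenizer: the whole
# window is the document, leaving few enough player tokens for exact Shapley
# enumeration (2^n coalitions)
small_example <- function(toy) {
  # names drawn from the fixture corpus so each is a single vocabulary token
  nms <- unique(unlist(lapply(toy$dev_docs, function(d) d$entities$text)))[1:2]
  txt <- sprintf("%s binds %s.", nms[1], nms[2])
  ann <- paste0(
    sprintf("T1\tGene_or_gene_product 0 %d\t%s\n", nchar(nms[1]), nms[1]),
    sprintf("T2\tGene_or_gene_product %d %d\t%s\n",
            nchar(nms[1]) + 7L, nchar(nms[1]) + 7L + nchar(nms[2]), nms[2]),
    "R1\tComplex_formation Arg1:T1 Arg2:T2\n")
  doc <- read_standoff(txt, ann, "small")
  build_example(doc, list(e1 = "T1", e2 = "T2", label = "positive"),
                toy$config, toy$tokenizer)
}
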