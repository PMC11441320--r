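#' Attribution configuration
#'
#' @param method `"LIG"` (layer integrated gradients) or `"SHAP"`
#'   (permutation-sampled Shapley values).
#' @param layer layer whose outputs are attributed (0 = embedding output,
#'   `1..n_layers` the hidden layers; LIG only).
#' @param steps number of path-integration points (LIG; >= 8).
#' @param samples number of sampled permutations (SHAP; >= 1).
#' @param include_boundary include the `[CLS]`/`[SEP]` boundary tokens in
#'   the SHAP player set.
#' @param seed seed for the SHAP permutation draws.
#' @param heuristics character vector of post-processing rules applied
#'   before span selection (see [apply_heuristics]); use `character()` to
#'   disable.
#' @return a list of class `attrib_config`.
#' @export
attrib_config <- function(method = c("LIG", "SHAP"), layer = 1L, steps = 50L,
                          samples = 200L, include_boundary = FALSE, seed = 1L,
                          heuristics = default_heuristics()) {
  method <- match.arg(method)
  if (steps < 8) stop("steps must be >= 8")
  if (samples < 1) stop("samples must be >= 1")
  structure(list(method = method, layer = as.integer(layer),
                 steps = as.integer(steps), samples = as.integer(samples),
                 include_boundary = include_boundary, seed = as.integer(seed),
                 heuristics = heuristics),
            class = "attrib_config")
}

#' @rdname apply_heuristics
#' @export
default_heuristics <- function() {
  c("special", "focus_entities", "other_entities", "numeric", "stopwords",
    "sentence_punct")
}

# function words that cannot be relation cues; removing them keeps the argmax
# on content tokens (punctuation such as "-" or "/" is deliberately retained)
trigger_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "of", "in", "on", "at", "to",
    "by", "for", "from", "into", "under", "over", "this", "that", "these",
    "those", "it", "its", "was", "were", "is", "are", "be", "been", "being",
    "also", "both", "each", "as", "we", "our")
}

#' Path-integrated attribution core
#'
#' Riemann (trapezoidal) approximation of the straight-line path integral
#' of gradients from `x0` to `x1`:
#' `(x1 - x0) * mean_k grad f(x0 + alpha_k (x1 - x0))`. For a linear `f`
#' with zero baseline this reduces exactly to `w * x`; in general the
#' completeness identity `sum(attr) = f(x1) - f(x0)` holds up to the
#' integration error.
#'
#' @param grad_fn function(x) returning the gradient of the scalar target
#'   at `x` (same shape as `x`).
#' @param x0 baseline point (matrix or vector).
#' @param x1 input point.
#' @param steps number of integration points.
#' @return attribution of the same shape as `x1`.
#' @export
integrated_gradients_core <- function(grad_fn, x0, x1, steps) {
  alphas <- seq(0, 1, length.out = steps)
  weights <- rep(1, steps); weights[c(1, steps)] <- 0.5
  weights <- weights / sum(weights)
  acc <- x1 * 0
  for (k in seq_len(steps))
    acc <- acc + weights[k] * grad_fn(x0 + alphas[k] * (x1 - x0))
  (x1 - x0) * acc
}

# baseline input: non-special tokens replaced by [PAD]; boundary and
# reserved placeholder tokens are kept so the reference stays structurally
# aligned with the input
baseline_ids <- function(example, pad_id = 1L) {
  ids <- example$ids
  ids[!example$special] <- pad_id
  ids
}

#' Layer integrated gradients for one example
#'
#' Attributes the positive-class probability to the outputs of the chosen
#' layer along the straight-line path from the activations induced by a
#' content-free baseline (non-special tokens replaced by `[PAD]`) to the
#' actual activations, and sums over the hidden dimension to yield one
#' score per token.
#'
#' @param model an `re_model`.
#' @param example an `encoded_example`.
#' @param config an [attrib_config] (fields `layer`, `steps`).
#' @return list of class `attribution_vector`: `scores` (one per token),
#'   `method`, `layer`, `example`, `completeness` (list with `sum`,
#'   `delta` = f(input) - f(baseline)).
#' @export
layer_integrated_gradients <- function(model, example, config = attrib_config()) {
  enc <- model$encoder
  L <- enc$config$n_layers
  if (config$layer < 0 || config$layer > L)
    stop(sprintf("layer must be in 0..%d", L))
  f_in <- encoder_forward(enc, example$ids, keep_cache = TRUE)
  f_bl <- encoder_forward(enc, baseline_ids(example), keep_cache = TRUE)
  x1 <- f_in$cache$layer_out[[config$layer + 1L]]
  x0 <- f_bl$cache$layer_out[[config$layer + 1L]]
  n_tok <- length(example$ids)
  grad_fn <- function(acts) {
    fwd <- encoder_forward_from(enc, acts, config$layer, keep_cache = TRUE)
    encoder_backward_to(enc, fwd, dlogits_positive_prob(fwd$probs), n_tok)
  }
  attr_mat <- integrated_gradients_core(grad_fn, x0, x1, config$steps)
  scores <- rowSums(attr_mat)
  structure(list(scores = scores, method = "LIG", layer = config$layer,
                 example = example,
                 completeness = list(sum = sum(scores),
                                     delta = f_in$probs[2] - f_bl$probs[2])),
            class = "attribution_vector")
}

#' @export
print.attribution_vector <- function(x, ...) {
  cat(sprintf("<attribution_vector %s layer=%s: %d tokens, max=%.4g>\n",
              x$method, ifelse(is.null(x$layer), "-", x$layer),
              length(x$scores), max(x$scores[is.finite(x$scores)])))
  invisible(x)
}

#' Sampled Shapley values for one example
#'
#' Shapley values of each token under the masking value function: the
#' value of a coalition is the positive-class probability of the input
#' with all absent player tokens replaced by `[PAD]`. Estimated by
#' permutation sampling (`config$samples` permutations, fixed seed); the
#' boundary tokens join the player set only when
#' `config$include_boundary`. Non-player tokens score 0. The efficiency
#' identity `sum(values) = f(full) - f(empty)` holds in expectation and is
#' exact for every single permutation's telescoping sum, so the sampled
#' estimate satisfies it exactly.
#'
#' @param model an `re_model`.
#' @param example an `encoded_example`.
#' @param config an [attrib_config].
#' @return an `attribution_vector` (layer `NA`).
#' @export
shapley_values <- function(model, example, config = attrib_config(method = "SHAP")) {
  enc <- model$encoder
  ids <- example$ids
  players <- which(!example$special |
                     (config$include_boundary & example$tokens %in% c("[CLS]", "[SEP]")))
  scores <- numeric(length(ids))
  if (length(players)) {
    pad <- 1L
    value <- function(present) {
      v <- ids
      v[setdiff(players, present)] <- pad
      encoder_forward(enc, v)$probs[2]
    }
    acc <- numeric(length(players))
    perms <- with_seed(config$seed, lapply(seq_len(config$samples),
                                           function(i) sample(players)))
    for (perm in perms) {
      prev <- value(integer(0))
      present <- integer(0)
      for (p in perm) {
        present <- c(present, p)
        cur <- value(present)
        acc[match(p, players)] <- acc[match(p, players)] + (cur - prev)
        prev <- cur
      }
    }
    scores[players] <- acc / config$samples
  }
  structure(list(scores = scores, method = "SHAP", layer = NA_integer_,
                 example = example, completeness = NULL),
            class = "attribution_vector")
}

#' Post-processing heuristics on an attribution vector
#'
#' Applies the named rules in order; tokens removed by a rule get score
#' `-Inf` so they can never be selected. Rules:
#' \describe{
#'   \item{`special`}{boundary (`[CLS]`/`[SEP]`) and reserved
#'     marker/placeholder tokens.}
#'   \item{`focus_entities`}{sub-tokens inside either focus mention.}
#'   \item{`other_entities`}{sub-tokens inside any other annotated entity
#'     mention (requires `doc`).}
#'   \item{`numeric`}{purely numeric tokens. Punctuation is retained —
#'     tokens like the hyphen in `CD40-TRAF2` stay selectable.}
#'   \item{`stopwords`}{closed-class function words (articles,
#'     prepositions, auxiliaries), which cannot be relation cues but often
#'     soak up attribution mass as context carriers.}
#'   \item{`sentence_punct`}{sentence-delimiting punctuation (periods,
#'     commas, brackets). Linking punctuation — the hyphen or slash joining
#'     two entities — is kept, since it can itself be the cue.}
#' }
#'
#' @param vector an `attribution_vector`.
#' @param example the `encoded_example` the vector aligns to.
#' @param rules character vector of rule names (order respected).
#' @param doc the source [standoff_document], needed by `other_entities`.
#' @return the filtered `attribution_vector`.
#' @export
apply_heuristics <- function(vector, example, rules = default_heuristics(),
                             doc = NULL) {
  scores <- vector$scores
  stopifnot(length(scores) == length(example$ids))
  for (rule in rules) {
    drop <- switch(rule,
      special = example$special,
      focus_entities = example$in_e1 | example$in_e2,
      other_entities = {
        if (is.null(doc)) rep(FALSE, length(scores))
        else {
          e <- doc$entities[!(doc$entities$id %in% c(example$e1, example$e2)), ,
                            drop = FALSE]
          inside <- rep(FALSE, length(scores))
          for (i in seq_len(nrow(e)))
            inside <- inside | (!is.na(example$start) &
                                  example$start >= e$start[i] &
                                  example$end <= e$end[i])
          inside
        }
      },
      numeric = grepl("^##?[0-9]+$|^[0-9]+$", example$tokens),
      stopwords = tolower(example$tokens) %in% trigger_stopwords(),
      sentence_punct = example$tokens %in% c(".", ",", "(", ")", ";", ":",
                                             "?", "!", "[", "]", "{", "}"),
      stop(sprintf("unknown heuristic rule %s", dQuote(rule))))
    scores[drop] <- -Inf
  }
  if (all(!is.finite(scores)))
    stop("heuristics removed every token; no trigger assignable")
  vector$scores <- scores
  vector
}

#' Select the trigger span from an attribution vector
#'
#' Picks the highest-scoring surviving token (ties broken leftmost),
#' always discarding boundary and reserved placeholder tokens, extends the
#' choice to the full word-piece group of its word, and maps the result to
#' original-document character coordinates.
#'
#' @param vector an `attribution_vector` (possibly heuristics-filtered).
#' @param example the `encoded_example`.
#' @return list of class `trigger_prediction`: `doc_id`, `e1`, `e2`,
#'   `start`, `end`, `score`, `method`, `layer`.
#' @export
select_trigger <- function(vector, example) {
  scores <- vector$scores
  eligible <- is.finite(scores) & !example$special & !is.na(example$start)
  if (!any(eligible)) stop("no surviving token to select a trigger from")
  idx <- which(eligible)
  win <- idx[which.max(scores[idx])]          # which.max: leftmost tie-break
  group <- which(!is.na(example$word_id) &
                   example$word_id == example$word_id[win] & !example$special)
  structure(list(doc_id = example$doc_id, e1 = example$e1, e2 = example$e2,
                 start = min(example$start[group]),
                 end = max(example$end[group]),
                 score = scores[win], method = vector$method,
                 layer = vector$layer),
            class = "trigger_prediction")
}

#' Detect triggers for positive-predicted pairs
#'
#' The full explanation pipeline: predict all examples, keep the
#' positive-predicted ones, attribute ([layer_integrated_gradients] or
#' [shapley_values]), filter ([apply_heuristics]) and select
#' ([select_trigger]). Pairs the model scores negative yield no trigger.
#'
#' @param model an `re_model`.
#' @param examples list of `encoded_example`s.
#' @param config an [attrib_config].
#' @param docs optional named list of source documents (enables the
#'   `other_entities` heuristic and trigger text extraction).
#' @return data.frame with one row per emitted trigger: `doc_id`, `e1`,
#'   `e2`, `start`, `end`, `text`, `score`, `method`, `layer`.
#' @export
detect_triggers <- function(model, examples, config = attrib_config(),
                            docs = NULL) {
  preds <- predict_pairs(model, examples)
  out <- list()
  for (i in seq_along(examples)) {
    if (preds$label[i] != "positive") next
    ex <- examples[[i]]
    vec <- if (config$method == "LIG") layer_integrated_gradients(model, ex, config)
           else shapley_values(model, ex, config)
    doc <- if (!is.null(docs)) docs[[ex$doc_id]] else NULL
    res <- tryCatch({
      if (length(config$heuristics))
        vec <- apply_heuristics(vec, ex, config$heuristics, doc)
      select_trigger(vec, ex)
    }, error = function(e) NULL)
    if (is.null(res)) next
    txt <- if (!is.null(doc))
      substring(doc$text, res$start + 1L, res$end) else NA_character_
    out[[length(out) + 1L]] <- data.frame(
      doc_id = res$doc_id, e1 = res$e1, e2 = res$e2,
      start = res$start, end = res$end, text = txt, score = res$score,
      method = res$method, layer = res$layer, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(doc_id = character(), e1 = character(), e2 = character(),
                      start = integer(), end = integer(), text = character(),
                      score = numeric(), method = character(), layer = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-layer prediction-set sweep
#'
#' Generates the full family of trigger prediction sets a layer sweep
#' yields: one LIG set per layer (embedding output plus each hidden
#' layer) and two SHAP sets (with and without the boundary tokens) —
#' `n_layers + 1 + 2` sets in total (27 for a 24-layer encoder).
#'
#' @param model an `re_model`.
#' @param examples list of `encoded_example`s.
#' @param config base [attrib_config] (steps/samples/heuristics reused).
#' @param docs optional source documents.
#' @return named list of trigger data.frames, one per prediction set.
#' @export
trigger_prediction_sets <- function(model, examples, config = attrib_config(),
                                    docs = NULL) {
  L <- model$config$n_layers
  sets <- list()
  for (l in 0:L) {
    cfg <- config; cfg$method <- "LIG"; cfg$layer <- l
    sets[[sprintf("LIG_layer%d", l)]] <- detect_triggers(model, examples, cfg, docs)
  }
  for (wb in c(FALSE, TRUE)) {
    cfg <- config; cfg$method <- "SHAP"; cfg$include_boundary <- wb
    nm <- sprintf("SHAP_%s_boundary", if (wb) "with" else "without")
    sets[[nm]] <- detect_triggers(model, examples, cfg, docs)
  }
  sets
}

#' Lexicon/window baseline trigger matcher
#'
#' Defines a window of `window_size` sub-tokens around each focus mention
#' and matches the lexicon items inside either window, longest item first,
#' case-insensitively, at whole-token boundaries. Matched spans are
#' reported once (overlapping shorter matches are suppressed).
#'
#' @param example an `encoded_example`.
#' @param lexicon character vector of trigger words/phrases (typically
#'   harvested from the trigger dev set).
#' @param window_size window radius in sub-tokens (>= 1).
#' @param doc the source [standoff_document] (for window text).
#' @return data.frame of spans: `doc_id`, `e1`, `e2`, `start`, `end`,
#'   `text` (empty when nothing matches).
#' @export
baseline_trigger_match <- function(example, lexicon, window_size, doc) {
  empty <- data.frame(doc_id = character(), e1 = character(), e2 = character(),
                      start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (!length(lexicon)) return(empty)
  if (window_size < 1) stop("window_size must be >= 1")
  spans <- list()
  for (role in c("in_e1", "in_e2")) {
    pos <- which(example[[role]])
    if (!length(pos)) next
    lo <- max(1L, min(pos) - window_size)
    hi <- min(length(example$ids), max(pos) + window_size)
    idx <- seq(lo, hi)
    idx <- idx[!is.na(example$start[idx])]
    if (!length(idx)) next
    spans[[role]] <- c(min(example$start[idx]), max(example$end[idx]))
  }
  if (!length(spans)) return(empty)

  hits <- list()
  taken <- matrix(numeric(0), ncol = 2)
  for (item in lexicon[order(-nchar(lexicon))]) {
    pat <- paste0("(?<![A-Za-z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", item),
                  "(?![A-Za-z0-9])")
    for (w in spans) {
      seg <- substring(doc$text, w[1] + 1L, w[2])
      m <- gregexpr(pat, seg, ignore.case = TRUE, perl = TRUE)[[1]]
      if (m[1] == -1) next
      for (k in seq_along(m)) {
        s <- w[1] + as.integer(m[k]) - 1L
        e <- s + attr(m, "match.length")[k]
        if (nrow(taken) && any(pmax(taken[, 1], s) < pmin(taken[, 2], e))) next
        taken <- rbind(taken, c(s, e))
        hits[[length(hits) + 1L]] <- data.frame(
          doc_id = example$doc_id, e1 = example$e1, e2 = example$e2,
          start = s, end = e, text = substring(doc$text, s + 1L, e),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  res <- unique(do.call(rbind, hits))
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Triggers as standoff-style span annotations
#'
#' Renders detected triggers as `T`/`#` standoff lines per document for
#' visual inspection next to the source `.txt` (e.g. in an annotation
#' viewer). Spans are typed `Trigger`; a note line records the pair.
#'
#' @param triggers data.frame from [detect_triggers].
#' @param docs named list of source [standoff_document]s.
#' @return named character vector: one `.ann` payload per document id.
#' @export
triggers_as_standoff <- function(triggers, docs) {
  out <- character(0)
  for (id in unique(triggers$doc_id)) {
    tr <- triggers[triggers$doc_id == id, , drop = FALSE]
    doc <- docs[[id]]
    lines <- character(0)
    for (i in seq_len(nrow(tr))) {
      surface <- substring(doc$text, tr$start[i] + 1L, tr$end[i])
      lines <- c(lines,
                 sprintf("T%d\tTrigger %d %d\t%s", i, tr$start[i], tr$end[i],
                         surface),
                 sprintf("#%d\tAnnotatorNotes T%d\ttrigger for %s-%s (%s)",
                         i, i, tr$e1[i], tr$e2[i], tr$method[i]))
    }
    out[id] <- paste0(paste(lines, collapse = "\n"), "\n")
  }
  out
}

#' Export triggers as tab-delimited text
#' @param triggers data.frame from [detect_triggers].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_triggers <- function(triggers, path) {
  utils::write.table(triggers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
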