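#' Model / training configuration
#'
#' Bundles the encoder shape and the training hyper-parameters the grid
#' search explores. The `reference` preset carries the published best
#' values (MSL 128, lr 3e-6, 11 epochs, mini-batch 5); the `baseline`
#' preset the BERT-base comparison values (lr 5e-6, 12 epochs).
#'
#' @param msl maximum sequence length in sub-tokens (window budget,
#'   including the `[CLS]`/`[SEP]` boundary tokens); must be >= 16.
#' @param scheme entity transform, `"mark"` or `"mask"`.
#' @param lr peak learning rate.
#' @param batch_size mini-batch size.
#' @param epochs number of training epochs (no early stopping); >= 1.
#' @param seed integer seed for weight init and batch shuffling.
#' @param d_model,n_layers,n_heads,d_ff encoder dimensions.
#' @param warmup_frac fraction of steps under linear warmup.
#' @param weight_decay decoupled weight decay on non-bias parameters.
#' @param preset optional name: `"reference"` or `"baseline"` fills the
#'   published hyper-parameter values before applying explicit arguments.
#' @return a list of class `model_config`.
#' @export
model_config <- function(msl = 128L, scheme = c("mark", "mask"),
                         lr = 3e-4, batch_size = 8L, epochs = 5L, seed = 42L,
                         d_model = 32L, n_layers = 2L, n_heads = 2L,
                         d_ff = 64L, warmup_frac = 0.1, weight_decay = 0.01,
                         preset = NULL) {
  scheme <- match.arg(scheme)
  cfg <- list(msl = as.integer(msl), scheme = scheme, lr = lr,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              seed = as.integer(seed), d_model = as.integer(d_model),
              n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              d_ff = as.integer(d_ff), warmup_frac = warmup_frac,
              weight_decay = weight_decay)
  if (!is.null(preset)) {
    pre <- switch(match.arg(preset, c("reference", "baseline")),
                  reference = list(msl = 128L, lr = 3e-6, epochs = 11L, batch_size = 5L),
                  baseline = list(msl = 128L, lr = 5e-6, epochs = 12L, batch_size = 5L))
    called <- names(match.call())[-1]
    for (nm in setdiff(names(pre), called)) cfg[[nm]] <- pre[[nm]]
  }
  if (cfg$msl < 16L) stop("msl must be >= 16")
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  if (cfg$d_model %% cfg$n_heads != 0L) stop("d_model must be divisible by n_heads")
  structure(cfg, class = "model_config")
}

#' Enumerate candidate mention pairs of one document
#'
#' All unordered mention pairs. A pair is positive iff a
#' `Complex_formation` relation links the two mentions or any
#' Equiv-expansion of them; two mentions inside the same Equiv group are
#' aliases of one entity and are not enumerated. When `labeled = FALSE`
#' (prediction regime: no relation layer) labels are `"unlabeled"`.
#'
#' @param doc a filtered [standoff_document].
#' @param labeled whether gold relations define labels.
#' @return data.frame with columns `doc_id`, `e1`, `e2`, `label`
#'   (`e1 < e2` by text position, then id).
#' @export
enumerate_pairs <- function(doc, labeled = TRUE) {
  e <- doc$entities
  empty <- data.frame(doc_id = character(), e1 = character(), e2 = character(),
                      label = character(), stringsAsFactors = FALSE)
  if (nrow(e) < 2) return(empty)
  ord <- order(e$start, e$end, e$id, method = "radix")
  ids <- e$id[ord]

  group_of <- stats::setNames(ids, ids)
  for (gi in seq_along(doc$equivs))
    group_of[doc$equivs[[gi]]] <- paste0("equiv", gi)
  expand <- function(id) names(group_of)[group_of == group_of[id]]

  rel_keys <- character()
  r <- doc$relations[doc$relations$type == "Complex_formation", , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    a_set <- expand(r$arg1[i]); b_set <- r$arg2[i]
    b_set <- expand(b_set)
    grid <- expand.grid(a = a_set, b = b_set, stringsAsFactors = FALSE)
    rel_keys <- c(rel_keys, pair_key(grid$a, grid$b))
  }
  rel_keys <- unique(rel_keys)

  combs <- utils::combn(length(ids), 2)
  e1 <- ids[combs[1, ]]; e2 <- ids[combs[2, ]]
  same_group <- group_of[e1] == group_of[e2]
  e1 <- e1[!same_group]; e2 <- e2[!same_group]
  label <- if (!labeled) rep("unlabeled", length(e1))
           else ifelse(pair_key(e1, e2) %in% rel_keys, "positive", "negative")
  data.frame(doc_id = doc$doc_id, e1 = e1, e2 = e2, label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mark or mask the two focus mentions in a document's text
#'
#' `mark` wraps the two mentions in reserved boundary placeholders
#' (`[E1] ... [/E1]`, `[E2] ... [/E2]`); `mask` replaces each mention's
#' surface with a reserved placeholder (`[P1]`, `[P2]`). All other text —
#' including other entity mentions — is unchanged. Insertions happen at
#' exact offsets, so nested or interleaved focus mentions are handled
#' without altering non-focus text.
#'
#' @param doc a [standoff_document].
#' @param pair list or one-row data.frame with elements `e1`, `e2`.
#' @param scheme `"mark"` or `"mask"`.
#' @return list with `text` (transformed string) and `segments`, a
#'   data.frame mapping transformed offsets back to the original:
#'   columns `new_start`, `new_end`, `orig_start`, `orig_end` (NA for
#'   inserted placeholders), `kind` (`"text"` or `"special"`), `token`
#'   (the reserved token for special segments) and `role`
#'   (`""`/`"e1"`/`"e2"`, which focus mention a segment belongs to).
#' @export
transform_text <- function(doc, pair, scheme = c("mark", "mask")) {
  scheme <- match.arg(scheme)
  e <- doc$entities
  m1 <- e[e$id == pair$e1, , drop = FALSE]
  m2 <- e[e$id == pair$e2, , drop = FALSE]
  if (!nrow(m1) || !nrow(m2)) stop("pair mentions not found in document")

  # breakpoints where insertions/replacements happen, in document order
  if (scheme == "mark") {
    ins <- data.frame(
      pos = c(m1$start, m1$end, m2$start, m2$end),
      token = c("[E1]", "[/E1]", "[E2]", "[/E2]"),
      open = c(TRUE, FALSE, TRUE, FALSE),
      role = c("e1", "e1", "e2", "e2"),
      stringsAsFactors = FALSE)
    # closers sort before openers at equal positions so adjacent mentions
    # produce "... [/E1] [E2] ..."
    ins <- ins[order(ins$pos, ins$open), , drop = FALSE]
    segs <- list(); cur <- 0L
    for (i in seq_len(nrow(ins))) {
      if (ins$pos[i] > cur)
        segs[[length(segs) + 1L]] <- list(kind = "text", orig_start = cur,
                                          orig_end = ins$pos[i], token = "", role = "")
      segs[[length(segs) + 1L]] <- list(kind = "special", orig_start = NA_integer_,
                                        orig_end = NA_integer_, token = ins$token[i],
                                        role = ins$role[i])
      cur <- max(cur, ins$pos[i])
    }
    if (cur < nchar(doc$text))
      segs[[length(segs) + 1L]] <- list(kind = "text", orig_start = cur,
                                        orig_end = nchar(doc$text), token = "", role = "")
  } else {
    spans <- data.frame(start = c(m1$start, m2$start), end = c(m1$end, m2$end),
                        token = c("[P1]", "[P2]"), role = c("e1", "e2"),
                        stringsAsFactors = FALSE)
    spans <- spans[order(spans$start, spans$end), , drop = FALSE]
    segs <- list(); cur <- 0L
    for (i in seq_len(nrow(spans))) {
      s <- max(cur, spans$start[i])
      if (s > cur)
        segs[[length(segs) + 1L]] <- list(kind = "text", orig_start = cur,
                                          orig_end = s, token = "", role = "")
      segs[[length(segs) + 1L]] <- list(kind = "special",
                                        orig_start = spans$start[i],
                                        orig_end = spans$end[i],
                                        token = spans$token[i], role = spans$role[i])
      cur <- max(cur, spans$end[i])
    }
    if (cur < nchar(doc$text))
      segs[[length(segs) + 1L]] <- list(kind = "text", orig_start = cur,
                                        orig_end = nchar(doc$text), token = "", role = "")
  }

  # assemble transformed text, padding specials with spaces to keep word
  # boundaries clean for the tokenizer
  pieces <- character(length(segs))
  new_start <- integer(length(segs)); new_end <- integer(length(segs))
  cursor <- 0L
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    piece <- if (s$kind == "text")
      substring(doc$text, s$orig_start + 1L, s$orig_end)
    else paste0(" ", s$token, " ")
    pieces[i] <- piece
    new_start[i] <- cursor
    cursor <- cursor + nchar(piece)
    new_end[i] <- cursor
  }
  segments <- data.frame(
    new_start = new_start, new_end = new_end,
    orig_start = vapply(segs, function(s) as.integer(s$orig_start), 0L),
    orig_end = vapply(segs, function(s) as.integer(s$orig_end), 0L),
    kind = vapply(segs, `[[`, "", "kind"),
    token = vapply(segs, `[[`, "", "token"),
    role = vapply(segs, `[[`, "", "role"),
    stringsAsFactors = FALSE)
  list(text = paste(pieces, collapse = ""), segments = segments)
}

#' Map a transformed-text character span back to original coordinates
#'
#' Restricts the span to copied (non-inserted) segments and returns the
#' enclosing original-document interval, or NULL when the span covers only
#' inserted placeholder material.
#'
#' @param segments the `segments` table from [transform_text].
#' @param start,end 0-based half-open span in transformed coordinates.
#' @return integer vector `c(start, end)` in original coordinates, or NULL.
#' @export
map_to_original <- function(segments, start, end) {
  seg <- segments[segments$kind == "text" &
                    segments$new_end > start & segments$new_start < end, , drop = FALSE]
  if (!nrow(seg)) return(NULL)
  os <- seg$orig_start + pmax(0L, start - seg$new_start)
  oe <- seg$orig_end - pmax(0L, seg$new_end - end)
  c(min(os), max(oe))
}

#' Encode one candidate pair as a token window
#'
#' Transforms the text ([transform_text]), tokenizes it, and — if the two
#' focus mentions (with their markers) fit a window of at most
#' `config$msl` sub-tokens including the `[CLS]`/`[SEP]` boundary tokens —
#' returns the window with maximal symmetric context: the minimal
#' entity-enclosing token span is extended alternately left and right
#' until the budget is exhausted or the document ends, leftover budget
#' flowing to the other side. No sentence splitting is performed, so
#' cross-sentence pairs encode whenever they fit.
#'
#' @param doc a [standoff_document].
#' @param pair list/row with `e1`, `e2` and optionally `label`.
#' @param config a [model_config].
#' @param tokenizer a [wp_tokenizer].
#' @return an `encoded_example` (see Details) or NULL when the pair cannot
#'   fit any window. Fields: `doc_id`, `e1`, `e2`, `label`, `scheme`,
#'   `ids` (token ids incl. boundaries), `tokens`, `start`/`end`
#'   (original-document character offsets per token, NA for specials),
#'   `word_id`, `special` (boundary/placeholder flags), `in_e1`/`in_e2`
#'   (tokens belonging to the focus mentions incl. their markers) and
#'   `window` (original-document char span covered).
#' @export
build_example <- function(doc, pair, config, tokenizer) {
  tr <- transform_text(doc, pair, config$scheme)
  toks <- tokenize_transformed(tokenizer, tr)
  if (!nrow(toks)) return(NULL)

  focus <- toks$role %in% c("e1", "e2") |
    (config$scheme == "mark" & (toks$in_span_e1 | toks$in_span_e2))
  if (!any(focus)) return(NULL)
  lo <- min(which(focus)); hi <- max(which(focus))
  budget <- config$msl - 2L       # [CLS] + [SEP]
  if (hi - lo + 1L > budget) return(NULL)

  extra <- budget - (hi - lo + 1L)
  left_avail <- lo - 1L
  right_avail <- nrow(toks) - hi
  take_left <- min(left_avail, ceiling(extra / 2))
  take_right <- min(right_avail, extra - take_left)
  # leftover flows back to the other side
  take_left <- min(left_avail, extra - take_right)
  sel <- seq(lo - take_left, hi + take_right)
  w <- toks[sel, , drop = FALSE]

  cls <- tokenizer$index[["[CLS]"]]; sep <- tokenizer$index[["[SEP]"]]
  ids <- c(cls, w$id, sep)
  tokens <- c("[CLS]", w$token, "[SEP]")
  start <- c(NA_integer_, w$orig_start, NA_integer_)
  end <- c(NA_integer_, w$orig_end, NA_integer_)
  word_id <- c(NA_integer_, w$word_id, NA_integer_)
  special <- c(TRUE, w$special, TRUE)
  in_e1 <- c(FALSE, w$role == "e1" | w$in_span_e1, FALSE)
  in_e2 <- c(FALSE, w$role == "e2" | w$in_span_e2, FALSE)
  covered <- start[!is.na(start)]
  structure(list(
    doc_id = doc$doc_id, e1 = pair$e1, e2 = pair$e2,
    label = if (!is.null(pair$label)) pair$label else "unlabeled",
    scheme = config$scheme,
    ids = as.integer(ids), tokens = tokens, start = start, end = end,
    word_id = word_id, special = special, in_e1 = in_e1, in_e2 = in_e2,
    window = c(min(covered), max(end[!is.na(end)]))
  ), class = "encoded_example")
}

#' @export
print.encoded_example <- function(x, ...) {
  cat(sprintf("<encoded_example %s %s-%s [%s, %s]: %d tokens>\n",
              x$doc_id, x$e1, x$e2, x$label, x$scheme, length(x$ids)))
  invisible(x)
}

# tokenize a transformed text segment-wise: copied segments carry exact
# original offsets, inserted specials become single reserved tokens
tokenize_transformed <- function(tokenizer, tr) {
  segs <- tr$segments
  out <- list(); word_base <- 0L
  # focus-mention original spans (for mark scheme entity-token flags)
  e1_span <- map_role_span(segs, "e1")
  e2_span <- map_role_span(segs, "e2")
  for (i in seq_len(nrow(segs))) {
    if (segs$kind[i] == "special") {
      out[[length(out) + 1L]] <- data.frame(
        token = segs$token[i], id = unname(tokenizer$index[segs$token[i]]),
        orig_start = segs$orig_start[i], orig_end = segs$orig_end[i],
        word_id = word_base + 1L, special = TRUE, role = segs$role[i],
        in_span_e1 = FALSE, in_span_e2 = FALSE, stringsAsFactors = FALSE)
      word_base <- word_base + 1L
    } else {
      tk <- tokenize(tokenizer, substring(tr$text, segs$new_start[i] + 1L,
                                          segs$new_end[i]))
      if (!nrow(tk)) next
      os <- segs$orig_start[i] + tk$start
      oe <- segs$orig_start[i] + tk$end
      out[[length(out) + 1L]] <- data.frame(
        token = tk$token, id = tk$id, orig_start = os, orig_end = oe,
        word_id = word_base + tk$word_id, special = FALSE, role = "",
        in_span_e1 = span_contains(e1_span, os, oe),
        in_span_e2 = span_contains(e2_span, os, oe),
        stringsAsFactors = FALSE)
      word_base <- word_base + max(tk$word_id)
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

map_role_span <- function(segs, role) {
  if (any(segs$role == role & segs$kind == "special" & !is.na(segs$orig_start))) {
    # mask scheme: the placeholder segment records the mention span
    s <- segs[segs$role == role & segs$kind == "special", , drop = FALSE]
    return(c(min(s$orig_start, na.rm = TRUE), max(s$orig_end, na.rm = TRUE)))
  }
  idx <- which(segs$role == role)
  if (length(idx) < 2) return(NULL)
  # mark scheme: mention text lies between the opener and closer segments
  inner <- segs[seq(min(idx) + 1L, max(idx) - 1L), , drop = FALSE]
  inner <- inner[inner$kind == "text", , drop = FALSE]
  if (!nrow(inner)) return(NULL)
  c(min(inner$orig_start), max(inner$orig_end))
}

span_contains <- function(span, start, end) {
  if (is.null(span)) return(rep(FALSE, length(start)))
  start >= span[1] & end <= span[2]
}

#' Serialize encoded examples to JSON-lines
#' @param examples list of `encoded_example`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_examples <- function(examples, path) {
  lines <- vapply(examples, function(ex) {
    jsonlite::toJSON(list(doc_id = ex$doc_id, e1 = ex$e1, e2 = ex$e2,
                          label = ex$label, scheme = ex$scheme,
                          ids = ex$ids, tokens = ex$tokens,
                          start = ex$start, end = ex$end,
                          word_id = ex$word_id, special = ex$special,
                          in_e1 = ex$in_e1, in_e2 = ex$in_e2,
                          window = ex$window),
                     auto_unbox = TRUE, null = "null", na = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Build all examples for a set of documents
#' @param docs list of filtered [standoff_document]s.
#' @param config a [model_config].
#' @param tokenizer a [wp_tokenizer].
#' @param labeled passed to [enumerate_pairs].
#' @return list of `encoded_example`s (pairs not fitting are skipped).
#' @export
build_examples <- function(docs, config, tokenizer, labeled = TRUE) {
  out <- list()
  for (doc in docs) {
    prs <- enumerate_pairs(doc, labeled = labeled)
    for (i in seq_len(nrow(prs))) {
      ex <- build_example(doc, prs[i, ], config, tokenizer)
      if (!is.null(ex)) out[[length(out) + 1L]] <- ex
    }
  }
  out
}
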