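#' WordPiece-style tokenizer with character offsets
#'
#' A small sub-word tokenizer in the BERT WordPiece family: the text is
#' first split into word tokens (runs of letters/digits) and single
#' punctuation characters; words absent from the vocabulary are split by
#' greedy longest-match into in-vocabulary pieces, continuation pieces
#' carrying a `##` prefix. A single-character backstop in the vocabulary
#' guarantees every seen character tokenizes without `[UNK]`. Every
#' sub-token keeps its exact 0-based half-open character span.
#'
#' Reserved entries (always present, in fixed id order): `[PAD]`, `[UNK]`,
#' `[CLS]`, `[SEP]`, the pair markers `[E1]` `[/E1]` `[E2]` `[/E2]` and the
#' mask placeholders `[P1]` `[P2]` — the "unused token" mechanism of
#' pretrained vocabularies, reproduced here explicitly.
#'
#' @param vocab character vector of word / `##piece` entries (reserved
#'   tokens are added automatically and must not be supplied).
#' @return an object of class `wp_tokenizer`.
#' @export
wp_tokenizer <- function(vocab = character()) {
  specials <- reserved_tokens()
  vocab <- setdiff(unique(vocab), specials)
  full <- c(specials, vocab)
  structure(list(vocab = full,
                 index = stats::setNames(seq_along(full), full),
                 n_special = length(specials)),
            class = "wp_tokenizer")
}

reserved_tokens <- function() {
  c("[PAD]", "[UNK]", "[CLS]", "[SEP]",
    "[E1]", "[/E1]", "[E2]", "[/E2]", "[P1]", "[P2]")
}

#' @export
print.wp_tokenizer <- function(x, ...) {
  cat(sprintf("<wp_tokenizer: %d entries (%d reserved)>\n",
              length(x$vocab), x$n_special))
  invisible(x)
}

token_id <- function(tok, token) {
  id <- tok$index[token]
  ifelse(is.na(id), tok$index[["[UNK]"]], id)
}

#' Build a tokenizer vocabulary from raw texts
#'
#' Whole words are ranked by frequency and kept up to `max_size`; all
#' single characters observed (and their `##` continuations) are always
#' included so tokenization never falls back to `[UNK]` on seen text.
#'
#' @param texts character vector of training texts.
#' @param max_size maximum number of whole-word entries.
#' @param min_count drop words rarer than this.
#' @return a [wp_tokenizer].
#' @export
build_vocab <- function(texts, max_size = 4000L, min_count = 1L) {
  words <- unlist(lapply(texts, basic_tokens_chr))
  tab <- table(words)
  tab <- tab[tab >= min_count]
  # radix (byte) order: locale-independent, so vocabularies — and with them
  # token ids and weight initialization — are reproducible everywhere
  ord <- order(-as.vector(tab), names(tab), method = "radix")
  keep <- names(tab)[ord][seq_len(min(length(tab), max_size))]
  chars <- unique(unlist(strsplit(unique(words), "", fixed = TRUE)))
  wp_tokenizer(c(keep, chars, paste0("##", chars)))
}

basic_token_spans <- function(text) {
  m <- gregexpr("[A-Za-z0-9_]+|[^A-Za-z0-9_[:space:]]", text)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer(),
                                    text = character(), stringsAsFactors = FALSE))
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len,
             text = substring(text, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

basic_tokens_chr <- function(text) basic_token_spans(text)$text

# greedy longest-match wordpiece split of one word; returns character vector
# of pieces (continuations ##-prefixed) or NULL when the word cannot be split
wordpiece_split <- function(tok, word) {
  if (!is.na(tok$index[word])) return(word)
  pieces <- character()
  pos <- 1L
  n <- nchar(word)
  while (pos <= n) {
    found <- NA_character_
    for (len in seq(n - pos + 1L, 1L)) {
      cand <- substr(word, pos, pos + len - 1L)
      key <- if (pos == 1L) cand else paste0("##", cand)
      if (!is.na(tok$index[key])) { found <- key; pos <- pos + len; break }
    }
    if (is.na(found)) return(NULL)
    pieces <- c(pieces, found)
  }
  pieces
}

#' Tokenize text into sub-tokens with offsets
#'
#' @param tok a [wp_tokenizer].
#' @param text a single string.
#' @return data.frame with columns `token`, `id`, `start`, `end` (0-based
#'   half-open character offsets into `text`) and `word_id` (index of the
#'   basic word the sub-token belongs to, for word-level span merging).
#' @export
tokenize <- function(tok, text) {
  basics <- basic_token_spans(text)
  out <- vector("list", nrow(basics))
  for (i in seq_len(nrow(basics))) {
    w <- basics$text[i]
    pieces <- wordpiece_split(tok, w)
    if (is.null(pieces)) {
      out[[i]] <- data.frame(token = "[UNK]", id = tok$index[["[UNK]"]],
                             start = basics$start[i], end = basics$end[i],
                             word_id = i, stringsAsFactors = FALSE)
    } else {
      lens <- nchar(sub("^##", "", pieces))
      ends <- basics$start[i] + cumsum(lens)
      starts <- ends - lens
      out[[i]] <- data.frame(token = pieces, id = unname(token_id(tok, pieces)),
                             start = starts, end = ends, word_id = i,
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(token = character(), id = integer(),
                                      start = integer(), end = integer(),
                                      word_id = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
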