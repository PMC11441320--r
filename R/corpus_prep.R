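#' Restrict a document to the prediction regime
#'
#' Keeps only `Gene_or_gene_product` mentions without the `Blocklisted`
#' attribute, the regime the large-scale protein–protein run operates in.
#' Relations losing an argument are dropped, attributes of removed
#' entities are dropped, and Equiv groups are pruned to surviving members
#' (groups shrinking below two members disappear). Idempotent.
#'
#' @param doc a [standoff_document].
#' @return the filtered [standoff_document].
#' @export
filter_for_prediction <- function(doc) {
  e <- doc$entities
  blocked <- unique(doc$attributes$target[doc$attributes$name == "Blocklisted"])
  keep <- e$type == "Gene_or_gene_product" & !(e$id %in% blocked)
  kept_ids <- e$id[keep]

  r <- doc$relations
  r <- r[r$arg1 %in% kept_ids & r$arg2 %in% kept_ids, , drop = FALSE]
  a <- doc$attributes
  a <- a[a$target %in% c(kept_ids, r$id), , drop = FALSE]
  equivs <- lapply(doc$equivs, function(g) intersect(g, kept_ids))
  equivs <- equivs[vapply(equivs, length, 0L) >= 2]

  standoff_document(doc$doc_id, doc$text,
                    e[keep, , drop = FALSE], r, a, equivs, doc$notes)
}

#' Document-level train/dev/test split
#'
#' Partitions a corpus by whole document, uniformly at random under a
#' recorded seed. Partition sizes follow the largest-remainder rule so
#' e.g. 10 documents under fractions (0.6, 0.2, 0.2) give 6/2/2.
#'
#' @param corpus named list of [standoff_document]s.
#' @param fractions numeric vector summing to 1, one entry per partition.
#' @param seed integer seed making the split reproducible.
#' @param names partition names (default train/dev/test for 3 fractions).
#' @return named list of sub-corpora (lists of documents).
#' @export
split_documents <- function(corpus, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                            names = NULL) {
  if (!length(corpus)) stop("cannot split an empty corpus")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names)) {
    names <- if (length(fractions) == 3) c("train", "dev", "test")
             else paste0("part", seq_along(fractions))
  }
  n <- length(corpus)
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac_part <- fractions * n - sizes
    order_idx <- order(frac_part, decreasing = TRUE)
    sizes[order_idx[seq_len(rem)]] <- sizes[order_idx[seq_len(rem)]] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  bounds <- cumsum(c(0L, sizes))
  out <- lapply(seq_along(fractions), function(i) {
    idx <- perm[seq(bounds[i] + 1L, length.out = sizes[i])]
    corpus[sort(idx)]
  })
  stats::setNames(out, names)
}

#' Load a released split from manifest files
#'
#' A manifest is a plain-text file with one document id per line; it takes
#' precedence over re-sampling when the released split is available.
#'
#' @param corpus named list of [standoff_document]s (names = doc ids).
#' @param manifest_paths named character vector of file paths
#'   (e.g. `c(train = ..., dev = ..., test = ...)`).
#' @return named list of sub-corpora in manifest order.
#' @export
load_split_manifest <- function(corpus, manifest_paths) {
  lapply(manifest_paths, function(p) {
    ids <- readLines(p, warn = FALSE)
    ids <- trimws(ids[nzchar(trimws(ids))])
    missing <- setdiff(ids, names(corpus))
    if (length(missing))
      stop(sprintf("manifest %s names %d document(s) absent from the corpus (first: %s)",
                   p, length(missing), missing[1]))
    corpus[ids]
  })
}

#' Positive Protein–Protein pairs of a document set
#'
#' @param docs list of filtered [standoff_document]s.
#' @return data.frame with columns `doc_id`, `e1`, `e2` (order-normalized),
#'   one row per gold-positive unordered pair after Equiv expansion.
#' @keywords internal
positive_pairs <- function(docs) {
  out <- lapply(docs, function(doc) {
    pr <- enumerate_pairs(doc)
    pr[pr$label == "positive", c("doc_id", "e1", "e2"), drop = FALSE]
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(doc_id = character(), e1 = character(),
                                      e2 = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Build trigger development and test pair sets
#'
#' Takes the gold-positive Protein–Protein pairs of the development
#' documents, drops pairs whose encoded example would not fit a window of
#' `msl` sub-tokens (exclusion depends only on the tokenizer and `msl`),
#' and splits the remainder into two halves balanced by document count,
#' the odd document going to the dev half. Document order is shuffled
#' under `seed` before halving.
#'
#' @param dev_docs list of filtered [standoff_document]s.
#' @param msl window budget in sub-tokens.
#' @param tokenizer a [wp_tokenizer].
#' @param seed integer seed for the document shuffle.
#' @param scheme entity transform used for the fit test (`"mark"` default).
#' @return list with data.frames `trigger_dev` and `trigger_test`
#'   (columns `doc_id`, `e1`, `e2`), plus `excluded` (pairs dropped by the
#'   window test).
#' @export
build_trigger_sets <- function(dev_docs, msl, tokenizer, seed = 1L,
                               scheme = "mark") {
  if (is.null(names(dev_docs)))
    names(dev_docs) <- vapply(dev_docs, `[[`, "", "doc_id")
  pos <- positive_pairs(dev_docs)
  cfg <- model_config(msl = msl, scheme = scheme)
  fits <- logical(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    ex <- build_example(dev_docs[[pos$doc_id[i]]],
                        list(e1 = pos$e1[i], e2 = pos$e2[i], label = "positive"),
                        cfg, tokenizer)
    fits[i] <- !is.null(ex)
  }
  kept <- pos[fits, , drop = FALSE]
  doc_ids <- sort(unique(kept$doc_id), method = "radix")
  perm <- with_seed(seed, sample(doc_ids))
  n_dev <- ceiling(length(perm) / 2)
  dev_ids <- perm[seq_len(n_dev)]
  list(trigger_dev = kept[kept$doc_id %in% dev_ids, , drop = FALSE],
       trigger_test = kept[!(kept$doc_id %in% dev_ids), , drop = FALSE],
       excluded = pos[!fits, , drop = FALSE])
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
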