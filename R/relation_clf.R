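#' Train the binary Complex_formation classifier
#'
#' Fine-tunes the encoder and learns the decision layer from scratch with
#' AdamW (decoupled weight decay), linear warmup over the first
#' `warmup_frac` of steps followed by linear decay to zero. No early
#' stopping: the model trains for the configured number of epochs, dev
#' metrics are computed after every epoch, and the returned weights are
#' those of the epoch with the highest dev F1 (ties broken by the earliest
#' epoch).
#'
#' @param train_examples list of `encoded_example`s with both labels
#'   present.
#' @param dev_examples non-empty list of `encoded_example`s with labels.
#' @param config a [model_config].
#' @param tokenizer the [wp_tokenizer] the examples were built with (fixes
#'   the vocabulary size).
#' @param verbose print per-epoch dev metrics.
#' @return list with `model` (class `re_model`: encoder + config +
#'   vocabulary size), `history` (data.frame epoch/loss/precision/recall/
#'   F1) and `best_epoch`.
#' @export
train_relation_model <- function(train_examples, dev_examples, config,
                                 tokenizer, verbose = FALSE) {
  labels <- vapply(train_examples, `[[`, "", "label")
  if (!length(train_examples)) stop("empty training set")
  if (length(unique(labels)) < 2)
    stop(sprintf("training set carries a single label (%s); both classes are required",
                 unique(labels)))
  if (!length(dev_examples)) stop("empty development set")
  over <- vapply(train_examples, function(ex) length(ex$ids), 0L) > config$msl
  if (any(over)) stop("training example exceeds MSL")

  model <- encoder_init(length(tokenizer$vocab), config)
  opt <- adamw_init(model$params)
  n <- length(train_examples)
  steps_total <- config$epochs * ceiling(n / config$batch_size)
  warmup <- max(1L, floor(config$warmup_frac * steps_total))
  step <- 0L

  y <- ifelse(labels == "positive", 2L, 1L)
  best <- list(f1 = -1, epoch = NA_integer_, params = NULL)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     precision = numeric(), recall = numeric(), f1 = numeric())

  rng <- with_seed(config$seed + 1L, lapply(seq_len(config$epochs),
                                            function(i) sample.int(n)))
  for (epoch in seq_len(config$epochs)) {
    ord <- rng[[epoch]]
    epoch_loss <- 0
    for (b_start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[seq(b_start, min(b_start + config$batch_size - 1L, n))]
      grads <- NULL
      for (i in idx) {
        ex <- train_examples[[i]]
        fwd <- encoder_forward(model, ex$ids, keep_cache = TRUE)
        epoch_loss <- epoch_loss - log(max(fwd$probs[y[i]], 1e-12))
        dlogits <- fwd$probs
        dlogits[y[i]] <- dlogits[y[i]] - 1
        g <- encoder_backward(model, fwd, dlogits / length(idx))
        grads <- if (is.null(grads)) g else add_grads(grads, g)
      }
      step <- step + 1L
      lr_t <- lr_schedule(config$lr, step, warmup, steps_total)
      model$params <- adamw_step(model$params, grads, opt, lr_t,
                                 config$weight_decay)
    }
    preds <- predict_pairs(as_re_model(model), dev_examples)
    rep <- evaluate_pairs(preds, examples_gold(dev_examples))
    hist <- rbind(hist, data.frame(epoch = epoch, loss = epoch_loss / n,
                                   precision = rep$precision,
                                   recall = rep$recall, f1 = rep$f1))
    if (verbose)
      message(sprintf("epoch %d: loss=%.4f dev P=%.3f R=%.3f F1=%.3f",
                      epoch, epoch_loss / n, rep$precision, rep$recall, rep$f1))
    if (rep$f1 > best$f1) {                     # strict >: earliest epoch wins ties
      best <- list(f1 = rep$f1, epoch = epoch, params = model$params)
    }
  }
  model$params <- best$params
  list(model = as_re_model(model), history = hist, best_epoch = best$epoch)
}

as_re_model <- function(encoder) {
  structure(list(encoder = encoder, config = encoder$config,
                 vocab_size = encoder$vocab_size),
            class = "re_model")
}

#' @export
print.re_model <- function(x, ...) {
  cat(sprintf("<re_model: %d-layer encoder, d=%d, msl=%d, scheme=%s>\n",
              x$config$n_layers, x$config$d_model, x$config$msl,
              x$config$scheme))
  invisible(x)
}

lr_schedule <- function(lr, step, warmup, total) {
  if (step <= warmup) return(lr * step / warmup)
  lr * max(0, (total - step) / max(1, total - warmup))
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

adamw_init <- function(params) {
  env <- new.env(parent = emptyenv())
  env$m <- lapply(params, function(p) p * 0)
  env$v <- lapply(params, function(p) p * 0)
  env$t <- 0L
  env
}

adamw_step <- function(params, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  decayed <- grepl("^(L[0-9]+\\.)?(W|E_)", names(params))
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    if (decayed[match(nm, names(params))])
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  params
}

#' Predict labels for encoded examples
#'
#' @param model an `re_model`.
#' @param examples list of `encoded_example`s built with the model's
#'   tokenizer and MSL (an example longer than the model MSL is an error).
#' @return data.frame with columns `doc_id`, `e1`, `e2`, `score`
#'   (positive-class probability) and `label` (`"positive"` iff
#'   `score >= 0.5`, the two-way softmax argmax).
#' @export
predict_pairs <- function(model, examples) {
  if (!length(examples))
    return(data.frame(doc_id = character(), e1 = character(), e2 = character(),
                      score = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  lens <- vapply(examples, function(ex) length(ex$ids), 0L)
  if (any(lens > model$config$msl))
    stop(sprintf("example with %d tokens exceeds model MSL %d",
                 max(lens), model$config$msl))
  score <- vapply(examples, function(ex)
    encoder_forward(model$encoder, ex$ids)$probs[2], 0)
  data.frame(doc_id = vapply(examples, `[[`, "", "doc_id"),
             e1 = vapply(examples, `[[`, "", "e1"),
             e2 = vapply(examples, `[[`, "", "e2"),
             score = score,
             label = ifelse(score >= 0.5, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}

examples_gold <- function(examples) {
  data.frame(doc_id = vapply(examples, `[[`, "", "doc_id"),
             e1 = vapply(examples, `[[`, "", "e1"),
             e2 = vapply(examples, `[[`, "", "e2"),
             label = vapply(examples, `[[`, "", "label"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Precision/recall/F1 on the positive class
#'
#' Counts TP/FP/FN over unordered pairs; predictions and gold must cover
#' the same pair universe (gold labels are already Equiv-expanded by
#' [enumerate_pairs]).
#'
#' @param predictions data.frame from [predict_pairs].
#' @param gold_pairs data.frame with `doc_id`, `e1`, `e2`, `label`.
#' @return list of class `pair_eval_report`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_pairs <- function(predictions, gold_pairs) {
  pkey <- function(df) paste(df$doc_id, pair_key(df$e1, df$e2))
  kp <- pkey(predictions); kg <- pkey(gold_pairs)
  if (length(kp) != length(kg) || !setequal(kp, kg) || anyDuplicated(kp))
    stop("prediction and gold pair universes differ")
  gold_lab <- stats::setNames(gold_pairs$label, kg)[kp]
  tp <- sum(predictions$label == "positive" & gold_lab == "positive")
  fp <- sum(predictions$label == "positive" & gold_lab != "positive")
  fn <- sum(predictions$label != "positive" & gold_lab == "positive")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1),
            class = "pair_eval_report")
}

#' @export
print.pair_eval_report <- function(x, ...) {
  cat(sprintf("pair evaluation: TP=%d FP=%d FN=%d  P=%.3f R=%.3f F1=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Repeated-training grid search
#'
#' Runs `repeats` trainings per configuration with distinct seeds
#' (`config$seed + repeat - 1`) and summarizes the best-epoch dev F1 of
#' each repeat as mean and standard deviation; the winning configuration
#' is the one with the highest mean F1. A failing cell is recorded and the
#' grid continues.
#'
#' @param train_examples,dev_examples encoded example lists.
#' @param config_grid list of [model_config]s.
#' @param repeats trainings per configuration (>= 1).
#' @param tokenizer the shared [wp_tokenizer].
#' @return list of class `experiment_report`: `cells` (per-config
#'   data.frame with `mean_f1`, `sd_f1`, `mean_precision`, `mean_recall`,
#'   `error`), `runs` (per-repeat metrics), `best` (index of the winning
#'   config or NA).
#' @export
grid_search <- function(train_examples, dev_examples, config_grid, repeats,
                        tokenizer) {
  if (!length(config_grid)) stop("empty configuration grid")
  if (repeats < 1) stop("repeats must be >= 1")
  runs <- list(); cells <- list()
  for (ci in seq_along(config_grid)) {
    cfg <- config_grid[[ci]]
    f1s <- ps <- rs <- rep(NA_real_, repeats)
    err <- NA_character_
    for (rep_i in seq_len(repeats)) {
      cfg_r <- cfg; cfg_r$seed <- cfg$seed + rep_i - 1L
      res <- tryCatch(
        train_relation_model(train_examples, dev_examples, cfg_r, tokenizer),
        error = function(e) e)
      if (inherits(res, "error")) { err <- conditionMessage(res); next }
      brow <- res$history[res$history$epoch == res$best_epoch, ]
      f1s[rep_i] <- brow$f1; ps[rep_i] <- brow$precision; rs[rep_i] <- brow$recall
      runs[[length(runs) + 1L]] <- data.frame(config = ci, rep = rep_i,
                                              best_epoch = res$best_epoch,
                                              precision = brow$precision,
                                              recall = brow$recall, f1 = brow$f1)
    }
    ok <- !is.na(f1s)
    cells[[ci]] <- data.frame(
      config = ci,
      mean_f1 = if (any(ok)) mean(f1s[ok]) else NA_real_,
      sd_f1 = if (sum(ok) > 1) stats::sd(f1s[ok]) else if (any(ok)) 0 else NA_real_,
      mean_precision = if (any(ok)) mean(ps[ok]) else NA_real_,
      mean_recall = if (any(ok)) mean(rs[ok]) else NA_real_,
      n_ok = sum(ok), error = err, stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(config = integer(), rep = integer(), best_epoch = integer(),
               precision = numeric(), recall = numeric(), f1 = numeric())
  best <- if (all(is.na(cells$mean_f1))) NA_integer_ else
    which.max(ifelse(is.na(cells$mean_f1), -Inf, cells$mean_f1))
  structure(list(cells = cells, runs = runs, best = best),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("grid search report\n")
  print(x$cells, row.names = FALSE)
  if (!is.na(x$best)) cat(sprintf("best config: %d\n", x$best))
  invisible(x)
}

#' Save / load a trained model as JSON text
#'
#' Weights are serialized with full double precision; the directory also
#' records the configuration and vocabulary so predictions are exactly
#' reproducible.
#'
#' @param model an `re_model`.
#' @param dir output directory.
#' @param tokenizer optional [wp_tokenizer] to store alongside.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir, tokenizer = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  weights <- lapply(model$encoder$params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = length(p), data = as.numeric(p))
  })
  jsonlite::write_json(weights, file.path(dir, "weights.json"), digits = NA)
  if (!is.null(tokenizer))
    writeLines(tokenizer$vocab, file.path(dir, "vocab.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(model_config, cfg[setdiff(names(cfg), c())])
  raw <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  params <- lapply(raw, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2]) else as.numeric(w$data)
  })
  vocab_file <- file.path(dir, "vocab.txt")
  vocab_size <- if (file.exists(vocab_file)) length(readLines(vocab_file))
                else nrow(params$E_tok)
  enc <- structure(list(params = params, config = config,
                        vocab_size = vocab_size), class = "re_encoder")
  as_re_model(enc)
}

#' Load the tokenizer stored with a model directory
#' @param dir model directory written by [save_model].
#' @return a [wp_tokenizer].
#' @export
load_model_tokenizer <- function(dir) {
  vocab <- readLines(file.path(dir, "vocab.txt"))
  wp_tokenizer(setdiff(vocab, reserved_tokens()))
}

#' Export predictions as the tab-delimited score file
#' @param predictions data.frame from [predict_pairs].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
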