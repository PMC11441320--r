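#' Annotated document container
#'
#' An `standoff_document` holds one document's text together with its
#' entity mentions, entity attributes, undirected `Complex_formation`
#' relations and Equiv (alias) groups, all in 0-based half-open character
#' offsets over `text`.
#'
#' @param doc_id document identifier (usually the file stem).
#' @param text document text, a single string.
#' @param entities data.frame with columns `id`, `type`, `start`, `end`,
#'   `text` and a list column `fragments` (two-column start/end matrix per
#'   entity; one row for contiguous mentions). For discontinuous mentions
#'   `start`/`end` are the enclosing span.
#' @param relations data.frame with columns `id`, `type`, `arg1`, `arg2`.
#' @param attributes data.frame with columns `id`, `name`, `target`,
#'   `value` (`value` is `""` for binary attributes).
#' @param equivs list of character vectors of entity ids (disjoint after
#'   transitive merge).
#' @param notes character vector of opaque standoff lines (`#` notes and
#'   `N` normalizations) preserved verbatim for lossless round-trips.
#' @return an object of class `standoff_document`.
#' @export
standoff_document <- function(doc_id, text,
                              entities = empty_entities(),
                              relations = empty_relations(),
                              attributes = empty_attributes(),
                              equivs = list(),
                              notes = character()) {
  # canonical form so write/parse round-trips compare identical
  if (nrow(entities))
    entities$fragments <- I(unname(unclass(entities$fragments)))
  equivs <- merge_equiv_groups(equivs)
  doc <- structure(
    list(doc_id = doc_id, text = text, entities = entities,
         relations = relations, attributes = attributes,
         equivs = equivs, notes = notes),
    class = "standoff_document")
  validate_standoff(doc)
  doc
}

empty_entities <- function() {
  data.frame(id = character(), type = character(),
             start = integer(), end = integer(), text = character(),
             fragments = I(list()), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(), type = character(),
             arg1 = character(), arg2 = character(), stringsAsFactors = FALSE)
}

empty_attributes <- function() {
  data.frame(id = character(), name = character(),
             target = character(), value = character(), stringsAsFactors = FALSE)
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff_document %s: %d chars, %d entities, %d relations, %d equiv groups>\n",
              x$doc_id, nchar(x$text), nrow(x$entities), nrow(x$relations),
              length(x$equivs)))
  invisible(x)
}

entity_types <- function() {
  c("Gene_or_gene_product", "Chemical", "Complex", "Protein_Family")
}

#' Attribute names carried by one entity
#' @param doc a `standoff_document`.
#' @param entity_id a `T` id.
#' @return character vector of attribute names (possibly empty).
#' @export
entity_attributes <- function(doc, entity_id) {
  doc$attributes$name[doc$attributes$target == entity_id]
}

#' Validate a standoff document's referential integrity
#'
#' Checks offsets against the text, surface strings against offsets,
#' relation/attribute/Equiv id resolution and relation uniqueness per
#' unordered pair.
#'
#' @param doc a `standoff_document`.
#' @return `doc`, invisibly; stops with an integrity error otherwise.
#' @export
validate_standoff <- function(doc) {
  n <- nchar(doc$text)
  e <- doc$entities
  if (nrow(e)) {
    bad <- e$start < 0 | e$start >= e$end | e$end > n
    if (any(bad))
      stop(sprintf("integrity error in %s: entity %s has offsets outside text [0,%d)",
                   doc$doc_id, e$id[which(bad)[1]], n))
    for (i in seq_len(nrow(e))) {
      frag <- e$fragments[[i]]
      ref <- paste(substring(doc$text, frag[, 1] + 1L, frag[, 2]), collapse = " ")
      if (!identical(ref, e$text[i]))
        stop(sprintf("integrity error in %s: entity %s surface %s does not match text %s",
                     doc$doc_id, e$id[i], dQuote(e$text[i]), dQuote(ref)))
    }
  }
  ids <- e$id
  r <- doc$relations
  if (nrow(r)) {
    missing <- setdiff(c(r$arg1, r$arg2), ids)
    if (length(missing))
      stop(sprintf("integrity error in %s: relation argument(s) %s unresolved",
                   doc$doc_id, paste(missing, collapse = ", ")))
    if (any(r$arg1 == r$arg2))
      stop(sprintf("integrity error in %s: self-relation", doc$doc_id))
    key <- pair_key(r$arg1, r$arg2)
    if (anyDuplicated(key))
      stop(sprintf("integrity error in %s: duplicate relation on one pair", doc$doc_id))
  }
  if (nrow(doc$attributes)) {
    missing <- setdiff(doc$attributes$target, c(ids, r$id))
    if (length(missing))
      stop(sprintf("integrity error in %s: attribute target(s) %s unresolved",
                   doc$doc_id, paste(missing, collapse = ", ")))
  }
  for (g in doc$equivs) {
    if (length(g) < 2) stop(sprintf("integrity error in %s: Equiv group with <2 members", doc$doc_id))
    if (length(setdiff(g, ids)))
      stop(sprintf("integrity error in %s: Equiv member unresolved", doc$doc_id))
  }
  if (length(doc$equivs) > 1 &&
      anyDuplicated(unlist(doc$equivs)))
    stop(sprintf("integrity error in %s: Equiv groups not disjoint", doc$doc_id))
  invisible(doc)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Parse one BRAT standoff document
#'
#' Reads a `.txt`/`.ann` content pair into a [standoff_document]. `T`
#' (entity), `R` (relation), `A`/`M` (attribute) and `*  Equiv` lines are
#' interpreted; `#` notes and `N` normalizations are preserved opaquely.
#' Discontinuous entity spans (semicolon-separated fragments) are stored
#' with their fragment list; the working span is the enclosing
#' `(min start, max end)` interval. Equiv groups are transitively merged.
#' Multiple relations on the same unordered pair collapse to one, with a
#' warning.
#'
#' @param txt_content document text (single string).
#' @param ann_content annotation file content (single string, possibly empty).
#' @param doc_id identifier attached to the parsed document.
#' @return a [standoff_document].
#' @export
read_standoff <- function(txt_content, ann_content, doc_id = "doc") {
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]

  ents <- list(); rels <- list(); attrs <- list()
  equiv_raw <- list(); notes <- character()

  for (i in seq_along(lines)) {
    line <- lines[i]
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    lid <- fields[1]
    kind <- substr(lid, 1, 1)
    perr <- function(msg) stop(sprintf("parse error at line %d (%s): %s", i, doc_id, msg))

    if (kind == "T") {
      if (length(fields) < 2) perr("entity line needs a type/offset field")
      head_parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      type <- head_parts[1]
      span_str <- paste(head_parts[-1], collapse = " ")
      frags <- strsplit(span_str, ";", fixed = TRUE)[[1]]
      if (!length(frags)) perr("entity line needs offsets")
      mat <- matrix(NA_integer_, nrow = length(frags), ncol = 2)
      for (k in seq_along(frags)) {
        se <- suppressWarnings(as.integer(strsplit(trimws(frags[k]), " ")[[1]]))
        if (length(se) != 2 || anyNA(se)) perr("malformed entity offsets")
        mat[k, ] <- se
      }
      surface <- if (length(fields) >= 3) paste(fields[-(1:2)], collapse = "\t") else ""
      ents[[lid]] <- list(id = lid, type = type,
                          start = min(mat[, 1]), end = max(mat[, 2]),
                          text = surface, fragments = mat)
    } else if (kind == "R") {
      if (length(fields) < 2) perr("relation line needs arguments")
      parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(parts) != 3) perr("relation line needs 'Type Arg1:Tx Arg2:Ty'")
      a1 <- sub("^Arg1:", "", parts[2]); a2 <- sub("^Arg2:", "", parts[3])
      if (identical(a1, parts[2]) || identical(a2, parts[3]))
        perr("relation arguments must be 'Arg1:' / 'Arg2:'")
      rels[[lid]] <- list(id = lid, type = parts[1], arg1 = a1, arg2 = a2)
    } else if (kind == "A" || kind == "M") {
      parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(parts) < 2) perr("attribute line needs 'Name Target [Value]'")
      attrs[[length(attrs) + 1L]] <- list(
        id = lid, name = parts[1], target = parts[2],
        value = if (length(parts) >= 3) paste(parts[-(1:2)], collapse = " ") else "")
    } else if (kind == "*") {
      parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (parts[1] != "Equiv" || length(parts) < 3) perr("malformed Equiv line")
      equiv_raw[[length(equiv_raw) + 1L]] <- parts[-1]
    } else if (kind == "#" || kind == "N") {
      notes <- c(notes, line)
    } else {
      perr(sprintf("unrecognized standoff line id %s", dQuote(lid)))
    }
  }

  entities <- if (length(ents)) {
    data.frame(id = vapply(ents, `[[`, "", "id"),
               type = vapply(ents, `[[`, "", "type"),
               start = vapply(ents, `[[`, 0L, "start"),
               end = vapply(ents, `[[`, 0L, "end"),
               text = vapply(ents, `[[`, "", "text"),
               fragments = I(unname(lapply(ents, `[[`, "fragments"))),
               stringsAsFactors = FALSE, row.names = NULL)
  } else empty_entities()

  relations <- if (length(rels)) {
    data.frame(id = vapply(rels, `[[`, "", "id"),
               type = vapply(rels, `[[`, "", "type"),
               arg1 = vapply(rels, `[[`, "", "arg1"),
               arg2 = vapply(rels, `[[`, "", "arg2"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else empty_relations()
  if (nrow(relations)) {
    key <- paste(relations$type, pair_key(relations$arg1, relations$arg2))
    if (anyDuplicated(key)) {
      warning(sprintf("%s: %d duplicate relation(s) on the same unordered pair collapsed",
                      doc_id, sum(duplicated(key))))
      relations <- relations[!duplicated(key), , drop = FALSE]
    }
  }

  attributes <- if (length(attrs)) {
    data.frame(id = vapply(attrs, `[[`, "", "id"),
               name = vapply(attrs, `[[`, "", "name"),
               target = vapply(attrs, `[[`, "", "target"),
               value = vapply(attrs, `[[`, "", "value"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else empty_attributes()

  standoff_document(doc_id, txt_content, entities, relations, attributes,
                    merge_equiv_groups(equiv_raw), notes)
}

# transitive merge of alias groups; output sorted for determinism
merge_equiv_groups <- function(groups) {
  if (!length(groups)) return(list())
  repeat {
    merged <- FALSE
    out <- list()
    for (g in groups) {
      hit <- which(vapply(out, function(o) length(intersect(o, g)) > 0, TRUE))
      if (length(hit)) {
        out[[hit[1]]] <- union(out[[hit[1]]], g)
        merged <- TRUE
      } else out[[length(out) + 1L]] <- g
    }
    groups <- out
    if (!merged) break
  }
  lapply(groups, function(g) sort(unique(g), method = "radix"))
}

#' Serialize a document back to standoff
#'
#' Inverse of [read_standoff] up to line order:
#' `read_standoff(write_standoff(doc))` reproduces the document.
#'
#' @param doc a [standoff_document].
#' @return list with elements `txt` and `ann` (single strings).
#' @export
write_standoff <- function(doc) {
  validate_standoff(doc)
  lines <- character()
  e <- doc$entities
  for (i in seq_len(nrow(e))) {
    frag <- e$fragments[[i]]
    span <- paste(apply(frag, 1, function(se) paste(se[1], se[2])), collapse = ";")
    lines <- c(lines, sprintf("%s\t%s %s\t%s", e$id[i], e$type[i], span, e$text[i]))
  }
  r <- doc$relations
  for (i in seq_len(nrow(r)))
    lines <- c(lines, sprintf("%s\t%s Arg1:%s Arg2:%s", r$id[i], r$type[i], r$arg1[i], r$arg2[i]))
  a <- doc$attributes
  for (i in seq_len(nrow(a))) {
    val <- if (nzchar(a$value[i])) paste0(" ", a$value[i]) else ""
    lines <- c(lines, sprintf("%s\t%s %s%s", a$id[i], a$name[i], a$target[i], val))
  }
  for (g in doc$equivs)
    lines <- c(lines, sprintf("*\tEquiv %s", paste(g, collapse = " ")))
  lines <- c(lines, doc$notes)
  list(txt = doc$text, ann = paste0(paste(lines, collapse = "\n"),
                                    if (length(lines)) "\n" else ""))
}

#' Read a directory of standoff file pairs
#'
#' @param dir directory holding `<id>.txt` / `<id>.ann` pairs (a missing
#'   `.ann` is treated as empty).
#' @return named list of [standoff_document]s, sorted by id.
#' @export
read_standoff_dir <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE),
               method = "radix")
  docs <- lapply(txts, function(tf) {
    id <- sub("\\.txt$", "", basename(tf))
    af <- file.path(dir, paste0(id, ".ann"))
    ann <- if (file.exists(af)) read_file_utf8(af) else ""
    read_standoff(read_file_utf8(tf), ann, doc_id = id)
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  docs
}

#' Write a corpus of documents as standoff file pairs
#' @param corpus list of [standoff_document]s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_standoff_dir <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus) {
    out <- write_standoff(doc)
    write_file_utf8(out$txt, file.path(dir, paste0(doc$doc_id, ".txt")))
    write_file_utf8(out$ann, file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(dir)
}

read_file_utf8 <- function(path) {
  readChar(path, file.size(path), useBytes = TRUE)
}

write_file_utf8 <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(x, con, eos = NULL, useBytes = TRUE)
}

#' Corpus statistics
#'
#' Counts documents, whitespace-delimited words, entities per type,
#' relations per type and entity attributes per name, the summary the
#' corpus release reports (e.g. documents, `Complex_formation` relations,
#' Blocklisted entities).
#'
#' @param corpus list of [standoff_document]s.
#' @return an object of class `standoff_stats` with fields `documents`,
#'   `words`, `entities` (named count vector by type), `relations` (by
#'   type), `attributes` (by name) and `total_entities`.
#' @export
corpus_statistics <- function(corpus) {
  tab <- function(x) if (length(x)) table(x) else table(character())
  ents <- unlist(lapply(corpus, function(d) d$entities$type))
  rels <- unlist(lapply(corpus, function(d) d$relations$type))
  attrs <- unlist(lapply(corpus, function(d) d$attributes$name))
  words <- sum(vapply(corpus, function(d)
    length(strsplit(trimws(d$text), "\\s+")[[1]][nzchar(strsplit(trimws(d$text), "\\s+")[[1]])]),
    0L))
  structure(list(
    documents = length(corpus),
    words = words,
    entities = c(tab(ents)),
    total_entities = length(ents),
    relations = c(tab(rels)),
    attributes = c(tab(attrs))
  ), class = "standoff_stats")
}

#' @export
print.standoff_stats <- function(x, ...) {
  cat("Corpus statistics\n")
  cat(sprintf("  documents : %d\n  words     : %d\n", x$documents, x$words))
  cat(sprintf("  entities  : %d\n", x$total_entities))
  for (nm in names(x$entities)) cat(sprintf("    %-22s %d\n", nm, x$entities[[nm]]))
  cat("  relations :\n")
  for (nm in names(x$relations)) cat(sprintf("    %-22s %d\n", nm, x$relations[[nm]]))
  cat("  attributes:\n")
  for (nm in names(x$attributes)) cat(sprintf("    %-22s %d\n", nm, x$attributes[[nm]]))
  invisible(x)
}

#' Statistics as a two-column TSV table
#' @param stats a `standoff_stats` object.
#' @return data.frame with columns `key`, `count`.
#' @export
stats_as_table <- function(stats) {
  keys <- c("documents", "words", "entities_total",
            if (length(stats$entities)) paste0("entity_", names(stats$entities)),
            if (length(stats$relations)) paste0("relation_", names(stats$relations)),
            if (length(stats$attributes)) paste0("attribute_", names(stats$attributes)))
  counts <- c(stats$documents, stats$words, stats$total_entities,
              unname(stats$entities), unname(stats$relations), unname(stats$attributes))
  data.frame(key = keys, count = as.integer(counts), stringsAsFactors = FALSE)
}
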