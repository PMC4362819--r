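# Dictionary tagging of sentences: gene mentions via a symbol lexicon,
# interaction keywords via the ontology keyword index. Matching is
# case-insensitive, word-boundary, longest-match-first, left-to-right;
# tokens are maximal runs of [A-Za-z0-9-], so hyphenated forms such as
# "IL-12" or "IFN-gamma" are single tokens.

tokenize_text <- function(text) {
  m <- gregexpr("[A-Za-z0-9-]+", text)[[1L]]
  if (m[1L] == -1L) return(character(0))
  regmatches(text, list(m))[[1L]]
}

# canonical lowercase token-sequence key for a surface form / phrase
phrase_key <- function(x) {
  vapply(x, function(s) paste(tolower(tokenize_text(s)), collapse = " "), "",
         USE.NAMES = FALSE)
}

# A matcher is a hashed phrase table plus the distinct phrase lengths
# (in tokens), scanned longest-first. `payload` is a list parallel to
# `phrases`; phrases normalizing to the same key must carry mergeable
# payloads, combined with `merge_fun` (default: error on collision).
build_matcher <- function(phrases, payload, merge_fun = NULL) {
  keys <- phrase_key(phrases)
  keep <- nzchar(keys)
  keys <- keys[keep]
  payload <- payload[keep]
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(keys)) {
    k <- keys[[i]]
    if (is.null(env[[k]])) {
      env[[k]] <- payload[[i]]
    } else if (is.null(merge_fun)) {
      if (!identical(env[[k]], payload[[i]])) {
        stop("conflicting dictionary entries for surface form '", k, "'")
      }
    } else {
      env[[k]] <- merge_fun(env[[k]], payload[[i]])
    }
  }
  lens <- sort(unique(lengths(strsplit(keys, " ", fixed = TRUE))),
               decreasing = TRUE)
  list(env = env, lens = lens)
}

# Greedy longest-match-first, left-to-right scan; each token is consumed by
# at most one match. Returns the list of payloads of the matches, in order.
scan_matches <- function(tokens_lc, matcher) {
  n <- length(tokens_lc)
  hits <- list()
  i <- 1L
  while (i <= n) {
    advanced <- FALSE
    for (L in matcher$lens) {
      if (i + L - 1L > n) next
      key <- paste(tokens_lc[i:(i + L - 1L)], collapse = " ")
      val <- matcher$env[[key]]
      if (!is.null(val)) {
        hits[[length(hits) + 1L]] <- val
        i <- i + L
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  hits
}

#' Construct a gene lexicon
#'
#' Maps case-normalized surface forms (the symbol itself plus optional
#' synonyms) to canonical uppercase gene symbols. Two different canonical
#' symbols claiming the same surface form is a load error.
#'
#' @param symbols character vector of canonical gene symbols.
#' @param synonyms list (parallel to `symbols`) of character vectors of
#'   surface-form synonyms; may be `NULL`.
#' @return a `gene_lexicon` object.
#' @export
gene_lexicon <- function(symbols, synonyms = NULL) {
  stopifnot(is.character(symbols), length(symbols) >= 1L)
  symbols <- toupper(symbols)
  if (anyDuplicated(symbols)) {
    stop("duplicate canonical symbol: ", symbols[duplicated(symbols)][1L])
  }
  if (is.null(synonyms)) synonyms <- rep(list(character(0)), length(symbols))
  stopifnot(length(synonyms) == length(symbols))
  surfaces <- mapply(function(sym, syn) unique(c(sym, syn[nzchar(syn)])),
                     symbols, synonyms, SIMPLIFY = FALSE)
  phrases <- unlist(surfaces, use.names = FALSE)
  payload <- as.list(rep(symbols, lengths(surfaces)))
  keys <- phrase_key(phrases)
  collide <- tapply(unlist(payload), keys, function(x) length(unique(x)))
  if (any(collide > 1L)) {
    stop("lexicon collision: surface form '", names(collide)[collide > 1L][1L],
         "' maps to multiple canonical symbols")
  }
  matcher <- build_matcher(phrases, payload)
  structure(list(symbols = symbols, matcher = matcher), class = "gene_lexicon")
}

#' Read a gene lexicon from TSV
#'
#' Expects a header line `symbol<TAB>synonyms` with pipe-separated synonyms
#' (the synonyms column may be empty).
#'
#' @param path path to the lexicon TSV.
#' @return a `gene_lexicon` object.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          na.strings = character(0))
  if (!"symbol" %in% names(df)) stop("lexicon must have a 'symbol' column")
  syn <- if ("synonyms" %in% names(df)) {
    lapply(strsplit(df$synonyms, "|", fixed = TRUE), trimws)
  } else NULL
  gene_lexicon(df$symbol, syn)
}

# keyword matcher built from a keyword_index; payload = term-id sets
keyword_matcher <- function(index) {
  stopifnot(inherits(index, "keyword_index"))
  build_matcher(names(index), unname(as.list(index)),
                merge_fun = function(a, b) sort(unique(c(a, b))))
}

#' Tag one sentence with gene mentions and interaction keywords
#'
#' Gene mentions and interaction keywords are matched independently (one
#' channel each) by case-insensitive, word-boundary, longest-match-first
#' dictionary lookup; a token span is consumed by at most one match per
#' channel.
#'
#' @param sent a list or one-row data frame with fields `doc_id`, `sent_id`,
#'   `text`, or a plain character sentence.
#' @param lexicon a [gene_lexicon()].
#' @param index a [keyword_index()].
#' @return a list with `genes` (canonical symbols, deduplicated, in order of
#'   first mention) and `term_ids` (sorted union of term ids of all matched
#'   keywords).
#' @export
tag_sentence <- function(sent, lexicon, index) {
  text <- if (is.character(sent)) sent else sent$text
  tag_tokens(tolower(tokenize_text(text)), lexicon$matcher,
             keyword_matcher(index))
}

tag_tokens <- function(tokens_lc, gene_matcher, kw_matcher) {
  genes <- unlist(scan_matches(tokens_lc, gene_matcher), use.names = FALSE)
  terms <- unlist(scan_matches(tokens_lc, kw_matcher), use.names = FALSE)
  list(genes = unique(genes),
       term_ids = sort(unique(terms)))
}

new_records <- function(doc_id = character(0), sent_id = integer(0),
                        gene1 = character(0), gene2 = character(0),
                        term_ids = character(0), score = numeric(0)) {
  data.frame(doc_id = doc_id, sent_id = as.integer(sent_id),
             gene1 = gene1, gene2 = gene2, term_ids = term_ids,
             score = if (length(score)) score else rep(NA_real_, length(doc_id)),
             stringsAsFactors = FALSE)
}

#' Extract gene-pair interaction records from one sentence
#'
#' Emits one record per unordered pair of distinct canonical gene symbols
#' co-mentioned in the sentence, provided at least one interaction keyword
#' matched; each record carries the full set of matched term ids
#' (pipe-joined, sorted) and a lexicographically ordered pair. Scores are
#' left unset.
#'
#' @inheritParams tag_sentence
#' @return a records data frame with columns `doc_id`, `sent_id`, `gene1`,
#'   `gene2`, `term_ids`, `score` (zero rows when fewer than two genes or no
#'   keyword matched).
#' @export
extract_records <- function(sent, lexicon, index) {
  tagged <- tag_sentence(sent, lexicon, index)
  records_from_tags(sent$doc_id, sent$sent_id, tagged)
}

records_from_tags <- function(doc_id, sent_id, tagged) {
  g <- tagged$genes
  if (length(g) < 2L || !length(tagged$term_ids)) return(new_records())
  pairs <- utils::combn(sort(g), 2L)
  n <- ncol(pairs)
  new_records(rep(doc_id, n), rep(as.integer(sent_id), n),
              pairs[1L, ], pairs[2L, ],
              rep(paste(tagged$term_ids, collapse = "|"), n))
}

#' Tag a whole corpus and extract interaction records
#'
#' @param corpus a data frame with columns `doc_id`, `sent_id`, `text`
#'   (see [read_corpus()]).
#' @param lexicon a [gene_lexicon()].
#' @param index a [keyword_index()].
#' @return one records data frame for all sentences (see [extract_records()]).
#' @export
tag_corpus <- function(corpus, lexicon, index) {
  km <- keyword_matcher(index)
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    tagged <- tag_tokens(tolower(tokenize_text(corpus$text[[i]])),
                         lexicon$matcher, km)
    out[[i]] <- records_from_tags(corpus$doc_id[[i]], corpus$sent_id[[i]],
                                  tagged)
  }
  out <- out[vapply(out, nrow, 0L) > 0L]
  if (!length(out)) return(new_records())
  do.call(rbind, out)
}

#' Filter interaction records by confidence score
#'
#' Confidence scores (e.g., from an external sentence classifier) are
#' attached by `(doc_id, sent_id, gene1, gene2)` lookup; records whose score
#' is non-positive are removed. Records without a score entry are treated as
#' unscored and retained; with `scores = NULL` every record passes through
#' (this package does not itself score sentences).
#'
#' @param records a records data frame.
#' @param scores a data frame with columns `doc_id`, `sent_id`, `gene1`,
#'   `gene2`, `score`, or `NULL`.
#' @return the filtered records data frame, scores attached where available.
#' @export
filter_by_score <- function(records, scores = NULL) {
  if (!is.null(scores)) {
    need <- c("doc_id", "sent_id", "gene1", "gene2", "score")
    stopifnot(all(need %in% names(scores)))
    g1 <- pmin(scores$gene1, scores$gene2)
    g2 <- pmax(scores$gene1, scores$gene2)
    key_s <- paste(scores$doc_id, scores$sent_id, g1, g2, sep = "\r")
    key_r <- paste(records$doc_id, records$sent_id, records$gene1,
                   records$gene2, sep = "\r")
    hit <- match(key_r, key_s)
    records$score <- ifelse(is.na(hit), records$score, scores$score[hit])
  }
  keep <- is.na(records$score) | records$score > 0
  records[keep, , drop = FALSE]
}

#' Select documents matching a concept vocabulary
#'
#' A document is selected when any of its sentences contains (by the same
#' case-insensitive, word-boundary matching used for tagging; multiword terms
#' as contiguous token sequences) any base variant of the concept word or any
#' specific concept term.
#'
#' @param corpus a corpus data frame (`doc_id`, `sent_id`, `text`).
#' @param base_variants lowercase character vector of concept-word variants
#'   (e.g., `c("vaccine", "vaccines", "vaccination", "vaccinated")`).
#' @param concept_terms lowercase character vector of specific concept terms
#'   (may be multiword); may be empty if `base_variants` is not.
#' @return sorted character vector of selected `doc_id`s.
#' @export
select_concept_documents <- function(corpus, base_variants,
                                     concept_terms = character(0)) {
  vocab <- unique(c(base_variants, concept_terms))
  vocab <- vocab[nzchar(vocab)]
  if (!length(vocab)) stop("empty concept vocabulary")
  matcher <- build_matcher(vocab, as.list(rep(TRUE, length(vocab))),
                           merge_fun = function(a, b) TRUE)
  sel <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(corpus))) {
    doc <- corpus$doc_id[[i]]
    if (!is.null(sel[[doc]])) next
    toks <- tolower(tokenize_text(corpus$text[[i]]))
    if (length(scan_matches(toks, matcher))) sel[[doc]] <- TRUE
  }
  sort(ls(sel))
}

#' Read a sentence corpus
#'
#' Accepts either TSV with header `doc_id<TAB>sent_id<TAB>text` or JSONL with
#' the same keys (detected from the file extension `.jsonl`/`.json`).
#' Malformed rows are reported with their line number.
#'
#' @param path path to the corpus file.
#' @return a data frame with character `doc_id`, integer `sent_id`,
#'   character `text`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      x <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) NULL)
      if (is.null(x) || !all(c("doc_id", "sent_id", "text") %in% names(x))) {
        stop("malformed corpus row at line ", i)
      }
      data.frame(doc_id = as.character(x$doc_id),
                 sent_id = as.integer(x$sent_id),
                 text = as.character(x$text), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    if (!length(lines)) stop("empty corpus file: ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (!identical(header[1:3], c("doc_id", "sent_id", "text"))) {
      stop("corpus header must be doc_id, sent_id, text")
    }
    body <- lines[-1L]
    body_keep <- nzchar(trimws(body))
    fields <- strsplit(body, "\t", fixed = TRUE)
    rows <- vector("list", length(body))
    for (i in seq_along(body)) {
      if (!body_keep[[i]]) next
      f <- fields[[i]]
      sid <- suppressWarnings(as.integer(f[2L]))
      if (length(f) != 3L || is.na(sid) || !nzchar(f[3L])) {
        stop("malformed corpus row at line ", i + 1L)
      }
      rows[[i]] <- c(f[1L], f[2L], f[3L])
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    df <- data.frame(
      doc_id = vapply(rows, `[[`, "", 1L),
      sent_id = as.integer(vapply(rows, `[[`, "", 2L)),
      text = vapply(rows, `[[`, "", 3L),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(paste(df$doc_id, df$sent_id))) {
    stop("duplicate (doc_id, sent_id) in corpus")
  }
  df
}

#' Read a concept-term list
#'
#' Plain text, one term per line; `#` starts a comment; terms are lowercased.
#'
#' @param path path to the term list.
#' @return character vector of lowercase terms.
#' @export
read_concept_terms <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  tolower(lines[nzchar(lines)])
}

#' Read a confidence-score table
#'
#' TSV with header `doc_id`, `sent_id`, `gene1`, `gene2`, `score`.
#'
#' @param path path to the score TSV.
#' @return a data frame suitable for [filter_by_score()].
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("doc_id", "sent_id", "gene1", "gene2", "score")
  if (!all(need %in% names(df))) {
    stop("score table must have columns: ", paste(need, collapse = ", "))
  }
  df$doc_id <- as.character(df$doc_id)
  df$sent_id <- as.integer(df$sent_id)
  df$score <- as.numeric(df$score)
  df
}
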