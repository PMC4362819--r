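# Term-annotated gene-pair networks. The counting unit for enrichment is the
# unique unordered gene pair per term; distinct-document counts are kept only
# for the "most frequent gene pair" report column. Annotations obey the
# true-path rule: a pair annotated to a term is annotated to all its
# ancestors, so a parent term's count includes all its child terms.

pair_id <- function(gene1, gene2) paste(gene1, gene2, sep = " ")

render_pair <- function(pair) sub(" ", "_", pair, fixed = TRUE)

new_network <- function(pairs_by_term, universe, doc_count) {
  structure(list(pairs_by_term = pairs_by_term, universe = universe,
                 doc_count = doc_count),
            class = "annotated_network")
}

#' Build a term-annotated gene-pair network
#'
#' Aggregates interaction records into a mapping term -> set of unique gene
#' pairs, propagating every record's pair from its directly matched terms to
#' all their ancestors (up to the interaction root). For each (term, pair)
#' the number of distinct supporting documents is recorded.
#'
#' @param records a records data frame (`doc_id`, `sent_id`, `gene1`,
#'   `gene2`, `term_ids` pipe-joined, optional `score`).
#' @param onto the `interaction_ontology` the records were tagged against.
#' @return an `annotated_network`: `pairs_by_term` (term id -> sorted pair
#'   set), `universe` (pairs annotated to at least one term), `doc_count`
#'   (term id -> named integer vector of distinct-document counts per pair).
#' @export
build_network <- function(records, onto) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(new_network(stats::setNames(list(), character(0)), character(0),
                       stats::setNames(list(), character(0))))
  }
  tl <- strsplit(records$term_ids, "|", fixed = TRUE)
  used <- unique(unlist(tl, use.names = FALSE))
  unknown <- setdiff(used, onto$ids)
  if (length(unknown)) stop("record references unknown term: ", unknown[1L])

  prop <- lapply(used, function(t) c(t, term_ancestors(onto, t)))
  names(prop) <- used
  per_row <- lapply(tl, function(ts) {
    unique(unlist(prop[ts], use.names = FALSE))
  })
  nrep <- lengths(per_row)

  pair <- pair_id(records$gene1, records$gene2)
  long_term <- unlist(per_row, use.names = FALSE)
  long_pair <- rep.int(pair, nrep)
  long_doc <- rep.int(records$doc_id, nrep)

  keep <- !duplicated(paste(long_term, long_pair, long_doc, sep = "\r"))
  doc_count <- lapply(split(long_pair[keep], long_term[keep]), function(p) {
    tb <- table(p)
    stats::setNames(as.integer(tb), names(tb))
  })
  pairs_by_term <- lapply(doc_count, names)
  new_network(pairs_by_term, sort(unique(pair)), doc_count)
}

#' Build the sub-network restricted to a document subset
#'
#' Identical to [build_network()] applied to the records whose `doc_id` lies
#' in `doc_ids` (e.g., the concept-specific document set).
#'
#' @inheritParams build_network
#' @param doc_ids character vector of selected document ids.
#' @return an `annotated_network`.
#' @export
subset_network <- function(records, doc_ids, onto) {
  build_network(records[records$doc_id %in% doc_ids, , drop = FALSE], onto)
}

#' Write a network as TSV
#'
#' One row per (term, pair): `term_id`, `gene1`, `gene2`, `n_docs`.
#'
#' @param network an `annotated_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  terms <- names(network$pairs_by_term)
  rows <- lapply(terms, function(t) {
    dc <- network$doc_count[[t]]
    g <- strsplit(names(dc), " ", fixed = TRUE)
    data.frame(term_id = t,
               gene1 = vapply(g, `[[`, "", 1L),
               gene2 = vapply(g, `[[`, "", 2L),
               n_docs = as.integer(dc), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), gene1 = character(0),
               gene2 = character(0), n_docs = integer(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.annotated_network <- function(x, ...) {
  cat(sprintf("Annotated gene-pair network: %d pairs, %d terms\n",
              length(x$universe), length(x$pairs_by_term)))
  invisible(x)
}
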