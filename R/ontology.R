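# Interaction-type ontology: a rooted is_a DAG whose terms carry
# literature-mining keyword annotations. Only the subsumption hierarchy is
# modeled; interactor roles, networks and pathways are out of scope.

#' Normalize an ontology identifier
#'
#' Identifiers are used in underscore form internally (`"MI_0194"`); the colon
#' form (`"MI:0194"`) is accepted on input and normalized.
#'
#' @param x character vector of identifiers.
#' @return character vector in underscore form.
#' @export
#' @examples
#' normalize_term_id(c("GO:0018377", "MI_0194"))
normalize_term_id <- function(x) {
  sub(":", "_", x, fixed = TRUE)
}

# internal constructor shared by the parser and the simulator; validates
# uniqueness, dangling parents and acyclicity, and builds the child map.
new_ontology <- function(ids, labels, parents, keywords, root_id) {
  stopifnot(is.character(ids), length(ids) >= 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term id: ", ids[duplicated(ids)][1L])
  }
  names(labels) <- ids
  names(parents) <- ids
  names(keywords) <- ids
  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, ids)
  if (length(missing)) {
    stop("dangling parent reference: ", missing[1L])
  }
  if (!root_id %in% ids) {
    stop("root term not present: ", root_id)
  }
  cyc <- find_cycle_member(ids, parents)
  if (!is.na(cyc)) {
    stop("cyclic ontology: term ", cyc, " lies on an is_a cycle")
  }
  children <- build_children(ids, parents)
  structure(
    list(ids = ids, labels = labels, parents = parents,
         children = children, keywords = keywords, root_id = root_id),
    class = "interaction_ontology"
  )
}

# Kahn-style elimination: returns NA when acyclic, else one cycle member.
find_cycle_member <- function(ids, parents) {
  remaining <- stats::setNames(lengths(parents), ids)
  children <- build_children(ids, parents)
  queue <- ids[remaining == 0L]
  done <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    done <- done + 1L
    for (ch in children[[v]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done == length(ids)) NA_character_ else sort(ids[remaining > 0L])[1L]
}

build_children <- function(ids, parents) {
  ch <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) ch[[id]] <- character(0)
  for (id in ids) {
    for (p in parents[[id]]) ch[[p]] <- c(ch[[p]], id)
  }
  lapply(ch, function(x) sort(unique(x)))
}

#' Read an interaction-type ontology
#'
#' Parses a flat OBO-subset file into a rooted DAG restricted to `root_id`
#' and its descendants. The dialect has one `[Term]` stanza per term with
#' `id:`, `name:`, repeatable `is_a:` lines, an optional
#' `property_value: has_literature_mining_keywords "kw1|kw2|..."` annotation
#' carrying pipe-separated literature-mining keywords, and an optional
#' `is_obsolete: true` flag. Obsolete terms are dropped; keywords are
#' lowercased and deduplicated; identifiers in colon form are normalized to
#' underscore form.
#'
#' @param path path to the ontology file.
#' @param root_id identifier of the interaction branch root; the returned
#'   graph contains only this term and its descendants.
#' @return an `interaction_ontology` object: a rooted DAG with fields
#'   `ids`, `labels`, `parents`, `children`, `keywords`, `root_id`.
#' @seealso [write_ontology()], [term_ancestors()], [keyword_index()]
#' @export
read_ontology <- function(path, root_id) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  root_id <- normalize_term_id(root_id)
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))

  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur)) {
      if (is.null(cur$id)) stop("term stanza without an id")
      terms[[length(terms) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- list(id = NULL, name = "", is_a = character(0),
                  keywords = character(0), obsolete = FALSE)
      next
    }
    if (grepl("^\\[.*\\]$", ln)) {  # other stanza kinds are ignored
      flush()
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) {
      cur$id <- normalize_term_id(trimws(sub("^id:", "", ln)))
    } else if (grepl("^name:", ln)) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (grepl("^is_a:", ln)) {
      val <- trimws(sub("^is_a:", "", ln))
      val <- trimws(sub("!.*$", "", val))  # strip trailing label comment
      cur$is_a <- c(cur$is_a, normalize_term_id(val))
    } else if (grepl("^property_value:\\s*has_literature_mining_keywords", ln)) {
      m <- regmatches(ln, regexec("\"([^\"]*)\"", ln))[[1L]]
      if (length(m) < 2L) stop("malformed keyword annotation: ", ln)
      kws <- tolower(trimws(strsplit(m[[2L]], "|", fixed = TRUE)[[1L]]))
      cur$keywords <- unique(c(cur$keywords, kws[nzchar(kws)]))
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      cur$obsolete <- TRUE
    }
  }
  flush()
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  ids <- vapply(terms, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate term id: ", ids[duplicated(ids)][1L])

  # dangling = reference to an id nowhere in the file (obsolete ids count as
  # present; links onto them are pruned when the obsolete term is dropped)
  all_refs <- unique(unlist(lapply(terms, `[[`, "is_a"), use.names = FALSE))
  missing <- setdiff(all_refs, ids)
  if (length(missing)) stop("dangling parent reference: ", missing[1L])

  obsolete <- vapply(terms, `[[`, FALSE, "obsolete")
  terms <- terms[!obsolete]
  live <- ids[!obsolete]
  if (!root_id %in% live) stop("root term not present: ", root_id)

  labels <- vapply(terms, `[[`, "", "name")
  parents <- lapply(terms, function(t) unique(intersect(t$is_a, live)))
  keywords <- lapply(terms, `[[`, "keywords")
  onto <- new_ontology(live, labels, parents, keywords, root_id)

  keep <- c(root_id, term_descendants(onto, root_id))
  restrict_ontology(onto, keep)
}

# subset to a term set, pruning parent links that leave the set
restrict_ontology <- function(onto, keep) {
  keep <- intersect(onto$ids, keep)  # preserves original order
  parents <- lapply(onto$parents[keep], function(p) intersect(p, keep))
  new_ontology(keep, onto$labels[keep], parents, onto$keywords[keep],
               onto$root_id)
}

#' Write an interaction-type ontology
#'
#' Serializes the graph in the same OBO-subset dialect consumed by
#' [read_ontology()]; a parse/write/parse round trip preserves term ids,
#' labels, is_a edges and keyword sets.
#'
#' @param onto an `interaction_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(onto, path) {
  stopifnot(inherits(onto, "interaction_ontology"))
  out <- character(0)
  for (id in onto$ids) {
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", onto$labels[[id]]))
    for (p in onto$parents[[id]]) out <- c(out, paste0("is_a: ", p))
    kws <- onto$keywords[[id]]
    if (length(kws)) {
      out <- c(out, paste0("property_value: has_literature_mining_keywords \"",
                           paste(kws, collapse = "|"), "\""))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

check_term <- function(onto, term_id) {
  if (!term_id %in% onto$ids) stop("unknown term: ", term_id)
  invisible(term_id)
}

#' Strict ancestors of a term
#'
#' All terms reachable from `term_id` by following `is_a` links, excluding
#' `term_id` itself. The root is included for every non-root term. With
#' multiple parents, ancestors along all paths are merged by set semantics.
#'
#' @param onto an `interaction_ontology`.
#' @param term_id a term identifier present in the graph.
#' @return sorted character vector of ancestor term ids.
#' @export
term_ancestors <- function(onto, term_id) {
  check_term(onto, term_id)
  seen <- character(0)
  frontier <- onto$parents[[term_id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(onto$parents[new], use.names = FALSE))
  }
  sort(seen)
}

#' Descendants of a term
#'
#' All terms from which `term_id` is reachable by `is_a`, excluding
#' `term_id` itself.
#'
#' @inheritParams term_ancestors
#' @return sorted character vector of descendant term ids.
#' @export
term_descendants <- function(onto, term_id) {
  check_term(onto, term_id)
  seen <- character(0)
  frontier <- onto$children[[term_id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(onto$children[new], use.names = FALSE))
  }
  sort(seen)
}

#' Build the literature-mining keyword index
#'
#' Maps every lowercase keyword declared by any non-obsolete term to the set
#' of term ids declaring it. A keyword may map to several terms; terms with
#' no keywords are simply absent.
#'
#' @param onto an `interaction_ontology`.
#' @return a named list of class `keyword_index`: keyword -> sorted character
#'   vector of term ids.
#' @export
keyword_index <- function(onto) {
  kw <- unlist(onto$keywords, use.names = FALSE)
  tid <- rep(onto$ids, lengths(onto$keywords))
  idx <- lapply(split(tid, kw), function(x) sort(unique(x)))
  structure(idx, class = "keyword_index")
}

#' Extract a minimal sub-hierarchy covering a seed set
#'
#' Returns the smallest subgraph containing the seed terms plus every term on
#' an `is_a` path from a seed to the root (the "computed intermediates" that
#' make a reported hierarchy complete), with parent links restricted to the
#' subgraph.
#'
#' @param onto an `interaction_ontology`.
#' @param seed_terms character vector of term ids present in the graph.
#' @return an `interaction_ontology` restricted to the seeds and their
#'   ancestors.
#' @export
subhierarchy <- function(onto, seed_terms) {
  seed_terms <- unique(normalize_term_id(seed_terms))
  for (s in seed_terms) check_term(onto, s)
  anc <- unlist(lapply(seed_terms, function(s) term_ancestors(onto, s)),
                use.names = FALSE)
  restrict_ontology(onto, unique(c(seed_terms, anc)))
}

#' @export
print.interaction_ontology <- function(x, ...) {
  cat(sprintf("Interaction-type ontology: %d terms, root %s (%s)\n",
              length(x$ids), x$root_id, x$labels[[x$root_id]]))
  cat(sprintf("  is_a edges: %d; literature-mining keywords: %d\n",
              sum(lengths(x$parents)), length(unique(unlist(x$keywords)))))
  invisible(x)
}
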