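# Seeded synthetic fixtures: toy interaction-type ontologies, gene lexicons,
# and template corpora with planted enrichment. The generator emulates, at
# roughly 1/1000 of the published literature-mining scale, the statistical
# structure the enrichment analysis assumes: a skewed (Zipf) background
# distribution of term usage over gene pairs, and a concept-specific
# document subset in which selected terms are used at a shifted rate.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the test suite:
#' a whole network of 5,000 annotated gene pairs with a concept subset of
#' 4\% (200 pairs), 30 ontology terms with Zipf-distributed background usage
#' (rate `q_max / rank` for rank 1, 2, ... over non-root terms), and no
#' planted enrichment.
#'
#' @param seed integer RNG seed; every generated artifact is a deterministic
#'   function of the configuration.
#' @param n_terms number of ontology terms including the root (>= 2).
#' @param dag_density probability that a non-root term receives a second
#'   parent (multiple inheritance), in `[0, 1]`.
#' @param n_genes number of gene symbols in the lexicon.
#' @param n_docs_whole number of documents the records are spread over.
#' @param concept_fraction fraction (0, 1] of gene pairs (and of documents)
#'   belonging to the concept subset.
#' @param planted named numeric vector: term id -> target fold; the concept
#'   subset uses each planted term with probability fold x background rate.
#' @param n_pairs_whole number of distinct gene pairs in the whole network.
#' @param q_max background usage rate of the most frequent term.
#' @param doc_rate Poisson rate of extra supporting documents per
#'   (pair, term) annotation beyond the first.
#' @param hard_mode emit some sentences containing two interaction keywords
#'   (multi-term records) instead of exactly one.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_terms = 30L, dag_density = 0.25,
                       n_genes = 150L, n_docs_whole = 6000L,
                       concept_fraction = 0.04, planted = numeric(0),
                       n_pairs_whole = 5000L, q_max = 0.3, doc_rate = 0.2,
                       hard_mode = FALSE) {
  stopifnot(n_terms >= 2L, n_terms <= 400L,
            dag_density >= 0, dag_density <= 1,
            n_genes >= 3L, n_pairs_whole <= choose(n_genes, 2L),
            concept_fraction > 0, concept_fraction <= 1,
            q_max > 0, q_max <= 1, doc_rate >= 0)
  if (length(planted) && (is.null(names(planted)) || any(planted <= 0))) {
    stop("planted must be a named vector of positive target folds")
  }
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 dag_density = dag_density, n_genes = as.integer(n_genes),
                 n_docs_whole = as.integer(n_docs_whole),
                 concept_fraction = concept_fraction, planted = planted,
                 n_pairs_whole = as.integer(n_pairs_whole), q_max = q_max,
                 doc_rate = doc_rate, hard_mode = isTRUE(hard_mode)),
            class = "sim_config")
}

sim_term_ids <- function(n) sprintf("ITO_%07d", seq_len(n))

#' Background term usage rates of a configuration
#'
#' Zipf rates `q_max / rank` over the non-root terms, rank following term
#' order.
#'
#' @param config a [sim_config()].
#' @return named numeric vector over non-root term ids.
#' @export
sim_background_rates <- function(config) {
  ids <- sim_term_ids(config$n_terms)[-1L]
  stats::setNames(config$q_max / seq_along(ids), ids)
}

#' Generate a toy interaction-type ontology
#'
#' A rooted DAG of `n_terms` terms. Each non-root term gets one parent among
#' the earlier terms and, with probability `dag_density`, a second one. Each
#' term's label is an invented reaction name (`<stem>ation`) and its 2-5
#' literature-mining keywords are deterministic inflections of the stem
#' (`<stem>ate`, `<stem>ates`, ...), mirroring how real interaction terms
#' carry surface-form variants; stems are unique across terms so template
#' sentences are unambiguous.
#'
#' @param config a [sim_config()].
#' @return an `interaction_ontology`.
#' @export
simulate_ontology <- function(config) {
  set.seed(config$seed)
  n <- config$n_terms
  ids <- sim_term_ids(n)
  syl <- c("bran", "dor", "fex", "gul", "hem", "jas", "kol", "lum", "mer",
           "nix", "pol", "quar", "rend", "sol", "tav", "vex", "wim", "yor",
           "zeph", "crat")
  pool <- as.vector(outer(syl, syl, paste0))
  stems <- sample(pool, n)  # without replacement: unique by construction
  suffixes <- c("ation", "ate", "ates", "ated", "ating")
  labels <- c("interaction", paste0(stems[-1L], "ation"))
  keywords <- vector("list", n)
  keywords[[1L]] <- c("interacts", "interacting", "interaction")
  parents <- vector("list", n)
  parents[[1L]] <- character(0)
  for (i in seq_len(n)[-1L]) {
    p <- ids[[sample.int(i - 1L, 1L)]]
    if (i >= 3L && stats::runif(1) < config$dag_density) {
      p <- c(p, ids[[sample.int(i - 1L, 1L)]])
    }
    parents[[i]] <- unique(p)
    k <- sample(2:5, 1L)
    keywords[[i]] <- paste0(stems[[i]], sample(suffixes, k))
  }
  new_ontology(ids, labels, parents, keywords, ids[[1L]])
}

# gene symbols and their one hyphenated synonym surface form
sim_genes <- function(n_genes) {
  sym <- sprintf("G%03d", seq_len(n_genes))
  list(symbols = sym, synonyms = as.list(paste0("gx-", seq_len(n_genes))))
}

#' Generate seeded interaction records with planted enrichment
#'
#' Draws the whole-network pair universe, marks a concept subset of pairs
#' and documents, and annotates each pair with each non-root term: a
#' concept pair uses term `t` with probability `fold_t x q_t` (planted fold,
#' else 1) and a background pair with probability `q_t`, where `q_t` is the
#' Zipf background rate. Each (pair, term) annotation is supported by
#' `1 + Poisson(doc_rate)` distinct documents, drawn from the concept or
#' background document pool according to the pair's subset.
#'
#' @param config a [sim_config()].
#' @param onto the ontology from [simulate_ontology()] (regenerated when
#'   omitted).
#' @return a list: `records` (one row per supporting document of each
#'   (pair, term) annotation), `concept_docs`, `concept_pairs`, `genes`,
#'   `rates`.
#' @export
simulate_records <- function(config, onto = simulate_ontology(config)) {
  q <- sim_background_rates(config)
  planted <- config$planted
  if (length(planted)) {
    names(planted) <- normalize_term_id(names(planted))
    bad <- setdiff(names(planted), names(q))
    if (length(bad)) stop("planted term not in ontology: ", bad[1L])
    infeasible <- planted * q[names(planted)] > 1
    if (any(infeasible)) {
      stop("infeasible planted fold for ", names(planted)[infeasible][1L],
           ": fold x background rate exceeds 1")
    }
  }
  set.seed(config$seed + 1000003L)

  genes <- sim_genes(config$n_genes)
  all_pairs <- utils::combn(genes$symbols, 2L)
  sel <- sample.int(ncol(all_pairs), config$n_pairs_whole)
  g1 <- all_pairs[1L, sel]
  g2 <- all_pairs[2L, sel]
  n_pairs <- config$n_pairs_whole
  n_c <- max(1L, round(config$concept_fraction * n_pairs))
  is_concept <- seq_len(n_pairs) <= n_c  # the sampled order is random

  n_cd <- max(1L, round(config$concept_fraction * config$n_docs_whole))
  n_bd <- max(1L, config$n_docs_whole - n_cd)
  concept_docs <- sprintf("DC%05d", seq_len(n_cd))
  background_docs <- sprintf("DB%05d", seq_len(n_bd))

  rows <- list()
  for (t in names(q)) {
    p_use <- rep(q[[t]], n_pairs)
    if (t %in% names(planted)) {
      p_use[is_concept] <- planted[[t]] * q[[t]]
    }
    hit <- which(stats::runif(n_pairs) < p_use)
    if (!length(hit)) next
    n_docs <- 1L + stats::rpois(length(hit), config$doc_rate)
    docs <- lapply(seq_along(hit), function(j) {
      pool <- if (is_concept[hit[[j]]]) concept_docs else background_docs
      sample(pool, min(n_docs[[j]], length(pool)))
    })
    nd <- lengths(docs)
    rows[[t]] <- data.frame(
      doc_id = unlist(docs, use.names = FALSE),
      gene1 = rep.int(g1[hit], nd),
      gene2 = rep.int(g2[hit], nd),
      term_ids = t, stringsAsFactors = FALSE)
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(0), gene1 = character(0),
               gene2 = character(0), term_ids = character(0),
               stringsAsFactors = FALSE)
  # stable order, then per-document sentence numbering
  rec <- rec[order(rec$doc_id, rec$gene1, rec$gene2, rec$term_ids), ,
             drop = FALSE]
  rec$sent_id <- stats::ave(seq_len(nrow(rec)), rec$doc_id,
                            FUN = seq_along)
  rec <- new_records(rec$doc_id, rec$sent_id, rec$gene1, rec$gene2,
                     rec$term_ids)
  list(records = rec, concept_docs = concept_docs,
       concept_pairs = pair_id(g1[is_concept], g2[is_concept]),
       genes = genes, rates = q)
}

sim_concept_contexts <- c(
  "a vaccine trial", "the vaccination cohort", "vaccinated mice",
  "a measles vaccine study", "subjects given bcg")
sim_background_contexts <- c(
  "a cell culture assay", "a murine knockout model",
  "primary fibroblast lines", "an in vitro kinase panel")

#' Default concept base variants
#'
#' The surface variants of the concept word used by the generated corpora
#' and by the command-line defaults.
#'
#' @return character vector of lowercase variants.
#' @export
concept_base_variants <- function() {
  c("vaccine", "vaccines", "vaccination", "vaccinated")
}

#' Generate a template sentence corpus with ground truth
#'
#' Wraps the records of [simulate_records()] into template sentences
#' `"<gene> <keyword> <gene> in <context>."`. Concept-document contexts
#' contain a concept marker (a base variant of the concept word, or a
#' specific concept term such as `"bcg"`); background contexts contain
#' neither. Gene mentions use the canonical symbol or its synonym at random.
#' In hard mode a third of the sentences carry a second interaction keyword
#' from another term.
#'
#' @param config a [sim_config()].
#' @param onto optional pre-generated ontology.
#' @return a list: `corpus` (doc_id, sent_id, text), `lexicon`
#'   (a [gene_lexicon()]), `ground_truth` (doc_id, sent_id, gene1, gene2,
#'   term_id), `concept_terms`, `base_variants`, `concept_docs`, `onto`.
#' @export
simulate_corpus <- function(config, onto = simulate_ontology(config)) {
  sim <- simulate_records(config, onto)
  rec <- sim$records
  set.seed(config$seed + 2000003L)

  lex <- gene_lexicon(sim$genes$symbols, sim$genes$synonyms)
  surf <- function(g) {
    i <- match(g, sim$genes$symbols)
    pick <- stats::runif(length(g)) < 0.5
    ifelse(pick, g, unlist(sim$genes$synonyms)[i])
  }
  n <- nrow(rec)
  gt <- rec[c("doc_id", "sent_id", "gene1", "gene2")]
  gt$term_id <- rec$term_ids
  if (n) {
    kw <- vapply(rec$term_ids, function(t) {
      ks <- onto$keywords[[t]]
      ks[[sample.int(length(ks), 1L)]]
    }, "", USE.NAMES = FALSE)
    in_concept <- rec$doc_id %in% sim$concept_docs
    ctx <- ifelse(in_concept,
                  sample(sim_concept_contexts, n, replace = TRUE),
                  sample(sim_background_contexts, n, replace = TRUE))
    text <- paste0(surf(rec$gene1), " ", kw, " ", surf(rec$gene2),
                   " in ", ctx, ".")
    if (config$hard_mode) {
      extra <- which(stats::runif(n) < 1 / 3)
      if (length(extra)) {
        other <- vapply(rec$term_ids[extra], function(t) {
          cand <- setdiff(onto$ids[-1L], t)
          cand[[sample.int(length(cand), 1L)]]
        }, "", USE.NAMES = FALSE)
        kw2 <- vapply(other, function(t) {
          ks <- onto$keywords[[t]]
          ks[[sample.int(length(ks), 1L)]]
        }, "", USE.NAMES = FALSE)
        text[extra] <- paste0(surf(rec$gene1[extra]), " ", kw[extra],
                              " and ", kw2, " ", surf(rec$gene2[extra]),
                              " in ", ctx[extra], ".")
        gt <- rbind(gt, data.frame(doc_id = rec$doc_id[extra],
                                   sent_id = rec$sent_id[extra],
                                   gene1 = rec$gene1[extra],
                                   gene2 = rec$gene2[extra],
                                   term_id = other,
                                   stringsAsFactors = FALSE))
      }
    }
  } else {
    text <- character(0)
  }
  corpus <- data.frame(doc_id = rec$doc_id, sent_id = rec$sent_id,
                       text = text, stringsAsFactors = FALSE)
  ord <- order(gt$doc_id, gt$sent_id, gt$term_id)
  list(corpus = corpus, lexicon = lex,
       ground_truth = gt[ord, , drop = FALSE],
       concept_terms = c("tuberculosis vaccine bcg", "bcg"),
       base_variants = concept_base_variants(),
       concept_docs = sim$concept_docs, onto = onto)
}

#' Write a complete synthetic fixture bundle
#'
#' Writes `ontology.obo`, `lexicon.tsv`, `corpus.tsv`, `concept_terms.txt`
#' and `ground_truth.tsv` under `dir` in the exact dialects the readers of
#' this package consume. Byte-identical for a fixed configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_corpus(config)
  paths <- c(ontology = file.path(dir, "ontology.obo"),
             lexicon = file.path(dir, "lexicon.tsv"),
             corpus = file.path(dir, "corpus.tsv"),
             concept_terms = file.path(dir, "concept_terms.txt"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_ontology(sim$onto, paths[["ontology"]])
  lex_df <- data.frame(symbol = sim$lexicon$symbols,
                       synonyms = vapply(sim_genes(config$n_genes)$synonyms,
                                         paste, "", collapse = "|"),
                       stringsAsFactors = FALSE)
  utils::write.table(lex_df, paths[["lexicon"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$corpus, paths[["corpus"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("# specific concept terms (one per line)",
               sim$concept_terms), paths[["concept_terms"]])
  utils::write.table(sim$ground_truth, paths[["ground_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
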