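# Fixtures are built in code: a small cleavage-chain ontology mirroring the
# canonical parent-child chain (cleavage reaction > nucleic acid cleavage >
# RNA cleavage > mRNA cleavage), a diamond DAG, and independent brute-force
# oracles for ancestor closure, hierarchy propagation and hypergeometric
# tails.

obo_stanza <- function(id, name, is_a = character(0), kws = character(0),
                       obsolete = FALSE) {
  out <- c("[Term]", paste0("id: ", id), paste0("name: ", name))
  for (p in is_a) out <- c(out, paste0("is_a: ", p))
  if (length(kws)) {
    out <- c(out, paste0("property_value: has_literature_mining_keywords \"",
                         paste(kws, collapse = "|"), "\""))
  }
  if (obsolete) out <- c(out, "is_obsolete: true")
  c(out, "")
}

write_obo <- function(..., path = withr::local_tempfile(fileext = ".obo",
                                                        .local_envir = parent.frame())) {
  writeLines(unlist(list(...)), path)
  path
}

chain_obo_path <- function(path = withr::local_tempfile(fileext = ".obo",
                                                        .local_envir = parent.frame())) {
  write_obo(
    obo_stanza("ITO_0000001", "interaction", kws = c("interacts")),
    obo_stanza("MI_0194", "cleavage reaction", "ITO_0000001",
               c("cleavage", "cleaves")),
    obo_stanza("MI_0910", "nucleic acid cleavage", "MI_0194",
               "nucleic acid cleavage"),
    obo_stanza("MI_0902", "RNA cleavage", "MI_0910", "rna cleavage"),
    obo_stanza("MI_0571", "mRNA cleavage", "MI_0902", "mrna cleavage"),
    obo_stanza("GO_0018377", "protein myristoylation", "ITO_0000001",
               c("myristoylate", "myristoylates", "myristoylated",
                 "myristoylating", "myristoylation")),
    obo_stanza("INO_0000140", "neutralization", "ITO_0000001",
               "neutralization"),
    obo_stanza("INO_0000235", "negative regulation", "ITO_0000001",
               c("impaired", "impairs")),
    path = path)
}

chain_ontology <- function() {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  read_ontology(chain_obo_path(path), "ITO_0000001")
}

# D is_a B, D is_a C; B is_a A; C is_a A
diamond_ontology <- function() {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  write_obo(
    obo_stanza("T_A", "root"),
    obo_stanza("T_B", "left", "T_A", "binds"),
    obo_stanza("T_C", "right", "T_A", "binds"),
    obo_stanza("T_D", "bottom", c("T_B", "T_C")),
    path = path)
  read_ontology(path, "T_A")
}

demo_lexicon <- function() {
  gene_lexicon(c("IL12A", "IFNG", "CD4", "S100B"),
               list("IL-12", "IFN-gamma", character(0), character(0)))
}

as_sentence <- function(text, doc_id = "D1", sent_id = 1L) {
  list(doc_id = doc_id, sent_id = sent_id, text = text)
}

make_records <- function(doc_id, gene1, gene2, term_ids,
                         sent_id = seq_along(doc_id)) {
  data.frame(doc_id = doc_id, sent_id = as.integer(sent_id),
             gene1 = gene1, gene2 = gene2, term_ids = term_ids,
             score = rep(NA_real_, length(doc_id)), stringsAsFactors = FALSE)
}

# brute-force ancestor closure by iterated parent expansion
oracle_ancestors <- function(onto, id) {
  out <- character(0)
  frontier <- id
  repeat {
    parents <- unique(unlist(onto$parents[frontier], use.names = FALSE))
    new <- setdiff(parents, out)
    if (!length(new)) break
    out <- c(out, new)
    frontier <- new
  }
  sort(out)
}

# brute-force propagation: a term's pair set is the union of the direct pair
# sets of itself and all descendants
oracle_pairs_by_term <- function(records, onto) {
  direct <- list()
  for (i in seq_len(nrow(records))) {
    for (t in strsplit(records$term_ids[[i]], "|", fixed = TRUE)[[1L]]) {
      direct[[t]] <- union(direct[[t]],
                           paste(records$gene1[[i]], records$gene2[[i]]))
    }
  }
  out <- list()
  for (t in onto$ids) {
    fam <- c(t, term_descendants(onto, t))
    pairs <- sort(unique(unlist(direct[fam], use.names = FALSE)))
    if (length(pairs)) out[[t]] <- pairs
  }
  out
}

# independent hypergeometric tail enumeration from binomial coefficients
oracle_tail <- function(a, b, A, B, upper = TRUE) {
  N <- a + b + A + B
  m <- a + A
  k <- a + b
  lo <- max(0, k - (N - m))
  hi <- min(k, m)
  xs <- if (upper) seq(max(a, lo), hi) else seq(lo, min(a, hi))
  if (upper && a > hi) return(0)
  if (!upper && a < lo) return(0)
  sum(exp(lchoose(m, xs) + lchoose(N - m, k - xs) - lchoose(N, k)))
}

# hand-rolled BH step-up used as the independent multiple-testing oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}
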