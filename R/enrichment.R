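# Per-term enrichment of a concept-specific sub-network against the whole
# network. For each interaction-type term a 2x2 table of unique gene-pair
# counts is formed (sub-network with/without the term; whole network
# with/without it, the whole network containing the sub-network), and a
# conservative "minus one" modified one-sided Fisher's exact test is applied:
# for over-representation one pair is removed from the evidence cell before
# the exact hypergeometric tail is computed (EASE-style), making calls based
# on a single borderline pair impossible. Folds are ratios of raw
# proportions; multiplicity is handled by Benjamini-Hochberg across the
# tested term set.

#' Construct a 2x2 contingency table of gene-pair counts
#'
#' `a` = sub-network pairs carrying the term, `b` = sub-network pairs not
#' carrying it, `A`/`B` likewise for the whole network. The sub-network must
#' be contained in the whole network (`a <= A`, `a + b <= A + B`).
#'
#' @param a,b,A,B non-negative integer counts.
#' @return a `contingency_table` object.
#' @export
contingency_table <- function(a, b, A, B) {
  v <- c(a = a, b = b, A = A, B = B)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("contingency counts must be non-negative integers")
  }
  if (a > A || a + b > A + B) {
    stop("sub-network counts exceed whole-network counts")
  }
  structure(as.list(v), class = "contingency_table")
}

as_table <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    return(contingency_table(x[[1L]], x[[2L]], x[[3L]], x[[4L]]))
  }
  stop("expected a contingency_table or a numeric vector (a, b, A, B)")
}

#' Contingency table for one term
#'
#' @param term_id a term id.
#' @param sub,whole `annotated_network`s for the concept sub-network and the
#'   whole network (the whole network includes the sub-network's records).
#' @return a `contingency_table`.
#' @export
build_table <- function(term_id, sub, whole) {
  n_sub <- length(sub$universe)
  if (!n_sub) stop("empty sub-network")
  n_whole <- length(whole$universe)
  a <- length(sub$pairs_by_term[[term_id]])
  A <- length(whole$pairs_by_term[[term_id]])
  contingency_table(a, n_sub - a, A, n_whole - A)
}

# Exact one-sided hypergeometric tail of the 2x2 (a, b, A, B), margins taken
# from the table itself: X ~ Hypergeom(N = a+b+A+B, m = a+A, k = a+b);
# upper tail = P(X >= a), lower = P(X <= a). Summed point masses in log
# space; exact, no chi-square or normal approximation.
#' Exact hypergeometric tail of a 2x2 table
#'
#' @param a,b,A,B non-negative integer cells; margins are recomputed from the
#'   cells themselves.
#' @param tail `"upper"` for `P(X >= a)`, `"lower"` for `P(X <= a)`.
#' @return the exact tail probability.
#' @export
fisher_tail <- function(a, b, A, B, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  N <- a + b + A + B
  m <- a + A
  k <- a + b
  lo <- max(0L, k - (N - m))
  hi <- min(k, m)
  if (tail == "upper") {
    if (a <= lo) return(1)
    if (a > hi) return(0)
    xs <- a:hi
  } else {
    if (a >= hi) return(1)
    if (a < lo) return(0)
    xs <- lo:a
  }
  lp <- stats::dhyper(xs, m, N - m, k, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Modified Fisher's exact test for one term
#'
#' One-sided exact test on the 2x2 of gene-pair counts, with a conservative
#' modification of the evidence cell: for over-representation the
#' sub-network with-term count is decreased by one (floored at 0) before the
#' tail is computed; for under-representation it is symmetrically increased
#' by one (capped at `min(a + b, A)`). Margins are recomputed from the
#' modified cells. `modify = FALSE` gives the ordinary one-sided Fisher
#' test; `sided = "two"` computes the usual two-sided exact p (sum of all
#' outcomes no more probable than the observed one) on the modified table,
#' for sensitivity analysis.
#'
#' @param table a [contingency_table()] or numeric `c(a, b, A, B)`.
#' @param direction `"over"` or `"under"`.
#' @param modify apply the conservative one-pair modification (default TRUE).
#' @param sided `"one"` (default) or `"two"`.
#' @return the p-value.
#' @export
modified_fisher <- function(table, direction = c("over", "under"),
                            modify = TRUE, sided = c("one", "two")) {
  tab <- as_table(table)
  direction <- match.arg(direction)
  sided <- match.arg(sided)
  a <- tab$a; b <- tab$b; A <- tab$A; B <- tab$B
  a2 <- if (direction == "over") {
    if (modify) max(a - 1L, 0L) else a
  } else {
    if (modify) min(a + 1L, min(a + b, A)) else a
  }
  if (sided == "one") {
    fisher_tail(a2, b, A, B,
                tail = if (direction == "over") "upper" else "lower")
  } else {
    two_sided_exact(a2, b, A, B)
  }
}

two_sided_exact <- function(a, b, A, B) {
  N <- a + b + A + B
  m <- a + A
  k <- a + b
  lo <- max(0L, k - (N - m))
  hi <- min(k, m)
  xs <- lo:hi
  lp <- stats::dhyper(xs, m, N - m, k, log = TRUE)
  cutoff <- lp[[a - lo + 1L]] + log1p(1e-7)  # fisher.test-style relative slack
  sel <- lp <= cutoff
  mx <- max(lp[sel])
  min(1, exp(mx) * sum(exp(lp[sel] - mx)))
}

#' Enrichment fold of a term
#'
#' Ratio of the term's gene-pair proportion in the sub-network to its
#' proportion in the whole network, from raw (unmodified) counts. Undefined
#' (`NA`) when the term is absent from the whole network.
#'
#' @param table a [contingency_table()] or numeric `c(a, b, A, B)`.
#' @return a non-negative real, or `NA_real_` when `A = 0`.
#' @export
enrichment_fold <- function(table) {
  tab <- as_table(table)
  if (tab$A == 0) return(NA_real_)
  if (tab$a + tab$b == 0) stop("empty sub-network")
  (tab$a / (tab$a + tab$b)) / (tab$A / (tab$A + tab$B))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted values returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the per-term enrichment analysis
#'
#' Tests every term carrying at least `min_pairs` unique gene pairs in the
#' sub-network. For each tested term the fold is computed from raw counts,
#' the candidate direction is over when fold > 1 and under otherwise, the
#' one-sided modified Fisher p is computed in that direction, and BH
#' correction is applied across the tested set only. A term is finally
#' called over-represented iff its BH p < `alpha` and fold >=
#' `fold_threshold`, under-represented iff BH p < `alpha` and fold <=
#' `1/fold_threshold`, and `none` otherwise. The most frequent supporting
#' gene pair (by distinct documents in the sub-network, ties broken
#' lexicographically) is reported per term.
#'
#' @param sub,whole `annotated_network`s built against the same ontology;
#'   `whole` must contain `sub`.
#' @param onto the `interaction_ontology` (for labels).
#' @param min_pairs minimum sub-network pair count for a term to be tested
#'   (default 5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param fold_threshold minimal fold for an over call; `1/fold_threshold`
#'   is the maximal fold for an under call (default 2).
#' @param modify,sided passed to [modified_fisher()].
#' @return a data frame sorted by (direction, BH p) with columns `term_id`,
#'   `label`, `direction`, `a`, `sub_total`, `A`, `whole_total`, `fold`,
#'   `p_raw`, `p_bh`, `top_pair`, `top_pair_docs`.
#' @export
run_enrichment <- function(sub, whole, onto, min_pairs = 5L, alpha = 0.05,
                           fold_threshold = 2, modify = TRUE,
                           sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!length(sub$universe)) {
    stop(errorCondition("empty sub-network",
                        class = c("itoenrich_empty", "error", "condition")))
  }
  tested <- names(sub$pairs_by_term)[lengths(sub$pairs_by_term) >= min_pairs]
  tested <- tested[vapply(tested,
                          function(t) length(whole$pairs_by_term[[t]]) > 0L,
                          TRUE)]
  if (!length(tested)) {
    return(data.frame(term_id = character(0), label = character(0),
                      direction = character(0), a = integer(0),
                      sub_total = integer(0), A = integer(0),
                      whole_total = integer(0), fold = numeric(0),
                      p_raw = numeric(0), p_bh = numeric(0),
                      top_pair = character(0), top_pair_docs = integer(0),
                      stringsAsFactors = FALSE))
  }
  n <- length(tested)
  a <- A <- top_docs <- integer(n)
  fold <- p_raw <- numeric(n)
  cand <- top_pair <- character(n)
  sub_total <- length(sub$universe)
  whole_total <- length(whole$universe)
  for (i in seq_len(n)) {
    t <- tested[[i]]
    tab <- build_table(t, sub, whole)
    a[[i]] <- tab$a
    A[[i]] <- tab$A
    fold[[i]] <- enrichment_fold(tab)
    cand[[i]] <- if (fold[[i]] > 1) "over" else "under"
    p_raw[[i]] <- modified_fisher(tab, cand[[i]], modify = modify,
                                  sided = sided)
    dc <- sub$doc_count[[t]]
    best <- sort(names(dc)[dc == max(dc)])[1L]
    top_pair[[i]] <- render_pair(best)
    top_docs[[i]] <- dc[[best]]
  }
  p_bh <- bh_adjust(p_raw)
  direction <- rep("none", n)
  direction[p_bh < alpha & fold >= fold_threshold] <- "over"
  direction[p_bh < alpha & fold <= 1 / fold_threshold] <- "under"
  res <- data.frame(term_id = tested,
                    label = unname(onto$labels[tested]),
                    direction = direction, a = a, sub_total = sub_total,
                    A = A, whole_total = whole_total, fold = fold,
                    p_raw = p_raw, p_bh = p_bh, top_pair = top_pair,
                    top_pair_docs = top_docs, stringsAsFactors = FALSE)
  ord <- order(match(res$direction, c("over", "under", "none")), res$p_bh,
               res$term_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results as TSV
#'
#' Columns mirror the per-term report: term, label, direction, counts,
#' fold, raw and BH-adjusted p, most frequent gene pair (as
#' `GENE1_GENE2`) with its distinct-document count.
#'
#' @param results data frame from [run_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  out$fold <- sprintf("%.6g", out$fold)
  out$p_raw <- sprintf("%.6e", out$p_raw)
  out$p_bh <- sprintf("%.6e", out$p_bh)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
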