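#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test of each gene set against a
#' query, with BH adjustment across all tested terms. Sets are intersected
#' with the background universe first; terms with no members in the
#' background are dropped.
#'
#' @param query Character vector of query genes (must overlap the
#'   background; genes outside it are ignored).
#' @param gene_sets A `GeneSetCollection`.
#' @param background Character vector: the gene universe.
#' @return data.frame with one row per tested term: `term_id`,
#'   `term_name`, `k` (overlap), `K` (set size in background), `n` (query
#'   size), `N` (background size), `p_value`, `q_value`.
#' @export
hypergeom_enrich <- function(query, gene_sets, background) {
  stopifnot(inherits(gene_sets, "GeneSetCollection"))
  background <- unique(background)
  if (!length(background)) stop("empty background")
  query <- unique(intersect(query, background))
  if (!length(query)) stop("empty query (after intersection with background)")
  n <- length(query)
  N <- length(background)
  sets <- lapply(gene_sets$sets, intersect, background)
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (!length(sets)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(sets),
                    term_name = unname(gene_sets$name[names(sets)]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p_value = unname(p), q_value = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool significant terms across queries and rank by occurrence
#'
#' Counts, for every term, in how many of the per-query significant lists
#' it appears; terms present in strictly more than `occurrence_min` of the
#' queries are flagged for summarization.
#'
#' @param sig_lists List of character vectors: per query, the significant
#'   term ids.
#' @param occurrence_min Strict occurrence-frequency threshold (default
#'   0.5, i.e. "> 50% of the collective ontologies").
#' @return data.frame ordered by occurrence frequency (descending) then
#'   term id: `term_id`, `occurrence_count`, `occurrence_frequency`,
#'   `flagged`.
#' @export
pool_and_rank <- function(sig_lists, occurrence_min = 0.5) {
  if (!length(sig_lists)) stop("pool_and_rank needs at least one query list")
  n_queries <- length(sig_lists)
  terms <- sort(unique(unlist(sig_lists)))
  if (!length(terms)) {
    return(data.frame(term_id = character(0), occurrence_count = integer(0),
                      occurrence_frequency = numeric(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  }
  count <- vapply(terms, function(t) {
    sum(vapply(sig_lists, function(l) t %in% l, logical(1)))
  }, integer(1))
  out <- data.frame(term_id = terms, occurrence_count = unname(count),
                    occurrence_frequency = unname(count) / n_queries,
                    stringsAsFactors = FALSE)
  out$flagged <- out$occurrence_frequency > occurrence_min
  out <- out[order(-out$occurrence_frequency, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Information content of ontology terms
#'
#' IC(t) = -ln of the annotation frequency of t, where a gene annotated to
#' a term is propagated to all its is_a ancestors. The corpus is the union
#' of all annotated genes, so a root annotated (implicitly) to every gene
#' has IC 0, and IC is nonincreasing from child to parent.
#'
#' @param gene_sets A `GeneSetCollection` whose set ids are ontology term
#'   ids (direct annotation).
#' @param ontology An `OntologyGraph`.
#' @return Named numeric vector of IC values for every term that has at
#'   least one (propagated) annotation.
#' @export
information_content <- function(gene_sets, ontology) {
  stopifnot(inherits(gene_sets, "GeneSetCollection"),
            inherits(ontology, "OntologyGraph"))
  direct <- gene_sets$sets[intersect(names(gene_sets$sets),
                                     ontology$terms$id)]
  corpus <- unique(unlist(direct))
  if (!length(corpus)) stop("no annotated genes shared with the ontology")
  prop <- new.env(parent = emptyenv())
  for (t in names(direct)) {
    for (anc in term_ancestors(ontology, t)) {
      prev <- get0(anc, envir = prop, ifnotfound = NULL)
      assign(anc, union(prev, direct[[t]]), envir = prop)
    }
  }
  ids <- ls(prop)
  freq <- vapply(ids, function(t) {
    length(get(t, envir = prop)) / length(corpus)
  }, numeric(1))
  sort(-log(freq))
}

#' Semantic similarity between two ontology terms
#'
#' Based on the most-informative common ancestor (MICA):
#' * `lin`: `2 IC(MICA) / (IC(a) + IC(b))`;
#' * `simrel`: the Lin similarity damped by `1 - exp(-IC(MICA))`, i.e. by
#'   one minus the MICA's annotation probability, so similarity via a
#'   near-root ancestor counts for little.
#'
#' Both are in \[0, 1\]; two terms whose only common ancestor is the root
#' have similarity 0.
#'
#' @param a,b Term ids (same namespace).
#' @param ontology An `OntologyGraph`.
#' @param ic Information content from [information_content()].
#' @param measure `"simrel"` (default) or `"lin"`.
#' @return Similarity value in \[0, 1\].
#' @export
semantic_similarity <- function(a, b, ontology, ic,
                                measure = c("simrel", "lin")) {
  measure <- match.arg(measure)
  for (t in c(a, b)) {
    if (!t %in% ontology$terms$id) stop("term absent from ontology: ", t)
  }
  ns <- ontology$terms$namespace[match(c(a, b), ontology$terms$id)]
  if (ns[1] != ns[2]) {
    stop("terms belong to different namespaces: ", ns[1], " vs ", ns[2])
  }
  common <- intersect(term_ancestors(ontology, a), term_ancestors(ontology, b))
  common <- intersect(common, names(ic))
  if (!length(common)) return(0)
  ic_mica <- max(ic[common])
  ic_a <- ic[[a]] %||% NA_real_
  ic_b <- ic[[b]] %||% NA_real_
  if (is.na(ic_a) || is.na(ic_b)) stop("term without information content")
  denom <- ic_a + ic_b
  if (denom <= 0) return(0)
  lin <- 2 * ic_mica / denom
  switch(measure,
         lin = lin,
         simrel = lin * (1 - exp(-ic_mica)))
}

#' Greedy semantic-similarity reduction of a term list
#'
#' REVIGO-style summarization: terms are processed by decreasing
#' occurrence frequency (ties: smaller best q first, then term id); each
#' term joins the most similar existing representative whose similarity
#' exceeds the cutoff, otherwise it becomes a new representative. Run per
#' namespace. Reducing the set of representatives again changes nothing
#' (idempotence).
#'
#' @param terms data.frame with columns `term_id`,
#'   `occurrence_frequency`, and optionally `best_q` (used only for tie
#'   breaks).
#' @param ontology An `OntologyGraph`.
#' @param ic Information content.
#' @param cutoff Similarity cutoff C (default 0.90).
#' @param measure Passed to [semantic_similarity()].
#' @return The input (duplicated term ids collapsed) plus a
#'   `representative` column mapping every term to its cluster
#'   representative.
#' @export
reduce_terms <- function(terms, ontology, ic, cutoff = 0.90,
                         measure = c("simrel", "lin")) {
  measure <- match.arg(measure)
  stopifnot("term_id" %in% colnames(terms),
            "occurrence_frequency" %in% colnames(terms))
  terms <- terms[!duplicated(terms$term_id), , drop = FALSE]
  if (!nrow(terms)) {
    terms$representative <- character(0)
    return(terms)
  }
  if (!"best_q" %in% colnames(terms)) terms$best_q <- NA_real_
  ord <- order(-terms$occurrence_frequency,
               ifelse(is.na(terms$best_q), Inf, terms$best_q),
               terms$term_id)
  terms <- terms[ord, , drop = FALSE]
  ns <- ontology$terms$namespace[match(terms$term_id, ontology$terms$id)]
  if (any(is.na(ns))) {
    stop("term absent from ontology: ", terms$term_id[is.na(ns)][1])
  }
  if (length(unique(ns)) > 1) {
    stop("reduce_terms must be run per namespace; got: ",
         paste(unique(ns), collapse = ", "))
  }
  reps <- character(0)
  assign_to <- character(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    t <- terms$term_id[i]
    if (length(reps)) {
      sims <- vapply(reps, function(r) {
        semantic_similarity(t, r, ontology, ic, measure)
      }, numeric(1))
      best <- which.max(sims)
      if (sims[best] > cutoff) {
        assign_to[i] <- reps[best]
        next
      }
    }
    reps <- c(reps, t)
    assign_to[i] <- t
  }
  terms$representative <- assign_to
  rownames(terms) <- NULL
  terms
}

#' Stratified ontology analysis of candidate correlate sets
#'
#' For each of the four (candidate direction x correlation sign) strata:
#' every candidate's correlates of that sign form one query; each query is
#' tested by [hypergeom_enrich()]; the significant terms are pooled and
#' ranked by occurrence; terms above the occurrence rule are reduced by
#' semantic similarity. Strata in which no query returns a significant
#' term yield an empty summary, not an error.
#'
#' @param candidates Candidate table from [select_candidates()].
#' @param pairs Pair table from [screen_pairs()].
#' @param gene_sets A `GeneSetCollection`.
#' @param ontology An `OntologyGraph`.
#' @param background Gene universe for the hypergeometric test (typically
#'   all detectable genes).
#' @param q_enrich Per-query significance threshold on the BH q-value.
#' @param occurrence_min Strict occurrence-frequency rule for
#'   summarization.
#' @param similarity_cutoff Cutoff C for [reduce_terms()].
#' @param measure Similarity measure.
#' @return Named list (`up.pos`, `up.neg`, `down.pos`, `down.neg`), each
#'   with `queries` (per-candidate gene lists), `enrichment`
#'   (per-candidate result tables), `summary` (pooled occurrence table)
#'   and `reduced` (flagged terms with representatives).
#' @export
run_candidate_ontology_analysis <- function(candidates, pairs, gene_sets,
                                            ontology, background,
                                            q_enrich = 0.05,
                                            occurrence_min = 0.5,
                                            similarity_cutoff = 0.90,
                                            measure = c("simrel", "lin")) {
  measure <- match.arg(measure)
  ic <- information_content(gene_sets, ontology)
  strata <- expand.grid(direction = c("up", "down"), sign = c(1L, -1L),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(strata)), function(i) {
    dir <- strata$direction[i]; sgn <- strata$sign[i]
    cand <- candidates$intimal_gene[candidates$direction_under_flow == dir]
    queries <- lapply(cand, function(g) {
      pairs$medial_gene[pairs$intimal_gene == g & pairs$sign == sgn]
    })
    names(queries) <- cand
    queries <- queries[vapply(queries, function(q) {
      length(intersect(q, background)) > 0
    }, logical(1))]
    if (!length(queries)) {
      return(list(queries = list(), enrichment = list(),
                  summary = pool_and_rank(list(character(0)),
                                          occurrence_min),
                  reduced = NULL))
    }
    enr <- lapply(queries, hypergeom_enrich, gene_sets = gene_sets,
                  background = background)
    sig_lists <- lapply(enr, function(e) e$term_id[e$q_value < q_enrich])
    summary <- pool_and_rank(sig_lists, occurrence_min)
    reduced <- NULL
    flagged <- summary[summary$flagged, , drop = FALSE]
    if (nrow(flagged)) {
      best_q <- vapply(flagged$term_id, function(t) {
        min(vapply(enr, function(e) {
          q <- e$q_value[e$term_id == t]
          if (length(q)) q else Inf
        }, numeric(1)))
      }, numeric(1))
      flagged$best_q <- unname(best_q)
      ns <- ontology$terms$namespace[match(flagged$term_id,
                                           ontology$terms$id)]
      reduced <- do.call(rbind, lapply(unique(ns), function(x) {
        reduce_terms(flagged[ns == x, , drop = FALSE], ontology, ic,
                     similarity_cutoff, measure)
      }))
    }
    list(queries = queries, enrichment = enr, summary = summary,
         reduced = reduced)
  })
  stats::setNames(out, paste(strata$direction,
                             ifelse(strata$sign > 0, "pos", "neg"),
                             sep = "."))
}
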