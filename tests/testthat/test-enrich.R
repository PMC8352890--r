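# exact combinatorial oracle for the upper-tail hypergeometric p
hyper_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

test_that("hypergeometric p matches exact enumeration", {
  # N = 20, K = 5, n = 5, k = 4:
  # C(5,4)C(15,1)/C(20,5) + C(5,5)C(15,0)/C(20,5)
  background <- sprintf("g%02d", 1:20)
  gsc <- gene_set_collection(list(term = background[1:5]))
  query <- c(background[2:5], background[10])  # overlap k = 4
  res <- hypergeom_enrich(query, gsc, background)
  expected <- (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5)
  expect_equal(res$p_value, expected)
  expect_equal(res$k, 4)

  # random small instances vs the enumeration oracle
  withr::with_seed(9, {
    for (i in 1:20) {
      N <- sample(10:30, 1)
      bg <- sprintf("x%02d", seq_len(N))
      K <- sample(2:(N - 2), 1)
      n <- sample(2:(N - 2), 1)
      set <- sample(bg, K)
      q <- sample(bg, n)
      res <- hypergeom_enrich(q, gene_set_collection(list(s = set)), bg)
      expect_equal(res$p_value,
                   hyper_oracle(length(intersect(set, q)), K, n, N),
                   tolerance = 1e-12)
    }
  })
})

test_that("hypergeometric boundaries: disjoint query and self-query", {
  bg <- sprintf("g%02d", 1:20)
  gsc <- gene_set_collection(list(inset = bg[1:5], self = bg[6:10]))
  res <- hypergeom_enrich(bg[6:10], gsc, bg)
  expect_equal(res$p_value[res$term_id == "inset"], 1)  # k = 0 upper tail
  expect_equal(res$k[res$term_id == "self"], 5)
  expect_lt(res$p_value[res$term_id == "self"],
            res$p_value[res$term_id == "inset"])
  expect_error(hypergeom_enrich(character(0), gsc, bg), "empty query")
  expect_error(hypergeom_enrich("g01", gsc, character(0)),
               "empty background")
})

test_that("occurrence pooling applies the strict > 50% rule", {
  lists <- list(q1 = c("A", "B"), q2 = c("A", "B"), q3 = c("A", "B"),
                q4 = c("A"), q5 = "C", q6 = character(0))
  out <- pool_and_rank(lists)
  # A in 4/6 -> flagged; B in 3/6 -> exactly 0.5, not flagged
  expect_equal(out$occurrence_frequency[out$term_id == "A"], 4 / 6)
  expect_true(out$flagged[out$term_id == "A"])
  expect_equal(out$occurrence_frequency[out$term_id == "B"], 0.5)
  expect_false(out$flagged[out$term_id == "B"])
  # single query: every term has frequency 1
  single <- pool_and_rank(list(c("A", "C")))
  expect_equal(single$occurrence_frequency, c(1, 1))
  # deterministic ordering: frequency desc then id
  expect_equal(out$term_id, c("A", "B", "C"))
})

test_that("information content has root zero and is monotone to parents", {
  ont <- toy_ontology()
  ic <- information_content(toy_gene_sets(), ont)
  expect_equal(unname(ic["T:root"]), 0)
  expect_equal(unname(ic["T:c1"]), log(4))   # 2 of 8 genes
  expect_equal(unname(ic["T:p1"]), log(2))   # {g1,g2,g3,g8} of 8
  expect_equal(unname(ic["T:p2"]), log(2))
  for (t in setdiff(names(ic), "T:root")) {
    for (parent in ont$parents[[t]]) {
      expect_lte(ic[[parent]], ic[[t]] + 1e-12)
    }
  }
})

test_that("semantic similarity matches hand computation on the toy DAG", {
  ont <- toy_ontology()
  ic <- information_content(toy_gene_sets(), ont)
  # identity with positive IC
  expect_equal(semantic_similarity("T:c1", "T:c1", ont, ic, "lin"), 1)
  # siblings under p1: MICA = p1, IC = ln 2; Lin = 2 ln2 / (ln4 + ln4)
  expect_equal(semantic_similarity("T:c1", "T:c2", ont, ic, "lin"), 0.5)
  # simrel damps by 1 - exp(-IC(MICA)) = 1 - 1/2
  expect_equal(semantic_similarity("T:c1", "T:c2", ont, ic, "simrel"),
               0.25)
  # only common ancestor is the root -> 0
  expect_equal(semantic_similarity("T:c1", "T:c3", ont, ic, "lin"), 0)
  # child/parent: MICA = parent
  expect_equal(semantic_similarity("T:c1", "T:p1", ont, ic, "lin"),
               2 * log(2) / (log(4) + log(2)))
  # symmetry and bounds
  withr::with_seed(2, {
    ids <- ont$terms$id
    for (i in 1:10) {
      ab <- sample(ids, 2)
      s1 <- semantic_similarity(ab[1], ab[2], ont, ic)
      s2 <- semantic_similarity(ab[2], ab[1], ont, ic)
      expect_equal(s1, s2)
      expect_gte(s1, 0); expect_lte(s1, 1)
    }
  })
  expect_error(semantic_similarity("T:c1", "NOPE", ont, ic), "absent")
})

test_that("greedy reduction clusters by similarity and is idempotent", {
  ont <- toy_ontology()
  ic <- information_content(toy_gene_sets(), ont)
  # all pairwise similarities below cutoff -> everyone their own rep
  terms <- data.frame(term_id = c("T:c1", "T:c3"),
                      occurrence_frequency = c(1, 0.8),
                      stringsAsFactors = FALSE)
  red <- reduce_terms(terms, ont, ic, cutoff = 0.9, measure = "lin")
  expect_equal(red$representative, red$term_id)

  # child/parent pair above cutoff: higher-frequency member is the rep
  terms2 <- data.frame(term_id = c("T:p1", "T:c1"),
                       occurrence_frequency = c(0.6, 1),
                       stringsAsFactors = FALSE)
  red2 <- reduce_terms(terms2, ont, ic, cutoff = 0.6, measure = "lin")
  expect_equal(red2$representative[red2$term_id == "T:p1"], "T:c1")
  expect_equal(red2$representative[red2$term_id == "T:c1"], "T:c1")

  # duplicates collapse to a single assignment
  dup <- rbind(terms2, terms2[1, ])
  red3 <- reduce_terms(dup, ont, ic, cutoff = 0.6, measure = "lin")
  expect_equal(nrow(red3), 2)

  # idempotence: reducing the representatives changes nothing
  reps <- red2[red2$term_id == red2$representative, ]
  red4 <- reduce_terms(reps, ont, ic, cutoff = 0.6, measure = "lin")
  expect_equal(red4$representative, red4$term_id)

  expect_error(
    reduce_terms(data.frame(term_id = "NOPE", occurrence_frequency = 1),
                 ont, ic), "absent")
})

test_that("stratified analysis recovers a planted module and tolerates empties", {
  gen <- small_dataset()
  gs <- truth_gene_sets(gen$truth, seed = 3)
  rm <- gen$truth$responder_map
  dirs <- stats::setNames(gen$truth$signal_genes$direction,
                          gen$truth$signal_genes$gene)
  up_sig <- names(dirs)[dirs == "up"][1]
  # single up candidate whose positive correlates are its planted
  # responders: pooling degenerates to that query's significant list
  cand <- data.frame(intimal_gene = up_sig, direction_under_flow = "up",
                     n_total = 10L, n_pos = 7L, n_neg = 3L,
                     product_class = "cytokine", stringsAsFactors = FALSE)
  resp <- rm[rm$signal_gene == up_sig, ]
  pairs <- data.frame(intimal_gene = up_sig,
                      medial_gene = resp$responder_gene,
                      r = 0.99 * resp$sign, p_value = 1e-8,
                      sign = resp$sign, n_points = 8L,
                      stringsAsFactors = FALSE)
  background <- rownames(gen$expression$counts)
  out <- run_candidate_ontology_analysis(cand, pairs, gs$gene_sets,
                                         gs$ontology, background)
  up_pos <- out$up.pos$summary
  expect_true(gs$planted_terms[["up.pos"]] %in%
                up_pos$term_id[up_pos$flagged])
  expect_equal(max(up_pos$occurrence_frequency), 1)
  # no down candidates: empty summaries, no error
  expect_equal(nrow(out$down.pos$summary), 0)
  expect_equal(nrow(out$down.neg$summary), 0)
})
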