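# Shared fixtures, generated in code. Expensive objects are built once per
# test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small but complete synthetic dataset with defaults-like noise
small_config <- function(..., seed = 101) {
  simulation_config(n_background_genes = 800, responders_per_signal = 12,
                    seed = seed, ...)
}

small_dataset <- function() {
  memo("small_dataset", function() {
    gen <- generate_dataset(small_config())
    gen$rpkm <- compute_rpkm(gen$expression)
    gen
  })
}

# noise-free dataset (Poisson counting noise only)
clean_dataset <- function() {
  memo("clean_dataset", function() {
    gen <- generate_dataset(small_config(biological_cv = 0,
                                         nb_dispersion = 0))
    gen$rpkm <- compute_rpkm(gen$expression)
    gen
  })
}

# hand-built tiny expression matrix: 3 genes x 4 samples, 2 matched slots
tiny_matrix <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(10, 0, 5,
                       20, 1, 5,
                       30, 2, 5,
                       40, 3, 5),
                     nrow = 3,
                     dimnames = list(c("gA", "gB", "gC"),
                                     c("intima_BA_a1", "media_BA_a1",
                                       "intima_BA_a2", "media_BA_a2")))
  }
  expression_matrix(counts, c(gA = 1000, gB = 2000, gC = 500))
}

# a valid 16-sample design table
default_design <- function() {
  small_dataset()$samples
}

# toy ontology with hand-assigned annotation counts, used for semantic
# similarity oracles:
#          root
#         /    \
#        p1     p2
#       /  \      \
#      c1   c2     c3
toy_ontology <- function() {
  terms <- data.frame(
    id = c("T:root", "T:p1", "T:p2", "T:c1", "T:c2", "T:c3"),
    name = c("root", "parent one", "parent two", "child one", "child two",
             "child three"),
    namespace = "toy", stringsAsFactors = FALSE)
  parents <- list(`T:root` = character(0), `T:p1` = "T:root",
                  `T:p2` = "T:root", `T:c1` = "T:p1", `T:c2` = "T:p1",
                  `T:c3` = "T:p2")
  ontology_graph(terms, parents)
}

# annotations chosen so that IC values are easy to derive by hand:
# corpus = g1..g8; c1 = {g1,g2}, c2 = {g2,g3}, c3 = {g4..g7},
# p1 direct = {g8}; propagated: p1 = {g1,g2,g3,g8}, p2 = {g4..g7},
# root = all 8
toy_gene_sets <- function() {
  gene_set_collection(list(
    `T:c1` = c("g1", "g2"),
    `T:c2` = c("g2", "g3"),
    `T:c3` = c("g4", "g5", "g6", "g7"),
    `T:p1` = c("g8")))
}

expect_same_pairs <- function(pairs, expected_keys) {
  expect_setequal(paste(pairs$intimal_gene, pairs$medial_gene),
                  expected_keys)
}
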