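test_that("pearson_with_p matches analytic cases and a t-CDF oracle", {
  x <- 1:8
  perfect <- pearson_with_p(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)
  expect_equal(pearson_with_p(x, rev(x))$r, -1)

  # r = 0.95 at n = 8: p from numerically integrating the t density with
  # 6 degrees of freedom
  r <- 0.95; n <- 8
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  dens <- function(t) {
    gamma(3.5) / (sqrt(6 * pi) * gamma(3)) * (1 + t^2 / 6)^(-3.5)
  }
  p_oracle <- 2 * stats::integrate(dens, tstat, Inf)$value
  # build vectors with this exact correlation
  y <- r * scale(x)[, 1] + sqrt(1 - r^2) *
    scale(stats::resid(stats::lm(c(2, 1, 4, 3, 6, 5, 8, 7) ~ x)))[, 1]
  got <- pearson_with_p(x, y)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, p_oracle, tolerance = 1e-6)

  expect_error(pearson_with_p(1:3, rep(2, 3)), "zero-variance")
  expect_error(pearson_with_p(1:3, 1:4), "equal length")
})

test_that("correlation is symmetric and affine-invariant", {
  withr::with_seed(5, {
    for (i in 1:10) {
      x <- rnorm(8); y <- rnorm(8)
      a <- pearson_with_p(x, y); b <- pearson_with_p(y, x)
      expect_equal(a$r, b$r); expect_equal(a$p, b$p)
      c <- pearson_with_p(3.7 * x + 11, y)
      expect_equal(a$r, c$r, tolerance = 1e-12)
    }
  })
})

test_that("matched vectors cover the eight slots and are order-canonical", {
  gen <- small_dataset()
  v <- assemble_matched_vectors(gen$rpkm, gen$samples, "PECAM1", "intima")
  expect_length(v, 8)
  # permuted sample table gives identical vectors
  perm <- withr::with_seed(3, sample(16))
  v2 <- assemble_matched_vectors(gen$rpkm, gen$samples[perm, ], "PECAM1",
                                 "intima")
  expect_identical(v, v2)

  broken <- gen$samples[gen$samples$sample_id != "media_BT_sham1", ]
  expect_error(matched_slots(broken), "partner|missing")
  expect_error(assemble_matched_vectors(gen$rpkm, gen$samples, "NOPE",
                                        "intima"), "absent")
})

test_that("screen output equals brute-force all-pairs enumeration", {
  gen <- small_dataset()
  rpkm <- gen$rpkm
  genes <- rownames(rpkm)
  intimal <- c(gen$truth$signal_genes$gene[1:5],
               gen$truth$null_genes[1:10])
  medial <- c(gen$truth$responder_map$responder_gene[c(1, 2, 13, 25)],
              gen$truth$null_genes[11:20])
  pairs <- screen_pairs(intimal, medial, rpkm, gen$samples)
  # independent route: per-pair cor.test on assembled vectors
  slots <- matched_slots(gen$samples)
  brute <- list()
  for (gi in intimal) for (gm in medial) {
    x <- rpkm[gi, slots$intima_sample]
    y <- rpkm[gm, slots$media_sample]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- stats::cor.test(x, y)
    if (abs(ct$estimate) > 0.9 && ct$p.value < 1e-4) {
      brute[[paste(gi, gm)]] <- unname(ct$estimate)
    }
  }
  expect_same_pairs(pairs, names(brute))
  expect_equal(pairs$r,
               unname(unlist(
                 brute[paste(pairs$intimal_gene, pairs$medial_gene)])),
               tolerance = 1e-10)
  # deterministic lexicographic ordering
  expect_false(is.unsorted(pairs$intimal_gene))
})

test_that("constant-shift pairs pass with sign +1; zero variance is skipped", {
  s <- small_dataset()$samples
  ids <- s$sample_id
  counts <- matrix(10L, 3, 16, dimnames = list(c("gi", "gm", "gz"), ids))
  slots <- matched_slots(s)
  vals <- c(10, 20, 30, 40, 50, 60, 70, 80)
  counts["gi", slots$intima_sample] <- vals
  counts["gm", slots$media_sample] <- vals + 5
  counts["gz", ] <- 10  # zero variance across slots
  # equalize library sizes so RPKM keeps the affine relation exact
  other <- matrix(1000L - colSums(counts), 1, 16,
                  dimnames = list("filler", ids))
  x <- expression_matrix(rbind(counts, other),
                         c(gi = 1000, gm = 1000, gz = 1000, filler = 1000))
  rpkm <- compute_rpkm(x)
  expect_message(
    pairs <- screen_pairs(c("gi", "gz"), "gm", rpkm, s),
    "zero-variance")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$sign, 1L)
  expect_equal(pairs$intimal_gene, "gi")
  expect_equal(attr(pairs, "n_skipped"), 1L)
})

test_that("independent noise passes the screen at far below 1e-3", {
  # 2500 null pairs built from pure noise at n = 8
  withr::with_seed(17, {
    s <- small_dataset()$samples
    ids <- s$sample_id
    ng <- 100
    counts <- matrix(rpois(ng * 16, 500), ng,
                     dimnames = list(sprintf("n%03d", 1:ng), ids))
    x <- expression_matrix(counts, stats::setNames(rep(1000, ng),
                                                   rownames(counts)))
    rpkm <- compute_rpkm(x)
    pairs <- screen_pairs(rownames(counts)[1:50], rownames(counts)[51:100],
                          rpkm, s)
    expect_lte(nrow(pairs) / 2500, 1e-3)
  })
})

test_that("planted responders are recovered with the correct sign", {
  gen <- clean_dataset()
  rm <- gen$truth$responder_map
  neg <- rm[rm$sign < 0, ][1:5, ]
  pos <- rm[rm$sign > 0, ][1:5, ]
  pairs <- screen_pairs(unique(c(neg$signal_gene, pos$signal_gene)),
                        c(neg$responder_gene, pos$responder_gene),
                        gen$rpkm, gen$samples, scale = "log2")
  key <- paste(pairs$intimal_gene, pairs$medial_gene)
  for (i in seq_len(nrow(neg))) {
    k <- paste(neg$signal_gene[i], neg$responder_gene[i])
    expect_true(k %in% key)
    expect_equal(pairs$sign[key == k], -1L)
  }
  for (i in seq_len(nrow(pos))) {
    k <- paste(pos$signal_gene[i], pos$responder_gene[i])
    expect_true(k %in% key)
    expect_equal(pairs$sign[key == k], 1L)
  }
})

test_that("empty DEG sets warn and return an empty frame", {
  gen <- small_dataset()
  expect_warning(p <- screen_pairs(character(0), "PECAM1", gen$rpkm,
                                   gen$samples), "empty DEG set")
  expect_equal(nrow(p), 0)
})

test_that("correlate tallies keep the additive identity and drop empties", {
  pairs <- data.frame(
    intimal_gene = c(rep("SERP-like", 287), rep("CYT-like", 283)),
    medial_gene = sprintf("m%03d", 1:570),
    r = 0.99, p_value = 1e-6,
    sign = c(rep(1L, 182), rep(-1L, 105), rep(1L, 106), rep(-1L, 177)),
    n_points = 8L, stringsAsFactors = FALSE)
  tally <- count_correlates(pairs)
  expect_equal(tally$n_total[tally$intimal_gene == "SERP-like"], 287)
  expect_equal(tally$n_pos[tally$intimal_gene == "SERP-like"], 182)
  expect_equal(tally$n_total[tally$intimal_gene == "CYT-like"], 283)
  expect_equal(tally$n_neg[tally$intimal_gene == "CYT-like"], 177)
  expect_true(all(tally$n_total == tally$n_pos + tally$n_neg))
  # gene with no passing pairs simply absent
  expect_false("ghost" %in% tally$intimal_gene)
  expect_equal(nrow(count_correlates(pairs[0, ])), 0)
})

test_that("candidate selection applies the strict > rule and annotation", {
  counts <- data.frame(
    intimal_gene = c("exact200", "ec250", "nonec300"),
    n_total = c(200L, 250L, 300L),
    n_pos = c(100L, 150L, 200L),
    n_neg = c(100L, 100L, 100L), stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("exact200", "ec250"),
                    is_extracellular = c(TRUE, TRUE),
                    product_class = c("cytokine", "enzyme"),
                    stringsAsFactors = FALSE)
  dirs <- c(exact200 = "up", ec250 = "up", nonec300 = "down")
  expect_message(cand <- select_candidates(counts, ann, dirs),
                 "non-extracellular")
  expect_equal(cand$intimal_gene, "ec250")
  expect_equal(cand$product_class, "enzyme")
})

test_that("imported correlate tables with broken arithmetic are flagged", {
  df <- data.frame(n_total = c(287, 219), n_pos = c(182, 112),
                   n_neg = c(105, 97))
  expect_message(out <- validate_correlate_counts(df), "violate")
  expect_equal(out$consistent, c(TRUE, FALSE))
})
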