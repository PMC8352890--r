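# brute-force step-up oracle for BH
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * sp[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

test_that("BH adjustment matches hand-computed and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(11, {
    for (n in c(1, 2, 7, 23, 50)) {
      p <- runif(n)
      expect_equal(bh_adjust(p), bh_oracle(p))
      # monotone nondecreasing in p rank
      expect_true(all(diff(bh_adjust(p)[order(p)]) > -1e-12))
    }
  })
})

test_that("detectability keeps genes whose best group mean exceeds 1 RPKM", {
  rpkm <- matrix(c(0.4, 0.8,   0.0, 1.2,   0, 0,   3, 3), nrow = 4,
                 byrow = TRUE,
                 dimnames = list(c("low", "oneside", "zero", "high"),
                                 c("s1", "s2")))
  groups <- list(a = "s1", b = "s2")
  kept <- filter_detectable(rpkm, groups)
  expect_setequal(kept, c("oneside", "high"))
  expect_error(filter_detectable(rpkm, list(a = character(0))), "empty")
})

test_that("moderated fold changes behave at the boundaries", {
  counts <- matrix(c(8, 8, 2, 2,
                     5, 5, 5, 5,
                     0, 0, 400, 400), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g4x", "gflat", "gzero"),
                                   paste0("s", 1:4)))
  groups <- list(A = c("s1", "s2"), B = c("s3", "s4"))
  sf <- stats::setNames(rep(1, 4), paste0("s", 1:4))
  expect_equal(unname(log2_fold_change(counts, groups, sf)["gflat"]), 0)
  fc <- log2_fold_change(counts, groups, sf, prior_count = 1e-9)
  expect_equal(unname(fc["g4x"]), 2, tolerance = 1e-6)
  fz <- unname(log2_fold_change(counts, groups, sf)["gzero"])
  expect_lt(fz, -5)
  expect_true(is.finite(fz))
  expect_error(log2_fold_change(counts, groups, sf, prior_count = 0),
               "prior_count")
})

test_that("dispersion estimation recovers known truth", {
  groups <- list(A = c("s1", "s2"), B = c("s3", "s4"))
  # constant equal counts -> dispersion 0
  const <- matrix(100, 5, 4,
                  dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_equal(unname(estimate_dispersion(const, groups)), rep(0, 5),
               tolerance = 1e-6)

  withr::with_seed(21, {
    ngene <- 2000
    mu <- exp(runif(ngene, log(50), log(2000)))
    ids <- sprintf("g%04d", seq_len(ngene))
    # Poisson counts (true dispersion 0), library ~1e6
    cp <- matrix(rpois(ngene * 4, rep(mu, 4)), ngene,
                 dimnames = list(ids, paste0("s", 1:4)))
    dp <- estimate_dispersion(cp, groups)
    expect_lt(stats::median(dp), 0.05)
    # NB dispersion 0.4, n = 4 per group
    c4 <- matrix(rnbinom(ngene * 8, mu = rep(mu, 8), size = 1 / 0.4),
                 ngene, dimnames = list(ids, paste0("t", 1:8)))
    g4 <- list(A = paste0("t", 1:4), B = paste0("t", 5:8))
    d4 <- estimate_dispersion(c4, g4)
    expect_gt(stats::median(d4), 0.2)
    expect_lt(stats::median(d4), 0.6)
  })
  expect_error(estimate_dispersion(const, list(A = "s1", B = "s2")),
               ">= 2 samples")
})

test_that("exact NB test finds no signal in balanced counts", {
  counts <- matrix(5000, 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  groups <- list(A = c("s1", "s2"), B = c("s3", "s4"))
  sf <- stats::setNames(rep(1, 4), paste0("s", 1:4))
  p <- nb_exact_test(counts, groups,
                     stats::setNames(rep(0, 3), paste0("g", 1:3)), sf)
  expect_true(all(p > 0.9))
})

test_that("a planted 8-fold change at low dispersion is highly significant", {
  withr::with_seed(31, {
    ids <- sprintf("g%03d", 1:100)
    counts <- matrix(rnbinom(400, mu = rep(c(800, 800, 100, 100),
                                           each = 100),
                             size = 100), 100,
                     dimnames = list(ids, paste0("s", 1:4)))
    groups <- list(A = c("s1", "s2"), B = c("s3", "s4"))
    sf <- stats::setNames(rep(1, 4), paste0("s", 1:4))
    p <- nb_exact_test(counts, groups,
                       stats::setNames(rep(0.01, 100), ids), sf)
    expect_true(all(p < 0.01))
  })
})

test_that("p-values are invariant to relabeling within groups", {
  withr::with_seed(41, {
    ids <- sprintf("g%03d", 1:50)
    counts <- matrix(rnbinom(50 * 4, mu = 300, size = 20), 50,
                     dimnames = list(ids, paste0("s", 1:4)))
    g1 <- list(A = c("s1", "s2"), B = c("s3", "s4"))
    g2 <- list(A = c("s2", "s1"), B = c("s4", "s3"))
    disp <- estimate_dispersion(counts, g1)
    sf <- size_factors(counts)
    expect_equal(nb_exact_test(counts, g1, disp, sf),
                 nb_exact_test(counts, g2, disp, sf))
  })
})

test_that("larger fold changes never raise the exact-test p-value", {
  base <- c(200, 220, 210, 190)
  sf <- stats::setNames(rep(1, 4), paste0("s", 1:4))
  groups <- list(A = c("s1", "s2"), B = c("s3", "s4"))
  prev <- Inf
  for (fold in c(1, 2, 4, 8)) {
    counts <- matrix(round(base * c(fold, fold, 1, 1)), 1,
                     dimnames = list("g1", paste0("s", 1:4)))
    p <- nb_exact_test(counts, groups, c(g1 = 0.05), sf)
    expect_lte(p, prev + 1e-12)
    prev <- p
  }
})

test_that("DEG calling enforces set semantics across locations", {
  fake <- function(tissue, location, genes, q, fc) {
    data.frame(gene = genes, tissue = tissue, location = location,
               log2_fc = fc, p_value = q / 2, q_value = q,
               mean_rpkm_ligated = 10, mean_rpkm_sham = 10,
               detectable = TRUE,
               is_deg = q < 0.05, stringsAsFactors = FALSE)
  }
  genes <- c("gA", "gB", "gC")
  results <- list(
    intima.BA = fake("intima", "BA", genes, c(0.01, 0.20, 0.01),
                     c(2, 1, -1)),
    intima.BT = fake("intima", "BT", genes, c(0.02, 0.01, 0.90),
                     c(2, -1, 0.5)),
    media.BA = fake("media", "BA", genes, c(0.5, 0.5, 0.5), c(1, 1, 1)),
    media.BT = fake("media", "BT", genes, c(0.5, 0.5, 0.5), c(1, 1, 1)))
  calls <- call_degs(results)
  # gA significant at both locations: once in each list, once in overlap
  expect_equal(sort(calls$degs$intima.BA$gene), c("gA", "gC"))
  expect_equal(sort(calls$degs$intima.BT$gene), c("gA", "gB"))
  expect_equal(unname(calls$overlap["intima"]), 1)
  expect_setequal(calls$union$intima, c("gA", "gB", "gC"))
  expect_equal(nrow(calls$degs$media.BA), 0)
  expect_equal(unname(calls$overlap["media"]), 0)
  expect_error(call_degs(results[1:3]), "missing comparison")
})

test_that("external DE tables are importable with validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2_fc\tp_value\tq_value",
               "g1\t2.5\t0.001\t0.01"), path)
  df <- read_de_table(path)
  expect_equal(df$log2_fc, 2.5)
  writeLines(c("gene\tlog2_fc\tp_value\tq_value",
               "g1\t2.5\t1.7\t0.01"), path)
  expect_error(read_de_table(path), "\\[0, 1\\]")
})
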