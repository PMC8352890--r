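#' Per-sample size factors
#'
#' Median-of-ratios depth normalization: each sample's factor is the
#' median, over genes with nonzero counts in every sample, of the ratio of
#' the gene's count to its geometric mean across samples. This is robust
#' to library-composition shifts (a block of strongly regulated genes
#' changing between conditions would bias total-count ratios and with them
#' every null gene). When fewer than 10 genes are everywhere-positive the
#' total-count ratio to the geometric mean library is used instead.
#' Factors are rescaled to geometric mean 1; deterministic.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) >= 10) {
    lc <- log(counts[pos, , drop = FALSE])
    ratios <- exp(lc - rowMeans(lc))
    sf <- apply(ratios, 2, stats::median)
  } else {
    sf <- lib
  }
  sf / exp(mean(log(sf)))
}

#' Detectability filter
#'
#' A gene is detectable when the maximum over groups of its group-mean RPKM
#' exceeds `rpkm_min` (default 1 RPKM).
#'
#' @param rpkm RPKM matrix.
#' @param groups Named list of sample-id vectors.
#' @param rpkm_min Detection threshold in RPKM.
#' @return Character vector of detectable gene ids.
#' @export
filter_detectable <- function(rpkm, groups, rpkm_min = 1) {
  if (any(lengths(groups) == 0)) stop("empty group in detectability filter")
  means <- vapply(groups, function(s) {
    rowMeans(rpkm[, s, drop = FALSE])
  }, numeric(nrow(rpkm)))
  rownames(rpkm)[apply(means, 1, max) > rpkm_min]
}

#' Estimate per-gene negative-binomial dispersion
#'
#' Per-gene method-of-moments estimates (excess of the depth-normalized
#' count variance over the Poisson expectation, relative to the squared
#' mean, pooled across groups and floored at zero) are shrunk toward a
#' common dispersion estimated by conditional maximum likelihood. With the
#' few residual degrees of freedom typical of this design the raw per-gene
#' values are nearly uninformative, so shrinkage is weighted by degrees of
#' freedom: `phi = (df * raw + prior_df * common) / (df + prior_df)`.
#'
#' @param counts Count matrix.
#' @param groups Named list of two (or more) sample-id vectors, each with
#'   >= 2 samples.
#' @param sf Size factors (defaults to [size_factors()] of `counts`).
#' @param prior_df Prior degrees of freedom carried by the common
#'   dispersion (default 10; larger values pull harder toward the common
#'   value).
#' @return Named numeric vector of dispersions (>= 0), one per gene.
#' @export
estimate_dispersion <- function(counts, groups, sf = size_factors(counts),
                                prior_df = 10) {
  if (any(lengths(groups) < 2)) {
    stop("dispersion estimation needs >= 2 samples per group")
  }
  wsum <- 0
  acc <- rep(0, nrow(counts))
  for (g in groups) {
    y <- sweep(counts[, g, drop = FALSE], 2, sf[g], "/")
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    pois <- m * mean(1 / sf[g])
    ok <- m > 0
    phi_g <- ifelse(ok, (v - pois) / pmax(m, 1e-300)^2, 0)
    acc <- acc + (length(g) - 1) * phi_g
    wsum <- wsum + (length(g) - 1)
  }
  raw <- pmax(acc / wsum, 0)
  common <- common_dispersion_cml(counts, groups, sf)
  df <- wsum
  phi <- (df * raw + prior_df * common) / (df + prior_df)
  stats::setNames(pmax(phi, 0), rownames(counts))
}

#' Common dispersion by conditional maximum likelihood
#'
#' Maximizes, over a single dispersion shared by all genes, the likelihood
#' of the depth-normalized counts within each group conditional on the
#' group total (which removes the per-gene mean). Size factors close to 1
#' are assumed, as produced by [size_factors()] on samples of comparable
#' depth.
#'
#' @inheritParams estimate_dispersion
#' @return A single dispersion value >= 0.
#' @export
common_dispersion_cml <- function(counts, groups, sf = size_factors(counts)) {
  ylist <- lapply(groups, function(g) {
    round(sweep(counts[, g, drop = FALSE], 2, sf[g], "/"))
  })
  neg_loglik <- function(log_phi) {
    r <- 1 / exp(log_phi)
    ll <- 0
    for (y in ylist) {
      n <- ncol(y)
      z <- rowSums(y)
      keep <- z > 0
      if (!any(keep)) next
      yk <- y[keep, , drop = FALSE]
      zk <- z[keep]
      ll <- ll + sum(rowSums(lgamma(yk + r)) - n * lgamma(r)) -
        sum(lgamma(zk + n * r) - lgamma(n * r))
    }
    -ll
  }
  opt <- stats::optimize(neg_loglik, interval = log(c(1e-8, 5)))
  phi <- exp(opt$minimum)
  # boundary: effectively Poisson
  if (phi < 2e-8) phi <- 0
  phi
}

#' Exact-style conditional negative-binomial test
#'
#' Two-sided test for a difference in expression between two groups.
#' Depth-normalized counts are summed within each group; conditional on the
#' total, the probability of each split between the groups is evaluated
#' under a common-mean negative binomial (group sums of NB(mu, phi) counts
#' over n samples are treated as NB(n mu, phi / n)), and the p-value is the
#' total probability of all splits at most as likely as the observed one.
#' With dispersion zero the conditional distribution is binomial.
#'
#' @param counts Count matrix.
#' @param groups Named list of exactly two sample-id vectors; the first is
#'   the "treatment" group by convention.
#' @param dispersions Per-gene dispersion from [estimate_dispersion()].
#' @param sf Size factors; must be strictly positive.
#' @return Named numeric vector of two-sided p-values in (0, 1].
#' @export
nb_exact_test <- function(counts, groups, dispersions,
                          sf = size_factors(counts)) {
  if (length(groups) != 2) stop("nb_exact_test expects exactly two groups")
  if (any(sf <= 0)) stop("size factors must be > 0")
  a_ids <- groups[[1]]; b_ids <- groups[[2]]
  nA <- length(a_ids); nB <- length(b_ids)
  yA <- sweep(counts[, a_ids, drop = FALSE], 2, sf[a_ids], "/")
  yB <- sweep(counts[, b_ids, drop = FALSE], 2, sf[b_ids], "/")
  sA <- round(rowSums(yA)); sB <- round(rowSums(yB))
  phi <- dispersions[rownames(counts)]
  p <- vapply(seq_len(nrow(counts)), function(i) {
    exact_split_p(sA[i], sB[i], nA, nB, phi[i])
  }, numeric(1))
  stats::setNames(p, rownames(counts))
}

# conditional two-sided p for an (sA, sB) split of S = sA + sB
exact_split_p <- function(sA, sB, nA, nB, phi) {
  S <- sA + sB
  if (S == 0) return(1)
  mu <- S / (nA + nB)
  if (!is.finite(phi) || phi < 1e-10) {
    support <- window_support(S, sA, function(q) {
      stats::qbinom(q, S, nA / (nA + nB))
    })
    probs <- stats::dbinom(support, S, nA / (nA + nB))
  } else {
    rA <- nA / phi; rB <- nB / phi
    support <- window_support(S, sA, function(q) {
      stats::qnbinom(q, size = rA, mu = nA * mu)
    })
    probs <- stats::dnbinom(support, size = rA, mu = nA * mu) *
      stats::dnbinom(S - support, size = rB, mu = nB * mu)
  }
  tot <- sum(probs)
  if (tot <= 0) return(1)
  p_obs <- probs[match(sA, support)]
  min(1, max(sum(probs[probs <= p_obs * (1 + 1e-8)]) / tot,
             .Machine$double.xmin))
}

# integer support for the conditional split distribution; truncates far
# tails (mass < ~1e-14) for very large totals but always contains sA
window_support <- function(S, sA, qfun) {
  if (S <= 20000) return(0:S)
  lo <- max(0, qfun(1e-15))
  hi <- min(S, qfun(1 - 1e-15))
  lo <- min(lo, sA); hi <- max(hi, sA)
  lo:hi
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m p_(j) / j)` clipped at
#' 1 and mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Moderated log2 fold change
#'
#' log2 ratio of group-mean depth-normalized counts, with a prior count
#' added to both means so genes silent in one group get a large but finite
#' fold change.
#'
#' @param counts Count matrix.
#' @param groups Named list of two sample-id vectors (numerator group
#'   first).
#' @param sf Size factors.
#' @param prior_count Offset added to both normalized means (> 0).
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(counts, groups, sf = size_factors(counts),
                             prior_count = 0.5) {
  if (prior_count <= 0) stop("prior_count must be > 0")
  mA <- rowMeans(sweep(counts[, groups[[1]], drop = FALSE], 2,
                       sf[groups[[1]]], "/"))
  mB <- rowMeans(sweep(counts[, groups[[2]], drop = FALSE], 2,
                       sf[groups[[2]]], "/"))
  stats::setNames(log2((mA + prior_count) / (mB + prior_count)),
                  rownames(counts))
}

#' Differential expression for one tissue x location comparison
#'
#' Compares ligated vs sham samples of one compartment at one location:
#' detectability filter on group-mean RPKM, dispersion estimation,
#' exact-style NB test, BH adjustment across detectable genes, and
#' moderated fold changes. Genes failing the detectability filter carry NA
#' p/q and are never DEGs.
#'
#' @param x An `ExpressionMatrix`.
#' @param samples Sample table.
#' @param tissue `"intima"` or `"media"`.
#' @param location `"BA"` or `"BT"`.
#' @param rpkm_min Detectability threshold (group-mean RPKM).
#' @param q_threshold DEG threshold on the BH-adjusted p-value.
#' @param prior_count Prior for [log2_fold_change()].
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @return data.frame with one row per gene: `gene`, `tissue`, `location`,
#'   `log2_fc`, `p_value`, `q_value`, `mean_rpkm_ligated`,
#'   `mean_rpkm_sham`, `detectable`, `is_deg`.
#' @export
de_comparison <- function(x, samples, tissue, location, rpkm_min = 1,
                          q_threshold = 0.05, prior_count = 0.5,
                          prior_df = 10) {
  samples <- validate_samples(samples)
  sel <- samples$tissue == tissue & samples$location == location
  if (!any(sel)) stop("no samples for ", tissue, " at ", location)
  sub <- samples[sel, ]
  groups <- list(ligated = sub$sample_id[sub$condition == "ligated"],
                 sham = sub$sample_id[sub$condition == "sham"])
  if (any(lengths(groups) == 0)) {
    stop("missing condition group for ", tissue, " at ", location)
  }
  counts <- x$counts[, sub$sample_id, drop = FALSE]
  sub_x <- expression_matrix(counts, x$gene_length_bp)
  rpkm <- compute_rpkm(sub_x)
  sf <- size_factors(counts)

  detectable <- filter_detectable(rpkm, groups, rpkm_min)
  res <- data.frame(
    gene = rownames(counts),
    tissue = tissue, location = location,
    log2_fc = unname(log2_fold_change(counts, groups, sf, prior_count)),
    p_value = NA_real_, q_value = NA_real_,
    mean_rpkm_ligated = unname(rowMeans(rpkm[, groups$ligated,
                                             drop = FALSE])),
    mean_rpkm_sham = unname(rowMeans(rpkm[, groups$sham, drop = FALSE])),
    detectable = rownames(counts) %in% detectable,
    stringsAsFactors = FALSE)
  if (length(detectable)) {
    dc <- counts[detectable, , drop = FALSE]
    disp <- estimate_dispersion(dc, groups, sf, prior_df)
    p <- nb_exact_test(dc, groups, disp, sf)
    res$p_value[res$detectable] <- unname(p)
    res$q_value[res$detectable] <- bh_adjust(unname(p))
  }
  res$is_deg <- res$detectable & !is.na(res$q_value) &
    res$q_value < q_threshold
  res
}

#' Differential expression for all four comparisons
#'
#' Runs [de_comparison()] for intima and media at both locations.
#'
#' @inheritParams de_comparison
#' @return Named list of four DE tables
#'   (`intima.BA`, `intima.BT`, `media.BA`, `media.BT`).
#' @export
run_de <- function(x, samples, rpkm_min = 1, q_threshold = 0.05,
                   prior_count = 0.5, prior_df = 10) {
  combos <- expand.grid(tissue = c("intima", "media"),
                        location = c("BA", "BT"),
                        stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    de_comparison(x, samples, combos$tissue[i], combos$location[i],
                  rpkm_min, q_threshold, prior_count, prior_df)
  })
  stats::setNames(res, paste(combos$tissue, combos$location, sep = "."))
}

#' DEG calls, per-tissue unions and cross-location overlaps
#'
#' Summarizes the four DE tables into per-comparison DEG sets with
#' direction, per-tissue unions (a gene detectable with q below threshold
#' in either location of a compartment — the inclusion rule for the
#' correlation screen), the count of DEGs shared between BA and BT per
#' tissue, and a volcano-plot table.
#'
#' @param results Named list from [run_de()]; all four comparisons must be
#'   present.
#' @param q_threshold DEG threshold on q.
#' @return List with `degs` (per comparison: data.frame gene/direction),
#'   `union` (per tissue: character vector), `overlap` (per tissue: count
#'   shared between BA and BT), `counts` (per comparison: total/up/down),
#'   and `volcano` (long data.frame for plotting).
#' @export
call_degs <- function(results, q_threshold = 0.05) {
  needed <- c("intima.BA", "intima.BT", "media.BA", "media.BT")
  missing <- setdiff(needed, names(results))
  if (length(missing)) {
    stop("missing comparison(s): ", paste(missing, collapse = ", "))
  }
  degs <- lapply(results[needed], function(res) {
    sel <- res$detectable & !is.na(res$q_value) & res$q_value < q_threshold
    data.frame(gene = res$gene[sel],
               direction = ifelse(res$log2_fc[sel] > 0, "up", "down"),
               stringsAsFactors = FALSE)
  })
  union_sets <- list(
    intima = sort(unique(c(degs$intima.BA$gene, degs$intima.BT$gene))),
    media = sort(unique(c(degs$media.BA$gene, degs$media.BT$gene))))
  overlap <- c(
    intima = length(intersect(degs$intima.BA$gene, degs$intima.BT$gene)),
    media = length(intersect(degs$media.BA$gene, degs$media.BT$gene)))
  counts <- do.call(rbind, lapply(names(degs), function(nm) {
    data.frame(comparison = nm, n_deg = nrow(degs[[nm]]),
               n_up = sum(degs[[nm]]$direction == "up"),
               n_down = sum(degs[[nm]]$direction == "down"),
               stringsAsFactors = FALSE)
  }))
  volcano <- do.call(rbind, lapply(results[needed], function(res) {
    data.frame(gene = res$gene, tissue = res$tissue,
               location = res$location, log2_fc = res$log2_fc,
               neg_log10_p = -log10(pmax(res$p_value,
                                         .Machine$double.xmin)),
               is_deg = res$detectable & !is.na(res$q_value) &
                 res$q_value < q_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(volcano) <- NULL
  list(degs = degs, union = union_sets, overlap = overlap, counts = counts,
       volcano = volcano)
}

#' Import an external differential-expression table
#'
#' The DE stage is pluggable: results from any external DE tool can be
#' supplied as a TSV with columns `gene`, `log2_fc`, `p_value`, `q_value`
#' (plus optional `tissue`/`location`) and used by the downstream screen.
#'
#' @param path Path to the TSV.
#' @return data.frame with at least the four required columns.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "log2_fc", "p_value", "q_value")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop("DE table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$p_value < 0 | df$p_value > 1, na.rm = TRUE) ||
      any(df$q_value < 0 | df$q_value > 1, na.rm = TRUE)) {
    stop("imported p/q values outside [0, 1]")
  }
  df
}
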