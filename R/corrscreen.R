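#' Matched intima/media sample slots
#'
#' The screen correlates expression over the (animal x location) slots; the
#' default 16-sample design yields 8 slots, each holding exactly one intima
#' and one media sample. Slot order is canonicalized (animal, then
#' location) so results do not depend on the input row order.
#'
#' @param samples Sample table.
#' @return data.frame with one row per slot: `animal_id`, `location`,
#'   `condition`, `wss_pa`, `intima_sample`, `media_sample`.
#' @export
matched_slots <- function(samples) {
  samples <- validate_samples(samples)
  slots <- unique(samples[, c("animal_id", "location", "condition")])
  slots <- slots[order(slots$animal_id, slots$location), , drop = FALSE]
  rownames(slots) <- NULL
  pick <- function(tissue, i) {
    sel <- samples$tissue == tissue &
      samples$animal_id == slots$animal_id[i] &
      samples$location == slots$location[i]
    id <- samples$sample_id[sel]
    if (length(id) == 0) {
      stop(sprintf("missing %s sample in slot (%s, %s)", tissue,
                   slots$animal_id[i], slots$location[i]))
    }
    if (length(id) > 1) {
      stop(sprintf("duplicated %s sample in slot (%s, %s)", tissue,
                   slots$animal_id[i], slots$location[i]))
    }
    id
  }
  slots$intima_sample <- vapply(seq_len(nrow(slots)),
                                function(i) pick("intima", i), character(1))
  slots$media_sample <- vapply(seq_len(nrow(slots)),
                               function(i) pick("media", i), character(1))
  wss <- samples$wss_pa[match(slots$intima_sample, samples$sample_id)]
  slots$wss_pa <- wss
  slots
}

#' Expression vector of one gene over the matched slots
#'
#' @param rpkm RPKM matrix.
#' @param samples Sample table.
#' @param gene Gene id.
#' @param tissue `"intima"` or `"media"`.
#' @return Named numeric vector (one value per slot, canonical slot
#'   order).
#' @export
assemble_matched_vectors <- function(rpkm, samples, gene, tissue) {
  if (!gene %in% rownames(rpkm)) stop("gene absent from matrix: ", gene)
  slots <- matched_slots(samples)
  col <- if (tissue == "intima") slots$intima_sample else slots$media_sample
  stats::setNames(rpkm[gene, col],
                  paste(slots$animal_id, slots$location, sep = "."))
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' `r` is the sample Pearson coefficient and the p-value comes from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom; a
#' perfect correlation gives p = 0.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return List with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance vector: correlation undefined")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  n <- length(x)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' All-pairs intima-media correlation screen
#'
#' Correlates every intimal DEG with every medial DEG across the matched
#' slots and keeps the pairs with `|r| > r_threshold` and
#' `p < p_threshold` (both conditions applied literally; at n = 8 the
#' p < 1e-4 condition is the binding one and implies |r| above about
#' 0.96). Genes with zero variance across the slots are skipped and
#' counted, not fatal. Output rows are ordered by intimal then medial gene
#' so reruns diff cleanly.
#'
#' @param intimal_degs,medial_degs Character vectors of DEG ids (per-tissue
#'   unions from [call_degs()]).
#' @param rpkm RPKM matrix covering both tissues.
#' @param samples Sample table.
#' @param r_threshold Absolute-correlation threshold.
#' @param p_threshold p-value threshold.
#' @param scale `"rpkm"` correlates raw RPKM values (default, the
#'   published procedure); `"log2"` correlates log2(RPKM + 1), the natural
#'   scale when responses are multiplicative.
#' @return data.frame of passing pairs: `intimal_gene`, `medial_gene`,
#'   `r`, `p_value`, `sign`, `n_points`; attribute `n_skipped` counts
#'   zero-variance genes dropped.
#' @export
screen_pairs <- function(intimal_degs, medial_degs, rpkm, samples,
                         r_threshold = 0.9, p_threshold = 1e-4,
                         scale = c("rpkm", "log2")) {
  scale <- match.arg(scale)
  empty <- data.frame(intimal_gene = character(0),
                      medial_gene = character(0), r = numeric(0),
                      p_value = numeric(0), sign = integer(0),
                      n_points = integer(0), stringsAsFactors = FALSE)
  if (!length(intimal_degs) || !length(medial_degs)) {
    warning("empty DEG set: correlation screen returns no pairs")
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  slots <- matched_slots(samples)
  n <- nrow(slots)
  if (n < 3) stop("need at least 3 matched slots")
  X <- t(rpkm[intimal_degs, slots$intima_sample, drop = FALSE])
  Y <- t(rpkm[medial_degs, slots$media_sample, drop = FALSE])
  if (scale == "log2") {
    X <- log2(X + 1); Y <- log2(Y + 1)
  }
  sd0x <- apply(X, 2, stats::sd) == 0
  sd0y <- apply(Y, 2, stats::sd) == 0
  n_skipped <- sum(sd0x) + sum(sd0y)
  if (n_skipped > 0) {
    message(n_skipped, " zero-variance gene(s) skipped in the screen")
  }
  X <- X[, !sd0x, drop = FALSE]
  Y <- Y[, !sd0y, drop = FALSE]
  if (!ncol(X) || !ncol(Y)) {
    attr(empty, "n_skipped") <- as.integer(n_skipped)
    return(empty)
  }
  R <- stats::cor(X, Y)
  R <- pmin(pmax(R, -1), 1)
  tstat <- abs(R) * sqrt(n - 2) / sqrt(pmax(1 - R^2, 0))
  P <- 2 * stats::pt(-tstat, df = n - 2)
  P[abs(R) >= 1] <- 0
  pass <- which(abs(R) > r_threshold & P < p_threshold, arr.ind = TRUE)
  out <- data.frame(
    intimal_gene = colnames(X)[pass[, 1]],
    medial_gene = colnames(Y)[pass[, 2]],
    r = R[pass], p_value = P[pass],
    sign = ifelse(R[pass] > 0, 1L, -1L),
    n_points = rep(n, nrow(pass)), stringsAsFactors = FALSE)
  out <- out[order(out$intimal_gene, out$medial_gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

#' Tally medial correlates per intimal gene
#'
#' @param pairs Pair table from [screen_pairs()].
#' @return data.frame with one row per intimal gene that has at least one
#'   passing pair: `intimal_gene`, `n_total`, `n_pos`, `n_neg`
#'   (`n_total = n_pos + n_neg` by construction).
#' @export
count_correlates <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(intimal_gene = character(0), n_total = integer(0),
                      n_pos = integer(0), n_neg = integer(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(pairs$sign, pairs$intimal_gene)
  out <- data.frame(
    intimal_gene = names(sp),
    n_total = as.integer(lengths(sp)),
    n_pos = vapply(sp, function(s) sum(s > 0), integer(1)),
    n_neg = vapply(sp, function(s) sum(s < 0), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Check an imported correlate-count table for internal consistency
#'
#' Enforces the identity `n_total = n_pos + n_neg`; rows violating it are
#' flagged rather than silently accepted.
#'
#' @param df data.frame with columns `n_total`, `n_pos`, `n_neg`.
#' @return The input with an added logical column `consistent`.
#' @export
validate_correlate_counts <- function(df) {
  stopifnot(all(c("n_total", "n_pos", "n_neg") %in% colnames(df)))
  df$consistent <- df$n_total == df$n_pos + df$n_neg
  if (any(!df$consistent)) {
    message(sum(!df$consistent),
            " correlate-count row(s) violate n_total = n_pos + n_neg")
  }
  df
}

#' Select extracellular signal candidates
#'
#' A candidate is an intimal DEG coding for an extracellular product with
#' strictly more than `min_correlates` medial correlates. Genes missing
#' from the annotation are treated as non-extracellular (with a message).
#'
#' @param counts Correlate tallies from [count_correlates()].
#' @param annotation Extracellular annotation (see
#'   [read_extracellular()]).
#' @param directions Named character vector: intimal gene -> direction of
#'   its flow response ("up"/"down").
#' @param min_correlates Strict lower bound on `n_total`.
#' @return data.frame of candidates: `intimal_gene`,
#'   `direction_under_flow`, `n_total`, `n_pos`, `n_neg`,
#'   `product_class`, ordered by direction (up first) then descending
#'   `n_total`.
#' @export
select_candidates <- function(counts, annotation, directions,
                              min_correlates = 200) {
  idx <- match(counts$intimal_gene, annotation$gene_id)
  if (any(is.na(idx))) {
    message(sum(is.na(idx)),
            " gene(s) missing from annotation; treated as non-extracellular")
  }
  is_ec <- !is.na(idx) & annotation$is_extracellular[idx]
  keep <- is_ec & counts$n_total > min_correlates
  out <- counts[keep, , drop = FALSE]
  out$direction_under_flow <- unname(directions[out$intimal_gene])
  out$product_class <- annotation$product_class[idx[keep]]
  out <- out[order(match(out$direction_under_flow, c("up", "down")),
                   -out$n_total, out$intimal_gene), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("intimal_gene", "direction_under_flow", "n_total", "n_pos",
          "n_neg", "product_class")]
}
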