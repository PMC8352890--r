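#' Tissue-purity check from compartment marker genes
#'
#' For each marker gene and each matched (animal, location, condition)
#' intima/media pair, computes the intima/media RPKM ratio. A ratio is
#' flagged infinite when the media RPKM is zero while the intima RPKM is
#' positive (the marker is then "infinitely more abundant" in the intima);
#' infinite ratios are excluded from the mean. Media markers are
#' additionally summarized as intima expression as a percentage of media
#' expression, the natural scale for quantifying medial carry-over into the
#' intimal dissection.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param samples Sample table (see [read_samples()]).
#' @param intima_markers Character vector of endothelial marker genes.
#' @param media_markers Character vector of smooth-muscle marker genes.
#' @return List with `per_pair` (one row per marker x tissue pair) and
#'   `summary` (one row per marker: mean finite ratio, number of infinite
#'   pairs, and for media markers the mean intima level as % of media).
#' @export
marker_purity <- function(rpkm, samples, intima_markers, media_markers) {
  samples <- validate_samples(samples)
  markers <- c(intima_markers, media_markers)
  absent <- setdiff(markers, rownames(rpkm))
  if (length(absent)) {
    stop("marker gene absent from matrix: ", paste(absent, collapse = ", "))
  }
  intima <- samples[samples$tissue == "intima", ]
  media <- samples[samples$tissue == "media", ]
  key <- function(df) paste(df$animal_id, df$location, df$condition)
  media <- media[match(key(intima), key(media)), ]
  if (any(is.na(media$sample_id))) stop("unpaired intima sample")

  per_pair <- do.call(rbind, lapply(markers, function(g) {
    iv <- rpkm[g, intima$sample_id]
    mv <- rpkm[g, media$sample_id]
    data.frame(marker = g,
               marker_tissue = ifelse(g %in% intima_markers, "intima",
                                      "media"),
               animal_id = intima$animal_id,
               location = intima$location,
               condition = intima$condition,
               intima_rpkm = unname(iv),
               media_rpkm = unname(mv),
               ratio = ifelse(mv == 0 & iv > 0, Inf,
                              ifelse(mv == 0, NA_real_, iv / mv)),
               infinite = mv == 0 & iv > 0,
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(markers, function(g) {
    rows <- per_pair[per_pair$marker == g, ]
    finite <- rows$ratio[is.finite(rows$ratio)]
    data.frame(marker = g,
               marker_tissue = rows$marker_tissue[1],
               mean_ratio = if (length(finite)) mean(finite) else NA_real_,
               n_pairs = nrow(rows),
               n_infinite = sum(rows$infinite),
               pct_of_media = if (rows$marker_tissue[1] == "media" &&
                                  length(finite))
                 100 * mean(finite) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_pair = per_pair, summary = summary)
}

#' Sample overview by principal component analysis
#'
#' Removes genes with a zero count sum across all samples, log2(x + 1)
#' transforms the remaining counts, and computes principal components of
#' the centered gene-by-sample values. If the retained matrix has zero
#' variance the coordinates are reported as all-zero rather than failing.
#'
#' @param x An `ExpressionMatrix`.
#' @param samples Sample table; carried through to the output for
#'   plotting/grouping.
#' @return List with `coords` (data.frame: sample metadata plus `PC1`,
#'   `PC2`) and `var_explained` (fraction of variance on each returned
#'   component).
#' @export
pca_overview <- function(x, samples) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  samples <- validate_samples(samples)
  counts <- x$counts[, samples$sample_id, drop = FALSE]
  if (ncol(counts) < 3) stop("PCA overview needs at least 3 samples")
  keep <- rowSums(counts) > 0
  if (sum(keep) < 2) stop("fewer than 2 genes with nonzero count sum")
  lg <- log2(counts[keep, , drop = FALSE] + 1)
  m <- t(lg)
  if (all(abs(sweep(m, 2, colMeans(m))) < .Machine$double.eps^0.5)) {
    coords <- data.frame(samples, PC1 = 0, PC2 = 0,
                         stringsAsFactors = FALSE)
    return(list(coords = coords, var_explained = c(PC1 = 0, PC2 = 0)))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- data.frame(samples, pc$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords,
       var_explained = stats::setNames(ve[seq_len(k)],
                                       colnames(pc$x)[seq_len(k)]))
}
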