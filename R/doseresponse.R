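#' Expression of one gene as a function of local wall shear stress
#'
#' One point per intimal sample: the sample's mean WSS (Pa) against the
#' gene's RPKM, in canonical slot order.
#'
#' @param gene Gene id.
#' @param rpkm RPKM matrix.
#' @param samples Sample table with a `wss_pa` value for every intimal
#'   sample.
#' @return data.frame `DoseSeries`: `gene`, `animal_id`, `location`,
#'   `condition`, `wss_pa`, `rpkm`.
#' @export
assemble_dose_series <- function(gene, rpkm, samples) {
  if (!gene %in% rownames(rpkm)) stop("gene absent from matrix: ", gene)
  samples <- validate_samples(samples)
  intima <- samples[samples$tissue == "intima", , drop = FALSE]
  if (any(is.na(intima$wss_pa))) {
    stop("missing WSS for sample: ",
         intima$sample_id[is.na(intima$wss_pa)][1])
  }
  intima <- intima[order(intima$animal_id, intima$location), , drop = FALSE]
  data.frame(gene = gene,
             animal_id = intima$animal_id,
             location = intima$location,
             condition = intima$condition,
             wss_pa = intima$wss_pa,
             rpkm = unname(rpkm[gene, intima$sample_id]),
             stringsAsFactors = FALSE)
}

#' Classify the WSS dose-response shape of a gene
#'
#' Rules are applied in order:
#' 1. *peaked_decline*: the WSS at which expression is maximal lies below
#'    `peak_wss_max` AND mean expression at points with WSS above
#'    `high_wss_min` is at most `decline_fraction` of the maximum.
#'    Checked first because a declining curve can incidentally fit a
#'    negative line.
#' 2. *linear_increasing*: Pearson r of expression on WSS is at least
#'    `r_linear` with positive slope.
#' 3. *plateau*: expression rises at least two-fold from the lowest-WSS
#'    tercile to the middle tercile but changes by less than 25% from the
#'    middle to the highest tercile (terciles of the points sorted by WSS,
#'    extra points going to the earlier groups).
#' 4. otherwise *unclassified*. Zero-variance expression is unclassified
#'    with r reported as NA.
#'
#' @param series A dose series from [assemble_dose_series()] (>= 4 points
#'   spanning >= 2 distinct WSS values).
#' @param r_linear Pearson threshold for the linear class.
#' @param peak_wss_max Upper bound (Pa) on the location of the maximum for
#'   the peaked class.
#' @param high_wss_min WSS (Pa) above which the peaked class must have
#'   declined.
#' @param decline_fraction Maximum remaining fraction of peak expression
#'   at high WSS.
#' @return data.frame `DoseFit` with one row: `gene`, `pearson_r`,
#'   `slope`, `intercept`, `shape_class`.
#' @export
fit_and_classify <- function(series, r_linear = 0.8, peak_wss_max = 40,
                             high_wss_min = 50, decline_fraction = 0.1) {
  stopifnot(all(c("gene", "wss_pa", "rpkm") %in% colnames(series)))
  if (nrow(series) < 4) stop("need at least 4 dose-response points")
  if (length(unique(series$wss_pa)) < 2) {
    stop("need at least 2 distinct WSS values")
  }
  x <- series$wss_pa
  y <- series$rpkm
  fit1 <- function(cls, r, slope, intercept) {
    data.frame(gene = series$gene[1], pearson_r = r, slope = slope,
               intercept = intercept, shape_class = cls,
               stringsAsFactors = FALSE)
  }
  if (stats::sd(y) == 0) {
    return(fit1("unclassified", NA_real_, 0, y[1]))
  }
  r <- stats::cor(x, y)
  ls <- stats::lm.fit(cbind(1, x), y)$coefficients
  intercept <- unname(ls[1]); slope <- unname(ls[2])

  # 1. peaked decline
  peak_wss <- x[which.max(y)]
  high <- y[x > high_wss_min]
  if (peak_wss < peak_wss_max && length(high) &&
      mean(high) <= decline_fraction * max(y)) {
    return(fit1("peaked_decline", r, slope, intercept))
  }
  # 2. linear increasing
  if (!is.na(r) && r >= r_linear && slope > 0) {
    return(fit1("linear_increasing", r, slope, intercept))
  }
  # 3. plateau
  ord <- order(x)
  n <- length(x)
  base_size <- n %/% 3
  extra <- n %% 3
  sizes <- base_size + (seq_len(3) <= extra)
  grp <- rep(1:3, sizes)
  means <- tapply(y[ord], grp, mean)
  if (means[1] > 0 && means[2] >= 2 * means[1] &&
      abs(means[3] - means[2]) < 0.25 * means[2]) {
    return(fit1("plateau", r, slope, intercept))
  }
  fit1("unclassified", r, slope, intercept)
}

#' Dose-response classification for a set of genes
#'
#' @param genes Character vector of gene ids (typically the candidate
#'   table's intimal genes).
#' @param rpkm RPKM matrix.
#' @param samples Sample table.
#' @inheritParams fit_and_classify
#' @return data.frame with one `DoseFit` row per gene.
#' @export
classify_dose_response <- function(genes, rpkm, samples, r_linear = 0.8,
                                   peak_wss_max = 40, high_wss_min = 50,
                                   decline_fraction = 0.1) {
  do.call(rbind, lapply(genes, function(g) {
    fit_and_classify(assemble_dose_series(g, rpkm, samples), r_linear,
                     peak_wss_max, high_wss_min, decline_fraction)
  }))
}
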