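#' Pipeline configuration
#'
#' A single configuration drives the full analysis. Data come either from
#' files (`counts_path`, `samples_path`, plus optional annotation and
#' ontology inputs) or from the synthetic generator (`simulation`); every
#' stage threshold is a named key defaulting to the study's value so
#' sensitivity analyses are one-line edits.
#'
#' @param counts_path,samples_path Paths to a counts TSV and sample TSV
#'   (ignored when `simulation` is given).
#' @param annotation_path Optional extracellular annotation TSV.
#' @param gmt_path,obo_path Optional gene-set and ontology files for the
#'   enrichment stage.
#' @param simulation Optional [simulation_config()]; when present the
#'   dataset, annotation and gene sets are generated in memory (the
#'   simulation seed is replaced by `seed`).
#' @param output_dir Directory for stage outputs and the report.
#' @param rpkm_min Detectability threshold (group-mean RPKM).
#' @param q_deg DEG threshold on BH q.
#' @param r_threshold,p_threshold Correlation screen thresholds.
#' @param correlation_scale `"rpkm"` or `"log2"` (see [screen_pairs()]).
#' @param min_correlates Strict lower bound on medial correlates for
#'   candidate selection.
#' @param q_enrich Per-query enrichment significance threshold.
#' @param occurrence_min Occurrence rule for pooled terms.
#' @param similarity_cutoff Semantic-similarity cutoff C.
#' @param measure Similarity measure (`"simrel"` or `"lin"`).
#' @param r_linear Pearson threshold for the linear dose-response class.
#' @param seed Root seed; all stage randomness derives from it.
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(counts_path = NULL, samples_path = NULL,
                       annotation_path = NULL, gmt_path = NULL,
                       obo_path = NULL, simulation = NULL,
                       output_dir = tempfile("imcorr_run_"),
                       rpkm_min = 1, q_deg = 0.05, r_threshold = 0.9,
                       p_threshold = 1e-4,
                       correlation_scale = c("rpkm", "log2"),
                       min_correlates = 200, q_enrich = 0.05,
                       occurrence_min = 0.5, similarity_cutoff = 0.90,
                       measure = c("simrel", "lin"), r_linear = 0.8,
                       seed = 1L) {
  correlation_scale <- match.arg(correlation_scale)
  measure <- match.arg(measure)
  stopifnot(rpkm_min >= 0, q_deg > 0, q_deg <= 1, r_threshold >= 0,
            r_threshold <= 1, p_threshold > 0, p_threshold <= 1,
            min_correlates >= 0, q_enrich > 0, q_enrich <= 1,
            occurrence_min >= 0, occurrence_min <= 1,
            similarity_cutoff >= 0, similarity_cutoff <= 1,
            r_linear >= -1, r_linear <= 1)
  if (is.null(simulation) &&
      (is.null(counts_path) || is.null(samples_path))) {
    stop("provide either counts_path + samples_path or a simulation config")
  }
  structure(list(counts_path = counts_path, samples_path = samples_path,
                 annotation_path = annotation_path, gmt_path = gmt_path,
                 obo_path = obo_path, simulation = simulation,
                 output_dir = output_dir, rpkm_min = rpkm_min,
                 q_deg = q_deg, r_threshold = r_threshold,
                 p_threshold = p_threshold,
                 correlation_scale = correlation_scale,
                 min_correlates = min_correlates, q_enrich = q_enrich,
                 occurrence_min = occurrence_min,
                 similarity_cutoff = similarity_cutoff, measure = measure,
                 r_linear = r_linear, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Sum of positive and negative pair counts
#'
#' The report's pair-total statistic is always derived from its parts, so
#' the identity `n_total = n_pos + n_neg` holds by construction.
#'
#' @param n_pos,n_neg Non-negative counts.
#' @return `n_pos + n_neg`.
#' @export
report_totals <- function(n_pos, n_neg) {
  if (any(c(n_pos, n_neg) < 0)) stop("pair counts must be >= 0")
  n_pos + n_neg
}

#' Direction of the flow response of intimal DEGs
#'
#' For each gene in the intimal DEG union, the direction (sign of the
#' log2 fold change) is taken from the intima comparison with the smaller
#' q-value.
#'
#' @param results DE result list from [run_de()].
#' @return Named character vector gene -> "up"/"down".
#' @export
deg_directions <- function(results) {
  ba <- results$intima.BA; bt <- results$intima.BT
  genes <- sort(unique(c(ba$gene[ba$is_deg], bt$gene[bt$is_deg])))
  vapply(genes, function(g) {
    qa <- ba$q_value[ba$gene == g]; qb <- bt$q_value[bt$gene == g]
    qa <- ifelse(length(qa) && !is.na(qa), qa, Inf)
    qb <- ifelse(length(qb) && !is.na(qb), qb, Inf)
    fc <- if (qa <= qb) ba$log2_fc[ba$gene == g] else bt$log2_fc[bt$gene == g]
    if (fc > 0) "up" else "down"
  }, character(1))
}

write_stage_tsv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full pipeline
#'
#' Executes QC, differential expression, the correlation screen, candidate
#' selection, the stratified ontology analysis and dose-response
#' classification, writing every stage table as TSV plus a consolidated
#' JSON report. Identical configuration and seed produce byte-identical
#' reports. The counts in the report (pair totals, DEG counts) are
#' recomputed from the stage files just written, never carried through
#' separately.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a named list mirroring `report.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    gen <- generate_dataset(validate_simulation_config(sim))
    x <- gen$expression; samples <- gen$samples; truth <- gen$truth
    annotation <- truth_annotation(truth, rownames(x$counts))
    gs <- truth_gene_sets(truth, seed = config$seed + 1L)
    gene_sets <- gs$gene_sets; ontology <- gs$ontology
    write_truth(truth, file.path(config$output_dir, "truth.json"))
  } else {
    x <- read_counts(config$counts_path)
    samples <- read_samples(config$samples_path)
    annotation <- if (!is.null(config$annotation_path)) {
      read_extracellular(config$annotation_path)
    }
    gene_sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
    ontology <- if (!is.null(config$obo_path)) read_obo(config$obo_path)
  }
  rpkm <- compute_rpkm(x)

  # ---- qc -----------------------------------------------------------------
  pca <- pca_overview(x, samples)
  write_stage_tsv(pca$coords, config$output_dir, "pca_coordinates")
  marker_summary <- NULL
  if (!is.null(truth)) {
    mk <- truth$tissue_markers
    purity <- marker_purity(rpkm, samples,
                            names(mk)[mk == "intima"],
                            names(mk)[mk == "media"])
    marker_summary <- purity$summary
    write_stage_tsv(purity$per_pair, config$output_dir, "marker_purity")
  }

  # ---- differential expression -------------------------------------------
  de <- run_de(x, samples, rpkm_min = config$rpkm_min,
               q_threshold = config$q_deg)
  for (nm in names(de)) {
    write_stage_tsv(de[[nm]], config$output_dir, paste0("de_", nm))
  }
  calls <- call_degs(de, config$q_deg)

  # ---- correlation screen -------------------------------------------------
  pairs <- screen_pairs(calls$union$intima, calls$union$media, rpkm,
                        samples, config$r_threshold, config$p_threshold,
                        config$correlation_scale)
  pairs_path <- write_stage_tsv(pairs, config$output_dir, "pairs")
  tallies <- count_correlates(pairs)
  write_stage_tsv(tallies, config$output_dir, "correlate_counts")
  directions <- deg_directions(de)
  candidates <- if (!is.null(annotation)) {
    select_candidates(tallies, annotation, directions,
                      config$min_correlates)
  } else {
    tallies[0, , drop = FALSE]
  }
  write_stage_tsv(candidates, config$output_dir, "candidates")

  # ---- ontology analysis --------------------------------------------------
  enrichment <- NULL
  if (!is.null(gene_sets) && !is.null(ontology) && nrow(candidates)) {
    background <- unique(c(
      filter_detectable(rpkm, list(all = samples$sample_id),
                        config$rpkm_min)))
    enrichment <- run_candidate_ontology_analysis(
      candidates, pairs, gene_sets, ontology, background,
      config$q_enrich, config$occurrence_min, config$similarity_cutoff,
      config$measure)
    for (nm in names(enrichment)) {
      write_stage_tsv(enrichment[[nm]]$summary, config$output_dir,
                      paste0("enrichment_summary_", nm))
    }
  }

  # ---- dose response ------------------------------------------------------
  dose <- if (nrow(candidates)) {
    classify_dose_response(candidates$intimal_gene, rpkm, samples,
                           r_linear = config$r_linear)
  } else {
    data.frame(gene = character(0), pearson_r = numeric(0),
               slope = numeric(0), intercept = numeric(0),
               shape_class = character(0), stringsAsFactors = FALSE)
  }
  write_stage_tsv(dose, config$output_dir, "dose_response")

  # ---- report (recomputed from the stage files) ---------------------------
  pairs_back <- utils::read.delim(pairs_path, stringsAsFactors = FALSE)
  n_pos <- sum(pairs_back$sign > 0)
  n_neg <- sum(pairs_back$sign < 0)
  report <- list(
    package_version = as.character(utils::packageVersion("imcorr")),
    seed = config$seed,
    thresholds = config[c("rpkm_min", "q_deg", "r_threshold", "p_threshold",
                          "correlation_scale", "min_correlates", "q_enrich",
                          "occurrence_min", "similarity_cutoff", "measure",
                          "r_linear")],
    deg_counts = calls$counts,
    deg_overlap = as.list(calls$overlap),
    pair_counts = list(n_pos = n_pos, n_neg = n_neg,
                       n_total = report_totals(n_pos, n_neg)),
    n_candidates = nrow(candidates),
    candidates = candidates,
    marker_summary = marker_summary,
    enriched_terms = if (!is.null(enrichment)) {
      lapply(enrichment, function(s) {
        s$summary$term_id[s$summary$flagged]
      })
    },
    dose_classes = if (nrow(dose)) {
      stats::setNames(as.list(dose$shape_class), dose$gene)
    } else list())
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null")
  invisible(report)
}
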