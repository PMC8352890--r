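#' Simulation configuration for synthetic intima/media datasets
#'
#' Defines the 2 tissue x 2 location x 2 condition x n-animal design and the
#' statistical structure the downstream analysis assumes: planted intimal
#' signal genes whose expression follows a wall-shear-stress (WSS)
#' dose-response shape, medial responder genes coupled to them in log space,
#' tissue markers, cross-contamination of media into intima, animal-level
#' biological noise and negative-binomial counting noise.
#'
#' @param n_animals_per_condition Animals per condition (default 2; the
#'   default design therefore yields 16 samples).
#' @param n_background_genes Total number of genes in the dataset. Markers,
#'   signal genes and responders are carved out of this budget; the
#'   remainder are null genes with flat expression.
#' @param n_marker_genes_per_tissue Tissue markers per compartment.
#' @param n_signal_up Intimal signal genes whose expression increases with
#'   WSS. When more than one is requested the last one is given a plateau
#'   shape and the rest are linear, mirroring the observed mix of linear
#'   responders and a single plateauing gene.
#' @param n_signal_down Intimal signal genes with a peaked-decline shape
#'   (maximum at low-to-moderate WSS, near-silent above 50 Pa).
#' @param responders_per_signal Medial responder genes coupled to each
#'   signal gene.
#' @param coupling_strength Log-space slope of responder on signal
#'   expression.
#' @param wss_map Named numeric vector giving mean WSS in pascal for the
#'   four location x condition cells (`BA.sham`, `BT.sham`, `BA.ligated`,
#'   `BT.ligated`). Defaults reproduce the carotid-ligation flow
#'   environment: 10/20 Pa before ligation at the basilar artery/terminus,
#'   rising to 40/130 Pa after ligation.
#' @param biological_cv Standard deviation of the animal-level log-normal
#'   expression multiplier, shared per (gene, animal) so that tissue pairs
#'   from one animal stay coupled.
#' @param nb_dispersion Negative-binomial dispersion of the count noise
#'   (0 gives Poisson counts).
#' @param library_size_mean Target sequencing depth per sample.
#' @param gene_length_range Integer pair: transcript lengths are drawn
#'   uniformly from this range (bp).
#' @param contamination_fraction Fraction of the intimal signal that is
#'   actually medial tissue admixed at microdissection (applied to true
#'   expression before counts are sampled). Media samples are taken as
#'   pure.
#' @param positive_responder_fraction Fraction of each signal gene's
#'   responders coupled with sign +1; the rest couple with sign -1.
#' @param shape_params Optional list overriding default dose-response
#'   parameters; see [response_curve()].
#' @param seed Integer seed; identical configurations produce bit-identical
#'   datasets.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_animals_per_condition = 2,
                              n_background_genes = 12000,
                              n_marker_genes_per_tissue = 3,
                              n_signal_up = 6,
                              n_signal_down = 12,
                              responders_per_signal = 80,
                              coupling_strength = 1,
                              wss_map = c(BA.sham = 10, BT.sham = 20,
                                          BA.ligated = 40, BT.ligated = 130),
                              biological_cv = 0.02,
                              nb_dispersion = 0.002,
                              library_size_mean = 1e7,
                              gene_length_range = c(1000L, 3000L),
                              contamination_fraction = 0.3,
                              positive_responder_fraction = 0.6,
                              shape_params = NULL,
                              seed = 20210809) {
  cfg <- list(n_animals_per_condition = as.integer(n_animals_per_condition),
              n_background_genes = as.integer(n_background_genes),
              n_marker_genes_per_tissue = as.integer(n_marker_genes_per_tissue),
              n_signal_up = as.integer(n_signal_up),
              n_signal_down = as.integer(n_signal_down),
              responders_per_signal = as.integer(responders_per_signal),
              coupling_strength = coupling_strength,
              wss_map = wss_map,
              biological_cv = biological_cv,
              nb_dispersion = nb_dispersion,
              library_size_mean = as.numeric(library_size_mean),
              gene_length_range = as.integer(gene_length_range),
              contamination_fraction = contamination_fraction,
              positive_responder_fraction = positive_responder_fraction,
              shape_params = shape_params,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
}

#' Validate a simulation configuration
#' @param cfg A list as built by [simulation_config()].
#' @return The validated config.
#' @export
validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_animals_per_condition >= 1, n_background_genes >= 1,
              n_marker_genes_per_tissue >= 0, n_signal_up >= 0,
              n_signal_down >= 0, responders_per_signal >= 0,
              biological_cv >= 0, nb_dispersion >= 0,
              library_size_mean > 0,
              length(gene_length_range) == 2,
              gene_length_range[1] > 0,
              gene_length_range[2] >= gene_length_range[1],
              positive_responder_fraction >= 0,
              positive_responder_fraction <= 1)
  })
  if (cfg$contamination_fraction < 0 || cfg$contamination_fraction >= 1) {
    stop("contamination_fraction must lie in [0, 1)")
  }
  cells <- c("BA.sham", "BT.sham", "BA.ligated", "BT.ligated")
  if (!all(cells %in% names(cfg$wss_map))) {
    stop("wss_map must cover all four location x condition cells: ",
         paste(setdiff(cells, names(cfg$wss_map)), collapse = ", "))
  }
  if (any(cfg$wss_map < 0)) stop("WSS values must be >= 0")
  n_special <- 2 * cfg$n_marker_genes_per_tissue + cfg$n_signal_up +
    cfg$n_signal_down +
    (cfg$n_signal_up + cfg$n_signal_down) * cfg$responders_per_signal
  if (n_special > cfg$n_background_genes) {
    stop(sprintf(paste0("gene budget exceeded: markers + signals + ",
                        "responders = %d > n_background_genes = %d"),
                 n_special, cfg$n_background_genes))
  }
  structure(cfg, class = "SimulationConfig")
}

default_shape_params <- function() {
  list(linear = list(intercept = 5, slope = 2),
       plateau = list(intercept = 5, slope = 2, knee = 40),
       peaked_decline = list(amplitude = 200, peak_wss = 20, width = 12,
                             baseline_frac = 0.08))
}

#' Dose-response shapes for planted signal genes
#'
#' Three canonical WSS dose-response shapes:
#' * `linear`: affine increasing, `intercept + slope * wss`;
#' * `plateau`: increases like the linear shape up to `knee` Pa and is
#'   constant above it;
#' * `peaked_decline`: Gaussian bump centred at `peak_wss` (default 20 Pa,
#'   i.e. maximal expression between ~10 and ~30 Pa) on a small baseline,
#'   so that expression above 50 Pa is at most 10% of the maximum.
#'
#' @param shape One of `"linear"`, `"plateau"`, `"peaked_decline"`.
#' @param wss Numeric vector of wall shear stress values (Pa, >= 0).
#' @param params Optional list of shape parameters; defaults as above.
#' @return Expression level (arbitrary RPKM-like units), same length as
#'   `wss`.
#' @export
response_curve <- function(shape, wss, params = NULL) {
  if (any(wss < 0)) stop("wss must be >= 0")
  defaults <- default_shape_params()
  if (!shape %in% names(defaults)) {
    stop("unknown response shape: ", shape)
  }
  p <- utils::modifyList(defaults[[shape]], as.list(params %||% list()))
  switch(shape,
    linear = p$intercept + p$slope * wss,
    plateau = p$intercept + p$slope * pmin(wss, p$knee),
    peaked_decline = p$amplitude *
      (exp(-(wss - p$peak_wss)^2 / (2 * p$width^2)) + p$baseline_frac))
}

default_marker_names <- function(tissue, n) {
  canonical <- list(intima = c("PECAM1", "VWF", "CDH5"),
                    media = c("DES", "ACTA2", "MYH11"))[[tissue]]
  if (n <= length(canonical)) return(canonical[seq_len(n)])
  c(canonical, sprintf("MRK_%s_%02d", toupper(tissue),
                       seq_len(n - length(canonical))))
}

#' Generate a synthetic paired intima/media count dataset
#'
#' Builds true RPKM-scale expression per gene and sample slot, applies
#' animal-level log-normal noise and media-into-intima contamination, then
#' samples negative-binomial read counts whose mean is
#' `true RPKM x gene length (kb) x library size (millions)`.
#'
#' Gene classes: tissue markers (high in one compartment, near-zero in the
#' other), intimal signal genes following their planted dose-response shape
#' at the sample's WSS, medial responders whose true log-expression is
#' `sign x coupling_strength x log(signal expression) + offset`, and null
#' genes with flat expression. Planted true RPKM values are globally
#' rescaled so that computed RPKM comes out on approximately the planted
#' scale.
#'
#' @param config A [simulation_config()].
#' @return List with elements `expression` ([expression_matrix()]),
#'   `samples` (sample table), and `truth` (a `PlantedTruth` list with
#'   `tissue_markers`, `signal_genes`, `responder_map`, `null_genes`).
#' @export
generate_dataset <- function(config) {
  config <- validate_simulation_config(config)
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n_cond <- cfg$n_animals_per_condition
  animals <- c(sprintf("lig%d", seq_len(n_cond)),
               sprintf("sham%d", seq_len(n_cond)))
  conditions <- rep(c("ligated", "sham"), each = n_cond)
  slots <- expand.grid(animal_id = animals, location = c("BA", "BT"),
                       stringsAsFactors = FALSE)
  slots$condition <- conditions[match(slots$animal_id, animals)]
  slots$wss_pa <- unname(cfg$wss_map[paste(slots$location, slots$condition,
                                           sep = ".")])
  n_slots <- nrow(slots)

  samples <- rbind(
    data.frame(tissue = "intima", slots, stringsAsFactors = FALSE),
    data.frame(tissue = "media", slots, stringsAsFactors = FALSE))
  samples$sample_id <- paste(samples$tissue, samples$location,
                             samples$animal_id, sep = "_")
  samples <- samples[, c("sample_id", "animal_id", "tissue", "location",
                         "condition", "wss_pa")]

  # ---- gene classes -------------------------------------------------------
  nm <- cfg$n_marker_genes_per_tissue
  intima_markers <- default_marker_names("intima", nm)
  media_markers <- default_marker_names("media", nm)
  up_shapes <- if (cfg$n_signal_up >= 2) {
    c(rep("linear", cfg$n_signal_up - 1), "plateau")
  } else rep("linear", cfg$n_signal_up)
  signal_genes <- data.frame(
    gene = c(sprintf("SIGUP%02d", seq_len(cfg$n_signal_up)),
             sprintf("SIGDN%02d", seq_len(cfg$n_signal_down))),
    direction = rep(c("up", "down"), c(cfg$n_signal_up, cfg$n_signal_down)),
    response_shape = c(up_shapes, rep("peaked_decline", cfg$n_signal_down)),
    stringsAsFactors = FALSE)

  n_pos <- round(cfg$positive_responder_fraction * cfg$responders_per_signal)
  responder_map <- do.call(rbind, lapply(seq_len(nrow(signal_genes)),
    function(i) {
      if (cfg$responders_per_signal == 0) return(NULL)
      j <- seq_len(cfg$responders_per_signal)
      data.frame(signal_gene = signal_genes$gene[i],
                 responder_gene = sprintf("RSP_%s_%03d",
                                          signal_genes$gene[i], j),
                 sign = ifelse(j <= n_pos, 1L, -1L),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(responder_map)) {
    responder_map <- data.frame(signal_gene = character(0),
                                responder_gene = character(0),
                                sign = integer(0))
  }
  n_special <- 2 * nm + nrow(signal_genes) + nrow(responder_map)
  null_genes <- sprintf("BG%05d", seq_len(cfg$n_background_genes - n_special))
  genes <- c(intima_markers, media_markers, signal_genes$gene,
             responder_map$responder_gene, null_genes)

  lengths_bp <- sample(seq(cfg$gene_length_range[1],
                           cfg$gene_length_range[2]),
                       length(genes), replace = TRUE)
  names(lengths_bp) <- genes

  # ---- true expression per gene x slot, RPKM-like units ------------------
  ng <- length(genes)
  intima_true <- matrix(0, ng, n_slots, dimnames = list(genes, NULL))
  media_true <- matrix(0, ng, n_slots, dimnames = list(genes, NULL))

  marker_level <- function(n) stats::runif(n, 80, 200)
  intima_true[intima_markers, ] <- marker_level(nm)
  media_true[intima_markers, ] <- 0.05
  media_true[media_markers, ] <- marker_level(nm)
  intima_true[media_markers, ] <- 0.05

  shape_of <- stats::setNames(signal_genes$response_shape, signal_genes$gene)
  for (g in signal_genes$gene) {
    intima_true[g, ] <- response_curve(shape_of[g], slots$wss_pa,
                                       cfg$shape_params[[shape_of[g]]])
    media_true[g, ] <- 1
  }
  if (nrow(responder_map)) {
    centers <- exp(stats::runif(nrow(responder_map), log(10), log(100)))
    intima_base <- exp(stats::runif(nrow(responder_map), log(5), log(50)))
    for (i in seq_len(nrow(responder_map))) {
      s <- responder_map$signal_gene[i]
      r <- responder_map$responder_gene[i]
      log_sig <- log(intima_true[s, ])
      lr <- responder_map$sign[i] * cfg$coupling_strength *
        (log_sig - mean(log_sig)) + log(centers[i])
      media_true[r, ] <- exp(lr)
      intima_true[r, ] <- intima_base[i]
    }
  }
  if (length(null_genes)) {
    intima_true[null_genes, ] <- exp(stats::runif(length(null_genes),
                                                  log(2), log(200)))
    media_true[null_genes, ] <- exp(stats::runif(length(null_genes),
                                                 log(2), log(200)))
  }

  # animal-level biological noise, shared per (gene, animal)
  if (cfg$biological_cv > 0) {
    noise <- matrix(exp(stats::rnorm(ng * length(animals), 0,
                                     cfg$biological_cv)),
                    ng, length(animals), dimnames = list(genes, animals))
    mult <- noise[, slots$animal_id, drop = FALSE]
    intima_true <- intima_true * mult
    media_true <- media_true * mult
  }

  # physical admixture of media into the intimal dissection
  f <- cfg$contamination_fraction
  intima_obs <- (1 - f) * intima_true + f * media_true

  # rescale so that sum(rpkm * length_kb) is ~1e6: planted values then read
  # as RPKM after normalization
  len_kb <- lengths_bp / 1000
  w <- mean(c(colSums(intima_obs * len_kb), colSums(media_true * len_kb)))
  intima_obs <- intima_obs * (1e6 / w)
  media_true <- media_true * (1e6 / w)

  # ---- counts -------------------------------------------------------------
  lib_m <- cfg$library_size_mean / 1e6
  mu <- cbind(intima_obs * len_kb * lib_m, media_true * len_kb * lib_m)
  draw <- if (cfg$nb_dispersion > 0) {
    function(m) stats::rnbinom(length(m), mu = m, size = 1 / cfg$nb_dispersion)
  } else {
    function(m) stats::rpois(length(m), m)
  }
  counts <- matrix(draw(mu), nrow = ng,
                   dimnames = list(genes, samples$sample_id))

  truth <- structure(
    list(tissue_markers = c(stats::setNames(rep("intima", nm),
                                            intima_markers),
                            stats::setNames(rep("media", nm),
                                            media_markers)),
         signal_genes = signal_genes,
         responder_map = responder_map,
         null_genes = null_genes),
    class = "PlantedTruth")

  list(expression = expression_matrix(counts, lengths_bp),
       samples = validate_samples(samples),
       truth = truth)
}

#' Extracellular-product annotation for a synthetic dataset
#'
#' Marks the planted signal genes as extracellular (they model secreted
#' signals) and everything else as intracellular.
#'
#' @param truth A `PlantedTruth` object.
#' @param genes Character vector of all gene ids in the dataset.
#' @return data.frame in the [read_extracellular()] schema.
#' @export
truth_annotation <- function(truth, genes) {
  classes <- rep(c("cytokine", "growth factor", "peptidase", "enzyme",
                   "other"),
                 length.out = nrow(truth$signal_genes))
  data.frame(
    gene_id = genes,
    is_extracellular = genes %in% truth$signal_genes$gene,
    product_class = ifelse(genes %in% truth$signal_genes$gene,
                           classes[match(genes, truth$signal_genes$gene)],
                           "other"),
    stringsAsFactors = FALSE)
}

#' Gene sets and a toy ontology matching the planted truth
#'
#' Builds one gene set per (signal direction x responder sign) stratum
#' containing exactly the planted responders of that stratum, plus decoy
#' sets drawn from null genes, and a small is_a DAG in which the four
#' planted terms hang under a common "cell communication" parent. The
#' planted term ids are returned so recovery of the enrichment stage can be
#' checked against ground truth.
#'
#' @param truth A `PlantedTruth` object.
#' @param n_decoy_sets Number of random decoy sets.
#' @param decoy_size_range Integer pair giving decoy set sizes.
#' @param seed Integer seed for decoy sampling.
#' @return List with `gene_sets` (a [gene_set_collection()]), `ontology`
#'   (an [ontology_graph()]), and `planted_terms` (named character vector:
#'   stratum label "up.pos"/"up.neg"/"down.pos"/"down.neg" -> term id).
#' @export
truth_gene_sets <- function(truth, n_decoy_sets = 30,
                            decoy_size_range = c(10, 40), seed = 1L) {
  dir_of <- stats::setNames(truth$signal_genes$direction,
                            truth$signal_genes$gene)
  rm <- truth$responder_map
  strata <- list(
    up.pos = rm$responder_gene[dir_of[rm$signal_gene] == "up" & rm$sign > 0],
    up.neg = rm$responder_gene[dir_of[rm$signal_gene] == "up" & rm$sign < 0],
    down.pos = rm$responder_gene[dir_of[rm$signal_gene] == "down" &
                                   rm$sign > 0],
    down.neg = rm$responder_gene[dir_of[rm$signal_gene] == "down" &
                                   rm$sign < 0])
  strata <- strata[lengths(strata) > 0]
  planted_ids <- stats::setNames(sprintf("SYN:%07d", 10 + seq_along(strata)),
                                 names(strata))
  sets <- stats::setNames(strata, planted_ids)
  descs <- stats::setNames(
    paste("planted medial response module:", names(strata)), planted_ids)

  decoys <- withr::with_seed(seed, {
    lapply(seq_len(n_decoy_sets), function(i) {
      size <- sample(seq(decoy_size_range[1], decoy_size_range[2]), 1)
      sample(truth$null_genes, min(size, length(truth$null_genes)))
    })
  })
  decoy_ids <- sprintf("SYN:%07d", 100 + seq_len(n_decoy_sets))
  sets[decoy_ids] <- decoys
  descs[decoy_ids] <- sprintf("decoy process %02d", seq_len(n_decoy_sets))

  root <- "SYN:0000001"
  comm <- "SYN:0000002"
  house <- "SYN:0000003"
  terms <- data.frame(
    id = c(root, comm, house, planted_ids, decoy_ids),
    name = c("biological_process", "cell communication",
             "cellular process", unname(descs[planted_ids]),
             unname(descs[decoy_ids])),
    namespace = "biological_process",
    stringsAsFactors = FALSE)
  parents <- c(
    stats::setNames(list(character(0), root, root), c(root, comm, house)),
    stats::setNames(rep(list(comm), length(planted_ids)), planted_ids),
    stats::setNames(rep(list(house), length(decoy_ids)), decoy_ids))

  list(gene_sets = gene_set_collection(sets, descs),
       ontology = ontology_graph(terms, parents),
       planted_terms = planted_ids)
}

#' Serialize planted truth to JSON
#' @param truth A `PlantedTruth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$tissue_markers <- as.list(x$tissue_markers)
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read planted truth back from JSON
#' @param path Path written by [write_truth()].
#' @return A `PlantedTruth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$tissue_markers <- unlist(x$tissue_markers)
  x$signal_genes <- as.data.frame(x$signal_genes,
                                  stringsAsFactors = FALSE)
  x$responder_map <- as.data.frame(x$responder_map,
                                   stringsAsFactors = FALSE)
  structure(x, class = "PlantedTruth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
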