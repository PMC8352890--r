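#' Construct an expression matrix
#'
#' Bundles a gene-by-sample matrix of raw read counts with per-gene
#' transcript lengths, the two ingredients needed for RPKM normalization.
#'
#' @param counts Integer matrix (genes x samples) with unique row and column
#'   names. Values must be non-negative whole numbers.
#' @param gene_length_bp Numeric vector of transcript lengths in base pairs,
#'   one per gene, in the same order as `rownames(counts)` (or named).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `counts` (integer matrix) and `gene_length_bp` (named numeric vector).
#' @export
expression_matrix <- function(counts, gene_length_bp) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (any(is.na(counts))) stop("counts contain NA")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for gene '%s' in sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count for gene '%s' in sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (is.null(names(gene_length_bp))) {
    if (length(gene_length_bp) != nrow(counts)) {
      stop("gene_length_bp must have one entry per gene")
    }
    names(gene_length_bp) <- rownames(counts)
  }
  gene_length_bp <- gene_length_bp[rownames(counts)]
  if (any(is.na(gene_length_bp)) || any(gene_length_bp <= 0)) {
    stop("gene lengths must be strictly positive for every gene")
  }
  storage.mode(gene_length_bp) <- "double"

  storage.mode(counts) <- "double"
  structure(list(counts = counts, gene_length_bp = gene_length_bp),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("gene length (bp) range:",
      paste(range(x$gene_length_bp), collapse = " - "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV
#'
#' Expected layout: header row, first column `gene_id`, second column
#' `length_bp`, one further column per sample.
#'
#' @param path Path to a tab-delimited text file.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(colnames(df)[1:2], c("gene_id", "length_bp"))) {
    stop("counts file must start with columns 'gene_id' and 'length_bp'")
  }
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene_id
  expression_matrix(counts, stats::setNames(df$length_bp, df$gene_id))
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, p))` reproduces
#' `x` exactly.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x$counts),
                   length_bp = unname(x$gene_length_bp),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Compute RPKM from raw counts
#'
#' RPKM (reads per kilobase of transcript per million mapped reads) for gene
#' g in sample s is `counts[g, s] / (length_kb[g] * total_counts[s] / 1e6)`.
#' The per-sample total of the loaded matrix serves as the "million mapped
#' reads" denominator.
#'
#' @param x An `ExpressionMatrix`.
#' @return Numeric matrix of RPKM values with the same dimnames as the
#'   count matrix. A value is zero exactly where the count is zero.
#' @export
compute_rpkm <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  lib <- colSums(x$counts)
  if (any(lib <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(x$counts)[lib <= 0], collapse = ", "))
  }
  len_kb <- x$gene_length_bp / 1000
  sweep(x$counts / len_kb, 2, lib / 1e6, "/")
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `animal_id`, `tissue` (intima/media),
#' `location` (BA/BT), `condition` (ligated/sham), `wss_pa` (mean wall shear
#' stress in pascal). Each (animal, tissue, location) combination must be
#' unique and every intima sample must have a media partner from the same
#' animal and location.
#'
#' @param path Path to a tab-delimited file.
#' @return A `data.frame` with factor-free character columns and numeric
#'   `wss_pa`.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_samples(df)
}

#' Validate a sample table
#'
#' @param df A data.frame as described in [read_samples()].
#' @return The validated data.frame (row order preserved).
#' @export
validate_samples <- function(df) {
  needed <- c("sample_id", "animal_id", "tissue", "location", "condition",
              "wss_pa")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop("sample table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample table")
  bad_tissue <- setdiff(unique(df$tissue), c("intima", "media"))
  if (length(bad_tissue)) {
    stop("unknown tissue level(s): ", paste(bad_tissue, collapse = ", "))
  }
  bad_loc <- setdiff(unique(df$location), c("BA", "BT"))
  if (length(bad_loc)) {
    stop("unknown location level(s): ", paste(bad_loc, collapse = ", "))
  }
  bad_cond <- setdiff(unique(df$condition), c("ligated", "sham"))
  if (length(bad_cond)) {
    stop("unknown condition level(s): ", paste(bad_cond, collapse = ", "))
  }
  if (!is.numeric(df$wss_pa) || any(is.na(df$wss_pa)) || any(df$wss_pa < 0)) {
    stop("wss_pa must be numeric and >= 0 for every sample")
  }
  key <- paste(df$animal_id, df$tissue, df$location)
  if (anyDuplicated(key)) {
    stop("(animal, tissue, location) must uniquely identify a sample; ",
         "duplicated: ", key[duplicated(key)][1])
  }
  intima <- df[df$tissue == "intima", ]
  media <- df[df$tissue == "media", ]
  ikey <- paste(intima$animal_id, intima$location, intima$condition)
  mkey <- paste(media$animal_id, media$location, media$condition)
  orphan <- setdiff(ikey, mkey)
  if (length(orphan)) {
    stop("intima sample without media partner in slot: ", orphan[1])
  }
  df
}

#' Write a sample table to TSV
#' @param df Sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an extracellular-product annotation table
#'
#' Tab-delimited with columns `gene_id`, `is_extracellular` (TRUE/FALSE) and
#' `product_class` (one of enzyme, peptidase, growth factor, cytokine,
#' transporter, kinase, other). Each gene may appear only once.
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with one row per annotated gene.
#' @export
read_extracellular <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "is_extracellular", "product_class")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop("annotation missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("gene annotated more than once: ",
         df$gene_id[duplicated(df$gene_id)][1])
  }
  df$is_extracellular <- as.logical(df$is_extracellular)
  if (any(is.na(df$is_extracellular))) {
    stop("is_extracellular must be TRUE/FALSE")
  }
  classes <- c("enzyme", "peptidase", "growth factor", "cytokine",
               "transporter", "kinase", "other")
  bad <- setdiff(unique(df$product_class), classes)
  if (length(bad)) {
    stop("unknown product_class: ", paste(bad, collapse = ", "))
  }
  df
}

#' Write an extracellular annotation table
#' @param df Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extracellular <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
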