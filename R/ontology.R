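#' Read a GMT gene-set file
#'
#' One set per line: term id, description, then member genes, all
#' tab-separated. Empty member lists are rejected.
#'
#' @param path Path to a GMT file.
#' @return A `GeneSetCollection`: named list with `name` (term id ->
#'   description) and `sets` (term id -> character vector of genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate term id in GMT: ", ids[duplicated(ids)][1])
  }
  descs <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "",
                  character(1))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- ids
  empty <- ids[lengths(sets) == 0]
  if (length(empty)) {
    stop("GMT term with empty member set: ", empty[1])
  }
  gene_set_collection(sets, stats::setNames(descs, ids))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param names Optional named character vector of term descriptions.
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, names = NULL) {
  if (is.null(base::names(sets))) stop("sets must be a named list")
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  if (is.null(names)) {
    names <- stats::setNames(base::names(sets), base::names(sets))
  }
  structure(list(sets = sets, name = names[base::names(sets)]),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, median size %d\n",
              length(x$sets), as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param gsc A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  ids <- names(gsc$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, unname(gsc$name[id]), gsc$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct an ontology graph
#'
#' A rooted DAG of terms connected by `is_a` edges (child -> parent).
#' Acyclicity and reachability of a root from every non-root term are
#' enforced.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents Named list: term id -> character vector of parent ids
#'   (empty for roots).
#' @return An `OntologyGraph` object.
#' @export
ontology_graph <- function(terms, parents) {
  stopifnot(is.data.frame(terms),
            all(c("id", "name", "namespace") %in% colnames(terms)))
  if (anyDuplicated(terms$id)) {
    stop("duplicate term id: ", terms$id[duplicated(terms$id)][1])
  }
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  unknown <- setdiff(unlist(parents), terms$id)
  if (length(unknown)) {
    stop("is_a parent not defined as a term: ", unknown[1])
  }
  edges <- data.frame(
    child = rep(names(parents), lengths(parents)),
    parent = unlist(parents, use.names = FALSE),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = terms$id, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) stop("is_a graph contains a cycle")
  roots <- terms$id[lengths(parents) == 0]
  if (!length(roots)) stop("ontology has no root term")
  # every non-root must reach a root along is_a edges
  for (ns in unique(terms$namespace)) {
    ids <- terms$id[terms$namespace == ns]
    ns_roots <- intersect(roots, ids)
    if (!length(ns_roots)) stop("namespace without a root: ", ns)
  }
  reach <- igraph::subcomponent
  obj <- structure(list(terms = terms, parents = parents, graph = g,
                        roots = roots),
                   class = "OntologyGraph")
  unreachable <- setdiff(terms$id, unlist(lapply(roots, function(r) {
    names(igraph::subcomponent(g, r, mode = "in"))
  })))
  if (length(unreachable)) {
    stop("term cannot reach a root: ", unreachable[1])
  }
  obj
}

#' @export
print.OntologyGraph <- function(x, ...) {
  cat(sprintf("OntologyGraph: %d terms, %d is_a edges, root(s): %s\n",
              nrow(x$terms), sum(lengths(x$parents)),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Read an OBO ontology file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `namespace` and `is_a`
#' relations. Obsolete terms and relation types other than `is_a` are
#' ignored. Terms without a namespace inherit the file's
#' `default-namespace`, if any.
#'
#' @param path Path to an OBO file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  default_ns <- sub("^default-namespace: *", "",
                    grep("^default-namespace:", lines, value = TRUE))
  if (!length(default_ns)) default_ns <- NA_character_
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file")
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  for (i in seq_along(starts)) {
    block <- lines[bounds[i]:(bounds[i + 1] - 1L)]
    if (!identical(block[1], "[Term]")) next
    get1 <- function(tag) {
      v <- sub(paste0("^", tag, ": *"), "",
               grep(paste0("^", tag, ":"), block, value = TRUE))
      if (length(v)) v[1] else NA_character_
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) stop("malformed [Term] stanza without id")
    isa <- sub("^is_a: *", "", grep("^is_a:", block, value = TRUE))
    isa <- sub(" *!.*$", "", isa)  # strip trailing "! name" comments
    ids <- c(ids, id)
    nms <- c(nms, get1("name"))
    ns <- get1("namespace")
    nss <- c(nss, if (is.na(ns)) default_ns[1] else ns)
    parents[[id]] <- isa
  }
  if (!length(ids)) stop("OBO file contains no usable [Term] stanzas")
  # parents referencing obsolete/absent terms are dropped
  parents <- lapply(parents, function(p) intersect(p, ids))
  terms <- data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE)
  ontology_graph(terms, parents)
}

#' Write an ontology graph as OBO
#' @param ont An `OntologyGraph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "OntologyGraph"))
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", ont$terms$name[i]),
             paste0("namespace: ", ont$terms$namespace[i]),
             if (length(ont$parents[[id]]))
               paste0("is_a: ", ont$parents[[id]]),
             "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Ancestors of a term (including itself)
#'
#' @param ont An `OntologyGraph`.
#' @param term Term id.
#' @return Character vector of the term and all its is_a ancestors.
#' @export
term_ancestors <- function(ont, term) {
  stopifnot(inherits(ont, "OntologyGraph"))
  if (!term %in% ont$terms$id) stop("term absent from ontology: ", term)
  names(igraph::subcomponent(ont$graph, term, mode = "out"))
}
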