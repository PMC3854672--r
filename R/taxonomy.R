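#' Build a TaxonomyTree from lineage strings
#'
#' Each lineage is a root-to-node path of taxon names separated by `;`
#' (NCBI-style, e.g. `"bacteria;bacilli;bacillales"`). All lineages must
#' share the same root. Nodes are created in order of first appearance, so
#' construction is deterministic.
#'
#' @param lineages character vector of `;`-separated lineage strings.
#' @param ranks optional list of rank vectors matching each lineage
#'   (defaults to empty rank labels).
#' @return a [TaxonomyTree].
#' @examples
#' tax <- taxonomyFromLineages(c("bacteria;bacilli;bacillales",
#'                               "bacteria;clostridia"))
#' lineage(tax, "bacillales")
#' @export
taxonomyFromLineages <- function(lineages, ranks = NULL) {
  parts <- lapply(lineages, function(s) {
    p <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    p[nzchar(p)]
  })
  if (any(lengths(parts) == 0L)) stop("empty lineage string")
  roots <- unique(vapply(parts, `[[`, character(1), 1L))
  if (length(roots) != 1L)
    stop("all lineages must share a single root taxon (found: ",
         paste(roots, collapse = ", "), ")")
  nodes <- character(0); parent <- integer(0); rank <- character(0)
  addNode <- function(name, par, rk) {
    nodes <<- c(nodes, name)
    parent <<- c(parent, par)
    rank <<- c(rank, rk)
    length(nodes)
  }
  for (li in seq_along(parts)) {
    p <- parts[[li]]
    rks <- if (!is.null(ranks)) ranks[[li]] else rep("", length(p))
    parIdx <- NA_integer_
    for (k in seq_along(p)) {
      i <- match(p[k], nodes)
      if (is.na(i)) {
        i <- addNode(p[k], parIdx, rks[k])
      } else if (!identical(parent[i], parIdx)) {
        stop(sprintf("taxon '%s' appears with two different parents", p[k]))
      }
      parIdx <- i
    }
  }
  new("TaxonomyTree", nodes = nodes, parent = parent, rank = rank)
}

#' Read a sequence-to-taxonomy TSV
#'
#' Two tab-separated columns: sequence identifier and lineage string
#' (`root;...;genus`). Lines starting with `#` are skipped; CRLF line ends
#' and trailing whitespace are tolerated.
#'
#' @param path file path.
#' @return list with `taxonomy` (a [TaxonomyTree]) and `taxonMap` (named
#'   character vector: sequence id -> leaf taxon name).
#' @export
readTaxonomyTSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2L
  if (any(bad)) stop("malformed taxonomy line: ", lines[which(bad)[1]])
  ids <- vapply(fields, `[[`, character(1), 1L)
  lin <- vapply(fields, `[[`, character(1), 2L)
  if (anyDuplicated(ids)) stop("duplicate sequence identifier in taxonomy file")
  tree <- taxonomyFromLineages(lin)
  leaf <- vapply(strsplit(lin, ";", fixed = TRUE), function(p) {
    p <- trimws(p); p[nzchar(p)][sum(nzchar(p))]
  }, character(1))
  list(taxonomy = tree, taxonMap = stats::setNames(leaf, ids))
}

#' Write a sequence-to-taxonomy TSV
#' @param taxonMap named character vector (sequence id -> taxon name).
#' @param taxonomyTree the [TaxonomyTree] resolving the taxa.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTaxonomyTSV <- function(taxonMap, taxonomyTree, path) {
  lin <- vapply(taxonMap, function(t)
    paste(lineage(taxonomyTree, t), collapse = ";"), character(1))
  writeLines(paste(names(taxonMap), lin, sep = "\t"), path)
  invisible(path)
}

#' @rdname lineage
#' @export
setMethod("lineage", "TaxonomyTree", function(x, node) {
  i <- match(node, x@nodes)
  if (is.na(i)) stop(sprintf("taxon '%s' is not in the tree", node))
  path <- character(0)
  while (!is.na(i)) {
    path <- c(x@nodes[i], path)
    i <- x@parent[i]
  }
  path
})

#' @rdname taxonDepth
#' @export
setMethod("taxonDepth", "TaxonomyTree", function(x, node)
  length(lineage(x, node)) - 1L)

#' Root of a taxonomy
#' @param x a [TaxonomyTree].
#' @return root node name.
#' @export
taxonomyRoot <- function(x) x@nodes[is.na(x@parent)]

#' All node names of a taxonomy
#' @param x a [TaxonomyTree].
#' @return character vector in creation order.
#' @export
taxonNames <- function(x) x@nodes

#' Direct children of a node
#' @param x a [TaxonomyTree].
#' @param node node name.
#' @return character vector of child names (creation order).
#' @export
taxonChildren <- function(x, node) {
  i <- match(node, x@nodes)
  if (is.na(i)) stop(sprintf("taxon '%s' is not in the tree", node))
  x@nodes[which(x@parent == i)]
}

#' Test taxon membership including descendants
#'
#' `isWithinTaxon(tree, labels, taxon)` returns, for each taxon label, whether
#' the labelled node lies in the subtree rooted at `taxon` (i.e. `taxon` is on
#' the label's lineage).
#'
#' @param x a [TaxonomyTree].
#' @param labels character vector of node names.
#' @param taxon ancestor node name.
#' @return logical vector.
#' @export
isWithinTaxon <- function(x, labels, taxon) {
  vapply(labels, function(l) taxon %in% lineage(x, l), logical(1),
         USE.NAMES = FALSE)
}

setMethod("show", "TaxonomyTree", function(object) {
  cat(sprintf("TaxonomyTree with %d nodes (root: %s)\n",
              length(object@nodes), taxonomyRoot(object)))
  depths <- vapply(object@nodes, function(n) taxonDepth(object, n), integer(1))
  cat(sprintf("  max depth: %d\n", max(depths)))
})
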