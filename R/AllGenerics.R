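#' Lineage of a taxonomy node
#'
#' Ordered path of node names from the root down to (and including) `node`.
#'
#' @param x a [TaxonomyTree] (or an object carrying one).
#' @param node node name.
#' @return character vector, first element the root, last element `node`.
#' @export
setGeneric("lineage", function(x, node) standardGeneric("lineage"))

#' Depth of a taxonomy node (root = 0)
#' @param x a [TaxonomyTree].
#' @param node node name.
#' @return integer depth.
#' @export
setGeneric("taxonDepth", function(x, node) standardGeneric("taxonDepth"))

#' Alignment matrix accessor
#' @param x a [TemplateAlignment].
#' @return character matrix (sequences x columns).
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' Per-sequence taxon labels
#' @param x a [TemplateAlignment].
#' @return named character vector.
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))

#' Taxonomy accessor
#' @param x an object carrying a [TaxonomyTree].
#' @return the [TaxonomyTree].
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' Base-pair accessor
#' @param x a [TemplateAlignment] or [StructureModel].
#' @return two-column integer matrix of paired columns.
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' Block partition accessor
#' @param x an [AlignmentProfile].
#' @return data.frame with columns block, start, end, nConserved.
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))

#' Names of statistics-bearing taxa
#' @param x an [AlignmentProfile] or [StructureDescriptor].
#' @return character vector of taxon names.
#' @export
setGeneric("profileTaxa", function(x) standardGeneric("profileTaxa"))

#' Structural element table
#' @param x a [StructureModel] or [StructureDescriptor].
#' @return data.frame with one row per ordered element.
#' @export
setGeneric("elementTable", function(x) standardGeneric("elementTable"))

#' Gapped row of an aligned query
#' @param x an [AlignedQuery].
#' @return single character string of template width.
#' @export
setGeneric("alignedRow", function(x) standardGeneric("alignedRow"))
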