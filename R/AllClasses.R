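#' @import methods
NULL

#' TaxonomyTree: a rooted taxonomic classification tree
#'
#' A lightweight rooted tree of named taxa (NCBI-style lineages). Nodes are
#' stored in a flat table: `nodes[i]` is the unique node name, `parent[i]` the
#' index of its parent (`NA` for the single root), `rank[i]` a free-text rank
#' label (e.g. `"genus"`). Sequence records reference taxa by name; membership
#' of a taxon includes all sequences labelled with the taxon itself or any of
#' its descendants.
#'
#' @slot nodes character vector of unique node names.
#' @slot parent integer vector of parent indices (`NA` at the root).
#' @slot rank character vector of rank labels (may be `""`).
#'
#' @seealso [taxonomyFromLineages()], [lineage()], [taxonDepth()]
#' @export
setClass("TaxonomyTree",
  representation(nodes = "character", parent = "integer", rank = "character"))

setValidity("TaxonomyTree", function(object) {
  n <- length(object@nodes)
  if (length(object@parent) != n || length(object@rank) != n)
    return("nodes, parent and rank must have equal length")
  if (n == 0L) return("tree must have at least one node (the root)")
  if (anyDuplicated(object@nodes)) return("node names must be unique")
  roots <- which(is.na(object@parent))
  if (length(roots) != 1L) return("tree must have exactly one root")
  ok <- object@parent[!is.na(object@parent)]
  if (any(ok < 1L | ok > n)) return("parent index out of range")
  # every node must reach the root (no cycles, no detached components)
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(object@parent[j])) {
      if (seen[j]) return(sprintf("cycle detected at node '%s'", object@nodes[i]))
      seen[j] <- TRUE
      j <- object@parent[j]
    }
  }
  TRUE
})

#' TemplateAlignment: a gapped template multiple sequence alignment
#'
#' The curated reference alignment into which new sequences are placed. Rows
#' are aligned sequences over the RNA alphabet plus `-` (gap); every row
#' carries a taxon label resolving into the accompanying [TaxonomyTree].
#' An optional set of column base pairs links the alignment to a secondary
#' structure model.
#'
#' On ingest, `T` is normalised to `U`, symbols are uppercased, and `.` gaps
#' become `-`. IUPAC ambiguity codes are retained as literal symbols in the
#' alignment but are counted as gaps by all statistics (conservation and
#' composition enumerate only A, C, G, U).
#'
#' 5'/3'-partial extents are pre-computed: `firstRes`/`lastRes` give, per
#' sequence, the first and last non-gap column; a sequence is 5'-partial at
#' column i when `firstRes > i` and 3'-partial when `lastRes < i`.
#'
#' @slot mat character matrix, rows = sequences (rownames = identifiers),
#'   columns = alignment columns.
#' @slot taxon character vector: per-sequence taxon name.
#' @slot taxonomy a [TaxonomyTree].
#' @slot pairs two-column integer matrix of paired columns (may be empty).
#' @slot firstRes,lastRes integer vectors: first/last non-gap column per row.
#'
#' @seealso [ingestAlignment()], [readTemplateAlignment()]
#' @export
setClass("TemplateAlignment",
  representation(mat = "matrix", taxon = "character",
                 taxonomy = "TaxonomyTree", pairs = "matrix",
                 firstRes = "integer", lastRes = "integer"))

setValidity("TemplateAlignment", function(object) {
  if (!is.character(object@mat)) return("mat must be a character matrix")
  n <- nrow(object@mat)
  if (n == 0L) return("alignment must contain at least one sequence")
  if (is.null(rownames(object@mat))) return("mat must have sequence identifiers as rownames")
  if (anyDuplicated(rownames(object@mat))) return("sequence identifiers must be unique")
  if (length(object@taxon) != n) return("one taxon label per sequence required")
  if (!all(object@taxon %in% object@taxonomy@nodes))
    return("every sequence taxon must be a node of the taxonomy")
  if (length(object@firstRes) != n || length(object@lastRes) != n)
    return("firstRes/lastRes must have one entry per sequence")
  if (any(is.na(object@firstRes)))
    return("all-gap sequences are not allowed")
  if (ncol(object@mat) > 0L && any(colSums(object@mat != "-") == 0L))
    return("every retained column must contain at least one non-gap symbol")
  if (ncol(object@pairs) != 2L) return("pairs must be a two-column matrix")
  if (nrow(object@pairs) > 0L) {
    p <- as.vector(object@pairs)
    if (any(p < 1L | p > ncol(object@mat))) return("pair column out of range")
    if (anyDuplicated(p)) return("a column may participate in at most one base pair")
  }
  TRUE
})

#' AlignmentProfile: per-taxon column and block statistics of a template
#'
#' Holds everything the block aligner consumes: the root-level block
#' partition, and for every qualifying taxon the per-column conservation and
#' nucleotide composition, the per-block taxon-specific conserved column
#' sets, per-sequence and average block scores, and the min/max nucleotide
#' counts per block.
#'
#' @slot ncol number of alignment columns.
#' @slot blocks list of blocks, each `list(block, start, end, conserved)`
#'   with 1-based inclusive column coordinates.
#' @slot taxa named list (one entry per statistics-bearing taxon); each entry
#'   has `nseq`, `conservation` (numeric per column), `composition` (4 x ncol
#'   matrix, rows A/C/G/U), `conservedByBlock` (list of integer vectors),
#'   `blockScores` (numeric per block), `perSeqScores` (matrix sequences x
#'   blocks, NA where the sequence is partial over the block), `minNt`/`maxNt`
#'   (integer per block).
#' @slot taxonomy the [TaxonomyTree] the statistics are stratified by.
#' @slot params the configuration used (block size, conservation cutoff,
#'   composition weight, minimum sequences).
#' @export
setClass("AlignmentProfile",
  representation(ncol = "integer", blocks = "list", taxa = "list",
                 taxonomy = "TaxonomyTree", params = "list"))

setValidity("AlignmentProfile", function(object) {
  if (length(object@blocks) == 0L) return("profile must contain at least one block")
  if (length(object@taxa) == 0L) return("profile must contain at least one taxon")
  if (!all(names(object@taxa) %in% object@taxonomy@nodes))
    return("profile taxa must be taxonomy nodes")
  ends <- vapply(object@blocks, `[[`, numeric(1), "end")
  starts <- vapply(object@blocks, `[[`, numeric(1), "start")
  if (starts[1] != 1L || ends[length(ends)] != object@ncol ||
      (length(starts) > 1L && any(starts[-1] != ends[-length(ends)] + 1L)))
    return("blocks must tile all columns without overlap")
  TRUE
})

#' StructureModel: a column-level RNA secondary structure
#'
#' The nested base-pair skeleton of the template structure, decomposed into
#' an ordered list of structural elements that tile the alignment columns:
#' helix 5'/3' strands (maximal runs of consecutive nested pairs) and
#' single-strand regions (hairpin/internal/multistem loops and terminal
#' tails). Crossing (pseudoknotted) pairs are set aside as tertiary
#' constraints and excluded from the element ordering.
#'
#' @slot ncol number of columns spanned.
#' @slot pairs two-column integer matrix of nested pairs (5' column < 3').
#' @slot tertiary two-column integer matrix of crossing pairs (flagged only).
#' @slot elements ordered list; each element is `list(id, type, partner,
#'   cols)` with `type` one of `"strand5"`, `"strand3"`, `"ss"`, `partner`
#'   the id of the opposing helix strand (NA for single strands), `cols` the
#'   integer columns, and a `role` label for single strands (hairpin,
#'   internal, tail5, tail3).
#' @export
setClass("StructureModel",
  representation(ncol = "integer", pairs = "matrix", tertiary = "matrix",
                 elements = "list"))

setValidity("StructureModel", function(object) {
  cols <- unlist(lapply(object@elements, `[[`, "cols"))
  if (!identical(sort(as.integer(cols)), seq_len(object@ncol)))
    return("elements must tile all columns exactly once")
  TRUE
})

#' StructureDescriptor: constraints derived from a template and its structure
#'
#' The computer-generated descriptor of the template's conserved secondary
#' structure: for the root and for every qualifying taxon, each structural
#' element carries a length histogram (observed frequencies as weights), a
#' mispair-count histogram for helices, a pooled nucleotide-frequency
#' profile, and a conservation summary. A per-section weight-score cutoff
#' bounds the score of an elongating structural model during search.
#'
#' @slot model the underlying [StructureModel].
#' @slot sections named list of sections (`"root"` plus taxon names); each
#'   section is a named list over element ids with entries `lengths` (named
#'   numeric: length -> frequency weight), `mispairs` (helices, on the 5'
#'   strand), `freq` (named numeric over A/C/G/U), `conservation`.
#' @slot cutoffs named numeric: per-section weight-score cutoff.
#' @slot params generation parameters (minimum sequences, canonical pairs).
#' @export
setClass("StructureDescriptor",
  representation(model = "StructureModel", sections = "list",
                 cutoffs = "numeric", params = "list"))

setValidity("StructureDescriptor", function(object) {
  if (!"root" %in% names(object@sections)) return("descriptor must have a root section")
  for (sec in object@sections) {
    for (el in sec) {
      w <- el$lengths
      if (length(w) && abs(sum(w) - 1) > 1e-6)
        return("length histogram weights must sum to 1")
      if (length(w) && (any(w < 0) || any(w > 1)))
        return("weights must be observed frequencies in [0, 1]")
    }
  }
  TRUE
})

#' StructureInstance: descriptor elements located on one query sequence
#'
#' The result of the seed-and-extend structure search: per-element sequence
#' intervals (1-based, inclusive; zero-length elements have end = start - 1),
#' a completeness flag (all elements placed), and the number of exceptions
#' spent on out-of-histogram observations.
#'
#' @slot query the ungapped query sequence (single string).
#' @slot queryId identifier of the query.
#' @slot placements data.frame with columns `id`, `type`, `start`, `end`,
#'   `length`, `exception` (logical), in descriptor element order.
#' @slot complete logical: was every element identified?
#' @slot exceptions integer: exceptions consumed.
#' @slot section descriptor section used.
#' @slot trace character log of the extension rounds.
#' @export
setClass("StructureInstance",
  representation(query = "character", queryId = "character",
                 placements = "data.frame", complete = "logical",
                 exceptions = "integer", section = "character",
                 trace = "character"))

#' AlignedQuery: one query aligned into the template coordinate system
#'
#' @slot id query identifier.
#' @slot row gapped alignment row (single string, template width).
#' @slot colOf integer vector: template column assigned to each query
#'   nucleotide (NA = placed as an insertion, see `insertions`).
#' @slot engine `"block"` or `"structure"`.
#' @slot taxon taxon whose statistics anchored the alignment.
#' @slot blocks data.frame log: per aligned block its taxon, stage,
#'   threshold and subsequence score (block engine only).
#' @slot insertions data.frame: query nucleotides that exceed template gap
#'   capacity, annotated by the column they follow.
#' @export
setClass("AlignedQuery",
  representation(id = "character", row = "character", colOf = "integer",
                 engine = "character", taxon = "character",
                 blocks = "data.frame", insertions = "data.frame"))
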