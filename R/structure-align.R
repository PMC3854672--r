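#' Split an identified sequence into structural-element fragments
#'
#' Requires a complete [StructureInstance]: every descriptor element must
#' have been identified (a partial model cannot be aligned element by
#' element, so partial instances raise an error).
#'
#' @param instance a [StructureInstance].
#' @return data.frame with columns `id`, `type`, `start`, `end`, `length`,
#'   one row per descriptor element; fragments tile the whole sequence.
#' @export
fragmentSequence <- function(instance) {
  if (!instance@complete)
    stop("partial-model error: structure-based alignment requires a ",
         "complete structural model")
  instance@placements[, c("id", "type", "start", "end", "length")]
}

elementResidues <- function(mat, rowIdx, cols) {
  r <- mat[rowIdx, cols]
  r[r != GAP]
}

fragmentResidues <- function(q, frag) {
  if (frag$length == 0L) return(character(0))
  q[frag$start:frag$end]
}

# identity between two residue vectors; helix strands anchor at the
# loop-proximal end (right end for 5' strands, left end for 3' strands),
# single strands left-align.
fragmentIdentity <- function(a, b, type) {
  la <- length(a); lb <- length(b)
  if (la == 0L && lb == 0L) return(1)
  k <- min(la, lb)
  if (k == 0L) return(0)
  if (type == "strand5") {
    matches <- sum(a[la - seq_len(k) + 1L] == b[lb - seq_len(k) + 1L])
  } else {
    matches <- sum(a[seq_len(k)] == b[seq_len(k)])
  }
  matches / max(la, lb)
}

#' Choose the template sequence most similar to a fragmented query
#'
#' Similarity to each template sequence is the mean over elements of an
#' equally weighted combination of fragment-length agreement
#' (min/max of the two lengths) and fragment sequence identity. Ties go to
#' the first sequence in template order.
#'
#' @param instance a complete [StructureInstance].
#' @param template the [TemplateAlignment].
#' @param descriptor the [StructureDescriptor] (supplies the element
#'   decomposition shared by template and query).
#' @param lengthWeight weight of length agreement (identity gets
#'   `1 - lengthWeight`; default 0.5).
#' @return sequence identifier of the chosen reference.
#' @export
chooseReference <- function(instance, template, descriptor,
                            lengthWeight = 0.5) {
  if (nSequences(template) == 0L) stop("empty template")
  frags <- fragmentSequence(instance)
  q <- splitChars(instance@query)
  els <- descriptor@model@elements
  mat <- alignmentMatrix(template)
  sims <- vapply(seq_len(nSequences(template)), function(ri) {
    per <- vapply(seq_along(els), function(k) {
      fr <- frags[k, ]
      a <- fragmentResidues(q, fr)
      b <- elementResidues(mat, ri, els[[k]]$cols)
      la <- length(a); lb <- length(b)
      lenAg <- if (la == 0L && lb == 0L) 1 else min(la, lb) / max(la, lb)
      lengthWeight * lenAg +
        (1 - lengthWeight) * fragmentIdentity(a, b, fr$type)
    }, numeric(1))
    mean(per)
  }, numeric(1))
  sequenceIds(template)[which.max(sims)]
}

#' Align a structurally identified query into the template
#'
#' Helix fragments are juxtaposed structurally, regardless of sequence
#' conservation: each strand is anchored at its closing (loop-proximal)
#' pair and occupies that many loop-proximal columns of its element, so
#' length mismatches place gaps at the loop-distal end and opposed residues
#' always sit in paired columns. Single-strand fragments are placed by an
#' order-preserving dynamic program that maximizes, per residue, a
#' reference-occupancy bonus plus the template composition value of the
#' residue in its column, so conservation drives the placement of unpaired
#' regions. Residues exceeding an element's column capacity are reported as
#' insertion annotations; the template is never widened.
#'
#' @param instance a complete [StructureInstance] for the query.
#' @param template the [TemplateAlignment].
#' @param descriptor the [StructureDescriptor].
#' @param reference reference sequence identifier (chosen by
#'   [chooseReference()] when NULL).
#' @return an [AlignedQuery] with engine `"structure"`.
#' @export
alignByStructure <- function(instance, template, descriptor,
                             reference = NULL) {
  if (is.null(reference))
    reference <- chooseReference(instance, template, descriptor)
  frags <- fragmentSequence(instance)
  q <- splitChars(instance@query)
  L <- length(q)
  els <- descriptor@model@elements
  mat <- alignmentMatrix(template)
  comp <- compositionValues(template, taxonomyRoot(taxonomy(template)),
                            strict = FALSE)
  refRow <- mat[reference, ]
  colAssign <- rep(NA_integer_, L)
  insRows <- list()
  for (k in seq_along(els)) {
    fr <- frags[k, ]
    if (fr$length == 0L) next
    cols <- els[[k]]$cols
    idx <- fr$start:fr$end
    nc <- length(cols)
    if (els[[k]]$type == "strand5") {
      nPlace <- min(fr$length, nc)
      # loop-proximal = right end of the 5' strand
      colAssign[idx[fr$length - seq_len(nPlace) + 1L]] <-
        cols[nc - seq_len(nPlace) + 1L]
      extra <- if (fr$length > nc) idx[seq_len(fr$length - nc)] else integer(0)
    } else if (els[[k]]$type == "strand3") {
      nPlace <- min(fr$length, nc)
      colAssign[idx[seq_len(nPlace)]] <- cols[seq_len(nPlace)]
      extra <- if (fr$length > nc) idx[nc + seq_len(fr$length - nc)] else integer(0)
    } else {
      qIdx <- match(q[idx], NUCS)
      refOcc <- as.numeric(refRow[cols] != GAP)
      scoreMat <- matrix(rep(2 * refOcc, each = length(idx)),
                         nrow = length(idx))
      ok <- !is.na(qIdx)
      scoreMat[ok, ] <- scoreMat[ok, , drop = FALSE] +
        comp[qIdx[ok], cols, drop = FALSE]
      assign <- placeResiduesDP(length(idx), nc, scoreMat)
      placedIn <- !is.na(assign)
      colAssign[idx[placedIn]] <- cols[assign[placedIn]]
      extra <- idx[!placedIn]
    }
    if (length(extra)) {
      afterCol <- vapply(extra, function(i) {
        prev <- colAssign[seq_len(i - 1L)]
        prev <- prev[!is.na(prev)]
        if (length(prev)) max(prev) else 0L
      }, integer(1))
      insRows[[length(insRows) + 1L]] <-
        data.frame(position = extra, afterColumn = afterCol,
                   residue = q[extra])
    }
  }
  insertions <- if (length(insRows)) do.call(rbind, insRows) else
    data.frame(position = integer(0), afterColumn = integer(0),
               residue = character(0))
  new("AlignedQuery", id = instance@queryId,
      row = buildRow(q, colAssign, alignmentWidth(template)),
      colOf = colAssign, engine = "structure", taxon = instance@section,
      blocks = data.frame(block = integer(0), taxon = character(0),
                          stage = character(0), threshold = numeric(0),
                          score = numeric(0), deletions = integer(0)),
      insertions = insertions)
}

#' End-to-end structure-based alignment of one query
#'
#' Runs the structure search ([findStructure()]) with the section matching
#' the taxon hint (falling back to the root section), then the
#' element-by-element alignment. Queries whose structural model is partial
#' raise an error unless a block-engine `fallbackProfile` is supplied, in
#' which case they are aligned with [alignToProfile()] instead.
#'
#' @param query ungapped sequence (single string).
#' @param template the [TemplateAlignment].
#' @param descriptor the [StructureDescriptor].
#' @param hint optional taxon name selecting a descriptor section.
#' @param maxExceptions exception budget for the search (default 0).
#' @param fallbackProfile optional [AlignmentProfile] used when the model
#'   is partial (default NULL: partial models are an error).
#' @param id query identifier.
#' @return an [AlignedQuery].
#' @export
alignWithStructure <- function(query, template, descriptor, hint = NULL,
                               maxExceptions = 0L, fallbackProfile = NULL,
                               id = "query") {
  section <- if (!is.null(hint) && hint %in% names(descriptor@sections))
    hint else "root"
  inst <- findStructure(query, descriptor, section, maxExceptions,
                        queryId = id)
  if (!inst@complete) {
    if (!is.null(fallbackProfile))
      return(alignToProfile(query, fallbackProfile, hint = hint, id = id))
    stop("partial-model error: no complete structural model for '", id,
         "'; supply fallbackProfile to align it with the block engine")
  }
  alignByStructure(inst, template, descriptor)
}
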