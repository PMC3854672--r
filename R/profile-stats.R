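#' Column conservation value within a taxon
#'
#' The conservation value of column i for a taxonomic node is the number of
#' the node's sequences bearing a nucleotide (A/C/G/U) at i divided by the
#' number of its sequences counted at i. Sequences that are 5'-partial after
#' or 3'-partial before the column (their first non-gap column lies beyond i,
#' or their last lies before it) are excluded from both numerator and
#' denominator, so truncated sequences do not depress conservation at the
#' alignment ends. IUPAC ambiguity codes do not count as nucleotides.
#'
#' @param x a [TemplateAlignment].
#' @param taxon taxon name (membership includes descendants).
#' @param columns integer column indices (default: all columns).
#' @return numeric vector of fractions in `[0, 1]`. Columns where every
#'   sequence is excluded are 0, with a warning.
#' @examples
#' fx <- toyProfileTemplate()
#' conservationValue(fx$template, "bacilli", 28)  # 6/7
#' @export
conservationValue <- function(x, taxon, columns = seq_len(alignmentWidth(x))) {
  rows <- taxonMembers(x, taxon)
  if (!length(rows)) stop(sprintf("taxon '%s' has no sequences", taxon))
  sub <- x@mat[rows, columns, drop = FALSE]
  isN <- matrix(isNuc(sub), nrow = length(rows))
  counted <- outer(x@firstRes[rows], columns, `<=`) &
             outer(x@lastRes[rows], columns, `>=`)
  denom <- colSums(counted)
  num <- colSums(isN & counted)
  if (any(denom == 0L)) {
    warning("column(s) with no counted sequences; conservation set to 0")
  }
  ifelse(denom == 0L, 0, num / denom)
}

#' Nucleotide composition values within a taxon
#'
#' For each requested column, the fraction of the taxon's nucleotide-bearing
#' sequences that carry each of A, C, G, U. Fractions sum to 1 wherever a
#' nucleotide is present.
#'
#' @inheritParams conservationValue
#' @param strict error (rather than return zero columns) when a requested
#'   column has no nucleotide within the taxon. Default TRUE.
#' @return numeric matrix with rows A, C, G, U and one column per requested
#'   column.
#' @examples
#' fx <- toyProfileTemplate()
#' compositionValues(fx$template, "bacillales", 10)  # C 1/3, G 2/3
#' @export
compositionValues <- function(x, taxon, columns = seq_len(alignmentWidth(x)),
                              strict = TRUE) {
  rows <- taxonMembers(x, taxon)
  if (!length(rows)) stop(sprintf("taxon '%s' has no sequences", taxon))
  sub <- x@mat[rows, columns, drop = FALSE]
  counts <- vapply(NUCS, function(p) colSums(sub == p),
                   numeric(length(columns)))
  counts <- matrix(counts, ncol = length(NUCS),
                   dimnames = list(NULL, NUCS))
  tot <- rowSums(counts)
  if (strict && any(tot == 0))
    stop("empty column within taxon '", taxon, "': column(s) ",
         paste(columns[tot == 0], collapse = ", "))
  out <- t(counts / ifelse(tot == 0, 1, tot))
  dimnames(out) <- list(NUCS, columns)
  out
}

#' Partition alignment columns into blocks of conserved columns
#'
#' Conservation is computed at the root taxon; columns with conservation
#' strictly greater than `threshold` are highly conserved. Blocks are runs of
#' columns each containing `conservedPerBlock` highly conserved columns (the
#' last block may have fewer). A block extends from the column after the
#' previous block's last conserved column through its own last conserved
#' column; the final block extends to the alignment end, so blocks tile the
#' alignment exactly.
#'
#' @param x a [TemplateAlignment].
#' @param conservedPerBlock conserved columns per block (default 16; the
#'   figure-scale toys use 5).
#' @param threshold conservation cutoff; strictly-greater comparison
#'   (default 0.8).
#' @return data.frame with columns `block`, `start`, `end`, `nConserved` and
#'   a list column `conserved` of the conserved column indices.
#' @export
partitionBlocks <- function(x, conservedPerBlock = 16L, threshold = 0.8) {
  stopifnot(conservedPerBlock >= 1L)
  cons <- conservationValue(x, taxonomyRoot(x@taxonomy))
  consCols <- which(cons > threshold)
  if (!length(consCols))
    stop("alignment is un-partitionable: no highly conserved columns at ",
         "threshold ", threshold)
  grp <- (seq_along(consCols) - 1L) %/% conservedPerBlock
  sets <- split(consCols, grp)
  nb <- length(sets)
  ends <- vapply(sets, max, integer(1))
  ends[nb] <- alignmentWidth(x)
  starts <- c(1L, vapply(sets[-nb], max, integer(1)) + 1L)
  data.frame(block = seq_len(nb), start = as.integer(starts),
             end = as.integer(ends), nConserved = lengths(sets),
             conserved = I(unname(sets)), row.names = NULL)
}

#' Score of a subsequence placed on a block's conserved columns
#'
#' The block score combines conservation and composition: with Y the block's
#' conserved columns (within the scoring taxon) and Z those of them where the
#' subsequence has a nucleotide,
#' \deqn{SC(b) = \frac{\sum_{i \in Z} C_i}{|Y|} +
#'       w \frac{\sum_{j \in Z} N_j(S_j)}{|Z|}}
#' where \eqn{C_i} is the taxon's conservation at column i, \eqn{N_j(S_j)}
#' the taxon's composition value for the subsequence's nucleotide at column
#' j, and w the composition weight (0.8 by default, determined
#' heuristically). The score lies in `[0, 1 + w]`; 1.8 is the maximum with
#' the default weight. An empty subsequence (|Z| = 0) scores 0, with a
#' warning.
#'
#' @param conservation numeric: taxon conservation at each of the block's
#'   conserved columns (length |Y|).
#' @param composition numeric, same length: the taxon composition value of
#'   the subsequence's nucleotide at each conserved column, `NA` where the
#'   subsequence has no nucleotide there.
#' @param weight composition weight (default 0.8).
#' @return numeric score.
#' @examples
#' subsequenceBlockScore(rep(1, 5), rep(1, 5))            # 1.8, the maximum
#' subsequenceBlockScore(c(6/7, 1, 1, 1, 1), c(1, 4/7, 1, 1, 1))
#' @export
subsequenceBlockScore <- function(conservation, composition, weight = 0.8) {
  stopifnot(length(conservation) == length(composition))
  z <- !is.na(composition)
  if (!any(z)) {
    warning("empty subsequence over block; score defined as 0")
    return(0)
  }
  sum(conservation[z]) / length(conservation) +
    weight * sum(composition[z]) / sum(z)
}

#' Build per-taxon alignment statistics (an AlignmentProfile)
#'
#' Generates, for every taxon holding at least `minSequences` template
#' sequences (the root is always included), the per-column conservation and
#' composition, and per block: the taxon-specific conserved column set
#' (recomputed with the same strictly-greater threshold within the root
#' block's column interval, so taxa may differ in how many columns a block
#' conserves), per-sequence subsequence scores, their average, and the
#' minimum/maximum nucleotide count over the block. Sequences that are
#' partial over a block's conserved span are excluded from that block's
#' average.
#'
#' @param x a [TemplateAlignment].
#' @param blockSize conserved columns per block (default 16).
#' @param minSequences minimum sequences for a taxon to receive statistics
#'   (default 5).
#' @param threshold conservation cutoff (default 0.8, strict).
#' @param weight composition weight in the block score (default 0.8).
#' @return an [AlignmentProfile].
#' @export
buildProfile <- function(x, blockSize = 16L, minSequences = 5L,
                         threshold = 0.8, weight = 0.8) {
  blocksDf <- partitionBlocks(x, blockSize, threshold)
  blocks <- lapply(seq_len(nrow(blocksDf)), function(i)
    list(block = i, start = blocksDf$start[i], end = blocksDf$end[i],
         conserved = blocksDf$conserved[[i]]))
  tree <- x@taxonomy
  counts <- vapply(tree@nodes, function(t) length(taxonMembers(x, t)),
                   integer(1))
  keep <- tree@nodes[counts >= minSequences]
  keep <- union(taxonomyRoot(tree), keep)
  taxa <- lapply(keep, function(t)
    taxonStats(x, t, blocks, threshold, weight))
  names(taxa) <- keep
  new("AlignmentProfile", ncol = alignmentWidth(x), blocks = blocks,
      taxa = taxa, taxonomy = tree,
      params = list(blockSize = as.integer(blockSize),
                    minSequences = as.integer(minSequences),
                    threshold = threshold, weight = weight))
}

# statistics for one taxon over the root-defined blocks
taxonStats <- function(x, taxon, blocks, threshold, weight) {
  rows <- taxonMembers(x, taxon)
  cons <- conservationValue(x, taxon)
  comp <- compositionValues(x, taxon, strict = FALSE)
  sub <- x@mat[rows, , drop = FALSE]
  isN <- matrix(isNuc(sub), nrow = length(rows))
  nb <- length(blocks)
  conservedByBlock <- vector("list", nb)
  blockScores <- numeric(nb)
  perSeq <- matrix(NA_real_, length(rows), nb,
                   dimnames = list(rownames(sub), NULL))
  minNt <- integer(nb); maxNt <- integer(nb)
  for (b in seq_len(nb)) {
    itv <- blocks[[b]]$start:blocks[[b]]$end
    Y <- itv[cons[itv] > threshold]
    conservedByBlock[[b]] <- Y
    ntCount <- rowSums(isN[, itv, drop = FALSE])
    minNt[b] <- as.integer(min(ntCount)); maxNt[b] <- as.integer(max(ntCount))
    if (!length(Y)) { blockScores[b] <- 0; next }
    # exclude sequences partial over the block's conserved span
    included <- x@firstRes[rows] <= min(Y) & x@lastRes[rows] >= max(Y)
    for (si in seq_along(rows)) {
      if (!included[si]) next
      nts <- sub[si, Y]
      compVals <- ifelse(isNuc(nts), comp[cbind(match(nts, NUCS), Y)], NA)
      perSeq[si, b] <- if (all(is.na(compVals))) 0 else
        subsequenceBlockScore(cons[Y], compVals, weight)
    }
    blockScores[b] <- mean(perSeq[included, b])
  }
  list(nseq = length(rows), conservation = cons, composition = comp,
       conservedByBlock = conservedByBlock, blockScores = blockScores,
       perSeqScores = perSeq, minNt = minNt, maxNt = maxNt)
}

#' @rdname blockTable
#' @export
setMethod("blockTable", "AlignmentProfile", function(x) {
  data.frame(block = vapply(x@blocks, `[[`, numeric(1), "block"),
             start = vapply(x@blocks, `[[`, numeric(1), "start"),
             end = vapply(x@blocks, `[[`, numeric(1), "end"),
             nConserved = vapply(x@blocks, function(b)
               length(b$conserved), integer(1)))
})

#' @rdname profileTaxa
#' @export
setMethod("profileTaxa", "AlignmentProfile", function(x) names(x@taxa))

#' @rdname taxonomy
#' @export
setMethod("taxonomy", "AlignmentProfile", function(x) x@taxonomy)

#' Per-block average scores of a taxon
#' @param x an [AlignmentProfile].
#' @param taxon taxon name.
#' @return numeric vector, one average score per block.
#' @export
blockScores <- function(x, taxon) {
  st <- x@taxa[[taxon]]
  if (is.null(st)) stop(sprintf("no statistics for taxon '%s'", taxon))
  st$blockScores
}

setMethod("show", "AlignmentProfile", function(object) {
  cat(sprintf("AlignmentProfile: %d columns, %d blocks, %d taxa\n",
              object@ncol, length(object@blocks), length(object@taxa)))
  cat("  taxa:", paste(names(object@taxa), collapse = ", "), "\n")
  cat(sprintf("  block size %d, conservation cutoff > %.2f, weight %.2f\n",
              object@params$blockSize, object@params$threshold,
              object@params$weight))
})

## ---- JSON serialization -------------------------------------------------

#' Serialize / restore an AlignmentProfile as versioned JSON
#'
#' @param x an [AlignmentProfile].
#' @param path file path.
#' @return `writeProfileJSON` returns `path` invisibly; `readProfileJSON`
#'   returns the restored [AlignmentProfile].
#' @export
writeProfileJSON <- function(x, path) {
  obj <- list(
    format = "tralign-profile", version = 1L,
    ncol = x@ncol, params = x@params,
    taxonomy = list(nodes = x@taxonomy@nodes, parent = x@taxonomy@parent,
                    rank = x@taxonomy@rank),
    blocks = lapply(x@blocks, function(b)
      list(block = b$block, start = b$start, end = b$end,
           conserved = b$conserved)),
    taxa = lapply(x@taxa, function(st) list(
      nseq = st$nseq, conservation = st$conservation,
      composition = st$composition,
      conservedByBlock = st$conservedByBlock,
      blockScores = st$blockScores,
      perSeqScores = st$perSeqScores,
      seqIds = rownames(st$perSeqScores),
      minNt = st$minNt, maxNt = st$maxNt)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname writeProfileJSON
#' @export
readProfileJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tralign-profile"))
    stop("not a tralign profile JSON file")
  tree <- new("TaxonomyTree", nodes = obj$taxonomy$nodes,
              parent = as.integer(obj$taxonomy$parent),
              rank = as.character(obj$taxonomy$rank))
  blocks <- lapply(seq_len(nrow(obj$blocks)), function(i)
    list(block = obj$blocks$block[i], start = obj$blocks$start[i],
         end = obj$blocks$end[i],
         conserved = as.integer(obj$blocks$conserved[[i]])))
  taxa <- lapply(obj$taxa, function(st) {
    comp <- st$composition
    rownames(comp) <- NUCS
    ps <- st$perSeqScores
    if (is.null(dim(ps))) ps <- matrix(ps, nrow = st$nseq)
    rownames(ps) <- st$seqIds
    list(nseq = st$nseq, conservation = st$conservation, composition = comp,
         conservedByBlock = lapply(st$conservedByBlock, as.integer),
         blockScores = st$blockScores, perSeqScores = ps,
         minNt = as.integer(st$minNt), maxNt = as.integer(st$maxNt))
  })
  params <- obj$params
  params$blockSize <- as.integer(params$blockSize)
  params$minSequences <- as.integer(params$minSequences)
  new("AlignmentProfile", ncol = as.integer(obj$ncol), blocks = blocks,
      taxa = taxa, taxonomy = tree, params = params)
}
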