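rowPair <- function(aln, i) {
  if (is.character(aln) && !is.matrix(aln))
    do.call(rbind, lapply(aln, splitChars))
  else aln
}

asMatrixAln <- function(aln) {
  if (is(aln, "TemplateAlignment")) return(alignmentMatrix(aln))
  if (is.matrix(aln)) return(aln)
  if (is.character(aln)) {
    m <- do.call(rbind, lapply(aln, splitChars))
    rownames(m) <- names(aln)
    return(m)
  }
  stop("unsupported alignment representation")
}

#' Pairwise sequence identity between two aligned rows
#'
#' The co-occupancy ratio `|B| / |E|`: B the columns where both sequences
#' have a nucleotide, E the columns where either does (columns gapped in
#' both are ignored entirely). `method = "matched"` is the residue-identity
#' refinement: only columns of B whose two nucleotides are identical are
#' counted in the numerator. The co-occupancy form is the verbatim
#' definition and the default; identity binning of diverged sequence pairs
#' (e.g. "50-60% identity") is only meaningful with the matched variant,
#' so both are exposed.
#'
#' @param aln a [TemplateAlignment], character matrix, or named character
#'   vector of equal-length gapped rows.
#' @param i,j row indices or identifiers.
#' @param method `"occupancy"` (default) or `"matched"`.
#' @return fraction in `[0, 1]`.
#' @export
pairwiseIdentity <- function(aln, i, j, method = c("occupancy", "matched")) {
  method <- match.arg(method)
  m <- asMatrixAln(aln)
  a <- m[i, ]; b <- m[j, ]
  an <- a != GAP; bn <- b != GAP
  E <- an | bn
  if (!any(E)) stop("undefined pair: no column holds a nucleotide from either sequence")
  B <- an & bn
  num <- if (method == "occupancy") sum(B) else sum(B & a == b)
  num / sum(E)
}

# residue index of each column (0 where gapped)
residueIndex <- function(chars) {
  nz <- chars != GAP
  idx <- integer(length(chars))
  idx[nz] <- seq_len(sum(nz))
  idx
}

#' Pairwise alignment accuracy against a reference alignment
#'
#' A nucleotide of sequence i "stacks" with whatever occupies its column in
#' sequence j: a specific nucleotide of j, or a gap. Accuracy is
#' `|S| / |E|`, with E the reference columns holding a nucleotide from
#' either sequence and S those whose stack is reproduced identically in
#' the test alignment (a nucleotide stacked against a gap must again stack
#' against a gap, and a nucleotide stacked with nucleotide k of the partner
#' must again stack with exactly nucleotide k). Both alignments must
#' contain the two sequences with identical degapped content.
#'
#' @param test test alignment (same accepted types as
#'   [pairwiseIdentity()]).
#' @param reference reference (correct) alignment.
#' @param i,j row identifiers present in both alignments.
#' @return fraction in `[0, 1]`; 1 when `test` and `reference` agree on
#'   the pair.
#' @export
pairwiseAccuracy <- function(test, reference, i, j) {
  tm <- asMatrixAln(test); rm <- asMatrixAln(reference)
  ta <- tm[i, ]; tb <- tm[j, ]
  ra <- rm[i, ]; rb <- rm[j, ]
  if (!identical(ra[ra != GAP], ta[ta != GAP]) ||
      !identical(rb[rb != GAP], tb[tb != GAP]))
    stop("integrity error: degapped sequences differ between alignments")
  riA <- residueIndex(ra); riB <- residueIndex(rb)
  tiA <- residueIndex(ta); tiB <- residueIndex(tb)
  # test stack partner of each residue of A: residue index of B in the same
  # column (0 = stacked against a gap)
  partnerA_test <- integer(max(tiA))
  partnerA_test[tiA[tiA > 0]] <- tiB[tiA > 0]
  partnerB_test <- integer(max(tiB))
  partnerB_test[tiB[tiB > 0]] <- tiA[tiB > 0]
  E <- which(ra != GAP | rb != GAP)
  S <- 0L
  for (col in E) {
    a <- riA[col]; b <- riB[col]
    okA <- if (a > 0L) partnerA_test[a] == b else TRUE
    okB <- if (b > 0L) partnerB_test[b] == a else TRUE
    if (okA && okB) S <- S + 1L
  }
  S / length(E)
}

#' Mean pairwise accuracy binned by reference identity
#'
#' Every unordered sequence pair is assigned to an identity bin by its
#' pairwise identity in the reference alignment; the mean accuracy
#' ([pairwiseAccuracy()]) is reported per bin. Bins are left-closed,
#' right-open, except the last which is closed; pairs below the first edge
#' are dropped, and empty bins are absent from the result rather than
#' reported as zero.
#'
#' @param test test alignment.
#' @param reference reference alignment (rows matched by identifier).
#' @param bins increasing numeric bin edges (default
#'   `c(0.5, 0.6, 0.7, 0.8, 0.9, 1)`).
#' @param method identity method passed to [pairwiseIdentity()].
#' @return data.frame with columns `bin` (label), `lower`, `upper`,
#'   `nPairs`, `meanAccuracy`.
#' @export
accuracyTable <- function(test, reference, bins = c(0.5, 0.6, 0.7, 0.8, 0.9, 1),
                          method = c("occupancy", "matched")) {
  method <- match.arg(method)
  tm <- asMatrixAln(test); rm <- asMatrixAln(reference)
  ids <- intersect(rownames(tm), rownames(rm))
  if (length(ids) < 2L) stop("need at least two shared sequences")
  combs <- utils::combn(ids, 2L)
  psi <- numeric(ncol(combs)); acc <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    psi[k] <- pairwiseIdentity(rm, combs[1, k], combs[2, k], method)
    acc[k] <- pairwiseAccuracy(tm, rm, combs[1, k], combs[2, k])
  }
  nb <- length(bins) - 1L
  rows <- list()
  for (b in seq_len(nb)) {
    inBin <- psi >= bins[b] & (psi < bins[b + 1L] |
                               (b == nb & psi <= bins[b + 1L]))
    if (!any(inBin)) next
    rows[[length(rows) + 1L]] <- data.frame(
      bin = sprintf("%g-%g%%", 100 * bins[b], 100 * bins[b + 1L]),
      lower = bins[b], upper = bins[b + 1L],
      nPairs = sum(inBin), meanAccuracy = mean(acc[inBin]))
  }
  if (!length(rows))
    return(data.frame(bin = character(0), lower = numeric(0),
                      upper = numeric(0), nPairs = integer(0),
                      meanAccuracy = numeric(0)))
  do.call(rbind, rows)
}

#' Recovery of conserved-column placements against a truth row
#'
#' For self-recovery experiments: the fraction of conserved columns where
#' the truth row has a residue and the realigned row places the identical
#' residue (by residue index) in the same column.
#'
#' @param alignedRow gapped row produced by an aligner (string or
#'   [AlignedQuery]).
#' @param truthRow the true gapped row (string).
#' @param conservedCols integer vector of conserved columns.
#' @return fraction in `[0, 1]`.
#' @export
conservedColumnRecovery <- function(alignedRow, truthRow, conservedCols) {
  t <- splitChars(truthRow)
  truthCols <- which(t != GAP)
  if (is(alignedRow, "AlignedQuery")) {
    # exact per-residue comparison via the recorded column assignment
    colOf <- alignedRow@colOf
    if (length(colOf) != length(truthCols))
      stop("aligned query and truth row disagree on residue count")
    sel <- truthCols %in% conservedCols
    if (!any(sel)) return(1)
    return(mean(!is.na(colOf[sel]) & colOf[sel] == truthCols[sel]))
  }
  # plain gapped rows: compare residue indices column by column (only
  # valid when the aligned row retains every residue)
  a <- splitChars(alignedRow)
  ia <- residueIndex(a); it <- residueIndex(t)
  hasRes <- conservedCols[it[conservedCols] > 0L]
  if (!length(hasRes)) return(1)
  mean(ia[hasRes] == it[hasRes])
}
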