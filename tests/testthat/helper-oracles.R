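# Independent oracles used across the suite. These deliberately recompute
# quantities symbol by symbol with naive loops, sharing no code with the
# package's vectorized implementations.

NUCS4 <- c("A", "C", "G", "U")

# brute-force block score: recomputes conservation, composition and the
# two-term score directly from the raw sub-alignment
oracleBlockScore <- function(mat, taxonRows, subseqRow, consCols,
                             weight = 0.8) {
  Cvals <- numeric(length(consCols))
  Nvals <- numeric(length(consCols))
  placed <- logical(length(consCols))
  for (k in seq_along(consCols)) {
    col <- consCols[k]
    counted <- 0; withNuc <- 0
    counts <- setNames(numeric(4), NUCS4)
    for (r in taxonRows) {
      firstRes <- which(mat[r, ] != "-")[1]
      lastRes <- max(which(mat[r, ] != "-"))
      if (firstRes > col || lastRes < col) next
      counted <- counted + 1
      if (mat[r, col] %in% NUCS4) {
        withNuc <- withNuc + 1
        counts[mat[r, col]] <- counts[mat[r, col]] + 1
      }
    }
    Cvals[k] <- if (counted > 0) withNuc / counted else 0
    s <- mat[subseqRow, col]
    if (s %in% NUCS4) {
      placed[k] <- TRUE
      Nvals[k] <- counts[s] / sum(counts)
    }
  }
  if (!any(placed)) return(0)
  sum(Cvals[placed]) / length(consCols) +
    weight * sum(Nvals[placed]) / sum(placed)
}

# exhaustive stack-comparison accuracy: for every reference column with a
# nucleotide from either sequence, search the test alignment explicitly
# for the corresponding stack
oracleAccuracy <- function(test, ref, i, j) {
  tm <- if (is.matrix(test)) test else
    do.call(rbind, lapply(test, function(s) strsplit(s, "")[[1]]))
  rm <- if (is.matrix(ref)) ref else
    do.call(rbind, lapply(ref, function(s) strsplit(s, "")[[1]]))
  if (!is.matrix(test)) rownames(tm) <- names(test)
  if (!is.matrix(ref)) rownames(rm) <- names(ref)
  ra <- rm[i, ]; rb <- rm[j, ]; ta <- tm[i, ]; tb <- tm[j, ]
  resIdx <- function(x) {
    out <- integer(length(x)); n <- 0
    for (k in seq_along(x)) if (x[k] != "-") { n <- n + 1; out[k] <- n }
    out
  }
  ria <- resIdx(ra); rib <- resIdx(rb)
  tia <- resIdx(ta); tib <- resIdx(tb)
  E <- which(ra != "-" | rb != "-")
  S <- 0
  for (col in E) {
    a <- ria[col]; b <- rib[col]
    okA <- TRUE; okB <- TRUE
    if (a > 0) {
      tcol <- which(tia == a)
      okA <- (tib[tcol] == b) || (b == 0 && tib[tcol] == 0)
    }
    if (b > 0) {
      tcol <- which(tib == b)
      okB <- (tia[tcol] == a) || (a == 0 && tia[tcol] == 0)
    }
    if (okA && okB) S <- S + 1
  }
  S / length(E)
}

oraclePSI <- function(aln, i, j) {
  a <- strsplit(aln[[i]], "")[[1]]; b <- strsplit(aln[[j]], "")[[1]]
  B <- 0; E <- 0
  for (k in seq_along(a)) {
    an <- a[k] != "-"; bn <- b[k] != "-"
    if (an || bn) E <- E + 1
    if (an && bn) B <- B + 1
  }
  B / E
}

# random gapped alignment over a small taxonomy, for property tests
randomToyAlignment <- function(nseq = 8, ncol = 30, seed = 1,
                               gapProb = 0.15) {
  set.seed(seed)
  mat <- matrix(sample(NUCS4, nseq * ncol, replace = TRUE), nseq, ncol)
  mat[matrix(runif(nseq * ncol) < gapProb, nseq, ncol)] <- "-"
  # keep every column and row occupied
  for (j in seq_len(ncol)) if (all(mat[, j] == "-"))
    mat[sample(nseq, 1), j] <- sample(NUCS4, 1)
  for (i in seq_len(nseq)) if (all(mat[i, ] == "-"))
    mat[i, sample(ncol, 1)] <- sample(NUCS4, 1)
  rows <- apply(mat, 1, paste, collapse = "")
  names(rows) <- sprintf("r%d", seq_len(nseq))
  tax <- taxonomyFromLineages(c("root;ga", "root;gb"))
  taxonMap <- setNames(rep(c("ga", "gb"), length.out = nseq), names(rows))
  ingestAlignment(rows, taxonMap, tax)
}

# pair of random gapped rows with identical degapped content (for the
# accuracy metric): start from one residue string, gap it two ways
randomRowPair <- function(seed) {
  set.seed(seed)
  nres <- sample(8:16, 2)
  width <- max(nres) + sample(4:8, 1)
  mk <- function(n) {
    res <- sample(NUCS4, n, replace = TRUE)
    row <- rep("-", width)
    row[sort(sample(width, n))] <- res
    paste(row, collapse = "")
  }
  ref <- c(a = mk(nres[1]), b = mk(nres[2]))
  # a second alignment of the same residues: re-gap each row
  regap <- function(rowStr) {
    res <- strsplit(rowStr, "")[[1]]
    res <- res[res != "-"]
    row <- rep("-", width)
    row[sort(sample(width, length(res)))] <- res
    paste(row, collapse = "")
  }
  tst <- c(a = regap(ref["a"]), b = regap(ref["b"]))
  list(ref = ref, test = tst)
}
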