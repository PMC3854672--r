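NUCS <- c("A", "C", "G", "U")
GAP <- "-"
# IUPAC one-letter codes accepted on ingest; anything outside this set (plus
# the gap) triggers a per-sequence warning and is treated as a gap.
IUPAC <- c(NUCS, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

# placement-search penalty per query nucleotide inserted beyond the
# template's own gap capacity between adjacent conserved columns; applies
# to the search objective only, never to the reported block score
INSERT_PENALTY <- 1

isNuc <- function(x) x %in% NUCS

#' @keywords internal
normalizeSymbols <- function(x) {
  x <- toupper(x)
  x[x == "T"] <- "U"
  x[x == "."] <- GAP
  x
}

#' @keywords internal
splitChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' @keywords internal
collapseChars <- function(x) paste(x, collapse = "")

# order-preserving DP: place residues q[1..n] onto columns cols[1..k],
# maximizing sum of score[residue, column]; residues may be left unplaced
# (insertions, score 0). Returns integer vector of assigned column per
# residue (NA = insertion). Ties resolved leftmost (earliest columns).
placeResiduesDP <- function(n, k, scoreMat) {
  if (n == 0L) return(integer(0))
  if (k == 0L) return(rep(NA_integer_, n))
  # f[i+1, j+1]: best score using first i residues and first j columns
  f <- matrix(0, n + 1L, k + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      place <- f[i, j] + scoreMat[i, j]
      skipc <- f[i + 1L, j]      # leave column j empty
      skipr <- f[i, j + 1L]      # residue i becomes an insertion
      f[i + 1L, j + 1L] <- max(place, skipc, skipr)
    }
  }
  # traceback, preferring placement, then earlier columns
  assign <- rep(NA_integer_, n)
  i <- n; j <- k
  while (i > 0L && j > 0L) {
    v <- f[i + 1L, j + 1L]
    if (abs(v - (f[i, j] + scoreMat[i, j])) < 1e-12 &&
        f[i, j] + scoreMat[i, j] >= f[i + 1L, j] - 1e-12) {
      assign[i] <- j
      i <- i - 1L; j <- j - 1L
    } else if (f[i + 1L, j] >= f[i, j + 1L] - 1e-12) {
      j <- j - 1L
    } else {
      i <- i - 1L
    }
  }
  assign
}

# sliding-window maximum: out[p] = max(x[p + 1], ..., x[p + w]) with -Inf
# padding beyond the end; w >= 1. With cap/lambda set, an offset d spending
# more than `cap` intervening residues costs lambda per extra residue
# (penalizing insertions beyond the template's own gap capacity).
windowMax <- function(x, w, cap = w, lambda = 0) {
  n <- length(x)
  out <- rep(-Inf, n)
  for (d in seq_len(min(w, n))) {
    pen <- lambda * max(0L, d - 1L - cap)
    shifted <- c(x[-seq_len(d)], rep(-Inf, d)) - pen
    out <- pmax(out, shifted)
  }
  out
}

# as windowMax but returns the smallest offset (absolute index) achieving
# the penalized maximum when scanning from position `from`
windowArgMax <- function(x, from, w, cap = w, lambda = 0) {
  hi <- min(length(x), from + w - 1L)
  if (from > length(x)) return(NA_integer_)
  d <- seq_len(hi - from + 1L)
  win <- x[from:hi] - lambda * pmax(0L, d - 1L - cap)
  if (all(!is.finite(win))) return(NA_integer_)
  from + which.max(win) - 1L
}
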