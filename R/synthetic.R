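# Deterministic synthetic template/query generation in alignment space.
# Sequences are generated directly as gapped rows over a fixed set of
# columns, so the true column of every residue is known by construction.

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

mutateChars <- function(x, rate, mutable = rep(TRUE, length(x))) {
  hit <- which(mutable & stats::runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(NUCS, x[i]), 1L)
  x
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# structure layout used when structured = TRUE: repeating 60-column module
# [ss 8][helix5 8][loop 12][helix3 8][ss 24]; the last 6 columns of the loop
# and 6 columns of the trailing single strand are the designated variable
# (indel-bearing) regions, so helices stay full length in every sequence.
synthStructureLayout <- function(nColumns) {
  if (nColumns %% 60L != 0L)
    stop("structured synthetic templates require nColumns to be a multiple of 60")
  nMod <- nColumns %/% 60L
  pairs <- NULL
  variable <- logical(nColumns)
  for (k in seq_len(nMod) - 1L) {
    m <- k * 60L
    pairs <- rbind(pairs, cbind(m + 8L + seq_len(8L), m + 37L - seq_len(8L)))
    variable[m + 23L:28L] <- TRUE   # tail of the hairpin loop
    variable[m + 45L:50L] <- TRUE   # interior of the trailing single strand
  }
  list(pairs = pairs, variable = variable)
}

#' Generate a synthetic template alignment with known truth
#'
#' Each taxon receives an ancestral sequence (the shared root sequence
#' mutated at `substitutionRate`), and each sequence is its taxon's ancestor
#' mutated again at `substitutionRate` (substitutions draw uniformly from
#' the three alternative nucleotides). Deletions (gaps) occur only in
#' designated variable regions, independently per column at `indelRate`;
#' conserved regions (and all helix columns in structured templates) are
#' never deleted, so the truth column of every residue is the column it was
#' generated in. With `structured = TRUE` the alignment carries a repeating
#' hairpin architecture and 3'-strand residues are set to the
#' Watson-Crick/GU complement of their 5' partner after mutation, with a
#' small mispair rate.
#'
#' @param nTaxa number of taxa under the root (default 3).
#' @param seqsPerTaxon sequences per taxon (default 10).
#' @param nColumns alignment width (default 600).
#' @param substitutionRate per-column substitution probability in `[0, 0.5)`
#'   applied once from root to taxon ancestor and once from ancestor to
#'   sequence (default 0.05).
#' @param indelRate per-variable-column deletion probability in `[0, 0.5)`
#'   (default 0.3: variable regions show strong length variation, so their
#'   columns fall below the 80% conservation cutoff and the alignment
#'   partitions into conserved blocks separated by variable runs).
#' @param structured generate helices and carry base pairs (default FALSE).
#' @param mispairRate per-pair probability of a non-canonical pair in
#'   structured templates (default 0.03).
#' @param seed integer seed; generation is byte-identical for a fixed seed.
#' @return list with `template` (a [TemplateAlignment]), `taxonomy`,
#'   `pairs` (NULL unless structured), `variable` (logical per column), and
#'   `truth` (the gapped rows, named character vector).
#' @export
synthTemplate <- function(nTaxa = 3L, seqsPerTaxon = 10L, nColumns = 600L,
                          substitutionRate = 0.05, indelRate = 0.3,
                          structured = FALSE, mispairRate = 0.03,
                          seed = 1L) {
  if (substitutionRate < 0 || substitutionRate >= 0.5)
    stop("substitutionRate must be in [0, 0.5)")
  if (indelRate < 0 || indelRate >= 0.5)
    stop("indelRate must be in [0, 0.5)")
  withLocalSeed(seed, {
    if (structured) {
      layout <- synthStructureLayout(nColumns)
      pairs <- layout$pairs
      variable <- layout$variable
    } else {
      pairs <- NULL
      # variable regions: the last 6 columns of every 30-column window
      variable <- rep(rep(c(FALSE, TRUE), times = c(24L, 6L)),
                      length.out = nColumns)
    }
    helixCol <- logical(nColumns)
    if (!is.null(pairs)) helixCol[as.vector(pairs)] <- TRUE
    root <- sample(NUCS, nColumns, replace = TRUE)
    if (!is.null(pairs))
      root[pairs[, 2]] <- RNA_COMPLEMENT[root[pairs[, 1]]]
    rows <- character(0)
    taxa <- character(0)
    for (t in seq_len(nTaxa)) {
      anc <- mutateChars(root, substitutionRate)
      for (s in seq_len(seqsPerTaxon)) {
        x <- mutateChars(anc, substitutionRate)
        if (!is.null(pairs)) {
          x[pairs[, 2]] <- RNA_COMPLEMENT[x[pairs[, 1]]]
          mp <- stats::runif(nrow(pairs)) < mispairRate
          for (i in which(mp)) x[pairs[i, 2]] <- sample(NUCS, 1L)
        }
        del <- variable & !helixCol & stats::runif(nColumns) < indelRate
        x[del] <- GAP
        rows <- c(rows, collapseChars(x))
        taxa <- c(taxa, sprintf("taxon%d", t))
      }
    }
    names(rows) <- sprintf("t%ds%d", rep(seq_len(nTaxa), each = seqsPerTaxon),
                           rep(seq_len(seqsPerTaxon), nTaxa))
    tree <- taxonomyFromLineages(
      c("root", sprintf("root;taxon%d", seq_len(nTaxa))))
    template <- ingestAlignment(rows, stats::setNames(taxa, names(rows)),
                                tree, pairs = pairs)
    list(template = template, taxonomy = tree, pairs = pairs,
         variable = variable, truth = rows)
  })
}

#' Sample query sequences from a synthetic template with truth rows
#'
#' Queries are drawn from the template's rows, mutated at `divergence`
#' (substitutions in place, so the truth column of every residue is
#' preserved), and optionally 5'-truncated to a fraction of their length to
#' produce incomplete sequences. The returned truth rows are the mutated
#' gapped rows in template coordinates.
#'
#' @param synth the list returned by [synthTemplate()].
#' @param n number of queries.
#' @param divergence per-residue substitution probability in `[0, 0.5)`.
#' @param completenessFraction fraction of residues retained from the 3'
#'   end (1 = complete sequences).
#' @param seed integer seed.
#' @return list with `queries` (named character vector of ungapped
#'   sequences), `truth` (named character vector of gapped truth rows),
#'   `source` (template row sampled) and `taxon` (its taxon label).
#' @export
synthQueries <- function(synth, n = 10L, divergence = 0,
                         completenessFraction = 1, seed = 1L) {
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)")
  tpl <- synth$template
  withLocalSeed(seed, {
    src <- sample(sequenceIds(tpl), n, replace = n > nSequences(tpl))
    queries <- character(n); truth <- character(n)
    for (i in seq_len(n)) {
      x <- splitChars(gappedRow(tpl, src[i]))
      res <- which(x != GAP)
      x[res] <- mutateChars(x[res], divergence)
      if (completenessFraction < 1) {
        drop <- res[seq_len(floor((1 - completenessFraction) * length(res)))]
        x[drop] <- GAP
        res <- setdiff(res, drop)
      }
      truth[i] <- collapseChars(x)
      queries[i] <- collapseChars(x[res])
    }
    ids <- sprintf("q%d", seq_len(n))
    list(queries = stats::setNames(queries, ids),
         truth = stats::setNames(truth, ids),
         source = stats::setNames(src, ids),
         taxon = stats::setNames(unname(taxonLabels(tpl)[src]), ids))
  })
}
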