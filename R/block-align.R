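#' Alignment configuration for the block engine
#'
#' Collects the tunable parameters of the iterative block-alignment
#' procedure. The stage-1 score threshold is `scoreFraction` times the
#' maximum attainable block score (1 + composition weight), i.e. 1.62 with
#' the defaults; each relaxation multiplies it by `relaxFactor` (1.296 after
#' the single default relaxation) and additionally permits deletions of
#' conserved columns.
#'
#' @param scoreFraction fraction of the maximum score required at the
#'   strict stage (default 0.9).
#' @param relaxFactor multiplicative threshold relaxation per relaxed stage
#'   (default 0.8).
#' @param maxRelaxations number of relaxed stages (default 1).
#' @param maxInsertStrict inserted query nucleotides tolerated between
#'   adjacent conserved columns at the strict stage, beyond the template's
#'   own gap capacity (default 2).
#' @param maxDeletions conserved-column deletions considered per block at
#'   relaxed stages (default 2).
#' @param leafLevel taxonomy depth searched by the superficial pass when no
#'   taxon hint is given (default 6).
#' @return a named list of class `tralignConfig`.
#' @export
alignConfig <- function(scoreFraction = 0.9, relaxFactor = 0.8,
                        maxRelaxations = 1L, maxInsertStrict = 2L,
                        maxDeletions = 2L, leafLevel = 6L) {
  stopifnot(scoreFraction > 0, scoreFraction <= 1,
            relaxFactor > 0, relaxFactor < 1,
            maxRelaxations >= 0, maxInsertStrict >= 0, maxDeletions >= 0)
  structure(list(scoreFraction = scoreFraction, relaxFactor = relaxFactor,
                 maxRelaxations = as.integer(maxRelaxations),
                 maxInsertStrict = as.integer(maxInsertStrict),
                 maxDeletions = as.integer(maxDeletions),
                 leafLevel = as.integer(leafLevel)),
            class = "tralignConfig")
}

# composition value of each query symbol at one column, for a taxon
compAt <- function(st, qIdx, col) {
  v <- numeric(length(qIdx))
  ok <- !is.na(qIdx)
  v[ok] <- st$composition[cbind(qIdx[ok], col)]
  v[!ok] <- 0
  v
}

#' Candidate placements of a query subsequence onto one block
#'
#' Enumerates order-preserving placements of query nucleotides onto the
#' block's conserved columns (the scoring taxon's own conserved set),
#' bounded by the search window implied by previously anchored neighbour
#' blocks, by the number of insertions tolerated between adjacent conserved
#' columns, and by the block's observed maximum nucleotide count. At the
#' strict stage no conserved column may be deleted; at relaxed stages up to
#' `maxDeletions` conserved columns may be skipped. One candidate is
#' returned per feasible start position (its best-scoring placement);
#' candidates score at least `threshold` and are sorted by score, then by
#' leftmost position.
#'
#' @param query character vector of query nucleotides.
#' @param colAssign integer vector: current column of each query nucleotide
#'   (NA = unassigned); defines the anchoring window.
#' @param profile an [AlignmentProfile].
#' @param taxon scoring taxon (must have statistics).
#' @param block block number.
#' @param threshold minimum subsequence block score.
#' @param allowDeletion permit conserved-column deletions.
#' @param insertSlack inserted nucleotides tolerated between adjacent
#'   conserved columns beyond template gap capacity.
#' @param maxDeletions deletion budget per block when `allowDeletion`.
#' @return list of candidates, each `list(start, positions, placedCols,
#'   score, deletions)`; `positions` maps each of the taxon's conserved
#'   columns to a query position (NA = deleted).
#' @export
candidateMatches <- function(query, colAssign, profile, taxon, block,
                             threshold, allowDeletion = FALSE,
                             insertSlack = 2L, maxDeletions = 2L) {
  st <- profile@taxa[[taxon]]
  if (is.null(st)) stop(sprintf("no statistics for taxon '%s'", taxon))
  Y <- st$conservedByBlock[[block]]
  m <- length(Y)
  if (m == 0L) return(list())
  L <- length(query)
  if (L < 1L) return(list())
  qIdx <- match(query, NUCS)
  C <- st$conservation[Y]
  w <- profile@params$weight
  V <- vapply(seq_len(m), function(j) compAt(st, qIdx, Y[j]),
              numeric(L))        # L x m composition values
  V <- matrix(V, nrow = L)

  # anchoring window from previously assigned neighbours
  assigned <- which(!is.na(colAssign))
  prevPos <- assigned[colAssign[assigned] < Y[1]]
  nextPos <- assigned[colAssign[assigned] > Y[m]]
  lo1 <- if (length(prevPos)) max(prevPos) + 1L else 1L
  hi1 <- if (length(prevPos)) {
    p <- max(prevPos)
    p + (Y[1] - colAssign[p] - 1L) + insertSlack + 1L
  } else L
  him <- if (length(nextPos)) min(nextPos) - 1L else L
  lom <- if (length(nextPos)) {
    np <- min(nextPos)
    np - (colAssign[np] - Y[m] - 1L) - insertSlack - 1L
  } else 1L
  if (lo1 > L || him < 1L || lo1 > him) return(list())
  caps <- if (m > 1L) Y[-1] - Y[-m] - 1L else integer(0)
  gmax <- caps + insertSlack
  maxSpan <- st$maxNt[block] + insertSlack

  res <- list()
  collect <- function(cand) res[[length(res) + 1L]] <<- cand

  # ---- strict DP (no deletions): composition is the position-dependent
  # part of the score; intervening residues beyond the template's own gap
  # capacity are penalized in the placement objective (the reported score
  # itself follows the block-score definition)
  B <- vector("list", m)
  Bm <- V[, m]
  Bm[seq_len(L) < lom | seq_len(L) > him] <- -Inf
  B[[m]] <- Bm
  if (m > 1L) for (j in (m - 1L):1L) {
    B[[j]] <- V[, j] + windowMax(B[[j + 1L]], gmax[j] + 1L, caps[j],
                                 INSERT_PENALTY)
  }
  constC <- sum(C) / m
  starts <- seq.int(max(1L, lo1), min(L, hi1))
  starts <- starts[is.finite(B[[1L]][starts])]
  for (p in starts) {
    rank <- constC + w * B[[1L]][p] / m
    if (rank < threshold - 1e-9) next
    pos <- integer(m); pos[1L] <- p
    if (m > 1L) for (j in seq_len(m - 1L)) {
      nxt <- windowArgMax(B[[j + 1L]], pos[j] + 1L, gmax[j] + 1L, caps[j],
                          INSERT_PENALTY)
      if (is.na(nxt)) { pos <- NULL; break }
      pos[j + 1L] <- nxt
    }
    if (is.null(pos)) next
    if (pos[m] - pos[1L] + 1L > maxSpan) {
      # the start's best placement overruns the block's observed maximum
      # length; re-run the DP restricted to the admissible window
      wres <- strictWindowDP(V, m, gmax, caps, p, min(p + maxSpan - 1L, him))
      if (is.null(wres)) next
      rank <- constC + w * wres$value / m
      if (rank < threshold - 1e-9) next
      pos <- wres$pos
    }
    score <- constC + w * sum(V[cbind(pos, seq_len(m))]) / m
    collect(list(start = p, positions = pos, placedCols = Y,
                 score = score, rank = rank, deletions = 0L))
  }

  # ---- relaxed DP with up to maxDeletions skipped conserved columns
  if (allowDeletion && maxDeletions > 0L && m > 1L) {
    for (d in seq_len(min(maxDeletions, m - 1L))) {
      # value of placing column j at pos, for exactly d total deletions
      val <- function(j) {
        v <- C[j] / m + w * V[, j] / (m - d)
        v
      }
      # D[[j]] is an L x (d+1) matrix: col k+1 = k deletions still available
      Dnext <- matrix(-Inf, L, d + 1L)
      Dnext[, 1L] <- 0  # past the last column with 0 deletions left
      gBig <- max(c(gmax, 1L))
      D <- vector("list", m + 1L)
      D[[m + 1L]] <- Dnext
      for (j in m:1L) {
        g <- if (j <= length(gmax)) gmax[j] + 1L else 1L
        capj <- if (j <= length(caps)) caps[j] else 0L
        Dj <- matrix(-Inf, L, d + 1L)
        vj <- val(j)
        nx <- D[[j + 1L]]
        for (k in 0L:d) {
          shifted <- if (j == m) {
            # terminal column: value only, successor contributes base
            ifelse(rep(k == 0L, L), 0, -Inf)
          } else windowMax(nx[, k + 1L], g, capj, INSERT_PENALTY)
          place <- vj + shifted
          Dj[, k + 1L] <- place
          if (k > 0L) Dj[, k + 1L] <- pmax(Dj[, k + 1L], nx[, k])
        }
        D[[j]] <- Dj
      }
      clamp <- seq_len(L) < lo1 | seq_len(L) > him
      total <- D[[1L]][, d + 1L]
      total[clamp] <- -Inf
      cand <- which(total >= threshold - 1e-9)
      for (p in cand) {
        tb <- tracebackDeletions(D, V, C, w, m, d, gmax, caps, p, L)
        if (is.null(tb)) next
        if (max(tb, na.rm = TRUE) > him) next
        span <- diff(range(tb, na.rm = TRUE)) + 1L
        if (span > maxSpan) next
        placed <- which(!is.na(tb))
        score <- sum(C[placed]) / m +
          w * sum(V[cbind(tb[placed], placed)]) / (m - d)
        collect(list(start = min(tb, na.rm = TRUE), positions = tb,
                     placedCols = Y, score = score, rank = total[p],
                     deletions = d))
      }
    }
  }

  if (!length(res)) return(list())
  # forced insertions: intervening query residues beyond the template's
  # own gap capacity between consecutively placed conserved columns; used
  # as a tie-break (a true placement of a template subsequence needs none)
  res <- lapply(res, function(x) {
    keep <- !is.na(x$positions)
    p <- x$positions[keep]; cc <- x$placedCols[keep]
    x$forcedIns <- if (length(p) > 1L)
      sum(pmax(0L, (p[-1L] - p[-length(p)] - 1L) -
                   (cc[-1L] - cc[-length(cc)] - 1L))) else 0L
    x
  })
  # dedupe identical placements, keep best; order by penalized rank, then
  # fewer forced insertions, then leftmost
  key <- vapply(res, function(x) paste(x$positions, collapse = ","),
                character(1))
  res <- res[!duplicated(key)]
  ord <- order(-vapply(res, `[[`, numeric(1), "rank"),
               vapply(res, `[[`, numeric(1), "forcedIns"),
               vapply(res, `[[`, numeric(1), "start"))
  res[ord]
}

# strict placement DP restricted to positions [p, hi], anchored at p;
# returns list(value, pos) or NULL if infeasible
strictWindowDP <- function(V, m, gmax, caps, p, hi) {
  if (hi < p + m - 1L) return(NULL)
  idx <- p:hi
  B <- vector("list", m)
  Bm <- V[idx, m]
  B[[m]] <- Bm
  if (m > 1L) for (j in (m - 1L):1L)
    B[[j]] <- V[idx, j] + windowMax(B[[j + 1L]], gmax[j] + 1L, caps[j],
                                    INSERT_PENALTY)
  if (!is.finite(B[[1L]][1L])) return(NULL)
  pos <- integer(m); pos[1L] <- 1L
  if (m > 1L) for (j in seq_len(m - 1L)) {
    nxt <- windowArgMax(B[[j + 1L]], pos[j] + 1L, gmax[j] + 1L, caps[j],
                        INSERT_PENALTY)
    if (is.na(nxt)) return(NULL)
    pos[j + 1L] <- nxt
  }
  list(value = B[[1L]][1L], pos = pos + p - 1L)
}

# traceback for the deletion DP; returns positions (NA where deleted)
tracebackDeletions <- function(D, V, C, w, m, d, gmax, caps, p, L) {
  pos <- rep(NA_integer_, m)
  k <- d; cur <- p
  for (j in seq_len(m)) {
    Dj <- D[[j]]; nx <- D[[j + 1L]]
    here <- Dj[cur, k + 1L]
    if (!is.finite(here)) return(NULL)
    vj <- C[j] / m + w * V[cur, j] / (m - d)
    g <- if (j <= length(gmax)) gmax[j] + 1L else 1L
    capj <- if (j <= length(caps)) caps[j] else 0L
    placedVal <- if (j == m) {
      if (k == 0L) vj else -Inf
    } else {
      nxt <- windowArgMax(nx[, k + 1L], cur + 1L, g, capj, INSERT_PENALTY)
      if (is.na(nxt)) -Inf else {
        pen <- INSERT_PENALTY * max(0L, (nxt - cur - 1L) - capj)
        vj + nx[nxt, k + 1L] - pen
      }
    }
    if (is.finite(placedVal) && abs(placedVal - here) < 1e-9) {
      pos[j] <- cur
      if (j < m) cur <- windowArgMax(nx[, k + 1L], cur + 1L, g, capj,
                                     INSERT_PENALTY)
    } else if (k > 0L) {
      k <- k - 1L   # column j deleted; position carries over
    } else {
      return(NULL)
    }
  }
  if (all(is.na(pos))) return(NULL)
  pos
}

#' Select the taxonomic node used to align a query
#'
#' With a taxon hint that names a node of the template's taxonomy, returns
#' the lowest ancestor-or-self of the hint that carries alignment
#' statistics. Without a usable hint, runs the superficial pass: a
#' strict-stage-only alignment against every statistics-bearing taxon at
#' depth at most `leafLevel`, returning the taxon that aligns the most
#' query nucleotides (ties go to the shallower, more general taxon, then to
#' taxonomy order).
#'
#' @param query ungapped query sequence (single string).
#' @param profile an [AlignmentProfile].
#' @param hint optional taxonomic name (e.g. a genus).
#' @param config an [alignConfig()].
#' @return taxon name.
#' @export
selectTaxon <- function(query, profile, hint = NULL,
                        config = alignConfig()) {
  taxa <- names(profile@taxa)
  if (!length(taxa)) stop("profile carries no taxon statistics")
  tree <- profile@taxonomy
  if (!is.null(hint) && hint %in% tree@nodes) {
    path <- rev(lineage(tree, hint))
    for (t in path) if (t %in% taxa) return(t)
  }
  cand <- taxa[vapply(taxa, function(t) taxonDepth(tree, t), integer(1)) <=
               config$leafLevel]
  q <- normalizeSymbols(splitChars(query))
  thr <- config$scoreFraction * (1 + profile@params$weight)
  nAligned <- vapply(cand, function(t) {
    st <- runSweeps(q, profile, chain = t, threshold = thr,
                    allowDeletion = FALSE,
                    insertSlack = config$maxInsertStrict,
                    maxDeletions = 0L,
                    state = list(colAssign = rep(NA_integer_, length(q)),
                                 aligned = logical(length(profile@blocks)),
                                 log = list()),
                    stage = "superficial", log = FALSE)
    sum(!is.na(st$colAssign))
  }, integer(1))
  depths <- vapply(cand, function(t) taxonDepth(tree, t), integer(1))
  ord <- order(-nAligned, depths, match(cand, tree@nodes))
  cand[ord][1L]
}

commitMatch <- function(state, cand, b, t, stage, threshold, log) {
  keep <- !is.na(cand$positions)
  state$colAssign[cand$positions[keep]] <- cand$placedCols[keep]
  state$aligned[b] <- TRUE
  if (log) state$log[[length(state$log) + 1L]] <-
    data.frame(block = b, taxon = t, stage = stage, threshold = threshold,
               score = cand$score, deletions = cand$deletions)
  state
}

# one full stage: sweeps over the taxon chain until no block commits. A
# block commits when its candidate set is unambiguous: a single acceptable
# placement, or a strictly best-scoring one. Multi-candidate blocks stay
# pending for a later sweep (a committed neighbour narrows their window)
# or for the end-of-procedure resolution. Returns the updated state.
runSweeps <- function(q, profile, chain, threshold, allowDeletion,
                      insertSlack, maxDeletions, state, stage, log = TRUE) {
  repeat {
    progress <- FALSE
    for (t in chain) {
      st <- profile@taxa[[t]]
      elig <- which(!state$aligned & st$blockScores >= threshold - 1e-9)
      elig <- elig[order(-round(st$blockScores[elig], 9L), elig)]
      for (b in elig) {
        if (state$aligned[b]) next
        cands <- candidateMatches(q, state$colAssign, profile, t, b,
                                  threshold, allowDeletion, insertSlack,
                                  maxDeletions)
        if (!length(cands)) next
        if (length(cands) == 1L ||
            cands[[1L]]$rank > cands[[2L]]$rank + 1e-9 ||
            (abs(cands[[1L]]$rank - cands[[2L]]$rank) <= 1e-9 &&
             cands[[1L]]$forcedIns < cands[[2L]]$forcedIns)) {
          state <- commitMatch(state, cands[[1L]], b, t, stage, threshold,
                               log)
          progress <- TRUE
        }
      }
    }
    if (!progress) break
  }
  state
}

# force-commit one still-ambiguous block (highest average block score
# first; highest match score, then leftmost placement, wins)
resolveOne <- function(q, profile, chain, threshold, allowDeletion,
                       insertSlack, maxDeletions, state, stage) {
  cand <- NULL
  for (t in chain) {
    st <- profile@taxa[[t]]
    elig <- which(!state$aligned & st$blockScores >= threshold - 1e-9)
    elig <- elig[order(-round(st$blockScores[elig], 9L), elig)]
    for (b in elig) {
      cands <- candidateMatches(q, state$colAssign, profile, t, b,
                                threshold, allowDeletion, insertSlack,
                                maxDeletions)
      if (!length(cands)) next
      if (is.null(cand) || st$blockScores[b] > cand$blockScore + 1e-9) {
        cand <- list(blockScore = st$blockScores[b], b = b, t = t,
                     match = cands[[1L]])
      }
    }
    if (!is.null(cand)) break  # prefer the lowest (most specific) taxon
  }
  if (is.null(cand)) return(NULL)
  commitMatch(state, cand$match, cand$b, cand$t,
              paste0(stage, "-resolved"), threshold, TRUE)
}

#' Align one query sequence against an alignment profile
#'
#' The iterative block-alignment procedure: pick the query's taxonomic
#' node, then repeatedly align query subsequences to blocks in descending
#' average-score order, first at the selected taxon and then at each
#' ancestor up to the root, committing a block only once its placement is
#' unambiguous (multi-candidate blocks stay pending until a neighbouring
#' anchor constrains them, or are resolved best-score-first at the end of a
#' sweep). After the strict stage, the threshold is relaxed by
#' `relaxFactor` and conserved-column deletions are permitted. Residues
#' never captured by a block are finally placed between their anchors by a
#' composition-maximizing fill; residues exceeding template gap capacity
#' are reported as insertions rather than widening the template.
#'
#' @param query ungapped query sequence (single string).
#' @param profile an [AlignmentProfile].
#' @param hint optional taxonomic name; see [selectTaxon()].
#' @param config an [alignConfig()].
#' @param id query identifier used in the result.
#' @return an [AlignedQuery]. A query for which no block aligns at any
#'   stage is returned with an all-insertion (unalignable) annotation
#'   rather than raising an error.
#' @export
alignToProfile <- function(query, profile, hint = NULL,
                           config = alignConfig(), id = "query") {
  q <- normalizeSymbols(splitChars(query))
  if (!length(q) || any(q == GAP)) stop("query must be a non-empty ungapped sequence")
  taxonSel <- selectTaxon(query, profile, hint, config)
  chain <- intersect(rev(lineage(profile@taxonomy, taxonSel)),
                     names(profile@taxa))
  maxScore <- 1 + profile@params$weight
  thr <- config$scoreFraction * maxScore
  bigSlack <- max(profile@taxa[[chain[1L]]]$maxNt)
  stages <- list(list(name = "strict", thr = thr, del = FALSE,
                      slack = config$maxInsertStrict, maxDel = 0L))
  relThr <- thr
  for (r in seq_len(config$maxRelaxations)) {
    relThr <- relThr * config$relaxFactor
    stages[[r + 1L]] <- list(name = sprintf("relaxed%d", r), thr = relThr,
                             del = TRUE, slack = bigSlack,
                             maxDel = config$maxDeletions)
  }
  state <- list(colAssign = rep(NA_integer_, length(q)),
                aligned = logical(length(profile@blocks)), log = list())
  repeat {
    nOuter <- sum(state$aligned)
    # each stage runs to exhaustion (sweeps, then forced resolution of its
    # still-ambiguous blocks) before the criteria are relaxed further
    for (sp in stages) {
      repeat {
        nBefore <- sum(state$aligned)
        state <- runSweeps(q, profile, chain, sp$thr, sp$del, sp$slack,
                           sp$maxDel, state, sp$name)
        if (sum(state$aligned) > nBefore) next
        resolved <- resolveOne(q, profile, chain, sp$thr, sp$del, sp$slack,
                               sp$maxDel, state, sp$name)
        if (is.null(resolved)) break
        state <- resolved
      }
    }
    if (sum(state$aligned) == nOuter) break
  }
  blockLog <- if (length(state$log)) do.call(rbind, state$log) else
    data.frame(block = integer(0), taxon = character(0),
               stage = character(0), threshold = numeric(0),
               score = numeric(0), deletions = integer(0))

  fill <- fillUnassigned(q, state$colAssign, profile, taxonSel)
  new("AlignedQuery", id = id, row = buildRow(q, fill$colAssign, profile@ncol),
      colOf = fill$colAssign, engine = "block", taxon = taxonSel,
      blocks = blockLog, insertions = fill$insertions)
}

#' Align a batch of queries
#'
#' Each query is aligned independently (the result of a batch equals the
#' results of aligning each query alone).
#'
#' @param queries named character vector of ungapped sequences.
#' @param profile an [AlignmentProfile].
#' @param hints optional named character vector of taxon hints.
#' @param config an [alignConfig()].
#' @return named list of [AlignedQuery] objects.
#' @export
alignSequences <- function(queries, profile, hints = NULL,
                           config = alignConfig()) {
  ids <- names(queries)
  if (is.null(ids)) ids <- sprintf("query%d", seq_along(queries))
  out <- lapply(seq_along(queries), function(i)
    alignToProfile(queries[[i]], profile,
                   hint = if (!is.null(hints)) hints[[ids[i]]] else NULL,
                   config = config, id = ids[i]))
  stats::setNames(out, ids)
}

# composition-maximizing placement of residues not captured by any block
fillUnassigned <- function(q, colAssign, profile, taxon) {
  st <- profile@taxa[[taxon]]
  rootSt <- profile@taxa[[taxonomyRoot(profile@taxonomy)]]
  comp <- st$composition
  empty <- colSums(comp) == 0
  comp[, empty] <- rootSt$composition[, empty]
  L <- length(q)
  insRows <- list()
  runs <- unassignedRuns(colAssign)
  for (r in runs) {
    a <- r[1L]; b <- r[2L]
    cl <- if (a > 1L) colAssign[a - 1L] else 0L
    cr <- if (b < L) colAssign[b + 1L] else profile@ncol + 1L
    cols <- if (cr - cl > 1L) (cl + 1L):(cr - 1L) else integer(0)
    n <- b - a + 1L
    qIdx <- match(q[a:b], NUCS)
    if (length(cols)) {
      scoreMat <- matrix(0, n, length(cols))
      ok <- !is.na(qIdx)
      if (any(ok))
        scoreMat[ok, ] <- comp[qIdx[ok], cols, drop = FALSE]
      assign <- placeResiduesDP(n, length(cols), scoreMat)
      placed <- !is.na(assign)
      colAssign[(a:b)[placed]] <- cols[assign[placed]]
    } else placed <- rep(FALSE, n)
    if (any(!placed)) {
      idx <- (a:b)[!placed]
      afterCol <- vapply(idx, function(i) {
        prev <- colAssign[seq_len(i - 1L)]
        prev <- prev[!is.na(prev)]
        if (length(prev)) max(prev) else 0L
      }, integer(1))
      insRows[[length(insRows) + 1L]] <-
        data.frame(position = idx, afterColumn = afterCol,
                   residue = q[idx])
    }
  }
  insertions <- if (length(insRows)) do.call(rbind, insRows) else
    data.frame(position = integer(0), afterColumn = integer(0),
               residue = character(0))
  list(colAssign = colAssign, insertions = insertions)
}

unassignedRuns <- function(colAssign) {
  un <- is.na(colAssign)
  if (!any(un)) return(list())
  r <- rle(un)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

buildRow <- function(q, colAssign, ncol) {
  row <- rep(GAP, ncol)
  ok <- !is.na(colAssign)
  row[colAssign[ok]] <- q[ok]
  collapseChars(row)
}

#' @rdname alignedRow
#' @export
setMethod("alignedRow", "AlignedQuery", function(x) x@row)

setMethod("show", "AlignedQuery", function(object) {
  nAss <- sum(!is.na(object@colOf))
  cat(sprintf("AlignedQuery '%s' (%s engine): %d/%d nucleotides in columns",
              object@id, object@engine, nAss, length(object@colOf)))
  if (nrow(object@insertions))
    cat(sprintf(", %d insertion(s)", nrow(object@insertions)))
  cat("\n")
  if (nrow(object@blocks))
    cat(sprintf("  %d block(s) aligned via taxon '%s'\n",
                nrow(object@blocks), object@taxon))
})
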