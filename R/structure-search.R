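#' Rank descriptor elements by stringency
#'
#' Each element receives a probability score: the expected number of times
#' a window satisfying the element's constraints occurs by chance in an
#' i.i.d. background sequence of the given length. With `a` the fraction of
#' the four nucleotides observed in the element (pooled frequency > 0) and
#' `S` its supported lengths, the expectation is
#' `length * sum_{L in S} a^L`. The more stringent an element, the lower
#' its score; elements are returned most stringent first (ties keep
#' descriptor order). Doubling the sequence length doubles every
#' expectation and never changes the order.
#'
#' @param descriptor a [StructureDescriptor].
#' @param sequenceLength background sequence length.
#' @param section section name (default `"root"`).
#' @return data.frame with columns `id`, `type`, `expected`, in rank order.
#' @export
rankElements <- function(descriptor, sequenceLength, section = "root") {
  sec <- descriptor@sections[[section]]
  if (is.null(sec)) stop(sprintf("no descriptor section '%s'", section))
  ids <- vapply(descriptor@model@elements, `[[`, character(1), "id")
  types <- vapply(descriptor@model@elements, `[[`, character(1), "type")
  expected <- vapply(ids, function(en) {
    el <- sec[[en]]
    a <- sum(el$freq > 0) / 4
    supp <- as.numeric(names(el$lengths)[el$lengths > 0])
    sequenceLength * sum(a^supp)
  }, numeric(1))
  ord <- order(expected, seq_along(ids))
  data.frame(id = ids[ord], type = types[ord], expected = expected[ord],
             row.names = NULL)
}

# supported lengths (integer) of an element in a section
suppLengths <- function(sec, id) {
  w <- sec[[id]]$lengths
  as.integer(names(w)[w > 0])
}

lenWeight <- function(sec, id, l) {
  w <- sec[[id]]$lengths[as.character(l)]
  if (is.na(w)) 0 else unname(w)
}

mpWeight <- function(sec, id, k) {
  w <- sec[[id]]$mispairs[as.character(k)]
  if (is.na(w)) 0 else unname(w)
}

minPosWeight <- function(w) min(w[w > 0])

countMispairs <- function(q, i5 = integer(0), i3 = integer(0)) {
  k <- min(length(i5), length(i3))
  if (k == 0L) return(0L)
  a <- q[i5[length(i5) - seq_len(k) + 1L]]   # loop-proximal first
  b <- q[i3[seq_len(k)]]
  sum(!(paste0(a, b) %in% CANONICAL_PAIRS))
}

#' Identify a descriptor's structural elements in an unaligned sequence
#'
#' Seed-and-extend search: elements are ranked by stringency
#' ([rankElements()]); occurrences of the most stringent element seed the
#' model, which is extended one adjacent element per round, alternating
#' between the 5' and 3' ends while both are open. At every round the
#' elongating model must remain consistent: element lengths must lie in
#' the section's length histogram, opposed helix strands may not exceed
#' the supported mispair count, and the product of observed weights must
#' stay at or above the section's cutoff. An observation outside a
#' histogram's support costs one exception from the user budget (a helix
#' whose two strands share the same out-of-support length costs one, not
#' two; out-of-support observations are exempt from the cutoff product).
#' The search is exhaustive with branch-and-bound pruning and returns the
#' complete model with the fewest exceptions and, among those, the highest
#' weight product; when no seed occurrence of the top-ranked element
#' extends to a complete model, the next-ranked element seeds the search.
#' If no complete model is reachable the deepest partial model found is
#' returned. Completeness is non-decreasing in `maxExceptions`, and the
#' result is deterministic for fixed inputs.
#'
#' @param query ungapped sequence (single string).
#' @param descriptor a [StructureDescriptor].
#' @param section section name (a taxon, or `"root"`).
#' @param maxExceptions exception budget (default 0).
#' @param queryId identifier recorded on the instance.
#' @return a [StructureInstance]; `isComplete(instance)` is TRUE when every
#'   element was placed (the model then tiles the entire sequence).
#' @export
findStructure <- function(query, descriptor, section = "root",
                          maxExceptions = 0L, queryId = "query") {
  sec <- descriptor@sections[[section]]
  if (is.null(sec)) stop(sprintf("no descriptor section '%s'", section))
  q <- normalizeSymbols(splitChars(query))
  n <- length(q)
  els <- descriptor@model@elements
  K <- length(els)
  ids <- vapply(els, `[[`, character(1), "id")
  cutoff <- descriptor@cutoffs[[section]]
  logCut <- if (cutoff > 0) log(cutoff) else -Inf

  supp <- lapply(ids, function(id) suppLengths(sec, id))
  minS <- vapply(supp, function(s) if (length(s)) min(s) else 0L, integer(1))
  maxS <- vapply(supp, function(s) if (length(s)) max(s) else 0L, integer(1))
  maxLw <- vapply(ids, function(id) {
    w <- sec[[id]]$lengths
    if (any(w > 0)) log(max(w)) else 0
  }, numeric(1))
  maxMw <- vapply(seq_len(K), function(k) {
    if (els[[k]]$type != "strand5") return(0)
    w <- sec[[ids[k]]]$mispairs
    if (length(w) && any(w > 0)) log(max(w)) else 0
  }, numeric(1))

  seqRange <- function(p) if (p$len == 0L) integer(0) else p$start:p$end
  trace <- character(0)
  bestPartial <- list(nPlaced = -1L, placed = NULL, exceptions = 0L)

  # positional quality of a placed helix strand: log-likelihood of its
  # residues under the per-column profile, anchored at the loop-proximal
  # end (floored at 0.01 so rare variants are penalized, not forbidden);
  # breaks ties between same-weight tilings in favour of the strand's
  # true columns
  strandQuality <- function(k, p) {
    pf <- sec[[ids[k]]]$posFreq
    if (is.null(pf) || p$len == 0L) return(0)
    K2 <- ncol(pf)
    l <- min(p$len, K2)
    resid <- q[seqRange(p)]
    if (els[[k]]$type == "strand5") {
      resid <- resid[p$len - l + seq_len(l)]     # last l residues
      colsIdx <- K2 - l + seq_len(l)             # last l columns
    } else {
      resid <- resid[seq_len(l)]
      colsIdx <- seq_len(l)
    }
    ri <- match(resid, NUCS)
    vals <- ifelse(is.na(ri), 0.01, pmax(pf[cbind(ri, colsIdx)], 0.01))
    sum(log(vals))
  }

  # candidate lengths for element k with r exceptions left: supported
  # lengths by descending weight (ties: shorter first), then out-of-support
  # lengths within [minS - r, maxS + r] by distance (each costs one);
  # `free` additionally admits the partner strand's length at no cost
  candLengths <- function(k, r, free = integer(0)) {
    s <- supp[[k]]
    w <- vapply(s, function(l) lenWeight(sec, ids[k], l), numeric(1))
    ordered <- s[order(-w, s)]
    out <- data.frame(len = c(free[!free %in% s], ordered),
                      exception = c(rep(FALSE, sum(!free %in% s)),
                                    rep(FALSE, length(ordered))))
    if (r > 0L) {
      extra <- setdiff(seq.int(max(0L, minS[k] - r), maxS[k] + r),
                       c(s, free))
      if (length(extra)) {
        dist <- pmin(abs(extra - minS[k]), abs(extra - maxS[k]))
        extra <- extra[order(dist, extra)]
        out <- rbind(out, data.frame(len = extra, exception = TRUE))
      }
    }
    out
  }

  # helix consistency once both strands are placed
  helixCheck <- function(k, placed, r) {
    e <- els[[k]]
    mateIdx <- match(e$partner, ids)
    idx5 <- if (e$type == "strand5") k else mateIdx
    idx3 <- if (e$type == "strand5") mateIdx else k
    p5 <- placed[[idx5]]; p3 <- placed[[idx3]]
    if (is.null(p5) || is.null(p3)) return(list(cost = 0L, logw = 0))
    mp <- countMispairs(q, seqRange(p5), seqRange(p3))
    w <- mpWeight(sec, ids[idx5], mp)
    if (w > 0) return(list(cost = 0L, logw = log(w)))
    if (r > 0L) return(list(cost = 1L, logw = 0))
    NULL
  }

  # exhaustive best-first extension for a fixed exception budget; keeps
  # the highest-weight complete model, pruning branches that cannot beat it
  searchBudget <- function(budget) {
    bestC <- NULL
    extend <- function(le, ri, spanL, spanR, placed, r, logw, logq, side) {
      nPlaced <- sum(!vapply(placed, is.null, logical(1)))
      if (nPlaced > bestPartial$nPlaced)
        bestPartial <<- list(nPlaced = nPlaced, placed = placed,
                             exceptions = budget - r)
      openL <- le >= 1L
      openR <- ri <= K
      if (!openL && !openR) {
        if (spanL == 1L && spanR == n &&
            (is.null(bestC) || logw + logq > bestC$objective + 1e-12))
          bestC <<- list(placed = placed, exceptions = budget - r,
                         logw = logw, objective = logw + logq)
        return()
      }
      # bound: best conceivable weight of the remaining elements (their
      # positional quality is at most 0)
      remAll <- c(seq_len(if (openL) le else 0L),
                  if (openR) ri:K else integer(0))
      bound <- logw + logq + sum(maxLw[remAll]) + sum(maxMw[remAll])
      if (!is.null(bestC) && bound <= bestC$objective + 1e-12) return()
      goLeft <- openL && (!openR || side == "L")
      k <- if (goLeft) le else ri
      avail <- if (goLeft) spanL - 1L else n - spanR
      remIdx <- if (goLeft) seq_len(le - 1L) else
        if (ri < K) (ri + 1L):K else integer(0)
      free <- integer(0)
      if (els[[k]]$type != "ss") {
        mate <- placed[[match(els[[k]]$partner, ids)]]
        if (!is.null(mate) && isTRUE(mate$exception)) free <- mate$len
      }
      cl <- candLengths(k, r, free)
      for (cand in seq_len(nrow(cl))) {
        l <- cl$len[cand]; exc <- cl$exception[cand]
        if (l > avail) next
        outSupp <- !(l %in% supp[[k]])   # exc = paid; waived if via free
        rLeft <- r - as.integer(exc)
        rest <- avail - l
        loRest <- sum(pmax(0L, minS[remIdx] - rLeft))
        hiRest <- sum(maxS[remIdx] + rLeft)
        if (rest < loRest || rest > hiRest) next
        if (!length(remIdx) && rest != 0L) next
        p <- if (goLeft) list(start = spanL - l, end = spanL - 1L, len = l,
                              exception = outSupp)
             else list(start = spanR + 1L, end = spanR + l, len = l,
                       exception = outSupp)
        placed2 <- placed
        placed2[[k]] <- p
        lw <- if (outSupp) 0 else log(lenWeight(sec, ids[k], l))
        hx <- if (els[[k]]$type != "ss") helixCheck(k, placed2, rLeft)
          else list(cost = 0L, logw = 0)
        if (is.null(hx)) next
        rLeft2 <- rLeft - hx$cost
        logw2 <- logw + lw + hx$logw
        if (logw2 < logCut - 1e-9) next
        logq2 <- logq + if (els[[k]]$type != "ss") strandQuality(k, p) else 0
        extend(if (goLeft) le - 1L else le, if (goLeft) ri else ri + 1L,
               if (goLeft) spanL - l else spanL,
               if (goLeft) spanR else spanR + l,
               placed2, rLeft2, logw2, logq2,
               side = if (side == "L") "R" else "L")
      }
    }

    ranking <- rankElements(descriptor, n, section)
    for (seedId in ranking$id) {
      k <- match(seedId, ids)
      freq <- sec[[seedId]]$freq
      occ <- list()
      for (l in supp[[k]]) {
        if (l == 0L || l > n) next
        lo5 <- sum(pmax(0L, minS[seq_len(k - 1L)] - budget))
        hi5 <- sum(maxS[seq_len(k - 1L)] + budget)
        rem3 <- if (k < K) (k + 1L):K else integer(0)
        lo3 <- sum(pmax(0L, minS[rem3] - budget))
        hi3 <- sum(maxS[rem3] + budget)
        if (max(1L, lo5 + 1L) > min(n - l + 1L, hi5 + 1L)) next
        starts <- seq.int(max(1L, lo5 + 1L), min(n - l + 1L, hi5 + 1L))
        starts <- starts[n - (starts + l - 1L) >= lo3 &
                         n - (starts + l - 1L) <= hi3]
        for (s0 in starts) {
          resid <- q[s0:(s0 + l - 1L)]
          fr <- freq[match(resid, NUCS)]
          if (any(is.na(fr)) || any(fr == 0)) next
          occ[[length(occ) + 1L]] <-
            list(start = s0, len = l,
                 score = lenWeight(sec, seedId, l) * prod(fr))
        }
      }
      if (!length(occ)) next
      occ <- occ[order(-vapply(occ, `[[`, numeric(1), "score"),
                       vapply(occ, `[[`, numeric(1), "start"))]
      for (o in occ) {
        placed <- vector("list", K)
        placed[[k]] <- list(start = o$start, end = o$start + o$len - 1L,
                            len = o$len, exception = FALSE)
        trace <<- c(trace, sprintf("seed %s at %d-%d (budget %d)", seedId,
                                   o$start, o$start + o$len - 1L, budget))
        seedQ <- if (els[[k]]$type != "ss")
          strandQuality(k, placed[[k]]) else 0
        extend(k - 1L, k + 1L, o$start, o$start + o$len - 1L, placed,
               budget, log(lenWeight(sec, seedId, o$len)), seedQ, "L")
      }
      if (!is.null(bestC)) break  # fall back to next seed only if none
    }
    bestC
  }

  found <- NULL
  for (b in 0L:as.integer(maxExceptions)) {
    found <- searchBudget(b)
    if (!is.null(found)) break
  }

  result <- if (!is.null(found)) found else
    list(placed = if (bestPartial$nPlaced > 0L) bestPartial$placed else
           vector("list", K),
         exceptions = if (bestPartial$nPlaced > 0L)
           bestPartial$exceptions else 0L)
  pl <- data.frame(
    id = ids,
    type = vapply(els, `[[`, character(1), "type"),
    start = vapply(result$placed, function(p)
      if (is.null(p)) NA_integer_ else p$start, integer(1)),
    end = vapply(result$placed, function(p)
      if (is.null(p)) NA_integer_ else p$end, integer(1)),
    length = vapply(result$placed, function(p)
      if (is.null(p)) NA_integer_ else p$len, integer(1)),
    exception = vapply(result$placed, function(p)
      if (is.null(p)) FALSE else isTRUE(p$exception), logical(1)))
  new("StructureInstance", query = collapseChars(q), queryId = queryId,
      placements = pl, complete = !is.null(found),
      exceptions = as.integer(result$exceptions), section = section,
      trace = trace)
}

#' Is a structure instance complete?
#' @param x a [StructureInstance].
#' @return logical.
#' @export
isComplete <- function(x) x@complete

#' Placement table of a structure instance
#' @param x a [StructureInstance].
#' @return data.frame (one row per descriptor element).
#' @export
placements <- function(x) x@placements

setMethod("show", "StructureInstance", function(object) {
  nP <- sum(!is.na(object@placements$start))
  cat(sprintf("StructureInstance '%s': %s (%d/%d elements, %d exception(s), section %s)\n",
              object@queryId,
              if (object@complete) "complete" else "partial",
              nP, nrow(object@placements), object@exceptions,
              object@section))
})

#' Count chance matches of descriptor elements in a sequence
#'
#' For each element, counts the windows whose length is in the section's
#' histogram support and whose residues all have pooled frequency > 0.
#' Taxon sections constrain at least as strongly as the root section, so
#' their counts are never larger.
#'
#' @param descriptor a [StructureDescriptor].
#' @param query sequence (single string).
#' @param section section name.
#' @return integer: total match-window count over all elements.
#' @export
countElementMatches <- function(descriptor, query, section = "root") {
  sec <- descriptor@sections[[section]]
  if (is.null(sec)) stop(sprintf("no descriptor section '%s'", section))
  q <- normalizeSymbols(splitChars(query))
  n <- length(q)
  total <- 0L
  for (id in names(sec)) {
    freq <- sec[[id]]$freq
    okres <- !is.na(match(q, NUCS)) & freq[match(q, NUCS)] > 0
    for (l in suppLengths(sec, id)) {
      if (l == 0L || l > n) next
      runs <- cumsum(okres)
      winOk <- runs[seq.int(l, n)] - c(0L, runs[seq_len(n - l)])
      total <- total + sum(winOk == l)
    }
  }
  total
}

#' Sample sequences satisfying a descriptor's constraints
#'
#' The fixture generator for the structure search: element lengths are
#' drawn from the section's length histograms, residues i.i.d. from the
#' pooled frequency profiles; for each helix the 3' strand opposes the 5'
#' strand with Watson-Crick/GU complements except for a mispair count drawn
#' from the mispair histogram. Draws whose weight product falls below the
#' section's cutoff are rejected and redrawn, so every sampled sequence
#' satisfies all descriptor constraints (including the cutoff) with zero
#' exceptions.
#'
#' @param descriptor a [StructureDescriptor].
#' @param n number of sequences.
#' @param section section name.
#' @param seed integer seed.
#' @return character vector of ungapped sequences.
#' @export
sampleFromDescriptor <- function(descriptor, n = 1L, section = "root",
                                 seed = 1L) {
  sec <- descriptor@sections[[section]]
  if (is.null(sec)) stop(sprintf("no descriptor section '%s'", section))
  els <- descriptor@model@elements
  ids <- vapply(els, `[[`, character(1), "id")
  cutoff <- descriptor@cutoffs[[section]]
  withLocalSeed(seed, {
    vapply(seq_len(n), function(dummy) {
      for (attempt in seq_len(1000L)) {
        lens <- vapply(ids, function(id) {
          w <- sec[[id]]$lengths
          as.integer(sample(names(w), 1L, prob = w))
        }, integer(1))
        mps <- rep(0L, length(els))
        logw <- sum(log(vapply(seq_along(ids), function(k)
          lenWeight(sec, ids[k], lens[k]), numeric(1))))
        for (k in seq_along(els)) {
          if (els[[k]]$type != "strand5") next
          m <- match(els[[k]]$partner, ids)
          kk <- min(lens[k], lens[m])
          w <- sec[[ids[k]]]$mispairs
          mps[k] <- min(as.integer(sample(names(w), 1L, prob = w)), kk)
          logw <- logw + log(mpWeight(sec, ids[k], mps[k]))
        }
        if (cutoff <= 0 || logw >= log(cutoff) - 1e-12) break
      }
      frags <- vector("list", length(els))
      for (k in seq_along(els)) {
        freq <- sec[[ids[k]]]$freq
        if (sum(freq) == 0) freq <- rep(0.25, 4)
        frags[[k]] <- sample(NUCS, lens[k], replace = TRUE, prob = freq)
      }
      for (k in seq_along(els)) {
        e <- els[[k]]
        if (e$type != "strand5") next
        m <- match(e$partner, ids)
        l5 <- lens[k]; l3 <- lens[m]
        kk <- min(l5, l3)
        if (kk > 0L) {
          prox5 <- frags[[k]][l5 - seq_len(kk) + 1L]
          frags[[m]][seq_len(kk)] <- unname(RNA_COMPLEMENT[prox5])
          if (mps[k] > 0L) {
            at <- sample(seq_len(kk), mps[k])
            for (t in at) {
              a <- prox5[t]
              bad <- NUCS[!(paste0(a, NUCS) %in% CANONICAL_PAIRS)]
              frags[[m]][t] <- sample(bad, 1L)
            }
          }
        }
      }
      collapseChars(unlist(frags))
    }, character(1))
  })
}
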