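#' Derive ordered structural elements from column base pairs
#'
#' Maximal runs of consecutive nested pairs become helices (a 5' strand and
#' a 3' strand element each); all remaining columns form single-strand
#' elements (classified as hairpin loop, internal/multistem region, or
#' 5'/3' tail). Crossing (pseudoknotted) pairs are set aside as tertiary
#' constraints: they are flagged on the model but excluded from the element
#' ordering. Elements are ordered 5' to 3' and tile every column exactly
#' once.
#'
#' @param pairs two-column integer matrix of paired columns.
#' @param ncol total number of columns.
#' @return a [StructureModel].
#' @examples
#' m <- deriveElements(cbind(1:4, 12:9), 14)
#' elementTable(m)
#' @export
deriveElements <- function(pairs, ncol) {
  ncol <- as.integer(ncol)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    storage.mode(pairs) <- "integer"
    dimnames(pairs) <- NULL
    if (any(pairs < 1L | pairs > ncol)) stop("pair column out of range")
    if (anyDuplicated(as.vector(pairs)))
      stop("structure-format error: a column is paired twice")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  # nested skeleton: keep pairs compatible with all previously kept ones
  kept <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ok <- TRUE
    for (j in which(kept)) {
      a <- pairs[j, ]; b <- pairs[i, ]
      crossing <- (a[1] < b[1] & b[1] < a[2] & a[2] < b[2]) ||
                  (b[1] < a[1] & a[1] < b[2] & b[2] < a[2])
      if (crossing) { ok <- FALSE; break }
    }
    kept[i] <- ok
  }
  nested <- pairs[kept, , drop = FALSE]
  tertiary <- pairs[!kept, , drop = FALSE]
  # helices: maximal runs of consecutive nested pairs
  helixId <- integer(nrow(nested))
  h <- 0L
  for (i in seq_len(nrow(nested))) {
    if (i > 1L && nested[i, 1] == nested[i - 1L, 1] + 1L &&
        nested[i, 2] == nested[i - 1L, 2] - 1L) {
      helixId[i] <- h
    } else {
      h <- h + 1L
      helixId[i] <- h
    }
  }
  colOwner <- integer(ncol)     # 0 = single strand, else helix id
  colStrand <- integer(ncol)    # 1 = 5' strand, 2 = 3' strand
  for (i in seq_len(nrow(nested))) {
    colOwner[nested[i, 1]] <- helixId[i]; colStrand[nested[i, 1]] <- 1L
    colOwner[nested[i, 2]] <- helixId[i]; colStrand[nested[i, 2]] <- 2L
  }
  elements <- list()
  i <- 1L; eid <- 0L
  while (i <= ncol) {
    j <- i
    while (j < ncol && colOwner[j + 1L] == colOwner[i] &&
           colStrand[j + 1L] == colStrand[i]) j <- j + 1L
    eid <- eid + 1L
    type <- if (colOwner[i] == 0L) "ss" else
      c("strand5", "strand3")[colStrand[i]]
    elements[[eid]] <- list(id = sprintf("e%d", eid), type = type,
                            helix = colOwner[i], partner = NA_character_,
                            cols = i:j, role = NA_character_)
    i <- j + 1L
  }
  # partner links and single-strand roles
  types <- vapply(elements, `[[`, character(1), "type")
  helixOf <- vapply(elements, `[[`, integer(1), "helix")
  for (k in seq_along(elements)) {
    if (types[k] != "ss") {
      mate <- which(helixOf == helixOf[k] & seq_along(elements) != k)
      elements[[k]]$partner <- elements[[mate]]$id
    } else {
      before <- any(types[seq_len(k - 1L)] != "ss")
      after <- any(types[-seq_len(k)] != "ss")
      elements[[k]]$role <-
        if (!before) "tail5"
        else if (!after) "tail3"
        else if (k > 1L && k < length(elements) &&
                 types[k - 1L] == "strand5" && types[k + 1L] == "strand3" &&
                 helixOf[k - 1L] == helixOf[k + 1L]) "hairpin"
        else "internal"
    }
  }
  new("StructureModel", ncol = ncol, pairs = nested, tertiary = tertiary,
      elements = elements)
}

#' @rdname elementTable
#' @export
setMethod("elementTable", "StructureModel", function(x) {
  data.frame(
    id = vapply(x@elements, `[[`, character(1), "id"),
    type = vapply(x@elements, `[[`, character(1), "type"),
    partner = vapply(x@elements, `[[`, character(1), "partner"),
    role = vapply(x@elements, `[[`, character(1), "role"),
    start = vapply(x@elements, function(e) min(e$cols), integer(1)),
    end = vapply(x@elements, function(e) max(e$cols), integer(1)))
})

#' @rdname elementTable
#' @export
setMethod("elementTable", "StructureDescriptor",
          function(x) elementTable(x@model))

#' @rdname basePairs
#' @export
setMethod("basePairs", "StructureModel", function(x) x@pairs)

setMethod("show", "StructureModel", function(object) {
  et <- elementTable(object)
  cat(sprintf("StructureModel: %d columns, %d nested pairs, %d helices, %d elements\n",
              object@ncol, nrow(object@pairs),
              length(unique(et$partner[et$type == "strand5"])),
              nrow(et)))
  if (nrow(object@tertiary))
    cat(sprintf("  %d crossing pair(s) flagged as tertiary\n",
                nrow(object@tertiary)))
})

#' Build a structure descriptor from a template and its structure
#'
#' Generates, for the root and for every taxon holding at least
#' `minSequences` sequences, the constraint section of each structural
#' element: a length histogram (per-sequence non-gap residue counts within
#' the element's columns, weighted by observed frequency), a mispair-count
#' histogram for helices (a mispair is an opposed residue pair that is not
#' AU/UA/GC/CG/GU/UG), a pooled nucleotide-frequency profile, and a mean
#' conservation. The per-section weight-score cutoff is the minimum over
#' the section's sequences of the product of their observed length and
#' mispair weights, so every template sequence satisfies its own descriptor
#' by construction.
#'
#' @param x a [TemplateAlignment].
#' @param structure a [StructureModel], or a two-column pair matrix (the
#'   template's own pairs are used when NULL).
#' @param minSequences minimum sequences for a taxon section (default 2).
#' @return a [StructureDescriptor].
#' @export
buildDescriptor <- function(x, structure = NULL, minSequences = 2L) {
  if (is.null(structure)) {
    if (!nrow(x@pairs)) stop("template carries no structure; supply pairs")
    structure <- deriveElements(x@pairs, alignmentWidth(x))
  } else if (is.matrix(structure)) {
    structure <- deriveElements(structure, alignmentWidth(x))
  }
  if (structure@ncol != alignmentWidth(x))
    stop("structure width does not match the alignment")
  tree <- x@taxonomy
  counts <- vapply(tree@nodes, function(t) length(taxonMembers(x, t)),
                   integer(1))
  secTaxa <- tree@nodes[counts >= minSequences & tree@nodes != taxonomyRoot(tree)]
  sections <- list(root = descriptorSection(x, structure, seq_len(nSequences(x))))
  for (t in secTaxa) sections[[t]] <- descriptorSection(x, structure,
                                                        taxonMembers(x, t))
  cutoffs <- vapply(sections, attr, numeric(1), "cutoff")
  sections <- lapply(sections, function(s) { attr(s, "cutoff") <- NULL; s })
  new("StructureDescriptor", model = structure, sections = sections,
      cutoffs = cutoffs,
      params = list(minSequences = as.integer(minSequences),
                    canonical = CANONICAL_PAIRS))
}

descriptorSection <- function(x, model, rows) {
  mat <- x@mat[rows, , drop = FALSE]
  n <- length(rows)
  sec <- list()
  logW <- rep(0, n)   # per-sequence log product of observed weights
  for (e in model@elements) {
    sub <- mat[, e$cols, drop = FALSE]
    lens <- rowSums(matrix(isNuc(sub), nrow = n))
    lt <- table(lens) / n
    lengths <- stats::setNames(as.numeric(lt), names(lt))
    counts <- vapply(NUCS, function(p) sum(sub == p), numeric(1))
    freq <- if (sum(counts) > 0) counts / sum(counts) else counts
    cons <- mean(colMeans(matrix(sub != GAP, nrow = n)))
    entry <- list(lengths = lengths, freq = freq, conservation = cons)
    if (e$type != "ss") {
      # per-position profile: helix strands are length-stable, so their
      # column-wise frequencies anchor the strand during search
      pf <- vapply(seq_along(e$cols), function(ci)
        vapply(NUCS, function(p) sum(sub[, ci] == p), numeric(1)),
        numeric(4))
      tot <- colSums(pf)
      entry$posFreq <- sweep(matrix(pf, nrow = 4,
                                    dimnames = list(NUCS, NULL)),
                             2, ifelse(tot == 0, 1, tot), "/")
    }
    if (e$type == "strand5") {
      hp <- model@pairs[model@pairs[, 1] %in% e$cols, , drop = FALSE]
      mp <- vapply(seq_len(n), function(si) {
        a <- mat[si, hp[, 1]]; b <- mat[si, hp[, 2]]
        both <- isNuc(a) & isNuc(b)
        sum(both & !(paste0(a, b) %in% CANONICAL_PAIRS))
      }, numeric(1))
      mt <- table(mp) / n
      entry$mispairs <- stats::setNames(as.numeric(mt), names(mt))
      logW <- logW + log(entry$mispairs[as.character(mp)])
    }
    logW <- logW + log(lengths[as.character(lens)])
    sec[[e$id]] <- entry
  }
  attr(sec, "cutoff") <- exp(min(logW))
  sec
}

#' @rdname profileTaxa
#' @export
setMethod("profileTaxa", "StructureDescriptor",
          function(x) names(x@sections))

setMethod("show", "StructureDescriptor", function(object) {
  cat(sprintf("StructureDescriptor: %d elements, sections: %s\n",
              length(object@model@elements),
              paste(names(object@sections), collapse = ", ")))
  cat(sprintf("  weight-score cutoffs: %s\n",
              paste(sprintf("%s=%.3g", names(object@cutoffs),
                            object@cutoffs), collapse = ", ")))
})

## ---- descriptor text format --------------------------------------------

#' Write / read the versioned descriptor text format
#'
#' A plain-text, line-oriented serialization of a [StructureDescriptor]
#' (sections: model pairs, elements, per-section constraints with full
#' floating-point precision). `readDescriptor(writeDescriptor(x))`
#' reproduces the descriptor exactly.
#'
#' @param x a [StructureDescriptor].
#' @param path file path.
#' @return `writeDescriptor` returns `path` invisibly; `readDescriptor`
#'   the restored [StructureDescriptor].
#' @export
writeDescriptor <- function(x, path) {
  num <- function(v) sprintf("%.17g", v)
  out <- c("# tralign descriptor v1",
           paste("ncol", x@model@ncol),
           paste("minSequences", x@params$minSequences))
  if (nrow(x@model@pairs))
    out <- c(out, paste("pair", x@model@pairs[, 1], x@model@pairs[, 2]))
  if (nrow(x@model@tertiary))
    out <- c(out, paste("tertiary", x@model@tertiary[, 1],
                        x@model@tertiary[, 2]))
  for (sn in names(x@sections)) {
    out <- c(out, paste("section", sn),
             paste("cutoff", num(x@cutoffs[[sn]])))
    sec <- x@sections[[sn]]
    for (en in names(sec)) {
      el <- sec[[en]]
      out <- c(out, paste("element", en),
               paste("lengths", paste(names(el$lengths),
                                      num(el$lengths), sep = "=",
                                      collapse = " ")),
               paste("freq", paste(names(el$freq), num(el$freq),
                                   sep = "=", collapse = " ")),
               paste("conservation", num(el$conservation)))
      if (!is.null(el$posFreq))
        out <- c(out, paste("posfreq",
                            paste(num(as.vector(el$posFreq)),
                                  collapse = " ")))
      if (!is.null(el$mispairs))
        out <- c(out, paste("mispairs",
                            paste(names(el$mispairs), num(el$mispairs),
                                  sep = "=", collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname writeDescriptor
#' @export
readDescriptor <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", trimws(lines, "right"))
  if (!length(lines) || lines[1] != "# tralign descriptor v1")
    stop("not a tralign descriptor file")
  kv <- function(s) {
    parts <- strsplit(s, " ", fixed = TRUE)[[1]]
    vals <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(as.numeric(vapply(vals, `[[`, character(1), 2L)),
                    vapply(vals, `[[`, character(1), 1L))
  }
  ncol <- NA_integer_; minSeq <- 2L
  pairs <- NULL; tertiary <- NULL
  sections <- list(); cutoffs <- numeric(0)
  curSec <- NULL; curEl <- NULL
  for (ln in lines[-1]) {
    if (!nzchar(ln)) next
    sp <- regmatches(ln, regexpr("^\\S+", ln))
    rest <- trimws(sub("^\\S+\\s*", "", ln))
    switch(sp,
      ncol = { ncol <- as.integer(rest) },
      minSequences = { minSeq <- as.integer(rest) },
      pair = { p <- as.integer(strsplit(rest, " ")[[1]])
               pairs <- rbind(pairs, p) },
      tertiary = { p <- as.integer(strsplit(rest, " ")[[1]])
                   tertiary <- rbind(tertiary, p) },
      section = { curSec <- rest; sections[[curSec]] <- list() },
      cutoff = { cutoffs[[curSec]] <- as.numeric(rest) },
      element = { curEl <- rest; sections[[curSec]][[curEl]] <- list() },
      lengths = { sections[[curSec]][[curEl]]$lengths <- kv(rest) },
      freq = { sections[[curSec]][[curEl]]$freq <- kv(rest) },
      conservation = { sections[[curSec]][[curEl]]$conservation <-
                         as.numeric(rest) },
      mispairs = { sections[[curSec]][[curEl]]$mispairs <- kv(rest) },
      posfreq = { v <- as.numeric(strsplit(rest, " ", fixed = TRUE)[[1]])
                  sections[[curSec]][[curEl]]$posFreq <-
                    matrix(v, nrow = 4, dimnames = list(NUCS, NULL)) },
      stop("unknown descriptor line: ", ln))
  }
  allPairs <- rbind(pairs, tertiary)
  model <- deriveElements(if (is.null(allPairs)) matrix(integer(0), ncol = 2)
                          else allPairs, ncol)
  # reorder section entries to element order
  ids <- vapply(model@elements, `[[`, character(1), "id")
  sections <- lapply(sections, function(s) s[ids])
  new("StructureDescriptor", model = model, sections = sections,
      cutoffs = cutoffs,
      params = list(minSequences = minSeq, canonical = CANONICAL_PAIRS))
}
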