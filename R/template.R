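#' Ingest a gapped alignment into a TemplateAlignment
#'
#' Normalises the alphabet (uppercase, T to U, `.` to `-`), computes the
#' 5'/3'-partial extents, and attaches taxon labels. Symbols outside the
#' IUPAC nucleotide set raise a per-sequence warning and are replaced by
#' gaps. All-gap columns are dropped (with a message) so that every retained
#' column has at least one non-gap symbol.
#'
#' @param records named character vector (or list) of equal-length gapped
#'   sequences; names are the sequence identifiers.
#' @param taxonMap named character vector mapping every identifier to a
#'   taxon name present in `taxonomyTree`.
#' @param taxonomyTree a [TaxonomyTree].
#' @param pairs optional two-column integer matrix of paired columns.
#' @return a [TemplateAlignment]; sequence order is preserved.
#' @examples
#' tax <- taxonomyFromLineages(c("root;a", "root;b"))
#' aln <- ingestAlignment(c(s1 = "ACGU-", s2 = "ACG-U"),
#'                        c(s1 = "a", s2 = "b"), tax)
#' alignmentMatrix(aln)
#' @export
ingestAlignment <- function(records, taxonMap, taxonomyTree, pairs = NULL) {
  records <- unlist(records)
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids))) stop("records must be named")
  widths <- nchar(records)
  if (length(unique(widths)) != 1L)
    stop("format error: gapped sequences have unequal lengths (",
         paste(range(widths), collapse = "-"), ")")
  missing <- setdiff(ids, names(taxonMap))
  if (length(missing))
    stop("no taxon mapping for sequence(s): ", paste(missing, collapse = ", "))
  mat <- do.call(rbind, lapply(records, splitChars))
  rownames(mat) <- ids
  mat[] <- normalizeSymbols(mat)
  bad <- !(mat %in% c(IUPAC, GAP))
  if (any(bad)) {
    rows <- unique(rownames(mat)[row(mat)[bad]])
    warning("unknown symbol(s) treated as gaps in sequence(s): ",
            paste(rows, collapse = ", "))
    mat[bad] <- GAP
  }
  keep <- colSums(mat != GAP) > 0L
  if (!all(keep)) {
    message(sum(!keep), " all-gap column(s) dropped")
    mat <- mat[, keep, drop = FALSE]
    if (!is.null(pairs) && nrow(pairs)) {
      remap <- cumsum(keep)
      ok <- keep[pairs[, 1]] & keep[pairs[, 2]]
      pairs <- cbind(remap[pairs[ok, 1]], remap[pairs[ok, 2]])
    }
  }
  nonGap <- mat != GAP
  firstRes <- apply(nonGap, 1L, function(z) which(z)[1])
  lastRes <- apply(nonGap, 1L, function(z) max(which(z)))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2L)
  storage.mode(pairs) <- "integer"
  new("TemplateAlignment", mat = mat,
      taxon = unname(taxonMap[ids]), taxonomy = taxonomyTree,
      pairs = pairs, firstRes = as.integer(firstRes),
      lastRes = as.integer(lastRes))
}

#' @rdname alignmentMatrix
#' @export
setMethod("alignmentMatrix", "TemplateAlignment", function(x) x@mat)

#' @rdname taxonLabels
#' @export
setMethod("taxonLabels", "TemplateAlignment",
          function(x) stats::setNames(x@taxon, rownames(x@mat)))

#' @rdname taxonomy
#' @export
setMethod("taxonomy", "TemplateAlignment", function(x) x@taxonomy)

#' @rdname basePairs
#' @export
setMethod("basePairs", "TemplateAlignment", function(x) x@pairs)

#' Number of sequences / alignment width
#' @param x a [TemplateAlignment].
#' @return integer.
#' @export
nSequences <- function(x) nrow(x@mat)

#' @rdname nSequences
#' @export
alignmentWidth <- function(x) ncol(x@mat)

#' Sequence identifiers of a template alignment
#' @param x a [TemplateAlignment].
#' @return character vector.
#' @export
sequenceIds <- function(x) rownames(x@mat)

#' Rows belonging to a taxon (including its descendants)
#' @param x a [TemplateAlignment].
#' @param taxon taxon name.
#' @return integer row indices.
#' @export
taxonMembers <- function(x, taxon)
  which(isWithinTaxon(x@taxonomy, x@taxon, taxon))

#' Gapped row as a string
#' @param x a [TemplateAlignment].
#' @param i row index or identifier.
#' @return single string.
#' @export
gappedRow <- function(x, i) collapseChars(x@mat[i, ])

#' Ungapped sequence of a template row
#' @param x a [TemplateAlignment].
#' @param i row index or identifier.
#' @return single string without gaps.
#' @export
degappedRow <- function(x, i) {
  r <- x@mat[i, ]
  collapseChars(r[r != GAP])
}

setMethod("show", "TemplateAlignment", function(object) {
  cat(sprintf("TemplateAlignment: %d sequences x %d columns\n",
              nrow(object@mat), ncol(object@mat)))
  tab <- table(object@taxon)
  cat("  taxa:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  if (nrow(object@pairs))
    cat(sprintf("  structure: %d column base pairs\n", nrow(object@pairs)))
})

## ---- file formats -------------------------------------------------------

#' Read a template alignment from gapped FASTA or Stockholm
#'
#' @param path alignment file.
#' @param taxonomyPath taxonomy TSV (see [readTaxonomyTSV()]).
#' @param format `"fasta"` or `"stockholm"`; the default guesses from the
#'   first non-blank line.
#' @return a [TemplateAlignment].
#' @export
readTemplateAlignment <- function(path, taxonomyPath,
                                  format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  recs <- switch(format,
    fasta = {
      set <- Biostrings::readBStringSet(path)
      stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
    },
    stockholm = readStockholm(path))
  tx <- readTaxonomyTSV(taxonomyPath)
  ingestAlignment(recs, tx$taxonMap, tx$taxonomy)
}

#' Write a template alignment
#'
#' @param x a [TemplateAlignment].
#' @param path output file.
#' @param format `"fasta"` (gapped FASTA) or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
writeTemplateAlignment <- function(x, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  rows <- apply(x@mat, 1L, collapseChars)
  if (format == "fasta") {
    set <- Biostrings::BStringSet(rows)
    Biostrings::writeXStringSet(set, path)
  } else {
    writeStockholm(rows, path)
  }
  invisible(path)
}

# minimal Stockholm 1.0 reader: concatenates multi-block sequence lines,
# ignores #= annotation lines; tolerates CRLF and trailing whitespace.
readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines, which = "right")
  seqs <- list()
  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#") || ln == "//") next
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed Stockholm line: ", ln)
    seqs[[m[2]]] <- paste0(if (is.null(seqs[[m[2]]])) "" else seqs[[m[2]]], m[3])
  }
  if (!length(seqs)) stop("no sequences found in Stockholm file")
  unlist(seqs)
}

writeStockholm <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  pad <- max(nchar(names(rows))) + 2L
  writeLines(sprintf("%-*s%s", pad, names(rows), rows), con)
  writeLines("//", con)
  invisible(path)
}
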