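# Readers/writers for per-sequence secondary-structure files (CT, bpseq,
# dot-bracket), all with 1-based positions. Internally a structure is a
# list(seq = character string, pairs = two-column matrix with i < j).

#' Write a secondary structure file
#'
#' @param seq ungapped sequence (single string).
#' @param pairs two-column integer matrix of paired positions (i, j).
#' @param path output file.
#' @param format `"ct"`, `"bpseq"` or `"dbn"` (dot-bracket; nested pairs
#'   only).
#' @param name record name written to the header.
#' @return `path`, invisibly.
#' @export
writeStructureFile <- function(seq, pairs, path,
                               format = c("ct", "bpseq", "dbn"),
                               name = "structure") {
  format <- match.arg(format)
  chars <- splitChars(seq)
  n <- length(chars)
  partner <- integer(n)
  if (!is.null(pairs) && nrow(pairs)) {
    if (any(pairs < 1L | pairs > n)) stop("pair position out of range")
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  lines <- switch(format,
    ct = c(sprintf("%d %s", n, name),
           sprintf("%d %s %d %d %d %d", seq_len(n), chars,
                   seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                   partner, seq_len(n))),
    bpseq = sprintf("%d %s %d", seq_len(n), chars, partner),
    dbn = {
      db <- rep(".", n)
      if (!is.null(pairs) && nrow(pairs)) {
        ord <- order(pairs[, 1])
        for (i in ord) {
          db[min(pairs[i, ])] <- "("
          db[max(pairs[i, ])] <- ")"
        }
      }
      c(paste0(">", name), seq, collapseChars(db))
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read a secondary structure file
#'
#' @param path input file.
#' @param format `"ct"`, `"bpseq"` or `"dbn"`; guessed from content when
#'   `"auto"`.
#' @return list with `seq` (single string), `pairs` (two-column matrix,
#'   i < j) and `name`.
#' @export
readStructureFile <- function(path, format = c("auto", "ct", "bpseq", "dbn")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", trimws(lines, "right"))
  lines <- lines[nzchar(lines)]
  if (format == "auto") {
    f1 <- strsplit(lines[1], "\\s+")[[1]]
    format <- if (startsWith(lines[1], ">")) "dbn"
      else if (length(f1) == 3L && f1[1] == "1" &&
               !is.na(suppressWarnings(as.integer(f1[3])))) "bpseq"
      else "ct"
  }
  switch(format,
    dbn = {
      name <- sub("^>", "", lines[1])
      seq <- lines[2]
      db <- splitChars(lines[3])
      stack <- integer(0); pairs <- NULL
      for (i in seq_along(db)) {
        if (db[i] == "(") stack <- c(stack, i)
        else if (db[i] == ")") {
          pairs <- rbind(pairs, c(stack[length(stack)], i))
          stack <- stack[-length(stack)]
        }
      }
      if (length(stack)) stop("unbalanced dot-bracket string")
      list(seq = seq, pairs = pairMat(pairs), name = name)
    },
    ct = {
      hdr <- strsplit(lines[1], "\\s+")[[1]]
      n <- as.integer(hdr[1])
      name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else ""
      rows <- lapply(lines[1 + seq_len(n)], function(l)
        strsplit(l, "\\s+")[[1]])
      chars <- vapply(rows, `[[`, character(1), 2L)
      partner <- as.integer(vapply(rows, `[[`, character(1), 5L))
      keep <- partner > seq_len(n)
      list(seq = collapseChars(chars),
           pairs = pairMat(cbind(seq_len(n)[keep], partner[keep])),
           name = name)
    },
    bpseq = {
      rows <- lapply(lines, function(l) strsplit(l, "\\s+")[[1]])
      chars <- vapply(rows, `[[`, character(1), 2L)
      partner <- as.integer(vapply(rows, `[[`, character(1), 3L))
      n <- length(chars)
      keep <- partner > seq_len(n)
      list(seq = collapseChars(chars),
           pairs = pairMat(cbind(seq_len(n)[keep], partner[keep])),
           name = "")
    })
}

pairMat <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(matrix(integer(0), ncol = 2L))
  out <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  storage.mode(out) <- "integer"
  out[order(out[, 1]), , drop = FALSE]
}

#' Base pairs of a structure instance in query coordinates
#'
#' For every helix with both strands placed, the loop-proximal ends are
#' opposed pair by pair over the shorter strand length.
#'
#' @param instance a [StructureInstance].
#' @param descriptor the [StructureDescriptor] the instance was built from.
#' @return two-column integer matrix of paired query positions.
#' @export
instancePairs <- function(instance, descriptor) {
  pl <- instance@placements
  pairs <- NULL
  for (e in descriptor@model@elements) {
    if (e$type != "strand5") next
    r5 <- pl[pl$id == e$id, ]
    r3 <- pl[pl$id == e$partner, ]
    if (!nrow(r5) || !nrow(r3) || is.na(r5$start) || is.na(r3$start)) next
    k <- min(r5$length, r3$length)
    if (k < 1L) next
    pairs <- rbind(pairs, cbind(r5$end - seq_len(k) + 1L,
                                r3$start + seq_len(k) - 1L))
  }
  pairMat(pairs)
}

#' Export a structure instance to CT, bpseq or dot-bracket
#'
#' Partial instances export with unplaced regions unpaired.
#'
#' @param instance a [StructureInstance] (must cover at least one element).
#' @param descriptor the [StructureDescriptor] used for the search.
#' @param path output file.
#' @param format `"ct"`, `"bpseq"` or `"dbn"`.
#' @return `path`, invisibly.
#' @export
exportStructure <- function(instance, descriptor, path,
                            format = c("ct", "bpseq", "dbn")) {
  format <- match.arg(format)
  if (!any(!is.na(instance@placements$start)))
    stop("instance is empty; nothing to export")
  writeStructureFile(instance@query, instancePairs(instance, descriptor),
                     path, format, name = instance@queryId)
}
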