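#' Toy 10-sequence profile template (synthetic reconstruction)
#'
#' A small worked example for the profile/block engine: a template alignment
#' of 10 sequences and 37 columns over three nested taxa (bacillales inside
#' bacilli inside the bacteria root). It is constructed so that the
#' statistics it yields are the classic worked values for this kind of
#' profile: 28 root-conserved columns falling into six blocks of
#' (5, 5, 5, 5, 5, 3) conserved columns; a conserved column whose
#' composition is \{C 1/3, G 2/3\} in bacillales and \{A 1/7, C 2/7, G 4/7\}
#' in bacilli; a block-5 column conserved in 6 of 7 bacilli sequences (0.86)
#' next to columns conserved in all 7 (1.0); a block-5 average score of
#' about 1.665 at the bacilli node; a block scoring the 1.8 maximum at the
#' bacillales node; and three root-level sequences truncated at their 5'
#' end, which does not depress conservation there. The sequence letters are
#' synthetic: the fixture is engineered to reproduce those numbers, not
#' transcribed from any real alignment.
#'
#' @return list with `template` (a [TemplateAlignment]), `taxonomy`, and
#'   `notes` (named list locating the designed features: the composition
#'   column, the 6/7 and 7/7 conservation columns).
#' @examples
#' fx <- toyProfileTemplate()
#' partitionBlocks(fx$template, conservedPerBlock = 5)
#' @export
toyProfileTemplate <- function() {
  seqs <- c(
    s1  = "UGC-UGACCCGCAGGCCUC-UAGGG-GGAGUUGU-UA",
    s2  = "UGC-UGACCGGCAGGCCUC-UAGGG-GGAGUUGU-UA",
    s3  = "UGCAUGACCGG-AGGCCUC-UAGGG-GGAGUUGUCUA",
    s4  = "UGCAUGACCAG-AGGCCUCGUAGGG-GGAGUU-UCUA",
    s5  = "UGCAUGACCCG-AGGCCUCGUAGGG--GGGUU-UCUA",
    s6  = "UGCAUG-CCGGCAGGC-UCGUGGGG--GGGUUGUCUA",
    s7  = "UGCAUG-CCGGCAGGC-UCGUGGGG-G-GGUUGUCUA",
    s8  = "-GCAUGACCGGCAGGCCUCGUAGGGAGGAGUUGUCUA",
    s9  = "--CAUGACCGGCAGGCCUCGUAGGGAGGAGUUGUCUA",
    s10 = "--CAUGACCGGCAGGCCUCGUAGGGAGGAGUUGUCUA")
  tax <- taxonomyFromLineages(c("bacteria;bacilli;bacillales",
                                "bacteria;bacilli",
                                "bacteria"))
  taxonMap <- stats::setNames(
    c(rep("bacillales", 3), rep("bacilli", 4), rep("bacteria", 3)),
    names(seqs))
  template <- ingestAlignment(seqs, taxonMap, tax)
  list(template = template, taxonomy = tax,
       notes = list(compositionColumn = 10L,
                    conservation67Column = 28L,
                    conservation77Column = 29L,
                    blockSize = 5L, minSequences = 3L))
}

#' Toy 7-sequence structured template (synthetic)
#'
#' A small structured alignment for the descriptor engine: 7 sequences in
#' three phylogenetic nodes under a root, folded into two helices (5 and 3
#' base pairs) separated by loops, with a 5' tail and a 3' tail. Element
#' lengths vary across sequences (one sequence has a one-nucleotide longer
#' hairpin loop; one sequence carries a single mispair in the first helix)
#' so that descriptor histograms have non-trivial weights.
#'
#' @return list with `template` (a [TemplateAlignment] carrying column base
#'   pairs), `taxonomy`, `pairs` (the base-pair matrix) and `layout` (the
#'   element column layout used for construction).
#' @export
toyStructureTemplate <- function() {
  # column layout (38 columns):
  # tail5 1-3 | helixA5 4-8 | loopA 9-14 | helixA3 15-19 | ssI 20-24 |
  # helixB5 25-27 | loopB 28-31 | helixB3 32-34 | tail3 35-38
  pairs <- cbind(c(4:8, 25:27), c(19:15, 34:32))
  comp <- function(s) {
    chartr("ACGU", "UGCA", collapseChars(rev(splitChars(s))))
  }
  pad <- function(s, width) paste0(s, strrep("-", width - nchar(s)))
  buildRow <- function(t5, hA5, loopA, hA3, ssI, hB5, loopB, t3) {
    paste0(pad(t5, 3), hA5, pad(loopA, 6), hA3, pad(ssI, 5),
           hB5, pad(loopB, 4), comp(hB5), pad(t3, 4))
  }
  hA5 <- c(s1 = "GCGCA", s2 = "GCGCA", s3 = "GCGCU", s4 = "GCGCU",
           s5 = "GCACA", s6 = "GCACA", s7 = "GCACA")
  hA3 <- vapply(hA5, comp, character(1))
  hA3["s4"] <- "CGCGC"  # single U:C mispair at the closing pair of helix A
  rows <- c(
    s1 = buildRow("GAA", hA5["s1"], "UUCGA",  hA3["s1"], "AAUC", "GGC", "UUU",  "ACCA"),
    s2 = buildRow("GAA", hA5["s2"], "UUCGG",  hA3["s2"], "AAUC", "GGC", "UUU",  "ACCA"),
    s3 = buildRow("GAU", hA5["s3"], "UUUGA",  hA3["s3"], "AAU",  "GGC", "UUUA", "ACCA"),
    s4 = buildRow("GAU", hA5["s4"], "UUUGA",  hA3["s4"], "AAU",  "GGC", "UUUA", "ACCA"),
    s5 = buildRow("GA",  hA5["s5"], "UACGA",  hA3["s5"], "AAUCC","GGC", "UUU",  "ACC"),
    s6 = buildRow("GA",  hA5["s6"], "UACGA",  hA3["s6"], "AAUCC","GGC", "UUU",  "ACC"),
    s7 = buildRow("GA",  hA5["s7"], "UACGAA", hA3["s7"], "AAUCC","GGC", "UUU",  "ACC"))
  tax <- taxonomyFromLineages(c("root;node1", "root;node2", "root;node3"))
  taxonMap <- stats::setNames(
    c("node1", "node1", "node2", "node2", "node3", "node3", "node3"),
    names(rows))
  template <- ingestAlignment(rows, taxonMap, tax, pairs = pairs)
  list(template = template, taxonomy = tax, pairs = pairs,
       layout = list(tail5 = 1:3, helixA5 = 4:8, loopA = 9:14,
                     helixA3 = 15:19, ssI = 20:24, helixB5 = 25:27,
                     loopB = 28:31, helixB3 = 32:34, tail3 = 35:38))
}
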