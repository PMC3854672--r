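fx <- toyProfileTemplate()
tpl <- fx$template
prof <- buildProfile(tpl, blockSize = 5, minSequences = 3)

test_that("degapped template members recover their own rows", {
  for (id in setdiff(sequenceIds(tpl), "s7")) {
    res <- alignToProfile(degappedRow(tpl, id), prof,
                          hint = taxonLabels(tpl)[[id]], id = id)
    expect_identical(alignedRow(res), gappedRow(tpl, id), info = id)
    expect_identical(nrow(res@insertions), 0L, info = id)
  }
})

test_that("a block unmatched at the low taxon aligns at the parent", {
  # s7 lacks a nucleotide in one of the six bacillales-conserved columns of
  # block 5; at the bacilli node the block has only five conserved columns
  # and the subsequence matches without any deletion
  res <- alignToProfile(degappedRow(tpl, "s7"), prof,
                        hint = "bacillales", id = "s7")
  b5 <- res@blocks[res@blocks$block == 5, ]
  expect_identical(nrow(b5), 1L)
  expect_identical(b5$taxon, "bacilli")
  expect_identical(b5$deletions, 0L)
  # the five bacilli-conserved columns all received nucleotides
  Y <- prof@taxa$bacilli$conservedByBlock[[5]]
  row <- splitChars(alignedRow(res))
  expect_true(all(row[Y] != "-"))
})

test_that("strict-stage matching refuses conserved-column deletions", {
  # anchor s7's alignment outside block 5, then ask for block-5 matches at
  # the bacillales node, where the block has six conserved columns but the
  # query can supply at most five nucleotides: the strict stage finds
  # nothing, the relaxed stage matches by deleting a conserved column
  res <- alignToProfile(degappedRow(tpl, "s7"), prof, hint = "bacillales",
                        id = "s7")
  q <- splitChars(degappedRow(tpl, "s7"))
  ca <- res@colOf
  ca[!is.na(ca) & ca >= 26 & ca <= 32] <- NA    # clear the block-5 interval
  strict <- candidateMatches(q, ca, prof, "bacillales", 5, 1.62,
                             allowDeletion = FALSE, insertSlack = 2L)
  expect_length(strict, 0L)
  relaxed <- candidateMatches(q, ca, prof, "bacillales", 5, 1.296,
                              allowDeletion = TRUE, insertSlack = 10L,
                              maxDeletions = 2L)
  expect_gt(length(relaxed), 0L)
  expect_true(all(vapply(relaxed, `[[`, numeric(1), "deletions") > 0))
})

test_that("an exact consensus subsequence yields a single strict match", {
  q <- splitChars(degappedRow(tpl, "s1"))
  ca <- rep(NA_integer_, length(q))
  cands <- candidateMatches(q, ca, prof, "bacillales", 4, 1.62,
                            allowDeletion = FALSE, insertSlack = 2L)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$score, 1.8, tolerance = 1e-9)
})

test_that("taxon selection follows hints, climbs to statistics, and falls
           back to the superficial pass", {
  expect_identical(selectTaxon(degappedRow(tpl, "s1"), prof,
                               hint = "bacillales"), "bacillales")
  # hint below the statistics threshold climbs to the nearest ancestor
  profRootOnly <- buildProfile(tpl, blockSize = 5, minSequences = 99)
  expect_identical(selectTaxon(degappedRow(tpl, "s1"), profRootOnly,
                               hint = "bacillales"), "bacteria")
  # unknown query identical to a bacillales member wins at bacillales
  expect_identical(selectTaxon(degappedRow(tpl, "s1"), prof), "bacillales")
  # a query aligning nothing anywhere ties at zero; the shallowest (most
  # general) taxon wins
  expect_identical(selectTaxon("AAAA", prof), "bacteria")
})

test_that("batch alignment equals aligning each query alone", {
  qs <- setNames(vapply(c("s1", "s4", "s9"), function(id)
    degappedRow(tpl, id), character(1)), c("s1", "s4", "s9"))
  hints <- setNames(taxonLabels(tpl)[names(qs)], names(qs))
  batch <- alignSequences(qs, prof, hints = hints)
  for (id in names(qs)) {
    solo <- alignToProfile(qs[[id]], prof, hint = hints[[id]], id = id)
    expect_identical(alignedRow(batch[[id]]), alignedRow(solo))
    expect_identical(batch[[id]]@colOf, solo@colOf)
  }
})

test_that("column assignments are strictly increasing and blocks immovable", {
  for (id in c("s1", "s5", "s8")) {
    res <- alignToProfile(degappedRow(tpl, id), prof,
                          hint = taxonLabels(tpl)[[id]], id = id)
    cols <- res@colOf[!is.na(res@colOf)]
    expect_true(all(diff(cols) > 0), info = id)
  }
})

test_that("residues beyond template capacity become insertion annotations", {
  q <- degappedRow(tpl, "s8")
  # splice extra nucleotides into the middle of a conserved run
  qIns <- paste0(substr(q, 1, 20), "AGUCA", substr(q, 21, nchar(q)))
  res <- alignToProfile(qIns, prof, hint = "bacteria", id = "ins")
  expect_gt(nrow(res@insertions), 0L)
  expect_identical(nchar(alignedRow(res)), alignmentWidth(tpl))
  # every query nucleotide is either placed or annotated
  expect_identical(sum(!is.na(res@colOf)) + nrow(res@insertions),
                   nchar(qIns))
})

test_that("an unalignable query is reported, not fatal", {
  res <- alignToProfile("AAAAAAAA", prof, id = "junk")
  expect_identical(nrow(res@blocks), 0L)
  expect_s4_class(res, "AlignedQuery")
})

test_that("alignment from a JSON-restored profile is identical", {
  f <- tempfile(fileext = ".json")
  writeProfileJSON(prof, f)
  prof2 <- readProfileJSON(f)
  for (id in c("s3", "s6")) {
    a <- alignToProfile(degappedRow(tpl, id), prof, hint = "bacilli")
    b <- alignToProfile(degappedRow(tpl, id), prof2, hint = "bacilli")
    expect_identical(alignedRow(a), alignedRow(b))
  }
})
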