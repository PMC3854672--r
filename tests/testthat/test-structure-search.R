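fx <- toyStructureTemplate()
tpl <- fx$template
desc <- buildDescriptor(tpl, minSequences = 2)

test_that("stringency ranking orders elements by chance expectation", {
  rk <- rankElements(desc, 40)
  # helix B (3 nt, composition-restricted, fixed length) is most stringent
  expect_identical(rk$id[1], "e6")
  expect_true(all(diff(rk$expected) >= -1e-12))
  # doubling the sequence length doubles every expectation, same order
  rk2 <- rankElements(desc, 80)
  expect_identical(rk$id, rk2$id)
  expect_equal(rk2$expected, 2 * rk$expected)
  # a long highly restricted single strand outranks a lax short loop
  tax <- taxonomyFromLineages("r;g")
  rows <- setNames(rep("GGGGGGGGGGGGGGGGGGGGACGUAAAA", 3), paste0("s", 1:3))
  aln <- ingestAlignment(rows, setNames(rep("g", 3), names(rows)), tax,
                         pairs = cbind(21:24, 28:25))
  d2 <- buildDescriptor(aln, minSequences = 3)
  rk3 <- rankElements(d2, 50)
  expect_identical(rk3$id[1], "e1")   # the 20-nt G-only strand
})

test_that("template members receive complete models with zero exceptions", {
  for (id in sequenceIds(tpl)) {
    inst <- findStructure(degappedRow(tpl, id), desc, "root", 0L,
                          queryId = id)
    expect_true(inst@complete, info = id)
    expect_identical(inst@exceptions, 0L, info = id)
    pl <- placements(inst)
    # placements tile the sequence in order
    expect_identical(pl$start[1], 1L)
    expect_identical(pl$end[nrow(pl)], nchar(degappedRow(tpl, id)))
    nonEmpty <- pl[pl$length > 0, ]
    expect_true(all(diff(nonEmpty$start) > 0))
  }
})

test_that("an out-of-histogram helix length costs exactly one exception", {
  # helix A lengthened to six pairs (its histogram supports only five)
  q <- "GAAAGCGCAUUCGAUGCGCUAAUCGGCUUUGCCACCA"
  i0 <- findStructure(q, desc, "root", 0L)
  i1 <- findStructure(q, desc, "root", 1L)
  expect_false(i0@complete)
  expect_true(i1@complete)
  expect_identical(i1@exceptions, 1L)
  expect_gte(sum(placements(i1)$exception), 1L)
  expect_lt(sum(!is.na(placements(i0)$start)), nrow(placements(i0)))
})

test_that("completeness is non-decreasing in the exception budget", {
  set.seed(42)
  qs <- sampleFromDescriptor(desc, 12, "root", seed = 11)
  # perturb some: lengthen or shorten a random stretch
  mutate <- function(s) {
    at <- sample(nchar(s) - 4, 1)
    if (runif(1) < 0.5) paste0(substr(s, 1, at), "A",
                               substr(s, at + 1, nchar(s)))
    else paste0(substr(s, 1, at), substr(s, at + 2, nchar(s)))
  }
  qs <- c(qs, vapply(qs[1:6], mutate, character(1)))
  prev <- rep(FALSE, length(qs))
  for (b in 0:2) {
    compl <- vapply(qs, function(q)
      findStructure(q, desc, "root", b)@complete, logical(1))
    expect_true(all(compl >= prev), info = sprintf("budget %d", b))
    prev <- compl
  }
})

test_that("the search is deterministic", {
  q <- degappedRow(tpl, "s3")
  a <- findStructure(q, desc, "root", 1L)
  b <- findStructure(q, desc, "root", 1L)
  expect_identical(placements(a), placements(b))
  expect_identical(a@complete, b@complete)
})

test_that("a sequence too short for any seed yields an empty partial", {
  inst <- findStructure("A", desc, "root", 0L)
  expect_false(inst@complete)
  expect_identical(sum(!is.na(placements(inst)$start)), 0L)
})

test_that("taxon sections match no more chance windows than the root", {
  set.seed(9)
  for (rep in 1:5) {
    q <- paste(sample(c("A", "C", "G", "U"), 150, replace = TRUE),
               collapse = "")
    nRoot <- countElementMatches(desc, q, "root")
    for (node in c("node1", "node2", "node3"))
      expect_lte(countElementMatches(desc, q, node), nRoot)
  }
})

test_that("descriptor-sampled sequences are identified completely", {
  qs <- sampleFromDescriptor(desc, 40, "root", seed = 3)
  compl <- vapply(qs, function(q)
    findStructure(q, desc, "root", 0L)@complete, logical(1))
  expect_true(all(compl))
})

test_that("structure files round-trip through ct, bpseq and dot-bracket", {
  inst <- findStructure(degappedRow(tpl, "s1"), desc, "root", 0L,
                        queryId = "s1")
  pairs <- instancePairs(inst, desc)
  expect_gt(nrow(pairs), 0L)
  for (fmt in c("ct", "bpseq", "dbn")) {
    f <- tempfile(fileext = paste0(".", fmt))
    exportStructure(inst, desc, f, fmt)
    back <- readStructureFile(f)
    expect_identical(back$seq, inst@query, info = fmt)
    expect_identical(back$pairs, pairs, info = fmt)
  }
  # a CT file has one row per nucleotide and symmetric pair columns
  f <- tempfile(fileext = ".ct")
  exportStructure(inst, desc, f, "ct")
  lines <- readLines(f)
  expect_identical(length(lines), nchar(inst@query) + 1L)
  # partial instance exports with unplaced regions unpaired in bpseq
  partial <- findStructure("AAAGGC", desc, "root", 0L, queryId = "p")
  if (any(!is.na(placements(partial)$start))) {
    fb <- tempfile(fileext = ".bpseq")
    exportStructure(partial, desc, fb, "bpseq")
    bk <- readStructureFile(fb)
    expect_identical(nchar(bk$seq), 6L)
  }
})
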