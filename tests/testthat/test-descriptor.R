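test_that("consecutive nested pairs form helices, the rest single strands", {
  m <- deriveElements(cbind(1:5, 14:10), 14)
  et <- elementTable(m)
  expect_identical(et$type, c("strand5", "ss", "strand3"))
  expect_identical(et$role[2], "hairpin")
  expect_identical(et$end - et$start + 1L, c(5L, 4L, 5L))
  # canonical hairpin with tails
  m2 <- deriveElements(cbind(3:6, 14:11), 16)
  expect_identical(elementTable(m2)$role,
                   c("tail5", NA, "hairpin", NA, "tail3"))
  # elements always tile the columns exactly once
  for (pairs in list(cbind(1:4, 20:17), cbind(c(2, 8), c(15, 11)))) {
    mm <- deriveElements(pairs, 20)
    expect_identical(sort(unlist(lapply(mm@elements, `[[`, "cols"))),
                     1:20)
  }
})

test_that("crossing pairs are flagged tertiary, duplicates rejected", {
  nested <- cbind(c(1, 2, 3), c(12, 11, 10))
  withCross <- rbind(nested, c(5, 14))
  m <- deriveElements(withCross, 14)
  expect_identical(nrow(m@pairs), 3L)
  expect_identical(unname(m@tertiary), cbind(5L, 14L))
  expect_error(deriveElements(rbind(nested, c(3, 8)), 14), "paired twice")
})

test_that("the toy structured template yields root plus three node sections", {
  fx <- toyStructureTemplate()
  desc <- buildDescriptor(fx$template, minSequences = 2)
  expect_identical(names(desc@sections),
                   c("root", "node1", "node2", "node3"))
  # hairpin loop histogram: six sequences at length 5, one at 6
  loopA <- desc@sections$root$e3
  expect_equal(loopA$lengths, c(`5` = 6 / 7, `6` = 1 / 7))
  # one sequence carries a single mispair in helix A
  expect_equal(desc@sections$root$e2$mispairs, c(`0` = 6 / 7, `1` = 1 / 7))
  # helix B is perfectly paired throughout
  expect_equal(desc@sections$root$e6$mispairs, c(`0` = 1))
  # weights are frequencies summing to one
  for (sec in desc@sections)
    for (el in sec) expect_equal(sum(el$lengths), 1)
})

test_that("identical sequences give point-mass histograms", {
  tax <- taxonomyFromLineages("r;g")
  rows <- setNames(rep("GGGAAAACCC", 3), paste0("s", 1:3))
  aln <- ingestAlignment(rows, setNames(rep("g", 3), names(rows)), tax,
                         pairs = cbind(1:3, 10:8))
  desc <- buildDescriptor(aln, minSequences = 3)
  for (el in desc@sections$root) {
    expect_length(el$lengths, 1L)
    expect_equal(unname(el$lengths), 1)
  }
  expect_equal(unname(desc@cutoffs["root"]), 1)
})

test_that("every template sequence satisfies its own descriptor", {
  fx <- toyStructureTemplate()
  desc <- buildDescriptor(fx$template, minSequences = 2)
  mat <- alignmentMatrix(fx$template)
  for (i in seq_len(nrow(mat))) {
    logw <- 0
    for (e in desc@model@elements) {
      len <- sum(mat[i, e$cols] %in% c("A", "C", "G", "U"))
      w <- desc@sections$root[[e$id]]$lengths[as.character(len)]
      expect_false(is.na(w) || w == 0)
      logw <- logw + log(w)
    }
    expect_gte(exp(logw), desc@cutoffs[["root"]] * (1 - 1e-9))
  }
})

test_that("descriptor text serialization round-trips losslessly", {
  fx <- toyStructureTemplate()
  desc <- buildDescriptor(fx$template, minSequences = 2)
  f <- tempfile(fileext = ".desc")
  writeDescriptor(desc, f)
  back <- readDescriptor(f)
  expect_identical(back@model@pairs, desc@model@pairs)
  expect_identical(elementTable(back), elementTable(desc))
  expect_equal(back@sections, desc@sections)
  expect_equal(back@cutoffs, desc@cutoffs)
  # and the round-trip is textually stable
  f2 <- tempfile(fileext = ".desc")
  writeDescriptor(back, f2)
  expect_identical(readLines(f), readLines(f2))
})
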