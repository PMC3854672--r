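test_that("generation is byte-identical under a fixed seed", {
  a <- synthTemplate(nTaxa = 2, seqsPerTaxon = 4, nColumns = 120, seed = 3)
  b <- synthTemplate(nTaxa = 2, seqsPerTaxon = 4, nColumns = 120, seed = 3)
  expect_identical(a$truth, b$truth)
  expect_identical(alignmentMatrix(a$template), alignmentMatrix(b$template))
  d <- synthTemplate(nTaxa = 2, seqsPerTaxon = 4, nColumns = 120, seed = 4)
  expect_false(identical(a$truth, d$truth))
  q1 <- synthQueries(a, n = 3, divergence = 0.1, seed = 5)
  q2 <- synthQueries(a, n = 3, divergence = 0.1, seed = 5)
  expect_identical(q1$queries, q2$queries)
})

test_that("zero substitution rate gives identical sequences and 1.8 blocks", {
  syn <- synthTemplate(nTaxa = 2, seqsPerTaxon = 4, nColumns = 120,
                       substitutionRate = 0, indelRate = 0, seed = 1)
  rows <- unique(syn$truth)
  expect_length(rows, 1L)
  prof <- buildProfile(syn$template, blockSize = 8, minSequences = 4)
  for (t in profileTaxa(prof))
    expect_equal(blockScores(prof, t),
                 rep(1.8, length(prof@blocks)), tolerance = 1e-12)
})

test_that("parameters outside their ranges are usage errors", {
  expect_error(synthTemplate(substitutionRate = 0.6), "substitutionRate")
  expect_error(synthTemplate(indelRate = -0.1), "indelRate")
  expect_error(synthQueries(synthTemplate(nColumns = 60, seqsPerTaxon = 2),
                            divergence = 0.7), "divergence")
  expect_error(synthTemplate(nColumns = 50, structured = TRUE),
               "multiple of 60")
})

test_that("pairwise identities bracket the requested mutation band", {
  syn <- synthTemplate(nTaxa = 3, seqsPerTaxon = 10, nColumns = 300,
                       substitutionRate = 0.05, seed = 1)
  mat <- alignmentMatrix(syn$template)
  set.seed(1)
  ids <- sequenceIds(syn$template)
  psis <- replicate(100, {
    p <- sample(ids, 2)
    pairwiseIdentity(mat, p[1], p[2], method = "matched")
  })
  # within-taxon pairs differ by ~2 rounds of 5% substitution, between-taxon
  # pairs by ~4; matched identity should sit between those extremes
  expect_gt(mean(psis), 1 - 4 * 2 * 0.05)
  expect_lt(mean(psis), 1 - 0.5 * 2 * 0.05 * 3 / 4)
  expect_true(all(psis > 0.5))
})

test_that("divergence-0 complete queries are recovered by both engines", {
  syn <- synthTemplate(nTaxa = 2, seqsPerTaxon = 5, nColumns = 120,
                       structured = TRUE, seed = 2)
  qs <- synthQueries(syn, n = 3, divergence = 0, seed = 3)
  prof <- buildProfile(syn$template, blockSize = 8, minSequences = 5)
  desc <- buildDescriptor(syn$template, minSequences = 5)
  cons <- which(conservationValue(syn$template,
                                  taxonomyRoot(taxonomy(syn$template))) > 0.8)
  for (id in names(qs$queries)) {
    bq <- alignToProfile(qs$queries[[id]], prof,
                         hint = qs$taxon[[id]], id = id)
    expect_equal(conservedColumnRecovery(bq, qs$truth[[id]], cons), 1.0,
                 info = paste("block", id))
    sq <- alignWithStructure(qs$queries[[id]], syn$template, desc, id = id)
    expect_identical(alignedRow(sq), unname(qs$truth[id]),
                     info = paste("structure", id))
  }
})

test_that("truncated queries fail the structure engine, pass the block one", {
  syn <- synthTemplate(nTaxa = 2, seqsPerTaxon = 5, nColumns = 120,
                       structured = TRUE, seed = 2)
  qs <- synthQueries(syn, n = 2, divergence = 0,
                     completenessFraction = 0.7, seed = 4)
  desc <- buildDescriptor(syn$template, minSequences = 5)
  prof <- buildProfile(syn$template, blockSize = 8, minSequences = 5)
  for (id in names(qs$queries)) {
    inst <- findStructure(qs$queries[[id]], desc, "root", 0L)
    expect_false(inst@complete, info = id)
    bq <- alignToProfile(qs$queries[[id]], prof, hint = qs$taxon[[id]],
                         id = id)
    expect_gt(nrow(bq@blocks), 0L)
  }
})

test_that("fixtures satisfy the shared data-model invariants", {
  for (fx in list(toyProfileTemplate()$template,
                  toyStructureTemplate()$template,
                  synthTemplate(nTaxa = 2, seqsPerTaxon = 3,
                                nColumns = 60, seed = 9)$template)) {
    expect_true(validObject(fx))
    expect_true(all(taxonLabels(fx) %in% taxonNames(taxonomy(fx))))
    m <- alignmentMatrix(fx)
    expect_true(all(colSums(m != "-") > 0))
  }
})
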