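fx <- toyProfileTemplate()
tpl <- fx$template

test_that("conservation counts nucleotides over counted sequences only", {
  # six of the seven bacilli sequences bear a nucleotide at this column
  expect_equal(conservationValue(tpl, "bacilli", fx$notes$conservation67Column),
               6 / 7)
  expect_equal(conservationValue(tpl, "bacilli", fx$notes$conservation77Column),
               1.0)
  # three root sequences are 5'-truncated, yet leading-column conservation
  # is unaffected because partial sequences are excluded from the count
  expect_equal(conservationValue(tpl, "bacteria", 1), 1.0)
  expect_equal(conservationValue(tpl, "bacteria", 2), 1.0)
  expect_error(conservationValue(tpl, "nosuch", 1), "no sequences")
})

test_that("composition values are nucleotide fractions among bearers", {
  col <- fx$notes$compositionColumn
  expect_equal(compositionValues(tpl, "bacillales", col)[, 1],
               c(A = 0, C = 1 / 3, G = 2 / 3, U = 0))
  expect_equal(compositionValues(tpl, "bacilli", col)[, 1],
               c(A = 1 / 7, C = 2 / 7, G = 4 / 7, U = 0))
  # single-symbol column
  one <- compositionValues(tpl, "bacillales", 21)[, 1]
  expect_equal(sum(one), 1)
  expect_equal(max(one), 1)
  # empty column within a taxon errors
  expect_error(compositionValues(tpl, "bacillales", 26), "empty column")
  # fractions sum to one wherever any nucleotide is present
  cc <- compositionValues(tpl, "bacteria", strict = FALSE)
  expect_true(all(abs(colSums(cc) - 1) < 1e-9 | colSums(cc) == 0))
})

test_that("block partition tiles the alignment with fixed conserved counts", {
  pb <- partitionBlocks(tpl, conservedPerBlock = 5)
  expect_identical(nrow(pb), 6L)
  expect_identical(pb$nConserved, c(5L, 5L, 5L, 5L, 5L, 3L))
  expect_identical(pb$start[1], 1L)
  expect_identical(pb$end[6], alignmentWidth(tpl))
  expect_identical(pb$start[-1], pb$end[-6] + 1L)
  # exact division
  pb4 <- partitionBlocks(tpl, conservedPerBlock = 7)
  expect_identical(nrow(pb4), 4L)
  expect_identical(pb4$nConserved, c(7L, 7L, 7L, 7L))
  # a fully conserved alignment collapses to a single block
  tax <- taxonomyFromLineages("r;g")
  flat <- ingestAlignment(c(x = "ACGUA", y = "ACGUA"),
                          c(x = "g", y = "g"), tax)
  pb1 <- partitionBlocks(flat, conservedPerBlock = 5)
  expect_identical(nrow(pb1), 1L)
  expect_identical(c(pb1$start, pb1$end), c(1L, 5L))
  # un-partitionable when no column clears the cutoff
  expect_error(partitionBlocks(flat, 5, threshold = 1), "un-partitionable")
})

test_that("the subsequence block score follows the two-term definition", {
  expect_equal(subsequenceBlockScore(rep(1, 5), rep(1, 5)), 1.8)
  expect_equal(subsequenceBlockScore(c(6/7, 1, 1, 1, 1),
                                     c(1, 4/7, 1, 1, 1)),
               (6/7 + 4) / 5 + 0.8 * (1 + 4/7 + 1 + 1 + 1) / 5)
  expect_warning(z <- subsequenceBlockScore(rep(1, 4), rep(NA_real_, 4)),
                 "empty subsequence")
  expect_equal(z, 0)
  # a missing conserved column is penalized through the |Y| denominator
  expect_lt(subsequenceBlockScore(rep(1, 5), c(NA, 1, 1, 1, 1)),
            subsequenceBlockScore(rep(1, 5), rep(1, 5)))
  # the weight is configurable
  expect_equal(subsequenceBlockScore(rep(1, 3), rep(1, 3), weight = 0.5),
               1.5)
})

test_that("taxon statistics cover qualifying taxa and reuse root blocks", {
  prof <- buildProfile(tpl, blockSize = 5, minSequences = 3)
  expect_setequal(profileTaxa(prof), c("bacteria", "bacilli", "bacillales"))
  # per-taxon conserved sets may differ: six conserved columns in block 5
  # for bacillales, five for bacilli
  expect_length(prof@taxa$bacillales$conservedByBlock[[5]], 6L)
  expect_length(prof@taxa$bacilli$conservedByBlock[[5]], 5L)
  # the bacilli block-5 average reproduces the worked value
  expect_equal(blockScores(prof, "bacilli")[5], 1.66531, tolerance = 1e-4)
  expect_true(all(unlist(lapply(prof@taxa, `[[`, "blockScores")) <= 1.8 + 1e-9))
  # min_sequences beyond every taxon leaves only the root
  profRoot <- buildProfile(tpl, blockSize = 5, minSequences = 99)
  expect_identical(profileTaxa(profRoot), "bacteria")
})

test_that("identical sequences score the 1.8 maximum in every block", {
  tax <- taxonomyFromLineages("r;g")
  rows <- setNames(rep("AGCUAGCUAGGUACGU", 4), paste0("s", 1:4))
  aln <- ingestAlignment(rows, setNames(rep("g", 4), names(rows)), tax)
  prof <- buildProfile(aln, blockSize = 4, minSequences = 3)
  for (t in profileTaxa(prof))
    expect_equal(blockScores(prof, t), rep(1.8, 4), tolerance = 1e-12)
})

test_that("block averages equal a brute-force symbol-by-symbol oracle", {
  for (seed in 1:6) {
    aln <- randomToyAlignment(nseq = 6 + seed %% 3, ncol = 24, seed = seed)
    prof <- buildProfile(aln, blockSize = 4, minSequences = 2,
                         threshold = 0.5)
    mat <- alignmentMatrix(aln)
    for (taxon in profileTaxa(prof)) {
      st <- prof@taxa[[taxon]]
      rows <- taxonMembers(aln, taxon)
      for (b in seq_along(prof@blocks)) {
        Y <- st$conservedByBlock[[b]]
        if (!length(Y)) next
        included <- aln@firstRes[rows] <= min(Y) & aln@lastRes[rows] >= max(Y)
        if (!any(included)) next
        want <- mean(vapply(rows[included], function(r)
          suppressWarnings(
            oracleBlockScore(mat, rows, r, Y, weight = 0.8)),
          numeric(1)))
        expect_equal(unname(st$blockScores[b]), want, tolerance = 1e-9,
                     info = sprintf("seed %d taxon %s block %d",
                                    seed, taxon, b))
      }
    }
  }
})

test_that("a majority-matching duplicate never lowers the block average", {
  for (seed in 1:3) {
    aln <- randomToyAlignment(nseq = 6, ncol = 20, seed = seed, gapProb = 0)
    mat <- alignmentMatrix(aln)
    gaRows <- taxonMembers(aln, "ga")
    # append the taxon's own per-column majority sequence to taxon ga
    maj <- apply(mat[gaRows, , drop = FALSE], 2, function(col) {
      tb <- table(col[col != "-"])
      names(tb)[which.max(tb)]
    })
    rows <- c(apply(mat, 1, paste, collapse = ""),
              dup = paste(maj, collapse = ""))
    tax <- taxonomy(aln)
    labs <- c(taxonLabels(aln), dup = "ga")
    aln2 <- ingestAlignment(rows, labs, tax)
    p1 <- buildProfile(aln, blockSize = 4, minSequences = 2, threshold = 0.5)
    p2 <- buildProfile(aln2, blockSize = 4, minSequences = 2, threshold = 0.5)
    expect_true(all(blockScores(p2, "ga") >=
                    blockScores(p1, "ga") - 1e-9))
  }
})

test_that("profiles serialize to JSON and back without loss", {
  prof <- buildProfile(tpl, blockSize = 5, minSequences = 3)
  f <- tempfile(fileext = ".json")
  writeProfileJSON(prof, f)
  back <- readProfileJSON(f)
  expect_equal(back@ncol, prof@ncol)
  expect_identical(profileTaxa(back), profileTaxa(prof))
  for (t in profileTaxa(prof)) {
    expect_equal(back@taxa[[t]]$conservation, prof@taxa[[t]]$conservation)
    expect_equal(back@taxa[[t]]$blockScores, prof@taxa[[t]]$blockScores)
    expect_equal(unname(back@taxa[[t]]$composition),
                 unname(prof@taxa[[t]]$composition))
  }
})
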