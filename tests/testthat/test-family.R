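# A hand-built three-member family on one chromosome: identical 30-nt CDS
# (ATG + 8x AAA + TAA) at offsets 1, 101, 201, all plus strand.
threeMemberFixture <- function(aln = NULL) {
  cds <- paste0("ATG", strrep("AAA", 8), "TAA")
  genome <- Biostrings::DNAStringSet(c(chrF = paste(
    c(cds, strrep("C", 70), cds, strrep("C", 70), cds), collapse = "")))
  starts <- c(1, 101, 201)
  ft <- GRanges("chrF", IRanges(starts, starts + 29), strand = "+",
                gene_id = c("g1", "g2", "g3"), type = "CDS")
  models <- geneModelSet(ft)
  aa <- paste(Biostrings::GENETIC_CODE[substring(
    cds, 3 * (1:10) - 2, 3 * (1:10))], collapse = "")
  if (is.null(aln))
    aln <- setNames(rep(sub("\\*$", "-", aa), 3), c("g1", "g2", "g3"))
  fam <- geneFamilySet(
    data.frame(family_id = "famA", species = c("s1", "s2", "s3"),
               gene_id = c("g1", "g2", "g3")),
    list(famA = aln))
  list(models = models, families = fam, genome = genome,
       starts = starts)
}

test_that("sites map to alignment columns through gaps", {
  fx <- threeMemberFixture()
  # ungapped alignment: codon 7 -> column 7 (genomic pos 19-21 of g1)
  expect_identical(mapSiteToColumn(fx$models, fx$families, "g1", 19), 7L)
  # two leading gap columns shift codon 1 to column 3
  aln <- c(g1 = "--MKKKKKKKK-", g2 = "MK--KKKKKKK-", g3 = "MKKKKKKKK---")
  fx2 <- threeMemberFixture(aln = aln)
  expect_identical(mapSiteToColumn(fx2$models, fx2$families, "g1", 1), 3L)
  expect_identical(mapSiteToColumn(fx2$models, fx2$families, "g2", 107), 5L)
  # member absent from the alignment errors
  fx3 <- threeMemberFixture(aln = c(g1 = "MKKKKKKKK-",
                                    g2 = "MKKKKKKKK-"))
  expect_error(mapSiteToColumn(fx3$models, fx3$families, "g3", 1),
               "absent from the alignment")
  # beyond the aligned region errors
  expect_error(mapSiteToColumn(fx3$models, fx3$families, "g1", 31),
               "outside the CDS")
})

test_that("event typing follows the singleton/shared-column definitions", {
  fx <- threeMemberFixture()
  singleton_models <- geneModelSet(GRanges(
    "chrS", IRanges(1, 30), strand = "+", gene_id = "solo", type = "CDS"))
  singleton_fam <- geneFamilySet(
    data.frame(family_id = "famS", species = "s1", gene_id = "solo"),
    list(famS = c(solo = "MKKKKKKKK-")))

  # singleton gene event -> type I
  ev <- data.frame(chrom = "chrS", pos = 5, gene = "solo")
  got <- classifyEventTypes(ev, singleton_fam, singleton_models)
  expect_identical(got$type, "I")

  # five events on a three-member family: two share codon column 4,
  # the rest are private
  ev5 <- data.frame(chrom = "chrF",
                    pos = c(10, 110, 5, 125, 222),
                    gene = c("g1", "g2", "g1", "g2", "g3"))
  got5 <- classifyEventTypes(ev5, fx$families, fx$models)
  # pos 10 (g1 codon 4) and 110 (g2 codon 4) share a column
  expect_identical(got5$type, c("III", "III", "II", "II", "II"))
  expect_identical(unique(na.omit(got5$cluster_id)), "famA:c4")
  # partition: counts per type sum to total CDS events
  expect_identical(sum(table(got5$type)), nrow(ev5))

  # two events in the SAME member at one column stay type II
  ev_same <- data.frame(chrom = "chrF", pos = c(10, 11), gene = "g1")
  got_same <- classifyEventTypes(ev_same, fx$families, fx$models)
  expect_true(all(got_same$type == "II"))

  # order invariance
  perm <- c(4, 1, 5, 3, 2)
  got_p <- classifyEventTypes(ev5[perm, ], fx$families, fx$models)
  expect_identical(got_p$type, got5$type[perm])

  # non-CDS events are rejected
  ev_bad <- data.frame(chrom = "chrF", pos = 60, gene = "g1")
  expect_error(classifyEventTypes(ev_bad, fx$families, fx$models),
               "non-CDS")
})

test_that("dropping the partner events of a cluster demotes it to type II", {
  truth <- generateTruth(smallSimConfig(seed = 91L))
  ev <- truth@events
  expect_gt(sum(ev$type == "III"), 0L)
  # keep only one event per conserved cluster; families stay intact
  first_in_cluster <- !duplicated(ev$cluster_id) | is.na(ev$cluster_id)
  ev1 <- ev[first_in_cluster, c("chrom", "pos", "gene", "type")]
  got <- classifyEventTypes(ev1[, c("chrom", "pos", "gene")],
                            truth@families, truth@models)
  expect_false(any(got$type == "III"))
  expect_true(all(got$type[ev1$type == "III"] == "II"))
  expect_identical(got$type[ev1$type == "I"], ev1$type[ev1$type == "I"])
})

test_that("bidirectional best hits equal brute-force mutual argmax", {
  scores <- data.frame(
    query = c("a1", "a1", "a2", "a2"),
    subject = c("b1", "b2", "b1", "b2"),
    score = c(10, 3, 2, 8))
  got <- bbhPairs(scores)
  expect_identical(got$a, c("a1", "a2"))
  expect_identical(got$b, c("b1", "b2"))

  # a -> b best, but b's best is c: no pair for a
  tab <- data.frame(query = c("a", "a", "c"),
                    subject = c("b", "d", "b"),
                    score = c(5, 1, 9))
  got2 <- bbhPairs(tab)
  expect_false("a" %in% got2$a)
  expect_identical(got2$a, "c")

  # random 4x4 matrices vs brute-force enumeration
  set.seed(7)
  for (rep in 1:20) {
    m <- matrix(sample(1:100, 16), 4, 4,
                dimnames = list(paste0("x", 1:4), paste0("y", 1:4)))
    long <- data.frame(query = rep(rownames(m), 4),
                       subject = rep(colnames(m), each = 4),
                       score = as.vector(m))
    got <- bbhPairs(long)
    brute <- list()
    for (i in 1:4) for (j in 1:4) {
      if (which.max(m[i, ]) == j && which.max(m[, j]) == i)
        brute[[length(brute) + 1]] <- c(rownames(m)[i], colnames(m)[j])
    }
    brute <- do.call(rbind, brute)
    expect_identical(nrow(got), if (is.null(brute)) 0L else nrow(brute))
    if (!is.null(brute)) {
      ord <- order(brute[, 1])
      expect_identical(got$a, brute[ord, 1])
      expect_identical(got$b, brute[ord, 2])
    }
  }
  expect_identical(nrow(bbhPairs(data.frame(query = character(),
                                            subject = character(),
                                            score = numeric()))), 0L)
})

test_that("the star-alignment fallback handles indels and round-trips", {
  # equal-length, gap-free case: identity alignment
  s <- c(a = "MKKT", b = "MKRT")
  expect_identical(starAlignment(s), s)

  # an insertion in one member opens a shared gap column
  s2 <- c(a = "MKKT", b = "MKXKT", c = "MKKT")
  aln <- starAlignment(s2)
  expect_identical(unique(nchar(aln)), 5L)
  expect_identical(aln[["b"]], "MKXKT")
  expect_identical(sum(strsplit(aln[["a"]], "")[[1]] == "-"), 1L)

  # a deletion in one member appears as its own gap
  s3 <- c(a = "MKKTW", b = "MKTW")
  aln3 <- starAlignment(s3)
  expect_identical(aln3[["a"]], "MKKTW")
  expect_identical(sum(strsplit(aln3[["b"]], "")[[1]] == "-"), 1L)

  # aligned columns feed event typing like a supplied alignment
  single <- starAlignment(c(only = "MKKT"))
  expect_identical(single, c(only = "MKKT"))
})
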