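test_that("potential-edit enumeration matches the brute-force oracle", {
  # hand examples
  pe <- enumeratePotentialEdits(c(g = "ATGAAA"))
  expect_identical(pe$possible_nonsyn, 3L)
  expect_identical(pe$possible_syn, 1L)
  expect_identical(enumeratePotentialEdits(c(g = "CCCGGG"))$possible_syn +
                   enumeratePotentialEdits(c(g = "CCCGGG"))$possible_nonsyn,
                   0L)
  pe2 <- enumeratePotentialEdits(c(g = "ATGGGG"))
  expect_identical(c(pe2$possible_nonsyn, pe2$possible_syn), c(1L, 0L))

  # brute force over random CDS
  set.seed(5)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("g", 1:20)
  pe3 <- enumeratePotentialEdits(seqs)
  counts <- c(synonymous = 0L, nonsynonymous = 0L, stop_change = 0L)
  for (s in seqs) {
    a_loc <- which(strsplit(s, "")[[1]] == "A")
    if (!length(a_loc)) next
    for (cls in oracleRecodingBatch(s, a_loc))
      counts[cls] <- counts[cls] + 1L
  }
  expect_identical(pe3$possible_syn, unname(counts["synonymous"]))
  expect_identical(pe3$possible_nonsyn, unname(counts["nonsynonymous"]))
  expect_identical(pe3$possible_stop, unname(counts["stop_change"]))

  # additive over disjoint gene sets and invariant to reordering
  pe_a <- enumeratePotentialEdits(seqs[1:10])
  pe_b <- enumeratePotentialEdits(seqs[11:20])
  expect_identical(pe_a$possible_syn + pe_b$possible_syn, pe3$possible_syn)
  pe_r <- enumeratePotentialEdits(seqs[sample(20)])
  expect_identical(pe_r$possible_nonsyn, pe3$possible_nonsyn)

  # ambiguous codons are skipped with an account
  expect_message(peN <- enumeratePotentialEdits(c(g = "ATGANA")),
                 "ambiguous")
  expect_identical(peN$n_ambiguous, 2L)  # both adenosines of the ANA codon
  expect_error(enumeratePotentialEdits(c(g = "ATGA")), "divisible")
})

test_that("the selection test reproduces frequencies and directions", {
  obs <- data.frame(type = c("I", "III"),
                    observed_nonsyn = c(94, 1029),
                    observed_syn = c(112, 202))
  poss <- data.frame(type = c("I", "III"),
                     possible_nonsyn = c(46078, 565787),
                     possible_syn = c(13595, 137252))
  st <- selectionTest(obs, poss)
  expect_equal(st$freq_nonsyn, c(94 / 46078, 1029 / 565787))
  expect_identical(st$direction, c("purifying-like", "positive-like"))
  expect_lt(st$p[st$type == "III"], 6.575e-3)

  # equal observed/possible ratios: chi2 ~ 0, p ~ 1
  null_st <- selectionTest(
    data.frame(type = "x", observed_nonsyn = 50, observed_syn = 100),
    data.frame(type = "x", possible_nonsyn = 5000, possible_syn = 10000))
  expect_lt(null_st$chi2, 1e-10)
  expect_gt(null_st$p, 0.999)

  # small expected cells switch to Fisher's exact test
  f <- selectionTest(
    data.frame(type = "y", observed_nonsyn = 2, observed_syn = 1),
    data.frame(type = "y", possible_nonsyn = 10, possible_syn = 30))
  expect_identical(f$test, "fisher")
  expect_true(is.na(f$chi2))

  expect_error(selectionTest(
    data.frame(type = "z", observed_nonsyn = 1, observed_syn = 1),
    data.frame(type = "z", possible_nonsyn = 0, possible_syn = 10)),
    "zero possible")
})

test_that("chi-square and Fisher agree on well-populated tables", {
  # tables drawn near the null so both tests operate away from the far
  # tail, where the asymptotic and exact p-values are comparable
  set.seed(11)
  for (i in 1:20) {
    pn <- sample(500:2000, 1); ps <- sample(500:2000, 1)
    m <- sample(120:200, 1)
    on_ <- rbinom(1, m, pn / (pn + ps))
    os <- m - on_
    tab <- matrix(c(on_, pn - on_, os, ps - os), 2)
    if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 20)) next
    st <- selectionTest(
      data.frame(type = "t", observed_nonsyn = on_, observed_syn = os),
      data.frame(type = "t", possible_nonsyn = pn, possible_syn = ps))
    pf <- fisher.test(tab)$p.value
    expect_lt(abs(log10(st$p) - log10(pf)), 0.3)
  }
})

test_that("NG86 counting matches exhaustive pathway enumeration", {
  # identical sequences
  r0 <- ng86KaKs("ATGAAACCC", "ATGAAACCC")
  expect_identical(c(r0$Ka, r0$Ks, r0$N_diffs, r0$S_diffs), c(0, 0, 0, 0))

  # single-codon synonymous pair: one synonymous difference
  r1 <- suppressWarnings(ng86KaKs("AAA", "AAG"))
  expect_identical(c(r1$S_diffs, r1$N_diffs), c(1, 0))

  # cross-check against an independent reference implementation of the
  # counting method (frozen values)
  r2 <- ng86KaKs("ATGTTTAAAGGG", "ATGTTCAGAGGG")
  expect_equal(r2$Ka, 0.105436, tolerance = 1e-5)
  expect_equal(r2$Ks, 0.974462, tolerance = 1e-5)

  # symmetry
  r3 <- ng86KaKs("ATGTTCAGAGGG", "ATGTTTAAAGGG")
  expect_equal(r2$Ka, r3$Ka)
  expect_equal(r2$Ks, r3$Ks)

  # sites identity: N + S = 3 x codons
  expect_equal(r2$N_sites + r2$S_sites, 12)

  # exhaustive oracle over all sense-codon pairs with <= 2 differences
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  ndiff <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  checked <- 0L; max_dev <- 0
  for (c1 in sense) for (c2 in sense) {
    k <- ndiff(c1, c2)
    if (k == 0 || k > 2) next
    r <- suppressWarnings(ng86KaKs(c1, c2))
    want <- oracleCodonDiffs(c1, c2)
    max_dev <- max(max_dev, abs(r$S_diffs - want[["syn"]]),
                   abs(r$N_diffs - want[["nonsyn"]]))
    checked <- checked + 1L
  }
  expect_gt(checked, 2000L)
  expect_lt(max_dev, 1e-12)

  expect_error(ng86KaKs("ATG", "AT"), "equal length")
  expect_error(ng86KaKs("ATGTAA", "ATGTAA"), "stop codons")
  expect_error(ng86KaKs("AT-", "ATG"), "gap-free")
})

test_that("11-codon windows centre, truncate and compose correctly", {
  set.seed(3)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  cod1 <- sample(sense, 20, replace = TRUE)
  cod2 <- cod1
  cod2[4] <- "AAA"; cod2[11] <- "CCC"   # two whole-codon substitutions
  s1 <- paste(cod1, collapse = "")
  s2 <- paste(cod2, collapse = "")
  w <- windowKaKs(s1, s2, editing_codons = c(6, 1, 20))
  expect_identical(w$start, c(1L, 1L, 15L))
  expect_identical(w$end, c(11L, 6L, 20L))

  # identical block -> Ka = Ks = 0
  w0 <- windowKaKs(s1, s1, editing_codons = 10)
  expect_identical(c(w0$Ka, w0$Ks), c(0, 0))

  # compositional: window result equals ng86KaKs on the extracted block
  blk1 <- substring(s1, 3 * 1 - 2, 3 * 11)
  blk2 <- substring(s2, 3 * 1 - 2, 3 * 11)
  direct <- suppressWarnings(ng86KaKs(blk1, blk2))
  expect_equal(w$Ka[1], direct$Ka)
  expect_equal(w$Ks[1], direct$Ks)
})
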