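test_that("single-sample filter criteria match the published thresholds", {
  models <- toyModels()
  # positions inside gene_plus (+, CDS) with ref A, alt G
  tab <- rbind(
    siteRow(pos = 105, ref = "A", A = 3, G = 1),              # depth 4
    siteRow(pos = 106, ref = "A", A = 1, G = 19),             # rate 0.95
    siteRow(pos = 107, ref = "A", A = 2, G = 18),             # rate 0.90
    siteRow(pos = 108, ref = "A", A = 198, G = 2),            # rate 0.01
    siteRow(pos = 109, ref = "A", A = 199, G = 1),            # rate 0.005
    siteRow(pos = 110, ref = "A", A = 10, G = 5, distinct = 1),
    siteRow(pos = 111, ref = "A", A = 10, G = 5, interior = 0),
    siteRow(pos = 112, ref = "A", A = 10, C = 5))             # A>C change
  ev <- callCandidateEvents(list(s1 = tab), models)
  expect_setequal(ev$pos, c(107, 108))
  expect_true(all(ev$ref == "A" & ev$alt == "G"))

  # depth exactly 5 passes; 4 fails
  t5 <- siteRow(pos = 105, ref = "A", A = 3, G = 2)
  expect_identical(callCandidateEvents(list(s1 = t5), models)$pos, 105)
})

test_that("strand orientation gates the A-to-G filter", {
  models <- toyModels()
  tab <- rbind(
    siteRow(pos = 210, ref = "T", C = 10, T = 30),  # minus gene: T>C kept
    siteRow(pos = 212, ref = "A", G = 10, A = 30),  # A>G inside minus gene
    siteRow(pos = 380, ref = "A", G = 10, A = 30),  # intergenic A>G kept
    siteRow(pos = 385, ref = "T", C = 10, T = 30),  # intergenic T>C kept
    siteRow(pos = 390, ref = "C", T = 10, C = 30))  # intergenic C>T dropped
  ev <- callCandidateEvents(list(s1 = tab), models)
  expect_setequal(ev$pos, c(210, 380, 385))
  expect_identical(ev$strand[ev$pos == 210], "-")
  expect_setequal(ev$strand[ev$pos %in% c(380, 385)], ".")
})

test_that("the majority-of-samples rule uses ceiling(fraction x n)", {
  models <- toyModels()
  good <- function(s) siteRow(pos = 105, ref = "A", A = 30, G = 10,
                              sample = s)
  bad <- function(s) siteRow(pos = 105, ref = "A", A = 3, G = 1,
                             sample = s)
  # passes in 1 of 3 -> excluded; 2 of 3 -> included
  ev1 <- callCandidateEvents(list(a = good("a"), b = bad("b"),
                                  c = bad("c")), models)
  expect_identical(nrow(ev1), 0L)
  ev2 <- callCandidateEvents(list(a = good("a"), b = good("b"),
                                  c = bad("c")), models)
  expect_identical(ev2$pos, 105)
  expect_identical(ev2$n_pass, 2L)
  # with a single sample, one passing sample suffices
  ev3 <- callCandidateEvents(list(a = good("a")), models)
  expect_identical(ev3$pos, 105)
  expect_error(callCandidateEvents(list(), models), "empty")
})

test_that("caller output is a subset of input and thresholds are monotone", {
  truth <- generateTruth(smallSimConfig(seed = 61L))
  counts <- simulateReadCounts(truth)
  wt <- counts[!truth@config@samples$adar_null]
  base <- callCandidateEvents(wt, truth@models)
  in_keys <- unique(unlist(lapply(wt, function(s)
    paste(s$chrom, s$pos))))
  expect_true(all(paste(base$chrom, base$pos) %in% in_keys))

  tighter <- list(
    callerParams(min_depth = 10),
    callerParams(min_distinct_reads = 4),
    callerParams(rate_low = 0.05),
    callerParams(rate_high = 0.5),
    callerParams(sample_fraction = 1))
  for (p in tighter) {
    ev <- callCandidateEvents(wt, truth@models, p)
    expect_true(all(paste(ev$chrom, ev$pos) %in%
                    paste(base$chrom, base$pos)))
  }
})

test_that("injected events are recovered and all calls are A-to-G", {
  truth <- generateTruth(smallSimConfig(seed = 71L))
  counts <- simulateReadCounts(truth)
  wt <- counts[!truth@config@samples$adar_null]
  ev <- callCandidateEvents(wt, truth@models)
  expect_true(all((ev$ref == "A" & ev$alt == "G") |
                  (ev$ref == "T" & ev$alt == "C")))
  expect_true(all(ev$strand[ev$ref == "T" & !is.na(ev$gene)] == "-"))
  tr <- truth@events
  eligible <- tr$level >= 0.01 & tr$level <= 0.90
  recall <- mean(paste(tr$chrom, tr$pos)[eligible] %in%
                 paste(ev$chrom, ev$pos))
  expect_gte(recall, 0.9)
})

test_that("mismatch spectrum proportions behave like a multinomial", {
  models <- toyModels()
  # degenerate spectrum: all candidates A>G
  tab <- rbind(siteRow(pos = 105, ref = "A", A = 30, G = 10),
               siteRow(pos = 106, ref = "A", A = 30, G = 10))
  sp <- mismatchSpectrum(list(s1 = tab))
  expect_identical(sp@proportions[["A>G"]], 1)
  expect_identical(sum(sp@proportions), 1)

  # 6 A>G and 4 C>T candidates -> 0.6 / 0.4
  rows <- c(lapply(1:6, function(i)
    siteRow(pos = 400 + i, ref = "A", A = 30, G = 10)),
    lapply(1:4, function(i)
      siteRow(pos = 420 + i, ref = "C", C = 30, T = 10)))
  sp2 <- mismatchSpectrum(list(s1 = do.call(rbind, rows)))
  expect_equal(sp2@proportions[["A>G"]], 0.6)
  expect_equal(sp2@proportions[["C>T"]], 0.4)

  # uniform errors: all 12 proportions within 3 SE of 1/12
  set.seed(99)
  n <- 2400
  refs <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  rows <- lapply(seq_len(n), function(i) {
    counts <- setNames(rep(0, 4), c("A", "C", "G", "T"))
    counts[refs[i]] <- 30; counts[alts[i]] <- 10
    siteRow(pos = 1000 + i, ref = refs[i], A = counts[["A"]],
            C = counts[["C"]], G = counts[["G"]], T = counts[["T"]])
  })
  sp3 <- mismatchSpectrum(list(s1 = do.call(rbind, rows)))
  se <- sqrt((1 / 12) * (11 / 12) / n)
  expect_true(all(abs(sp3@proportions - 1 / 12) < 3.5 * se))
  expect_error(mismatchSpectrum(list(s1 = siteRow(pos = 1, ref = "A",
                                                  A = 2))),
               "no candidate sites")
})

test_that("background FP rate follows the spectrum formula", {
  expect_equal(backgroundFpRate(0.619), ((1 - 0.619) / 11) / 0.619)
  expect_lt(abs(100 * backgroundFpRate(0.619) - 5.59), 0.01)
  expect_identical(backgroundFpRate(1), 0)
  expect_equal(backgroundFpRate(0.5), 1 / 11)
  expect_error(backgroundFpRate(0), "zero")
  # strictly decreasing in the A>G proportion
  p <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(vapply(p, backgroundFpRate, numeric(1))) < 0))
})

test_that("SNP cross-check flags events at A/G variants", {
  ev <- data.frame(chrom = "chr1", pos = 1:1299,
                   stringsAsFactors = FALSE)
  snps <- data.frame(chrom = "chr1", pos = c(1:110, 5000:5100),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  r <- snpCrosscheck(ev, snps)
  expect_identical(nrow(r$flagged), 110L)
  expect_equal(r$fp_rate, 110 / 1299)
  # disjoint set
  r0 <- snpCrosscheck(ev, data.frame(chrom = "chr2", pos = 1:10,
                                     ref = "A", alt = "G"))
  expect_identical(r0$fp_rate, 0)
  # non-A/G SNPs are ignored
  r1 <- snpCrosscheck(ev, data.frame(chrom = "chr1", pos = 1:50,
                                     ref = "C", alt = "T"))
  expect_identical(r1$fp_rate, 0)
  expect_error(snpCrosscheck(ev[0, ], snps), "undefined")
})

test_that("null-sample validation counts reference-only positions", {
  n <- 523
  ev <- data.frame(chrom = "chr1", pos = seq_len(n + 7))
  nullc <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (i <= 485) siteRow(pos = i, ref = "A", A = 20, sample = "null")
    else siteRow(pos = i, ref = "A", A = 18, G = 2, sample = "null")
  }))
  r <- nullSampleValidation(ev, nullc)
  expect_identical(nrow(r$genuine), 485L)
  expect_identical(nrow(r$uncovered), 7L)
  expect_equal(r$fp_rate, 1 - 485 / 523)
  expect_equal(round(100 * (1 - r$fp_rate), 1), 92.7)

  # error-free synthetic null: FP rate 0
  cfg <- smallSimConfig(seed = 81L, seq_error_rate = 0, snp_rate = 0,
                        depth_dist = c(mean = 80, size = 50))
  truth <- generateTruth(cfg)
  counts <- simulateReadCounts(truth)
  wt <- counts[!cfg@samples$adar_null]
  called <- callCandidateEvents(wt, truth@models)
  rv <- nullSampleValidation(called, counts[["head_adar_null"]])
  expect_identical(rv$fp_rate, 0)
})

test_that("genotyping confirmation applies thresholds then the odds ratio", {
  expect_true(confirmByGenotyping(c(85, 15), c(95, 5)))
  expect_false(confirmByGenotyping(c(60, 40), c(50, 50)))   # het SNP
  # OR branch: (8/92)/(1/99) ~ 8.6 > 3
  expect_true(confirmByGenotyping(c(92, 8), c(99, 1)))
  # zero gDNA G: OR undefined, threshold branch decides
  expect_true(confirmByGenotyping(c(80, 20), c(100, 0)))
  expect_false(confirmByGenotyping(c(98, 2), c(100, 0)))
  expect_error(confirmByGenotyping(c(0, 0), c(10, 1)), "positive")
})
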