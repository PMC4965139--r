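# Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# One count-table row in the pileup TSV dialect.
siteRow <- function(chrom = "chr1", pos, ref, A = 0, C = 0, G = 0, T = 0,
                    distinct = NULL, interior = NULL,
                    sample = "s1") {
  counts <- c(A = A, C = C, G = G, T = T)
  nonref <- sum(counts) - counts[[ref]]
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
             A = A, C = C, G = G, T = T,
             distinct_nonref_reads =
               if (is.null(distinct)) nonref else distinct,
             nonref_reads_ge10bp_from_ends =
               if (is.null(interior)) nonref else interior,
             stringsAsFactors = FALSE)
}

# A two-gene toy locus: plus-strand gene with two CDS intervals (intron
# between), a minus-strand single-interval gene, and an ncRNA gene.
#   gene_plus : chr1:101-130 + chr1:141-152  (+)   42 nt CDS
#   gene_minus: chr1:201-230               (-)   30 nt CDS
#   nc1       : chr1:301-340               (+)   ncRNA
toyModels <- function() {
  ft <- GRanges("chr1",
                IRanges(start = c(101, 141, 201, 301),
                        end = c(130, 152, 230, 340)),
                strand = c("+", "+", "-", "+"))
  ft$gene_id <- c("gene_plus", "gene_plus", "gene_minus", "nc1")
  ft$type <- c("CDS", "CDS", "CDS", "ncRNA")
  geneModelSet(ft, ncRNA = "nc1")
}

# Genome matching toyModels(): gene_plus carries ATG + lysine codons, the
# minus-strand gene is the reverse complement of an ATG-led CDS.
toyGenome <- function() {
  chr <- paste(rep("C", 400), collapse = "")
  plus_cds <- paste0("ATG", strrep("AAA", 13))             # 42 nt
  minus_cds <- paste0("ATG", strrep("AAA", 8), "TAA")      # 30 nt
  minus_locus <- as.character(
    reverseComplement(DNAString(minus_cds)))
  substr(chr, 101, 130) <- substr(plus_cds, 1, 30)
  substr(chr, 141, 152) <- substr(plus_cds, 31, 42)
  substr(chr, 201, 230) <- minus_locus
  DNAStringSet(c(chr1 = chr))
}

# Small, fast simulation config used across suites.
smallSimConfig <- function(seed = 1L, n_background_sites = 300L, ...) {
  simConfig(n_families = 60L, cds_length_codons = c(60L, 120L),
            n_background_sites = n_background_sites,
            seed = as.integer(seed), ...)
}

# Brute-force recoding oracle, batch form: translate the whole CDS before
# and after each substitution (all mutants in one translate call) and
# compare the proteins.
oracleRecodingBatch <- function(cds, positions) {
  mutants <- vapply(positions, function(p) {
    m <- cds; substr(m, p, p) <- "G"; m
  }, character(1))
  prots <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(c(cds, mutants)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  p1 <- prots[1]; p2 <- prots[-1]
  i <- (positions - 1) %/% 3 + 1
  a1 <- substring(p1, i, i)
  a2 <- substring(p2, i, i)
  ifelse(a1 == a2, "synonymous",
         ifelse(a1 == "*" | a2 == "*", "stop_change", "nonsynonymous"))
}

# Brute-force recoding oracle: translate the whole CDS before and after the
# substitution and compare proteins.
oracleRecoding <- function(cds, pos) {
  mutated <- cds
  substr(mutated, pos, pos) <- "G"
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  p2 <- as.character(Biostrings::translate(Biostrings::DNAString(mutated),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  i <- (pos - 1) %/% 3 + 1
  a1 <- substr(p1, i, i); a2 <- substr(p2, i, i)
  if (a1 == a2) "synonymous"
  else if (a1 == "*" || a2 == "*") "stop_change"
  else "nonsynonymous"
}

# Exhaustive pathway-averaging oracle for per-codon-pair substitution
# differences (independent re-derivation used against ng86KaKs).
GEN_CODE <- Biostrings::GENETIC_CODE
oracleCodonDiffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      out <- list()
      for (a in pos) for (b in setdiff(pos, a))
        out[[length(out) + 1]] <- c(a, b, setdiff(pos, c(a, b)))
      out
    }
  }
  walk <- function(ord) {
    cur <- c1; sd <- 0; nd <- 0; stops <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GEN_CODE[[nxt]] == "*") stops <- TRUE
      if (GEN_CODE[[nxt]] == GEN_CODE[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, stops)
  }
  w <- sapply(perms, walk)
  use <- w[3, ] == 0
  if (!any(use)) use <- rep(TRUE, ncol(w))
  c(syn = mean(w[1, use]), nonsyn = mean(w[2, use]))
}

# Exact hypergeometric tail by combinatorial summation (no phyper).
oracleHyperOver <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
oracleHyperUnder <- function(k, K, N, n) {
  j <- 0:k
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# O(n^2) pair-enumeration tau-b oracle.
oracleTauB <- function(x, y) {
  n <- length(x); nc <- 0; nd <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    if (sx != 0 && sy != 0) {
      if (sx == sy) nc <- nc + 1 else nd <- nd + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# The analysis stages of the pipeline run in memory on a simulated truth:
# caller -> recoding annotation -> typing -> selection.
runSelectionFromTruth <- function(truth, counts) {
  cfg <- truth@config
  wt <- counts[!cfg@samples$adar_null]
  ev <- callCandidateEvents(wt, truth@models)
  ev <- ev[ev$region == "CDS" & !is.na(ev$gene), , drop = FALSE]
  ev$recoding <- classifyRecoding(truth@models, truth@genomes,
                                  ev$gene, ev$pos)
  typed <- classifyEventTypes(ev, truth@families, truth@models)
  keep <- typed$recoding %in% c("synonymous", "nonsynonymous")
  typed_k <- typed[keep, , drop = FALSE]
  obs <- do.call(rbind, lapply(split(typed_k, typed_k$type), function(d)
    data.frame(type = d$type[1],
               observed_nonsyn = sum(d$recoding == "nonsynonymous"),
               observed_syn = sum(d$recoding == "synonymous"))))
  poss <- do.call(rbind, lapply(split(typed_k, typed_k$type), function(d) {
    seqs <- editome:::.codingSequences(truth@models, truth@genomes,
                                       unique(d$gene))
    pe <- enumeratePotentialEdits(seqs)
    data.frame(type = d$type[1], possible_nonsyn = pe$possible_nonsyn,
               possible_syn = pe$possible_syn)
  }))
  list(typed = typed, table = selectionTest(obs, poss))
}
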