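#' @rdname callCandidateEvents
#' @param min_depth,min_end_distance_bp,min_distinct_reads,rate_low,rate_high,sample_fraction,keep_change
#'   see \linkS4class{CallerParams}
#' @export
callerParams <- function(min_depth = 5, min_end_distance_bp = 10,
                         min_distinct_reads = 2, rate_low = 0.01,
                         rate_high = 0.90, sample_fraction = 0.5,
                         keep_change = "AG") {
  new("CallerParams", min_depth = min_depth,
      min_end_distance_bp = min_end_distance_bp,
      min_distinct_reads = min_distinct_reads,
      rate_low = rate_low, rate_high = rate_high,
      sample_fraction = sample_fraction, keep_change = keep_change)
}

#' @rdname callCandidateEvents
#' @details \code{snpCallerParams} is the published SNP-calling variant of
#'   the filter: variance rate above 1\% with no upper bound.
#' @export
snpCallerParams <- function() callerParams(rate_high = 1, rate_low = 0.01)

.CHANGE_TYPES <- as.vector(outer(c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T"),
                                 function(a, b) paste0(a, ">", b)))
.CHANGE_TYPES <- .CHANGE_TYPES[substr(.CHANGE_TYPES, 1, 1) !=
                               substr(.CHANGE_TYPES, 3, 3)]

# Per-sample site evaluation shared by the caller, the spectrum and presence
# detection.  Adds depth, focal alt base (largest non-reference count, ties
# broken in A,C,G,T order), its count, the variance rate, and the pass flag
# for criteria 1-4.
.evalSites <- function(df, params) {
  bases <- c("A", "C", "G", "T")
  cm <- as.matrix(df[bases])
  depth <- rowSums(cm)
  ref_idx <- match(df$ref, bases)
  nonref <- cm
  nonref[cbind(seq_len(nrow(df)), ref_idx)] <- -1L
  alt_idx <- max.col(nonref, ties.method = "first")
  alt <- bases[alt_idx]
  alt_count <- cm[cbind(seq_len(nrow(df)), alt_idx)]
  rate <- ifelse(depth > 0, alt_count / depth, 0)
  pass <- depth >= params@min_depth &
    df$distinct_nonref_reads >= params@min_distinct_reads &
    df$nonref_reads_ge10bp_from_ends >= 1L &
    alt_count > 0L &
    rate >= params@rate_low & rate <= params@rate_high
  cbind(df, depth = depth, alt = alt, alt_count = alt_count,
        rate = rate, pass = pass)
}

# Aggregate per-sample evaluations into one row per site with the number of
# passing samples and the modal alt base among passing samples.
.aggregateSites <- function(evald) {
  all <- do.call(rbind, lapply(names(evald), function(s) {
    e <- evald[[s]]
    data.frame(sample = s, chrom = e$chrom, pos = e$pos, ref = e$ref,
               alt = e$alt, rate = e$rate, pass = e$pass,
               stringsAsFactors = FALSE)
  }))
  key <- paste(all$chrom, all$pos, sep = ":")
  passing <- all[all$pass, , drop = FALSE]
  pkey <- paste(passing$chrom, passing$pos, sep = ":")
  n_pass <- table(pkey)
  uk <- unique(pkey)
  modal_alt <- vapply(uk, function(k) {
    tt <- sort(table(passing$alt[pkey == k]), decreasing = TRUE)
    names(tt)[1L]
  }, character(1L))
  first <- match(uk, key)
  data.frame(chrom = all$chrom[first], pos = all$pos[first],
             ref = all$ref[first], alt = modal_alt,
             n_pass = as.integer(n_pass[uk]),
             stringsAsFactors = FALSE)
}

#' Call candidate A-to-I editing events from read-count tables
#'
#' Applies the six published filter criteria to per-site per-sample count
#' tables: (1) depth >= 5, (2) at least one supporting read more than 10 bp
#' from both read ends, (3) >= 2 non-identical supporting reads, (4)
#' variance rate within [1\%, 90\%] (bounds inclusive), (5) passing in at
#' least 50\% of samples (count >= ceiling(fraction x n)), and (6) the
#' change is A-to-G on the transcribed strand -- genomic A>G for plus-strand
#' genes, T>C for minus-strand genes.  Intergenic sites are kept if the
#' genomic change is A>G or T>C on either strand and reported with strand
#' \code{"."}.
#'
#' @param samples named list of site-count data.frames (columns
#'   \code{sample, chrom, pos, ref, A, C, G, T, distinct_nonref_reads,
#'   nonref_reads_ge10bp_from_ends})
#' @param models a \linkS4class{GeneModelSet} used for strand and region
#' @param params a \linkS4class{CallerParams}
#' @return data.frame of events: chrom, pos, strand, gene, region, ref, alt,
#'   n_pass, mean_level, plus one \code{level.<sample>} column per input
#'   sample (the per-sample variance rate, NA at zero depth)
#' @export
callCandidateEvents <- function(samples, models, params = callerParams()) {
  if (length(samples) == 0L) stop("empty sample list")
  chrom_sets <- lapply(samples, function(s) unique(s$chrom))
  if (length(samples) > 1L &&
      length(Reduce(intersect, chrom_sets)) == 0L &&
      any(lengths(chrom_sets) > 0L))
    stop("inconsistent chromosome namespaces across samples")
  evald <- lapply(samples, .evalSites, params = params)
  agg <- .aggregateSites(evald)
  n <- length(samples)
  need <- ceiling(params@sample_fraction * n)
  agg <- agg[agg$n_pass >= need, , drop = FALSE]
  if (!nrow(agg))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), gene = character(),
                      region = character(), ref = character(),
                      alt = character(), n_pass = integer(),
                      mean_level = numeric()))

  # strand resolution and the A-to-G change filter
  genes_at <- .cdsGenesAt(models, agg$chrom, agg$pos)
  spans <- .geneSpans(models)
  site_gr <- GRanges(agg$chrom, IRanges(agg$pos, agg$pos))
  hit <- findOverlaps(site_gr, spans, ignore.strand = TRUE)
  span_genes <- vector("list", nrow(agg))
  for (i in seq_len(nrow(agg))) span_genes[[i]] <- character()
  if (length(hit)) {
    sp <- split(spans$gene_id[subjectHits(hit)], queryHits(hit))
    span_genes[as.integer(names(sp))] <- sp
  }
  strnd <- character(nrow(agg)); gene <- character(nrow(agg))
  keep <- logical(nrow(agg))
  for (i in seq_len(nrow(agg))) {
    cand_genes <- if (length(genes_at[[i]])) genes_at[[i]] else
      span_genes[[i]]
    chg <- paste0(agg$ref[i], ">", agg$alt[i])
    if (length(cand_genes)) {
      strands <- geneStrand(models, cand_genes)
      # a gene whose strand orients the change as A-to-G wins
      ok <- (strands == "+" & chg == "A>G") |
            (strands == "-" & chg == "T>C")
      if (params@keep_change == "none") ok <- rep(TRUE, length(ok))
      if (any(ok)) {
        j <- which(ok)[1L]
        strnd[i] <- strands[j]; gene[i] <- cand_genes[j]; keep[i] <- TRUE
      }
    } else {
      if (params@keep_change == "none" || chg %in% c("A>G", "T>C")) {
        strnd[i] <- "."; gene[i] <- NA_character_; keep[i] <- TRUE
      }
    }
  }
  if (params@keep_change == "none") keep[] <- TRUE
  agg$strand <- strnd; agg$gene <- gene
  agg <- agg[keep, , drop = FALSE]
  if (!nrow(agg)) {
    res <- agg
    res$region <- character(0); res$mean_level <- numeric(0)
    return(res[c("chrom", "pos", "strand", "gene", "region", "ref",
                 "alt", "n_pass", "mean_level")])
  }
  agg$region <- annotateRegion(models, agg$chrom, agg$pos)
  # per-sample variance rates at the retained sites
  key <- paste(agg$chrom, agg$pos, sep = ":")
  lv <- sapply(names(evald), function(s) {
    e <- evald[[s]]
    m <- match(key, paste(e$chrom, e$pos, sep = ":"))
    ifelse(!is.na(m) & e$depth[m] > 0, e$rate[m], NA_real_)
  })
  lv <- matrix(lv, nrow = nrow(agg),
               dimnames = list(NULL, paste0("level.", names(evald))))
  agg$mean_level <- rowMeans(lv, na.rm = TRUE)
  out <- cbind(agg[c("chrom", "pos", "strand", "gene", "region", "ref",
                     "alt", "n_pass", "mean_level")], lv)
  rownames(out) <- NULL
  out
}

#' Mismatch spectrum of candidate variant sites
#'
#' Tabulates the 12 ordered base-change types among sites passing the
#' depth/support/rate and majority-of-samples criteria with the change-type
#' filter disabled.
#'
#' @inheritParams callCandidateEvents
#' @return a \linkS4class{MismatchSpectrum}
#' @export
mismatchSpectrum <- function(samples, params = callerParams()) {
  if (length(samples) == 0L) stop("empty sample list")
  evald <- lapply(samples, .evalSites, params = params)
  agg <- .aggregateSites(evald)
  need <- ceiling(params@sample_fraction * length(samples))
  agg <- agg[agg$n_pass >= need & agg$ref != agg$alt, , drop = FALSE]
  if (!nrow(agg)) stop("no candidate sites pass the filters")
  chg <- paste0(agg$ref, ">", agg$alt)
  tt <- table(factor(chg, levels = .CHANGE_TYPES))
  props <- as.numeric(tt) / sum(tt)
  names(props) <- .CHANGE_TYPES
  new("MismatchSpectrum", proportions = props, n_sites = nrow(agg))
}

#' Background false-positive rate from the mismatch spectrum
#'
#' Under the assumptions that all non-canonical mismatches are background
#' noise and that the error rates of the 12 base-change types are equal, the
#' expected fraction of spurious calls within the A-to-G class is the
#' average non-canonical proportion divided by the A-to-G proportion:
#' \eqn{((1 - p_{AG})/11) / p_{AG}}.
#'
#' @param x a \linkS4class{MismatchSpectrum}, or the A>G proportion as a
#'   number in (0, 1]
#' @return the estimated false-positive fraction
#' @examples
#' backgroundFpRate(0.619)   # 0.0559..., i.e. ~5.6%
#' @export
backgroundFpRate <- function(x) {
  p_ag <- if (is(x, "MismatchSpectrum")) x@proportions[["A>G"]] else x
  if (!is.numeric(p_ag) || length(p_ag) != 1L)
    stop("need a MismatchSpectrum or a single A>G proportion")
  if (p_ag <= 0) stop("A>G proportion is zero; rate undefined")
  ((1 - p_ag) / 11) / p_ag
}

#' Keep only A/G single-nucleotide variants
#'
#' Restricts a SNP table to the changes that can masquerade as A-to-I
#' editing: genomic A>G, or T>C (A>G on the minus strand).
#'
#' @param snps data.frame with columns \code{chrom, pos, ref, alt}
#' @export
filterAgSnps <- function(snps) {
  snps[(snps$ref == "A" & snps$alt == "G") |
       (snps$ref == "T" & snps$alt == "C"), , drop = FALSE]
}

#' Cross-check editing events against genomic variants
#'
#' An event whose position matches an A/G genomic variant is a suspect,
#' possibly a SNP rather than an editing site; the flagged fraction
#' estimates the false-positive rate due to genomic variation.
#'
#' @param events event data.frame from \code{\link{callCandidateEvents}}
#' @param snps SNP table, already restricted with
#'   \code{\link{filterAgSnps}} (applied again defensively)
#' @return list(clean, flagged, fp_rate)
#' @export
snpCrosscheck <- function(events, snps) {
  if (nrow(events) == 0L)
    stop("no events: false-positive rate undefined")
  snps <- filterAgSnps(snps)
  hit <- paste(events$chrom, events$pos) %in% paste(snps$chrom, snps$pos)
  list(clean = events[!hit, , drop = FALSE],
       flagged = events[hit, , drop = FALSE],
       fp_rate = mean(hit))
}

#' Validate events against an editing-null sample
#'
#' Events called in the wild type whose position shows only the reference
#' base among the null-mutant reads are considered genuine; positions with
#' any non-reference reads in the null sample are suspects.  Events with
#' zero null-sample coverage are reported separately and excluded from the
#' rate denominator.
#'
#' @param events event data.frame
#' @param null_counts site-count table of the ADAR-null sample
#' @return list(genuine, suspect, uncovered, fp_rate)
#' @export
nullSampleValidation <- function(events, null_counts) {
  bases <- c("A", "C", "G", "T")
  key <- paste(null_counts$chrom, null_counts$pos)
  m <- match(paste(events$chrom, events$pos), key)
  cm <- as.matrix(null_counts[bases])
  depth_all <- rowSums(cm)
  refc_all <- cm[cbind(seq_len(nrow(null_counts)),
                       match(null_counts$ref, bases))]
  depth <- depth_all[m]
  ref_count <- refc_all[m]
  covered <- !is.na(m) & !is.na(depth) & depth > 0
  adenosine_only <- covered & (depth == ref_count)
  genuine <- events[adenosine_only, , drop = FALSE]
  suspect <- events[covered & !adenosine_only, , drop = FALSE]
  uncovered <- events[!covered, , drop = FALSE]
  if (!sum(covered))
    stop("no events covered in the null sample; rate undefined")
  list(genuine = genuine, suspect = suspect, uncovered = uncovered,
       fp_rate = 1 - nrow(genuine) / sum(covered))
}

#' Confirm an editing site from cDNA/gDNA genotyping signals
#'
#' A site is confirmed when the edited allele is visible in cDNA while the
#' genome is homozygous reference -- cDNA G/(A+G) >= 0.10 and gDNA
#' A/(A+G) > 0.90 -- or when the odds ratio
#' (cDNA G/A) / (gDNA G/A) exceeds 3.  Zero denominators in the odds-ratio
#' branch fall back to the threshold branch alone.  A heterozygous A/G SNP
#' (gDNA ~50/50) fails both branches.
#'
#' @param cdna,gdna numeric pairs c(A, G) of allele signals
#' @return logical: confirmed or not
#' @export
confirmByGenotyping <- function(cdna, gdna) {
  stopifnot(length(cdna) == 2L, length(gdna) == 2L)
  if (sum(cdna) <= 0 || sum(gdna) <= 0)
    stop("signal totals must be positive")
  cA <- cdna[[1L]]; cG <- cdna[[2L]]
  gA <- gdna[[1L]]; gG <- gdna[[2L]]
  thresh <- (cG / (cA + cG) >= 0.10) && (gA / (gA + gG) > 0.90)
  or_ok <- FALSE
  if (cA > 0 && gA > 0 && gG > 0)
    or_ok <- (cG / cA) / (gG / gA) > 3
  isTRUE(thresh || or_ok)
}
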