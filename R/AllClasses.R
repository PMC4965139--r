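#' Gene model container
#'
#' Holds transcript structure for a set of genes: CDS and UTR intervals as a
#' \link[GenomicRanges]{GRanges} (1-based, inclusive), one strand and
#' chromosome per gene, plus a per-gene table with an ncRNA flag.  Total CDS
#' length of every protein-coding gene must be divisible by three and the
#' intervals of a gene must not overlap.
#'
#' @slot features GRanges with metadata columns \code{gene_id} and
#'   \code{type} (one of \code{CDS}, \code{five_prime_UTR},
#'   \code{three_prime_UTR}, \code{ncRNA}).
#' @slot genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{ncRNA}.
#' @aliases GeneModelSet
#' @exportClass GeneModelSet
setClass("GeneModelSet",
         representation(features = "GRanges", genes = "data.frame"))

setValidity("GeneModelSet", function(object) {
  ft <- object@features
  gn <- object@genes
  msgs <- character()
  ok_types <- c("CDS", "five_prime_UTR", "three_prime_UTR", "ncRNA")
  if (length(ft)) {
    if (is.null(ft$gene_id) || is.null(ft$type))
      return("features need 'gene_id' and 'type' metadata columns")
    if (!all(ft$type %in% ok_types))
      msgs <- c(msgs, paste("unknown feature type(s):",
                            paste(setdiff(unique(ft$type), ok_types),
                                  collapse = ", ")))
    if (!all(ft$gene_id %in% gn$gene_id))
      msgs <- c(msgs, "features reference genes absent from the gene table")
  }
  if (anyDuplicated(gn$gene_id))
    msgs <- c(msgs, "duplicated gene_id in gene table")
  cds <- ft[ft$type == "CDS" &
            ft$gene_id %in% gn$gene_id[!gn$ncRNA]]
  if (length(cds)) {
    wsum <- tapply(BiocGenerics::width(cds), cds$gene_id, sum)
    bad3 <- names(wsum)[wsum %% 3L != 0L]
    if (length(bad3))
      msgs <- c(msgs, paste0("gene ", bad3,
                             ": total CDS length not divisible by 3"))
    nint <- table(cds$gene_id)
    for (g in names(nint)[nint > 1L]) {
      gi <- cds[cds$gene_id == g]
      if (sum(BiocGenerics::width(GenomicRanges::reduce(gi))) !=
          sum(BiocGenerics::width(gi)))
        msgs <- c(msgs, paste0("gene ", g, ": overlapping CDS intervals"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Homologous gene family container
#'
#' Family membership (which genes of which species belong to which family)
#' together with per-family protein alignments.  Aligned sequences of a
#' family must have equal length; gap characters are \code{-}.
#'
#' @slot members data.frame with columns \code{family_id}, \code{species},
#'   \code{gene_id}.
#' @slot alignments named list (by \code{family_id}) of named character
#'   vectors of aligned amino-acid sequences (names are gene ids).
#' @aliases GeneFamilySet
#' @exportClass GeneFamilySet
setClass("GeneFamilySet",
         representation(members = "data.frame", alignments = "list"))

setValidity("GeneFamilySet", function(object) {
  mb <- object@members
  msgs <- character()
  if (!all(c("family_id", "species", "gene_id") %in% names(mb)))
    return("members needs columns family_id, species, gene_id")
  if (nrow(mb) && anyDuplicated(mb$gene_id))
    msgs <- c(msgs, "a gene may belong to exactly one family")
  for (fid in names(object@alignments)) {
    aln <- object@alignments[[fid]]
    if (length(aln) && length(unique(nchar(aln))) != 1L)
      msgs <- c(msgs, paste0("family ", fid, ": unequal aligned lengths"))
    if (!all(names(aln) %in% mb$gene_id[mb$family_id == fid]))
      msgs <- c(msgs, paste0("family ", fid,
                             ": alignment holds non-member sequences"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic editome generator.  Defaults emulate the study
#' conditions of a multi-species fly editome survey: seven species, gene
#' families of two to four members, per-type event rates close to the
#' empirical events-per-gene, recoding bias suppressing non-synonymous edits
#' for types I/II and favouring them for type III, Beta-distributed editing
#' levels, negative-binomial sequencing depth, Illumina-scale error rate and
#' sparse A/G SNP contamination, with one ADAR-null sample among the
#' replicates.
#'
#' @slot n_species,n_families counts
#' @slot singleton_fraction fraction of families with a single member
#' @slot family_size_range integer pair (min, max), min >= 2
#' @slot cds_length_codons integer pair (min, max)
#' @slot per_type_event_rates named numeric (I, II, III), events per gene
#' @slot nonsyn_bias named numeric (I, II, III): odds multiplier applied to
#'   non-synonymous candidate adenosines
#' @slot editing_level_dist (alpha, beta) of the Beta law for true levels
#' @slot depth_dist (mean, size) of the negative-binomial depth law
#' @slot seq_error_rate per-base sequencing error fraction
#' @slot snp_rate per-candidate-adenosine SNP fraction
#' @slot samples data.frame with columns sample_id, tissue, adar_null
#' @slot branch_mut_rate per-site mutation rate applied on each family branch
#' @slot syn_mut_bias fraction of branch mutations forced synonymous
#' @slot n_background_sites non-variant sites carried in each count table
#' @slot type3_head_only when TRUE type III events are expressed (non-zero
#'   level) only in samples whose tissue is "head"
#' @slot allow_stop_targets allow stop-loss adenosines as editing targets
#' @slot seed integer random seed
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
         representation(
           n_species = "integer", n_families = "integer",
           singleton_fraction = "numeric", family_size_range = "integer",
           cds_length_codons = "integer", per_type_event_rates = "numeric",
           nonsyn_bias = "numeric", editing_level_dist = "numeric",
           depth_dist = "numeric", seq_error_rate = "numeric",
           snp_rate = "numeric", samples = "data.frame",
           branch_mut_rate = "numeric", syn_mut_bias = "numeric",
           n_background_sites = "integer", type3_head_only = "logical",
           allow_stop_targets = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@family_size_range[1L] < 2L)
    msgs <- c(msgs, "family_size_range min must be >= 2")
  if (object@family_size_range[2L] > object@n_species)
    msgs <- c(msgs, "family_size_range max cannot exceed n_species")
  for (f in c("singleton_fraction", "seq_error_rate", "snp_rate",
              "syn_mut_bias", "branch_mut_rate")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msgs <- c(msgs, paste(f, "must lie in [0, 1]"))
  }
  if (any(object@per_type_event_rates < 0))
    msgs <- c(msgs, "event rates must be >= 0")
  if (!all(c("I", "II", "III") %in% names(object@per_type_event_rates)))
    msgs <- c(msgs, "per_type_event_rates needs entries I, II, III")
  if (!all(c("I", "II", "III") %in% names(object@nonsyn_bias)))
    msgs <- c(msgs, "nonsyn_bias needs entries I, II, III")
  if (!all(c("sample_id", "tissue", "adar_null") %in%
           names(object@samples)))
    msgs <- c(msgs, "samples needs columns sample_id, tissue, adar_null")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic ground truth
#'
#' Output of \code{\link{generateTruth}}: per-species genomes, gene models,
#' gene families with alignments, the injected editing events with their true
#' conservation type and level, and the injected SNPs.
#'
#' @slot genomes \link[Biostrings]{DNAStringSet}, one entry per chromosome
#' @slot models \linkS4class{GeneModelSet}
#' @slot families \linkS4class{GeneFamilySet}
#' @slot events data.frame: chrom, pos, strand, gene, species, cds_pos,
#'   codon_column, type, recoding, level, cluster_id
#' @slot snps data.frame: chrom, pos, ref, alt, genotype
#' @slot config the \linkS4class{SimConfig} used
#' @aliases SyntheticTruth
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(genomes = "DNAStringSet", models = "GeneModelSet",
                        families = "GeneFamilySet", events = "data.frame",
                        snps = "data.frame", config = "SimConfig"))

setValidity("SyntheticTruth", function(object) {
  ev <- object@events
  msgs <- character()
  if (nrow(ev)) {
    sizes <- table(object@families@members$family_id)
    fam_of <- setNames(object@families@members$family_id,
                       object@families@members$gene_id)
    singleton <- sizes[fam_of[ev$gene]] == 1L
    if (any(ev$type == "I" & !singleton))
      msgs <- c(msgs, "type I event outside a singleton gene")
    if (any(ev$type != "I" & singleton))
      msgs <- c(msgs, "type II/III event in a singleton gene")
    iii <- ev[ev$type == "III", , drop = FALSE]
    if (nrow(iii)) {
      per <- tapply(iii$gene, iii$cluster_id,
                    function(g) length(unique(g)))
      if (any(per < 2L))
        msgs <- c(msgs, "type III cluster with fewer than two members")
    }
    if (nrow(object@snps) &&
        any(paste(ev$chrom, ev$pos) %in%
            paste(object@snps$chrom, object@snps$pos)))
      msgs <- c(msgs, "SNP and editing sites must be disjoint")
  }
  if (length(msgs)) msgs else TRUE
})

#' Editing-site caller parameters
#'
#' Thresholds of the six-criterion editing-site filter.  The defaults are the
#' published pipeline settings: depth >= 5, at least one supporting read more
#' than 10 bp from both read ends, >= 2 non-identical supporting reads,
#' variance rate within [1\%, 90\%] (inclusive), a site must pass in at least
#' 50\% of samples, and only A-to-G changes on the transcribed strand are
#' kept.
#'
#' @slot min_depth minimum read depth
#' @slot min_end_distance_bp read-end exclusion distance (informational; the
#'   count tables carry the interior-read count precomputed at this cutoff)
#' @slot min_distinct_reads minimum non-identical supporting reads
#' @slot rate_low,rate_high inclusive variance-rate bounds
#' @slot sample_fraction fraction of samples that must pass
#' @slot keep_change "AG" to retain A-to-G on the transcribed strand only,
#'   "none" to disable the change-type filter (criteria 1-5 only)
#' @aliases CallerParams
#' @exportClass CallerParams
setClass("CallerParams",
         representation(min_depth = "numeric", min_end_distance_bp = "numeric",
                        min_distinct_reads = "numeric", rate_low = "numeric",
                        rate_high = "numeric", sample_fraction = "numeric",
                        keep_change = "character"))

setValidity("CallerParams", function(object) {
  if (object@rate_low < 0 || object@rate_high > 1 ||
      object@rate_low >= object@rate_high)
    return("need 0 <= rate_low < rate_high <= 1")
  if (!object@keep_change %in% c("AG", "none"))
    return("keep_change must be 'AG' or 'none'")
  TRUE
})

#' Mismatch spectrum
#'
#' Proportions of the 12 ordered base-change types among candidate variant
#' sites that pass the depth/support/rate filters with the change-type filter
#' disabled.  Proportions sum to one.
#'
#' @slot proportions named numeric of length 12 ("A>C", "A>G", ...)
#' @slot n_sites number of candidate sites behind the spectrum
#' @aliases MismatchSpectrum
#' @exportClass MismatchSpectrum
setClass("MismatchSpectrum",
         representation(proportions = "numeric", n_sites = "integer"))

setValidity("MismatchSpectrum", function(object) {
  if (length(object@proportions) != 12L)
    return("proportions must have 12 entries")
  if (abs(sum(object@proportions) - 1) > 1e-9)
    return("proportions must sum to 1")
  TRUE
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", nrow(object@genes), "genes and",
      length(object@features), "features\n")
  tt <- table(object@features$type)
  if (length(tt)) cat(" ", paste(names(tt), tt, collapse = ", "), "\n")
})

setMethod("show", "GeneFamilySet", function(object) {
  n_fam <- length(unique(object@members$family_id))
  cat("GeneFamilySet with", n_fam, "families,",
      nrow(object@members), "member genes,",
      length(object@alignments), "alignments\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_families, "families across",
      object@n_species, "species;",
      nrow(object@samples), "samples; seed", object@seed, "\n")
  cat("  event rates/gene:",
      paste(names(object@per_type_event_rates),
            signif(object@per_type_event_rates, 3), collapse = ", "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@genomes), "chromosomes,",
      nrow(object@models@genes), "genes,",
      nrow(object@events), "true editing events,",
      nrow(object@snps), "SNPs\n")
  if (nrow(object@events))
    print(table(type = object@events$type))
})

setMethod("show", "CallerParams", function(object) {
  cat(sprintf(paste0("CallerParams: depth>=%g, distinct>=%g, ",
                     "rate in [%g, %g], sample fraction %g, change %s\n"),
              object@min_depth, object@min_distinct_reads, object@rate_low,
              object@rate_high, object@sample_fraction, object@keep_change))
})

setMethod("show", "MismatchSpectrum", function(object) {
  cat("MismatchSpectrum over", object@n_sites, "candidate sites\n")
  print(round(object@proportions, 4))
})
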