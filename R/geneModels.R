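#' Construct a gene model set
#'
#' @param features \link[GenomicRanges]{GRanges} of 1-based inclusive
#'   intervals with metadata columns \code{gene_id} and \code{type}
#'   (\code{CDS}, \code{five_prime_UTR}, \code{three_prime_UTR},
#'   \code{ncRNA}).
#' @param ncRNA character vector of gene ids that are non-coding.
#' @return a \linkS4class{GeneModelSet}
#' @export
geneModelSet <- function(features, ncRNA = character()) {
  if (length(features)) {
    ids <- unique(features$gene_id)
    chrom <- as.character(seqnames(features))[match(ids, features$gene_id)]
    strnd <- as.character(strand(features))[match(ids, features$gene_id)]
  } else {
    ids <- character(); chrom <- character(); strnd <- character()
  }
  genes <- data.frame(gene_id = ids, chrom = chrom, strand = strnd,
                      ncRNA = ids %in% ncRNA, stringsAsFactors = FALSE)
  new("GeneModelSet", features = features, genes = genes)
}

#' @rdname geneModelSet
#' @param x a GeneModelSet
#' @export
geneIds <- function(x) x@genes$gene_id

#' @rdname geneModelSet
#' @param gene gene id(s)
#' @export
geneStrand <- function(x, gene) {
  x@genes$strand[match(gene, x@genes$gene_id)]
}

#' CDS intervals of one gene, sorted 5' to 3' in transcript orientation
#' @inheritParams geneStrand
#' @return GRanges of CDS intervals
#' @export
cdsRanges <- function(x, gene) {
  cds <- x@features[x@features$gene_id == gene & x@features$type == "CDS"]
  cds <- cds[order(start(cds))]
  if (geneStrand(x, gene) == "-") cds <- cds[rev(seq_along(cds))]
  cds
}

# Genomic span of each gene (smallest interval covering all its features).
.geneSpans <- function(x) {
  ft <- x@features
  if (!length(ft)) return(GRanges())
  ids <- unique(ft$gene_id)
  s <- tapply(start(ft), ft$gene_id, min)[ids]
  e <- tapply(end(ft), ft$gene_id, max)[ids]
  ch <- as.character(seqnames(ft))[match(ids, ft$gene_id)]
  st <- as.character(strand(ft))[match(ids, ft$gene_id)]
  sp <- GRanges(ch, IRanges(as.integer(s), as.integer(e)), strand = st)
  sp$gene_id <- ids
  sp
}

#' Coding sequence of a gene
#'
#' Concatenates the CDS intervals in transcript order; minus-strand genes are
#' reverse-complemented so the result reads 5' to 3' on the coding strand.
#'
#' @inheritParams geneStrand
#' @param genome named \link[Biostrings]{DNAStringSet} of chromosomes
#' @return a \link[Biostrings]{DNAString}
#' @export
codingSequence <- function(x, genome, gene) {
  cds <- cdsRanges(x, gene)
  if (!length(cds)) stop("gene ", gene, " has no CDS")
  chrom <- as.character(seqnames(cds))[1L]
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " absent from genome")
  ord <- order(start(cds))
  seqs <- lapply(ord, function(i)
    subseq(genome[[chrom]], start(cds)[i], end(cds)[i]))
  s <- do.call(Biostrings::xscat, seqs)
  if (geneStrand(x, gene) == "-") s <- reverseComplement(s)
  as(s, "DNAString")
}

# Plain-vector view of every gene's CDS (chrom, strand, sorted interval
# starts/ends).  One pass over the GRanges; the hot paths below index this
# instead of subsetting S4 objects per gene.
.cdsInfoTable <- function(x) {
  ft <- x@features
  sel <- which(ft$type == "CDS")
  gene <- ft$gene_id[sel]
  chrom <- as.character(seqnames(ft))[sel]
  st <- start(ft)[sel]; en <- end(ft)[sel]
  strand_of <- setNames(x@genes$strand, x@genes$gene_id)
  idx <- split(seq_along(gene), gene)
  lapply(idx, function(i) {
    i <- i[order(st[i])]
    g <- gene[i[1L]]
    list(chrom = chrom[i[1L]], strand = strand_of[[g]],
         starts = st[i], ends = en[i])
  })
}

# CDS coordinate arithmetic on a .cdsInfoTable entry.
.cdsCoordPlain <- function(info, pos) {
  w <- info$ends - info$starts + 1L
  before <- cumsum(c(0L, w))[seq_along(w)]
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(info$starts)) {
    hit <- pos >= info$starts[i] & pos <= info$ends[i]
    out[hit] <- before[i] + (pos[hit] - info$starts[i] + 1L)
  }
  if (info$strand == "-") {
    total <- sum(w)
    out <- ifelse(is.na(out), NA_integer_, total - out + 1L)
  }
  out
}

# Coding-strand CDS sequence from a pre-converted character genome.
.codingSeqPlain <- function(info, genome_chr) {
  s <- paste(substring(genome_chr[[info$chrom]], info$starts, info$ends),
             collapse = "")
  if (info$strand == "-") s <- .revcomp(s)
  s
}

# Coding sequences of many genes at once (single GRanges pass).
.codingSequences <- function(x, genome, genes) {
  info_tab <- .cdsInfoTable(x)
  genome_chr <- as.character(genome)
  vapply(genes, function(g) {
    info <- info_tab[[g]]
    if (is.null(info)) stop("gene ", g, " has no CDS")
    .codingSeqPlain(info, genome_chr)
  }, character(1L))
}

# Map genomic positions inside a gene's CDS to 1-based coding-strand CDS
# coordinates.  Returns NA for positions outside the CDS.
.cdsCoordinate <- function(x, gene, pos) {
  info <- .cdsInfoTable(x)[[gene]]
  if (is.null(info)) stop("gene ", gene, " has no CDS")
  .cdsCoordPlain(info, pos)
}

#' Read and write gene models as GFF3
#'
#' \code{readGeneModels} keeps \code{CDS}, \code{five_prime_UTR},
#' \code{three_prime_UTR} and \code{ncRNA} features and requires a
#' \code{gene_id} attribute; \code{writeGeneModels} emits one \code{gene}
#' record per gene plus its feature children.  Coordinates are 1-based
#' inclusive on both sides of the round trip.
#'
#' @param x a \linkS4class{GeneModelSet}
#' @param path GFF3 file path
#' @return \code{readGeneModels} returns a GeneModelSet.
#' @export
writeGeneModels <- function(x, path) {
  spans <- .geneSpans(x)
  if (length(spans)) {
    spans$type <- "gene"
    mcols(spans) <- mcols(spans)[c("type", "gene_id")]
    ft <- x@features
    mcols(ft) <- mcols(ft)[c("type", "gene_id")]
    all <- c(spans, ft)
    all$ID <- paste0(all$gene_id, ifelse(all$type == "gene", "",
                                         paste0(":", all$type, ":",
                                                seq_along(all))))
    # phase of the first interval; later intervals carry the running frame
    all$phase <- NA_integer_
    for (g in unique(all$gene_id)) {
      i <- which(all$gene_id == g & all$type == "CDS")
      if (!length(i)) next
      i <- i[order(start(all)[i])]
      if (as.character(strand(all))[i[1L]] == "-")
        i <- i[rev(seq_along(i))]
      w <- width(all)[i]
      before <- cumsum(c(0L, w))[seq_along(i)]
      all$phase[i] <- as.integer((3L - before %% 3L) %% 3L)
    }
    all$type <- factor(all$type)
  } else {
    all <- GRanges()
  }
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGeneModels
#' @param ncRNA gene ids to flag as non-coding (in addition to genes whose
#'   features carry type \code{ncRNA})
#' @export
readGeneModels <- function(path, ncRNA = character()) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in%
    c("CDS", "five_prime_UTR", "three_prime_UTR", "ncRNA")
  gr <- gr[keep]
  if (length(gr) && is.null(gr$gene_id))
    stop(path, ": features lack a gene_id attribute")
  ft <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                strand = strand(gr))
  ft$gene_id <- as.character(gr$gene_id)
  ft$type <- as.character(gr$type)
  auto_nc <- unique(ft$gene_id[ft$type == "ncRNA"])
  geneModelSet(ft, ncRNA = union(ncRNA, auto_nc))
}

#' Refine UTR boundaries from transcriptome coverage
#'
#' Extends each protein-coding gene's CDS into flanking untranslated regions
#' along contiguously covered bases, capped at \code{max_utr5} upstream of
#' the start codon and \code{max_utr3} downstream of the stop codon (the
#' published caps, chosen so that 95\% of known fly UTRs fall within them),
#' and truncated at the nearest neighbouring gene boundary.  Genes that
#' already carry UTR features, and ncRNA genes, are left unchanged.
#'
#' @param x a \linkS4class{GeneModelSet}
#' @param coverage named list (by chromosome) of integer vectors of per-base
#'   read depth
#' @param max_utr5,max_utr3 UTR length caps in bp
#' @param min_depth a base is "covered" at depth >= this (default 1)
#' @return a GeneModelSet with \code{five_prime_UTR}/\code{three_prime_UTR}
#'   features added
#' @export
refineUtrs <- function(x, coverage, max_utr5 = 600L, max_utr3 = 1400L,
                       min_depth = 1L) {
  spans <- .geneSpans(x)
  new_feats <- list()
  for (g in geneIds(x)) {
    if (x@genes$ncRNA[x@genes$gene_id == g]) next
    has_utr <- any(x@features$gene_id == g &
                   x@features$type %in% c("five_prime_UTR",
                                          "three_prime_UTR"))
    if (has_utr) next
    chrom <- x@genes$chrom[x@genes$gene_id == g]
    if (!chrom %in% names(coverage)) next
    cov <- coverage[[chrom]]
    cds <- x@features[x@features$gene_id == g & x@features$type == "CDS"]
    if (!length(cds)) next
    gstart <- min(start(cds)); gend <- max(end(cds))
    plus <- geneStrand(x, g) == "+"
    others <- spans[spans$gene_id != g &
                    as.character(seqnames(spans)) == chrom]
    # nearest neighbouring gene boundaries on each side
    left_lim <- suppressWarnings(max(end(others)[end(others) < gstart]))
    right_lim <- suppressWarnings(min(start(others)[start(others) > gend]))
    left_lim <- if (is.finite(left_lim)) left_lim + 1L else 1L
    right_lim <- if (is.finite(right_lim)) right_lim - 1L
                 else length(cov)
    walk <- function(from, dir, cap, lim) {
      n <- 0L
      p <- from + dir
      while (n < cap && p >= 1L && p <= length(cov)) {
        if (dir > 0L && p > lim) break
        if (dir < 0L && p < lim) break
        if (cov[p] < min_depth) break
        n <- n + 1L
        p <- p + dir
      }
      n
    }
    up <- walk(gstart, -1L, if (plus) max_utr5 else max_utr3, left_lim)
    down <- walk(gend, 1L, if (plus) max_utr3 else max_utr5, right_lim)
    add <- function(s, e, type) {
      if (e < s) return(NULL)
      gr <- GRanges(chrom, IRanges(s, e),
                    strand = if (plus) "+" else "-")
      gr$gene_id <- g
      gr$type <- type
      gr
    }
    f1 <- add(gstart - up, gstart - 1L,
              if (plus) "five_prime_UTR" else "three_prime_UTR")
    f2 <- add(gend + 1L, gend + down,
              if (plus) "three_prime_UTR" else "five_prime_UTR")
    new_feats <- c(new_feats, Filter(Negate(is.null), list(f1, f2)))
  }
  if (length(new_feats)) {
    feats <- c(x@features, do.call(c, new_feats))
    x <- geneModelSet(feats, ncRNA = x@genes$gene_id[x@genes$ncRNA])
  }
  x
}

#' Annotate genomic sites with a region class
#'
#' Assigns each site exactly one label with precedence
#' CDS > UTR5 > UTR3 > ncRNA > intronic > intergenic when annotations
#' overlap.  A site inside a gene span but in none of its intervals is
#' intronic.
#'
#' @param x a \linkS4class{GeneModelSet}
#' @param chrom,pos parallel vectors of chromosome and 1-based position
#' @return character vector of labels, one per site
#' @export
annotateRegion <- function(x, chrom, pos) {
  n <- length(pos)
  stopifnot(length(chrom) == n)
  out <- rep("intergenic", n)
  if (!length(x@features)) return(out)
  sites <- GRanges(chrom, IRanges(pos, pos))
  label_of <- c(CDS = "CDS", five_prime_UTR = "UTR5",
                three_prime_UTR = "UTR3", ncRNA = "ncRNA")
  spans <- .geneSpans(x)
  hit <- findOverlaps(sites, spans, ignore.strand = TRUE)
  is_nc <- setNames(x@genes$ncRNA, x@genes$gene_id)
  has_nc <- tapply(spans$gene_id[subjectHits(hit)], queryHits(hit),
                   function(g) any(is_nc[g]))
  idx <- as.integer(names(has_nc))
  out[idx] <- ifelse(has_nc, "ncRNA", "intronic")
  precedence <- c("ncRNA", "three_prime_UTR", "five_prime_UTR", "CDS")
  for (type in precedence) {
    ft <- x@features[x@features$type == type]
    if (!length(ft)) next
    hit <- findOverlaps(sites, ft, ignore.strand = TRUE)
    out[unique(queryHits(hit))] <- label_of[[type]]
  }
  out
}

# Genes whose CDS covers each site (list parallel to pos).
.cdsGenesAt <- function(x, chrom, pos) {
  sites <- GRanges(chrom, IRanges(pos, pos))
  cds <- x@features[x@features$type == "CDS"]
  hit <- findOverlaps(sites, cds, ignore.strand = TRUE)
  res <- vector("list", length(pos))
  for (i in seq_along(res)) res[[i]] <- character()
  if (length(hit)) {
    sp <- split(cds$gene_id[subjectHits(hit)], queryHits(hit))
    res[as.integer(names(sp))] <- lapply(sp, unique)
  }
  res
}

#' Classify the recoding effect of an A-to-G edit
#'
#' For a CDS site whose coding-strand base is adenosine, substitutes G within
#' its codon and compares the translations under the standard nuclear code.
#' Changes touching a stop codon (stop-loss) are labelled
#' \code{stop_change}.
#'
#' @param x a \linkS4class{GeneModelSet}
#' @param genome named \link[Biostrings]{DNAStringSet}
#' @param gene gene id (scalar or vector recycled against \code{pos})
#' @param pos genomic position(s) within the gene's CDS
#' @return character vector: \code{synonymous}, \code{nonsynonymous} or
#'   \code{stop_change}
#' @export
classifyRecoding <- function(x, genome, gene, pos) {
  n <- max(length(gene), length(pos))
  gene <- rep_len(gene, n); pos <- rep_len(pos, n)
  out <- character(n)
  info_tab <- .cdsInfoTable(x)
  genome_chr <- as.character(genome)
  for (g in unique(gene)) {
    info <- info_tab[[g]]
    if (is.null(info)) stop("gene ", g, " has no CDS")
    sel <- which(gene == g)
    cds <- .codingSeqPlain(info, genome_chr)
    cpos <- .cdsCoordPlain(info, pos[sel])
    if (anyNA(cpos))
      stop("position(s) outside the CDS of gene ", g)
    base <- substring(cds, cpos, cpos)
    if (any(base != "A"))
      stop("reference base on the coding strand is not adenosine at ",
           g, ":", paste(pos[sel][base != "A"], collapse = ","))
    codon_idx <- (cpos - 1L) %/% 3L
    within <- cpos - codon_idx * 3L
    codon <- substring(cds, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
    out[sel] <- .recodingClass(codon, within)
  }
  out
}
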