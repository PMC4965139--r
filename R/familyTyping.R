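#' Construct a gene family set
#'
#' @param members data.frame with columns \code{family_id, species, gene_id}
#' @param alignments named list (by family id) of named character vectors of
#'   aligned amino-acid sequences (gaps as \code{-}); names are gene ids
#' @return a \linkS4class{GeneFamilySet}
#' @export
geneFamilySet <- function(members, alignments = list()) {
  new("GeneFamilySet", members = members, alignments = alignments)
}

#' @rdname geneFamilySet
#' @param x a GeneFamilySet
#' @param gene gene id(s)
#' @return \code{familyOf}: the family id of each gene (NA if unassigned)
#' @export
familyOf <- function(x, gene) {
  x@members$family_id[match(gene, x@members$gene_id)]
}

#' @rdname geneFamilySet
#' @return \code{familySizes}: named integer vector of member counts
#' @export
familySizes <- function(x) {
  tt <- table(x@members$family_id)
  setNames(as.integer(tt), names(tt))
}

#' Map a CDS site to its family alignment column
#'
#' Returns the aligned amino-acid column holding the event's codon: the
#' position of the codon-th non-gap character in the member's aligned
#' sequence.  With a gap-free alignment the column equals the codon index.
#'
#' @param models a \linkS4class{GeneModelSet}
#' @param families a \linkS4class{GeneFamilySet}
#' @param gene host gene id (must be present in its family alignment)
#' @param pos genomic position inside the gene's CDS
#' @return integer alignment column
#' @export
mapSiteToColumn <- function(models, families, gene, pos) {
  fid <- familyOf(families, gene)
  if (is.na(fid)) stop("gene ", gene, " belongs to no family")
  aln <- families@alignments[[fid]]
  if (is.null(aln) || !gene %in% names(aln))
    stop("gene ", gene, " absent from the alignment of family ", fid)
  cpos <- .cdsCoordinate(models, gene, pos)
  if (anyNA(cpos)) stop("position outside the CDS of gene ", gene)
  codon <- (cpos - 1L) %/% 3L + 1L
  chars <- strsplit(aln[[gene]], "", fixed = TRUE)[[1L]]
  nongap <- which(chars != "-")
  if (any(codon > length(nongap)))
    stop("codon beyond the aligned region of gene ", gene)
  nongap[codon]
}

#' Classify CDS editing events into conservation types
#'
#' Type I: the host gene is a singleton family.  Type III: events of a
#' multi-member family sharing an alignment column across at least two
#' distinct members (one cluster per family/column, labelled
#' \code{<family>:c<column>}).  Type II: remaining events in multi-member
#' families.  The three types partition the CDS events; classification is
#' independent of input order.
#'
#' @param events data.frame with columns \code{gene}, \code{pos},
#'   \code{chrom}; all events must be CDS (checked against \code{models})
#' @param families a \linkS4class{GeneFamilySet}
#' @param models a \linkS4class{GeneModelSet}
#' @return the events data.frame with \code{type}, \code{family_id},
#'   \code{alignment_column} and \code{cluster_id} columns appended
#' @export
classifyEventTypes <- function(events, families, models) {
  if (!nrow(events)) {
    events$type <- character(0); events$family_id <- character(0)
    events$alignment_column <- integer(0)
    events$cluster_id <- character(0)
    return(events)
  }
  region <- annotateRegion(models, events$chrom, events$pos)
  if (any(region != "CDS"))
    stop("non-CDS events cannot be typed (",
         sum(region != "CDS"), " offending)")
  fid <- familyOf(families, events$gene)
  if (anyNA(fid))
    stop("events in genes with no family: ",
         paste(unique(events$gene[is.na(fid)]), collapse = ", "))
  sizes <- familySizes(families)
  n <- nrow(events)
  col <- rep(NA_integer_, n)
  multi <- unname(sizes[fid] > 1L)
  info_tab <- .cdsInfoTable(models)
  nongap_cache <- list()
  for (g in unique(events$gene[multi])) {
    sel <- which(multi & events$gene == g)
    f <- fid[sel[1L]]
    aln <- families@alignments[[f]]
    if (is.null(aln) || !g %in% names(aln))
      stop("gene ", g, " absent from the alignment of family ", f)
    key <- paste(f, g)
    if (is.null(nongap_cache[[key]]))
      nongap_cache[[key]] <- which(
        strsplit(aln[[g]], "", fixed = TRUE)[[1L]] != "-")
    nongap <- nongap_cache[[key]]
    info <- info_tab[[g]]
    if (is.null(info)) stop("gene ", g, " has no CDS")
    cpos <- .cdsCoordPlain(info, events$pos[sel])
    if (anyNA(cpos)) stop("position outside the CDS of gene ", g)
    codon <- (cpos - 1L) %/% 3L + 1L
    if (any(codon > length(nongap)))
      stop("codon beyond the aligned region of gene ", g)
    col[sel] <- nongap[codon]
  }
  type <- ifelse(multi, "II", "I")
  cluster <- rep(NA_character_, n)
  key <- paste(fid, col, sep = ":c")
  for (k in unique(key[multi])) {
    idx <- which(key == k & multi)
    if (length(unique(events$gene[idx])) >= 2L) {
      type[idx] <- "III"
      cluster[idx] <- k
    }
  }
  events$type <- type
  events$family_id <- fid
  events$alignment_column <- col
  events$cluster_id <- cluster
  events
}

#' Bidirectional best hits
#'
#' Emits the pair (a, b) iff b is a's top-scoring hit and a is b's.  Score
#' ties are broken by lexicographic gene id and flagged.
#'
#' @param scores data.frame with columns \code{query, subject, score};
#'   queries and subjects come from the two proteomes being compared
#' @return data.frame of ortholog pairs: \code{a, b, score, tie}
#' @export
bbhPairs <- function(scores) {
  if (!nrow(scores))
    return(data.frame(a = character(), b = character(),
                      score = numeric(), tie = logical()))
  best <- function(df, from, to) {
    out <- lapply(split(df, df[[from]]), function(d) {
      top <- d[d$score == max(d$score), , drop = FALSE]
      tie <- nrow(top) > 1L
      top <- top[order(top[[to]]), , drop = FALSE][1L, ]
      data.frame(from = top[[from]], to = top[[to]],
                 score = top$score, tie = tie,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  fwd <- best(scores, "query", "subject")
  rev_ <- best(scores, "subject", "query")
  m <- match(fwd$to, rev_$from)
  mutual <- !is.na(m) & rev_$to[m] == fwd$from
  res <- data.frame(a = fwd$from[mutual], b = fwd$to[mutual],
                    score = fwd$score[mutual],
                    tie = fwd$tie[mutual] | rev_$tie[m][mutual],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$a), , drop = FALSE]
}
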