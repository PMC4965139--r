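#' Detect editing events in one sample
#'
#' An event is present in a sample when, at its position, depth >= 5, at
#' least one supporting read lies more than 10 bp from both read ends, and
#' at least two non-identical reads support the edited genotype.  Positions
#' absent from the count table are absent.
#'
#' @param events event data.frame (needs \code{chrom}, \code{pos})
#' @param counts site-count table of the sample
#' @param min_depth,min_distinct detection thresholds
#' @return logical vector parallel to \code{events}
#' @export
detectInSample <- function(events, counts, min_depth = 5L,
                           min_distinct = 2L) {
  bases <- c("A", "C", "G", "T")
  m <- match(paste(events$chrom, events$pos),
             paste(counts$chrom, counts$pos))
  cm <- as.matrix(counts[bases])
  depth <- rowSums(cm)[m]
  distinct <- counts$distinct_nonref_reads[m]
  interior <- counts$nonref_reads_ge10bp_from_ends[m]
  present <- !is.na(m) & depth >= min_depth & interior >= 1L &
    distinct >= min_distinct
  present & !is.na(present)
}

#' Per-site editing level
#'
#' The fraction of reads carrying the edited base (G for reference A, C for
#' reference T) among all reads covering the site.
#'
#' @param counts site-count table rows
#' @return numeric vector of levels; zero-coverage rows raise an error
#' @export
editingLevel <- function(counts) {
  bases <- c("A", "C", "G", "T")
  cm <- as.matrix(counts[bases])
  depth <- rowSums(cm)
  if (any(depth == 0))
    stop("zero coverage at ", sum(depth == 0),
         " site(s): editing level undefined")
  edited <- c(A = "G", T = "C", C = "T", G = "A")[counts$ref]
  cm[cbind(seq_len(nrow(cm)), match(edited, bases))] / depth
}

#' Build an events-by-samples presence matrix
#'
#' @param events event data.frame
#' @param samples named list of site-count tables
#' @param ... passed to \code{\link{detectInSample}}
#' @return logical matrix, rows labelled \code{chrom:pos}
#' @export
presenceMatrix <- function(events, samples, ...) {
  m <- vapply(samples, function(s) detectInSample(events, s, ...),
              logical(nrow(events)))
  m <- matrix(m, nrow = nrow(events),
              dimnames = list(paste0(events$chrom, ":", events$pos),
                              names(samples)))
  m
}

#' Complete-linkage clustering of a binary presence matrix
#'
#' Agglomerates samples (columns) and events (rows) by complete linkage on
#' Euclidean distances, the published clustering recipe for tissue
#' presence/absence profiles.  Labels are sorted first so that ties are
#' broken deterministically by label order.
#'
#' @param mat logical or 0/1 matrix, events x samples
#' @param margin "columns", "rows" or "both"
#' @return an \code{hclust} object, or list(columns=, rows=) for "both"
#' @export
clusterBinary <- function(mat, margin = c("both", "columns", "rows")) {
  margin <- match.arg(margin)
  one <- function(m) {
    if (nrow(m) < 2L) stop("need at least two profiles to cluster")
    m <- m[order(rownames(m)), , drop = FALSE]
    hclust(dist(m * 1, method = "euclidean"), method = "complete")
  }
  switch(margin,
         columns = one(t(mat)),
         rows = one(mat),
         both = list(columns = one(t(mat)), rows = one(mat)))
}

#' Export a dendrogram as Newick
#'
#' @param hc an \code{hclust} object
#' @param path optional file path; when NULL the Newick string is returned
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}

#' Kendall's tau-b rank correlation
#'
#' Pair-counting implementation with tie correction:
#' \eqn{\tau_b = (n_c - n_d)/\sqrt{(n_0 - n_1)(n_0 - n_2)}} where
#' \eqn{n_1, n_2} count tied pairs within each variable.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return correlation in [-1, 1]
#' @export
kendallTauB <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  nc <- 0L; nd <- 0L; tx <- 0L; ty <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1L; ty <- ty + 1L }
      else if (dx == 0) tx <- tx + 1L
      else if (dy == 0) ty <- ty + 1L
      else if (dx == dy) nc <- nc + 1L
      else nd <- nd + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tx) * (n0 - ty))
  if (denom == 0) stop("all pairs tied: tau-b undefined")
  (nc - nd) / denom
}

#' Gained and lost events between two conditions
#'
#' Differences two presence calls over a shared event universe: events
#' present only in condition A are lost, present only in B gained, each
#' annotated with its conservation type, editing levels and host-gene
#' expression in both conditions when supplied.
#'
#' @param presenceA,presenceB named logical vectors (same names)
#' @param types named character vector of event types (by event name)
#' @param levelsA,levelsB optional named numeric editing levels
#' @param expressionA,expressionB optional named numeric host-gene
#'   expression (by event name)
#' @return list(gained=, lost=) of data.frames
#' @export
stageDiff <- function(presenceA, presenceB, types = NULL,
                      levelsA = NULL, levelsB = NULL,
                      expressionA = NULL, expressionB = NULL) {
  if (!identical(sort(names(presenceA)), sort(names(presenceB))))
    stop("presence vectors must share one event universe")
  presenceB <- presenceB[names(presenceA)]
  build <- function(ids) {
    df <- data.frame(event = ids, stringsAsFactors = FALSE)
    grab <- function(v) if (is.null(v)) rep(NA, length(ids))
                        else unname(v[ids])
    df$type <- grab(types)
    df$levelA <- grab(levelsA); df$levelB <- grab(levelsB)
    df$exprA <- grab(expressionA); df$exprB <- grab(expressionB)
    df
  }
  list(lost = build(names(presenceA)[presenceA & !presenceB]),
       gained = build(names(presenceA)[!presenceA & presenceB]))
}

#' Normalise expression to a reference sample
#'
#' Divides each sample's expression by the reference sample's value,
#' mirroring reporting an enzyme's expression on a 0-1 scale with a chosen
#' tissue at 1.
#'
#' @param x named numeric vector of per-sample expression
#' @param reference name of the reference sample (default: the maximum)
#' @export
normalizeToReference <- function(x, reference = NULL) {
  ref_val <- if (is.null(reference)) max(x) else x[[reference]]
  if (ref_val == 0) stop("reference expression is zero")
  x / ref_val
}
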