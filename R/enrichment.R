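#' Hypergeometric GO-term enrichment
#'
#' For each annotation term, tests over-representation of the gene set among
#' the universe by the hypergeometric tail (probability of drawing at least
#' the observed number of term genes in \code{|gene_set|} draws without
#' replacement), and under-representation by the complementary tail.
#' P-values are Benjamini-Hochberg adjusted across the tested terms.  Under
#' the default preset a term is tested when it has at least 2 set genes and
#' 5 universe genes; the alternative \code{"strict"} preset requires more
#' than 4 set genes.  Ontology root terms are excluded.
#'
#' @param gene_set character vector of genes of interest (subset of
#'   \code{universe})
#' @param universe character vector of background genes
#' @param term_map data.frame with columns \code{gene, term} (optional
#'   \code{namespace})
#' @param preset "default" (set >= 2, universe >= 5) or "strict" (set > 4)
#' @param min_set_count,min_universe_count explicit testing thresholds that
#'   override the preset (e.g. \code{min_set_count = 0} to test
#'   under-representation of terms with no set genes)
#' @param exclude_terms term ids never tested (defaults to the GO roots)
#' @return data.frame: term, set_count, universe_count, p_over, p_under,
#'   fdr_over, fdr_under, ordered by p_over
#' @export
goEnrichment <- function(gene_set, universe, term_map,
                         preset = c("default", "strict"),
                         min_set_count = NULL, min_universe_count = NULL,
                         exclude_terms = c("GO:0008150", "GO:0003674",
                                           "GO:0005575")) {
  preset <- match.arg(preset)
  if (is.null(min_set_count))
    min_set_count <- if (preset == "strict") 5L else 2L
  if (is.null(min_universe_count))
    min_universe_count <- if (preset == "strict") 0L else 5L
  if (!all(gene_set %in% universe))
    stop("gene(s) outside the universe: ",
         paste(head(setdiff(gene_set, universe), 5L), collapse = ", "))
  gene_set <- unique(gene_set); universe <- unique(universe)
  term_map <- term_map[term_map$gene %in% universe &
                       !term_map$term %in% exclude_terms, , drop = FALSE]
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(split(term_map$gene, term_map$term), unique)
  res <- lapply(names(rows), function(tm) {
    K <- length(rows[[tm]])
    k <- sum(rows[[tm]] %in% gene_set)
    data.frame(term = tm, set_count = k, universe_count = K,
               p_over = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               p_under = phyper(k, K, N - K, n),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res))
    return(data.frame(term = character(), set_count = integer(),
                      universe_count = integer(), p_over = numeric(),
                      p_under = numeric(), fdr_over = numeric(),
                      fdr_under = numeric()))
  tested <- res$set_count >= min_set_count &
    res$universe_count >= min_universe_count
  res <- res[tested, , drop = FALSE]
  res$fdr_over <- p.adjust(res$p_over, method = "BH")
  res$fdr_under <- p.adjust(res$p_under, method = "BH")
  res <- res[order(res$p_over, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Protein-domain enrichment of editing events
#'
#' Tests whether editing events concentrate inside a domain family's
#' intervals.  For each domain family, \code{k} = events falling in its
#' intervals out of \code{n} total events, against the background
#' proportion \code{p0} = total family interval length / total gene length,
#' via the exact binomial tail (default), or via the hypergeometric
#' distribution over positions behind \code{method = "hypergeometric"}.
#' Families are tested only when they hold more than 4 events; BH-adjusted
#' p-values are reported.
#'
#' @param events data.frame with columns \code{gene} and \code{cds_pos}
#'   (1-based position within the gene CDS)
#' @param domains data.frame with columns \code{gene, domain, start, end}
#'   (CDS nucleotide intervals)
#' @param gene_lengths named numeric vector of CDS lengths for all genes in
#'   the background
#' @param method test formulation (see Details)
#' @param min_events minimum events in a family for it to be tested
#' @return data.frame: domain, set_count, domain_length, p0, p_over,
#'   p_under, fdr_over, fdr_under
#' @export
domainEnrichment <- function(events, domains, gene_lengths,
                             method = c("binomial", "hypergeometric"),
                             min_events = 5L) {
  method <- match.arg(method)
  total_len <- sum(gene_lengths)
  if (total_len <= 0) stop("zero total gene length")
  n <- nrow(events)
  res <- lapply(split(domains, domains$domain), function(d) {
    dl <- sum(d$end - d$start + 1)
    inside <- logical(n)
    for (r in seq_len(nrow(d))) {
      inside <- inside | (events$gene == d$gene[r] &
                          events$cds_pos >= d$start[r] &
                          events$cds_pos <= d$end[r])
    }
    k <- sum(inside)
    p0 <- dl / total_len
    if (method == "binomial") {
      p_over <- pbinom(k - 1L, n, p0, lower.tail = FALSE)
      p_under <- pbinom(k, n, p0)
    } else {
      white <- round(dl); black <- round(total_len - dl)
      p_over <- phyper(k - 1L, white, black, n, lower.tail = FALSE)
      p_under <- phyper(k, white, black, n)
    }
    data.frame(domain = d$domain[1L], set_count = k, domain_length = dl,
               p0 = p0, p_over = p_over, p_under = p_under,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res))
    return(data.frame(domain = character(), set_count = integer(),
                      domain_length = numeric(), p0 = numeric(),
                      p_over = numeric(), p_under = numeric(),
                      fdr_over = numeric(), fdr_under = numeric()))
  res <- res[res$set_count >= min_events, , drop = FALSE]
  res$fdr_over <- p.adjust(res$p_over, method = "BH")
  res$fdr_under <- p.adjust(res$p_under, method = "BH")
  res <- res[order(res$p_over, res$domain), , drop = FALSE]
  rownames(res) <- NULL
  res
}
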