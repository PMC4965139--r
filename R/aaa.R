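#' @import methods
#' @importFrom stats rbinom rpois rbeta rnbinom runif chisq.test fisher.test
#'   phyper pbinom p.adjust dist hclust cor setNames complete.cases
#' @importFrom utils read.delim write.table count.fields head
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom GenomicRanges GRanges reduce findOverlaps seqnames start end
#'   strand
#' @importFrom IRanges IRanges isDisjoint
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- DataFrame
#' @importFrom BiocGenerics width
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   writeXStringSet reverseComplement subseq GENETIC_CODE
NULL

# Codon-level recoding lookup for the single A->G substitution, built once at
# install time.  For codon `c` with an adenosine at position `p`, the class of
# replacing that A with G under the standard nuclear code:
#   "synonymous"     same amino acid
#   "stop_change"    stop <-> sense (only stop-loss is reachable by A->G)
#   "nonsynonymous"  amino acid replacement
# NA where the base at `p` is not A.
.CODONS <- names(Biostrings::GENETIC_CODE)
.AA <- Biostrings::GENETIC_CODE

.recodingLookup <- local({
  m <- matrix(NA_character_, nrow = length(.CODONS), ncol = 3,
              dimnames = list(.CODONS, NULL))
  for (cod in .CODONS) {
    for (p in 1:3) {
      if (substr(cod, p, p) != "A") next
      mut <- cod
      substr(mut, p, p) <- "G"
      a1 <- .AA[[cod]]
      a2 <- .AA[[mut]]
      m[cod, p] <- if (a1 == a2) "synonymous"
      else if (a1 == "*" || a2 == "*") "stop_change"
      else "nonsynonymous"
    }
  }
  m
})

.STOP_CODONS <- names(.AA)[.AA == "*"]
.SENSE_CODONS <- setdiff(.CODONS, .STOP_CODONS)

# Class of the A->G edit for vectors of codons and within-codon positions.
.recodingClass <- function(codon, pos) {
  .recodingLookup[cbind(match(codon, .CODONS), pos)]
}

.checkFraction <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

# Strict TSV reader: hard failure with a line number when a row does not have
# the expected number of fields (catches truncated files early).
.readTsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  n_fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(n_fields) > 1L && length(unique(n_fields)) > 1L) {
    bad <- which(n_fields != n_fields[1L])[1L]
    stop(path, ": line ", bad, " has ", n_fields[bad],
         " fields, expected ", n_fields[1L], call. = FALSE)
  }
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}

# Reverse complement on plain character strings (hot path in the simulator;
# avoids XString construction per gene).
.revcomp <- function(s) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1L))
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
}
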