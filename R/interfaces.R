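#' Read a bedGraph coverage track as per-chromosome depth vectors
#'
#' @param path bedGraph file (0-based half-open intervals)
#' @param seqlengths named integer vector giving each chromosome's length
#' @return named list of integer depth vectors, one per chromosome, suitable
#'   for \code{\link{refineUtrs}}
#' @export
readCoverageBedGraph <- function(path, seqlengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(seqlengths, function(n) integer(n))
  for (i in seq_along(gr)) {
    ch <- as.character(seqnames(gr))[i]
    if (!ch %in% names(out)) next
    from <- max(1L, start(gr)[i])
    to <- min(seqlengths[[ch]], end(gr)[i])
    if (to >= from)
      out[[ch]][from:to] <- out[[ch]][from:to] + as.integer(gr$score[i])
  }
  out
}

#' Write called events as VCF-like records
#'
#' Emits one record per event with the reference and edited base and an
#' INFO field carrying strand, region, recoding and conservation type when
#' present, plus the per-sample editing levels.
#'
#' @param events event data.frame (from \code{\link{callCandidateEvents}},
#'   optionally annotated/typed)
#' @param path output file
#' @export
writeEventsVcf <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Transcribed strand\">",
               "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Region class\">",
               "##INFO=<ID=RECODING,Number=1,Type=String,Description=\"Recoding class\">",
               "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Conservation type\">",
               "##INFO=<ID=LEVELS,Number=.,Type=Float,Description=\"Per-sample editing levels\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (!nrow(events)) return(invisible(path))
  lvl_cols <- grep("^level\\.", names(events), value = TRUE)
  for (i in seq_len(nrow(events))) {
    info <- c(paste0("STRAND=", events$strand[i]))
    if (!is.null(events$region)) info <- c(info,
      paste0("REGION=", events$region[i]))
    if (!is.null(events$recoding) && !is.na(events$recoding[i]))
      info <- c(info, paste0("RECODING=", events$recoding[i]))
    if (!is.null(events$type) && !is.na(events$type[i]))
      info <- c(info, paste0("TYPE=", events$type[i]))
    if (length(lvl_cols)) {
      lv <- unlist(events[i, lvl_cols])
      info <- c(info, paste0("LEVELS=",
                             paste(signif(lv, 4), collapse = ",")))
    }
    writeLines(paste(events$chrom[i], events$pos[i], ".",
                     events$ref[i], events$alt[i], ".", "PASS",
                     paste(info, collapse = ";"), sep = "\t"), con)
  }
  invisible(path)
}

#' Star alignment fallback for families without a supplied alignment
#'
#' Aligns every member pairwise to the first sequence (the star centre)
#' with linear scoring (match 1, mismatch -1, gap -2) and merges the
#' pairwise alignments over the centre's coordinates.  Intended only for
#' synthetic or fixture data whose divergence is small; real analyses
#' should supply curated family alignments.
#'
#' @param seqs named character vector of protein sequences
#' @return named character vector of aligned sequences of equal length
#' @export
starAlignment <- function(seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  center <- seqs[[1L]]
  letters_all <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  mat <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(mat) <- 1
  pats <- lapply(seqs[-1L], function(s)
    Biostrings::pairwiseAlignment(center, s, type = "global",
                                  substitutionMatrix = mat,
                                  gapOpening = 0, gapExtension = 2))
  # per member: aligned centre and member strings
  ctr_aln <- lapply(pats, function(p)
    strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1L]])
  mem_aln <- lapply(pats, function(p)
    strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1L]])
  L <- nchar(center)
  # insertions relative to the centre: count gap columns after centre
  # position i (i = 0 for leading insertions)
  ins <- matrix(0L, nrow = length(pats), ncol = L + 1L)
  for (k in seq_along(pats)) {
    ci <- 0L
    for (j in seq_along(ctr_aln[[k]])) {
      if (ctr_aln[[k]][j] == "-") ins[k, ci + 1L] <- ins[k, ci + 1L] + 1L
      else ci <- ci + 1L
    }
  }
  ins_max <- apply(ins, 2L, max)
  width_out <- L + sum(ins_max)
  build <- function(chars_ctr, chars_mem) {
    ci <- 0L
    emit <- function(slot, filled) {
      pad <- ins_max[slot] - length(filled)
      c(filled, rep("-", pad))
    }
    j <- 1L
    filled <- character(0)
    res <- character(0)
    while (j <= length(chars_ctr)) {
      if (chars_ctr[j] == "-") {
        filled <- c(filled, chars_mem[j])
      } else {
        res <- c(res, emit(ci + 1L, filled))
        filled <- character(0)
        ci <- ci + 1L
        res <- c(res, chars_mem[j])
      }
      j <- j + 1L
    }
    res <- c(res, emit(ci + 1L, filled))
    paste(res, collapse = "")
  }
  out <- character(length(seqs))
  names(out) <- names(seqs)
  ctr_chars <- strsplit(center, "")[[1L]]
  out[1L] <- build(ctr_chars, ctr_chars)
  for (k in seq_along(pats))
    out[k + 1L] <- build(ctr_aln[[k]], mem_aln[[k]])
  stopifnot(length(unique(nchar(out))) == 1L)
  out
}
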