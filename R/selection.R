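#' Enumerate all possible A-to-G recoding changes
#'
#' For every adenosine on the coding strand of each gene, classifies the
#' single A-to-G substitution as synonymous, non-synonymous or stop-affecting
#' under the standard nuclear code.  Stop-affecting changes are tracked
#' separately and excluded from both bins; codons containing ambiguous bases
#' are skipped and counted.
#'
#' @param genes named character vector or \link[Biostrings]{DNAStringSet} of
#'   coding-strand CDS sequences (lengths divisible by 3)
#' @return list with \code{possible_nonsyn}, \code{possible_syn},
#'   \code{possible_stop}, \code{n_ambiguous} and a \code{per_gene}
#'   data.frame breakdown
#' @export
enumeratePotentialEdits <- function(genes) {
  if (is(genes, "DNAStringSet")) {
    nm <- names(genes)
    genes <- as.character(genes)
    names(genes) <- nm
  }
  if (is.null(names(genes)))
    names(genes) <- paste0("gene", seq_along(genes))
  if (any(nchar(genes) %% 3L != 0L))
    stop("CDS length not divisible by 3 for: ",
         paste(names(genes)[nchar(genes) %% 3L != 0L], collapse = ", "))
  per <- lapply(names(genes), function(g) {
    s <- genes[[g]]
    n_cod <- nchar(s) %/% 3L
    codons <- substring(s, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    ambiguous <- !codons %in% .CODONS
    n_amb <- sum(vapply(strsplit(codons[ambiguous], "", fixed = TRUE),
                        function(x) sum(x == "A"), integer(1L)))
    codons <- codons[!ambiguous]
    cls <- c(.recodingLookup[codons, 1L], .recodingLookup[codons, 2L],
             .recodingLookup[codons, 3L])
    data.frame(gene = g,
               possible_syn = sum(cls == "synonymous", na.rm = TRUE),
               possible_nonsyn = sum(cls == "nonsynonymous", na.rm = TRUE),
               possible_stop = sum(cls == "stop_change", na.rm = TRUE),
               n_ambiguous = n_amb, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (sum(per$n_ambiguous))
    message("skipped ", sum(per$n_ambiguous),
            " adenosine(s) in ambiguous codons")
  list(possible_nonsyn = sum(per$possible_nonsyn),
       possible_syn = sum(per$possible_syn),
       possible_stop = sum(per$possible_stop),
       n_ambiguous = sum(per$n_ambiguous),
       per_gene = per)
}

#' Observed-versus-possible editing-frequency selection test
#'
#' The core selection statistic: for each conservation type, the frequency
#' of detected synonymous (non-synonymous) editing events over all possible
#' synonymous (non-synonymous) A-to-G changes in the edited genes, with a
#' 2x2 chi-square test of \{edited, not edited\} x \{non-synonymous,
#' synonymous\}.  The uncorrected Pearson statistic is the headline; the
#' Yates-corrected one is also reported, and Fisher's exact test is
#' substituted whenever an expected cell is below 5.  A type is
#' purifying-like when the non-synonymous frequency falls below the
#' synonymous one, positive-like when it exceeds it.
#'
#' @param observed data.frame with columns \code{type, observed_nonsyn,
#'   observed_syn}
#' @param possible data.frame with columns \code{type, possible_nonsyn,
#'   possible_syn}
#' @return data.frame per type: counts, \code{freq_nonsyn, freq_syn,
#'   chi2, p, chi2_yates, p_yates, test, direction}
#' @export
selectionTest <- function(observed, possible) {
  m <- merge(observed, possible, by = "type", sort = FALSE)
  if (any(m$possible_nonsyn == 0 | m$possible_syn == 0))
    stop("zero possible counts: frequency undefined")
  if (any(m$observed_nonsyn > m$possible_nonsyn |
          m$observed_syn > m$possible_syn))
    stop("observed counts exceed possible counts")
  res <- lapply(seq_len(nrow(m)), function(i) {
    on <- m$observed_nonsyn[i]; os <- m$observed_syn[i]
    pn <- m$possible_nonsyn[i]; ps <- m$possible_syn[i]
    tab <- matrix(c(on, pn - on, os, ps - os), nrow = 2L,
                  dimnames = list(c("edited", "not_edited"),
                                  c("nonsyn", "syn")))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- any(expected < 5)
    if (use_fisher) {
      p <- fisher.test(tab)$p.value
      chi2 <- NA_real_; chi2y <- NA_real_; py <- NA_real_
    } else {
      t0 <- suppressWarnings(chisq.test(tab, correct = FALSE))
      t1 <- suppressWarnings(chisq.test(tab, correct = TRUE))
      chi2 <- unname(t0$statistic); p <- t0$p.value
      chi2y <- unname(t1$statistic); py <- t1$p.value
    }
    fn <- on / pn; fs <- os / ps
    data.frame(type = m$type[i],
               observed_nonsyn = on, observed_syn = os,
               possible_nonsyn = pn, possible_syn = ps,
               freq_nonsyn = fn, freq_syn = fs,
               chi2 = chi2, p = p, chi2_yates = chi2y, p_yates = py,
               test = if (use_fisher) "fisher" else "chisq",
               direction = if (fn > fs) "positive-like" else
                 "purifying-like",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# ---- Nei-Gojobori (1986) counting method -------------------------------

# Synonymous site fraction of one codon: at each position, the share of the
# three possible changes that are synonymous.  Changes creating a stop codon
# count as non-synonymous.
.ng86SitesCodon <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    b <- substr(codon, p, p)
    for (nb in setdiff(bases, b)) {
      mut <- codon
      substr(mut, p, p) <- nb
      if (.AA[[mut]] != "*" && .AA[[mut]] == .AA[[codon]])
        s <- s + 1 / 3
    }
  }
  s
}

.NG86_SITES <- vapply(.SENSE_CODONS, .ng86SitesCodon, numeric(1L))

# Average synonymous/non-synonymous differences between two codons over all
# minimal substitution pathways.  Pathways passing through a stop codon are
# excluded; if every pathway does, all are kept (degenerate fallback).
.ng86DiffsPair <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (k == 1L) list(pos) else
    lapply(asplit(.permutations(pos), 1L), as.integer)
  score <- function(order_) {
    cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (.AA[[nxt]] == "*") valid <- FALSE
      if (.AA[[nxt]] == .AA[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, valid)
  }
  sc <- vapply(paths, score, numeric(3L))
  use <- sc[3L, ] == 1
  if (!any(use)) use <- rep(TRUE, ncol(sc))
  c(syn = mean(sc[1L, use]), nonsyn = mean(sc[2L, use]))
}

.permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], .permutations(v[-i])))
  out
}

#' Nei-Gojobori (1986) Ka/Ks for an aligned codon pair
#'
#' Counting-method estimate of the non-synonymous and synonymous
#' substitution rates: per-codon synonymous site fractions averaged over
#' both sequences, observed differences averaged over all minimal
#' substitution pathways (pathways through stop codons excluded), and the
#' Jukes-Cantor correction \eqn{d = -3/4 \log(1 - 4p/3)} applied to the
#' proportions.  The method is symmetric in its two sequences.
#'
#' @param seq1,seq2 aligned coding sequences of equal length (multiple of
#'   3), gap-free, without stop codons
#' @return list: \code{Ka, Ks, ratio} (NA when Ks = 0), \code{N_sites,
#'   S_sites, N_diffs, S_diffs, pN, pS}
#' @export
ng86KaKs <- function(seq1, seq2) {
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  if (nchar(seq1) != nchar(seq2))
    stop("sequences must be aligned to equal length")
  if (nchar(seq1) %% 3L != 0L) stop("length not divisible by 3")
  if (grepl("-", seq1, fixed = TRUE) || grepl("-", seq2, fixed = TRUE))
    stop("gap-free aligned columns required")
  n_cod <- nchar(seq1) %/% 3L
  cod1 <- substring(seq1, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  cod2 <- substring(seq2, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  if (any(cod1 %in% .STOP_CODONS) || any(cod2 %in% .STOP_CODONS))
    stop("internal stop codons are not allowed")
  S1 <- sum(.NG86_SITES[cod1]); S2 <- sum(.NG86_SITES[cod2])
  S_sites <- (S1 + S2) / 2
  N_sites <- 3 * n_cod - S_sites
  diffs <- vapply(seq_len(n_cod), function(i)
    .ng86DiffsPair(cod1[i], cod2[i]), numeric(2L))
  S_d <- sum(diffs["syn", ]); N_d <- sum(diffs["nonsyn", ])
  pS <- if (S_sites > 0) S_d / S_sites else 0
  pN <- if (N_sites > 0) N_d / N_sites else 0
  if (pS >= 0.75 || pN >= 0.75)
    warning("substitution saturation: Jukes-Cantor correction undefined")
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    if (p == 0) 0 else -3 / 4 * log(1 - 4 * p / 3)
  }
  Ka <- jc(pN); Ks <- jc(pS)
  list(Ka = Ka, Ks = Ks,
       ratio = if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks
               else NA_real_,
       N_sites = N_sites, S_sites = S_sites,
       N_diffs = N_d, S_diffs = S_d, pN = pN, pS = pS)
}

#' Sliding-window Ka/Ks around editing sites
#'
#' Computes the Nei-Gojobori Ka/Ks on an 11-codon window centred on each
#' editing site's codon, truncated at the sequence ends.  Aligned columns
#' containing gaps are dropped from a window before counting.  Windows with
#' Ks = 0 are reported with an undefined ratio, not dropped.
#'
#' @param seq1,seq2 aligned coding sequences (may contain \code{-} gaps)
#' @param editing_codons integer vector of codon indices (in alignment
#'   coordinates) to centre windows on
#' @param window_codons window size in codons (default 11)
#' @return data.frame: center, start, end, Ka, Ks, ratio, N_diffs, S_diffs
#' @export
windowKaKs <- function(seq1, seq2, editing_codons, window_codons = 11L) {
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) %% 3L == 0L)
  n_cod <- nchar(seq1) %/% 3L
  half <- (window_codons - 1L) %/% 2L
  res <- lapply(editing_codons, function(ctr) {
    from <- as.integer(max(1L, ctr - half))
    to <- as.integer(min(n_cod, ctr + half))
    idx <- from:to
    c1 <- substring(seq1, 3L * idx - 2L, 3L * idx)
    c2 <- substring(seq2, 3L * idx - 2L, 3L * idx)
    ok <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
    if (!any(ok))
      return(data.frame(center = ctr, start = from, end = to,
                        Ka = NA_real_, Ks = NA_real_, ratio = NA_real_,
                        N_diffs = NA_real_, S_diffs = NA_real_))
    r <- ng86KaKs(paste(c1[ok], collapse = ""),
                  paste(c2[ok], collapse = ""))
    data.frame(center = ctr, start = from, end = to, Ka = r$Ka,
               Ks = r$Ks, ratio = r$ratio, N_diffs = r$N_diffs,
               S_diffs = r$S_diffs)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
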