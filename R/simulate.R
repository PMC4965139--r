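#' Build a simulation configuration
#'
#' Defaults describe the emulated study conditions: seven related species,
#' families of 2-4 members generated by duplicating an ancestor CDS with
#' synonymous-biased branch mutations, roughly 10\% singleton families,
#' events-per-gene rates of 1.5/1.0/0.5 for types I/II/III, a recoding bias
#' of 0.3 (purifying-like) for types I and II and 2.0 (positive-like) for
#' type III, Beta(2,2) editing levels, negative-binomial depth with mean 50,
#' 0.1\% sequencing error, sparse A/G SNPs, and two whole-fly replicates plus
#' a head sample and an ADAR-null head sample.
#'
#' @param n_species,n_families,singleton_fraction,family_size_range
#'   population structure; see \linkS4class{SimConfig}
#' @param cds_length_codons range of CDS lengths in codons (incl. start/stop)
#' @param per_type_event_rates,nonsyn_bias named numerics over I, II, III
#' @param editing_level_dist Beta (alpha, beta) for true editing levels
#' @param depth_dist negative-binomial (mean, size) for per-site depth
#' @param seq_error_rate,snp_rate per-base error and per-adenosine SNP rates
#' @param samples data.frame(sample_id, tissue, adar_null)
#' @param branch_mut_rate,syn_mut_bias family sequence divergence controls
#' @param n_background_sites extra non-variant sites per count table
#' @param type3_head_only restrict type III expression to "head" samples
#' @param allow_stop_targets allow stop-loss adenosines as editing targets
#' @param seed integer seed driving all randomness
#' @return a \linkS4class{SimConfig}
#' @export
simConfig <- function(n_species = 7L, n_families = 300L,
                      singleton_fraction = 0.1,
                      family_size_range = c(2L, 4L),
                      cds_length_codons = c(80L, 300L),
                      per_type_event_rates = c(I = 1.5, II = 1.0, III = 0.5),
                      nonsyn_bias = c(I = 0.3, II = 0.3, III = 2.0),
                      editing_level_dist = c(2, 2),
                      depth_dist = c(mean = 50, size = 10),
                      seq_error_rate = 0.001, snp_rate = 0.002,
                      samples = data.frame(
                        sample_id = c("wholefly_r1", "wholefly_r2", "head",
                                      "head_adar_null"),
                        tissue = c("wholefly", "wholefly", "head", "head"),
                        adar_null = c(FALSE, FALSE, FALSE, TRUE)),
                      branch_mut_rate = 0.01, syn_mut_bias = 0.8,
                      n_background_sites = 2000L, type3_head_only = FALSE,
                      allow_stop_targets = FALSE, seed = 1L) {
  new("SimConfig",
      n_species = as.integer(n_species),
      n_families = as.integer(n_families),
      singleton_fraction = singleton_fraction,
      family_size_range = as.integer(family_size_range),
      cds_length_codons = as.integer(cds_length_codons),
      per_type_event_rates = per_type_event_rates,
      nonsyn_bias = nonsyn_bias,
      editing_level_dist = editing_level_dist,
      depth_dist = depth_dist,
      seq_error_rate = seq_error_rate, snp_rate = snp_rate,
      samples = samples,
      branch_mut_rate = branch_mut_rate, syn_mut_bias = syn_mut_bias,
      n_background_sites = as.integer(n_background_sites),
      type3_head_only = type3_head_only,
      allow_stop_targets = allow_stop_targets,
      seed = as.integer(seed))
}

# Random ancestor CDS of n codons: ATG + sense codons + stop.
.randomCds <- function(n_codons) {
  body <- sample(setdiff(.SENSE_CODONS, "ATG"), n_codons - 2L,
                 replace = TRUE)
  c("ATG", body, sample(.STOP_CODONS, 1L))
}

# Mutate a codon vector along one branch.  With probability syn_mut_bias a
# mutation replaces an internal codon by a random synonymous codon; otherwise
# a random base change is applied (rejected if it creates an internal stop or
# destroys the start).
.mutateCds <- function(codons, rate, syn_bias) {
  L <- length(codons)
  n_mut <- rbinom(1L, 3L * L, rate)
  if (n_mut == 0L) return(codons)
  for (i in seq_len(n_mut)) {
    if (runif(1L) < syn_bias) {
      j <- sample(2:(L - 1L), 1L)
      syns <- .SENSE_CODONS[.AA[.SENSE_CODONS] == .AA[[codons[j]]]]
      if (length(syns) > 1L)
        codons[j] <- sample(setdiff(syns, codons[j]), 1L)
    } else {
      for (try in 1:5) {
        j <- sample(2:(L - 1L), 1L)
        p <- sample(3L, 1L)
        cand <- codons[j]
        substr(cand, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(cand, p, p)), 1L)
        if (!cand %in% .STOP_CODONS) { codons[j] <- cand; break }
      }
    }
  }
  codons
}

# Candidate editing targets of one CDS (character scalar): adenosines whose
# A->G change is synonymous or nonsynonymous (stop-loss excluded unless
# allowed).  Returns data.frame(cds_pos, codon, class).
.editCandidates <- function(cds, allow_stop = FALSE) {
  bases <- strsplit(cds, "", fixed = TRUE)[[1L]]
  a_pos <- which(bases == "A")
  if (!length(a_pos))
    return(data.frame(cds_pos = integer(), codon = integer(),
                      class = character()))
  codon_idx <- (a_pos - 1L) %/% 3L + 1L
  within <- a_pos - (codon_idx - 1L) * 3L
  codons <- substring(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  cls <- .recodingClass(codons, within)
  keep <- if (allow_stop) !is.na(cls) else cls %in%
    c("synonymous", "nonsynonymous")
  data.frame(cds_pos = a_pos[keep], codon = codon_idx[keep],
             class = cls[keep], stringsAsFactors = FALSE)
}

#' Generate a synthetic ground truth
#'
#' Creates per-species genomes, gene models, gene families and true editing
#' events with the statistical structure the downstream analysis assumes:
#' type I events in singleton genes, type II events private to one member of
#' a multi-member family, type III events shared at the same alignment column
#' by at least two members, non-synonymous candidates drawn with odds
#' multiplied by the per-type recoding bias, Beta-distributed true levels and
#' disjoint A/G SNPs.  Family members are ancestor duplicates with
#' synonymous-biased branch mutations, so family alignments are gap-free and
#' the aligned amino-acid column of codon \emph{k} is \emph{k}.
#'
#' @param config a \linkS4class{SimConfig}
#' @return a \linkS4class{SyntheticTruth}
#' @export
generateTruth <- function(config) {
  validObject(config)
  set.seed(config@seed)
  rates <- config@per_type_event_rates
  bias <- config@nonsyn_bias
  n_fam <- config@n_families
  fam_ids <- sprintf("fam%04d", seq_len(n_fam))

  members <- list(); alignments <- list(); gene_seq <- list()
  gene_species <- character()
  for (fi in seq_len(n_fam)) {
    fid <- fam_ids[fi]
    singleton <- runif(1L) < config@singleton_fraction
    size <- if (singleton) 1L else
      sample(seq(config@family_size_range[1L],
                 config@family_size_range[2L]), 1L)
    spp <- sort(sample(seq_len(config@n_species), size))
    n_codons <- sample(seq(config@cds_length_codons[1L],
                           config@cds_length_codons[2L]), 1L)
    anc <- .randomCds(n_codons)
    ids <- sprintf("%s_sp%d", fid, spp)
    aln <- character(0)
    for (k in seq_len(size)) {
      cod <- .mutateCds(anc, config@branch_mut_rate, config@syn_mut_bias)
      seq <- paste(cod, collapse = "")
      gene_seq[[ids[k]]] <- seq
      gene_species[ids[k]] <- paste0("sp", spp[k])
      aa <- paste(.AA[cod], collapse = "")
      aln[ids[k]] <- aa
    }
    members[[fid]] <- data.frame(family_id = fid,
                                 species = paste0("sp", spp),
                                 gene_id = ids, stringsAsFactors = FALSE)
    alignments[[fid]] <- aln
  }
  members <- do.call(rbind, members)
  rownames(members) <- NULL
  families <- new("GeneFamilySet", members = members,
                  alignments = alignments)

  # --- assemble genomes: one chromosome per species, genes separated by
  # random intergenic spacers, random strand per gene
  chrom_of <- character(); gstart <- integer(); gstrand <- character()
  chrom_seqs <- setNames(vector("list", config@n_species),
                         paste0("chr_sp", seq_len(config@n_species)))
  cursor <- setNames(rep(0L, config@n_species),
                     paste0("sp", seq_len(config@n_species)))
  parts <- setNames(vector("list", config@n_species),
                    paste0("sp", seq_len(config@n_species)))
  for (sp in names(parts)) parts[[sp]] <- character()
  for (g in names(gene_seq)) {
    sp <- gene_species[[g]]
    spacer_len <- sample(100:300, 1L)
    spacer <- paste(sample(c("A", "C", "G", "T"), spacer_len,
                           replace = TRUE), collapse = "")
    strnd <- sample(c("+", "-"), 1L)
    seq <- gene_seq[[g]]
    locus <- if (strnd == "+") seq else .revcomp(seq)
    parts[[sp]] <- c(parts[[sp]], spacer, locus)
    gstart[g] <- cursor[[sp]] + spacer_len + 1L
    cursor[[sp]] <- cursor[[sp]] + spacer_len + nchar(seq)
    chrom_of[g] <- paste0("chr_", sp)
    gstrand[g] <- strnd
  }
  genomes <- DNAStringSet(vapply(names(parts), function(sp)
    paste(parts[[sp]], collapse = ""), character(1L)))
  names(genomes) <- paste0("chr_", names(parts))
  genomes <- genomes[width(genomes) > 0L]

  gene_len <- vapply(gene_seq, nchar, integer(1L))
  feats <- GRanges(chrom_of[names(gene_seq)],
                   IRanges(gstart[names(gene_seq)],
                           gstart[names(gene_seq)] +
                             gene_len[names(gene_seq)] - 1L),
                   strand = gstrand[names(gene_seq)])
  feats$gene_id <- names(gene_seq)
  feats$type <- "CDS"
  models <- geneModelSet(feats)

  # --- place editing events
  to_genomic <- function(g, cds_pos) {
    if (gstrand[[g]] == "+") gstart[[g]] + cds_pos - 1L
    else gstart[[g]] + gene_len[[g]] - cds_pos
  }
  cand <- lapply(gene_seq, .editCandidates,
                 allow_stop = config@allow_stop_targets)
  lvl <- function(n) rbeta(n, config@editing_level_dist[1L],
                           config@editing_level_dist[2L])
  events <- list()
  push <- function(g, rows, type, cluster = NA_character_) {
    data.frame(chrom = chrom_of[[g]],
               pos = vapply(rows$cds_pos, function(p) to_genomic(g, p),
                            integer(1L)),
               strand = gstrand[[g]], gene = g,
               species = gene_species[[g]], cds_pos = rows$cds_pos,
               codon_column = rows$codon, type = type,
               recoding = rows$class, level = lvl(nrow(rows)),
               cluster_id = cluster, stringsAsFactors = FALSE)
  }
  sizes <- table(members$family_id)
  for (fid in fam_ids) {
    mem <- members$gene_id[members$family_id == fid]
    if (length(mem) == 1L) {                      # singleton -> type I
      g <- mem
      cd <- cand[[g]]
      if (!nrow(cd)) next
      k <- min(rpois(1L, rates[["I"]]), nrow(cd))
      if (k == 0L) next
      w <- ifelse(cd$class == "nonsynonymous", bias[["I"]], 1)
      rows <- cd[sample.int(nrow(cd), k, prob = w), , drop = FALSE]
      events[[length(events) + 1L]] <- push(g, rows, "I")
      next
    }
    used_cols <- integer(0)                       # codon columns taken
    s <- length(mem)
    # type III clusters first (they reserve their column family-wide)
    m_mean <- 2 + (s - 2) * 0.25
    n_clust <- rpois(1L, rates[["III"]] * s / m_mean)
    if (n_clust > 0L) {
      # columns where >= 2 members carry a candidate adenosine
      col_mem <- lapply(mem, function(g) unique(cand[[g]]$codon))
      tab <- table(unlist(col_mem))
      shared <- as.integer(names(tab)[tab >= 2L])
      for (ci in seq_len(n_clust)) {
        avail <- setdiff(shared, used_cols)
        if (!length(avail)) break
        # pick a source candidate in a shared column, biased on recoding
        pool <- do.call(rbind, lapply(mem, function(g) {
          cd <- cand[[g]][cand[[g]]$codon %in% avail, , drop = FALSE]
          if (nrow(cd)) cbind(cd, gene = g) else NULL
        }))
        if (is.null(pool) || !nrow(pool)) break
        w <- ifelse(pool$class == "nonsynonymous", bias[["III"]], 1)
        src <- pool[sample.int(nrow(pool), 1L, prob = w), ]
        col <- src$codon
        partners <- setdiff(mem[vapply(mem, function(g)
          col %in% cand[[g]]$codon, logical(1L))], src$gene)
        if (!length(partners)) { used_cols <- c(used_cols, col); next }
        m_target <- min(2L + rbinom(1L, s - 2L, 0.25),
                        length(partners) + 1L)
        chosen <- sample(partners, m_target - 1L)
        cl_id <- paste0(fid, ":c", col)
        for (g in c(src$gene, chosen)) {
          cd <- cand[[g]][cand[[g]]$codon == col, , drop = FALSE]
          w2 <- ifelse(cd$class == "nonsynonymous", bias[["III"]], 1)
          row <- cd[sample.int(nrow(cd), 1L, prob = w2), , drop = FALSE]
          events[[length(events) + 1L]] <- push(g, row, "III", cl_id)
        }
        used_cols <- c(used_cols, col)
      }
    }
    # type II events, avoiding columns already used in this family
    for (g in mem) {
      cd <- cand[[g]][!cand[[g]]$codon %in% used_cols, , drop = FALSE]
      if (!nrow(cd)) next
      k <- min(rpois(1L, rates[["II"]]), length(unique(cd$codon)))
      if (k == 0L) next
      w <- ifelse(cd$class == "nonsynonymous", bias[["II"]], 1)
      picked <- integer(0)
      for (i in seq_len(k)) {
        ok <- which(!cd$codon %in% used_cols)
        if (!length(ok)) break
        j <- ok[sample.int(length(ok), 1L, prob = w[ok])]
        picked <- c(picked, j)
        used_cols <- c(used_cols, cd$codon[j])
      }
      if (length(picked))
        events[[length(events) + 1L]] <-
          push(g, cd[picked, , drop = FALSE], "II")
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = character(), pos = integer(), strand = character(),
               gene = character(), species = character(),
               cds_pos = integer(), codon_column = integer(),
               type = character(), recoding = character(),
               level = numeric(), cluster_id = character(),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL

  # --- SNPs on candidate adenosines not used by events
  snps <- list()
  ev_key <- paste(events$gene, events$cds_pos)
  for (g in names(gene_seq)) {
    cd <- cand[[g]]
    if (!nrow(cd)) next
    free <- cd$cds_pos[!paste(g, cd$cds_pos) %in% ev_key]
    take <- free[runif(length(free)) < config@snp_rate]
    if (!length(take)) next
    plus <- gstrand[[g]] == "+"
    snps[[g]] <- data.frame(
      chrom = chrom_of[[g]],
      pos = vapply(take, function(p) to_genomic(g, p), integer(1L)),
      ref = if (plus) "A" else "T", alt = if (plus) "G" else "C",
      genotype = sample(c("het", "hom"), length(take), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), genotype = character(),
               stringsAsFactors = FALSE)
  rownames(snps) <- NULL

  new("SyntheticTruth", genomes = genomes, models = models,
      families = families, events = events, snps = snps, config = config)
}

#' Simulate per-sample site read-count tables
#'
#' Draws a pileup-style count table per configured sample over the true
#' editing sites, the SNP sites, and a shared panel of background positions.
#' At an editing site of a non-null sample the edited-read count is a
#' binomial draw at the true level over a negative-binomial depth; in an
#' ADAR-null sample edited reads arise only from sequencing error; SNP sites
#' show the alternate allele at ~0.5 (het) or 1.0 (hom).  Every record
#' carries a distinct-read count and an interior-read count (reads whose
#' site lies >10 bp from both ends) so the caller criteria are exercisable.
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param config the matching \linkS4class{SimConfig}
#' @return named list of data.frames (one per sample) with columns
#'   \code{sample, chrom, pos, ref, A, C, G, T, distinct_nonref_reads,
#'   nonref_reads_ge10bp_from_ends}
#' @export
simulateReadCounts <- function(truth, config = truth@config) {
  set.seed(config@seed + 1L)
  ev <- truth@events; sn <- truth@snps
  genome_chr <- as.character(truth@genomes)
  base_at <- function(chrom, pos) substring(genome_chr[chrom], pos, pos)

  # site panel shared across samples
  sites <- rbind(
    if (nrow(ev)) data.frame(chrom = ev$chrom, pos = ev$pos,
                             kind = "edit", idx = seq_len(nrow(ev))),
    if (nrow(sn)) data.frame(chrom = sn$chrom, pos = sn$pos,
                             kind = "snp", idx = seq_len(nrow(sn))))
  n_bg <- config@n_background_sites
  if (n_bg > 0L && length(truth@genomes)) {
    bg_chrom <- sample(names(truth@genomes), n_bg, replace = TRUE,
                       prob = width(truth@genomes))
    bg_pos <- vapply(bg_chrom, function(ch)
      sample.int(width(truth@genomes)[match(ch, names(truth@genomes))], 1L),
      integer(1L))
    bg <- data.frame(chrom = bg_chrom, pos = bg_pos, kind = "bg", idx = NA)
    bg <- bg[!paste(bg$chrom, bg$pos) %in% paste(sites$chrom, sites$pos), ]
    sites <- rbind(sites, bg)
  }
  if (is.null(sites) || !nrow(sites))
    sites <- data.frame(chrom = character(), pos = integer(),
                        kind = character(), idx = integer())
  rownames(sites) <- NULL
  ref <- if (nrow(sites)) base_at(sites$chrom, sites$pos) else character()
  bases <- c("A", "C", "G", "T")
  edited_base <- function(r) c(A = "G", T = "C", C = "T", G = "A")[[r]]

  mu <- config@depth_dist[[1L]]; size <- config@depth_dist[[2L]]
  err <- config@seq_error_rate
  out <- list()
  for (si in seq_len(nrow(config@samples))) {
    samp <- config@samples$sample_id[si]
    is_null <- config@samples$adar_null[si]
    tissue <- config@samples$tissue[si]
    n <- nrow(sites)
    depth <- rnbinom(n, mu = mu, size = size)
    counts <- matrix(0L, n, 4L, dimnames = list(NULL, bases))
    focal <- vapply(ref, edited_base, character(1L))
    lev <- numeric(n)
    i_edit <- which(sites$kind == "edit")
    if (length(i_edit)) {
      e <- ev[sites$idx[i_edit], , drop = FALSE]
      l <- e$level
      if (is_null) l[] <- 0
      if (config@type3_head_only && tissue != "head")
        l[e$type == "III"] <- 0
      lev[i_edit] <- l
    }
    sig <- integer(n)
    if (length(i_edit))
      sig[i_edit] <- rbinom(length(i_edit), depth[i_edit], lev[i_edit])
    i_snp <- which(sites$kind == "snp")
    if (length(i_snp)) {
      s <- sn[sites$idx[i_snp], , drop = FALSE]
      focal[i_snp] <- s$alt
      hom <- s$genotype == "hom"
      sig[i_snp[hom]] <- depth[i_snp[hom]]
      sig[i_snp[!hom]] <- rbinom(sum(!hom), depth[i_snp[!hom]], 0.5)
    }
    rest <- depth - sig
    n_err <- rbinom(n, rest, err)
    counts[cbind(seq_len(n), match(ref, bases))] <- rest - n_err
    fidx <- cbind(seq_len(n), match(focal, bases))
    counts[fidx] <- counts[fidx] + sig
    for (i in which(n_err > 0L)) {
      err_bases <- sample(setdiff(bases, ref[i]), n_err[i],
                          replace = TRUE)
      for (b in err_bases) counts[i, b] <- counts[i, b] + 1L
    }
    if (n == 0L) {
      out[[samp]] <- data.frame(
        sample = character(), chrom = character(), pos = integer(),
        ref = character(), A = numeric(), C = numeric(), G = numeric(),
        T = numeric(), distinct_nonref_reads = integer(),
        nonref_reads_ge10bp_from_ends = integer(),
        stringsAsFactors = FALSE)
      next
    }
    nonref <- depth - counts[cbind(seq_len(nrow(sites)),
                                   match(ref, bases))]
    distinct <- ifelse(nonref == 0L, 0L,
                       1L + rbinom(length(nonref), pmax(nonref - 1L, 0L),
                                   0.95))
    interior <- rbinom(length(nonref), nonref, 0.8)
    out[[samp]] <- data.frame(
      sample = samp, chrom = sites$chrom, pos = sites$pos, ref = ref,
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
      T = counts[, "T"],
      distinct_nonref_reads = distinct,
      nonref_reads_ge10bp_from_ends = interior,
      stringsAsFactors = FALSE)
  }
  out
}
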