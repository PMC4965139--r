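#' Write a synthetic bundle to disk
#'
#' Emits the full plain-text input set of the pipeline: genome FASTA, gene
#' models GFF3, family membership TSV, per-family protein alignment FASTA,
#' SNP TSV, sample sheet, true-event TSV and one site-count TSV per sample.
#' The bundle round-trips losslessly through \code{\link{loadInputs}}.
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param counts output of \code{\link{simulateReadCounts}}
#' @param dir target directory (created if needed)
#' @return the directory, invisibly
#' @export
writeBundle <- function(truth, counts, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, mode = 2L) != 0L)
    stop("directory not writable: ", dir)
  writeXStringSet(truth@genomes, file.path(dir, "genome.fa"))
  writeGeneModels(truth@models, file.path(dir, "models.gff3"))
  .writeTsv(truth@families@members, file.path(dir, "families.tsv"))
  aln <- truth@families@alignments
  aln_flat <- unlist(unname(aln))
  if (is.null(aln_flat)) aln_flat <- character()
  writeLines(
    if (length(aln_flat))
      paste0(">", names(aln_flat), "\n", aln_flat) else character(),
    file.path(dir, "alignments.fa"))
  .writeTsv(truth@snps, file.path(dir, "snps.tsv"))
  .writeTsv(truth@events, file.path(dir, "truth_events.tsv"))
  .writeTsv(truth@config@samples, file.path(dir, "samples.tsv"))
  counts_dir <- file.path(dir, "counts")
  dir.create(counts_dir, showWarnings = FALSE)
  for (s in names(counts))
    .writeTsv(counts[[s]], file.path(counts_dir, paste0(s, ".tsv")))
  invisible(dir)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param dir bundle directory holding the standard input files (see
#'   \code{\link{writeBundle}})
#' @param params a \linkS4class{CallerParams}
#' @param stages subset of the pipeline stages to run, in order
#' @param out_dir where \code{\link{runAll}} writes per-stage outputs
#' @param term_map optional path to a gene-to-term TSV for the enrichment
#'   stage
#' @param seed integer seed
#' @return a classed list
#' @export
runConfig <- function(dir, params = callerParams(),
                      stages = c("caller", "annotate", "typing",
                                 "selection", "profiles", "enrichment"),
                      out_dir = file.path(dir, "out"),
                      term_map = NULL, seed = 1L) {
  structure(list(dir = dir, params = params, stages = stages,
                 out_dir = out_dir, term_map = term_map,
                 seed = as.integer(seed)),
            class = "editome_run_config")
}

#' Load and validate a pipeline input bundle
#'
#' Reads genome, gene models, families, alignments, SNPs, sample sheet and
#' site-count tables, and fails hard on the first inconsistency: missing
#' files, truncated TSVs (reported with a line number), CDS lengths not
#' divisible by three (reported with the gene id), model chromosomes absent
#' from the genome, or family members lacking aligned sequences.
#'
#' @param config a \code{\link{runConfig}} or a bundle directory path
#' @return list(genome, models, families, snps, samples, counts,
#'   truth_events)
#' @export
loadInputs <- function(config) {
  dir <- if (is.character(config)) config else config$dir
  if (!dir.exists(dir)) stop("missing bundle directory: ", dir)
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", p)
    p
  }
  genome <- readDNAStringSet(need("genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  models <- readGeneModels(need("models.gff3"))
  bad_chrom <- setdiff(unique(models@genes$chrom), names(genome))
  if (length(bad_chrom))
    stop("model chromosome(s) absent from genome: ",
         paste(bad_chrom, collapse = ", "))
  members <- .readTsv(need("families.tsv"),
                      c("family_id", "species", "gene_id"))
  orphan <- setdiff(members$gene_id, geneIds(models))
  if (length(orphan))
    stop("family member(s) without gene model: ",
         paste(head(orphan, 5L), collapse = ", "))
  aln_path <- need("alignments.fa")
  aln_seqs <- if (file.size(aln_path) > 0L) {
    s <- Biostrings::readAAStringSet(aln_path)
    setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else setNames(character(), character())
  alignments <- lapply(split(members$gene_id, members$family_id),
                       function(g) {
    missing <- setdiff(g, names(aln_seqs))
    if (length(missing))
      stop("family member without aligned sequence: ",
           paste(missing, collapse = ", "))
    aln_seqs[g]
  })
  families <- geneFamilySet(members, alignments)
  snps <- .readTsv(need("snps.tsv"), c("chrom", "pos", "ref", "alt"))
  samples_meta <- .readTsv(need("samples.tsv"),
                           c("sample_id", "tissue", "adar_null"))
  samples_meta$adar_null <- as.logical(samples_meta$adar_null)
  counts <- list()
  for (s in samples_meta$sample_id) {
    counts[[s]] <- .readTsv(file.path(dir, "counts", paste0(s, ".tsv")),
                            c("sample", "chrom", "pos", "ref", "A", "C",
                              "G", "T", "distinct_nonref_reads",
                              "nonref_reads_ge10bp_from_ends"))
    bad <- setdiff(unique(counts[[s]]$chrom), names(genome))
    if (length(bad))
      stop("count table ", s, ": unknown chromosome(s) ",
           paste(bad, collapse = ", "))
  }
  truth_path <- file.path(dir, "truth_events.tsv")
  truth_events <- if (file.exists(truth_path))
    .readTsv(truth_path) else NULL
  list(genome = genome, models = models, families = families,
       snps = snps, samples = samples_meta, counts = counts,
       truth_events = truth_events)
}

#' Run the full analysis pipeline on a bundle
#'
#' Orchestrates caller, recoding annotation, conservation typing, the
#' observed-versus-possible selection test, presence profiling/clustering
#' and (when a term map is configured) GO enrichment.  ADAR-null samples are
#' excluded from calling and used for null-sample validation.  Per-stage
#' TSVs and a JSON summary are written under the configured output
#' directory; the run is deterministic given the seed.
#'
#' @param config a \code{\link{runConfig}}
#' @return list with elements per executed stage plus \code{summary}
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- runConfig(config)
  set.seed(config$seed)
  bundle <- loadInputs(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  res <- list()
  summary <- list(seed = config$seed)
  wt <- bundle$counts[!bundle$samples$adar_null]
  nulls <- bundle$counts[bundle$samples$adar_null]

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("caller" %in% stages) {
    res$events <- run_stage("caller", function()
      callCandidateEvents(wt, bundle$models, config$params))
    .writeTsv(res$events, file.path(out_dir, "events.tsv"))
    summary$n_events <- nrow(res$events)
    summary$n_samples_called <- length(wt)
    if (length(nulls) && nrow(res$events)) {
      nv <- nullSampleValidation(res$events, nulls[[1L]])
      summary$null_validation <- list(
        covered = nrow(nv$genuine) + nrow(nv$suspect),
        genuine = nrow(nv$genuine), fp_rate = nv$fp_rate)
    }
    if (nrow(bundle$snps) && nrow(res$events)) {
      sc <- snpCrosscheck(res$events, bundle$snps)
      summary$snp_crosscheck <- list(flagged = nrow(sc$flagged),
                                     fp_rate = sc$fp_rate)
      res$events <- sc$clean
    }
  }
  ev <- res$events
  if ("annotate" %in% stages && !is.null(ev) && nrow(ev)) {
    cds <- ev$region == "CDS" & !is.na(ev$gene)
    ev$recoding <- NA_character_
    ev$cds_pos <- NA_integer_
    if (any(cds)) {
      ev$recoding[cds] <- run_stage("annotate", function()
        classifyRecoding(bundle$models, bundle$genome, ev$gene[cds],
                         ev$pos[cds]))
      info_tab <- .cdsInfoTable(bundle$models)
      for (g in unique(ev$gene[cds])) {
        sel <- which(cds & ev$gene == g)
        ev$cds_pos[sel] <- .cdsCoordPlain(info_tab[[g]], ev$pos[sel])
      }
    }
    res$events <- ev
    .writeTsv(ev, file.path(out_dir, "events_annotated.tsv"))
    summary$region_counts <- as.list(table(ev$region))
  }
  if ("typing" %in% stages && !is.null(ev) && nrow(ev)) {
    cds_ev <- ev[ev$region == "CDS" & !is.na(ev$gene), , drop = FALSE]
    typed <- run_stage("typing", function()
      classifyEventTypes(cds_ev, bundle$families, bundle$models))
    res$typed <- typed
    .writeTsv(typed, file.path(out_dir, "typed_events.tsv"))
    summary$type_counts <- as.list(table(typed$type))
  }
  if ("selection" %in% stages && !is.null(res$typed) &&
      nrow(res$typed)) {
    typed <- res$typed
    typed <- typed[typed$recoding %in% c("synonymous", "nonsynonymous"), ,
                   drop = FALSE]
    obs <- do.call(rbind, lapply(split(typed, typed$type), function(d)
      data.frame(type = d$type[1L],
                 observed_nonsyn = sum(d$recoding == "nonsynonymous"),
                 observed_syn = sum(d$recoding == "synonymous"))))
    poss <- do.call(rbind, lapply(split(typed, typed$type), function(d) {
      seqs <- .codingSequences(bundle$models, bundle$genome,
                               unique(d$gene))
      pe <- enumeratePotentialEdits(seqs)
      data.frame(type = d$type[1L],
                 possible_nonsyn = pe$possible_nonsyn,
                 possible_syn = pe$possible_syn)
    }))
    res$selection <- run_stage("selection", function()
      selectionTest(obs, poss))
    .writeTsv(res$selection, file.path(out_dir, "selection.tsv"))
    summary$selection <- lapply(seq_len(nrow(res$selection)), function(i)
      as.list(res$selection[i, ]))
  }
  if ("profiles" %in% stages && !is.null(ev) && nrow(ev)) {
    pm <- run_stage("profiles", function()
      presenceMatrix(res$events, bundle$counts))
    res$presence <- pm
    .writeTsv(cbind(event = rownames(pm), as.data.frame(pm * 1)),
              file.path(out_dir, "presence.tsv"))
    summary$presence_per_sample <- as.list(colSums(pm))
    if (ncol(pm) >= 2L && nrow(pm) >= 2L) {
      hc <- clusterBinary(pm, margin = "columns")
      res$sample_tree <- hc
      dendrogramNewick(hc, file.path(out_dir, "sample_tree.nwk"))
    }
  }
  if ("enrichment" %in% stages && !is.null(config$term_map) &&
      !is.null(res$typed) && nrow(res$typed)) {
    tm <- .readTsv(config$term_map, c("gene", "term"))
    universe <- geneIds(bundle$models)
    res$enrichment <- lapply(split(res$typed, res$typed$type),
                             function(d)
      run_stage("enrichment", function()
        goEnrichment(unique(d$gene), universe, tm)))
    for (ty in names(res$enrichment))
      .writeTsv(res$enrichment[[ty]],
                file.path(out_dir, paste0("enrichment_", ty, ".tsv")))
  }
  res$summary <- summary
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}
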