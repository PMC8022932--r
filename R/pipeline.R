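#' Run the full variant prioritization pipeline
#'
#' Stage order: read inputs, hard-filter each line's calls, annotate the
#' survivors, remove universal background mutations, summarize per-line
#' counts, select and rank candidate genes, write reports.  Outputs are
#' deterministic for identical inputs: filtered VCFs per line
#' (\code{<line>.filtered.vcf}), \code{annotations.tsv},
#' \code{summary.tsv}, \code{candidates.tsv}, \code{report.txt} and a
#' \code{run_log.txt} recording the thresholds applied.
#'
#' @param genome_path reference FASTA.
#' @param gff3_path gene models (GFF3).
#' @param vcf_paths named character vector: line_id -> VCF path.
#' @param out_dir output directory (created if absent).
#' @param thresholds a \code{\link{filter_thresholds}}.
#' @param annot_config an \code{\link{annotator_config}}.
#' @param cand_config a \code{\link{candidate_config}}.
#' @param check_ref verify VCF REF alleles against the genome
#'   (default TRUE).
#' @return (invisibly) a list with \code{summary}, \code{candidates},
#'   \code{annotated} (background-free annotated cohort), \code{filtered}
#'   (hard-filter result), \code{index} (recurrence index) and
#'   \code{out_dir}.
#' @export
run_pipeline <- function(genome_path, gff3_path, vcf_paths,
                         out_dir = "varscreen_out",
                         thresholds = filter_thresholds(),
                         annot_config = annotator_config(),
                         cand_config = candidate_config(),
                         check_ref = TRUE) {
  for (p in c(genome_path, gff3_path, vcf_paths))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- load_genome(genome_path)
  models <- load_gene_models(gff3_path, genome)
  cohort <- read_cohort(vcf_paths, genome = if (check_ref) genome else NULL)

  filt <- filter_cohort(cohort, thresholds)
  clen <- setNames(Biostrings::width(genome), names(genome))
  for (id in names(filt$passed))
    write_vcf(filt$passed[[id]], file.path(out_dir, paste0(id, ".filtered.vcf")),
              clen)

  annotated <- annotate_cohort(filt$passed, models, genome, annot_config)
  index <- build_recurrence_index(filt$passed)
  annotated <- remove_background(annotated, index)
  write_annotations(annotated, file.path(out_dir, "annotations.tsv"))

  summary <- summarize_counts(annotated)
  candidates <- select_candidates(annotated, index, cand_config)
  write_report(candidates, summary, out_dir)

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("varscreen ", as.character(utils::packageVersion("varscreen"))),
    sprintf("lines: %s", paste(names(vcf_paths), collapse = ",")),
    sprintf("thresholds: QD<%g MQ<%g QUAL<%g MQRankSum<%g SOR>%g FS>%g ReadPosRankSum<%g",
            thresholds$qd_min, thresholds$mq_min, thresholds$qual_min,
            thresholds$mqranksum_min, thresholds$sor_max, thresholds$fs_max,
            thresholds$readpos_min),
    sprintf("flank_window: %d", annot_config$flank_window),
    sprintf("max_recurrence: %d, drop_synonymous: %s",
            cand_config$max_recurrence, cand_config$drop_synonymous)),
    log_path)

  invisible(list(summary = summary, candidates = candidates,
                 annotated = annotated, filtered = filt, index = index,
                 out_dir = out_dir))
}
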