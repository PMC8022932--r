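SUMMARY_REGION_COLS <- c("upstream", "downstream", "intergenic", "intronic",
                         "utr5", "utr3", "exonic")
SUMMARY_SUBTYPE_COLS <- c("frameshift_indel", "nonframeshift_indel",
                          "nonsynonymous_snv", "synonymous_snv", "stop_gain")
SUMMARY_COLS <- c("line_id", SUMMARY_REGION_COLS, SUMMARY_SUBTYPE_COLS, "total")

#' Count in how many mutant lines each variant occurs
#'
#' @param cohort a \code{cohort_callset} (per-line sets are deduplicated on
#'   construction).
#' @return a named integer vector: identity key
#'   (\code{contig:pos:ref:alt}) -> number of distinct lines carrying it.
#' @export
build_recurrence_index <- function(cohort) {
  keys <- unlist(lapply(cohort, function(df) unique(variant_key(df))),
                 use.names = FALSE)
  if (!length(keys)) return(setNames(integer(0), character(0)))
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

#' Remove background mutations shared by every line
#'
#' A variant is background when it occurs in all lines of the cohort --
#' pre-existing divergence between the mutagenized clone and the reference
#' assembly rather than an induced mutation.  Variants shared by fewer than
#' all lines survive this stage (recurrence-based exclusion happens later,
#' at candidate selection).
#'
#' @param cohort a \code{cohort_callset}.
#' @param index recurrence index from \code{\link{build_recurrence_index}}
#'   built from this cohort (rebuilt when omitted).
#' @return the cohort with universal variants removed from every line.
#' @export
remove_background <- function(cohort, index = NULL) {
  if (is.null(index)) index <- build_recurrence_index(cohort)
  n_lines <- length(cohort)
  universal <- names(index)[index == n_lines]
  out <- lapply(cohort, function(df) {
    df[!(variant_key(df) %in% universal), , drop = FALSE]
  })
  structure(out, class = c("cohort_callset", "list"))
}

#' Candidate-selection configuration
#'
#' @param max_recurrence maximum number of distinct mutant lines a
#'   candidate variant may occur in (default 2: variants occurring in more
#'   than two lines are excluded as unlikely to be independently causal).
#' @param drop_synonymous exclude synonymous SNVs (default TRUE).
#' @param severity_order consequence classes from most to least severe;
#'   genes are ranked by their most severe surviving variant.
#' @return a \code{candidate_config} list.
#' @export
candidate_config <- function(max_recurrence = 2L, drop_synonymous = TRUE,
                             severity_order = c("stop_gain",
                                                "frameshift_indel",
                                                "nonframeshift_indel",
                                                "stop_loss",
                                                "nonsynonymous_snv")) {
  if (max_recurrence < 1L) stop("max_recurrence must be >= 1")
  structure(list(max_recurrence = as.integer(max_recurrence),
                 drop_synonymous = isTRUE(drop_synonymous),
                 severity_order = severity_order),
            class = "candidate_config")
}

#' Select and rank candidate genes for a mutant line
#'
#' Keeps variants that are (i) exonic, (ii) not synonymous (when
#' \code{drop_synonymous}), and (iii) present in at most
#' \code{max_recurrence} lines; groups the survivors by gene and ranks
#' genes by the severity of their most severe variant (ties broken by
#' gene_id).  Variants with consequence \code{"unknown"} cannot be assessed
#' and are never candidates.
#'
#' @param annotated an annotated variant data.frame (one line or a whole
#'   cohort; a \code{cohort_callset} is bound first).
#' @param index recurrence index from \code{\link{build_recurrence_index}}.
#' @param config a \code{\link{candidate_config}}.
#' @return a data.frame with one row per (line_id, gene_id): columns
#'   \code{line_id, gene_id, top_consequence, severity_rank, n_variants,
#'   variant_keys}, ordered by line then rank then gene_id.
#' @export
select_candidates <- function(annotated, index, config = candidate_config()) {
  if (inherits(annotated, "cohort_callset")) annotated <- bind_cohort(annotated)
  empty <- data.frame(line_id = character(0), gene_id = character(0),
                      top_consequence = character(0),
                      severity_rank = integer(0), n_variants = integer(0),
                      variant_keys = character(0), stringsAsFactors = FALSE)
  if (!nrow(annotated)) return(empty)
  keep <- annotated$region == "exonic" & annotated$consequence != "unknown"
  if (config$drop_synonymous)
    keep <- keep & annotated$consequence != "synonymous_snv"
  rec <- unname(index[variant_key(annotated)])
  rec[is.na(rec)] <- 1L
  keep <- keep & rec <= config$max_recurrence
  surv <- annotated[keep, , drop = FALSE]
  if (!nrow(surv)) return(empty)
  n_sev <- length(config$severity_order)
  surv$severity_rank <- match(surv$consequence, config$severity_order,
                              nomatch = n_sev + 1L)
  grp <- paste(surv$line_id, surv$gene_id, sep = "\r")
  agg <- lapply(split(surv, grp), function(g) {
    best <- which.min(g$severity_rank)
    data.frame(line_id = g$line_id[1], gene_id = g$gene_id[1],
               top_consequence = g$consequence[best],
               severity_rank = g$severity_rank[best],
               n_variants = nrow(g),
               variant_keys = paste(variant_key(g), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(unname(agg), list(make.row.names = FALSE)))
  out[order(out$line_id, out$severity_rank, out$gene_id), , drop = FALSE]
}

#' Per-line mutation count summary
#'
#' Counts variants by region class and, within exonic, by coding
#' consequence subtype, one row per line.  Two identities hold by
#' construction: \code{total} is the sum of the seven region classes, and
#' \code{exonic} is the sum of its five subtypes.  \code{stop_loss} (not a
#' category of the classic screen summary) is folded into
#' \code{nonsynonymous_snv}; exonic variants with consequence
#' \code{"unknown"} are dropped from the table with a warning so the
#' identities stay exact.
#'
#' @param annotated an annotated \code{cohort_callset} or bound data.frame
#'   (background already removed).
#' @return a data.frame with columns \code{line_id, upstream, downstream,
#'   intergenic, intronic, utr5, utr3, exonic, frameshift_indel,
#'   nonframeshift_indel, nonsynonymous_snv, synonymous_snv, stop_gain,
#'   total}.
#' @export
summarize_counts <- function(annotated) {
  line_ids <- NULL
  if (inherits(annotated, "cohort_callset")) {
    line_ids <- names(annotated)
    annotated <- bind_cohort(annotated)
  }
  unk <- !is.na(annotated$consequence) & annotated$consequence == "unknown"
  if (any(unk)) {
    warning(sum(unk), " variant(s) with unknown consequence dropped from summary")
    annotated <- annotated[!unk, , drop = FALSE]
  }
  if (is.null(line_ids)) line_ids <- sort(unique(annotated$line_id))
  rows <- lapply(line_ids, function(id) {
    df <- annotated[annotated$line_id == id, , drop = FALSE]
    reg <- vapply(SUMMARY_REGION_COLS, function(r) sum(df$region == r), 0L)
    cons <- df$consequence[df$region == "exonic"]
    cons[cons == "stop_loss"] <- "nonsynonymous_snv"
    sub <- vapply(SUMMARY_SUBTYPE_COLS, function(s) sum(cons == s), 0L)
    cbind(data.frame(line_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(reg)), as.data.frame(as.list(sub)),
          data.frame(total = sum(reg)))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Derive exonic and total counts from per-category counts
#'
#' Worked-example arithmetic on a count row: \code{exonic} is the sum of
#' the five exonic subtype columns and \code{total} the sum of the seven
#' region columns.
#'
#' @param counts a data.frame with the six non-exonic region columns
#'   (\code{upstream, downstream, intergenic, intronic, utr5, utr3}) and
#'   the five subtype columns (\code{frameshift_indel,
#'   nonframeshift_indel, nonsynonymous_snv, synonymous_snv, stop_gain}).
#' @return the input with \code{exonic} and \code{total} (re)computed.
#' @export
summary_from_category_counts <- function(counts) {
  sub <- as.matrix(counts[, SUMMARY_SUBTYPE_COLS, drop = FALSE])
  counts$exonic <- as.integer(rowSums(sub))
  reg <- as.matrix(counts[, SUMMARY_REGION_COLS, drop = FALSE])
  counts$total <- as.integer(rowSums(reg))
  counts
}

#' Published per-line mutation counts from the reference screen
#'
#' The per-line summary counts of a published forward genetic screen in the
#' nematode-trapping fungus \emph{Arthrobotrys oligospora} (14 mutant lines
#' after background-mutation removal), shipped as a plain-text fixture and
#' used for worked-example arithmetic.
#'
#' @return a data.frame in \code{\link{summarize_counts}} column layout.
#' @export
screen_count_table <- function() {
  utils::read.delim(system.file("extdata", "screen_mutation_counts.tsv",
                                package = "varscreen"),
                    stringsAsFactors = FALSE)
}

#' Write candidate and summary reports
#'
#' Emits the per-line summary table as TSV (column order as in the classic
#' screen summary), the candidate table as TSV, and a short human-readable
#' report.  Output is deterministic for identical input.
#'
#' @param candidates candidate table from \code{\link{select_candidates}}.
#' @param summary summary table from \code{\link{summarize_counts}}.
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_report <- function(candidates, summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sum_path <- file.path(dir, "summary.tsv")
  cand_path <- file.path(dir, "candidates.tsv")
  rep_path <- file.path(dir, "report.txt")
  utils::write.table(summary[, SUMMARY_COLS], sum_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(candidates, cand_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- file(rep_path, "w")
  on.exit(close(con))
  writeLines("varscreen candidate report", con)
  writeLines(sprintf("lines: %d, candidate genes: %d",
                     nrow(summary), nrow(candidates)), con)
  for (id in summary$line_id) {
    cc <- candidates[candidates$line_id == id, , drop = FALSE]
    writeLines(sprintf("%s: %d candidate gene(s)", id, nrow(cc)), con)
    if (nrow(cc))
      writeLines(sprintf("  %s  %s (%d variant(s))", cc$gene_id,
                         cc$top_consequence, cc$n_variants), con)
  }
  invisible(c(summary = sum_path, candidates = cand_path, report = rep_path))
}
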