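#' Annotator configuration
#'
#' @param flank_window bases defining the upstream/downstream flanks of a
#'   gene (strand-aware).  Default 1000, the conventional flank of
#'   gene-based annotators.
#' @return an \code{annotator_config} list.
#' @export
annotator_config <- function(flank_window = 1000L) {
  if (flank_window <= 0) stop("flank_window must be positive")
  structure(list(flank_window = as.integer(flank_window)),
            class = "annotator_config")
}

REGION_CLASSES <- c("exonic", "utr5", "utr3", "intronic",
                    "upstream", "downstream", "intergenic")

CODING_CONSEQUENCES <- c("synonymous_snv", "nonsynonymous_snv", "stop_gain",
                         "frameshift_indel", "nonframeshift_indel",
                         "stop_loss", "unknown")

# region precedence: lower number wins when classes from overlapping genes
# compete for one position
REGION_PRECEDENCE <- setNames(seq_along(REGION_CLASSES), REGION_CLASSES)

# one GRanges of typed segments (exonic/utr5/utr3/intronic/upstream/
# downstream) across all models, carrying precedence and gene_id
build_region_ranges <- function(models, contig_lengths,
                                config = annotator_config()) {
  ct <- character(0); s <- integer(0); e <- integer(0)
  cls <- character(0); gid <- character(0)
  add <- function(contig, start, end, class, gene_id) {
    keep <- start <= end
    ct <<- c(ct, rep(contig, sum(keep)))
    s <<- c(s, start[keep]); e <<- c(e, end[keep])
    cls <<- c(cls, rep(class, sum(keep)))
    gid <<- c(gid, rep(gene_id, sum(keep)))
  }
  for (m in models) {
    len <- contig_lengths[[m$contig]]
    add(m$contig, m$cds$start, m$cds$end, "exonic", m$gene_id)
    if (nrow(m$utr5)) add(m$contig, m$utr5$start, m$utr5$end, "utr5", m$gene_id)
    if (nrow(m$utr3)) add(m$contig, m$utr3$start, m$utr3$end, "utr3", m$gene_id)
    # introns: gaps inside the gene body not covered by any segment
    segs <- rbind(m$cds, m$utr5, m$utr3)
    segs <- segs[order(segs$start), , drop = FALSE]
    body <- IRanges::IRanges(m$span[1], m$span[2])
    gaps <- IRanges::setdiff(body, IRanges::IRanges(segs$start, segs$end))
    if (length(gaps))
      add(m$contig, IRanges::start(gaps), IRanges::end(gaps), "intronic", m$gene_id)
    w <- config$flank_window
    if (m$strand == "+") {
      add(m$contig, max(1L, m$span[1] - w), m$span[1] - 1L, "upstream", m$gene_id)
      add(m$contig, m$span[2] + 1L, min(len, m$span[2] + w), "downstream", m$gene_id)
    } else {
      add(m$contig, m$span[2] + 1L, min(len, m$span[2] + w), "upstream", m$gene_id)
      add(m$contig, max(1L, m$span[1] - w), m$span[1] - 1L, "downstream", m$gene_id)
    }
  }
  gr <- GenomicRanges::GRanges(ct, IRanges::IRanges(s, e))
  S4Vectors::mcols(gr)$class <- cls
  S4Vectors::mcols(gr)$prec <- REGION_PRECEDENCE[cls]
  S4Vectors::mcols(gr)$gene_id <- gid
  gr
}

#' Classify variants into gene-based region classes
#'
#' Assigns each variant exactly one of \code{exonic, utr5, utr3, intronic,
#' upstream, downstream, intergenic}.  The variant's affected reference
#' interval (\code{pos .. pos + nchar(ref) - 1}) is used, so an indel
#' overlapping any coding base is exonic.  When classes from overlapping
#' genes compete, the highest-precedence class wins
#' (exonic > utr5 > utr3 > intronic > upstream > downstream > intergenic);
#' ties on class are broken by lexicographic gene_id.
#'
#' @param variants a variant data.frame.
#' @param models list of \code{gene_model}s (same contig set as the
#'   variants).
#' @param genome a \code{DNAStringSet}; used for contig-bound checks.
#' @param config an \code{\link{annotator_config}}.
#' @return a data.frame with columns \code{region} and \code{gene_id}
#'   (\code{NA} for intergenic), one row per input variant.
#' @export
classify_region <- function(variants, models, genome,
                            config = annotator_config()) {
  n <- nrow(variants)
  if (!n) return(data.frame(region = character(0), gene_id = character(0)))
  glen <- setNames(Biostrings::width(genome), names(genome))
  if (any(!variants$contig %in% names(glen)))
    stop("variant contig not present in genome")
  iv_end <- variants$pos + nchar(variants$ref) - 1L
  if (any(variants$pos < 1L | iv_end > glen[variants$contig]))
    stop("variant position beyond contig bounds")

  segs <- build_region_ranges(models, glen, config)
  vgr <- GenomicRanges::GRanges(variants$contig,
                                IRanges::IRanges(variants$pos, iv_end))
  hits <- GenomicRanges::findOverlaps(vgr, segs)
  q <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (length(q)) {
    prec <- S4Vectors::mcols(segs)$prec[sj]
    gid <- S4Vectors::mcols(segs)$gene_id[sj]
    cls <- S4Vectors::mcols(segs)$class[sj]
    o <- order(q, prec, gid)
    first <- o[!duplicated(q[o])]
    region[q[first]] <- cls[first]
    gene_id[q[first]] <- gid[first]
  }
  data.frame(region = region, gene_id = gene_id, stringsAsFactors = FALSE)
}

# 1-based CDS coordinate of a genomic position within a model, in
# translation order; NA when the position is not in any CDS segment
cds_coordinate <- function(pos, model) {
  widths <- model$cds$end - model$cds$start + 1L
  seg <- which(pos >= model$cds$start & pos <= model$cds$end)
  if (!length(seg)) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (seg > 1L) sum(widths[seq_len(seg - 1L)]) else 0L
    before + (pos - model$cds$start[seg] + 1L)
  } else {
    after <- if (seg < length(widths)) sum(widths[seq(seg + 1L, length(widths))]) else 0L
    after + (model$cds$end[seg] - pos + 1L)
  }
}

# number of coding bases an indel adds or removes (see vignette for the
# boundary conventions)
indel_coding_change <- function(pos, ref, alt, model) {
  lr <- nchar(ref); la <- nchar(alt)
  in_cds <- function(p) any(p >= model$cds$start & p <= model$cds$end)
  if (la > lr) {                       # insertion after anchor pos+lr-1
    if (in_cds(pos + lr - 1L)) la - lr else 0L
  } else {                             # deletion of pos+la .. pos+lr-1
    removed <- seq(pos + la, pos + lr - 1L)
    sum(vapply(removed, in_cds, TRUE))
  }
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Codon-level coding consequence of an exonic variant
#'
#' For SNVs the affected codon is mutated and translated with the standard
#' genetic code: same amino acid is \code{synonymous_snv}; a new stop is
#' \code{stop_gain}; a lost reference stop is \code{stop_loss}; any other
#' change is \code{nonsynonymous_snv}.  Indels are classified by the number
#' of coding bases added or removed: a multiple of 3 is
#' \code{nonframeshift_indel}, anything else \code{frameshift_indel}.
#' Codons containing N yield \code{unknown}.
#'
#' @param variant a one-row variant data.frame (or list with \code{pos,
#'   ref, alt, vclass}).
#' @param model the \code{gene_model} supplying the exonic call.
#' @param genome a \code{DNAStringSet}.
#' @param cds optional pre-extracted CDS string (cache for batch callers).
#' @return a list with \code{consequence} and \code{protein_change}
#'   (\code{"refAA<codon index>altAA"} for SNVs, \code{NA} otherwise).
#' @export
classify_coding_effect <- function(variant, model, genome, cds = NULL) {
  if (!isTRUE(model$coding))
    return(list(consequence = "unknown", protein_change = NA_character_))
  if (variant$vclass != "SNV") {
    chg <- indel_coding_change(variant$pos, variant$ref, variant$alt, model)
    cons <- if (chg %% 3L == 0L) "nonframeshift_indel" else "frameshift_indel"
    return(list(consequence = cons, protein_change = NA_character_))
  }
  cpos <- cds_coordinate(variant$pos, model)
  if (is.na(cpos))
    stop("contract violation: SNV at ", variant$contig, ":", variant$pos,
         " is not inside a CDS segment of ", model$gene_id)
  if (is.null(cds)) cds <- extract_cds(model, genome)
  codon_idx <- (cpos - 1L) %/% 3L + 1L
  offset <- (cpos - 1L) %% 3L + 1L
  codon <- substring(cds, 3L * codon_idx - 2L, 3L * codon_idx)
  alt_base <- if (model$strand == "+") variant$alt else COMPLEMENT[[variant$alt]]
  alt_codon <- codon
  substring(alt_codon, offset, offset) <- alt_base
  if (grepl("N", codon) || grepl("N", alt_codon))
    return(list(consequence = "unknown", protein_change = NA_character_))
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
  cons <- if (aa_ref == aa_alt) "synonymous_snv"
    else if (aa_alt == "*") "stop_gain"
    else if (aa_ref == "*") "stop_loss"
    else "nonsynonymous_snv"
  list(consequence = cons,
       protein_change = paste0(aa_ref, codon_idx, aa_alt))
}

#' Annotate a callset with region classes and coding consequences
#'
#' One annotated row per input variant; \code{consequence} is populated
#' exactly when \code{region == "exonic"}.  Exonic variants in genes that
#' failed CDS-length validation get consequence \code{"unknown"}.
#'
#' @param variants a variant data.frame (normally the hard-filter
#'   survivors).
#' @param models list of \code{gene_model}s.
#' @param genome a \code{DNAStringSet}.
#' @param config an \code{\link{annotator_config}}.
#' @return the input data.frame with columns \code{region},
#'   \code{consequence}, \code{gene_id}, \code{protein_change} appended.
#' @export
annotate_callset <- function(variants, models, genome,
                             config = annotator_config()) {
  rc <- classify_region(variants, models, genome, config)
  out <- variants
  out$region <- rc$region
  out$gene_id <- rc$gene_id
  out$consequence <- rep(NA_character_, nrow(out))
  out$protein_change <- rep(NA_character_, nrow(out))
  ex <- which(out$region == "exonic")
  if (length(ex)) {
    by_id <- setNames(models, vapply(models, `[[`, "", "gene_id"))
    cds_cache <- new.env(parent = emptyenv())
    for (i in ex) {
      m <- by_id[[out$gene_id[i]]]
      cds <- NULL
      if (isTRUE(m$coding)) {
        if (is.null(cds_cache[[m$gene_id]]))
          cds_cache[[m$gene_id]] <- extract_cds(m, genome)
        cds <- cds_cache[[m$gene_id]]
      }
      eff <- classify_coding_effect(out[i, ], m, genome, cds = cds)
      out$consequence[i] <- eff$consequence
      out$protein_change[i] <- eff$protein_change
    }
  }
  out
}

#' Annotate every line of a cohort
#'
#' @param cohort a \code{cohort_callset}.
#' @inheritParams annotate_callset
#' @return a \code{cohort_callset} of annotated tables.
#' @export
annotate_cohort <- function(cohort, models, genome,
                            config = annotator_config()) {
  structure(lapply(cohort, annotate_callset, models = models,
                   genome = genome, config = config),
            class = c("cohort_callset", "list"))
}

#' Write annotated variants to TSV
#'
#' @param annotated an annotated variant data.frame (or
#'   \code{cohort_callset}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(annotated, path) {
  if (inherits(annotated, "cohort_callset")) annotated <- bind_cohort(annotated)
  cols <- c("contig", "pos", "ref", "alt", "line_id", "region",
            "consequence", "gene_id", "protein_change")
  utils::write.table(annotated[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
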