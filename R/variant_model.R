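VCF_INFO_KEYS <- c("QD", "MQ", "MQRankSum", "SOR", "FS", "ReadPosRankSum")
METRIC_COLS <- c("QD", "MQ", "QUAL", "MQRankSum", "SOR", "FS", "ReadPosRankSum")

#' Classify an allele change as SNV, insertion or deletion
#'
#' @param ref,alt reference and alternate allele strings (A/C/G/T only).
#'   Vectorized.
#' @return character vector with values \code{"SNV"}, \code{"insertion"} or
#'   \code{"deletion"}.  Equal-length multi-base substitutions (MNVs) are
#'   rejected with an error.
#' @export
classify_allele <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("alleles must be non-empty")
  if (any(grepl("[^ACGT]", ref)) || any(grepl("[^ACGT]", alt)))
    stop("alleles must contain only A, C, G, T")
  lr <- nchar(ref); la <- nchar(alt)
  if (any(lr == la & lr > 1L))
    stop("unsupported variant: multi-nucleotide substitution (ref '",
         ref[lr == la & lr > 1L][1], "')")
  ifelse(lr == la, "SNV", ifelse(la > lr, "insertion", "deletion"))
}

new_variant_table <- function(contig = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              line_id = character(0),
                              QD = numeric(0), MQ = numeric(0),
                              QUAL = numeric(0), MQRankSum = numeric(0),
                              SOR = numeric(0), FS = numeric(0),
                              ReadPosRankSum = numeric(0)) {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = if (length(ref)) classify_allele(ref, alt) else character(0),
             line_id = line_id, QD = QD, MQ = MQ, QUAL = QUAL,
             MQRankSum = MQRankSum, SOR = SOR, FS = FS,
             ReadPosRankSum = ReadPosRankSum,
             stringsAsFactors = FALSE, row.names = NULL)
}

# light structural pre-check so malformed body lines are reported with their
# line number before handing the file to the full parser
prevalidate_vcf <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[2]))))
      stop("VCF format error in ", path, " at line ", i,
           ": expected >= 8 tab-separated fields with integer POS")
  }
  invisible(TRUE)
}

#' Read per-line variant calls from a VCF file
#'
#' Multi-allelic records are split into one row per alternate allele, each
#' inheriting the record's quality metrics.  Symbolic alleles
#' (\code{<DEL>}, \code{<*>}, breakends) and multi-nucleotide substitutions
#' are skipped with a warning.  INFO keys absent from a record become
#' \code{NA} ("metric absent"), as does a missing QUAL (\code{"."}).
#'
#' @param path path to a VCF (v4.x) file.
#' @param line_id mutant-line identifier attached to every variant.
#' @param genome optional \code{DNAStringSet}; when supplied, REF alleles
#'   are checked against the genome sequence.
#' @return a variant data.frame with columns \code{contig, pos, ref, alt,
#'   vclass, line_id} and the metric columns \code{QD, MQ, QUAL, MQRankSum,
#'   SOR, FS, ReadPosRankSum}.
#' @export
read_vcf <- function(path, line_id, genome = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  prevalidate_vcf(path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("VCF format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  qual <- rr$QUAL

  info <- VariantAnnotation::info(vcf)
  metric <- function(key) {
    if (key %in% names(info)) {
      v <- suppressWarnings(as.numeric(info[[key]]))
      v
    } else rep(NA_real_, length(rr))
  }
  m <- lapply(VCF_INFO_KEYS, metric)
  names(m) <- VCF_INFO_KEYS

  symbolic <- grepl("[^ACGT]", alt) | !nzchar(alt)
  mnv <- !symbolic & nchar(ref) == nchar(alt) & nchar(ref) > 1L
  drop <- symbolic | mnv
  if (any(symbolic))
    warning(sum(symbolic), " symbolic-allele record(s) skipped in ", path)
  if (any(mnv))
    warning(sum(mnv), " multi-nucleotide substitution record(s) skipped in ", path)
  keep <- !drop

  out <- new_variant_table(
    contig = contig[keep], pos = pos[keep], ref = ref[keep], alt = alt[keep],
    line_id = rep(line_id, sum(keep)),
    QD = m$QD[keep], MQ = m$MQ[keep], QUAL = as.numeric(qual)[keep],
    MQRankSum = m$MQRankSum[keep], SOR = m$SOR[keep], FS = m$FS[keep],
    ReadPosRankSum = m$ReadPosRankSum[keep])

  if (!is.null(genome)) {
    for (ct in unique(out$contig)) {
      idx <- out$contig == ct
      seq <- as.character(genome[[ct]])
      obs <- substring(seq, out$pos[idx], out$pos[idx] + nchar(out$ref[idx]) - 1L)
      bad <- obs != out$ref[idx]
      if (any(bad))
        stop("REF allele mismatch vs genome at ", ct, ":",
             out$pos[idx][bad][1], " (VCF '", out$ref[idx][bad][1],
             "', genome '", obs[bad][1], "')")
    }
  }
  out
}

fmt_vcf_num <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  out[ok] <- format(x[ok], scientific = FALSE, trim = TRUE, digits = 15)
  out
}

#' Write variants to a VCF 4.2 file
#'
#' Emits a fixed header (no timestamps) with INFO definitions for the six
#' metric keys, so output is byte-identical for identical input.
#'
#' @param variants a variant data.frame sorted by (contig, pos).
#' @param path output path.
#' @param contig_lengths named integer vector of contig lengths for the
#'   \code{##contig} header lines.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(variants, path, contig_lengths) {
  if (nrow(variants)) {
    o <- order(variants$contig, variants$pos)
    if (!identical(o, seq_len(nrow(variants))))
      stop("variants must be sorted by (contig, pos) before writing")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=varscreen",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank-sum test">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Symmetric odds ratio of strand bias">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled Fisher strand bias">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank-sum test">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  recs <- character(0)
  if (nrow(variants)) {
    info <- vapply(seq_len(nrow(variants)), function(i) {
      vals <- unlist(variants[i, VCF_INFO_KEYS])
      ok <- !is.na(vals)
      if (!any(ok)) return(".")
      paste(paste0(VCF_INFO_KEYS[ok], "=", fmt_vcf_num(vals[ok])), collapse = ";")
    }, "")
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s",
                    variants$contig, variants$pos, variants$ref, variants$alt,
                    fmt_vcf_num(variants$QUAL), info)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Assemble a cohort callset from per-line variant tables
#'
#' @param line_tables named list (by line_id) of variant data.frames.
#' @return a \code{cohort_callset}: the same named list, with duplicate
#'   identity keys within a line removed (with a warning).
#' @export
cohort_callset <- function(line_tables) {
  if (is.null(names(line_tables)) || any(!nzchar(names(line_tables))))
    stop("line tables must be named by line_id")
  out <- lapply(names(line_tables), function(id) {
    df <- line_tables[[id]]
    df$line_id <- id
    dup <- duplicated(variant_key(df))
    if (any(dup)) {
      warning(sum(dup), " duplicate variant(s) removed from line ", id)
      df <- df[!dup, , drop = FALSE]
    }
    df
  })
  names(out) <- names(line_tables)
  structure(out, class = c("cohort_callset", "list"))
}

#' Read a cohort of per-line VCFs
#'
#' @param paths named character vector: \code{line_id -> VCF path}.
#' @param genome optional \code{DNAStringSet} for REF checking.
#' @return a \code{cohort_callset}.
#' @export
read_cohort <- function(paths, genome = NULL) {
  if (is.null(names(paths))) stop("paths must be named by line_id")
  cohort_callset(lapply(setNames(names(paths), names(paths)),
                        function(id) read_vcf(paths[[id]], id, genome)))
}

#' Bind a cohort callset into one data.frame
#'
#' @param cohort a \code{cohort_callset}.
#' @return a single data.frame with all lines stacked.
#' @export
bind_cohort <- function(cohort) {
  do.call(rbind, c(unname(cohort), list(make.row.names = FALSE)))
}
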