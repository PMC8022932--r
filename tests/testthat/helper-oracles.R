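# Independent oracles, implemented along different routes than the package.

# paint-the-array region oracle: walk every base of a contig, painting
# classes from lowest to highest precedence (and, within a class, genes in
# reverse lexicographic order) so the final winner per base matches the
# precedence contract.  Returns per-base class and gene vectors.
oracle_region_arrays <- function(models, contig, contig_len, flank = 1000L) {
  cls <- rep("intergenic", contig_len)
  gene <- rep(NA_character_, contig_len)
  paint_order <- c("downstream", "upstream", "intronic", "utr3", "utr5", "exonic")
  models <- Filter(function(m) m$contig == contig, models)
  ord <- order(vapply(models, `[[`, "", "gene_id"), decreasing = TRUE)
  for (class in paint_order) {
    for (m in models[ord]) {
      ivs <- switch(class,
        exonic = m$cds,
        utr5 = m$utr5,
        utr3 = m$utr3,
        intronic = {
          segs <- rbind(m$cds, m$utr5, m$utr3)
          covered <- rep(FALSE, m$span[2] - m$span[1] + 1L)
          for (i in seq_len(nrow(segs)))
            covered[(segs$start[i]:segs$end[i]) - m$span[1] + 1L] <- TRUE
          r <- rle(covered)
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1L
          data.frame(start = starts[!r$values] + m$span[1] - 1L,
                     end = ends[!r$values] + m$span[1] - 1L)
        },
        upstream = if (m$strand == "+")
          data.frame(start = m$span[1] - flank, end = m$span[1] - 1L)
        else data.frame(start = m$span[2] + 1L, end = m$span[2] + flank),
        downstream = if (m$strand == "+")
          data.frame(start = m$span[2] + 1L, end = m$span[2] + flank)
        else data.frame(start = m$span[1] - flank, end = m$span[1] - 1L))
      if (is.null(ivs) || !nrow(ivs)) next
      for (i in seq_len(nrow(ivs))) {
        a <- max(1L, ivs$start[i]); b <- min(contig_len, ivs$end[i])
        if (a > b) next
        cls[a:b] <- class
        gene[a:b] <- m$gene_id
      }
    }
  }
  list(class = cls, gene = gene)
}

# interval query against the per-base arrays: lexicographic min of
# (precedence, gene_id) over the covered bases
oracle_region_query <- function(arrays, pos, ref_len = 1L) {
  prec <- c(exonic = 1, utr5 = 2, utr3 = 3, intronic = 4,
            upstream = 5, downstream = 6, intergenic = 7)
  span <- pos:(pos + ref_len - 1L)
  p <- prec[arrays$class[span]]
  g <- arrays$gene[span]
  best <- order(p, g)[1]
  list(region = arrays$class[span][best], gene_id = g[best])
}

# local reverse complement, independent of Biostrings
rc_chr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

oracle_extract_cds <- function(model, contig_seq) {
  parts <- substring(contig_seq, model$cds$start, model$cds$end)
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- rc_chr(cds)
  cds
}

oracle_translate <- function(cds) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

# full-CDS retranslation oracle for SNV consequences: mutate the contig,
# re-extract and translate the whole CDS, diff the proteins
oracle_snv_consequence <- function(variant, model, contig_seq) {
  p0 <- oracle_translate(oracle_extract_cds(model, contig_seq))
  mut <- contig_seq
  substring(mut, variant$pos, variant$pos) <- variant$alt
  p1 <- oracle_translate(oracle_extract_cds(model, mut))
  if (p0 == p1) return("synonymous_snv")
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
  a0 <- substring(p0, d, d); a1 <- substring(p1, d, d)
  if (a1 == "*") "stop_gain" else if (a0 == "*") "stop_loss" else "nonsynonymous_snv"
}

# indel oracle: net change in coding length computed on the expanded set of
# coding genomic positions
oracle_indel_consequence <- function(variant, model) {
  cds_positions <- unlist(mapply(seq, model$cds$start, model$cds$end,
                                 SIMPLIFY = FALSE))
  lr <- nchar(variant$ref); la <- nchar(variant$alt)
  chg <- if (la > lr) {
    if ((variant$pos + lr - 1L) %in% cds_positions) la - lr else 0L
  } else {
    length(intersect(seq(variant$pos + la, variant$pos + lr - 1L), cds_positions))
  }
  if (chg %% 3L == 0L) "nonframeshift_indel" else "frameshift_indel"
}

# quadratic brute-force recount of cross-line recurrence
oracle_recurrence <- function(cohort) {
  all_keys <- unique(unlist(lapply(cohort, variant_key)))
  counts <- integer(length(all_keys))
  for (i in seq_along(all_keys))
    for (df in cohort)
      if (all_keys[i] %in% variant_key(df)) counts[i] <- counts[i] + 1L
  setNames(counts, all_keys)
}

# direct re-evaluation of the printed hard-filter inequalities
oracle_hard_filter <- function(m, t = filter_thresholds()) {
  fails <- character(0)
  chk <- function(x) !is.null(x) && !is.na(x)
  if (chk(m$QD) && m$QD < t$qd_min) fails <- c(fails, "QD")
  if (chk(m$MQ) && m$MQ < t$mq_min) fails <- c(fails, "MQ")
  if (chk(m$QUAL) && m$QUAL < t$qual_min) fails <- c(fails, "QUAL")
  if (chk(m$MQRankSum) && m$MQRankSum < t$mqranksum_min) fails <- c(fails, "MQRankSum")
  if (chk(m$SOR) && m$SOR > t$sor_max) fails <- c(fails, "SOR")
  if (chk(m$FS) && m$FS > t$fs_max) fails <- c(fails, "FS")
  if (chk(m$ReadPosRankSum) && m$ReadPosRankSum < t$readpos_min)
    fails <- c(fails, "ReadPosRankSum")
  list(passed = length(fails) == 0L, failed_criteria = fails)
}
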