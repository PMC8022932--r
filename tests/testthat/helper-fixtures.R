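# In-code fixtures shared across test files.

write_fasta_text <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

make_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# direct gene_model constructor (bypasses GFF3) for hand-built fixtures
make_model <- function(gene_id, contig, strand, cds, utr5 = NULL, utr3 = NULL,
                       coding = TRUE) {
  seg <- function(x) {
    if (is.null(x)) return(varscreen:::empty_segments())
    data.frame(start = x[c(TRUE, FALSE)], end = x[c(FALSE, TRUE)])
  }
  varscreen:::new_gene_model(gene_id, contig, strand, seg(cds), seg(utr5),
                             seg(utr3), coding = coding)
}

make_variant <- function(contig, pos, ref, alt, line_id = "L1",
                         QD = 30, MQ = 60, QUAL = 500, MQRankSum = 0,
                         SOR = 1, FS = 0, ReadPosRankSum = 0) {
  varscreen:::new_variant_table(contig = contig, pos = pos, ref = ref,
                                alt = alt, line_id = rep(line_id, length(pos)),
                                QD = rep_len(QD, length(pos)),
                                MQ = rep_len(MQ, length(pos)),
                                QUAL = rep_len(QUAL, length(pos)),
                                MQRankSum = rep_len(MQRankSum, length(pos)),
                                SOR = rep_len(SOR, length(pos)),
                                FS = rep_len(FS, length(pos)),
                                ReadPosRankSum = rep_len(ReadPosRankSum, length(pos)))
}

# minimal VCF text writer for malformed/edge-case inputs
write_vcf_text <- function(records, contig = "chr1", len = 10000L) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, len),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="qd">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="mq">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="x">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records), f)
  f
}

# a deterministic random callset for round-trip properties
random_callset <- function(n, seed, line_id = "L1", contig_len = 100000L) {
  set.seed(seed)
  pos <- sort(sample.int(contig_len - 10L, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  make_variant("chr1", pos, ref, alt, line_id,
               QD = round(runif(n, 0, 40), 2), MQ = round(runif(n, 10, 60), 2),
               QUAL = round(runif(n, 0, 1000), 2),
               MQRankSum = ifelse(runif(n) < 0.2, NA, round(runif(n, -15, 5), 2)),
               SOR = round(runif(n, 0, 6), 2), FS = round(runif(n, 0, 80), 2),
               ReadPosRankSum = ifelse(runif(n) < 0.2, NA, round(runif(n, -10, 5), 2)))
}

# annotated exonic rows for count-driven fixtures: each variant in its own
# gene unless gene ids are supplied
mock_exonic_line <- function(line_id, consequences, genes = NULL,
                             start_pos = 1000L) {
  n <- length(consequences)
  v <- make_variant("c1", start_pos + seq_len(n) * 10L,
                    rep("A", n), rep("G", n), line_id)
  v$region <- "exonic"
  v$consequence <- consequences
  v$gene_id <- if (is.null(genes)) sprintf("%s_g%03d", line_id, seq_len(n)) else genes
  v$protein_change <- NA_character_
  v
}
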