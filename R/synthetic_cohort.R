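#' Simulation configuration for a synthetic mutagenized cohort
#'
#' Defaults emulate the screen the pipeline targets: 15 mutant lines; a set
#' of background variants shared by every line (pre-existing divergence
#' from the reference clone); decoy variants recurring in more than two
#' lines; private variants drawn from the mutagen's spectrum; one planted
#' causal exonic loss-of-function variant per line in a line-unique gene;
#' and a controllable fraction of variants given metrics that violate the
#' hard filter.  \code{paper_scale = TRUE} raises the private load to
#' ~2700 variants per line, the scale reported for real EMS/UV mutant
#' lines; the desk-scale default of 200 keeps test runs fast.
#'
#' @param seed RNG seed (integer).
#' @param n_lines number of mutant lines (default 15).
#' @param genome_length single-contig genome length in bases (default 1e5).
#' @param n_genes number of simulated genes; must be >= \code{n_lines} so
#'   each line's causal gene is unique (default 20).
#' @param n_background_universal variants planted in all lines (default 50).
#' @param n_recurrent_decoys exonic nonsynonymous decoys, each planted in
#'   3..\code{n_lines}-1 lines (default 10).
#' @param n_synonymous_decoys exonic synonymous decoys, one line each
#'   (default 10).
#' @param n_private_per_line random-spectrum private variants per line
#'   (default 200).
#' @param paper_scale when TRUE, sets \code{n_private_per_line} to 2700.
#' @param mutagen_profile \code{"EMS"} or \code{"UV"}.
#' @param spectrum_fraction fraction of private/background SNVs drawn from
#'   the mutagen's signature class: G:C->A:T transitions for EMS, C->T at
#'   pyrimidine dinucleotides for UV (default 0.9).
#' @param indel_fraction fraction of private/background variants that are
#'   indels of length 1-6 (default 0.1).
#' @param fail_fraction fraction of private variants per line given
#'   metrics violating at least one hard-filter criterion; background
#'   variants fail with the same probability (consistently across lines);
#'   causal variants and decoys always receive passing metrics
#'   (default 0.2).
#' @param min_gap minimum intergenic gap between genes, in bases; kept
#'   above twice the default flank window so upstream/downstream calls are
#'   unambiguous (default 2100).
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L, n_lines = 15L,
                              genome_length = 100000L, n_genes = 20L,
                              n_background_universal = 50L,
                              n_recurrent_decoys = 10L,
                              n_synonymous_decoys = 10L,
                              n_private_per_line = 200L,
                              paper_scale = FALSE,
                              mutagen_profile = c("EMS", "UV"),
                              spectrum_fraction = 0.9,
                              indel_fraction = 0.1,
                              fail_fraction = 0.2,
                              min_gap = 2100L) {
  mutagen_profile <- match.arg(mutagen_profile)
  if (paper_scale) n_private_per_line <- 2700L
  cfg <- structure(list(seed = as.integer(seed), n_lines = as.integer(n_lines),
                        genome_length = as.integer(genome_length),
                        n_genes = as.integer(n_genes),
                        n_background_universal = as.integer(n_background_universal),
                        n_recurrent_decoys = as.integer(n_recurrent_decoys),
                        n_synonymous_decoys = as.integer(n_synonymous_decoys),
                        n_private_per_line = as.integer(n_private_per_line),
                        mutagen_profile = mutagen_profile,
                        spectrum_fraction = spectrum_fraction,
                        indel_fraction = indel_fraction,
                        fail_fraction = fail_fraction,
                        min_gap = as.integer(min_gap)),
                   class = "simulation_config")
  if (cfg$n_genes < cfg$n_lines)
    stop("n_genes must be >= n_lines so causal genes are line-unique")
  if (cfg$n_recurrent_decoys > 0L && cfg$n_lines < 4L)
    stop("recurrent decoys need n_lines >= 4 (placement in 3..n_lines-1 lines)")
  if (cfg$fail_fraction < 0 || cfg$fail_fraction >= 1)
    stop("fail_fraction must be in [0, 1)")
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

random_codons <- function(n) {
  # codons with no stop among them
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cd <- random_dna(3L)
      if (!cd %in% STOP_CODONS) break
    }
    out[i] <- cd
  }
  paste(out, collapse = "")
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# construct one gene: local layout in transcript-plus orientation, then
# mirrored onto the genome for minus-strand genes
build_sim_gene <- function(gene_id, strand, gstart) {
  u5 <- sample(60:150, 1L)
  u3 <- sample(60:200, 1L)
  n_codons <- sample(150:400, 1L)
  cds_len <- 3L * n_codons
  cds_seq <- paste0("ATG", random_codons(n_codons - 2L), sample(STOP_CODONS, 1L))
  n_exons <- sample(1:3, 1L)
  # split CDS at arbitrary (not codon-aligned) points
  cuts <- if (n_exons > 1L) sort(sample(seq_len(cds_len - 1L), n_exons - 1L)) else integer(0)
  piece_start <- c(1L, cuts + 1L)
  piece_end <- c(cuts, cds_len)
  introns <- if (n_exons > 1L) sample(50:80, n_exons - 1L, replace = TRUE) else integer(0)

  # local coordinates (1-based within the gene sequence)
  off <- u5
  pieces <- data.frame(a = integer(n_exons), b = integer(n_exons),
                       cds_start = piece_start, cds_end = piece_end)
  local_parts <- character(0)
  utr5_seq <- random_dna(u5)
  local_parts <- utr5_seq
  for (i in seq_len(n_exons)) {
    w <- piece_end[i] - piece_start[i] + 1L
    pieces$a[i] <- off + 1L
    pieces$b[i] <- off + w
    local_parts <- c(local_parts, substring(cds_seq, piece_start[i], piece_end[i]))
    off <- off + w
    if (i < n_exons) {
      local_parts <- c(local_parts, random_dna(introns[i]))
      off <- off + introns[i]
    }
  }
  utr3_seq <- random_dna(u3)
  local_parts <- c(local_parts, utr3_seq)
  L <- off + u3
  gseq_local <- paste(local_parts, collapse = "")
  stopifnot(nchar(gseq_local) == L)

  loc2gen <- function(a, b) {
    if (strand == "+") c(gstart + a - 1L, gstart + b - 1L)
    else c(gstart + L - b, gstart + L - a)
  }
  seg_df <- function(iv_list) {
    if (!length(iv_list)) return(empty_segments())
    m <- do.call(rbind, iv_list)
    df <- data.frame(start = m[, 1], end = m[, 2])
    df[order(df$start), , drop = FALSE]
  }
  cds_iv <- lapply(seq_len(n_exons), function(i) loc2gen(pieces$a[i], pieces$b[i]))
  u5_iv <- list(loc2gen(1L, u5))
  u3_iv <- list(loc2gen(L - u3 + 1L, L))
  if (strand == "+") { utr5_g <- seg_df(u5_iv); utr3_g <- seg_df(u3_iv) }
  else { utr5_g <- seg_df(u5_iv); utr3_g <- seg_df(u3_iv) }

  # genomic positions of CDS bases in translation order
  cds_gpos <- integer(0)
  for (i in seq_len(n_exons)) {
    loc <- pieces$a[i]:pieces$b[i]
    gp <- if (strand == "+") gstart + loc - 1L else gstart + L - loc
    cds_gpos <- c(cds_gpos, gp)
  }
  stopifnot(length(cds_gpos) == cds_len)

  list(gene_id = gene_id, strand = strand, gstart = gstart, L = L,
       cds_seq = cds_seq, cds_len = cds_len, cds_gpos = cds_gpos,
       genomic_seq = if (strand == "+") gseq_local else revcomp_chr(gseq_local),
       model = new_gene_model(gene_id, "contig_1", strand,
                              seg_df(cds_iv), utr5_g, utr3_g))
}

.simulate_genome <- function(config) {
  n <- config$n_genes
  strands <- sample(c("+", "-"), n, replace = TRUE)
  # draw gene bodies first, then lay them out with random intergenic gaps
  genes <- vector("list", n)
  lens <- integer(n)
  tmp <- lapply(seq_len(n), function(i) build_sim_gene(sprintf("gene_%03d", i),
                                                       strands[i], 1L))
  lens <- vapply(tmp, `[[`, 0L, "L")
  extra <- config$genome_length - sum(lens) - (n + 1L) * config$min_gap
  if (extra < 0L)
    stop("cannot place ", n, " genes in a ", config$genome_length,
         " bp genome with min_gap ", config$min_gap)
  r <- stats::runif(n + 1L)
  gaps <- config$min_gap + floor(extra * r / sum(r))
  cursor <- 0L
  genome_seq <- random_dna(config$genome_length)
  for (i in seq_len(n)) {
    cursor <- cursor + gaps[i]
    gstart <- cursor + 1L
    g <- build_sim_gene_at(tmp[[i]], gstart)
    substring(genome_seq, gstart, gstart + g$L - 1L) <- g$genomic_seq
    genes[[i]] <- g
    cursor <- cursor + g$L
  }
  genome <- Biostrings::DNAStringSet(setNames(genome_seq, "contig_1"))
  list(genome = genome, genes = genes,
       models = lapply(genes, `[[`, "model"))
}

# rebase a built gene (drawn at gstart=1) to its final genomic start
build_sim_gene_at <- function(g, gstart) {
  shift <- gstart - g$gstart
  g$gstart <- gstart
  g$cds_gpos <- g$cds_gpos + shift
  m <- g$model
  for (f in c("cds", "utr5", "utr3")) {
    if (nrow(m[[f]])) {
      m[[f]]$start <- m[[f]]$start + shift
      m[[f]]$end <- m[[f]]$end + shift
    }
  }
  m$span <- m$span + shift
  g$model <- m
  g
}

#' Simulate a reference genome with gene models
#'
#' Generates a single-contig genome whose genes are non-overlapping open
#' reading frames (ATG start, in-frame stop, no internal stop) with 5'/3'
#' UTRs and optional introns, on random strands, and writes FASTA + GFF3
#' files that parse back through \code{\link{load_genome}} and
#' \code{\link{load_gene_models}}.  Deterministic for a fixed seed.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param dir output directory (created if absent).
#' @return a list with \code{genome} (\code{DNAStringSet}), \code{models}
#'   (list of \code{gene_model}), \code{fasta} and \code{gff3} paths.
#' @export
simulate_genome <- function(config = simulation_config(), dir = tempfile("sim")) {
  set.seed(config$seed)
  sim <- .simulate_genome(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "genes.gff3")
  write_genome(sim$genome, fasta)
  write_gff3(sim$models, gff3)
  list(genome = sim$genome, models = sim$models, fasta = fasta, gff3 = gff3)
}

# ---- intent classification (simulator's own per-base bookkeeping) --------

# class of one base for one gene, or NA when the base is outside the gene
# and its flanks
intent_base_class <- function(p, g, flank = 1000L) {
  m <- g$model
  if (any(p >= m$cds$start & p <= m$cds$end)) return("exonic")
  if (nrow(m$utr5) && any(p >= m$utr5$start & p <= m$utr5$end)) return("utr5")
  if (nrow(m$utr3) && any(p >= m$utr3$start & p <= m$utr3$end)) return("utr3")
  if (p >= m$span[1] && p <= m$span[2]) return("intronic")
  if (m$strand == "+") {
    if (p >= m$span[1] - flank && p < m$span[1]) return("upstream")
    if (p > m$span[2] && p <= m$span[2] + flank) return("downstream")
  } else {
    if (p > m$span[2] && p <= m$span[2] + flank) return("upstream")
    if (p >= m$span[1] - flank && p < m$span[1]) return("downstream")
  }
  NA_character_
}

# intended region over the variant's affected interval, with the same
# precedence contract the annotator implements
intent_region <- function(pos, ref, genes, flank = 1000L) {
  span <- pos:(pos + nchar(ref) - 1L)
  best <- "intergenic"; best_gene <- NA_character_
  best_prec <- REGION_PRECEDENCE[["intergenic"]]
  for (g in genes) {
    if (pos + nchar(ref) - 1L < g$gstart - flank ||
        pos > g$gstart + g$L - 1L + flank) next
    for (p in span) {
      cl <- intent_base_class(p, g, flank)
      if (is.na(cl)) next
      pr <- REGION_PRECEDENCE[[cl]]
      if (pr < best_prec ||
          (pr == best_prec && !is.na(best_gene) && g$gene_id < best_gene)) {
        best <- cl; best_prec <- pr; best_gene <- g$gene_id
      }
    }
  }
  list(region = best, gene_id = best_gene)
}

# intended coding consequence from the simulator's stored CDS sequence and
# genomic-position map (built at gene construction, not via extract_cds)
intent_consequence <- function(pos, ref, alt, g) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1L && la == 1L) {
    i <- match(pos, g$cds_gpos)
    if (is.na(i)) return(NA_character_)
    talt <- if (g$strand == "+") alt else COMPLEMENT[[alt]]
    k <- (i - 1L) %/% 3L + 1L
    off <- (i - 1L) %% 3L + 1L
    codon <- substring(g$cds_seq, 3L * k - 2L, 3L * k)
    mcodon <- codon
    substring(mcodon, off, off) <- talt
    aa0 <- unname(Biostrings::GENETIC_CODE[codon])
    aa1 <- unname(Biostrings::GENETIC_CODE[mcodon])
    if (aa0 == aa1) return("synonymous_snv")
    if (aa1 == "*") return("stop_gain")
    if (aa0 == "*") return("stop_loss")
    return("nonsynonymous_snv")
  }
  chg <- if (la > lr) {
    if ((pos + lr - 1L) %in% g$cds_gpos) la - lr else 0L
  } else {
    sum(seq(pos + la, pos + lr - 1L) %in% g$cds_gpos)
  }
  if (chg %% 3L == 0L) "nonframeshift_indel" else "frameshift_indel"
}

# ---- quality-metric sampling ---------------------------------------------

# passing metrics sit comfortably inside every criterion; the two rank-sum
# statistics are occasionally absent, as in real callsets
sample_passing_metrics <- function() {
  m <- list(QD = runif(1, 20, 35), MQ = runif(1, 55, 60),
            QUAL = runif(1, 300, 1000), MQRankSum = runif(1, -2, 2),
            SOR = runif(1, 0.5, 2), FS = runif(1, 0, 10),
            ReadPosRankSum = runif(1, -2, 2))
  if (runif(1) < 0.1) m$MQRankSum <- NA_real_
  if (runif(1) < 0.1) m$ReadPosRankSum <- NA_real_
  m
}

# failing metrics: one criterion chosen uniformly and drawn beyond its
# threshold; the rest stay in passing ranges
sample_failing_metrics <- function() {
  m <- sample_passing_metrics()
  m$MQRankSum <- if (is.na(m$MQRankSum)) runif(1, -2, 2) else m$MQRankSum
  m$ReadPosRankSum <- if (is.na(m$ReadPosRankSum)) runif(1, -2, 2) else m$ReadPosRankSum
  crit <- sample(METRIC_COLS, 1L)
  m[[crit]] <- switch(crit,
    QD = runif(1, 0, 1.9), MQ = runif(1, 10, 39.5), QUAL = runif(1, 0, 99),
    MQRankSum = runif(1, -20, -12.6), SOR = runif(1, 4.1, 8),
    FS = runif(1, 61, 100), ReadPosRankSum = runif(1, -15, -8.1))
  m
}

# ---- spectrum sampling ----------------------------------------------------

is_signature_snv <- function(profile, chars, pos, ref, alt) {
  if (profile == "EMS")
    return((ref == "G" && alt == "A") || (ref == "C" && alt == "T"))
  # UV: C->T with a pyrimidine neighbor (dipyrimidine context)
  if (!(ref == "C" && alt == "T")) return(FALSE)
  n <- length(chars)
  (pos > 1L && chars[pos - 1L] %in% c("C", "T")) ||
    (pos < n && chars[pos + 1L] %in% c("C", "T"))
}

# registry of occupied reference positions so identity keys never collide
new_registry <- function(n) new.env(parent = emptyenv())
reserve <- function(reg, p, q = p) {
  for (x in p:q) assign(as.character(x), TRUE, envir = reg)
}
is_free <- function(reg, p, q = p) {
  for (x in p:q) if (exists(as.character(x), envir = reg)) return(FALSE)
  TRUE
}

draw_signature_snv <- function(chars, sig_pos, reg, profile) {
  repeat {
    p <- sig_pos[sample.int(length(sig_pos), 1L)]
    if (!is_free(reg, p)) next
    ref <- chars[p]
    alt <- if (profile == "EMS") (if (ref == "G") "A" else "T") else "T"
    reserve(reg, p)
    return(list(pos = p, ref = ref, alt = alt))
  }
}

draw_other_snv <- function(chars, reg, profile) {
  n <- length(chars)
  repeat {
    p <- sample.int(n - 8L, 1L) + 1L
    if (!is_free(reg, p)) next
    ref <- chars[p]
    alt <- sample(setdiff(BASES, ref), 1L)
    if (is_signature_snv(profile, chars, p, ref, alt)) next
    reserve(reg, p)
    return(list(pos = p, ref = ref, alt = alt))
  }
}

draw_indel <- function(chars, reg) {
  n <- length(chars)
  len <- sample(1:6, 1L)
  repeat {
    p <- sample.int(n - 8L, 1L) + 1L
    if (runif(1) < 0.5) {                      # insertion after p
      if (!is_free(reg, p)) next
      reserve(reg, p)
      return(list(pos = p, ref = chars[p],
                  alt = paste0(chars[p], random_dna(len))))
    } else {                                   # deletion of p+1 .. p+len
      if (p + len > n - 1L || !is_free(reg, p, p + len)) next
      reserve(reg, p, p + len)
      return(list(pos = p,
                  ref = paste(chars[p:(p + len)], collapse = ""),
                  alt = chars[p]))
    }
  }
}

draw_spectrum_variant <- function(config, chars, sig_pos, reg) {
  if (runif(1) < config$indel_fraction) return(draw_indel(chars, reg))
  if (runif(1) < config$spectrum_fraction)
    draw_signature_snv(chars, sig_pos, reg, config$mutagen_profile)
  else
    draw_other_snv(chars, reg, config$mutagen_profile)
}

# ---- planted exonic variants ---------------------------------------------

# an SNV inside gene g with the requested coding consequence
draw_exonic_snv <- function(g, chars, reg, want) {
  n_codons <- g$cds_len %/% 3L
  for (try in seq_len(4000L)) {
    k <- sample(2:(n_codons - 1L), 1L)
    off <- sample(1:3, 1L)
    i <- 3L * (k - 1L) + off
    gpos <- g$cds_gpos[i]
    if (!is_free(reg, gpos)) next
    codon <- substring(g$cds_seq, 3L * k - 2L, 3L * k)
    for (talt in sample(setdiff(BASES, substring(codon, off, off)))) {
      mcodon <- codon
      substring(mcodon, off, off) <- talt
      aa0 <- unname(Biostrings::GENETIC_CODE[codon])
      aa1 <- unname(Biostrings::GENETIC_CODE[mcodon])
      ok <- switch(want,
        stop_gain = aa1 == "*" && aa0 != "*",
        nonsynonymous_snv = aa0 != aa1 && aa1 != "*" && aa0 != "*",
        synonymous_snv = aa0 == aa1)
      if (ok) {
        reserve(reg, gpos)
        alt <- if (g$strand == "+") talt else COMPLEMENT[[talt]]
        return(list(pos = gpos, ref = chars[gpos], alt = alt))
      }
    }
  }
  NULL
}

# a frameshift insertion of 1-2 bp anchored at a coding base of gene g
draw_frameshift_insertion <- function(g, chars, reg) {
  repeat {
    i <- sample.int(g$cds_len - 3L, 1L)
    gpos <- g$cds_gpos[i]
    if (!is_free(reg, gpos)) next
    reserve(reg, gpos)
    len <- sample(1:2, 1L)
    return(list(pos = gpos, ref = chars[gpos],
                alt = paste0(chars[gpos], random_dna(len))))
  }
}

# ---- cohort simulation ----------------------------------------------------

#' Simulate a mutagenized cohort with a truth table
#'
#' Generates a genome (\code{\link{simulate_genome}}) and per-line VCFs with
#' the statistical structure the analysis assumes: universal background
#' variants present in every line; exonic nonsynonymous decoys recurring in
#' more than two lines; private exonic synonymous decoys; random
#' mutagen-spectrum private variants; and one causal exonic
#' loss-of-function variant (stop gain or frameshift insertion) per line,
#' each in a line-unique gene.  A configurable fraction of private and
#' background variants receive quality metrics violating one hard-filter
#' criterion; causal variants and decoys always receive passing metrics.
#' Output files are byte-deterministic for a fixed seed.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param dir output directory (created if absent).
#' @return a list with \code{genome}, \code{models}, \code{genes}
#'   (simulator-internal gene records), \code{fasta}, \code{gff3},
#'   \code{vcfs} (named character vector line_id -> path), \code{truth}
#'   (data.frame, also written to \code{truth.tsv}) and \code{truth_path}.
#' @export
simulate_cohort <- function(config = simulation_config(), dir = tempfile("sim")) {
  set.seed(config$seed)
  sim <- .simulate_genome(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "genes.gff3")
  write_genome(sim$genome, fasta)
  write_gff3(sim$models, gff3)

  genes <- sim$genes
  genome_seq <- as.character(sim$genome[[1]])
  chars <- strsplit(genome_seq, "", fixed = TRUE)[[1]]
  sig_pos <- if (config$mutagen_profile == "EMS") {
    which(chars %in% c("G", "C"))
  } else {
    pyr <- chars %in% c("C", "T")
    which(chars == "C" &
            (c(FALSE, pyr[-length(pyr)]) | c(pyr[-1], FALSE)))
  }
  sig_pos <- sig_pos[sig_pos > 1L & sig_pos < length(chars) - 7L]
  reg <- new_registry(length(chars))
  line_ids <- sprintf("line_%02d", seq_len(config$n_lines))

  recs <- list()
  push <- function(v, category, lines, metrics, filter_pass, is_causal = FALSE) {
    ir <- intent_region(v$pos, v$ref, genes)
    cons <- NA_character_
    if (ir$region == "exonic") {
      g <- genes[[which(vapply(genes, `[[`, "", "gene_id") == ir$gene_id)]]
      cons <- intent_consequence(v$pos, v$ref, v$alt, g)
    }
    recs[[length(recs) + 1L]] <<- c(
      list(contig = "contig_1", pos = v$pos, ref = v$ref, alt = v$alt,
           category = category, lines = paste(lines, collapse = ","),
           n_lines = length(lines), region = ir$region,
           consequence = cons, gene_id = ir$gene_id,
           filter_pass = filter_pass, is_causal = is_causal),
      metrics)
  }

  # universal background: same record (and metrics) in every line
  for (i in seq_len(config$n_background_universal)) {
    v <- draw_spectrum_variant(config, chars, sig_pos, reg)
    fail <- runif(1) < config$fail_fraction
    m <- if (fail) sample_failing_metrics() else sample_passing_metrics()
    push(v, "background", line_ids, m, filter_pass = !fail)
  }

  # recurrent decoys: exonic nonsynonymous, planted in 3..n_lines-1 lines
  for (i in seq_len(config$n_recurrent_decoys)) {
    g <- genes[[sample.int(length(genes), 1L)]]
    v <- draw_exonic_snv(g, chars, reg, "nonsynonymous_snv")
    if (is.null(v)) stop("could not place recurrent decoy in ", g$gene_id)
    ks <- 3:(config$n_lines - 1L)           # guard against scalar sample()
    k <- ks[sample.int(length(ks), 1L)]
    push(v, "recurrent_decoy", sort(sample(line_ids, k)),
         sample_passing_metrics(), filter_pass = TRUE)
  }

  # synonymous decoys: exonic synonymous, private to one line
  for (i in seq_len(config$n_synonymous_decoys)) {
    g <- genes[[sample.int(length(genes), 1L)]]
    v <- draw_exonic_snv(g, chars, reg, "synonymous_snv")
    if (is.null(v)) stop("could not place synonymous decoy in ", g$gene_id)
    push(v, "synonymous_decoy", sample(line_ids, 1L),
         sample_passing_metrics(), filter_pass = TRUE)
  }

  # causal loss-of-function variants: one line-unique gene per line
  causal_gene_idx <- sample.int(length(genes), config$n_lines)
  for (li in seq_len(config$n_lines)) {
    g <- genes[[causal_gene_idx[li]]]
    v <- NULL
    if (runif(1) < 0.5) v <- draw_exonic_snv(g, chars, reg, "stop_gain")
    if (is.null(v)) v <- draw_frameshift_insertion(g, chars, reg)
    push(v, "causal", line_ids[li], sample_passing_metrics(),
         filter_pass = TRUE, is_causal = TRUE)
  }

  # private mutagen-spectrum variants, with an exact count of
  # hard-filter-failing metrics per line
  n_priv <- config$n_private_per_line
  n_fail <- round(config$fail_fraction * n_priv)
  for (li in seq_len(config$n_lines)) {
    fail_idx <- if (n_fail > 0L) sample.int(n_priv, n_fail) else integer(0)
    for (i in seq_len(n_priv)) {
      v <- draw_spectrum_variant(config, chars, sig_pos, reg)
      fail <- i %in% fail_idx
      m <- if (fail) sample_failing_metrics() else sample_passing_metrics()
      push(v, "private", line_ids[li], m, filter_pass = !fail)
    }
  }

  truth <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  truth$key <- variant_key(truth)
  truth <- truth[, c("key", "contig", "pos", "ref", "alt", "category",
                     "lines", "n_lines", "region", "consequence", "gene_id",
                     "filter_pass", "is_causal", METRIC_COLS)]
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth[order(truth$pos), ], truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  clen <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  vcfs <- setNames(file.path(dir, paste0(line_ids, ".vcf")), line_ids)
  member <- strsplit(truth$lines, ",", fixed = TRUE)
  for (li in seq_along(line_ids)) {
    id <- line_ids[li]
    sel <- vapply(member, function(l) id %in% l, TRUE)
    df <- truth[sel, , drop = FALSE]
    tab <- new_variant_table(contig = df$contig, pos = df$pos, ref = df$ref,
                             alt = df$alt, line_id = rep(id, nrow(df)),
                             QD = df$QD, MQ = df$MQ, QUAL = df$QUAL,
                             MQRankSum = df$MQRankSum, SOR = df$SOR,
                             FS = df$FS, ReadPosRankSum = df$ReadPosRankSum)
    tab <- tab[order(tab$contig, tab$pos), , drop = FALSE]
    rownames(tab) <- NULL
    write_vcf(tab, vcfs[[id]], clen)
  }

  list(genome = sim$genome, models = sim$models, genes = genes,
       config = config, fasta = fasta, gff3 = gff3, vcfs = vcfs,
       truth = truth, truth_path = truth_path)
}

#' Score causal-gene recovery against the simulation truth
#'
#' @param candidates candidate table from \code{\link{select_candidates}}
#'   run on the simulated cohort.
#' @param truth truth data.frame from \code{\link{simulate_cohort}}.
#' @return a list with \code{per_line} (line_id, causal_gene, recovered,
#'   rank), \code{n_recovered}, \code{n_lines}, and
#'   \code{decoys_surviving}: counts of background / recurrent-decoy /
#'   synonymous-decoy variants present in any candidate (expected 0).
#' @export
evaluate_recovery <- function(candidates, truth) {
  cand_keys <- unique(unlist(strsplit(candidates$variant_keys, ",", fixed = TRUE)))
  if (length(cand_keys) && !all(cand_keys %in% truth$key))
    stop("candidate output does not correspond to this truth table")
  causal <- truth[truth$is_causal, , drop = FALSE]
  per_line <- do.call(rbind, lapply(seq_len(nrow(causal)), function(i) {
    id <- causal$lines[i]
    cc <- candidates[candidates$line_id == id, , drop = FALSE]
    hit <- match(causal$gene_id[i], cc$gene_id)
    data.frame(line_id = id, causal_gene = causal$gene_id[i],
               recovered = !is.na(hit), rank = hit,
               stringsAsFactors = FALSE)
  }))
  decoys <- vapply(c(background = "background",
                     recurrent_decoy = "recurrent_decoy",
                     synonymous_decoy = "synonymous_decoy"),
                   function(cat) sum(truth$key[truth$category == cat] %in% cand_keys),
                   0L)
  list(per_line = per_line, n_recovered = sum(per_line$recovered),
       n_lines = nrow(per_line), decoys_surviving = decoys)
}
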