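#' Load a reference genome from FASTA
#'
#' Reads all contigs, uppercases the sequence and validates the alphabet.
#' Multi-line records are concatenated.  The returned object is a
#' \link[Biostrings]{DNAStringSet}; contig lengths are available via
#' \code{Biostrings::width()}.
#'
#' @param path path to a FASTA file.
#' @return a \code{DNAStringSet}, one element per contig, named by the first
#'   whitespace-delimited token of each header.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(raw) == 0L) stop("FASTA format error: ", path, " contains no records")
  seqs <- toupper(as.character(raw))
  names(seqs) <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(names(seqs)))) stop("FASTA format error: empty contig name")
  if (anyDuplicated(names(seqs)))
    stop("FASTA format error: duplicate contig name '",
         names(seqs)[duplicated(names(seqs))][1], "'")
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("FASTA format error: contig '", names(seqs)[i],
         "' has non-IUPAC character '", substring(seqs[i], bad[i], bad[i]),
         "' at position ", bad[i])
  }
  Biostrings::DNAStringSet(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a \code{DNAStringSet} as returned by \code{\link{load_genome}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d CDS segment(s), coding=%s\n",
              x$gene_id, x$contig, x$span[1], x$span[2], x$strand,
              nrow(x$cds), x$coding))
  invisible(x)
}

new_gene_model <- function(gene_id, contig, strand, cds, utr5, utr3, coding = TRUE) {
  segs <- rbind(cds, utr5, utr3)
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 cds = cds[order(cds$start), , drop = FALSE],
                 utr5 = utr5, utr3 = utr3,
                 span = c(min(segs$start), max(segs$end)),
                 coding = coding),
            class = "gene_model")
}

empty_segments <- function() data.frame(start = integer(0), end = integer(0))

#' Load gene models from GFF3
#'
#' Parses gene/mRNA/CDS/five_prime_UTR/three_prime_UTR features into one
#' model per gene.  When a gene has several mRNAs the transcript with the
#' longest total CDS is kept (with a warning).  Genes whose total CDS length
#' is not a multiple of 3 are retained for region classification but flagged
#' non-coding for consequence calls (with a warning).
#'
#' @param path path to a GFF3 file.  Gene features must carry an \code{ID}
#'   attribute.
#' @param genome a \code{DNAStringSet}; used to check that features lie
#'   within contig bounds.
#' @return a list of \code{gene_model} objects, sorted by contig then span
#'   start.  Each model has fields \code{gene_id}, \code{contig},
#'   \code{strand}, \code{cds}, \code{utr5}, \code{utr3} (data.frames of
#'   1-based inclusive genomic intervals), \code{span} and \code{coding}.
#' @export
load_gene_models <- function(path, genome) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gff)
  type <- as.character(md$type)
  contig <- as.character(GenomicRanges::seqnames(gff))
  strand <- as.character(GenomicRanges::strand(gff))
  start <- GenomicRanges::start(gff)
  end <- GenomicRanges::end(gff)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gff))
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, "")
  } else rep(NA_character_, length(gff))

  glen <- setNames(Biostrings::width(genome), names(genome))
  unknown <- !(contig %in% names(glen))
  if (any(unknown))
    stop("GFF3 format error: contig '", contig[unknown][1], "' not in genome")
  oob <- start < 1L | end > glen[contig]
  if (any(oob))
    stop("GFF3 format error: feature outside contig bounds at ",
         contig[oob][1], ":", start[oob][1], "-", end[oob][1])

  gene_idx <- which(type == "gene")
  models <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    if (is.na(gid)) stop("GFF3 format error: gene feature without ID at ",
                         contig[gi], ":", start[gi])
    mrnas <- which(type == "mRNA" & parent == gid)
    # choose the transcript: longest total CDS when several mRNAs exist
    if (length(mrnas) > 1L) {
      cds_tot <- vapply(mrnas, function(mi) {
        ci <- which(type == "CDS" & parent == ids[mi])
        sum(end[ci] - start[ci] + 1L)
      }, 0L)
      warning("gene ", gid, " has ", length(mrnas),
              " mRNAs; keeping the one with the longest CDS")
      mrnas <- mrnas[which.max(cds_tot)]
    }
    feat_parent <- if (length(mrnas) == 1L) ids[mrnas] else gid
    seg_df <- function(what) {
      ix <- which(type == what & parent == feat_parent)
      if (!length(ix)) return(empty_segments())
      data.frame(start = start[ix], end = end[ix])[order(start[ix]), , drop = FALSE]
    }
    cds <- seg_df("CDS")
    if (!nrow(cds)) {
      warning("gene ", gid, " has no CDS features; skipped")
      next
    }
    if (nrow(cds) > 1L && any(cds$start[-1] <= cds$end[-nrow(cds)]))
      stop("GFF3 format error: overlapping CDS segments in gene ", gid)
    coding <- TRUE
    if (sum(cds$end - cds$start + 1L) %% 3L != 0L) {
      warning("gene ", gid, " total CDS length is not a multiple of 3; ",
              "excluded from coding-consequence calls")
      coding <- FALSE
    }
    models[[length(models) + 1L]] <-
      new_gene_model(gid, contig[gi], strand[gi], cds,
                     seg_df("five_prime_UTR"), seg_df("three_prime_UTR"),
                     coding = coding)
  }
  ord <- order(vapply(models, `[[`, "", "contig"),
               vapply(models, function(m) m$span[1], 0))
  models[ord]
}

#' Extract the coding sequence of a gene model
#'
#' Concatenates the CDS segments in genomic order and, for minus-strand
#' genes, reverse-complements the result so that translation starts at the
#' highest-coordinate segment.
#'
#' @param model a \code{gene_model}.
#' @param genome a \code{DNAStringSet}.
#' @return the coding DNA as a single character string (length a multiple of
#'   3 for coding-valid models).
#' @export
extract_cds <- function(model, genome) {
  seq <- as.character(genome[[model$contig]])
  parts <- substring(seq, model$cds$start, model$cds$end)
  cds <- paste(parts, collapse = "")
  if (model$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

#' Translate coding DNA with the standard genetic code
#'
#' Codons containing N (or any non-ACGT base) translate to \code{"X"}; stop
#' codons translate to \code{"*"}.  Trailing partial codons are an error.
#'
#' @param cds coding DNA string, length a multiple of 3.
#' @return a character string of amino acids.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Write gene models to GFF3
#'
#' Deterministic plain-text emitter (fixed header, fixed attribute order)
#' used by the simulator; output parses back through
#' \code{\link{load_gene_models}}.
#'
#' @param models list of \code{gene_model} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(contig, src, type, s, e, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", contig, src, type, s, e, strand, attrs)
  for (m in models) {
    gid <- m$gene_id
    tid <- paste0(gid, ".t1")
    lines <- c(
      fmt(m$contig, "varscreen", "gene", m$span[1], m$span[2], m$strand,
          paste0("ID=", gid)),
      fmt(m$contig, "varscreen", "mRNA", m$span[1], m$span[2], m$strand,
          paste0("ID=", tid, ";Parent=", gid)))
    seg_lines <- function(df, type) {
      if (!nrow(df)) return(character(0))
      fmt(m$contig, "varscreen", type, df$start, df$end, m$strand,
          paste0("ID=", tid, ".", type, ";Parent=", tid))
    }
    writeLines(c(lines,
                 seg_lines(m$utr5, "five_prime_UTR"),
                 seg_lines(m$cds, "CDS"),
                 seg_lines(m$utr3, "three_prime_UTR")), con)
  }
  invisible(path)
}
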