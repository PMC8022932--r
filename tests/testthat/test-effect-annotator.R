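# fixture: plus-strand gene, CDS 5..16 = ATG TGG GCA TAA on a 20 bp contig
plus_fixture <- function() {
  g <- make_genome(c1 = paste0("TTTT", "ATGTGGGCATAA", "TTTT"))
  m <- make_model("gP", "c1", "+", cds = c(5, 16))
  list(g = g, m = m)
}

test_that("classify_region assigns the documented classes with strand-aware flanks", {
  seq <- paste(rep("A", 5000), collapse = "")
  g <- make_genome(c1 = seq)
  plus <- make_model("gA", "c1", "+", cds = c(1001, 1300),
                     utr5 = c(901, 1000), utr3 = c(1301, 1400))
  minus <- make_model("gB", "c1", "-", cds = c(3001, 3300))
  models <- list(plus, minus)

  v <- make_variant("c1", c(1100L, 950L, 1350L, 600L, 1500L, 3800L, 2400L, 4600L),
                    rep("A", 8), rep("G", 8))
  rc <- classify_region(v, models, g)
  expect_equal(rc$region, c("exonic", "utr5", "utr3", "upstream", "downstream",
                            "upstream", "downstream", "intergenic"))
  expect_equal(rc$gene_id[1:3], rep("gA", 3))
  expect_equal(rc$gene_id[6], "gB")   # 500 bp 5' of a minus-strand gene's top end
  expect_true(is.na(rc$gene_id[8]))
})

test_that("positions beyond contig bounds are an error", {
  g <- make_genome(c1 = "ACGTACGT")
  v <- make_variant("c1", 50L, "A", "G")
  expect_error(classify_region(v, list(), g), "contig bounds")
})

test_that("exonic beats flank classes when overlapping genes compete", {
  g <- make_genome(c1 = paste(rep("A", 2000), collapse = ""))
  a <- make_model("gA", "c1", "+", cds = c(100, 201))
  b <- make_model("gB", "c1", "+", cds = c(300, 401))
  v <- make_variant("c1", 150L, "A", "G")   # exonic in gA, upstream of gB
  rc <- classify_region(v, list(a, b), g)
  expect_equal(rc$region, "exonic")
  expect_equal(rc$gene_id, "gA")

  # between two genes: upstream of one, downstream of the other -> upstream
  v2 <- make_variant("c1", 250L, "A", "G")
  rc2 <- classify_region(v2, list(a, b), g)
  expect_equal(rc2$region, "upstream")
  expect_equal(rc2$gene_id, "gB")
})

test_that("SNV consequences follow the genetic code on both strands", {
  f <- plus_fixture()
  # TGG -> TGA: stop gain, W2*
  v <- make_variant("c1", 10L, "G", "A")
  eff <- classify_coding_effect(v[1, ], f$m, f$g)
  expect_equal(eff$consequence, "stop_gain")
  expect_equal(eff$protein_change, "W2*")
  # GCA -> GCG: synonymous (both Ala)
  v <- make_variant("c1", 13L, "A", "G")
  expect_equal(classify_coding_effect(v[1, ], f$m, f$g)$consequence,
               "synonymous_snv")
  # TGG -> TCG: nonsynonymous W2S
  v <- make_variant("c1", 9L, "G", "C")
  eff <- classify_coding_effect(v[1, ], f$m, f$g)
  expect_equal(eff$consequence, "nonsynonymous_snv")
  expect_equal(eff$protein_change, "W2S")

  # minus strand: genomic TTACAT at 5..10 is transcript ATGTAA
  gm <- make_genome(c2 = paste0("CCCC", "TTACAT", "CCCC"))
  mm <- make_model("gM", "c2", "-", cds = c(5, 10))
  # destroy the stop codon: genomic A7 -> G gives transcript CAA (Gln)
  v <- make_variant("c2", 7L, "A", "G")
  expect_equal(classify_coding_effect(v[1, ], mm, gm)$consequence, "stop_loss")
})

test_that("indel consequences depend on coding-length change mod 3", {
  f <- plus_fixture()
  del2 <- make_variant("c1", 8L, "TGG", "T")      # removes 2 coding bases
  expect_equal(classify_coding_effect(del2[1, ], f$m, f$g)$consequence,
               "frameshift_indel")
  del3 <- make_variant("c1", 8L, "TGGG", "T")     # removes 3 coding bases
  expect_equal(classify_coding_effect(del3[1, ], f$m, f$g)$consequence,
               "nonframeshift_indel")
  ins1 <- make_variant("c1", 9L, "G", "GT")
  expect_equal(classify_coding_effect(ins1[1, ], f$m, f$g)$consequence,
               "frameshift_indel")
  ins3 <- make_variant("c1", 9L, "G", "GTTT")
  expect_equal(classify_coding_effect(ins3[1, ], f$m, f$g)$consequence,
               "nonframeshift_indel")
})

test_that("junction-spanning codons are handled and invariant to segmentation", {
  # CDS segments (5..8) + (15..19): transcript ATGT|GGTAA -> ATG TGG TAA
  g <- make_genome(c1 = paste0("TTTT", "ATGT", "CCCCCC", "GGTAA", "TT"))
  split <- make_model("gS", "c1", "+", cds = c(5, 8, 15, 19))
  expect_equal(extract_cds(split, g), "ATGTGGTAA")
  # codon 2 spans the junction (genomic 8, 15, 16); G at 15 -> A gives TAG
  v <- make_variant("c1", 15L, "G", "A")
  eff <- classify_coding_effect(v[1, ], split, g)
  expect_equal(eff$consequence, "stop_gain")
  expect_equal(eff$protein_change, "W2*")

  # the same transcript as a single segment yields the same call
  g2 <- make_genome(c1 = paste0("TTTT", "ATGTGGTAA", "TT"))
  solid <- make_model("gT", "c1", "+", cds = c(5, 13))
  v2 <- make_variant("c1", 9L, "G", "A")
  expect_equal(classify_coding_effect(v2[1, ], solid, g2)$consequence, "stop_gain")
})

test_that("codons containing N yield unknown", {
  g <- make_genome(c1 = paste0("TTTT", "ATGTNGTAA", "TTTT"))
  m <- make_model("gN", "c1", "+", cds = c(5, 13))
  v <- make_variant("c1", 8L, "T", "C")
  expect_equal(classify_coding_effect(v[1, ], m, g)$consequence, "unknown")
})

test_that("an SNV outside the CDS is a contract violation for the coding classifier", {
  f <- plus_fixture()
  v <- make_variant("c1", 2L, "T", "C")
  expect_error(classify_coding_effect(v[1, ], f$m, f$g), "contract violation")
})

test_that("region calls match the exhaustive paint-array oracle on a simulated genome", {
  cfg <- simulation_config(seed = 31, n_genes = 6, n_lines = 4,
                           genome_length = 30000)
  sim <- simulate_genome(cfg, tempfile("ann"))
  len <- Biostrings::width(sim$genome)[1]
  arrays <- oracle_region_arrays(sim$models, "contig_1", len)

  set.seed(8)
  pos <- sample.int(len - 10L, 20000L, replace = TRUE)
  v <- make_variant("contig_1", as.integer(pos), rep("A", length(pos)),
                    rep("G", length(pos)))
  rc <- classify_region(v, sim$models, sim$genome)
  want <- vapply(pos, function(p) oracle_region_query(arrays, p)$region, "")
  expect_identical(rc$region, want)
  want_gene <- vapply(pos, function(p) {
    g <- oracle_region_query(arrays, p)$gene_id
    if (is.null(g)) NA_character_ else g
  }, "")
  expect_identical(rc$gene_id, unname(want_gene))

  # multi-base intervals (deletion-like) follow the any-overlap precedence rule
  set.seed(9)
  dpos <- sample.int(len - 10L, 500L, replace = TRUE)
  dlen <- sample(2:6, 500L, replace = TRUE)
  seqc <- as.character(sim$genome[[1]])
  dv <- make_variant("contig_1", as.integer(dpos),
                     substring(seqc, dpos, dpos + dlen),
                     substring(seqc, dpos, dpos))
  drc <- classify_region(dv, sim$models, sim$genome)
  dwant <- vapply(seq_along(dpos), function(i)
    oracle_region_query(arrays, dpos[i], dlen[i] + 1L)$region, "")
  expect_identical(drc$region, dwant)
})

test_that("coding consequences match the full-CDS retranslation oracle", {
  cfg <- simulation_config(seed = 32, n_genes = 6, n_lines = 4,
                           genome_length = 30000)
  sim <- simulate_genome(cfg, tempfile("oracle"))
  seqc <- as.character(sim$genome[[1]])
  set.seed(10)
  for (rep in seq_len(300)) {
    m <- sim$models[[sample.int(length(sim$models), 1)]]
    cds_pos <- unlist(mapply(seq, m$cds$start, m$cds$end, SIMPLIFY = FALSE))
    p <- sample(cds_pos, 1)
    ref <- substring(seqc, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- make_variant("contig_1", as.integer(p), ref, alt)
    got <- classify_coding_effect(v[1, ], m, sim$genome)$consequence
    want <- oracle_snv_consequence(list(pos = p, alt = alt), m, seqc)
    expect_equal(got, want, label = sprintf("SNV %s:%d %s>%s", m$gene_id, p, ref, alt))
  }
  for (rep in seq_len(100)) {
    m <- sim$models[[sample.int(length(sim$models), 1)]]
    cds_pos <- unlist(mapply(seq, m$cds$start, m$cds$end, SIMPLIFY = FALSE))
    p <- sample(cds_pos, 1)
    if (runif(1) < 0.5) {
      len <- sample(1:6, 1)
      v <- list(pos = p, ref = substring(seqc, p, p),
                alt = paste0(substring(seqc, p, p),
                             paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = "")))
    } else {
      len <- sample(1:6, 1)
      v <- list(pos = p, ref = substring(seqc, p, p + len),
                alt = substring(seqc, p, p))
    }
    vt <- make_variant("contig_1", as.integer(v$pos), v$ref, v$alt)
    got <- classify_coding_effect(vt[1, ], m, sim$genome)$consequence
    expect_equal(got, oracle_indel_consequence(v, m),
                 label = sprintf("indel %s:%d", m$gene_id, v$pos))
  }
})

test_that("annotate_callset populates consequence exactly for exonic variants", {
  empty <- make_variant(character(0), integer(0), character(0), character(0))
  cfg <- simulation_config(seed = 33, n_genes = 6, n_lines = 4,
                           genome_length = 30000)
  sim <- simulate_genome(cfg, tempfile("ac"))
  expect_equal(nrow(annotate_callset(empty, sim$models, sim$genome)), 0L)

  set.seed(12)
  pos <- sort(sample.int(29000L, 800L))
  seqc <- as.character(sim$genome[[1]])
  ref <- substring(seqc, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  ann <- annotate_callset(make_variant("contig_1", pos, ref, alt),
                          sim$models, sim$genome)
  expect_equal(is.na(ann$consequence), ann$region != "exonic")
  expect_equal(is.na(ann$gene_id), ann$region == "intergenic")
  # the exonic count partitions into the consequence subtypes
  ex <- ann[ann$region == "exonic", ]
  expect_equal(nrow(ex), sum(table(ex$consequence)))
})
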