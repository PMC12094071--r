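test_that("GenBank coordinates convert to 0-based half-open records", {
  gb <- tiny_genbank(c("     gene            101..200",
                       "                     /locus_tag=\"g1\"",
                       "     CDS             101..200",
                       "                     /locus_tag=\"g1\"",
                       "     gene            complement(251..320)",
                       "                     /locus_tag=\"g2\"",
                       "     tRNA            complement(251..320)",
                       "                     /locus_tag=\"g2\""))
  ann <- parse_genbank(gb)
  expect_equal(ann$genes$start, c(100L, 250L))
  expect_equal(ann$genes$end, c(200L, 320L))
  expect_equal(ann$genes$strand, c("+", "-"))
  expect_equal(ann$genes$feature_class, c("CDS", "tRNA"))
  expect_equal(ann$genes$genome_index, 1:2)
})

test_that("parser rejects degenerate or malformed input", {
  expect_error(parse_genbank(tiny_genbank(character())), "empty genome")
  expect_error(parse_genbank(tiny_genbank(
    c("     gene            join(1..10,20..30)",
      "                     /locus_tag=\"g1\""))), "not supported")
  expect_error(parse_genbank(c("LOCUS x", "ORIGIN", "//")), "FEATURES")
})

test_that("synthetic genomes round-trip through the parser with their gaps", {
  spec <- genome_spec(n_genes = 5, gap_lengths = c(70, 95, 130, 160),
                      seed = 21)
  gen <- generate_genome(spec)
  ann <- parse_genbank(gen$genbank)
  expect_equal(nrow(ann$genes), 5L)
  expect_equal(ann$genes, gen$genes)
  observed_gaps <- ann$genes$start[-1] - ann$genes$end[-5]
  expect_equal(observed_gaps, c(70L, 95L, 130L, 160L))
  expect_identical(ann$sequence, gen$sequence)
})

test_that("upstream regions follow strand, with orientation and overlap flags", {
  # two tandem + genes, 80 bp gap
  lay <- random_layout(2, seed = 1)
  lay$genes$strand <- c("+", "+")
  lay$genes$start <- c(100L, 230L); lay$genes$end <- c(150L, 280L)
  cand <- extract_candidate_utrs(lay$genes, lay$genome)
  expect_equal(cand$length[2], 80L)
  expect_equal(cand$sequence[2], substr(lay$genome, 151, 230))
  expect_false(any(unlist(flag_cols(cand[2, ]))))

  # divergent pair: <- gene, gap, gene -> : both flagged opposing
  lay$genes$strand <- c("-", "+")
  cand <- extract_candidate_utrs(lay$genes, lay$genome)
  expect_true(all(cand$flag_opposing_orientation))
  # the minus gene's candidate is the reverse complement of the shared gap
  expect_equal(cand$sequence[1], oracle_revcomp(substr(lay$genome, 151, 230)))

  # overlapping tandem genes
  lay$genes$strand <- c("+", "+")
  lay$genes$start <- c(100L, 140L); lay$genes$end <- c(150L, 200L)
  cand <- extract_candidate_utrs(lay$genes, lay$genome)
  expect_true(cand$flag_overlap[2])
  expect_identical(cand$sequence[2], "")

  expect_error(extract_candidate_utrs(
    data.frame(gene_id = "g", start = 0L, end = 10000L, strand = "+",
               feature_class = "CDS", genome_index = 1L),
    "ACGT"), "outside")
})

test_that("extraction matches the brute-force neighbour-slice oracle", {
  for (seed in c(3, 17, 42)) {
    lay <- random_layout(n_genes = sample(5:50, 1), seed = seed)
    cand <- extract_candidate_utrs(lay$genes, lay$genome)
    orc <- oracle_candidates(lay$genes, lay$genome)
    expect_equal(cand$sequence, orc$sequence)
    expect_equal(cand$length, orc$length)
    expect_equal(cand$flag_opposing_orientation, orc$opposing)
    expect_equal(cand$flag_overlap, orc$overlap)
  }
})

test_that("mining is symmetric under reverse-complementing the genome", {
  lay <- random_layout(12, seed = 9)
  cand <- extract_candidate_utrs(lay$genes, lay$genome)
  L <- nchar(lay$genome)
  flipped <- data.frame(gene_id = rev(lay$genes$gene_id),
                        start = rev(L - lay$genes$end),
                        end = rev(L - lay$genes$start),
                        strand = rev(ifelse(lay$genes$strand == "+", "-", "+")),
                        feature_class = "CDS",
                        genome_index = seq_len(nrow(lay$genes)),
                        stringsAsFactors = FALSE)
  cand2 <- extract_candidate_utrs(flipped, oracle_revcomp(lay$genome))
  m <- match(cand$gene_id, cand2$gene_id)
  expect_equal(cand2$sequence[m], cand$sequence)
  expect_equal(cand2$flag_opposing_orientation[m],
               cand$flag_opposing_orientation)
  expect_equal(cand2$flag_overlap[m], cand$flag_overlap)
})

test_that("length filter keeps 60-170 inclusive and is idempotent", {
  cand <- generate_candidate_set(4, seed = 1)
  cand$length <- c(59L, 60L, 170L, 171L)
  f1 <- filter_by_length(cand)
  expect_equal(f1$flag_too_short, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(f1$flag_too_long, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(filter_by_length(f1), f1)
})

test_that("transcriptome merge flags absent genes and attaches counts", {
  cand <- generate_candidate_set(3, seed = 2)
  counts <- data.frame(gene_id = c("SYN_0001", "SYN_0003"),
                       est_counts = c(1234, 7))
  f <- filter_by_transcriptome(cand, counts)
  expect_equal(f$read_count, c(1234, NA, 7))
  expect_equal(f$flag_no_transcript, c(FALSE, TRUE, FALSE))
  expect_identical(filter_by_transcriptome(f, counts), f)
  dup <- rbind(counts, counts[1, ])
  expect_error(filter_by_transcriptome(cand, dup), "duplicate")
})

test_that("restriction scan finds sites on both strands at 1-based positions", {
  hit <- scan_restriction_sites("AAGGTCTCAA")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$enzyme, "BsaI")
  expect_equal(hit$position, 3L)
  expect_equal(hit$strand, "+")

  hit <- scan_restriction_sites("AAGAGACCAA")   # revcomp of GGTCTC
  expect_equal(hit$enzyme, "BsaI")
  expect_equal(hit$strand, "-")
  expect_equal(hit$position, 3L)

  expect_equal(nrow(scan_restriction_sites("ATATATATAT")), 0L)
  expect_error(scan_restriction_sites("ACGTN"), "alphabet")
})

test_that("restriction hits reflect coordinates under reverse complement", {
  set.seed(5)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    s <- paste0(substr(s, 1, 50), "GGTCTC", substr(s, 57, 200), "GAAGAC",
                substr(s, 207, 300))
    fwd <- scan_restriction_sites(s)
    rev <- scan_restriction_sites(oracle_revcomp(s))
    L <- nchar(s)
    mapped <- data.frame(enzyme = rev$enzyme,
                         position = L - rev$position - 4L,
                         strand = ifelse(rev$strand == "+", "-", "+"))
    o1 <- fwd[order(fwd$position, fwd$enzyme, fwd$strand), ]
    o2 <- mapped[order(mapped$position, mapped$enzyme, mapped$strand), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2)
  }
})

test_that("candidates with a planted site get the restriction flag", {
  spec <- genome_spec(n_genes = 3, gap_lengths = c(100, 100),
                      planted_sites = data.frame(gap = 1, enzyme = "BsaI"),
                      seed = 4)
  gen <- generate_genome(spec)
  ann <- parse_genbank(gen$genbank)
  cand <- flag_restriction_sites(
    extract_candidate_utrs(ann$genes, ann$sequence))
  expect_equal(cand$flag_restriction_site, gen$truth$flag_restriction_site)
  expect_true(cand$flag_restriction_site[2])   # gene 2's upstream gap
  expect_false(cand$flag_restriction_site[3])
})

test_that("gc_content computes percent G+C and is strand-invariant", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("ATGC"), 50)
  expect_error(gc_content(""), "empty")
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 76, replace = TRUE), collapse = "")
  expect_equal(gc_content(s), gc_content(oracle_revcomp(s)))
})

test_that("motif scanning reports 1-based inclusive spans", {
  motif <- "TTACAAGAAA"
  spec <- genome_spec(n_genes = 2, gap_lengths = 120,
                      planted_motifs = data.frame(gap = 1, motif = motif,
                                                  offset = 20),
                      seed = 6)
  gen <- generate_genome(spec)
  cand <- extract_candidate_utrs(parse_genbank(gen$genbank)$genes,
                                 gen$sequence)
  span <- find_motif(cand$sequence[2], motif)
  expect_equal(span$start, 20L)
  expect_equal(span$end, 29L)
  expect_equal(span$end - span$start + 1L, nchar(motif))
  expect_equal(nrow(find_motif("ACGTACGT", "TTT")), 0L)
  expect_equal(nrow(find_motif("ACG", "ACGTACGT")), 0L)
})

test_that("surviving() and the attrition table agree on conservation", {
  spec <- genome_spec(n_genes = 20,
                      gap_lengths = rep(c(59, 80, 171, 100), 5)[1:19],
                      strand_pattern = c(rep("+", 15), rep("-", 5)),
                      seed = 30)
  gen <- generate_genome(spec)
  ann <- parse_genbank(gen$genbank)
  cand <- extract_candidate_utrs(ann$genes, ann$sequence)
  cand <- filter_by_length(cand)
  cand <- filter_by_transcriptome(
    cand, generate_counts(ann$genes$gene_id, decades = 2, per_decade_n = 15,
                          seed = 31))
  cand <- flag_restriction_sites(cand)
  att <- attrition_table(cand)
  expect_equal(nrow(att), nrow(cand))          # nothing destroyed
  expect_equal(sum(att$surviving), nrow(surviving(cand)))
  expect_true(all(att$surviving == (att$n_flags == 0)))
})
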