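# Independent oracles used to freeze expected values. These deliberately do
# not call into the package's extraction/scanning code paths.

# reverse complement via chartr, independent of Biostrings
oracle_revcomp <- function(s) {
  if (nchar(s) == 0) return(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Brute-force upstream-region scan: for every gene, slice the genome directly
# between the neighbour coordinates given by the documented convention.
oracle_candidates <- function(genes, genome_seq) {
  L <- nchar(genome_seq)
  n <- nrow(genes)
  out <- list()
  for (i in seq_len(n)) {
    g <- genes[i, ]
    if (g$strand == "+") {
      lo <- if (i > 1) genes$end[i - 1] else 0L
      hi <- g$start
      up <- if (i > 1) i - 1 else NA
      s <- if (hi > lo) substr(genome_seq, lo + 1, hi) else ""
    } else {
      lo <- g$end
      hi <- if (i < n) genes$start[i + 1] else L
      up <- if (i < n) i + 1 else NA
      s <- if (hi > lo) substr(genome_seq, lo + 1, hi) else ""
      s <- oracle_revcomp(s)
    }
    out[[i]] <- data.frame(
      gene_id = g$gene_id, sequence = s, length = nchar(s),
      opposing = !is.na(up) && genes$strand[up] != g$strand,
      overlap = hi - lo <= 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# hand GenBank snippet builder for parser tests
tiny_genbank <- function(features, seq = strrep("ACGT", 100)) {
  starts <- seq(1, nchar(seq), by = 60)
  c(sprintf("LOCUS       TEST %d bp DNA linear", nchar(seq)),
    "FEATURES             Location/Qualifiers",
    features,
    "ORIGIN",
    sprintf("%9d %s", starts,
            tolower(substring(seq, starts, pmin(starts + 59, nchar(seq))))),
    "//")
}

# random annotated layout (coordinates only) for oracle-equivalence tests
random_layout <- function(n_genes, L_gene = 50L, seed) {
  set.seed(seed)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  gaps <- sample(c(-10L, 0L, 5L, 40L, 80L, 120L, 200L), n_genes - 1L,
                 replace = TRUE, prob = c(.05, .05, .1, .3, .3, .1, .1))
  starts <- integer(n_genes); ends <- integer(n_genes)
  pos <- 100L
  for (i in seq_len(n_genes)) {
    if (i > 1) pos <- ends[i - 1] + gaps[i - 1]
    starts[i] <- pos; ends[i] <- pos + L_gene
  }
  L <- ends[n_genes] + 100L
  genome <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  list(genes = data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                          start = starts, end = ends, strand = strands,
                          feature_class = "CDS",
                          genome_index = seq_len(n_genes),
                          stringsAsFactors = FALSE),
       genome = genome)
}

flag_cols <- function(df) df[, grep("^flag_", names(df)), drop = FALSE]
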