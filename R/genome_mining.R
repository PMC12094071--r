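#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
NULL

FILTER_FLAGS <- c("opposing_orientation", "overlap", "too_short", "too_long",
                  "no_transcript", "restriction_site")

# Recognition sequences of the type-IIS enzymes screened during library
# design. Hits on either strand disqualify a candidate for Golden Gate.
TYPE_IIS_SITES <- c(BsaI = "GGTCTC", BsmBI = "CGTCTC", BbsI = "GAAGAC")

new_candidate_table <- function(df) {
  for (f in FILTER_FLAGS) {
    col <- paste0("flag_", f)
    if (is.null(df[[col]])) df[[col]] <- logical(nrow(df))
  }
  if (is.null(df$read_count)) df$read_count <- rep(NA_real_, nrow(df))
  rownames(df) <- NULL
  df
}

#' Extract candidate 5' UTRs from a gene annotation
#'
#' For every gene the intergenic region immediately upstream on its coding
#' strand is extracted: for a \code{+} gene the region between the previous
#' gene's end and its start; for a \code{-} gene the region between its end
#' and the next gene's start, reverse-complemented so the candidate reads on
#' the gene's coding strand. Candidates whose upstream flanking gene lies on
#' the opposite strand are flagged \code{opposing_orientation}; candidates
#' whose region has length <= 0 (overlapping neighbours) are flagged
#' \code{overlap} and carry an empty sequence. Flags never remove rows; use
#' \code{\link{surviving}} to select flag-free candidates.
#'
#' @param genes data.frame of gene records as returned by
#'   \code{\link{parse_genbank}} (sorted by \code{genome_index}).
#' @param genome_sequence Replicon sequence as a character string.
#' @param circular If \code{TRUE} the replicon is treated as circular and the
#'   upstream region of a boundary gene wraps around the origin. Default
#'   linear: boundary genes take the region up to the replicon edge.
#' @param id_prefix Prefix for generated candidate identifiers.
#' @return data.frame with one row per gene: \code{candidate_id},
#'   \code{gene_id}, \code{strand}, \code{sequence}, \code{length},
#'   \code{upstream_gene_id}, \code{upstream_strand}, \code{read_count} and
#'   one logical \code{flag_*} column per filter.
#' @export
extract_candidate_utrs <- function(genes, genome_sequence, circular = FALSE,
                                   id_prefix = "CPL") {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1L)
  if (is.unsorted(genes$genome_index)) {
    stop("genes must be sorted by genome_index", call. = FALSE)
  }
  L <- nchar(genome_sequence)
  if (any(genes$start < 0L) || any(genes$end > L)) {
    stop("gene coordinates fall outside the genome sequence", call. = FALSE)
  }
  n <- nrow(genes)

  slice <- function(from0, to0) {
    # 0-based half-open [from0, to0); wrapping handled by caller
    if (to0 <= from0) return("")
    substr(genome_sequence, from0 + 1L, to0)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    if (g$strand == "+") {
      up <- if (i > 1L) genes[i - 1L, ] else NULL
      if (!is.null(up)) {
        gap <- g$start - up$end
        seqv <- slice(up$end, g$start)
      } else if (circular && n > 1L) {
        up <- genes[n, ]
        gap <- g$start + (L - up$end)
        seqv <- paste0(slice(up$end, L), slice(0L, g$start))
      } else {
        gap <- g$start
        seqv <- slice(0L, g$start)
      }
    } else {
      up <- if (i < n) genes[i + 1L, ] else NULL
      if (!is.null(up)) {
        gap <- up$start - g$end
        seqv <- slice(g$end, up$start)
      } else if (circular && n > 1L) {
        up <- genes[1L, ]
        gap <- (L - g$end) + up$start
        seqv <- paste0(slice(g$end, L), slice(0L, up$start))
      } else {
        gap <- L - g$end
        seqv <- slice(g$end, L)
      }
      seqv <- revcomp(seqv)
    }
    overlap <- gap <= 0L
    if (overlap) seqv <- ""
    opposing <- !is.null(up) && up$strand != g$strand
    rows[[i]] <- data.frame(
      candidate_id = sprintf("%s%04d", id_prefix, i),
      gene_id = g$gene_id,
      strand = g$strand,
      sequence = seqv,
      length = nchar(seqv),
      upstream_gene_id = if (is.null(up)) NA_character_ else up$gene_id,
      upstream_strand = if (is.null(up)) NA_character_ else up$strand,
      flag_opposing_orientation = opposing,
      flag_overlap = overlap,
      stringsAsFactors = FALSE)
  }
  new_candidate_table(do.call(rbind, rows))
}

#' Flag candidates outside the accepted 5' UTR length range
#'
#' Lengths strictly below \code{min_len} are flagged \code{too_short},
#' strictly above \code{max_len} flagged \code{too_long}; the bounds
#' themselves are retained. Re-applying the filter recomputes the same flags
#' (idempotent).
#'
#' @param candidates Candidate table from \code{\link{extract_candidate_utrs}}.
#' @param min_len,max_len Inclusive length bounds in bp (defaults 60 and 170).
#' @return The candidate table with \code{flag_too_short}/\code{flag_too_long}
#'   updated.
#' @export
filter_by_length <- function(candidates, min_len = 60L, max_len = 170L) {
  stopifnot(is.data.frame(candidates), min_len <= max_len)
  candidates$flag_too_short <- candidates$length < min_len
  candidates$flag_too_long <- candidates$length > max_len
  candidates
}

#' Flag candidates without transcriptional evidence and attach read counts
#'
#' Candidates whose downstream gene is absent from the count table are
#' flagged \code{no_transcript}; present candidates get their read count
#' attached. Because tRNA/rRNA genes are not part of an mRNA-seq count table,
#' this same mechanism removes their upstream regions.
#'
#' @param candidates Candidate table.
#' @param counts Either a named numeric vector (names = gene ids) or a
#'   two-column data.frame \code{(gene_id, est_counts)} as read by
#'   \code{\link{read_count_table}}.
#' @return Candidate table with \code{read_count} and
#'   \code{flag_no_transcript} set.
#' @export
filter_by_transcriptome <- function(candidates, counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(as.numeric(counts[[2]]), as.character(counts[[1]]))
  }
  if (anyDuplicated(names(counts))) {
    stop("duplicate gene_id in count table: ",
         names(counts)[duplicated(names(counts))][1], call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  hit <- candidates$gene_id %in% names(counts)
  candidates$read_count <- ifelse(hit, counts[candidates$gene_id], NA_real_)
  candidates$flag_no_transcript <- !hit
  candidates
}

#' Scan a sequence for type-IIS restriction sites
#'
#' Reports every occurrence of the BsaI (GGTCTC), BsmBI (CGTCTC) and BbsI
#' (GAAGAC) recognition sequences on both strands; minus-strand hits are
#' occurrences of the reverse complement, positioned by the 1-based start of
#' the match on the given strand. Both strands are screened because type-IIS
#' enzymes cut regardless of site orientation during Golden Gate assembly.
#'
#' @param sequence Character string over \{A,C,G,T\}.
#' @return data.frame with columns \code{enzyme}, \code{position} (1-based
#'   start of the 6-mer on the given sequence) and \code{strand}.
#' @examples
#' scan_restriction_sites("AAGGTCTCAA")  # one BsaI hit at position 3
#' @export
scan_restriction_sites <- function(sequence) {
  assert_dna(sequence)
  if (nchar(sequence) < 6L) {
    return(data.frame(enzyme = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  subj <- Biostrings::DNAString(sequence)
  res <- list()
  for (enz in names(TYPE_IIS_SITES)) {
    site <- TYPE_IIS_SITES[[enz]]
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(site), subj)
    rev <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(site)), subj)
    if (length(fwd)) {
      res[[length(res) + 1L]] <- data.frame(
        enzyme = enz, position = BiocGenerics::start(fwd), strand = "+",
        stringsAsFactors = FALSE)
    }
    if (length(rev)) {
      res[[length(res) + 1L]] <- data.frame(
        enzyme = enz, position = BiocGenerics::start(rev), strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(enzyme = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$position, out$enzyme), , drop = FALSE]
}

#' Flag candidates carrying a type-IIS restriction site
#'
#' @param candidates Candidate table.
#' @return Candidate table with \code{flag_restriction_site} updated; empty
#'   sequences (overlap candidates) trivially carry no site.
#' @export
flag_restriction_sites <- function(candidates) {
  candidates$flag_restriction_site <- vapply(candidates$sequence, function(s) {
    if (nchar(s) == 0L) return(FALSE)
    nrow(scan_restriction_sites(s)) > 0L
  }, logical(1), USE.NAMES = FALSE)
  candidates
}

#' GC content of a sequence in percent
#'
#' @param sequence Nonempty character string over \{A,C,G,T\}.
#' @param digits Rounding for display; \code{NULL} returns the exact value.
#' @return 100 * (#G + #C) / length.
#' @export
gc_content <- function(sequence, digits = NULL) {
  assert_dna(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pct <- 100 * sum(chars %in% c("G", "C")) / length(chars)
  if (is.null(digits)) pct else round(pct, digits)
}

#' Locate exact occurrences of a motif
#'
#' Exact-match scanning (no degeneracy) on the given strand only. Spans are
#' reported as 1-based inclusive positions, the convention used for motif
#' positions such as 20-29 for a 10-mer.
#'
#' @param sequence Subject sequence.
#' @param motif Nonempty query; if longer than the sequence the result is
#'   empty.
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive; \code{end - start + 1 == nchar(motif)}).
#' @export
find_motif <- function(sequence, motif) {
  assert_dna(sequence)
  assert_dna(motif, "motif")
  if (nchar(motif) == 0L) stop("motif must be nonempty", call. = FALSE)
  if (nchar(motif) > nchar(sequence)) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                Biostrings::DNAString(sequence))
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
}

#' Select candidates that survived every filter
#'
#' Filters never delete rows, so attrition stays auditable; this view returns
#' the flag-free records that feed library design.
#'
#' @param candidates Candidate table.
#' @return Subset of rows whose filter flags are all \code{FALSE}.
#' @export
surviving <- function(candidates) {
  flags <- as.matrix(candidates[, paste0("flag_", FILTER_FLAGS), drop = FALSE])
  out <- candidates[rowSums(flags) == 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-candidate attrition table
#'
#' @param candidates Candidate table.
#' @return data.frame with one row per candidate, one logical column per
#'   filter flag and a final \code{surviving} column.
#' @export
attrition_table <- function(candidates) {
  cols <- c("candidate_id", "gene_id", "length", "read_count",
            paste0("flag_", FILTER_FLAGS))
  out <- candidates[, cols, drop = FALSE]
  flags <- as.matrix(candidates[, paste0("flag_", FILTER_FLAGS), drop = FALSE])
  out$n_flags <- rowSums(flags)
  out$surviving <- out$n_flags == 0L
  out
}
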