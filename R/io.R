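# Tabular and sequence IO: plain TSV via utils, FASTA via Biostrings.

#' Read a two-column read-count table
#'
#' @param path TSV with columns \code{gene_id} and \code{est_counts}
#'   (header optional; the first two columns are used).
#' @return data.frame \code{(gene_id, est_counts)}.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "est_counts") %in% names(df))) {
    names(df)[1:2] <- c("gene_id", "est_counts")
  }
  df[, c("gene_id", "est_counts")]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write candidates as FASTA with flag-bearing headers
#'
#' Headers carry the downstream gene, length and any filter flags, so the
#' file doubles as a human-readable audit trail. Overlap candidates have an
#' empty sequence and are skipped (FASTA cannot hold empty records).
#'
#' @param candidates Candidate table.
#' @param path Output file.
#' @export
write_candidate_fasta <- function(candidates, path) {
  keep <- nchar(candidates$sequence) > 0L
  cand <- candidates[keep, , drop = FALSE]
  flags <- apply(cand[, paste0("flag_", FILTER_FLAGS), drop = FALSE], 1,
                 function(r) paste(FILTER_FLAGS[as.logical(r)], collapse = ","))
  headers <- sprintf("%s gene=%s length=%d flags=%s", cand$candidate_id,
                     cand$gene_id, cand$length,
                     ifelse(nchar(flags) > 0L, flags, "none"))
  seqs <- Biostrings::DNAStringSet(cand$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Write the synthesis order sheet and oligo FASTA
#'
#' @param order_sheet Output of \code{\link{design_library}}.
#' @param tsv_path,fasta_path Output files (either may be \code{NULL}).
#' @export
write_order_sheet <- function(order_sheet, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path)) write_tsv(order_sheet, tsv_path)
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(order_sheet$oligo)
    names(seqs) <- order_sheet$candidate_id
    Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  }
  invisible(order_sheet)
}

#' Read a long-format plate-reader table
#'
#' @param path TSV with columns \code{well}, \code{strain}, \code{time_h},
#'   \code{od600}, \code{mcherry}, \code{gfp}.
#' @export
read_plate_table <- function(path) read_tsv(path)

#' Read a well map (well, role, strain)
#' @param path TSV path.
#' @export
read_well_map <- function(path) {
  wm <- read_tsv(path)
  if (!all(c("well", "role", "strain") %in% names(wm))) {
    stop("well map ", path, " must have columns well, role, strain",
         call. = FALSE)
  }
  wm
}
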