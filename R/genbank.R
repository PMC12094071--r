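#' Parse an annotated genome from a GenBank flat file
#'
#' Reads a GenBank record and returns the gene annotation together with the
#' replicon sequence. Only the information the mining pipeline needs is kept:
#' one row per feature labelled \code{gene}, in genome order, with coordinates
#' converted from GenBank 1-based inclusive to internal 0-based half-open
#' (\code{start} points at the first base, \code{end} one past the last).
#' The feature class (CDS, tRNA, rRNA) is resolved by matching the gene's
#' locus tag against sibling CDS/tRNA/rRNA features.
#'
#' @param x Path to a GenBank flat file, or a character vector of its lines.
#' @return An object of class \code{genome_annotation}: a list with
#'   \item{genes}{data.frame with columns \code{gene_id}, \code{start},
#'     \code{end}, \code{strand}, \code{feature_class}, \code{genome_index}.}
#'   \item{sequence}{the replicon sequence as an uppercase character string.}
#' @examples
#' gb <- generate_genome(genome_spec(n_genes = 4, gap_lengths = c(80, 80, 80)))
#' ann <- parse_genbank(gb$genbank)
#' ann$genes
#' @export
parse_genbank <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(feat_start) != 1L) {
    stop("malformed GenBank: no FEATURES table found", call. = FALSE)
  }
  if (length(origin_start) != 1L) {
    stop("malformed GenBank: no ORIGIN section found", call. = FALSE)
  }

  # ---- sequence -----------------------------------------------------------
  seq_lines <- lines[(origin_start + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))

  # ---- feature table ------------------------------------------------------
  flines <- lines[(feat_start + 1L):(origin_start - 1L)]
  # a new feature starts at indent 5 with a key; continuation/qualifier lines
  # are indented to column 21
  is_feat <- grepl("^ {5}\\S", flines)
  idx <- which(is_feat)
  feats <- list()
  for (k in seq_along(idx)) {
    first <- idx[k]
    last <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
    block <- flines[first:last]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    loc <- sub("^ {5}\\S+\\s+", "", block[1])
    # location may wrap onto continuation lines that are not qualifiers
    cont <- block[-1]
    qual_at <- grep("^\\s+/", cont)
    loc_cont <- if (length(qual_at)) cont[seq_len(min(qual_at) - 1L)] else cont
    loc <- paste0(loc, paste(trimws(loc_cont), collapse = ""))
    quals <- cont[grepl("^\\s+/", cont)]
    tag <- sub('.*/locus_tag="([^"]+)".*', "\\1",
               grep("/locus_tag=", quals, value = TRUE)[1])
    if (length(tag) == 0L || is.na(tag)) tag <- NA_character_
    feats[[k]] <- list(key = key, location = loc, locus_tag = tag)
  }

  parse_location <- function(loc, key, tag) {
    strand <- "+"
    inner <- loc
    if (grepl("^complement\\(", inner)) {
      strand <- "-"
      inner <- sub("^complement\\((.*)\\)$", "\\1", inner)
    }
    if (grepl("join|order", inner)) {
      stop("malformed GenBank: compound location for feature ", key,
           " [", tag %||% "?", "]: '", loc, "' is not supported",
           call. = FALSE)
    }
    m <- regmatches(inner, regexec("^[<>]?([0-9]+)\\.\\.[<>]?([0-9]+)$", inner))[[1]]
    if (length(m) != 3L) {
      stop("malformed GenBank: cannot parse location for feature ", key,
           " [", ifelse(is.na(tag), "?", tag), "]: '", loc, "'",
           call. = FALSE)
    }
    list(start1 = as.integer(m[2]), end1 = as.integer(m[3]), strand = strand)
  }

  keys <- vapply(feats, `[[`, "", "key")
  gene_i <- which(keys == "gene")
  if (length(gene_i) == 0L) {
    stop("empty genome: no features labelled 'gene' in the annotation",
         call. = FALSE)
  }

  # class lookup from CDS/tRNA/rRNA siblings sharing the locus tag
  class_of <- new.env(parent = emptyenv())
  for (f in feats[keys %in% c("CDS", "tRNA", "rRNA")]) {
    if (!is.na(f$locus_tag) && is.null(class_of[[f$locus_tag]])) {
      class_of[[f$locus_tag]] <- f$key
    }
  }

  rows <- lapply(seq_along(gene_i), function(j) {
    f <- feats[[gene_i[j]]]
    loc <- parse_location(f$location, f$key, f$locus_tag)
    gid <- if (is.na(f$locus_tag)) sprintf("gene_%04d", j) else f$locus_tag
    cls <- class_of[[gid]] %||% "other"
    data.frame(gene_id = gid,
               start = loc$start1 - 1L,     # 0-based half-open
               end = loc$end1,
               strand = loc$strand,
               feature_class = cls,
               genome_index = j,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  if (anyDuplicated(genes$gene_id)) {
    stop("malformed GenBank: duplicate locus_tag ",
         genes$gene_id[duplicated(genes$gene_id)][1], call. = FALSE)
  }
  if (nchar(sequence) > 0L && any(genes$end > nchar(sequence))) {
    bad <- genes$gene_id[genes$end > nchar(sequence)][1]
    stop("feature ", bad, " extends beyond the replicon sequence",
         call. = FALSE)
  }
  structure(list(genes = genes, sequence = sequence),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      nchar(x$sequence), "bp replicon\n")
  invisible(x)
}

# Serialize a minimal, parseable GenBank record (used by the generator).
format_genbank <- function(name, sequence, genes) {
  n <- nchar(sequence)
  out <- c(
    sprintf("LOCUS       %-16s %9d bp    DNA     linear   BCT 01-JAN-2025",
            name, n),
    "DEFINITION  Synthetic replicon (generated fixture).",
    sprintf("ACCESSION   %s", name),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    loc <- sprintf("%d..%d", g$start + 1L, g$end)
    if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (g$feature_class %in% c("tRNA", "rRNA")) g$feature_class else "CDS"
    out <- c(out,
             sprintf("     gene            %s", loc),
             sprintf("                     /locus_tag=\"%s\"", g$gene_id),
             sprintf("     %-15s %s", key, loc),
             sprintf("                     /locus_tag=\"%s\"", g$gene_id))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(sequence, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")))
  }
  c(out, "//")
}
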