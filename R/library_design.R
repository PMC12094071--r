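#' Selection plan for the two-tranche library pick
#'
#' The synthesis order is capped (default 500 sequences). Tranche 1 takes the
#' \code{tranche1_size} shortest surviving candidates, which by construction
#' contains every candidate already at or below the \code{tranche1_max_len}
#' insert length whenever they number no more than the tranche. The remaining
#' candidates are binned by the order of magnitude of their RNA-seq read
#' count and the \code{per_decade} highest-count candidates of each decade
#' are added, covering the expression range, until the cap is reached.
#'
#' @param cap Maximum library size.
#' @param tranche1_size Number of shortest candidates taken first.
#' @param tranche1_max_len Insert length (bp) that tranche 1 is meant to
#'   cover without trimming.
#' @param per_decade Candidates taken per read-count order of magnitude.
#' @return A \code{selection_plan} list.
#' @export
selection_plan <- function(cap = 500L, tranche1_size = 350L,
                           tranche1_max_len = 98L, per_decade = 50L) {
  stopifnot(cap >= 1L, tranche1_size >= 0L, per_decade >= 0L)
  structure(list(cap = as.integer(cap),
                 tranche1_size = as.integer(tranche1_size),
                 tranche1_max_len = as.integer(tranche1_max_len),
                 per_decade = as.integer(per_decade)),
            class = "selection_plan")
}

# Order-of-magnitude bin of a read count: floor(log10(count)) for count >= 1,
# -1 for counts in (0,1); counts of exactly zero carry no magnitude and are
# excluded from decade ranking.
decade_bin <- function(count) {
  ifelse(is.na(count) | count <= 0, NA_real_,
         ifelse(count < 1, -1, floor(log10(count))))
}

#' Select candidates for synthesis by the two-tranche rule
#'
#' Deterministic given the candidate set: ties in length or read count are
#' broken by \code{gene_id} lexicographic order. Raising the cap never
#' removes a previously selected candidate (the ordered selection list is
#' simply truncated at the cap).
#'
#' @param candidates Surviving candidate table (every row needs
#'   \code{length} and \code{read_count}).
#' @param plan A \code{\link{selection_plan}}.
#' @return The selected rows, in selection order, with an added
#'   \code{tranche} column (1 = shortest-first, 2 = per-decade pick).
#' @export
select_candidates <- function(candidates, plan = selection_plan()) {
  stopifnot(inherits(plan, "selection_plan"))
  n <- nrow(candidates)
  if (n == 0L) stop("empty candidate set: nothing to select", call. = FALSE)
  if (any(is.na(candidates$length))) {
    stop("every candidate needs a length", call. = FALSE)
  }

  ord <- order(candidates$length, candidates$gene_id)
  t1 <- ord[seq_len(min(plan$tranche1_size, n))]

  rest <- setdiff(ord, t1)
  t2 <- integer(0)
  if (length(rest)) {
    bins <- decade_bin(candidates$read_count[rest])
    for (d in sort(unique(bins[!is.na(bins)]), decreasing = TRUE)) {
      members <- rest[!is.na(bins) & bins == d]
      mo <- members[order(-candidates$read_count[members],
                          candidates$gene_id[members])]
      t2 <- c(t2, utils::head(mo, plan$per_decade))
    }
  }

  pick <- utils::head(c(t1, t2), plan$cap)
  if (length(pick) < plan$cap) {
    warning("selection shortfall: only ", length(pick),
            " candidates available for a cap of ", plan$cap, call. = FALSE)
  }
  out <- candidates[pick, , drop = FALSE]
  out$tranche <- ifelse(seq_along(pick) <= length(t1), 1L, 2L)
  rownames(out) <- NULL
  out
}

#' Trim a candidate to the insert length from its 5' end
#'
#' Sequences longer than \code{target_len} keep their 3'-most
#' \code{target_len} bases — the bases nearest the start codon, where the
#' ribosome-binding site lives. Shorter sequences pass unchanged (padding is
#' the oligo builder's job, outside the cloned insert).
#'
#' @param sequence Candidate sequence on the coding strand.
#' @param target_len Maximum insert length in bp (default 98).
#' @return The trimmed sequence.
#' @export
trim_to_insert <- function(sequence, target_len = 98L) {
  assert_dna(sequence)
  n <- nchar(sequence)
  if (n <= target_len) return(sequence)
  substr(sequence, n - target_len + 1L, n)
}

#' Default Golden Gate flank sequences
#'
#' Documented placeholder flanks with correct BsaI geometry: the left flank
#' carries a forward BsaI recognition site (GGTCTC), one spacer base and a
#' 4-nt fusion overhang; the right flank mirrors it with the overhang, a
#' spacer and the reverse-complement site (GAGACC), so both cuts point into
#' the insert. Real designs substitute the overhangs dictated by the entry
#' vector.
#'
#' @return Named list with \code{left} and \code{right} character strings.
#' @export
default_flanks <- function() {
  list(left = "GGTCTCTAATG",   # GGTCTC + N + AATG overhang
       right = "GCTTAGAGACC")  # GCTT overhang + N + revcomp(GGTCTC)
}

# fast both-strand site counter for the pad-redraw screen; lookahead counts
# overlapping occurrences, matching what scan_restriction_sites reports
count_type_iis <- function(sequence) {
  if (nchar(sequence) < 6L) return(0L)
  pats <- c(TYPE_IIS_SITES, vapply(TYPE_IIS_SITES, revcomp, character(1)))
  sum(vapply(pats, function(p) {
    m <- gregexpr(paste0("(?=", p, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1)))
}

#' Assemble a synthesis oligo of fixed total length
#'
#' Concatenates (pad +) left flank + insert + right flank (+ pad) to exactly
#' \code{total_len} bases. Pad bases are drawn uniformly from \{A,C,G,T\} and
#' the whole oligo is rescreened: a draw that would create an extra BsaI,
#' BsmBI or BbsI site anywhere (including across junctions) is rejected and
#' redrawn, up to \code{max_redraw} times. The pad sits outside the
#' restriction sites, by default on the outermost 5' end, so it is never
#' cloned.
#'
#' @param insert Trimmed insert sequence; must be free of internal type-IIS
#'   sites.
#' @param flanks List with \code{left} and \code{right} flank sequences
#'   (see \code{\link{default_flanks}}).
#' @param total_len Required oligo length (default 150).
#' @param pad_side \code{"5p"} (default) or \code{"3p"}.
#' @param seed Optional integer seed making the pad reproducible.
#' @param max_redraw Redraw budget for the restriction-site screen.
#' @param strict_junctions If \code{TRUE}, error when the fixed flank-insert
#'   junctions themselves form a type-IIS site (the default mirrors the
#'   screen of the mined sequences only: junction sites are tolerated, pad
#'   draws may never add one).
#' @return List of class \code{oligo_design}: \code{insert}, \code{left_flank},
#'   \code{right_flank}, \code{pad}, \code{oligo}, \code{seed}.
#' @export
build_oligo <- function(insert, flanks = default_flanks(), total_len = 150L,
                        pad_side = c("5p", "3p"), seed = NULL,
                        max_redraw = 100L, strict_junctions = FALSE) {
  pad_side <- match.arg(pad_side)
  assert_dna(insert, "insert")
  assert_dna(flanks$left, "left flank")
  assert_dna(flanks$right, "right flank")
  if (count_type_iis(insert) > 0L) {
    stop("insert contains a type-IIS restriction site; it must be filtered out",
         call. = FALSE)
  }
  core <- paste0(flanks$left, insert, flanks$right)
  pad_len <- total_len - nchar(core)
  if (pad_len < 0L) {
    stop("design infeasible: insert plus flanks exceed the total oligo length (",
         nchar(core), " > ", total_len, ")", call. = FALSE)
  }
  baseline <- count_type_iis(core)
  if (strict_junctions) {
    flank_only <- count_type_iis(flanks$left) + count_type_iis(flanks$right)
    if (baseline > flank_only) {
      stop("design infeasible: a flank-insert junction forms a type-IIS site",
           call. = FALSE)
    }
  }

  draw <- function() {
    paste(sample(c("A", "C", "G", "T"), pad_len, replace = TRUE),
          collapse = "")
  }
  assemble <- function(pad) {
    if (pad_side == "5p") paste0(pad, core) else paste0(core, pad)
  }

  result <- with_seed(seed, {
    pad <- ""
    oligo <- assemble(pad)
    if (pad_len > 0L) {
      ok <- FALSE
      for (try in seq_len(max_redraw)) {
        pad <- draw()
        oligo <- assemble(pad)
        if (count_type_iis(oligo) == baseline) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not draw a pad free of new restriction sites within ",
             max_redraw, " attempts", call. = FALSE)
      }
    }
    list(pad = pad, oligo = oligo)
  })

  structure(list(insert = insert, left_flank = flanks$left,
                 right_flank = flanks$right, pad = result$pad,
                 oligo = result$oligo, seed = seed),
            class = "oligo_design")
}

#' Design the synthesis library for a selected candidate set
#'
#' Trims every selected candidate to the insert length and assembles one
#' fixed-length oligo each. Per-candidate pad seeds are derived
#' deterministically from the library seed so reruns are byte-identical.
#'
#' @param selected Output of \code{\link{select_candidates}}.
#' @param flanks,total_len,target_len,pad_side See \code{\link{build_oligo}}
#'   and \code{\link{trim_to_insert}}.
#' @param seed Integer library seed.
#' @return data.frame (order sheet): \code{candidate_id}, \code{gene_id},
#'   \code{pre_trim_length}, \code{insert}, \code{insert_length}, \code{pad},
#'   \code{pad_length}, \code{oligo}, \code{oligo_length}, \code{seed}.
#' @export
design_library <- function(selected, flanks = default_flanks(),
                           total_len = 150L, target_len = 98L,
                           pad_side = "5p", seed = 1L) {
  if (nrow(selected) == 0L) {
    stop("empty library: no selected candidates to design", call. = FALSE)
  }
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max - 1L, nrow(selected)))
  rows <- lapply(seq_len(nrow(selected)), function(i) {
    s <- selected[i, ]
    insert <- trim_to_insert(s$sequence, target_len)
    d <- build_oligo(insert, flanks = flanks, total_len = total_len,
                     pad_side = pad_side, seed = seeds[i])
    data.frame(candidate_id = s$candidate_id, gene_id = s$gene_id,
               pre_trim_length = nchar(s$sequence), insert = d$insert,
               insert_length = nchar(d$insert), pad = d$pad,
               pad_length = nchar(d$pad), oligo = d$oligo,
               oligo_length = nchar(d$oligo), seed = seeds[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "library_seed") <- seed
  out
}
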