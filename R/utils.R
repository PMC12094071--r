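# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps library design and the generators pure
# functions of their seed without clobbering user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

assert_dna <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop(what, " contains characters outside {A,C,G,T}: unsupported alphabet",
         call. = FALSE)
  }
  invisible(sequence)
}

revcomp <- function(sequence) {
  if (nchar(sequence) == 0L) return(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
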