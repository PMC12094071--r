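# Seeded generators producing every input the pipeline consumes, each with a
# ground-truth table computed from the generator's own layout (never by
# running the pipeline), so round-trip tests are meaningful.

# independent site screen used only for ground truth (plain substring match)
gt_has_type_iis <- function(sequence) {
  pats <- c(TYPE_IIS_SITES,
            vapply(TYPE_IIS_SITES, revcomp, character(1)))
  any(vapply(pats, function(p) grepl(p, sequence, fixed = TRUE), logical(1)))
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# draw an intergenic spacer free of type-IIS sites unless one is planted
clean_random_dna <- function(n, max_try = 50L) {
  for (i in seq_len(max_try)) {
    s <- random_dna(n)
    if (!gt_has_type_iis(s)) return(s)
  }
  stop("failed to draw a restriction-free spacer of length ", n, call. = FALSE)
}

#' Specification of a synthetic annotated genome
#'
#' Describes a linear replicon of \code{n_genes} genes laid out left to
#' right, separated by intergenic gaps of the given lengths (a gap of 0
#' or a negative value makes the neighbours overlap). Restriction sites and
#' motifs can be planted into specific gaps at recorded positions so their
#' recovery is testable.
#'
#' @param n_genes Number of genes.
#' @param gap_lengths Integer vector of the \code{n_genes - 1} intergenic
#'   gap lengths (bp); recycled if shorter.
#' @param gene_length Length of every gene body (bp).
#' @param strand_pattern Character vector over \{"+","-"\} of length
#'   \code{n_genes} (recycled).
#' @param lead_length,tail_length Unannotated sequence before the first and
#'   after the last gene.
#' @param trna_rrna Indices of genes annotated as tRNA (they are absent from
#'   mRNA count tables).
#' @param planted_sites data.frame \code{(gap, enzyme)}: plant the enzyme's
#'   recognition site in the middle of gap number \code{gap}.
#' @param planted_motifs data.frame \code{(gap, motif, offset)}: plant
#'   \code{motif} at 1-based \code{offset} within the gap.
#' @param seed Integer seed; the realized genome is a pure function of it.
#' @return A \code{genome_spec} list.
#' @export
genome_spec <- function(n_genes, gap_lengths = 100L, gene_length = 900L,
                        strand_pattern = "+", lead_length = 200L,
                        tail_length = 200L, trna_rrna = integer(),
                        planted_sites = NULL, planted_motifs = NULL,
                        seed = 1L) {
  stopifnot(n_genes >= 1L)
  if (length(gap_lengths) > n_genes - 1L) {
    stop("more gap lengths than gaps (n_genes - 1)", call. = FALSE)
  }
  gaps <- if (n_genes > 1L) {
    rep_len(as.integer(gap_lengths), n_genes - 1L)
  } else {
    integer()
  }
  strands <- rep_len(strand_pattern, n_genes)
  if (!all(strands %in% c("+", "-"))) {
    stop("strand_pattern must consist of '+' and '-'", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), gaps = gaps,
                 gene_length = as.integer(gene_length), strands = strands,
                 lead_length = as.integer(lead_length),
                 tail_length = as.integer(tail_length),
                 trna_rrna = as.integer(trna_rrna),
                 planted_sites = planted_sites,
                 planted_motifs = planted_motifs, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic annotated genome with ground truth
#'
#' Realizes a \code{\link{genome_spec}} as a GenBank flat file plus a
#' ground-truth table of every upstream candidate the mining stage should
#' extract, with the flags it should assign. The truth table is computed
#' directly from the generator's layout (gap sequences, strands, planted
#' sites), not by running the extraction code.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @return List with \code{genbank} (character vector of file lines),
#'   \code{sequence}, \code{genes} (the annotation laid down) and
#'   \code{truth} (expected candidate table: sequence, length, flags).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    gaps <- spec$gaps
    gap_seqs <- lapply(gaps, function(g) {
      if (g > 0L) clean_random_dna(g) else ""
    })
    # plant sites/motifs at recorded positions
    plant <- function(gap_seq, insert_seq, offset) {
      if (nchar(insert_seq) + offset - 1L > nchar(gap_seq)) {
        stop("planted element does not fit in its gap", call. = FALSE)
      }
      paste0(substr(gap_seq, 1L, offset - 1L), insert_seq,
             substr(gap_seq, offset + nchar(insert_seq), nchar(gap_seq)))
    }
    if (!is.null(spec$planted_sites)) {
      for (i in seq_len(nrow(spec$planted_sites))) {
        g <- spec$planted_sites$gap[i]
        site <- TYPE_IIS_SITES[[spec$planted_sites$enzyme[i]]]
        off <- max(1L, (nchar(gap_seqs[[g]]) - nchar(site)) %/% 2L)
        gap_seqs[[g]] <- plant(gap_seqs[[g]], site, off)
      }
    }
    motif_truth <- NULL
    if (!is.null(spec$planted_motifs)) {
      for (i in seq_len(nrow(spec$planted_motifs))) {
        g <- spec$planted_motifs$gap[i]
        off <- spec$planted_motifs$offset[i]
        mot <- spec$planted_motifs$motif[i]
        gap_seqs[[g]] <- plant(gap_seqs[[g]], mot, off)
        motif_truth <- rbind(motif_truth,
                             data.frame(gap = g, motif = mot, start = off,
                                        end = off + nchar(mot) - 1L))
      }
    }

    gene_seqs <- replicate(n, random_dna(spec$gene_length))
    lead <- clean_random_dna(spec$lead_length)
    tail_seq <- clean_random_dna(spec$tail_length)

    # lay out coordinates (0-based half-open)
    starts <- integer(n); ends <- integer(n)
    pos <- spec$lead_length
    sequence <- lead
    for (i in seq_len(n)) {
      if (i > 1L) {
        g <- gaps[i - 1L]
        if (g > 0L) {
          sequence <- paste0(sequence, gap_seqs[[i - 1L]])
          pos <- pos + g
        } else {
          # overlap: rewind; the overlapping gene body is shared sequence
          pos <- pos + g
          sequence <- substr(sequence, 1L, pos)
        }
      }
      starts[i] <- pos
      ends[i] <- pos + spec$gene_length
      sequence <- paste0(substr(sequence, 1L, pos), gene_seqs[i])
      pos <- ends[i]
    }
    sequence <- paste0(sequence, tail_seq)

    genes <- data.frame(
      gene_id = sprintf("SYN_%04d", seq_len(n)),
      start = starts, end = ends, strand = spec$strands,
      feature_class = ifelse(seq_len(n) %in% spec$trna_rrna, "tRNA", "CDS"),
      genome_index = seq_len(n), stringsAsFactors = FALSE)

    # ---- ground truth from the layout itself ------------------------------
    truth_rows <- lapply(seq_len(n), function(i) {
      st <- spec$strands[i]
      if (st == "+") {
        up_i <- if (i > 1L) i - 1L else NA_integer_
        gap <- if (i > 1L) gaps[i - 1L] else spec$lead_length
        seqv <- if (i > 1L) {
          if (gap > 0L) gap_seqs[[i - 1L]] else ""
        } else {
          lead
        }
      } else {
        up_i <- if (i < n) i + 1L else NA_integer_
        gap <- if (i < n) gaps[i] else spec$tail_length
        seqv <- if (i < n) {
          if (gap > 0L) gap_seqs[[i]] else ""
        } else {
          tail_seq
        }
        seqv <- revcomp(seqv)
      }
      overlap <- gap <= 0L
      opposing <- !is.na(up_i) && spec$strands[up_i] != st
      data.frame(
        candidate_id = sprintf("CPL%04d", i),
        gene_id = genes$gene_id[i],
        strand = st,
        sequence = seqv,
        length = nchar(seqv),
        upstream_gene_id = if (is.na(up_i)) NA_character_ else genes$gene_id[up_i],
        upstream_strand = if (is.na(up_i)) NA_character_ else spec$strands[up_i],
        flag_opposing_orientation = opposing,
        flag_overlap = overlap,
        flag_too_short = nchar(seqv) < 60L,
        flag_too_long = nchar(seqv) > 170L,
        flag_restriction_site = nchar(seqv) > 0L && gt_has_type_iis(seqv),
        stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, truth_rows)

    list(genbank = format_genbank("SYNREP01", sequence, genes),
         sequence = sequence, genes = genes, truth = truth,
         motif_truth = motif_truth)
  })
}

#' Generate a read-count table spanning several orders of magnitude
#'
#' Assigns \code{per_decade_n} genes to each decade \code{d}, with counts
#' drawn uniformly from \code{[10^d, 10^(d+1))}; any remaining genes (and
#' every gene named in \code{omit}) are left out of the table entirely, so
#' the no-transcript filter has something to catch.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param decades Integer decades to cover (default \code{1:3}).
#' @param per_decade_n Genes per decade.
#' @param omit Gene ids to exclude from the table.
#' @param seed Integer seed.
#' @return data.frame \code{(gene_id, est_counts)}.
#' @export
generate_counts <- function(gene_ids, decades = 1:3, per_decade_n = 50L,
                            omit = character(), seed = 1L) {
  if (!length(decades)) stop("decades must be nonempty", call. = FALSE)
  with_seed(seed, {
    pool <- setdiff(gene_ids, omit)
    need <- length(decades) * per_decade_n
    if (length(pool) < need) {
      stop("not enough genes (", length(pool), ") for ", need, " counts",
           call. = FALSE)
    }
    chosen <- sample(pool, need)
    counts <- unlist(lapply(decades, function(d) {
      stats::runif(per_decade_n, 10^d, 10^(d + 1))
    }))
    data.frame(gene_id = chosen, est_counts = counts,
               stringsAsFactors = FALSE)
  })
}

#' Generate a surviving-candidate table directly
#'
#' Convenience generator for the design stage: random restriction-free
#' candidate sequences with lengths and read counts under full control,
#' shaped like the output of the mining stage after all filters.
#'
#' @param n Number of candidates.
#' @param length_range Inclusive bp range candidate lengths are drawn from.
#' @param decades,per_decade_n Passed to \code{\link{generate_counts}}-style
#'   count drawing: counts are spread evenly over the decades.
#' @param seed Integer seed.
#' @return Candidate table with empty filter flags.
#' @export
generate_candidate_set <- function(n, length_range = c(60L, 170L),
                                   decades = 1:3, seed = 1L) {
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    decs <- rep_len(decades, n)
    counts <- vapply(decs, function(d) stats::runif(1, 10^d, 10^(d + 1)),
                     numeric(1))
    df <- data.frame(
      candidate_id = sprintf("CPL%04d", seq_len(n)),
      gene_id = sprintf("SYN_%04d", seq_len(n)),
      strand = "+",
      sequence = vapply(lens, clean_random_dna, character(1)),
      length = lens,
      upstream_gene_id = NA_character_, upstream_strand = NA_character_,
      read_count = counts, stringsAsFactors = FALSE)
    new_candidate_table(df)
  })
}

#' Specification of one synthetic reporter growth curve
#'
#' Logistic biomass with biomass-proportional GFP, promoter-driven mCherry
#' whose biomass-normalized level moves from
#' \code{true_ratio * stationary_level} in the exponential phase to
#' \code{stationary_level} in the stationary phase, shared linear
#' fluorophore accumulation after the growth plateau (so the mCherry/GFP
#' ratio stays flat in late stationary), additive media background and
#' multiplicative Gaussian noise. With \code{noise_sd = 0} the analytic
#' curves are returned exactly.
#'
#' @param K Carrying capacity (OD600).
#' @param r Logistic growth rate (1/h).
#' @param t0 Inflection time (h) — the true mid-exponential timepoint.
#' @param gfp_per_biomass GFP signal per OD unit (AU/OD).
#' @param true_ratio Ground-truth differential activity
#'   (exponential RFU / stationary RFU); 0 = promoterless strain.
#' @param stationary_level Ground-truth RFU in the stationary phase.
#' @param noise_sd Gaussian noise SD as a fraction of each signal.
#' @param media_od,media_gfp,media_mcherry Media background levels.
#' @param drift_rate Shared fluorophore accumulation per hour after the
#'   growth plateau.
#' @param transition Hours after \code{t0} at which the promoter's activity
#'   starts (first element) and finishes (second) its shift to the
#'   stationary level.
#' @param sampling \code{c(t_start, t_end, dt)} in hours.
#' @param seed Integer seed for the noise stream.
#' @return A \code{curve_spec} list.
#' @export
curve_spec <- function(K = 1.0, r = 0.5, t0 = 10, gfp_per_biomass = 20000,
                       true_ratio = 1.0, stationary_level = 0.1,
                       noise_sd = 0.02, media_od = 0.04, media_gfp = 100,
                       media_mcherry = 50, drift_rate = 0.02,
                       transition = c(2, 6), sampling = c(0, 36, 0.25),
                       seed = 1L) {
  stopifnot(K > 0, r > 0, noise_sd >= 0, transition[2] > transition[1])
  tgrid <- seq(sampling[1], sampling[2], by = sampling[3])
  if (length(tgrid) < 5L) {
    stop("sampling grid must contain at least 5 points", call. = FALSE)
  }
  structure(list(K = K, r = r, t0 = t0, gfp_per_biomass = gfp_per_biomass,
                 true_ratio = true_ratio, stationary_level = stationary_level,
                 noise_sd = noise_sd, media_od = media_od,
                 media_gfp = media_gfp, media_mcherry = media_mcherry,
                 drift_rate = drift_rate, transition = transition,
                 sampling = sampling, seed = as.integer(seed)),
            class = "curve_spec")
}

# analytic pieces of the curve model
logistic_od <- function(t, K, r, t0) K / (1 + exp(-r * (t - t0)))

rfu_profile_true <- function(t, spec) {
  a_s <- spec$stationary_level
  a_e <- spec$true_ratio * a_s
  t1 <- spec$t0 + spec$transition[1]
  t2 <- spec$t0 + spec$transition[2]
  w <- ifelse(t <= t1, 1, ifelse(t >= t2, 0, (t2 - t) / (t2 - t1)))
  a_s + (a_e - a_s) * w
}

#' Generate one strain's plate-reader time series
#'
#' @param spec A \code{\link{curve_spec}}.
#' @return data.frame \code{(time_h, od600, mcherry, gfp)} plus the analytic
#'   media-control levels as attributes.
#' @export
generate_strain_series <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  t <- seq(spec$sampling[1], spec$sampling[2], by = spec$sampling[3])
  od <- logistic_od(t, spec$K, spec$r, spec$t0)
  t_plateau <- spec$t0 + 6 / spec$r            # OD within ~0.25% of K
  drift <- 1 + spec$drift_rate * pmax(0, t - t_plateau)
  biomass_fluor <- spec$gfp_per_biomass * od * drift
  gfp <- biomass_fluor + spec$media_gfp
  mch <- rfu_profile_true(t, spec) * biomass_fluor + spec$media_mcherry
  with_seed(spec$seed, {
    noise <- function(x) x + stats::rnorm(length(x), 0, spec$noise_sd * abs(x))
    data.frame(time_h = t, od600 = noise(od), mcherry = noise(mch),
               gfp = noise(gfp))
  })
}

#' Design table for a synthetic expression cohort
#'
#' Emulates a sorted promoter cohort: a configurable number of active
#' strains per temporal class plus inactive strains whose reporter never
#' leaves the media background. True differential-activity ratios are drawn
#' uniformly inside class-typical bands well clear of the 0.7/1.3
#' thresholds, and stationary expression levels are log-spaced over the
#' two-orders-of-magnitude dynamic range observed for active promoters
#' (strongest first, weakest last).
#'
#' @param n_stationary,n_unbiased,n_exponential Active strains per class.
#' @param n_inactive Strains with no promoter activity.
#' @param ratio_bands Named list of \code{c(lo, hi)} ratio bands per class.
#' @param level_range RFU range (stationary phase) spanned by the active
#'   strains.
#' @param seed Integer seed.
#' @return data.frame \code{(strain, true_class, true_ratio,
#'   stationary_level)}.
#' @export
cohort_design <- function(n_stationary = 12L, n_unbiased = 10L,
                          n_exponential = 3L, n_inactive = 8L,
                          ratio_bands = list(stationary_biased = c(0.35, 0.60),
                                             unbiased = c(0.85, 1.15),
                                             exponential_biased = c(1.5, 2.2)),
                          level_range = c(0.005, 0.61), seed = 1L) {
  with_seed(seed, {
    classes <- c(rep("stationary_biased", n_stationary),
                 rep("unbiased", n_unbiased),
                 rep("exponential_biased", n_exponential))
    ratios <- vapply(classes, function(cl) {
      b <- ratio_bands[[cl]]
      stats::runif(1, b[1], b[2])
    }, numeric(1), USE.NAMES = FALSE)
    n_active <- length(classes)
    levels <- 10^seq(log10(level_range[2]), log10(level_range[1]),
                     length.out = n_active)
    out <- data.frame(
      strain = sprintf("S%03d", seq_len(n_active + n_inactive)),
      true_class = c(classes, rep(NA_character_, n_inactive)),
      true_ratio = c(ratios, rep(0, n_inactive)),
      stationary_level = c(levels, rep(0, n_inactive)),
      stringsAsFactors = FALSE)
    out
  })
}

#' Generate a full plate experiment for a cohort
#'
#' Builds the long-format plate table and well map the analysis stage
#' consumes: replicate wells per strain, media-only control wells, and one
#' reporter-free background strain for the detectability call.
#'
#' @param design Cohort design table (see \code{\link{cohort_design}}).
#' @param n_replicates Wells per strain.
#' @param n_media Media-control wells.
#' @param noise_sd,K,r,t0,gfp_per_biomass,sampling Curve parameters shared
#'   by all strains (see \code{\link{curve_spec}}).
#' @param seed Integer seed.
#' @return List with \code{plate} (long data.frame), \code{well_map} and
#'   \code{truth} (the design table).
#' @export
generate_plate_timeseries <- function(design, n_replicates = 3L, n_media = 3L,
                                      noise_sd = 0.02, K = 1.0, r = 0.5,
                                      t0 = 10, gfp_per_biomass = 20000,
                                      sampling = c(0, 36, 0.25), seed = 1L) {
  strains <- c(design$strain, "background")
  roles <- c(rep("sample", nrow(design)), "background")
  well_no <- 0L
  plate <- list(); map <- list()
  base <- curve_spec(K = K, r = r, t0 = t0, gfp_per_biomass = gfp_per_biomass,
                     noise_sd = noise_sd, sampling = sampling)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      (length(strains)) * n_replicates + n_media))
  si <- 0L
  for (j in seq_along(strains)) {
    sp <- base
    if (roles[j] == "sample") {
      sp$true_ratio <- design$true_ratio[j]
      sp$stationary_level <- design$stationary_level[j]
    } else {
      sp$true_ratio <- 0
      sp$stationary_level <- 0
    }
    for (rep_i in seq_len(n_replicates)) {
      well_no <- well_no + 1L; si <- si + 1L
      sp$seed <- seeds[si]
      ser <- generate_strain_series(sp)
      ser$well <- sprintf("W%03d", well_no)
      ser$strain <- strains[j]
      plate[[length(plate) + 1L]] <- ser
      map[[length(map) + 1L]] <- data.frame(
        well = sprintf("W%03d", well_no), role = roles[j],
        strain = strains[j], stringsAsFactors = FALSE)
    }
  }
  tgrid <- seq(sampling[1], sampling[2], by = sampling[3])
  for (m in seq_len(n_media)) {
    well_no <- well_no + 1L; si <- si + 1L
    med <- with_seed(seeds[si], {
      noise <- function(x) x + stats::rnorm(length(tgrid), 0, noise_sd * abs(x))
      data.frame(time_h = tgrid, od600 = noise(rep(base$media_od, length(tgrid))),
                 mcherry = noise(rep(base$media_mcherry, length(tgrid))),
                 gfp = noise(rep(base$media_gfp, length(tgrid))))
    })
    med$well <- sprintf("W%03d", well_no)
    med$strain <- "media"
    plate[[length(plate) + 1L]] <- med
    map[[length(map) + 1L]] <- data.frame(well = sprintf("W%03d", well_no),
                                          role = "media", strain = "media",
                                          stringsAsFactors = FALSE)
  }
  plate <- do.call(rbind, plate)
  plate <- plate[, c("well", "strain", "time_h", "od600", "mcherry", "gfp")]
  list(plate = plate, well_map = do.call(rbind, map), truth = design)
}
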