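#' Pipeline configuration
#'
#' Collects every tunable of the mine/design/analyze stages plus the input
#' and output paths into one list that round-trips losslessly through YAML.
#' Every run writes the resolved configuration into its output manifest so
#' results can be reproduced exactly.
#'
#' @param genome Path to the annotated genome (GenBank flat file).
#' @param counts Path to the per-gene read-count TSV.
#' @param plate,well_map Paths to the plate-reader long table and well map.
#' @param outdir Output directory (created if missing).
#' @param ... Overrides for any default parameter (see the returned list).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(genome = NULL, counts = NULL, plate = NULL,
                            well_map = NULL, outdir = ".", ...) {
  cfg <- list(
    genome = genome, counts = counts, plate = plate, well_map = well_map,
    outdir = outdir,
    min_len = 60L, max_len = 170L, circular = FALSE,
    cap = 500L, tranche1_size = 350L, tranche1_max_len = 98L,
    per_decade = 50L, target_len = 98L, total_len = 150L, pad_side = "5p",
    left_flank = default_flanks()$left, right_flank = default_flanks()$right,
    sg_window = 11L, sg_polyorder = 3L, ratio_window = 3L,
    ratio_low = 0.7, ratio_high = 1.3, detect_k = 3, eps = 1e-9,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @rdname pipeline_config_io
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @param config A \code{\link{pipeline_config}}.
#' @rdname pipeline_config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

ensure_outdir <- function(config) {
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }
  config$outdir
}

#' Mining stage: genome to filtered candidate set
#'
#' Parses the genome, extracts every upstream candidate and applies the
#' length, orientation/overlap, transcriptome and restriction-site filters.
#' Writes \code{candidates.tsv} (full table), \code{candidates.fasta}
#' (flag-annotated sequences) and \code{attrition.tsv} to the output
#' directory. Candidate conservation holds at every stage: no row is ever
#' dropped, only flagged.
#'
#' @param config A \code{\link{pipeline_config}} with \code{genome} and
#'   \code{counts} set.
#' @return The candidate table, invisibly.
#' @export
run_mine <- function(config) {
  if (is.null(config$genome) || !file.exists(config$genome)) {
    stop("genome input missing or unreadable: ",
         config$genome %||% "<unset>", call. = FALSE)
  }
  if (is.null(config$counts) || !file.exists(config$counts)) {
    stop("count table missing or unreadable: ",
         config$counts %||% "<unset>", call. = FALSE)
  }
  out <- ensure_outdir(config)
  ann <- parse_genbank(config$genome)
  cand <- extract_candidate_utrs(ann$genes, ann$sequence,
                                 circular = isTRUE(config$circular))
  cand <- filter_by_length(cand, config$min_len, config$max_len)
  cand <- filter_by_transcriptome(cand, read_count_table(config$counts))
  cand <- flag_restriction_sites(cand)
  write_tsv(cand, file.path(out, "candidates.tsv"))
  write_candidate_fasta(cand, file.path(out, "candidates.fasta"))
  write_tsv(attrition_table(cand), file.path(out, "attrition.tsv"))
  invisible(cand)
}

#' Design stage: surviving candidates to synthesis order sheet
#'
#' Selects up to \code{cap} survivors by the two-tranche rule, trims them to
#' the insert length and assembles fixed-length oligos. Writes
#' \code{order_sheet.tsv}, \code{oligos.fasta} and \code{manifest.json}
#' (resolved parameters + seed) for exact reruns.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param candidates Candidate table; defaults to reading
#'   \code{candidates.tsv} from the output directory of a prior mine run.
#' @return The order sheet, invisibly.
#' @export
run_design <- function(config, candidates = NULL) {
  out <- ensure_outdir(config)
  if (is.null(candidates)) {
    path <- file.path(out, "candidates.tsv")
    if (!file.exists(path)) {
      stop("no candidate table found at ", path, "; run the mine stage first",
           call. = FALSE)
    }
    candidates <- read_tsv(path)
  }
  surv <- surviving(candidates)
  if (nrow(surv) == 0L) {
    stop("empty library: no candidates survived the filters", call. = FALSE)
  }
  plan <- selection_plan(cap = config$cap,
                         tranche1_size = config$tranche1_size,
                         tranche1_max_len = config$tranche1_max_len,
                         per_decade = config$per_decade)
  sel <- select_candidates(surv, plan)
  sheet <- design_library(sel,
                          flanks = list(left = config$left_flank,
                                        right = config$right_flank),
                          total_len = config$total_len,
                          target_len = config$target_len,
                          pad_side = config$pad_side, seed = config$seed)
  write_order_sheet(sheet, file.path(out, "order_sheet.tsv"),
                    file.path(out, "oligos.fasta"))
  manifest <- list(stage = "design", plan = unclass(plan),
                   seed = config$seed, n_oligos = nrow(sheet),
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(sheet)
}

#' Analysis stage: plate-reader series to activity profiles
#'
#' Profiles every sample strain (background correction, GFP normalization,
#' growth-phase timepointing, differential activity and classification) and
#' writes \code{profiles.tsv} plus \code{class_summary.tsv}.
#'
#' @param config A \code{\link{pipeline_config}} with \code{plate} and
#'   \code{well_map} set.
#' @return The \code{\link{analyze_plate}} result, invisibly.
#' @export
run_analyze <- function(config) {
  if (is.null(config$plate) || !file.exists(config$plate)) {
    stop("plate table missing or unreadable: ",
         config$plate %||% "<unset>", call. = FALSE)
  }
  if (is.null(config$well_map) || !file.exists(config$well_map)) {
    stop("well map missing or unreadable: ",
         config$well_map %||% "<unset>", call. = FALSE)
  }
  out <- ensure_outdir(config)
  res <- analyze_plate(read_plate_table(config$plate),
                       read_well_map(config$well_map),
                       sg_window = config$sg_window,
                       sg_polyorder = config$sg_polyorder,
                       ratio_window = config$ratio_window,
                       low = config$ratio_low, high = config$ratio_high,
                       k = config$detect_k, eps = config$eps)
  write_tsv(res$profiles, file.path(out, "profiles.tsv"))
  write_tsv(res$summary, file.path(out, "class_summary.tsv"))
  invisible(res)
}

#' Simulation stage: write a complete synthetic input set
#'
#' Generates an annotated genome, a matching count table and a cohort plate
#' experiment into the output directory, with their ground-truth tables, so
#' a full mine/design/analyze run needs no external data.
#'
#' @param config A \code{\link{pipeline_config}}; \code{seed} drives all
#'   generators.
#' @param n_genes Genome size for the synthetic replicon.
#' @return Invisible list of written paths.
#' @export
run_simulate <- function(config, n_genes = 60L) {
  out <- ensure_outdir(config)
  seed <- config$seed
  spec <- genome_spec(n_genes = n_genes,
                      gap_lengths = rep(c(80L, 120L, 40L, 200L, 100L),
                                        length.out = n_genes - 1L),
                      strand_pattern = rep(c("+", "+", "-", "+"),
                                           length.out = n_genes),
                      seed = seed)
  gen <- generate_genome(spec)
  writeLines(gen$genbank, file.path(out, "genome.gbk"))
  counts <- generate_counts(gen$genes$gene_id, decades = 1:3,
                            per_decade_n = max(1L, n_genes %/% 4L),
                            seed = seed + 1L)
  write_tsv(counts, file.path(out, "counts.tsv"))
  write_tsv(gen$truth, file.path(out, "mining_truth.tsv"))
  design <- cohort_design(seed = seed + 2L)
  sim <- generate_plate_timeseries(design, seed = seed + 3L)
  write_tsv(sim$plate, file.path(out, "plate.tsv"))
  write_tsv(sim$well_map, file.path(out, "well_map.tsv"))
  write_tsv(sim$truth, file.path(out, "cohort_truth.tsv"))
  invisible(list(genome = file.path(out, "genome.gbk"),
                 counts = file.path(out, "counts.tsv"),
                 plate = file.path(out, "plate.tsv"),
                 well_map = file.path(out, "well_map.tsv")))
}
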