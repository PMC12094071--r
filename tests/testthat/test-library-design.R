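test_that("two-tranche selection fills the cap from shortest then by decade", {
  cand <- generate_candidate_set(40, length_range = c(60, 170),
                                 decades = 1:3, seed = 14)
  plan <- selection_plan(cap = 22, tranche1_size = 10, per_decade = 4)
  sel <- select_candidates(cand, plan)
  expect_equal(nrow(sel), 22L)
  expect_equal(sum(sel$tranche == 1), 10L)
  # tranche 1 is exactly the 10 shortest (gene_id tiebreak)
  ord <- order(cand$length, cand$gene_id)
  expect_setequal(sel$candidate_id[sel$tranche == 1],
                  cand$candidate_id[ord[1:10]])
  # tranche 2 takes the top counts per decade among the remainder
  rest <- cand[-ord[1:10], ]
  for (d in 1:3) {
    bin <- rest[floor(log10(rest$read_count)) == d, ]
    expected <- bin$candidate_id[order(-bin$read_count, bin$gene_id)][1:4]
    expect_true(all(expected %in% sel$candidate_id))
  }
})

test_that("under-capacity and under-filled bins degrade gracefully", {
  cand <- generate_candidate_set(10, seed = 3)
  expect_warning(sel <- select_candidates(cand, selection_plan(cap = 500)),
                 "shortfall")
  expect_equal(nrow(sel), 10L)

  # a decade bin with only 3 members yields all 3, no backfill
  cand <- generate_candidate_set(23, decades = 1, seed = 4)
  cand$length <- c(61:80, 160L, 161L, 162L)         # decade-2 members are long
  cand$read_count <- c(rep(15, 20), 150, 250, 350)  # 3 candidates in decade 2
  plan <- selection_plan(cap = 30, tranche1_size = 10, per_decade = 50)
  expect_warning(sel <- select_candidates(cand, plan), "shortfall")
  t2 <- sel[sel$tranche == 2, ]
  expect_equal(sum(floor(log10(t2$read_count)) == 2), 3L)
})

test_that("selection is deterministic, monotone in the cap, and complete for short candidates", {
  cand <- generate_candidate_set(300, seed = 19)
  plan100 <- selection_plan(cap = 100, tranche1_size = 60, per_decade = 20)
  s1 <- select_candidates(cand, plan100)
  expect_identical(s1, select_candidates(cand, plan100))
  plan150 <- selection_plan(cap = 150, tranche1_size = 60, per_decade = 20)
  s2 <- suppressWarnings(select_candidates(cand, plan150))
  expect_true(all(s1$candidate_id %in% s2$candidate_id))

  # every survivor at or below the tranche-1 insert length is selected
  # whenever their number fits the tranche
  short <- cand$candidate_id[cand$length <= 98]
  plan <- selection_plan(cap = 300, tranche1_size = max(150, length(short)))
  s3 <- suppressWarnings(select_candidates(cand, plan))
  expect_true(all(short %in% s3$candidate_id))
})

test_that("trimming keeps the 3'-most bases nearest the start codon", {
  set.seed(7)
  s120 <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  expect_identical(trim_to_insert(s120), substr(s120, 23, 120))
  s98 <- substr(s120, 1, 98)
  expect_identical(trim_to_insert(s98), s98)
  s60 <- substr(s120, 1, 60)
  expect_identical(trim_to_insert(s60), s60)
})

test_that("oligos are padded to exactly the synthesis length", {
  flanks <- default_flanks()   # 11 + 11 bp
  insert <- strrep("AT", 49)   # 98 bp
  d <- build_oligo(insert, flanks, seed = 5)
  expect_equal(nchar(d$oligo), 150L)
  expect_equal(nchar(d$pad), 150L - 98L - 22L)
  expect_true(grepl(insert, d$oligo, fixed = TRUE))

  # insert exactly filling the design: empty pad
  insert128 <- strrep("AT", 64)
  d0 <- build_oligo(insert128, flanks, seed = 5)
  expect_identical(d0$pad, "")

  expect_error(build_oligo(strrep("AT", 70), flanks), "infeasible")
  expect_error(build_oligo("AAGGTCTCAA", flanks), "type-IIS")
})

test_that("pad draws are seeded and never introduce new restriction sites", {
  insert <- strrep("CA", 40)
  d1 <- build_oligo(insert, seed = 11)
  d2 <- build_oligo(insert, seed = 11)
  expect_identical(d1$oligo, d2$oligo)
  d3 <- build_oligo(insert, seed = 12)
  expect_false(identical(d1$pad, d3$pad))
  # only the pad differs between seeds
  expect_identical(sub(d1$pad, "", d1$oligo, fixed = TRUE),
                   sub(d3$pad, "", d3$oligo, fixed = TRUE))

  # site census of the full oligo equals that of the flanks alone:
  # exactly one BsaI per flank orientation, nothing from insert or pad
  for (seed in 1:20) {
    d <- build_oligo(insert, seed = seed)
    hits <- scan_restriction_sites(d$oligo)
    expect_equal(nrow(hits), 2L)
    expect_setequal(hits$strand, c("-", "+"))
    expect_equal(unique(hits$enzyme), "BsaI")
  }
})

test_that("library design emits one fixed-length oligo per selected candidate", {
  cand <- generate_candidate_set(30, length_range = c(60, 140), seed = 23)
  sel <- suppressWarnings(select_candidates(cand))
  sheet <- design_library(sel, seed = 2)
  expect_equal(nrow(sheet), 30L)
  expect_true(all(sheet$oligo_length == 150L))
  expect_true(all(sheet$insert_length <= 98L))
  expect_true(all(sheet$insert_length == pmin(sheet$pre_trim_length, 98L)))
  # inserts appear verbatim inside their oligos
  expect_true(all(mapply(grepl, sheet$insert, sheet$oligo, fixed = TRUE)))
  expect_identical(sheet, design_library(sel, seed = 2))
})
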