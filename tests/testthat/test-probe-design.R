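test_that("gc_content computes percent G+C and rejects bad input", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  sixty <- paste0(strrep("GC", 15), strrep("AT", 15))
  expect_equal(gc_content(sixty), 50)
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("ACGN"), "only A, C, G, T")
})

test_that("melting temperature follows the salt-adjusted long-oligo formula", {
  gc50 <- paste0(strrep("GC", 15), strrep("AT", 15))
  gc60 <- paste0(strrep("GC", 18), strrep("AT", 12))
  # frozen from direct evaluation: 81.5 + 16.6*log10(Na) + 0.41*GC - 600/L
  expect_equal(melting_temperature(gc50, 0.3), 83.320213, tolerance = 1e-6)
  expect_equal(melting_temperature(gc60, 0.3), 87.420213, tolerance = 1e-6)
  expect_equal(melting_temperature(gc50, 1.0), 92.0) # log term vanishes
  expect_error(melting_temperature(gc50, 0), "positive")
  expect_error(melting_temperature("ACGTACGTACGT", 0.3), ">= 14")
})

test_that("position score is 1 at the 3' end and proportional otherwise", {
  expect_equal(position_score(540, 60, 600), 1.0)
  expect_equal(position_score(0, 60, 600), 0.1)
  expect_equal(position_score(270, 60, 600), 0.55)
  expect_error(position_score(541, 60, 600), "past")
})

test_that("enumeration emits one candidate per N-free window", {
  withr::local_seed(1)
  cand <- enumerate_candidates(make_tx(t1 = random_sequence(61)))
  expect_equal(cand$start, c(0L, 1L))

  short <- enumerate_candidates(make_tx(t1 = random_sequence(59)))
  expect_equal(nrow(short), 0)

  withr::local_seed(2)
  s <- random_sequence(100)
  substr(s, 31, 31) <- "N" # 0-based position 30
  cand_n <- enumerate_candidates(make_tx(t1 = s))
  # no window may cover 0-based position 30: starts 0..30 all overlap it
  expect_true(all(cand_n$start > 30))
  expect_false(any(cand_n$start <= 30 & cand_n$start + 60 > 30))
})

test_that("candidate annotations are consistent with their sequences", {
  withr::local_seed(3)
  tx <- make_tx(t1 = random_sequence(300))
  cand <- enumerate_candidates(tx, design_params())
  expect_equal(cand$gc_percent, gc_content(cand$sequence))
  expect_equal(cand$tm_celsius, melting_temperature(cand$sequence, 0.3))
  expect_equal(cand$position_score, (cand$start + 60) / 300)
  expect_equal(cand$sequence,
               substring(tx$sequence, cand$start + 1, cand$start + 60))
  # composite score combines GC centrality and position with weight w
  q <- pmin(pmax(1 - abs(cand$gc_percent - 50) / 10, 0), 1)
  expect_equal(cand$composite_score, 0.7 * q + 0.3 * cand$position_score)
})

test_that("filtering enforces GC, Tm and homopolymer predicates in order", {
  withr::local_seed(4)
  tx <- make_tx(t1 = random_sequence(500))
  cand <- enumerate_candidates(tx)
  kept <- filter_candidates(cand)
  expect_true(all(kept$gc_percent >= 40 & kept$gc_percent <= 60))
  expect_true(all(kept$tm_celsius >= 80 & kept$tm_celsius <= 90))
  expect_false(any(grepl("A{7}|C{7}|G{7}|T{7}", kept$sequence)))
  expect_true(!is.unsorted(kept$start)) # order preserved

  # a long homopolymer is removed even when GC and Tm pass
  poly <- paste0(strrep("GC", 13), "AAAAAAA", strrep("AT", 13), "G")
  expect_equal(nchar(poly), 60)
  cpoly <- enumerate_candidates(make_tx(t1 = poly))
  expect_true(cpoly$gc_percent >= 40 && cpoly$tm_celsius >= 80)
  expect_equal(nrow(filter_candidates(cpoly)), 0)
})

test_that("greedy selection respects k, spacing and deterministic ties", {
  base <- enumerate_candidates(make_tx(t1 = random_sequence(400)))[0, ]
  expect_equal(nrow(select_probes(base)), 0)

  cand <- tibble::tibble(
    transcript_id = "t1",
    start = c(0L, 100L, 200L),
    sequence = strrep(c("A", "C", "G"), 60),
    gc_percent = c(50, 50, 50), tm_celsius = c(85, 85, 85),
    position_score = c(0.2, 0.5, 0.9),
    composite_score = c(0.5, 0.6, 0.7)
  )
  sel <- select_probes(cand, design_params())
  expect_equal(nrow(sel), 3)
  expect_equal(sel$rank, 1:3)
  expect_equal(sel$probe_id, c("t1_p1", "t1_p2", "t1_p3"))
  expect_equal(sel$start, c(200L, 100L, 0L)) # by descending score

  # overlapping pair: only the higher-scoring one survives
  overlap <- cand[1:2, ]
  overlap$start <- c(0L, 30L)
  sel2 <- select_probes(overlap, design_params())
  expect_equal(nrow(sel2), 1)
  expect_equal(sel2$start, 30L)

  # score tie is broken toward the 3' (larger) start
  tie <- cand
  tie$composite_score <- 0.5
  tie$start <- c(0L, 30L, 45L)
  sel3 <- select_probes(tie, design_params())
  expect_equal(sel3$start[1], 45L)
})

test_that("design_array reports coverage over designable transcripts", {
  withr::local_seed(5)
  ok <- stats::setNames(
    vapply(1:10, function(i) random_sequence(1000), character(1)),
    sprintf("t%02d", 1:10)
  )
  d <- design_array(do.call(make_tx, as.list(ok)))
  expect_equal(d$coverage, 1.0)
  expect_true(all(d$per_transcript_counts$n_probes == 3))

  ok9 <- ok
  ok9[["t01"]] <- strrep("A", 1000) # no admissible window
  d9 <- design_array(do.call(make_tx, as.list(ok9)))
  expect_equal(d9$coverage, 0.9)
  expect_equal(
    d9$per_transcript_counts$n_probes[d9$per_transcript_counts$transcript_id == "t01"],
    0L
  )

  short <- design_array(make_tx(t1 = random_sequence(59)))
  expect_equal(short$coverage, 0)
  expect_equal(nrow(tidy(short)), 0)

  expect_error(design_array(make_tx(t1 = "ACGT")[0, ]), "empty")
})

test_that("every emitted probe satisfies the design invariants", {
  for (seed in c(21, 22)) {
    tx <- simulate_transcriptome(15, c(200, 1200), 0.5, seed = seed)
    d <- design_array(tx)
    p <- tidy(d)
    expect_true(all(nchar(p$sequence) == 60))
    expect_true(all(p$gc_percent >= 40 & p$gc_percent <= 60))
    expect_true(all(p$tm_celsius >= 80 & p$tm_celsius <= 90))
    expect_equal(
      p$sequence,
      substring(tx$sequence[match(p$transcript_id, tx$id)],
                p$start + 1, p$start + 60)
    )
    counts <- table(p$transcript_id)
    expect_true(all(counts <= 3))
    # pairwise spacing within each transcript
    by_tx <- split(p$start, p$transcript_id)
    gaps_ok <- vapply(by_tx, function(s) {
      if (length(s) < 2) return(TRUE)
      all(diff(sort(s)) >= 60 + 10)
    }, logical(1))
    expect_true(all(gaps_ok))
  }
})

test_that("identical inputs give byte-identical probe tables", {
  tx <- simulate_transcriptome(8, c(300, 900), 0.5, seed = 33)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(tidy(design_array(tx)), f1)
  write_probe_table(tidy(design_array(tx)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("widening the GC or Tm band never loses probes", {
  for (seed in c(41, 42, 43)) {
    tx <- simulate_transcriptome(10, c(200, 800), 0.45, seed = seed)
    narrow <- design_array(tx, design_params())
    wide_gc <- design_array(tx, design_params(gc_min = 30, gc_max = 70))
    wide_tm <- design_array(tx, design_params(tm_min = 75, tm_max = 95))
    expect_gte(nrow(tidy(wide_gc)), nrow(tidy(narrow)))
    expect_gte(nrow(tidy(wide_tm)), nrow(tidy(narrow)))
  }
})
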