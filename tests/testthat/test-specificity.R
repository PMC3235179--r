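test_that("hamming distance counts mismatches and treats N as unknown", {
  expect_equal(hamming_distance("AAAA", "AAAA"), 0)
  expect_equal(hamming_distance("AAAA", "AAAT"), 1)
  expect_equal(hamming_distance("ACGT", "TGCA"), 4)
  expect_equal(hamming_distance("ANAA", "ANAA"), 1) # N never matches
  expect_error(hamming_distance("AAA", "AAAA"), "equal-length")
})

test_that("hamming distance is a metric on random strings", {
  withr::local_seed(9)
  for (i in 1:20) {
    a <- random_sequence(30)
    b <- random_sequence(30)
    c <- random_sequence(30)
    expect_equal(hamming_distance(a, b), hamming_distance(b, a))
    expect_equal(hamming_distance(a, a), 0)
    expect_lte(hamming_distance(a, c),
               hamming_distance(a, b) + hamming_distance(b, c))
  }
})

test_that("find_hits locates exact and near matches at correct offsets", {
  tx <- make_tx(
    t1 = "AAAACGTACGTTTTT",
    t2 = "GGGGGGGGGGGGGGG"
  )
  h <- find_hits(tx, "ACGTACGT", max_mm = 0)
  expect_equal(nrow(h), 1)
  expect_equal(h$transcript_id, "t1")
  expect_equal(h$offset, 3L)
  expect_equal(h$mismatches, 0L)

  # 4 mismatches from the nearest window is out of reach at max_mm = 3
  h2 <- find_hits(make_tx(t1 = "AAAAAAAAAA"), "TTTTA", max_mm = 3)
  expect_equal(nrow(h2), 0)

  # probe longer than every transcript: empty result, not an error
  h3 <- find_hits(make_tx(t1 = "ACGT"), "ACGTACGT", max_mm = 3)
  expect_equal(nrow(h3), 0)
})

test_that("find_hits equals the brute-force oracle on random instances", {
  withr::local_seed(10)
  for (i in 1:8) {
    tx <- simulate_transcriptome(8, c(60, 300), 0.5, seed = 100 + i)
    max_mm <- sample(0:3, 1)
    plen <- sample(c(20, 36, 60), 1)
    src <- sample.int(8, 1)
    start <- sample.int(nchar(tx$sequence[src]) - plen + 1, 1)
    probe <- substr(tx$sequence[src], start, start + plen - 1)
    got <- find_hits(tx, probe, max_mm)
    want <- oracle_hits(tx, probe, max_mm)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("specificity classification follows the single/multiple/none rule", {
  withr::local_seed(13)
  t1 <- random_sequence(200)
  probe <- substr(t1, 50, 109)
  tx <- make_tx(t1 = t1, t2 = random_sequence(200))

  one <- tibble::tibble(probe_id = "p1", sequence = probe)
  call <- classify_probes(one, tx, max_mm = 3)
  expect_equal(as.character(call$status), "single")
  expect_equal(call$perfect_hits, "t1")
  expect_equal(call$near_hits, "")

  # a second transcript within 2 mismatches makes the probe multiple
  near <- probe
  substr(near, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(near, 5, 5))[1]
  tx2 <- make_tx(t1 = t1, t2 = paste0(random_sequence(30), near,
                                      random_sequence(30)))
  call2 <- classify_probes(one, tx2, max_mm = 3)
  expect_equal(as.character(call2$status), "multiple")
  expect_equal(call2$perfect_hits, "t1")
  expect_equal(call2$near_hits, "t2")

  # nothing within 3 mismatches: none
  call3 <- classify_probes(
    tibble::tibble(probe_id = "p1", sequence = strrep("ACGT", 15)),
    make_tx(t1 = strrep("G", 100)), max_mm = 3
  )
  expect_equal(as.character(call3$status), "none")
  expect_false(call3$near_only)

  # a single near hit without any perfect hit is none, flagged near_only
  call4 <- classify_probes(one, make_tx(t2 = tx2$sequence[2]), max_mm = 3)
  expect_equal(as.character(call4$status), "none")
  expect_true(call4$near_only)
})

test_that("reannotation summarizes class fractions", {
  withr::local_seed(14)
  tx <- simulate_transcriptome(3, c(300, 300), 0.5, seed = 900)
  probes <- tibble::tibble(
    probe_id = paste0(tx$id, "_p1"),
    sequence = substr(tx$sequence, 101, 160)
  )
  re <- reannotate_probe_set(probes, tx)
  expect_equal(re$fraction_single, 1)
  expect_equal(re$fraction_multiple, 0)
  expect_equal(re$fraction_none, 0)

  # dropping one target transcript moves its probe to none
  re2 <- reannotate_probe_set(probes, tx[1:2, ])
  expect_equal(re2$fraction_single, 2 / 3)
  expect_equal(re2$fraction_none, 1 / 3)
  expect_equal(
    re2$fraction_single + re2$fraction_multiple + re2$fraction_none, 1
  )

  # duplicating a transcript under a new id forces its probes to multiple
  dup <- dplyr::bind_rows(tx, tibble::tibble(
    id = "copy_of_1", sequence = tx$sequence[1], description = ""
  ))
  re3 <- reannotate_probe_set(probes, dup)
  calls <- tidy(re3)
  expect_equal(as.character(calls$status[1]), "multiple")
  expect_equal(as.character(calls$status[2:3]), c("single", "single"))

  expect_error(reannotate_probe_set(probes[0, ], tx), "non-empty")
})

test_that("appending an exact transcript copy flips single to multiple", {
  for (seed in c(31, 32, 33)) {
    tx <- simulate_transcriptome(6, c(200, 500), 0.5, seed = seed)
    d <- design_array(tx)
    probes <- tidy(d)
    calls <- classify_probes(probes, tx)
    single_t1 <- calls$probe_id[calls$status == "single" &
                                  calls$perfect_hits == tx$id[1]]
    dup <- dplyr::bind_rows(tx, tibble::tibble(
      id = "dup", sequence = tx$sequence[1], description = ""
    ))
    calls_dup <- classify_probes(probes, dup)
    flipped <- calls_dup$status[calls_dup$probe_id %in% single_t1]
    expect_true(all(as.character(flipped) == "multiple"))
  }
})

test_that("raising max_mm never turns multiple into single", {
  withr::local_seed(15)
  tx <- simulate_transcriptome(10, c(100, 400), 0.5, seed = 501)
  probes <- tibble::tibble(
    probe_id = sprintf("p%d", 1:10),
    sequence = vapply(seq_len(10), function(i) {
      s <- tx$sequence[i]
      start <- sample.int(nchar(s) - 59, 1)
      substr(s, start, start + 59)
    }, character(1))
  )
  prev <- classify_probes(probes, tx, max_mm = 0)
  for (mm in 1:3) {
    cur <- classify_probes(probes, tx, max_mm = mm)
    # each probe has exactly one status
    expect_true(all(!is.na(cur$status)))
    # multiple never reverts to single
    was_multiple <- prev$status == "multiple"
    expect_true(all(cur$status[was_multiple] == "multiple"))
    prev <- cur
  }
})
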