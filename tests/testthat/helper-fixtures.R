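# Fixtures are built in code at test time; nothing is read from disk except
# temporary files the tests themselves write.

make_tx <- function(...) {
  seqs <- c(...)
  tibble::tibble(
    id = names(seqs),
    sequence = unname(seqs),
    description = ""
  )
}

write_fasta_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_sequence <- function(len, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

random_probe_table <- function(n) {
  seqs <- vapply(seq_len(n), function(i) random_sequence(60), character(1))
  tibble::tibble(
    probe_id = sprintf("t%02d_p1", seq_len(n)),
    transcript_id = sprintf("t%02d", seq_len(n)),
    start = sample.int(500L, n),
    sequence = seqs,
    gc_percent = gc_content(seqs),
    tm_celsius = melting_temperature(seqs, 0.3),
    position_score = round(stats::runif(n), 6),
    origin = "designed"
  )
}

# Position-by-position brute-force search, kept deliberately naive and
# independent of the package's vectorized scanner.
oracle_hits <- function(transcriptome, probe, max_mm) {
  P <- nchar(probe)
  pc <- strsplit(probe, "")[[1]]
  rows <- list()
  for (i in seq_len(nrow(transcriptome))) {
    s <- transcriptome$sequence[i]
    L <- nchar(s)
    if (L < P) next
    for (off in 0:(L - P)) {
      w <- strsplit(substr(s, off + 1, off + P), "")[[1]]
      mm <- sum(w != pc | w == "N" | pc == "N")
      if (mm <= max_mm) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          transcript_id = transcriptome$id[i],
          offset = off, mismatches = mm
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(transcript_id = character(), offset = integer(),
                          mismatches = integer()))
  }
  out[order(out$transcript_id, out$offset, method = "radix"), ]
}

# Ten-line reference for the Holm step-down adjustment, written straight
# from the closed form.
holm_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (j in seq_len(m)) {
    running <- max(running, (m - j + 1) * p[o[j]])
    adj[o[j]] <- min(1, running)
  }
  adj
}
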