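#' Hamming distance between equal-length sequences
#'
#' Counts mismatching positions between two nucleotide strings of equal
#' length. `N` is treated as unknown and mismatches every base, including
#' another `N`. Vectorized elementwise over pairs.
#'
#' @param a,b Character vectors of equal-length sequences.
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming_distance("ACGT", "TGCA")
#' hamming_distance("ANAA", "ANAA") # N mismatches N
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same number of sequences.")
  }
  n_code <- utf8ToInt("N")
  mapply(function(x, y) {
    xi <- utf8ToInt(x)
    yi <- utf8ToInt(y)
    if (length(xi) != length(yi)) {
      abort("Hamming distance requires equal-length sequences.")
    }
    sum(xi != yi | xi == n_code | yi == n_code)
  }, a, b, USE.NAMES = FALSE)
}

## Mismatch counts of a probe against every offset of one transcript,
## accumulated column-wise so each probe position costs one vectorized
## comparison across all offsets.
scan_offsets <- function(tx_int, p_int, max_mm) {
  n <- length(tx_int)
  P <- length(p_int)
  if (n < P) return(NULL)
  n_off <- n - P + 1L
  mm <- integer(n_off)
  n_code <- utf8ToInt("N")
  for (j in seq_len(P)) {
    tj <- tx_int[j:(j + n_off - 1L)]
    mm <- mm + ((tj != p_int[j]) | (tj == n_code))
  }
  keep <- which(mm <= max_mm)
  if (length(keep) == 0) return(NULL)
  list(offset = keep - 1L, mismatches = mm[keep])
}

#' Find all bounded-mismatch alignments of a probe in a transcriptome
#'
#' Reports every ungapped alignment of the probe to the sense strand of
#' every transcript with Hamming distance at most `max_mm`. The scan is
#' exhaustive: each possible offset of each transcript is evaluated, so the
#' result is identical to a position-by-position brute-force search.
#'
#' @inheritParams enumerate_candidates
#' @param probe_sequence A single probe sequence over `{A, C, G, T, N}`.
#' @param max_mm Maximum tolerated number of mismatches (`>= 0`).
#' @return Tibble with columns `transcript_id`, `offset` (0-based alignment
#'   start), `mismatches`, sorted by `(transcript_id, offset)`. A probe
#'   longer than every transcript yields an empty tibble.
#' @examples
#' tx <- tibble::tibble(id = "t1", sequence = "ACGTACGTACGT", description = "")
#' find_hits(tx, "GTAC", max_mm = 0)
#' @export
find_hits <- function(transcriptome, probe_sequence, max_mm = 3) {
  check_transcriptome(transcriptome)
  if (length(probe_sequence) != 1 || is.na(probe_sequence) ||
      !nzchar(probe_sequence)) {
    abort("`probe_sequence` must be a single non-empty string.")
  }
  if (grepl("[^ACGTN]", probe_sequence)) {
    abort("`probe_sequence` must be over {A, C, G, T, N}.")
  }
  if (max_mm < 0) abort("`max_mm` must be >= 0.")
  p_int <- utf8ToInt(probe_sequence)
  res <- purrr::map2(
    transcriptome$id, transcriptome$sequence,
    function(id, s) {
      h <- scan_offsets(utf8ToInt(s), p_int, max_mm)
      if (is.null(h)) return(NULL)
      tibble::tibble(transcript_id = id, offset = h$offset,
                     mismatches = h$mismatches)
    }
  )
  hits <- dplyr::bind_rows(res)
  if (nrow(hits) == 0) {
    return(tibble::tibble(transcript_id = character(), offset = integer(),
                          mismatches = integer()))
  }
  hits[order(hits$transcript_id, hits$offset, method = "radix"), ]
}

classify_from_hits <- function(hits) {
  perfect <- sort(unique(hits$transcript_id[hits$mismatches == 0]))
  near_raw <- sort(unique(hits$transcript_id[hits$mismatches > 0]))
  near <- setdiff(near_raw, perfect)
  n_targets <- length(union(perfect, near))
  status <- if (length(perfect) == 1 && length(near) == 0) {
    "single"
  } else if (n_targets >= 2) {
    "multiple"
  } else {
    "none"
  }
  list(
    status = status,
    perfect_hits = perfect,
    near_hits = near,
    near_only = length(perfect) == 0 && length(near) == 1
  )
}

#' Classify probe specificity against a transcriptome
#'
#' Applies the single/multiple/none specificity rule to each probe: a probe
#' is `single` when it aligns perfectly to exactly one transcript and to no
#' other transcript within `max_mm` mismatches; `multiple` when two or more
#' transcripts carry a perfect or near (1..`max_mm` mismatch) alignment; and
#' `none` otherwise. A probe whose only alignment is a single near hit has no
#' assignable perfect target and is classified `none`, flagged `near_only`
#' for transparency.
#'
#' @param probes Probe tibble with columns `probe_id` and `sequence`
#'   (a single probe is a one-row tibble).
#' @inheritParams find_hits
#' @return Tibble with one row per probe: `probe_id`, `status` (factor with
#'   levels single/multiple/none), `perfect_hits` and `near_hits`
#'   (comma-separated transcript ids; near hits exclude perfect-hit
#'   transcripts), and `near_only`.
#' @export
classify_probes <- function(probes, transcriptome, max_mm = 3) {
  if (!is.data.frame(probes) ||
      !all(c("probe_id", "sequence") %in% names(probes))) {
    abort("`probes` must be a data frame with columns `probe_id` and `sequence`.")
  }
  check_transcriptome(transcriptome)
  tx_int <- lapply(transcriptome$sequence, utf8ToInt)
  rows <- purrr::map2(probes$probe_id, probes$sequence, function(pid, pseq) {
    p_int <- utf8ToInt(pseq)
    hit_tx <- character()
    hit_mm <- integer()
    for (i in seq_along(tx_int)) {
      h <- scan_offsets(tx_int[[i]], p_int, max_mm)
      if (!is.null(h)) {
        hit_tx <- c(hit_tx, rep(transcriptome$id[i], length(h$offset)))
        hit_mm <- c(hit_mm, h$mismatches)
      }
    }
    cl <- classify_from_hits(
      tibble::tibble(transcript_id = hit_tx, mismatches = hit_mm)
    )
    tibble::tibble(
      probe_id = pid,
      status = cl$status,
      perfect_hits = paste(cl$perfect_hits, collapse = ","),
      near_hits = paste(cl$near_hits, collapse = ","),
      near_only = cl$near_only
    )
  })
  out <- dplyr::bind_rows(rows)
  out$status <- factor(out$status, levels = c("single", "multiple", "none"))
  out
}

#' Re-annotate a probe set against a new transcript catalogue
#'
#' Classifies every probe of an existing design against a (typically newer)
#' annotation release and summarizes the fractions of probes that remain
#' specific (`single`), that cross-hybridize (`multiple`), and that no longer
#' align (`none`).
#'
#' @inheritParams classify_probes
#' @param new_transcriptome Transcript tibble of the new annotation release.
#' @return An object of class `reannotation` with the per-probe `calls`
#'   tibble and the three class fractions. [tidy()] returns the calls,
#'   [glance()] the fractions.
#' @export
reannotate_probe_set <- function(probes, new_transcriptome, max_mm = 3) {
  if (!is.data.frame(probes) || nrow(probes) == 0) {
    abort("`probes` must be a non-empty probe table.")
  }
  calls <- classify_probes(probes, new_transcriptome, max_mm = max_mm)
  frac <- proportions(table(calls$status))
  structure(
    list(
      calls = calls,
      fraction_single = unname(frac[["single"]]),
      fraction_multiple = unname(frac[["multiple"]]),
      fraction_none = unname(frac[["none"]]),
      n_probes = nrow(calls),
      max_mm = max_mm
    ),
    class = "reannotation"
  )
}

#' @export
print.reannotation <- function(x, ...) {
  cat("<reannotation>\n")
  cat(sprintf("  probes:   %d (max %d mismatches)\n", x$n_probes, x$max_mm))
  cat(sprintf("  single:   %.1f%%\n", 100 * x$fraction_single))
  cat(sprintf("  multiple: %.1f%%\n", 100 * x$fraction_multiple))
  cat(sprintf("  none:     %.1f%%\n", 100 * x$fraction_none))
  invisible(x)
}

#' @describeIn reannotate_probe_set Per-probe specificity calls.
#' @param x A `reannotation` object.
#' @param ... Unused.
#' @export
tidy.reannotation <- function(x, ...) {
  x$calls
}

#' @describeIn reannotate_probe_set One-row summary with the three class
#'   fractions.
#' @export
glance.reannotation <- function(x, ...) {
  tibble::tibble(
    n_probes = x$n_probes,
    fraction_single = x$fraction_single,
    fraction_multiple = x$fraction_multiple,
    fraction_none = x$fraction_none,
    max_mm = x$max_mm
  )
}
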