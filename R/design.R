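#' G+C content of a nucleotide sequence
#'
#' @param sequence Character vector of sequences over `{A, C, G, T}`.
#'   Ambiguous bases (including `N`) are rejected: a probe's GC content is
#'   only meaningful for a fully determined sequence.
#' @return Numeric vector of G+C percentages in `[0, 100]`.
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGT"))
#' @export
gc_content <- function(sequence) {
  if (length(sequence) == 0) return(numeric())
  if (any(!nzchar(sequence)) || any(is.na(sequence))) {
    abort("`sequence` must not contain empty or missing values.")
  }
  if (any(grepl("[^ACGT]", sequence))) {
    abort("`sequence` must contain only A, C, G, T (no N or ambiguity codes).")
  }
  100 * stringr::str_count(sequence, "[GC]") / nchar(sequence)
}

#' Salt-adjusted melting temperature of a long oligonucleotide
#'
#' Estimates Tm with the classical salt-adjusted long-oligo formula
#' `Tm = 81.5 + 16.6 * log10([Na+]) + 0.41 * GC% - 600 / length` (degrees
#' Celsius). The formula is a length/GC/salt approximation valid for oligos
#' of roughly 14 nt and longer; shorter inputs are rejected.
#'
#' @inheritParams gc_content
#' @param na_molar Sodium concentration in mol/L (must be positive).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' # a 60-mer with 50% GC at 0.3 M sodium
#' melting_temperature(strrep("ATGC", 15), na_molar = 0.3)
#' @export
melting_temperature <- function(sequence, na_molar = 0.3) {
  if (length(na_molar) != 1 || is.na(na_molar) || na_molar <= 0) {
    abort("`na_molar` must be a single positive number.")
  }
  gc <- gc_content(sequence)
  len <- nchar(sequence)
  if (any(len < 14)) {
    abort("Sequences must be >= 14 nt for the long-oligo Tm formula.")
  }
  81.5 + 16.6 * log10(na_molar) + 0.41 * gc - 600 / len
}

#' 3'-bias position score of a probe window
#'
#' Scores a probe window by how close its end lies to the transcript 3'
#' terminus: `(start + probe_length) / transcript_length`, which is 1 for a
#' probe ending exactly at the 3' end and decreases toward the 5' end.
#' Coordinates are 0-based, half-open, in transcript (sense) space.
#'
#' @param start 0-based window start(s).
#' @param probe_length Probe length in nt.
#' @param transcript_length Transcript length(s) in nt.
#' @return Numeric score(s) in `(0, 1]`.
#' @examples
#' position_score(0, 60, 600)
#' position_score(540, 60, 600)
#' @export
position_score <- function(start, probe_length, transcript_length) {
  if (any(start < 0)) abort("`start` must be >= 0.")
  if (any(start + probe_length > transcript_length)) {
    abort("Probe window extends past the transcript 3' end.")
  }
  (start + probe_length) / transcript_length
}

gc_window_quality <- function(gc_percent, gc_min, gc_max) {
  mid <- (gc_min + gc_max) / 2
  half <- (gc_max - gc_min) / 2
  if (half == 0) return(as.numeric(gc_percent == mid))
  pmin(pmax(1 - abs(gc_percent - mid) / half, 0), 1)
}

empty_candidates <- function() {
  tibble::tibble(
    transcript_id = character(), start = integer(), sequence = character(),
    gc_percent = numeric(), tm_celsius = numeric(),
    position_score = numeric(), composite_score = numeric()
  )
}

## Per-transcript sliding-window enumeration. Window statistics come from
## cumulative sums over the base vector, so cost is linear in transcript
## length; substrings are materialized only for N-free windows.
enumerate_one <- function(id, sequence, params) {
  P <- params$probe_length
  L <- nchar(sequence)
  if (L < P) return(empty_candidates())
  bases <- charToRaw(sequence)
  cs_gc <- c(0L, cumsum(bases == as.raw(71L) | bases == as.raw(67L))) # G, C
  cs_n <- c(0L, cumsum(bases == as.raw(78L)))                        # N
  i1 <- seq_len(L - P + 1L)                                          # 1-based
  keep <- (cs_n[i1 + P] - cs_n[i1]) == 0L
  if (!any(keep)) return(empty_candidates())
  i1 <- i1[keep]
  start0 <- i1 - 1L
  gc <- 100 * (cs_gc[i1 + P] - cs_gc[i1]) / P
  tm <- 81.5 + 16.6 * log10(params$na_molar) + 0.41 * gc - 600 / P
  pos <- (start0 + P) / L
  quality <- gc_window_quality(gc, params$gc_min, params$gc_max)
  w <- params$position_weight
  tibble::tibble(
    transcript_id = id,
    start = start0,
    sequence = substring(sequence, i1, i1 + P - 1L),
    gc_percent = gc,
    tm_celsius = tm,
    position_score = pos,
    composite_score = (1 - w) * quality + w * pos
  )
}

check_transcriptome <- function(transcriptome) {
  if (!is.data.frame(transcriptome) ||
      !all(c("id", "sequence") %in% names(transcriptome))) {
    abort("`transcriptome` must be a data frame with columns `id` and `sequence`.")
  }
  dup <- transcriptome$id[duplicated(transcriptome$id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate transcript id: '", dup[1], "'."))
  }
  invisible(transcriptome)
}

#' Enumerate all probe candidates of a transcriptome
#'
#' Slides a window of `probe_length` over every transcript and emits one
#' candidate per N-free window, annotated with GC content, melting
#' temperature, 3'-position score, and a composite score
#' `(1 - w) * gc_centrality + w * position_score`, where `gc_centrality` is 1
#' at the midpoint of the admissible GC band and falls linearly to 0 at its
#' edges (clamped). Transcripts shorter than the probe yield no candidates.
#'
#' @param transcriptome Tibble with columns `id` and `sequence` (see
#'   [read_fasta()]); a single transcript is a one-row tibble.
#' @param params A [design_params()] object.
#' @return Candidate tibble ordered by transcript (input order) then
#'   ascending `start` (0-based).
#' @export
enumerate_candidates <- function(transcriptome, params = design_params()) {
  check_transcriptome(transcriptome)
  purrr::map2(
    transcriptome$id, transcriptome$sequence,
    function(id, s) enumerate_one(id, s, params)
  ) |>
    dplyr::bind_rows()
}

#' Filter probe candidates on GC, Tm and homopolymer constraints
#'
#' Keeps exactly those candidates whose GC content lies in
#' `[gc_min, gc_max]`, whose melting temperature lies in `[tm_min, tm_max]`
#' (both bands inclusive), and whose longest single-base run does not exceed
#' `max_homopolymer`. Input order is preserved.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @inheritParams enumerate_candidates
#' @return The retained candidates.
#' @export
filter_candidates <- function(candidates, params = design_params()) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- candidates$gc_percent >= params$gc_min &
    candidates$gc_percent <= params$gc_max &
    candidates$tm_celsius >= params$tm_min &
    candidates$tm_celsius <= params$tm_max
  run <- strrep(c("A", "C", "G", "T"), params$max_homopolymer + 1L)
  for (r in run) {
    keep <- keep & !grepl(r, candidates$sequence, fixed = TRUE)
  }
  candidates[keep, , drop = FALSE]
}

empty_probes <- function() {
  tibble::tibble(
    probe_id = character(), transcript_id = character(), start = integer(),
    sequence = character(), gc_percent = numeric(), tm_celsius = numeric(),
    position_score = numeric(), composite_score = numeric(),
    rank = integer(), origin = character()
  )
}

#' Greedily select up to k spaced probes for one transcript
#'
#' Ranks filtered candidates by descending composite score (ties broken by
#' the more 3'-ward start, then by ascending sequence) and accepts a
#' candidate only when its interval is at least `min_spacing` nt away from
#' every already-accepted interval. Selection stops at `k` probes or when
#' candidates are exhausted; the procedure is fully deterministic.
#'
#' @param candidates Filtered candidates of a single transcript.
#' @inheritParams enumerate_candidates
#' @return Probe tibble with `probe_id` (`"<transcript_id>_p<rank>"`),
#'   `rank` in selection order, and `origin = "designed"`.
#' @export
select_probes <- function(candidates, params = design_params()) {
  if (nrow(candidates) == 0) return(empty_probes())
  tid <- unique(candidates$transcript_id)
  if (length(tid) != 1) {
    abort("`select_probes()` expects candidates of a single transcript.")
  }
  o <- order(-candidates$composite_score, -candidates$start,
             candidates$sequence, method = "radix")
  min_gap <- params$probe_length + params$min_spacing
  sel <- integer()
  for (i in o) {
    if (length(sel) >= params$k) break
    if (all(abs(candidates$start[i] - candidates$start[sel]) >= min_gap)) {
      sel <- c(sel, i)
    }
  }
  chosen <- candidates[sel, , drop = FALSE]
  chosen$rank <- seq_len(nrow(chosen))
  chosen$probe_id <- paste0(tid, "_p", chosen$rank)
  chosen$origin <- "designed"
  dplyr::select(
    chosen, "probe_id", "transcript_id", "start", "sequence",
    "gc_percent", "tm_celsius", "position_score", "composite_score",
    "rank", "origin"
  )
}

#' Design an array: up to k filtered, spaced probes per transcript
#'
#' Runs enumerate / filter / select for every transcript and assembles the
#' probe set together with per-transcript probe counts and overall coverage
#' (the fraction of transcripts that received at least one probe).
#'
#' @inheritParams enumerate_candidates
#' @param quiet If `FALSE`, transcripts for which fewer than `k` probes could
#'   be designed are reported via a warning summary.
#' @return An object of class `array_design` with components `probes`
#'   (probe tibble), `per_transcript_counts` (tibble `transcript_id`,
#'   `n_probes`, covering all transcripts), `coverage`, `n_transcripts`, and
#'   `params`. Use [tidy()] for the probe table, [glance()] for a one-row
#'   summary and [autoplot()] for GC/Tm histograms.
#' @examples
#' tx <- simulate_transcriptome(5, c(500, 800), 0.5, seed = 1)
#' design <- design_array(tx, design_params())
#' glance(design)
#' @export
design_array <- function(transcriptome, params = design_params(),
                         quiet = TRUE) {
  check_transcriptome(transcriptome)
  if (nrow(transcriptome) == 0) abort("`transcriptome` is empty.")
  probe_list <- purrr::map2(
    transcriptome$id, transcriptome$sequence,
    function(id, s) {
      enumerate_one(id, s, params) |>
        filter_candidates(params) |>
        select_probes(params)
    }
  )
  probes <- dplyr::bind_rows(probe_list)
  n_per <- vapply(probe_list, nrow, integer(1))
  counts <- tibble::tibble(
    transcript_id = transcriptome$id,
    n_probes = n_per
  )
  short <- counts$transcript_id[counts$n_probes < params$k]
  if (!quiet && length(short) > 0) {
    warn(paste0(
      length(short), " transcript(s) received fewer than k = ", params$k,
      " probes (e.g. '", short[1], "')."
    ))
  }
  structure(
    list(
      probes = probes,
      per_transcript_counts = counts,
      coverage = mean(counts$n_probes >= 1),
      n_transcripts = nrow(transcriptome),
      params = params
    ),
    class = "array_design"
  )
}

#' @export
print.array_design <- function(x, ...) {
  cat("<array_design>\n")
  cat(sprintf("  transcripts: %d\n", x$n_transcripts))
  cat(sprintf("  probes:      %d (%d-mers, up to %d per transcript)\n",
              nrow(x$probes), x$params$probe_length, x$params$k))
  cat(sprintf("  coverage:    %.1f%% of transcripts with >= 1 probe\n",
              100 * x$coverage))
  invisible(x)
}

#' @describeIn design_array Probe table of a design, one row per probe.
#' @param x An `array_design` object.
#' @param ... Unused.
#' @export
tidy.array_design <- function(x, ...) {
  x$probes
}

#' @describeIn design_array One-row design summary: transcript and probe
#'   counts, coverage, and the fraction of transcripts with the full k
#'   probes.
#' @export
glance.array_design <- function(x, ...) {
  tibble::tibble(
    n_transcripts = x$n_transcripts,
    n_probes = nrow(x$probes),
    coverage = x$coverage,
    full_k_fraction = mean(x$per_transcript_counts$n_probes == x$params$k),
    probe_length = x$params$probe_length,
    k = x$params$k
  )
}

#' @describeIn design_array Histograms of probe GC content and melting
#'   temperature, the standard design QC figure.
#' @param object An `array_design` object.
#' @param bins Number of histogram bins.
#' @export
autoplot.array_design <- function(object, bins = 30, ...) {
  df <- tidyr::pivot_longer(
    object$probes[, c("gc_percent", "tm_celsius")],
    dplyr::everything(),
    names_to = "property", values_to = "value"
  )
  df$property <- factor(
    df$property, levels = c("gc_percent", "tm_celsius"),
    labels = c("G+C content (%)", "Melting temperature (°C)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~property, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Probes") +
    ggplot2::theme_bw()
}
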