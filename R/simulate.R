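#' Simulate a synthetic transcriptome
#'
#' Generates `n` transcripts with i.i.d. bases where G and C each have
#' probability `gc_mean / 2`, lengths drawn uniformly from `length_range`,
#' and ids `synth_0001`, `synth_0002`, ... The output is fully reproducible
#' for a given seed and has the same shape as [read_fasta()] output.
#'
#' @param n Number of transcripts (`>= 1`).
#' @param length_range Closed interval of transcript lengths (nt).
#' @param gc_mean Expected GC fraction in `[0, 1]`.
#' @param seed Integer seed fixing all randomness.
#' @return Transcript tibble with columns `id`, `sequence`, `description`.
#' @examples
#' simulate_transcriptome(3, c(80, 120), 0.5, seed = 1)
#' @export
simulate_transcriptome <- function(n, length_range, gc_mean, seed) {
  n <- as.integer(n)
  length_range <- as.integer(length_range)
  if (is.na(n) || n < 1) abort("`n` must be >= 1.")
  if (length(length_range) != 2 || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must be an increasing pair of lengths >= 1.")
  }
  if (gc_mean < 0 || gc_mean > 1) abort("`gc_mean` must lie in [0, 1].")
  withr::local_seed(as.integer(seed))
  lens <- length_range[1] - 1L +
    sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE)
  prob <- c((1 - gc_mean) / 2, gc_mean / 2, gc_mean / 2, (1 - gc_mean) / 2)
  bases <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE,
                  prob = prob)
  grp <- rep.int(seq_len(n), lens)
  seqs <- vapply(split(bases, grp), paste0, character(1), collapse = "")
  width <- max(4L, nchar(as.character(n)))
  tibble::tibble(
    id = sprintf("synth_%0*d", width, seq_len(n)),
    sequence = unname(seqs),
    description = ""
  )
}

#' Simulate ground-truth expression profiles
#'
#' Assigns each transcript a true log2 abundance in the reference and
#' treatment conditions. A random `floor(frac_de * n)` subset of
#' non-knockout transcripts receives a true shift of `effect_log2`
#' magnitude, up or down with equal probability. Knockout transcripts are
#' flagged and carry no abundance in either condition (`NA`; they contribute
#' background only when hybridized).
#'
#' @inheritParams enumerate_candidates
#' @param params A [sim_params()] object; randomness is fixed by
#'   `params$seed`.
#' @return Tibble with columns `transcript_id`, `true_log2_ref`,
#'   `true_log2_trt`, `de_flag`, `knockout_flag`.
#' @export
simulate_expression <- function(transcriptome, params = sim_params()) {
  check_transcriptome(transcriptome)
  n <- nrow(transcriptome)
  missing_ko <- setdiff(params$knockout_ids, transcriptome$id)
  if (length(missing_ko) > 0) {
    abort(paste0("Knockout id not in transcriptome: '", missing_ko[1], "'."))
  }
  withr::local_seed(params$seed + 1L)
  base <- params$baseline_log2 + rnorm(n, 0, params$abundance_sd)
  ko <- transcriptome$id %in% params$knockout_ids
  n_de <- floor(params$frac_de * n)
  eligible <- which(!ko)
  if (n_de > length(eligible)) n_de <- length(eligible)
  de_idx <- if (n_de > 0) sample(eligible, n_de) else integer()
  de <- seq_len(n) %in% de_idx
  sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
  trt <- base + ifelse(de, sign * params$effect_log2, 0)
  tibble::tibble(
    transcript_id = transcriptome$id,
    true_log2_ref = ifelse(ko, NA_real_, base),
    true_log2_trt = ifelse(ko, NA_real_, trt),
    de_flag = de & !ko,
    knockout_flag = ko
  )
}

## Shared two-channel intensity generator. Green (Cy3) carries the reference
## condition; red (Cy5) carries `trt_log2` plus the intensity-dependent dye
## bias d(A) = c0 + c1*A + c2*A^2 evaluated at the feature's bias-free mean
## log2 intensity. Absent (knockout) transcripts draw foregrounds from the
## background distribution.
simulate_channels <- function(probes, profile, params, trt_log2) {
  idx <- match(probes$transcript_id, profile$transcript_id)
  if (anyNA(idx)) {
    orphan <- probes$transcript_id[which(is.na(idx))[1]]
    abort(paste0("Probe targets transcript '", orphan,
                 "' absent from the expression profile."))
  }
  n_p <- nrow(probes)
  ref <- profile$true_log2_ref[idx]
  trt <- trt_log2[idx]
  absent <- is.na(ref)
  withr::local_seed(params$seed + 2L)
  phi <- rnorm(n_p, 0, params$affinity_sd)
  db <- params$dye_bias
  reps <- purrr::map(seq_len(params$n_replicates), function(r) {
    eps3 <- rnorm(n_p, 0, params$noise_sd)
    eps5 <- rnorm(n_p, 0, params$noise_sd)
    l3 <- ref + phi + eps3
    l5_pre <- trt + phi + eps5
    a0 <- (l3 + l5_pre) / 2
    l5 <- l5_pre + db[1] + db[2] * a0 + db[3] * a0^2
    cy3_fg <- 2^l3
    cy5_fg <- 2^l5
    if (any(absent)) {
      cy3_fg[absent] <- 2^rnorm(sum(absent), params$bg_log2_mean,
                                params$bg_log2_sd)
      cy5_fg[absent] <- 2^rnorm(sum(absent), params$bg_log2_mean,
                                params$bg_log2_sd)
    }
    tibble::tibble(
      probe_id = probes$probe_id,
      replicate = r,
      cy3_fg = cy3_fg,
      cy3_bg = 2^rnorm(n_p, params$bg_log2_mean, params$bg_log2_sd),
      cy5_fg = cy5_fg,
      cy5_bg = 2^rnorm(n_p, params$bg_log2_mean, params$bg_log2_sd)
    )
  })
  dplyr::bind_rows(reps)
}

#' Simulate two-channel hybridization intensities
#'
#' Generates replicate feature intensities for a probe set against a
#' ground-truth expression profile. On the log2 scale, the green (Cy3,
#' reference) foreground is `true_log2_ref + phi + eps` and the red (Cy5,
#' treatment) foreground is `true_log2_trt + phi + eps' + d(A)`, where `phi`
#' is a per-probe affinity fixed across replicates, `eps` is fresh Gaussian
#' noise per measurement, and `d(A)` is the quadratic dye bias evaluated at
#' the feature's bias-free mean intensity. Backgrounds are lognormal;
#' knockout transcripts contribute background-only foregrounds in both
#' channels.
#'
#' @param probes Probe tibble with `probe_id` and `transcript_id`.
#' @param profile Expression profile from [simulate_expression()].
#' @inheritParams simulate_expression
#' @return Feature-intensity tibble with columns `probe_id`, `replicate`,
#'   `cy3_fg`, `cy3_bg`, `cy5_fg`, `cy5_bg`.
#' @export
simulate_hybridization <- function(probes, profile, params = sim_params()) {
  simulate_channels(probes, profile, params, profile$true_log2_trt)
}

#' Simulate a self-self hybridization
#'
#' Both channels are generated from the reference abundances (the treatment
#' profile is ignored), emulating the dye-test design in which one RNA
#' sample is labeled with both dyes and co-hybridized. The dye bias `d(A)`
#' is still applied to the red channel, so any deviation of M from zero is
#' purely technical.
#'
#' @inheritParams simulate_hybridization
#' @return Feature-intensity tibble as in [simulate_hybridization()].
#' @export
simulate_self_self <- function(probes, profile, params = sim_params()) {
  simulate_channels(probes, profile, params, profile$true_log2_ref)
}
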