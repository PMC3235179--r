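#' Probe design parameters
#'
#' Bundles the constraints under which 60-mer probes are enumerated, filtered
#' and selected. Defaults correspond to the array design this package
#' implements: 60 nt probes, three probes per transcript, a 40--60% GC band,
#' an 80--90 degree Celsius melting-temperature band at 0.3 M sodium, and a
#' mild 3'-end preference.
#'
#' @param probe_length Probe length in nucleotides.
#' @param k Maximum number of probes selected per transcript.
#' @param gc_min,gc_max Admissible G+C content band, in percent.
#' @param tm_min,tm_max Admissible melting-temperature band, in degrees
#'   Celsius (salt-adjusted long-oligo formula, see
#'   [melting_temperature()]).
#' @param na_molar Sodium concentration (mol/L) used for the Tm estimate.
#' @param min_spacing Minimum gap, in nucleotides, between the intervals of
#'   two selected probes on the same transcript.
#' @param max_homopolymer Longest tolerated single-base run inside a probe.
#' @param position_weight Weight in `[0, 1]` given to the 3'-position score in
#'   the composite ranking (the remainder weights GC centrality).
#'
#' @return A list of class `design_params`.
#' @examples
#' design_params()
#' design_params(gc_min = 35, gc_max = 65)
#' @export
design_params <- function(probe_length = 60,
                          k = 3,
                          gc_min = 40,
                          gc_max = 60,
                          tm_min = 80,
                          tm_max = 90,
                          na_molar = 0.3,
                          min_spacing = 10,
                          max_homopolymer = 6,
                          position_weight = 0.3) {
  p <- list(
    probe_length = as.integer(probe_length), k = as.integer(k),
    gc_min = gc_min, gc_max = gc_max, tm_min = tm_min, tm_max = tm_max,
    na_molar = na_molar, min_spacing = as.integer(min_spacing),
    max_homopolymer = as.integer(max_homopolymer),
    position_weight = position_weight
  )
  if (p$probe_length < 1) abort("`probe_length` must be >= 1.")
  if (p$k < 1) abort("`k` must be >= 1.")
  if (!(p$gc_min >= 0 && p$gc_min <= p$gc_max && p$gc_max <= 100)) {
    abort("Need 0 <= gc_min <= gc_max <= 100.")
  }
  if (p$tm_min > p$tm_max) abort("`tm_min` must not exceed `tm_max`.")
  if (p$na_molar <= 0) abort("`na_molar` must be positive.")
  if (p$min_spacing < 0) abort("`min_spacing` must be >= 0.")
  if (p$max_homopolymer < 1) abort("`max_homopolymer` must be >= 1.")
  if (p$position_weight < 0 || p$position_weight > 1) {
    abort("`position_weight` must lie in [0, 1].")
  }
  structure(p, class = "design_params")
}

#' Simulation parameters for synthetic hybridizations
#'
#' Controls the seeded generator of synthetic transcriptomes, expression
#' profiles and two-channel feature intensities. The defaults emulate a
#' nutrient-stress style experiment: a moderate fraction of transcripts
#' shifted four-fold (|log2| = 2) in either direction, per-probe affinity
#' spread, per-measurement noise, a quadratic intensity-dependent dye bias on
#' the red channel, and a lognormal background well separated from signal.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param length_range Two-element integer vector: transcript lengths are
#'   drawn uniformly from this closed interval (nt).
#' @param gc_mean Expected GC fraction of simulated sequences, in `[0, 1]`.
#' @param frac_de Fraction of transcripts that are truly differentially
#'   expressed; `floor(frac_de * n_transcripts)` transcripts are shifted.
#' @param effect_log2 Magnitude of the true log2 change for DE transcripts
#'   (sign chosen up/down with equal probability).
#' @param noise_sd SD of per-measurement Gaussian noise on the log2 scale.
#' @param affinity_sd SD of the per-probe multiplicative affinity (log2
#'   scale); fixed per probe across replicates.
#' @param dye_bias Numeric coefficients `c(c0, c1, c2)` of the quadratic
#'   `c0 + c1 * A + c2 * A^2` added to the red (Cy5) channel on the log2
#'   scale. The default puts a curved offset of roughly +0.3 log2 units at
#'   mid intensities, curvature that median-centering cannot remove but
#'   lowess can.
#' @param bg_log2_mean,bg_log2_sd Mean and SD (log2 scale) of the lognormal
#'   background fluorescence.
#' @param baseline_log2 Mean true log2 abundance of expressed transcripts.
#' @param abundance_sd SD of the per-transcript baseline abundance spread
#'   (log2 scale); shared by both channels, so it moves A but not M.
#' @param n_replicates Number of replicate arrays.
#' @param knockout_ids Character vector of transcript ids simulated as
#'   knocked out (background-only signal in both channels).
#' @param seed Integer master seed; fixes all randomness of the generator.
#'
#' @return A list of class `sim_params`.
#' @examples
#' sim_params(n_transcripts = 50, seed = 7)
#' @export
sim_params <- function(n_transcripts = 200,
                       length_range = c(500L, 2000L),
                       gc_mean = 0.5,
                       frac_de = 0.1,
                       effect_log2 = 2,
                       noise_sd = 0.25,
                       affinity_sd = 0.5,
                       dye_bias = c(5.3, -1.0, 0.05),
                       bg_log2_mean = 6,
                       bg_log2_sd = 0.5,
                       baseline_log2 = 10,
                       abundance_sd = 1.0,
                       n_replicates = 4,
                       knockout_ids = character(),
                       seed = 1L) {
  p <- list(
    n_transcripts = as.integer(n_transcripts),
    length_range = as.integer(length_range),
    gc_mean = gc_mean, frac_de = frac_de, effect_log2 = effect_log2,
    noise_sd = noise_sd, affinity_sd = affinity_sd, dye_bias = dye_bias,
    bg_log2_mean = bg_log2_mean, bg_log2_sd = bg_log2_sd,
    baseline_log2 = baseline_log2, abundance_sd = abundance_sd,
    n_replicates = as.integer(n_replicates),
    knockout_ids = as.character(knockout_ids),
    seed = as.integer(seed)
  )
  if (p$n_transcripts < 1) abort("`n_transcripts` must be >= 1.")
  if (length(p$length_range) != 2 || any(p$length_range < 1) ||
      p$length_range[1] > p$length_range[2]) {
    abort("`length_range` must be an increasing pair of lengths >= 1.")
  }
  if (p$gc_mean < 0 || p$gc_mean > 1) abort("`gc_mean` must lie in [0, 1].")
  if (p$frac_de < 0 || p$frac_de > 1) abort("`frac_de` must lie in [0, 1].")
  if (p$noise_sd < 0 || p$affinity_sd < 0 || p$bg_log2_sd < 0 ||
      p$abundance_sd < 0) {
    abort("Standard deviations must be >= 0.")
  }
  if (length(p$dye_bias) != 3) abort("`dye_bias` needs 3 coefficients.")
  if (p$n_replicates < 1) abort("`n_replicates` must be >= 1.")
  structure(p, class = "sim_params")
}

#' Expression-analysis parameters
#'
#' Tuning knobs of the two-color analysis pipeline: background detection,
#' lowess normalization, and the significance plus fold-change rule used to
#' call differential expression.
#'
#' @param detection_k Multiplier of the background SD: a channel is detected
#'   when its foreground exceeds `bg_mean + detection_k * bg_sd` (strictly).
#' @param lowess_span Fraction of features forming each local neighbourhood
#'   of the M-vs-A lowess fit, in `(0, 1]`.
#' @param lowess_iterations Number of robustness (residual reweighting)
#'   iterations of the lowess fit.
#' @param alpha Significance level applied to Holm-adjusted p-values.
#' @param min_abs_log2 Minimum |mean log2 ratio| for a DE call; the default 1
#'   is the classical two-fold rule.
#' @param floor Positive value at which background-subtracted intensities are
#'   floored before taking logs, in fluorescence units.
#'
#' @return A list of class `analysis_params`.
#' @examples
#' analysis_params(alpha = 0.01)
#' @export
analysis_params <- function(detection_k = 2,
                            lowess_span = 0.3,
                            lowess_iterations = 3,
                            alpha = 0.05,
                            min_abs_log2 = 1,
                            floor = 1) {
  p <- list(
    detection_k = detection_k, lowess_span = lowess_span,
    lowess_iterations = as.integer(lowess_iterations), alpha = alpha,
    min_abs_log2 = min_abs_log2, floor = floor
  )
  if (p$detection_k < 0) abort("`detection_k` must be >= 0.")
  if (p$lowess_span <= 0 || p$lowess_span > 1) {
    abort("`lowess_span` must lie in (0, 1].")
  }
  if (p$lowess_iterations < 0) abort("`lowess_iterations` must be >= 0.")
  if (p$alpha <= 0 || p$alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (p$min_abs_log2 < 0) abort("`min_abs_log2` must be >= 0.")
  if (p$floor <= 0) abort("`floor` must be positive.")
  structure(p, class = "analysis_params")
}
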