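#' Feature detection against background
#'
#' A channel is detected when its foreground strictly exceeds
#' `bg_mean + detection_k * bg_sd`. Features used for analysis must pass in
#' both channels; combine two calls with `&`.
#'
#' @param fg Foreground intensities (`>= 0`).
#' @param bg_mean,bg_sd Background mean and SD (`>= 0`), typically estimated
#'   from all background values of the channel on one array.
#' @param detection_k Background SD multiplier.
#' @return Logical vector of detection flags.
#' @examples
#' detect_feature(c(1000, 150, 200), bg_mean = 100, bg_sd = 50)
#' @export
detect_feature <- function(fg, bg_mean, bg_sd, detection_k = 2) {
  if (any(fg < 0) || any(bg_mean < 0) || any(bg_sd < 0)) {
    abort("Intensities and background statistics must be >= 0.")
  }
  fg > bg_mean + detection_k * bg_sd
}

#' Compute M and A from two-channel intensities
#'
#' Background-subtracts each channel, floors the result at `floor`
#' fluorescence units so logs stay finite, and returns the log2 ratio
#' `M = log2(r / g)` and mean log intensity `A = 0.5 * log2(r * g)`, where
#' `r` and `g` are the floored red (Cy5) and green (Cy3) net intensities.
#'
#' @param cy5_fg,cy5_bg Red-channel foreground and background.
#' @param cy3_fg,cy3_bg Green-channel foreground and background.
#' @param floor Positive flooring value for background-subtracted
#'   intensities.
#' @return Tibble with columns `M` and `A`.
#' @examples
#' compute_ma(2048, 0, 1024, 0)
#' @export
compute_ma <- function(cy5_fg, cy5_bg, cy3_fg, cy3_bg, floor = 1) {
  if (any(c(cy5_fg, cy5_bg, cy3_fg, cy3_bg) < 0)) {
    abort("Intensities must be >= 0.")
  }
  if (floor <= 0) abort("`floor` must be positive.")
  r <- pmax(cy5_fg - cy5_bg, floor)
  g <- pmax(cy3_fg - cy3_bg, floor)
  tibble::tibble(M = log2(r / g), A = 0.5 * log2(r * g))
}

#' Lowess normalization of M against A
#'
#' Fits a robust locally-weighted linear regression of M on A (tri-cube
#' kernel over the `span` fraction of nearest neighbours, with `iterations`
#' residual-reweighting passes) and subtracts the fitted curve, removing
#' intensity-dependent dye bias. The fit is deterministic.
#'
#' @param features Tibble with numeric columns `M` and `A`, one row per
#'   detected feature. At least 10 features are required.
#' @param span Neighbourhood fraction in `(0, 1]`.
#' @param iterations Number of robustness iterations.
#' @return `features` with `M` replaced by the normalized value and two
#'   added columns: `M_raw` (the input M) and `fitted` (the lowess curve at
#'   the feature's A).
#' @export
lowess_normalize <- function(features, span = 0.3, iterations = 3) {
  if (!is.data.frame(features) || !all(c("M", "A") %in% names(features))) {
    abort("`features` must be a data frame with columns `M` and `A`.")
  }
  n <- nrow(features)
  if (n < 10) {
    abort(paste0(
      "Only ", n, " features; lowess normalization needs >= 10. ",
      "Consider a global-median fallback for such small feature sets."
    ))
  }
  o <- order(features$A)
  fit <- stats::lowess(features$A[o], features$M[o], f = span,
                       iter = iterations)
  fitted <- numeric(n)
  fitted[o] <- fit$y
  features$M_raw <- features$M
  features$fitted <- fitted
  features$M <- features$M - fitted
  features
}

#' Aggregate normalized ratios per transcript
#'
#' Pools all detected observations of a transcript (its probes times the
#' replicates) and reports their arithmetic mean, sample SD and count. With
#' a single observation the SD is reported as 0.
#'
#' @param features Tibble with columns `transcript_id` and `M` (one row per
#'   detected observation).
#' @return Tibble with one row per transcript: `transcript_id`, `mean_M`,
#'   `sd_M`, `n_obs`.
#' @export
aggregate_transcripts <- function(features) {
  if (!is.data.frame(features) ||
      !all(c("transcript_id", "M") %in% names(features))) {
    abort("`features` must have columns `transcript_id` and `M`.")
  }
  features |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      mean_M = mean(.data$M),
      sd_M = ifelse(dplyr::n() > 1, stats::sd(.data$M), 0),
      n_obs = dplyr::n(),
      .groups = "drop"
    )
}

p_one_sample <- function(x) {
  n <- length(x)
  if (n < 2) return(1)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    if (m == 0) return(1) else return(.Machine$double.xmin)
  }
  stats::t.test(x, mu = 0)$p.value
}

#' Test a transcript's normalized ratios against zero
#'
#' Two-sided one-sample t-test of the mean normalized log2 ratio against 0.
#' Degenerate inputs follow fixed rules: fewer than two observations give
#' p = 1 (with a warning); zero variance gives p = 1 when the mean is also 0
#' and the smallest positive representable p otherwise.
#'
#' @param observations Numeric vector of normalized M values of one
#'   transcript.
#' @return A single p-value in `(0, 1]`.
#' @examples
#' test_differential(c(-1, 1))
#' test_differential(c(1.9, 2.0, 2.1))
#' @export
test_differential <- function(observations) {
  x <- observations[!is.na(observations)]
  if (length(x) < 2) {
    warn("Fewer than 2 observations; returning p = 1.")
  }
  p_one_sample(x)
}

#' Holm-Bonferroni step-down p-value adjustment
#'
#' Adjusts a family of p-values with the Holm step-down procedure:
#' after sorting ascending, `adjusted(i) = min(1, max_{j <= i} (m - j + 1) *
#' p(j))`, mapped back to input order. Controls the familywise error rate.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.2))
#' @export
holm_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("`p_values` must lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Call differential expression
#'
#' Flags a transcript as differentially expressed when its Holm-adjusted
#' p-value is below `alpha` and its |mean log2 ratio| reaches
#' `min_abs_log2` (the default 1 is the two-fold rule). Direction is `up`
#' or `down` by the sign of `mean_M` for DE transcripts and `none`
#' otherwise.
#'
#' @param results Tibble with columns `mean_M` and `p_adjusted`.
#' @param alpha Significance level.
#' @param min_abs_log2 Fold-change threshold on the log2 scale.
#' @return `results` with columns `de_flag` (logical) and `direction`
#'   (factor up/down/none) added.
#' @export
call_de <- function(results, alpha = 0.05, min_abs_log2 = 1) {
  if (!all(c("mean_M", "p_adjusted") %in% names(results))) {
    abort("`results` must have columns `mean_M` and `p_adjusted`.")
  }
  de <- results$p_adjusted < alpha & abs(results$mean_M) >= min_abs_log2
  dir <- ifelse(!de, "none", ifelse(results$mean_M > 0, "up", "down"))
  results$de_flag <- de
  results$direction <- factor(dir, levels = c("up", "down", "none"))
  results
}

#' Run the full two-color expression analysis
#'
#' The complete pipeline for one experiment: per-array background detection
#' (both channels must exceed `bg_mean + k * bg_sd`, estimated per replicate
#' and channel from the feature backgrounds), MA computation with floored
#' background subtraction, per-replicate lowess normalization of M against
#' A over detected features, pooling of probes and replicates per
#' transcript, a one-sample t-test of the mean normalized ratio against 0,
#' Holm-Bonferroni correction across all tested transcripts, and the
#' significance-plus-two-fold DE call. Transcripts without any detected
#' observation are excluded and listed in the returned object.
#'
#' @param intensities Feature-intensity tibble (`probe_id`, `replicate`,
#'   `cy3_fg`, `cy3_bg`, `cy5_fg`, `cy5_bg`), e.g. from
#'   [simulate_hybridization()].
#' @param probes Probe tibble mapping `probe_id` to `transcript_id`.
#' @param params An [analysis_params()] object.
#' @return An object of class `expression_analysis` with components
#'   `results` (per-transcript tibble: `transcript_id`, `mean_M`, `sd_M`,
#'   `n_obs`, `p_value`, `p_adjusted`, `de_flag`, `direction`), `features`
#'   (per-feature tibble with detection flags and raw/normalized M),
#'   `excluded` (transcript ids with no detected feature), and `params`.
#'   [tidy()] returns the results, [glance()] a one-row summary,
#'   [autoplot()] the MA plots before and after normalization.
#' @export
analyze_experiment <- function(intensities, probes,
                               params = analysis_params()) {
  needed <- c("probe_id", "replicate", "cy3_fg", "cy3_bg", "cy5_fg", "cy5_bg")
  if (!is.data.frame(intensities) || !all(needed %in% names(intensities))) {
    abort(paste0("`intensities` must have columns: ",
                 paste(needed, collapse = ", "), "."))
  }
  if (!all(c("probe_id", "transcript_id") %in% names(probes))) {
    abort("`probes` must have columns `probe_id` and `transcript_id`.")
  }
  idx <- match(intensities$probe_id, probes$probe_id)
  if (anyNA(idx)) {
    abort(paste0("Intensity row refers to unknown probe '",
                 intensities$probe_id[which(is.na(idx))[1]], "'."))
  }
  feats <- intensities
  feats$transcript_id <- probes$transcript_id[idx]

  feats <- feats |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(
      detected = detect_feature(.data$cy3_fg, mean(.data$cy3_bg),
                                stats::sd(.data$cy3_bg), params$detection_k) &
        detect_feature(.data$cy5_fg, mean(.data$cy5_bg),
                       stats::sd(.data$cy5_bg), params$detection_k)
    ) |>
    dplyr::ungroup()

  ma <- compute_ma(feats$cy5_fg, feats$cy5_bg, feats$cy3_fg, feats$cy3_bg,
                   floor = params$floor)
  feats$M <- ma$M
  feats$A <- ma$A

  detected <- feats[feats$detected, , drop = FALSE]
  normalized <- detected |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(d, key) {
      lowess_normalize(d, span = params$lowess_span,
                       iterations = params$lowess_iterations)
    }) |>
    dplyr::ungroup()

  results <- aggregate_transcripts(normalized)
  p <- vapply(split(normalized$M, normalized$transcript_id), p_one_sample,
              numeric(1))
  results$p_value <- unname(p[results$transcript_id])
  results$p_adjusted <- holm_adjust(results$p_value)
  results <- call_de(results, alpha = params$alpha,
                     min_abs_log2 = params$min_abs_log2)

  structure(
    list(
      results = results,
      features = normalized[, c("probe_id", "transcript_id", "replicate",
                                "A", "M_raw", "M", "detected")],
      all_features = feats[, c("probe_id", "transcript_id", "replicate",
                               "A", "M", "detected")],
      excluded = setdiff(unique(probes$transcript_id),
                         results$transcript_id),
      params = params
    ),
    class = "expression_analysis"
  )
}

#' @export
print.expression_analysis <- function(x, ...) {
  cat("<expression_analysis>\n")
  cat(sprintf("  transcripts tested: %d (%d excluded, no detected feature)\n",
              nrow(x$results), length(x$excluded)))
  cat(sprintf("  DE calls:           %d up, %d down\n",
              sum(x$results$direction == "up"),
              sum(x$results$direction == "down")))
  invisible(x)
}

#' @describeIn analyze_experiment Per-transcript results table.
#' @param x An `expression_analysis` object.
#' @param ... Unused.
#' @export
tidy.expression_analysis <- function(x, ...) {
  x$results
}

#' @describeIn analyze_experiment One-row experiment summary.
#' @export
glance.expression_analysis <- function(x, ...) {
  tibble::tibble(
    n_transcripts_tested = nrow(x$results),
    n_excluded = length(x$excluded),
    n_features = nrow(x$all_features),
    fraction_detected = mean(x$all_features$detected),
    n_de = sum(x$results$de_flag),
    n_up = sum(x$results$direction == "up"),
    n_down = sum(x$results$direction == "down")
  )
}

#' @describeIn analyze_experiment MA plots of detected features before and
#'   after lowess normalization.
#' @param object An `expression_analysis` object.
#' @export
autoplot.expression_analysis <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$features[, c("A", "M_raw", "M")],
    cols = c("M_raw", "M"),
    names_to = "stage", values_to = "value"
  )
  df$stage <- factor(df$stage, levels = c("M_raw", "M"),
                     labels = c("raw", "normalized"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$A, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "red", linewidth = 0.3) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "A (mean log2 intensity)", y = "M (log2 ratio)") +
    ggplot2::theme_bw()
}

#' Per-probe detection summary of an experiment
#'
#' Reduces per-feature (probe by replicate) detection flags to one flag per
#' probe: a probe counts as detected when it is detected in more than half
#' of the replicates. This is the input expected by [detect_knockout()].
#'
#' @inheritParams analyze_experiment
#' @return Tibble with columns `probe_id`, `transcript_id`, `detected`.
#' @export
summarize_probe_detection <- function(intensities, probes,
                                      params = analysis_params()) {
  fit <- analyze_experiment_detection_only(intensities, probes, params)
  fit |>
    dplyr::group_by(.data$probe_id, .data$transcript_id) |>
    dplyr::summarise(
      detected = mean(.data$detected) > 0.5,
      .groups = "drop"
    )
}

## Detection flags without the normalization/testing stages (used for
## knockout screening, where mutant arrays may detect almost nothing and a
## lowess fit would be meaningless).
analyze_experiment_detection_only <- function(intensities, probes, params) {
  idx <- match(intensities$probe_id, probes$probe_id)
  if (anyNA(idx)) {
    abort(paste0("Intensity row refers to unknown probe '",
                 intensities$probe_id[which(is.na(idx))[1]], "'."))
  }
  feats <- intensities
  feats$transcript_id <- probes$transcript_id[idx]
  feats |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(
      detected = detect_feature(.data$cy3_fg, mean(.data$cy3_bg),
                                stats::sd(.data$cy3_bg), params$detection_k) &
        detect_feature(.data$cy5_fg, mean(.data$cy5_bg),
                       stats::sd(.data$cy5_bg), params$detection_k)
    ) |>
    dplyr::ungroup()
}
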