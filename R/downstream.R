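#' Average per-time-point log2 ratios over a time course
#'
#' Computes the unweighted mean of the per-time-point mean log2 ratios of
#' each transcript over whichever time points are available for it, the way
#' multi-day starvation series are commonly reported as a single value per
#' gene.
#'
#' @param results Tibble with columns `transcript_id`, `time_point` and
#'   `mean_M` (typically several [analyze_experiment()] results bound
#'   together with a `time_point` label).
#' @return Tibble with one row per transcript: `transcript_id`, `mean_M`
#'   (time-course average) and `n_timepoints`.
#' @export
timecourse_average <- function(results) {
  needed <- c("transcript_id", "time_point", "mean_M")
  if (!is.data.frame(results) || !all(needed %in% names(results))) {
    abort(paste0("`results` must have columns: ",
                 paste(needed, collapse = ", "), "."))
  }
  if (nrow(results) == 0) {
    abort("`results` is empty; nothing to average.")
  }
  results |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      mean_M = mean(.data$mean_M),
      n_timepoints = dplyr::n(),
      .groups = "drop"
    )
}

#' Ward clustering of expression profiles
#'
#' Agglomerative hierarchical clustering of per-transcript profiles (for
#' example time-point means) with the Euclidean metric and Ward linkage,
#' cut into `n_clusters` groups. The procedure is deterministic for a given
#' row order.
#'
#' @param profiles Tibble with a `transcript_id` column and one numeric
#'   column per time point / condition (no missing values), or a numeric
#'   matrix with row names.
#' @param n_clusters Number of clusters to cut the tree into.
#' @return Tibble with columns `transcript_id` and `cluster` (integer
#'   labels 1..`n_clusters`).
#' @export
hierarchical_cluster <- function(profiles, n_clusters) {
  if (is.data.frame(profiles)) {
    if (!"transcript_id" %in% names(profiles)) {
      abort("`profiles` must have a `transcript_id` column.")
    }
    ids <- profiles$transcript_id
    mat <- as.matrix(profiles[setdiff(names(profiles), "transcript_id")])
  } else if (is.matrix(profiles)) {
    ids <- rownames(profiles)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(profiles)))
    mat <- profiles
  } else {
    abort("`profiles` must be a data frame or a matrix.")
  }
  if (anyNA(mat)) abort("`profiles` must be complete (no missing values).")
  if (n_clusters > nrow(mat)) {
    abort("`n_clusters` exceeds the number of transcripts.")
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  tibble::tibble(
    transcript_id = ids,
    cluster = unname(stats::cutree(hc, k = n_clusters))
  )
}

#' Concordance of differential-expression patterns between two platforms
#'
#' Compares per-transcript direction categories (up/down/none) from two
#' analyses over their shared transcripts. Restricted to transcripts called
#' DE on at least one platform, the concordance is the fraction whose
#' category is identical on both.
#'
#' @param calls_a,calls_b Tibbles with columns `transcript_id` and
#'   `direction` (e.g. `tidy(analyze_experiment(...))`).
#' @return One-row tibble: `n_compared`, `n_identical`,
#'   `fraction_identical`.
#' @examples
#' a <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
#'                     direction = c("up", "up", "down"))
#' b <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
#'                     direction = c("up", "down", "down"))
#' concordance(a, b)
#' @export
concordance <- function(calls_a, calls_b) {
  for (d in list(calls_a, calls_b)) {
    if (!is.data.frame(d) ||
        !all(c("transcript_id", "direction") %in% names(d))) {
      abort("Call sets must have columns `transcript_id` and `direction`.")
    }
  }
  shared <- intersect(calls_a$transcript_id, calls_b$transcript_id)
  if (length(shared) == 0) {
    abort("The two call sets share no transcript ids.")
  }
  dir_a <- as.character(calls_a$direction[match(shared, calls_a$transcript_id)])
  dir_b <- as.character(calls_b$direction[match(shared, calls_b$transcript_id)])
  de_any <- dir_a != "none" | dir_b != "none"
  n_compared <- sum(de_any)
  n_identical <- sum(dir_a[de_any] == dir_b[de_any])
  tibble::tibble(
    n_compared = n_compared,
    n_identical = n_identical,
    fraction_identical = if (n_compared > 0) n_identical / n_compared
                         else NA_real_
  )
}

#' Call transcript knockouts from paired detection flags
#'
#' Declares a transcript `absent` when none of its probes are detected in
#' the mutant while at least one is detected in the control, `present` when
#' at least one probe is detected in both samples, and `indeterminate`
#' otherwise (in particular when the transcript is undetected in both).
#'
#' @param control_detect,mutant_detect Tibbles with columns `probe_id`,
#'   `transcript_id`, `detected` (see [summarize_probe_detection()]); both
#'   must cover the same probe set.
#' @return Tibble with columns `transcript_id` and `status` (factor
#'   present/absent/indeterminate).
#' @export
detect_knockout <- function(control_detect, mutant_detect) {
  needed <- c("probe_id", "transcript_id", "detected")
  for (d in list(control_detect, mutant_detect)) {
    if (!is.data.frame(d) || !all(needed %in% names(d))) {
      abort(paste0("Detection tables must have columns: ",
                   paste(needed, collapse = ", "), "."))
    }
  }
  if (!setequal(control_detect$probe_id, mutant_detect$probe_id)) {
    abort("Control and mutant cover different probe sets.")
  }
  m <- mutant_detect$detected[match(control_detect$probe_id,
                                    mutant_detect$probe_id)]
  merged <- tibble::tibble(
    transcript_id = control_detect$transcript_id,
    control = control_detect$detected,
    mutant = m
  )
  merged |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      any_control = any(.data$control),
      any_mutant = any(.data$mutant),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      status = factor(
        dplyr::case_when(
          !.data$any_mutant & .data$any_control ~ "absent",
          .data$any_mutant & .data$any_control ~ "present",
          .default = "indeterminate"
        ),
        levels = c("present", "absent", "indeterminate")
      )
    ) |>
    dplyr::select("transcript_id", "status")
}
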