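# Phase II/III analysis: firefly/Renilla normalisation, percent-of-control
# and percent-inhibition computation, replicate aggregation, and threshold
# classification with at-least-one-amplicon logic.

#' Normalised reporter activity (firefly/Renilla ratio)
#'
#' The inducible (firefly) channel divided by the constitutive (Renilla)
#' channel of the same well. Any multiplicative factor common to both
#' channels — a plate effect, a pipetting volume, cell number — cancels
#' exactly in the ratio.
#'
#' @param firefly,renilla Non-negative luminescence readings (vectorised).
#' @return Dimensionless ratio(s).
#' @export
normalized_activity <- function(firefly, renilla) {
  if (any(is.na(renilla)) || any(renilla <= 0))
    stop("renilla reading missing or non-positive: well flagged as a viability/measurement failure",
         call. = FALSE)
  if (any(firefly < 0, na.rm = TRUE))
    stop("negative firefly luminescence", call. = FALSE)
  firefly / renilla
}

#' Percent inhibition relative to on-plate negative controls
#'
#' Expresses a sample's normalised activity as a percentage of the mean of
#' the negative-control (GFP dsRNA) well ratios — taken from the *same
#' plate* — and returns 100 minus that percentage. Inhibition can be
#' negative (activation above control); it is reported as-is, never
#' clipped, but negative values never promote a hit downstream.
#'
#' @param sample_ratio Normalised activity of the sample well(s)
#'   (vectorised).
#' @param control_ratios Normalised activities of the plate's negative
#'   control wells (at least one, all > 0).
#' @return Percent inhibition; <= 100 always.
#' @export
percent_inhibition <- function(sample_ratio, control_ratios) {
  if (!length(control_ratios))
    stop("no valid negative-control wells on plate", call. = FALSE)
  if (any(is.na(control_ratios)) || any(control_ratios <= 0))
    stop("control ratios must all be positive", call. = FALSE)
  100 - 100 * sample_ratio / mean(control_ratios)
}

#' Mean, SD and count of replicate percent-inhibition values
#'
#' @param values Numeric vector (n >= 1) of per-replicate percentages.
#' @return List with `mean`, `sd` (NA when n < 2; sample SD otherwise) and
#'   `n`.
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1, !anyNA(values))
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Per-amplicon inhibition summaries from a dual-reporter dataset
#'
#' For every sample well: compute the firefly/Renilla ratio, normalise to
#' the mean ratio of the same plate's negative-control wells, convert to
#' percent inhibition, then aggregate each reagent's replicate values into
#' a mean/SD summary keyed by gene and amplicon.
#'
#' @param ds A `screen_dataset` whose non-empty wells carry Renilla
#'   readings.
#' @param annotation Reagent table (`reagent_id`, `target_gene_id`,
#'   `amplicon_index`).
#' @return data.frame with columns `gene_id`, `amplicon_index`,
#'   `mean_inhibition`, `sd_inhibition`, `n`.
#' @export
score_dual_reporter <- function(ds, annotation) {
  stopifnot(inherits(ds, "screen_dataset"))
  w <- ds$wells[ds$wells$role != "empty", ]
  per_plate <- lapply(split(w, w$plate_id), function(pw) {
    ctrl <- pw[pw$role == "negative_control", ]
    if (!nrow(ctrl))
      stop("plate ", pw$plate_id[1], ": no negative-control wells",
           call. = FALSE)
    ctrl_ratio <- normalized_activity(ctrl$firefly, ctrl$renilla)
    smp <- pw[pw$role == "sample", ]
    if (!nrow(smp)) return(NULL)
    data.frame(reagent_id = smp$reagent_id,
               replicate = unname(ds$replicate_map[smp$plate_id]),
               pct_inhibition = percent_inhibition(
                 normalized_activity(smp$firefly, smp$renilla), ctrl_ratio),
               stringsAsFactors = FALSE)
  })
  pct <- do.call(rbind, per_plate)
  pct <- merge(pct, annotation, by = "reagent_id")
  rows <- lapply(split(pct, pct$reagent_id), function(g) {
    a <- aggregate_replicates(g$pct_inhibition)
    data.frame(gene_id = g$target_gene_id[1],
               amplicon_index = g$amplicon_index[1],
               mean_inhibition = a$mean, sd_inhibition = a$sd, n = a$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$gene_id, res$amplicon_index), ]
  rownames(res) <- NULL
  res
}

max_inhibition_by_gene <- function(amplicon_summary) {
  stopifnot(all(c("gene_id", "mean_inhibition") %in% names(amplicon_summary)),
            nrow(amplicon_summary) >= 1)
  agg <- stats::aggregate(mean_inhibition ~ gene_id, data = amplicon_summary,
                          FUN = max)
  cnt <- stats::aggregate(mean_inhibition ~ gene_id, data = amplicon_summary,
                          FUN = length)
  data.frame(gene_id = agg$gene_id, max_inhibition = agg$mean_inhibition,
             n_amplicons = cnt$mean_inhibition, stringsAsFactors = FALSE)
}

#' Secondary-screen classification (group A / group B / non-hit)
#'
#' A gene is a secondary-screen hit when *at least one* of its amplicons
#' gives a mean inhibition strictly greater than the hit threshold (50%).
#' Hits are stratified by the strongest amplicon m: group A when m is
#' strictly over the strong threshold (75%), group B when
#' 50 < m <= 75. Both inequalities are strict at the lower bound, matching
#' the "more than 50%" / "over 75%" reading; genes with a single amplicon
#' are classified on that amplicon alone.
#'
#' @param amplicon_summary data.frame with `gene_id`, `amplicon_index`,
#'   `mean_inhibition` (e.g. from [score_dual_reporter()] or
#'   [table1_amplicon_summaries()]).
#' @param hit_threshold,strong_threshold Percent-inhibition thresholds
#'   (defaults 50 and 75).
#' @return data.frame with one row per gene: `gene_id`, `max_inhibition`,
#'   `n_amplicons`, `label` in {group_A, group_B, non_hit}.
#' @export
classify_secondary <- function(amplicon_summary, hit_threshold = 50,
                               strong_threshold = 75) {
  stopifnot(hit_threshold > 0, hit_threshold < 100,
            strong_threshold > hit_threshold, strong_threshold < 100)
  res <- max_inhibition_by_gene(amplicon_summary)
  res$label <- ifelse(res$max_inhibition > strong_threshold, "group_A",
               ifelse(res$max_inhibition > hit_threshold, "group_B",
                      "non_hit"))
  res
}

#' Tertiary-screen classification (positive / negative)
#'
#' A gene re-tested in hypoxia scores positive when at least one of its
#' amplicons gives a mean inhibition strictly greater than the threshold
#' (50%).
#'
#' @inheritParams classify_secondary
#' @param threshold Percent-inhibition threshold (default 50).
#' @return data.frame with one row per gene: `gene_id`, `max_inhibition`,
#'   `n_amplicons`, `label` in {positive, negative}.
#' @export
classify_tertiary <- function(amplicon_summary, threshold = 50) {
  stopifnot(threshold > 0, threshold < 100)
  res <- max_inhibition_by_gene(amplicon_summary)
  res$label <- ifelse(res$max_inhibition > threshold, "positive", "negative")
  res
}
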