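# Phase-I analysis: plate-wise Z-scores of the single-reporter signal,
# replicate summaries, threshold hit calling, and replicate-agreement
# diagnostics.

#' Plate-wise Z-scores of well luminescence
#'
#' For every non-empty well, z = (signal - plate mean) / plate SD, with mean
#' and SD computed over the whole plate's non-empty wells (controls included
#' by default; the normalisation is over "the whole plate"). The SD is the
#' sample SD (denominator n - 1) by default; both the control handling and
#' the denominator are flags because screening centres differ on them and
#' the difference is negligible at 384 wells.
#'
#' @param ds A `screen_dataset`.
#' @param include_controls Include control wells in the plate mean/SD
#'   (default TRUE). Control wells are scored either way.
#' @param sd_denom "n-1" (sample SD, default) or "n" (population SD).
#' @return data.frame with columns `plate_id`, `row`, `col`, `reagent_id`,
#'   `role`, `replicate`, `z`. Within each plate (with controls included)
#'   the z values have mean 0 and SD 1 to floating tolerance.
#' @export
plate_zscores <- function(ds, include_controls = TRUE,
                          sd_denom = c("n-1", "n")) {
  stopifnot(inherits(ds, "screen_dataset"))
  sd_denom <- match.arg(sd_denom)
  w <- ds$wells[ds$wells$role != "empty", ]
  out <- lapply(split(w, w$plate_id), function(pw) {
    stats_wells <- if (include_controls) pw else pw[pw$role == "sample", ]
    n <- nrow(stats_wells)
    if (n < 3)
      stop("plate ", pw$plate_id[1], ": fewer than 3 wells for plate statistics",
           call. = FALSE)
    m <- mean(stats_wells$firefly)
    s <- stats::sd(stats_wells$firefly)
    if (sd_denom == "n") s <- s * sqrt((n - 1) / n)
    if (!is.finite(s) || s == 0)
      stop("plate ", pw$plate_id[1], ": zero plate SD (degenerate plate)",
           call. = FALSE)
    data.frame(plate_id = pw$plate_id, row = pw$row, col = pw$col,
               reagent_id = pw$reagent_id, role = pw$role,
               replicate = unname(ds$replicate_map[pw$plate_id]),
               z = (pw$firefly - m) / s,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse well Z-scores to per-gene, per-replicate scores
#'
#' Joins sample wells to their reagent annotation and summarises each gene's
#' replicate score as the most inhibitory (minimum) z across its amplicons —
#' the "at least one dsRNA" reading used throughout the screen. With one
#' amplicon per gene (a first-pass library) this is the identity.
#'
#' @param ztab Output of [plate_zscores()].
#' @param annotation Reagent table (`reagent_id`, `target_gene_id`,
#'   `amplicon_index`).
#' @return data.frame with columns `gene_id`, `replicate`, `z`,
#'   `n_amplicons`.
#' @export
gene_zscores <- function(ztab, annotation) {
  s <- ztab[ztab$role == "sample" & !is.na(ztab$reagent_id), ]
  s <- merge(s, annotation, by = "reagent_id")
  if (!nrow(s)) stop("no annotated sample wells", call. = FALSE)
  agg <- stats::aggregate(z ~ target_gene_id + replicate, data = s, FUN = min)
  cnt <- stats::aggregate(z ~ target_gene_id + replicate, data = s, FUN = length)
  names(agg) <- c("gene_id", "replicate", "z")
  agg$n_amplicons <- cnt$z
  agg <- agg[order(agg$gene_id, agg$replicate), ]
  rownames(agg) <- NULL
  agg
}

#' Threshold hit calling on per-gene Z-scores
#'
#' A gene is a primary-screen hit when its Z-score falls strictly below the
#' cut-off (default -2.5). Under `replicate_rule = "any"` (the default) one
#' replicate below the cut-off suffices; under `"mean"` the across-replicate
#' mean must fall below it. The inequality is strict: z exactly at the
#' cut-off is not a hit.
#'
#' @param gene_z Per-gene, per-replicate scores from [gene_zscores()] (or
#'   any data.frame with `gene_id`, `replicate`, `z`).
#' @param cutoff Z-score cut-off (default -2.5).
#' @param replicate_rule "any" or "mean".
#' @return data.frame with one row per gene: `gene_id`, `z_rep<k>` columns
#'   (when every gene has the same replicate count), `z_mean`, `z_min`,
#'   `n_replicates`, `label` in {hit, non_hit}.
#' @export
call_primary_hits <- function(gene_z, cutoff = -2.5,
                              replicate_rule = c("any", "mean")) {
  replicate_rule <- match.arg(replicate_rule)
  stopifnot(all(c("gene_id", "replicate", "z") %in% names(gene_z)),
            nrow(gene_z) >= 1)
  by_gene <- split(gene_z, gene_z$gene_id)
  rows <- lapply(by_gene, function(g) {
    g <- g[order(g$replicate), ]
    data.frame(gene_id = g$gene_id[1],
               z_mean = mean(g$z), z_min = min(g$z),
               n_replicates = nrow(g),
               label = if (replicate_rule == "any") {
                 if (any(g$z < cutoff)) "hit" else "non_hit"
               } else {
                 if (mean(g$z) < cutoff) "hit" else "non_hit"
               },
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # wide per-replicate columns when the replicate structure is balanced
  reps <- sort(unique(gene_z$replicate))
  if (all(vapply(by_gene, nrow, 1L) == length(reps))) {
    for (k in seq_along(reps)) {
      res[[sprintf("z_rep%d", k)]] <-
        vapply(by_gene[res$gene_id], function(g)
          g$z[g$replicate == reps[k]][1], numeric(1))
    }
    res <- res[, c("gene_id", sprintf("z_rep%d", seq_along(reps)),
                   "z_mean", "z_min", "n_replicates", "label")]
  }
  rownames(res) <- NULL
  res
}

#' Pearson correlation between replicate score vectors
#'
#' Replicate-agreement diagnostic for a duplicate screen: the Pearson
#' product-moment correlation of the two replicates' per-reagent scores,
#' paired over the same reagent set.
#'
#' @param z_rep1,z_rep2 Numeric vectors of equal length (>= 3), paired by
#'   reagent.
#' @return Pearson r in [-1, 1].
#' @export
replicate_correlation <- function(z_rep1, z_rep2) {
  if (length(z_rep1) != length(z_rep2))
    stop("replicate vectors must be paired over the same reagent set",
         call. = FALSE)
  if (length(z_rep1) < 3)
    stop("need at least 3 paired reagents", call. = FALSE)
  if (stats::sd(z_rep1) == 0 || stats::sd(z_rep2) == 0)
    stop("zero variance in a replicate", call. = FALSE)
  stats::cor(z_rep1, z_rep2, method = "pearson")
}
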