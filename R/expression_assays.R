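# Downstream quantification assays: relative qPCR expression by the
# delta-delta-Ct method and kinetic beta-galactosidase activity.

#' Delta-Ct of a target gene against a reference gene
#'
#' Averages replicate Ct values on the Ct (cycle) scale — standard practice
#' for the comparative-Ct method — and returns mean Ct(target) minus mean
#' Ct(reference). Adding a constant to every Ct of a sample (instrument
#' drift) leaves the result unchanged.
#'
#' @param ct_target Numeric vector of target-gene Ct values (typically a
#'   triplicate).
#' @param ct_reference Numeric vector of reference-gene (e.g. tubulin) Ct
#'   values from the same sample.
#' @return Delta-Ct in cycles.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (!length(ct_target) || anyNA(ct_target))
    stop("missing target Ct values", call. = FALSE)
  if (!length(ct_reference) || anyNA(ct_reference))
    stop("missing reference-gene Ct values for sample", call. = FALSE)
  stopifnot(all(ct_target > 0), all(ct_reference > 0))
  mean(ct_target) - mean(ct_reference)
}

#' Fold induction by the comparative-Ct method
#'
#' fold = base^-(dCt_sample - dCt_control). The default base of exactly 2
#' assumes 100% amplification efficiency for both target and reference
#' reactions; pass `efficiency` (amplification factor per cycle, in (1, 2])
#' to correct for a measured efficiency.
#'
#' @param delta_ct_sample Delta-Ct of the treated sample.
#' @param delta_ct_control Delta-Ct of the control condition (e.g. GFP
#'   dsRNA, or normoxia).
#' @param efficiency Amplification factor per cycle (default 2).
#' @return Dimensionless fold change; 1 when sample equals control.
#' @export
fold_induction <- function(delta_ct_sample, delta_ct_control, efficiency = 2) {
  stopifnot(is.finite(delta_ct_sample), is.finite(delta_ct_control),
            efficiency > 1, efficiency <= 2)
  efficiency^-(delta_ct_sample - delta_ct_control)
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample_id,gene,replicate,ct`.
#'
#' @param path Path to the CSV file.
#' @return data.frame with those columns.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("header lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tab[, required]
}

#' Relative expression of every target gene in every sample
#'
#' For each (sample, target gene): average the Ct replicates, subtract the
#' sample's mean reference-gene Ct to get delta-Ct, then express each
#' sample relative to the control sample of the same gene as
#' `fold_induction()`.
#'
#' @param ct data.frame with columns `sample_id`, `gene`, `ct` (a
#'   `replicate` column may be present and is ignored — replication is
#'   implicit in repeated rows).
#' @param reference_gene Name of the normaliser gene (default "tubulin").
#' @param control_sample `sample_id` of the reference condition.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return data.frame with columns `sample_id`, `gene`, `delta_ct`, `fold`.
#' @export
fold_induction_table <- function(ct, reference_gene = "tubulin",
                                 control_sample, efficiency = 2) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct)))
  if (!control_sample %in% ct$sample_id)
    stop("control sample '", control_sample, "' not in table", call. = FALSE)
  samples <- unique(ct$sample_id)
  targets <- setdiff(unique(ct$gene), reference_gene)
  rows <- list()
  dct <- matrix(NA_real_, length(samples), length(targets),
                dimnames = list(samples, targets))
  for (s in samples) {
    ref_ct <- ct$ct[ct$sample_id == s & ct$gene == reference_gene]
    if (!length(ref_ct))
      stop("sample '", s, "' lacks reference gene '", reference_gene, "'",
           call. = FALSE)
    for (g in targets) {
      tgt_ct <- ct$ct[ct$sample_id == s & ct$gene == g]
      if (length(tgt_ct)) dct[s, g] <- delta_ct(tgt_ct, ref_ct)
    }
  }
  for (g in targets) {
    if (is.na(dct[control_sample, g]))
      stop("control sample lacks gene '", g, "'", call. = FALSE)
    for (s in samples) {
      if (is.na(dct[s, g])) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene = g, delta_ct = dct[s, g],
        fold = fold_induction(dct[s, g], dct[control_sample, g], efficiency),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Kinetic beta-galactosidase activity from a timed absorbance series
#'
#' Subtracts the heat-inactivated background series point-wise, fits an
#' ordinary least-squares line of corrected OD(574 nm) against time, and
#' reports the slope per microgram of protein. Colour development is
#' expected to be linear over the assay window; a fit with R-squared below
#' `r2_threshold` is flagged (not an error). With exactly two time points
#' the fitted slope equals the two-point closed form.
#'
#' @param time_min Strictly increasing time points, minutes (>= 2).
#' @param od574 Absorbance of the sample at each time point.
#' @param od574_background Absorbance of the heat-inactivated background
#'   sample on the *same* time grid.
#' @param protein_ug Protein input of the reaction, micrograms (> 0).
#' @param time_background Time grid of the background series if it was
#'   recorded separately (must equal `time_min`; a mismatch is an error).
#' @param r2_threshold Linearity flag threshold on R-squared (default 0.9).
#' @return Object of class `bgal_result`: list with `activity`
#'   (delta-OD574 per minute per microgram), `slope`, `intercept`,
#'   `r_squared` (NA for a flat series), and `linearity_flagged`.
#' @export
bgal_activity <- function(time_min, od574, od574_background, protein_ug,
                          time_background = time_min, r2_threshold = 0.9) {
  if (length(time_background) != length(time_min) ||
      any(time_background != time_min))
    stop("background series recorded on a different time grid", call. = FALSE)
  stopifnot(length(time_min) >= 2, all(diff(time_min) > 0),
            length(od574) == length(time_min),
            length(od574_background) == length(time_min))
  if (!is.finite(protein_ug) || protein_ug <= 0)
    stop("protein_ug must be > 0", call. = FALSE)
  corrected <- od574 - od574_background
  fit <- stats::lm(corrected ~ time_min)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((corrected - mean(corrected))^2)
  r2 <- if (ss_tot == 0) NA_real_
        else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(activity = slope / protein_ug,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 linearity_flagged = !is.na(r2) && r2 < r2_threshold),
            class = "bgal_result")
}

#' @export
print.bgal_result <- function(x, ...) {
  cat(sprintf("<bgal_result> activity %.4g OD574/min/ug (slope %.4g, R^2 %s)%s\n",
              x$activity, x$slope,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              if (x$linearity_flagged) " [non-linear: flagged]" else ""))
  invisible(x)
}
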