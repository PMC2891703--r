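# Synthetic multi-plate duplicate screens with known ground truth, so every
# analysis stage has a parameter-recovery test without external screen data.

#' Parameters of a synthetic reporter screen
#'
#' The generative model is multiplicative throughout, reflecting that
#' luminescence is positive and screen variability is fold-change-like.
#' For a sample well w of gene g on plate p:
#' \deqn{firefly(w) = P_p \cdot F_0 \cdot I \cdot (1 - e_g) \cdot v_g \cdot \epsilon_w}
#' \deqn{renilla(w) = P_p \cdot R_0 \cdot v_g \cdot \epsilon'_w}
#' where \eqn{P_p = \exp N(0, \sigma_{plate})} is a per-plate factor shared
#' by all wells of the plate, \eqn{F_0, R_0} are baselines, \eqn{I} the
#' reporter induction fold under the hypoxia-mimetic stimulus, \eqn{e_g} the
#' reporter-specific knockdown fraction (0 for neutral genes and negative
#' controls; drawn from `hit_effect` for planted HIF regulators; fixed at
#' 0.9 for the positive-control reagent), \eqn{v_g} a viability factor that
#' depresses both channels (below 1 only for planted viability genes), and
#' \eqn{\epsilon} i.i.d. log-normal noise with unit mean and coefficient of
#' variation `noise_cv`. Because \eqn{P_p} multiplies both channels, the
#' firefly/Renilla ratio cancels plate effects exactly — the point of the
#' dual-reporter design.
#'
#' @param n_genes Number of genes on the screen.
#' @param amplicons_per_gene dsRNA amplicons per gene (1 for a first-pass
#'   library, 2 for a validation library).
#' @param plate_format 96 or 384.
#' @param n_replicates Number of replicate plate sets (default 2, a
#'   duplicate screen).
#' @param fraction_true_hits Proportion of genes planted as HIF regulators.
#' @param hit_effect Knockdown fraction of planted effects: a single number
#'   for a fixed effect, or length-2 `c(min, max)` for a uniform draw
#'   (default `c(0.5, 0.95)`).
#' @param fraction_viability Proportion of genes whose depletion suppresses
#'   both reporters (cell-viability confounders).
#' @param baseline_firefly,baseline_renilla Unstimulated channel baselines
#'   (arbitrary luminescence units).
#' @param induction_fold Reporter induction by the stimulus (default 10).
#' @param noise_cv Coefficient of variation of the per-well log-normal noise.
#' @param plate_effect_sd SD (log scale) of the per-plate multiplicative
#'   factor.
#' @param controls_per_plate Control wells per role on every plate.
#' @param measure_renilla Record the Renilla channel (required for
#'   secondary/tertiary-style screens).
#' @param control_placement "head" places controls in the first wells of
#'   each plate (row-major); "spread" spaces them evenly across the plate.
#' @param n_plates Optional fixed number of plates per replicate; an error
#'   is raised (suggesting the required count) if the reagents do not fit.
#' @param seed Integer seed; the same seed yields a bit-identical screen.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes,
                              amplicons_per_gene = 1L,
                              plate_format = 384,
                              n_replicates = 2L,
                              fraction_true_hits = 0.05,
                              hit_effect = c(0.5, 0.95),
                              fraction_viability = 0.05,
                              baseline_firefly = 1000,
                              baseline_renilla = 400,
                              induction_fold = 10,
                              noise_cv = 0.2,
                              plate_effect_sd = 0.15,
                              controls_per_plate = 4L,
                              measure_renilla = FALSE,
                              control_placement = c("head", "spread"),
                              n_plates = NULL,
                              seed = 1L) {
  control_placement <- match.arg(control_placement)
  stopifnot(n_genes >= 1, amplicons_per_gene >= 1, n_replicates >= 1,
            controls_per_plate >= 1)
  props <- c(fraction_true_hits = fraction_true_hits,
             fraction_viability = fraction_viability)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (fraction_true_hits + fraction_viability > 1)
    stop("fraction_true_hits + fraction_viability must be <= 1", call. = FALSE)
  if (!length(hit_effect) %in% 1:2 || any(hit_effect < 0 | hit_effect > 1))
    stop("hit_effect must be a knockdown fraction in [0,1] or a c(min,max) range",
         call. = FALSE)
  scales <- c(baseline_firefly = baseline_firefly,
              baseline_renilla = baseline_renilla,
              induction_fold = induction_fold)
  if (any(scales <= 0)) stop("scale parameters must be > 0", call. = FALSE)
  if (noise_cv < 0 || plate_effect_sd < 0)
    stop("noise_cv and plate_effect_sd must be >= 0", call. = FALSE)
  plate_format_spec(plate_format)  # errors on unsupported format

  structure(list(
    n_genes = as.integer(n_genes),
    amplicons_per_gene = as.integer(amplicons_per_gene),
    plate_format = as.integer(plate_format),
    n_replicates = as.integer(n_replicates),
    fraction_true_hits = fraction_true_hits,
    hit_effect = hit_effect,
    fraction_viability = fraction_viability,
    baseline_firefly = baseline_firefly,
    baseline_renilla = baseline_renilla,
    induction_fold = induction_fold,
    noise_cv = noise_cv,
    plate_effect_sd = plate_effect_sd,
    controls_per_plate = as.integer(controls_per_plate),
    measure_renilla = isTRUE(measure_renilla),
    control_placement = control_placement,
    n_plates = if (is.null(n_plates)) NULL else as.integer(n_plates),
    seed = as.integer(seed)), class = "simulation_config")
}

# unit-mean log-normal noise with the given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

draw_effect <- function(n, hit_effect) {
  if (length(hit_effect) == 1) rep(hit_effect, n)
  else stats::runif(n, hit_effect[1], hit_effect[2])
}

#' Simulate a multi-plate replicate screen with ground truth
#'
#' Draws gene effects first, then per-plate factors, then per-well noise
#' (one seed drives the whole hierarchy), lays reagents out row-major across
#' as many plates as needed, places negative (GFP dsRNA) and positive (HIF
#' alpha dsRNA) control wells on every plate, and emits a validated
#' [screen_dataset()] alongside the planted truth. Replicates share the gene
#' effects and re-draw plate factors and well noise only.
#'
#' @param config A [simulation_config()].
#' @param truth Optional ground-truth table from an earlier simulation
#'   (columns `gene_id`, `class`, `knockdown`); when given, its genes,
#'   classes and effect sizes are reused (e.g. to re-screen primary
#'   survivors with a validation library) and `n_genes` is ignored.
#' @return List of class `screen_simulation` with elements `dataset`
#'   (a `screen_dataset`), `truth` (data.frame: gene_id, class, knockdown),
#'   and `annotation` (reagent table: reagent_id, target_gene_id,
#'   amplicon_index).
#' @export
simulate_screen <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fmt <- plate_format_spec(config$plate_format)

  # -- gene effects (fixed across replicates) -----------------------------
  if (is.null(truth)) {
    n <- config$n_genes
    genes <- sprintf("g%04d", seq_len(n))
    n_hit <- round(config$fraction_true_hits * n)
    n_via <- round(config$fraction_viability * n)
    shuffled <- sample(genes)
    class <- rep("neutral", n)
    names(class) <- genes
    class[shuffled[seq_len(n_hit)]] <- "hif_regulator"
    if (n_via > 0) class[shuffled[n_hit + seq_len(n_via)]] <- "viability"
    knockdown <- rep(0, n)
    names(knockdown) <- genes
    planted <- class != "neutral"
    knockdown[planted] <- draw_effect(sum(planted), config$hit_effect)
    truth <- data.frame(gene_id = genes, class = unname(class),
                        knockdown = unname(knockdown),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene_id", "class", "knockdown") %in% names(truth)))
    truth <- truth[, c("gene_id", "class", "knockdown")]
    genes <- truth$gene_id
  }

  # -- reagent annotation -------------------------------------------------
  k <- config$amplicons_per_gene
  annotation <- data.frame(
    reagent_id = paste0(rep(truth$gene_id, each = k), "_a", seq_len(k)),
    target_gene_id = rep(truth$gene_id, each = k),
    amplicon_index = rep(seq_len(k), times = nrow(truth)),
    stringsAsFactors = FALSE)

  # firefly-specific knockdown e and both-channel viability factor v
  e_gene <- ifelse(truth$class == "hif_regulator", truth$knockdown, 0)
  v_gene <- ifelse(truth$class == "viability", 1 - truth$knockdown, 1)
  names(e_gene) <- names(v_gene) <- truth$gene_id

  # -- plate layout -------------------------------------------------------
  n_controls <- 2L * config$controls_per_plate
  capacity <- fmt$n_wells - n_controls
  if (capacity < 1)
    stop("controls_per_plate leaves no room for samples on a ",
         config$plate_format, "-well plate", call. = FALSE)
  n_reagents <- nrow(annotation)
  plates_needed <- ceiling(n_reagents / capacity)
  if (!is.null(config$n_plates) && config$n_plates < plates_needed)
    stop(sprintf(
      "plate capacity exceeded: %d reagents plus %d controls per plate need at least %d plate(s) per replicate, not %d",
      n_reagents, n_controls, plates_needed, config$n_plates), call. = FALSE)
  n_plates <- if (is.null(config$n_plates)) plates_needed else config$n_plates

  # row-major well positions; controls placed per config, samples fill the rest
  all_pos <- seq_len(fmt$n_wells)
  ctrl_pos <- if (config$control_placement == "head") {
    seq_len(n_controls)
  } else {
    unique(round(seq(1, fmt$n_wells, length.out = n_controls)))
  }
  neg_pos <- ctrl_pos[seq_len(config$controls_per_plate)]
  pos_pos <- ctrl_pos[config$controls_per_plate + seq_len(config$controls_per_plate)]
  sample_pos <- setdiff(all_pos, ctrl_pos)

  pos_row <- function(pos) fmt$rows[(pos - 1L) %/% fmt$n_col + 1L]
  pos_col <- function(pos) (pos - 1L) %% fmt$n_col + 1L

  reagent_plate <- rep(seq_len(n_plates), each = capacity)[seq_len(n_reagents)]
  reagent_slot <- (seq_len(n_reagents) - 1L) %% capacity + 1L

  # -- well table, replicate by replicate (plate factors and noise re-drawn)
  well_list <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    plate_factor <- exp(stats::rnorm(n_plates, 0, config$plate_effect_sd))
    per_plate <- vector("list", n_plates)
    for (p in seq_len(n_plates)) {
      idx <- which(reagent_plate == p)
      s_reagent <- annotation$reagent_id[idx]
      s_gene <- annotation$target_gene_id[idx]
      s_pos <- sample_pos[reagent_slot[idx]]
      pos <- c(neg_pos, pos_pos, s_pos)
      role <- c(rep("negative_control", config$controls_per_plate),
                rep("positive_control", config$controls_per_plate),
                rep("sample", length(idx)))
      reagent <- c(rep("GFP_dsRNA", config$controls_per_plate),
                   rep("sima_dsRNA", config$controls_per_plate),
                   s_reagent)
      e <- c(rep(0, config$controls_per_plate),
             rep(0.9, config$controls_per_plate),
             unname(e_gene[s_gene]))
      v <- c(rep(1, 2L * config$controls_per_plate), unname(v_gene[s_gene]))
      n_w <- length(pos)
      mu_f <- plate_factor[p] * config$baseline_firefly *
        config$induction_fold * (1 - e) * v
      firefly <- mu_f * rlnorm_cv(n_w, config$noise_cv)
      renilla <- if (config$measure_renilla) {
        plate_factor[p] * config$baseline_renilla * v * rlnorm_cv(n_w, config$noise_cv)
      } else rep(NA_real_, n_w)
      per_plate[[p]] <- data.frame(
        plate_id = sprintf("P%02d_r%d", p, r),
        row = pos_row(pos), col = pos_col(pos),
        reagent_id = reagent, role = role,
        firefly = firefly, renilla = renilla,
        stringsAsFactors = FALSE)
    }
    well_list[[r]] <- do.call(rbind, per_plate)
  }
  wells <- do.call(rbind, well_list)

  stage <- if (config$measure_renilla) "secondary" else "primary"
  ds <- screen_dataset(wells, stage = stage, condition = "DFO",
                       plate_format = config$plate_format)
  structure(list(dataset = ds, truth = truth, annotation = annotation,
                 config = config),
            class = "screen_simulation")
}

#' @export
print.screen_simulation <- function(x, ...) {
  cat(sprintf("<screen_simulation> %d genes (%d regulator, %d viability), seed %d\n",
              nrow(x$truth), sum(x$truth$class == "hif_regulator"),
              sum(x$truth$class == "viability"), x$config$seed))
  print(x$dataset)
  invisible(x)
}

#' Per-amplicon percent-inhibition table of the 35 tertiary-screen genes
#'
#' Returns the packaged transcription of the published tertiary-screen
#' results: for each of the 35 genes taken into the hypoxia re-test, the
#' mean and SD of the percent inhibition of normalised reporter activity for
#' one or two dsRNA amplicons (decimal commas of the printed table converted
#' to points; an absent second amplicon is NA, meaning "not tested").
#'
#' @return data.frame with columns `gene_id`, `inhibition_amp1_mean`,
#'   `inhibition_amp1_sd`, `inhibition_amp2_mean`, `inhibition_amp2_sd`.
#' @export
make_table1_fixture <- function() {
  path <- system.file("extdata", "table1_tertiary_inhibition.tsv",
                      package = "hifscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}

#' Reshape the tertiary fixture to per-amplicon summaries
#'
#' Converts the wide per-gene table of [make_table1_fixture()] to the long
#' amplicon-summary layout consumed by [classify_secondary()] and
#' [classify_tertiary()]; untested second amplicons are dropped.
#'
#' @param tbl A table in the fixture's wide layout (defaults to the packaged
#'   fixture).
#' @return data.frame with columns `gene_id`, `amplicon_index`,
#'   `mean_inhibition`, `sd_inhibition`, `n`.
#' @export
table1_amplicon_summaries <- function(tbl = make_table1_fixture()) {
  long <- rbind(
    data.frame(gene_id = tbl$gene_id, amplicon_index = 1L,
               mean_inhibition = tbl$inhibition_amp1_mean,
               sd_inhibition = tbl$inhibition_amp1_sd,
               stringsAsFactors = FALSE),
    data.frame(gene_id = tbl$gene_id, amplicon_index = 2L,
               mean_inhibition = tbl$inhibition_amp2_mean,
               sd_inhibition = tbl$inhibition_amp2_sd,
               stringsAsFactors = FALSE))
  long <- long[!is.na(long$mean_inhibition), ]
  long$n <- 2L  # the underlying screen was run in duplicate
  long <- long[order(match(long$gene_id, tbl$gene_id), long$amplicon_index), ]
  rownames(long) <- NULL
  long
}
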