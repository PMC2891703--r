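# Orchestration: a configuration-driven end-to-end run of
# simulate -> primary -> filter -> secondary -> tertiary with seed control
# and a machine-readable report.

#' Configuration of an end-to-end screen run
#'
#' Bundles the stage parameters of a full three-phase screen over a
#' simulated library. The tertiary candidate set is formed from every
#' group-A gene plus an explicit, user-supplied selection of group-B genes:
#' that selection was expert judgment in the original screen design and is
#' never inferred here.
#'
#' @param n_genes Genes on the simulated primary library.
#' @param seed Master seed; stage simulations use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param cutoff Primary-stage Z cut-off (must be negative; default -2.5).
#' @param replicate_rule Primary-stage replicate rule ("any" or "mean").
#' @param hit_threshold,strong_threshold Secondary/tertiary
#'   percent-inhibition thresholds, in (0, 100).
#' @param exclusion_lists Named list of gene-id vectors applied after the
#'   primary stage, in order.
#' @param group_b_selection Character vector of group-B genes to carry into
#'   the tertiary stage.
#' @param sim Named list of overrides passed to [simulation_config()]
#'   (e.g. `noise_cv`, `fraction_true_hits`, `hit_effect`).
#' @param out_dir Optional directory: per-stage TSVs and `report.json` are
#'   written there.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_genes = 300, seed = 1,
                            cutoff = -2.5, replicate_rule = "any",
                            hit_threshold = 50, strong_threshold = 75,
                            exclusion_lists = list(),
                            group_b_selection = character(),
                            sim = list(), out_dir = NULL) {
  if (cutoff >= 0) stop("Z cut-off must be negative", call. = FALSE)
  if (hit_threshold <= 0 || hit_threshold >= 100 ||
      strong_threshold <= hit_threshold || strong_threshold >= 100)
    stop("inhibition thresholds must satisfy 0 < hit < strong < 100",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), seed = as.integer(seed),
                 cutoff = cutoff, replicate_rule = replicate_rule,
                 hit_threshold = hit_threshold,
                 strong_threshold = strong_threshold,
                 exclusion_lists = exclusion_lists,
                 group_b_selection = as.character(group_b_selection),
                 sim = sim, out_dir = out_dir),
            class = "pipeline_config")
}

stage_sim_config <- function(cfg, genes_or_n, seed, amplicons, renilla) {
  args <- cfg$sim
  args$n_genes <- if (is.numeric(genes_or_n)) genes_or_n else max(1L, length(genes_or_n))
  args$amplicons_per_gene <- amplicons
  args$measure_renilla <- renilla
  args$seed <- seed %% 2147483647L
  do.call(simulation_config, args)
}

#' Run the full three-phase screen pipeline on a simulated library
#'
#' Executes, in order: (I) simulate a single-reporter primary screen
#' (one amplicon per gene), compute plate Z-scores, and call hits at the Z
#' cut-off; filter the hit list through the configured exclusion lists;
#' (II) re-screen the survivors with a two-amplicon dual-reporter library
#' (gene effects carried over from the primary ground truth), classify into
#' group A / group B; (III) re-screen the group-A genes plus the selected
#' group-B genes under hypoxia and classify positive/negative. Identical
#' config and seed give an identical report.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `screen_run_report`: per-stage counts, parameter
#'   echo, seed, and the per-stage result tables. When `out_dir` is set,
#'   per-stage TSVs and a `report.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  # Phase I: single-reporter primary screen
  sim1 <- simulate_screen(stage_sim_config(config, config$n_genes,
                                           config$seed, 1L, FALSE))
  ztab <- plate_zscores(sim1$dataset)
  gz <- gene_zscores(ztab, sim1$annotation)
  primary <- call_primary_hits(gz, cutoff = config$cutoff,
                               replicate_rule = config$replicate_rule)
  primary_hits <- primary$gene_id[primary$label == "hit"]

  # exclusion-list filtering
  excl <- apply_exclusions(primary_hits, config$exclusion_lists)

  # Phase II: dual-reporter secondary screen on the survivors
  secondary <- NULL
  group_a <- group_b <- character()
  if (length(excl$surviving)) {
    truth2 <- sim1$truth[sim1$truth$gene_id %in% excl$surviving, ]
    sim2 <- simulate_screen(stage_sim_config(config, excl$surviving,
                                             config$seed + 1L, 2L, TRUE),
                            truth = truth2)
    sim2$dataset$stage <- "secondary"
    secondary <- classify_secondary(score_dual_reporter(sim2$dataset,
                                                        sim2$annotation),
                                    hit_threshold = config$hit_threshold,
                                    strong_threshold = config$strong_threshold)
    group_a <- secondary$gene_id[secondary$label == "group_A"]
    group_b <- secondary$gene_id[secondary$label == "group_B"]
  }

  # Phase III: group A plus the user-selected group-B genes, in hypoxia
  selected_b <- intersect(config$group_b_selection, group_b)
  outside <- setdiff(config$group_b_selection, group_b)
  if (length(outside))
    warning("group_b_selection gene(s) not in group B: ",
            paste(outside, collapse = ", "), call. = FALSE)
  candidates <- union(group_a, selected_b)
  tertiary <- NULL
  if (length(candidates)) {
    truth3 <- sim1$truth[sim1$truth$gene_id %in% candidates, ]
    sim3 <- simulate_screen(stage_sim_config(config, candidates,
                                             config$seed + 2L, 2L, TRUE),
                            truth = truth3)
    sim3$dataset$stage <- "tertiary"
    sim3$dataset$condition <- "hypoxia"
    tertiary <- classify_tertiary(score_dual_reporter(sim3$dataset,
                                                      sim3$annotation),
                                  threshold = config$hit_threshold)
  }

  counts <- list(
    input_genes = config$n_genes,
    primary_hits = length(primary_hits),
    removed = as.list(excl$removed),
    filtered = excl$surviving_count,
    secondary_hits = length(group_a) + length(group_b),
    group_A = length(group_a),
    group_B = length(group_b),
    tertiary_candidates = length(candidates),
    tertiary_positive = if (is.null(tertiary)) 0L
                        else sum(tertiary$label == "positive"))

  report <- structure(list(
    seed = config$seed,
    version = as.character(utils::packageVersion("hifscreen")),
    parameters = list(cutoff = config$cutoff,
                      replicate_rule = config$replicate_rule,
                      hit_threshold = config$hit_threshold,
                      strong_threshold = config$strong_threshold,
                      sim = config$sim),
    counts = counts,
    primary = primary, exclusion = excl,
    secondary = secondary, tertiary = tertiary,
    truth = sim1$truth), class = "screen_run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stage_tab <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(config$out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    stage_tab(primary, "primary_calls.tsv")
    stage_tab(data.frame(gene_id = excl$surviving), "filtered_genes.tsv")
    stage_tab(secondary, "secondary_calls.tsv")
    stage_tab(tertiary, "tertiary_calls.tsv")
    jsonlite::write_json(
      list(seed = report$seed, version = report$version,
           parameters = report$parameters, counts = counts),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.screen_run_report <- function(x, ...) {
  c_ <- x$counts
  cat(sprintf("<screen_run_report> seed %d\n", x$seed))
  cat(sprintf("  phase I   : %d genes -> %d hits (Z < %.2f, rule %s)\n",
              c_$input_genes, c_$primary_hits, x$parameters$cutoff,
              x$parameters$replicate_rule))
  if (length(c_$removed))
    cat(sprintf("  filtering : -%s -> %d surviving\n",
                paste(unlist(c_$removed), collapse = " -"), c_$filtered))
  cat(sprintf("  phase II  : %d hits (group A %d, group B %d)\n",
              c_$secondary_hits, c_$group_A, c_$group_B))
  cat(sprintf("  phase III : %d candidates -> %d positive\n",
              c_$tertiary_candidates, c_$tertiary_positive))
  invisible(x)
}
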