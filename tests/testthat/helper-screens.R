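# Small in-code fixtures shared across test files.

# a minimal one-plate well table: two samples, one control of each role
toy_wells <- function(firefly = c(100, 200, 300, 400)) {
  data.frame(
    plate_id = "P1",
    row = c("A", "A", "B", "B"), col = c(1, 2, 1, 2),
    reagent_id = c("amp1", "amp2", "GFP_dsRNA", "sima_dsRNA"),
    role = c("sample", "sample", "negative_control", "positive_control"),
    firefly = firefly,
    stringsAsFactors = FALSE)
}

toy_annotation <- function(genes, amplicons = 1L) {
  data.frame(
    reagent_id = paste0(rep(genes, each = amplicons), "_a", seq_len(amplicons)),
    target_gene_id = rep(genes, each = amplicons),
    amplicon_index = rep(seq_len(amplicons), times = length(genes)),
    stringsAsFactors = FALSE)
}

# a noiseless dual-reporter config: percent inhibition is then exact
noiseless_config <- function(n_genes = 10, seed = 1, ...) {
  simulation_config(n_genes = n_genes, amplicons_per_gene = 2L,
                    plate_format = 96, noise_cv = 0, plate_effect_sd = 0,
                    fraction_true_hits = 0.3, hit_effect = 0.8,
                    fraction_viability = 0, measure_renilla = TRUE,
                    seed = seed, ...)
}

# amplicon-summary row constructor for classification tests
amp_summary <- function(gene_id, means) {
  data.frame(gene_id = gene_id, amplicon_index = seq_along(means),
             mean_inhibition = means, sd_inhibition = NA_real_,
             n = 2L, stringsAsFactors = FALSE)
}
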