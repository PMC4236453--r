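# hand-built fixtures shared across test files

make_annotation <- function(df, replicon_lengths = NULL) {
  if (is.null(df$operon_id)) df$operon_id <- paste0("mono_", df$gene_id)
  if (is.null(df$operon_rank)) df$operon_rank <- 1L
  if (is.null(df$start_codon)) {
    df$start_codon <- ifelse(df$strand == "+", df$start, df$end)
  }
  if (is.null(replicon_lengths)) {
    replicon_lengths <- tapply(df$end, df$replicon, max) + 500
  }
  attr(df, "replicon_lengths") <- replicon_lengths
  class(df) <- c("gene_annotation", "data.frame")
  df
}

make_sites <- function(tf, replicon, position, pvalue, intensity = 1) {
  data.frame(tf = tf, replicon = replicon, position = position,
             intensity = intensity, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

# compendium from a matrix and a named list of array-id groups
make_compendium <- function(mat, sets) {
  manifest <- data.frame(
    array_id = unlist(sets, use.names = FALSE),
    condition_set_id = rep(names(sets), lengths(sets)))
  new_compendium(mat, manifest)
}

# a small planted study used by several conditional-regulation tests
small_planted_study <- function(seed = 11, ...) {
  pr <- data.frame(tf = c(1, 2), condition_set = c(3, 5),
                   role = c("activator", "repressor"))
  cfg <- sim_config(n_genes = 300, n_operons = 180, n_tfs = 4,
                    n_condition_sets = 8, arrays_per_set = c(10, 12),
                    targets_per_tf = c(30, 40), planted_regulons = pr,
                    seed = seed, ...)
  sim_study(cfg)
}
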