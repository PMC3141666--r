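# Small shared synthetic configurations and a convenience runner for the
# discovery chain, used across the module tests.

small_synth <- function(seed = 1, n_hairpins = 4, ...) {
  synthetic_config(seed = seed, n_hairpins = n_hairpins,
                   n_chromosomes = 2, chrom_length = 15000,
                   background_tag_count = 10, ...)
}

run_discovery_chain <- function(synth, config = pipeline_config()) {
  reads <- simulate_libraries(synth)
  expanded <- reads[rep(seq_len(nrow(reads)), reads$count),
                    c("sequence", "library")]
  tags <- collapse_reads(expanded)
  kept <- filter_tags(tags, config)
  index <- build_index(synth$genome)
  hits <- suppressMessages(map_and_filter(kept, index, config))
  list(tags = tags, kept = kept, index = index, hits = hits,
       candidates = discover(kept, hits, index, config = config))
}

# A truth hairpin counts as recovered when a candidate on its strand
# overlaps its locus; a candidate is background-derived (a false
# discovery) when it overlaps no truth locus on either strand (for
# perfect, mismatch-free duplexes exact mapping cannot resolve the
# transcribed strand, so the mirrored record of a true locus is not a
# false discovery).
recovery_stats <- function(truth, candidates) {
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    any(candidates$chrom == truth$chrom[i] &
          candidates$strand == truth$strand[i] &
          candidates$start <= truth$end[i] &
          candidates$end >= truth$start[i])
  }, logical(1))
  false_pos <- vapply(seq_len(nrow(candidates)), function(i) {
    !any(truth$chrom == candidates$chrom[i] &
           truth$start <= candidates$end[i] &
           truth$end >= candidates$start[i])
  }, logical(1))
  list(sensitivity = mean(recovered), n_false = sum(false_pos))
}
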