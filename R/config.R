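#' Pipeline configuration
#'
#' Collects the constants of the discovery chain in one object. Defaults
#' follow the published soybean analysis: tags with a pooled read count of
#' two or fewer are discarded; tag lengths run 19-24 nt; 200 bp of genomic
#' sequence is taken on each side of a mapped tag; tags with more than five
#' genome matches are dropped; the miRNA/miRNA-star duplex tolerates at
#' most four mismatches and at most one asymmetric bulge of at most two
#' bases; target sites are reported at a complementarity score of at most
#' 3.0 points (mismatch = 1, G:U = 0.5); expression differences are called
#' at P < 0.05.
#'
#' @param min_total_count minimum pooled read count to keep a tag.
#' @param length_window inclusive tag length window in nt.
#' @param flank_length flanking genomic sequence per side, in nt.
#' @param max_genome_hits maximum number of exact genome matches.
#' @param max_duplex_mismatches criterion-ii mismatch ceiling.
#' @param max_asym_bulges criterion-iii ceiling on asymmetric bulges
#'   (0 gives the strict reading of the rule).
#' @param max_bulge_size criterion-iii ceiling on bulge size, in nt.
#' @param target_score_cutoff reporting cutoff for target scores.
#' @param mismatch_weight,gu_weight target-score weights.
#' @param alpha significance level for expression tests.
#' @param sw_match,sw_mismatch,sw_gap Smith-Waterman scoring (the source
#'   analysis does not state these; defaults are conventional).
#' @param min_star_score_frac minimum star alignment score as a fraction of
#'   the perfect rc-tag score (an artifact parameter, not from the source
#'   analysis).
#' @param min_loop minimum hairpin loop length for folding.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_total_count = 3L,
                            length_window = c(19L, 24L),
                            flank_length = 200L,
                            max_genome_hits = 5L,
                            max_duplex_mismatches = 4L,
                            max_asym_bulges = 1L,
                            max_bulge_size = 2L,
                            target_score_cutoff = 3.0,
                            mismatch_weight = 1.0,
                            gu_weight = 0.5,
                            alpha = 0.05,
                            sw_match = 1,
                            sw_mismatch = -1,
                            sw_gap = -2,
                            min_star_score_frac = 0.6,
                            min_loop = 3L) {
  cfg <- list(min_total_count = as.integer(min_total_count),
              length_window = as.integer(length_window),
              flank_length = as.integer(flank_length),
              max_genome_hits = as.integer(max_genome_hits),
              max_duplex_mismatches = as.integer(max_duplex_mismatches),
              max_asym_bulges = as.integer(max_asym_bulges),
              max_bulge_size = as.integer(max_bulge_size),
              target_score_cutoff = target_score_cutoff,
              mismatch_weight = mismatch_weight,
              gu_weight = gu_weight,
              alpha = alpha,
              sw_match = sw_match,
              sw_mismatch = sw_mismatch,
              sw_gap = sw_gap,
              min_star_score_frac = min_star_score_frac,
              min_loop = as.integer(min_loop))
  stopifnot(cfg$min_total_count >= 0L,
            length(cfg$length_window) == 2L,
            cfg$length_window[1L] <= cfg$length_window[2L],
            cfg$flank_length >= 0L,
            cfg$max_genome_hits >= 0L,
            cfg$max_duplex_mismatches >= 0L,
            cfg$max_asym_bulges >= 0L,
            cfg$max_bulge_size >= 0L,
            cfg$mismatch_weight > 0,
            cfg$gu_weight > 0,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("read_pipeline_config(): unknown keys: ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}
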