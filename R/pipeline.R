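#' Run the discovery pipeline end to end
#'
#' Executes collapse -> filter -> map -> discover (and optionally
#' annotate, target scan and qPCR analysis) on on-disk inputs, writes every
#' stage's output to `out_dir` and a JSON run manifest recording the
#' configuration, input digests and per-stage record counts.
#'
#' @param genome path to the genome FASTA (or a `genome_index`).
#' @param reads either a path to a collapsed tag TSV (`sequence`,
#'   `library`, `count`), a data frame of the same shape, or a character
#'   vector of FASTA/FASTQ paths (one library per file).
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param annotation optional GFF3 path for genomic-context labels.
#' @param species_mature,species_hairpin,other_mature optional catalog
#'   FASTA paths for classification.
#' @param transcripts optional transcript FASTA; when given, accepted
#'   matures are scanned for targets.
#' @param ct_table optional Ct TSV path plus `ref_genes` for expression
#'   analysis.
#' @param ref_genes reference gene ids for the Ct analysis.
#' @param species species prefix for naming (default `"gma"`).
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(genome, reads, out_dir,
                         config = pipeline_config(),
                         annotation = NULL,
                         species_mature = NULL, species_hairpin = NULL,
                         other_mature = NULL,
                         transcripts = NULL,
                         ct_table = NULL, ref_genes = character(0),
                         species = "gma") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  digest_file <- function(p) {
    if (is.character(p) && length(p) == 1L && file.exists(p))
      unname(tools::md5sum(p)) else NA_character_
  }
  manifest <- list(
    tool = "stemloop",
    version = as.character(utils::packageVersion("stemloop")),
    config = unclass(config),
    inputs = list(genome = digest_file(genome),
                  annotation = digest_file(annotation)),
    counts = list())

  index <- if (inherits(genome, "genome_index")) genome else build_index(genome)

  # ---- collapse ----
  if (is.data.frame(reads)) {
    tag_df <- reads
    tags <- if (all(c("sequence", "library", "count") %in% names(tag_df))) {
      expanded <- tag_df[rep(seq_len(nrow(tag_df)), tag_df$count), ]
      collapse_reads(expanded[, c("sequence", "library")])
    } else {
      collapse_reads(tag_df)
    }
  } else if (length(reads) == 1L && grepl("\\.tsv$", reads)) {
    manifest$inputs$reads <- digest_file(reads)
    tags <- read_tag_tsv(reads)
  } else {
    manifest$inputs$reads <- vapply(reads, digest_file, "")
    tags <- collapse_reads(read_small_rna(reads))
  }
  manifest$counts$tags_in <- nrow(tags)
  write_tag_tsv(tags, file.path(out_dir, "tags.tsv"))

  # ---- filter ----
  kept <- filter_tags(tags, config)
  manifest$counts$tags_filtered <- nrow(kept)
  write_tag_tsv(kept, file.path(out_dir, "tags_filtered.tsv"))

  # ---- map ----
  hits <- map_and_filter(kept, index, config)
  manifest$counts$tags_mapped <- length(hits)
  write_hits_bed(hits, file.path(out_dir, "hits.bed"), tags = kept)

  # ---- discover ----
  ann <- if (!is.null(annotation)) rtracklayer::import(annotation) else NULL
  candidates <- discover(kept, hits, index, annotation = ann, config = config)
  manifest$counts$candidates_accepted <- nrow(candidates)
  write_candidates_tsv(candidates, file.path(out_dir, "candidates.tsv"))

  # ---- annotate ----
  records <- classify_mirnas(candidates, species_mature, species_hairpin,
                             other_mature, species = species)
  records <- assign_names(records, species = species)
  manifest$counts$classified <- as.list(table(records$class))
  rec_out <- records[, setdiff(names(records), "members")]
  utils::write.table(rec_out, file.path(out_dir, "mirna_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- isomiR groups ----
  iso <- list()
  for (i in seq_len(nrow(records))) {
    members <- records$members[[i]]
    # keep members on the mature's own arm: their placement in the
    # precursor must overlap the reference mature's placement
    ref_at <- regexpr(records$mature[i], records$precursor[i], fixed = TRUE)
    ref_iv <- c(ref_at, ref_at + nchar(records$mature[i]) - 1L)
    in_prec <- members[vapply(members, function(s) {
      p <- regexpr(s, records$precursor[i], fixed = TRUE)
      p > 0L && p <= ref_iv[2L] && (p + nchar(s) - 1L) >= ref_iv[1L]
    }, logical(1L))]
    if (length(in_prec) == 0L) next
    g <- group_isomirs(in_prec, records$precursor[i],
                       reference = records$mature[i])
    iso[[length(iso) + 1L]] <- data.frame(
      id = records$id[i], pattern = g$pattern, n_isos = g$n_isoforms,
      chrom = records$chrom[i], start = records$start[i],
      end = records$end[i], stringsAsFactors = FALSE)
  }
  iso_df <- if (length(iso)) do.call(rbind, iso) else
    data.frame(id = character(0), pattern = character(0),
               n_isos = integer(0), chrom = character(0),
               start = integer(0), end = integer(0))
  manifest$counts$isomir_groups <- nrow(iso_df)
  utils::write.table(iso_df, file.path(out_dir, "isomirs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- targets (optional) ----
  if (!is.null(transcripts)) {
    manifest$inputs$transcripts <- digest_file(transcripts)
    preds <- list()
    for (i in seq_len(nrow(records))) {
      p <- scan_targets(records$mature[i], transcripts, config,
                        mirna_id = records$id[i])
      if (nrow(p)) preds[[length(preds) + 1L]] <- p
    }
    pred_df <- if (length(preds)) do.call(rbind, preds) else
      scan_targets("ACGUACGUACGUACGUACG", character(0), config)
    manifest$counts$target_predictions <- nrow(pred_df)
    write_targets_tsv(pred_df, file.path(out_dir, "targets.tsv"))
  }

  # ---- qPCR (optional) ----
  if (!is.null(ct_table)) {
    manifest$inputs$ct_table <- digest_file(ct_table)
    ct <- read_ct_table(ct_table, ref_genes = ref_genes)
    genes <- setdiff(unique(ct$gene), ref_genes)
    conds <- sort(unique(ct$condition))
    res <- list()
    for (g in genes) {
      for (i in seq_along(conds)) {
        for (j in seq_len(i - 1L)) {
          r <- relative_expression(ct, g, conds[i], conds[j],
                                   ref_genes = ref_genes,
                                   alpha = config$alpha)
          res[[length(res) + 1L]] <- data.frame(
            gene = g, condition_a = conds[i], condition_b = conds[j],
            ddct = r$ddct, rq = r$rq, p_value = r$p_value,
            significant = r$significant, stringsAsFactors = FALSE)
        }
      }
    }
    qpcr_df <- do.call(rbind, res)
    manifest$counts$qpcr_comparisons <- nrow(qpcr_df)
    utils::write.table(qpcr_df, file.path(out_dir, "qpcr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
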