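#' Extract the flanked genomic window around a mapped tag
#'
#' Takes up to `flank_length` nt of genomic sequence on each side of the
#' hit. For minus-strand hits the window is reverse-complemented so that
#' the tag reads in its sequenced orientation; a coordinate map back to
#' genome space is retained. Truncation at chromosome ends is flagged.
#'
#' @param hit one row of a hit data frame (`chrom`, `start`, `end`,
#'   `strand`).
#' @param index a `genome_index`.
#' @param flank_length nt of flank per side (default 200).
#' @return a `flank_window`: list with `seq` (RNA, tag orientation),
#'   `tag_start`/`tag_end` (1-based window coordinates of the tag),
#'   `chrom`, `strand`, `g_start`/`g_end` (genomic span of the window) and
#'   truncation flags `trunc5`/`trunc3` (relative to the oriented window).
#' @export
extract_flanks <- function(hit, index, flank_length = 200L) {
  chrom_len <- length(index$genome[[hit$chrom]])
  w_start <- max(1L, hit$start - flank_length)
  w_end <- min(chrom_len, hit$end + flank_length)
  s <- genome_slice(index, hit$chrom, w_start, w_end, strand = "+")
  trunc_left <- (hit$start - w_start) < flank_length
  trunc_right <- (w_end - hit$end) < flank_length
  if (hit$strand == "+") {
    tag_start <- hit$start - w_start + 1L
    trunc5 <- trunc_left; trunc3 <- trunc_right
  } else {
    s <- revcomp_dna(s)
    tag_start <- w_end - hit$end + 1L
    trunc5 <- trunc_right; trunc3 <- trunc_left
  }
  structure(list(seq = as_rna(s),
                 tag_start = as.integer(tag_start),
                 tag_end = as.integer(tag_start + (hit$end - hit$start)),
                 chrom = hit$chrom, strand = hit$strand,
                 g_start = as.integer(w_start), g_end = as.integer(w_end),
                 trunc5 = trunc5, trunc3 = trunc3),
            class = "flank_window")
}

#' Map an oriented window position back to genome coordinates
#'
#' @param window a `flank_window`.
#' @param pos 1-based position(s) in the window.
#' @return genomic position(s), 1-based on the plus strand.
#' @export
window_to_genome <- function(window, pos) {
  if (window$strand == "+") window$g_start + pos - 1L
  else window$g_end - pos + 1L
}

#' Locate the candidate star arm by aligning the reverse-complemented tag
#'
#' Runs a Smith-Waterman alignment of the reverse complement of the tag
#' (rc-tag) against the window on either side of the tag's own interval
#' (alignments overlapping the tag are excluded) and keeps the best
#' placement. Placements scoring below `min_star_score_frac` of the
#' perfect rc-tag score are rejected.
#'
#' @param window a `flank_window`.
#' @param tag the tag sequence (must occur at the window's tag interval).
#' @param config a [pipeline_config()].
#' @return `NULL` when no acceptable placement exists, else a list with
#'   `s_start`/`s_end` (window coordinates of the star placement), `score`
#'   and the `local_alignment`.
#' @export
locate_star <- function(window, tag, config = pipeline_config()) {
  tag <- as_rna(tag)
  wtag <- substr(window$seq, window$tag_start, window$tag_end)
  if (wtag != tag) {
    stop("locate_star(): window does not contain the tag at its interval")
  }
  rc <- revcomp_rna(tag)
  floor_score <- config$min_star_score_frac * config$sw_match * nchar(tag)

  segs <- list()
  if (window$tag_start > 1L) {
    segs$left <- list(seq = substr(window$seq, 1L, window$tag_start - 1L),
                      offset = 0L)
  }
  if (window$tag_end < nchar(window$seq)) {
    segs$right <- list(seq = substr(window$seq, window$tag_end + 1L,
                                    nchar(window$seq)),
                       offset = window$tag_end)
  }
  best <- NULL
  for (sg in segs) {
    if (nchar(sg$seq) < 4L) next
    aln <- smith_waterman(rc, sg$seq, match = config$sw_match,
                          mismatch = config$sw_mismatch, gap = config$sw_gap)
    if (aln$score >= floor_score &&
        (is.null(best) || aln$score > best$score)) {
      best <- list(s_start = sg$offset + aln$s_start,
                   s_end = sg$offset + aln$s_end,
                   score = aln$score, alignment = aln)
    }
  }
  best
}

#' Evaluate the miRNA/miRNA-star duplex against the acceptance criteria
#'
#' Given a fold of the candidate precursor and the mature and star
#' intervals (precursor coordinates), checks:
#' \describe{
#'   \item{criterion i}{mature and star lie entirely on opposite arms of
#'     the terminal loop of the longest stem, neither overlapping the loop;}
#'   \item{criterion ii}{the number of mature positions that are neither
#'     Watson-Crick- nor G:U-paired to a star position is at most
#'     `max_duplex_mismatches` (G:U wobbles count as pairs);}
#'   \item{criterion iii}{the duplex contains at most `max_asym_bulges`
#'     asymmetric bulges, each of size at most `max_bulge_size` nt.}
#' }
#'
#' @param fold a `fold_structure` over the precursor.
#' @param mature_iv,star_iv integer length-2 vectors, 1-based inclusive
#'   intervals within the precursor.
#' @param config a [pipeline_config()].
#' @return a `duplex_evaluation` list: `n_mismatches`, `bulges` (data frame
#'   of `size` per bulge), `criterion_i`, `criterion_ii`, `criterion_iii`,
#'   `accepted`.
#' @export
evaluate_duplex <- function(fold, mature_iv, star_iv,
                            config = pipeline_config()) {
  n <- nchar(fold$sequence)
  if (mature_iv[1L] < 1L || mature_iv[2L] > n || star_iv[1L] < 1L ||
      star_iv[2L] > n) {
    stop("evaluate_duplex(): mature/star interval outside the precursor")
  }
  loop <- terminal_loop(fold)

  crit_i <- FALSE
  if (!is.null(loop)) {
    mid <- (loop$loop_start + loop$loop_end) / 2
    m5 <- mature_iv[2L] < loop$loop_start   # entirely 5' of the loop
    m3 <- mature_iv[1L] > loop$loop_end     # entirely 3' of the loop
    s5 <- star_iv[2L] < loop$loop_start
    s3 <- star_iv[1L] > loop$loop_end
    crit_i <- (m5 && s3 && mature_iv[2L] < mid && star_iv[1L] > mid) ||
      (m3 && s5 && mature_iv[1L] > mid && star_iv[2L] < mid)
  }

  partner <- fold$partner
  mpos <- seq.int(mature_iv[1L], mature_iv[2L])
  paired_to_star <- !is.na(partner[mpos]) &
    partner[mpos] >= star_iv[1L] & partner[mpos] <= star_iv[2L]
  n_mismatch <- sum(!paired_to_star)
  crit_ii <- n_mismatch <= config$max_duplex_mismatches

  # Asymmetric bulges: walk consecutive mature positions paired into the
  # star; unequal unpaired runs on the two strands between successive
  # paired positions form a bulge of size |gap_mature - gap_star|.
  pm <- mpos[paired_to_star]
  sizes <- integer(0)
  if (length(pm) >= 2L) {
    for (k in seq_len(length(pm) - 1L)) {
      gap_m <- pm[k + 1L] - pm[k] - 1L
      gap_s <- abs(partner[pm[k]] - partner[pm[k + 1L]]) - 1L
      asym <- abs(gap_m - gap_s)
      if (asym > 0L) sizes <- c(sizes, asym)
    }
  }
  crit_iii <- length(sizes) <= config$max_asym_bulges &&
    (length(sizes) == 0L || max(sizes) <= config$max_bulge_size)

  structure(list(n_mismatches = as.integer(n_mismatch),
                 bulges = data.frame(size = sizes),
                 criterion_i = crit_i,
                 criterion_ii = crit_ii,
                 criterion_iii = crit_iii,
                 accepted = crit_i && crit_ii && crit_iii),
            class = "duplex_evaluation")
}

# Evaluate one (tag, hit) pair through extract -> locate -> fold ->
# evaluate. Returns NULL or an accepted candidate record (a list).
candidate_from_hit <- function(tag, hit, index, config) {
  window <- extract_flanks(hit, index, config$flank_length)
  star <- locate_star(window, tag, config)
  if (is.null(star)) return(NULL)

  cand_start <- min(window$tag_start, star$s_start)
  cand_end <- max(window$tag_end, star$s_end)
  precursor <- substr(window$seq, cand_start, cand_end)
  fold <- fold_hairpin(precursor, min_loop = config$min_loop)
  mature_iv <- c(window$tag_start, window$tag_end) - cand_start + 1L
  star_iv <- c(star$s_start, star$s_end) - cand_start + 1L
  ev <- evaluate_duplex(fold, mature_iv, star_iv, config)
  if (!ev$accepted) return(NULL)

  loop <- terminal_loop(fold)
  mature_arm <- if (mature_iv[2L] < loop$loop_start) "5p" else "3p"
  star_arm <- if (mature_arm == "5p") "3p" else "5p"
  g1 <- window_to_genome(window, cand_start)
  g2 <- window_to_genome(window, cand_end)
  list(chrom = hit$chrom,
       start = min(g1, g2), end = max(g1, g2),
       strand = hit$strand,
       precursor = precursor,
       dotbracket = fold$dotbracket,
       mature = tag,
       mature_offset = mature_iv[1L],
       mature_arm = mature_arm,
       star = substr(precursor, star_iv[1L], star_iv[2L]),
       star_offset = star_iv[1L],
       star_arm = star_arm,
       n_mismatches = ev$n_mismatches,
       n_bulges = nrow(ev$bulges))
}

#' Discover miRNA precursor candidates from mapped tags
#'
#' For every (tag, genomic hit) pair, extracts the flanked window, locates
#' the star arm from the rc-tag, delimits the candidate precursor between
#' the tag and rc-tag alignments, folds it and applies the three duplex
#' criteria. Accepted candidates from the same locus (e.g. when the mature
#' and star arms were both sequenced, or isomiR variants of one mature)
#' are merged into a single record keyed by the most abundant tag, with
#' every supporting tag listed in `members` and both arms annotated when
#' observed.
#'
#' @param tags a `tag_table` (filtered).
#' @param hits named list of hit data frames from [map_and_filter()].
#' @param index a `genome_index`.
#' @param annotation optional `GRanges` (e.g. from a GFF3 file) used to
#'   label the genomic context of each candidate; intervals of type `CDS`
#'   mark coding sequence, other intervals within a `gene` are introns.
#' @param config a [pipeline_config()].
#' @return a data frame of accepted `precursor_candidate` records with
#'   columns `chrom`, `start`, `end`, `length`, `strand`, `precursor`,
#'   `dotbracket`, `mature`, `mature_arm`, `star`, `star_arm`,
#'   `n_mismatches`, `n_bulges`, `context`, `arms_observed`, `n_members`,
#'   and a list column `members` of supporting tag sequences.
#' @export
discover <- function(tags, hits, index, annotation = NULL,
                     config = pipeline_config()) {
  cands <- list()
  for (tag in names(hits)) {
    for (r in seq_len(nrow(hits[[tag]]))) {
      hit <- hits[[tag]][r, ]
      rec <- tryCatch(candidate_from_hit(tag, hit, index, config),
                      error = function(e) {
                        message(sprintf("discover(): %s at %s:%d failed: %s",
                                        tag, hit$chrom, hit$start,
                                        conditionMessage(e)))
                        NULL
                      })
      if (!is.null(rec)) cands[[length(cands) + 1L]] <- rec
    }
  }
  if (length(cands) == 0L) return(empty_candidates())

  counts <- stats::setNames(tags$total_count, tags$sequence)
  merged <- merge_candidates(cands, counts)
  df <- do.call(rbind, lapply(merged, function(x) {
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               length = x$end - x$start + 1L, strand = x$strand,
               precursor = x$precursor, dotbracket = x$dotbracket,
               mature = x$mature, mature_arm = x$mature_arm,
               star = x$star, star_arm = x$star_arm,
               n_mismatches = x$n_mismatches, n_bulges = x$n_bulges,
               arms_observed = x$arms_observed, n_members = length(x$members),
               stringsAsFactors = FALSE)
  }))
  df$members <- lapply(merged, `[[`, "members")
  df$context <- if (is.null(annotation)) NA_character_ else
    context_labels(df, annotation)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("precursor_candidates", "data.frame")
  df
}

empty_candidates <- function() {
  df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   length = integer(0), strand = character(0),
                   precursor = character(0), dotbracket = character(0),
                   mature = character(0), mature_arm = character(0),
                   star = character(0), star_arm = character(0),
                   n_mismatches = integer(0), n_bulges = integer(0),
                   arms_observed = character(0), n_members = integer(0),
                   stringsAsFactors = FALSE)
  df$members <- list()
  df$context <- character(0)
  class(df) <- c("precursor_candidates", "data.frame")
  df
}

# Merge per-hit candidates that describe the same locus (same chromosome
# and strand, overlapping precursor intervals). The representative mature
# is the most abundant member tag; arms_observed records which arms were
# directly sequenced.
merge_candidates <- function(cands, counts) {
  groups <- list()
  for (rec in cands) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      ref <- groups[[g]][[1L]]
      if (ref$chrom == rec$chrom && ref$strand == rec$strand &&
          rec$start <= max(vapply(groups[[g]], `[[`, 0L, "end")) &&
          rec$end >= min(vapply(groups[[g]], `[[`, 0L, "start"))) {
        groups[[g]][[length(groups[[g]]) + 1L]] <- rec
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- list(rec)
  }
  lapply(groups, function(grp) {
    tags_in <- vapply(grp, `[[`, "", "mature")
    cnt <- counts[tags_in]
    cnt[is.na(cnt)] <- 0L
    # representative: highest count, ties by sequence for determinism
    rep_i <- order(-cnt, tags_in)[1L]
    out <- grp[[rep_i]]
    out$members <- sort(unique(tags_in))
    out$arms_observed <- paste(sort(unique(vapply(grp, `[[`, "", "mature_arm"))),
                               collapse = "/")
    out
  })
}

# Genomic context of each candidate from an annotation GRanges:
# "CDS" when overlapping a CDS feature, "intronic" when inside a gene but
# not a CDS, otherwise "intergenic".
context_labels <- function(df, annotation) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  type <- as.character(annotation$type)
  cds <- annotation[type == "CDS"]
  gene <- annotation[type == "gene"]
  in_cds <- GenomicRanges::countOverlaps(gr, cds) > 0
  in_gene <- GenomicRanges::countOverlaps(gr, gene) > 0
  ifelse(in_cds, "CDS", ifelse(in_gene, "intronic", "intergenic"))
}

#' Write discovered candidates as a TSV report
#'
#' Columns mirror the locus table of the source analysis (mature sequence,
#' size, chromosome, start, end, length, sense, arm, region) plus the
#' dot-bracket structure.
#'
#' @param candidates output of [discover()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  out <- data.frame(mature = candidates$mature,
                    size = nchar(candidates$mature),
                    chrom = candidates$chrom,
                    start = candidates$start,
                    end = candidates$end,
                    length = candidates$length,
                    sense = candidates$strand,
                    arm = candidates$mature_arm,
                    region = candidates$context,
                    arms_observed = candidates$arms_observed,
                    n_members = candidates$n_members,
                    precursor = candidates$precursor,
                    dotbracket = candidates$dotbracket,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
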