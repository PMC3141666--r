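#' Configuration for the synthetic genome and library generator
#'
#' The generator emulates the study design of the source analysis: a
#' multi-chromosome genome with planted pre-miRNA hairpins whose
#' mature/star duplex carries 2-nt 3' overhangs, eight small-RNA libraries
#' (two genotypes x two conditions for each of two stress types) with
#' isomiR end-variation, background degradation tags absent from the
#' genome, and condition-dependent abundance fold changes.
#'
#' @param seed integer seed; all generator output is a deterministic
#'   function of the configuration.
#' @param n_chromosomes,chrom_length genome shape (nt).
#' @param n_hairpins number of planted hairpin loci.
#' @param mature_length_range inclusive mature length window (nt).
#' @param precursor_length_range inclusive precursor length window (nt);
#'   planted precursors always fall inside it.
#' @param duplex_mismatch_range inclusive range for the number of planted
#'   duplex mismatches per hairpin. The default (0-2) keeps every planted
#'   star detectable at the default 60-percent star-score floor; values up
#'   to 4 (the criterion-ii ceiling) are allowed.
#' @param bulge_max_count,bulge_max_size planted asymmetric bulges per
#'   duplex (count 0..max, size in nt).
#' @param library_labels eight library identifiers (genotype/tissue/
#'   condition codes).
#' @param isomir_shift_prob fraction of each mature's reads emitted as
#'   5'/3' end-shifted isomiR variants.
#' @param background_tag_count number of random background tags (drawn
#'   uniformly over the alphabet and rejected if they match the genome, so
#'   their truth label is known-negative).
#' @param fold_change_map optional numeric matrix (`n_hairpins` rows, one
#'   column per library) of abundance multipliers; default all 1.
#' @param star_fraction star-read abundance as a fraction of the mature's.
#' @param base_count_range inclusive range the per-hairpin baseline mature
#'   read count is drawn from.
#' @param u5_bias probability that a planted mature starts with U (plant
#'   miRNAs are strongly 5'-U biased).
#' @param prop_context length-3 numeric (intergenic, CDS, intronic)
#'   placement proportions.
#' @param dispersion negative-binomial over-dispersion of simulated
#'   counts; 0 (default) emits exact expected counts so tests are
#'   deterministic.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chrom_length = 50000L,
                             n_hairpins = 20L,
                             mature_length_range = c(19L, 24L),
                             precursor_length_range = c(55L, 240L),
                             duplex_mismatch_range = c(0L, 2L),
                             bulge_max_count = 1L,
                             bulge_max_size = 1L,
                             library_labels = c("DSRC", "DSRT", "DTRC", "DTRT",
                                                "RSLC", "RSLT", "RRLC", "RRLT"),
                             isomir_shift_prob = 0.2,
                             background_tag_count = 50L,
                             fold_change_map = NULL,
                             star_fraction = 0.1,
                             base_count_range = c(30L, 300L),
                             u5_bias = 0.7,
                             prop_context = c(intergenic = 0.85, CDS = 0.075,
                                              intronic = 0.075),
                             dispersion = 0) {
  cfg <- as.list(environment())
  stopifnot(length(library_labels) == 8L,
            !anyDuplicated(library_labels),
            mature_length_range[1L] >= 19L, mature_length_range[2L] <= 24L,
            duplex_mismatch_range[1L] >= 0L, duplex_mismatch_range[2L] <= 4L,
            isomir_shift_prob >= 0, isomir_shift_prob <= 1,
            dispersion >= 0)
  # the shortest hostable precursor: mature + star + minimal loop
  min_needed <- 2L * mature_length_range[1L] + 12L
  if (precursor_length_range[2L] < min_needed) {
    stop("synthetic_config(): precursor_length_range too small to host ",
         "mature + star + loop (needs at least ", min_needed, " nt)")
  }
  structure(cfg, class = "synthetic_config")
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                             collapse = "")

comp_rna_base <- function(b) chartr("ACGU", "UGCA", b)

# A replacement for star position that neither WC- nor GU-pairs the mature
# base `p` (and differs from the current base).
non_pairing_base <- function(p, current) {
  banned <- switch(p, A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
  pool <- setdiff(c("A", "C", "G", "U"), c(banned, current))
  sample(pool, 1L)
}

# Build one hairpin around a mature sequence. The precursor is a
# continuous stem  LEFT | LOOP | RIGHT  with RIGHT = revcomp(LEFT) before
# star-side mutations. The mature arm reads  E5 | mature | spacer  (spacer
# toward the loop, so the mature is fully paired), and the star strand of
# the duplex carries the canonical 2-nt 3' overhang: its 3' end pairs two
# positions 5' of the mature's own 5' end. Mismatches and asymmetric
# bulges are introduced on the star arm only, away from the duplex ends.
build_hairpin <- function(mature, arm, loop_len, e5_len, sp_len,
                          n_mismatch, bulge_sizes) {
  m <- nchar(mature)
  mch <- seq_chars(mature)
  e5 <- rand_nt(e5_len)
  sp <- rand_nt(sp_len)
  n_bulge_nt <- sum(bulge_sizes)
  loop <- rand_nt(loop_len)

  # The mature arm reads (5'->3') E5|mature|spacer on the 5' side, or
  # spacer|mature|E5' on the 3' side; the star arm is its reverse
  # complement, so within the star arm the rc-mature region starts after
  # rc0 = (spacer or E5) positions, and its offset j pairs mature position
  # m - j + 1.
  mutate_star_arm <- function(star_arm, rc0) {
    interior <- seq.int(4L, m - 3L)
    if (n_mismatch > 0L) {
      at <- sort(sample(interior, n_mismatch))
      for (j in at) {
        star_arm[rc0 + j] <- non_pairing_base(mch[m - j + 1L],
                                              star_arm[rc0 + j])
      }
    }
    for (bs in bulge_sizes) {
      at <- rc0 + sample(seq.int(5L, m - 4L), 1L)
      star_arm <- append(star_arm, seq_chars(rand_nt(bs)), after = at)
    }
    star_arm
  }

  if (arm == "5p") {
    left <- paste0(e5, mature, sp)
    right <- paste(mutate_star_arm(seq_chars(revcomp_rna(left)), sp_len),
                   collapse = "")
    precursor <- paste0(left, loop, right)
    off <- nchar(left) + loop_len   # star-arm origin in precursor coords
    mature_iv <- c(e5_len + 1L, e5_len + m)
    star_iv <- off + c(sp_len + 3L, sp_len + m + 2L + n_bulge_nt)
    rc_iv <- off + c(sp_len + 1L, sp_len + m + n_bulge_nt)
  } else {
    right <- paste0(sp, mature, revcomp_rna(e5))
    left <- paste(mutate_star_arm(seq_chars(revcomp_rna(right)), e5_len),
                  collapse = "")
    precursor <- paste0(left, loop, right)
    mstart <- nchar(left) + loop_len + sp_len + 1L
    mature_iv <- c(mstart, mstart + m - 1L)
    star_iv <- c(e5_len + 3L, e5_len + m + 2L + n_bulge_nt)
    rc_iv <- c(e5_len + 1L, e5_len + m + n_bulge_nt)
  }
  list(precursor = precursor, mature_iv = mature_iv, star_iv = star_iv,
       rc_iv = rc_iv,
       star = substr(precursor, star_iv[1L], star_iv[2L]))
}

# Constructive validity: the planted hairpin must pass the discovery chain
# on its own window — star locatable from the rc-tag at the score floor,
# and the trimmed tag-to-rc-tag precursor folding into a duplex that
# passes the acceptance criteria.
hairpin_is_valid <- function(hp, pcfg) {
  window <- structure(list(seq = hp$precursor,
                           tag_start = hp$mature_iv[1L],
                           tag_end = hp$mature_iv[2L],
                           chrom = "synthetic", strand = "+",
                           g_start = 1L, g_end = nchar(hp$precursor),
                           trunc5 = TRUE, trunc3 = TRUE),
                      class = "flank_window")
  mature <- substr(hp$precursor, hp$mature_iv[1L], hp$mature_iv[2L])
  star <- tryCatch(locate_star(window, mature, pcfg),
                   error = function(e) NULL)
  if (is.null(star)) return(FALSE)
  cand_start <- min(window$tag_start, star$s_start)
  cand_end <- max(window$tag_end, star$s_end)
  trimmed <- substr(hp$precursor, cand_start, cand_end)
  fold <- fold_hairpin(trimmed, min_loop = pcfg$min_loop)
  ev <- tryCatch(
    evaluate_duplex(fold,
                    c(window$tag_start, window$tag_end) - cand_start + 1L,
                    c(star$s_start, star$s_end) - cand_start + 1L,
                    pcfg),
    error = function(e) NULL)
  !is.null(ev) && ev$accepted
}

# Synthetic gene models: per chromosome a few genes of structure
# CDS(1000) - intron(1000) - CDS(1000), used for context labelling.
make_gene_annotation <- function(cfg) {
  rows <- list()
  genes_per_chrom <- max(1L, cfg$chrom_length %/% 15000L)
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- sprintf("Chr%02d", ci)
    slots <- floor(seq(0.1, 0.9, length.out = genes_per_chrom) * cfg$chrom_length)
    for (gi in seq_along(slots)) {
      gstart <- slots[gi]
      if (gstart + 3000L > cfg$chrom_length) next
      gid <- sprintf("%s_gene%02d", chrom, gi)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, type = c("gene", "CDS", "CDS"),
        start = c(gstart, gstart, gstart + 2000L),
        end = c(gstart + 2999L, gstart + 999L, gstart + 2999L),
        strand = "+", id = gid, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

annotation_granges <- function(ann) {
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start, ann$end),
                               strand = ann$strand)
  gr$type <- ann$type
  gr$ID <- ann$id
  gr$phase <- ifelse(ann$type == "CDS", 0L, NA_integer_)
  gr
}

#' Generate a synthetic genome with planted hairpin loci and known truth
#'
#' Builds random chromosomes, plants `n_hairpins` pre-miRNA hairpins whose
#' mature/star duplex satisfies the acceptance criteria by construction
#' (each candidate hairpin is verified by folding and duplex evaluation
#' before insertion and re-drawn if necessary), embeds a fraction of them
#' inside synthetic gene models to exercise context labelling, and inserts
#' minus-strand hairpins as reverse complements.
#'
#' @param config a [synthetic_config()].
#' @param pcfg the [pipeline_config()] the planted hairpins must satisfy.
#' @return a `synthetic_data` list: `genome` (named `DNAStringSet`),
#'   `truth` (data frame, one row per hairpin: coordinates, strand,
#'   precursor/mature/star sequences and arms, genomic context,
#'   `base_count`), `annotation` (gene-model data frame), and the `config`.
#' @export
generate_genome_and_truth <- function(config = synthetic_config(),
                                      pcfg = pipeline_config()) {
  set.seed(config$seed)
  ann <- make_gene_annotation(config)

  chroms <- lapply(seq_len(config$n_chromosomes), function(i) {
    seq_chars(rand_nt(config$chrom_length))
  })
  names(chroms) <- sprintf("Chr%02d", seq_len(config$n_chromosomes))

  if (config$n_hairpins > 0L) {
    contexts <- sample(names(config$prop_context), config$n_hairpins,
                       replace = TRUE, prob = config$prop_context)
  } else {
    contexts <- character(0)
  }
  occupied <- lapply(chroms, function(x) cbind(start = integer(0),
                                               end = integer(0)))
  truth <- list()

  for (h in seq_len(config$n_hairpins)) {
    hp <- NULL
    for (try in seq_len(100L)) {
      m <- sample(seq.int(config$mature_length_range[1L],
                          config$mature_length_range[2L]), 1L)
      first <- if (stats::runif(1L) < config$u5_bias) "U" else
        sample(c("A", "C", "G"), 1L)
      mature <- paste0(first, rand_nt(m - 1L))
      arm <- sample(c("5p", "3p"), 1L)
      k <- sample(seq.int(config$duplex_mismatch_range[1L],
                          config$duplex_mismatch_range[2L]), 1L)
      nb <- if (config$bulge_max_count > 0L && m <= 23L)
        sample(0:config$bulge_max_count, 1L) else 0L
      bulges <- if (nb > 0L)
        sample(seq_len(config$bulge_max_size), nb, replace = TRUE) else integer(0)
      sp_len <- sample(3:6, 1L)
      # loop sized so the tag-to-rc-tag span lands inside the length window
      span_min <- config$precursor_length_range[1L]
      loop_lo <- max(12L, span_min - 2L * m - 2L * sp_len)
      loop_len <- sample(seq.int(loop_lo, loop_lo + 14L), 1L)
      e5_len <- sample(8:14, 1L)
      cand <- build_hairpin(mature, arm, loop_len, e5_len, sp_len, k, bulges)
      span <- cand$rc_iv[2L] - cand$mature_iv[1L] + 1L
      if (cand$mature_iv[1L] > cand$rc_iv[1L]) {
        span <- cand$mature_iv[2L] - cand$rc_iv[1L] + 1L
      }
      if (span < config$precursor_length_range[1L] ||
          nchar(cand$precursor) > config$precursor_length_range[2L]) next
      if (hairpin_is_valid(cand, pcfg)) {
        hp <- cand
        break
      }
    }
    if (is.null(hp)) {
      stop("generate_genome_and_truth(): could not construct a valid hairpin; ",
           "widen precursor_length_range or relax the duplex settings")
    }

    # placement honouring the requested genomic context
    plen <- nchar(hp$precursor)
    strand <- sample(c("+", "-"), 1L, prob = c(0.63, 0.37))
    placed <- FALSE
    for (try in seq_len(200L)) {
      chrom <- sample(names(chroms), 1L)
      ctx <- contexts[h]
      pos_range <- NULL
      if (ctx == "intergenic") {
        pos_range <- c(300L, config$chrom_length - plen - 300L)
      } else {
        feats <- ann[ann$chrom == chrom &
                       ann$type == (if (ctx == "CDS") "CDS" else "gene"), ,
                     drop = FALSE]
        if (ctx == "intronic") {
          # intron = central third of the synthetic gene model
          feats$start <- feats$start + 1000L
          feats$end <- feats$end - 1000L
        }
        if (nrow(feats) == 0L) next
        f <- feats[sample(nrow(feats), 1L), ]
        if (f$end - f$start + 1L < plen + 20L) next
        pos_range <- c(f$start + 10L, f$end - plen - 10L)
      }
      start <- sample(seq.int(pos_range[1L], pos_range[2L]), 1L)
      end <- start + plen - 1L
      occ <- occupied[[chrom]]
      if (nrow(occ) && any(start <= occ[, "end"] + 450L &
                           end >= occ[, "start"] - 450L)) next
      insert <- if (strand == "+") hp$precursor else revcomp_rna(hp$precursor)
      chroms[[chrom]][seq.int(start, end)] <- seq_chars(as_dna(insert))
      occupied[[chrom]] <- rbind(occ, cbind(start = start, end = end))
      mature <- substr(hp$precursor, hp$mature_iv[1L], hp$mature_iv[2L])
      m_arm <- if (hp$mature_iv[1L] < hp$star_iv[1L]) "5p" else "3p"
      if (strand == "+") {
        m_start <- start + hp$mature_iv[1L] - 1L
        m_end <- start + hp$mature_iv[2L] - 1L
      } else {
        m_start <- end - hp$mature_iv[2L] + 1L
        m_end <- end - hp$mature_iv[1L] + 1L
      }
      truth[[h]] <- data.frame(
        hairpin_id = sprintf("hp%02d", h),
        chrom = chrom, start = start, end = end, strand = strand,
        context = ctx,
        precursor = hp$precursor,
        mature = mature, mature_arm = m_arm,
        mature_offset = hp$mature_iv[1L],
        mature_start = m_start, mature_end = m_end,
        star = hp$star,
        star_arm = if (m_arm == "5p") "3p" else "5p",
        star_offset = hp$star_iv[1L],
        base_count = sample(seq.int(config$base_count_range[1L],
                                    config$base_count_range[2L]), 1L),
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("generate_genome_and_truth(): no room to place hairpin ", h,
           "; increase chrom_length or reduce n_hairpins")
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(chroms, function(x)
    as_dna(paste(x, collapse = "")), ""))
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(hairpin_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               context = character(0), precursor = character(0),
               mature = character(0), mature_arm = character(0),
               mature_offset = integer(0), mature_start = integer(0),
               mature_end = integer(0), star = character(0),
               star_arm = character(0), star_offset = integer(0),
               base_count = integer(0), stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  structure(list(genome = genome, truth = truth_df, annotation = ann,
                 config = config),
            class = "synthetic_data")
}

# Deterministic per-hairpin isomiR variant set: end shifts (d5, d3) with
# positive values extending into the precursor.
isomir_shift_pool <- rbind(c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L),
                           c(1L, 1L), c(-1L, -1L), c(2L, 0L), c(0L, 2L))

#' Simulate the eight small-RNA libraries from a synthetic truth
#'
#' Emits the mature, star, isomiR-shifted variants and random background
#' tags with per-library counts proportional to the configured fold-change
#' map. With `dispersion = 0` the emitted counts equal the rounded expected
#' counts exactly; otherwise counts are drawn from a negative binomial with
#' the expected count as mean. All emitted tag lengths stay within
#' 19-24 nt.
#'
#' @param synth a `synthetic_data` object from [generate_genome_and_truth()].
#' @return a data frame (`sequence`, `library`, `count`; zero-count rows
#'   omitted) with attribute `expected`, a data frame of the per-tag
#'   per-library expected counts (background tags excluded).
#' @export
simulate_libraries <- function(synth) {
  config <- synth$config
  truth <- synth$truth
  set.seed(config$seed + 1L)
  libs <- config$library_labels
  fcm <- config$fold_change_map
  if (is.null(fcm)) {
    fcm <- matrix(1, nrow = nrow(truth), ncol = length(libs),
                  dimnames = list(truth$hairpin_id, libs))
  }
  stopifnot(nrow(fcm) == nrow(truth), ncol(fcm) == length(libs))

  rows <- list()
  add <- function(hairpin, sequence, role, lib, expected) {
    rows[[length(rows) + 1L]] <<- data.frame(
      hairpin = hairpin, sequence = sequence, role = role, library = lib,
      expected = expected, stringsAsFactors = FALSE)
  }

  for (h in seq_len(nrow(truth))) {
    tr <- truth[h, ]
    m_iv <- c(tr$mature_offset, tr$mature_offset + nchar(tr$mature) - 1L)
    variants <- list()
    if (config$isomir_shift_prob > 0) {
      n_var <- 2L
      pick <- sample(nrow(isomir_shift_pool), n_var)
      for (v in pick) {
        d <- isomir_shift_pool[v, ]
        a <- m_iv[1L] - d[1L]
        b <- m_iv[2L] + d[2L]
        len <- b - a + 1L
        if (a < 1L || b > nchar(tr$precursor) || len < 19L || len > 24L) next
        vs <- substr(tr$precursor, a, b)
        if (vs != tr$mature) variants[[length(variants) + 1L]] <- vs
      }
    }
    variants <- unique(unlist(variants))
    p_iso <- if (length(variants)) config$isomir_shift_prob else 0
    for (l in seq_along(libs)) {
      e_mature <- tr$base_count * fcm[h, l]
      add(tr$hairpin_id, tr$mature, "mature", libs[l], e_mature * (1 - p_iso))
      if (length(variants)) {
        for (vs in variants) {
          add(tr$hairpin_id, vs, "isomir", libs[l],
              e_mature * p_iso / length(variants))
        }
      }
      if (nchar(tr$star) >= 19L && nchar(tr$star) <= 24L) {
        add(tr$hairpin_id, tr$star, "star", libs[l],
            config$star_fraction * e_mature)
      }
    }
  }
  expected <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hairpin = character(0), sequence = character(0),
               role = character(0), library = character(0),
               expected = numeric(0), stringsAsFactors = FALSE)

  counts <- expected[, c("sequence", "library")]
  counts$count <- if (config$dispersion > 0) {
    stats::rnbinom(nrow(expected), mu = expected$expected,
                   size = 1 / config$dispersion)
  } else {
    as.integer(round(expected$expected))
  }

  # background tags: uniform random sequences rejected if they (or their
  # reverse complement) occur in the genome
  bg <- character(0)
  genome_str <- as.character(synth$genome)
  while (length(bg) < config$background_tag_count) {
    s <- rand_nt(sample(19:24, 1L))
    d <- as_dna(s)
    present <- any(vapply(genome_str, function(g)
      grepl(d, g, fixed = TRUE) || grepl(revcomp_dna(d), g, fixed = TRUE),
      logical(1L)))
    if (!present && !(s %in% bg)) bg <- c(bg, s)
  }
  if (length(bg)) {
    bg_rows <- expand.grid(sequence = bg, library = libs,
                           stringsAsFactors = FALSE)
    bg_rows$count <- sample(0:3, nrow(bg_rows), replace = TRUE)
    counts <- rbind(counts, bg_rows)
  }

  counts <- counts[counts$count > 0, , drop = FALSE]
  agg <- stats::aggregate(count ~ sequence + library, data = counts, FUN = sum)
  agg <- agg[order(agg$sequence, agg$library), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "expected") <- expected
  agg
}

#' Simulate a stem-loop RT-qPCR Ct table with known fold changes
#'
#' Reference genes have stable Ct across conditions; each target gene's Ct
#' shifts by `-log2(fold change)` relative to its baseline condition, plus
#' Gaussian replicate noise.
#'
#' @param genes character vector of target gene ids.
#' @param conditions character vector of condition ids.
#' @param log2fc numeric matrix (genes x conditions) of log2 fold changes
#'   relative to baseline expression (0 = unchanged).
#' @param ref_genes reference gene ids (default three, as in stem-loop
#'   qPCR practice).
#' @param n_rep replicates per (gene, condition).
#' @param sd_ct Gaussian Ct noise (cycles).
#' @param base_ct baseline target Ct; references sit at `base_ct - 3`.
#' @param seed integer seed.
#' @return a `ct_table` data frame: `gene`, `condition`, `replicate`, `ct`,
#'   with attribute `ref_genes`.
#' @export
simulate_ct_table <- function(genes, conditions, log2fc = NULL,
                              ref_genes = c("ref1", "ref2", "ref3"),
                              n_rep = 3L, sd_ct = 0.15, base_ct = 26,
                              seed = 1L) {
  set.seed(seed)
  if (is.null(log2fc)) {
    log2fc <- matrix(0, nrow = length(genes), ncol = length(conditions),
                     dimnames = list(genes, conditions))
  }
  rows <- list()
  for (g in c(genes, ref_genes)) {
    for (cond in conditions) {
      mu <- if (g %in% ref_genes) base_ct - 3 else
        base_ct - log2fc[g, cond]     # higher expression -> lower Ct
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, replicate = seq_len(n_rep),
        ct = stats::rnorm(n_rep, mu, sd_ct), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ref_genes") <- ref_genes
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Write a synthetic genome as FASTA
#'
#' @param synth a `synthetic_data` object (or a `DNAStringSet`).
#' @param path output FASTA path (60-column wrap).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(synth, path) {
  genome <- if (inherits(synth, "synthetic_data")) synth$genome else synth
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Write the synthetic gene annotation as GFF3
#'
#' @param synth a `synthetic_data` object.
#' @param path output GFF3 path (1-based inclusive coordinates).
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(synth, path) {
  rtracklayer::export(annotation_granges(synth$annotation), path,
                      format = "gff3")
  invisible(path)
}

#' Write the synthetic truth table as TSV
#'
#' @param synth a `synthetic_data` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(synth, path) {
  utils::write.table(synth$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulated reads as per-library FASTQ
#'
#' Each tag is replicated `count` times with dummy qualities.
#'
#' @param reads long data frame from [simulate_libraries()].
#' @param dir output directory; one `<library>.fastq` per library.
#' @return the directory, invisibly.
#' @export
write_reads_fastq <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (lib in unique(reads$library)) {
    sub <- reads[reads$library == lib, , drop = FALSE]
    seqs <- rep(as_dna(sub$sequence), sub$count)
    if (length(seqs) == 0L) {
      file.create(file.path(dir, paste0(lib, ".fastq")))
      next
    }
    ids <- sprintf("@%s_read%06d", lib, seq_along(seqs))
    qual <- vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), "")
    writeLines(as.vector(rbind(ids, seqs, "+", qual)),
               file.path(dir, paste0(lib, ".fastq")))
  }
  invisible(dir)
}
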