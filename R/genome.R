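#' Build an exact-match genome index
#'
#' Wraps the genome as a `DNAStringSet` and validates chromosome names.
#' Lookups are exact substring matches on both strands, served by
#' Biostrings pattern matching; hits are reported in a deterministic order
#' (chromosome id, then start).
#'
#' @param genome a `DNAStringSet`, a named character vector of chromosome
#'   sequences (DNA or RNA alphabet), or a path to a FASTA file.
#' @return a `genome_index` object.
#' @export
build_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(as_dna(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("build_index(): every chromosome needs a name")
  }
  if (anyDuplicated(names(genome))) {
    stop("build_index(): duplicate chromosome id: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  }
  structure(list(genome = genome), class = "genome_index")
}

#' Find all exact genomic matches of one tag
#'
#' Searches both strands; a minus-strand hit means the reverse complement
#' of the genomic slice equals the tag. Coordinates are 1-based inclusive
#' on the plus strand of the chromosome. Overlapping matches each count as
#' a distinct locus.
#'
#' @param index a `genome_index`.
#' @param tag tag sequence (RNA or DNA alphabet).
#' @return data frame with columns `chrom`, `start`, `end`, `strand`,
#'   ordered by chromosome then start then strand.
#' @export
match_tag <- function(index, tag) {
  stopifnot(inherits(index, "genome_index"))
  pat <- Biostrings::DNAString(as_dna(tag))
  rcp <- Biostrings::reverseComplement(pat)
  hits <- list()
  for (chrom in names(index$genome)) {
    subj <- index$genome[[chrom]]
    fwd <- Biostrings::matchPattern(pat, subj)
    if (length(fwd)) {
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = Biostrings::start(fwd),
        end = Biostrings::end(fwd), strand = "+", stringsAsFactors = FALSE)
    }
    rev <- Biostrings::matchPattern(rcp, subj)
    if (length(rev)) {
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = Biostrings::start(rev),
        end = Biostrings::end(rev), strand = "-", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map tags to the genome and apply the locus-count filter
#'
#' Tags with zero exact matches are dropped, as are tags matching the
#' genome at more than `max_genome_hits` loci (both strands pooled); both
#' removals are reported via `message()`.
#'
#' @param tags a `tag_table` (or data frame with a `sequence` column).
#' @param index a `genome_index`.
#' @param config a [pipeline_config()].
#' @return named list: one hit data frame (see [match_tag()]) per retained
#'   tag sequence.
#' @export
map_and_filter <- function(tags, index, config = pipeline_config()) {
  seqs <- tags$sequence
  out <- list()
  n_unmapped <- 0L
  n_multi <- 0L
  for (s in seqs) {
    h <- match_tag(index, s)
    if (nrow(h) == 0L) {
      n_unmapped <- n_unmapped + 1L
    } else if (nrow(h) > config$max_genome_hits) {
      n_multi <- n_multi + 1L
      message(sprintf("map_and_filter(): dropped %s (%d genome matches > %d)",
                      s, nrow(h), config$max_genome_hits))
    } else {
      out[[s]] <- h
    }
  }
  if (n_unmapped > 0L) {
    message(sprintf("map_and_filter(): %d tag(s) had no exact genome match",
                    n_unmapped))
  }
  out
}

#' Write genome hits as BED
#'
#' BED is written half-open 0-based on disk (start column = internal
#' 1-based start minus one); the score column carries the tag's pooled
#' read count when available.
#'
#' @param hits named list of hit data frames from [map_and_filter()].
#' @param path output path.
#' @param tags optional `tag_table` supplying pooled counts.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, tags = NULL) {
  rows <- lapply(names(hits), function(s) {
    h <- hits[[s]]
    score <- 0L
    if (!is.null(tags)) {
      k <- match(s, tags$sequence)
      if (!is.na(k)) score <- tags$total_count[k]
    }
    data.frame(chrom = h$chrom, start = h$start - 1L, end = h$end,
               name = s, score = score, strand = h$strand,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0))
  out <- out[order(out$chrom, out$start, out$name), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract a chromosome slice as a character string
#'
#' @param index a `genome_index`.
#' @param chrom chromosome id.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"` (minus returns the reverse complement).
#' @return DNA sequence string.
#' @export
genome_slice <- function(index, chrom, start, end, strand = "+") {
  subj <- index$genome[[chrom]]
  stopifnot(!is.null(subj), start >= 1L, end <= length(subj), start <= end)
  s <- as.character(Biostrings::subseq(subj, start, end))
  if (strand == "-") s <- revcomp_dna(s)
  s
}
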