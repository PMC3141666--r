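#' Collapse small-RNA reads into unique counted tags
#'
#' Groups adapter-trimmed reads into unique sequences (tags) and counts
#' them per library. Sequences are uppercased and T is normalised to U;
#' reads containing characters outside A/C/G/U/T are skipped with a
#' warning. The result is ordered lexicographically by sequence so that
#' repeated runs are byte-identical.
#'
#' @param reads a data frame with columns `sequence` and `library` (one row
#'   per read occurrence), or a character vector of sequences for a single
#'   unnamed library.
#' @return a `tag_table`: data frame with columns `sequence`, one count
#'   column per library, and `total_count`; the library names are kept in
#'   attribute `libraries`.
#' @examples
#' collapse_reads(data.frame(sequence = c("ACGU", "ACGU", "acgt"),
#'                           library = c("L1", "L1", "L2")))
#' @export
collapse_reads <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(sequence = reads,
                        library = rep("library_1", length(reads)))
  }
  stopifnot(is.data.frame(reads),
            all(c("sequence", "library") %in% names(reads)))
  if (nrow(reads) == 0L) {
    out <- data.frame(sequence = character(0), total_count = integer(0))
    attr(out, "libraries") <- character(0)
    class(out) <- c("tag_table", "data.frame")
    return(out)
  }
  seqs <- as_rna(reads$sequence)
  ok <- grepl("^[ACGU]+$", seqs)
  if (any(!ok)) {
    warning(sprintf("collapse_reads(): skipped %d read(s) with characters outside ACGU/T",
                    sum(!ok)))
  }
  seqs <- seqs[ok]
  libs <- as.character(reads$library)[ok]
  lib_levels <- sort(unique(libs))
  counts <- table(factor(seqs), factor(libs, levels = lib_levels))
  mat <- matrix(as.integer(counts), nrow = nrow(counts),
                dimnames = dimnames(counts))
  out <- data.frame(sequence = rownames(mat), stringsAsFactors = FALSE)
  for (l in lib_levels) out[[l]] <- mat[, l]
  out$total_count <- as.integer(rowSums(mat))
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "libraries") <- lib_levels
  class(out) <- c("tag_table", "data.frame")
  out
}

#' Filter tags by read count and length window
#'
#' Applies the low-count filter (pooled read count of at most
#' `min_total_count - 1` is discarded; the published rule drops pooled
#' counts of two or fewer) and the tag length window. Counts of retained
#' tags are left unchanged, so the filter is idempotent.
#'
#' @param tags a `tag_table` from [collapse_reads()].
#' @param config a [pipeline_config()].
#' @param per_library if `TRUE` a tag is kept when *any* single library
#'   reaches `min_total_count` (the published text does not say whether the
#'   count rule was pooled or per library; pooled is the default).
#' @return the filtered `tag_table`.
#' @export
filter_tags <- function(tags, config = pipeline_config(), per_library = FALSE) {
  stopifnot(inherits(tags, "tag_table") || is.data.frame(tags))
  libs <- attr(tags, "libraries")
  if (is.null(libs)) libs <- setdiff(names(tags), c("sequence", "total_count"))
  len_ok <- nchar(tags$sequence) >= config$length_window[1L] &
    nchar(tags$sequence) <= config$length_window[2L]
  if (per_library && length(libs)) {
    cnt <- as.matrix(tags[, libs, drop = FALSE])
    count_ok <- apply(cnt, 1L, max) >= config$min_total_count
  } else {
    count_ok <- tags$total_count >= config$min_total_count
  }
  out <- tags[len_ok & count_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "libraries") <- libs
  class(out) <- c("tag_table", "data.frame")
  out
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Qualities in FASTQ are ignored. The library label is taken from
#' `library`, one label per file.
#'
#' @param paths character vector of FASTA/FASTQ file paths.
#' @param library library labels, recycled along `paths`; defaults to the
#'   file base names.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (by file extension).
#' @return a data frame with columns `sequence` and `library`, one row per
#'   read, suitable for [collapse_reads()].
#' @export
read_small_rna <- function(paths, library = NULL, format = "auto") {
  if (is.null(library)) {
    library <- tools::file_path_sans_ext(basename(paths))
  }
  library <- rep_len(library, length(paths))
  res <- lapply(seq_along(paths), function(k) {
    fmt <- format
    if (fmt == "auto") {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", paths[k], ignore.case = TRUE))
        "fastq" else "fasta"
    }
    ss <- Biostrings::readBStringSet(paths[k], format = fmt)
    data.frame(sequence = as.character(ss),
               library = rep(library[k], length(ss)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read a collapsed tag table from TSV
#'
#' The on-disk format is long: columns `sequence`, `library`, `count`.
#'
#' @param path TSV path.
#' @return a `tag_table`.
#' @export
read_tag_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "library", "count") %in% names(df)))
  expanded <- df[df$count > 0, , drop = FALSE]
  reads <- data.frame(
    sequence = rep(expanded$sequence, expanded$count),
    library = rep(expanded$library, expanded$count),
    stringsAsFactors = FALSE)
  collapse_reads(reads)
}

#' Write a collapsed tag table to TSV
#'
#' @param tags a `tag_table`.
#' @param path output TSV path (columns `sequence`, `library`, `count`;
#'   zero counts omitted).
#' @return `path`, invisibly.
#' @export
write_tag_tsv <- function(tags, path) {
  libs <- attr(tags, "libraries")
  rows <- list()
  for (l in libs) {
    nz <- tags[[l]] > 0
    if (any(nz)) {
      rows[[l]] <- data.frame(sequence = tags$sequence[nz],
                              library = l,
                              count = tags[[l]][nz],
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), library = character(0),
               count = integer(0))
  out <- out[order(out$sequence, out$library), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
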