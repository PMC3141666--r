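#' Read a miRBase-style FASTA catalog
#'
#' Header lines are expected to start with an id carrying a three-letter
#' species prefix (e.g. `gma-miR156a`); the remainder of the header is
#' kept as description. Sequences are normalised to RNA.
#'
#' @param path FASTA path.
#' @return data frame with columns `id`, `species`, `description`,
#'   `sequence`.
#' @export
read_mirna_catalog <- function(path) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("read_mirna_catalog(): cannot parse ",
                                          path, ": ", conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(ss))
  desc <- sub("^\\S+\\s*", "", names(ss))
  data.frame(id = ids,
             species = sub("^([A-Za-z]{3})-.*$", "\\1", ids),
             description = desc,
             sequence = as_rna(as.character(ss)),
             stringsAsFactors = FALSE)
}

# id "gma-miR156a-5p" -> family key "MIR156" (strip species, letter and
# arm suffixes, case-folded); ties hairpins to their recorded matures.
catalog_family <- function(id) {
  x <- sub("^[A-Za-z]{3}-", "", id)
  x <- sub("-(5p|3p)$", "", x)
  toupper(sub("(?i)^((mir)[-]?[0-9]+).*$", "\\1", x, perl = TRUE))
}

#' Classify accepted miRNA candidates into novelty classes
#'
#' Implements the five-way partition used for sequencing-derived miRNAs:
#' \describe{
#'   \item{KNOWN}{mature identical to a same-species catalog mature at its
#'     catalog locus (the candidate precursor and the catalog hairpin
#'     contain one another or share the recorded mature placement);}
#'   \item{ANTISENSE_ARM_OF_KNOWN}{mature lies on a same-species catalog
#'     hairpin on the arm opposite the recorded mature;}
#'   \item{NEW_MEMBER_KNOWN_FAMILY}{mature identical to a same-species
#'     catalog mature but from a different locus, or within
#'     `max_family_subs` substitutions of one;}
#'   \item{CONSERVED_OTHER_SPECIES}{mature identical to a catalog mature
#'     of another species;}
#'   \item{ISOFORM}{an end-shifted variant of a recorded mature on its own
#'     hairpin;}
#'   \item{NOVEL_FAMILY}{none of the above.}
#' }
#' Matching is U/T- and case-insensitive. Classes are assigned in the
#' priority order listed, so each record receives exactly one class.
#'
#' @param candidates a `precursor_candidates` data frame from [discover()].
#' @param species_mature,species_hairpin catalog data frames from
#'   [read_mirna_catalog()] (or FASTA paths) for the study species; either
#'   may be `NULL`.
#' @param other_mature catalog of other-species matures (or path), or
#'   `NULL`.
#' @param species three-letter prefix of the study species (default
#'   `"gma"`).
#' @param max_family_subs substitutions tolerated for family membership
#'   (default 2).
#' @return the candidates with columns `class` and `matched_id` appended.
#' @export
classify_mirnas <- function(candidates, species_mature = NULL,
                            species_hairpin = NULL, other_mature = NULL,
                            species = "gma", max_family_subs = 2L) {
  as_catalog <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) read_mirna_catalog(x) else x
  }
  species_mature <- as_catalog(species_mature)
  species_hairpin <- as_catalog(species_hairpin)
  other_mature <- as_catalog(other_mature)
  if (!is.null(species_mature)) {
    species_mature <- species_mature[species_mature$species == species, ,
                                     drop = FALSE]
  }
  if (!is.null(other_mature)) {
    other_mature <- other_mature[other_mature$species != species, ,
                                 drop = FALSE]
  }

  n_subs <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(seq_chars(a) != seq_chars(b))
  }

  cls <- character(nrow(candidates))
  hit_id <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    mat <- as_rna(candidates$mature[i])
    prec <- as_rna(candidates$precursor[i])
    cls_i <- NA_character_
    id_i <- NA_character_

    if (!is.null(species_mature) && !is.null(species_hairpin)) {
      for (k in seq_len(nrow(species_hairpin))) {
        hp <- species_hairpin$sequence[k]
        hp_fam <- catalog_family(species_hairpin$id[k])
        rec <- species_mature[vapply(species_mature$id, catalog_family, "") ==
                                hp_fam, , drop = FALSE]
        rec <- rec[vapply(rec$sequence, function(s) grepl(s, hp, fixed = TRUE),
                          logical(1L)), , drop = FALSE]
        same_locus <- grepl(prec, hp, fixed = TRUE) ||
          grepl(hp, prec, fixed = TRUE)
        if (!same_locus) next
        if (nrow(rec) && mat %in% rec$sequence) {
          cls_i <- "KNOWN"; id_i <- species_hairpin$id[k]; break
        }
        cand_pos <- regexpr(mat, hp, fixed = TRUE)
        if (cand_pos < 0L) next
        cand_iv <- c(cand_pos, cand_pos + nchar(mat) - 1L)
        overlapping <- FALSE
        disjoint_rec <- FALSE
        for (r in seq_len(nrow(rec))) {
          rp <- regexpr(rec$sequence[r], hp, fixed = TRUE)
          if (rp < 0L) next
          riv <- c(rp, rp + nchar(rec$sequence[r]) - 1L)
          if (cand_iv[1L] <= riv[2L] && cand_iv[2L] >= riv[1L]) {
            overlapping <- TRUE
          } else {
            disjoint_rec <- TRUE
          }
        }
        if (disjoint_rec && !overlapping) {
          cls_i <- "ANTISENSE_ARM_OF_KNOWN"; id_i <- species_hairpin$id[k]
          break
        }
        if (overlapping) {
          cls_i <- "ISOFORM"; id_i <- species_hairpin$id[k]
          break
        }
      }
    }
    if (is.na(cls_i) && !is.null(species_mature) && nrow(species_mature)) {
      exact <- species_mature$sequence == mat
      near <- vapply(species_mature$sequence, n_subs, 0, b = mat) <=
        max_family_subs
      if (any(exact)) {
        cls_i <- "NEW_MEMBER_KNOWN_FAMILY"
        id_i <- species_mature$id[which(exact)[1L]]
      } else if (any(near)) {
        cls_i <- "NEW_MEMBER_KNOWN_FAMILY"
        id_i <- species_mature$id[which(near)[1L]]
      }
    }
    if (is.na(cls_i) && !is.null(other_mature) && nrow(other_mature)) {
      exact <- other_mature$sequence == mat
      if (any(exact)) {
        cls_i <- "CONSERVED_OTHER_SPECIES"
        id_i <- other_mature$id[which(exact)[1L]]
      }
    }
    if (is.na(cls_i)) cls_i <- "NOVEL_FAMILY"
    cls[i] <- cls_i
    hit_id[i] <- id_i
  }
  candidates$class <- cls
  candidates$matched_id <- hit_id
  candidates
}

#' Assign provisional family names to classified records
#'
#' Novel families are numbered in deterministic order of their first locus
#' (chromosome, then start): `<species>-MIR-Seq01`, `Seq02`, ... Records
#' with identical mature sequences at different loci share a family and
#' receive letter suffixes `a`, `b`, ... in coordinate order; when both
#' arms of one precursor are observed the two records carry `-5p`/`-3p`
#' suffixes instead. Naming is stable: records are keyed by mature
#' sequence and locus, so adding unrelated records never renames an
#' existing family.
#'
#' @param records classified candidates from [classify_mirnas()] (novel
#'   records are named; others keep their matched catalog id).
#' @param species species prefix for the ids (default `"gma"`).
#' @return `records` with an `id` column appended.
#' @export
assign_names <- function(records, species = "gma") {
  records$id <- rep(NA_character_, nrow(records))
  novel <- which(records$class == "NOVEL_FAMILY")
  if (length(novel)) {
    # Two novel records belong to one family when they share a locus (the
    # two arms of one precursor) or have identical mature sequences (a
    # second locus of the family). Union-find over those relations.
    locus <- sprintf("%s:%d-%d", records$chrom[novel], records$start[novel],
                     records$end[novel])
    parent <- seq_along(novel)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union_ <- function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
    }
    for (i in seq_along(novel)) {
      for (j in seq_len(i - 1L)) {
        if (locus[i] == locus[j] ||
            records$mature[novel[i]] == records$mature[novel[j]]) {
          union_(i, j)
        }
      }
    }
    fam <- vapply(seq_along(novel), find, 0L)
    fam_first <- vapply(unique(fam), function(f) {
      rows <- novel[fam == f]
      i <- rows[order(records$chrom[rows], records$start[rows])][1L]
      sprintf("%s:%012d", records$chrom[i], records$start[i])
    }, "")
    fam_num <- stats::setNames(order(order(fam_first)), unique(fam))
    for (f in unique(fam)) {
      rows <- novel[fam == f]
      rows <- rows[order(records$chrom[rows], records$start[rows],
                         records$mature_arm[rows])]
      base <- sprintf("%s-MIR-Seq%02d", species, fam_num[[as.character(f)]])
      loci <- unique(sprintf("%s:%d", records$chrom[rows], records$start[rows]))
      for (r in rows) {
        id <- base
        this_locus <- sprintf("%s:%d", records$chrom[r], records$start[r])
        if (length(loci) > 1L) {
          id <- paste0(id, letters[match(this_locus, loci)])
        }
        same_locus_rows <- rows[sprintf("%s:%d", records$chrom[rows],
                                        records$start[rows]) == this_locus]
        if (length(same_locus_rows) > 1L ||
            identical(records$arms_observed[r], "3p/5p")) {
          id <- paste0(id, "-", records$mature_arm[r])
        }
        records$id[r] <- id
      }
    }
  }
  known <- which(records$class != "NOVEL_FAMILY")
  if (length(known)) {
    records$id[known] <- ifelse(is.na(records$matched_id[known]),
                                sprintf("%s-unnamed%02d", species,
                                        seq_along(known)),
                                records$matched_id[known])
  }
  records
}

#' Group the isomiRs of one mature miRNA
#'
#' Summarises all end-variants observed within one precursor as the
#' positional intersection pattern `+n5/CORE/+n3`: `CORE` is the maximal
#' region shared by every member (their placement intersection on the
#' precursor) and `n5`/`n3` are the largest extensions observed 5' and 3'
#' of it. Zero extensions are omitted from the serialised pattern.
#'
#' @param members character vector of member tag sequences (each must be a
#'   substring of the precursor); duplicates are ignored.
#' @param precursor the precursor sequence.
#' @param reference the reference mature sequence (counted as a member).
#' @return an `isomir_group` list: `core`, `n5`, `n3`, `pattern`,
#'   `n_isoforms`, `members`.
#' @export
group_isomirs <- function(members, precursor, reference = NULL) {
  precursor <- as_rna(precursor)
  members <- unique(as_rna(c(reference, members)))
  pos <- lapply(members, function(s) {
    p <- regexpr(s, precursor, fixed = TRUE)
    if (p < 0L) NULL else c(p, p + nchar(s) - 1L)
  })
  bad <- vapply(pos, is.null, logical(1L))
  if (any(bad)) {
    warning("group_isomirs(): dropped ", sum(bad),
            " member(s) not found in the precursor")
    members <- members[!bad]
    pos <- pos[!bad]
  }
  if (length(members) == 0L) {
    stop("group_isomirs(): no member occurs in the precursor")
  }
  starts <- vapply(pos, `[`, 0, 1L)
  ends <- vapply(pos, `[`, 0, 2L)
  core_start <- max(starts)
  core_end <- min(ends)
  if (core_start > core_end) {
    stop("group_isomirs(): members share no common core on the precursor")
  }
  n5 <- core_start - min(starts)
  n3 <- max(ends) - core_end
  core <- substr(precursor, core_start, core_end)
  pattern <- core
  if (n5 > 0) pattern <- paste0("+", n5, "/", pattern)
  if (n3 > 0) pattern <- paste0(pattern, "/+", n3)
  structure(list(core = core, n5 = as.integer(n5), n3 = as.integer(n3),
                 pattern = pattern, n_isoforms = length(members),
                 members = sort(members)),
            class = "isomir_group")
}

#' @export
print.isomir_group <- function(x, ...) {
  cat(sprintf("isomiR group: %s (%d isoforms)\n", x$pattern, x$n_isoforms))
  invisible(x)
}
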