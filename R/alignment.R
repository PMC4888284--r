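# Gapless binding-site alignments: the raw material for profile construction.
#
# All coordinates (provenance, mask indices, column ranges) are 0-based
# half-open; strand "+" is the GenBank top strand.

#' Construct a binding-site alignment
#'
#' A `site_alignment` holds a gapless set of equal-length DNA sequences
#' (a binding-site or promoter alignment), an optional per-sequence genome
#' provenance, and a set of masked columns that are ignored by information
#' content and window scoring.
#'
#' @param name Alignment name (usually the regulator).
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of DNA sequences over `{A,C,G,T,N}`, all the
#'   same length, no gaps.
#' @param provenance Optional data frame with columns `genome`, `start`,
#'   `end`, `strand` (0-based half-open, top-strand coordinates), one row per
#'   sequence; rows may be all-`NA` for sequences of unknown origin.
#' @param mask Integer vector of masked 0-based column indices.
#' @return An object of class `site_alignment`.
#' @export
site_alignment <- function(name, ids, seqs, provenance = NULL, mask = integer()) {
  if (length(seqs) < 1L) {
    regsig_error("alignment must contain at least one sequence", "regsig_argument_error")
  }
  if (length(ids) != length(seqs)) {
    regsig_error("ids and seqs must have equal length", "regsig_argument_error")
  }
  seqs <- toupper(seqs)
  if (any(grepl("[-.]", seqs))) {
    regsig_error("alignment sequences must not contain gap characters", "regsig_content_error")
  }
  check_dna(seqs, "alignment sequence")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- ids[which(lens != lens[1L])[1L]]
    regsig_error(
      sprintf("sequences have unequal lengths (first offending record: %s)", off),
      "regsig_shape_error"
    )
  }
  L <- lens[1L]
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 0L || max(mask) >= L)) {
    regsig_error("mask indices must lie in [0, L)", "regsig_range_error")
  }
  if (is.null(provenance)) {
    provenance <- data.frame(
      genome = rep(NA_character_, length(seqs)),
      start = NA_integer_, end = NA_integer_, strand = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    provenance <- as.data.frame(provenance, stringsAsFactors = FALSE)
    stopifnot(all(c("genome", "start", "end", "strand") %in% names(provenance)))
    provenance <- provenance[, c("genome", "start", "end", "strand")]
    has <- !is.na(provenance$genome)
    if (any(has & (provenance$end - provenance$start != L))) {
      regsig_error("provenance interval length must equal alignment width", "regsig_shape_error")
    }
  }
  rownames(provenance) <- NULL
  structure(
    list(name = name, ids = as.character(ids), seqs = seqs,
         provenance = provenance, mask = mask),
    class = "site_alignment"
  )
}

#' @export
print.site_alignment <- function(x, ...) {
  cat(sprintf("<site_alignment> %s: %d sequences x %d columns (%d masked)\n",
              x$name, length(x$seqs), alignment_width(x), length(x$mask)))
  invisible(x)
}

#' Alignment width (number of columns)
#' @param aln A `site_alignment`.
#' @return Integer column count.
#' @export
alignment_width <- function(aln) nchar(aln$seqs[1L])

#' Number of sequences in an alignment
#' @param aln A `site_alignment`.
#' @return Integer sequence count.
#' @export
alignment_size <- function(aln) length(aln$seqs)

has_provenance <- function(aln) !any(is.na(aln$provenance$genome))

#' Load a binding-site alignment from FASTA
#'
#' Reads a gapless FASTA alignment. When a record header is formatted as
#' `id:genome:start-end:strand` the genome provenance (0-based half-open)
#' is parsed; otherwise provenance is absent for that record.
#'
#' @param path FASTA file.
#' @param name Alignment name; defaults to the file basename.
#' @return A [site_alignment()].
#' @export
load_alignment <- function(path, name = NULL) {
  if (!file.exists(path)) {
    regsig_error(sprintf("alignment file not found: %s", path), "regsig_io_error")
  }
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) regsig_error(sprintf("cannot read FASTA %s: %s", path, conditionMessage(e)),
                                     "regsig_io_error")
  )
  if (length(ss) == 0L) {
    regsig_error(sprintf("no FASTA records in %s", path), "regsig_io_error")
  }
  headers <- names(ss)
  seqs <- unname(as.character(ss))
  ids <- headers
  prov <- data.frame(genome = NA_character_, start = NA_integer_,
                     end = NA_integer_, strand = NA_character_,
                     stringsAsFactors = FALSE)[rep(1L, length(seqs)), ]
  m <- regmatches(headers, regexec("^(\\S+?):(\\S+?):(\\d+)-(\\d+):([+-])$", headers))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 6L) {
      ids[i] <- m[[i]][2L]
      prov$genome[i] <- m[[i]][3L]
      prov$start[i] <- as.integer(m[[i]][4L])
      prov$end[i] <- as.integer(m[[i]][5L])
      prov$strand[i] <- m[[i]][6L]
    } else {
      ids[i] <- sub("\\s.*$", "", headers[i])
    }
  }
  rownames(prov) <- NULL
  if (is.null(name)) name <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  site_alignment(name, ids, seqs, provenance = prov)
}

#' Write an alignment to FASTA
#'
#' Provenance, when present, is encoded in the record headers as
#' `id:genome:start-end:strand` so that [load_alignment()] round-trips it.
#'
#' @param aln A `site_alignment`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  headers <- aln$ids
  has <- !is.na(aln$provenance$genome)
  headers[has] <- sprintf("%s:%s:%d-%d:%s", aln$ids[has],
                          aln$provenance$genome[has], aln$provenance$start[has],
                          aln$provenance$end[has], aln$provenance$strand[has])
  ss <- Biostrings::DNAStringSet(aln$seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

check_ranges <- function(ranges, L) {
  if (length(ranges) == 0L) {
    regsig_error("at least one column range is required", "regsig_argument_error")
  }
  ranges <- lapply(ranges, function(r) as.integer(r))
  for (r in ranges) {
    if (length(r) != 2L || r[1L] >= r[2L]) {
      regsig_error("each range must be a (start, end) pair with start < end", "regsig_argument_error")
    }
    if (r[1L] < 0L || r[2L] > L) {
      regsig_error(sprintf("range [%d,%d) outside [0,%d)", r[1L], r[2L], L), "regsig_range_error")
    }
  }
  ord <- order(vapply(ranges, `[`, integer(1L), 1L))
  ranges <- ranges[ord]
  if (length(ranges) > 1L) {
    for (i in 2:length(ranges)) {
      if (ranges[[i]][1L] < ranges[[i - 1L]][2L]) {
        regsig_error("column ranges must not overlap", "regsig_argument_error")
      }
    }
  }
  ranges
}

#' Extract columns from an alignment
#'
#' Concatenates the selected column intervals (0-based half-open) in genomic
#' order, e.g. to export part of a logo selection as a new alignment. With a
#' single range the provenance coordinates are shifted accordingly; with
#' several ranges the result is no longer a contiguous genome slice, so
#' provenance is dropped.
#'
#' @param aln A `site_alignment`.
#' @param ranges List of `c(start, end)` column intervals.
#' @return A new `site_alignment`.
#' @export
slice_alignment <- function(aln, ranges) {
  L <- alignment_width(aln)
  ranges <- check_ranges(ranges, L)
  cols <- unlist(lapply(ranges, function(r) seq.int(r[1L] + 1L, r[2L])))
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  seqs <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
  mask0 <- aln$mask
  new_mask <- which((cols - 1L) %in% mask0) - 1L
  prov <- NULL
  if (length(ranges) == 1L && has_provenance(aln)) {
    a <- ranges[[1L]][1L]; b <- ranges[[1L]][2L]
    prov <- aln$provenance
    plus <- prov$strand == "+"
    ns <- ifelse(plus, prov$start + a, prov$end - b)
    ne <- ifelse(plus, prov$start + b, prov$end - a)
    prov$start <- as.integer(ns); prov$end <- as.integer(ne)
  }
  site_alignment(aln$name, aln$ids, seqs, provenance = prov, mask = new_mask)
}

#' Mask alignment columns
#'
#' Masked columns contribute 0 bits to information content and 0 to window
#' scores in profiles built from the alignment.
#'
#' @param aln A `site_alignment`.
#' @param ranges List of `c(start, end)` 0-based half-open column intervals;
#'   an empty list leaves the alignment unchanged.
#' @return A copy with the mask extended.
#' @export
mask_columns <- function(aln, ranges) {
  if (length(ranges) == 0L) return(aln)
  L <- alignment_width(aln)
  ranges <- check_ranges(ranges, L)
  extra <- unlist(lapply(ranges, function(r) seq.int(r[1L], r[2L] - 1L)))
  aln$mask <- sort(unique(c(aln$mask, as.integer(extra))))
  aln
}

#' Extend alignment sequences into their genomic flanks
#'
#' Replaces each sequence by the genome slice `[start - left, end + right)`
#' read on its own strand (minus-strand sequences take their "left" flank
#' from the high-coordinate side and are reverse-complemented), so `left`
#' is always 5' of the site as the site itself is read.
#'
#' @param aln A `site_alignment` in which every sequence has provenance.
#' @param genomes Named list of [genome_record()]s keyed by genome id.
#' @param left,right Non-negative flank widths in nucleotides.
#' @param drop_on_error If `TRUE`, sequences whose flanks fall outside the
#'   replicon are dropped (with a warning) instead of raising an error.
#' @return A new `site_alignment` of width `L + left + right`.
#' @export
extend_alignment <- function(aln, genomes, left, right, drop_on_error = FALSE) {
  left <- as.integer(left); right <- as.integer(right)
  stopifnot(left >= 0L, right >= 0L)
  if (!has_provenance(aln)) {
    regsig_error("every sequence needs provenance for extension", "regsig_provenance_error")
  }
  if (left == 0L && right == 0L) return(aln)
  n <- alignment_size(aln)
  seqs <- character(n); keep <- logical(n)
  prov <- aln$provenance
  bad <- character(0)
  for (i in seq_len(n)) {
    gid <- prov$genome[i]
    if (!gid %in% names(genomes)) {
      regsig_error(sprintf("genome '%s' not supplied", gid), "regsig_provenance_error")
    }
    g <- genomes[[gid]]
    glen <- nchar(g$sequence)
    if (prov$strand[i] == "+") {
      ns <- prov$start[i] - left; ne <- prov$end[i] + right
    } else {
      ns <- prov$start[i] - right; ne <- prov$end[i] + left
    }
    if (ns < 0L || ne > glen) {
      bad <- c(bad, aln$ids[i]); keep[i] <- FALSE; next
    }
    s <- substr(g$sequence, ns + 1L, ne)
    if (prov$strand[i] == "-") s <- revcomp(s)
    seqs[i] <- s; keep[i] <- TRUE
    prov$start[i] <- ns; prov$end[i] <- ne
  }
  if (length(bad)) {
    msg <- sprintf("flank extension leaves replicon bounds for: %s", paste(bad, collapse = ", "))
    if (!drop_on_error) regsig_error(msg, "regsig_boundary_error")
    regsig_warn(paste0(msg, " (sequences dropped)"))
  }
  new_mask <- aln$mask + left
  site_alignment(aln$name, aln$ids[keep], seqs[keep],
                 provenance = prov[keep, , drop = FALSE], mask = new_mask)
}
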