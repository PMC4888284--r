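# Transcription-unit (regulon) inference: each annotated promoter or
# binding site anchors a putative transcription unit extending over
# successive co-oriented genes until a terminator, a large non-coding gap,
# an opposite-strand gene, or the replicon end.

#' Regulon inference configuration
#'
#' @param site_to_start_min,site_to_start_max Allowed distance window (nt)
#'   from a site's 3' edge to the first gene start of the unit (defaults
#'   0, 300, mirroring the hit-filter defaults).
#' @param max_gap Non-coding gene-end to next-gene-start distance (nt) at
#'   or above which a unit ends (default 200).
#' @param list_divergons Merge units extending in both directions from an
#'   orientation-free site into a single divergon unit (default `TRUE`).
#' @param regulator_filter Optional regulator name restricting
#'   [list_regulons()] to one regulator.
#' @return A list of class `regulon_config`.
#' @export
regulon_config <- function(site_to_start_min = 0L, site_to_start_max = 300L,
                           max_gap = 200L, list_divergons = TRUE,
                           regulator_filter = NULL) {
  if (site_to_start_min > site_to_start_max) {
    regsig_error("site_to_start_min must be <= site_to_start_max", "regsig_argument_error")
  }
  if (max_gap < 0L) regsig_error("max_gap must be >= 0", "regsig_argument_error")
  structure(list(site_to_start_min = as.integer(site_to_start_min),
                 site_to_start_max = as.integer(site_to_start_max),
                 max_gap = as.integer(max_gap),
                 list_divergons = isTRUE(list_divergons),
                 regulator_filter = regulator_filter),
            class = "regulon_config")
}

# Deduplicated gene-level intervals (gene/CDS collapsed) with locus tags.
regulon_genes <- function(record) {
  g <- gene_intervals(record)
  if (nrow(g) == 0L) return(g)
  g$locus_tag <- vapply(seq_len(nrow(g)), function(i) {
    lt <- g$qualifiers[[i]]$locus_tag
    if (is.null(lt)) sprintf("%s_%d_%d", g$kind[i], g$start[i], g$end[i]) else lt[1L]
  }, character(1L))
  g
}

same_strand_terminator_between <- function(record, lo, hi, strand) {
  f <- record$features
  t <- f[f$kind == "terminator" & f$strand == strand, , drop = FALSE]
  any(t$start >= lo & t$end <= hi)
}

#' Infer the transcription unit anchored at one regulatory site
#'
#' Finds the first gene on `direction` whose start lies downstream of the
#' site within `[site_to_start_min, site_to_start_max]`; absent such a gene
#' the site anchors no unit (`NULL`). The unit then extends over successive
#' same-strand genes until (a) a same-strand terminator feature between
#' consecutive genes (`end_reason = "terminator"`), (b) a non-coding gap of
#' at least `max_gap` or an intervening opposite-strand gene
#' (`end_reason = "gap"`), or (c) the replicon end
#' (`end_reason = "contig-end"`).
#'
#' @param record An annotated [genome_record()].
#' @param site One-row feature data frame (a `promoter`/`protein_bind`
#'   feature of `record`).
#' @param direction `"+"` or `"-"`: the strand the unit is transcribed on.
#' @param cfg A [regulon_config()].
#' @return A list of class `transcription_unit` (regulator, site, strand,
#'   genes data frame in transcription order, `end_reason`, `divergon`), or
#'   `NULL` when no first gene is in the window.
#' @export
infer_unit <- function(record, site, direction, cfg = regulon_config()) {
  genes <- regulon_genes(record)
  if (nrow(genes) == 0L) {
    regsig_error("record has no gene/CDS annotation", "regsig_annotation_error")
  }
  s_start <- site$start[1L]; s_end <- site$end[1L]
  if (direction == "+") {
    cand <- which(genes$strand == "+" & genes$start >= s_end)
    if (!length(cand)) return(NULL)
    d <- genes$start[cand] - s_end
    ok <- cand[d >= cfg$site_to_start_min & d <= cfg$site_to_start_max]
    if (!length(ok)) return(NULL)
    first <- ok[which.min(genes$start[ok])]
  } else {
    cand <- which(genes$strand == "-" & genes$end <= s_start)
    if (!length(cand)) return(NULL)
    d <- s_start - genes$end[cand]
    ok <- cand[d >= cfg$site_to_start_min & d <= cfg$site_to_start_max]
    if (!length(ok)) return(NULL)
    first <- ok[which.max(genes$end[ok])]
  }
  unit_idx <- first
  end_reason <- NULL
  cur <- first
  glen <- nchar(record$sequence)
  repeat {
    if (direction == "+") {
      nxt <- which(genes$start >= genes$end[cur])
      nxt <- if (length(nxt)) nxt[which.min(genes$start[nxt])] else NA_integer_
      gap_lo <- genes$end[cur]
      gap_hi <- if (is.na(nxt)) glen else genes$start[nxt]
    } else {
      nxt <- which(genes$end <= genes$start[cur])
      nxt <- if (length(nxt)) nxt[which.max(genes$end[nxt])] else NA_integer_
      gap_lo <- if (is.na(nxt)) 0L else genes$end[nxt]
      gap_hi <- genes$start[cur]
    }
    if (same_strand_terminator_between(record, gap_lo, gap_hi, direction)) {
      end_reason <- "terminator"; break
    }
    if (is.na(nxt)) { end_reason <- "contig-end"; break }
    if (genes$strand[nxt] != direction) { end_reason <- "gap"; break }
    if (gap_hi - gap_lo >= cfg$max_gap) { end_reason <- "gap"; break }
    unit_idx <- c(unit_idx, nxt)
    cur <- nxt
  }
  # Transcription order: ascending coordinates on "+", descending on "-".
  ord <- if (direction == "+") order(genes$start[unit_idx]) else order(-genes$start[unit_idx])
  structure(list(regulator = site_regulator(site), site = site,
                 strand = direction,
                 genes = genes[unit_idx[ord], , drop = FALSE],
                 end_reason = end_reason, divergon = FALSE),
            class = "transcription_unit")
}

site_regulator <- function(site) {
  q <- site$qualifiers[[1L]]
  if (!is.null(q$bound_moiety)) return(q$bound_moiety[1L])
  if (!is.null(q$note)) {
    note <- q$note[1L]
    if (grepl(" promoter", note)) return(sub(" promoter.*$", "", note))
    return(note)
  }
  "unknown"
}

# A site is orientation-free when it is a protein_bind feature (a bound
# regulator can activate either flank) or has no annotated strand;
# promoters are strand-specific.
site_directions <- function(site) {
  if (site$kind[1L] == "protein_bind" || site$strand[1L] == ".") c("+", "-")
  else site$strand[1L]
}

#' List putative transcription units for all regulators
#'
#' For every annotated `promoter`/`protein_bind` feature (optionally
#' restricted to one regulator) this attempts [infer_unit()] in both
#' directions for orientation-free sites (protein_bind or unstranded) and
#' only in the annotated direction for promoters. When both directions
#' yield units and `list_divergons` is set, the two are merged into a
#' single unit flagged `divergon = TRUE` and counted once.
#'
#' @param record An annotated [genome_record()].
#' @param cfg A [regulon_config()].
#' @return List with `units` (list of `transcription_unit`) and `counts`
#'   (named integer vector of unit counts per regulator; divergons count
#'   once).
#' @export
list_regulons <- function(record, cfg = regulon_config()) {
  f <- record$features
  sites <- which(f$kind %in% c("promoter", "protein_bind"))
  units <- list()
  for (i in sites) {
    site <- f[i, , drop = FALSE]
    reg <- site_regulator(site)
    if (!is.null(cfg$regulator_filter) && reg != cfg$regulator_filter) next
    dirs <- site_directions(site)
    got <- list()
    for (d in dirs) {
      u <- infer_unit(record, site, d, cfg)
      if (!is.null(u)) got[[length(got) + 1L]] <- u
    }
    if (length(got) == 2L && cfg$list_divergons) {
      merged <- got[[1L]]
      merged$divergon <- TRUE
      merged$strand <- "."
      merged$genes <- rbind(got[[2L]]$genes, got[[1L]]$genes)
      merged$end_reason <- paste(got[[2L]]$end_reason, got[[1L]]$end_reason, sep = "/")
      units[[length(units) + 1L]] <- merged
    } else {
      units <- c(units, got)
    }
  }
  regs <- vapply(units, function(u) u$regulator, character(1L))
  counts <- if (length(regs)) {
    tbl <- table(regs)
    stats::setNames(as.integer(tbl), names(tbl))
  } else {
    stats::setNames(integer(), character())
  }
  list(units = units, counts = counts)
}

#' Tabulate transcription units
#'
#' @param units List of `transcription_unit` objects from [list_regulons()].
#' @return Data frame with one row per unit: regulator, site location and
#'   strand, unit strand, gene locus tags (comma-separated, transcription
#'   order), gene count, end reason, divergon flag.
#' @export
regulon_table <- function(units) {
  if (!length(units)) {
    return(data.frame(regulator = character(), site_start = integer(),
                      site_end = integer(), site_strand = character(),
                      unit_strand = character(), genes = character(),
                      n_genes = integer(), end_reason = character(),
                      divergon = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(units, function(u) {
    data.frame(regulator = u$regulator,
               site_start = u$site$start[1L], site_end = u$site$end[1L],
               site_strand = u$site$strand[1L], unit_strand = u$strand,
               genes = paste(u$genes$locus_tag, collapse = ","),
               n_genes = nrow(u$genes), end_reason = u$end_reason,
               divergon = u$divergon, stringsAsFactors = FALSE)
  }))
}
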