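# Context-aware filtering of raw scan hits against the genome annotation:
# palindromic duplicate removal, orientation/converging-region/intragenic
# classification, and the filter report.

#' Filter configuration
#'
#' @param max_upstream Maximum allowed distance (nt) from a hit's 3' edge to
#'   the next same-strand gene start (default 300, typical bacterial
#'   promoter spacing).
#' @param min_upstream Minimum allowed distance (default 0).
#' @param drop_intragenic Drop hits inside genes (default `TRUE`).
#' @param palindromic Remove strand duplicates of palindromic motifs.
#' @param overlap_fraction Reciprocal-overlap fraction for duplicate pairing
#'   (default 0.5; engine-reported intervals on opposite strands may be
#'   offset by a base, so exact coordinate equality is not required).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_upstream = 300L, min_upstream = 0L,
                          drop_intragenic = TRUE, palindromic = FALSE,
                          overlap_fraction = 0.5) {
  if (min_upstream > max_upstream) {
    regsig_error("min_upstream must be <= max_upstream", "regsig_argument_error")
  }
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    regsig_error("overlap_fraction must be in (0, 1]", "regsig_argument_error")
  }
  structure(list(max_upstream = as.integer(max_upstream),
                 min_upstream = as.integer(min_upstream),
                 drop_intragenic = isTRUE(drop_intragenic),
                 palindromic = isTRUE(palindromic),
                 overlap_fraction = overlap_fraction),
            class = "filter_config")
}

#' Remove palindromic strand duplicates
#'
#' Because both strands are always scanned, a palindromic site is reported
#' twice. Hits on opposite strands whose intervals reciprocally overlap by
#' at least `overlap_fraction` form connected components; only the
#' highest-scoring hit of each component is kept, with exact score ties
#' resolved in favour of the plus strand (then the smaller start). With
#' `cfg$palindromic` unset this is the identity.
#'
#' @param hits Hit data frame.
#' @param cfg A [filter_config()].
#' @return Deduplicated hit data frame, sorted by start then strand.
#' @export
dedupe_palindromic <- function(hits, cfg) {
  if (!cfg$palindromic || nrow(hits) < 2L) return(hits)
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (hits$strand[i] == hits$strand[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov <= 0) next
      li <- hits$end[i] - hits$start[i]; lj <- hits$end[j] - hits$start[j]
      if (ov / li >= cfg$overlap_fraction && ov / lj >= cfg$overlap_fraction) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  keep <- logical(n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    ord <- order(-hits$score[members],
                 match(hits$strand[members], c("+", "-")),
                 hits$start[members])
    keep[members[ord[1L]]] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

gene_intervals <- function(record) {
  f <- record$features
  g <- f[f$kind %in% c("gene", "CDS"), , drop = FALSE]
  if (nrow(g) == 0L) return(g)
  key <- paste(g$start, g$end, g$strand)
  g <- g[!duplicated(key), , drop = FALSE]
  g <- g[order(g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  g
}

classify_one <- function(start, end, strand, genes, cfg) {
  if (any(genes$start < end & genes$end > start)) return("intragenic")
  left <- which(genes$end <= start)
  right <- which(genes$start >= end)
  if (length(left) && length(right)) {
    li <- left[which.max(genes$end[left])]
    ri <- right[which.min(genes$start[right])]
    if (genes$strand[li] == "+" && genes$strand[ri] == "-") return("converging-region")
  }
  if (strand == "+") {
    cand <- which(genes$strand == "+" & genes$start >= end)
    d <- if (length(cand)) min(genes$start[cand]) - end else NA_integer_
  } else {
    cand <- which(genes$strand == "-" & genes$end <= start)
    d <- if (length(cand)) start - max(genes$end[cand]) else NA_integer_
  }
  if (!is.na(d) && d >= cfg$min_upstream && d <= cfg$max_upstream) "upstream-ok" else "wrong-orientation"
}

#' Classify a hit by its genomic context
#'
#' Categories, in precedence order: `intragenic` (interval intersects a
#' gene/CDS), `converging-region` (the hit lies strictly between the 3'
#' ends of two adjacent opposite-strand genes facing the gap — downstream
#' of both, where no promoter or binding site belongs), `upstream-ok`
#' (the nearest same-strand gene start downstream of the hit, 5'->3' on the
#' hit's strand, lies within `[min_upstream, max_upstream]` of the hit's 3'
#' edge), otherwise `wrong-orientation`.
#'
#' @param hit One-row hit data frame (or list with `start`, `end`, `strand`).
#' @param record An annotated [genome_record()].
#' @param cfg A [filter_config()].
#' @return One of `"upstream-ok"`, `"wrong-orientation"`,
#'   `"converging-region"`, `"intragenic"`.
#' @export
classify_context <- function(hit, record, cfg = filter_config()) {
  genes <- gene_intervals(record)
  if (nrow(genes) == 0L) {
    regsig_error("record has no gene/CDS annotation", "regsig_annotation_error")
  }
  classify_one(hit$start[1L], hit$end[1L], hit$strand[1L], genes, cfg)
}

#' Filter hits by genomic context
#'
#' Applies [dedupe_palindromic()], then classifies every remaining hit with
#' [classify_context()]. Wrong-orientation and converging-region hits are
#' always dropped; intragenic hits only when `cfg$drop_intragenic`. The
#' report counts partition the input exactly (removed strand duplicates are
#' counted under `palindromic_duplicate`).
#'
#' @param hits Hit data frame.
#' @param record An annotated [genome_record()].
#' @param cfg A [filter_config()].
#' @return List with `kept` (hit data frame) and `report` (named integer
#'   vector of category counts summing to `nrow(hits)`).
#' @export
filter_hits <- function(hits, record, cfg = filter_config()) {
  report <- c(upstream_ok = 0L, intragenic = 0L, converging_region = 0L,
              wrong_orientation = 0L, palindromic_duplicate = 0L)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(kept = hits, report = report))
  }
  deduped <- dedupe_palindromic(hits, cfg)
  report["palindromic_duplicate"] <- nrow(hits) - nrow(deduped)
  genes <- gene_intervals(record)
  if (nrow(genes) == 0L) {
    regsig_error("record has no gene/CDS annotation", "regsig_annotation_error")
  }
  cats <- vapply(seq_len(nrow(deduped)), function(i) {
    classify_one(deduped$start[i], deduped$end[i], deduped$strand[i], genes, cfg)
  }, character(1L))
  report["upstream_ok"] <- sum(cats == "upstream-ok")
  report["intragenic"] <- sum(cats == "intragenic")
  report["converging_region"] <- sum(cats == "converging-region")
  report["wrong_orientation"] <- sum(cats == "wrong-orientation")
  keep <- cats == "upstream-ok" | (!cfg$drop_intragenic & cats == "intragenic")
  kept <- deduped[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

#' Format a filter report as text
#' @param report Named counts from [filter_hits()].
#' @return Character vector of report lines.
#' @export
format_filter_report <- function(report) {
  c("hit filter report:",
    sprintf("  %-22s %d", names(report), report),
    sprintf("  %-22s %d", "total", sum(report)))
}
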