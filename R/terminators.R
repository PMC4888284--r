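# Intrinsic (rho-independent) terminator detection: GC-rich stem-loop
# followed by a U-rich tail. The pair scores, tail weights and logistic
# confidence map are this package's documented scoring scheme, chosen so
# that canonical terminators (strong stem + U tail) clear the default
# confidence cutoff while hairpin-free sequence never does.

#' Terminator search parameters
#'
#' @param stem_min,stem_max Stem length bounds in base pairs (defaults 4, 20).
#' @param loop_min,loop_max Loop length bounds in nucleotides (defaults 3, 10).
#' @param tail_len Length of the scored U(T)-tail window (default 8).
#' @param allow_GU Count G-T wobble pairs in the stem (default `TRUE`).
#' @param max_mismatches Maximum interior stem mismatches (default 1).
#' @param min_confidence Confidence cutoff 0-100 for reported candidates
#'   (default 70).
#' @return A list of class `terminator_params`.
#' @export
terminator_params <- function(stem_min = 4L, stem_max = 20L,
                              loop_min = 3L, loop_max = 10L,
                              tail_len = 8L, allow_GU = TRUE,
                              max_mismatches = 1L, min_confidence = 70) {
  if (stem_min > stem_max) regsig_error("stem_min must be <= stem_max", "regsig_argument_error")
  if (loop_min > loop_max) regsig_error("loop_min must be <= loop_max", "regsig_argument_error")
  if (tail_len < 1L) regsig_error("tail_len must be >= 1", "regsig_argument_error")
  structure(list(stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
                 loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
                 tail_len = as.integer(tail_len), allow_GU = isTRUE(allow_GU),
                 max_mismatches = as.integer(max_mismatches),
                 min_confidence = min_confidence),
            class = "terminator_params")
}

MISMATCH_SCORE <- -3

# 5 x 5 stem pair-score matrix over (A,C,G,T,N): G:C +3, A:T +2, G:T wobble
# +1 (when enabled), anything else (incl. N) a -3 mismatch.
pair_score_matrix <- function(allow_GU) {
  m <- matrix(MISMATCH_SCORE, 5L, 5L)
  m[1L, 4L] <- m[4L, 1L] <- 2   # A:T
  m[2L, 3L] <- m[3L, 2L] <- 3   # C:G
  if (allow_GU) m[3L, 4L] <- m[4L, 3L] <- 1   # G:T wobble
  m
}

empty_candidates <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             stem_len = integer(), loop_len = integer(), mismatches = integer(),
             hairpin_score = numeric(), tail_score = numeric(),
             confidence = numeric(), stringsAsFactors = FALSE)
}

#' Enumerate hairpin candidates on the plus strand of a sequence
#'
#' Finds every decomposition left-arm / loop / right-arm where the arms are
#' reverse-complementary (Watson-Crick, plus G-T wobble when enabled) with
#' at most `max_mismatches` interior mismatches and stem/loop lengths within
#' bounds. The innermost and outermost stem positions must be true pairs.
#' `hairpin_score` sums the pair scores (G:C +3, A:T +2, wobble +1,
#' mismatch -3) minus `0.5 * loop_len`. Candidates sharing the same loop
#' (nested stems) collapse to the highest-scoring one. Tail and confidence
#' are left unscored (see [score_tail()]).
#'
#' @param seq DNA string.
#' @param params A [terminator_params()].
#' @return Data frame of candidates with `start`/`end` (0-based half-open
#'   span of stem1..stem2), `strand = "+"`, `stem_len`, `loop_len`,
#'   `mismatches`, `hairpin_score`; `tail_score`/`confidence` are `NA`.
#' @export
find_hairpins <- function(seq, params = terminator_params()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L * params$stem_min + params$loop_min) return(empty_candidates())
  idx <- encode_dna(seq)
  ps <- pair_score_matrix(params$allow_GU)
  out <- list()
  for (l in params$loop_min:params$loop_max) {
    # j = inner-left stem index (1-based); pair k (k = 0..s-1) is
    # (j - k, j + l + 1 + k).
    jmax <- n - l - 1L
    if (jmax < 1L) next
    j <- seq_len(jmax)
    score_acc <- numeric(jmax)
    mm_acc <- integer(jmax)
    best_score <- rep(-Inf, jmax)
    best_s <- integer(jmax)
    best_mm <- integer(jmax)
    inner_ok <- NULL
    for (k in 0:(params$stem_max - 1L)) {
      li <- j - k
      riix <- j + l + 1L + k
      valid <- li >= 1L & riix <= n
      pk <- rep(MISMATCH_SCORE, jmax)
      pk[valid] <- ps[cbind(idx[li[valid]], idx[riix[valid]])]
      if (k == 0L) inner_ok <- valid & pk > 0
      score_acc <- score_acc + pk
      mm_acc <- mm_acc + as.integer(pk == MISMATCH_SCORE)
      s <- k + 1L
      if (s < params$stem_min) next
      cand_ok <- valid & inner_ok & pk > 0 & mm_acc <= params$max_mismatches
      sc <- score_acc - 0.5 * l
      better <- cand_ok & sc > best_score
      best_score[better] <- sc[better]
      best_s[better] <- s
      best_mm[better] <- mm_acc[better]
    }
    found <- which(is.finite(best_score))
    if (length(found)) {
      out[[length(out) + 1L]] <- data.frame(
        start = found - best_s[found],               # 0-based: (j - s + 1) - 1
        end = found + l + best_s[found],
        strand = "+",
        stem_len = best_s[found], loop_len = l,
        mismatches = best_mm[found],
        hairpin_score = best_score[found],
        tail_score = NA_real_, confidence = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty_candidates())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$loop_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

logistic <- function(x) 1 / (1 + exp(-x))

# Decreasing tail weights 1.0, 0.9, ... floored at 0.1.
tail_weights <- function(tail_len) pmax(1 - 0.1 * (seq_len(tail_len) - 1L), 0.1)

#' Score the U-tail of a hairpin candidate and assign confidence
#'
#' `tail_score` is a position-weighted count of T's in the `tail_len` bases
#' immediately 3' of the stem (weights 1.0, 0.9, ... floored at 0.1;
#' truncated tails at the contig end are scored over the available bases).
#' Confidence is `100 * logistic(0.35 * (hairpin_score + 3 * tail_score - 18))`.
#'
#' @param seq The same DNA string the candidate came from.
#' @param cand One-row candidate data frame from [find_hairpins()].
#' @param params A [terminator_params()].
#' @return The candidate with `tail_score` and `confidence` filled in.
#' @export
score_tail <- function(seq, cand, params = terminator_params()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  w <- tail_weights(params$tail_len)
  pos <- cand$end[1L] + seq_len(params$tail_len)   # 1-based tail positions
  pos <- pos[pos <= n]
  ts <- if (length(pos)) {
    bases <- strsplit(substr(seq, pos[1L], pos[length(pos)]), "")[[1L]]
    sum(w[seq_along(pos)] * (bases == "T"))
  } else 0
  cand$tail_score <- ts
  cand$confidence <- 100 * logistic(0.35 * (cand$hairpin_score + 3 * ts - 18))
  cand
}

score_tails_vec <- function(seq, cands, params) {
  if (nrow(cands) == 0L) return(cands)
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  w <- tail_weights(params$tail_len)
  ts <- numeric(nrow(cands))
  for (i in seq_len(params$tail_len)) {
    pos <- cands$end + i
    ok <- pos <= n
    ts[ok] <- ts[ok] + w[i] * (chars[pos[ok]] == "T")
  }
  cands$tail_score <- ts
  cands$confidence <- 100 * logistic(0.35 * (cands$hairpin_score + 3 * ts - 18))
  cands
}

# Greedy same-strand collapse: a candidate is suppressed when it overlaps a
# kept candidate with strictly higher (confidence, hairpin score); exact
# ties are all kept, which makes the result invariant under strand
# reflection of the input sequence.
collapse_overlapping <- function(cands) {
  if (nrow(cands) < 2L) return(cands)
  ord <- order(-cands$confidence, -cands$hairpin_score, cands$start)
  cands <- cands[ord, , drop = FALSE]
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    sel <- which(keep & cands$strand == cands$strand[i])
    ov <- sel[cands$start[sel] < cands$end[i] & cands$end[sel] > cands$start[i]]
    beaten <- any(cands$confidence[ov] > cands$confidence[i] |
                  (cands$confidence[ov] == cands$confidence[i] &
                   cands$hairpin_score[ov] > cands$hairpin_score[i]))
    keep[i] <- !beaten
  }
  cands[keep, , drop = FALSE]
}

#' Find intrinsic terminators in a genome record
#'
#' Runs hairpin enumeration and tail scoring on both strands (the minus
#' strand via the reverse complement, with coordinates reflected back to
#' the top strand), keeps candidates with confidence at or above
#' `min_confidence`, and collapses overlapping same-strand candidates to
#' the highest-confidence one.
#'
#' @param record A [genome_record()] (annotation not consulted: the
#'   detector is annotation-agnostic; relevance is decided downstream).
#' @param params A [terminator_params()].
#' @return Data frame of terminator candidates sorted by start, with
#'   top-strand coordinates and a `strand` column.
#' @export
find_terminators <- function(record, params = terminator_params()) {
  stopifnot(inherits(record, "genome_record"))
  n <- nchar(record$sequence)
  fwd <- find_hairpins(record$sequence, params)
  fwd <- score_tails_vec(record$sequence, fwd, params)
  rc <- revcomp(record$sequence)
  rev_ <- find_hairpins(rc, params)
  rev_ <- score_tails_vec(rc, rev_, params)
  if (nrow(rev_)) {
    new_start <- n - rev_$end
    rev_$end <- n - rev_$start
    rev_$start <- new_start
    rev_$strand <- "-"
  }
  all <- rbind(fwd, rev_)
  all <- all[!is.na(all$confidence) & all$confidence >= params$min_confidence, , drop = FALSE]
  all <- collapse_overlapping(all)
  all <- all[order(all$start, all$end), , drop = FALSE]
  rownames(all) <- NULL
  if (nrow(all)) all <- cbind(genome_id = record$id, all)
  else all <- cbind(genome_id = character(), all)
  all
}

#' Canonical terminator building blocks
#'
#' Returns the sequence pieces of a canonical intrinsic terminator used by
#' the synthetic-genome simulator: an 8-bp perfect GC-rich stem, a 4-nt
#' GAAA loop, and an 8-nt T tail, preceded by a two-base CC guard. The
#' guard bases cannot pair with the T tail, so no stem extension across the
#' planted boundary survives the mismatch limit and the detected hairpin is
#' exactly the planted one.
#'
#' @return List with `guard`, `stem1`, `loop`, `stem2`, `tail`, and the
#'   concatenated `full` sequence (guard + hairpin + tail).
#' @export
canonical_terminator <- function() {
  stem1 <- "GGCAGCCG"
  loop <- "GAAA"
  stem2 <- revcomp(stem1)
  tail <- "TTTTTTTT"
  guard <- "CC"
  list(guard = guard, stem1 = stem1, loop = loop, stem2 = stem2, tail = tail,
       full = paste0(guard, stem1, loop, stem2, tail))
}

#' Write terminator candidates as BED6
#' @param candidates Data frame from [find_terminators()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_terminators_bed <- function(candidates, path) {
  chrom <- if ("genome_id" %in% names(candidates)) candidates$genome_id else "terminators"
  bed <- data.frame(chrom, candidates$start, candidates$end,
                    sprintf("stem%d_loop%d", candidates$stem_len, candidates$loop_len),
                    as.integer(round(candidates$confidence)), candidates$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
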