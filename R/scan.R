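# Genome scanning with log-odds PWM scores and exact p-values from the
# discretized score distribution under the background model.

# 5 x L log-odds matrix in bits: rows A,C,G,T plus an N row holding the
# background-weighted mean of the four per-column log-odds. Masked columns
# contribute 0 for every base.
log_odds_matrix <- function(profile) {
  p <- profile$matrix
  q <- profile$background
  lo <- log2(sweep(p, 1L, q, `/`))   # -Inf where p == 0 (pseudocount 0)
  nrow_vals <- colSums(lo * q)
  lo <- rbind(lo, N = nrow_vals)
  if (length(profile$masked_columns)) lo[, profile$masked_columns + 1L] <- 0
  lo
}

#' Score a single window against a profile
#'
#' Log-odds score in bits: `sum_j log2(p(b_j, j) / q(b_j))` over unmasked
#' columns. An `N` contributes the background-weighted mean of the column's
#' log-odds; masked columns contribute 0. A zero-probability base (possible
#' at pseudocount 0) yields `-Inf`.
#'
#' @param profile A [motif_profile()].
#' @param window DNA string of length `profile_width(profile)`.
#' @return Score in bits.
#' @export
score_window <- function(profile, window) {
  L <- profile_width(profile)
  if (nchar(window) != L) {
    regsig_error(sprintf("window length %d != profile width %d", nchar(window), L),
                 "regsig_argument_error")
  }
  check_dna(window, "window")
  lo <- log_odds_matrix(profile)
  idx <- encode_dna(window)
  sum(lo[cbind(idx, seq_len(L))])
}

# Exact distribution of the window score under the background model, with
# per-column scores rounded to multiples of `granularity` bits. Returns the
# support (bits), the probability mass function, and the mass absorbed by
# -Inf scores (words hitting a zero-probability base).
score_distribution <- function(profile, granularity = 0.001) {
  if (granularity <= 0) {
    regsig_error("granularity must be > 0", "regsig_argument_error")
  }
  lo <- log_odds_matrix(profile)[1:4, , drop = FALSE]
  q <- profile$background
  pmf <- 1
  offset <- 0L       # value of pmf[i] is (offset + i - 1) * granularity
  dead <- 0
  for (j in seq_len(ncol(lo))) {
    v <- lo[, j]
    fin <- is.finite(v)
    if (any(!fin)) {
      dead <- dead + sum(pmf) * sum(q[!fin])
      if (!any(fin)) { pmf <- numeric(0); break }
    }
    vb <- as.integer(round(v[fin] / granularity))
    qb <- q[fin]
    lo_new <- offset + min(vb)
    hi_new <- offset + length(pmf) - 1L + max(vb)
    new <- numeric(hi_new - lo_new + 1L)
    for (k in seq_along(vb)) {
      at <- offset + vb[k] - lo_new + 1L
      span <- at:(at + length(pmf) - 1L)
      new[span] <- new[span] + pmf * qb[k]
    }
    pmf <- new
    offset <- lo_new
  }
  list(values = (offset + seq_along(pmf) - 1L) * granularity,
       pmf = pmf, dead = dead, granularity = granularity)
}

dist_tail <- function(dist, threshold) {
  if (threshold == -Inf) return(1)
  p <- sum(dist$pmf[dist$values >= threshold - 1e-12])
  min(max(p, 0), 1)
}

#' Exact p-value of a score threshold
#'
#' Probability that a random L-mer drawn from the profile's background
#' attains score >= `threshold`, computed by column-wise convolution of the
#' discretized per-column score distributions (deterministic; discretization
#' error bounded by `L * granularity / 2` on the score axis).
#'
#' @param profile A [motif_profile()].
#' @param threshold Score threshold in bits (`-Inf` gives 1).
#' @param granularity Discretization step in bits (default 0.001).
#' @return p-value in `[0, 1]`.
#' @export
score_pvalue <- function(profile, threshold, granularity = 0.001) {
  dist_tail(score_distribution(profile, granularity), threshold)
}

# All window scores on the plus strand of an integer-encoded sequence.
window_scores <- function(lo, idx, L) {
  n <- length(idx)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  scores <- numeric(nw)
  for (j in seq_len(L)) {
    scores <- scores + lo[cbind(idx[j:(j + nw - 1L)], j)]
  }
  scores
}

#' Scan a genome record with a profile
#'
#' Slides the profile over every position of the top strand and of the
#' reverse complement; minus-strand hits are reported in top-strand
#' coordinates (`start < end` always). In `score-cutoff` mode the cutoff
#' defaults to the profile's gathering cutoff; in `pvalue-cutoff` mode hits
#' with exact p-value <= cutoff are emitted. Ties at the cutoff are kept.
#' The origin of circular replicons is not wrapped.
#'
#' @param profile A [motif_profile()].
#' @param record A [genome_record()].
#' @param mode `"score-cutoff"` (bits) or `"pvalue-cutoff"`.
#' @param cutoff Numeric cutoff; in score mode defaults to the gathering
#'   cutoff and errors if neither is available.
#' @param granularity p-value discretization step in bits.
#' @return Data frame of hits with columns `genome_id`, `start`, `end`
#'   (0-based half-open), `strand`, `score`, `pvalue`, `profile`, sorted by
#'   start then strand (`+` before `-`).
#' @export
scan_genome <- function(profile, record, mode = c("score-cutoff", "pvalue-cutoff"),
                        cutoff = NULL, granularity = 0.001) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "genome_record"))
  L <- profile_width(profile)
  empty <- data.frame(genome_id = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(), pvalue = numeric(),
                      profile = character(), stringsAsFactors = FALSE)
  n <- nchar(record$sequence)
  if (n < L) {
    regsig_warn(sprintf("sequence %s shorter than profile width %d", record$id, L))
    return(empty)
  }
  dist <- score_distribution(profile, granularity)
  if (mode == "score-cutoff") {
    if (is.null(cutoff)) cutoff <- profile$cutoffs$gathering
    if (is.null(cutoff)) {
      regsig_error("no score cutoff supplied and profile has no gathering cutoff",
                   "regsig_config_error")
    }
    score_cut <- cutoff
  } else {
    if (is.null(cutoff)) {
      regsig_error("pvalue-cutoff mode requires a cutoff", "regsig_config_error")
    }
    # Smallest discretized score whose tail probability is within the cutoff.
    tails <- rev(cumsum(rev(dist$pmf)))
    ok <- which(tails <= cutoff)
    score_cut <- if (length(ok)) dist$values[min(ok)] - dist$granularity / 2 else Inf
  }
  lo <- log_odds_matrix(profile)
  idx_f <- encode_dna(record$sequence)
  idx_r <- c(4L, 3L, 2L, 1L, 5L)[rev(idx_f)]   # reverse complement encoding
  sc_f <- window_scores(lo, idx_f, L)
  sc_r <- window_scores(lo, idx_r, L)
  hit_f <- which(is.finite(sc_f) & sc_f >= score_cut)
  hit_r <- which(is.finite(sc_r) & sc_r >= score_cut)
  hits <- rbind(
    data.frame(start = hit_f - 1L, strand = rep("+", length(hit_f)),
               score = sc_f[hit_f], stringsAsFactors = FALSE),
    data.frame(start = n - (hit_r - 1L) - L, strand = rep("-", length(hit_r)),
               score = sc_r[hit_r], stringsAsFactors = FALSE)
  )
  if (nrow(hits) == 0L) return(empty)
  pv <- vapply(hits$score, function(s) {
    dist_tail(dist, round(s / granularity) * granularity - granularity / 2)
  }, numeric(1L))
  out <- data.frame(genome_id = record$id, start = as.integer(hits$start),
                    end = as.integer(hits$start + L), strand = hits$strand,
                    score = hits$score, pvalue = pv, profile = profile$name,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the genomic sequence of a hit (on its own strand)
#'
#' @param record A [genome_record()].
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return DNA string as read 5'->3' on `strand`.
#' @export
hit_sequence <- function(record, start, end, strand) {
  s <- substr(record$sequence, start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}

#' Write hits as BED6
#'
#' Columns: chrom, start, end, name (profile), score (bits x 100, rounded),
#' strand.
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$genome_id, hits$start, hits$end, hits$profile,
                    as.integer(round(hits$score * 100)), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write hits as a tab-separated table (with p-values)
#' @param hits Hit data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hit table written by [write_hits_tsv()]
#' @param path Input path.
#' @return Hit data frame.
#' @export
read_hits_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(genome_id = "character", strand = "character",
                                   profile = "character"))
}
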