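# Iterative cross-genome profile optimisation: scan target genomes with the
# current profile, retain seed and high-scoring sites, rebuild, probe the
# boundaries for additional conserved columns, rescan until the site set
# and width stabilise, then calibrate the final profile.

#' Optimisation configuration
#'
#' @param max_iterations Maximum optimisation rounds (default 5).
#' @param retain_score Score (bits) a hit must reach to be retained, or
#'   `"noise-cutoff"` to use the profile's noise cutoff.
#' @param extension_probe Bases probed on each side per round (default 5).
#' @param column_keep_ic Per-column information content (bits) a probed
#'   flank column must reach to be kept (default 0.3).
#' @param target_regions Optional data frame (`genome`, `start`, `end`)
#'   restricting *additional* (non-seed) sites to listed intervals — the
#'   operational stand-in for curator judgment about which downstream genes
#'   belong to the same physiological process.
#' @param seed Integer seed for any stochastic tie-breaking (default 1).
#' @return A list of class `optimize_config`.
#' @export
optimize_config <- function(max_iterations = 5L, retain_score = "noise-cutoff",
                            extension_probe = 5L, column_keep_ic = 0.3,
                            target_regions = NULL, seed = 1L) {
  if (extension_probe < 0L) regsig_error("extension_probe must be >= 0", "regsig_argument_error")
  if (column_keep_ic < 0 || column_keep_ic > 2) {
    regsig_error("column_keep_ic must be in [0, 2]", "regsig_argument_error")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 retain_score = retain_score,
                 extension_probe = as.integer(extension_probe),
                 column_keep_ic = column_keep_ic,
                 target_regions = target_regions, seed = as.integer(seed)),
            class = "optimize_config")
}

resolve_retain_score <- function(profile, cfg) {
  if (identical(cfg$retain_score, "noise-cutoff")) {
    if (is.null(profile$cutoffs$noise)) {
      regsig_error("retain_score 'noise-cutoff' requires a calibrated (at least provisional) profile",
                   "regsig_config_error")
    }
    profile$cutoffs$noise
  } else {
    as.numeric(cfg$retain_score)
  }
}

in_target_regions <- function(genome, start, end, regions) {
  if (is.null(regions)) return(TRUE)
  any(regions$genome == genome & regions$start < end & regions$end > start)
}

#' Collect candidate sites for a profile across genomes
#'
#' Scans every genome at the retain score. Hits overlapping a seed site's
#' provenance interval count as orthologous and are always retained (they
#' bypass context filtering and the target-region restriction); additional
#' hits must pass the context filter (when `filter_cfg` is supplied) and,
#' when `cfg$target_regions` is given, fall inside a listed region.
#'
#' @param profile A [motif_profile()].
#' @param genomes List of [genome_record()]s.
#' @param cfg An [optimize_config()].
#' @param filter_cfg A [filter_config()], or `NULL` to skip context
#'   filtering (e.g. for unannotated target genomes).
#' @param seed_aln Optional seed [site_alignment()] whose provenance marks
#'   orthologous intervals.
#' @return A [site_alignment()] of the retained site sequences with full
#'   provenance, ordered by (genome, start, strand).
#' @export
collect_candidate_sites <- function(profile, genomes, cfg, filter_cfg = NULL,
                                    seed_aln = NULL) {
  if (length(genomes) == 0L) {
    regsig_error("at least one genome is required", "regsig_argument_error")
  }
  retain <- resolve_retain_score(profile, cfg)
  rows <- list()
  for (g in genomes) {
    hits <- scan_genome(profile, g, mode = "score-cutoff", cutoff = retain)
    if (nrow(hits) == 0L) next
    is_seed <- rep(FALSE, nrow(hits))
    if (!is.null(seed_aln)) {
      sp <- seed_aln$provenance
      sp <- sp[!is.na(sp$genome) & sp$genome == g$id, , drop = FALSE]
      if (nrow(sp)) {
        is_seed <- vapply(seq_len(nrow(hits)), function(i) {
          any(sp$start < hits$end[i] & sp$end > hits$start[i])
        }, logical(1L))
      }
    }
    extra <- hits[!is_seed, , drop = FALSE]
    if (nrow(extra) && !is.null(filter_cfg)) {
      extra <- filter_hits(extra, g, filter_cfg)$kept
    }
    if (nrow(extra) && !is.null(cfg$target_regions)) {
      keep <- vapply(seq_len(nrow(extra)), function(i) {
        in_target_regions(extra$genome_id[i], extra$start[i], extra$end[i],
                          cfg$target_regions)
      }, logical(1L))
      extra <- extra[keep, , drop = FALSE]
    }
    kept <- rbind(hits[is_seed, , drop = FALSE], extra)
    rows[[length(rows) + 1L]] <- kept
  }
  if (!length(rows)) {
    regsig_error("no sites retained in any genome", "regsig_collapse_error")
  }
  all <- do.call(rbind, rows)
  all <- all[!duplicated(paste(all$genome_id, all$start, all$end, all$strand)), , drop = FALSE]
  all <- all[order(all$genome_id, all$start, all$strand), , drop = FALSE]
  gmap <- stats::setNames(genomes, vapply(genomes, function(g) g$id, character(1L)))
  seqs <- vapply(seq_len(nrow(all)), function(i) {
    hit_sequence(gmap[[all$genome_id[i]]], all$start[i], all$end[i], all$strand[i])
  }, character(1L))
  site_alignment(
    profile$name,
    ids = sprintf("%s_%d_%s", all$genome_id, all$start, all$strand),
    seqs = seqs,
    provenance = data.frame(genome = all$genome_id, start = all$start,
                            end = all$end, strand = all$strand,
                            stringsAsFactors = FALSE)
  )
}

#' Refine alignment boundaries by flank information content
#'
#' Extends every sequence by `extension_probe` bases on each side, computes
#' the per-column information content of the extended alignment (pseudocount
#' 0, so a fully conserved probed column reads 2 bits), keeps the maximal
#' contiguous flank adjacent to the old boundary whose every column reaches
#' `column_keep_ic`, and symmetrically trims old edge columns below the
#' threshold. Deterministic.
#'
#' @param aln A [site_alignment()] with full provenance.
#' @param genomes Named list (or list) of [genome_record()]s.
#' @param cfg An [optimize_config()].
#' @return A re-sliced `site_alignment`.
#' @export
refine_boundaries <- function(aln, genomes, cfg) {
  if (!is.null(names(genomes)) && all(nzchar(names(genomes)))) gmap <- genomes
  else gmap <- stats::setNames(genomes, vapply(genomes, function(g) g$id, character(1L)))
  probe <- cfg$extension_probe
  if (probe == 0L) return(aln)
  L0 <- alignment_width(aln)
  ext <- extend_alignment(aln, gmap, left = probe, right = probe, drop_on_error = TRUE)
  ic <- information_content(build_profile(ext, pseudocount = 0))$per_column
  Lx <- length(ic)
  keep_left <- 0L
  for (k in seq_len(probe)) {               # walk outward from the old left edge
    if (ic[probe - k + 1L] >= cfg$column_keep_ic) keep_left <- k else break
  }
  keep_right <- 0L
  for (k in seq_len(probe)) {
    if (ic[probe + L0 + k] >= cfg$column_keep_ic) keep_right <- k else break
  }
  a <- probe - keep_left                     # 0-based start column
  b <- probe + L0 + keep_right               # 0-based end column (exclusive)
  if (keep_left == 0L) {
    while (a < b - 1L && ic[a + 1L] < cfg$column_keep_ic) a <- a + 1L
  }
  if (keep_right == 0L) {
    while (b > a + 1L && ic[b] < cfg$column_keep_ic) b <- b - 1L
  }
  if (b <= a) regsig_error("boundary refinement removed every column", "regsig_collapse_error")
  slice_alignment(ext, list(c(a, b)))
}

#' Iteratively optimise a profile against target genomes
#'
#' Repeats collect -> rebuild -> boundary refinement until the (site set,
#' width) pair is unchanged between rounds or `max_iterations` is reached,
#' then calibrates the final profile with the final site scores as training
#' scores and the best-scoring rejected hits as decoys. The final alignment
#' (attached as `attr(, "alignment")`) carries only target-genome
#' provenance.
#'
#' @param seed_aln Seed [site_alignment()].
#' @param genomes List of [genome_record()]s (the target genomes).
#' @param cfg An [optimize_config()] with a numeric `retain_score` (or a
#'   seed profile calibrated well enough for `"noise-cutoff"`).
#' @param filter_cfg Optional [filter_config()] passed to site collection.
#' @param pseudocount Pseudocount for profile building (default 0.5).
#' @return A calibrated [motif_profile()] with attributes `alignment`
#'   (final `site_alignment`), `converged` (logical) and `rounds`.
#' @export
optimize_profile <- function(seed_aln, genomes, cfg, filter_cfg = NULL,
                             pseudocount = 0.5) {
  if (length(genomes) == 0L) {
    regsig_error("at least one genome is required", "regsig_argument_error")
  }
  aln <- seed_aln
  prev_key <- NULL
  converged <- FALSE
  rounds <- 0L
  with_seed(cfg$seed, {
    for (round in seq_len(cfg$max_iterations)) {
      rounds <- round
      prof <- build_profile(aln, pseudocount = pseudocount)
      prof$name <- seed_aln$name
      sites <- tryCatch(
        collect_candidate_sites(prof, genomes, cfg, filter_cfg, seed_aln = seed_aln),
        regsig_collapse_error = function(e) {
          regsig_error(sprintf("optimisation collapsed in round %d: %s",
                               round, conditionMessage(e)),
                       "regsig_collapse_error")
        }
      )
      aln2 <- refine_boundaries(sites, genomes, cfg)
      key <- list(sites = paste(aln2$provenance$genome, aln2$provenance$start,
                                aln2$provenance$end, aln2$provenance$strand),
                  width = alignment_width(aln2))
      message(sprintf("optimise round %d: %d sites, width %d",
                      round, alignment_size(aln2), alignment_width(aln2)))
      aln <- aln2
      if (identical(key, prev_key)) { converged <- TRUE; break }
      prev_key <- key
    }
  })
  final <- build_profile(aln, pseudocount = pseudocount)
  final$name <- seed_aln$name
  training <- vapply(aln$seqs, function(s) score_window(final, s), numeric(1L),
                     USE.NAMES = FALSE)
  decoys <- collect_decoy_scores(final, genomes, aln)
  final <- suppressWarnings(calibrate(final, training, decoys))
  attr(final, "alignment") <- aln
  attr(final, "converged") <- converged
  attr(final, "rounds") <- rounds
  final
}

# Best scores of hits that are NOT part of the final site set: scanned at a
# low floor (0 bits) so genuine background maxima are visible.
collect_decoy_scores <- function(profile, genomes, aln) {
  decoys <- numeric()
  for (g in genomes) {
    hits <- scan_genome(profile, g, mode = "score-cutoff", cutoff = 0)
    if (!nrow(hits)) next
    prov <- aln$provenance[aln$provenance$genome == g$id, , drop = FALSE]
    is_site <- vapply(seq_len(nrow(hits)), function(i) {
      any(prov$start < hits$end[i] & prov$end > hits$start[i])
    }, logical(1L))
    decoys <- c(decoys, hits$score[!is_site])
  }
  if (length(decoys)) utils::head(sort(decoys, decreasing = TRUE), 25L) else NULL
}
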