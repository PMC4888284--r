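# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (enumeration / brute force) and never call
# the code paths they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random profile from a random alignment of `n` sites of width `L`.
random_profile <- function(L, n = 8L, pseudocount = 0.5) {
  seqs <- vapply(seq_len(n), function(i) random_dna(L), character(1L))
  build_profile(site_alignment("rnd", sprintf("s%d", seq_len(n)), seqs),
                pseudocount = pseudocount)
}

# Enumerate the scores of all 4^L words of a profile under its own scoring
# definition (recomputed here from the probability matrix, independently of
# the package's log-odds code path).
enumerate_scores <- function(profile) {
  p <- profile$matrix
  q <- profile$background
  L <- ncol(p)
  masked <- profile$masked_columns
  scores <- 0
  for (j in seq_len(L)) {
    col <- if ((j - 1L) %in% masked) rep(0, 4) else log2(p[, j] / q)
    scores <- as.vector(outer(scores, col, `+`))
  }
  scores
}

# Exhaustive-enumeration p-value: fraction of words at or above a threshold.
enum_pvalue <- function(profile, threshold) {
  sc <- enumerate_scores(profile)
  mean(sc >= threshold)
}

# Brute-force hairpin enumeration: every (start, stem, loop) decomposition,
# scored by first principles, grouped by loop interval keeping the best
# (smallest stem on ties) — the oracle for find_hairpins.
brute_hairpins <- function(seq, params = terminator_params()) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  pair_sc <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
    if (params$allow_GU && ((a == "G" && b == "T") || (a == "T" && b == "G"))) return(1)
    -3
  }
  found <- list()
  for (start in 0:(n - 1L)) {
    for (s in params$stem_min:params$stem_max) {
      for (l in params$loop_min:params$loop_max) {
        end <- start + 2L * s + l
        if (end > n) next
        sc <- vapply(seq_len(s), function(k) {
          pair_sc(chars[start + k], chars[end - k + 1L])
        }, numeric(1L))
        mm <- sum(sc == -3)
        if (mm > params$max_mismatches) next
        if (sc[1L] == -3 || sc[s] == -3) next    # outer/inner must pair
        key <- sprintf("%d_%d", start + s, l)    # loop interval
        score <- sum(sc) - 0.5 * l
        rec <- list(start = start, end = end, stem = s, loop = l,
                    mm = mm, score = score)
        old <- found[[key]]
        # highest score wins; the shorter (more compact) stem wins ties
        if (is.null(old) || score > old$score ||
            (score == old$score && s < old$stem)) found[[key]] <- rec
      }
    }
  }
  if (!length(found)) {
    return(data.frame(start = integer(), end = integer(), stem_len = integer(),
                      loop_len = integer(), mismatches = integer(),
                      hairpin_score = numeric()))
  }
  df <- do.call(rbind, lapply(found, function(r) {
    data.frame(start = r$start, end = r$end, stem_len = r$stem, loop_len = r$loop,
               mismatches = r$mm, hairpin_score = r$score)
  }))
  df <- df[order(df$start, df$end, df$loop_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Hand-built toy annotation exercising every hit-filter category:
# a converging +/- gene pair with hits upstream, downstream, inside and
# between the genes.
toy_filter_fixture <- function() {
  feats <- rbind(
    regsig:::make_feature("gene", 100L, 400L, "+", list(locus_tag = "TOY_0001")),
    regsig:::make_feature("CDS", 100L, 400L, "+", list(locus_tag = "TOY_0001")),
    regsig:::make_feature("gene", 600L, 900L, "-", list(locus_tag = "TOY_0002")),
    regsig:::make_feature("CDS", 600L, 900L, "-", list(locus_tag = "TOY_0002"))
  )
  record <- genome_record("toy", strrep("A", 2000L), feats)
  hits <- data.frame(
    genome_id = "toy",
    start = c(50L, 450L, 950L, 950L, 200L),
    end = c(70L, 470L, 970L, 970L, 220L),
    strand = c("+", "+", "-", "+", "+"),
    score = c(12, 11, 10, 9, 8),
    pvalue = rep(1e-4, 5), profile = "toy",
    stringsAsFactors = FALSE
  )
  expected <- c("upstream-ok", "converging-region", "upstream-ok",
                "wrong-orientation", "intragenic")
  list(record = record, hits = hits, expected = expected)
}

# Four synthetic target genomes with the same 22-bp motif planted 12 times
# each (alternating strands), plus the seed alignment trimmed one column on
# each side: the profile-optimisation fixture.
ortholog_fixture <- function(seed = 42L, n_genomes = 4L, n_sites = 12L,
                             glen = 20000L,
                             full_motif = "TACGGTCAGTTCAATGCGTCCA") {
  set.seed(seed)
  W <- nchar(full_motif)
  pg <- lapply(seq_len(n_genomes), function(g) {
    chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    pos <- sort(sample(seq(100L, glen - 200L, by = 600L), n_sites))
    strands <- rep(c("+", "-"), length.out = n_sites)
    for (i in seq_along(pos)) {
      s <- if (strands[i] == "+") full_motif else revcomp(full_motif)
      chars[(pos[i] + 1L):(pos[i] + W)] <- strsplit(s, "")[[1L]]
    }
    list(rec = genome_record(sprintf("tg%d", g), paste(chars, collapse = "")),
         pos = pos, strands = strands)
  })
  genomes <- lapply(pg, `[[`, "rec")
  p1 <- pg[[1L]]$pos; s1 <- pg[[1L]]$strands
  seed_aln <- site_alignment(
    "opt", sprintf("s%d", seq_along(p1)),
    vapply(seq_along(p1), function(i) {
      hit_sequence(genomes[[1L]], p1[i] + 1L, p1[i] + W - 1L, s1[i])
    }, character(1L)),
    provenance = data.frame(genome = "tg1", start = p1 + 1L, end = p1 + W - 1L,
                            strand = s1, stringsAsFactors = FALSE)
  )
  truth <- do.call(rbind, lapply(seq_along(pg), function(g) {
    data.frame(genome = sprintf("tg%d", g), start = pg[[g]]$pos,
               end = pg[[g]]$pos + W, strand = pg[[g]]$strands,
               stringsAsFactors = FALSE)
  }))
  list(genomes = genomes, seed_aln = seed_aln, truth = truth, width = W)
}

# The full planted-truth analysis: profile from the planted sites,
# calibration against genome background, scan at the gathering cutoff,
# context filter, annotation, regulon inference.
planted_pipeline <- function(sim) {
  rec <- sim$record; truth <- sim$truth
  reg_sites <- truth$sites[truth$sites$kind == "regulatory", , drop = FALSE]
  aln <- site_alignment(
    "planted_motif", sprintf("s%d", seq_len(nrow(reg_sites))),
    vapply(seq_len(nrow(reg_sites)), function(i) {
      hit_sequence(rec, reg_sites$start[i], reg_sites$end[i], reg_sites$strand[i])
    }, character(1L)),
    provenance = data.frame(genome = rec$id, start = reg_sites$start,
                            end = reg_sites$end, strand = reg_sites$strand,
                            stringsAsFactors = FALSE)
  )
  prof <- build_profile(aln)
  training <- vapply(aln$seqs, function(s) score_window(prof, s), numeric(1L))
  low <- scan_genome(prof, rec, cutoff = 0)
  planted <- truth$sites
  is_pl <- vapply(seq_len(nrow(low)), function(i) {
    any(planted$start < low$end[i] & planted$end > low$start[i])
  }, logical(1L))
  prof <- suppressWarnings(calibrate(prof, training, low$score[!is_pl]))
  hits <- scan_genome(prof, rec)
  res <- filter_hits(hits, rec, filter_config())
  rec2 <- annotate_sites(rec, res$kept, "planted_motif")
  reg <- list_regulons(rec2, regulon_config())
  list(profile = prof, hits = hits, filtered = res, record = rec2,
       regulons = reg, site_alignment = aln, reg_sites = reg_sites)
}
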