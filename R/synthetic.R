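# Synthetic annotated genomes with planted operons, regulatory sites and
# intrinsic terminators, plus matching ground truth, so every other module
# is testable without downloads.
#
# Layout: operons are placed left to right with alternating strands
# (+,-,+,...). Adjacent +/- operon pairs then produce the two intergenic
# geometries the filters care about: a converging gap (3' ends facing,
# hosting both terminators and converging decoys) and a divergent gap
# (5' ends facing, hosting both regulatory sites).

#' Simulation configuration
#'
#' Defaults describe a 50 kb genome with 10 operons regulated by one 20-bp
#' motif — small enough for fast tests, large enough that intergenic
#' geometry, calibration and regulon inference are all exercised.
#'
#' @param length Genome length (nt).
#' @param gc_content Background GC fraction.
#' @param n_operons Number of planted operons.
#' @param genes_per_operon `c(min, max)` genes per operon.
#' @param gene_len `c(min, max)` gene length (nt).
#' @param intra_operon_gap `c(min, max)` gap between operon genes (nt; keep
#'   below the regulon `max_gap`).
#' @param inter_operon_gap `c(min, max)` gap between operons (nt; keep
#'   above the regulon `max_gap`).
#' @param motif Planted motif: a consensus DNA string (instances planted
#'   verbatim) or a [motif_profile()] (instances sampled per column).
#' @param sites_per_motif Number of operons receiving an upstream site
#'   (default: all).
#' @param site_upstream_offset `c(min, max)` distance (nt) from the site's
#'   3' edge to the first gene start.
#' @param terminator_fraction Fraction of operons ending in a planted
#'   canonical terminator.
#' @param decoy_intragenic_sites Motif copies planted inside genes
#'   (exercise the intragenic filter).
#' @param decoy_converging_sites Motif copies planted between converging
#'   gene pairs (exercise the converging-region filter).
#' @param seed RNG seed; the whole genome is deterministic given the config.
#' @param name Replicon id.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(length = 50000L, gc_content = 0.5, n_operons = 10L,
                       genes_per_operon = c(2L, 4L), gene_len = c(300L, 900L),
                       intra_operon_gap = c(20L, 80L),
                       inter_operon_gap = c(600L, 900L),
                       motif = "ACGGTCAGTTCAATGCGTCC",
                       sites_per_motif = NULL,
                       site_upstream_offset = c(20L, 60L),
                       terminator_fraction = 0.5,
                       decoy_intragenic_sites = 5L,
                       decoy_converging_sites = 2L,
                       seed = 1L, name = "synth1") {
  if (gc_content < 0 || gc_content > 1 || terminator_fraction < 0 || terminator_fraction > 1) {
    regsig_error("fractions must lie in [0, 1]", "regsig_argument_error")
  }
  if (is.null(sites_per_motif)) sites_per_motif <- n_operons
  structure(list(length = as.integer(length), gc_content = gc_content,
                 n_operons = as.integer(n_operons),
                 genes_per_operon = as.integer(genes_per_operon),
                 gene_len = as.integer(gene_len),
                 intra_operon_gap = as.integer(intra_operon_gap),
                 inter_operon_gap = as.integer(inter_operon_gap),
                 motif = motif, sites_per_motif = as.integer(sites_per_motif),
                 site_upstream_offset = as.integer(site_upstream_offset),
                 terminator_fraction = terminator_fraction,
                 decoy_intragenic_sites = as.integer(decoy_intragenic_sites),
                 decoy_converging_sites = as.integer(decoy_converging_sites),
                 seed = as.integer(seed), name = name),
            class = "sim_config")
}

rint <- function(range) if (range[1L] >= range[2L]) range[1L] else sample(range[1L]:range[2L], 1L)

sample_motif_instance <- function(motif) {
  if (inherits(motif, "motif_profile")) {
    paste(vapply(seq_len(profile_width(motif)), function(j) {
      sample(BASES, 1L, prob = motif$matrix[, j])
    }, character(1L)), collapse = "")
  } else {
    toupper(motif)
  }
}

motif_len <- function(motif) {
  if (inherits(motif, "motif_profile")) profile_width(motif) else nchar(motif)
}

motif_name <- function(motif) {
  if (inherits(motif, "motif_profile")) motif$name else "planted_motif"
}

#' Simulate an annotated genome with planted regulatory structure
#'
#' Generates i.i.d. background sequence at the requested GC content, lays
#' out operons on alternating strands with gene + CDS feature pairs, plants
#' one motif instance upstream of each chosen operon, plants canonical
#' terminators (8-bp perfect stem, 4-nt loop, 8-nt T tail, preceded by a
#' non-pairing guard base) after a fraction of the operons, and plants
#' decoy motif copies inside genes and between converging gene pairs.
#' Planted terminators are part of the emitted annotation (`terminator`
#' features); planted sites are not annotated — recovering them is the
#' scanner's job. Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `record` (a [genome_record()]) and `truth` (class
#'   `truth_table`: `sites`, `terminators`, `operons` data frames).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_genome_impl(cfg))
}

simulate_genome_impl <- function(cfg) {
  Lm <- motif_len(cfg$motif)
  term <- canonical_terminator()
  term_len <- nchar(term$full)
  probs <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
             cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  chars <- sample(BASES, cfg$length, replace = TRUE, prob = probs)

  plant <- function(chars, pos0, s) {   # pos0: 0-based start
    sub <- strsplit(s, "")[[1L]]
    if (pos0 < 0L || pos0 + length(sub) > length(chars)) {
      regsig_error("planted element exceeds genome bounds", "regsig_layout_error")
    }
    chars[(pos0 + 1L):(pos0 + length(sub))] <- sub
    chars
  }

  feats <- list()
  sites <- list(); terms <- list(); operons <- list()
  gene_rows <- list()
  locus_n <- 0L
  cursor <- rint(cfg$inter_operon_gap)
  term_ops <- if (cfg$n_operons > 0L) {
    utils::head(seq_len(cfg$n_operons), round(cfg$terminator_fraction * cfg$n_operons))
  } else integer()
  for (op in seq_len(cfg$n_operons)) {
    strand <- if (op %% 2L == 1L) "+" else "-"
    k <- rint(cfg$genes_per_operon)
    lens <- vapply(seq_len(k), function(i) rint(cfg$gene_len), integer(1L))
    gaps <- if (k > 1L) vapply(seq_len(k - 1L), function(i) rint(cfg$intra_operon_gap), integer(1L)) else integer()
    op_span <- sum(lens) + sum(gaps)
    # Reserve room before/after for site + terminator + margins.
    if (cursor + op_span + 200L > cfg$length - 100L) {
      regsig_error(sprintf("layout infeasible: operon %d exceeds genome length", op),
                   "regsig_layout_error")
    }
    gstart <- cursor
    starts <- integer(k)
    for (i in seq_len(k)) {
      starts[i] <- gstart
      gstart <- gstart + lens[i] + if (i < k) gaps[i] else 0L
    }
    ends <- starts + lens
    tags <- character(k)
    for (i in seq_len(k)) {
      locus_n <- locus_n + 1L
      tags[i] <- sprintf("SYN_%04d", locus_n)
      quals_g <- list(locus_tag = tags[i])
      quals_c <- list(locus_tag = tags[i], product = "hypothetical protein")
      feats[[length(feats) + 1L]] <- make_feature("gene", starts[i], ends[i], strand, quals_g)
      feats[[length(feats) + 1L]] <- make_feature("CDS", starts[i], ends[i], strand, quals_c)
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(operon = op, locus_tag = tags[i], start = starts[i],
                   end = ends[i], strand = strand, stringsAsFactors = FALSE)
    }
    # Biological order: on "-" the first gene is the rightmost one.
    bio_tags <- if (strand == "+") tags else rev(tags)

    has_site <- op <= cfg$sites_per_motif
    if (has_site) {
      off <- rint(cfg$site_upstream_offset)
      inst <- sample_motif_instance(cfg$motif)
      if (strand == "+") {
        s0 <- starts[1L] - off - Lm
        chars <- plant(chars, s0, inst)
      } else {
        s0 <- ends[k] + off
        chars <- plant(chars, s0, revcomp(inst))
      }
      sites[[length(sites) + 1L]] <-
        data.frame(motif = motif_name(cfg$motif), start = s0, end = s0 + Lm,
                   strand = strand, kind = "regulatory", operon = op,
                   stringsAsFactors = FALSE)
    }

    has_term <- op %in% term_ops
    if (has_term) {
      guard_len <- nchar(term$guard)
      tail_len <- nchar(term$tail)
      hairpin_len <- term_len - guard_len - tail_len
      if (strand == "+") {
        t0 <- ends[k] + 15L                      # guard bases at t0, then hairpin
        chars <- plant(chars, t0, term$full)
        hp_start <- t0 + guard_len
        terms[[length(terms) + 1L]] <-
          data.frame(start = hp_start, end = hp_start + hairpin_len,
                     strand = "+", operon = op, stringsAsFactors = FALSE)
      } else {
        t1 <- starts[1L] - 15L                   # hairpin ends here (0-based excl.)
        full_rc <- revcomp(term$full)            # tail_rc + hairpin_rc + guard_rc
        f0 <- t1 - hairpin_len - tail_len        # start of tail_rc
        chars <- plant(chars, f0, full_rc)
        terms[[length(terms) + 1L]] <-
          data.frame(start = f0 + tail_len, end = t1, strand = "-", operon = op,
                     stringsAsFactors = FALSE)
      }
      tt <- terms[[length(terms)]]
      feats[[length(feats) + 1L]] <- make_feature(
        "terminator", tt$start, tt$end, tt$strand,
        list(note = "planted intrinsic terminator", confidence = "100"))
    }

    operons[[length(operons) + 1L]] <-
      data.frame(operon = op, strand = strand,
                 genes = paste(bio_tags, collapse = ","),
                 end_reason = if (has_term) "terminator"
                              else if (op < cfg$n_operons || (strand == "-" && op > 1L)) "gap"
                              else "contig-end",
                 has_site = has_site, stringsAsFactors = FALSE)
    cursor <- gstart + rint(cfg$inter_operon_gap)
  }

  genes_df <- if (length(gene_rows)) do.call(rbind, gene_rows) else NULL

  # Intragenic decoys: verbatim motif copies in the middle of distinct genes.
  if (cfg$decoy_intragenic_sites > 0L) {
    if (is.null(genes_df) || nrow(genes_df) < cfg$decoy_intragenic_sites) {
      regsig_error("not enough genes to host intragenic decoys", "regsig_layout_error")
    }
    big <- which(genes_df$end - genes_df$start >= Lm + 100L)
    if (length(big) < cfg$decoy_intragenic_sites) {
      regsig_error("not enough long genes to host intragenic decoys", "regsig_layout_error")
    }
    pick <- big[sample.int(length(big), cfg$decoy_intragenic_sites)]
    for (gi in pick) {
      gl <- genes_df$end[gi] - genes_df$start[gi]
      s0 <- genes_df$start[gi] + 50L + sample.int(gl - Lm - 100L, 1L)
      inst <- sample_motif_instance(cfg$motif)
      chars <- plant(chars, s0, inst)
      sites[[length(sites) + 1L]] <-
        data.frame(motif = motif_name(cfg$motif), start = s0, end = s0 + Lm,
                   strand = "+", kind = "decoy_intragenic",
                   operon = genes_df$operon[gi], stringsAsFactors = FALSE)
    }
  }

  # Converging-region decoys: between the facing 3' ends of a +,- operon
  # pair, clear of the planted terminators.
  if (cfg$decoy_converging_sites > 0L && cfg$n_operons >= 2L) {
    ops <- do.call(rbind, operons)
    pairs <- which(ops$strand[-nrow(ops)] == "+" & ops$strand[-1L] == "-")
    if (length(pairs) < cfg$decoy_converging_sites) {
      regsig_error("not enough converging gaps for decoys", "regsig_layout_error")
    }
    pick <- pairs[sample.int(length(pairs), cfg$decoy_converging_sites)]
    for (p in pick) {
      left_end <- max(genes_df$end[genes_df$operon == p])
      right_start <- min(genes_df$start[genes_df$operon == p + 1L])
      mid <- (left_end + right_start - Lm) %/% 2L
      inst <- sample_motif_instance(cfg$motif)
      chars <- plant(chars, mid, inst)
      sites[[length(sites) + 1L]] <-
        data.frame(motif = motif_name(cfg$motif), start = mid, end = mid + Lm,
                   strand = "+", kind = "decoy_converging", operon = NA_integer_,
                   stringsAsFactors = FALSE)
    }
  }

  features <- if (length(feats)) do.call(rbind, feats) else NULL
  record <- genome_record(cfg$name, paste(chars, collapse = ""), features)
  truth <- structure(list(
    sites = if (length(sites)) do.call(rbind, sites) else
      data.frame(motif = character(), start = integer(), end = integer(),
                 strand = character(), kind = character(), operon = integer(),
                 stringsAsFactors = FALSE),
    terminators = if (length(terms)) do.call(rbind, terms) else
      data.frame(start = integer(), end = integer(), strand = character(),
                 operon = integer(), stringsAsFactors = FALSE),
    operons = if (length(operons)) do.call(rbind, operons) else
      data.frame(operon = integer(), strand = character(), genes = character(),
                 end_reason = character(), has_site = logical(),
                 stringsAsFactors = FALSE)
  ), class = "truth_table")
  list(record = record, truth = truth)
}

#' Write simulation outputs to a directory
#'
#' Writes the annotated genome (GenBank), the planted sites and terminators
#' (BED6), and a structured-text manifest of the ground truth.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(sim$record, file.path(dir, "genome.gbk"))
  s <- sim$truth$sites
  utils::write.table(
    data.frame(sim$record$id, s$start, s$end, paste(s$motif, s$kind, sep = "|"),
               0L, s$strand),
    file.path(dir, "sites.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  t <- sim$truth$terminators
  utils::write.table(
    data.frame(sim$record$id, t$start, t$end, "terminator", 0L, t$strand),
    file.path(dir, "terminators.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(
    genome = sim$record$id,
    operons = lapply(seq_len(nrow(sim$truth$operons)), function(i) {
      as.list(sim$truth$operons[i, ])
    })
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
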