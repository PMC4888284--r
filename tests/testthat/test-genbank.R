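toy_record <- function() {
  feats <- rbind(
    regsig:::make_feature("source", 0L, 1200L, "+", list(organism = "synthetic construct")),
    regsig:::make_feature("gene", 100L, 400L, "+", list(locus_tag = "T_0001", gene = "abcA")),
    regsig:::make_feature("CDS", 100L, 400L, "+",
                          list(locus_tag = "T_0001", gene = "abcA",
                               product = "hypothetical protein", codon_start = "1")),
    regsig:::make_feature("gene", 600L, 900L, "-", list(locus_tag = "T_0002")),
    regsig:::make_feature("CDS", 600L, 900L, "-",
                          list(locus_tag = "T_0002",
                               product = paste("a deliberately long product name that",
                                               "forces the qualifier writer to wrap",
                                               "across several continuation lines")))
  )
  genome_record("toy1", random_dna(1200), feats)
}

test_that("GenBank locations convert between 1-based inclusive and half-open", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       conv1 40 bp    DNA     linear   UNA 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             11..30",
    "                     /locus_tag=\"X1\"",
    "     CDS             complement(5..16)",
    "                     /locus_tag=\"X2\"",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(tolower(strrep("acgt", 10)),
                                         seq(1, 40, 10), seq(10, 40, 10)),
                               collapse = " ")),
    "//"
  ), gb)
  rec <- read_genbank(gb)[[1]]
  expect_equal(rec$id, "conv1")
  expect_equal(nchar(rec$sequence), 40L)
  f <- rec$features
  expect_equal(f$start, c(4L, 10L))
  expect_equal(f$end, c(16L, 30L))
  expect_equal(f$strand, c("-", "+"))
  # written back out, locations are 1-based inclusive again
  out <- tempfile(fileext = ".gbk")
  write_genbank(rec, out)
  txt <- readLines(out)
  expect_true(any(grepl("^     CDS             11\\.\\.30$", txt)))
  expect_true(any(grepl("complement\\(5\\.\\.16\\)", txt)))
})

test_that("GenBank round trip is semantically lossless", {
  set.seed(67)
  rec <- toy_record()
  path <- tempfile(fileext = ".gbk")
  write_genbank(rec, path)
  back <- read_genbank(path)[[1]]
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$features[c("kind", "start", "end", "strand")],
               rec$features[c("kind", "start", "end", "strand")])
  expect_equal(lapply(back$features$qualifiers, function(q) lapply(q, as.character)),
               lapply(rec$features$qualifiers, function(q) lapply(q, as.character)))
  # and the rewrite is byte-stable
  path2 <- tempfile(fileext = ".gbk")
  write_genbank(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("join locations keep the enclosing span and round-trip verbatim", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       j1 60 bp    DNA     linear   UNA 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(3..20,31..45)",
    "                     /locus_tag=\"J1\"",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(tolower(strrep("acgtgg", 10)),
                                         seq(1, 60, 10), seq(10, 60, 10)),
                               collapse = " ")),
    "//"
  ), gb)
  rec <- read_genbank(gb)[[1]]
  expect_equal(rec$features$start, 2L)
  expect_equal(rec$features$end, 45L)
  expect_equal(rec$features$qualifiers[[1]]$raw_location, "join(3..20,31..45)")
  out <- tempfile(fileext = ".gbk")
  write_genbank(rec, out)
  expect_true(any(grepl("join(3..20,31..45)", readLines(out), fixed = TRUE)))
})

test_that("a record without ORIGIN is a format error", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       bad 10 bp DNA linear",
               "FEATURES             Location/Qualifiers", "//"), gb)
  expect_error(read_genbank(gb), class = "regsig_format_error")
})

test_that("annotate_sites adds idempotent protein_bind/promoter features", {
  set.seed(71)
  rec <- toy_record()
  hits <- data.frame(genome_id = "toy1", start = 100L, end = 118L, strand = "+",
                     score = 21.37, pvalue = 3.2e-7, profile = "Fur",
                     stringsAsFactors = FALSE)
  expect_identical(annotate_sites(rec, hits[0, ], "Fur"), rec)
  rec1 <- annotate_sites(rec, hits, "Fur")
  expect_equal(nrow(rec1$features), nrow(rec$features) + 1L)
  pb <- rec1$features[rec1$features$kind == "protein_bind", ]
  expect_equal(pb$qualifiers[[1]]$bound_moiety, "Fur")
  expect_match(pb$qualifiers[[1]]$note, "score 21.37")
  # idempotent on reapplication
  rec2 <- annotate_sites(rec1, hits, "Fur")
  expect_equal(nrow(rec2$features), nrow(rec1$features))
  # coordinates survive the GenBank round trip as 1-based inclusive
  path <- tempfile(fileext = ".gbk")
  write_genbank(rec1, path)
  expect_true(any(grepl("^     protein_bind    101\\.\\.118$", readLines(path))))
  back <- read_genbank(path)[[1]]
  pb2 <- back$features[back$features$kind == "protein_bind", ]
  expect_equal(c(pb2$start, pb2$end), c(100L, 118L))

  # promoter annotation uses a note, no bound_moiety
  recp <- annotate_sites(rec, hits, "RpoS", is_promoter = TRUE)
  pr <- recp$features[recp$features$kind == "promoter", ]
  expect_match(pr$qualifiers[[1]]$note, "^RpoS promoter")

  # out-of-bounds hits are reported and the rest applied
  oob <- rbind(hits, within(hits, { start <- 5000L; end <- 5018L }))
  expect_warning(rec3 <- annotate_sites(rec, oob, "Fur"), class = "regsig_warning")
  expect_equal(sum(rec3$features$kind == "protein_bind"), 1L)
})

test_that("annotate_terminators mirrors the site annotation contract", {
  set.seed(73)
  rec <- toy_record()
  cand <- data.frame(start = 450L, end = 470L, strand = "+", stem_len = 8L,
                     loop_len = 4L, mismatches = 0L, hairpin_score = 21,
                     tail_score = 5.2, confidence = 99.4, stringsAsFactors = FALSE)
  rec1 <- annotate_terminators(rec, cand)
  tf <- rec1$features[rec1$features$kind == "terminator", ]
  expect_equal(nrow(tf), 1L)
  expect_equal(tf$qualifiers[[1]]$confidence, "99")
  expect_equal(nrow(annotate_terminators(rec1, cand)$features), nrow(rec1$features))
  expect_identical(annotate_terminators(rec, cand[0, ]), rec)
  expect_identical(rec1$sequence, rec$sequence)
})

test_that("edit_feature replaces qualifiers and renames gene pairs", {
  set.seed(79)
  rec <- toy_record()
  sel <- list(kind = "CDS", start = 100L, end = 400L, strand = "+")
  ed <- edit_feature(rec, sel,
                     updates = list(product = "cellobiose-specific PTS system subunit IIB"))
  cds <- ed$features[ed$features$kind == "CDS" & ed$features$start == 100L, ]
  expect_equal(cds$qualifiers[[1]]$product,
               "cellobiose-specific PTS system subunit IIB")
  # untouched qualifiers and their order survive
  expect_equal(names(cds$qualifiers[[1]]),
               c("locus_tag", "gene", "product", "codon_start"))

  # empty updates leave the record unchanged
  expect_identical(edit_feature(rec, sel), rec)

  # renaming propagates to the paired gene feature on the same interval
  rn <- edit_feature(rec, sel, rename_gene = "celB")
  both <- rn$features[rn$features$start == 100L & rn$features$kind %in% c("gene", "CDS"), ]
  expect_true(all(vapply(both$qualifiers, function(q) q$gene == "celB", logical(1))))

  expect_error(edit_feature(rec, list(kind = "CDS", start = 1L, end = 2L, strand = "+")),
               class = "regsig_selector_error")
  dup <- rec
  dup$features <- rbind(dup$features, dup$features[dup$features$kind == "CDS" &
                                                     dup$features$start == 100L, ])
  expect_error(edit_feature(dup, sel), class = "regsig_selector_error")
  expect_error(edit_feature(dup, sel), "2")
})

test_that("coverage tracks parse both dialects and validate ordering", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("1\t10", "2\t12.5", "7\t0"), tf)
  tr <- read_coverage_track(tf, "sample")
  expect_s3_class(tr, "coverage_track")
  expect_equal(nrow(tr$points), 3L)
  expect_equal(tr$points$value, c(10, 12.5, 0))
  expect_equal(tr$label, "sample")

  writeLines("chr1\t1\t10", tf)
  tr3 <- read_coverage_track(tf)
  expect_equal(nrow(tr3$points), 1L)
  expect_equal(tr3$points$coord, 1L)

  writeLines(c("2\t5", "1\t7"), tf)
  expect_error(read_coverage_track(tf), class = "regsig_order_error")
  writeLines(c("1\tfoo"), tf)
  expect_error(read_coverage_track(tf), class = "regsig_parse_error")
  expect_error(read_coverage_track(tf), "line 1")
  writeLines(c("1\t-3"), tf)
  expect_error(read_coverage_track(tf), class = "regsig_content_error")
})

test_that("written GenBank is parseable by an independent reader", {
  set.seed(83)
  rec <- toy_record()
  path <- tempfile(fileext = ".gbk")
  write_genbank(rec, path)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from Bio import SeqIO",
    "r = SeqIO.read(sys.argv[1], 'genbank')",
    "print(len(r.seq), len(r.features))"
  ), script)
  out <- system2("python", c(script, path), stdout = TRUE, stderr = FALSE)
  vals <- as.integer(strsplit(out[[1]], " ")[[1]])
  expect_equal(vals[1], nchar(rec$sequence))
  expect_equal(vals[2], nrow(rec$features))
})
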