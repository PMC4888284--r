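test_that("build_profile applies the pseudocount formula with N as 1/4 counts", {
  aln <- site_alignment("p", c("a", "b"), c("ACGT", "ACGT"))
  p0 <- build_profile(aln, pseudocount = 0)
  expect_equal(unname(p0$matrix[, 1L]), c(1, 0, 0, 0))

  p2 <- build_profile(site_alignment("p", c("a", "b"), c("AA", "AT")),
                      pseudocount = 0)
  expect_equal(unname(p2$matrix[, 2L]), c(0.5, 0, 0, 0.5))

  # hand arithmetic: counts (2,1,0,0) + 0.5 over n + 4*0.5
  p3 <- build_profile(site_alignment("p", c("a", "b", "c"), c("A", "A", "C")),
                      pseudocount = 0.5)
  expect_equal(unname(p3$matrix[, 1L]), c(2.5, 1.5, 0.5, 0.5) / 5)

  # N spreads fractional counts
  pn <- build_profile(site_alignment("p", c("a", "b"), c("N", "A")),
                      pseudocount = 0)
  expect_equal(unname(pn$matrix[, 1L]), c(1.25, 0.25, 0.25, 0.25) / 2)
})

test_that("column normalization holds for random counts and pseudocounts", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    L <- sample(1:25, 1)
    pc <- stats::runif(1, 0, 3)
    seqs <- vapply(seq_len(n), function(i) random_dna(L), character(1))
    prof <- build_profile(site_alignment("r", sprintf("s%d", 1:n), seqs),
                          pseudocount = pc)
    expect_true(all(abs(colSums(prof$matrix) - 1) < 1e-9))
    expect_true(all(prof$matrix >= 0))
  }
})

test_that("information content matches Shannon entropy and respects the mask", {
  single <- build_profile(site_alignment("i", "a", "A"), pseudocount = 0)
  expect_equal(information_content(single)$total, 2)

  uniform <- motif_profile("u", matrix(0.25, 4, 1))
  expect_equal(information_content(uniform)$total, 0)

  # column (2/3, 0, 0, 1/3): 2 - H = 2 - 0.918296 = 1.081704
  p <- motif_profile("h", matrix(c(2 / 3, 0, 0, 1 / 3), 4, 1))
  expect_equal(information_content(p)$per_column, 1.0817042, tolerance = 1e-6)

  set.seed(7)
  for (rep in 1:10) {
    prof <- random_profile(sample(2:20, 1), n = sample(1:15, 1),
                           pseudocount = stats::runif(1, 0, 1))
    ic <- information_content(prof)$per_column
    expect_true(all(ic >= 0 & ic <= 2 + 1e-12))
    L <- profile_width(prof)
    k <- sample(0:L, 1)
    masked <- prof
    masked$masked_columns <- sort(sample(seq_len(L), k)) - 1L
    expect_lte(information_content(masked)$total, 2 * (L - k) + 1e-9)
  }
})

test_that("small-sample correction subtracts the per-column bias estimate", {
  prof <- build_profile(site_alignment("c", c("a", "b"), c("AA", "AA")),
                        pseudocount = 0)
  plain <- information_content(prof)$per_column
  corr <- information_content(prof, small_sample_correction = TRUE)$per_column
  expect_equal(corr, pmax(plain - 3 / (2 * log(2) * 2), 0))
  nop <- motif_profile("x", matrix(0.25, 4, 2))
  expect_error(information_content(nop, small_sample_correction = TRUE),
               class = "regsig_argument_error")
})

test_that("logo heights are probability-weighted information content", {
  single <- build_profile(site_alignment("l", "a", "A"), pseudocount = 0)
  expect_equal(unname(logo_matrix(single)[, 1L]), c(2, 0, 0, 0))
  expect_equal(unname(logo_matrix(motif_profile("u", matrix(0.25, 4, 1)))[, 1L]),
               rep(0, 4))
  p <- motif_profile("h", matrix(c(2 / 3, 0, 0, 1 / 3), 4, 1))
  expect_equal(unname(logo_matrix(p)[, 1L]), c(0.7211361, 0, 0, 0.3605681),
               tolerance = 1e-6)
  # column sums equal per-column IC
  prof <- random_profile(6)
  expect_equal(unname(colSums(logo_matrix(prof))),
               information_content(prof)$per_column)
})

test_that("calibrate follows the trusted/noise/gathering rule", {
  prof <- random_profile(6)
  cal <- calibrate(prof, c(10.2, 12.5, 15.1), c(8.0, 3.1))
  expect_equal(cal$cutoffs$trusted, 10.2)
  expect_equal(cal$cutoffs$noise, 8.0)
  expect_equal(cal$cutoffs$gathering, 9.1)
  expect_false(cal$cutoffs$provisional)

  # degenerate equality warns but stores values
  expect_warning(deg <- calibrate(prof, 5.0, 5.0), class = "regsig_cutoff_warning")
  expect_equal(unlist(deg$cutoffs[c("trusted", "noise", "gathering")]),
               c(trusted = 5, noise = 5, gathering = 5))

  expect_error(calibrate(prof, numeric()), class = "regsig_argument_error")

  # missing decoys: provisional fallback noise = trusted - 0.5 |trusted|
  prov <- calibrate(prof, c(12, 20))
  expect_true(prov$cutoffs$provisional)
  expect_equal(prov$cutoffs$noise, 12 - 0.5 * 12)

  # order invariance and exact-mean gathering on random score sets
  set.seed(11)
  for (rep in 1:20) {
    tr <- stats::rnorm(sample(1:20, 1), 15, 5)
    de <- stats::rnorm(sample(1:20, 1), 5, 5)
    a <- suppressWarnings(calibrate(prof, tr, de))
    b <- suppressWarnings(calibrate(prof, tr[sample.int(length(tr))],
                                    de[sample.int(length(de))]))
    expect_equal(a$cutoffs, b$cutoffs)
    expect_equal(a$cutoffs$trusted, min(tr))
    expect_equal(a$cutoffs$noise, max(de))
    expect_equal(a$cutoffs$gathering, (min(tr) + max(de)) / 2)
  }
})

test_that("MEME/side-car serialization round-trips every profile field", {
  set.seed(23)
  for (rep in 1:10) {
    prof <- random_profile(sample(2:20, 1), n = sample(2:30, 1))
    prof$description <- "synthetic round-trip profile"
    prof$palindromic <- rep %% 2 == 0
    prof$masked_columns <- sort(sample(seq_len(profile_width(prof)),
                                       sample(0:2, 1))) - 1L
    if (rep %% 3 == 0) prof <- suppressWarnings(calibrate(prof, c(9, 12), c(4)))
    path <- tempfile(fileext = ".meme")
    write_profile(prof, path)
    back <- read_profile(path)
    expect_equal(back$matrix, prof$matrix, tolerance = 1e-6)
    expect_equal(back$background, prof$background, tolerance = 1e-6)
    expect_equal(back$name, prof$name)
    expect_equal(back$masked_columns, prof$masked_columns)
    expect_equal(back$cutoffs, prof$cutoffs)
    expect_equal(back$palindromic, prof$palindromic)
    expect_equal(back$filter_defaults, prof$filter_defaults)
    expect_equal(back$description, prof$description)
    expect_equal(back$nsites, prof$nsites)
  }
})

test_that("MEME writer records the width and the reader validates alength", {
  prof <- random_profile(16)
  path <- tempfile(fileext = ".meme")
  write_profile(prof, path)
  expect_true(any(grepl("w= 16", readLines(path))))

  bad <- sub("alength= 4", "alength= 20", readLines(path))
  writeLines(bad, path)
  expect_error(read_profile(path), class = "regsig_parse_error")
  expect_error(read_profile(path), "line")
})

test_that("a profile without a side-car loads with a warning and unset cutoffs", {
  prof <- suppressWarnings(calibrate(random_profile(8), c(10, 12), c(3)))
  path <- tempfile(fileext = ".meme")
  write_profile(prof, path)
  file.remove(regsig:::sidecar_path(path))
  expect_warning(bare <- read_profile(path), class = "regsig_sidecar_warning")
  expect_null(bare$cutoffs$trusted)
  expect_equal(bare$matrix, prof$matrix, tolerance = 1e-6)
})
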