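# Position weight matrix profiles: construction, information content,
# cutoff calibration, MEME-format (de)serialization.

#' Construct a motif profile
#'
#' A `motif_profile` is the scannable unit: an L-column base-probability
#' matrix, a background distribution, trusted/noise/gathering score cutoffs
#' (in bits, HMMER-style), a column mask, and per-profile filter defaults
#' used by the post-processing step.
#'
#' @param name Profile name (usually the regulator).
#' @param matrix 4 x L numeric matrix of column base probabilities, rows in
#'   A,C,G,T order; every column must sum to 1 (within 1e-9).
#' @param background Length-4 probability vector (A,C,G,T), all entries > 0.
#' @param pseudocount Pseudocount used at construction (kept as metadata).
#' @param masked_columns Integer vector of masked 0-based column indices.
#' @param cutoffs List with optional numeric elements `trusted`, `noise`,
#'   `gathering` (bits) and logical `provisional`.
#' @param palindromic Whether the motif is (treated as) its own reverse
#'   complement, enabling duplicate removal across strands.
#' @param filter_defaults List with `max_upstream`, `min_upstream` (nt) and
#'   `allow_intragenic` used as per-profile defaults by [filter_hits()].
#' @param description Free-text profile description.
#' @param nsites Number of sequences the profile was built from.
#' @return An object of class `motif_profile`.
#' @export
motif_profile <- function(name, matrix, background = rep(0.25, 4),
                          pseudocount = 0.5, masked_columns = integer(),
                          cutoffs = list(trusted = NULL, noise = NULL,
                                         gathering = NULL, provisional = FALSE),
                          palindromic = FALSE,
                          filter_defaults = list(max_upstream = 300L,
                                                 min_upstream = 0L,
                                                 allow_intragenic = FALSE),
                          description = "", nsites = NA_integer_) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) {
    regsig_error("profile matrix must have 4 rows (A,C,G,T)", "regsig_shape_error")
  }
  rownames(matrix) <- BASES
  csums <- colSums(matrix)
  if (any(abs(csums - 1) > 1e-9) || any(matrix < 0)) {
    regsig_error("every profile column must be a probability vector summing to 1",
                 "regsig_content_error")
  }
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) || abs(sum(background) - 1) > 1e-9) {
    regsig_error("background must be 4 strictly positive probabilities summing to 1",
                 "regsig_content_error")
  }
  names(background) <- BASES
  L <- ncol(matrix)
  masked_columns <- sort(unique(as.integer(masked_columns)))
  if (length(masked_columns) && (min(masked_columns) < 0L || max(masked_columns) >= L)) {
    regsig_error("masked_columns must lie in [0, L)", "regsig_range_error")
  }
  if (is.null(cutoffs$provisional)) cutoffs$provisional <- FALSE
  structure(
    list(name = name, matrix = matrix, background = background,
         pseudocount = pseudocount, masked_columns = masked_columns,
         cutoffs = cutoffs, palindromic = isTRUE(palindromic),
         filter_defaults = filter_defaults,
         description = description, nsites = as.integer(nsites)),
    class = "motif_profile"
  )
}

#' @export
print.motif_profile <- function(x, ...) {
  co <- x$cutoffs
  fmt <- function(v) if (is.null(v)) "unset" else sprintf("%.2f", v)
  cat(sprintf("<motif_profile> %s: %d columns, %d masked; cutoffs T/N/G = %s/%s/%s bits\n",
              x$name, ncol(x$matrix), length(x$masked_columns),
              fmt(co$trusted), fmt(co$noise), fmt(co$gathering)))
  invisible(x)
}

#' Profile width (number of columns)
#' @param profile A `motif_profile`.
#' @return Integer column count.
#' @export
profile_width <- function(profile) ncol(profile$matrix)

#' Build a probability profile from a site alignment
#'
#' Column probabilities are `(count(b, j) + pseudocount) / (n + 4 pseudocount)`;
#' an `N` in the input contributes 1/4 of a count to each base. The alignment
#' mask is carried over; cutoffs are left unset (see [calibrate()]).
#'
#' @param aln A [site_alignment()].
#' @param pseudocount Non-negative per-base pseudocount (default 0.5).
#' @param background Length-4 background probabilities (default uniform).
#' @param palindromic Mark the profile palindromic (default `FALSE`).
#' @return A [motif_profile()].
#' @export
build_profile <- function(aln, pseudocount = 0.5, background = rep(0.25, 4),
                          palindromic = FALSE) {
  stopifnot(inherits(aln, "site_alignment"), pseudocount >= 0)
  n <- alignment_size(aln)
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  L <- ncol(mat)
  counts <- matrix(0, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
  for (b in BASES) counts[b, ] <- colSums(mat == b)
  n_counts <- colSums(mat == "N")
  counts <- counts + matrix(n_counts / 4, nrow = 4L, ncol = L, byrow = TRUE)
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  motif_profile(aln$name, probs, background = background,
                pseudocount = pseudocount, masked_columns = aln$mask,
                palindromic = palindromic, nsites = n)
}

#' Per-column and total information content
#'
#' Uses the uniform-background definition `IC_j = 2 + sum_b p(b,j) log2 p(b,j)`
#' (with `0 log 0 = 0`), the height budget of a sequence logo column. Masked
#' columns report 0 bits. A small-sample correction (`3 / (2 ln(2) n)` per
#' column, floored at 0) can optionally be subtracted when the profile knows
#' its site count.
#'
#' @param profile A `motif_profile`.
#' @param small_sample_correction Subtract the per-column small-sample bias
#'   estimate (default `FALSE`).
#' @return List with `per_column` (numeric vector, bits) and `total` (bits).
#' @export
information_content <- function(profile, small_sample_correction = FALSE) {
  p <- profile$matrix
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)
  if (small_sample_correction) {
    n <- profile$nsites
    if (is.na(n) || n < 1L) {
      regsig_error("small-sample correction requires a profile with known nsites",
                   "regsig_argument_error")
    }
    ic <- pmax(ic - 3 / (2 * log(2) * n), 0)
  }
  if (length(profile$masked_columns)) ic[profile$masked_columns + 1L] <- 0
  list(per_column = ic, total = sum(ic))
}

#' Sequence-logo letter heights
#'
#' Letter heights `height(b, j) = p(b, j) * IC_j`, so each column's heights
#' sum to its information content.
#'
#' @param profile A `motif_profile`.
#' @return 4 x L numeric matrix of letter heights (bits), rows A,C,G,T.
#' @export
logo_matrix <- function(profile) {
  ic <- information_content(profile)$per_column
  sweep(profile$matrix, 2L, ic, `*`)
}

#' Calibrate profile score cutoffs
#'
#' Sets the trusted cutoff to the lowest score of a known true site, the
#' noise cutoff to the highest score of a nonspecific hit, and the gathering
#' cutoff (the default scanning threshold) to their mean. Without decoy
#' scores a provisional noise cutoff of `trusted - 0.5 |trusted|` is stored
#' and flagged. A noise cutoff at or above the trusted cutoff triggers a
#' warning, not an error: non-canonical orderings remain representable.
#'
#' @param profile A `motif_profile`.
#' @param training_scores Non-empty numeric vector of true-site scores (bits).
#' @param decoy_scores Optional numeric vector of nonspecific-hit scores.
#' @return A copy of `profile` with `cutoffs` set.
#' @export
calibrate <- function(profile, training_scores, decoy_scores = NULL) {
  if (length(training_scores) == 0L) {
    regsig_error("training_scores must be non-empty", "regsig_argument_error")
  }
  trusted <- min(training_scores)
  provisional <- FALSE
  if (is.null(decoy_scores) || length(decoy_scores) == 0L) {
    noise <- trusted - 2 * abs(trusted) * 0.25
    provisional <- TRUE
  } else {
    noise <- max(decoy_scores)
  }
  if (noise >= trusted) {
    regsig_warn(sprintf("noise cutoff (%.3f) >= trusted cutoff (%.3f)", noise, trusted),
                "regsig_cutoff_warning")
  }
  profile$cutoffs <- list(trusted = trusted, noise = noise,
                          gathering = (trusted + noise) / 2,
                          provisional = provisional)
  profile
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yaml")
}

#' Write a profile to MEME motif format plus metadata side-car
#'
#' The probability matrix and background go into a MEME motif format
#' version 4 file; cutoffs, mask, palindromicity, filter defaults and the
#' description go into a YAML side-car with the same basename, so
#' `read_profile(write_profile(p))` reproduces every field (within 1e-6
#' for probabilities).
#'
#' @param profile A `motif_profile`.
#' @param path Output path for the MEME file (side-car: same basename,
#'   `.yaml` extension).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  L <- profile_width(profile)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.10f C %.10f G %.10f T %.10f",
            profile$background[1L], profile$background[2L],
            profile$background[3L], profile$background[4L]),
    "",
    sprintf("MOTIF %s", profile$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            L, if (is.na(profile$nsites)) 0L else profile$nsites),
    apply(profile$matrix, 2L, function(col) sprintf(" %.10f %.10f %.10f %.10f",
                                                    col[1L], col[2L], col[3L], col[4L]))
  )
  writeLines(lines, path)
  meta <- list(
    name = profile$name,
    pseudocount = profile$pseudocount,
    masked_columns = as.integer(profile$masked_columns),
    cutoffs = list(
      trusted = profile$cutoffs$trusted,
      noise = profile$cutoffs$noise,
      gathering = profile$cutoffs$gathering,
      provisional = isTRUE(profile$cutoffs$provisional)
    ),
    palindromic = profile$palindromic,
    filter_defaults = profile$filter_defaults,
    description = profile$description
  )
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a profile from MEME motif format (plus side-car)
#'
#' Parses a MEME motif format version 4 file written by [write_profile()]
#' (or any single-motif MEME file with `alength= 4`). If the YAML side-car
#' is missing the profile loads with cutoffs unset and a warning.
#'
#' @param path MEME file path.
#' @return A [motif_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) {
    regsig_error(sprintf("profile file not found: %s", path), "regsig_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  perr <- function(msg, i) {
    regsig_error(sprintf("%s (%s line %d)", msg, basename(path), i), "regsig_parse_error")
  }
  bg <- rep(0.25, 4)
  bi <- grep("^Background letter frequencies", lines)
  if (length(bi)) {
    toks <- strsplit(trimws(lines[bi[1L] + 1L]), "\\s+")[[1L]]
    if (length(toks) < 8L) perr("malformed background frequency line", bi[1L] + 1L)
    vals <- suppressWarnings(as.numeric(toks[c(2L, 4L, 6L, 8L)]))
    if (any(is.na(vals))) perr("non-numeric background frequency", bi[1L] + 1L)
    bg <- vals
  }
  mi <- grep("^MOTIF\\s+", lines)
  if (!length(mi)) perr("no MOTIF block found", length(lines))
  name <- strsplit(trimws(lines[mi[1L]]), "\\s+")[[1L]][2L]
  li <- grep("^letter-probability matrix:", lines)
  li <- li[li > mi[1L]][1L]
  if (is.na(li)) perr("no letter-probability matrix line", mi[1L])
  hdr <- lines[li]
  getnum <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=\\s*(\\S+)"), hdr))[[1L]]
    if (length(m) < 2L) NA else suppressWarnings(as.numeric(m[2L]))
  }
  alength <- getnum("alength")
  w <- getnum("w")
  nsites <- getnum("nsites")
  if (is.na(alength) || alength != 4) perr("alength must be 4", li)
  if (is.na(w) || w < 1) perr("invalid motif width", li)
  rows <- matrix(NA_real_, nrow = 4L, ncol = w)
  ri <- li
  for (j in seq_len(w)) {
    ri <- ri + 1L
    if (ri > length(lines)) perr("truncated probability matrix", length(lines))
    toks <- strsplit(trimws(lines[ri]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 4L || any(is.na(vals))) perr("malformed matrix row", ri)
    rows[, j] <- vals
  }
  # Re-normalize rounded columns so the probability invariant holds exactly.
  rows <- sweep(rows, 2L, colSums(rows), `/`)
  bg <- bg / sum(bg)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    motif_profile(
      name = if (!is.null(meta$name)) meta$name else name,
      matrix = rows, background = bg,
      pseudocount = if (!is.null(meta$pseudocount)) meta$pseudocount else 0.5,
      masked_columns = if (!is.null(meta$masked_columns)) unlist(meta$masked_columns) else integer(),
      cutoffs = list(trusted = meta$cutoffs$trusted, noise = meta$cutoffs$noise,
                     gathering = meta$cutoffs$gathering,
                     provisional = isTRUE(meta$cutoffs$provisional)),
      palindromic = isTRUE(meta$palindromic),
      filter_defaults = lapply(meta$filter_defaults, function(x) x),
      description = if (!is.null(meta$description)) meta$description else "",
      nsites = if (!is.na(nsites) && nsites > 0) nsites else NA_integer_
    )
  } else {
    regsig_warn(sprintf("no side-car metadata for %s; cutoffs unset", basename(path)),
                "regsig_sidecar_warning")
    motif_profile(name, rows, background = bg,
                  nsites = if (!is.na(nsites) && nsites > 0) nsites else NA_integer_)
  }
}
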