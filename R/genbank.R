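# GenBank flat-file I/O and annotation editing.
#
# In-memory locations are 0-based half-open on the top strand; GenBank files
# use 1-based inclusive locations. Features live in a data frame with a
# list-column of ordered qualifier maps, so qualifier order survives a
# round trip. join()/order() locations are kept as their enclosing span with
# the verbatim location string preserved in a `raw_location` qualifier that
# is written back in place of the span.

#' Construct an annotated genome record
#'
#' @param id Replicon identifier.
#' @param sequence DNA string (IUPAC; internally only A,C,G,T,N are scored).
#' @param features Data frame with columns `kind` (character), `start`,
#'   `end` (0-based half-open integers), `strand` (`"+"`, `"-"` or `"."`),
#'   and `qualifiers` (list of named lists of character vectors). May be
#'   `NULL` for a featureless record.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = NULL, topology = "linear") {
  sequence <- toupper(sequence)
  if (is.null(features) || nrow(features) == 0L) {
    features <- empty_features()
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    stopifnot(all(c("kind", "start", "end", "strand", "qualifiers") %in% names(features)))
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    if (any(features$start < 0L | features$end > nchar(sequence) |
            features$start >= features$end)) {
      regsig_error("feature locations must satisfy 0 <= start < end <= length",
                   "regsig_range_error")
    }
    features <- sort_features(features)
  }
  structure(list(id = id, sequence = sequence, features = features,
                 topology = match.arg(topology, c("linear", "circular"))),
            class = "genome_record")
}

empty_features <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             strand = character(), qualifiers = I(list()),
             stringsAsFactors = FALSE)
}

sort_features <- function(features) {
  ord <- order(features$start, features$end)
  features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  features
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp (%s), %d features\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features)))
  invisible(x)
}

make_feature <- function(kind, start, end, strand, qualifiers = list()) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             strand = strand, qualifiers = I(list(qualifiers)),
             stringsAsFactors = FALSE)
}

qualifier1 <- function(feature_row, key) {
  q <- feature_row$qualifiers[[1L]][[key]]
  if (is.null(q)) NA_character_ else q[1L]
}

parse_location <- function(loc) {
  raw <- loc
  strand <- "+"
  s <- gsub("\\s", "", loc)
  complemented <- grepl("^complement\\(", s)
  if (complemented) strand <- "-"
  nums <- regmatches(s, gregexpr("\\d+", s))[[1L]]
  if (length(nums) < 1L) return(NULL)
  nums <- as.numeric(nums)
  start1 <- min(nums); end1 <- max(nums)
  joined <- grepl("join\\(|order\\(", s)
  list(start = as.integer(start1 - 1), end = as.integer(end1), strand = strand,
       raw = if (joined) raw else NULL)
}

format_location <- function(start, end, strand) {
  core <- if (end - start == 1L) sprintf("%d", start + 1L) else sprintf("%d..%d", start + 1L, end)
  if (strand == "-") sprintf("complement(%s)", core) else core
}

#' Read GenBank flat files
#'
#' Parses one or more records from a GenBank flat file: LOCUS name/length/
#' topology, the feature table, and the ORIGIN sequence. 1-based inclusive
#' locations become 0-based half-open; `complement()` becomes minus strand;
#' `join()`/`order()` locations are represented by their enclosing span with
#' the original location string kept verbatim in a `raw_location` qualifier.
#' Unparsable locations produce a per-feature warning and the feature is
#' kept with the raw string only.
#'
#' @param path GenBank file.
#' @return List of [genome_record()]s.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) {
    regsig_error(sprintf("GenBank file not found: %s", path), "regsig_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) }
  records <- list()
  for (r in seq_along(starts)) {
    chunk <- lines[starts[r]:ends[r]]
    chunk <- chunk[!grepl("^//\\s*$", chunk)]
    if (!any(nzchar(trimws(chunk)))) next
    locus_i <- grep("^LOCUS", chunk)
    id <- "unknown"; topology <- "linear"
    if (length(locus_i)) {
      toks <- strsplit(trimws(sub("^LOCUS\\s+", "", chunk[locus_i[1L]])), "\\s+")[[1L]]
      id <- toks[1L]
      if (any(toks == "circular")) topology <- "circular"
    }
    origin_i <- grep("^ORIGIN", chunk)
    if (!length(origin_i)) {
      regsig_error(sprintf("record %s has no ORIGIN sequence", id), "regsig_format_error")
    }
    seq_lines <- chunk[(origin_i[1L] + 1L):length(chunk)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    feat_i <- grep("^FEATURES", chunk)
    features <- empty_features()
    if (length(feat_i)) {
      flines <- chunk[(feat_i[1L] + 1L):(origin_i[1L] - 1L)]
      flines <- flines[grepl("^\\s{5}", flines)]
      features <- parse_feature_table(flines, id)
    }
    records[[length(records) + 1L]] <-
      genome_record(id, sequence, features, topology)
  }
  records
}

parse_feature_table <- function(flines, record_id) {
  is_new <- grepl("^\\s{5}\\S", flines)
  idx <- which(is_new)
  feats <- list()
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
    block <- flines[from:to]
    kind <- trimws(substr(block[1L], 1L, 21L))
    rest <- trimws(substr(block[1L], 22L, nchar(block[1L])))
    body <- trimws(substr(block[-1L], 22L, nchar(block[-1L])))
    # Location may continue over lines until the first qualifier.
    qstart <- which(startsWith(body, "/"))
    loc_extra <- if (length(qstart)) body[seq_len(min(qstart) - 1L)] else body
    qlines <- if (length(qstart)) body[min(qstart):length(body)] else character()
    loc_str <- paste(c(rest, loc_extra), collapse = "")
    quals <- parse_qualifiers(qlines)
    parsed <- parse_location(loc_str)
    if (is.null(parsed)) {
      regsig_warn(sprintf("unparsable location '%s' for %s feature in %s; kept raw",
                          loc_str, kind, record_id))
      quals <- c(list(raw_location = loc_str), quals)
      parsed <- list(start = 0L, end = 1L, strand = ".", raw = NULL)
    } else if (!is.null(parsed$raw)) {
      quals <- c(list(raw_location = parsed$raw), quals)
    }
    feats[[k]] <- make_feature(kind, parsed$start, parsed$end, parsed$strand, quals)
  }
  if (!length(feats)) return(empty_features())
  do.call(rbind, feats)
}

parse_qualifiers <- function(qlines) {
  quals <- list()
  i <- 1L
  while (i <= length(qlines)) {
    line <- qlines[i]
    m <- regmatches(line, regexec("^/([A-Za-z0-9_]+)(=(.*))?$", line))[[1L]]
    if (length(m) == 0L) { i <- i + 1L; next }
    key <- m[2L]
    if (m[3L] == "") {                       # flag qualifier, e.g. /pseudo
      val <- NA_character_
      i <- i + 1L
    } else {
      val <- m[4L]
      if (startsWith(val, "\"")) {
        val <- substring(val, 2L)
        parts <- character()
        while (TRUE) {
          if (grepl("\"$", val)) { parts <- c(parts, sub("\"$", "", val)); break }
          parts <- c(parts, val)
          i <- i + 1L
          if (i > length(qlines)) break
          val <- qlines[i]
        }
        # Continuation lines are joined with a space (translation-style
        # qualifiers are not re-split; this package never writes them).
        val <- paste(parts, collapse = " ")
      }
      i <- i + 1L
    }
    if (is.null(quals[[key]])) quals[[key]] <- val else quals[[key]] <- c(quals[[key]], val)
  }
  quals
}

wrap_qualifier <- function(key, value, width = 58L) {
  if (is.na(value)) return(sprintf("/%s", key))
  numeric_like <- grepl("^\\d+$", value)
  text <- if (numeric_like) sprintf("/%s=%s", key, value) else sprintf("/%s=\"%s\"", key, value)
  if (nchar(text) <= width) return(text)
  # Break quoted values at spaces; pieces are re-joined with a space on read.
  words <- strsplit(text, " ")[[1L]]
  out <- character(); cur <- words[1L]
  for (w in words[-1L]) {
    if (nchar(cur) + 1L + nchar(w) <= width) cur <- paste(cur, w) else { out <- c(out, cur); cur <- w }
  }
  c(out, cur)
}

#' Write records as a GenBank flat file
#'
#' Features are written in coordinate order with their qualifier order
#' preserved; locations are 1-based inclusive, minus strand as
#' `complement()`, and features carrying a `raw_location` qualifier get that
#' string written back verbatim.
#'
#' @param records A [genome_record()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  out <- character()
  for (rec in records) {
    n <- nchar(rec$sequence)
    out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA 01-JAN-2000",
                          rec$id, n, rec$topology),
             sprintf("DEFINITION  %s.", rec$id),
             sprintf("ACCESSION   %s", rec$id),
             "FEATURES             Location/Qualifiers")
    feats <- sort_features(rec$features)
    for (i in seq_len(nrow(feats))) {
      quals <- feats$qualifiers[[i]]
      loc <- if (!is.null(quals$raw_location)) {
        quals$raw_location[1L]
      } else {
        format_location(feats$start[i], feats$end[i], feats$strand[i])
      }
      quals$raw_location <- NULL
      out <- c(out, sprintf("     %-16s%s", feats$kind[i], loc))
      for (key in names(quals)) {
        for (v in quals[[key]]) {
          out <- c(out, sprintf("                     %s", wrap_qualifier(key, v)))
        }
      }
    }
    out <- c(out, "ORIGIN")
    seq_lc <- tolower(rec$sequence)
    pos <- seq.int(1L, n, by = 60L)
    for (p in pos) {
      chunk <- substr(seq_lc, p, min(p + 59L, n))
      blocks <- substring(chunk, seq.int(1L, nchar(chunk), by = 10L),
                          pmin(seq.int(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Add regulatory-site features from hits
#'
#' Each hit becomes a `promoter` feature (qualifier
#' `note="<regulator> promoter, score <bits>"`) or a `protein_bind` feature
#' (qualifiers `bound_moiety=<regulator>`,
#' `note="score <bits>, p-value <p>"`). Duplicate features — same kind,
#' interval, strand and bound moiety — are not added twice, so repeated
#' scans are safe; the sequence is never modified.
#'
#' @param record A [genome_record()].
#' @param hits Hit data frame from [scan_genome()]/[filter_hits()].
#' @param regulator Regulator name.
#' @param is_promoter Annotate as `promoter` instead of `protein_bind`.
#' @return The record with features added and re-sorted.
#' @export
annotate_sites <- function(record, hits, regulator, is_promoter = FALSE) {
  if (is.null(hits) || nrow(hits) == 0L) return(record)
  n <- nchar(record$sequence)
  bad <- hits$start < 0L | hits$end > n
  if (any(bad)) {
    regsig_warn(sprintf("%d hit(s) outside sequence bounds skipped: %s",
                        sum(bad),
                        paste(sprintf("[%d,%d)", hits$start[bad], hits$end[bad]),
                              collapse = ", ")))
    hits <- hits[!bad, , drop = FALSE]
  }
  existing <- feature_keys(record$features)
  add <- list()
  for (i in seq_len(nrow(hits))) {
    kind <- if (is_promoter) "promoter" else "protein_bind"
    moiety <- if (is_promoter) NA_character_ else regulator
    key <- paste(kind, hits$start[i], hits$end[i], hits$strand[i], moiety, sep = "|")
    if (key %in% existing) next
    existing <- c(existing, key)
    quals <- if (is_promoter) {
      list(note = sprintf("%s promoter, score %.2f", regulator, hits$score[i]))
    } else {
      list(bound_moiety = regulator,
           note = sprintf("score %.2f, p-value %.3g", hits$score[i], hits$pvalue[i]))
    }
    add[[length(add) + 1L]] <-
      make_feature(kind, hits$start[i], hits$end[i], hits$strand[i], quals)
  }
  if (length(add)) {
    record$features <- sort_features(rbind(record$features, do.call(rbind, add)))
  }
  record
}

feature_keys <- function(features) {
  if (nrow(features) == 0L) return(character())
  moiety <- vapply(seq_len(nrow(features)), function(i) {
    q <- features$qualifiers[[i]]$bound_moiety
    if (is.null(q)) NA_character_ else q[1L]
  }, character(1L))
  paste(features$kind, features$start, features$end, features$strand, moiety, sep = "|")
}

#' Add terminator features from detected candidates
#'
#' Each candidate becomes a `terminator` feature with a `confidence`
#' qualifier; duplicates (same interval and strand) are not added twice.
#'
#' @param record A [genome_record()].
#' @param candidates Terminator data frame from [find_terminators()].
#' @return The record with features added and re-sorted.
#' @export
annotate_terminators <- function(record, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(record)
  existing <- feature_keys(record$features)
  add <- list()
  for (i in seq_len(nrow(candidates))) {
    key <- paste("terminator", candidates$start[i], candidates$end[i],
                 candidates$strand[i], NA, sep = "|")
    if (key %in% existing) next
    existing <- c(existing, key)
    add[[length(add) + 1L]] <- make_feature(
      "terminator", candidates$start[i], candidates$end[i], candidates$strand[i],
      list(note = "intrinsic (rho-independent) terminator",
           confidence = sprintf("%d", as.integer(round(candidates$confidence[i]))))
    )
  }
  if (length(add)) {
    record$features <- sort_features(rbind(record$features, do.call(rbind, add)))
  }
  record
}

#' Edit one feature's qualifiers
#'
#' The selector must match exactly one feature. Listed qualifiers are
#' replaced (or added); `rename_gene` additionally updates the `gene`
#' qualifier on the feature and on its gene/CDS partner sharing the same
#' interval and strand.
#'
#' @param record A [genome_record()].
#' @param selector List with `kind`, `start`, `end` (0-based half-open) and
#'   `strand`.
#' @param updates Named list of qualifier values (character vectors); an
#'   empty list leaves qualifiers untouched.
#' @param rename_gene Optional new gene name.
#' @return The edited record.
#' @export
edit_feature <- function(record, selector, updates = list(), rename_gene = NULL) {
  f <- record$features
  hitsel <- which(f$kind == selector$kind &
                  f$start == as.integer(selector$start) &
                  f$end == as.integer(selector$end) &
                  f$strand == selector$strand)
  if (length(hitsel) != 1L) {
    regsig_error(sprintf("selector matches %d features (need exactly 1)", length(hitsel)),
                 "regsig_selector_error")
  }
  q <- f$qualifiers[[hitsel]]
  for (key in names(updates)) q[[key]] <- as.character(updates[[key]])
  if (!is.null(rename_gene)) {
    q[["gene"]] <- rename_gene
    partner_kind <- if (selector$kind == "gene") "CDS" else "gene"
    partner <- which(f$kind == partner_kind &
                     f$start == as.integer(selector$start) &
                     f$end == as.integer(selector$end) &
                     f$strand == selector$strand)
    for (p in partner) {
      qp <- f$qualifiers[[p]]
      qp[["gene"]] <- rename_gene
      f$qualifiers[[p]] <- qp
    }
  }
  f$qualifiers[[hitsel]] <- q
  record$features <- f
  record
}

#' Read a coverage track
#'
#' Accepts tab-separated two-column (coordinate, value) files and the
#' three-column (reference, coordinate, value) dialect emitted by per-base
#' depth tools; the dialect is auto-detected per file. Coordinates are
#' 1-based and must be strictly increasing; values must be non-negative.
#'
#' @param path Track file.
#' @param label Track label.
#' @return An object of class `coverage_track` with elements `points`
#'   (data frame `coord`, `value`) and `label`.
#' @export
read_coverage_track <- function(path, label = basename(path)) {
  if (!file.exists(path)) {
    regsig_error(sprintf("track file not found: %s", path), "regsig_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(list(points = data.frame(coord = integer(), value = numeric()),
                          label = label), class = "coverage_track"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1L]])
  if (!ncol1 %in% c(2L, 3L)) {
    regsig_error(sprintf("expected 2 or 3 tab-separated columns (line 1 has %d)", ncol1),
                 "regsig_parse_error")
  }
  ci <- if (ncol1 == 3L) 2L else 1L
  coords <- numeric(length(fields)); values <- numeric(length(fields))
  for (i in seq_along(fields)) {
    fl <- fields[[i]]
    if (length(fl) != ncol1) {
      regsig_error(sprintf("inconsistent column count at line %d", i), "regsig_parse_error")
    }
    cv <- suppressWarnings(as.numeric(fl[ci]))
    vv <- suppressWarnings(as.numeric(fl[ci + 1L]))
    if (is.na(cv) || is.na(vv)) {
      regsig_error(sprintf("non-numeric field at line %d", i), "regsig_parse_error")
    }
    coords[i] <- cv; values[i] <- vv
  }
  if (any(diff(coords) <= 0)) {
    bad <- which(diff(coords) <= 0)[1L] + 1L
    regsig_error(sprintf("coordinates not strictly increasing at line %d", bad),
                 "regsig_order_error")
  }
  if (any(values < 0)) {
    regsig_error("track values must be non-negative", "regsig_content_error")
  }
  structure(list(points = data.frame(coord = as.integer(coords), value = values),
                 label = label),
            class = "coverage_track")
}
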