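# Tabular data contracts: read-length tables, experimental designs,
# transcript annotations. All tables are plain data.frames with canonical
# column names; TSV is the only on-disk format.

.LENGTH_COLS_REQUIRED <- c("read_id", "library_id", "transcript_id", "length")
.LENGTH_COLS_OPTIONAL <- c("adaptor_ligated", "has_polya")

#' Column dialect for read-length tables
#'
#' Maps the canonical column names used internally to the headers expected in
#' a TSV file. The defaults are `read_id`, `library`, `feature`, `length` and,
#' optionally, `adaptor` and `polya`. Override any entry to read files written
#' with different headers.
#'
#' @param read_id,library_id,transcript_id,length Header names for the four
#'   required columns.
#' @param adaptor_ligated,has_polya Header names for the optional logical
#'   flag columns (5' adaptor ligation status, poly(A) tail detected).
#' @return Named character vector mapping canonical names to file headers.
#' @export
#' @examples
#' length_dialect(transcript_id = "tx_id")
length_dialect <- function(read_id = "read_id", library_id = "library",
                           transcript_id = "feature", length = "length",
                           adaptor_ligated = "adaptor", has_polya = "polya") {
  c(read_id = read_id, library_id = library_id, transcript_id = transcript_id,
    length = length, adaptor_ligated = adaptor_ligated, has_polya = has_polya)
}

.validate_length_table <- function(df) {
  len <- suppressWarnings(as.numeric(df$length))
  bad <- which(is.na(len) | !is.finite(len) | len <= 0)
  if (length(bad) > 0L) {
    stop("invalid read length (non-numeric or not > 0) on row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         call. = FALSE)
  }
  df$length <- len
  key <- paste(df$library_id, df$read_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicated (library_id, read_id) on row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  for (col in .LENGTH_COLS_OPTIONAL) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  class(df) <- c("read_length_table", "data.frame")
  df
}

#' Construct a read-length table from a data.frame
#'
#' @param df data.frame with columns `read_id`, `library_id`, `transcript_id`,
#'   `length` and optionally `adaptor_ligated`, `has_polya`.
#' @return A validated `read_length_table` (a data.frame).
#' @export
as_length_table <- function(df) {
  missing_cols <- setdiff(.LENGTH_COLS_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(c(.LENGTH_COLS_REQUIRED, .LENGTH_COLS_OPTIONAL), names(df))
  df <- as.data.frame(df)[, keep, drop = FALSE]
  for (col in c("read_id", "library_id", "transcript_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  rownames(df) <- NULL
  .validate_length_table(df)
}

#' Read a read-length table from TSV
#'
#' Reads a tab-separated file with a header row, one row per sequenced read:
#' read identifier, library identifier, transcript identifier and read length
#' in nucleotides, plus optional logical flags for 5' adaptor ligation and
#' poly(A) detection. Rows violating the invariants (non-positive or
#' non-numeric length, duplicated read within a library) raise an error
#' naming the offending rows.
#'
#' @param path Path to a TSV file (UTF-8, header required).
#' @param dialect Header mapping, see [length_dialect()].
#' @return A `read_length_table` data.frame with canonical column names.
#' @export
load_length_table <- function(path, dialect = length_dialect()) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  required <- dialect[.LENGTH_COLS_REQUIRED]
  missing_cols <- required[!required %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    read_id = as.character(raw[[dialect[["read_id"]]]]),
    library_id = as.character(raw[[dialect[["library_id"]]]]),
    transcript_id = as.character(raw[[dialect[["transcript_id"]]]]),
    length = raw[[dialect[["length"]]]],
    stringsAsFactors = FALSE
  )
  for (col in .LENGTH_COLS_OPTIONAL) {
    header <- dialect[[col]]
    if (!is.na(header) && header %in% names(raw)) out[[col]] <- raw[[header]]
  }
  .validate_length_table(out)
}

#' Write a read-length table as TSV
#'
#' Inverse of [load_length_table()]: canonical columns are renamed through the
#' dialect before writing, so that save-then-load round-trips.
#'
#' @param table A `read_length_table`.
#' @param path Output file path.
#' @param dialect Header mapping, see [length_dialect()].
#' @return `path`, invisibly.
#' @export
write_length_table <- function(table, path, dialect = length_dialect()) {
  df <- as.data.frame(table)
  names(df) <- dialect[names(df)]
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct an experimental design
#'
#' A design maps each sequencing library to one of exactly two condition
#' levels, one of which is the reference (control). The fitted condition
#' effect is always "non-reference minus reference".
#'
#' @param library_id Character vector of unique library identifiers.
#' @param condition Character vector (same length) with at most two levels.
#' @param reference Reference (control) level. Defaults to the
#'   lexicographically smallest level.
#' @param extra Optional data.frame of additional per-library covariates.
#' @return A `length_design` data.frame with attributes `reference` and
#'   `single_library` (TRUE when some condition has fewer than two libraries,
#'   in which case the mixed model refuses to fit and falls back).
#' @export
new_design <- function(library_id, condition, reference = NULL, extra = NULL) {
  library_id <- as.character(library_id)
  condition <- as.character(condition)
  stopifnot(length(library_id) == length(condition))
  dup <- library_id[duplicated(library_id)]
  if (length(dup) > 0L) {
    stop("duplicated library_id in design: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  levels <- sort(unique(condition))
  if (length(levels) > 2L) {
    stop("design must have at most 2 condition levels, found ",
         length(levels), ": ", paste(levels, collapse = ", "), call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- levels[1L]
  } else if (!reference %in% levels) {
    stop("reference level '", reference, "' not among condition levels: ",
         paste(levels, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(library_id = library_id, condition = condition,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, as.data.frame(extra))
  attr(df, "reference") <- reference
  attr(df, "single_library") <- any(table(condition) < 2L) || length(levels) < 2L
  class(df) <- c("length_design", "data.frame")
  df
}

#' Read an experimental design from TSV
#'
#' Expects columns `library` and `condition`; any further columns are kept as
#' per-library covariates. More than two condition levels is an error; a
#' duplicated library is an error.
#'
#' @param path Path to a TSV file with a header row.
#' @param reference Optional explicit reference (control) level; when absent
#'   the lexicographically smallest level is used.
#' @return A `length_design`, see [new_design()].
#' @export
load_design <- function(path, reference = NULL) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  for (col in c("library", "condition")) {
    if (!col %in% names(raw)) {
      stop("design file ", path, " is missing required column: ", col,
           call. = FALSE)
    }
  }
  extra_cols <- setdiff(names(raw), c("library", "condition"))
  extra <- if (length(extra_cols) > 0L) raw[, extra_cols, drop = FALSE] else NULL
  new_design(raw$library, raw$condition, reference = reference, extra = extra)
}

#' Write a design as TSV
#'
#' @param design A `length_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design)
  names(df)[names(df) == "library_id"] <- "library"
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Reference (control) level of a design
#' @param design A `length_design`.
#' @return Character scalar.
#' @export
design_reference <- function(design) attr(design, "reference")

# condition level per library, as a 0/1 indicator (1 = non-reference)
.condition_indicator <- function(design) {
  ref <- attr(design, "reference")
  stats::setNames(as.integer(design$condition != ref), design$library_id)
}

.check_design_covers <- function(table, design) {
  missing_libs <- setdiff(unique(table$library_id), design$library_id)
  if (length(missing_libs) > 0L) {
    stop("libraries present in length table but absent from design: ",
         paste(missing_libs, collapse = ", "), call. = FALSE)
  }
}

#' Filter reads and transcripts ahead of testing
#'
#' Optional flag filters are applied first: `adaptor_only` keeps only reads
#' whose 5' adaptor was detected (certifying the molecule was sequenced to
#' its true 5' end), `polya_only` keeps only reads with a detected poly(A)
#' tail. A read with an unknown (NA) flag is never treated as flagged, so it
#' is dropped by the corresponding filter. The count filter is then applied:
#' a transcript is kept only when it has at least `min_reads_per_condition`
#' remaining reads in *both* conditions.
#'
#' @param table A `read_length_table`.
#' @param design A `length_design` covering all libraries in `table`.
#' @param min_reads_per_condition Minimum reads per transcript in each
#'   condition (default 10).
#' @param adaptor_only,polya_only Logical flag filters; requesting one when
#'   the corresponding column is absent is an error.
#' @return The filtered `read_length_table` (row order preserved).
#' @export
filter_reads <- function(table, design, min_reads_per_condition = 10,
                         adaptor_only = FALSE, polya_only = FALSE) {
  stopifnot(min_reads_per_condition >= 1)
  .check_design_covers(table, design)
  if (adaptor_only) {
    if (!"adaptor_ligated" %in% names(table)) {
      stop("adaptor_only requested but column 'adaptor_ligated' is absent",
           call. = FALSE)
    }
    table <- table[table$adaptor_ligated %in% TRUE, , drop = FALSE]
  }
  if (polya_only) {
    if (!"has_polya" %in% names(table)) {
      stop("polya_only requested but column 'has_polya' is absent", call. = FALSE)
    }
    table <- table[table$has_polya %in% TRUE, , drop = FALSE]
  }
  if (nrow(table) == 0L) {
    class(table) <- c("read_length_table", "data.frame")
    return(table)
  }
  ind <- .condition_indicator(design)
  cond <- ind[table$library_id]
  counts <- table(factor(table$transcript_id), factor(cond, levels = c(0, 1)))
  ok <- rownames(counts)[counts[, "0"] >= min_reads_per_condition &
                         counts[, "1"] >= min_reads_per_condition]
  out <- table[table$transcript_id %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_length_table", "data.frame")
  out
}

#' Per-transcript average read length by condition
#'
#' Summarises a read-length table into one row per transcript that has at
#' least `min_reads` reads in both conditions: read counts and arithmetic
#' mean read length per condition, plus the difference (condition minus
#' control) in nucleotides.
#'
#' @param table A `read_length_table`.
#' @param design A `length_design` covering all libraries in `table`.
#' @param min_reads Minimum reads per condition (default 10).
#' @return data.frame with columns `transcript_id`, `n_control`,
#'   `n_condition`, `mean_control`, `mean_condition`, `diff`, sorted by
#'   `transcript_id`. An empty input yields an empty summary.
#' @export
average_length_per_feature <- function(table, design, min_reads = 10) {
  stopifnot(min_reads >= 1)
  empty <- data.frame(transcript_id = character(), n_control = integer(),
                      n_condition = integer(), mean_control = numeric(),
                      mean_condition = numeric(), diff = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(table) == 0L) return(empty)
  .check_design_covers(table, design)
  ind <- .condition_indicator(design)
  cond <- factor(ind[table$library_id], levels = c(0, 1))
  tx <- factor(table$transcript_id)
  n <- table(tx, cond)
  mean_len <- tapply(table$length, list(tx, cond), mean)
  out <- data.frame(
    transcript_id = rownames(n),
    n_control = as.integer(n[, "0"]),
    n_condition = as.integer(n[, "1"]),
    mean_control = as.numeric(mean_len[, "0"]),
    mean_condition = as.numeric(mean_len[, "1"]),
    stringsAsFactors = FALSE
  )
  out$diff <- out$mean_condition - out$mean_control
  out <- out[out$n_control >= min_reads & out$n_condition >= min_reads, ,
             drop = FALSE]
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a transcript annotation table from TSV
#'
#' Expects columns `transcript`, `length` and optionally `utr5_start`,
#' `utr5_end` (0-based half-open interval in transcript coordinates). The
#' interval must satisfy 0 <= utr5_start < utr5_end <= length.
#'
#' @param path Path to a TSV file with a header row.
#' @return data.frame with columns `transcript_id`, `annotated_length`,
#'   `utr5_start`, `utr5_end` (the UTR columns NA when not annotated).
#' @export
load_annotation <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  for (col in c("transcript", "length")) {
    if (!col %in% names(raw)) {
      stop("annotation file ", path, " is missing required column: ", col,
           call. = FALSE)
    }
  }
  out <- data.frame(
    transcript_id = as.character(raw$transcript),
    annotated_length = as.integer(raw$length),
    utr5_start = if ("utr5_start" %in% names(raw)) as.integer(raw$utr5_start) else NA_integer_,
    utr5_end = if ("utr5_end" %in% names(raw)) as.integer(raw$utr5_end) else NA_integer_,
    stringsAsFactors = FALSE
  )
  as_annotation(out)
}

#' Validate a transcript annotation data.frame
#'
#' @param df data.frame with columns `transcript_id`, `annotated_length` and
#'   optionally `utr5_start`, `utr5_end`.
#' @return The validated annotation data.frame.
#' @export
as_annotation <- function(df) {
  stopifnot(all(c("transcript_id", "annotated_length") %in% names(df)))
  df <- as.data.frame(df)
  if (!"utr5_start" %in% names(df)) df$utr5_start <- NA_integer_
  if (!"utr5_end" %in% names(df)) df$utr5_end <- NA_integer_
  if (any(duplicated(df$transcript_id))) {
    stop("duplicated transcript_id in annotation", call. = FALSE)
  }
  if (any(df$annotated_length <= 0, na.rm = TRUE)) {
    stop("annotated_length must be positive", call. = FALSE)
  }
  has_utr <- !is.na(df$utr5_start) & !is.na(df$utr5_end)
  bad <- has_utr & !(df$utr5_start >= 0 & df$utr5_start < df$utr5_end &
                     df$utr5_end <= df$annotated_length)
  if (any(bad)) {
    stop("invalid 5' UTR interval for transcript(s): ",
         paste(utils::head(df$transcript_id[bad], 10L), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Derive a transcript annotation from a BED12 file
#'
#' Treats each BED12 record as one transcript: the annotated length is the
#' sum of block sizes, and the 5' UTR is the exonic span between the
#' transcript 5' end and the thickStart/thickEnd coding boundary, projected
#' into transcript coordinates (strand-aware). Records with no coding region
#' (thickStart == thickEnd) or an empty 5' UTR get NA UTR columns.
#'
#' @param path Path to a 12-column BED file (no header).
#' @return Annotation data.frame as in [load_annotation()].
#' @export
annotation_from_bed12 <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(bed) < 12L) {
    stop("expected 12 BED columns, found ", ncol(bed), call. = FALSE)
  }
  names(bed)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                        "thick_start", "thick_end", "rgb", "n_blocks",
                        "block_sizes", "block_starts")
  parse_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1L]])
  res <- lapply(seq_len(nrow(bed)), function(i) {
    sizes <- parse_ints(bed$block_sizes[i])
    starts <- parse_ints(bed$block_starts[i]) + bed$start[i]
    ends <- starts + sizes
    tx_len <- sum(sizes)
    utr_len <- NA_integer_
    if (bed$thick_start[i] < bed$thick_end[i]) {
      if (bed$strand[i] == "-") {
        # exonic bases 3'-of thickEnd in genome space are the transcript 5' UTR
        utr_len <- sum(pmax(0L, ends - pmax(starts, bed$thick_end[i])))
      } else {
        utr_len <- sum(pmax(0L, pmin(ends, bed$thick_start[i]) - starts))
      }
      if (utr_len == 0L) utr_len <- NA_integer_
    }
    data.frame(transcript_id = bed$name[i], annotated_length = tx_len,
               utr5_start = if (is.na(utr_len)) NA_integer_ else 0L,
               utr5_end = utr_len, stringsAsFactors = FALSE)
  })
  as_annotation(do.call(rbind, res))
}
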