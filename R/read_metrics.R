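# Read geometry from transcriptome alignments: per-read templated-end
# coordinates, 20-bin meta-length, TSS calls from 5' end density, and
# nucleotide composition around read 5' ends.
#
# Coordinates are 0-based half-open everywhere in memory; 1-based only at
# the SAM boundary.

# Reference-space width of CIGAR strings (M, =, X, D, N consume reference).
.cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    if (length(ops) == 0L) return(NA_integer_)
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substring(ops, nchar(ops))
    sum(n[op %in% c("M", "=", "X", "D", "N")])
  }, integer(1L))
}

#' Extract per-read transcript coordinates from a SAM/BAM file
#'
#' Reads transcriptome alignments (one reference sequence per transcript)
#' and reports, per retained read, the 0-based inclusive coordinate of its
#' 5' templated end (`start5`), the 0-based exclusive coordinate one past
#' its 3' templated end (`end3`), and the aligned reference span. Soft and
#' hard clips never count towards the span, so adaptor and poly(A) bases do
#' not inflate read lengths.
#'
#' Unmapped records are dropped; secondary and supplementary records are
#' dropped when `primary_only`; records below `min_mapq` are dropped.
#' Reverse-strand alignments are biologically unexpected on a transcriptome
#' reference for direct RNA reads and are skipped with a message counting
#' them.
#'
#' @param path Path to a BAM file, or a SAM text file (converted on the
#'   fly).
#' @param library_id Library identifier attached to every read (default:
#'   file name without extension).
#' @param min_mapq Minimum mapping quality (default 0).
#' @param primary_only Drop secondary/supplementary alignments (default
#'   TRUE).
#' @return data.frame (`read_coord_table`) with columns `read_id`,
#'   `library_id`, `transcript_id`, `start5`, `end3`, `aligned_length`.
#' @export
extract_read_coords <- function(path, library_id = NULL, min_mapq = 0,
                                primary_only = TRUE) {
  if (is.null(library_id)) {
    library_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  flag <- res$flag
  keep <- !bitwAnd(flag, 4L)                      # mapped
  if (primary_only) {
    keep <- keep & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  }
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 0L
  keep <- keep & mapq >= min_mapq
  rev <- keep & bitwAnd(flag, 16L) > 0L
  if (any(rev)) {
    message(sum(rev), " reverse-strand alignment(s) skipped")
    keep <- keep & !rev
  }
  start5 <- res$pos[keep] - 1L
  width <- .cigar_ref_width(res$cigar[keep])
  out <- data.frame(
    read_id = res$qname[keep],
    library_id = library_id,
    transcript_id = as.character(res$rname[keep]),
    start5 = start5,
    end3 = start5 + width,
    aligned_length = width,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("read_coord_table", "data.frame")
  out
}

#' Convert read coordinates to a read-length table
#'
#' The read "length" handed to the differential tests is the aligned
#' reference span (`end3 - start5`) by default, so untemplated adaptor and
#' poly(A) bases are excluded.
#'
#' @param coords A `read_coord_table`.
#' @return A `read_length_table` suitable for [run_differential_length()].
#' @export
coords_to_length_table <- function(coords) {
  as_length_table(data.frame(
    read_id = coords$read_id, library_id = coords$library_id,
    transcript_id = coords$transcript_id, length = coords$aligned_length,
    stringsAsFactors = FALSE
  ))
}

#' Read/write a read-coordinate table as TSV
#'
#' @param path File path.
#' @return `load_read_coords` returns a `read_coord_table`;
#'   `write_read_coords` returns `path` invisibly.
#' @export
load_read_coords <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  required <- c("read_id", "library_id", "transcript_id", "start5", "end3")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("coordinate file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$aligned_length <- df$end3 - df$start5
  if (any(df$start5 < 0 | df$aligned_length < 1)) {
    stop("invalid coordinates: need 0 <= start5 < end3", call. = FALSE)
  }
  class(df) <- c("read_coord_table", "data.frame")
  df
}

#' @rdname load_read_coords
#' @param coords A `read_coord_table`.
#' @export
write_read_coords <- function(coords, path) {
  data.table::fwrite(as.data.frame(coords), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' 20-bin meta-length of reads
#'
#' Each annotated transcript is divided into 20 equal bins indexed 0..19;
#' a read's 5' and 3' templated ends are assigned to bins
#' `bin(x) = floor(x / (L/20))` (using the last covered base, `end3 - 1`,
#' for the 3' end) and its meta-length is the inclusive bin span as a
#' percentage of full length: `(bin3 - bin5 + 1) / 20 * 100`. A
#' full-length read therefore scores exactly 100% and the smallest possible
#' read 5%.
#'
#' @param coords A `read_coord_table`.
#' @param annotation Annotation data.frame (see [load_annotation()]); every
#'   transcript in `coords` must be present, and transcripts shorter than
#'   20 nt are skipped with a warning.
#' @return data.frame with columns `read_id`, `transcript_id`, `bin5`,
#'   `bin3`, `meta_length_percent`.
#' @export
compute_meta_length <- function(coords, annotation) {
  i <- match(coords$transcript_id, annotation$transcript_id)
  if (anyNA(i)) {
    missing_tx <- unique(coords$transcript_id[is.na(i)])
    stop("transcript(s) missing from annotation: ",
         paste(utils::head(missing_tx, 10L), collapse = ", "), call. = FALSE)
  }
  len <- annotation$annotated_length[i]
  short <- len < 20L
  if (any(short)) {
    warning("skipping ", length(unique(coords$transcript_id[short])),
            " transcript(s) shorter than 20 nt", call. = FALSE)
    coords <- coords[!short, , drop = FALSE]
    len <- len[!short]
  }
  bad <- coords$start5 < 0 | coords$end3 > len | coords$start5 >= coords$end3
  if (any(bad)) {
    stop("read coordinates outside annotated transcript for read(s): ",
         paste(utils::head(coords$read_id[bad], 10L), collapse = ", "),
         call. = FALSE)
  }
  bw <- len / 20
  bin5 <- pmin(floor(coords$start5 / bw), 19)
  bin3 <- pmin(floor((coords$end3 - 1) / bw), 19)
  out <- data.frame(
    read_id = coords$read_id,
    transcript_id = coords$transcript_id,
    bin5 = as.integer(bin5),
    bin3 = as.integer(bin3),
    meta_length_percent = (bin3 - bin5 + 1) * 5,  # == span/20 * 100, exact
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Call transcription start sites from read 5' end density
#'
#' Pools reads (from all libraries when `pool_libraries`), counts read 5'
#' ends at each position inside the annotated 5' UTR, and calls the modal
#' position as the TSS when its support reaches `min_support` reads;
#' otherwise no call is made for that transcript. Ties are broken towards
#' the smallest (most 5') coordinate and flagged. Transcripts without a 5'
#' UTR annotation are skipped and counted in a message.
#'
#' @param coords A `read_coord_table`.
#' @param annotation Annotation data.frame with `utr5_start` / `utr5_end`.
#' @param min_support Minimum reads at the called position (default 5).
#' @param pool_libraries Combine all libraries before counting (default
#'   TRUE); otherwise calls are made per library and the result gains a
#'   `library_id` column.
#' @return data.frame with columns `transcript_id`, `tss_position`,
#'   `support`, `total_utr_reads`, `tie` (plus `library_id` when not
#'   pooling). Transcripts whose best position falls below `min_support`
#'   are absent.
#' @export
call_tss <- function(coords, annotation, min_support = 5,
                     pool_libraries = TRUE) {
  ann <- annotation[!is.na(annotation$utr5_start) & !is.na(annotation$utr5_end), ,
                    drop = FALSE]
  skipped <- setdiff(unique(coords$transcript_id), ann$transcript_id)
  if (length(skipped) > 0L) {
    message(length(skipped), " transcript(s) without 5' UTR annotation skipped")
  }
  coords <- coords[coords$transcript_id %in% ann$transcript_id, , drop = FALSE]
  i <- match(coords$transcript_id, ann$transcript_id)
  in_utr <- coords$start5 >= ann$utr5_start[i] & coords$start5 < ann$utr5_end[i]
  coords <- coords[in_utr, , drop = FALSE]
  empty <- data.frame(transcript_id = character(), tss_position = integer(),
                      support = integer(), total_utr_reads = integer(),
                      tie = logical(), stringsAsFactors = FALSE)
  if (nrow(coords) == 0L) return(empty)
  group <- if (pool_libraries) {
    coords$transcript_id
  } else {
    paste(coords$transcript_id, coords$library_id, sep = "\r")
  }
  idx <- split(seq_len(nrow(coords)), group)
  rows <- lapply(idx, function(j) {
    cnt <- table(coords$start5[j])
    pos <- as.integer(names(cnt))
    best <- which(cnt == max(cnt))
    support <- as.integer(max(cnt))
    if (support < min_support) return(NULL)
    data.frame(transcript_id = coords$transcript_id[j][1L],
               library_id = coords$library_id[j][1L],
               tss_position = min(pos[best]),
               support = support,
               total_utr_reads = length(j),
               tie = length(best) > 1L,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  if (pool_libraries) out$library_id <- NULL
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nucleotide composition around read 5' ends
#'
#' For every read, takes the transcript bases at offsets `-flank` to
#' `+flank` relative to the read's 5' templated end (offset 0 is the first
#' templated base) and tallies base frequencies per offset. Read-offset
#' pairs falling outside the transcript are skipped, so the number of
#' counted reads can differ between offsets; each row's A/C/G/T fractions
#' sum to 1 over the reads counted at that offset.
#'
#' @param coords A `read_coord_table`.
#' @param sequences Transcript sequences: a FASTA path, a
#'   `Biostrings::DNAStringSet`, or a named character vector. Every
#'   transcript in `coords` must be present.
#' @param flank Number of positions on each side of the 5' end (default
#'   10).
#' @return Numeric matrix with one row per offset (rownames the signed
#'   offsets) and columns A, C, G, T; attribute `n_reads` gives the reads
#'   counted per offset.
#' @export
nt_composition <- function(coords, sequences, flank = 10) {
  stopifnot(flank >= 0)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (inherits(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
  } else {
    seqs <- sequences
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing_tx <- setdiff(unique(coords$transcript_id), names(seqs))
  if (length(missing_tx) > 0L) {
    stop("transcript(s) absent from sequences: ",
         paste(utils::head(missing_tx, 10L), collapse = ", "), call. = FALSE)
  }
  tx_seq <- seqs[coords$transcript_id]
  tx_len <- nchar(tx_seq)
  offsets <- seq.int(-flank, flank)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, nrow = length(offsets), ncol = 4L,
                dimnames = list(offsets, bases))
  n_reads <- integer(length(offsets))
  for (k in seq_along(offsets)) {
    pos <- coords$start5 + offsets[k]          # 0-based
    ok <- pos >= 0L & pos < tx_len
    if (!any(ok)) next
    b <- substr(tx_seq[ok], pos[ok] + 1L, pos[ok] + 1L)
    cnt <- table(factor(b, levels = bases))
    n_reads[k] <- sum(cnt)                     # non-ACGT bases not counted
    if (n_reads[k] > 0L) mat[k, ] <- as.numeric(cnt) / n_reads[k]
  }
  attr(mat, "n_reads") <- stats::setNames(n_reads, offsets)
  mat
}
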