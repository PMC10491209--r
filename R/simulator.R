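# Simulation engine: synthetic read-length datasets under a transcript
# shortening model, and power / type-I-error evaluation over scenario grids.

#' Define a shortening-simulation scenario
#'
#' One scenario fixes the generative model for a synthetic experiment. For
#' gene g and library j the expected read length is the true length for
#' control libraries and `shortening_proportion` times the true length for
#' condition libraries; a per-gene-per-library random intercept (SD =
#' `lib_effect_sd_frac` times the true length) emulates between-library
#' fluctuation, and each read adds residual noise with SD =
#' `resid_sd_frac` times its group mean (so shortened reads are less noisy
#' in absolute nucleotides). Lengths are rounded to whole nucleotides and
#' clamped at 1.
#'
#' Defaults are the study conditions used throughout: 3 control + 3
#' condition libraries, library SD 10% of the true length, residual SD 20%
#' of the group mean, 1000 genes per scenario. The true length defaults to
#' 1000 nt for hand-checkability; because both noise terms scale with it,
#' results on the log scale are insensitive to its value.
#'
#' @param true_length True transcript length in nucleotides (default 1000).
#' @param reads_per_library Reads simulated per gene per library.
#' @param shortening_proportion Condition mean as a fraction of the true
#'   length, in (0, 1]; 1.0 is the null of no change.
#' @param n_control_libs,n_condition_libs Library counts (default 3 and 3).
#' @param lib_effect_sd_frac Library random-effect SD as a fraction of the
#'   true length (default 0.10).
#' @param resid_sd_frac Residual SD as a fraction of the group mean length
#'   (default 0.20).
#' @param n_genes Genes per scenario (default 1000).
#' @param seed Master RNG seed; everything downstream is reproducible from it.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(true_length = 1000, reads_per_library = 100,
                                shortening_proportion = 1,
                                n_control_libs = 3, n_condition_libs = 3,
                                lib_effect_sd_frac = 0.10,
                                resid_sd_frac = 0.20,
                                n_genes = 1000, seed = 1) {
  stopifnot(true_length > 0,
            reads_per_library >= 1,
            shortening_proportion > 0, shortening_proportion <= 1,
            n_control_libs >= 1, n_condition_libs >= 1,
            lib_effect_sd_frac >= 0, resid_sd_frac >= 0,
            n_genes >= 1)
  if (shortening_proportion * true_length < 1) {
    stop("expected condition mean length is below 1 nt", call. = FALSE)
  }
  structure(list(true_length = true_length,
                 reads_per_library = as.integer(reads_per_library),
                 shortening_proportion = shortening_proportion,
                 n_control_libs = as.integer(n_control_libs),
                 n_condition_libs = as.integer(n_condition_libs),
                 lib_effect_sd_frac = lib_effect_sd_frac,
                 resid_sd_frac = resid_sd_frac,
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

# Deterministic per-gene seeds derived from the master seed, so any single
# gene can be regenerated without replaying the whole stream.
.gene_seeds <- function(seed, n_genes) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_genes)
}

#' Simulate a read-length dataset from a scenario
#'
#' Draws `reads_per_library` read lengths per gene per library under the
#' scenario's shortening model and returns them as a standard read-length
#' table plus the matching design (condition levels `control` /
#' `shortened`, reference `control`). Two calls with the same scenario are
#' identical. More than 0.1% of reads clamped at the 1 nt floor triggers a
#' warning.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with elements `table` (a `read_length_table`), `design`
#'   (a `length_design`), and `n_clamped`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  libs <- c(sprintf("ctrl_%d", seq_len(sc$n_control_libs)),
            sprintf("case_%d", seq_len(sc$n_condition_libs)))
  cond01 <- rep(c(0L, 1L), c(sc$n_control_libs, sc$n_condition_libs))
  n_libs <- length(libs)
  mu <- ifelse(cond01 == 1L, sc$shortening_proportion * sc$true_length,
               sc$true_length)
  lib_sd <- sc$lib_effect_sd_frac * sc$true_length
  seeds <- .gene_seeds(sc$seed, sc$n_genes)
  count <- sc$reads_per_library
  per_gene <- n_libs * count
  gene_ids <- sprintf("gene_%04d", seq_len(sc$n_genes))
  lengths <- numeric(sc$n_genes * per_gene)
  n_clamped <- 0L
  for (g in seq_len(sc$n_genes)) {
    set.seed(seeds[g])
    b <- stats::rnorm(n_libs, 0, lib_sd)
    y <- stats::rnorm(per_gene,
                      mean = rep(mu + b, each = count),
                      sd = rep(sc$resid_sd_frac * mu, each = count))
    y <- round(y)
    n_clamped <- n_clamped + sum(y < 1)
    lengths[((g - 1L) * per_gene + 1L):(g * per_gene)] <- pmax(1, y)
  }
  if (n_clamped > 0.001 * length(lengths)) {
    warning(sprintf("%d of %d simulated lengths (%.2f%%) clamped at 1 nt",
                    n_clamped, length(lengths),
                    100 * n_clamped / length(lengths)), call. = FALSE)
  }
  table <- data.frame(
    read_id = sprintf("%s:%s:r%03d",
                      rep(gene_ids, each = per_gene),
                      rep(rep(libs, each = count), times = sc$n_genes),
                      rep(seq_len(count), times = sc$n_genes * n_libs)),
    library_id = rep(rep(libs, each = count), times = sc$n_genes),
    transcript_id = rep(gene_ids, each = per_gene),
    length = lengths,
    stringsAsFactors = FALSE
  )
  class(table) <- c("read_length_table", "data.frame")
  design <- new_design(libs, ifelse(cond01 == 1L, "shortened", "control"),
                       reference = "control")
  list(table = table, design = design, n_clamped = n_clamped)
}

#' Evaluate a test over a grid of shortening proportions and read counts
#'
#' For every (proportion, count) cell, simulates `n_genes` genes under the
#' base scenario with those values, runs [run_differential_length()], and
#' records the mean condition-effect estimate and the fraction of genes
#' called significant at `alpha` (on the raw p-value, and on the BH-adjusted
#' one). The proportion = 1.0 cell measures the empirical type-I error; at
#' other proportions the significant fraction is the empirical power and,
#' under `logscale`, the mean estimate should recover log2(proportion).
#'
#' Each cell gets its own seed derived deterministically from the base
#' scenario's seed, so the grid is reproducible cell by cell.
#'
#' @param proportions Numeric vector of shortening proportions in (0, 1].
#' @param counts Integer vector of reads per gene per library.
#' @param base_scenario Scenario supplying all other parameters.
#' @param model,logscale,alpha Passed to [run_differential_length()].
#' @param min_reads_per_condition Read filter passed through (default 10).
#' @param keep_results Keep the per-gene result tables as the
#'   `results` attribute (default FALSE).
#' @return data.frame with one row per grid cell: `proportion`, `count`,
#'   `n_genes`, `mean_estimate`, `sd_estimate`, `significant_fraction`,
#'   `significant_fraction_adj`, `n_fallback`, `seed`.
#' @export
run_simulation_grid <- function(proportions, counts,
                                base_scenario = simulation_scenario(),
                                model = "lmm", logscale = TRUE, alpha = 0.05,
                                min_reads_per_condition = 10,
                                keep_results = FALSE) {
  stopifnot(length(proportions) >= 1, length(counts) >= 1)
  grid <- expand.grid(proportion = proportions, count = counts,
                      KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_seed <- (base_scenario$seed + 7919L * i) %% (.Machine$integer.max - 1L)
    sc <- simulation_scenario(
      true_length = base_scenario$true_length,
      reads_per_library = grid$count[i],
      shortening_proportion = grid$proportion[i],
      n_control_libs = base_scenario$n_control_libs,
      n_condition_libs = base_scenario$n_condition_libs,
      lib_effect_sd_frac = base_scenario$lib_effect_sd_frac,
      resid_sd_frac = base_scenario$resid_sd_frac,
      n_genes = base_scenario$n_genes,
      seed = cell_seed
    )
    sim <- simulate_scenario(sc)
    res <- run_differential_length(sim$table, sim$design, model = model,
                                   logscale = logscale,
                                   min_reads_per_condition = min_reads_per_condition,
                                   alpha = alpha)
    if (keep_results) results[[i]] <- res
    rows[[i]] <- data.frame(
      proportion = grid$proportion[i], count = grid$count[i],
      n_genes = nrow(res),
      mean_estimate = mean(res$estimate, na.rm = TRUE),
      sd_estimate = stats::sd(res$estimate, na.rm = TRUE),
      significant_fraction = mean(res$sig_raw),
      significant_fraction_adj = mean(res$sig_adj),
      n_fallback = sum(res$fallback_flag),
      seed = cell_seed
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_results) attr(out, "results") <- results
  out
}

# -- fixture generation -------------------------------------------------------

.write_toy_fasta <- function(path) {
  writeLines(c(">TX1", strrep("ACGT", 15L),    # 60 nt, base at p is ACGT[p %% 4]
               ">TX2", strrep("GGGGGCCCCC", 10L)),  # 100 nt, G when p %% 10 < 5
             path)
}

.write_toy_sam <- function(path) {
  rec <- function(qname, flag, rname, pos, mapq, cigar) {
    paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*", sep = "\t")
  }
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:TX1\tLN:60",
    "@SQ\tSN:TX2\tLN:100",
    rec("r1", 0,   "TX1", 11, 60, "50M"),        # [10, 60)
    rec("r2", 0,   "TX1", 1,  60, "5S40M10S"),   # clips excluded: [0, 40)
    rec("r3", 0,   "TX2", 1,  60, "100M"),       # full length: [0, 100)
    rec("r4", 0,   "TX2", 26, 3,  "20M5D25M"),   # deletion spans ref: [25, 75)
    rec("r5", 0,   "TX2", 1,  60, "3M2I2M"),     # insertion not in ref: [0, 5)
    rec("r6", 16,  "TX1", 5,  60, "20M"),        # reverse strand: skipped
    rec("r7", 256, "TX1", 3,  60, "30M"),        # secondary: skipped
    rec("r8", 4,   "TX2", 1,  0,  "*")           # unmapped: skipped
  ), path)
}

# Expected coordinates for the toy SAM under defaults (primary-only, mapq 0),
# hand-computed from POS and CIGAR.
.toy_coord_manifest <- function(library_id = "toy") {
  data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    library_id = library_id,
    transcript_id = c("TX1", "TX1", "TX2", "TX2", "TX2"),
    start5 = c(10L, 0L, 0L, 25L, 0L),
    end3 = c(60L, 40L, 100L, 75L, 5L),
    aligned_length = c(50L, 40L, 100L, 50L, 5L),
    stringsAsFactors = FALSE
  )
}

# Hand-computed meta-length for the manifest reads (TX1 60 nt -> bin width 3;
# TX2 100 nt -> bin width 5).
.toy_meta_manifest <- function() {
  data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    transcript_id = c("TX1", "TX1", "TX2", "TX2", "TX2"),
    bin5 = c(3L, 0L, 0L, 5L, 0L),
    bin3 = c(19L, 13L, 19L, 14L, 0L),
    meta_length_percent = c(85, 70, 100, 50, 5),
    stringsAsFactors = FALSE
  )
}

# 5' end positions for TSS calling on the toy transcripts: TX1 has a clear
# mode with 6 supporting reads at position 5 inside its [0, 20) UTR; TX2's
# best position has only 4 reads, below the minimum support, so no call.
.toy_tss_reads <- function(library_id = "toy") {
  pos <- c(rep(5L, 6), rep(12L, 3), rep(25L, 4),   # TX1 (25 is outside the UTR)
           rep(10L, 4), rep(20L, 4))               # TX2
  tx <- c(rep("TX1", 13), rep("TX2", 8))
  data.frame(read_id = sprintf("t%02d", seq_along(pos)),
             library_id = library_id, transcript_id = tx,
             start5 = pos, end3 = pos + 30L,
             aligned_length = 30L, stringsAsFactors = FALSE)
}

.toy_annotation <- function() {
  as_annotation(data.frame(
    transcript_id = c("TX1", "TX2"),
    annotated_length = c(60L, 100L),
    utr5_start = c(0L, 0L), utr5_end = c(20L, 30L),
    stringsAsFactors = FALSE
  ))
}

#' Write seed-reproducible test fixtures to disk
#'
#' Generates the small plain-text inputs used across the test suite:
#' \describe{
#'   \item{toy_lengths}{A 5-transcript length table + design (proportion
#'     0.7, 20 reads/library).}
#'   \item{null_table}{A 20-transcript null table + design (proportion 1.0,
#'     30 reads/library).}
#'   \item{shortened_table}{A 20-transcript table + design where 5
#'     transcripts are shortened to 50% of the true length (50
#'     reads/library), plus `manifest.tsv` naming the shortened ones.}
#'   \item{toy_bam}{A miniature 2-transcript FASTA, a hand-written 8-record
#'     SAM exercising clips/indels/flags, an annotation TSV, a coordinate
#'     table for TSS calling, and hand-computed manifests for coordinates
#'     and meta-length.}
#' }
#' Repeated calls with the same seed write identical files.
#'
#' @param kind One of `"toy_lengths"`, `"null_table"`, `"shortened_table"`,
#'   `"toy_bam"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (ignored by the fully hand-written `toy_bam`).
#' @return Named list of the file paths written, invisibly.
#' @export
make_fixture <- function(kind = c("toy_lengths", "null_table",
                                  "shortened_table", "toy_bam"),
                         dir, seed = 1) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir, call. = FALSE)
  }
  path <- function(...) file.path(dir, paste0(...))
  paths <- list()
  if (kind == "toy_lengths") {
    sim <- simulate_scenario(simulation_scenario(
      true_length = 1000, reads_per_library = 20, shortening_proportion = 0.7,
      n_genes = 5, seed = seed))
    paths$lengths <- write_length_table(sim$table, path("lengths.tsv"))
    paths$design <- write_design(sim$design, path("design.tsv"))
  } else if (kind == "null_table") {
    sim <- simulate_scenario(simulation_scenario(
      true_length = 1000, reads_per_library = 30, shortening_proportion = 1,
      n_genes = 20, seed = seed))
    paths$lengths <- write_length_table(sim$table, path("lengths.tsv"))
    paths$design <- write_design(sim$design, path("design.tsv"))
  } else if (kind == "shortened_table") {
    null_part <- simulate_scenario(simulation_scenario(
      true_length = 1000, reads_per_library = 50, shortening_proportion = 1,
      n_genes = 15, seed = seed))
    short_part <- simulate_scenario(simulation_scenario(
      true_length = 1000, reads_per_library = 50, shortening_proportion = 0.5,
      n_genes = 5, seed = seed + 104729L))
    relabel <- function(x, offset) {
      old <- sprintf("gene_%04d", seq_len(length(unique(x))))
      new <- sprintf("gene_%04d", seq_len(length(old)) + offset)
      new[match(x, old)]
    }
    short_part$table$transcript_id <- relabel(short_part$table$transcript_id, 15L)
    short_part$table$read_id <- paste0("s", short_part$table$read_id)
    tab <- rbind(null_part$table, short_part$table)
    class(tab) <- c("read_length_table", "data.frame")
    paths$lengths <- write_length_table(tab, path("lengths.tsv"))
    paths$design <- write_design(null_part$design, path("design.tsv"))
    manifest <- data.frame(transcript_id = sprintf("gene_%04d", 1:20),
                           shortened = rep(c(FALSE, TRUE), c(15, 5)),
                           proportion = rep(c(1, 0.5), c(15, 5)))
    data.table::fwrite(manifest, path("manifest.tsv"), sep = "\t", quote = FALSE)
    paths$manifest <- path("manifest.tsv")
  } else if (kind == "toy_bam") {
    .write_toy_fasta(path("toy.fa"))
    .write_toy_sam(path("toy.sam"))
    data.table::fwrite(.toy_coord_manifest(), path("coords_manifest.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(.toy_meta_manifest(), path("meta_manifest.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(.toy_tss_reads(), path("tss_reads.tsv"),
                       sep = "\t", quote = FALSE)
    ann <- .toy_annotation()
    data.table::fwrite(data.frame(transcript = ann$transcript_id,
                                  length = ann$annotated_length,
                                  utr5_start = ann$utr5_start,
                                  utr5_end = ann$utr5_end),
                       path("annotation.tsv"), sep = "\t", quote = FALSE)
    paths <- list(fasta = path("toy.fa"), sam = path("toy.sam"),
                  coords_manifest = path("coords_manifest.tsv"),
                  meta_manifest = path("meta_manifest.tsv"),
                  tss_reads = path("tss_reads.tsv"),
                  annotation = path("annotation.tsv"))
  }
  invisible(paths)
}
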