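test_that("length tables round-trip through TSV and honour dialects", {
  tab <- table_from_spec(list(
    tx1 = list(ctrl_1 = c(100, 200), case_1 = 300),
    tx2 = list(ctrl_1 = c(50, 60, 70), case_1 = c(40, 45))
  ))
  tab$adaptor_ligated <- c(TRUE, FALSE, NA, TRUE, TRUE, FALSE, TRUE, FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_length_table(tab, path)
  reloaded <- load_length_table(path)
  expect_equal(as.data.frame(reloaded), as.data.frame(tab))

  # custom headers through a dialect map
  dial <- length_dialect(transcript_id = "tx", library_id = "lib")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_length_table(tab, path2, dialect = dial)
  expect_equal(as.data.frame(load_length_table(path2, dialect = dial)),
               as.data.frame(tab))
})

test_that("length table validation reports offending rows and columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read_id\tlibrary\tfeature\tlength",
               "r1\tlib1\ttx1\t100",
               "r2\tlib1\ttx1\t-5",
               "r3\tlib1\ttx2\t80"), path)
  expect_error(load_length_table(path), "row\\(s\\): 2")

  writeLines(c("read_id\tlibrary\tlength", "r1\tlib1\t100"), path)
  expect_error(load_length_table(path), "feature")

  # duplicated read within a library
  expect_error(as_length_table(data.frame(
    read_id = c("r1", "r1"), library_id = "lib1",
    transcript_id = c("tx1", "tx2"), length = c(10, 20))),
    "duplicated")
  # same read id in different libraries is legal
  expect_s3_class(as_length_table(data.frame(
    read_id = c("r1", "r1"), library_id = c("lib1", "lib2"),
    transcript_id = "tx1", length = c(10, 20))),
    "read_length_table")
})

test_that("designs resolve the reference level and reject bad inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("library\tcondition",
               paste(sprintf("u%d", 1:3), "unstressed", sep = "\t"),
               paste(sprintf("a%d", 1:3), "arsenite", sep = "\t")), path)
  d <- load_design(path)
  expect_equal(design_reference(d), "arsenite")  # lexicographic default
  expect_false(attr(d, "single_library"))
  d2 <- load_design(path, reference = "unstressed")
  expect_equal(design_reference(d2), "unstressed")
  expect_error(load_design(path, reference = "mock"), "not among")

  writeLines(c("library\tcondition", "l1\ta", "l2\tb", "l3\tc"), path)
  expect_error(load_design(path), "a, b, c")

  writeLines(c("library\tcondition", "l1\ta", "l1\tb"), path)
  expect_error(load_design(path), "duplicated")

  writeLines(c("library\tcondition", "l1\ta"), path)
  d3 <- load_design(path)
  expect_true(attr(d3, "single_library"))
})

test_that("filter_reads applies flag filters then the per-condition count", {
  # 4 control / 10 condition reads with min 5 drops the transcript
  tab <- table_from_spec(list(
    weak = list(ctrl_1 = rep(100, 4), case_1 = rep(90, 10)),
    ok = list(ctrl_1 = rep(100, 6), case_1 = rep(90, 7))
  ))
  d <- toy_design()
  out <- filter_reads(tab, d, min_reads_per_condition = 5)
  expect_equal(unique(out$transcript_id), "ok")

  # all-adaptor table is unchanged by adaptor_only
  tab$adaptor_ligated <- TRUE
  expect_equal(nrow(filter_reads(tab, d, 5, adaptor_only = TRUE)), nrow(out))
  # NA flags are unknown, not TRUE: the read is dropped by the filter
  tab$adaptor_ligated[1] <- NA
  expect_lt(sum(filter_reads(tab, d, 1, adaptor_only = TRUE)$transcript_id == "weak"), 14)
  tab$adaptor_ligated <- NULL
  expect_error(filter_reads(tab, d, 5, adaptor_only = TRUE), "adaptor_ligated")

  # idempotence
  once <- filter_reads(tab, d, 5)
  expect_identical(filter_reads(once, d, 5), once)
})

test_that("a high read-count threshold keeps exactly the well-covered transcripts", {
  # 5 transcripts; exactly 2 have >= 50 reads in both conditions
  per_cond <- list(t1 = c(60, 55), t2 = c(50, 50), t3 = c(49, 80),
                   t4 = c(200, 30), t5 = c(10, 10))
  spec <- lapply(per_cond, function(n) {
    list(ctrl_1 = rep(100, n[1]), case_1 = rep(95, n[2]))
  })
  tab <- table_from_spec(spec)
  out <- filter_reads(tab, toy_design(), min_reads_per_condition = 50)
  expect_setequal(unique(out$transcript_id), c("t1", "t2"))
})

test_that("average length per feature is arithmetic and order-invariant", {
  tab <- table_from_spec(list(tx = list(ctrl_1 = c(100, 200), case_1 = 300)))
  s <- average_length_per_feature(tab, toy_design(), min_reads = 1)
  expect_equal(s$mean_control, 150)
  expect_equal(s$mean_condition, 300)
  expect_equal(s$diff, 150)

  expect_equal(nrow(average_length_per_feature(tab, toy_design(), min_reads = 5)), 0)
  expect_equal(nrow(average_length_per_feature(tab[0, ], toy_design())), 0)

  sim <- simulate_scenario(simulation_scenario(n_genes = 10, reads_per_library = 15,
                                               shortening_proportion = 0.8, seed = 4))
  shuffled <- sim$table[sample(nrow(sim$table)), ]
  expect_equal(average_length_per_feature(sim$table, sim$design, 1),
               average_length_per_feature(shuffled, sim$design, 1))
})

test_that("null simulations give per-transcript mean differences centred on zero", {
  sim <- simulate_scenario(simulation_scenario(n_genes = 200, reads_per_library = 30,
                                               shortening_proportion = 1, seed = 11))
  s <- average_length_per_feature(sim$table, sim$design, min_reads = 1)
  expect_equal(nrow(s), 200)
  # SE of the mean difference across genes: 2 * (lib_sd^2/3 + resid^2/(3*30)) per gene
  se <- sqrt(2 * (100^2 / 3 + 200^2 / 90) / 200)
  expect_lt(abs(mean(s$diff)), 3 * se)
})

test_that("annotation validation and BED12 import are strand-aware", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript\tlength\tutr5_start\tutr5_end",
               "tx1\t2000\t0\t150", "tx2\t500\tNA\tNA"), path)
  ann <- load_annotation(path)
  expect_equal(ann$annotated_length, c(2000L, 500L))
  expect_true(is.na(ann$utr5_end[2]))

  writeLines(c("transcript\tlength\tutr5_start\tutr5_end",
               "tx1\t2000\t100\t50"), path)
  expect_error(load_annotation(path), "tx1")

  # plus-strand: 2 exons of 100, CDS starts 30 bases into exon 1 -> UTR 30 nt
  # minus-strand: 5' UTR is the exonic span after thickEnd -> 40 nt
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    paste("chr1", 1000, 1400, "txA", 0, "+", 1030, 1380, "0", 2,
          "100,100,", "0,300,", sep = "\t"),
    paste("chr1", 2000, 2400, "txB", 0, "-", 2050, 2360, "0", 2,
          "100,100,", "0,300,", sep = "\t")
  ), bed)
  ann2 <- annotation_from_bed12(bed)
  expect_equal(ann2$annotated_length, c(200L, 200L))
  expect_equal(ann2$utr5_end, c(30L, 40L))
  expect_equal(ann2$utr5_start, c(0L, 0L))
})
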