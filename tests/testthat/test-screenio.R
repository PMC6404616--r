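test_that("plate layout TSV round-trips byte-identically through read/write", {
  layout <- make_test_layout()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_plate_layout(layout, f1)
  layout2 <- read_plate_layout(f1)
  write_plate_layout(layout2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(nrow(layout2$positions), 96)
  expect_equal(nrow(wt_positions(layout2)), 4)
  expect_identical(layout2$positions, layout$positions)
})

test_that("layout reader rejects duplicates, unmapped wt and malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "plate_id\trow\tcol\tstrain_id\tis_wt\tdilution_step"
  writeLines(c(hdr,
               "P1\tA\t1\twt\t1\t",
               "P1\tA\t1\ts001\t0\t"), f)
  expect_error(read_plate_layout(f),
               class = "phenolscreen_duplicate_position_error")

  writeLines(c(hdr, "P1\tA\t1\ts001\t1\t"), f)  # wt flag on non-wt strain
  expect_error(read_plate_layout(f), class = "phenolscreen_layout_error")

  writeLines(c(hdr, "P1\tA\t1\twt\t1\t", "P1\tB\tnot_a_col\ts2\t0\t"), f)
  err <- expect_error(read_plate_layout(f),
                      class = "phenolscreen_parse_error")
  expect_match(conditionMessage(err), "line 3")

  expect_error(read_plate_layout(tempfile()), class = "phenolscreen_io_error")
})

test_that("A1-style labels convert both ways, including multi-letter rows", {
  expect_identical(pos_to_label(c(1, 8, 27), c(1, 12, 5)),
                   c("A1", "H12", "AA5"))
  pos <- label_to_pos(c("A1", "H12", "AA5"))
  expect_identical(pos$row, c(1L, 8L, 27L))
  expect_identical(pos$col, c(1L, 12L, 5L))
  expect_error(label_to_pos("1A"), class = "phenolscreen_parse_error")
})

test_that("GMT gene sets parse, deduplicate and round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO1\tDNA repair\tg1\tg2\tg3",
               "GO2\toxidation\tg2\tg4",
               "GO3\ttransport\tg5\tg5\tg6"), f)
  tm <- read_gene_sets(f)
  expect_length(tm, 3)
  expect_equal(lengths(lapply(tm, `[[`, "genes")),
               c(GO1 = 3L, GO2 = 2L, GO3 = 2L))
  expect_identical(tm$GO3$genes, c("g5", "g6"))  # deduplicated

  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(tm, f2)
  expect_identical(read_gene_sets(f2), tm)

  writeLines(c("GO1\tempty set"), f)
  expect_error(read_gene_sets(f), class = "phenolscreen_parse_error")
  writeLines(c("GO1\ta\tg1", "GO1\tb\tg2"), f)
  expect_error(read_gene_sets(f),
               class = "phenolscreen_duplicate_term_error")
})

test_that("results tables write with stable schema and read back equal", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(strain = character(0), gsv = numeric(0))
  write_results_table(empty, f)
  expect_length(readLines(f), 1)  # header only

  rec <- data.frame(strain = c("s1", "s2"), compound = "BHA",
                    gsv = c(0.512345678, 2.0))
  write_results_table(rec, f)
  expect_length(readLines(f), 3)
  back <- read_results_table(f)
  expect_equal(back$gsv, rec$gsv, tolerance = 1e-5)
  expect_identical(names(back), names(rec))
  expect_error(write_results_table(rec, "/nonexistent/dir/x.tsv"),
               class = "phenolscreen_io_error")
})

test_that("gene annotation validates flags and term membership", {
  flags <- data.frame(gene = c("g1", "g2"), kinase = c(1L, 0L))
  ann <- gene_annotation(c("g1", "g2", "g3"), flags = flags,
                         term_map = list(T1 = list(name = "t",
                                                   genes = c("g1", "g3"))))
  expect_s3_class(ann, "gene_annotation")
  expect_error(
    gene_annotation(c("g1"), term_map = list(T1 = list(name = "t",
                                                       genes = "gX"))),
    class = "phenolscreen_config_error")
  expect_error(
    gene_annotation(c("g1"), flags = data.frame(gene = "g1", kinase = 2)),
    class = "phenolscreen_parse_error")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_flags(flags, f)
  expect_equal(read_gene_flags(f), flags)
})

test_that("compound conditions enforce the control convention", {
  expect_error(compound_condition("CONTROL", concentration = 0.3),
               class = "phenolscreen_config_error")
  cc <- compound_condition("BHA", 0.3, solvent_fraction = 1, replicate = 2)
  expect_equal(cc$concentration, 0.3)
})
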