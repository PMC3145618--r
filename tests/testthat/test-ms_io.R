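# small in-code fixtures -----------------------------------------------------

panel_csv <- function(rows = c("MX_AC20_3,120,ACGTAC,GGTTAA",
                               "M7_AG15_1,110,AACCGG,TTGGCC",
                               "MX_GT18_2,116,AAAACC,GGGTTT")) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Name,Size,Forward primer,Reverse primer", rows), path)
  path
}

fragment_csv <- function(rows, header = "Animal ID,Sample ID,Tissue,Isolation method,MX_AC20_3,M7_AG15_1_a,M7_AG15_1_b,MX_GT18_2") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(header, rows), path)
  path
}

test_that("locus names parse under the documented grammar", {
  panel <- read_locus_panel(panel_csv())
  expect_s3_class(panel, "ms_panel")
  expect_equal(panel$chromosome, c("X", "7", "X"))
  expect_equal(panel$repeat_unit[1], "AC")
  expect_equal(panel$unit_length, c(2L, 2L, 2L))
  expect_equal(panel$reference_repeat_count, c(20L, 15L, 18L))
  expect_equal(panel$expected_allele_count, c(1L, 2L, 1L))
})

test_that("malformed and duplicate locus names are rejected; empty panel warns", {
  expect_error(read_locus_panel(panel_csv("BAD-NAME,1,a,b")), "malformed")
  expect_error(read_locus_panel(panel_csv(c("MX_AC20_3,1,a,b", "MX_AC20_3,2,a,b"))),
               "duplicate")
  empty <- tempfile(fileext = ".csv")
  writeLines("Name,Size,Forward primer,Reverse primer", empty)
  expect_warning(p <- read_locus_panel(empty), "no rows")
  expect_equal(nrow(p), 0L)
})

test_that("fragment cells parse X as missing and Null as unmeasured", {
  panel <- read_locus_panel(panel_csv())
  fr <- read_fragment_table(fragment_csv(c(
    "m1,tail1,Tail,digestion,120,110,140,116",
    "m1,s1,Colon,digestion,X,112,140,Null")), panel)
  expect_equal(fr$cells["s1", "MX_AC20_3"], "X")
  expect_equal(fr$cells["s1", "MX_GT18_2"], "Null")
  expect_equal(fr$cells["s1", "M7_AG15_1_a"], "112")
  expect_equal(nrow(fr$meta), 2L)
})

test_that("unknown locus columns and unparseable cells error", {
  panel <- read_locus_panel(panel_csv())
  expect_error(read_fragment_table(fragment_csv(
    "m1,s1,Colon,digestion,120,110,140,116",
    header = "Animal ID,Sample ID,Tissue,Isolation method,NOPE_1,M7_AG15_1_a,M7_AG15_1_b,MX_GT18_2"),
    panel), "matches no locus")
  expect_error(read_fragment_table(fragment_csv(
    "m1,s1,Colon,digestion,abc,110,140,116"), panel), "unparseable")
})

test_that("fragment tables round-trip through write and read", {
  panel <- read_locus_panel(panel_csv())
  fr <- read_fragment_table(fragment_csv(c(
    "m1,tail1,Tail,digestion,120,110,140,116",
    "m1,s1,Colon,digestion,X,112,140,Null",
    "m1,s2,Colon,laser,122,110,138,114")), panel)
  out <- tempfile(fileext = ".csv")
  write_fragment_table(fr, out)
  fr2 <- read_fragment_table(out, panel)
  expect_identical(fr$cells, fr2$cells)
  expect_identical(fr$meta, fr2$meta)
})

test_that("QC drops low-coverage samples at the strict >25 threshold", {
  # panel with 30 X loci so allele counts are easy to control
  rows <- sprintf("MX_AC%d_%d,100,aa,bb", 15:44, 1:30)
  panel <- read_locus_panel(panel_csv(rows))
  header <- paste(c("Animal ID,Sample ID,Tissue,Isolation method",
                    panel$name), collapse = ",")
  mk_row <- function(id, n_meas) paste(c("m1", id, "Colon", "digestion",
    rep("100", n_meas), rep("X", 30 - n_meas)), collapse = ",")
  fr <- read_fragment_table(fragment_csv(c(mk_row("s25", 25), mk_row("s26", 26)),
                                         header = header), panel)
  filt <- qc_filter(fr, panel)
  expect_false("s25" %in% rownames(filt$cells))  # 25 alleles: dropped
  expect_true("s26" %in% rownames(filt$cells))   # 26 alleles: kept
  rep <- attr(filt, "qc_report")
  expect_true(any(grepl("low_allele_count", rep$reason)))
})

test_that("QC removes loci with more alleles than expected and negative-control loci", {
  panel <- read_locus_panel(panel_csv())
  fr <- read_fragment_table(fragment_csv(c(
    "m1,s1,Colon,digestion,120/124,110,140,116",   # two peaks at an X locus
    "m1,s2,Colon,digestion,120,110,140,116")), panel)
  filt <- qc_filter(fr, panel, min_alleles = 1L)
  expect_equal(filt$cells["s1", "MX_AC20_3"], "X")
  expect_equal(filt$cells["s2", "MX_AC20_3"], "120")
  filt2 <- qc_filter(fr, panel, negative_control_loci = "MX_GT18_2",
                     min_alleles = 1L)
  expect_true(all(filt2$cells[, "MX_GT18_2"] == "Null"))
})

test_that("QC is idempotent and empty control set removes nothing extra", {
  panel <- read_locus_panel(panel_csv())
  fr <- read_fragment_table(fragment_csv(c(
    "m1,s1,Colon,digestion,120/124,110,140,116",
    "m1,s2,Colon,digestion,120,110,140,116")), panel)
  once <- qc_filter(fr, panel, min_alleles = 1L)
  twice <- qc_filter(once, panel, min_alleles = 1L)
  expect_identical(once$cells, twice$cells)
  expect_identical(once$meta, twice$meta)
})

test_that("root signature is the per-channel median of tail samples", {
  panel <- read_locus_panel(panel_csv())
  fr <- read_fragment_table(fragment_csv(c(
    "m1,t1,Tail,digestion,200,110,140,116",
    "m1,t2,Tail,digestion,200,110,140,116",
    "m1,t3,Tail,digestion,202,112,138,116")), panel)
  root <- root_signature(fr, panel)
  expect_equal(unclass(root)[["MX_AC20_3"]], 200)
  # alleles are sorted per sample, so _a is the smaller size
  expect_equal(unclass(root)[["M7_AG15_1_a"]], 110)
  expect_equal(unclass(root)[["M7_AG15_1_b"]], 140)
})

test_that("a channel measured in no tail sample is excluded with a warning", {
  panel <- read_locus_panel(panel_csv())
  fr <- read_fragment_table(fragment_csv(
    "m1,t1,Tail,digestion,200,110,140,X"), panel)
  expect_warning(root <- root_signature(fr, panel), "MX_GT18_2")
  expect_false("MX_GT18_2" %in% names(root))
})

test_that("signatures are integer deviations; self-root gives all zeros", {
  panel <- read_locus_panel(panel_csv())
  fr <- read_fragment_table(fragment_csv(c(
    "m1,t1,Tail,digestion,200,110,140,116",
    "m1,s1,Colon,digestion,204,110,142,112")), panel)
  root <- root_signature(structure(list(
    meta = fr$meta[1, , drop = FALSE], cells = fr$cells["t1", , drop = FALSE],
    channels = fr$channels), class = "ms_fragments"), panel)
  sig <- compute_signatures(fr, root, panel)
  expect_true(all(sig["t1", ] == 0L))                 # own sizes => zero
  expect_equal(unname(sig["s1", "MX_AC20_3"]), 2L)  # (204-200)/2
  expect_equal(unname(sig["s1", "MX_GT18_2"]), -2L)
  expect_true(all(sig == round(sig), na.rm = TRUE))
})

test_that("two-allele pairing minimizes total absolute deviation", {
  panel <- read_locus_panel(panel_csv("M7_AG15_1,110,a,b"))
  header <- "Animal ID,Sample ID,Tissue,Isolation method,M7_AG15_1_a,M7_AG15_1_b"
  fr <- read_fragment_table(fragment_csv(c(
    "m1,t1,Tail,digestion,200,202",
    "m1,s1,Colon,digestion,198,204"), header = header), panel)
  root <- root_signature(structure(list(
    meta = fr$meta[1, , drop = FALSE], cells = fr$cells["t1", , drop = FALSE],
    channels = fr$channels), class = "ms_fragments"), panel)
  sig <- compute_signatures(fr, root, panel)
  # {198,204} vs root {200,202}: sorted pairing gives (-1,+1), total 2;
  # the swap gives (+2,-2), total 4 -- so (-1,+1) must win
  expect_equal(unname(sig["s1", ]), c(-1L, 1L))
})

test_that("non-integer repeat deviations beyond tolerance are excluded", {
  panel <- read_locus_panel(panel_csv("MX_AC20_3,120,a,b"))
  header <- "Animal ID,Sample ID,Tissue,Isolation method,MX_AC20_3"
  fr <- read_fragment_table(fragment_csv(c(
    "m1,t1,Tail,digestion,200",
    "m1,s1,Colon,digestion,201"), header = header), panel)  # 0.5-unit shift
  root <- root_signature(structure(list(
    meta = fr$meta[1, , drop = FALSE], cells = fr$cells["t1", , drop = FALSE],
    channels = fr$channels), class = "ms_fragments"), panel)
  sig <- compute_signatures(fr, root, panel)
  expect_true(is.na(sig["s1", "MX_AC20_3"]))
})
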