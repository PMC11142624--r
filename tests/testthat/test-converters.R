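write_rmats_se <- function(path, rows) {
  header <- c("GeneID", "geneSymbol", "chr", "strand", "exonStart_0base",
              "exonEnd", "upstreamES", "upstreamEE", "downstreamES",
              "downstreamEE", "PValue", "FDR", "IncLevelDifference")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

test_that("rMATS 0-based starts convert and stats map onto the event", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_rmats_se(path, list(
    c("ENSG1", "GENE1", "chr1", "+", "1199", "1300", "900", "1000", "1500",
      "1600", "0.01", "0.02", "0.25")))
  res <- parse_rmats(path, "SE")
  expect_equal(res$report$n_input, 1L)
  expect_equal(res$report$n_converted, 1L)
  ev <- res$events[[1]]
  expect_identical(encode_event_id(ev), "GENE1|SE|chr1|+|1000:1200:1300:1500")
  expect_equal(ev$stats$p_value, 0.01)
  expect_equal(ev$stats$fdr, 0.02)
  expect_equal(ev$stats$dpsi, 0.25)
})

test_that("duplicate rMATS rows collapse and the report accounts for them", {
  path <- withr::local_tempfile(fileext = ".txt")
  row <- c("ENSG1", "GENE1", "chr1", "+", "1199", "1300", "900", "1000",
           "1500", "1600", "0.01", "0.02", "0.25")
  write_rmats_se(path, list(row, row))
  res <- parse_rmats(path, "SE")
  expect_length(res$events, 1L)
  expect_equal(res$report$n_converted, 1L)
  expect_equal(res$report$n_duplicates, 1L)
  expect_equal(res$report$n_input,
               res$report$n_converted + res$report$n_duplicates +
                 res$report$n_failed)
})

test_that("schema and row-level failures are distinguished", {
  # missing required column -> schema error naming it
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("GeneID\tgeneSymbol\tchr\tstrand\texonStart_0base\texonEnd\tupstreamES\tupstreamEE\tdownstreamES\tdownstreamEE\tPValue\tFDR",
               "ENSG1\tG1\tchr1\t+\t1199\t1300\t900\t1000\t1500\t1600\t0.1\t0.2"),
             path)
  expect_error(parse_rmats(path, "SE"), "IncLevelDifference")

  # non-numeric coordinate -> row failure recorded, conversion continues
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_rmats_se(path2, list(
    c("E1", "G1", "chr1", "+", "xx", "1300", "900", "1000", "1500", "1600",
      "0.1", "0.2", "0.0"),
    c("E2", "G2", "chr1", "+", "1199", "1300", "900", "1000", "1500", "1600",
      "0.1", "0.2", "0.0")))
  res <- parse_rmats(path2, "SE")
  expect_equal(res$report$n_failed, 1L)
  expect_equal(res$report$n_converted, 1L)
  expect_match(res$report$failures$reason[1], "exonStart_0base")

  # unparseable statistics keep the event with absent stats
  path3 <- withr::local_tempfile(fileext = ".txt")
  write_rmats_se(path3, list(
    c("E1", "G1", "chr1", "+", "1199", "1300", "900", "1000", "1500", "1600",
      "NA", "NA", "notanumber")))
  res3 <- parse_rmats(path3, "SE")
  expect_equal(res3$report$n_converted, 1L)
  expect_true(is.na(res3$events[[1]]$stats$dpsi))
})

test_that("SUPPA events decode to the same canonical IDs as their rMATS twins", {
  path <- withr::local_tempfile(fileext = ".dpsi")
  writeLines(c("event_id\tdPSI\tp-val",
               "GENE1;SE:chr1:1000-1200:1300-1500:+\t0.25\t0.01",
               "GENE2;XX:chr1:1-2:3-4:+\t0\t0.5"), path)
  res <- parse_suppa(path)
  expect_equal(res$report$n_converted, 1L)
  expect_equal(res$report$n_failed, 1L)
  expect_match(res$report$failures$reason[1], "XX")
  expect_identical(encode_event_id(res$events[[1]]),
                   "GENE1|SE|chr1|+|1000:1200:1300:1500")
  expect_equal(res$events[[1]]$stats$dpsi, 0.25)

  # negative-strand A5SS expressed in both dialects
  rm_path <- withr::local_tempfile(fileext = ".txt")
  header <- c("GeneID", "geneSymbol", "chr", "strand", "longExonStart_0base",
              "longExonEnd", "shortES", "shortEE", "flankingES", "flankingEE",
              "PValue", "FDR", "IncLevelDifference")
  writeLines(c(paste(header, collapse = "\t"),
               paste(c("E", "GENEN", "chr2", "-", "2099", "2300", "2160",
                       "2300", "1900", "2000", "0.3", "0.4", "0.0"),
                     collapse = "\t")), rm_path)
  rm_ev <- parse_rmats(rm_path, "A5SS")$events[[1]]

  sp_path <- withr::local_tempfile(fileext = ".dpsi")
  writeLines(c("event_id\tdPSI\tp-val",
               "GENEN;A5:chr2:2000-2100:2000-2160:-\t0.0\t0.3"), sp_path)
  sp_ev <- parse_suppa(sp_path)$events[[1]]
  expect_identical(encode_event_id(rm_ev), encode_event_id(sp_ev))
})

test_that("spliceR-style isoform pairs convert through the catalog", {
  g <- make_truth_gene("GS", "SE", "+", 2000L)
  ann <- tx_annotation(list(g$tx1, g$tx2))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("isoform_a\tisoform_b\tp_value\tfdr\tdpsi",
               "GS.a\tGS.b\t0.002\t0.01\t-0.4",
               "GS.a\tGS.a\t0.9\t0.9\t0.0",
               "GS.a\tMISSING\t0.5\t0.5\t0.1"), path)
  res <- parse_splicer(path, ann)
  expect_equal(res$report$n_input, 3L)
  expect_equal(res$report$n_failed, 1L)
  expect_match(res$report$failures$reason[1], "unknown isoform")
  expect_equal(res$report$n_converted, 2L)  # one event + one converted-empty
  expect_length(res$events, 1L)
  expect_identical(encode_event_id(res$events[[1]]), g$expected_id)
  expect_equal(res$events[[1]]$stats$dpsi, -0.4)
})

test_that("a pair spanning two differences emits both events with shared stats", {
  # SE at exon 3 plus an A3SS shift at exon 5
  exa <- data.frame(start = c(1000, 2000, 3000, 4000, 5000),
                    end = c(1100, 2100, 3100, 4100, 5100))
  exb <- exa[-3, ]
  exb$start[exb$start == 5000] <- 4950
  ta <- transcript("D.a", "GD", "chr1", "+", exa)
  tb <- transcript("D.b", "GD", "chr1", "+", exb)
  ann <- tx_annotation(list(ta, tb))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("isoform_a\tisoform_b\tp_value\tfdr\tdpsi",
               "D.a\tD.b\t0.004\t0.02\t0.33"), path)
  res <- parse_splicer(path, ann)
  expect_length(res$events, 2L)
  types <- sort(vapply(res$events, `[[`, character(1), "event_type"))
  expect_identical(types, c("A3SS", "SE"))
  for (ev in res$events) expect_equal(ev$stats$dpsi, 0.33)
})

test_that("the generic dialect and the conversion report handle edge inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ttype\tchrom\tstrand\tc1\tc2\tc3\tc4\tc5\tc6\tp_value\tfdr\tdpsi",
               "G1\tSE\tchr1\t+\t1000\t1200\t1300\t1500\t\t\t0.01\t0.05\t0.2",
               "G2\tAF\tchr1\t+\t100\t200\t300\t400\t900\t\t0.5\t0.6\t0.0"),
             path)
  res <- parse_generic(path)
  expect_equal(res$report$n_converted, 2L)
  expect_identical(encode_event_id(res$events[[1]]),
                   "G1|SE|chr1|+|1000:1200:1300:1500")
  expect_identical(res$events[[2]]$event_type, "AF")

  # empty file: header only, accounting identity holds
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\ttype\tchrom\tstrand\tc1\tc2\tc3\tc4\tc5\tc6\tp_value\tfdr\tdpsi",
             empty)
  res0 <- parse_generic(empty)
  expect_equal(res0$report$n_input, 0L)
  expect_equal(res0$report$n_converted + res0$report$n_duplicates +
                 res0$report$n_failed, 0L)
})

test_that("all dialects of the planted fixture agree byte-for-byte on IDs", {
  fx <- fixture_cache()
  gen <- parse_generic(fx$das_paths$generic)
  sup <- parse_suppa(fx$das_paths$suppa)
  spl <- parse_splicer(fx$das_paths$splicer, fx$annotation)
  ids <- function(res) sort(vapply(res$events, encode_event_id, character(1)))
  expect_identical(ids(gen), sort(fx$truth$event_id))
  expect_identical(ids(sup), ids(gen))
  expect_identical(ids(spl), ids(gen))
  rm_ids <- character()
  for (type in names(fx$das_paths$rmats)) {
    res <- parse_rmats(fx$das_paths$rmats[[type]], type)
    expect_equal(res$report$n_failed, 0L)
    rm_ids <- c(rm_ids, vapply(res$events, encode_event_id, character(1)))
  }
  in_rmats <- fx$truth$event_type %in% c("SE", "MXE", "RI", "A5SS", "A3SS")
  expect_identical(sort(rm_ids), sort(fx$truth$event_id[in_rmats]))
})

test_that("significance filtering is explicit, not baked into parsing", {
  fx <- fixture_cache()
  res <- parse_generic(fx$das_paths$generic)
  kept <- filter_events(res$events, p_max = 0.05, dpsi_min = 0.1)
  expect_equal(length(kept), sum(fx$truth$p_value < 0.05 &
                                   abs(fx$truth$dpsi) > 0.1))
  expect_length(filter_events(res$events, p_max = 0, dpsi_min = 1), 0L)
})
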