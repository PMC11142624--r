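write_bed_lines <- function(df, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", df$chrom, df$start - 1L, df$end,
                     df$name), path)
  path
}

small_annotation <- function() {
  tx_annotation(list(
    transcript("T1", "G1", "chr1", "+",
               data.frame(start = c(1001, 2001), end = c(1100, 2100)),
               cds = data.frame(start = c(1001, 2001), end = c(1100, 2099))),
    transcript("T2", "G1", "chr1", "+",
               data.frame(start = c(1001, 2001), end = c(1100, 2100)))))
}

test_that("inclusive overlap semantics: single-base touch counts", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed_lines(data.frame(chrom = "chr1", start = 100, end = 200,
                             name = "cons1"), bed)
  db <- build_db(small_annotation(), list(CONS = bed))
  expect_equal(nrow(query_interval(db, "chr1", 200, 300)), 1L)
  expect_equal(nrow(query_interval(db, "chr1", 201, 300)), 0L)
  expect_equal(nrow(query_interval(db, "chr2", 100, 200)), 0L)
  expect_error(query_interval(db, "chr1", 300, 200), "start > end")
  expect_error(query_interval(db, "chr1", 1, 10, classes = "NOPE"),
               "unknown genomic class")
})

test_that("an empty track set yields a gene-model-only store", {
  db <- build_db(small_annotation(), list())
  expect_equal(nrow(query_interval(db, "chr1", 1, 1e6)), 0L)
  expect_equal(nrow(query_isoform_features(db, "T1")), 0L)
  expect_equal(sum(unlist(db$build$counts)), 0L)
  expect_error(build_db(small_annotation(), list(CONS = "/nope.bed")),
               "unreadable track")
  expect_error(build_db(small_annotation(), list(WHAT = "x")),
               "unknown feature class")
})

test_that("interval queries equal the brute-force scan on random instances", {
  set.seed(31)
  n <- 400L
  rec <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = sample(1:5000, n, replace = TRUE),
                    name = sprintf("f%03d", seq_len(n)))
  rec$end <- rec$start + sample(0:300, n, replace = TRUE)
  beds <- list(
    CONS = write_bed_lines(rec[1:200, ], withr::local_tempfile(fileext = ".bed")),
    RBP_BS = write_bed_lines(rec[201:400, ], withr::local_tempfile(fileext = ".bed")))
  db <- build_db(small_annotation(), beds)
  records <- rbind(cbind(rec[1:200, ], class = "CONS"),
                   cbind(rec[201:400, ], class = "RBP_BS"))
  for (q in 1:60) {
    chrom <- sample(c("chr1", "chr2"), 1L)
    s <- sample(1:5200, 1L); e <- s + sample(0:400, 1L)
    classes <- sample(list("CONS", "RBP_BS", c("CONS", "RBP_BS")), 1L)[[1L]]
    got <- query_interval(db, chrom, s, e, classes)
    want <- brute_force_query(records, chrom, s, e, classes)
    expect_setequal(sprintf("%s:%d-%d:%s", got$class, got$start, got$end, got$name),
                    sprintf("%s:%d-%d:%s", want$class, want$start, want$end, want$name))
  }
})

test_that("rebuilding from identical inputs answers identically and persists", {
  fx <- fixture_cache()
  db1 <- build_db(fx$gtf, fx$tracks)
  db2 <- build_db(fx$gtf, fx$tracks)
  set.seed(5)
  for (i in 1:50) {
    chrom <- sample(paste0("chr", 1:4), 1L)
    s <- sample(1:120000, 1L); e <- s + sample(0:5000, 1L)
    expect_identical(query_interval(db1, chrom, s, e),
                     query_interval(db2, chrom, s, e))
  }
  path <- withr::local_tempfile(fileext = ".rds")
  save_feature_db(db1, path)
  db3 <- load_feature_db(path)
  expect_identical(db3$genomic, db1$genomic)
  expect_identical(db3$isoform, db1$isoform)
})

test_that("isoform feature retrieval is exact-match and deduplicated", {
  ppi <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx_id\tpartner", "T1\tPARTNER_A", "T1\tPARTNER_A",
               "T2\tPARTNER_B"), ppi)
  db <- build_db(small_annotation(), list(PPI = ppi))
  hit <- query_isoform_features(db, "T1", classes = "PPI")
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$partner, "PARTNER_A")
  expect_equal(nrow(query_isoform_features(db, "T3", classes = "PPI")), 0L)
  expect_error(query_isoform_features(db, "T1", classes = "CONS"),
               "unknown isoform class")
})

test_that("protein records whose isoform lacks CDS are skipped with a warning", {
  dom <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx_id\taa_start\taa_end\tname",
               "T1\t1\t10\tDOM_OK", "T2\t1\t10\tDOM_NO_CDS"), dom)
  expect_warning(db <- build_db(small_annotation(), list(DOMAIN = dom)),
                 "lacks CDS")
  expect_equal(db$build$counts$DOMAIN, 1L)
  expect_equal(db$build$n_skipped_no_cds, 1L)
})

test_that("protein-to-genome projection follows the CDS arithmetic", {
  ann <- tx_annotation(list(
    transcript("P1", "GP", "chr1", "+",
               data.frame(start = 1001, end = 1300),
               cds = data.frame(start = 1001, end = 1300)),
    transcript("P2", "GP2", "chr1", "+",
               data.frame(start = c(1001, 2001), end = c(1004, 2100)),
               cds = data.frame(start = c(1001, 2001), end = c(1004, 2099))),
    transcript("P3", "GP3", "chr1", "-",
               data.frame(start = c(1001, 2001), end = c(1100, 2100)),
               cds = data.frame(start = c(1002, 2001), end = c(1100, 2100)))))
  # single-exon CDS, aa 1..2 -> first six coding bases
  seg <- project_protein_to_genome(ann, "P1", 1, 2)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(1001, 1006))
  # codon 2 spans the exon junction: 4 nt in exon1, then exon2
  seg2 <- project_protein_to_genome(ann, "P2", 2, 2)
  expect_equal(nrow(seg2), 2L)
  expect_equal(sum(seg2$end - seg2$start + 1), 3)
  expect_equal(seg2$start[1], 1004)  # last base of exon 1
  expect_equal(c(seg2$start[2], seg2$end[2]), c(2001, 2002))
  # minus strand: aa 1 = last three coding bases in genomic order
  seg3 <- project_protein_to_genome(ann, "P3", 1, 1)
  expect_equal(c(seg3$start, seg3$end), c(2098, 2100))
  # errors
  expect_error(project_protein_to_genome(ann, "P1", 1, 1000), "outside protein")
  ann2 <- tx_annotation(list(transcript("N1", "GN", "chr1", "+",
                                        data.frame(start = 1, end = 99))))
  expect_error(project_protein_to_genome(ann2, "N1", 1, 1), "no CDS")
  expect_error(project_protein_to_genome(ann, "NOPE", 1, 1), "unknown isoform")
})

test_that("projection conserves length on randomized CDS structures", {
  set.seed(41)
  for (rep in 1:50) {
    n_ex <- sample(2:4, 1L)
    widths <- sample(30:90, n_ex, replace = TRUE)
    starts <- cumsum(c(1000L, widths[-n_ex] + sample(100:300, n_ex - 1L,
                                                     replace = TRUE)))
    ex <- data.frame(start = starts, end = starts + widths - 1L)
    total <- sum(widths)
    usable <- total - total %% 3L
    strand <- sample(c("+", "-"), 1L)
    # CDS = first `usable` exonic bases (genomic order), trimmed per strand
    cds <- ex
    extra <- total - usable
    if (extra > 0) {
      if (strand == "+") cds$end[n_ex] <- cds$end[n_ex] - extra
      else cds$start[1L] <- cds$start[1L] + extra
    }
    tx <- transcript("R1", "GR", "chr1", strand, ex, cds = cds)
    ann <- tx_annotation(list(tx))
    prot_len <- usable %/% 3L
    a <- sample(seq_len(prot_len), 1L)
    b <- sample(a:prot_len, 1L)
    seg <- project_protein_to_genome(ann, "R1", a, b)
    expect_equal(sum(seg$end - seg$start + 1), 3 * (b - a + 1))
    expect_true(all(seg$start <= seg$end))
  }
})
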