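# one SE gene with hand-placed features per rule region
annotator_setup <- function(tracks = list()) {
  g <- make_truth_gene("GA", "SE", "+", 10000L)
  ex1 <- g$tx1$exons; ex2 <- g$tx2$exons
  mkcds <- function(ex) {
    lo <- ex$start[2] + 9L; hi <- ex$start[nrow(ex)] + 20L
    segs <- ex[ex$end >= lo & ex$start <= hi, ]
    segs$start <- pmax(segs$start, lo); segs$end <- pmin(segs$end, hi)
    extra <- sum(segs$end - segs$start + 1L) %% 3L
    segs$end[nrow(segs)] <- segs$end[nrow(segs)] - extra
    segs
  }
  tx1 <- transcript("GA.a", "GA", "chr9", "+", ex1, cds = mkcds(ex1))
  tx2 <- transcript("GA.b", "GA", "chr9", "+", ex2, cds = mkcds(ex2))
  ann <- tx_annotation(list(tx1, tx2))
  ev <- classify_transcript_pair(tx1, tx2)$events[[1]]
  db <- build_db(ann, tracks)
  list(ev = ev, ann = ann, db = db, tx1 = tx1, tx2 = tx2)
}

test_that("mutations hit inside distinct+boundary windows only", {
  s <- annotator_setup()
  d <- decompose_regions(s$ev, w = 10)$distinct
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("chr9\t%d\tacceptor_minus5\tA\tG\t.\tPASS\t.", d$start - 5L),
               sprintf("chr9\t%d\tdeep_intronic\tA\tG\t.\tPASS\t.", d$start - 50L)),
             vcf)
  db <- build_db(s$ann, list(MUT = vcf))
  row <- annotate_event(s$ev, db, w = 10)
  expect_match(row$mutation, "acceptor_minus5")
  expect_false(grepl("deep_intronic", row$mutation))
})

test_that("domains require distinct-exon overlap after genome projection", {
  s <- annotator_setup()
  d <- decompose_regions(s$ev, w = 10)$distinct
  aa_in <- asannot:::genome_span_to_protein(s$tx1, d$start, d$end)
  # an aa span confined to the upstream common exon (exon 2)
  ex2 <- s$tx1$exons[2, ]
  aa_common <- asannot:::genome_span_to_protein(s$tx1, ex2$start + 12L,
                                                ex2$start + 21L)
  dom <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx_id\taa_start\taa_end\tname",
               sprintf("GA.a\t%d\t%d\tDOM_IN", aa_in[1], aa_in[2]),
               sprintf("GA.a\t%d\t%d\tDOM_COMMON", aa_common[1], aa_common[2])),
             dom)
  db <- build_db(s$ann, list(DOMAIN = dom))
  row <- annotate_event(s$ev, db, w = 10)
  expect_match(row$domain, "DOM_IN")
  expect_false(grepl("DOM_COMMON", row$domain))
  expect_match(row$domain_genomic, "chr9:")
})

test_that("RBP sites honour intron inclusion and common-region exclusion", {
  s <- annotator_setup()
  r <- decompose_regions(s$ev, w = 10)
  intron <- r$flanking_introns[1, ]
  cc <- s$ev$coords
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(sprintf("chr9\t%d\t%d\trbp_intron\t0\t+",
                       intron$start + 49L, intron$start + 60L),
               # fully inside the downstream common exon
               sprintf("chr9\t%d\t%d\trbp_common\t0\t+", cc[4] + 9L, cc[4] + 30L),
               # straddles the upstream common anchor into the intron
               sprintf("chr9\t%d\t%d\trbp_straddle\t0\t+", cc[1] - 6L, cc[1] + 5L)),
             bed)
  db <- build_db(s$ann, list(RBP_BS = bed))
  row <- annotate_event(s$ev, db, w = 10)
  expect_match(row$rbp_bs, "rbp_intron")
  expect_match(row$rbp_bs, "rbp_straddle")  # residual intronic overlap >= 1 bp
  expect_false(grepl("rbp_common", row$rbp_bs))
})

test_that("the NMD 50-nt rule matches a per-base transcript-walk oracle", {
  set.seed(53)
  checked_edges <- c(FALSE, FALSE)
  for (rep in 1:120) {
    d <- if (rep <= 4) c(50L, 51L, 50L, 51L)[rep] else
      sample(-40:120, 1L)  # includes stops inside the last exon (d < 0)
    n_exons <- sample(2:5, 1L)
    widths <- sample(60:200, n_exons, replace = TRUE)
    strand <- sample(c("+", "-"), 1L)
    tx <- make_nmd_transcript(sprintf("N%03d", rep), n_exons, widths, d,
                              strand)
    if (is.null(tx)) next
    if (d == 50L) checked_edges[1] <- TRUE
    if (d == 51L) checked_edges[2] <- TRUE
    expect_identical(tx_nmd_status(tx), d > 50L,
                     info = sprintf("d=%d strand=%s n=%d", d, strand, n_exons))
  }
  expect_true(all(checked_edges))
  # no CDS -> NA; single exon -> never sensitive
  bare <- transcript("B", "G", "chr1", "+", data.frame(start = 1, end = 300))
  expect_true(is.na(tx_nmd_status(bare)))
  mono <- transcript("M", "G", "chr1", "+", data.frame(start = 1, end = 300),
                     cds = data.frame(start = 10, end = 108))
  expect_false(tx_nmd_status(mono))
})

test_that("call_nmd reports per-side status with unknown for CDS-less sides", {
  g <- make_truth_gene("GN", "SE", "+", 30000L)  # transcripts without CDS
  ann <- tx_annotation(list(g$tx1, g$tx2))
  ev <- classify_transcript_pair(g$tx1, g$tx2)$events[[1]]
  expect_identical(unname(call_nmd(ev, ann)), c("unknown", "unknown"))

  s <- annotator_setup()
  nmd <- call_nmd(s$ev, s$ann)
  expect_true(all(nmd %in% c("sensitive", "not_sensitive")))
  # fixture CDS ends inside the last exon on both isoforms
  expect_identical(unname(nmd), c("not_sensitive", "not_sensitive"))
})

test_that("PPI edges partition into inclusion-specific, exclusion-specific and shared", {
  s <- annotator_setup()
  ppi <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx_id\tpartner",
               "GA.a\tONLY_INC", "GA.b\tONLY_EXC",
               "GA.a\tBOTH", "GA.b\tBOTH"), ppi)
  db <- build_db(s$ann, list(PPI = ppi))
  res <- assign_isoform_ppi(s$ev, db)
  expect_identical(res$inclusion$partner, "ONLY_INC")
  expect_identical(res$exclusion$partner, "ONLY_EXC")
  expect_setequal(res$shared$partner, "BOTH")

  empty_db <- build_db(s$ann, list())
  res0 <- assign_isoform_ppi(s$ev, empty_db)
  expect_equal(nrow(res0$inclusion) + nrow(res0$exclusion) + nrow(res0$shared), 0L)
})

test_that("the table schema is fixed at 23 columns regardless of content", {
  empty <- assemble_table(list())
  expect_equal(ncol(empty), 23L)
  expect_identical(names(empty), ANNOTATION_COLUMNS)
  expect_equal(nrow(empty), 0L)

  s <- annotator_setup()
  tbl <- annotate_events(list(s$ev), s$db)
  expect_equal(ncol(tbl), 23L)
  expect_identical(names(tbl), ANNOTATION_COLUMNS)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(tbl, csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(ncol(back), 23L)
})

test_that("a fully planted event populates exactly the twelve class columns", {
  spec <- fixture_spec(seed = 99, n_genes = 8,
                       feature_density = c(CONS = 1, MUT = 1, REPEAT = 1,
                                           MIRNA_BS = 1, RBP_BS = 1,
                                           EXON_USAGE = 1, DOMAIN = 1,
                                           PTM = 1, PPI = 1,
                                           LOCALIZATION = 1,
                                           SPLICE_SITE_VARIANT = 1))
  fx <- simulate_fixture(spec, withr::local_tempdir())
  db <- build_db(fx$gtf, fx$tracks)
  tbl <- annotate_events(lapply(fx$truth$event_id, decode_event_id), db)
  pres <- class_presence(tbl)
  # at least one event with codeable distinct region hits all 12 classes
  expect_true(any(rowSums(pres) == 12L))
  # and every event matches its own ledger expectation exactly
  led <- fx$ledger
  obs <- mapply(function(e, cl) pres[e, cl], led$event_id, led$class)
  expect_identical(unname(obs), led$expected)
})

test_that("annotation is monotone in the database", {
  fx <- fixture_cache()
  events <- lapply(fx$truth$event_id[1:8], decode_event_id)
  some <- fx$tracks[intersect(names(fx$tracks), c("CONS", "MUT", "PPI"))]
  db_small <- build_db(fx$gtf, some)
  db_full <- build_db(fx$gtf, fx$tracks)
  p_small <- class_presence(annotate_events(events, db_small))
  p_full <- class_presence(annotate_events(events, db_full))
  expect_true(all(p_full[p_small]))  # nothing populated disappears
})

test_that("an incomplete rule table is rejected", {
  s <- annotator_setup()
  rules <- default_region_rules()
  expect_error(annotate_event(s$ev, s$db, rules = rules[-1, ]),
               "exactly once")
})
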