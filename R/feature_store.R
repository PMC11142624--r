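#' The twelve sequence-feature class codes
#'
#' DNA level: `CONS` (conservation), `MUT` (point mutations), `REPEAT`;
#' RNA level: `MIRNA_BS` (miRNA binding sites), `NMD` (nonsense-mediated
#' decay, derived), `RBP_BS` (RNA-binding-protein / splicing-factor sites),
#' `EXON_USAGE` (cross-sample exon usage); protein level: `DOMAIN`, `PTM`,
#' `PPI`, `LOCALIZATION`; plus `SPLICE_SITE_VARIANT` (splicing-inducing
#' point mutations at splice-site boundaries).
#'
#' @export
FEATURE_CLASSES <- c("CONS", "MUT", "REPEAT", "MIRNA_BS", "NMD", "RBP_BS",
                     "EXON_USAGE", "DOMAIN", "PTM", "PPI", "LOCALIZATION",
                     "SPLICE_SITE_VARIANT")

GENOMIC_CLASSES <- c("CONS", "MUT", "REPEAT", "MIRNA_BS", "RBP_BS",
                     "EXON_USAGE", "SPLICE_SITE_VARIANT")
ISOFORM_CLASSES <- c("DOMAIN", "PTM", "PPI", "LOCALIZATION")

empty_genomic_records <- function() {
  data.frame(class = character(), chrom = character(), start = integer(),
             end = integer(), name = character(), source = character(),
             score = numeric(), payload = character(),
             stringsAsFactors = FALSE)
}

empty_isoform_records <- function() {
  data.frame(class = character(), tx_id = character(), aa_start = integer(),
             aa_end = integer(), partner = character(), name = character(),
             source = character(), payload = character(),
             stringsAsFactors = FALSE)
}

read_bed_track <- function(path, class, source = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  n <- length(gr)
  if (n == 0L) return(empty_genomic_records())
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, n)
  sc <- if (!is.null(gr$score)) as.numeric(gr$score) else rep(NA_real_, n)
  data.frame(class = class,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = nm, source = source, score = sc,
             payload = NA_character_, stringsAsFactors = FALSE)
}

read_vcf_track <- function(path, class, source = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fx) == 0L) return(empty_genomic_records())
  pos <- as.integer(fx$POS)
  change <- paste0(fx$REF, ">", fx$ALT)
  id <- as.character(fx$ID)
  nm <- ifelse(is.na(id) | id == ".", change, id)
  data.frame(class = class, chrom = as.character(fx$CHROM),
             start = pos, end = pos, name = nm, source = source,
             score = NA_real_, payload = change, stringsAsFactors = FALSE)
}

read_exon_usage_track <- function(path, source = basename(path)) {
  df <- read_tsv_checked(path, c("chrom", "start", "end"), "exon usage track")
  if (nrow(df) == 0L) return(empty_genomic_records())
  sample_cols <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  payload <- vapply(seq_len(nrow(df)), function(i)
    paste(sprintf("%s=%s", sample_cols, unlist(df[i, sample_cols])),
          collapse = ","), character(1))
  data.frame(class = "EXON_USAGE", chrom = as.character(df$chrom),
             start = as.integer(df$start), end = as.integer(df$end),
             name = "psi", source = source, score = NA_real_,
             payload = payload, stringsAsFactors = FALSE)
}

read_protein_span_track <- function(path, class, source = basename(path)) {
  df <- read_tsv_checked(path, c("tx_id", "aa_start", "aa_end", "name"),
                         sprintf("%s track", class))
  if (nrow(df) == 0L) return(empty_isoform_records())
  data.frame(class = class, tx_id = as.character(df$tx_id),
             aa_start = as.integer(df$aa_start), aa_end = as.integer(df$aa_end),
             partner = NA_character_, name = as.character(df$name),
             source = source, payload = NA_character_,
             stringsAsFactors = FALSE)
}

read_ppi_track <- function(path, source = basename(path)) {
  df <- read_tsv_checked(path, c("tx_id", "partner"), "PPI track")
  if (nrow(df) == 0L) return(empty_isoform_records())
  data.frame(class = "PPI", tx_id = as.character(df$tx_id),
             aa_start = NA_integer_, aa_end = NA_integer_,
             partner = as.character(df$partner), name = NA_character_,
             source = source, payload = NA_character_,
             stringsAsFactors = FALSE)
}

read_localization_track <- function(path, source = basename(path)) {
  df <- read_tsv_checked(path, c("tx_id", "compartment"), "localization track")
  if (nrow(df) == 0L) return(empty_isoform_records())
  data.frame(class = "LOCALIZATION", tx_id = as.character(df$tx_id),
             aa_start = NA_integer_, aa_end = NA_integer_,
             partner = NA_character_, name = as.character(df$compartment),
             source = source, payload = NA_character_,
             stringsAsFactors = FALSE)
}

#' Build a local feature database from annotation and feature tracks
#'
#' Assembles the gene model plus any subset of the twelve feature classes
#' into a single queryable store with a per-chromosome interval index.
#' Rebuilding from identical inputs yields identical query answers; query
#' results are independent of track insertion order (records are sorted on
#' their full key).
#'
#' Track formats by class: BED for `CONS`/`REPEAT`/`MIRNA_BS`/`RBP_BS`;
#' VCF (v4.x site records; genotypes ignored) for
#' `MUT`/`SPLICE_SITE_VARIANT`; TSV for `EXON_USAGE`
#' (chrom/start/end + one column per sample holding PSI), `DOMAIN`/`PTM`
#' (tx_id/aa_start/aa_end/name, protein coordinates), `PPI`
#' (tx_id/partner) and `LOCALIZATION` (tx_id/compartment).
#'
#' @param annotation a [tx_annotation()] or a GTF file path
#' @param tracks named list mapping class codes to file paths
#' @param out_path optional path; when given, the store is persisted there
#'   as a single file (readable with [load_feature_db()])
#' @param genome free-text genome label recorded in the build metadata
#' @return an object of class `feature_db`
#' @export
build_db <- function(annotation, tracks = list(), out_path = NULL,
                     genome = "custom") {
  if (is.character(annotation)) annotation <- read_gtf_annotation(annotation)
  if (!inherits(annotation, "tx_annotation"))
    stop("build_db: annotation must be a tx_annotation or GTF path",
         call. = FALSE)
  bad <- setdiff(names(tracks), setdiff(FEATURE_CLASSES, "NMD"))
  if (length(bad) > 0L)
    stop(sprintf("build_db: unknown feature class(es): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)

  genomic <- empty_genomic_records()
  isoform <- empty_isoform_records()
  n_skipped_no_cds <- 0L
  for (class in names(tracks)) {
    path <- tracks[[class]]
    if (!file.exists(path))
      stop(sprintf("build_db: unreadable track for class %s: %s", class, path),
           call. = FALSE)
    rec <- switch(class,
      CONS = , REPEAT = , MIRNA_BS = , RBP_BS = read_bed_track(path, class),
      MUT = , SPLICE_SITE_VARIANT = read_vcf_track(path, class),
      EXON_USAGE = read_exon_usage_track(path),
      DOMAIN = , PTM = read_protein_span_track(path, class),
      PPI = read_ppi_track(path),
      LOCALIZATION = read_localization_track(path))
    if (class %in% c("DOMAIN", "PTM") && nrow(rec) > 0L) {
      ok <- vapply(rec$tx_id, function(id) {
        tx <- annotation$transcripts[[id]]
        !is.null(tx) && !is.null(tx$cds)
      }, logical(1))
      n_skipped_no_cds <- n_skipped_no_cds + sum(!ok)
      if (any(!ok))
        warning(sprintf("build_db: skipped %d %s record(s) whose isoform lacks CDS",
                        sum(!ok), class), call. = FALSE)
      rec <- rec[ok, , drop = FALSE]
    }
    if (class %in% GENOMIC_CLASSES) genomic <- rbind(genomic, rec)
    else isoform <- rbind(isoform, rec)
  }

  # canonical order + dedup on the full key -> insertion-order independence
  if (nrow(genomic) > 0L) {
    key <- do.call(paste, c(genomic, sep = "\r"))
    genomic <- genomic[!duplicated(key), , drop = FALSE]
    genomic <- genomic[order(genomic$class, genomic$chrom, genomic$start,
                             genomic$end, genomic$name), , drop = FALSE]
    rownames(genomic) <- NULL
  }
  if (nrow(isoform) > 0L) {
    key <- do.call(paste, c(isoform, sep = "\r"))
    isoform <- isoform[!duplicated(key), , drop = FALSE]
    isoform <- isoform[order(isoform$class, isoform$tx_id, isoform$aa_start,
                             isoform$partner, isoform$name), , drop = FALSE]
    rownames(isoform) <- NULL
  }

  counts <- c(table(factor(c(genomic$class, isoform$class),
                           levels = FEATURE_CLASSES)))
  db <- structure(list(
    annotation = annotation,
    genomic = genomic,
    isoform = isoform,
    index = if (nrow(genomic) > 0L) intervals_to_granges(
      data.frame(chrom = genomic$chrom, start = genomic$start,
                 end = genomic$end)) else NULL,
    build = list(genome = genome, counts = as.list(counts),
                 n_transcripts = length(annotation$transcripts),
                 n_skipped_no_cds = n_skipped_no_cds,
                 built_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "feature_db")
  if (!is.null(out_path)) save_feature_db(db, out_path)
  db
}

#' @exportS3Method print feature_db
print.feature_db <- function(x, ...) {
  cat(sprintf("<feature_db> %d transcripts | %d genomic + %d isoform feature records\n",
              length(x$annotation$transcripts), nrow(x$genomic),
              nrow(x$isoform)))
  invisible(x)
}

#' Persist / restore a feature database as a single file
#'
#' @param db a `feature_db`
#' @param path file path
#' @return `path` (save) or the restored `feature_db` (load)
#' @export
save_feature_db <- function(db, path) {
  saveRDS(db, path)
  invisible(path)
}

#' @rdname save_feature_db
#' @export
load_feature_db <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature db not found: %s", path),
                               call. = FALSE)
  db <- readRDS(path)
  if (!inherits(db, "feature_db")) stop("not a feature_db file", call. = FALSE)
  db
}

#' Query genomic feature records overlapping an interval
#'
#' Overlap is 1-based inclusive: a record `[rs, re]` overlaps the query
#' `[start, end]` iff `max(rs, start) <= min(re, end)`; single-base touch
#' counts.
#'
#' @param db a `feature_db`
#' @param chrom chromosome name
#' @param start,end query interval, 1-based inclusive, `start <= end`
#' @param classes genomic feature classes to search (default: all)
#' @return the matching rows of the genomic record table
#' @export
query_interval <- function(db, chrom, start, end, classes = GENOMIC_CLASSES) {
  if (start > end) stop("query_interval: start > end", call. = FALSE)
  bad <- setdiff(classes, GENOMIC_CLASSES)
  if (length(bad) > 0L)
    stop(sprintf("query_interval: unknown genomic class(es): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (is.null(db$index)) return(empty_genomic_records())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, db$index))
  idx <- S4Vectors::subjectHits(hits)
  res <- db$genomic[idx, , drop = FALSE]
  res <- res[res$class %in% classes, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Query isoform-keyed feature records
#'
#' Exact-match retrieval on isoform identifiers for the protein-level
#' classes.
#'
#' @param db a `feature_db`
#' @param tx_ids character vector of isoform identifiers
#' @param classes subset of `PPI`, `LOCALIZATION`, `DOMAIN`, `PTM`
#' @return the matching rows of the isoform record table
#' @export
query_isoform_features <- function(db, tx_ids,
                                   classes = ISOFORM_CLASSES) {
  bad <- setdiff(classes, ISOFORM_CLASSES)
  if (length(bad) > 0L)
    stop(sprintf("query_isoform_features: unknown isoform class(es): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  res <- db$isoform[db$isoform$tx_id %in% tx_ids &
                    db$isoform$class %in% classes, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# coding exon chain in transcription order: data.frame(start, end) of CDS
# segments, genomic ascending for '+', descending for '-'
cds_chain <- function(tx) {
  if (is.null(tx$cds) || nrow(tx$cds) == 0L)
    stop(sprintf("transcript '%s' has no CDS", tx$tx_id), call. = FALSE)
  ch <- tx$cds
  if (tx$strand == "-") ch <- ch[rev(seq_len(nrow(ch))), , drop = FALSE]
  ch
}

#' Project a protein (amino-acid) span onto genomic coordinates
#'
#' Walks the transcript's CDS in transcription order (strand-aware) and
#' returns the genomic segments covering codons `aa_start..aa_end`,
#' possibly split across exon junctions. Segment lengths always sum to
#' `3 * (aa_end - aa_start + 1)`.
#'
#' @param annotation a [tx_annotation()]
#' @param tx_id transcript id with annotated CDS
#' @param aa_start,aa_end 1-based amino-acid positions, within the protein
#' @return genomic-interval data.frame (ascending genomic order)
#' @export
project_protein_to_genome <- function(annotation, tx_id, aa_start, aa_end) {
  tx <- get_transcript(annotation, tx_id)
  ch <- cds_chain(tx)
  seg_len <- ch$end - ch$start + 1L
  total <- sum(seg_len)
  prot_len <- total %/% 3L
  if (aa_start < 1L || aa_end < aa_start || aa_end > prot_len)
    stop(sprintf("aa range [%d, %d] outside protein of length %d (tx '%s')",
                 aa_start, aa_end, prot_len, tx_id), call. = FALSE)
  nt_from <- 3L * (aa_start - 1L) + 1L
  nt_to <- 3L * aa_end
  out_s <- integer(); out_e <- integer()
  offset <- 0L
  for (i in seq_len(nrow(ch))) {
    lo <- offset + 1L; hi <- offset + seg_len[i]
    a <- max(nt_from, lo); b <- min(nt_to, hi)
    if (a <= b) {
      if (tx$strand == "+") {
        out_s <- c(out_s, ch$start[i] + (a - lo))
        out_e <- c(out_e, ch$start[i] + (b - lo))
      } else {
        out_s <- c(out_s, ch$end[i] - (b - lo))
        out_e <- c(out_e, ch$end[i] - (a - lo))
      }
    }
    offset <- hi
  }
  ord <- order(out_s)
  genomic_interval(tx$chrom, out_s[ord], out_e[ord], tx$strand, "cds")
}

# inverse mapping used by the fixture generator: amino acids whose codons
# overlap the genomic interval [s, e] on tx (NULL if none)
genome_span_to_protein <- function(tx, s, e) {
  ch <- cds_chain(tx)
  seg_len <- ch$end - ch$start + 1L
  offset <- 0L
  nts <- integer()
  for (i in seq_len(nrow(ch))) {
    a <- max(ch$start[i], s); b <- min(ch$end[i], e)
    if (a <= b) {
      if (tx$strand == "+") nts <- c(nts, offset + (a - ch$start[i] + 1L):(b - ch$start[i] + 1L))
      else nts <- c(nts, offset + (ch$end[i] - b + 1L):(ch$end[i] - a + 1L))
    }
    offset <- offset + seg_len[i]
  }
  if (length(nts) == 0L) return(NULL)
  prot_len <- sum(seg_len) %/% 3L
  aa <- unique((sort(nts) - 1L) %/% 3L + 1L)
  aa <- aa[aa <= prot_len]
  if (length(aa) == 0L) return(NULL)
  c(min(aa), max(aa))
}
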