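#' Fixed 23-column annotation schema
#'
#' Nine event/statistics columns followed by fourteen feature columns
#' covering the twelve feature classes (`DOMAIN` and `PTM` each carry a
#' protein-space and a genome-space column). Column order is stable
#' regardless of which classes are populated; unpopulated cells are empty
#' strings.
#'
#' @export
ANNOTATION_COLUMNS <- c(
  "event_id", "gene", "event_type", "chrom", "strand", "coords",
  "p_value", "fdr", "dpsi",
  "conservation", "mutation", "repeats", "mirna_bs", "nmd", "rbp_bs",
  "exon_usage", "domain", "domain_genomic", "ptm", "ptm_genomic",
  "ppi", "localization", "splice_site_variant")

# primary column per feature class (domain/ptm genomic columns ride along)
CLASS_COLUMN_MAP <- c(
  CONS = "conservation", MUT = "mutation", REPEAT = "repeats",
  MIRNA_BS = "mirna_bs", NMD = "nmd", RBP_BS = "rbp_bs",
  EXON_USAGE = "exon_usage", DOMAIN = "domain", PTM = "ptm",
  PPI = "ppi", LOCALIZATION = "localization",
  SPLICE_SITE_VARIANT = "splice_site_variant")

#' The class-specific region rule table
#'
#' Each of the twelve feature classes is consumed by exactly one region
#' selector: point mutations and splice-site variants are screened over the
#' distinct region(s) plus the splice-site boundary windows; RBP /
#' splicing-factor sites over the distinct region(s) and flanking introns
#' with common-region overlap subtracted before querying; conservation,
#' repeats, miRNA sites and exon usage over the distinct region(s) only;
#' domains and PTM sites are protein-level records projected to the genome
#' and intersected with the distinct region(s); NMD is derived from the
#' isoform CDS structure; PPI and localization resolve through the
#' inclusion/exclusion isoform partition.
#'
#' @return data.frame with columns `class`, `selector`, `level`
#' @export
default_region_rules <- function() {
  data.frame(
    class = c("CONS", "MUT", "REPEAT", "MIRNA_BS", "NMD", "RBP_BS",
              "EXON_USAGE", "DOMAIN", "PTM", "PPI", "LOCALIZATION",
              "SPLICE_SITE_VARIANT"),
    selector = c("distinct", "distinct+boundaries", "distinct", "distinct",
                 "derived", "distinct+introns-common", "distinct",
                 "distinct", "distinct", "isoform-partition",
                 "isoform-partition", "distinct+boundaries"),
    level = c("genomic", "genomic", "genomic", "genomic", "derived",
              "genomic", "genomic", "isoform", "isoform", "isoform",
              "isoform", "genomic"),
    stringsAsFactors = FALSE)
}

genomic_digest <- function(rec, side = NULL) {
  if (nrow(rec) == 0L) return(character())
  d <- sprintf("%s@%s:%d-%d", ifelse(is.na(rec$name), "feature", rec$name),
               rec$chrom, rec$start, rec$end)
  extra <- ifelse(rec$class == "EXON_USAGE" & !is.na(rec$payload),
                  paste0("{", rec$payload, "}"), "")
  d <- paste0(d, extra)
  if (!is.null(side)) d <- paste0(side, ":", d)
  d
}

join_digest <- function(x) paste(sort(unique(x)), collapse = ";")

#' Per-transcript NMD status under the 50-nt rule
#'
#' A transcript is NMD-sensitive iff its stop codon (the last coding base)
#' lies more than `threshold` nucleotides upstream of the final exon-exon
#' junction in mRNA coordinates. Single-exon transcripts are never
#' sensitive; transcripts without CDS return `NA`.
#'
#' @param tx a [transcript()]
#' @param threshold rule threshold in nt (default 50)
#' @return `TRUE`, `FALSE` or `NA`
#' @export
tx_nmd_status <- function(tx, threshold = 50L) {
  if (is.null(tx$cds) || nrow(tx$cds) == 0L) return(NA)
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(FALSE)
  len <- ex$end - ex$start + 1L
  last_junction <- sum(len[-n])
  stop_genomic <- if (tx$strand == "+") max(tx$cds$end) else min(tx$cds$start)
  # mRNA coordinate of the stop codon's last base
  pos <- 0L
  stop_mrna <- NA_integer_
  for (i in seq_len(n)) {
    if (stop_genomic >= ex$start[i] && stop_genomic <= ex$end[i]) {
      stop_mrna <- pos + if (tx$strand == "+") stop_genomic - ex$start[i] + 1L
                         else ex$end[i] - stop_genomic + 1L
      break
    }
    pos <- pos + len[i]
  }
  if (is.na(stop_mrna)) return(NA)
  (last_junction - stop_mrna) > threshold
}

#' Call NMD sensitivity for the two isoform sides of an event
#'
#' An isoform side is NMD-sensitive iff any of its CDS-bearing transcripts
#' places the stop codon more than 50 nt upstream of its final exon-exon
#' junction (the 50-nt rule); sides with no CDS-bearing transcript are
#' `"unknown"`.
#'
#' @param event an `as_event`
#' @param annotation a [tx_annotation()]
#' @param threshold rule threshold in nt (default 50)
#' @return named character vector
#'   `c(inclusion = ..., exclusion = ...)` with values `"sensitive"`,
#'   `"not_sensitive"` or `"unknown"`
#' @export
call_nmd <- function(event, annotation, threshold = 50L) {
  part <- map_transcripts_to_event(event, annotation)
  side_status <- function(ids) {
    st <- vapply(ids, function(id)
      tx_nmd_status(annotation$transcripts[[id]], threshold), logical(1))
    st <- st[!is.na(st)]
    if (length(st) == 0L) return("unknown")
    if (any(st)) "sensitive" else "not_sensitive"
  }
  c(inclusion = side_status(part$inclusion),
    exclusion = side_status(part$exclusion))
}

#' Partition protein-interaction edges by isoform specificity
#'
#' An interaction partner is inclusion-specific iff it appears on at least
#' one inclusion isoform and on no exclusion isoform (symmetrically for
#' exclusion); partners seen on both sides are shared. Edges on
#' not-informative isoforms are ignored.
#'
#' @param event an `as_event`
#' @param db a `feature_db` carrying PPI records
#' @return list of data.frames `$inclusion`, `$exclusion`, `$shared`
#'   (columns `tx_id`, `partner`), plus `$partition` (the isoform
#'   partition used)
#' @export
assign_isoform_ppi <- function(event, db) {
  part <- map_transcripts_to_event(event, db$annotation)
  edges <- query_isoform_features(db, c(part$inclusion, part$exclusion),
                                  classes = "PPI")
  empty <- data.frame(tx_id = character(), partner = character(),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    return(list(inclusion = empty, exclusion = empty, shared = empty,
                partition = part))
  edges <- unique(edges[, c("tx_id", "partner")])
  on_inc <- edges$tx_id %in% part$inclusion
  partners_inc <- unique(edges$partner[on_inc])
  partners_exc <- unique(edges$partner[!on_inc])
  cls <- ifelse(edges$partner %in% intersect(partners_inc, partners_exc),
                "shared", ifelse(on_inc, "inclusion", "exclusion"))
  split_df <- function(which) {
    d <- edges[cls == which, , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(inclusion = split_df("inclusion"), exclusion = split_df("exclusion"),
       shared = split_df("shared"), partition = part)
}

query_regions <- function(db, regions_df, classes) {
  if (nrow(regions_df) == 0L) return(empty_genomic_records())
  out <- lapply(seq_len(nrow(regions_df)), function(i)
    query_interval(db, regions_df$chrom[i], regions_df$start[i],
                   regions_df$end[i], classes))
  res <- do.call(rbind, out)
  res[!duplicated(do.call(paste, c(res, sep = "\r"))), , drop = FALSE]
}

#' Annotate one event with all twelve feature classes
#'
#' Applies the region rule table to the event's decomposition and returns
#' one fixed-schema annotation row. For MXE/AF/AL the rules are applied to
#' both distinct regions and digests carry an `inc:`/`exc:` side prefix.
#'
#' @param event an `as_event`
#' @param db a `feature_db`
#' @param w splice-site boundary half-width in bp (default 10)
#' @param rules region rule table (default [default_region_rules()])
#' @return a named list with the 23 [ANNOTATION_COLUMNS]
#' @export
annotate_event <- function(event, db, w = 10L, rules = default_region_rules()) {
  stopifnot(inherits(db, "feature_db"))
  if (anyDuplicated(rules$class) || !setequal(rules$class, names(CLASS_COLUMN_MAP)))
    stop("annotate_event: rule table must cover each of the 12 classes exactly once",
         call. = FALSE)
  regions <- decompose_regions(event, w = w)
  d <- regions$distinct
  two_sided <- nrow(d) == 2L
  side_tag <- function(i) if (two_sided) c("inc", "exc")[i] else NULL

  row <- stats::setNames(as.list(rep("", length(ANNOTATION_COLUMNS))),
                         ANNOTATION_COLUMNS)
  row$event_id <- encode_event_id(event)
  row$gene <- event$gene
  row$event_type <- event$event_type
  row$chrom <- event$chrom
  row$strand <- event$strand
  row$coords <- paste(event$coords, collapse = ":")
  row$p_value <- if (is.null(event$stats)) NA_real_ else event$stats$p_value
  row$fdr <- if (is.null(event$stats)) NA_real_ else event$stats$fdr
  row$dpsi <- if (is.null(event$stats)) NA_real_ else event$stats$dpsi

  # genomic classes, per side
  for (i in seq_len(nrow(d))) {
    di <- d[i, , drop = FALSE]
    bounds_i <- regions$boundaries[c(2L * i - 1L, 2L * i), , drop = FALSE]
    tag <- side_tag(i)

    # distinct-only classes
    rec <- query_regions(db, di, c("CONS", "REPEAT", "MIRNA_BS", "EXON_USAGE"))
    for (cls in c("CONS", "REPEAT", "MIRNA_BS", "EXON_USAGE")) {
      hit <- rec[rec$class == cls, , drop = FALSE]
      col <- CLASS_COLUMN_MAP[[cls]]
      row[[col]] <- join_digest(c(
        if (nzchar(row[[col]])) strsplit(row[[col]], ";", fixed = TRUE)[[1L]],
        genomic_digest(hit, tag)))
    }

    # mutation classes over distinct + boundary windows
    rec <- query_regions(db, rbind(di, bounds_i),
                         c("MUT", "SPLICE_SITE_VARIANT"))
    for (cls in c("MUT", "SPLICE_SITE_VARIANT")) {
      hit <- rec[rec$class == cls, , drop = FALSE]
      col <- CLASS_COLUMN_MAP[[cls]]
      row[[col]] <- join_digest(c(
        if (nzchar(row[[col]])) strsplit(row[[col]], ";", fixed = TRUE)[[1L]],
        genomic_digest(hit, tag)))
    }

    # RBP sites over (distinct + flanking introns) minus common regions;
    # truncation keeps residual pieces of >= 1 bp
    rbp_region <- rbind(di, regions$flanking_introns)
    rbp_region <- subtract_intervals(rbp_region, regions$common)
    rec <- query_regions(db, rbp_region, "RBP_BS")
    row$rbp_bs <- join_digest(c(
      if (nzchar(row$rbp_bs)) strsplit(row$rbp_bs, ";", fixed = TRUE)[[1L]],
      genomic_digest(rec, tag)))
  }

  # protein-level spans: project to genome, intersect with distinct regions
  part <- map_transcripts_to_event(event, db$annotation)
  informative <- c(part$inclusion, part$exclusion)
  spans <- query_isoform_features(db, informative, classes = c("DOMAIN", "PTM"))
  for (k in seq_len(nrow(spans))) {
    rec <- spans[k, ]
    seg <- tryCatch(project_protein_to_genome(db$annotation, rec$tx_id,
                                              rec$aa_start, rec$aa_end),
                    error = function(e) NULL)
    if (is.null(seg)) next
    ov <- FALSE
    for (i in seq_len(nrow(d)))
      ov <- ov || any(interval_overlaps(seg$chrom, seg$start, seg$end,
                                        d$chrom[i], d$start[i], d$end[i]))
    if (!ov) next
    col <- CLASS_COLUMN_MAP[[rec$class]]
    gcol <- paste0(col, "_genomic")
    pdig <- sprintf("%s:%s[%d-%d]", rec$tx_id, rec$name, rec$aa_start, rec$aa_end)
    gdig <- sprintf("%s:%s@%s:%d-%d", rec$tx_id, rec$name, seg$chrom[1L],
                    min(seg$start), max(seg$end))
    row[[col]] <- join_digest(c(
      if (nzchar(row[[col]])) strsplit(row[[col]], ";", fixed = TRUE)[[1L]], pdig))
    row[[gcol]] <- join_digest(c(
      if (nzchar(row[[gcol]])) strsplit(row[[gcol]], ";", fixed = TRUE)[[1L]], gdig))
  }

  # derived NMD
  nmd <- call_nmd(event, db$annotation)
  row$nmd <- if (all(nmd == "unknown")) "" else
    sprintf("inclusion:%s|exclusion:%s", nmd[["inclusion"]], nmd[["exclusion"]])

  # isoform-partition classes
  ppi <- assign_isoform_ppi(event, db)
  fmt_edges <- function(d) paste(sort(unique(d$partner)), collapse = ",")
  if (nrow(ppi$inclusion) + nrow(ppi$exclusion) + nrow(ppi$shared) > 0L) {
    pieces <- c(
      if (nrow(ppi$inclusion)) sprintf("inclusion=%s", fmt_edges(ppi$inclusion)),
      if (nrow(ppi$exclusion)) sprintf("exclusion=%s", fmt_edges(ppi$exclusion)),
      if (nrow(ppi$shared)) sprintf("shared=%s", fmt_edges(ppi$shared)))
    row$ppi <- paste(pieces, collapse = "|")
  }
  loc <- query_isoform_features(db, informative, classes = "LOCALIZATION")
  if (nrow(loc) > 0L) {
    side <- ifelse(loc$tx_id %in% part$inclusion, "inclusion", "exclusion")
    row$localization <- join_digest(sprintf("%s:%s", side, loc$name))
  }

  row
}

#' Annotate a list of events
#'
#' @param events list of [as_event()]
#' @param db a `feature_db`
#' @param w boundary half-width in bp
#' @param rules region rule table
#' @return the assembled 23-column annotation table (see [assemble_table()])
#' @export
annotate_events <- function(events, db, w = 10L,
                            rules = default_region_rules()) {
  rows <- lapply(events, annotate_event, db = db, w = w, rules = rules)
  assemble_table(rows)
}

#' Assemble annotation rows into the fixed 23-column table
#'
#' @param rows list of rows as returned by [annotate_event()]
#' @return data.frame with exactly the 23 [ANNOTATION_COLUMNS]; zero rows
#'   yield a header-only table
#' @export
assemble_table <- function(rows) {
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(
      lapply(ANNOTATION_COLUMNS, function(cl)
        if (cl %in% c("p_value", "fdr", "dpsi")) numeric() else character()),
      ANNOTATION_COLUMNS), stringsAsFactors = FALSE, check.names = FALSE)
    return(df)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[ANNOTATION_COLUMNS], stringsAsFactors = FALSE,
                  check.names = FALSE)))
  names(df) <- ANNOTATION_COLUMNS
  rownames(df) <- NULL
  df
}

#' Write an annotation table as CSV
#'
#' RFC-4180 quoting, one row per event, stable 23-column header.
#'
#' @param table output of [assemble_table()] / [annotate_events()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Which feature classes are populated in an annotation row
#'
#' @param table annotation table
#' @return logical matrix, events x the 12 feature classes
#' @export
class_presence <- function(table) {
  out <- vapply(names(CLASS_COLUMN_MAP), function(cls) {
    col <- table[[CLASS_COLUMN_MAP[[cls]]]]
    !is.na(col) & nzchar(col)
  }, logical(nrow(table)))
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(table$event_id, names(CLASS_COLUMN_MAP)))
  out
}
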