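#' Construct a transcript model
#'
#' @param tx_id transcript identifier
#' @param gene gene identifier
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param exons two-column matrix-like (start, end) of exon coordinates,
#'   1-based inclusive; will be sorted ascending and must be pairwise
#'   disjoint
#' @param cds optional (start, end) pairs of coding segments, contained in
#'   the exon union
#' @return an object of class `transcript`
#' @export
transcript <- function(tx_id, gene, chrom, strand, exons, cds = NULL) {
  ex <- as.data.frame(exons)
  names(ex)[1:2] <- c("start", "end")
  ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
  ex <- ex[order(ex$start), c("start", "end"), drop = FALSE]
  rownames(ex) <- NULL
  if (nrow(ex) < 1L) stop("transcript: at least one exon required", call. = FALSE)
  if (any(ex$end < ex$start)) stop("transcript: exon end < start", call. = FALSE)
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
    stop("transcript: exons must be pairwise disjoint", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("transcript: bad strand", call. = FALSE)
  cds_df <- NULL
  if (!is.null(cds) && NROW(cds) > 0L) {
    cds_df <- as.data.frame(cds)
    names(cds_df)[1:2] <- c("start", "end")
    cds_df$start <- as.integer(cds_df$start); cds_df$end <- as.integer(cds_df$end)
    cds_df <- cds_df[order(cds_df$start), c("start", "end"), drop = FALSE]
    rownames(cds_df) <- NULL
    contained <- vapply(seq_len(nrow(cds_df)), function(i)
      any(ex$start <= cds_df$start[i] & cds_df$end[i] <= ex$end), logical(1))
    if (!all(contained))
      stop("transcript: cds segments must lie within exons", call. = FALSE)
  }
  structure(list(tx_id = as.character(tx_id), gene = as.character(gene),
                 chrom = as.character(chrom), strand = as.character(strand),
                 exons = ex, cds = cds_df),
            class = "transcript")
}

#' Build a transcript-annotation container
#'
#' @param transcripts a list of [transcript()] objects
#' @return an object of class `tx_annotation` with by-id and by-gene indexes
#' @export
tx_annotation <- function(transcripts) {
  if (length(transcripts) == 0L)
    return(structure(list(transcripts = list(), genes = list()),
                     class = "tx_annotation"))
  ids <- vapply(transcripts, `[[`, character(1), "tx_id")
  if (anyDuplicated(ids))
    stop("tx_annotation: duplicate transcript ids", call. = FALSE)
  names(transcripts) <- ids
  genes <- split(ids, vapply(transcripts, `[[`, character(1), "gene"))
  structure(list(transcripts = transcripts, genes = genes),
            class = "tx_annotation")
}

#' @exportS3Method print tx_annotation
print.tx_annotation <- function(x, ...) {
  cat(sprintf("<tx_annotation> %d transcripts, %d genes\n",
              length(x$transcripts), length(x$genes)))
  invisible(x)
}

annotation_genes <- function(annotation) names(annotation$genes)

get_transcript <- function(annotation, tx_id) {
  tx <- annotation$transcripts[[tx_id]]
  if (is.null(tx))
    stop(sprintf("unknown isoform '%s' in annotation", tx_id), call. = FALSE)
  tx
}

#' Read transcript models from a GTF file
#'
#' Accepts Ensembl- and RefSeq-dialect GTF (attributes `gene_id` /
#' `transcript_id`; `exon` and `CDS` features); input need not be sorted.
#'
#' @param path GTF file path
#' @return a [tx_annotation()]
#' @export
read_gtf_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("GTF not found: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) return(tx_annotation(list()))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   gene = as.character(gr$gene_id),
                   tx_id = as.character(gr$transcript_id),
                   stringsAsFactors = FALSE)
  txs <- lapply(split(df, df$tx_id), function(d) {
    ex <- d[d$type == "exon", c("start", "end")]
    cds <- d[d$type == "CDS", c("start", "end")]
    transcript(d$tx_id[1L], d$gene[1L], d$chrom[1L], d$strand[1L],
               exons = ex, cds = if (nrow(cds)) cds else NULL)
  })
  tx_annotation(unname(txs))
}

# junctions of a transcript: (end of exon i, start of exon i+1) pairs
tx_junctions <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(matrix(integer(), ncol = 2L,
                            dimnames = list(NULL, c("l", "r"))))
  cbind(l = ex$end[-n], r = ex$start[-1L])
}

has_junction <- function(J, l, r) any(J[, "l"] == l & J[, "r"] == r)

# is [s,e] fully inside one exon of tx?
region_exonic <- function(tx, s, e) {
  any(tx$exons$start <= s & e <= tx$exons$end)
}

# does tx have an intron fully covering [s,e]?
region_intronic <- function(tx, s, e) {
  J <- tx_junctions(tx)
  nrow(J) > 0L && any(J[, "l"] < s & e < J[, "r"])
}

# exonic-coverage XOR of two transcripts over the union span, as an IRanges
exonic_xor <- function(tx_a, tx_b) {
  ir_a <- IRanges::IRanges(tx_a$exons$start, tx_a$exons$end)
  ir_b <- IRanges::IRanges(tx_b$exons$start, tx_b$exons$end)
  IRanges::union(IRanges::setdiff(ir_a, ir_b), IRanges::setdiff(ir_b, ir_a))
}

#' Classify the structural differences between two transcripts
#'
#' Compares the two exon chains junction-by-junction and maps each local
#' difference bounded by shared splice sites onto one of the seven AS event
#' types. Differences that match no type (multi-exon skips, overlapping
#' mutually-exclusive candidates, bare terminal truncations) are returned
#' under `$unclassified` as genomic intervals rather than silently dropped.
#'
#' Terminal exon pairs that are disjoint and share their inner junction are
#' classified as AF/AL; overlapping terminal exons fall through to the
#' alternative-splice-site rule.
#'
#' @param tx_a,tx_b two [transcript()]s of the same gene, chromosome and
#'   strand
#' @param stats optional [das_record()] attached to every emitted event
#' @return a list of class `pair_classification` with `$events` (list of
#'   `as_event`) and `$unclassified` (genomic-interval data.frame)
#' @export
classify_transcript_pair <- function(tx_a, tx_b, stats = NULL) {
  if (tx_a$gene != tx_b$gene || tx_a$chrom != tx_b$chrom ||
      tx_a$strand != tx_b$strand)
    stop("classify_transcript_pair: incompatible pair (gene/chrom/strand differ)",
         call. = FALSE)
  gene <- tx_a$gene; ch <- tx_a$chrom; st <- tx_a$strand
  mk <- function(type, coords) as_event(gene, type, ch, st, coords,
                                        source = "catalog", stats = stats)
  events <- list()
  JA <- tx_junctions(tx_a); JB <- tx_junctions(tx_b)

  # --- SE and MXE: junction-bounded internal cassettes ---------------------
  # For every (l, r) bracket where both transcripts have an exon ending at l
  # and one starting at r, compare the exon content strictly inside (l, r).
  inner_exons <- function(tx, l, r)
    tx$exons[tx$exons$start > l & tx$exons$end < r, , drop = FALSE]
  chained <- function(tx, l, r, inner) {
    # tx walks l -> inner exons -> r through consecutive junctions
    J <- tx_junctions(tx)
    pts_l <- c(l, inner$end); pts_r <- c(inner$start, r)
    all(vapply(seq_along(pts_l), function(i)
      has_junction(J, pts_l[i], pts_r[i]), logical(1)))
  }
  # candidate brackets: shared exon-end coordinate l paired with a shared
  # exon-start coordinate r downstream of it (the bracket itself need not
  # be a junction of either transcript, e.g. for MXE)
  ends_shared <- intersect(tx_a$exons$end, tx_b$exons$end)
  starts_shared <- intersect(tx_a$exons$start, tx_b$exons$start)
  brackets <- expand.grid(l = ends_shared, r = starts_shared)
  brackets <- brackets[brackets$l < brackets$r, , drop = FALSE]
  for (i in seq_len(nrow(brackets))) {
    l <- brackets$l[i]; r <- brackets$r[i]
    in_a <- inner_exons(tx_a, l, r); in_b <- inner_exons(tx_b, l, r)
    if (!chained(tx_a, l, r, in_a) || !chained(tx_b, l, r, in_b)) next
    na <- nrow(in_a); nb <- nrow(in_b)
    if (na == nb && na > 0L && all(in_a$start == in_b$start) &&
        all(in_a$end == in_b$end)) next
    if (na == 1L && nb == 0L) {
      events <- c(events, list(mk("SE", c(l, in_a$start, in_a$end, r))))
    } else if (na == 0L && nb == 1L) {
      events <- c(events, list(mk("SE", c(l, in_b$start, in_b$end, r))))
    } else if (na == 1L && nb == 1L) {
      if (in_a$end < in_b$start) {
        events <- c(events, list(mk("MXE", c(l, in_a$start, in_a$end,
                                             in_b$start, in_b$end, r))))
      } else if (in_b$end < in_a$start) {
        events <- c(events, list(mk("MXE", c(l, in_b$start, in_b$end,
                                             in_a$start, in_a$end, r))))
      } # overlapping alternatives -> unclassified residue
    }   # multi-exon content -> unclassified residue
  }

  # --- RI: a junction of one transcript inside an exon of the other -------
  detect_ri <- function(tx_spliced, tx_retained) {
    J <- tx_junctions(tx_spliced)
    out <- list()
    for (i in seq_len(nrow(J))) {
      l <- J[i, "l"]; r <- J[i, "r"]
      if (r - l < 2L) next
      cover <- tx_retained$exons$start <= l & r <= tx_retained$exons$end
      if (!any(cover)) next
      up <- tx_spliced$exons[tx_spliced$exons$end == l, , drop = FALSE]
      dn <- tx_spliced$exons[tx_spliced$exons$start == r, , drop = FALSE]
      if (nrow(up) != 1L || nrow(dn) != 1L) next
      out <- c(out, list(mk("RI", c(up$start, l, r, dn$end))))
    }
    out
  }
  events <- c(events, detect_ri(tx_a, tx_b), detect_ri(tx_b, tx_a))

  # --- terminal AF/AL: disjoint terminal exons sharing the inner junction --
  first_a <- tx_a$exons[1L, ]; first_b <- tx_b$exons[1L, ]
  na_ex <- nrow(tx_a$exons); nb_ex <- nrow(tx_b$exons)
  last_a <- tx_a$exons[na_ex, ]; last_b <- tx_b$exons[nb_ex, ]
  af_al <- list()
  if (na_ex > 1L && nb_ex > 1L) {
    # genomic-left termini share the junction target r
    ra <- JA[1L, "r"]; rb <- JB[1L, "r"]
    if (ra == rb && !(first_a$start == first_b$start && first_a$end == first_b$end) &&
        (first_a$end < first_b$start || first_b$end < first_a$start)) {
      exl <- if (first_a$start < first_b$start) rbind(first_a, first_b)
             else rbind(first_b, first_a)
      type <- if (st == "+") "AF" else "AL"
      af_al <- c(af_al, list(mk(type, c(exl$start[1L], exl$end[1L],
                                        exl$start[2L], exl$end[2L], ra))))
    }
    # genomic-right termini share the junction source l
    la <- JA[nrow(JA), "l"]; lb <- JB[nrow(JB), "l"]
    if (la == lb && !(last_a$start == last_b$start && last_a$end == last_b$end) &&
        (last_a$end < last_b$start || last_b$end < last_a$start)) {
      exr <- if (last_a$start < last_b$start) rbind(last_a, last_b)
             else rbind(last_b, last_a)
      type <- if (st == "+") "AL" else "AF"
      af_al <- c(af_al, list(mk(type, c(la, exr$start[1L], exr$end[1L],
                                        exr$start[2L], exr$end[2L]))))
    }
  }
  events <- c(events, af_al)

  # --- A5SS / A3SS: one shared junction coordinate, one alternative -------
  for (i in seq_len(nrow(JA))) {
    l1 <- JA[i, "l"]; r1 <- JA[i, "r"]
    for (j in seq_len(nrow(JB))) {
      l2 <- JB[j, "l"]; r2 <- JB[j, "r"]
      if (r1 == r2 && l1 != l2) {
        lmin <- min(l1, l2); lmax <- max(l1, l2)
        tx_long <- if (l1 > l2) tx_a else tx_b
        tx_short <- if (l1 > l2) tx_b else tx_a
        # the longer form's exon must carry the alt segment; the shorter
        # form's intron must cover it
        if (region_exonic(tx_long, lmin + 1L, lmax) &&
            region_intronic(tx_short, lmin + 1L, lmax)) {
          type <- if (st == "+") "A5SS" else "A3SS"
          cand <- mk(type, c(lmin, lmin + 1L, lmax, r1))
          events <- c(events, list(cand))
        }
      } else if (l1 == l2 && r1 != r2) {
        rmin <- min(r1, r2); rmax <- max(r1, r2)
        tx_long <- if (r1 < r2) tx_a else tx_b
        tx_short <- if (r1 < r2) tx_b else tx_a
        if (region_exonic(tx_long, rmin, rmax - 1L) &&
            region_intronic(tx_short, rmin, rmax - 1L)) {
          type <- if (st == "+") "A3SS" else "A5SS"
          cand <- mk(type, c(l1, rmin, rmax - 1L, rmax))
          events <- c(events, list(cand))
        }
      }
    }
  }

  # dedup on canonical ID, deterministic order
  ids <- vapply(events, encode_event_id, character(1))
  events <- events[!duplicated(ids)]
  ids <- ids[!duplicated(ids)]
  events <- events[order(ids)]

  # --- unclassified residue: exonic XOR not explained by any event --------
  xr <- exonic_xor(tx_a, tx_b)
  uncl <- genomic_interval(character(), integer(), integer())
  if (length(xr) > 0L) {
    explained <- IRanges::IRanges()
    for (ev in events) {
      reg <- decompose_regions(ev, w = 0L)$distinct
      explained <- IRanges::union(explained,
                                  IRanges::IRanges(reg$start, reg$end))
    }
    res <- IRanges::setdiff(xr, explained)
    if (length(res) > 0L)
      uncl <- genomic_interval(ch, IRanges::start(res), IRanges::end(res),
                               st, "unclassified")
  }

  structure(list(events = events, unclassified = uncl),
            class = "pair_classification")
}

#' Enumerate all AS events of a gene from its annotated transcripts
#'
#' Deduplicated union of [classify_transcript_pair()] over all transcript
#' pairs of the gene, ordered by canonical event ID. A gene with a single
#' transcript yields no events.
#'
#' @param annotation a [tx_annotation()]
#' @param gene gene identifier present in the annotation
#' @return list of `as_event`, sorted by canonical ID
#' @export
enumerate_events <- function(annotation, gene) {
  tx_ids <- annotation$genes[[gene]]
  if (is.null(tx_ids))
    stop(sprintf("enumerate_events: gene '%s' not found in annotation", gene),
         call. = FALSE)
  tx_ids <- sort(tx_ids)
  if (length(tx_ids) < 2L) return(list())
  events <- list()
  for (i in seq_len(length(tx_ids) - 1L)) {
    for (j in seq.int(i + 1L, length(tx_ids))) {
      cls <- classify_transcript_pair(annotation$transcripts[[tx_ids[i]]],
                                      annotation$transcripts[[tx_ids[j]]])
      events <- c(events, cls$events)
    }
  }
  ids <- vapply(events, encode_event_id, character(1))
  events <- events[!duplicated(ids)]
  ids <- unique(ids)
  events[order(ids)]
}

#' Partition a gene's transcripts by their relation to an event
#'
#' Inclusion isoforms carry the event's inclusion-side distinct region
#' entirely within one exon; exclusion isoforms splice it out (an intron
#' spans it, or — for two-region events — they carry the exclusion-side
#' region instead); transcripts that do not span the event locus, or that
#' are ambiguous, are reported as not informative.
#'
#' @param event an `as_event`
#' @param annotation a [tx_annotation()] containing the event's gene
#' @return list with character vectors `$inclusion`, `$exclusion`,
#'   `$not_informative` of transcript ids
#' @export
map_transcripts_to_event <- function(event, annotation) {
  tx_ids <- annotation$genes[[event$gene]]
  if (is.null(tx_ids))
    stop(sprintf("map_transcripts_to_event: gene '%s' not in annotation",
                 event$gene), call. = FALSE)
  regions <- decompose_regions(event, w = 0L)
  d <- regions$distinct
  two_sided <- nrow(d) == 2L
  inc <- character(); exc <- character(); ni <- character()
  for (id in sort(tx_ids)) {
    tx <- annotation$transcripts[[id]]
    span_lo <- min(d$start); span_hi <- max(d$end)
    spans <- tx$exons$start[1L] <= span_hi && tx$exons$end[nrow(tx$exons)] >= span_lo
    if (!spans) { ni <- c(ni, id); next }
    if (two_sided) {
      has_inc <- region_exonic(tx, d$start[1L], d$end[1L])
      has_exc <- region_exonic(tx, d$start[2L], d$end[2L])
      if (has_inc && !has_exc) inc <- c(inc, id)
      else if (has_exc && !has_inc) exc <- c(exc, id)
      else ni <- c(ni, id)
    } else {
      if (region_exonic(tx, d$start[1L], d$end[1L])) inc <- c(inc, id)
      else if (region_intronic(tx, d$start[1L], d$end[1L])) exc <- c(exc, id)
      else ni <- c(ni, id)
    }
  }
  list(inclusion = inc, exclusion = exc, not_informative = ni)
}
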