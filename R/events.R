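#' The seven supported alternative-splicing event type codes
#'
#' SE (skipped exon), MXE (mutually exclusive exons), RI (retained intron),
#' A5SS / A3SS (alternative 5'/3' splice site), AF / AL (alternative
#' first/last exon).
#'
#' @export
AS_EVENT_TYPES <- c("SE", "MXE", "RI", "A5SS", "A3SS", "AF", "AL")

# Fixed coordinate-tuple arity per type. All tuples are strictly ascending
# genomic coordinates, 1-based inclusive:
#   SE   (4): upstream-exon end, skipped-exon start, skipped-exon end,
#             downstream-exon start
#   MXE  (6): upstream-exon end, exon1 start/end, exon2 start/end,
#             downstream-exon start
#   RI   (4): upstream exon start, upstream exon end, downstream exon start,
#             downstream exon end (retained intron = [c2+1, c3-1])
#   A5SS/A3SS (4): constitutive anchor, alt-segment start, alt-segment end,
#             flanking junction coordinate (anchor side depends on strand)
#   AF/AL (5): the two alternative terminal exons (start/end each) plus the
#             shared inner junction coordinate, ascending
AS_EVENT_ARITY <- c(SE = 4L, MXE = 6L, RI = 4L, A5SS = 4L, A3SS = 4L,
                    AF = 5L, AL = 5L)

#' Construct a differential-splicing statistics record
#'
#' @param p_value test p-value in \[0,1\]
#' @param fdr adjusted p-value in \[0,1\]
#' @param dpsi inclusion-level (PSI) difference in \[-1,1\]
#' @return a list of class `das_record`; `NA` entries are allowed and mean
#'   "not reported by the upstream tool".
#' @export
das_record <- function(p_value = NA_real_, fdr = NA_real_, dpsi = NA_real_) {
  chk <- function(x, lo, hi, nm) {
    if (!is.na(x) && (x < lo || x > hi))
      stop(sprintf("das_record: %s = %g outside [%g, %g]", nm, x, lo, hi),
           call. = FALSE)
  }
  chk(p_value, 0, 1, "p_value"); chk(fdr, 0, 1, "fdr"); chk(dpsi, -1, 1, "dpsi")
  structure(list(p_value = as.numeric(p_value), fdr = as.numeric(fdr),
                 dpsi = as.numeric(dpsi)), class = "das_record")
}

#' Construct a canonical alternative-splicing event
#'
#' @param gene gene identifier or symbol
#' @param event_type one of [AS_EVENT_TYPES]
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param coords strictly ascending integer coordinate tuple whose arity is
#'   fixed per type (see `AS_EVENT_ARITY`); 1-based inclusive
#' @param source provenance tag: one of `"rmats"`, `"suppa"`, `"splicer"`,
#'   `"catalog"`, `"generic"`
#' @param stats optional [das_record()]
#' @return an object of class `as_event`
#' @export
as_event <- function(gene, event_type, chrom, strand, coords,
                     source = "catalog", stats = NULL) {
  ev <- structure(list(gene = as.character(gene),
                       event_type = as.character(event_type),
                       chrom = as.character(chrom),
                       strand = as.character(strand),
                       coords = as.integer(coords),
                       source = as.character(source),
                       stats = stats),
                  class = "as_event")
  validate_event(ev)
  ev
}

#' Validate an `as_event` against the event-model invariants
#'
#' @param ev an `as_event`
#' @return `ev`, invisibly; otherwise an error naming the offending field
#' @export
validate_event <- function(ev) {
  if (length(ev$gene) != 1L || is.na(ev$gene) || !nzchar(ev$gene))
    stop("as_event: field 'gene' must be a non-empty string", call. = FALSE)
  if (grepl("[|:]", ev$gene))
    stop("as_event: field 'gene' must not contain '|' or ':'", call. = FALSE)
  if (!ev$event_type %in% AS_EVENT_TYPES)
    stop(sprintf("as_event: field 'event_type' ('%s') is not one of the seven AS type codes",
                 ev$event_type), call. = FALSE)
  if (is.na(ev$chrom) || !nzchar(ev$chrom) || grepl("[|:]", ev$chrom))
    stop("as_event: field 'chrom' must be non-empty without '|' or ':'",
         call. = FALSE)
  if (!ev$strand %in% c("+", "-"))
    stop("as_event: field 'strand' must be '+' or '-'", call. = FALSE)
  n <- AS_EVENT_ARITY[[ev$event_type]]
  if (length(ev$coords) != n)
    stop(sprintf("as_event: field 'coords' has arity %d but type %s requires %d",
                 length(ev$coords), ev$event_type, n), call. = FALSE)
  if (anyNA(ev$coords) || any(ev$coords < 1L))
    stop("as_event: field 'coords' must be positive integers", call. = FALSE)
  if (any(diff(ev$coords) <= 0L))
    stop("as_event: field 'coords' must be strictly ascending", call. = FALSE)
  if (!is.null(ev$stats) && !inherits(ev$stats, "das_record"))
    stop("as_event: field 'stats' must be a das_record or NULL", call. = FALSE)
  invisible(ev)
}

#' @exportS3Method print as_event
print.as_event <- function(x, ...) {
  cat(sprintf("<as_event> %s\n", encode_event_id(x)))
  if (!is.null(x$stats))
    cat(sprintf("  p = %.4g, fdr = %.4g, dPSI = %.3f\n",
                x$stats$p_value, x$stats$fdr, x$stats$dpsi))
  invisible(x)
}

#' Encode an event as its canonical ID string
#'
#' The canonical grammar is
#' `<gene>|<type>|<chrom>|<strand>|<c1>:<c2>:...` with strictly ascending
#' 1-based inclusive coordinates. The mapping is one-to-one: distinct valid
#' events yield distinct IDs and [decode_event_id()] inverts it exactly.
#'
#' @param event an `as_event`
#' @return the canonical ID string
#' @examples
#' ev <- as_event("GENE1", "SE", "chr1", "+", c(1000, 1200, 1300, 1500))
#' encode_event_id(ev)  # "GENE1|SE|chr1|+|1000:1200:1300:1500"
#' @export
encode_event_id <- function(event) {
  validate_event(event)
  paste(event$gene, event$event_type, event$chrom, event$strand,
        paste(event$coords, collapse = ":"), sep = "|")
}

#' Decode a canonical event ID string
#'
#' Inverse of [encode_event_id()] on its image. Statistics and source are
#' not part of the ID; the decoded event carries `source = "catalog"` and no
#' stats.
#'
#' @param id a canonical ID string
#' @return an `as_event`
#' @export
decode_event_id <- function(id) {
  if (length(id) != 1L || is.na(id))
    stop("decode_event_id: id must be a single string", call. = FALSE)
  parts <- strsplit(id, "|", fixed = TRUE)[[1L]]
  if (length(parts) != 5L)
    stop(sprintf("decode_event_id: expected 5 '|'-separated fields, got %d in '%s'",
                 length(parts), id), call. = FALSE)
  type <- parts[2L]
  if (!type %in% AS_EVENT_TYPES)
    stop(sprintf("decode_event_id: unknown type code '%s' at field 2", type),
         call. = FALSE)
  coords_str <- strsplit(parts[5L], ":", fixed = TRUE)[[1L]]
  coords <- suppressWarnings(as.integer(coords_str))
  if (anyNA(coords))
    stop(sprintf("decode_event_id: non-integer coordinate at field 5 ('%s')",
                 parts[5L]), call. = FALSE)
  if (length(coords) != AS_EVENT_ARITY[[type]])
    stop(sprintf("decode_event_id: type %s requires arity %d, got %d at field 5",
                 type, AS_EVENT_ARITY[[type]], length(coords)), call. = FALSE)
  as_event(gene = parts[1L], event_type = type, chrom = parts[3L],
           strand = parts[4L], coords = coords)
}

#' Decompose an event into its annotation regions
#'
#' Splits an event into *distinct* region(s) (the segment whose usage
#' differs between isoform forms), *common* anchors (junction-adjacent
#' constitutive coordinates; full exon extents for RI where the tuple
#' carries them), splice-site *boundary* windows of width `2*w + 1` centered
#' on each edge of each distinct region, and *flanking introns*.
#'
#' For MXE/AF/AL the two distinct regions are labeled
#' `"inclusion"`/`"exclusion"`: the genomically first alternative region in
#' the coordinate tuple is the inclusion side (the form whose junctions are
#' listed first by the upstream tools).
#'
#' @param event an `as_event`
#' @param w boundary half-width in bp (default 10); windows are
#'   `[edge - w, edge + w]`
#' @return a list of class `event_regions` with elements `distinct`,
#'   `common`, `boundaries`, `flanking_introns` (each a genomic-interval
#'   data.frame, see [genomic_interval()])
#' @export
decompose_regions <- function(event, w = 10L) {
  validate_event(event)
  w <- as.integer(w)
  if (is.na(w) || w < 0L) stop("decompose_regions: w must be >= 0", call. = FALSE)
  ch <- event$chrom; st <- event$strand; cc <- event$coords
  gi <- function(s, e, label = NA_character_) {
    if (length(s) == 0L) return(genomic_interval(character(), integer(), integer()))
    genomic_interval(ch, s, e, st, label)
  }
  type <- event$event_type

  if (type == "SE") {
    distinct <- gi(cc[2L], cc[3L], "distinct")
    common <- gi(c(cc[1L], cc[4L]), c(cc[1L], cc[4L]), "common")
    introns <- gi(c(cc[1L] + 1L, cc[3L] + 1L), c(cc[2L] - 1L, cc[4L] - 1L), "intron")
  } else if (type == "RI") {
    if (cc[3L] - cc[2L] < 2L)
      stop("decompose_regions: degenerate RI event (no intron between exons)",
           call. = FALSE)
    distinct <- gi(cc[2L] + 1L, cc[3L] - 1L, "distinct")
    common <- gi(c(cc[1L], cc[3L]), c(cc[2L], cc[4L]), "common")
    introns <- gi(integer(), integer())
  } else if (type %in% c("A5SS", "A3SS")) {
    distinct <- gi(cc[2L], cc[3L], "distinct")
    common <- gi(c(cc[1L], cc[4L]), c(cc[1L], cc[4L]), "common")
    i_s <- integer(); i_e <- integer()
    if (cc[2L] - cc[1L] > 1L) { i_s <- c(i_s, cc[1L] + 1L); i_e <- c(i_e, cc[2L] - 1L) }
    if (cc[4L] - cc[3L] > 1L) { i_s <- c(i_s, cc[3L] + 1L); i_e <- c(i_e, cc[4L] - 1L) }
    introns <- gi(i_s, i_e, "intron")
  } else if (type == "MXE") {
    distinct <- gi(c(cc[2L], cc[4L]), c(cc[3L], cc[5L]),
                   c("inclusion", "exclusion"))
    common <- gi(c(cc[1L], cc[6L]), c(cc[1L], cc[6L]), "common")
    introns <- gi(c(cc[1L] + 1L, cc[3L] + 1L, cc[5L] + 1L),
                  c(cc[2L] - 1L, cc[4L] - 1L, cc[6L] - 1L), "intron")
  } else { # AF / AL: coords = two terminal exons + one shared junction anchor
    anchor_last <- (type == "AF" && st == "+") || (type == "AL" && st == "-")
    if (anchor_last) {
      ex <- rbind(c(cc[1L], cc[2L]), c(cc[3L], cc[4L]))
      anchor <- cc[5L]
      i_s <- c(cc[2L] + 1L, cc[4L] + 1L); i_e <- c(anchor - 1L, anchor - 1L)
    } else {
      ex <- rbind(c(cc[2L], cc[3L]), c(cc[4L], cc[5L]))
      anchor <- cc[1L]
      i_s <- c(anchor + 1L, anchor + 1L); i_e <- c(cc[2L] - 1L, cc[4L] - 1L)
    }
    # inclusion side = the alternative exon nearest the gene body junction
    # listed first in transcription order: keep genomic-first as inclusion.
    distinct <- gi(ex[, 1L], ex[, 2L], c("inclusion", "exclusion"))
    common <- gi(anchor, anchor, "common")
    keep <- i_e >= i_s
    introns <- gi(i_s[keep], i_e[keep], "intron")
  }

  if (any(distinct$end < distinct$start))
    stop("decompose_regions: degenerate event with zero-length distinct region",
         call. = FALSE)
  edges <- unlist(lapply(seq_len(nrow(distinct)), function(i)
    c(distinct$start[i], distinct$end[i])))
  if (any(edges - w < 1L))
    stop("decompose_regions: boundary window extends below position 1",
         call. = FALSE)
  boundaries <- gi(edges - w, edges + w, "boundary")

  structure(list(distinct = distinct, common = common,
                 boundaries = boundaries, flanking_introns = introns,
                 w = w),
            class = "event_regions")
}
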