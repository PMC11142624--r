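#' @title DAS-result converters
#' @description
#' Parsers turning rMATS, SUPPA, spliceR-style and generic TSV differential
#' alternative-splicing outputs into canonical [as_event()] lists plus a
#' [conversion_report]. Row-level problems (bad coordinates, malformed
#' event strings, unknown isoforms) are recorded per row and never abort
#' the run; missing required columns abort with a schema error.
#' @name converters
NULL

new_report <- function(n_input, n_converted, n_duplicates, failures) {
  rep <- list(n_input = n_input, n_converted = n_converted,
              n_duplicates = n_duplicates, n_failed = nrow(failures),
              failures = failures)
  stopifnot(rep$n_input == rep$n_converted + rep$n_duplicates + rep$n_failed)
  structure(rep, class = "conversion_report")
}

#' @exportS3Method print conversion_report
print.conversion_report <- function(x, ...) {
  cat(sprintf("<conversion_report> input %d | converted %d | duplicates %d | failed %d\n",
              x$n_input, x$n_converted, x$n_duplicates, x$n_failed))
  invisible(x)
}

empty_failures <- function() {
  data.frame(row = integer(), reason = character(), stringsAsFactors = FALSE)
}

safe_stat <- function(x, lo, hi) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v) || v < lo || v > hi) NA_real_ else v
}

row_stats <- function(p, fdr, dpsi) {
  das_record(p_value = safe_stat(p, 0, 1), fdr = safe_stat(fdr, 0, 1),
             dpsi = safe_stat(dpsi, -1, 1))
}

# shared row-accounting loop: `one_row(i)` returns a list of as_event
# (possibly empty) or signals an error -> row failure.
convert_rows <- function(n, one_row) {
  events <- list(); seen <- character()
  n_conv <- 0L; n_dup <- 0L
  failures <- empty_failures()
  for (i in seq_len(n)) {
    evs <- tryCatch(one_row(i), error = function(e) e)
    if (inherits(evs, "error")) {
      failures <- rbind(failures,
                        data.frame(row = i, reason = conditionMessage(evs),
                                   stringsAsFactors = FALSE))
      next
    }
    ids <- vapply(evs, encode_event_id, character(1))
    fresh <- !(ids %in% seen)
    if (length(evs) > 0L && !any(fresh)) {
      n_dup <- n_dup + 1L
    } else {
      n_conv <- n_conv + 1L
      events <- c(events, evs[fresh])
      seen <- c(seen, ids[fresh])
    }
  }
  list(events = events, report = new_report(n, n_conv, n_dup, failures))
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

need_int <- function(x, col) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v) || v != round(v))
    stop(sprintf("non-numeric coordinate in column '%s'", col), call. = FALSE)
  as.integer(v)
}

rmats_coord_columns <- list(
  SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  MXE  = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart_0base",
           "2ndExonEnd", "upstreamES", "upstreamEE", "downstreamES",
           "downstreamEE"),
  RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"))

#' Parse an rMATS junction-count result file
#'
#' Reads a `*.MATS.JC.txt`-style tab-separated table for one event type.
#' Columns suffixed `_0base` are 0-based starts and are shifted by +1 to
#' the 1-based inclusive convention; all other coordinate columns are taken
#' as written. `PValue`/`FDR`/`IncLevelDifference` map onto the event's
#' statistics; rows whose statistics fail to parse keep the event with
#' absent statistics (significance filtering is the caller's job).
#'
#' @param path file path
#' @param event_type one of `"SE"`, `"MXE"`, `"RI"`, `"A5SS"`, `"A3SS"`
#'   (rMATS does not emit AF/AL)
#' @return list with `$events` (deduplicated [as_event()]s) and `$report`
#'   (a `conversion_report`)
#' @export
parse_rmats <- function(path, event_type) {
  if (!event_type %in% names(rmats_coord_columns))
    stop(sprintf("parse_rmats: unsupported rMATS event type '%s'", event_type),
         call. = FALSE)
  cols <- rmats_coord_columns[[event_type]]
  required <- c("GeneID", "geneSymbol", "chr", "strand", cols,
                "PValue", "FDR", "IncLevelDifference")
  df <- read_tsv_checked(path, required, "parse_rmats")

  one_row <- function(i) {
    r <- df[i, , drop = FALSE]
    v <- vapply(cols, function(cl) {
      x <- need_int(r[[cl]], cl)
      if (grepl("_0base$", cl)) x + 1L else x
    }, integer(1))
    names(v) <- cols
    strand <- as.character(r$strand)
    coords <- switch(event_type,
      SE = c(v[["upstreamEE"]], v[["exonStart_0base"]], v[["exonEnd"]],
             v[["downstreamES"]]),
      MXE = {
        p1 <- c(v[["1stExonStart_0base"]], v[["1stExonEnd"]])
        p2 <- c(v[["2ndExonStart_0base"]], v[["2ndExonEnd"]])
        if (p1[1L] > p2[1L]) { tmp <- p1; p1 <- p2; p2 <- tmp }
        c(v[["upstreamEE"]], p1, p2, v[["downstreamES"]])
      },
      RI = c(v[["upstreamES"]], v[["upstreamEE"]], v[["downstreamES"]],
             v[["downstreamEE"]]),
      A5SS = if (strand == "+")
        c(v[["shortEE"]], v[["shortEE"]] + 1L, v[["longExonEnd"]],
          v[["flankingES"]])
      else
        c(v[["flankingEE"]], v[["longExonStart_0base"]], v[["shortES"]] - 1L,
          v[["shortES"]]),
      A3SS = if (strand == "+")
        c(v[["flankingEE"]], v[["longExonStart_0base"]], v[["shortES"]] - 1L,
          v[["shortES"]])
      else
        c(v[["shortEE"]], v[["shortEE"]] + 1L, v[["longExonEnd"]],
          v[["flankingES"]]))
    gene <- as.character(r$geneSymbol)
    if (is.na(gene) || !nzchar(gene)) gene <- as.character(r$GeneID)
    list(as_event(gene, event_type, as.character(r$chr), strand, coords,
                  source = "rmats",
                  stats = row_stats(r$PValue, r$FDR, r$IncLevelDifference)))
  }
  convert_rows(nrow(df), one_row)
}

suppa_type_map <- c(SE = "SE", MX = "MXE", RI = "RI", A5 = "A5SS",
                    A3 = "A3SS", AF = "AF", AL = "AL")

parse_suppa_event_string <- function(s) {
  halves <- strsplit(s, ";", fixed = TRUE)[[1L]]
  if (length(halves) != 2L)
    stop(sprintf("malformed SUPPA event '%s': expected '<gene>;<event>'", s),
         call. = FALSE)
  gene <- halves[1L]
  toks <- strsplit(halves[2L], ":", fixed = TRUE)[[1L]]
  if (length(toks) < 4L)
    stop(sprintf("malformed SUPPA event '%s': too few ':' fields", s),
         call. = FALSE)
  token <- toks[1L]
  if (!token %in% names(suppa_type_map))
    stop(sprintf("unknown SUPPA type token '%s' in '%s'", token, s),
         call. = FALSE)
  type <- suppa_type_map[[token]]
  chrom <- toks[2L]
  strand <- toks[length(toks)]
  if (!strand %in% c("+", "-"))
    stop(sprintf("malformed SUPPA event '%s': bad strand token '%s'", s, strand),
         call. = FALSE)
  mid <- toks[seq.int(3L, length(toks) - 1L)]
  ints <- function(tok) {
    v <- suppressWarnings(as.integer(strsplit(tok, "-", fixed = TRUE)[[1L]]))
    if (anyNA(v)) stop(sprintf("malformed coordinate token '%s' in '%s'",
                               tok, s), call. = FALSE)
    v
  }
  pieces <- lapply(mid, ints)
  coords <- switch(type,
    SE = {
      if (length(pieces) != 2L || any(lengths(pieces) != 2L))
        stop(sprintf("SE event '%s' requires two junction tokens", s), call. = FALSE)
      c(pieces[[1L]], pieces[[2L]])
    },
    MXE = {
      if (length(pieces) != 4L || any(lengths(pieces) != 2L))
        stop(sprintf("MX event '%s' requires four junction tokens", s), call. = FALSE)
      u <- sort(unique(unlist(pieces)))
      if (length(u) != 6L)
        stop(sprintf("MX event '%s' does not reduce to 6 coordinates", s),
             call. = FALSE)
      u
    },
    RI = {
      if (length(pieces) != 3L || !identical(lengths(pieces), c(1L, 2L, 1L)))
        stop(sprintf("RI event '%s' requires s1:e1-s2:e2 tokens", s), call. = FALSE)
      c(pieces[[1L]], pieces[[2L]], pieces[[3L]])
    },
    A5SS = ,
    A3SS = {
      if (length(pieces) != 2L || any(lengths(pieces) != 2L))
        stop(sprintf("%s event '%s' requires two junction tokens", token, s),
             call. = FALSE)
      j1 <- pieces[[1L]]; j2 <- pieces[[2L]]
      if (j1[2L] == j2[2L] && j1[1L] != j2[1L]) {
        d <- sort(c(j1[1L], j2[1L]))
        c(d[1L], d[1L] + 1L, d[2L], j1[2L])
      } else if (j1[1L] == j2[1L] && j1[2L] != j2[2L]) {
        t <- sort(c(j1[2L], j2[2L]))
        c(j1[1L], t[1L], t[2L] - 1L, t[2L])
      } else {
        stop(sprintf("%s event '%s': junctions share no coordinate", token, s),
             call. = FALSE)
      }
    },
    AF = ,
    AL = {
      u <- sort(unique(unlist(pieces)))
      if (length(u) != 5L)
        stop(sprintf("%s event '%s' does not reduce to 5 coordinates", token, s),
             call. = FALSE)
      u
    })
  list(gene = gene, type = type, chrom = chrom, strand = strand,
       coords = coords)
}

#' Parse a SUPPA event file (.dpsi / .ioe style)
#'
#' Accepts any tab-separated table carrying SUPPA event strings
#' (`<gene>;<TYPE>:<chrom>:<junctions...>:<strand>`, 1-based) in a column
#' named `event_id`/`Event` (or the first column). dPSI and p-value columns
#' are located by name (`dPSI`, `p-val`/`pval`) when present.
#'
#' @param path file path
#' @return list with `$events` and `$report` as for [parse_rmats()]
#' @export
parse_suppa <- function(path) {
  if (!file.exists(path)) stop(sprintf("parse_suppa: file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ev_col <- intersect(c("event_id", "Event", "event"), names(df))
  ev_col <- if (length(ev_col) > 0L) ev_col[1L] else names(df)[1L]
  dpsi_col <- grep("dpsi", names(df), ignore.case = TRUE, value = TRUE)
  p_col <- grep("p.?val", names(df), ignore.case = TRUE, value = TRUE)

  one_row <- function(i) {
    parsed <- parse_suppa_event_string(as.character(df[[ev_col]][i]))
    stats <- row_stats(if (length(p_col)) df[[p_col[1L]]][i] else NA,
                       NA, if (length(dpsi_col)) df[[dpsi_col[1L]]][i] else NA)
    list(as_event(parsed$gene, parsed$type, parsed$chrom, parsed$strand,
                  parsed$coords, source = "suppa", stats = stats))
  }
  convert_rows(nrow(df), one_row)
}

#' Parse a spliceR-style isoform-pair table
#'
#' Two-step conversion: each row's isoform identifiers are resolved to exon
#' chains through the annotation, then [classify_transcript_pair()] maps
#' the structural differences onto canonical events, all carrying the row's
#' statistics. A pair spanning several differences emits several events; a
#' pair of identical isoforms emits none (counted as converted).
#'
#' @param path TSV with columns `isoform_a`, `isoform_b`, and optional
#'   `p_value`, `fdr`, `dpsi`
#' @param annotation a [tx_annotation()] resolving the isoform ids
#' @return list with `$events` and `$report` as for [parse_rmats()]
#' @export
parse_splicer <- function(path, annotation) {
  df <- read_tsv_checked(path, c("isoform_a", "isoform_b"), "parse_splicer")
  one_row <- function(i) {
    a <- as.character(df$isoform_a[i]); b <- as.character(df$isoform_b[i])
    for (id in c(a, b))
      if (is.null(annotation$transcripts[[id]]))
        stop(sprintf("unknown isoform '%s'", id), call. = FALSE)
    stats <- row_stats(df$p_value[i], df$fdr[i], df$dpsi[i])
    cls <- classify_transcript_pair(annotation$transcripts[[a]],
                                    annotation$transcripts[[b]],
                                    stats = stats)
    lapply(cls$events, function(ev) { ev$source <- "splicer"; ev })
  }
  # optional stats columns: absent -> NULL indexing yields NULL; normalize
  if (is.null(df$p_value)) df$p_value <- NA_real_
  if (is.null(df$fdr)) df$fdr <- NA_real_
  if (is.null(df$dpsi)) df$dpsi <- NA_real_
  convert_rows(nrow(df), one_row)
}

#' Parse the generic canonical TSV dialect
#'
#' Columns: `gene, type, chrom, strand, c1..c6, p_value, fdr, dpsi`, with
#' unused coordinate cells empty. This is the documented entry point for
#' DAS tools without a dedicated converter.
#'
#' @param path file path
#' @return list with `$events` and `$report` as for [parse_rmats()]
#' @export
parse_generic <- function(path) {
  df <- read_tsv_checked(path, c("gene", "type", "chrom", "strand",
                                 paste0("c", 1:6), "p_value", "fdr", "dpsi"),
                         "parse_generic")
  one_row <- function(i) {
    r <- df[i, , drop = FALSE]
    raw <- unlist(r[paste0("c", 1:6)], use.names = FALSE)
    raw <- raw[!is.na(raw) & nzchar(as.character(raw))]
    coords <- vapply(seq_along(raw), function(k) need_int(raw[k], paste0("c", k)),
                     integer(1))
    list(as_event(as.character(r$gene), as.character(r$type),
                  as.character(r$chrom), as.character(r$strand), coords,
                  source = "generic",
                  stats = row_stats(r$p_value, r$fdr, r$dpsi)))
  }
  convert_rows(nrow(df), one_row)
}

#' Write converted events as a canonical-ID TSV
#'
#' @param events list of [as_event()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_events_tsv <- function(events, path) {
  df <- events_to_frame(events)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a list of events to a data.frame
#'
#' @param events list of [as_event()]
#' @return data.frame with columns event_id, gene, event_type, chrom,
#'   strand, coords, source, p_value, fdr, dpsi
#' @export
events_to_frame <- function(events) {
  if (length(events) == 0L)
    return(data.frame(event_id = character(), gene = character(),
                      event_type = character(), chrom = character(),
                      strand = character(), coords = character(),
                      source = character(), p_value = numeric(),
                      fdr = numeric(), dpsi = numeric(),
                      stringsAsFactors = FALSE))
  stat <- function(ev, f) if (is.null(ev$stats)) NA_real_ else ev$stats[[f]]
  data.frame(
    event_id = vapply(events, encode_event_id, character(1)),
    gene = vapply(events, `[[`, character(1), "gene"),
    event_type = vapply(events, `[[`, character(1), "event_type"),
    chrom = vapply(events, `[[`, character(1), "chrom"),
    strand = vapply(events, `[[`, character(1), "strand"),
    coords = vapply(events, function(e) paste(e$coords, collapse = ":"),
                    character(1)),
    source = vapply(events, `[[`, character(1), "source"),
    p_value = vapply(events, stat, numeric(1), "p_value"),
    fdr = vapply(events, stat, numeric(1), "fdr"),
    dpsi = vapply(events, stat, numeric(1), "dpsi"),
    stringsAsFactors = FALSE)
}

#' Filter events on significance thresholds
#'
#' The case-study style cut (`p < 0.05`, `|dPSI| > 0.1`) is a caller
#' choice, never hard-coded in the converters.
#'
#' @param events list of [as_event()]
#' @param p_max keep events with `p_value < p_max` (NA stats never pass)
#' @param dpsi_min keep events with `|dpsi| > dpsi_min`
#' @return filtered list
#' @export
filter_events <- function(events, p_max = 0.05, dpsi_min = 0.1) {
  keep <- vapply(events, function(ev) {
    if (is.null(ev$stats)) return(FALSE)
    !is.na(ev$stats$p_value) && !is.na(ev$stats$dpsi) &&
      ev$stats$p_value < p_max && abs(ev$stats$dpsi) > dpsi_min
  }, logical(1))
  events[keep]
}
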