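#' Specification for the synthetic fixture generator
#'
#' Every generator below is a pure function of this spec (seed included):
#' identical specs give byte-identical output files. A single integer seed
#' drives one master stream; each sub-generator derives its own stream
#' from the seed plus a fixed tag, so adding a generator never perturbs
#' the output of earlier ones.
#'
#' @param seed master RNG seed (integer)
#' @param n_genes number of genes, one planted AS event per gene
#' @param type_mix named proportions over the seven event types (summing
#'   to 1)
#' @param feature_density named per-class probability of planting a
#'   feature inside the event's rule region (decoys outside the rule
#'   regions are always planted)
#' @param frac_significant fraction of planted events given a significant
#'   DAS signal (p < 0.05 and |dPSI| above `dpsi_magnitude`)
#' @param dpsi_magnitude absolute dPSI of significant events
#' @param boundary_width splice-site boundary half-width `w` in bp used
#'   when planting boundary edge cases
#' @param n_sets,set_size,target_logodds,base_rate gene-set generator
#'   parameters: number of decoy sets, genes per set, log-odds boost for
#'   target-set genes entering the simulated DAS gene list, and baseline
#'   inclusion rate
#' @return a list of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, n_genes = 20L,
                         type_mix = c(SE = 0.30, RI = 0.15, MXE = 0.15,
                                      A5SS = 0.10, A3SS = 0.10, AF = 0.10,
                                      AL = 0.10),
                         feature_density = c(CONS = 0.7, MUT = 0.7,
                                             REPEAT = 0.7, MIRNA_BS = 0.7,
                                             RBP_BS = 0.7, EXON_USAGE = 0.7,
                                             DOMAIN = 0.7, PTM = 0.7,
                                             PPI = 0.7, LOCALIZATION = 0.7,
                                             SPLICE_SITE_VARIANT = 0.7),
                         frac_significant = 0.5, dpsi_magnitude = 0.3,
                         boundary_width = 10L,
                         n_sets = 20L, set_size = 25L, target_logodds = 3,
                         base_rate = 0.1) {
  if (abs(sum(type_mix) - 1) > 1e-8)
    stop("fixture_spec: type_mix proportions must sum to 1", call. = FALSE)
  if (!all(names(type_mix) %in% AS_EVENT_TYPES))
    stop("fixture_spec: unknown event type in type_mix", call. = FALSE)
  if (any(feature_density < 0))
    stop("fixture_spec: feature densities must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 type_mix = type_mix, feature_density = feature_density,
                 frac_significant = frac_significant,
                 dpsi_magnitude = dpsi_magnitude,
                 boundary_width = as.integer(boundary_width),
                 n_sets = as.integer(n_sets), set_size = as.integer(set_size),
                 target_logodds = target_logodds, base_rate = base_rate),
            class = "fixture_spec")
}

# derived sub-stream seed; stays well below 2^31
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_stream <- function(seed, tag, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, tag))
  force(code)
}

write_gtf <- function(annotation, path) {
  lines <- character()
  for (id in names(annotation$transcripts)) {
    tx <- annotation$transcripts[[id]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene, tx$tx_id)
    span <- sprintf("%s\tasannot\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                    tx$chrom, min(tx$exons$start), max(tx$exons$end),
                    tx$strand, attrs)
    ex <- sprintf("%s\tasannot\texon\t%d\t%d\t.\t%s\t.\t%s",
                  tx$chrom, tx$exons$start, tx$exons$end, tx$strand, attrs)
    cds <- if (!is.null(tx$cds))
      sprintf("%s\tasannot\tCDS\t%d\t%d\t.\t%s\t0\t%s",
              tx$chrom, tx$cds$start, tx$cds$end, tx$strand, attrs)
    else character()
    lines <- c(lines, span, ex, cds)
  }
  writeLines(lines, path)
  invisible(path)
}

# genomic CDS span for a synthetic transcript: start codon in the second
# transcription exon, stop codon inside the transcription-last exon; total
# length trimmed to a codon multiple at the 3' end
make_cds <- function(exons, strand) {
  n <- nrow(exons)
  if (n < 2L) return(NULL)
  if (strand == "+") { lo <- exons$start[2L] + 9L; hi <- exons$start[n] + 20L }
  else { lo <- exons$end[1L] - 20L; hi <- exons$end[n - 1L] - 9L }
  segs <- exons[exons$end >= lo & exons$start <= hi, , drop = FALSE]
  if (nrow(segs) == 0L) return(NULL)
  segs$start <- pmax(segs$start, lo); segs$end <- pmin(segs$end, hi)
  extra <- sum(segs$end - segs$start + 1L) %% 3L
  if (extra > 0L) {
    if (strand == "+") segs$end[nrow(segs)] <- segs$end[nrow(segs)] - extra
    else segs$start[1L] <- segs$start[1L] + extra
  }
  segs
}

build_gene_fixture <- function(gene, type, chrom, strand, origin) {
  # base chain: 6 exons, generous introns so every construction fits
  widths <- sample(90:180, 6L, replace = TRUE)
  introns <- sample(400:900, 5L, replace = TRUE)
  starts <- integer(6L); ends <- integer(6L)
  pos <- origin
  for (i in 1:6) {
    starts[i] <- pos
    ends[i] <- pos + widths[i] - 1L
    pos <- ends[i] + if (i < 6L) introns[i] else 0L
  }
  base <- data.frame(start = starts, end = ends)
  ex1 <- base; ex2 <- base
  if (type == "SE") {
    ex2 <- base[-3L, ]
  } else if (type == "RI") {
    ex2 <- base
    ex2$end[3L] <- base$end[4L]
    ex2 <- ex2[-4L, ]
  } else if (type == "MXE") {
    alt <- data.frame(start = base$end[3L] + 150L, end = base$end[3L] + 249L)
    ex2 <- rbind(base[1:2, ], alt, base[4:6, ])
  } else if ((type == "A5SS" && strand == "+") ||
             (type == "A3SS" && strand == "-")) {
    ex2$end[3L] <- base$end[3L] + 60L       # alternative donor/acceptor, right edge
  } else if (type %in% c("A5SS", "A3SS")) {
    ex2$start[3L] <- base$start[3L] - 60L   # left edge
  } else if ((type == "AF" && strand == "+") ||
             (type == "AL" && strand == "-")) {
    alt <- data.frame(start = base$end[1L] + 120L, end = base$end[1L] + 219L)
    ex2 <- rbind(alt, base[2:6, ])          # alternative genomic-left terminus
  } else { # AL "+" or AF "-": alternative genomic-right terminus
    alt <- data.frame(start = base$end[5L] + 120L, end = base$end[5L] + 219L)
    ex2 <- rbind(base[1:5, ], alt)
  }
  tx1 <- transcript(paste0(gene, ".t1"), gene, chrom, strand, ex1,
                    cds = make_cds(ex1, strand))
  tx2 <- transcript(paste0(gene, ".t2"), gene, chrom, strand, ex2,
                    cds = make_cds(ex2, strand))
  list(tx1 = tx1, tx2 = tx2)
}

#' Simulate a transcript annotation with one planted AS event per gene
#'
#' Each gene carries two transcripts whose exon-chain difference is exactly
#' one event of the requested type mix; the truth table records each
#' planted event's canonical ID and the inclusion/exclusion isoforms. The
#' toy genome uses short contigs so brute-force oracles remain fast.
#'
#' @param spec a [fixture_spec()]
#' @param dir output directory for `annotation.gtf` (created if needed);
#'   `NULL` skips writing
#' @return list with `$annotation` ([tx_annotation()]), `$truth`
#'   (data.frame: gene, event_id, event_type, chrom, strand, coords,
#'   tx_inclusion, tx_exclusion) and `$gtf` (path or NULL)
#' @export
simulate_annotation <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  res <- with_stream(spec$seed, "annotation", {
    n <- spec$n_genes
    if (n == 0L) {
      list(annotation = tx_annotation(list()),
           truth = data.frame(gene = character(), event_id = character(),
                              event_type = character(), chrom = character(),
                              strand = character(), coords = character(),
                              tx_inclusion = character(),
                              tx_exclusion = character(),
                              stringsAsFactors = FALSE))
    } else {
      types <- sample(names(spec$type_mix), n, replace = TRUE,
                      prob = spec$type_mix)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      txs <- list(); rows <- list()
      for (g in seq_len(n)) {
        gene <- sprintf("GENE%03d", g)
        chrom <- paste0("chr", ((g - 1L) %% 4L) + 1L)
        origin <- 5000L + ((g - 1L) %/% 4L) * 20000L
        fx <- build_gene_fixture(gene, types[g], chrom, strands[g], origin)
        cls <- classify_transcript_pair(fx$tx1, fx$tx2)
        if (length(cls$events) != 1L)
          stop(sprintf("fixture construction for %s (%s) yielded %d events",
                       gene, types[g], length(cls$events)), call. = FALSE)
        ev <- cls$events[[1L]]
        if (ev$event_type != types[g])
          stop(sprintf("fixture construction for %s planted %s but classified %s",
                       gene, types[g], ev$event_type), call. = FALSE)
        part <- map_transcripts_to_event(ev, tx_annotation(list(fx$tx1, fx$tx2)))
        txs <- c(txs, list(fx$tx1, fx$tx2))
        rows[[g]] <- data.frame(gene = gene, event_id = encode_event_id(ev),
                                event_type = ev$event_type, chrom = chrom,
                                strand = strands[g],
                                coords = paste(ev$coords, collapse = ":"),
                                tx_inclusion = part$inclusion[1L],
                                tx_exclusion = part$exclusion[1L],
                                stringsAsFactors = FALSE)
      }
      list(annotation = tx_annotation(txs), truth = do.call(rbind, rows))
    }
  })
  gtf <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gtf <- file.path(dir, "annotation.gtf")
    write_gtf(res$annotation, gtf)
  }
  list(annotation = res$annotation, truth = res$truth, gtf = gtf)
}

exon_with <- function(tx, start = NULL, end = NULL, containing = NULL) {
  ex <- tx$exons
  sel <- rep(TRUE, nrow(ex))
  if (!is.null(start)) sel <- sel & ex$start == start
  if (!is.null(end)) sel <- sel & ex$end == end
  if (!is.null(containing))
    sel <- sel & ex$start <= containing[1L] & ex$end >= containing[2L]
  hit <- ex[sel, , drop = FALSE]
  if (nrow(hit) == 0L) stop("fixture: expected exon not found", call. = FALSE)
  hit[1L, ]
}

rmats_row <- function(ev, annotation, stats_row) {
  cc <- ev$coords
  inc <- annotation$transcripts[[stats_row$tx_inclusion]]
  exc <- annotation$transcripts[[stats_row$tx_exclusion]]
  base <- list(GeneID = ev$gene, geneSymbol = ev$gene, chr = ev$chrom,
               strand = ev$strand)
  coords <- switch(ev$event_type,
    SE = {
      up <- exon_with(inc, end = cc[1L]); dn <- exon_with(inc, start = cc[4L])
      list(exonStart_0base = cc[2L] - 1L, exonEnd = cc[3L],
           upstreamES = up$start, upstreamEE = cc[1L],
           downstreamES = cc[4L], downstreamEE = dn$end)
    },
    MXE = {
      up <- exon_with(inc, end = cc[1L]); dn <- exon_with(inc, start = cc[6L])
      list(`1stExonStart_0base` = cc[2L] - 1L, `1stExonEnd` = cc[3L],
           `2ndExonStart_0base` = cc[4L] - 1L, `2ndExonEnd` = cc[5L],
           upstreamES = up$start, upstreamEE = cc[1L],
           downstreamES = cc[6L], downstreamEE = dn$end)
    },
    RI = list(riExonStart_0base = cc[1L] - 1L, riExonEnd = cc[4L],
              upstreamES = cc[1L], upstreamEE = cc[2L],
              downstreamES = cc[3L], downstreamEE = cc[4L]),
    A5SS = ,
    A3SS = {
      long_ex <- exon_with(inc, containing = c(cc[2L], cc[3L]))
      if (cc[2L] == cc[1L] + 1L) {   # shared-left exon edge, alt at right
        short_ex <- exon_with(exc, end = cc[1L])
        flank <- exon_with(inc, start = cc[4L])
        list(longExonStart_0base = long_ex$start - 1L, longExonEnd = cc[3L],
             shortES = short_ex$start, shortEE = cc[1L],
             flankingES = cc[4L], flankingEE = flank$end)
      } else {                       # shared-right exon edge, alt at left
        short_ex <- exon_with(exc, start = cc[4L])
        flank <- exon_with(inc, end = cc[1L])
        list(longExonStart_0base = cc[2L] - 1L, longExonEnd = long_ex$end,
             shortES = cc[4L], shortEE = short_ex$end,
             flankingES = flank$start, flankingEE = cc[1L])
      }
    },
    stop(sprintf("rMATS cannot express %s events", ev$event_type),
         call. = FALSE))
  c(base, coords, list(PValue = stats_row$p_value, FDR = stats_row$fdr,
                       IncLevelDifference = stats_row$dpsi))
}

suppa_event_string <- function(ev) {
  cc <- ev$coords; ch <- ev$chrom; st <- ev$strand
  body <- switch(ev$event_type,
    SE = sprintf("SE:%s:%d-%d:%d-%d:%s", ch, cc[1L], cc[2L], cc[3L], cc[4L], st),
    MXE = sprintf("MX:%s:%d-%d:%d-%d:%d-%d:%d-%d:%s", ch, cc[1L], cc[2L],
                  cc[3L], cc[6L], cc[1L], cc[4L], cc[5L], cc[6L], st),
    RI = sprintf("RI:%s:%d:%d-%d:%d:%s", ch, cc[1L], cc[2L], cc[3L], cc[4L], st),
    A5SS = ,
    A3SS = {
      tok <- if (ev$event_type == "A5SS") "A5" else "A3"
      if (cc[2L] == cc[1L] + 1L)
        sprintf("%s:%s:%d-%d:%d-%d:%s", tok, ch, cc[3L], cc[4L], cc[1L], cc[4L], st)
      else
        sprintf("%s:%s:%d-%d:%d-%d:%s", tok, ch, cc[1L], cc[2L], cc[1L], cc[4L], st)
    },
    AF = ,
    AL = {
      tok <- ev$event_type
      anchor_last <- (tok == "AF" && st == "+") || (tok == "AL" && st == "-")
      if (anchor_last)
        sprintf("%s:%s:%d:%d-%d:%d:%d-%d:%s", tok, ch, cc[1L], cc[2L], cc[5L],
                cc[3L], cc[4L], cc[5L], st)
      else
        sprintf("%s:%s:%d-%d:%d:%d-%d:%d:%s", tok, ch, cc[1L], cc[2L], cc[3L],
                cc[1L], cc[4L], cc[5L], st)
    })
  paste0(ev$gene, ";", body)
}

#' Render the planted events in every supported DAS dialect
#'
#' The same planted events are written as rMATS junction-count tables (the
#' five rMATS-expressible types), a SUPPA dPSI table (all seven types), the
#' generic TSV dialect (all seven) and a spliceR-style isoform-pair table,
#' all carrying identical statistics drawn once per event.
#'
#' @param sim output of [simulate_annotation()]
#' @param spec the [fixture_spec()]
#' @param dir output directory
#' @return list with `$paths` (named: rmats = named vector by type, suppa,
#'   generic, splicer) and `$truth` (the truth table extended with
#'   p_value, fdr, dpsi)
#' @export
simulate_das_outputs <- function(sim, spec, dir) {
  truth <- sim$truth
  if (nrow(truth) == 0L) stop("simulate_das_outputs: empty truth table",
                              call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- with_stream(spec$seed, "das", {
    n <- nrow(truth)
    sig <- stats::runif(n) < spec$frac_significant
    p <- ifelse(sig, stats::runif(n, 1e-6, 0.049), stats::runif(n, 0.051, 0.999))
    dpsi <- ifelse(sig,
                   sample(c(-1, 1), n, replace = TRUE) *
                     (spec$dpsi_magnitude + stats::runif(n, 0, 0.1)),
                   stats::runif(n, -0.09, 0.09))
    truth$p_value <- round(p, 6)
    truth$fdr <- round(bh_adjust(p), 6)
    truth$dpsi <- round(pmax(pmin(dpsi, 1), -1), 4)
    truth
  })
  events <- lapply(truth$event_id, decode_event_id)

  # rMATS: one file per expressible type
  rmats_paths <- c()
  for (type in c("SE", "MXE", "RI", "A5SS", "A3SS")) {
    idx <- which(truth$event_type == type)
    if (length(idx) == 0L) next
    rows <- lapply(idx, function(i) rmats_row(events[[i]], sim$annotation,
                                              truth[i, ]))
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
    path <- file.path(dir, sprintf("%s.MATS.JC.txt", type))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    rmats_paths[type] <- path
  }

  # SUPPA dPSI-style table
  suppa_path <- file.path(dir, "events.dpsi")
  suppa_df <- data.frame(
    event_id = vapply(events, suppa_event_string, character(1)),
    dPSI = truth$dpsi, `p-val` = truth$p_value,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(suppa_df, suppa_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # generic canonical TSV
  generic_path <- file.path(dir, "events.generic.tsv")
  cmat <- matrix("", nrow = nrow(truth), ncol = 6L)
  for (i in seq_len(nrow(truth))) {
    cc <- events[[i]]$coords
    cmat[i, seq_along(cc)] <- as.character(cc)
  }
  gen_df <- data.frame(gene = truth$gene, type = truth$event_type,
                       chrom = truth$chrom, strand = truth$strand,
                       c1 = cmat[, 1L], c2 = cmat[, 2L], c3 = cmat[, 3L],
                       c4 = cmat[, 4L], c5 = cmat[, 5L], c6 = cmat[, 6L],
                       p_value = truth$p_value, fdr = truth$fdr,
                       dpsi = truth$dpsi, stringsAsFactors = FALSE)
  utils::write.table(gen_df, generic_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # spliceR-style isoform pairs
  splicer_path <- file.path(dir, "events.splicer.tsv")
  spl_df <- data.frame(isoform_a = truth$tx_inclusion,
                       isoform_b = truth$tx_exclusion,
                       gene = truth$gene, p_value = truth$p_value,
                       fdr = truth$fdr, dpsi = truth$dpsi,
                       stringsAsFactors = FALSE)
  utils::write.table(spl_df, splicer_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(paths = list(rmats = rmats_paths, suppa = suppa_path,
                    generic = generic_path, splicer = splicer_path),
       truth = truth)
}

write_bed <- function(df, path) {
  # df: chrom, start, end (1-based inclusive), name
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t+", df$chrom, df$start - 1L, df$end,
                   df$name)
  writeLines(lines, path)
  invisible(path)
}

write_vcf <- function(df, path) {
  # df: chrom, pos, id, ref, alt
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.", df$chrom, df$pos, df$id,
                  df$ref, df$alt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Plant feature tracks with a per-event expected-hit ledger
#'
#' For every planted event and feature class a record is planted inside
#' the class's rule region with the spec's per-class density (and the
#' ledger marks the class column as expected-populated), while decoy
#' records are always planted outside every rule region (dead zones,
#' common exons, or exactly 1 bp outside a boundary window), so annotation
#' against these tracks must reproduce the ledger exactly.
#'
#' @param sim output of [simulate_annotation()]
#' @param spec the [fixture_spec()]
#' @param dir output directory
#' @return list with `$tracks` (named class -> path) and `$ledger`
#'   (data.frame: event_id, class, expected)
#' @export
simulate_feature_tracks <- function(sim, spec, dir) {
  truth <- sim$truth
  annotation <- sim$annotation
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- spec$boundary_width

  out <- with_stream(spec$seed, "tracks", {
    bed <- list(CONS = NULL, REPEAT = NULL, MIRNA_BS = NULL, RBP_BS = NULL)
    vcf <- list(MUT = NULL, SPLICE_SITE_VARIANT = NULL)
    usage <- NULL; domain <- NULL; ptm <- NULL; ppi <- NULL; loc <- NULL
    ledger <- list()
    dens <- spec$feature_density

    add_bed <- function(cls, chrom, s, e, name)
      bed[[cls]] <<- rbind(bed[[cls]], data.frame(chrom = chrom, start = s,
                                                  end = e, name = name,
                                                  stringsAsFactors = FALSE))
    add_vcf <- function(cls, chrom, pos, id)
      vcf[[cls]] <<- rbind(vcf[[cls]], data.frame(chrom = chrom, pos = pos,
                                                  id = id, ref = "A",
                                                  alt = "G",
                                                  stringsAsFactors = FALSE))
    plant <- function(cls) stats::runif(1) < dens[[cls]]

    for (i in seq_len(nrow(truth))) {
      ev <- decode_event_id(truth$event_id[i])
      regions <- decompose_regions(ev, w = w)
      d1 <- regions$distinct[1L, ]
      mid <- as.integer((d1$start + d1$end) %/% 2L)
      # per-gene dead zone: beyond every transcript of this block
      gene_txs <- annotation$genes[[ev$gene]]
      span_hi <- max(vapply(gene_txs, function(id)
        max(annotation$transcripts[[id]]$exons$end), integer(1)))
      dead <- span_hi + 3000L
      exp_row <- function(cls, expected)
        ledger[[length(ledger) + 1L]] <<-
          data.frame(event_id = truth$event_id[i], class = cls,
                     expected = expected, stringsAsFactors = FALSE)

      # simple distinct-region classes
      for (cls in c("CONS", "REPEAT", "MIRNA_BS")) {
        hit <- plant(cls)
        if (hit) add_bed(cls, ev$chrom, mid - 4L, mid + 5L,
                         sprintf("%s_%s", tolower(cls), ev$gene))
        add_bed(cls, ev$chrom, dead, dead + 20L,
                sprintf("%s_decoy_%s", tolower(cls), ev$gene))
        exp_row(cls, hit)
      }

      # point mutations: alternate mid-distinct and the exact boundary
      # window edge; the decoy sits 1 bp outside the window
      hit <- plant("MUT")
      if (hit) {
        pos <- if (i %% 2L == 0L) d1$start - w else mid
        add_vcf("MUT", ev$chrom, pos, sprintf("mut_%s", ev$gene))
      }
      add_vcf("MUT", ev$chrom, d1$start - w - 1L,
              sprintf("mut_decoy_%s", ev$gene))
      exp_row("MUT", hit)

      hit <- plant("SPLICE_SITE_VARIANT")
      if (hit) add_vcf("SPLICE_SITE_VARIANT", ev$chrom, d1$end + w,
                       sprintf("ssv_%s", ev$gene))
      add_vcf("SPLICE_SITE_VARIANT", ev$chrom, d1$end + w + 1L,
              sprintf("ssv_decoy_%s", ev$gene))
      exp_row("SPLICE_SITE_VARIANT", hit)

      # RBP sites: flanking intron when available (every third event as a
      # common-boundary straddler), otherwise mid-distinct; decoy inside
      # the nearest common exon / anchor-adjacent exonic region
      hit <- plant("RBP_BS")
      introns <- regions$flanking_introns
      if (hit) {
        if (nrow(introns) > 0L) {
          it <- introns[1L, ]
          if (i %% 3L == 0L) {
            add_bed("RBP_BS", ev$chrom, it$start - 3L,
                    min(it$start + 6L, it$end),
                    sprintf("rbp_straddle_%s", ev$gene))
          } else {
            imid <- as.integer((it$start + it$end) %/% 2L)
            add_bed("RBP_BS", ev$chrom, imid - 3L, imid + 3L,
                    sprintf("rbp_%s", ev$gene))
          }
        } else {
          add_bed("RBP_BS", ev$chrom, mid - 3L, mid + 3L,
                  sprintf("rbp_%s", ev$gene))
        }
      }
      add_bed("RBP_BS", ev$chrom, dead + 40L, dead + 55L,
              sprintf("rbp_decoy_%s", ev$gene))
      exp_row("RBP_BS", hit)

      # exon usage: the distinct region itself carries per-sample PSI
      hit <- plant("EXON_USAGE")
      if (hit)
        usage <- rbind(usage, data.frame(
          chrom = ev$chrom, start = d1$start, end = d1$end,
          s1 = round(stats::runif(1), 3), s2 = round(stats::runif(1), 3),
          s3 = round(stats::runif(1), 3), stringsAsFactors = FALSE))
      usage <- rbind(usage, data.frame(
        chrom = ev$chrom, start = dead + 80L, end = dead + 120L,
        s1 = 0.5, s2 = 0.5, s3 = 0.5, stringsAsFactors = FALSE))
      exp_row("EXON_USAGE", hit)

      # protein spans: an aa span covering the distinct region of the
      # carrying isoform (skipped when the region is non-coding there,
      # e.g. untranslated terminal exons)
      inc_tx <- annotation$transcripts[[truth$tx_inclusion[i]]]
      aa_in <- tryCatch(genome_span_to_protein(inc_tx, d1$start, d1$end),
                        error = function(e) NULL)
      aa_common <- tryCatch({
        ex2 <- exon_with(inc_tx, containing = NULL)
        # interior of the second transcription exon, outside the distinct
        cand <- inc_tx$exons[inc_tx$exons$end < d1$start |
                             inc_tx$exons$start > d1$end, , drop = FALSE]
        cand <- cand[(cand$end - cand$start) > 30L, , drop = FALSE]
        if (nrow(cand) == 0L) NULL
        else genome_span_to_protein(inc_tx, cand$start[1L] + 10L,
                                    cand$start[1L] + 19L)
      }, error = function(e) NULL)
      for (cls in c("DOMAIN", "PTM")) {
        hit <- plant(cls) && !is.null(aa_in)
        tbl <- data.frame(tx_id = character(), aa_start = integer(),
                          aa_end = integer(), name = character(),
                          stringsAsFactors = FALSE)
        if (hit)
          tbl <- rbind(tbl, data.frame(
            tx_id = inc_tx$tx_id, aa_start = aa_in[1L], aa_end = aa_in[2L],
            name = sprintf("%s_%s", tolower(cls), ev$gene),
            stringsAsFactors = FALSE))
        if (!is.null(aa_common))
          tbl <- rbind(tbl, data.frame(
            tx_id = inc_tx$tx_id, aa_start = aa_common[1L],
            aa_end = aa_common[2L],
            name = sprintf("%s_decoy_%s", tolower(cls), ev$gene),
            stringsAsFactors = FALSE))
        if (cls == "DOMAIN") domain <- rbind(domain, tbl)
        else ptm <- rbind(ptm, tbl)
        exp_row(cls, hit)
      }

      # isoform-level: PPI partners and localization
      hit <- plant("PPI")
      if (hit)
        ppi <- rbind(ppi, data.frame(
          tx_id = c(truth$tx_inclusion[i], truth$tx_exclusion[i],
                    truth$tx_inclusion[i], truth$tx_exclusion[i]),
          partner = c(sprintf("PARTNER_INC_%s", ev$gene),
                      sprintf("PARTNER_EXC_%s", ev$gene),
                      sprintf("PARTNER_SHARED_%s", ev$gene),
                      sprintf("PARTNER_SHARED_%s", ev$gene)),
          stringsAsFactors = FALSE))
      exp_row("PPI", hit)

      hit <- plant("LOCALIZATION")
      if (hit)
        loc <- rbind(loc, data.frame(
          tx_id = c(truth$tx_inclusion[i], truth$tx_exclusion[i]),
          compartment = c("nucleus", "cytoplasm"),
          stringsAsFactors = FALSE))
      exp_row("LOCALIZATION", hit)

      # NMD derives from the CDS structure; populated whenever either side
      # carries a CDS (always true for these fixtures)
      exp_row("NMD", !is.null(inc_tx$cds) ||
                !is.null(annotation$transcripts[[truth$tx_exclusion[i]]]$cds))
    }
    list(bed = bed, vcf = vcf, usage = usage, domain = domain, ptm = ptm,
         ppi = ppi, loc = loc, ledger = do.call(rbind, ledger))
  })

  tracks <- list()
  for (cls in names(out$bed)) {
    if (is.null(out$bed[[cls]])) next
    path <- file.path(dir, sprintf("%s.bed", tolower(cls)))
    write_bed(out$bed[[cls]], path)
    tracks[[cls]] <- path
  }
  for (cls in names(out$vcf)) {
    if (is.null(out$vcf[[cls]])) next
    path <- file.path(dir, sprintf("%s.vcf", tolower(cls)))
    write_vcf(out$vcf[[cls]], path)
    tracks[[cls]] <- path
  }
  tsv_out <- function(df, name) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  p <- tsv_out(out$usage, "exon_usage.tsv"); if (!is.null(p)) tracks$EXON_USAGE <- p
  p <- tsv_out(out$domain, "domain.tsv"); if (!is.null(p)) tracks$DOMAIN <- p
  p <- tsv_out(out$ptm, "ptm.tsv"); if (!is.null(p)) tracks$PTM <- p
  p <- tsv_out(out$ppi, "ppi.tsv"); if (!is.null(p)) tracks$PPI <- p
  p <- tsv_out(out$loc, "localization.tsv"); if (!is.null(p)) tracks$LOCALIZATION <- p

  list(tracks = tracks, ledger = out$ledger)
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Decoy sets are uniform draws from the universe; the target set's genes
#' enter the simulated DAS gene list with a log-odds boost over the
#' baseline inclusion rate, so over-representation testing should rank the
#' target first when the boost is large and uniformly when it is zero.
#'
#' @param spec a [fixture_spec()]
#' @param universe character vector of candidate genes (at least twice the
#'   set size)
#' @param dir optional output directory for `sets.gmt`
#' @return list with `$sets` (named list incl. the target), `$target`
#'   (set name), `$query` (the simulated DAS gene list) and `$gmt`
#'   (path or NULL)
#' @export
simulate_gene_sets <- function(spec, universe, dir = NULL) {
  universe <- unique(as.character(universe))
  if (length(universe) < 2L * spec$set_size)
    stop("simulate_gene_sets: universe must be at least twice the set size",
         call. = FALSE)
  res <- with_stream(spec$seed, "genesets", {
    sets <- list()
    for (k in seq_len(spec$n_sets)) {
      nm <- sprintf("PW_DECOY_%02d", k)
      sets[[nm]] <- sort(sample(universe, spec$set_size))
    }
    target <- "PW_TARGET"
    sets[[target]] <- sort(sample(universe, spec$set_size))
    boost <- universe %in% sets[[target]]
    prob <- stats::plogis(stats::qlogis(spec$base_rate) +
                          spec$target_logodds * boost)
    repeat {
      query <- universe[stats::runif(length(universe)) < prob]
      if (length(query) > 0L) break
    }
    list(sets = sets, target = target, query = query)
  })
  gmt <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gmt <- file.path(dir, "sets.gmt")
    write_gmt(res$sets, gmt)
  }
  list(sets = res$sets, target = res$target, query = res$query, gmt = gmt)
}

#' Generate a complete fixture tree
#'
#' Runs [simulate_annotation()], [simulate_das_outputs()],
#' [simulate_feature_tracks()] and [simulate_gene_sets()] into one
#' directory.
#'
#' @param spec a [fixture_spec()]
#' @param dir output directory
#' @return list with all component outputs
#' @export
simulate_fixture <- function(spec, dir) {
  sim <- simulate_annotation(spec, dir)
  das <- simulate_das_outputs(sim, spec, dir)
  tracks <- simulate_feature_tracks(sim, spec, dir)
  gene_universe <- unique(c(sim$truth$gene,
                            sprintf("BG%04d", seq_len(max(200L, 4L * spec$set_size)))))
  sets <- simulate_gene_sets(spec, gene_universe, dir)
  list(spec = spec, annotation = sim$annotation, truth = das$truth,
       gtf = sim$gtf, das_paths = das$paths, tracks = tracks$tracks,
       ledger = tracks$ledger, gene_sets = sets)
}
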