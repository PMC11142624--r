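# Independent oracles used across the suite. Everything here is written
# against the definitions, not against the package implementation paths it
# checks.

# -- random valid events for codec properties ------------------------------

random_event <- function() {
  type <- sample(AS_EVENT_TYPES, 1L)
  arity <- c(SE = 4L, MXE = 6L, RI = 4L, A5SS = 4L, A3SS = 4L,
             AF = 5L, AL = 5L)[[type]]
  coords <- sort(sample(100:100000, arity))
  while (any(diff(coords) == 0L)) coords <- sort(sample(100:100000, arity))
  as_event(gene = sprintf("G%04d", sample(1:5000, 1L)), event_type = type,
           chrom = sample(c("chr1", "chr2", "chrX", "chr10_alt"), 1L),
           strand = sample(c("+", "-"), 1L), coords = coords)
}

ivl_overlap <- function(s1, e1, s2, e2) max(s1, s2) <= min(e1, e2)

# -- brute-force interval scan ---------------------------------------------

brute_force_query <- function(records, chrom, start, end,
                              classes = unique(records$class)) {
  hit <- records$chrom == chrom & pmax(records$start, start) <= pmin(records$end, end) &
    records$class %in% classes
  records[hit, , drop = FALSE]
}

# -- hypergeometric upper-tail by explicit enumeration ---------------------

hyper_tail_oracle <- function(k, K, n, N) {
  # P(X >= k) for X ~ Hypergeom(N, K, n), summed term by term
  kmax <- min(K, n)
  if (k > kmax) return(0)
  terms <- vapply(k:kmax, function(x)
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)), numeric(1))
  sum(terms)
}

# -- two-sided Fisher exact p by full margin-fixed enumeration -------------

fisher_enum_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)), numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# -- NMD 50-nt rule by explicit per-base transcript walk -------------------

# build a transcript whose stop codon sits exactly `d` nt upstream of the
# final exon-exon junction (d may be negative: stop inside the last exon);
# returns NULL when the requested geometry does not fit
make_nmd_transcript <- function(id, n_exons, widths, d, strand = "+",
                                origin = 10000L) {
  introns <- rep(300L, n_exons - 1L)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- origin
  for (i in seq_len(n_exons)) {
    starts[i] <- pos; ends[i] <- pos + widths[i] - 1L
    pos <- ends[i] + if (i < n_exons) introns[i] else 0L
  }
  exons <- data.frame(start = starts, end = ends)
  total <- sum(widths)
  tr_widths <- if (strand == "+") widths else rev(widths)
  junction_mrna <- sum(tr_widths[-n_exons]) # mRNA coord of last base before junction
  stop_mrna <- junction_mrna - d
  if (stop_mrna < 10L || stop_mrna > total) return(NULL)
  cds_start_mrna <- stop_mrna - 8L         # 9 nt = 3 codons of coding sequence
  # map mRNA positions to genomic segments by explicit walk
  mrna_to_genomic <- function(p) {
    off <- 0L
    for (i in seq_len(n_exons)) {
      idx <- if (strand == "+") i else n_exons - i + 1L
      len <- widths[idx]
      if (p <= off + len) {
        return(if (strand == "+") exons$start[idx] + (p - off - 1L)
               else exons$end[idx] - (p - off - 1L))
      }
      off <- off + len
    }
    stop("mRNA position out of range")
  }
  g <- vapply(cds_start_mrna:stop_mrna, mrna_to_genomic, integer(1))
  g <- sort(g)
  # collapse consecutive runs into segments
  breaks <- c(0L, which(diff(g) != 1L), length(g))
  cds <- do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(j)
    data.frame(start = g[breaks[j] + 1L], end = g[breaks[j + 1L]])))
  transcript(id, "GNMD", "chr1", strand, exons, cds = cds)
}

# -- independent per-type gene constructions with hand-derived event IDs ---

# Build a two-transcript gene of the requested type; the expected canonical
# coordinates are computed here from the construction arithmetic, not by
# the package classifier.
make_truth_gene <- function(gene, type, strand, origin) {
  w <- c(120L, 130L, 140L, 150L, 160L, 170L)
  gaps <- c(500L, 600L, 700L, 550L, 650L)
  starts <- integer(6L); ends <- integer(6L)
  pos <- origin
  for (i in 1:6) {
    starts[i] <- pos; ends[i] <- pos + w[i] - 1L
    pos <- ends[i] + if (i < 6L) gaps[i] else 0L
  }
  base <- data.frame(start = starts, end = ends)
  ex2 <- base
  expected <- NULL
  if (type == "SE") {
    ex2 <- base[-3L, ]
    expected <- c(ends[2L], starts[3L], ends[3L], starts[4L])
  } else if (type == "RI") {
    ex2$end[3L] <- ends[4L]; ex2 <- ex2[-4L, ]
    expected <- c(starts[3L], ends[3L], starts[4L], ends[4L])
  } else if (type == "MXE") {
    alt <- c(ends[3L] + 200L, ends[3L] + 299L)
    ex2 <- rbind(base[1:2, ], data.frame(start = alt[1L], end = alt[2L]),
                 base[4:6, ])
    expected <- c(ends[2L], starts[3L], ends[3L], alt[1L], alt[2L], starts[4L])
  } else if ((type == "A5SS" && strand == "+") ||
             (type == "A3SS" && strand == "-")) {
    ex2$end[3L] <- ends[3L] + 80L
    expected <- c(ends[3L], ends[3L] + 1L, ends[3L] + 80L, starts[4L])
  } else if (type %in% c("A5SS", "A3SS")) {
    ex2$start[3L] <- starts[3L] - 80L
    expected <- c(ends[2L], starts[3L] - 80L, starts[3L] - 1L, starts[3L])
  } else if ((type == "AF" && strand == "+") ||
             (type == "AL" && strand == "-")) {
    alt <- c(ends[1L] + 150L, ends[1L] + 249L)
    ex2 <- rbind(data.frame(start = alt[1L], end = alt[2L]), base[2:6, ])
    expected <- c(starts[1L], ends[1L], alt[1L], alt[2L], starts[2L])
  } else {
    alt <- c(ends[5L] + 150L, ends[5L] + 249L)
    ex2 <- rbind(base[1:5, ], data.frame(start = alt[1L], end = alt[2L]))
    expected <- c(ends[5L], alt[1L], alt[2L], starts[6L], ends[6L])
  }
  tx1 <- transcript(paste0(gene, ".a"), gene, "chr9", strand, base)
  tx2 <- transcript(paste0(gene, ".b"), gene, "chr9", strand, ex2)
  expected_id <- paste(gene, type, "chr9", strand,
                       paste(expected, collapse = ":"), sep = "|")
  list(tx1 = tx1, tx2 = tx2, expected_id = expected_id)
}

# small reusable fixture tree, built once per test run
fixture_cache <- local({
  cache <- list()
  function(seed = 7L, n_genes = 24L) {
    key <- sprintf("%d_%d", seed, n_genes)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), sprintf("asannot_fx_%s", key))
      cache[[key]] <<- simulate_fixture(fixture_spec(seed = seed,
                                                     n_genes = n_genes), dir)
    }
    cache[[key]]
  }
})
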