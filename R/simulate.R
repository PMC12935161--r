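# Seeded synthetic data: gene annotations with planted ORFs, a matching
# genome, two-group counts with planted expression and usage effects, and a
# hand-written toy locus used in documentation and golden tests.

# Human-like codon usage weights (frequencies per 1000 codons) used to give
# planted ORFs a realistic in-frame hexamer bias.
CODON_WEIGHTS <- c(
  TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9,
  CTT = 13.2, CTC = 19.6, CTA = 7.2, CTG = 39.6,
  ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1,
  TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
  CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
  GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
  TAT = 12.2, TAC = 15.3,
  CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
  AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
  GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
  TGT = 10.6, TGC = 12.6, TGG = 13.2,
  CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4,
  AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
  GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5
)

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# replace every ATG occurrence starting outside [keep_start, keep_end) by ACG
scrub_atg <- function(seq, keep_start = -1L, keep_end = -1L) {
  repeat {
    hits <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    hits <- hits[hits - 1L < keep_start | hits - 1L >= keep_end] # 0-based start
    if (!length(hits)) break
    for (h in hits) substr(seq, h + 1L, h + 1L) <- "C"
  }
  seq
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults match the
#' study conditions used throughout the test-suite simulations: NB dispersion
#' 0.1, Dirichlet-multinomial precision 50, planted log2 fold changes of
#' magnitude 2 and usage shifts of 0.3.
#'
#' @param seed RNG seed; every simulation is bit-reproducible from
#'   `(config, seed)`.
#' @param n_genes number of gene loci.
#' @param isoforms_per_gene,exons_per_gene inclusive integer ranges.
#' @param exon_length,intron_length inclusive nt ranges.
#' @param n_samples samples per group.
#' @param depth expected total counts per sample.
#' @param nb_dispersion NB dispersion of gene totals.
#' @param dm_precision Dirichlet-multinomial precision of isoform splits.
#' @param frac_de fraction of transcripts with a planted fold change.
#' @param lfc planted log2 fold-change magnitude (sign randomized).
#' @param frac_diu fraction of multi-isoform genes with a planted usage shift.
#' @param usage_shift usage shift (proportion units) in planted genes.
#' @param frac_novel fraction of coding transcripts emitted without CDS.
#' @param frac_noncoding fraction of noncoding gene loci.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L,
                       isoforms_per_gene = c(2L, 4L), exons_per_gene = c(4L, 7L),
                       exon_length = c(120L, 300L), intron_length = c(200L, 1500L),
                       n_samples = 10L, depth = 2e5,
                       nb_dispersion = 0.1, dm_precision = 50,
                       frac_de = 0.1, lfc = 2,
                       frac_diu = 0.1, usage_shift = 0.3,
                       frac_novel = 0.3, frac_noncoding = 0.3) {
  cfg <- as.list(environment())
  stopifnot(
    is_count(cfg$n_genes), cfg$n_samples >= 2, cfg$depth > 0,
    cfg$nb_dispersion >= 0, cfg$dm_precision > 0,
    all(c(cfg$frac_de, cfg$frac_diu, cfg$frac_novel, cfg$frac_noncoding) >= 0),
    all(c(cfg$frac_de, cfg$frac_diu, cfg$frac_novel, cfg$frac_noncoding) <= 1),
    cfg$exons_per_gene[1] >= 4L
  )
  if (cfg$exon_length[1] * 2 < 120) {
    iso_abort("exon length range too small to host planted ORFs", "config")
  }
  structure(cfg, class = "sim_config")
}

sample_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep(r[1], n) else sample(seq.int(r[1], r[2]), n, replace = TRUE)
}

#' Simulate an annotated transcriptome with planted ORFs
#'
#' Generates random multi-isoform gene loci on one synthetic chromosome.
#' Isoforms of a gene share a core exon block and differ at the 5' and 3'
#' ends (alternative first/last exons and 5' truncation), so transcription
#' start sites vary while a planted ORF inside the core block is carried by
#' every isoform. Coding loci receive an ATG-initiated ORF with human-like
#' codon bias; all other exonic sequence is scrubbed of ATG so the planted
#' start is unambiguous ground truth. A configurable fraction of coding
#' transcripts is emitted without CDS records (the "novel" set); noncoding
#' loci never carry CDS.
#'
#' @param config a [sim_config()].
#' @return list with `models` ([tx_models]), `genome` (`DNAStringSet`),
#'   `truth` (per-transcript tibble: `coding`, `novel`, `orf_t_start`,
#'   `orf_t_end` including the stop codon) and `config`.
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  chrom <- "chrS1"
  chrom_parts <- list(random_nt(500L))
  cursor <- 500L
  tx_rows <- list()
  exon_rows <- list()
  cds_rows <- list()
  truth_rows <- list()

  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("SIMG%03d", g)
    strand <- if (g %% 2L == 0L) "-" else "+"
    E <- sample_range(config$exons_per_gene)
    exon_lens <- sample_range(config$exon_length, E) # transcript order T1..TE
    intron_lens <- sample_range(config$intron_length, E - 1L)
    coding <- stats::runif(1) > config$frac_noncoding
    m <- sample_range(config$isoforms_per_gene)

    # template sequence in transcript orientation
    exon_seqs <- vapply(exon_lens, random_nt, "")
    template <- paste0(exon_seqs, collapse = "")
    core_off <- exon_lens[1] # template offset where the core block starts
    core_len <- sum(exon_lens[2:(E - 1L)])
    orf <- NULL
    if (coding) {
      max_orf <- 3L * ((core_len - 30L) %/% 3L)
      target <- 3L * (floor(stats::runif(1, 0.5, 0.8) * core_len) %/% 3L)
      orf_nt <- max(75L, min(max_orf, target))
      n_cod <- orf_nt %/% 3L - 2L
      body <- paste(sample(names(CODON_WEIGHTS), n_cod, replace = TRUE, prob = CODON_WEIGHTS),
                    collapse = "")
      orf_seq <- paste0("ATG", body, sample(STOP_CODONS, 1L))
      orf_start <- core_off + 15L # template coordinate, 0-based
      substr(template, orf_start + 1L, orf_start + orf_nt) <- orf_seq
      template <- scrub_atg(template, orf_start, orf_start + orf_nt - 3L)
      orf <- c(start = orf_start, end = orf_start + orf_nt)
    }

    # genomic layout: exons in genomic order (reverse transcript order on -)
    t_order <- seq_len(E)
    g_order <- if (strand == "+") t_order else rev(t_order)
    cursor <- cursor + 400L
    chrom_parts[[length(chrom_parts) + 1L]] <- random_nt(400L)
    g_start <- integer(E)
    g_end <- integer(E)
    for (pos in seq_len(E)) {
      ti <- g_order[pos]
      piece <- exon_seqs[ti]
      if (strand == "-") {
        piece <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(piece)))
      }
      g_start[ti] <- cursor
      cursor <- cursor + exon_lens[ti]
      g_end[ti] <- cursor
      chrom_parts[[length(chrom_parts) + 1L]] <- piece
      if (pos < E) {
        il <- intron_lens[min(ti, E - 1L)]
        chrom_parts[[length(chrom_parts) + 1L]] <- random_nt(il)
        cursor <- cursor + il
      }
    }
    # rebuild template slices into genome is done; but the scrubbed/planted
    # template must be what was written: rewrite exon pieces from template
    # (exon_seqs were pre-scrub). Recompute slices:
    t_cum <- cumsum(c(0L, exon_lens))
    # overwrite chrom_parts entries for this gene's exons with template slices
    # (indices: the exon parts were appended in genomic order)
    part_idx <- length(chrom_parts) - (2L * E - 2L) # index of first exon part
    for (pos in seq_len(E)) {
      ti <- g_order[pos]
      piece <- substring(template, t_cum[ti] + 1L, t_cum[ti + 1L])
      if (strand == "-") {
        piece <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(piece)))
      }
      chrom_parts[[part_idx + 2L * (pos - 1L)]] <- piece
    }

    novel_flags <- if (coding) stats::runif(m) < config$frac_novel else rep(FALSE, m)
    seen <- character()
    for (i in seq_len(m)) {
      tid <- sprintf("%s.T%02d", gid, i)
      s <- if (i == 1L) 1L else sample(1:2, 1L)
      e <- if (i == 1L) E else sample((E - 1L):E, 1L)
      trim <- if (s == 1L && i > 1L) sample(0:(exon_lens[1] %/% 3L), 1L) else 0L
      if (paste(s, e, trim) %in% seen) {
        # force a distinct structure via a unique 5' truncation of exon 1
        s <- 1L
        trim <- 3L * i + sample(0:2, 1L)
      }
      seen <- c(seen, paste(s, e, trim))
      use <- s:e
      es <- g_start[use]
      ee <- g_end[use]
      if (trim > 0L) {
        if (strand == "+") es[1] <- es[1] + trim else ee[1] <- ee[1] - trim
      }
      exon_rows[[tid]] <- tibble::tibble(transcript_id = tid, start = es, end = ee)
      # transcript-space ORF position for this isoform
      orf_t <- c(NA_integer_, NA_integer_)
      if (coding) {
        prefix_missing <- if (s == 2L) exon_lens[1] else trim
        orf_t <- c(orf[["start"]] - prefix_missing, orf[["end"]] - prefix_missing)
      }
      tx_rows[[tid]] <- tibble::tibble(
        transcript_id = tid, gene_id = gid, gene_name = gid,
        chrom = chrom, strand = strand, cds_incomplete = FALSE,
        attributes = list(c(biotype = if (coding) "protein_coding" else "noncoding"))
      )
      truth_rows[[tid]] <- tibble::tibble(
        transcript_id = tid, gene_id = gid, strand = strand,
        coding = coding, novel = coding && novel_flags[i],
        orf_t_start = orf_t[1], orf_t_end = orf_t[2]
      )
      if (coding && !novel_flags[i]) {
        cds_rows[[tid]] <- tibble::tibble(transcript_id = tid, start = 0L, end = 0L)
      }
    }
  }
  chrom_parts[[length(chrom_parts) + 1L]] <- random_nt(300L)
  genome <- Biostrings::DNAStringSet(stats::setNames(paste0(unlist(chrom_parts), collapse = ""), chrom))
  models <- tx_models(dplyr::bind_rows(tx_rows), dplyr::bind_rows(exon_rows))
  truth <- dplyr::bind_rows(truth_rows)

  # write CDS (planted ORF minus stop) for annotated coding transcripts
  for (tid in names(cds_rows)) {
    tr <- truth[truth$transcript_id == tid, ]
    iv <- project_interval(models, tid, tr$orf_t_start, tr$orf_t_end - 3L)
    models$cds <- dplyr::bind_rows(
      models$cds, tibble::tibble(transcript_id = tid, start = iv$start, end = iv$end)
    )
  }
  models <- validate_tx_models(models)
  list(models = models, genome = genome, truth = truth, config = config)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) x <- alpha / sum(alpha) else x <- x / sum(x)
  x
}

#' Simulate a two-group count matrix with planted effects
#'
#' Gene expected totals are drawn from a log-normal profile scaled to the
#' configured sequencing depth; per-sample gene totals get NB noise; isoform
#' splits are Dirichlet-multinomial around group proportion vectors. Planted
#' usage shifts move `usage_shift` of the dominant isoform's share to another
#' isoform in the case group; planted fold changes multiply one transcript's
#' expected mean by `2^lfc` (random sign) in the case group, leaving the other
#' isoforms untouched.
#'
#' @param models a [tx_models] object (e.g. from [simulate_annotation()]).
#' @param config a [sim_config()]; `config$seed + 1` seeds the count draw so
#'   annotation and counts are independently reproducible.
#' @return list with `counts` (wide tibble), `design` ([sample_design()]),
#'   `truth_de` (`transcript_id`, `lfc`), `truth_diu` (`gene_id`,
#'   `tx_up`, `tx_down`, `shift`).
#' @export
simulate_counts <- function(models, config) {
  set.seed(config$seed + 1L)
  genes <- split(models$transcripts$transcript_id, models$transcripts$gene_id)
  genes <- genes[order(names(genes))]
  n <- config$n_samples
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(n)), sprintf("case_%02d", seq_len(n)))
  group <- rep(c("control", "case"), each = n)
  nG <- length(genes)
  w <- stats::rlnorm(nG, 0, 1)
  gene_mean <- config$depth * w / sum(w)

  multi <- which(lengths(genes) >= 2L)
  diu_genes <- sort(sample(multi, round(config$frac_diu * length(multi))))
  base_props <- lapply(genes, function(tx) rdirichlet1(rep(2, length(tx))))
  case_props <- base_props
  truth_diu <- list()
  for (gi in diu_genes) {
    p <- base_props[[gi]]
    up_candidates <- setdiff(seq_along(p), which.max(p))
    up <- up_candidates[which.min(p[up_candidates])]
    down <- which.max(p)
    shift <- min(config$usage_shift, p[down] - 0.02)
    q <- p
    q[down] <- q[down] - shift
    q[up] <- q[up] + shift
    case_props[[gi]] <- q
    truth_diu[[length(truth_diu) + 1L]] <- tibble::tibble(
      gene_id = names(genes)[gi],
      tx_up = genes[[gi]][up], tx_down = genes[[gi]][down], shift = shift
    )
  }
  all_tx <- unlist(genes, use.names = FALSE)
  de_pool <- unlist(genes[setdiff(seq_len(nG), diu_genes)], use.names = FALSE)
  de_tx <- sort(sample(de_pool, round(config$frac_de * length(all_tx))))
  de_sign <- sample(c(-1, 1), length(de_tx), replace = TRUE)
  truth_de <- tibble::tibble(transcript_id = de_tx, lfc = de_sign * config$lfc)

  counts <- matrix(0L, length(all_tx), 2L * n,
                   dimnames = list(all_tx, sample_ids))
  for (gi in seq_len(nG)) {
    tx <- genes[[gi]]
    for (j in seq_len(2L * n)) {
      p <- if (group[j] == "control") base_props[[gi]] else case_props[[gi]]
      mu <- gene_mean[gi] * p
      if (group[j] == "case") {
        hit <- match(tx, truth_de$transcript_id)
        fc <- ifelse(is.na(hit), 1, 2^truth_de$lfc[hit])
        mu <- mu * fc
      }
      tot <- if (config$nb_dispersion > 0) {
        stats::rnbinom(1, mu = sum(mu), size = 1 / config$nb_dispersion)
      } else {
        stats::rpois(1, sum(mu))
      }
      if (length(tx) == 1L) {
        counts[tx, j] <- tot
      } else {
        ps <- rdirichlet1(config$dm_precision * mu / sum(mu))
        counts[tx, j] <- stats::rmultinom(1, tot, ps)
      }
    }
  }
  list(
    counts = dplyr::bind_cols(
      tibble::tibble(transcript_id = rownames(counts)),
      tibble::as_tibble(counts)
    ),
    design = sample_design(tibble::tibble(sample_id = sample_ids, group = group),
                           control = "control"),
    truth_de = truth_de,
    truth_diu = dplyr::bind_rows(truth_diu)
  )
}

#' The documented worked example: a fixed four-isoform locus
#'
#' A hand-written locus mimicking a compensatory isoform switch: in the case
#' group the long dominant isoform loses 30 percentage points of usage and a
#' short isoform gains them, while overall gene output drops. Counts, domain
#' annotations and non-positional attributes are fixed constants, so every
#' derived number (usage, fold change, figure geometry) is reproducible
#' bit-exactly.
#'
#' @return list with `models`, `counts`, `design`, `features` (a
#'   [load_features()]-shaped list) and `expected` (hand-computed usage
#'   values: control `(0.4, 0.3, 0.2, 0.1)`, case `(0.1, 0.3, 0.2, 0.4)` for
#'   `TOYT01`, `TOYT02`, `TOYT03`, `TOYT04`).
#' @export
make_toy_locus <- function() {
  tx <- tibble::tibble(
    transcript_id = c("TOYT01", "TOYT02", "TOYT03", "TOYT04"),
    gene_id = "TOYG1", gene_name = "TOY1", chrom = "chrT", strand = "+",
    cds_incomplete = FALSE,
    attributes = list(
      c(biotype = "protein_coding"), c(biotype = "protein_coding"),
      c(biotype = "protein_coding"), c(biotype = "protein_coding")
    )
  )
  ex <- function(tid, m) tibble::tibble(transcript_id = tid, start = m[, 1], end = m[, 2])
  exons <- dplyr::bind_rows(
    ex("TOYT01", rbind(c(1000, 1200), c(6200, 6400), c(11400, 11650), c(16650, 16900), c(21900, 22100))),
    ex("TOYT02", rbind(c(1000, 1200), c(6200, 6400), c(16650, 16900), c(21900, 22100))),
    ex("TOYT03", rbind(c(6300, 6400), c(11400, 11650), c(16650, 16900), c(21900, 22100))),
    ex("TOYT04", rbind(c(1000, 1200), c(6200, 6400), c(11400, 11650), c(12650, 12850)))
  )
  cds <- dplyr::bind_rows(
    ex("TOYT01", rbind(c(1100, 1200), c(6200, 6400), c(11400, 11650), c(16650, 16900), c(21900, 21952))),
    ex("TOYT02", rbind(c(1100, 1200), c(6200, 6400), c(16650, 16900), c(21900, 21953))),
    ex("TOYT03", rbind(c(11400, 11650), c(16650, 16900), c(21900, 21940))),
    ex("TOYT04", rbind(c(1100, 1200), c(6200, 6400), c(11400, 11601)))
  )
  models <- tx_models(tx, exons, cds)
  totals_ctrl <- c(100, 150, 200, 120, 180, 250)
  totals_case <- c(140, 110, 200, 160, 90, 210)
  p_ctrl <- c(0.4, 0.3, 0.2, 0.1)
  p_case <- c(0.1, 0.3, 0.2, 0.4)
  m <- cbind(outer(p_ctrl, totals_ctrl), outer(p_case, totals_case))
  storage.mode(m) <- "integer"
  sample_ids <- c(sprintf("N%d", 1:6), sprintf("T%d", 1:6))
  colnames(m) <- sample_ids
  counts <- dplyr::bind_cols(
    tibble::tibble(transcript_id = tx$transcript_id),
    tibble::as_tibble(m)
  )
  design <- sample_design(
    tibble::tibble(sample_id = sample_ids, group = rep(c("control", "case"), each = 6)),
    control = "control"
  )
  features <- list(
    positional = tibble::tibble(
      transcript_id = c("TOYT01", "TOYT01", "TOYT01", "TOYT04"),
      kind = c("signal_peptide", "domain", "domain", "domain"),
      space = "protein_aa",
      start = c(1L, 10L, 120L, 10L),
      end = c(20L, 60L, 200L, 60L),
      label = c("SP", "DOM_A", "DOM_B", "DOM_A")
    ),
    nonpositional = tibble::tibble(
      transcript_id = rep(c("TOYT01", "TOYT02", "TOYT03", "TOYT04"), 3),
      name = rep(c("biotype", "uorf", "expression"), each = 4),
      dtype = rep(c("categorical", "binary", "continuous"), each = 4),
      value = c(
        rep("protein_coding", 4),
        c("false", "false", "true", "false"),
        c("35.2", "12.1", "8.4", "20.5")
      ),
      value_num = c(rep(NA, 8), 35.2, 12.1, 8.4, 20.5),
      value_bool = c(rep(NA, 4), FALSE, FALSE, TRUE, FALSE, rep(NA, 4))
    ),
    unknown_ids = character()
  )
  list(
    models = models, counts = counts, design = design, features = features,
    expected = list(
      usage_control = p_ctrl, usage_case = p_case,
      delta_usage = p_case - p_ctrl,
      transcript_ids = tx$transcript_id
    )
  )
}
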