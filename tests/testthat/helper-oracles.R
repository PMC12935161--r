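# Brute-force oracles and small generators shared across the test suite.
# Every oracle is coded directly from the defining formula, independently of
# the package implementation paths it checks.

# random single-transcript model (returns a tx_models with one transcript)
random_transcript <- function(n_exons = sample(1:6, 1), strand = sample(c("+", "-"), 1),
                              id = "TX1") {
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- sample(100:500, 1)
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    len <- sample(20:300, 1)
    ends[i] <- pos + len
    pos <- ends[i] + sample(30:500, 1)
  }
  tx_models(
    tibble::tibble(
      transcript_id = id, gene_id = "G1", gene_name = "G1", chrom = "chr1",
      strand = strand, cds_incomplete = FALSE, attributes = list(character())
    ),
    tibble::tibble(transcript_id = id, start = starts, end = ends)
  )
}

# per-base lookup table: exonic genomic position -> transcript offset
brute_tx_map <- function(models, id) {
  ex <- tx_exons(models, id)
  gpos <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:(ex$end[i] - 1L)))
  gpos <- sort(gpos)
  if (tx_strand(models, id) == "-") gpos <- rev(gpos)
  tibble::tibble(tpos = seq_along(gpos) - 1L, gpos = gpos)
}

# literal three-frame ORF scanner (character-by-character walk)
brute_orf_scan <- function(seq, min_len = 75) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  res <- list()
  for (f in 0:2) {
    i <- f + 1L
    open_start <- NA
    while (i + 2L <= n) {
      codon <- paste0(ch[i:(i + 2L)], collapse = "")
      if (is.na(open_start) && codon == "ATG") open_start <- i
      if (!is.na(open_start) && codon %in% c("TAA", "TAG", "TGA")) {
        res[[length(res) + 1L]] <- c(f, open_start - 1L, i + 2L, 1L)
        open_start <- NA
      }
      i <- i + 3L
    }
    if (!is.na(open_start)) res[[length(res) + 1L]] <- c(f, open_start - 1L, n, 0L)
  }
  if (!length(res)) {
    return(tibble::tibble(frame = integer(), t_start = integer(), t_end = integer(),
                          has_stop = logical(), length_nt = integer()))
  }
  m <- do.call(rbind, res)
  out <- tibble::tibble(
    frame = as.integer(m[, 1]), t_start = as.integer(m[, 2]),
    t_end = as.integer(m[, 3]), has_stop = m[, 4] == 1L,
    length_nt = as.integer(m[, 3] - m[, 2])
  )
  out <- out[out$length_nt >= min_len, ]
  out[order(out$t_start, out$frame), ]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# independent Fickett lookup (tables re-entered from the published reference)
oracle_fickett <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  pos_par <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
  con_par <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0)
  pos_p <- rbind(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
  )
  con_p <- rbind(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
  )
  pw <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  cw <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  total <- sum(ch %in% c("A", "C", "G", "T"))
  s <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- sapply(0:2, function(p) sum(ch == b & (seq_along(ch) - 1) %% 3 == p))
    pv <- max(cnt) / (min(cnt) + 1)
    cv <- sum(cnt) / total
    s <- s + pos_p[b, which(pv >= pos_par)[1]] * pw[b] + con_p[b, which(cv >= con_par)[1]] * cw[b]
  }
  unname(s)
}

# literal BH definition: running minimum over the tail of p * m / rank
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  a <- pmin(1, ps * m / seq_len(m))
  a <- rev(cummin(rev(a)))
  out <- numeric(m)
  out[o] <- a
  out
}

# direct transcription of the trimmed weighted-mean TMM formula
oracle_tmm <- function(m, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(m)
  mm <- m[rowSums(m) > 0, , drop = FALSE]
  uq <- apply(mm, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(mm)), function(j) {
    if (j == ref) return(1)
    obs <- mm[, j]; r <- mm[, ref]
    keep <- obs > 0 & r > 0
    obs <- obs[keep]; r <- r[keep]
    # ratio form inside the log, as in the published formula; writing the
    # difference of logs instead perturbs exact rank ties by one ulp
    M <- log2((obs / lib[j]) / (r / lib[ref]))
    A <- (log2(obs / lib[j]) + log2(r / lib[ref])) / 2
    w <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  })
  f / exp(mean(log(f)))
}

# direct Dirichlet-multinomial log-pmf via log-gamma sums
oracle_dm_loglik <- function(Y, alpha) {
  tot <- 0
  for (s in seq_len(nrow(Y))) {
    y <- Y[s, ]
    n <- sum(y)
    tot <- tot + lgamma(n + 1) - sum(lgamma(y + 1)) +
      lgamma(sum(alpha)) - lgamma(n + sum(alpha)) +
      sum(lgamma(y + alpha) - lgamma(alpha))
  }
  tot
}

rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

wide_counts <- function(m, ids = NULL) {
  ids <- ids %||% paste0("t", seq_len(nrow(m)))
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)) || any(colnames(m) == "")) {
    colnames(m) <- paste0("s", seq_len(ncol(m)))
  }
  dplyr::bind_cols(tibble::tibble(transcript_id = ids), tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample ids match the s1..sN naming of wide_counts()
two_group_design <- function(n_per_group, labels = c("control", "case")) {
  sample_design(tibble::tibble(
    sample_id = paste0("s", seq_len(2L * n_per_group)),
    group = rep(labels, each = n_per_group)
  ), control = labels[1])
}
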