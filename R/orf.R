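STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Enumerate candidate open reading frames
#'
#' Scans all three frames of a spliced transcript sequence for ATG-initiated
#' reading frames extending to the first in-frame stop codon, or to the
#' transcript end when no stop follows (3'-incomplete candidates, flagged with
#' `has_stop = FALSE`). For each stop only the 5'-most ATG is reported.
#' Codon matching is exact, so `N` never matches ATG or a stop.
#'
#' @param seq nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @param min_len_nt minimum candidate length in nucleotides (stop included).
#' @return tibble with columns `frame`, `t_start`, `t_end` (half-open,
#'   transcript space), `has_stop`, `length_nt`, ordered by `t_start`.
#' @export
enumerate_orfs <- function(seq, min_len_nt = 75) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    starts1 <- seq.int(f + 1L, by = 3L, length.out = max(0L, (n - f) %/% 3L))
    if (!length(starts1)) next
    codons <- substring(seq, starts1, starts1 + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    boundary <- 0L # codon index of last consumed stop
    stops <- which(is_stop)
    for (s in stops) {
      a <- which(is_atg[seq_len(s - 1L)] & seq_len(s - 1L) > boundary)
      if (length(a)) {
        a0 <- a[1]
        out[[length(out) + 1L]] <- c(f, starts1[a0] - 1L, starts1[s] + 2L, 1L)
      }
      boundary <- s
    }
    a <- which(is_atg & seq_along(codons) > boundary)
    if (length(a)) {
      out[[length(out) + 1L]] <- c(f, starts1[a[1]] - 1L, n, 0L)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      frame = integer(), t_start = integer(), t_end = integer(),
      has_stop = logical(), length_nt = integer()
    ))
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(
    frame = as.integer(m[, 1]), t_start = as.integer(m[, 2]),
    t_end = as.integer(m[, 3]), has_stop = m[, 4] == 1L,
    length_nt = as.integer(m[, 3] - m[, 2])
  )
  res <- res[res$length_nt >= min_len_nt, ]
  res[order(res$t_start, res$frame), ]
}

# --- Fickett TESTCODE ------------------------------------------------------
# Published lookup tables (Fickett 1982): probabilities that a sequence with a
# given position asymmetry / base content is coding, with per-base weights.

FICKETT_POSITION_PARAM <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_PARAM <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0)
FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

fickett_lookup <- function(value, thresholds, probs) {
  probs[which(value >= thresholds)[1]]
}

#' Fickett TESTCODE statistic
#'
#' For each base, the position value is the ratio of the maximal to the
#' (minimal + 1) count over the three codon phases, and the content value is
#' the base fraction; both are converted to coding probabilities through the
#' published lookup tables and combined as the published weighted sum.
#' `N` bases are ignored.
#'
#' @param seq nucleotide string of length >= 6.
#' @return the TESTCODE score (higher = more coding-like).
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6L) iso_abort("fickett_score requires length >= 6", "domain")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  phase <- (seq_len(n) - 1L) %% 3L
  score <- 0
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(chars == b & phase == p), 0)
    pos_val <- max(cnt) / (min(cnt) + 1)
    content <- if (n_acgt > 0) sum(cnt) / n_acgt else 0
    score <- score +
      fickett_lookup(pos_val, FICKETT_POSITION_PARAM, FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(content, FICKETT_CONTENT_PARAM, FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  score
}

# --- hexamer usage model ---------------------------------------------------

ALL_HEXAMERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1, paste0, collapse = ""))
})

count_hexamers <- function(seqs, step) {
  counts <- stats::setNames(numeric(4096), ALL_HEXAMERS)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 6L) next
    starts <- seq.int(1L, n - 5L, by = step)
    hx <- substring(s, starts, starts + 5L)
    hx <- hx[!grepl("[^ACGT]", hx)]
    if (length(hx)) {
      tab <- table(hx)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts
}

#' Train a hexamer usage table
#'
#' In-frame (step 3) hexamer frequencies are tabulated from coding sequences
#' (assumed to start in frame 0, e.g. CDS sequences) and all-frame (step 1)
#' frequencies from noncoding sequences; both are pseudocounted and normalized
#' to probability distributions over the 4096 hexamers.
#'
#' @param coding_seqs,noncoding_seqs character vectors of sequences.
#' @param pseudocount added to every hexamer count before normalization.
#' @return an object of class `hexamer_table`.
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (!length(coding_seqs) || !length(noncoding_seqs)) {
    iso_abort("both coding and noncoding training sequences are required", "domain")
  }
  cc <- count_hexamers(coding_seqs, 3L) + pseudocount
  nc <- count_hexamers(noncoding_seqs, 1L) + pseudocount
  structure(
    list(coding = cc / sum(cc), noncoding = nc / sum(nc)),
    class = "hexamer_table"
  )
}

#' Mean in-frame hexamer log-odds
#'
#' Mean over sliding in-frame (step 3) hexamers of
#' `log(coding frequency / noncoding frequency)`. Hexamers containing `N` are
#' skipped; if every window is skipped the score is 0.
#'
#' @param seq nucleotide string of length >= 6.
#' @param table a [train_hexamer_table()] result.
#' @export
hexamer_score <- function(seq, table) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6L) iso_abort("hexamer_score requires length >= 6", "domain")
  starts <- seq.int(1L, n - 5L, by = 3L)
  hx <- substring(seq, starts, starts + 5L)
  hx <- hx[!grepl("[^ACGT]", hx)]
  if (!length(hx)) return(0)
  mean(log(table$coding[hx] / table$noncoding[hx]))
}

#' Serialize / load a hexamer table as TSV
#'
#' @param table a `hexamer_table`.
#' @param path TSV path (columns `hexamer`, `coding_freq`, `noncoding_freq`).
#' @export
write_hexamer_table <- function(table, path) {
  readr::write_tsv(tibble::tibble(
    hexamer = ALL_HEXAMERS,
    coding_freq = unname(table$coding[ALL_HEXAMERS]),
    noncoding_freq = unname(table$noncoding[ALL_HEXAMERS])
  ), path)
  invisible(path)
}

#' @rdname write_hexamer_table
#' @export
read_hexamer_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  structure(
    list(
      coding = stats::setNames(d$coding_freq, d$hexamer),
      noncoding = stats::setNames(d$noncoding_freq, d$hexamer)
    ),
    class = "hexamer_table"
  )
}

# --- coding-potential features and logistic model --------------------------

#' Coding-potential features of an ORF candidate
#'
#' @param seq full transcript sequence.
#' @param candidate one row of [enumerate_orfs()] output, or `NULL` when the
#'   sequence has no candidate (features fall back to zero ORF length).
#' @param table a `hexamer_table`.
#' @return one-row tibble: `orf_length`, `orf_coverage`, `fickett`, `hexamer`.
#' @export
coding_features <- function(seq, candidate, table) {
  n <- nchar(seq)
  if (is.null(candidate) || !nrow(candidate)) {
    return(tibble::tibble(
      orf_length = 0L, orf_coverage = 0,
      fickett = fickett_score(seq), hexamer = hexamer_score(seq, table)
    ))
  }
  orf_seq <- substring(seq, candidate$t_start + 1L, candidate$t_end)
  tibble::tibble(
    orf_length = candidate$length_nt,
    orf_coverage = candidate$length_nt / n,
    fickett = fickett_score(orf_seq),
    hexamer = hexamer_score(orf_seq, table)
  )
}

logistic <- function(x) 1 / (1 + exp(-x))

feature_matrix <- function(features) {
  cbind(
    1,
    log1p(features$orf_length),
    features$orf_coverage,
    features$fickett,
    features$hexamer
  )
}

ridge_irls <- function(X, y, lambda = 1e-3, maxit = 100) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- logistic(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

#' Fit the coding-potential logistic model
#'
#' Maximum-likelihood logistic regression of the coding label on
#' `log1p(orf_length)`, `orf_coverage`, `fickett` and `hexamer`. Under perfect
#' separation the fit falls back to a lightly ridge-penalized IRLS solution and
#' flags it.
#'
#' @param features data frame from [coding_features()] rows.
#' @param label logical (or 0/1) vector, `TRUE` = coding.
#' @return an object of class `coding_model`.
#' @export
fit_coding_model <- function(features, label) {
  label <- as.integer(label)
  if (length(unique(label)) < 2L) iso_abort("both labels must be present", "domain")
  X <- feature_matrix(features)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, label, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- fit$coefficients
  if (separated || anyNA(beta) || max(abs(beta[-1])) > 30) {
    beta <- ridge_irls(X, label)
    separated <- TRUE
  }
  prob <- logistic(drop(X %*% beta))
  structure(
    list(
      coefficients = stats::setNames(
        drop(beta), c("(Intercept)", "log1p_orf_length", "orf_coverage", "fickett", "hexamer")
      ),
      ridge = separated,
      n = length(label),
      accuracy = mean((prob > 0.5) == (label == 1L))
    ),
    class = "coding_model"
  )
}

#' @export
print.coding_model <- function(x, ...) {
  cat(sprintf(
    "<coding_model> n=%d training accuracy=%.3f%s\n", x$n, x$accuracy,
    if (x$ridge) " (ridge fallback)" else ""
  ))
  print(x$coefficients)
  invisible(x)
}

#' Predict coding probability from a coding model
#'
#' @param object a `coding_model`.
#' @param newdata data frame of [coding_features()] rows.
#' @param ... unused.
#' @export
predict.coding_model <- function(object, newdata, ...) {
  logistic(drop(feature_matrix(newdata) %*% object$coefficients))
}

#' Serialize / load a coding model as TSV
#'
#' @param model a `coding_model`.
#' @param path TSV path.
#' @export
write_coding_model <- function(model, path) {
  readr::write_tsv(tibble::tibble(
    term = names(model$coefficients),
    estimate = unname(model$coefficients),
    ridge = model$ridge
  ), path)
  invisible(path)
}

#' @rdname write_coding_model
#' @export
read_coding_model <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  structure(
    list(
      coefficients = stats::setNames(d$estimate, d$term),
      ridge = isTRUE(d$ridge[1]), n = NA_integer_, accuracy = NA_real_
    ),
    class = "coding_model"
  )
}

#' Score candidates and select the most likely ORF
#'
#' Scores every candidate with the coding model and returns the one with the
#' highest coding probability; ties are broken towards the longer candidate,
#' then the 5'-most start. Returns `NULL` when the best probability falls
#' below `threshold`.
#'
#' @param seq full transcript sequence.
#' @param candidates [enumerate_orfs()] output.
#' @param model a `coding_model`.
#' @param table a `hexamer_table`.
#' @param threshold minimum coding probability.
#' @return a one-row tibble (candidate plus `probability`) or `NULL`.
#' @export
select_orf <- function(seq, candidates, model, table, threshold = 0.5) {
  if (is.null(candidates) || !nrow(candidates)) return(NULL)
  feats <- dplyr::bind_rows(lapply(seq_len(nrow(candidates)), function(i) {
    coding_features(seq, candidates[i, ], table)
  }))
  prob <- predict(model, feats)
  ord <- order(-prob, -candidates$length_nt, candidates$t_start)
  best <- ord[1]
  if (prob[best] < threshold) return(NULL)
  out <- candidates[best, ]
  out$probability <- prob[best]
  out
}

#' Write a predicted ORF into a transcript as CDS
#'
#' The CDS footprint is the genomic projection of the ORF with the stop codon
#' excluded (GENCODE convention); candidates without an in-frame stop are
#' written in full and flagged `cds_incomplete`. Reference annotation is never
#' overwritten: annotating a transcript that already has CDS is an error.
#'
#' @inheritParams coords
#' @param orf one row of [enumerate_orfs()] / [select_orf()] output.
#' @return the updated [tx_models] object.
#' @export
annotate_cds <- function(models, transcript_id, orf) {
  if (nrow(tx_cds(models, transcript_id))) {
    iso_abort(paste0("transcript already has CDS annotation: ", transcript_id), "validation")
  }
  cds_end <- if (orf$has_stop) orf$t_end - 3L else orf$t_end
  iv <- project_interval(models, transcript_id, orf$t_start, cds_end)
  models$cds <- dplyr::bind_rows(
    models$cds,
    tibble::tibble(transcript_id = transcript_id, start = iv$start, end = iv$end)
  )
  i <- match(transcript_id, models$transcripts$transcript_id)
  at <- models$transcripts$attributes[[i]]
  at[["orf_source"]] <- "predicted"
  models$transcripts$attributes[[i]] <- at
  models$transcripts$cds_incomplete[i] <- !orf$has_stop || (cds_end - orf$t_start) %% 3L != 0L
  models
}

cds_t_range <- function(models, transcript_id) {
  cd <- tx_cds(models, transcript_id)
  if (!nrow(cd)) iso_abort(paste0("transcript has no CDS: ", transcript_id), "domain")
  tpos <- c(
    genome_to_transcript(models, transcript_id, cd$start),
    genome_to_transcript(models, transcript_id, cd$end - 1L)
  )
  c(min(tpos), max(tpos) + 1L)
}

#' Detect an upstream ORF in the 5' UTR
#'
#' `TRUE` iff an ATG-initiated ORF with an in-frame stop, at least 9 nt long
#' (start codon, one codon, stop), lies fully within the 5' UTR, i.e.
#' terminates at or before the annotated CDS start.
#'
#' @inheritParams spliced_sequence
#' @export
detect_uorf <- function(models, transcript_id, genome) {
  tr <- cds_t_range(models, transcript_id)
  if (tr[1] < 9L) return(FALSE)
  utr5 <- substring(spliced_sequence(models, transcript_id, genome), 1L, tr[1])
  cand <- enumerate_orfs(utr5, min_len_nt = 9L)
  any(cand$has_stop)
}

#' Predict nonsense-mediated decay susceptibility (50-nt rule)
#'
#' `TRUE` iff the stop codon lies more than 50 nt (transcript coordinates)
#' upstream of the last exon-exon junction. Single-exon transcripts are never
#' flagged.
#'
#' @inheritParams coords
#' @export
predict_nmd <- function(models, transcript_id) {
  ex <- tx_exons(models, transcript_id)
  tr <- cds_t_range(models, transcript_id) # errors when no CDS
  if (nrow(ex) < 2L) return(FALSE)
  last_exon_len <- if (tx_strand(models, transcript_id) == "+") {
    ex$end[nrow(ex)] - ex$start[nrow(ex)]
  } else {
    ex$end[1] - ex$start[1]
  }
  junction_t <- sum(ex$end - ex$start) - last_exon_len
  (junction_t - tr[2]) > 50L
}

#' Predict and annotate ORFs for all CDS-less transcripts
#'
#' Runs candidate enumeration, coding-potential scoring and best-ORF selection
#' for every transcript lacking CDS annotation, writes the selected ORFs back
#' as CDS (with `orf_source = "predicted"`), and reports per-transcript
#' outcomes including uORF and NMD attributes for newly annotated transcripts.
#'
#' @inheritParams spliced_sequence
#' @param model a `coding_model`.
#' @param table a `hexamer_table`.
#' @param min_len_nt minimum candidate ORF length.
#' @param threshold minimum coding probability for annotation.
#' @return list with `models` (augmented) and `predictions` (tibble:
#'   `transcript_id`, `t_start`, `t_end`, `has_stop`, `probability`,
#'   `annotated`, `uorf`, `nmd`).
#' @export
predict_orfs <- function(models, genome, model, table, min_len_nt = 75, threshold = 0.5) {
  todo <- setdiff(tx_ids(models), unique(models$cds$transcript_id))
  rows <- list()
  for (tid in todo) {
    s <- spliced_sequence(models, tid, genome)
    best <- select_orf(s, enumerate_orfs(s, min_len_nt), model, table, threshold)
    if (is.null(best)) {
      rows[[tid]] <- tibble::tibble(
        transcript_id = tid, t_start = NA_integer_, t_end = NA_integer_,
        has_stop = NA, probability = NA_real_, annotated = FALSE,
        uorf = NA, nmd = NA
      )
    } else {
      models <- annotate_cds(models, tid, best)
      rows[[tid]] <- tibble::tibble(
        transcript_id = tid, t_start = best$t_start, t_end = best$t_end,
        has_stop = best$has_stop, probability = best$probability, annotated = TRUE,
        uorf = detect_uorf(models, tid, genome),
        nmd = predict_nmd(models, tid)
      )
    }
  }
  list(models = models, predictions = dplyr::bind_rows(rows))
}
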