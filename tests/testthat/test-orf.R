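test_that("enumerate_orfs matches hand-checked small cases", {
  r <- enumerate_orfs("ATGAAATGA", min_len_nt = 6)
  expect_equal(nrow(r), 1L)
  expect_equal(r$t_start, 0L)
  expect_equal(r$t_end, 9L)
  expect_true(r$has_stop)
  expect_equal(nrow(enumerate_orfs("CCCCCC", min_len_nt = 6)), 0L)
  # no-stop candidate runs to the sequence end
  r2 <- enumerate_orfs("AATGAAAAAA", min_len_nt = 6)
  expect_false(any(r2$has_stop))
  expect_equal(r2$t_end, 10L)
  # N never matches ATG or a stop
  expect_equal(nrow(enumerate_orfs("ANGAAATGA", min_len_nt = 3)), 1L)
})

test_that("enumerate_orfs equals the brute-force three-frame scanner", {
  set.seed(21)
  for (rep in 1:120) {
    s <- random_seq(sample(30:400, 1))
    ml <- sample(c(9, 30, 75), 1)
    expect_equal(enumerate_orfs(s, ml), brute_orf_scan(s, ml))
  }
})

test_that("fickett score reproduces the independent table lookup", {
  expect_equal(fickett_score(strrep("A", 99)), oracle_fickett(strrep("A", 99)), tolerance = 1e-12)
  set.seed(22)
  for (rep in 1:40) {
    s <- random_seq(sample(6:300, 1))
    expect_equal(fickett_score(s), oracle_fickett(s), tolerance = 1e-12)
  }
  # regression fixture: self-concatenation changes the score only through the
  # position-value denominators; both values must still match the oracle
  s <- random_seq(99)
  expect_equal(fickett_score(paste0(s, s)), oracle_fickett(paste0(s, s)), tolerance = 1e-12)
  expect_error(fickett_score("ACGTA"), class = "isoscope_domain")
})

test_that("hexamer tables are normalized distributions and score log-odds", {
  tab <- train_hexamer_table("ATGGCC", c("AAAAAA", "CCCCCC"))
  expect_equal(sum(tab$coding), 1, tolerance = 1e-9)
  expect_equal(sum(tab$noncoding), 1, tolerance = 1e-9)
  expect_true(all(tab$coding > 0) && all(tab$noncoding > 0))
  expect_gt(tab$coding[["ATGGCC"]], tab$coding[["AAAAAA"]])

  # identical coding/noncoding distributions give zero log-odds everywhere
  eq <- structure(list(coding = tab$coding, noncoding = tab$coding), class = "hexamer_table")
  set.seed(23)
  for (rep in 1:5) expect_equal(hexamer_score(random_seq(60), eq), 0)

  # hand oracle on a printed toy: mean over in-frame hexamers
  s <- "ATGGCCATG"
  expected <- mean(log(tab$coding[c("ATGGCC", "GCCATG")] / tab$noncoding[c("ATGGCC", "GCCATG")]))
  expect_equal(hexamer_score(s, tab), expected)
  expect_error(hexamer_score("ACGTA", tab), class = "isoscope_domain")

  # sequences sampled from the coding distribution score positive on average
  set.seed(24)
  hx <- names(tab$coding)
  draws <- replicate(200, paste(sample(hx, 20, replace = TRUE, prob = tab$coding), collapse = ""))
  expect_gt(mean(vapply(draws, hexamer_score, 0, table = tab)), 0)

  rt <- withr::local_tempfile(fileext = ".tsv")
  write_hexamer_table(tab, rt)
  back <- read_hexamer_table(rt)
  expect_equal(unname(back$coding[names(tab$coding)]), unname(tab$coding), tolerance = 1e-12)
})

test_that("select_orf maximizes probability with length/5'-most tie-breaks", {
  set.seed(25)
  # model with known coefficients: probability driven by length only
  model <- structure(list(
    coefficients = c("(Intercept)" = -10, log1p_orf_length = 2,
                     orf_coverage = 0, fickett = 0, hexamer = 0),
    ridge = FALSE, n = 0L, accuracy = NA_real_
  ), class = "coding_model")
  tab <- train_hexamer_table("ATGGCC", "AAAAAA")
  s <- paste0(
    "ATG", strrep("GCA", 40), "TAA", # frame-0 ORF, 126 nt
    "CC",
    "ATG", strrep("GCA", 10), "TAA" # shorter ORF, other frame
  )
  cand <- enumerate_orfs(s, min_len_nt = 30)
  best <- select_orf(s, cand, model, tab, threshold = 0.3)
  expect_equal(best$t_start, 0L)
  expect_equal(best$length_nt, 126L)
  # threshold gate
  expect_null(select_orf(s, cand, model, tab, threshold = 1))
  # tie on probability -> longer wins (force flat model)
  flat <- model
  flat$coefficients[] <- c(0, 0, 0, 0, 0)
  best_flat <- select_orf(s, cand, flat, tab, threshold = 0.4)
  expect_equal(best_flat$length_nt, max(cand$length_nt))
})

single_exon_tx <- function(seq_len = 60L) {
  tx_models(
    tibble::tibble(
      transcript_id = "T1", gene_id = "G1", gene_name = NA_character_,
      chrom = "c", strand = "+", cds_incomplete = FALSE, attributes = list(character())
    ),
    tibble::tibble(transcript_id = "T1", start = 0L, end = seq_len)
  )
}

test_that("annotate_cds writes the stop-codon-excluded projection", {
  m <- single_exon_tx()
  orf <- tibble::tibble(frame = 0L, t_start = 0L, t_end = 9L, has_stop = TRUE, length_nt = 9L)
  m2 <- annotate_cds(m, "T1", orf)
  cd <- tx_cds(m2, "T1")
  expect_equal(sum(cd$end - cd$start), 6L)
  expect_equal(unname(m2$transcripts$attributes[[1]]["orf_source"]), "predicted")
  expect_error(annotate_cds(m2, "T1", orf), class = "isoscope_validation")

  # junction-spanning ORF: two CDS pieces summing to length - 3
  mj <- tx_models(
    tibble::tibble(
      transcript_id = "T1", gene_id = "G1", gene_name = NA_character_,
      chrom = "c", strand = "+", cds_incomplete = FALSE, attributes = list(character())
    ),
    tibble::tibble(transcript_id = "T1", start = c(0L, 100L), end = c(50L, 160L))
  )
  orfj <- tibble::tibble(frame = 0L, t_start = 30L, t_end = 90L, has_stop = TRUE, length_nt = 60L)
  mj2 <- annotate_cds(mj, "T1", orfj)
  cdj <- tx_cds(mj2, "T1")
  expect_equal(nrow(cdj), 2L)
  expect_equal(sum(cdj$end - cdj$start), 57L)
})

test_that("uORF detection scans the 5' UTR only", {
  mk <- function(utr5) {
    main <- paste0("ATG", strrep("GGA", 20), "TAA")
    seq <- paste0(utr5, main, "CCCCC")
    genome <- c(c1 = seq)
    m <- tx_models(
      tibble::tibble(
        transcript_id = "T1", gene_id = "G1", gene_name = NA_character_,
        chrom = "c1", strand = "+", cds_incomplete = FALSE, attributes = list(character())
      ),
      tibble::tibble(transcript_id = "T1", start = 0L, end = nchar(seq)),
      cds = tibble::tibble(transcript_id = "T1",
                           start = nchar(utr5), end = nchar(utr5) + 63L)
    )
    detect_uorf(m, "T1", genome)
  }
  expect_true(mk(paste0("CCC", "ATGAAATGA", "CCC")))
  expect_false(mk(strrep("C", 15)))
  # uORF without a stop inside the UTR does not count
  expect_false(mk(paste0("CCC", "ATGAAAAAA")))
  set.seed(26)
  # brute-force 5' UTR scan agreement on random fixtures
  for (rep in 1:60) {
    utr <- random_seq(sample(10:60, 1))
    got <- mk(utr)
    cand <- brute_orf_scan(utr, 9)
    expect_equal(got, any(cand$has_stop))
  }
})

test_that("the 50-nt rule flags distal stop codons and is monotone", {
  mk <- function(cds_end, exons = tibble::tibble(transcript_id = "T1",
                                                 start = c(0L, 300L), end = c(200L, 500L))) {
    tx_models(
      tibble::tibble(
        transcript_id = "T1", gene_id = "G1", gene_name = NA_character_,
        chrom = "c", strand = "+", cds_incomplete = FALSE, attributes = list(character())
      ),
      exons,
      cds = tibble::tibble(transcript_id = "T1", start = 0L, end = cds_end)
    )
  }
  # spliced length 400, last junction at t=200
  expect_true(predict_nmd(mk(145L), "T1")) # stop at 145, 55 nt upstream
  expect_false(predict_nmd(mk(190L), "T1")) # 10 nt upstream
  expect_false(predict_nmd(mk(150L), "T1")) # exactly 50 -> not flagged
  single <- tx_models(
    tibble::tibble(
      transcript_id = "T1", gene_id = "G1", gene_name = NA_character_,
      chrom = "c", strand = "+", cds_incomplete = FALSE, attributes = list(character())
    ),
    tibble::tibble(transcript_id = "T1", start = 0L, end = 400L),
    cds = tibble::tibble(transcript_id = "T1", start = 0L, end = 90L)
  )
  expect_false(predict_nmd(single, "T1"))
  no_cds <- tx_models(
    single$transcripts,
    tibble::tibble(transcript_id = "T1", start = 0L, end = 400L)
  )
  expect_error(predict_nmd(no_cds, "T1"), class = "isoscope_domain")
  # monotone: moving the stop 5' never un-flags
  flags <- vapply(seq(30L, 195L, by = 15L), function(e) predict_nmd(mk(e), "T1"), TRUE)
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("spliced sequences concatenate strand-aware exon sequence", {
  genome <- c(chr = "ACGTCCGGCCTT")
  m <- tx_models(
    tibble::tibble(
      transcript_id = "T1", gene_id = "G1", gene_name = NA_character_,
      chrom = "chr", strand = "+", cds_incomplete = FALSE, attributes = list(character())
    ),
    tibble::tibble(transcript_id = "T1", start = c(0L, 8L), end = c(4L, 12L))
  )
  expect_equal(spliced_sequence(m, "T1", genome), "ACGTCCTT")
  mneg <- m
  mneg$transcripts$strand <- "-"
  expect_equal(
    spliced_sequence(mneg, "T1", genome),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString("ACGTCCTT")))
  )
  expect_error(spliced_sequence(m, "T1", c(other = "AAA")), class = "isoscope_lookup")
  set.seed(27)
  for (rep in 1:10) {
    mm <- random_transcript()
    g <- stats::setNames(random_seq(max(tx_exons(mm, "TX1")$end) + 10), "chr1")
    expect_equal(nchar(spliced_sequence(mm, "TX1", g)), spliced_length(mm, "TX1"))
  }
})
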