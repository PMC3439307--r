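test_that("the k-mer index stores every word occurrence and skips N", {
  idx1 <- build_index(list(qual_seq_record("s", "ACGTACGTACG")), 11)
  info1 <- flanktag:::.ft_index_info(idx1$ptr)
  expect_equal(info1$n_kmers, 1)
  expect_equal(info1$n_positions, 1)

  idx2 <- build_index(list(qual_seq_record("s", strrep("A", 20))), 11)
  info2 <- flanktag:::.ft_index_info(idx2$ptr)
  expect_equal(info2$n_kmers, 1)
  expect_equal(info2$n_positions, 10)
  hits <- flanktag:::.ft_index_lookup(idx2$ptr, strrep("A", 11))
  expect_equal(hits[, 2], 0:9)

  with_n <- build_index(list(qual_seq_record("s", "ACGTACGTACGNACGTACGTACG")), 11)
  # N splits the sequence into two 11-mer-bearing halves; the k-mers touching
  # N are absent
  expect_equal(flanktag:::.ft_index_info(with_n$ptr)$n_positions, 2)
})

test_that("Smith-Waterman reproduces hand-derived local alignments", {
  sp <- scoring_params()        # +2/-3, gaps 5/2
  expect_equal(smith_waterman("ACGT", "ACGT", sp)$score, 8)
  # best local alignment of ACGT vs AGGT is GT/GT = 4 (full-length is 3)
  expect_equal(smith_waterman("ACGT", "AGGT", sp)$score, 4)
  q <- random_dna(40)
  self <- smith_waterman(q, q, sp)
  expect_equal(self$score, 2 * 40)
  expect_equal(self$identity, 1)
})

test_that("Smith-Waterman agrees with Biostrings pairwiseAlignment", {
  sp <- scoring_params()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  withr::local_seed(99)
  for (i in 1:25) {
    q <- random_dna(sample(20:120, 1))
    s <- random_dna(sample(20:200, 1))
    if (i %% 2 == 0) {
      k <- sample(15:40, 1)
      st <- sample(1:(nchar(s) - k), 1)
      q <- paste0(substr(q, 1, 10), substr(s, st, st + k - 1),
                  substr(q, 11, nchar(q)))
    }
    ref <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(smith_waterman(q, s, sp)$score, ref, info = paste("pair", i))
  }
})

test_that("Karlin-Altschul e-values follow the closed form", {
  sp <- scoring_params(lambda = 1.3, k = 0.7)
  # direct evaluation: 0.7 * 100 * 10000 * exp(-1.3 * 20)
  expect_equal(evalue_from_score(20, 100, 10000, sp), 3.576362e-06,
               tolerance = 1e-6)
  expect_equal(evalue_from_score(20, 100, 20000, sp) /
                 evalue_from_score(20, 100, 10000, sp), 2)
  scores <- seq(10, 60, by = 5)
  ev <- evalue_from_score(scores, 100, 10000, sp)
  expect_true(all(diff(ev) < 0))
  expect_lt(evalue_from_score(1e4, 100, 10000, sp), 1e-300)
  # the default lambda solves the Karlin sum equation
  l <- karlin_lambda(2, -3)
  expect_equal(0.25 * exp(2 * l) + 0.75 * exp(-3 * l), 1, tolerance = 1e-9)
})

test_that("seeded search finds exact substrings on both strands", {
  withr::local_seed(11)
  g <- random_dna(6000)
  idx <- build_index(c(chrX = g), 11)
  sp <- scoring_params()
  q <- substring(g, 2001, 2100)
  h <- search_hits(q, idx, sp, evalue_cutoff = 1e-5)
  expect_gte(nrow(h), 1L)
  expect_equal(h$score[1], 2 * 100)
  expect_equal(h$identity[1], 1)
  expect_equal(c(h$q_start[1], h$q_end[1]), c(0, 100))
  expect_equal(c(h$s_start[1], h$s_end[1]), c(2000, 2100))
  expect_equal(h$strand[1], "+")

  hr <- search_hits(revcomp(q), idx, sp, evalue_cutoff = 1e-5)
  expect_equal(hr$strand[1], "-")
  expect_equal(hr$score[1], h$score[1])
  expect_equal(c(hr$s_start[1], hr$s_end[1]), c(2000, 2100))
})

test_that("a query duplicated at two loci yields two equal top hits", {
  withr::local_seed(12)
  core <- random_dna(80)
  g1 <- paste0(random_dna(500), core, random_dna(500))
  g2 <- paste0(random_dna(300), core, random_dna(700))
  idx <- build_index(c(c1 = g1, c2 = g2), 11)
  h <- search_hits(core, idx, evalue_cutoff = 1e-5)
  expect_gte(nrow(h), 2L)
  expect_equal(h$score[1], h$score[2])
  expect_setequal(h$subject_id[1:2], c("c1", "c2"))
})

test_that("strand symmetry: reverse-complementing the query flips the strand only", {
  withr::local_seed(13)
  g <- random_dna(4000)
  idx <- build_index(c(chr = g), 11)
  for (i in 1:10) {
    st <- sample(1:3800, 1)
    q <- substring(g, st, st + sample(40:150, 1))
    h1 <- search_hits(q, idx, evalue_cutoff = 1)
    h2 <- search_hits(revcomp(q), idx, evalue_cutoff = 1)
    expect_equal(nrow(h1), nrow(h2))
    expect_equal(h1$score, h2$score)
    expect_equal(h1$s_start, h2$s_start)
    expect_equal(h1$s_end, h2$s_end)
    expect_equal(h1$strand, chartr("+-", "-+", h2$strand))
  }
})

test_that("seeded search is deterministic and matches the exact DP score", {
  withr::local_seed(14)
  sp <- scoring_params()
  for (i in 1:40) {
    s <- random_dna(sample(100:200, 1))
    hom_len <- sample(30:80, 1)
    hst <- sample(1:(nchar(s) - hom_len), 1)
    hom <- substring(s, hst, hst + hom_len - 1)
    q <- paste0(random_dna(sample(5:40, 1)), hom,
                random_dna(sample(5:40, 1)))
    idx <- build_index(c(s = s), 11)
    h <- search_hits(q, idx, sp, evalue_cutoff = 1e6)
    sw <- smith_waterman(q, s, sp)
    expect_gte(nrow(h), 1L)
    expect_equal(h$score[1], sw$score, info = paste("pair", i))
    h2 <- search_hits(q, idx, sp, evalue_cutoff = 1e6)
    expect_identical(h, h2)
  }
})

test_that("the external blastn adapter matches the internal aligner on an exact hit", {
  skip_if(Sys.which("blastn") == "", "no blastn executable on PATH")
  withr::local_seed(15)
  g <- random_dna(5000)
  q <- substring(g, 1001, 1150)
  qf <- withr::local_tempfile(fileext = ".fasta")
  sf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1", q), qf)
  writeLines(c(">chr1", g), sf)
  h <- external_blastn(qf, sf, evalue_cutoff = 1e-5)
  expect_gte(nrow(h), 1L)
  expect_equal(h$identity[1], 1)
  expect_equal(c(h$s_start[1], h$s_end[1]), c(1000, 1150))
  expect_equal(h$strand[1], "+")
})

test_that("missing blastn raises the unavailable-aligner error", {
  expect_error(external_blastn("q.fa", "s.fa", blastn = ""),
               "external aligner unavailable")
})
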