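# A planted-insertion harness: builds a small genome, plants one FST, and
# checks the junction coordinate round-trips through validation + mapping.
plant_and_map <- function(genome, j0, L, read_strand, design, word = 11) {
  chrom <- names(genome)[1]
  seg <- if (read_strand == "+")
    substring(genome[[chrom]], j0 + 1, j0 + L)
  else revcomp(substring(genome[[chrom]], j0 - L + 2, j0 + 1))
  rec <- qual_seq_record("planted", paste0(design$border, seg, design$adaptor))
  opt <- optional_seq_set(border = design$border, adaptor = design$adaptor)
  tr <- trim_by_quality(rec)
  mfst <- classify(rec, tr, annotate_optional_sequences(tr$record, opt))
  idx <- build_index(genome, word)
  call_insertion(mfst, map_fst(mfst, idx))
}

test_that("the junction coordinate round-trips through mapping on both strands", {
  withr::local_seed(31)
  design <- small_design(7)
  genome <- c(chrZ = random_dna(30000))
  for (strand in c("+", "-")) {
    j0 <- 10000   # 0-based junction -> 1-based 10001
    call <- plant_and_map(genome, j0, 80, strand, design)
    expect_equal(call$chrom, "chrZ")
    expect_equal(call$position, 10001)
    expect_equal(call$strand, strand)
  }
})

test_that("equal top scores at two loci give a repeat; no hits give unmapped", {
  withr::local_seed(32)
  design <- small_design(7)
  core <- random_dna(2000)
  genome <- c(c1 = paste0(random_dna(3000), core, random_dna(3000)),
              c2 = paste0(random_dna(2000), core, random_dna(4000)))
  rep_call <- plant_and_map(genome, 3000 + 500, 80, "+", design)
  expect_equal(rep_call$itype, "repeat")
  expect_true(is.na(rep_call$position))

  # a segment absent from the genome
  rec <- qual_seq_record("lost", paste0(design$border, random_dna(80),
                                        design$adaptor))
  opt <- optional_seq_set(border = design$border, adaptor = design$adaptor)
  tr <- trim_by_quality(rec)
  mfst <- classify(rec, tr, annotate_optional_sequences(tr$record, opt))
  un <- call_insertion(mfst, map_fst(mfst, build_index(genome, 11)))
  expect_equal(un$itype, "unmapped")
})

test_that("categorization matches the fixture geometry", {
  store <- fixture_store()
  # inside exon 2 of the plus gene, within the CDS
  cl <- categorize(make_call("chrA", 4201), store)
  expect_equal(cl$itype, "exon")
  expect_equal(cl$subfeature, "CDS")
  expect_equal(cl$gene_id, "gplus")
  # before the ATG but inside exon 1 -> 5UTR
  expect_equal(categorize(make_call("chrA", 3050), store)$subfeature, "5UTR")
  # past the minus gene's stop boundary (low coordinates are 3' for minus)
  mu <- categorize(make_call("chrA", 10100), store)
  expect_equal(mu$itype, "exon")
  expect_equal(mu$subfeature, "3UTR")
  # intron of the plus gene
  expect_equal(categorize(make_call("chrA", 3700), store)$itype, "intron")
  # 500 bp 5' of the plus gene's ATG (position 3100 0-based -> atg at 3101)
  up <- categorize(make_call("chrA", 2601), store)
  expect_equal(up$itype, "upstream5")
  expect_equal(up$gene_id, "gplus")
  # 200 bp 3' of the plus gene's stop
  dn <- categorize(make_call("chrA", 6100), store)
  expect_equal(dn$itype, "downstream3")
  expect_equal(dn$gene_id, "gplus")
  # minus-strand gene: upstream lies at higher coordinates than the ATG
  upm <- categorize(make_call("chrA", 12500), store)
  expect_equal(upm$itype, "upstream5")
  expect_equal(upm$gene_id, "gminus")
  # far from everything -> intergenic with the nearest gene and distance
  ig <- categorize(make_call("chrA", 8000), store)
  expect_equal(ig$itype, "intergenic")
  expect_equal(ig$gene_id, "gplus")
  expect_equal(ig$distance_to_gene, -(7999 - 5999))
  # repeat and unmapped pass through untouched
  expect_equal(categorize(make_call("chrA", NA, itype = "repeat"), store)$itype,
               "repeat")
  expect_error(categorize(make_call("chrA", 99999), store), "outside")
})

test_that("categorization agrees with a linear-scan oracle on random positions", {
  withr::local_seed(33)
  design <- small_design(8)
  sim <- simulate_genome(design)
  store <- annotation_store(sim$genes, design$chrom_lengths)
  for (i in 1:300) {
    chrom <- sample(names(design$chrom_lengths), 1)
    pos <- sample.int(design$chrom_lengths[[chrom]], 1)
    got <- categorize(make_call(chrom, pos), store)
    want <- categorize_oracle(sim$genes, chrom, pos)
    expect_equal(got$itype, want$itype,
                 info = sprintf("%s:%d", chrom, pos))
    if (got$itype != "intergenic")
      expect_equal(got$gene_id, want$gene_id,
                   info = sprintf("%s:%d", chrom, pos))
  }
})

test_that("nearest_gene minimizes boundary distance with deterministic ties", {
  store <- fixture_store()
  # inside a transcript: distance 0
  expect_equal(nearest_gene(4000, "chrA", store)$distance, 0)
  # midway-ish: 7000 is 1000 past gplus (ends 6000) and 3001 before gminus
  ng <- nearest_gene(7000, "chrA", store)
  expect_equal(ng$gene$gene_id, "gplus")
  expect_equal(ng$distance, -1000)
  mid <- nearest_gene(8001, "chrA", store)   # 2001 bp vs 2000 bp -> gminus
  expect_equal(mid$gene$gene_id, "gminus")
  # an exactly equidistant pair resolves to the lower start coordinate
  tie_store <- annotation_store(
    list(gene_model("gA", "chrB", "+", 100, 200, 100, 200, 110, 190),
         gene_model("gB", "chrB", "+", 299, 400, 299, 400, 310, 390)),
    c(chrB = 1000))
  tie <- nearest_gene(250, "chrB", tie_store)  # 50 bp to either side
  expect_equal(tie$gene$gene_id, "gA")
  expect_equal(abs(tie$distance), 50)
  empty <- annotation_store(list(), c(chrB = 1000))
  expect_null(nearest_gene(500, "chrB", empty)$gene)
})

test_that("flank extraction marks the insertion point and round-trips", {
  withr::local_seed(34)
  genome <- c(chrF = random_dna(10000))
  cl <- make_call("chrF", 600)
  fl <- extract_flank(genome, cl, 500)
  expect_equal(nchar(fl), 500 + 5 + 500)
  parts <- strsplit(fl, "\\*{5}")[[1]]
  expect_equal(nchar(parts[1]), 500)
  # re-locating the joined flanks recovers the position
  joined <- paste0(parts[1], parts[2])
  hit <- regexpr(joined, genome[["chrF"]], fixed = TRUE)
  expect_equal(as.integer(hit) + 500 - 1, 599)   # 0-based junction
  edge <- extract_flank(genome, make_call("chrF", 101), 500)
  expect_equal(nchar(edge), 100 + 5 + 500)
})

test_that("strand invariance: reverse-complementing the segment moves nothing", {
  withr::local_seed(35)
  design <- small_design(7)
  genome <- c(chrS = random_dna(20000))
  p <- plant_and_map(genome, 9000, 70, "+", design)
  m <- plant_and_map(genome, 9000, 70, "-", design)
  expect_equal(p$position, m$position)
  expect_equal(p$chrom, m$chrom)
})
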