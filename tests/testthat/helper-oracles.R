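# Independent brute-force oracles and small fixture builders shared across
# the test files.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive O(n^2) maximal-scoring-segment search with the same tie rules
# as the trimmer (leftmost start, then longest)
mott_oracle <- function(quals, p = 0.03) {
  sc <- p - 10^(-quals / 10)
  n <- length(sc)
  best <- 0; bs <- 0L; be <- 0L
  for (s in 0:(n - 1)) {
    acc <- 0
    for (e in (s + 1):n) {
      acc <- acc + sc[e]
      if (acc > best + 1e-12) { best <- acc; bs <- s; be <- e }
      else if (acc > 1e-12 && abs(acc - best) <= 1e-12 &&
               (s < bs || (s == bs && e > be))) { bs <- s; be <- e }
    }
  }
  c(bs, be)
}

# brute-force enumeration of sliding windows containing each insertion
window_counts_oracle <- function(pos1, chrom_len, window, step) {
  starts <- seq(0, chrom_len - 1, by = step)
  vapply(starts, function(s) {
    sum(vapply(pos1, function(p) {
      p0 <- p - 1
      p0 >= s && p0 < s + window
    }, TRUE))
  }, 0)
}

# linear-scan categorization applying the documented precedence rules
categorize_oracle <- function(genes, chrom, pos1, up = 1000, dn = 300) {
  p0 <- pos1 - 1
  gl <- Filter(function(g) g$chrom == chrom, genes)
  body <- Filter(function(g) p0 >= g$tx_start && p0 < g$tx_end, gl)
  atg_of <- function(g) if (g$strand == "+") g$cds_start else g$cds_end - 1
  stop_of <- function(g) if (g$strand == "+") g$cds_end - 1 else g$cds_start
  if (length(body)) {
    d <- vapply(body, function(g) abs(p0 - atg_of(g)), 0)
    g <- body[[which.min(d)]]
    in_exon <- any(p0 >= g$exon_starts & p0 < g$exon_ends)
    return(list(itype = if (in_exon) "exon" else "intron",
                gene_id = g$gene_id))
  }
  best <- NULL
  for (g in gl) {       # upstream candidates first: upstream wins ties
    a <- atg_of(g)
    in_up <- if (g$strand == "+") p0 >= a - up && p0 < a
             else p0 > a && p0 <= a + up
    if (in_up) {
      d <- abs(p0 - a)
      if (is.null(best) || d < best$d)
        best <- list(itype = "upstream5", d = d, gene_id = g$gene_id)
    }
  }
  for (g in gl) {
    s <- stop_of(g)
    in_dn <- if (g$strand == "+") p0 > s && p0 <= s + dn
             else p0 >= s - dn && p0 < s
    if (in_dn) {
      d <- abs(p0 - s)
      if (is.null(best) || d < best$d)
        best <- list(itype = "downstream3", d = d, gene_id = g$gene_id)
    }
  }
  if (!is.null(best))
    return(list(itype = best$itype, gene_id = best$gene_id))
  list(itype = "intergenic", gene_id = NA_character_)
}

# a small hand-laid two-gene annotation on one 20-kb chromosome:
#   plus-strand gene [3000, 6000) with 3 exons, CDS [3100, 5900)
#   minus-strand gene [10000, 12000) with 2 exons, CDS [10150, 11900)
fixture_genes <- function() {
  list(
    gene_model("gplus", "chrA", "+", 3000, 6000,
               exon_starts = c(3000, 4000, 5500),
               exon_ends = c(3500, 4600, 6000),
               cds_start = 3100, cds_end = 5900,
               description = "plus strand fixture gene"),
    gene_model("gminus", "chrA", "-", 10000, 12000,
               exon_starts = c(10000, 11200),
               exon_ends = c(10800, 12000),
               cds_start = 10150, cds_end = 11900,
               description = "minus strand fixture gene"))
}

fixture_store <- function() {
  annotation_store(fixture_genes(), c(chrA = 20000))
}

make_call <- function(chrom, position, strand = "+", itype = NA_character_,
                      fst_id = "probe") {
  structure(list(fst_id = fst_id, chrom = chrom, position = position,
                 strand = strand, itype = itype, gene_id = NA_character_,
                 gene_description = NA_character_,
                 distance_to_gene = NA_real_, subfeature = NA_character_),
            class = "insertion_call")
}

# read a pipeline TSV, restoring the literal "NA" category label that
# read.table would otherwise treat as missing
read_report_tsv <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if ("category" %in% names(x))
    x$category[is.na(x$category)] <- "NA"
  x
}

small_design <- function(seed = 5L) {
  sim_design(seed = seed,
             chrom_lengths = c(chr1 = 300000, chr2 = 200000),
             n_genes = c(8L, 6L),
             n_per_itype = c(exon = 4L, intron = 4L, upstream5 = 4L,
                             downstream3 = 4L, intergenic = 4L),
             n_repeat = 3L, n_na = 4L, n_vector = 4L, n_low = 3L)
}
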