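# Deterministic generator of genomes, gene annotations, and FST batches
# with known ground truth, so every pipeline stage is testable end to end
# without external data.

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Design of a synthetic FST experiment
#'
#' Defaults describe the reference verification scenario: a 2-Mb two
#' chromosome genome carrying 60 multi-exon genes on both strands plus one
#' duplicated 2-kb block, and a 300-read batch (36 reads for each of the
#' five placed insertional types, 20 repeat-locus reads, 40 too-short reads,
#' 40 vector reads, 20 low-quality reads). Border (25 bp), adaptor (20 bp),
#' and vector (3 kb) sequences are generated deterministically from the
#' seed.
#'
#' @param seed integer seed; the whole simulation is a pure function of it
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param n_genes genes per chromosome (same order as `chrom_lengths`)
#' @param n_per_itype named counts of intended-A reads per placed type
#'   (exon, intron, upstream5, downstream3, intergenic)
#' @param n_repeat,n_na,n_vector,n_low counts of repeat-locus, too-short,
#'   vector, and low-quality reads
#' @param msl minimum genomic-segment length the validator will use
#' @param segment_len_range genomic-segment length range for A reads (bp);
#'   must stay at least 10 bp above `msl`
#' @param na_len_range segment length range for intended-NA reads; must stay
#'   at least 10 bp below `msl`
#' @param exon_count_range,exon_len_range,intron_len_range gene structure
#'   parameters (bp)
#' @param border_len,adaptor_len,vector_len construct sequence lengths (bp)
#' @return an object of class `sim_design`
#' @export
sim_design <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1200000, chr2 = 800000),
                       n_genes = c(36L, 24L),
                       n_per_itype = c(exon = 36L, intron = 36L,
                                       upstream5 = 36L, downstream3 = 36L,
                                       intergenic = 36L),
                       n_repeat = 20L, n_na = 40L, n_vector = 40L,
                       n_low = 20L, msl = 30L,
                       segment_len_range = c(60L, 120L),
                       na_len_range = c(15L, 20L),
                       exon_count_range = c(2L, 5L),
                       exon_len_range = c(150L, 400L),
                       intron_len_range = c(100L, 800L),
                       border_len = 25L, adaptor_len = 20L,
                       vector_len = 3000L) {
  stopifnot(length(chrom_lengths) == length(n_genes),
            all(n_per_itype >= 0), n_repeat >= 0, n_na >= 0, n_vector >= 0,
            n_low >= 0,
            segment_len_range[1L] >= msl + 10L,
            na_len_range[2L] <= msl - 10L,
            seed == floor(seed), abs(seed) < 2^31)
  optseqs <- withr::with_seed(seed + 101L, list(
    border = .random_dna(border_len),
    adaptor = .random_dna(adaptor_len),
    vector = .random_dna(vector_len)))
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_genes = as.integer(n_genes), n_per_itype = n_per_itype,
                 n_repeat = n_repeat, n_na = n_na, n_vector = n_vector,
                 n_low = n_low, msl = msl,
                 segment_len_range = segment_len_range,
                 na_len_range = na_len_range,
                 exon_count_range = exon_count_range,
                 exon_len_range = exon_len_range,
                 intron_len_range = intron_len_range,
                 border = optseqs$border, adaptor = optseqs$adaptor,
                 vector = optseqs$vector),
            class = "sim_design")
}

# write a codon (forward-strand representation) into a chromosome string
.write_codon <- function(seq, pos0, codon) {
  paste0(substring(seq, 1, pos0), codon,
         substring(seq, pos0 + 4, nchar(seq)))
}

#' Simulate a genome with gene models and a duplicated block
#'
#' Uniform-random DNA per chromosome; non-overlapping multi-exon genes on
#' both strands, each with a real ATG at its start-codon position and a stop
#' codon at its CDS end; one 2-kb block duplicated between the first and
#' last chromosomes (the repeat-read locus). Identical seeds give identical
#' output.
#'
#' @param design a [sim_design]
#' @return list with `genome` (named character vector), `genes` (list of
#'   [gene_model]), and `dup_blocks` (data.frame `chrom`, `start`, `end`,
#'   0-based half-open)
#' @export
simulate_genome <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  withr::with_seed(design$seed, {
    genome <- vapply(design$chrom_lengths, .random_dna, "")
    names(genome) <- names(design$chrom_lengths)
    genes <- list()
    gid <- 0L
    for (ci in seq_along(genome)) {
      chrom <- names(genome)[ci]
      L <- design$chrom_lengths[[ci]]
      ng <- design$n_genes[ci]
      if (ng == 0L) next
      slot <- (L - 4000) / ng
      for (k in seq_len(ng)) {
        n_ex <- sample(design$exon_count_range[1L]:design$exon_count_range[2L], 1L)
        ex_len <- sample(design$exon_len_range[1L]:design$exon_len_range[2L],
                         n_ex, replace = TRUE)
        in_len <- if (n_ex > 1L)
          sample(design$intron_len_range[1L]:design$intron_len_range[2L],
                 n_ex - 1L, replace = TRUE) else integer(0)
        tx_len <- sum(ex_len) + sum(in_len)
        if (tx_len + 2400 > slot)
          stop("genes requested beyond chromosome capacity on ", chrom)
        jitter <- floor(runif(1L, 0, slot - tx_len - 2400))
        tx_start <- floor(2000 + (k - 1) * slot + 1200 + jitter)
        es <- numeric(n_ex); ee <- numeric(n_ex)
        cur <- tx_start
        for (e in seq_len(n_ex)) {
          es[e] <- cur; ee[e] <- cur + ex_len[e]
          cur <- ee[e] + if (e < n_ex) in_len[e] else 0
        }
        tx_end <- ee[n_ex]
        utr5 <- sample(30:80, 1L); utr3 <- sample(30:80, 1L)
        cds_start <- es[1L] + utr5
        cds_end <- ee[n_ex] - utr3
        strand <- sample(c("+", "-"), 1L)
        gid <- gid + 1L
        gene_id <- sprintf("SYNG%03d", gid)
        genes[[gid]] <- gene_model(gene_id, chrom, strand, tx_start, tx_end,
                                   es, ee, cds_start, cds_end,
                                   description = paste("synthetic gene", gid),
                                   cds_flagged = FALSE)
        # anchor real start/stop codons in the sequence
        if (strand == "+") {
          genome[ci] <- .write_codon(genome[ci], cds_start, "ATG")
          genome[ci] <- .write_codon(genome[ci], cds_end - 3, "TGA")
        } else {
          genome[ci] <- .write_codon(genome[ci], cds_end - 3, "CAT")
          genome[ci] <- .write_codon(genome[ci], cds_start, "TCA")
        }
      }
    }
    # duplicated 2-kb block: copy from the start gap of chr1 (before any
    # gene) into the start gap of the last chromosome
    if (min(design$chrom_lengths) < 4100)
      stop("chromosomes too short for the duplicated block")
    src <- c(1, 50, 2050)      # chrom index, start, end (0-based)
    dst_ci <- length(genome)
    block <- substring(genome[[1L]], src[2L] + 1, src[3L])
    dst_start <- 50
    genome[dst_ci] <- paste0(substring(genome[[dst_ci]], 1, dst_start),
                             block,
                             substring(genome[[dst_ci]], dst_start + 2001,
                                       nchar(genome[[dst_ci]])))
    dup_blocks <- data.frame(
      chrom = c(names(genome)[1L], names(genome)[dst_ci]),
      start = c(50, dst_start), end = c(2050, dst_start + 2000),
      stringsAsFactors = FALSE)
    list(genome = genome, genes = genes, dup_blocks = dup_blocks)
  })
}

# itype the pipeline's categorization assigns to a bare position
.position_call <- function(store, chrom, position) {
  call <- structure(list(fst_id = "probe", chrom = chrom, position = position,
                         strand = "+", itype = NA_character_,
                         gene_id = NA_character_,
                         gene_description = NA_character_,
                         distance_to_gene = NA_real_,
                         subfeature = NA_character_),
                    class = "insertion_call")
  categorize(call, store)
}

.count_occurrences <- function(genome_set, segment) {
  pat <- Biostrings::DNAString(segment)
  sum(Biostrings::vcountPattern(pat, genome_set)) +
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                  genome_set))
}

#' Simulate an FST batch with ground truth
#'
#' Every intended-A read is border + genomic segment + adaptor at Q40, with
#' the segment sampled so that its junction coordinate has the intended
#' insertional type and the segment occurs exactly once in the genome
#' (twice, inside the duplicated block, for repeat reads). NA reads carry
#' segments at least 10 bp below the MSL; vector reads carry a vector
#' substring in place of genome; low-quality reads are Q8 throughout, below
#' the 0.03 error-probability trim threshold at every base.
#'
#' @param sim a [simulate_genome()] result
#' @param design the same [sim_design]
#' @return list with `reads` (list of [qual_seq_record]) and `truth`
#'   (data.frame: `fst_id`, `category`, `chrom`, `position` 1-based junction
#'   coordinate, `strand`, `itype`, `gene_id`)
#' @export
simulate_fsts <- function(sim, design) {
  stopifnot(inherits(design, "sim_design"))
  genome <- sim$genome
  genome_set <- Biostrings::DNAStringSet(genome)
  store <- annotation_store(sim$genes, design$chrom_lengths)
  withr::with_seed(design$seed + 1L, {
    reads <- list(); truth <- list()
    add <- function(seq, quals, category, chrom = NA, position = NA,
                    strand = NA, itype = NA, gene_id = NA) {
      i <- length(reads) + 1L
      id <- sprintf("FST%04d", i)
      reads[[i]] <<- qual_seq_record(id, seq, quals)
      truth[[i]] <<- data.frame(
        fst_id = id, category = category, chrom = as.character(chrom),
        position = as.numeric(position), strand = as.character(strand),
        itype = as.character(itype), gene_id = as.character(gene_id),
        stringsAsFactors = FALSE)
    }
    seg_at <- function(chrom, j0, L, strand) {
      # segment whose border-adjacent base sits at 0-based coordinate j0
      cl <- nchar(genome[[chrom]])
      if (strand == "+") {
        if (j0 + L > cl) return(NULL)
        substring(genome[[chrom]], j0 + 1, j0 + L)
      } else {
        if (j0 - L + 1 < 0) return(NULL)
        revcomp(substring(genome[[chrom]], j0 - L + 2, j0 + 1))
      }
    }
    mkread <- function(seg) paste0(design$border, seg, design$adaptor)
    q40 <- function(s) rep(40L, nchar(s))

    # candidate junctions for each intended type
    sample_junction <- function(itype) {
      for (try in 1:500) {
        if (itype == "intergenic") {
          chrom <- sample(names(genome), 1L)
          j0 <- sample.int(nchar(genome[[chrom]]) - 200L, 1L) - 1L
        } else {
          g <- sim$genes[[sample.int(length(sim$genes), 1L)]]
          chrom <- g$chrom
          j0 <- switch(itype,
            exon = {
              cs <- pmax(g$exon_starts, g$cds_start)
              ce <- pmin(g$exon_ends, g$cds_end)
              ok <- which(ce - cs > 10)
              if (!length(ok)) next
              e <- sample(rep(ok, 2L), 1L)
              sample(seq(cs[e] + 2, ce[e] - 3), 1L)
            },
            intron = {
              if (length(g$exon_starts) < 2L) next
              i <- sample(rep(seq_len(length(g$exon_starts) - 1L), 2L), 1L)
              lo <- g$exon_ends[i] + 5; hi <- g$exon_starts[i + 1L] - 5
              if (hi <= lo) next
              sample(seq(lo, hi), 1L)
            },
            upstream5 = {
              a <- .atg_pos(g)
              if (g$strand == "+") sample(seq(a - 900, a - 30), 1L)
              else sample(seq(a + 30, a + 900), 1L)
            },
            downstream3 = {
              s <- .stop_pos(g)
              if (g$strand == "+") sample(seq(s + 10, s + 280), 1L)
              else sample(seq(s - 280, s - 10), 1L)
            })
        }
        if (j0 < 150 || j0 > nchar(genome[[chrom]]) - 150) next
        pc <- .position_call(store, chrom, j0 + 1)
        if (identical(pc$itype, itype)) return(list(chrom = chrom, j0 = j0,
                                                    call = pc))
      }
      stop("no eligible locus found for intended category ", itype)
    }

    for (itype in names(design$n_per_itype)) {
      n <- design$n_per_itype[[itype]]
      made <- 0L
      while (made < n) {
        cand <- sample_junction(itype)
        strand <- sample(c("+", "-"), 1L)
        L <- sample(design$segment_len_range[1L]:design$segment_len_range[2L], 1L)
        seg <- seg_at(cand$chrom, cand$j0, L, strand)
        if (is.null(seg) || .count_occurrences(genome_set, seg) != 1L) next
        add(mkread(seg), q40(mkread(seg)), "A", cand$chrom, cand$j0 + 1,
            strand, itype, cand$call$gene_id)
        made <- made + 1L
      }
    }

    # repeat-locus reads sample the duplicated block interior
    db <- sim$dup_blocks[1L, ]
    made <- 0L
    while (made < design$n_repeat) {
      L <- sample(design$segment_len_range[1L]:design$segment_len_range[2L], 1L)
      strand <- sample(c("+", "-"), 1L)
      j0 <- sample(seq(db$start + L + 5, db$end - L - 5), 1L)
      seg <- seg_at(db$chrom, j0, L, strand)
      if (is.null(seg) || .count_occurrences(genome_set, seg) != 2L) next
      add(mkread(seg), q40(mkread(seg)), "A", NA, NA, NA, "repeat", NA)
      made <- made + 1L
    }

    for (i in seq_len(design$n_na)) {
      chrom <- sample(names(genome), 1L)
      L <- sample(design$na_len_range[1L]:design$na_len_range[2L], 1L)
      j0 <- sample.int(nchar(genome[[chrom]]) - L - 10L, 1L) - 1L
      seg <- seg_at(chrom, j0, L, "+")
      add(mkread(seg), q40(mkread(seg)), "NA")
    }
    for (i in seq_len(design$n_vector)) {
      L <- sample(100:150, 1L)
      s0 <- sample.int(nchar(design$vector) - L, 1L)
      seg <- substring(design$vector, s0, s0 + L - 1L)
      add(mkread(seg), q40(mkread(seg)), "VECTOR")
    }
    for (i in seq_len(design$n_low)) {
      chrom <- sample(names(genome), 1L)
      j0 <- sample.int(nchar(genome[[chrom]]) - 100L, 1L) - 1L
      seg <- seg_at(chrom, j0, 80L, "+")
      rd <- mkread(seg)
      add(rd, rep(8L, nchar(rd)), "LOW")
    }

    ord <- sample.int(length(reads))
    list(reads = reads[ord], truth = do.call(rbind, truth)[ord, ])
  })
}

# serialize gene models to a GRanges hierarchy for GFF3 export
.genes_to_gff3 <- function(genes) {
  rows <- list()
  for (g in genes) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = g$tx_start + 1, end = g$tx_end,
      strand = g$strand, type = "gene", ID = g$gene_id, Parent = NA,
      phase = NA_integer_, descr = g$description)
    tid <- paste0(g$gene_id, ".1")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = g$tx_start + 1, end = g$tx_end,
      strand = g$strand, type = "mRNA", ID = tid, Parent = g$gene_id,
      phase = NA_integer_, descr = NA)
    cds <- list()
    for (e in seq_along(g$exon_starts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = g$exon_starts[e] + 1, end = g$exon_ends[e],
        strand = g$strand, type = "exon",
        ID = sprintf("%s.exon%d", tid, e), Parent = tid,
        phase = NA_integer_, descr = NA)
      cs <- max(g$exon_starts[e], g$cds_start)
      ce <- min(g$exon_ends[e], g$cds_end)
      if (ce > cs) cds[[length(cds) + 1L]] <- c(cs, ce)
    }
    # phase: bases to skip to reach the next codon start, accumulated in
    # transcript orientation
    ord <- if (g$strand == "+") seq_along(cds) else rev(seq_along(cds))
    cum <- 0
    for (k in seq_along(ord)) {
      iv <- cds[[ord[k]]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = iv[1L] + 1, end = iv[2L], strand = g$strand,
        type = "CDS", ID = sprintf("%s.cds%d", tid, k), Parent = tid,
        phase = as.integer((3 - cum %% 3) %% 3), descr = NA)
      cum <- cum + (iv[2L] - iv[1L])
    }
  }
  do.call(rbind, rows)
}

#' Write synthetic gene models as GFF3
#'
#' @param genes list of [gene_model] objects
#' @param path output GFF3 path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path) {
  tab <- .genes_to_gff3(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  gr$phase <- tab$phase
  gr$description <- tab$descr
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
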