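# Mapping module: align acceptable FSTs to the genome, pick the integration
# site, detect repeat loci, categorize by genomic context, and report the
# interrupted or nearest gene.

#' Build an annotation store for insertion categorization
#'
#' Precomputes, per chromosome, interval sets for transcript bodies, exons,
#' and strand-aware upstream/downstream flanks: for a `+` gene the upstream
#' flank is the `upstream_bp` window 5' of the ATG and the downstream flank
#' the `downstream_bp` window 3' of the stop codon (mirrored for `-` genes).
#' Flank intervals exclude positions inside the same gene's transcript.
#'
#' @param genes list of [gene_model] objects
#' @param chrom_lengths named numeric vector of chromosome lengths (bp)
#' @param upstream_bp genic region extent 5' of the ATG (default 1000)
#' @param downstream_bp genic region extent 3' of the stop (default 300)
#' @return an object of class `annotation_store`
#' @export
annotation_store <- function(genes, chrom_lengths, upstream_bp = 1000L,
                             downstream_bp = 300L) {
  stopifnot(!is.null(names(chrom_lengths)), upstream_bp >= 0,
            downstream_bp >= 0)
  for (g in genes) {
    if (!g$chrom %in% names(chrom_lengths)) next
    if (g$tx_end > chrom_lengths[[g$chrom]])
      stop("gene ", g$gene_id, " extends beyond chromosome ", g$chrom)
  }
  by_chrom <- split(genes, vapply(genes, `[[`, "", "chrom"))
  tabs <- lapply(by_chrom, function(gl) {
    up <- t(vapply(gl, function(g) {
      if (g$strand == "+") c(.atg_pos(g) - upstream_bp, .atg_pos(g))
      else c(.atg_pos(g) + 1, .atg_pos(g) + 1 + upstream_bp)
    }, numeric(2)))
    dn <- t(vapply(gl, function(g) {
      if (g$strand == "+") c(.stop_pos(g) + 1, .stop_pos(g) + 1 + downstream_bp)
      else c(.stop_pos(g) - downstream_bp, .stop_pos(g))
    }, numeric(2)))
    list(genes = gl,
         tx = IRanges::IRanges(
           start = vapply(gl, `[[`, 0, "tx_start") + 1L,
           end = vapply(gl, `[[`, 0, "tx_end")),
         up = IRanges::IRanges(start = pmax(up[, 1L], 0) + 1L,
                               end = pmax(up[, 2L], 0)),
         dn = IRanges::IRanges(start = pmax(dn[, 1L], 0) + 1L,
                               end = pmax(dn[, 2L], 0)))
  })
  structure(list(chrom_lengths = chrom_lengths, genes = genes,
                 tabs = tabs, upstream_bp = upstream_bp,
                 downstream_bp = downstream_bp),
            class = "annotation_store")
}

#' Map one acceptable FST's genomic segment to the genome
#'
#' Only the unmasked genomic segment is aligned. Hits are filtered to the
#' mapping e-value cutoff (default 1e-5) and sorted by descending score.
#'
#' @param mfst a `masked_fst` with category `"A"`
#' @param genome_index [build_index()] over the genome chromosomes
#' @param scoring a [scoring_params]
#' @param evalue_cutoff mapping e-value threshold (default 1e-5)
#' @return data.frame of hits as in [search_hits()]
#' @export
map_fst <- function(mfst, genome_index, scoring = scoring_params(),
                    evalue_cutoff = 1e-5) {
  stopifnot(inherits(mfst, "masked_fst"))
  if (mfst$category != "A")
    stop("map_fst expects an acceptable (A) FST, got ", mfst$category)
  seg <- genomic_segment(mfst)
  search_hits(qual_seq_record(mfst$record$id, seg), genome_index, scoring,
              evalue_cutoff = evalue_cutoff)
}

# does the border mask sit left or right of the genomic segment?
.border_side <- function(mfst) {
  b_iv <- .mask_matrix(mfst$mask, "border")
  if (!nrow(b_iv)) return("none")
  seg <- mfst$genomic_segment
  if (any(b_iv[, 2L] <= seg[1L])) "left"
  else if (any(b_iv[, 1L] >= seg[2L])) "right"
  else "none"
}

#' Select the integration site from a hit list
#'
#' The highest-scoring region is the integration site. When two or more hits
#' tie the top raw score at distinct loci (subject overlap <= 50% with the
#' top hit) the FST is a `repeat` with no position; with no hits it is
#' `unmapped`. Otherwise the position is the 1-based genome coordinate
#' aligned to the query base adjacent to the border mask (the junction
#' base); without a border mask, the query-5'-most aligned base.
#'
#' @param mfst the `masked_fst` that produced the hits
#' @param hits [map_fst()] output (sorted by descending score)
#' @return an object of class `insertion_call`: `fst_id`, `chrom`,
#'   `position` (1-based), `strand`, `itype` (here `repeat`, `unmapped`, or
#'   `NA` pending [categorize()])
#' @export
call_insertion <- function(mfst, hits) {
  fst_id <- mfst$record$id
  mk <- function(chrom = NA_character_, position = NA_real_,
                 strand = NA_character_, itype = NA_character_)
    structure(list(fst_id = fst_id, chrom = chrom, position = position,
                   strand = strand, itype = itype, gene_id = NA_character_,
                   gene_description = NA_character_,
                   distance_to_gene = NA_real_, subfeature = NA_character_),
              class = "insertion_call")
  if (!nrow(hits)) return(mk(itype = "unmapped"))
  top <- hits[1L, ]
  if (nrow(hits) > 1L) {
    ties <- hits[-1L, , drop = FALSE]
    ties <- ties[ties$score == top$score, , drop = FALSE]
    if (nrow(ties)) {
      ov <- pmax(0, pmin(ties$s_end, top$s_end) -
                     pmax(ties$s_start, top$s_start))
      ov[ties$subject_id != top$subject_id] <- 0
      shorter <- pmin(ties$s_end - ties$s_start, top$s_end - top$s_start)
      if (any(ov <= 0.5 * shorter)) return(mk(itype = "repeat"))
    }
  }
  side <- .border_side(mfst)
  junction_left <- side %in% c("left", "none")
  pos <- if (junction_left == (top$strand == "+")) top$s_start + 1
         else top$s_end
  mk(chrom = top$subject_id, position = pos, strand = top$strand)
}

#' Nearest gene to a genomic position
#'
#' Distance is measured to the closer transcript boundary (zero inside a
#' transcript); ties go to the gene with the lower start coordinate. The
#' signed distance is negative when the gene lies 5' of the position on the
#' forward strand.
#'
#' @param position 1-based genomic coordinate
#' @param chrom chromosome name
#' @param store an [annotation_store]
#' @return list `(gene, distance)`; `gene = NULL` when the chromosome has no
#'   genes
#' @export
nearest_gene <- function(position, chrom, store) {
  tab <- store$tabs[[chrom]]
  if (is.null(tab) || !length(tab$genes)) return(list(gene = NULL, distance = NA))
  p0 <- position - 1
  ts <- IRanges::start(tab$tx) - 1L
  te <- IRanges::end(tab$tx)
  d <- pmax(0, pmax(ts - p0, p0 - (te - 1)))
  i <- order(d, ts)[1L]
  signed <- if (d[i] == 0) 0
    else if (te[i] - 1 < p0) -(p0 - (te[i] - 1))   # gene 5' of the site
    else ts[i] - p0
  list(gene = tab$genes[[i]], distance = signed)
}

#' Categorize an insertion call by genomic context
#'
#' Precedence: (1) inside a gene's transcript span -> `exon` (with
#' CDS/5UTR/3UTR subfeature) or `intron`; overlapping transcripts resolve to
#' the gene whose ATG is nearer. (2) inside an upstream flank -> `upstream5`;
#' (3) inside a downstream flank -> `downstream3`; competing flanks of
#' different genes resolve to the smaller distance (tie: upstream5).
#' (4) otherwise `intergenic` with the nearest gene and signed distance.
#' `repeat` and `unmapped` calls pass through unchanged.
#'
#' @param call an [call_insertion()] result with a position
#' @param store an [annotation_store]
#' @return the call with `itype`, `gene_id`, `gene_description`,
#'   `subfeature`, `distance_to_gene` filled in
#' @export
categorize <- function(call, store) {
  if (!is.na(call$itype) && call$itype %in% c("repeat", "unmapped"))
    return(call)
  stopifnot(!is.na(call$position))
  L <- store$chrom_lengths[[call$chrom]]
  if (is.null(L) || call$position > L || call$position < 1)
    stop("insertion call ", call$fst_id, ": position ", call$position,
         " outside chromosome ", call$chrom)
  p0 <- call$position - 1
  tab <- store$tabs[[call$chrom]]
  pq <- IRanges::IRanges(start = call$position, width = 1L)
  if (!is.null(tab) && length(tab$genes)) {
    # (1) transcript body
    txhit <- IRanges::overlapsAny(tab$tx, pq)
    if (any(txhit)) {
      cand <- which(txhit)
      atg_d <- vapply(cand, function(i) abs(p0 - .atg_pos(tab$genes[[i]])), 0)
      g <- tab$genes[[cand[order(atg_d)[1L]]]]
      in_exon <- any(p0 >= g$exon_starts & p0 < g$exon_ends)
      call$gene_id <- g$gene_id
      call$gene_description <- g$description
      call$distance_to_gene <- 0
      if (in_exon) {
        call$itype <- "exon"
        call$subfeature <-
          if (p0 >= g$cds_start && p0 < g$cds_end) "CDS"
          else if ((g$strand == "+" && p0 < g$cds_start) ||
                   (g$strand == "-" && p0 >= g$cds_end)) "5UTR"
          else "3UTR"
      } else call$itype <- "intron"
      return(call)
    }
    # (2)/(3) flanks, transcript-excluded
    up_i <- which(IRanges::overlapsAny(tab$up, pq) & !txhit)
    dn_i <- which(IRanges::overlapsAny(tab$dn, pq) & !txhit)
    # a position inside any transcript was handled above, so overlap with a
    # *different* gene's transcript cannot occur here; exclude only the
    # flank owner's transcript
    up_i <- up_i[!IRanges::overlapsAny(tab$tx[up_i], pq)]
    dn_i <- dn_i[!IRanges::overlapsAny(tab$tx[dn_i], pq)]
    best <- NULL
    for (i in up_i) {
      d <- abs(p0 - .atg_pos(tab$genes[[i]]))
      if (is.null(best) || d < best$d) best <- list(type = "upstream5", i = i, d = d)
    }
    for (i in dn_i) {
      d <- abs(p0 - .stop_pos(tab$genes[[i]]))
      if (is.null(best) || d < best$d) best <- list(type = "downstream3", i = i, d = d)
    }
    if (!is.null(best)) {
      g <- tab$genes[[best$i]]
      call$itype <- best$type
      call$gene_id <- g$gene_id
      call$gene_description <- g$description
      call$distance_to_gene <- best$d
      return(call)
    }
  }
  # (4) intergenic
  ng <- nearest_gene(call$position, call$chrom, store)
  call$itype <- "intergenic"
  if (!is.null(ng$gene)) {
    call$gene_id <- ng$gene$gene_id
    call$gene_description <- ng$gene$description
    call$distance_to_gene <- ng$distance
  }
  call
}

#' Extract the genome flank around an insertion, marked with asterisks
#'
#' Returns `genome[pos - flank, pos)`, five asterisks marking the insertion
#' point, then `genome[pos, pos + flank)`, truncated at chromosome edges.
#'
#' @param genome named character vector of chromosome sequences
#' @param call an insertion call with a position
#' @param flank_bp flank length, 500-1000 bp (default 1000)
#' @return the marked flank string
#' @export
extract_flank <- function(genome, call, flank_bp = 1000L) {
  stopifnot(flank_bp >= 500L, flank_bp <= 1000L, !is.na(call$position))
  s <- genome[[call$chrom]]
  L <- nchar(s)
  p0 <- call$position - 1
  left <- substring(s, max(0, p0 - flank_bp) + 1, p0)
  right <- substring(s, p0 + 1, min(L, p0 + flank_bp))
  paste0(left, "*****", right)
}

#' Map, call, and categorize a batch of validated FSTs
#'
#' Runs [map_fst()], [call_insertion()], and [categorize()] over every
#' acceptable read of a validation result.
#'
#' @param masked list of `masked_fst` objects (all categories; non-A reads
#'   are skipped)
#' @param genome_index [build_index()] over the genome
#' @param store an [annotation_store]
#' @param scoring a [scoring_params]
#' @param evalue_cutoff mapping e-value threshold (default 1e-5)
#' @return list of `insertion_call` objects, one per acceptable read
#' @export
map_batch <- function(masked, genome_index, store,
                      scoring = scoring_params(), evalue_cutoff = 1e-5) {
  acc <- Filter(function(m) m$category == "A", masked)
  lapply(acc, function(m) {
    hits <- map_fst(m, genome_index, scoring, evalue_cutoff)
    categorize(call_insertion(m, hits), store)
  })
}

#' Flatten insertion calls to a report table
#'
#' @param calls list of `insertion_call` objects
#' @return data.frame with one row per call (1-based positions)
#' @export
calls_table <- function(calls) {
  data.frame(
    fst_id = vapply(calls, `[[`, "", "fst_id"),
    chrom = vapply(calls, `[[`, "", "chrom"),
    position = vapply(calls, `[[`, 0, "position"),
    strand = vapply(calls, `[[`, "", "strand"),
    itype = vapply(calls, `[[`, "", "itype"),
    subfeature = vapply(calls, `[[`, "", "subfeature"),
    gene_id = vapply(calls, `[[`, "", "gene_id"),
    gene_description = vapply(calls, `[[`, "", "gene_description"),
    distance_to_gene = vapply(calls, `[[`, 0, "distance_to_gene"),
    stringsAsFactors = FALSE)
}
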