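# Sequence and annotation input/output.
#
# Internal convention: all coordinates are 0-based half-open; every
# user-facing report converts to 1-based inclusive.

#' Construct a sequence record
#'
#' A minimal container for one FST read: identifier, DNA string, and optional
#' per-base Phred qualities.
#'
#' @param id non-empty record identifier
#' @param seq DNA string over A/C/G/T/N (case-insensitive; stored upper case)
#' @param quals optional integer vector of Phred scores, same length as `seq`
#' @return an object of class `qual_seq_record`
#' @export
qual_seq_record <- function(id, seq, quals = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(as.character(seq))
  if (nzchar(seq) && grepl("[^ACGTN]", seq))
    stop("record '", id, "': sequence contains characters outside A/C/G/T/N")
  if (!is.null(quals)) {
    quals <- as.integer(quals)
    if (length(quals) != nchar(seq))
      stop("record '", id, "': ", length(quals), " quality values for ",
           nchar(seq), " bases")
    if (any(quals < 0L)) stop("record '", id, "': negative Phred score")
  }
  structure(list(id = id, seq = seq, quals = quals),
            class = "qual_seq_record")
}

#' @export
print.qual_seq_record <- function(x, ...) {
  cat(sprintf("<qual_seq_record> %s: %d bp%s\n", x$id, nchar(x$seq),
              if (is.null(x$quals)) "" else " (+quals)"))
  invisible(x)
}

.check_duplicate_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate record ids: ", paste(dup, collapse = ", "))
}

.read_fasta_records <- function(path) {
  first <- ""
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) break
    if (nzchar(trimws(ln))) { first <- ln; break }
  }
  if (nzchar(first) && !startsWith(first, ">"))
    stop("malformed FASTA in '", path, "': first record (line 1) does not start with '>'")
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  .check_duplicate_ids(ids)
  mapply(function(i, s) qual_seq_record(i, s),
         ids, as.character(x), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

.read_fastq_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in '", path, "': ", length(lines),
         " lines is not a multiple of 4 (near line ", length(lines), ")")
  n <- length(lines) %/% 4L
  recs <- vector("list", n)
  for (k in seq_len(n)) {
    i <- (k - 1L) * 4L
    if (!startsWith(lines[i + 1L], "@"))
      stop("malformed FASTQ record ", k, " in '", path, "': line ", i + 1L,
           " does not start with '@'")
    if (!startsWith(lines[i + 3L], "+"))
      stop("malformed FASTQ record ", k, " in '", path, "': line ", i + 3L,
           " does not start with '+'")
    if (nchar(lines[i + 2L]) != nchar(lines[i + 4L]))
      stop("malformed FASTQ record ", k, " in '", path,
           "': sequence and quality lengths differ (line ", i + 4L, ")")
    id <- sub("\\s.*$", "", substring(lines[i + 1L], 2L))
    quals <- as.integer(charToRaw(lines[i + 4L])) - 33L
    recs[[k]] <- qual_seq_record(id, lines[i + 2L], quals)
  }
  .check_duplicate_ids(vapply(recs, `[[`, "", "id"))
  recs
}

# phred/consed PHD dialect: bases in a BEGIN_DNA ... END_DNA block,
# one "base quality [position]" triple per line.
.read_phd_record <- function(path) {
  lines <- readLines(path)
  id <- NA_character_
  seqline <- grep("^BEGIN_SEQUENCE", lines, value = TRUE)
  if (length(seqline)) id <- trimws(sub("^BEGIN_SEQUENCE\\s*", "", seqline[1L]))
  if (is.na(id) || !nzchar(id))
    id <- sub("\\.phd(\\.\\d+)?$", "", basename(path))
  b <- which(lines == "BEGIN_DNA")
  e <- which(lines == "END_DNA")
  if (length(b) != 1L || length(e) != 1L || e <= b)
    stop("malformed PHD file '", basename(path),
         "': expected one BEGIN_DNA/END_DNA block")
  body <- lines[(b + 1L):(e - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(qual_seq_record(id, "", integer(0)))
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad))
    stop("malformed PHD file '", basename(path), "': line ", b + bad[1L],
         " lacks a 'base quality' pair")
  bases <- toupper(vapply(fields, `[[`, "", 1L))
  quals <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(quals))
    stop("malformed PHD file '", basename(path), "': non-numeric quality")
  qual_seq_record(id, paste(bases, collapse = ""), quals)
}

.read_phd_zip <- function(path) {
  listing <- utils::unzip(path, list = TRUE)
  members <- listing$Name[!grepl("/$", listing$Name)]
  if (!length(members)) return(list())
  tmp <- tempfile("phd")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, files = members, exdir = tmp, junkpaths = FALSE)
  recs <- lapply(members, function(m) .read_phd_record(file.path(tmp, m)))
  .check_duplicate_ids(vapply(recs, `[[`, "", "id"))
  recs
}

.detect_seq_format <- function(path) {
  lc <- tolower(path)
  if (grepl("\\.zip$", lc)) return("phd_zip")
  if (grepl("\\.(fastq|fq)$", lc)) return("fastq")
  if (grepl("\\.(fasta|fa|fna|fas)$", lc)) return("fasta")
  first <- readLines(path, n = 1L)
  if (!length(first)) return("fasta")
  if (startsWith(first, "@")) "fastq" else "fasta"
}

#' Read FST sequences from FASTA, FASTQ, or a ZIP of PHD files
#'
#' FASTQ qualities are decoded as Phred+33; PHD files carry explicit integer
#' qualities. FASTA records have no qualities. Sequence case is normalized to
#' upper case on input.
#'
#' @param path input file
#' @param format one of `"fasta"`, `"fastq"`, `"phd_zip"`, `"auto"`
#' @return list of [qual_seq_record] objects (possibly empty, with a warning)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq", "phd_zip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") format <- .detect_seq_format(path)
  recs <- switch(format,
    fasta = .read_fasta_records(path),
    fastq = .read_fastq_records(path),
    phd_zip = .read_phd_zip(path))
  if (!length(recs)) warning("no sequence records found in '", path, "'")
  recs
}

#' Quality-trim a read by the modified-Mott algorithm
#'
#' Finds the contiguous subread maximizing the running sum of
#' `max_error_prob - 10^(-q/10)` over its bases, i.e. the maximal-scoring
#' segment where bases better than the error-probability threshold score
#' positively. Records without qualities are returned whole. An all-bad read
#' trims to length zero. Equal-scoring segments resolve to the leftmost,
#' then longest.
#'
#' @param rec a [qual_seq_record]
#' @param max_error_prob error-probability threshold (default 0.03)
#' @return list with `record` (trimmed [qual_seq_record]), `kept` (0-based
#'   half-open interval `c(start, end)` on the original read), and
#'   `max_error_prob`
#' @export
trim_by_quality <- function(rec, max_error_prob = 0.03) {
  stopifnot(inherits(rec, "qual_seq_record"), max_error_prob > 0)
  n <- nchar(rec$seq)
  if (is.null(rec$quals)) {
    return(list(record = rec, kept = c(0L, n), max_error_prob = max_error_prob))
  }
  sc <- max_error_prob - 10^(-rec$quals / 10)
  # maximal-scoring segment via prefix sums; ties resolve to the leftmost
  # start, then the longest segment
  eps <- 1e-12
  P <- c(0, cumsum(sc))
  best <- 0; bs <- 0L; be <- 0L
  minP <- P[1L]; min_s <- 0L
  for (e in seq_len(n)) {
    cand <- P[e + 1L] - minP
    if (cand > best + eps ||
        (cand > eps && abs(cand - best) <= eps &&
         (min_s < bs || (min_s == bs && e > be)))) {
      best <- cand; bs <- min_s; be <- e
    }
    if (P[e + 1L] < minP - eps) { minP <- P[e + 1L]; min_s <- e }
  }
  if (be == bs) {
    trimmed <- qual_seq_record(rec$id, "", integer(0))
    return(list(record = trimmed, kept = c(0L, 0L),
                max_error_prob = max_error_prob))
  }
  trimmed <- qual_seq_record(rec$id,
                             substring(rec$seq, bs + 1L, be),
                             rec$quals[(bs + 1L):be])
  list(record = trimmed, kept = c(bs, be), max_error_prob = max_error_prob)
}

# ------------------------------------------------------------------
# gene models

#' Construct a gene model
#'
#' Coordinates are 0-based half-open on the forward strand. `cds_start`/
#' `cds_end` bound the coding sequence; for a `+` gene the ATG starts at
#' `cds_start` and the stop codon ends at `cds_end`; for a `-` gene the ATG
#' base is `cds_end - 1` and the stop codon ends (in gene orientation) at
#' `cds_start`.
#'
#' @param gene_id gene identifier
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param tx_start,tx_end transcript span, 0-based half-open
#' @param exon_starts,exon_ends parallel vectors of exon bounds within the
#'   transcript, sorted, non-overlapping
#' @param cds_start,cds_end CDS bounds; when the annotation lacks a CDS these
#'   default to the transcript bounds and `cds_flagged` is set
#' @param description free-text gene description
#' @param cds_flagged `TRUE` when CDS bounds were imputed from the transcript
#' @return an object of class `gene_model`
#' @export
gene_model <- function(gene_id, chrom, strand, tx_start, tx_end,
                       exon_starts, exon_ends,
                       cds_start = NA, cds_end = NA,
                       description = "", cds_flagged = FALSE) {
  stopifnot(strand %in% c("+", "-"), tx_start < tx_end,
            length(exon_starts) == length(exon_ends))
  o <- order(exon_starts)
  exon_starts <- as.numeric(exon_starts[o]); exon_ends <- as.numeric(exon_ends[o])
  if (any(exon_starts >= exon_ends)) stop("gene ", gene_id, ": empty exon")
  if (any(exon_starts < tx_start) || any(exon_ends > tx_end))
    stop("gene ", gene_id, ": exon outside transcript span")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)]))
    stop("gene ", gene_id, ": overlapping exons")
  if (is.na(cds_start) || is.na(cds_end)) {
    cds_start <- tx_start; cds_end <- tx_end; cds_flagged <- TRUE
  }
  if (cds_start < tx_start || cds_end > tx_end || cds_start >= cds_end)
    stop("gene ", gene_id, ": CDS outside transcript or empty")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tx_start = as.numeric(tx_start), tx_end = as.numeric(tx_end),
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 cds_start = as.numeric(cds_start),
                 cds_end = as.numeric(cds_end),
                 description = description, cds_flagged = cds_flagged),
            class = "gene_model")
}

# 0-based position of the A of the start codon / boundary past the stop codon
.atg_pos <- function(g) if (g$strand == "+") g$cds_start else g$cds_end - 1
.stop_pos <- function(g) if (g$strand == "+") g$cds_end - 1 else g$cds_start

.gff_attr <- function(meta, keys) {
  for (k in keys) {
    if (!is.null(meta[[k]])) {
      v <- meta[[k]]
      if (is(v, "CharacterList")) v <- vapply(v, function(z)
        if (length(z)) z[[1L]] else NA_character_, "")
      return(as.character(v))
    }
  }
  rep(NA_character_, nrow(meta))
}

.read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  type <- tolower(as.character(gr$type))
  ids <- .gff_attr(meta, c("ID"))
  parents <- if (!is.null(gr$Parent)) vapply(gr$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, "") else rep(NA_character_, length(gr))
  descr <- .gff_attr(meta, c("description", "Note", "Name"))
  is_gene <- type == "gene"
  is_tx <- type %in% c("mrna", "transcript")
  is_exon <- type == "exon"
  is_cds <- type == "cds"
  genes <- list()
  for (gi in which(is_gene)) {
    gid <- ids[gi]
    chrom <- as.character(GenomicRanges::seqnames(gr)[gi])
    strand <- as.character(GenomicRanges::strand(gr)[gi])
    if (!strand %in% c("+", "-")) strand <- "+"
    txi <- which(is_tx & parents == gid)
    if (length(txi)) {
      # longest transcript carries the gene structure
      w <- GenomicRanges::width(gr)[txi]
      tx <- txi[which.max(w)]
      tid <- ids[tx]
      exi <- which(is_exon & parents == tid)
      cdi <- which(is_cds & parents == tid)
      tx_start <- GenomicRanges::start(gr)[tx] - 1
      tx_end <- GenomicRanges::end(gr)[tx]
    } else {
      tid <- gid
      exi <- which(is_exon & parents == gid)
      cdi <- which(is_cds & parents == gid)
      tx_start <- GenomicRanges::start(gr)[gi] - 1
      tx_end <- GenomicRanges::end(gr)[gi]
    }
    if (length(exi)) {
      es <- GenomicRanges::start(gr)[exi] - 1
      ee <- GenomicRanges::end(gr)[exi]
    } else { es <- tx_start; ee <- tx_end }
    if (length(cdi)) {
      cs <- min(GenomicRanges::start(gr)[cdi]) - 1
      ce <- max(GenomicRanges::end(gr)[cdi])
      flag <- FALSE
    } else { cs <- NA; ce <- NA; flag <- TRUE }
    d <- descr[gi]
    genes[[length(genes) + 1L]] <- gene_model(
      gene_id = gid, chrom = chrom, strand = strand,
      tx_start = tx_start, tx_end = tx_end,
      exon_starts = es, exon_ends = ee,
      cds_start = cs, cds_end = ce,
      description = if (is.na(d)) "" else d, cds_flagged = flag)
  }
  genes
}

.read_bed12_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  genes <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!strand %in% c("+", "-")) strand <- "+"
    tx_start <- GenomicRanges::start(gr)[i] - 1
    tx_end <- GenomicRanges::end(gr)[i]
    if (!is.null(gr$blocks) && length(gr$blocks[[i]])) {
      bl <- gr$blocks[[i]]
      es <- tx_start + IRanges::start(bl) - 1
      ee <- tx_start + IRanges::end(bl)
    } else { es <- tx_start; ee <- tx_end }
    flag <- FALSE
    if (!is.null(gr$thick)) {
      cs <- GenomicRanges::start(gr$thick)[i] - 1
      ce <- GenomicRanges::end(gr$thick)[i]
      if (ce <= cs) { cs <- NA; ce <- NA; flag <- TRUE }
    } else { cs <- NA; ce <- NA; flag <- TRUE }
    nm <- if (!is.null(gr$name)) gr$name[i] else paste0("bed_", i)
    genes[[i]] <- gene_model(nm, chrom, strand, tx_start, tx_end, es, ee,
                             cs, ce, description = "", cds_flagged = flag)
  }
  genes
}

#' Read gene annotation from GFF3 or BED12
#'
#' One [gene_model] per gene. For GFF3 the longest transcript of each gene is
#' used; BED12 `thickStart`/`thickEnd` become the CDS bounds. Genes without a
#' CDS keep transcript bounds as CDS and are flagged. All coordinates are
#' converted to 0-based half-open.
#'
#' @param path annotation file
#' @param format `"gff3"`, `"bed12"`, or `"auto"` (by extension)
#' @return list of [gene_model] objects
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", tolower(path))) "bed12" else "gff3"
  }
  if (format == "gff3") .read_gff3_genes(path) else .read_bed12_genes(path)
}

# merge overlapping/adjacent 0-based half-open intervals given as 2-col matrix
.merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), ncol = 2))
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    j <- nrow(out)
    if (iv[i, 1L] <= out[j, 2L]) out[j, 2L] <- max(out[j, 2L], iv[i, 2L])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

#' Write masked FSTs as case-annotated FASTA
#'
#' Masked positions (border/adaptor/vector) are written lower-case, genomic
#' positions upper-case; upper-casing the output reproduces the input
#' sequences exactly. Overlapping mask intervals are merged before writing.
#'
#' @param records list of `masked_fst` objects (see [classify()])
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_masked_fasta <- function(records, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) {
    stopifnot(inherits(r, "masked_fst"))
    s <- r$record$seq
    iv <- .merge_intervals(.mask_matrix(r$mask))
    if (nrow(iv)) {
      chars <- strsplit(s, "")[[1L]]
      for (i in seq_len(nrow(iv))) {
        idx <- seq.int(iv[i, 1L] + 1L, iv[i, 2L])
        chars[idx] <- tolower(chars[idx])
      }
      s <- paste(chars, collapse = "")
    }
    writeLines(c(paste0(">", r$record$id), s), con)
  }
  invisible(path)
}

#' Write records as plain FASTA
#'
#' @param records list of [qual_seq_record] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) writeLines(c(paste0(">", r$id), r$seq), con)
  invisible(path)
}

#' Write records as Phred+33 FASTQ
#'
#' Records without qualities are written at Q40.
#'
#' @param records list of [qual_seq_record] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) {
    q <- if (is.null(r$quals)) rep(40L, nchar(r$seq)) else r$quals
    writeLines(c(paste0("@", r$id), r$seq, "+",
                 rawToChar(as.raw(pmin(q, 93L) + 33L))), con)
  }
  invisible(path)
}
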