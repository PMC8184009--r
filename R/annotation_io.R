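#' Load a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file into an indexed, uppercased
#' [Biostrings::DNAStringSet]. IUPAC ambiguity codes other than N are
#' converted to N with a warning; symbols outside the IUPAC nucleotide
#' alphabet raise an error. Duplicate record names raise an error.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one entry per chromosome.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; chromosome name is the first token
  names(g) <- vapply(strsplit(names(g), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(names(g))) {
    stop("duplicate record names in FASTA: ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  }
  freq <- Biostrings::alphabetFrequency(g, collapse = TRUE)
  amb <- setdiff(names(freq)[freq > 0], c("A", "C", "G", "T", "N"))
  if (length(amb)) {
    warning("ambiguity codes ", paste(amb, collapse = ","),
            " present; converted to N")
    g <- Biostrings::DNAStringSet(
      chartr(paste(amb, collapse = ""),
             strrep("N", length(amb)), toupper(as.character(g))))
  }
  g
}

#' Extract a genomic slice
#'
#' Coordinates are 0-based half-open; `strand == "-"` returns the reverse
#' complement of the plus-strand slice, so the result always reads in sense
#' orientation.
#'
#' @param genome A `DNAStringSet` from [load_genome()].
#' @param chrom,start,end,strand Slice location.
#' @return A character DNA string of length `end - start`.
#' @export
genome_slice <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start > end) {
    stop("slice [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", len, ")")
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (strand == "-") s <- revcomp(s)
  s
}

#' Extract a window around a boundary, in sense orientation
#'
#' `anchor` is a cut point (0-based boundary between two bases). The window
#' covers `up` bases upstream and `down` bases downstream of the boundary in
#' *transcriptional* orientation. Windows clipped at a chromosome edge are
#' shortened and flagged with attribute `clipped = TRUE`.
#'
#' @param genome A `DNAStringSet`.
#' @param chrom,strand,anchor Boundary location.
#' @param up,down Bases upstream/downstream of the boundary (sense space).
#' @return Character DNA string with attribute `clipped`.
#' @export
extract_window <- function(genome, chrom, strand, anchor, up, down) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (anchor < 0 || anchor > len) stop("anchor outside chromosome: ", anchor)
  if (strand == "+") {
    s <- max(0L, anchor - up); e <- min(len, anchor + down)
  } else {
    s <- max(0L, anchor - down); e <- min(len, anchor + up)
  }
  clipped <- (e - s) < (up + down)
  w <- genome_slice(genome, chrom, s, e, strand)
  attr(w, "clipped") <- clipped
  w
}

# ---------------------------------------------------------------------------
# Transcript models and annotation indexes

#' Construct a transcript model
#'
#' Exons are genomic 0-based half-open intervals, stored in ascending genomic
#' order regardless of strand; transcript orientation is derived from
#' `strand`. `cds` is an optional set of genomic intervals contained in the
#' exons.
#'
#' @param transcript_id,gene_id,chrom,strand Identifiers and location.
#' @param exons data.frame with columns `start`, `end`.
#' @param cds Optional data.frame with columns `start`, `end`.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) stop("empty exon in ", transcript_id)
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  if (!is.null(cds) && nrow(cds)) {
    cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
    cds$start <- as.integer(cds$start)
    cds$end <- as.integer(cds$end)
    rownames(cds) <- NULL
  } else {
    cds <- NULL
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

tx_length <- function(t) sum(t$exons$end - t$exons$start)

# Intron intervals of a transcript, ascending genomic order (n_exons - 1 rows)
tx_introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = t$exons$end[-n], end = t$exons$start[-1])
}

#' Map genomic positions to mRNA coordinates
#'
#' Positions must be exonic (0-based genomic base positions); non-exonic
#' input raises an error. Vectorized. The inverse is [mrna_to_genome()];
#' the two are bijective over exonic space.
#'
#' @param t A `transcript_model`.
#' @param gpos Integer vector of genomic positions.
#' @return Integer vector of 0-based mRNA coordinates.
#' @export
genome_to_mrna <- function(t, gpos) {
  ex <- t$exons
  idx <- findInterval(gpos, ex$start)
  bad <- idx == 0 | gpos >= ex$end[pmax(idx, 1L)]
  if (any(bad)) {
    stop("position(s) not exonic in ", t$transcript_id, ": ",
         paste(utils::head(gpos[bad], 5), collapse = ", "))
  }
  cum <- cumsum(c(0L, ex$end - ex$start))
  m_plus <- cum[idx] + (gpos - ex$start[idx])
  if (t$strand == "+") m_plus else tx_length(t) - 1L - m_plus
}

#' @rdname genome_to_mrna
#' @param mpos Integer vector of 0-based mRNA coordinates.
#' @export
mrna_to_genome <- function(t, mpos) {
  L <- tx_length(t)
  if (any(mpos < 0 | mpos >= L)) stop("mRNA coordinate out of range")
  m_plus <- if (t$strand == "+") mpos else L - 1L - mpos
  ex <- t$exons
  cum <- cumsum(c(0L, ex$end - ex$start))
  idx <- findInterval(m_plus, cum, rightmost.closed = FALSE)
  ex$start[idx] + (m_plus - cum[idx])
}

#' Reconstruct the mature mRNA sequence of a transcript
#'
#' @param t A `transcript_model`.
#' @param genome A `DNAStringSet`.
#' @return Character DNA string of length equal to the summed exon lengths,
#'   in sense orientation.
#' @export
transcript_sequence <- function(t, genome) {
  pieces <- mapply(function(s, e) genome_slice(genome, t$chrom, s, e, "+"),
                   t$exons$start, t$exons$end)
  s <- paste(pieces, collapse = "")
  if (t$strand == "-") s <- revcomp(s)
  s
}

#' Load a GTF annotation
#'
#' Reads an Ensembl-dialect GTF (features `exon` and `CDS`; all others
#' ignored), converts 1-based inclusive coordinates to the internal 0-based
#' half-open convention, and builds the junction, donor/acceptor and
#' exon/intron interval indexes used throughout the pipeline.
#'
#' @param path Path to a GTF file.
#' @param genome A `DNAStringSet`; transcripts on chromosomes absent from it
#'   are rejected with an error listing them.
#' @return A `genome_annotation` object: list with elements `transcripts`
#'   (named list of `transcript_model`), `tx_table`, `junctions`, `jx_tx`
#'   (junction-to-transcript map with intron index in transcript
#'   orientation), `donors`, `acceptors` (site-key sets), and `exons_gr` /
#'   `introns_gr` ([GenomicRanges::GRanges] point-query indexes).
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (!length(gr)) stop("no exon/CDS features in ", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,      # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    stringsAsFactors = FALSE)
  missing_chr <- setdiff(unique(df$chrom), names(genome))
  if (length(missing_chr)) {
    stop("transcripts on chromosomes absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(df$start < 0 | df$end > chrlen[df$chrom])) {
    stop("exon/CDS outside chromosome bounds")
  }
  txs <- split(df, df$transcript_id)
  transcripts <- lapply(txs, function(d) {
    ex <- d[d$type == "exon", ]
    cd <- d[d$type == "CDS", ]
    transcript_model(ex$transcript_id[1], ex$gene_id[1], ex$chrom[1],
                     ex$strand[1], ex[, c("start", "end")],
                     if (nrow(cd)) cd[, c("start", "end")] else NULL)
  })
  build_annotation(transcripts)
}

#' Build a `genome_annotation` from transcript models
#'
#' Used by [load_annotation()] and directly by the simulator/tests.
#'
#' @param transcripts List of `transcript_model` objects.
#' @return A `genome_annotation` object.
#' @export
build_annotation <- function(transcripts) {
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "transcript_id")
  tx_table <- data.frame(
    transcript_id = names(transcripts),
    gene_id = vapply(transcripts, `[[`, character(1), "gene_id"),
    chrom = vapply(transcripts, `[[`, character(1), "chrom"),
    strand = vapply(transcripts, `[[`, character(1), "strand"),
    n_exons = vapply(transcripts, function(t) nrow(t$exons), integer(1)),
    tx_len = vapply(transcripts, tx_length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  jx_list <- lapply(transcripts, function(t) {
    intr <- tx_introns(t)
    if (!nrow(intr)) return(NULL)
    # intron index in transcript orientation (1 = most 5')
    idx <- if (t$strand == "+") seq_len(nrow(intr)) else rev(seq_len(nrow(intr)))
    data.frame(chrom = t$chrom, strand = t$strand,
               start = intr$start, end = intr$end,
               transcript_id = t$transcript_id, gene_id = t$gene_id,
               intron_index = idx, stringsAsFactors = FALSE)
  })
  jx_tx <- rbind_all(jx_list)
  if (is.null(jx_tx)) {
    jx_tx <- data.frame(chrom = character(0), strand = character(0),
                        start = integer(0), end = integer(0),
                        transcript_id = character(0), gene_id = character(0),
                        intron_index = integer(0))
  }
  jx_tx$key <- junction_key(jx_tx$chrom, jx_tx$strand, jx_tx$start, jx_tx$end)
  junctions <- jx_tx[!duplicated(jx_tx$key),
                     c("chrom", "strand", "start", "end", "key")]
  junctions$donor <- donor_boundary(junctions$strand, junctions$start,
                                    junctions$end)
  junctions$acceptor <- acceptor_boundary(junctions$strand, junctions$start,
                                          junctions$end)
  rownames(junctions) <- NULL

  donors <- unique(site_key(junctions$chrom, junctions$strand, junctions$donor))
  acceptors <- unique(site_key(junctions$chrom, junctions$strand,
                               junctions$acceptor))

  mk_gr <- function(get_iv) {
    rows <- lapply(transcripts, function(t) {
      iv <- get_iv(t)
      if (!nrow(iv)) return(NULL)
      data.frame(chrom = t$chrom, start = iv$start, end = iv$end,
                 strand = t$strand, transcript_id = t$transcript_id,
                 gene_id = t$gene_id, stringsAsFactors = FALSE)
    })
    d <- rbind_all(rows)
    if (is.null(d)) {
      return(GenomicRanges::GRanges())
    }
    GenomicRanges::GRanges(d$chrom,
                           IRanges::IRanges(d$start + 1L, d$end),
                           strand = d$strand, transcript_id = d$transcript_id,
                           gene_id = d$gene_id)
  }
  structure(list(transcripts = transcripts, tx_table = tx_table,
                 junctions = junctions, jx_tx = jx_tx,
                 donors = donors, acceptors = acceptors,
                 exons_gr = mk_gr(function(t) t$exons),
                 introns_gr = mk_gr(tx_introns)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$tx_table), "transcripts,",
      nrow(x$junctions), "junctions,",
      length(x$donors), "donors,", length(x$acceptors), "acceptors\n")
  invisible(x)
}

# Point query: is (chrom, strand, pos) inside an annotated exon / intron?
# Returns union over all transcripts.
point_in_index <- function(gr, chrom, strand, pos) {
  if (!length(gr)) return(FALSE)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L),
                              strand = strand)
  length(GenomicRanges::findOverlaps(q, gr)) > 0
}
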