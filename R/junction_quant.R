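#' Extract junction-spanning split reads from a spliced alignment file
#'
#' Mines a SAM or BAM file for high-quality junction-spanning reads: primary,
#' mapped, non-duplicate alignments with at most `max_mismatches` mismatches
#' (NM tag; reads lacking NM are excluded and counted) and at least
#' `min_overhang` nt in the shortest aligned block immediately flanking each
#' CIGAR N-operation. Each qualifying N-operation increments its junction
#' once. Junction strand is taken from the XS splice-strand tag when present,
#' otherwise inferred from the intron-terminal dinucleotides (GT..AG on the
#' plus strand, CT..AC for minus) when a genome is supplied, otherwise stored
#' unstranded (`"*"`).
#'
#' @param path Path to a SAM or BAM file (SAM is converted on the fly).
#' @param min_overhang Minimum flanking aligned-block length in nt.
#' @param max_mismatches Maximum NM value for a read to qualify.
#' @param genome Optional `DNAStringSet` for dinucleotide strand inference.
#' @return List with `counts` (data.frame chrom/strand/start/end/count, intron
#'   interval 0-based half-open), `library_size` (number of qualifying
#'   primary mapped reads) and `n_missing_nm`.
#' @export
extract_split_reads <- function(path, min_overhang = 8L, max_mismatches = 0L,
                                genome = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, tag = c("NM", "XS"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  nm <- S4Vectors::mcols(aln)$NM
  xs <- S4Vectors::mcols(aln)$XS
  n_missing_nm <- sum(is.na(nm))
  if (n_missing_nm > 0) {
    warning(n_missing_nm, " read(s) lacking NM tag excluded")
  }
  keep <- !is.na(nm) & nm <= max_mismatches
  aln <- aln[keep]
  xs <- if (is.null(xs)) rep(NA_character_, length(aln)) else xs[keep]
  library_size <- length(aln)

  cig <- GenomicAlignments::cigar(aln)
  has_n <- grepl("N", cig, fixed = TRUE)
  counts <- data.frame(chrom = character(0), strand = character(0),
                       start = integer(0), end = integer(0),
                       count = integer(0), stringsAsFactors = FALSE)
  if (any(has_n)) {
    spl <- aln[has_n]
    xs_spl <- xs[has_n]
    ops <- GenomicAlignments::explodeCigarOps(GenomicAlignments::cigar(spl))
    lens <- GenomicAlignments::explodeCigarOpLengths(
      GenomicAlignments::cigar(spl))
    jlist <- mapply(function(op, ln, pos, chrom, xstag) {
      split_read_junctions(op, ln, pos, chrom, xstag, min_overhang)
    }, ops, lens, GenomicAlignments::start(spl),
      as.character(GenomicAlignments::seqnames(spl)), xs_spl,
      SIMPLIFY = FALSE)
    jx <- rbind_all(jlist)
    if (!is.null(jx) && nrow(jx)) {
      jx$strand <- infer_strand(jx, genome)
      key <- junction_key(jx$chrom, jx$strand, jx$start, jx$end)
      tab <- table(key)
      first <- jx[!duplicated(key), ]
      first <- first[match(names(tab), junction_key(first$chrom, first$strand,
                                                    first$start, first$end)), ]
      counts <- data.frame(chrom = first$chrom, strand = first$strand,
                           start = first$start, end = first$end,
                           count = as.integer(tab), stringsAsFactors = FALSE)
      counts <- counts[order(counts$chrom, counts$start, counts$end,
                             counts$strand), ]
      rownames(counts) <- NULL
    }
  }
  list(counts = counts, library_size = library_size,
       n_missing_nm = n_missing_nm)
}

# One read's qualifying junctions from exploded CIGAR. Aligned-block length
# between N operations = total M/=/X length of the block; overhang of an N op
# is the shorter of its two flanking blocks.
split_read_junctions <- function(ops, lens, pos, chrom, xstag, min_overhang) {
  ref_consume <- ops %in% c("M", "D", "N", "=", "X")
  ref_start <- pos - 1L + c(0L, cumsum(lens * ref_consume))[seq_along(ops)]
  n_idx <- which(ops == "N")
  if (!length(n_idx)) return(NULL)
  # block id between N ops (soft/hard clips do not break blocks)
  block_id <- cumsum(ops == "N") + 1L
  block_id[n_idx] <- NA_integer_
  aligned <- ops %in% c("M", "=", "X")
  block_len <- tapply(lens[aligned], block_id[aligned], sum)
  res <- lapply(n_idx, function(i) {
    if (i == 1L || i == length(ops)) return(NULL)
    left <- block_len[as.character(block_id[i - 1L])]
    b_after <- cumsum(ops == "N")[i] + 1L
    right <- block_len[as.character(b_after)]
    if (is.na(left) || is.na(right)) return(NULL)
    if (min(left, right) < min_overhang) return(NULL)
    data.frame(chrom = chrom, start = ref_start[i],
               end = ref_start[i] + lens[i],
               xs = if (is.na(xstag)) NA_character_ else xstag,
               stringsAsFactors = FALSE)
  })
  rbind_all(res)
}

infer_strand <- function(jx, genome) {
  strand <- ifelse(is.na(jx$xs), "*", jx$xs)
  need <- strand == "*"
  if (any(need) && !is.null(genome)) {
    for (i in which(need)) {
      d5 <- genome_slice(genome, jx$chrom[i], jx$start[i], jx$start[i] + 2L)
      d3 <- genome_slice(genome, jx$chrom[i], jx$end[i] - 2L, jx$end[i])
      if (d5 == "GT" && d3 == "AG") strand[i] <- "+"
      else if (d5 == "CT" && d3 == "AC") strand[i] <- "-"
    }
  }
  strand
}

#' Assemble a junction count matrix across libraries
#'
#' @param per_sample Named list of [extract_split_reads()] results, one per
#'   library.
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `is_control` (logical), rows matching `names(per_sample)`.
#' @return A `junction_count_matrix`: list with `junctions` (data.frame),
#'   `samples`, `raw` (junction x sample integer matrix), `library_sizes`,
#'   and empty `normalized` / `psi` slots filled by [normalize_counts()] and
#'   [compute_psi()].
#' @export
junction_count_matrix <- function(per_sample, samples) {
  stopifnot(all(samples$sample_id %in% names(per_sample)))
  per_sample <- per_sample[samples$sample_id]
  all_j <- unique(do.call(rbind, c(lapply(per_sample, function(x)
    x$counts[, c("chrom", "strand", "start", "end")]),
    list(make.row.names = FALSE))))
  if (is.null(all_j) || !nrow(all_j)) {
    all_j <- data.frame(chrom = character(0), strand = character(0),
                        start = integer(0), end = integer(0))
  }
  all_j <- all_j[order(all_j$chrom, all_j$start, all_j$end, all_j$strand), ,
                 drop = FALSE]
  rownames(all_j) <- NULL
  all_j$key <- junction_key(all_j$chrom, all_j$strand, all_j$start, all_j$end)
  raw <- matrix(0L, nrow(all_j), nrow(samples),
                dimnames = list(all_j$key, samples$sample_id))
  for (s in samples$sample_id) {
    cts <- per_sample[[s]]$counts
    if (nrow(cts)) {
      k <- junction_key(cts$chrom, cts$strand, cts$start, cts$end)
      raw[k, s] <- cts$count
    }
  }
  structure(list(junctions = all_j, samples = samples, raw = raw,
                 library_sizes = vapply(per_sample, `[[`, numeric(1),
                                        "library_size"),
                 normalized = NULL, psi = NULL),
            class = "junction_count_matrix")
}

#' Normalize raw split-read counts to library depth (counts per million)
#'
#' @param m A `junction_count_matrix`.
#' @return `m` with the `normalized` matrix filled; raw counts preserved.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "junction_count_matrix"))
  zero <- m$library_sizes <= 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(names(m$library_sizes)[zero], collapse = ", "))
  }
  m$normalized <- sweep(m$raw, 2, m$library_sizes, "/") * 1e6
  m
}

#' Compute per-library PSI for every junction
#'
#' PSI for junction j in sample s is `raw(j,s)` divided by the summed raw
#' counts of all junctions sharing j's donor site or j's acceptor site
#' (including j itself) — a local-splice-variant proxy. PSI is `NA`
#' (undefined, not zero) when that denominator is zero.
#'
#' @param m A `junction_count_matrix`.
#' @return `m` with the `psi` matrix filled.
#' @export
compute_psi <- function(m) {
  stopifnot(inherits(m, "junction_count_matrix"))
  j <- m$junctions
  dk <- site_key(j$chrom, j$strand, donor_boundary(j$strand, j$start, j$end))
  ak <- site_key(j$chrom, j$strand, acceptor_boundary(j$strand, j$start, j$end))
  psi <- m$raw * NA_real_
  for (s in seq_len(ncol(m$raw))) {
    x <- m$raw[, s]
    dsum <- tapply(x, dk, sum)[dk]
    asum <- tapply(x, ak, sum)[ak]
    denom <- dsum + asum - x
    psi[, s] <- ifelse(denom > 0, x / denom, NA_real_)
  }
  m$psi <- psi
  m
}

#' Write a junction count table as TSV
#'
#' One row per junction with raw, CPM and PSI columns per library.
#' @param m A normalized, PSI-filled `junction_count_matrix`.
#' @param path Output TSV path.
#' @export
write_junction_counts <- function(m, path) {
  out <- m$junctions[, c("chrom", "strand", "start", "end")]
  sid <- m$samples$sample_id
  for (s in sid) out[[paste0("raw_", s)]] <- m$raw[, s]
  if (!is.null(m$normalized)) {
    for (s in sid) out[[paste0("cpm_", s)]] <- m$normalized[, s]
  }
  if (!is.null(m$psi)) {
    for (s in sid) out[[paste0("psi_", s)]] <- m$psi[, s]
  }
  attr_line <- paste0("#library_sizes\t",
                      paste(sid, m$library_sizes[sid], sep = "=",
                            collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a junction count table written by [write_junction_counts()]
#'
#' @param path TSV path.
#' @param samples Sample sheet data.frame (`sample_id`, `condition`,
#'   `is_control`).
#' @return A `junction_count_matrix`.
#' @export
read_junction_counts <- function(path, samples) {
  first <- readLines(path, n = 1)
  libs <- NULL
  if (startsWith(first, "#library_sizes")) {
    kv <- strsplit(strsplit(first, "\t")[[1]][-1], "=")
    libs <- stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                            vapply(kv, `[`, character(1), 1))
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                         stringsAsFactors = FALSE)
  j <- d[, c("chrom", "strand", "start", "end")]
  j$key <- junction_key(j$chrom, j$strand, j$start, j$end)
  sid <- samples$sample_id
  get_mat <- function(prefix) {
    cols <- paste0(prefix, sid)
    if (!all(cols %in% names(d))) return(NULL)
    mm <- as.matrix(d[, cols, drop = FALSE])
    dimnames(mm) <- list(j$key, sid)
    mm
  }
  m <- structure(list(junctions = j, samples = samples,
                      raw = get_mat("raw_"),
                      library_sizes = libs[sid],
                      normalized = get_mat("cpm_"), psi = get_mat("psi_")),
                 class = "junction_count_matrix")
  m
}
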