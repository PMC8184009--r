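#' mRNA coordinates of a transcript's exon-exon junctions
#'
#' Junction i (in transcript orientation) sits at the cumulative length of
#' the first i exons; a transcript with n exons has n-1 junctions.
#'
#' @param t A `transcript_model`.
#' @return Integer vector of 0-based mRNA cut points (empty for single-exon
#'   transcripts).
#' @export
map_junctions_to_mrna <- function(t) {
  lens <- t$exons$end - t$exons$start
  if (t$strand == "-") lens <- rev(lens)
  n <- length(lens)
  if (n < 2) return(integer(0))
  cumsum(lens)[-n]
}

#' Detect splice-site remnants regenerated at exon-exon junctions
#'
#' For every junction on the mature mRNA, tests both site types: a
#' regenerated 5' splice site requires GT as the first two bases downstream
#' of the junction, a regenerated 3' splice site requires AG as the last two
#' bases upstream. PWM scores are computed on the mRNA window spanning the
#' junction (donor geometry: 3 nt upstream + 6 nt downstream; acceptor: 14
#' upstream + 3 downstream); windows clipped at transcript ends yield a
#' missing score.
#'
#' @param t A `transcript_model` with at least one junction.
#' @param genome A `DNAStringSet`.
#' @param donor_pwm,acceptor_pwm Trained `pwm` objects (optional; scores NA
#'   when absent).
#' @return data.frame with one row per (junction, site type):
#'   `transcript_id`, `junction_index`, `mrna_pos`, `site_type`,
#'   `dinucleotide_ok`, `score`.
#' @export
detect_regenerated_sites <- function(t, genome, donor_pwm = NULL,
                                     acceptor_pwm = NULL) {
  jx <- map_junctions_to_mrna(t)
  if (!length(jx)) {
    return(data.frame(transcript_id = character(0),
                      junction_index = integer(0), mrna_pos = integer(0),
                      site_type = character(0), dinucleotide_ok = logical(0),
                      score = numeric(0)))
  }
  m <- transcript_sequence(t, genome)
  L <- nchar(m)
  rows <- lapply(seq_along(jx), function(i) {
    J <- jx[i]
    down2 <- substr(m, J + 1, J + 2)
    up2 <- substr(m, J - 1, J)
    sc5 <- mrna_window_score(m, J, donor_pwm)
    sc3 <- mrna_window_score(m, J, acceptor_pwm)
    data.frame(transcript_id = t$transcript_id, junction_index = i,
               mrna_pos = J,
               site_type = c("regenerated_5ss", "regenerated_3ss"),
               dinucleotide_ok = c(identical(down2, "GT"),
                                   identical(up2, "AG")),
               score = c(sc5, sc3), stringsAsFactors = FALSE)
  })
  rbind_all(rows)
}

# normalized PWM score of the mRNA window around cut point J, using the
# PWM's own geometry (exonic_up upstream of the cut for donors; width -
# exonic_down upstream for acceptors). NA when pwm NULL or window clipped.
mrna_window_score <- function(m, J, pwm) {
  if (is.null(pwm)) return(NA_real_)
  up <- if (pwm$kind == "donor") pwm$exonic_up else pwm$width - pwm$exonic_down
  s <- J - up
  e <- s + pwm$width
  if (s < 0 || e > nchar(m)) return(NA_real_)
  score_site(pwm, substr(m, s + 1, e))$normalized
}

#' Call re-splicing-compatible events for a cryptic junction
#'
#' For an `exonic_5ss` call (novel donor joined to an annotated acceptor A),
#' locates the mRNA junction formed by removal of the intron ending at A and
#' emits an event iff that junction carries a regenerated 3' splice site
#' with the AG dinucleotide; the predicted mRNA deletion runs from the
#' cryptic donor cut to the junction. For an `exonic_3ss` call (annotated
#' donor D joined to a novel acceptor), the junction formed by removal of
#' the intron starting at D must carry a regenerated 5' GT; the deletion
#' runs from the junction to the cryptic acceptor cut. Events are computed
#' per host transcript, de-duplicated by identical mRNA sequence context,
#' sorted by partner score (descending); deletions reaching a transcript
#' end are dropped and counted (attribute `n_dropped_at_end`). mRNA cut
#' points of junctions strictly inside the deletion are listed in
#' `intermediate_junctions`.
#'
#' @param call One-row data.frame: a classified cryptic call.
#' @param ann A `genome_annotation`.
#' @param genome A `DNAStringSet`.
#' @param donor_pwm,acceptor_pwm Optional `pwm` objects for partner scores.
#' @return data.frame of re-splicing events (possibly empty).
#' @export
resplicing_compatibility <- function(call, ann, genome, donor_pwm = NULL,
                                     acceptor_pwm = NULL) {
  stopifnot(nrow(call) == 1)
  empty <- data.frame(key = character(0), transcript_id = character(0),
                      gene_id = character(0), junction_index = integer(0),
                      site_type = character(0), partner_score = numeric(0),
                      deletion_start = integer(0), deletion_end = integer(0),
                      deletion_length = integer(0),
                      intermediate_junctions = character(0),
                      stringsAsFactors = FALSE)
  if (!call$css_class %in% c("exonic_5ss", "exonic_3ss")) return(empty)
  strand <- call$strand
  d <- donor_boundary(strand, call$start, call$end)
  a <- acceptor_boundary(strand, call$start, call$end)
  novel_is_donor <- call$css_class == "exonic_5ss"
  ann_boundary <- if (novel_is_donor) a else d
  role <- if (novel_is_donor) "acceptor" else "donor"

  jx <- ann$jx_tx
  b <- if (role == "donor") donor_boundary(jx$strand, jx$start, jx$end)
       else acceptor_boundary(jx$strand, jx$start, jx$end)
  hosts <- jx[jx$chrom == call$chrom & jx$strand == strand &
                b == ann_boundary, ]
  if (!nrow(hosts)) {
    stop("no host transcript carries the annotated ",
         role, " at ", ann_boundary)
  }
  n_dropped <- 0L
  rows <- list()
  for (h in seq_len(nrow(hosts))) {
    t <- ann$transcripts[[hosts$transcript_id[h]]]
    jxm <- map_junctions_to_mrna(t)
    J <- jxm[hosts$intron_index[h]]
    # novel-end cut point on this transcript's mRNA (novel base must be
    # exonic in the host)
    cut <- tryCatch(
      novel_site_mrna_cut(
        data.frame(strand = strand, start = call$start, end = call$end,
                   novel_end = if (novel_is_donor) "donor" else "acceptor"),
        t),
      error = function(e) NA_integer_)
    if (is.na(cut)) next
    m <- transcript_sequence(t, genome)
    if (novel_is_donor) {
      del <- c(cut, J)
      need_type <- "regenerated_3ss"
      dinuc_ok <- substr(m, J - 1, J) == "AG"
      pwm <- acceptor_pwm
    } else {
      del <- c(J, cut)
      need_type <- "regenerated_5ss"
      dinuc_ok <- substr(m, J + 1, J + 2) == "GT"
      pwm <- donor_pwm
    }
    if (!dinuc_ok) next
    if (del[2] <= del[1]) next
    if (del[1] <= 0 || del[2] >= nchar(m)) {
      n_dropped <- n_dropped + 1L
      next
    }
    inter <- jxm[jxm > del[1] & jxm < del[2] & jxm != J]
    rows[[length(rows) + 1]] <- data.frame(
      key = call$key %||% junction_key(call$chrom, strand, call$start,
                                       call$end),
      transcript_id = t$transcript_id, gene_id = t$gene_id,
      junction_index = hosts$intron_index[h], site_type = need_type,
      partner_score = mrna_window_score(m, J, pwm),
      deletion_start = del[1], deletion_end = del[2],
      deletion_length = del[2] - del[1],
      intermediate_junctions = paste(inter, collapse = ","),
      context = paste0(substr(m, max(1, del[1] - 20), del[1]),
                       "|", substr(m, del[2] + 1, del[2] + 20)),
      stringsAsFactors = FALSE)
  }
  ev <- rbind_all(rows)
  if (is.null(ev)) ev <- empty
  else {
    ev <- ev[!duplicated(ev$context), , drop = FALSE]
    ev <- ev[order(-ifelse(is.na(ev$partner_score), -Inf,
                           ev$partner_score)), , drop = FALSE]
    ev$context <- NULL
    rownames(ev) <- NULL
  }
  attr(ev, "n_dropped_at_end") <- n_dropped
  ev
}

#' Annotate the coding consequence of a predicted mRNA deletion
#'
#' The deletion span (mRNA coordinates) is intersected with the
#' transcript's CDS. Fully inside the CDS: length divisible by 3 gives an
#' in-frame deletion with the number of removed amino acids computed by
#' translating the reference and deleted CDS and diffing; otherwise a
#' frameshift. Deletions crossing the CDS start or end are flagged
#' `spans_start_or_stop`; transcripts without CDS (or deletions confined to
#' UTR) are `noncoding`.
#'
#' @param deletion_start,deletion_end 0-based half-open mRNA deletion span.
#' @param t A `transcript_model`.
#' @param genome A `DNAStringSet`.
#' @return List with `frame_consequence` and `aa_deleted` (NA unless
#'   in-frame).
#' @export
consequence <- function(deletion_start, deletion_end, t, genome) {
  if (deletion_end <= deletion_start) stop("empty deletion span")
  L <- tx_length(t)
  if (deletion_start < 0 || deletion_end > L) {
    stop("deletion outside transcript bounds")
  }
  if (is.null(t$cds)) {
    return(list(frame_consequence = "noncoding", aa_deleted = NA_integer_))
  }
  cds_m <- cds_mrna_interval(t)
  s <- deletion_start; e <- deletion_end
  if (e <= cds_m[1] || s >= cds_m[2]) {
    return(list(frame_consequence = "noncoding", aa_deleted = NA_integer_))
  }
  if (s < cds_m[1] || e > cds_m[2]) {
    return(list(frame_consequence = "spans_start_or_stop",
                aa_deleted = NA_integer_))
  }
  len <- e - s
  if (len %% 3 != 0) {
    return(list(frame_consequence = "frameshift", aa_deleted = NA_integer_))
  }
  m <- transcript_sequence(t, genome)
  ref_cds <- substr(m, cds_m[1] + 1, cds_m[2])
  del_cds <- paste0(substr(m, cds_m[1] + 1, s),
                    substr(m, e + 1, cds_m[2]))
  aa <- translated_aa_deleted(ref_cds, del_cds)
  list(frame_consequence = "in_frame_deletion", aa_deleted = aa)
}

# CDS as an mRNA interval [start, end), from the genomic CDS intervals
cds_mrna_interval <- function(t) {
  stopifnot(!is.null(t$cds))
  # first and last CDS base in mRNA space
  firsts <- genome_to_mrna(t, t$cds$start)
  lasts <- genome_to_mrna(t, t$cds$end - 1L)
  all_pos <- c(firsts, lasts)
  c(min(all_pos), max(all_pos) + 1L)
}

translated_aa_deleted <- function(ref_cds, del_cds) {
  trim <- function(s) substr(s, 1, 3 * (nchar(s) %/% 3))
  ref_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(trim(ref_cds)), if.fuzzy.codon = "X"))
  del_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(trim(del_cds)), if.fuzzy.codon = "X"))
  nchar(ref_aa) - nchar(del_aa)
}

#' Scan all cryptic calls for re-splicing events and annotate consequences
#'
#' @param calls Classified cryptic calls.
#' @param ann A `genome_annotation`.
#' @param genome A `DNAStringSet`.
#' @param donor_pwm,acceptor_pwm Optional `pwm` objects.
#' @return data.frame of events with `frame_consequence` and `aa_deleted`.
#' @export
scan_resplicing <- function(calls, ann, genome, donor_pwm = NULL,
                            acceptor_pwm = NULL) {
  evs <- lapply(seq_len(nrow(calls)), function(i) {
    if (!calls$css_class[i] %in% c("exonic_5ss", "exonic_3ss")) return(NULL)
    tryCatch(resplicing_compatibility(calls[i, , drop = FALSE], ann, genome,
                                      donor_pwm, acceptor_pwm),
             error = function(e) NULL)
  })
  ev <- rbind_all(evs)
  if (is.null(ev) || !nrow(ev)) {
    out <- data.frame(key = character(0), transcript_id = character(0),
                      gene_id = character(0), junction_index = integer(0),
                      site_type = character(0), partner_score = numeric(0),
                      deletion_start = integer(0), deletion_end = integer(0),
                      deletion_length = integer(0),
                      intermediate_junctions = character(0),
                      frame_consequence = character(0),
                      aa_deleted = integer(0))
    return(out)
  }
  cons <- lapply(seq_len(nrow(ev)), function(i) {
    t <- ann$transcripts[[ev$transcript_id[i]]]
    consequence(ev$deletion_start[i], ev$deletion_end[i], t, genome)
  })
  ev$frame_consequence <- vapply(cons, `[[`, character(1),
                                 "frame_consequence")
  ev$aa_deleted <- vapply(cons, `[[`, integer(1), "aa_deleted")
  rownames(ev) <- NULL
  ev
}

#' Predicted re-spliced mRNA product sequence
#'
#' Deletes the event span from the reconstructed mature mRNA and rejoins.
#'
#' @param event One event row.
#' @param ann A `genome_annotation`.
#' @param genome A `DNAStringSet`.
#' @return Character DNA string.
#' @export
respliced_product <- function(event, ann, genome) {
  t <- ann$transcripts[[event$transcript_id]]
  m <- transcript_sequence(t, genome)
  paste0(substr(m, 1, event$deletion_start),
         substr(m, event$deletion_end + 1, nchar(m)))
}
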