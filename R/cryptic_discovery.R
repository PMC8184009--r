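#' Pipeline thresholds and parameters
#'
#' Defaults follow the discovery cascade: junctions need at least 5 split
#' reads in the aggregate data, a greater-than-2-fold depth-normalized count
#' increase in at least 2 of the knockdown conditions relative to control,
#' and a greater-than-2-fold PSI increase in at least 2 knockdown
#' conditions. Pseudocounts bound the ratios when control expression is zero
#' (the typical case for cryptic junctions).
#'
#' @param min_aggregate_reads Minimum summed raw reads across all libraries.
#' @param count_fc_threshold Fold-change threshold on CPM (strict `>`).
#' @param psi_fc_threshold Fold-change threshold on PSI (strict `>`).
#' @param min_concordant_kd Minimum number of knockdown conditions that must
#'   individually exceed each fold-change threshold.
#' @param count_pseudocount CPM pseudocount added to both ratio terms.
#' @param psi_epsilon PSI pseudocount; undefined PSI is treated as 0 before
#'   adding it.
#' @param strong_ss_threshold Normalized PWM score above which a site is
#'   reported as strong.
#' @param metagene_window Half-width (nt) of the metagene window around
#'   exon-exon junctions.
#' @param ejc_offset Expected EJC deposition distance upstream of exon-exon
#'   junctions (nt, mRNA space).
#' @param ejc_footprint_halfwidth Half-width of the EJC footprint flag
#'   window around `-ejc_offset`.
#' @param bp_window Branchpoint search window upstream of the 3' splice
#'   site, nt (interval).
#' @param bp_match_min Minimum normalized branchpoint PWM match.
#' @param min_overhang,max_mismatches Split-read quality filters.
#' @param n_permutations Permutations for the set-overlap test.
#' @param rng_seed Seed for seeded operations.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_aggregate_reads = 5, count_fc_threshold = 2,
                            psi_fc_threshold = 2, min_concordant_kd = 2,
                            count_pseudocount = 1, psi_epsilon = 0.01,
                            strong_ss_threshold = 0.75, metagene_window = 50,
                            ejc_offset = 24, ejc_footprint_halfwidth = 10,
                            bp_window = c(15, 45), bp_match_min = 0.75,
                            min_overhang = 8, max_mismatches = 0,
                            n_permutations = 1e5, rng_seed = 1L) {
  cfg <- list(min_aggregate_reads = min_aggregate_reads,
              count_fc_threshold = count_fc_threshold,
              psi_fc_threshold = psi_fc_threshold,
              min_concordant_kd = min_concordant_kd,
              count_pseudocount = count_pseudocount,
              psi_epsilon = psi_epsilon,
              strong_ss_threshold = strong_ss_threshold,
              metagene_window = metagene_window, ejc_offset = ejc_offset,
              ejc_footprint_halfwidth = ejc_footprint_halfwidth,
              bp_window = bp_window, bp_match_min = bp_match_min,
              min_overhang = min_overhang, max_mismatches = max_mismatches,
              n_permutations = n_permutations, rng_seed = rng_seed)
  stopifnot(min_aggregate_reads > 0, count_fc_threshold > 0,
            psi_fc_threshold > 0, bp_window[1] < bp_window[2])
  structure(cfg, class = "pipeline_config")
}

#' Flag junctions absent from the annotation
#'
#' A junction is novel iff its (chrom, strand, donor, acceptor) quadruple is
#' not an annotated junction. Unstranded junctions (`"*"`) are matched
#' against both strands and adopt the annotated strand on a hit.
#'
#' @param junctions data.frame with chrom/strand/start/end.
#' @param ann A `genome_annotation`.
#' @return `junctions` with logical column `annotated` (strand resolved
#'   where possible).
#' @export
identify_novel <- function(junctions, ann) {
  known <- ann$junctions$key
  strand <- junctions$strand
  unres <- strand == "*"
  if (any(unres)) {
    plus <- junction_key(junctions$chrom, "+", junctions$start, junctions$end)
    minus <- junction_key(junctions$chrom, "-", junctions$start, junctions$end)
    strand[unres & plus %in% known] <- "+"
    strand[unres & minus %in% known] <- "-"
  }
  junctions$strand <- strand
  junctions$annotated <- junction_key(junctions$chrom, strand,
                                      junctions$start,
                                      junctions$end) %in% known
  junctions
}

#' Apply the cryptic-junction filter cascade
#'
#' Selects unannotated junctions that (1) carry at least
#' `min_aggregate_reads` raw split reads summed over all libraries, (2) show
#' a CPM fold change above `count_fc_threshold` in at least
#' `min_concordant_kd` knockdown conditions relative to control, and (3)
#' show a PSI fold change above `psi_fc_threshold` in at least
#' `min_concordant_kd` knockdown conditions. Fold changes are recorded per
#' condition; samples within a condition are averaged.
#'
#' @param m A normalized, PSI-filled `junction_count_matrix`.
#' @param design List with `control` (sample ids) and `kd` (named list of
#'   condition -> sample ids).
#' @param cfg A `pipeline_config`.
#' @param ann A `genome_annotation` (for the novelty flag).
#' @return data.frame of cryptic junction calls with per-condition
#'   `count_fc_*` and `psi_fc_*` columns, `aggregate_reads`, plus the filter
#'   waterfall as attribute `waterfall`.
#' @export
filter_cryptic <- function(m, design, cfg = pipeline_config(), ann) {
  stopifnot(inherits(m, "junction_count_matrix"))
  if (is.null(m$normalized) || is.null(m$psi)) {
    stop("count matrix must be normalized and PSI-filled")
  }
  if (!length(design$kd)) stop("design has zero knockdown conditions")
  stopifnot(all(unlist(c(design$control, design$kd)) %in%
                  colnames(m$raw)))

  j <- identify_novel(m$junctions, ann)
  novel <- !j$annotated
  cand <- j[novel, , drop = FALSE]
  raw <- m$raw[novel, , drop = FALSE]
  cpm <- m$normalized[novel, , drop = FALSE]
  psi <- m$psi[novel, , drop = FALSE]

  agg <- rowSums(raw)
  pass1 <- agg >= cfg$min_aggregate_reads

  cond_mean <- function(mat, ids) rowMeans(mat[, ids, drop = FALSE])
  ctrl_cpm <- cond_mean(cpm, design$control)
  psi0 <- psi
  psi0[is.na(psi0)] <- 0
  ctrl_psi <- cond_mean(psi0, design$control)

  kd_names <- names(design$kd)
  count_fc <- sapply(kd_names, function(k)
    (cond_mean(cpm, design$kd[[k]]) + cfg$count_pseudocount) /
      (ctrl_cpm + cfg$count_pseudocount))
  psi_fc <- sapply(kd_names, function(k)
    (cond_mean(psi0, design$kd[[k]]) + cfg$psi_epsilon) /
      (ctrl_psi + cfg$psi_epsilon))
  if (!is.matrix(count_fc)) {
    count_fc <- matrix(count_fc, nrow = nrow(cand),
                       dimnames = list(NULL, kd_names))
    psi_fc <- matrix(psi_fc, nrow = nrow(cand),
                     dimnames = list(NULL, kd_names))
  }
  pass2 <- pass1 & rowSums(count_fc > cfg$count_fc_threshold) >=
    cfg$min_concordant_kd
  pass3 <- pass2 & rowSums(psi_fc > cfg$psi_fc_threshold) >=
    cfg$min_concordant_kd

  calls <- cand[pass3, c("chrom", "strand", "start", "end", "key"),
                drop = FALSE]
  calls$aggregate_reads <- agg[pass3]
  for (k in kd_names) calls[[paste0("count_fc_", k)]] <- count_fc[pass3, k]
  for (k in kd_names) calls[[paste0("psi_fc_", k)]] <- psi_fc[pass3, k]
  rownames(calls) <- NULL
  attr(calls, "waterfall") <- c(candidates = nrow(cand),
                                aggregate_floor = sum(pass1),
                                count_fc_pass = sum(pass2),
                                psi_fc_pass = sum(pass3))
  calls
}

#' Classify cryptic splice sites against the annotation
#'
#' Each call receives exactly one class: `novel_alternative` when both ends
#' are annotated splice sites but the pairing is not; `exonic_5ss` /
#' `exonic_3ss` when the single novel end (donor / acceptor) falls in
#' annotated exonic sequence; `intronic_5ss` / `intronic_3ss` when it falls
#' in intronic sequence (exonic takes precedence for positions that are
#' exonic in one transcript and intronic in another); otherwise
#' `unclassified`. The host gene is the gene of the transcript carrying the
#' annotated end, ties broken by longest transcript then lexicographic gene
#' id.
#'
#' @param calls data.frame of calls (chrom/strand/start/end).
#' @param ann A `genome_annotation`.
#' @return `calls` with columns `css_class`, `novel_end`, `host_gene`,
#'   `host_transcript`.
#' @export
classify_calls <- function(calls, ann) {
  n <- nrow(calls)
  css <- character(n); novel_end <- character(n)
  host_gene <- rep(NA_character_, n); host_tx <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- calls[i, ]
    cl <- classify_one(r$chrom, r$strand, r$start, r$end, ann)
    css[i] <- cl$css_class; novel_end[i] <- cl$novel_end
    host_gene[i] <- cl$host_gene; host_tx[i] <- cl$host_transcript
  }
  calls$css_class <- css
  calls$novel_end <- novel_end
  calls$host_gene <- host_gene
  calls$host_transcript <- host_tx
  calls
}

classify_one <- function(chrom, strand, start, end, ann) {
  out <- list(css_class = "unclassified", novel_end = "neither",
              host_gene = NA_character_, host_transcript = NA_character_)
  if (strand == "*") return(out)
  d <- donor_boundary(strand, start, end)
  a <- acceptor_boundary(strand, start, end)
  d_ann <- site_key(chrom, strand, d) %in% ann$donors
  a_ann <- site_key(chrom, strand, a) %in% ann$acceptors
  if (d_ann && a_ann) {
    out$css_class <- "novel_alternative"
    out$novel_end <- "neither"
    h <- host_of_site(ann, chrom, strand, d, "donor")
    out$host_gene <- h$gene; out$host_transcript <- h$tx
    return(out)
  }
  if (!d_ann && !a_ann) {
    out$novel_end <- "both"
    return(out)
  }
  # exactly one annotated end; locate the novel one
  if (d_ann) {
    out$novel_end <- "acceptor"
    # novel acceptor: first exonic base downstream of the cut
    pos <- if (strand == "+") a else a - 1L
    h <- host_of_site(ann, chrom, strand, d, "donor")
    kind <- point_class(ann, chrom, strand, pos)
    out$css_class <- switch(kind, exon = "exonic_3ss",
                            intron = "intronic_3ss", "unclassified")
  } else {
    out$novel_end <- "donor"
    # novel donor: first base of the cryptic intron
    pos <- if (strand == "+") d else d - 1L
    h <- host_of_site(ann, chrom, strand, a, "acceptor")
    kind <- point_class(ann, chrom, strand, pos)
    out$css_class <- switch(kind, exon = "exonic_5ss",
                            intron = "intronic_5ss", "unclassified")
  }
  out$host_gene <- h$gene; out$host_transcript <- h$tx
  out
}

# exon takes precedence over intron for overlapping transcripts
point_class <- function(ann, chrom, strand, pos) {
  if (point_in_index(ann$exons_gr, chrom, strand, pos)) return("exon")
  if (point_in_index(ann$introns_gr, chrom, strand, pos)) return("intron")
  "intergenic"
}

host_of_site <- function(ann, chrom, strand, boundary, role) {
  jx <- ann$jx_tx
  b <- if (role == "donor") donor_boundary(jx$strand, jx$start, jx$end)
       else acceptor_boundary(jx$strand, jx$start, jx$end)
  hit <- jx[jx$chrom == chrom & jx$strand == strand & b == boundary, ]
  if (!nrow(hit)) return(list(gene = NA_character_, tx = NA_character_))
  tx <- ann$tx_table[match(hit$transcript_id, ann$tx_table$transcript_id), ]
  ord <- order(-tx$tx_len, tx$gene_id)
  list(gene = tx$gene_id[ord[1]], tx = tx$transcript_id[ord[1]])
}

#' Signed mRNA distance from a novel exonic splice site to the nearest
#' exon-exon junction
#'
#' Distance is measured on the mature mRNA of the host transcript between
#' the cryptic cut point and the nearest annotated exon-exon junction cut;
#' negative values lie upstream of the junction. Also flags sites falling
#' within the expected EJC footprint (`-ejc_offset +/-
#' ejc_footprint_halfwidth`).
#'
#' @param calls Classified calls (from [classify_calls()]).
#' @param ann A `genome_annotation`.
#' @param cfg A `pipeline_config`.
#' @return `calls` with `boundary_distance` (signed nt, NA where
#'   undefined) and `within_ejc_footprint`.
#' @export
boundary_distances <- function(calls, ann, cfg = pipeline_config()) {
  n <- nrow(calls)
  dist <- rep(NA_real_, n); foot <- rep(NA, n)
  for (i in seq_len(n)) {
    r <- calls[i, ]
    if (!r$css_class %in% c("exonic_5ss", "exonic_3ss") ||
        is.na(r$host_transcript)) next
    t <- ann$transcripts[[r$host_transcript]]
    cut <- tryCatch(novel_site_mrna_cut(r, t), error = function(e) NA)
    if (is.na(cut)) next
    jx <- map_junctions_to_mrna(t)
    if (!length(jx)) next
    dlt <- cut - jx
    dist[i] <- dlt[which.min(abs(dlt))]
    foot[i] <- any(abs((cut - jx) + cfg$ejc_offset) <=
                     cfg$ejc_footprint_halfwidth)
  }
  calls$boundary_distance <- dist
  calls$within_ejc_footprint <- foot
  calls
}

# mRNA cut point of the novel end of a call within transcript t.
# Donor: cut after the last retained exonic base; acceptor: cut before the
# first retained base. Errors when the flanking base is not exonic in t.
novel_site_mrna_cut <- function(r, t) {
  d <- donor_boundary(r$strand, r$start, r$end)
  a <- acceptor_boundary(r$strand, r$start, r$end)
  if (r$novel_end == "donor") {
    base <- if (r$strand == "+") d - 1L else d      # last exonic base
    genome_to_mrna(t, base) + 1L
  } else {
    base <- if (r$strand == "+") a else a - 1L      # first retained base
    genome_to_mrna(t, base)
  }
}

#' Permutation test for multi-set junction overlap
#'
#' Observed statistic is the size of the intersection of `sets`. Each
#' permutation draws subsets of the same sizes uniformly without replacement
#' from `universe` and records their intersection size. The p-value uses the
#' add-one correction `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param sets List of character vectors (junction keys), each a subset of
#'   `universe`.
#' @param universe Character vector of all eligible junctions.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with `observed`, `p_value`, `n_perm`, `perm_mean`.
#' @export
overlap_permutation_test <- function(sets, universe, n_perm = 1e5,
                                     seed = 1L) {
  stopifnot(length(sets) >= 2, n_perm >= 1)
  universe <- unique(universe)
  for (s in sets) {
    if (!all(s %in% universe)) stop("set contains elements outside universe")
  }
  k <- length(sets)
  sizes <- lengths(lapply(sets, unique))
  obs <- length(Reduce(intersect, sets))
  N <- length(universe)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- unlist(lapply(sizes, function(m) sample.int(N, m)))
    perm[i] <- sum(tabulate(idx, N) == k)
  }
  list(observed = obs, p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm, perm_mean = mean(perm))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write the cryptic-call catalogue and a BED file of cryptic sites
#'
#' @param calls Final annotated calls.
#' @param tsv_path,bed_path Output paths (`NULL` to skip either).
#' @export
write_cryptic_calls <- function(calls, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    novel_pos <- ifelse(calls$novel_end == "donor",
                        donor_boundary(calls$strand, calls$start, calls$end),
                        acceptor_boundary(calls$strand, calls$start,
                                          calls$end))
    bed <- data.frame(calls$chrom, pmax(novel_pos - 1L, 0L), novel_pos + 1L,
                      paste0(calls$css_class, "_", seq_len(nrow(calls))),
                      0L, calls$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(calls)
}
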