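#' Simulation configuration
#'
#' The defaults emulate the knockdown study design the pipeline targets: one
#' control library (lacZ) plus three core-EJC knockdown libraries
#' (eIF4AIII, mago, tsu), annotated junctions at moderate depth, and planted
#' cryptic junctions of all five classes that are upregulated in at least 2
#' of the 3 knockdowns with an 8-fold count change over a low control
#' baseline (cryptic junctions are typically near-absent in control).
#'
#' @param n_genes Number of simulated genes.
#' @param exons_per_gene,exon_length,intron_length Ranges (min, max).
#' @param canonical_ss_fidelity Per-position probability that non-invariant
#'   consensus positions of annotated splice sites match the consensus.
#' @param planted_cryptic data.frame describing planted cryptic junctions
#'   (columns `class`, `offset_min`, `offset_max`, `strength_min`,
#'   `strength_max`, `control_reads`, `fold_change`, `n_responsive_kd`);
#'   `NULL` for the default plan (two junctions per class, responsive in 2
#'   or 3 knockdowns).
#' @param remnant_prob_gt_down,remnant_prob_ag_up Probability that an
#'   exon-exon junction carries a GT immediately downstream / an AG
#'   immediately upstream (regenerated 5'/3' splice-site remnants); defaults
#'   follow the observed transcriptome-wide rates (roughly 54% and 57%).
#' @param conditions List with `control` (single name) and `kd` (names).
#' @param base_junction_reads Range of per-library reads for annotated
#'   junctions.
#' @param depth Optional target library size; libraries are padded with
#'   unspliced filler reads up to it.
#' @param read_length Read length (nt).
#' @param noise `list(type = "none")` or `list(type = "nb", dispersion = d)`
#'   for negative-binomial count noise.
#' @param min_overhang Minimum overhang used when placing split reads.
#' @param seed RNG seed; a fixed seed yields byte-identical outputs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 30, exons_per_gene = c(3, 6),
                              exon_length = c(150, 300),
                              intron_length = c(70, 140),
                              canonical_ss_fidelity = 0.9,
                              planted_cryptic = NULL,
                              remnant_prob_gt_down = 0.54,
                              remnant_prob_ag_up = 0.57,
                              conditions = list(control = "lacZ",
                                                kd = c("eIF4AIII", "mago",
                                                       "tsu")),
                              base_junction_reads = c(30, 80),
                              depth = NULL, read_length = 100,
                              noise = list(type = "none"),
                              min_overhang = 8, seed = 1L) {
  if (is.null(planted_cryptic)) {
    classes <- c("exonic_5ss", "exonic_3ss", "intronic_5ss", "intronic_3ss",
                 "novel_alternative")
    planted_cryptic <- data.frame(
      class = rep(classes, each = 2),
      offset_min = 24, offset_max = 60,
      strength_min = 0.3, strength_max = 0.95,
      control_reads = 2, fold_change = 8,
      n_responsive_kd = rep(c(2, 3), 5),
      stringsAsFactors = FALSE)
  }
  stopifnot(exons_per_gene[1] >= 2, exon_length[1] > 2 * min_overhang + 60,
            intron_length[1] >= 55,
            all(planted_cryptic$fold_change >= 1),
            length(conditions$control) == 1, length(conditions$kd) >= 1,
            all(planted_cryptic$n_responsive_kd <= length(conditions$kd)))
  structure(list(n_genes = n_genes, exons_per_gene = exons_per_gene,
                 exon_length = exon_length, intron_length = intron_length,
                 canonical_ss_fidelity = canonical_ss_fidelity,
                 planted_cryptic = planted_cryptic,
                 remnant_prob_gt_down = remnant_prob_gt_down,
                 remnant_prob_ag_up = remnant_prob_ag_up,
                 conditions = conditions,
                 base_junction_reads = base_junction_reads, depth = depth,
                 read_length = read_length, noise = noise,
                 min_overhang = min_overhang, seed = seed),
            class = "simulation_config")
}

rand_dna <- function(n) sample(BASES, n, replace = TRUE)

# sample a consensus-shaped motif; `fixed` positions always match
sample_consensus <- function(consensus, fidelity, fixed = integer(0)) {
  b <- strsplit(consensus, "")[[1]]
  out <- vapply(seq_along(b), function(i) {
    if (i %in% fixed || stats::runif(1) < fidelity) b[i]
    else sample(BASES, 1)
  }, character(1))
  out
}

# --- gene plan: everything in sense-local coordinates -----------------------

build_gene_plan <- function(gene_id, tx_id, strand, n_exons, exon_len,
                            intron_len, fidelity, gt_down, ag_up) {
  n_intr <- n_exons - 1L
  lens <- integer(2 * n_exons - 1L)
  lens[seq(1, 2 * n_exons - 1, 2)] <- exon_len
  if (n_intr) lens[seq(2, 2 * n_exons - 2, 2)] <- intron_len
  bounds <- cumsum(c(0L, lens))
  L <- bounds[length(bounds)]
  ex_idx <- seq(1, 2 * n_exons - 1, 2)
  exons <- data.frame(start = bounds[ex_idx], end = bounds[ex_idx + 1L])
  introns <- if (n_intr) data.frame(start = exons$end[-n_exons],
                                    end = exons$start[-1]) else
    data.frame(start = integer(0), end = integer(0))
  s <- rand_dna(L)
  for (i in seq_len(n_intr)) {
    is0 <- introns$start[i]; ie <- introns$end[i]
    s[(is0 + 1):(is0 + 6)] <- sample_consensus("GTAAGT", fidelity, fixed = 1:2)
    # branchpoint-like motif 20-35 nt upstream of the 3' splice site
    bp_off <- sample(20:35, 1)
    s[(ie - bp_off + 1):(ie - bp_off + 5)] <-
      sample_consensus("CTAAT", fidelity)
    # polypyrimidine tract then invariant AG
    ppt <- ifelse(stats::runif(12) < fidelity,
                  sample(c("T", "C"), 12, replace = TRUE, prob = c(.7, .3)),
                  sample(BASES, 12, replace = TRUE))
    s[(ie - 14):(ie - 3)] <- ppt
    s[(ie - 1):ie] <- c("A", "G")
    # donor exonic context (last 3 exon bases): consensus MAG, but the
    # terminal AG is owned by the remnant plan below
    s[is0 - 2] <- if (stats::runif(1) < fidelity) "A" else sample(BASES, 1)
  }
  # regenerated-site remnants at exon termini
  for (i in seq_len(n_intr)) {
    up_end <- exons$end[i]          # last base of upstream exon = up_end - 1
    dn_start <- exons$start[i + 1L]
    if (ag_up[i]) {
      s[(up_end - 1):up_end] <- c("A", "G")
    } else {
      while (paste(s[(up_end - 1):up_end], collapse = "") == "AG") {
        s[(up_end - 1):up_end] <- rand_dna(2)
      }
    }
    if (gt_down[i]) {
      s[(dn_start + 1):(dn_start + 2)] <- c("G", "T")
    } else {
      while (paste(s[(dn_start + 1):(dn_start + 2)], collapse = "") == "GT") {
        s[(dn_start + 1):(dn_start + 2)] <- rand_dna(2)
      }
    }
  }
  plan <- list(gene_id = gene_id, tx_id = tx_id, strand = strand,
               exons = exons, introns = introns, L = L, seq = s,
               gt_down = gt_down, ag_up = ag_up, cds_mrna = NULL,
               planted = list())
  plan
}

# mRNA position -> sense-local genomic position
local_from_mrna <- function(plan, mpos) {
  lens <- plan$exons$end - plan$exons$start
  cum <- cumsum(c(0L, lens))
  idx <- findInterval(mpos, cum, rightmost.closed = FALSE)
  plan$exons$start[idx] + (mpos - cum[idx])
}

mrna_from_local <- function(plan, lpos) {
  lens <- plan$exons$end - plan$exons$start
  cum <- cumsum(c(0L, lens))
  idx <- findInterval(lpos, plan$exons$start)
  cum[idx] + (lpos - plan$exons$start[idx])
}

# place an in-frame CDS: ATG at mRNA 30, stop codon ending 30 nt before the
# transcript end (length forced to a multiple of 3)
place_cds <- function(plan) {
  L_m <- sum(plan$exons$end - plan$exons$start)
  cs <- 30L
  ce <- L_m - 30L
  ce <- cs + 3L * ((ce - cs) %/% 3L)
  for (k in 0:2) plan$seq[local_from_mrna(plan, cs + k) + 1L] <-
    c("A", "T", "G")[k + 1]
  for (k in 0:2) plan$seq[local_from_mrna(plan, ce - 3L + k) + 1L] <-
    c("T", "A", "A")[k + 1]
  plan$cds_mrna <- c(cs, ce)
  plan
}

# rejection-sample a splice-site-like window into the target strength band
sample_site_window <- function(pwm, fixed_pos, fixed_bases, band,
                               max_tries = 300) {
  # without a trained model (tiny annotations) fall back to a random window
  # with the invariant dinucleotide fixed
  if (is.null(pwm)) {
    w <- if (fixed_pos[1] == 4) 9L else 17L
    cand <- rand_dna(w); cand[fixed_pos] <- fixed_bases
    return(cand)
  }
  w <- pwm$width
  best <- NULL; best_d <- Inf
  for (i in seq_len(max_tries)) {
    cand <- rand_dna(w)
    cand[fixed_pos] <- fixed_bases
    sc <- score_site(pwm, paste(cand, collapse = ""))$normalized
    if (sc >= band[1] && sc <= band[2]) return(cand)
    d <- min(abs(sc - band))
    if (d < best_d) { best <- cand; best_d <- d }
  }
  best
}

# plant one cryptic junction into a gene plan; returns updated plan plus the
# junction description in sense-local coordinates
plant_cryptic <- function(plan, row, intron_idx, pwms) {
  k <- intron_idx
  ik <- plan$introns[k, ]
  off <- sample(row$offset_min:row$offset_max, 1)
  band <- c(row$strength_min, row$strength_max)
  cls <- row$class
  if (cls == "exonic_5ss") {
    D <- plan$exons$end[k] - off
    win <- sample_site_window(pwms$donor, 4:5, c("G", "T"), band)
    plan$seq[(D - 2):(D + 6)] <- win
    jx <- c(D, ik$end)
  } else if (cls == "exonic_3ss") {
    A <- plan$exons$start[k + 1L] + off
    win <- sample_site_window(pwms$acceptor, 13:14, c("A", "G"), band)
    plan$seq[(A - 13):(A + 3)] <- win
    jx <- c(ik$start, A)
  } else if (cls == "intronic_5ss") {
    D <- ik$start + off
    win <- sample_site_window(pwms$donor, 4:5, c("G", "T"), band)
    plan$seq[(D - 2):(D + 6)] <- win
    jx <- c(D, ik$end)
  } else if (cls == "intronic_3ss") {
    A <- ik$end - off
    win <- sample_site_window(pwms$acceptor, 13:14, c("A", "G"), band)
    plan$seq[(A - 13):(A + 3)] <- win
    jx <- c(ik$start, A)
  } else if (cls == "novel_alternative") {
    if (k + 1L > nrow(plan$introns)) stop("novel_alternative needs 2 introns")
    jx <- c(ik$start, plan$introns$end[k + 1L])
  } else stop("unknown planted class: ", cls)
  # cryptic "intron" must itself start GT / end AG so its reads are
  # strand-inferable and splice-like
  if (cls != "novel_alternative") {
    if (cls %in% c("exonic_5ss", "intronic_5ss")) {
      # partner acceptor is annotated (already AG); donor planted GT above
    } else {
      # partner donor is annotated (already GT); acceptor planted AG above
    }
  }
  plan$planted[[length(plan$planted) + 1]] <-
    list(class = cls, local_start = jx[1], local_end = jx[2],
         intron_index = k, offset = off,
         control_reads = row$control_reads, fold_change = row$fold_change,
         n_responsive_kd = row$n_responsive_kd)
  plan
}

# sense-local interval -> genomic interval given gene offset/length/strand
local_to_genomic <- function(a, b, offset, L, strand) {
  if (strand == "+") c(offset + a, offset + b) else
    c(offset + L - b, offset + L - a)
}

#' Generate a synthetic spliced-read dataset
#'
#' Builds a genome FASTA, an Ensembl-dialect GTF, one SAM file per library
#' and a truth manifest. Canonical introns begin GT and end AG with
#' consensus context at the configured fidelity; planted cryptic sites are
#' embedded at configured offsets with sequence rejection-sampled into the
#' target PWM strength band against splice-site models trained on the
#' simulated annotation itself; splice-site remnants are written into exon
#' termini per the remnant plan. Split reads are single-end and placed
#' uniformly subject to the minimum overhang on both sides; counts are
#' exact in noise-free mode and negative-binomial otherwise. All randomness
#' derives from the seed.
#'
#' @param cfg A `simulation_config`.
#' @param dir Output directory (created).
#' @return A `splice_sim` list: file paths (`genome`, `gtf`, `sam` per
#'   sample, `manifest`, `remnants`, `samples`), the in-memory `genome`,
#'   `annotation`, `manifest` and `remnants` tables, trained `pwms`, and the
#'   config.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  # phase A: canonical gene plans
  plans <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    n_exons <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
    exon_len <- sample(cfg$exon_length[1]:cfg$exon_length[2], n_exons,
                       replace = TRUE)
    intron_len <- sample(cfg$intron_length[1]:cfg$intron_length[2],
                         n_exons - 1L, replace = TRUE)
    gt_down <- stats::runif(n_exons - 1L) < cfg$remnant_prob_gt_down
    ag_up <- stats::runif(n_exons - 1L) < cfg$remnant_prob_ag_up
    plans[[g]] <- build_gene_plan(sprintf("GENE%04d", g),
                                  sprintf("TX%04d", g),
                                  if (g %% 2 == 0) "-" else "+",
                                  n_exons, exon_len, intron_len,
                                  cfg$canonical_ss_fidelity, gt_down, ag_up)
    plans[[g]] <- place_cds(plans[[g]])
  }

  # train toy splice models on the canonical annotation for strength-band
  # rejection sampling of planted sites
  tmp <- assemble_genome_annotation(plans, spacer = 200L)
  pwms <- if (nrow(tmp$annotation$junctions) >= 10) {
    train_splice_models(tmp$annotation, tmp$genome, min_introns = 10L)
  } else NULL

  # phase B: plant cryptic junctions, assigned round-robin over genes
  pc <- cfg$planted_cryptic
  used <- list()
  for (i in seq_len(nrow(pc))) {
    need2 <- pc$class[i] == "novel_alternative"
    placed <- FALSE
    for (try_g in (((i - 1L) + 0:(cfg$n_genes - 1L)) %% cfg$n_genes) + 1L) {
      n_intr <- nrow(plans[[try_g]]$introns)
      avail <- setdiff(seq_len(max(0L, if (need2) n_intr - 1L else n_intr)),
                       used[[as.character(try_g)]] %||% integer(0))
      if (need2) {
        avail <- avail[!(avail + 1L) %in%
                         (used[[as.character(try_g)]] %||% integer(0))]
      }
      if (!length(avail)) next
      k <- avail[1]
      used[[as.character(try_g)]] <-
        c(used[[as.character(try_g)]] %||% integer(0),
          if (need2) c(k, k + 1L) else k)
      plans[[try_g]] <- plant_cryptic(plans[[try_g]], pc[i, ], k, pwms)
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible config: no free intron for planted ",
                      "junction ", i, " (", pc$class[i], ")")
  }

  emit_sim(plans, cfg, dir, pwms)
}

# assemble, add noise, and write all artifacts for a set of gene plans
emit_sim <- function(plans, cfg, dir, pwms = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asm <- assemble_genome_annotation(plans, spacer = 200L)
  genome <- asm$genome; ann <- asm$annotation

  # expected counts per junction per library
  samples <- data.frame(
    sample_id = c(cfg$conditions$control, cfg$conditions$kd),
    condition = c(cfg$conditions$control, cfg$conditions$kd),
    is_control = c(TRUE, rep(FALSE, length(cfg$conditions$kd))),
    stringsAsFactors = FALSE)
  counts <- expected_counts_table(plans, asm, cfg, samples)

  noisy <- identical(cfg$noise$type, "nb")
  obs <- counts
  if (noisy) {
    size <- 1 / cfg$noise$dispersion
    for (s in samples$sample_id) {
      obs[[s]] <- stats::rnbinom(nrow(obs), mu = counts[[s]], size = size)
    }
  }

  # write outputs
  fasta <- file.path(dir, "genome.fa")
  writeLines(c(">chrSim", chunk_seq(asm$chrom_seq, 70)), fasta)
  gtf <- file.path(dir, "annotation.gtf")
  write_sim_gtf(plans, asm, gtf)
  sam_paths <- stats::setNames(
    file.path(dir, paste0(samples$sample_id, ".sam")), samples$sample_id)
  for (s in samples$sample_id) {
    write_sim_sam(obs[, c("chrom", "strand", "gstart", "gend")], obs[[s]],
                  asm$chrom_seq, cfg, sam_paths[[s]], s)
  }
  manifest <- build_manifest(counts, obs, plans, asm, samples, cfg)
  man_path <- file.path(dir, "manifest_junctions.tsv")
  utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  remn <- remnant_table(plans)
  remn_path <- file.path(dir, "manifest_remnants.tsv")
  utils::write.table(remn, remn_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- file.path(dir, "samples.tsv")
  utils::write.table(
    data.frame(path = unname(sam_paths), sample_id = samples$sample_id,
               condition = samples$condition,
               is_control = samples$is_control),
    sheet, sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(paths = list(genome = fasta, gtf = gtf, sam = sam_paths,
                              manifest = man_path, remnants = remn_path,
                              samples = sheet),
                 genome = genome, annotation = ann, manifest = manifest,
                 remnants = remn, pwms = pwms, plans = plans,
                 samples = samples, config = cfg),
            class = "splice_sim")
}

chunk_seq <- function(s, width) {
  n <- nchar(s)
  substring(s, seq(1, n, width), pmin(seq(1, n, width) + width - 1, n))
}

# concatenate gene loci (minus genes reverse-complemented) into one
# chromosome; build transcript models and annotation
assemble_genome_annotation <- function(plans, spacer = 200L) {
  offset <- spacer
  pieces <- character(0)
  transcripts <- list()
  meta <- list()
  pieces <- c(pieces, paste(rand_dna_fixed(spacer), collapse = ""))
  for (p in plans) {
    sense <- paste(p$seq, collapse = "")
    gseq <- if (p$strand == "+") sense else revcomp(sense)
    n_ex <- nrow(p$exons)
    giv <- t(mapply(function(a, b) local_to_genomic(a, b, offset, p$L,
                                                    p$strand),
                    p$exons$start, p$exons$end))
    exons_g <- data.frame(start = giv[, 1], end = giv[, 2])
    cds_g <- NULL
    if (!is.null(p$cds_mrna)) {
      cds_g <- cds_genomic_intervals(p, offset)
    }
    transcripts[[p$tx_id]] <- transcript_model(p$tx_id, p$gene_id, "chrSim",
                                               p$strand, exons_g, cds_g)
    meta[[p$gene_id]] <- list(offset = offset, L = p$L, strand = p$strand)
    pieces <- c(pieces, gseq,
                paste(rand_dna_fixed(spacer), collapse = ""))
    offset <- offset + p$L + spacer
  }
  chrom_seq <- paste(pieces, collapse = "")
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- "chrSim"
  list(genome = genome, chrom_seq = chrom_seq,
       annotation = build_annotation(transcripts), meta = meta)
}

# deterministic spacer content is irrelevant; still draw from the seeded RNG
rand_dna_fixed <- function(n) sample(BASES, n, replace = TRUE)

# genomic CDS intervals from the mRNA CDS interval
cds_genomic_intervals <- function(p, offset) {
  cs <- p$cds_mrna[1]; ce <- p$cds_mrna[2]
  lens <- p$exons$end - p$exons$start
  cum <- cumsum(c(0L, lens))
  rows <- list()
  for (i in seq_len(nrow(p$exons))) {
    s <- max(cs, cum[i]); e <- min(ce, cum[i + 1])
    if (s >= e) next
    la <- p$exons$start[i] + (s - cum[i])
    lb <- p$exons$start[i] + (e - cum[i])
    gv <- local_to_genomic(la, lb, offset, p$L, p$strand)
    rows[[length(rows) + 1]] <- data.frame(start = gv[1], end = gv[2])
  }
  do.call(rbind, rows)
}

# full per-junction expected-count table (annotated + planted), genomic coords
expected_counts_table <- function(plans, asm, cfg, samples) {
  rows <- list()
  kd <- cfg$conditions$kd
  for (p in plans) {
    mt <- asm$meta[[p$gene_id]]
    n_intr <- nrow(p$introns)
    if (n_intr) {
      base <- sample(cfg$base_junction_reads[1]:cfg$base_junction_reads[2],
                     n_intr, replace = TRUE)
      for (i in seq_len(n_intr)) {
        gv <- local_to_genomic(p$introns$start[i], p$introns$end[i],
                               mt$offset, mt$L, p$strand)
        r <- data.frame(chrom = "chrSim", strand = p$strand,
                        gstart = gv[1], gend = gv[2], gene_id = p$gene_id,
                        class = "annotated", responsive = FALSE,
                        intron_index = i, offset = NA_integer_,
                        stringsAsFactors = FALSE)
        for (s in samples$sample_id) r[[s]] <- base[i]
        rows[[length(rows) + 1]] <- r
      }
    }
    for (pl in p$planted) {
      gv <- local_to_genomic(pl$local_start, pl$local_end, mt$offset, mt$L,
                             p$strand)
      resp_kd <- if (pl$n_responsive_kd > 0)
        sample(kd, pl$n_responsive_kd) else character(0)
      r <- data.frame(chrom = "chrSim", strand = p$strand,
                      gstart = gv[1], gend = gv[2], gene_id = p$gene_id,
                      class = pl$class,
                      responsive = pl$n_responsive_kd >= 2,
                      intron_index = pl$intron_index, offset = pl$offset,
                      stringsAsFactors = FALSE)
      for (s in samples$sample_id) {
        r[[s]] <- if (s %in% resp_kd)
          round(pl$control_reads * pl$fold_change) else pl$control_reads
      }
      rows[[length(rows) + 1]] <- r
    }
  }
  rbind_all(rows)
}

write_sim_gtf <- function(plans, asm, path) {
  lines <- character(0)
  for (p in plans) {
    t <- asm$annotation$transcripts[[p$tx_id]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', p$gene_id, p$tx_id)
    mk <- function(type, iv) {
      sprintf("chrSim\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              type, iv$start + 1L, iv$end, p$strand, attrs)
    }
    for (i in seq_len(nrow(t$exons))) {
      lines <- c(lines, mk("exon", t$exons[i, ]))
    }
    if (!is.null(t$cds)) {
      for (i in seq_len(nrow(t$cds))) lines <- c(lines, mk("CDS", t$cds[i, ]))
    }
  }
  writeLines(lines, path)
}

# write one library's SAM: split reads per junction plus optional filler
write_sim_sam <- function(jx, counts, chrom_seq, cfg, path, sample_id) {
  chrlen <- nchar(chrom_seq)
  rl <- cfg$read_length
  mo <- cfg$min_overhang
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:chrSim\tLN:", chrlen))
  rid <- 0L
  recs_list <- vector("list", nrow(jx))
  for (i in seq_len(nrow(jx))) {
    n <- counts[i]
    if (n <= 0) next
    gs <- jx$gstart[i]; ge <- jx$gend[i]
    a_max <- min(rl - mo, gs)
    a_min <- max(mo, rl - (chrlen - ge))
    a <- sample(a_min:a_max, n, replace = TRUE)
    b <- rl - a
    pos <- gs - a + 1L  # 1-based
    seqs <- paste0(substring(chrom_seq, pos, gs),
                   substring(chrom_seq, ge + 1, ge + b))
    recs_list[[i]] <- sprintf(
      "%s_r%06d\t0\tchrSim\t%d\t60\t%dM%dN%dM\t*\t0\t0\t%s\t%s\tNM:i:0\tXS:A:%s",
      sample_id, rid + seq_len(n), pos, a, ge - gs, b, seqs,
      strrep("I", rl), jx$strand[i])
    rid <- rid + n
  }
  recs <- unlist(recs_list)
  if (is.null(recs)) recs <- character(0)
  if (!is.null(cfg$depth) && length(recs) < cfg$depth) {
    n_fill <- cfg$depth - length(recs)
    pos <- sample.int(chrlen - rl, n_fill, replace = TRUE)
    fill <- sprintf("%s_f%06d\t0\tchrSim\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:0",
                    sample_id, seq_len(n_fill), pos, rl,
                    substring(chrom_seq, pos, pos + rl - 1L),
                    strrep("I", rl))
    recs <- c(recs, fill)
  }
  writeLines(c(lines, recs), path)
  invisible(path)
}

# truth manifest: expected (and, under noise, realized) counts and the PSI
# implied by the expected counts, plus expected re-splicing compatibility
build_manifest <- function(counts, obs, plans, asm, samples, cfg) {
  m <- counts
  m$key <- junction_key(m$chrom, m$strand, m$gstart, m$gend)
  # expected PSI from expected counts via the same local-PSI arithmetic
  raw <- as.matrix(counts[, samples$sample_id])
  rownames(raw) <- m$key
  jcm <- structure(list(
    junctions = data.frame(chrom = m$chrom, strand = m$strand,
                           start = m$gstart, end = m$gend, key = m$key),
    samples = samples, raw = raw,
    library_sizes = stats::setNames(pmax(colSums(raw), 1),
                                    samples$sample_id),
    normalized = NULL, psi = NULL), class = "junction_count_matrix")
  jcm <- compute_psi(jcm)
  for (s in samples$sample_id) {
    m[[paste0("obs_", s)]] <- obs[[s]]
    m[[paste0("psi_", s)]] <- jcm$psi[, s]
  }
  # expected re-splicing compatibility for planted exonic calls
  m$expected_resplice <- NA
  m$expected_deletion_length <- NA_integer_
  for (p in plans) {
    for (pl in p$planted) {
      mt <- asm$meta[[p$gene_id]]
      gv <- local_to_genomic(pl$local_start, pl$local_end, mt$offset, mt$L,
                             p$strand)
      idx <- which(m$key == junction_key("chrSim", p$strand, gv[1], gv[2]))
      if (pl$class == "exonic_5ss") {
        m$expected_resplice[idx] <- p$ag_up[pl$intron_index]
        m$expected_deletion_length[idx] <- pl$offset
      } else if (pl$class == "exonic_3ss") {
        m$expected_resplice[idx] <- p$gt_down[pl$intron_index]
        m$expected_deletion_length[idx] <- pl$offset
      }
    }
  }
  m
}

remnant_table <- function(plans) {
  rows <- lapply(plans, function(p) {
    n <- nrow(p$introns)
    if (!n) return(NULL)
    data.frame(transcript_id = p$tx_id, gene_id = p$gene_id,
               junction_index = seq_len(n),
               gt_downstream = p$gt_down, ag_upstream = p$ag_up,
               stringsAsFactors = FALSE)
  })
  rbind_all(rows)
}

#' Negative-binomial count-level replicate study
#'
#' Generates a junction count matrix directly at the count layer: each
#' cryptic junction shares its acceptor with an annotated partner junction;
#' responsive junctions get `fold_change`-times the control mean in a random
#' 2 of the 3 knockdown libraries, null junctions the control mean
#' everywhere; all counts are negative-binomial with the given dispersion.
#' Used to measure filter-cascade sensitivity and false-call rates under
#' realistic count noise without materializing reads.
#'
#' @param n_responsive,n_null Numbers of planted responsive / null cryptic
#'   junctions.
#' @param fold_change Count fold change in responsive knockdowns.
#' @param dispersion NB dispersion (`size = 1/dispersion`).
#' @param depth Library size used for CPM scaling.
#' @param control_reads Control-mean reads for cryptic junctions.
#' @param canonical_reads Mean reads for the annotated partner junctions.
#' @param seed RNG seed.
#' @return List with `matrix` (PSI-filled `junction_count_matrix`),
#'   `annotation`, `design`, and `truth` (key + responsive flag).
#' @export
simulate_count_study <- function(n_responsive = 50, n_null = 50,
                                 fold_change = 8, dispersion = 0.1,
                                 depth = 2e5, control_reads = 5,
                                 canonical_reads = 100, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_responsive + n_null
  kd <- c("eIF4AIII", "mago", "tsu")
  samples <- data.frame(sample_id = c("lacZ", kd),
                        condition = c("lacZ", kd),
                        is_control = c(TRUE, FALSE, FALSE, FALSE))
  # annotated partner i: intron [i*1000, i*1000+100); cryptic shares its
  # acceptor with a novel donor 40 nt upstream inside the exon
  base <- 1000L * seq_len(n)
  ann_j <- data.frame(chrom = "chrSim", strand = "+", start = base,
                      end = base + 100L)
  cry_j <- data.frame(chrom = "chrSim", strand = "+", start = base - 40L,
                      end = base + 100L)
  transcripts <- lapply(seq_len(n), function(i) {
    transcript_model(sprintf("TXS%04d", i), sprintf("GENES%04d", i),
                     "chrSim", "+",
                     data.frame(start = c(base[i] - 200L, base[i] + 100L),
                                end = c(base[i], base[i] + 300L)))
  })
  ann <- build_annotation(transcripts)
  jx <- rbind(ann_j, cry_j)
  jx$key <- junction_key(jx$chrom, jx$strand, jx$start, jx$end)
  size <- 1 / dispersion
  mu <- matrix(canonical_reads, nrow(jx), 4,
               dimnames = list(jx$key, samples$sample_id))
  mu[n + seq_len(n), ] <- control_reads
  responsive <- c(rep(TRUE, n_responsive), rep(FALSE, n_null))
  # responsive junctions react in 2 or 3 knockdowns (alternating), matching
  # the generator's default plan: core-EJC factors are mutually required, so
  # most truly suppressed junctions respond in every knockdown
  for (i in which(responsive)) {
    resp_kd <- sample(kd, if (i %% 2 == 0) 3 else 2)
    mu[n + i, resp_kd] <- control_reads * fold_change
  }
  raw <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
  m <- structure(list(junctions = jx, samples = samples, raw = raw,
                      library_sizes = stats::setNames(rep(depth, 4),
                                                      samples$sample_id),
                      normalized = NULL, psi = NULL),
                 class = "junction_count_matrix")
  m <- compute_psi(normalize_counts(m))
  list(matrix = m, annotation = ann,
       design = list(control = "lacZ",
                     kd = stats::setNames(as.list(kd), kd)),
       truth = data.frame(key = jx$key[n + seq_len(n)],
                          responsive = responsive))
}

#' Build the two-gene re-splicing fixture
#'
#' Constructs one gene with a CkIIbeta-like topology (an annotated donor
#' joined to a cryptic 3' splice site 54 nt into the next exon, whose first
#' two bases are GT: a regenerated 5' splice site, in-frame 54-nt deletion,
#' 18 amino acids removed) and one minus-strand gene with a CG31156-like
#' topology (a cryptic 5' splice site 110 nt upstream of an exon end that
#' carries a terminal AG: a regenerated 3' splice site, 110-nt frameshift
#' deletion). Cryptic junctions are supported by split reads in all three
#' knockdown libraries but near-absent in control. With
#' `mutate_remnants = TRUE` the remnant dinucleotides are mutated away, so
#' no re-splicing event is possible.
#'
#' @param dir Output directory.
#' @param mutate_remnants Replace the GT/AG remnants with non-splice bases.
#' @param seed RNG seed.
#' @return A `splice_sim` object (see [simulate_dataset()]).
#' @export
plant_resplice_fixture <- function(dir, mutate_remnants = FALSE, seed = 1L) {
  cfg <- simulation_config(n_genes = 2, seed = seed,
                           planted_cryptic = data.frame(
                             class = "exonic_3ss", offset_min = 54,
                             offset_max = 54, strength_min = 0,
                             strength_max = 1, control_reads = 2,
                             fold_change = 8, n_responsive_kd = 3))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # gene A: plus strand, cryptic acceptor 54 nt into exon 3, exon 3 begins GT
  pA <- build_gene_plan("GENEA", "TXA", "+", 4L, rep(200L, 4), rep(80L, 3),
                        0.95,
                        gt_down = c(FALSE, !mutate_remnants, FALSE),
                        ag_up = c(FALSE, FALSE, FALSE))
  if (mutate_remnants) {
    pA$seq[(pA$exons$start[3] + 1):(pA$exons$start[3] + 2)] <- c("C", "A")
  }
  pA <- place_cds(pA)
  A <- pA$exons$start[3] + 54L
  pA$seq[(A - 13):(A - 2)] <- strsplit("TTTCTTTTTCTT", "")[[1]]
  pA$seq[(A - 1):A] <- c("A", "G")
  pA$planted[[1]] <- list(class = "exonic_3ss",
                          local_start = pA$introns$start[2], local_end = A,
                          intron_index = 2L, offset = 54L,
                          control_reads = 2, fold_change = 8,
                          n_responsive_kd = 3L)

  # gene B: minus strand, cryptic donor 110 nt upstream of exon 2 end,
  # exon 2 ends AG
  pB <- build_gene_plan("GENEB", "TXB", "-", 4L, rep(250L, 4), rep(80L, 3),
                        0.95,
                        gt_down = c(FALSE, FALSE, FALSE),
                        ag_up = c(FALSE, !mutate_remnants, FALSE))
  if (mutate_remnants) {
    pB$seq[(pB$exons$end[2] - 1):pB$exons$end[2]] <- c("C", "T")
  }
  pB <- place_cds(pB)
  D <- pB$exons$end[2] - 110L
  pB$seq[(D + 1):(D + 6)] <- strsplit("GTAAGT", "")[[1]]
  pB$seq[(D - 2):D] <- c("C", "A", "G")
  pB$planted[[1]] <- list(class = "exonic_5ss", local_start = D,
                          local_end = pB$introns$end[2],
                          intron_index = 2L, offset = 110L,
                          control_reads = 2, fold_change = 8,
                          n_responsive_kd = 3L)

  emit_sim(list(pA, pB), cfg, dir)
}
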