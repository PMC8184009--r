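test_that("PWM training pins consensus to 1 and anti-consensus to 0", {
  windows <- rep("ACGTAC", 20)
  pwm <- train_pwm(windows, background = rep(0.25, 4))
  expect_equal(score_site(pwm, "ACGTAC")$normalized, 1)
  # anti-consensus: per-column minimum base
  lo <- pwm$log_odds
  anti <- paste(colnames(lo)[apply(lo, 1, which.min)], collapse = "")
  expect_equal(score_site(pwm, anti)$normalized, 0)
  expect_error(score_site(pwm, "ACGT"), "length")
  s <- score_site(pwm, "ACGNAC")
  expect_true(s$missing)
  expect_true(is.na(s$normalized))
})

test_that("training drops N windows and requires 10 usable windows", {
  expect_error(train_pwm(rep("ACGT", 5)), "fewer than 10")
  pwm <- train_pwm(c(rep("ACGT", 12), "ACNT"))
  expect_equal(attr(pwm, "n_dropped"), 1)
})

test_that("PWM ranking matches brute-force log-odds enumeration", {
  set.seed(17)
  windows <- vapply(1:60, function(i)
    paste0("AG", paste(sample(c("G", "T", "A", "C"), 4, TRUE,
                              prob = c(.4, .3, .2, .1)), collapse = "")),
    character(1))
  pwm <- train_pwm(windows)
  bases <- c("A", "C", "G", "T")
  all6 <- do.call(expand.grid,
                  c(rep(list(bases), 6), stringsAsFactors = FALSE))
  seqs <- do.call(paste0, all6)
  got <- vapply(seqs, function(s) score_site(pwm, s)$raw, numeric(1),
                USE.NAMES = FALSE)
  # independent brute force: per-position frequency/log-odds recomputation
  cnt <- sapply(1:6, function(j)
    table(factor(substr(windows, j, j), levels = bases)))
  bg <- rowSums(cnt) / sum(cnt)
  fr <- t(t(cnt + 1) / (colSums(cnt) + 4))
  lo <- log2(fr / bg)
  brute <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    sum(vapply(1:6, function(j) lo[b[j], j], numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(got, brute, tolerance = 1e-12)
  expect_equal(order(got), order(brute))
})

test_that("normalized scores are invariant to per-column affine shifts", {
  set.seed(3)
  pwm <- train_pwm(replicate(30, rand_seq(8)))
  shifted <- pwm
  shift <- runif(8, -2, 2)
  shifted$log_odds <- pwm$log_odds + shift
  shifted$score_min <- pwm$score_min + sum(shift)
  shifted$score_max <- pwm$score_max + sum(shift)
  for (i in 1:10) {
    w <- rand_seq(8)
    expect_equal(score_site(pwm, w)$normalized,
                 score_site(shifted, w)$normalized, tolerance = 1e-10)
  }
})

consensus_annotation <- function(n = 120, seed = 5, intron_len = 90,
                                 fidelity = 1) {
  set.seed(seed)
  plant <- function(motif, keep) {
    b <- strsplit(motif, "")[[1]]
    ifelse(seq_along(b) %in% keep | runif(length(b)) < fidelity, b,
           sample(c("A", "C", "G", "T"), length(b), TRUE))
  }
  txs <- list()
  seqs <- character(n)
  for (i in 1:n) {
    ex1 <- 100; ex2 <- 100
    s <- strsplit(rand_seq(ex1 + intron_len + ex2), "")[[1]]
    s[(ex1 + 1):(ex1 + 6)] <- plant("GTAAGT", 1:2)
    s[(ex1 + intron_len - 5):(ex1 + intron_len)] <- plant("TTTCAG", 5:6)
    seqs[i] <- paste(s, collapse = "")
    txs[[i]] <- transcript_model(
      paste0("t", i), paste0("g", i), paste0("chr", i), "+",
      data.frame(start = c(0, ex1 + intron_len),
                 end = c(ex1, ex1 + intron_len + ex2)))
  }
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", 1:n)
  list(genome = g, ann = build_annotation(txs))
}

test_that("splice models learn the annotated consensus and its geometry", {
  cx <- consensus_annotation()
  pwms <- train_splice_models(cx$ann, cx$genome)
  expect_match(pwm_consensus(pwms$donor), "GTAAGT$")
  expect_identical(substr(pwm_consensus(pwms$acceptor), 12, 14), "CAG")
  expect_equal(pwms$donor$width, 9)
  expect_equal(pwms$acceptor$width, 17)
  # invariant dinucleotide columns carry maximal information
  ic <- function(pwm, bg) {
    fr <- 2^pwm$log_odds * rep(pwm$background, each = pwm$width)
    rowSums(fr * log2(fr / rep(bg, each = pwm$width)))
  }
  # with randomized interiors but invariant GT/AG, the invariant columns
  # carry maximal information
  cx0 <- consensus_annotation(seed = 6, fidelity = 0)
  pwms0 <- train_splice_models(cx0$ann, cx0$genome)
  icd <- ic(pwms0$donor, pwms0$donor$background)
  expect_true(all(icd[4:5] >= max(icd[-c(4:5)])))
  ica <- ic(pwms0$acceptor, pwms0$acceptor$background)
  expect_true(all(ica[13:14] >= max(ica[-c(13:14)])))
})

test_that("annotated donors outscore random exonic windows", {
  sim <- simulate_dataset(simulation_config(n_genes = 12, seed = 55),
                          tempfile("simsc"))
  pwms <- train_splice_models(sim$annotation, sim$genome, min_introns = 20)
  set.seed(1)
  j <- sim$annotation$junctions
  wins <- mapply(function(chrom, strand, d)
    extract_window(sim$genome, chrom, strand, d, 3, 6),
    j$chrom, j$strand, j$donor)
  ann_scores <- vapply(wins, function(w) score_site(pwms$donor, w)$normalized,
                       numeric(1))
  better <- 0; total <- 0
  for (i in 1:1000) {
    jx <- sample(nrow(j), 1)
    t <- sim$annotation$transcripts[[
      sim$annotation$jx_tx$transcript_id[jx]]]
    pos <- sample(500:1500, 1)
    w <- extract_window(sim$genome, "chrSim", "+", pos, 3, 6)
    rnd <- score_site(pwms$donor, w)$normalized
    total <- total + 1
    if (ann_scores[jx] > rnd) better <- better + 1
  }
  expect_gte(better / total, 0.95)
})

test_that("EM recovers a planted motif and its objective never decreases", {
  set.seed(9)
  windows <- vapply(1:200, function(i) {
    s <- strsplit(rand_seq(31), "")[[1]]
    o <- sample(1:27, 1)
    s[o:(o + 4)] <- strsplit("CTAAC", "")[[1]]
    paste(s, collapse = "")
  }, character(1))
  fit <- em_motif(windows, 5, seed = 12)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_lte(utils::adist("CTAAC", fit$consensus)[1, 1], 1)
})

test_that("EM on identical windows converges to the closed-form optimum", {
  # all 4-mers of this string are distinct, so the optimum concentrates all
  # mass on one offset shared by every (identical) sequence
  windows <- rep("ACGTTGCA", 30)
  fit <- em_motif(windows, 4, n_restarts = 1, seed = 2)
  expect_true(fit$consensus %in% c("ACGT", "CGTT", "GTTG", "TTGC", "TGCA"))
  # closed form: background everywhere except the motif columns, which are
  # (n + pc)/(n + 4 pc)-pure, with the uniform-offset penalty and the
  # Dirichlet regularizer (small cross-offset leakage -> loose tolerance)
  n <- 30; pc <- 1; L <- 8; w <- 4; n_off <- L - w + 1
  f_hit <- (n + pc) / (n + 4 * pc)
  ll <- n * ((L - w) * log(.25) + w * log(f_hit) - log(n_off))
  penal <- pc * sum(log(c(rep(f_hit, w),
                          rep(pc / (n + 4 * pc), 3 * w))))
  expect_equal(fit$loglik, ll + penal, tolerance = 1e-3)
})

test_that("branchpoint derivation finds the planted intronic motif", {
  set.seed(41)
  n_intr <- 120
  txs <- list(); seqs <- character(n_intr)
  for (i in 1:n_intr) {
    s <- strsplit(rand_seq(300), "")[[1]]
    # intron [100, 200); plant CTAAC inside the -45..-15 window
    s[101:102] <- c("G", "T"); s[199:200] <- c("A", "G")
    o <- sample(0:20, 1)
    s[(158 + o):(162 + o)] <- strsplit("CTAAC", "")[[1]]
    seqs[i] <- paste(s, collapse = "")
    txs[[i]] <- transcript_model(paste0("t", i), paste0("g", i),
                                 paste0("chr", i), "+",
                                 data.frame(start = c(0, 200),
                                            end = c(100, 300)))
  }
  g <- Biostrings::DNAStringSet(seqs); names(g) <- paste0("chr", 1:n_intr)
  ann <- build_annotation(txs)
  pwm <- derive_branchpoint_pwm(ann, g, motif_width = 5, seed = 6)
  expect_lte(utils::adist("CTAAC", pwm_consensus(pwm))[1, 1], 1)
  tr <- attr(pwm, "em")$loglik_trace
  expect_true(all(diff(tr) >= -1e-9))
})

test_that("branchpoint scanning respects threshold monotonicity", {
  set.seed(8)
  pwm <- train_pwm(replicate(30, paste0("CT", rand_seq(3), "AC")),
                   kind = "branchpoint")
  cons <- pwm_consensus(pwm)
  region <- paste0(rand_seq(20), cons, rand_seq(20))
  hits <- scan_branchpoint(pwm, region, min_match = 0.99)
  expect_true(any(hits$offset == 20 & hits$match >= 0.999))
  # anti-consensus region: no hits at 0.75, best still reported
  lo <- pwm$log_odds
  anti <- paste(colnames(lo)[apply(lo, 1, which.min)], collapse = "")
  region2 <- strrep(anti, 5)
  h2 <- scan_branchpoint(pwm, region2, 0.75)
  expect_equal(nrow(h2), 0)
  expect_true(is.finite(attr(h2, "best")$match))
  expect_lt(attr(h2, "best")$match, 0.75)
  # hit sets nest as the threshold decreases
  for (i in 1:10) {
    r <- rand_seq(80)
    hi <- scan_branchpoint(pwm, r, 0.8)$offset
    lo_hits <- scan_branchpoint(pwm, r, 0.6)$offset
    expect_true(all(hi %in% lo_hits))
  }
  expect_error(scan_branchpoint(pwm, "ACG"), "shorter")
})

test_that("nucleotide content equals brute-force column tallies", {
  m <- nucleotide_content(rep("AAAA", 5))
  expect_true(all(m[, "A"] == 1))
  m2 <- nucleotide_content(c("AC", "AG"))
  expect_equal(unname(m2[1, "A"]), 1)
  expect_equal(unname(m2[2, c("C", "G")]), c(0.5, 0.5))
  set.seed(4)
  ws <- replicate(50, rand_seq(6))
  m3 <- nucleotide_content(ws)
  for (j in 1:6) {
    tab <- table(factor(substr(ws, j, j), levels = c("A", "C", "G", "T")))
    expect_equal(unname(m3[j, ]), unname(as.vector(tab) / 50))
  }
  expect_error(nucleotide_content(character(0)), "empty")
})

test_that("PWMs round-trip through their text serialization", {
  set.seed(2)
  pwm <- train_pwm(replicate(25, rand_seq(7)), kind = "acceptor",
                   exonic_up = 0L, exonic_down = 3L)
  path <- tempfile(fileext = ".tsv")
  write_pwm(pwm, path)
  p2 <- read_pwm(path)
  expect_equal(p2$kind, "acceptor")
  expect_equal(p2$width, 7L)
  expect_equal(unname(p2$log_odds), unname(pwm$log_odds), tolerance = 1e-5)
  w <- rand_seq(7)
  expect_equal(score_site(p2, w)$normalized, score_site(pwm, w)$normalized,
               tolerance = 1e-4)
})

test_that("branchpoint match and acceptor strength pair up consistently", {
  sim <- simulate_dataset(simulation_config(n_genes = 12, seed = 23),
                          tempfile("simbp"))
  pwms <- train_splice_models(sim$annotation, sim$genome, min_introns = 20)
  bp <- derive_branchpoint_pwm(sim$annotation, sim$genome, motif_width = 5,
                               seed = 3)
  m <- quantify_sim(sim)
  calls <- classify_calls(
    filter_cryptic(m, default_design(), pipeline_config(), sim$annotation),
    sim$annotation)
  acc <- calls[calls$novel_end == "acceptor", ]
  joint <- lapply(seq_len(nrow(acc)), function(i) {
    r <- acc[i, ]
    a <- if (r$strand == "+") r$end else r$start
    region <- extract_window(sim$genome, r$chrom, r$strand, a, 45, 0)
    region <- substr(region, 1, 31)
    best <- attr(scan_branchpoint(bp, region, 0.75), "best")
    win <- extract_window(sim$genome, r$chrom, r$strand, a, 14, 3)
    data.frame(bp_match = best$match,
               ss = score_site(pwms$acceptor, win)$normalized)
  })
  joint <- do.call(rbind, joint)
  expect_gt(nrow(joint), 0)
  # marginals agree with direct recomputation
  redo <- vapply(seq_len(nrow(acc)), function(i) {
    r <- acc[i, ]
    a <- if (r$strand == "+") r$end else r$start
    region <- substr(extract_window(sim$genome, r$chrom, r$strand, a, 45, 0),
                     1, 31)
    max(vapply(0:(31 - bp$width), function(o)
      score_site(bp, substr(region, o + 1, o + bp$width))$normalized,
      numeric(1)))
  }, numeric(1))
  expect_equal(joint$bp_match, redo, tolerance = 1e-10)
})
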