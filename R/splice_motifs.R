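BASES <- c("A", "C", "G", "T")

# windows (character vector, equal length) -> integer matrix n x width
# (1..4 = ACGT, NA for N/other)
windows_to_int <- function(windows) {
  w <- nchar(windows[1])
  m <- matrix(match(unlist(strsplit(windows, "")), BASES),
              nrow = length(windows), ncol = w, byrow = TRUE)
  m
}

#' Train a position weight matrix from aligned windows
#'
#' Per-column base counts plus a pseudocount become frequencies, then
#' log2-odds against `background`. Attainable score bounds (`score_min`,
#' `score_max`) are the sums of column minima/maxima, so the min-max
#' normalized score of the column-wise consensus is exactly 1 and of the
#' anti-consensus exactly 0. Windows containing N are dropped (count
#' reported via attribute `n_dropped`).
#'
#' @param windows Character vector of equal-length DNA strings (>= 10 usable).
#' @param background Base frequencies (A,C,G,T); defaults to the pooled base
#'   frequencies of the training windows.
#' @param pseudocount Count added per cell.
#' @param kind One of `"donor"`, `"acceptor"`, `"branchpoint"`.
#' @param exonic_up,exonic_down Window geometry bookkeeping (nt of exonic
#'   context on each side).
#' @return A `pwm` object.
#' @export
train_pwm <- function(windows, background = NULL, pseudocount = 1,
                      kind = "donor", exonic_up = 0L, exonic_down = 0L) {
  stopifnot(length(unique(nchar(windows))) == 1)
  usable <- !grepl("[^ACGT]", windows)
  n_dropped <- sum(!usable)
  windows <- windows[usable]
  if (length(windows) < 10) {
    stop("fewer than 10 usable training windows (", length(windows), ")")
  }
  x <- windows_to_int(windows)
  w <- ncol(x)
  counts <- vapply(seq_len(w), function(j) tabulate(x[, j], 4L),
                   numeric(4))                      # 4 x w
  if (is.null(background)) {
    background <- rowSums(counts) / sum(counts)
  }
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  freq <- t(t(counts + pseudocount) / (colSums(counts) + 4 * pseudocount))
  log_odds <- log2(freq / background)               # 4 x w
  pwm <- structure(list(kind = kind, width = w,
                        exonic_up = exonic_up, exonic_down = exonic_down,
                        log_odds = t(log_odds),     # width x 4
                        background = stats::setNames(background, BASES),
                        score_min = sum(apply(log_odds, 2, min)),
                        score_max = sum(apply(log_odds, 2, max))),
                   class = "pwm")
  colnames(pwm$log_odds) <- BASES
  attr(pwm, "n_dropped") <- n_dropped
  pwm
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm(", x$kind, "): width ", x$width, ", consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Column-wise consensus sequence of a PWM
#' @param pwm A `pwm`.
#' @return Character string.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$log_odds, 1, which.max)], collapse = "")
}

#' Score a window against a PWM
#'
#' @param pwm A `pwm`.
#' @param window DNA string of length `pwm$width`.
#' @return List with `raw` (log-odds sum), `normalized` (min-max scaled to
#'   \[0,1\]) and `missing` (TRUE when the window contains N or was clipped;
#'   scores NA then).
#' @export
score_site <- function(pwm, window) {
  if (nchar(window) != pwm$width) {
    stop("window length ", nchar(window), " != pwm width ", pwm$width)
  }
  if (grepl("[^ACGT]", window) || isTRUE(attr(window, "clipped"))) {
    return(list(raw = NA_real_, normalized = NA_real_, missing = TRUE))
  }
  idx <- match(strsplit(window, "")[[1]], BASES)
  raw <- sum(pwm$log_odds[cbind(seq_len(pwm$width), idx)])
  list(raw = raw,
       normalized = (raw - pwm$score_min) / (pwm$score_max - pwm$score_min),
       missing = FALSE)
}

# vectorized normalized scores for many windows (NA where N present)
score_sites <- function(pwm, windows) {
  vapply(windows, function(w) score_site(pwm, w)$normalized, numeric(1),
         USE.NAMES = FALSE)
}

#' Train donor and acceptor PWMs from an annotation
#'
#' Donor windows cover 3 exonic + 6 intronic nt around each annotated donor
#' (the AG|GTRAGT context); acceptor windows cover 14 intronic + 3 exonic nt
#' around each annotated acceptor (polypyrimidine tract, terminal AG and two
#' exonic bases). Background frequencies are pooled from the training
#' windows. Deterministic given the annotation.
#'
#' @param ann A `genome_annotation` with at least 100 annotated introns.
#' @param genome A `DNAStringSet`.
#' @param donor_exonic,donor_intronic,acceptor_intronic,acceptor_exonic
#'   Window geometry in nt.
#' @param min_introns Minimum number of annotated introns required.
#' @return List with elements `donor` and `acceptor` (both `pwm`).
#' @export
train_splice_models <- function(ann, genome, donor_exonic = 3L,
                                donor_intronic = 6L, acceptor_intronic = 14L,
                                acceptor_exonic = 3L, min_introns = 100L) {
  j <- ann$junctions
  if (nrow(j) < min_introns) {
    stop("fewer than ", min_introns, " annotated introns (", nrow(j), ")")
  }
  dwin <- mapply(function(chrom, strand, d)
    extract_window(genome, chrom, strand, d, donor_exonic, donor_intronic),
    j$chrom, j$strand, j$donor)
  awin <- mapply(function(chrom, strand, a)
    extract_window(genome, chrom, strand, a, acceptor_intronic,
                   acceptor_exonic),
    j$chrom, j$strand, j$acceptor)
  full_d <- nchar(dwin) == donor_exonic + donor_intronic
  full_a <- nchar(awin) == acceptor_intronic + acceptor_exonic
  list(donor = train_pwm(unname(dwin[full_d]), kind = "donor",
                         exonic_up = donor_exonic, exonic_down = 0L),
       acceptor = train_pwm(unname(awin[full_a]), kind = "acceptor",
                            exonic_up = 0L, exonic_down = acceptor_exonic))
}

#' Derive a branchpoint PWM from intronic sequence by EM
#'
#' Extracts the 15-45 nt window upstream of the 3' splice site from up to
#' `n_introns` randomly selected annotated introns (introns shorter than
#' `window[2] + motif_width` nt are skipped and counted) and runs a
#' one-occurrence-per-sequence EM motif finder (posterior over motif start
#' positions against a 0-order background; expected-count update with
#' pseudocount 1; `n_restarts` random restarts, at most `max_iter`
#' iterations, convergence when the objective gains less than `tol`).
#' Returns the highest-objective PWM. Seeded and reproducible.
#'
#' @param ann A `genome_annotation`.
#' @param genome A `DNAStringSet`.
#' @param n_introns Number of introns to sample.
#' @param window Upstream window (nt before the 3' splice site).
#' @param motif_width Motif width.
#' @param seed RNG seed.
#' @param n_restarts,max_iter,tol EM control parameters.
#' @return A branchpoint `pwm` with attributes `em` (fit details) and
#'   `n_skipped`.
#' @export
derive_branchpoint_pwm <- function(ann, genome, n_introns = 10000,
                                   window = c(15, 45), motif_width = 7,
                                   seed = 1L, n_restarts = 5, max_iter = 200,
                                   tol = 1e-6) {
  j <- ann$junctions
  ilen <- j$end - j$start
  ok <- ilen >= window[2] + motif_width
  n_skipped <- sum(!ok)
  j <- j[ok, , drop = FALSE]
  if (nrow(j) < min(1000, nrow(ann$junctions))) {
    stop("fewer usable introns (", nrow(j), ") than required")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (nrow(j) > n_introns) j <- j[sample.int(nrow(j), n_introns), ]
  wins <- mapply(function(chrom, strand, a) {
    w <- extract_window(genome, chrom, strand, a, window[2], 0L)
    substr(w, 1, window[2] - window[1] + 1)  # positions -45..-15
  }, j$chrom, j$strand, j$acceptor)
  wins <- unname(wins[!grepl("[^ACGT]", wins)])
  fit <- em_motif(wins, motif_width, n_restarts = n_restarts,
                  max_iter = max_iter, tol = tol,
                  seed = seed + 1L)
  pwm <- structure(list(kind = "branchpoint", width = motif_width,
                        exonic_up = 0L, exonic_down = 0L,
                        log_odds = log2(fit$freq /
                                          rep(fit$background,
                                              each = motif_width)),
                        background = fit$background,
                        score_min = NA_real_, score_max = NA_real_),
                   class = "pwm")
  colnames(pwm$log_odds) <- BASES
  pwm$score_min <- sum(apply(pwm$log_odds, 1, min))
  pwm$score_max <- sum(apply(pwm$log_odds, 1, max))
  attr(pwm, "em") <- fit[c("loglik_trace", "loglik", "n_restarts_run")]
  attr(pwm, "n_skipped") <- n_skipped
  pwm
}

#' One-occurrence-per-sequence EM motif finder
#'
#' Each sequence is modelled as containing exactly one motif occurrence at a
#' uniform start position, with all other positions drawn from a 0-order
#' background estimated from the input. The E-step computes the posterior
#' over start positions; the M-step updates the motif frequencies from
#' expected counts with a Dirichlet pseudocount. The monitored objective is
#' the pseudocount-penalized (MAP) log-likelihood, which is non-decreasing
#' across iterations.
#'
#' After the restarts converge, a phase-shift refinement re-seeds EM from
#' one- and two-column shifts of the best motif and keeps any improvement,
#' countering the register ambiguity inherent to one-occurrence models.
#'
#' @param windows Equal-length DNA strings (ACGT only).
#' @param width Motif width.
#' @param n_restarts Random restarts; the best objective wins.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   objective.
#' @param pseudocount Dirichlet pseudocount.
#' @param seed RNG seed.
#' @return List with `freq` (width x 4 motif frequencies), `background`,
#'   `loglik`, `loglik_trace` (per-iteration objective of the winning
#'   restart), `consensus`, `n_restarts_run`.
#' @export
em_motif <- function(windows, width, n_restarts = 5, max_iter = 200,
                     tol = 1e-6, pseudocount = 1, seed = 1L) {
  L <- nchar(windows[1])
  stopifnot(all(nchar(windows) == L), width <= L, length(windows) >= 2)
  x <- windows_to_int(windows)
  n <- nrow(x)
  n_off <- L - width + 1L
  bg <- tabulate(x, 4L); bg <- bg / sum(bg)
  log_bg <- log(bg)
  # per-sequence constant: full-background log-likelihood
  const <- rowSums(matrix(log_bg[x], nrow = n)) - log(n_off)

  run_em <- function(f) {
    trace <- numeric(0)
    prev <- -Inf
    z <- NULL
    for (it in seq_len(max_iter)) {
      lr <- log(f) - rep(log_bg, each = width)   # width x 4 log ratio
      sc <- matrix(0, n, n_off)
      for (k in seq_len(width)) {
        sc <- sc + matrix(lr[k, x[, k:(k + n_off - 1L), drop = FALSE]],
                          n, n_off)
      }
      mx <- apply(sc, 1, max)
      ez <- exp(sc - mx)
      rs <- rowSums(ez)
      ll <- sum(const + mx + log(rs))
      z <- ez / rs
      cnt <- matrix(0, width, 4)
      for (k in seq_len(width)) {
        xk <- x[, k:(k + n_off - 1L), drop = FALSE]
        for (b in 1:4) cnt[k, b] <- sum(z[xk == b])
      }
      # MAP objective at the current parameters (before the update): EM
      # guarantees this never decreases across iterations
      obj <- ll + pseudocount * sum(log(f))
      trace <- c(trace, obj)
      f <- (cnt + pseudocount) / (n + 4 * pseudocount)
      if (it > 1 && obj - prev < tol) break
      prev <- obj
    }
    list(freq = f, loglik = trace[length(trace)], loglik_trace = trace)
  }

  init_from_mer <- function(mer) {
    f <- matrix(0.1 / 3, width, 4)
    f[cbind(seq_len(width), mer)] <- 0.9
    f
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # init from a random w-mer in the data, smoothed
    i0 <- sample.int(n, 1); j0 <- sample.int(n_off, 1)
    fit <- run_em(init_from_mer(x[i0, j0:(j0 + width - 1L)]))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # phase-shift refinement: one-occurrence EM can converge one or two
  # columns off the optimal register; restart from shifted versions of the
  # best motif (new columns filled with background) and keep improvements
  repeat {
    improved <- FALSE
    for (d in c(-2L, -1L, 1L, 2L)) {
      f0 <- matrix(bg, width, 4, byrow = TRUE)
      src <- seq_len(width) + d
      keep <- src >= 1 & src <= width
      f0[keep, ] <- best$freq[src[keep], ]
      f0 <- f0 / rowSums(f0)
      fit <- run_em(f0)
      if (fit$loglik > best$loglik + tol) {
        best <- fit
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  colnames(best$freq) <- BASES
  best$background <- stats::setNames(bg, BASES)
  best$consensus <- paste(BASES[apply(best$freq, 1, which.max)],
                          collapse = "")
  best$n_restarts_run <- n_restarts
  best
}

#' Scan a region for branchpoint matches
#'
#' Slides the PWM across `region` and reports every offset whose min-max
#' normalized score reaches `min_match`, plus the best match regardless of
#' threshold (attribute `best`).
#'
#' @param pwm A branchpoint `pwm`.
#' @param region DNA string of length >= `pwm$width`.
#' @param min_match Minimum normalized match fraction.
#' @return data.frame with `offset` (0-based) and `match`; attribute `best`
#'   holds the top offset/match pair.
#' @export
scan_branchpoint <- function(pwm, region, min_match = 0.75) {
  w <- pwm$width
  L <- nchar(region)
  if (L < w) stop("region shorter than PWM width")
  offs <- 0:(L - w)
  sc <- vapply(offs, function(o)
    score_site(pwm, substr(region, o + 1, o + w))$normalized, numeric(1))
  hits <- data.frame(offset = offs[!is.na(sc) & sc >= min_match],
                     match = sc[!is.na(sc) & sc >= min_match])
  bi <- which.max(sc)
  attr(hits, "best") <- data.frame(offset = offs[bi], match = sc[bi])
  hits
}

#' Position-by-base nucleotide content of aligned windows
#'
#' Column frequencies over A,C,G,T; N is excluded from each column's
#' denominator. Suitable as logo-tool input.
#'
#' @param windows Equal-length DNA strings.
#' @return Matrix (positions x 4) of frequencies summing to 1 per row.
#' @export
nucleotide_content <- function(windows) {
  if (!length(windows)) stop("empty input")
  stopifnot(length(unique(nchar(windows))) == 1)
  x <- windows_to_int(windows)
  m <- t(vapply(seq_len(ncol(x)), function(j) {
    cnt <- tabulate(x[, j], 4L)
    cnt / sum(cnt)
  }, numeric(4)))
  colnames(m) <- BASES
  m
}

#' Serialize / read a PWM as tab-delimited text
#'
#' A `#key value` header block (kind, width, geometry, background) followed
#' by the width x 4 log-odds matrix.
#'
#' @param pwm A `pwm`.
#' @param path Output path.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("#kind\t", pwm$kind),
               paste0("#width\t", pwm$width),
               paste0("#exonic_up\t", pwm$exonic_up),
               paste0("#exonic_down\t", pwm$exonic_down),
               paste0("#background\t",
                      paste(sprintf("%.10g", pwm$background),
                            collapse = "\t"))), con)
  utils::write.table(pwm$log_odds, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), "\t")
  vals <- stats::setNames(lapply(kv, `[`, -1), vapply(kv, `[`, character(1), 1))
  lo <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")],
                                    header = TRUE, sep = "\t"))
  colnames(lo) <- BASES
  p <- structure(list(kind = vals$kind, width = as.integer(vals$width),
                      exonic_up = as.integer(vals$exonic_up),
                      exonic_down = as.integer(vals$exonic_down),
                      log_odds = lo,
                      background = stats::setNames(
                        as.numeric(vals$background), BASES),
                      score_min = sum(apply(lo, 1, min)),
                      score_max = sum(apply(lo, 1, max))),
                 class = "pwm")
  p
}
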