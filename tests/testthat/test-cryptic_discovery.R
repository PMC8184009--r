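# A count matrix built directly from numbers, for filter arithmetic tests
direct_matrix <- function(junctions, raw, lib = 1e6) {
  samples <- data.frame(sample_id = colnames(raw), condition = colnames(raw),
                        is_control = colnames(raw) == "lacZ")
  junctions$key <- paste(junctions$chrom, junctions$strand, junctions$start,
                         junctions$end, sep = ":")
  rownames(raw) <- junctions$key
  m <- structure(list(junctions = junctions, samples = samples, raw = raw,
                      library_sizes = stats::setNames(rep(lib, ncol(raw)),
                                                      colnames(raw)),
                      normalized = NULL, psi = NULL),
                 class = "junction_count_matrix")
  compute_psi(normalize_counts(m))
}

empty_ann <- function() build_annotation(list(
  transcript_model("tz", "gz", "c1", "+",
                   data.frame(start = c(5000, 5200), end = c(5100, 5300)))))

test_that("novelty is keyed on the full junction quadruple", {
  lx <- toy_locus()
  j <- data.frame(chrom = "c1",
                  strand = c("+", "+", "+", "*"),
                  start = c(300, 300, 310, 300),
                  end = c(400, 700, 410, 400))
  out <- identify_novel(j, lx$ann)
  expect_equal(out$annotated, c(TRUE, FALSE, FALSE, TRUE))
  # annotated donor joined to the acceptor of a different intron is novel
  expect_false(out$annotated[2])
  # unstranded junction matching an annotated junction adopts its strand
  expect_equal(out$strand[4], "+")
})

test_that("the filter cascade applies floor, count FC and PSI FC in order", {
  kd <- c("eIF4AIII", "mago", "tsu")
  j <- data.frame(chrom = "c1", strand = "+",
                  start = c(100, 100, 150, 150), end = c(200, 180, 260, 240))
  # lib = 1e6 so raw counts are CPM directly
  mk <- function(lacZ, a, b, cc, partner = 100L) {
    raw <- rbind(c(partner, partner, partner, partner),
                 c(lacZ, a, b, cc),
                 c(partner, partner, partner, partner),
                 c(lacZ, a, b, cc))
    colnames(raw) <- c("lacZ", kd)
    direct_matrix(j, raw)
  }
  design <- default_design()
  cfg <- pipeline_config()

  # aggregate floor: 1+1+1+1 = 4 < 5 excludes the cryptic junctions even
  # with big fold changes (their high-count partners do pass the floor)
  m <- mk(1L, 1L, 1L, 1L)
  out <- filter_cryptic(m, design, cfg, empty_ann())
  expect_equal(attr(out, "waterfall")[["aggregate_floor"]], 2)
  expect_equal(nrow(out), 0)

  # ctrl CPM 0, KDs (9,9,0): ratios (10,10,1) pass in exactly 2/3
  m2 <- mk(0L, 9L, 9L, 0L)
  out2 <- filter_cryptic(m2, design, cfg, empty_ann())
  expect_equal(attr(out2, "waterfall")[["count_fc_pass"]], 2)
  expect_equal(unname(out2$count_fc_eIF4AIII), rep(10, 2))
  expect_equal(unname(out2$count_fc_tsu), rep(1, 2))

  # PSI fold-change gate: counts pass, PSI change too small
  # ctrl PSI 0.10 vs KD PSI ~0.15/0.12/0.11 via partner scaling
  raw <- rbind(c(900L, 1700L, 2200L, 2425L),
               c(100L, 300L, 300L, 300L),
               c(900L, 900L, 900L, 900L),
               c(100L, 100L, 100L, 100L))
  colnames(raw) <- c("lacZ", kd)
  m3 <- direct_matrix(j, raw)
  psi_kd <- m3$psi[2, kd]
  expect_true(all((psi_kd + 0.01) / (m3$psi[2, "lacZ"] + 0.01) < 2))
  out3 <- filter_cryptic(m3, design, cfg, empty_ann())
  expect_equal(attr(out3, "waterfall")[["psi_fc_pass"]], 0)
  expect_equal(nrow(out3), 0)
})

test_that("raising any threshold never enlarges the call set", {
  sim <- simulate_dataset(simulation_config(n_genes = 8, seed = 13),
                          tempfile("simmono"))
  m <- quantify_sim(sim)
  design <- default_design()
  base <- filter_cryptic(m, design, pipeline_config(), sim$annotation)
  tweaks <- list(list(min_aggregate_reads = 50),
                 list(count_fc_threshold = 6),
                 list(psi_fc_threshold = 6),
                 list(min_concordant_kd = 3))
  for (tw in tweaks) {
    cfg <- do.call(pipeline_config, tw)
    out <- filter_cryptic(m, design, cfg, sim$annotation)
    expect_true(all(out$key %in% base$key))
  }
})

test_that("classification assigns each constructed class exactly once", {
  lx <- toy_locus()
  # t1: + strand exons [100,300) [400,600) [700,900)
  cases <- data.frame(
    chrom = "c1", strand = "+",
    start = c(300, 250, 300, 330, 300, 250, 300),
    end = c(700, 400, 450, 400, 370, 450, 2500),
    expect = c("novel_alternative", "exonic_5ss", "exonic_3ss",
               "intronic_5ss", "intronic_3ss", "unclassified",
               "unclassified"))
  out <- classify_calls(cases, lx$ann)
  expect_equal(out$css_class, cases$expect)
  expect_equal(out$novel_end,
               c("neither", "donor", "acceptor", "donor", "acceptor",
                 "both", "acceptor"))
  expect_equal(out$host_gene[1:5], rep("g1", 5))
  # minus strand: t2 exons [1500,1700) [1800,2000), intron [1700,1800)
  # novel donor inside exon [1800,2000): boundary 1900 (first intronic base
  # sense = genomic 1899, exonic)
  mcase <- data.frame(chrom = "c1", strand = "-", start = 1700, end = 1900)
  outm <- classify_calls(mcase, lx$ann)
  expect_equal(outm$css_class, "exonic_5ss")
  expect_equal(outm$host_gene, "g2")
})

test_that("classification is total and single-valued on simulated calls", {
  sim <- simulate_dataset(simulation_config(n_genes = 10, seed = 31),
                          tempfile("simclass"))
  m <- quantify_sim(sim)
  calls <- filter_cryptic(m, default_design(), pipeline_config(),
                          sim$annotation)
  calls <- classify_calls(calls, sim$annotation)
  man <- sim$manifest[sim$manifest$class != "annotated", ]
  idx <- match(calls$key, man$key)
  expect_false(any(is.na(idx)))
  expect_equal(calls$css_class, man$class[idx])
})

test_that("boundary distance is the planted offset in mRNA space", {
  lx <- toy_locus()
  # novel acceptor 30 nt into exon 2 (genomic 430): mRNA cut 230, junction
  # cuts at 200 and 400 -> distance +30 from the nearest junction
  calls <- data.frame(chrom = "c1", strand = "+", start = 300, end = 430,
                      key = "k1")
  calls <- classify_calls(calls, lx$ann)
  out <- boundary_distances(calls, lx$ann, pipeline_config())
  expect_equal(out$boundary_distance, 30)
  expect_false(out$within_ejc_footprint)
  # novel donor 30 nt before exon 2 end (genomic 570): cut 370, nearest
  # junction 400 -> -30; inside the EJC footprint window [-34, -14]
  calls2 <- classify_calls(
    data.frame(chrom = "c1", strand = "+", start = 570, end = 700,
               key = "k2"), lx$ann)
  out2 <- boundary_distances(calls2, lx$ann, pipeline_config())
  expect_equal(out2$boundary_distance, -30)
  expect_true(out2$within_ejc_footprint)
  # a site whose mRNA cut coincides with a junction has distance 0
  # (constructed directly: acceptor at the exon 3 start, cut = 400)
  calls3 <- data.frame(chrom = "c1", strand = "+", start = 250, end = 700,
                       key = "k3", css_class = "exonic_3ss",
                       novel_end = "acceptor", host_transcript = "t1")
  out3 <- boundary_distances(calls3, lx$ann, pipeline_config())
  expect_equal(out3$boundary_distance, 0)
})

test_that("planted metagene offsets are recovered exactly on simulation", {
  sim <- simulate_dataset(simulation_config(n_genes = 10, seed = 77),
                          tempfile("simmeta"))
  m <- quantify_sim(sim)
  calls <- classify_calls(
    filter_cryptic(m, default_design(), pipeline_config(), sim$annotation),
    sim$annotation)
  calls <- boundary_distances(calls, sim$annotation, pipeline_config())
  man <- sim$manifest
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (!cl$css_class %in% c("exonic_5ss", "exonic_3ss")) next
    off <- man$offset[match(cl$key, man$key)]
    expected <- if (cl$css_class == "exonic_5ss") -off else off
    expect_equal(cl$boundary_distance, expected)
  }
})

test_that("null count noise yields few spurious calls when counts are
          well measured", {
  # with no condition effect the cascade should stay quiet; at very low
  # baselines the single control library dominates the error (see the
  # methods vignette), so the invariant is checked in the regime where the
  # counts themselves are informative
  study <- simulate_count_study(n_responsive = 0, n_null = 200,
                                dispersion = 0.1, control_reads = 20,
                                canonical_reads = 400, seed = 99)
  calls <- filter_cryptic(study$matrix, study$design, pipeline_config(),
                          study$annotation)
  expect_lt(nrow(calls) / 200, 0.05)
})

test_that("degenerate permutation tests return p = 1", {
  u <- paste0("j", 1:30)
  # every set equal to the universe: every permutation ties
  res <- overlap_permutation_test(list(u, u, u), u, n_perm = 200, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed, 30)
  # observed overlap 0 can never be exceeded downward
  res0 <- overlap_permutation_test(list(u[1:10], u[11:20]), u,
                                   n_perm = 200, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p_value, 1)
  expect_error(overlap_permutation_test(list(c(u, "zz"), u), u, 10, 1),
               "outside universe")
})

test_that("permutation test is reproducible under a fixed seed", {
  u <- paste0("j", 1:50)
  s1 <- u[1:20]; s2 <- u[10:35]
  a <- overlap_permutation_test(list(s1, s2), u, n_perm = 2000, seed = 42)
  b <- overlap_permutation_test(list(s1, s2), u, n_perm = 2000, seed = 42)
  expect_identical(a, b)
})
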