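# Shared in-code fixtures: toy genomes, annotations and SAM files are built
# programmatically so tests carry no binary data.

toy_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# A deterministic genome + three-exon plus/minus transcripts with canonical
# GT..AG introns, for classification and coordinate tests.
toy_locus <- function(seed = 11) {
  set.seed(seed)
  s <- strsplit(rand_seq(3000), "")[[1]]
  # plus transcript: exons [100,300) [400,600) [700,900)
  for (i in c(300, 600)) s[(i + 1):(i + 2)] <- c("G", "T")
  for (i in c(400, 700)) s[(i - 1):i] <- c("A", "G")
  # minus transcript: exons [1500,1700) [1800,2000); sense intron
  # [1700,1800) needs genome-forward CT..AC
  s[1701:1702] <- c("C", "T"); s[1799:1800] <- c("A", "C")
  genome <- toy_genome(list(c1 = paste(s, collapse = "")))
  t1 <- transcript_model("t1", "g1", "c1", "+",
                         data.frame(start = c(100, 400, 700),
                                    end = c(300, 600, 900)))
  t2 <- transcript_model("t2", "g2", "c1", "-",
                         data.frame(start = c(1500, 1800),
                                    end = c(1700, 2000)))
  list(genome = genome, ann = build_annotation(list(t1, t2)), t1 = t1,
       t2 = t2)
}

# write a SAM file from a data.frame of records
write_test_sam <- function(path, recs, chrom = "c1", chrlen = 3000) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrlen))
  lines <- vapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    paste(r$qname, r$flag, chrom, r$pos, 60, r$cigar, "*", 0, 0,
          r$seq, "*", r$tags, sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

sam_rec <- function(qname, pos, cigar, nm = 0, flag = 0, seq = "*",
                    extra = NULL) {
  tags <- paste0("NM:i:", nm)
  if (!is.null(extra)) tags <- paste(tags, extra, sep = "\t")
  data.frame(qname = qname, flag = flag, pos = pos, cigar = cigar,
             seq = seq, tags = tags, stringsAsFactors = FALSE)
}

# random multi-exon transcript inside a chromosome of the given length
random_transcript <- function(id, chrom = "c1", chrom_len = 5000,
                              strand = NULL) {
  n_ex <- sample(1:5, 1)
  widths <- sample(10:60, n_ex, replace = TRUE)
  gaps <- sample(5:40, n_ex, replace = TRUE)
  starts <- cumsum(gaps + c(0, widths[-n_ex])) + sample(0:50, 1)
  transcript_model(id, paste0("g_", id), chrom,
                   strand %||% sample(c("+", "-"), 1),
                   data.frame(start = starts, end = starts + widths))
}

default_design <- function() {
  list(control = "lacZ",
       kd = list(eIF4AIII = "eIF4AIII", mago = "mago", tsu = "tsu"))
}

# quantify a simulated dataset through the standard chain
quantify_sim <- function(sim) {
  sheet <- read_sample_sheet(sim$paths$samples)
  per <- lapply(stats::setNames(sheet$path, sheet$sample_id),
                extract_split_reads, genome = sim$genome)
  compute_psi(normalize_counts(junction_count_matrix(per, sheet)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

strip_attrs <- function(x) { attributes(x) <- NULL; x }

tx_length_for_test <- function(t) sum(t$exons$end - t$exons$start)

toy_constant_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- toy_genome(list(c1 = strrep("ACGT", 1500)))
    g
  }
})
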