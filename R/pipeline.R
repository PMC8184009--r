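#' Read and validate a sample sheet
#'
#' A TSV with columns `path`, `sample_id`, `condition`, `is_control`;
#' exactly one control condition and at least one knockdown condition are
#' required.
#'
#' @param path Sample sheet TSV path (or a data.frame).
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- if (is.data.frame(path)) path else
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  need <- c("path", "sample_id", "condition", "is_control")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing field(s): ", paste(miss, collapse = ", "))
  }
  sheet$is_control <- as.logical(sheet$is_control)
  ctrl <- unique(sheet$condition[sheet$is_control])
  kd <- unique(sheet$condition[!sheet$is_control])
  if (length(ctrl) != 1) {
    stop("sample sheet must define exactly one control condition (found ",
         length(ctrl), ")")
  }
  if (!length(kd)) stop("sample sheet has zero knockdown conditions")
  sheet
}

sheet_design <- function(sheet) {
  kd <- unique(sheet$condition[!sheet$is_control])
  list(control = sheet$sample_id[sheet$is_control],
       kd = stats::setNames(lapply(kd, function(k)
         sheet$sample_id[sheet$condition == k]), kd))
}

#' Run the cryptic-splicing pipeline
#'
#' Orchestrates the stages behind one entry point. Stages communicate via
#' TSV artifacts in `outdir`, so each is independently runnable and
#' resumable: `simulate` writes a synthetic dataset; `quantify` extracts and
#' normalizes split-read junction counts; `motifs` trains donor/acceptor and
#' branchpoint models; `discover` applies the cryptic filter cascade and
#' classifies calls; `resplice` scans for regenerated-site partners;
#' `report` recounts everything into a run summary; `all` runs the full
#' chain. Logging is `key=value` on stderr; a JSON run summary accompanies
#' the report.
#'
#' @param subcommand One of simulate, quantify, motifs, discover, resplice,
#'   report, all.
#' @param config Path to a YAML config file or a named list; keys override
#'   [pipeline_config()] defaults, plus `genome` / `gtf` paths and a `sim`
#'   block for the simulate stage.
#' @param samples Sample sheet path or data.frame (see
#'   [read_sample_sheet()]); not needed for `simulate`.
#' @param outdir Output directory.
#' @param seed Seed recorded into the config.
#' @return The run report (invisible for artifact-writing stages).
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "quantify",
                                        "motifs", "discover", "resplice",
                                        "report"),
                         config = NULL, samples = NULL, outdir, seed = 1L) {
  subcommand <- match.arg(subcommand)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  raw_cfg <- if (is.character(config)) yaml::read_yaml(config) else
    (config %||% list())
  known <- names(formals(pipeline_config))
  cfg <- do.call(pipeline_config,
                 c(raw_cfg[intersect(names(raw_cfg), known)],
                   list(rng_seed = seed)))
  log_kv(subcommand, outdir = outdir, seed = seed)

  if (subcommand %in% c("simulate", "all")) {
    sim_args <- raw_cfg$sim %||% list()
    sim_args$seed <- seed
    scfg <- do.call(simulation_config, sim_args)
    sim <- simulate_dataset(scfg, file.path(outdir, "sim"))
    raw_cfg$genome <- sim$paths$genome
    raw_cfg$gtf <- sim$paths$gtf
    samples <- sim$paths$samples
    log_kv("simulate", genes = scfg$n_genes,
           planted = nrow(scfg$planted_cryptic))
    if (subcommand == "simulate") return(invisible(sim))
  }

  if (is.null(raw_cfg$genome) || is.null(raw_cfg$gtf)) {
    stop("config must provide genome and gtf paths")
  }
  if (!file.exists(raw_cfg$genome)) stop("missing input: ", raw_cfg$genome)
  if (!file.exists(raw_cfg$gtf)) stop("missing input: ", raw_cfg$gtf)
  genome <- load_genome(raw_cfg$genome)
  ann <- load_annotation(raw_cfg$gtf, genome)
  sheet <- read_sample_sheet(samples)
  design <- sheet_design(sheet)
  counts_path <- file.path(outdir, "junction_counts.tsv")
  calls_path <- file.path(outdir, "cryptic_calls.tsv")
  bed_path <- file.path(outdir, "cryptic_sites.bed")
  events_path <- file.path(outdir, "resplice_events.tsv")
  products_path <- file.path(outdir, "respliced_products.fa")

  if (subcommand %in% c("quantify", "all")) {
    per_sample <- lapply(stats::setNames(sheet$path, sheet$sample_id),
                         extract_split_reads,
                         min_overhang = cfg$min_overhang,
                         max_mismatches = cfg$max_mismatches,
                         genome = genome)
    m <- junction_count_matrix(per_sample, sheet)
    m <- compute_psi(normalize_counts(m))
    write_atomic(counts_path, function(p) write_junction_counts(m, p))
    log_kv("quantify", junctions = nrow(m$junctions),
           libraries = ncol(m$raw))
    if (subcommand == "quantify") return(invisible(counts_path))
  }

  pwms <- NULL
  if (subcommand %in% c("motifs", "discover", "resplice", "all")) {
    n_intr <- nrow(ann$junctions)
    pwms <- train_splice_models(ann, genome,
                                min_introns = min(100L, max(10L, n_intr)))
    write_pwm(pwms$donor, file.path(outdir, "pwm_donor.tsv"))
    write_pwm(pwms$acceptor, file.path(outdir, "pwm_acceptor.tsv"))
    if (subcommand == "motifs") {
      bp <- derive_branchpoint_pwm(ann, genome, seed = seed,
                                   window = cfg$bp_window)
      write_pwm(bp, file.path(outdir, "pwm_branchpoint.tsv"))
      log_kv("motifs", donor_consensus = pwm_consensus(pwms$donor),
             bp_consensus = pwm_consensus(bp))
      return(invisible(pwms))
    }
  }

  if (subcommand %in% c("discover", "resplice", "all")) {
    if (!file.exists(counts_path)) {
      stop("missing input: ", counts_path, " (run quantify first)")
    }
    m <- read_junction_counts(counts_path, sheet)
    calls <- filter_cryptic(m, design, cfg, ann)
    waterfall <- attr(calls, "waterfall")
    calls <- classify_calls(calls, ann)
    calls <- boundary_distances(calls, ann, cfg)
    calls$ss_score <- call_ss_scores(calls, ann, genome, pwms)
    write_atomic(calls_path, function(p)
      utils::write.table(calls, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    write_cryptic_calls(calls, NULL, bed_path)
    log_kv("discover", candidates = waterfall[["candidates"]],
           calls = nrow(calls))
    if (subcommand == "discover") return(invisible(calls))
  } else {
    calls <- NULL
  }

  if (subcommand %in% c("resplice", "all")) {
    if (is.null(calls)) {
      if (!file.exists(calls_path)) stop("missing input: ", calls_path)
      calls <- utils::read.table(calls_path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    }
    events <- scan_resplicing(calls, ann, genome, pwms$donor, pwms$acceptor)
    write_atomic(events_path, function(p)
      utils::write.table(events, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    fa <- unlist(lapply(seq_len(nrow(events)), function(i) {
      c(paste0(">", events$key[i], "_", events$transcript_id[i]),
        respliced_product(events[i, ], ann, genome))
    }))
    writeLines(fa %||% character(0), products_path)
    log_kv("resplice", events = nrow(events))
    if (subcommand == "resplice") return(invisible(events))
  }

  # report (for "report" and "all")
  if (is.null(calls)) {
    if (!file.exists(calls_path)) stop("missing input: ", calls_path)
    calls <- utils::read.table(calls_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    m <- read_junction_counts(counts_path, sheet)
    waterfall <- attr(filter_cryptic(m, design, cfg, ann), "waterfall")
    events <- if (file.exists(events_path))
      utils::read.table(events_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE) else NULL
  }
  report <- run_report(calls, waterfall, events, cfg)
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(format_report(report), file.path(outdir, "run_report.txt"))
  log_kv("report", calls = report$n_calls)
  invisible(report)
}

call_ss_scores <- function(calls, ann, genome, pwms) {
  vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    if (!r$novel_end %in% c("donor", "acceptor")) return(NA_real_)
    pwm <- if (r$novel_end == "donor") pwms$donor else pwms$acceptor
    boundary <- if (r$novel_end == "donor")
      donor_boundary(r$strand, r$start, r$end) else
      acceptor_boundary(r$strand, r$start, r$end)
    up <- if (pwm$kind == "donor") pwm$exonic_up else
      pwm$width - pwm$exonic_down
    # prefer mRNA context of the host transcript (exonic sites); fall back
    # to genomic context when the site is not exonic in the host
    if (!is.na(r$host_transcript) &&
        r$css_class %in% c("exonic_5ss", "exonic_3ss")) {
      t <- ann$transcripts[[r$host_transcript]]
      cut <- tryCatch(novel_site_mrna_cut(r, t), error = function(e) NA)
      if (!is.na(cut)) {
        m <- transcript_sequence(t, genome)
        s <- cut - up
        if (s >= 0 && s + pwm$width <= nchar(m)) {
          return(score_site(pwm, substr(m, s + 1, s + pwm$width))$normalized)
        }
      }
    }
    w <- extract_window(genome, r$chrom, r$strand, boundary, up,
                        pwm$width - up)
    score_site(pwm, w)$normalized
  }, numeric(1))
}

write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

run_report <- function(calls, waterfall, events, cfg) {
  classes <- c("exonic_5ss", "exonic_3ss", "intronic_5ss", "intronic_3ss",
               "novel_alternative", "unclassified")
  class_dist <- as.list(table(factor(calls$css_class, levels = classes)))
  compat <- list()
  for (cl in c("exonic_5ss", "exonic_3ss")) {
    n_cl <- sum(calls$css_class == cl)
    n_compat <- if (!is.null(events) && nrow(events))
      length(intersect(calls$key[calls$css_class == cl], events$key)) else 0L
    compat[[cl]] <- list(n = n_cl, compatible = n_compat,
                         fraction = if (n_cl) n_compat / n_cl else NA)
  }
  strong <- if (!is.null(events) && nrow(events))
    sum(events$partner_score >= cfg$strong_ss_threshold, na.rm = TRUE) else 0L
  list(waterfall = as.list(waterfall), n_calls = nrow(calls),
       class_distribution = class_dist,
       resplice_compatibility = compat,
       strong_partner_sites = strong,
       n_events = if (is.null(events)) 0L else nrow(events),
       config = unclass(cfg),
       version = as.character(utils::packageVersion("crypticsplice")))
}

format_report <- function(r) {
  c("cryptic splicing run report",
    paste0("  filter waterfall: ",
           paste(names(r$waterfall), unlist(r$waterfall), sep = "=",
                 collapse = " -> ")),
    paste0("  calls: ", r$n_calls),
    paste0("  classes: ",
           paste(names(r$class_distribution),
                 unlist(r$class_distribution), sep = "=", collapse = " ")),
    paste0("  resplice events: ", r$n_events,
           " (strong partners: ", r$strong_partner_sites, ")"))
}
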