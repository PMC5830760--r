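#' Default pipeline configuration
#'
#' Every parameter defaults to the protocol's stated value where one
#' exists: simulation with 12 diploid individuals at heterozygosity 0.02,
#' 125 bp reads over the 200-700 bp insert ladder in 50 bp steps at mean
#' depth 10 per step with substitution error 0.01; minimum stack depth 5;
#' threshold scans 1..10 (within) and 1..8 (across); read-pool bounds
#' 10/400; short-read overlap assembly parameters; minimum contig length
#' 125 bp.
#'
#' @param ... overrides of any default.
#' @return a named list of class `rad_config`.
#' @export
rad_config <- function(...) {
  cfg <- list(
    n_loci = 200L, n_individuals = 12L, het = 0.02,
    insert_min = 200L, n_steps = 10L, step = 50L, depth_per_step = 10,
    read_len = 125L, err = 0.01,
    window_frac = 0.1, score_limit = 13, remnant = "TGCAGG",
    site_mismatch = 0L,
    min_depth = 5L, max_stacks = 3L, removal = TRUE,
    m_range = 1:10, n_range = 1:8, tau = 0.05, subsample = NULL,
    mismatch_within = NULL, mismatch_across = NULL,
    min_reads = 10L, max_reads = 400L,
    min_overlap = 20L, max_mismatch_rate = 0.06, mismatch_penalty = 2L,
    min_contig_len = 125L,
    map_k = 21L, min_identity = 0.9, insert_range = c(100L, 1000L),
    threads = 1L, seed = 1L,
    preprocess = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- c("rad_config", "list")
  cfg
}

stage_log <- function(out_dir, stage, t0, params) {
  entry <- list(stage = stage, wall_s = round(as.numeric(Sys.time()) - t0, 2),
                params = params)
  if (!is.null(out_dir)) {
    mf <- file.path(out_dir, "manifest.json")
    man <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
    man[[stage]] <- entry
    jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(entry)
}

stage_done <- function(out_dir, stage, files) {
  if (is.null(out_dir)) return(FALSE)
  mf <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf)) return(FALSE)
  man <- jsonlite::read_json(mf)
  !is.null(man[[stage]]) && all(file.exists(file.path(out_dir, files)))
}

#' Run the whole pipeline
#'
#' Orchestrates simulate (-> preprocess) -> optimize -> cluster -> catalog
#' -> sort -> assemble -> evaluate.  With `out_dir` set, each stage writes
#' its outputs (FASTA/FASTQ/TSV) plus a `manifest.json` recording stage
#' parameters and wall time; on a rerun, stages whose outputs are already
#' present are skipped and reloaded, so deleting one stage's files reruns
#' that stage alone (and any later ones).  Rerunning with the same seed
#' gives byte-identical contigs.
#'
#' @param config a [rad_config()] list.
#' @param out_dir optional run directory for stage outputs and resume.
#' @param input_pairs optional named list of `rad_pairs` (one per
#'   individual) to use instead of simulating; ground-truth metrics are
#'   skipped unless ids carry simulator labels.
#' @return list with `thresholds`, `catalog`, `contigs`, `metrics`,
#'   `config`, and (when simulated) `truth`.
#' @export
run_pipeline <- function(config = rad_config(), out_dir = NULL,
                         input_pairs = NULL) {
  cfg <- config
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate (or accept input) ---------------------------------------
  truth <- NULL
  t0 <- as.numeric(Sys.time())
  if (is.null(input_pairs)) {
    sim_files <- c("truth.tsv", "truth.fa")
    if (stage_done(out_dir, "simulate", sim_files)) {
      truth <- read.delim(file.path(out_dir, "truth.tsv"))
      tf <- read_fasta(file.path(out_dir, "truth.fa"))
      truth$ref_seq <- tf$seq[match(paste0("locus", truth$locus_id), tf$id)]
      nms <- sprintf("ind%02d", seq_len(cfg$n_individuals))
      pairs <- lapply(nms, function(nm)
        read_fastq_pairs(file.path(out_dir, paste0(nm, "_1.fq.gz")),
                         file.path(out_dir, paste0(nm, "_2.fq.gz")), nm))
      names(pairs) <- nms
    } else {
      sim <- simulate_radseq(cfg$n_loci, cfg$n_individuals, cfg$het, cfg$seed,
                             insert_min = cfg$insert_min, n_steps = cfg$n_steps,
                             step = cfg$step, depth_per_step = cfg$depth_per_step,
                             read_len = cfg$read_len, err = cfg$err)
      truth <- sim$truth
      pairs <- sim$pairs
      if (!is.null(out_dir)) {
        write_fasta(data.frame(id = "chr1", seq = sim$genome$chroms[["chr1"]]),
                    file.path(out_dir, "genome.fa"))
        write_fasta(data.frame(id = paste0("locus", truth$locus_id),
                               seq = truth$ref_seq),
                    file.path(out_dir, "truth.fa"))
        write.table(truth[, c("locus_id", "chrom", "start", "end", "strand")],
                    file.path(out_dir, "truth.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        for (nm in names(pairs))
          write_fastq_pairs(pairs[[nm]],
                            file.path(out_dir, paste0(nm, "_1.fq.gz")),
                            file.path(out_dir, paste0(nm, "_2.fq.gz")))
      }
      stage_log(out_dir, "simulate", t0,
                cfg[c("n_loci", "n_individuals", "het", "insert_min", "n_steps",
                      "step", "depth_per_step", "read_len", "err", "seed")])
    }
  } else {
    pairs <- input_pairs
    if (all(grepl("^L\\d+_", pairs[[1]]$id))) {
      # simulated input: ids carry truth labels but no reference sequences
      truth <- NULL
    }
  }

  # --- preprocess (optional; simulated reads are already clean) ----------
  if (isTRUE(cfg$preprocess)) {
    t0 <- as.numeric(Sys.time())
    reports <- list()
    for (nm in names(pairs)) {
      pp <- preprocess_pairs(pairs[[nm]], cfg$window_frac, cfg$score_limit,
                             cfg$remnant, cfg$site_mismatch)
      pairs[[nm]] <- pp$pairs
      reports[[nm]] <- cbind(individual = nm, pp$report)
    }
    if (!is.null(out_dir))
      write.table(do.call(rbind, reports), file.path(out_dir, "preprocess.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    stage_log(out_dir, "preprocess", t0,
              cfg[c("window_frac", "score_limit", "remnant", "site_mismatch")])
  }

  fwd_reads <- lapply(pairs, function(p) data.frame(id = p$id, seq = p$fwd_seq))

  # --- fast-forward resume: assembled outputs already on disk -----------
  if (stage_done(out_dir, "assemble", c("contigs.fa", "assembly_report.tsv")) &&
      stage_done(out_dir, "sort", file.path("sorted", "index.tsv")) &&
      stage_done(out_dir, "catalog", c("catalog.fa", "membership.tsv")) &&
      stage_done(out_dir, "optimize", "thresholds.tsv")) {
    thr <- read.delim(file.path(out_dir, "thresholds.tsv"))
    m_opt <- thr$value[thr$param == "mismatch_within"]
    n_opt <- thr$value[thr$param == "mismatch_across"]
    catfa <- read_fasta(file.path(out_dir, "catalog.fa"))
    cat_res <- list(catalog = data.frame(cat_id = as.integer(sub("^cl", "", catfa$id)),
                                         consensus = catfa$seq),
                    membership = read.delim(file.path(out_dir, "membership.tsv")))
    idx <- read.delim(file.path(out_dir, "sorted", "index.tsv"))
    read_sets <- lapply(seq_len(nrow(idx)), function(i) {
      cid <- idx$cat_id[i]
      rd <- data.frame(individual = character(), id = character(),
                       seq = character())
      fa_path <- file.path(out_dir, "sorted", sprintf("locus_%05d.fa", cid))
      if (idx$n_used[i] > 0 && file.exists(fa_path)) {
        fa <- read_fasta(fa_path)
        parts <- strsplit(fa$id, "|", fixed = TRUE)
        rd <- data.frame(individual = vapply(parts, `[`, "", 1),
                         id = vapply(parts, `[`, "", 2), seq = fa$seq)
      }
      list(cat_id = cid,
           consensus = cat_res$catalog$consensus[match(cid, cat_res$catalog$cat_id)],
           reads = rd, n_before = idx$n_before[i],
           consensus_only = idx$consensus_only[i])
    })
    ctgfa <- read_fasta(file.path(out_dir, "contigs.fa"))
    rep <- read.delim(file.path(out_dir, "assembly_report.tsv"))
    contigs <- data.frame(cat_id = as.integer(sub("^cl", "", ctgfa$id)),
                          seq = ctgfa$seq)
    contigs$source <- sub("^source=(\\S+).*", "\\1", ctgfa$desc)
    contigs$padded <- sub(".*padded=(\\S+)", "\\1", ctgfa$desc) == "TRUE"
    contigs$pad_start <- ifelse(contigs$padded,
                                as.integer(regexpr("NNNNNNNNNN", contigs$seq)),
                                NA_integer_)
    contigs$length <- nchar(contigs$seq)
    contigs$n_reads <- rep$n_reads_in[match(contigs$cat_id, rep$cat_id)]
    asm <- list(contigs = contigs, report = rep)
    return(pipeline_evaluate(cfg, out_dir, pairs, truth, m_opt, n_opt,
                             NULL, NULL, cat_res, read_sets, asm))
  }

  # --- optimize ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  m_opt <- cfg$mismatch_within
  n_opt <- cfg$mismatch_across
  within_curve <- NULL; across_curve <- NULL
  if (is.null(m_opt)) {
    sw <- select_within(fwd_reads[[1]], cfg$m_range, cfg$min_depth,
                        cfg$max_stacks, removal = FALSE)
    m_opt <- sw$m_opt; within_curve <- sw$curve
  }
  if (is.null(n_opt)) {
    sel <- names(fwd_reads)
    if (!is.null(cfg$subsample))
      sel <- subsample_individuals(sel, cfg$subsample,
                                   derive_seed(cfg$seed, "subsample"))
    locsets <- lapply(fwd_reads[sel], function(fr) {
      cl <- cluster_individual(fr, m_opt, cfg$min_depth, cfg$max_stacks,
                               removal = FALSE)
      cl$loci$consensus[!cl$loci$flagged]
    })
    sa <- select_across(locsets, cfg$n_range, cfg$tau)
    n_opt <- sa$n_opt; across_curve <- sa$curve
  }
  if (!is.null(out_dir)) {
    write.table(data.frame(param = c("mismatch_within", "mismatch_across"),
                           value = c(m_opt, n_opt)),
                file.path(out_dir, "thresholds.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    if (!is.null(within_curve))
      write.table(within_curve, file.path(out_dir, "within_curve.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(across_curve))
      write.table(across_curve[, c("n", "delta")],
                  file.path(out_dir, "across_curve.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }
  stage_log(out_dir, "optimize", t0,
            list(m_range = range(cfg$m_range), n_range = range(cfg$n_range),
                 tau = cfg$tau, m_opt = m_opt, n_opt = n_opt))

  # --- cluster -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  clusters <- lapply(fwd_reads, function(fr)
    cluster_individual(fr, m_opt, cfg$min_depth, cfg$max_stacks, cfg$removal))
  if (!is.null(out_dir)) {
    loctab <- do.call(rbind, lapply(names(clusters), function(nm)
      cbind(individual = nm,
            clusters[[nm]]$loci[, c("locus_id", "consensus", "haplotypes",
                                    "depth", "flagged")])))
    write.table(loctab, file.path(out_dir, "loci.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  stage_log(out_dir, "cluster", t0,
            list(m = m_opt, min_depth = cfg$min_depth,
                 max_stacks = cfg$max_stacks, removal = cfg$removal))

  # --- catalog -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  locsets <- lapply(clusters, function(cl)
    cl$loci[!cl$loci$flagged, c("locus_id", "consensus")])
  cat_res <- build_catalog(locsets, n_opt)
  if (!is.null(out_dir)) {
    write_fasta(data.frame(id = paste0("cl", cat_res$catalog$cat_id),
                           seq = cat_res$catalog$consensus),
                file.path(out_dir, "catalog.fa"))
    write.table(cat_res$membership, file.path(out_dir, "membership.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  stage_log(out_dir, "catalog", t0, list(n = n_opt))

  # --- sort --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  read_sets <- sort_read_pairs(cat_res, clusters, pairs, cfg$min_reads,
                               cfg$max_reads, cfg$seed)
  if (!is.null(out_dir)) {
    sdir <- file.path(out_dir, "sorted")
    dir.create(sdir, showWarnings = FALSE)
    idx <- do.call(rbind, lapply(read_sets, function(rs)
      data.frame(cat_id = rs$cat_id, n_before = rs$n_before,
                 n_used = nrow(rs$reads), consensus_only = rs$consensus_only)))
    write.table(idx, file.path(out_dir, "sorted", "index.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    for (rs in read_sets) if (nrow(rs$reads))
      write_fasta(data.frame(id = paste0(rs$reads$individual, "|", rs$reads$id),
                             seq = rs$reads$seq),
                  file.path(sdir, sprintf("locus_%05d.fa", rs$cat_id)))
  }
  stage_log(out_dir, "sort", t0,
            list(min_reads = cfg$min_reads, max_reads = cfg$max_reads))

  # --- assemble ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  asm <- assemble_loci(read_sets, cfg$min_overlap, cfg$max_mismatch_rate,
                       cfg$mismatch_penalty, cfg$min_contig_len, cfg$threads)
  if (!is.null(out_dir)) {
    write_fasta(data.frame(id = paste0("cl", asm$contigs$cat_id),
                           desc = paste0("source=", asm$contigs$source,
                                         " padded=", asm$contigs$padded),
                           seq = asm$contigs$seq),
                file.path(out_dir, "contigs.fa"))
    write.table(asm$report, file.path(out_dir, "assembly_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  stage_log(out_dir, "assemble", t0,
            cfg[c("min_overlap", "max_mismatch_rate", "mismatch_penalty",
                  "min_contig_len", "threads")])

  pipeline_evaluate(cfg, out_dir, pairs, truth, m_opt, n_opt, within_curve,
                    across_curve, cat_res, read_sets, asm)
}

# Evaluation stage shared by the normal and fast-forward paths.
pipeline_evaluate <- function(cfg, out_dir, pairs, truth, m_opt, n_opt,
                              within_curve, across_curve, cat_res,
                              read_sets, asm) {
  t0 <- as.numeric(Sys.time())
  used_ids <- unlist(lapply(read_sets, function(rs) rs$reads$id))
  allp <- do.call(rbind, unname(pairs))
  used <- allp[allp$id %in% used_ids, , drop = FALSE]
  stats <- contig_stats(asm$contigs$seq)
  mp <- map_read_pairs(asm$contigs$seq, used, cfg$map_k, cfg$min_identity,
                       cfg$insert_range)
  metrics <- data.frame(n_clusters = stats$n_contigs, n50 = stats$n50,
                        mean_len = stats$mean_len, total_cov = stats$total_cov,
                        total_mapped_pct = mp$total_mapped_pct,
                        proper_paired_pct = mp$proper_paired_pct,
                        n_pairs_mapped_input = mp$n_pairs)
  if (!is.null(truth)) {
    tl <- majority_truth_locus(read_sets)
    ctg <- asm$contigs
    ctg$truth_locus <- tl$truth_locus[match(ctg$cat_id, tl$cat_id)]
    ti <- truth_identity(ctg, truth)
    metrics$identical_clusters_pct <- ti$pct_contigs_matched
    metrics$mean_identity_pct <- ti$mean_identity
  }
  if (!is.null(out_dir))
    write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  stage_log(out_dir, "evaluate", t0,
            cfg[c("map_k", "min_identity", "insert_range")])

  list(thresholds = list(m_opt = m_opt, n_opt = n_opt,
                         within_curve = within_curve,
                         across_curve = across_curve),
       catalog = cat_res, read_sets = read_sets, contigs = asm$contigs,
       assembly_report = asm$report, metrics = metrics, truth = truth,
       config = cfg)
}
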