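# End-to-end orchestration: fold -> cpg -> triplex -> events, with
# deterministic reports. Stage outputs carry no timestamps, so two runs
# with the same config (and seed) are byte-identical.

#' Build a pipeline configuration
#'
#' @param mirna_fasta Path to the microRNA FASTA (RNA alphabet).
#' @param promoter_fasta Path to a promoter FASTA, or \code{NULL} if
#'   \code{genome_fasta} + \code{annotation} are given instead.
#' @param genome_fasta,annotation Optional genome FASTA and BED/GFF3
#'   annotation; promoters are extracted as 600-bp 5'-flanks.
#' @param event_table,edge_list Paths to the somatic-event TSV and
#'   interaction edge-list TSV (optional; the events stage is skipped when
#'   absent).
#' @param output_dir Directory for all reports.
#' @param energy_window Suboptimal enumeration window (kcal/mol);
#'   \code{NULL} = 5\% of |MFE| with a 1.0 floor.
#' @param cpg_window,cpg_step CpG sliding-window size and step.
#' @param score_threshold,energy_threshold Triplex retention thresholds.
#' @param background_n Background sample size for hit grading.
#' @param upstream_bp Promoter length when extracting from a genome.
#' @param seed Master seed recorded in every report and used for the
#'   triplex background.
#' @return A validated config list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mirna_fasta, promoter_fasta = NULL,
                            genome_fasta = NULL, annotation = NULL,
                            event_table = NULL, edge_list = NULL,
                            output_dir = "mirtriplex_out",
                            energy_window = NULL, cpg_window = 200L,
                            cpg_step = 1L, score_threshold = 140,
                            energy_threshold = -140, background_n = 1000L,
                            upstream_bp = 600L, seed = 1L) {
  cfg <- list(paths = list(mirna_fasta = mirna_fasta,
                           promoter_fasta = promoter_fasta,
                           genome_fasta = genome_fasta,
                           annotation = annotation,
                           event_table = event_table, edge_list = edge_list),
              output_dir = output_dir,
              fold = list(energy_window = energy_window),
              cpg = list(window = as.integer(cpg_window),
                         step = as.integer(cpg_step)),
              triplex = list(score_threshold = score_threshold,
                             energy_threshold = energy_threshold,
                             background_n = as.integer(background_n)),
              upstream_bp = as.integer(upstream_bp),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}}.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

validate_config <- function(cfg) {
  p <- cfg$paths
  if (is.null(p$mirna_fasta)) stop("mirna_fasta is required", call. = FALSE)
  if (is.null(p$promoter_fasta) &&
      (is.null(p$genome_fasta) || is.null(p$annotation)))
    stop("either promoter_fasta or genome_fasta + annotation is required",
         call. = FALSE)
  for (f in Filter(Negate(is.null), p)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  invisible(cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_log <- function(cfg, stage, params, path) {
  p <- Filter(Negate(is.null), cfg$paths)
  lines <- c(
    sprintf("stage: %s", stage),
    sprintf("mirtriplex_version: %s",
            as.character(utils::packageVersion("mirtriplex"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_hash: %s", config_hash(cfg)),
    sprintf("param %s: %s", names(params),
            vapply(params, function(x) paste(format(x), collapse = ","),
                   character(1))),
    sprintf("input %s: %s md5=%s", names(p), unlist(p),
            vapply(unlist(p), file_md5, character(1))))
  writeLines(lines, path)
  invisible(path)
}

load_promoters <- function(cfg) {
  p <- cfg$paths
  if (!is.null(p$promoter_fasta)) {
    read_fasta(p$promoter_fasta, "DNA")
  } else {
    genome <- read_fasta(p$genome_fasta, "DNA")
    anns <- read_annotation(p$annotation)
    out <- lapply(seq_len(nrow(anns)), function(r)
      extract_promoter(genome, anns[r, , drop = FALSE], cfg$upstream_bp))
    names(out) <- vapply(out, function(x) x$id, character(1))
    out
  }
}

promoter_gene <- function(id) sub("_promoter$", "", id)

#' Run the folding stage
#'
#' Folds every microRNA, writes \code{table1.tsv} (id, length,
#' energy_window, structure energies, structure count), a Vienna
#' dot-bracket file \code{folds.txt}, and a stage log.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Named list of \code{fold_result}s, invisibly.
#' @export
run_fold <- function(config) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  mirnas <- read_fasta(config$paths$mirna_fasta, "RNA")
  if (!length(mirnas)) stop("empty microRNA FASTA", call. = FALSE)
  model <- default_energy_model()
  folds <- lapply(mirnas, fold_suboptimal, model = model,
                  energy_window = config$fold$energy_window)
  tab <- do.call(rbind, lapply(folds, function(f) data.frame(
    id = f$sequence$id, length = f$sequence$length,
    energy_window = sprintf("%.2f", f$energy_window),
    energies = paste(sprintf("%.2f", vapply(f$structures, `[[`, numeric(1),
                                            "energy")), collapse = ","),
    structure_count = f$structure_count)))
  write.table(tab, file.path(config$output_dir, "table1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_dotbracket(folds, file.path(config$output_dir, "folds.txt"))
  write_stage_log(config, "fold",
                  list(energy_window = config$fold$energy_window %||% "auto"),
                  file.path(config$output_dir, "fold_log.txt"))
  invisible(folds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the CpG-island stage
#'
#' Per-promoter window statistics, island calls and the per-gene summary
#' table (\code{table2.tsv}, two-decimal report precision), islands as BED,
#' all window statistics as TSV, and a stage log.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Named list (per gene) of \code{stats}/\code{islands}/
#'   \code{summary}, invisibly.
#' @export
run_cpg <- function(config) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  promoters <- load_promoters(config)
  res <- lapply(promoters, function(p) {
    stats <- window_stats(p, config$cpg$window, config$cpg$step)
    islands <- call_islands(stats)
    list(stats = stats, islands = islands,
         summary = cpg_summary(promoter_gene(p$id), stats, islands))
  })
  summ <- do.call(rbind, lapply(res, `[[`, "summary"))
  summ$min_gc <- sprintf("%.2f", summ$min_gc)
  summ$max_gc <- sprintf("%.2f", summ$max_gc)
  summ$min_obs_exp <- sprintf("%.2f", summ$min_obs_exp)
  summ$max_obs_exp <- sprintf("%.2f", summ$max_obs_exp)
  write.table(summ, file.path(config$output_dir, "table2.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bed <- unlist(lapply(names(res), function(g) {
    isl <- res[[g]]$islands
    if (!nrow(isl)) return(character(0))
    sprintf("%s\t%d\t%d\tCpG_island_%d\t%d\t.", g, isl$start, isl$end,
            seq_len(nrow(isl)), round(isl$mean_obs_exp * 100))
  }))
  writeLines(bed, file.path(config$output_dir, "islands.bed"))
  win <- do.call(rbind, lapply(names(res), function(g) {
    s <- res[[g]]$stats
    data.frame(gene = promoter_gene(g), start = s$start, end = s$end,
               gc_percent = sprintf("%.2f", s$gc_percent),
               obs_exp = sprintf("%.4f", s$obs_exp), skipped = s$skipped)
  }))
  write.table(win, file.path(config$output_dir, "windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_stage_log(config, "cpg", config$cpg,
                  file.path(config$output_dir, "cpg_log.txt"))
  invisible(res)
}

#' Run the triplex stage
#'
#' Scans every microRNA against every promoter, grades retained hits
#' against a seeded dinucleotide-shuffled background, and writes the hit
#' table (\code{hits.tsv}), the signed summary matrix (\code{table3.tsv}),
#' hit intervals as BED, and a stage log.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List with \code{hits} and \code{summary}, invisibly.
#' @export
run_triplex <- function(config) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  mirnas <- read_fasta(config$paths$mirna_fasta, "RNA")
  promoters <- load_promoters(config)
  code <- default_triplet_code()
  all_hits <- list()
  for (m in mirnas) {
    for (p in promoters) {
      h <- find_triplex_sites(m, p, code,
                              config$triplex$score_threshold,
                              config$triplex$energy_threshold)
      if (nrow(h)) {
        bg <- triplex_background(m, p, code, n = config$triplex$background_n,
                                 seed = config$seed)
        h <- grade_hits(h, bg)
        all_hits[[length(all_hits) + 1L]] <- h
      }
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    find_triplex_sites(rna_seq("x", "A"), dna_seq("y", "A"), code)
  hits$gene_id <- promoter_gene(hits$gene_id)
  write.table(hits, file.path(config$output_dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary <- summarize_matrix(hits, names(mirnas),
                              promoter_gene(names(promoters)))
  mat <- render_triplex_matrix(summary)
  tab3 <- data.frame(MicroRNA = rownames(mat), mat, check.names = FALSE)
  write.table(tab3, file.path(config$output_dir, "table3.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bed <- if (nrow(hits)) {
    sprintf("%s\t%d\t%d\t%s\t%.0f\t%s", hits$gene_id, hits$target_start,
            hits$target_end, hits$mirna_id, hits$hit_score,
            ifelse(hits$orientation == "direct", "+", "-"))
  } else character(0)
  writeLines(bed, file.path(config$output_dir, "hits.bed"))
  write_stage_log(config, "triplex", config$triplex,
                  file.path(config$output_dir, "triplex_log.txt"))
  invisible(list(hits = hits, summary = summary))
}

#' Run the event-network stage
#'
#' Loads the somatic-event table and interaction edge list, writes the
#' Cytoscape SIF and GraphML exports, the per-gene stage table
#' (\code{stages.tsv}), the interaction composition (\code{composition.tsv},
#' two decimals) and a stage log.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List with \code{network} and \code{composition}, invisibly.
#' @export
run_events <- function(config) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$paths$event_table))
    stop("no event_table configured", call. = FALSE)
  network <- load_event_table(config$paths$event_table)
  export_network(network, file.path(config$output_dir, "events.sif"), "SIF")
  export_network(network, file.path(config$output_dir, "events.graphml"),
                 "GraphML")
  write.table(network$nodes, file.path(config$output_dir, "stages.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- NULL
  if (!is.null(config$paths$edge_list)) {
    edges <- load_edge_list(config$paths$edge_list)
    comp <- edge_composition(edges)
    write.table(data.frame(kind = names(comp),
                           percent = sprintf("%.2f", comp)),
                file.path(config$output_dir, "composition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_stage_log(config, "events", list(),
                  file.path(config$output_dir, "events_log.txt"))
  invisible(list(network = network, composition = comp))
}

#' Run the whole pipeline
#'
#' Executes fold, cpg, triplex and (when configured) events, then writes a
#' per-microRNA cross-reference (\code{summary.tsv}): structure count,
#' stability rank, triplex partner genes and the partners' disease stages.
#' A microRNA with a retained hit on a gene whose stage set contains
#' "early" is flagged \code{early-detection candidate}; one with no
#' retained hits is flagged \code{no triplex evidence}.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List with all stage results plus the summary data.frame,
#'   invisibly.
#' @export
run_all <- function(config) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  folds <- run_fold(config)
  cpg <- run_cpg(config)
  tri <- run_triplex(config)
  ev <- if (!is.null(config$paths$event_table)) run_events(config) else NULL
  rank <- stability_rank(folds)
  summary <- do.call(rbind, lapply(names(folds), function(m) {
    f <- folds[[m]]
    h <- tri$hits[tri$hits$mirna_id == m, , drop = FALSE]
    partners <- sort(unique(h$gene_id), method = "radix")
    pstages <- character(0)
    if (!is.null(ev)) {
      for (g in partners) {
        if (g %in% ev$network$nodes$gene)
          pstages <- c(pstages, stage_of(g, ev$network$nodes))
      }
    }
    pstages <- sort(unique(pstages), method = "radix")
    flag <- if (!nrow(h)) "no triplex evidence"
            else if ("early" %in% pstages) "early-detection candidate"
            else "triplex evidence, no early-stage link"
    data.frame(mirna = m, length = f$sequence$length,
               mfe = sprintf("%.2f", f$mfe),
               structure_count = f$structure_count,
               stability_rank = match(m, rank),
               n_triplex_hits = nrow(h),
               partner_genes = paste(partners, collapse = ";"),
               partner_stages = paste(pstages, collapse = ";"),
               flag = flag, stringsAsFactors = FALSE)
  }))
  write.table(summary, file.path(config$output_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_log(config, "run_all",
                  list(stages = "fold,cpg,triplex,events"),
                  file.path(config$output_dir, "run_log.txt"))
  invisible(list(folds = folds, cpg = cpg, triplex = tri, events = ev,
                 summary = summary))
}
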