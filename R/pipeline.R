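#' replimir: miRNA seed-site scanning and small RNA-seq analysis of
#' T-cell replicative aging
#'
#' Tools to study how replicative age (cumulative population doublings)
#' of T-cell clones relates to CD28 loss through specific miRNAs:
#' seed-match scanning and reporter mutagenesis design on 3'UTR
#' sequences, CPM normalisation / detection filtering / exact
#' Mann-Whitney differential expression for mature-miRNA count matrices,
#' qPCR and dual-luciferase validation statistics, and a synthetic-data
#' generator with ground truth.
#'
#' @keywords internal
"_PACKAGE"

PIPELINE_STAGES <- c("simulate", "scan", "mutate", "de", "qpcr", "luciferase")

RUN_CONFIG_KEYS <- c(
  "stages", "out_dir", "rng_seed",
  "mirna_fasta", "utr_fasta", "counts_tsv", "meta_tsv",
  "qpcr_tsv", "luciferase_tsv",
  "alpha", "min_count", "min_samples", "fc_min", "expr_min_cpm",
  "pseudo_mean", "luciferase_control")

#' Build and validate a pipeline run configuration
#'
#' A run configuration is a flat key-value list (typically read from a
#' YAML file) naming the stages to run, the input paths, the output
#' directory and every analysis threshold. Unknown keys are rejected so
#' that a typo cannot silently fall back to a default.
#'
#' @param ... configuration entries, or a single list.
#' @return validated list of class `run_config` with defaults filled in.
#' @export
run_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args))) {
    args <- args[[1]]
  }
  unknown <- setdiff(names(args), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(stages = "de", out_dir = "replimir_out", rng_seed = 1L,
                   alpha = 0.05, min_count = 10, min_samples = 3,
                   fc_min = 1.5, expr_min_cpm = NULL, pseudo_mean = 0.5,
                   luciferase_control = "control")
  cfg <- utils::modifyList(defaults, args)
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of key-value pairs (see [run_config()]).
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

config_fingerprint <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

input_checksums <- function(cfg) {
  keys <- c("mirna_fasta", "utr_fasta", "counts_tsv", "meta_tsv",
            "qpcr_tsv", "luciferase_tsv")
  paths <- unlist(cfg[intersect(keys, names(cfg))])
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order (`simulate` first,
#' then `scan`/`mutate` and `de`/`qpcr`/`luciferase`, which are mutually
#' independent), writing every stage output plus a run manifest to the
#' configured output directory. The manifest records the package
#' version, a fingerprint of the configuration, the checksums of all
#' inputs, and every threshold in force; it is written even when a stage
#' fails. Re-running with identical config and inputs reproduces
#' identical outputs.
#'
#' @param cfg a [run_config] (or list coercible to one).
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "replimir",
    version = as.character(utils::packageVersion("replimir")),
    config = unclass(cfg),
    config_md5 = config_fingerprint(cfg),
    inputs_md5 = input_checksums(cfg),
    stages_run = character(),
    status = "started")
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(write_manifest())
  stages <- intersect(PIPELINE_STAGES, cfg$stages)  # dependency order
  for (st in stages) {
    ok <- tryCatch({
      switch(st,
             simulate = stage_simulate(cfg, out),
             scan = stage_scan(cfg, out),
             mutate = stage_mutate(cfg, out),
             de = stage_de(cfg, out),
             qpcr = stage_qpcr(cfg, out),
             luciferase = stage_luciferase(cfg, out))
      TRUE
    }, error = function(e) {
      manifest$status <<- paste0("failed at stage '", st, "': ",
                                 conditionMessage(e))
      FALSE
    })
    if (!ok) {
      write_manifest()
      stop(manifest$status, call. = FALSE)
    }
    manifest$stages_run <- c(manifest$stages_run, st)
  }
  manifest$status <- "ok"
  invisible(manifest)
}

stage_simulate <- function(cfg, out) {
  sim <- gen_counts(sim_config(rng_seed = cfg$rng_seed))
  df <- data.frame(mirna_id = rownames(sim$counts), sim$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, file.path(out, "sim_counts.tsv"))
  write_tsv(sim$meta, file.path(out, "sim_meta.tsv"))
  jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                       dataframe = "columns", digits = NA)
  # downstream stages default to the simulated data when no input given
  invisible(NULL)
}

resolve_input <- function(cfg, key, out, sim_name) {
  if (!is.null(cfg[[key]])) {
    if (!file.exists(cfg[[key]])) {
      stop("input '", key, "' not found: ", cfg[[key]])
    }
    return(cfg[[key]])
  }
  sim_path <- file.path(out, sim_name)
  if ("simulate" %in% cfg$stages && file.exists(sim_path)) return(sim_path)
  stop("stage needs '", key, "' (or a prior simulate stage)")
}

stage_scan <- function(cfg, out) {
  mirnas <- read_mirna_fasta(resolve_input(cfg, "mirna_fasta", out, NA))
  utrs <- read_utr_fasta(resolve_input(cfg, "utr_fasta", out, NA))
  sites <- scan_panel(mirnas, utrs)
  write_tsv(sites, file.path(out, "sites.tsv"))
  write_tsv(sites_to_bed(sites), file.path(out, "sites.bed"))
  counts <- site_counts(sites)
  write_tsv(data.frame(mirna = names(counts), n_sites = unname(counts)),
            file.path(out, "site_counts.tsv"))
  invisible(NULL)
}

stage_mutate <- function(cfg, out) {
  mirnas <- read_mirna_fasta(resolve_input(cfg, "mirna_fasta", out, NA))
  utrs <- read_utr_fasta(resolve_input(cfg, "utr_fasta", out, NA))
  muts <- lapply(utrs, design_mutant, panel = mirnas)
  write_utr_fasta(lapply(muts, `[[`, "mutated"),
                  file.path(out, "mutant_utrs.fasta"))
  subs <- do.call(rbind, lapply(seq_along(muts), function(i) {
    s <- muts[[i]]$substitutions
    if (nrow(s)) cbind(transcript = utrs[[i]]$transcript_id, s)
    else NULL
  }))
  if (is.null(subs)) {
    subs <- data.frame(transcript = character(), position = integer(),
                       from = character(), to = character())
  }
  write_tsv(subs, file.path(out, "substitutions.tsv"))
  invisible(NULL)
}

stage_de <- function(cfg, out) {
  counts <- read_count_matrix(resolve_input(cfg, "counts_tsv", out,
                                            "sim_counts.tsv"))
  meta <- read_sample_meta(resolve_input(cfg, "meta_tsv", out,
                                         "sim_meta.tsv"))
  filtered <- detection_filter(counts, cfg$min_count, cfg$min_samples)
  res <- run_de(filtered, meta, alpha = cfg$alpha,
                pseudo_mean = cfg$pseudo_mean)
  write_tsv(res, file.path(out, "de_results.tsv"))
  if (!is.null(cfg$expr_min_cpm)) {
    sel <- select_candidates(res, fc_min = cfg$fc_min,
                             expr_min_cpm = cfg$expr_min_cpm)
    writeLines(sel, file.path(out, "candidates.txt"))
  }
  pca <- pca_scores(cpm_normalize(filtered))
  sc <- data.frame(sample_id = rownames(pca$scores),
                   pca$scores[, seq_len(min(4L, ncol(pca$scores))),
                              drop = FALSE],
                   check.names = FALSE)
  write_tsv(sc, file.path(out, "pca_scores.tsv"))
  cl <- hcluster_order(log2(cpm_normalize(filtered) + 1))
  writeLines(cluster_newick(cl), file.path(out, "cluster_tree.nwk"))
  invisible(NULL)
}

stage_qpcr <- function(cfg, out) {
  qpcr <- utils::read.delim(resolve_input(cfg, "qpcr_tsv", out, NA),
                            stringsAsFactors = FALSE)
  write_tsv(qpcr_rel_expr(qpcr), file.path(out, "qpcr_rel_expr.tsv"))
  invisible(NULL)
}

stage_luciferase <- function(cfg, out) {
  wells <- utils::read.delim(resolve_input(cfg, "luciferase_tsv", out, NA),
                             stringsAsFactors = FALSE)
  norm <- luciferase_normalize(wells, control = cfg$luciferase_control)
  write_tsv(norm, file.path(out, "luciferase_normalized.tsv"))
  invisible(NULL)
}
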