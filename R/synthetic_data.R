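#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators, with defaults
#' emulating the study design: 6 T-cell clones sampled at low and high
#' population doublings (12 libraries), a few hundred expressed miRNAs
#' of which ten are differentially expressed at a planted log2
#' fold change of 1.5, negative-binomial counts with dispersion 0.1,
#' qPCR Ct tables anchored to a reference gene, and dual-luciferase
#' plates measured in duplicate over three independent experiments.
#' Unknown arguments are rejected.
#'
#' @param rng_seed integer seed; every generator is a pure function of
#'   its config including this seed.
#' @param n_mirnas number of simulated miRNAs.
#' @param n_samples_per_group clones per PD group (paired design: each
#'   clone appears once per group).
#' @param n_de number of planted differentially expressed miRNAs.
#' @param log2fc planted absolute log2 fold change (high vs low PD).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param mean_cpm_range range of baseline mean CPM, sampled
#'   log-uniformly.
#' @param depth_range per-sample library size range (mapped reads).
#' @param utr_length length of generated UTR backgrounds (nt).
#' @param ct_reference reference-gene Ct used in qPCR tables.
#' @param ct_noise_sd Gaussian sd added to target Ct values (cycles).
#' @param luciferase_repression multiplicative factor (0 < r <= 1)
#'   applied to WT-construct RL/FF ratios per bound mimic.
#' @param noise_cv multiplicative (lognormal) coefficient of variation
#'   of luciferase well readings.
#' @param n_experiments,n_duplicates luciferase experiments and in-plate
#'   duplicate wells.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_mirnas = 300L,
                       n_samples_per_group = 6L,
                       n_de = 10L,
                       log2fc = 1.5,
                       nb_dispersion = 0.1,
                       mean_cpm_range = c(5, 5000),
                       depth_range = c(8e5, 1.2e6),
                       utr_length = 500L,
                       ct_reference = 25,
                       ct_noise_sd = 0.25,
                       luciferase_repression = 0.7,
                       noise_cv = 0.05,
                       n_experiments = 3L,
                       n_duplicates = 2L) {
  cfg <- list(rng_seed = as.integer(rng_seed),
              n_mirnas = as.integer(n_mirnas),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_de = as.integer(n_de),
              log2fc = log2fc,
              nb_dispersion = nb_dispersion,
              mean_cpm_range = mean_cpm_range,
              depth_range = depth_range,
              utr_length = as.integer(utr_length),
              ct_reference = ct_reference,
              ct_noise_sd = ct_noise_sd,
              luciferase_repression = luciferase_repression,
              noise_cv = noise_cv,
              n_experiments = as.integer(n_experiments),
              n_duplicates = as.integer(n_duplicates))
  stopifnot(cfg$n_mirnas > 0, cfg$n_samples_per_group > 0,
            cfg$n_de >= 0, cfg$n_de <= cfg$n_mirnas,
            cfg$log2fc >= 0, cfg$nb_dispersion >= 0,
            cfg$luciferase_repression > 0, cfg$luciferase_repression <= 1,
            cfg$noise_cv >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a clone count matrix with planted PD-group effects
#'
#' Draws negative-binomial counts for `n_mirnas` miRNAs over a paired
#' design of clones each sampled at low and high PD. Baseline mean CPM
#' is log-uniform over `mean_cpm_range`; for the `n_de` planted miRNAs
#' the group means differ by a factor 2^log2fc (direction random per
#' miRNA, effect split symmetrically around the baseline). Library sizes
#' vary uniformly over `depth_range`.
#'
#' @param config a [sim_config].
#' @return list with `counts` (integer matrix), `meta` (sample
#'   metadata: `sample_id`, `clone_id`, `age_group`, `pd_value`,
#'   `pd_group`) and `truth` (per-miRNA `is_de` and signed
#'   `log2fc_high_vs_low`).
#' @export
gen_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  g <- config$n_samples_per_group
  n_samp <- 2L * g
  mirna_ids <- sprintf("sim-miR-%03d", seq_len(config$n_mirnas))
  clone_ids <- sprintf("clone%02d", seq_len(g))
  meta <- data.frame(
    sample_id = c(paste0(clone_ids, "_low"), paste0(clone_ids, "_high")),
    clone_id = rep(clone_ids, 2L),
    age_group = rep(rep_len(c("young", "old"), g), 2L),
    pd_value = c(sample(20:40, g, replace = TRUE),
                 sample(41:70, g, replace = TRUE)),
    pd_group = rep(c("low", "high"), each = g),
    stringsAsFactors = FALSE)
  base_cpm <- 10^stats::runif(config$n_mirnas,
                              log10(config$mean_cpm_range[1]),
                              log10(config$mean_cpm_range[2]))
  de_idx <- if (config$n_de > 0) sample.int(config$n_mirnas, config$n_de)
            else integer()
  signs <- integer(config$n_mirnas)
  signs[de_idx] <- sample(c(-1L, 1L), length(de_idx), replace = TRUE)
  lfc <- signs * config$log2fc
  if (config$log2fc == 0) lfc[] <- 0  # zero effect means non-DE truth
  mu_low <- base_cpm * 2^(-lfc / 2)
  mu_high <- base_cpm * 2^(lfc / 2)
  depth <- round(stats::runif(n_samp, config$depth_range[1],
                              config$depth_range[2]))
  counts <- matrix(0L, config$n_mirnas, n_samp,
                   dimnames = list(mirna_ids, meta$sample_id))
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  for (j in seq_len(n_samp)) {
    mu <- (if (meta$pd_group[j] == "low") mu_low else mu_high) /
      1e6 * depth[j]
    counts[, j] <- as.integer(if (is.finite(size)) {
      stats::rnbinom(config$n_mirnas, mu = mu, size = size)
    } else {
      stats::rpois(config$n_mirnas, lambda = mu)
    })
  }
  truth <- data.frame(mirna_id = mirna_ids,
                      is_de = seq_len(config$n_mirnas) %in% de_idx &
                        config$log2fc > 0,
                      log2fc_high_vs_low = if (config$log2fc > 0) lfc else 0,
                      baseline_cpm = base_cpm,
                      stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, truth = truth)
}

# Bases allowed as a guard flank so the planted class is realised exactly
# and not upgraded by chance: 5' guard must differ from the position-8
# complement, 3' guard from A.
guard_base <- function(exclude) {
  setdiff(c("A", "C", "G", "T"), exclude)[1]
}

#' Generate a UTR with planted seed sites and clean background
#'
#' Builds a random background sequence and splices in seed-match sites
#' of the requested classes, with guard flanks that pin each site to
#' exactly its planted class. The whole sequence is rejection-sampled:
#' it is re-scanned with the full panel and regenerated until the only
#' panel sites present are the planted ones, so the emitted truth list
#' is complete by construction.
#'
#' @param panel list of [mature_mirna] (the scan panel; rejection applies
#'   to every panel member, planted or not).
#' @param planted data.frame with columns `mirna` (name, must be in the
#'   panel), `class` (site class) and `pos` (approximate local start).
#'   May have zero rows.
#' @param config a [sim_config] (uses `utr_length`, `rng_seed`).
#' @param transcript_id id of the generated region.
#' @param offset transcript offset of the region.
#' @param max_tries rejection-sampling budget (default 500).
#' @return list with `utr` (a [utr_region]) and `truth` (data.frame of
#'   planted sites with realised transcript coordinates).
#' @export
gen_utr <- function(panel, planted, config, transcript_id = "synthUTR",
                    offset = 1L, max_tries = 500L) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(panel, "mature_mirna")) panel <- list(panel)
  set.seed(config$rng_seed)
  len <- config$utr_length
  nms <- vapply(panel, `[[`, character(1), "name")
  if (nrow(planted) > 0 && !all(planted$mirna %in% nms)) {
    stop("planted sites reference miRNAs absent from the panel")
  }
  blocks <- lapply(seq_len(nrow(planted)), function(i) {
    m <- panel[[match(planted$mirna[i], nms)]]
    strs <- seed_match_strings(m)
    cls <- planted$class[i]
    if (!cls %in% names(strs)) stop("unknown site class: ", cls)
    site <- strs[[cls]]
    m8 <- substr(strs[["7mer-m8"]], 1L, 1L)
    # guards: left guard needed unless the site itself starts at the m8
    # base (8mer/7mer-m8); right guard needed unless it ends in the A1
    # adenine (8mer/7mer-A1)
    left <- if (cls %in% c("8mer", "7mer-m8")) "" else guard_base(m8)
    right <- if (cls %in% c("8mer", "7mer-A1")) "" else "C"
    list(seq = paste0(left, site, right),
         site_offset = nchar(left), site_len = nchar(site),
         mirna = planted$mirna[i], class = cls, pos = planted$pos[i])
  })
  for (try in seq_len(max_tries)) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    placed <- list()
    occupied <- rep(FALSE, len)
    ok <- TRUE
    for (b in blocks) {
      w <- nchar(b$seq)
      start <- min(max(1L, as.integer(b$pos)), len - w + 1L)
      if (any(occupied[start:(start + w - 1L)])) { ok <- FALSE; break }
      s[start:(start + w - 1L)] <- strsplit(b$seq, "")[[1]]
      occupied[start:(start + w - 1L)] <- TRUE
      placed[[length(placed) + 1L]] <- data.frame(
        mirna = b$mirna, class = b$class,
        start = start + b$site_offset + offset - 1L,
        end = start + b$site_offset + b$site_len - 1L + offset - 1L,
        stringsAsFactors = FALSE)
    }
    if (!ok) next
    utr <- utr_region(transcript_id, paste(s, collapse = ""), offset)
    truth <- if (length(placed)) do.call(rbind, placed)
             else data.frame(mirna = character(), class = character(),
                             start = integer(), end = integer(),
                             stringsAsFactors = FALSE)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    found <- scan_panel(panel, utr)
    found <- found[order(found$start), , drop = FALSE]
    if (nrow(found) == nrow(truth) &&
        all(found$start == truth$start) && all(found$end == truth$end) &&
        all(found$class == truth$class) && all(found$mirna == truth$mirna)) {
      return(list(utr = utr, truth = truth))
    }
  }
  stop("could not generate a clean UTR in ", max_tries,
       " attempts (infeasible packing or length too short)")
}

#' Generate a qPCR Ct table from planted expression ratios
#'
#' Each planted relative expression e (target vs reference) is realised
#' as `ct_target = ct_reference - log2(e) + N(0, ct_noise_sd)`, so the
#' 2^-dCt method recovers the planted ratio in expectation.
#'
#' @param ratios data.frame with columns `sample_id`, `target`,
#'   `expression` (planted 2^-dCt value, > 0).
#' @param config a [sim_config] (uses `ct_reference`, `ct_noise_sd`,
#'   `rng_seed`).
#' @return data.frame with `sample_id`, `target`, `ct_target`,
#'   `ct_reference`, plus the planted `expression` as truth.
#' @export
gen_ct <- function(ratios, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(ratios$expression <= 0)) stop("planted expression must be positive")
  set.seed(config$rng_seed)
  noise <- stats::rnorm(nrow(ratios), 0, config$ct_noise_sd)
  data.frame(sample_id = ratios$sample_id,
             target = ratios$target,
             ct_target = config$ct_reference - log2(ratios$expression) + noise,
             ct_reference = config$ct_reference,
             expression = ratios$expression,
             stringsAsFactors = FALSE)
}

#' Generate a dual-luciferase plate table with planted repression
#'
#' Emulates the reporter design: per experiment a lognormal baseline
#' RL/FF ratio; mimic conditions multiply the ratio of wild-type
#' constructs by the planted repression factor while mutant constructs
#' are unaffected; every (construct, condition) is measured in
#' `n_duplicates` wells per experiment with multiplicative lognormal
#' noise of coefficient of variation `noise_cv`.
#'
#' @param config a [sim_config].
#' @param constructs character vector; names ending in `-mut` are
#'   treated as mutants.
#' @param conditions mimic condition labels (besides `"control"`).
#' @param repression named vector of per-condition repression factors on
#'   wild-type constructs; defaults to `config$luciferase_repression`
#'   for every condition.
#' @return list with `wells` (plate table for
#'   [luciferase_normalize()]) and `truth` (per-condition planted
#'   repression).
#' @export
gen_luciferase <- function(config,
                           constructs = c("UTR1-WT", "UTR1-mut"),
                           conditions = "mimic",
                           repression = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(repression)) {
    repression <- stats::setNames(rep(config$luciferase_repression,
                                      length(conditions)), conditions)
  }
  set.seed(config$rng_seed)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  rows <- list()
  for (e in seq_len(config$n_experiments)) {
    base_ratio <- stats::rlnorm(1, meanlog = log(2), sdlog = 0.15)
    for (con in constructs) {
      is_mut <- grepl("-mut$", con)
      for (cond in c("control", conditions)) {
        fac <- if (cond == "control" || is_mut) 1 else repression[[cond]]
        for (rep_i in seq_len(config$n_duplicates)) {
          firefly <- stats::rlnorm(1, meanlog = log(1e6), sdlog = sdlog)
          noise <- if (config$noise_cv > 0) {
            stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
          } else 1
          renilla <- firefly * base_ratio * fac * noise
          rows[[length(rows) + 1L]] <- data.frame(
            experiment = paste0("exp", e), construct = con,
            condition = cond, renilla = renilla, firefly = firefly,
            replicate = rep_i, stringsAsFactors = FALSE)
        }
      }
    }
  }
  wells <- do.call(rbind, rows)
  truth <- data.frame(condition = conditions,
                      repression = unname(repression[conditions]),
                      stringsAsFactors = FALSE)
  list(wells = wells, truth = truth)
}
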