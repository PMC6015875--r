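#' Relative expression by the 2^-dCt method
#'
#' `value = 2^-(ct_target - ct_reference)`, the standard single-reference
#' relative quantification (reference here: RNU44). Vectorised.
#'
#' @param ct_target,ct_reference cycle-threshold values (finite,
#'   positive).
#' @return relative expression value(s); 1 exactly when the Ct values are
#'   equal.
#' @examples
#' rel_expr(25, 22)  # 2^-3 = 0.125
#' @export
rel_expr <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  if (any(ct_target <= 0) || any(ct_reference <= 0)) {
    stop("Ct values must be positive")
  }
  2^-(ct_target - ct_reference)
}

#' Compute 2^-dCt values for a long-format qPCR table
#'
#' The table holds one row per (sample, target) with the target Ct and
#' the reference-gene Ct measured in the same sample.
#'
#' @param qpcr data.frame with columns `sample_id`, `target`,
#'   `ct_target`, `ct_reference`.
#' @return the table with an added `rel_expr` column.
#' @export
qpcr_rel_expr <- function(qpcr) {
  need <- c("sample_id", "target", "ct_target", "ct_reference")
  miss <- setdiff(need, names(qpcr))
  if (length(miss)) stop("qPCR table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(qpcr$ct_reference)) {
    stop("missing reference Ct for sample(s): ",
         paste(unique(qpcr$sample_id[is.na(qpcr$ct_reference)]),
               collapse = ", "))
  }
  qpcr$rel_expr <- rel_expr(qpcr$ct_target, qpcr$ct_reference)
  qpcr
}

#' Spearman rank correlation with exact permutation p for small n
#'
#' rho is the Pearson correlation of mid-ranks. For n <= `exact_max_n`
#' the two-sided p-value is exact: all n! permutations of one rank vector
#' are enumerated and p is the fraction with |rho| at least the observed
#' |rho|. Larger n uses the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_max_n largest n enumerated exactly (default 8).
#' @return list with `rho`, `p` and `method`.
#' @export
spearman_corr <- function(x, y, exact_max_n = 8L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    list(rho = rho, p = p, method = "permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    list(rho = rho, p = p, method = "t_approx")
  }
}

# All n! permutations of 1..n as rows (n <= 8: at most 40320 rows).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Exact Wilcoxon signed-rank test
#'
#' Zero differences are dropped; W is the sum of signed mid-ranks of the
#' absolute differences. For m <= `exact_max_m` nonzero differences the
#' two-sided p is exact over all 2^m sign assignments (ties kept as
#' observed mid-ranks); beyond that a normal approximation with tie
#' correction is used.
#'
#' @param a,b paired measurement vectors, or give `d` directly.
#' @param d differences (overrides `a`/`b`).
#' @param exact_max_m enumeration cutoff (default 20).
#' @return list with `w_statistic` (signed-rank sum), `p_exact`, `m`
#'   (nonzero differences used) and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, d = NULL, exact_max_m = 20L) {
  if (is.null(d)) {
    if (length(a) != length(b)) stop("paired vectors must have equal length")
    d <- a - b
  }
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) stop("degenerate input: all differences are zero")
  r <- rank(abs(d))
  w <- sum(sign(d) * r)
  if (m <= exact_max_m) {
    # all sign assignments: W = sum(eps_i * r_i), eps in {-1, +1}^m
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
    ws <- as.vector(signs %*% r)
    p <- mean(abs(ws) >= abs(w) - 1e-9)
    list(w_statistic = w, p_exact = p, m = m, method = "enumeration")
  } else {
    sigma2 <- sum(r^2)  # Var(W) under random signs, mid-ranks kept
    z <- w / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(w_statistic = w, p_exact = p, m = m, method = "normal_approx")
  }
}

#' Friedman test with exact permutation p for small designs
#'
#' Values are mid-ranked within each block; the statistic is
#' `chi2_f = 12/(n*k*(k+1)) * sum(R_j^2) - 3*n*(k+1)` over treatment rank
#' sums R_j. When the number of within-block orderings (k!)^n does not
#' exceed `exact_limit`, the p-value is exact by enumerating every
#' configuration of within-block permutations of the observed values;
#' beyond that the chi-square approximation on k-1 df is used.
#'
#' @param x numeric matrix, blocks x treatments, complete.
#' @param exact_limit maximum number of enumerated configurations
#'   (default 1e6).
#' @return list with `chi2_f`, `p`, `n` (blocks), `k` (treatments) and
#'   `method`.
#' @export
friedman_test <- function(x, exact_limit = 1e6) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("incomplete matrix: Friedman test needs all cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 blocks and >= 2 treatments")
  ranks <- t(apply(x, 1, rank))
  stat <- function(rk) {
    rj <- colSums(rk)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  chi2_obs <- stat(ranks)
  n_config <- factorial(k)^n
  if (n_config <= exact_limit) {
    perms <- all_permutations(k)
    np <- nrow(perms)
    # rank sums over all (k!)^n within-block permutation choices, built
    # block by block as a distribution over rank-sum vectors
    configs <- matrix(0, 1, k)
    counts <- 1
    for (b in seq_len(n)) {
      block_ranks <- perms
      block_ranks[] <- ranks[b, ][perms]  # permuted mid-ranks of block b
      idx <- rep(seq_len(nrow(configs)), each = np)
      configs <- configs[idx, , drop = FALSE] +
        block_ranks[rep(seq_len(np), times = length(counts)), , drop = FALSE]
      counts <- rep(counts, each = np)
      # collapse duplicate rank-sum vectors to keep the table small
      key <- apply(configs, 1, paste, collapse = ",")
      agg <- rowsum(counts, key)
      configs <- do.call(rbind,
                         lapply(strsplit(rownames(agg), ","), as.numeric))
      counts <- as.vector(agg)
    }
    chis <- 12 / (n * k * (k + 1)) * rowSums(configs^2) - 3 * n * (k + 1)
    p <- sum(counts[chis >= chi2_obs - 1e-9]) / sum(counts)
    list(chi2_f = chi2_obs, p = p, n = n, k = k, method = "enumeration")
  } else {
    p <- stats::pchisq(chi2_obs, df = k - 1, lower.tail = FALSE)
    list(chi2_f = chi2_obs, p = p, n = n, k = k, method = "chisq_approx")
  }
}

#' Post hoc comparisons against a baseline treatment
#'
#' After a Friedman test, compares every other treatment to the baseline
#' (e.g. day 0 of a cytokine time course) with the exact Wilcoxon
#' signed-rank test on the blocks, multiplying p-values by the number of
#' comparisons (Bonferroni bound, capped at 1). This is a conservative
#' rank-based stand-in for a Dunnett-style many-to-one procedure.
#'
#' @param x blocks x treatments matrix with treatment column names.
#' @param baseline name of the baseline column.
#' @return data.frame with `treatment`, `w_statistic`, `p_raw`,
#'   `p_adjusted`.
#' @export
posthoc_vs_baseline <- function(x, baseline) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || !(baseline %in% colnames(x))) {
    stop("baseline treatment '", baseline, "' not found")
  }
  others <- setdiff(colnames(x), baseline)
  m <- length(others)
  rows <- lapply(others, function(tr) {
    # a treatment identical to baseline carries no evidence: p = 1
    if (all(x[, tr] == x[, baseline])) {
      return(data.frame(treatment = tr, w_statistic = 0, p_raw = 1,
                        p_adjusted = 1, stringsAsFactors = FALSE))
    }
    res <- wilcoxon_signed_rank(x[, tr], x[, baseline])
    data.frame(treatment = tr, w_statistic = res$w_statistic,
               p_raw = res$p_exact,
               p_adjusted = min(1, res$p_exact * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test on matched measurements
#'
#' @param a,b paired vectors (length >= 2; nonzero variance of the
#'   differences).
#' @return list with `t`, `p` (two-sided, n-1 df) and `n`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  if (length(d) < 2L) stop("need at least two pairs")
  if (stats::var(d) == 0) stop("degenerate input: zero variance of differences")
  res <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(res$statistic), p = res$p.value, n = length(d))
}

#' Normalise dual-luciferase plate readings
#'
#' Per well the raw ratio is Renilla / Firefly (the Renilla construct
#' carries the tested UTR; Firefly is the in-well transfection control).
#' Duplicate wells are averaged within each experiment, then every
#' condition is divided by the same experiment's control-condition
#' average, so the control maps to exactly 1.
#'
#' @param wells data.frame with columns `experiment`, `construct`,
#'   `condition`, `renilla`, `firefly`, `replicate`.
#' @param control label of the control condition (default `"control"`).
#' @return data.frame with one row per (experiment, construct,
#'   condition): `ratio_raw` (duplicate-averaged RL/FF) and `value`
#'   (control-anchored normalised ratio).
#' @export
luciferase_normalize <- function(wells, control = "control") {
  need <- c("experiment", "construct", "condition", "renilla", "firefly")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop("luciferase table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(wells$firefly <= 0)) {
    stop("nonpositive Firefly reading(s): transfection control failed")
  }
  wells$ratio <- wells$renilla / wells$firefly
  agg <- stats::aggregate(ratio ~ experiment + construct + condition,
                          data = wells, FUN = mean)
  names(agg)[names(agg) == "ratio"] <- "ratio_raw"
  ctrl <- agg[agg$condition == control, c("experiment", "construct", "ratio_raw")]
  names(ctrl)[3] <- "ctrl_ratio"
  out <- merge(agg, ctrl, by = c("experiment", "construct"), all.x = TRUE)
  if (anyNA(out$ctrl_ratio)) {
    bad <- unique(paste(out$experiment[is.na(out$ctrl_ratio)],
                        out$construct[is.na(out$ctrl_ratio)]))
    stop("missing control condition for: ", paste(bad, collapse = "; "))
  }
  out$value <- out$ratio_raw / out$ctrl_ratio
  out$ctrl_ratio <- NULL
  out[order(out$experiment, out$construct, out$condition), , drop = FALSE]
}

#' Wild-type vs seed-mutant relative reporter ratio
#'
#' For matched construct regions and mimic conditions, divides the
#' normalised RL/FF ratio of the wild-type UTR construct by that of the
#' same region with mutated seed sites. Values below 1 indicate
#' repression acting through the mutated sites.
#'
#' @param norm data.frame from [luciferase_normalize()].
#' @param wt,mut construct labels of the wild-type and mutant region.
#' @return data.frame with one row per (experiment, condition):
#'   `value_wt`, `value_mut`, `relative` (= wt / mut).
#' @export
wt_vs_mut_relative <- function(norm, wt, mut) {
  a <- norm[norm$construct == wt, c("experiment", "condition", "value")]
  b <- norm[norm$construct == mut, c("experiment", "condition", "value")]
  names(a)[3] <- "value_wt"; names(b)[3] <- "value_mut"
  out <- merge(a, b, by = c("experiment", "condition"))
  if (nrow(out) < max(nrow(a), nrow(b))) {
    stop("condition labels of '", wt, "' and '", mut, "' do not fully match")
  }
  out$relative <- out$value_wt / out$value_mut
  out[order(out$experiment, out$condition), , drop = FALSE]
}
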