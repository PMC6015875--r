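validate_count_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must have miRNA row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate miRNA ids in count matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in count matrix")
  if (anyNA(m) || any(m < 0)) stop("counts must be nonnegative and non-missing")
  invisible(m)
}

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "clone_id", "age_group", "pd_value", "pd_group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(meta$pd_group %in% c("low", "high"))) {
    stop("pd_group must be 'low' or 'high'")
  }
  if (!all(meta$age_group %in% c("young", "old"))) {
    stop("age_group must be 'young' or 'old'")
  }
  invisible(meta)
}

#' Counts-per-million normalisation
#'
#' Scales each sample (column) so mapped reads sum to one million:
#' `cpm = count / column_total * 1e6`.
#'
#' @param counts nonnegative count matrix, miRNAs x samples.
#' @return numeric matrix of the same shape; every column sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  totals <- colSums(counts)
  zero <- totals <= 0
  if (any(zero)) {
    stop("cannot CPM-normalize sample(s) with zero total counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Detection filter on raw counts
#'
#' Retains miRNAs observed above a count threshold in enough samples; the
#' study design keeps miRNAs with a read count strictly greater than 10
#' in at least 3 of 12 samples. The filter operates on raw counts (the
#' threshold is a read count, not a CPM). Row order is preserved.
#'
#' @param counts raw count matrix.
#' @param min_count exclusive count threshold (default 10).
#' @param min_samples minimum number of qualifying samples (default 3).
#' @return the retained sub-matrix.
#' @export
detection_filter <- function(counts, min_count = 10, min_samples = 3) {
  if (min_samples > ncol(counts)) {
    stop("min_samples exceeds the number of samples")
  }
  keep <- rowSums(counts > min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

# Mid-ranks U statistic for group x against group y.
u_from_ranks <- function(r_pooled, idx_x, nx) {
  sum(r_pooled[idx_x]) - nx * (nx + 1) / 2
}

#' Exact two-sided Mann-Whitney U test
#'
#' U is computed from mid-ranks of the pooled sample. For small samples
#' (nx + ny <= `exact_max_n`) the two-sided p-value is exact by
#' enumeration of all choose(nx+ny, nx) group assignments of the observed
#' values — ties are handled by enumerating over the observed multiset —
#' with p the fraction of assignments whose deviation |U - nx*ny/2| is at
#' least the observed deviation. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param exact_max_n largest pooled size for which full enumeration is
#'   used (default 14).
#' @return list with `u_statistic` (for `x`), `p_exact`, and `method`
#'   ("enumeration" or "normal_approx").
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(x, y, exact_max_n = 14L) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- u_from_ranks(r, seq_len(nx), nx)
  mu <- nx * ny / 2
  if (n <= exact_max_n) {
    combos <- utils::combn(n, nx)
    dev_obs <- abs(u_obs - mu)
    devs <- abs(colSums(matrix(r[combos], nrow = nx)) -
                  nx * (nx + 1) / 2 - mu)
    p <- mean(devs >= dev_obs - 1e-9)
    list(u_statistic = u_obs, p_exact = p, method = "enumeration")
  } else {
    ties <- table(r)
    sigma2 <- (nx * ny / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u_statistic = u_obs, p_exact = 1,
                                 method = "normal_approx"))
    z <- u_obs - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(u_statistic = u_obs, p_exact = p, method = "normal_approx")
  }
}

#' Direction-agnostic fold change between two group means
#'
#' @param mean_a,mean_b group means on the CPM scale.
#' @param pseudo_mean value substituted for a zero mean so the ratio is
#'   defined (default 0.5 CPM).
#' @return list with `magnitude` (>= 1) and `direction`
#'   (`"up_in_first"`, `"up_in_second"` or `"none"`).
#' @export
fold_change <- function(mean_a, mean_b, pseudo_mean = 0.5) {
  if (mean_a < 0 || mean_b < 0) stop("means must be nonnegative")
  if (mean_a == 0 && mean_b == 0) {
    return(list(magnitude = 1, direction = "none"))
  }
  a <- if (mean_a == 0) pseudo_mean else mean_a
  b <- if (mean_b == 0) pseudo_mean else mean_b
  if (a == b) return(list(magnitude = 1, direction = "none"))
  if (a > b) list(magnitude = a / b, direction = "up_in_first")
  else list(magnitude = b / a, direction = "up_in_second")
}

#' Differential expression between low- and high-PD groups
#'
#' Runs the exact Mann-Whitney test per miRNA on CPM values, comparing
#' the `pd_group == "low"` against `pd_group == "high"` samples, and
#' derives group means and fold changes. Expects a detection-filtered
#' raw count matrix; CPM normalisation happens internally.
#'
#' @param counts detection-filtered raw count matrix.
#' @param meta sample metadata (see [read_sample_meta()]); every matrix
#'   column must be present in `meta$sample_id`.
#' @param alpha two-sided significance level (default 0.05).
#' @param pseudo_mean zero-mean replacement for fold changes.
#' @return data.frame with one row per miRNA: `mirna_id`, `u_statistic`,
#'   `p_exact`, `mean_cpm_low`, `mean_cpm_high`, `fold_change`,
#'   `direction` (`up_in_high`/`down_in_high`/`none`), `significant`;
#'   sorted by `p_exact` then decreasing fold change.
#' @export
run_de <- function(counts, meta, alpha = 0.05, pseudo_mean = 0.5) {
  validate_count_matrix(counts)
  validate_sample_meta(meta)
  miss <- setdiff(colnames(counts), meta$sample_id)
  if (length(miss)) stop("samples missing from metadata: ",
                         paste(miss, collapse = ", "))
  grp <- meta$pd_group[match(colnames(counts), meta$sample_id)]
  low <- which(grp == "low"); high <- which(grp == "high")
  if (length(low) < 1L || length(high) < 1L) {
    stop("both PD groups must contain at least one sample")
  }
  cpm <- cpm_normalize(counts)
  rows <- lapply(seq_len(nrow(cpm)), function(i) {
    v <- cpm[i, ]
    mw <- mann_whitney_exact(v[low], v[high])
    m_lo <- mean(v[low]); m_hi <- mean(v[high])
    fc <- fold_change(m_hi, m_lo, pseudo_mean = pseudo_mean)
    dir <- switch(fc$direction,
                  up_in_first = "up_in_high",
                  up_in_second = "down_in_high",
                  "none")
    data.frame(mirna_id = rownames(cpm)[i],
               u_statistic = mw$u_statistic, p_exact = mw$p_exact,
               mean_cpm_low = m_lo, mean_cpm_high = m_hi,
               fold_change = fc$magnitude, direction = dir,
               significant = mw$p_exact < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_exact, -out$fold_change), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Select validation candidates from DE results
#'
#' Keeps significant miRNAs with a fold change above `fc_min` and a group
#' mean CPM (larger of the two) of at least `expr_min_cpm`. The
#' expression cut-off has no default: "highly expressed" is a
#' study-specific choice and must be stated explicitly.
#'
#' @param results data.frame from [run_de()].
#' @param fc_min exclusive fold-change threshold (default 1.5).
#' @param expr_min_cpm minimum of max(group mean CPM); required.
#' @return character vector of selected miRNA ids.
#' @export
select_candidates <- function(results, fc_min = 1.5, expr_min_cpm) {
  if (missing(expr_min_cpm)) {
    stop("expr_min_cpm has no default and must be supplied")
  }
  keep <- results$significant &
    results$fold_change > fc_min &
    pmax(results$mean_cpm_low, results$mean_cpm_high) >= expr_min_cpm
  results$mirna_id[keep]
}

#' Principal-component scores of the samples
#'
#' Computes PCA of the samples on log2(CPM + 1), centered per miRNA and
#' unscaled. Axis signs are fixed deterministically by making each axis's
#' largest-magnitude loading positive.
#'
#' @param cpm CPM matrix (miRNAs x samples).
#' @param log_transform apply log2(x + 1) first (default TRUE; set FALSE
#'   if the matrix is already on a suitable scale).
#' @return list with `scores` (samples x components), `loadings`
#'   (miRNAs x components) and `var_explained` (proportions).
#' @export
pca_scores <- function(cpm, log_transform = TRUE) {
  if (ncol(cpm) < 2L) stop("PCA needs at least two samples")
  x <- if (log_transform) log2(cpm + 1) else cpm
  if (all(apply(x, 1, stats::var) == 0)) {
    stop("degenerate input: all miRNAs are constant across samples")
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Average-linkage clustering on correlation distance
#'
#' Agglomerates the matrix columns (samples) under the distance
#' 1 - Pearson correlation with average linkage. The merge order is fully
#' deterministic: equal-distance candidate merges are broken by the
#' smallest original item index, and the leaf ordering places each
#' merge's lower-index subtree first.
#'
#' @param x numeric matrix; columns are the items to cluster.
#' @return list with `merge` (hclust-style merge matrix), `height`
#'   (merge distances), `order` (leaf order, item indices), `labels`.
#' @export
hcluster_order <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least two items to cluster")
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0)) {
    stop("correlation distance undefined for zero-variance item(s): ",
         paste(colnames(x)[vars == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(x)
  # active cluster bookkeeping: members, hclust code, min original index
  clusters <- lapply(seq_len(n), function(i) {
    list(members = i, code = -i, minidx = i, leaves = i)
  })
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  avg_dist <- function(a, b) {
    mean(d[a$members, b$members])
  }
  for (step in seq_len(n - 1L)) {
    best <- NULL
    k <- length(clusters)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- avg_dist(clusters[[i]], clusters[[j]])
      key <- c(dij, min(clusters[[i]]$minidx, clusters[[j]]$minidx),
               max(clusters[[i]]$minidx, clusters[[j]]$minidx))
      if (is.null(best) || dij < best$key[1] - 1e-12 ||
          (abs(dij - best$key[1]) <= 1e-12 &&
           (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(i = i, j = j, key = key)
      }
    }
    a <- clusters[[best$i]]; b <- clusters[[best$j]]
    if (b$minidx < a$minidx) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(a$code, b$code)
    height[step] <- best$key[1]
    newc <- list(members = c(a$members, b$members), code = step,
                 minidx = min(a$minidx, b$minidx),
                 leaves = c(a$leaves, b$leaves))
    clusters <- clusters[-c(best$i, best$j)]
    clusters[[length(clusters) + 1L]] <- newc
  }
  list(merge = merge, height = height, order = clusters[[1]]$leaves,
       labels = colnames(x))
}

#' Render a merge tree as a Newick-like string
#'
#' @param cl result of [hcluster_order()].
#' @return single Newick string with merge heights as branch annotations.
#' @export
cluster_newick <- function(cl) {
  lab <- cl$labels
  if (is.null(lab)) lab <- paste0("item", seq_len(nrow(cl$merge) + 1L))
  node <- function(code) {
    if (code < 0) lab[-code]
    else {
      kids <- cl$merge[code, ]
      paste0("(", node(kids[1]), ",", node(kids[2]), "):",
             format(cl$height[code], digits = 8))
    }
  }
  paste0(node(nrow(cl$merge)), ";")
}
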