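# Independent oracles used across the suite. These deliberately use
# different formulations than the package code paths they check.

# Base-pairing oracle: complement via lookup, reversal via indexing.
oracle_revcomp <- function(s) {
  pair <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(s, "")[[1]]
  paste(pair[rev(chars)], collapse = "")
}

# Site strings derived from first principles: the UTR site read 5'->3'
# is the reverse complement of the miRNA seed (DNA space).
oracle_site_strings <- function(mirna_seq_rna) {
  dna <- chartr("U", "T", mirna_seq_rna)
  chars <- strsplit(dna, "")[[1]]
  m6 <- oracle_revcomp(paste(chars[2:7], collapse = ""))
  m7 <- oracle_revcomp(paste(chars[2:8], collapse = ""))
  c("8mer" = paste0(m7, "A"), "7mer-m8" = m7,
    "7mer-A1" = paste0(m6, "A"), "6mer" = m6)
}

# Brute-force scan: test every substring of length 6-8 against the four
# class strings, group matches by the position of their 6mer core, and
# keep the strongest class per core locus.
oracle_scan <- function(mirna_seq_rna, utr_seq, offset = 1L) {
  strs <- oracle_site_strings(mirna_seq_rna)
  n <- nchar(utr_seq)
  hits <- data.frame(core = integer(), class = character(),
                     start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (cls in names(strs)) {
      w <- nchar(strs[[cls]])
      if (i + w - 1L > n) next
      if (substr(utr_seq, i, i + w - 1L) == strs[[cls]]) {
        core <- if (cls %in% c("8mer", "7mer-m8")) i + 1L else i
        hits <- rbind(hits, data.frame(core = core, class = cls,
                                       start = i, end = i + w - 1L,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }
  prec <- c("8mer" = 1, "7mer-m8" = 2, "7mer-A1" = 3, "6mer" = 4)
  best <- do.call(rbind, lapply(split(hits, hits$core), function(h) {
    h[which.min(prec[h$class]), ]
  }))
  best <- best[order(best$start), ]
  data.frame(start = best$start + offset - 1L,
             end = best$end + offset - 1L,
             class = best$class, stringsAsFactors = FALSE,
     row.names = NULL)
}

# Exact Mann-Whitney oracle: pair-counting U over every bitmask subset.
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  u_pairs <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_pairs(x, y)
  devs <- c()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) != nx) next
    devs <- c(devs, abs(u_pairs(pooled[idx], pooled[-idx]) - nx * ny / 2))
  }
  mean(devs >= abs(u_obs - nx * ny / 2) - 1e-9)
}

# Exact signed-rank oracle over bitmask sign assignments.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0]) - sum(r[d < 0])
  ws <- vapply(0:(2^m - 1), function(mask) {
    s <- ifelse(bitwAnd(mask, 2^(0:(m - 1))) > 0, 1, -1)
    sum(s * r)
  }, numeric(1))
  mean(abs(ws) >= abs(w_obs) - 1e-9)
}

# Friedman oracle: enumerate every combination of within-block
# permutations directly via expand.grid (small k and n only).
oracle_friedman <- function(x) {
  n <- nrow(x); k <- ncol(x)
  chi2 <- function(mat) {
    rk <- t(apply(mat, 1, rank))
    rj <- colSums(rk)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  obs <- chi2(x)
  perms <- combinat_perms(k)
  grid <- expand.grid(rep(list(seq_len(nrow(perms))), n))
  stats <- apply(grid, 1, function(choice) {
    chi2(t(vapply(seq_len(n), function(b) x[b, perms[choice[b], ]],
                  numeric(k))))
  })
  list(chi2 = obs, p = mean(stats >= obs - 1e-9))
}

combinat_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(j) {
    cbind(j, sub + (sub >= j))
  }))
}

random_mirna <- function(len = sample(18:23, 1)) {
  mature_mirna(paste0("rand-", paste0(sample(letters, 6), collapse = "")),
               paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                     collapse = ""))
}

random_utr <- function(len = sample(50:500, 1), offset = 1L) {
  utr_region("randUTR",
             paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""),
             offset)
}

# Panel used throughout: mature miRNAs targeting the CD28 3'UTR.
cd28_panel <- function() {
  read_mirna_fasta(system.file("extdata", "cd28_panel.fasta",
                               package = "replimir"))
}
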