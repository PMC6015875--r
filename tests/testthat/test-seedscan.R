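mirx <- mature_mirna("miR-X", "UAGGCAACUGA")

test_that("sequence constructors normalise alphabets and reject bad input", {
  expect_equal(mature_mirna("m", "taggcaactga")$sequence, "UAGGCAACUGA")
  expect_equal(utr_region("u", "uuacgu")$sequence, "TTACGT")
  expect_error(mature_mirna("m", "UAGGCAAX"), "non-RNA")
  expect_error(mature_mirna("m", "UAGGCAA"), "shorter than 8")
  expect_error(utr_region("u", "ACGTQ"), "non-DNA")
  expect_error(utr_region("u", "ACGT", offset = 0), "1-based")
})

test_that("reverse_complement is a length-preserving involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement(""), "")
  expect_error(reverse_complement("ACGB"), "non-nucleotide")
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(0:30, 1),
                      replace = TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("seed_match_strings yields the four class strings", {
  strs <- seed_match_strings(mirx)
  expect_equal(strs[["6mer"]], "TTGCCT")
  expect_equal(strs[["7mer-A1"]], "TTGCCTA")
  expect_equal(strs[["7mer-m8"]], "GTTGCCT")
  expect_equal(strs[["8mer"]], "GTTGCCTA")
  for (i in 1:20) {
    m <- random_mirna()
    expect_equal(seed_match_strings(m), oracle_site_strings(m$sequence))
  }
})

test_that("scan_sites classifies loci by their strongest applicable class", {
  s8 <- scan_sites(mirx, utr_region("u", "AAGTTGCCTAAA"))
  expect_equal(nrow(s8), 1L)
  expect_equal(s8$class, "8mer")
  expect_equal(c(s8$start, s8$end), c(3L, 10L))
  expect_equal(s8$site_seq, "GTTGCCTA")

  s6 <- scan_sites(mirx, utr_region("u", "AATTGCCTCAA"))
  expect_equal(s6$class, "6mer")
  expect_equal(c(s6$start, s6$end), c(3L, 8L))

  # 7mer-m8: position-8 complement 5' of core, non-A 3'
  s7 <- scan_sites(mirx, utr_region("u", "AGTTGCCTC"))
  expect_equal(s7$class, "7mer-m8")
  expect_equal(c(s7$start, s7$end), c(2L, 8L))

  # 7mer-A1: adenine 3' of core, wrong base 5'
  s7a <- scan_sites(mirx, utr_region("u", "ATTTGCCTAC"))
  expect_equal(s7a$class, "7mer-A1")
  expect_equal(c(s7a$start, s7a$end), c(3L, 9L))

  expect_equal(nrow(scan_sites(mirx, utr_region("u", "AAAAAAAA"))), 0L)
  # N never matches
  expect_equal(nrow(scan_sites(mirx, utr_region("u", "AATTGCNTCAA"))), 0L)
})

test_that("coordinates shift with the region offset", {
  base <- scan_sites(mirx, utr_region("u", "AAGTTGCCTAAA", offset = 1))
  shifted <- scan_sites(mirx, utr_region("u", "AAGTTGCCTAAA", offset = 870))
  expect_equal(shifted$start, base$start + 869L)
  expect_equal(shifted$end, base$end + 869L)
  expect_equal(shifted$class, base$class)
})

test_that("scan_sites matches the brute-force oracle on random inputs", {
  set.seed(42)
  for (i in 1:60) {
    m <- random_mirna()
    u <- random_utr(len = sample(50:300, 1))
    got <- scan_sites(m, u)
    want <- oracle_scan(m$sequence, u$sequence)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$class, want$class)
  }
})

test_that("scan_panel reports per-miRNA counts and rejects duplicates", {
  u1 <- utr_region("u1", "AAGTTGCCTAAA")
  u2 <- utr_region("u2", "CCGTTGCCTACC")
  tab <- scan_panel(list(mirx), list(u1, u2))
  expect_equal(nrow(tab), 2L)
  expect_equal(site_counts(tab), c("miR-X" = 2L))
  expect_equal(nrow(scan_panel(list(mirx), list())), 0L)
  expect_error(scan_panel(list(mirx, mirx), u1), "duplicate")
  # absent miRNA still counted with zero
  miry <- mature_mirna("miR-Y", "UGGGGGGGGGA")
  tab2 <- scan_panel(list(mirx, miry), u1)
  expect_equal(site_counts(tab2)[["miR-Y"]], 0L)
})

test_that("compare_utrs differences are consistent with scan_panel", {
  cfg <- sim_config(rng_seed = 11, utr_length = 400)
  panel <- list(mirx)
  g3 <- gen_utr(panel, data.frame(mirna = "miR-X",
                                  class = c("8mer", "6mer", "7mer-A1"),
                                  pos = c(40, 160, 300)), cfg,
                transcript_id = "utrA")
  g1 <- gen_utr(panel, data.frame(mirna = "miR-X", class = "7mer-m8",
                                  pos = 100),
                sim_config(rng_seed = 12, utr_length = 400),
                transcript_id = "utrB")
  cmp <- compare_utrs(panel, g3$utr, g1$utr)
  expect_equal(cmp$count_a, 3L)
  expect_equal(cmp$count_b, 1L)
  expect_equal(cmp$difference, 2L)
  same <- compare_utrs(panel, g3$utr, g3$utr)
  expect_equal(same$difference, 0L)
})

test_that("design_mutant substitutes seed positions 2/4/6 and clears sites", {
  mut <- design_mutant(utr_region("u", "AAGTTGCCTAAA"), mirx)
  expect_equal(mut$substitutions$position, c(5L, 7L, 9L))
  expect_equal(mut$substitutions$from, c("T", "C", "T"))
  expect_equal(mut$substitutions$to, c("G", "A", "G"))
  expect_equal(mut$residual_sites, 0L)
  expect_equal(nrow(scan_panel(list(mirx), mut$mutated)), 0L)

  # no sites: unchanged sequence, empty substitution table
  clean <- design_mutant(utr_region("u", "AAAAAAAAAA"), mirx)
  expect_equal(nrow(clean$substitutions), 0L)
  expect_equal(clean$mutated$sequence, "AAAAAAAAAA")

  # two non-overlapping sites: 6 substitutions
  g <- gen_utr(list(mirx),
               data.frame(mirna = "miR-X", class = c("8mer", "7mer-m8"),
                          pos = c(30, 120)),
               sim_config(rng_seed = 3, utr_length = 200))
  mut2 <- design_mutant(g$utr, list(mirx))
  expect_equal(nrow(mut2$substitutions), 6L)
  expect_equal(mut2$residual_sites, 0L)
})

test_that("mutant design clears all panel sites on random planted UTRs", {
  panel <- cd28_panel()
  set.seed(7)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    planted <- data.frame(
      mirna = sample(vapply(panel, `[[`, character(1), "name"), k,
                     replace = TRUE),
      class = sample(c("8mer", "7mer-m8", "7mer-A1", "6mer"), k,
                     replace = TRUE),
      pos = sort(sample(seq(10, 350, by = 40), k)))
    g <- gen_utr(panel, planted, sim_config(rng_seed = 100 + i,
                                            utr_length = 400))
    mut <- design_mutant(g$utr, panel)
    expect_equal(mut$residual_sites, 0L)
    expect_equal(nrow(scan_panel(panel, mut$mutated)), 0L)
    # every detected site receives its three core substitutions
    sites <- scan_panel(panel, g$utr)
    hit <- vapply(seq_len(nrow(sites)), function(r) {
      sum(mut$substitutions$position >= sites$start[r] &
            mut$substitutions$position <= sites$end[r]) >= 3L
    }, logical(1))
    expect_true(all(hit))
  }
})

test_that("FASTA round trips preserve sequences and offsets", {
  tmp <- tempfile(fileext = ".fasta")
  u <- utr_region("tx1", "ACGTACGTAAGG", offset = 870)
  write_utr_fasta(list(u, utr_region("tx2", "TTTTCCCC")), tmp)
  back <- read_utr_fasta(tmp)
  expect_equal(back[[1]]$offset, 870L)
  expect_equal(back[[1]]$sequence, u$sequence)
  expect_equal(back[[2]]$offset, 1L)

  panel <- cd28_panel()
  expect_length(panel, 5L)
  expect_equal(panel[[1]]$name, "hsa-miR-9-5p")
  expect_true(all(grepl("^[ACGU]+$",
                        vapply(panel, `[[`, character(1), "sequence"))))
})

test_that("BED export is 0-based half-open", {
  s <- scan_sites(mirx, utr_region("u", "AAGTTGCCTAAA", offset = 870))
  bed <- sites_to_bed(s)
  expect_equal(bed$chromStart, s$start - 1L)
  expect_equal(bed$chromEnd, s$end)
  expect_equal(bed$chromEnd - bed$chromStart, s$end - s$start + 1L)
})
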