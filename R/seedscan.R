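# Site classes in decreasing binding strength.
SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Construct a mature miRNA
#'
#' A mature miRNA is stored as a named 5'->3' RNA-alphabet sequence. The
#' seed region (positions 2-7, extended to 2-8 for the stronger site
#' classes) is what pairs with the target 3'UTR, so at least the first
#' eight nucleotides must be present. DNA-alphabet input (T) is accepted
#' and normalised to U.
#'
#' @param name miRNA identifier, e.g. `"hsa-miR-24-3p"`.
#' @param sequence 5'->3' sequence, RNA or DNA alphabet, length >= 8.
#' @return An object of class `mature_mirna` with elements `name` and
#'   `sequence` (RNA alphabet).
#' @examples
#' mature_mirna("miR-X", "UAGGCAACUGA")
#' @export
mature_mirna <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seq <- toupper(as.character(sequence))
  seq <- chartr("T", "U", seq)
  bad <- gsub("[ACGU]", "", seq)
  if (nzchar(bad)) {
    stop("miRNA '", name, "' contains non-RNA characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  if (nchar(seq) < 8L) {
    stop("miRNA '", name, "' is shorter than 8 nt; positions 1-8 must exist")
  }
  structure(list(name = name, sequence = seq), class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat("mature miRNA ", x$name, ": 5'-", x$sequence, "-3' (",
      nchar(x$sequence), " nt)\n", sep = "")
  invisible(x)
}

#' Construct a 3'UTR region
#'
#' A UTR region is a DNA-alphabet sequence anchored in transcript
#' coordinates: `offset` is the 1-based transcript position of the
#' region's first base, so sites found at local position `i` are reported
#' at transcript position `i + offset - 1`. This mirrors cloned-fragment
#' numbering such as "nt 870-2279" of a transcript. U is normalised to T;
#' N is allowed but never matches any site class.
#'
#' @param transcript_id transcript identifier.
#' @param sequence DNA-alphabet sequence (A/C/G/T/N; U accepted).
#' @param offset 1-based transcript coordinate of the first base.
#' @return An object of class `utr_region`.
#' @examples
#' utr_region("ENST-X", "AAGTTGCCTAAA", offset = 870)
#' @export
utr_region <- function(transcript_id, sequence, offset = 1L) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L) stop("offset must be a 1-based positive integer")
  seq <- toupper(as.character(sequence))
  seq <- chartr("U", "T", seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("UTR '", transcript_id, "' contains non-DNA characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  structure(list(transcript_id = transcript_id, sequence = seq,
                 offset = offset),
            class = "utr_region")
}

#' @export
print.utr_region <- function(x, ...) {
  n <- nchar(x$sequence)
  cat("UTR region ", x$transcript_id, " nt ", x$offset, "-",
      x$offset + n - 1L, " (", n, " bp)\n", sep = "")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A/C/G/T/N).
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (nzchar(gsub("[ACGTN]", "", s))) {
    stop("reverse_complement: sequence contains non-nucleotide characters")
  }
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Seed-match strings for the four canonical site classes
#'
#' For a mature miRNA the UTR substring constituting a perfect seed match
#' is the reverse complement (in DNA space) of the seed:
#' \itemize{
#'   \item 6mer: reverse complement of miRNA positions 2-7;
#'   \item 7mer-A1: the 6mer followed by an A (the A opposite miRNA
#'     position 1 is recognised as adenine regardless of pairing);
#'   \item 7mer-m8: reverse complement of positions 2-8;
#'   \item 8mer: the 7mer-m8 followed by an A.
#' }
#'
#' @param mirna a [mature_mirna].
#' @return Named character vector with elements `"8mer"`, `"7mer-m8"`,
#'   `"7mer-A1"`, `"6mer"` (DNA alphabet, 5'->3').
#' @examples
#' seed_match_strings(mature_mirna("miR-X", "UAGGCAACUGA"))
#' @export
seed_match_strings <- function(mirna) {
  mirna <- as_mature_mirna(mirna)
  dna <- chartr("U", "T", mirna$sequence)
  seed27 <- substr(dna, 2L, 7L)
  seed28 <- substr(dna, 2L, 8L)
  m6 <- reverse_complement(seed27)
  m7m8 <- reverse_complement(seed28)
  c("8mer" = paste0(m7m8, "A"),
    "7mer-m8" = m7m8,
    "7mer-A1" = paste0(m6, "A"),
    "6mer" = m6)
}

as_mature_mirna <- function(x) {
  if (inherits(x, "mature_mirna")) return(x)
  stop("expected a mature_mirna object")
}

as_utr_region <- function(x) {
  if (inherits(x, "utr_region")) return(x)
  stop("expected a utr_region object")
}

empty_site_table <- function() {
  data.frame(mirna = character(), transcript = character(),
             start = integer(), end = integer(),
             class = character(), site_seq = character(),
             stringsAsFactors = FALSE)
}

# All start positions of (possibly overlapping) occurrences of `pat` in `s`.
str_find_all <- function(s, pat) {
  hits <- integer()
  from <- 1L
  repeat {
    i <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
    if (i < 0L) break
    hits <- c(hits, from + i - 1L)
    from <- from + i  # step one base: overlapping occurrences count
  }
  hits
}

#' Scan one UTR region for seed-match sites of one miRNA
#'
#' Finds every occurrence of the miRNA's 6mer seed core (reverse
#' complement of positions 2-7) in the UTR and reports each core locus
#' exactly once, upgraded to the strongest applicable class given its
#' flanking bases: a match to miRNA position 8 immediately 5' of the core
#' and/or an adenine immediately 3' of it. Precedence is
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer. Coordinates are 1-based inclusive in
#' transcript numbering (the region offset is applied). N never matches.
#'
#' @param mirna a [mature_mirna].
#' @param utr a [utr_region].
#' @return data.frame with columns `mirna`, `transcript`, `start`, `end`,
#'   `class`, `site_seq`, sorted by `start`; zero rows when no site.
#' @examples
#' scan_sites(mature_mirna("miR-X", "UAGGCAACUGA"),
#'            utr_region("utr", "AAGTTGCCTAAA"))
#' @export
scan_sites <- function(mirna, utr) {
  mirna <- as_mature_mirna(mirna)
  utr <- as_utr_region(utr)
  strs <- seed_match_strings(mirna)
  core <- strs[["6mer"]]
  m8_base <- substr(strs[["7mer-m8"]], 1L, 1L)  # complement of miRNA pos 8
  s <- utr$sequence
  n <- nchar(s)
  starts <- str_find_all(s, core)
  if (length(starts) == 0L) return(empty_site_table())
  rows <- lapply(starts, function(i) {
    five <- if (i > 1L) substr(s, i - 1L, i - 1L) else ""
    three <- if (i + 6L <= n) substr(s, i + 6L, i + 6L) else ""
    has_m8 <- identical(five, m8_base)
    has_a1 <- identical(three, "A")
    if (has_m8 && has_a1) {
      cls <- "8mer"; a <- i - 1L; b <- i + 6L
    } else if (has_m8) {
      cls <- "7mer-m8"; a <- i - 1L; b <- i + 5L
    } else if (has_a1) {
      cls <- "7mer-A1"; a <- i; b <- i + 6L
    } else {
      cls <- "6mer"; a <- i; b <- i + 5L
    }
    data.frame(mirna = mirna$name, transcript = utr$transcript_id,
               start = a + utr$offset - 1L, end = b + utr$offset - 1L,
               class = cls, site_seq = substr(s, a, b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Scan a panel of miRNAs over one or more UTR regions
#'
#' Union of [scan_sites()] over all (miRNA, UTR) pairs. Sites of different
#' miRNAs may overlap and are reported independently.
#'
#' @param mirnas list of [mature_mirna] (unique names).
#' @param utrs a [utr_region] or list of them.
#' @return data.frame as in [scan_sites()], with an attribute
#'   `"site_counts"`: named integer vector of per-miRNA site counts
#'   (zero-count panel members included).
#' @export
scan_panel <- function(mirnas, utrs) {
  if (inherits(mirnas, "mature_mirna")) mirnas <- list(mirnas)
  if (inherits(utrs, "utr_region")) utrs <- list(utrs)
  stopifnot(length(mirnas) >= 1L)
  nms <- vapply(mirnas, function(m) as_mature_mirna(m)$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate miRNA names in panel: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  tabs <- list(empty_site_table())
  for (m in mirnas) for (u in utrs) tabs[[length(tabs) + 1L]] <- scan_sites(m, u)
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  counts <- vapply(nms, function(nm) sum(out$mirna == nm), integer(1))
  attr(out, "site_counts") <- counts
  out
}

#' Per-miRNA site counts of a panel scan
#'
#' @param sites result of [scan_panel()].
#' @return named integer vector, one entry per panel miRNA.
#' @export
site_counts <- function(sites) {
  sc <- attr(sites, "site_counts")
  if (is.null(sc)) stop("no site_counts attribute; pass a scan_panel() result")
  sc
}

#' Compare seed-site content of two UTRs
#'
#' Scans both UTRs with the same panel and class rules and reports, per
#' miRNA, the site counts and their difference. Used e.g. to contrast the
#' human and mouse CD28 3'UTRs, where part of the human miR-27a sites are
#' absent from the mouse transcript.
#'
#' @param mirnas miRNA panel, as in [scan_panel()].
#' @param utr_a,utr_b the two [utr_region]s.
#' @return data.frame with columns `mirna`, `count_a`, `count_b`,
#'   `difference` (= count_a - count_b).
#' @export
compare_utrs <- function(mirnas, utr_a, utr_b) {
  ca <- site_counts(scan_panel(mirnas, utr_a))
  cb <- site_counts(scan_panel(mirnas, utr_b))
  data.frame(mirna = names(ca),
             count_a = unname(ca), count_b = unname(cb),
             difference = unname(ca - cb),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Transversion map used for reporter mutagenesis: destroys Watson-Crick
# pairing at the substituted position whatever the original base.
TRANSVERSION <- c(A = "C", C = "A", G = "T", T = "G")

#' Design a seed-mutant UTR for reporter constructs
#'
#' Reproduces the reporter-construct mutagenesis strategy: at every
#' detected panel site the UTR bases pairing with miRNA seed positions 2,
#' 4 and 6 are substituted by a fixed transversion (A->C, C->A, G->T,
#' T->G). Within the 7mer-m8 match frame (whose base 1 pairs miRNA
#' position 8), seed position p pairs frame position 9 - p, so positions
#' 2/4/6 map to frame positions 7/5/3 — always inside the 6mer core. The
#' mutated sequence is re-scanned over the whole panel; any residual or
#' newly created site is an error, so a successful design is guaranteed
#' site-free.
#'
#' Because the transversion is deterministic, a substitution can
#' occasionally spell a new core for another panel member; the design
#' runs additional mutation passes over such sites until the re-scan is
#' clean (an error is raised if `max_passes` is exhausted).
#'
#' @param utr a [utr_region].
#' @param panel list of [mature_mirna].
#' @param max_passes mutation-pass budget before a design failure is
#'   raised (default 10; pass two is already rare).
#' @return An object of class `mutated_utr`: list with `base` (input
#'   region), `mutated` (a `utr_region` carrying the mutated sequence),
#'   `substitutions` (data.frame: `position` in transcript coordinates,
#'   `from`, `to`) and `residual_sites` (always 0 on success).
#' @export
design_mutant <- function(utr, panel, max_passes = 10L) {
  utr <- as_utr_region(utr)
  if (inherits(panel, "mature_mirna")) panel <- list(panel)
  s <- strsplit(utr$sequence, "")[[1]]
  all_subs <- list()
  cur <- utr
  for (pass in seq_len(max_passes)) {
    sites <- scan_panel(panel, cur)
    if (nrow(sites) == 0L) break
    sub_pos <- integer()
    for (r in seq_len(nrow(sites))) {
      cls <- sites$class[r]
      # local 1-based start of the 7mer-m8 frame (may sit one base 5' of
      # the reported site for 7mer-A1/6mer sites; substituted frame
      # positions 3/5/7 are inside the core either way)
      local_start <- sites$start[r] - utr$offset + 1L
      frame_start <- if (cls %in% c("8mer", "7mer-m8")) local_start
                     else local_start - 1L
      sub_pos <- c(sub_pos, frame_start + c(2L, 4L, 6L))
    }
    sub_pos <- sort(unique(sub_pos))
    from <- s[sub_pos]
    to <- unname(TRANSVERSION[from])
    if (anyNA(to)) stop("cannot mutate ambiguous base inside a site core")
    s[sub_pos] <- to
    all_subs[[pass]] <- data.frame(position = sub_pos + utr$offset - 1L,
                                   from = from, to = to,
                                   stringsAsFactors = FALSE)
    cur <- utr_region(utr$transcript_id, paste(s, collapse = ""),
                      utr$offset)
    # the transversion can itself spell a new panel core; further passes
    # clear such sites the same way (almost always one extra pass)
  }
  rescan <- scan_panel(panel, cur)
  if (nrow(rescan) > 0L) {
    stop("mutant design failed: panel site(s) remain after ", max_passes,
         " mutation passes at ",
         paste0(rescan$mirna, ":", rescan$start, "-", rescan$end,
                collapse = ", "))
  }
  subs <- if (length(all_subs)) do.call(rbind, all_subs)
          else data.frame(position = integer(), from = character(),
                          to = character(), stringsAsFactors = FALSE)
  # collapse positions touched in several passes to original -> final base
  if (nrow(subs)) {
    subs <- subs[order(subs$position), , drop = FALSE]
    first <- !duplicated(subs$position)
    last <- !duplicated(subs$position, fromLast = TRUE)
    subs <- data.frame(position = subs$position[first],
                       from = subs$from[first], to = subs$to[last],
                       stringsAsFactors = FALSE)
    subs <- subs[subs$from != subs$to, , drop = FALSE]
    rownames(subs) <- NULL
  }
  structure(list(base = utr, mutated = cur, substitutions = subs,
                 residual_sites = 0L),
            class = "mutated_utr")
}

#' @export
print.mutated_utr <- function(x, ...) {
  cat("mutated UTR ", x$base$transcript_id, ": ",
      nrow(x$substitutions), " substitution(s), ",
      x$residual_sites, " residual panel site(s)\n", sep = "")
  invisible(x)
}

#' Export a site table as BED-like 0-based half-open intervals
#'
#' @param sites data.frame from [scan_sites()]/[scan_panel()].
#' @return data.frame with columns `chrom`, `chromStart` (0-based),
#'   `chromEnd` (exclusive), `name` (`mirna|class`).
#' @export
sites_to_bed <- function(sites) {
  data.frame(chrom = sites$transcript,
             chromStart = sites$start - 1L,
             chromEnd = sites$end,
             name = paste(sites$mirna, sites$class, sep = "|"),
             stringsAsFactors = FALSE)
}
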