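#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits
NULL

QPID_MOTIFS <- list(CRE_full = "TGACGTCA", CRE_half = "CGTCA")

site_motif <- function(site_type) {
  m <- QPID_MOTIFS[[site_type]]
  if (is.null(m)) qpid_stop("qpid_invalid_argument",
                            "unknown site type '%s'", site_type)
  m
}

fixed_matches <- function(seq, pattern) {
  if (nchar(seq) < nchar(pattern)) return(integer(0))
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find CRE or CRE half-site occurrences in a sequence
#'
#' Scans for the motif in either orientation: forward matches of the motif
#' plus forward matches of its reverse complement. For the palindromic CRE
#' full site both orientations coincide; duplicates are reported once with
#' strand '+'. N never matches.
#'
#' @param seq DNA string (ACGTN)
#' @param site_type `"CRE_full"` (TGACGTCA) or `"CRE_half"` (CGTCA)
#' @return data.frame `start` (1-based), `end`, `strand`, `site_type`,
#'   sorted by position
#' @export
find_sites <- function(seq, site_type = c("CRE_full", "CRE_half")) {
  site_type <- match.arg(site_type)
  seq <- toupper(seq)
  motif <- site_motif(site_type)
  w <- nchar(motif)
  fwd <- fixed_matches(seq, motif)
  rcm <- revcomp_chr(motif)
  rev <- if (rcm == motif) integer(0) else fixed_matches(seq, rcm)
  rev <- setdiff(rev, fwd)
  starts <- c(fwd, rev)
  out <- data.frame(
    start = starts, end = starts + w - 1L,
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    site_type = rep(site_type, length(starts)), stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' 200 bp window centered on the first site in a peak
#'
#' Finds the leftmost motif occurrence inside the peak interval and extracts
#' the 200 bp window centered on its core: window start =
#' `core_start - (100 - floor(w/2))`, length exactly 200, so a half-site
#' (w = 5) core occupies positions 98-102 of the window. Windows clipped by
#' a chromosome end are rejected with a boundary warning.
#'
#' @param genome named character vector of chromosome sequences
#' @param chrom chromosome name
#' @param peak_start,peak_end 1-based inclusive peak interval
#' @param site_type `"CRE_full"` or `"CRE_half"`
#' @return a one-row data.frame `chrom`, `start`, `end` (1-based window),
#'   `strand`, `site_type`, `core_start` (genomic), `core_offset` (1-based
#'   within window), `sequence`; or NULL if the peak has no site or the
#'   window is clipped
#' @export
first_site_window <- function(genome, chrom, peak_start, peak_end, site_type) {
  seq <- genome[[chrom]]
  sub <- substring(seq, peak_start, peak_end)
  hits <- find_sites(sub, site_type)
  if (nrow(hits) == 0L) return(NULL)
  h <- hits[1L, ]                                   # leftmost occurrence
  w <- nchar(site_motif(site_type))
  core_start <- peak_start + h$start - 1L
  win_start <- core_start - (100L - w %/% 2L)
  win_end <- win_start + 199L
  if (win_start < 1L || win_end > nchar(seq)) {
    warning(sprintf("window for site at %s:%d clipped at chromosome end; rejected",
                    chrom, core_start))
    return(NULL)
  }
  data.frame(chrom = chrom, start = win_start, end = win_end,
             strand = h$strand, site_type = site_type,
             core_start = core_start,
             core_offset = core_start - win_start + 1L,
             sequence = substring(seq, win_start, win_end),
             stringsAsFactors = FALSE)
}

#' Exclude half-site windows with a full site in the 15 bp flanks
#'
#' A CRE half-site entry is dropped when the full site TGACGTCA (palindromic,
#' so one orientation suffices) occurs with any overlap of the 15 bp
#' immediately 5' or 3' of the core.
#'
#' @param entry one-row data.frame from [first_site_window()] (site_type
#'   `"CRE_half"`), with `sequence` and `core_offset`
#' @return TRUE to keep, FALSE to drop
#' @export
exclude_full_in_flanks <- function(entry) {
  stopifnot(entry$site_type == "CRE_half")
  full <- site_motif("CRE_full"); fw <- nchar(full)
  w <- nchar(site_motif("CRE_half"))
  core_lo <- entry$core_offset; core_hi <- entry$core_offset + w - 1L
  flank_lo <- core_lo - 15L; flank_hi <- core_hi + 15L
  hits <- fixed_matches(entry$sequence, full)
  for (s in hits) {
    e <- s + fw - 1L
    overlaps_flank <- (e >= flank_lo && s <= core_lo - 1L) ||
                      (s <= flank_hi && e >= core_hi + 1L)
    if (overlaps_flank) return(FALSE)
  }
  TRUE
}

peaks_to_granges <- function(peaks) {
  # peak tables carry BED 0-based half-open coordinates
  GRanges(peaks$chrom, IRanges(peaks$start + 1L, peaks$end))
}

#' Categorize sites by ChIP and DNase peak membership
#'
#' Only sites whose core lies fully inside a DNase-accessible peak are
#' considered. Among those, overlap (core fully within a peak) with the two
#' ChIP experiments assigns `A_only`, `B_only`, `both`, or
#' `accessible_unbound`; sites outside DNase accessibility get NA
#' (excluded from the library).
#'
#' @param sites data.frame with `chrom`, `core_start`, `core_end` (1-based
#'   inclusive core coordinates)
#' @param chip_a,chip_b,dnase peak data.frames (BED 0-based half-open
#'   `chrom`, `start`, `end`), e.g. from [read_narrowpeak()]
#' @return character vector of categories, one per site
#' @export
categorize_sites <- function(sites, chip_a, chip_b, dnase) {
  core <- GRanges(sites$chrom, IRanges(sites$core_start, sites$core_end))
  within <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0L) return(rep(FALSE, length(core)))
    hit <- findOverlaps(core, peaks_to_granges(peaks), type = "within")
    seq_along(core) %in% queryHits(hit)
  }
  acc <- within(dnase); in_a <- within(chip_a); in_b <- within(chip_b)
  out <- rep(NA_character_, nrow(sites))
  out[acc & in_a & in_b]   <- "both"
  out[acc & in_a & !in_b]  <- "A_only"
  out[acc & !in_a & in_b]  <- "B_only"
  out[acc & !in_a & !in_b] <- "accessible_unbound"
  out
}

#' Extract categorized library candidates from peaks
#'
#' End-to-end candidate extraction: for every DNase-accessible peak, take
#' the 200 bp window on the first motif occurrence, apply the full-site
#' flank exclusion (half-sites only), and categorize by ChIP membership.
#'
#' @param genome named character vector of chromosome sequences
#' @param chip_a,chip_b,dnase peak data.frames (0-based half-open)
#' @param site_type `"CRE_full"` or `"CRE_half"`
#' @return data.frame of candidate entries with a `category` column
#' @export
extract_candidates <- function(genome, chip_a, chip_b, dnase,
                               site_type = "CRE_half") {
  rows <- lapply(seq_len(nrow(dnase)), function(i)
    first_site_window(genome, dnase$chrom[i], dnase$start[i] + 1L,
                      dnase$end[i], site_type))
  cand <- do.call(rbind, rows)
  if (is.null(cand) || nrow(cand) == 0L)
    return(NULL)
  if (site_type == "CRE_half") {
    keep <- vapply(seq_len(nrow(cand)), function(i)
      exclude_full_in_flanks(cand[i, ]), logical(1))
    message(sprintf("full-site flank exclusion dropped %d of %d half-site candidates",
                    sum(!keep), nrow(cand)))
    cand <- cand[keep, , drop = FALSE]
  }
  w <- nchar(site_motif(site_type))
  cand$core_end <- cand$core_start + w - 1L
  cand$category <- categorize_sites(cand, chip_a, chip_b, dnase)
  cand <- cand[!is.na(cand$category), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Select the measurement library from categorized candidates
#'
#' Seeded uniform sampling without replacement per category, e.g. quotas
#' 34/34/34/5 over A_only/B_only/both/accessible_unbound for a 107-entry
#' half-site library, plus optional motif-free control windows drawn from
#' the genome.
#'
#' @param candidates data.frame from [extract_candidates()]
#' @param quota named integer vector: categories to counts; may include
#'   `control`
#' @param seed integer seed
#' @param genome required when `quota` includes controls
#' @return data.frame of library entries (`id`, candidate columns,
#'   `category`)
#' @export
design_library <- function(candidates, quota, seed = 1L, genome = NULL) {
  set.seed(derive_seed(seed, "design_library"))
  picks <- list()
  for (cat in setdiff(names(quota), "control")) {
    q <- quota[[cat]]
    if (q == 0L) next
    pool <- candidates[candidates$category == cat, , drop = FALSE]
    if (nrow(pool) < q)
      qpid_stop("qpid_shortfall",
                "category '%s': quota %d exceeds %d available candidates",
                cat, q, nrow(pool))
    picks[[cat]] <- pool[sample.int(nrow(pool), q), , drop = FALSE]
  }
  out <- do.call(rbind, picks)
  if (!is.null(out)) rownames(out) <- NULL
  nctrl <- if ("control" %in% names(quota)) quota[["control"]] else 0L
  if (nctrl > 0L) {
    stopifnot(!is.null(genome))
    ctrl <- draw_control_windows(genome, nctrl)
    out <- rbind(out, ctrl)
  }
  if (is.null(out))
    out <- candidates[0, , drop = FALSE]
  out$id <- sprintf("lib%03d", seq_len(nrow(out)))
  out[, c("id", setdiff(names(out), "id")), drop = FALSE]
}

draw_control_windows <- function(genome, n, tries = 1000L) {
  out <- NULL; t <- 0L
  chroms <- names(genome)
  while ((is.null(out) || nrow(out) < n) && t < tries) {
    t <- t + 1L
    chrom <- sample(chroms, 1L)
    L <- nchar(genome[[chrom]])
    if (L < 200L) next
    s <- sample.int(L - 199L, 1L)
    sq <- substring(genome[[chrom]], s, s + 199L)
    if (nrow(find_sites(sq, "CRE_full")) > 0L ||
        nrow(find_sites(sq, "CRE_half")) > 0L) next
    row <- data.frame(chrom = chrom, start = s, end = s + 199L, strand = "+",
                      site_type = "none", core_start = NA_integer_,
                      core_offset = NA_integer_, sequence = sq,
                      core_end = NA_integer_, category = "control",
                      stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  if (is.null(out) || nrow(out) < n)
    qpid_stop("qpid_shortfall", "could not place %d motif-free control windows", n)
  out
}
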