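#' Synthetic genome with planted CRE sites and peak sets
#'
#' Builds a small single-chromosome genome with planted CRE full sites
#' (TGACGTCA) and CRE half-sites (CGTCA, random orientation), at least
#' 400 bp apart and at least 200 bp from the ends, with the background
#' scrubbed of any spurious motif occurrence. Every planted site is covered
#' by a DNase-accessible peak; two ChIP peak sets ("A" and "B") cover sites
#' according to their assigned category (A_only, B_only, both,
#' accessible_unbound), drawn from `category_fractions` by largest-remainder
#' apportionment so the category counts are exact.
#'
#' @param length_bp genome length, bp (>= 400 * (n_full_sites + n_half_sites))
#' @param n_full_sites,n_half_sites planted site counts
#' @param category_fractions named fractions over `A_only`, `B_only`,
#'   `both`, `accessible_unbound`, summing to 1
#' @param seed integer seed
#' @return list: `genome` (named character vector), `truth` (data.frame
#'   `chrom`, `core_start`, `core_end` 1-based, `strand`, `site_type`,
#'   `category`), and peak data.frames `chip_a`, `chip_b`, `dnase`
#'   (BED 0-based half-open with narrowPeak columns)
#' @export
synth_genome_and_peaks <- function(length_bp = 80000L, n_full_sites = 14L,
                                   n_half_sites = 140L,
                                   category_fractions = c(
                                     A_only = 0.25, B_only = 0.25,
                                     both = 0.25, accessible_unbound = 0.25),
                                   seed = 1L) {
  n <- n_full_sites + n_half_sites
  if (length_bp < 400L * n)
    qpid_stop("qpid_invalid_argument",
              "cannot pack %d sites >= 400 bp apart in %d bp", n, length_bp)
  if (abs(sum(category_fractions) - 1) > 1e-9)
    qpid_stop("qpid_invalid_argument", "category fractions must sum to 1")
  set.seed(derive_seed(seed, "synth_genome"))
  chrom <- "chrS"
  bases <- sample(DNA_BASES4, length_bp, replace = TRUE)

  # site start positions: even slots with bounded jitter keep the spacing
  step <- (length_bp - 400L) %/% n
  jit_max <- max(step - 400L, 0L)
  starts <- 200L + (seq_len(n) - 1L) * step +
    if (jit_max > 0L) sample.int(jit_max, n, replace = TRUE) - 1L else 0L
  is_full <- sample(rep(c(TRUE, FALSE), c(n_full_sites, n_half_sites)))

  apportion <- function(total) {  # largest remainder
    raw <- category_fractions * total
    cnt <- floor(raw); rem <- total - sum(cnt)
    if (rem > 0) {
      o <- order(raw - cnt, decreasing = TRUE)
      cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
    }
    cnt
  }
  assign_cat <- function(total) {
    cnt <- apportion(total)
    sample(rep(names(cnt), cnt))
  }
  category <- character(n)
  category[is_full] <- assign_cat(n_full_sites)
  category[!is_full] <- assign_cat(n_half_sites)

  strand <- ifelse(runif(n) < 0.5, "+", "-")
  strand[is_full] <- "+"                      # palindromic full site
  motif <- ifelse(is_full, QPID_MOTIFS$CRE_full,
                  ifelse(strand == "+", QPID_MOTIFS$CRE_half,
                         revcomp_chr(QPID_MOTIFS$CRE_half)))
  width <- nchar(motif)
  for (i in seq_len(n))
    bases[starts[i]:(starts[i] + width[i] - 1L)] <-
      strsplit(motif[i], "")[[1]]

  genome_str <- paste(bases, collapse = "")
  genome_str <- scrub_spurious_motifs(genome_str, starts, width)
  genome <- setNames(genome_str, chrom)

  truth <- data.frame(chrom = chrom, core_start = starts,
                      core_end = starts + width - 1L, strand = strand,
                      site_type = ifelse(is_full, "CRE_full", "CRE_half"),
                      category = category, stringsAsFactors = FALSE)

  mk_peak <- function(keep, label) {
    k <- which(keep)
    if (length(k) == 0L)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = integer(0), strand = character(0),
                        signalValue = numeric(0), pValue = numeric(0),
                        qValue = numeric(0), peak = integer(0)))
    lo <- pmax(starts[k] - sample(80:180, length(k), replace = TRUE), 1L)
    hi <- pmin(starts[k] + width[k] - 1L +
                 sample(80:180, length(k), replace = TRUE), length_bp)
    data.frame(chrom = chrom, start = lo - 1L, end = hi,   # to 0-based half-open
               name = sprintf("%s_peak%d", label, seq_along(k)),
               score = sample(200:1000, length(k), replace = TRUE),
               strand = ".", signalValue = round(runif(length(k), 2, 30), 3),
               pValue = -1, qValue = -1,
               peak = as.integer(starts[k] - lo + width[k] %/% 2L),
               stringsAsFactors = FALSE)
  }
  list(genome = genome, truth = truth,
       chip_a = mk_peak(category %in% c("A_only", "both"), "chipA"),
       chip_b = mk_peak(category %in% c("B_only", "both"), "chipB"),
       dnase = mk_peak(rep(TRUE, n), "dnase"))
}

# mutate away any CGTCA/TGACG occurrence not inside a planted core so peak
# scans find exactly the planted sites
scrub_spurious_motifs <- function(genome_str, core_starts, core_widths,
                                  max_rounds = 20L) {
  protected <- unlist(mapply(function(s, w) s:(s + w - 1L), core_starts,
                             core_widths, SIMPLIFY = FALSE))
  pats <- c(QPID_MOTIFS$CRE_half, revcomp_chr(QPID_MOTIFS$CRE_half))
  for (round in seq_len(max_rounds)) {
    hits <- unlist(lapply(pats, fixed_matches, seq = genome_str))
    bad <- hits[!vapply(hits, function(s)
      all(s:(s + 4L) %in% protected), logical(1))]
    if (length(bad) == 0L) return(genome_str)
    v <- strsplit(genome_str, "")[[1]]
    for (s in bad) {
      p <- s + 2L                                  # middle base of the 5-mer
      if (p %in% protected) p <- max(setdiff(s:(s + 4L), protected))
      v[p] <- sample(setdiff(DNA_BASES4, v[p]), 1L)
    }
    genome_str <- paste(v, collapse = "")
  }
  qpid_stop("qpid_configuration", "could not scrub spurious motifs")
}
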