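test_that("find_sites scans both orientations and de-duplicates palindromes", {
  h <- find_sites("AATGACGTCAAA", "CRE_full")
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 3L)          # 0-based position 2
  expect_equal(h$strand, "+")

  h2 <- find_sites("TTCGTCATT", "CRE_half")
  expect_equal(nrow(h2), 1)
  expect_equal(h2$start, 3L)
  expect_equal(h2$strand, "+")

  h3 <- find_sites("TTTGACGTT", "CRE_half")  # TGACG = rc(CGTCA)
  expect_equal(h3$strand, "-")

  expect_equal(nrow(find_sites("", "CRE_half")), 0)
  expect_equal(nrow(find_sites("CGNCA", "CRE_half")), 0)  # N never matches
  expect_error(find_sites("ACGT", "bogus"))
})

test_that("find_sites equals the brute-force double scan", {
  set.seed(21)
  for (s in random_dna(100, 60)) {
    for (st in c("CRE_full", "CRE_half")) {
      mine <- find_sites(s, st)
      ours <- naive_find_sites(s, if (st == "CRE_full") "TGACGTCA" else "CGTCA")
      expect_equal(mine$start, ours$start)
      expect_equal(mine$strand, ours$strand)
    }
  }
})

test_that("first_site_window applies the frozen centering rule", {
  pad <- function(n) substring(strrep("ACT", n %/% 3 + 1), 1, n)  # motif-free
  g <- list(chr1 = paste0(pad(500), "CGTCA", pad(500)))
  w <- first_site_window(g, "chr1", 480, 540, "CRE_half")
  expect_equal(w$core_start, 501L)
  expect_equal(w$start, 501L - (100L - 2L))   # core_start - (100 - floor(w/2))
  expect_equal(nchar(w$sequence), 200L)
  expect_equal(substring(w$sequence, w$core_offset, w$core_offset + 4), "CGTCA")

  # round trip: stored window sequence equals re-extraction from the genome
  expect_identical(w$sequence, substring(g$chr1, w$start, w$end))

  # site too close to the chromosome start: boundary rejection
  g2 <- list(chr1 = paste0(strrep("A", 50), "CGTCA", strrep("T", 400)))
  expect_warning(res <- first_site_window(g2, "chr1", 1, 455, "CRE_half"),
                 "clipped")
  expect_null(res)

  # leftmost occurrence wins
  g3 <- list(chr1 = paste0(strrep("A", 300), "CGTCA", strrep("C", 50),
                           "CGTCA", strrep("T", 300)))
  w3 <- first_site_window(g3, "chr1", 250, 700, "CRE_half")
  expect_equal(w3$core_start, 301L)

  # peak without any site
  expect_null(first_site_window(list(chr1 = strrep("A", 1000)), "chr1",
                                100, 300, "CRE_half"))
})

test_that("exclude_full_in_flanks implements the 15 bp rule", {
  mk_entry <- function(gap_after) {
    pre <- strrep("A", 97)
    post <- strrep("T", 200)
    seq <- paste0(pre, "CGTCA", strrep("C", gap_after), "TGACGTCA", post)
    data.frame(sequence = substring(seq, 1, 200), core_offset = 98L,
               site_type = "CRE_half", stringsAsFactors = FALSE)
  }
  expect_false(exclude_full_in_flanks(mk_entry(3)))    # inside the flank
  expect_true(exclude_full_in_flanks(mk_entry(40)))    # beyond the flank
  clean <- data.frame(sequence = paste0(strrep("A", 97), "CGTCA",
                                        strrep("T", 98)),
                      core_offset = 98L, site_type = "CRE_half")
  expect_true(exclude_full_in_flanks(clean))
})

test_that("categorize_sites applies the DNase gate and ChIP overlap rules", {
  sites <- data.frame(chrom = "c", core_start = c(100, 300, 500, 700, 900),
                      core_end = c(104, 304, 504, 704, 904))
  peak <- function(lo, hi) data.frame(chrom = "c", start = lo, end = hi)
  dnase <- do.call(rbind, lapply(c(50, 250, 450, 650), function(s)
    peak(s, s + 150)))
  chip_a <- rbind(peak(80, 180), peak(480, 580))
  chip_b <- rbind(peak(280, 380), peak(480, 580))
  cat <- categorize_sites(sites, chip_a, chip_b, dnase)
  expect_equal(cat, c("A_only", "B_only", "both", "accessible_unbound", NA))

  # partial overlap of the core does not count as "found"
  chip_edge <- peak(0, 102)   # covers only part of the first core
  cat2 <- categorize_sites(sites[1, ], chip_edge, chip_b[0, ], dnase)
  expect_equal(cat2, "accessible_unbound")
})

test_that("synthetic genome recovers every planted category exactly", {
  sim <- synth_genome_and_peaks(length_bp = 30000, n_full_sites = 6,
                                n_half_sites = 60, seed = 31)
  expect_equal(nrow(sim$truth), 66)
  expect_true(all(table(sim$truth$category[sim$truth$site_type == "CRE_half"])
                  == 15))
  # determinism
  sim2 <- synth_genome_and_peaks(length_bp = 30000, n_full_sites = 6,
                                 n_half_sites = 60, seed = 31)
  expect_identical(sim, sim2)

  # genome-wide scan finds exactly the planted half-site cores
  half <- sim$truth[sim$truth$site_type == "CRE_half", ]
  full <- sim$truth[sim$truth$site_type == "CRE_full", ]
  hits <- find_sites(sim$genome[[1]], "CRE_half")
  # a planted full site TGACGTCA carries TGACG at its start and CGTCA 3 bp in
  planted <- sort(c(half$core_start, full$core_start, full$core_start + 3L))
  expect_equal(hits$start, planted)

  # categorization over planted truth coordinates reproduces the labels
  got <- categorize_sites(sim$truth, sim$chip_a, sim$chip_b, sim$dnase)
  expect_equal(got, sim$truth$category)

  expect_error(synth_genome_and_peaks(length_bp = 1000, n_full_sites = 2,
                                      n_half_sites = 10, seed = 1),
               class = "qpid_invalid_argument")
})

test_that("extract_candidates + design_library yield a clean library", {
  sim <- synth_genome_and_peaks(length_bp = 30000, n_full_sites = 6,
                                n_half_sites = 60, seed = 32)
  suppressMessages(
    cand <- extract_candidates(sim$genome, sim$chip_a, sim$chip_b, sim$dnase))
  half_truth <- sim$truth[sim$truth$site_type == "CRE_half", ]
  # every half-site candidate corresponds to a planted site with its label
  m <- match(cand$core_start, half_truth$core_start)
  expect_false(anyNA(m))
  expect_equal(cand$category, half_truth$category[m])
  expect_true(all(nchar(cand$sequence) == 200))
  expect_true(all(vapply(seq_len(nrow(cand)), function(i)
    exclude_full_in_flanks(cand[i, ]), logical(1))))

  lib <- design_library(cand, c(A_only = 10, B_only = 10, both = 10,
                                accessible_unbound = 5), seed = 5)
  expect_equal(nrow(lib), 35)
  expect_equal(unname(table(lib$category)[c("A_only", "B_only", "both",
                                            "accessible_unbound")]),
               c(10L, 10L, 10L, 5L), ignore_attr = TRUE)
  lib2 <- design_library(cand, c(A_only = 10, B_only = 10, both = 10,
                                 accessible_unbound = 5), seed = 5)
  expect_identical(lib, lib2)

  expect_error(design_library(cand, c(A_only = 10000), seed = 1),
               class = "qpid_shortfall")
  empty <- design_library(cand, c(A_only = 0), seed = 1)
  expect_equal(nrow(empty), 0)

  # controls contain no motif at all
  ctrl <- design_library(cand, c(control = 3), seed = 2, genome = sim$genome)
  expect_equal(nrow(ctrl), 3)
  expect_true(all(vapply(ctrl$sequence, function(s)
    nrow(find_sites(s, "CRE_half")) == 0, logical(1))))
})

test_that("narrowPeak IO round-trips and validates", {
  sim <- synth_genome_and_peaks(length_bp = 30000, n_full_sites = 6,
                                n_half_sites = 60, seed = 33)
  p <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(sim$dnase, p)
  back <- read_narrowpeak(p)
  expect_equal(back$start, sort(sim$dnase$start))
  expect_equal(ncol(back), 10)

  bed3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t50", "chr1\t100\t200"), bed3)
  b <- read_narrowpeak(bed3)
  expect_equal(ncol(b), 10)
  expect_equal(b$end, c(50L, 200L))

  badf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t50\t10", badf)
  expect_error(read_narrowpeak(badf), class = "qpid_io")
})
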