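#' CRE mini-library oligonucleotide sequences
#'
#' The 32 Cy5-labeled dsDNA probes of the CRE mini-library: CRE consensus
#' (TGACGTCA), AP-1 element (TGAGTCA), CRE half-site and mutated controls
#' embedded in genomic promoter scaffolds.
#'
#' @return data.frame with columns `oligo` (id, "oligo1".."oligo32"),
#'   `sequence`, and `site` (annotated element for the characterized
#'   oligos 1-7, NA otherwise)
#' @export
cre_minilibrary <- function() {
  seqs <- c(
    "GGCCACTACCGCTTCCTCCACATGACGTCATGGTTTTCTCCACCAAGGAAGT",
    "TTATGACCTGGGAGTGACGTCATGGAATCCACAGA",
    "GGCCACTACCGCTTCCTCCACATGAGTCATGGTTTTCTCCACCAAGGAAGT",
    "TTATGACCTGGGAGTGAGTCAATGGAATCCACAGA",
    "GGCCACTACCGCTTCCTCCACATGGCGTCATGGTTTTCTCCACCAAGGAAGT",
    "TTATCCACTTGCGCTCGCCGAGTGGCGTCACCAGCGGTACTGTAATGACGAT",
    "GGCCACTACCGCTTCCTCCACAAATAAAATTGGTTTTCTCCACCAAGGAAGT",
    "GGCCACTACCGCTTCCTCCACATGAGATCATGGTTTTCTCCACCAAGGAAGT",
    "GGCCACTACCGCTTCCTCCACATGTCTACATGGTTTTCTCCACCAAGGAAGT",
    "GCAGGGACCCAAAGCAGCAGCCTGAGCTCATGATCAGAGTGAAAGGAGAAGG",
    "CAGGGACCCAAAGCAGCAGCCTGTCTACATGATCAGAGTGAAAGGAGAAGGC",
    "TTGGCCCCAGATTGCCACAGAATCCTGGTGGGGACGACGGGGGAGAGATTCC",
    "CCACGTCATTATGACCTGGGAGTGCGTGAATGGAATCCACAGATGAGGGCCC",
    "CCAAAAATTTATGACCTGGGAGTGCGTGAATGGAATCCACAGATGAGGGCCC",
    "TTATGACCTGGGAGTGCGTGAATGGAATCCACAGA",
    "TTATGACCTGGGAGTAAATGAATGGAATCCACAGA",
    "TTATGACCTGGGAGAATAAAATTGGAATCCACAGA",
    "AGCCCATTTATCCACGTCATTATGACCTGGGAG",
    "AGCCCATTTATCCAAAAATTTATGACCTGGGAG",
    "GTAATGCAGAAGTTCATTCCGACCAGTTCTTTAGCGCTTACAATGCAAAAA",
    "GTAATGCAGAAAAAATTTCCGACCAGTTCTTTAGCGCTTACAATGCAAAAA",
    "GTAATGCAGAAGTTCATAATAAATGTTCTTTAGCGCTTACAATGCAAAAAC",
    "GTAATGCAGAAGTTCATTCCGACCAGTTCTTTAATAAATCAATGCAAAAAC",
    "AAAAAAAAAAAGAAAGAAATTAAACTCAAAAATTGCATGGTTTAGAAGAGGG",
    "AAAAAAAAAAAGAAAGAAATTAAAAAATAAAATTGCATGGTTTAGAAGAGGG",
    "AAGCGGAAAGACAGAGTCACCACTACGTCACGTGGAGTCCGCTTTACAGACT",
    "AAGCGGAAAGACAGAGTCACCAAATAAAATCGTGGAGTCCGCTTTACAGACT",
    "GTGTGCGTGCTCTGAGCAGCGAGCACGTCAGACTGCGCCCAGTGGGGAGAGG",
    "GTGTGCGTGCTCTGAGCAGCGAAATAAAATGACTGCGCCCAGTGGGGAGAGG",
    "CACATGAGATCATGGGAATTTCCACCAAGGAAGTTTTCCGAGGGTTGAATGAGA",
    "CACATGAGATCATAGATTTCGAAACCAAGGAAGTTTTCCGAGGGTTGAATGAGA",
    "CTCCGGCGGTATGAC")
  site <- rep(NA_character_, 32L)
  site[1:7] <- c("CRE", "CRE", "AP-1", "AP-1", "HS", "HS", "Mutant")
  data.frame(oligo = paste0("oligo", seq_along(seqs)), sequence = seqs,
             site = site, stringsAsFactors = FALSE)
}

#' Reference dissociation constants for the CRE mini-library
#'
#' Measured Kd values (uM) of ATF1, c-Jun, c-Fos and the c-Jun/c-Fos
#' heterodimer (AP-1 complex) against the characterized CRE-element oligos.
#' Interactions weaker than the 50 uM quantitative sensitivity limit are
#' censored and stored as NA (rendered '-' in reports). These values serve
#' as the planted ground truth for full-chip simulations.
#'
#' @return data.frame with columns `oligo`, `site`, `ATF1`, `cJun`, `cFos`,
#'   `AP1` (Kd in uM, NA = censored-weak)
#' @export
reference_kd_table <- function() {
  data.frame(
    oligo = paste0("oligo", 1:7),
    site = c("CRE", "CRE", "AP-1", "AP-1", "HS", "HS", "Mutant"),
    ATF1 = c(0.04, 0.03, 11, 17, 0.17, 0.04, NA),
    cJun = c(1.3, 2.4, 2.5, NA, NA, NA, NA),
    cFos = c(NA, NA, NA, NA, NA, NA, NA),
    AP1  = c(0.19, 0.15, 0.27, 0.50, 3.5, 4.0, NA),
    stringsAsFactors = FALSE)
}
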