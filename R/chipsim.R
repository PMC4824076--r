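#' Geometric dilution series
#'
#' The device is programmed with a serial dilution for every oligonucleotide.
#' Successive concentrations keep a constant ratio `(end/start)^(1/(n-1))`
#' so the series spans the two endpoints exactly; the default 32-point series
#' runs from 2 uM down to 0.0156 uM.
#'
#' @param start highest concentration, uM
#' @param end lowest concentration, uM
#' @param n number of dilution points (>= 2)
#' @return object of class `qpid_dilution` with fields `start_conc`,
#'   `end_conc`, `n_points`, `values`
#' @export
make_dilution_series <- function(start = 2.0, end = 0.0156, n = 32L) {
  if (!is.numeric(start) || !is.numeric(end) || start <= 0 || end <= 0)
    qpid_stop("qpid_invalid_argument", "concentrations must be positive")
  if (end >= start)
    qpid_stop("qpid_invalid_argument", "series must be decreasing: start > end")
  if (n < 2)
    qpid_stop("qpid_invalid_argument", "need at least 2 dilution points")
  ratio <- (end / start)^(1 / (n - 1))
  values <- start * ratio^(seq_len(n) - 1)
  values[n] <- end  # pin the printed endpoint against rounding drift
  structure(list(start_conc = start, end_conc = end, n_points = as.integer(n),
                 values = values, ratio = ratio),
            class = "qpid_dilution")
}

#' Single-site equilibrium with ligand depletion
#'
#' Mass-action partitioning of total DNA `D_T` between solution and a fixed
#' concentration of immobilized protein sites `P_T` with dissociation
#' constant `K_d`:
#' `bound = ((D_T + P_T + K_d) - sqrt((D_T + P_T + K_d)^2 - 4 D_T P_T)) / 2`.
#' All arguments are vectorized and recycled.
#'
#' @param total_dna total DNA in the chamber, uM
#' @param protein_sites immobilized protein binding sites, uM
#' @param kd dissociation constant, uM
#' @return list with numeric vectors `bound` and `free` (uM)
#' @export
solve_equilibrium <- function(total_dna, protein_sites, kd) {
  if (any(total_dna < 0) || any(protein_sites < 0))
    qpid_stop("qpid_invalid_argument", "concentrations must be non-negative")
  if (any(kd <= 0))
    qpid_stop("qpid_invalid_argument", "kd must be positive")
  s <- total_dna + protein_sites + kd
  disc <- s * s - 4 * total_dna * protein_sites
  # conjugate form of the quadratic root: numerically stable when the
  # bound fraction is tiny (kd >> D, P), where (s - sqrt(disc)) cancels
  bound <- 2 * total_dna * protein_sites / (s + sqrt(pmax(disc, 0)))
  bound <- pmin(bound, total_dna, protein_sites)  # guard rounding at limits
  list(bound = bound, free = total_dna - bound)
}

#' Chip layout
#'
#' The device is a 64 x 64 chamber array. In `"four-section"` mode it is
#' split into four independent 32 x 32 quadrants, one protein per quadrant;
#' each (oligo, dilution) pair appears exactly once per quadrant (32 oligos x
#' 32 dilutions). In `"whole-chip"` mode a single protein is measured
#' against 128 oligos x 32 dilutions covering all 4096 chambers.
#'
#' @param mode `"four-section"` or `"whole-chip"`
#' @param proteins protein identifiers: length 4 (four-section, one per
#'   section) or length 1 (whole-chip)
#' @param oligos oligo identifiers: length 32 (four-section) or 128
#'   (whole-chip)
#' @return object of class `qpid_layout`; `$cell_map` is a data.frame with
#'   one row per chamber (`row`, `col`, `section`, `protein`, `oligo`,
#'   `dilution`, `replicate`), 1-based coordinates
#' @export
chip_layout <- function(mode = c("four-section", "whole-chip"),
                        proteins = NULL, oligos = NULL) {
  mode <- match.arg(mode)
  if (mode == "four-section") {
    if (is.null(proteins)) proteins <- paste0("protein", 1:4)
    if (is.null(oligos))   oligos   <- paste0("oligo", 1:32)
    stopifnot(length(proteins) == 4L, length(oligos) == 32L)
    grid <- expand.grid(row = 1:64, col = 1:64)
    sec_r <- (grid$row - 1L) %/% 32L          # 0/1
    sec_c <- (grid$col - 1L) %/% 32L
    section <- sec_r * 2L + sec_c + 1L        # 1..4
    lrow <- (grid$row - 1L) %% 32L + 1L       # oligo within section
    lcol <- (grid$col - 1L) %% 32L + 1L       # dilution within section
    cell_map <- data.frame(
      row = grid$row, col = grid$col, section = section,
      protein = proteins[section], oligo = oligos[lrow],
      dilution = lcol, replicate = section, stringsAsFactors = FALSE)
  } else {
    if (is.null(proteins)) proteins <- "protein1"
    if (is.null(oligos))   oligos   <- paste0("oligo", 1:128)
    stopifnot(length(proteins) == 1L, length(oligos) == 128L)
    grid <- expand.grid(col = 1:64, row = 1:64)[, c("row", "col")]
    idx <- (grid$row - 1L) * 64L + grid$col - 1L      # row-major 0..4095
    section <- ((grid$row - 1L) %/% 32L) * 2L + (grid$col - 1L) %/% 32L + 1L
    cell_map <- data.frame(
      row = grid$row, col = grid$col, section = section,
      protein = proteins, oligo = oligos[idx %/% 32L + 1L],
      dilution = idx %% 32L + 1L, replicate = 1L, stringsAsFactors = FALSE)
  }
  structure(list(n_rows = 64L, n_cols = 64L, mode = mode,
                 proteins = proteins, oligos = oligos, cell_map = cell_map),
            class = "qpid_layout")
}

#' Noise specification for the chip simulator
#'
#' Defaults follow the device characterization: protein immobilization
#' variability with a standard deviation of 6-40% of the mean (one CV drawn
#' per section), a signal-to-background ratio of about 100:1, and 5%
#' multiplicative spot/scan noise.
#'
#' @param protein_cv_range length-2 fraction pair, low/high CV of the
#'   immobilized protein level
#' @param snr signal-to-background ratio (> 1)
#' @param intensity_cv multiplicative CV applied to the spotted DNA amount
#'   of each chamber
#' @param seed integer seed governing all randomness of the simulation
#' @return object of class `qpid_noise`
#' @export
noise_spec <- function(protein_cv_range = c(0.06, 0.40), snr = 100,
                       intensity_cv = 0.05, seed = 1L) {
  stopifnot(length(protein_cv_range) == 2L)
  if (!(protein_cv_range[1] > 0 && protein_cv_range[1] <= protein_cv_range[2] &&
        protein_cv_range[2] < 1) && !all(protein_cv_range == 0))
    qpid_stop("qpid_invalid_argument", "need 0 < cv_low <= cv_high < 1")
  if (snr <= 1) qpid_stop("qpid_invalid_argument", "snr must exceed 1")
  structure(list(protein_cv_range = protein_cv_range, snr = snr,
                 intensity_cv = intensity_cv, seed = as.integer(seed)),
            class = "qpid_noise")
}

# truncated multiplicative perturbation; cv = 0 is the identity
mult_noise <- function(x, cv, n = length(x)) {
  if (cv <= 0) return(x)
  x * pmax(1 + cv * rnorm(n), 0)
}

#' Simulate a full chip scan
#'
#' Emulates one device run: per chamber the spotted DNA amount is perturbed
#' multiplicatively, the immobilized protein level is drawn with a
#' per-section CV, the single-site equilibrium is solved, and the three
#' fluorescence channels (solution DNA in the chamber, bound DNA under the
#' button, protein under the button) are produced by applying a linear
#' fluorescence response plus a local background equal to signal/SNR.
#' The recorded background columns are the local background estimates
#' (the background level without the chamber's own jitter), mirroring a
#' spot-quantification workflow.
#'
#' @param layout a [chip_layout()]
#' @param truths data.frame with columns `protein`, `oligo`, `kd_uM` giving
#'   the ground-truth dissociation constant for every mapped pair
#' @param spotted_concs a [make_dilution_series()]
#' @param noise a [noise_spec()]
#' @param calibration a [calibration_curve()] used as the fluorescence
#'   response of the solution-DNA channel; the bound-DNA channel uses the
#'   same slope through zero, the protein channel uses `protein_scale`
#' @param protein_sites_uM mean immobilized protein site concentration, uM
#' @param protein_scale protein-channel fluorescence response, RFU per uM
#' @return a scan table data.frame (see [read_scan_table()] for the schema)
#'   with the layout columns `protein`, `oligo`, `dilution` appended
#' @export
simulate_chip <- function(layout, truths, spotted_concs = make_dilution_series(),
                          noise = noise_spec(),
                          calibration = calibration_curve(35579, 0),
                          protein_sites_uM = 0.1, protein_scale = 20000) {
  stopifnot(inherits(layout, "qpid_layout"), inherits(noise, "qpid_noise"))
  cm <- layout$cell_map
  key <- paste(cm$protein, cm$oligo)
  tkey <- paste(truths$protein, truths$oligo)
  if (!all(key %in% tkey))
    qpid_stop("qpid_configuration",
              "missing kd truth for mapped pair(s): %s",
              paste(unique(key[!key %in% tkey])[1:3], collapse = ", "))
  kd <- truths$kd_uM[match(key, tkey)]
  n <- nrow(cm)
  set.seed(derive_seed(noise$seed, "simulate_chip"))

  d_total <- mult_noise(spotted_concs$values[cm$dilution], noise$intensity_cv, n)
  cv_sec <- if (diff(noise$protein_cv_range) == 0) rep(noise$protein_cv_range[1], 4)
            else runif(4, noise$protein_cv_range[1], noise$protein_cv_range[2])
  prot <- pmax(protein_sites_uM * (1 + cv_sec[cm$section] * rnorm(n)), 1e-6)
  eq <- solve_equilibrium(d_total, prot, kd)

  sig_ch <- pmax(calibration$slope * eq$free + calibration$intercept, 0)
  sig_bd <- calibration$slope * eq$bound
  sig_pr <- protein_scale * prot

  # local background per chamber: level = signal/SNR; the true background
  # jitters 10% around the level, the recorded column is the level itself
  mk_bg <- function(sig) {
    level <- if (is.finite(noise$snr)) sig / noise$snr else numeric(n)
    list(true = pmax(level * (1 + 0.1 * rnorm(n)), 0), est = level)
  }
  bch <- mk_bg(sig_ch); bbd <- mk_bg(sig_bd); bpr <- mk_bg(sig_pr)

  data.frame(
    row = cm$row, col = cm$col, section = cm$section,
    chamber_dna = sig_ch + bch$true,
    button_dna = sig_bd + bbd$true,
    button_protein = sig_pr + bpr$true,
    bg_chamber = bch$est, bg_button_dna = bbd$est, bg_button_protein = bpr$est,
    protein = cm$protein, oligo = cm$oligo, dilution = cm$dilution,
    stringsAsFactors = FALSE)
}

#' Simulate a calibration series
#'
#' Generates (concentration, intensity) standards from a linear fluorescence
#' response with multiplicative Gaussian noise, emulating the on-chip
#' calibration experiment with labeled oligonucleotides at known
#' concentrations. Concentrations are geometrically spaced (a serial
#' dilution of the standard), 128 points over 0.005-1 uM by default.
#'
#' @param curve a [calibration_curve()]; default is the device line
#'   y = 35579 x - 1471
#' @param n number of standards
#' @param conc_range length-2 range in uM
#' @param cv multiplicative noise CV
#' @param seed integer seed
#' @return data.frame with columns `conc_uM`, `intensity`
#' @export
simulate_calibration_series <- function(curve = calibration_curve(35579, -1471),
                                        n = 128L, conc_range = c(0.005, 1),
                                        cv = 0.05, seed = 1L) {
  set.seed(derive_seed(seed, "calibration_series"))
  conc <- exp(seq(log(conc_range[1]), log(conc_range[2]), length.out = n))
  intensity <- (curve$slope * conc + curve$intercept) * (1 + cv * rnorm(n))
  data.frame(conc_uM = conc, intensity = intensity)
}
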