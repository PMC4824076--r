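#' Calibration curve
#'
#' Linear fluorescence response `intensity = slope * conc + intercept`
#' relating solution DNA concentration to scanner intensity. The bundled
#' device line is y = 35579 x - 1471 (RFU vs uM, fitted on 128 standards).
#'
#' @param slope RFU per uM, must be positive
#' @param intercept RFU
#' @param n_points number of standards behind the fit
#' @param r_squared coefficient of determination of the fit
#' @return object of class `qpid_calibration`
#' @export
calibration_curve <- function(slope, intercept = 0, n_points = 2L,
                              r_squared = NA_real_) {
  if (!is.numeric(slope) || slope <= 0)
    qpid_stop("qpid_invalid_curve", "calibration slope must be positive")
  structure(list(slope = slope, intercept = intercept,
                 n_points = as.integer(n_points), r_squared = r_squared),
            class = "qpid_calibration")
}

#' Fit the fluorescence calibration line
#'
#' Ordinary least squares of raw intensity on concentration. An
#' unconstrained two-parameter line is fitted (the intercept is free).
#'
#' @param points data.frame with columns `conc_uM` and `intensity`
#' @return a [calibration_curve()] carrying `n_points` and `r_squared`
#' @export
fit_calibration <- function(points) {
  stopifnot(all(c("conc_uM", "intensity") %in% names(points)))
  conc <- points$conc_uM; intensity <- points$intensity
  if (length(unique(conc)) < 2L)
    qpid_stop("qpid_degenerate_fit",
              "all calibration concentrations identical; cannot fit a line")
  if (any(conc < 0.005 - 1e-12) || any(conc > 1 + 1e-12))
    warning("calibration concentrations outside the characterized 0.005-1 uM range")
  fit <- lm(intensity ~ conc)
  cf <- coef(fit)
  # summary.lm warns on exact-line input ("essentially perfect fit")
  r2 <- if (all(intensity == intensity[1])) 0
        else suppressWarnings(summary(fit)$r.squared)
  if (cf[["conc"]] <= 0)
    qpid_stop("qpid_invalid_curve", "fitted calibration slope is non-positive")
  calibration_curve(cf[["conc"]], cf[["(Intercept)"]],
                    n_points = length(conc), r_squared = r2)
}

#' Convert intensity to concentration
#'
#' Inverts the calibration line: `conc = (intensity - intercept) / slope`.
#' Values below the line's x-intercept clamp to 0 uM with a warning so that
#' sparse noise at the lowest dilutions does not abort a full-chip run.
#'
#' @param curve a [calibration_curve()]
#' @param intensity RFU, vectorized
#' @return concentrations in uM
#' @export
intensity_to_conc <- function(curve, intensity) {
  if (!inherits(curve, "qpid_calibration") || curve$slope <= 0)
    qpid_stop("qpid_invalid_curve", "invalid calibration curve")
  conc <- (intensity - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning(sprintf("%d intensity value(s) below the calibration intercept; clamped to 0 uM",
                    sum(conc < 0)))
    conc <- pmax(conc, 0)
  }
  conc
}

#' Background-corrected occupancy ratio
#'
#' Ratio of bound-DNA to protein fluorescence under the button valve, each
#' locally background-corrected; proportional to DNA molecules bound per
#' immobilized protein (fractional occupancy). A negative DNA numerator
#' clamps to zero; a protein signal at or below its background is a
#' no-protein condition.
#'
#' @param button_dna,button_dna_bg bound-DNA signal and local background
#' @param button_protein,button_protein_bg protein signal and local background
#' @return dimensionless ratio(s)
#' @export
compute_ratio <- function(button_dna, button_dna_bg,
                          button_protein, button_protein_bg) {
  prot <- button_protein - button_protein_bg
  if (any(prot <= 0))
    qpid_stop("qpid_no_protein",
              "protein signal at or below background in %d cell(s)",
              sum(prot <= 0))
  pmax(button_dna - button_dna_bg, 0) / prot
}

#' Quantify a scan table
#'
#' Per-chamber free DNA concentration (from the chamber channel via the
#' calibration curve) and the background-corrected bound/protein occupancy
#' ratio. Chambers whose protein signal does not rise above background are
#' flagged unusable and excluded from fitting rather than erroring.
#'
#' @param scan scan table data.frame (see [read_scan_table()]); must carry
#'   `protein`, `oligo`, `dilution` annotation columns (joined from the
#'   layout if absent, see [annotate_scan()])
#' @param curve a [calibration_curve()]
#' @return occupancy data.frame: `protein`, `oligo`, `dilution`, `section`,
#'   `free_conc`, `ratio`, `usable`
#' @export
quantify_scan <- function(scan, curve) {
  needed <- c("chamber_dna", "button_dna", "button_protein",
              "bg_chamber", "bg_button_dna", "bg_button_protein",
              "protein", "oligo", "dilution")
  stopifnot(all(needed %in% names(scan)))
  usable <- (scan$button_protein - scan$bg_button_protein) > 0
  if (!all(usable))
    message(sprintf("%d chamber(s) flagged no-protein and excluded", sum(!usable)))
  ratio <- rep(NA_real_, nrow(scan))
  if (any(usable))
    ratio[usable] <- compute_ratio(scan$button_dna[usable],
                                   scan$bg_button_dna[usable],
                                   scan$button_protein[usable],
                                   scan$bg_button_protein[usable])
  free_conc <- suppressWarnings(
    intensity_to_conc(curve, scan$chamber_dna - scan$bg_chamber))
  data.frame(protein = scan$protein, oligo = scan$oligo,
             dilution = scan$dilution, section = scan$section,
             free_conc = free_conc, ratio = ratio, usable = usable,
             stringsAsFactors = FALSE)
}

#' Attach layout annotation to a bare scan table
#'
#' @param scan scan table with `row`, `col` columns
#' @param layout a [chip_layout()]
#' @return scan with `protein`, `oligo`, `dilution` columns appended
#' @export
annotate_scan <- function(scan, layout) {
  cm <- layout$cell_map
  i <- match(paste(scan$row, scan$col), paste(cm$row, cm$col))
  if (anyNA(i)) qpid_stop("qpid_configuration", "scan contains unmapped cells")
  cbind(scan, cm[i, c("protein", "oligo", "dilution")])
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate replicate chambers
#'
#' Collapses the usable replicate measurements of one (protein, oligo,
#' dilution) combination — the four chip sections when they carry the same
#' protein — to a mean ratio, population SD, and mean calibrated free
#' concentration.
#'
#' @param occupancy output of [quantify_scan()]
#' @return data.frame with one row per (protein, oligo, dilution):
#'   `free_conc`, `ratio`, `ratio_sd`, `n_replicates`
#' @export
aggregate_replicates <- function(occupancy) {
  ok <- occupancy[occupancy$usable & !is.na(occupancy$ratio), , drop = FALSE]
  if (nrow(ok) == 0L)
    qpid_stop("qpid_missing_data", "no usable occupancy records to aggregate")
  key <- interaction(ok$protein, ok$oligo, ok$dilution, drop = TRUE, sep = "\r")
  agg <- lapply(split(ok, key), function(g)
    data.frame(protein = g$protein[1], oligo = g$oligo[1],
               dilution = g$dilution[1],
               free_conc = mean(g$free_conc), ratio = mean(g$ratio),
               ratio_sd = pop_sd(g$ratio), n_replicates = nrow(g),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$protein, out$oligo, out$dilution), , drop = FALSE]
}
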