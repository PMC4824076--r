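#' Assemble per-pair binding series
#'
#' Groups aggregated occupancy records into one binding series per
#' (protein, oligo) pair. Points with non-positive calibrated free
#' concentration are dropped; a series with fewer than 4 usable
#' concentrations is flagged unfittable.
#'
#' @param occupancy output of [aggregate_replicates()]
#' @return named list of `qpid_series` objects, names `protein|oligo`;
#'   each has `protein`, `oligo`, `points` (data.frame `free_conc`,
#'   `ratio`, `sd`, `n`) and `fittable`
#' @export
assemble_series <- function(occupancy) {
  key <- paste(occupancy$protein, occupancy$oligo, sep = "|")
  lapply(split(occupancy, key), function(g) {
    dropped <- sum(g$free_conc <= 0)
    g <- g[g$free_conc > 0, , drop = FALSE]
    if (dropped > 0)
      message(sprintf("%s/%s: dropped %d point(s) with free concentration <= 0",
                      g$protein[1], g$oligo[1], dropped))
    structure(list(protein = g$protein[1], oligo = g$oligo[1],
                   points = data.frame(free_conc = g$free_conc,
                                       ratio = g$ratio, sd = g$ratio_sd,
                                       n = g$n_replicates),
                   fittable = length(unique(g$free_conc)) >= 4L),
              class = "qpid_series")
  })
}

# profiled residual sum of squares: for fixed kd the saturation level has
# the closed form rmax = sum(r*x)/sum(x^2), x = c/(kd + c)
profile_rss <- function(log10_kd, conc, ratio) {
  x <- conc / (10^log10_kd + conc)
  rmax <- sum(ratio * x) / sum(x * x)
  sum((ratio - rmax * x)^2)
}

#' Estimate a dissociation constant from a binding series
#'
#' Unweighted nonlinear least squares of the single-site isotherm
#' `ratio = Rmax * c / (Kd + c)` on the measured free concentration `c`.
#' Because free DNA is measured directly in each chamber, the simple
#' hyperbola is valid even under ligand depletion. The Kd is profiled out on
#' a log scale with multi-start initialization at the minimum, geometric
#' mean and maximum observed concentrations (ties broken by lowest RSS,
#' then smallest Kd). Fits outside the quantitative range of the assay are
#' censored: above `upper_limit` (default 50 uM) or with relative standard
#' error above 100% as `censored_weak` (reported '-'), below `lower_limit`
#' (default 1e-3 uM) as `censored_strong`.
#'
#' @param series a `qpid_series` from [assemble_series()]
#' @param lower_limit,upper_limit censoring thresholds, uM
#' @return object of class `qpid_kdfit`: `kd`, `rmax`, `kd_se`, `rss`,
#'   `converged`, `status`, `n_points`
#' @export
fit_kd <- function(series, lower_limit = 1e-3, upper_limit = 50) {
  stopifnot(inherits(series, "qpid_series"))
  mk <- function(kd = NA_real_, rmax = NA_real_, kd_se = NA_real_,
                 rss = NA_real_, converged = FALSE, status = "failed")
    structure(list(protein = series$protein, oligo = series$oligo,
                   kd = kd, rmax = rmax, kd_se = kd_se, rss = rss,
                   converged = converged, status = status,
                   n_points = nrow(series$points)), class = "qpid_kdfit")
  if (!isTRUE(series$fittable)) return(mk(status = "failed"))
  conc <- series$points$free_conc; ratio <- series$points$ratio
  starts <- log10(c(min(conc), exp(mean(log(conc))), max(conc)))
  fits <- lapply(starts, function(s)
    tryCatch(nlminb(s, profile_rss, conc = conc, ratio = ratio,
                    lower = -6, upper = 5),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) return(mk(status = "failed"))
  fits <- fits[ok]
  rss <- vapply(fits, function(f) f$objective, numeric(1))
  kds <- 10^vapply(fits, function(f) f$par, numeric(1))
  best <- order(rss, kds)[1]
  kd <- kds[best]
  x <- conc / (kd + conc)
  rmax <- sum(ratio * x) / sum(x * x)
  # delta-method SE from the Jacobian of (rmax, kd)
  J <- cbind(x, -rmax * conc / (kd + conc)^2)
  dof <- length(conc) - 2L
  kd_se <- tryCatch({
    sigma2 <- rss[best] / max(dof, 1L)
    sqrt(sigma2 * solve(crossprod(J))[2, 2])
  }, error = function(e) Inf)
  # a series that a straight line through the origin (the kd -> Inf limit of
  # the isotherm) explains as well as the hyperbola does not constrain kd
  lin_rss <- {
    m <- sum(ratio * conc) / sum(conc * conc)
    sum((ratio - m * conc)^2)
  }
  f_stat <- if (rss[best] <= 0) Inf
            else (lin_rss - rss[best]) / (rss[best] / max(dof, 1L))
  unconstrained <- !is.finite(kd_se) || kd_se / kd > 1 ||
    f_stat < stats::qf(0.95, 1, max(dof, 1L))
  status <- if (kd > upper_limit || unconstrained) "censored_weak"
  else if (kd < lower_limit) "censored_strong" else "quantitative"
  mk(kd = kd, rmax = rmax, kd_se = kd_se, rss = rss[best],
     converged = TRUE, status = status)
}

#' @export
format.qpid_kdfit <- function(x, digits = 3, ...) {
  if (x$status == "censored_weak" || x$status == "failed") "-"
  else if (x$status == "censored_strong") sprintf("<%g", 1e-3)
  else as.character(signif(x$kd, digits))
}

#' @export
print.qpid_kdfit <- function(x, ...) {
  cat(sprintf("Kd fit %s/%s: %s uM (status %s, n=%d)\n",
              x$protein, x$oligo, format(x), x$status, x$n_points))
  invisible(x)
}

#' Fit every series of a chip run
#'
#' @param series_list output of [assemble_series()]
#' @param ... passed to [fit_kd()]
#' @return data.frame `protein`, `oligo`, `kd_uM`, `kd_se`, `rmax`,
#'   `status`, `n_points`
#' @export
fit_all_kd <- function(series_list, ...) {
  rows <- lapply(series_list, function(s) {
    f <- fit_kd(s, ...)
    data.frame(protein = f$protein, oligo = f$oligo, kd_uM = f$kd,
               kd_se = f$kd_se, rmax = f$rmax, status = f$status,
               n_points = f$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Group affinity summary
#'
#' Mean and population standard deviation of the quantitative Kd values in a
#' group; for a pair the population SD equals half the absolute difference.
#' Censored values (NA) are excluded and counted.
#'
#' @param kds numeric Kd values, uM; NA marks censored entries
#' @param label group label
#' @return object of class `qpid_summary`: `label`, `mean_kd`, `spread`,
#'   `n`, `n_censored`; or an empty-summary marker when all are censored
#' @export
summarize_group <- function(kds, label = "") {
  cen <- sum(is.na(kds)); kds <- kds[!is.na(kds)]
  if (length(kds) == 0L)
    return(structure(list(label = label, mean_kd = NA_real_, spread = NA_real_,
                          n = 0L, n_censored = cen, empty = TRUE),
                     class = "qpid_summary"))
  structure(list(label = label, mean_kd = mean(kds), spread = pop_sd(kds),
                 n = length(kds), n_censored = cen, empty = FALSE),
            class = "qpid_summary")
}

#' @export
print.qpid_summary <- function(x, ...) {
  if (x$empty) cat(sprintf("%s: all %d values censored\n", x$label, x$n_censored))
  else cat(sprintf("%s: %g +/- %g uM (n=%d, %d censored)\n",
                   x$label, x$mean_kd, x$spread, x$n, x$n_censored))
  invisible(x)
}

kd_to_affinity <- function(kd, status) {
  # censored-weak interactions are below detection: affinity contribution 0
  ifelse(!is.na(status) & status == "censored_weak", 0,
         ifelse(is.na(kd), NA_real_, 1 / kd))
}

#' Affinity difference between two fits
#'
#' Difference of affinity constants `1/Kd_a - 1/Kd_b` for one oligo.
#' A `censored_weak` fit contributes affinity 0 (below detection); if both
#' fits are censored the difference is the missing marker `NA`.
#'
#' @param kd_a,kd_b `qpid_kdfit` objects, or numeric Kd values (uM) with NA
#'   meaning censored-weak
#' @return difference in 1/uM
#' @export
affinity_difference <- function(kd_a, kd_b) {
  get <- function(f) {
    if (inherits(f, "qpid_kdfit")) kd_to_affinity(f$kd, f$status)
    else ifelse(is.na(f), 0, 1 / f)
  }
  a <- get(kd_a); b <- get(kd_b)
  both_cens <- (inherits(kd_a, "qpid_kdfit") && kd_a$status != "quantitative" &&
                inherits(kd_b, "qpid_kdfit") && kd_b$status != "quantitative") ||
    (is.numeric(kd_a) && is.numeric(kd_b) && is.na(kd_a) && is.na(kd_b))
  if (both_cens) return(NA_real_)
  a - b
}

#' Rank-based group comparisons
#'
#' One-sided rank tests between affinity categories: `"unpaired-rank"` is
#' the Wilcoxon rank-sum test of two independent groups;
#' `"paired-signed-rank"` is the Wilcoxon signed-rank test over per-oligo
#' differences. Degenerate inputs (all ties / all zero differences) return
#' p = 1 with a warning.
#'
#' @param x,y numeric vectors: the two groups (unpaired) or the paired
#'   samples; for the paired mode `y` may be omitted if `x` already holds
#'   differences
#' @param mode `"unpaired-rank"` or `"paired-signed-rank"`
#' @param alternative passed to [stats::wilcox.test()]; default `"greater"`
#'   (x stochastically larger)
#' @return list with `statistic` and `p_value`
#' @export
compare_groups <- function(x, y = NULL,
                           mode = c("unpaired-rank", "paired-signed-rank"),
                           alternative = "greater") {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  if (mode == "unpaired-rank") {
    y <- y[!is.na(y)]
    if (length(unique(c(x, y))) == 1L) {
      warning("degenerate comparison: all values tied; p = 1")
      return(list(statistic = NA_real_, p_value = 1))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                       exact = FALSE, correct = TRUE))
  } else {
    d <- if (is.null(y)) x else { stopifnot(length(x) == length(y)); x - y }
    d <- d[!is.na(d)]
    if (all(d == 0)) {
      warning("degenerate comparison: all paired differences zero; p = 1")
      return(list(statistic = NA_real_, p_value = 1))
    }
    wt <- suppressWarnings(wilcox.test(d, alternative = alternative,
                                       exact = FALSE, correct = TRUE))
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
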