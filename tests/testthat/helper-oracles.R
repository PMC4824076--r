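# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: bisection instead of the closed form, exhaustive
# grids instead of optimization, per-position loops instead of vectorized
# windows, and bit-level enumeration instead of binomial sums.

# mass-action bisection: solve bound * kd = (D - bound) * (P - bound)
bisect_equilibrium <- function(total_dna, protein_sites, kd) {
  f <- function(b) b * kd - (total_dna - b) * (protein_sites - b)
  lo <- 0; hi <- min(total_dna, protein_sites)
  if (hi == 0) return(list(bound = 0, free = total_dna))
  for (i in 1:200) {   # full 200 halvings: converges to machine precision
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  b <- (lo + hi) / 2
  list(bound = b, free = total_dna - b)
}

# exhaustive 2-D grid search over (kd, rmax)
grid_search_kd <- function(conc, ratio, n_kd = 100, n_rmax = 100,
                           kd_range = c(1e-4, 1e4),
                           rmax_range = NULL) {
  if (is.null(rmax_range)) rmax_range <- c(1e-6, 4 * max(ratio))
  kds <- exp(seq(log(kd_range[1]), log(kd_range[2]), length.out = n_kd))
  rmaxs <- seq(rmax_range[1], rmax_range[2], length.out = n_rmax)
  best <- list(rss = Inf)
  for (kd in kds) {
    x <- conc / (kd + conc)
    for (rm in rmaxs) {
      rss <- sum((ratio - rm * x)^2)
      if (rss < best$rss) best <- list(rss = rss, kd = kd, rmax = rm)
    }
  }
  best$log_step <- diff(log(kd_range)) / (n_kd - 1)
  best$rm_step <- diff(rmax_range) / (n_rmax - 1)
  best
}

# RSS variation across one grid cell around the grid optimum: the tolerance
# within which optimizer and grid minima must agree
grid_cell_tol <- function(conc, ratio, g) {
  vals <- c()
  for (kd in g$kd * exp(c(-1, 0, 1) * g$log_step))
    for (rm in g$rmax + c(-1, 0, 1) * g$rm_step) {
      x <- conc / (kd + conc)
      vals <- c(vals, sum((ratio - rm * x)^2))
    }
  max(vals) - g$rss
}

# naive per-position shape prediction: direct lookups, no shared windows
naive_predict_shape <- function(seq, table) {
  L <- nchar(seq)
  look <- function(p, col) {
    i <- which(table$pentamer == p)
    table[[col]][i]
  }
  pent_at <- function(c) if (c >= 3 && c <= L - 2)
    substring(seq, c - 2, c + 2) else NA
  step_val <- function(j, left_col, right_col) {
    vals <- c()
    pj <- pent_at(j)
    if (!is.na(pj)) vals <- c(vals, look(pj, right_col))
    pj1 <- pent_at(j + 1)
    if (!is.na(pj1)) vals <- c(vals, look(pj1, left_col))
    if (length(vals) == 0) NA_real_ else mean(vals)
  }
  out <- data.frame(pos = 1:L, mgw = NA_real_, prot = NA_real_,
                    roll = NA_real_, helt = NA_real_)
  for (i in 3:(L - 2)) {
    p <- pent_at(i)
    out$mgw[i] <- look(p, "mgw")
    out$prot[i] <- look(p, "prot")
    out$roll[i] <- mean(c(step_val(i - 1, "roll_left", "roll_right"),
                          step_val(i, "roll_left", "roll_right")))
    out$helt[i] <- mean(c(step_val(i - 1, "helt_left", "helt_right"),
                          step_val(i, "helt_left", "helt_right")))
  }
  out
}

# brute-force motif scan: forward scan of sequence and of its reverse
# complement, no regex machinery
naive_find_sites <- function(seq, motif) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  w <- nchar(motif); L <- nchar(seq)
  hits <- data.frame(start = integer(0), strand = character(0))
  if (L >= w) for (i in 1:(L - w + 1)) {
    sub <- substring(seq, i, i + w - 1)
    if (sub == motif) hits <- rbind(hits, data.frame(start = i, strand = "+"))
    else if (sub == rc(motif))
      hits <- rbind(hits, data.frame(start = i, strand = "-"))
  }
  hits
}

# exact tail probability by bit enumeration over all 2^n outcomes
enum_binomial_tail <- function(n, k) {
  stopifnot(n <= 20)
  hits <- 0L
  for (m in 0:(2^n - 1)) {
    ones <- sum(as.integer(intToBits(m))[1:n])
    if (ones >= k) hits <- hits + 1L
  }
  hits / 2^n
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

rc_str <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                            collapse = "")

# noiseless or multiplicatively perturbed isotherm series on the standard
# 32-point dilution grid
make_series <- function(kd, rmax = 1, eps = 0,
                        conc = make_dilution_series()$values) {
  ratio <- rmax * conc / (kd + conc) * (1 + eps)
  occ <- data.frame(protein = "p", oligo = "o", dilution = seq_along(conc),
                    free_conc = conc, ratio = ratio, ratio_sd = 0,
                    n_replicates = 1L)
  assemble_series(occ)[[1]]
}

fixture_shape_table <- function() {
  if (is.null(.qpid_test_env$shape_table))
    .qpid_test_env$shape_table <- synth_pentamer_table(seed = 42)
  .qpid_test_env$shape_table
}
.qpid_test_env <- new.env()

# block-wise reversal of a feature vector: the layout a reverse-complemented
# site produces (each 2k+w block flips 5'->3')
rev_fvec_oracle <- function(v, w, k) {
  blk <- 2 * k + w
  out <- as.numeric(v)
  for (b in 0:3) out[b * blk + 1:blk] <- rev(out[b * blk + 1:blk])
  structure(out, w = as.integer(w), k = as.integer(k),
            block_order = attr(v, "block_order"), class = "qpid_fvec")
}
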