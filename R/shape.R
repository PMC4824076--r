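#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Validate a pentamer shape table
#'
#' Checks the shape-table contract: all 1024 pentamers present exactly once
#' and reverse-complement symmetry — `mgw(p) = mgw(rc(p))`,
#' `prot(p) = prot(rc(p))`, `roll_left(p) = roll_right(rc(p))`,
#' `helt_left(p) = helt_right(rc(p))`.
#'
#' @param table data.frame with columns `pentamer`, `mgw`, `prot`,
#'   `roll_left`, `roll_right`, `helt_left`, `helt_right`
#' @param tol numeric tolerance for the symmetry checks
#' @return invisibly TRUE; errors on violation
#' @export
validate_shape_table <- function(table, tol = 1e-9) {
  need <- c("pentamer", "mgw", "prot", "roll_left", "roll_right",
            "helt_left", "helt_right")
  if (!all(need %in% names(table)))
    qpid_stop("qpid_shape_table", "missing columns: %s",
              paste(setdiff(need, names(table)), collapse = ", "))
  all5 <- apply(expand.grid(DNA_BASES4, DNA_BASES4, DNA_BASES4,
                            DNA_BASES4, DNA_BASES4), 1, paste, collapse = "")
  if (!setequal(table$pentamer, all5) || anyDuplicated(table$pentamer))
    qpid_stop("qpid_shape_table", "table must contain each of the 1024 pentamers once")
  i <- match(revcomp_chr(table$pentamer), table$pentamer)
  ok <- max(abs(table$mgw - table$mgw[i]),
            abs(table$prot - table$prot[i]),
            abs(table$roll_left - table$roll_right[i]),
            abs(table$helt_left - table$helt_right[i])) <= tol
  if (!ok)
    qpid_stop("qpid_shape_table", "reverse-complement symmetry violated")
  invisible(TRUE)
}

#' Synthetic pentamer shape table
#'
#' Generates a stand-in pentamer lookup table with the structure of a
#' published shape query table: minor groove width (MGW, Angstrom) and
#' propeller twist (ProT, degrees) per pentamer, plus left/right base-pair
#' step values for roll and helix twist (degrees). Values are drawn per
#' reverse-complement pentamer pair so the symmetry contract of
#' [validate_shape_table()] holds by construction, stay inside plausible
#' physical ranges (MGW 2.8-6.2 A, ProT -17..-1 deg, Roll -9..9 deg, HelT
#' 30-40 deg), and encode A/T-tract minor-groove narrowing (MGW and ProT
#' decrease with the pentamer's A/T content), so A-tracts have narrow
#' grooves as in real DNA. It is synthetic: its values do not reproduce any
#' published table.
#'
#' @param seed integer seed
#' @return data.frame in the [validate_shape_table()] schema
#' @export
synth_pentamer_table <- function(seed = 1L) {
  set.seed(derive_seed(seed, "pentamer_table"))
  all5 <- apply(expand.grid(DNA_BASES4, DNA_BASES4, DNA_BASES4,
                            DNA_BASES4, DNA_BASES4), 1, paste, collapse = "")
  rc <- revcomp_chr(all5)
  canon <- pmin(all5, rc)
  reps <- sort(unique(canon))                      # 512 rc-pair representatives
  at <- vapply(strsplit(reps, ""), function(b) sum(b %in% c("A", "T")),
               numeric(1))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  n <- length(reps)
  val <- data.frame(
    pentamer = reps,
    mgw  = clamp(5.35 - 0.38 * at + 0.15 * rnorm(n), 2.8, 6.2),
    prot = clamp(-5.5 - 1.4 * at + 0.8 * rnorm(n), -17, -1),
    roll_left  = clamp(rnorm(n, 0, 3), -9, 9),
    roll_right = clamp(rnorm(n, 0, 3), -9, 9),
    helt_left  = clamp(rnorm(n, 34.5, 1.4), 30, 40),
    helt_right = clamp(rnorm(n, 34.5, 1.4), 30, 40),
    stringsAsFactors = FALSE)
  j <- match(canon, reps)
  out <- val[j, ]
  out$pentamer <- all5
  flip <- all5 != canon                            # rc partner: swap step sides
  rl <- out$roll_left; out$roll_left[flip] <- out$roll_right[flip]
  out$roll_right[flip] <- rl[flip]
  hl <- out$helt_left; out$helt_left[flip] <- out$helt_right[flip]
  out$helt_right[flip] <- hl[flip]
  rownames(out) <- NULL
  validate_shape_table(out)
  out
}

#' Predict per-base DNA shape tracks
#'
#' Sliding-pentamer shape prediction. Position i (1-based, 3 <= i <= L-2)
#' takes MGW and ProT from the pentamer centered at i. Roll and HelT are
#' base-pair-step parameters: the step between bases (j, j+1) is the mean of
#' the right-step value of the pentamer centered at j and the left-step
#' value of the pentamer centered at j+1 (whichever are defined); position
#' i's per-base value is the mean of its two flanking steps. This yields one
#' value per base so all four tracks align, and is strand-symmetric. The
#' first two and last two positions are undefined (NA).
#'
#' @param seq DNA string (ACGT only)
#' @param table pentamer shape table (see [validate_shape_table()])
#' @return data.frame with columns `pos`, `mgw`, `prot`, `roll`, `helt`,
#'   `defined`
#' @export
predict_shape <- function(seq, table) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    qpid_stop("qpid_invalid_sequence", "sequence contains non-ACGT characters")
  L <- nchar(seq)
  if (L < 5)
    qpid_stop("qpid_invalid_sequence", "sequence shorter than a pentamer")
  centers <- 3:(L - 2)
  pent <- substring(seq, centers - 2, centers + 2)
  i <- match(pent, table$pentamer)
  mgw <- prot <- roll <- helt <- rep(NA_real_, L)
  mgw[centers] <- table$mgw[i]
  prot[centers] <- table$prot[i]
  # steps j -> (j, j+1), j = 2..L-2; contributions from pentamers j and j+1
  step_mean <- function(left_col, right_col) {
    sr <- sl <- rep(NA_real_, L)                   # indexed by step start j
    sr[centers] <- table[[right_col]][i]           # pentamer j, right step
    sl[centers - 1L] <- table[[left_col]][i]       # pentamer j+1, left step
    num <- ifelse(is.na(sr), 0, sr) + ifelse(is.na(sl), 0, sl)
    den <- (!is.na(sr)) + (!is.na(sl))
    ifelse(den > 0, num / den, NA_real_)
  }
  roll_step <- step_mean("roll_left", "roll_right")
  helt_step <- step_mean("helt_left", "helt_right")
  per_base <- function(step) {
    v <- rep(NA_real_, L)
    v[centers] <- (step[centers - 1L] + step[centers]) / 2
    v
  }
  roll <- per_base(roll_step); helt <- per_base(helt_step)
  data.frame(pos = seq_len(L), mgw = mgw, prot = prot, roll = roll,
             helt = helt, defined = seq_len(L) %in% centers)
}

SHAPE_BLOCKS <- c("HelT", "MGW", "Roll", "ProT")  # frozen serialization order

#' Build a shape feature vector for a core site with flanks
#'
#' Concatenates the four per-base shape tracks over the core of width `w`
#' plus `k` flanking bases on each side into a single `4(2k+w)`-long vector
#' (block order HelT, MGW, Roll, ProT, each block 5'->3'). The sequence
#' must extend at least `k + 2` bases beyond the core on both sides so that
#' every included position has a defined pentamer value.
#'
#' @param seq DNA string
#' @param core_start 1-based start of the core within `seq`
#' @param w core width, bp
#' @param k flank width, bp
#' @param table pentamer shape table
#' @return numeric vector of length `4(2k+w)` with attributes `w`, `k`,
#'   `block_order`, class `qpid_fvec`
#' @export
build_feature_vector <- function(seq, core_start, w, k, table) {
  L <- nchar(seq)
  lo <- core_start - k; hi <- core_start + w - 1 + k
  if (lo < 3 || hi > L - 2)
    qpid_stop("qpid_context",
              "need %d defined flank positions: core [%d,%d] in %d bp leaves a shortfall of %d bp",
              k, core_start, core_start + w - 1, L,
              max(3 - lo, hi - (L - 2)))
  tr <- predict_shape(seq, table)
  idx <- lo:hi
  v <- c(tr$helt[idx], tr$mgw[idx], tr$roll[idx], tr$prot[idx])
  structure(v, w = as.integer(w), k = as.integer(k),
            block_order = SHAPE_BLOCKS, class = "qpid_fvec")
}

#' Average reference shape profile over aligned sites
#'
#' Element-wise mean feature vector over a set of binding sites that are all
#' the same length with the core at the same offset (minus-strand sites must
#' be reverse-complemented before calling).
#'
#' @param sites character vector of aligned site sequences
#' @param core_start,w,k as in [build_feature_vector()]
#' @param table pentamer shape table
#' @param label source label
#' @return object of class `qpid_profile`: `mean` (a `qpid_fvec`),
#'   `n_sites`, `label`
#' @export
reference_profile <- function(sites, core_start, w, k, table, label = "") {
  if (length(sites) < 1L)
    qpid_stop("qpid_alignment", "need at least one site")
  if (length(unique(nchar(sites))) != 1L)
    qpid_stop("qpid_alignment", "sites have inconsistent lengths")
  vecs <- lapply(sites, build_feature_vector, core_start = core_start,
                 w = w, k = k, table = table)
  m <- Reduce(`+`, vecs) / length(vecs)
  structure(list(mean = m, n_sites = length(sites), label = label),
            class = "qpid_profile")
}

#' Normalized Euclidean shape distance
#'
#' `d = ||x - mu||_2 / sqrt(length)`, computed either per feature block
#' (HelT, MGW, Roll, ProT; each of length 2k+w) or on the full 4(2k+w)
#' vector.
#'
#' @param query a `qpid_fvec`
#' @param profile a `qpid_profile` (or a `qpid_fvec` of the same layout)
#' @param scope `"per-feature"` or `"overall"`
#' @return named numeric vector of distances (one per block, or `overall`)
#' @export
normalized_distance <- function(query, profile,
                                scope = c("per-feature", "overall")) {
  scope <- match.arg(scope)
  mu <- if (inherits(profile, "qpid_profile")) profile$mean else profile
  if (length(query) != length(mu))
    qpid_stop("qpid_layout_mismatch", "query and profile layouts differ")
  d <- as.numeric(query) - as.numeric(mu)
  if (scope == "overall")
    return(c(overall = sqrt(sum(d^2) / length(d))))
  blk <- length(d) / 4L
  if (blk != round(blk))
    qpid_stop("qpid_layout_mismatch", "vector length is not divisible into 4 blocks")
  out <- vapply(seq_len(4L), function(b) {
    di <- d[((b - 1L) * blk + 1L):(b * blk)]
    sqrt(sum(di^2) / blk)
  }, numeric(1))
  names(out) <- SHAPE_BLOCKS
  out
}

#' One-sided binomial concordance test
#'
#' Exact upper-tail probability `P(X >= n_concordant)` for
#' `X ~ Binomial(n_comparisons, 1/2)`, by direct summation of binomial
#' coefficients. Used to test whether independent feature-wise distance
#' comparisons agree in direction more often than chance.
#'
#' @param n_comparisons number of comparisons
#' @param n_concordant number agreeing in direction
#' @return one-sided p-value
#' @export
concordance_binomial <- function(n_comparisons, n_concordant) {
  if (n_comparisons < 1 || n_concordant < 0 || n_concordant > n_comparisons)
    qpid_stop("qpid_invalid_argument", "invalid counts")
  sum(choose(n_comparisons, n_concordant:n_comparisons)) / 2^n_comparisons
}
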