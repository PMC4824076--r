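#' Design matrix of flank shape features
#'
#' One row per oligo, one column per (feature, position) pair over the
#' selected flank positions of the feature vector. The default position set
#' is the 5 bp immediately 5' and 3' of the core (10 positions x 4 features
#' = 40 columns); any per-block index set within 1..(2k+w) may be supplied
#' instead (e.g. a literal published index set whose coordinate frame the
#' caller controls).
#'
#' @param vectors named list of `qpid_fvec` feature vectors (one per
#'   oligo), all with identical `w`, `k`
#' @param positions integer per-block positions (1-based into the 2k+w
#'   block); NULL selects the default 5 bp flanks
#' @return numeric matrix with rownames = oligo ids and colnames
#'   `FEATURE_p<position>`; attributes `w`, `k`, `positions`
#' @export
build_design_matrix <- function(vectors, positions = NULL) {
  if (length(vectors) == 0L)
    qpid_stop("qpid_invalid_argument", "no feature vectors supplied")
  ids <- names(vectors)
  if (is.null(ids) || anyDuplicated(ids))
    qpid_stop("qpid_invalid_argument", "vectors must carry unique oligo ids")
  w <- attr(vectors[[1]], "w"); k <- attr(vectors[[1]], "k")
  blk <- 2L * k + w
  same <- vapply(vectors, function(v)
    identical(attr(v, "w"), w) && identical(attr(v, "k"), k), logical(1))
  if (!all(same))
    qpid_stop("qpid_layout_mismatch", "feature vectors have mixed (w, k)")
  if (is.null(positions)) {
    if (k < 5L)
      qpid_stop("qpid_invalid_argument",
                "default 5 bp flank positions need k >= 5 (have k = %d)", k)
    positions <- c((k - 4L):k, (k + w + 1L):(k + w + 5L))
  }
  positions <- as.integer(positions)
  if (length(positions) == 0L || any(positions < 1L) || any(positions > blk))
    qpid_stop("qpid_invalid_argument", "positions out of 1..%d", blk)
  cols <- unlist(lapply(seq_along(SHAPE_BLOCKS), function(b)
    (b - 1L) * blk + positions))
  X <- t(vapply(vectors, function(v) as.numeric(v)[cols],
                numeric(length(cols))))
  colnames(X) <- unlist(lapply(SHAPE_BLOCKS, function(f)
    sprintf("%s_p%d", f, positions)))
  rownames(X) <- ids
  structure(X, w = w, k = k, positions = positions)
}

#' Fit a multiple linear regression of affinity on shape features
#'
#' Ordinary least squares of the response (affinity `1/Kd` in 1/uM, or an
#' affinity difference) on the design-matrix columns, with training-set r2
#' and standardized weights `weight * sd(column) / sd(response)` for
#' scale-free feature-importance comparison. When rows < columns + 2 the
#' fit is rank-deficient; a flagged ridge fallback is available for such
#' synthetic edge cases.
#'
#' @param X design matrix from [build_design_matrix()]
#' @param response numeric response per row (NA rows are dropped)
#' @param response_label one of `"affinity_A"`, `"affinity_B"`,
#'   `"affinity_difference"` (free-form allowed)
#' @param ridge NULL for plain OLS; a positive penalty enables the flagged
#'   ridge fallback
#' @return object of class `qpid_shapemodel`: `intercept`, `weights`,
#'   `std_weights`, `r_squared`, `response_label`, `ridge`
#' @export
fit_model <- function(X, response, response_label = "affinity_A",
                      ridge = NULL) {
  keep <- !is.na(response) & complete.cases(X)
  Xk <- X[keep, , drop = FALSE]; y <- response[keep]
  p <- ncol(Xk)
  if (is.null(ridge) && nrow(Xk) < p + 2L)
    qpid_stop("qpid_rank_deficient",
              "only %d rows for %d columns; enable the ridge fallback or reduce features",
              nrow(Xk), p)
  Z <- cbind(`(Intercept)` = 1, Xk)
  coefs <- if (is.null(ridge)) {
    qr_ <- qr(Z)
    if (qr_$rank < ncol(Z))
      qpid_stop("qpid_rank_deficient",
                "design matrix is rank deficient (rank %d < %d)", qr_$rank, ncol(Z))
    qr.coef(qr_, y)
  } else {
    pen <- diag(c(0, rep(ridge, p)))
    solve(crossprod(Z) + pen, crossprod(Z, y))[, 1]
  }
  fitted <- as.numeric(Z %*% coefs)
  ssr <- sum((y - fitted)^2); sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  sy <- pop_sd(y)
  sx <- apply(Xk, 2, pop_sd)
  stdw <- if (sy == 0) setNames(rep(0, p), colnames(Xk))
          else coefs[-1] * sx / sy
  structure(list(intercept = unname(coefs[1]),
                 weights = setNames(coefs[-1], colnames(Xk)),
                 std_weights = setNames(as.numeric(stdw), colnames(Xk)),
                 r_squared = r2, response_label = response_label,
                 ridge = if (is.null(ridge)) NA_real_ else ridge,
                 n = nrow(Xk)),
            class = "qpid_shapemodel")
}

#' Fit a model of the affinity difference between two proteins
#'
#' Response is `affinity_a - affinity_b` per oligo (1/uM); rows where both
#' affinities are missing (both proteins censored) are dropped.
#'
#' @param X design matrix
#' @param affinity_a,affinity_b numeric affinities (1/uM) per row, NA =
#'   censored for both -> row dropped (a single NA contributes affinity 0)
#' @param ... passed to [fit_model()]
#' @return a `qpid_shapemodel` with response label `"affinity_difference"`
#' @export
fit_difference_model <- function(X, affinity_a, affinity_b, ...) {
  both_na <- is.na(affinity_a) & is.na(affinity_b)
  a <- ifelse(is.na(affinity_a), 0, affinity_a)
  b <- ifelse(is.na(affinity_b), 0, affinity_b)
  d <- a - b
  d[both_na] <- NA_real_
  fit_model(X, d, response_label = "affinity_difference", ...)
}

#' Predict from a shape regression model
#'
#' @param object a `qpid_shapemodel`
#' @param newdata design matrix with the model's columns
#' @param ... ignored
#' @return numeric predictions
#' @export
predict.qpid_shapemodel <- function(object, newdata, ...) {
  as.numeric(object$intercept +
               newdata[, names(object$weights), drop = FALSE] %*% object$weights)
}

#' Rank features by standardized weight magnitude
#'
#' Columns ordered by decreasing |standardized weight| (ties broken by
#' column order). The sign is reported so that, e.g., a preference for a
#' narrower minor groove renders as a negative MGW weight.
#'
#' @param model a `qpid_shapemodel`
#' @return data.frame `feature`, `position`, `weight`, `std_weight`,
#'   `rank`
#' @export
rank_features <- function(model) {
  stopifnot(inherits(model, "qpid_shapemodel"))
  nm <- names(model$std_weights)
  parts <- regmatches(nm, regexec("^([A-Za-z]+)_p(\\d+)$", nm))
  o <- order(-abs(model$std_weights), seq_along(nm))
  data.frame(feature = vapply(parts, `[`, "", 2)[o],
             position = as.integer(vapply(parts, `[`, "", 3)[o]),
             weight = unname(model$weights[o]),
             std_weight = unname(model$std_weights[o]),
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Planted ground-truth shape model
#'
#' Simulates affinities from a linear model on design-matrix columns for
#' regression-recovery testing: `1/Kd = intercept + X w + noise`, clamped
#' strictly positive.
#'
#' @param X design matrix
#' @param weights named numeric vector over a subset of `colnames(X)`
#' @param intercept affinity intercept, 1/uM
#' @param noise_sd Gaussian noise SD in affinity units (0 = noiseless)
#' @param seed integer seed
#' @return list `response` (1/uM), `weights` (full-length named vector),
#'   `intercept`
#' @export
planted_shape_model <- function(X, weights, intercept = 1, noise_sd = 0,
                                seed = 1L) {
  w <- setNames(numeric(ncol(X)), colnames(X))
  if (!all(names(weights) %in% colnames(X)))
    qpid_stop("qpid_invalid_argument", "planted weights name unknown columns")
  w[names(weights)] <- weights
  set.seed(derive_seed(seed, "planted_shape_model"))
  y <- intercept + as.numeric(X %*% w) + rnorm(nrow(X), 0, noise_sd)
  list(response = pmax(y, 1e-6), weights = w, intercept = intercept)
}
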