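#' Estimate plate background from empty wells
#'
#' Background is the mean plus one standard deviation (sample SD, n-1
#' denominator) of the empty-well MFI readings across the non-control
#' analytes.  By default all empty wells x antigen analytes are pooled
#' into a single scalar; `per_analyte = TRUE` instead returns one
#' background value per antigen.
#'
#' @param plate an `sba_plate` (see [read_plate()], [simulate_bead_array()]).
#' @param per_analyte estimate a separate background per antigen analyte?
#' @return Scalar background (MFI units), or a named vector when
#'   `per_analyte = TRUE`.  A single pooled value yields SD = 0.
#' @export
estimate_background <- function(plate, per_analyte = FALSE) {
  stopifnot(inherits(plate, "sba_plate"))
  empty <- names(plate$well_role)[plate$well_role == "empty"]
  if (length(empty) == 0) {
    stop("plate has no empty wells; background cannot be estimated",
         call. = FALSE)
  }
  ag <- names(plate$analyte_role)[plate$analyte_role == "antigen"]
  if (length(ag) == 0) stop("all analytes are controls", call. = FALSE)
  sub <- plate$mfi[empty, ag, drop = FALSE]
  one <- function(v) {
    s <- if (length(v) > 1) stats::sd(v) else 0
    mean(v) + s
  }
  if (per_analyte) apply(sub, 2, one) else one(as.numeric(sub))
}

#' Background-correct a plate
#'
#' Subtracts the background from every MFI value, floors negatives at zero
#' and adds 1 (so downstream log transforms are safe); empty wells and
#' control analytes are dropped.  Wherever MFI is at or below background
#' the output is exactly 1.
#'
#' @param plate an `sba_plate`.
#' @param background scalar from [estimate_background()], or a per-antigen
#'   vector.
#' @return Numeric matrix, sample wells x antigen analytes, minimum 1.
#' @export
subtract_and_floor <- function(plate, background) {
  stopifnot(inherits(plate, "sba_plate"))
  if (any(background < 0)) stop("background must be >= 0", call. = FALSE)
  keep_r <- names(plate$well_role)[plate$well_role == "sample"]
  keep_c <- names(plate$analyte_role)[plate$analyte_role == "antigen"]
  x <- plate$mfi[keep_r, keep_c, drop = FALSE]
  if (length(background) == 1) {
    pmax(x - background, 0) + 1
  } else {
    if (!all(keep_c %in% names(background))) {
      stop("per-analyte background misses some antigens", call. = FALSE)
    }
    pmax(sweep(x, 2, background[keep_c]), 0) + 1
  }
}

#' Join the reactivity matrix with the clinical table
#'
#' Retains only samples present in both the plate and the clinical table,
#' reordering rows to the clinical order; plate samples without a clinical
#' row (patients excluded from the study after sample collection) are
#' dropped and reported.
#'
#' @param x patients x antigens matrix (row names are sample IDs).
#' @param clinical data.frame with a unique `patient_id` column.
#' @return list: `values` (aligned matrix), `clinical` (aligned table),
#'   `excluded` (dropped sample IDs), `n_excluded`.
#' @export
join_clinical <- function(x, clinical) {
  x <- as_reactivity_matrix(x)
  if (anyDuplicated(rownames(x)) || anyDuplicated(clinical$patient_id)) {
    stop("duplicate sample or patient identifiers", call. = FALSE)
  }
  keep <- intersect(clinical$patient_id, rownames(x))
  if (length(keep) == 0) {
    stop("no overlap between plate samples and clinical patients",
         call. = FALSE)
  }
  clin <- clinical[match(keep, clinical$patient_id), , drop = FALSE]
  rownames(clin) <- NULL
  excluded <- setdiff(rownames(x), keep)
  list(values = x[keep, , drop = FALSE], clinical = clin,
       excluded = excluded, n_excluded = length(excluded))
}

#' Robust spline normalization across patients
#'
#' Between-sample intensity normalization on the log2 scale: a virtual
#' reference is built as the per-antigen median across patients; for each
#' patient a rank-invariant antigen set is selected (antigens whose
#' within-patient rank differs from the reference rank by at most
#' `ceiling(window * n_antigens)`), and refined by offset concordance — the
#' rank-invariant residuals seed a shorth-type modal offset, and all
#' antigens whose reference residual lies within min(3 MAD, 1.5 log2) of it
#' join the fit set, so genuinely differential antigens are excluded while
#' the fit keeps broad support.  A monotone increasing spline mapping the
#' patient's values onto the reference is fitted on that set (a stiff
#' smoothing spline on the deviation from the identity, projected onto the
#' isotone cone, extended with slope 1 beyond the fitted range).  The
#' correction is then decomposed into a patient offset plus curvature, and
#' both components are hierarchically shrunk toward the identity
#' (\eqn{\tau^2/(\tau^2 + se^2)}, with \eqn{\tau^2} the across-patient
#' spread of fitted offsets in excess of sampling error): cohorts that need
#' no correction are injected with (almost) no fit noise, while genuinely
#' shifted samples are corrected in full.  When the invariant set has fewer
#' than `min_invariant` points the full antigen set seeds the fit.
#' `mode = "quantile"` substitutes full quantile normalization (via limma).
#'
#' Each per-patient map is monotone non-decreasing, so within-patient rank
#' order is preserved (ties allowed).
#'
#' @param x strictly positive patients x antigens matrix.
#' @param window rank-invariance window as a fraction of the antigen count.
#' @param mode `"rsn"` (default) or `"quantile"`.
#' @param min_invariant minimum size of the rank-invariant set.
#' @return Normalized matrix on the linear scale, same dimnames as `x`.
#' @export
robust_spline_normalize <- function(x, window = 0.05,
                                    mode = c("rsn", "quantile"),
                                    min_invariant = 8) {
  mode <- match.arg(mode)
  x <- as_reactivity_matrix(x)
  if (any(x <= 0)) stop("normalization requires strictly positive values",
                        call. = FALSE)
  m <- ncol(x)
  if (m < 8) stop("need at least 8 antigens to normalize", call. = FALSE)

  if (mode == "quantile") {
    out <- t(limma::normalizeBetweenArrays(t(x), method = "quantile"))
    dimnames(out) <- dimnames(x)
    return(out)
  }

  lx <- log2(x)
  ref <- apply(lx, 2, stats::median)
  rref <- rank(ref, ties.method = "average")
  win <- ceiling(window * m)
  np <- nrow(lx)

  # pass 1: per patient, select the fit set (rank-invariant seed refined by
  # offset concordance) and fit the monotone map; record the fitted offset,
  # its sampling error, and the curvature component
  maps <- vector("list", np)
  off_hat <- se_off <- c_mag2 <- se_c2 <- numeric(np)
  for (i in seq_len(np)) {
    ri <- rank(lx[i, ], ties.method = "average")
    inv <- which(abs(ri - rref) <= win)
    if (length(inv) < min_invariant) inv <- seq_len(m)
    # the rank-invariant set seeds a robust estimate of the patient-level
    # offset (the technical effect); the spline is then fitted on every
    # offset-concordant antigen, so genuinely differential antigens are
    # excluded while the fit keeps enough support to stay stable
    res_inv <- ref[inv] - lx[i, inv]
    mo <- modal_offset(res_inv)
    spread <- max(stats::mad(res_inv, center = mo), 0.2)
    res_all <- ref - lx[i, ]
    hw <- min(3 * spread, 1.5)  # differential antigens sit beyond ~1.5 log2
    core <- which(abs(res_all - mo) <= hw)
    if (length(core) >= min_invariant) {
      mo2 <- stats::median(res_all[core])
      hw2 <- min(3 * max(stats::mad(res_all[core], center = mo2), 0.2), 1.5)
      core2 <- which(abs(res_all - mo2) <= hw2)
      inv <- if (length(core2) >= min_invariant) core2 else core
    }
    map <- monotone_map(lx[i, inv], ref[inv])
    res_core <- ref[inv] - lx[i, inv]
    off_hat[i] <- stats::median(res_core)
    se_off[i] <- 1.2533 * stats::mad(res_core) / sqrt(length(res_core))
    cv <- map(lx[i, inv]) - lx[i, inv] - off_hat[i]
    c_mag2[i] <- mean(cv^2)
    se_c2[i] <- 2 * (1.4826 * stats::mad(res_core))^2 / max(length(res_core), 1)
    maps[[i]] <- map
  }

  # pass 2: hierarchical shrinkage of the corrections toward the identity.
  # The spread of fitted offsets across patients in excess of their
  # sampling error estimates the real between-sample technical variance;
  # each patient's correction is scaled by the usual ratio
  # tau^2 / (tau^2 + se_i^2), so cohorts that need no correction get
  # (almost) none and genuinely shifted samples are corrected in full.
  tau2 <- max(0, stats::var(off_hat) - mean(se_off^2))
  tauc2 <- max(0, mean(c_mag2) - mean(se_c2))
  out <- lx
  for (i in seq_len(np)) {
    k_off <- if (tau2 + se_off[i]^2 > 0) tau2 / (tau2 + se_off[i]^2) else 0
    k_c <- if (tauc2 + se_c2[i] > 0) tauc2 / (tauc2 + se_c2[i]) else 0
    curv_all <- maps[[i]](lx[i, ]) - lx[i, ] - off_hat[i]
    out[i, ] <- lx[i, ] + k_off * off_hat[i] + k_c * curv_all
  }
  2^out
}

# Center of the densest half of a residual distribution (shorth-type mode):
# robust to up to half of the antigens being genuinely differential.
modal_offset <- function(r) {
  r <- sort(r)
  n <- length(r)
  h <- max(4, ceiling(n / 2))
  if (n <= h) return(stats::median(r))
  width <- r[h:n] - r[1:(n - h + 1)]
  i <- which.min(width)
  mean(r[i:(i + h - 1)])
}

# Fit a monotone non-decreasing map from xs to ys: smoothing spline (where
# enough support exists) evaluated on the sorted grid, projected onto the
# isotone cone, interpolated piecewise-linearly, and extended with slope 1
# beyond the fitted range.
monotone_map <- function(xs, ys) {
  fit <- monotone_fit(xs, ys)
  if (is.null(fit)) {
    off <- stats::median(ys) - stats::median(xs)
    return(function(v) v + off)
  }
  fit
}

monotone_fit <- function(xs, ys) {
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  grid <- sort(unique(xs))
  if (length(grid) < 4) return(NULL)
  # fit the deviation from the identity: the map is close to a shift, so a
  # stiff spline on (x, y - x) is far more stable than a free-form fit
  fit <- tryCatch(
    grid + stats::predict(stats::smooth.spline(xs, ys - xs,
                                               df = min(2, length(grid) - 1)),
                          grid)$y,
    error = function(e) stats::approx(xs, ys, xout = grid, ties = mean,
                                      rule = 2)$y)
  mono <- stats::isoreg(grid, fit)$yf
  lo <- grid[1]; hi <- grid[length(grid)]
  flo <- mono[1]; fhi <- mono[length(mono)]
  function(v) {
    y <- stats::approx(grid, mono, xout = v, rule = 2)$y
    y[v < lo] <- flo + (v[v < lo] - lo)
    y[v > hi] <- fhi + (v[v > hi] - hi)
    y
  }
}

#' Box-Cox variance stabilization
#'
#' If the global minimum \eqn{m \le 0}, the offset \eqn{1 - m} is added to
#' all values first.  Per antigen (or globally, `per_antigen = FALSE`), the
#' transform parameter \eqn{\lambda} is estimated by maximizing the Box-Cox
#' profile log-likelihood over \eqn{[-5, 5]} (coarse grid, then
#' golden-section refinement to tolerance 1e-4); the transform is
#' \eqn{y = (x^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0} and
#' \eqn{y = \ln x} when \eqn{|\hat\lambda| < 10^{-3}}.  Constant columns
#' have no defined \eqn{\lambda}; they are left on the identity transform
#' (\eqn{\lambda = 1}) and flagged.
#'
#' @param x patients x antigens matrix of finite values.
#' @param per_antigen estimate a separate lambda per antigen?
#' @return list: `values` (transformed matrix), `lambda` (named vector),
#'   `offset`, `constant_antigens` (flagged columns).
#' @export
boxcox_transform <- function(x, per_antigen = TRUE) {
  x <- as_reactivity_matrix(x)
  if (any(!is.finite(x))) stop("non-finite values", call. = FALSE)
  offset <- 0
  mn <- min(x)
  if (mn <= 0) {
    offset <- 1 - mn
    x <- x + offset
  }
  m <- ncol(x)
  lambda <- stats::setNames(rep(NA_real_, m), colnames(x))
  flagged <- character(0)
  out <- x
  cols <- if (per_antigen) seq_len(m) else list(seq_len(m))
  if (!per_antigen) {
    lam <- boxcox_lambda(as.numeric(x))
    lambda[] <- lam
    out[] <- boxcox_apply(x, lam)
    return(list(values = out, lambda = lambda, offset = offset,
                constant_antigens = flagged))
  }
  for (j in seq_len(m)) {
    v <- x[, j]
    if (stats::var(v) < 1e-12) {
      lambda[j] <- 1
      flagged <- c(flagged, colnames(x)[j])
      out[, j] <- v - 1  # identity transform (x^1 - 1)/1
      next
    }
    lam <- boxcox_lambda(v)
    lambda[j] <- lam
    out[, j] <- boxcox_apply(v, lam)
  }
  list(values = out, lambda = lambda, offset = offset,
       constant_antigens = flagged)
}

#' Box-Cox profile-likelihood estimate of lambda
#'
#' @param v strictly positive numeric vector.
#' @param lower,upper search range.
#' @param tol golden-section tolerance.
#' @return The maximizing lambda (values with `|lambda| < 1e-3` are snapped
#'   to 0).
#' @export
boxcox_lambda <- function(v, lower = -5, upper = 5, tol = 1e-4) {
  if (any(v <= 0)) stop("Box-Cox requires positive values", call. = FALSE)
  ll <- function(lam) boxcox_loglik(v, lam)
  grid <- seq(lower, upper, by = 0.25)
  vals <- vapply(grid, ll, 0)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  lam <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = tol)$maximum
  if (abs(lam) < 1e-3) 0 else lam
}

boxcox_loglik <- function(v, lam) {
  n <- length(v)
  lx <- log(v)
  y <- if (abs(lam) < 1e-3) lx else (v^lam - 1) / lam
  s2 <- mean((y - mean(y))^2)
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lam - 1) * sum(lx)
}

boxcox_apply <- function(x, lam) {
  if (abs(lam) < 1e-3) log(x) else (x^lam - 1) / lam
}

#' Remove zero-variance antigens
#'
#' Drops antigen columns whose variance within the given patient scope is
#' below `tol` (zero variance up to floating-point noise).
#'
#' @param x patients x antigens matrix.
#' @param scope optional patient row names (or indices) defining the
#'   subset in which variance is assessed; default all patients.
#' @param tol variance threshold.
#' @return list: `values` (filtered matrix), `removed` (dropped antigen
#'   names).  All columns removed is an error.
#' @export
zero_variance_filter <- function(x, scope = NULL, tol = 1e-12) {
  x <- as_reactivity_matrix(x)
  sub <- if (is.null(scope)) x else x[scope, , drop = FALSE]
  v <- apply(sub, 2, stats::var)
  drop <- which(v < tol)
  if (length(drop) == ncol(x)) {
    stop("all antigens have zero variance in this scope", call. = FALSE)
  }
  list(values = if (length(drop)) x[, -drop, drop = FALSE] else x,
       removed = colnames(x)[drop])
}

#' Full pre-processing pipeline
#'
#' Runs background estimation, subtraction with floor and +1 offset,
#' the clinical join, a global zero-variance filter, robust spline (or
#' quantile) normalization and per-antigen Box-Cox variance stabilization.
#'
#' @param plate an `sba_plate`.
#' @param clinical clinical data.frame (`patient_id` keyed).
#' @param mode normalization mode, `"rsn"` or `"quantile"`.
#' @param per_analyte_background per-antigen background estimation?
#' @param variance_filter apply the global zero-variance filter?
#' @return An object of class `sba_norm`: list with `values` (patients x
#'   antigens, transformed reactivity), `clinical` (aligned), `lambda`,
#'   `offset`, `background`, `excluded_samples`, `removed_antigens`,
#'   `steps` (provenance log).
#' @examples
#' ds <- simulate_bead_array(sba_config(rng_seed = 3))
#' nm <- preprocess_plate(ds$plate, ds$clinical)
#' dim(nm$values)
#' @export
preprocess_plate <- function(plate, clinical, mode = c("rsn", "quantile"),
                             per_analyte_background = FALSE,
                             variance_filter = TRUE) {
  mode <- match.arg(mode)
  steps <- character(0)
  bg <- estimate_background(plate, per_analyte = per_analyte_background)
  steps <- c(steps, sprintf("background: empty-well mean + 1 SD = %s",
                            paste(signif(bg, 6), collapse = ",")))
  corrected <- subtract_and_floor(plate, bg)
  steps <- c(steps, "corrected: max(MFI - background, 0) + 1")
  jn <- join_clinical(corrected, clinical)
  steps <- c(steps, sprintf("join: %d samples excluded (%s)", jn$n_excluded,
                            paste(utils::head(jn$excluded, 5), collapse = ", ")))
  x <- jn$values
  removed <- character(0)
  if (variance_filter) {
    vf <- zero_variance_filter(x)
    x <- vf$values
    removed <- vf$removed
    steps <- c(steps, sprintf("variance filter: removed %d antigens",
                              length(removed)))
  }
  x <- robust_spline_normalize(x, mode = mode)
  steps <- c(steps, sprintf("normalization: %s", mode))
  bc <- boxcox_transform(x)
  steps <- c(steps, sprintf("box-cox: offset %g, lambda in [%.3g, %.3g]",
                            bc$offset, min(bc$lambda), max(bc$lambda)))
  structure(list(values = bc$values, clinical = jn$clinical,
                 lambda = bc$lambda, offset = bc$offset, background = bg,
                 mode = mode, excluded_samples = jn$excluded,
                 removed_antigens = removed,
                 constant_antigens = bc$constant_antigens, steps = steps),
            class = "sba_norm")
}

#' @export
print.sba_norm <- function(x, ...) {
  cat("Normalized reactivity matrix\n")
  cat(sprintf("  %d patients x %d antigens (%d samples excluded at join,"
              , nrow(x$values), ncol(x$values), length(x$excluded_samples)),
      sprintf("%d antigens removed)\n", length(x$removed_antigens)))
  for (s in x$steps) cat("  - ", s, "\n", sep = "")
  invisible(x)
}
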