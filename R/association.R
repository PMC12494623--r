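#' Derive worse-is-higher clinical variables
#'
#' Adds `VFI_loss_diagnosis = 100 - VFI_diagnosis`, `VFI_loss_3 =
#' 100 - VFI_3`, `MD_abs = |MD|` and `MD3_abs = |MD_3|` so that higher
#' values consistently represent worse outcomes; original columns are
#' retained.  The attribute `screen_params` lists the numeric parameters
#' used by the default Spearman screen (transformed variables replacing
#' their originals).
#'
#' @param clinical data.frame with `VFI_diagnosis`, `VFI_3`, `MD`, `MD_3`
#'   columns (VFI values must lie in `[0, 100]`).
#' @return The augmented data.frame (class unchanged).
#' @export
transform_clinical <- function(clinical) {
  for (v in c("VFI_diagnosis", "VFI_3")) {
    if (!v %in% names(clinical)) stop("missing column ", v, call. = FALSE)
    bad <- !is.na(clinical[[v]]) & (clinical[[v]] < 0 | clinical[[v]] > 100)
    if (any(bad)) stop(v, " outside [0, 100]", call. = FALSE)
  }
  clinical$VFI_loss_diagnosis <- 100 - clinical$VFI_diagnosis
  clinical$VFI_loss_3 <- 100 - clinical$VFI_3
  clinical$MD_abs <- abs(clinical$MD)
  clinical$MD3_abs <- abs(clinical$MD_3)
  attr(clinical, "screen_params") <-
    c("age", "IOP", "CCT", "SE", "VA", "MD_abs", "MD3_abs",
      "VFI_loss_diagnosis", "VFI_loss_3", "ROP", "CD", "OCT", "medications")
  clinical
}

#' Spearman screen of antigens against numeric clinical parameters
#'
#' For every antigen x parameter pair: Spearman rho (Pearson correlation of
#' average ranks), a two-sided p-value from the t approximation with
#' `n - 2` degrees of freedom (`|rho| = 1` gives p = 0), and a
#' Benjamini-Hochberg q-value.  Missing values are removed pairwise and
#' the complete-pair count is recorded.  The BH family is the full
#' antigen x parameter table by default, or each parameter separately with
#' `family = "per_parameter"`.
#'
#' @param x patients x antigens matrix, or an `sba_norm`.
#' @param clinical aligned clinical data.frame (same patient order as the
#'   matrix rows); typically from [transform_clinical()].
#' @param params numeric parameter names to screen; defaults to the
#'   `screen_params` attribute, falling back to all numeric columns.
#' @param family `"global"` or `"per_parameter"` BH family.
#' @return data.frame of class `assoc_table` with columns `antigen`,
#'   `parameter`, `rho`, `p`, `q`, `n_used`.  Pairs where rho is undefined
#'   (a constant column) carry NA.
#' @export
spearman_screen <- function(x, clinical, params = NULL,
                            family = c("global", "per_parameter")) {
  family <- match.arg(family)
  x <- as_reactivity_matrix(x)
  if (nrow(x) != nrow(clinical)) {
    stop("matrix rows and clinical rows are not aligned", call. = FALSE)
  }
  if (is.null(params)) {
    params <- attr(clinical, "screen_params") %||%
      setdiff(names(clinical)[vapply(clinical, is.numeric, TRUE)],
              "patient_id")
  }
  res <- vector("list", length(params))
  for (k in seq_along(params)) {
    pr <- params[[k]]
    sv <- spearman_vs(x, clinical[[pr]])
    res[[k]] <- data.frame(antigen = colnames(x), parameter = pr,
                           rho = sv$rho, p = sv$p, n_used = sv$n_used,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  tab$q <- NA_real_
  if (family == "global") {
    ok <- !is.na(tab$p)
    tab$q[ok] <- bh_adjust(tab$p[ok])
  } else {
    for (pr in params) {
      sel <- tab$parameter == pr & !is.na(tab$p)
      tab$q[sel] <- bh_adjust(tab$p[sel])
    }
  }
  tab <- tab[, c("antigen", "parameter", "rho", "p", "q", "n_used")]
  rownames(tab) <- NULL
  class(tab) <- c("assoc_table", "data.frame")
  attr(tab, "family") <- family
  tab
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, clipped at 1 and mapped
#' back to the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order (`q >= p` elementwise).
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Distance-based PERMANOVA
#'
#' One-way permutational multivariate ANOVA on the patient reactivity
#' profiles.  With distance matrix \eqn{d}, \eqn{N} patients and \eqn{a}
#' groups: \eqn{SS_{total} = \frac1N \sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac1{n_g} \sum_{i<j \in g} d_{ij}^2},
#' pseudo-F \eqn{= \frac{(SS_{total}-SS_{within})/(a-1)}{SS_{within}/(N-a)}};
#' the p-value is \eqn{(\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{perm}+1)} under
#' random relabeling.  Degenerate \eqn{SS_{within} = 0} is treated as
#' \eqn{F = +\infty} (it ties or beats any permuted statistic).
#'
#' @param x patients x antigens matrix, or an `sba_norm`.
#' @param labels group labels (factor or character; NA rows are dropped);
#'   every group must have at least 2 members.
#' @param n_perm number of permutations (at least 99).
#' @param seed optional RNG seed for the permutations.
#' @param metric distance metric: `"euclidean"` (default), `"manhattan"`
#'   or `"correlation"` (1 - Pearson between patient rows).
#' @return Object of class `permanova`: list with `parameter`, `pseudo_F`,
#'   `p_perm`, `n_permutations`, `group_sizes`.
#' @export
permanova <- function(x, labels, n_perm = 999, seed = NULL,
                      metric = c("euclidean", "manhattan", "correlation")) {
  metric <- match.arg(metric)
  x <- as_reactivity_matrix(x)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs at least 2 members", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)

  d2 <- switch(metric,
    euclidean = as.matrix(stats::dist(x))^2,
    manhattan = as.matrix(stats::dist(x, method = "manhattan"))^2,
    correlation = (1 - stats::cor(t(x)))^2)
  N <- nrow(d2)
  a <- length(sizes)
  ss_total <- sum(d2) / (2 * N)

  f_stat <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    if (ssw <= 1e-12) return(Inf)
    ((ss_total - ssw) / (a - 1)) / (ssw / (N - a))
  }

  f_obs <- f_stat(labels)
  f_perm <- with_seed(seed, {
    # group-indicator formulation, vectorized across permutations
    perm <- matrix(0L, N, n_perm)
    for (b in seq_len(n_perm)) perm[, b] <- sample.int(N)
    ssw <- numeric(n_perm)
    for (g in names(sizes)) {
      sel <- labels == g
      M <- matrix(0, N, n_perm)
      M[cbind(as.vector(perm[sel, ]), rep(seq_len(n_perm), each = sum(sel)))] <- 1
      ssw <- ssw + colSums(M * (d2 %*% M)) / (2 * sizes[[g]])
    }
    ifelse(ssw <= 1e-12, Inf,
           ((ss_total - ssw) / (a - 1)) / (ssw / (N - a)))
  })
  # permutations recreating the observed partition must count as ties,
  # so the comparison carries a relative float tolerance
  p <- (sum(f_perm >= f_obs - 1e-8 * (1 + abs(f_obs))) + 1) / (n_perm + 1)
  structure(list(parameter = attr(labels, "parameter") %||% NA_character_,
                 pseudo_F = f_obs, p_perm = p, n_permutations = n_perm,
                 group_sizes = as.integer(sizes),
                 groups = names(sizes), metric = metric),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s distance): pseudo-F = %.4g, p = %.4g (%d permutations)\n",
              x$metric, x$pseudo_F, x$p_perm, x$n_permutations))
  cat("  groups:", paste(sprintf("%s (n=%d)", x$groups, x$group_sizes),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Two-group permutation t-test
#'
#' Welch t statistic; the two-sided p-value is
#' \eqn{(\#\{|t_{perm}| \ge |t_{obs}|\} + 1)/(n_{perm} + 1)} under random
#' label shuffles.  When both groups have zero variance and equal means the
#' statistic is defined as 0.
#'
#' @param values numeric vector.
#' @param labels two-group labels, each group with at least 2 members.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @return list: `statistic` (Welch t), `p` (permutation p-value),
#'   `n_permutations`.
#' @export
permutation_t_test <- function(values, labels, n_perm = 10000, seed = NULL) {
  labels <- as.character(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  lv <- unique(labels)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  n1 <- sum(labels == lv[1]); n2 <- sum(labels == lv[2])
  if (min(n1, n2) < 2) stop("each group needs at least 2 members", call. = FALSE)

  welch <- function(idx1) {
    g1 <- values[idx1]; g2 <- values[-idx1]
    v1 <- stats::var(g1); v2 <- stats::var(g2)
    se2 <- v1 / n1 + v2 / n2
    dm <- mean(g1) - mean(g2)
    if (se2 <= 0) {
      # both groups constant: equal means give t = 0, unequal give +/-Inf
      return(if (dm == 0) 0 else sign(dm) * Inf)
    }
    dm / sqrt(se2)
  }
  t_obs <- welch(which(labels == lv[1]))
  t_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    welch(sample.int(length(values), n1))
  }, 0))
  tol <- if (is.finite(t_obs)) 1e-8 * max(abs(t_obs), 1) else 0
  p <- (sum(abs(t_perm) >= abs(t_obs) - tol) + 1) / (n_perm + 1)
  list(statistic = t_obs, p = p, n_permutations = n_perm)
}

#' Screen categorical clinical parameters
#'
#' Runs [permanova()] for each categorical parameter (groups smaller than 2
#' are dropped from the test) and, for parameters significant at `alpha`,
#' per-antigen [permutation_t_test()]s with BH adjustment across antigens
#' (only defined for two-level parameters).
#'
#' @param x patients x antigens matrix, or an `sba_norm`.
#' @param clinical aligned clinical data.frame.
#' @param params categorical parameter names; default the standard seven
#'   (sex, diabetes, hypertension, migraine, smoking, SLT, GPA),
#'   intersected with the available columns.
#' @param n_perm PERMANOVA permutations (the study design uses 1000).
#' @param t_perm per-antigen t-test permutations (the study design uses
#'   10000).
#' @param alpha significance threshold on the PERMANOVA p for triggering
#'   the per-antigen follow-up.
#' @param seed optional RNG seed.
#' @return list: `permanova` (data.frame parameter / pseudo_F / p_perm),
#'   `per_antigen` (named list of data.frames with t, p, q per antigen).
#' @export
categorical_screen <- function(x, clinical, params = NULL, n_perm = 999,
                               t_perm = 10000, alpha = 0.05, seed = NULL) {
  x <- as_reactivity_matrix(x)
  if (is.null(params)) {
    params <- intersect(c("sex", "diabetes", "hypertension", "migraine",
                          "smoking", "SLT", "GPA"), names(clinical))
  }
  res <- data.frame(parameter = character(0), pseudo_F = numeric(0),
                    p_perm = numeric(0), stringsAsFactors = FALSE)
  per_antigen <- list()
  for (k in seq_along(params)) {
    pr <- params[[k]]
    lab <- as.character(clinical[[pr]])
    sizes <- table(lab[!is.na(lab)])
    keepg <- names(sizes)[sizes >= 2]
    sel <- lab %in% keepg
    if (length(keepg) < 2) next
    pv <- permanova(x[sel, , drop = FALSE], lab[sel], n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else seed + k)
    res <- rbind(res, data.frame(parameter = pr, pseudo_F = pv$pseudo_F,
                                 p_perm = pv$p_perm, stringsAsFactors = FALSE))
    if (pv$p_perm < alpha && length(keepg) == 2) {
      tt <- lapply(seq_len(ncol(x)), function(j) {
        permutation_t_test(x[sel, j], lab[sel], n_perm = t_perm,
                           seed = if (is.null(seed)) NULL else seed + 1000L * k + j)
      })
      tab <- data.frame(antigen = colnames(x),
                        t = vapply(tt, `[[`, 0, "statistic"),
                        p = vapply(tt, `[[`, 0, "p"),
                        stringsAsFactors = FALSE)
      tab$q <- bh_adjust(tab$p)
      per_antigen[[pr]] <- tab
    }
  }
  list(permanova = res, per_antigen = per_antigen)
}
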