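#' Stratify patients into reactivity tiers
#'
#' Complete-linkage agglomerative clustering on Euclidean distances between
#' patient reactivity profiles, cut to exactly `k` clusters; clusters are
#' labelled `high` / `intermediate` / `low` (for `k = 3`; otherwise
#' `tier1..tierk`) by descending mean reactivity across all antigens.
#' The procedure is deterministic: repeated runs on the same matrix give
#' identical labels (hclust's fixed tie-breaking by merge order).
#'
#' @param x patients x antigens matrix, or an `sba_norm`.
#' @param k number of clusters (>= 2); alternatively cut at `height`.
#' @param height optional dendrogram cut height (overrides `k`).
#' @return Object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector), `tier` (named character vector), `hclust`
#'   (linkage record), `k`, `tier_means` (mean reactivity per tier,
#'   descending).
#' @export
cluster_patients <- function(x, k = 3, height = NULL) {
  x <- as_reactivity_matrix(x)
  if (is.null(height) && k < 2) stop("k must be at least 2", call. = FALSE)
  if (nrow(x) < max(2, k)) stop("not enough patients", call. = FALSE)
  hc <- stats::hclust(stats::dist(x), method = "complete")
  cl <- if (is.null(height)) stats::cutree(hc, k = k) else
    stats::cutree(hc, h = height)
  k_eff <- length(unique(cl))
  cluster_mean <- tapply(rowMeans(x), cl, mean)
  ord <- order(cluster_mean, decreasing = TRUE)
  tier_names <- if (k_eff == 3) c("high", "intermediate", "low") else
    paste0("tier", seq_len(k_eff))
  tier_of_cluster <- stats::setNames(tier_names, names(cluster_mean)[ord])
  tier <- tier_of_cluster[as.character(cl)]
  names(tier) <- rownames(x)
  structure(list(cluster = stats::setNames(cl, rownames(x)), tier = tier,
                 hclust = hc, k = k_eff,
                 tier_means = stats::setNames(cluster_mean[ord], tier_names),
                 metric = "euclidean", linkage = "complete"),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Patient stratification: %d clusters (%s linkage, %s distance)\n",
              x$k, x$linkage, x$metric))
  tb <- table(x$tier)[names(x$tier_means)]
  for (t in names(x$tier_means)) {
    cat(sprintf("  %-12s n = %2d   mean reactivity %.3f\n", t, tb[[t]],
                x$tier_means[[t]]))
  }
  invisible(x)
}

#' Re-screen clinical associations within reactivity tiers
#'
#' For each requested tier: antigens with zero variance within the tier are
#' removed, then [spearman_screen()] is run on the tier's patients with BH
#' adjustment inside the tier's own family.  Tiers with fewer than 5
#' patients are skipped with a warning.
#'
#' @param x patients x antigens matrix, or an `sba_norm`.
#' @param clinical aligned clinical data.frame.
#' @param assignment a `cluster_assignment` from [cluster_patients()].
#' @param tiers tier labels to screen (default high and low).
#' @param params forwarded to [spearman_screen()].
#' @return Named list per tier: `assoc` (an `assoc_table`), `removed`
#'   (zero-variance antigens in the tier), `n_patients`.
#' @export
subgroup_screen <- function(x, clinical, assignment,
                            tiers = c("high", "low"), params = NULL) {
  x <- as_reactivity_matrix(x)
  stopifnot(inherits(assignment, "cluster_assignment"))
  out <- list()
  for (t in tiers) {
    sel <- which(assignment$tier[rownames(x)] == t)
    if (length(sel) == 0) stop("tier not present: ", t, call. = FALSE)
    if (length(sel) < 5) {
      warning("tier ", t, " has fewer than 5 patients; skipped", call. = FALSE)
      next
    }
    vf <- zero_variance_filter(x[sel, , drop = FALSE])
    assoc <- spearman_screen(vf$values, clinical[sel, , drop = FALSE],
                             params = params)
    out[[t]] <- list(assoc = assoc, removed = vf$removed,
                     n_patients = length(sel))
  }
  out
}

#' Standardize reactivity within each patient
#'
#' Row z-scores: each patient's profile is centred on its mean and scaled
#' by its SD (n-1 denominator), so antigen-antigen correlations reflect
#' relative, not absolute, reactivity.  Rows with zero SD become all zeros
#' and are flagged in the `degenerate` attribute.
#'
#' @param x patients x antigens matrix (>= 2 antigens), or an `sba_norm`.
#' @return The row-standardized matrix with attribute `degenerate`
#'   (patient IDs of zero-SD rows).
#' @export
patient_scale <- function(x) {
  x <- as_reactivity_matrix(x)
  if (ncol(x) < 2) stop("need at least 2 antigens per patient", call. = FALSE)
  mu <- rowMeans(x)
  sd_ <- apply(x, 1, stats::sd)
  degen <- rownames(x)[sd_ == 0]
  sd_[sd_ == 0] <- Inf  # degenerate rows map to all zeros
  out <- (x - mu) / sd_
  attr(out, "degenerate") <- degen
  out
}

#' Antigen-antigen Spearman correlation
#'
#' Pairwise Spearman correlations between antigen columns across patients
#' (typically on a [patient_scale()]d matrix), with t-approximation
#' p-values and BH adjustment over the `choose(m, 2)` unordered pairs.
#' All-zero (degenerate) antigen columns are excluded and reported.
#'
#' @param x patients x antigens matrix (>= 3 patients).
#' @return Object of class `antigen_cor`: list with `rho` (symmetric, unit
#'   diagonal), `p`, `q` (symmetric matrices, NA diagonal), `excluded`.
#' @export
antigen_correlation <- function(x) {
  x <- as_reactivity_matrix(x)
  if (nrow(x) < 3) stop("need at least 3 patients", call. = FALSE)
  const <- apply(x, 2, function(v) stats::var(v) < 1e-12)
  excluded <- colnames(x)[const]
  x <- x[, !const, drop = FALSE]
  m <- ncol(x)
  rho <- stats::cor(x, method = "spearman")
  n <- nrow(x)
  p <- matrix(NA_real_, m, m, dimnames = dimnames(rho))
  ut <- upper.tri(rho)
  p[ut] <- vapply(rho[ut], spearman_p, 0, n = n)
  q <- matrix(NA_real_, m, m, dimnames = dimnames(rho))
  q[ut] <- bh_adjust(p[ut])
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(rho) <- 1
  structure(list(rho = rho, p = p, q = q, excluded = excluded, n = n),
            class = "antigen_cor")
}

#' Cut antigen clusters at a size-constrained threshold
#'
#' Complete-linkage clustering of antigens on correlation distance
#' `1 - rho`.  All distinct merge heights are candidate cuts; the chosen
#' cut minimizes the number of out-of-range clusters (smaller than
#' `size_min` or larger than `size_max`); ties are broken by the most
#' persistent cut (the widest height gap until the next merge, i.e. the
#' dendrogram's natural plateau) and then by the lowest height.  Clusters
#' outside the size bounds are flagged ineligible (and excluded from
#' downstream shortest-path seeding).
#'
#' @param cor_ an `antigen_cor`, or a correlation matrix.
#' @param size_min,size_max eligible cluster size bounds (study values 3
#'   and 20).
#' @return Object of class `antigen_clusters`: list with `clusters` (list
#'   of antigen-name vectors), `sizes`, `eligible` (logical), `height`
#'   (chosen cut), `hclust`, `labels` (antigen -> cluster id).
#' @export
cut_antigen_clusters <- function(cor_, size_min = 3, size_max = 20) {
  rho <- if (inherits(cor_, "antigen_cor")) cor_$rho else cor_
  if (!isTRUE(all.equal(rho, t(rho), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  m <- ncol(rho)
  if (m < 3) stop("need at least 3 antigens", call. = FALSE)
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "complete")
  cand <- sort(unique(c(0, hc$height)))
  gap <- c(diff(cand), 0)  # persistence: height until the next merge
  best <- NULL
  for (i in seq_along(cand)) {
    h <- cand[i]
    cl <- stats::cutree(hc, h = h)
    sz <- table(cl)
    n_out <- sum(sz < size_min | sz > size_max)
    score <- c(-n_out, gap[i], -h)
    if (is.null(best) || lex_gt(score, best$score)) {
      best <- list(score = score, h = h, cl = cl)
    }
  }
  cl <- best$cl
  ids <- sort(unique(cl))
  clusters <- lapply(ids, function(i) colnames(rho)[cl == i])
  sizes <- lengths(clusters)
  structure(list(clusters = clusters, sizes = sizes,
                 eligible = sizes >= size_min & sizes <= size_max,
                 height = best$h, hclust = hc,
                 labels = stats::setNames(cl, colnames(rho)),
                 size_min = size_min, size_max = size_max),
            class = "antigen_clusters")
}

lex_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.antigen_clusters <- function(x, ...) {
  cat(sprintf("Antigen clusters: %d at height %.3f (eligible size %d-%d)\n",
              length(x$clusters), x$height, x$size_min, x$size_max))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d: %d antigens%s\n", i, x$sizes[i],
                if (x$eligible[i]) "" else "  [ineligible]"))
  }
  invisible(x)
}
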