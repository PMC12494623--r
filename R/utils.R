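# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Accept either a plain patients x antigens matrix or the list returned by
# the pre-processing pipeline and return the numeric matrix.
as_reactivity_matrix <- function(x) {
  if (is.list(x) && !is.null(x$values)) x <- x$values
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric patients x antigens matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("reactivity matrix must carry patient row names and antigen column names",
         call. = FALSE)
  }
  x
}

# Normal-scores of the mid-ranks of a vector (ties -> average rank).
rank_z <- function(v) {
  n <- sum(!is.na(v))
  stats::qnorm(rank(v, na.last = "keep", ties.method = "average") / (n + 1))
}

# Spearman rho of a matrix of columns against one vector, with the two-sided
# t-approximation p-value (df = n - 2).  Returns rho, p, n per column.
spearman_vs <- function(mat, y) {
  m <- ncol(mat)
  rho <- p <- rep(NA_real_, m)
  n_used <- integer(m)
  for (j in seq_len(m)) {
    ok <- stats::complete.cases(mat[, j], y)
    n <- sum(ok)
    n_used[j] <- n
    if (n < 3) next
    xj <- mat[ok, j]
    yj <- y[ok]
    if (stats::sd(xj) == 0 || stats::sd(yj) == 0) next  # rho undefined
    r <- stats::cor(xj, yj, method = "spearman")
    rho[j] <- r
    p[j] <- spearman_p(r, n)
  }
  list(rho = rho, p = p, n_used = n_used)
}

spearman_p <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
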