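make_plate <- function(mfi, n_empty = 1, empty_value = 10) {
  m <- ncol(mfi)
  empty <- matrix(empty_value, n_empty, m,
                  dimnames = list(sprintf("E%d", seq_len(n_empty)),
                                  colnames(mfi)))
  structure(list(
    mfi = rbind(mfi, empty),
    well_role = setNames(c(rep("sample", nrow(mfi)), rep("empty", n_empty)),
                         c(rownames(mfi), rownames(empty))),
    analyte_role = setNames(rep("antigen", m), colnames(mfi))
  ), class = "sba_plate")
}

test_that("background is the empty-well mean plus one sample SD", {
  mfi <- matrix(500, 2, 2, dimnames = list(c("s1", "s2"), c("a1", "a2")))
  # zero-variance empty wells: background equals the mean
  pl <- make_plate(mfi, n_empty = 2, empty_value = 10)
  expect_equal(estimate_background(pl), 10)
  # two pooled values {8, 12}: 10 + sd(c(8,12)) = 10 + 2.8284271...
  pl2 <- make_plate(mfi[, 1, drop = FALSE], n_empty = 2)
  pl2$mfi[c("E1", "E2"), 1] <- c(8, 12)
  expect_equal(estimate_background(pl2), 10 + sqrt(8), tolerance = 1e-12)
  # error paths: no empty wells / only control analytes
  pl3 <- pl
  pl3$well_role[] <- "sample"
  expect_error(estimate_background(pl3), "empty")
  pl4 <- pl
  pl4$analyte_role[] <- "control_tag"
  expect_error(estimate_background(pl4), "control")
})

test_that("background subtraction floors at zero and adds one", {
  mfi <- matrix(c(500, 100, 120, 130), 2, 2,
                dimnames = list(c("s1", "s2"), c("a1", "a2")))
  pl <- make_plate(mfi)
  out <- subtract_and_floor(pl, 120)
  expect_equal(out["s1", "a1"], 381)   # 500 - 120 + 1
  expect_equal(out["s2", "a1"], 1)     # below background -> exactly 1
  expect_equal(out["s1", "a2"], 1)     # at background -> exactly 1
  expect_equal(out["s2", "a2"], 11)
  expect_true(all(out >= 1))
  # all-background plate collapses to the all-ones matrix
  allbg <- make_plate(matrix(50, 3, 2, dimnames = list(paste0("s", 1:3),
                                                       c("a1", "a2"))))
  expect_true(all(subtract_and_floor(allbg, 120) == 1))
  # monotone in the input MFI
  expect_true(all(diff(subtract_and_floor(
    make_plate(matrix(seq(0, 400, 50), 9, 1,
                      dimnames = list(paste0("s", 1:9), "a1"))), 120)) >= 0))
})

test_that("clinical join retains the intersection in clinical order", {
  x <- matrix(rnorm(12), 4, 3,
              dimnames = list(c("p1", "p2", "p3", "p4"), c("a", "b", "c")))
  clin <- data.frame(patient_id = c("p3", "p1"), age = c(70, 65))
  jn <- join_clinical(x, clin)
  expect_identical(rownames(jn$values), c("p3", "p1"))
  expect_identical(sort(jn$excluded), c("p2", "p4"))
  expect_equal(jn$n_excluded, 2)
  # idempotence: joining twice equals joining once
  jn2 <- join_clinical(jn$values, jn$clinical)
  expect_identical(jn2$values, jn$values)
  expect_equal(jn2$n_excluded, 0)
  # minimal join
  expect_equal(dim(join_clinical(x, clin[1, ])$values), c(1L, 3L))
  # error paths
  expect_error(join_clinical(x, data.frame(patient_id = c("q1", "q2"))),
               "no overlap")
  expect_error(join_clinical(x, data.frame(patient_id = c("p1", "p1"))),
               "duplicate")
})

test_that("the study join drops exactly the nine unmatched samples", {
  ds <- simulate_bead_array(sba_config(rng_seed = 13))
  corrected <- subtract_and_floor(ds$plate, estimate_background(ds$plate))
  jn <- join_clinical(corrected, ds$clinical)
  expect_equal(jn$n_excluded, 9)
  expect_equal(nrow(jn$values), 116)
  expect_setequal(jn$excluded, ds$truth$dropout_ids)
})

test_that("normalization leaves a patient identical to the reference unchanged", {
  set.seed(31)
  m <- 20
  base <- 2^runif(m, 5, 11)
  # seven patients; patient 1 holds the exact per-antigen median
  x <- t(sapply(1:7, function(i) base * 2^rnorm(m, 0, 0.3)))
  for (j in seq_len(m)) x[1, j] <- sort(x[, j])[4]
  dimnames(x) <- list(paste0("p", 1:7), paste0("a", 1:m))
  out <- robust_spline_normalize(x)
  expect_equal(log2(out[1, ]), log2(x[1, ]), tolerance = 1e-6)
})

test_that("a patient scaled by two is mapped back onto the reference", {
  set.seed(77)
  m <- 40
  base <- 2^seq(5, 11, length.out = m)
  x <- t(sapply(1:20, function(i) base * 2^rnorm(m, 0, 0.05)))
  x <- rbind(x, scaled = base * 2)
  rownames(x) <- c(paste0("p", 1:20), "scaled")
  colnames(x) <- paste0("a", seq_len(m))
  out <- robust_spline_normalize(x)
  expect_true(all(abs(out["scaled", ] / base - 1) < 0.02))
  # agrees with an independent isotonic-fit oracle on the same pairs
  iso <- isoreg(log2(x["scaled", ]), log2(apply(x[1:20, ], 2, median)))
  oracle <- approx(sort(log2(x["scaled", ])), iso$yf,
                   xout = log2(x["scaled", ]))$y
  expect_equal(log2(out["scaled", ]), oracle, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("quantile mode equalizes the sorted values of every patient", {
  x <- matrix(2^runif(40, 4, 12), 2, 20,
              dimnames = list(c("p1", "p2"), paste0("a", 1:20)))
  out <- robust_spline_normalize(x, mode = "quantile")
  expect_equal(sort(out[1, ]), sort(out[2, ]), ignore_attr = TRUE)
})

test_that("normalization preserves within-patient rank order and shrinks scale shifts", {
  set.seed(19)
  base <- 2^runif(30, 5, 11)
  x <- t(sapply(1:12, function(i) base * 2^rnorm(30, 0, 0.2) *
                  2^rnorm(1, 0, 0.6)))
  dimnames(x) <- list(paste0("p", 1:12), paste0("a", 1:30))
  out <- robust_spline_normalize(x)
  for (i in 1:12) {
    o <- order(x[i, ])
    expect_true(all(diff(out[i, o]) >= -1e-9))
  }
  pair_gap <- function(mat) {
    med <- apply(log2(mat), 1, median)
    mean(abs(outer(med, med, "-")))
  }
  expect_lte(pair_gap(out), pair_gap(x) + 1e-9)
  expect_error(robust_spline_normalize(x - 100), "positive")
  expect_error(robust_spline_normalize(x[, 1:5]), "at least 8")
})

test_that("Box-Cox estimates lambda by profile likelihood", {
  # closed form: the log transform at lambda = 0
  expect_equal(boxcox_apply(8, 0), log(8))
  set.seed(8)
  # lognormal column: lambda near 0
  x1 <- exp(rnorm(500, 2, 0.7))
  expect_lt(abs(boxcox_lambda(x1)), 0.15)
  # already-normal column: lambda near 1 (mean over replicates; single
  # draws of the profile MLE are noisy for near-symmetric data)
  lam1 <- mean(replicate(10, boxcox_lambda(rnorm(500, 100, 5))))
  expect_lt(abs(lam1 - 1), 0.5)
  # agreement with the MASS profile-likelihood oracle
  bc <- MASS::boxcox(x1 ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(boxcox_lambda(x1) - bc$x[which.max(bc$y)]), 0.01)
})

test_that("Box-Cox transform offsets non-positive data and flags constants", {
  x <- cbind(a = rnorm(50, 5, 2), b = exp(rnorm(50)), cst = rep(4, 50))
  x[1, "a"] <- -3
  rownames(x) <- paste0("p", 1:50)
  bc <- boxcox_transform(x)
  expect_equal(bc$offset, 1 - min(x))
  expect_identical(bc$constant_antigens, "cst")
  expect_equal(unname(bc$lambda["cst"]), 1)
  expect_true(all(is.finite(bc$values)))
  expect_true(all(is.finite(bc$lambda)))
})

test_that("zero-variance filtering removes exactly the flat antigens", {
  x <- cbind(a = rnorm(20), b = rep(2, 20), c = rnorm(20))
  rownames(x) <- paste0("p", 1:20)
  vf <- zero_variance_filter(x)
  expect_identical(vf$removed, "b")
  expect_identical(colnames(vf$values), c("a", "c"))
  expect_length(zero_variance_filter(x[, c("a", "c")])$removed, 0)
  expect_error(zero_variance_filter(x[, "b", drop = FALSE]), "zero variance")
  # scoped filtering: flat only within the given patient subset
  x2 <- cbind(a = rnorm(20), b = c(rep(1, 10), rnorm(10)))
  rownames(x2) <- paste0("p", 1:20)
  expect_identical(zero_variance_filter(x2, scope = 1:10)$removed, "b")
})

test_that("the filter recovers the six planted low-tier constants", {
  ds <- simulate_bead_array(sba_config(rng_seed = 21))
  corrected <- subtract_and_floor(ds$plate, estimate_background(ds$plate))
  jn <- join_clinical(corrected, ds$clinical)
  low <- names(ds$truth$tier_of_patient)[ds$truth$tier_of_patient == "low"]
  vf <- zero_variance_filter(jn$values, scope = intersect(low, rownames(jn$values)))
  expect_setequal(vf$removed, ds$truth$zero_variance_antigens)
  expect_length(vf$removed, 6)
})

test_that("the full pipeline yields a complete normalized matrix", {
  ds <- simulate_bead_array(sba_config(rng_seed = 17))
  nm <- preprocess_plate(ds$plate, ds$clinical)
  expect_s3_class(nm, "sba_norm")
  expect_equal(dim(nm$values), c(116L, 92L))
  expect_false(anyNA(nm$values))
  expect_true(all(is.finite(nm$lambda)))
  expect_length(nm$excluded_samples, 9)
  expect_identical(nm$clinical$patient_id, rownames(nm$values))
})
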