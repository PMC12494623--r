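#' Simulate a complete synthetic bead-array study
#'
#' Generates an MFI plate (samples x analytes, four assay controls, empty
#' wells), a clinical table for the retained patients, a protein-interaction
#' graph with a planted bridge node, and a ground-truth record of everything
#' planted.  The generative model, per patient \eqn{i} and antigen \eqn{j}:
#' \deqn{MFI_{ij} = round( e^{\mu_j + b_i w_j + s_{ij} + \log g_i} + \epsilon_{ij} )}
#' where \eqn{\mu_j} is the antigen's log-titer level, \eqn{b_i =
#' \log(\mathrm{tier\ scale}_i)} the reactivity-tier boost, \eqn{w_j} the
#' antigen's susceptibility to broad reactivity (zero for the tier-stable
#' majority of the panel), \eqn{s_{ij}} Gaussian
#' biological noise (with a shared factor inside co-reactive blocks),
#' \eqn{g_i} a lognormal technical sample scale and \eqn{\epsilon_{ij}}
#' additive plate background \eqn{N(\beta, \sigma_\beta)}; values are
#' floored at zero.  Planted antigen-clinical Spearman correlations are
#' realized through a Gaussian copula on the ranks of the *emitted* MFI
#' values, so the recorded targets are not attenuated by assay noise.
#'
#' Identical configurations (seed included) produce byte-identical
#' datasets; the caller's RNG stream is left untouched.
#'
#' @param config an [sba_config()] object.
#' @return An object of class `sba_dataset`: list with elements `plate`
#'   (class `sba_plate`: `mfi` matrix, `well_role`, `analyte_role`),
#'   `clinical` (data.frame), `graph` (igraph, see
#'   [simulate_interaction_graph()]), `truth` (planted ground truth) and
#'   `config`.
#' @examples
#' ds <- simulate_bead_array(sba_config(rng_seed = 42))
#' dim(ds$plate$mfi)
#' @export
simulate_bead_array <- function(config) {
  validate_sba_config(config)
  with_seed(config$rng_seed, simulate_bead_array_impl(config))
}

simulate_bead_array_impl <- function(cfg) {
  lay <- panel_layout(cfg)
  n <- cfg$n_recruited
  m <- cfg$n_antigens
  tiers_nm <- c("high", "intermediate", "low")

  sample_ids <- sprintf("PAT%03d", seq_len(n))
  dropout <- sort(sample.int(n, cfg$n_dropout))
  retained <- setdiff(seq_len(n), dropout)

  # reactivity tiers: exact counts among retained patients, sampled for dropouts
  tier <- character(n)
  cnt <- largest_remainder(cfg$tier_fractions[tiers_nm] * length(retained))
  tier[retained] <- sample(rep(tiers_nm, cnt))
  if (length(dropout)) {
    tier[dropout] <- sample(tiers_nm, length(dropout), replace = TRUE,
                            prob = cfg$tier_fractions[tiers_nm])
  }

  p_male <- cfg$clinical$categorical$p[cfg$clinical$categorical$parameter == "sex"]
  sex <- ifelse(stats::runif(n) < p_male, "male", "female")

  # latent log-titers: antigen-specific levels spread across the intensity
  # range (the tier-stable majority of the panel anchors normalization)
  mu <- stats::rnorm(m, cfg$signal_meanlog, 0.9)
  # individually planted antigens emulate antigens whose reactivity was
  # reliably measurable: keep them clear of the background floor
  for (pa in cfg$planted_assoc) {
    if (!is.null(pa$antigens)) mu[pa$antigens] <- cfg$signal_meanlog + 0.5
  }
  sd_j <- rep(cfg$signal_sdlog, m)
  if (length(cfg$coreactive_blocks)) {
    # co-reactive antigens share a common driver; their idiosyncratic
    # within-antigen dispersion is correspondingly smaller
    for (bl in cfg$coreactive_blocks) {
      sd_j[bl$indices] <- cfg$signal_sdlog * (bl$sd_shrink %||% 0.7)
    }
  }

  e <- matrix(stats::rnorm(n * m), n, m)
  f <- NULL
  if (length(cfg$coreactive_blocks)) {
    f <- matrix(stats::rnorm(n * length(cfg$coreactive_blocks)), n,
                length(cfg$coreactive_blocks))
    for (k in seq_along(cfg$coreactive_blocks)) {
      bl <- cfg$coreactive_blocks[[k]]
      # loading may be tier-scoped: strong co-reactivity can be a feature
      # of the highly reactive patients only
      lam <- rep(bl$loading, n)
      if (!is.null(bl$scope_tier)) {
        lam[tier != bl$scope_tier] <- bl$loading_out %||% bl$loading
      }
      e[, bl$indices] <- lam * f[, k] +
        sqrt(1 - lam^2) * e[, bl$indices, drop = FALSE]
    }
  }

  L <- sweep(e, 2, sd_j, `*`)
  L <- sweep(L, 2, mu, `+`)
  # tier boost with antigen-specific susceptibility: broad reactivity
  # elevates responsive antigens to different degrees, so reactivity tiers
  # are a compositional signature rather than a pure scale shift (a pure
  # shift would be indistinguishable from a technical effect)
  boost <- log(cfg$tier_scale[tier])
  suscept <- stats::setNames(rep(0, m), lay$names)
  if (length(lay$responsive)) {
    suscept[lay$responsive] <- stats::runif(length(lay$responsive), 1.5, 2.5)
    L[, lay$responsive] <- L[, lay$responsive] +
      outer(boost, suscept[lay$responsive])
  }

  n_aff <- round(m / 2)
  sex_affected <- sort(sample.int(m, n_aff))
  if (cfg$sex_effect_size != 0 && n_aff > 0) {
    male <- sex == "male"
    L[male, sex_affected] <- L[male, sex_affected] +
      cfg$sex_effect_size * cfg$signal_sdlog
  }

  g_i <- exp(stats::rnorm(n, 0, cfg$tech_sd))
  L <- L + log(g_i)

  mfi <- exp(L) +
    matrix(stats::rnorm(n * m, cfg$background_mean, cfg$background_sd), n, m)
  mfi <- pmax(round(mfi), 0)

  # antigens constant within the low tier (instrument saturating at a fixed
  # readout for these patient-antigen combinations)
  if (length(lay$zv)) {
    low <- tier == "low"
    const_val <- round(exp(mu[lay$zv]) + cfg$background_mean)
    mfi[low, lay$zv] <- matrix(const_val, sum(low), length(lay$zv), byrow = TRUE)
  }

  colnames(mfi) <- lay$names
  rownames(mfi) <- sample_ids

  # assay controls and empty wells
  ctrl_names <- c("CTRL_HIS6ABP", "CTRL_BLANK", "CTRL_ANTI_HIGG", "CTRL_EBNA1")
  ctrl_roles <- c("control_tag", "control_blank", "control_loading",
                  "control_positive")
  ctrl_mean <- c(800, cfg$background_mean, 15000, 8000)
  ctrl_sd <- c(80, cfg$background_sd, 500, 2000)
  ctrl <- sapply(seq_along(ctrl_names), function(k) {
    pmax(round(stats::rnorm(n, ctrl_mean[k], ctrl_sd[k])), 0)
  })
  colnames(ctrl) <- ctrl_names
  full <- cbind(mfi, ctrl)

  ne <- cfg$n_empty_wells
  empty <- matrix(stats::rnorm(ne * ncol(full), cfg$background_mean,
                               cfg$background_sd), ne, ncol(full))
  empty <- pmax(round(empty), 0)
  rownames(empty) <- sprintf("EMPTY%02d", seq_len(ne))
  colnames(empty) <- colnames(full)
  full <- rbind(full, empty)

  plate <- structure(list(
    mfi = full,
    well_role = stats::setNames(c(rep("sample", n), rep("empty", ne)),
                                rownames(full)),
    analyte_role = stats::setNames(c(rep("antigen", m), ctrl_roles),
                                   colnames(full))
  ), class = "sba_plate")

  clin <- simulate_clinical(cfg, lay, sample_ids, retained, tier, sex, mfi, f)
  graph <- simulate_interaction_graph(cfg)

  truth <- list(
    true_background = cfg$background_mean,
    background_sd = cfg$background_sd,
    tier_of_patient = stats::setNames(tier, sample_ids),
    dropout_ids = sample_ids[dropout],
    sex = stats::setNames(sex, sample_ids),
    planted_assoc = clin$realized,
    zero_variance_antigens = lay$names[lay$zv],
    susceptibility = suscept,
    stable_antigens = lay$names[lay$stable],
    responsive_antigens = lay$names[lay$responsive],
    coreactive_blocks = lapply(cfg$coreactive_blocks, function(bl)
      list(antigens = lay$names[bl$indices], loading = bl$loading)),
    sex_affected_antigens = lay$names[sex_affected],
    bridge_nodes = igraph::graph_attr(graph, "bridges"),
    config = cfg
  )

  structure(list(plate = plate, clinical = clin$table, graph = graph,
                 truth = truth, config = cfg),
            class = "sba_dataset")
}

# Clinical table for retained patients; planted parameters are coupled to
# the emitted antigen ranks (individual antigens) or to a co-reactive block
# factor (block plantings), with empirically solved weights so the realized
# Spearman correlation hits the target.
simulate_clinical <- function(cfg, lay, sample_ids, retained, tier, sex, mfi, f) {
  nr <- length(retained)
  num <- cfg$clinical$numeric
  catd <- cfg$clinical$categorical
  z <- matrix(stats::rnorm(nr * nrow(num)), nr, nrow(num),
              dimnames = list(NULL, num$parameter))

  realized <- data.frame(parameter = character(0), antigen = character(0),
                         target_rho = numeric(0), realized_rho = numeric(0),
                         tier = character(0), stringsAsFactors = FALSE)
  tier_r <- tier[retained]

  for (pa in cfg$planted_assoc) {
    if (!pa$parameter %in% num$parameter) {
      stop("planted parameter must be numeric: ", pa$parameter, call. = FALSE)
    }
    scope <- if (identical(pa$tier, "all")) rep(TRUE, nr) else tier_r == pa$tier
    ns <- sum(scope)
    if (ns < 4) next
    r_star <- 2 * sin(pi * pa$rho / 6)
    if (!is.null(pa$antigens)) {
      A <- pa$antigens
      Za <- apply(mfi[retained[scope], A, drop = FALSE], 2, rank_z)
      S <- stats::cor(Za)
      diag(S) <- diag(S) + 1e-8
      w <- solve(S, rep(r_star, length(A)))
      v <- as.numeric(crossprod(w, S %*% w))
      if (v > 0.98) {
        w <- w * sqrt(0.98 / v)
        v <- 0.98
      }
      z[scope, pa$parameter] <- as.numeric(Za %*% w) +
        sqrt(max(0, 1 - v)) * stats::rnorm(ns)
      idx <- A
    } else {
      k <- pa$block
      bl <- cfg$coreactive_blocks[[k]]
      fs <- f[retained[scope], k]
      fs <- (fs - mean(fs)) / stats::sd(fs)
      Za <- apply(mfi[retained[scope], bl$indices, drop = FALSE], 2, rank_z)
      calib <- mean(stats::cor(Za, fs))
      r_f <- max(-0.98, min(0.98, r_star / calib))
      z[scope, pa$parameter] <- r_f * fs + sqrt(1 - r_f^2) * stats::rnorm(ns)
      idx <- bl$indices
    }
    val <- z[scope, pa$parameter]
    rr <- vapply(idx, function(j)
      stats::cor(mfi[retained[scope], j], val, method = "spearman"), 0)
    realized <- rbind(realized, data.frame(
      parameter = pa$parameter, antigen = lay$names[idx],
      target_rho = pa$rho, realized_rho = rr,
      tier = pa$tier, stringsAsFactors = FALSE))
  }

  tab <- data.frame(patient_id = sample_ids[retained], stringsAsFactors = FALSE)
  for (i in seq_len(nrow(num))) {
    v <- num$mean[i] + num$sd[i] * z[, num$parameter[i]]
    v <- pmin(pmax(v, num$lo[i]), num$hi[i])
    if (num$integer[i]) v <- round(v)
    tab[[num$parameter[i]]] <- v
  }
  for (i in seq_len(nrow(catd))) {
    p <- catd$parameter[i]
    if (p == "sex") {
      tab$sex <- sex[retained]
    } else {
      tab[[p]] <- ifelse(stats::runif(nrow(tab)) < catd$p[i],
                         catd$level_yes[i], catd$level_no[i])
    }
  }
  list(table = tab, realized = realized)
}

# Apportion fractional counts to integers preserving the total
# (largest-remainder rule).
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  stats::setNames(as.integer(fl), names(x))
}

#' @export
print.sba_dataset <- function(x, ...) {
  cat("Synthetic bead-array dataset\n")
  cat(sprintf("  plate: %d wells x %d analytes (%d empty wells, %d controls)\n",
              nrow(x$plate$mfi), ncol(x$plate$mfi),
              sum(x$plate$well_role == "empty"),
              sum(x$plate$analyte_role != "antigen")))
  cat(sprintf("  clinical: %d patients, %d parameters\n",
              nrow(x$clinical), ncol(x$clinical) - 1L))
  cat(sprintf("  graph: %d nodes, %d edges, bridges: %s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              paste(x$truth$bridge_nodes, collapse = ", ")))
  invisible(x)
}
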