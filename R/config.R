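#' Simulation configuration for a synthetic bead-array study
#'
#' Builds and validates the full parameter set for [simulate_bead_array()].
#' The defaults emulate the cohort and assay the package targets: 125
#' recruited patients of whom 9 drop out before the clinical join, a panel
#' of 92 antigen fragments (67 distinct proteins, multi-fragment proteins
#' carry an `_k` suffix), at least four empty wells, additive plate
#' background around 120 MFI, three patient reactivity tiers of 35/45/36
#' retained patients with 4x/2x/1x multiplicative reactivity, three antigens
#' carrying a planted Spearman correlation of 0.3 with spherical equivalent
#' (SE), a 46-antigen co-reactive block with a high-tier-only negative CCT
#' association, six antigens constant within the low tier, a sex shift on a
#' random half of the responsive antigens, and an interaction graph with one
#' planted bridge node joining three communities.
#'
#' Antigens split into a minority of "responsive" antigens (which carry the
#' tier boost, with antigen-specific susceptibility) and a majority of
#' tier-stable antigens spanning the whole intensity range; the stable
#' majority is what rank-invariant normalization calibrates on, so genuine
#' reactivity-tier differences survive normalization.
#'
#' @param n_recruited number of plate samples (patients recruited).
#' @param n_dropout number of samples without a clinical row (excluded at
#'   the metadata join).
#' @param n_antigens number of antigen analytes on the panel.
#' @param n_empty_wells number of serum-free wells used for background
#'   estimation (at least 1; the study layout motivates the default 4).
#' @param background_mean,background_sd mean and SD (MFI units) of the
#'   additive plate background.
#' @param tier_fractions named proportions (`high`, `intermediate`, `low`)
#'   of retained patients per reactivity tier; must sum to 1.
#' @param tier_scale named multiplicative reactivity factors per tier;
#'   must be non-increasing from `high` to `low`.
#' @param responsive_fraction fraction of antigens carrying the tier boost.
#' @param signal_meanlog,signal_sdlog log-scale mean and within-antigen SD
#'   of the lognormal titer component (between-antigen level spread is
#'   fixed at 0.9 log units).
#' @param tech_sd log-scale SD of the per-sample technical scale factor.
#' @param sex_effect_size shift (in units of `signal_sdlog`) applied to a
#'   random half of the responsive antigens for male patients.
#' @param n_zero_variance_low number of antigens held exactly constant
#'   within the low tier.
#' @param planted_assoc list of planted antigen-clinical couplings; each
#'   element is a list with `parameter`, `rho`, `tier` (`"all"` or a tier
#'   name) and either `antigens` (panel indices, coupled individually via a
#'   Gaussian copula on emitted ranks) or `block` (index into
#'   `coreactive_blocks`, coupled through the block's common factor).
#'   `NULL` gives the default SE and high-tier CCT plantings; `list()`
#'   plants nothing.
#' @param coreactive_blocks list of co-reactive antigen blocks, each a list
#'   with `indices` and factor `loading` in (0, 1). `NULL` gives the default
#'   46/12/8 blocks (when the panel is large enough); `list()` plants none.
#' @param graph_spec list describing the synthetic interaction graph:
#'   `n_nodes`, `n_communities`, `n_bridges`, `p_within` (within-community
#'   edge probability) and `n_decoy` (sub-threshold cross-community edges).
#' @param clinical_overrides optional named list overriding entries of the
#'   default clinical parameter table (see [clinical_defaults()]).
#' @param rng_seed integer seed; identical configurations (seed included)
#'   produce byte-identical datasets.
#'
#' @return An object of class `sba_config` (a validated list).
#' @seealso [simulate_bead_array()], [simulate_interaction_graph()]
#' @export
sba_config <- function(n_recruited = 125,
                       n_dropout = 9,
                       n_antigens = 92,
                       n_empty_wells = 4,
                       background_mean = 120,
                       background_sd = 10,
                       tier_fractions = c(high = 35, intermediate = 45, low = 36) / 116,
                       tier_scale = c(high = 4, intermediate = 2, low = 1),
                       responsive_fraction = 0.25,
                       signal_meanlog = log(400),
                       signal_sdlog = 0.5,
                       tech_sd = 0.1,
                       sex_effect_size = 0.5,
                       n_zero_variance_low = 6,
                       planted_assoc = NULL,
                       coreactive_blocks = NULL,
                       graph_spec = list(n_nodes = 60, n_communities = 3,
                                         n_bridges = 1, p_within = 0.3,
                                         n_decoy = 15),
                       clinical_overrides = NULL,
                       rng_seed = 1L) {
  m <- as.integer(n_antigens)
  n_resp <- max(0L, round(responsive_fraction * m))

  if (is.null(coreactive_blocks)) {
    coreactive_blocks <- default_blocks(m)
  }
  if (is.null(planted_assoc)) {
    planted_assoc <- default_planted(m, coreactive_blocks)
  }

  cfg <- list(
    n_recruited = as.integer(n_recruited),
    n_dropout = as.integer(n_dropout),
    n_antigens = m,
    n_empty_wells = as.integer(n_empty_wells),
    background_mean = background_mean,
    background_sd = background_sd,
    tier_fractions = tier_fractions,
    tier_scale = tier_scale,
    responsive_fraction = responsive_fraction,
    n_responsive = n_resp,
    signal_meanlog = signal_meanlog,
    signal_sdlog = signal_sdlog,
    tech_sd = tech_sd,
    sex_effect_size = sex_effect_size,
    n_zero_variance_low = as.integer(n_zero_variance_low),
    planted_assoc = planted_assoc,
    coreactive_blocks = coreactive_blocks,
    graph_spec = graph_spec,
    clinical = clinical_defaults(clinical_overrides),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sba_config"
  validate_sba_config(cfg)
  cfg
}

# Default co-reactive blocks: a large block (the high-tier CCT carrier, the
# analogue of the broad CCT-correlated antigen group), plus two smaller
# blocks, laid out after the three free planted-association antigens.
default_blocks <- function(m) {
  if (m < 20) return(list())
  avail <- round(m * 66 / 92)  # indices 1:3 reserved for planted antigens
  s1 <- min(46L, floor(avail * 46 / 66))
  s2 <- min(12L, floor(avail * 12 / 66))
  s3 <- min(8L, max(0L, avail - s1 - s2))
  out <- list()
  at <- 4L
  for (s in c(s1, s2, s3)) {
    if (s >= 2) {
      out[[length(out) + 1L]] <- if (length(out) == 0) {
        # the broad co-reactive block is strongly coherent only among
        # high-reactivity patients (where its clinical correlation lives)
        list(indices = seq.int(at, at + s - 1L), loading = 0.65,
             scope_tier = "high", loading_out = 0.3)
      } else {
        list(indices = seq.int(at, at + s - 1L), loading = 0.7)
      }
      at <- at + s
    }
  }
  out
}

default_planted <- function(m, blocks) {
  out <- list()
  if (m >= 6) {
    out <- c(out, list(list(antigens = 1:3, parameter = "SE", rho = 0.3,
                            tier = "all")))
  }
  if (length(blocks) >= 1) {
    out <- c(out, list(list(block = 1L, parameter = "CCT", rho = -0.55,
                            tier = "high")))
  }
  out
}

#' Default clinical parameter distributions
#'
#' Gaussian means/SDs for the numeric parameters and Bernoulli probabilities
#' for the categorical ones, taken from the cohort summary where published
#' (age 70.97 +/- 6.12 y; IOP at diagnosis 32.44 +/- 5.58 mmHg; CCT
#' 541.40 +/- 33.04 um; MD -6.51 +/- 4.89 dB; MD at year 3 -10.07 +/- 6.36 dB;
#' VFI 85.56 +/- 14.40 %; VFI at year 3 74.92 +/- 19.04 %; ROP
#' -2.89 +/- 2.43 %/y; 2.70 +/- 0.84 medications; 48% male; 32% SLT; 59% GPA
#' progression) and from typical elderly-glaucoma ranges otherwise (SE, VA,
#' CD ratio, OCT RNFL thickness, comorbidity prevalences).
#'
#' @param overrides named list; each entry replaces the same-named default.
#' @return list with `numeric` (data.frame: parameter, mean, sd, lo, hi,
#'   integer) and `categorical` (data.frame: parameter, p, levels).
#' @export
clinical_defaults <- function(overrides = NULL) {
  num <- data.frame(
    parameter = c("age", "IOP", "CCT", "SE", "VA", "MD", "MD_3",
                  "VFI_diagnosis", "VFI_3", "ROP", "CD", "OCT", "medications"),
    mean = c(70.97, 32.44, 541.40, 0.5, 0.8, -6.51, -10.07,
             85.56, 74.92, -2.89, 0.70, 70, 2.70),
    sd   = c(6.12, 5.58, 33.04, 2.0, 0.25, 4.89, 6.36,
             14.40, 19.04, 2.43, 0.15, 15, 0.84),
    lo   = c(40, 21, 400, -12, 0.05, -17.9, -17.9, 41, 0, -15, 0.1, 30, 0),
    hi   = c(85, 60, 700, 12, 1.2, 0, 0, 100, 100, 5, 0.99, 120, 8),
    integer = c(TRUE, rep(FALSE, 11), TRUE),
    stringsAsFactors = FALSE
  )
  cat_ <- data.frame(
    parameter = c("sex", "diabetes", "hypertension", "migraine",
                  "smoking", "SLT", "GPA"),
    p = c(0.483, 0.20, 0.45, 0.10, 0.15, 0.32, 0.59),
    level_yes = c("male", "yes", "yes", "yes", "yes", "yes", "progression"),
    level_no = c("female", "no", "no", "no", "no", "no", "stable"),
    stringsAsFactors = FALSE
  )
  out <- list(numeric = num, categorical = cat_)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (nm %in% out$numeric$parameter) {
        i <- match(nm, out$numeric$parameter)
        for (f in names(overrides[[nm]])) out$numeric[i, f] <- overrides[[nm]][[f]]
      } else if (nm %in% out$categorical$parameter) {
        i <- match(nm, out$categorical$parameter)
        for (f in names(overrides[[nm]])) out$categorical[i, f] <- overrides[[nm]][[f]]
      } else {
        stop("unknown clinical parameter in overrides: ", nm, call. = FALSE)
      }
    }
  }
  out
}

validate_sba_config <- function(cfg) {
  stopifnot(is.list(cfg))
  counts <- c(cfg$n_recruited, cfg$n_antigens, cfg$n_empty_wells)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (cfg$n_dropout < 0 || cfg$n_dropout >= cfg$n_recruited) {
    stop("n_dropout must be in [0, n_recruited)", call. = FALSE)
  }
  tf <- cfg$tier_fractions
  if (!all(c("high", "intermediate", "low") %in% names(tf))) {
    stop("tier_fractions must be named high/intermediate/low", call. = FALSE)
  }
  if (abs(sum(tf) - 1) > 1e-9) {
    stop("tier_fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  ts <- cfg$tier_scale[c("high", "intermediate", "low")]
  if (any(is.na(ts))) stop("tier_scale must be named high/intermediate/low",
                           call. = FALSE)
  if (ts["high"] < ts["intermediate"] || ts["intermediate"] < ts["low"]) {
    stop("tier_scale must be non-increasing from high to low", call. = FALSE)
  }
  if (cfg$background_sd < 0) stop("background_sd must be >= 0", call. = FALSE)
  for (pa in cfg$planted_assoc) {
    if (abs(pa$rho) >= 1) stop("planted |rho| must be < 1", call. = FALSE)
    if (!is.null(pa$antigens) && any(pa$antigens > cfg$n_antigens)) {
      stop("planted antigen index exceeds n_antigens", call. = FALSE)
    }
    if (!is.null(pa$block) && pa$block > length(cfg$coreactive_blocks)) {
      stop("planted block index exceeds number of co-reactive blocks",
           call. = FALSE)
    }
  }
  for (bl in cfg$coreactive_blocks) {
    if (any(bl$indices > cfg$n_antigens)) {
      stop("co-reactive block index exceeds n_antigens", call. = FALSE)
    }
    if (bl$loading <= 0 || bl$loading >= 1) {
      stop("block loading must be in (0, 1)", call. = FALSE)
    }
  }
  gs <- cfg$graph_spec
  if (!is.null(gs)) {
    if (gs$n_bridges >= gs$n_nodes) {
      stop("n_bridges must be smaller than n_nodes", call. = FALSE)
    }
    if (gs$n_communities < 1) stop("need at least one community", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sba_config <- function(x, ...) {
  cat("Synthetic bead-array study configuration\n")
  cat(sprintf("  samples: %d recruited, %d dropout, %d empty wells\n",
              x$n_recruited, x$n_dropout, x$n_empty_wells))
  cat(sprintf("  antigens: %d (%d tier-responsive), background %g +/- %g MFI\n",
              x$n_antigens, x$n_responsive, x$background_mean, x$background_sd))
  cat(sprintf("  tiers: %s (scale %s)\n",
              paste(sprintf("%s %.2f", names(x$tier_fractions), x$tier_fractions),
                    collapse = ", "),
              paste(x$tier_scale, collapse = "/")))
  cat(sprintf("  planted associations: %d; co-reactive blocks: %d; seed %d\n",
              length(x$planted_assoc), length(x$coreactive_blocks), x$rng_seed))
  invisible(x)
}

# Deterministic panel layout derived from the configuration: antigen names
# (fragment suffixes included), anchor/responsive split, constant-in-low-tier
# indices.
panel_layout <- function(cfg) {
  m <- cfg$n_antigens
  n_two <- floor(m * 25 / 92)        # proteins with two fragments
  n_prot <- m - n_two
  nm <- character(m)
  k <- 1L
  for (p in seq_len(n_prot)) {
    pn <- sprintf("PRT%03d", p)
    nm[k] <- pn
    k <- k + 1L
    if (p <= n_two) {
      nm[k] <- paste0(pn, "_2")
      k <- k + 1L
    }
  }
  pool <- if (m > 3) seq.int(4L, m) else seq_len(m)
  n_resp <- min(cfg$n_responsive, length(pool))
  responsive <- if (n_resp > 0) {
    pool[unique(round(seq(1, length(pool), length.out = n_resp)))]
  } else integer(0)
  stable <- setdiff(seq_len(m), responsive)
  zv <- integer(0)
  if (cfg$n_zero_variance_low > 0) {
    pool <- if (length(cfg$coreactive_blocks) >= 1) {
      cfg$coreactive_blocks[[1]]$indices
    } else responsive
    zv <- utils::head(pool, cfg$n_zero_variance_low)
  }
  list(names = nm, stable = stable, responsive = responsive, zv = zv)
}
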