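#' Simulation configuration for replicated OTU time series
#'
#' Describes a multi-treatment, multi-generation rhizosphere-style study:
#' each treatment is sampled over `n_generations` time points with
#' `n_replicates` pots per time point, and each sample is a multinomial
#' draw of `depth` reads from a latent composition.  Known association
#' structure is planted two ways: `planted_pairs` (pairwise latent
#' correlations, optionally lagged by one generation) and `planted_modules`
#' (blocks of OTUs sharing a common latent factor).  Per-treatment knobs
#' grade the planted signal (`connectivity_scale`) and the community
#' evenness (`evenness`, a symmetric Dirichlet concentration).
#'
#' The latent model: per treatment, baseline log-abundances come from a
#' sorted Dirichlet draw (most abundant OTUs first, so planted structure —
#' which is assigned to low-index OTUs — sits in taxa abundant enough to be
#' observable at the configured read depth).  Per-OTU deviations follow a
#' stationary AR(1) across generations (`ar_smoothing`), scaled by
#' `sigma_latent`; replicate noise is lognormal (`sigma_replicate`); the
#' per-sample composition is a softmax of the log-abundances, and counts
#' are multinomial.  Negative planted correlations negate one member's
#' deviations.
#'
#' @param n_otus number of OTUs (default 120).
#' @param treatments ordered treatment labels (default
#'   `c("high","random","control")`).
#' @param n_generations time points per treatment (default 8).
#' @param n_replicates replicates per treatment x generation (default 8).
#' @param depth reads per sample (default 3000).
#' @param planted_pairs tibble with columns `otu_a`, `otu_b`, `rho`
#'   (latent correlation in \[-1,1\]) and `lag` (0 or 1), or NULL for the
#'   default of 10 pairs at rho 0.95 (seven lag-0, three lag-1).
#' @param planted_modules list of `list(otus =, rho =)` blocks, or NULL
#'   for the default eight blocks of eight members (within-module
#'   correlation 0.95).  Member sets must be disjoint.
#' @param connectivity_scale named numeric, one multiplier per treatment
#'   applied to all planted correlation strengths (default all 1).
#' @param evenness named numeric, one symmetric Dirichlet concentration
#'   per treatment; larger is more even (default all 60).
#' @param module_link loading of a shared community-wide factor on every
#'   module factor, in \[0,1); scaled by `connectivity_scale` like the
#'   within-module loadings, it interlinks the planted modules into one
#'   densely connected cluster at high connectivity (default 0.65).
#' @param ar_smoothing AR(1) coefficient of the latent trajectories in
#'   \[0,1) (default 0.1; 0 gives exchangeable time points).
#' @param sigma_latent SD of the latent log-abundance deviations (default 1).
#' @param sigma_replicate SD of the lognormal replicate noise (default 0.4).
#' @param seed integer RNG seed; all randomness flows from one stream.
#' @return a `sim_config` list.
#' @seealso [simulate_dataset()], [treatment_gradient_preset()]
#' @export
sim_config <- function(n_otus = 120,
                       treatments = c("high", "random", "control"),
                       n_generations = 8,
                       n_replicates = 8,
                       depth = 3000,
                       planted_pairs = NULL,
                       planted_modules = NULL,
                       connectivity_scale = NULL,
                       evenness = NULL,
                       module_link = 0.65,
                       ar_smoothing = 0.1,
                       sigma_latent = 1.0,
                       sigma_replicate = 0.4,
                       seed = 1) {
  if (n_otus < 1 || n_generations < 2 || n_replicates < 1 || depth < 1) {
    abort("n_otus, n_replicates and depth must be positive; n_generations >= 2")
  }
  if (anyDuplicated(treatments)) abort("duplicate treatment labels")
  if (length(treatments) < 1) abort("at least one treatment label required")
  if (ar_smoothing < 0 || ar_smoothing >= 1) abort("ar_smoothing must be in [0, 1)")
  if (module_link < 0 || module_link >= 1) abort("module_link must be in [0, 1)")

  otus <- otu_ids(n_otus)
  if (is.null(planted_pairs)) planted_pairs <- default_planted_pairs(otus)
  planted_pairs <- tibble::as_tibble(planted_pairs)
  if (nrow(planted_pairs) > 0) {
    stopifnot(all(c("otu_a", "otu_b", "rho", "lag") %in% names(planted_pairs)))
    if (any(abs(planted_pairs$rho) > 1)) abort("|rho| must be <= 1")
    if (!all(planted_pairs$lag %in% c(0L, 1L))) abort("lag must be 0 or 1")
    bad <- setdiff(c(planted_pairs$otu_a, planted_pairs$otu_b), otus)
    if (length(bad) > 0) {
      abort(paste0("planted pair references unknown OTU id(s): ",
                   paste(unique(bad), collapse = ", ")))
    }
    key <- pair_key(planted_pairs$otu_a, planted_pairs$otu_b)
    if (anyDuplicated(key)) abort("a planted pair appears more than once")
  }

  if (is.null(planted_modules)) planted_modules <- default_planted_modules(otus)
  if (length(planted_modules) > 0) {
    members <- unlist(lapply(planted_modules, `[[`, "otus"))
    if (anyDuplicated(members)) abort("planted module member sets must be disjoint")
    bad <- setdiff(members, otus)
    if (length(bad) > 0) {
      abort(paste0("planted module references unknown OTU id(s): ",
                   paste(unique(bad), collapse = ", ")))
    }
    rhos <- vapply(planted_modules, `[[`, numeric(1), "rho")
    if (any(rhos < 0 | rhos > 1)) abort("module rho must be in [0, 1]")
  }

  connectivity_scale <- fill_per_treatment(connectivity_scale, treatments, 1)
  evenness <- fill_per_treatment(evenness, treatments, 60)
  if (any(evenness <= 0)) abort("evenness must be > 0")
  if (any(connectivity_scale < 0)) abort("connectivity_scale must be >= 0")

  structure(list(
    n_otus = as.integer(n_otus), treatments = treatments,
    n_generations = as.integer(n_generations),
    n_replicates = as.integer(n_replicates), depth = as.integer(depth),
    planted_pairs = planted_pairs, planted_modules = planted_modules,
    connectivity_scale = connectivity_scale, evenness = evenness,
    module_link = module_link, ar_smoothing = ar_smoothing, sigma_latent = sigma_latent,
    sigma_replicate = sigma_replicate, seed = as.integer(seed)
  ), class = "sim_config")
}

otu_ids <- function(n) sprintf("OTU%03d", seq_len(n))

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

fill_per_treatment <- function(x, treatments, default) {
  if (is.null(x)) x <- rep(default, length(treatments))
  if (is.null(names(x))) {
    if (length(x) != length(treatments)) {
      abort("per-treatment parameter length must match number of treatments")
    }
    names(x) <- treatments
  }
  missing <- setdiff(treatments, names(x))
  if (length(missing) > 0) {
    abort(paste0("per-treatment parameter missing for: ",
                 paste(missing, collapse = ", ")))
  }
  x[treatments]
}

# pairs occupy the 20 most abundant OTUs so pairwise recovery is not
# limited by counting noise; modules occupy ranks 21-84 as eight blocks of
# eight, giving eight independent factor draws (a single unlucky factor
# realization then cannot erase a treatment's planted signal)
default_planted_modules <- function(otus) {
  lapply(0:7, function(b) {
    list(otus = otus[(21 + 8 * b):(28 + 8 * b)], rho = 0.95)
  })
}

default_planted_pairs <- function(otus) {
  idx <- 1:20
  a <- otus[idx[seq(1, 20, by = 2)]]
  b <- otus[idx[seq(2, 20, by = 2)]]
  tibble::tibble(otu_a = a, otu_b = b, rho = 0.95,
                 lag = c(rep(0L, 7), rep(1L, 3)))
}

#' Preset configuration with a treatment gradient
#'
#' Returns a [sim_config()] whose planted-association strength
#' (`connectivity_scale`) decreases and whose community evenness
#' (`evenness`) increases along the given treatment order — the first
#' label gets the densest, least even community.  Defaults grade
#' `connectivity_scale` from 1 down to 0.3 (convex spacing, so the middle
#' levels keep usable signal) and `evenness` from 45 up to 75 across the
#' levels.
#'
#' @param levels ordered treatment labels (2 to 5, no duplicates); the
#'   first level receives the strongest planted signal.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`.
#' @export
treatment_gradient_preset <- function(levels = c("high", "random", "control"), ...) {
  if (anyDuplicated(levels)) abort("duplicate treatment labels")
  n <- length(levels)
  if (n < 2 || n > 5) abort("between 2 and 5 treatment labels required")
  # convex spacing: detection power is convex in the latent correlation,
  # so equal steps in correlation would bunch the weaker levels together
  frac <- ((seq_len(n) - 1) / (n - 1))^2
  scale <- 1 - frac * (1 - 0.3)
  evenness <- seq(45, 75, length.out = n)
  names(scale) <- names(evenness) <- levels
  sim_config(treatments = levels, connectivity_scale = scale,
             evenness = evenness, ...)
}

#' Simulate a replicated OTU count time series with planted associations
#'
#' Draws one count table covering every treatment x generation x replicate
#' cell of the design in `config`, together with the ground truth needed to
#' score downstream edge recovery.  See [sim_config()] for the latent
#' model.  All randomness comes from a single stream seeded at
#' `config$seed`; the draw order is: the shared factors (community-wide,
#' one per module, one per planted pair), then per treatment (in
#' `config$treatments` order) baseline composition, idiosyncratic
#' deviations, replicate noise, multinomial counts.  The factor
#' trajectories are shared across treatments — the treatments experience
#' the same environmental forcing and differ in coupling strength — so
#' between-treatment contrasts are not driven by independent factor
#' realizations.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{table}{count tibble (one row per sample; metadata columns plus
#'       one column per OTU; every row sums to `depth`).}
#'     \item{truth}{`ground_truth` list: `true_edges` tibble (`otu_a`,
#'       `otu_b`, `sign`, `lag`, `rho`), `true_modules` tibble (`otu`,
#'       `module`), and `latent_series` (per treatment, a generations x
#'       OTU matrix of noise-free latent deviations).}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_otus = 20, n_generations = 4,
#'                                    n_replicates = 3, depth = 500,
#'                                    planted_pairs = tibble::tibble(
#'                                      otu_a = "OTU001", otu_b = "OTU002",
#'                                      rho = 0.9, lag = 0L),
#'                                    planted_modules = list()))
#' dim(sim$table)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth < config$n_otus) {
    warn(sprintf("depth (%d) is below the number of OTUs (%d); rare OTUs will mostly be unobserved",
                 config$depth, config$n_otus))
  }
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  otus <- otu_ids(config$n_otus)
  G <- config$n_generations
  R <- config$n_replicates
  phi <- config$ar_smoothing

  # stationary unit-variance AR(1) over g = 0..G (index 1 = pre-series
  # point so lag-1 pairs have a defined leading value)
  ar1 <- function() {
    z <- numeric(G + 1)
    z[1] <- rnorm(1)
    if (G >= 1) {
      for (g in 2:(G + 1)) z[g] <- phi * z[g - 1] + sqrt(1 - phi^2) * rnorm(1)
    }
    z
  }

  # Shared environmental forcing: the community-wide factor, the module
  # factors and the pair factors are drawn once and reused by every
  # treatment (all treatments sit in the same growth chamber on the same
  # generation schedule).  Treatments differ in how strongly their taxa
  # couple to these shared trajectories (connectivity_scale), in their
  # baseline composition (evenness), and in idiosyncratic/observation
  # noise, which are drawn per treatment.
  super_f <- ar1()
  mod_g <- lapply(config$planted_modules, function(m) ar1())
  pair_f <- if (nrow(config$planted_pairs) > 0) {
    lapply(seq_len(nrow(config$planted_pairs)), function(k) ar1())
  } else list()
  # one set of baseline uniforms, mapped through each treatment's own
  # Dirichlet quantile function: the treatments descend from a common
  # source community, and a treatment's evenness parameter reshapes that
  # shared rank-abundance curve rather than drawing an unrelated one
  base_u <- stats::runif(config$n_otus)

  rows <- list()
  latent_series <- list()
  for (trt in config$treatments) {
    scale_t <- config$connectivity_scale[[trt]]
    alpha_t <- config$evenness[[trt]]

    # baseline composition: sorted symmetric Dirichlet (abundant OTUs first)
    gam <- stats::qgamma(base_u, shape = alpha_t / config$n_otus, rate = 1)
    gam[gam < 1e-300] <- 1e-300
    p0 <- sort(gam / sum(gam), decreasing = TRUE)
    mu <- log(p0)

    # module factors: shared module trajectory blended with the shared
    # community-wide factor that interlinks modules
    l_eff <- min(config$module_link * scale_t, 0.9)
    mod_f <- lapply(mod_g, function(g) {
      sqrt(l_eff) * super_f + sqrt(1 - l_eff) * g
    })
    eps <- matrix(0, G + 1, config$n_otus)
    for (i in seq_len(config$n_otus)) eps[, i] <- ar1()

    # assemble latent deviations z (rows g = 0..G, cols OTUs)
    z <- eps
    for (mi in seq_along(config$planted_modules)) {
      m <- config$planted_modules[[mi]]
      r_eff <- min(m$rho * scale_t, 0.99)
      cols <- match(m$otus, otus)
      # alternating loading signs keep the module mass-balanced: planted
      # blocks mix positive and negative associations (|corr| = r_eff), so
      # their aggregate abundance does not swing the compositional
      # denominator and induce spurious coupling among unrelated OTUs
      for (k in seq_along(cols)) {
        sgn <- if (k %% 2 == 0) -1 else 1
        cc <- cols[k]
        z[, cc] <- sgn * sqrt(r_eff) * mod_f[[mi]] + sqrt(1 - r_eff) * eps[, cc]
      }
    }
    if (nrow(config$planted_pairs) > 0) {
      for (k in seq_len(nrow(config$planted_pairs))) {
        pp <- config$planted_pairs[k, ]
        rho_eff <- min(abs(pp$rho) * scale_t, 0.995)
        ca <- match(pp$otu_a, otus)
        cb <- match(pp$otu_b, otus)
        u <- pair_f[[k]]
        z[, ca] <- u
        # member b tracks u shifted by `lag` generations (b lags a)
        u_shift <- if (pp$lag == 1L) c(NA, u[seq_len(G)]) else u
        u_shift[1] <- u[1]  # pre-series point, never observed
        zb <- rho_eff * u_shift + sqrt(1 - rho_eff^2) * eps[, cb]
        if (pp$rho < 0) zb <- -zb
        z[, cb] <- zb
      }
    }

    zg <- z[-1, , drop = FALSE]  # observed generations 1..G
    rownames(zg) <- as.character(seq_len(G))
    colnames(zg) <- otus
    latent_series[[trt]] <- zg

    # replicate sampling
    counts <- matrix(0L, nrow = G * R, ncol = config$n_otus,
                     dimnames = list(NULL, otus))
    meta <- vector("list", G * R)
    k <- 0
    for (g in seq_len(G)) {
      lam_g <- mu + config$sigma_latent * zg[g, ]
      for (r in seq_len(R)) {
        lam <- lam_g + config$sigma_replicate * rnorm(config$n_otus)
        pr <- exp(lam - max(lam))
        pr <- pr / sum(pr)
        k <- k + 1
        counts[k, ] <- as.integer(rmultinom(1, size = config$depth, prob = pr))
        meta[[k]] <- list(sample_id = sprintf("%s_g%d_r%d", trt, g, r),
                          treatment = trt, generation = g, replicate = r)
      }
    }
    rows[[trt]] <- dplyr::bind_cols(dplyr::bind_rows(meta),
                                    tibble::as_tibble(counts))
  }

  table <- dplyr::bind_rows(rows)
  table$generation <- as.integer(table$generation)
  table$replicate <- as.integer(table$replicate)
  table <- set_units(table, "counts")

  true_edges <- if (nrow(config$planted_pairs) > 0) {
    dplyr::mutate(config$planted_pairs,
                  sign = ifelse(.data$rho >= 0, "+", "-"),
                  .after = "otu_b")
  } else {
    tibble::tibble(otu_a = character(), otu_b = character(),
                   sign = character(), rho = numeric(), lag = integer())
  }
  true_modules <- dplyr::bind_rows(lapply(seq_along(config$planted_modules), function(mi) {
    tibble::tibble(otu = config$planted_modules[[mi]]$otus, module = mi)
  }))
  if (nrow(true_modules) == 0) {
    true_modules <- tibble::tibble(otu = character(), module = integer())
  }

  truth <- structure(list(true_edges = true_edges, true_modules = true_modules,
                          latent_series = latent_series),
                     class = "ground_truth")
  list(table = table, truth = truth)
}
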