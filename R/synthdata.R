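# Synthetic wheat-trial generator: biallelic genotypes, line genetic values
# with covariance proportional to the GRM, year and year-by-line effects,
# NDVI covariates genetically correlated with the trait, Gaussian residuals.

#' Simulation configuration
#'
#' Defaults emulate the first study panel: 350 lines over 2 cropping cycles
#' with 4 vegetative and 2 grain-filling NDVI timepoints; the marker count
#' defaults to 2000 (enough for a stable GRM at this panel size).  Trait
#' scale mimics grain yield in g/m^2: mean 600 with a phenotypic coefficient
#' of variation around 0.12.
#'
#' @param J number of lines.
#' @param p number of markers.
#' @param years year labels.
#' @param environments environment labels (`"none"` for a single regime).
#' @param maf_range allele-frequency range markers are drawn from.
#' @param h2 target heritability `var(g) / (var(g) + var(e))` in `(0, 1]`.
#' @param var_year,var_gxe variance shares (of total phenotypic variance)
#'   for the year effect and the year-by-line interaction; their sum must be
#'   below 1.
#' @param ndvi_gen_cor target within-year correlation between each NDVI
#'   timepoint and the genetic value.
#' @param mu trait mean.
#' @param sigma_p total phenotypic standard deviation.
#' @param het_rate,miss_rate rates at which heterozygous and missing calls
#'   are injected into the categorical call matrix (for QC exercises).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(J = 350, p = 2000,
                       years = c("2015-2016", "2016-2017"),
                       environments = "none",
                       maf_range = c(0.05, 0.5), h2 = 0.5,
                       var_year = 0.2, var_gxe = 0.1,
                       ndvi_gen_cor = 0.5, mu = 600, sigma_p = 72,
                       het_rate = 0, miss_rate = 0, seed = NULL) {
  stopifnot(J >= 2, p >= 1, h2 > 0, h2 <= 1,
            var_year >= 0, var_gxe >= 0, var_year + var_gxe < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            abs(ndvi_gen_cor) <= 1, sigma_p > 0,
            het_rate >= 0, het_rate < 1, miss_rate >= 0, miss_rate < 1)
  structure(list(J = as.integer(J), p = as.integer(p), years = years,
                 environments = environments, maf_range = maf_range,
                 h2 = h2, var_year = var_year, var_gxe = var_gxe,
                 ndvi_gen_cor = ndvi_gen_cor, mu = mu, sigma_p = sigma_p,
                 het_rate = het_rate, miss_rate = miss_rate, seed = seed),
            class = "sim_config")
}

#' Simulate biallelic genotypes
#'
#' Each marker draws an allele frequency uniformly from `maf_range`; binary
#' genotypes are sampled independently per line (no linkage).  Heterozygous
#' and missing calls are injected into the categorical call matrix at the
#' configured rates; the clean 0/1 matrix is returned alongside.
#'
#' @param config a [sim_config].
#' @return list with `calls` (a [genotype_calls] with AA/AB/BB/NA entries),
#'   `coded` (clean `coded_genotypes`), and `freq` (true frequencies).
#' @export
simulate_genotypes <- function(config) {
  with_seed(config$seed, {
    J <- config$J; p <- config$p
    freq <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    X <- matrix(stats::rbinom(J * p, 1L, rep(freq, each = J)), J, p)
    line_ids <- sprintf("L%03d", seq_len(J))
    marker_ids <- sprintf("M%05d", seq_len(p))
    dimnames(X) <- list(line_ids, marker_ids)
    cm <- matrix(ifelse(X == 1, "BB", "AA"), J, p,
                 dimnames = dimnames(X))
    if (config$het_rate > 0) {
      flip <- matrix(stats::runif(J * p) < config$het_rate, J, p)
      cm[flip] <- "AB"
    }
    if (config$miss_rate > 0) {
      gone <- matrix(stats::runif(J * p) < config$miss_rate, J, p)
      cm[gone] <- NA_character_
    }
    coded <- structure(list(line_ids = line_ids, marker_ids = marker_ids,
                            X = X * 1.0, maf = pmin(colMeans(X), 1 - colMeans(X)),
                            qc_log = list(het_removed = 0L, miss_removed = 0L,
                                          maf_removed = 0L, imputed = 0L,
                                          surviving = p)),
                       class = "coded_genotypes")
    list(calls = genotype_calls(cm, line_ids, marker_ids),
         coded = coded, freq = freq)
  })
}

#' Simulate a phenotype trial with NDVI covariates
#'
#' Genetic values are drawn with covariance `sigma_g^2 G` through the
#' Cholesky factor of the GRM; year (or year-environment) effects and
#' year-by-line interaction effects carry the configured variance shares;
#' residuals are Gaussian with `var(g)/(var(g)+var(e)) = h2`.  NDVI
#' timepoints are built as `rho * g_std + sqrt(1-rho^2) * noise` on the NDVI
#' scale (about 0.6 +/- 0.08), plus small year- and timepoint-specific
#' offsets, so date-aligned and period-averaged covariate modes differ.
#'
#' @param config a [sim_config].
#' @param coded a `coded_genotypes` object (e.g. from [simulate_genotypes]).
#' @return list with `records` (a [trial_table]), `ndvi` (an [ndvi_table]),
#'   `features` (Cholesky-completed `genomic_features`), and `truth` (latent
#'   components and variances for recovery tests).
#' @export
simulate_trial <- function(config, coded) {
  features <- cholesky_factor(vanraden_grm(coded))
  J <- length(coded$line_ids)
  contexts <- expand.grid(year = config$years,
                          environment = config$environments,
                          stringsAsFactors = FALSE)
  n_ctx <- nrow(contexts)

  s2p <- config$sigma_p^2
  s2_ge <- s2p * (1 - config$var_year - config$var_gxe)
  s2g <- config$h2 * s2_ge
  s2e <- (1 - config$h2) * s2_ge
  s2y <- s2p * config$var_year
  s2u <- s2p * config$var_gxe

  with_seed(derive_seed(config$seed, 2L), {
    Lt <- t(features$L)
    g <- sqrt(s2g) * as.vector(Lt %*% stats::rnorm(J))
    year_eff <- stats::rnorm(n_ctx, 0, sqrt(s2y))
    u <- if (s2u > 0) {
      sapply(seq_len(n_ctx), function(i) sqrt(s2u) * as.vector(Lt %*% stats::rnorm(J)))
    } else matrix(0, J, n_ctx)

    rec <- do.call(rbind, lapply(seq_len(n_ctx), function(i) {
      data.frame(line = coded$line_ids, year = contexts$year[i],
                 environment = contexts$environment[i],
                 stringsAsFactors = FALSE)
    }))
    ctx_idx <- rep(seq_len(n_ctx), each = J)
    line_idx <- rep(seq_len(J), times = n_ctx)
    e <- stats::rnorm(nrow(rec), 0, sqrt(s2e))
    y <- config$mu + year_eff[ctx_idx] + g[line_idx] +
      u[cbind(line_idx, ctx_idx)] + e
    records <- trial_table(rec$line, rec$year, y,
                           environment = rec$environment, trait = "YLD")

    # NDVI: per (line, context, period, timepoint)
    rho <- config$ndvi_gen_cor
    g_std <- (g - mean(g)) / stats::sd(g)
    ndvi_rows <- list()
    for (i in seq_len(n_ctx)) {
      for (pd in c("vg", "gf")) {
        for (tp in seq_len(ndvi_timepoints[[pd]])) {
          offset <- stats::rnorm(1, 0, 0.02)
          vals <- 0.6 + offset +
            0.08 * (rho * g_std + sqrt(1 - rho^2) * stats::rnorm(J))
          ndvi_rows[[length(ndvi_rows) + 1L]] <- data.frame(
            line = coded$line_ids, year = contexts$year[i], period = pd,
            timepoint = tp, value = vals, stringsAsFactors = FALSE)
        }
      }
    }
    nd <- do.call(rbind, ndvi_rows)
    ndvi <- ndvi_table(nd$line, nd$year, nd$period, nd$timepoint, nd$value)

    list(records = records, ndvi = ndvi, features = features,
         truth = list(g = stats::setNames(g, coded$line_ids),
                      year_eff = stats::setNames(year_eff,
                        paste(contexts$year, contexts$environment, sep = "/")),
                      u = u, resid = e,
                      var = c(sigma2_g = s2g, sigma2_u = s2u,
                              sigma2_year = s2y, sigma2 = s2e),
                      h2 = config$h2, seed = config$seed))
  })
}

#' Write a simulated data set to CSV files plus a truth JSON
#'
#' @param sim a [simulate_trial] result.
#' @param geno the matching [simulate_genotypes] result.
#' @param dir output directory.
#' @return named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, geno, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genotypes = file.path(dir, "genotypes.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    ndvi = file.path(dir, "ndvi.csv"),
    truth = file.path(dir, "truth.json"))
  gm <- geno$calls$calls
  utils::write.csv(data.frame(line = rownames(gm), gm, check.names = FALSE),
                   paths$genotypes, row.names = FALSE)
  utils::write.csv(as.data.frame(sim$records), paths$phenotypes, row.names = FALSE)
  utils::write.csv(as.data.frame(sim$ndvi), paths$ndvi, row.names = FALSE)
  jsonlite::write_json(
    list(var = as.list(sim$truth$var), h2 = sim$truth$h2,
         g = as.list(sim$truth$g), seed = sim$truth$seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
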