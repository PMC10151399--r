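# Phenotype records, NDVI covariates and assembly of model-ready predictor
# blocks for every predictor set used in the analyses.

#' Construct a trial table
#'
#' @param line,year,environment,trait,value parallel vectors describing one
#'   adjusted phenotype record each.  `environment` defaults to `"none"`.
#' @return data.frame of class `trial_table` with one row per record; the
#'   (line, year, environment, trait) key must be unique and values finite.
#' @export
trial_table <- function(line, year, value, environment = "none", trait = "trait") {
  df <- data.frame(line = as.character(line), year = as.character(year),
                   environment = as.character(environment),
                   trait = as.character(trait), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$value))) stop_mmgp("non-finite phenotype values")
  key <- do.call(paste, c(df[c("line", "year", "environment", "trait")], sep = "\r"))
  if (anyDuplicated(key)) stop_mmgp("duplicated (line, year, environment, trait) records")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Construct an NDVI covariate table
#'
#' Long format: one row per (line, year, period, timepoint) measurement.
#' The vegetative (`vg`) period carries 4 timepoints and the grain-filling
#' (`gf`) period 2, matching the aerial campaign the models expect.
#'
#' @param line,year,period,timepoint,value parallel vectors; `period` in
#'   `{"vg","gf"}`, `timepoint` a positive integer index within period.
#' @return data.frame of class `ndvi_table`.
#' @export
ndvi_table <- function(line, year, period, timepoint, value) {
  period <- as.character(period)
  if (!all(period %in% c("vg", "gf"))) stop_mmgp("period must be 'vg' or 'gf'")
  df <- data.frame(line = as.character(line), year = as.character(year),
                   period = period, timepoint = as.integer(timepoint),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  class(df) <- c("ndvi_table", "data.frame")
  df
}

ndvi_timepoints <- c(vg = 4L, gf = 2L)

#' Specify a predictor set
#'
#' Mirrors the model rows of the study design: optional year main effect,
#' genomic term, year-by-line interaction, and NDVI covariate blocks either
#' date-aligned (4 vegetative + 2 grain-filling columns) or averaged within
#' period (1 + 1 columns).
#'
#' @param include_year include the year (or environment) main effect.
#' @param include_G include the genomic term.
#' @param include_year_by_G include the year-by-line interaction (requires
#'   both `include_year` and `include_G`).
#' @param ndvi character subset of `c("vg", "gf")`; empty means no NDVI.
#' @param ndvi_mode `"dates_aligned"`, `"average"` or `"none"`.
#' @return list of class `predictor_spec`.
#' @export
predictor_spec <- function(include_year = TRUE, include_G = TRUE,
                           include_year_by_G = FALSE,
                           ndvi = character(), ndvi_mode = "none") {
  ndvi <- as.character(ndvi)
  if (!all(ndvi %in% c("vg", "gf"))) stop_mmgp("ndvi must be a subset of c('vg','gf')")
  ndvi_mode <- match.arg(ndvi_mode, c("none", "dates_aligned", "average"))
  if (length(ndvi) && ndvi_mode == "none") {
    stop_mmgp("ndvi requested but ndvi_mode is 'none'")
  }
  if (include_year_by_G && !(include_year && include_G)) {
    stop_mmgp("include_year_by_G requires include_year and include_G")
  }
  structure(list(include_year = include_year, include_G = include_G,
                 include_year_by_G = include_year_by_G,
                 ndvi = ndvi, ndvi_mode = ndvi_mode),
            class = "predictor_spec")
}

#' Drop year terms from a predictor set for leave-one-out prediction
#'
#' When a whole year (or environment) is predicted from the others, the year
#' main effect and the year-by-line interaction cannot be estimated for the
#' held-out label and are removed from the model.
#'
#' @param spec a [predictor_spec].
#' @return The adjusted spec.
#' @export
loo_adjust_spec <- function(spec) {
  spec$include_year <- FALSE
  spec$include_year_by_G <- FALSE
  spec
}

# context label = the grouping used for the "year" effect; DS2-style runs
# leave an environment out, so environment plays the role of year there.
context_labels <- function(records, unit = c("year", "environment")) {
  unit <- match.arg(unit)
  as.character(records[[unit]])
}

#' Assemble model-ready predictor blocks
#'
#' Builds the design blocks consumed by every model: a one-hot year design,
#' the genomic inputs `Z_L L'`, and the NDVI covariate block (date-aligned or
#' period-averaged).  NDVI columns are standardized to zero mean and unit
#' variance using statistics computed on `train_idx` rows only, so test rows
#' never leak into the scaling.
#'
#' @param records a [trial_table].
#' @param spec a [predictor_spec].
#' @param features a [cholesky_factor]-completed `genomic_features` object.
#' @param ndvi an [ndvi_table]; required when `spec$ndvi` is non-empty.
#' @param train_idx record rows whose statistics standardize the NDVI block
#'   (default: all rows).
#' @param unit which label plays the role of the year effect (`"year"` or
#'   `"environment"`).
#' @return list with `y`, `X_year` (or NULL), `Z` (or NULL), `X_ndvi` (or
#'   NULL), `line_index`, `year_index`, `year_levels`, `line_ids`, `spec`.
#' @export
assemble_predictors <- function(records, spec, features, ndvi = NULL,
                                train_idx = seq_len(nrow(records)),
                                unit = "year") {
  n <- nrow(records)
  ctx <- context_labels(records, unit)
  year_levels <- sort(unique(ctx))
  year_index <- match(ctx, year_levels)
  line_index <- resolve_lines(records$line, features$line_ids)

  X_year <- NULL
  if (spec$include_year) {
    X_year <- matrix(0, n, length(year_levels),
                     dimnames = list(NULL, year_levels))
    X_year[cbind(seq_len(n), year_index)] <- 1
  }

  Z <- if (spec$include_G) genomic_inputs(features, line_index) else NULL

  X_ndvi <- NULL
  ndvi_scale <- NULL
  if (length(spec$ndvi)) {
    if (is.null(ndvi)) stop_mmgp("spec requests NDVI but no ndvi table given")
    X_ndvi <- build_ndvi_block(records, ndvi, spec$ndvi, spec$ndvi_mode)
    mu <- colMeans(X_ndvi[train_idx, , drop = FALSE])
    sg <- apply(X_ndvi[train_idx, , drop = FALSE], 2L, stats::sd)
    sg[!is.finite(sg) | sg < 1e-12] <- 1
    X_ndvi <- sweep(sweep(X_ndvi, 2L, mu, "-"), 2L, sg, "/")
    ndvi_scale <- list(mean = mu, sd = sg)
  }

  list(y = records$value, X_year = X_year, Z = Z, X_ndvi = X_ndvi,
       line_index = line_index, year_index = year_index,
       year_levels = year_levels, line_ids = features$line_ids,
       ndvi_scale = ndvi_scale, spec = spec)
}

build_ndvi_block <- function(records, ndvi, periods, mode) {
  periods <- intersect(c("vg", "gf"), periods)  # fixed column order
  key <- paste(ndvi$line, ndvi$year, ndvi$period, ndvi$timepoint, sep = "\r")
  cols <- list()
  for (p in periods) {
    tps <- seq_len(ndvi_timepoints[[p]])
    block <- sapply(tps, function(t) {
      want <- paste(records$line, records$year, p, t, sep = "\r")
      hit <- match(want, key)
      if (anyNA(hit)) {
        miss <- unique(paste(records$line, records$year, p, t)[is.na(hit)])
        stop_mmgp("missing NDVI for record(s): %s",
                  paste(utils::head(miss, 5L), collapse = "; "))
      }
      ndvi$value[hit]
    })
    block <- matrix(block, nrow = nrow(records))
    colnames(block) <- paste0(p, seq_along(tps))
    if (mode == "average") {
      block <- matrix(rowMeans(block), ncol = 1,
                      dimnames = list(NULL, paste0(p, "_avg")))
    }
    cols[[p]] <- block
  }
  do.call(cbind, cols)
}

#' Read phenotype and NDVI CSV files
#'
#' Phenotype CSV columns: `line, year, environment, trait, value`.
#' NDVI CSV columns: `line, year, period, timepoint, value`.
#'
#' @param path file path.
#' @return a [trial_table] / [ndvi_table].
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial_table(df$line, df$year, df$value,
              environment = df$environment %||% "none",
              trait = df$trait %||% "trait")
}

#' @rdname read_trial
#' @export
read_ndvi <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ndvi_table(df$line, df$year, df$period, df$timepoint, df$value)
}
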