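# Genotype containers, marker quality control, the VanRaden genomic
# relationship matrix and its Cholesky feature transform.

#' Construct a genotype-call set
#'
#' Holds raw biallelic calls for a panel of lines, prior to quality control.
#' Calls are categorical: `"AA"`, `"AB"`, `"BB"` or `NA`.  A numeric matrix
#' with entries in `[0, 1]` (and `NA`) is also accepted and is treated as
#' already homozygous-coded (0 = one homozygote, 1 = the other); fractional
#' values arise from mean imputation and are passed through unchanged.
#'
#' @param calls lines x markers matrix, character calls or numeric codes.
#' @param line_ids,marker_ids optional identifier vectors; default to the
#'   dimnames of `calls` or generated labels.
#' @return An object of class `genotype_calls`.
#' @export
genotype_calls <- function(calls, line_ids = NULL, marker_ids = NULL) {
  if (!is.matrix(calls)) stop_mmgp("`calls` must be a matrix")
  if (nrow(calls) < 2L || ncol(calls) < 1L) {
    stop_mmgp("need at least 2 lines and 1 marker (got %d x %d)",
              nrow(calls), ncol(calls))
  }
  line_ids <- line_ids %||% rownames(calls) %||% paste0("L", seq_len(nrow(calls)))
  marker_ids <- marker_ids %||% colnames(calls) %||% paste0("M", seq_len(ncol(calls)))
  if (length(line_ids) != nrow(calls) || length(marker_ids) != ncol(calls)) {
    stop_mmgp("id lengths do not match call matrix dimensions")
  }
  if (anyDuplicated(line_ids)) stop_mmgp("duplicated line ids")
  if (anyDuplicated(marker_ids)) stop_mmgp("duplicated marker ids")
  numeric_coded <- is.numeric(calls)
  if (is.character(calls)) {
    bad <- !is.na(calls) & !(calls %in% c("AA", "AB", "BB"))
    if (any(bad)) stop_mmgp("invalid calls: %s", paste(unique(calls[bad]), collapse = ", "))
  } else if (numeric_coded) {
    rng <- range(calls, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop_mmgp("numeric calls must lie in [0, 1]")
  } else {
    stop_mmgp("`calls` must be character or numeric")
  }
  dimnames(calls) <- list(line_ids, marker_ids)
  structure(list(line_ids = line_ids, marker_ids = marker_ids,
                 calls = calls, numeric_coded = numeric_coded),
            class = "genotype_calls")
}

#' Marker quality control and imputation
#'
#' Applies, in order: (1) removal of markers whose heterozygote fraction among
#' non-missing calls exceeds `het_max`; (2) recoding of remaining `AB` calls
#' to the homozygote with higher frequency at that marker (ties go to `AA`);
#' (3) removal of markers with missing fraction above `miss_max`; (4) 0/1
#' coding (`AA` = 0, `BB` = 1) and removal of markers with minor allele
#' frequency below `maf_min`; (5) mean imputation of residual missing values.
#'
#' @param calls a [genotype_calls] object.
#' @param het_max maximum tolerated heterozygote fraction (default 0.10).
#' @param miss_max maximum tolerated missing fraction (default 0.20).
#' @param maf_min minimum tolerated minor allele frequency (default 0.05).
#' @return An object of class `coded_genotypes` with elements `line_ids`,
#'   `marker_ids`, `X` (complete numeric matrix in `[0, 1]`), `maf` and
#'   `qc_log` (markers removed per rule and survivors).
#' @export
apply_qc <- function(calls, het_max = 0.10, miss_max = 0.20, maf_min = 0.05) {
  stopifnot(inherits(calls, "genotype_calls"))
  for (th in c(het_max, miss_max)) {
    if (!(th > 0 && th <= 1)) stop_mmgp("het_max/miss_max must lie in (0, 1]")
  }
  if (maf_min < 0 || maf_min >= 0.5) stop_mmgp("maf_min must lie in [0, 0.5)")

  cm <- calls$calls
  keep <- calls$marker_ids
  log <- list()

  if (!calls$numeric_coded) {
    het <- colMeans(cm == "AB", na.rm = TRUE)
    het[is.nan(het)] <- 0  # all-missing marker: handled by the missingness rule
    drop_het <- het > het_max
    log$het_removed <- sum(drop_het)
    cm <- cm[, !drop_het, drop = FALSE]

    # recode surviving AB calls to the majority homozygote
    for (j in seq_len(ncol(cm))) {
      ab <- which(!is.na(cm[, j]) & cm[, j] == "AB")
      if (length(ab)) {
        n_aa <- sum(cm[, j] == "AA", na.rm = TRUE)
        n_bb <- sum(cm[, j] == "BB", na.rm = TRUE)
        cm[ab, j] <- if (n_bb > n_aa) "BB" else "AA"
      }
    }
  } else {
    log$het_removed <- 0L
  }

  miss <- colMeans(is.na(cm))
  drop_miss <- miss > miss_max
  log$miss_removed <- sum(drop_miss)
  cm <- cm[, !drop_miss, drop = FALSE]

  X <- if (calls$numeric_coded) {
    cm
  } else {
    matrix(ifelse(is.na(cm), NA_real_, ifelse(cm == "BB", 1, 0)),
           nrow(cm), ncol(cm), dimnames = dimnames(cm))
  }
  freq <- colMeans(X, na.rm = TRUE)
  freq[is.nan(freq)] <- 0
  maf <- pmin(freq, 1 - freq)
  drop_maf <- maf < maf_min
  log$maf_removed <- sum(drop_maf)
  X <- X[, !drop_maf, drop = FALSE]
  maf <- maf[!drop_maf]

  if (ncol(X) == 0L) stop_mmgp("empty after QC: all %d markers removed",
                               length(calls$marker_ids))

  n_imputed <- sum(is.na(X))
  if (n_imputed) {
    for (j in seq_len(ncol(X))) {
      na <- is.na(X[, j])
      if (any(na)) X[na, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  log$imputed <- n_imputed
  log$surviving <- ncol(X)

  structure(list(line_ids = calls$line_ids, marker_ids = colnames(X),
                 X = X, maf = unname(maf), qc_log = log),
            class = "coded_genotypes")
}

#' @export
print.coded_genotypes <- function(x, ...) {
  cat(sprintf("coded_genotypes: %d lines x %d markers (removed: het %d, miss %d, maf %d; imputed %d cells)\n",
              nrow(x$X), ncol(x$X), x$qc_log$het_removed, x$qc_log$miss_removed,
              x$qc_log$maf_removed, x$qc_log$imputed))
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' With single-copy 0/1 coding, `p_k` the mean of marker `k` and
#' `M = X - 1 p'`, computes `G = M M' / sum_k p_k (1 - p_k)`.  Monomorphic
#' columns (`p_k` exactly 0 or 1) contribute nothing and are excluded from
#' both numerator and denominator.
#'
#' @param coded a [apply_qc] result (or compatible list with `X`, `line_ids`).
#' @return Object of class `genomic_features` with element `G` (symmetric,
#'   lines x lines).  Pass it to [cholesky_factor] to add the factor.
#' @export
vanraden_grm <- function(coded) {
  X <- coded$X
  if (nrow(X) < 2L) stop_mmgp("need at least 2 lines")
  if (anyNA(X)) stop_mmgp("missing values present; run apply_qc first")
  p <- colMeans(X)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_mmgp("zero denominator: all columns monomorphic")
  Xp <- X[, poly, drop = FALSE]
  p <- p[poly]
  M <- sweep(Xp, 2L, p, "-")
  G <- tcrossprod(M) / sum(p * (1 - p))
  G <- (G + t(G)) / 2
  dimnames(G) <- list(coded$line_ids, coded$line_ids)
  structure(list(G = G, L = NULL, jitter = NULL, line_ids = coded$line_ids),
            class = "genomic_features")
}

#' Cholesky factor of the relationship matrix
#'
#' Factors `G + jitter * I = L' L` with `L` upper triangular.  `jitter` starts
#' at zero and escalates through `base_jitter * 10^m`, `m = 0..6`, until the
#' factorization succeeds; the jitter actually used is recorded.
#'
#' @param features a [vanraden_grm] result, or a bare symmetric matrix.
#' @param base_jitter first non-zero jitter tried (default 1e-8).
#' @return The `genomic_features` object with `L` and `jitter` filled in.
#' @export
cholesky_factor <- function(features, base_jitter = 1e-8) {
  if (is.matrix(features)) {
    features <- structure(list(G = features, L = NULL, jitter = NULL,
                               line_ids = rownames(features) %||%
                                 paste0("L", seq_len(nrow(features)))),
                          class = "genomic_features")
  }
  G <- features$G
  if (max(abs(G - t(G))) > 1e-10) stop_mmgp("G is not symmetric")
  jitters <- c(0, base_jitter * 10^(0:6))
  for (j in jitters) {
    L <- tryCatch(chol(G + diag(j, nrow(G))), error = function(e) NULL)
    if (!is.null(L)) {
      features$L <- L
      features$jitter <- j
      return(features)
    }
  }
  ev <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  stop_mmgp("Cholesky failed at maximum jitter %g (smallest eigenvalue %g)",
            max(jitters), ev)
}

#' Genomic input rows for phenotype records
#'
#' Builds `Z_L L'`: row `r` is the row of `L'` belonging to the line of record
#' `r`, so that rowwise inner products reconstruct `G + jitter * I`.  This is
#' the genomic-modality input of the deep learning model and the line design
#' used by the samplers.
#'
#' @param features a [cholesky_factor] result.
#' @param record_line record-to-line map: integer indices into
#'   `features$line_ids`, or a character vector of line ids.
#' @return records x lines numeric matrix.
#' @export
genomic_inputs <- function(features, record_line) {
  if (is.null(features$L)) features <- cholesky_factor(features)
  idx <- resolve_lines(record_line, features$line_ids)
  Lt <- t(features$L)
  out <- Lt[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_lines <- function(record_line, line_ids) {
  if (is.character(record_line) || is.factor(record_line)) {
    record_line <- as.character(record_line)
    idx <- match(record_line, line_ids)
    if (anyNA(idx)) {
      stop_mmgp("unknown line id(s): %s",
                paste(unique(record_line[is.na(idx)]), collapse = ", "))
    }
    idx
  } else {
    idx <- as.integer(record_line)
    if (any(idx < 1L | idx > length(line_ids))) {
      stop_mmgp("line index out of range")
    }
    idx
  }
}

#' Read a genotype matrix from CSV/TSV
#'
#' First column holds line ids, the header row marker ids; cells are
#' `AA`/`AB`/`BB`/`NA` or numeric 0/1 codes.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv` means tab, anything else comma).
#' @return A [genotype_calls] object.
#' @export
read_genotypes <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (all(is.na(m)) || is.numeric(m)) {
    storage.mode(m) <- "double"
  }
  genotype_calls(m, line_ids = ids, marker_ids = colnames(m))
}

#' Write a coded genotype matrix or GRM to CSV
#'
#' @param x a `coded_genotypes` or `genomic_features` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genomic_csv <- function(x, path) {
  m <- if (inherits(x, "genomic_features")) x$G else x$X
  df <- data.frame(line = rownames(m) %||% x$line_ids, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
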