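# Shared fixtures, built in code.

# Wrap a complete numeric 0/1 matrix as a coded_genotypes object.
make_coded <- function(X, line_ids = paste0("L", seq_len(nrow(X)))) {
  dimnames(X) <- list(line_ids, paste0("M", seq_len(ncol(X))))
  structure(list(line_ids = line_ids, marker_ids = colnames(X), X = X,
                 maf = pmin(colMeans(X), 1 - colMeans(X)),
                 qc_log = list(het_removed = 0L, miss_removed = 0L,
                               maf_removed = 0L, imputed = 0L,
                               surviving = ncol(X))),
            class = "coded_genotypes")
}

# Small simulated trial used across tests.
tiny_sim <- function(J = 40, p = 200, seed = 1, ...) {
  cfg <- sim_config(J = J, p = p, seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_trial(cfg, geno$coded)
  sim$config <- cfg
  sim$geno <- geno
  sim
}

# Random categorical call matrix with heterozygous/missing calls injected
# and a couple of near-monomorphic markers, for QC stress tests.
random_calls <- function(n_lines, n_markers, seed) {
  set.seed(seed)
  freq <- stats::runif(n_markers, 0, 0.5)
  freq[sample(n_markers, max(1, n_markers %/% 10))] <- 0  # monomorphic
  X <- matrix(stats::rbinom(n_lines * n_markers, 1, rep(freq, each = n_lines)),
              n_lines, n_markers)
  cm <- ifelse(X == 1, "BB", "AA")
  het_rate <- stats::runif(n_markers, 0, 0.25)
  miss_rate <- stats::runif(n_markers, 0, 0.35)
  for (j in seq_len(n_markers)) {
    flip <- stats::runif(n_lines) < het_rate[j]
    cm[flip, j] <- "AB"
    gone <- stats::runif(n_lines) < miss_rate[j]
    cm[gone, j] <- NA_character_
  }
  genotype_calls(cm, paste0("L", seq_len(n_lines)), paste0("M", seq_len(n_markers)))
}

# Independent re-application of the QC rules, written directly from their
# definitions (used as the oracle for apply_qc survivor sets).
qc_oracle_survivors <- function(calls, het_max = 0.10, miss_max = 0.20,
                                maf_min = 0.05) {
  cm <- calls$calls
  keep <- character(0)
  for (j in seq_len(ncol(cm))) {
    col <- cm[, j]
    obs <- col[!is.na(col)]
    het <- if (length(obs)) mean(obs == "AB") else 0
    if (het > het_max) next
    if (any(obs == "AB")) {
      major <- if (sum(obs == "BB") > sum(obs == "AA")) "BB" else "AA"
      col[!is.na(col) & col == "AB"] <- major
    }
    if (mean(is.na(col)) > miss_max) next
    x <- ifelse(col == "BB", 1, 0)
    f <- mean(x, na.rm = TRUE)
    if (is.nan(f)) f <- 0
    if (min(f, 1 - f) < maf_min) next
    keep <- c(keep, colnames(cm)[j])
  }
  keep
}
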