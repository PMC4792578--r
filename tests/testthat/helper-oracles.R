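# Independent oracles and shared fixtures.  Oracles deliberately use a
# different computational route than the package code they check.

# ---- shared simulation cache (built once per test run) ----------------

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

default_sim <- function() cached("sim7", simulate_cohort(sim_config(seed = 7)))
default_stable <- function() cached("sp7", find_stable_pairs(default_sim()$normal))

# ---- oracle: upper-tail binomial(0.5) --------------------------------

# exhaustive outcome counting via Pascal's triangle (pure integer adds;
# exact in doubles for n <= 20); no logs, no choose()
oracle_binom_upper <- function(n, k) {
  counts <- 1
  for (i in seq_len(n)) counts <- c(counts, 0) + c(0, counts)
  if (k == 0) 1 else sum(counts[(k + 1):(n + 1)]) / 2^n
}

# literal enumeration of all 2^n coin-flip outcomes (n <= 14)
oracle_binom_enum <- function(n, k) {
  x <- 0:(2^n - 1)
  bits <- vapply(x, function(v)
    sum(bitwAnd(bitwShiftR(v, 0:(n - 1L)), 1L)), 0L)
  mean(bits >= k)
}

# ---- oracle: Harrell's C by explicit double loop ---------------------

oracle_c_index <- function(score, time, event) {
  n <- length(time)
  usable <- 0; conc <- 0; tied <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      usable <- usable + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / usable
}

# ---- oracle: exhaustive best subset under the zero-reversal rule -----

exhaustive_best_subset <- function(status, surv) {
  m <- nrow(status)
  best_c <- -Inf; best_sets <- list()
  for (mask in seq_len(2^m - 1)) {
    idx <- which(bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L) == 1L)
    unfav <- as.integer(colSums(status[idx, , drop = FALSE]) > 0L)
    cc <- tryCatch(harrell_c(unfav, surv)$c, error = function(e) NA)
    if (is.na(cc)) next
    if (cc > best_c + 1e-12) { best_c <- cc; best_sets <- list(idx) }
    else if (abs(cc - best_c) <= 1e-12)
      best_sets <- c(best_sets, list(idx))
  }
  list(c = best_c, subsets = best_sets)
}

# ---- misc fixtures ----------------------------------------------------

toy_surv <- function(time, event, ...,
                     ids = sprintf("s%02d", seq_along(time))) {
  survival_table(data.frame(sample_id = ids, time_months = time,
                            event = event, ..., stringsAsFactors = FALSE))
}

# a different strictly increasing map per sample (column)
monotone_per_sample <- function(m, seed = 401L) {
  set.seed(seed)
  for (j in seq_len(ncol(m))) {
    a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
    m[, j] <- a * exp(m[, j] / 8) + b
  }
  m
}

# wrap a raw 0/1 matrix as a reversal_matrix for rule-level tests
status_rev <- function(mat, sample_ids = sprintf("s%02d", seq_len(ncol(mat))),
                       pair_names = sprintf("P%d|Q%d", seq_len(nrow(mat)),
                                            seq_len(nrow(mat)))) {
  pairs <- data.frame(
    gene_a = sub("\\|.*", "", pair_names),
    gene_b = sub(".*\\|", "", pair_names), stringsAsFactors = FALSE)
  dimnames(mat) <- list(pair_names, sample_ids)
  structure(list(pairs = pairs, status = mat), class = "reversal_matrix")
}

# tiny expression matrix from explicit per-sample columns
expr_mat <- function(..., genes) {
  m <- cbind(...)
  rownames(m) <- genes
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}
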