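# Within-sample relative expression ordering (REO) primitives.
#
# A "stable pair" (A,B) means expression(A) > expression(B) in more than
# a threshold fraction (default 99%) of normal samples; tumours are then
# characterised by which stable orderings they reverse.  Everything here
# depends on the data only through within-sample ranks, so results are
# invariant under any per-sample strictly increasing transform.

#' Relative ordering of two genes within one sample
#'
#' @param sample_expression named numeric vector (gene id -> log2 value).
#' @param gene_a,gene_b gene identifiers present in the vector.
#' @return `"GREATER"`, `"LESS"` or `"TIE"` describing
#'   `expression(gene_a)` versus `expression(gene_b)`.
#' @export
pairwise_reo <- function(sample_expression, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!g %in% names(sample_expression))
      stop("gene not present in sample: ", g)
  a <- sample_expression[[gene_a]]
  b <- sample_expression[[gene_b]]
  if (a > b) "GREATER" else if (a < b) "LESS" else "TIE"
}

new_stable_pairs <- function(gene_a, gene_b, support, n_normal, threshold) {
  sp <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   support = as.numeric(support),
                   stringsAsFactors = FALSE)
  attr(sp, "n_normal") <- as.integer(n_normal)
  attr(sp, "threshold") <- as.numeric(threshold)
  class(sp) <- c("stable_pairs", "data.frame")
  sp
}

#' @export
print.stable_pairs <- function(x, ...) {
  cat(sprintf("Stable gene-pair set: %d pairs (threshold %.3g, %d normal samples)\n",
              nrow(x), attr(x, "threshold"), attr(x, "n_normal")))
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), 6L), ...)
  invisible(x)
}

pair_key <- function(gene_a, gene_b) {
  # unordered key; direction recoverable from gene_a
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\r")
}

pair_id <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "|")

#' Identify gene pairs with stable orderings in normal tissue
#'
#' A directed pair (A,B) is stable when A is strictly greater than B in
#' more than `threshold` of the normal samples ("more than 99%" read as a
#' strict count inequality: `count > threshold * n`).  Ties count against
#' stability on both sides, and the denominator is always the full normal
#' sample count.  The returned direction is the supported one, so the set
#' never contains both orientations of a pair.
#'
#' @param normal numeric matrix, genes x samples (log2 scale).
#' @param threshold stability fraction in (0.5, 1]; default 0.99.
#' @param gene_universe optional character vector; restrict the analysis
#'   to these gene ids (e.g. the intersection of two platforms).
#' @return a `stable_pairs` data frame with columns `gene_a`, `gene_b`,
#'   `support`, plus attributes `n_normal` and `threshold`.
#' @export
find_stable_pairs <- function(normal, threshold = 0.99, gene_universe = NULL) {
  validate_expression(normal)
  if (ncol(normal) < 2L) stop("need at least 2 normal samples")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  if (!is.null(gene_universe)) {
    keep <- rownames(normal) %in% gene_universe
    if (!any(keep)) stop("no genes of the matrix are in gene_universe")
    normal <- normal[keep, , drop = FALSE]
  }
  g <- nrow(normal)
  n <- ncol(normal)
  counts <- matrix(0L, g, g)
  for (s in seq_len(n)) {
    v <- normal[, s]
    counts <- counts + outer(v, v, ">")
  }
  need <- threshold * n                  # strict: count > threshold * n
  hits <- which(counts > need, arr.ind = TRUE)
  if (nrow(hits) == 0L)
    return(new_stable_pairs(character(), character(), numeric(),
                            n, threshold))
  ids <- rownames(normal)
  sp <- new_stable_pairs(ids[hits[, 1L]], ids[hits[, 2L]],
                         counts[hits] / n, n, threshold)
  sp <- sp[order(sp$gene_a, sp$gene_b), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Exact upper-tail binomial consistency test
#'
#' Probability that at least `k` of `n` independent fair coin flips
#' succeed: `P(X >= k)` for `X ~ Binomial(n, 0.5)`.  Used to judge
#' whether an observed fraction of direction-concordant gene pairs could
#' arise by chance (each pair agrees with probability 0.5 under the
#' null).  Summation is done over the smaller tail in log space, so n in
#' the tens of millions is handled without overflow; `log_p` stays
#' meaningful even when `p` underflows double precision.
#'
#' @param n number of trials (overlapping pairs); non-negative integer.
#' @param k number of successes (same-direction pairs); `0 <= k <= n`.
#' @return list with `p` (upper-tail probability), `log_p` (its natural
#'   log), `n` and `k`.
#' @export
binomial_consistency_test <- function(n, k) {
  if (length(n) != 1L || length(k) != 1L || is.na(n) || is.na(k) ||
      n < 0 || k < 0 || k > n || n != floor(n) || k != floor(k))
    stop("need integers 0 <= k <= n")
  if (k == 0) return(list(p = 1, log_p = 0, n = n, k = k))
  const <- n * log(0.5)                  # log 0.5^i (1-0.5)^(n-i), any i
  tail_lse <- function(from, to) {
    # log sum of binomial masses for i in from..to, chunked for memory
    parts <- numeric(0)
    i <- from
    while (i <= to) {
      j <- min(i + 5e6 - 1, to)
      parts <- c(parts, log_sum_exp(lchoose(n, i:j) + const))
      i <- j + 1
    }
    log_sum_exp(parts)
  }
  if (n - k + 1 <= k) {                  # upper tail is the smaller sum
    log_p <- tail_lse(k, n)
  } else {                               # complement of P(X <= k-1)
    log_lower <- tail_lse(0, k - 1)
    log_p <- log1p(-exp(log_lower))
  }
  log_p <- min(log_p, 0)                 # clamp fp noise at p = 1
  list(p = exp(log_p), log_p = log_p, n = n, k = k)
}

#' Intersect two stable-pair sets across platforms
#'
#' Overlap is counted on unordered gene pairs; `k` of the `n` overlapping
#' pairs agree in direction.  The consistency score is `k/n` and its
#' chance probability comes from [binomial_consistency_test()].  The
#' returned consistent set keeps only same-direction pairs, with support
#' equal to the smaller of the two supports.
#'
#' @param set1,set2 `stable_pairs` objects.
#' @return list with `consistent` (a `stable_pairs` object) and `result`
#'   (list `n`, `k`, `score`, `p`, `log_p`; `score` is `NA` when `n = 0`).
#' @export
intersect_stable_pairs <- function(set1, set2) {
  stopifnot(inherits(set1, "stable_pairs"), inherits(set2, "stable_pairs"))
  k1 <- pair_key(set1$gene_a, set1$gene_b)
  k2 <- pair_key(set2$gene_a, set2$gene_b)
  m <- match(k1, k2)
  ov <- which(!is.na(m))
  n <- length(ov)
  if (n == 0L) {
    empty <- new_stable_pairs(character(), character(), numeric(),
                              attr(set1, "n_normal"),
                              attr(set1, "threshold"))
    return(list(consistent = empty,
                result = list(n = 0L, k = 0L, score = NA_real_,
                              p = 1, log_p = 0)))
  }
  same <- set1$gene_a[ov] == set2$gene_a[m[ov]]
  k <- sum(same)
  bt <- binomial_consistency_test(n, k)
  keep <- ov[same]
  consistent <- new_stable_pairs(
    set1$gene_a[keep], set1$gene_b[keep],
    pmin(set1$support[keep], set2$support[m[keep]]),
    attr(set1, "n_normal"), attr(set1, "threshold"))
  list(consistent = consistent,
       result = list(n = n, k = k, score = k / n,
                     p = bt$p, log_p = bt$log_p))
}

#' Reversal status of stable pairs in tumour samples
#'
#' For each directed pair (A,B), stable as A > B in normal tissue, a
#' tumour sample scores 1 when it shows the strict opposite ordering
#' (B > A) and 0 otherwise; ties score 0 (in line with the normal
#' ordering by convention).
#'
#' @param tumor numeric matrix, genes x samples.
#' @param pairs a `stable_pairs` object or data frame with `gene_a`,
#'   `gene_b` (direction: a > b in normal).
#' @return a `reversal_matrix`: list with `pairs` (data frame) and
#'   `status` (integer matrix, pairs x samples, rownames `"a|b"`).
#' @export
reversal_status <- function(tumor, pairs) {
  validate_expression(tumor)
  pairs <- as.data.frame(pairs)[, c("gene_a", "gene_b")]
  if (nrow(pairs) == 0L) stop("no pairs supplied")
  absent <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(tumor))
  if (length(absent) > 0L)
    stop("genes absent from tumour matrix: ",
         paste(absent, collapse = ", "))
  a <- tumor[pairs$gene_a, , drop = FALSE]
  b <- tumor[pairs$gene_b, , drop = FALSE]
  status <- matrix(as.integer(b > a), nrow = nrow(pairs),
                   dimnames = list(pair_id(pairs$gene_a, pairs$gene_b),
                                   colnames(tumor)))
  structure(list(pairs = pairs, status = status),
            class = "reversal_matrix")
}

#' @export
print.reversal_matrix <- function(x, ...) {
  cat(sprintf("Reversal matrix: %d pairs x %d samples (%.1f%% reversed)\n",
              nrow(x$status), ncol(x$status), 100 * mean(x$status)))
  invisible(x)
}

#' Read / write stable-pair sets as TSV
#'
#' Columns `gene_a`, `gene_b`, `support`; the stated direction is
#' `gene_a > gene_b` in normal tissue.  Attributes `n_normal` and
#' `threshold` are carried in a comment header and round-trip losslessly.
#'
#' @param path file path.
#' @return for the reader, a `stable_pairs` object.
#' @export
read_stable_pairs <- function(path) {
  hdr <- readLines(path, n = 1L)
  n_normal <- NA_integer_; threshold <- NA_real_
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.]+", hdr))[[1L]]
    for (x in kv) {
      p <- strsplit(x, "=", fixed = TRUE)[[1L]]
      if (p[1L] == "n_normal") n_normal <- as.integer(p[2L])
      if (p[1L] == "threshold") threshold <- as.numeric(p[2L])
    }
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = "gene_a",
                          colClasses = list(character = c("gene_a", "gene_b")))
  new_stable_pairs(dt$gene_a, dt$gene_b, dt$support, n_normal, threshold)
}

#' @rdname read_stable_pairs
#' @param sp a `stable_pairs` object.
#' @export
write_stable_pairs <- function(sp, path) {
  stopifnot(inherits(sp, "stable_pairs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stable_pairs n_normal=%d threshold=%g",
                     attr(sp, "n_normal"), attr(sp, "threshold")), con)
  writeLines("gene_a\tgene_b\tsupport", con)
  if (nrow(sp) > 0L)
    writeLines(sprintf("%s\t%s\t%.17g", sp$gene_a, sp$gene_b, sp$support),
               con)
  invisible(path)
}
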