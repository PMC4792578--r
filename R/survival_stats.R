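# Survival-analysis primitives.  Cox partial-likelihood fitting is
# delegated to survival::coxph (Efron ties, Newton-Raphson, tol 1e-9);
# the concordance index, the Spearman test and the DEG direction-
# concordance check are implemented here because the pipeline's contracts
# (pair definition, tie handling, exact small-n permutation) are specific.

#' Construct / validate a survival table
#'
#' The clinical container used throughout: one row per sample with a
#' positive recurrence-free survival time in months, an event flag
#' (1 = recurrence observed, 0 = censored) and optional covariates such
#' as `age`, `grade`, `size_cm`, `node`, `treated`.
#'
#' @param df data frame with columns `sample_id`, `time_months`, `event`.
#' @return the validated data frame with class `survival_table`.
#' @export
survival_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("survival table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  if (any(!is.finite(df$time_months)) || any(df$time_months <= 0))
    stop("times must be positive and finite")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read a clinical table from TSV
#'
#' Required columns `sample_id`, `time_months`, `event`; any further
#' columns are kept as covariates.
#' @param path file path.
#' @return a `survival_table`.
#' @export
read_survival_table <- function(path) {
  survival_table(data.table::fread(path, sep = "\t", header = TRUE,
                                   colClasses = list(character = "sample_id")))
}

cox_result <- function(coef, se, n, n_events, converged = TRUE,
                       p_lrt = NA_real_) {
  z <- qnorm(0.975)
  structure(list(coef = coef, se = se, hr = exp(coef),
                 ci_low = exp(coef - z * se), ci_high = exp(coef + z * se),
                 p_wald = 2 * pnorm(-abs(coef / se)),
                 p_lrt = p_lrt,
                 n = n, n_events = n_events, converged = converged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: HR %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d (%d events)%s\n",
              x$hr, x$ci_low, x$ci_high, x$p_wald, x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

fit_cox <- function(X, surv) {
  # shared fitting core; X a numeric matrix of covariates (complete cases)
  fit <- NULL
  warned <- FALSE
  withCallingHandlers(
    fit <- survival::coxph(
      survival::Surv(surv$time_months, surv$event) ~ X,
      ties = "efron",
      control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- as.numeric(fit$coefficients)
  se <- sqrt(diag(as.matrix(fit$var)))
  # rely on coxph's own diagnostics: warnings flag non-convergence and
  # monotone likelihood; coefficient magnitude alone is no criterion
  # (fraction-scaled covariates legitimately give large per-unit coefs)
  converged <- !warned && all(is.finite(co)) && all(is.finite(se))
  list(coef = co, se = se, converged = converged,
       names = colnames(X), fit = fit)
}

#' Univariate Cox proportional-hazards regression
#'
#' Efron tie handling, Newton-Raphson with tolerance 1e-9 (at most 100
#' iterations); Wald two-sided p and 95% CI as `exp(coef +- 1.96 * SE)`.
#' A partial-likelihood-ratio p (`p_lrt`) is reported alongside: for
#' near-degenerate covariates (e.g. a disruption index that varies in a
#' handful of samples) the Wald z is unreliable in the tail, so the
#' screening stages test on `p_lrt`.  Non-convergence (including
#' monotone likelihood from perfect separation) is reported through
#' `converged = FALSE` so screening stages can exclude the result
#' rather than crash.
#'
#' @param x numeric (or 0/1) covariate vector, one value per row of `surv`.
#' @param surv a `survival_table`.
#' @return a `cox_result` list: `coef`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p_wald`, `p_lrt`, `n`, `n_events`, `converged`.
#' @export
cox_univariate <- function(x, surv) {
  surv <- survival_table(surv)
  x <- as.numeric(x)
  if (length(x) != nrow(surv)) stop("covariate length != sample count")
  if (sum(surv$event) < 2) stop("need at least 2 events")
  if (length(unique(x)) < 2L) stop("constant covariate")
  f <- fit_cox(matrix(x, ncol = 1L), surv)
  p_lrt <- pchisq(2 * diff(f$fit$loglik), df = 1, lower.tail = FALSE)
  cox_result(f$coef, f$se, nrow(surv), sum(surv$event), f$converged,
             p_lrt = as.numeric(p_lrt))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Joint fit over all covariates on complete cases (rows with any missing
#' covariate are dropped and counted).  Factors are expanded via
#' treatment contrasts.
#'
#' @param X data frame or matrix of covariates, rows aligned with `surv`.
#' @param surv a `survival_table`.
#' @return named list of `cox_result` objects (one per model column),
#'   with attributes `n_used` and `n_dropped`.
#' @export
cox_multivariate <- function(X, surv) {
  surv <- survival_table(surv)
  X <- as.data.frame(X)
  if (nrow(X) != nrow(surv)) stop("covariate rows != sample count")
  cc <- complete.cases(X)
  n_dropped <- sum(!cc)
  Xc <- X[cc, , drop = FALSE]
  sc <- survival_table(as.data.frame(surv)[cc, , drop = FALSE])
  mm <- stats::model.matrix(~ ., data = Xc)[, -1L, drop = FALSE]
  if (qr(mm)$rank < ncol(mm))
    stop("rank-deficient covariate matrix (collinear columns)")
  if (sum(sc$event) <= ncol(mm))
    stop("fewer events than covariates")
  f <- fit_cox(mm, sc)
  out <- lapply(seq_along(f$coef), function(j)
    cox_result(f$coef[j], f$se[j], nrow(sc), sum(sc$event), f$converged))
  names(out) <- colnames(mm)
  attr(out, "n_used") <- nrow(sc)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Unstratified log-rank (score) test with `n_groups - 1` degrees of
#' freedom, plus per-group Kaplan-Meier step functions.
#'
#' @param groups vector of group labels, one per row of `surv`.
#' @param surv a `survival_table`.
#' @return list with `chi2`, `df`, `p`, and `curves`: a named list of
#'   data frames (`time`, `surv`, `n_risk`, `n_event`) per group.
#' @export
km_logrank <- function(groups, surv) {
  surv <- survival_table(surv)
  groups <- as.character(groups)
  if (length(groups) != nrow(surv)) stop("group labels != sample count")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 non-empty groups")
  sd_ <- survival::survdiff(
    survival::Surv(surv$time_months, surv$event) ~ groups)
  df <- length(tab) - 1L
  chi2 <- as.numeric(sd_$chisq)
  fit <- survival::survfit(
    survival::Surv(surv$time_months, surv$event) ~ groups)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- lapply(split(seq_along(fit$time), strata), function(i)
    data.frame(time = fit$time[i], surv = fit$surv[i],
               n_risk = fit$n.risk[i], n_event = fit$n.event[i]))
  names(curves) <- sub("^groups=", "", names(curves))
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       curves = curves)
}

#' Harrell's concordance index
#'
#' Usable (ordered) pairs are those `(i, j)` with `t_i < t_j` and
#' `event_i = 1`; a pair is concordant when the earlier-failing subject
#' has the higher risk score, and tied scores contribute 0.5.  This is
#' the plain O(n^2) pair enumeration; it is invariant under strictly
#' increasing transforms of the score.
#'
#' @param score numeric risk scores (higher = predicted earlier failure).
#'   For a binary risk-group classification, code high-risk as 1 and
#'   low-risk as 0.
#' @param surv a `survival_table`.
#' @return list `c`, `n_usable`, `n_concordant`, `n_tied`.
#' @export
harrell_c <- function(score, surv) {
  surv <- survival_table(surv)
  score <- as.numeric(score)
  if (length(score) != nrow(surv)) stop("score length != sample count")
  t <- surv$time_months; e <- surv$event
  usable <- outer(t, t, "<") & (e == 1)        # row i fails before j
  n_usable <- sum(usable)
  if (n_usable == 0L) stop("no usable pairs (no ordered event times)")
  conc <- sum(usable & outer(score, score, ">"))
  tied <- sum(usable & outer(score, score, "=="))
  list(c = (conc + 0.5 * tied) / n_usable,
       n_usable = n_usable, n_concordant = conc, n_tied = tied)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values), order-preserving and clipped at
#' 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of the same length.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

all_perms <- function(n) {
  # all permutations of 1..n as an n! x n integer matrix
  p <- matrix(1L, 1L, 1L)
  for (k in seq_len(n)[-1L]) {
    p <- do.call(rbind, lapply(seq_len(k), function(i) {
      left <- p[, seq_len(i - 1L), drop = FALSE]
      right <- if (i <= k - 1L) p[, i:(k - 1L), drop = FALSE] else p[, 0L]
      cbind(left, k, right, deparse.level = 0)
    }))
  }
  p
}

#' Spearman rank correlation test
#'
#' Rank correlation with midranks for ties.  Two-sided p-value: exact
#' permutation null for `n <= 10`, t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (var(x) == 0 || var(y) == 0)
    stop("rho undefined for a constant vector")
  ra <- rank(x); rb <- rank(y)
  rho <- cor(ra, rb)
  if (n <= 10L) {
    P <- all_perms(n)
    rbP <- matrix(rb[P], nrow = nrow(P))
    Tstat <- as.numeric(rbP %*% ra)
    rho_perm <- (Tstat - n * mean(ra) * mean(rb)) /
      ((n - 1) * sd(ra) * sd(rb))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tval), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

welch_rows <- function(m, g1, g2) {
  # vectorised per-gene Welch t-test; returns two-sided p and mean diff
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  x1 <- m[, g1, drop = FALSE]; x2 <- m[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tval <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tval), df = df)
  p[!is.finite(p)] <- 1                  # zero-variance genes: untestable
  list(p = p, delta = m2 - m1)
}

#' Direction concordance of differential expression between two cohorts
#'
#' In each cohort, differentially expressed genes (DEGs) between its two
#' groups are found by per-gene Welch t-tests under Benjamini-Hochberg
#' FDR < `fdr`; the direction is the sign of `mean(group2) -
#' mean(group1)`.  The two DEG lists are intersected and the probability
#' that the observed number of direction-concordant shared genes arises
#' by chance (each agreeing with probability 0.5) is the upper-tail
#' binomial test.
#'
#' @param exprA,exprB expression matrices (genes x samples).
#' @param labelsA,labelsB two-level group label vectors aligned with the
#'   matrix columns.
#' @param fdr DEG threshold on the BH-adjusted p-values (default 0.05).
#' @return list `shared`, `same_direction`, `p`, `log_p`, `n_deg_a`,
#'   `n_deg_b`.
#' @export
deg_concordance <- function(exprA, labelsA, exprB, labelsB, fdr = 0.05) {
  deg_set <- function(m, labels) {
    validate_expression(m)
    labels <- as.character(labels)
    if (length(labels) != ncol(m)) stop("labels != sample count")
    lv <- sort(unique(labels))
    if (length(lv) != 2L) stop("need exactly 2 groups")
    w <- welch_rows(m, which(labels == lv[1L]), which(labels == lv[2L]))
    q <- bh_fdr(w$p)
    keep <- which(q < fdr)
    data.frame(gene = rownames(m)[keep], dir = sign(w$delta[keep]),
               stringsAsFactors = FALSE)
  }
  da <- deg_set(exprA, labelsA)
  db <- deg_set(exprB, labelsB)
  m <- match(da$gene, db$gene)
  ov <- which(!is.na(m))
  shared <- length(ov)
  same <- if (shared == 0L) 0L else sum(da$dir[ov] == db$dir[m[ov]])
  bt <- binomial_consistency_test(shared, same)
  list(shared = shared, same_direction = same,
       p = bt$p, log_p = bt$log_p,
       n_deg_a = nrow(da), n_deg_b = nrow(db))
}
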