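# Sequential (coupled) application of two gene-pair signatures.
#
# Stage 1: a drug-free prognostic signature separates patients who would
# do well on surgery alone (zero reversals -> low risk).  Stage 2: among
# the remaining high-risk patients, a treatment-benefit signature
# separates those whose outcomes improve under endocrine therapy (zero
# reversals -> benefit).  The result is a three-group stratification.

#' Three-group stratification labels
#' @return the three label strings, in precedence order.
#' @export
three_group_labels <- function() {
  c("DRUG_FREE_LOW_RISK", "TAMOXIFEN_BENEFIT", "TAMOXIFEN_NON_BENEFIT")
}

#' Stratify samples with two coupled signatures
#'
#' Samples favorable under the drug-free prognostic signature (zero
#' reversed pairs) become `DRUG_FREE_LOW_RISK` regardless of the benefit
#' signature; the remaining high-risk samples become `TAMOXIFEN_BENEFIT`
#' when favorable under the benefit signature and
#' `TAMOXIFEN_NON_BENEFIT` otherwise.
#'
#' @param rev_drug_free `reversal_matrix` restricted to the drug-free
#'   signature's pairs.
#' @param rev_benefit `reversal_matrix` restricted to the benefit
#'   signature's pairs; must cover the same samples.
#' @return named character vector of [three_group_labels()] values.
#' @export
stratify <- function(rev_drug_free, rev_benefit) {
  s1 <- colnames(rev_drug_free$status)
  s2 <- colnames(rev_benefit$status)
  if (!setequal(s1, s2))
    stop("the two reversal matrices cover different sample sets")
  low <- colSums(rev_drug_free$status) == 0L
  ben <- colSums(rev_benefit$status[, s1, drop = FALSE]) == 0L
  lab <- three_group_labels()
  setNames(ifelse(low, lab[1L], ifelse(ben, lab[2L], lab[3L])), s1)
}

#' Two-stage coupled signature discovery
#'
#' Stage 1 discovers the drug-free prognostic signature on a cohort of
#' untreated (surgery-only) patients.  Stage 2 classifies the treated
#' cohort with that signature, keeps the unfavorable (high-risk)
#' samples, and discovers the treatment-benefit signature on that
#' subset.  Both stages run [discover_signature()] with the same stable
#' pairs and pathway collection.
#'
#' @param drug_free_cohort list with elements `expr` (genes x samples
#'   matrix) and `surv` (`survival_table`).
#' @param tamoxifen_cohort same structure, treated patients.
#' @param stable a `stable_pairs` object.
#' @param pathways named list of gene-id sets.
#' @param params see [discovery_params()].
#' @param min_stage2 minimum size of the stage-2 discovery subset
#'   (default 40); fewer high-risk samples is an error.
#' @return list with `drug_free` and `benefit` (`reo_signature`s) and
#'   `stage2_samples` (ids of the high-risk treated samples used).
#' @export
discover_coupled <- function(drug_free_cohort, tamoxifen_cohort,
                             stable, pathways,
                             params = discovery_params(),
                             min_stage2 = 40L) {
  sig1 <- discover_signature(drug_free_cohort$expr, drug_free_cohort$surv,
                             stable, pathways, params,
                             labels = c("low-risk", "high-risk"),
                             name = "drug_free_prognostic")
  rev_t <- reversal_status(tamoxifen_cohort$expr, sig1$pairs)
  cls <- classify_by_signature(rev_t, sig1)
  high <- names(cls)[cls == sig1$labels[["unfavorable"]]]
  if (length(high) == 0L)
    stop(errorCondition("empty discovery subset: stage-1 signature flags no high-risk treated samples",
                        class = c("reopair_no_signal", "reopair_error")))
  if (length(high) < min_stage2)
    stop("stage-2 discovery subset too small: ", length(high),
         " high-risk samples < minimum ", min_stage2)
  surv_t <- survival_table(tamoxifen_cohort$surv)
  sub_surv <- survival_table(
    as.data.frame(surv_t)[surv_t$sample_id %in% high, , drop = FALSE])
  sig2 <- discover_signature(
    tamoxifen_cohort$expr[, sub_surv$sample_id, drop = FALSE],
    sub_surv, stable, pathways, params,
    labels = c("benefit", "non-benefit"),
    name = "tamoxifen_benefit")
  list(drug_free = sig1, benefit = sig2, stage2_samples = high)
}

estimate_treatment_effect <- function(surv, treated) {
  # treated-vs-untreated contrast within one group; never throws
  res <- tryCatch({
    if (length(unique(treated)) < 2L) stop("single treatment arm")
    if (sum(surv$event[treated == 1]) == 0L ||
        sum(surv$event[treated == 0]) == 0L)
      stop("a treatment arm has zero events")
    fit <- cox_univariate(treated, surv)
    lr <- km_logrank(ifelse(treated == 1, "treated", "untreated"), surv)
    list(estimable = TRUE, hr = fit$hr, ci_low = fit$ci_low,
         ci_high = fit$ci_high, p_wald = fit$p_wald, logrank_p = lr$p,
         n_treated = sum(treated == 1), n_untreated = sum(treated == 0))
  }, error = function(e)
    list(estimable = FALSE, reason = conditionMessage(e)))
  res
}

#' Evaluate a three-group stratification against survival
#'
#' Reports group sizes, per-group Kaplan-Meier curves, pairwise log-rank
#' tests between groups, and within each group the treated-vs-untreated
#' hazard ratio with CI and log-rank p.  Contrasts that cannot be
#' estimated (single arm, zero events in an arm, single sample) are
#' flagged `estimable = FALSE` instead of failing.
#'
#' @param labels per-sample group labels (any label set works).
#' @param surv a `survival_table` aligned with `labels`.
#' @param treated 0/1 treatment indicator aligned with `labels`.
#' @return list `n` (group sizes), `curves`, `pairwise` (data frame
#'   `group1`, `group2`, `chi2`, `p`), `treatment` (per-group list).
#' @export
evaluate_groups <- function(labels, surv, treated) {
  surv <- survival_table(surv)
  labels <- as.character(labels)
  if (length(labels) != nrow(surv) || length(treated) != nrow(surv))
    stop("labels, treatment and survival table must be aligned")
  grp <- sort(unique(labels))
  curves <- lapply(grp, function(g) {
    idx <- labels == g
    fit <- survival::survfit(
      survival::Surv(surv$time_months[idx], surv$event[idx]) ~ 1)
    data.frame(time = fit$time, surv = fit$surv,
               n_risk = fit$n.risk, n_event = fit$n.event)
  })
  names(curves) <- grp
  pw <- NULL
  if (length(grp) >= 2L) {
    cmb <- combn(grp, 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      idx <- labels %in% cmb[, j]
      res <- tryCatch({
        lr <- km_logrank(labels[idx], survival_table(
          as.data.frame(surv)[idx, , drop = FALSE]))
        data.frame(group1 = cmb[1L, j], group2 = cmb[2L, j],
                   chi2 = lr$chi2, p = lr$p, stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(group1 = cmb[1L, j], group2 = cmb[2L, j],
                   chi2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
      res
    }))
  }
  treatment <- lapply(grp, function(g) {
    idx <- labels == g
    if (sum(idx) < 2L)
      return(list(estimable = FALSE, reason = "fewer than 2 samples"))
    estimate_treatment_effect(
      survival_table(as.data.frame(surv)[idx, , drop = FALSE]),
      treated[idx])
  })
  names(treatment) <- grp
  list(n = table(factor(labels, levels = grp)), curves = curves,
       pairwise = pw, treatment = treatment)
}

#' Load a published gene-pair signature fixture
#'
#' Returns the packaged drug-free prognostic signature (9 pairs) or the
#' tamoxifen-benefit predictive signature (10 pairs) with the printed
#' Entrez gene IDs and symbols.  The published tables do not state which
#' gene of each pair is the higher one in normal tissue, so the fixtures
#' carry `direction_known = FALSE` and refuse classification until
#' directions are bound from a user-supplied normal-tissue stable-pair
#' set via [bind_signature_direction()].
#'
#' @param name `"drug_free"` or `"benefit"`.
#' @return a `reo_signature` with `direction_known = FALSE`; gene
#'   symbols are kept in `provenance$symbols`.
#' @export
load_published_signature <- function(name = c("drug_free", "benefit")) {
  name <- match.arg(name)
  fn <- system.file("extdata",
                    paste0("published_", name, "_pairs.tsv"),
                    package = "reopair", mustWork = TRUE)
  tab <- data.table::fread(fn, sep = "\t", header = TRUE,
                           colClasses = "character")
  new_signature(
    data.frame(gene_a = tab$gene_a_id, gene_b = tab$gene_b_id,
               stringsAsFactors = FALSE),
    labels = if (name == "drug_free") c("low-risk", "high-risk")
             else c("benefit", "non-benefit"),
    name = paste0("published_", name),
    provenance = list(source = "published signature tables",
                      symbols = data.frame(
                        gene_a_symbol = tab$gene_a_symbol,
                        gene_b_symbol = tab$gene_b_symbol,
                        stringsAsFactors = FALSE)),
    direction_known = FALSE)
}

#' Bind normal-tissue directions to a signature
#'
#' Orients each (unordered) signature pair according to a stable-pair
#' set derived from normal tissue, making the signature executable.
#' Every signature pair must appear (in either orientation) in the
#' stable set.
#'
#' @param sig a `reo_signature` (typically a published fixture).
#' @param stable a `stable_pairs` object.
#' @return the signature with oriented pairs and
#'   `direction_known = TRUE`.
#' @export
bind_signature_direction <- function(sig, stable) {
  stopifnot(inherits(sig, "reo_signature"), inherits(stable, "stable_pairs"))
  key_sig <- pair_key(sig$pairs$gene_a, sig$pairs$gene_b)
  key_stb <- pair_key(stable$gene_a, stable$gene_b)
  m <- match(key_sig, key_stb)
  if (anyNA(m)) {
    miss <- sig$pairs[is.na(m), , drop = FALSE]
    stop("no normal-tissue direction available for pair(s): ",
         paste(pair_id(miss$gene_a, miss$gene_b), collapse = ", "))
  }
  sig$pairs <- data.frame(gene_a = stable$gene_a[m],
                          gene_b = stable$gene_b[m],
                          stringsAsFactors = FALSE)
  sig$direction_known <- TRUE
  sig
}
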