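# Gene-pair signature discovery.
#
# Candidate pairs are intra-core-pathway stable pairs whose reversal is
# associated with poor survival (Cox HR > 1 under BH-FDR); the final
# signature is a minimal subset chosen by forward-stepwise maximisation
# of Harrell's C-index for the zero-reversal rule: a sample is
# "favorable" iff none of the signature's pairs is reversed in it.

new_signature <- function(pairs, labels = c("low-risk", "high-risk"),
                          name = "signature", provenance = list(),
                          direction_known = TRUE) {
  pairs <- as.data.frame(pairs)[, c("gene_a", "gene_b")]
  if (nrow(pairs) == 0L) stop("signature needs at least one pair")
  if (anyDuplicated(pair_id(pairs$gene_a, pairs$gene_b)))
    stop("duplicate pairs in signature")
  structure(list(name = name, pairs = pairs,
                 labels = c(favorable = labels[[1L]],
                            unfavorable = labels[[2L]]),
                 provenance = provenance,
                 direction_known = isTRUE(direction_known)),
            class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("REO signature '%s': %d gene pairs; rule: zero reversals -> '%s', else '%s'\n",
              x$name, nrow(x$pairs), x$labels[["favorable"]],
              x$labels[["unfavorable"]]))
  print.data.frame(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Screen candidate prognostic gene pairs
#'
#' Each pair's binary reversal status across the cohort is regressed on
#' survival with a univariate Cox model.  BH adjustment is computed over
#' all tested pairs, after which candidates with `q < fdr` AND hazard
#' ratio > 1 (reversal associated with poor survival) are retained.
#' Pairs whose status is constant across the cohort, or whose fit fails
#' to converge, are skipped (not part of the testing family).
#'
#' @param core_pairs data frame of directed pairs (`gene_a`, `gene_b`),
#'   typically the deduplicated union over the core pathways.
#' @param tumor numeric matrix, genes x samples.
#' @param surv a `survival_table` aligned to the tumour samples
#'   (order-insensitive on `sample_id`).
#' @param fdr BH-FDR threshold (default 0.10).
#' @return data frame of candidates with `gene_a`, `gene_b`, `coef`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `q`, sorted by `q`; attribute
#'   `n_tested` records the testing-family size.
#' @export
screen_candidate_pairs <- function(core_pairs, tumor, surv, fdr = 0.10) {
  core_pairs <- unique(as.data.frame(core_pairs)[, c("gene_a", "gene_b")])
  if (nrow(core_pairs) == 0L) stop("empty candidate pair list")
  surv <- survival_table(surv)
  if (!setequal(colnames(tumor), surv$sample_id))
    stop("sample ids of tumour matrix and survival table differ")
  rev <- reversal_status(tumor, core_pairs)
  status <- rev$status[, surv$sample_id, drop = FALSE]
  fits <- vector("list", nrow(core_pairs))
  for (i in seq_len(nrow(core_pairs))) {
    x <- status[i, ]
    if (length(unique(x)) < 2L) next     # never / always reversed: skip
    fit <- cox_univariate(x, surv)
    if (fit$converged) fits[[i]] <- fit
  }
  tested <- which(!vapply(fits, is.null, TRUE))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      coef = numeric(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  if (length(tested) == 0L) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  p <- vapply(fits[tested], `[[`, 0, "p_lrt")
  q <- bh_fdr(p)
  out <- data.frame(
    gene_a = core_pairs$gene_a[tested], gene_b = core_pairs$gene_b[tested],
    coef = vapply(fits[tested], `[[`, 0, "coef"),
    hr = vapply(fits[tested], `[[`, 0, "hr"),
    ci_low = vapply(fits[tested], `[[`, 0, "ci_low"),
    ci_high = vapply(fits[tested], `[[`, 0, "ci_high"),
    p = p, q = q, stringsAsFactors = FALSE)
  out <- out[out$q < fdr & out$hr > 1, , drop = FALSE]
  out <- out[order(out$q, out$p, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(tested)
  out
}

#' Classify samples with a gene-pair signature (zero-reversal rule)
#'
#' A sample is assigned the favorable label iff every signature pair has
#' reversal status 0 in it; any reversed pair makes it unfavorable.
#'
#' @param rev a `reversal_matrix` containing (at least) the signature
#'   pairs.
#' @param signature a `reo_signature`, or a data frame of pairs.
#' @return named character vector of per-sample labels.
#' @export
classify_by_signature <- function(rev, signature) {
  labels <- c(favorable = "favorable", unfavorable = "unfavorable")
  if (inherits(signature, "reo_signature")) {
    if (!isTRUE(signature$direction_known))
      stop("signature '", signature$name, "' has unbound pair directions; ",
           "bind them from a normal-tissue stable-pair set with ",
           "bind_signature_direction()")
    labels <- signature$labels
    pairs <- signature$pairs
  } else pairs <- as.data.frame(signature)[, c("gene_a", "gene_b")]
  ids <- pair_id(pairs$gene_a, pairs$gene_b)
  miss <- setdiff(ids, rownames(rev$status))
  if (length(miss) > 0L)
    stop("signature pairs absent from reversal matrix: ",
         paste(miss, collapse = ", "))
  any_rev <- colSums(rev$status[ids, , drop = FALSE]) > 0L
  setNames(ifelse(any_rev, labels[["unfavorable"]], labels[["favorable"]]),
           colnames(rev$status))
}

usable_pair_matrix <- function(surv) {
  # U[i, j] = TRUE when i fails before j and i's event is observed
  outer(surv$time_months, surv$time_months, "<") & (surv$event == 1)
}

concordance_binary <- function(unfav, U, n_usable) {
  # C-index of a 0/1 risk vector given the precomputed usable matrix
  s <- as.numeric(unfav)
  conc <- as.numeric(t(s) %*% U %*% (1 - s))
  tied <- as.numeric(t(s) %*% U %*% s + t(1 - s) %*% U %*% (1 - s))
  (conc + 0.5 * tied) / n_usable
}

#' Forward-stepwise signature selection by C-index
#'
#' Starts from the single candidate pair with the largest C-index of its
#' zero-reversal classification (favorable = 0, unfavorable = 1) against
#' survival, then repeatedly adds the candidate whose inclusion most
#' increases the C-index, stopping when the best improvement does not
#' exceed `eps`.  Ties are broken by larger univariate hazard ratio,
#' then lexicographically on (gene_a, gene_b).
#'
#' @param candidates candidate data frame from
#'   [screen_candidate_pairs()] (needs `gene_a`, `gene_b`, `hr`).
#' @param rev a `reversal_matrix` covering the candidate pairs.
#' @param surv a `survival_table` aligned to the reversal matrix samples.
#' @param eps minimal C-index improvement counted as progress
#'   (default 1e-10).
#' @param labels favorable/unfavorable label pair for the result.
#' @param name signature name.
#' @return a `reo_signature` whose `provenance` holds `c_index` and the
#'   step `trace` (data frame `step`, `gene_a`, `gene_b`, `c`).
#' @export
forward_stepwise_select <- function(candidates, rev, surv, eps = 1e-10,
                                    labels = c("low-risk", "high-risk"),
                                    name = "signature") {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0L) stop("no candidate pairs")
  surv <- survival_table(surv)
  if (!setequal(colnames(rev$status), surv$sample_id))
    stop("sample ids of reversal matrix and survival table differ")
  ids <- pair_id(candidates$gene_a, candidates$gene_b)
  miss <- setdiff(ids, rownames(rev$status))
  if (length(miss) > 0L)
    stop("candidate pairs absent from reversal matrix: ",
         paste(miss, collapse = ", "))
  status <- rev$status[ids, surv$sample_id, drop = FALSE]
  U <- usable_pair_matrix(surv)
  n_usable <- sum(U)
  if (n_usable == 0L) stop("no usable survival pairs")
  hr <- if ("hr" %in% names(candidates)) candidates$hr else
    rep(0, nrow(candidates))
  # deterministic preference order for exact C ties
  pref <- order(-hr, candidates$gene_a, candidates$gene_b)
  rank_pref <- integer(nrow(candidates)); rank_pref[pref] <- seq_along(pref)

  selected <- integer(0)
  cum_rev <- rep(0L, ncol(status))       # count of reversed selected pairs
  best_c <- -Inf
  trace <- list()
  remaining <- seq_len(nrow(candidates))
  repeat {
    cs <- vapply(remaining, function(i)
      concordance_binary((cum_rev + status[i, ]) > 0L, U, n_usable),
      0)
    top <- max(cs)
    if (top <= best_c + eps && length(selected) > 0L) break
    cand_best <- remaining[cs >= top - 1e-15]
    pick <- cand_best[which.min(rank_pref[cand_best])]
    selected <- c(selected, pick)
    cum_rev <- cum_rev + status[pick, ]
    best_c <- concordance_binary(cum_rev > 0L, U, n_usable)
    trace[[length(trace) + 1L]] <-
      data.frame(step = length(selected),
                 gene_a = candidates$gene_a[pick],
                 gene_b = candidates$gene_b[pick],
                 c = best_c, stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0L) break
  }
  new_signature(candidates[selected, c("gene_a", "gene_b")],
                labels = labels, name = name,
                provenance = list(c_index = best_c,
                                  trace = do.call(rbind, trace),
                                  n_candidates = nrow(candidates)))
}

no_signal <- function(stage, msg) {
  stop(errorCondition(sprintf("no signal at stage '%s': %s", stage, msg),
                      stage = stage,
                      class = c("reopair_no_signal", "reopair_error")))
}

#' Default discovery parameters
#' @return list of the tunable thresholds of [discover_signature()].
#' @export
discovery_params <- function() {
  list(fdr_pathway = 0.05, fdr_spearman = 0.05, rho_min = 0.6,
       fdr_pair = 0.10, min_pathway_pairs = 5L)
}

#' Discover a gene-pair signature from a cohort
#'
#' The full discovery chain: intra-pathway stable pairs -> per-sample
#' disruption indexes -> Cox screen of survival-relevant pathways
#' (BH-FDR < `fdr_pathway`) -> core pathway set as the largest connected
#' component of the Spearman network (rho > `rho_min`, BH-FDR <
#' `fdr_spearman`) -> Cox screen of intra-core-pathway pair reversals
#' (BH-FDR < `fdr_pair`, HR > 1) -> forward-stepwise C-index selection.
#' Deterministic given its inputs.  Stages that find nothing raise a
#' condition of class `reopair_no_signal` naming the stage.
#'
#' @param tumor numeric matrix, genes x samples.
#' @param surv a `survival_table` for the same samples.
#' @param stable a `stable_pairs` object (normal-tissue reference).
#' @param pathways named list of gene-id sets.
#' @param params list as from [discovery_params()].
#' @param labels,name passed to the resulting signature.
#' @return a `reo_signature`; `provenance` records the thresholds, the
#'   selected pathways, the core set, candidate counts, the achieved
#'   C-index and the step trace.
#' @export
discover_signature <- function(tumor, surv, stable, pathways,
                               params = discovery_params(),
                               labels = c("low-risk", "high-risk"),
                               name = "signature") {
  params <- utils::modifyList(discovery_params(), params)
  dis <- disruption_matrix(tumor, stable, pathways,
                           min_pairs = params$min_pathway_pairs)
  screen <- screen_rfs_pathways(dis, surv, fdr = params$fdr_pathway)
  sel <- screen$pathway[screen$selected]
  if (length(sel) < 2L)
    no_signal("pathway_screen",
              sprintf("%d survival-relevant pathway(s); need >= 2",
                      length(sel)))
  net <- core_pathway_network(dis[sel, , drop = FALSE],
                              rho_min = params$rho_min,
                              fdr = params$fdr_spearman)
  if (length(net$core) == 0L)
    no_signal("core_network", "no connected pathways in Spearman network")
  pp <- pathway_stable_pairs(pathways[net$core], stable)
  core_pairs <- unique(do.call(rbind, pp)[, c("gene_a", "gene_b")])
  cands <- screen_candidate_pairs(core_pairs, tumor, surv,
                                  fdr = params$fdr_pair)
  if (nrow(cands) == 0L)
    no_signal("candidate_screen", "no pair passed the reversal Cox screen")
  rev <- reversal_status(tumor, cands)
  sig <- forward_stepwise_select(cands, rev, surv, labels = labels,
                                 name = name)
  sig$provenance <- c(sig$provenance,
                      list(params = params,
                           pathways_selected = sel,
                           core_pathways = net$core,
                           n_core_pairs = nrow(core_pairs),
                           n_candidates_screened = attr(cands, "n_tested")))
  sig
}

#' Read / write a signature as JSON
#'
#' JSON fields: `name`, `labels` (favorable, unfavorable), `pairs`
#' (array of `{gene_a, gene_b, direction: "a>b"}`), `provenance`.
#'
#' @param path file path.
#' @return for the reader, a `reo_signature`.
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- if (is.null(x$provenance)) list() else as.list(x$provenance)
  new_signature(x$pairs[, c("gene_a", "gene_b")],
                labels = c(x$labels$favorable, x$labels$unfavorable),
                name = x$name, provenance = prov)
}

#' @rdname read_signature
#' @param sig a `reo_signature`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "reo_signature"))
  prov <- sig$provenance
  prov$trace <- NULL                     # step trace is session metadata
  out <- list(name = sig$name,
              labels = list(favorable = sig$labels[["favorable"]],
                            unfavorable = sig$labels[["unfavorable"]]),
              pairs = data.frame(gene_a = sig$pairs$gene_a,
                                 gene_b = sig$pairs$gene_b,
                                 direction = "a>b"),
              provenance = prov)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
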