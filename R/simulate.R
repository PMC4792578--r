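# Synthetic-cohort generator.
#
# Emulates the statistical structure the pipeline assumes: normal
# tissue with a shared consensus gene ordering plus Gaussian noise (so
# >99%-stable pairs exist by construction); tumours in which designated
# "planted" pairs swap their two genes' values with a per-sample
# probability (a clean ordering flip that leaves marginal distributions
# unchanged); exponential recurrence times whose hazard is multiplied
# by a planted hazard ratio per reversed prognostic pair; an optional
# benefit pair whose non-reversal defines the subgroup in which
# treatment multiplies the hazard by a planted HR < 1; and a pathway
# collection in which two designated "signal" pathways co-annotate all
# planted genes.  Every artifact draws from its own RNG stream (a fixed
# offset from the master seed), so adding one artifact never perturbs
# another.

#' Simulation configuration
#'
#' Defaults describe the standing test world: 500 genes, 150 normal and
#' 300 tumour samples, log2 noise SD 0.5, three planted prognostic
#' pairs each reversed with probability 0.35 and multiplying the hazard
#' by 4 per reversal, one benefit pair (reversal probability 0.5,
#' treatment HR 0.4 in the non-reversed stratum), exponential baseline
#' hazard 0.005 per month, 30% censoring, half the cohort treated.
#'
#' @param n_genes,n_normal,n_tumor cohort dimensions.
#' @param noise_sd per-measurement Gaussian noise SD (log2 units).
#' @param n_pathways,pathway_size_min,pathway_size_max pathway collection
#'   shape.
#' @param n_prognostic_pairs,prognostic_reversal_prob,prognostic_hr
#'   planted prognostic structure (HR is per reversed pair).
#' @param benefit_pair logical: plant a treatment-benefit pair?
#' @param benefit_reversal_prob,benefit_treatment_hr benefit-pair
#'   reversal probability and the treatment hazard ratio applying only
#'   to treated samples whose benefit pair is NOT reversed.
#' @param baseline_hazard exponential hazard rate per month.
#' @param censor_rate target fraction censored (uniform censoring).
#' @param treated_fraction probability a tumour sample is treated.
#' @param seed master integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, n_normal = 150L, n_tumor = 300L,
                       noise_sd = 0.5, n_pathways = 50L,
                       pathway_size_min = 10L, pathway_size_max = 40L,
                       n_prognostic_pairs = 3L,
                       prognostic_reversal_prob = 0.35,
                       prognostic_hr = 4,
                       benefit_pair = TRUE,
                       benefit_reversal_prob = 0.5,
                       benefit_treatment_hr = 0.4,
                       baseline_hazard = 0.005,
                       censor_rate = 0.3,
                       treated_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
              n_tumor = as.integer(n_tumor), noise_sd = noise_sd,
              n_pathways = as.integer(n_pathways),
              pathway_size_min = as.integer(pathway_size_min),
              pathway_size_max = as.integer(pathway_size_max),
              n_prognostic_pairs = as.integer(n_prognostic_pairs),
              prognostic_reversal_prob = prognostic_reversal_prob,
              prognostic_hr = prognostic_hr,
              benefit_pair = isTRUE(benefit_pair),
              benefit_reversal_prob = benefit_reversal_prob,
              benefit_treatment_hr = benefit_treatment_hr,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate,
              treated_fraction = treated_fraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_normal > 1, n_tumor > 1, noise_sd > 0,
              n_pathways > 0, pathway_size_min >= 3,
              pathway_size_max >= pathway_size_min,
              pathway_size_max <= n_genes,
              n_prognostic_pairs >= 0,
              prognostic_reversal_prob >= 0, prognostic_reversal_prob <= 1,
              prognostic_hr > 0,
              benefit_reversal_prob >= 0, benefit_reversal_prob <= 1,
              benefit_treatment_hr > 0, baseline_hazard > 0,
              censor_rate >= 0, censor_rate < 1,
              treated_fraction >= 0, treated_fraction <= 1)
  })
  n_planted_genes <- 2L * (cfg$n_prognostic_pairs + cfg$benefit_pair)
  if (n_planted_genes >= cfg$n_genes)
    stop("planted genes exceed n_genes")
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Field names mirror [sim_config()] arguments exactly; absent fields
#' keep their defaults.
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0L)
    stop("unknown simulation config field(s): ",
         paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Consensus expression state and planted structure
#'
#' Deterministic given the seed.  Ordinary genes draw a consensus mean
#' from Uniform(4, 11); each planted pair occupies a reserved expression
#' band above that range with an intra-pair gap of 6 noise SDs, so the
#' pair is >99%-stable in normal tissue and a value swap flips exactly
#' that one stable comparison.
#'
#' @param config a `sim_config`.
#' @return list: `mu` (named consensus vector), `prognostic_pairs`
#'   (data frame `gene_a`, `gene_b`, `hr`), `benefit_pair` (one-row data
#'   frame or NULL).
#' @export
sim_consensus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sprintf("g%04d", seq_len(config$n_genes))
  n_pairs <- config$n_prognostic_pairs + as.integer(config$benefit_pair)
  planted_idx <- if (n_pairs > 0)
    sample(config$n_genes, 2L * n_pairs) else integer(0)
  mu <- runif(config$n_genes, 4, 11)
  gap <- 3 * config$noise_sd             # half-gap: pair gap = 6 SDs
  band <- 11 + 4 * config$noise_sd       # clearance above ordinary genes
  pg <- list(); bp <- NULL
  for (j in seq_len(n_pairs)) {
    ia <- planted_idx[2L * j - 1L]; ib <- planted_idx[2L * j]
    centre <- band + gap + (j - 1L) * 4 * gap
    mu[ia] <- centre + gap
    mu[ib] <- centre - gap
    row <- data.frame(gene_a = ids[ia], gene_b = ids[ib],
                      stringsAsFactors = FALSE)
    if (j <= config$n_prognostic_pairs) {
      row$hr <- config$prognostic_hr
      pg[[j]] <- row
    } else bp <- row
  }
  names(mu) <- ids
  list(mu = mu,
       prognostic_pairs = if (length(pg) > 0) do.call(rbind, pg) else
         data.frame(gene_a = character(), gene_b = character(),
                    hr = numeric(), stringsAsFactors = FALSE),
       benefit_pair = bp)
}

#' Simulate a normal-tissue expression matrix
#'
#' Every value is the gene's consensus mean plus independent
#' Normal(0, noise_sd) noise; sample ids `N0001`, ...
#'
#' @param config a `sim_config`.
#' @param consensus optional precomputed [sim_consensus()] result.
#' @return numeric matrix, genes x `n_normal` samples.
#' @export
simulate_normal <- function(config, consensus = sim_consensus(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- matrix(consensus$mu, nrow = config$n_genes, ncol = config$n_normal) +
    rnorm(config$n_genes * config$n_normal, sd = config$noise_sd)
  dimnames(m) <- list(names(consensus$mu),
                      sprintf("N%04d", seq_len(config$n_normal)))
  m
}

calibrate_censor_horizon <- function(lambda, censor_rate) {
  # uniform censoring on [0, M]: choose M so the expected censored
  # fraction, averaged over per-sample hazards, hits the target
  if (censor_rate <= 0) return(Inf)
  frac <- function(M) mean((1 - exp(-lambda * M)) / (lambda * M)) -
    censor_rate
  uniroot(frac, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Simulate a tumour cohort with survival and ground truth
#'
#' Tumour expression is the consensus plus noise, except that each
#' planted pair's two gene values are swapped with its configured
#' per-sample probability.  Recurrence time is exponential with hazard
#' `baseline * prognostic_hr^(reversed prognostic pairs)`, multiplied by
#' `benefit_treatment_hr` for treated samples whose benefit pair is not
#' reversed (the "benefit stratum").  Censoring is uniform on a horizon
#' calibrated to the target censor rate.
#'
#' @param config a `sim_config`.
#' @param consensus optional precomputed [sim_consensus()] result.
#' @param treated_fraction override of `config$treated_fraction` (e.g. 1
#'   for an all-treated endocrine-therapy cohort).
#' @param stream non-negative integer choosing an independent cohort
#'   draw from the same consensus (distinct RNG stream per stream id);
#'   lets one simulation provide e.g. a surgery-only and a treated
#'   cohort that share the normal-tissue reference.
#' @return list with `expr` (matrix), `surv` (`survival_table` with a
#'   `treated` column) and `ground_truth`: planted pairs with true HRs,
#'   true per-sample swap states (pairs x samples matrix), benefit
#'   stratum membership, treated flags and the censor horizon.
#' @export
simulate_tumor <- function(config, consensus = sim_consensus(config),
                           treated_fraction = config$treated_fraction,
                           stream = 0L) {
  stopifnot(inherits(config, "sim_config"), stream >= 0)
  n <- config$n_tumor
  ids <- sprintf("T%04d_%d", seq_len(n), stream)

  set.seed(config$seed + 2L + 100L * stream)   # expression stream
  m <- matrix(consensus$mu, nrow = config$n_genes, ncol = n) +
    rnorm(config$n_genes * n, sd = config$noise_sd)
  dimnames(m) <- list(names(consensus$mu), ids)
  planted <- consensus$prognostic_pairs[, c("gene_a", "gene_b")]
  probs <- rep(config$prognostic_reversal_prob, nrow(planted))
  if (!is.null(consensus$benefit_pair)) {
    planted <- rbind(planted,
                     consensus$benefit_pair[, c("gene_a", "gene_b")])
    probs <- c(probs, config$benefit_reversal_prob)
  }
  swapped <- matrix(0L, nrow(planted), n,
                    dimnames = list(pair_id(planted$gene_a, planted$gene_b),
                                    ids))
  for (i in seq_len(nrow(planted))) {
    sw <- runif(n) < probs[i]
    swapped[i, ] <- as.integer(sw)
    if (any(sw)) {
      a <- planted$gene_a[i]; b <- planted$gene_b[i]
      tmp <- m[a, sw]
      m[a, sw] <- m[b, sw]
      m[b, sw] <- tmp
    }
  }

  set.seed(config$seed + 3L + 100L * stream)   # survival stream
  k_prog <- config$n_prognostic_pairs
  n_rev <- if (k_prog > 0)
    colSums(swapped[seq_len(k_prog), , drop = FALSE]) else rep(0L, n)
  treated <- as.integer(runif(n) < treated_fraction)
  benefit_member <- if (!is.null(consensus$benefit_pair))
    swapped[nrow(swapped), ] == 0L else rep(FALSE, n)
  lambda <- config$baseline_hazard * config$prognostic_hr^n_rev
  lambda <- lambda * ifelse(treated == 1L & benefit_member,
                            config$benefit_treatment_hr, 1)
  t_event <- rexp(n, rate = lambda)
  horizon <- calibrate_censor_horizon(lambda, config$censor_rate)
  c_time <- if (is.finite(horizon)) runif(n, 0, horizon) else rep(Inf, n)
  surv <- survival_table(data.frame(
    sample_id = ids,
    time_months = pmin(t_event, c_time),
    event = as.integer(t_event <= c_time),
    treated = treated,
    stringsAsFactors = FALSE))
  gt <- list(prognostic_pairs = consensus$prognostic_pairs,
             benefit_pair = consensus$benefit_pair,
             swapped = swapped,
             n_reversed_prognostic = n_rev,
             benefit_stratum = setNames(benefit_member, ids),
             treated = setNames(treated, ids),
             censor_horizon = horizon)
  list(expr = m, surv = surv, ground_truth = gt)
}

#' Simulate a pathway collection co-annotating the planted pairs
#'
#' Random gene sets of the configured size range, plus two designated
#' "signal" pathways that both contain all planted genes (prognostic and
#' benefit) with a handful of disjoint filler genes.  Two overlapping
#' signal pathways are generated so that their disruption indexes are
#' strongly rank-correlated and the core-network stage has an edge to
#' find; overlap statistics are reported in the attribute `overlap`.
#'
#' @param config a `sim_config`.
#' @param consensus optional precomputed [sim_consensus()] result.
#' @return named list of gene-id sets; signal pathways are named
#'   `pathway_signal_1` / `pathway_signal_2`.
#' @export
simulate_pathways <- function(config, consensus = sim_consensus(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  ids <- names(consensus$mu)
  planted_genes <- unique(c(consensus$prognostic_pairs$gene_a,
                            consensus$prognostic_pairs$gene_b,
                            consensus$benefit_pair$gene_a,
                            consensus$benefit_pair$gene_b))
  others <- setdiff(ids, planted_genes)
  sets <- list()
  if (length(planted_genes) > 0) {
    fill <- sample(others, 8L)
    sets[["pathway_signal_1"]] <- c(planted_genes, fill[1:4])
    sets[["pathway_signal_2"]] <- c(planted_genes, fill[5:8])
  }
  n_rand <- config$n_pathways - length(sets)
  sizes <- sample(config$pathway_size_min:config$pathway_size_max,
                  n_rand, replace = TRUE)
  for (i in seq_len(n_rand))
    sets[[sprintf("pathway_%03d", i)]] <- sample(ids, sizes[i])
  genes_all <- unlist(sets, use.names = FALSE)
  attr(sets, "overlap") <- list(
    n_pathways = length(sets),
    n_unique_genes = length(unique(genes_all)),
    mean_annotations_per_gene = length(genes_all) /
      length(unique(genes_all)))
  sets
}

#' Simulate a complete cohort bundle
#'
#' Convenience wrapper producing everything a pipeline run needs:
#' normal and tumour matrices, clinical table, pathway collection and
#' the ground-truth manifest.
#'
#' @param config a `sim_config`.
#' @param treated_fraction optional override for the tumour cohort.
#' @return list `config`, `normal`, `tumor` (list `expr`, `surv`),
#'   `pathways`, `ground_truth`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            treated_fraction = config$treated_fraction) {
  consensus <- sim_consensus(config)
  tum <- simulate_tumor(config, consensus,
                        treated_fraction = treated_fraction)
  list(config = config,
       normal = simulate_normal(config, consensus),
       tumor = list(expr = tum$expr, surv = tum$surv),
       pathways = simulate_pathways(config, consensus),
       ground_truth = tum$ground_truth)
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits `normal.tsv`, `tumor.tsv`, `clinical.tsv`, `pathways.gmt` and
#' `ground_truth.json`.
#'
#' @param config a `sim_config`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  write_expression(sim$normal, file.path(outdir, "normal.tsv"))
  write_expression(sim$tumor$expr, file.path(outdir, "tumor.tsv"))
  data.table::fwrite(as.data.frame(sim$tumor$surv),
                     file.path(outdir, "clinical.tsv"), sep = "\t")
  write_gmt(sim$pathways, file.path(outdir, "pathways.gmt"))
  gt <- sim$ground_truth
  gt$swapped <- as.data.frame(t(gt$swapped))
  jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
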