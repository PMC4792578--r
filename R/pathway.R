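# Per-sample pathway disruption analysis.
#
# A pathway's "disruption index" in a tumour sample is the fraction of
# that pathway's stable intra-pathway gene pairs whose normal-tissue
# ordering the sample reverses.  Pathways whose index correlates with
# recurrence-free survival are screened by univariate Cox under BH-FDR,
# and a core set is extracted as the largest connected component of the
# Spearman correlation network among the survival-relevant pathways.

#' Read gene sets from a GMT file
#'
#' Standard tab-separated lines `name<TAB>description<TAB>gene...`;
#' duplicate genes within a set are removed, empty sets rejected.
#'
#' @param path file path.
#' @return named list of character vectors (gene ids), with the
#'   description lines kept in attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description strings (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Stable pairs falling entirely inside each pathway
#'
#' @param pathways named list of gene-id sets (see [read_gmt()]).
#' @param stable a `stable_pairs` object.
#' @return named list: pathway -> data frame of its intra-pathway stable
#'   pairs (possibly zero rows).
#' @export
pathway_stable_pairs <- function(pathways, stable) {
  stopifnot(inherits(stable, "stable_pairs"))
  lapply(pathways, function(genes) {
    keep <- stable$gene_a %in% genes & stable$gene_b %in% genes
    as.data.frame(stable)[keep, , drop = FALSE]
  })
}

#' Disruption index of one pathway across tumour samples
#'
#' Fraction of the pathway's stable pairs reversed in each sample.
#'
#' @param tumor numeric matrix, genes x samples.
#' @param pathway_pairs data frame of directed pairs (`gene_a`, `gene_b`;
#'   a > b in normal tissue).
#' @return named numeric vector (one fraction in `[0, 1]` per sample).
#' @export
disruption_index <- function(tumor, pathway_pairs) {
  if (NROW(pathway_pairs) == 0L)
    stop("disruption index undefined: pathway has no stable pairs")
  rev <- reversal_status(tumor, pathway_pairs)
  colMeans(rev$status)
}

#' Disruption-index matrix over a pathway collection
#'
#' Builds the pathways x samples disruption matrix.  Pathways with fewer
#' than `min_pairs` intra-pathway stable pairs are omitted (a fraction of
#' very few pairs is unstable), as are pathways with none.
#'
#' @param tumor numeric matrix, genes x samples.
#' @param stable a `stable_pairs` object.
#' @param pathways named list of gene-id sets.
#' @param min_pairs minimum intra-pathway stable-pair count (default 5).
#' @return numeric matrix (pathways x samples) with attribute `n_pairs`,
#'   the per-pathway stable-pair count used.
#' @export
disruption_matrix <- function(tumor, stable, pathways, min_pairs = 5L) {
  pp <- pathway_stable_pairs(pathways, stable)
  pp <- pp[vapply(pp, nrow, 0L) >= min_pairs]
  if (length(pp) == 0L)
    stop("no pathway has >= ", min_pairs, " intra-pathway stable pairs")
  all_pairs <- unique(do.call(rbind, pp)[, c("gene_a", "gene_b")])
  rev <- reversal_status(tumor, all_pairs)
  ids <- pair_id(all_pairs$gene_a, all_pairs$gene_b)
  dis <- t(vapply(pp, function(d) {
    colMeans(rev$status[match(pair_id(d$gene_a, d$gene_b), ids), ,
                        drop = FALSE])
  }, numeric(ncol(tumor))))
  dimnames(dis) <- list(names(pp), colnames(tumor))
  attr(dis, "n_pairs") <- vapply(pp, nrow, 0L)
  dis
}

#' Screen pathways whose disruption index correlates with survival
#'
#' Univariate Cox regression of survival on each pathway's continuous
#' disruption index (per-unit-fraction hazard ratio); pathways are kept
#' when their BH-adjusted p-value is below `fdr`.  Pathways with a
#' constant index, or whose fit does not converge, are skipped with a
#' warning rather than failing the screen.
#'
#' @param dis disruption matrix (pathways x samples).
#' @param surv a `survival_table`; `sample_id` must match the matrix
#'   columns (order-insensitive).
#' @param fdr BH-FDR threshold (default 0.05).
#' @return data frame (one row per tested pathway) with `pathway`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `q`, `selected`, sorted by `q`.
#' @export
screen_rfs_pathways <- function(dis, surv, fdr = 0.05) {
  surv <- survival_table(surv)
  if (!setequal(colnames(dis), surv$sample_id))
    stop("sample ids of disruption matrix and survival table differ")
  dis <- dis[, surv$sample_id, drop = FALSE]
  fits <- vector("list", nrow(dis))
  for (i in seq_len(nrow(dis))) {
    x <- dis[i, ]
    if (length(unique(x)) < 2L) {
      warning("constant disruption index, skipping pathway: ",
              rownames(dis)[i])
      next
    }
    fit <- cox_univariate(x, surv)
    if (fit$converged) fits[[i]] <- fit
  }
  tested <- which(!vapply(fits, is.null, TRUE))
  if (length(tested) == 0L)
    return(data.frame(pathway = character(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p = numeric(), q = numeric(), selected = logical()))
  p <- vapply(fits[tested], `[[`, 0, "p_lrt")
  q <- bh_fdr(p)
  out <- data.frame(
    pathway = rownames(dis)[tested],
    hr = vapply(fits[tested], `[[`, 0, "hr"),
    ci_low = vapply(fits[tested], `[[`, 0, "ci_low"),
    ci_high = vapply(fits[tested], `[[`, 0, "ci_high"),
    p = p, q = q, selected = q < fdr,
    stringsAsFactors = FALSE)
  out[order(out$q, out$p), , drop = FALSE]
}

connected_components <- function(nodes, from, to) {
  # union-find over character node ids
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    ri <- find(match(from[e], nodes)); rj <- find(match(to[e], nodes))
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  split(nodes, roots)
}

#' Core pathway set from the Spearman correlation network
#'
#' Nodes are the supplied (survival-relevant) pathways; an edge joins
#' two pathways when the Spearman correlation of their disruption
#' indexes is significant after BH adjustment across all pathway pairs
#' (q < `fdr`) AND rho strictly exceeds `rho_min`.  The core is the
#' largest connected component of that graph (ties between equal-sized
#' components broken by the lexicographically smallest member); with no
#' edges the core is empty.
#'
#' @param dis disruption matrix restricted to the candidate pathways.
#' @param rho_min correlation threshold, strict (default 0.6).
#' @param fdr BH-FDR threshold over all pathway pairs (default 0.05).
#' @return list with `core` (character vector of pathway names) and
#'   `edges` (data frame `from`, `to`, `rho`, `q`).
#' @export
core_pathway_network <- function(dis, rho_min = 0.6, fdr = 0.05) {
  if (nrow(dis) < 2L) stop("need at least 2 pathways")
  cmb <- combn(rownames(dis), 2L)
  rho <- numeric(ncol(cmb)); p <- numeric(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    x <- dis[cmb[1L, j], ]; y <- dis[cmb[2L, j], ]
    if (var(x) == 0 || var(y) == 0) { rho[j] <- NA; p[j] <- 1; next }
    st <- spearman_test(x, y)
    rho[j] <- st$rho; p[j] <- st$p
  }
  q <- bh_fdr(p)
  keep <- !is.na(rho) & q < fdr & rho > rho_min
  edges <- data.frame(from = cmb[1L, keep], to = cmb[2L, keep],
                      rho = rho[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    return(list(core = character(), edges = edges))
  nodes <- sort(unique(c(edges$from, edges$to)))
  comps <- connected_components(nodes, edges$from, edges$to)
  sizes <- lengths(comps)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    first_member <- vapply(comps[best], function(x) min(sort(x)), "")
    best <- best[order(first_member)][1L]
  }
  list(core = sort(comps[[best]]), edges = edges)
}

#' Write a disruption matrix as TSV (pathways x samples)
#' @param dis disruption matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disruption <- function(dis, path) {
  dt <- data.table::data.table(pathway = rownames(dis), dis)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a disruption matrix written by [write_disruption()]
#' @param path file path.
#' @return numeric matrix, pathways x samples.
#' @export
read_disruption <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  m
}
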