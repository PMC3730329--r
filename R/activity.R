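#' Default cut-off ladder for the differential-activity analysis
#'
#' Ten trials of increasingly stringent per-gene inclusion cut-offs:
#' trial 1 includes all genes; trial 2 adds the per-gene t-test cut-off
#' (p <= 0.001); trials 3-10 additionally require a minimum percent
#' difference in class medians of 10\%, 20\%, ..., 80\%.
#'
#' @return data.frame with columns \code{trial}, \code{min_diff_pct},
#'   \code{p_max} (\code{NA} = no p cut-off).
#' @export
default_trial_ladder <- function() {
  data.frame(trial = 1:10,
             min_diff_pct = c(0, 0, seq(10, 80, by = 10)),
             p_max = c(NA, rep(0.001, 9)))
}

# percent difference of class medians on the ratio scale; inputs are class
# median log2 ratios
percent_median_difference <- function(med_loc, med_met) {
  100 * abs(2^med_met - 2^med_loc) / 2^med_loc
}

# per-gene dataset statistics reused across hubs and trials
activity_gene_stats <- function(em, var_equal = TRUE) {
  loc <- loc_samples(em); met <- met_samples(em)
  vl <- em$values[, loc, drop = FALSE]
  vm <- em$values[, met, drop = FALSE]
  med_loc <- apply(vl, 1L, median)
  med_met <- apply(vm, 1L, median)
  sd_loc <- apply(vl, 1L, sd)
  cds <- (med_met - med_loc) / sd_loc
  cds[sd_loc == 0] <- NA_real_
  list(gene_p = gene_t_pvalues(em, var_equal = var_equal),
       pct_diff = percent_median_difference(med_loc, med_met),
       cds = cds)
}

#' Select the genes of a hub network passing a cut-off trial
#'
#' A member gene is retained iff (the trial has no p cut-off, or its
#' two-class t-test p-value is at most \code{p_max}) and the percent
#' difference of its class medians on the ratio scale,
#' \code{100 * |2^mB - 2^mA| / 2^mA}, is at least \code{min_diff_pct}.
#'
#' @param hub A \code{\link{hub_network}}.
#' @param em An imputed \code{\link{expression_matrix}}.
#' @param trial One row of \code{\link{default_trial_ladder}} (or a list
#'   with \code{min_diff_pct} and \code{p_max}).
#' @param gene_stats Optional precomputed result of the internal per-gene
#'   statistics pass (used by \code{\link{run_activity_analysis}}).
#' @return Character vector of retained member genes (possibly empty).
#' @export
select_subset <- function(hub, em, trial, gene_stats = NULL) {
  stopifnot(inherits(hub, "hub_network"))
  if (is.null(gene_stats)) gene_stats <- activity_gene_stats(em)
  g <- intersect(hub$members, names(gene_stats$gene_p))
  ok <- rep(TRUE, length(g))
  if (!is.na(trial$p_max))
    ok <- ok & gene_stats$gene_p[g] <= trial$p_max
  if (trial$min_diff_pct > 0)
    ok <- ok & gene_stats$pct_diff[g] >= trial$min_diff_pct
  g[ok]
}

#' Class difference score of one gene
#'
#' Difference in median expression between the metastatic and localized
#' classes, normalized by the sample standard deviation within the
#' localized class:
#' \code{CDS = (median_met - median_loc) / sd_loc}.
#'
#' @param values Named numeric vector of one gene's values across samples.
#' @param classes Named character vector sample -> class.
#' @return The CDS (signed).
#' @export
class_difference_score <- function(values, classes) {
  loc <- values[names(classes)[classes == "localized"]]
  met <- values[names(classes)[classes == "metastatic"]]
  if (length(loc) < 2L) stop("need >= 2 localized values")
  s <- sd(loc)
  if (s == 0) stop("zero standard deviation in the localized class")
  (median(met) - median(loc)) / s
}

#' Network activity score
#'
#' Arithmetic mean of the absolute class difference scores of the genes in
#' a (cut-off-filtered) network subset.
#'
#' @param cds_values Numeric vector of CDS values (NA entries, from
#'   zero-variance genes, are dropped with a warning).
#' @return NAS >= 0.
#' @export
network_activity_score <- function(cds_values) {
  if (!length(cds_values)) stop("empty CDS vector")
  if (anyNA(cds_values)) {
    warning(sum(is.na(cds_values)),
            " undefined CDS value(s) dropped from NAS")
    cds_values <- cds_values[!is.na(cds_values)]
    if (!length(cds_values)) stop("no defined CDS values")
  }
  mean(abs(cds_values))
}

# NAS of a fixed gene-subset matrix under one class assignment.
# loc_idx: column indices of the localized class.  Returns NA if no gene
# has positive localized-class variance.
nas_for_assignment <- function(vals, loc_idx) {
  vl <- vals[, loc_idx, drop = FALSE]
  vm <- vals[, -loc_idx, drop = FALSE]
  s <- apply(vl, 1L, sd)
  ok <- s > 0
  if (!any(ok)) return(NA_real_)
  cds <- (apply(vm[ok, , drop = FALSE], 1L, median) -
            apply(vl[ok, , drop = FALSE], 1L, median)) / s[ok]
  mean(abs(cds))
}

#' Permutation p-values for one hub network's activity score
#'
#' The observed NAS is compared against two empirical nulls of
#' \code{n_perm} draws each: random reassignment of class labels to
#' samples (sample-label permutation, subset fixed), and random
#' reassignment of expression rows to the subset's gene slots drawn
#' without replacement from all study genes (gene-label permutation,
#' class labels fixed).  p = #\{null NAS >= observed NAS\} / n_perm, so
#' ties count against the observed score and p = 0 is attainable.
#'
#' @param hub A \code{\link{hub_network}}.
#' @param em An imputed \code{\link{expression_matrix}}.
#' @param trial Cut-off trial row (default: trial 1, all genes).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the permutation stream is derived from it and
#'   the hub id, so results do not depend on hub iteration order.
#' @param gene_stats Optional precomputed per-gene statistics.
#' @param loc_assignments Optional list of integer vectors, each a set of
#'   column indices to treat as the localized class; replaces random
#'   sampling for the sample-label null (used for exhaustive
#'   enumeration on small cohorts).
#' @return List: \code{p_sample}, \code{p_gene}, \code{null_nas_sample},
#'   \code{null_nas_gene}, \code{nas}, \code{subset}.
#' @export
permutation_pvalues <- function(hub, em, trial = default_trial_ladder()[1L, ],
                                n_perm = 1000L, seed = 1L,
                                gene_stats = NULL, loc_assignments = NULL) {
  if (!is.null(loc_assignments)) n_perm <- length(loc_assignments)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(gene_stats)) gene_stats <- activity_gene_stats(em)
  subset <- select_subset(hub, em, trial, gene_stats)
  if (!length(subset)) stop("empty subset: network not scorable in this trial")
  obs_cds <- gene_stats$cds[subset]
  nas <- suppressWarnings(network_activity_score(obs_cds))

  vals <- em$values[subset, , drop = FALSE]
  n_loc <- length(loc_samples(em))
  ns <- ncol(vals)
  g <- length(subset)
  all_cds_abs <- abs(gene_stats$cds)

  null_s <- if (is.null(loc_assignments))
    with_seed(derive_seed(seed, hub$hub, trial$trial, "sample"),
      vapply(seq_len(n_perm), function(i)
        nas_for_assignment(vals, sample.int(ns, n_loc)), numeric(1L)))
  else
    vapply(loc_assignments, function(idx)
      nas_for_assignment(vals, idx), numeric(1L))
  null_g <- with_seed(derive_seed(seed, hub$hub, trial$trial, "gene"),
    vapply(seq_len(n_perm), function(i)
      mean(all_cds_abs[sample.int(length(all_cds_abs), g)], na.rm = TRUE),
      numeric(1L)))

  list(p_sample = sum(null_s >= nas, na.rm = TRUE) / n_perm,
       p_gene = sum(null_g >= nas, na.rm = TRUE) / n_perm,
       null_nas_sample = null_s, null_nas_gene = null_g,
       nas = nas, subset = subset)
}

#' p-values of the null scores themselves
#'
#' For each null score, p = #\{null scores >= it\} / n_perm within the same
#' null set (self included, so the minimum attainable p is 1/n_perm).
#' These feed the empirical FDR.
#'
#' @param null_nas Numeric vector of null scores (length n_perm).
#' @return Numeric vector of per-permutation p-values.
#' @export
null_pvalues <- function(null_nas) {
  n <- length(null_nas)
  ok <- !is.na(null_nas)
  p <- rep(NA_real_, n)
  x <- null_nas[ok]
  p[ok] <- (length(x) - rank(x, ties.method = "min") + 1) / n
  p
}

#' Empirical false-discovery rate from permutation p-values
#'
#' For each real network phi with p-value p_phi, the FDR is the average
#' (over permutation replicates) number of permuted networks with p <=
#' p_phi, divided by the number of real networks with p <= p_phi.  The
#' ratio is reported unclipped and may exceed 1.
#'
#' @param real_pvalues Numeric vector, one p-value per real network.
#' @param null_pvalue_sets Matrix (networks x n_perm), or list of
#'   per-network numeric vectors, of null p-values from
#'   \code{\link{null_pvalues}}.
#' @return Numeric vector of FDR values aligned with \code{real_pvalues}.
#' @export
empirical_fdr <- function(real_pvalues, null_pvalue_sets) {
  if (is.list(null_pvalue_sets)) {
    n_perm <- unique(lengths(null_pvalue_sets))
    if (length(n_perm) != 1L)
      stop("all networks must contribute the same number of null p-values")
    pool <- unlist(null_pvalue_sets, use.names = FALSE)
  } else {
    n_perm <- ncol(null_pvalue_sets)
    pool <- as.vector(null_pvalue_sets)
  }
  pool <- sort(pool[!is.na(pool)])
  rp <- sort(real_pvalues)
  vapply(real_pvalues, function(p) {
    num <- findInterval(p, pool) / n_perm
    den <- findInterval(p, rp)
    num / den
  }, numeric(1L))
}

#' Run the full differential-activity analysis
#'
#' Executes the cut-off ladder in order.  Per trial and hub network: the
#' gene subset passing the trial cut-off is scored (NAS), calibrated by
#' sample- and gene-label permutation, and two empirical FDRs are computed
#' across networks.  The ladder stops after the first trial (beyond the
#' first) that contributes no network not already significant in an
#' earlier trial.  Each network's consolidated record is its best trial:
#' the maximum NAS among trials where it is significant, else the maximum
#' NAS overall.
#'
#' @param em An imputed \code{\link{expression_matrix}}.
#' @param hubs Named list of \code{\link{hub_network}}s (e.g. from
#'   \code{\link{intersect_with_expression}}).
#' @param trials Cut-off ladder data.frame (default
#'   \code{\link{default_trial_ladder}}).
#' @param n_perm Permutations per network (default 1000).
#' @param seed Master seed.
#' @param sig_p_max,sig_fdr_max Significance thresholds applied to both
#'   permutation p-values and both FDRs when deciding which networks a
#'   trial contributes (defaults: the permissive policy, p <= 0.05 and
#'   FDR <= 0.2).
#' @return Object of class \code{"activity_analysis"}: \code{per_trial}
#'   (one row per scorable hub x trial), \code{best} (one consolidated row
#'   per hub), \code{subsets} (best-trial gene subsets), \code{hubs},
#'   \code{trials_run}, \code{n_perm}, \code{seed}.
#' @export
run_activity_analysis <- function(em, hubs,
                                  trials = default_trial_ladder(),
                                  n_perm = 1000L, seed = 1L,
                                  sig_p_max = 0.05, sig_fdr_max = 0.2) {
  stopifnot(inherits(em, "expression_matrix"), length(hubs) > 0L)
  if (anyNA(em$values)) stop("matrix must be imputed first")
  hubs <- hubs[order(names(hubs))]
  gs <- activity_gene_stats(em)

  per_trial <- list()
  subsets <- list()
  sig_so_far <- character(0)
  trials_run <- integer(0)

  for (ti in seq_len(nrow(trials))) {
    trial <- trials[ti, ]
    rows <- list()
    null_s <- list(); null_g <- list()
    for (h in names(hubs)) {
      sub <- select_subset(hubs[[h]], em, trial, gs)
      if (!length(sub)) next
      pr <- suppressWarnings(
        permutation_pvalues(hubs[[h]], em, trial, n_perm, seed, gs))
      rows[[h]] <- data.frame(
        hub = h, trial = trial$trial, subset_size = length(pr$subset),
        nas = pr$nas, p_sample = pr$p_sample, p_gene = pr$p_gene,
        stringsAsFactors = FALSE)
      null_s[[h]] <- null_pvalues(pr$null_nas_sample)
      null_g[[h]] <- null_pvalues(pr$null_nas_gene)
      subsets[[paste(h, trial$trial, sep = "\r")]] <- pr$subset
    }
    trials_run <- c(trials_run, trial$trial)
    if (!length(rows)) {
      if (ti > 1L) break else next
    }
    tab <- do.call(rbind, rows)
    tab$fdr_sample <- empirical_fdr(tab$p_sample, null_s)
    tab$fdr_gene <- empirical_fdr(tab$p_gene, null_g)
    tab$significant <- tab$p_sample <= sig_p_max & tab$p_gene <= sig_p_max &
      tab$fdr_sample <= sig_fdr_max & tab$fdr_gene <= sig_fdr_max
    per_trial[[ti]] <- tab
    new_sig <- setdiff(tab$hub[tab$significant], sig_so_far)
    sig_so_far <- union(sig_so_far, new_sig)
    if (ti > 1L && !length(new_sig)) break
  }

  per_trial <- do.call(rbind, per_trial)
  rownames(per_trial) <- NULL

  # consolidate: per hub, max NAS among significant trials, else overall
  best_idx <- vapply(split(seq_len(nrow(per_trial)), per_trial$hub),
    function(ii) {
      sig <- ii[per_trial$significant[ii]]
      pool <- if (length(sig)) sig else ii
      pool[which.max(per_trial$nas[pool])]
    }, integer(1L))
  best <- per_trial[best_idx, , drop = FALSE]
  best <- best[order(best$hub), , drop = FALSE]
  rownames(best) <- NULL
  best_subsets <- stats::setNames(
    subsets[paste(best$hub, best$trial, sep = "\r")], best$hub)

  structure(list(per_trial = per_trial, best = best,
                 subsets = best_subsets, hubs = hubs,
                 trials_run = trials_run, n_perm = n_perm, seed = seed),
            class = "activity_analysis")
}

#' @export
print.activity_analysis <- function(x, ...) {
  cat(sprintf(
    "activity_analysis: %d networks, trials run: %s, %d significant\n",
    nrow(x$best), paste(x$trials_run, collapse = ","),
    sum(x$best$significant)))
  invisible(x)
}

#' Write the per-trial activity table as TSV
#'
#' Columns mirror the reporting layout: hub, trial, subset_size, NAS,
#' p_sample, FDR_sample, p_gene, FDR_gene.
#'
#' @param activity An \code{activity_analysis}.
#' @param path Output TSV.
#' @param which \code{"best"} (default) or \code{"per_trial"}.
#' @return Invisibly, the written data.frame.
#' @export
write_activity <- function(activity, path, which = c("best", "per_trial")) {
  which <- match.arg(which)
  tab <- activity[[which]]
  out <- tab[, c("hub", "trial", "subset_size", "nas",
                 "p_sample", "fdr_sample", "p_gene", "fdr_gene")]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], signif, 6L)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(out)
}
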