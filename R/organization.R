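#' Pearson correlation of two paired vectors
#'
#' Standard sample Pearson correlation coefficient.  Requires at least
#' three pairs; a zero-variance vector yields \code{NA} with a warning
#' (the caller skips such edges rather than treating them as r = 0).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return r in [-1, 1], or NA.
#' @export
pearson_pcc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need >= 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Two-sided p-value of a Pearson correlation
#'
#' From t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' |r| = 1 returns p = 0 by convention.
#'
#' @param r Correlation coefficient.
#' @param n_pairs Number of pairs (>= 3).
#' @return Two-sided p-value.
#' @export
pcc_pvalue <- function(r, n_pairs) {
  if (n_pairs < 3L) stop("need n_pairs >= 3")
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n_pairs - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n_pairs - 2)
}

# per-edge correlations of hub vs interactors over the given columns;
# one cor() call vectorized across interactors
edge_pccs <- function(vals, hub, interactors, cols) {
  x <- vals[hub, cols]
  if (sd(x) == 0) return(rep(NA_real_, length(interactors)))
  y <- t(vals[interactors, cols, drop = FALSE])
  r <- suppressWarnings(as.vector(cor(x, y)))
  sds <- apply(y, 2L, sd)
  r[sds == 0] <- NA_real_
  r
}

#' Differential organization of one hub network
#'
#' For each hub-interactor edge, the Pearson correlation is computed
#' separately over the localized and the metastatic samples; the per-edge
#' change is \code{delta_pcc = pcc_metastatic - pcc_localized} and the
#' hub-level statistic is its mean over scorable edges (AvgDeltaPCC,
#' reported as DeltaPCC_Total).  Edges with zero variance in either class
#' are skipped with a warning rather than diluting the average.
#'
#' @param hub A \code{\link{hub_network}}.
#' @param em An imputed \code{\link{expression_matrix}}.
#' @return Object of class \code{"organization_result"}: \code{hub},
#'   \code{degree} (scorable interactor count), \code{edges} (data.frame
#'   interactor / pcc_localized / pcc_metastatic / delta_pcc),
#'   \code{avg_delta_pcc}; or NULL (with a warning) if no edge is
#'   scorable.
#' @export
hub_organization <- function(hub, em) {
  stopifnot(inherits(hub, "hub_network"), inherits(em, "expression_matrix"))
  ints <- intersect(hub$interactors, rownames(em$values))
  if (!length(ints) || !(hub$hub %in% rownames(em$values)))
    stop("hub '", hub$hub, "' not scorable: genes missing from matrix")
  loc <- loc_samples(em); met <- met_samples(em)
  r_loc <- edge_pccs(em$values, hub$hub, ints, loc)
  r_met <- edge_pccs(em$values, hub$hub, ints, met)
  ok <- !is.na(r_loc) & !is.na(r_met)
  if (!any(ok)) {
    warning("hub '", hub$hub, "' dropped: no scorable edge")
    return(NULL)
  }
  if (any(!ok))
    warning(sum(!ok), " zero-variance edge(s) skipped for hub '",
            hub$hub, "'")
  edges <- data.frame(interactor = ints[ok],
                      pcc_localized = r_loc[ok],
                      pcc_metastatic = r_met[ok],
                      delta_pcc = r_met[ok] - r_loc[ok],
                      stringsAsFactors = FALSE)
  structure(list(hub = hub$hub, degree = nrow(edges), edges = edges,
                 avg_delta_pcc = mean(edges$delta_pcc)),
            class = "organization_result")
}

#' @export
print.organization_result <- function(x, ...) {
  cat(sprintf("organization_result %s: degree %d, AvgDeltaPCC %.3f\n",
              x$hub, x$degree, x$avg_delta_pcc))
  invisible(x)
}

#' Class-label permutation p-value for differential organization
#'
#' The observed AvgDeltaPCC is compared to the same statistic recomputed
#' under \code{n_perm} random reassignments of the class labels (class
#' sizes preserved).  By default the comparison is on absolute values
#' (two-sided in magnitude): p = #\{|perm| >= |observed|\} / n_perm; with
#' \code{signed = TRUE} the comparison is \code{perm >= observed}.
#'
#' @param hub A \code{\link{hub_network}}.
#' @param em An imputed \code{\link{expression_matrix}}.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (per-hub stream derived from it).
#' @param signed Compare signed instead of absolute statistics.
#' @param org Optional precomputed \code{\link{hub_organization}} result.
#' @param loc_assignments Optional list of localized-column index sets
#'   replacing random sampling (exhaustive enumeration on small cohorts).
#' @return p in [0, 1], a multiple of 1/n_perm.
#' @export
organization_permutation_p <- function(hub, em, n_perm = 1000L, seed = 1L,
                                       signed = FALSE, org = NULL,
                                       loc_assignments = NULL) {
  if (!is.null(loc_assignments)) n_perm <- length(loc_assignments)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(org))
    org <- suppressWarnings(hub_organization(hub, em))
  if (is.null(org)) stop("hub not scorable")
  ints <- org$edges$interactor
  vals <- em$values
  ns <- ncol(vals)
  n_loc <- length(loc_samples(em))
  obs <- org$avg_delta_pcc
  perm_stat <- function(idx) {
    rl <- edge_pccs(vals, hub$hub, ints, idx)
    rm <- edge_pccs(vals, hub$hub, ints, seq_len(ns)[-idx])
    mean(rm - rl, na.rm = TRUE)
  }
  null <- if (is.null(loc_assignments))
    with_seed(derive_seed(seed, hub$hub, "organization"),
      vapply(seq_len(n_perm), function(i)
        perm_stat(sample.int(ns, n_loc)), numeric(1L)))
  else vapply(loc_assignments, perm_stat, numeric(1L))
  if (signed) sum(null >= obs, na.rm = TRUE) / n_perm
  else sum(abs(null) >= abs(obs), na.rm = TRUE) / n_perm
}

#' Run the differential-organization analysis over all hub networks
#'
#' One \code{\link{hub_organization}} score and one class-label
#' permutation p-value per scorable hub, in stable hub-id order.
#'
#' @param em An imputed \code{\link{expression_matrix}}.
#' @param hubs Named list of \code{\link{hub_network}}s.
#' @param n_perm Permutations per hub (default 1000).
#' @param seed Master seed.
#' @param signed Passed to \code{\link{organization_permutation_p}}.
#' @return Object of class \code{"organization_analysis"}: \code{table}
#'   (hub / degree / avg_delta_pcc / p_sample), \code{edges} (per-edge
#'   records across hubs, with per-class correlation p-values),
#'   \code{n_perm}, \code{seed}.
#' @export
run_organization_analysis <- function(em, hubs, n_perm = 1000L, seed = 1L,
                                      signed = FALSE) {
  stopifnot(inherits(em, "expression_matrix"), length(hubs) > 0L)
  if (anyNA(em$values)) stop("matrix must be imputed first")
  hubs <- hubs[order(names(hubs))]
  n_loc <- length(loc_samples(em))
  n_met <- length(met_samples(em))
  rows <- list(); edge_rows <- list()
  for (h in names(hubs)) {
    org <- suppressWarnings(tryCatch(hub_organization(hubs[[h]], em),
                                     error = function(e) NULL))
    if (is.null(org)) next
    p <- organization_permutation_p(hubs[[h]], em, n_perm, seed,
                                    signed = signed, org = org)
    rows[[h]] <- data.frame(hub = h, degree = org$degree,
                            avg_delta_pcc = org$avg_delta_pcc,
                            p_sample = p, stringsAsFactors = FALSE)
    e <- org$edges
    e$pcc_p_localized <- vapply(e$pcc_localized, pcc_pvalue, numeric(1L),
                                n_pairs = n_loc)
    e$pcc_p_metastatic <- vapply(e$pcc_metastatic, pcc_pvalue, numeric(1L),
                                 n_pairs = n_met)
    edge_rows[[h]] <- cbind(hub = h, e, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no scorable hub network")
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  edges <- do.call(rbind, edge_rows); rownames(edges) <- NULL
  structure(list(table = tab, edges = edges, n_perm = n_perm, seed = seed),
            class = "organization_analysis")
}

#' @export
print.organization_analysis <- function(x, ...) {
  cat(sprintf("organization_analysis: %d networks (n_perm = %d)\n",
              nrow(x$table), x$n_perm))
  invisible(x)
}

#' Write organization results as hub-level and edge-level TSVs
#'
#' @param organization An \code{organization_analysis}.
#' @param hub_path Hub-level TSV (hub, degree, avg_delta_pcc, p_sample).
#' @param edge_path Optional edge-level TSV.
#' @return Invisibly, the hub-level data.frame.
#' @export
write_organization <- function(organization, hub_path, edge_path = NULL) {
  tab <- organization$table
  tab$avg_delta_pcc <- signif(tab$avg_delta_pcc, 6L)
  data.table::fwrite(tab, hub_path, sep = "\t", quote = FALSE)
  if (!is.null(edge_path)) {
    e <- organization$edges
    num <- vapply(e, is.numeric, logical(1L))
    e[num] <- lapply(e[num], signif, 6L)
    data.table::fwrite(e, edge_path, sep = "\t", quote = FALSE)
  }
  invisible(tab)
}
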