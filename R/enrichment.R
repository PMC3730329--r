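#' Packaged GO-Slim term simplification map
#'
#' The default map collapsing GO-Slim generic process terms into the broad
#' simplified vocabulary used throughout the package (death, development,
#' metabolism, signaling, transport, ...).  Terms already in the simplified
#' vocabulary map to themselves; junk catch-all terms (e.g. "biological
#' process") map to \code{"NaN"}.
#'
#' @return Named character vector: original term -> simplified term.
#' @export
default_term_simplification <- function() {
  path <- system.file("extdata", "term_simplification.tsv",
                      package = "hubdiff", mustWork = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  stats::setNames(dt$simplified_term, dt$original_term)
}

#' Simplify gene annotations with a term-simplification map
#'
#' @param gene_terms Named character vector gene -> original term.
#' @param map Named character vector original -> simplified term
#'   (default \code{\link{default_term_simplification}}).
#' @param unmapped What to do with terms absent from the map:
#'   \code{"nan"} (default; they become \code{"NaN"}) or \code{"keep"}.
#' @return Named character vector gene -> simplified term.
#' @export
simplify_terms <- function(gene_terms, map = default_term_simplification(),
                           unmapped = c("nan", "keep")) {
  unmapped <- match.arg(unmapped)
  out <- unname(map[gene_terms])
  miss <- is.na(out)
  out[miss] <- if (unmapped == "nan") "NaN" else gene_terms[miss]
  stats::setNames(out, names(gene_terms))
}

#' Majority-term annotation of a gene set
#'
#' Assigns the modal simplified term among the given genes.  Genes with no
#' annotation are ignored; if none is annotated the result is
#' \code{"NaN"}.  Ties are broken alphabetically and flagged via the
#' \code{"tie"} attribute (and a message).
#'
#' @param member_genes Character vector of gene ids.
#' @param gene_terms Named character vector gene -> (simplified) term.
#' @return Length-1 character term, with attribute \code{tie}.
#' @export
annotate_network <- function(member_genes, gene_terms) {
  terms <- gene_terms[intersect(member_genes, names(gene_terms))]
  terms <- terms[!is.na(terms)]
  if (!length(terms))
    return(structure("NaN", tie = FALSE))
  counts <- sort(table(terms), decreasing = TRUE)
  top <- names(counts)[counts == counts[1L]]
  tie <- length(top) > 1L
  if (tie) message("annotation tie among: ", paste(sort(top), collapse = ", "))
  structure(sort(top)[1L], tie = tie)
}

#' Re-annotate activity networks by their significant subsets
#'
#' Each network is annotated twice: by the majority term over its full
#' membership and over its best-trial subset only.  The discordance rate
#' between the two is reported as an attribute (informative, not
#' asserted).
#'
#' @param activity An \code{activity_analysis} from
#'   \code{\link{run_activity_analysis}}.
#' @param gene_terms Named character vector gene -> simplified term.
#' @return data.frame (hub, network_annotation, subset_annotation,
#'   discordant) with attribute \code{discordance_rate}.
#' @export
annotate_activity_subsets <- function(activity, gene_terms) {
  stopifnot(inherits(activity, "activity_analysis"))
  hubs <- activity$hubs[names(activity$subsets)]
  full <- vapply(hubs, function(h)
    as.character(annotate_network(h$members, gene_terms)), character(1L))
  sub <- vapply(names(hubs), function(h) {
    s <- activity$subsets[[h]]
    if (!length(s)) "NaN"
    else as.character(annotate_network(s, gene_terms))
  }, character(1L))
  out <- data.frame(hub = names(hubs), network_annotation = unname(full),
                    subset_annotation = unname(sub),
                    discordant = unname(full != sub),
                    stringsAsFactors = FALSE)
  attr(out, "discordance_rate") <- mean(out$discordant)
  out
}

#' Hypergeometric enrichment p-value
#'
#' With N networks in the study, M of them annotated to a process, and n
#' significant networks of which i are annotated to the process:
#' \code{mode = "point"} gives the probability mass P(X = i) for
#' X ~ Hypergeometric(N, M, n) (the form matching the published table
#' values, computed via a probability-density routine);
#' \code{mode = "tail"} gives the conventional upper tail P(X >= i).
#'
#' @param N Total networks in the study.
#' @param M Study networks annotated to the process.
#' @param n Significant networks.
#' @param i Significant networks annotated to the process.
#' @param mode \code{"point"} (default) or \code{"tail"}.
#' @return p in [0, 1].
#' @export
enrichment_pvalue <- function(N, M, n, i, mode = c("point", "tail")) {
  mode <- match.arg(mode)
  if (any(c(N, M, n, i) < 0) || M > N || n > N || i > min(M, n) ||
      i < max(0, n - (N - M)))
    stop("inconsistent counts: need 0 <= i <= min(M, n) <= N (and i >= n-(N-M))")
  if (mode == "point") dhyper(i, m = M, n = N - M, k = n)
  else phyper(i - 1, m = M, n = N - M, k = n, lower.tail = FALSE)
}

#' Process enrichment table over both analysis arms
#'
#' Builds the study-versus-significant contingency summary per process.
#' The activated arm compares subset-based annotations of significant
#' activated networks to the subset-based study composition; the organized
#' arm compares full-network annotations of significant organized networks
#' to the full-network study composition.  A process is flagged enriched
#' in an arm when its proportion among that arm's significant networks
#' exceeds its study proportion; a hypergeometric p-value is computed only
#' for flagged processes (never for \code{"NaN"}).
#'
#' @param study_annotations Named character vector hub -> full-network
#'   process, covering all N study networks.
#' @param subset_annotations Named character vector hub -> subset-based
#'   process, covering all N study networks (fall back to
#'   \code{study_annotations} for hubs without a scored subset).
#' @param significant_activated,significant_organized Character vectors of
#'   significant hub ids.
#' @param mode Passed to \code{\link{enrichment_pvalue}}.
#' @return data.frame with one row per process: study counts and
#'   percentages for both compositions, significant counts, percentages,
#'   enrichment flags and p-values for both arms.
#' @export
enrichment_table <- function(study_annotations, subset_annotations,
                             significant_activated, significant_organized,
                             mode = c("point", "tail")) {
  mode <- match.arg(mode)
  N <- length(study_annotations)
  if (length(subset_annotations) != N)
    stop("subset and study annotations must cover the same networks")
  subset_annotations <- subset_annotations[names(study_annotations)]
  procs <- sort(unique(c(study_annotations, subset_annotations)))
  procs <- c(setdiff(procs, "NaN"), intersect("NaN", procs))

  cnt <- function(ann, ids = names(ann))
    vapply(procs, function(p) sum(ann[ids] == p), integer(1L))
  m_subset <- cnt(subset_annotations)
  m_full <- cnt(study_annotations)
  n_act <- length(significant_activated)
  n_org <- length(significant_organized)
  i_act <- cnt(subset_annotations, significant_activated)
  i_org <- cnt(study_annotations, significant_organized)

  act_flag <- n_act > 0 & (i_act / max(n_act, 1L)) > (m_subset / N)
  org_flag <- n_org > 0 & (i_org / max(n_org, 1L)) > (m_full / N)
  act_p <- rep(NA_real_, length(procs))
  org_p <- rep(NA_real_, length(procs))
  for (j in seq_along(procs)) {
    if (procs[j] == "NaN") next
    if (act_flag[j])
      act_p[j] <- enrichment_pvalue(N, m_subset[j], n_act, i_act[j], mode)
    if (org_flag[j])
      org_p[j] <- enrichment_pvalue(N, m_full[j], n_org, i_org[j], mode)
  }
  data.frame(
    process = procs,
    subset_count = unname(m_subset),
    subset_pct = unname(100 * m_subset / N),
    network_count = unname(m_full),
    network_pct = unname(100 * m_full / N),
    activated_count = unname(i_act),
    activated_pct = unname(if (n_act) 100 * i_act / n_act else 0 * i_act),
    activated_enriched = unname(act_flag),
    activated_p = unname(act_p),
    organized_count = unname(i_org),
    organized_pct = unname(if (n_org) 100 * i_org / n_org else 0 * i_org),
    organized_enriched = unname(org_flag),
    organized_p = unname(org_p),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an enrichment table as TSV
#'
#' @param table Result of \code{\link{enrichment_table}}.
#' @param path Output TSV; unflagged processes get blank p cells.
#' @return Invisibly, the written data.frame.
#' @export
write_enrichment <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], signif, 6L)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(out)
}
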