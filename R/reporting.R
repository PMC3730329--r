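#' Tiered significance cut-off policies
#'
#' Three packaged tiers mirror the study design: \code{"permissive"}
#' (broad trends; activated: both p <= 0.05 and both FDR <= 0.2;
#' organized: p <= 0.001), \code{"visualization"} (activated: p <= 0.05,
#' FDR <= 0.1, NAS >= 1.65; organized: p <= 0.001 and |AvgDeltaPCC| >=
#' 0.4) and \code{"stringent"} (activated: p <= 0.01, FDR <= 0.1, NAS >=
#' 1.65; organized: p = 0 exactly, |AvgDeltaPCC| >= 0.4, at least 7
#' interactors).  \code{"custom"} starts from permissive and overrides
#' selected thresholds.
#'
#' @param name Preset name.
#' @param activated,organized Named lists overriding preset thresholds
#'   (fields \code{p_max_sample}, \code{p_max_gene}, \code{fdr_max_sample},
#'   \code{fdr_max_gene}, \code{nas_min}; resp. \code{p_max},
#'   \code{abs_avg_delta_pcc_min}, \code{min_interactors}).
#' @return Object of class \code{"cutoff_policy"}.
#' @export
cutoff_policy <- function(name = c("permissive", "visualization",
                                   "stringent", "custom"),
                          activated = list(), organized = list()) {
  name <- match.arg(name)
  presets <- list(
    permissive = list(
      activated = list(p_max_sample = 0.05, p_max_gene = 0.05,
                       fdr_max_sample = 0.2, fdr_max_gene = 0.2,
                       nas_min = 0),
      organized = list(p_max = 0.001, abs_avg_delta_pcc_min = 0,
                       min_interactors = 1)),
    visualization = list(
      activated = list(p_max_sample = 0.05, p_max_gene = 0.05,
                       fdr_max_sample = 0.1, fdr_max_gene = 0.1,
                       nas_min = 1.65),
      organized = list(p_max = 0.001, abs_avg_delta_pcc_min = 0.4,
                       min_interactors = 1)),
    stringent = list(
      activated = list(p_max_sample = 0.01, p_max_gene = 0.01,
                       fdr_max_sample = 0.1, fdr_max_gene = 0.1,
                       nas_min = 1.65),
      organized = list(p_max = 0, abs_avg_delta_pcc_min = 0.4,
                       min_interactors = 7)))
  base <- presets[[if (name == "custom") "permissive" else name]]
  pol <- list(name = name,
              activated = modifyList(base$activated, activated),
              organized = modifyList(base$organized, organized))
  if (any(unlist(pol$activated) < 0) || any(unlist(pol$organized) < 0))
    stop("thresholds must be non-negative")
  structure(pol, class = "cutoff_policy")
}

#' @export
print.cutoff_policy <- function(x, ...) {
  a <- x$activated; o <- x$organized
  cat(sprintf(paste0(
    "cutoff_policy '%s'\n",
    "  activated: p <= %g (sample) & %g (gene), FDR <= %g & %g, NAS >= %g\n",
    "  organized: p <= %g, |AvgDeltaPCC| >= %g, interactors >= %g\n"),
    x$name, a$p_max_sample, a$p_max_gene, a$fdr_max_sample, a$fdr_max_gene,
    a$nas_min, o$p_max, o$abs_avg_delta_pcc_min, o$min_interactors))
  invisible(x)
}

#' Apply a cut-off policy to activity and organization results
#'
#' Membership in each significant set is the conjunction of every
#' threshold in the policy.
#'
#' @param activity An \code{activity_analysis} (its consolidated
#'   \code{best} table is used), or NULL.
#' @param organization An \code{organization_analysis}, or NULL.
#' @param policy A \code{\link{cutoff_policy}}.
#' @return List with \code{activated} and \code{organized}: character
#'   vectors of significant hub ids.
#' @export
apply_cutoffs <- function(activity, organization,
                          policy = cutoff_policy("permissive")) {
  stopifnot(inherits(policy, "cutoff_policy"))
  activated <- character(0); organized <- character(0)
  if (!is.null(activity)) {
    b <- activity$best; a <- policy$activated
    keep <- b$p_sample <= a$p_max_sample & b$p_gene <= a$p_max_gene &
      b$fdr_sample <= a$fdr_max_sample & b$fdr_gene <= a$fdr_max_gene &
      b$nas >= a$nas_min
    activated <- sort(b$hub[keep])
  }
  if (!is.null(organization)) {
    t <- organization$table; o <- policy$organized
    keep <- t$p_sample <= o$p_max &
      abs(t$avg_delta_pcc) >= o$abs_avg_delta_pcc_min &
      t$degree >= o$min_interactors
    organized <- sort(t$hub[keep])
  }
  message(length(activated), " activated / ", length(organized),
          " organized networks significant under '", policy$name,
          "' cut-offs")
  list(activated = activated, organized = organized)
}

#' Look up query genes among significant networks
#'
#' For every query gene, reports every significant network whose member
#' set contains it, with the network's statistics (activity: NAS and both
#' p/FDR pairs; organization: AvgDeltaPCC and its p).  Query genes absent
#' from the study (not a member of any hub network) are flagged.
#'
#' @param activity An \code{activity_analysis} or NULL.
#' @param organization An \code{organization_analysis} or NULL.
#' @param significant Result of \code{\link{apply_cutoffs}}.
#' @param query_genes Character vector of gene ids to look up.
#' @param hubs Named list of \code{\link{hub_network}}s (defaults to the
#'   hubs stored in \code{activity}).
#' @return List with data.frames \code{activated} (query, node, score,
#'   p_sample, fdr_sample, p_gene, fdr_gene) and \code{organized} (query,
#'   node, delta_pcc_total, p_sample), plus \code{absent}: query genes not
#'   in the study.
#' @export
query_gene_lookup <- function(activity, organization, significant,
                              query_genes, hubs = activity$hubs) {
  stopifnot(!is.null(hubs))
  members <- lapply(hubs, `[[`, "members")
  study_genes <- unique(unlist(members, use.names = FALSE))
  absent <- setdiff(query_genes, study_genes)
  present <- intersect(query_genes, study_genes)

  act_rows <- list(); org_rows <- list()
  for (q in present) {
    holds <- names(members)[vapply(members, function(m) q %in% m,
                                   logical(1L))]
    for (h in intersect(holds, significant$activated)) {
      r <- activity$best[activity$best$hub == h, ]
      act_rows[[length(act_rows) + 1L]] <- data.frame(
        query = q, node = h, score = r$nas, p_sample = r$p_sample,
        fdr_sample = r$fdr_sample, p_gene = r$p_gene,
        fdr_gene = r$fdr_gene, stringsAsFactors = FALSE)
    }
    for (h in intersect(holds, significant$organized)) {
      r <- organization$table[organization$table$hub == h, ]
      org_rows[[length(org_rows) + 1L]] <- data.frame(
        query = q, node = h, delta_pcc_total = r$avg_delta_pcc,
        p_sample = r$p_sample, stringsAsFactors = FALSE)
    }
  }
  empty_act <- data.frame(query = character(0), node = character(0),
                          score = numeric(0), p_sample = numeric(0),
                          fdr_sample = numeric(0), p_gene = numeric(0),
                          fdr_gene = numeric(0), stringsAsFactors = FALSE)
  empty_org <- data.frame(query = character(0), node = character(0),
                          delta_pcc_total = numeric(0),
                          p_sample = numeric(0), stringsAsFactors = FALSE)
  if (length(absent))
    message("query gene(s) absent from the study: ",
            paste(absent, collapse = ", "))
  list(activated = if (length(act_rows)) do.call(rbind, act_rows)
         else empty_act,
       organized = if (length(org_rows)) do.call(rbind, org_rows)
         else empty_org,
       absent = absent)
}

#' Export significant networks for graph-visualization tools
#'
#' Writes a SIF file of the significant hubs' edges, a node-attribute TSV
#' (log2 and percent fold change metastatic vs localized, t-test p-value,
#' interactor count for node sizing), an edge-attribute TSV (per-class
#' correlations and p-values, delta_pcc, a both-classes-significant flag)
#' and a combined GraphML.  Following the visualization convention, edges
#' are restricted to interactors whose correlation with the hub is
#' significant (PCC p <= \code{pcc_p_max}) in at least one class, and node
#' attributes are emitted only for genes with t-test p <=
#' \code{node_p_max} (set either to \code{Inf} to disable).
#'
#' @param significant Result of \code{\link{apply_cutoffs}} (union of both
#'   sets is exported); must be nonempty.
#' @param organization An \code{organization_analysis} providing per-edge
#'   correlations.
#' @param em An imputed \code{\link{expression_matrix}}.
#' @param dir Output directory (created if needed).
#' @param pcc_p_max Edge inclusion threshold (default 0.001).
#' @param node_p_max Node-attribute threshold (default 0.001).
#' @return Invisibly, list with the node and edge data.frames and file
#'   paths.
#' @export
export_graph <- function(significant, organization, em, dir,
                         pcc_p_max = 0.001, node_p_max = 0.001) {
  hubs_sig <- union(significant$activated, significant$organized)
  if (!length(hubs_sig))
    stop("nothing to export: both significant sets are empty")
  e <- organization$edges
  e <- e[e$hub %in% hubs_sig &
           (e$pcc_p_localized <= pcc_p_max |
              e$pcc_p_metastatic <= pcc_p_max), , drop = FALSE]
  if (!nrow(e)) stop("no edge passes the correlation-significance filter")
  e$both_significant <- e$pcc_p_localized <= pcc_p_max &
    e$pcc_p_metastatic <= pcc_p_max

  genes <- unique(c(e$hub, e$interactor))
  loc <- loc_samples(em); met <- met_samples(em)
  m_loc <- rowMeans(em$values[genes, loc, drop = FALSE])
  m_met <- rowMeans(em$values[genes, met, drop = FALSE])
  t_p <- vapply(genes, function(g)
    gene_t_test(em$values[g, loc], em$values[g, met])$p_value, numeric(1L))
  degree <- table(factor(c(e$hub, e$interactor), levels = genes))
  nodes <- data.frame(
    gene = genes,
    log2_fold_change = unname(m_met - m_loc),
    pct_fold_change = unname(100 * (2^m_met - 2^m_loc) / 2^m_loc),
    t_p = unname(t_p),
    interactor_count = as.integer(degree),
    stringsAsFactors = FALSE)
  node_attr <- nodes[nodes$t_p <= node_p_max, , drop = FALSE]

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(sif = file.path(dir, "significant.sif"),
                nodes = file.path(dir, "node_attributes.tsv"),
                edges = file.path(dir, "edge_attributes.tsv"),
                graphml = file.path(dir, "significant.graphml"))
  writeLines(paste(e$hub, "interacts", e$interactor, sep = "\t"),
             paths$sif)
  fmt <- function(d) { n <- vapply(d, is.numeric, logical(1L))
    d[n] <- lapply(d[n], signif, 6L); d }
  data.table::fwrite(fmt(node_attr), paths$nodes, sep = "\t", quote = FALSE)
  data.table::fwrite(fmt(e), paths$edges, sep = "\t", quote = FALSE)

  g <- igraph::graph_from_data_frame(
    e[, c("hub", "interactor", "pcc_localized", "pcc_metastatic",
          "delta_pcc", "both_significant")],
    directed = FALSE,
    vertices = nodes[, c("gene", "log2_fold_change", "pct_fold_change",
                         "t_p", "interactor_count")])
  igraph::write_graph(g, paths$graphml, format = "graphml")
  invisible(list(nodes = node_attr, edges = e, paths = paths))
}
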