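#' Read an expression matrix and its sample class labels
#'
#' The expression file is a TSV whose header row is \code{gene_id} followed
#' by sample ids, one gene per row; empty cells are read as missing (never
#' as zero).  The label file is a two-column TSV (\code{sample_id},
#' \code{class}) with classes in \{localized, metastatic\}.
#'
#' @param matrix_path Path to the expression TSV.
#' @param labels_path Path to the sample-label TSV.
#' @param class_levels Admissible class labels (reference class first).
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(matrix_path, labels_path,
                            class_levels = CLASS_LEVELS) {
  dt <- data.table::fread(matrix_path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          na.strings = c("", "NA", "NaN"))
  if (ncol(dt) < 2L) stop("expression file has no sample columns")
  genes <- dt[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  vals <- as.matrix(dt[, -1L])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes

  lab <- data.table::fread(labels_path, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (ncol(lab) < 2L) stop("label file must have two columns")
  classes <- stats::setNames(lab[[2L]], lab[[1L]])
  expression_matrix(vals, classes, class_levels)
}

#' Write an expression matrix and its sample labels
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param matrix_path,labels_path Output TSV paths.
#' @return Invisibly, \code{em}.
#' @export
write_expression <- function(em, matrix_path, labels_path) {
  stopifnot(inherits(em, "expression_matrix"))
  dt <- data.table::data.table(gene_id = rownames(em$values))
  v <- signif(em$values, 6L)
  for (s in colnames(v)) dt[[s]] <- v[, s]
  data.table::fwrite(dt, matrix_path, sep = "\t", na = "", quote = FALSE)
  data.table::fwrite(
    data.table::data.table(sample_id = names(em$classes),
                           class = unname(em$classes)),
    labels_path, sep = "\t", quote = FALSE)
  invisible(em)
}

#' Read an interaction network from SIF or adjacency format
#'
#' SIF lines are \code{source <tab> relation <tab> target [targets...]};
#' adjacency lines are \code{source [:] neighbor [neighbors...]} (a plain
#' two-column TSV is the minimal case).  Reversed and duplicate edges are
#' collapsed and self-loops dropped with a message.
#'
#' @param path Input file.
#' @param format \code{"sif"} or \code{"adjacency"}.
#' @return An \code{\link{interaction_network}}.
#' @export
read_network <- function(path, format = c("sif", "adjacency")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  from <- character(0); to <- character(0); nodes <- character(0)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    if (format == "sif") {
      if (length(f) < 3L)
        stop("malformed SIF line ", i, ": '", lines[i], "'")
      from <- c(from, rep(f[1L], length(f) - 2L))
      to <- c(to, f[-(1:2)])
    } else {
      f[1L] <- sub(":$", "", f[1L])
      if (length(f) < 2L)
        stop("malformed adjacency line ", i, ": '", lines[i], "'")
      from <- c(from, rep(f[1L], length(f) - 1L))
      to <- c(to, f[-1L])
    }
  }
  if (!length(from)) stop("no edges in '", path, "'")
  interaction_network(cbind(from, to))
}

#' Write an interaction network as SIF or two-column adjacency TSV
#'
#' @param network An \code{\link{interaction_network}}.
#' @param path Output file.
#' @param format \code{"sif"} or \code{"adjacency"}.
#' @param relation SIF relation token (default \code{"interacts"}).
#' @return Invisibly, \code{network}.
#' @export
write_network <- function(network, path, format = c("sif", "adjacency"),
                          relation = "interacts") {
  format <- match.arg(format)
  e <- network$edges
  out <- if (format == "sif")
    paste(e$from, relation, e$to, sep = "\t")
  else paste(e$from, e$to, sep = "\t")
  writeLines(out, path)
  invisible(network)
}

#' Read / write a gene-to-term annotation table
#'
#' Two-column TSV with header (\code{gene_id}, \code{term}).
#'
#' @param path File path.
#' @return Named character vector gene -> term.
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stats::setNames(dt[[2L]], dt[[1L]])
}

#' @rdname read_annotations
#' @param annotations Named character vector gene -> term.
#' @export
write_annotations <- function(annotations, path) {
  data.table::fwrite(
    data.table::data.table(gene_id = names(annotations),
                           term = unname(annotations)),
    path, sep = "\t", quote = FALSE)
  invisible(annotations)
}

#' Restrict a network to profiled genes and extract hub networks
#'
#' Keeps the nodes common to the interaction network and the expression
#' matrix, drops edges with an unprofiled endpoint, and builds one hub
#' network per retained node that still has at least one retained
#' interactor.
#'
#' @param network An \code{\link{interaction_network}}.
#' @param em An \code{\link{expression_matrix}}.
#' @return List with \code{network} (the restricted network) and
#'   \code{hubs} (named list of \code{\link{hub_network}}s).
#' @export
intersect_with_expression <- function(network, em) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(em, "expression_matrix"))
  common <- intersect(network$nodes, rownames(em$values))
  if (!length(common))
    stop("no genes in common between network and expression matrix")
  e <- network$edges
  keep <- e$from %in% common & e$to %in% common
  sub <- interaction_network(as.matrix(e[keep, , drop = FALSE]),
                             nodes = common)
  nb <- neighbor_list(sub)
  connected <- names(nb)[lengths(nb) > 0L]
  dropped <- length(common) - length(connected)
  if (dropped)
    message(dropped, " gene(s) with no retained interactor dropped as hubs")
  hubs <- lapply(connected, function(h) hub_network(h, nb[[h]]))
  names(hubs) <- connected
  list(network = sub, hubs = hubs)
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Each missing entry is replaced by the inverse-distance-weighted average
#' of the values, in that sample, of the \code{k} genes nearest to the
#' target gene.  Distances are pairwise-complete Euclidean distances
#' normalized per shared sample count; candidate neighbours must be
#' observed in the target sample and share at least one observed sample
#' with the target gene.  Ties are broken by gene id order.
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param k Number of neighbours (default 10).
#' @return An imputed \code{\link{expression_matrix}} with no missing
#'   values; observed entries are unchanged.
#' @export
impute_knn <- function(em, k = 10L) {
  stopifnot(inherits(em, "expression_matrix"), k >= 1L)
  v <- em$values
  all_missing <- rownames(v)[rowSums(!is.na(v)) == 0L]
  if (length(all_missing))
    stop("gene(s) with no observed value: ",
         paste(all_missing, collapse = ", "))
  holes <- which(is.na(v), arr.ind = TRUE)
  if (!nrow(holes)) return(em)
  obs <- !is.na(v)
  for (g in unique(holes[, "row"])) {
    target <- v[g, ]
    shared <- obs & rep(obs[g, ], each = nrow(v))
    n_shared <- rowSums(shared)
    # mean squared difference over shared samples, scale-free in coverage
    diff2 <- (v - rep(target, each = nrow(v)))^2
    diff2[!shared] <- 0
    d <- sqrt(rowSums(diff2, na.rm = TRUE) / pmax(n_shared, 1L))
    d[g] <- Inf
    d[n_shared == 0L] <- Inf
    for (s in holes[holes[, "row"] == g, "col"]) {
      cand <- which(obs[, s] & is.finite(d))
      if (!length(cand))
        stop("cannot impute gene '", rownames(v)[g],
             "': no observed neighbour in sample '", colnames(v)[s], "'")
      ord <- cand[order(d[cand], rownames(v)[cand])]
      nn <- head(ord, k)
      w <- 1 / pmax(d[nn], .Machine$double.eps)
      v[g, s] <- sum(w * em$values[nn, s]) / sum(w)
    }
  }
  expression_matrix(v, em$classes, em$class_levels)
}

#' Two-sample t-test on a single gene's class values
#'
#' Pooled-variance (Student) two-sample t by default, the form used for the
#' per-gene differential-expression filter; Welch's unequal-variance
#' variant is available via \code{var_equal = FALSE}.  Degenerate
#' zero-variance input follows a documented convention: equal means give
#' p = 1, unequal means give p = 0.
#'
#' @param x,y Numeric vectors (observed values in each class; >= 2 each).
#' @param var_equal Pooled variance (TRUE, default) or Welch.
#' @return List with \code{statistic} and \code{p_value} (two-sided).
#' @export
gene_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 observed values per class")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0 || !is.finite(se)) {
    if (isTRUE(all.equal(m1, m2)))
      return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(m1 - m2) * Inf, p_value = 0))
  }
  t <- (m1 - m2) / se
  list(statistic = t, p_value = 2 * pt(-abs(t), df))
}

#' Per-gene two-class t-test p-values
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param var_equal Passed to \code{\link{gene_t_test}}.
#' @return Named numeric vector of two-sided p-values, one per gene.
#' @export
gene_t_pvalues <- function(em, var_equal = TRUE) {
  loc <- loc_samples(em); met <- met_samples(em)
  vapply(rownames(em$values), function(g)
    gene_t_test(em$values[g, loc], em$values[g, met],
                var_equal = var_equal)$p_value,
    numeric(1L))
}

#' Variable-gene filter (fold change in enough samples plus t-test)
#'
#' Retains genes whose absolute log2 ratio reaches \code{log2(fold_min)} in
#' at least \code{min_samples} samples and whose two-class t-test p-value
#' is at most \code{p_max}.  Expression values are log2 ratios against the
#' array reference, so fold change is taken as |log2 ratio| against that
#' reference.
#'
#' @param em An imputed \code{\link{expression_matrix}}.
#' @param fold_min Minimum fold change (default 6).
#' @param min_samples Minimum number of samples reaching it (default 4).
#' @param p_max Maximum t-test p-value (default 0.001).
#' @return Character vector of retained gene ids, input order preserved.
#' @export
filter_variable_genes <- function(em, fold_min = 6, min_samples = 4L,
                                  p_max = 0.001) {
  stopifnot(inherits(em, "expression_matrix"))
  if (anyNA(em$values)) stop("matrix must be imputed first")
  thr <- log2(fold_min)
  n_big <- rowSums(abs(em$values) >= thr)
  p <- gene_t_pvalues(em)
  rownames(em$values)[n_big >= min_samples & p <= p_max]
}
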