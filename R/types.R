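#' @importFrom stats rnorm rnbinom qnbinom median sd cor pt dhyper phyper
#' @importFrom utils head modifyList
NULL

CLASS_LEVELS <- c("localized", "metastatic")

#' Construct a two-class expression matrix
#'
#' The central data container: a genes x samples matrix of log2 expression
#' ratios together with a sample -> class assignment.  Classes are the two
#' phenotype groups being contrasted (by convention \code{"localized"} and
#' \code{"metastatic"}).
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).  \code{NA} entries denote missing measurements.
#' @param classes Named character vector mapping every sample id to one of
#'   the two class labels.
#' @param class_levels Length-2 character vector of admissible class labels;
#'   the first is treated as the reference ("localized") class.
#' @return An object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(values, classes, class_levels = CLASS_LEVELS) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (length(class_levels) != 2L)
    stop("exactly two class levels required")
  missing_lab <- setdiff(colnames(values), names(classes))
  if (length(missing_lab))
    stop("no class label for sample(s): ", paste(missing_lab, collapse = ", "))
  classes <- classes[colnames(values)]
  bad <- setdiff(unique(classes), class_levels)
  if (length(bad))
    stop("unknown class token(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(class_levels, collapse = "/"), ")")
  if (!all(class_levels %in% classes))
    stop("both classes must be represented among the samples")
  structure(
    list(values = values, classes = classes, class_levels = class_levels),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(factor(x$classes, levels = x$class_levels))
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  nm <- sum(is.na(x$values))
  if (nm) cat(sprintf("  %d missing entries (%.2f%%)\n", nm,
                      100 * nm / length(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# sample ids of the reference / non-reference class
samples_of <- function(em, level) names(em$classes)[em$classes == level]
loc_samples <- function(em) samples_of(em, em$class_levels[1L])
met_samples <- function(em) samples_of(em, em$class_levels[2L])

#' Construct an interaction network
#'
#' An undirected simple graph over gene identifiers.  Self-loops are
#' dropped and duplicate / reversed edges are collapsed; edges are stored
#' canonically (lexicographically smaller endpoint first) and sorted.
#'
#' @param edges Two-column character matrix or data.frame of gene pairs.
#' @param nodes Optional character vector of node ids; defaults to the ids
#'   appearing in \code{edges}.  Extra isolated nodes are allowed.
#' @return An object of class \code{"interaction_network"} with elements
#'   \code{nodes} (character) and \code{edges} (two-column data.frame).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  loops <- edges$from == edges$to
  n_loops <- sum(loops)
  if (n_loops) {
    message(n_loops, " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(from = a[keep], to = b[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  structure(list(nodes = all_nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges (median degree %g)\n",
              length(x$nodes), nrow(x$edges),
              if (length(x$nodes)) median(network_degrees(x)) else 0))
  invisible(x)
}

#' Node degrees of an interaction network
#'
#' @param network An \code{interaction_network}.
#' @return Named integer vector of degrees, one entry per node (0 for
#'   isolated nodes).
#' @export
network_degrees <- function(network) {
  d <- table(factor(c(network$edges$from, network$edges$to),
                    levels = network$nodes))
  stats::setNames(as.integer(d), names(d))
}

# adjacency as a named list of neighbor character vectors
neighbor_list <- function(network) {
  nb <- split(c(network$edges$to, network$edges$from),
              factor(c(network$edges$from, network$edges$to),
                     levels = network$nodes))
  lapply(nb, function(v) sort(unique(v)))
}

#' Construct a hub network
#'
#' The unit of analysis: one central gene (the hub) plus its direct
#' interactors.
#'
#' @param hub Gene id of the central node.
#' @param interactors Character vector of the hub's direct interactors.
#' @return Object of class \code{"hub_network"} with \code{hub},
#'   \code{interactors}, and \code{members} (hub first, then sorted
#'   interactors).
#' @export
hub_network <- function(hub, interactors) {
  interactors <- sort(unique(setdiff(as.character(interactors), hub)))
  if (!length(interactors)) stop("hub '", hub, "' has no interactors")
  structure(list(hub = as.character(hub), interactors = interactors,
                 members = c(hub, interactors)),
            class = "hub_network")
}

#' @export
print.hub_network <- function(x, ...) {
  cat(sprintf("hub_network %s: %d interactors\n", x$hub,
              length(x$interactors)))
  invisible(x)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Stable 31-bit seed derived from a master seed and arbitrary string keys,
# so per-hub permutation streams do not depend on iteration order.
derive_seed <- function(seed, ...) {
  keys <- paste(c(...), collapse = "\r")
  h <- 0
  for (cc in utf8ToInt(keys)) h <- (h * 131 + cc) %% 1987654321
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587 + 1)
}
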