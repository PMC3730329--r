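#' Default cellular-process proportions for the annotation generator
#'
#' Proportions of the simplified GO-Slim processes among the 5,855 hub
#' networks of the osteosarcoma study that motivated this package (full
#' network annotation counts), normalized to sum to one.  Used as the
#' default \code{process_labels} of \code{\link{sim_config}}.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_process_proportions <- function() {
  counts <- c(
    "protein modification" = 573, "transport" = 1002, "signaling" = 954,
    "transcription" = 595, "stress" = 247, "metabolism" = 1340,
    "cell cycle" = 65, "reproduction" = 130,
    "intracellular organization" = 195, "development" = 338,
    "translation" = 146, "death" = 31, "cytoskeleton" = 57,
    "ion transport" = 10, "proliferation" = 3, "homeostasis" = 2,
    "differentiation" = 6, "NaN" = 161)
  counts / sum(counts)
}

#' Configuration for the synthetic two-class cohort generator
#'
#' Describes a synthetic study: an interaction network with hub-like degree
#' structure, a two-class expression cohort (defaults mirror the
#' 46 localized + 17 metastatic osteosarcoma design), optional planted
#' differential-activity modules (mean shift in the metastatic class) and
#' planted differential-organization hubs (hub-interactor correlation
#' rewired between classes), and per-gene process annotations.
#'
#' @param n_genes Number of genes (network nodes).
#' @param n_localized,n_metastatic Samples per class (defaults 46 / 17).
#' @param degree_law Degree distribution spec, a list with element
#'   \code{dist}: \code{"nbinom"} (shifted negative binomial truncated at 1,
#'   tuned so the median equals \code{target_median}; \code{size} controls
#'   tail heaviness), \code{"star"} (one hub of degree n-1), or
#'   \code{"fixed"} (explicit \code{degrees} vector).
#' @param noise_sd Standard deviation of the background log2-ratio noise.
#' @param missing_rate Fraction of entries set missing completely at random.
#' @param n_active_hubs Number of planted differentially activated hubs.
#' @param activity_shift Mean shift (log2 units) added to metastatic-class
#'   values of shifted genes in planted active modules.
#' @param active_fraction Fraction of each planted module's members that
#'   receive the shift.
#' @param n_rewired_hubs Number of planted differentially organized hubs.
#' @param rho_localized,rho_metastatic Target hub-interactor correlation of
#'   rewired hubs in each class (|rho| < 1).
#' @param process_labels Named vector of process proportions (must sum to 1).
#' @param seed Master RNG seed; all generator randomness derives from it.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 500,
                       n_localized = 46,
                       n_metastatic = 17,
                       degree_law = list(dist = "nbinom", size = 1.5,
                                         target_median = 6),
                       noise_sd = 1.0,
                       missing_rate = 0,
                       n_active_hubs = 0,
                       activity_shift = 0,
                       active_fraction = 1,
                       n_rewired_hubs = 0,
                       rho_localized = 0.7,
                       rho_metastatic = 0,
                       process_labels = default_process_proportions(),
                       seed = 1L) {
  stopifnot(n_genes >= 10, n_localized >= 2, n_metastatic >= 2,
            noise_sd > 0, missing_rate >= 0, missing_rate < 1,
            n_active_hubs >= 0, n_rewired_hubs >= 0,
            active_fraction >= 0, active_fraction <= 1,
            abs(rho_localized) < 1, abs(rho_metastatic) < 1)
  if (!is.list(degree_law) || is.null(degree_law$dist))
    stop("'degree_law' must be a list with a 'dist' element")
  if (identical(degree_law$dist, "fixed")) {
    if (is.null(degree_law$degrees) || all(degree_law$degrees <= 0))
      stop("degenerate degree law: no positive degrees")
  }
  if (is.null(names(process_labels)) || !length(process_labels))
    stop("'process_labels' must be a nonempty named vector")
  if (abs(sum(process_labels) - 1) > 1e-6)
    stop("process proportions must sum to 1")
  structure(list(
    n_genes = as.integer(n_genes), n_localized = as.integer(n_localized),
    n_metastatic = as.integer(n_metastatic), degree_law = degree_law,
    noise_sd = noise_sd, missing_rate = missing_rate,
    n_active_hubs = as.integer(n_active_hubs),
    activity_shift = activity_shift, active_fraction = active_fraction,
    n_rewired_hubs = as.integer(n_rewired_hubs),
    rho_localized = rho_localized, rho_metastatic = rho_metastatic,
    process_labels = process_labels, seed = as.integer(seed)),
    class = "sim_config")
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# mu of the shifted truncated negative binomial whose median is the target.
# qnbinom is a step function of mu; take the midpoint of the mu interval
# on which the median is exact, deterministically.
nbinom_mu_for_median <- function(size, target_median) {
  want <- target_median - 1L        # median of the un-shifted NB part
  f <- function(mu) qnbinom(0.5, size = size, mu = mu)
  lo <- 0.01; hi <- 1000
  if (f(hi) < want) stop("target median unreachable")
  for (i in 1:60) { mid <- (lo + hi) / 2; if (f(mid) < want) lo <- mid else hi <- mid }
  lower <- hi
  lo <- lower; hi <- 2000
  for (i in 1:60) { mid <- (lo + hi) / 2; if (f(mid) <= want) lo <- mid else hi <- mid }
  (lower + lo) / 2
}

sample_degrees <- function(config) {
  law <- config$degree_law
  n <- config$n_genes
  switch(law$dist,
    nbinom = {
      size <- if (is.null(law$size)) 1.5 else law$size
      tm <- if (is.null(law$target_median)) 6L else law$target_median
      mu <- nbinom_mu_for_median(size, tm)
      pmin(1L + rnbinom(n, size = size, mu = mu), n - 1L)
    },
    star = c(n - 1L, rep(1L, n - 1L)),
    fixed = {
      d <- rep_len(as.integer(law$degrees), n)
      if (all(d <= 0)) stop("degenerate degree law: no positive degrees")
      pmin(pmax(d, 0L), n - 1L)
    },
    stop("unknown degree law '", law$dist, "'"))
}

#' Generate a synthetic hub-like interaction network
#'
#' Draws a target degree per gene from the configured degree law and
#' realizes an undirected simple graph by random stub pairing
#' (configuration model); self-loops and duplicate edges are discarded.
#' The default shifted negative-binomial law is tuned so the median degree
#' is 6 with a heavy right tail, emulating the hub structure of curated
#' interaction databases.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An \code{\link{interaction_network}}; deterministic given
#'   \code{config$seed}.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- gene_ids(config$n_genes)
  with_seed(derive_seed(config$seed, "network"), {
    if (identical(config$degree_law$dist, "star")) {
      edges <- cbind(ids[1L], ids[-1L])
      return(interaction_network(edges, nodes = ids))
    }
    d <- sample_degrees(config)
    if (sum(d) %% 2L == 1L) d[1L] <- d[1L] + 1L
    stubs <- rep.int(seq_along(ids), d)
    stubs <- stubs[sample.int(length(stubs))]
    half <- length(stubs) %/% 2L
    edges <- cbind(ids[stubs[seq_len(half)]],
                   ids[stubs[half + seq_len(half)]])
    suppressMessages(interaction_network(edges, nodes = ids))
  })
}

#' Generate a two-class expression cohort with planted effects
#'
#' Background genes are i.i.d. Normal(0, \code{noise_sd^2}) in both classes.
#' Planted active modules receive \code{activity_shift} added to the
#' metastatic-class values of a fraction \code{active_fraction} of their
#' members.  Planted rewired hubs use a shared latent factor per hub:
#' interactor = rho * hub-latent + sqrt(1 - rho^2) * noise, with the class's
#' target rho, so the population hub-interactor correlation is exact.
#' Missing entries (if any) are inserted completely at random.  Class labels
#' are assigned to shuffled sample ids, never encoded in column order.
#'
#' @param network An \code{\link{interaction_network}} (typically from
#'   \code{\link{generate_network}}).
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{matrix} (an \code{\link{expression_matrix}}) and
#'   \code{truth}: \code{active_hub_ids}, \code{rewired_hub_ids},
#'   \code{gene_shift} (named vector, nonzero entries only) and
#'   \code{hub_rho} (data.frame hub / rho_localized / rho_metastatic).
#' @export
generate_expression <- function(network, config) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(config, "sim_config"))
  genes <- network$nodes
  ns <- config$n_localized + config$n_metastatic
  deg <- network_degrees(network)
  eligible <- names(deg)[deg >= 1L]
  if (config$n_active_hubs + config$n_rewired_hubs > length(eligible))
    stop("not enough connected hubs to plant the requested effects")
  nb <- neighbor_list(network)

  with_seed(derive_seed(config$seed, "expression"), {
    sample_ids <- sprintf("S%03d", seq_len(ns))
    classes <- stats::setNames(
      sample(rep(CLASS_LEVELS, c(config$n_localized, config$n_metastatic))),
      sample_ids)
    loc <- names(classes)[classes == "localized"]
    met <- names(classes)[classes == "metastatic"]

    vals <- matrix(rnorm(length(genes) * ns, sd = config$noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, sample_ids))

    # rewired hubs are chosen with pairwise-disjoint closed neighbourhoods
    # so one hub's latent-factor construction cannot overwrite another's
    rewired_hubs <- character(0)
    claimed <- character(0)
    for (cand in sample(eligible)) {
      if (length(rewired_hubs) == config$n_rewired_hubs) break
      closed <- c(cand, nb[[cand]])
      if (!length(intersect(closed, claimed))) {
        rewired_hubs <- c(rewired_hubs, cand)
        claimed <- c(claimed, closed)
      }
    }
    if (length(rewired_hubs) < config$n_rewired_hubs)
      stop("cannot place ", config$n_rewired_hubs,
           " rewired hubs with disjoint neighbourhoods")
    rewired_hubs <- sort(rewired_hubs)
    active_hubs <- sort(sample(setdiff(eligible, rewired_hubs),
                               config$n_active_hubs))

    # correlation rewiring first; the later mean shift leaves PCC unchanged
    rho <- c(localized = config$rho_localized,
             metastatic = config$rho_metastatic)
    for (h in rewired_hubs) {
      z <- rnorm(ns)
      vals[h, ] <- config$noise_sd * z
      for (g in nb[[h]]) {
        e <- rnorm(ns)
        for (cl in CLASS_LEVELS) {
          idx <- if (cl == "localized") loc else met
          vals[g, idx] <- config$noise_sd *
            (rho[[cl]] * z[match(idx, sample_ids)] +
               sqrt(1 - rho[[cl]]^2) * e[match(idx, sample_ids)])
        }
      }
    }

    gene_shift <- numeric(0)
    for (h in active_hubs) {
      members <- c(h, nb[[h]])
      k <- max(1L, round(config$active_fraction * length(members)))
      shifted <- sample(members, k)
      vals[shifted, met] <- vals[shifted, met] + config$activity_shift
      gene_shift[shifted] <- config$activity_shift
    }

    if (config$missing_rate > 0) {
      holes <- which(stats::runif(length(vals)) < config$missing_rate)
      vals[holes] <- NA_real_
    }

    truth <- list(
      active_hub_ids = active_hubs,
      rewired_hub_ids = rewired_hubs,
      gene_shift = gene_shift,
      hub_rho = data.frame(
        hub = rewired_hubs,
        rho_localized = rep(config$rho_localized,
                            length(rewired_hubs)),
        rho_metastatic = rep(config$rho_metastatic,
                             length(rewired_hubs)),
        stringsAsFactors = FALSE))
    list(matrix = expression_matrix(vals, classes), truth = truth)
  })
}

#' Generate per-gene process annotations
#'
#' Assigns every network gene exactly one simplified process term, drawn
#' independently from the configured process proportions.
#'
#' @param network An \code{\link{interaction_network}}.
#' @param config A \code{\link{sim_config}}.
#' @return Named character vector gene id -> term.
#' @export
generate_annotations <- function(network, config) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(config, "sim_config"))
  p <- config$process_labels
  if (!length(p)) stop("empty process list")
  with_seed(derive_seed(config$seed, "annotations"), {
    stats::setNames(
      sample(names(p), length(network$nodes), replace = TRUE, prob = p),
      network$nodes)
  })
}

#' Generate a full synthetic study (network, cohort, annotations)
#'
#' Convenience wrapper running \code{\link{generate_network}},
#' \code{\link{generate_expression}} and \code{\link{generate_annotations}}
#' and optionally writing the standard file set: expression TSV, sample
#' label TSV, network SIF and two-column adjacency TSV, annotation TSV and
#' a ground-truth JSON.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Optional directory; created if needed.
#' @return List with \code{network}, \code{matrix}, \code{truth},
#'   \code{annotations}.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  network <- generate_network(config)
  expr <- generate_expression(network, config)
  ann <- generate_annotations(network, config)
  res <- list(network = network, matrix = expr$matrix, truth = expr$truth,
              annotations = ann)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(res$matrix,
                     file.path(out_dir, "expression.tsv"),
                     file.path(out_dir, "labels.tsv"))
    write_network(network, file.path(out_dir, "network.sif"), "sif")
    write_network(network, file.path(out_dir, "network_adjacency.tsv"),
                  "adjacency")
    write_annotations(ann, file.path(out_dir, "annotations.tsv"))
    jsonlite::write_json(
      res$truth, file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  res
}
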