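# hand-built result objects small enough to evaluate by eye
fake_activity <- function() {
  best <- data.frame(
    hub = c("h1", "h2", "h3", "h4", "h5"),
    trial = 1L, subset_size = 5L,
    nas = c(2.0, 1.7, 1.0, 3.0, 1.66),
    p_sample = c(0, 0.02, 0.2, 0.04, 0.005),
    p_gene = c(0.01, 0.03, 0.5, 0.04, 0.009),
    fdr_sample = c(0.01, 0.15, 0.9, 0.25, 0.05),
    fdr_gene = c(0.02, 0.18, 1.2, 0.1, 0.08),
    significant = TRUE, stringsAsFactors = FALSE)
  hubs <- list(
    h1 = hub_network("h1", c("q1", "x1")),
    h2 = hub_network("h2", c("q1", "x2")),
    h3 = hub_network("h3", "x3"),
    h4 = hub_network("h4", "x4"),
    h5 = hub_network("h5", c("x5", "x6")))
  structure(list(best = best, per_trial = best, hubs = hubs,
                 subsets = lapply(hubs, `[[`, "members"),
                 trials_run = 1L, n_perm = 1000L, seed = 1L),
            class = "activity_analysis")
}

fake_organization <- function() {
  tab <- data.frame(
    hub = c("o1", "o2", "o3", "h1"),
    degree = c(8L, 3L, 9L, 2L),
    avg_delta_pcc = c(-0.45, 0.41, 0.2, -0.5),
    p_sample = c(0, 0.001, 0, 0.002), stringsAsFactors = FALSE)
  structure(list(table = tab, edges = NULL, n_perm = 1000L, seed = 1L),
            class = "organization_analysis")
}

test_that("packaged policies match their stated thresholds", {
  p <- cutoff_policy("permissive")
  expect_equal(p$activated[c("p_max_sample", "fdr_max_sample")],
               list(p_max_sample = 0.05, fdr_max_sample = 0.2))
  expect_equal(p$organized$p_max, 0.001)
  s <- cutoff_policy("stringent")
  expect_equal(s$activated$nas_min, 1.65)
  expect_equal(s$organized,
               list(p_max = 0, abs_avg_delta_pcc_min = 0.4,
                    min_interactors = 7))
  c <- cutoff_policy("custom", activated = list(nas_min = 2))
  expect_equal(c$activated$nas_min, 2)
  expect_error(cutoff_policy("custom", organized = list(p_max = -1)),
               "non-negative")
})

test_that("cut-offs are conjunctive and match hand evaluation", {
  act <- fake_activity(); org <- fake_organization()
  sig <- suppressMessages(
    apply_cutoffs(act, org, cutoff_policy("permissive")))
  # h1: all pass. h2: all pass. h3: p_sample 0.2 fails. h4: fdr_sample
  # 0.25 fails. h5: all pass.
  expect_setequal(sig$activated, c("h1", "h2", "h5"))
  # organized permissive: p <= 0.001 -> o1, o2, o3
  expect_setequal(sig$organized, c("o1", "o2", "o3"))

  sigv <- suppressMessages(
    apply_cutoffs(act, org, cutoff_policy("visualization")))
  # adds FDR <= 0.1, NAS >= 1.65: h1 (0.01/0.02, 2.0), h5 (0.05/0.08, 1.66)
  expect_setequal(sigv$activated, c("h1", "h5"))
  # organized adds |dPCC| >= 0.4: o1, o2
  expect_setequal(sigv$organized, c("o1", "o2"))

  sigs <- suppressMessages(
    apply_cutoffs(act, org, cutoff_policy("stringent")))
  # p = 0 exactly for organized, degree >= 7: o1 only (o2 p = 0.001)
  expect_setequal(sigs$organized, "o1")
  # activated: p <= 0.01 both, FDR <= 0.1, NAS >= 1.65 -> h1, h5
  expect_setequal(sigs$activated, c("h1", "h5"))

  # nesting across presets
  expect_true(all(sigs$activated %in% sigv$activated))
  expect_true(all(sigv$activated %in% sig$activated))
  expect_true(all(sigs$organized %in% sigv$organized))
  expect_true(all(sigv$organized %in% sig$organized))

  # vacuous thresholds keep everything
  all_pol <- cutoff_policy("custom",
    activated = list(p_max_sample = 1, p_max_gene = 1, fdr_max_sample = 99,
                     fdr_max_gene = 99, nas_min = 0),
    organized = list(p_max = 1, abs_avg_delta_pcc_min = 0,
                     min_interactors = 0))
  siga <- suppressMessages(apply_cutoffs(act, org, all_pol))
  expect_setequal(siga$activated, act$best$hub)
  expect_setequal(siga$organized, org$table$hub)
})

test_that("query lookup reports all containing networks and absences", {
  act <- fake_activity(); org <- fake_organization()
  sig <- list(activated = c("h1", "h2", "h5"), organized = c("o1"))
  res <- suppressMessages(
    query_gene_lookup(act, org, sig, c("q1", "h1", "zz")))
  # q1 sits in two significant activated hubs -> two rows
  expect_equal(sort(res$activated$node[res$activated$query == "q1"]),
               c("h1", "h2"))
  # a hub queried by itself: Query == Node
  self <- res$activated[res$activated$query == "h1", ]
  expect_equal(self$node, "h1")
  expect_equal(self$score, 2.0)
  expect_equal(res$absent, "zz")
  # organized arm: h1 the gene is not in o1's members (o1 not in hubs) ->
  # no organized rows here
  expect_equal(nrow(res$organized), 0L)
})

test_that("graph export filters edges and round-trips the SIF", {
  # one hub, two interactors; only one edge correlation-significant
  set.seed(9)
  ns <- 40
  z <- rnorm(ns)
  v <- rbind(hub = z,
             good = z + rnorm(ns, sd = 0.1),   # strongly correlated
             bad = rnorm(ns))                  # uncorrelated
  colnames(v) <- sprintf("S%02d", 1:ns)
  cl <- stats::setNames(rep(c("localized", "metastatic"), each = ns / 2),
                        colnames(v))
  em <- expression_matrix(v, cl)
  hubs <- list(hub = hub_network("hub", c("good", "bad")))
  org <- suppressWarnings(
    run_organization_analysis(em, hubs, n_perm = 20, seed = 1))
  sig <- list(activated = character(0), organized = "hub")
  dir <- withr::local_tempdir()
  out <- export_graph(sig, org, em, dir, node_p_max = Inf)
  expect_equal(nrow(out$edges), 1L)
  expect_equal(out$edges$interactor, "good")
  expect_true(all(file.exists(unlist(out$paths))))
  # SIF re-read reproduces the exported topology
  net <- read_network(out$paths$sif, "sif")
  expect_setequal(paste(net$edges$from, net$edges$to),
                  paste(pmin(out$edges$hub, out$edges$interactor),
                        pmax(out$edges$hub, out$edges$interactor)))
  # node attributes carry fold change and sizing fields
  expect_true(all(c("gene", "log2_fold_change", "pct_fold_change", "t_p",
                    "interactor_count") %in% names(out$nodes)))
  # empty significant set errors
  expect_error(export_graph(list(activated = character(0),
                                 organized = character(0)), org, em, dir),
               "empty")
})
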