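# independent brute-force implementations used as oracles --------------------

brute_cds <- function(vals, loc_cols, met_cols) {
  # direct textbook computation, no shared code with the package internals
  apply(vals, 1L, function(x)
    (median(x[met_cols]) - median(x[loc_cols])) / sd(x[loc_cols]))
}

brute_nas <- function(vals, loc_cols, met_cols) {
  mean(abs(brute_cds(vals, loc_cols, met_cols)))
}

test_that("class difference score matches hand computation", {
  em <- tiny_em()
  expect_equal(class_difference_score(em$values["gA", ], em$classes), 3.0)
  expect_equal(class_difference_score(em$values["gB", ], em$classes), 0)
  expect_equal(class_difference_score(em$values["gC", ], em$classes), -3.0)
  # sign flips when class labels are swapped
  swapped <- stats::setNames(
    ifelse(em$classes == "localized", "metastatic", "localized"),
    names(em$classes))
  expect_equal(sign(class_difference_score(em$values["gA", ], swapped)), -1)
  const <- stats::setNames(rep(1, 6), paste0("S", 1:6))
  expect_error(class_difference_score(const, em$classes), "zero standard")
})

test_that("network activity score is the mean absolute CDS", {
  expect_equal(network_activity_score(c(2, -1, 3)), 2)
  expect_equal(network_activity_score(5), 5)
  expect_equal(network_activity_score(c(0, 0)), 0)
  expect_error(network_activity_score(numeric(0)), "empty")
  expect_warning(out <- network_activity_score(c(1, NA)), "dropped")
  expect_equal(out, 1)
})

test_that("subset selection follows the trial cut-offs", {
  set.seed(42)
  n <- 8
  v <- matrix(rnorm(6 * n, sd = 0.1), 6, n,
              dimnames = list(paste0("g", 1:6), paste0("S", 1:n)))
  # g1: medians 1.0 vs 1.6 on the ratio scale -> 60% difference
  v["g1", ] <- c(rep(0, 4), rep(log2(1.6), 4)) + rnorm(n, sd = 1e-3)
  cl <- stats::setNames(rep(c("localized", "metastatic"), each = 4),
                        colnames(v))
  em <- expression_matrix(v, cl)
  hub <- hub_network("g1", paste0("g", 2:6))
  ladder <- default_trial_ladder()

  expect_setequal(select_subset(hub, em, ladder[1L, ]), hub$members)
  sub50 <- select_subset(hub, em, list(trial = 99, min_diff_pct = 50,
                                       p_max = NA))
  expect_true("g1" %in% sub50)
  sub70 <- select_subset(hub, em, list(trial = 99, min_diff_pct = 70,
                                       p_max = NA))
  expect_false("g1" %in% sub70)
  # p cut-off excludes genes with weak class difference
  gp <- gene_t_pvalues(em)
  subp <- select_subset(hub, em, ladder[2L, ])
  expect_setequal(subp, hub$members[gp[hub$members] <= 0.001])

  # monotonicity: raising the percent threshold never enlarges the subset
  for (seed in 1:5) {
    emr <- random_em(n_genes = 10, seed = seed)
    hubr <- hub_network("g01", rownames(emr$values)[-1])
    prev <- select_subset(hubr, emr, list(trial = 0, min_diff_pct = 0,
                                          p_max = NA))
    for (pct in c(10, 30, 50, 70)) {
      cur <- select_subset(hubr, emr, list(trial = 0, min_diff_pct = pct,
                                           p_max = NA))
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("null score p-values follow the self-inclusive rank rule", {
  expect_equal(null_pvalues(c(1, 2, 3)), c(1, 2 / 3, 1 / 3))
  expect_equal(null_pvalues(rep(5, 4)), rep(1, 4))
  expect_equal(min(null_pvalues(rnorm(100))), 1 / 100)
})

test_that("permutation p-values match exhaustive brute-force enumeration", {
  em <- random_em(n_genes = 5, n_loc = 4, n_met = 4, seed = 8)
  hub <- hub_network("g01", c("g02", "g03", "g04"))
  assigns <- all_assignments(8, 4)
  res <- permutation_pvalues(hub, em, loc_assignments = assigns)

  loc <- match(names(em$classes)[em$classes == "localized"],
               colnames(em$values))
  met <- setdiff(seq_len(8), loc)
  vals <- em$values[hub$members, ]
  expect_equal(res$nas, brute_nas(vals, loc, met), tolerance = 1e-12)
  null_ref <- vapply(assigns, function(idx)
    brute_nas(vals, idx, setdiff(1:8, idx)), numeric(1L))
  expect_equal(res$null_nas_sample, null_ref, tolerance = 1e-12)
  expect_equal(res$p_sample, mean(null_ref >= res$nas), tolerance = 1e-12)

  # granularity and determinism of the sampled path
  r1 <- permutation_pvalues(hub, em, n_perm = 50, seed = 3)
  r2 <- permutation_pvalues(hub, em, n_perm = 50, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(abs(r1$p_sample * 50 - round(r1$p_sample * 50)) < 1e-9))
  expect_true(all(abs(r1$p_gene * 50 - round(r1$p_gene * 50)) < 1e-9))
})

test_that("an observed NAS of zero gives p = 1", {
  # met values equal the loc values gene-wise: all medians agree, CDS = 0
  v <- rbind(g1 = c(1, 2, 3, 1, 2, 3), g2 = c(4, 6, 8, 4, 6, 8),
             g3 = c(0, 1, 2, 0, 1, 2))
  colnames(v) <- paste0("S", 1:6)
  cl <- stats::setNames(rep(c("localized", "metastatic"), each = 3),
                        colnames(v))
  em <- expression_matrix(v, cl)
  hub <- hub_network("g1", c("g2", "g3"))
  res <- permutation_pvalues(hub, em, n_perm = 25, seed = 2)
  expect_equal(res$nas, 0)
  expect_equal(res$p_sample, 1)
})

test_that("NAS is invariant under a global sign flip of the matrix", {
  em <- random_em(n_genes = 6, seed = 13)
  hub <- hub_network("g01", rownames(em$values)[-1])
  flipped <- expression_matrix(-em$values, em$classes)
  a <- permutation_pvalues(hub, em, n_perm = 10, seed = 1)
  b <- permutation_pvalues(hub, flipped, n_perm = 10, seed = 1)
  expect_equal(a$nas, b$nas, tolerance = 1e-12)
})

test_that("empirical FDR matches a tiny hand-counted instance", {
  # 3 real networks with p {0, 0.5, 1}; each contributes 4 null p's
  real_p <- c(0, 0.5, 1)
  nulls <- list(c(0.25, 0.5, 0.75, 1),
                c(0.25, 0.25, 1, 1),
                c(0.5, 0.5, 0.75, 1))
  # brute-force count for each network
  pool <- unlist(nulls)
  expected <- vapply(real_p, function(p)
    (sum(pool <= p) / 4) / sum(real_p <= p), numeric(1L))
  expect_equal(empirical_fdr(real_p, nulls), expected)
  # a network below every null p has FDR 0
  expect_equal(empirical_fdr(real_p, nulls)[1L], 0)
  # matrix input agrees with list input
  expect_equal(empirical_fdr(real_p, do.call(rbind, nulls)),
               expected)
  expect_error(empirical_fdr(real_p, list(1:4 / 4, 1:3 / 3, 1:4 / 4)),
               "same number")
})

test_that("activity analysis recovers a planted module and consolidates", {
  cfg <- sim_config(n_genes = 100, n_active_hubs = 2, activity_shift = 2.5,
                    active_fraction = 1, seed = 21)
  sim <- simulate_cohort(cfg)
  em <- sim$matrix
  ix <- suppressMessages(intersect_with_expression(sim$network, em))
  act <- suppressMessages(
    run_activity_analysis(em, ix$hubs, n_perm = 60, seed = 5))
  expect_s3_class(act, "activity_analysis")
  # one consolidated row per scorable hub; best row exists in per_trial
  expect_false(any(duplicated(act$best$hub)))
  expect_true(all(act$best$p_sample %in% ((0:60) / 60)))
  # planted hubs rank above the typical network on the all-genes trial
  # (later trials keep only each hub's most extreme genes, which inflates
  # the NAS of null hubs, so recovery is judged on trial 1)
  t1 <- act$per_trial[act$per_trial$trial == 1L, ]
  planted <- t1$hub %in% sim$truth$active_hub_ids
  expect_equal(sum(planted), 2L)
  expect_gt(min(t1$nas[planted]), median(t1$nas))

  # degenerate single-trial ladder: output is that trial's scores
  one <- suppressMessages(
    run_activity_analysis(em, ix$hubs, trials = default_trial_ladder()[1L, ],
                          n_perm = 30, seed = 5))
  expect_true(all(one$best$trial == 1))
  expect_identical(one$best$hub, sort(names(ix$hubs)))
})
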