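# shared fixtures, all built in code

# hand-sized expression matrix: values chosen so class medians and sds are
# easy to compute by eye
tiny_em <- function() {
  v <- rbind(
    gA = c(1, 2, 3, 4, 5, 6),       # loc {1,2,3}, met {4,5,6}
    gB = c(1, 2, 3, 1, 2, 3),       # identical distributions
    gC = c(0, 1, 2, -3, -2, -1))    # met shifted by -3
  colnames(v) <- paste0("S", 1:6)
  cl <- stats::setNames(rep(c("localized", "metastatic"), each = 3),
                        colnames(v))
  expression_matrix(v, cl)
}

# small two-class matrix with named samples and a seeded random fill
random_em <- function(n_genes = 12, n_loc = 5, n_met = 4, seed = 1,
                      sd = 1) {
  set.seed(seed)
  ns <- n_loc + n_met
  v <- matrix(rnorm(n_genes * ns, sd = sd), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(ns))))
  cl <- stats::setNames(rep(c("localized", "metastatic"), c(n_loc, n_met)),
                        colnames(v))
  expression_matrix(v, cl)
}

# all localized-class column index sets of a cohort, for exhaustive
# permutation enumeration
all_assignments <- function(ns, n_loc) {
  asplit(utils::combn(ns, n_loc), 2L)
}

# area under the ROC curve of a score against binary truth (Wilcoxon form)
rank_auc <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

write_tsv_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
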