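# Bayes-factor scoring, essential calling, PR-AUC, gating, ECDF-AUC, skew.

make_ref_fc <- function(n_genes_per_class = 15, guides_per_gene = 4,
                        mu_e = -3, mu_n = 0, sd = 0.25, seed = 11) {
  set.seed(seed)
  ess <- paste0("ESS", seq_len(n_genes_per_class))
  non <- paste0("NON", seq_len(n_genes_per_class))
  genes <- c(rep(ess, each = guides_per_gene), rep(non, each = guides_per_gene))
  fc <- c(rnorm(n_genes_per_class * guides_per_gene, mu_e, sd),
          rnorm(n_genes_per_class * guides_per_gene, mu_n, sd))
  list(fc = tibble::tibble(sgrna = paste0("g", seq_along(genes)),
                           gene = genes, fc = fc),
       refs = reference_sets(ess, non))
}

test_that("separated reference distributions yield ordered, signed Bayes factors", {
  d <- make_ref_fc()
  extra <- tibble::tibble(
    sgrna = paste0("x", 1:8),
    gene = rep(c("STRONG", "HALF"), each = 4),
    fc = c(rep(-3, 4), rep(-1.5, 4)))
  fc <- dplyr::bind_rows(d$fc, extra)
  scores <- bayes_factor_scores(fc, d$refs, essentiality_config(n_bootstrap = 20, seed = 3))
  bf_strong <- scores$bf[scores$gene == "STRONG"]
  bf_half <- scores$bf[scores$gene == "HALF"]
  expect_gt(bf_strong, 0)
  expect_gt(bf_strong, bf_half)
  # direction agrees with the closed-form normal log-likelihood-ratio oracle
  oracle <- 4 * oracle_normal_llr(-3, -3, 0.25, 0, 0.25)
  expect_gt(oracle, 0)
  expect_equal(sign(bf_strong), sign(oracle))
})

test_that("identical reference distributions give near-zero Bayes factors", {
  set.seed(5)
  ess <- paste0("E", 1:12); non <- paste0("N", 1:12)
  half <- rnorm(48, 0, 1)
  # the nonessential guides carry exactly the same values as the essential
  # ones, so the two training distributions coincide
  fc <- tibble::tibble(sgrna = paste0("g", 1:96),
                       gene = c(rep(ess, each = 4), rep(non, each = 4)),
                       fc = c(half, half))
  scores <- bayes_factor_scores(fc, reference_sets(ess, non),
                                essentiality_config(n_bootstrap = 30, seed = 2))
  # bootstrap/fold noise only: far below any decisive evidence level (BF 6)
  expect_lt(max(abs(scores$bf)), 3)
})

test_that("Bayes factors are invariant to guide row order and deterministic by seed", {
  d <- make_ref_fc(n_genes_per_class = 8)
  cfg <- essentiality_config(n_bootstrap = 10, seed = 9)
  s1 <- bayes_factor_scores(d$fc, d$refs, cfg)
  s2 <- bayes_factor_scores(d$fc[sample(nrow(d$fc)), ], d$refs, cfg)
  expect_equal(dplyr::arrange(s1, gene), dplyr::arrange(s2, gene))
})

test_that("BF weakly increases when a gene's guides are shifted toward depletion", {
  d <- make_ref_fc()
  extra <- tibble::tibble(sgrna = paste0("x", 1:4), gene = "T1", fc = rep(-1, 4))
  cfg <- essentiality_config(n_bootstrap = 15, seed = 4)
  bf0 <- bayes_factor_scores(dplyr::bind_rows(d$fc, extra), d$refs, cfg)
  shifted <- extra; shifted$fc <- shifted$fc - 1.5
  bf1 <- bayes_factor_scores(dplyr::bind_rows(d$fc, shifted), d$refs, cfg)
  expect_gte(bf1$bf[bf1$gene == "T1"], bf0$bf[bf0$gene == "T1"])
})

test_that("FDR-mode calling matches a brute-force threshold scan", {
  scores <- structure(tibble::tibble(
    gene = c(paste0("E", 1:6), paste0("N", 1:6), "X1", "X2"),
    bf = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0, -1, 6.5, 0.5),
    n_guides = 4L), class = c("gene_scores", "tbl_df", "tbl", "data.frame"))
  refs <- reference_sets(paste0("E", 1:6), paste0("N", 1:6))
  called <- call_essentials(scores, refs, mode = "fdr",
                            cfg = essentiality_config(fdr = 0.05))
  # perfect separation of refs: everything >= min essential-ref BF (5) is called
  expect_setequal(called, c(paste0("E", 1:6), "X1"))

  # strict inequality at the BF cutoff
  scores2 <- scores; scores2$bf[1] <- 6.0
  expect_false("E1" %in% call_essentials(scores2, mode = "bf",
                                         cfg = essentiality_config(bf_cut = 6)))
  expect_true("E2" %in% call_essentials(scores2, mode = "bf",
                                        cfg = essentiality_config(bf_cut = 6)))
})

test_that("all-equal scores are called all-or-none by pooled reference FDR", {
  refs <- reference_sets(paste0("E", 1:19), "N1")
  mk <- function(genes) structure(tibble::tibble(gene = genes, bf = 1, n_guides = 4L),
                                  class = c("gene_scores", "tbl_df", "tbl", "data.frame"))
  # pooled FDR 1/20 = 0.05 <= 0.05 -> everything called
  s <- mk(c(paste0("E", 1:19), "N1", "X"))
  expect_setequal(call_essentials(s, refs, mode = "fdr"),
                  c(paste0("E", 1:19), "N1", "X"))
  # pooled FDR 2/20 = 0.1 > 0.05 -> nothing
  refs2 <- reference_sets(paste0("E", 1:18), c("N1", "N2"))
  s2 <- mk(c(paste0("E", 1:18), "N1", "N2", "X"))
  expect_length(call_essentials(s2, refs2, mode = "fdr"), 0)
})

test_that("call set shrinks weakly as the FDR is tightened", {
  set.seed(21)
  refs <- reference_sets(paste0("E", 1:20), paste0("N", 1:20))
  scores <- structure(tibble::tibble(
    gene = c(paste0("E", 1:20), paste0("N", 1:20)),
    bf = c(rnorm(20, 4, 2), rnorm(20, 0, 2)), n_guides = 4L),
    class = c("gene_scores", "tbl_df", "tbl", "data.frame"))
  sizes <- vapply(c(0.3, 0.2, 0.1, 0.05, 0.01), function(f)
    length(call_essentials(scores, refs, mode = "fdr",
                           cfg = essentiality_config(fdr = f))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("PR-AUC matches the exhaustive oracle and has the forced boundary values", {
  mk_scores <- function(bf, genes) {
    structure(tibble::tibble(gene = genes, bf = bf, n_guides = 1L),
              class = c("gene_scores", "tbl_df", "tbl", "data.frame"))
  }
  refs <- reference_sets(paste0("E", 1:5), paste0("N", 1:5))
  genes <- c(paste0("E", 1:5), paste0("N", 1:5))
  # perfect separation
  expect_equal(precision_recall_auc(mk_scores(c(5:1, -1:-5), genes), refs), 1.0)
  # reversed separation: AUC <= prevalence
  rev_auc <- precision_recall_auc(mk_scores(c(-1:-5, 5:1), genes), refs)
  expect_lte(rev_auc, 0.5)
  expect_equal(rev_auc, oracle_pr_auc(c(-1:-5, 5:1), c(rep(TRUE, 5), rep(FALSE, 5))))
  # random instances agree exactly with the oracle, ties included
  set.seed(33)
  for (i in 1:10) {
    n <- 40
    bf <- sample(round(rnorm(n), 1))  # rounding forces ties
    is_pos <- rep(c(TRUE, FALSE), n / 2)
    g <- ifelse(is_pos, paste0("E", seq_len(n)), paste0("N", seq_len(n)))
    refs_i <- reference_sets(g[is_pos], g[!is_pos])
    expect_equal(precision_recall_auc(mk_scores(bf, g), refs_i),
                 oracle_pr_auc(bf, is_pos))
  }
  expect_error(precision_recall_auc(mk_scores(1:5, paste0("E", 1:5)), refs),
               "both reference classes")
})

test_that("random balanced scores give PR-AUC near the 0.5 prevalence", {
  set.seed(8)
  n <- 2000
  genes <- c(paste0("E", 1:(n / 2)), paste0("N", 1:(n / 2)))
  scores <- structure(tibble::tibble(gene = genes, bf = rnorm(n), n_guides = 1L),
                      class = c("gene_scores", "tbl_df", "tbl", "data.frame"))
  refs <- reference_sets(paste0("E", 1:(n / 2)), paste0("N", 1:(n / 2)))
  expect_equal(precision_recall_auc(scores, refs), 0.5, tolerance = 0.05)
})

test_that("the screen quality gate retains AUC >= 0.9 and excludes below", {
  qc <- tibble::tibble(screen = c("s1", "s2", "s3"),
                       pr_auc = c(0.95, 0.89, 0.90))
  gated <- screen_quality_gate(qc)
  expect_equal(gated$retained, c(TRUE, FALSE, TRUE))
})

test_that("ECDF-AUC hits its limits and mirror subsets sum to one", {
  set.seed(12)
  fc <- tibble::tibble(sgrna = paste0("g", 1:500), gene = "G",
                       fc = sort(rnorm(500)))
  expect_equal(ecdf_auc(fc, "g1"), 1, tolerance = 2e-3)    # global minimum
  expect_equal(ecdf_auc(fc, "g500"), 0, tolerance = 2e-3)  # global maximum
  expect_equal(ecdf_auc(fc, fc$sgrna), 0.5)                # whole library
  # the most depleted decile scores near 1
  expect_gt(ecdf_auc(fc, paste0("g", 1:50)), 0.9)
  m <- fc; m$fc <- -fc$fc
  expect_equal(ecdf_auc(fc, fc$sgrna) + ecdf_auc(m, m$sgrna), 1,
               tolerance = 1e-12)
  expect_error(ecdf_auc(dplyr::mutate(fc, fc = 1), "g1"), "constant")
  expect_error(ecdf_auc(fc, "nope"), "absent")
})

test_that("skew ratio uses linear-interpolation percentiles", {
  cm <- count_matrix(tibble::tibble(sgrna = paste0("g", 1:100),
                                    gene = "G", s1 = 1:100))
  expect_equal(skew_ratio(cm, "s1"), 90.1 / 10.9)
  cm2 <- count_matrix(tibble::tibble(sgrna = paste0("g", 1:10),
                                     gene = "G", s1 = rep(7L, 10)))
  expect_equal(skew_ratio(cm2, "s1"), 1.0)
  cm3 <- count_matrix(tibble::tibble(sgrna = paste0("g", 1:10),
                                     gene = "G", s1 = c(rep(0L, 5), rep(10L, 5))))
  expect_error(skew_ratio(cm3, "s1"), "undefined skew ratio")
})
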