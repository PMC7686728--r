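# Reference-set Bayes-factor essentiality scoring and screen quality metrics.
#
# The caller follows the BAGEL strategy: kernel-density estimates of the
# fold-change distributions of guides targeting core-essential and
# nonessential reference genes are trained per bootstrap round, and each
# guide's log2 likelihood ratio (essential vs nonessential) is summed per
# gene. Reference genes are scored with their own fold held out of training
# so they never score against themselves.

#' Configuration for essentiality calling
#'
#' @param fdr False discovery rate for `call_essentials(mode = "fdr")`
#'   (default 0.05).
#' @param bf_cut Bayes-factor cutoff, log2 units, for
#'   `call_essentials(mode = "bf")`; a gene is essential when BF is strictly
#'   greater (default 6).
#' @param n_bootstrap Bootstrap rounds over reference genes (default 100).
#' @param n_folds Leave-out folds for scoring reference genes (default 10).
#' @param min_pr_auc Minimum precision-recall AUC for a screen to be retained
#'   (default 0.9; screens strictly below are excluded).
#' @param density_floor Floor applied to kernel density values before taking
#'   logs (default 1e-12).
#' @param seed Integer seed controlling the bootstrap (default 1).
#' @return An `essentiality_config` list.
#' @export
essentiality_config <- function(fdr = 0.05, bf_cut = 6, n_bootstrap = 100L,
                                n_folds = 10L, min_pr_auc = 0.9,
                                density_floor = 1e-12, seed = 1L) {
  stopifnot(fdr > 0, fdr < 1, n_bootstrap >= 1, n_folds >= 2, density_floor > 0)
  structure(list(fdr = fdr, bf_cut = bf_cut, n_bootstrap = as.integer(n_bootstrap),
                 n_folds = as.integer(n_folds), min_pr_auc = min_pr_auc,
                 density_floor = density_floor, seed = as.integer(seed)),
            class = "essentiality_config")
}

# Gaussian KDE (Silverman bandwidth) evaluated at `at`, floored.
kde_log2 <- function(train, at, floor_val) {
  d <- density(train, bw = "nrd0", n = 512,
               from = min(c(train, at)) - 1, to = max(c(train, at)) + 1)
  y <- approx(d$x, d$y, xout = at, rule = 2)$y
  log2(pmax(y, floor_val))
}

#' Bayes-factor essentiality scores per gene
#'
#' For each bootstrap round, reference genes of each class are resampled with
#' replacement and a Gaussian kernel density is fit to the fold changes of
#' their guides. Every guide is scored as the log2 ratio of the essential to
#' the nonessential density at its fold change; guides of reference genes are
#' scored against densities trained without their own fold (k-fold leave-out).
#' A gene's Bayes factor is the mean over bootstrap rounds of the sum of its
#' guides' log ratios; positive values favour essentiality.
#'
#' @param fc A fold-change tibble (columns `sgrna`, `gene`, `fc`). Control
#'   guides are ignored for scoring.
#' @param refs A [reference_sets()] object.
#' @param cfg An [essentiality_config()].
#' @return A `gene_scores` tibble: `gene`, `bf`, `n_guides`.
#' @export
bayes_factor_scores <- function(fc, refs, cfg = essentiality_config()) {
  fc <- tibble::as_tibble(fc)
  if ("control_class" %in% names(fc)) {
    fc <- dplyr::filter(fc, .data$control_class == "gene_targeting" |
                          !.data$control_class %in% .CONTROL_CLASSES)
  }
  ess_genes <- sort(intersect(unique(fc$gene), refs$core_essential))
  non_genes <- sort(intersect(unique(fc$gene), refs$nonessential))
  n_ess_guides <- sum(fc$gene %in% ess_genes)
  n_non_guides <- sum(fc$gene %in% non_genes)
  if (n_ess_guides == 0 || n_non_guides == 0) {
    abort("reference gene sets do not overlap the screened genes")
  }
  if (n_ess_guides < 10 || n_non_guides < 10) {
    abort("need at least 10 reference guides per class")
  }

  fc <- dplyr::arrange(fc, .data$gene, .data$sgrna)  # order-invariant scores
  genes <- unique(fc$gene)
  guide_gene <- fc$gene
  x <- fc$fc

  # fixed fold assignment for reference genes (seeded, independent of bootstrap)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  fold_of <- c(
    setNames(sample(rep_len(seq_len(cfg$n_folds), length(ess_genes))), ess_genes),
    setNames(sample(rep_len(seq_len(cfg$n_folds), length(non_genes))), non_genes)
  )
  guide_fold <- unname(fold_of[guide_gene])  # NA for non-reference guides

  total <- numeric(length(x))
  for (b in seq_len(cfg$n_bootstrap)) {
    boot_ess <- sample(ess_genes, replace = TRUE)
    boot_non <- sample(non_genes, replace = TRUE)
    tr_ess <- x[guide_gene %in% boot_ess]
    tr_non <- x[guide_gene %in% boot_non]
    llr <- kde_log2(tr_ess, x, cfg$density_floor) -
      kde_log2(tr_non, x, cfg$density_floor)
    # reference guides: rescore with their fold's genes held out of training
    for (k in sort(unique(guide_fold[!is.na(guide_fold)]))) {
      idx <- which(!is.na(guide_fold) & guide_fold == k)
      held <- names(fold_of)[fold_of == k]
      te <- setdiff(boot_ess, held); tn <- setdiff(boot_non, held)
      if (length(te) < 2 || length(tn) < 2) next
      llr[idx] <- kde_log2(x[guide_gene %in% te], x[idx], cfg$density_floor) -
        kde_log2(x[guide_gene %in% tn], x[idx], cfg$density_floor)
    }
    total <- total + llr
  }
  per_guide <- total / cfg$n_bootstrap

  out <- tibble::tibble(gene = guide_gene, llr = per_guide) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(bf = sum(.data$llr), n_guides = dplyr::n(), .groups = "drop")
  structure(out, class = c("gene_scores", class(out)))
}

#' Call essential genes from Bayes-factor scores
#'
#' In `bf` mode, genes with Bayes factor strictly greater than `cfg$bf_cut`
#' are essential. In `fdr` mode, genes are ranked by Bayes factor descending
#' and, at every candidate threshold, the false discovery rate is estimated
#' over reference genes only as FP / (TP + FP), where TP counts core-essential
#' and FP nonessential reference genes at or above the threshold; all genes at
#' or above the most lenient threshold with estimated FDR <= `cfg$fdr` are
#' returned.
#'
#' @param scores A `gene_scores` tibble from [bayes_factor_scores()].
#' @param refs A [reference_sets()] object (required in `fdr` mode).
#' @param mode `"fdr"` or `"bf"`.
#' @param cfg An [essentiality_config()].
#' @return Character vector of essential gene symbols.
#' @export
call_essentials <- function(scores, refs = NULL, mode = c("fdr", "bf"),
                            cfg = essentiality_config()) {
  mode <- match.arg(mode)
  if (nrow(scores) == 0) abort("empty score table")
  if (mode == "bf") {
    return(scores$gene[scores$bf > cfg$bf_cut])
  }
  if (is.null(refs)) abort("fdr mode needs reference sets")
  is_pos <- scores$gene %in% refs$core_essential
  is_neg <- scores$gene %in% refs$nonessential
  if (!any(is_pos) || !any(is_neg)) abort("fdr mode needs both reference classes in the scores")
  thresholds <- sort(unique(scores$bf), decreasing = TRUE)
  best <- NULL
  for (t in thresholds) {
    above <- scores$bf >= t
    tp <- sum(above & is_pos); fp <- sum(above & is_neg)
    if (tp + fp == 0) next
    if (fp / (tp + fp) <= cfg$fdr) best <- t
  }
  if (is.null(best)) return(character(0))
  scores$gene[scores$bf >= best]
}

#' Area under the precision-recall curve for reference-set recovery
#'
#' Reference genes are ranked by Bayes factor descending; core-essential genes
#' are positives and nonessential genes negatives. Precision and recall are
#' evaluated after each block of tied scores and the area is computed by
#' trapezoidal integration over recall.
#'
#' @param scores A `gene_scores` tibble.
#' @param refs A [reference_sets()] object.
#' @return PR-AUC in `[0, 1]`.
#' @export
precision_recall_auc <- function(scores, refs) {
  lab <- dplyr::case_when(
    scores$gene %in% refs$core_essential ~ 1L,
    scores$gene %in% refs$nonessential ~ 0L,
    TRUE ~ NA_integer_
  )
  keep <- !is.na(lab)
  s <- scores$bf[keep]; y <- lab[keep]
  if (length(unique(y)) < 2) abort("both reference classes must be represented")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  n_pos <- sum(y)
  # cumulative TP/FP at the end of each tied-score block
  block_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[block_end]
  fp <- cumsum(1 - y)[block_end]
  recall <- c(0, tp / n_pos)
  precision <- c(1, tp / (tp + fp))  # anchor at recall 0
  sum(diff(recall) * (head(precision, -1) + tail(precision, -1)) / 2)
}

#' Gate screens on precision-recall AUC
#'
#' Screens whose PR-AUC is strictly below `cfg$min_pr_auc` are excluded;
#' screens at exactly the cutoff are retained.
#'
#' @param qc A tibble with columns `screen` and `pr_auc`.
#' @param cfg An [essentiality_config()].
#' @return `qc` with a logical `retained` column added.
#' @export
screen_quality_gate <- function(qc, cfg = essentiality_config()) {
  dplyr::mutate(tibble::as_tibble(qc), retained = .data$pr_auc >= cfg$min_pr_auc)
}

#' Area under the ECDF of a guide subset's fold changes
#'
#' The subset's empirical cumulative distribution is integrated against the
#' full table's ECDF (a probability-probability curve on `[0, 1]`), which
#' makes the area the probability that a subset guide is more depleted than
#' a randomly chosen library guide (ties split evenly). Subsets drawn
#' uniformly from the library score 0.5; strongly and consistently depleted
#' subsets score near 1, subsets that hold their representation score below
#' 0.5 regardless of how extreme the screen's outlier fold changes are.
#'
#' @param fc A fold-change tibble covering the whole screen.
#' @param subset Character vector of guide ids; must be contained in `fc`.
#' @return ECDF-AUC in `[0, 1]`.
#' @export
ecdf_auc <- function(fc, subset) {
  if (length(subset) == 0) abort("empty guide subset")
  if (!all(subset %in% fc$sgrna)) abort("subset contains guides absent from the table")
  if (diff(range(fc$fc)) == 0) abort("constant fold changes: ECDF-AUC undefined")
  n <- nrow(fc)
  r <- rank(fc$fc, ties.method = "average")
  1 - (mean(r[fc$sgrna %in% subset]) - 0.5) / n
}

#' Skew ratio of a count sample
#'
#' The 90th percentile of counts divided by the 10th percentile
#' (linear-interpolation quantiles), a uniformity metric for plasmid pools.
#'
#' @param counts A `count_matrix`.
#' @param sample Sample name.
#' @return The skew ratio (>= 1 for any non-degenerate library).
#' @export
skew_ratio <- function(counts, sample) {
  if (!sample %in% count_samples(counts)) abort(paste0("unknown sample name ", sample))
  q <- quantile(counts[[sample]], c(0.1, 0.9), type = 7, names = FALSE)
  if (q[1] == 0) abort("undefined skew ratio: 10th percentile is 0")
  q[2] / q[1]
}
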