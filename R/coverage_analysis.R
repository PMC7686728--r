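# Essential-gene detection as a function of guides per gene, by repeated
# subsampling of a combined library.

#' Subsample a count matrix to k guides per gene
#'
#' Gene-targeting guides are sampled without replacement, exactly `k` per
#' gene; control guides are always retained in full (they are needed for
#' normalisation). Reproducible given the seed.
#'
#' @param counts A `count_matrix`.
#' @param k Guides to keep per gene.
#' @param seed Integer seed.
#' @return A `count_matrix` restricted to the sampled guides plus controls.
#' @export
subsample_guides <- function(counts, k, seed = 1L) {
  x <- tibble::as_tibble(counts)
  gt <- dplyr::filter(x, .data$control_class == "gene_targeting")
  short <- gt |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n < k)
  if (nrow(short) > 0) {
    abort(paste0("gene ", short$gene[[1]], " has fewer than ", k, " guides"))
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  kept <- gt |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_sample(n = k) |>
    dplyr::ungroup()
  out <- dplyr::bind_rows(kept, dplyr::filter(x, .data$control_class != "gene_targeting"))
  out <- out[order(match(out$sgrna, x$sgrna)), ]
  count_matrix(out, meta = attr(counts, "meta"))
}

#' Essential-gene detection versus guides per gene
#'
#' For each coverage `k` and each of `n_rep` independent samplings: subsample
#' the combined library to `k` guides per gene, renormalise, recompute fold
#' changes, and call essential genes with both the strict Bayes-factor cutoff
#' (`bf` caller, BF > cfg$bf_cut) and the reference-set FDR caller (`fdr`
#' caller, 5% by default). Reports the mean and standard error (sd / sqrt(n))
#' of the hit count per (k, caller).
#'
#' @param counts Combined `count_matrix` with a plasmid/reference sample.
#' @param refs A [reference_sets()] object.
#' @param sample,reference Sample names for the fold-change contrast.
#' @param cfg An [essentiality_config()].
#' @param k_range Coverages to test (default 2:8).
#' @param n_rep Independent samplings per coverage (default 5).
#' @param seed Base seed; sampling r of coverage k uses `seed + 1000*k + r`.
#' @return A `coverage_curve` tibble: `k`, `caller`, `mean_hits`, `sem`,
#'   `n_rep`.
#' @export
coverage_curve <- function(counts, refs, sample, reference,
                           cfg = essentiality_config(), k_range = 2:8,
                           n_rep = 5L, seed = 1L) {
  res <- purrr::map_dfr(k_range, function(k) {
    hits <- purrr::map_dfr(seq_len(n_rep), function(r) {
      sub <- subsample_guides(counts, k, seed = seed + 1000L * k + r)
      norm <- normalize_counts(sub)
      fc <- log2_fold_change(norm, sample, reference)
      scores <- bayes_factor_scores(fc, refs, cfg)
      tibble::tibble(
        rep = r,
        bf = length(call_essentials(scores, refs, mode = "bf", cfg = cfg)),
        fdr = length(call_essentials(scores, refs, mode = "fdr", cfg = cfg))
      )
    })
    tidyr::pivot_longer(hits, c("bf", "fdr"), names_to = "caller",
                        values_to = "hits") |>
      dplyr::group_by(.data$caller) |>
      dplyr::summarise(mean_hits = mean(.data$hits),
                       sem = sd(.data$hits) / sqrt(dplyr::n()),
                       n_rep = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(k = k, .before = 1)
  })
  structure(res, class = c("coverage_curve", class(res)))
}
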