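# Four-component univariate Gaussian mixture over control fold changes and
# nearest-control classification of library guides as cutting / not cutting /
# target phenotype.
#
# Component roles are anchored by mean order: the highest-mean component
# behaves like the non-targeting controls (role 1), the next like targeting
# controls that cut a neutral locus (role 2), and the two lowest-mean
# components capture moderate and severe toxic phenotypes (roles 3 and 4).

#' Fit a 4-component Gaussian mixture to control fold changes
#'
#' EM with quantile-spread initialisation (component means start at the
#' 12.5/37.5/62.5/87.5 percentiles of the data), equal starting weights, a
#' variance floor, and a non-decreasing log-likelihood trace. Roles are
#' assigned by sorting the fitted means.
#'
#' @param control_fcs Numeric vector of control fold changes (>= 40 values
#'   recommended; fewer than 4 is an error).
#' @param tol Convergence tolerance on the log-likelihood increment
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param var_floor Lower bound on component variances (default 1e-4).
#' @param seed Accepted for interface stability; the quantile-spread
#'   initialisation is fully deterministic, so the fit does not depend on it.
#' @return A `mixture_fit` object: components tibble (`component`, `role`,
#'   `weight`, `mean`, `sd`), `loglik` trace, `converged` flag, and the
#'   training data.
#' @export
fit_control_mixture <- function(control_fcs, seed = NULL, tol = 1e-8,
                                max_iter = 2000L, var_floor = 1e-4) {
  x <- as.numeric(control_fcs)
  x <- x[is.finite(x)]
  K <- 4L
  if (length(x) < K) abort("need at least 4 control values to fit 4 components")
  if (length(x) < 40) warn("fewer than 40 control values: mixture fit may be unstable")

  mu <- quantile(x, (seq_len(K) - 0.5) / K, type = 7, names = FALSE)
  sig2 <- rep(max(stats::var(x) / K, var_floor), K)
  w <- rep(1 / K, K)
  n <- length(x)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * dnorm(x, mu[k], sqrt(sig2[k])),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    loglik <- c(loglik, ll)
    if (it > 1 && abs(ll - loglik[it - 1]) < tol) { converged <- TRUE; break }
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sig2 <- pmax(vapply(seq_len(K),
                        function(k) sum(resp[, k] * (x - mu[k])^2) / nk[k],
                        numeric(1)),
                 var_floor)
  }
  if (!converged) warn("EM did not converge within max_iter")
  role <- integer(K)
  role[order(mu)] <- c(4L, 3L, 2L, 1L)  # lowest mean = severe toxic ... highest = non-targeting-like
  comp <- tibble::tibble(
    component = seq_len(K),
    role = role,
    role_label = c("nontargeting_like", "targeting_like",
                   "toxic_moderate", "toxic_severe")[role],
    weight = w, mean = mu, sd = sqrt(sig2)
  )
  structure(list(components = comp, loglik = loglik, converged = converged,
                 data = x, var_floor = var_floor),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> 4-component Gaussian mixture,", length(x$data), "controls,",
      length(x$loglik), "EM iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(dplyr::arrange(x$components, .data$role))
  invisible(x)
}

#' Posterior component responsibilities under a mixture fit
#'
#' @param fit A `mixture_fit`.
#' @param x Numeric values.
#' @return Matrix `length(x)` x 4, columns ordered by role (1 =
#'   nontargeting_like ... 4 = toxic_severe); rows sum to 1.
#' @export
posterior_responsibilities <- function(fit, x) {
  comp <- dplyr::arrange(fit$components, .data$role)
  dens <- vapply(seq_len(nrow(comp)),
                 function(k) comp$weight[k] * dnorm(x, comp$mean[k], comp$sd[k]),
                 numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  rs <- rowSums(dens)
  rs[rs == 0] <- .Machine$double.xmin
  out <- dens / rs
  colnames(out) <- paste0("p", seq_len(nrow(comp)))
  out
}

#' Classify library guides by nearest-control phenotype
#'
#' Guides targeting core-essential reference genes are excluded (their strong
#' depletion is expected and carries no information about cutting). Every
#' other guide is mapped to the control with the most similar fold change
#' (ties resolved toward the lower-fc control). With `p1..p4` the posteriors
#' of that control under the mixture (roles 1-4): if `p3 + p4 >= threshold`
#' the guide has a target-dependent viability phenotype; else if
#' `p2 >= threshold` it is likely cutting; else if `p1 >= threshold` likely
#' not cutting; otherwise undetermined.
#'
#' @param fc Fold-change tibble of library guides (`sgrna`, `gene`, `fc`).
#' @param fit A `mixture_fit` trained on `control_fcs`.
#' @param control_fcs Named numeric vector of control fold changes (names =
#'   control guide ids).
#' @param core_essential Character vector of core-essential reference genes.
#' @param threshold Posterior mass needed for a confident class
#'   (default 0.80).
#' @return A tibble `sgrna`, `gene`, `fc`, `nearest_control`, `p1..p4`,
#'   `class`.
#' @export
classify_guides <- function(fc, fit, control_fcs, core_essential = character(0),
                            threshold = 0.80) {
  if (length(control_fcs) == 0) abort("empty control set")
  if (is.null(names(control_fcs))) {
    names(control_fcs) <- paste0("ctrl_", seq_along(control_fcs))
  }
  # deterministic nearest-control: minimal |diff|, ties -> lower-fc control
  o <- order(control_fcs, names(control_fcs))
  cv <- control_fcs[o]
  post <- posterior_responsibilities(fit, unname(cv))
  nearest_idx <- vapply(fc$fc, function(v) {
    d <- abs(v - cv)
    which.min(d)  # first minimum = lowest fc among tied (cv sorted ascending)
  }, integer(1))
  p <- post[nearest_idx, , drop = FALSE]
  cls <- dplyr::case_when(
    fc$gene %in% core_essential ~ "excluded_core_essential",
    p[, 3] + p[, 4] >= threshold ~ "target_phenotype",
    p[, 2] >= threshold ~ "likely_cutting",
    p[, 1] >= threshold ~ "likely_not_cutting",
    TRUE ~ "undetermined"
  )
  tibble::tibble(
    sgrna = fc$sgrna, gene = fc$gene, fc = fc$fc,
    nearest_control = names(cv)[nearest_idx],
    p1 = p[, 1], p2 = p[, 2], p3 = p[, 3], p4 = p[, 4],
    class = cls
  )
}

#' Cross-tabulate guide classes by design provenance
#'
#' @param classes Output of [classify_guides()].
#' @param design A `library_design` (provides per-guide provenance).
#' @param essential_calls Genes called essential in the analysed screen.
#' @return A tibble `category`, `gene_essential`, `class`, `n` covering every
#'   combination (zero-filled).
#' @export
class_by_provenance <- function(classes, design, essential_calls = character(0)) {
  prov <- dplyr::select(tibble::as_tibble(design$guides), "sgrna", "category")
  joined <- dplyr::inner_join(tibble::as_tibble(classes), prov, by = "sgrna") |>
    dplyr::mutate(gene_essential = .data$gene %in% essential_calls)
  all_classes <- c("target_phenotype", "likely_cutting", "likely_not_cutting",
                   "undetermined", "excluded_core_essential")
  joined |>
    dplyr::count(.data$category, .data$gene_essential, .data$class, name = "n") |>
    tidyr::complete(category = unique(prov$category),
                    gene_essential = c(TRUE, FALSE),
                    class = all_classes, fill = list(n = 0L))
}
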