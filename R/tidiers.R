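# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture fit
#'
#' One row per mixture component, ordered by role (1 = nontargeting_like to
#' 4 = toxic_severe).
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A tibble `role`, `role_label`, `weight`, `mean`, `sd`.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  dplyr::arrange(x$components, .data$role) |>
    dplyr::select("role", "role_label", "weight", "mean", "sd")
}

#' One-row summary of a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A tibble `n`, `logLik`, `n_iter`, `converged`.
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(n = length(x$data), logLik = tail(x$loglik, 1),
                 n_iter = length(x$loglik), converged = x$converged)
}

#' Tidy a library design
#'
#' @param x A `library_design`.
#' @param ... Unused.
#' @return The per-guide tibble (`sgrna`, `seq`, `gene`, `sublibrary`,
#'   `category`, `rank`).
#' @method tidy library_design
#' @export
tidy.library_design <- function(x, ...) tibble::as_tibble(x$guides)

#' One-row-per-sub-library summary of a design
#'
#' @param x A `library_design`.
#' @param ... Unused.
#' @return A tibble `sublibrary`, `n_genes`, `n_guides`, `n_controls`,
#'   `total`.
#' @method glance library_design
#' @export
glance.library_design <- function(x, ...) {
  if (nrow(x$guides) == 0) {
    return(tibble::tibble(sublibrary = character(0), n_genes = integer(0),
                          n_guides = integer(0), n_controls = integer(0),
                          total = integer(0)))
  }
  x$guides |>
    dplyr::group_by(sublibrary = .data$sublibrary) |>
    dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene),
                     n_guides = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(n_controls = nrow(x$controls),
                  total = .data$n_guides + .data$n_controls)
}
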