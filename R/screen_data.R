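# Count-table data model, normalisation, fold changes, sub-library
# combination and replicate correlation for pooled CRISPR screens.

#' Build a count matrix from a tibble
#'
#' A count matrix is a tibble with one row per sgRNA: columns `sgrna`, `gene`,
#' `control_class` and one non-negative integer column per sample. The control
#' class of a guide is one of `gene_targeting`, `targeting_control` or
#' `non_targeting_control`; control classes are derived from the reserved gene
#' labels `NON_TARGETING` and `TARGETING_CTRL` when not given explicitly.
#'
#' @param x A data frame with columns `sgrna`, `gene`, optionally
#'   `control_class`, and at least one sample column of counts.
#' @param meta Optional named list of screen metadata (screen id, cell line,
#'   sub-library tag); stored as an attribute.
#' @return A `count_matrix` tibble.
#' @export
count_matrix <- function(x, meta = list()) {
  x <- tibble::as_tibble(x)
  if (!all(c("sgrna", "gene") %in% names(x))) {
    abort("count matrix needs `sgrna` and `gene` columns")
  }
  if (!"control_class" %in% names(x)) {
    x <- dplyr::mutate(
      x,
      control_class = dplyr::case_when(
        .data$gene == .NON_TARGETING_LABEL ~ "non_targeting_control",
        .data$gene == .TARGETING_CTRL_LABEL ~ "targeting_control",
        TRUE ~ "gene_targeting"
      ),
      .after = "gene"
    )
  }
  x <- dplyr::relocate(x, "sgrna", "gene", "control_class")
  validate_count_matrix(x)
  structure(x, meta = meta, class = c("count_matrix", class(tibble::tibble())))
}

validate_count_matrix <- function(x) {
  dup <- x$sgrna[duplicated(x$sgrna)]
  if (length(dup) > 0) {
    abort(paste0("duplicate guide id ", dup[[1]]))
  }
  samples <- count_samples(x)
  if (length(samples) < 1) abort("count matrix needs at least one sample column")
  for (s in samples) {
    v <- x[[s]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(paste0("invalid count in sample ", s, ", row ", bad[[1]],
                   ": counts must be non-negative integers"))
    }
  }
  if (!all(x$control_class %in% .CONTROL_CLASSES)) {
    abort("unknown control class")
  }
  invisible(x)
}

#' Sample columns of a count or normalized matrix
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return Character vector of sample names, in column order.
#' @export
count_samples <- function(x) {
  setdiff(names(x), c("sgrna", "gene", "control_class"))
}

#' Read a tab-separated sgRNA count table
#'
#' Expects a header row `sgRNA<TAB>gene<TAB><sample>...` (MAGeCK-style count
#' table dialect). Genes named `NON_TARGETING` or `TARGETING_CTRL` are mapped
#' to the corresponding control classes; all other guides are gene-targeting.
#'
#' @param path Path to the TSV file.
#' @param meta Optional metadata list, stored on the result.
#' @return A [count_matrix()] tibble with row order preserved.
#' @export
read_count_table <- function(path, meta = list()) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                       progress = FALSE, show_col_types = FALSE)
  nm <- names(x)
  if (length(nm) < 3 || tolower(nm[[1]]) != "sgrna" || tolower(nm[[2]]) != "gene") {
    abort(paste0("missing or malformed header in ", path,
                 ": expected 'sgRNA<TAB>gene<TAB><sample>...'"))
  }
  names(x)[1:2] <- c("sgrna", "gene")
  for (s in names(x)[-(1:2)]) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(paste0("non-numeric count column ", s))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(paste0("invalid count ", v[bad[[1]]], " in sample ", s,
                   ", row ", bad[[1]]))
    }
    x[[s]] <- as.integer(round(v))
  }
  count_matrix(x, meta = meta)
}

#' Write a count matrix as a MAGeCK-style TSV
#' @param x A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  out <- tibble::as_tibble(x)[, c("sgrna", "gene", count_samples(x))]
  names(out)[1:2] <- c("sgRNA", "gene")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Normalize counts to the targeting-control median
#'
#' A pseudocount is added to every count, then each sample is divided by the
#' median pseudocounted count of its targeting-control guides, so that the
#' per-sample targeting-control median of the output equals 1.
#'
#' @param counts A `count_matrix` containing at least one targeting control.
#' @param pseudocount Integer pseudocount, added before the median is taken
#'   (default 1).
#' @return A `normalized_matrix` tibble: same axes, strictly positive values,
#'   with the pseudocount recorded in `attr(, "pseudocount")`.
#' @export
normalize_counts <- function(counts, pseudocount = 1L) {
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (pseudocount < 1 && any(unlist(counts[count_samples(counts)]) <= 0)) {
    abort("pseudocount must be >= 1 when zero counts are present")
  }
  tc <- counts$control_class == "targeting_control"
  if (!any(tc)) abort("no targeting controls present; cannot normalize")
  out <- tibble::as_tibble(counts)
  for (s in count_samples(counts)) {
    v <- counts[[s]] + pseudocount
    out[[s]] <- v / median(v[tc])
  }
  structure(out,
            pseudocount = pseudocount,
            meta = attr(counts, "meta"),
            class = c("normalized_matrix", class(tibble::tibble())))
}

#' Per-guide log2 fold change between two samples
#'
#' Computes `fc(g) = log2(norm(g, sample) / norm(g, reference))` for every
#' guide; negative values indicate depletion relative to the reference
#' (typically the plasmid or T0 sample).
#'
#' @param norm A `normalized_matrix`.
#' @param sample,reference Sample names present in `norm`.
#' @return A tibble `sgrna, gene, control_class, fc` with attributes `sample`
#'   and `reference`.
#' @export
log2_fold_change <- function(norm, sample, reference) {
  for (s in c(sample, reference)) {
    if (!s %in% count_samples(norm)) abort(paste0("unknown sample name ", s))
  }
  out <- tibble::tibble(
    sgrna = norm$sgrna,
    gene = norm$gene,
    control_class = norm$control_class,
    fc = log2(norm[[sample]] / norm[[reference]])
  )
  structure(out, sample = sample, reference = reference,
            class = c("fold_change_tbl", class(out)))
}

#' Write a fold-change table as TSV
#' @param fc A fold-change tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(fc, path) {
  readr::write_tsv(dplyr::select(tibble::as_tibble(fc), "sgrna", "gene", "fc"),
                   path, progress = FALSE)
  invisible(path)
}

# round half-up to nearest integer (round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Combine two sub-library screens into one count matrix
#'
#' Counts from each input are rescaled to a common depth: per sample, divided
#' by that sample's median count and multiplied by the median count across all
#' samples of both inputs, then rounded half-up to the nearest integer and
#' concatenated. Sample columns must correspond pairwise (same replicate
#' labels). Gene-targeting guides must be disjoint between the inputs; control
#' guides present in both are kept as two rows with origin-suffixed ids
#' (`<id>__A`, `<id>__B`).
#'
#' @param a,b `count_matrix` objects for sub-libraries A and B.
#' @return A combined `count_matrix`.
#' @export
combine_sublibraries <- function(a, b) {
  sa <- count_samples(a); sb <- count_samples(b)
  if (!identical(sort(sa), sort(sb))) {
    abort("sample sets of the two sub-libraries do not correspond")
  }
  ga <- a$sgrna[a$control_class == "gene_targeting"]
  gb <- b$sgrna[b$control_class == "gene_targeting"]
  clash <- intersect(ga, gb)
  if (length(clash) > 0) {
    abort(paste0("overlapping gene-targeting guide ids: ", clash[[1]]))
  }
  global_med <- median(c(unlist(a[sa]), unlist(b[sa])))
  rescale <- function(x) {
    out <- tibble::as_tibble(x)
    for (s in sa) out[[s]] <- round_half_up(x[[s]] / median(x[[s]]) * global_med)
    out[, c("sgrna", "gene", "control_class", sa)]
  }
  ra <- rescale(a); rb <- rescale(b)
  shared <- intersect(ra$sgrna, rb$sgrna)
  if (length(shared) > 0) {
    ra$sgrna[ra$sgrna %in% shared] <- paste0(ra$sgrna[ra$sgrna %in% shared], "__A")
    rb$sgrna[rb$sgrna %in% shared] <- paste0(rb$sgrna[rb$sgrna %in% shared], "__B")
  }
  count_matrix(dplyr::bind_rows(ra, rb),
               meta = list(combined_from = list(attr(a, "meta"), attr(b, "meta"))))
}

#' Replicate correlation of fold changes
#'
#' Pearson and Spearman correlation over guides shared by two fold-change
#' tables, the standard replicate-reproducibility readout for screens.
#'
#' @param x,y Fold-change tibbles over the same guide id set.
#' @return A one-row tibble with columns `pearson`, `spearman`, `n`.
#' @export
replicate_correlation <- function(x, y) {
  if (!setequal(x$sgrna, y$sgrna)) abort("fold-change tables cover different guide sets")
  m <- dplyr::inner_join(dplyr::select(tibble::as_tibble(x), "sgrna", fx = "fc"),
                         dplyr::select(tibble::as_tibble(y), "sgrna", fy = "fc"),
                         by = "sgrna")
  if (nrow(m) < 3) abort("fewer than 3 shared guides")
  if (sd(m$fx) == 0 || sd(m$fy) == 0) abort("zero variance: correlation undefined")
  tibble::tibble(
    pearson = cor(m$fx, m$fy, method = "pearson"),
    spearman = cor(m$fx, m$fy, method = "spearman"),
    n = nrow(m)
  )
}

#' Reference gene sets for essentiality calling
#'
#' Holds the two disjoint gold-standard gene lists used to calibrate and
#' evaluate the Bayes-factor caller: core essential genes (CEGv2-like) and
#' nonessential genes (NEGv1-like).
#'
#' @param core_essential,nonessential Character vectors of gene symbols;
#'   non-empty and disjoint.
#' @return A `reference_sets` list.
#' @export
reference_sets <- function(core_essential, nonessential) {
  core_essential <- unique(as.character(core_essential))
  nonessential <- unique(as.character(nonessential))
  if (length(core_essential) == 0 || length(nonessential) == 0) {
    abort("both reference sets must be non-empty")
  }
  if (length(intersect(core_essential, nonessential)) > 0) {
    abort("reference sets must be disjoint")
  }
  structure(list(core_essential = core_essential, nonessential = nonessential),
            class = "reference_sets")
}
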