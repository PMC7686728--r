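# The empirical library-design algorithm: per-screen activity labels,
# cross-screen aggregation, off-target outlier flags, candidate ranking and
# assembly of mutually exclusive sub-libraries A and B with shared controls.

#' Configuration for empirical guide selection
#'
#' @param active_quantile A guide counts as phenotypically active in a screen
#'   when its fold change is at or below this quantile of all fold changes in
#'   the screen (default 0.20 — a lenient threshold chosen because roughly
#'   12% of genes are expected to be essential).
#' @param min_active_fraction Minimum fraction of used screens in which a
#'   guide must be active for activity to count as a selection criterion
#'   (default 0.05, inclusive).
#' @param z_cut Absolute per-gene effect z-score above which a guide is
#'   flagged as a potential off-targeting outlier (default 1.25, strict).
#' @param guides_per_sublibrary Guides per gene in each sub-library
#'   (default 4).
#' @param n_nontargeting_controls,n_targeting_controls Control guides added
#'   to each sub-library (defaults 300 and 135).
#' @param min_group_size_for_z Minimum same-gene group size for z flagging
#'   (default 3; smaller groups and zero-spread groups are never flagged).
#' @param max_offtargets Candidates with more predicted off-targets are
#'   dropped (default `Inf`, i.e. off-target count only breaks ties).
#' @param seed Integer seed (default 1).
#' @return A `selection_config` list.
#' @export
selection_config <- function(active_quantile = 0.20, min_active_fraction = 0.05,
                             z_cut = 1.25, guides_per_sublibrary = 4L,
                             n_nontargeting_controls = 300L,
                             n_targeting_controls = 135L,
                             min_group_size_for_z = 3L,
                             max_offtargets = Inf, seed = 1L) {
  stopifnot(active_quantile > 0, active_quantile < 1, z_cut > 0,
            guides_per_sublibrary >= 1, min_group_size_for_z >= 2)
  structure(list(active_quantile = active_quantile,
                 min_active_fraction = min_active_fraction, z_cut = z_cut,
                 guides_per_sublibrary = as.integer(guides_per_sublibrary),
                 n_nontargeting_controls = as.integer(n_nontargeting_controls),
                 n_targeting_controls = as.integer(n_targeting_controls),
                 min_group_size_for_z = as.integer(min_group_size_for_z),
                 max_offtargets = max_offtargets, seed = as.integer(seed)),
            class = "selection_config")
}

#' Label guides active in one screen
#'
#' A guide is active when its target gene was called essential in the screen
#' AND its fold change is at or below the `active_quantile` quantile of all
#' fold changes in the screen (ties at the threshold count as active).
#'
#' @param fc A fold-change tibble for one screen.
#' @param essential_genes Genes called essential in this screen, typically
#'   from [call_essentials()] in FDR mode.
#' @param cfg A [selection_config()].
#' @return `fc` with a logical `active` column added.
#' @export
label_active <- function(fc, essential_genes, cfg = selection_config()) {
  if (nrow(fc) == 0) abort("empty fold-change table")
  thr <- quantile(fc$fc, cfg$active_quantile, type = 7, names = FALSE)
  dplyr::mutate(tibble::as_tibble(fc),
                active = .data$gene %in% essential_genes & .data$fc <= thr)
}

#' Aggregate per-screen activity labels across retained screens
#'
#' @param labels A list of labelled fold-change tibbles (from
#'   [label_active()]), one per retained screen; only screens passing
#'   [screen_quality_gate()] should be included.
#' @param cfg A [selection_config()].
#' @return An activity tibble: `sgrna`, `gene`, `n_used`, `n_active`,
#'   `active_fraction`, `empirical_essential_eligible`.
#' @export
aggregate_activity <- function(labels, cfg = selection_config()) {
  all_lab <- dplyr::bind_rows(labels)
  out <- all_lab |>
    dplyr::group_by(.data$sgrna, .data$gene) |>
    dplyr::summarise(n_used = dplyr::n(), n_active = sum(.data$active),
                     .groups = "drop") |>
    dplyr::mutate(
      active_fraction = ifelse(.data$n_used > 0, .data$n_active / .data$n_used, 0),
      empirical_essential_eligible =
        .data$n_active > 0 & .data$active_fraction >= cfg$min_active_fraction
    )
  out
}

#' Flag guides with outlier phenotypes within their gene group
#'
#' Within each gene, aggregate effect scores are centred and scaled
#' (sample standard deviation); guides with `|z|` strictly greater than
#' `cfg$z_cut` are flagged as potentially off-targeting. Groups smaller than
#' `cfg$min_group_size_for_z` or with zero spread are never flagged.
#'
#' @param effect_scores A tibble `sgrna`, `gene`, `score` of per-guide
#'   aggregate effect scores (e.g. from [aggregate_effect_scores()]).
#' @param cfg A [selection_config()].
#' @return `effect_scores` with `effect_z` and `offtarget_outlier` columns.
#' @export
flag_offtarget_outliers <- function(effect_scores, cfg = selection_config()) {
  effect_scores |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(
      .gsd = sd(.data$score),
      effect_z = dplyr::if_else(
        dplyr::n() >= cfg$min_group_size_for_z & .data$.gsd > 0,
        (.data$score - mean(.data$score)) / .data$.gsd, 0),
      offtarget_outlier = abs(.data$effect_z) > cfg$z_cut
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".gsd")
}

#' Aggregate effect scores across screens
#'
#' Stand-in for a database effect score: within each screen, fold changes are
#' rank-normalized and mapped linearly to `[-1, 1]` (most depleted guide
#' -> -1), then averaged across the screens in which the guide was used.
#'
#' @param fcs List of fold-change tibbles (retained screens).
#' @return A tibble `sgrna`, `gene`, `score`.
#' @export
aggregate_effect_scores <- function(fcs) {
  per_screen <- purrr::map(fcs, function(fc) {
    n <- nrow(fc)
    r <- rank(fc$fc, ties.method = "average")
    dplyr::mutate(tibble::as_tibble(fc),
                  score = if (n > 1) 2 * (r - 1) / (n - 1) - 1 else 0)
  })
  dplyr::bind_rows(per_screen) |>
    dplyr::group_by(.data$sgrna, .data$gene) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
}

#' Rank a gene's candidate guides for library selection
#'
#' Candidates with any sequence filter flag, an off-target outlier flag, or
#' more than `cfg$max_offtargets` predicted off-targets are dropped. The
#' survivors are ordered: first the empirically essential-eligible guides
#' (by `n_active` descending, then `active_fraction` descending), then the
#' remaining guides (category `empirical_nonessential`, by `n_transcripts`
#' descending, `tss_distance` ascending, `offtarget_count` ascending). Ties
#' are broken by guide sequence ascending, making the order deterministic.
#'
#' @param candidates A tibble with columns `sgrna`, `seq`, `gene` plus the
#'   activity columns (`n_active`, `active_fraction`,
#'   `empirical_essential_eligible`), annotation columns (`n_transcripts`,
#'   `tss_distance`, `offtarget_count`), flag columns (`any_flag`,
#'   `offtarget_outlier`).
#' @param cfg A [selection_config()].
#' @return The eligible candidates, ordered, with `category` and `rank`
#'   columns. May be empty.
#' @export
rank_candidates <- function(candidates, cfg = selection_config()) {
  x <- tibble::as_tibble(candidates) |>
    dplyr::filter(!.data$any_flag, !.data$offtarget_outlier,
                  .data$offtarget_count <= cfg$max_offtargets)
  if (nrow(x) == 0) {
    return(dplyr::mutate(x, category = character(0), rank = integer(0)))
  }
  ess <- dplyr::filter(x, .data$empirical_essential_eligible) |>
    dplyr::arrange(dplyr::desc(.data$n_active), dplyr::desc(.data$active_fraction),
                   .data$seq) |>
    dplyr::mutate(category = "empirical_essential")
  rest <- dplyr::filter(x, !.data$empirical_essential_eligible) |>
    dplyr::arrange(dplyr::desc(.data$n_transcripts), .data$tss_distance,
                   .data$offtarget_count, .data$seq) |>
    dplyr::mutate(category = "empirical_nonessential")
  dplyr::bind_rows(ess, rest) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Design candidate guides de novo from a gene's coding exons
#'
#' Enumerates all 20-mers immediately 5' of an NGG PAM on either strand
#' within the gene's exons, drops any with sequence filter flags or more than
#' `cfg$max_offtargets` near-match sites, and orders the survivors by
#' (exon rank ascending, off-target count ascending, sequence ascending).
#'
#' @param gene Gene id present in the annotation.
#' @param genome A `DNAStringSet` or FASTA path.
#' @param annotation Exon table from [read_annotation()].
#' @param cfg A [selection_config()].
#' @param max_mm Mismatch budget for off-target counting (default 3).
#' @return A tibble `seq`, `exon_rank`, `offtarget_count`, `category`
#'   (`de_novo`), ordered; empty for genes without usable exons.
#' @export
design_de_novo <- function(gene, genome, annotation, cfg = selection_config(),
                           max_mm = 3L) {
  genome <- as_genome(genome)
  ex <- dplyr::filter(tibble::as_tibble(annotation), .data$gene == .env$gene)
  if (nrow(ex) == 0) return(tibble::tibble(seq = character(0),
                                           exon_rank = integer(0),
                                           offtarget_count = integer(0),
                                           category = character(0)))
  cands <- purrr::pmap_dfr(ex[, c("chrom", "start0", "end0", "exon_rank")],
    function(chrom, start0, end0, exon_rank) {
      s <- as.character(genome[[chrom]])
      found <- list()
      # + strand: [p, p+19] followed by NGG at p+21..p+22 (1-based here)
      for (p in seq_len(nchar(s) - 22)) {
        cut0 <- p - 1 + 17  # 0-based cut position of this candidate
        if (cut0 < start0 || cut0 >= end0) next
        if (substr(s, p + 21, p + 22) == "GG") {
          found[[length(found) + 1]] <- tibble::tibble(
            seq = substr(s, p, p + 19), exon_rank = exon_rank)
        }
        if (substr(s, p, p + 1) == "CC") {  # - strand PAM: CCN then protospacer
          sq <- substr(s, p + 3, p + 22)
          cut0m <- p - 1 + 3 + 3  # revcomp protospacer cut, 3 bp from PAM end
          if (cut0m >= start0 && cut0m < end0) {
            found[[length(found) + 1]] <- tibble::tibble(
              seq = as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq))),
              exon_rank = exon_rank)
          }
        }
      }
      dplyr::bind_rows(found)
    })
  if (nrow(cands) == 0) return(tibble::tibble(seq = character(0),
                                              exon_rank = integer(0),
                                              offtarget_count = integer(0),
                                              category = character(0)))
  cands <- dplyr::distinct(cands, .data$seq, .keep_all = TRUE)
  flags <- sequence_flags(cands$seq)
  cands <- cands[!flags$any_flag, , drop = FALSE]
  if (nrow(cands) == 0) return(tibble::tibble(seq = character(0),
                                              exon_rank = integer(0),
                                              offtarget_count = integer(0),
                                              category = character(0)))
  cands$offtarget_count <- vapply(cands$seq, count_offtargets, integer(1),
                                  genome = genome, max_mm = max_mm)
  cands |>
    dplyr::filter(.data$offtarget_count <= cfg$max_offtargets) |>
    dplyr::arrange(.data$exon_rank, .data$offtarget_count, .data$seq) |>
    dplyr::mutate(category = "de_novo")
}

#' Assemble mutually exclusive sub-libraries A and B
#'
#' Per gene, sub-library A takes candidate ranks 1-4 and B ranks 5-8;
#' shortfalls are backfilled from de novo designs (A filled before B). The
#' full control set (`n_nontargeting_controls` + `n_targeting_controls`) is
#' appended to each sub-library and is identical in both. Genes that cannot
#' be filled even after backfill are reported in `failed_genes`, not an
#' error.
#'
#' @param ranked Named list (by gene) of ranked candidate tibbles from
#'   [rank_candidates()] (columns `seq`, `category`; optionally `sgrna`).
#' @param de_novo Named list (by gene) of de novo candidate tibbles from
#'   [design_de_novo()]; may be missing genes.
#' @param controls A tibble of control guides with columns `sgrna`, `seq`,
#'   `control_class` (`non_targeting_control` / `targeting_control`).
#' @param cfg A [selection_config()].
#' @return A `library_design` object: list with `guides` (tibble `sgrna`,
#'   `seq`, `gene`, `sublibrary`, `category`, `rank`), `controls`, and
#'   `failed_genes`.
#' @export
assemble_library <- function(ranked, de_novo = list(), controls,
                             cfg = selection_config()) {
  k <- cfg$guides_per_sublibrary
  nt <- dplyr::filter(controls, .data$control_class == "non_targeting_control")
  tc <- dplyr::filter(controls, .data$control_class == "targeting_control")
  if (nrow(nt) < cfg$n_nontargeting_controls || nrow(tc) < cfg$n_targeting_controls) {
    abort("control pool smaller than the configured control counts")
  }
  ctrl <- dplyr::bind_rows(head(nt, cfg$n_nontargeting_controls),
                           head(tc, cfg$n_targeting_controls))

  rows <- list(); failed <- character(0)
  for (gene in sort(names(ranked))) {
    cand <- ranked[[gene]]
    pool <- tibble::tibble(seq = character(0), category = character(0))
    if (!is.null(cand) && nrow(cand) > 0) {
      pool <- tibble::tibble(seq = cand$seq, category = cand$category)
    }
    dn <- de_novo[[gene]]
    if (!is.null(dn) && nrow(dn) > 0) {
      dn_pool <- tibble::tibble(seq = dn$seq, category = "de_novo")
      pool <- dplyr::bind_rows(pool, dn_pool)
    }
    pool <- dplyr::distinct(pool, .data$seq, .keep_all = TRUE)
    if (nrow(pool) < 2 * k) {
      # cannot fill both sub-libraries even after backfill: report, keep the
      # design invariants (4 guides per gene per sub-library) intact
      failed <- c(failed, gene)
      next
    }
    rows[[gene]] <- dplyr::mutate(
      head(pool, 2 * k),
      gene = gene,
      rank = dplyr::row_number(),
      sublibrary = ifelse(.data$rank <= k, "A", "B"),
      sgrna = paste0(gene, "_", .data$rank)
    )
  }
  guides <- dplyr::bind_rows(rows)
  if (nrow(guides) > 0) {
    guides <- guides[, c("sgrna", "seq", "gene", "sublibrary", "category", "rank")]
    for (sl in c("A", "B")) {
      seqs <- c(guides$seq[guides$sublibrary == sl], ctrl$seq)
      if (anyDuplicated(seqs)) {
        abort(paste0("duplicate sequence within sub-library ", sl))
      }
    }
  }
  structure(list(guides = guides, controls = ctrl,
                 failed_genes = tibble::tibble(gene = failed), cfg = cfg),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design>\n")
  for (sl in c("A", "B")) {
    n <- sum(x$guides$sublibrary == sl)
    cat("  sub-library ", sl, ": ", n, " gene-targeting + ",
        nrow(x$controls), " control guides\n", sep = "")
  }
  if (nrow(x$failed_genes) > 0) {
    cat("  failed genes:", nrow(x$failed_genes), "\n")
  }
  invisible(x)
}

#' Provenance composition of a library design
#'
#' @param design A `library_design`.
#' @return A tibble `sublibrary`, `category`, `n`, `fraction`; fractions sum
#'   to 1 within each sub-library.
#' @export
provenance_summary <- function(design) {
  if (nrow(design$guides) == 0) abort("empty library design")
  design$guides |>
    dplyr::count(.data$sublibrary, .data$category, name = "n") |>
    dplyr::group_by(.data$sublibrary) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Export a library design as TSV (and optionally FASTA)
#'
#' @param design A `library_design`.
#' @param path Output TSV path (`sgRNA_id, sequence, gene, sublibrary,
#'   category, rank`; controls carry their class as category).
#' @param fasta Optional FASTA output path for all sequences.
#' @return `path`, invisibly.
#' @export
write_library_design <- function(design, path, fasta = NULL) {
  ctrl <- design$controls |>
    dplyr::transmute(sgrna = .data$sgrna, seq = .data$seq, gene = .data$control_class,
                     sublibrary = "AB", category = .data$control_class,
                     rank = NA_integer_)
  out <- dplyr::bind_rows(tibble::as_tibble(design$guides), ctrl)
  names(out) <- c("sgRNA_id", "sequence", "gene", "sublibrary", "category", "rank")
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(setNames(out$sequence, out$sgRNA_id))
    Biostrings::writeXStringSet(seqs, fasta)
  }
  invisible(path)
}
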