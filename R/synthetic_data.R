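# Ground-truth synthetic data: pooled-screen count collections with known
# essential genes, guide efficacies and toxic off-target guides; and random
# genomes with annotation and planted near-match sites.
#
# The generator emulates the structure of large public screen collections:
# ~12% essential genes, heterogeneous per-guide efficacy, rare guides with a
# gene-independent toxic phenotype, a small double-strand-break cost for
# every cutting guide, log-normal library abundance and negative-binomial
# sequencing noise.

#' Configuration for the screen-collection simulator
#'
#' @param n_genes Number of protein-coding genes.
#' @param guides_per_gene Guides targeting each gene.
#' @param essential_fraction Fraction of genes that are essential
#'   (default 0.12, the community expectation for proliferation screens);
#'   the essential count is `round(essential_fraction * n_genes)`.
#' @param essential_effect Mean log2 depletion of a fully effective guide
#'   targeting an essential gene (default -3).
#' @param efficacy_shape1,efficacy_shape2 Beta distribution of per-guide
#'   efficacy in `[0, 1]` (defaults 6 and 2: most guides cut well, a tail of
#'   poor cutters).
#' @param toxic_offtarget_rate Fraction of gene-targeting guides given a
#'   gene-independent toxic depletion (default 0.01).
#' @param toxic_effect Log2 depletion added to toxic guides (default -3).
#' @param nb_dispersion Negative-binomial dispersion shared by all counts
#'   (default 0.05; `size = 1/dispersion`).
#' @param sequencing_depth Expected total reads per sample (default 1e7).
#' @param n_screens Screens in the collection (default 3).
#' @param n_replicates Endpoint replicates per screen (default 2).
#' @param n_nontargeting,n_targeting Control guides (defaults 300 and 135).
#' @param targeting_dsb_effect Log2 depletion from the double-strand-break
#'   cost paid by every cutting guide, including targeting controls
#'   (default -0.3).
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000L, guides_per_gene = 4L,
                              essential_fraction = 0.12, essential_effect = -3,
                              efficacy_shape1 = 6, efficacy_shape2 = 2,
                              toxic_offtarget_rate = 0.01, toxic_effect = -3,
                              nb_dispersion = 0.05, sequencing_depth = 1e7,
                              n_screens = 3L, n_replicates = 2L,
                              n_nontargeting = 300L, n_targeting = 135L,
                              targeting_dsb_effect = -0.3, seed = 1L) {
  stopifnot(essential_fraction >= 0, essential_fraction <= 1,
            toxic_offtarget_rate >= 0, toxic_offtarget_rate <= 1,
            sequencing_depth > 0, nb_dispersion > 0)
  structure(list(n_genes = as.integer(n_genes),
                 guides_per_gene = as.integer(guides_per_gene),
                 essential_fraction = essential_fraction,
                 essential_effect = essential_effect,
                 efficacy_shape1 = efficacy_shape1,
                 efficacy_shape2 = efficacy_shape2,
                 toxic_offtarget_rate = toxic_offtarget_rate,
                 toxic_effect = toxic_effect,
                 nb_dispersion = nb_dispersion,
                 sequencing_depth = sequencing_depth,
                 n_screens = as.integer(n_screens),
                 n_replicates = as.integer(n_replicates),
                 n_nontargeting = as.integer(n_nontargeting),
                 n_targeting = as.integer(n_targeting),
                 targeting_dsb_effect = targeting_dsb_effect,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# unique 20-mers free of the cloning/sequence filter flags, as in a designed
# (pre-filtered) library
random_guide_seqs <- function(n) {
  draw <- function(m) vapply(seq_len(m), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  seqs <- draw(n)
  repeat {
    bad <- duplicated(seqs) | sequence_flags(seqs)$any_flag
    if (!any(bad)) return(seqs)
    seqs[bad] <- draw(sum(bad))
  }
}

#' Simulate a collection of pooled viability screens
#'
#' Plasmid abundance per guide is log-normal; the expected endpoint count is
#' `plasmid_mean * 2^(efficacy * gene_effect + toxic_effect + dsb_effect)`
#' where the gene effect is `essential_effect` for essential genes and 0
#' otherwise, the toxic effect applies to the rare toxic guides regardless of
#' their target, and the double-strand-break cost applies to every cutting
#' guide (gene-targeting and targeting controls). Counts are drawn
#' negative-binomial with the configured dispersion; the plasmid sample
#' carries no treatment effect. Fully reproducible given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `screens` (named list of `count_matrix`, samples
#'   `plasmid`, `T14_R1`, ...) and `truth` (list of `genes`, `guides`,
#'   `screens` tibbles).
#' @export
simulate_screen_collection <- function(cfg = simulation_config()) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  n_ess <- round(cfg$essential_fraction * cfg$n_genes)
  essential <- sort(sample(genes, n_ess))
  gene_tbl <- tibble::tibble(gene = genes, essential = genes %in% essential)

  gt <- tidyr::expand_grid(gene = genes, g = seq_len(cfg$guides_per_gene)) |>
    dplyr::mutate(sgrna = paste0(.data$gene, "_g", .data$g),
                  control_class = "gene_targeting")
  nt <- tibble::tibble(sgrna = sprintf("nt_ctrl_%03d", seq_len(cfg$n_nontargeting)),
                       gene = .NON_TARGETING_LABEL,
                       control_class = "non_targeting_control")
  tc <- tibble::tibble(sgrna = sprintf("tgt_ctrl_%03d", seq_len(cfg$n_targeting)),
                       gene = .TARGETING_CTRL_LABEL,
                       control_class = "targeting_control")
  guides <- dplyr::bind_rows(dplyr::select(gt, "sgrna", "gene", "control_class"),
                             nt, tc)
  n_gt <- nrow(gt)
  guides$seq <- random_guide_seqs(nrow(guides))
  guides$efficacy <- c(rbeta(n_gt, cfg$efficacy_shape1, cfg$efficacy_shape2),
                       rep(0, cfg$n_nontargeting), rep(1, cfg$n_targeting))
  guides$toxic <- c(rbinom(n_gt, 1, cfg$toxic_offtarget_rate) == 1,
                    rep(FALSE, cfg$n_nontargeting + cfg$n_targeting))
  guides$essential_gene <- guides$gene %in% essential

  cuts <- guides$control_class %in% c("gene_targeting", "targeting_control")
  gene_effect <- ifelse(guides$essential_gene, cfg$essential_effect, 0)
  log2_effect <- guides$efficacy * gene_effect * cuts +
    cfg$toxic_effect * guides$toxic +
    cfg$targeting_dsb_effect * cuts
  # non-targeting controls: efficacy 0 and no DSB cost -> effect 0 by the
  # lines above

  abundance <- rlnorm(nrow(guides), meanlog = 0, sdlog = 0.5)
  plasmid_mu <- abundance / sum(abundance) * cfg$sequencing_depth
  size <- 1 / cfg$nb_dispersion

  screens <- list()
  for (sc in seq_len(cfg$n_screens)) {
    tab <- dplyr::select(guides, "sgrna", "gene", "control_class")
    tab$plasmid <- rnbinom(nrow(guides), mu = plasmid_mu, size = size)
    for (r in seq_len(cfg$n_replicates)) {
      tab[[paste0("T14_R", r)]] <- rnbinom(nrow(guides),
                                           mu = plasmid_mu * 2^log2_effect,
                                           size = size)
    }
    id <- sprintf("screen%02d", sc)
    screens[[id]] <- count_matrix(tab, meta = list(screen = id))
  }

  truth <- list(
    genes = gene_tbl,
    guides = dplyr::select(guides, "sgrna", "gene", "control_class", "seq",
                           "efficacy", "toxic"),
    screens = tibble::tibble(screen = names(screens),
                             essential_genes = list(essential))
  )
  list(screens = screens, truth = truth)
}

#' Simulate a random genome with annotation and planted off-target sites
#'
#' Generates one random chromosome, places `n_genes` non-overlapping genes
#' (one transcript each, `exons_per_gene` exons), extracts one NGG-adjacent
#' candidate guide per gene from its first exon where possible, and plants
#' additional copies of selected guide sites in intergenic space with 0-4
#' substitutions, yielding known off-target counts at a 3-mismatch budget.
#'
#' @param n_genes Genes to place.
#' @param exons_per_gene Exons per gene (default 2).
#' @param genome_length Chromosome length in bp.
#' @param planted_duplications Number of guide sites to duplicate.
#' @param seed Integer seed.
#' @return A list: `genome` (`DNAStringSet`), `annotation` (exon tibble as
#'   from [read_annotation()]), `guides` (tibble `sgrna`, `seq`, `gene`),
#'   `truth` (tibble `sgrna`, `seq`, `planted_mm`, `offtarget_truth`).
#' @export
simulate_genome <- function(n_genes = 10L, exons_per_gene = 2L,
                            genome_length = 20000L, planted_duplications = 3L,
                            seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  exon_len <- 120L
  gene_span <- exons_per_gene * exon_len + (exons_per_gene - 1) * 60L
  slot <- gene_span + 200L
  if (n_genes * slot + planted_duplications * 40L > genome_length) {
    abort("infeasible packing: genome too short for the requested genes")
  }
  base <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3))
  seq <- paste(base, collapse = "")

  exons <- list(); txs <- list(); gguides <- list()
  for (i in seq_len(n_genes)) {
    gene <- sprintf("g%03d", i)
    tx <- paste0(gene, ".t1")
    gstart0 <- (i - 1L) * slot + 100L
    ex_starts <- gstart0 + (seq_len(exons_per_gene) - 1L) * (exon_len + 60L)
    exons[[i]] <- tibble::tibble(
      chrom = "chr1", start0 = ex_starts, end0 = ex_starts + exon_len,
      strand = "+", transcript = tx, gene = gene,
      exon_rank = seq_len(exons_per_gene))
    txs[[i]] <- tibble::tibble(
      transcript = tx, gene = gene, chrom = "chr1", strand = "+",
      start0 = ex_starts[1], end0 = ex_starts[exons_per_gene] + exon_len,
      tss0 = ex_starts[1])
    # engineer one NGG-adjacent candidate in exon 1: set a GG at a fixed spot
    p0 <- ex_starts[1] + 30L  # protospacer start, 0-based
    substr(seq, p0 + 22L, p0 + 23L) <- "GG"  # PAM GG, 1-based
    gseq <- substr(seq, p0 + 1L, p0 + 20L)
    gguides[[i]] <- tibble::tibble(sgrna = paste0(gene, "_guide"), seq = gseq,
                                   gene = gene)
  }
  ann <- dplyr::bind_rows(exons)
  attr(ann, "transcripts") <- dplyr::bind_rows(txs)
  guides <- dplyr::bind_rows(gguides)

  # plant near-match copies of the first few guides in intergenic tail space
  tail_start0 <- n_genes * slot + 50L
  truth <- tibble::tibble(sgrna = guides$sgrna, seq = guides$seq,
                          planted_mm = NA_integer_, offtarget_truth = 0L)
  mm_cycle <- c(0L, 1L, 2L, 3L, 4L)
  for (j in seq_len(min(planted_duplications, nrow(guides)))) {
    mm <- mm_cycle[(j - 1L) %% length(mm_cycle) + 1L]
    g <- strsplit(guides$seq[j], "")[[1]]
    if (mm > 0) {
      pos <- sample(20L, mm)
      for (p in pos) g[p] <- sample(setdiff(c("A", "C", "G", "T"), g[p]), 1)
    }
    at0 <- tail_start0 + (j - 1L) * 40L
    if (at0 + 20L > genome_length) abort("infeasible packing: no room for planted sites")
    substr(seq, at0 + 1L, at0 + 20L) <- paste(g, collapse = "")
    truth$planted_mm[j] <- mm
    truth$offtarget_truth[j] <- as.integer(mm <= 3L)
  }
  genome <- Biostrings::DNAStringSet(setNames(seq, "chr1"))
  list(genome = genome, annotation = ann, guides = guides, truth = truth)
}

#' Write a genome and annotation to FASTA + GFF3-like files
#'
#' @param genome A `DNAStringSet`.
#' @param annotation Exon tibble with a `transcripts` attribute.
#' @param fasta,gff Output paths.
#' @return Invisibly, `c(fasta, gff)`.
#' @export
write_genome_files <- function(genome, annotation, fasta, gff) {
  Biostrings::writeXStringSet(genome, fasta)
  tx <- attr(annotation, "transcripts")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(tx))) {
    lines <- c(lines,
      paste(tx$chrom[i], "guidescreen", "gene", tx$start0[i] + 1L, tx$end0[i],
            ".", tx$strand[i], ".",
            paste0("ID=", tx$gene[i], ";gene_id=", tx$gene[i]), sep = "\t"),
      paste(tx$chrom[i], "guidescreen", "mRNA", tx$start0[i] + 1L, tx$end0[i],
            ".", tx$strand[i], ".",
            paste0("ID=", tx$transcript[i], ";Parent=", tx$gene[i],
                   ";gene_id=", tx$gene[i]), sep = "\t"))
  }
  ex <- tibble::as_tibble(annotation)
  for (i in seq_len(nrow(ex))) {
    lines <- c(lines,
      paste(ex$chrom[i], "guidescreen", "exon", ex$start0[i] + 1L, ex$end0[i],
            ".", ex$strand[i], ".",
            paste0("ID=", ex$transcript[i], ".e", ex$exon_rank[i],
                   ";Parent=", ex$transcript[i], ";gene_id=", ex$gene[i]),
            sep = "\t"))
  }
  writeLines(lines, gff)
  invisible(c(fasta, gff))
}
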