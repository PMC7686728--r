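# Fixture builders and independent brute-force oracles used across tests.

# small count matrix with explicit targeting / non-targeting controls
make_counts <- function(genes = c("A", "A", "B", "B"),
                        plasmid = c(100L, 200L, 150L, 120L),
                        T14 = c(10L, 20L, 150L, 110L),
                        n_tc = 3L, n_nt = 2L,
                        ctrl_plasmid = NULL, ctrl_T14 = NULL) {
  n <- length(genes)
  gt <- tibble::tibble(
    sgrna = paste0("g", seq_len(n)), gene = genes,
    plasmid = plasmid, T14 = T14)
  nc <- n_tc + n_nt
  if (is.null(ctrl_plasmid)) ctrl_plasmid <- rep(100L, nc)
  if (is.null(ctrl_T14)) ctrl_T14 <- rep(100L, nc)
  ctrl <- tibble::tibble(
    sgrna = c(sprintf("tc%d", seq_len(n_tc)), sprintf("nt%d", seq_len(n_nt))),
    gene = c(rep("TARGETING_CTRL", n_tc), rep("NON_TARGETING", n_nt)),
    plasmid = ctrl_plasmid, T14 = ctrl_T14)
  count_matrix(dplyr::bind_rows(gt, ctrl))
}

# brute-force Hamming scan over both strands of a genome (vectorised over
# window positions, but still a direct position-by-position comparison)
oracle_offtargets <- function(seq, genome_chars, max_mm = 3) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  count_hits <- function(pat, s) {
    p <- utf8ToInt(pat)
    sv <- utf8ToInt(s)
    nw <- length(sv) - 19L
    if (nw < 1) return(c(0L, 0L))
    mm <- integer(nw)
    for (j in 1:20) mm <- mm + (sv[j:(j + nw - 1L)] != p[j])
    c(sum(mm <= max_mm), sum(mm == 0))
  }
  tot <- c(0L, 0L)
  for (chrom in genome_chars) {
    tot <- tot + count_hits(seq, chrom) + count_hits(revcomp(seq), chrom)
  }
  max(tot[1] - (tot[2] > 0), 0L)
}

# exhaustive threshold-scan PR-AUC on a small labelled instance
oracle_pr_auc <- function(bf, is_pos) {
  o <- order(bf, decreasing = TRUE)
  bf <- bf[o]; y <- as.integer(is_pos[o])
  n_pos <- sum(y)
  block_end <- which(!duplicated(bf, fromLast = TRUE))
  tp <- cumsum(y)[block_end]; fp <- cumsum(1 - y)[block_end]
  rec <- c(0, tp / n_pos); prec <- c(1, tp / (tp + fp))
  sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
}

# direct per-gene z computation for the outlier flags
oracle_outlier_flags <- function(scores, genes, z_cut = 1.25, min_n = 3) {
  flag <- logical(length(scores))
  for (g in unique(genes)) {
    idx <- which(genes == g)
    if (length(idx) < min_n) next
    s <- sd(scores[idx])
    if (is.na(s) || s == 0) next
    z <- (scores[idx] - mean(scores[idx])) / s
    flag[idx] <- abs(z) > z_cut
  }
  flag
}

# closed-form normal log2 likelihood-ratio (essential vs nonessential)
oracle_normal_llr <- function(x, mu_e, sd_e, mu_n, sd_n) {
  log2(dnorm(x, mu_e, sd_e) / dnorm(x, mu_n, sd_n))
}

random_guide_seqs_test <- function(n) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
}

# candidate table with neutral annotation/flag columns for rank_candidates()
make_candidates <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sgrna = paste0("g", seq_len(n)),
    seq = random_guide_seqs_test(n),
    gene = "G1",
    n_active = 0L, active_fraction = 0,
    empirical_essential_eligible = FALSE,
    n_transcripts = 1L, tss_distance = 100L, offtarget_count = 0L,
    any_flag = FALSE, offtarget_outlier = FALSE)
}

# per-gene ranked lists plus a control pool for assemble_library()
make_design_inputs <- function(n_genes = 2, per_gene = 8, n_nt = 300, n_tc = 135,
                               seed = 6) {
  set.seed(seed)
  ranked <- list()
  for (i in seq_len(n_genes)) {
    g <- paste0("G", i)
    ranked[[g]] <- tibble::tibble(
      seq = random_guide_seqs_test(per_gene),
      category = rep("empirical_essential", per_gene))
  }
  controls <- tibble::tibble(
    sgrna = c(sprintf("nt%d", seq_len(n_nt)), sprintf("tc%d", seq_len(n_tc))),
    seq = random_guide_seqs_test(n_nt + n_tc),
    control_class = c(rep("non_targeting_control", n_nt),
                      rep("targeting_control", n_tc)))
  list(ranked = ranked, controls = controls)
}

random_fc_tbl <- function(n, genes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) genes <- paste0("G", seq_len(n))
  tibble::tibble(sgrna = paste0("g", seq_len(n)), gene = genes,
                 fc = rnorm(n))
}
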