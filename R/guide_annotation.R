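# Sequence-level guide filters, mismatch off-target counting and
# exon/transcript/TSS annotation against a genome + GFF-like annotation.
#
# Coordinates are 0-based half-open internally; the GFF-like reader converts
# from 1-based closed input.

.GUIDE_LEN <- 20L
.BBSI <- c("GAAGAC", "GTCTTC")

check_guide_seq <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) != .GUIDE_LEN) abort("guide sequence must be 20 nt")
  if (grepl("[^ACGT]", seq)) abort(paste0("invalid guide alphabet in ", seq))
  seq
}

#' Sequence-level filter flags for a guide
#'
#' Flags the sequence features excluded from library design: homopolymer
#' stretches (4 or more consecutive A or T, 5 or more consecutive G or C),
#' BbsI recognition sites (GAAGAC or its reverse complement GTCTTC, which
#' would interfere with library cloning), and extreme GC content (strictly
#' above 75% or strictly below 20%).
#'
#' @param seq A 20-nt guide sequence (character scalar or vector); case
#'   insensitive.
#' @return A tibble with one row per input: `seq`, `gc_fraction`,
#'   `homopolymer`, `bbsi_site`, `gc_out_of_range`, `any_flag`.
#' @export
sequence_flags <- function(seq) {
  seq <- vapply(seq, check_guide_seq, character(1), USE.NAMES = FALSE)
  gc <- (stringr::str_count(seq, "G") + stringr::str_count(seq, "C")) / .GUIDE_LEN
  homopolymer <- grepl("A{4,}|T{4,}|G{5,}|C{5,}", seq)
  bbsi <- grepl(paste(.BBSI, collapse = "|"), seq)
  gc_out <- gc > 0.75 | gc < 0.20
  tibble::tibble(seq = seq, gc_fraction = gc, homopolymer = homopolymer,
                 bbsi_site = bbsi, gc_out_of_range = gc_out,
                 any_flag = homopolymer | bbsi | gc_out)
}

#' Read a genome from FASTA
#' @param path FASTA file path.
#' @return A named `Biostrings::DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) {
    if (length(genome) == 1 && file.exists(genome)) return(read_genome(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  abort("genome must be a DNAStringSet, a FASTA path, or named sequences")
}

#' Count near-match off-target sites of a guide in a genome
#'
#' Counts genomic 20-mers on either strand that differ from the guide by at
#' most `max_mm` substitutions, subtracting one on-target occurrence when the
#' guide matches somewhere exactly. No PAM is required by default, mirroring
#' alignment-based off-target prediction with a fixed mismatch budget; set
#' `require_pam = TRUE` to count only sites followed by NGG.
#'
#' @param seq A 20-nt guide sequence.
#' @param genome A `DNAStringSet`, FASTA path or named character vector.
#' @param max_mm Maximum substitutions (default 3).
#' @param require_pam Require an NGG immediately 3' of the protospacer
#'   (default `FALSE`).
#' @return Non-negative integer off-target count.
#' @export
count_offtargets <- function(seq, genome, max_mm = 3L, require_pam = FALSE) {
  seq <- check_guide_seq(seq)
  genome <- as_genome(genome)
  pat_f <- Biostrings::DNAString(seq)
  pat_r <- Biostrings::reverseComplement(pat_f)
  n_hits <- 0L
  n_exact <- 0L
  for (i in seq_along(genome)) {
    chrom <- genome[[i]]
    if (!require_pam) {
      n_hits <- n_hits +
        Biostrings::countPattern(pat_f, chrom, max.mismatch = max_mm) +
        Biostrings::countPattern(pat_r, chrom, max.mismatch = max_mm)
    } else {
      mf <- Biostrings::matchPattern(pat_f, chrom, max.mismatch = max_mm)
      mr <- Biostrings::matchPattern(pat_r, chrom, max.mismatch = max_mm)
      n_hits <- n_hits + sum(has_pam(chrom, IRanges::end(mf), "+")) +
        sum(has_pam(chrom, IRanges::start(mr), "-"))
    }
    n_exact <- n_exact +
      Biostrings::countPattern(pat_f, chrom, max.mismatch = 0) +
      Biostrings::countPattern(pat_r, chrom, max.mismatch = 0)
  }
  max(n_hits - (n_exact > 0), 0L)
}

# is there an NGG immediately 3' of a protospacer match? `pos` is the 1-based
# match end (+) or start (-)
has_pam <- function(chrom, pos, strand) {
  L <- length(chrom)
  vapply(pos, function(p) {
    if (strand == "+") {
      p + 3 <= L && substr(as.character(chrom), p + 2, p + 3) == "GG"
    } else {
      p - 3 >= 1 && substr(as.character(chrom), p - 3, p - 2) == "CC"
    }
  }, logical(1))
}

#' Read a GFF3-like annotation into a tidy exon table
#'
#' Accepts the minimal gene/mRNA/exon dialect this package writes: 9 tab
#' columns, 1-based closed coordinates, attributes `ID`, `Parent` and
#' `gene_id`. Coordinates are converted to 0-based half-open.
#'
#' @param path GFF file path.
#' @return A tibble of exons: `chrom`, `start0`, `end0`, `strand`, `gene`,
#'   `transcript`, `exon_rank`, plus a transcript table attribute
#'   `transcripts` (`transcript`, `gene`, `chrom`, `strand`, `start0`,
#'   `end0`, `tss0`).
#' @export
read_annotation <- function(path) {
  gff <- readr::read_tsv(path, comment = "#",
                         col_names = c("chrom", "source", "type", "start", "end",
                                       "score", "strand", "phase", "attributes"),
                         col_types = "ccciicccc", progress = FALSE)
  attr_field <- function(a, key) {
    m <- stringr::str_match(a, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  tx <- dplyr::filter(gff, .data$type %in% c("mRNA", "transcript")) |>
    dplyr::transmute(
      transcript = attr_field(.data$attributes, "ID"),
      gene = attr_field(.data$attributes, "gene_id"),
      chrom = .data$chrom, strand = .data$strand,
      start0 = .data$start - 1L, end0 = .data$end
    ) |>
    dplyr::mutate(tss0 = ifelse(.data$strand == "+", .data$start0, .data$end0 - 1L))
  ex <- dplyr::filter(gff, .data$type == "exon") |>
    dplyr::transmute(
      chrom = .data$chrom,
      start0 = .data$start - 1L, end0 = .data$end,
      strand = .data$strand,
      transcript = attr_field(.data$attributes, "Parent"),
      gene = attr_field(.data$attributes, "gene_id")
    )
  # exon rank: order along transcript direction
  ex <- ex |>
    dplyr::group_by(.data$transcript) |>
    dplyr::arrange(.data$start0, .by_group = TRUE) |>
    dplyr::mutate(exon_rank = if (dplyr::first(.data$strand) == "+")
      dplyr::row_number() else rev(dplyr::row_number())) |>
    dplyr::ungroup()
  structure(ex, transcripts = tx)
}

#' Annotate a guide with its genomic context
#'
#' Locates the guide's unique exact genomic match, places the cut site between
#' protospacer positions 17 and 18 (3 bp from the PAM-proximal end), and
#' derives: the rank of the containing coding exon within the gene's longest
#' annotated transcript, the number of transcripts with an exon overlapping
#' the cut site, and the distance to that longest transcript's transcription
#' start site. Intergenic guides are returned with `n_transcripts = 0` and
#' `NA` gene.
#'
#' @param seq A 20-nt guide sequence.
#' @param genome A `DNAStringSet` or FASTA path.
#' @param annotation An exon table from [read_annotation()] (or built by
#'   [simulate_genome()]).
#' @return A one-row tibble: `seq`, `chrom`, `match_start0`, `cut_pos`,
#'   `strand`, `gene`, `exon_rank`, `n_transcripts`, `tss_distance`.
#' @export
annotate_guide <- function(seq, genome, annotation) {
  seq <- check_guide_seq(seq)
  genome <- as_genome(genome)
  pat_f <- Biostrings::DNAString(seq)
  pat_r <- Biostrings::reverseComplement(pat_f)
  hits <- list()
  for (i in seq_along(genome)) {
    for (str in c("+", "-")) {
      m <- Biostrings::matchPattern(if (str == "+") pat_f else pat_r, genome[[i]])
      if (length(m) > 0) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          chrom = names(genome)[i], start0 = IRanges::start(m) - 1L, strand = str)
      }
    }
  }
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) abort("unmappable guide: no exact genomic match")
  if (nrow(hits) > 1) abort("ambiguous on-target: multiple exact genomic matches")
  start0 <- hits$start0; strand <- hits$strand; chrom <- hits$chrom
  # cut between protospacer positions 17|18: 3 bp from the PAM-proximal end
  cut_pos <- if (strand == "+") start0 + 17L else start0 + 3L

  ex <- annotation
  tx <- attr(annotation, "transcripts")
  over <- dplyr::filter(ex, .data$chrom == .env$chrom,
                        .data$start0 <= .env$cut_pos, .data$end0 > .env$cut_pos)
  if (nrow(over) == 0) {
    return(tibble::tibble(seq = seq, chrom = chrom, match_start0 = start0,
                          cut_pos = cut_pos, strand = strand, gene = NA_character_,
                          exon_rank = NA_integer_, n_transcripts = 0L,
                          tss_distance = NA_integer_))
  }
  gene <- over$gene[[1]]
  n_tx <- length(unique(over$transcript))
  gene_tx <- dplyr::filter(tx, .data$gene == .env$gene) |>
    dplyr::mutate(len = .data$end0 - .data$start0) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$transcript)
  longest <- gene_tx$transcript[[1]]
  in_longest <- dplyr::filter(over, .data$transcript == .env$longest)
  exon_rank <- if (nrow(in_longest) > 0) in_longest$exon_rank[[1]] else NA_integer_
  tss0 <- gene_tx$tss0[[1]]
  tibble::tibble(seq = seq, chrom = chrom, match_start0 = start0,
                 cut_pos = cut_pos, strand = strand, gene = gene,
                 exon_rank = exon_rank, n_transcripts = n_tx,
                 tss_distance = abs(cut_pos - tss0))
}

#' Annotate many guides at once
#'
#' @param guides Tibble with columns `sgrna` and `seq`.
#' @inheritParams annotate_guide
#' @return A tibble with one row per guide (annotation columns as in
#'   [annotate_guide()], plus `offtarget_count`).
#' @param max_mm Mismatch budget for off-target counting.
#' @export
annotate_guides <- function(guides, genome, annotation, max_mm = 3L) {
  genome <- as_genome(genome)
  purrr::pmap_dfr(guides[, c("sgrna", "seq")], function(sgrna, seq) {
    ctx <- annotate_guide(seq, genome, annotation)
    dplyr::mutate(ctx, sgrna = sgrna,
                  offtarget_count = count_offtargets(seq, genome, max_mm = max_mm),
                  .before = 1)
  })
}
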