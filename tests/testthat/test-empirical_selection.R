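# Activity labelling, aggregation, outlier flags, ranking, assembly.

test_that("active labels match a sort-based quantile oracle", {
  fc <- tibble::tibble(sgrna = paste0("g", 1:10),
                       gene = paste0("G", 1:10),
                       fc = c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4))
  ess <- paste0("G", 1:10)
  lab <- label_active(fc, ess)
  thr <- quantile(fc$fc, 0.20, type = 7)
  expect_equal(lab$active, fc$fc <= thr)
  expect_equal(sum(lab$active), 2)  # the two most depleted guides

  # most-depleted guide of a non-essential gene stays inactive
  lab2 <- label_active(fc, setdiff(ess, "G1"))
  expect_false(lab2$active[1])

  # essential guide ranked 3rd of 10 is above the 20% quantile -> inactive
  expect_false(lab$active[3])

  # ties at the threshold count as active
  fc_t <- tibble::tibble(sgrna = paste0("g", 1:5), gene = paste0("G", 1:5),
                         fc = c(-1, -1, -1, -1, -1))
  expect_true(all(label_active(fc_t, paste0("G", 1:5))$active))
  expect_error(label_active(fc[0, ], ess), "empty")
})

test_that("activity aggregates with an inclusive 5% eligibility boundary", {
  mk <- function(active) tibble::tibble(sgrna = "g1", gene = "G1", fc = 0,
                                        active = active)
  labels40 <- lapply(c(rep(TRUE, 2), rep(FALSE, 38)), mk)
  agg <- aggregate_activity(labels40)
  expect_equal(agg$n_used, 40)
  expect_equal(agg$active_fraction, 0.05)
  expect_true(agg$empirical_essential_eligible)  # exactly at the boundary

  labels1 <- lapply(c(TRUE, rep(FALSE, 39)), mk)
  expect_false(aggregate_activity(labels1)$empirical_essential_eligible)  # 0.025
})

test_that("outlier flags reproduce the hand z computation and degenerate rules", {
  es <- tibble::tibble(sgrna = paste0("g", 1:4), gene = "G1",
                       score = c(0, 0, 0, -10))
  out <- flag_offtarget_outliers(es)
  expect_equal(out$effect_z[4], (-10 - (-2.5)) / 5)  # z = -1.5
  expect_equal(out$offtarget_outlier, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$effect_z[1], 0.5)

  const <- tibble::tibble(sgrna = paste0("g", 1:4), gene = "G1", score = rep(2, 4))
  expect_false(any(flag_offtarget_outliers(const)$offtarget_outlier))

  two <- tibble::tibble(sgrna = c("g1", "g2"), gene = "G1", score = c(100, -100))
  expect_false(any(flag_offtarget_outliers(two)$offtarget_outlier))
})

test_that("outlier flags equal the brute-force per-gene z oracle on random tables", {
  set.seed(14)
  for (i in 1:10) {
    n <- 60
    es <- tibble::tibble(sgrna = paste0("g", 1:n),
                         gene = sample(paste0("G", 1:12), n, replace = TRUE),
                         score = round(rnorm(n), 2))
    got <- flag_offtarget_outliers(es)
    expect_identical(got$offtarget_outlier,
                     oracle_outlier_flags(es$score, es$gene))
  }
})

test_that("candidate ranking orders by activity, then annotation, then sequence", {
  x <- make_candidates(8)
  x$empirical_essential_eligible <- TRUE
  x$n_active <- c(5L, 40L, 12L, 33L, 1L, 8L, 21L, 17L)
  x$active_fraction <- x$n_active / 50
  r <- rank_candidates(x)
  expect_equal(r$n_active, sort(x$n_active, decreasing = TRUE))
  expect_true(all(r$category == "empirical_essential"))
  expect_equal(r$rank, 1:8)

  # inactive candidates: ordered by off-target count when all else ties
  y <- make_candidates(3, seed = 2)
  y$offtarget_count <- c(5L, 0L, 2L)
  r2 <- rank_candidates(y)
  expect_equal(r2$offtarget_count, c(0L, 2L, 5L))
  expect_true(all(r2$category == "empirical_nonessential"))

  # flagged candidates are dropped even with the best activity
  z <- make_candidates(4, seed = 3)
  z$empirical_essential_eligible[1] <- TRUE
  z$n_active[1] <- 100L
  z$any_flag[1] <- TRUE
  z$offtarget_outlier[2] <- TRUE
  r3 <- rank_candidates(z)
  expect_false(any(c(z$sgrna[1], z$sgrna[2]) %in% r3$sgrna))

  # essential-eligible guides always precede the rest
  w <- make_candidates(4, seed = 4)
  w$empirical_essential_eligible[3] <- TRUE
  w$n_active[3] <- 2L
  expect_equal(rank_candidates(w)$sgrna[1], "g3")
})

test_that("de novo design enumerates PAM-adjacent guides in exon order", {
  sim <- simulate_genome(n_genes = 3, exons_per_gene = 2, genome_length = 9000,
                         planted_duplications = 0, seed = 12)
  cand <- design_de_novo("g001", sim$genome, sim$annotation)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$category == "de_novo"))
  expect_true(all(diff(cand$exon_rank) >= 0))
  flags <- sequence_flags(cand$seq)
  expect_false(any(flags$any_flag))
  # every candidate is a genomic 20-mer next to an NGG on some strand
  for (i in seq_len(min(3, nrow(cand)))) {
    expect_equal(count_offtargets(cand$seq[i], sim$genome, max_mm = 0), 0)
  }
  expect_equal(nrow(design_de_novo("missing", sim$genome, sim$annotation)), 0)
})

test_that("assembled sub-libraries have the documented sizes and shared controls", {
  inp <- make_design_inputs(n_genes = 2)
  d <- assemble_library(inp$ranked, controls = inp$controls)
  # 2 genes x 4 guides + 300 + 135 controls = 443 entries per sub-library
  gl <- glance(d)
  expect_equal(gl$total[gl$sublibrary == "A"], 2 * 4 + 300 + 135)
  expect_equal(gl$total[gl$sublibrary == "B"], 443)
  # mutual exclusivity and identical controls
  a <- d$guides$seq[d$guides$sublibrary == "A"]
  b <- d$guides$seq[d$guides$sublibrary == "B"]
  expect_length(intersect(a, b), 0)
  expect_equal(nrow(d$controls), 435)
})

test_that("short candidate lists are backfilled de novo, and failures reported", {
  inp <- make_design_inputs(n_genes = 1, per_gene = 4)
  dn <- list(G1 = tibble::tibble(seq = random_guide_seqs_test(6),
                                 category = "de_novo"))
  d <- assemble_library(inp$ranked, de_novo = dn, controls = inp$controls)
  ga <- d$guides[d$guides$sublibrary == "A", ]
  gb <- d$guides[d$guides$sublibrary == "B", ]
  expect_equal(nrow(ga), 4); expect_equal(nrow(gb), 4)
  expect_true(all(ga$category == "empirical_essential"))  # A gets the ranked 4
  expect_true(all(gb$category == "de_novo"))              # B backfilled
  expect_equal(nrow(d$failed_genes), 0)

  # a gene that cannot be filled is reported, not fatal
  inp2 <- make_design_inputs(n_genes = 1, per_gene = 3)
  d2 <- assemble_library(inp2$ranked, controls = inp2$controls)
  expect_equal(d2$failed_genes$gene, "G1")
  expect_equal(nrow(d2$guides), 0)

  # duplicate sequences within a sub-library are a hard error
  inp3 <- make_design_inputs(n_genes = 2)
  inp3$ranked$G2$seq[1] <- inp3$ranked$G1$seq[1]
  expect_error(assemble_library(inp3$ranked, controls = inp3$controls),
               "duplicate sequence")
})

test_that("provenance fractions sum to one and match constructed splits", {
  inp <- make_design_inputs(n_genes = 25, per_gene = 8)
  # engineer a 42/54/4 percent split of categories within sub-library A:
  # ranks 1-4 of 25 genes = 100 guides
  cats <- c(rep("empirical_essential", 42), rep("empirical_nonessential", 54),
            rep("de_novo", 4))
  k <- 0
  for (g in names(inp$ranked)) {
    inp$ranked[[g]]$category[1:4] <- cats[k + 1:4]
    k <- k + 4
  }
  d <- assemble_library(inp$ranked, controls = inp$controls)
  ps <- provenance_summary(d)
  a <- ps[ps$sublibrary == "A", ]
  expect_equal(sum(a$fraction), 1)
  expect_equal(a$fraction[a$category == "empirical_essential"], 0.42)
  expect_equal(a$fraction[a$category == "empirical_nonessential"], 0.54)
  expect_equal(a$fraction[a$category == "de_novo"], 0.04)
  expect_error(provenance_summary(structure(list(
    guides = tibble::tibble()), class = "library_design")), "empty")
})

test_that("raising the activity floor never grows the empirical-essential pool", {
  set.seed(30)
  mk_label <- function() {
    tibble::tibble(sgrna = paste0("g", 1:50), gene = rep(paste0("G", 1:10), 5),
                   fc = rnorm(50), active = runif(50) < 0.3)
  }
  labels <- replicate(10, mk_label(), simplify = FALSE)
  fractions <- c(0.01, 0.05, 0.2, 0.5)
  counts <- vapply(fractions, function(f) {
    agg <- aggregate_activity(labels, selection_config(min_active_fraction = f))
    sum(agg$empirical_essential_eligible)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("library invariants hold under randomized assembly (fuzz)", {
  set.seed(77)
  for (rep in 1:25) {
    n_genes <- sample(2:6, 1)
    inp <- make_design_inputs(n_genes = n_genes,
                              per_gene = sample(8:12, 1),
                              n_nt = 20, n_tc = 10, seed = rep)
    cfg <- selection_config(n_nontargeting_controls = 20,
                            n_targeting_controls = 10)
    d <- assemble_library(inp$ranked, controls = inp$controls, cfg = cfg)
    g <- d$guides
    expect_equal(nrow(g), n_genes * 8)
    per <- dplyr::count(g, gene, sublibrary)
    expect_true(all(per$n == 4))
    expect_length(intersect(g$seq[g$sublibrary == "A"],
                            g$seq[g$sublibrary == "B"]), 0)
    expect_false(anyDuplicated(c(g$seq[g$sublibrary == "A"], d$controls$seq)) > 0)
  }
})
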