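# Synthetic-data generator: limiting cases, closed-form expectations,
# reproducibility, and truth-ledger consistency.

test_that("zero rates give identical copies everywhere", {
  tax <- toy_taxonomy(4, 0)
  cfg <- simulation_config(seed = 5, n_families = 3,
                           duplication_rate = 0, loss_rate = 0)
  sim <- simulate_proteomes(tax, cfg)
  expect_true(all(vapply(sim$proteomes, length, integer(1)) == 3L))
  for (f in names(sim$truth$root_sequences)) {
    root <- sim$truth$root_sequences[[f]]
    for (org in names(sim$proteomes)) {
      ids <- sim$truth$orthogroups[[f]][[org]]
      expect_equal(unname(as.character(sim$proteomes[[org]][ids])), root)
    }
  }
  expect_equal(nrow(sim$truth$co_ortholog_events), 0L)
})

test_that("saturating loss removes the family and is recorded", {
  tax <- toy_taxonomy(4, 0.1)
  # loss rate so high that every branch loses everything it can
  cfg <- simulation_config(seed = 11, n_families = 2, loss_rate = 5000,
                           duplication_rate = 0)
  sim <- simulate_proteomes(tax, cfg)
  expect_true(all(vapply(sim$proteomes, length, integer(1)) == 0L))
  expect_true(all(sim$truth$events$type == "loss"))
})

test_that("per-branch substitution fraction tracks 1 - exp(-t)", {
  # two-tip star: one branch of length t, one of length 0, no dup/loss
  t <- 0.4
  tree <- ape::read.tree(text = sprintf("(human:%f,org01:0):0;", t))
  tax <- taxonomy(tree)
  cfg <- simulation_config(seed = 13, n_families = 1, root_length = 500,
                           pore_rate_multiplier = 1,
                           duplication_rate = 0, loss_rate = 0)
  sim <- simulate_proteomes(tax, cfg)
  a <- strsplit(as.character(sim$proteomes$human[[1]]), "")[[1]]
  b <- strsplit(as.character(sim$proteomes$org01[[1]]), "")[[1]]
  expect_equal(b, strsplit(sim$truth$root_sequences$fam01, "")[[1]])
  p <- 1 - exp(-t)
  obs <- sum(a != b)
  ci <- qbinom(c(0.005, 0.995), 500, p)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
})

test_that("the pore subregion diverges more slowly than the flanks", {
  tax <- toy_taxonomy(4, 0.5)
  cfg <- simulation_config(seed = 17, n_families = 8,
                           pore_rate_multiplier = 0.3,
                           duplication_rate = 0, loss_rate = 0)
  sim <- simulate_proteomes(tax, cfg)
  pore <- cfg$pore_region
  ident <- function(x, y, idx) mean(x[idx] == y[idx])
  inside <- outside <- numeric(0)
  for (f in names(sim$truth$root_sequences)) {
    root <- strsplit(sim$truth$root_sequences[[f]], "")[[1]]
    for (org in names(sim$proteomes)) {
      ids <- sim$truth$orthogroups[[f]][[org]]
      for (id in ids) {
        tipseq <- strsplit(as.character(sim$proteomes[[org]][id]), "")[[1]]
        inside <- c(inside, ident(root, tipseq, pore[1]:pore[2]))
        outside <- c(outside, ident(root, tipseq,
                                    setdiff(seq_along(root),
                                            pore[1]:pore[2])))
      }
    }
  }
  expect_gt(mean(inside), mean(outside))
})

test_that("gene counts at tips equal births minus losses along each path", {
  tax <- toy_taxonomy(8, 0.3)
  cfg <- simulation_config(seed = 23, n_families = 10,
                           duplication_rate = 0.4, loss_rate = 0.4)
  sim <- simulate_proteomes(tax, cfg)
  ev <- sim$truth$events
  for (f in names(sim$truth$orthogroups)) {
    for (org in names(sim$proteomes)) {
      path <- c(tax$lineage[[org]], org)  # clades passed plus the tip
      onpath <- ev[ev$family == f & ev$edge_child %in% path, , drop = FALSE]
      expected <- 1 +
        sum(onpath$count[onpath$type == "duplication"]) -
        sum(onpath$count[onpath$type == "loss"])
      expect_equal(length(sim$truth$orthogroups[[f]][[org]]),
                   max(0L, expected))
    }
  }
})

test_that("generation is bitwise reproducible for a fixed config", {
  tax <- toy_taxonomy(4, 0.3)
  cfg <- simulation_config(seed = 31, n_families = 4,
                           duplication_rate = 0.2, loss_rate = 0.2,
                           metadata = list(p_unreviewed = 0.5, p_low_pe = 0.5,
                                           p_fragment = 0.5))
  s1 <- simulate_proteomes(tax, cfg)
  s2 <- simulate_proteomes(tax, cfg)
  expect_identical(lapply(s1$proteomes, as.character),
                   lapply(s2$proteomes, as.character))
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_proteomes(s1, d1)
  write_proteomes(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  md <- make_metadata(c("a", "b", "c"),
                      replicate(3, random_protein(100)))
  expect_identical(corrupt_metadata(md, cfg), corrupt_metadata(md, cfg))
})

test_that("metadata corruption plants exactly what it records", {
  set.seed(3)
  md <- make_metadata(sprintf("acc%02d", 1:40),
                      replicate(40, random_protein(120)))
  cfg0 <- simulation_config(seed = 37)
  clean <- corrupt_metadata(md, cfg0)
  expect_identical(clean$records, md)
  expect_true(all(lengths(clean$truth) == 0))
  expect_true(all(validate_records(clean$records)$passed))

  cfg <- simulation_config(seed = 41, metadata = list(
    p_unreviewed = 0.6, p_low_pe = 0.6, p_fragment = 0.3,
    p_nonstandard = 0.3, p_low_complexity = 0.3, p_high_version = 0.3,
    p_no_crossrefs = 0.3))
  out <- corrupt_metadata(md, cfg)
  for (i in seq_len(nrow(out$records))) {
    planted <- out$truth[[md$accession[i]]]
    rec <- out$records[i, ]
    expect_equal(rec$entry_type == "Unreviewed", "unreviewed" %in% planted)
    expect_equal(rec$protein_existence %in% 4:5, "low_pe" %in% planted)
    if ("fragment" %in% planted && !"low_complexity" %in% planted)
      expect_true(rec$length < 30 || rec$length > 5000)
    expect_equal(rec$sequence_version > 100, "high_version" %in% planted)
    expect_equal(rec$domain_count == 0 & rec$xref_count == 0,
                 "no_crossrefs" %in% planted)
  }
})

test_that("fragment probability 1 fails every unreviewed low-PE record", {
  md <- make_metadata(sprintf("acc%02d", 1:20),
                      replicate(20, random_protein(150)))
  cfg <- simulation_config(seed = 43, metadata = list(
    p_unreviewed = 1, p_low_pe = 1, p_fragment = 1))
  out <- corrupt_metadata(md, cfg)
  v <- validate_records(out$records)
  expect_true(all(!v$passed))
  expect_true(all(v$deciding_step == 3))
  expect_true(all(grepl("length", v$failed_checks)))
})

test_that("planted MSA columns carry the planted signal", {
  cfg <- simulation_config(seed = 47, msa = list(
    n_fg = 40, n_bg = 40, length = 60, n_pattern = 3, strength = 1,
    gap_rate = 0))
  msa <- simulate_pattern_msa(cfg)
  aln <- msa$family$alignment
  fg <- msa$family$labels == "foreground"
  for (r in seq_len(nrow(msa$truth))) {
    col <- aln[fg, msa$truth$column[r]]
    expect_true(all(col %in% strsplit(msa$truth$residues[r], ",")[[1]]))
  }
  # strength < 1: empirical foreground frequency within binomial 99% CI
  cfg2 <- simulation_config(seed = 53, msa = list(
    n_fg = 200, n_bg = 10, length = 40, n_pattern = 4, strength = 0.9,
    gap_rate = 0))
  msa2 <- simulate_pattern_msa(cfg2)
  fg2 <- msa2$family$labels == "foreground"
  for (r in seq_len(nrow(msa2$truth))) {
    col <- msa2$family$alignment[fg2, msa2$truth$column[r]]
    k <- sum(col %in% strsplit(msa2$truth$residues[r], ",")[[1]])
    ci <- qbinom(c(0.005, 0.995), 200, 0.9 + 0.1 / 20)
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }
})

test_that("background term assignment is binomial and planting is recorded", {
  cl <- list(c1 = sprintf("g%03d", 1:30), c2 = sprintf("g%03d", 31:60))
  cfg <- simulation_config(seed = 59, terms = list(
    n_background_terms = 400, p0 = 0.1, p1 = 0.9, planted_per_cluster = 1))
  out <- simulate_term_annotations(cl, cfg)
  expect_setequal(names(out$truth), c("c1", "c2"))
  expect_true(all(grepl("^TP_", unlist(out$truth))))
  bg <- out$term_map[!grepl("^TP_", out$term_map$term), ]
  # total background assignments ~ Binomial(400 * 60, 0.1)
  n <- 400 * 60
  ci <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(nrow(bg), ci[1])
  expect_lte(nrow(bg), ci[2])
  # p1 = p0: nothing planted
  cfg0 <- simulation_config(seed = 61, terms = list(p0 = 0.1, p1 = 0.1))
  out0 <- simulate_term_annotations(cl, cfg0)
  expect_true(all(lengths(out0$truth) == 0))
  expect_false(any(grepl("^TP_", out0$term_map$term)))
})
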