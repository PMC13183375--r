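# Orthology inference: RBH pairing, Markov clustering, evidence
# intersection, relation typing, and the end-to-end pipeline on planted
# truth.

mk_hits <- function(query, target, bit, ev = 10^(-bit / 10)) {
  data.frame(query = query, target = target, raw_score = NA_real_,
             bit_score = bit, evalue = ev, qstart = 1L, qend = 10L,
             tstart = 1L, tend = 10L, pident = 100, align_length = 10L,
             mismatches = 0L, gapopens = 0L, stringsAsFactors = FALSE)
}

test_that("mutual top hits are paired; asymmetric ones are not", {
  params <- orthology_params(forward_evalue_max = 1, reciprocal_evalue_max = 1)
  fwd <- mk_hits(c("q1", "q1"), c("orgA|t1", "orgB|t2"), c(300, 250))
  rec <- mk_hits(c("orgA|t1", "orgB|t2"), c("q1", "q1"), c(300, 250))
  pairs <- reciprocal_best_pairs(fwd, rec, params)
  expect_equal(pairs$query, c("q1", "q1"))
  expect_equal(pairs$target, c("orgA|t1", "orgB|t2"))
  expect_equal(pairs$organism, c("orgA", "orgB"))

  # the target's best reciprocal hit is a different query -> rejected
  rec2 <- rbind(mk_hits("orgA|t1", "q2", 400), mk_hits("orgA|t1", "q1", 300))
  pairs2 <- reciprocal_best_pairs(fwd[1, ], rec2, params)
  expect_equal(nrow(pairs2), 0L)

  # empty inputs give empty output
  expect_equal(nrow(reciprocal_best_pairs(fwd[0, ], rec, params)), 0L)
})

test_that("RBH pairs equal the brute-force double-loop oracle on simulations", {
  s <- small_sim(seed = 303, n_org = 4, n_fam = 5, branch = 0.25)
  queries <- s$sim$proteomes$human
  targets <- s$sim$proteomes[names(s$sim$proteomes) != "human"]
  fwd <- do.call(rbind, lapply(targets, function(db)
    search_all(queries, db, evalue_max = 1e-5)))
  all_targets <- do.call(c, unname(targets))
  rec <- search_all(all_targets, queries, evalue_max = 1e-5)
  params <- orthology_params(reciprocal_evalue_max = 1e-5)
  got <- reciprocal_best_pairs(fwd, rec, params)[, c("query", "target")]
  want <- oracle_rbh(fwd, rec, 1e-5, 1e-5)
  expect_equal(got, want, ignore_attr = TRUE)
  # symmetry: each retained target's best reciprocal is its query
  rec_sorted <- sort_hits(rec)
  best_back <- rec_sorted[!duplicated(rec_sorted$query), ]
  lookup <- stats::setNames(best_back$target, best_back$query)
  expect_true(all(lookup[got$target] == got$query))
})

test_that("Markov clustering separates components and matches the oracle", {
  tri <- function(a, b, c) data.frame(from = c(a, b, a), to = c(b, c, c))
  edges <- rbind(tri("a1", "a2", "a3"), tri("b1", "b2", "b3"))
  cl <- markov_cluster(edges)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[c("a1", "a2", "a3")])), 1L)
  expect_equal(length(unique(cl[c("b1", "b2", "b3")])), 1L)

  single <- markov_cluster(data.frame(from = "x", to = "x"))
  expect_equal(unname(single), "C1")

  set.seed(311)
  for (rep in 1:12) {
    n <- sample(3:8, 1)
    nodes <- paste0("n", seq_len(n))
    ne <- sample(2:(n * 2), 1)
    edges <- data.frame(from = sample(nodes, ne, replace = TRUE),
                        to = sample(nodes, ne, replace = TRUE),
                        weight = sample(1:50, ne, replace = TRUE))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    if (!nrow(edges)) next
    got <- markov_cluster(edges)
    want <- oracle_mcl(edges)
    expect_true(same_partition(got, want))
    # clusters refine connected components
    g <- unique(rbind(as.matrix(edges[, 1:2]),
                      as.matrix(edges[, 2:1])))
    comp <- stats::setNames(seq_along(names(got)), names(got))
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(g))) {
        a <- g[r, 1]; b <- g[r, 2]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[comp == max(comp[a], comp[b])] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    split_by_cluster <- split(names(got), got)
    for (members in split_by_cluster)
      expect_equal(length(unique(comp[members])), 1L)
  }
})

test_that("within-cluster filtering keeps exactly same-cluster pairs", {
  pairs <- data.frame(query = c("q1", "q2", "q3"),
                      target = c("orgA|t1", "orgA|t2", "orgA|t3"),
                      stringsAsFactors = FALSE)
  one <- stats::setNames(rep("C1", 6),
                         c("q1", "q2", "q3", "orgA|t1", "orgA|t2", "orgA|t3"))
  expect_equal(filter_within_cluster(pairs, one)[, 1:2], pairs,
               ignore_attr = TRUE)
  mixed <- one
  mixed["orgA|t2"] <- "C2"
  kept <- filter_within_cluster(pairs, mixed)
  expect_equal(kept$query, c("q1", "q3"))
  expect_error(filter_within_cluster(pairs, one[-4]), "orgA\\|t1")

  set.seed(317)
  for (rep in 1:10) {
    labs <- stats::setNames(sample(c("C1", "C2", "C3"), 6, replace = TRUE),
                            names(one))
    got <- filter_within_cluster(pairs, labs)
    want <- pairs[labs[pairs$query] == labs[pairs$target], , drop = FALSE]
    expect_equal(got$target, want$target)
  }
})

test_that("evidence intersection behaves as set intersection", {
  a <- data.frame(query = c("q1", "q2", "q3"),
                  target = c("o|t1", "o|t2", "o|t3"),
                  stringsAsFactors = FALSE)
  same <- intersect_evidence(a, a)
  expect_equal(same[, 1:2], a, ignore_attr = TRUE)
  expect_true(all(same$evidence == "full_length,domain"))
  expect_equal(nrow(intersect_evidence(a, a[0, ])), 0L)
  set.seed(331)
  for (rep in 1:10) {
    ia <- sample(3, sample(0:3, 1))
    ib <- sample(3, sample(0:3, 1))
    got <- intersect_evidence(a[ia, , drop = FALSE], a[ib, , drop = FALSE])
    expect_setequal(got$query, a$query[intersect(ia, ib)])
    expect_lte(nrow(got), min(length(ia), length(ib)))
  }
})

test_that("relation typing flags duplicate targets as co-orthologs", {
  pairs <- data.frame(query = c("q1", "q1", "q2"),
                      target = c("orgA|t1", "orgA|t2", "orgB|t9"),
                      organism = c("orgA", "orgA", "orgB"),
                      stringsAsFactors = FALSE)
  out <- classify_relation(pairs)
  expect_equal(out$relation, c("co_ortholog", "co_ortholog", "one_to_one"))
  # a target claimed by two queries is a co-ortholog cell for both
  pairs2 <- data.frame(query = c("q1", "q2"), target = c("orgA|t1", "orgA|t1"),
                       organism = c("orgA", "orgA"), stringsAsFactors = FALSE)
  expect_equal(classify_relation(pairs2)$relation,
               c("co_ortholog", "co_ortholog"))
})

test_that("a planted duplicate target is recovered as a co-ortholog pair", {
  set.seed(337)
  base <- random_protein(200)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- sample(channelome:::AA_STANDARD, k, replace = TRUE)
    paste(ch, collapse = "")
  }
  queries <- Biostrings::AAStringSet(c("human|h1" = base))
  proteomes <- list(
    orgA = Biostrings::AAStringSet(c("orgA|t1" = mutate(base, 8),
                                     "orgA|t2" = mutate(base, 8))),
    orgB = Biostrings::AAStringSet(c("orgB|u1" = mutate(base, 8))))
  qd <- data.frame(accession = "human|h1", start = 20L, end = 150L)
  res <- run_orthology(queries, qd, proteomes,
                       params = orthology_params(
                         reciprocal_evalue_max = 1e-5,
                         forward_mode = "all"))
  cellA <- res$pairs[res$pairs$organism == "orgA", ]
  expect_setequal(cellA$target, c("orgA|t1", "orgA|t2"))
  expect_true(all(cellA$relation == "co_ortholog"))
  cellB <- res$pairs[res$pairs$organism == "orgB", ]
  expect_equal(cellB$relation, "one_to_one")
})

test_that("zero-divergence simulations are recovered perfectly", {
  tax <- toy_taxonomy(4, 0)
  cfg <- simulation_config(seed = 347, n_families = 4,
                           duplication_rate = 0, loss_rate = 0)
  sim <- simulate_proteomes(tax, cfg)
  queries <- sim$proteomes$human
  targets <- sim$proteomes[names(sim$proteomes) != "human"]
  qd <- data.frame(accession = names(queries),
                   start = cfg$pore_region[1], end = cfg$pore_region[2])
  res <- run_orthology(queries, qd, targets,
                       params = orthology_params(reciprocal_evalue_max = 1e-5))
  # one one-to-one pair per query per organism
  expect_equal(nrow(res$pairs), length(queries) * length(targets))
  expect_true(all(res$pairs$relation == "one_to_one"))
  expect_true(all(res$pairs$evidence == "full_length,domain"))
  fam_of <- function(id) sub("^.*\\|(fam[0-9]+)_g[0-9]+$", "\\1", id)
  expect_true(all(fam_of(res$pairs$query) == fam_of(res$pairs$target)))
})

test_that("a planted fragment target is dropped with a validation reason", {
  set.seed(353)
  base <- random_protein(200)
  queries <- Biostrings::AAStringSet(c("human|h1" = base))
  frag <- substr(base, 1, 150)  # still alignable, but metadata says fragment
  proteomes <- list(orgA = Biostrings::AAStringSet(c("orgA|t1" = base)),
                    orgB = Biostrings::AAStringSet(c("orgB|u1" = base)))
  qd <- data.frame(accession = "human|h1", start = 20L, end = 150L)
  metadata <- make_metadata(c("orgA|t1", "orgB|u1"), c(base, base))
  metadata$entry_type[1] <- "Unreviewed"
  metadata$protein_existence[1] <- 5L
  metadata$sequence[1] <- substr(base, 1, 20)
  metadata$length[1] <- 20L
  res <- run_orthology(queries, qd, proteomes,
                       params = orthology_params(reciprocal_evalue_max = 1e-5),
                       metadata = metadata)
  expect_false("orgA|t1" %in% res$pairs$target)
  expect_true("orgB|u1" %in% res$pairs$target)
  led <- res$dropped[res$dropped$stage == "validation", ]
  expect_equal(led$target, "orgA|t1")
  expect_match(led$reason, "validation: .*length")
})

test_that("relaxing the forward cutoff never removes a retained pair", {
  s <- small_sim(seed = 359, n_org = 4, n_fam = 4, branch = 0.2)
  queries <- s$sim$proteomes$human
  targets <- s$sim$proteomes[names(s$sim$proteomes) != "human"]
  fwd <- do.call(rbind, lapply(targets, function(db)
    search_all(queries, db, evalue_max = Inf)))
  rec <- search_all(do.call(c, unname(targets)), queries, evalue_max = Inf)
  strict <- reciprocal_best_pairs(fwd, rec, orthology_params(
    forward_evalue_max = 1e-20, reciprocal_evalue_max = 1e-5))
  loose <- reciprocal_best_pairs(fwd, rec, orthology_params(
    forward_evalue_max = 1e-5, reciprocal_evalue_max = 1e-5))
  key <- function(p) paste(p$query, p$target)
  expect_true(all(key(strict) %in% key(loose)))
})
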