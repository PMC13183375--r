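# Synthetic-data generator: proteome families evolving on a taxonomy with
# duplication/loss and a slowly evolving pore subregion, metadata records
# with planted integrity defects, alignments with planted foreground-
# conserved columns, and term annotations with planted enrichment. Every
# planting is recorded in a truth ledger so downstream inference can be
# scored exactly.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator, with defaults
#' that represent a moderately diverged set of single-domain membrane
#' proteins: 240-residue proteins whose pore subregion (residues 61-180)
#' evolves at 0.3x the background rate, and sparse duplication/loss at 0.05
#' expected events per unit branch length.
#'
#' @param seed Master seed; each generator stage derives its own stream.
#' @param n_families Number of planted gene families.
#' @param root_length Root protein length (residues).
#' @param pore_region Integer c(start, end): the slowly evolving subregion,
#'   recorded as the planted pore domain of every gene.
#' @param pore_rate_multiplier rho in (0, 1]: per-site substitution
#'   probability inside the pore region is rho times the outside value.
#' @param duplication_rate,loss_rate Expected events per unit branch length.
#' @param background_freqs Named numeric(20) amino-acid profile summing to 1.
#' @param metadata List of corruption probabilities (see
#'   [corrupt_metadata()]).
#' @param msa List of alignment-generator settings (see
#'   [simulate_pattern_msa()]).
#' @param terms List of term-annotation settings (see
#'   [simulate_term_annotations()]).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_families = 20L,
                              root_length = 240L,
                              pore_region = c(61L, 180L),
                              pore_rate_multiplier = 0.3,
                              duplication_rate = 0.05,
                              loss_rate = 0.05,
                              background_freqs = NULL,
                              metadata = list(),
                              msa = list(),
                              terms = list()) {
  if (is.null(background_freqs))
    background_freqs <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  stopifnot(length(background_freqs) == 20,
            abs(sum(background_freqs) - 1) < 1e-9,
            all(background_freqs >= 0),
            pore_rate_multiplier > 0, pore_rate_multiplier <= 1,
            duplication_rate >= 0, loss_rate >= 0,
            root_length >= 1,
            length(pore_region) == 2, pore_region[1] >= 1,
            pore_region[2] <= root_length, pore_region[2] >= pore_region[1])
  md <- utils::modifyList(list(p_unreviewed = 0, p_low_pe = 0, p_fragment = 0,
                               p_nonstandard = 0, p_low_complexity = 0,
                               p_high_version = 0, p_no_crossrefs = 0),
                          metadata)
  stopifnot(all(unlist(md) >= 0), all(unlist(md) <= 1))
  ms <- utils::modifyList(list(n_fg = 50L, n_bg = 200L, length = 120L,
                               n_pattern = 5L, strength = 0.95,
                               set_size = 1L, gap_rate = 0.02),
                          msa)
  stopifnot(ms$n_fg >= 2, ms$n_bg >= 2, ms$length >= 1,
            ms$n_pattern >= 0, ms$n_pattern <= ms$length,
            ms$strength > 0.5, ms$strength <= 1,
            ms$gap_rate >= 0, ms$gap_rate < 1)
  tm <- utils::modifyList(list(n_background_terms = 250L, p0 = 0.1, p1 = 0.9,
                               planted_per_cluster = 1L),
                          terms)
  stopifnot(tm$p0 >= 0, tm$p0 <= 1, tm$p1 >= 0, tm$p1 <= 1)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 root_length = as.integer(root_length),
                 pore_region = as.integer(pore_region),
                 pore_rate_multiplier = pore_rate_multiplier,
                 duplication_rate = duplication_rate, loss_rate = loss_rate,
                 background_freqs = background_freqs,
                 metadata = md, msa = ms, terms = tm),
            class = "simulation_config")
}

.draw_root <- function(len, freqs) {
  sample(names(freqs), len, replace = TRUE, prob = freqs)
}

# Per-site substitution along a branch of length t: each site substitutes
# with probability (1 - exp(-t)), damped by rho inside the pore region;
# replacements are uniform over the 19 other residues.
.evolve_branch <- function(seq, t, pore, rho) {
  if (t <= 0) return(seq)
  p <- 1 - exp(-t)
  prob <- rep(p, length(seq))
  prob[pore[1]:pore[2]] <- p * rho
  hit <- which(stats::runif(length(seq)) < prob)
  for (i in hit) {
    alt <- AA_STANDARD[AA_STANDARD != seq[i]]
    seq[i] <- alt[sample.int(19L, 1L)]
  }
  seq
}

#' Simulate proteomes with planted ortholog groups
#'
#' Each family starts from a single root sequence drawn from the background
#' amino-acid profile and evolves down the taxonomy. Along each branch,
#' duplication and loss events are drawn as Poisson counts proportional to
#' branch length (duplicated copies evolve independently thereafter), and
#' every copy accumulates site-independent substitutions, with the pore
#' subregion substituting more slowly. Deterministic given the config seed.
#'
#' @param tax A `"taxonomy"`.
#' @param config A [simulation_config()].
#' @return A list with
#'   \describe{
#'     \item{proteomes}{named list organism -> `Biostrings::AAStringSet`;
#'       gene identifiers are `"<organism>|fam<k>_g<i>"`.}
#'     \item{truth}{ground-truth ledger: `orthogroups` (family -> organism ->
#'       gene ids, empty = planted loss), `co_ortholog_events` (data.frame of
#'       organism/family with >1 retained copy), `pore_regions` (data.frame
#'       gene/start/end), `events` (per-branch duplication/loss ledger),
#'       `root_sequences`.}
#'   }
#' @export
simulate_proteomes <- function(tax, config) {
  stopifnot(inherits(tax, "taxonomy"), inherits(config, "simulation_config"))
  tree <- tax$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  node_name <- function(node)
    if (node <= n_tip) tree$tip.label[node] else tree$node.label[node - n_tip]
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fam_ids <- sprintf("fam%02d", seq_len(config$n_families))
  pore <- config$pore_region

  with_seed(stage_seed(config$seed, "proteomes"), {
    tip_copies <- stats::setNames(
      replicate(n_tip, list(), simplify = FALSE), tree$tip.label)
    events <- list()
    roots <- list()
    for (f in fam_ids) {
      root_seq <- .draw_root(config$root_length, config$background_freqs)
      roots[[f]] <- paste(root_seq, collapse = "")
      # preorder walk; state = list of copy sequences at the entering node
      walk <- function(node, copies) {
        for (e in children[[as.character(node)]] %||% integer(0)) {
          child <- tree$edge[e, 2]
          t <- tree$edge.length[e]
          cur <- copies
          n_dup <- stats::rpois(1L, config$duplication_rate * t)
          if (n_dup > 0L && length(cur) > 0L) {
            for (d in seq_len(n_dup))
              cur[[length(cur) + 1L]] <- cur[[sample.int(length(cur), 1L)]]
            events[[length(events) + 1L]] <<- data.frame(
              family = f, edge_child = node_name(child), type = "duplication",
              count = n_dup, stringsAsFactors = FALSE)
          }
          n_loss <- stats::rpois(1L, config$loss_rate * t)
          n_loss <- min(n_loss, length(cur))
          if (n_loss > 0L) {
            drop <- sample.int(length(cur), n_loss)
            cur <- cur[-drop]
            events[[length(events) + 1L]] <<- data.frame(
              family = f, edge_child = node_name(child), type = "loss",
              count = n_loss, stringsAsFactors = FALSE)
          }
          cur <- lapply(cur, .evolve_branch, t = t, pore = pore,
                        rho = config$pore_rate_multiplier)
          if (child <= n_tip) {
            if (length(cur) > 0L) {
              names(cur) <- sprintf("%s|%s_g%d", tree$tip.label[child], f,
                                    seq_along(cur))
              tip_copies[[tree$tip.label[child]]] <<-
                c(tip_copies[[tree$tip.label[child]]], cur)
            }
          } else {
            walk(child, cur)
          }
        }
      }
      walk(root, list(root_seq))
    }

    proteomes <- lapply(tip_copies, function(copies) {
      seqs <- vapply(copies, paste, character(1), collapse = "")
      Biostrings::AAStringSet(seqs)
    })

    orthogroups <- lapply(fam_ids, function(f) {
      lapply(tip_copies, function(copies) {
        ids <- names(copies)
        ids[grepl(paste0("\\|", f, "_g"), ids)]
      })
    })
    names(orthogroups) <- fam_ids

    co <- do.call(rbind, lapply(fam_ids, function(f) {
      n <- vapply(orthogroups[[f]], length, integer(1))
      orgs <- names(n)[n > 1L]
      if (!length(orgs)) return(NULL)
      data.frame(organism = orgs, family = f,
                 n_copies = unname(n[n > 1L]), stringsAsFactors = FALSE)
    }))
    if (is.null(co))
      co <- data.frame(organism = character(), family = character(),
                       n_copies = integer(), stringsAsFactors = FALSE)

    genes <- unlist(lapply(proteomes, names), use.names = FALSE)
    pore_regions <- data.frame(gene = genes,
                               start = rep(pore[1], length(genes)),
                               end = rep(pore[2], length(genes)),
                               stringsAsFactors = FALSE)
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(family = character(), edge_child = character(),
                 type = character(), count = integer(), stringsAsFactors = FALSE)

    list(proteomes = proteomes,
         truth = list(orthogroups = orthogroups, co_ortholog_events = co,
                      pore_regions = pore_regions, events = events,
                      root_sequences = roots))
  })
}

#' Write simulated proteomes as per-organism FASTA files
#'
#' @param sim Result of [simulate_proteomes()].
#' @param dir Output directory (created if needed); one `<organism>.fasta`
#'   per organism, file stem = organism identifier.
#' @return Character vector of written paths, invisibly.
#' @export
write_proteomes <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$proteomes), function(org) {
    p <- file.path(dir, paste0(org, ".fasta"))
    Biostrings::writeXStringSet(sim$proteomes[[org]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Plant integrity defects into protein metadata records
#'
#' Starting from default-valid records, each defect is planted independently
#' with its configured probability: unreviewed entry status, low protein-
#' existence evidence (level 4 or 5), fragment/fusion length (< 30 or
#' > 5000 residues), an elevated fraction of non-standard residues, a
#' low-complexity expansion, an inflated sequence version, and total absence
#' of cross-references. Every planting is recorded.
#'
#' @param records data.frame as from [make_metadata()].
#' @param config A [simulation_config()]; probabilities under
#'   `config$metadata` (`p_unreviewed`, `p_low_pe`, `p_fragment`,
#'   `p_nonstandard`, `p_low_complexity`, `p_high_version`,
#'   `p_no_crossrefs`).
#' @return list(records = corrupted data.frame, truth = named list
#'   accession -> character vector of planted defect labels).
#' @export
corrupt_metadata <- function(records, config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$metadata
  with_seed(stage_seed(config$seed, "metadata"), {
    truth <- stats::setNames(vector("list", nrow(records)), records$accession)
    for (i in seq_len(nrow(records))) {
      planted <- character(0)
      seq <- records$sequence[i]
      if (stats::runif(1) < p$p_unreviewed) {
        records$entry_type[i] <- "Unreviewed"
        planted <- c(planted, "unreviewed")
      }
      if (stats::runif(1) < p$p_low_pe) {
        records$protein_existence[i] <- sample(4:5, 1L)
        planted <- c(planted, "low_pe")
      }
      if (stats::runif(1) < p$p_fragment) {
        if (stats::runif(1) < 0.5) {
          seq <- substr(seq, 1L, sample(5:29, 1L))
        } else {
          extra <- paste(sample(AA_STANDARD, 5001L - min(nchar(seq), 5000L) + 100L,
                                replace = TRUE), collapse = "")
          seq <- paste0(seq, extra)
        }
        planted <- c(planted, "fragment")
      }
      if (stats::runif(1) < p$p_nonstandard) {
        n <- nchar(seq)
        k <- max(1L, ceiling(0.1 * n))
        pos <- sample.int(n, k)
        chars <- strsplit(seq, "")[[1]]
        chars[pos] <- sample(c("X", "B", "Z", "U", "O", "J"), k, replace = TRUE)
        seq <- paste(chars, collapse = "")
        planted <- c(planted, "nonstandard_aa")
      }
      if (stats::runif(1) < p$p_low_complexity) {
        n <- nchar(seq)
        run <- strrep("A", max(12L, ceiling(0.75 * n)))
        seq <- paste0(substr(seq, 1L, floor(0.125 * n)), run)
        planted <- c(planted, "low_complexity")
      }
      if (stats::runif(1) < p$p_high_version) {
        records$sequence_version[i] <- 150L
        planted <- c(planted, "high_version")
      }
      if (stats::runif(1) < p$p_no_crossrefs) {
        records$domain_count[i] <- 0L
        records$xref_count[i] <- 0L
        planted <- c(planted, "no_crossrefs")
      }
      records$sequence[i] <- seq
      records$length[i] <- nchar(seq)
      truth[[i]] <- planted
    }
    list(records = records, truth = truth)
  })
}

#' Default-valid metadata records for a set of sequences
#'
#' @param accessions Character vector of identifiers.
#' @param sequences Character vector of residue strings (same length).
#' @return data.frame with the metadata schema consumed by
#'   [validate_record()]: Reviewed entries, protein existence 1, sequence
#'   version 1, one annotated domain, five cross-references.
#' @export
make_metadata <- function(accessions, sequences) {
  stopifnot(length(accessions) == length(sequences))
  data.frame(accession = accessions, entry_type = "Reviewed",
             protein_existence = 1L, sequence_version = 1L,
             sequence = as.character(sequences),
             length = nchar(as.character(sequences)),
             domain_count = 1L, xref_count = 5L, stringsAsFactors = FALSE)
}

#' Simulate an alignment with planted foreground-conserved columns
#'
#' Generates a gapped alignment of foreground (`FG|...`) and background
#' (`BG|...`) sequences. Non-pattern columns are i.i.d. draws from the
#' background amino-acid profile for every sequence. Pattern columns draw
#' from a small planted residue set with probability `strength` in the
#' foreground and from the background profile otherwise (and always in the
#' background sequences). Gaps are inserted cell-wise at `gap_rate`.
#'
#' @param config A [simulation_config()]; settings under `config$msa`
#'   (`n_fg`, `n_bg`, `length`, `n_pattern`, `strength`, `set_size`,
#'   `gap_rate`).
#' @return list(family = an [aligned_family()] whose reference is the first
#'   foreground sequence, truth = data.frame(column, residues, strength)).
#' @export
simulate_pattern_msa <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ms <- config$msa
  freqs <- config$background_freqs
  with_seed(stage_seed(config$seed, "msa"), {
    n_seq <- ms$n_fg + ms$n_bg
    labels <- c(rep("foreground", ms$n_fg), rep("background", ms$n_bg))
    ids <- c(sprintf("FG|fg%03d", seq_len(ms$n_fg)),
             sprintf("BG|bg%03d", seq_len(ms$n_bg)))
    mat <- matrix(sample(names(freqs), n_seq * ms$length, replace = TRUE,
                         prob = freqs),
                  nrow = n_seq, ncol = ms$length)
    cols <- sort(sample.int(ms$length, ms$n_pattern))
    sets <- lapply(seq_along(cols), function(i)
      sample(names(freqs), ms$set_size))
    for (i in seq_along(cols)) {
      use <- stats::runif(ms$n_fg) < ms$strength
      draw <- sample(sets[[i]], sum(use), replace = TRUE)
      mat[seq_len(ms$n_fg)[use], cols[i]] <- draw
    }
    if (ms$gap_rate > 0) {
      gap <- matrix(stats::runif(n_seq * ms$length) < ms$gap_rate,
                    nrow = n_seq)
      mat[gap] <- "-"
    }
    aln <- Biostrings::AAStringSet(apply(mat, 1, paste, collapse = ""))
    names(aln) <- ids
    truth <- data.frame(column = cols,
                        residues = vapply(sets, paste, character(1),
                                          collapse = ","),
                        strength = rep(ms$strength, length(cols)),
                        stringsAsFactors = FALSE)
    list(family = aligned_family(aln, labels = labels, reference_id = ids[1]),
         truth = truth)
  })
}

#' Simulate term annotations with planted cluster enrichment
#'
#' Background terms are assigned to every gene independently at rate `p0`.
#' For each cluster, `planted_per_cluster` extra terms are created and
#' assigned to that cluster's genes at rate `p1` (and to all other genes at
#' `p0`). With `p1 = p0` nothing is effectively planted and the truth ledger
#' is empty.
#'
#' @param clusters Named list cluster label -> character vector of genes
#'   (disjoint).
#' @param config A [simulation_config()]; settings under `config$terms`
#'   (`n_background_terms`, `p0`, `p1`, `planted_per_cluster`).
#' @return list(term_map = data.frame(term, gene), truth = named list
#'   cluster -> planted term ids).
#' @export
simulate_term_annotations <- function(clusters, config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(genes)) stopf("clusters must be disjoint")
  tm <- config$terms
  with_seed(stage_seed(config$seed, "terms"), {
    rows <- list()
    add <- function(term, gs)
      rows[[length(rows) + 1L]] <<- data.frame(term = term, gene = gs,
                                               stringsAsFactors = FALSE)
    for (j in seq_len(tm$n_background_terms)) {
      hit <- genes[stats::runif(length(genes)) < tm$p0]
      if (length(hit)) add(sprintf("T%04d", j), hit)
    }
    truth <- stats::setNames(vector("list", length(clusters)), names(clusters))
    if (tm$p1 > tm$p0) {
      for (cl in names(clusters)) {
        for (r in seq_len(tm$planted_per_cluster)) {
          term <- sprintf("TP_%s_%d", cl, r)
          inside <- clusters[[cl]][stats::runif(length(clusters[[cl]])) < tm$p1]
          outside <- setdiff(genes, clusters[[cl]])
          outside <- outside[stats::runif(length(outside)) < tm$p0]
          hit <- c(inside, outside)
          if (length(hit)) add(term, hit)
          truth[[cl]] <- c(truth[[cl]], term)
        }
      }
    }
    term_map <- if (length(rows)) do.call(rbind, rows) else
      data.frame(term = character(), gene = character(), stringsAsFactors = FALSE)
    list(term_map = term_map, truth = truth)
  })
}
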