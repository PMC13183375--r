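# Independent oracles used across the suite. These re-derive expected
# values by brute force or closed form and deliberately share no code with
# the package implementation.

# Optimal local alignment score by exhaustive enumeration of monotone
# matchings: a local alignment is a strictly increasing set of aligned
# residue pairs, with internal unaligned stretches paying affine gap costs
# open + w * ext per sequence. The empty alignment scores 0.
oracle_local_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  gapc <- function(w) if (w <= 0) 0 else open + w * ext
  best <- 0
  rec <- function(iprev, jprev, score) {
    if (iprev >= n || jprev >= m) return(invisible())
    for (i in (iprev + 1L):n) {
      for (j in (jprev + 1L):m) {
        s2 <- score
        if (iprev > 0L)
          s2 <- s2 - gapc(i - iprev - 1L) - gapc(j - jprev - 1L)
        s2 <- s2 + mat[A[i], B[j]]
        best <<- max(best, s2)
        rec(i, j, s2)
      }
    }
  }
  rec(0L, 0L, 0)
  best
}

random_protein <- function(n) paste(sample(channelome:::AA_STANDARD, n,
                                           replace = TRUE), collapse = "")

# Reference MCL: straightforward dense-matrix implementation written
# independently of the package's (same definition of the iteration, no
# pruning, component-based attractor merge via repeated set union).
oracle_mcl <- function(edges, inflation = 1.5) {
  nodes <- sort(unique(c(as.character(edges[[1]]), as.character(edges[[2]]))))
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
  for (r in seq_len(nrow(edges))) {
    i <- as.character(edges[[1]][r]); j <- as.character(edges[[2]][r])
    M[i, j] <- M[j, i] <- max(M[i, j], w[r])
  }
  for (i in seq_len(n)) {
    mx <- max(M[, i])
    M[i, i] <- if (mx > 0) mx else 1
  }
  norm <- function(X) sweep(X, 2, colSums(X), "/")
  M <- norm(M)
  for (iter in 1:500) {
    old <- M
    M <- norm((M %*% M)^inflation)
    if (max(abs(M - old)) < 1e-7) break
  }
  groups <- list()
  for (i in which(diag(M) > 1e-4)) {
    members <- nodes[M[i, ] > 1e-4]
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (length(intersect(groups[[g]], members))) {
        groups[[g]] <- union(groups[[g]], members)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- members
  }
  leftover <- setdiff(nodes, unlist(groups))
  for (x in leftover) groups[[length(groups) + 1L]] <- x
  out <- integer(0)
  for (g in seq_along(groups)) out[groups[[g]]] <- g
  out[nodes]
}

# Two cluster assignments describe the same partition?
same_partition <- function(a, b) {
  stopifnot(setequal(names(a), names(b)))
  b <- b[names(a)]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Ward linkage heights by the Lance-Williams recurrence on squared
# Euclidean distances (heights on the distance scale).
oracle_ward_heights <- function(x) {
  d2 <- as.matrix(stats::dist(x))^2
  n <- nrow(x)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- Inf; bi <- bj <- NA
    for (a in seq_along(active)) for (b in seq_along(active)) if (a < b) {
      i <- active[a]; j <- active[b]
      if (d2[i, j] < best) { best <- d2[i, j]; bi <- i; bj <- j }
    }
    heights <- c(heights, sqrt(best))
    for (k in setdiff(active, c(bi, bj))) {
      d2[bi, k] <- d2[k, bi] <- ((sizes[bi] + sizes[k]) * d2[bi, k] +
        (sizes[bj] + sizes[k]) * d2[bj, k] - sizes[k] * best) /
        (sizes[bi] + sizes[bj] + sizes[k])
    }
    sizes[bi] <- sizes[bi] + sizes[bj]
    active <- setdiff(active, bj)
  }
  heights
}

# Independent contrast-score evaluation (no greedy; fixed residue set).
oracle_contrast <- function(residues, labels, set, a = 1) {
  keep <- !(residues %in% c("-", "."))
  res <- residues[keep]; lab <- labels[keep]
  nF <- sum(lab == "foreground"); nB <- sum(lab == "background")
  kF <- sum(res %in% set & lab == "foreground")
  kB <- sum(res %in% set & lab == "background")
  p <- (kF + a) / (nF + 2 * a)
  q <- (kB + a) / (nB + 2 * a)
  max(0, kF * log(p / q) + (nF - kF) * log((1 - p) / (1 - q)))
}

# Independent greedy maximal contrast for one column.
oracle_greedy_max <- function(residues, labels, a = 1) {
  keep <- !(residues %in% c("-", "."))
  res <- residues[keep]; lab <- labels[keep]
  cnt <- table(factor(res[lab == "foreground"], levels = sort(unique(res))))
  cand <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  best <- -Inf; set <- character(0)
  for (i in seq_along(cand)) {
    s <- oracle_contrast(res, lab, cand[seq_len(i)], a)
    if (s > best) { best <- s; set <- cand[seq_len(i)] } else break
  }
  list(score = best, set = set)
}

# Simple RBH oracle: double loop over queries and organisms using raw
# best-score logic on a hit table (ties by bit, evalue, id).
oracle_rbh <- function(forward, reciprocal, fwd_max, rec_max) {
  forward <- forward[forward$evalue <= fwd_max, , drop = FALSE]
  reciprocal <- reciprocal[reciprocal$evalue <= rec_max, , drop = FALSE]
  forward$organism <- sub("\\|.*$", "", forward$target)
  pick_top <- function(h) h[order(-h$bit_score, h$evalue, h$target)[1], ]
  pairs <- list()
  for (q in unique(forward$query)) {
    for (org in unique(forward$organism[forward$query == q])) {
      f <- forward[forward$query == q & forward$organism == org, ]
      top <- pick_top(f)
      r <- reciprocal[reciprocal$query == top$target, ]
      if (!nrow(r)) next
      back <- pick_top(r)
      if (back$target == q)
        pairs[[length(pairs) + 1L]] <- data.frame(query = q,
                                                  target = top$target,
                                                  stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) return(data.frame(query = character(),
                                        target = character()))
  out <- do.call(rbind, pairs)
  out[order(out$query, out$target), , drop = FALSE]
}

# Small deterministic proteome simulation shared by orthology tests.
small_sim <- function(seed = 42, n_org = 4, n_fam = 6, branch = 0.15) {
  tax <- toy_taxonomy(n_org, branch)
  cfg <- simulation_config(seed = seed, n_families = n_fam)
  list(tax = tax, cfg = cfg, sim = simulate_proteomes(tax, cfg))
}

blosum62 <- function() channelome:::.extended_matrix("BLOSUM62")
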