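# Markov clustering (MCL) of a weighted undirected graph: alternate
# expansion (matrix squaring) and inflation (entrywise power followed by
# column normalization) on the column-stochastic transition matrix until
# the matrix stops changing, then read clusters off the attractor rows.

#' Markov graph clustering
#'
#' @param edges data.frame whose first two columns are node identifiers and
#'   whose optional `weight` column carries edge weights (default 1).
#'   The graph is treated as undirected; self-loops are added with the
#'   maximum incident weight of each node (1 for isolated nodes) to damp
#'   oscillation, the standard MCL device.
#' @param inflation Inflation exponent (> 1); default 1.5.
#' @param max_iter,tol Convergence controls: stop when the largest
#'   entrywise change after a full expansion-inflation step falls below
#'   `tol` (default 1e-6) or after `max_iter` (default 200) iterations.
#' @return Named character vector node -> cluster id (`"C1"`, `"C2"`, ...);
#'   clusters are numbered by their lexicographically smallest member so
#'   the labelling is deterministic.
#' @export
markov_cluster <- function(edges, inflation = 1.5, max_iter = 200L,
                           tol = 1e-6) {
  stopifnot(inflation > 1)
  if (is.null(edges) || nrow(edges) == 0L)
    return(stats::setNames(character(0), character(0)))
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight)
       else rep(1, nrow(edges))
  if (any(w < 0)) stopf("edge weights must be >= 0")
  nodes <- sort(unique(c(from, to)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_along(from)) {
    A[from[i], to[i]] <- max(A[from[i], to[i]], w[i])
    A[to[i], from[i]] <- A[from[i], to[i]]
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M            # expansion
    M <- normalize(M^inflation)  # inflation
    M[M < 1e-12] <- 0
    M <- normalize(M)
    if (max(abs(M - prev)) < tol) break
  }
  # attractors: nodes with mass on their own row; each attractor row spans
  # one cluster, overlapping rows are merged
  tau <- 1e-5
  attractors <- which(diag(M) > tau)
  member <- lapply(attractors, function(i) which(M[i, ] > tau))
  assign <- rep(NA_integer_, n)
  cl <- 0L
  for (k in seq_along(member)) {
    ids <- member[[k]]
    existing <- unique(stats::na.omit(assign[ids]))
    if (length(existing)) {
      keep <- existing[1]
      assign[ids] <- keep
      if (length(existing) > 1L)
        assign[assign %in% existing[-1]] <- keep
    } else {
      cl <- cl + 1L
      assign[ids] <- cl
    }
  }
  for (i in which(is.na(assign))) {
    cl <- cl + 1L
    assign[i] <- cl
  }
  # deterministic labels: order clusters by smallest member name
  first <- vapply(split(nodes, assign), min, character(1))
  relabel <- stats::setNames(seq_along(first), names(first)[order(first)])
  out <- paste0("C", relabel[as.character(assign)])
  stats::setNames(out, nodes)
}
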