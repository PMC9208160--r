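# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package implementations.

# --- scoring ---------------------------------------------------------------

# Literal case analysis of the evidence-scoring rules.
oracleScore <- function(cats) {
  if ("known_vector" %in% cats) return(5L)
  hasWild <- "wild_infection" %in% cats
  hasInf <- "lab_infection" %in% cats
  hasDis <- "lab_dissemination" %in% cats
  hasTra <- "lab_transmission" %in% cats
  if (hasTra) {
    if (hasWild) return(4L) else return(3L)
  }
  if (hasDis) {
    if (hasWild) return(3L) else return(2L)
  }
  if (hasInf) {
    if (hasWild) return(2L) else return(1L)
  }
  stopifnot(hasWild)
  1L
}

# All non-empty subsets of a character vector.
allSubsets <- function(x) {
  n <- length(x)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    out[[length(out) + 1L]] <- x[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  }
  out
}

# --- modularity ------------------------------------------------------------

# Direct double-sum evaluation of Newman-Girvan Q on a symmetric adjacency.
bruteModularity <- function(A, comm) {
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (comm[i] == comm[j]) q <- q + A[i, j] - k[i] * k[j] / m2
    }
  }
  unname(q / m2)
}

# --- betweenness -----------------------------------------------------------

# Neighbor lists (pathogens then vectors, matching the package node order).
adjListOf <- function(net) {
  labels <- c(pathogenNodes(net), vectorNodes(net))
  e <- edgeTable(net)
  adj <- lapply(labels, function(l) {
    sort(match(c(e$vector[e$pathogen == l], e$pathogen[e$vector == l]), labels))
  })
  names(adj) <- labels
  adj
}

# All simple paths between two nodes, by depth-first enumeration.
allSimplePaths <- function(adj, s, t) {
  paths <- list()
  walk <- function(v, visited) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible(NULL))
    }
    for (w in adj[[v]]) {
      if (!w %in% visited) walk(w, c(visited, w))
    }
  }
  walk(s, s)
  paths
}

# Betweenness by exhaustive shortest-path enumeration, normalized by
# (n-1)(n-2)/2. Feasible for graphs of up to ~8 nodes.
bruteBetweenness <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- allSimplePaths(adj, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      sp <- paths[lens == min(lens)]
      inner <- lapply(sp, function(p) setdiff(p, c(s, t)))
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        bc[v] <- bc[v] + sum(vapply(inner, function(p) v %in% p, logical(1))) /
          length(sp)
      }
    }
  }
  setNames(bc / ((n - 1) * (n - 2) / 2), names(adj))
}

# --- extinction ------------------------------------------------------------

# Survival curve by literal stepwise removal on a plain edge table.
stepwiseCurve <- function(edges, order) {
  pathogens <- unique(edges$pathogen)
  P <- length(pathogens)
  remaining <- edges
  y <- 1
  for (v in order) {
    remaining <- remaining[remaining$vector != v, , drop = FALSE]
    y <- c(y, length(unique(remaining$pathogen)) / P)
  }
  y
}

trapzAuc <- function(y) sum((y[-1] + y[-length(y)]) / 2) / (length(y) - 1)

breakOf <- function(y) which(y < 1 - 1e-12)[1] - 1L

allPermutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in allPermutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# Exact mean robustness and break point over all removal permutations.
exhaustiveExtinction <- function(edges) {
  vecs <- sort(unique(edges$vector))
  perms <- allPermutations(vecs)
  rob <- bp <- numeric(length(perms))
  for (i in seq_along(perms)) {
    y <- stepwiseCurve(edges, perms[[i]])
    rob[i] <- trapzAuc(y)
    bp[i] <- breakOf(y)
  }
  list(robustness = mean(rob), breakPoint = mean(bp), n = length(perms))
}

# --- fixtures --------------------------------------------------------------

makeNet <- function(vector, pathogen, score = 1L) {
  buildNetwork(data.frame(vector = vector, pathogen = pathogen,
                          score = as.integer(score)))
}

# Random bipartite edge table; every pathogen and vector label used gets at
# least one edge because nodes enter the network only via edges.
randomEdges <- function(nP, nV, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(runif(nP * nV) < p, nP, nV)
    if (any(m)) break
  }
  idx <- which(m, arr.ind = TRUE)
  data.frame(vector = paste0("v", idx[, 2]),
             pathogen = paste0("p", idx[, 1]),
             score = sample(1:5, nrow(idx), replace = TRUE))
}
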