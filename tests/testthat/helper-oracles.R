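# Independent reference implementations used as oracles. These are kept
# deliberately literal (nested loops, brute-force enumeration) and never
# share code with the package internals they check.

# all (disease, lncRNA, miRNA) triples whose three edges co-occur
oracle_triangles <- function(ld, md, lm) {
  key <- function(a, b) paste(a, b, sep = "\r")
  e1 <- key(ld[[1]], ld[[2]])
  e2 <- key(md[[1]], md[[2]])
  e3 <- key(lm[[1]], lm[[2]])
  out <- list()
  for (d in unique(c(ld[[2]], md[[2]]))) {
    for (l in unique(ld[[1]])) {
      if (!key(l, d) %in% e1) next
      for (m in unique(md[[1]])) {
        if (key(m, d) %in% e2 && key(l, m) %in% e3) {
          out[[length(out) + 1L]] <- data.frame(disease = d, lncRNA = l, miRNA = m)
        }
      }
    }
  }
  if (length(out) == 0L) return(data.frame(disease = character(),
                                           lncRNA = character(),
                                           miRNA = character()))
  do.call(rbind, out)
}

# literal double-loop Gaussian interaction-profile kernel over columns
oracle_gip <- function(m) {
  n <- ncol(m)
  gamma <- 1 / (mean(colSums(m^2)))
  out <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      out[i, j] <- exp(-gamma * sum((m[, i] - m[, j])^2))
    }
  }
  diag(out) <- 1
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

# literal best-match-average functional similarity
oracle_funsim <- function(sets, sem) {
  genes <- names(sets)
  n <- length(genes)
  out <- matrix(0, n, n, dimnames = list(genes, genes))
  diag(out) <- 1
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      a <- sets[[i]]
      b <- sets[[j]]
      if (length(a) == 0L || length(b) == 0L) next
      s <- 0
      for (x in a) s <- s + max(sapply(b, function(y) sem[x, y]))
      for (y in b) s <- s + max(sapply(a, function(x) sem[y, x]))
      out[i, j] <- s / (length(a) + length(b))
    }
  }
  out
}

# literal four-index pair similarity
oracle_pairsim <- function(lncSim, miRSim, method) {
  nl <- nrow(lncSim)
  nm <- nrow(miRSim)
  avg_l <- mean(lncSim)
  avg_m <- mean(miRSim)
  np <- nl * nm
  out <- matrix(0, np, np)
  for (i in 1:nl) for (j in 1:nm) for (a in 1:nl) for (b in 1:nm) {
    p <- (i - 1) * nm + j
    q <- (a - 1) * nm + b
    x <- lncSim[i, a]
    y <- miRSim[j, b]
    out[p, q] <- switch(method,
      average = (x + y) / 2,
      sqrt = sqrt(x * y),
      centre = sqrt((x - avg_l)^2 + (y - avg_m)^2)
    )
  }
  out
}

# accumulated dense block powers: pair-by-disease block of
# sum_{l=1..K} gamma^l (DPstar)^l
oracle_katz <- function(P, DP, S, gamma, K) {
  dpstar <- rbind(cbind(P, DP), cbind(t(DP), S))
  acc <- matrix(0, nrow(dpstar), ncol(dpstar))
  pw <- diag(nrow(dpstar))
  for (l in 1:K) {
    pw <- pw %*% dpstar
    acc <- acc + gamma^l * pw
  }
  np <- nrow(DP)
  acc[seq_len(np), np + seq_len(ncol(DP)), drop = FALSE]
}

# pairwise Mann-Whitney AUC
oracle_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

# random symmetric similarity matrix in [0,1] with unit diagonal
random_sim <- function(n, ids = sprintf("x%d", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

# random hierarchy: a random recursive tree plus a few extra parent edges
# (multiple inheritance), always acyclic because parents precede children
random_dag <- function(n, p_extra = 0.15) {
  ids <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(child = character(), parent = character())
  for (t in seq_len(n)[-1]) {
    parents <- ids[sample.int(t - 1L, 1L)]
    if (t > 2L && stats::runif(1) < p_extra) {
      parents <- unique(c(parents, ids[sample.int(t - 1L, 1L)]))
    }
    edges <- rbind(edges, data.frame(child = ids[t], parent = parents))
  }
  disease_dag(edges, nodes = ids)
}

# brute-force max-over-paths semantic contribution: enumerate every
# directed path from the disease up to the ancestor and take the best
# delta^length over them
oracle_semantic_contribution <- function(dag, disease, ancestor, delta) {
  best <- -Inf
  walk <- function(node, w) {
    if (node == ancestor && w > best) best <<- w
    for (p in dag$parents[[node]]) walk(p, w * delta)
  }
  walk(disease, 1)
  if (is.finite(best)) best else NA_real_
}
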