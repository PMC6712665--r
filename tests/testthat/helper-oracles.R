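# Independent brute-force oracles. These re-derive each quantity from
# first principles, separately from the package's implementation paths.

# ---- Spearman: Pearson correlation of brute-force average ranks ----

avg_rank_oracle <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

spearman_oracle <- function(x, y) {
  rx <- avg_rank_oracle(x)
  ry <- avg_rank_oracle(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# ---- Fisher: two-sided p by hypergeometric enumeration ----

fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[1, 2] # white balls
  n <- tab[2, 1] + tab[2, 2] # black balls
  k <- tab[1, 1] + tab[2, 1] # drawn
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  rel_err <- 1 + 1e-7
  sum(d[d <= stats::dhyper(a, m, n, k) * rel_err])
}

# ---- Wilcoxon rank-sum: exact p by permutation enumeration ----

wilcox_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  w_all <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  if (w_obs > nx * ny / 2) {
    p <- 2 * mean(w_all >= w_obs)
  } else {
    p <- 2 * mean(w_all <= w_obs)
  }
  min(1, p)
}

# ---- CRISPR spacers: sliding-window Hamming scan on both strands ----

hamming_profile <- function(pattern, subject) {
  p <- utf8ToInt(pattern)
  s <- utf8ToInt(subject)
  k <- length(p)
  n <- length(s)
  if (n < k) return(integer())
  mm <- integer(n - k + 1L)
  for (j in seq_len(k)) {
    mm <- mm + (s[j:(n - k + j)] != p[j])
  }
  mm
}

spacer_oracle_best <- function(spacer, phage_seq, max_mm = 1L) {
  best <- NA_integer_
  for (pat in c(spacer, revcomp(spacer))) {
    mm <- hamming_profile(pat, phage_seq)
    if (length(mm) && min(mm) <= max_mm) {
      best <- min(best, min(mm), na.rm = TRUE)
    }
  }
  best
}

# ---- Breadth of coverage: position marking ----

coverage_oracle <- function(starts, ends, L) {
  hit <- logical(L)
  for (i in seq_along(starts)) {
    s <- max(0L, starts[i])
    e <- min(L, ends[i])
    if (e > s) hit[(s + 1L):e] <- TRUE
  }
  mean(hit)
}

# ---- Clustering: all-pairs similarity matrix + transitive closure ----

union_width_oracle <- function(starts, ends, L) {
  round(coverage_oracle(starts, ends, L) * L)
}

similarity_matrix_oracle <- function(aln, lengths, min_identity = 0.90,
                                     min_coverage = 0.70,
                                     min_length_ratio = 0.7) {
  ids <- sort(names(lengths))
  n <- length(ids)
  sim <- diag(TRUE, n)
  dimnames(sim) <- list(ids, ids)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    a <- ids[i]; b <- ids[j]
    sel <- (aln$query_id == a & aln$target_id == b) |
      (aln$query_id == b & aln$target_id == a)
    sub <- aln[sel, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ident <- sum(sub$identity * sub$aligned_length) / sum(sub$aligned_length)
    shorter <- if (lengths[[a]] <= lengths[[b]]) a else b
    len_s <- min(lengths[[a]], lengths[[b]])
    ss <- ifelse(sub$query_id == shorter, sub$query_start, sub$target_start)
    se <- ifelse(sub$query_id == shorter, sub$query_end, sub$target_end)
    cov <- union_width_oracle(ss, se, len_s) / len_s
    ratio <- len_s / max(lengths[[a]], lengths[[b]])
    ok <- ident >= min_identity && cov >= min_coverage &&
      ratio >= min_length_ratio
    sim[i, j] <- sim[j, i] <- ok
  }
  sim
}

transitive_closure_clusters <- function(sim) {
  reach <- sim
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, nrow(reach))
  k <- 0L
  for (i in seq_len(nrow(reach))) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[which(reach[i, ])] <- k
    }
  }
  split(rownames(sim), comp)
}

# ---- Circularizer: exhaustive enumeration of all legal merge orders ----

oracle_graph_df <- function(graph) {
  u <- graph$unitigs
  data.frame(sequence = u$sequence, depth = u$depth, bin_id = u$bin_id,
             from = u$from, to = u$to, stringsAsFactors = FALSE)
}

oracle_state_key <- function(u) {
  paste(sort(paste(u$sequence, signif(u$depth, 10), u$bin_id, u$from, u$to,
                   sep = "|")), collapse = ";")
}

oracle_mergeable <- function(u) {
  js <- unique(c(u$from, u$to))
  ok <- vapply(js, function(j) {
    ins <- which(u$to == j)
    outs <- which(u$from == j)
    length(ins) == 1L && length(outs) == 1L && ins != outs &&
      u$bin_id[ins] == u$bin_id[outs]
  }, NA)
  js[ok]
}

oracle_merge <- function(u, j) {
  i1 <- which(u$to == j)
  i2 <- which(u$from == j)
  l1 <- nchar(u$sequence[i1])
  l2 <- nchar(u$sequence[i2])
  merged <- data.frame(
    sequence = paste0(u$sequence[i1], u$sequence[i2]),
    depth = (u$depth[i1] * l1 + u$depth[i2] * l2) / (l1 + l2),
    bin_id = u$bin_id[i1],
    from = u$from[i1], to = u$to[i2],
    stringsAsFactors = FALSE
  )
  rbind(u[-c(i1, i2), , drop = FALSE], merged)
}

# Returns the set of terminal state keys reachable by any merge order.
exhaustive_merge_oracle <- function(graph, max_states = 50000) {
  seen <- new.env(parent = emptyenv())
  finals <- new.env(parent = emptyenv())
  n_states <- 0L
  rec <- function(u) {
    k <- oracle_state_key(u)
    if (!is.null(seen[[k]])) return(invisible(NULL))
    seen[[k]] <- TRUE
    n_states <<- n_states + 1L
    if (n_states > max_states) stop("oracle state explosion")
    js <- oracle_mergeable(u)
    if (length(js) == 0L) {
      finals[[k]] <- TRUE
      return(invisible(NULL))
    }
    for (j in js) rec(oracle_merge(u, j))
  }
  rec(oracle_graph_df(graph))
  ls(finals)
}

# Canonical serialization of a merged unitig_graph for equality checks.
merged_graph_key <- function(graph) {
  oracle_state_key(oracle_graph_df(graph))
}

# Fixed-point merging with an explicitly randomized junction order,
# built on the package's single-junction merge step.
merge_random_order <- function(graph) {
  repeat {
    js <- emgekit:::mergeable_junctions(graph)
    if (length(js) == 0L) return(graph)
    j <- if (length(js) == 1L) js else sample(js, 1L)
    graph <- emgekit:::merge_at_junction(graph, j)
  }
}
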