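aln_pair <- function(q, t, qs, qe, ts, te, identity, qlen = NA, tlen = NA) {
  alignments(query_id = q, target_id = t,
             query_start = qs, query_end = qe,
             target_start = ts, target_end = te,
             strand = "+", identity = identity,
             aligned_length = qe - qs, query_len = qlen, target_len = tlen)
}

test_that("mapped coverage is the breadth of the interval union", {
  a <- aln_pair(c("r1", "r2"), "e1", c(0, 0), c(300, 400),
                c(0, 200), c(300, 600), 1)
  expect_equal(mapped_coverage(a, "e1", 1000), 0.6)

  a2 <- aln_pair("r1", "e1", 0, 590, 0, 590, 1)
  expect_equal(mapped_coverage(a2, "e1", 1000), 0.59)
  expect_equal(mapped_coverage(alignments(), "e1", 1000), 0)
})

test_that("mapped coverage equals the position-marking oracle", {
  withr::local_seed(61)
  for (rep in 1:20) {
    L <- sample(500:2000, 1)
    n <- sample(1:30, 1)
    s <- sample(0:(L - 10), n, replace = TRUE)
    e <- pmin(L, s + sample(10:300, n, replace = TRUE))
    a <- alignments(sprintf("r%02d", 1:n), "e", 0, e - s, s, e, "+", 1, e - s)
    expect_equal(mapped_coverage(a, "e", L), coverage_oracle(s, e, L))
  }
})

test_that("clustering follows the 90/70/0.7 rule with longest
           representative", {
  lengths <- c(A = 100000, B = 80000, C = 30000)
  # A-B similar (95% identity, 85% coverage of B, ratio 0.8)
  aln <- aln_pair("B", "A", 0, 68000, 0, 68000, 0.95)
  cl <- cluster_emges(aln, lengths)
  expect_length(cl, 2)
  ab <- cl[[which(vapply(cl, function(x) "A" %in% x$members, NA))]]
  expect_setequal(ab$members, c("A", "B"))
  expect_equal(ab$representative, "A")
  expect_equal(ab$representative_length, 100000)

  # high identity but length ratio 0.3 -> separate
  aln2 <- aln_pair("C", "A", 0, 29000, 0, 29000, 0.95)
  cl2 <- cluster_emges(aln2, lengths[c("A", "C")])
  expect_length(cl2, 2)

  # isolated element is a singleton
  cl3 <- cluster_emges(alignments(), c(X = 5000))
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$members, "X")

  expect_error(cluster_emges(aln, c(A = 100000, B = NA)), "length")
})

test_that("clustering equals the transitive-closure oracle", {
  withr::local_seed(62)
  for (rep in 1:5) {
    n <- 12
    lens <- stats::setNames(sample(5000:20000, n), sprintf("E%02d", 1:n))
    rows <- list()
    for (k in 1:10) {
      p <- sample(names(lens), 2)
      shorter <- p[which.min(lens[p])]
      longer <- setdiff(p, shorter)
      covfrac <- stats::runif(1, 0.4, 1)
      len <- round(lens[shorter] * covfrac)
      rows[[k]] <- aln_pair(shorter, longer, 0, len, 0, len,
                            stats::runif(1, 0.85, 1))
    }
    aln <- do.call(rbind, rows)
    got <- cluster_emges(aln, lens)
    got_sets <- lapply(got, `[[`, "members")
    want <- transitive_closure_clusters(similarity_matrix_oracle(aln, lens))
    want_sets <- lapply(unname(want), sort)
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want_sets, paste, collapse = ","))
  }
})

test_that("cluster abundance counts each read once at >= 95% identity", {
  cl <- list(emge_cluster("cluster:A", c("A", "B"),
                          c(A = 50000, B = 40000)),
             emge_cluster("cluster:C", "C", c(C = 10000)))
  reads <- alignments(
    query_id = c(sprintf("r%03d", 1:500), "low", "dup", "dup"),
    target_id = c(rep("A", 500), "A", "A", "B"),
    query_start = 0, query_end = 100,
    target_start = 0, target_end = 100,
    strand = "+",
    identity = c(rep(1, 500), 0.94, 0.99, 0.97),
    aligned_length = 100
  )
  res <- cluster_abundance(list(s1 = reads), cl)
  expect_equal(unname(res$counts["cluster:A", "s1"]), 501) # dup once
  expect_equal(unname(res$abundance["cluster:A", "s1"]), 501 / 50)
  expect_equal(unname(res$counts["cluster:C", "s1"]), 0)
})

test_that("the ratio estimator follows its closed form", {
  expect_equal(emge_to_chromosome_ratio(100, 1000, 100, 1000), 1.0)
  expect_equal(emge_to_chromosome_ratio(2000, 1e4, 1e4, 5e6), 100)
  expect_error(emge_to_chromosome_ratio(10, 1000, 0, 1000), "chromosome")
})

test_that("composition from contigs applies the depth/length formula", {
  g <- gene_table(
    gene_id = c("g1", "g2"), contig_id = c("c1", "c2"),
    start = 0, end = 1000, taxon = c("T1", "T2")
  )
  comp <- composition_from_contigs(g, c(c1 = 10, c2 = 30))
  expect_equal(unname(comp["T1"]), 0.25)
  expect_equal(unname(comp["T2"]), 0.75)

  single <- composition_from_contigs(g[1, ], c(c1 = 10))
  expect_equal(unname(single), 1.0)

  expect_error(composition_from_contigs(g[0, ], c(c1 = 10)), "genes")
})

test_that("composition recovers configured abundances within 5% on
           error-free gene panels", {
  withr::local_seed(65)
  abund <- c(T1 = 0.5, T2 = 0.3, T3 = 0.2)
  # the same 40-gene marker panel per taxon (universal single-copy genes)
  lens <- sample(600:1400, 40, replace = TRUE)
  genes <- do.call(rbind, lapply(names(abund), function(tx) {
    starts <- cumsum(c(0, lens[-40] + 100))
    gene_table(sprintf("%s_g%02d", tx, 1:40), paste0("ctg_", tx),
               start = starts, end = starts + lens, taxon = tx)
  }))
  depths <- stats::setNames(abund * 100, paste0("ctg_", names(abund)))
  comp <- composition_from_contigs(genes, depths)
  expect_true(all(abs(comp[names(abund)] - abund) / abund < 0.05))
})

test_that("composition concordance is Pearson over the taxon union", {
  a <- c(T1 = 0.7, T2 = 0.3)
  expect_equal(composition_concordance(a, a), 1.0)
  expect_equal(composition_concordance(c(T1 = 1), c(T2 = 1)), -1.0)
  expect_true(is.na(composition_concordance(c(T1 = 0.5, T2 = 0.5),
                                            c(T1 = 0.2, T2 = 0.8))))
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  p_genes <- gene_table(sprintf("p%02d", 1:10), "pl", 0, 100,
                        cog_id = c(rep("COG0001", 5), rep(NA, 5)),
                        cog_category = c(rep("P", 5), rep("X", 5)))
  c_genes <- gene_table(sprintf("c%02d", 1:10), "ch", 0, 100,
                        cog_id = c(rep("COG0001", 5), rep(NA, 5)),
                        cog_category = c(rep("P", 5), rep("X", 5)))
  res <- cog_enrichment(p_genes, c_genes)
  expect_equal(res$per_cog$p[res$per_cog$cog_id == "COG0001"], 1.0)

  # fully separated 10/0 vs 0/10 table
  p2 <- gene_table(sprintf("p%02d", 1:10), "pl", 0, 100, cog_id = "COG0002")
  c2 <- gene_table(sprintf("c%02d", 1:10), "ch", 0, 100, cog_id = NA)
  res2 <- cog_enrichment(p2, c2)
  want <- fisher_oracle(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res2$per_cog$p, want, tolerance = 1e-10)
  expect_equal(want, 1.082509e-05, tolerance = 1e-3)
  expect_true(res2$per_cog$plasmid_only)

  withr::local_seed(63)
  for (rep in 1:20) {
    n_p <- sample(5:30, 1)
    n_c <- sample(5:30, 1)
    a <- sample(0:n_p, 1)
    b <- sample(0:n_c, 1)
    tab <- matrix(c(a, n_p - a, b, n_c - b), 2)
    expect_equal(stats::fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("plasmid-only COGs are flagged", {
  p <- gene_table(sprintf("p%02d", 1:20), "pl", 0, 100,
                  cog_id = c(rep("COGX", 4), rep(NA, 16)))
  c_ <- gene_table(sprintf("c%03d", 1:100), "ch", 0, 100, cog_id = NA)
  res <- cog_enrichment(p, c_)
  expect_true(res$per_cog$plasmid_only[res$per_cog$cog_id == "COGX"])
})

test_that("Wilcoxon matches exact permutation enumeration", {
  withr::local_seed(64)
  for (rep in 1:10) {
    nx <- sample(3:5, 1)
    ny <- sample(3:5, 1)
    x <- stats::runif(nx)
    y <- stats::runif(ny)
    expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 wilcox_oracle(x, y), tolerance = 1e-10)
  }
  # fully separated small groups
  x <- 1:4
  y <- 5:8
  expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
               wilcox_oracle(x, y), tolerance = 1e-10)
})

test_that("ARG abundance comparison validates its groups", {
  arg <- data.frame(plasmid_id = sprintf("p%d", 1:6),
                    is_arg = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ab <- stats::setNames(c(1, 2, 3, 10, 11, 12), arg$plasmid_id)
  res <- arg_summary(arg, ab)
  expect_equal(res$p, wilcox_oracle(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-10)
  expect_error(arg_summary(data.frame(plasmid_id = "p1", is_arg = TRUE),
                           c(p1 = 1)), "non-empty")
})
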