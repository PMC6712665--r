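host_prediction_df <- function(e, h, m, s, taxon = NA_character_) {
  data.frame(emge_id = e, host_id = h, method = m, score = s,
             evidence = NA_character_, host_taxon = taxon,
             stringsAsFactors = FALSE)
}

mk_ab <- function(rows, lengths = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(lengths)) {
    lengths <- stats::setNames(rep(1000, length(rows)), names(rows))
  }
  abundance_matrix(m, lengths)
}

test_that("co-occurrence applies the Spearman threshold inclusively", {
  ab <- mk_ab(list(e = c(1, 3, 2, 4, 5), h = c(1, 2, 3, 4, 5),
                   x = c(5, 4, 3, 2, 1)))
  # hand formula: 1 - 6*sum(d^2)/(n(n^2-1)) with d = (0,1,-1,0,0) -> 0.9
  preds <- cooccurrence_hosts(ab, "e", c("h", "x"))
  expect_equal(nrow(preds), 1)
  expect_equal(preds$host_id, "h")
  expect_equal(preds$score, 0.9)

  ident <- mk_ab(list(e = c(1, 2, 3), h = c(10, 20, 30)))
  expect_equal(cooccurrence_hosts(ident, "e", "h")$score, 1.0)

  rev <- mk_ab(list(e = c(1, 2, 3), h = c(3, 2, 1)))
  expect_equal(nrow(cooccurrence_hosts(rev, "e", "h")), 0)

  two <- mk_ab(list(e = c(1, 2), h = c(1, 2)))
  expect_error(cooccurrence_hosts(two, "e", "h"), "3 samples")

  const <- mk_ab(list(e = c(1, 2, 3), h = c(5, 5, 5)))
  expect_equal(nrow(cooccurrence_hosts(const, "e", "h")), 0)
})

test_that("Spearman agrees with the average-rank brute force under ties", {
  withr::local_seed(51)
  for (rep in 1:30) {
    n <- sample(5:15, 1)
    x <- sample(1:6, n, replace = TRUE) + stats::runif(n, 0, 0.01)
    y <- sample(1:6, n, replace = TRUE)
    expect_equal(stats::cor(x, y, method = "spearman"),
                 spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("spacer matching enforces length, mismatch and strand rules", {
  withr::local_seed(52)
  phage <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = "")
  ph <- data.frame(id = "ph1", sequence = phage, stringsAsFactors = FALSE)
  sp_exact <- substr(phage, 101, 130)
  sp_2mm <- sp_exact
  substr(sp_2mm, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                  substr(sp_2mm, 1, 1))[1]
  substr(sp_2mm, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                    substr(sp_2mm, 15, 15))[1]
  sp_short <- substr(phage, 200, 218) # 19 bp
  sp_rc <- revcomp(substr(phage, 900, 935))
  spacers <- data.frame(
    host_id = c("hA", "hB", "hC", "hD"),
    spacer_id = c("exact", "twomm", "short", "rc"),
    sequence = c(sp_exact, sp_2mm, sp_short, sp_rc),
    stringsAsFactors = FALSE
  )
  hits <- spacer_hits(spacers, ph)
  expect_setequal(hits$evidence, c("exact", "rc"))
  expect_equal(hits$score[hits$evidence == "exact"], 0)
})

test_that("spacer matching equals the Hamming-scan oracle", {
  withr::local_seed(53)
  phage <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                 collapse = "")
  ph <- data.frame(id = "ph1", sequence = phage, stringsAsFactors = FALSE)
  spacers <- do.call(rbind, lapply(1:30, function(i) {
    if (i <= 10) { # planted with 0-2 mismatches
      pos <- sample(1:(8000 - 30), 1)
      s <- substr(phage, pos, pos + 29)
      nmm <- sample(0:2, 1)
      for (k in sample(30, nmm)) {
        substr(s, k, k) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, k, k))[1]
      }
      if (i %% 2 == 0) s <- revcomp(s)
    } else {
      s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    }
    data.frame(host_id = sprintf("h%02d", i), spacer_id = sprintf("sp%02d", i),
               sequence = s, stringsAsFactors = FALSE)
  }))
  hits <- spacer_hits(spacers, ph)
  got <- stats::setNames(hits$score, hits$evidence)
  for (i in seq_len(nrow(spacers))) {
    want <- spacer_oracle_best(spacers$sequence[i], phage)
    sid <- spacers$spacer_id[i]
    if (is.na(want)) {
      expect_false(sid %in% names(got))
    } else {
      expect_true(sid %in% names(got))
      expect_equal(unname(got[sid]), want)
    }
  }
})

test_that("motif baiting applies inclusive thresholds and drops GATC", {
  profs <- motif_profiles(
    sequence_id = c("b1", "b1", "b1", "b1"),
    motif = c("CCWGG", "GGCC", "GATC", "AACGTT"),
    methylated_fraction = c(0.59, 0.8, 0.95, 0.7),
    mean_coverage = c(30, 25, 40, 24),
    mean_ipd_ratio = 4
  )
  baits <- filter_motifs(profs)
  expect_equal(baits$motif, "GGCC") # 0.8/25 retained (inclusive boundary)
})

test_that("IPD binarization uses a strict 2.5 cutoff", {
  expect_equal(binarize_ipd(c(2.6, 2.4, 2.5, NA)), c(1L, 0L, 0L, NA))
})

test_that("motif linking requires all shared baits to agree", {
  baits <- data.frame(motif = c("M1", "M2"), mod_type = "m6A",
                      stringsAsFactors = FALSE)
  prof <- function(id, states, type) {
    motif_profiles(
      sequence_id = id, motif = names(states), mod_type = "m6A",
      mean_ipd_ratio = ifelse(is.na(states), NA,
                              ifelse(states == 1, 4.0, 1.0)),
      sequence_type = type
    )
  }
  bin <- prof("b1", c(M1 = 1, M2 = 1), "chromosome")

  linked <- link_by_motifs(prof("e1", c(M1 = 1), "plasmid"), bin, baits)
  expect_equal(nrow(linked), 1)
  expect_equal(linked$score, 1)

  disagree <- link_by_motifs(prof("e2", c(M1 = 1, M2 = 0), "plasmid"),
                             bin, baits)
  expect_equal(nrow(disagree), 0)

  missing_ok <- link_by_motifs(
    prof("e3", c(M1 = 1, M2 = NA), "plasmid"),
    prof("b2", c(M1 = 1, M2 = 0), "chromosome"), baits)
  expect_equal(nrow(missing_ok), 1)
})

test_that("consolidation flags agreement and conflict per rank", {
  preds <- rbind(
    host_prediction_df("e1", "h1", "crispr", 0, "Bact;Gen1;sp1"),
    host_prediction_df("e1", "h1", "methylation", 2, "Bact;Gen1;sp1"),
    host_prediction_df("e2", "h2", "crispr", 0, "Bact;Gen1;sp1"),
    host_prediction_df("e2", "h3", "methylation", 1, "Bact;Gen2;sp9"),
    host_prediction_df("e3", "h4", "crispr", 1, "Bact;Gen3;sp3")
  )
  tab <- consolidate_hosts(preds)
  expect_true(grepl("agree@species", tab$flags[tab$emge_id == "e1"]))
  expect_true(grepl("conflict@genus", tab$flags[tab$emge_id == "e2"]))
  expect_equal(tab$flags[tab$emge_id == "e3"], "")
})

test_that("the host network lists one edge per host-eMGE pair", {
  preds <- rbind(
    host_prediction_df("p1", "h1", "co-occurrence", 0.9),
    host_prediction_df("p2", "h1", "co-occurrence", 0.8),
    host_prediction_df("p3", "h1", "crispr", 0),
    host_prediction_df("p3", "h2", "methylation", 1)
  )
  net <- host_network(preds)
  expect_equal(nrow(net), 4)
  expect_equal(sum(net$host == "h1"), 3)
  expect_equal(nrow(host_network(preds[0, ])), 0)
})
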