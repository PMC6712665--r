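# Host prediction of eMGEs by three independent lines of evidence:
# cross-sample abundance co-occurrence, CRISPR spacer-protospacer
# matching, and shared DNA methylation motifs with equal binarized IPD
# states. Predictions are consolidated per eMGE without overriding any
# method.

host_prediction_row <- function(emge_id, host_id, method, score,
                                evidence = NA_character_,
                                host_taxon = NA_character_) {
  data.frame(emge_id = emge_id, host_id = host_id, method = method,
             score = score, evidence = evidence, host_taxon = host_taxon,
             stringsAsFactors = FALSE)
}

empty_predictions <- function() {
  data.frame(emge_id = character(), host_id = character(),
             method = character(), score = numeric(),
             evidence = character(), host_taxon = character(),
             stringsAsFactors = FALSE)
}

#' Predict hosts by cross-sample abundance co-occurrence
#'
#' Spearman rank correlation (average ranks under ties) between each
#' eMGE's and each candidate host's length-normalized abundance across
#' samples; pairs at or above the threshold are predicted.
#'
#' @param abundance an [abundance_matrix()] containing both eMGEs and
#'   candidate hosts.
#' @param emge_ids,host_ids row names to correlate.
#' @param threshold minimum Spearman correlation (default 0.7,
#'   inclusive).
#' @param taxa optional named vector mapping host ids to taxon strings.
#' @return prediction data.frame (`emge_id`, `host_id`, `method`,
#'   `score`, ...). Pairs where either vector is constant are skipped.
#' @export
cooccurrence_hosts <- function(abundance, emge_ids, host_ids,
                               threshold = 0.7, taxa = NULL) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  norm <- normalize_abundance(abundance)
  if (ncol(norm) < 3L) stop("co-occurrence requires at least 3 samples")
  miss <- setdiff(c(emge_ids, host_ids), rownames(norm))
  if (length(miss)) stop("missing abundance rows: ", paste(miss, collapse = ", "))
  out <- list()
  for (e in emge_ids) {
    x <- norm[e, ]
    if (stats::sd(x) == 0) next
    for (h in host_ids) {
      y <- norm[h, ]
      if (stats::sd(y) == 0) next
      scc <- stats::cor(x, y, method = "spearman")
      if (!is.na(scc) && scc >= threshold) {
        out[[length(out) + 1L]] <- host_prediction_row(
          e, h, "co-occurrence", scc,
          host_taxon = if (!is.null(taxa)) unname(taxa[h]) else NA_character_)
      }
    }
  }
  do.call(rbind, out) %||% empty_predictions()
}

#' Predict phage hosts by CRISPR spacer matching
#'
#' A spacer of at least `min_len` bp matches a phage when an ungapped
#' alignment covers more than `min_coverage` of the spacer with at most
#' `max_mismatch` mismatches; both strands are searched. Full-length
#' ungapped matches are used, so coverage is complete whenever a hit
#' exists.
#'
#' @param spacers data.frame with `host_id`, `spacer_id`, `sequence`.
#' @param phage_seqs data.frame with `id`, `sequence`.
#' @param min_len minimum spacer length (default 20; shorter spacers are
#'   excluded before the search).
#' @param max_mismatch maximum mismatches (default 1).
#' @param min_coverage minimum alignment coverage of the spacer
#'   (default 0.95, strict `>`).
#' @param taxa optional named host taxon vector.
#' @return prediction data.frame with `score` = mismatch count of the
#'   best hit, and the spacer id in `evidence`.
#' @export
spacer_hits <- function(spacers, phage_seqs, min_len = 20L,
                        max_mismatch = 1L, min_coverage = 0.95,
                        taxa = NULL) {
  spacers <- spacers[nchar(spacers$sequence) >= min_len, , drop = FALSE]
  out <- list()
  if (nrow(spacers) == 0L || nrow(phage_seqs) == 0L) {
    return(empty_predictions())
  }
  subjects <- lapply(phage_seqs$sequence, Biostrings::DNAString)
  for (p in seq_len(nrow(phage_seqs))) {
    subj <- subjects[[p]]
    for (s in seq_len(nrow(spacers))) {
      sp <- spacers$sequence[s]
      best <- NA_integer_
      for (pat in c(sp, revcomp(sp))) {
        m <- Biostrings::matchPattern(pat, subj,
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m)) {
          mm <- vapply(as.character(m), function(hit) {
            sum(utf8ToInt(hit) != utf8ToInt(pat))
          }, 0L, USE.NAMES = FALSE)
          best <- min(best, min(mm), na.rm = TRUE)
        }
      }
      if (!is.na(best) && best <= max_mismatch) {
        out[[length(out) + 1L]] <- host_prediction_row(
          phage_seqs$id[p], spacers$host_id[s], "crispr", best,
          evidence = spacers$spacer_id[s],
          host_taxon = if (!is.null(taxa)) unname(taxa[spacers$host_id[s]])
                       else NA_character_)
      }
    }
  }
  do.call(rbind, out) %||% empty_predictions()
}

#' Filter chromosome methylation motifs into a bait set
#'
#' Chromosome-bin motifs with methylated fraction and mean coverage at or
#' above the thresholds are retained as baits for eMGE-host linking. The
#' motif GATC (m6A) is always removed: it is ubiquitous among bacteria
#' and carries no host-specific signal.
#'
#' @param profiles [motif_profiles()] of chromosome bins.
#' @param min_fraction minimum methylated fraction (default 0.6,
#'   inclusive).
#' @param min_coverage minimum mean coverage (default 25, inclusive).
#' @return data.frame with `motif`, `mod_type`: the baited motif set.
#' @export
filter_motifs <- function(profiles, min_fraction = 0.6, min_coverage = 25) {
  keep <- !is.na(profiles$methylated_fraction) &
    !is.na(profiles$mean_coverage) &
    profiles$methylated_fraction >= min_fraction &
    profiles$mean_coverage >= min_coverage &
    !(profiles$motif == "GATC" & profiles$mod_type == "m6A")
  unique(profiles[keep, c("motif", "mod_type"), drop = FALSE])
}

#' Binarize mean IPD ratios
#'
#' IPD ratios strictly above the threshold indicate methylation (1);
#' others are unmethylated (0); missing stays missing.
#'
#' @param ipd numeric vector of mean IPD ratios (NA = motif absent).
#' @param threshold binarization cutoff (default 2.5, strict `>`).
#' @return integer vector of 0/1/NA.
#' @export
binarize_ipd <- function(ipd, threshold = 2.5) {
  ifelse(is.na(ipd), NA_integer_, as.integer(ipd > threshold))
}

#' Link eMGEs to chromosome bins by shared methylation motifs
#'
#' An eMGE and a bin are linked when at least one baited motif occurs in
#' both and, for every baited motif present in both, the binarized IPD
#' states are equal (missing values are ignored as wildcards). The score
#' is the number of agreeing shared motifs.
#'
#' @param emge_profiles,bin_profiles [motif_profiles()] tables.
#' @param baits bait motif set from [filter_motifs()].
#' @param threshold IPD binarization cutoff (default 2.5).
#' @param taxa optional named host taxon vector keyed by bin id.
#' @return prediction data.frame (`method` = `"methylation"`).
#' @export
link_by_motifs <- function(emge_profiles, bin_profiles, baits,
                           threshold = 2.5, taxa = NULL) {
  key <- function(df) paste(df$motif, df$mod_type)
  bait_keys <- key(baits)
  prep <- function(df) {
    df <- df[key(df) %in% bait_keys, , drop = FALSE]
    df$state <- binarize_ipd(df$mean_ipd_ratio, threshold)
    df
  }
  ep <- prep(emge_profiles)
  bp <- prep(bin_profiles)
  out <- list()
  for (e in unique(ep$sequence_id)) {
    e_rows <- ep[ep$sequence_id == e & !is.na(ep$state), , drop = FALSE]
    if (nrow(e_rows) == 0L) next
    e_states <- stats::setNames(e_rows$state, key(e_rows))
    for (b in unique(bp$sequence_id)) {
      b_rows <- bp[bp$sequence_id == b & !is.na(bp$state), , drop = FALSE]
      shared <- intersect(names(e_states), key(b_rows))
      if (length(shared) == 0L) next
      b_states <- stats::setNames(b_rows$state, key(b_rows))
      if (all(e_states[shared] == b_states[shared])) {
        out[[length(out) + 1L]] <- host_prediction_row(
          e, b, "methylation", length(shared),
          evidence = paste(shared, collapse = ","),
          host_taxon = if (!is.null(taxa)) unname(taxa[b]) else NA_character_)
      }
    }
  }
  do.call(rbind, out) %||% empty_predictions()
}

#' Consolidate host predictions across methods
#'
#' One row per eMGE listing each method's predicted host(s) and
#' agreement/conflict flags at each taxonomic rank. No method's call is
#' overridden. Similarity-search assignments computed upstream may be
#' supplied as additional rows with `method = "similarity"`.
#'
#' @param predictions prediction data.frame (rows from any of the
#'   prediction functions, and optionally similarity assignments).
#' @param ranks names of the `;`-separated fields of the taxon strings
#'   (outermost first).
#' @return data.frame with one row per eMGE: per-method host lists, and
#'   `flags` such as `"agree@species"` or `"conflict@genus"`.
#' @export
consolidate_hosts <- function(predictions,
                              ranks = c("phylum", "genus", "species")) {
  if (nrow(predictions) == 0L) {
    return(data.frame(emge_id = character(), flags = character(),
                      stringsAsFactors = FALSE))
  }
  methods <- sort(unique(predictions$method))
  out <- lapply(sort(unique(predictions$emge_id)), function(e) {
    pe <- predictions[predictions$emge_id == e, , drop = FALSE]
    row <- list(emge_id = e)
    for (m in methods) {
      hosts <- sort(unique(pe$host_id[pe$method == m]))
      row[[paste0("host_", gsub("[^a-z]", "_", m))]] <-
        paste(hosts, collapse = ",")
    }
    # rank-by-rank comparison of the best (first) host taxon per method
    flags <- character()
    tax_by_method <- lapply(methods, function(m) {
      tx <- pe$host_taxon[pe$method == m]
      tx <- tx[!is.na(tx)]
      if (length(tx)) strsplit(tx[1L], ";", fixed = TRUE)[[1L]] else NULL
    })
    tax_by_method <- Filter(Negate(is.null), tax_by_method)
    if (length(tax_by_method) >= 2L) {
      for (r in seq_along(ranks)) {
        vals <- vapply(tax_by_method,
                       function(t) if (length(t) >= r) t[r] else NA_character_,
                       "")
        vals <- vals[!is.na(vals)]
        if (length(vals) >= 2L) {
          if (length(unique(vals)) == 1L) {
            flags <- c(flags, paste0("agree@", ranks[r]))
          } else {
            flags <- c(flags, paste0("conflict@", ranks[r]))
          }
        }
      }
    }
    row$n_methods <- length(unique(pe$method))
    row$flags <- paste(flags, collapse = ";")
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Host-eMGE bipartite network edges
#'
#' @param predictions prediction data.frame (or consolidated table rows
#'   expanded upstream).
#' @return data.frame with `host`, `emge` and `methods` columns, one row
#'   per unique host-eMGE pair, suitable for TSV export.
#' @export
host_network <- function(predictions) {
  if (nrow(predictions) == 0L) {
    return(data.frame(host = character(), emge = character(),
                      methods = character(), stringsAsFactors = FALSE))
  }
  sp <- split(predictions$method,
              paste(predictions$host_id, predictions$emge_id, sep = "\r"))
  keys <- strsplit(names(sp), "\r", fixed = TRUE)
  df <- data.frame(
    host = vapply(keys, `[[`, "", 1L),
    emge = vapply(keys, `[[`, "", 2L),
    methods = vapply(sp, function(m) paste(sort(unique(m)), collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$host, df$emge), , drop = FALSE]
  rownames(df) <- NULL
  df
}
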