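# eMGE clustering and quantification: breadth-of-coverage exclusion,
# similarity clustering with a longest-representative convention,
# per-cluster read counting with length normalization, the
# eMGE-per-chromosome ratio estimator, and gene-based microbial
# composition from contigs.

#' Breadth of coverage of an element by alignments
#'
#' @param aln [alignments()] whose targets include the element.
#' @param element_id element id (alignment target).
#' @param element_length element length in bp.
#' @return fraction of positions covered by at least one alignment
#'   (union of aligned target intervals over element length).
#' @export
mapped_coverage <- function(aln, element_id, element_length) {
  a <- aln[aln$target_id == element_id, , drop = FALSE]
  if (nrow(a) == 0L) return(0)
  interval_union_width(a$target_start, a$target_end,
                       limit = element_length) / element_length
}

# Pairwise similarity decision used for clustering: identity (length-
# weighted), union coverage of the SHORTER sequence, and length ratio.
pair_similarity <- function(aln_pair, id_a, id_b, len_a, len_b) {
  if (nrow(aln_pair) == 0L) {
    return(list(identity = 0, coverage = 0,
                length_ratio = min(len_a, len_b) / max(len_a, len_b)))
  }
  ident <- sum(aln_pair$identity * aln_pair$aligned_length) /
    sum(aln_pair$aligned_length)
  shorter <- if (len_a <= len_b) id_a else id_b
  len_short <- min(len_a, len_b)
  ss <- ifelse(aln_pair$query_id == shorter,
               aln_pair$query_start, aln_pair$target_start)
  se <- ifelse(aln_pair$query_id == shorter,
               aln_pair$query_end, aln_pair$target_end)
  cov <- interval_union_width(ss, se, limit = len_short) / len_short
  list(identity = ident, coverage = cov,
       length_ratio = len_short / max(len_a, len_b))
}

#' Cluster eMGEs by pairwise sequence similarity
#'
#' Two elements are similar when their alignment identity is at least
#' `min_identity`, the union alignment coverage of the shorter sequence
#' is at least `min_coverage`, and the shorter-to-longer length ratio is
#' at least `min_length_ratio`. Clusters are the connected components of
#' the similarity graph (single linkage); each cluster's representative
#' is its longest member (ties broken by lexicographic id).
#'
#' @param aln pairwise [alignments()] among elements.
#' @param lengths named numeric vector of element lengths for every
#'   element to cluster (isolated elements become singletons).
#' @param min_identity,min_coverage,min_length_ratio thresholds
#'   (defaults 0.90, 0.70, 0.7; all inclusive).
#' @return list of [emge_cluster()] objects, ordered by representative
#'   id; clusters whose internal pairs do not all meet the thresholds
#'   carry attribute `nontransitive = TRUE`.
#' @export
cluster_emges <- function(aln, lengths, min_identity = 0.90,
                          min_coverage = 0.70, min_length_ratio = 0.7) {
  ids <- sort(names(lengths))
  if (length(ids) == 0L) return(list())
  if (anyNA(lengths)) stop("missing element length")
  ref <- unique(c(aln$query_id, aln$target_id))
  miss <- setdiff(ref, ids)
  if (length(miss)) stop("alignments reference elements without lengths: ",
                         paste(miss, collapse = ", "))
  similar <- function(a, b) {
    sel <- (aln$query_id == a & aln$target_id == b) |
      (aln$query_id == b & aln$target_id == a)
    s <- pair_similarity(aln[sel, , drop = FALSE], a, b,
                         lengths[[a]], lengths[[b]])
    s$identity >= min_identity && s$coverage >= min_coverage &&
      s$length_ratio >= min_length_ratio
  }
  pairs <- unique(data.frame(
    a = pmin(aln$query_id, aln$target_id),
    b = pmax(aln$query_id, aln$target_id),
    stringsAsFactors = FALSE))
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  edge <- vapply(seq_len(nrow(pairs)),
                 function(i) similar(pairs$a[i], pairs$b[i]), NA)
  g <- igraph::graph_from_data_frame(
    pairs[edge, , drop = FALSE], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  clusters <- split(names(comp$membership), comp$membership)
  out <- list()
  for (members in clusters) {
    cl <- emge_cluster(cluster_id = "", members = members, lengths = lengths)
    cl$cluster_id <- paste0("cluster:", cl$representative)
    if (length(members) > 2L) {
      all_ok <- all(utils::combn(sort(members), 2L, FUN = function(p) {
        similar(p[1L], p[2L])
      }))
      if (!all_ok) attr(cl, "nontransitive") <- TRUE
    }
    out[[length(out) + 1L]] <- cl
  }
  out[order(vapply(out, `[[`, "", "representative"))]
}

#' Per-cluster read-count abundance across samples
#'
#' Per sample, reads aligning at identity `min_identity` or better to
#' any cluster member are counted once for that cluster: each read's
#' best hit wins (highest identity, then fewest mismatches, then
#' lexicographic cluster id). Counts are normalized by the length of the
#' cluster's longest representative, in reads per kb.
#'
#' @param read_aln named list (one [alignments()] per sample) of read
#'   alignments against cluster members.
#' @param clusters list of [emge_cluster()].
#' @param min_identity identity threshold (default 0.95, inclusive).
#' @return list with `counts` (clusters x samples matrix of read
#'   counts) and `abundance` (reads per kb of representative).
#' @export
cluster_abundance <- function(read_aln, clusters, min_identity = 0.95) {
  cl_ids <- vapply(clusters, `[[`, "", "cluster_id")
  member_to_cluster <- stats::setNames(
    rep(cl_ids, vapply(clusters, function(cl) length(cl$members), 0L)),
    unlist(lapply(clusters, `[[`, "members")))
  rep_len <- stats::setNames(
    vapply(clusters, `[[`, 0, "representative_length"), cl_ids)
  counts <- matrix(0L, nrow = length(cl_ids), ncol = length(read_aln),
                   dimnames = list(cl_ids, names(read_aln)))
  for (s in seq_along(read_aln)) {
    a <- read_aln[[s]]
    a <- a[a$identity >= min_identity &
             a$target_id %in% names(member_to_cluster), , drop = FALSE]
    if (nrow(a) == 0L) next
    a$cluster <- unname(member_to_cluster[a$target_id])
    a$mismatches <- round((1 - a$identity) * a$aligned_length)
    a <- a[order(a$query_id, -a$identity, a$mismatches, a$cluster), ,
           drop = FALSE]
    best <- a[!duplicated(a$query_id), , drop = FALSE]
    tb <- table(best$cluster)
    counts[names(tb), s] <- counts[names(tb), s] + as.integer(tb)
  }
  list(counts = counts,
       abundance = sweep(counts, 1, rep_len / 1000, "/"))
}

#' eMGE-per-chromosome ratio estimator
#'
#' The number of eMGE molecules per chromosome, estimated from mapped
#' read counts and average element sizes:
#' `(reads_emge / mean_emge_size) / (reads_chrom / mean_chrom_size)`.
#'
#' @param reads_emge,reads_chrom mapped read counts.
#' @param mean_emge_size,mean_chrom_size average element sizes in bp.
#' @return the ratio (dimensionless molecules per chromosome).
#' @export
emge_to_chromosome_ratio <- function(reads_emge, mean_emge_size,
                                     reads_chrom, mean_chrom_size) {
  stopifnot(mean_emge_size > 0, mean_chrom_size > 0)
  if (reads_chrom <= 0) stop("no reads mapped to chromosomes")
  (reads_emge / mean_emge_size) / (reads_chrom / mean_chrom_size)
}

#' Microbial composition from gene-annotated contigs
#'
#' Each taxon's score is the sum over its genes of the gene's contig
#' read depth divided by the gene length; relative abundance is the
#' score normalized over all taxa.
#'
#' @param genes a [gene_table()] with non-missing `taxon` for assigned
#'   genes (unassigned genes are dropped).
#' @param contig_depths named numeric vector of contig read depths.
#' @return named numeric vector of relative abundances summing to 1.
#' @export
composition_from_contigs <- function(genes, contig_depths) {
  g <- genes[!is.na(genes$taxon), , drop = FALSE]
  if (nrow(g) == 0L) stop("no taxon-assigned genes")
  miss <- setdiff(unique(g$contig_id), names(contig_depths))
  if (length(miss)) stop("missing contig depths: ", paste(miss, collapse = ", "))
  score <- tapply(contig_depths[g$contig_id] / g$length, g$taxon, sum)
  score <- score / sum(score)
  stats::setNames(as.numeric(score), names(score))
}

#' Concordance between two composition vectors
#'
#' Pearson correlation over the union of taxa (absent taxa count as 0).
#'
#' @param a,b named numeric composition vectors.
#' @return Pearson correlation, or `NA` when either vector is constant.
#' @export
composition_concordance <- function(a, b) {
  taxa <- union(names(a), names(b))
  x <- stats::setNames(rep(0, length(taxa)), taxa)
  y <- x
  x[names(a)] <- a
  y[names(b)] <- b
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
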