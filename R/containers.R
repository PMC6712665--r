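# Domain containers. Tables are plain data.frames with required columns;
# structured objects are lightweight S3 lists, in the style of base-R
# bioinformatics packages.

#' Construct a unitig graph
#'
#' The assembly graph substrate for circular-contig recovery. Unitigs are
#' edges; junctions are nodes. A unitig runs from its `from` junction (its
#' 5' head) to its `to` junction (its 3' tail), so at a junction the
#' in-edges are the unitigs whose `to` equals the junction and the
#' out-edges those whose `from` equals it.
#'
#' @param unitigs data.frame with columns `id`, `sequence`, `depth`,
#'   `bin_id`, `from`, `to` (junction ids). An optional list-column
#'   `members` tracks the original unitigs merged into each edge.
#' @param junctions character vector of junction ids; defaults to those
#'   referenced by `unitigs`.
#' @param junction_overlap named numeric vector of overlap lengths (bp)
#'   trimmed when merging across a junction; missing junctions default 0.
#' @return an object of class `unitig_graph`.
#' @export
unitig_graph <- function(unitigs, junctions = NULL, junction_overlap = numeric()) {
  stopifnot(is.data.frame(unitigs))
  need <- c("id", "sequence", "depth", "bin_id", "from", "to")
  miss <- setdiff(need, names(unitigs))
  if (length(miss)) stop("unitigs lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(unitigs$id)) stop("duplicate unitig ids")
  if (nrow(unitigs)) {
    assert_dna(unitigs$sequence, "unitig sequence")
    if (any(unitigs$depth < 0)) stop("unitig depth must be >= 0")
    if (any(!nzchar(unitigs$bin_id))) stop("bin_id must be non-empty")
  }
  if (is.null(junctions)) {
    junctions <- unique(c(unitigs$from, unitigs$to))
  }
  if (nrow(unitigs) && !all(c(unitigs$from, unitigs$to) %in% junctions)) {
    stop("unitig endpoint references an unknown junction")
  }
  if (is.null(unitigs$members)) {
    unitigs$members <- as.list(unitigs$id)
  }
  structure(
    list(unitigs = unitigs, junctions = junctions,
         junction_overlap = junction_overlap),
    class = "unitig_graph"
  )
}

#' @export
print.unitig_graph <- function(x, ...) {
  cat("unitig_graph:", nrow(x$unitigs), "unitigs,",
      length(x$junctions), "junctions\n")
  invisible(x)
}

junction_overlap_of <- function(graph, junction) {
  ov <- graph$junction_overlap
  if (!is.null(ov) && junction %in% names(ov)) unname(ov[[junction]]) else 0
}

#' Construct a circular contig
#'
#' @param id contig id.
#' @param sequence circular DNA sequence (one copy, canonical or as
#'   assembled).
#' @param depth mean read depth.
#' @param member_unitigs ordered character vector of source unitig ids.
#' @param min_length minimum admissible circle length in bp (assembly
#'   overlap cutoff; circles below it are not identifiable).
#' @return object of class `circular_contig`.
#' @export
circular_contig <- function(id, sequence, depth = NA_real_,
                            member_unitigs = character(),
                            min_length = 2200) {
  assert_dna(sequence, "circular contig sequence")
  if (nchar(sequence) < min_length) {
    stop("circular contig shorter than minimum circle length (",
         min_length, " bp)")
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         depth = depth, member_unitigs = member_unitigs),
    class = "circular_contig"
  )
}

#' Evidence supporting a terminal-direct-repeat call
#'
#' @param coverage_ratio observed depth in the candidate repeat region over
#'   the median depth of the remainder (about 2 for a collapsed TDR).
#' @param spanning_reads number of reads spanning the candidate with flanks
#'   on both sides (0 expected for a genuine TDR).
#' @param start_excess read-terminus frequency at the candidate boundaries
#'   relative to background.
#' @return object of class `tdr_evidence`.
#' @export
tdr_evidence <- function(coverage_ratio, spanning_reads, start_excess) {
  stopifnot(coverage_ratio > 0, spanning_reads >= 0)
  structure(list(coverage_ratio = coverage_ratio,
                 spanning_reads = as.integer(spanning_reads),
                 start_excess = start_excess),
            class = "tdr_evidence")
}

#' Construct a linear genome with terminal direct repeats
#'
#' @param id genome id.
#' @param sequence full linear sequence including both TDR copies.
#' @param tdr_length length of the terminal repeat in bp.
#' @param evidence optional [tdr_evidence()].
#' @param max_tdr_mismatch maximum tolerated mismatches between the two
#'   TDR copies (0 for error-free assemblies).
#' @return object of class `linear_genome` with `left_tdr`/`right_tdr`
#'   0-based half-open intervals.
#' @export
linear_genome <- function(id, sequence, tdr_length, evidence = NULL,
                          max_tdr_mismatch = 0L) {
  assert_dna(sequence, "linear genome sequence")
  L <- nchar(sequence)
  stopifnot(tdr_length >= 1, 2 * tdr_length <= L)
  left <- substr(sequence, 1L, tdr_length)
  right <- substr(sequence, L - tdr_length + 1L, L)
  mm <- sum(utf8ToInt(left) != utf8ToInt(right))
  if (mm > max_tdr_mismatch) {
    stop("left and right TDR copies differ at ", mm,
         " positions (tolerance ", max_tdr_mismatch, ")")
  }
  structure(
    list(id = id, sequence = sequence, length = L,
         tdr_length = as.integer(tdr_length),
         left_tdr = c(0L, as.integer(tdr_length)),
         right_tdr = c(L - as.integer(tdr_length), L),
         evidence = evidence),
    class = "linear_genome"
  )
}

#' Build an alignment record table
#'
#' Generic query-to-target interval alignments (the carrier for read
#' mappings, reference hits and pairwise eMGE comparisons). Coordinates
#' are 0-based half-open; on circular targets `target_end` may exceed the
#' target length to encode wrap-around.
#'
#' @param query_id,target_id character vectors.
#' @param query_start,query_end,target_start,target_end integer vectors,
#'   0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param identity fraction of matching columns in `[0, 1]`.
#' @param aligned_length alignment block length in bp.
#' @param query_len,target_len optional full sequence lengths (kept for
#'   PAF round-trips).
#' @return data.frame of class `c("alignments", "data.frame")`.
#' @export
alignments <- function(query_id = character(), target_id = character(),
                       query_start = integer(), query_end = integer(),
                       target_start = integer(), target_end = integer(),
                       strand = character(), identity = numeric(),
                       aligned_length = integer(),
                       query_len = NA_integer_, target_len = NA_integer_) {
  n <- length(query_id)
  if (length(query_len) != n) query_len <- rep_len(query_len, n)
  if (length(target_len) != n) target_len <- rep_len(target_len, n)
  if (n > 0L) {
    query_start <- rep_len(query_start, n)
    query_end <- rep_len(query_end, n)
    target_start <- rep_len(target_start, n)
    target_end <- rep_len(target_end, n)
    strand <- rep_len(strand, n)
    identity <- rep_len(identity, n)
    aligned_length <- rep_len(aligned_length, n)
  }
  df <- data.frame(
    query_id = as.character(query_id), target_id = as.character(target_id),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    target_start = as.integer(target_start), target_end = as.integer(target_end),
    strand = as.character(strand), identity = as.numeric(identity),
    aligned_length = as.integer(aligned_length),
    query_len = as.integer(query_len), target_len = as.integer(target_len),
    stringsAsFactors = FALSE
  )
  validate_alignments(df)
}

validate_alignments <- function(df) {
  if (nrow(df)) {
    if (any(df$query_end <= df$query_start) ||
        any(df$target_end <= df$target_start)) {
      stop("alignment intervals must satisfy end > start")
    }
    if (any(df$query_start < 0) || any(df$target_start < 0)) {
      stop("alignment coordinates must be non-negative")
    }
    if (any(df$identity < 0 | df$identity > 1)) {
      stop("identity must lie in [0, 1]")
    }
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  class(df) <- unique(c("alignments", class(df)))
  df
}

#' Build a gene annotation table
#'
#' @param gene_id,contig_id character vectors.
#' @param start,end 0-based half-open gene coordinates on the contig.
#' @param strand `"+"`/`"-"`.
#' @param cog_id COG family id (`NA` if unannotated).
#' @param cog_category single-letter COG functional category (`NA` allowed).
#' @param pog_hit logical: gene hits a phage orthologous group.
#' @param hit_coverage fraction of gene length covered by the POG hit.
#' @param taxon semicolon-delimited taxon string (`NA` allowed).
#' @param is_arg logical: antibiotic resistance gene.
#' @return data.frame of class `c("gene_table", "data.frame")`.
#' @export
gene_table <- function(gene_id, contig_id, start, end, strand = "+",
                       cog_id = NA_character_, cog_category = NA_character_,
                       pog_hit = FALSE, hit_coverage = 0,
                       taxon = NA_character_, is_arg = FALSE) {
  n <- length(gene_id)
  contig_id <- rep_len(contig_id, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  strand <- rep_len(strand, n)
  cog_id <- rep_len(cog_id, n)
  cog_category <- rep_len(cog_category, n)
  pog_hit <- rep_len(pog_hit, n)
  hit_coverage <- rep_len(hit_coverage, n)
  taxon <- rep_len(taxon, n)
  is_arg <- rep_len(is_arg, n)
  df <- data.frame(
    gene_id = as.character(gene_id), contig_id = as.character(contig_id),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    cog_id = as.character(cog_id), cog_category = as.character(cog_category),
    pog_hit = as.logical(pog_hit), hit_coverage = as.numeric(hit_coverage),
    taxon = as.character(taxon), is_arg = as.logical(is_arg),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$end <= df$start)) stop("gene end must exceed start")
    if (any(df$hit_coverage < 0 | df$hit_coverage > 1)) {
      stop("hit_coverage must lie in [0, 1]")
    }
  }
  df$length <- df$end - df$start
  class(df) <- unique(c("gene_table", class(df)))
  df
}

#' Build a methylation motif profile table
#'
#' One row per (sequence, motif): the motif's methylated fraction, mean
#' per-strand coverage at motif sites, and mean IPD ratio. A motif absent
#' from the sequence is recorded with missing kinetics.
#'
#' @param sequence_id,motif,mod_type character vectors (`mod_type` is
#'   `"m6A"` or `"m4C"`).
#' @param methylated_fraction fraction of motif sites called methylated.
#' @param mean_coverage mean per-strand read depth over motif sites.
#' @param mean_ipd_ratio mean inter-pulse-duration ratio (`NA` if the
#'   motif does not occur).
#' @param binary_state optional 0/1/`NA`; recomputed by [binarize_ipd()].
#' @param sequence_type optional `"chromosome"`/`"plasmid"`/`"phage"`.
#' @return data.frame of class `c("motif_profiles", "data.frame")`.
#' @export
motif_profiles <- function(sequence_id, motif, mod_type = "m6A",
                           methylated_fraction = NA_real_,
                           mean_coverage = NA_real_,
                           mean_ipd_ratio = NA_real_,
                           binary_state = NA_integer_,
                           sequence_type = NA_character_) {
  df <- data.frame(
    sequence_id = as.character(sequence_id), motif = as.character(motif),
    mod_type = as.character(mod_type),
    methylated_fraction = as.numeric(methylated_fraction),
    mean_coverage = as.numeric(mean_coverage),
    mean_ipd_ratio = as.numeric(mean_ipd_ratio),
    binary_state = as.integer(binary_state),
    sequence_type = as.character(sequence_type),
    stringsAsFactors = FALSE
  )
  ok <- is.na(df$methylated_fraction) |
    (df$methylated_fraction >= 0 & df$methylated_fraction <= 1)
  if (!all(ok)) stop("methylated_fraction must lie in [0, 1]")
  class(df) <- unique(c("motif_profiles", class(df)))
  df
}

#' Construct an abundance matrix
#'
#' @param counts numeric matrix, elements x samples, of mapped read counts
#'   (all entries >= 0).
#' @param lengths named numeric vector of element lengths in bp, covering
#'   every row of `counts`.
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("abundance entries must be >= 0")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) stop("missing lengths for: ", paste(miss, collapse = ", "))
  structure(list(counts = counts, lengths = lengths[rownames(counts)]),
            class = "abundance_matrix")
}

#' Length-normalize an abundance matrix
#'
#' @param x an [abundance_matrix()].
#' @param per bp unit of normalization (default 1000: reads per kb).
#' @return numeric matrix of reads per `per` bp.
#' @export
normalize_abundance <- function(x, per = 1000) {
  stopifnot(inherits(x, "abundance_matrix"))
  sweep(x$counts, 1, x$lengths / per, "/")
}

#' Construct an eMGE cluster
#'
#' @param cluster_id cluster label.
#' @param members character vector of member element ids.
#' @param lengths named numeric vector of member lengths.
#' @return object of class `emge_cluster`; the representative is the
#'   longest member (ties broken by lexicographic id).
#' @export
emge_cluster <- function(cluster_id, members, lengths) {
  stopifnot(length(members) >= 1, all(members %in% names(lengths)))
  len <- lengths[members]
  ord <- order(-len, members)
  rep_id <- members[ord[1L]]
  structure(
    list(cluster_id = cluster_id, members = sort(members),
         representative = rep_id,
         representative_length = unname(len[ord[1L]])),
    class = "emge_cluster"
  )
}
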