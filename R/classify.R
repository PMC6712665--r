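# Phage/plasmid classification of circular contigs from gene-level
# evidence: phage orthologous group (POG) content, plasmid-enriched COGs,
# reference similarity, and optional external classifier verdicts.

#' Plasmid-enriched COG families
#'
#' The fixed 13-member list of COGs related to plasmid replication,
#' toxin-antitoxin systems and the type IV secretion system whose presence
#' on a circular contig is evidence of plasmid origin.
#'
#' @format character vector of 13 COG ids.
#' @export
PLASMID_COGS <- c("COG1475", "COG2026", "COG2126", "COG2336", "COG2948",
                  "COG3077", "COG3451", "COG3505", "COG3704", "COG3736",
                  "COG3843", "COG5527", "COG5655")

#' Fraction of a contig's genes with confident POG hits
#'
#' A gene counts as POG-supported when its best phage-orthologous-group
#' hit covers strictly more than `min_hit_coverage` of the gene length.
#'
#' @param genes a [gene_table()] restricted to one circular contig.
#' @param min_hit_coverage length-coverage threshold (default 0.90,
#'   strict `>`).
#' @return numeric fraction in `[0, 1]`, with attribute `no_genes = TRUE`
#'   when the gene list is empty.
#' @export
pog_fraction <- function(genes, min_hit_coverage = 0.90) {
  if (nrow(genes) == 0L) {
    return(structure(0, no_genes = TRUE))
  }
  hit <- genes$pog_hit & genes$hit_coverage > min_hit_coverage
  structure(mean(hit), no_genes = FALSE)
}

#' Plasmid-enriched COGs present on a contig
#'
#' @param genes a [gene_table()] for one contig.
#' @param cog_list the plasmid-enriched COG set (default [PLASMID_COGS]).
#' @return character vector: intersection of the contig's COG annotations
#'   with `cog_list`.
#' @export
plasmid_cog_evidence <- function(genes, cog_list = PLASMID_COGS) {
  cogs <- unique(genes$cog_id[!is.na(genes$cog_id)])
  sort(intersect(cogs, cog_list))
}

#' Assign a contig to a reference plasmid/phage by similarity
#'
#' A contig is assigned to the best reference with sequence identity at or
#' above `min_identity` and length coverage (union of aligned contig
#' intervals over contig length) at or above `min_coverage`. The best
#' reference is the one with highest coverage, ties broken by higher
#' identity then lexicographic id.
#'
#' @param cc_id contig id (the alignment query).
#' @param cc_length contig length in bp.
#' @param aln [alignments()] of the contig against reference sequences.
#' @param ref_classes named character vector mapping reference ids to
#'   `"plasmid"` or `"phage"`.
#' @param min_identity identity threshold (default 0.90, inclusive).
#' @param min_coverage contig length-coverage threshold (default 0.70,
#'   inclusive).
#' @return `NULL` when unassigned, else list(reference, class, identity,
#'   coverage).
#' @export
reference_assignment <- function(cc_id, cc_length, aln, ref_classes,
                                 min_identity = 0.90, min_coverage = 0.70) {
  a <- aln[aln$query_id == cc_id, , drop = FALSE]
  if (nrow(a) == 0L) return(NULL)
  refs <- sort(unique(a$target_id))
  best <- NULL
  for (r in refs) {
    ar <- a[a$target_id == r, , drop = FALSE]
    cov <- interval_union_width(ar$query_start, ar$query_end,
                                limit = cc_length) / cc_length
    ident <- sum(ar$identity * ar$aligned_length) / sum(ar$aligned_length)
    if (ident >= min_identity && cov >= min_coverage) {
      cand <- list(reference = r,
                   class = unname(ref_classes[[r]]),
                   identity = ident, coverage = cov)
      if (is.null(best) ||
          cand$coverage > best$coverage ||
          (cand$coverage == best$coverage && cand$identity > best$identity)) {
        best <- cand
      }
    }
  }
  best
}

#' Classify a circular contig as phage or plasmid
#'
#' A contig is called phage when its POG fraction reaches
#' `phage_call_fraction` or an external classifier supplies a phage
#' verdict, unless a reference assignment says plasmid, in which case the
#' reference wins and the contig is flagged as a conflict. Everything
#' else is a plasmid: plasmid is the default class, and plasmid-enriched
#' COGs or a reference plasmid hit only add supporting rationale.
#'
#' @param pog_frac output of [pog_fraction()].
#' @param plasmid_cogs output of [plasmid_cog_evidence()].
#' @param ref output of [reference_assignment()] (`NULL` if none).
#' @param external optional list of external classifier verdicts:
#'   `virsorter_category` (integer; categories 1, 2, 4 and 5 count as
#'   phage evidence, 3 and 6 are ignored as false-positive-prone) and/or
#'   `plasflow` (`"plasmid"`/`"chromosome"`/`"unclassified"`).
#' @param phage_call_fraction POG-fraction cutoff for calling phage
#'   (default 0.5).
#' @return list(class, rationale, conflict) where `class` is `"phage"` or
#'   `"plasmid"` and `rationale` lists each evidence item considered.
#' @export
classify_cc <- function(pog_frac, plasmid_cogs = character(), ref = NULL,
                        external = NULL, phage_call_fraction = 0.5) {
  rationale <- character()
  phage_evidence <- FALSE
  if (isTRUE(attr(pog_frac, "no_genes"))) {
    rationale <- c(rationale, "no genes annotated")
  }
  if (as.numeric(pog_frac) >= phage_call_fraction) {
    phage_evidence <- TRUE
    rationale <- c(rationale, sprintf("POG fraction %.2f >= %.2f",
                                      as.numeric(pog_frac),
                                      phage_call_fraction))
  } else {
    rationale <- c(rationale, sprintf("POG fraction %.2f < %.2f",
                                      as.numeric(pog_frac),
                                      phage_call_fraction))
  }
  if (!is.null(external)) {
    vc <- external$virsorter_category
    if (!is.null(vc) && !is.na(vc)) {
      if (vc %in% c(1L, 2L, 4L, 5L)) {
        phage_evidence <- TRUE
        rationale <- c(rationale, sprintf("VirSorter category %d", vc))
      } else {
        rationale <- c(rationale,
                       sprintf("VirSorter category %d ignored", vc))
      }
    }
    pf <- external$plasflow
    if (!is.null(pf) && !is.na(pf) && identical(pf, "plasmid")) {
      rationale <- c(rationale, "PlasFlow plasmid call")
    }
  }
  if (length(plasmid_cogs)) {
    rationale <- c(rationale, paste0("plasmid-enriched COGs: ",
                                     paste(plasmid_cogs, collapse = ",")))
  }
  conflict <- FALSE
  if (!is.null(ref)) {
    rationale <- c(rationale,
                   sprintf("reference %s (%s): identity %.3f coverage %.3f",
                           ref$reference, ref$class, ref$identity,
                           ref$coverage))
    if (identical(ref$class, "plasmid")) {
      if (phage_evidence) conflict <- TRUE
      return(list(class = "plasmid", rationale = rationale,
                  conflict = conflict))
    }
    if (identical(ref$class, "phage")) {
      return(list(class = "phage", rationale = rationale, conflict = FALSE))
    }
  }
  list(class = if (phage_evidence) "phage" else "plasmid",
       rationale = rationale, conflict = FALSE)
}
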