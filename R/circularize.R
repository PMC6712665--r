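# Bin-guided untangling of the unitig graph: if a junction has exactly one
# in-edge and one out-edge carrying the same bin id, the two unitigs are
# concatenated. Applied to fixed point, the surviving self-loops of
# sufficient length are reported as circular contigs.

# Classify a junction for merging. Returns a list(status, in_id, out_id).
junction_status <- function(graph, j) {
  u <- graph$unitigs
  ins <- u$id[u$to == j]
  outs <- u$id[u$from == j]
  self <- intersect(ins, outs)
  if (length(ins) == 1L && length(outs) == 1L && ins == outs) {
    return(list(status = "self_loop"))
  }
  if (length(ins) != 1L || length(outs) != 1L) {
    # a head-to-head or tail-to-tail pairing shows up as degree-2 junction
    # with 2 in- or 2 out-edges: an orientation conflict, skipped
    n_end <- length(ins) + length(outs)
    if (n_end == 2L && (length(ins) == 2L || length(outs) == 2L)) {
      return(list(status = "orientation_conflict"))
    }
    return(list(status = "degree"))
  }
  b_in <- u$bin_id[u$id == ins]
  b_out <- u$bin_id[u$id == outs]
  if (!identical(b_in, b_out)) return(list(status = "bin_mismatch"))
  list(status = "mergeable", in_id = ins, out_id = outs)
}

mergeable_junctions <- function(graph) {
  js <- sort(graph$junctions)
  js[vapply(js, function(j) junction_status(graph, j)$status == "mergeable",
            NA)]
}

# Merge the single in-edge and out-edge at junction j (must be mergeable).
merge_at_junction <- function(graph, j) {
  st <- junction_status(graph, j)
  stopifnot(st$status == "mergeable")
  u <- graph$unitigs
  i1 <- which(u$id == st$in_id)
  i2 <- which(u$id == st$out_id)
  ov <- junction_overlap_of(graph, j)
  s1 <- u$sequence[i1]
  s2 <- u$sequence[i2]
  if (ov >= nchar(s2)) stop("junction overlap exceeds successor length")
  merged_seq <- paste0(s1, substr(s2, ov + 1L, nchar(s2)))
  l1 <- nchar(s1); l2 <- nchar(s2) - ov
  merged <- data.frame(
    id = paste(u$id[i1], u$id[i2], sep = ";"),
    sequence = merged_seq,
    depth = (u$depth[i1] * l1 + u$depth[i2] * l2) / (l1 + l2),
    bin_id = u$bin_id[i1],
    from = u$from[i1], to = u$to[i2],
    stringsAsFactors = FALSE
  )
  merged$members <- list(c(u$members[[i1]], u$members[[i2]]))
  u <- u[-c(i1, i2), , drop = FALSE]
  u <- rbind(u, merged)
  rownames(u) <- NULL
  graph$unitigs <- u
  graph$junctions <- setdiff(graph$junctions, j)
  graph$junction_overlap <- graph$junction_overlap[
    setdiff(names(graph$junction_overlap), j)]
  graph
}

#' Merge unitigs across junctions guided by bin assignments
#'
#' Repeatedly, every junction with exactly one in-edge and exactly one
#' out-edge whose bin ids are equal has its two unitigs concatenated
#' (trimming any recorded junction overlap from the successor) into one
#' unitig inheriting the shared bin id and the length-weighted mean depth.
#' The result is independent of the junction visit order.
#'
#' @param graph a [unitig_graph()] whose unitigs all carry bin ids
#'   (unbinned unitigs must already hold distinct fresh ids, as
#'   [read_unitig_graph()] ensures).
#' @param fixed_point if `TRUE` (default) iterate until no junction is
#'   mergeable; if `FALSE` perform a single sweep over the junctions
#'   present at entry.
#' @param order optional character vector of junction ids giving an
#'   explicit processing order (used to exercise order-independence);
#'   default lexicographic.
#' @return the merged [unitig_graph()], with a `report` attribute listing
#'   `merged_junctions` and `skipped` (junction, reason).
#' @export
merge_by_bins <- function(graph, fixed_point = TRUE, order = NULL) {
  stopifnot(inherits(graph, "unitig_graph"))
  merged_log <- character()
  warned <- character()
  initial <- if (is.null(order)) sort(graph$junctions) else order
  queue <- initial
  repeat {
    done_any <- FALSE
    for (j in queue) {
      if (!(j %in% graph$junctions)) next
      st <- junction_status(graph, j)
      if (st$status == "mergeable") {
        graph <- merge_at_junction(graph, j)
        merged_log <- c(merged_log, j)
        done_any <- TRUE
      } else if (st$status == "orientation_conflict" && !(j %in% warned)) {
        warned <- c(warned, j)
        warning("orientation conflict at junction ", j, "; skipped",
                call. = FALSE)
      }
    }
    if (!fixed_point || !done_any) break
    queue <- sort(graph$junctions)
  }
  skipped <- do.call(rbind, lapply(sort(graph$junctions), function(j) {
    data.frame(junction = j, reason = junction_status(graph, j)$status,
               stringsAsFactors = FALSE)
  }))
  attr(graph, "report") <- list(
    merged_junctions = merged_log,
    skipped = skipped %||% data.frame(junction = character(),
                                      reason = character())
  )
  graph
}

#' Detect circular contigs in a merged unitig graph
#'
#' A unitig whose head and tail meet at the same junction is a circle;
#' those at least `min_length` bp long (after trimming the junction
#' overlap) are reported. Sequences are emitted in canonical rotation:
#' the lexicographically minimal rotation, taken on whichever strand
#' yields the smaller minimal rotation, so circles are comparable across
#' runs.
#'
#' @param graph a merged [unitig_graph()].
#' @param min_length minimum circle length in bp (default 2200, the
#'   assembly overlap cutoff below which circles cannot be identified).
#' @return list of [circular_contig()] objects.
#' @export
detect_circles <- function(graph, min_length = 2200) {
  stopifnot(inherits(graph, "unitig_graph"))
  u <- graph$unitigs
  idx <- which(u$from == u$to)
  out <- list()
  for (i in idx) {
    ov <- junction_overlap_of(graph, u$from[i])
    s <- u$sequence[i]
    if (ov > 0) s <- substr(s, 1L, nchar(s) - ov)
    if (nchar(s) < min_length) next
    out[[length(out) + 1L]] <- circular_contig(
      id = paste0("cc:", u$id[i]),
      sequence = canonical_rotation(s),
      depth = u$depth[i],
      member_unitigs = u$members[[i]],
      min_length = min_length
    )
  }
  out
}

#' Recover circular contigs from a unitig graph (stage entry point)
#'
#' Composition of [merge_by_bins()] and [detect_circles()].
#'
#' @inheritParams merge_by_bins
#' @inheritParams detect_circles
#' @return list with `circles` (list of [circular_contig()]), `graph`
#'   (the merged graph) and `report` (merge log and skipped junctions).
#' @export
circularize <- function(graph, min_length = 2200, fixed_point = TRUE) {
  merged <- merge_by_bins(graph, fixed_point = fixed_point)
  list(circles = detect_circles(merged, min_length = min_length),
       graph = merged,
       report = attr(merged, "report"))
}
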