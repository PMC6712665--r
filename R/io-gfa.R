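# GFA-1 dialect for unitig graphs: S-lines carry the unitig sequence with
# dp:f (mean read depth) and bn:Z (bin id) tags; L-lines are junction
# links. No installed R package parses GFA, so the dialect is implemented
# here directly.

#' Read a unitig graph from a GFA-1 file
#'
#' S-lines become unitigs (tags `dp:f:<depth>`, `bn:Z:<bin>`); L-lines
#' join segment ends into junctions. An unbinned unitig receives a fresh
#' unique bin id so that it can never merge with anything (self-loops
#' through unbinned repeats are thereby avoided). A missing depth tag
#' yields a warning and depth 1.0.
#'
#' @param path GFA-1 file.
#' @return a [unitig_graph()].
#' @export
read_unitig_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(recs, `[[`, "", 1L)

  seg <- recs[types == "S"]
  ids <- vapply(seg, `[[`, "", 2L)
  if (anyDuplicated(ids)) stop("duplicate segment names in GFA")
  seqs <- toupper(vapply(seg, `[[`, "", 3L))
  tagval <- function(fields, prefix) {
    hit <- fields[startsWith(fields, prefix)]
    if (length(hit)) sub(prefix, "", hit[1L], fixed = TRUE) else NA_character_
  }
  depth <- vapply(seg, function(f) {
    v <- tagval(f[-(1:3)], "dp:f:")
    if (is.na(v)) NA_real_ else as.numeric(v)
  }, 0)
  if (anyNA(depth)) {
    warning("GFA segments without dp:f depth tag; assuming depth 1.0")
    depth[is.na(depth)] <- 1.0
  }
  bins <- vapply(seg, function(f) tagval(f[-(1:3)], "bn:Z:"), "")
  unbinned <- is.na(bins) | !nzchar(bins)
  bins[unbinned] <- paste0("unbinned:", ids[unbinned])

  # union-find over segment ends; each class of linked ends is a junction
  ends <- c(paste0(ids, ":head"), paste0(ids, ":tail"))
  parent <- stats::setNames(ends, ends)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[rb]] <<- ra
    invisible(NULL)
  }

  overlaps <- list()
  for (f in recs[types == "L"]) {
    a <- f[[2L]]; oa <- f[[3L]]; b <- f[[4L]]; ob <- f[[5L]]
    if (!(a %in% ids) || !(b %in% ids)) {
      stop("GFA L-line references unknown segment: ",
           if (!(a %in% ids)) a else b)
    }
    end_a <- paste0(a, if (oa == "+") ":tail" else ":head")
    end_b <- paste0(b, if (ob == "+") ":head" else ":tail")
    if (end_a == end_b) {
      warning("GFA link joins a segment end to itself; ignored: ",
              paste(f, collapse = " "))
      next
    }
    union2(end_a, end_b)
    ov <- 0L
    if (length(f) >= 6L && grepl("^[0-9]+M$", f[[6L]])) {
      ov <- as.integer(sub("M", "", f[[6L]]))
    }
    overlaps[[length(overlaps) + 1L]] <- list(end = end_a, ov = ov)
  }

  roots <- vapply(ends, find, "")
  jid <- stats::setNames(paste0("J", as.integer(factor(roots, unique(roots)))),
                         ends)
  from <- unname(jid[paste0(ids, ":head")])
  to <- unname(jid[paste0(ids, ":tail")])

  junction_overlap <- numeric()
  for (o in overlaps) {
    j <- unname(jid[[o$end]])
    prev <- if (j %in% names(junction_overlap)) junction_overlap[[j]] else 0
    junction_overlap[[j]] <- max(prev, o$ov)
  }

  unitig_graph(
    data.frame(id = ids, sequence = seqs, depth = depth, bin_id = bins,
               from = from, to = to, stringsAsFactors = FALSE),
    junctions = unique(c(from, to)),
    junction_overlap = junction_overlap
  )
}

#' Write a unitig graph to a GFA-1 file
#'
#' Emits one S-line per unitig with `dp:f`/`bn:Z` tags and L-lines
#' reconstructing the junction structure (in-to-out ends as `+/+`,
#' in-to-in as `+/-`, out-to-out as `-/+`).
#'
#' @param graph a [unitig_graph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_unitig_graph <- function(graph, path) {
  stopifnot(inherits(graph, "unitig_graph"))
  u <- graph$unitigs
  out <- c("H\tVN:Z:1.0",
           sprintf("S\t%s\t%s\tdp:f:%g\tbn:Z:%s",
                   u$id, u$sequence, u$depth, u$bin_id))
  for (j in graph$junctions) {
    ins <- u$id[u$to == j]    # tails at j
    outs <- u$id[u$from == j] # heads at j
    ov <- junction_overlap_of(graph, j)
    cig <- paste0(ov, "M")
    emitted <- character()
    add <- function(line) {
      if (!(line %in% emitted)) {
        emitted <<- c(emitted, line)
        out <<- c(out, line)
      }
    }
    for (a in ins) for (b in outs) add(sprintf("L\t%s\t+\t%s\t+\t%s", a, b, cig))
    if (length(ins) >= 2L) {
      for (i in seq_len(length(ins) - 1L)) for (k in seq.int(i + 1L, length(ins)))
        add(sprintf("L\t%s\t+\t%s\t-\t%s", ins[i], ins[k], cig))
    }
    if (length(outs) >= 2L) {
      for (i in seq_len(length(outs) - 1L)) for (k in seq.int(i + 1L, length(outs)))
        add(sprintf("L\t%s\t-\t%s\t+\t%s", outs[i], outs[k], cig))
    }
  }
  writeLines(out, path)
  invisible(path)
}
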