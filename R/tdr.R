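# Terminal-direct-repeat detection on contigs assembled as circles.
# A linear genome whose ends carry an identical ~kb-scale repeat collapses
# during assembly into a circle one repeat copy short; read mappings then
# show roughly twofold coverage over the collapsed repeat, an excess of
# read termini at its boundaries, and no reads spanning it.

#' Per-position read depth on a (circular) contig
#'
#' @param aln [alignments()] whose targets are the contig; `target_end`
#'   may exceed `contig_length` to encode wrap-around.
#' @param contig_length contig length in bp.
#' @return integer vector of depth at positions `0 .. contig_length - 1`.
#' @export
coverage_profile <- function(aln, contig_length) {
  L <- as.integer(contig_length)
  delta <- integer(L + 1L)
  if (nrow(aln)) {
    s <- aln$target_start %% L
    e <- s + (aln$target_end - aln$target_start)
    if (any(e - s > L)) stop("alignment longer than the contig")
    for (i in seq_along(s)) {
      if (e[i] <= L) {
        delta[s[i] + 1L] <- delta[s[i] + 1L] + 1L
        delta[e[i] + 1L] <- delta[e[i] + 1L] - 1L
      } else {
        delta[s[i] + 1L] <- delta[s[i] + 1L] + 1L
        delta[L + 1L] <- delta[L + 1L] - 1L
        delta[1L] <- delta[1L] + 1L
        delta[e[i] - L + 1L] <- delta[e[i] - L + 1L] - 1L
      }
    }
  }
  cumsum(delta[seq_len(L)])
}

#' Read-terminus counts per window
#'
#' Counts, for every window, how many alignments have their left terminus
#' (`target_start`) and how many their right terminus (`target_end - 1`)
#' inside the window, on either strand. Terminus pileups at both
#' boundaries of a collapsed TDR are a hallmark of a linear template.
#'
#' @param aln [alignments()] on the contig.
#' @param contig_length contig length in bp.
#' @param window window size in bp.
#' @return data.frame with `window_start` (0-based), `starts`, `ends`.
#' @export
read_start_profile <- function(aln, contig_length, window = 100) {
  L <- as.integer(contig_length)
  breaks <- seq.int(0L, L - 1L, by = window)
  idx <- function(pos) findInterval(pos %% L, breaks)
  starts <- integer(length(breaks))
  ends <- integer(length(breaks))
  if (nrow(aln)) {
    ts <- tabulate(idx(aln$target_start), nbins = length(breaks))
    te <- tabulate(idx(aln$target_end - 1L), nbins = length(breaks))
    starts <- ts
    ends <- te
  }
  data.frame(window_start = breaks, starts = starts, ends = ends)
}

#' Count alignments spanning an interval with flanks
#'
#' An alignment spans `[interval_start, interval_end)` when it contains
#' the interval plus at least `flank` bp on each side.
#'
#' @param aln [alignments()] on the contig.
#' @param interval numeric length-2 vector, 0-based half-open.
#' @param flank required flank on each side in bp (default 100).
#' @param contig_length if given, coordinates are circular and shifted
#'   copies of the alignments are considered.
#' @return integer count.
#' @export
spanning_count <- function(aln, interval, flank = 100, contig_length = NULL) {
  if (nrow(aln) == 0L) return(0L)
  i_s <- interval[1L] - flank
  i_e <- interval[2L] + flank
  s <- aln$target_start
  e <- aln$target_end
  n <- 0L
  shifts <- if (is.null(contig_length)) 0 else c(-contig_length, 0, contig_length)
  for (k in shifts) {
    n <- n + sum(s <= i_s + k & e >= i_e + k)
  }
  as.integer(n)
}

#' Detect a collapsed terminal direct repeat on a circular contig
#'
#' The candidate region is the longest contiguous (circularly wrapped)
#' stretch whose depth reaches `ratio_low` times the median depth of the
#' remainder. It is accepted as a collapsed TDR when no more than
#' `max_spanning` alignments span it with `flank`-bp flanks (a genuine
#' TDR has no spanning reads, since the linear template has no junction)
#' and the read-terminus excess at both of its boundaries reaches
#' `start_excess_min` times the background per-window terminus rate. When
#' short-read alignments are supplied, their coverage over the candidate
#' must corroborate the twofold signal as well.
#'
#' Evidence is split by read type the way the underlying signals demand:
#' when short-read alignments are supplied they drive the coverage
#' candidate and the reported coverage ratio (short reads resolve a
#' kb-scale plateau far more precisely than reads longer than the repeat
#' itself), while long reads always supply the spanning-read and
#' terminus-excess evidence. Without short reads, long-read coverage is
#' used throughout.
#'
#' @param circle a [circular_contig()].
#' @param long_aln long-read [alignments()] on the circle.
#' @param short_aln optional short-read [alignments()]; used for the
#'   coverage evidence when present.
#' @param ratio_low detection band for the "about twofold" coverage signal
#'   (default 1.6).
#' @param min_depth minimum mean long-read depth to attempt detection.
#' @param flank spanning-read flank in bp (default 100).
#' @param max_spanning maximum tolerated spanning reads (default 0,
#'   i.e. absence).
#' @param start_excess_min required terminus excess at the candidate
#'   boundaries over background (default 3).
#' @param start_window window for terminus counting in bp.
#' @param min_candidate minimum candidate length in bp; shorter
#'   high-coverage blips are ignored.
#' @param smooth_window running-mean window (bp) applied to the depth
#'   profile before thresholding; candidate boundaries are then snapped
#'   to the strongest read-terminus pileups within this distance.
#' @return `NULL` if no TDR is detected; the string
#'   `"insufficient-coverage"` (with class `tdr_no_call`) when depth is
#'   too low to decide; otherwise list(tdr_interval, evidence) with the
#'   0-based half-open candidate interval (end may exceed the contig
#'   length when the region wraps) and a [tdr_evidence()].
#' @export
detect_tdr <- function(circle, long_aln, short_aln = NULL,
                       ratio_low = 1.6, min_depth = 10, flank = 100,
                       max_spanning = 0, start_excess_min = 3,
                       start_window = 100, min_candidate = 200,
                       smooth_window = 500) {
  stopifnot(inherits(circle, "circular_contig"))
  L <- circle$length
  long_depth <- coverage_profile(long_aln, L)
  if (mean(long_depth) < min_depth) {
    return(structure("insufficient-coverage", class = "tdr_no_call"))
  }
  use_short <- !is.null(short_aln) && nrow(short_aln) > 0L
  depth <- if (use_short) coverage_profile(short_aln, L) else long_depth
  smooth <- circ_runmean(depth, min(smooth_window, L %/% 4L))
  thr <- ratio_low * stats::median(smooth)
  high <- smooth >= thr
  if (!any(high)) return(NULL)
  run <- longest_circular_run(high)
  if (is.null(run) || run[2L] - run[1L] < min_candidate) return(NULL)
  # refine boundaries to the read-terminus pileups: reads of the linear
  # template are clipped at the genome ends, which project exactly onto
  # the collapsed repeat's boundaries
  starts_tab <- tabulate((long_aln$target_start %% L) + 1L, nbins = L)
  ends_tab <- tabulate((long_aln$target_end %% L) + 1L, nbins = L)
  run <- refine_boundary(run, starts_tab, ends_tab, L,
                         window = smooth_window)
  if (run[2L] - run[1L] < min_candidate) return(NULL)
  cand_pos <- ((run[1L]:(run[2L] - 1L)) %% L) + 1L
  remainder <- depth[-cand_pos]
  if (length(remainder) == 0L) return(NULL)
  med_rest <- stats::median(remainder)
  if (med_rest <= 0) return(NULL)
  ratio <- mean(depth[cand_pos]) / med_rest
  if (ratio < ratio_low) return(NULL)

  span <- spanning_count(long_aln, run, flank = flank, contig_length = L)

  prof <- read_start_profile(long_aln, L, window = start_window)
  w_start <- (run[1L] %% L) %/% start_window + 1L
  w_end <- ((run[2L] - 1L) %% L) %/% start_window + 1L
  bg_windows <- setdiff(seq_len(nrow(prof)), c(w_start, w_end))
  bg <- max(1, stats::median(c(prof$starts[bg_windows],
                               prof$ends[bg_windows])))
  excess_start <- prof$starts[w_start] / bg
  excess_end <- prof$ends[w_end] / bg

  ok <- span <= max_spanning &&
    excess_start >= start_excess_min && excess_end >= start_excess_min
  if (!ok) return(NULL)
  list(tdr_interval = run,
       evidence = tdr_evidence(coverage_ratio = ratio,
                               spanning_reads = span,
                               start_excess = min(excess_start, excess_end)))
}

# Circular running mean of window w (centred).
circ_runmean <- function(x, w) {
  n <- length(x)
  w <- max(1L, min(w, n))
  pad <- w %/% 2L
  xx <- c(x[(n - pad + 1L):n], x, x[1L:w])
  cs <- cumsum(c(0, xx))
  out <- (cs[(w + 1L):(w + n)] - cs[1L:n]) / w
  out
}

# Snap a candidate interval's boundaries to the strongest read-terminus
# pileups nearby (counts indexed 1..L for positions 0..L-1; the end
# table is indexed by exclusive end position mod L).
refine_boundary <- function(run, starts_tab, ends_tab, L, window,
                            min_pileup = 3L) {
  near <- function(center, tab) {
    pos <- ((center - window):(center + window)) %% L
    cnt <- tab[pos + 1L]
    if (max(cnt) < min_pileup) return(NULL)
    pos[which.max(cnt)]
  }
  s <- near(run[1L] %% L, starts_tab)
  e <- near(run[2L] %% L, ends_tab)
  if (!is.null(s)) run[1L] <- s
  if (!is.null(e)) {
    run[2L] <- if (e > run[1L]) e else e + L
  } else {
    run[2L] <- if (run[2L] > run[1L]) run[2L] else run[2L] + L
  }
  run
}

# Longest circular run of TRUE in a logical vector; returns c(start, end)
# 0-based half-open, end may exceed length(x) when the run wraps.
longest_circular_run <- function(x) {
  n <- length(x)
  if (!any(x)) return(NULL)
  if (all(x)) return(c(0L, n))
  r <- rle(c(x, x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths # 0-based
  cand <- which(r$values)
  keep <- cand[starts[cand] < n]
  lens <- pmin(r$lengths[keep], n)
  best <- keep[which.max(lens)]
  c(starts[best], min(starts[best] + r$lengths[best], starts[best] + n))
}

#' Linearize a circular contig at a detected terminal direct repeat
#'
#' Re-expands the collapsed repeat: the output is the TDR sequence,
#' followed by the circle rotated to start at the TDR's end, so the
#' repeat appears verbatim at both ends and the total length is the
#' circle length plus the TDR length.
#'
#' @param circle a [circular_contig()].
#' @param tdr_interval 0-based half-open interval of the collapsed TDR on
#'   the circle (end may exceed the circle length when wrapping).
#' @param evidence optional [tdr_evidence()] attached to the result.
#' @param id output genome id (default derived from the circle id).
#' @return a [linear_genome()].
#' @export
linearize <- function(circle, tdr_interval, evidence = NULL, id = NULL) {
  stopifnot(inherits(circle, "circular_contig"))
  if (is.null(tdr_interval) || length(tdr_interval) != 2L ||
      tdr_interval[2L] <= tdr_interval[1L]) {
    stop("tdr_interval must be a non-empty [start, end) interval")
  }
  L <- circle$length
  t_len <- tdr_interval[2L] - tdr_interval[1L]
  stopifnot(t_len < L)
  tdr_seq <- circ_substr(circle$sequence, tdr_interval[1L], tdr_interval[2L])
  rotated <- circ_substr(circle$sequence, tdr_interval[2L] %% L,
                         tdr_interval[2L] %% L + L)
  linear_genome(
    id = id %||% paste0(circle$id, ":linear"),
    sequence = paste0(tdr_seq, rotated),
    tdr_length = t_len,
    evidence = evidence
  )
}

#' GC skew along a sequence
#'
#' Skew is `(G - C) / (G + C)` in sliding windows; windows without G or C
#' yield `NA`.
#'
#' @param sequence DNA string.
#' @param window window size in bp (default 100).
#' @param step step size in bp (default 50).
#' @return data.frame with `start` (0-based window start) and `skew`.
#' @export
gc_skew <- function(sequence, window = 100, step = 50) {
  L <- nchar(sequence)
  stopifnot(window >= 1, step >= 1)
  if (L < window) {
    return(data.frame(start = integer(), skew = numeric()))
  }
  starts <- seq.int(0L, L - window, by = step)
  v <- Biostrings::Views(Biostrings::DNAString(sequence),
                         start = starts + 1L, width = window)
  fr <- Biostrings::letterFrequency(v, c("G", "C"))
  g <- fr[, "G"]; c_ <- fr[, "C"]
  skew <- ifelse(g + c_ == 0, NA_real_, (g - c_) / (g + c_))
  data.frame(start = starts, skew = skew)
}

#' Locate the GC-skew transition (cumulative-skew extremum)
#'
#' The replication origin/terminus of many genomes shows as a sign change
#' in GC skew; the largest extremum of the cumulative skew marks it.
#'
#' @param skew data.frame from [gc_skew()].
#' @param genome_length optional genome length in bp; when given, the
#'   distances of the transition from both genome ends are reported.
#' @return `NULL` when all windows are missing; else list(position,
#'   cumulative, distance_from_start, distance_from_end).
#' @export
skew_transition <- function(skew, genome_length = NULL) {
  if (nrow(skew) == 0L || all(is.na(skew$skew))) return(NULL)
  s <- ifelse(is.na(skew$skew), 0, skew$skew)
  cs <- cumsum(s)
  i <- which.max(abs(cs))
  pos <- skew$start[i]
  list(position = pos,
       cumulative = cs[i],
       distance_from_start = pos,
       distance_from_end = if (is.null(genome_length)) NA_real_
                           else genome_length - pos)
}
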