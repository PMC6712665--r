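# Synthetic community generator: host chromosomes carrying circular
# plasmids and linear phages with terminal direct repeats, long reads,
# methylation kinetics (IPD ratios), CRISPR arrays holding protospacers
# of resident phages, and cross-sample abundance matrices in which eMGEs
# covary with their hosts. Every stage draws from its own child RNG
# stream derived from the root seed, so adding a stage never perturbs
# the others.

#' Simulation configuration
#'
#' Defaults describe a desk-scale gut-like community: a handful of host
#' chromosomes (50-100 kb stand-ins for Mb-scale genomes), plasmids of
#' 5-20 kb at a community-level copy ratio of 3.0 plasmids per
#' chromosome, and 30-60 kb linear phages with 1-3 kb terminal direct
#' repeats. Long reads follow a lognormal length distribution with an
#' 8-kb median; IPD ratios are Normal on the ratio scale with methylated
#' mean 4.0 (sd 0.5) and unmethylated mean 1.0 (sd 0.2), so the 2.5
#' binarization cutoff separates the classes.
#'
#' @param n_hosts,n_plasmids,n_phages community composition.
#' @param host_length_range,plasmid_length_range,phage_length_range
#'   genome length ranges in bp.
#' @param tdr_length_range phage terminal-repeat length range in bp.
#' @param plasmid_copy_ratio community-level plasmid copies per chromosome
#'   (each plasmid gets copy number `ratio * n_hosts / n_plasmids`).
#' @param read_length_meanlog,read_length_sdlog lognormal read-length
#'   parameters (defaults give an 8-kb median).
#' @param long_error_rate,short_error_rate per-base error rates
#'   (substitution + indel).
#' @param depth target long-read depth per copy.
#' @param motifs_per_host,motif_length_range methylation motifs per host
#'   (distinct across hosts) and their length range.
#' @param ipd_methylated_mean,ipd_methylated_sd,ipd_unmethylated_mean,ipd_unmethylated_sd
#'   IPD-ratio model parameters.
#' @param ipd_threshold binarization cutoff for the mean IPD ratio.
#' @param spacer_length_range protospacer length range in bp.
#' @param decoys_per_host random (non-protospacer) spacers per CRISPR
#'   array.
#' @param n_samples,total_reads cross-sample abundance design.
#' @param host_abundance_sdlog lognormal sd of per-sample host abundance.
#' @param coupling_noise_sd lognormal sd of the eMGE-host abundance
#'   coupling.
#' @param seed root seed (integer).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_hosts = 5, n_plasmids = 10, n_phages = 3,
                       host_length_range = c(50000, 100000),
                       plasmid_length_range = c(5000, 20000),
                       phage_length_range = c(30000, 60000),
                       tdr_length_range = c(1000, 3000),
                       plasmid_copy_ratio = 3.0,
                       read_length_meanlog = log(8000),
                       read_length_sdlog = 0.4,
                       long_error_rate = 0.10,
                       short_error_rate = 0.002,
                       depth = 30,
                       motifs_per_host = c(1, 3),
                       motif_length_range = c(4, 6),
                       ipd_methylated_mean = 4.0, ipd_methylated_sd = 0.5,
                       ipd_unmethylated_mean = 1.0, ipd_unmethylated_sd = 0.2,
                       ipd_threshold = 2.5,
                       spacer_length_range = c(25, 40),
                       decoys_per_host = 5,
                       n_samples = 50, total_reads = 1e5,
                       host_abundance_sdlog = 1.0,
                       coupling_noise_sd = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$long_error_rate, cfg$short_error_rate)
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")
  lens <- c(cfg$host_length_range, cfg$plasmid_length_range,
            cfg$phage_length_range, cfg$tdr_length_range)
  if (any(lens <= 0)) stop("lengths must be positive")
  if (max(cfg$tdr_length_range) * 2 >= min(cfg$phage_length_range)) {
    stop("TDRs must fit twice inside the shortest phage")
  }
  structure(cfg, class = "sim_config")
}

# Distinct random motifs, none equal to GATC, none a duplicate.
draw_motifs <- function(n, len_range) {
  out <- character()
  while (length(out) < n) {
    len <- sample(seq.int(len_range[1L], len_range[2L]), 1L)
    m <- random_dna(len)
    if (m != "GATC" && !(m %in% out)) out <- c(out, m)
  }
  out
}

#' Generate a synthetic community with ground truth
#'
#' Genomes are i.i.d. uniform over A/C/G/T. Each phage is built as a core
#' plus a terminal direct repeat copied verbatim to both ends. Each host
#' methylates the ubiquitous motif GATC (m6A) plus 1-3 host-specific
#' motifs drawn without replacement across the community (restriction-
#' modification systems are host-specific). Each host's CRISPR array
#' holds one protospacer per resident phage plus random decoy spacers.
#'
#' @param config a [sim_config()].
#' @return list of class `community_truth` with elements `chromosomes`,
#'   `plasmids`, `phages`, `motifs` (host id -> data.frame(motif,
#'   mod_type)), `crispr` (data.frame host_id, spacer_id, sequence,
#'   source_phage), `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Actinobacteria", "Fusobacteria")

  chromosomes <- with_seed(child_seed(config$seed, "hosts"), {
    lapply(seq_len(config$n_hosts), function(i) {
      L <- sample(seq.int(config$host_length_range[1L],
                          config$host_length_range[2L]), 1L)
      list(id = sprintf("host_%02d", i),
           sequence = random_dna(L),
           length = L,
           taxon = paste(phyla[(i - 1L) %% length(phyla) + 1L],
                         sprintf("Genus_%02d", i),
                         sprintf("species_%02d", i), sep = ";"),
           bin_id = sprintf("bin_%02d", i),
           copy_number = 1)
    })
  })
  host_ids <- vapply(chromosomes, `[[`, "", "id")

  copy_each <- config$plasmid_copy_ratio * config$n_hosts /
    max(1, config$n_plasmids)
  plasmids <- with_seed(child_seed(config$seed, "plasmids"), {
    lapply(seq_len(config$n_plasmids), function(i) {
      L <- sample(seq.int(config$plasmid_length_range[1L],
                          config$plasmid_length_range[2L]), 1L)
      list(id = sprintf("plasmid_%02d", i),
           sequence = random_dna(L),
           length = L,
           host = host_ids[(i - 1L) %% config$n_hosts + 1L],
           copy_number = copy_each)
    })
  })

  phages <- with_seed(child_seed(config$seed, "phages"), {
    lapply(seq_len(config$n_phages), function(i) {
      L <- sample(seq.int(config$phage_length_range[1L],
                          config$phage_length_range[2L]), 1L)
      t_len <- sample(seq.int(config$tdr_length_range[1L],
                              config$tdr_length_range[2L]), 1L)
      if (2 * t_len >= L) stop("TDR longer than half the phage genome")
      tdr <- random_dna(t_len)
      core <- random_dna(L - 2L * t_len)
      g <- linear_genome(id = sprintf("phage_%02d", i),
                         sequence = paste0(tdr, core, tdr),
                         tdr_length = t_len)
      g$host <- host_ids[(i - 1L) %% config$n_hosts + 1L]
      g$copy_number <- 1
      g
    })
  })

  motifs <- with_seed(child_seed(config$seed, "motifs"), {
    n_per <- sample(seq.int(config$motifs_per_host[1L],
                            config$motifs_per_host[2L]),
                    config$n_hosts, replace = TRUE)
    pool <- draw_motifs(sum(n_per), config$motif_length_range)
    idx <- c(0L, cumsum(n_per))
    out <- lapply(seq_len(config$n_hosts), function(i) {
      own <- pool[seq2(idx[i] + 1L, idx[i + 1L])]
      data.frame(motif = c("GATC", own),
                 mod_type = "m6A",
                 stringsAsFactors = FALSE)
    })
    names(out) <- host_ids
    out
  })

  crispr <- with_seed(child_seed(config$seed, "crispr"), {
    rows <- list()
    for (ph in phages) {
      sp_len <- sample(seq.int(config$spacer_length_range[1L],
                               config$spacer_length_range[2L]), 1L)
      pos <- sample.int(ph$length - sp_len + 1L, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        host_id = ph$host,
        spacer_id = paste0("sp_", ph$id),
        sequence = substr(ph$sequence, pos, pos + sp_len - 1L),
        source_phage = ph$id,
        stringsAsFactors = FALSE
      )
    }
    for (h in host_ids) {
      for (d in seq_len(config$decoys_per_host)) {
        sp_len <- sample(seq.int(config$spacer_length_range[1L],
                                 config$spacer_length_range[2L]), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          host_id = h,
          spacer_id = sprintf("decoy_%s_%02d", h, d),
          sequence = random_dna(sp_len),
          source_phage = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows) %||%
      data.frame(host_id = character(), spacer_id = character(),
                 sequence = character(), source_phage = character())
  })

  structure(
    list(chromosomes = chromosomes, plasmids = plasmids, phages = phages,
         motifs = motifs, crispr = crispr, config = config),
    class = "community_truth"
  )
}

#' @export
print.community_truth <- function(x, ...) {
  cat("community_truth:", length(x$chromosomes), "hosts,",
      length(x$plasmids), "plasmids,", length(x$phages), "phages\n")
  invisible(x)
}

# All elements of a community as a uniform list of
# list(id, sequence?, length, copy_number, circular, host, type).
community_elements <- function(truth, sequences = TRUE) {
  take <- function(x, type, circular) {
    list(id = x$id,
         sequence = if (sequences) x$sequence else NULL,
         length = x$length, copy_number = x$copy_number,
         circular = circular, host = x$host %||% x$id, type = type)
  }
  c(lapply(truth$chromosomes, take, type = "chromosome", circular = FALSE),
    lapply(truth$plasmids, take, type = "plasmid", circular = TRUE),
    lapply(truth$phages, take, type = "phage", circular = FALSE))
}

# Apply i.i.d. substitution + indel errors to a DNA string.
mutate_sequence <- function(s, rate) {
  if (rate <= 0) return(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(s)
  kind <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  alphabet <- c("A", "C", "G", "T")
  out <- bases
  for (k in seq_along(hit)) {
    i <- hit[k]
    if (kind[k] == "sub") {
      out[i] <- sample(setdiff(alphabet, bases[i]), 1L)
    } else if (kind[k] == "ins") {
      out[i] <- paste0(out[i], sample(alphabet, 1L))
    } else {
      out[i] <- ""
    }
  }
  paste(out, collapse = "")
}

#' Simulate long or short reads with true source intervals
#'
#' Per-element read counts are Poisson with mean
#' `depth * copy_number * length / mean_read_length`, so sampling is
#' proportional to length times copy number. Circular templates are
#' sampled with wrap-around; linear templates are sampled as sheared
#' molecules whose fragments are clipped at the genome ends (producing
#' the natural pileup of read termini at the ends of a linear genome and
#' never a read crossing the non-existent junction between the two TDR
#' copies).
#'
#' @param truth a `community_truth` from [generate_community()].
#' @param config its [sim_config()] (defaults to `truth$config`).
#' @param which `"long"` or `"short"` (selects error rate; short reads
#'   are 150 bp).
#' @param elements optional subset of element ids to sequence.
#' @param sequences if `FALSE`, only true intervals are returned (fast
#'   path for mapping-level analyses).
#' @return list with `reads` (data.frame `read_id`, `source_id`, `start`,
#'   `end`, `strand`, and `sequence` unless disabled; `end` may exceed
#'   the source length for wrap-around reads) and `alignments` (the true
#'   intervals as an [alignments()] table).
#' @export
simulate_reads <- function(truth, config = truth$config,
                           which = c("long", "short"),
                           elements = NULL, sequences = TRUE) {
  which <- match.arg(which)
  stopifnot(inherits(truth, "community_truth"))
  els <- community_elements(truth, sequences = sequences)
  if (!is.null(elements)) {
    els <- Filter(function(e) e$id %in% elements, els)
  }
  err <- if (which == "long") config$long_error_rate else config$short_error_rate
  mean_len <- if (which == "long") {
    exp(config$read_length_meanlog + config$read_length_sdlog^2 / 2)
  } else 150

  with_seed(child_seed(config$seed, paste0("reads:", which)), {
    rows <- list()
    for (e in els) {
      lambda <- config$depth * e$copy_number * e$length / mean_len
      n <- stats::rpois(1L, lambda)
      if (n == 0L) next
      rl <- if (which == "long") {
        pmax(200L, pmin(e$length,
                        round(stats::rlnorm(n, config$read_length_meanlog,
                                            config$read_length_sdlog))))
      } else rep(150L, n)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      if (e$circular) {
        start <- sample.int(e$length, n, replace = TRUE) - 1L
        end <- start + rl
      } else {
        # sheared molecule: fragment may begin before 0 or run past L;
        # clipping at the template ends keeps coverage flat and piles
        # read termini at the ends
        raw_start <- floor(stats::runif(n, min = -(rl - 1L), max = e$length - 1L))
        start <- pmax(0L, raw_start)
        end <- pmin(e$length, raw_start + rl)
        keep <- end - start >= pmin(rl, 200L)
        start <- start[keep]; end <- end[keep]; strand <- strand[keep]
        n <- length(start)
        if (n == 0L) next
      }
      ids <- sprintf("%s_read_%05d", e$id, seq_len(n))
      seqs <- NULL
      if (sequences) {
        seqs <- vapply(seq_len(n), function(i) {
          s <- circ_substr(e$sequence, start[i], end[i])
          if (strand[i] == "-") s <- revcomp(s)
          mutate_sequence(s, err)
        }, "")
      }
      df <- data.frame(read_id = ids, source_id = e$id,
                       start = start, end = end, strand = strand,
                       stringsAsFactors = FALSE)
      if (sequences) df$sequence <- seqs
      rows[[length(rows) + 1L]] <- df
    }
    reads <- do.call(rbind, rows) %||%
      data.frame(read_id = character(), source_id = character(),
                 start = integer(), end = integer(), strand = character())
    aln <- if (nrow(reads)) {
      alignments(
        query_id = reads$read_id, target_id = reads$source_id,
        query_start = 0L, query_end = reads$end - reads$start,
        target_start = reads$start, target_end = reads$end,
        strand = reads$strand,
        identity = 1 - err,
        aligned_length = reads$end - reads$start
      )
    } else alignments()
    list(reads = reads, alignments = aln)
  })
}

#' Collapse a linear TDR genome into the circle the assembler would build
#'
#' A linear genome with terminal direct repeats misassembles as a circle
#' one repeat copy short: both copies collapse into one. The true
#' interval of the collapsed repeat on the circle is recorded for
#' recovery tests.
#'
#' @param phage a [linear_genome()].
#' @param min_length minimum circle length passed through to
#'   [circular_contig()].
#' @return a [circular_contig()] of length `L - tdr_length`, with
#'   attribute `true_tdr`: the 0-based half-open collapsed-repeat
#'   interval `[L - 2*tdr, L - tdr)` on the circle.
#' @export
misassemble_tdr_as_circle <- function(phage, min_length = 2200) {
  stopifnot(inherits(phage, "linear_genome"))
  t_len <- phage$tdr_length
  if (is.null(t_len) || t_len < 1L) {
    stop("not a TDR genome: tdr_length must be >= 1")
  }
  L <- phage$length
  circ_seq <- substr(phage$sequence, t_len + 1L, L)
  cc <- circular_contig(id = paste0(phage$id, "_cc"),
                        sequence = circ_seq,
                        member_unitigs = phage$id,
                        min_length = min_length)
  attr(cc, "true_tdr") <- c(cc$length - t_len, cc$length)
  attr(cc, "source_phage") <- phage$id
  cc
}

#' Project reads from a linear TDR genome onto its collapsed circle
#'
#' Computes, without running an aligner, where error-free reads of the
#' linear genome map on the misassembled circle: the left repeat copy
#' maps onto the collapsed copy, and reads crossing the repeat/core
#' boundary wrap around the circle origin.
#'
#' @param read_aln true-read [alignments()] against the linear genome
#'   (from [simulate_reads()]).
#' @param genome_length linear genome length in bp.
#' @param tdr_length repeat length in bp.
#' @param circle_id target id for the produced records.
#' @return an [alignments()] table on the circle (length
#'   `genome_length - tdr_length`), with `target_end` beyond the circle
#'   length encoding wrap-around.
#' @export
project_reads_onto_circle <- function(read_aln, genome_length, tdr_length,
                                      circle_id = "circle") {
  L <- genome_length; t_len <- tdr_length; Lc <- L - t_len
  a <- read_aln$target_start
  b <- read_aln$target_end
  stopifnot(all(b <= L))
  s <- ifelse(b <= t_len, a + Lc - t_len,
        ifelse(a >= t_len, a - t_len,
               a + Lc - t_len))
  len <- b - a
  alignments(
    query_id = read_aln$query_id, target_id = circle_id,
    query_start = 0L, query_end = len,
    target_start = s %% Lc, target_end = s %% Lc + len,
    strand = read_aln$strand,
    identity = read_aln$identity,
    aligned_length = len,
    target_len = Lc
  )
}

#' Simulate methylation motif profiles with IPD kinetics
#'
#' For every sequence in the community and every motif methylated by some
#' host, the motif's occurrences are counted; sequences lacking the motif
#' get a missing profile. A sequence whose (true) host methylates the
#' motif draws its mean IPD ratio from the methylated Normal and its
#' methylated fraction from a Beta concentrated near 0.9; otherwise from
#' the unmethylated Normal and a Beta near 0.05. Mean coverage is drawn
#' around the configured depth. Plasmids and phages inherit their true
#' host's motif states.
#'
#' @param truth a `community_truth`.
#' @param config its [sim_config()].
#' @return a [motif_profiles()] table covering all sequences and all
#'   community motifs.
#' @export
simulate_motif_profiles <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "community_truth"))
  all_motifs <- unique(do.call(rbind, unname(truth$motifs)))
  els <- community_elements(truth, sequences = TRUE)
  methylates <- function(host, motif) {
    motif %in% truth$motifs[[host]]$motif
  }
  with_seed(child_seed(config$seed, "motif_profiles"), {
    rows <- list()
    for (e in els) {
      subj <- Biostrings::DNAString(e$sequence)
      for (k in seq_len(nrow(all_motifs))) {
        m <- all_motifs$motif[k]
        n_occ <- Biostrings::countPattern(m, subj, fixed = FALSE) +
          Biostrings::countPattern(as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(m))),
            subj, fixed = FALSE)
        if (n_occ == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence_id = e$id, motif = m,
            mod_type = all_motifs$mod_type[k],
            methylated_fraction = NA_real_, mean_coverage = NA_real_,
            mean_ipd_ratio = NA_real_, binary_state = NA_integer_,
            sequence_type = e$type, stringsAsFactors = FALSE)
          next
        }
        meth <- methylates(e$host, m)
        ipd <- if (meth) {
          stats::rnorm(1L, config$ipd_methylated_mean,
                       config$ipd_methylated_sd)
        } else {
          stats::rnorm(1L, config$ipd_unmethylated_mean,
                       config$ipd_unmethylated_sd)
        }
        frac <- if (meth) stats::rbeta(1L, 18, 2) else stats::rbeta(1L, 1, 19)
        cov <- stats::rnorm(1L, config$depth, config$depth * 0.1)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = e$id, motif = m,
          mod_type = all_motifs$mod_type[k],
          methylated_fraction = frac, mean_coverage = cov,
          mean_ipd_ratio = ipd,
          binary_state = as.integer(ipd > config$ipd_threshold),
          sequence_type = e$type, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    motif_profiles(df$sequence_id, df$motif, df$mod_type,
                   df$methylated_fraction, df$mean_coverage,
                   df$mean_ipd_ratio, df$binary_state, df$sequence_type)
  })
}

#' Simulate a cross-sample abundance matrix
#'
#' Per-sample host cell abundances are lognormal; each eMGE's molecule
#' abundance is its host's abundance times its copy number times
#' lognormal coupling noise. Read counts are a multinomial draw of
#' `total_reads` per sample with probabilities proportional to molecule
#' abundance times element length.
#'
#' @param truth a `community_truth`.
#' @param config its [sim_config()].
#' @return an [abundance_matrix()] over all elements (chromosomes and
#'   eMGEs) by `n_samples` samples.
#' @export
simulate_abundance_matrix <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "community_truth"))
  els <- community_elements(truth, sequences = FALSE)
  ids <- vapply(els, `[[`, "", "id")
  lens <- vapply(els, `[[`, 0, "length")
  hosts <- vapply(els, `[[`, "", "host")
  copies <- vapply(els, `[[`, 0, "copy_number")
  host_ids <- vapply(truth$chromosomes, `[[`, "", "id")
  with_seed(child_seed(config$seed, "abundance"), {
    counts <- matrix(0, nrow = length(ids), ncol = config$n_samples,
                     dimnames = list(ids, sprintf("sample_%02d",
                                                  seq_len(config$n_samples))))
    for (s in seq_len(config$n_samples)) {
      host_ab <- stats::setNames(
        stats::rlnorm(length(host_ids), 0, config$host_abundance_sdlog),
        host_ids)
      mol <- host_ab[hosts] * copies *
        stats::rlnorm(length(ids), 0, config$coupling_noise_sd)
      # chromosomes track their host abundance exactly (no coupling noise)
      is_chrom <- ids %in% host_ids
      mol[is_chrom] <- host_ab[hosts[is_chrom]]
      w <- mol * lens
      counts[, s] <- stats::rmultinom(1L, size = config$total_reads,
                                      prob = w / sum(w))
    }
    abundance_matrix(counts, stats::setNames(lens, ids))
  })
}

#' Break a community into a unitig graph the circularizer can solve
#'
#' Each plasmid circle and each (misassembled) phage circle is split into
#' `pieces` unitigs sharing a bin, joined in a cycle; each chromosome is
#' split into a linear chain of unitigs in its bin. Recovering the
#' plasmid and phage circles from this graph exercises the bin-guided
#' merging end to end.
#'
#' @param truth a `community_truth`.
#' @param pieces unitigs per element (>= 1).
#' @return a [unitig_graph()]; the ground-truth circle count is the
#'   number of plasmids plus phages (phages enter as collapsed circles).
#' @export
community_unitig_graph <- function(truth, pieces = 3L) {
  stopifnot(inherits(truth, "community_truth"), pieces >= 1L)
  rows <- list()
  jn <- 0L
  new_j <- function() {
    jn <<- jn + 1L
    sprintf("J%04d", jn)
  }
  add_element <- function(id, sequence, bin, depth, circular) {
    L <- nchar(sequence)
    k <- min(pieces, max(1L, L %/% 1000L))
    cuts <- unique(c(0L, round(seq_len(k - 1L) * L / k), L))
    juncs <- replicate(length(cuts) - 1L, new_j())
    if (circular) juncs <- c(juncs, juncs[1L])
    else juncs <- c(juncs, new_j())
    for (i in seq_len(length(cuts) - 1L)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = sprintf("%s_u%02d", id, i),
        sequence = substr(sequence, cuts[i] + 1L, cuts[i + 1L]),
        depth = depth, bin_id = bin,
        from = juncs[i], to = juncs[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  for (ch in truth$chromosomes) {
    add_element(ch$id, ch$sequence, ch$bin_id, truth$config$depth, FALSE)
  }
  for (p in truth$plasmids) {
    add_element(p$id, p$sequence, paste0("bin_", p$id),
                truth$config$depth * p$copy_number, TRUE)
  }
  for (ph in truth$phages) {
    cc <- misassemble_tdr_as_circle(ph)
    add_element(ph$id, cc$sequence, paste0("bin_", ph$id),
                truth$config$depth, TRUE)
  }
  unitig_graph(do.call(rbind, rows))
}

#' Random unitig graph for order-invariance testing
#'
#' @param n_unitigs number of unitigs.
#' @param n_bins number of bin labels to draw from.
#' @param seq_length unitig sequence length in bp.
#' @param n_junctions number of junctions (default about
#'   `n_unitigs`).
#' @return a [unitig_graph()] with unitig endpoints assigned to random
#'   junctions.
#' @export
random_unitig_graph <- function(n_unitigs = 12L, n_bins = 4L,
                                seq_length = 40L, n_junctions = NULL) {
  n_junctions <- n_junctions %||% max(3L, n_unitigs)
  juncs <- sprintf("J%02d", seq_len(n_junctions))
  u <- data.frame(
    id = sprintf("u%02d", seq_len(n_unitigs)),
    sequence = vapply(seq_len(n_unitigs), function(i) random_dna(seq_length), ""),
    depth = round(stats::runif(n_unitigs, 5, 50), 1),
    bin_id = sprintf("B%02d", sample.int(n_bins, n_unitigs, replace = TRUE)),
    from = sample(juncs, n_unitigs, replace = TRUE),
    to = sample(juncs, n_unitigs, replace = TRUE),
    stringsAsFactors = FALSE
  )
  unitig_graph(u, junctions = juncs)
}
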