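# Tabular readers/writers: PAF-like alignment TSV, gene tables, motif
# tables, spacer lists and abundance matrices.

#' Read alignments from a PAF-like TSV file
#'
#' Standard 12-column PAF: query name/length/start/end, strand, target
#' name/length/start/end, number of matching bases, alignment block
#' length, mapping quality. Coordinates are 0-based half-open already;
#' identity is computed as matches / block length.
#'
#' @param path PAF file.
#' @return an [alignments()] table.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(alignments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(f, length, 0L)
  if (any(ncols < 12L)) {
    stop("PAF parse error at line ", which(ncols < 12L)[1L],
         ": fewer than 12 columns")
  }
  col <- function(i) vapply(f, `[[`, "", i)
  num <- function(i) as.numeric(col(i))
  qs <- num(3); qe <- num(4); ts <- num(8); te <- num(9)
  if (any(c(qs, ts) < 0)) stop("PAF parse error: negative coordinates")
  matches <- num(10); block <- num(11)
  alignments(
    query_id = col(1), target_id = col(6),
    query_start = qs, query_end = qe,
    target_start = ts, target_end = te,
    strand = col(5), identity = ifelse(block > 0, matches / block, 0),
    aligned_length = block,
    query_len = num(2), target_len = num(7)
  )
}

#' Write alignments to a PAF-like TSV file
#'
#' @param aln an [alignments()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  aln <- validate_alignments(aln)
  matches <- round(aln$identity * aln$aligned_length)
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   aln$query_id,
                   ifelse(is.na(aln$query_len), aln$query_end, aln$query_len),
                   aln$query_start, aln$query_end, aln$strand,
                   aln$target_id,
                   ifelse(is.na(aln$target_len), aln$target_end, aln$target_len),
                   aln$target_start, aln$target_end,
                   as.integer(matches), aln$aligned_length, 255L)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table from TSV
#'
#' Expected columns: `gene_id`, `contig_id`, `start`, `end`, `strand`,
#' `cog_id`, `cog_category`, `pog_hit`, `hit_coverage`, `taxon`, `is_arg`
#' (missing optional columns are filled with defaults).
#'
#' @param path TSV file with header.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  gene_table(
    gene_id = df$gene_id, contig_id = df$contig_id,
    start = df$start, end = df$end,
    strand = df$strand %||% "+",
    cog_id = df$cog_id %||% NA_character_,
    cog_category = df$cog_category %||% NA_character_,
    pog_hit = df$pog_hit %||% FALSE,
    hit_coverage = df$hit_coverage %||% 0,
    taxon = df$taxon %||% NA_character_,
    is_arg = df$is_arg %||% FALSE
  )
}

#' Write a table to TSV
#'
#' @param df data.frame (gene, motif, spacer or host tables).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation motif profile table from TSV
#'
#' @param path TSV with columns matching [motif_profiles()].
#' @return a [motif_profiles()] table.
#' @export
read_motif_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  motif_profiles(
    sequence_id = df$sequence_id, motif = df$motif,
    mod_type = df$mod_type %||% "m6A",
    methylated_fraction = df$methylated_fraction %||% NA_real_,
    mean_coverage = df$mean_coverage %||% NA_real_,
    mean_ipd_ratio = df$mean_ipd_ratio %||% NA_real_,
    binary_state = df$binary_state %||% NA_integer_,
    sequence_type = df$sequence_type %||% NA_character_
  )
}

#' Read a CRISPR spacer list from TSV
#'
#' @param path TSV with columns `host_id`, `spacer_id`, `sequence`.
#' @return data.frame.
#' @export
read_spacers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("host_id", "spacer_id", "sequence") %in% names(df)))
  df$sequence <- toupper(df$sequence)
  df
}

#' Read an abundance matrix from TSV
#'
#' First column `element_id`, second `length`, remaining columns one per
#' sample.
#'
#' @param path TSV file.
#' @return an [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("element_id", "length") %in% names(df)))
  m <- as.matrix(df[, setdiff(names(df), c("element_id", "length")),
                    drop = FALSE])
  rownames(m) <- df$element_id
  abundance_matrix(m, stats::setNames(df$length, df$element_id))
}

#' Write an abundance matrix to TSV
#'
#' @param x an [abundance_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(element_id = rownames(x$counts),
                   length = unname(x$lengths),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
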