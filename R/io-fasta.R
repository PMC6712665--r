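# FASTA reading/writing via Biostrings, with a light pre-validation pass
# so malformed files are reported with line numbers.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return data.frame with columns `id` and `sequence` (uppercased), in
#'   file order.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1L],
         ": expected '>' header", call. = FALSE)
  }
  hdr <- nonblank[startsWith(trimws(lines[nonblank]), ">")]
  ids <- sub("\\s.*$", "", sub("^>", "", trimws(lines[hdr])))
  empty_id <- which(!nzchar(ids))
  if (length(empty_id)) {
    stop("FASTA parse error at line ", hdr[empty_id[1L]],
         ": empty record id", call. = FALSE)
  }
  # a header immediately followed by another header (or EOF) has no sequence
  nxt <- c(hdr[-1L], length(lines) + 1L)
  for (i in seq_along(hdr)) {
    body <- lines[seq2(hdr[i] + 1L, nxt[i] - 1L)]
    if (sum(nchar(gsub("\\s", "", body))) == 0L) {
      stop("FASTA parse error at line ", hdr[i],
           ": record '", ids[i], "' has empty sequence", call. = FALSE)
    }
  }
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             stringsAsFactors = FALSE)
}

seq2 <- function(from, to) if (from > to) integer() else seq.int(from, to)

#' Write sequences to a FASTA file
#'
#' @param seqs data.frame with `id` and `sequence` columns, or a named
#'   character vector.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, width = 80L) {
  if (is.data.frame(seqs)) {
    x <- seqs$sequence
    names(x) <- seqs$id
  } else {
    x <- seqs
  }
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
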