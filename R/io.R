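# Format plumbing: FASTA/FASTQ via Biostrings, TSV tables with a
# key=value config echo in comment headers, BED nick tracks, JSON records.

# Normalise read input to parallel vectors (id, seq, qual).
.norm_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq",
                                      with.qualities = TRUE)
    q <- S4Vectors::mcols(x)$qualities
    return(list(id = if (is.null(names(x))) paste0("read", seq_along(x))
                     else names(x),
                seq = as.character(x),
                qual = if (is.null(q)) rep(NA_character_, length(x))
                       else as.character(q)))
  }
  if (inherits(reads, "DNAStringSet")) {
    q <- tryCatch(S4Vectors::mcols(reads)$qualities, error = function(e) NULL)
    return(list(id = if (is.null(names(reads)))
                       paste0("read", seq_along(reads)) else names(reads),
                seq = as.character(reads),
                qual = if (is.null(q)) rep(NA_character_, length(reads))
                       else as.character(q)))
  }
  if (is.character(reads)) {
    ids <- if (is.null(names(reads))) paste0("read", seq_along(reads))
           else names(reads)
    return(list(id = ids, seq = unname(toupper(reads)),
                qual = rep(NA_character_, length(reads))))
  }
  if (is.data.frame(reads) &&
      all(c("read_id", "seq") %in% names(reads))) {
    return(list(id = reads$read_id, seq = toupper(reads$seq),
                qual = if ("qual" %in% names(reads)) reads$qual
                       else rep(NA_character_, nrow(reads))))
  }
  stop("unsupported read input", call. = FALSE)
}

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file (gz transparent).  The first record is returned.
#' @return List with `id` and `seq` (character).
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path, call. = FALSE)
  list(id = sub("\\s.*$", "", names(x)[1]), seq = as.character(x[[1]]))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads Data frame with columns `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

# TSV with "# key=value" comment header lines carrying the config echo.
write_tsv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# %s=%s", names(config),
                       vapply(config, function(v) paste(v, collapse = ","),
                              character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write nick junctions as a BED track
#'
#' Each nick junction j (0-based inter-base index) is emitted as the
#' zero-width-style 1-bp BED feature `[j, j+1)` named by its source site
#' and variant, so the cut falls at the feature's left edge.
#'
#' @param nicks List of `nick_site` objects.
#' @param path Output path.
#' @param reference_id Chromosome/contig name for the BED column.
#' @export
write_nicks_bed <- function(nicks, path, reference_id = NULL) {
  rows <- vapply(nicks, function(nk) {
    rid <- if (is.null(reference_id)) nk$source_site$reference_id
           else reference_id
    sprintf("%s\t%d\t%d\t%s\t0\t%s", rid, nk$junction, nk$junction + 1L,
            paste0(nk$variant, "_nick"), nk$strand_nicked)
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
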