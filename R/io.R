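# File-format plumbing: FASTA targets, FASTQ/FASTA reads, variant flank
# tables and FACS event tables. Standard formats go through Biostrings.

#' Read a target sequence from a FASTA file
#'
#' @param path FASTA file; the first record is returned unless `name` picks
#'   one.
#' @param name Optional record name.
#' @return A [dna()] with the record name attached.
#' @export
read_target_fasta <- function(path, name = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  i <- if (is.null(name)) 1L else match(name, names(set))
  if (is.na(i)) stop(sprintf("no record named '%s' in %s", name, path), call. = FALSE)
  dna(as.character(set[[i]]), name = names(set)[i])
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (or single [dna()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_fasta <- function(seqs, path) {
  if (inherits(seqs, "fp_dna")) {
    nm <- attr(seqs, "name")
    seqs <- stats::setNames(unclass(seqs), if (is.null(nm)) "target" else nm)
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read merged amplicon reads from FASTA or FASTQ
#'
#' @param path Read file; format inferred from the extension (`.fq`/`.fastq`
#'   vs anything else).
#' @return Named character vector of reads.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(set), names(set))
}

#' Read a variant flank table (TSV)
#'
#' Expected columns: `variant_id`, `flank`, `edit_pos`, `kind`, `ref`, `alt`
#' (empty `ref` for insertions, empty `alt` for deletions).
#'
#' @param path TSV file path.
#' @return A data.frame suitable for [scan_variant_table()].
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  needed <- c("variant_id", "flank", "edit_pos", "kind", "ref", "alt")
  if (!all(needed %in% names(tab))) {
    stop("variant table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tab$edit_pos <- as.integer(tab$edit_pos)
  tab
}

#' Read a FACS event table (CSV)
#'
#' @param path CSV with header columns `gfp` and `cherry` (an `event_id`
#'   column is added when absent).
#' @return A data.frame.
#' @export
read_facs_events <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_events(tab)
  if (!"event_id" %in% names(tab)) tab$event_id <- seq_len(nrow(tab))
  tab
}
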