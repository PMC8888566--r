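# Foundational sequence types: validation, reverse complement, frame-aware
# translation, stop scanning and edit application. All user-facing coordinates
# are 1-based inclusive on the top strand.

#' Validate and normalise a nucleotide sequence
#'
#' Uppercases the input, maps `U` to `T` (RNA-style pastes are tolerated) and
#' rejects anything outside the concrete DNA alphabet `A/C/G/T`. Ambiguity
#' codes are only meaningful in PAM patterns, never in targets.
#'
#' @param x A character scalar of nucleotides.
#' @param name Optional identifier attached as the `name` attribute.
#' @return A character scalar of class `fp_dna` containing only `A/C/G/T`.
#' @examples
#' dna("acguACGT")
#' @export
dna <- function(x, name = NULL) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  s <- chartr("u", "t", x)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  if (nchar(s) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  bad <- gsub("[ACGT]", "", s)
  if (nchar(bad) > 0L) {
    stop(sprintf("invalid nucleotide character(s): %s",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  structure(s, class = c("fp_dna", "character"), name = name)
}

as_dna <- function(x) if (inherits(x, "fp_dna")) x else dna(x)

COMPLEMENT_FROM <- "ACGTacgt"
COMPLEMENT_TO <- "TGCAtgca"

#' Reverse complement
#'
#' @param seq A nucleotide sequence (string or [dna()]).
#' @return The Watson-Crick reverse complement, same length.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  s <- as_dna(seq)
  rc <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO,
               paste(rev(strsplit(unclass(s), "")[[1]]), collapse = ""))
  structure(rc, class = c("fp_dna", "character"), name = attr(s, "name"))
}

# fast internal revcomp for plain validated strings (no re-validation)
rc_ <- function(s) {
  if (nchar(s) == 0L) return(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# codon table from the standard genetic code; stops rendered as '*'
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate one reading frame
#'
#' Translates codons of the (possibly reverse-complemented) sequence starting
#' at `offset`, using the standard genetic code. A trailing partial codon is
#' ignored; stop codons are rendered as `*`.
#'
#' @param seq Nucleotide sequence.
#' @param offset Frame offset in `0:2`, counted from the 5' end of the chosen
#'   strand.
#' @param strand `"+"` (top strand as given) or `"-"` (reverse complement).
#' @return Peptide string (possibly empty).
#' @examples
#' translate_frame("ATGTAA", 0, "+")  # "M*"
#' @export
translate_frame <- function(seq, offset = 0L, strand = "+") {
  s <- unclass(as_dna(seq))
  stopifnot(offset %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") s <- rc_(s)
  n <- nchar(s)
  starts <- seq.int(1L + offset, n - 2L, by = 3L)
  if (offset + 3L > n) return("")
  codons <- substring(s, starts, starts + 2L)
  paste(codon_table()[codons], collapse = "")
}

#' Find stop codons in one frame
#'
#' Reports the 1-based top-strand coordinate of the first base of every
#' `TAA`/`TAG`/`TGA` codon in the given frame, sorted ascending.
#'
#' @inheritParams translate_frame
#' @return Integer vector of top-strand codon start positions (possibly empty).
#' @examples
#' find_stop_codons("AATAGAA", 1, "+")  # 3
#' @export
find_stop_codons <- function(seq, offset = 0L, strand = "+") {
  s <- unclass(as_dna(seq))
  stopifnot(offset %in% 0:2, strand %in% c("+", "-"))
  n <- nchar(s)
  w <- if (strand == "-") rc_(s) else s
  if (offset + 3L > n) return(integer(0))
  starts <- seq.int(1L + offset, n - 2L, by = 3L)
  codons <- substring(w, starts, starts + 2L)
  hit <- starts[codons %in% c("TAA", "TAG", "TGA")]
  if (strand == "-") {
    # codon occupies strand coords [p, p+2] -> top coords [n-p-1, n-p+1]
    hit <- n - hit - 1L
  }
  sort(hit)
}

#' Specify an edit on a target sequence
#'
#' An edit is a substitution, insertion or deletion on the top strand of a
#' target. `position` is 1-based; for insertions it is the index of the base
#' immediately 5' of the inserted bases (inserted bases are placed immediately
#' 3' of `position`).
#'
#' @param kind One of `"substitution"`, `"insertion"`, `"deletion"`.
#' @param position 1-based top-strand coordinate.
#' @param ref Reference allele (`""` for insertions).
#' @param alt Alternate allele (`""` for deletions).
#' @return A list of class `fp_edit`.
#' @examples
#' edit_spec("substitution", 2, "C", "G")
#' @export
edit_spec <- function(kind, position, ref = "", alt = "") {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"))
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("position must be a positive integer", call. = FALSE)
  chk <- function(x, label) {
    if (nchar(x) > 0L && nchar(gsub("[ACGT]", "", toupper(x))) > 0L) {
      stop(sprintf("%s allele contains invalid characters", label), call. = FALSE)
    }
    toupper(x)
  }
  ref <- chk(ref, "ref"); alt <- chk(alt, "alt")
  if (identical(ref, alt)) stop("ref and alt must differ", call. = FALSE)
  switch(kind,
    substitution = {
      if (nchar(ref) < 1L || nchar(ref) != nchar(alt)) {
        stop("substitution requires len(ref) == len(alt) >= 1", call. = FALSE)
      }
    },
    insertion = {
      if (nchar(ref) != 0L || nchar(alt) < 1L) {
        stop("insertion requires empty ref and non-empty alt", call. = FALSE)
      }
    },
    deletion = {
      if (nchar(ref) < 1L || nchar(alt) != 0L) {
        stop("deletion requires non-empty ref and empty alt", call. = FALSE)
      }
    }
  )
  structure(list(kind = kind, position = position, ref = ref, alt = alt),
            class = "fp_edit")
}

#' @export
print.fp_edit <- function(x, ...) {
  cat(sprintf("<edit> %s at %d: '%s' -> '%s'\n", x$kind, x$position, x$ref, x$alt))
  invisible(x)
}

#' Parse a compact edit string
#'
#' Accepts `KIND:POS:REF>ALT` where KIND is `sub`, `ins` or `del`
#' (e.g. `"sub:1399:G>A"`, `"ins:12:>TT"`, `"del:30:CGTACG>"`).
#'
#' @param x Character scalar.
#' @return An [edit_spec()].
#' @export
parse_edit_string <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L || !grepl(">", parts[3], fixed = TRUE)) {
    stop("edit string must look like 'sub:POS:REF>ALT'", call. = FALSE)
  }
  kind <- switch(parts[1], sub = "substitution", ins = "insertion",
                 del = "deletion",
                 stop("edit kind must be sub, ins or del", call. = FALSE))
  al <- strsplit(parts[3], ">", fixed = TRUE)[[1]]
  ref <- if (length(al) >= 1L) al[1] else ""
  alt <- if (length(al) >= 2L) al[2] else ""
  edit_spec(kind, as.integer(parts[2]), ref, alt)
}

# check the edit's invariants against a concrete target; returns the edit
validate_edit <- function(target, edit) {
  s <- unclass(as_dna(target))
  stopifnot(inherits(edit, "fp_edit"))
  n <- nchar(s)
  if (edit$kind == "insertion") {
    if (edit$position > n) {
      stop(sprintf("insertion anchor %d beyond target length %d", edit$position, n),
           call. = FALSE)
    }
    return(invisible(edit))
  }
  end <- edit$position + nchar(edit$ref) - 1L
  if (end > n) {
    stop(sprintf("edit span %d-%d beyond target length %d", edit$position, end, n),
         call. = FALSE)
  }
  obs <- substr(s, edit$position, end)
  if (obs != edit$ref) {
    stop(sprintf("ref check failed at %d: expected '%s', observed '%s'",
                 edit$position, edit$ref, obs), call. = FALSE)
  }
  invisible(edit)
}

#' Apply an edit to a sequence
#'
#' @param seq Nucleotide sequence.
#' @param edit An [edit_spec()]; its `ref` allele is checked against `seq`.
#' @return The edited sequence as [dna()].
#' @examples
#' apply_edit("ACGT", edit_spec("substitution", 2, "C", "G"))
#' @export
apply_edit <- function(seq, edit) {
  s <- as_dna(seq)
  validate_edit(s, edit)
  x <- unclass(s)
  out <- switch(edit$kind,
    substitution = paste0(substr(x, 1L, edit$position - 1L), edit$alt,
                          substr(x, edit$position + nchar(edit$ref), nchar(x))),
    deletion = paste0(substr(x, 1L, edit$position - 1L),
                      substr(x, edit$position + nchar(edit$ref), nchar(x))),
    insertion = paste0(substr(x, 1L, edit$position), edit$alt,
                       substr(x, edit$position + 1L, nchar(x)))
  )
  structure(out, class = c("fp_dna", "character"), name = attr(s, "name"))
}

# net length change of an edit
edit_delta <- function(edit) nchar(edit$alt) - nchar(edit$ref)

# shift an edit's coordinate (window localisation)
shift_edit <- function(edit, by) {
  edit$position <- edit$position + as.integer(by)
  edit
}

# map an edit given on the top strand of a sequence of length n into the
# coordinates of the reverse complement of that sequence
mirror_edit <- function(edit, n) {
  if (edit$kind == "insertion") {
    edit_spec("insertion", n - edit$position, ref = "", alt = rc_(edit$alt))
  } else {
    pos <- n - (edit$position + nchar(edit$ref) - 1L) + 1L
    edit_spec(edit$kind, pos, ref = rc_(edit$ref), alt = rc_(edit$alt))
  }
}

#' Prime-editor and base-editor profiles
#'
#' An editor profile bundles the PAM patterns an editor recognises (IUPAC
#' strings, in priority order), its spacer length, the nick offset (distance
#' of the nick 5' of the PAM on the protospacer strand; the default 3 places
#' the nick between protospacer positions 17 and 18, the canonical SpCas9
#' nickase geometry) and, for base editors, the editing window and conversion.
#'
#' @param name Identifier, e.g. `"PE2"`.
#' @param pam_patterns Character vector of IUPAC PAM strings, priority order.
#' @param spacer_length Protospacer length (default 20).
#' @param nick_offset Nick distance 5' of the PAM (default 3).
#' @param mode `"prime"` or `"base"`.
#' @param base_edit_window Inclusive protospacer position range (PAM-distal
#'   position = 1); base mode only.
#' @param base_conversion Length-2 character vector `c(from, to)`; base mode
#'   only.
#' @return A list of class `fp_editor`.
#' @examples
#' editor_profile("PE2", "NGG")
#' @export
editor_profile <- function(name, pam_patterns, spacer_length = 20L,
                           nick_offset = 3L, mode = c("prime", "base"),
                           base_edit_window = NULL, base_conversion = NULL) {
  mode <- match.arg(mode)
  pam_patterns <- toupper(pam_patterns)
  if (length(pam_patterns) < 1L) stop("pam_patterns must be non-empty", call. = FALSE)
  ok <- vapply(strsplit(pam_patterns, ""), function(ch) all(ch %in% names(IUPAC_SETS)),
               logical(1))
  if (!all(ok)) stop("pam_patterns must be valid IUPAC strings", call. = FALSE)
  spacer_length <- as.integer(spacer_length); nick_offset <- as.integer(nick_offset)
  if (!(nick_offset > 0L && nick_offset < spacer_length)) {
    stop("require 0 < nick_offset < spacer_length", call. = FALSE)
  }
  if (mode == "base") {
    if (is.null(base_edit_window) || is.null(base_conversion)) {
      stop("base mode requires base_edit_window and base_conversion", call. = FALSE)
    }
    base_edit_window <- as.integer(base_edit_window)
    stopifnot(length(base_edit_window) == 2L,
              base_edit_window[1] >= 1L,
              base_edit_window[2] <= spacer_length,
              base_edit_window[1] <= base_edit_window[2])
    base_conversion <- toupper(base_conversion)
    stopifnot(length(base_conversion) == 2L,
              all(base_conversion %in% c("A", "C", "G", "T")),
              base_conversion[1] != base_conversion[2])
  } else if (!is.null(base_edit_window) || !is.null(base_conversion)) {
    stop("base_edit_window/base_conversion only apply to base mode", call. = FALSE)
  }
  structure(list(name = name, pam_patterns = pam_patterns,
                 spacer_length = spacer_length, nick_offset = nick_offset,
                 mode = mode, base_edit_window = base_edit_window,
                 base_conversion = base_conversion),
            class = "fp_editor")
}

#' Built-in editor profiles
#'
#' PE2 (NGG), NG-PE2 (NG), SpG-PE2 (NGN), SpRY-PE2 (NNN, effectively PAM-less)
#' and an adenine base editor ABE8e (NGG, A-to-G, window 4-8; the window is
#' configurable common practice, not a measured constant).
#'
#' @param name Optional profile name; with no argument the full named list is
#'   returned.
#' @return An `fp_editor` or a named list of them.
#' @export
editor_profiles <- function(name = NULL) {
  all <- list(
    `PE2` = editor_profile("PE2", "NGG"),
    `NG-PE2` = editor_profile("NG-PE2", c("NG", "NGN")),
    `SpG-PE2` = editor_profile("SpG-PE2", "NGN"),
    `SpRY-PE2` = editor_profile("SpRY-PE2", "NNN"),
    `ABE8e` = editor_profile("ABE8e", "NGG", mode = "base",
                             base_edit_window = c(4L, 8L),
                             base_conversion = c("A", "G"))
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all)) {
    stop(sprintf("unknown editor profile '%s' (have: %s)", name,
                 paste(names(all), collapse = ", ")), call. = FALSE)
  }
  all[[name]]
}

# IUPAC nucleotide ambiguity sets
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# does concrete sequence s match IUPAC pattern pat (same length)?
iupac_match <- function(pat, s) {
  if (nchar(pat) != nchar(s)) return(FALSE)
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  for (i in seq_along(pc)) {
    if (!sc[i] %in% IUPAC_SETS[[pc[i]]]) return(FALSE)
  }
  TRUE
}
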