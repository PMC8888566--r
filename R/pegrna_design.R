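# pegRNA / epegRNA candidate generation, RTT mismatch counting, PE3/PE3b
# nicking-guide design and Golden Gate cloning oligos.

#' pegRNA design constraints
#'
#' Defaults follow the published design rules: primer binding sites (PBS) of
#' 9-15 nt containing at least 5 G/C nucleotides, and reverse transcriptase
#' templates (RTT) of 10-20 nt.
#'
#' @param pbs_min,pbs_max PBS length range (nt).
#' @param pbs_min_gc Minimum number of G/C nucleotides in the PBS.
#' @param rtt_min,rtt_max RTT length range (nt).
#' @param forbid_rtt_start_c If `TRUE` (default) candidates whose RTT begins
#'   with `C` are flagged with a warning field (common pegRNA guidance); they
#'   are never filtered out.
#' @return A list of class `fp_constraints`.
#' @export
design_constraints <- function(pbs_min = 9L, pbs_max = 15L, pbs_min_gc = 5L,
                               rtt_min = 10L, rtt_max = 20L,
                               forbid_rtt_start_c = TRUE) {
  pbs_min <- as.integer(pbs_min); pbs_max <- as.integer(pbs_max)
  rtt_min <- as.integer(rtt_min); rtt_max <- as.integer(rtt_max)
  pbs_min_gc <- as.integer(pbs_min_gc)
  stopifnot(pbs_min > 0L, pbs_min <= pbs_max, rtt_min > 0L, rtt_min <= rtt_max,
            pbs_min_gc <= pbs_max)
  structure(list(pbs_min = pbs_min, pbs_max = pbs_max, pbs_min_gc = pbs_min_gc,
                 rtt_min = rtt_min, rtt_max = rtt_max,
                 forbid_rtt_start_c = isTRUE(forbid_rtt_start_c)),
            class = "fp_constraints")
}

# default SpCas9 sgRNA scaffold (standard published sequence, DNA alphabet);
# user-replaceable through the `scaffold` argument of design_pegrnas()
FP_SCAFFOLD_V1 <- paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCA",
                         "ACTTGAAAAAGTGGCACCGAGTCGGTGC")

# placeholder 3' structured motif for epegRNAs; the real motif sequence must
# be supplied by the user for synthesis (this constant is a synthetic marker,
# not a published motif)
FP_EPEG_MOTIF_PLACEHOLDER <- "ACGCGTAAGCGCGTTCGAAACGCGA"

gc_count <- function(s) nchar(gsub("[AT]", "", s))

# orient a top-strand sequence onto the given strand
orient_seq <- function(s, strand) if (strand == "+") s else rc_(s)

# map an edit (top-strand coords) onto the given strand of a length-L target
orient_edit <- function(edit, L, strand) {
  if (strand == "+") edit else mirror_edit(edit, L)
}

# o-coord of the last base that the flap must cover: the full alt allele plus
# one downstream homologous base (for deletions, the first base after the
# junction, which is that homologous base)
flap_required_end <- function(edit_o) {
  switch(edit_o$kind,
    substitution = edit_o$position + nchar(edit_o$alt),
    insertion = edit_o$position + nchar(edit_o$alt) + 1L,
    deletion = edit_o$position
  )
}

#' Design pegRNA candidates for a spacer site
#'
#' Enumerates one candidate per (PBS length, RTT length) pair that satisfies
#' the constraints: the PBS is the reverse complement of the PAM-strand bases
#' immediately 5' of the nick with at least `pbs_min_gc` G/C; the RTT-encoded
#' 3' flap starts at the nick and spans the entire alt allele plus at least
#' one downstream homologous base. Candidates are ordered by the documented
#' heuristic (PBS length closest to 12, then RTT length closest to the
#' mid-range); this is a deterministic tie-break, not an efficiency score.
#'
#' @param target Target sequence (top strand).
#' @param edit An [edit_spec()].
#' @param site A site row from [find_spacer_sites()] for the same target/edit.
#' @param constraints A [design_constraints()].
#' @param epeg If `TRUE` append the named 3' structured motif (epegRNA).
#' @param scaffold,scaffold_id Scaffold sequence and its label.
#' @param epeg_motif,epeg_motif_id 3' motif sequence and label used when
#'   `epeg = TRUE`; the shipped default is a placeholder that must be replaced
#'   for real synthesis.
#' @return A list of `fp_pegrna` objects (possibly empty) with attribute
#'   `reasons`, a character vector of machine-readable failure reasons when no
#'   candidate could be emitted.
#' @export
design_pegrnas <- function(target, edit, site, constraints = design_constraints(),
                           epeg = FALSE, scaffold = FP_SCAFFOLD_V1,
                           scaffold_id = "SpCas9-scaffold-v1",
                           epeg_motif = FP_EPEG_MOTIF_PLACEHOLDER,
                           epeg_motif_id = "tevopreQ1-placeholder") {
  s <- unclass(as_dna(target))
  validate_edit(s, edit)
  site <- as_site(site)
  L <- nchar(s)
  o <- site$strand
  S_o <- orient_seq(s, o)
  edit_o <- orient_edit(edit, L, o)
  SL <- nchar(site$spacer)
  n <- if (o == "+") site$nick_position else L - site$nick_position + 1L
  proto_start_o <- if (o == "+") site$protospacer_start else L - site$protospacer_start + 1L
  if (substr(S_o, proto_start_o, proto_start_o + SL - 1L) != site$spacer) {
    stop("site does not match target: protospacer sequence mismatch", call. = FALSE)
  }
  if (site$nick_to_edit < 0L) {
    stop("edit lies 5' of the nick on the PAM strand (nick_to_edit < 0)", call. = FALSE)
  }
  Q_o <- unclass(apply_edit(S_o, edit_o))
  delta <- edit_delta(edit_o)
  req_end <- flap_required_end(edit_o)
  min_rtt <- req_end - n

  reasons <- character(0)
  pbs_rows <- list()
  for (pl in constraints$pbs_min:constraints$pbs_max) {
    if (n - pl + 1L < 1L) { reasons <- union(reasons, "pbs_window_out_of_bounds"); next }
    pbs <- rc_(substr(S_o, n - pl + 1L, n))
    gc <- gc_count(pbs)
    if (gc < constraints$pbs_min_gc) next
    pbs_rows[[length(pbs_rows) + 1L]] <- list(len = pl, pbs = pbs, gc = gc)
  }
  if (length(pbs_rows) == 0L) reasons <- union(reasons, "pbs_gc_below_min")

  rtt_lens <- integer(0)
  if (min_rtt > constraints$rtt_max) {
    reasons <- union(reasons, "edit_not_reachable_by_rtt")
  } else {
    lo <- max(constraints$rtt_min, min_rtt)
    cand <- lo:constraints$rtt_max
    rtt_lens <- cand[n + cand <= nchar(Q_o)]
    if (length(rtt_lens) == 0L) reasons <- union(reasons, "rtt_exceeds_target")
  }

  pegs <- list()
  for (pb in pbs_rows) {
    for (rl in rtt_lens) {
      flap <- substr(Q_o, n + 1L, n + rl)
      # flap-templated replacement must reproduce the post-edit sequence
      rebuilt <- paste0(substr(S_o, 1L, n), flap,
                        substr(S_o, n + rl - delta + 1L, L))
      if (rebuilt != Q_o) next
      rtt <- rc_(flap)
      extension <- paste0(rtt, pb$pbs)
      pegs[[length(pegs) + 1L]] <- structure(list(
        site = site,
        spacer = site$spacer,
        scaffold_id = scaffold_id,
        scaffold = scaffold,
        pbs = pb$pbs, pbs_length = pb$len, pbs_gc = pb$gc,
        rtt = rtt, rtt_length = rl,
        extension = extension,
        flap = flap,
        is_epeg = isTRUE(epeg),
        epeg_motif_id = if (isTRUE(epeg)) epeg_motif_id else NA_character_,
        epeg_motif = if (isTRUE(epeg)) epeg_motif else NA_character_,
        rtt_starts_with_c = constraints$forbid_rtt_start_c &&
          substr(rtt, 1L, 1L) == "C",
        edit = edit,
        strand = o,
        nick_top = site$nick_position,
        nick_offset = proto_start_o + SL - n - 1L,
        target_length = L,
        delta = delta
      ), class = "fp_pegrna")
    }
  }
  if (length(pegs) > 0L) {
    mid <- round((constraints$rtt_min + constraints$rtt_max) / 2)
    key <- vapply(pegs, function(p) {
      abs(p$pbs_length - 12L) * 1e6 + abs(p$rtt_length - mid) * 1e3 +
        p$pbs_length * 30 + p$rtt_length
    }, 0)
    pegs <- pegs[order(key)]
    reasons <- character(0)
  }
  attr(pegs, "reasons") <- reasons
  pegs
}

#' @export
print.fp_pegrna <- function(x, ...) {
  cat(sprintf("<pegRNA> %s strand %s\n  spacer %s\n  PBS %s (%d nt, %d G/C)\n  RTT %s (%d nt)\n",
              if (x$is_epeg) "epegRNA" else "pegRNA", x$strand, x$spacer,
              x$pbs, x$pbs_length, x$pbs_gc, x$rtt, x$rtt_length))
  invisible(x)
}

#' Tabulate a list of pegRNA candidates
#'
#' @param pegs List returned by [design_pegrnas()].
#' @return A data.frame, one row per candidate, in ranked order.
#' @export
pegrna_table <- function(pegs) {
  if (length(pegs) == 0L) {
    return(data.frame(spacer = character(0), pbs = character(0),
                      pbs_length = integer(0), pbs_gc = integer(0),
                      rtt = character(0), rtt_length = integer(0),
                      extension = character(0), strand = character(0),
                      is_epeg = logical(0), rtt_starts_with_c = logical(0)))
  }
  do.call(rbind, lapply(pegs, function(p) {
    data.frame(spacer = p$spacer, pbs = p$pbs, pbs_length = p$pbs_length,
               pbs_gc = p$pbs_gc, rtt = p$rtt, rtt_length = p$rtt_length,
               extension = p$extension, strand = p$strand, is_epeg = p$is_epeg,
               rtt_starts_with_c = p$rtt_starts_with_c,
               stringsAsFactors = FALSE)
  }))
}

#' Count mismatches between the RTT-encoded flap and the unedited target
#'
#' Returns the number of differences between the flap and the pre-edit
#' PAM-strand sequence over the flap footprint: substitutions plus the total
#' length of insertions/deletions (indels are scored via global pairwise
#' alignment when the lengths differ).
#'
#' @param peg An `fp_pegrna` from [design_pegrnas()].
#' @param target The (unedited) target it was designed against.
#' @return Integer mismatch count (0 for a no-op pegRNA).
#' @export
rtt_mismatch_count <- function(peg, target) {
  s <- unclass(as_dna(target))
  stopifnot(inherits(peg, "fp_pegrna"))
  S_o <- orient_seq(s, peg$strand)
  n <- if (peg$strand == "+") peg$nick_top else nchar(s) - peg$nick_top + 1L
  footprint <- substr(S_o, n + 1L, n + peg$rtt_length - peg$delta)
  flap <- peg$flap
  if (nchar(footprint) == nchar(flap)) {
    a <- strsplit(flap, "")[[1]]; b <- strsplit(footprint, "")[[1]]
    return(sum(a != b))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(pattern = flap, subject = footprint,
                                       substitutionMatrix = mat,
                                       gapOpening = 10, gapExtension = 1,
                                       type = "global")
  ind <- Biostrings::indel(aln)
  indel_len <- sum(unlist(lapply(Biostrings::insertion(ind), Biostrings::width))) +
    sum(unlist(lapply(Biostrings::deletion(ind), Biostrings::width)))
  Biostrings::nmismatch(aln) + indel_len
}

#' Design PE3 / PE3b nicking guides
#'
#' Scans the strand opposite the pegRNA site, on the post-edit sequence,
#' within `search_span` bp of the pegRNA nick, for PAM-bearing spacers. A
#' guide is flagged `pe3b` when its spacer/PAM footprint overlaps the edited
#' bases and the spacer matches the post-edit but not the pre-edit sequence
#' (so it can only nick after successful editing).
#'
#' @param target Unedited target (top strand).
#' @param edit The [edit_spec()].
#' @param peg The `fp_pegrna` being assisted.
#' @param profile [editor_profile()] supplying PAM patterns and nick geometry.
#' @param search_span Maximum |distance| (bp) between the two nicks
#'   (default 100).
#' @return A data.frame: `spacer`, `strand`, `pam`, `pam_pattern`,
#'   `nick_position` (top-strand coordinate on the post-edit sequence),
#'   `offset_from_peg_nick`, `pe3b`.
#' @export
design_nicking_guides <- function(target, edit, peg, profile = editor_profiles("PE2"),
                                  search_span = 100L) {
  s <- unclass(as_dna(target))
  validate_edit(s, edit)
  stopifnot(inherits(peg, "fp_pegrna"))
  Q <- unclass(apply_edit(s, edit))
  LQ <- nchar(Q)
  delta <- edit_delta(edit)
  oo <- if (peg$strand == "+") "-" else "+"
  SL <- profile$spacer_length
  # pegRNA nick in post-edit top coords: on '+' the edit is downstream (higher
  # top coords) of the nick, on '-' it is upstream, shifting the nick by delta
  peg_nick_post <- if (peg$strand == "+") peg$nick_top else peg$nick_top + delta

  # edited span in post-edit top coords (junction pair for deletions)
  span <- switch(edit$kind,
    substitution = c(edit$position, edit$position + nchar(edit$alt) - 1L),
    insertion = c(edit$position + 1L, edit$position + nchar(edit$alt)),
    deletion = c(edit$position - 1L, edit$position)
  )

  S_oo <- orient_seq(Q, oo)
  pre_oo <- orient_seq(s, oo)
  rows <- list()
  for (pat in profile$pam_patterns) {
    m <- nchar(pat)
    for (g in (SL + 1L):(LQ - m + 1L)) {
      pam_obs <- substr(S_oo, g, g + m - 1L)
      if (!iupac_match(pat, pam_obs)) next
      nick_oo <- g - profile$nick_offset - 1L
      nick_top <- if (oo == "+") nick_oo else LQ - nick_oo + 1L
      off <- nick_top - peg_nick_post
      if (abs(off) > search_span) next
      fp_oo <- c(g - SL, g + m - 1L)
      fp_top <- if (oo == "+") fp_oo else c(LQ - fp_oo[2] + 1L, LQ - fp_oo[1] + 1L)
      overlaps <- fp_top[1] <= span[2] && fp_top[2] >= span[1]
      spacer <- substr(S_oo, g - SL, g - 1L)
      # PE3b: the footprint overlaps the edited bases and the spacer is a
      # perfect match only to the post-edit sequence (a spacer that still
      # occurs anywhere in the pre-edit sequence can nick before editing)
      pe3b <- overlaps && !grepl(spacer, pre_oo, fixed = TRUE)
      key <- sprintf("%s:%d", oo, g)
      if (length(rows) > 0L && key %in% vapply(rows, `[[`, "", "key")) next
      rows[[length(rows) + 1L]] <- list(key = key, spacer = spacer, strand = oo,
                                        pam = pam_obs, pam_pattern = pat,
                                        nick_position = nick_top,
                                        offset_from_peg_nick = off, pe3b = pe3b)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(spacer = character(0), strand = character(0),
                      pam = character(0), pam_pattern = character(0),
                      nick_position = integer(0),
                      offset_from_peg_nick = integer(0), pe3b = logical(0)))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(spacer = r$spacer, strand = r$strand, pam = r$pam,
               pam_pattern = r$pam_pattern, nick_position = r$nick_position,
               offset_from_peg_nick = r$offset_from_peg_nick, pe3b = r$pe3b,
               stringsAsFactors = FALSE)
  }))
  out[order(abs(out$offset_from_peg_nick), out$nick_position), , drop = FALSE]
}

#' Define a Golden Gate acceptor for pegRNA cloning
#'
#' The acceptor provides the two vector-junction overhangs; the inter-duplex
#' junction overhangs are taken from the first four bases of the scaffold and
#' extension so that ligation reconstructs spacer+scaffold+extension exactly.
#' Overhang sequences are acceptor data, not hard-coded constants.
#'
#' @param name Acceptor identifier.
#' @param vector_overhang_top 4-nt 5' overhang of the spacer duplex's top
#'   oligo (vector-to-spacer junction).
#' @param vector_overhang_bottom 4-nt 5' overhang of the extension duplex's
#'   bottom oligo (extension-to-vector junction).
#' @return A list of class `fp_acceptor`.
#' @export
pegrna_acceptor <- function(name = "pU6-GG-acceptor",
                            vector_overhang_top = "CACC",
                            vector_overhang_bottom = "AAAA") {
  vt <- unclass(dna(vector_overhang_top)); vb <- unclass(dna(vector_overhang_bottom))
  if (nchar(vt) != 4L || nchar(vb) != 4L) {
    stop("acceptor overhangs must be 4 nt", call. = FALSE)
  }
  structure(list(name = name, vector_overhang_top = vt,
                 vector_overhang_bottom = vb), class = "fp_acceptor")
}

#' Emit Golden Gate oligo duplexes for a pegRNA
#'
#' Produces three annealed duplexes (spacer, scaffold, extension) whose 4-nt
#' 5' overhangs chain unambiguously: simulated sequential ligation (see
#' [simulate_golden_gate()]) reconstructs spacer+scaffold+extension 5'->3'.
#'
#' @param peg An `fp_pegrna`.
#' @param acceptor A [pegrna_acceptor()].
#' @return A list of class `fp_oligoset`: one element per duplex with `name`,
#'   `top`, `bottom` (both 5'->3'), `top_overhang`, `bottom_overhang`.
#' @export
emit_pegrna_oligos <- function(peg, acceptor = pegrna_acceptor()) {
  stopifnot(inherits(peg, "fp_pegrna"), inherits(acceptor, "fp_acceptor"))
  extension <- if (peg$is_epeg) paste0(peg$extension, peg$epeg_motif) else peg$extension
  scaffold <- peg$scaffold
  if (nchar(scaffold) < 8L || nchar(extension) < 8L) {
    stop("scaffold and extension must be at least 8 nt for 4-nt junctions",
         call. = FALSE)
  }
  j <- c(vector_top = acceptor$vector_overhang_top,
         spacer_scaffold = substr(scaffold, 1L, 4L),
         scaffold_extension = substr(extension, 1L, 4L),
         vector_bottom = rc_(acceptor$vector_overhang_bottom))
  if (anyDuplicated(j)) {
    stop(sprintf("acceptor definition error: junction overhang collision (%s)",
                 paste(j[duplicated(j)], collapse = ", ")), call. = FALSE)
  }
  duplex <- function(name, top_oh, core, bottom_oh) {
    list(name = name, top = paste0(top_oh, core),
         bottom = paste0(bottom_oh, rc_(core)),
         top_overhang = top_oh, bottom_overhang = bottom_oh)
  }
  out <- list(
    spacer = duplex("spacer", acceptor$vector_overhang_top, peg$spacer,
                    rc_(substr(scaffold, 1L, 4L))),
    scaffold = duplex("scaffold", substr(scaffold, 1L, 4L),
                      substr(scaffold, 5L, nchar(scaffold)),
                      rc_(substr(extension, 1L, 4L))),
    extension = duplex("extension", substr(extension, 1L, 4L),
                       substr(extension, 5L, nchar(extension)),
                       acceptor$vector_overhang_bottom)
  )
  structure(out, class = "fp_oligoset", acceptor = acceptor$name)
}
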