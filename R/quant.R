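# Quantification of editing outcomes: flow-cytometry ratio score and
# enrichment fractions from event tables; intended-edit and indel percentages
# from merged amplicon reads; condition ranking and rank correlation.

#' Gating configuration for FACS event tables
#'
#' Thresholds may be fixed numbers or derived from a negative-control event
#' table as its `control_quantile` quantile per channel (default 99.9th
#' percentile).
#'
#' @param gfp_threshold,cherry_threshold Numeric thresholds (>= 0), or `NULL`
#'   to derive them from `control`.
#' @param control Optional negative-control event table (data.frame with
#'   `gfp`, `cherry` columns).
#' @param control_quantile Quantile used on the control channels.
#' @return A list of class `fp_gate` with numeric `gfp_threshold` and
#'   `cherry_threshold`.
#' @export
gate_config <- function(gfp_threshold = NULL, cherry_threshold = NULL,
                        control = NULL, control_quantile = 0.999) {
  stopifnot(control_quantile > 0, control_quantile < 1)
  if (is.null(gfp_threshold) || is.null(cherry_threshold)) {
    if (is.null(control)) {
      stop("supply numeric thresholds or a negative-control event table",
           call. = FALSE)
    }
    check_events(control)
    if (is.null(gfp_threshold)) {
      gfp_threshold <- as.numeric(stats::quantile(control$gfp, control_quantile))
    }
    if (is.null(cherry_threshold)) {
      cherry_threshold <- as.numeric(stats::quantile(control$cherry, control_quantile))
    }
  }
  stopifnot(gfp_threshold >= 0, cherry_threshold >= 0)
  structure(list(gfp_threshold = gfp_threshold,
                 cherry_threshold = cherry_threshold,
                 control_quantile = control_quantile),
            class = "fp_gate")
}

check_events <- function(events) {
  if (!all(c("gfp", "cherry") %in% names(events))) {
    stop("event table needs 'gfp' and 'cherry' columns", call. = FALSE)
  }
  if (!all(is.finite(events$gfp)) || !all(is.finite(events$cherry)) ||
      any(events$gfp < 0) || any(events$cherry < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  invisible(events)
}

#' Cherry/GFP ratio score
#'
#' The reporter's editing-efficiency readout: mean Cherry intensity divided
#' by mean GFP intensity over all GFP-positive events. Invariant under a
#' common multiplicative gain on both channels.
#'
#' @param events Event table (data.frame with `gfp`, `cherry`).
#' @param gate A [gate_config()].
#' @return A list: `ratio` and `gfp_pos_n` (number of GFP+ events).
#' @export
facs_ratio_score <- function(events, gate) {
  check_events(events)
  stopifnot(inherits(gate, "fp_gate"))
  pos <- events$gfp > gate$gfp_threshold
  if (!any(pos)) {
    stop("no GFP+ events after gating: no transfected cells to score", call. = FALSE)
  }
  list(ratio = mean(events$cherry[pos]) / mean(events$gfp[pos]),
       gfp_pos_n = sum(pos))
}

#' Transfection and editing enrichment fractions
#'
#' @param events Event table.
#' @param gate A [gate_config()].
#' @return A list: `gfp_pos` (fraction of all events), `gfp_cherry_pos`
#'   (double-positive fraction of all events) and `cherry_given_gfp`
#'   (`NA` when there are no GFP+ events).
#' @export
enrichment_fractions <- function(events, gate) {
  check_events(events)
  stopifnot(inherits(gate, "fp_gate"))
  n <- nrow(events)
  gfp_pos <- events$gfp > gate$gfp_threshold
  both <- gfp_pos & events$cherry > gate$cherry_threshold
  list(gfp_pos = if (n == 0L) 0 else sum(gfp_pos) / n,
       gfp_cherry_pos = if (n == 0L) 0 else sum(both) / n,
       cherry_given_gfp = if (sum(gfp_pos) == 0L) NA_real_ else
         sum(both) / sum(gfp_pos))
}

#' Read-classification configuration
#'
#' @param comparison_range_r Half-width R of the window around the nick
#'   within which reads are compared and unwanted indels counted; R = 30 or
#'   70 gives 60 or 140 bp of flanking sequence.
#' @param min_freq Minimum allele frequency for inclusion in the denominator
#'   (default 0: no exclusion).
#' @param nick_position 1-based position on the amplicon of the base
#'   immediately 5' of the predicted nick.
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring used for
#'   indel detection.
#' @return A list of class `fp_readclass_config` (with derived `flank_total
#'   = 2 * R`).
#' @export
read_class_config <- function(comparison_range_r = 30L, min_freq = 0,
                              nick_position, match = 2, mismatch = -4,
                              gap_opening = 10, gap_extension = 1) {
  r <- as.integer(comparison_range_r)
  stopifnot(r > 0L, min_freq >= 0, min_freq < 1)
  structure(list(comparison_range_r = r, flank_total = 2L * r,
                 min_freq = min_freq, nick_position = as.integer(nick_position),
                 match = match, mismatch = mismatch, gap_opening = gap_opening,
                 gap_extension = gap_extension),
            class = "fp_readclass_config")
}

# indel positions (reference coordinates) from a global alignment of read vs
# reference; returns integer vector of reference coords touched by gaps
aligned_indel_positions <- function(read, ref, config) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = config$match,
                                                  mismatch = config$mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(pattern = read, subject = ref,
                                       substitutionMatrix = mat,
                                       gapOpening = config$gap_opening,
                                       gapExtension = config$gap_extension,
                                       type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- 0L
  out <- integer(0)
  for (i in seq_along(p)) {
    if (s[i] == "-") {
      out <- c(out, ref_pos)          # insertion after this reference base
    } else {
      ref_pos <- ref_pos + 1L
      if (p[i] == "-") out <- c(out, ref_pos)  # deletion of this base
    }
  }
  unique(out)
}

#' Classify amplicon reads against unedited and edited references
#'
#' Reads are collapsed to alleles; alleles below `min_freq` are excluded from
#' the denominator. Each remaining allele is classified within the comparison
#' window `[nick - R + 1, nick + R]`: an exact window match to the edited
#' amplicon is an intended edit, an exact window match to the unedited
#' amplicon is unedited, an alignment to the unedited amplicon containing an
#' insertion/deletion inside the window is an indel, anything else is other.
#' A read matching the intended edit but carrying an additional in-window
#' indel counts as indel (conservative tie-break).
#'
#' @param reads Character vector of merged reads (or a `DNAStringSet`).
#' @param wt_amplicon,edited_amplicon Reference sequences sharing coordinates
#'   up to the edit.
#' @param config A [read_class_config()].
#' @return A list of class `fp_read_counts`: `total_reads`,
#'   `above_min_freq_reads`, `intended_edit_reads`, `indel_reads`,
#'   `unedited_reads`, `other_reads`, `pe_efficiency_pct`, `indel_pct`.
#' @export
classify_amplicon_reads <- function(reads, wt_amplicon, edited_amplicon, config) {
  stopifnot(inherits(config, "fp_readclass_config"))
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  wt <- unclass(as_dna(wt_amplicon)); ed <- unclass(as_dna(edited_amplicon))
  nick <- config$nick_position
  r <- config$comparison_range_r
  if (nick - r + 1L < 1L || nick + r > nchar(wt) || nick + r > nchar(ed)) {
    stop(sprintf("comparison window [%d, %d] outside the amplicons",
                 nick - r + 1L, nick + r), call. = FALSE)
  }
  total <- length(reads)
  if (total == 0L) stop("no reads supplied", call. = FALSE)
  tab <- table(reads)
  keep <- as.vector(tab) / total >= config$min_freq
  alleles <- names(tab)[keep]
  counts <- as.vector(tab)[keep]
  above <- sum(counts)

  win <- function(x) substr(x, nick - r + 1L, nick + r)
  wt_win <- win(wt); ed_win <- win(ed)
  short_warned <- FALSE
  cls <- vapply(alleles, function(a) {
    if (nchar(a) < nick + r) {
      if (!short_warned) {
        warning("read(s) shorter than the comparison window counted as other",
                call. = FALSE)
        short_warned <<- TRUE
      }
      return("other")
    }
    if (nchar(a) == nchar(ed) && win(a) == ed_win) return("intended")
    if (nchar(a) == nchar(wt) && win(a) == wt_win) return("unedited")
    pos <- aligned_indel_positions(a, wt, config)
    if (any(pos >= nick - r + 1L & pos <= nick + r)) "indel" else "other"
  }, "")
  sum_by <- function(k) sum(counts[cls == k])
  intended <- sum_by("intended"); indel <- sum_by("indel")
  unedited <- sum_by("unedited"); other <- sum_by("other")
  structure(list(
    total_reads = total, above_min_freq_reads = above,
    intended_edit_reads = intended, indel_reads = indel,
    unedited_reads = unedited, other_reads = other,
    pe_efficiency_pct = 100 * intended / above,
    indel_pct = 100 * indel / above
  ), class = "fp_read_counts")
}

#' Rank two score tables and correlate them
#'
#' Ranks conditions in each table (average ranks for ties) and reports the
#' Spearman and Pearson correlations between the scores.
#'
#' @param scores_a,scores_b Data.frames with columns `condition`, `value`
#'   over the same condition set (n >= 3).
#' @return A list: `table` (condition, value_a, value_b, rank_a, rank_b),
#'   `spearman_rho`, `pearson_r`.
#' @export
rank_and_correlate <- function(scores_a, scores_b) {
  stopifnot(all(c("condition", "value") %in% names(scores_a)),
            all(c("condition", "value") %in% names(scores_b)))
  only_a <- setdiff(scores_a$condition, scores_b$condition)
  only_b <- setdiff(scores_b$condition, scores_a$condition)
  if (length(only_a) > 0L || length(only_b) > 0L) {
    stop(sprintf("condition sets differ (only in a: %s; only in b: %s)",
                 paste(only_a, collapse = ","), paste(only_b, collapse = ",")),
         call. = FALSE)
  }
  if (anyDuplicated(scores_a$condition) || anyDuplicated(scores_b$condition)) {
    stop("duplicated conditions", call. = FALSE)
  }
  if (nrow(scores_a) < 3L) stop("need at least 3 conditions", call. = FALSE)
  m <- merge(scores_a, scores_b, by = "condition", suffixes = c("_a", "_b"))
  m$rank_a <- rank(m$value_a)
  m$rank_b <- rank(m$value_b)
  list(table = m,
       spearman_rho = stats::cor(m$value_a, m$value_b, method = "spearman"),
       pearson_r = stats::cor(m$value_a, m$value_b, method = "pearson"))
}
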