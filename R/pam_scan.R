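# Enumeration of candidate protospacer/PAM sites around an edit, and batch
# PAM counting over variant flank tables.
#
# Geometry conventions (documented once, used everywhere):
# * "PAM strand" is the strand carrying the protospacer and PAM. Coordinates
#   on that strand ("o coords") run 5'->3' along it; for the minus strand,
#   o coord y maps to top-strand coord L - y + 1.
# * The protospacer occupies o coords [g - SL, g - 1] where g is the o coord
#   of the PAM's 5'-most base and SL the spacer length.
# * The nick sits nick_offset nt 5' of the PAM: the base immediately 5' of
#   the nicked bond has o coord g - nick_offset - 1 (between protospacer
#   positions 17/18 for the defaults).
# * The scan window constrains the offset of the PAM's 5'-most base relative
#   to the edited base, measured on the PAM strand. For multi-base edits the
#   anchor is the 5'-most edited base on the scanned strand.

#' Scan configuration for PAM searches
#'
#' @param window_start,window_end Inclusive offset window (PAM 5'-most base
#'   relative to the edited base, on the PAM strand). Defaults -10 and +4.
#' @param patterns IUPAC PAM patterns; `NULL` means take them from the editor
#'   profile at scan time.
#' @param both_strands Scan the bottom strand too? Default `TRUE`.
#' @return A list of class `fp_scan_config`.
#' @export
scan_config <- function(window_start = -10L, window_end = 4L, patterns = NULL,
                        both_strands = TRUE) {
  window_start <- as.integer(window_start); window_end <- as.integer(window_end)
  if (window_start > window_end) stop("window_start must be <= window_end", call. = FALSE)
  if (!is.null(patterns)) {
    patterns <- toupper(patterns)
    if (length(patterns) < 1L) stop("patterns must be non-empty", call. = FALSE)
  }
  structure(list(window_start = window_start, window_end = window_end,
                 patterns = patterns, both_strands = isTRUE(both_strands)),
            class = "fp_scan_config")
}

# anchor of an edit in o coords (edit already mapped to o coords)
edit_anchor_o <- function(edit_o) edit_o$position

# signed nick-to-edit distance in o coords; 0 = first base 3' of the nick
nick_to_edit_o <- function(edit_o, nick_o) {
  if (edit_o$kind == "insertion") edit_o$position - nick_o
  else edit_o$position - nick_o - 1L
}

#' Enumerate protospacer/PAM sites near an edit
#'
#' Scans both strands (unless disabled) for PAM matches whose 5'-most base
#' lies within the configured offset window of the edited base, with room for
#' a full protospacer. For prime-editor profiles only sites with the edit at
#' or downstream of the nick (`nick_to_edit >= 0`) are candidates; for base
#' editors the edited base must fall inside the base-editing window.
#'
#' @param target Target sequence.
#' @param edit An [edit_spec()], validated against `target`.
#' @param profile An [editor_profile()].
#' @param config A [scan_config()]; its `patterns` default to the profile's.
#' @return A data.frame of class `fp_sites` with one row per site: `strand`,
#'   `spacer`, `pam`, `pam_pattern`, `protospacer_start` (top-strand coord of
#'   the protospacer's 5' base on the PAM strand), `nick_position` (top-strand
#'   coord of the base immediately 5' of the nick on the PAM strand),
#'   `nick_to_edit`, `pam_offset`. Sorted by `|nick_to_edit|`, then strand
#'   (`+` first), then position.
#' @export
find_spacer_sites <- function(target, edit, profile, config = scan_config()) {
  s <- unclass(as_dna(target))
  validate_edit(s, edit)
  stopifnot(inherits(profile, "fp_editor"), inherits(config, "fp_scan_config"))
  patterns <- if (is.null(config$patterns)) profile$pam_patterns else config$patterns
  L <- nchar(s)
  SL <- profile$spacer_length
  maxm <- max(nchar(patterns))
  if (profile$mode == "base") {
    # base editing: the edited base must sit inside the editing window of the
    # protospacer, which pins the PAM offset range regardless of the scan
    # window (protospacer position p maps to PAM offset SL - p + 1)
    off_range <- c(SL - profile$base_edit_window[2] + 1L,
                   SL - profile$base_edit_window[1] + 1L)
  } else {
    off_range <- c(config$window_start, config$window_end)
  }
  need5 <- SL - off_range[1]                 # flank needed 5' of the anchor
  need3 <- off_range[2] + maxm - 1L          # flank needed 3' of the anchor
  need <- max(need5, need3)

  strands <- if (config$both_strands) c("+", "-") else "+"
  rows <- list()
  for (o in strands) {
    S_o <- if (o == "+") s else rc_(s)
    edit_o <- if (o == "+") edit else mirror_edit(edit, L)
    a <- edit_anchor_o(edit_o)
    if (a - 1L < need || L - a < need) {
      stop(sprintf(paste0("target too short around the edit: need >= %d nt on ",
                          "each side of the edited base (have %d 5', %d 3' on ",
                          "the %s strand)"), need, a - 1L, L - a, o),
           call. = FALSE)
    }
    seen <- character(0)
    for (pat in patterns) {
      m <- nchar(pat)
      for (g in (a + off_range[1]):(a + off_range[2])) {
        if (g - SL < 1L || g + m - 1L > L) next
        key <- sprintf("%s:%d", o, g)
        if (key %in% seen) next
        pam_obs <- substr(S_o, g, g + m - 1L)
        if (!iupac_match(pat, pam_obs)) next
        nick_o <- g - profile$nick_offset - 1L
        nte <- nick_to_edit_o(edit_o, nick_o)
        if (profile$mode == "prime") {
          if (nte < 0L) next
        } else {
          proto_pos <- a - (g - SL) + 1L
          if (proto_pos < profile$base_edit_window[1] ||
              proto_pos > profile$base_edit_window[2]) next
        }
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- data.frame(
          strand = o,
          spacer = substr(S_o, g - SL, g - 1L),
          pam = pam_obs,
          pam_pattern = pat,
          protospacer_start = if (o == "+") g - SL else L - (g - SL) + 1L,
          nick_position = if (o == "+") nick_o else L - nick_o + 1L,
          nick_to_edit = nte,
          pam_offset = g - a,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(strand = character(0), spacer = character(0), pam = character(0),
               pam_pattern = character(0), protospacer_start = integer(0),
               nick_position = integer(0), nick_to_edit = integer(0),
               pam_offset = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  ord <- order(abs(out$nick_to_edit), factor(out$strand, levels = c("+", "-")),
               out$protospacer_start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fp_sites", "data.frame")
  out
}

# normalise a site argument (one-row fp_sites data.frame or list) to a list
as_site <- function(site) {
  if (is.data.frame(site)) {
    if (nrow(site) != 1L) stop("expected exactly one site row", call. = FALSE)
    site <- as.list(site)
  }
  needed <- c("strand", "spacer", "pam", "pam_pattern", "protospacer_start",
              "nick_position", "nick_to_edit")
  if (!all(needed %in% names(site))) {
    stop("site is missing fields: ",
         paste(setdiff(needed, names(site)), collapse = ", "), call. = FALSE)
  }
  site
}

# geometry of a site in o coords of a sequence of length L
site_geometry_o <- function(site, L, profile) {
  SL <- profile$spacer_length
  ps_top <- site$protospacer_start
  proto_start_o <- if (site$strand == "+") ps_top else L - ps_top + 1L
  g <- proto_start_o + SL              # PAM 5'-most base, o coords
  nick_o <- g - profile$nick_offset - 1L
  list(proto_start = proto_start_o, pam_start = g,
       pam_end = g + nchar(site$pam) - 1L, nick = nick_o)
}

#' Batch PAM scan over a variant table
#'
#' One row per variant: a flank sequence and the edit it carries. Counts, for
#' every PAM pattern, the candidate sites within the window ([scan_config()]);
#' a site matching several patterns is counted once per pattern but only once
#' in the deduplicated total. Malformed rows are skipped with a warning and
#' tallied.
#'
#' @param table A data.frame with columns `variant_id`, `flank`, `edit_pos`,
#'   `kind`, `ref`, `alt` (see [read_variant_table()]).
#' @param config A [scan_config()] whose `patterns` must be set.
#' @param profile Editor profile supplying spacer geometry (default PE2, with
#'   the config's patterns substituted).
#' @return A list with `results` (data.frame: `variant_id`, one count column
#'   per pattern, `total`), `summary` (per-pattern mean/median and a histogram
#'   of per-variant totals) and `n_errors`.
#' @export
scan_variant_table <- function(table, config, profile = editor_profiles("PE2")) {
  stopifnot(inherits(config, "fp_scan_config"))
  if (is.null(config$patterns)) stop("config$patterns must be set for table scans",
                                     call. = FALSE)
  patterns <- config$patterns
  cols <- c("variant_id", "flank", "edit_pos", "kind", "ref", "alt")
  if (!all(cols %in% names(table))) {
    stop("variant table needs columns: ", paste(cols, collapse = ", "), call. = FALSE)
  }
  res <- list(); n_err <- 0L
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    counts <- tryCatch({
      ed <- edit_spec(as.character(row$kind), row$edit_pos,
                      ifelse(is.na(row$ref), "", as.character(row$ref)),
                      ifelse(is.na(row$alt), "", as.character(row$alt)))
      per <- integer(length(patterns)); names(per) <- patterns
      keys <- character(0)
      for (p in seq_along(patterns)) {
        cfg1 <- scan_config(config$window_start, config$window_end,
                            patterns[p], config$both_strands)
        hits <- find_spacer_sites(as.character(row$flank), ed, profile, cfg1)
        per[p] <- nrow(hits)
        keys <- c(keys, sprintf("%s:%d", hits$strand, hits$protospacer_start))
      }
      c(per, total = length(unique(keys)))
    }, error = function(e) {
      warning(sprintf("variant '%s' skipped: %s", row$variant_id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(counts)) { n_err <- n_err + 1L; next }
    res[[length(res) + 1L]] <- data.frame(variant_id = row$variant_id,
                                          t(counts), check.names = FALSE,
                                          stringsAsFactors = FALSE)
  }
  results <- if (length(res) == 0L) {
    empty <- as.data.frame(as.list(setNames(integer(length(patterns) + 1L),
                                            c(patterns, "total"))))[0, , drop = FALSE]
    cbind(data.frame(variant_id = character(0), stringsAsFactors = FALSE), empty)
  } else {
    do.call(rbind, res)
  }
  summ <- list(
    per_pattern = if (nrow(results) == 0L) {
      data.frame(pattern = patterns, mean = rep(NA_real_, length(patterns)),
                 median = rep(NA_real_, length(patterns)))
    } else {
      data.frame(pattern = patterns,
                 mean = vapply(patterns, function(p) mean(results[[p]]), 0),
                 median = vapply(patterns, function(p) stats::median(results[[p]]), 0),
                 row.names = NULL)
    },
    mean_total = if (nrow(results) == 0L) NA_real_ else mean(results$total),
    histogram = if (nrow(results) == 0L) table(integer(0)) else table(results$total)
  )
  list(results = results, summary = summ, n_errors = n_err)
}
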