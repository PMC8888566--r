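# Design of the fluorescent reporter insert: a 45-100 nt genomic window
# cloned between GFP and Cherry cassettes, blocked pre-edit by a stop codon
# or frameshift and restored by the simulated edit. Includes the six-frame
# base-editing mode, SalI/Acc65I cloning oligos and PAM variant panels.

#' Reporter cassette segment constants
#'
#' Named segments of the reporter construct
#' (CMV - GFP - P2A - insert - P2A - Cherry, with the inert stalling-reporter
#' domain retained downstream). The P2A is the standard published 66-nt P2A
#' peptide sequence. The GFP and Cherry coding segments shipped here are
#' short SYNTHETIC stop-free stand-in open reading frames: only frame/stop
#' logic is simulated, so any stop-free in-frame sequence is equivalent;
#' replace them with full-length eGFP/mCherry CDS if a complete construct
#' map is needed. Fixed cloning-scar bases at the insert junctions are
#' absorbed into the flanking segments.
#'
#' @return Named list of DNA strings (`gfp`, `p2a`, `cherry`, `k0sr`), each a
#'   multiple of 3 nt with no in-frame stop.
#' @export
reporter_segments <- function() {
  segs <- list(
    # synthetic stand-in ORF (not eGFP)
    gfp = paste0("ATGGCTTCTAAGGGTGAAGAACTGTTCACCGGTGTTGTTCCAATCCTGGTT",
                 "GAACTGGATGGT"),
    p2a = paste0("GGAAGCGGAGCTACTAACTTCAGCCTGCTGAAGCAGGCTGGAGACGTGGAG",
                 "GAGAACCCTGGACCT"),
    # synthetic stand-in ORF (not mCherry)
    cherry = paste0("ATGGTTTCTAAGGGTGAAGAAGATAACATGGCTATCATCAAGGAATTCATG",
                    "CGTTTCAAGGTT"),
    # inert stalling-reporter domain; not part of the expression logic
    k0sr = "AAGAAGAAGAAGAAGAAGAAGAAGAAGAAG"
  )
  for (nm in c("gfp", "p2a", "cherry")) {
    stopifnot(nchar(segs[[nm]]) %% 3 == 0,
              length(find_stop_codons(segs[[nm]], 0, "+")) == 0L)
  }
  segs
}

design_failure <- function(message, report) {
  cond <- structure(class = c("fp_design_failure", "error", "condition"),
                    list(message = message, call = NULL, report = report))
  stop(cond)
}

#' @export
print.fp_reporter_insert <- function(x, ...) {
  cat(sprintf("<reporter insert> window %d-%d (%s), frame offset %d, disruption %s\n",
              x$window[1], x$window[2], x$orientation, x$frame_offset,
              x$disruption$kind))
  cat(sprintf("  pre  (%d nt): %s\n", nchar(x$pre_edit_seq), x$pre_edit_seq))
  cat(sprintf("  post (%d nt): %s\n", nchar(x$post_edit_seq), x$post_edit_seq))
  invisible(x)
}

new_reporter_insert <- function(window, frame_offset, trim3, orientation,
                                pre_seq, post_seq, disruption, peg = NULL) {
  ins <- structure(list(
    window = window, frame_offset = frame_offset, trim3 = trim3,
    orientation = orientation,
    pre_edit_seq = pre_seq, post_edit_seq = post_seq,
    disruption = disruption, peg = peg, oligos = NULL
  ), class = "fp_reporter_insert")
  ins$oligos <- emit_insert_oligos(ins)
  ins
}

# shared frame/stop feasibility test for a (pre, post) candidate pair
frame_ok <- function(pre_seq, post_seq) {
  lp <- nchar(post_seq); lr <- nchar(pre_seq)
  list(
    pre_len_ok = lr >= 45L && lr <= 100L,
    post_mod3 = lp %% 3L == 0L,
    post_stop_free = length(find_stop_codons(post_seq, 0, "+")) == 0L,
    pre_blocked = (lr %% 3L != 0L) ||
      length(find_stop_codons(pre_seq, 0, "+")) > 0L
  )
}

#' Design a reporter insert for a prime edit
#'
#' Selects a window of roughly `length_pref` nt (clamped to 45-100) around
#' the pegRNA footprint (protospacer, PAM, PBS and RTT spans), chooses a
#' frame offset and boundary trims so that the post-edit insert is in frame
#' and stop-free while the pre-edit insert is blocked by an in-frame stop or
#' a frameshift. When the genomic edit itself is not nonsense/frameshift, a
#' disruption is added inside the RTT-rewritten span (default: a 1-nt
#' frameshift insertion placed as far from the nick as possible while leaving
#' `homology_margin` nt of flap homology past it, and downstream of the PAM)
#' so that the simulated prime edit removes it.
#'
#' @param target Target sequence (top strand).
#' @param edit The [edit_spec()] the pegRNA installs.
#' @param peg An `fp_pegrna` designed for (`target`, `edit`).
#' @param length_pref Preferred insert length, default 60 nt.
#' @param disruption_kind `"added_frameshift"` (default, 1-nt insertion) or
#'   `"added_stop"` (in-frame TAA insertion), used only when the edit is not
#'   itself nonsense/frameshift.
#' @param homology_margin Flap 3' homology retained past an added disruption
#'   (nt, default 4).
#' @return An `fp_reporter_insert`; on failure a condition of class
#'   `fp_design_failure` whose `report` field enumerates the violated
#'   constraints per candidate window/frame.
#' @export
design_reporter_insert <- function(target, edit, peg, length_pref = 60L,
                                   disruption_kind = c("added_frameshift", "added_stop"),
                                   homology_margin = 4L) {
  disruption_kind <- match.arg(disruption_kind)
  s <- unclass(as_dna(target))
  validate_edit(s, edit)
  stopifnot(inherits(peg, "fp_pegrna"))
  L <- nchar(s)
  o <- peg$strand
  site <- peg$site
  SL <- nchar(peg$spacer)
  m <- nchar(site$pam)
  f <- peg$rtt_length
  delta <- peg$delta
  margin <- 5L

  # footprint in target o coords, then top coords
  n_t <- if (o == "+") peg$nick_top else L - peg$nick_top + 1L
  proto_start_t <- if (o == "+") site$protospacer_start else L - site$protospacer_start + 1L
  fp_o <- c(min(proto_start_t, n_t - peg$pbs_length + 1L),
            max(proto_start_t + SL + m - 1L, n_t + f))
  fp_top <- if (o == "+") fp_o else c(L - fp_o[2] + 1L, L - fp_o[1] + 1L)
  fp_len <- fp_top[2] - fp_top[1] + 1L
  if (fp_len + 2L * margin > 100L) {
    design_failure("pegRNA footprint exceeds the maximum 100-nt insert length",
                   data.frame(constraint = "footprint_too_long",
                              footprint_length = fp_len))
  }
  win_len <- min(100L, max(45L, as.integer(length_pref), fp_len + 2L * margin))
  center <- (proto_start_t + proto_start_t + SL - 1L) %/% 2L
  center_top <- if (o == "+") center else L - center + 1L
  ws0 <- center_top - win_len %/% 2L
  # clamp so the window plus margins covers the footprint and fits the target
  ws_lo <- max(1L, fp_top[2] + margin - win_len + 1L)
  ws_hi <- min(fp_top[1] - margin, L - win_len + 1L)
  if (ws_lo > ws_hi) {
    design_failure("target too short to host the insert window around the footprint",
                   data.frame(constraint = "window_does_not_fit",
                              footprint = sprintf("%d-%d", fp_top[1], fp_top[2]),
                              target_length = L))
  }
  ws0 <- min(max(ws0, ws_lo), ws_hi)

  report <- list()
  for (attempt in c("native", "added")) {
    for (shift in c(0L, -3L, 3L, -6L, 6L)) {
      ws <- ws0 + shift
      if (ws < ws_lo || ws > ws_hi) next
      we <- ws + win_len - 1L
      W <- substr(s, ws, we)
      edit_w <- shift_edit(edit, -(ws - 1L))
      W_post <- unclass(apply_edit(W, edit_w))
      Lw <- win_len
      off_o <- if (o == "+") ws - 1L else L - we
      n_w <- n_t - off_o
      pam_end_w <- (proto_start_t + SL + m - 1L) - off_o

      base_choices <- if (attempt == "native") {
        list(NULL)
      } else if (disruption_kind == "added_frameshift") {
        list("T", "A", "G", "C")
      } else {
        list("TAA")
      }
      # footprint in window coords (o coords of the window)
      fp_w <- fp_o - off_o

      for (bases_o in base_choices) {
        if (attempt == "native") {
          pre_full <- W
          disruption <- list(kind = if (edit_delta(edit) %% 3L != 0L)
            "native_frameshift" else "native_stop",
            position = edit_w$position, bases = "")
        } else {
          j_max <- n_w + f - delta - nchar(bases_o)
          j_min <- pam_end_w
          j_w <- max(j_min, j_max - homology_margin)
          if (j_w < j_min || j_w > j_max || j_w >= Lw) {
            report[[length(report) + 1L]] <- data.frame(
              window_start = ws, constraint = "no_room_for_disruption_in_rtt_span")
            break
          }
          j_loc <- if (o == "+") j_w else Lw - j_w
          bases_top <- if (o == "+") bases_o else rc_(bases_o)
          dis_edit <- edit_spec("insertion", j_loc, "", bases_top)
          pre_full <- unclass(apply_edit(W, dis_edit))
          disruption <- list(kind = disruption_kind,
                             position = j_loc + 1L, bases = bases_top)
        }

        for (ofs in 0:2) {
          for (t3 in 0:2) {
            pre_seq <- substr(pre_full, 1L + ofs, nchar(pre_full) - t3)
            post_seq <- substr(W_post, 1L + ofs, nchar(W_post) - t3)
            cov_lo <- if (o == "+") 1L + ofs else 1L + t3
            cov_hi_slack <- if (o == "+") t3 else ofs
            checks <- frame_ok(pre_seq, post_seq)
            checks$footprint_covered <- fp_w[1] >= cov_lo &&
              fp_w[2] <= Lw - cov_hi_slack
            if (all(unlist(checks))) {
              # the design must round-trip through the editing simulator:
              # ambiguous flap resolution (e.g. repeats at the disruption)
              # disqualifies the candidate
              sim <- tryCatch(simulate_prime_edit(pre_seq, peg),
                              error = function(e) NULL)
              if (is.null(sim) || sim$status != "edited" ||
                  unclass(sim$edited_seq) != post_seq) {
                checks$simulation_round_trip <- FALSE
              }
            }
            if (all(unlist(checks))) {
              dis <- disruption
              if (attempt == "added") dis$position <- dis$position - ofs
              return(new_reporter_insert(
                window = c(start = ws, end = we), frame_offset = ofs, trim3 = t3,
                orientation = "+", pre_seq = pre_seq, post_seq = post_seq,
                disruption = dis, peg = peg))
            }
            bad <- names(checks)[!unlist(checks)]
            report[[length(report) + 1L]] <- data.frame(
              attempt = attempt, window_start = ws, frame_offset = ofs, trim3 = t3,
              constraint = paste(bad, collapse = ";"))
          }
        }
      }
    }
  }
  rep_df <- if (length(report) > 0L) do.call(rbind, lapply(report, function(r) {
    miss <- setdiff(c("attempt", "window_start", "frame_offset", "trim3", "constraint"),
                    names(r))
    for (mi in miss) r[[mi]] <- NA
    r[c("attempt", "window_start", "frame_offset", "trim3", "constraint")]
  })) else data.frame()
  design_failure("no (window, frame, disruption) combination satisfies the reporter invariants",
                 rep_df)
}

#' Verify reporter behaviour by translation
#'
#' Builds the pre- and post-edit constructs (GFP - P2A - insert - P2A -
#' Cherry) and simulates translation as one continuous reading frame:
#' Cherry is expressed iff the insert length is a multiple of 3 and no
#' premature stop codon occurs. Ribosome skipping at P2A is not modelled;
#' only the frame/stop logic that the design rules depend on is.
#'
#' @param insert An `fp_reporter_insert`.
#' @param segments Cassette segments, see [reporter_segments()].
#' @return A list of class `fp_reporter_check` with `pre` and `post`
#'   constructs (`gfp_expressed`, `cherry_expressed`, `peptide` trace). A
#'   pre-edit construct that expresses Cherry is a design bug and raises an
#'   error rather than returning.
#' @export
verify_reporter <- function(insert, segments = reporter_segments()) {
  stopifnot(inherits(insert, "fp_reporter_insert"))
  construct <- function(ins_seq) {
    cds <- paste0(segments$gfp, segments$p2a, ins_seq, segments$p2a, segments$cherry)
    pep <- translate_frame(cds, 0, "+")
    list(gfp_expressed = TRUE,  # GFP is 5' of the insert and always intact
         cherry_expressed = (nchar(ins_seq) %% 3L == 0L) &&
           !grepl("*", pep, fixed = TRUE),
         peptide = pep)
  }
  pre <- construct(insert$pre_edit_seq)
  post <- construct(insert$post_edit_seq)
  if (pre$cherry_expressed) {
    stop("reporter invariant violated: pre-edit construct expresses Cherry (design bug)",
         call. = FALSE)
  }
  structure(list(pre = pre, post = post), class = "fp_reporter_check")
}

#' Emit SalI/Acc65I cloning oligos for a reporter insert
#'
#' The top oligo carries a 5' `TCGACC` and a 3' `G`; the bottom oligo a 5'
#' `GTACC` and a 3' `GG`, so that ligation into a SalI/Acc65I-cut vector
#' regenerates both recognition sites.
#'
#' @param insert An `fp_reporter_insert`, or a plain insert sequence.
#' @return A list of class `fp_insert_oligos` with `top` and `bottom`
#'   (5'->3') satisfying `bottom` minus its 4-nt 5' overhang ==
#'   reverse complement of `top` minus its 4-nt 5' overhang.
#' @export
emit_insert_oligos <- function(insert) {
  s <- if (inherits(insert, "fp_reporter_insert")) insert$pre_edit_seq else
    unclass(as_dna(insert))
  structure(list(top = paste0("TCGACC", s, "G"),
                 bottom = paste0("GTACC", rc_(s), "GG")),
            class = "fp_insert_oligos")
}

#' Design a base-editing reporter (six-frame stop scan)
#'
#' Scans all six reading frames (both orientations, three offsets) of a
#' window around a single-base substitution and selects a frame in which the
#' pre-edit sequence carries a stop codon covering the edited base that the
#' edit resolves, with the post-edit insert in frame and stop-free. The
#' insert is cloned in the selected orientation with the selected 5' frame
#' offset.
#'
#' @param target Target sequence (top strand).
#' @param edit Single-base substitution consistent with the profile's base
#'   conversion on either strand.
#' @param profile An [editor_profile()] with `mode = "base"`.
#' @param length_pref Preferred insert length (default 60).
#' @return An `fp_reporter_insert` (disruption kind `native_stop`); on
#'   failure an `fp_design_failure` whose `report` lists the verdict for all
#'   six frames.
#' @export
design_base_edit_reporter <- function(target, edit, profile, length_pref = 60L) {
  s <- unclass(as_dna(target))
  validate_edit(s, edit)
  if (profile$mode != "base") stop("profile must be a base editor", call. = FALSE)
  if (edit$kind != "substitution" || nchar(edit$ref) != 1L) {
    stop("base-editing reporter requires a single-base substitution", call. = FALSE)
  }
  conv <- profile$base_conversion
  on_plus <- edit$ref == conv[1] && edit$alt == conv[2]
  on_minus <- rc_(edit$ref) == conv[1] && rc_(edit$alt) == conv[2]
  if (!on_plus && !on_minus) {
    stop(sprintf("edit %s>%s is not a %s->%s conversion on either strand",
                 edit$ref, edit$alt, conv[1], conv[2]), call. = FALSE)
  }
  L <- nchar(s)
  win_len <- min(100L, max(45L, as.integer(length_pref)))
  ws <- min(max(1L, edit$position - win_len %/% 2L), max(1L, L - win_len + 1L))
  we <- ws + win_len - 1L
  if (we > L) {
    design_failure("target too short for a 45-nt insert window",
                   data.frame(constraint = "target_too_short", target_length = L))
  }
  W <- substr(s, ws, we)
  edit_w <- shift_edit(edit, -(ws - 1L))
  W_post <- unclass(apply_edit(W, edit_w))
  Lw <- win_len

  verdicts <- list()
  pick <- NULL
  for (orientation in c("+", "-")) {
    O_pre <- orient_seq(W, orientation)
    O_post <- orient_seq(W_post, orientation)
    e_o <- if (orientation == "+") edit_w$position else Lw - edit_w$position + 1L
    for (ofs in 0:2) {
      found <- FALSE
      for (t3 in 0:2) {
        if ((Lw - ofs - t3) %% 3L != 0L) next
        pre_seq <- substr(O_pre, 1L + ofs, Lw - t3)
        post_seq <- substr(O_post, 1L + ofs, Lw - t3)
        e_i <- e_o - ofs
        if (e_i < 1L || e_i > nchar(pre_seq)) next
        stops_pre <- find_stop_codons(pre_seq, 0, "+")
        covering <- stops_pre[stops_pre <= e_i & stops_pre + 2L >= e_i]
        post_clean <- length(find_stop_codons(post_seq, 0, "+")) == 0L
        len_ok <- nchar(pre_seq) >= 45L
        verdicts[[length(verdicts) + 1L]] <- data.frame(
          orientation = orientation, frame_offset = ofs,
          covering_stop = length(covering) > 0L, post_stop_free = post_clean,
          length_ok = len_ok)
        if (length(covering) > 0L && post_clean && len_ok && is.null(pick)) {
          pick <- new_reporter_insert(
            window = c(start = ws, end = we), frame_offset = ofs, trim3 = t3,
            orientation = orientation, pre_seq = pre_seq, post_seq = post_seq,
            disruption = list(kind = "native_stop", position = covering[1],
                              bases = ""))
        }
        found <- TRUE
        break
      }
      if (!found) {
        verdicts[[length(verdicts) + 1L]] <- data.frame(
          orientation = orientation, frame_offset = ofs,
          covering_stop = FALSE, post_stop_free = FALSE, length_ok = FALSE)
      }
    }
  }
  if (!is.null(pick)) return(pick)
  design_failure("no stop-resolving frame among the six reading frames",
                 do.call(rbind, verdicts))
}

#' Generate a PAM-variant panel of reporter inserts
#'
#' Enumerates every assignment of A/C/G/T to the chosen variable positions of
#' a PAM template region inside the insert (4^k variants for k variable
#' positions); all other insert bases are untouched.
#'
#' @param insert An `fp_reporter_insert`.
#' @param pam_template IUPAC string describing the PAM region.
#' @param variable_positions Integer indices (within the template) to vary.
#' @param at 1-based start of the template within `pre_edit_seq`; if `NULL`
#'   the unique IUPAC match of the template in the insert is used.
#' @return A list of `fp_reporter_insert` variants, each with a `pam` field
#'   recording the assigned PAM bases.
#' @export
pam_variant_panel <- function(insert, pam_template, variable_positions, at = NULL) {
  stopifnot(inherits(insert, "fp_reporter_insert"))
  tpl <- toupper(pam_template)
  k <- length(variable_positions)
  variable_positions <- as.integer(variable_positions)
  if (k > 0L && (min(variable_positions) < 1L || max(variable_positions) > nchar(tpl))) {
    stop("variable position outside the PAM template", call. = FALSE)
  }
  pre <- insert$pre_edit_seq; post <- insert$post_edit_seq
  if (is.null(at)) {
    hits <- integer(0)
    for (p in seq_len(nchar(pre) - nchar(tpl) + 1L)) {
      if (iupac_match(tpl, substr(pre, p, p + nchar(tpl) - 1L))) hits <- c(hits, p)
    }
    if (length(hits) == 0L) stop("PAM template not found in the insert", call. = FALSE)
    if (length(hits) > 1L) {
      stop(sprintf("PAM template matches the insert at %d positions; supply `at`",
                   length(hits)), call. = FALSE)
    }
    at <- hits
  }
  at <- as.integer(at)
  if (at < 1L || at + nchar(tpl) - 1L > nchar(pre)) {
    stop("PAM template region outside the insert", call. = FALSE)
  }
  # map to the post-edit sequence: identical coordinates require either an
  # equal-length edit or a template region within the shared 5' prefix
  if (nchar(pre) != nchar(post)) {
    both <- min(nchar(pre), nchar(post))
    pre_ch <- strsplit(substr(pre, 1, both), "")[[1]]
    post_ch <- strsplit(substr(post, 1, both), "")[[1]]
    d <- which(pre_ch != post_ch)
    first_diff <- if (length(d) == 0L) both + 1L else min(d)
    if (at + nchar(tpl) - 1L >= first_diff) {
      stop("variable PAM region overlaps the edited span; cannot map to the post-edit insert",
           call. = FALSE)
    }
  }
  if (k == 0L) {
    v <- insert; v$pam <- substr(pre, at, at + nchar(tpl) - 1L)
    return(list(v))
  }
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    v <- insert
    for (j in seq_len(k)) {
      p <- at + variable_positions[j] - 1L
      substr(v$pre_edit_seq, p, p) <- grid[i, j]
      substr(v$post_edit_seq, p, p) <- grid[i, j]
    }
    v$pam <- substr(v$pre_edit_seq, at, at + nchar(tpl) - 1L)
    v$oligos <- emit_insert_oligos(v)
    v
  })
}
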