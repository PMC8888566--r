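# Deterministic in-silico editing engines: prime editing (nick -> PBS anneal
# -> RTT flap -> flap resolution), base editing (window conversion) and
# restriction/ligation simulation. These are design verifiers with exact-match
# site recognition, not off-target or efficiency models.

new_outcome <- function(seq, status, diagnostics = list()) {
  structure(list(edited_seq = seq, status = status, diagnostics = diagnostics),
            class = "fp_outcome")
}

#' @export
print.fp_outcome <- function(x, ...) {
  cat(sprintf("<edit outcome> status: %s\n", x$status))
  invisible(x)
}

# Levenshtein distances between `flap` and every prefix tail[1..r] for
# r in 0..rmax (returns integer vector indexed r+1)
prefix_edit_distances <- function(flap, tail, rmax) {
  f <- nchar(flap)
  fc <- strsplit(flap, "")[[1]]
  tc <- strsplit(substr(tail, 1L, rmax), "")[[1]]
  prev <- 0:rmax
  for (i in seq_len(f)) {
    cur <- integer(rmax + 1L)
    cur[1] <- i
    for (r in seq_len(rmax)) {
      cost <- if (fc[i] == tc[r]) 0L else 1L
      cur[r + 1L] <- min(prev[r] + cost, prev[r + 1L] + 1L, cur[r] + 1L)
    }
    prev <- cur
  }
  prev
}

#' Simulate prime editing of a sequence by a pegRNA
#'
#' Locates the protospacer+PAM (exact spacer match plus IUPAC PAM match, on
#' either strand; multiple matches are an error), checks that the PBS is the
#' exact reverse complement of the bases 5' of the nick, and resolves the
#' RTT-encoded 3' flap against the displaced strand. Flap resolution is
#' parsimony-based: among replaced-segment lengths whose 3' end retains at
#' least `min_homology` nt of terminal homology with the flap, the length
#' minimising the edit distance between flap and displaced segment wins (ties:
#' smallest length shift, then shortest segment).
#'
#' @param seq Sequence to edit (top strand).
#' @param peg An `fp_pegrna` from [design_pegrnas()].
#' @param profile Optional [editor_profile()] supplying the nick offset; by
#'   default the offset recorded on the pegRNA at design time is used.
#' @param min_homology Minimum 3'-terminal flap homology (nt, default 1).
#' @param max_shift Largest |length difference| between flap and replaced
#'   segment considered during resolution (default 10).
#' @return An `fp_outcome`: `edited_seq`, `status` (`edited`, `no_site`,
#'   `pbs_mismatch` or `flap_mismatch`) and a per-step `diagnostics` trace.
#' @export
simulate_prime_edit <- function(seq, peg, profile = NULL,
                                min_homology = 1L, max_shift = 10L) {
  x <- unclass(as_dna(seq))
  stopifnot(inherits(peg, "fp_pegrna"))
  nick_offset <- if (is.null(profile)) {
    if (is.null(peg$nick_offset)) 3L else peg$nick_offset
  } else {
    profile$nick_offset
  }
  SL <- nchar(peg$spacer)
  L <- nchar(x)
  pat <- peg$site$pam_pattern
  m <- nchar(pat)

  hits <- list()
  for (w in c("+", "-")) {
    S_w <- orient_seq(x, w)
    starts <- gregexpr(peg$spacer, S_w, fixed = TRUE)[[1]]
    if (starts[1] != -1L) {
      for (st in starts) {
        g <- st + SL
        if (g + m - 1L > L) next
        if (iupac_match(pat, substr(S_w, g, g + m - 1L))) {
          hits[[length(hits) + 1L]] <- list(strand = w, start = st, pam_start = g)
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(new_outcome(structure(x, class = c("fp_dna", "character")), "no_site",
                       list(reason = "no exact protospacer+PAM match")))
  }
  if (length(hits) > 1L) {
    stop(sprintf("ambiguous target: %d protospacer+PAM matches", length(hits)),
         call. = FALSE)
  }
  hit <- hits[[1]]
  S_o <- orient_seq(x, hit$strand)
  n <- hit$pam_start - nick_offset - 1L
  diag <- list(strand = hit$strand, protospacer_start = hit$start, nick = n)

  pl <- peg$pbs_length
  pbs_target <- rc_(peg$pbs)
  if (n - pl + 1L < 1L || substr(S_o, n - pl + 1L, n) != pbs_target) {
    diag$pbs_ok <- FALSE
    diag$pbs_expected <- pbs_target
    diag$pbs_observed <- if (n - pl + 1L >= 1L) substr(S_o, n - pl + 1L, n) else ""
    return(new_outcome(structure(x, class = c("fp_dna", "character")),
                       "pbs_mismatch", diag))
  }
  diag$pbs_ok <- TRUE

  flap <- peg$flap
  f <- nchar(flap)
  tail_seq <- substr(S_o, n + 1L, L)
  rmax <- min(nchar(tail_seq), f + max_shift)
  rmin <- max(min_homology, f - max_shift)
  if (rmax < rmin) {
    return(new_outcome(structure(x, class = c("fp_dna", "character")),
                       "flap_mismatch", c(diag, list(reason = "no room for flap"))))
  }
  h <- as.integer(min_homology)
  # terminal homology: longest common suffix of the flap and the displaced
  # segment ending at r
  fc <- strsplit(flap, "")[[1]]
  suffix_homology <- function(r) {
    hmax <- min(f, r)
    k <- 0L
    while (k < hmax && fc[f - k] == substr(tail_seq, r - k, r - k)) k <- k + 1L
    k
  }
  ok_r <- integer(0); hom <- integer(0)
  for (r in rmin:rmax) {
    if (r < h) next
    hr <- suffix_homology(r)
    if (hr >= h) { ok_r <- c(ok_r, r); hom <- c(hom, hr) }
  }
  if (length(ok_r) == 0L) {
    return(new_outcome(structure(x, class = c("fp_dna", "character")),
                       "flap_mismatch",
                       c(diag, list(reason = "flap 3' end not homologous to displaced strand"))))
  }
  # resolution: maximal terminal homology, then minimal edit distance between
  # flap and displaced segment, then smallest length shift
  dists <- prefix_edit_distances(flap, tail_seq, rmax)
  key <- vapply(seq_along(ok_r), function(i) {
    r <- ok_r[i]
    -hom[i] * 1e9 + dists[r + 1L] * 1e6 + abs(r - f) * 1e3 + r
  }, 0)
  r <- ok_r[which.min(key)]
  diag$terminal_homology <- hom[which.min(key)]
  diag$replaced_length <- r
  diag$flap_distance <- dists[r + 1L]
  edited_o <- paste0(substr(S_o, 1L, n), flap, substr(S_o, n + r + 1L, L))
  edited <- if (hit$strand == "+") edited_o else rc_(edited_o)
  new_outcome(structure(edited, class = c("fp_dna", "character")), "edited", diag)
}

#' Simulate base editing within the editing window
#'
#' Converts every base equal to the profile's conversion source within the
#' base-editing window of the protospacer (PAM-strand coordinates, PAM-distal
#' position 1). By default a single all-converted outcome is returned; with
#' `exhaustive = TRUE`, one outcome per non-empty subset of convertible
#' positions.
#'
#' @param seq Sequence to edit (top strand).
#' @param site A site row from [find_spacer_sites()].
#' @param profile An [editor_profile()] with `mode = "base"`.
#' @param exhaustive Return per-subset products as well?
#' @return A list of `fp_outcome` objects (a single `no_site` outcome when no
#'   convertible base lies in the window).
#' @export
simulate_base_edit <- function(seq, site, profile, exhaustive = FALSE) {
  x <- unclass(as_dna(seq))
  if (profile$mode != "base") stop("profile must be a base editor", call. = FALSE)
  site <- as_site(site)
  L <- nchar(x)
  S_o <- orient_seq(x, site$strand)
  SL <- profile$spacer_length
  proto_start_o <- if (site$strand == "+") site$protospacer_start else
    L - site$protospacer_start + 1L
  win <- proto_start_o + profile$base_edit_window - 1L
  from <- profile$base_conversion[1]; to <- profile$base_conversion[2]
  pos <- win[1]:win[2]
  pos <- pos[pos >= 1L & pos <= L]
  conv <- pos[substring(S_o, pos, pos) == from]
  back <- function(s_o) {
    s_top <- if (site$strand == "+") s_o else rc_(s_o)
    structure(s_top, class = c("fp_dna", "character"))
  }
  if (length(conv) == 0L) {
    return(list(new_outcome(back(S_o), "no_site",
                            list(reason = "no convertible base in window",
                                 window = win))))
  }
  convert_at <- function(p_set) {
    ch <- strsplit(S_o, "")[[1]]
    ch[p_set] <- to
    paste(ch, collapse = "")
  }
  outcomes <- list(new_outcome(back(convert_at(conv)), "edited",
                               list(converted_positions = conv, window = win)))
  if (isTRUE(exhaustive) && length(conv) > 1L) {
    subsets <- unlist(lapply(seq_along(conv), function(k) {
      utils::combn(conv, k, simplify = FALSE)
    }), recursive = FALSE)
    subsets <- Filter(function(s) length(s) < length(conv), subsets)
    extra <- lapply(subsets, function(s) {
      new_outcome(back(convert_at(s)), "edited",
                  list(converted_positions = s, window = win))
    })
    outcomes <- c(outcomes, extra)
  }
  outcomes
}

#' Built-in restriction enzyme table
#'
#' SalI (`G^TCGAC`) and Acc65I (`G^GTACC`) as 4-nt 5'-overhang cutters, plus
#' the type IIS enzymes BsaI and BbsI used for Golden Gate assembly.
#'
#' @return Named list of enzyme definitions.
#' @export
restriction_enzymes <- function() {
  list(
    SalI = list(site = "GTCGAC", cut = 1L, overhang_len = 4L, type = "palindromic"),
    Acc65I = list(site = "GGTACC", cut = 1L, overhang_len = 4L, type = "palindromic"),
    BsaI = list(site = "GGTCTC", offset = 1L, overhang_len = 4L, type = "IIS"),
    BbsI = list(site = "GAAGAC", offset = 2L, overhang_len = 4L, type = "IIS")
  )
}

enzyme_overhang <- function(enz) substr(enz$site, enz$cut + 1L, enz$cut + enz$overhang_len)

#' Simulate ligation of an annealed duplex into a double-digested vector
#'
#' Verifies overhang complementarity at both junctions of a vector cut with
#' two enzymes and reports the reconstituted top-strand junction sequences and
#' whether each recognition site is regenerated.
#'
#' @param vector_ends Length-2 character vector of enzyme names from
#'   [restriction_enzymes()], upstream junction first (e.g.
#'   `c("SalI", "Acc65I")`).
#' @param duplex A list or character vector with elements `top` and `bottom`
#'   (5'->3' oligos with 4-nt 5' overhangs).
#' @return A list of class `fp_ligation`: per-junction `ligated`,
#'   `junction_seq`, `site_regenerated`, plus overall `ok` and a `failure`
#'   message naming the junction when ligation is impossible.
#' @export
simulate_digest_ligate <- function(vector_ends, duplex) {
  enzymes <- restriction_enzymes()
  stopifnot(length(vector_ends) == 2L, all(vector_ends %in% names(enzymes)))
  e1 <- enzymes[[vector_ends[1]]]; e2 <- enzymes[[vector_ends[2]]]
  if (!identical(e1$type, "palindromic") || !identical(e2$type, "palindromic")) {
    stop("vector ends must be palindromic-overhang enzymes; use simulate_golden_gate() for type IIS chains",
         call. = FALSE)
  }
  top <- unclass(dna(duplex[["top"]])); bottom <- unclass(dna(duplex[["bottom"]]))
  oh1 <- enzyme_overhang(e1); oh2 <- enzyme_overhang(e2)
  top_oh <- substr(top, 1L, e1$overhang_len)
  bottom_oh <- substr(bottom, 1L, e2$overhang_len)

  left_ok <- top_oh == rc_(oh1)
  right_ok <- bottom_oh == rc_(oh2)
  left_seq <- paste0(substr(e1$site, 1L, e1$cut), top)
  right_seq <- paste0(substr(top, nchar(top) - e2$cut + 1L, nchar(top)),
                      oh2, substr(e2$site, e2$cut + e2$overhang_len + 1L,
                                  nchar(e2$site)))
  res <- list(
    left = list(enzyme = vector_ends[1], ligated = left_ok,
                junction_seq = if (left_ok) substr(left_seq, 1L, nchar(e1$site)) else NA_character_,
                site_regenerated = left_ok && startsWith(left_seq, e1$site)),
    right = list(enzyme = vector_ends[2], ligated = right_ok,
                 junction_seq = if (right_ok) right_seq else NA_character_,
                 site_regenerated = right_ok && grepl(e2$site, right_seq, fixed = TRUE)),
    ok = left_ok && right_ok
  )
  if (!res$ok) {
    res$failure <- sprintf("overhang mismatch at the %s junction",
                           paste(c(if (!left_ok) vector_ends[1],
                                   if (!right_ok) vector_ends[2]),
                                 collapse = " and "))
  }
  structure(res, class = "fp_ligation")
}

#' Simulate a Golden Gate ligation chain
#'
#' Chains annealed duplexes in order by overhang identity: each duplex's
#' bottom 5' overhang must be the reverse complement of the next duplex's top
#' 5' overhang. Returns the single assembled top strand.
#'
#' @param duplexes A list of duplexes (each with `top`, `bottom`), e.g. an
#'   [emit_pegrna_oligos()] result.
#' @param overhang_len Junction overhang length (default 4).
#' @return A list: `assembled_top` (concatenated top strands, including the
#'   leading vector-junction overhang) and `insert` (assembled product with
#'   the leading overhang stripped).
#' @export
simulate_golden_gate <- function(duplexes, overhang_len = 4L) {
  stopifnot(length(duplexes) >= 1L)
  tops <- vapply(duplexes, function(d) unclass(dna(d[["top"]])), "")
  bottoms <- vapply(duplexes, function(d) unclass(dna(d[["bottom"]])), "")
  nm <- names(duplexes)
  if (is.null(nm)) nm <- paste0("duplex", seq_along(duplexes))
  if (length(duplexes) > 1L) {
    for (i in seq_len(length(duplexes) - 1L)) {
      boh <- substr(bottoms[i], 1L, overhang_len)
      toh <- substr(tops[i + 1L], 1L, overhang_len)
      if (toh != rc_(boh)) {
        stop(sprintf("ligation failure at the %s-%s junction: overhang %s does not pair with %s",
                     nm[i], nm[i + 1L], boh, toh), call. = FALSE)
      }
    }
  }
  assembled <- paste(tops, collapse = "")
  list(assembled_top = assembled,
       insert = substr(assembled, overhang_len + 1L, nchar(assembled)))
}
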