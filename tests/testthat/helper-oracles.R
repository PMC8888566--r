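# Independent oracles used by the tests. These deliberately re-derive results
# by different routes (regex scans, hand splicing, codon walks) and never call
# into the implementation paths they check.

ORACLE_IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "GC", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# plain string comparison helper: drops class and name attributes
seq_str <- function(x) {
  y <- unclass(x)
  attributes(y) <- NULL
  y
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

iupac_to_regex <- function(pat) {
  paste(vapply(strsplit(pat, "")[[1]],
               function(ch) paste0("[", ORACLE_IUPAC[[ch]], "]"), ""),
        collapse = "")
}

# brute-force site scan: tests every PAM offset in the window on both strands
# with a regex, entirely independently of find_spacer_sites()
oracle_scan <- function(target, edit, pattern, window_start = -10L,
                        window_end = 4L, spacer_len = 20L, nick_offset = 3L) {
  s <- toupper(as.character(target))
  L <- nchar(s)
  m <- nchar(pattern)
  rex <- paste0("^", iupac_to_regex(pattern), "$")
  out <- list()
  for (strand in c("+", "-")) {
    S_o <- if (strand == "+") s else oracle_revcomp(s)
    if (strand == "+") {
      a <- edit$position
    } else {
      a <- if (edit$kind == "insertion") L - edit$position else
        L - (edit$position + nchar(edit$ref) - 1L) + 1L
    }
    for (g in (a + window_start):(a + window_end)) {
      if (g - spacer_len < 1L || g + m - 1L > L) next
      if (!grepl(rex, substr(S_o, g, g + m - 1L))) next
      nick <- g - nick_offset - 1L
      nte <- if (edit$kind == "insertion") a - nick else a - nick - 1L
      if (nte < 0L) next
      out[[length(out) + 1L]] <- sprintf(
        "%s:%d", strand,
        if (strand == "+") g - spacer_len else L - (g - spacer_len) + 1L)
    }
  }
  out <- sort(unique(unlist(out)))
  if (is.null(out)) character(0) else out
}

# exhaustive stop-codon walk for one frame, by naive codon slicing
oracle_stops <- function(s, offset, strand) {
  s <- toupper(s)
  n <- nchar(s)
  w <- if (strand == "-") oracle_revcomp(s) else s
  hits <- integer(0)
  p <- 1L + offset
  while (p + 2L <= n) {
    if (substr(w, p, p + 2L) %in% c("TAA", "TAG", "TGA")) hits <- c(hits, p)
    p <- p + 3L
  }
  if (strand == "-") hits <- n - hits - 1L
  sort(hits)
}

# random DNA string (plain sample-based, no package code)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# a GC-rich target carrying one NGG site with a known geometry: returns the
# target, an edit `nick_to_edit` bases 3' of the nick, and the site row
gc_rich_case <- function(seed = 101L, nick_to_edit = 3L) {
  withr::with_seed(seed, {
    s <- paste(sample(c("G", "C", "A", "T"), 160, TRUE,
                      prob = c(0.35, 0.35, 0.15, 0.15)), collapse = "")
  })
  target <- dna(s)
  # pick a site from an SpRY scan of an arbitrary central substitution, then
  # re-anchor the edit so its nick_to_edit is as requested
  probe <- edit_spec("substitution", 80, substr(s, 80, 80),
                     setdiff(c("A", "C", "G", "T"), substr(s, 80, 80))[1])
  sites <- find_spacer_sites(target, probe, editor_profiles("SpRY-PE2"))
  site <- sites[sites$strand == "+", ][1, ]
  pos <- site$nick_position + nick_to_edit + 1L
  ref <- substr(s, pos, pos)
  edit <- edit_spec("substitution", pos, ref,
                    setdiff(c("A", "C", "G", "T"), ref)[1])
  sites2 <- find_spacer_sites(target, edit, editor_profiles("SpRY-PE2"))
  key <- sites2$strand == "+" & sites2$protospacer_start == site$protospacer_start
  list(target = target, edit = edit, site = sites2[key, ][1, ])
}

# run the full design pipeline for one seeded random target; returns NULL on
# a (legitimate) design failure, otherwise all intermediate products
run_pipeline <- function(seed, length = 200L, gc = 0.5,
                         profile = editor_profiles("SpRY-PE2")) {
  fx <- gen_random_target(seed, length, gc)
  sites <- find_spacer_sites(fx$target, fx$edit, profile)
  if (nrow(sites) == 0L) return(NULL)
  pegs <- design_pegrnas(fx$target, fx$edit, sites[1, ])
  if (length(pegs) == 0L) return(NULL)
  peg <- pegs[[1]]
  ins <- tryCatch(design_reporter_insert(fx$target, fx$edit, peg),
                  error = function(e) {
                    if (inherits(e, "fp_design_failure")) NULL else stop(e)
                  })
  if (is.null(ins)) return(NULL)
  list(fx = fx, sites = sites, peg = peg, insert = ins)
}
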