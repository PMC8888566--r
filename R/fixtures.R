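# Seeded synthetic-data generators: random targets with a valid edit, FACS
# event tables with planted populations, and amplicon read sets with planted
# class fractions. Same seed, same bytes.

# deterministically split n into count-weighted parts that sum to n
apportion <- function(n, fracs) {
  raw <- n * fracs
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0L) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  }
  as.integer(out)
}

#' Generate a random target sequence with a random valid edit
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param length Target length (>= 45).
#' @param gc_fraction Desired G+C fraction in (0, 1).
#' @param kinds Edit kinds to sample from.
#' @param max_indel Maximum insertion/deletion length (default 6).
#' @param flank Minimum distance of the edit from either end (default 40).
#' @return A list: `target` ([dna()]) and `edit` ([edit_spec()]).
#' @export
gen_random_target <- function(seed, length = 200L, gc_fraction = 0.5,
                              kinds = c("substitution", "insertion", "deletion"),
                              max_indel = 6L, flank = 40L) {
  length <- as.integer(length)
  if (length < 45L) stop("length must be >= 45", call. = FALSE)
  if (!(gc_fraction > 0 && gc_fraction < 1)) {
    stop("gc_fraction must be inside (0, 1)", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                    prob = c((1 - gc_fraction) / 2, (1 - gc_fraction) / 2,
                             gc_fraction / 2, gc_fraction / 2))
    s <- paste(bases, collapse = "")
    kind <- sample(kinds, 1L)
    lo <- min(flank, length %/% 3L)
    pos <- sample(lo:(length - lo), 1L)
    edit <- switch(kind,
      substitution = {
        ref <- substr(s, pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        edit_spec("substitution", pos, ref, alt)
      },
      insertion = {
        k <- sample(seq_len(max_indel), 1L)
        edit_spec("insertion", pos, "",
                  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                        collapse = ""))
      },
      deletion = {
        k <- sample(seq_len(max_indel), 1L)
        edit_spec("deletion", pos, substr(s, pos, pos + k - 1L), "")
      }
    )
    list(target = dna(s, name = sprintf("random_target_seed%d", as.integer(seed))),
         edit = edit)
  })
}

#' Generate a FACS event table with planted populations
#'
#' Three populations with log-normal channel intensities: untransfected
#' (both channels background), transfected-unedited (GFP high, Cherry
#' background) and transfected-edited (both high). Planted fractions and
#' analytic between-population gates are recorded in the returned `truth`.
#'
#' @param seed Integer seed.
#' @param n Number of events (>= 1).
#' @param frac_transfected Planted GFP+ fraction.
#' @param frac_edited Planted Cherry+ fraction among transfected events.
#' @param meanlog_bg,meanlog_hi Log-scale means of background and positive
#'   intensities.
#' @param sdlog Log-scale standard deviation (small = well separated).
#' @return A list: `events` (data.frame `event_id`, `gfp`, `cherry`) and
#'   `truth` (planted counts/fractions plus `gfp_gate`, `cherry_gate`).
#' @export
gen_facs_events <- function(seed, n = 10000L, frac_transfected = 0.6,
                            frac_edited = 0.25, meanlog_bg = log(50),
                            meanlog_hi = log(5000), sdlog = 0.25) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  stopifnot(frac_transfected >= 0, frac_transfected <= 1,
            frac_edited >= 0, frac_edited <= 1)
  withr::with_seed(as.integer(seed), {
    n_trans <- apportion(n, c(frac_transfected, 1 - frac_transfected))[1]
    n_edit <- apportion(n_trans, c(frac_edited, 1 - frac_edited))[1]
    n_unt <- n - n_trans
    pop <- c(rep("untransfected", n_unt),
             rep("transfected_unedited", n_trans - n_edit),
             rep("transfected_edited", n_edit))
    gfp <- stats::rlnorm(n, ifelse(pop == "untransfected", meanlog_bg, meanlog_hi),
                         sdlog)
    cherry <- stats::rlnorm(n, ifelse(pop == "transfected_edited", meanlog_hi,
                                      meanlog_bg), sdlog)
    events <- data.frame(event_id = seq_len(n), gfp = gfp, cherry = cherry)
    # shuffle so population order carries no information
    events <- events[sample.int(n), , drop = FALSE]
    events$event_id <- seq_len(n)
    rownames(events) <- NULL
    truth <- list(
      n = n, n_transfected = n_trans, n_edited = n_edit,
      frac_gfp_pos = n_trans / n,
      frac_gfp_cherry_pos = n_edit / n,
      frac_cherry_given_gfp = if (n_trans == 0L) NA_real_ else n_edit / n_trans,
      gfp_gate = exp((meanlog_bg + meanlog_hi) / 2),
      cherry_gate = exp((meanlog_bg + meanlog_hi) / 2),
      meanlog_bg = meanlog_bg, meanlog_hi = meanlog_hi, sdlog = sdlog
    )
    list(events = events, truth = truth)
  })
}

#' Generate amplicon reads with planted class fractions
#'
#' Reads are drawn from the edited amplicon, 1-3 bp indel alleles at the
#' nick, scrambled "other" alleles and the unedited amplicon, at planted
#' fractions (deterministically apportioned so planted counts are exact).
#' An optional uniform per-base substitution error is applied afterwards.
#'
#' @param wt_amplicon,edited_amplicon Reference amplicons.
#' @param seed Integer seed.
#' @param n Number of reads (>= 1).
#' @param frac_edited,frac_indel,frac_other Planted fractions (sum <= 1; the
#'   remainder is unedited).
#' @param nick_position Nick coordinate on the wt amplicon.
#' @param error_rate Per-base substitution error probability (default 0).
#' @param max_indel Largest planted indel (default 3).
#' @return A list: `reads` (character vector) and `truth` (exact planted
#'   counts per class).
#' @export
gen_amplicon_reads <- function(wt_amplicon, edited_amplicon, seed, n = 1000L,
                               frac_edited = 0.3, frac_indel = 0.1,
                               frac_other = 0, nick_position,
                               error_rate = 0, max_indel = 3L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (frac_edited + frac_indel + frac_other > 1 + 1e-12) {
    stop("planted fractions must sum to at most 1", call. = FALSE)
  }
  wt <- unclass(as_dna(wt_amplicon)); ed <- unclass(as_dna(edited_amplicon))
  nick <- as.integer(nick_position)
  stopifnot(nick >= 1L, nick < nchar(wt))
  withr::with_seed(as.integer(seed), {
    counts <- apportion(n, c(frac_edited, frac_indel, frac_other,
                             1 - frac_edited - frac_indel - frac_other))
    names(counts) <- c("edited", "indel", "other", "unedited")
    indel_reads <- vapply(seq_len(counts["indel"]), function(i) {
      k <- sample.int(max_indel, 1L)
      if (stats::runif(1) < 0.5) {
        paste0(substr(wt, 1L, nick), substr(wt, nick + k + 1L, nchar(wt)))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
        paste0(substr(wt, 1L, nick), ins, substr(wt, nick + 1L, nchar(wt)))
      }
    }, "")
    other_reads <- vapply(seq_len(counts["other"]), function(i) {
      ch <- strsplit(wt, "")[[1]]
      pos <- sample.int(nchar(wt), 5L)
      ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      paste(ch, collapse = "")
    }, "")
    reads <- c(rep(ed, counts["edited"]), indel_reads, other_reads,
               rep(wt, counts["unedited"]))
    if (error_rate > 0) {
      reads <- vapply(reads, function(rd) {
        ch <- strsplit(rd, "")[[1]]
        hit <- which(stats::runif(length(ch)) < error_rate)
        if (length(hit) > 0L) {
          ch[hit] <- vapply(ch[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, "")
        }
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    reads <- reads[sample.int(length(reads))]
    names(reads) <- sprintf("read_%06d", seq_along(reads))
    list(reads = reads, truth = as.list(counts))
  })
}

#' Write reads to an uncompressed FASTQ file
#'
#' @param reads Named character vector of reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  nm <- names(reads)
  if (is.null(nm)) nm <- sprintf("read_%06d", seq_along(reads))
  qual <- vapply(nchar(reads), function(k) strrep("I", k), "")
  writeLines(paste0("@", nm, "\n", reads, "\n+\n", qual), path)
  invisible(path)
}
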