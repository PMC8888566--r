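test_that("candidate enumeration matches an independent filter count on a GC-rich toy", {
  cs <- gc_rich_case(nick_to_edit = 3L)
  pegs <- design_pegrnas(cs$target, cs$edit, cs$site)
  # independent enumeration: recompute the PBS G/C filter and RTT coverage
  # bound by hand from the raw sequence
  L <- nchar(cs$target)
  n <- cs$site$nick_position
  s <- as.character(cs$target)
  pbs_ok <- vapply(9:15, function(pl) {
    win <- substr(s, n - pl + 1, n)
    nchar(gsub("[AT]", "", win)) >= 5
  }, NA)
  min_rtt_needed <- (cs$edit$position + 1 + 1) - n - 1   # alt end + 1 homologous
  rtt_count <- length(max(10, min_rtt_needed):20)
  expect_equal(length(pegs), sum(pbs_ok) * rtt_count)
  tab <- pegrna_table(pegs)
  expect_true(all(tab$pbs_length >= 9 & tab$pbs_length <= 15))
  expect_true(all(tab$pbs_gc >= 5))
  expect_true(all(tab$rtt_length >= 10 & tab$rtt_length <= 20))
  # top-ranked candidate follows the documented heuristic
  expect_equal(tab$pbs_length[1], 12L)
})

test_that("an A/T-only PBS window yields no candidates with a G/C reason", {
  s <- paste0(strrep("AT", 25), "GGGG", strrep("AT", 25))  # GGGG at 51-54
  # protospacer ends at 51, PAM GGG at 52: nick at 48, PBS window all A/T
  edit <- edit_spec("substitution", 53, "G", "C")
  sites <- find_spacer_sites(s, edit, editor_profiles("PE2"), scan_config(-3, 0))
  site <- sites[sites$strand == "+", ][1, ]
  pegs <- design_pegrnas(s, edit, site)
  expect_length(pegs, 0L)
  expect_true("pbs_gc_below_min" %in% attr(pegs, "reasons"))
})

test_that("an edit beyond the RTT range yields no candidates with a geometry reason", {
  cs <- gc_rich_case(nick_to_edit = 3L)
  s <- as.character(cs$target)
  n <- cs$site$nick_position
  pos <- n + 26L   # nick_to_edit = 25 > rtt_max = 20
  ref <- substr(s, pos, pos)
  edit <- edit_spec("substitution", pos, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
  site <- find_spacer_sites(s, edit, editor_profiles("SpRY-PE2"),
                            scan_config(-26, -20))
  site <- site[site$strand == "+" &
                 site$protospacer_start == cs$site$protospacer_start, ]
  skip_if(nrow(site) == 0L)
  pegs <- design_pegrnas(s, edit, site[1, ])
  expect_length(pegs, 0L)
  expect_true("edit_not_reachable_by_rtt" %in% attr(pegs, "reasons"))
})

test_that("emitted candidates satisfy the constraints and PBS identity", {
  withr::with_seed(31, {
    checked <- 0L
    for (i in 1:40) {
      out <- run_pipeline(sample.int(1e6, 1))
      if (is.null(out)) next
      pegs <- design_pegrnas(out$fx$target, out$fx$edit, out$sites[1, ])
      L <- nchar(out$fx$target)
      for (p in pegs[seq_len(min(5, length(pegs)))]) {
        expect_gte(p$pbs_gc, 5L)
        expect_true(p$pbs_length >= 9L && p$pbs_length <= 15L)
        expect_true(p$rtt_length >= 10L && p$rtt_length <= 20L)
        expect_equal(p$extension, paste0(p$rtt, p$pbs))
        expect_equal(p$pbs_gc, nchar(gsub("[AT]", "", p$pbs)))
        # reverse complement of the PBS is a suffix of the PAM-strand
        # sequence ending at the nick
        S_o <- if (p$strand == "+") as.character(out$fx$target) else
          oracle_revcomp(as.character(out$fx$target))
        n <- if (p$strand == "+") p$nick_top else L - p$nick_top + 1L
        expect_equal(oracle_revcomp(p$pbs), substr(S_o, n - p$pbs_length + 1L, n))
        # the flap carries the full alt allele and is RTT-revcomp
        expect_equal(p$flap, oracle_revcomp(p$rtt))
        checked <- checked + 1L
      }
    }
    expect_gt(checked, 50L)
  })
})

test_that("RTT mismatch counts follow intended + silent changes", {
  cs <- gc_rich_case(nick_to_edit = 3L)
  pegs <- design_pegrnas(cs$target, cs$edit, cs$site)
  peg <- pegs[[1]]
  # the intended single substitution is the only difference
  expect_equal(rtt_mismatch_count(peg, cs$target), 1L)
  # two extra silent substitutions in the flap
  peg2 <- peg
  flap <- strsplit(peg2$flap, "")[[1]]
  idx <- c(peg$rtt_length - 1L, peg$rtt_length)
  flap[idx] <- vapply(flap[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  peg2$flap <- paste(flap, collapse = "")
  peg2$rtt <- oracle_revcomp(peg2$flap)
  expect_equal(rtt_mismatch_count(peg2, cs$target), 3L)
  # a no-op pegRNA whose flap equals the unedited sequence
  peg0 <- peg
  s <- as.character(cs$target)
  S_o <- if (peg$strand == "+") s else oracle_revcomp(s)
  n <- if (peg$strand == "+") peg$nick_top else nchar(s) - peg$nick_top + 1L
  peg0$flap <- substr(S_o, n + 1L, n + peg0$rtt_length)
  peg0$rtt <- oracle_revcomp(peg0$flap)
  peg0$delta <- 0L
  expect_equal(rtt_mismatch_count(peg0, cs$target), 0L)
})

test_that("RTT mismatch counting scores indels as length difference", {
  withr::with_seed(32, {
    done <- FALSE
    for (i in 1:50) {
      fx <- gen_random_target(sample.int(1e6, 1), 200, 0.5, kinds = "deletion")
      sites <- find_spacer_sites(fx$target, fx$edit, editor_profiles("SpRY-PE2"))
      if (nrow(sites) == 0) next
      pegs <- design_pegrnas(fx$target, fx$edit, sites[1, ])
      if (length(pegs) == 0) next
      expect_equal(rtt_mismatch_count(pegs[[1]], fx$target), nchar(fx$edit$ref))
      done <- TRUE
      if (done) break
    }
    expect_true(done)
  })
})

test_that("nicking guides nick the opposite strand and flag PE3b correctly", {
  withr::with_seed(33, {
    n_guides <- 0L; n_pe3b <- 0L
    for (i in 1:25) {
      out <- run_pipeline(sample.int(1e6, 1))
      if (is.null(out)) next
      peg <- out$peg
      guides <- design_nicking_guides(out$fx$target, out$fx$edit, peg,
                                      editor_profiles("SpRY-PE2"))
      if (nrow(guides) == 0) next
      expect_true(all(guides$strand != peg$strand))
      expect_true(all(abs(guides$offset_from_peg_nick) <= 100))
      post <- as.character(apply_edit(out$fx$target, out$fx$edit))
      pre <- as.character(out$fx$target)
      pre_oo <- if (unique(guides$strand) == "+") pre else oracle_revcomp(pre)
      # validator: a PE3b spacer must never occur in the pre-edit sequence
      for (j in seq_len(nrow(guides))) {
        hit_pre <- grepl(guides$spacer[j], pre_oo, fixed = TRUE)
        if (guides$pe3b[j]) expect_false(hit_pre)
      }
      n_guides <- n_guides + nrow(guides)
      n_pe3b <- n_pe3b + sum(guides$pe3b)
    }
    expect_gt(n_guides, 50L)
    expect_gt(n_pe3b, 0L)
  })
})

test_that("a guide footprint away from the edit is PE3, not PE3b", {
  # construct: poly-T with a planted minus-strand site far from the edit
  s <- strrep("T", 200)
  substr(s, 120, 122) <- "CCA"       # bottom-strand PAM (TGG on rc)
  substr(s, 60, 62) <- "TGG"         # plus-strand PAM for the pegRNA
  substr(s, 45, 52) <- "GCGCGCGC"    # G/C for the PBS
  edit <- edit_spec("substitution", 59, "T", "A")
  sites <- find_spacer_sites(s, edit, editor_profiles("PE2"))
  site <- sites[sites$strand == "+", ][1, ]
  pegs <- design_pegrnas(s, edit, site,
                         design_constraints(pbs_min_gc = 4))
  skip_if(length(pegs) == 0L)
  guides <- design_nicking_guides(s, edit, pegs[[1]], editor_profiles("PE2"))
  far <- guides[abs(guides$offset_from_peg_nick) > 25, ]
  expect_gt(nrow(far), 0L)
  expect_false(any(far$pe3b))
})

test_that("pegRNA Golden Gate duplexes chain back into spacer+scaffold+extension", {
  cs <- gc_rich_case()
  peg <- design_pegrnas(cs$target, cs$edit, cs$site)[[1]]
  oligos <- emit_pegrna_oligos(peg)
  expect_length(oligos, 3L)
  for (d in oligos) {
    core_top <- substr(d$top, 5L, nchar(d$top))
    core_bottom <- substr(d$bottom, 5L, nchar(d$bottom))
    expect_equal(core_bottom, oracle_revcomp(core_top))
  }
  gg <- simulate_golden_gate(oligos)
  expect_equal(gg$insert, paste0(peg$spacer, peg$scaffold, peg$extension))
  # epegRNA: the 3' motif rides on the extension duplex
  pegs_e <- design_pegrnas(cs$target, cs$edit, cs$site, epeg = TRUE)
  gge <- simulate_golden_gate(emit_pegrna_oligos(pegs_e[[1]]))
  expect_equal(gge$insert, paste0(pegs_e[[1]]$spacer, pegs_e[[1]]$scaffold,
                                  pegs_e[[1]]$extension, pegs_e[[1]]$epeg_motif))
})

test_that("duplicate junction overhangs in the acceptor are rejected", {
  cs <- gc_rich_case()
  peg <- design_pegrnas(cs$target, cs$edit, cs$site)[[1]]
  clash <- pegrna_acceptor(vector_overhang_top = substr(peg$scaffold, 1, 4))
  expect_error(emit_pegrna_oligos(peg, clash), "overhang collision")
})
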