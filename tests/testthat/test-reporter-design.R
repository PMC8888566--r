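test_that("a nonsense-correcting edit uses the native stop as disruption", {
  # plant a premature TAG whose G is removed by the edit (TAG -> TAC)
  withr::with_seed(41, {
    done <- FALSE
    for (tries in 1:40) {
      s <- rand_dna(200)
      pos <- 100L
      substr(s, pos, pos + 2L) <- "TAG"
      edit <- edit_spec("substitution", pos + 2L, "G", "C")
      sites <- find_spacer_sites(s, edit, editor_profiles("SpRY-PE2"))
      if (nrow(sites) == 0) next
      pegs <- design_pegrnas(s, edit, sites[1, ])
      if (length(pegs) == 0) next
      ins <- tryCatch(design_reporter_insert(s, edit, pegs[[1]]),
                      error = function(e) NULL)
      if (is.null(ins)) next
      if (ins$disruption$kind != "native_stop") next
      expect_true(grepl("*", translate_frame(ins$pre_edit_seq, 0, "+"), fixed = TRUE))
      expect_false(grepl("*", translate_frame(ins$post_edit_seq, 0, "+"), fixed = TRUE))
      expect_equal(nchar(ins$pre_edit_seq), nchar(ins$post_edit_seq))
      done <- TRUE
      break
    }
    expect_true(done)
  })
})

test_that("a substitution with no native stop gets a 1-nt frameshift in the RTT span", {
  withr::with_seed(42, {
    checked <- 0L
    for (i in 1:40) {
      out <- run_pipeline(sample.int(1e6, 1))
      if (is.null(out)) next
      ins <- out$insert
      if (ins$disruption$kind != "added_frameshift") next
      expect_equal(nchar(ins$disruption$bases), 1L)
      expect_equal(nchar(ins$pre_edit_seq) %% 3L, 1L)
      expect_equal(nchar(ins$post_edit_seq) %% 3L, 0L)
      # the disruption is removed by the simulated edit
      sim <- simulate_prime_edit(ins$pre_edit_seq, out$peg)
      expect_equal(sim$status, "edited")
      expect_equal(unclass(sim$edited_seq), ins$post_edit_seq)
      checked <- checked + 1L
    }
    expect_gt(checked, 5L)
  })
})

test_that("reporter insert invariants hold across random designs", {
  withr::with_seed(43, {
    for (i in 1:30) {
      out <- run_pipeline(sample.int(1e6, 1))
      if (is.null(out)) next
      ins <- out$insert
      lr <- nchar(ins$pre_edit_seq)
      expect_true(lr >= 45L && lr <= 100L)
      expect_equal(nchar(ins$post_edit_seq) %% 3L, 0L)
      expect_length(find_stop_codons(ins$post_edit_seq, 0, "+"), 0L)
      expect_true(lr %% 3L != 0L ||
                    length(find_stop_codons(ins$pre_edit_seq, 0, "+")) > 0L)
      # the insert must contain the full protospacer and PBS footprint
      o_seq <- if (out$peg$strand == "+") ins$pre_edit_seq else
        oracle_revcomp(ins$pre_edit_seq)
      expect_true(grepl(out$peg$spacer, o_seq, fixed = TRUE))
      expect_true(grepl(oracle_revcomp(out$peg$pbs), o_seq, fixed = TRUE))
    }
  })
})

test_that("a stop-saturated context forces a design-failure report", {
  # TAA repeats in every frame around the footprint leave no stop-free
  # post-edit window in any frame
  s <- paste0(strrep("TAA", 25), "GCGCGCGCGCTGGCGCGC", strrep("TAA", 25))
  # protospacer ends inside the G/C island, PAM TGG at 86-88
  ref <- substr(s, 90, 90)
  edit <- edit_spec("substitution", 90, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
  err <- tryCatch({
    sites <- find_spacer_sites(s, edit, editor_profiles("SpRY-PE2"))
    pegs <- design_pegrnas(s, edit, sites[1, ])
    design_reporter_insert(s, edit, pegs[[1]])
  }, error = function(e) e)
  expect_s3_class(err, "fp_design_failure")
  expect_true(nrow(err$report) > 0L)
  expect_true(any(grepl("post_stop_free", err$report$constraint)))
})

test_that("verify_reporter flags expression states and rejects broken designs", {
  withr::with_seed(44, {
    out <- NULL
    while (is.null(out)) out <- run_pipeline(sample.int(1e6, 1))
    chk <- verify_reporter(out$insert)
    expect_true(chk$pre$gfp_expressed)
    expect_false(chk$pre$cherry_expressed)
    expect_true(chk$post$cherry_expressed)
    # removing the disruption by hand makes the pre-edit construct fluoresce:
    # that is a hard invariant violation, raised not returned
    broken <- out$insert
    broken$pre_edit_seq <- broken$post_edit_seq
    expect_error(verify_reporter(broken), "expresses Cherry")
  })
})

test_that("insert oligos carry the SalI/Acc65I flanks and anneal", {
  ol <- emit_insert_oligos("ATGAAA")
  expect_equal(ol$top, "TCGACCATGAAAG")
  expect_equal(ol$bottom, "GTACCTTTCATGG")
  expect_equal(substr(ol$bottom, 5, nchar(ol$bottom)),
               oracle_revcomp(substr(ol$top, 5, nchar(ol$top))))
  lig <- simulate_digest_ligate(c("SalI", "Acc65I"), ol)
  expect_true(lig$ok)
  expect_equal(lig$left$junction_seq, "GTCGAC")
  expect_true(lig$left$site_regenerated)
  expect_equal(lig$right$junction_seq, "GGTACC")
  expect_true(lig$right$site_regenerated)
})

test_that("base-edit reporter picks a stop-resolving frame among six", {
  withr::with_seed(45, {
    abe <- editor_profiles("ABE8e")
    done <- FALSE
    for (tries in 1:30) {
      s <- rand_dna(120)
      substr(s, 60, 62) <- "TAG"
      # A->G at the stop's A resolves TAG -> TGG
      edit <- edit_spec("substitution", 61, "A", "G")
      ins <- tryCatch(design_base_edit_reporter(s, edit, abe),
                      error = function(e) NULL)
      if (is.null(ins)) next
      expect_equal(ins$disruption$kind, "native_stop")
      stops <- find_stop_codons(ins$pre_edit_seq, 0, "+")
      expect_gt(length(stops), 0L)
      expect_length(find_stop_codons(ins$post_edit_seq, 0, "+"), 0L)
      expect_equal(nchar(ins$post_edit_seq) %% 3L, 0L)
      chk <- verify_reporter(ins)
      expect_false(chk$pre$cherry_expressed)
      expect_true(chk$post$cherry_expressed)
      done <- TRUE
      break
    }
    expect_true(done)
  })
})

test_that("base-edit reporter honours the strand of the conversion", {
  abe <- editor_profiles("ABE8e")
  # T->C on the top strand is A->G on the bottom strand
  s <- strrep("GC", 60)
  ok <- tryCatch({
    design_base_edit_reporter(s, edit_spec("substitution", 60, "C", "T"), abe)
    TRUE
  }, error = function(e) !grepl("conversion on either strand", conditionMessage(e)))
  expect_false(ok)  # C->T matches neither A->G nor T->C
})

test_that("an edit resolving no stop in any frame reports six verdicts", {
  abe <- editor_profiles("ABE8e")
  # GC-alternating background forms no stop codon anywhere; the single A->G
  # edit cannot resolve one
  s <- strrep("GC", 60)
  substr(s, 59, 59) <- "A"
  edit <- edit_spec("substitution", 59, "A", "G")
  err <- tryCatch(design_base_edit_reporter(s, edit, abe), error = function(e) e)
  expect_s3_class(err, "fp_design_failure")
  expect_equal(nrow(err$report), 6L)
  expect_false(any(err$report$covering_stop))
})

test_that("PAM variant panels enumerate 4^k distinct inserts", {
  withr::with_seed(46, {
    out <- NULL
    while (is.null(out)) out <- run_pipeline(sample.int(1e6, 1))
    ins <- out$insert
    p16 <- pam_variant_panel(ins, "NGNN", c(2, 4), at = 3)
    expect_length(p16, 16L)
    expect_length(unique(vapply(p16, function(v) v$pre_edit_seq, "")), 16L)
    p64 <- pam_variant_panel(ins, "NNNN", c(1, 2, 3), at = 3)
    expect_length(p64, 64L)
    expect_length(unique(vapply(p64, function(v) v$pre_edit_seq, "")), 64L)
    p1 <- pam_variant_panel(ins, "NNNN", integer(0), at = 3)
    expect_length(p1, 1L)
    expect_equal(p1[[1]]$pre_edit_seq, ins$pre_edit_seq)
    expect_error(pam_variant_panel(ins, "NGNN", c(2, 5), at = 3),
                 "outside the PAM template")
    # oligos track the varied sequence
    expect_equal(p16[[2]]$oligos$top, paste0("TCGACC", p16[[2]]$pre_edit_seq, "G"))
  })
})
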