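test_that("a single planted NGG site is found with the right geometry", {
  # poly-A background has no G anywhere, so the planted TGG is the only PAM
  s <- strrep("A", 120)
  substr(s, 62, 64) <- "TGG"
  edit <- edit_spec("substitution", 60, "A", "C")
  sites <- find_spacer_sites(s, edit, editor_profiles("PE2"))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$pam, "TGG")
  expect_equal(sites$pam_offset, 2L)           # PAM 5' base at edit + 2
  expect_equal(sites$protospacer_start, 42L)   # 20-nt spacer ends at 61
  expect_equal(sites$nick_position, 58L)       # 3 nt 5' of the PAM
  expect_equal(sites$nick_to_edit, 1L)
})

test_that("a PAM-less editor yields one site per in-window offset and strand", {
  s <- strrep("A", 140)
  edit <- edit_spec("substitution", 70, "A", "C")
  sites <- find_spacer_sites(s, edit, editor_profiles("SpRY-PE2"))
  # every offset in -10..+4 matches NNN, but nick_to_edit = 3 - offset, so
  # offsets +4 (nte = -1) drop out: 14 sites per strand remain
  expect_equal(sum(sites$strand == "+"), 14L)
  expect_equal(sum(sites$strand == "-"), 14L)
  expect_true(all(sites$nick_to_edit >= 0L))
  expect_setequal(sites$pam_offset, -10:3)
})

test_that("sites 5' of every candidate nick are filtered out", {
  # edit immediately 3' of the only PAM: nick_to_edit < 0 for that site
  s <- strrep("A", 120)
  substr(s, 40, 42) <- "TGG"  # nick would sit at 36
  edit <- edit_spec("substitution", 33, "A", "C")  # 5' of the nick
  cfg <- scan_config(0, 15)   # window catching the PAM at offset +7
  sites <- find_spacer_sites(s, edit, editor_profiles("PE2"), cfg)
  expect_equal(nrow(sites), 0L)
})

test_that("scanner agrees with the brute-force regex oracle", {
  withr::with_seed(21, {
    for (i in 1:30) {
      fx <- gen_random_target(sample.int(1e6, 1), sample(100:200, 1), runif(1, 0.3, 0.7))
      for (pat in c("NGG", "NG", "NGN", "NAN", "NNN")) {
        prof <- editor_profile("x", pat)
        got <- find_spacer_sites(fx$target, fx$edit, prof)
        keys <- sort(sprintf("%s:%d", got$strand, got$protospacer_start))
        expect_identical(keys, oracle_scan(fx$target, fx$edit, pat),
                         info = sprintf("seq %d pattern %s", i, pat))
      }
    }
  })
})

test_that("widening the window or adding patterns never removes sites", {
  withr::with_seed(22, {
    for (i in 1:10) {
      fx <- gen_random_target(sample.int(1e6, 1), 200, 0.5)
      prof <- editor_profiles("PE2")
      narrow <- find_spacer_sites(fx$target, fx$edit, prof, scan_config(-6, 2))
      wide <- find_spacer_sites(fx$target, fx$edit, prof, scan_config(-10, 4))
      keyn <- sprintf("%s:%d", narrow$strand, narrow$protospacer_start)
      keyw <- sprintf("%s:%d", wide$strand, wide$protospacer_start)
      expect_true(all(keyn %in% keyw))
      one <- find_spacer_sites(fx$target, fx$edit, prof,
                               scan_config(patterns = "NGG"))
      two <- find_spacer_sites(fx$target, fx$edit, prof,
                               scan_config(patterns = c("NGG", "NGN")))
      expect_true(all(sprintf("%s:%d", one$strand, one$protospacer_start) %in%
                        sprintf("%s:%d", two$strand, two$protospacer_start)))
    }
  })
})

test_that("scanning the reverse complement with the mirrored edit swaps strands", {
  withr::with_seed(23, {
    for (i in 1:10) {
      fx <- gen_random_target(sample.int(1e6, 1), 160, 0.5)
      prof <- editor_profiles("PE2")
      L <- nchar(fx$target)
      rc <- reverse_complement(fx$target)
      edit <- fx$edit
      mirrored <- if (edit$kind == "insertion") {
        edit_spec("insertion", L - edit$position, "", oracle_revcomp(edit$alt))
      } else {
        edit_spec(edit$kind, L - (edit$position + nchar(edit$ref) - 1L) + 1L,
                  oracle_revcomp(edit$ref),
                  if (nchar(edit$alt)) oracle_revcomp(edit$alt) else "")
      }
      a <- find_spacer_sites(fx$target, edit, prof)
      b <- find_spacer_sites(rc, mirrored, prof)
      flip <- function(df) sort(sprintf("%s:%s", ifelse(df$strand == "+", "-", "+"),
                                        df$spacer))
      expect_identical(sort(sprintf("%s:%s", a$strand, a$spacer)), flip(b))
    }
  })
})

test_that("a site matching several patterns is reported once, first pattern wins", {
  s <- strrep("A", 120)
  substr(s, 62, 64) <- "TGG"   # matches both NGG and NGN (and GGA matches NGN)
  edit <- edit_spec("substitution", 60, "A", "C")
  prof <- editor_profile("x", c("NGG", "NGN"))
  sites <- find_spacer_sites(s, edit, prof)
  key <- paste(sites$strand, sites$protospacer_start)
  expect_false(any(duplicated(key)))
  expect_equal(sites$pam_pattern[sites$pam_offset == 2L], "NGG")
})

test_that("short flanks raise an explicit boundary error", {
  expect_error(
    find_spacer_sites(strrep("A", 40), edit_spec("substitution", 20, "A", "C"),
                      editor_profiles("PE2")),
    "target too short")
})

test_that("variant tables are counted per pattern with a deduplicated total", {
  # counts fixed by construction: a poly-T background (scanned top strand
  # only) matches none of NGG/NAN/NGN, so only planted bases form PAMs
  mk <- function(plant) {
    s <- strrep("T", 130)
    for (p in plant) substr(s, p[[1]], p[[1]] + nchar(p[[2]]) - 1L) <- p[[2]]
    s
  }
  # edit at 65; window -10..+4 anchors the PAM 5' base at 55..69
  tab <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    flank = c(mk(list(list(60L, "GG"))),    # TGG at 59 (NGG+NGN), GGT at 60 (NGN)
              mk(list(list(58L, "A"), list(66L, "A"))),  # TAT at 57 and 65 (NAN)
              mk(list())),                               # nothing
    edit_pos = 65L, kind = "substitution", ref = "T", alt = "C",
    stringsAsFactors = FALSE)
  cfg <- scan_config(patterns = c("NGG", "NAN", "NGN"), both_strands = FALSE)
  res <- scan_variant_table(tab, cfg)
  expect_equal(res$results$NGG, c(1L, 0L, 0L))
  expect_equal(res$results$NAN, c(0L, 2L, 0L))
  expect_equal(res$results$NGN, c(2L, 0L, 0L))
  expect_equal(res$results$total, c(2L, 2L, 0L))  # NGG/NGN overlap deduplicated
  expect_equal(res$summary$per_pattern$mean[1], 1 / 3)
  expect_equal(res$n_errors, 0L)
})

test_that("empty and malformed variant rows are handled", {
  empty <- scan_variant_table(
    data.frame(variant_id = character(0), flank = character(0),
               edit_pos = integer(0), kind = character(0), ref = character(0),
               alt = character(0)),
    scan_config(patterns = "NGG"))
  expect_equal(nrow(empty$results), 0L)
  expect_true(is.na(empty$summary$mean_total))

  bad <- data.frame(variant_id = c("ok", "bad_ref", "too_short"),
                    flank = c(strrep("A", 130), strrep("A", 130), "ACGTACGT"),
                    edit_pos = c(65L, 65L, 2L), kind = "substitution",
                    ref = c("A", "G", "C"), alt = c("C", "C", "G"),
                    stringsAsFactors = FALSE)
  expect_warning(expect_warning(
    res <- scan_variant_table(bad, scan_config(patterns = "NGG")),
    "skipped"), "skipped")
  expect_equal(res$n_errors, 2L)
  expect_equal(res$results$variant_id, "ok")
})

test_that("summary mean equals an independently computed mean of totals", {
  withr::with_seed(24, {
    rows <- lapply(1:25, function(i) {
      fx <- gen_random_target(sample.int(1e6, 1), 140, 0.5,
                              kinds = "substitution")
      e <- fx$edit
      data.frame(variant_id = paste0("v", i), flank = unclass(fx$target),
                 edit_pos = e$position, kind = e$kind, ref = e$ref, alt = e$alt,
                 stringsAsFactors = FALSE)
    })
  })
  tab <- do.call(rbind, rows)
  res <- scan_variant_table(tab, scan_config(patterns = c("NGG", "NAN")))
  expect_equal(res$summary$mean_total, mean(res$results$total))
  expect_equal(unname(res$summary$per_pattern$mean),
               c(mean(res$results$NGG), mean(res$results$NAN)))
})
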