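test_that("single-mismatch detection reports position, bases, and seed flag", {
  mature <- c("mir-a" = "CCGTAGGCTAACGTTGACCTGG")  # A at position 5
  tag5 <- mature
  substr(tag5, 5, 5) <- "G"
  tags <- data.frame(sequence = unname(tag5), count = 7L,
                     stringsAsFactors = FALSE)
  ev <- detect_edits(tags, mature)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mirna, "mir-a")
  expect_equal(ev$position, 5L)
  expect_equal(ev$ref, "A")
  expect_equal(ev$obs, "G")
  expect_true(ev$in_seed)
  expect_equal(ev$count, 7L)

  # exact wild-type tags and two-mismatch tags yield nothing
  two <- unname(tag5); substr(two, 12, 12) <- "A"
  none <- detect_edits(data.frame(sequence = c(unname(mature), two),
                                  count = 1L, stringsAsFactors = FALSE),
                       mature)
  expect_equal(nrow(none), 0L)

  # seed boundary: positions 1 and 9 are outside, 2 and 8 inside
  for (pos in c(1, 2, 8, 9)) {
    tg <- unname(mature)
    old <- substr(tg, pos, pos)
    substr(tg, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    evp <- detect_edits(data.frame(sequence = tg, count = 1L,
                                   stringsAsFactors = FALSE), mature)
    expect_equal(evp$in_seed, pos >= 2 && pos <= 8, label = paste("pos", pos))
  }
  expect_error(detect_edits(tags, character(0)), "empty")
})

test_that("multi-mature ambiguity resolves by wild-type abundance then id", {
  m1 <- "AAGGCCTTAAGGCCTTAAGG"
  m2 <- m1; substr(m2, 3, 3) <- "C"
  matures <- c("mir-b" = m2, "mir-a" = m1)
  tag <- m1; substr(tag, 3, 3) <- "T"   # one mismatch from both
  tags <- data.frame(sequence = tag, count = 1L, stringsAsFactors = FALSE)
  expect_equal(detect_edits(tags, matures,
                            c("mir-a" = 5, "mir-b" = 50))$mirna, "mir-b")
  expect_equal(detect_edits(tags, matures,
                            c("mir-a" = 50, "mir-b" = 5))$mirna, "mir-a")
  # tie: lexicographically first id wins
  expect_equal(detect_edits(tags, matures)$mirna, "mir-a")
})

test_that("detected events reconstruct their tag and recover the simulated truth", {
  lib <- clean_library()
  res <- process_library(lib$reads, demo_profile()$adapter, demo_index())
  un <- res$tags[res$tags$category == "unannotated", ]
  wt <- wildtype_counts(res$tags, demo_ref()$mature)
  ev <- detect_edits(un, demo_ref()$mature, wt)

  # reconstruction: applying obs at position to the mature gives the tag
  mature <- demo_ref()$mature
  for (i in seq_len(nrow(ev))) {
    rebuilt <- mature[[ev$mirna[i]]]
    substr(rebuilt, ev$position[i], ev$position[i]) <- ev$obs[i]
    expect_identical(rebuilt, ev$sequence[i])
  }
  expect_true(all(ev$in_seed == (ev$position >= 2 & ev$position <= 8)))

  # per-miRNA edited fractions recover the simulated editing rates
  tr <- lib$truth
  got_edit <- tapply(ev$count, ev$mirna, sum)
  rates <- demo_profile()$editing_rate
  for (id in names(mature)) {
    n_id <- tr$mirna_counts[[id]]
    if (n_id < 50) next
    obs <- if (id %in% names(got_edit)) got_edit[[id]] else 0
    sigma <- sqrt(n_id * rates[[id]] * (1 - rates[[id]]))
    expect_lt(abs(obs - n_id * rates[[id]]), 3 * sigma + 3,
              label = paste("editing rate recovery for", id))
  }
  # and the event table agrees with the truth manifest
  expect_equal(sum(ev$count), sum(tr$edited_counts))
})

test_that("editing summaries reproduce the published percentage arithmetic", {
  expect_equal(editing_percentage(5823249, 15969875), 26.72)  # Q2 N
  expect_equal(editing_percentage(240370, 87935), 73.22)      # let-7e Q1 N
  expect_equal(editing_percentage(0, 1000), 0)
  expect_equal(editing_percentage(1000, 0), 100)
  expect_true(is.na(editing_percentage(0, 0)))
})

test_that("per-sample summaries total correctly and split substitution types", {
  mature <- c("mir-a" = "CCGTAGGCTAACGTTGACCTGG",
              "mir-b" = "TTGGCCAATTGGCCAATTGG")
  mk_tag <- function(m, pos, base, count) {
    s <- unname(mature[[m]]); substr(s, pos, pos) <- base
    data.frame(sequence = s, count = count, stringsAsFactors = FALSE)
  }
  ev_n <- detect_edits(rbind(mk_tag("mir-a", 5, "G", 10),
                             mk_tag("mir-a", 9, "C", 2)), mature)
  ev_t <- detect_edits(mk_tag("mir-b", 3, "A", 4), mature)
  meta <- data.frame(sample = c("P1N", "P1T"), patient = "P1",
                     tissue = c("N", "T"), stringsAsFactors = FALSE)
  wt <- list(P1N = c("mir-a" = 38, "mir-b" = 10),
             P1T = c("mir-a" = 20, "mir-b" = 0))
  summ <- editing_summary(list(P1N = ev_n, P1T = ev_t), wt, meta)
  expect_equal(summ$edited[summ$patient == "P1" & summ$tissue == "N"], 12)
  expect_equal(summ$wildtype[summ$patient == "P1" & summ$tissue == "N"], 48)
  expect_equal(summ$pct[summ$patient == "P1" & summ$tissue == "N"], 20)
  tot <- summ[summ$patient == "Total", ]
  expect_equal(tot$edited[tot$tissue == "N"],
               sum(summ$edited[summ$patient != "Total" & summ$tissue == "N"]))

  # A-to-G restriction drops the non A>G events
  ag <- editing_summary(list(P1N = ev_n, P1T = ev_t), wt, meta,
                        a_to_g_only = TRUE)
  expect_equal(ag$edited[ag$patient == "P1" & ag$tissue == "N"], 10)

  per <- per_mirna_editing(list(P1N = ev_n, P1T = ev_t), wt, "mir-a", meta)
  expect_equal(per$summary$edited, c(12, 0))
  expect_equal(sum(per$substitutions), 12)
  expect_equal(unname(per$substitutions[["A>G"]]), 10)
  expect_equal(unname(per$substitutions[["T>C"]]), 2)
  # wild-type pool of zero with edits present reads as 100%
  perb <- per_mirna_editing(list(P1N = ev_n, P1T = ev_t), wt, "mir-b", meta)
  expect_equal(perb$summary$pct[perb$summary$tissue == "T"], 100)
  expect_error(per_mirna_editing(list(P1N = ev_n, P1T = ev_t), wt, "mir-z",
                                 meta), "unknown miRNA")
})

test_that("tumor/normal comparison is a paired one-tailed test on percentages", {
  eq <- data.frame(patient = rep(paste0("P", 1:4), each = 2),
                   tissue = rep(c("N", "T"), 4),
                   pct = rep(c(10, 10), 4), stringsAsFactors = FALSE)
  expect_equal(compare_editing(eq)$p, 0.5)
  expect_error(compare_editing(eq[1:5, ]), "incomplete")
})

test_that("with equal editing rates the tumor-excess test rejects at close to nominal rate", {
  ref <- build_reference(n_mirnas = 50, n_other_loci = 3, seed = 7)
  rej <- vapply(1:200, function(s) {
    prof <- sim_profile(ref, seed = 500 + s, n_reads = 5000,
                        tumor_editing_delta = 0)
    coh <- simulate_cohort(ref, prof, n_pairs = 10, seed = 9000 + s,
                           emit_reads = FALSE)
    tot <- truth_editing_totals(coh)
    tot$pct <- editing_percentage(tot$edited, tot$wildtype)
    compare_editing(tot)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.12)
})
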