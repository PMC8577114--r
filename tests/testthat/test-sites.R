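run_fixture_pipeline <- function(protein, table, timepoint = NA_character_) {
  cls <- classify_termini(locate_peptides(read_peptide_table(table), protein), protein)
  q <- quantify_peptides(cls)
  sig <- significant_set(q)
  list(quantified = q,
       calls = call_sites(sig[grepl("^semi", sig$peptide_class), ], protein,
                          timepoint = timepoint))
}

test_that("seven autolysis-evidence peptides collapse to six spacer-domain bonds", {
  fx <- fx_adamts8_table()
  out <- run_fixture_pipeline(fx$protein, fx$table)
  expect_equal(nrow(out$calls), 6L)
  expect_setequal(out$calls$p1, c(734, 742, 789, 790, 816, 818))
  # opposite-side evidence for Ala734-Leu735 merges into one call
  expect_equal(out$calls$n_support[out$calls$p1 == 734], 2L)
  expect_setequal(out$calls$support[out$calls$p1 == 734][[1]]$side, c("N", "C"))
  rep <- site_report(out$calls, fx$protein)
  expect_true(all(rep$domain == "Sp"))
  expect_equal(rep$site[rep$p1 == 734], "Ala734-Leu735")
})

test_that("a C-terminal semi-tryptic peptide ending at residue 53 calls bond (53, 54)", {
  fx <- fx_opn_tables()
  out <- run_fixture_pipeline(fx$protein, fx$table_2h)
  call53 <- out$calls[out$calls$p1 == 53, ]
  expect_equal(nrow(call53), 1L)
  expect_equal(call53$p1p, 54L)
  expect_equal(call53$site, "Asn53-Leu54")
  expect_equal(nrow(call_sites(out$quantified[0, ], fx$protein)), 0L)
})

test_that("evidence merging is idempotent, order-independent and time-point aware", {
  fx <- fx_opn_tables()
  out2 <- run_fixture_pipeline(fx$protein, fx$table_2h, "2h")
  out24 <- run_fixture_pipeline(fx$protein, fx$table_24h, "24h")
  merged <- merge_evidence(out2$calls, out24$calls)
  expect_setequal(merged$p1, fx$sites_24h)
  expect_true(all(out2$calls$p1 %in% merged$p1))   # 2 h sites are a subset
  # both directions give the same result
  merged_rev <- merge_evidence(out24$calls, out2$calls)
  expect_equal(merged$site, merged_rev$site)
  expect_equal(merged$n_support, merged_rev$n_support)
  # idempotent
  expect_equal(merge_evidence(merged, merged)$n_support, merged$n_support)
  # the Asn53-Leu54 call carries both modification forms and both time points
  m53 <- merged[merged$p1 == 53, ]
  expect_equal(m53$timepoints, "24h,2h")
  expect_setequal(unique(m53$support[[1]]$modifications), c("", "1:Gln->pyro-Glu"))
})

test_that("cross-protein bonds never merge", {
  a <- protein_record("A", "MKAAADDDGGGKCCCR")
  b <- protein_record("B", "MKAAADDDGGGKCCCR")
  fake <- function(prot) {
    tibble::tibble(sequence = "AAADDD", modifications = "", protein_id = prot,
                   start = 3L, end = 8L, located = TRUE,
                   exclude_reason = NA_character_,
                   n_class = "tryptic", c_class = "non-tryptic",
                   peptide_class = "semi-tryptic-C", ratio = 100,
                   log2_ratio = log2(100), scaled = TRUE, z = 5)
  }
  calls <- merge_evidence(call_sites(fake("A"), list(a, b)),
                          call_sites(fake("B"), list(a, b)))
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$protein_id, c("A", "B"))
})

test_that("spanning evidence uses strict interval containment of the bond", {
  fx <- fx_opn_tables()
  out24 <- run_fixture_pipeline(fx$protein, fx$table_24h, "24h")
  calls <- spanning_support(out24$calls, out24$quantified)
  c33 <- calls[calls$p1 == 33, ]
  expect_gte(c33$n_spanning, 1L)
  sp <- c33$spanning[[1]]
  expect_true(any(sp$start == 31 & sp$end == 47))   # the bridging tryptic peptide
  # a peptide starting at P1' does not span
  expect_false(oracle_spans(34L, 47L, 33L))
  withr::with_seed(41, {
    for (i in 1:300) {
      st <- sample(100, 1); en <- st + sample(0:30, 1); p1 <- sample(100, 1)
      expect_equal(st <= p1 && en >= p1 + 1L, oracle_spans(st, en, p1))
    }
  })
})

test_that("denominator-only semi-tryptic peptides are listed apart with spanning flags", {
  fx <- fx_opn_tables()
  out24 <- run_fixture_pipeline(fx$protein, fx$table_24h, "24h")
  den <- denominator_only_peptides(out24$quantified, out24$calls)
  expect_equal(nrow(den), 2L)
  expect_true(den$spans_called_site[den$start == 31 & den$end == 36])
  expect_false(den$spans_called_site[den$start == 44 & den$end == 50])
})

test_that("site reports format residues and handle empty call lists", {
  fx <- fx_opn_tables()
  out24 <- run_fixture_pipeline(fx$protein, fx$table_24h, "24h")
  rep <- site_report(out24$calls, fx$protein)
  expect_equal(rep$site[rep$p1 == 217], "Asp217-Asp218")
  expect_equal(rep$domain[rep$p1 == 217], "CBD")
  empty <- site_report(out24$calls[0, ], fx$protein)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("protein", "p1", "p1_prime", "site", "domain") %in% names(empty)))
})

test_that("no call's evidence terminus is producible by trypsin alone", {
  fx <- fx_opn_tables()
  out24 <- run_fixture_pipeline(fx$protein, fx$table_24h, "24h")
  res <- strsplit(fx$protein$sequence, "")[[1]]
  for (i in seq_len(nrow(out24$calls))) {
    p1 <- out24$calls$p1[[i]]
    tryptic_bond <- res[[p1]] %in% c("K", "R") && res[[p1 + 1L]] != "P"
    expect_false(tryptic_bond)
  }
})
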