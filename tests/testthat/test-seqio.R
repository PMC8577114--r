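test_that("read_fasta parses single and multi-entry files and validates residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKR"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs$P1$id, "P1")
  expect_equal(recs$P1$sequence, "MKR")
  expect_equal(recs$P1$length, 3L)

  writeLines(c(">P1", "MKR", ">P2", "ACD", "EFG"), f)  # wrapped second entry
  recs <- read_fasta(f)
  expect_equal(names(recs), c("P1", "P2"))
  expect_equal(recs$P2$sequence, "ACDEFG")

  writeLines(c(">P1", "MK9R"), f)
  expect_error(read_fasta(f), "'9'.*line 2")
  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
})

test_that("motif scan finds the heparin-binding stretch and matches the oracle", {
  a <- synthetic_adamts8()
  hits <- scan_motif(a, "XBBXBX")
  hit567 <- hits[hits$start == 567, ]
  expect_equal(nrow(hit567), 1L)
  expect_equal(hit567$match, "GRRAKY")
  expect_equal(hit567$end, 572L)

  none <- scan_motif(protein_record("p", "AAAAAA"), "XBBXBX")
  expect_equal(nrow(none), 0L)
  expect_error(scan_motif(a, "XBZ"), "X and B")

  withr::with_seed(11, {
    for (i in 1:25) {
      s <- random_sequence(200)
      p <- protein_record("r", s)
      got <- scan_motif(p, "XBBXBX")
      expect_equal(got$start, oracle_motif_starts(s, "XBBXBX"))
      strict <- scan_motif(p, "XBBXBX", x_excludes_basic = TRUE)
      expect_equal(strict$start,
                   oracle_motif_starts(s, "XBBXBX", x_excludes_basic = TRUE))
    }
  })
})

test_that("sequon scan applies the proline rule and matches the oracle", {
  expect_equal(scan_sequons(protein_record("p", "ANGTA"))$start, 2L)
  expect_equal(nrow(scan_sequons(protein_record("p", "NPS"))), 0L)
  expect_true(all(c(344, 400, 465, 490, 599) %in% scan_sequons(synthetic_adamts8())$start))
  withr::with_seed(12, {
    for (i in 1:25) {
      s <- random_sequence(200)
      expect_equal(scan_sequons(protein_record("r", s))$start, oracle_sequon_starts(s))
    }
  })
})

test_that("extinction coefficient follows the W/Y/cystine composition rule", {
  expect_equal(extinction_coefficient("W"), 5500L)
  expect_equal(extinction_coefficient("Y"), 1490L)
  expect_equal(extinction_coefficient("CC", cys_paired = TRUE), 125L)
  expect_equal(extinction_coefficient("CC", cys_paired = FALSE), 0L)
  expect_equal(extinction_coefficient("C", cys_paired = TRUE), 0L)  # unpaired
  # additivity under concatenation in reduced mode
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- random_sequence(40); b <- random_sequence(60)
      expect_equal(extinction_coefficient(paste0(a, b), cys_paired = FALSE),
                   extinction_coefficient(a, cys_paired = FALSE) +
                     extinction_coefficient(b, cys_paired = FALSE))
    }
  })
})

test_that("the FLAG-tagged construct reproduces its design extinction and masses", {
  a <- synthetic_adamts8()
  flagged <- paste0(a$sequence, "DYKDDDDK")
  expect_equal(extinction_coefficient(flagged, cys_paired = TRUE), 95195L)
  expect_equal(average_mass(flagged), 95000, tolerance = 2000 / 95000)
  mature <- paste0(substr(a$sequence, 236, a$length), "DYKDDDDK")
  expect_equal(average_mass(mature), 70000, tolerance = 2000 / 70000)
})

test_that("average mass matches hand-computed residue sums", {
  expect_equal(average_mass("G"), 75.07, tolerance = 1e-4)
  # hand sum: 2 glycine residues (2 * 57.0519) + water 18.01524
  expect_equal(average_mass("GG"), 132.12, tolerance = 1e-4)
  expect_error(average_mass("GXG"), "X")
})

test_that("isoform-b coordinates map onto isoform a across the 14-residue deletion", {
  expect_equal(map_isoform_coord(57), 57L)
  expect_equal(map_isoform_coord(54), 54L)
  expect_equal(map_isoform_coord(218), 232L)
  expect_error(map_isoform_coord(0), "positive")
  # strictly increasing, hence injective
  v <- map_isoform_coord(1:400)
  expect_true(all(diff(v) > 0))
})

test_that("percent identity uses the one-side-ungapped column convention", {
  expect_equal(percent_identity("ACDEF", "ACDEF"), 100)
  expect_equal(percent_identity("AB-D", "ABCD"), 75)
  expect_error(percent_identity("AC", "ACD"), "length")
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- 60
      a <- strsplit(random_sequence(n, c("A", "C", "D", "-")), "")[[1]]
      b <- strsplit(random_sequence(n, c("A", "C", "D", "-")), "")[[1]]
      if (all(a == "-" & b == "-")) next
      scored <- a != "-" | b != "-"
      ident <- sum(scored & a == b & a != "-")
      expect_equal(percent_identity(paste(a, collapse = ""), paste(b, collapse = "")),
                   100 * ident / sum(scored))
      # symmetry
      expect_equal(percent_identity(paste(a, collapse = ""), paste(b, collapse = "")),
                   percent_identity(paste(b, collapse = ""), paste(a, collapse = "")))
    }
  })
})

test_that("domain annotation is inclusive at boundaries with first-interval ties", {
  p <- protein_record("p", strrep("A", 100),
                      domains = data.frame(name = c("D1", "D2"),
                                           start = c(10, 20), end = c(25, 40)))
  expect_equal(annotate_position(p, 10), "D1")
  expect_equal(annotate_position(p, 25), "D1")
  expect_equal(annotate_position(p, 20), "D1")   # overlap: first listed wins
  expect_equal(annotate_position(p, 26), "D2")
  expect_equal(annotate_position(p, 5), "inter-domain")
  expect_error(annotate_position(p, 101), "out of range")

  a <- synthetic_adamts8()
  expect_equal(annotate_position(a, 735), "Sp")
})

test_that("domain configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("PROT1:", "  - {name: Sp, start: 690, end: 831}",
               "  - {name: Mp, start: 351, end: 440}"), f)
  cfg <- read_domain_config(f)
  expect_equal(cfg$PROT1$name, c("Sp", "Mp"))
  expect_equal(cfg$PROT1$start, c(690, 351))
})
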