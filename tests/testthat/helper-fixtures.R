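# Fixture builders: peptide tables emulating a search-engine export for the
# two worked examples (autolysis of the ADAMTS8-like construct; digestion of
# the OPN-like construct), plus condition-balanced semi-tryptic background
# generated by truncating tryptic peptides (in-source-fragment style).

fx_abundance_cols <- function(wt1, wt2, eq1, eq2) {
  tibble::tibble(`abundance:WT:1` = wt1, `abundance:WT:2` = wt2,
                 `abundance:EQ:1` = eq1, `abundance:EQ:2` = eq2)
}

# Balanced semi-tryptic background peptides: truncated tryptic peptides whose
# exposed terminus is non-tryptic, present in both conditions with mild
# replicate jitter. `exclude_bonds` keeps planted-site bonds clean.
fx_background_semis <- function(protein, n, seed, exclude_bonds = integer()) {
  dg <- digest_protein(protein)
  dg <- dg[nchar(dg$sequence) >= 10, , drop = FALSE]
  res <- strsplit(protein$sequence, "")[[1]]
  cand <- list()
  for (i in seq_len(nrow(dg))) {
    s <- dg$start[[i]]; e <- dg$end[[i]]
    for (k in 3:(e - s - 5L)) {
      # C-terminal truncation [s, e-k]: exposed bond (e-k, e-k+1)
      if (!(res[[e - k]] %in% c("K", "R")) && !((e - k) %in% exclude_bonds)) {
        cand[[length(cand) + 1L]] <- c(start = s, end = e - k)
      }
      # N-terminal truncation [s+k, e]: exposed bond (s+k-1, s+k)
      if (!(res[[s + k - 1L]] %in% c("K", "R")) && !((s + k - 1L) %in% exclude_bonds)) {
        cand[[length(cand) + 1L]] <- c(start = s + k, end = e)
      }
    }
  }
  cand <- unique(do.call(rbind, cand))
  withr::with_seed(seed, {
    pick <- cand[sample(nrow(cand), min(n, nrow(cand))), , drop = FALSE]
    seqs <- substring(protein$sequence, pick[, "start"], pick[, "end"])
    keep <- !duplicated(seqs)
    seqs <- seqs[keep]
    base <- 2^stats::rnorm(length(seqs), 20, 1)
    jit <- function() exp(stats::rnorm(length(seqs), 0, 0.2))
    dplyr::bind_cols(
      tibble::tibble(sequence = seqs, modifications = ""),
      fx_abundance_cols(base * jit(), base * jit(), base * jit(), base * jit())
    )
  })
}

# Balanced fully tryptic background peptides straight from the digest.
fx_background_tryptics <- function(protein, n, seed) {
  dg <- digest_protein(protein)
  dg <- dg[nchar(dg$sequence) >= 6 & nchar(dg$sequence) <= 40, , drop = FALSE]
  dg <- dg[!duplicated(dg$sequence), , drop = FALSE]
  withr::with_seed(seed, {
    pick <- dg[sample(nrow(dg), min(n, nrow(dg))), , drop = FALSE]
    base <- 2^stats::rnorm(nrow(pick), 20, 1)
    jit <- function() exp(stats::rnorm(nrow(pick), 0, 0.2))
    dplyr::bind_cols(
      tibble::tibble(sequence = pick$sequence, modifications = ""),
      fx_abundance_cols(base * jit(), base * jit(), base * jit(), base * jit())
    )
  })
}

fx_peptide_row <- function(protein, start, end, wt, eq, modifications = "") {
  dplyr::bind_cols(
    tibble::tibble(sequence = substr(protein$sequence, start, end),
                   modifications = modifications),
    fx_abundance_cols(wt, wt, eq, eq)
  )
}

# Seven WT-only semi-tryptic peptides carrying the six autolysis bonds of the
# ADAMTS8-like construct (N-terminal starts at 735/743/790/791/817/819 and
# one C-terminal end at 734), on a balanced semi-tryptic background.
fx_adamts8_table <- function(n_background = 50) {
  a <- synthetic_adamts8()
  wt <- 2^20
  spans <- list(c(721, 734), c(735, 748), c(743, 748), c(790, 800),
                c(791, 800), c(817, 830), c(819, 830))
  planted <- dplyr::bind_rows(lapply(spans, function(sp) {
    fx_peptide_row(a, sp[[1]], sp[[2]], wt = wt, eq = NA_real_)
  }))
  site_bonds <- c(734, 742, 789, 790, 816, 818)
  bg <- fx_background_semis(a, n_background, seed = 421, exclude_bonds = site_bonds)
  list(protein = a, table = dplyr::bind_rows(planted, bg), spans = spans)
}

# Peptide tables for the OPN-like construct at the two digestion time points.
# 2 h: three sites (bond P1 53 via two modification forms, 217, 228);
# 24 h: the same plus seven more (33, 225, 226, 229, 251, 263, 264), two
# denominator-only semi-tryptic peptides and the tryptic peptide [31, 47]
# spanning bond (33, 34).
fx_opn_tables <- function(n_background = 100) {
  o <- synthetic_opn_b()
  wt <- 2^20
  early <- list(  # present already at 2 h
    fx_peptide_row(o, 44, 53, wt, NA),                              # -> (53,54)
    fx_peptide_row(o, 44, 53, wt, NA, "1:Gln->pyro-Glu"),           # -> (53,54)
    fx_peptide_row(o, 218, 227, wt, NA),                            # -> (217,218)
    fx_peptide_row(o, 215, 228, 25 * 1e6, 1e6)                      # -> (228,229), ratio 25
  )
  late_only <- list(
    fx_peptide_row(o, 26, 33, wt, NA),                              # -> (33,34)
    fx_peptide_row(o, 215, 225, wt, NA),                            # -> (225,226)
    fx_peptide_row(o, 215, 226, wt, NA),                            # -> (226,227)
    fx_peptide_row(o, 215, 229, wt, NA),                            # -> (229,230)
    fx_peptide_row(o, 241, 251, wt, NA),                            # -> (251,252)
    fx_peptide_row(o, 264, 275, wt, NA),                            # -> (263,264)
    fx_peptide_row(o, 265, 275, wt, NA),                            # -> (264,265)
    fx_peptide_row(o, 265, 275, wt, NA, "6:Oxidation")              # -> (264,265)
  )
  late_24h <- c(early, late_only)
  late_24h[[4]] <- fx_peptide_row(o, 215, 228, 45 * 1e6, 1e6)       # ratio 45 at 24 h
  eq_only <- list(
    fx_peptide_row(o, 31, 36, NA, wt),    # EQ-only semi spanning bond (33,34)
    fx_peptide_row(o, 44, 50, NA, wt)     # EQ-only semi elsewhere
  )
  tryptic <- list(
    fx_peptide_row(o, 31, 47, wt, wt)     # spans bond (33,34) in both conditions
  )
  site_bonds <- c(33, 53, 217, 225, 226, 228, 229, 251, 263, 264)
  # also keep the two denominator-only spans (ending at 36 and 50) unique
  bg <- fx_background_semis(o, n_background, seed = 422,
                            exclude_bonds = c(site_bonds, 36, 50))
  bg_tryp <- fx_background_tryptics(o, 15, seed = 423)
  bg_tryp <- bg_tryp[bg_tryp$sequence != substr(o$sequence, 31, 47), , drop = FALSE]
  list(
    protein = o,
    table_2h = dplyr::bind_rows(c(early, tryptic, list(bg), list(bg_tryp))),
    table_24h = dplyr::bind_rows(c(late_24h, eq_only, tryptic, list(bg), list(bg_tryp))),
    sites_2h = c(53, 217, 228),
    sites_24h = site_bonds
  )
}
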