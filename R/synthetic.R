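# Synthetic stand-in protein sequences.
#
# These are NOT the real UniProt sequences: they are deterministic, clearly
# synthetic constructs that carry the documented sequence features of the two
# study proteins (positions of cleavage-site residues, motifs, sequons,
# aromatic/cysteine composition and domain layout), so that every sequence-level
# computation in the package can be exercised end-to-end with realistic inputs.

# Typical vertebrate residue frequencies used for background sampling.
AA_BACKGROUND_FREQ <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.053, C = 0.000, E = 0.062,
  Q = 0.041, G = 0.074, H = 0.026, I = 0.053, L = 0.091, K = 0.058,
  M = 0.023, F = 0.040, P = 0.052, S = 0.073, T = 0.056, W = 0.000,
  Y = 0.000, V = 0.064
)

# Run code with a private, restored RNG state so constructors are
# deterministic without disturbing the caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_residues <- function(n, freqs = AA_BACKGROUND_FREQ) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# Greedy deterministic mass calibration: re-assign residues at `tuners`
# (choosing from a neutral palette) until the summed residue mass of
# `region` hits `target_sum` within `tol`.
calibrate_region_mass <- function(res, tuners, region, target_sum, tol = 40) {
  palette <- c("G", "A", "S", "V", "T", "L", "E", "F", "D", "Q")
  pal_mass <- AA_AVERAGE_MASS[palette]
  for (p in tuners) {
    current <- sum(AA_AVERAGE_MASS[res[region]])
    delta <- target_sum - current
    if (abs(delta) <= tol) break
    # pick the palette residue that moves the sum closest to the target
    change <- pal_mass - AA_AVERAGE_MASS[[res[[p]]]]
    best <- which.min(abs(delta - change))
    res[[p]] <- palette[[best]]
  }
  res
}

place <- function(res, start, letters) {
  idx <- start + seq_along(letters) - 1L
  res[idx] <- letters
  res
}

#' Synthetic ADAMTS8-like protein (stand-in sequence)
#'
#' A deterministic 889-residue synthetic construct mimicking the documented
#' features of the ADAMTS8 precursor: initiator Met; a furin site (RAKR)
#' ending at 235 so the mature form starts at 236; N-glycosylation sequons at
#' Asn 344, 400, 465, 490 and 599; the heparin-binding XBBXBX stretch GRRAKY
#' at 567-572; the six autolysis-site residue pairs (Ala734-Leu735,
#' Tyr742-Leu743, Gln789-Leu790, Leu790-Leu791, Met816-Gln817,
#' Ser818-Ser819) inside the spacer domain (690-831); tryptic anchor residues
#' flanking those sites; 12 Trp, 17 Tyr and 38 Cys so that the FLAG-tagged
#' construct has a paired-cysteine extinction coefficient of 95,195 M^-1cm^-1;
#' and residue masses calibrated so the FLAG-tagged precursor and furin-mature
#' forms weigh about 95 and 70 kDa. Everything outside these engineered
#' features is random background and shares no identity with the real protein.
#'
#' @return A [protein_record()] with id `"SYN_ADAMTS8"`, domain annotation
#'   (Pro, Mp, Dis, TSR, CR, Sp) and the mature start registered as an
#'   N-terminal boundary.
#' @export
synthetic_adamts8 <- function() {
  n <- 889L
  res <- with_local_seed(880901L, sample_residues(n))
  res[[1]] <- "M"
  res <- place(res, 232L, c("R", "A", "K", "R"))             # furin site, mature = 236
  for (p in c(344L, 400L, 465L, 490L, 599L)) {
    res <- place(res, p, c("N", "G", "T"))                   # sequons
  }
  res <- place(res, 567L, c("G", "R", "R", "A", "K", "Y"))   # XBBXBX match
  res <- place(res, 734L, c("A", "L"))                       # autolysis sites
  res <- place(res, 742L, c("Y", "L"))
  res <- place(res, 789L, c("Q", "L", "L"))
  res <- place(res, 816L, c("M", "Q"))
  res <- place(res, 818L, c("S", "S"))
  # tryptic anchors bounding the site-exposing peptides, with non-Pro successors
  res <- place(res, 720L, c("R", "T"))
  res <- place(res, 748L, c("K", "A"))
  res <- place(res, 800L, c("R", "A"))
  res <- place(res, 830L, c("K", "A"))

  # engineered aromatic/cysteine composition: 12 W, 17 Y (2 already placed at
  # 572 and 742), 38 C; positions avoid all constrained windows and the
  # mass-tuning regions below
  zones <- c(210:231, 236:343, 348:399, 404:464, 469:489, 494:566,
             574:598, 702:719, 723:733, 737:741, 745:747, 751:788,
             793:799, 803:815, 821:829, 833:839)
  slots <- zones[round(seq(1, length(zones), length.out = 65L))]
  res[slots[1:12]] <- "W"
  res[slots[13:27]] <- "Y"
  res[slots[28:65]] <- "C"

  flag_sum <- sum(AA_AVERAGE_MASS[strsplit("DYKDDDDK", "")[[1]]])
  mature <- 236:889
  res <- calibrate_region_mass(res, tuners = setdiff(603:689, slots), region = mature,
                               target_sum = 70000 - flag_sum - MASS_WATER)
  res <- calibrate_region_mass(res, tuners = setdiff(40:200, slots), region = 1:235,
                               target_sum = 95000 - flag_sum - MASS_WATER -
                                 sum(AA_AVERAGE_MASS[res[mature]]))

  protein_record(
    id = "SYN_ADAMTS8",
    sequence = paste(res, collapse = ""),
    domains = tibble::tibble(
      name = c("Pro", "Mp", "Dis", "TSR", "CR", "Sp"),
      start = c(30L, 351L, 441L, 510L, 580L, 690L),
      end = c(350L, 440L, 500L, 575L, 640L, 831L)
    ),
    nterm_boundaries = 236L
  )
}

#' Synthetic osteopontin isoform-b-like protein (stand-in sequence)
#'
#' A deterministic 300-residue synthetic construct mimicking osteopontin
#' isoform b (isoform a minus residues 58-71): it carries the residue pairs of
#' the ten documented cleavage sites (Tyr33-Asn34, Asn53-Leu54, Asp217-Asp218,
#' Ser225-His226, His226-Lys227, Gln228-Ser229, Ser229-Arg230, Glu251-Leu252,
#' Glu263-Phe264, Phe264-His265), tryptic anchor residues so each site yields
#' an identifiable semi-tryptic peptide (including the Gln at 44 that can
#' cyclise to pyroglutamate and the Met at 270 that can oxidise), the
#' RGD + SVVYGLR adhesion stretch at 128-137, a poly-Asp aspartate domain, and
#' annotated RGD/SVVYGLR/CBD/HBD/AD intervals. Everything outside these
#' engineered features is random background and shares no identity with the
#' real protein.
#'
#' @return A [protein_record()] with id `"SYN_OPN_B"` and domain annotation.
#' @export
synthetic_opn_b <- function() {
  n <- 300L
  freqs <- AA_BACKGROUND_FREQ
  # osteopontin is acidic and Ser/Asp-rich
  freqs[c("D", "E", "S")] <- c(0.10, 0.10, 0.10)
  freqs <- freqs / sum(freqs)
  res <- with_local_seed(104515L, sample_residues(n, freqs))
  res[[1]] <- "M"
  res <- place(res, 25L, c("K", "S"))          # anchor for peptide 26-33
  res <- place(res, 30L, c("K", "T"))          # anchor for peptides 31-47 / 31-33
  res <- place(res, 33L, c("Y", "N"))          # site Tyr33-Asn34
  res <- place(res, 43L, c("K", "Q"))          # anchor; Gln44 pyro-Glu candidate
  res <- place(res, 47L, c("R", "D"))          # tryptic end of spanning peptide 31-47
  res <- place(res, 53L, c("N", "L"))          # site Asn53-Leu54
  res <- place(res, 75L, rep("D", 12L))        # poly-Asp aspartate domain
  res <- place(res, 128L, strsplit("RGDSVVYGLR", "")[[1]])
  res <- place(res, 214L, c("R", "V"))         # anchor for peptides 215-
  res <- place(res, 217L, c("D", "D"))         # site Asp217-Asp218
  res <- place(res, 225L, c("S", "H", "K", "Q", "S", "R", "A"))
  #                     225 S, 226 H, 227 K, 228 Q, 229 S, 230 R, 231 A
  res <- place(res, 240L, c("R", "A"))         # anchor for peptide 241-251
  res <- place(res, 251L, c("E", "L"))         # site Glu251-Leu252
  res <- place(res, 263L, c("E", "F", "H"))    # sites Glu263-Phe264, Phe264-His265
  res <- place(res, 270L, "M")                 # oxidation candidate
  res <- place(res, 275L, c("R", "S"))         # tryptic end of peptides 264/265-275

  protein_record(
    id = "SYN_OPN_B",
    sequence = paste(res, collapse = ""),
    domains = tibble::tibble(
      name = c("AD", "RGD", "SVVYGLR", "CBD", "HBD"),
      start = c(75L, 128L, 131L, 207L, 280L),
      end = c(86L, 130L, 137L, 220L, 296L)
    )
  )
}
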