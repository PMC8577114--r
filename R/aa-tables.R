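# Amino-acid lookup tables shared across the package.

# Average (isotope-abundance weighted) residue masses in Da, i.e. the mass each
# residue contributes inside a peptide chain; one water is added per chain.
AA_AVERAGE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

MASS_WATER <- 18.01524

# Molar extinction coefficients at 280 nm (M^-1 cm^-1); cystine is per S-S pair.
EXT_TRP <- 5500
EXT_TYR <- 1490
EXT_CYSTINE <- 125

AA_THREE_LETTER <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  E = "Glu", Q = "Gln", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  X = "Xaa"
)

AA_LETTERS <- names(AA_AVERAGE_MASS)

# Modifications accepted on peptide observations, with the residue(s) each may
# sit on ("*" = any) and whether it is restricted to the peptide N terminus.
ALLOWED_MODIFICATIONS <- tibble::tibble(
  name = c("Oxidation", "Acetyl", "Gln->pyro-Glu", "Phospho", "Carbamidomethyl"),
  residues = c("M", "*", "Q", "STY", "C"),
  nterm_only = c(FALSE, TRUE, TRUE, FALSE, FALSE)
)
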