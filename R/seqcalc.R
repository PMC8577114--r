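# Sequence-level computations: motif and sequon scans, ProtParam-style
# parameters, and identity from a supplied alignment.

#' Scan a protein for a basic-residue motif
#'
#' Patterns are written over the two-letter alphabet `X`/`B` used for the
#' heparin-binding consensus XBBXBX: `B` matches a basic residue and `X` any
#' residue. By default `X` is fully permissive (it may itself match K/R);
#' set `x_excludes_basic = TRUE` for the strict reading in which `X` means
#' "any other amino acid".
#'
#' @param protein A [protein_record()].
#' @param pattern Motif over `{X, B}`, e.g. `"XBBXBX"`.
#' @param basic Residues counted as basic (default K and R).
#' @param x_excludes_basic Should `X` positions reject basic residues?
#' @return Tibble of matches: `pattern`, `start`, `end`, `match` (1-based,
#'   inclusive, overlapping matches allowed, ascending by start).
#' @export
scan_motif <- function(protein, pattern, basic = c("K", "R"),
                       x_excludes_basic = FALSE) {
  stopifnot(inherits(protein, "protein_record"))
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  sym <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(unique(sym), c("X", "B"))
  if (length(bad) > 0) {
    stop("motif pattern may only contain X and B, found: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  basic_cls <- paste0("[", paste(basic, collapse = ""), "]")
  x_cls <- if (x_excludes_basic) paste0("[^", paste(basic, collapse = ""), "]") else "."
  rx <- paste0("(?=(", paste(ifelse(sym == "B", basic_cls, x_cls), collapse = ""), "))")
  starts <- stringr::str_locate_all(protein$sequence, stringr::regex(rx))[[1]][, "start"]
  m <- length(sym)
  motif_match_tibble(protein$sequence, toupper(pattern), as.integer(starts), m)
}

#' Scan a protein for N-glycosylation sequons
#'
#' Finds every N-X-S/T sequon with X != P, reported at the asparagine
#' position. This is the plain consensus scan; it does not reproduce
#' neural-network site predictors, whose hit sets may be smaller.
#'
#' @param protein A [protein_record()].
#' @return Tibble of matches: `pattern` (`"N-X-S/T"`), `start` (Asn position),
#'   `end`, `match`.
#' @export
scan_sequons <- function(protein) {
  stopifnot(inherits(protein, "protein_record"))
  starts <- stringr::str_locate_all(
    protein$sequence, stringr::regex("(?=(N[^P][ST]))")
  )[[1]][, "start"]
  motif_match_tibble(protein$sequence, "N-X-S/T", as.integer(starts), 3L)
}

motif_match_tibble <- function(sequence, pattern, starts, width) {
  if (length(starts) == 0) {
    return(tibble::tibble(pattern = character(), start = integer(),
                          end = integer(), match = character()))
  }
  tibble::tibble(
    pattern = pattern,
    start = starts,
    end = starts + width - 1L,
    match = substring(sequence, starts, starts + width - 1L)
  )
}

#' ProtParam-style molar extinction coefficient at 280 nm
#'
#' Sums 5500 per tryptophan and 1490 per tyrosine; with `cys_paired = TRUE`
#' every cysteine pair is assumed disulfide-bonded and contributes 125 per
#' cystine (odd cysteines contribute nothing).
#'
#' @param sequence Amino-acid sequence (character scalar) or a
#'   [protein_record()].
#' @param cys_paired Assume all cysteines form cystines (default TRUE).
#' @return Integer extinction coefficient in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(sequence, cys_paired = TRUE) {
  sequence <- as_sequence(sequence)
  counts <- residue_counts(sequence)
  eps <- EXT_TRP * counts[["W"]] + EXT_TYR * counts[["Y"]]
  if (cys_paired) eps <- eps + EXT_CYSTINE * (counts[["C"]] %/% 2L)
  as.integer(eps)
}

#' Average molecular mass of a protein or peptide
#'
#' Sum of average residue masses plus one water. `X` residues are rejected
#' because their mass is undefined.
#'
#' @inheritParams extinction_coefficient
#' @return Mass in Da.
#' @export
average_mass <- function(sequence) {
  sequence <- as_sequence(sequence)
  res <- strsplit(sequence, "")[[1]]
  if (any(res == "X")) stop("cannot compute mass of a sequence containing X", call. = FALSE)
  sum(AA_AVERAGE_MASS[res]) + MASS_WATER
}

as_sequence <- function(x) {
  if (inherits(x, "protein_record")) return(x$sequence)
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), c(AA_LETTERS, "X"))
  if (length(bad) > 0) {
    stop("invalid residue character(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  x
}

residue_counts <- function(sequence) {
  res <- factor(strsplit(sequence, "")[[1]], levels = c(AA_LETTERS, "X"))
  table(res)
}

#' Percent identity from a supplied pairwise alignment
#'
#' Consumes an alignment (two equal-length gapped sequences); it never
#' produces one. Identity is counted over columns where at least one sequence
#' is ungapped: `100 * identical columns / such columns`. Columns gapped in
#' both sequences are ignored entirely.
#'
#' @param a,b Aligned sequences of equal length (gap character allowed).
#' @param gap Gap character (default `"-"`).
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(a, b, gap = "-") {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("aligned sequences differ in length (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  scored <- ca != gap | cb != gap
  if (!any(scored)) stop("alignment has no ungapped columns", call. = FALSE)
  ident <- scored & ca == cb & ca != gap
  100 * sum(ident) / sum(scored)
}

#' Read an aligned FASTA file (gapped sequences)
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of gapped sequences.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  stats::setNames(toupper(as.character(set)), ids)
}
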