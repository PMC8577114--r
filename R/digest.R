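# In-silico tryptic digestion and terminus classification of observed
# peptides against their parent protein.

#' Trypsin digestion rules
#'
#' @param cleave_after Residues after which trypsin cleaves (default K, R).
#' @param proline_block Suppress cleavage when the following residue is
#'   proline (default TRUE, the common search-engine trypsin rule).
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return An object of class `digestion_rules`.
#' @export
digestion_rules <- function(cleave_after = c("K", "R"), proline_block = TRUE,
                            max_missed = 2L) {
  max_missed <- as.integer(max_missed)
  stopifnot(length(max_missed) == 1L, max_missed >= 0L, is.logical(proline_block))
  structure(
    list(cleave_after = toupper(cleave_after), proline_block = proline_block,
         max_missed = max_missed),
    class = "digestion_rules"
  )
}

# Positions i such that the bond between residue i and i+1 is cut by trypsin.
cut_positions <- function(sequence, rules) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2L) return(integer())
  i <- which(res[-n] %in% rules$cleave_after)
  if (rules$proline_block) i <- i[res[i + 1L] != "P"]
  i
}

#' In-silico tryptic digest of a protein
#'
#' Enumerates every fully tryptic peptide with up to `max_missed` missed
#' cleavages; the protein termini count as tryptic boundaries.
#'
#' @param protein A [protein_record()] or plain sequence.
#' @param rules A [digestion_rules()].
#' @return Tibble with columns `start`, `end`, `n_missed`, `sequence`.
#' @export
digest_protein <- function(protein, rules = digestion_rules()) {
  sequence <- as_sequence(protein)
  cuts <- cut_positions(sequence, rules)
  bounds <- c(0L, cuts, nchar(sequence))   # segment boundaries (cut after index)
  k <- length(bounds)
  out <- list()
  for (m in 0:rules$max_missed) {
    i <- seq_len(k - 1L - m)
    if (length(i) == 0) break
    out[[m + 1L]] <- tibble::tibble(
      start = bounds[i] + 1L,
      end = bounds[i + 1L + m],
      n_missed = m
    )
  }
  pep <- dplyr::bind_rows(out)
  pep$sequence <- substring(sequence, pep$start, pep$end)
  dplyr::arrange(pep, .data$start, .data$end)[, c("start", "end", "n_missed", "sequence")]
}

#' Locate observed peptides in a set of proteins
#'
#' Each peptide's bare sequence is matched exactly (optionally with I/L
#' treated as indistinguishable) against every protein. Peptides matching no
#' protein or more than one position overall are excluded with a logged
#' reason; only uniquely located peptides go forward.
#'
#' @param peptides Character vector of bare peptide sequences, or a tibble
#'   with a `sequence` column (extra columns are carried through).
#' @param proteins A [protein_record()] or list of them.
#' @param il_equivalent Treat I and L as identical during matching
#'   (default FALSE).
#' @return Tibble: input columns plus `protein_id`, `start`, `end`,
#'   `located`, `exclude_reason` (`NA`, `"unmatched"` or `"ambiguous"`).
#' @export
locate_peptides <- function(peptides, proteins, il_equivalent = FALSE) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  proteins <- stats::setNames(proteins, vapply(proteins, `[[`, character(1), "id"))
  tbl <- if (is.character(peptides)) tibble::tibble(sequence = peptides)
         else tibble::as_tibble(peptides)
  stopifnot("sequence" %in% names(tbl))

  canon <- function(x) if (il_equivalent) gsub("L", "I", x, fixed = TRUE) else x
  uniq <- unique(tbl$sequence)
  # lookahead so that overlapping occurrences all count toward ambiguity
  pat <- stringr::regex(paste0("(?=", stringr::str_escape(canon(uniq)), ")"))
  hits <- vector("list", length(uniq))
  for (pid in names(proteins)) {
    subj <- canon(proteins[[pid]]$sequence)
    loc <- stringr::str_locate_all(subj, pat)
    for (j in seq_along(uniq)) {
      if (nrow(loc[[j]]) > 0) {
        hits[[j]] <- rbind(hits[[j]],
                           cbind(protein = pid, as.data.frame(loc[[j]])))
      }
    }
  }
  info <- lapply(seq_along(uniq), function(j) {
    h <- hits[[j]]
    if (is.null(h) || nrow(h) == 0) {
      list(protein_id = NA_character_, start = NA_integer_, end = NA_integer_,
           reason = "unmatched")
    } else if (nrow(h) > 1) {
      list(protein_id = NA_character_, start = NA_integer_, end = NA_integer_,
           reason = "ambiguous")
    } else {
      st <- as.integer(h$start[[1]])
      list(protein_id = h$protein[[1]], start = st,
           end = st + nchar(uniq[[j]]) - 1L, reason = NA_character_)
    }
  })
  idx <- match(tbl$sequence, uniq)
  tbl$protein_id <- vapply(info, `[[`, character(1), "protein_id")[idx]
  tbl$start <- vapply(info, `[[`, integer(1), "start")[idx]
  tbl$end <- vapply(info, `[[`, integer(1), "end")[idx]
  tbl$exclude_reason <- vapply(info, `[[`, character(1), "reason")[idx]
  tbl$located <- is.na(tbl$exclude_reason)
  tbl
}

#' Classify peptide termini as tryptic, non-tryptic or protein-terminal
#'
#' The N terminus is tryptic when the preceding residue is K/R (and, with the
#' proline block, the peptide does not start with P); the C terminus is
#' tryptic when the last residue is K/R (and the following residue is not P).
#' Termini at the protein ends or at annotated mature-form start sites are
#' flagged `protein-terminal`: they are never cleavage evidence. A peptide
#' with exactly one non-tryptic terminus is semi-tryptic and exposes the
#' scissile bond at that terminus; classification depends only on position
#' and flanking residues, never on modifications.
#'
#' @param located Tibble from [locate_peptides()] (only located rows are
#'   classified; others keep `NA` classes).
#' @param proteins A [protein_record()] or list of them.
#' @param rules A [digestion_rules()].
#' @return Input tibble plus `n_class`, `c_class` (each `tryptic`,
#'   `non-tryptic` or `protein-terminal`) and `peptide_class` (`fully-tryptic`,
#'   `semi-tryptic-N`, `semi-tryptic-C` or `non-tryptic`).
#' @export
classify_termini <- function(located, proteins, rules = digestion_rules()) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  proteins <- stats::setNames(proteins, vapply(proteins, `[[`, character(1), "id"))
  located <- tibble::as_tibble(located)
  n <- nrow(located)
  n_class <- c_class <- overall <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (!isTRUE(located$located[[i]])) next
    prot <- proteins[[located$protein_id[[i]]]]
    if (is.null(prot)) stop("located peptide references unknown protein '",
                            located$protein_id[[i]], "'", call. = FALSE)
    s <- located$start[[i]]; e <- located$end[[i]]
    seqc <- prot$sequence
    first <- substr(seqc, s, s)
    last <- substr(seqc, e, e)

    nc <- if (s %in% prot$nterm_boundaries) {
      "protein-terminal"
    } else {
      prev <- substr(seqc, s - 1L, s - 1L)
      if (prev %in% rules$cleave_after && !(rules$proline_block && first == "P"))
        "tryptic" else "non-tryptic"
    }
    cc <- if (e == prot$length) {
      "protein-terminal"
    } else {
      nxt <- substr(seqc, e + 1L, e + 1L)
      if (last %in% rules$cleave_after && !(rules$proline_block && nxt == "P"))
        "tryptic" else "non-tryptic"
    }
    n_class[[i]] <- nc
    c_class[[i]] <- cc
    n_bad <- nc == "non-tryptic"; c_bad <- cc == "non-tryptic"
    overall[[i]] <- if (n_bad && c_bad) "non-tryptic"
      else if (n_bad) "semi-tryptic-N"
      else if (c_bad) "semi-tryptic-C"
      else "fully-tryptic"
  }
  located$n_class <- n_class
  located$c_class <- c_class
  located$peptide_class <- overall
  located
}
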