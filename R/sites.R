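# Collapse significant semi-tryptic peptides into deduplicated scissile-bond
# calls, merge evidence across runs, attach spanning-peptide cross-checks and
# domain annotation.

#' Call scissile bonds from significant semi-tryptic peptides
#'
#' A semi-tryptic-N peptide starting at residue i exposes the bond
#' (P1 = i-1, P1' = i); a semi-tryptic-C peptide ending at j exposes
#' (P1 = j, P1' = j+1). Peptides pointing at the same bond (including
#' modified/unmodified forms and opposite-side evidence) are merged into one
#' call; calls are sorted by protein then position.
#'
#' @param significant Tibble of significant semi-tryptic peptides (rows from
#'   [significant_set()] with `peptide_class` `semi-tryptic-N`/`-C`; other
#'   classes are ignored).
#' @param proteins A [protein_record()] or list of them.
#' @param timepoint Optional label (e.g. `"2h"`) attached to every supporting
#'   peptide of this run.
#' @return Tibble of class `cleavage_calls`: `protein_id`, `p1`, `p1p`,
#'   `p1_res`, `p1p_res`, `site`, `best_z`, `n_support`, `timepoints`, and a
#'   `support` list-column of per-peptide evidence.
#' @export
call_sites <- function(significant, proteins, timepoint = NA_character_) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  proteins <- stats::setNames(proteins, vapply(proteins, `[[`, character(1), "id"))
  tbl <- tibble::as_tibble(significant)
  tbl <- tbl[tbl$peptide_class %in% c("semi-tryptic-N", "semi-tryptic-C"), , drop = FALSE]
  if (nrow(tbl) == 0) return(empty_calls())

  is_n <- tbl$peptide_class == "semi-tryptic-N"
  tbl$p1 <- ifelse(is_n, tbl$start - 1L, tbl$end)
  tbl$p1p <- tbl$p1 + 1L
  tbl$side <- ifelse(is_n, "N", "C")
  for (i in seq_len(nrow(tbl))) {
    len <- proteins[[tbl$protein_id[[i]]]]$length
    if (tbl$p1[[i]] < 1L || tbl$p1p[[i]] > len) {
      stop("called bond (", tbl$p1[[i]], ", ", tbl$p1p[[i]],
           ") lies outside protein '", tbl$protein_id[[i]], "'", call. = FALSE)
    }
  }
  tbl$timepoint <- if (all(is.na(timepoint))) {
    if ("timepoint" %in% names(significant)) tbl$timepoint else NA_character_
  } else timepoint

  keep <- intersect(
    c("sequence", "modifications", "side", "start", "end", "ratio",
      "log2_ratio", "z", "scaled", "timepoint"),
    names(tbl)
  )
  grouped <- dplyr::group_by(tbl, .data$protein_id, .data$p1, .data$p1p)
  calls <- dplyr::summarise(
    grouped,
    best_z = if (all(is.na(.data$z))) NA_real_ else max(.data$z, na.rm = TRUE),
    n_support = dplyr::n(),
    timepoints = paste(sort(unique(stats::na.omit(.data$timepoint))), collapse = ","),
    support = list(dplyr::pick(dplyr::all_of(keep))),
    .groups = "drop"
  )
  calls <- dplyr::arrange(calls, .data$protein_id, .data$p1)
  calls$p1_res <- residue_at(proteins, calls$protein_id, calls$p1)
  calls$p1p_res <- residue_at(proteins, calls$protein_id, calls$p1p)
  calls$site <- site_label(calls$p1_res, calls$p1, calls$p1p_res, calls$p1p)
  as_cleavage_calls(calls)
}

residue_at <- function(proteins, ids, pos) {
  vapply(seq_along(ids), function(i) {
    substr(proteins[[ids[[i]]]]$sequence, pos[[i]], pos[[i]])
  }, character(1))
}

#' Format a scissile bond in Ala734-Leu735 style
#'
#' @param p1_res,p1p_res One-letter residue codes.
#' @param p1,p1p Residue positions.
#' @return Character vector like `"Ala734-Leu735"`.
#' @export
site_label <- function(p1_res, p1, p1p_res, p1p) {
  paste0(AA_THREE_LETTER[p1_res], p1, "-", AA_THREE_LETTER[p1p_res], p1p)
}

empty_calls <- function() {
  as_cleavage_calls(tibble::tibble(
    protein_id = character(), p1 = integer(), p1p = integer(),
    best_z = numeric(), n_support = integer(), timepoints = character(),
    support = list(), p1_res = character(), p1p_res = character(),
    site = character()
  ))
}

as_cleavage_calls <- function(tbl) {
  class(tbl) <- unique(c("cleavage_calls", class(tbl)))
  tbl
}

#' Merge cleavage calls from multiple runs or time points
#'
#' Same-bond calls are merged: supporting-peptide evidence is concatenated
#' (time-point labels preserved), `best_z` becomes the maximum over all
#' evidence, and the result is position-sorted. Merging is idempotent and
#' order-independent. Calls on different proteins may coexist but a single
#' bond is never merged across proteins.
#'
#' @param ... `cleavage_calls` tibbles (or one list of them).
#' @return A unified `cleavage_calls` tibble.
#' @export
merge_evidence <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && !inherits(inputs[[1]], "data.frame")) {
    inputs <- inputs[[1]]
  }
  all_calls <- dplyr::bind_rows(inputs)
  if (nrow(all_calls) == 0) return(empty_calls())
  grouped <- dplyr::group_by(all_calls, .data$protein_id, .data$p1, .data$p1p,
                             .data$p1_res, .data$p1p_res, .data$site)
  merged <- dplyr::summarise(
    grouped,
    best_z = if (all(is.na(.data$best_z))) NA_real_ else max(.data$best_z, na.rm = TRUE),
    support = list(dplyr::distinct(dplyr::bind_rows(.data$support))),
    timepoints = paste(
      sort(unique(unlist(strsplit(.data$timepoints[nzchar(.data$timepoints)], ",")))),
      collapse = ","),
    .groups = "drop"
  )
  merged$n_support <- vapply(merged$support, nrow, integer(1))
  merged <- dplyr::arrange(merged, .data$protein_id, .data$p1)
  as_cleavage_calls(merged)
}

#' Attach spanning (bridging) peptide evidence to calls
#'
#' A peptide spans a bond when it covers both P1 and P1' (`start <= P1` and
#' `end >= P1'`). Fully tryptic spanning peptides that are significantly more
#' abundant in the denominator (inactive-enzyme) condition corroborate the
#' call; each spanning peptide is labelled `supportive` (tryptic-orientation
#' `z > threshold`), `contrary` (`z < -threshold`) or `neutral`. Contrary
#' evidence is reported, never used to veto a call.
#'
#' @param calls A `cleavage_calls` tibble.
#' @param quantified Quantified peptide tibble ([quantify_peptides()]); the
#'   fully tryptic rows (and, if present, denominator-only semi-tryptic rows)
#'   are considered.
#' @param config A [comparison_config()].
#' @return `calls` plus `n_spanning`, `n_supportive_spanning` and a
#'   `spanning` list-column.
#' @export
spanning_support <- function(calls, quantified, config = comparison_config()) {
  quantified <- tibble::as_tibble(quantified)
  cand <- quantified[
    quantified$peptide_class %in% "fully-tryptic" |
      (quantified$peptide_class %in% c("semi-tryptic-N", "semi-tryptic-C") &
         isTRUE_vec(quantified$scaled) & quantified$ratio < 1),
    , drop = FALSE]
  keep <- intersect(c("sequence", "peptide_class", "start", "end", "ratio",
                      "log2_ratio", "z", "scaled", "orientation"), names(cand))
  spans <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    hit <- cand$protein_id == calls$protein_id[[i]] &
      cand$start <= calls$p1[[i]] & cand$end >= calls$p1p[[i]]
    sp <- cand[hit %in% TRUE, keep, drop = FALSE]
    if (nrow(sp) > 0) {
      tryp <- sp$peptide_class == "fully-tryptic"
      sp$verdict <- dplyr::case_when(
        tryp & !is.na(sp$z) & sp$z > config$z_threshold ~ "supportive",
        tryp & !is.na(sp$z) & sp$z < -config$z_threshold ~ "contrary",
        TRUE ~ "neutral"
      )
    } else {
      sp$verdict <- character()
    }
    spans[[i]] <- sp
  }
  calls$spanning <- spans
  calls$n_spanning <- vapply(spans, nrow, integer(1))
  calls$n_supportive_spanning <- vapply(
    spans, function(s) sum(s$verdict == "supportive"), integer(1))
  calls
}

#' Tabulate cleavage calls for reporting
#'
#' Produces the flat per-site report: positions, residue labels in
#' Ala734-Leu735 style, domain annotation, best z (rounded to one decimal in
#' the report, full precision retained upstream), evidence counts and time
#' points.
#'
#' @param calls A `cleavage_calls` tibble (optionally after
#'   [spanning_support()]).
#' @param proteins A [protein_record()] or list of them (domain annotation is
#'   taken from these records).
#' @return Tibble ready to be written as TSV.
#' @export
site_report <- function(calls, proteins) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  proteins <- stats::setNames(proteins, vapply(proteins, `[[`, character(1), "id"))
  n <- nrow(calls)
  domain <- character(n)
  for (i in seq_len(n)) {
    domain[[i]] <- annotate_position(proteins[[calls$protein_id[[i]]]], calls$p1[[i]])
  }
  tibble::tibble(
    protein = calls$protein_id,
    p1 = calls$p1,
    p1_prime = calls$p1p,
    site = calls$site,
    domain = domain,
    best_z = round(calls$best_z, 1),
    n_supporting = calls$n_support,
    n_spanning = if ("n_spanning" %in% names(calls)) calls$n_spanning else NA_integer_,
    timepoints = calls$timepoints
  )
}

#' Denominator-only semi-tryptic peptides
#'
#' Semi-tryptic peptides found only in the denominator (inactive-enzyme)
#' condition are reported separately: they are not cleavage evidence for the
#' active enzyme, but when one spans a called bond it corroborates the call
#' (the intact stretch is preserved in the control).
#'
#' @param quantified Quantified peptide tibble.
#' @param calls Optional `cleavage_calls` tibble; when given, each peptide is
#'   flagged if it spans any called bond.
#' @return Tibble of denominator-only semi-tryptic peptides with
#'   `spans_called_site`.
#' @export
denominator_only_peptides <- function(quantified, calls = NULL) {
  quantified <- tibble::as_tibble(quantified)
  semi <- quantified$peptide_class %in% c("semi-tryptic-N", "semi-tryptic-C")
  only <- semi & isTRUE_vec(quantified$scaled) & quantified$ratio < 1
  tbl <- quantified[only %in% TRUE, , drop = FALSE]
  tbl$spans_called_site <- FALSE
  if (!is.null(calls) && nrow(calls) > 0 && nrow(tbl) > 0) {
    for (i in seq_len(nrow(tbl))) {
      tbl$spans_called_site[[i]] <- any(
        calls$protein_id == tbl$protein_id[[i]] &
          calls$p1 >= tbl$start[[i]] & calls$p1p <= tbl$end[[i]]
      )
    }
  }
  tbl
}
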