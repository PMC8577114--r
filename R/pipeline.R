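# End-to-end orchestration: table parsing, the classify -> quantify -> call
# chain per run, cross-run merging, reports and a machine-readable summary.

#' Read a peptide-level quantitation table
#'
#' Accepts TSV or CSV (by extension) with the canonical schema: a `sequence`
#' column, a `modifications` column (semicolon-separated `pos:name` entries,
#' empty for none) and one `abundance:<condition>:<replicate>` column per
#' condition/replicate. Blank abundance cells are absent (`NA`), never zero.
#' Malformed rows (invalid residues, unparseable or out-of-range
#' modifications, negative abundances) are rejected with a warning naming
#' their line numbers; duplicated (sequence, modifications) rows are
#' aggregated by summation with a warning.
#'
#' @param path Path to a TSV/CSV file, or a data frame already in the schema.
#' @return Tibble with columns `sequence`, `modifications` and the abundance
#'   columns.
#' @export
read_peptide_table <- function(path) {
  if (is.data.frame(path)) {
    tbl <- tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) stop("peptide table not found: ", path, call. = FALSE)
    reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv
              else readr::read_tsv
    hdr <- names(reader(path, n_max = 0, show_col_types = FALSE, progress = FALSE))
    if (!all(c("sequence", "modifications") %in% hdr)) {
      stop("peptide table is missing required column(s): ",
           paste(setdiff(c("sequence", "modifications"), hdr), collapse = ", "),
           call. = FALSE)
    }
    spec <- readr::cols(.default = readr::col_character())
    for (col in grep("^abundance:[^:]+:[^:]+$", hdr, value = TRUE)) {
      spec$cols[[col]] <- readr::col_double()
    }
    tbl <- reader(path, col_types = spec, progress = FALSE)
  }
  required <- c("sequence", "modifications")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("peptide table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ab_cols <- grep("^abundance:[^:]+:[^:]+$", names(tbl), value = TRUE)
  if (length(ab_cols) == 0) {
    stop("peptide table has no 'abundance:<condition>:<replicate>' columns",
         call. = FALSE)
  }
  tbl$modifications[is.na(tbl$modifications)] <- ""

  seq_ok <- !is.na(tbl$sequence) & nzchar(tbl$sequence) &
    grepl(paste0("^[", paste(c(AA_LETTERS, "X"), collapse = ""), "]+$"),
          toupper(tbl$sequence))
  ab_neg <- rowSums(as.matrix(tbl[, ab_cols, drop = FALSE]) < 0, na.rm = TRUE) > 0
  mods_ok <- !nzchar(trimws(tbl$modifications))
  for (i in which(!mods_ok)) {
    mods_ok[[i]] <- seq_ok[[i]] &&
      !identical(parse_modifications(tbl$modifications[[i]], tbl$sequence[[i]]), FALSE)
  }
  bad <- !(seq_ok & !ab_neg & mods_ok)
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
    tbl <- tbl[!bad, , drop = FALSE]
  }

  key <- paste(tbl$sequence, tbl$modifications, sep = "\r")
  if (anyDuplicated(key)) {
    warning("aggregated ", sum(duplicated(key)),
            " duplicated (sequence, modifications) row(s) by summation",
            call. = FALSE)
    tbl <- dplyr::summarise(
      dplyr::group_by(tbl, .data$sequence, .data$modifications),
      dplyr::across(dplyr::all_of(ab_cols),
                    ~ if (all(is.na(.x))) NA_real_ else sum(.x, na.rm = TRUE)),
      .groups = "drop")
  }
  tbl
}

# Parse "pos:name;pos:name" against the allowed modification set; returns a
# tibble (possibly empty) or FALSE when malformed.
parse_modifications <- function(modifications, sequence) {
  if (is.na(modifications) || !nzchar(trimws(modifications))) {
    return(tibble::tibble(position = integer(), name = character()))
  }
  parts <- strsplit(trimws(modifications), ";", fixed = TRUE)[[1]]
  out <- tibble::tibble(position = integer(), name = character())
  for (p in trimws(parts)) {
    m <- regmatches(p, regexec("^([0-9]+):(.+)$", p))[[1]]
    if (length(m) != 3) return(FALSE)
    pos <- as.integer(m[[2]]); name <- trimws(m[[3]])
    if (pos < 1L || pos > nchar(sequence)) return(FALSE)
    row <- ALLOWED_MODIFICATIONS[ALLOWED_MODIFICATIONS$name == name, ]
    if (nrow(row) == 0) return(FALSE)
    residue <- substr(toupper(sequence), pos, pos)
    if (row$residues != "*" && !grepl(residue, row$residues, fixed = TRUE)) return(FALSE)
    if (row$nterm_only && pos != 1L) return(FALSE)
    out <- dplyr::bind_rows(out, tibble::tibble(position = pos, name = name))
  }
  out
}

#' Pipeline run configuration
#'
#' @param fasta Path to a FASTA file or a list of [protein_record()]s.
#' @param tables Named list of peptide tables (paths or data frames); names
#'   are time-point labels (e.g. `"2h"`, `"24h"`). An unnamed single table
#'   gets the label `"run1"`.
#' @param domains Optional domain config: a YAML path or a named list of
#'   domain tibbles, applied to matching proteins.
#' @param comparison A [comparison_config()].
#' @param rules A [digestion_rules()].
#' @param il_equivalent Treat I/L as identical when locating peptides.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fasta, tables, domains = NULL,
                       comparison = comparison_config(),
                       rules = digestion_rules(),
                       il_equivalent = FALSE, out_dir = NULL) {
  if (!is.list(tables) || is.data.frame(tables)) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("run", seq_along(tables))
  }
  structure(
    list(fasta = fasta, tables = tables, domains = domains,
         comparison = comparison, rules = rules,
         il_equivalent = il_equivalent, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full cleavage-site mapping pipeline
#'
#' For every time-point table: parse, locate against the FASTA, classify
#' termini, quantify (replicate aggregation, scaled ratios, log2, per-class
#' z, strict significance; degenerate dispersion falls back to the
#' scaled-peptide rule with a warning) and call sites. Calls are then merged
#' across time points, spanning-peptide evidence and domain annotation are
#' attached, and reports are written when `out_dir` is set. Stage counts are
#' logged to standard error. The pipeline is fully deterministic.
#'
#' @param config A [run_config()].
#' @return List: `calls` (merged `cleavage_calls`), `report` (site report
#'   tibble), `quantified` (combined peptide tibble with `timepoint`),
#'   `significant`, `denominator_only`, `proteins`, `log` (stage-count
#'   tibble).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  proteins <- if (is.character(config$fasta)) read_fasta(config$fasta)
              else config$fasta
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  proteins <- stats::setNames(proteins, vapply(proteins, `[[`, character(1), "id"))
  if (length(proteins) == 0) stop("no proteins supplied", call. = FALSE)

  if (!is.null(config$domains)) {
    dom <- if (is.character(config$domains)) read_domain_config(config$domains)
           else config$domains
    for (id in intersect(names(dom), names(proteins))) {
      proteins[[id]] <- set_domains(proteins[[id]], dom[[id]])
    }
  }

  all_quant <- list()
  call_sets <- list()
  log_rows <- list()
  for (tp in names(config$tables)) {
    tbl <- read_peptide_table(config$tables[[tp]])
    if (nrow(tbl) == 0) stop("peptide table '", tp, "' is empty", call. = FALSE)
    located <- locate_peptides(tbl, proteins, il_equivalent = config$il_equivalent)
    classified <- classify_termini(located, proteins, config$rules)
    quantified <- quantify_peptides(classified, config$comparison,
                                    on_degenerate = "fallback")
    quantified$timepoint <- tp
    sig <- significant_set(quantified, config$comparison)
    sig_semi <- sig[sig$peptide_class %in% c("semi-tryptic-N", "semi-tryptic-C"), ,
                    drop = FALSE]
    calls_tp <- call_sites(sig_semi, proteins, timepoint = tp)
    all_quant[[tp]] <- quantified
    call_sets[[tp]] <- calls_tp

    counts <- table(factor(classified$peptide_class,
                           levels = c("fully-tryptic", "semi-tryptic-N",
                                      "semi-tryptic-C", "non-tryptic")))
    log_rows[[tp]] <- tibble::tibble(
      timepoint = tp,
      n_read = nrow(tbl),
      n_unmatched = sum(classified$exclude_reason %in% "unmatched"),
      n_ambiguous = sum(classified$exclude_reason %in% "ambiguous"),
      n_located = sum(classified$located),
      n_fully_tryptic = as.integer(counts[["fully-tryptic"]]),
      n_semi_tryptic = as.integer(counts[["semi-tryptic-N"]] +
                                    counts[["semi-tryptic-C"]]),
      n_non_tryptic = as.integer(counts[["non-tryptic"]]),
      n_quantified = nrow(quantified),
      n_significant = nrow(sig),
      n_calls = nrow(calls_tp)
    )
    message(sprintf(
      "[cleavemap] %s: read %d, located %d (unmatched %d, ambiguous %d), quantified %d, significant %d, calls %d",
      tp, nrow(tbl), sum(classified$located),
      log_rows[[tp]]$n_unmatched, log_rows[[tp]]$n_ambiguous,
      nrow(quantified), nrow(sig), nrow(calls_tp)))
  }

  quantified_all <- dplyr::bind_rows(all_quant)
  calls <- merge_evidence(call_sets)
  calls <- spanning_support(calls, quantified_all, config$comparison)
  report <- site_report(calls, proteins)
  significant <- significant_set(quantified_all, config$comparison)
  den_only <- denominator_only_peptides(quantified_all, calls)

  result <- list(calls = calls, report = report, quantified = quantified_all,
                 significant = significant, denominator_only = den_only,
                 proteins = proteins, log = dplyr::bind_rows(log_rows))
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  invisible(result)
}

flatten_for_tsv <- function(tbl) {
  tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$report, file.path(out_dir, "site_report.tsv"))
  readr::write_tsv(flatten_for_tsv(result$significant),
                   file.path(out_dir, "significant_peptides.tsv"))
  readr::write_tsv(flatten_for_tsv(result$denominator_only),
                   file.path(out_dir, "denominator_only_peptides.tsv"))
  summary <- list(
    stages = result$log,
    n_calls = nrow(result$calls),
    sites = result$report$site
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
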