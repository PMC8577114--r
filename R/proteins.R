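#' Construct a protein record
#'
#' A protein record holds one amino-acid sequence under 1-based residue
#' numbering together with optional named domain intervals (inclusive ends).
#' All coordinates reported by the package (peptide locations, scissile bonds,
#' motif matches) refer to this numbering.
#'
#' @param id Accession or identifier (scalar character).
#' @param sequence Amino-acid sequence: the 20 standard one-letter codes,
#'   optionally `X` for an unknown residue.
#' @param domains Optional `data.frame`/tibble with columns `name`, `start`,
#'   `end` (1-based, inclusive, inside the sequence).
#' @param nterm_boundaries Integer positions that count as annotated protein
#'   N termini (mature-form start sites). Positions 1 and 2 (initiator-Met
#'   removal) are always included.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, domains = NULL, nterm_boundaries = integer()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  sequence <- sub("\\*$", "", sequence)  # tolerate a terminal stop symbol
  if (!nzchar(sequence)) stop("protein '", id, "': sequence is empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA_LETTERS, "X"))
  if (length(bad) > 0) {
    stop("protein '", id, "': invalid residue character(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  n <- nchar(sequence)
  domains <- validate_domains(domains, n, id)
  nterm_boundaries <- sort(unique(c(1L, 2L, as.integer(nterm_boundaries))))
  structure(
    list(id = id, sequence = sequence, length = n, domains = domains,
         nterm_boundaries = nterm_boundaries),
    class = "protein_record"
  )
}

validate_domains <- function(domains, n, id) {
  if (is.null(domains)) {
    return(tibble::tibble(name = character(), start = integer(), end = integer()))
  }
  domains <- tibble::as_tibble(domains)
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  ok <- domains$start >= 1L & domains$start <= domains$end & domains$end <= n
  if (!all(ok)) {
    stop("protein '", id, "': domain interval(s) outside [1, ", n, "]: ",
         paste(domains$name[!ok], collapse = ", "), call. = FALSE)
  }
  domains[, c("name", "start", "end")]
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", x$length, " aa, ",
      nrow(x$domains), " domain(s))\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Wrapped or unwrapped FASTA is accepted; sequences are uppercased, a terminal
#' `*` is stripped, and the first whitespace-delimited token of each header
#' becomes the record id. Non-residue characters are rejected with an error
#' naming the character and the file line carrying it.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [protein_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("FASTA file is empty: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  # Validate residues up front so the error can cite the offending file line.
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), c(AA_LETTERS, "X"))
    if (length(bad) > 0) {
      lines <- readLines(path, warn = FALSE)
      hit <- grep(bad[[1]], lines, fixed = TRUE)
      hit <- hit[!startsWith(trimws(lines[hit]), ">")]
      stop("FASTA '", path, "', record '", ids[[i]], "': invalid residue character ",
           sQuote(bad[[1]]),
           if (length(hit) > 0) paste0(" on line ", hit[[1]]) else "",
           call. = FALSE)
    }
  }
  records <- lapply(seq_along(seqs), function(i) protein_record(ids[[i]], seqs[[i]]))
  stats::setNames(records, ids)
}

#' Read a domain-annotation config (YAML)
#'
#' The config maps protein ids to lists of named intervals:
#' ```yaml
#' SYN_ADAMTS8:
#'   - {name: Sp, start: 690, end: 831}
#' ```
#'
#' @param path Path to a YAML file.
#' @return Named list of tibbles with columns `name`, `start`, `end`.
#' @export
read_domain_config <- function(path) {
  if (!file.exists(path)) stop("domain config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(entries) {
    dplyr::bind_rows(lapply(entries, tibble::as_tibble))
  })
}

#' Attach domain annotations to a protein record
#'
#' @param protein A [protein_record()].
#' @param domains Tibble with columns `name`, `start`, `end`.
#' @return The protein record with domains replaced.
#' @export
set_domains <- function(protein, domains) {
  stopifnot(inherits(protein, "protein_record"))
  protein$domains <- validate_domains(domains, protein$length, protein$id)
  protein
}

#' Name the domain containing a residue position
#'
#' Interval ends are inclusive; when intervals overlap the first-listed one
#' wins; positions outside every interval return `"inter-domain"`.
#'
#' @param protein A [protein_record()] with domains.
#' @param pos Residue position(s), 1-based.
#' @return Character vector of domain names.
#' @export
annotate_position <- function(protein, pos) {
  stopifnot(inherits(protein, "protein_record"))
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > protein$length)) {
    stop("position out of range [1, ", protein$length, "] for '", protein$id, "'",
         call. = FALSE)
  }
  vapply(pos, function(p) {
    hit <- which(protein$domains$start <= p & protein$domains$end >= p)
    if (length(hit) == 0) "inter-domain" else protein$domains$name[[hit[[1]]]]
  }, character(1))
}

#' Map osteopontin isoform-b coordinates onto isoform a
#'
#' OPN isoform b lacks residues 58-71 of isoform a (a 14-residue deletion), so
#' positions below 58 are shared and positions from 58 onward shift by +14.
#'
#' @param pos_b Residue position(s) in isoform-b numbering (>= 1).
#' @return Residue position(s) in isoform-a numbering.
#' @export
map_isoform_coord <- function(pos_b) {
  pos_b <- as.integer(pos_b)
  if (any(is.na(pos_b)) || any(pos_b < 1L)) {
    stop("isoform positions must be positive integers", call. = FALSE)
  }
  ifelse(pos_b < 58L, pos_b, pos_b + 14L)
}
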