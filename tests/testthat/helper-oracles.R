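# Brute-force reference implementations, kept deliberately naive and
# independent of the package's internals.

random_sequence <- function(n, letters = c("A", "C", "D", "E", "F", "G", "H", "I",
                                           "K", "L", "M", "N", "P", "Q", "R", "S",
                                           "T", "V", "W", "Y")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# All start positions where an X/B motif matches, by sliding window.
oracle_motif_starts <- function(sequence, pattern, basic = c("K", "R"),
                                x_excludes_basic = FALSE) {
  res <- strsplit(sequence, "")[[1]]
  sym <- strsplit(pattern, "")[[1]]
  m <- length(sym)
  n <- length(res)
  hits <- integer()
  for (i in seq_len(max(0L, n - m + 1L))) {
    ok <- TRUE
    for (k in seq_len(m)) {
      r <- res[[i + k - 1L]]
      if (sym[[k]] == "B") {
        if (!(r %in% basic)) { ok <- FALSE; break }
      } else if (x_excludes_basic && r %in% basic) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_sequon_starts <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  hits <- integer()
  for (i in seq_len(max(0L, n - 2L))) {
    if (res[[i]] == "N" && res[[i + 1L]] != "P" && res[[i + 2L]] %in% c("S", "T")) {
      hits <- c(hits, i)
    }
  }
  hits
}

# Enumerate every substring and test its boundaries and internal missed
# cleavages directly against the trypsin rule.
oracle_digest <- function(sequence, cleave_after = c("K", "R"),
                          proline_block = TRUE, max_missed = 2L) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_ok <- function(k) {      # is the bond after residue k a tryptic cut?
    res[[k]] %in% cleave_after && !(proline_block && res[[k + 1L]] == "P")
  }
  out <- character()
  for (i in 1:n) for (j in i:n) {
    start_ok <- i == 1L || cut_ok(i - 1L)
    end_ok <- j == n || cut_ok(j)
    if (!start_ok || !end_ok) next
    internal <- if (j > i) sum(vapply(i:(j - 1L), cut_ok, logical(1))) else 0L
    if (internal <= max_missed) out <- c(out, paste(i, j, sep = "-"))
  }
  sort(out)
}

# Every (protein, position) at which the peptide occurs as an exact substring.
oracle_locate <- function(peptide, sequences) {
  hits <- list()
  m <- nchar(peptide)
  for (id in names(sequences)) {
    s <- sequences[[id]]
    for (i in seq_len(max(0L, nchar(s) - m + 1L))) {
      if (substr(s, i, i + m - 1L) == peptide) {
        hits[[length(hits) + 1L]] <- c(id = id, start = i)
      }
    }
  }
  hits
}

oracle_spans <- function(start, end, p1) {
  start <= p1 && end >= p1 + 1L
}
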