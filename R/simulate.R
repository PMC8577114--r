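# Synthetic-experiment generator: emulates a two-condition (active WT enzyme
# vs inactive EQ mutant) label-free degradomics experiment with technical
# replicates, a tryptic background, semi-tryptic peptides at planted cleavage
# sites, condition-balanced contaminant cleavages, log-normal abundance noise
# and abundance-dependent dropout. Fully deterministic given the seed.

#' Simulation configuration
#'
#' The default design mirrors the structure of a purified-enzyme digest
#' experiment as seen by a search engine: a substrate protein plus a large
#' co-purifying background (conditioned-medium proteins), trypsinised with up
#' to two missed cleavages; protease products appear only in the numerator
#' (WT) condition while contaminant (in-source/background) cleavages are
#' condition-balanced, so the z statistic sees protease products as outliers
#' against a majority of balanced semi-tryptic peptides.
#'
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param substrate Optional [protein_record()]; by default a random protein
#'   of `substrate_length` residues is generated.
#' @param substrate_length Length of the random substrate (default 1000).
#' @param background_length Length of the random co-purifying background
#'   protein (default 8000; 0 disables it).
#' @param n_sites Number of planted cleavage sites (default 20) when
#'   `planted_sites` is not given.
#' @param planted_sites Optional tibble with columns `p1` and `efficiency`
#'   (in substrate coordinates) to plant explicitly.
#' @param efficiency_range Range for randomly drawn site efficiencies.
#' @param replicates Technical replicates per condition (default 2).
#' @param baseline_log2_mean,baseline_log2_sd Log2 baseline abundance model
#'   for every peptide (defaults 20 and 1).
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise (default 0.2).
#' @param dropout Dropout probability at the baseline mean abundance
#'   (default 0.1).
#' @param dropout_slope Slope (per log2 unit) of the logistic
#'   abundance-dependent dropout; 0 gives uniform dropout (default 0.3).
#' @param contaminant_rate Per-bond probability of a condition-balanced
#'   background cleavage (default 0.02).
#' @param sides `"single"` (default): each cleavage event yields one
#'   observable fragment; `"both"`: all length-valid fragments.
#' @param peptide_length_range Observable peptide lengths (default 6-40).
#' @param rules [digestion_rules()] used for the tryptic background and for
#'   bounding semi-tryptic fragments.
#' @param numerator,denominator Condition labels (defaults `"WT"`, `"EQ"`).
#' @param strict Error (instead of warn) when an explicitly planted site is
#'   blind to the method (P1 is K/R with a non-proline successor).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              substrate = NULL,
                              substrate_length = 1000L,
                              background_length = 8000L,
                              n_sites = 20L,
                              planted_sites = NULL,
                              efficiency_range = c(0.5, 1),
                              replicates = 2L,
                              baseline_log2_mean = 20,
                              baseline_log2_sd = 1,
                              replicate_cv = 0.2,
                              dropout = 0.1,
                              dropout_slope = 0.3,
                              contaminant_rate = 0.02,
                              sides = c("single", "both"),
                              peptide_length_range = c(6L, 40L),
                              rules = digestion_rules(),
                              numerator = "WT", denominator = "EQ",
                              strict = FALSE) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation", call. = FALSE)
  stopifnot(dropout >= 0, dropout <= 1, contaminant_rate >= 0, contaminant_rate <= 1,
            replicate_cv >= 0, replicates >= 1)
  structure(
    list(seed = as.integer(seed), substrate = substrate,
         substrate_length = as.integer(substrate_length),
         background_length = as.integer(background_length),
         n_sites = as.integer(n_sites), planted_sites = planted_sites,
         efficiency_range = efficiency_range, replicates = as.integer(replicates),
         baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
         replicate_cv = replicate_cv, dropout = dropout,
         dropout_slope = dropout_slope, contaminant_rate = contaminant_rate,
         sides = match.arg(sides),
         peptide_length_range = as.integer(peptide_length_range),
         rules = rules, numerator = numerator, denominator = denominator,
         strict = strict),
    class = "simulation_config"
  )
}

# Length-valid semi-tryptic fragments exposing bond (b, b+1): the exposed
# terminus sits at the bond, the other terminus at a tryptic cut (or protein
# end) within the missed-cleavage budget. At most one fragment per side (the
# smallest valid one). Returns a list of parallel vectors (hot path: no
# tibble construction here).
semi_fragments_for_bond <- function(b, cuts, n, rules, len_range) {
  bounds <- c(0L, cuts, n)
  side <- character(); start <- integer(); end <- integer()
  # N-side: starts at b+1, ends at a downstream boundary
  ends <- bounds[bounds > b]
  kmax <- min(length(ends), rules$max_missed + 1L)
  for (k in seq_len(kmax)) {
    len <- ends[[k]] - b
    if (len >= len_range[[1]] && len <= len_range[[2]]) {
      side <- c(side, "N"); start <- c(start, b + 1L); end <- c(end, ends[[k]])
      break
    }
  }
  # C-side: ends at b, starts after an upstream boundary
  starts <- rev(bounds[bounds < b]) + 1L
  kmax <- min(length(starts), rules$max_missed + 1L)
  for (k in seq_len(kmax)) {
    len <- b - starts[[k]] + 1L
    if (len >= len_range[[1]] && len <= len_range[[2]]) {
      side <- c(side, "C"); start <- c(start, starts[[k]]); end <- c(end, b)
      break
    }
  }
  list(side = side, start = start, end = end, n = length(side))
}

#' Simulate a label-free degradomics experiment
#'
#' Generates the peptide-level quantitation table (canonical schema:
#' `sequence`, `modifications`, `abundance:<condition>:<replicate>`) together
#' with the ground truth needed for parameter-recovery scoring.
#'
#' @param config A [simulation_config()].
#' @return List with elements `table` (tibble), `truth` (list: `planted`
#'   sites tibble, `peptides` origin tibble, `config` echo) and `proteins`
#'   (list of [protein_record()]).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(config) {
  rules <- config$rules
  len_range <- config$peptide_length_range

  substrate <- config$substrate
  if (is.null(substrate)) {
    substrate <- protein_record(
      "SYN_SUBSTRATE",
      paste(sample_residues(config$substrate_length), collapse = ""))
  }
  proteins <- list(substrate)
  if (config$background_length > 0) {
    proteins <- c(proteins, list(protein_record(
      "SYN_BACKGROUND",
      paste(sample_residues(config$background_length), collapse = ""))))
  }
  names(proteins) <- vapply(proteins, `[[`, character(1), "id")

  # tryptic background, both conditions
  peps <- list()
  for (prot in proteins) {
    dg <- digest_protein(prot, rules)
    dg <- dg[nchar(dg$sequence) >= len_range[[1]] &
               nchar(dg$sequence) <= len_range[[2]], , drop = FALSE]
    if (nrow(dg) > 0) {
      m <- nrow(dg)
      peps[[length(peps) + 1L]] <- list(
        protein_id = rep(prot$id, m), start = dg$start, end = dg$end,
        sequence = dg$sequence, origin = rep("tryptic", m),
        bond = rep(NA_integer_, m), efficiency = rep(1, m),
        in_num = rep(TRUE, m), in_den = rep(TRUE, m))
    }
  }

  # planted protease sites on the substrate
  cuts_sub <- cut_positions(substrate$sequence, rules)
  res_sub <- strsplit(substrate$sequence, "")[[1]]
  n_sub <- substrate$length
  blind_bond <- function(b) {
    res_sub[[b]] %in% rules$cleave_after &&
      !(rules$proline_block && res_sub[[b + 1L]] == "P")
  }
  planted <- config$planted_sites
  if (is.null(planted)) {
    eligible <- which(!(res_sub[seq_len(n_sub - 1L)] %in% rules$cleave_after))
    eligible <- eligible[vapply(eligible, function(b) {
      semi_fragments_for_bond(b, cuts_sub, n_sub, rules, len_range)$n > 0
    }, logical(1))]
    if (length(eligible) < config$n_sites) {
      stop("substrate has only ", length(eligible), " eligible bonds for ",
           config$n_sites, " planted sites", call. = FALSE)
    }
    planted <- tibble::tibble(
      p1 = sort(sample(eligible, config$n_sites)),
      efficiency = stats::runif(config$n_sites, config$efficiency_range[[1]],
                                config$efficiency_range[[2]]))
  } else {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("p1", "efficiency") %in% names(planted)))
    planted$p1 <- as.integer(planted$p1)
    stopifnot(all(planted$p1 >= 1L & planted$p1 < n_sub))
  }
  planted$blind <- vapply(planted$p1, blind_bond, logical(1))
  if (any(planted$blind)) {
    msg <- paste0("planted site(s) at P1 = ",
                  paste(planted$p1[planted$blind], collapse = ", "),
                  " are invisible to the semi-tryptic method (P1 is a tryptic residue)")
    if (config$strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  emit_fragments <- function(b, protein, cuts, balanced, efficiency, origin) {
    frag <- semi_fragments_for_bond(b, cuts, protein$length, rules, len_range)
    if (frag$n == 0) return(NULL)
    pick <- if (config$sides == "single" && frag$n > 1) sample(frag$n, 1L)
            else seq_len(frag$n)
    list(protein_id = rep(protein$id, length(pick)),
         start = frag$start[pick], end = frag$end[pick],
         sequence = substring(protein$sequence, frag$start[pick], frag$end[pick]),
         origin = rep(origin, length(pick)), bond = rep(b, length(pick)),
         efficiency = rep(efficiency, length(pick)),
         in_num = rep(TRUE, length(pick)), in_den = rep(balanced, length(pick)))
  }

  planted$detectable <- FALSE
  for (i in seq_len(nrow(planted))) {
    fr <- emit_fragments(planted$p1[[i]], substrate, cuts_sub, balanced = FALSE,
                         efficiency = planted$efficiency[[i]], origin = "planted")
    if (!is.null(fr)) {
      planted$detectable[[i]] <- TRUE
      peps[[length(peps) + 1L]] <- fr
    }
  }

  # condition-balanced contaminant cleavages across all proteins
  for (prot in proteins) {
    res <- strsplit(prot$sequence, "")[[1]]
    cuts <- if (prot$id == substrate$id) cuts_sub else cut_positions(prot$sequence, rules)
    cand <- which(!(res[seq_len(prot$length - 1L)] %in% rules$cleave_after))
    if (prot$id == substrate$id) cand <- setdiff(cand, planted$p1)
    hit <- cand[stats::runif(length(cand)) < config$contaminant_rate]
    for (b in hit) {
      fr <- emit_fragments(b, prot, cuts, balanced = TRUE, efficiency = 1,
                           origin = "contaminant")
      if (!is.null(fr)) peps[[length(peps) + 1L]] <- fr
    }
  }

  field <- function(f) unlist(lapply(peps, `[[`, f), use.names = FALSE)
  peptides <- tibble::tibble(
    protein_id = field("protein_id"), start = field("start"),
    end = field("end"), sequence = field("sequence"), origin = field("origin"),
    bond = field("bond"), efficiency = field("efficiency"),
    in_num = field("in_num"), in_den = field("in_den"))
  # identical sequences from distinct loci would be ambiguous downstream; keep
  # one row per sequence (first occurrence)
  peptides <- peptides[!duplicated(peptides$sequence), , drop = FALSE]

  # abundance model: per-peptide log2 baseline; planted products scaled by
  # efficiency; multiplicative replicate noise; abundance-dependent dropout
  n_pep <- nrow(peptides)
  base_log2 <- stats::rnorm(n_pep, config$baseline_log2_mean, config$baseline_log2_sd)
  base_log2 <- base_log2 + ifelse(peptides$origin == "planted",
                                  log2(peptides$efficiency), 0)
  p_drop <- if (config$dropout <= 0) {
    rep(0, n_pep)
  } else if (config$dropout >= 1) {
    rep(1, n_pep)
  } else {
    stats::plogis(stats::qlogis(config$dropout) -
                    config$dropout_slope * (base_log2 - config$baseline_log2_mean))
  }
  sigma <- sqrt(log(1 + config$replicate_cv^2))

  tbl <- tibble::tibble(sequence = peptides$sequence, modifications = "")
  for (cond in c(config$numerator, config$denominator)) {
    present <- if (cond == config$numerator) peptides$in_num else peptides$in_den
    for (r in seq_len(config$replicates)) {
      value <- 2^base_log2 * exp(stats::rnorm(n_pep, 0, sigma))
      value[!present] <- NA_real_
      value[stats::runif(n_pep) < p_drop] <- NA_real_
      tbl[[paste0("abundance:", cond, ":", r)]] <- value
    }
  }

  truth <- list(
    planted = planted[, c("p1", "efficiency", "blind", "detectable")],
    peptides = peptides[, c("protein_id", "start", "end", "sequence", "origin",
                            "bond", "in_num", "in_den")],
    substrate_id = substrate$id,
    config = config
  )
  list(table = tbl, truth = truth, proteins = proteins)
}

#' Score cleavage calls against simulation truth
#'
#' Recall is computed over planted sites visible to the method (non-blind;
#' blind sites, whose P1 is itself a tryptic residue, are excluded by
#' default). Precision is computed over all calls on the substrate; with no
#' calls it is undefined and reported as `NA`.
#'
#' @param calls A `cleavage_calls` tibble.
#' @param truth Truth list from [simulate_experiment()].
#' @param include_blind Count blind planted sites in the recall denominator
#'   (default FALSE).
#' @return List: `recall`, `precision`, `n_calls`, `sites` (per planted site
#'   detection table), `false_calls`.
#' @export
score_calls <- function(calls, truth, include_blind = FALSE) {
  planted <- truth$planted
  eval_sites <- if (include_blind) planted else planted[!planted$blind, , drop = FALSE]
  sub_calls <- calls[calls$protein_id == truth$substrate_id, , drop = FALSE]
  eval_sites$detected <- eval_sites$p1 %in% sub_calls$p1
  true_call <- calls$protein_id == truth$substrate_id & calls$p1 %in% planted$p1
  n_calls <- nrow(calls)
  list(
    recall = if (nrow(eval_sites) == 0) NA_real_ else mean(eval_sites$detected),
    precision = if (n_calls == 0) NA_real_ else sum(true_call) / n_calls,
    n_calls = n_calls,
    sites = eval_sites,
    false_calls = calls[!true_call, , drop = FALSE]
  )
}
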