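# Condition comparison: replicate aggregation, ratios with the scaled
# fold-change convention for one-condition peptides, log2 transform, and the
# per-class z statistic.

#' Comparison configuration
#'
#' Defaults follow the active-versus-inactive (WT vs EQ) design: semi-tryptic
#' peptides are compared as numerator/denominator (WT/EQ); fully tryptic
#' peptides, whose informative direction is elevated abundance in the
#' inactive control, as denominator/numerator (EQ/WT). Peptides observed in
#' only one condition receive the scaled fold-change (default 100, i.e. log2
#' ratio 6.64) so that they can still be z-scored.
#'
#' @param numerator,denominator Condition labels (defaults `"WT"`, `"EQ"`).
#' @param scaled_fold_change Imputed ratio for one-condition peptides (> 1).
#' @param z_threshold Significance threshold; significance is strict
#'   (`z > z_threshold`).
#' @param tryptic_direction `"den/num"` (default) or `"num/den"`: ratio
#'   orientation used for the fully tryptic population.
#' @param include_scaled_in_moments Include scaled peptides in the mean/sd of
#'   the z computation (default TRUE).
#' @param replicate_aggregation `"mean"` (default) or `"sum"` over observed
#'   replicates.
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`.
#' @return An object of class `comparison_config`.
#' @export
comparison_config <- function(numerator = "WT", denominator = "EQ",
                              scaled_fold_change = 100, z_threshold = 2,
                              tryptic_direction = c("den/num", "num/den"),
                              include_scaled_in_moments = TRUE,
                              replicate_aggregation = c("mean", "sum"),
                              sd_mode = c("sample", "population")) {
  stopifnot(scaled_fold_change > 1, is.finite(z_threshold))
  structure(
    list(numerator = numerator, denominator = denominator,
         scaled_fold_change = scaled_fold_change, z_threshold = z_threshold,
         tryptic_direction = match.arg(tryptic_direction),
         include_scaled_in_moments = include_scaled_in_moments,
         replicate_aggregation = match.arg(replicate_aggregation),
         sd_mode = match.arg(sd_mode)),
    class = "comparison_config"
  )
}

#' Aggregate replicate abundances within one condition
#'
#' Aggregation runs over observed replicates only (missing replicates are
#' dropped, not zero-filled); a condition with no observed replicate is
#' absent (`NA`).
#'
#' @param values Numeric vector of replicate abundances (`NA` = not observed).
#' @param config A [comparison_config()].
#' @return Scalar aggregate or `NA` when nothing was observed.
#' @export
aggregate_replicates <- function(values, config = comparison_config()) {
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) stop("negative abundance", call. = FALSE)
  obs <- values[!is.na(values)]
  if (length(obs) == 0) return(NA_real_)
  switch(config$replicate_aggregation, mean = mean(obs), sum = sum(obs))
}

#' Abundance ratio with the scaled fold-change convention
#'
#' Both conditions present gives the plain ratio; a peptide observed only in
#' the numerator gets the scaled fold-change, only in the denominator its
#' reciprocal (both flagged `scaled`); observed in neither is dropped (`NA`
#' ratio). A present-but-zero denominator is treated as absent.
#'
#' @param num,den Aggregated abundances (vectorised; `NA` = absent).
#' @param config A [comparison_config()].
#' @return Tibble with columns `ratio` and `scaled`.
#' @export
compute_ratio <- function(num, den, config = comparison_config()) {
  stopifnot(length(num) == length(den))
  if (any(num < 0, na.rm = TRUE) || any(den < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  den <- ifelse(!is.na(den) & den == 0, NA_real_, den)
  num <- ifelse(!is.na(num) & num == 0, NA_real_, num)
  sfc <- config$scaled_fold_change
  ratio <- dplyr::case_when(
    !is.na(num) & !is.na(den) ~ num / den,
    !is.na(num) & is.na(den) ~ sfc,
    is.na(num) & !is.na(den) ~ 1 / sfc,
    TRUE ~ NA_real_
  )
  scaled <- xor(is.na(num), is.na(den))
  scaled[is.na(num) & is.na(den)] <- NA
  tibble::tibble(ratio = ratio, scaled = scaled)
}

#' Log2-transform ratios
#'
#' @param ratio Positive ratio(s).
#' @return `log2(ratio)`.
#' @export
log2_transform <- function(ratio) {
  if (any(!is.na(ratio) & ratio <= 0)) {
    stop("ratios must be positive for log2 transformation", call. = FALSE)
  }
  log2(ratio)
}

#' z-score a population of log2 ratios
#'
#' `z_i = (x_i - mean(x)) / sd(x)` over the supplied class population of log2
#' ratios. Scaled peptides can be excluded from the mean/sd (they are always
#' scored). The population must have at least two members and non-zero
#' dispersion.
#'
#' @param log2_ratio Numeric vector of log2 ratios for one peptide class.
#' @param scaled Logical vector flagging scaled (one-condition) peptides.
#' @param config A [comparison_config()].
#' @return Numeric vector of z-scores.
#' @export
compute_zscores <- function(log2_ratio, scaled = rep(FALSE, length(log2_ratio)),
                            config = comparison_config()) {
  x <- log2_ratio
  if (sum(is.finite(x)) < 2L) {
    stop("need at least two peptides with finite log2 ratios to z-score",
         call. = FALSE)
  }
  pool <- if (config$include_scaled_in_moments) x else x[!scaled]
  pool <- pool[is.finite(pool)]
  if (length(pool) < 2L) {
    stop("need at least two peptides in the moment pool to z-score", call. = FALSE)
  }
  mu <- mean(pool)
  s <- stats::sd(pool)
  if (config$sd_mode == "population") {
    s <- sqrt(mean((pool - mu)^2))
  }
  if (!is.finite(s) || s == 0) {
    stop("degenerate dispersion: all log2 ratios in the population are equal",
         call. = FALSE)
  }
  (x - mu) / s
}

#' Quantify classified peptides
#'
#' Runs the full comparison on a located/classified peptide table carrying
#' `abundance:<condition>:<replicate>` columns: replicate aggregation, ratio
#' with the scaled convention in the orientation of each peptide's class
#' (semi-tryptic and non-tryptic: numerator/denominator; fully tryptic: the
#' configured `tryptic_direction`), log2 transform, per-class z-scores and
#' strict significance. Peptides absent from both conditions are dropped.
#'
#' @param classified Tibble from [classify_termini()].
#' @param config A [comparison_config()].
#' @param on_degenerate What to do when a class population has zero
#'   dispersion: `"error"` (default, the statistical contract) or
#'   `"fallback"`, which marks numerator-only scaled peptides significant and
#'   everything else not (used by the pipeline in degenerate limits, with a
#'   warning).
#' @return Input tibble restricted to located, quantifiable rows, plus
#'   `abund_num`, `abund_den`, `ratio`, `log2_ratio`, `scaled`, `z`,
#'   `significant`, `orientation`.
#' @export
quantify_peptides <- function(classified, config = comparison_config(),
                              on_degenerate = c("error", "fallback")) {
  on_degenerate <- match.arg(on_degenerate)
  tbl <- tibble::as_tibble(classified)
  tbl <- tbl[isTRUE_vec(tbl$located), , drop = FALSE]
  if (nrow(tbl) == 0) {
    return(dplyr::mutate(tbl, abund_num = numeric(), abund_den = numeric(),
                         ratio = numeric(), log2_ratio = numeric(),
                         scaled = logical(), z = numeric(),
                         significant = logical(), orientation = character()))
  }
  tbl$abund_num <- aggregate_condition(tbl, config$numerator, config)
  tbl$abund_den <- aggregate_condition(tbl, config$denominator, config)

  semi_like <- tbl$peptide_class %in% c("semi-tryptic-N", "semi-tryptic-C", "non-tryptic")
  flip <- !semi_like & config$tryptic_direction == "den/num"
  num <- ifelse(flip, tbl$abund_den, tbl$abund_num)
  den <- ifelse(flip, tbl$abund_num, tbl$abund_den)
  rr <- compute_ratio(num, den, config)
  tbl$ratio <- rr$ratio
  tbl$scaled <- rr$scaled
  tbl$orientation <- ifelse(
    flip,
    paste0(config$denominator, "/", config$numerator),
    paste0(config$numerator, "/", config$denominator)
  )
  dropped <- is.na(tbl$ratio)
  if (any(dropped)) tbl <- tbl[!dropped, , drop = FALSE]
  tbl$log2_ratio <- log2_transform(tbl$ratio)

  tbl$z <- NA_real_
  tbl$significant <- NA
  for (cls in list(c("semi-tryptic-N", "semi-tryptic-C", "non-tryptic"),
                   "fully-tryptic")) {
    idx <- which(tbl$peptide_class %in% cls)
    if (length(idx) == 0) next
    z <- tryCatch(
      compute_zscores(tbl$log2_ratio[idx], tbl$scaled[idx], config),
      error = function(e) e
    )
    if (inherits(z, "error")) {
      if (on_degenerate == "error") stop(z)
      warning("z-score degenerate for class ", paste(cls, collapse = "/"),
              " (", conditionMessage(z), "); falling back to scaled-peptide rule",
              call. = FALSE)
      sig <- tbl$scaled[idx] & tbl$ratio[idx] > 1
      tbl$significant[idx] <- sig
    } else {
      tbl$z[idx] <- z
      tbl$significant[idx] <- z > config$z_threshold
    }
  }
  tbl
}

aggregate_condition <- function(tbl, condition, config) {
  cols <- grep(paste0("^abundance:", condition, ":"), names(tbl), value = TRUE)
  if (length(cols) == 0) {
    stop("no abundance columns found for condition '", condition, "'", call. = FALSE)
  }
  apply(as.matrix(tbl[, cols, drop = FALSE]), 1L, aggregate_replicates, config = config)
}

#' Significant subset of quantified peptides
#'
#' Strict inequality (`z > threshold`); input row order is preserved.
#'
#' @param quantified Tibble from [quantify_peptides()].
#' @param config A [comparison_config()].
#' @return Subset of rows with `z > z_threshold` (or, after a degenerate
#'   fallback, rows flagged significant).
#' @export
significant_set <- function(quantified, config = comparison_config()) {
  tbl <- tibble::as_tibble(quantified)
  if (nrow(tbl) == 0) return(tbl)
  keep <- ifelse(is.na(tbl$z), isTRUE_vec(tbl$significant),
                 tbl$z > config$z_threshold)
  tbl[keep %in% TRUE, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x
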