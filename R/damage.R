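#' Deamidation damage profiling
#'
#' Percent deamidation of asparagine (N) or glutamine (Q) is estimated
#' per peptide and averaged across peptides; uncertainty comes from a
#' seeded bootstrap that resamples peptides with replacement. Within a
#' peptide, spectra are combined with intensity weights (falling back to
#' MS/MS counts, then to equal weights); across peptides the mean is
#' unweighted by default, since the number of peptides is the natural
#' unit reported alongside each estimate.
#'
#' @name damage
NULL

#' Deamidated fraction of one peptide
#'
#' For each supporting row, `d_r` deamidated residues of the requested
#' type out of `t_r` total, weighted by `w_r` = intensity (fallback
#' `msms_count`, fallback 1): fraction = sum(w_r d_r) / sum(w_r t_r).
#'
#' @param rows Evidence rows, all with the same peptide sequence.
#' @param residue `"N"` or `"Q"`.
#' @return Fraction in `[0, 1]`, or `NA` when the peptide lacks the
#'   residue (such peptides are excluded from aggregation).
#' @export
peptide_fraction <- function(rows, residue = c("N", "Q")) {
  residue <- match.arg(residue)
  stopifnot(nrow(rows) >= 1, length(unique(rows$sequence)) == 1)
  pep <- rows$sequence[[1]]
  sites <- which(chars(pep) == residue)
  if (length(sites) == 0) return(NA_real_)
  t_r <- length(sites)
  num <- 0
  den <- 0
  for (r in seq_len(nrow(rows))) {
    mods <- rows$modifications[[r]]
    d_r <- sum(mods$name == "deamidation" & mods$position %in% sites)
    w_r <- rows$intensity[[r]]
    if (is.na(w_r) || w_r <= 0) w_r <- rows$msms_count[[r]]
    if (is.na(w_r) || w_r <= 0) w_r <- 1
    num <- num + w_r * d_r
    den <- den + w_r * t_r
  }
  num / den
}

#' Estimate percent deamidation with bootstrap uncertainty
#'
#' The point estimate is the unweighted mean of per-peptide deamidated
#' fractions, on a 0-100 scale. The standard deviation is that of the
#' bootstrap distribution obtained by resampling peptides with
#' replacement `B` times under the given seed. Estimates built on 20 or
#' fewer peptides are flagged `low_n`, reflecting the reliability limit
#' usually attached to small peptide counts.
#'
#' @param rows Evidence tibble for one sample.
#' @param residue `"N"` or `"Q"`.
#' @param subgroup Optional character vector of source classes; only
#'   peptides whose proteins map to these classes are used.
#' @param peptide_classes Named peptide -> source_class vector (required
#'   with `subgroup`).
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed (mandatory: bootstrap results are part of the
#'   reported numbers and must be reproducible).
#' @param label Subgroup label stored in the result (defaults to the
#'   subgroup classes or "all").
#' @param low_n_threshold Peptide count at or below which `low_n` is set.
#' @param weight_across Weight peptides by total intensity when averaging
#'   across peptides (default FALSE, i.e. unweighted).
#' @return One-row tibble: `residue`, `percent`, `sd`, `n_peptides`,
#'   `subgroup`, `B`, `seed`, `low_n`.
#' @export
estimate_deamidation <- function(rows, residue = c("N", "Q"), subgroup = NULL,
                                 peptide_classes = NULL, B = 1000, seed,
                                 label = NULL, low_n_threshold = 20,
                                 weight_across = FALSE) {
  residue <- match.arg(residue)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!is.null(subgroup)) {
    if (is.null(peptide_classes)) {
      abort_format("subgroup filtering requires peptide_classes")
    }
    keep <- rows$sequence %in% names(peptide_classes)[peptide_classes %in% subgroup]
    rows <- rows[keep, , drop = FALSE]
  }
  peps <- unique(rows$sequence)
  fracs <- vapply(peps, function(p) {
    peptide_fraction(rows[rows$sequence == p, , drop = FALSE], residue)
  }, numeric(1))
  weights <- vapply(peps, function(p) {
    w <- sum(rows$intensity[rows$sequence == p], na.rm = TRUE)
    if (w <= 0) length(which(rows$sequence == p)) else w
  }, numeric(1))
  keep <- !is.na(fracs)
  fracs <- fracs[keep]
  weights <- weights[keep]
  n <- length(fracs)
  if (n == 0) {
    abort_format("no residues of type %s in the (sub)group's peptides", residue)
  }
  point_of <- function(f, w) {
    if (weight_across) sum(w * f) / sum(w) else mean(f)
  }
  percent <- 100 * point_of(fracs, weights)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      100 * point_of(fracs[idx], weights[idx])
    }, numeric(1))
  })
  sd_boot <- if (length(unique(fracs)) == 1) 0 else stats::sd(boot)
  tibble::tibble(
    residue = residue,
    percent = percent,
    sd = sd_boot,
    n_peptides = n,
    subgroup = label %||% if (is.null(subgroup)) "all" else paste(subgroup, collapse = "+"),
    B = as.integer(B),
    seed = as.integer(seed),
    low_n = n <= low_n_threshold
  )
}

#' Compare two deamidation estimates
#'
#' @param a,b One-row estimate tibbles for the same residue type.
#' @return One-row tibble: `difference` (a minus b, percentage points),
#'   `combined_sd` and a qualitative `verdict` ("higher" / "comparable" /
#'   "lower") based on whether the difference exceeds twice the combined
#'   standard deviation.
#' @export
compare_deamidation <- function(a, b) {
  if (!identical(a$residue, b$residue)) {
    abort_format("cannot compare deamidation of %s with %s", a$residue, b$residue)
  }
  difference <- a$percent - b$percent
  combined_sd <- sqrt(a$sd^2 + b$sd^2)
  verdict <- if (abs(difference) <= 2 * combined_sd) "comparable"
             else if (difference > 0) "higher" else "lower"
  tibble::tibble(residue = a$residue, difference = difference,
                 combined_sd = combined_sd, verdict = verdict)
}

#' Bar plot of deamidation estimates
#'
#' Bars show percent deamidation per residue and subgroup with bootstrap
#' error bars; the number of peptides used appears above each bar.
#'
#' @param estimates Tibble of rows from [estimate_deamidation()], with an
#'   optional `sample_id` column for faceting.
#' @return A ggplot object.
#' @export
plot_deamidation <- function(estimates) {
  est <- estimates
  est$bar <- paste(est$subgroup, est$residue)
  p <- ggplot2::ggplot(est, ggplot2::aes(x = .data$bar, y = .data$percent,
                                         fill = .data$residue)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$percent - .data$sd),
                                        ymax = pmin(100, .data$percent + .data$sd)),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_peptides,
                                    y = pmin(100, .data$percent + .data$sd) + 3)) +
    ggplot2::labs(x = NULL, y = "Deamidation (%)", fill = "Residue") +
    ggplot2::ylim(0, 105) +
    ggplot2::theme_minimal()
  if ("sample_id" %in% names(est)) {
    p <- p + ggplot2::facet_wrap(~sample_id)
  }
  p
}
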