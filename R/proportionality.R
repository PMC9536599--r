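# Cell- and patient-level classification of cell volume versus ploidy:
# sub/proportional/supra cells against the scaled wild-type band, the
# near-WT call, and the conservative compound patient test
# (chi-square vs uniform, two-sided binomial on sub vs supra, 2-fold
# enrichment requirement).

#' Proportionality bounds from the wild-type Gaussian
#'
#' The diploid AT2 peak `mu +/- sigma` (582 +/- 127 fL at 2n) scales to
#' per-genome slopes `(mu - sigma)/2` and `(mu + sigma)/2` = 227.5 and
#' 354.5 fL per n. `truncate = TRUE` reproduces the printed integer
#' truncation (227) of the lower bound.
#'
#' @param mu_wt,sigma_wt wild-type diploid cell-volume Gaussian, fL.
#' @param truncate truncate the slopes to integers.
#' @return a `proportionality_bounds` list.
#' @export
proportionality_bounds <- function(mu_wt = 582, sigma_wt = 127,
                                   truncate = FALSE) {
  lower <- (mu_wt - sigma_wt) / 2
  upper <- (mu_wt + sigma_wt) / 2
  if (truncate) { lower <- trunc(lower); upper <- trunc(upper) }
  if (lower >= upper) stop("lower slope must be below upper slope")
  structure(list(mu_wt = mu_wt, sigma_wt = sigma_wt,
                 lower_slope = lower, upper_slope = upper),
            class = "proportionality_bounds")
}

#' Classify one cell's volume-ploidy proportionality
#'
#' The volume-per-genome ratio `cell_volume / ploidy` is compared to the
#' wild-type band: below the lower slope is subproportional, above the
#' upper slope supraproportional, otherwise proportional.
#'
#' @param cell_volume fL.
#' @param estimated_ploidy haploid units (> 0).
#' @param bounds a [proportionality_bounds()].
#' @return `"sub"`, `"proportional"` or `"supra"` (vectorised).
#' @export
classify_cell <- function(cell_volume, estimated_ploidy,
                          bounds = proportionality_bounds()) {
  if (any(estimated_ploidy <= 0, na.rm = TRUE)) stop("ploidy must be positive")
  ratio <- cell_volume / estimated_ploidy
  ifelse(ratio < bounds$lower_slope, "sub",
         ifelse(ratio > bounds$upper_slope, "supra", "proportional"))
}

#' Near-wild-type call
#'
#' TRUE when the cell volume lies in the wild-type band 455-709 fL
#' (mu +/- sigma) and the ploidy is near-euploid (1.6-4.4n), both
#' inclusive.
#'
#' @param cell_volume fL.
#' @param estimated_ploidy haploid units.
#' @param volume_range,ploidy_range inclusive bounds.
#' @return logical (vectorised).
#' @export
classify_near_wt <- function(cell_volume, estimated_ploidy,
                             volume_range = c(455, 709),
                             ploidy_range = c(1.6, 4.4)) {
  cell_volume >= volume_range[1L] & cell_volume <= volume_range[2L] &
    estimated_ploidy >= ploidy_range[1L] & estimated_ploidy <= ploidy_range[2L]
}

#' Patient-level proportionality call
#'
#' Conservative compound decision rule on the (sub, proportional, supra)
#' cell counts: (1) chi-square test against a uniform distribution over
#' the three bins (df = 2, asymptotic); retain the null => Proportional.
#' (2) Two-sided binomial test of sub vs supra counts at p = 0.5; retain
#' => Proportional. (3) Require the larger of sub/supra to be at least
#' `enrichment_fold` times the smaller (a zero denominator counts as
#' enriched); otherwise Proportional. (4) Call the direction of the larger
#' bin.
#'
#' @param counts numeric length-3 `(n_sub, n_prop, n_supra)`.
#' @param alpha significance level for both tests.
#' @param enrichment_fold required fold enrichment (default 2).
#' @return a `patient_call` list with counts, statistics and `call` in
#'   `{"Subproportional", "Proportional", "Supraproportional"}`.
#' @export
classify_patient <- function(counts, alpha = 0.05, enrichment_fold = 2) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("no classified cells")
  expected <- n / 3
  chi2 <- sum((counts - expected)^2 / expected)
  chi2_p <- pchisq(chi2, df = 2, lower.tail = FALSE)
  n_sub <- counts[1L]; n_supra <- counts[3L]
  binom_p <- if (n_sub + n_supra > 0) {
    binom.test(n_supra, n_sub + n_supra, p = 0.5)$p.value
  } else 1
  enrichment <- if (min(n_sub, n_supra) == 0) {
    if (max(n_sub, n_supra) > 0) Inf else 1
  } else max(n_sub, n_supra) / min(n_sub, n_supra)
  call <- "Proportional"
  if (chi2_p < alpha && binom_p < alpha && enrichment >= enrichment_fold &&
      n_sub != n_supra) {
    call <- if (n_supra > n_sub) "Supraproportional" else "Subproportional"
  }
  structure(list(counts = counts, chi2 = chi2, chi2_p = chi2_p,
                 binomial_p = binom_p, enrichment = enrichment,
                 alpha = alpha, enrichment_fold = enrichment_fold,
                 call = call),
            class = "patient_call")
}

#' Classify a table of cells and summarise per patient
#'
#' @param records data.frame with `patient_id`, `cell_volume`,
#'   `estimated_ploidy`.
#' @param bounds a [proportionality_bounds()].
#' @return list with `records` (classes appended) and `patients`
#'   (per-patient counts and calls).
#' @export
classify_cohort <- function(records, bounds = proportionality_bounds()) {
  ok <- is.finite(records$estimated_ploidy) & records$estimated_ploidy > 0
  records$proportionality_class <- NA_character_
  records$proportionality_class[ok] <- classify_cell(
    records$cell_volume[ok], records$estimated_ploidy[ok], bounds)
  records$near_wt <- classify_near_wt(records$cell_volume,
                                      records$estimated_ploidy)
  pts <- unique(records$patient_id)
  calls <- lapply(pts, function(p) {
    cls <- records$proportionality_class[records$patient_id == p]
    cnt <- c(sum(cls == "sub", na.rm = TRUE),
             sum(cls == "proportional", na.rm = TRUE),
             sum(cls == "supra", na.rm = TRUE))
    pc <- classify_patient(cnt)
    data.frame(patient_id = p, n_sub = cnt[1L], n_prop = cnt[2L],
               n_supra = cnt[3L], chi2 = pc$chi2, chi2_p = pc$chi2_p,
               binomial_p = pc$binomial_p, enrichment = pc$enrichment,
               call = pc$call, stringsAsFactors = FALSE)
  })
  list(records = records, patients = do.call(rbind, calls))
}
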