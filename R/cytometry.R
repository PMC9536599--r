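# Flow-cytometry size-sorting analysis: sequential signal gates
# (live/dead, EPCAM, DNA <= 1.5x mode), SSC-W size bins G1-G4 within the
# 50-200 SSC-H trim, the SSC-W -> cell-area linear model, and per-gate
# yield fractions.

#' Gate set
#'
#' @param live_max Zombie-Red cutoff (events below pass the live gate).
#' @param epcam_min EPCAM cutoff (events at/above pass).
#' @param dna_max_multiplier DNA gate: events pass when DRAQ5 <=
#'   multiplier x mode (default 1.5).
#' @param ssc_h_range SSC-H trim (default 50-200).
#' @param size_bins named list of SSC-W ranges; G4 is open-ended.
#' @param dna_mode optional precomputed DRAQ5 mode; when NULL the mode is
#'   computed on the gated population (or set by [calibrate_gates()]).
#' @return a `gate_set` list.
#' @export
gate_set <- function(live_max = 1000, epcam_min = 1000,
                     dna_max_multiplier = 1.5, ssc_h_range = c(50, 200),
                     size_bins = list(G1 = c(64, 79), G2 = c(84, 99),
                                      G3 = c(101, 113), G4 = c(114, Inf)),
                     dna_mode = NULL) {
  los <- vapply(size_bins, `[`, 1, 1L)
  his <- vapply(size_bins, `[`, 1, 2L)
  if (any(diff(los) <= 0) || any(his < los) ||
      any(his[-length(his)] >= los[-1L])) {
    stop("size bins must be non-overlapping and ascending")
  }
  structure(list(live_max = live_max, epcam_min = epcam_min,
                 dna_max_multiplier = dna_max_multiplier,
                 ssc_h_range = ssc_h_range, size_bins = size_bins,
                 dna_mode = dna_mode),
            class = "gate_set")
}

#' Data-driven gate calibration
#'
#' Sets the live/dead cutoff at the left FWHM shoulder of the positive
#' (dead) Zombie-Red peak, the EPCAM cutoff at the density valley between
#' the negative and positive populations, and computes the DNA mode by
#' Freedman-Diaconis histogram argmax on the supplied (CD45-depleted)
#' events.
#'
#' @param events event data.frame (columns `zombie_red`, `epcam`, `draq5`).
#' @param gates a [gate_set()] supplying the structural settings.
#' @return the gate set with calibrated cutoffs and `dna_mode` attached.
#' @export
calibrate_gates <- function(events, gates = gate_set()) {
  lz <- log10(pmax(events$zombie_red, 1))
  dz <- density(lz)
  pk <- rightmost_mode(dz)  # the positive (dead) peak
  half <- pk$y / 2
  left <- dz$x[dz$x < pk$x]
  ly <- dz$y[dz$x < pk$x]
  # walk down the left slope of the dead peak to its half maximum
  below <- which(ly < half)
  gates$live_max <- if (length(below)) 10^left[max(below)] else 10^pk$x / 2
  le <- log10(pmax(events$epcam, 1))
  gates$epcam_min <- 10^density_valley(le)
  gates$dna_mode <- fd_mode(events$draq5)
  gates
}

# rightmost local maximum with at least 10% of the peak density
rightmost_mode <- function(dz) {
  peaks <- which(diff(sign(diff(dz$y))) == -2) + 1L
  peaks <- peaks[dz$y[peaks] >= 0.1 * max(dz$y)]
  i <- if (length(peaks)) max(peaks) else which.max(dz$y)
  list(x = dz$x[i], y = dz$y[i])
}

density_valley <- function(v) {
  dz <- density(v)
  # valley = minimum between the two largest separated modes
  n <- length(dz$y)
  peaks <- which(diff(sign(diff(dz$y))) == -2) + 1L
  if (length(peaks) < 2L) return(median(v))
  ord <- peaks[order(dz$y[peaks], decreasing = TRUE)]
  p1 <- ord[1L]
  p2 <- ord[which(abs(dz$x[ord] - dz$x[p1]) > 0.5)[1L]]
  if (is.na(p2)) return(median(v))
  rng <- sort(c(p1, p2))
  i <- rng[1L] + which.min(dz$y[rng[1L]:rng[2L]]) - 1L
  dz$x[i]
}

# histogram mode with Freedman-Diaconis bins (median fallback for tiny or
# degenerate populations)
fd_mode <- function(values) {
  if (length(values) < 8L || IQR(values) <= 0) return(median(values))
  h <- fd_bins(values)
  hh <- graphics::hist(values, breaks = h$edges, plot = FALSE)
  hh$mids[which.max(hh$counts)]
}

#' Apply the sequential signal gates
#'
#' Zombie-Red- (live) -> EPCAM+ -> DRAQ5 <= multiplier x mode. The DNA
#' mode is taken from the gate set (`dna_mode` from [calibrate_gates()])
#' or computed on the live/EPCAM+ population.
#'
#' @param events event data.frame.
#' @param gates a [gate_set()].
#' @return list `(events, counts)`; `counts` logs the surviving events per
#'   stage.
#' @export
apply_signal_gates <- function(events, gates = gate_set()) {
  n0 <- nrow(events)
  live <- events[events$zombie_red <= gates$live_max, , drop = FALSE]
  epc <- live[live$epcam >= gates$epcam_min, , drop = FALSE]
  dna_mode <- gates$dna_mode %||% (if (nrow(epc) >= 4) fd_mode(epc$draq5) else NA_real_)
  dna <- epc[epc$draq5 <= gates$dna_max_multiplier * dna_mode, , drop = FALSE]
  list(events = dna,
       counts = c(total = n0, live = nrow(live), epcam = nrow(epc),
                  dna = nrow(dna)),
       dna_mode = dna_mode)
}

#' Assign the SSC-W size bin
#'
#' Events must sit in the SSC-H trim range; SSC-W values between bins map
#' to `"none"`.
#'
#' @param events event data.frame (columns `ssc_h`, `ssc_w`).
#' @param gates a [gate_set()].
#' @return character vector of bins (`"G1"`..`"G4"` or `"none"`).
#' @export
assign_size_bin <- function(events, gates = gate_set()) {
  bin <- rep("none", nrow(events))
  in_h <- events$ssc_h >= gates$ssc_h_range[1L] &
    events$ssc_h <= gates$ssc_h_range[2L]
  for (nm in names(gates$size_bins)) {
    rg <- gates$size_bins[[nm]]
    sel <- in_h & events$ssc_w >= rg[1L] & events$ssc_w <= rg[2L]
    bin[sel] <- nm
  }
  bin
}

#' Linear SSC-W to cell-area model
#'
#' @param intercept um^2 (published: -159 +/- 44).
#' @param slope um^2 per SSC-W unit (published: 4.35 +/- 0.48).
#' @param intercept_se,slope_se parameter standard errors.
#' @return an `area_model` list.
#' @export
area_model <- function(intercept = -159, slope = 4.35,
                       intercept_se = NA_real_, slope_se = NA_real_) {
  if (slope <= 0) stop("slope must be positive")
  structure(list(intercept = intercept, slope = slope,
                 intercept_se = intercept_se, slope_se = slope_se),
            class = "area_model")
}

#' Predict cell area from SSC-W
#'
#' `area = intercept + slope * ssc_w`; predictions at or below zero are
#' flagged with a warning (below the model's x-intercept).
#'
#' @param ssc_w numeric SSC-W values.
#' @param model an [area_model()].
#' @return numeric areas in um^2.
#' @export
predict_area <- function(ssc_w, model = area_model()) {
  a <- model$intercept + model$slope * ssc_w
  if (any(a <= 0)) {
    warning(sprintf("%d prediction(s) at or below zero area (SSC-W below the x-intercept %.1f)",
                    sum(a <= 0), -model$intercept / model$slope))
  }
  a
}

#' Fit the SSC-W to area model by ordinary least squares
#'
#' @param pairs data.frame with columns `ssc_w` (bin midpoints) and `area`
#'   (mean measured areas); >= 3 rows.
#' @return an [area_model()] with parameter standard errors.
#' @export
fit_area_model <- function(pairs) {
  stopifnot(all(c("ssc_w", "area") %in% names(pairs)))
  if (nrow(pairs) < 3L) stop("need at least 3 (ssc_w, area) pairs")
  fit <- lm(area ~ ssc_w, data = pairs)
  cf <- summary(fit)$coefficients
  area_model(intercept = cf[1L, 1L], slope = cf[2L, 1L],
             intercept_se = cf[1L, 2L], slope_se = cf[2L, 2L])
}

#' Per-bin yield report
#'
#' Bin counts divided by the signal-gated total; the `none` bin absorbs
#' the remainder so named fractions sum to <= 1.
#'
#' @param bins character vector from [assign_size_bin()].
#' @param gates a [gate_set()].
#' @return named numeric fractions (G1..G4, none).
#' @export
yield_report <- function(bins, gates = gate_set()) {
  nms <- c(names(gates$size_bins), "none")
  n <- length(bins)
  out <- setNames(numeric(length(nms)), nms)
  if (n == 0L) return(out)
  for (nm in nms) out[nm] <- sum(bins == nm) / n
  out
}
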