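#' Normalized spectral contrast (dot product) similarity
#'
#' Cosine similarity between two aligned nonnegative intensity vectors,
#' by default on square-root-transformed intensities (the targeted-
#' proteomics convention for library dot products; disable with
#' `sqrt_transform = FALSE`). Used both for library matching (dotp) and
#' light/heavy channel agreement (rdotp).
#'
#' @param observed,reference aligned nonnegative vectors, each with at
#'   least one positive entry.
#' @param sqrt_transform apply `sqrt` before the cosine (default `TRUE`).
#' @return similarity in `[0, 1]`.
#' @export
normalized_dotp <- function(observed, reference, sqrt_transform = TRUE) {
  if (length(observed) != length(reference))
    stop("vectors must be aligned", call. = FALSE)
  if (any(observed < 0) || any(reference < 0))
    stop("intensities must be nonnegative", call. = FALSE)
  if (all(observed == 0) || all(reference == 0))
    stop("all-zero intensity vector", call. = FALSE)
  if (sqrt_transform) {
    observed <- sqrt(observed)
    reference <- sqrt(reference)
  }
  sum(observed * reference) /
    (sqrt(sum(observed^2)) * sqrt(sum(reference^2)))
}

#' Light/heavy transition-pattern agreement with inclusion gates
#'
#' rdotp is the [normalized_dotp()] of the light vs heavy transition
#' areas; the decision follows the published gates: include at
#' `rdotp >= 0.9`, exclude at `rdotp <= 0.8` (inclusive), manual review
#' in between.
#'
#' @param light_areas,heavy_areas aligned nonnegative vectors.
#' @param sqrt_transform passed to [normalized_dotp()].
#' @return list with `rdotp`, `decision` (`include`/`exclude`/`review`).
#' @export
rdotp_gate <- function(light_areas, heavy_areas, sqrt_transform = TRUE) {
  r <- normalized_dotp(light_areas, heavy_areas, sqrt_transform)
  decision <- if (r >= 0.9) "include" else if (r <= 0.8) "exclude"
              else "review"
  list(rdotp = r, decision = decision)
}

#' Library-match (dotp) gate
#'
#' @param observed transition areas; `reference` library intensities.
#' @param reference aligned library intensities.
#' @param threshold strict lower gate (default 0.7, per `dotp > 0.7`).
#' @param sqrt_transform passed to [normalized_dotp()].
#' @return list with `dotp`, `pass`.
#' @export
dotp_gate <- function(observed, reference, threshold = 0.7,
                      sqrt_transform = TRUE) {
  d <- normalized_dotp(observed, reference, sqrt_transform)
  list(dotp = d, pass = d > threshold)
}

#' Light/heavy peptide quantification (summed transitions)
#'
#' Peptide intensity is the sum of its transition areas; the quantity is
#' the light/heavy intensity ratio.
#'
#' @param set a [transition_set()].
#' @return light/heavy ratio.
#' @export
srm_ratio <- function(set) {
  stopifnot(inherits(set, "transition_set"))
  h <- sum(set$heavy_areas)
  if (h <= 0) stop("zero heavy-channel intensity", call. = FALSE)
  sum(set$light_areas) / h
}

#' Carryover percentage from a blank injection
#'
#' @param blank_area summed area of the peptide in the blank (water) run.
#' @param preceding_area summed area in the preceding matrix run (> 0).
#' @return carryover percent (100 x blank / preceding).
#' @export
carryover_percent <- function(blank_area, preceding_area) {
  if (any(preceding_area <= 0))
    stop("preceding-run area must be > 0", call. = FALSE)
  100 * blank_area / preceding_area
}

#' Mass accuracy in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values (`theoretical_mz > 0`).
#' @param gate_ppm strict gate (default 10: pass iff `|ppm| < 10`).
#' @return list with `ppm`, `pass`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz, gate_ppm = 10) {
  if (any(theoretical_mz <= 0))
    stop("theoretical m/z must be > 0", call. = FALSE)
  ppm <- 1e6 * (observed_mz - theoretical_mz) / theoretical_mz
  list(ppm = ppm, pass = abs(ppm) < gate_ppm)
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope) - 1`; assays with `E` between 95\% and 105\%
#' (inclusive) pass. A slope of `-3.3219` (= -1/log10(2)) corresponds to
#' perfect doubling, `E = 1`.
#'
#' @param slope Cq change per log10 dilution (negative).
#' @param lower,upper inclusive gate bounds (defaults 0.95, 1.05).
#' @return list with `efficiency`, `pass`.
#' @export
amplification_efficiency <- function(slope, lower = 0.95, upper = 1.05) {
  if (any(slope >= 0))
    stop("standard-curve slope must be negative", call. = FALSE)
  E <- 10^(-1 / slope) - 1
  list(efficiency = E, pass = E >= lower & E <= upper)
}

#' Efficiency-corrected relative quantification (Pfaffl model)
#'
#' `ratio = (1 + E_target)^dCq_target / (1 + E_ref)^dCq_ref` with
#' `dCq = Cq(calibrator) - Cq(sample)`. With several reference genes the
#' reference term is the geometric mean of the per-reference terms. With
#' all efficiencies equal to 1 this reduces to the 2^ddCq (Livak) model.
#'
#' @param E_target target-gene efficiency (fraction, e.g. 1.0 = 100\%).
#' @param E_ref reference efficiency or vector of efficiencies.
#' @param dCq_target calibrator-minus-sample Cq for the target.
#' @param dCq_ref calibrator-minus-sample Cq per reference gene (same
#'   length as `E_ref`).
#' @return fold-change ratio (> 0).
#' @export
pfaffl_ratio <- function(E_target, E_ref, dCq_target, dCq_ref) {
  if (E_target < 0 || any(E_ref < 0))
    stop("efficiencies must be >= 0", call. = FALSE)
  if (length(E_ref) != length(dCq_ref))
    stop("E_ref and dCq_ref must be aligned", call. = FALSE)
  ref_term <- exp(mean(dCq_ref * log(1 + E_ref)))
  (1 + E_target)^dCq_target / ref_term
}

#' Impute qPCR non-detects at the maximum cycle number
#'
#' @param cq numeric Cq values with `NA` for non-detects.
#' @param max_cycles imputation value (default 40).
#' @return Cq vector with non-detects replaced by `max_cycles`.
#' @export
impute_nondetect_cq <- function(cq, max_cycles = 40) {
  cq[is.na(cq)] <- max_cycles
  cq
}

#' Full QC record for one transition set
#'
#' Combines the library dotp, the light/heavy rdotp and the mass-error
#' gate into a single decision: `exclude` if rdotp is in its exclusion
#' zone or dotp/ppm fail, `review` if rdotp falls in the manual zone,
#' else `include`.
#'
#' @param set a [transition_set()].
#' @param mass_ppm observed mass error in ppm (default 0 = not measured).
#' @param sqrt_transform passed to [normalized_dotp()].
#' @return data.frame row: `peptide_id`, `dotp`, `rdotp`,
#'   `mass_error_ppm`, `decision`.
#' @export
qc_record <- function(set, mass_ppm = 0, sqrt_transform = TRUE) {
  stopifnot(inherits(set, "transition_set"))
  d <- normalized_dotp(set$light_areas, set$library_intensities,
                       sqrt_transform)
  rg <- rdotp_gate(set$light_areas, set$heavy_areas, sqrt_transform)
  decision <- rg$decision
  if (d <= 0.7 || abs(mass_ppm) >= 10) decision <- "exclude"
  data.frame(peptide_id = set$peptide_id, dotp = d, rdotp = rg$rdotp,
             mass_error_ppm = mass_ppm, decision = decision,
             stringsAsFactors = FALSE)
}
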