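#' Simulation configuration for two-group LFQ matrices
#'
#' Describes a synthetic label-free quantitation experiment on the log2
#' scale: `n_features` proteins measured in `n_pos` pN+ and `n_neg` pN0
#' samples, with `n_true` planted differential features that carry an
#' additive `effect_size` (log2 units) in the pN+ group. Between-feature
#' baseline spread is `feature_sd`, within-feature technical noise is
#' `noise_sd`. `missing_target` and `mnar_steepness` parameterize the
#' left-censored missingness applied by [apply_mnar_missingness()].
#'
#' @param n_features,n_pos,n_neg,n_true nonnegative counts.
#' @param effect_size planted log2 shift in pN+ (default 2).
#' @param baseline_mean,feature_sd,noise_sd log2-scale distribution
#'   parameters (defaults 25, 2, 1 - typical LFQ intensity ranges).
#' @param missing_target overall missing fraction in `[0, 1)`.
#' @param mnar_steepness logistic steepness (> 0) of abundance-dependent
#'   missingness.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_features = 2000L, n_pos = 20L, n_neg = 20L,
                       n_true = 100L, effect_size = 2, baseline_mean = 25,
                       feature_sd = 2, noise_sd = 1, missing_target = 0.2,
                       mnar_steepness = 1, seed = 1L) {
  cfg <- list(n_features = as.integer(n_features), n_pos = as.integer(n_pos),
              n_neg = as.integer(n_neg), n_true = as.integer(n_true),
              effect_size = effect_size, baseline_mean = baseline_mean,
              feature_sd = feature_sd, noise_sd = noise_sd,
              missing_target = missing_target,
              mnar_steepness = mnar_steepness, seed = as.integer(seed))
  if (any(vapply(cfg[c("n_features", "n_pos", "n_neg", "n_true")],
                 function(v) is.na(v) || v < 0L, logical(1))))
    stop("counts must be nonnegative", call. = FALSE)
  if (cfg$n_true > cfg$n_features)
    stop("n_true must not exceed n_features", call. = FALSE)
  if (cfg$missing_target < 0 || cfg$missing_target >= 1)
    stop("missing_target must lie in [0, 1)", call. = FALSE)
  if (cfg$mnar_steepness <= 0)
    stop("mnar_steepness must be > 0", call. = FALSE)
  if (cfg$feature_sd < 0 || cfg$noise_sd < 0)
    stop("standard deviations must be nonnegative", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a complete two-group quantitation matrix with planted truth
#'
#' Feature baselines are drawn from Normal(`baseline_mean`, `feature_sd`);
#' each cell adds Normal(0, `noise_sd`) technical noise. A random subset of
#' `n_true` features receives `effect_size` added to every pN+ sample, so
#' the expected group-mean difference of a planted feature equals
#' `effect_size` (direction +1). No cell is missing; pair with
#' [apply_mnar_missingness()] for the left-censored pattern.
#'
#' @param config a [sim_config()].
#' @return list with `table` (complete [quant_table()]), `labels` (named
#'   `"pos"`/`"neg"` vector) and `truth` (list with `true_differential`
#'   data.frame of `feature_id`, `direction`).
#' @export
generate_group_quant <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_pos + config$n_neg
  if (config$n_features < 1L || n < 1L)
    stop("need at least one feature and one sample", call. = FALSE)
  feature_ids <- sprintf("F%05d", seq_len(config$n_features))
  sample_ids <- c(sprintf("POS%03d", seq_len(config$n_pos)),
                  sprintf("NEG%03d", seq_len(config$n_neg)))
  labels <- stats::setNames(rep(c("pos", "neg"),
                                c(config$n_pos, config$n_neg)), sample_ids)
  with_seed(derive_seed(config$seed, "group_quant"), {
    mu <- rnorm(config$n_features, config$baseline_mean, config$feature_sd)
    values <- mu + matrix(rnorm(config$n_features * n, 0, config$noise_sd),
                          config$n_features, n)
    planted <- sort(sample.int(config$n_features, config$n_true))
  })
  if (config$n_true > 0L && config$n_pos > 0L)
    values[planted, seq_len(config$n_pos)] <-
      values[planted, seq_len(config$n_pos)] + config$effect_size
  truth <- list(true_differential = data.frame(
    feature_id = feature_ids[planted],
    direction = rep(1L, length(planted)),
    stringsAsFactors = FALSE))
  list(table = quant_table(values, feature_ids, sample_ids),
       labels = labels, truth = truth)
}

#' Apply abundance-dependent (MNAR) missingness
#'
#' Each cell goes missing independently with probability
#' `plogis(-steepness * (x - m))` - a decreasing logistic in the cell's
#' abundance, emulating left-censored LFQ non-detection. The midpoint `m`
#' is calibrated by bisection so the expected missing fraction equals
#' `missing_target`.
#'
#' @param table complete [quant_table()].
#' @param missing_target target overall missing fraction in `[0, 1)`.
#' @param mnar_steepness logistic steepness, > 0.
#' @param seed integer seed.
#' @return a `quant_table` with `NA` holes.
#' @export
apply_mnar_missingness <- function(table, missing_target, mnar_steepness = 1,
                                   seed = 1L) {
  stopifnot(is_quant_table(table))
  if (anyNA(table)) stop("table must be complete", call. = FALSE)
  if (missing_target < 0 || missing_target >= 1)
    stop("missing_target must lie in [0, 1)", call. = FALSE)
  if (mnar_steepness <= 0) stop("mnar_steepness must be > 0", call. = FALSE)
  if (missing_target == 0) return(table)
  x <- as_quant_matrix(table)
  expected_rate <- function(m) mean(stats::plogis(-mnar_steepness * (x - m)))
  lo <- min(x) - 60 / mnar_steepness
  hi <- max(x) + 60 / mnar_steepness
  for (i in 1:200) {   # bisection on the logistic midpoint
    mid <- (lo + hi) / 2
    if (expected_rate(mid) < missing_target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  p_miss <- stats::plogis(-mnar_steepness * (x - (lo + hi) / 2))
  drop <- with_seed(derive_seed(seed, "mnar"),
                    matrix(runif(length(x)) < p_miss, nrow(x), ncol(x)))
  x[drop] <- NA_real_
  quant_table(x, rownames(table), colnames(table))
}

#' Export a quantitation table on the raw intensity scale
#'
#' Inverse of [log2_transform()]: raw = 2^log2 value, with missing cells
#' written as 0 intensity (the non-detection convention of LFQ exports).
#'
#' @param table a [quant_table()] of log2 values.
#' @return numeric matrix of raw intensities with 0 for missing.
#' @export
as_raw_intensities <- function(table) {
  stopifnot(is_quant_table(table))
  m <- 2^as_quant_matrix(table)
  m[is.na(m)] <- 0
  m
}

#' Multi-layer marker panel configuration
#'
#' Describes a targeted-verification panel: each `marker` is measured on up
#' to three molecular layers (`peptide`, `protein`, `transcript`); peptide
#' layers contribute `peptides_per_marker` variables. All layers of one
#' marker load on a shared standard-normal latent factor so that any two
#' layer variables of the same marker correlate at `layer_correlation`.
#' `informative_markers` carry `effect_size` (latent-sd units) on the latent
#' factor between pN+ and pN0.
#'
#' @param markers character vector of marker names.
#' @param layers nonempty subset of `c("peptide", "protein", "transcript")`.
#' @param peptides_per_marker count (default 2).
#' @param layer_correlation rho in `[0, 1]`.
#' @param informative_markers subset of `markers`.
#' @param effect_size latent group shift (default 2).
#' @param n_pos,n_neg group sizes.
#' @param seed integer seed.
#' @return a `panel_config` list.
#' @export
panel_config <- function(markers, layers = c("peptide", "protein",
                                             "transcript"),
                         peptides_per_marker = 2L, layer_correlation = 0.7,
                         informative_markers = character(0), effect_size = 2,
                         n_pos = 30L, n_neg = 30L, seed = 1L) {
  if (length(layers) == 0L) stop("layers must be nonempty", call. = FALSE)
  layers <- match.arg(layers, c("peptide", "protein", "transcript"),
                      several.ok = TRUE)
  if (layer_correlation < 0 || layer_correlation > 1)
    stop("layer_correlation must lie in [0, 1]", call. = FALSE)
  if (!all(informative_markers %in% markers))
    stop("informative_markers must be a subset of markers", call. = FALSE)
  structure(list(markers = as.character(markers), layers = layers,
                 peptides_per_marker = as.integer(peptides_per_marker),
                 layer_correlation = layer_correlation,
                 informative_markers = as.character(informative_markers),
                 effect_size = effect_size, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), seed = as.integer(seed)),
            class = "panel_config")
}

panel_variable_ids <- function(config) {
  unlist(lapply(config$markers, function(m) {
    ids <- character(0)
    if ("peptide" %in% config$layers)
      ids <- c(ids, sprintf("%s|pep%d", m,
                            seq_len(config$peptides_per_marker)))
    if ("protein" %in% config$layers) ids <- c(ids, sprintf("%s|protein", m))
    if ("transcript" %in% config$layers) ids <- c(ids, sprintf("%s|rna", m))
    ids
  }), use.names = FALSE)
}

#' Generate a correlated multi-layer marker panel with planted truth
#'
#' Variable value = `sqrt(rho) * latent + sqrt(1 - rho) * noise` with
#' standard-normal latent and idiosyncratic terms, so every variable has
#' unit variance and two variables of the same marker correlate at `rho`.
#' Informative markers shift the latent mean by `+effect_size/2` in pN+ and
#' `-effect_size/2` in pN0.
#'
#' @param config a [panel_config()].
#' @return list with `table` (variables x samples [quant_table()]),
#'   `labels`, and `truth` (`informative_variables`, `informative_markers`).
#' @export
generate_marker_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  rho <- config$layer_correlation
  var_ids <- panel_variable_ids(config)
  n <- config$n_pos + config$n_neg
  sample_ids <- c(sprintf("POS%03d", seq_len(config$n_pos)),
                  sprintf("NEG%03d", seq_len(config$n_neg)))
  labels <- stats::setNames(rep(c("pos", "neg"),
                                c(config$n_pos, config$n_neg)), sample_ids)
  marker_of <- sub("\\|.*$", "", var_ids)
  group_shift <- rep(0, n)
  group_shift[seq_len(config$n_pos)] <- config$effect_size / 2
  group_shift[config$n_pos + seq_len(config$n_neg)] <- -config$effect_size / 2
  values <- with_seed(derive_seed(config$seed, "panel"), {
    latent <- matrix(rnorm(length(config$markers) * n),
                     length(config$markers), n,
                     dimnames = list(config$markers, NULL))
    for (m in config$informative_markers)
      latent[m, ] <- latent[m, ] + group_shift
    idio <- matrix(rnorm(length(var_ids) * n), length(var_ids), n)
    sqrt(rho) * latent[marker_of, , drop = FALSE] + sqrt(1 - rho) * idio
  })
  truth <- list(
    informative_markers = config$informative_markers,
    informative_variables =
      var_ids[marker_of %in% config$informative_markers])
  list(table = quant_table(values, var_ids, sample_ids), labels = labels,
       truth = truth)
}

#' Generate matched tumor / lymph-node proteome pairs with an EMT shift
#'
#' Produces two column-matched quantitation tables. Mesenchymal ("Mes")
#' signature genes are shifted up by `shift` log2 units in the tumor site;
#' epithelial ("Epi") genes are shifted up by `shift` in the lymph-node
#' site. The expected paired EMT-score difference (tumor minus node) is
#' therefore `2 * shift`.
#'
#' @param n_pairs number of matched patients.
#' @param n_features total features (must cover the signature).
#' @param emt_signature named character vector gene -> `"Epi"`/`"Mes"`.
#' @param shift log2 shift per class (default 1).
#' @param noise_sd per-cell technical noise (default 0.5).
#' @param baseline_mean,feature_sd baseline distribution (defaults 25, 2).
#' @param seed integer seed.
#' @return list with `tumor`, `node` ([quant_table()]s, identical column
#'   ordering), `truth` (`emt_shifts`: named tumor-minus-node shifts).
#' @export
generate_paired_sites <- function(n_pairs, n_features, emt_signature,
                                  shift = 1, noise_sd = 0.5,
                                  baseline_mean = 25, feature_sd = 2,
                                  seed = 1L) {
  if (length(emt_signature) == 0L)
    stop("emt_signature must be nonempty", call. = FALSE)
  if (!all(emt_signature %in% c("Epi", "Mes")))
    stop('signature classes must be "Epi" or "Mes"', call. = FALSE)
  genes <- names(emt_signature)
  if (is.null(genes) || anyDuplicated(genes))
    stop("emt_signature must be uniquely named by gene", call. = FALSE)
  n_features <- max(n_features, length(genes))
  feature_ids <- c(genes,
                   sprintf("BG%05d", seq_len(n_features - length(genes))))
  cols <- sprintf("PT%03d", seq_len(n_pairs))
  with_seed(derive_seed(seed, "paired_sites"), {
    base <- rnorm(n_features, baseline_mean, feature_sd)
    tumor <- base + matrix(rnorm(n_features * n_pairs, 0, noise_sd),
                           n_features, n_pairs)
    node <- base + matrix(rnorm(n_features * n_pairs, 0, noise_sd),
                          n_features, n_pairs)
  })
  mes <- which(feature_ids %in% genes[emt_signature == "Mes"])
  epi <- which(feature_ids %in% genes[emt_signature == "Epi"])
  tumor[mes, ] <- tumor[mes, ] + shift
  node[epi, ] <- node[epi, ] + shift
  shifts <- stats::setNames(rep(0, length(genes)), genes)
  shifts[emt_signature == "Mes"] <- shift
  shifts[emt_signature == "Epi"] <- -shift
  list(tumor = quant_table(tumor, feature_ids, cols),
       node = quant_table(node, feature_ids, cols),
       truth = list(emt_shifts = shifts))
}

#' One peptide's transition-level areas for a single run
#'
#' @param run_id,peptide_id identifiers.
#' @param transition_ids character vector, length >= 3 (assays monitor 3-6
#'   transitions per peptide).
#' @param light_areas,heavy_areas,library_intensities nonnegative vectors
#'   aligned with `transition_ids`.
#' @return a `transition_set` list.
#' @export
transition_set <- function(run_id, peptide_id, transition_ids, light_areas,
                           heavy_areas, library_intensities = heavy_areas) {
  transition_ids <- as.character(transition_ids)
  if (length(transition_ids) < 3L)
    stop("at least 3 transitions per peptide are required", call. = FALSE)
  lens <- c(length(light_areas), length(heavy_areas),
            length(library_intensities))
  if (any(lens != length(transition_ids)))
    stop("transition vectors must be aligned", call. = FALSE)
  if (any(c(light_areas, heavy_areas, library_intensities) < 0, na.rm = TRUE))
    stop("areas must be nonnegative", call. = FALSE)
  structure(list(run_id = as.character(run_id),
                 peptide_id = as.character(peptide_id),
                 transition_ids = transition_ids,
                 light_areas = as.numeric(light_areas),
                 heavy_areas = as.numeric(heavy_areas),
                 library_intensities = as.numeric(library_intensities)),
            class = "transition_set")
}

#' Generate synthetic targeted (SRM-style) transition runs
#'
#' Each peptide gets a library relative-intensity pattern; heavy-channel
#' areas follow the pattern scaled by `heavy_spike`, and light areas equal
#' heavy x `light_ratio` x a multiplicative log-normal distortion with sd
#' `distortion`. With `distortion = 0` the light channel is exactly
#' proportional to the heavy one, so rdotp = 1 and the summed-intensity
#' ratio equals `light_ratio` exactly. With `include_blank`, one blank
#' (water) injection per peptide carries `blank_residual` of the heavy
#' signal for carryover checks.
#'
#' @param n_peptides,n_transitions counts (`n_transitions >= 3`).
#' @param heavy_spike heavy-channel scale (peak-area units).
#' @param light_ratio planted light/heavy ratio (default 0.5).
#' @param distortion log-normal sdlog distorting light vs heavy (default 0).
#' @param include_blank also emit blank-injection runs.
#' @param blank_residual fraction of heavy signal remaining in the blank.
#' @param seed integer seed.
#' @return list of [transition_set()]s (sample run first, then blanks).
#' @export
generate_transition_runs <- function(n_peptides = 5L, n_transitions = 4L,
                                     heavy_spike = 1e5, light_ratio = 0.5,
                                     distortion = 0, include_blank = FALSE,
                                     blank_residual = 0, seed = 1L) {
  if (n_transitions < 3L)
    stop("n_transitions must be >= 3", call. = FALSE)
  runs <- list()
  with_seed(derive_seed(seed, "transitions"), {
    for (i in seq_len(n_peptides)) {
      pep <- sprintf("PEP%02d", i)
      tids <- sprintf("%s_y%d", pep, seq_len(n_transitions) + 2L)
      pattern <- sort(stats::rlnorm(n_transitions, 0, 0.8),
                      decreasing = TRUE)
      pattern <- pattern / max(pattern)
      heavy <- heavy_spike * pattern
      light <- heavy * light_ratio *
        exp(rnorm(n_transitions, 0, distortion))
      runs[[length(runs) + 1L]] <- transition_set(
        "run01", pep, tids, light, heavy, library_intensities = pattern)
      if (include_blank)
        runs[[length(runs) + 1L]] <- transition_set(
          "blank01", pep, tids, rep(0, n_transitions),
          blank_residual * heavy, library_intensities = pattern)
    }
  })
  runs
}

#' Read / write transition runs as a long-format CSV
#'
#' Columns: `run_id`, `peptide`, `isotope_label` (`light`/`heavy`/
#' `library`), `transition_id`, `area` - a documented subset of a
#' Skyline-style transition-results export.
#'
#' @param runs list of [transition_set()]s.
#' @param path file path.
#' @export
write_transition_runs <- function(runs, path) {
  rows <- data.table::rbindlist(lapply(runs, function(ts) {
    data.table::data.table(
      run_id = ts$run_id, peptide = ts$peptide_id,
      isotope_label = rep(c("light", "heavy", "library"),
                          each = length(ts$transition_ids)),
      transition_id = rep(ts$transition_ids, 3L),
      area = c(ts$light_areas, ts$heavy_areas, ts$library_intensities))
  }))
  data.table::fwrite(rows, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_runs
#' @export
read_transition_runs <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  needed <- c("run_id", "peptide", "isotope_label", "transition_id", "area")
  if (!all(needed %in% colnames(dt)))
    stop("transition CSV must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  keys <- unique(dt[, c("run_id", "peptide")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- dt[dt$run_id == keys$run_id[i] & dt$peptide == keys$peptide[i], ]
    wide <- split(sub, sub$isotope_label)
    tids <- wide$light$transition_id
    align <- function(lab) {
      block <- wide[[lab]]
      block$area[match(tids, block$transition_id)]
    }
    transition_set(keys$run_id[i], keys$peptide[i], tids,
                   align("light"), align("heavy"), align("library"))
  })
}

#' Write planted ground truth as JSON
#'
#' @param truth a truth list from a generator.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
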