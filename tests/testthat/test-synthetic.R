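test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_true = 10, n_features = 5), "n_true")
  expect_error(sim_config(missing_target = 1), "missing_target")
  expect_error(sim_config(n_pos = -1), "nonnegative")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("generate_group_quant plants the stated effect and is deterministic", {
  cfg <- sim_config(n_features = 2000, n_pos = 20, n_neg = 20, n_true = 100,
                    effect_size = 2, seed = 1)
  g1 <- generate_group_quant(cfg)
  g2 <- generate_group_quant(cfg)
  expect_identical(g1$table, g2$table)
  expect_false(anyNA(g1$table))

  pos <- names(g1$labels)[g1$labels == "pos"]
  neg <- names(g1$labels)[g1$labels == "neg"]
  planted <- g1$truth$true_differential$feature_id
  expect_length(planted, 100)
  diff <- rowMeans(g1$table[planted, pos]) - rowMeans(g1$table[planted, neg])
  expect_equal(mean(diff), 2, tolerance = 0.1 / 2)

  # null case: no planted features
  g0 <- generate_group_quant(sim_config(n_features = 50, n_true = 0))
  expect_identical(nrow(g0$truth$true_differential), 0L)
})

test_that("effect-size recovery regression has slope ~ 1", {
  diffs <- effects <- numeric(0)
  for (es in c(0.5, 1, 2, 3)) {
    g <- generate_group_quant(sim_config(n_features = 300, n_pos = 20,
                                         n_neg = 20, n_true = 60,
                                         effect_size = es, seed = 7))
    pos <- names(g$labels)[g$labels == "pos"]
    neg <- names(g$labels)[g$labels == "neg"]
    planted <- g$truth$true_differential$feature_id
    diffs <- c(diffs, rowMeans(g$table[planted, pos]) -
                 rowMeans(g$table[planted, neg]))
    effects <- c(effects, rep(es, length(planted)))
  }
  slope <- coef(lm(diffs ~ effects))[["effects"]]
  expect_equal(slope, 1, tolerance = 0.1)
})

test_that("MNAR missingness hits its target and censors low abundances", {
  g <- generate_group_quant(sim_config(n_features = 2000, n_pos = 10,
                                       n_neg = 10, seed = 2))
  expect_identical(apply_mnar_missingness(g$table, 0), g$table)
  expect_error(apply_mnar_missingness(g$table, 1), "missing_target")

  mt <- apply_mnar_missingness(g$table, 0.3, mnar_steepness = 1, seed = 2)
  frac <- mean(is.na(mt))
  expect_gte(frac, 0.28)
  expect_lte(frac, 0.32)
  # dropped cells are lower in abundance than retained ones
  expect_lt(mean(g$table[is.na(mt)]), mean(g$table[!is.na(mt)]))
  # per-feature mean abundance anticorrelates with missing count
  rho <- cor(rowMeans(g$table), rowSums(is.na(mt)), method = "spearman")
  expect_lt(rho, -0.3)
  # determinism
  expect_identical(mt, apply_mnar_missingness(g$table, 0.3, 1, seed = 2))
})

test_that("MNAR property holds across steepness values", {
  g <- generate_group_quant(sim_config(n_features = 500, n_pos = 8,
                                       n_neg = 8, seed = 5))
  for (st in c(0.3, 1, 3)) {
    mt <- apply_mnar_missingness(g$table, 0.25, st, seed = 5)
    expect_lt(mean(g$table[is.na(mt)]), mean(g$table[!is.na(mt)]))
  }
})

test_that("marker panel encodes layers, correlation and informative truth", {
  cfg <- panel_config(markers = sprintf("MK%02d", 1:15),
                      layers = c("peptide", "protein", "transcript"),
                      peptides_per_marker = 2, informative_markers = "MK01",
                      seed = 3)
  p <- generate_marker_panel(cfg)
  expect_identical(nrow(p$table), 15L * 4L)  # 2 peptides + protein + rna
  expect_true(all(c("MK01|pep1", "MK01|protein", "MK01|rna") %in%
                    rownames(p$table)))
  expect_setequal(p$truth$informative_variables,
                  c("MK01|pep1", "MK01|pep2", "MK01|protein", "MK01|rna"))

  # rho = 1: layers of one marker perfectly rank-correlated
  p1 <- generate_marker_panel(panel_config(markers = "A",
                                           layers = c("protein",
                                                      "transcript"),
                                           layer_correlation = 1, seed = 4))
  expect_equal(cor(p1$table["A|protein", ], p1$table["A|rna", ],
                   method = "spearman"), 1)

  # rho = 0: average cross-layer correlation ~ 0
  p0 <- generate_marker_panel(panel_config(
    markers = sprintf("Z%02d", 1:50), layers = c("protein", "transcript"),
    layer_correlation = 0, n_pos = 30, n_neg = 30, seed = 5))
  cors <- vapply(sprintf("Z%02d", 1:50), function(m)
    cor(p0$table[paste0(m, "|protein"), ], p0$table[paste0(m, "|rna"), ]),
    numeric(1))
  expect_lt(abs(mean(cors)), 0.1)

  # rho intermediate: empirical pairwise correlation near rho
  ph <- generate_marker_panel(panel_config(
    markers = sprintf("H%02d", 1:50), layers = c("protein", "transcript"),
    layer_correlation = 0.7, n_pos = 40, n_neg = 40, seed = 6))
  corsh <- vapply(sprintf("H%02d", 1:50), function(m)
    cor(ph$table[paste0(m, "|protein"), ], ph$table[paste0(m, "|rna"), ]),
    numeric(1))
  expect_equal(mean(corsh), 0.7, tolerance = 0.07)

  expect_error(panel_config(markers = "A", layers = character(0)), "layers")
  expect_error(panel_config(markers = "A", informative_markers = "B"),
               "subset")
})

test_that("paired sites carry the planted EMT structure", {
  sig <- toy_signature(5)
  ps <- generate_paired_sites(11, 60, sig, shift = 0, seed = 1)
  expect_identical(colnames(ps$tumor), colnames(ps$node))
  expect_identical(ncol(ps$tumor), 11L)
  st <- emt_score(ps$tumor, sig)
  sn <- emt_score(ps$node, sig)
  expect_lt(abs(mean(st$score - sn$score)), 0.5)  # shift 0 -> ~0
  expect_error(generate_paired_sites(5, 10, setNames(character(0),
                                                     character(0))),
               "nonempty")
  expect_identical(ps$truth$emt_shifts[["MES01"]], 0)
})

test_that("transition runs realize planted ratio and blanks", {
  runs <- generate_transition_runs(n_peptides = 3, n_transitions = 4,
                                   light_ratio = 0.5, distortion = 0,
                                   include_blank = TRUE,
                                   blank_residual = 0, seed = 9)
  samples <- Filter(function(r) r$run_id == "run01", runs)
  blanks <- Filter(function(r) r$run_id == "blank01", runs)
  expect_length(samples, 3)
  expect_length(blanks, 3)
  for (ts in samples) {
    expect_identical(srm_ratio(ts), 0.5)
    expect_equal(rdotp_gate(ts$light_areas, ts$heavy_areas)$rdotp, 1)
  }
  for (i in seq_along(blanks))
    expect_identical(carryover_percent(sum(blanks[[i]]$heavy_areas),
                                       sum(samples[[i]]$heavy_areas)), 0)
  expect_error(generate_transition_runs(n_transitions = 2), ">= 3")
  # distortion > 0 degrades rdotp below 1
  rd <- generate_transition_runs(n_peptides = 1, distortion = 0.5, seed = 1)
  expect_lt(rdotp_gate(rd[[1]]$light_areas, rd[[1]]$heavy_areas)$rdotp, 1)
})

test_that("text round-trips are lossless and bitwise-stable", {
  g <- generate_group_quant(sim_config(n_features = 30, n_pos = 3,
                                       n_neg = 3, n_true = 5, seed = 6))
  mt <- apply_mnar_missingness(g$table, 0.2, seed = 6)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(mt, f1)
  write_quant_table(mt, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_quant_table(f1)
  expect_equal(unclass(back), unclass(mt))

  runs <- generate_transition_runs(n_peptides = 2, seed = 2,
                                   distortion = 0.2)
  ft <- withr::local_tempfile(fileext = ".csv")
  write_transition_runs(runs, ft)
  back_runs <- read_transition_runs(ft)
  expect_identical(length(back_runs), length(runs))
  expect_equal(back_runs[[1]]$light_areas, runs[[1]]$light_areas)

  labf <- withr::local_tempfile(fileext = ".tsv")
  write_group_labels(g$labels, labf)
  expect_identical(read_group_labels(labf), g$labels)

  tj <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(g$truth, tj)
  expect_identical(read_ground_truth(tj)$true_differential$feature_id,
                   g$truth$true_differential$feature_id)
})

test_that("raw-scale export inverts log2_transform", {
  g <- generate_group_quant(sim_config(n_features = 20, n_pos = 3,
                                       n_neg = 3, n_true = 4, seed = 8))
  mt <- apply_mnar_missingness(g$table, 0.25, seed = 8)
  raw <- as_raw_intensities(mt)
  expect_true(all(raw[is.na(mt)] == 0))
  back <- log2_transform(raw)
  expect_equal(unclass(back), unclass(mt))
})
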