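test_that("the standard genetic code enumerates 61 sense codons over 20 amino acids plus 3 stops", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  all64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0), c("A", "C", "G", "T"), paste0))
  aa <- translate_codon(all64)
  expect_equal(length(all64), 64L)
  expect_equal(sum(aa == "*"), 3L)
  expect_equal(length(setdiff(unique(aa), "*")), 20L)
  expect_setequal(setdiff(unique(aa), "*"), AA_ALPHABET)
  expect_error(translate_codon("AUN"), "A, C, G, T")
})

test_that("NNN libraries are uniform over 64 codons, seeded, and carry the binomial stop fraction", {
  region1 <- region_spec("toy", 1, 1, "M")
  lib <- build_nnn_library(region1, 64000L, seed = 101)
  stop_frac <- mean(lib$mut_aa == "*")
  p <- 3 / 64
  expect_lt(abs(stop_frac - p), 3 * sqrt(p * (1 - p) / 64000))

  expect_equal(nrow(build_nnn_library(region1, 0L, seed = 1)), 0L)

  region <- toy_region()
  l1 <- build_nnn_library(region, 50L, seed = 7)
  l2 <- build_nnn_library(region, 50L, seed = 7)
  expect_identical(l1, l2)
  l3 <- build_nnn_library(region, 50L, seed = 8)
  expect_false(identical(l1$codon, l3$codon))
  # position-major layout, `draw` indexes within position
  expect_equal(l1$position, rep(region_positions(region), each = 50))
  expect_equal(l1$draw[1:50], 1:50)
})

test_that("selection keeps exactly truth alleles, never stops, and tallies hits correctly", {
  region <- toy_region()
  truth <- sample_truth_set(region, 30, seed = 2)
  cfg <- screen_config(region, n_per_position = 300L, detection_prob = 0.6,
                       seed = 12)
  sample_out <- run_screen(cfg, truth)
  surv <- sample_out$survivors
  expect_gt(nrow(surv), 0)
  expect_false(any(surv$mut_aa == "*"))
  expect_true(all(paste(surv$position, surv$mut_aa) %in%
                    paste(truth$position, truth$mut_aa)))
  expect_lte(nrow(sample_out$records), nrow(truth))
  # hit counts equal an independent tally of the survivor list
  tally <- table(paste(surv$position, surv$mut_aa))
  expect_equal(sample_out$records$hit_count,
               unname(as.integer(tally[paste(sample_out$records$position,
                                             sample_out$records$mut_aa)])))
  # hit_saturation equals a direct recount
  expect_equal(hit_saturation(sample_out$records), mean(tally >= 2))

  # identical seeds give bit-identical outputs
  again <- run_screen(cfg, truth)
  expect_identical(sample_out$survivors, again$survivors)
  expect_equal(as.data.frame(sample_out$records), as.data.frame(again$records))

  # empty truth: zero survivors
  empty <- truth_set(region, data.frame(position = integer(),
                                        mut_aa = character()))
  expect_equal(nrow(run_screen(cfg, empty)$survivors), 0L)

  # full truth, detection 1, deep library: all 19 * L alleles recovered
  small <- region_spec("toy", 1, 3, "MKL")
  wt <- region_residues(small)
  full <- truth_set(small, do.call(rbind, lapply(1:3, function(i) {
    data.frame(position = i, mut_aa = setdiff(AA_ALPHABET, wt[i]))
  })))
  deep <- run_screen(screen_config(small, 4000L, 1, seed = 5), full)
  expect_equal(nrow(deep$records), 19L * 3L)
})

test_that("truth sets reject identity and stop alleles and round-trip through JSON with the config", {
  region <- toy_region()
  expect_error(truth_set(region, data.frame(position = 10, mut_aa = "L")),
               "identity")
  expect_error(truth_set(region, data.frame(position = 10, mut_aa = "*")),
               "stop")
  expect_error(truth_set(region, data.frame(position = 99, mut_aa = "R")),
               "outside")

  truth <- sample_truth_set(region, 12, seed = 4)
  tj <- tempfile(fileext = ".json")
  write_truth_set(truth, tj)
  back <- read_truth_set(tj)
  expect_equal(as.data.frame(back), as.data.frame(truth))

  cfg <- screen_config(region, 250L, 0.3, seed = 9)
  cj <- tempfile(fileext = ".json")
  write_screen_config(cfg, cj)
  cfg2 <- read_screen_config(cj)
  expect_equal(cfg2$n_per_position, 250L)
  expect_equal(cfg2$detection_prob, 0.3)
  expect_equal(cfg2$region$wt_sequence, region$wt_sequence)
  # same config file reproduces the same screen
  expect_identical(run_screen(cfg, truth)$survivors,
                   run_screen(cfg2, back)$survivors)
})

test_that("saturation curves are monotone in depth and match a full re-screen at full depth", {
  region <- toy_region()
  truth <- sample_truth_set(region, 40, seed = 31)
  cfg <- screen_config(region, 200L, 0.5, seed = 77)
  lib <- build_nnn_library(region, 200L, seed = cfg$seed)
  curve <- saturation_curve(lib, truth, cfg, depths = c(0L, 10L, 50L, 200L))

  expect_equal(curve$n_revertants[1], 0L)
  expect_true(is.na(curve$fraction_multi_hit[1]))
  expect_true(all(diff(curve$n_distinct) >= 0))
  expect_true(all(diff(curve$n_revertants) >= 0))

  # full-depth row equals an independent screen + tally with the same seed
  sim <- simulate_screen(lib, truth, cfg)
  expect_equal(curve$n_revertants[4], nrow(sim$survivors))
  expect_equal(curve$n_distinct[4], nrow(sim$records))
  expect_equal(curve$fraction_multi_hit[4], hit_saturation(sim$records))

  expect_error(saturation_curve(lib, truth, cfg, depths = c(50L, 10L)),
               "ascending")
  expect_error(saturation_curve(lib, truth, cfg, depths = 500L), "exceeds")
})

test_that("the multi-hit fraction tracks sampling depth and detection skew", {
  region <- region_spec("toy", 1, 20, "SNEKTSDIQASNEKTSDIQA")
  truth <- sample_truth_set(region, 40, seed = 13)
  # deep, uniformly well-detected screen: most alleles seen twice or more
  deep <- run_screen(screen_config(region, 2000L, 0.9, seed = 1), truth)
  # shallow screen: most alleles seen at most once
  shallow <- run_screen(screen_config(region, 60L, 0.08, seed = 1), truth)
  expect_gt(hit_saturation(deep$records), 0.9)
  expect_lt(hit_saturation(shallow$records), hit_saturation(deep$records))

  # skewing detection toward a subset drags the statistic down at fixed yield:
  # strongly detected alleles recur while weak ones surface once
  skew_tab <- data.frame(position = truth$position, mut_aa = truth$mut_aa,
                         prob = rep(c(0.9, 0.03), length.out = nrow(truth)))
  skew <- run_screen(screen_config(region, 400L, detection_prob = 0.9,
                                   detection_table = skew_tab, seed = 3),
                     truth)
  unif <- run_screen(screen_config(region, 400L, 0.9, seed = 3), truth)
  expect_lt(hit_saturation(skew$records), hit_saturation(unif$records))
})
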