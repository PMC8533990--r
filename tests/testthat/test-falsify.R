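small_study <- function(signal = "none", seed = 1, n_genes = 150,
                        n_samples = 80, effect = 1) {
  make_synthetic_study(synth_spec(n_genes = n_genes, n_samples = n_samples,
                                  n_terms = 20, signature_size = 8,
                                  signal = signal, effect = effect,
                                  seed = seed))
}

test_that("bonferroni adjustment is min(1, B * p) with range checks", {
  expect_equal(bonferroni(0.01, 10), 0.1)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(c(0.3, 0.02), 1), c(0.3, 0.02))
  expect_error(bonferroni(c(0.2, 1.2)), "\\[0, 1\\]")
  # agrees with p.adjust when B equals the family size
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_equal(bonferroni(p), stats::p.adjust(p, method = "bonferroni"))
})

test_that("the prognostic task joins samples and returns a p-value", {
  st <- small_study("signature_only", seed = 4)
  task <- run_prognostic_task(st$expr, st$clinical, st$signature$genes)
  expect_false(task$degenerate)
  expect_lt(task$p_value, 0.05)
  # determinism
  task2 <- run_prognostic_task(st$expr, st$clinical, st$signature$genes)
  expect_identical(task2$p_value, task$p_value)
  # no shared samples -> error
  cl <- st$clinical; cl$sample <- paste0("x", cl$sample)
  expect_error(run_prognostic_task(st$expr, cl, st$signature$genes),
               "share no samples")
  # all-censored clinical surfaces the log-rank error
  cl0 <- st$clinical; cl0$event <- 0
  expect_error(run_prognostic_task(st$expr, cl0, st$signature$genes),
               "zero events")
})

test_that("null prognostic p-values are approximately uniform", {
  withr::local_seed(314)
  p <- replicate(300, {
    sp <- synth_spec(n_genes = 12, n_samples = 60, signature_size = 8,
                     signal = "none", seed = NULL)
    co <- make_cohort(sp)
    run_prognostic_task(co$expr, co$clinical, co$signature$genes)$p_value
  })
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a fixed seed makes the falsification report reproducible", {
  st <- small_study("none", seed = 6)
  cfg <- falsification_config(B = 5, seed = 123)
  r1 <- suppressWarnings(falsification_run(st$expr, st$clinical, st$map,
                                           st$signature, cfg, pg = st$pg))
  r2 <- suppressWarnings(falsification_run(st$expr, st$clinical, st$map,
                                           st$signature, cfg, pg = st$pg))
  expect_identical(r1, r2)
  expect_equal(nrow(r1$surrogate), 5)
  expect_equal(r1$surrogate$p_adj, pmin(1, 5 * r1$surrogate$p))
})

test_that("strong-mode surrogates never share GO terms with the signature", {
  st <- small_study("none", seed = 8)
  cfg <- falsification_config(B = 25, seed = 9, mode = "strong")
  rep <- suppressWarnings(falsification_run(st$expr, st$clinical, st$map,
                                            st$signature, cfg, pg = st$pg))
  for (g in rep$surrogate$genes) {
    expect_length(common_meaning(st$map, g, st$signature$genes), 0)
  }
})

test_that("family-wise error under the null stays at or below alpha", {
  withr::local_seed(2718)
  any_sig <- replicate(100, {
    st <- make_synthetic_study(synth_spec(n_genes = 60, n_samples = 60,
                                          n_terms = 15, signature_size = 5,
                                          signal = "none", seed = NULL))
    cfg <- falsification_config(B = 100, alpha = 0.05, seed = NULL)
    rep <- suppressWarnings(falsification_run(st$expr, st$clinical, st$map,
                                              st$signature, cfg, pg = st$pg))
    rep$n_significant > 0
  })
  fwer <- mean(any_sig)
  # 0.05 + 2.58 * sqrt(0.05 * 0.95 / 100)
  expect_lte(fwer, 0.106)
})

test_that("signature genes missing from the matrix shrink |BM| with a warning", {
  st <- small_study("none", seed = 10)
  bm <- signature(c(st$signature$genes, "ghost_gene"), name = "padded")
  cfg <- falsification_config(B = 3, seed = 2)
  expect_warning(
    rep <- falsification_run(st$expr, st$clinical, st$map, bm, cfg, pg = st$pg),
    "absent from expression")
  expect_equal(length(rep$signature_genes), length(st$signature$genes))
  expect_true(all(lengths(rep$surrogate$genes) == length(st$signature$genes)))
})
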