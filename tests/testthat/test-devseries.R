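test_that("concurrent model pairs identical sample keys", {
  ds <- noiseless_dataset()
  spec <- model_spec("N vs N", "concurrent")
  m <- build_concurrent(ds$expression, ds$traits, spec)
  expect_equal(nrow(m$ge), 27)
  expect_identical(m$ge_keys, m$cw_keys)
  expect_equal(m$outcome_kind, "level")
  # values equal the source matrices at matching keys
  i <- 5
  k <- m$ge_keys[i, ]
  src <- which(ds$expression$keys$genotype == k$genotype &
                 ds$expression$keys$position == k$position &
                 ds$expression$keys$replicate == k$replicate)
  expect_equal(m$ge[i, ], ds$expression$values[src, ])

  sub <- model_spec("A4 N vs N", "concurrent", genotypes = "A4")
  expect_equal(nrow(build_concurrent(ds$expression, ds$traits, sub)$ge), 9)
})

test_that("delta model row counts follow G * R * (T - k)", {
  ds <- noiseless_dataset()
  d1 <- build_delta(ds$expression, ds$traits, model_spec("d1", "delta",
                                                         k = 1))
  expect_equal(nrow(d1$ge), 3 * 3 * (3 - 1))
  d2 <- build_delta(ds$expression, ds$traits, model_spec("d2", "delta",
                                                         k = 2))
  expect_equal(nrow(d2$ge), 3 * 3 * (3 - 2))
  # longer series obeys the same closed form
  ds4 <- generate_dataset(sim_config(noise_cv = 0,
                                     positions = c("P0", "P1", "P2", "P3")))
  for (k in 1:3) {
    dk <- build_delta(ds4$expression, ds4$traits,
                      model_spec("dk", "delta", k = k))
    expect_equal(nrow(dk$ge), 3 * 3 * (4 - k))
  }
})

test_that("delta outcomes are the within-replicate trait changes", {
  ds <- noiseless_dataset()
  d1 <- build_delta(ds$expression, ds$traits, model_spec("d1", "delta",
                                                         k = 1))
  expect_equal(d1$outcome_kind, "delta")
  for (i in seq_len(nrow(d1$ge))) {
    gk <- d1$ge_keys[i, ]; ck <- d1$cw_keys[i, ]
    expect_equal(ck$genotype, gk$genotype)
    expect_equal(ck$replicate, gk$replicate)
    expect_equal(ck$position, gk$position + 1L)
    at <- function(pos) ds$traits$values[
      ds$traits$keys$genotype == gk$genotype &
        ds$traits$keys$position == pos &
        ds$traits$keys$replicate == gk$replicate, "lignin"]
    expect_equal(unname(d1$cw[i, "lignin"]),
                 unname(at(gk$position + 1L) - at(gk$position)))
  }
})

test_that("degenerate delta offsets are rejected", {
  ds <- noiseless_dataset()
  expect_error(model_spec("d0", "delta", k = 0), "k >= 1")
  expect_error(build_delta(ds$expression, ds$traits,
                           model_spec("d3", "delta", k = 3)),
               "exceeds the series span")
  expect_error(model_spec("c1", "concurrent", k = 1), "k = 0")
})

test_that("cumulative models support offsets and fixed cross-series pairs", {
  two <- two_series_dataset()
  # pooled one-step cumulative on stages: 18 rows
  cum <- build_cumulative(two$expression, two$traits,
                          model_spec("Stages N vs N + 1", "cumulative",
                                     k = 1, series = "stage"))
  expect_equal(nrow(cum$ge), 18)
  expect_equal(cum$outcome_kind, "level")
  # segment S1 expression against stage R3 composition: 9 replicate pairs
  s1r3 <- build_cumulative(two$expression, two$traits,
                           model_spec("S1_E4 vs R3", "cumulative",
                                      ge_fixed = list(series = "segment",
                                                      position = 2L),
                                      cw_fixed = list(series = "stage",
                                                      position = 2L)))
  expect_equal(nrow(s1r3$ge), 9)
  expect_true(all(s1r3$ge_keys$series == "segment"))
  expect_true(all(s1r3$cw_keys$series == "stage"))
  expect_true(all(s1r3$ge_keys$genotype == s1r3$cw_keys$genotype))
  # fixed same-position pairing is the concurrent model on that subset
  r3 <- build_cumulative(two$expression, two$traits,
                         model_spec("R3 vs R3", "cumulative",
                                    ge_fixed = list(series = "stage",
                                                    position = 2L),
                                    cw_fixed = list(series = "stage",
                                                    position = 2L)))
  conc <- build_concurrent(two$expression, two$traits,
                           model_spec("conc", "concurrent",
                                      series = "stage"))
  keep <- conc$ge_keys$position == 2L
  expect_equal(sort(r3$ge[cbind(seq_len(9), 1)]),
               sort(conc$ge[keep, 1]))
  expect_equal(nrow(r3$ge), 9)
})

test_that("old-to-young direction reverses the pairing", {
  ds <- noiseless_dataset()
  fwd <- build_delta(ds$expression, ds$traits,
                     model_spec("f", "delta", k = 1))
  rev <- build_delta(ds$expression, ds$traits,
                     model_spec("r", "delta", k = 1,
                                direction = "old_to_young"))
  expect_equal(nrow(rev$ge), nrow(fwd$ge))
  # reversed direction pairs each position with the one before it
  expect_true(all(rev$cw_keys$position == rev$ge_keys$position - 1L))
})

test_that("run_model yields the full gene-by-outcome family", {
  ds <- noiseless_dataset()
  d1 <- build_delta(ds$expression, ds$traits,
                    model_spec("d1", "delta", k = 1))
  rec <- run_model(d1, B = 300, seed = 5)
  expect_equal(nrow(rec), 11 * 6)
  expect_true(all(rec$status == "ok"))
  # correct-lag construction: lagged traits perfect positive, ED perfect
  # negative for every gene (tied replicate triples allow ulp-level slack)
  expect_equal(rec$gcc[rec$outcome %in% c("lignin", "pCA")],
               rep(1, 22), tolerance = 1e-12)
  expect_equal(rec$gcc[rec$outcome_class == "digestibility"],
               rep(-1, 33), tolerance = 1e-12)
  # q-values computed within the 66-test family
  expect_true(all(rec$q[rec$outcome == "lignin"] < 0.05))
})

test_that("constant columns are flagged, and row order never matters", {
  ds <- noiseless_dataset()
  d1 <- build_delta(ds$expression, ds$traits,
                    model_spec("d1", "delta", k = 1))
  d1c <- d1
  d1c$ge[, "CAD"] <- 1  # constant transcript
  rec <- run_model(d1c, B = 100, seed = 5)
  expect_true(all(grepl("constant", rec$status[rec$gene == "CAD"])))
  expect_true(all(is.na(rec$gcc[rec$gene == "CAD"])))
  expect_true(all(rec$status[rec$gene != "CAD"] == "ok"))

  set.seed(99)
  shuf <- sample(nrow(d1$ge))
  d1s <- d1
  d1s$ge <- d1$ge[shuf, , drop = FALSE]
  d1s$cw <- d1$cw[shuf, , drop = FALSE]
  d1s$ge_keys <- d1$ge_keys[shuf, , drop = FALSE]
  d1s$cw_keys <- d1$cw_keys[shuf, , drop = FALSE]
  a <- run_model(d1, B = 200, seed = 17)
  b <- run_model(d1s, B = 200, seed = 17)
  expect_equal(a$gcc, b$gcc)
  expect_equal(a$p, b$p)
})

test_that("by-genotype-mean pairing collapses replicates", {
  ds <- noiseless_dataset()
  d1 <- build_delta(ds$expression, ds$traits,
                    model_spec("d1", "delta", k = 1,
                               pairing = "by_genotype_mean"))
  expect_equal(nrow(d1$ge), 3 * (3 - 1))
  expect_error(run_model(d1[["ge"]]), class = "error")
  expect_error(run_model(structure(list(ge = d1$ge[1:2, ], cw = d1$cw[1:2, ],
                                        spec = d1$spec),
                                   class = "model_dataset")),
               "insufficient-data")
})

test_that("significant-coefficient matrix mirrors the records", {
  ds <- noiseless_dataset()
  d1 <- build_delta(ds$expression, ds$traits,
                    model_spec("d1", "delta", k = 1))
  rec <- run_model(d1, B = 300, seed = 5)
  m <- significant_gcc_matrix(rec)
  expect_equal(dim(m), c(11, 6))
  sig <- !is.na(rec$q) & rec$q < rec$q_cutoff[1]
  expect_equal(sum(!is.na(m)), sum(sig))
  expect_equal(m["4CL", "lignin"],
               rec$gcc[rec$gene == "4CL" & rec$outcome == "lignin"])
})
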