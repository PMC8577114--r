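small_sim_config <- function(seed, ...) {
  simulation_config(seed = seed, substrate_length = 400L, background_length = 1500L,
                    n_sites = 5L, ...)
}

empty_calls_for_test <- function() {
  merge_evidence(list())
}

run_sim_pipeline <- function(sim) {
  res <- suppressMessages(suppressWarnings(
    run_pipeline(run_config(fasta = sim$proteins,
                            tables = list(run1 = sim$table)))))
  score_calls(res$calls, sim$truth)
}

test_that("identical seeds give byte-identical simulated tables", {
  t1 <- simulate_experiment(simulation_config(seed = 7, substrate_length = 300L,
                                              background_length = 1000L, n_sites = 5L))
  t2 <- simulate_experiment(simulation_config(seed = 7, substrate_length = 300L,
                                              background_length = 1000L, n_sites = 5L))
  expect_identical(t1$table, t2$table)
  expect_identical(t1$truth$planted, t2$truth$planted)
  t3 <- simulate_experiment(simulation_config(seed = 8, substrate_length = 300L,
                                              background_length = 1000L, n_sites = 5L))
  expect_false(identical(t1$table, t3$table))
})

test_that("the noise-free limit recovers every planted site exactly", {
  cfg <- simulation_config(seed = 3, substrate_length = 500L, background_length = 0L,
                           n_sites = 5L, replicate_cv = 0, dropout = 0,
                           contaminant_rate = 0, baseline_log2_sd = 0)
  sim <- simulate_experiment(cfg)
  sc <- run_sim_pipeline(sim)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$n_calls, 5L)
})

test_that("every emitted semi-tryptic peptide traces to a planted or contaminant bond", {
  for (seed in 1:5) {
    sim <- simulate_experiment(small_sim_config(seed))
    tp <- sim$truth$peptides
    semis <- tp[tp$origin != "tryptic", ]
    expect_true(all(!is.na(semis$bond)))
    planted_ok <- semis$origin != "planted" | semis$bond %in% sim$truth$planted$p1
    expect_true(all(planted_ok))
    # every table sequence traces back to a truth peptide
    expect_true(all(sim$table$sequence %in% tp$sequence))
    # exposed terminus sits at the bond
    expect_true(all(semis$start == semis$bond + 1L | semis$end == semis$bond))
  }
})

test_that("explicitly planting a trypsin-producible site warns or errors", {
  base <- simulate_experiment(small_sim_config(1))
  res <- strsplit(base$proteins$SYN_SUBSTRATE$sequence, "")[[1]]
  kr <- which(res %in% c("K", "R") & c(res[-1], "") != "P")[[5]]
  cfg <- simulation_config(seed = 1, substrate = base$proteins$SYN_SUBSTRATE,
                           background_length = 0L,
                           planted_sites = data.frame(p1 = kr, efficiency = 1))
  expect_warning(sim <- simulate_experiment(cfg), "invisible")
  expect_true(sim$truth$planted$blind)
  cfg_strict <- simulation_config(seed = 1, substrate = base$proteins$SYN_SUBSTRATE,
                                  background_length = 0L, strict = TRUE,
                                  planted_sites = data.frame(p1 = kr, efficiency = 1))
  expect_error(simulate_experiment(cfg_strict), "invisible")
  # blind sites are excluded from the recall denominator
  sc <- score_calls(empty_calls_for_test(), sim$truth)
  expect_true(is.na(sc$recall) || sc$recall == 0)
})

test_that("higher cleavage efficiency never lowers detectability", {
  # steep abundance-dependent dropout: a weak site's product should vanish
  # more often than a strong site's
  det <- matrix(0, nrow = 2, ncol = 30)
  base <- simulate_experiment(simulation_config(seed = 99, substrate_length = 400L,
                                                background_length = 0L, n_sites = 2L))
  sub <- base$proteins$SYN_SUBSTRATE
  planted <- base$truth$planted
  for (s in 1:30) {
    cfg <- simulation_config(seed = 1000 + s, substrate = sub, background_length = 0L,
                             planted_sites = data.frame(p1 = planted$p1,
                                                        efficiency = c(0.02, 1)),
                             dropout = 0.5, dropout_slope = 2)
    sim <- simulate_experiment(cfg)
    tp <- sim$truth$peptides
    for (k in 1:2) {
      seqs <- tp$sequence[tp$origin == "planted" & tp$bond == planted$p1[[k]]]
      obs <- sim$table[sim$table$sequence %in% seqs,
                       c("abundance:WT:1", "abundance:WT:2")]
      det[k, s] <- as.integer(nrow(obs) > 0 && any(!is.na(unlist(obs))))
    }
  }
  expect_gt(mean(det[2, ]), mean(det[1, ]))
})

test_that("score_calls matches hand-counted confusion entries", {
  truth <- list(
    planted = tibble::tibble(p1 = c(10L, 20L, 30L), efficiency = 1,
                             blind = c(FALSE, FALSE, TRUE), detectable = TRUE),
    substrate_id = "S"
  )
  calls <- tibble::tibble(protein_id = c("S", "S", "S"), p1 = c(10L, 40L, 20L))
  sc <- score_calls(calls, truth)
  expect_equal(sc$recall, 1)            # both non-blind sites called
  expect_equal(sc$precision, 2 / 3)     # call at 40 is false
  expect_equal(sc$false_calls$p1, 40L)
  sc0 <- score_calls(calls[0, ], truth)
  expect_equal(sc0$recall, 0)
  expect_true(is.na(sc0$precision))     # undefined with no calls
  expect_equal(score_calls(calls[c(1, 3), ], truth)$precision, 1)
})
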