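test_that("the hypergeometric tail matches exact rational arithmetic", {
  g <- hyper_grid()
  for (i in seq_len(nrow(g))) {
    p <- hypergeometric_test(g$N[i], g$K[i], g$n[i], g$k[i])
    expect_lte(abs(p - g$p[i]) / g$p[i], 1e-12)
  }
})

test_that("the hypergeometric tail agrees with the distribution in stats", {
  set.seed(8)
  for (i in 1:40) {
    N <- sample(5:200, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_test(N, K, n, k),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("hypergeometric edge cases and domain errors behave", {
  expect_equal(hypergeometric_test(100, 10, 20, 0), 1)     # certain event
  expect_equal(hypergeometric_test(50, 50, 12, 12), 1)     # pathway = universe
  expect_error(hypergeometric_test(10, 20, 5, 2), "inconsistent")
  expect_error(hypergeometric_test(10, 5, 5, 6), "inconsistent")
})

test_that("BH step-up matches the hand-computed example and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.8))
  expect_equal(bh_adjust(0.37), 0.37)                      # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))        # ties stay put
  set.seed(21)
  for (i in 1:20) {
    p <- stats::runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"))
  }
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("BH adjustment is permutation-equivariant and monotone", {
  set.seed(33)
  for (i in 1:15) {
    p <- stats::runif(12)
    perm <- sample(12)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
    p2 <- p
    j <- sample(12, 1)
    p2[j] <- min(1, p2[j] + stats::runif(1, 0, 1 - p2[j]))
    expect_true(all(bh_adjust(p2) >= bh_adjust(p) - 1e-12))
  }
})

test_that("pathway enrichment counts, universe and strict-active rule are right", {
  toy <- generate_toy_network(seed = 2)
  calls <- data.frame(reaction = toy$reactions$id, verdict = "undetermined",
                      stringsAsFactors = FALSE)
  planted <- toy$reactions$id[toy$reactions$pathway == "gluconeogenesis"]
  calls$verdict[calls$reaction %in% planted] <- "active"
  # exchanges are active too but carry no pathway: excluded from the universe
  calls$verdict[toy$reactions$exchange] <- "active"
  res <- suppressMessages(enrich_pathways(calls, toy, alpha = 0.05))
  expect_equal(res$N[1], 24L)
  expect_equal(res$n[1], 6L)
  top <- res[1, ]
  expect_identical(top$pathway, "gluconeogenesis")
  expect_equal(top$k, 6L)
  expect_equal(top$K, 6L)
  expect_true(top$significant)
  # undetermined reactions do not count as active
  expect_equal(res$k[res$pathway == "decoy_1"], 0L)
  expect_equal(res$p_raw[res$pathway == "decoy_1"], 1)
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(res$k <= pmin(res$K, res$n)))

  # empty active set: all p-values 1, with a message
  none <- data.frame(reaction = toy$reactions$id, verdict = "inactive")
  expect_message(res0 <- enrich_pathways(none, toy), "empty active set")
  expect_true(all(res0$p_raw == 1))
})

test_that("the enrichment contrast labels A-only/B-only/both/neither", {
  toy <- generate_toy_network(seed = 2)
  active_in <- function(pathways) {
    calls <- data.frame(reaction = toy$reactions$id, verdict = "inactive",
                        stringsAsFactors = FALSE)
    calls$verdict[toy$reactions$pathway %in% pathways] <- "active"
    suppressMessages(enrich_pathways(calls, toy))
  }
  ra <- active_in("gluconeogenesis")
  rb <- active_in("decoy_2")
  ct <- contrast_enrichment(ra, rb)
  expect_identical(ct$status[ct$pathway == "gluconeogenesis"], "A_only")
  expect_identical(ct$status[ct$pathway == "decoy_2"], "B_only")
  expect_identical(ct$status[ct$pathway == "decoy_1"], "neither")
  # identical inputs produce no one-sided flags
  ct2 <- contrast_enrichment(ra, ra)
  expect_false(any(ct2$status %in% c("A_only", "B_only")))
  expect_error(contrast_enrichment(ra, rb[-1, ]), "pathway sets differ")
})
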