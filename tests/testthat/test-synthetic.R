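test_that("the toy network has the documented shape and is valid", {
  toy <- generate_toy_network(n_pathways = 5, pathway_length = 6, seed = 1)
  expect_equal(nrow(toy$reactions), 5 * 6 + 10)   # internal + 2 exchanges each
  expect_equal(sum(toy$reactions$exchange), 10L)
  expect_equal(length(setdiff(unique(toy$reactions$pathway), "")), 5L)
  expect_equal(nrow(validate_model(toy)), 0L)     # no violations, no dead ends
  # one transport step: consecutive metabolites in different compartments
  comp <- toy$metabolites$compartment[toy$metabolites$id %in%
                                        paste0("gluc_m", 1:7)]
  expect_equal(sum(comp == "er"), 2L)
  # every internal reaction has a unique single-gene GPR and a pathway label
  internal <- !toy$reactions$exchange
  expect_false(any(duplicated(toy$reactions$gpr[internal])))
  expect_true(all(nzchar(toy$reactions$pathway[internal])))
  expect_error(generate_toy_network(n_pathways = 1), "n_pathways")
  expect_error(generate_toy_network(pathway_length = 2), "pathway_length")
})

test_that("the paired GPR mode emits two-gene complex/isozyme rules", {
  toy <- generate_toy_network(seed = 1, gpr_mode = "paired")
  internal <- which(!toy$reactions$exchange)
  expect_true(all(grepl(" (and|or) ", toy$reactions$gpr[internal])))
  sc <- generate_expression(toy, seed = 1)
  expect_gt(nrow(sc$profile$values), sum(!toy$reactions$exchange))
})

test_that("the planted pathway is never stoichiometrically blocked", {
  for (seed in 1:5) {
    toy <- generate_toy_network(seed = seed)
    planted <- toy$reactions$id[toy$reactions$pathway == "gluconeogenesis"]
    st <- data.frame(reaction = toy$reactions$id, state = 0L)
    st$state[st$reaction %in% planted] <- 1L
    sol <- solve_imat(toy, st)
    expect_identical(sol$objective, length(planted))  # all cues satisfiable
    expect_true(all(sol$flux[planted] >= 1))
  }
})

test_that("scenario generation is deterministic in the seed", {
  toy <- generate_toy_network(seed = 4)
  s1 <- generate_expression(toy, seed = 4)
  s2 <- generate_expression(toy, seed = 4)
  expect_identical(s1$profile$values, s2$profile$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_expression(toy, seed = 5)
  expect_false(identical(s1$profile$values, s3$profile$values))
  t1 <- generate_toy_network(seed = 4)
  expect_identical(toy$reactions, t1$reactions)
  expect_identical(unname(toy$S), unname(t1$S))
})

test_that("planted genes separate from baseline as the noise model implies", {
  toy <- generate_toy_network(seed = 1)
  hits <- 0L
  for (seed in 1:60) {
    sc <- generate_expression(toy, seed = seed)
    mA <- summarize_condition(sc$profile, "p53_active")
    planted_rxn <- sc$truth$reaction[sc$truth$condition == "p53_active" &
                                       sc$truth$intended_state == 1L]
    pg <- unique(unlist(lapply(toy$gpr_ast[planted_rxn], fluxcue:::gpr_genes)))
    if (all(mA[pg] > 5 + 3 * 1 / sqrt(3))) hits <- hits + 1L
  }
  expect_gte(hits, 59L)  # >= 99% of seeds in expectation
})

test_that("a near-noiseless scenario discretizes exactly to the truth table", {
  # explicit thresholds at the midpoints between the three expression levels;
  # quantile cues by construction always label a fixed fraction of genes, so
  # exact truth recovery is a property of the threshold mode
  toy <- generate_toy_network(seed = 9)
  sc <- generate_expression(toy, sigma = 1e-6, seed = 9)
  for (cond in c("p53_active", "p53_depleted")) {
    gs <- discretize_expression(summarize_condition(sc$profile, cond),
                                t_low = 2.5, t_high = 7.5)
    st <- suppressMessages(assign_reaction_states(toy, gs, cond))
    truth <- sc$truth[sc$truth$condition == cond, ]
    expect_identical(st$state, truth$intended_state[match(st$reaction,
                                                          truth$reaction)])
  }
})

test_that("truth covers every reaction in both conditions", {
  toy <- generate_toy_network(seed = 2)
  sc <- generate_expression(toy, seed = 2)
  for (cond in c("p53_active", "p53_depleted")) {
    expect_setequal(sc$truth$reaction[sc$truth$condition == cond],
                    toy$reactions$id)
  }
})
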