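test_that("build_milp reports the documented problem shape", {
  m <- toy_chain()
  p <- build_milp(m, chain_states(m, high = "R2"))
  expect_equal(p$n_continuous, 4L)
  expect_equal(p$n_binary, 1L)
  expect_equal(p$n_mass_balance, 3L)

  p0 <- build_milp(m, chain_states(m))
  expect_equal(p0$n_binary, 0L)

  # reversible high reaction carries two OR-linked binaries
  m$reactions$lb[2] <- -10
  m$reactions$reversible[2] <- TRUE
  p2 <- build_milp(m, chain_states(m, high = "R2"))
  expect_equal(p2$n_binary, 2L)
  expect_identical(p2$cue_table$n_binaries, 2L)

  st_bad <- rbind(chain_states(m), data.frame(reaction = "nope", state = 1L))
  expect_error(build_milp(m, st_bad), "unknown reactions")
})

test_that("the chain, conflict and moderate cases give objectives 1, 1, 0", {
  m <- toy_chain()
  s1 <- solve_imat(m, chain_states(m, high = "R2"))
  expect_identical(s1$objective, 1L)
  expect_identical(s1$solver_status, "optimal")
  expect_true(all(s1$flux >= 1))  # the whole chain must run to satisfy R2

  # mass balance forces v_R1 = v_R2: high R1 and low R2 cannot both hold
  s2 <- solve_imat(m, chain_states(m, high = "R1", low = "R2"))
  expect_identical(s2$objective, 1L)

  s0 <- solve_imat(m, chain_states(m))
  expect_identical(s0$objective, 0L)
  expect_equal(max(abs(s0$flux)), 0)  # all-zero flux is optimal with no cues
})

test_that("solutions respect mass balance, bounds and the indicator count", {
  insts <- c(list(list(model = toy_chain(),
                       states = chain_states(toy_chain(), high = "R2", low = "R4"))),
             lapply(1:8, random_small_instance))
  for (inst in insts) {
    sol <- solve_imat(inst$model, inst$states)
    expect_identical(sol$solver_status, "optimal")
    expect_lte(max(abs(inst$model$S %*% sol$flux)), 1e-6)
    expect_true(all(sol$flux >= inst$model$reactions$lb - 1e-9))
    expect_true(all(sol$flux <= inst$model$reactions$ub + 1e-9))
    # the objective equals the number of satisfied cues implied by the flux
    cfg <- imat_config()
    implied <- 0L
    for (i in seq_len(nrow(sol$indicators))) {
      v <- sol$flux[[sol$indicators$reaction[i]]]
      sat <- if (sol$indicators$state[i] == 1L) {
        abs(v) >= cfg$epsilon - 1e-7
      } else {
        abs(v) <= cfg$zero_tol + 1e-7
      }
      if (sat) implied <- implied + 1L
    }
    expect_identical(implied, sol$objective)
  }
})

test_that("the solver matches the exhaustive reference on random networks", {
  for (seed in 1:15) {
    inst <- random_small_instance(seed)
    fast <- solve_imat(inst$model, inst$states)
    slow <- brute_force_imat(inst$model, inst$states)
    expect_identical(fast$objective, slow$objective)
  }
})

test_that("the exhaustive solver refuses oversized instances", {
  toy <- generate_toy_network(n_pathways = 4, pathway_length = 6, seed = 1)
  st <- data.frame(reaction = toy$reactions$id, state = 0L)
  st$state[!toy$reactions$exchange] <- 1L  # 24 cues
  expect_error(brute_force_imat(toy, st), "exceed the limit")
  expect_identical(brute_force_imat(toy, chain_states(toy))$objective, 0L)
})

test_that("infeasible base constraints yield an infeasible status, not an error", {
  m <- toy_chain()
  m$reactions$lb[1] <- 5
  m$reactions$ub[4] <- 2  # import >= 5 but export <= 2 cannot balance
  sol <- solve_imat(m, chain_states(m))
  expect_identical(sol$solver_status, "infeasible")
  expect_true(is.na(sol$objective))
})

test_that("adding one cue changes the objective by 0 or +1", {
  for (seed in 16:25) {
    inst <- random_small_instance(seed)
    base <- solve_imat(inst$model, inst$states)$objective
    mod <- which(inst$states$state == 0L)
    j <- mod[1]
    for (s in c(1L, -1L)) {
      st2 <- inst$states
      st2$state[j] <- s
      obj2 <- solve_imat(inst$model, st2)$objective
      expect_true(obj2 %in% c(base, base + 1L))
    }
  }
})

test_that("objectives and verdicts are invariant to rescaling bounds and epsilon", {
  for (seed in 26:30) {
    inst <- random_small_instance(seed)
    cfg1 <- imat_config(epsilon = 1, zero_tol = 1e-6)
    cfg2 <- imat_config(epsilon = 50, zero_tol = 5e-5)
    scaled <- inst$model
    scaled$reactions$lb <- scaled$reactions$lb * 50
    scaled$reactions$ub <- scaled$reactions$ub * 50
    expect_identical(solve_imat(inst$model, inst$states, cfg1)$objective,
                     solve_imat(scaled, inst$states, cfg2)$objective)
    c1 <- classify_activity(inst$model, inst$states, cfg1)
    c2 <- classify_activity(scaled, inst$states, cfg2)
    expect_identical(c1$verdict, c2$verdict)
  }
})

test_that("forced re-optimization classifies the worked cases", {
  m <- toy_chain()
  ca <- classify_activity(m, chain_states(m, high = "R2"), condition = "A")
  expect_true(all(ca$verdict == "active"))
  expect_true(all(ca$obj_forced_inactive < ca$obj_forced_active))
  expect_true(all(ca$flux_min >= 1))

  dm <- diamond_network()
  cd <- classify_activity(dm, chain_states(dm, high = c("src", "sink")))
  expect_identical(cd$verdict[cd$reaction %in% c("src", "sink")],
                   c("active", "active"))
  expect_identical(cd$verdict[cd$reaction %in% c("ab", "bd", "ac", "cd")],
                   rep("undetermined", 4))
  expect_true(all(cd$obj_forced_active[cd$reaction == "ab"] ==
                    cd$obj_forced_inactive[cd$reaction == "ab"]))
})

test_that("a structurally blocked reaction is called inactive", {
  # M -> out with no producer of M: mass balance pins the flux at zero
  mets <- data.frame(id = c("M", "N"), name = c("M", "N"), compartment = "c")
  rxns <- data.frame(id = c("sinkM", "inN", "outN"), lb = 0, ub = 10, gpr = "",
                     pathway = "", exchange = c(TRUE, TRUE, TRUE))
  stoich <- list(sinkM = c(M = -1), inN = c(N = 1), outN = c(N = -1))
  m <- metabolic_model(mets, rxns, stoich, check = FALSE)
  ca <- classify_activity(m, chain_states(m))
  expect_identical(ca$verdict[ca$reaction == "sinkM"], "inactive")
  expect_equal(ca$flux_max[ca$reaction == "sinkM"], 0)
  expect_identical(ca$obj_forced_active[ca$reaction == "sinkM"], -Inf)
})

test_that("verdicts obey the forced-objective invariant table", {
  for (seed in 31:36) {
    inst <- random_small_instance(seed)
    ca <- classify_activity(inst$model, inst$states)
    act <- ca$verdict == "active"
    inact <- ca$verdict == "inactive"
    und <- ca$verdict == "undetermined"
    expect_true(all(ca$obj_forced_inactive[act] < ca$obj_forced_active[act]))
    expect_true(all(ca$obj_forced_active[inact] < ca$obj_forced_inactive[inact]))
    expect_true(all(ca$obj_forced_active[und] == ca$obj_forced_inactive[und]))
    opt <- attr(ca, "objective")
    expect_true(all(pmax(ca$obj_forced_active, ca$obj_forced_inactive) == opt))
    expect_true(all(ca$flux_min <= ca$flux_max + 1e-9))
  }
})

test_that("flux comparison uses strict interval separation", {
  a <- data.frame(reaction = c("r1", "r2"), condition = "A",
                  flux_min = c(1, 0), flux_max = c(2, 5))
  b <- data.frame(reaction = c("r1", "r2"), condition = "B",
                  flux_min = c(0, 0), flux_max = c(0, 5))
  cmp <- compare_conditions(a, b)
  expect_identical(cmp$call, c("higher_in_a", "indistinguishable"))
  b2 <- b[1, ]
  expect_error(compare_conditions(a, b2), "different reaction sets")
})

test_that("the solver honors its wall-clock budget with an incumbent", {
  inst <- random_small_instance(99)
  cfg <- imat_config(solver_time_limit = 1e-9)
  sol <- solve_imat(inst$model, inst$states, cfg)
  expect_identical(sol$solver_status, "feasible-timeout")
  expect_true(is.numeric(sol$objective) || is.integer(sol$objective))
})
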