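# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except the two shipped toy-chain files.

toy_chain <- function() {
  read_model_json(system.file("extdata", "toy_chain.json", package = "fluxcue"))
}

chain_states <- function(model, high = character(0), low = character(0)) {
  st <- data.frame(reaction = model$reactions$id, state = 0L,
                   stringsAsFactors = FALSE)
  st$state[st$reaction %in% high] <- 1L
  st$state[st$reaction %in% low] <- -1L
  st
}

# source -> A; A -> B -> D and A -> C -> D; D -> sink
diamond_network <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D"), name = c("A", "B", "C", "D"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("src", "ab", "bd", "ac", "cd", "sink"),
                     lb = 0, ub = 10, gpr = "", pathway = "",
                     exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  stoich <- list(src = c(A = 1), ab = c(A = -1, B = 1), bd = c(B = -1, D = 1),
                 ac = c(A = -1, C = 1), cd = c(C = -1, D = 1), sink = c(D = -1))
  metabolic_model(mets, rxns, stoich)
}

# Random small network with random conversions, exchanges, reversibility and
# cues; sized so the exhaustive reference solver stays cheap.
random_small_instance <- function(seed) {
  set.seed(seed)
  n_met <- sample(3:5, 1)
  mids <- paste0("M", seq_len(n_met))
  n_int <- sample(4:7, 1)
  rxns <- list()
  stoich <- list()
  for (i in seq_len(n_int)) {
    ab <- sample(n_met, 2)
    rid <- paste0("v", i)
    rev <- stats::runif(1) < 0.3
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = rid, lb = if (rev) -10 else 0, ub = 10, gpr = "", pathway = "",
      exchange = FALSE, stringsAsFactors = FALSE)
    stoich[[rid]] <- stats::setNames(c(-1, 1), mids[ab])
  }
  for (mi in sample(n_met, max(2L, ceiling(n_met / 2)))) {
    rid <- paste0("EX", mi)
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = rid, lb = -10, ub = 10, gpr = "", pathway = "", exchange = TRUE,
      stringsAsFactors = FALSE)
    stoich[[rid]] <- stats::setNames(1, mids[mi])
  }
  mets <- data.frame(id = mids, name = mids, compartment = "c",
                     stringsAsFactors = FALSE)
  model <- metabolic_model(mets, do.call(rbind, rxns), stoich)
  n_cue <- sample(2:6, 1)
  cue_r <- sample(model$reactions$id, n_cue)
  st <- data.frame(reaction = model$reactions$id, state = 0L,
                   stringsAsFactors = FALSE)
  st$state[match(cue_r, st$reaction)] <- sample(c(-1L, 1L), n_cue, replace = TRUE)
  list(model = model, states = st)
}

# One planted-recovery run on the default synthetic scenario; returns the
# facts the end-to-end properties assert on.
recovery_run <- function(seed) {
  toy <- generate_toy_network(seed = seed)
  sc <- generate_expression(toy, seed = seed)
  out <- list(planted = sc$planted_pathway)
  calls <- list()
  for (cond in c("p53_active", "p53_depleted")) {
    gs <- discretize_expression(summarize_condition(sc$profile, cond))
    st <- suppressMessages(assign_reaction_states(toy, gs, cond))
    calls[[cond]] <- classify_activity(toy, st, condition = cond)
  }
  enrA <- suppressMessages(enrich_pathways(calls$p53_active, toy))
  enrB <- suppressMessages(enrich_pathways(calls$p53_depleted, toy))
  planted_rxn <- sc$truth$reaction[sc$truth$condition == "p53_active" &
                                     sc$truth$intended_state == 1L]
  cmp <- compare_conditions(calls$p53_active, calls$p53_depleted)
  list(enrA = enrA, enrB = enrB, calls = calls, cmp = cmp,
       planted = sc$planted_pathway, planted_rxn = planted_rxn,
       scenario = sc, model = toy)
}
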