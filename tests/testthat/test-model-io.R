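test_that("the shipped toy chain loads with the expected structure", {
  m <- toy_chain()
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$metabolites), 3L)
  expect_equal(nrow(m$reactions), 4L)
  expect_equal(dim(m$S), c(3L, 4L))
  expect_true(all(colSums(abs(m$S)) > 0))
  expect_equal(nrow(validate_model(m)), 0L)
})

test_that("JSON round-trip is the identity on valid models", {
  m <- toy_chain()
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_model(m, tmp)
  m2 <- read_model_json(tmp)
  expect_identical(m$metabolites, m2$metabolites)
  expect_identical(m$reactions, m2$reactions)
  expect_equal(m$stoich, m2$stoich)
  expect_equal(m$S, m2$S)

  # unicode names and empty labels survive
  toy <- generate_toy_network(seed = 7)
  toy$metabolites$name[1] <- "glycérol (α)"
  write_model(toy, tmp)
  toy2 <- read_model_json(tmp)
  expect_identical(toy$metabolites$name, toy2$metabolites$name)
  expect_identical(toy$reactions$pathway, toy2$reactions$pathway)
})

test_that("SBML and JSON readers agree on equivalent encodings", {
  mj <- toy_chain()
  ms <- read_model_sbml(system.file("extdata", "toy_chain.sbml",
                                    package = "fluxcue"))
  expect_identical(ms$reactions$id, mj$reactions$id)
  expect_identical(ms$reactions$lb, mj$reactions$lb)
  expect_identical(ms$reactions$ub, mj$reactions$ub)
  expect_identical(ms$reactions$gpr, mj$reactions$gpr)
  expect_identical(ms$reactions$pathway, mj$reactions$pathway)
  expect_identical(ms$reactions$exchange, mj$reactions$exchange)
  expect_equal(unname(ms$S), unname(mj$S))
})

test_that("SBML reactions without bounds get the documented defaults", {
  src <- readLines(system.file("extdata", "toy_chain.sbml", package = "fluxcue"))
  src <- gsub(' fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten"', "", src)
  tmp <- tempfile(fileext = ".sbml")
  on.exit(unlink(tmp))
  writeLines(src, tmp)
  expect_message(m <- read_model_sbml(tmp), "applying defaults")
  expect_true(all(m$reactions$lb == 0))
  expect_true(all(m$reactions$ub == 1000))
})

test_that("malformed inputs raise parse/validation errors naming the problem", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines("this is not json {", tmp)
  expect_error(read_model_json(tmp), "malformed JSON")
  expect_error(read_model_sbml(tmp), "not parseable XML")

  bad <- jsonlite::read_json(system.file("extdata", "toy_chain.json",
                                         package = "fluxcue"))
  bad$reactions[[2]]$lb <- 5
  bad$reactions[[2]]$ub <- 1
  jsonlite::write_json(bad, tmp, auto_unbox = TRUE)
  expect_error(read_model_json(tmp), "lb \\(5\\) > ub \\(1\\)")
  expect_error(read_model_json("/nonexistent/model.json"), "does not exist")
})

test_that("the validator reports unknown metabolites and dead ends", {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c")
  rxns <- data.frame(id = c("in_A", "conv"), lb = 0, ub = 10, gpr = "",
                     pathway = "", exchange = c(TRUE, FALSE))
  stoich <- list(in_A = c(A = 1), conv = c(A = -1, B = 1, ghost = 1))
  rep <- validate_model(metabolic_model(mets, rxns, stoich, check = FALSE))
  bad <- rep[rep$level == "error", ]
  expect_equal(nrow(bad), 1L)
  expect_match(bad$message, "conv")
  expect_match(bad$message, "ghost")

  # chain missing its sink exchange: terminal metabolite is a dead end
  stoich2 <- list(in_A = c(A = 1), conv = c(A = -1, B = 1))
  rep2 <- validate_model(metabolic_model(mets, rxns, stoich2, check = FALSE))
  warn <- rep2[rep2$level == "warning", ]
  expect_true(any(warn$entity == "B" & grepl("never consumed", warn$message)))
})
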