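#' Generate a hepatocyte-like toy metabolic network with a planted glucogenic
#' pathway
#'
#' Builds `n_pathways` disjoint linear pathways, each a source exchange
#' feeding `pathway_length` internal single-gene conversions into a sink
#' exchange. The first pathway is the planted glucogenic route (label
#' `"gluconeogenesis"`): a precursor is imported, converted stepwise, shuttled
#' from the cytosol into the endoplasmic reticulum two steps before the end
#' (mirroring the glucose-6-phosphate shuttle that precedes
#' dephosphorylation), and the product is exported. The remaining
#' `n_pathways - 1` pathways are decoys of identical shape (labels
#' `"decoy_1"`, ...). Each internal reaction carries a unique single-gene GPR
#' (or a two-gene complex/isozyme rule with `gpr_mode = "paired"`) and its
#' pathway label; exchanges carry no GPR and no pathway. All reactions are
#' irreversible with bounds \[0, 10\]. With `pathway_length = 6` the planted
#' pathway's metabolite names spell out the glycerol route
#' (glycerol -> glycerol 3-phosphate -> DHAP -> fructose 1,6-bisphosphate ->
#' G6P (cytosol) -> G6P (ER) -> glucose (ER)).
#'
#' Pathways are private (no shared metabolites), so the network can never
#' stoichiometrically block the planted route, and the generated model passes
#' [validate_model()] with no dead ends. The topology is fully determined by
#' the size arguments; `seed` is recorded for provenance.
#'
#' @param n_pathways Number of pathways, at least 2 (default 4: the planted
#'   pathway's genes are then exactly the top quartile of all genes, matching
#'   the default quartile cue rule).
#' @param pathway_length Internal reactions per pathway, at least 3 (default 6).
#' @param seed Integer recorded on the model (attribute `seed`).
#' @param gpr_mode `"single"` (default) or `"paired"` (two-gene `and`/`or`
#'   rules on alternating reactions, to exercise GPR logic).
#' @return A [metabolic_model()]; attribute `planted_pathway` names the
#'   glucogenic label.
#' @export
generate_toy_network <- function(n_pathways = 4L, pathway_length = 6L, seed = 1L,
                                 gpr_mode = c("single", "paired")) {
  gpr_mode <- match.arg(gpr_mode)
  n_pathways <- as.integer(n_pathways)
  pathway_length <- as.integer(pathway_length)
  if (is.na(n_pathways) || n_pathways < 2L) {
    stop("n_pathways must be an integer >= 2", call. = FALSE)
  }
  if (is.na(pathway_length) || pathway_length < 3L) {
    stop("pathway_length must be an integer >= 3", call. = FALSE)
  }
  gluc_names <- c("glycerol", "glycerol 3-phosphate", "dihydroxyacetone phosphate",
                  "fructose 1,6-bisphosphate", "glucose-6-phosphate",
                  "glucose-6-phosphate", "glucose")
  mets <- list(); rxns <- list(); stoich <- list()
  labels <- c("gluconeogenesis", paste0("decoy_", seq_len(n_pathways - 1L)))
  for (p in seq_len(n_pathways)) {
    tag <- if (p == 1L) "gluc" else paste0("decoy", p - 1L)
    n_met <- pathway_length + 1L
    # the last two metabolites sit in the ER; the crossing reaction is the
    # transport step
    comp <- c(rep("c", n_met - 2L), "er", "er")
    mid <- paste0(tag, "_m", seq_len(n_met))
    mname <- if (p == 1L && pathway_length == 6L) gluc_names else mid
    for (i in seq_len(n_met)) {
      mets[[length(mets) + 1L]] <- data.frame(
        id = mid[i], name = mname[i], compartment = comp[i],
        stringsAsFactors = FALSE)
    }
    ex_in <- paste0("EX_", tag, "_in")
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = ex_in, lb = 0, ub = 10, gpr = "", pathway = "", exchange = TRUE,
      stringsAsFactors = FALSE)
    stoich[[ex_in]] <- stats::setNames(1, mid[1L])
    for (i in seq_len(pathway_length)) {
      rid <- paste0(tag, "_r", i)
      gpr <- if (gpr_mode == "single") {
        paste0(tag, "_g", i)
      } else if (i %% 2L == 1L) {
        sprintf("(%s_g%da and %s_g%db)", tag, i, tag, i)
      } else {
        sprintf("(%s_g%da or %s_g%db)", tag, i, tag, i)
      }
      rxns[[length(rxns) + 1L]] <- data.frame(
        id = rid, lb = 0, ub = 10, gpr = gpr, pathway = labels[p],
        exchange = FALSE, stringsAsFactors = FALSE)
      stoich[[rid]] <- stats::setNames(c(-1, 1), c(mid[i], mid[i + 1L]))
    }
    ex_out <- paste0("EX_", tag, "_out")
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = ex_out, lb = 0, ub = 10, gpr = "", pathway = "", exchange = TRUE,
      stringsAsFactors = FALSE)
    stoich[[ex_out]] <- stats::setNames(-1, mid[n_met])
  }
  model <- metabolic_model(do.call(rbind, mets), do.call(rbind, rxns), stoich)
  attr(model, "planted_pathway") <- labels[1L]
  attr(model, "seed") <- as.integer(seed)
  model
}

#' Generate a two-condition expression design over a toy network
#'
#' Emulates the contrast between p53-intact and p53-depleted hepatocyte-like
#' cells: in condition `"p53_active"` the planted glucogenic genes are induced
#' (drawn i.i.d. from Normal(`mu_high`, `sigma`) on the log-expression scale)
#' while every other gene sits at the baseline Normal(`mu_mid`, `sigma`); in
#' condition `"p53_depleted"` the glucogenic program is not induced and its
#' genes sit at the un-induced low baseline Normal(`mu_low`, `sigma`),
#' with all other genes again at Normal(`mu_mid`, `sigma`). Each condition
#' gets `n_reps` replicate samples. The recorded truth table marks planted
#' reactions intended-active in `"p53_active"`, intended-inactive in
#' `"p53_depleted"`, and everything else moderate.
#'
#' @param model A toy network from [generate_toy_network()] (any
#'   `metabolic_model` with a `planted_pathway` attribute or a
#'   `"gluconeogenesis"` pathway works).
#' @param mu_high Mean log-expression of induced planted genes (default 10).
#' @param mu_mid Baseline mean for all other genes (default 5).
#' @param sigma Replicate noise standard deviation, > 0 (default 1).
#' @param n_reps Replicates per condition, >= 1 (default 3).
#' @param seed Integer seed; the same seed reproduces the scenario exactly.
#' @param mu_low Mean log-expression of the un-induced planted genes in the
#'   depleted condition; default `mu_mid - (mu_high - mu_mid)`, the baseline
#'   reflected as far below `mu_mid` as induction sits above it.
#' @return An `imat_scenario`: `model`, `profile` (an
#'   [expression_profile()]), `design`, `truth` (long data frame `reaction`,
#'   `condition`, `intended_state`), `planted_pathway`, `seed`.
#' @export
generate_expression <- function(model, mu_high = 10, mu_mid = 5, sigma = 1,
                                n_reps = 3L, seed = 1L,
                                mu_low = mu_mid - (mu_high - mu_mid)) {
  stopifnot(inherits(model, "metabolic_model"), sigma > 0, n_reps >= 1L)
  planted <- attr(model, "planted_pathway") %||% "gluconeogenesis"
  genes <- unique(unlist(lapply(model$gpr_ast, gpr_genes)))
  if (length(genes) == 0L) stop("model has no GPR genes", call. = FALSE)
  planted_rxn <- model$reactions$id[model$reactions$pathway == planted]
  planted_genes <- unique(unlist(lapply(model$gpr_ast[planted_rxn], gpr_genes)))
  conditions <- c("p53_active", "p53_depleted")
  samples <- paste0(rep(conditions, each = n_reps), "_", seq_len(n_reps))
  design <- data.frame(sample = samples,
                       condition = rep(conditions, each = n_reps),
                       stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  mu <- matrix(mu_mid, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  mu[planted_genes, design$condition == "p53_active"] <- mu_high
  mu[planted_genes, design$condition == "p53_depleted"] <- mu_low
  values <- mu + matrix(stats::rnorm(length(mu), 0, sigma), nrow = nrow(mu))
  profile <- expression_profile(values, design)
  truth <- do.call(rbind, lapply(conditions, function(cond) {
    st <- integer(nrow(model$reactions))
    if (cond == "p53_active") st[model$reactions$id %in% planted_rxn] <- 1L
    if (cond == "p53_depleted") st[model$reactions$id %in% planted_rxn] <- -1L
    data.frame(reaction = model$reactions$id, condition = cond,
               intended_state = st, stringsAsFactors = FALSE)
  }))
  structure(list(model = model, profile = profile, design = design,
                 truth = truth, planted_pathway = planted,
                 seed = as.integer(seed)),
            class = "imat_scenario")
}

#' @export
print.imat_scenario <- function(x, ...) {
  cat(sprintf("<imat_scenario> seed %d: %d reactions, %d genes x %d samples, planted pathway '%s'\n",
              x$seed, nrow(x$model$reactions), nrow(x$profile$values),
              ncol(x$profile$values), x$planted_pathway))
  invisible(x)
}

#' Write a synthetic scenario to the file formats the pipeline consumes
#'
#' Emits `model.json`, `expression.tsv` (genes x samples), `design.tsv`,
#' `pathways.tsv` (pathway, reaction) and `truth.tsv` into `dir`.
#'
#' @param scenario An `imat_scenario` from [generate_expression()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the five file paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "imat_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    model = file.path(dir, "model.json"),
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_model(scenario$model, paths$model)
  expr <- data.frame(gene = rownames(scenario$profile$values),
                     scenario$profile$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scenario$design, paths$design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pathway_map_from_model(scenario$model), paths$pathways,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
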