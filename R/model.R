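#' Construct a metabolic network model
#'
#' A `metabolic_model` holds an ordered set of metabolites, an ordered set of
#' reactions with flux bounds, GPR rules and pathway (subsystem) labels, and
#' the implied stoichiometric matrix S (metabolites x reactions, negative
#' coefficients = consumed). Exchange reactions are one-sided stoichiometries
#' crossing the system boundary and are flagged explicitly.
#'
#' @param metabolites Data frame with columns `id`, `name`, `compartment`.
#' @param reactions Data frame with columns `id`, `lb`, `ub`, `gpr` (character
#'   rule, `""` for none), `pathway` (`""` for none), `exchange` (logical).
#' @param stoich Named list, one entry per reaction id, each a named numeric
#'   vector of metabolite coefficients.
#' @param check If `TRUE` (default), hard invariant violations raise an error.
#' @return An object of class `metabolic_model` with elements `metabolites`,
#'   `reactions` (gains a `reversible` column, `lb < 0`), `stoich`, `S`
#'   (dense numeric matrix, dimnames metabolite x reaction) and `gpr_ast`
#'   (list of parsed rules).
#' @seealso [read_model_json()], [validate_model()]
#' @export
metabolic_model <- function(metabolites, reactions, stoich, check = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "compartment") %in% names(metabolites)),
            all(c("id", "lb", "ub", "gpr", "pathway", "exchange") %in% names(reactions)),
            is.list(stoich))
  if (!setequal(names(stoich), reactions$id) ||
      length(stoich) != nrow(reactions)) {
    stop("stoich must have exactly one entry per reaction id", call. = FALSE)
  }
  stoich <- stoich[reactions$id]
  reactions$reversible <- reactions$lb < 0

  S <- matrix(0, nrow = nrow(metabolites), ncol = nrow(reactions),
              dimnames = list(metabolites$id, reactions$id))
  for (j in seq_along(stoich)) {
    sj <- stoich[[j]]
    idx <- match(names(sj), metabolites$id)
    known <- !is.na(idx)
    S[idx[known], j] <- sj[known]
  }
  gpr_ast <- lapply(reactions$gpr, parse_gpr)
  names(gpr_ast) <- reactions$id

  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoich = stoich, S = S, gpr_ast = gpr_ast),
    class = "metabolic_model")
  if (check) {
    rep <- validate_model(model)
    errs <- rep[rep$level == "error", , drop = FALSE]
    if (nrow(errs) > 0L) {
      stop("invalid model:\n", paste0("  - ", errs$message, collapse = "\n"),
           call. = FALSE)
    }
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites, %d reactions (%d exchange), %d pathways\n",
              nrow(x$metabolites), nrow(x$reactions), sum(x$reactions$exchange),
              length(setdiff(unique(x$reactions$pathway), ""))))
  invisible(x)
}

#' Validate a metabolic model
#'
#' Checks structural invariants and reports every violation rather than
#' stopping at the first. Hard errors: duplicate or empty metabolite/reaction
#' ids, empty compartments, `lb > ub`, empty stoichiometry, references to
#' unknown metabolites. Warnings: dead-end metabolites, i.e. internal
#' metabolites that are only ever produced or only ever consumed (exchange
#' reactions excluded from the scan), which make their neighborhood incapable
#' of carrying steady-state flux.
#'
#' @param model A `metabolic_model`.
#' @return Data frame with columns `level` ("error"/"warning"), `entity`,
#'   and `message`; zero rows iff the model has no violations or warnings.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  out <- list()
  add <- function(level, entity, message) {
    out[[length(out) + 1L]] <<- data.frame(level = level, entity = entity,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    for (d in unique(met$id[duplicated(met$id)]))
      add("error", d, sprintf("duplicate metabolite id '%s'", d))
  }
  if (any(!nzchar(met$id))) add("error", "", "empty metabolite id")
  for (i in which(!nzchar(met$compartment))) {
    add("error", met$id[i], sprintf("metabolite '%s' has empty compartment", met$id[i]))
  }
  if (anyDuplicated(rxn$id)) {
    for (d in unique(rxn$id[duplicated(rxn$id)]))
      add("error", d, sprintf("duplicate reaction id '%s'", d))
  }
  for (i in seq_len(nrow(rxn))) {
    rid <- rxn$id[i]
    if (!nzchar(rid)) add("error", "", "empty reaction id")
    if (rxn$lb[i] > rxn$ub[i]) {
      add("error", rid, sprintf("reaction '%s' has lb (%g) > ub (%g)",
                                rid, rxn$lb[i], rxn$ub[i]))
    }
    sj <- model$stoich[[rid]]
    if (length(sj) == 0L) {
      add("error", rid, sprintf("reaction '%s' has empty stoichiometry", rid))
    }
    unknown <- setdiff(names(sj), met$id)
    for (u in unknown) {
      add("error", rid, sprintf("reaction '%s' references unknown metabolite '%s'",
                                rid, u))
    }
  }
  # dead-end scan over internal (non-exchange) columns only
  if (nrow(met) > 0L && any(!rxn$exchange)) {
    Sint <- model$S[, !rxn$exchange, drop = FALSE]
    Sexc <- model$S[, rxn$exchange, drop = FALSE]
    for (i in seq_len(nrow(met))) {
      touched <- any(Sint[i, ] != 0) || any(Sexc[i, ] != 0)
      if (!touched) next
      # a metabolite reachable through an exchange or a reversible reaction
      # can always be balanced
      rev_touch <- any(Sint[i, ] != 0 & rxn$reversible[!rxn$exchange])
      exc_touch <- any(Sexc[i, ] != 0)
      producible <- any(Sint[i, ] > 0) || exc_touch || rev_touch
      consumable <- any(Sint[i, ] < 0) || exc_touch || rev_touch
      if (!producible || !consumable) {
        add("warning", met$id[i],
            sprintf("metabolite '%s' is a dead end (%s)", met$id[i],
                    if (!producible) "never produced" else "never consumed"))
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(level = character(0), entity = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}
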