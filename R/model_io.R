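#' @keywords internal
.default_flux_bound <- 1000

#' Read a metabolic model from the package's JSON dialect
#'
#' The dialect (schema shipped at
#' `system.file("extdata", "model_schema.json", package = "fluxcue")`) has two
#' top-level arrays: `metabolites` with `id`, `name`, `compartment`, and
#' `reactions` with `id`, `stoich` (object mapping metabolite id to signed
#' coefficient, negative = consumed), `lb`, `ub`, `gpr`, `pathway`,
#' `exchange`. Missing bounds default to \eqn{[-1000, 1000]} if `reversible`
#' is declared true, else \eqn{[0, 1000]}. Ordering of records is preserved.
#'
#' @param path Path to a JSON model file.
#' @return A validated [metabolic_model()].
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file '%s' does not exist", path), call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop(sprintf("malformed JSON in '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (!is.list(doc) || is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop(sprintf("'%s': expected top-level keys 'metabolites' and 'reactions'", path),
         call. = FALSE)
  }
  mets <- do.call(rbind, lapply(seq_along(doc$metabolites), function(i) {
    m <- doc$metabolites[[i]]
    if (is.null(m$id)) stop(sprintf("'%s': metabolite record %d has no id", path, i),
                            call. = FALSE)
    data.frame(id = as.character(m$id),
               name = as.character(m$name %||% m$id),
               compartment = as.character(m$compartment %||% "c"),
               stringsAsFactors = FALSE)
  }))
  stoich <- list()
  rxns <- do.call(rbind, lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    if (is.null(r$id)) stop(sprintf("'%s': reaction record %d has no id", path, i),
                            call. = FALSE)
    rid <- as.character(r$id)
    if (is.null(r$stoich) || length(r$stoich) == 0L) {
      stop(sprintf("'%s': reaction '%s' has empty stoichiometry", path, rid),
           call. = FALSE)
    }
    sj <- vapply(r$stoich, as.numeric, numeric(1))
    rev_declared <- isTRUE(r$reversible)
    lb <- if (is.null(r$lb)) (if (rev_declared) -.default_flux_bound else 0) else as.numeric(r$lb)
    ub <- if (is.null(r$ub)) .default_flux_bound else as.numeric(r$ub)
    if (lb > ub) {
      stop(sprintf("'%s': reaction '%s' has lb (%g) > ub (%g)", path, rid, lb, ub),
           call. = FALSE)
    }
    stoich[[rid]] <<- sj
    data.frame(id = rid, lb = lb, ub = ub,
               gpr = as.character(r$gpr %||% ""),
               pathway = as.character(r$pathway %||% ""),
               exchange = isTRUE(r$exchange),
               stringsAsFactors = FALSE)
  }))
  metabolic_model(mets, rxns, stoich)
}

#' Write a metabolic model to the JSON dialect
#'
#' The emitted file re-reads to a field-by-field equal model (round-trip
#' identity). Empty GPR and pathway labels are serialized as empty strings;
#' unicode names are preserved (UTF-8).
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    list(id = r$id, stoich = as.list(model$stoich[[r$id]]),
         lb = r$lb, ub = r$ub, gpr = r$gpr, pathway = r$pathway,
         exchange = r$exchange)
  })
  ok <- tryCatch({
    jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write model to '%s': %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read a metabolic model from an SBML Level 3 (FBC) subset
#'
#' Supports species, reactions with reactant/product stoichiometries, flux
#' bounds given as `fbc:lowerFluxBound` / `fbc:upperFluxBound` parameter
#' references, and `fbc:geneProductAssociation` trees (`fbc:and`, `fbc:or`,
#' `fbc:geneProductRef`). Pathway labels are taken from a `subsystem` notes
#' tag or a `fluxcue:pathway` attribute if present, otherwise left empty.
#' Reactions with missing bounds receive the documented defaults
#' (\eqn{[-1000, 1000]} if `reversible="true"`, else \eqn{[0, 1000]}) with a
#' message; unsupported constructs are skipped with a message, never silently.
#' Boundary species (`boundaryCondition="true"`) are dropped from
#' stoichiometries, which is how one-sided exchange reactions arise.
#'
#' @param path Path to an SBML file.
#' @return A validated [metabolic_model()].
#' @export
read_model_sbml <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file '%s' does not exist", path), call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("'%s' is not parseable XML: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    # fall back to namespace-agnostic lookup (e.g. fbc version 1 documents)
    model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
    if (inherits(model_node, "xml_missing")) {
      stop(sprintf("'%s': no <model> element found", path), call. = FALSE)
    }
  }
  first_all <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  attr1 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }

  # global parameters (bound values)
  params <- list()
  for (p in first_all(model_node, "parameter")) {
    pid <- attr1(p, "id"); pv <- attr1(p, "value")
    if (!is.null(pid) && !is.null(pv)) params[[pid]] <- as.numeric(pv)
  }
  # gene products: id -> label
  gene_label <- list()
  for (g in first_all(model_node, "geneProduct")) {
    gid <- attr1(g, "id")
    if (is.null(gid)) next
    gene_label[[gid]] <- attr1(g, "label") %||% gid
  }

  boundary <- character(0)
  mets <- list()
  for (sp in first_all(model_node, "species")) {
    sid <- attr1(sp, "id")
    if (is.null(sid)) next
    if (isTRUE(as.logical(attr1(sp, "boundaryCondition")))) {
      boundary <- c(boundary, sid)
      next
    }
    mets[[length(mets) + 1L]] <- data.frame(
      id = sid, name = attr1(sp, "name") %||% sid,
      compartment = attr1(sp, "compartment") %||% "c",
      stringsAsFactors = FALSE)
  }
  mets <- do.call(rbind, mets)

  gpr_from_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr1(node, "geneProduct")
      lab <- gene_label[[ref]] %||% ref
      return(lab)
    }
    kids <- xml2::xml_children(node)
    kids <- kids[xml2::xml_name(kids) %in% c("and", "or", "geneProductRef")]
    parts <- vapply(kids, gpr_from_node, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  stoich <- list()
  rxns <- list()
  for (rx in first_all(model_node, "reaction")) {
    rid <- attr1(rx, "id")
    if (is.null(rid)) next
    sj <- numeric(0)
    add_coef <- function(sp, delta) {
      cur <- if (sp %in% names(sj)) sj[[sp]] else 0
      sj[sp] <<- cur + delta
    }
    for (sr in xml2::xml_find_all(rx, ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      sp <- attr1(sr, "species"); co <- as.numeric(attr1(sr, "stoichiometry") %||% "1")
      if (sp %in% boundary) next
      add_coef(sp, -co)
    }
    for (sr in xml2::xml_find_all(rx, ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      sp <- attr1(sr, "species"); co <- as.numeric(attr1(sr, "stoichiometry") %||% "1")
      if (sp %in% boundary) next
      add_coef(sp, co)
    }
    reversible <- isTRUE(as.logical(attr1(rx, "reversible")))
    lb_ref <- attr1(rx, "lowerFluxBound"); ub_ref <- attr1(rx, "upperFluxBound")
    lb <- if (!is.null(lb_ref) && !is.null(params[[lb_ref]])) params[[lb_ref]] else NA_real_
    ub <- if (!is.null(ub_ref) && !is.null(params[[ub_ref]])) params[[ub_ref]] else NA_real_
    if (is.na(lb) || is.na(ub)) {
      message(sprintf("fluxcue: reaction '%s' has no flux bounds in SBML; applying defaults [%g, %g]",
                      rid, if (reversible) -.default_flux_bound else 0, .default_flux_bound))
      if (is.na(lb)) lb <- if (reversible) -.default_flux_bound else 0
      if (is.na(ub)) ub <- .default_flux_bound
    }
    gpa <- xml2::xml_find_first(rx, ".//*[local-name()='geneProductAssociation']")
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      kids <- kids[xml2::xml_name(kids) %in% c("and", "or", "geneProductRef")]
      if (length(kids) == 1L) gpr <- gpr_from_node(kids[[1L]])
    }
    pathway <- attr1(rx, "pathway") %||% ""
    if (!nzchar(pathway)) {
      note <- xml2::xml_find_first(rx, ".//*[local-name()='p'][starts-with(normalize-space(text()),'SUBSYSTEM:')]")
      if (!inherits(note, "xml_missing")) {
        pathway <- trimws(sub("^\\s*SUBSYSTEM:\\s*", "", xml2::xml_text(note)))
      }
    }
    kinetic <- xml2::xml_find_first(rx, ".//*[local-name()='kineticLaw']")
    if (!inherits(kinetic, "xml_missing")) {
      message(sprintf("fluxcue: skipping unsupported <kineticLaw> on reaction '%s'", rid))
    }
    is_exchange <- length(sj) == 1L || grepl("^(EX_|R_EX_)", rid)
    stoich[[rid]] <- sj
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = rid, lb = lb, ub = ub, gpr = gpr, pathway = pathway,
      exchange = is_exchange, stringsAsFactors = FALSE)
  }
  rxns <- do.call(rbind, rxns)
  if (is.null(mets) || is.null(rxns)) {
    stop(sprintf("'%s': SBML document contains no usable species/reactions", path),
         call. = FALSE)
  }
  metabolic_model(mets, rxns, stoich)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
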