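#' Construct an expression profile
#'
#' Bundles a genes x samples matrix of (log-scale) expression values with a
#' sample-to-condition design. Values must be finite, gene ids unique, and
#' every sample must carry a condition label.
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param design Data frame with columns `sample`, `condition`.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(values, design) {
  values <- as.matrix(values)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  stopifnot(is.numeric(values), !is.null(rownames(values)), !is.null(colnames(values)),
            all(c("sample", "condition") %in% names(design)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in expression values",
                                            call. = FALSE)
  if (!all(is.finite(values))) stop("expression values must be finite", call. = FALSE)
  missing <- setdiff(colnames(values), design$sample)
  if (length(missing) > 0L) {
    stop(sprintf("samples without a condition label: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  structure(list(values = values, design = design), class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d genes x %d samples; conditions: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$design$condition), collapse = ", ")))
  invisible(x)
}

#' Read an expression table (TSV)
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids.
#'
#' @param path Path to the expression TSV.
#' @param design Either a data frame (`sample`, `condition`) or a path to a
#'   two-column TSV mapping sample id to condition.
#' @return An [expression_profile()].
#' @export
read_expression <- function(path, design) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  if (is.character(design)) design <- read_design(design)
  expression_profile(values, design)
}

#' Read a condition design (TSV mapping sample to condition)
#' @param path Path to a two-column TSV with header `sample`, `condition`.
#' @return Data frame with columns `sample`, `condition`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition") %in% names(d)))
  d
}

#' Collapse a condition's replicates to a per-gene summary
#'
#' Replicate arrays within one condition are collapsed by the arithmetic mean
#' before discretization (no variance model is imposed).
#'
#' @param profile An [expression_profile()].
#' @param condition Condition label present in the design.
#' @return Named numeric vector, one summary value per gene.
#' @export
summarize_condition <- function(profile, condition) {
  stopifnot(inherits(profile, "expression_profile"))
  sel <- profile$design$condition == condition
  if (!any(sel)) stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  rowMeans(profile$values[, sel, drop = FALSE])
}

#' Discretize per-gene expression into trinary states
#'
#' Genes at or below the lower cutoff get state -1 (lowly expressed), at or
#' above the upper cutoff +1 (highly expressed), else 0 (moderate). Cutoffs
#' are either empirical quantiles of `summary` (default; quantile definition:
#' linear interpolation between order statistics, `stats::quantile` type 7,
#' pinned for reproducibility) or explicit thresholds `t_low` / `t_high` on
#' the expression scale. A constant input vector has no meaningful quantiles:
#' all states are 0 and a message is emitted.
#'
#' @param summary Named numeric vector from [summarize_condition()].
#' @param q_low,q_high Quantile fractions, `0 < q_low < q_high < 1`.
#' @param t_low,t_high Optional explicit thresholds; when both are given the
#'   quantile rule is bypassed.
#' @return Named integer vector of states in \{-1, 0, 1\} (a gene state map).
#' @examples
#' discretize_expression(stats::setNames(1:8, paste0("g", 1:8)))
#' @export
discretize_expression <- function(summary, q_low = 0.25, q_high = 0.75,
                                  t_low = NULL, t_high = NULL) {
  stopifnot(is.numeric(summary), !is.null(names(summary)))
  if (is.null(t_low) != is.null(t_high)) {
    stop("t_low and t_high must be given together", call. = FALSE)
  }
  if (is.null(t_low)) {
    stopifnot(q_low > 0, q_high < 1, q_low < q_high)
    if (length(unique(summary)) <= 1L) {
      message("fluxcue: constant expression vector; all gene states set to 0")
      return(stats::setNames(integer(length(summary)), names(summary)))
    }
    t_low <- stats::quantile(summary, q_low, names = FALSE, type = 7)
    t_high <- stats::quantile(summary, q_high, names = FALSE, type = 7)
  } else {
    stopifnot(t_low <= t_high)
  }
  states <- integer(length(summary))
  states[summary <= t_low] <- -1L
  states[summary >= t_high] <- 1L
  stats::setNames(states, names(summary))
}

#' Map gene states to reaction states through GPR rules
#'
#' Evaluates each reaction's GPR over the gene state map
#' (see [evaluate_gpr()]): reactions with state +1 form the highly-expressed
#' cue set R_H, state -1 the lowly-expressed set R_L; reactions with an empty
#' GPR are always moderate (0). Genes present in GPRs but absent from the
#' state map count as moderate. The sizes |R_H| and |R_L| are reported in a
#' message.
#'
#' @param model A [metabolic_model()].
#' @param gene_states Named integer vector from [discretize_expression()].
#' @param condition Optional condition label recorded on the result.
#' @return Data frame with columns `reaction`, `state` (integer in
#'   \{-1, 0, 1\}), one row per model reaction in model order; attribute
#'   `condition` carries the label.
#' @export
assign_reaction_states <- function(model, gene_states, condition = NA_character_) {
  stopifnot(inherits(model, "metabolic_model"))
  states <- vapply(model$gpr_ast, function(ast) {
    if (is.null(ast)) 0L else evaluate_gpr(ast, gene_states)
  }, integer(1))
  out <- data.frame(reaction = model$reactions$id, state = unname(states),
                    stringsAsFactors = FALSE)
  message(sprintf("fluxcue: condition %s: |R_H| = %d, |R_L| = %d",
                  ifelse(is.na(condition), "<unnamed>", condition),
                  sum(out$state == 1L), sum(out$state == -1L)))
  attr(out, "condition") <- condition
  out
}

#' Write a state map (gene or reaction) as a two-column TSV
#' @param states Named integer vector or a data frame with an id column and
#'   a `state` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_states <- function(states, path) {
  if (is.data.frame(states)) {
    utils::write.table(states, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(data.frame(id = names(states), state = unname(states)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
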