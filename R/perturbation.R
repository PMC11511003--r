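## In-silico mutants -----------------------------------------------------------
##
## Constitutive loss- (LOF) and gain-of-function (GOF) mutants are simulated
## by clamping nodes: the node's rule is replaced by the constant 0 (LOF) or
## 1 (GOF) and the node keeps that value throughout the dynamics.

#' Define a mutant perturbation
#'
#' @param clamp named vector of 0/1 values: 0 simulates loss of function,
#'   1 constitutive (gain-of-function) expression.  Must be non-empty.
#' @param label optional mutant name; derived from the clamp if omitted
#'   (lower case for LOF, upper case + `-ox` for GOF).
#' @return an object of class `perturbation_spec`.
#' @examples
#' perturbation(c(FUL = 0))
#' perturbation(c(NTT = 1))
#' @export
perturbation <- function(clamp, label = NULL) {
  if (length(clamp) == 0L) stop("a perturbation must clamp at least one node", call. = FALSE)
  if (is.null(names(clamp)) || any(!nzchar(names(clamp)))) {
    stop("clamp must be a named vector", call. = FALSE)
  }
  vals <- as.integer(clamp)
  if (any(!vals %in% c(0L, 1L))) stop("clamp values must be 0 (LOF) or 1 (GOF)", call. = FALSE)
  if (is.null(label)) {
    label <- paste(ifelse(vals == 0L, tolower(names(clamp)),
                          paste0(toupper(names(clamp)), "-ox")), collapse = " ")
  }
  structure(list(clamp = stats::setNames(vals, names(clamp)), label = label),
            class = "perturbation_spec")
}

#' Apply a perturbation to a network
#'
#' Clamped nodes' rules are replaced by constants; all other rules are
#' unchanged.  The clamp map is recorded on the returned network so that
#' downstream classification can exclude the clamped nodes.
#'
#' @param net a `boolean_network`.
#' @param spec a [perturbation()] (or a bare named 0/1 vector).
#' @return the clamped `boolean_network`.
#' @export
apply_perturbation <- function(net, spec) {
  if (!inherits(spec, "perturbation_spec")) spec <- perturbation(spec)
  unknown <- setdiff(names(spec$clamp), net$nodes)
  if (length(unknown) > 0L) {
    stop(sprintf("perturbation clamps unknown node(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  rules <- stats::setNames(lapply(net$nodes, function(nd) {
    if (nd %in% names(spec$clamp)) expr_const(spec$clamp[[nd]]) else net$exprs[[nd]]
  }), net$nodes)
  clamps <- c(net$clamps, spec$clamp)
  clamps <- clamps[!duplicated(names(clamps), fromLast = TRUE)]
  boolean_network(rules, clamps = clamps)
}

#' Simulate a constitutive mutant and classify its attractors
#'
#' Attractors of the clamped network are computed exhaustively and each
#' fixed point is matched against the reference cell-type profiles on the
#' marker nodes, ignoring the clamped node(s) themselves.  Fixed points whose
#' full state deviates from the matched profile (e.g. only through the clamp)
#' are reported with `canonical = FALSE` — the asterisked columns of the
#' published mutant panels.
#'
#' @param net the unperturbed `boolean_network`.
#' @param spec a [perturbation()] (or named 0/1 clamp vector).
#' @param profiles named list of marker vectors, as from [dz_profiles()].
#' @return an object of class `mutant_result` with `label`, `network`,
#'   `attractors`, `classification` (tibble) and `summary` (label counts).
#' @export
simulate_mutant <- function(net, spec, profiles = dz_profiles()) {
  if (!inherits(spec, "perturbation_spec")) spec <- perturbation(spec)
  mut <- apply_perturbation(net, spec)
  att <- find_attractors(mut)
  cls <- classify_attractors(att, profiles, exclude = names(spec$clamp))
  structure(
    list(label = spec$label, clamp = spec$clamp, network = mut,
         attractors = att, classification = cls,
         summary = dplyr::count(cls, .data$label, name = "n")),
    class = "mutant_result"
  )
}

#' @export
print.mutant_result <- function(x, ...) {
  cat(sprintf("Mutant simulation: %s\n", x$label))
  print(x$classification)
  invisible(x)
}

#' Tidy a mutant simulation into the published table layout
#'
#' @param x a `mutant_result`.
#' @param ... unused.
#' @return long tibble: one row per node and attractor with the node state,
#'   attractor label and basin size.
#' @method tidy mutant_result
#' @export
tidy.mutant_result <- function(x, ...) {
  dplyr::left_join(tidy(x$attractors),
                   dplyr::select(x$classification, "attractor", "label", "canonical"),
                   by = "attractor")
}

#' @method glance mutant_result
#' @export
glance.mutant_result <- function(x, ...) {
  lens <- vapply(x$attractors$attractors, function(a) length(a$states), integer(1))
  tibble::tibble(
    mutant = x$label,
    n_attractors = length(lens),
    n_fixed_points = sum(lens == 1L),
    n_cycles = sum(lens > 1L),
    labels = paste(sort(x$classification$label), collapse = ",")
  )
}

#' The standard loss-/gain-of-function mutant panel
#'
#' Runs the nine mutants of the published panel on the extended network:
#' FUL LOF, FUL GOF, SHP LOF, SHP GOF, NTT GOF, IND LOF, ALC LOF, SPT LOF
#' and RPL LOF.
#'
#' @param net the wild-type network (defaults to the extended model).
#' @param profiles reference profiles.
#' @return a named list of `mutant_result` objects, in panel order.
#' @export
mutant_panel <- function(net = dz_network("final"), profiles = dz_profiles()) {
  specs <- list(
    ful_lof = perturbation(c(FUL = 0)), FUL_gof = perturbation(c(FUL = 1)),
    shp_lof = perturbation(c(SHP = 0)), SHP_gof = perturbation(c(SHP = 1)),
    NTT_gof = perturbation(c(NTT = 1)), ind_lof = perturbation(c(IND = 0)),
    alc_lof = perturbation(c(ALC = 0)), spt_lof = perturbation(c(SPT = 0)),
    rpl_lof = perturbation(c(RPL = 0))
  )
  lapply(specs, function(sp) simulate_mutant(net, sp, profiles))
}
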