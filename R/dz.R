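## The dehiscence-zone models --------------------------------------------------
##
## Two curated rule sets for the gene regulatory network patterning the
## Arabidopsis fruit medio-lateral axis:
##
##  * "initial": the literature-compiled 11-node network (no NTT), built only
##    from the experimentally validated interactions flagged for the first
##    model version.  It recovers valve (V), a single undifferentiated valve
##    margin (VM) and replum (R), but cannot separate the lignification (LL)
##    and separation (SL) layers: ALC's regulators (IND, SHP, FUL) take the
##    same values in both layers, so no Boolean rule can distinguish them.
##  * "final": the extended 12-node network adding NTT (detected mainly in
##    the separation layer and active in the replum) plus hypothetical
##    interactions: JAG/FIL/YAB3 activate FUL only when NTT is absent,
##    activate SHP when NTT is present even alongside FUL, NTT confines ALC
##    to the separation layer, and margin identity (via IND) excludes FUL.
##
## Node grouping: SHP1/SHP2 -> SHP, JAG/FIL/YAB3 -> JFY, AS1/AS2 -> AS, and
## miR172 with the ARF6/8 requirement folded into its activation rule ->
## MIR172.  The rule files ship under inst/extdata and are a reconstruction
## constrained by the published interaction table and figure phenotypes; a
## documented variant restoring the ALC/SPT negative feedback on IND is
## shipped alongside.

.dz_file <- function(name, rules_dir = NULL) {
  if (!is.null(rules_dir)) {
    path <- file.path(rules_dir, name)
  } else {
    path <- system.file("extdata", name, package = "podnet")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("model file not found: %s", name), call. = FALSE)
  }
  path
}

#' Load one of the shipped dehiscence-zone networks
#'
#' @param model `"final"` (12 nodes, with NTT), `"initial"` (11 nodes), or
#'   `"final_variant"` (the final network with the ALC/SPT negative feedback
#'   on IND restored), or a path to a rule file.
#' @return a [boolean_network()].
#' @examples
#' net <- dz_network("final")
#' glance(find_attractors(net))
#' @export
dz_network <- function(model = c("final", "initial", "final_variant")) {
  if (length(model) == 1L && file.exists(model)) return(read_rules(model))
  model <- match.arg(model)
  file <- switch(model,
    final         = "dz_rules_final.txt",
    initial       = "dz_rules_initial.txt",
    final_variant = "dz_rules_final_variant_ind_feedback.txt")
  read_rules(.dz_file(file))
}

#' The compiled interaction catalogue
#'
#' The signed interaction records behind both models, with evidence class
#' (`well_supported`, `suggested`, `ppi`, `hypothetical`), a flag for the
#' records composing the initial model, and the published (ungrouped) node
#' names alongside the grouped ones used by the networks.
#'
#' @return a tibble with columns `regulator`, `target`, `sign`, `evidence`,
#'   `in_initial_model`, `printed_regulator`, `printed_target`.
#' @export
dz_interactions <- function() {
  df <- utils::read.csv(.dz_file("dz_interactions.csv"), stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Reference expression profiles of the four fruit cell types
#'
#' Marker states (0/1, `NA` = unconstrained) for the valve (V), lignification
#' layer (LL), separation layer (SL) and replum (R), plus the merged valve
#' margin (VM) state recovered by the initial model.  Only nodes with stated
#' tissue activity are constrained; the four final profiles are pairwise
#' distinguishable on marker nodes.
#'
#' @param cell_types which profiles to return (default: the four final ones).
#' @return a named list of named 0/1 vectors (markers only, `NA` dropped).
#' @export
dz_profiles <- function(cell_types = c("V", "LL", "SL", "R")) {
  df <- utils::read.csv(.dz_file("dz_profiles.csv"), stringsAsFactors = FALSE)
  missing <- setdiff(cell_types, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("unknown cell type(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(cell_types, function(ct) {
    v <- stats::setNames(df[[ct]], df$node)
    v <- v[!is.na(v)]
    storage.mode(v) <- "integer"
    v
  })
  stats::setNames(out, cell_types)
}

#' Load the full model catalogue
#'
#' Reads both networks, the interaction catalogue and the reference profiles,
#' and validates the structural bookkeeping: 11 nodes and exactly 22
#' initial-model interaction records over 11 published node groups, final
#' node set = initial node set plus NTT.
#'
#' @param rules_dir optional directory containing the model files (defaults
#'   to the copies shipped with the package).
#' @return a list with elements `initial_network`, `final_network`,
#'   `interactions`, `profiles`, and `validation` (a tibble of the checks).
#' @export
load_catalog <- function(rules_dir = NULL) {
  initial <- read_rules(.dz_file("dz_rules_initial.txt", rules_dir))
  final <- read_rules(.dz_file("dz_rules_final.txt", rules_dir))
  interactions <- dz_interactions()
  profiles <- dz_profiles(c("V", "LL", "SL", "R", "VM"))

  ini <- dplyr::filter(interactions, .data$in_initial_model)
  groups <- .printed_groups(c(ini$printed_regulator, ini$printed_target))
  checks <- tibble::tibble(
    check = c("initial nodes", "initial interactions", "initial node groups",
              "final = initial + NTT", "catalogue names resolve"),
    expected = c(11L, 22L, 11L, 1L, 1L),
    observed = c(
      length(initial$nodes),
      nrow(ini),
      length(unique(groups)),
      as.integer(setequal(final$nodes, c(initial$nodes, "NTT"))),
      as.integer(all(c(interactions$regulator, interactions$target) %in% final$nodes))
    )
  )
  checks$ok <- checks$expected == checks$observed
  if (!all(checks$ok)) {
    bad <- checks[!checks$ok, ]
    stop(sprintf("model catalogue validation failed: %s",
                 paste(sprintf("%s (expected %d, got %d)", bad$check, bad$expected,
                               bad$observed), collapse = "; ")), call. = FALSE)
  }
  list(initial_network = initial, final_network = final,
       interactions = interactions, profiles = profiles, validation = checks)
}

## Canonical published node-group for a printed Table-1 name.
.printed_groups <- function(printed) {
  x <- trimws(printed)
  x[x %in% c("FIL", "JAG", "YAB3", "JAG/FIL/YAB3", "JAG/YAB3")] <- "JAG/FIL/YAB3"
  x[x == "FUL (+ARF6/8)"] <- "FUL"
  x
}

## ---- profile matching and wild-type validation ------------------------------

#' Match a state against reference cell-type profiles
#'
#' A state matches a profile when it agrees with every constrained marker
#' node (restricted to nodes present in the network, minus any excluded
#' nodes).  No nearest-match fallback is applied: a state matching no profile
#' is labelled `"novel"`.
#'
#' @param state named 0/1 vector (a network state).
#' @param profiles named list of marker vectors, as from [dz_profiles()].
#' @param exclude node names to ignore when matching (e.g. clamped nodes).
#' @return the name of the unique matching profile, or `"novel"`.
#' @export
match_profile <- function(state, profiles, exclude = character(0)) {
  hits <- names(profiles)[vapply(profiles, function(m) {
    m <- m[setdiff(names(m), exclude)]
    m <- m[names(m) %in% names(state)]
    length(m) > 0L && all(state[names(m)] == m)
  }, logical(1))]
  if (length(hits) == 1L) hits else "novel"
}

#' Classify the attractors of a network against cell-type profiles
#'
#' @param att an `attractor_set`.
#' @param profiles named list of marker vectors.
#' @param exclude nodes to ignore when matching (e.g. clamped nodes).
#' @return a tibble with one row per attractor: `attractor`, `length`,
#'   `basin`, `label` (profile name, `"novel"`, or `"cycle"`), and
#'   `canonical` (`TRUE` when the state matches its profile on *all* marker
#'   nodes, including excluded ones — the non-asterisked columns of the
#'   published attractor tables).
#' @export
classify_attractors <- function(att, profiles, exclude = character(0)) {
  purrr::imap_dfr(att$attractors, function(a, i) {
    if (length(a$states) > 1L) {
      return(tibble::tibble(attractor = i, length = length(a$states),
                            basin = a$basin, label = "cycle", canonical = FALSE))
    }
    st <- int_to_state(a$states, att$nodes)
    lab <- match_profile(st, profiles, exclude = exclude)
    canon <- lab != "novel" && identical(lab, match_profile(st, profiles))
    tibble::tibble(attractor = i, length = 1L, basin = a$basin,
                   label = lab, canonical = canon)
  })
}

#' Validate wild-type dynamics against the reference cell types
#'
#' Computes all attractors and maps each fixed point to the unique profile
#' whose marker states it matches.  For the extended (final) network the four
#' cell-type profiles are each matched by exactly one fixed point; for the
#' compiled initial network the report records the failure to separate the
#' lignification and separation layers.
#'
#' @param net a `boolean_network`.
#' @param profiles named list of marker vectors (defaults to the four final
#'   cell types restricted to the network's nodes).
#' @return a list of class `dz_validation` with `classification` (tibble),
#'   `matched` (profiles matched exactly once), `unmatched`, `duplicated`,
#'   `separates_ll_sl` (logical) and `attractors`.
#' @export
validate_wildtype <- function(net, profiles = dz_profiles()) {
  att <- find_attractors(net)
  cls <- classify_attractors(att, profiles)
  fixed <- dplyr::filter(cls, .data$label != "cycle")
  counts <- table(factor(fixed$label, levels = c(names(profiles), "novel")))
  matched <- names(profiles)[counts[names(profiles)] == 1L]
  unmatched <- names(profiles)[counts[names(profiles)] == 0L]
  dup <- names(profiles)[counts[names(profiles)] > 1L]
  structure(
    list(classification = cls,
         matched = matched, unmatched = unmatched, duplicated = dup,
         separates_ll_sl = all(c("LL", "SL") %in% matched),
         attractors = att,
         hash = network_hash(net)),
    class = "dz_validation"
  )
}

#' @export
print.dz_validation <- function(x, ...) {
  cat("Wild-type validation\n")
  cat("  matched profiles:  ", if (length(x$matched)) paste(x$matched, collapse = ", ") else "none", "\n")
  cat("  unmatched profiles:", if (length(x$unmatched)) paste(x$unmatched, collapse = ", ") else "none", "\n")
  if (length(x$duplicated)) {
    cat("  profiles matched by several attractors:", paste(x$duplicated, collapse = ", "), "\n")
  }
  cat("  separates LL and SL:", x$separates_ll_sl, "\n")
  print(x$classification)
  invisible(x)
}
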