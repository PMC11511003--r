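## Attractor tables and fixtures -----------------------------------------------

#' Attractor table in the published layout
#'
#' One row per network node, one column per attractor state (cyclic
#' attractors contribute one column per phase), with the profile label,
#' cycle length and basin size attached per attractor.
#'
#' @param att an `attractor_set`.
#' @param profiles reference profiles for column labels.
#' @param exclude nodes ignored when matching profiles (e.g. clamped nodes).
#' @return a tibble: `node` column plus one 0/1 column per attractor state,
#'   with attributes `labels`, `lengths`, `basins` (per attractor).
#' @export
attractor_table <- function(att, profiles = dz_profiles(), exclude = character(0)) {
  cls <- classify_attractors(att, profiles, exclude = exclude)
  cols <- list()
  labels <- character(0)
  for (i in seq_along(att$attractors)) {
    a <- att$attractors[[i]]
    for (j in seq_along(a$states)) {
      nm <- if (length(a$states) == 1L) sprintf("att%d", i) else sprintf("att%d.%d", i, j)
      cols[[nm]] <- as.integer(int_to_state(a$states[[j]], att$nodes))
      labels[[nm]] <- cls$label[[i]]
    }
  }
  out <- tibble::as_tibble(c(list(node = att$nodes), cols))
  attr(out, "labels") <- labels
  attr(out, "lengths") <- cls$length
  attr(out, "basins") <- cls$basin
  out
}

#' Write an attractor table to CSV
#'
#' Deterministic row (node) and column (canonical attractor) order; the
#' node rows are followed by `_label`, `_length` and `_basin` rows.  An
#' empty attractor set produces a header-only file.  [read_attractor_table()]
#' round-trips the format.
#'
#' @param att an `attractor_set`.
#' @param profiles reference profiles.
#' @param path output CSV path.
#' @param exclude nodes ignored when matching (e.g. clamped nodes).
#' @return the path, invisibly.
#' @export
write_attractor_table <- function(att, profiles = dz_profiles(), path,
                                  exclude = character(0)) {
  if (length(att$attractors) == 0L) {
    writeLines("node", path)
    return(invisible(path))
  }
  tab <- attractor_table(att, profiles, exclude = exclude)
  labels <- attr(tab, "labels")
  state_cols <- setdiff(names(tab), "node")
  att_of_col <- as.integer(sub("^att(\\d+).*$", "\\1", state_cols))
  body <- as.data.frame(lapply(tab, as.character), stringsAsFactors = FALSE)
  extra <- data.frame(
    node = c("_label", "_length", "_basin"),
    rbind(labels[state_cols],
          as.character(attr(tab, "lengths")[att_of_col]),
          as.character(attr(tab, "basins")[att_of_col])),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(extra) <- names(body)
  utils::write.csv(rbind(body, extra), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_attractor_table
#' @export
read_attractor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  meta <- df$node %in% c("_label", "_length", "_basin")
  body <- df[!meta, , drop = FALSE]
  out <- tibble::as_tibble(body)
  for (cl in setdiff(names(out), "node")) out[[cl]] <- as.integer(out[[cl]])
  if (any(meta)) {
    md <- df[meta, , drop = FALSE]
    rownames(md) <- md$node
    attr(out, "labels") <- unlist(md["_label", -1L, drop = TRUE])
    attr(out, "lengths") <- as.integer(md["_length", -1L, drop = TRUE])
    attr(out, "basins") <- as.integer(md["_basin", -1L, drop = TRUE])
  }
  out
}

#' Generate the test and demonstration fixtures
#'
#' Writes the two model rule files, the profiles and interaction catalogue
#' CSVs, three toy networks with analytically known attractor structure
#' (identity: two fixed points; negation: one 2-cycle; two-node toggle: two
#' fixed points and one 2-cycle under synchronous update), and one seeded
#' random 12-node network with the dehiscence-model topology.
#'
#' @param outdir output directory (created if needed).
#' @param seed seed for the random topology-matched network.
#' @return named character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    initial = file.path(outdir, "dz_rules_initial.txt"),
    final = file.path(outdir, "dz_rules_final.txt"),
    profiles = file.path(outdir, "dz_profiles.csv"),
    interactions = file.path(outdir, "dz_interactions.csv"),
    toy_identity = file.path(outdir, "toy_identity.txt"),
    toy_negation = file.path(outdir, "toy_negation.txt"),
    toy_toggle = file.path(outdir, "toy_toggle.txt"),
    random12 = file.path(outdir, "random_dz_topology.txt")
  )
  file.copy(.dz_file("dz_rules_initial.txt"), paths[["initial"]], overwrite = TRUE)
  file.copy(.dz_file("dz_rules_final.txt"), paths[["final"]], overwrite = TRUE)
  file.copy(.dz_file("dz_profiles.csv"), paths[["profiles"]], overwrite = TRUE)
  file.copy(.dz_file("dz_interactions.csv"), paths[["interactions"]], overwrite = TRUE)
  write_rules(boolean_network(c(A = "A")), paths[["toy_identity"]])
  write_rules(boolean_network(c(A = "!A")), paths[["toy_negation"]])
  write_rules(boolean_network(c(A = "!B", B = "!A")), paths[["toy_toggle"]])
  set.seed(seed)
  write_rules(random_network_like(dz_network("final")), paths[["random12"]])
  invisible(paths)
}
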