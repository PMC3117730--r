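#' Pruning annotations
#'
#' User annotations steering the derivation of the closed subsystem:
#' reactions known to be partially modeled (incomplete stoichiometry, e.g.
#' implicit cofactor turnover), reactions known to be thermodynamically
#' dependent (coupled), and explicit overrides of the elementary-reaction
#' heuristic.
#'
#' @param partially_modeled,thermodynamically_dependent character vectors of
#'   reaction ids.
#' @param elementary_override named logical vector, names are reaction ids.
#' @return a `pruning_annotations` object.
#' @export
pruning_annotations <- function(partially_modeled = character(0),
                                thermodynamically_dependent = character(0),
                                elementary_override = logical(0)) {
  structure(
    list(partially_modeled = as.character(partially_modeled),
         thermodynamically_dependent = as.character(thermodynamically_dependent),
         elementary_override = elementary_override),
    class = "pruning_annotations"
  )
}

#' Derive the closed thermodynamic subsystem of an open network
#'
#' An open network exchanges mass with its surroundings through clamped
#' species, null-species exchange reactions, irreversible reactions, and
#' partially modeled reactions.  Detailed-balance analysis only applies to a
#' closed system, so the network is pruned in four ordered steps:
#'
#' 1. remove null-exchange, irreversible and partially modeled reactions;
#' 2. lift the clamping of species participating in the remaining reversible
#'    reactions (flag flip only -- initial concentrations are untouched);
#' 3. keep only thermodynamically independent reactions (heuristically, the
#'    elementary ones);
#' 4. remove species no longer participating in any retained reaction.
#'
#' The heuristic for step 3: a reversible reaction with total reactant
#' stoichiometry <= 2, total product stoichiometry <= 2 and `f == 1` is
#' treated as elementary (mono/bimolecular single-step) unless overridden by
#' an annotation or the reaction's own `elementary` field.
#'
#' @param network a `reaction_network`.
#' @param annotations a [pruning_annotations()] object (may be empty).
#' @return a `closed_subsystem`: retained species ids, retained reaction ids,
#'   the exact integer stoichiometry matrix of the closed subsystem, and a
#'   per-reaction provenance table giving each dropped reaction exactly one
#'   exclusion reason (`null_exchange`, `irreversible`, `partially_modeled`,
#'   `not_independent`) -- retained reactions have reason `retained`.
#' @export
prune_to_closed <- function(network, annotations = pruning_annotations()) {
  rx <- network$reactions
  check_ids(annotations$partially_modeled, rx$id, "reaction")
  check_ids(annotations$thermodynamically_dependent, rx$id, "reaction")
  check_ids(names(annotations$elementary_override), rx$id, "reaction")

  reason <- rep("retained", nrow(rx))
  names(reason) <- rx$id

  is_null_exchange <- vapply(seq_len(nrow(rx)), function(i) {
    length(rx$reactants[[i]]) == 0L || length(rx$products[[i]]) == 0L
  }, logical(1))
  partially <- rx$id %in% annotations$partially_modeled | !rx$fully_modeled

  # step 1 (ordered within: null exchange, then irreversible, then partial)
  reason[is_null_exchange & reason == "retained"] <- "null_exchange"
  reason[!rx$reversible & reason == "retained"] <- "irreversible"
  reason[partially & reason == "retained"] <- "partially_modeled"

  # step 3: thermodynamic independence via the elementary heuristic
  elem <- vapply(seq_len(nrow(rx)), function(i) {
    if (!is.na(ov <- annotations$elementary_override[rx$id[i]])) return(ov)
    if (!is.na(rx$elementary[i])) return(rx$elementary[i])
    sum(rx$reactants[[i]]) <= 2 && sum(rx$products[[i]]) <= 2 &&
      is.null(rx$f_expr[[i]]) && is.null(rx$rate_expr[[i]])
  }, logical(1))
  dependent <- rx$id %in% annotations$thermodynamically_dependent | !elem
  reason[dependent & reason == "retained"] <- "not_independent"

  retained_rx <- rx$id[reason == "retained"]

  # step 2 is implicit: every species participating in a retained reversible
  # reaction is treated as dynamic (clamping lifted); step 4 drops the rest
  retained_sp <- network$species$id[
    network$species$id %in% unique(unlist(lapply(
      which(reason == "retained"),
      function(i) c(names(rx$reactants[[i]]), names(rx$products[[i]]))
    )))
  ]

  stoich <- if (length(retained_rx) > 0L && length(retained_sp) > 0L) {
    stoichiometry_matrix(network, retained_sp, retained_rx)
  } else {
    matrix(0, length(retained_sp), length(retained_rx),
           dimnames = list(retained_sp, retained_rx))
  }

  structure(
    list(species_ids = retained_sp,
         reaction_ids = retained_rx,
         stoich = stoich,
         provenance = tibble::tibble(reaction_id = rx$id, reason = unname(reason))),
    class = "closed_subsystem"
  )
}

#' @export
print.closed_subsystem <- function(x, ...) {
  cat("<closed_subsystem> N0 = ", length(x$species_ids),
      " species, M0 = ", length(x$reaction_ids), " reversible reactions\n", sep = "")
  drops <- table(x$provenance$reason[x$provenance$reason != "retained"])
  if (length(drops) > 0L)
    cat("  dropped: ", paste(names(drops), drops, sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
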