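#' Build a species table
#'
#' Species are the state variables of the kinetic model.  A clamped species
#' has its concentration held fixed during simulation; thermodynamically it
#' represents implicit mass exchange with the environment, which is why
#' clamping matters for the pruning step that derives the closed subsystem.
#'
#' @param id character vector of unique species ids.
#' @param initial_concentration non-negative initial concentrations, in model
#'   units (the package performs no unit conversion).
#' @param clamped logical; is the concentration held fixed?
#' @param compartment compartment id per species.
#' @param name optional display name (defaults to `id`).
#' @return a tibble with one row per species.
#' @export
species_table <- function(id,
                          initial_concentration = 1,
                          clamped = FALSE,
                          compartment = "cell",
                          name = id) {
  stopifnot(!anyDuplicated(id), all(initial_concentration >= 0))
  tibble::tibble(
    id = as.character(id),
    name = as.character(name),
    compartment = rep_len(as.character(compartment), length(id)),
    initial_concentration = rep_len(as.numeric(initial_concentration), length(id)),
    clamped = rep_len(as.logical(clamped), length(id))
  )
}

#' Define a single reaction
#'
#' Reactions follow the generalized mass-action rate law: the net flux is
#' `(kf * prod(x^nu) - kr * prod(x^nu')) * f(x, pi)` where `nu`/`nu'` are the
#' reactant/product stoichiometries and `f` is a positive modulation factor
#' (identically 1 for plain mass action; a rational expression for e.g.
#' reversible Michaelis-Menten kinetics).
#'
#' @param id reaction id.
#' @param reactants named integer vector of reactant stoichiometries
#'   (names are species ids); empty for a source exchange reaction.
#' @param products named integer vector of product stoichiometries.
#' @param reversible logical.
#' @param kf,kr forward / reverse rate constants.  `kr` is required for
#'   reversible reactions; irreversible reactions have their reverse rate
#'   fixed to exactly zero.
#' @param f optional modulation factor: a one-sided formula or expression in
#'   species ids and the parameters named in `pi`; `NULL` means `f == 1`
#'   (plain mass action).
#' @param pi named numeric vector of modulation parameters used by `f`.
#' @param elementary logical or `NA`; elementary (single mechanistic step)
#'   reactions are the ones treated as thermodynamically independent.  `NA`
#'   lets the pruning heuristic decide.
#' @param fully_modeled `FALSE` marks a partially modeled reaction (known
#'   incomplete stoichiometry, e.g. an implicit ATP/ADP conversion); such
#'   reactions are excluded from the closed subsystem.
#' @return a one-row tibble; bind rows of these to form a reaction table.
#' @export
reaction <- function(id, reactants, products, reversible = TRUE,
                     kf = 1, kr = if (reversible) 1 else NA_real_,
                     f = NULL, pi = NULL,
                     elementary = NA, fully_modeled = TRUE,
                     rate_expr = NULL) {
  reactants <- normalize_stoich(reactants)
  products <- normalize_stoich(products)
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction '", id, "' has neither reactants nor products", call. = FALSE)
  if (!is.null(rate_expr)) {
    # raw rate law that does not decompose into forward/reverse rate
    # constants: the rate slots become artificial parameters fixed to zero
    # and the net flux is taken from the expression itself
    kf <- NA_real_; kr <- NA_real_
    if (isTRUE(elementary)) stop("a raw-rate-law reaction cannot be elementary",
                                 call. = FALSE)
    elementary <- FALSE
    rate_expr <- as_f_expression(rate_expr)
  } else if (reversible && is.na(kr)) {
    stop("reversible reaction '", id, "' needs a reverse rate constant", call. = FALSE)
  }
  if (!reversible) kr <- NA_real_
  f_expr <- if (is.null(f)) list(NULL) else list(as_f_expression(f))
  tibble::tibble(
    id = as.character(id),
    reactants = list(reactants),
    products = list(products),
    reversible = reversible,
    kf = as.numeric(kf),
    kr = as.numeric(kr),
    f_expr = f_expr,
    pi = list(if (is.null(pi)) numeric(0) else pi),
    elementary = elementary,
    fully_modeled = fully_modeled,
    rate_expr = list(rate_expr)
  )
}

normalize_stoich <- function(x) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  stopifnot(!is.null(names(x)), all(names(x) != ""), all(x > 0), all(x == round(x)))
  v <- as.numeric(x)
  names(v) <- names(x)
  v
}

as_f_expression <- function(f) {
  if (inherits(f, "formula")) f[[length(f)]]
  else if (is.expression(f)) f[[1L]]
  else if (is.call(f) || is.name(f) || is.numeric(f)) f
  else if (is.character(f)) str2lang(f)
  else stop("cannot interpret modulation factor", call. = FALSE)
}

#' Assemble a reaction network
#'
#' Combines species, reactions and compartments into the central model object.
#' The kinetic parameter table is derived with a stable ordering:
#' reaction-major, forward rate before reverse rate, modulation parameters
#' appended after all rate constants.  Irreversible reactions contribute a
#' reverse-rate slot whose value is fixed to exactly zero, so the parameter
#' vector always has two rate slots per reaction (plus modulation entries).
#'
#' @param species a species table from [species_table()].
#' @param reactions a reaction table (rows from [reaction()]).
#' @param compartments named numeric vector of compartment volumes (> 0).
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, compartments = c(cell = 1)) {
  stopifnot(is.data.frame(species), is.data.frame(reactions))
  stopifnot(!anyDuplicated(species$id), !anyDuplicated(reactions$id))
  referenced <- unique(unlist(lapply(
    seq_len(nrow(reactions)),
    function(i) c(names(reactions$reactants[[i]]), names(reactions$products[[i]]))
  )))
  missing <- setdiff(referenced, species$id)
  if (length(missing) > 0L)
    stop("reactions reference unknown species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stopifnot(all(compartments > 0), all(species$compartment %in% names(compartments)))

  net <- structure(
    list(species = tibble::as_tibble(species),
         reactions = tibble::as_tibble(reactions),
         compartments = compartments),
    class = "reaction_network"
  )
  net$parameters <- build_parameter_table(net)
  net
}

# Stable global parameter ordering: per reaction kf then kr, then every
# modulation parameter in reaction order.  Constraint-matrix columns depend
# on this ordering being reproducible.
build_parameter_table <- function(net) {
  rx <- net$reactions
  rows <- lapply(seq_len(nrow(rx)), function(i) {
    raw <- !is.null(rx$rate_expr[[i]])
    tibble::tibble(
      id = c(paste0(rx$id[i], "_kf"), paste0(rx$id[i], "_kr")),
      reaction_id = rx$id[i],
      role = c("forward", "reverse"),
      value = if (raw) c(0, 0) else c(rx$kf[i], ifelse(rx$reversible[i], rx$kr[i], 0)),
      fixed_zero = if (raw) c(TRUE, TRUE) else c(FALSE, !rx$reversible[i])
    )
  })
  mod <- lapply(seq_len(nrow(rx)), function(i) {
    p <- rx$pi[[i]]
    if (length(p) == 0L) return(NULL)
    tibble::tibble(id = names(p), reaction_id = rx$id[i], role = "modulation",
                   value = as.numeric(p), fixed_zero = FALSE)
  })
  out <- dplyr::bind_rows(c(rows, mod))
  if (anyDuplicated(out$id))
    stop("duplicated parameter ids: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "), call. = FALSE)
  out
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions, ",
      nrow(x$parameters), " parameters\n", sep = "")
  cat("  clamped species: ", sum(x$species$clamped),
      "; irreversible reactions: ", sum(!x$reactions$reversible), "\n", sep = "")
  invisible(x)
}

#' Stoichiometry matrix
#'
#' Net stoichiometry `S[n, m] = nu'[n, m] - nu[n, m]` over a species and
#' reaction subset, as an exact integer matrix.
#'
#' @param network a `reaction_network`.
#' @param species_ids,reaction_ids id subsets (default: all, in table order).
#' @param kind `"net"`, `"reactant"` (nu) or `"product"` (nu').
#' @return an integer-valued matrix with species ids as row names and
#'   reaction ids as column names.
#' @export
stoichiometry_matrix <- function(network, species_ids = NULL, reaction_ids = NULL,
                                 kind = c("net", "reactant", "product")) {
  kind <- match.arg(kind)
  if (is.null(species_ids)) species_ids <- network$species$id
  if (is.null(reaction_ids)) reaction_ids <- network$reactions$id
  check_ids(species_ids, network$species$id, "species")
  check_ids(reaction_ids, network$reactions$id, "reaction")
  m <- matrix(0, length(species_ids), length(reaction_ids),
              dimnames = list(species_ids, reaction_ids))
  rx <- network$reactions
  for (j in seq_along(reaction_ids)) {
    i <- match(reaction_ids[j], rx$id)
    nu <- rx$reactants[[i]]
    nup <- rx$products[[i]]
    for (sp in names(nu)) if (sp %in% species_ids) m[sp, j] <- m[sp, j] - nu[[sp]]
    for (sp in names(nup)) if (sp %in% species_ids) m[sp, j] <- m[sp, j] + nup[[sp]]
  }
  m
}

check_ids <- function(ids, known, what) {
  bad <- setdiff(ids, known)
  if (length(bad) > 0L)
    stop("unknown ", what, " id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Kinetic parameter table of a network
#'
#' @param network a `reaction_network`.
#' @return tibble with columns `id`, `reaction_id`, `role`
#'   (forward/reverse/modulation), `value` and `fixed_zero` (parameters whose
#'   value is structurally zero, e.g. reverse rates of irreversible
#'   reactions; these are held out of log space).
#' @export
parameter_table <- function(network) network$parameters

#' Replace kinetic parameter values by id
#'
#' @param network a `reaction_network`.
#' @param values named numeric vector (names are parameter ids).  Values for
#'   zero-fixed parameters must be 0.
#' @return the network with its parameter table, and the per-reaction
#'   `kf`/`kr`/`pi` fields, updated.
#' @export
set_parameters <- function(network, values) {
  stopifnot(!is.null(names(values)))
  check_ids(names(values), network$parameters$id, "parameter")
  pt <- network$parameters
  idx <- match(names(values), pt$id)
  if (any(pt$fixed_zero[idx] & values != 0))
    stop("attempt to set a zero-fixed parameter to a nonzero value", call. = FALSE)
  pt$value[idx] <- as.numeric(values)
  network$parameters <- pt
  # mirror into the reaction table so simulation sees the same values
  for (i in seq_len(nrow(network$reactions))) {
    if (!is.null(network$reactions$rate_expr[[i]])) next
    rid <- network$reactions$id[i]
    network$reactions$kf[i] <- pt$value[pt$id == paste0(rid, "_kf")]
    if (network$reactions$reversible[i])
      network$reactions$kr[i] <- pt$value[pt$id == paste0(rid, "_kr")]
    p <- network$reactions$pi[[i]]
    if (length(p) > 0L)
      network$reactions$pi[[i]] <- stats::setNames(
        pt$value[match(names(p), pt$id)], names(p))
  }
  network
}

#' Log-parameter vector
#'
#' Returns `kappa = log(k)` over the parameter table, with `NA` for
#' zero-fixed parameters, which live outside log space.
#'
#' @param network a `reaction_network`.
#' @return named numeric vector of length J.
#' @export
log_parameters <- function(network) {
  pt <- network$parameters
  kappa <- ifelse(pt$fixed_zero, NA_real_, log(pt$value))
  stats::setNames(kappa, pt$id)
}
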