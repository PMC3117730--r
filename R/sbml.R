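# SBML read/write on xml2.  Scope: SBML core as used by kinetic ODE models
# (compartments, species with boundaryCondition/constant, reactions with
# stoichiometries and kineticLaw MathML, global and local parameters).
# Accepts Level 2 and Level 3 documents; writes Level 3 Version 2.
# Events, rules and algebraic constraints are out of scope.

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
SBML_L3V2_NS <- "http://www.sbml.org/sbml/level3/version2/core"

# ---- MathML <-> R expressions ----------------------------------------------

mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("MathML <math> must have one child", call. = FALSE)
    return(mathml_to_expr(kids[[1L]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- trimws(strsplit(xml2::xml_text(node), "\\s+")[[1]])
      parts <- parts[parts != ""]
      return(as.numeric(parts[1]) * 10^as.numeric(parts[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    args <- lapply(kids[-1L], mathml_to_expr)
    fold <- function(fun) Reduce(function(a, b) call(fun, a, b), args)
    switch(op,
      plus = if (length(args) == 1L) args[[1L]] else fold("+"),
      minus = if (length(args) == 1L) call("-", args[[1L]]) else fold("-"),
      times = if (length(args) == 1L) args[[1L]] else fold("*"),
      divide = fold("/"),
      power = fold("^"),
      exp = call("exp", args[[1L]]),
      ln = call("log", args[[1L]]),
      root = call("sqrt", args[[length(args)]]),
      stop("unsupported MathML operator: ", op, call. = FALSE)
    )
  } else stop("unsupported MathML node: ", nm, call. = FALSE)
}

expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    if (e < 0) return(sprintf("<apply><minus/>%s</apply>", expr_to_mathml(-e)))
    return(sprintf("<cn> %s </cn>", format(e, digits = 17)))
  }
  if (is.name(e)) return(sprintf("<ci> %s </ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    args <- as.list(e)[-1L]
    body <- paste(vapply(args, expr_to_mathml, character(1)), collapse = "")
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", "exp" = "exp", "log" = "ln",
                  "(" = return(expr_to_mathml(args[[1L]])),
                  stop("cannot serialise operator to MathML: ", op, call. = FALSE))
    return(sprintf("<apply><%s/>%s</apply>", tag, body))
  }
  stop("cannot serialise expression to MathML", call. = FALSE)
}

# kf * prod(x^nu) as an R expression
monomial_expr <- function(rate_id, stoich) {
  e <- as.name(rate_id)
  for (sp in names(stoich)) {
    term <- if (stoich[[sp]] == 1) as.name(sp) else
      call("^", as.name(sp), as.numeric(stoich[[sp]]))
    e <- call("*", e, term)
  }
  e
}

mass_action_expr <- function(rx_row, kf_id, kr_id) {
  fwd <- monomial_expr(kf_id, rx_row$reactants[[1L]])
  e <- if (rx_row$reversible)
    call("-", fwd, monomial_expr(kr_id, rx_row$products[[1L]]))
  else fwd
  if (!is.null(rx_row$f_expr[[1L]])) e <- call("*", call("(", e), rx_row$f_expr[[1L]])
  e
}

# ---- writing ----------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num_attr <- function(x) format(x, digits = 17)

#' Write a reaction network to SBML
#'
#' Emits SBML Level 3 Version 2: clamped species carry
#' `boundaryCondition="true"`, every kinetic parameter becomes a global
#' parameter (zero values, e.g. fixed reverse rates, are written exactly),
#' and each reaction's kinetic law is the generalized mass-action expression
#' in MathML.  Re-reading the file reproduces the network's stoichiometry,
#' reversibility flags and parameter values.
#'
#' @param network a `reaction_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  sp <- network$species; rx <- network$reactions; pt <- network$parameters
  comp <- paste(sprintf(
    '      <compartment id="%s" size="%s" constant="true" spatialDimensions="3"/>',
    names(network$compartments), num_attr(network$compartments)), collapse = "\n")
  spec <- paste(sprintf(
    paste0('      <species id="%s" name="%s" compartment="%s"',
           ' initialConcentration="%s" boundaryCondition="%s"',
           ' constant="false" hasOnlySubstanceUnits="false"/>'),
    sp$id, xml_escape(sp$name), sp$compartment,
    num_attr(sp$initial_concentration),
    ifelse(sp$clamped, "true", "false")), collapse = "\n")
  pars <- paste(sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                        pt$id, num_attr(pt$value)), collapse = "\n")

  rx_chunks <- vapply(seq_len(nrow(rx)), function(i) {
    row <- rx[i, ]
    side <- function(stoich, tag) {
      if (length(stoich[[1L]]) == 0L) return("")
      refs <- paste(sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        names(stoich[[1L]]), num_attr(stoich[[1L]])), collapse = "\n")
      sprintf("        <%s>\n%s\n        </%s>", tag, refs, tag)
    }
    e <- if (!is.null(row$rate_expr[[1L]])) row$rate_expr[[1L]] else
      mass_action_expr(row, paste0(row$id, "_kf"), paste0(row$id, "_kr"))
    math <- sprintf('          <math xmlns="%s">%s</math>', MATHML_NS, expr_to_mathml(e))
    paste0(
      sprintf('      <reaction id="%s" reversible="%s">\n', row$id,
              ifelse(row$reversible, "true", "false")),
      side(row$reactants, "listOfReactants"),
      if (length(row$reactants[[1L]]) > 0L) "\n" else "",
      side(row$products, "listOfProducts"),
      if (length(row$products[[1L]]) > 0L) "\n" else "",
      "        <kineticLaw>\n", math, "\n        </kineticLaw>\n",
      "      </reaction>")
  }, character(1))

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<sbml xmlns="%s" level="3" version="2">\n', SBML_L3V2_NS),
    '  <model id="model">\n',
    "    <listOfCompartments>\n", comp, "\n    </listOfCompartments>\n",
    "    <listOfSpecies>\n", spec, "\n    </listOfSpecies>\n",
    "    <listOfParameters>\n", pars, "\n    </listOfParameters>\n",
    "    <listOfReactions>\n", paste(rx_chunks, collapse = "\n"),
    "\n    </listOfReactions>\n",
    "  </model>\n</sbml>\n")
  # parse before writing so an ill-formed document can never be emitted
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

# Decide whether a kinetic-law expression is the generalized mass-action
# form (r+ * prod x^nu - r- * prod x^nu') * f with f a shared positive
# factor.  Detection is numeric: the law and the candidate form are
# evaluated at random positive states; a constant ratio identifies plain
# mass action (the constant absorbs e.g. a compartment-volume factor), a
# state-dependent but everywhere-positive ratio identifies a generalized
# law whose modulation factor is the quotient.
decompose_rate_law <- function(expr, reversible, reactants, products,
                               param_values, species_ids,
                               compartment_ids = character(0), n_probe = 25) {
  vars <- all.vars(expr)
  cand <- setdiff(intersect(vars, names(param_values)), compartment_ids)
  other <- setdiff(vars, c(cand, species_ids, compartment_ids))
  if (length(other) > 0L)
    return(list(ok = FALSE, why = paste("unknown symbols:", paste(other, collapse = ", "))))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(20110506L)
  states <- matrix(stats::runif(n_probe * length(species_ids), 0.25, 4),
                   n_probe, length(species_ids), dimnames = list(NULL, species_ids))
  eval_at <- function(e, s) {
    env <- list2env(as.list(c(s, param_values)), parent = baseenv())
    eval(e, env)
  }
  lhs <- vapply(seq_len(n_probe), function(s) eval_at(expr, states[s, ]), numeric(1))
  if (any(!is.finite(lhs)))
    return(list(ok = FALSE, why = "rate law not finite at probe states"))

  mono <- function(rate, stoich, s) rate * prod(s[names(stoich)]^stoich)
  pairs <- if (reversible) {
    if (length(cand) < 2L) return(list(ok = FALSE, why = "fewer than two rate parameters"))
    expand.grid(f = cand, r = cand, stringsAsFactors = FALSE) |>
      (\(g) g[g$f != g$r, , drop = FALSE])()
  } else {
    if (length(cand) < 1L) return(list(ok = FALSE, why = "no rate parameter"))
    data.frame(f = cand, r = NA_character_, stringsAsFactors = FALSE)
  }

  best_general <- NULL
  for (p in seq_len(nrow(pairs))) {
    vf <- param_values[[pairs$f[p]]]
    vr <- if (reversible) param_values[[pairs$r[p]]] else 0
    rhs <- vapply(seq_len(n_probe), function(s) {
      mono(vf, reactants, states[s, ]) -
        (if (reversible) mono(vr, products, states[s, ]) else 0)
    }, numeric(1))
    if (any(abs(rhs) < 1e-12)) next
    ratio <- lhs / rhs
    if (any(!is.finite(ratio)) || any(ratio <= 0)) next
    if (diff(range(ratio)) <= 1e-9 * max(abs(ratio))) {
      alpha <- stats::median(ratio)
      pi_ids <- setdiff(cand, c(pairs$f[p], if (reversible) pairs$r[p]))
      return(list(ok = TRUE, kind = "mass_action",
                  kf = alpha * vf, kr = if (reversible) alpha * vr else NA_real_,
                  f = NULL, pi = param_values[pi_ids]))
    }
    if (is.null(best_general)) {
      base <- if (reversible)
        call("-", monomial_expr(pairs$f[p], reactants),
             monomial_expr(pairs$r[p], products))
      else monomial_expr(pairs$f[p], reactants)
      f_quot <- call("/", call("(", expr), call("(", base))
      pi_ids <- cand  # rate parameters appear inside the quotient factor
      best_general <- list(ok = TRUE, kind = "generalized",
                           kf = vf, kr = if (reversible) vr else NA_real_,
                           kf_id = pairs$f[p],
                           kr_id = if (reversible) pairs$r[p] else NA_character_,
                           f = f_quot, pi = param_values[pi_ids])
    }
  }
  if (!is.null(best_general)) return(best_general)
  list(ok = FALSE, why = "no forward/reverse split with a positive shared factor")
}

#' Read an SBML model into a reaction network
#'
#' Accepts SBML Level 2 or Level 3 single-model files.  Species with
#' `boundaryCondition="true"` or `constant="true"` are marked clamped.
#' Each reaction's kinetic law is decomposed into the generalized
#' mass-action form; laws that cannot be decomposed are kept as raw rate
#' expressions with two artificial zero-fixed rate parameters, flagged in
#' the `diagnostics` attribute (a tibble of structured records) rather than
#' silently accepted.
#'
#' @param path SBML file path.
#' @return a `reaction_network` with attribute `diagnostics`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot parse SBML file: ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  models <- xml2::xml_find_all(doc, "./model")
  if (length(models) != 1L) stop("expected a single <model>", call. = FALSE)
  model <- models[[1L]]

  attr_or <- function(node, a, default) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else v
  }

  comp_nodes <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  compartments <- stats::setNames(
    vapply(comp_nodes, function(n) as.numeric(attr_or(n, "size", "1")), numeric(1)),
    xml2::xml_attr(comp_nodes, "id"))
  if (length(compartments) == 0L) compartments <- c(cell = 1)

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) stop("model has no species", call. = FALSE)
  init <- vapply(sp_nodes, function(n) {
    v <- xml2::xml_attr(n, "initialConcentration")
    if (is.na(v)) v <- xml2::xml_attr(n, "initialAmount")
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  species <- species_table(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = vapply(sp_nodes, function(n) attr_or(n, "name", xml2::xml_attr(n, "id")),
                  character(1)),
    compartment = vapply(sp_nodes, function(n)
      attr_or(n, "compartment", names(compartments)[1]), character(1)),
    initial_concentration = init,
    clamped = vapply(sp_nodes, function(n) {
      attr_or(n, "boundaryCondition", "false") == "true" ||
        attr_or(n, "constant", "false") == "true"
    }, logical(1))
  )

  glob_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  globals <- stats::setNames(
    vapply(glob_nodes, function(n) as.numeric(attr_or(n, "value", "0")), numeric(1)),
    xml2::xml_attr(glob_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  diags <- list()
  rows <- list()
  seen_pi <- character(0)
  for (n in rx_nodes) {
    rid <- xml2::xml_attr(n, "id")
    reversible <- attr_or(n, "reversible", "true") == "true"
    get_side <- function(tag) {
      refs <- xml2::xml_find_all(n, sprintf("./%s/speciesReference", tag))
      if (length(refs) == 0L) return(stats::setNames(numeric(0), character(0)))
      st <- vapply(refs, function(r) as.numeric(attr_or(r, "stoichiometry", "1")),
                   numeric(1))
      tapply(st, xml2::xml_attr(refs, "species"), sum)[
        unique(xml2::xml_attr(refs, "species"))]
    }
    reactants <- get_side("listOfReactants")
    products <- get_side("listOfProducts")

    locals <- xml2::xml_find_all(
      n, "./kineticLaw/listOfLocalParameters/localParameter | ./kineticLaw/listOfParameters/parameter")
    local_vals <- stats::setNames(
      vapply(locals, function(l) as.numeric(attr_or(l, "value", "0")), numeric(1)),
      xml2::xml_attr(locals, "id"))
    pvals <- c(local_vals, globals[setdiff(names(globals), names(local_vals))],
               compartments)

    math <- xml2::xml_find_first(n, "./kineticLaw/math")
    if (inherits(math, "xml_missing")) {
      # no kinetic law: keep structure; rate slots become zero-fixed
      rows[[length(rows) + 1L]] <- reaction(
        rid, reactants, products, reversible = reversible, rate_expr = 0)
      diags[[length(diags) + 1L]] <- tibble::tibble(
        reaction_id = rid, issue = "no_kinetic_law")
      next
    }
    expr <- tryCatch(mathml_to_expr(math), error = function(e) e)
    if (inherits(expr, "error")) {
      stop("reaction '", rid, "': ", conditionMessage(expr), call. = FALSE)
    }
    dec <- decompose_rate_law(expr, reversible, reactants, products,
                              pvals, species$id, names(compartments))
    dedup_pi <- function(pi, f) {
      # modulation-parameter ids must be globally unique in the network
      if (is.null(pi) || length(pi) == 0L) return(list(pi = NULL, f = f))
      clash <- intersect(names(pi), seen_pi)
      if (length(clash) > 0L) {
        new <- paste(rid, clash, sep = "_")
        if (!is.null(f))
          f <- substitute_names(f, stats::setNames(lapply(new, as.name), clash))
        names(pi)[match(clash, names(pi))] <- new
      }
      seen_pi <<- c(seen_pi, names(pi))
      list(pi = pi, f = f)
    }
    if (isTRUE(dec$ok) && dec$kind == "mass_action") {
      dd <- dedup_pi(dec$pi, NULL)
      rows[[length(rows) + 1L]] <- reaction(
        rid, reactants, products, reversible = reversible,
        kf = dec$kf, kr = if (reversible) dec$kr else NA_real_,
        pi = dd$pi)
    } else if (isTRUE(dec$ok)) {
      # generalized law: the quotient modulation factor is retargeted at the
      # network's canonical forward/reverse parameter ids so it tracks
      # later parameter updates
      mapping <- stats::setNames(list(as.name(paste0(rid, "_kf"))), dec$kf_id)
      if (reversible)
        mapping[[dec$kr_id]] <- as.name(paste0(rid, "_kr"))
      f <- substitute_names(dec$f, mapping)
      pi <- dec$pi[setdiff(names(dec$pi),
                           c(dec$kf_id, if (reversible) dec$kr_id))]
      dd <- dedup_pi(if (length(pi) > 0L) pi else NULL, f)
      rows[[length(rows) + 1L]] <- reaction(
        rid, reactants, products, reversible = reversible,
        kf = dec$kf, kr = if (reversible) dec$kr else NA_real_,
        f = dd$f, pi = dd$pi, elementary = FALSE)
      diags[[length(diags) + 1L]] <- tibble::tibble(
        reaction_id = rid, issue = "generalized_rate_law")
    } else {
      pi <- pvals[intersect(all.vars(expr), names(pvals))]
      dd <- dedup_pi(if (length(pi) > 0L) pi else NULL, expr)
      rows[[length(rows) + 1L]] <- reaction(
        rid, reactants, products, reversible = reversible,
        rate_expr = dd$f, pi = dd$pi)
      diags[[length(diags) + 1L]] <- tibble::tibble(
        reaction_id = rid, issue = paste0("not_decomposable: ", dec$why))
    }
  }

  net <- reaction_network(species, dplyr::bind_rows(rows), compartments)
  attr(net, "diagnostics") <- if (length(diags) > 0L) dplyr::bind_rows(diags) else
    tibble::tibble(reaction_id = character(0), issue = character(0))
  net
}

# rename symbols in an expression (used to retarget a quotient modulation
# factor at the network's canonical rate-parameter ids)
substitute_names <- function(e, mapping) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(mapping)) return(mapping[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- substitute_names(e[[i]], mapping)
    return(e)
  }
  e
}
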