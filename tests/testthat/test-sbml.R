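round_trip <- function(net) {
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, path)
  read_sbml(path)
}

test_that("triangle SBML round-trip preserves structure and parameters", {
  net <- make_triangle(kf = c(2, 1, 1))
  net2 <- round_trip(net)
  expect_equal(nrow(net2$species), 3)
  expect_equal(nrow(net2$reactions), 3)
  expect_identical(stoichiometry_matrix(net2), stoichiometry_matrix(net))
  expect_identical(net2$reactions$reversible, net$reactions$reversible)
  expect_equal(parameter_table(net2)$value, parameter_table(net)$value)
  expect_equal(nrow(attr(net2, "diagnostics")), 0)
  # and a second round trip is the identity as well
  net3 <- round_trip(net2)
  expect_identical(stoichiometry_matrix(net3), stoichiometry_matrix(net))
  expect_equal(parameter_table(net3)$value, parameter_table(net)$value)
})

test_that("clamped species, irreversible reactions and exact zeros survive", {
  sp <- species_table(c("S", "P", "E"), c(5, 0, 1), clamped = c(FALSE, FALSE, TRUE))
  rx <- dplyr::bind_rows(
    reaction("r1", c(S = 1, E = 1), c(P = 1, E = 1), kf = 2, kr = 0.5),
    reaction("deg", c(P = 1), c(S = 1), reversible = FALSE, kf = 0.3),
    reaction("src", NULL, c(S = 1), reversible = FALSE, kf = 0.1)
  )
  net <- reaction_network(sp, rx)
  net2 <- round_trip(net)
  expect_identical(net2$species$clamped, c(FALSE, FALSE, TRUE))
  expect_identical(net2$reactions$reversible, c(TRUE, FALSE, FALSE))
  pt <- parameter_table(net2)
  expect_identical(pt$value[pt$id == "deg_kr"], 0)  # exact zero preserved
  expect_true(pt$fixed_zero[pt$id == "deg_kr"])
})

test_that("a generalized (Michaelis-Menten-like) law round-trips its fluxes", {
  sp <- species_table(c("S", "P"), c(5, 0))
  net <- reaction_network(sp, reaction(
    "mm", c(S = 1), c(P = 1), kf = 2, kr = 0.5,
    f = ~ 1 / (1 + S / Km + P / Kp), pi = c(Km = 0.7, Kp = 1.3)))
  net2 <- round_trip(net)
  d <- attr(net2, "diagnostics")
  expect_identical(d$issue, "generalized_rate_law")  # flagged, not silent
  # flux equality at several states is the meaningful identity for f
  for (s in list(c(S = 1.3, P = 0.4), c(S = 0.2, P = 2), c(S = 3, P = 3))) {
    expect_equal(net_flux(net2, s)$net, net_flux(net, s)$net, tolerance = 1e-9)
  }
  expect_equal(net2$reactions$kf[1], 2)
  expect_equal(net2$reactions$kr[1], 0.5)
})

test_that("a non-decomposable kinetic law is flagged and kept as raw rate", {
  path <- withr::local_tempfile(fileext = ".xml")
  # rate law exp(S) - k1: not of the generalized mass-action form
  writeLines(sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="m">
    <listOfCompartments><compartment id="cell" size="1" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="S" compartment="cell" initialConcentration="1" boundaryCondition="false" constant="false"/>
      <species id="P" compartment="cell" initialConcentration="0" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters><parameter id="k1" value="0.5" constant="true"/></listOfParameters>
    <listOfReactions>
      <reaction id="odd" reversible="true">
        <listOfReactants><speciesReference species="S" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="P" stoichiometry="1" constant="true"/></listOfProducts>
        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">
          <apply><minus/><apply><exp/><ci>S</ci></apply><ci>k1</ci></apply>
        </math></kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'), path)
  net <- read_sbml(path)
  d <- attr(net, "diagnostics")
  expect_match(d$issue, "not_decomposable")
  pt <- parameter_table(net)
  expect_true(all(pt$fixed_zero[pt$role %in% c("forward", "reverse")]))
  # the raw law still simulates: net flux is exp(S) - k1
  expect_equal(net_flux(net, c(S = 1, P = 0))$net, exp(1) - 0.5)
})

test_that("an SBML Level 2 style document reads (defaults applied)", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="m">
    <listOfCompartments><compartment id="c" size="2"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" initialConcentration="1"/>
      <species id="B" compartment="c" initialConcentration="0" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r">
        <listOfReactants><speciesReference species="A"/></listOfReactants>
        <listOfProducts><speciesReference species="B"/></listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><minus/>
              <apply><times/><ci>kf</ci><ci>A</ci></apply>
              <apply><times/><ci>kr</ci><ci>B</ci></apply>
            </apply>
          </math>
          <listOfParameters>
            <parameter id="kf" value="3"/>
            <parameter id="kr" value="0.5"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  net <- read_sbml(path)
  expect_true(net$reactions$reversible[1])      # L2 default
  expect_identical(net$species$clamped, c(FALSE, TRUE))
  expect_equal(net$reactions$kf[1], 3)
  expect_equal(net$reactions$kr[1], 0.5)
  expect_equal(unname(net$compartments["c"]), 2)
})

test_that("unparsable input raises a format error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not xml <", path)
  expect_error(read_sbml(path), "cannot parse SBML")
})
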