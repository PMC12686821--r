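# Shared fixtures: SBML sample, candidate-space shortcuts, reference-solver
# sweeps used as independent oracles.

write_mini_sbml <- function(path = tempfile(fileext = ".xml")) {
  writeLines(mini_sbml_text(), path)
  path
}

mini_sbml_text <- function() {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="mini" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="glc_e" compartment="e" constant="false" boundaryCondition="false"/>',
    '      <species id="glc_c" compartment="c" constant="false" boundaryCondition="false"/>',
    '      <species id="bm_c" compartment="c" constant="false" boundaryCondition="false"/>',
    '    </listOfSpecies>',
    '    <listOfParameters>',
    '      <parameter id="lb_ex" value="-10" constant="true"/>',
    '      <parameter id="zero" value="0" constant="true"/>',
    '      <parameter id="ub_big" value="1000" constant="true"/>',
    '    </listOfParameters>',
    '    <listOfReactions>',
    '      <reaction id="EX_glc" reversible="true" fbc:lowerFluxBound="lb_ex" fbc:upperFluxBound="zero">',
    '        <listOfReactants>',
    '          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>',
    '        </listOfReactants>',
    '      </reaction>',
    '      <reaction id="GLCt" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_big">',
    '        <listOfReactants>',
    '          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>',
    '        </listOfReactants>',
    '        <listOfProducts>',
    '          <speciesReference species="glc_c" stoichiometry="1" constant="true"/>',
    '        </listOfProducts>',
    '        <fbc:geneProductAssociation>',
    '          <fbc:geneProductRef fbc:geneProduct="g1"/>',
    '        </fbc:geneProductAssociation>',
    '      </reaction>',
    '      <reaction id="r_2111" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_big">',
    '        <listOfReactants>',
    '          <speciesReference species="glc_c" stoichiometry="2" constant="true"/>',
    '        </listOfReactants>',
    '        <listOfProducts>',
    '          <speciesReference species="bm_c" stoichiometry="1" constant="true"/>',
    '        </listOfProducts>',
    '      </reaction>',
    '      <reaction id="SINK_bm" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_big">',
    '        <listOfReactants>',
    '          <speciesReference species="bm_c" stoichiometry="1" constant="true"/>',
    '        </listOfReactants>',
    '      </reaction>',
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    '          <fbc:fluxObjective fbc:reaction="r_2111" fbc:coefficient="1"/>',
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
}

# candidate space without pruning, for GA/search tests
manual_candidate_space <- function(knockouts, env_space) {
  structure(list(knockout_candidates = knockouts,
                 environment = env_space,
                 provenance = data.frame(reaction = character(0),
                                         reason = character(0))),
            class = "candidate_space")
}

# reference-solver FVA range of one reaction (independent oracle path)
ref_flux_range <- function(model, rxn, lb = NULL, ub = NULL) {
  obj <- numeric(length(model$rxns))
  obj[match(rxn, model$rxns)] <- 1
  lo <- evolvexga:::ref_steady_state(model, obj, maximize = FALSE,
                                     lb = lb, ub = ub)
  hi <- evolvexga:::ref_steady_state(model, obj, maximize = TRUE,
                                     lb = lb, ub = ub)
  c(min = lo$objval, max = hi$objval)
}

# minimum |flux| of one reaction via two sign-restricted reference LPs
ref_abs_min <- function(model, rxn, extra_A = NULL, extra_sense = NULL,
                        extra_rhs = NULL) {
  n <- length(model$rxns)
  j <- match(rxn, model$rxns)
  obj <- numeric(n)
  vals <- c()
  for (s in c(1, -1)) {
    obj[j] <- s
    row <- numeric(n); row[j] <- -s   # s*v >= 0
    r <- evolvexga:::ref_steady_state(
      model, obj, maximize = FALSE,
      extra_A = rbind(extra_A, matrix(row, 1)),
      extra_sense = c(extra_sense, "<="),
      extra_rhs = c(extra_rhs, 0))
    if (r$status == "optimal") vals <- c(vals, r$objval)
  }
  if (length(vals) == 0L) NA_real_ else min(vals)
}

# attach a one-step production pathway draining a backbone metabolite
with_product <- function(model, from = "M2") {
  add_pathway(model, pathway_definition(list(
    list(id = "P", coeffs = stats::setNames(c(-1, 1), c(from, "Prod")),
         lb = 0, ub = 20),
    list(id = "EX_Prod", coeffs = c(Prod = -1), lb = 0, ub = 20)),
    new_metabolites = "Prod"))
}
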