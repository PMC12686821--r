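# Model container, tabular and SBML I/O, pathway augmentation, constraint
# views.

test_that("bundled branch toy loads with expected structure", {
  path <- system.file("extdata", "branch_toy.tsv", package = "evolvexga")
  m <- load_model(path)
  expect_length(m$mets, 3)
  expect_length(m$rxns, 5)
  expect_identical(m$growth_reaction, "GROWTH")
  expect_identical(m$category[m$rxns == "EX_A"], "exchange")
})

test_that("toy model round-trips through the tabular format", {
  m <- make_branch_toy()
  path <- tempfile(fileext = ".tsv")
  write_toy_model(m, path)
  m2 <- read_toy_model(path)
  expect_identical(m2$rxns, m$rxns)
  expect_identical(m2$mets[order(m2$mets)], m$mets[order(m$mets)])
  expect_equal(as.matrix(m2$S)[m$mets, ], as.matrix(m$S))
  expect_equal(m2$lb, m$lb)
  expect_equal(m2$ub, m$ub)
  expect_identical(m2$category, m$category)
})

test_that("duplicate reaction ids are rejected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tcategory",
               "R1\tA -> B\t0\t10\tauto",
               "R1\tB -> A\t0\t10\tauto",
               "GROWTH\tB ->\t0\t10\tbiomass"), path)
  expect_error(read_toy_model(path), "duplicate")
})

test_that("a model without identifiable growth reaction errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tcategory",
               "EX_A\tA ->\t-10\t0\tauto",
               "R1\tA -> B\t0\t10\tauto"), path)
  expect_error(read_toy_model(path), "growth")
})

test_that("SBML fbc models load with objective, bounds and categories", {
  path <- write_mini_sbml()
  m <- read_sbml_model(path)
  expect_identical(m$growth_reaction, "r_2111")  # from the fbc objective
  expect_equal(m$lb, c(-10, 0, 0, 0))
  expect_equal(m$ub, c(0, 1000, 1000, 1000))
  expect_identical(m$category,
                   c("exchange", "transport", "biomass", "exchange"))
  expect_identical(m$gene_associated, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fba(m)$objval, 5)  # 10 glucose / stoichiometry 2
  # explicit override beats the fbc objective
  m2 <- read_sbml_model(path, growth_reaction = "SINK_bm")
  expect_identical(m2$growth_reaction, "SINK_bm")
})

test_that("add_pathway appends reactions without touching the host", {
  host <- make_branch_toy()
  aug <- add_pathway(host, make_branch_pathway())
  expect_length(aug$rxns, 7)
  expect_length(aug$mets, 4)
  expect_identical(aug$product_exchange, "EX_Prod")
  expect_length(host$rxns, 5)  # host unchanged
  expect_equal(as.matrix(aug$S)[aug$mets != "Prod", host$rxns],
               as.matrix(host$S))
  # exchange invariant still holds after augmentation
  nnz <- Matrix::colSums(aug$S != 0)
  expect_true(all(nnz[aug$category == "exchange"] == 1))
})

test_that("pathway id collisions and undeclared metabolites error", {
  host <- make_branch_toy()
  clash <- pathway_definition(list(
    list(id = "R1", coeffs = c(C = -1), lb = 0, ub = 1)))
  expect_error(add_pathway(host, clash), "collides")
  orphan <- pathway_definition(list(
    list(id = "PX", coeffs = c(Nowhere = -1, C = 1), lb = 0, ub = 1)))
  expect_error(add_pathway(host, orphan), "undeclared")
})

test_that("apply_constraints is pure and encodes the design", {
  m <- make_branch_toy()
  env <- make_branch_env_space()
  v1 <- apply_constraints(m, "R3", "EX_A", env)
  v2 <- apply_constraints(m, "R3", "EX_A", env)
  expect_identical(v1$lb, v2$lb)
  expect_identical(v1$ub, v2$ub)
  expect_equal(m$lb[m$rxns == "R3"], 0)
  expect_equal(m$ub[m$rxns == "R3"], 20)  # base model untouched
  i <- match("R3", v1$rxns)
  expect_equal(c(v1$lb[i], v1$ub[i]), c(0, 0))
  j <- match("EX_A", v1$rxns)
  expect_equal(v1$lb[j], -10)
  expect_equal(v1$ub[j], -1)  # uptake forced
  expect_error(apply_constraints(m, "NOPE", character(0), env), "unknown")
  expect_error(apply_constraints(m, character(0), "EX_B", env),
               "not among candidates")
})

test_that("unselected candidate uptakes are closed", {
  m <- make_random_toy(12, seed = 3)
  env <- make_toy_env_space(m)
  expect_gt(nrow(env$candidates), 1)
  sel <- env$candidates$exchange_id[1]
  v <- apply_constraints(m, character(0), sel, env)
  others <- setdiff(env$candidates$exchange_id, sel)
  expect_true(all(v$lb[match(others, v$rxns)] >= 0))
})

test_that("bound edits apply by reaction id", {
  m <- make_branch_toy()
  m2 <- apply_bound_edits(m, data.frame(reaction_id = "R1", lb = 0,
                                        ub = 5))
  expect_equal(m2$ub[m2$rxns == "R1"], 5)
  expect_error(apply_bound_edits(m, data.frame(reaction_id = "ZZ",
                                               lb = 0, ub = 1)),
               "unknown")
})
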