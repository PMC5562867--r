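test_that("stoichiometric matrix reproduces declared coefficients", {
  comps <- compartments("c", side = "intracellular")
  mets <- metabolites(c("A", "B"), "c")
  m <- metabolic_model(comps, mets,
                       list(reaction("R1", c("A[c]" = -1, "B[c]" = 1), 0, 10)))
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(as.matrix(S), matrix(c(-1, 1), 2, 1,
                                    dimnames = list(c("A[c]", "B[c]"), "R1")))
})

test_that("empty model yields a 0x0 matrix", {
  m <- metabolic_model(compartments(character(0)),
                       metabolites(character(0), character(0)), list())
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(0L, 0L))
})

test_that("toy model matrix matches an independent dense construction", {
  m <- build_toy_model(small_toy_spec())
  S <- as.matrix(build_stoichiometric_matrix(m))
  dense <- matrix(0, nrow(m$metabolites), nrow(m$reactions),
                  dimnames = list(m$metabolites$id, m$reactions$id))
  for (j in seq_along(m$stoich))
    dense[names(m$stoich[[j]]), j] <- m$stoich[[j]]
  expect_equal(S, dense)
  # column sums equal the per-reaction net coefficient of the reaction list
  expect_equal(colSums(S),
               vapply(m$stoich, sum, numeric(1)))
  # every metabolite participates in at least one reaction
  expect_true(all(rowSums(S != 0) >= 1))
})

test_that("unresolved metabolite references raise a structural error", {
  comps <- compartments("c", side = "intracellular")
  mets <- metabolites("A", "c")
  expect_error(
    metabolic_model(comps, mets,
                    list(reaction("R1", c("A[c]" = -1, "ghost[c]" = 1)))),
    "R1.*ghost")
})

test_that("model -> matrix -> reaction list round trip is lossless", {
  m <- build_toy_model(small_toy_spec())
  S <- build_stoichiometric_matrix(m)
  back <- stoichiometry_from_matrix(S)
  for (id in m$reactions$id) {
    st <- m$stoich[[id]]
    expect_equal(sort(names(back[[id]])), sort(names(st)))
    expect_equal(back[[id]][names(st)], st)
  }
})

test_that("validation finds constructed holes and clean models pass", {
  # chain with no consumer of B: A_ext <-> A -> B
  comps <- compartments(c("e", "c"),
                        side = c("basolateral_extracellular", "intracellular"))
  mets <- rbind(metabolites("A", "e"), metabolites("A", "c"),
                metabolites("B", "c"))
  holey <- metabolic_model(comps, mets, list(
    exchange_reaction("A[e]", -10, 10),
    reaction("T", c("A[e]" = -1, "A[c]" = 1), -10, 10),
    reaction("R", c("A[c]" = -1, "B[c]" = 1), 0, 10)))
  rep <- validate_model(holey)
  expect_true("B[c]" %in% rep$dead_ends)
  expect_true("R" %in% rep$blocked)
  expect_false(rep$no_holes)

  clean <- validate_model(build_toy_model(small_toy_spec()))
  expect_equal(clean$dead_ends, character(0))
  expect_equal(clean$blocked, character(0))
  expect_true(clean$no_holes)
})

test_that("bound violations are reported, not raised, by validation", {
  m <- chain_model()
  m$reactions$lower_bound[3] <- 7
  m$reactions$upper_bound[3] <- 2   # corrupt post-construction
  rep <- validate_model(m)
  expect_equal(rep$bound_violations, "A2B")
})

test_that("knock_out zeroes bounds functionally and reversibly", {
  m <- chain_model(uptake_lb = -5)
  base <- max_flux(m, "EX_b_e")
  expect_equal(base, 5)
  ko <- knock_out(m, "A2B")
  expect_equal(max_flux(ko, "EX_b_e"), 0)           # sole path cut
  expect_equal(reaction_bounds(ko, "A2B"), c(0, 0))
  expect_equal(reaction_bounds(m, "A2B"), c(0, 1000))  # input untouched
  # idempotent
  expect_equal(knock_out(ko, "A2B"), ko)
  # restoring the original bounds restores the optimum
  restored <- set_reaction_bounds(ko, "A2B", 0, 1000)
  expect_equal(max_flux(restored, "EX_b_e"), base, tolerance = 1e-9)
  expect_error(knock_out(m, "NOPE"), "unknown reaction")
})

test_that("knocking out one of two parallel routes keeps redundant capacity", {
  m <- parallel_model(uptake_lb = -5, cap = 5)
  expect_equal(max_flux(m, "EX_b_e"), 5)
  expect_equal(max_flux(knock_out(m, "P1"), "EX_b_e"), 5)
})

test_that("knocking out the basolateral glucose exporter blocks secretion", {
  m <- build_toy_model(small_toy_spec())
  expect_gt(max_flux(m, "EX_glc_e"), 0)
  expect_equal(max_flux(knock_out(m, "GLCGLUT2"), "EX_glc_e"), 0)
})

test_that("constructor invariants reject malformed pieces", {
  expect_error(reaction("R", numeric(0)), "empty stoichiometry")
  expect_error(reaction("R", c("A[c]" = 1), 5, 2), "lower_bound exceeds")
  expect_error(reaction("R", c("A[c]" = -1, "B[c]" = 1), is_exchange = TRUE),
               "exactly one")
  expect_error(metabolites(c("A", "A"), c("c", "c")), "duplicate")
  comps <- compartments("c", side = "intracellular")
  expect_error(metabolic_model(comps, metabolites("A", "c"),
                               list(reaction("R", c("A[c]" = 1)),
                                    reaction("R", c("A[c]" = -1)))),
               "duplicate reaction ids")
})

test_that("gene rules parse, collect genes and evaluate deletions", {
  expect_null(parse_gene_rule(""))
  expect_equal(gene_rule_genes("(Ga and Gb) or Gc"), c("Ga", "Gb", "Gc"))
  expect_true(evaluate_gene_rule("(Ga and Gb) or Gc", "Ga"))
  expect_false(evaluate_gene_rule("(Ga and Gb) or Gc", c("Ga", "Gc")))
  expect_true(evaluate_gene_rule("", c("Ga")))
  expect_error(parse_gene_rule("Ga and (Gb or"), "parenthes|malformed")
  g <- model_genes(build_toy_model(small_toy_spec()))
  expect_true(all(c("Slc5a1", "Slc2a2", "Mttp", "Hmgcr") %in% g))
})
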