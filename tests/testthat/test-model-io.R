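# Model container, JSON dialect, constraints.

test_that("a toy JSON model is transcribed directly", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "A"}],
    "reactions": [
      {"id": "r1", "stoich": {"A": 1}, "lb": 0, "ub": 1, "gpr": null,
       "exchange": true},
      {"id": "r2", "stoich": {"A": -1}, "lb": 0, "ub": 1, "gpr": null,
       "exchange": true}
    ]
  }', path)
  m <- read_model(path)
  expect_equal(length(m$metabolite_ids), 1)
  expect_equal(m$reaction_ids, c("r1", "r2"))
  expect_equal(m$S, matrix(c(1, -1), 1, 2))
  expect_equal(m$v_inf, c(0, 0))
  expect_equal(m$v_sup, c(1, 1))
})

test_that("write_model / read_model round-trips every toy model", {
  for (nm in names(toys)) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model(toys[[nm]], path)
    m2 <- read_model(path)
    expect_equal(m2$metabolite_ids, toys[[nm]]$metabolite_ids, info = nm)
    expect_equal(m2$reaction_ids, toys[[nm]]$reaction_ids, info = nm)
    expect_equal(m2$S, toys[[nm]]$S, info = nm)
    expect_equal(m2$v_inf, toys[[nm]]$v_inf, info = nm)
    expect_equal(m2$v_sup, toys[[nm]]$v_sup, info = nm)
    expect_equal(m2$exchange, toys[[nm]]$exchange, info = nm)
    # GPR strings preserved verbatim up to whitespace
    expect_equal(lapply(m2$gpr_text, function(s) gsub("\\s+", " ", s)),
                 lapply(toys[[nm]]$gpr_text, function(s) gsub("\\s+", " ", s)),
                 info = nm)
  }
})

test_that("GPR strings with complexes survive the round trip", {
  m <- metabolic_model("A", c("r1", "r2"), matrix(c(1, -1), 1, 2),
                       c(0, 0), c(1, 1),
                       gpr = list(r1 = "(P1 AND P2) OR P3"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$gpr_text[["r1"]], "(P1 AND P2) OR P3")
})

test_that("malformed models are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "A"}],
    "reactions": [{"id": "r1", "stoich": {"B": 1}, "lb": 0, "ub": 1}]
  }', path)
  expect_error(read_model(path), "unknown metabolite")

  expect_error(
    metabolic_model("A", c("r1", "r1"), matrix(c(1, -1), 1, 2),
                    c(0, 0), c(1, 1)),
    "duplicate reaction")
  expect_error(
    metabolic_model(c("A", "B"), "r1", matrix(1, 1, 1), 0, 1),
    "stoichiometric matrix")
  expect_error(
    metabolic_model("A", c("r1", "r2"), matrix(c(1, -1), 1, 2),
                    c(0.5, 0), c(0.2, 1)),
    "empty flux interval")
  expect_error(
    suppressWarnings(write_model(toys$segment, "/nonexistent-dir/x/y.json")),
    "cannot write")
})

test_that("apply_constraints narrows bounds and records observations", {
  seg <- metabolic_model("A", c("r1", "r2"), matrix(c(1, -1), 1, 2),
                         c(-1, -1), c(1, 1))
  m1 <- apply_constraints(seg, constraint_spec(irreversible = "r1"))
  expect_equal(m1$v_inf, c(0, -1))
  expect_false(m1$reversible[1])

  m2 <- apply_constraints(seg, constraint_spec(zeroed = "r2"))
  expect_equal(m2$v_inf[2], 0)
  expect_equal(m2$v_sup[2], 0)

  m3 <- apply_constraints(seg, constraint_spec(
    fixed_exchanges = list(r2 = c(0.5, 0.005))))
  expect_equal(m3$v_inf, seg$v_inf)
  expect_equal(m3$v_sup, seg$v_sup)
  expect_equal(attr(m3, "fixed_exchanges")$r2, c(0.5, 0.005))

  expect_error(apply_constraints(seg, constraint_spec(zeroed = "nope")),
               "unknown reaction")
  # a spec that empties an interval fails
  down <- metabolic_model("A", c("r1", "r2"), matrix(c(1, -1), 1, 2),
                          c(-1, -1), c(-0.5, 1))
  expect_error(apply_constraints(down, constraint_spec(irreversible = "r1")),
               "empty")
})

test_that("apply_constraints never widens an interval", {
  for (seed in 1:10) {
    m <- small_random_model(seed)
    picks <- withr::with_seed(seed, sample(m$reaction_ids, 4))
    spec <- constraint_spec(irreversible = picks[1:2], zeroed = picks[3])
    m2 <- apply_constraints(m, spec)
    expect_true(all(m2$v_inf >= m$v_inf))
    expect_true(all(m2$v_sup <= m$v_sup))
  }
})

test_that("reversibility_summary partitions reactions", {
  seg <- metabolic_model("A", c("r1", "r2"), matrix(c(1, -1), 1, 2),
                         c(0, -1), c(1, 1))
  s <- reversibility_summary(seg)
  expect_equal(s$n_reversible, 1)
  expect_equal(s$n_irreversible, 1)
  expect_equal(s$n_zeroed, 0)

  z <- metabolic_model("A", c("r1", "r2"), matrix(c(1, -1), 1, 2),
                       c(0, 0), c(0, 0))
  sz <- reversibility_summary(z)
  expect_equal(sz$n_reversible, 0)
  expect_equal(sz$n_irreversible, 0)
  expect_equal(sz$n_zeroed, 2)
})

test_that("SBML level 3 + fbc import matches the JSON dialect", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">
 <model id="seg">
  <listOfParameters>
   <parameter id="lb0" value="0" constant="true"/>
   <parameter id="ub1" value="1" constant="true"/>
  </listOfParameters>
  <fbc:listOfGeneProducts xmlns="http://www.sbml.org/sbml/level3/version1/fbc/version2">
   <geneProduct fbc:id="g1" fbc:label="P1"/>
   <geneProduct fbc:id="g2" fbc:label="P2"/>
   <geneProduct fbc:id="g3" fbc:label="P3"/>
  </fbc:listOfGeneProducts>
  <listOfSpecies>
   <species id="A" boundaryCondition="false"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="r1" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1">
    <listOfProducts>
     <speciesReference species="A" stoichiometry="1"/>
    </listOfProducts>
    <fbc:geneProductAssociation xmlns="http://www.sbml.org/sbml/level3/version1/fbc/version2">
     <or>
      <and>
       <geneProductRef fbc:geneProduct="g1"/>
       <geneProductRef fbc:geneProduct="g2"/>
      </and>
      <geneProductRef fbc:geneProduct="g3"/>
     </or>
    </fbc:geneProductAssociation>
   </reaction>
   <reaction id="r2" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1">
    <listOfReactants>
     <speciesReference species="A" stoichiometry="1"/>
    </listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- read_model(path, format = "sbml")
  expect_equal(m$metabolite_ids, "A")
  expect_equal(m$reaction_ids, c("r1", "r2"))
  expect_equal(m$S, matrix(c(1, -1), 1, 2))
  expect_equal(m$v_inf, c(0, 0))
  expect_equal(m$v_sup, c(1, 1))
  expect_equal(deparse_gpr(m$gpr[["r1"]]), "P1 AND P2 OR P3")
  ev <- evaluate_gpr(m$gpr[["r1"]], c(P1 = 0.2, P2 = 0.5, P3 = 0.1))
  expect_equal(ev, 0.3)
})

test_that("proteome TSV round-trips", {
  mat <- matrix(c(1.5, 0, 2.25, 3), 2, 2,
                dimnames = list(c("P1", "P2"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_proteome(mat, path)
  expect_equal(read_proteome(path), mat)
})
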