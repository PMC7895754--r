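test_that("native JSON round trip is lossless and byte-stable", {
  net <- ref_network()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_native(net, p1)
  n2 <- read_native(p1)
  expect_identical(species_ids(net), species_ids(n2))
  expect_identical(names(net$reactions), names(n2$reactions))
  expect_equal(parameter_values(net), parameter_values(n2))
  expect_equal(initial_state(net), initial_state(n2))
  expect_length(validate_network(n2), 0)
  write_native(n2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an empty network round-trips through both formats", {
  empty <- network(name = "empty")
  pj <- withr::local_tempfile(fileext = ".json")
  px <- withr::local_tempfile(fileext = ".xml")
  write_native(empty, pj)
  expect_length(species_ids(read_native(pj)), 0)
  write_sbml(empty, px)
  expect_length(validate_sbml_document(px), 0)
  expect_length(species_ids(read_sbml(px)), 0)
})

test_that("SBML round trip preserves content and simulated trajectories", {
  net <- ref_network()
  px <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, px)
  expect_length(validate_sbml_document(px), 0)
  n2 <- read_sbml(px)
  expect_identical(species_ids(net), species_ids(n2))
  expect_equal(parameter_values(net), parameter_values(n2))
  expect_length(validate_network(n2), 0)

  p <- stimulation_protocol(events = dose_event(0, "L_IL10", 10),
                            duration = 8, name = "io")
  st <- ref_state()
  s1 <- simulate_protocol(net, p, state = st)
  s2 <- simulate_protocol(n2, p, state = st[species_ids(n2)])
  expect_lt(max(abs(s1$states - s2$states) / (abs(s1$states) + 1)), 1e-8)

  # full chain: write_native(read_sbml(write_sbml(read_native(...))))
  pj <- withr::local_tempfile(fileext = ".json")
  pj2 <- withr::local_tempfile(fileext = ".json")
  write_native(n2, pj)
  n3 <- read_native(pj)
  expect_equal(parameter_values(net), parameter_values(n3))
  expect_identical(length(net$reactions), length(n3$reactions))
})

test_that("plain foreign SBML with mass-action kinetics is imported", {
  # hand-written minimal SBML (no package annotations)
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
 <model id="mini">
  <listOfCompartments>
   <compartment id="cytoplasm" constant="true"/>
  </listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="cytoplasm" initialAmount="10" constant="false" boundaryCondition="false"/>
   <species id="B" compartment="cytoplasm" initialAmount="0" constant="false" boundaryCondition="false"/>
  </listOfSpecies>
  <listOfParameters>
   <parameter id="k1" value="0.7" constant="true"/>
  </listOfParameters>
  <listOfReactions>
   <reaction id="conv" reversible="false">
    <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><ci>k1</ci><ci>A</ci></apply>
     </math>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', p)
  net <- read_sbml(p)
  expect_length(net$reactions, 1)
  expect_equal(net$reactions[["conv"]]$law$kind, "mass_action")
  expect_equal(parameter_values(net)[["k1"]], 0.7)
  rhs <- build_rhs(net)
  expect_equal(rhs(c(A = 10, B = 0)), c(A = -7, B = 7))
})

test_that("unsupported SBML constructs raise explicit errors", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
 <model id="m">
  <listOfRules>
   <assignmentRule variable="x"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn>1</cn></math></assignmentRule>
  </listOfRules>
 </model>
</sbml>', p)
  expect_error(read_sbml(p), "unsupported SBML construct.*assignmentRule")

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model", bad)
  expect_error(read_sbml(bad), "parse error")
})

test_that("concentration-style species are coerced with a report", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
 <model id="m">
  <listOfSpecies>
   <species id="A" compartment="weird" initialConcentration="5"/>
  </listOfSpecies>
 </model>
</sbml>', p)
  net <- read_sbml(p)
  expect_equal(initial_state(net)[["A"]], 5)
  report <- attr(net, "import_report")
  expect_true(any(grepl("initialConcentration", report)))
  expect_true(any(grepl("compartment", report)))
})
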