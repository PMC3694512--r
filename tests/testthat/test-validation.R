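shipped <- shipped_constraint_docs()
bp_arch <- shipped[[1]]
bp_tmpl <- shipped[[2]]

test_that("reference-model validation reports structural problems as findings", {
  expect_true(is_valid(validate_rm(make_bp_composition(120, 80))))
  # both children and a leaf (constructed past the constructor's guard)
  broken <- make_bp_composition(120, 80)
  broken$value <- leaf_text("oops")
  rep <- validate_rm(broken)
  expect_false(is_valid(rep))
  expect_true(any(grepl("both children and a leaf", vapply(rep$findings, `[[`, character(1), "message"))))
  # non-numeric magnitude
  q <- rm_node("value", value = leaf_quantity(1, "mm[Hg]"))
  q$value$magnitude <- "high"
  rep2 <- validate_rm(rm_node("composition", children = list(q)))
  expect_false(is_valid(rep2))
  expect_equal(rep2$findings[[1]]$level, "rm")
  # unparseable timestamp
  t <- rm_node("time", value = leaf_timestamp("not-a-time"))
  expect_false(is_valid(validate_rm(rm_node("composition", children = list(t)))))
  # archetype ids are collected for the trigger workaround
  expect_setequal(validate_rm(make_bp_composition(1, 2))$archetype_ids,
                  c("openEHR-EHR-COMPOSITION.encounter.v1",
                    "openEHR-EHR-SECTION.vital_signs.v1",
                    "openEHR-EHR-OBSERVATION.blood_pressure.v1"))
})

test_that("constraint validation checks occurrences, ranges, units and codes", {
  comp <- make_bp_composition(120, 80)
  expect_true(is_valid(validate_against(comp, bp_arch)))
  # magnitude outside the range: finding at that path
  high <- make_bp_composition(1500, 80)
  rep <- validate_against(high, bp_arch)
  expect_false(is_valid(rep))
  expect_match(rep$findings[[1]]$path, "items\\[at0004\\]/value$")
  expect_equal(rep$findings[[1]]$level, "archetype")
  # occurrences 0 under min 1
  no_ctx <- comp
  no_ctx$children <- comp$children[-1]   # drop /context
  rep2 <- validate_against(no_ctx, bp_arch)
  expect_false(is_valid(rep2))
  expect_true(any(grepl("below minimum", vapply(rep2$findings, `[[`, character(1), "message"))))
  # wrong units
  wrong_units <- make_bp_composition(120, 80)
  doc <- constraint_doc("t.v1", "archetype", root = list(name = "composition"),
                        nodes = list(constraint_node(
                          sub("/magnitude$", "", bp_systolic_path()),
                          min = 1, max = 1, value_kind = "quantity", units = "kPa")))
  expect_false(is_valid(validate_against(wrong_units, doc)))
  # code sets
  coded <- rm_node("composition", children = list(
    rm_node("category", value = leaf_coded_text("433", "openehr", "event"))))
  cdoc <- constraint_doc("c.v1", "archetype", root = list(name = "composition"),
                         nodes = list(constraint_node("/category", min = 1, max = 1,
                                                      value_kind = "coded_text",
                                                      allowed_codes = c("431", "432"))))
  rep3 <- validate_against(coded, cdoc)
  expect_false(is_valid(rep3))
  expect_match(rep3$findings[[1]]$message, "not in allowed set")
})

test_that("a document valid under the archetype may still violate the template", {
  # systolic 350 is inside the permissive archetype range but outside the
  # template's narrowed range; diastolic present so only the range differs
  comp <- make_bp_composition(350, 80)
  expect_true(is_valid(validate_against(comp, bp_arch)))
  rep <- validate_against(comp, bp_tmpl)
  expect_false(is_valid(rep))
  expect_true(all(vapply(rep$findings, `[[`, character(1), "level") == "template"))
})

test_that("the shipped template narrows its archetype; widening is detected", {
  expect_length(verify_narrowing(bp_tmpl, bp_arch), 0L)
  widened <- bp_tmpl
  widened$nodes[[10]]$range <- c(0, 2000)   # wider than the archetype's
  expect_gt(length(verify_narrowing(widened, bp_arch)), 0L)
  relaxed <- bp_tmpl
  relaxed$nodes[[1]]$min <- 0L
  expect_gt(length(verify_narrowing(relaxed, bp_arch)), 0L)
})

test_that("template acceptance implies archetype acceptance on randomized documents", {
  set.seed(61)
  n_accepted <- 0L; violations <- character(0)
  for (i in 1:60) {
    sys_v <- round(stats::runif(1, 0, 400), 1)
    dia_v <- round(stats::runif(1, 0, 250), 1)
    comp <- make_bp_composition(sys_v, dia_v)
    if (stats::runif(1) < 0.2) comp$children <- comp$children[-1]  # sometimes drop context
    if (is_valid(validate_against(comp, bp_tmpl))) {
      n_accepted <- n_accepted + 1L
      if (!is_valid(validate_against(comp, bp_arch))) {
        violations <- c(violations, sprintf("sys=%s dia=%s", sys_v, dia_v))
      }
    }
  }
  expect_length(violations, 0L)
  expect_gt(n_accepted, 0L)      # the sample exercises the implication
  expect_lt(n_accepted, 60L)     # ... and also contains template-invalid cases
})

test_that("skeletons follow the min/max strategies and validate against their doc", {
  sk_min <- build_skeleton(bp_tmpl, "min")
  sk_max <- build_skeleton(bp_tmpl, "max")
  expect_true(is_valid(validate_against(sk_min, bp_tmpl)))
  expect_true(is_valid(validate_against(sk_max, bp_tmpl)))
  expect_true(is_valid(validate_rm(sk_min)))
  expect_true(is_valid(validate_rm(sk_max)))
  n_min <- length(resolve_path(sk_min, sub("/data\\[at0001\\].*$", "", bp_systolic_path())))
  n_max <- length(resolve_path(sk_max, sub("/data\\[at0001\\].*$", "", bp_systolic_path())))
  expect_lte(n_min, n_max)
  # the archetype leaves the diastolic item optional: absent under min
  arch_min <- build_skeleton(bp_arch, "min")
  expect_length(resolve_path_values(arch_min, bp_diastolic_path()), 0L)
  expect_true(is_valid(validate_against(arch_min, bp_arch)))
})

test_that("range-constrained numeric leaves default to the range midpoint", {
  doc <- constraint_doc("mid.v1", "archetype", root = list(name = "composition"),
                        nodes = list(
                          constraint_node("/items", min = 1, max = 1),
                          constraint_node("/items/value", min = 1, max = 1,
                                          value_kind = "quantity",
                                          range = c(90, 200), units = "mm[Hg]")))
  sk <- build_skeleton(doc, "min")
  v <- resolve_path_values(sk, "/items/value")[[1]]
  expect_equal(v$magnitude, 145)
  expect_gte(v$magnitude, 90); expect_lte(v$magnitude, 200)
  # an explicit default wins over the midpoint
  doc2 <- doc
  doc2$nodes[[2]]$default <- 120
  expect_equal(resolve_path_values(build_skeleton(doc2, "min"), "/items/value")[[1]]$magnitude, 120)
})

test_that("constraint documents round-trip through their JSON file format", {
  path <- tempfile(fileext = ".json")
  write_constraint_doc(bp_tmpl, path)
  back <- read_constraint_doc(path)
  expect_identical(back$id, bp_tmpl$id)
  expect_identical(back$kind, bp_tmpl$kind)
  expect_identical(back$bases, bp_tmpl$bases)
  expect_equal(length(back$nodes), length(bp_tmpl$nodes))
  for (i in seq_along(back$nodes)) {
    expect_identical(back$nodes[[i]]$path, bp_tmpl$nodes[[i]]$path)
    expect_equal(back$nodes[[i]]$min, bp_tmpl$nodes[[i]]$min)
    expect_equal(back$nodes[[i]]$max, bp_tmpl$nodes[[i]]$max)
    expect_equal(back$nodes[[i]]$range, bp_tmpl$nodes[[i]]$range)
  }
  # unsatisfiable constraints are refused
  # a mandatory child under a prohibited parent cannot be satisfied
  impossible <- constraint_doc("x.v1", "archetype", root = list(name = "c"),
                               nodes = list(constraint_node("/a", min = 0, max = 0),
                                            constraint_node("/a/b", min = 1, max = 1)))
  expect_error(build_skeleton(impossible, "min"), class = "ehrest_bad_request")
})
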