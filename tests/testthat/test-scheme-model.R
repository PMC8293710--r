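test_that("the template scheme is minimal, well-formed and deterministic", {
  s <- new_template_scheme("dmdScheme", "0.9.9")
  expect_s3_class(s, "md_scheme")
  expect_identical(scheme_id(s), "dmdScheme_0.9.9")
  expect_length(s$property_sets, 1L)
  expect_identical(s$property_sets[[1]]$name, "Metadata")
  expect_length(s$property_sets[[1]]$properties, 3L)
  expect_true(all(vapply(s$property_sets[[1]]$properties, `[[`, TRUE, "required")))
  expect_identical(nrow(check_scheme_definition(s)), 0L)
  expect_identical(s, new_template_scheme("dmdScheme", "0.9.9"))
})

test_that("invalid scheme identifiers are rejected at construction", {
  expect_error(new_template_scheme("", "1.0.0"), class = "mds_definition_error")
  expect_error(new_template_scheme("x", "not.a.version"), class = "mds_definition_error")
  expect_error(new_template_scheme("x", "1.0"), class = "mds_definition_error")
})

test_that("check_scheme_definition reports each broken invariant once", {
  base <- new_template_scheme()

  both <- add_property(base, "Metadata",
    md_property("Method", allowed = c("a"), suggested = c("b")))
  probs <- check_scheme_definition(both)
  expect_identical(nrow(probs), 1L)
  expect_identical(probs$rule, "both-vocabularies")
  expect_identical(probs$property, "Method")

  dangling <- add_property(base, "Metadata",
    md_property("Ref", refers_to = c("Nowhere", "Nothing")))
  probs <- check_scheme_definition(dangling)
  expect_identical(nrow(probs), 1L)
  expect_identical(probs$rule, "dangling-refers-to")

  cases <- list(
    list(p = md_property("Bad", "integer", min_value = 5, max_value = 1),
         rule = "range-order"),
    list(p = md_property("Bad", "character", min_value = 0, max_value = 1),
         rule = "range-type"),
    list(p = md_property("Bad", "integer", allowed = c("1", "x")),
         rule = "vocabulary-type"),
    list(p = md_property("has space"), rule = "property-name"),
    list(p = md_property("Bad", "colour"), rule = "property-type")
  )
  for (case in cases) {
    probs <- check_scheme_definition(add_property(base, "Metadata", case$p))
    expect_true(case$rule %in% probs$rule, label = case$rule)
  }
})

test_that("value types parse strictly", {
  ok <- list(integer = c("0", "42", "-7", "+3"), real = c("1.5", "-0.2", "1e3", ".5"),
             logical = c("TRUE", "false"), date = c("2021-06-25"),
             character = c("anything at all"))
  bad <- list(integer = c("3.7", "x", "1e3"), real = c("abc", "1,5", "TRUE"),
              logical = c("yes", "0"), date = c("2021-13-01", "21-06-25", "2021/06/25"))
  for (type in names(ok))
    for (v in ok[[type]])
      expect_true(mdscheme:::type_ok(v, type), label = paste(type, v))
  for (type in names(bad))
    for (v in bad[[type]])
      expect_false(mdscheme:::type_ok(v, type), label = paste(type, v))
})

test_that("scheme editing has value semantics and add/remove round-trips", {
  s <- new_template_scheme()
  s_orig <- s
  species <- md_property_set("Species", properties = list(
    md_property("SpeciesName", required = TRUE)))
  s2 <- add_property_set(s, species)
  expect_identical(s, s_orig)
  expect_length(s2$property_sets, 2L)
  expect_identical(remove_property_set(s2, "Species"), s)

  expect_error(add_property_set(s2, species), class = "mds_definition_error")
  expect_error(add_property(s, "Nowhere", md_property("X")),
               class = "mds_definition_error")
  expect_error(add_property(s2, "Species", md_property("SpeciesName")),
               class = "mds_definition_error")
  expect_error(remove_property_set(s, "Nowhere"), class = "mds_definition_error")
})

test_that("the JSON manifest round-trips schemes exactly", {
  for (s in list(new_template_scheme(), make_example_scheme(), tiny_scheme())) {
    path <- tempfile(fileext = ".json")
    write_scheme_json(s, path)
    expect_identical(read_scheme_json(path), s)
  }
  expect_error(read_scheme_json(tempfile()), class = "mds_io_error")
  bad <- tempfile(fileext = ".json")
  writeLines('{"not": "a scheme"}', bad)
  expect_error(read_scheme_json(bad), class = "mds_format_error")
})

test_that("semantic versions compare numerically fieldwise", {
  expect_identical(mdscheme:::semver_compare("1.1.7", "0.9.9"), 1L)
  expect_identical(mdscheme:::semver_compare("0.9.9", "0.10.0"), -1L)
  expect_identical(mdscheme:::semver_compare("2.0.0", "2.0.0"), 0L)
  expect_identical(mdscheme:::semver_compare("1.0.0-rc1", "1.0.0"), -1L)
  expect_null(mdscheme:::parse_semver("1.2"))
})
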