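test_that("sequence enumeration gives k^n specs in lexicographic order", {
  expect_length(enumerate_sequences(3), 8)
  expect_length(enumerate_sequences(1, "AB3"), 1)
  expect_equal(sum(vapply(1:3, function(g)
    length(enumerate_sequences(g)), integer(1))), 14)

  names2 <- vapply(enumerate_sequences(2, terminal_form = "ammonium"),
                   dendrimer_name, "")
  expect_identical(names2, c("G2-3-3-N", "G2-3-6-N", "G2-6-3-N", "G2-6-6-N"))

  expect_error(enumerate_sequences(0), "positive integer")
  expect_error(enumerate_sequences(2, character(0)), "non-empty")
})

test_that("peripheral group counts follow the branching calculus", {
  expect_equal(peripheral_group_count(parse_dendrimer_name("G3-6-6-6-N")), 864)
  expect_equal(peripheral_group_count(parse_dendrimer_name("G3-3-3-3-A")), 108)
  expect_equal(peripheral_group_count(parse_dendrimer_name("G2-6-6-N")), 144)
  expect_equal(peripheral_group_count(parse_dendrimer_name("G2-3-3-N")), 36)
  expect_equal(peripheral_group_count(dendrimer_spec()), 4)  # bare core

  # multiplicativity: appending a layer multiplies the count
  for (nm in all_14_names()) {
    sp <- parse_dendrimer_name(nm)
    tokens <- vapply(sp$layers, `[[`, "", "token")
    child <- parse_dendrimer_name(
      paste(c(paste0("G", length(tokens) + 1), tokens, "6", "N"),
            collapse = "-"))
    expect_equal(peripheral_group_count(child),
                 6 * peripheral_group_count(sp))
  }

  # the same calculus covers other dendrimer families: tetravalent core
  # with two 2-fold layers gives the familiar 16-end-group G2 pattern
  reg <- default_registry()
  reg$B2 <- building_block("B2", "branch", "C4H9N3", 2,
                           coupling_delta = "H2O", token = "2")
  expect_equal(peripheral_group_count(
    dendrimer_spec(c("B2", "B2"), registry = reg)), 16)
})

test_that("peripheral-group class histogram follows Pascal's triangle", {
  h3 <- pg_class_histogram(3)
  expect_identical(h3, c(`108` = 1L, `216` = 3L, `432` = 3L, `864` = 1L))
  expect_identical(pg_class_histogram(1), c(`12` = 1L, `24` = 1L))
  # one block collapses the triangle to a single class
  expect_identical(pg_class_histogram(2, "AB6"), c(`144` = 1L))
  # sum over classes = k^n; k = 2 multiplicities are binomial coefficients
  for (g in 1:4) {
    h <- pg_class_histogram(g)
    expect_equal(sum(h), 2^g)
    expect_equal(as.integer(h), choose(g, 0:g))
  }
})

test_that("compositions match brute-force atom bookkeeping on all 14 analogs", {
  for (form in c("A", "N")) {
    for (nm in all_14_names(form)) {
      sp <- parse_dendrimer_name(nm)
      tokens <- vapply(sp$layers, `[[`, "", "token")
      expect_composition_equal(elemental_composition(sp),
                               brute_force_composition(tokens, form))
    }
  }
})

test_that("printed molecular weights are reproduced", {
  expect_lt(abs(average_mass(parse_dendrimer_name("G2-3-6-N")) - 17107), 1)
  # generation-3 bounds of the 2^3 family, in kDa
  expect_gte(average_mass(parse_dendrimer_name("G3-3-3-3-N")) / 1000, 32)
  expect_gte(average_mass(parse_dendrimer_name("G3-6-6-6-N")) / 1000, 200)
  # MW ratio of the G1 allyl dendrimer to its activated-ester module
  reg <- default_registry()
  ratio <- average_mass(parse_dendrimer_name("G1-3-A")) /
    average_mass(reg$`BtO-AB3`)
  expect_equal(round(ratio, 1), 3.9)
})

test_that("ammonium and allyl forms differ by exactly one cap per end group", {
  cap_mass <- average_mass(default_registry()$CA$composition)
  for (nm in all_14_names("A")) {
    sp_a <- parse_dendrimer_name(nm)
    sp_n <- parse_dendrimer_name(sub("-A$", "-N", nm))
    expect_equal(average_mass(sp_n) - average_mass(sp_a),
                 peripheral_group_count(sp_a) * cap_mass)
  }
})

test_that("mass additivity links each spec to its generation n-1 parent", {
  reg <- default_registry()
  delta_mass <- average_mass(reg$AB6) -
    average_mass(reg$AB6$coupling_delta)
  for (nm in all_14_names("N")) {
    sp <- parse_dendrimer_name(nm)
    tokens <- vapply(sp$layers, `[[`, "", "token")
    child <- parse_dendrimer_name(
      paste(c(paste0("G", length(tokens) + 1), tokens, "6", "N"),
            collapse = "-"))
    n_parent <- peripheral_group_count(sp)
    # child(N) = parent(N) + one block per parent end group (net of the
    # amide coupling loss) + one cap per new end group
    expect_equal(average_mass(child),
                 average_mass(sp) + n_parent * delta_mass +
                   peripheral_group_count(child) *
                   average_mass(reg$CA$composition))
  }
})

test_that("names round-trip and malformed names fail with a position", {
  for (form in c("A", "N")) {
    for (nm in all_14_names(form)) {
      sp <- parse_dendrimer_name(nm)
      expect_identical(dendrimer_name(sp), nm)
      expect_identical(dendrimer_name(parse_dendrimer_name(dendrimer_name(sp))),
                       nm)
    }
  }
  expect_error(parse_dendrimer_name("X2-3-6-N"), "position 1")
  expect_error(parse_dendrimer_name("G2-3-6-Q"), "position 4")
  expect_error(parse_dendrimer_name("G2-3-N"), "position 2")
  expect_error(parse_dendrimer_name("G1-9-N"), "unknown layer token")
})

test_that("registry round-trips through YAML and JSON", {
  reg <- default_registry()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_registry(reg, path)
    back <- read_registry(path)
    expect_identical(names(back), names(reg))
    for (nm in names(reg)) {
      expect_identical(format(back[[nm]]$composition),
                       format(reg[[nm]]$composition))
      expect_identical(back[[nm]]$multiplicity, reg[[nm]]$multiplicity)
      expect_identical(back[[nm]]$token, reg[[nm]]$token)
      expect_identical(format(back[[nm]]$coupling_delta),
                       format(reg[[nm]]$coupling_delta))
    }
    # a parsed spec built from the reread registry gives identical masses
    expect_equal(average_mass(parse_dendrimer_name("G2-3-6-N", registry = back)),
                 average_mass(parse_dendrimer_name("G2-3-6-N")))
  }
  expect_error(read_registry(withr::local_tempfile()), "not found")
})
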