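test_that("descriptor table write-then-read round trip is exact, including missing cells", {
  m <- make_dm(n = 5, p = 4, seed = 42)
  m$values[2, 3] <- NA
  m$compounds$role <- c("training", "training", "training", "test", "test")
  csv <- tempfile(fileext = ".csv")
  side <- tempfile(fileext = ".json")
  write_descriptor_table(m, csv, sidecar = side)
  m2 <- read_descriptor_table(csv, sidecar = side)
  expect_identical(m2$values, m$values)
  expect_identical(m2$descriptors, m$descriptors)
  expect_identical(m2$compounds$role, m$compounds$role)
  expect_identical(attr(m2, "parse_report")$n_unparseable, 0L)
  # tab-delimited round trip too
  tsv <- tempfile(fileext = ".tsv")
  write_descriptor_table(m, tsv, sidecar = side)
  expect_identical(read_descriptor_table(tsv, sidecar = side)$values, m$values)
})

test_that("unparseable and blank cells become missing and are counted", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,d1,d2", "a,1.5,", "b,oops,3", "c,2,4"), csv)
  m <- read_descriptor_table(csv, dclass = "topological")
  expect_equal(sum(is.na(m$values)), 2)
  rep <- attr(m, "parse_report")
  expect_equal(rep$n_unparseable, 2)
  expect_setequal(rep$unparseable_cells$id, c("a", "b"))
  # the designated NA marker is missing but not unparseable
  writeLines(c("compound_id,d1,d2", "a,1.5,NA", "b,2,3"), csv)
  m2 <- read_descriptor_table(csv, dclass = "topological")
  expect_equal(sum(is.na(m2$values)), 1)
  expect_equal(attr(m2, "parse_report")$n_unparseable, 0)
})

test_that("duplicate compound ids or descriptor names are hard errors", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,d1,d2", "a,1,2", "a,3,4"), csv)
  expect_error(read_descriptor_table(csv, dclass = "topological"), "duplicate compound id")
  writeLines(c("compound_id,d1,d1", "a,1,2", "b,3,4"), csv)
  expect_error(read_descriptor_table(csv, dclass = "topological"), "duplicate descriptor name")
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(descriptor_matrix(v, "topological"), "duplicate compound id")
})

test_that("the descriptor catalogue has 26 uniquely named descriptors in the printed class counts", {
  cat26 <- load_descriptor_catalogue()
  expect_equal(nrow(cat26), 26)
  expect_false(anyDuplicated(cat26$name) > 0)
  counts <- table(cat26$dclass)
  expect_equal(unname(counts["constitutional"]), 8, ignore_attr = TRUE)
  expect_equal(unname(counts["thermodynamic"]), 3, ignore_attr = TRUE)
  expect_equal(unname(counts["electrostatic"]), 3, ignore_attr = TRUE)
  expect_equal(unname(counts["quantum_chemical"]), 12, ignore_attr = TRUE)
  # the catalogue round-trips through the descriptor_matrix constructor
  v <- matrix(rnorm(3 * 26), 3, 26,
              dimnames = list(c("a", "b", "c"), cat26$name))
  m <- descriptor_matrix(v, dclass = cat26$dclass)
  expect_equal(m$descriptors$dclass, cat26$dclass)
})

test_that("percent_uptake matches the printed integer percents and rounds half up", {
  expect_identical(percent_uptake(29.64, 23.71), 125L)
  expect_identical(percent_uptake(23.58, 25.92), 91L)
  expect_identical(percent_uptake(23.71, 23.71), 100L)
  # round-half-up, not banker's rounding
  expect_identical(percent_uptake(2.5, 100), 3L)
  expect_identical(percent_uptake(1.5, 100), 2L)
  expect_error(percent_uptake(-1, 10), "positive")
  expect_error(percent_uptake(10, 0), "positive")
})

test_that("apparent permeability follows Papp = (dQ/dt)/(A * D0)", {
  expect_equal(apparent_permeability(1, 1, 1), 1)
  expect_equal(apparent_permeability(2, 4, 0.5), 1)
  # homogeneity: doubling D0 halves Papp
  expect_equal(apparent_permeability(3, 2, 2), apparent_permeability(3, 2, 1) / 2)
  expect_error(apparent_permeability(1, 0, 1), "positive")
  expect_error(apparent_permeability(1, 1, 0), "positive")
})

test_that("the bundled uptake dataset has 18 training and 7 test sets across 3 polymorphs", {
  fx <- load_uptake_fixture()
  expect_named(fx$responses, c("482R", "482G", "482T"))
  expect_equal(sum(fx$compounds$role == "training"), 18)
  expect_equal(sum(fx$compounds$role == "test"), 7)
  for (r in fx$responses) expect_equal(nrow(r), 25)
  expect_false(anyDuplicated(fx$compounds$id) > 0)
  expect_true("ketoconazole_test" %in% fx$compounds$id)
  # control row: 100% of itself in all three polymorphs
  for (r in fx$responses)
    expect_identical(r$percent_recomputed[r$compound_id == "mitoxantrone"], 100L)
})

test_that("inconsistent printed percents are flagged verbatim, consistent ones are not", {
  fx <- load_uptake_fixture()
  flagged <- do.call(rbind, lapply(names(fx$responses), function(p) {
    r <- fx$responses[[p]]
    ids <- r$compound_id[r$inconsistent]
    data.frame(id = ids, polymorph = rep(p, length(ids)))
  }))
  # exactly the three cells whose printed percent cannot be recomputed
  expect_equal(nrow(flagged), 3)
  expect_true(any(flagged$id == "fumitremorginc" & flagged$polymorph == "482R"))
  expect_true(any(flagged$id == "epinephrine" & flagged$polymorph == "482T"))
  expect_true(any(flagged$id == "caffeine" & flagged$polymorph == "482T"))
  # spot checks: the flagged row keeps the printed value; a clean row agrees
  r482R <- fx$responses[["482R"]]
  expect_equal(r482R$percent[r482R$compound_id == "fumitremorginc"], 305)
  cipro <- r482R[r482R$compound_id == "ciprofloxacin", ]
  expect_false(cipro$inconsistent)
  expect_equal(cipro$percent, percent_uptake(57.38, 23.71))
})

test_that("split_train_test partitions the compounds without loss or duplication", {
  fx <- load_uptake_fixture()
  m <- make_dm(n = 25, p = 5, seed = 3)
  rownames(m$values) <- fx$compounds$id
  m$compounds$id <- fx$compounds$id
  sp <- split_train_test(m, fx$assignment)
  expect_equal(nrow(sp$training$values), 18)
  expect_equal(nrow(sp$test$values), 7)
  expect_setequal(c(sp$training$compounds$id, sp$test$compounds$id), m$compounds$id)
  expect_length(intersect(sp$training$compounds$id, sp$test$compounds$id), 0)
  expect_identical(sp$training$descriptors, sp$test$descriptors)
  # degenerate split: everything training
  all_tr <- split_train_test(m, setNames(rep("training", 25), m$compounds$id))
  expect_equal(nrow(all_tr$test$values), 0)
  expect_equal(nrow(all_tr$training$values), 25)
  # missing role is an error
  bad <- fx$assignment[-1]
  expect_error(split_train_test(m, bad), "no train/test role")
})
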