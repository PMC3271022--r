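# Structural model validation and identifiability rules.

test_that("model construction enforces structural invariants", {
  expect_error(gm_model(c("A", "A"), list(gm_process("p", "gain", "A"))),
               "unique")
  expect_error(gm_model("A", list(gm_process("p", "gain", "B"))),
               "unknown variable")
  expect_error(gm_process("p", "gain", "A", depends_on = "A",
                          assumptions = list(B = "linear")),
               "not in depends_on")
  # more than one unconstrained dependency is rejected outright
  expect_error(gm_process("p", "gain", "A", depends_on = c("A", "B"),
                          observability = "observed", assumptions = list()),
               class = "gm_identifiability_error")
})

test_that("the packaged scenario models pass identifiability", {
  expect_true(validate_identifiability(allee_model(), "births")$pass)
  expect_true(validate_identifiability(fishery_model(), "catch")$pass)
  expect_true(validate_identifiability(food_chain_model(), "top_mortality")$pass)
})

test_that("removing the observed channel violates the balance rule", {
  rep <- validate_identifiability(allee_model(), character())
  expect_false(rep$pass)
  expect_true(any(grepl("rule \\(a\\)", rep$failures)))
})

test_that("a two-variable process without assumptions violates rule (b)", {
  m <- gm_model(
    c("A", "B"),
    list(gm_process("flux", "gain", "A", depends_on = c("A", "B"),
                    observability = "observed",
                    assumptions = list(A = "free", B = "linear")),
         gm_process("loss", "loss", "A", depends_on = "A",
                    observability = "inferred_by_balance",
                    assumptions = list(A = "linear")),
         gm_process("growth", "gain", "B", depends_on = "B",
                    observability = "observed",
                    assumptions = list(B = "free"))))
  m$processes$flux$assumptions <- list() # strip assumptions post hoc
  rep <- validate_identifiability(m, c("flux", "growth"))
  expect_false(rep$pass)
  expect_true(any(grepl("rule \\(b\\)", rep$failures)))
})

test_that("known-form processes must reference declared constants", {
  m <- fishery_model()
  m$known_constants$mP <- NULL
  rep <- validate_identifiability(m, "catch")
  expect_false(rep$pass)
  expect_true(any(grepl("rule \\(c\\).*mP", rep$failures)))
})

test_that("two inferred processes in one balance violate rule (a)", {
  m <- gm_model(
    "A",
    list(gm_process("in1", "gain", "A", depends_on = "A",
                    observability = "inferred_by_balance",
                    assumptions = list(A = "linear")),
         gm_process("in2", "loss", "A", depends_on = "A",
                    observability = "inferred_by_balance",
                    assumptions = list(A = "linear"))))
  rep <- validate_identifiability(m, character())
  expect_false(rep$pass)
  expect_true(any(grepl("rule \\(a\\).*at most one", rep$failures)))
})

test_that("model files round-trip losslessly through YAML", {
  for (m in list(allee_model(), fishery_model(), food_chain_model())) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_model(m, path)
    m2 <- read_model(path)
    expect_identical(m2$variables, m$variables)
    expect_identical(m2$time_mode, m$time_mode)
    expect_equal(m2$known_constants, m$known_constants)
    expect_identical(names(m2$processes), names(m$processes))
    for (nm in names(m$processes)) {
      expect_equal(m2$processes[[nm]][c("sign", "target", "depends_on", "observability",
                                        "assumptions", "drifting", "form")],
                   m$processes[[nm]][c("sign", "target", "depends_on", "observability",
                                       "assumptions", "drifting", "form")])
    }
  }
})

test_that("the shipped model files are valid and identifiable", {
  files <- c(allee = "allee_model.yaml", fishery = "fishery_model.yaml",
             food_chain = "food_chain_model.yaml")
  channels <- list(allee = "births", fishery = "catch",
                   food_chain = "top_mortality")
  for (nm in names(files)) {
    path <- system.file("extdata", files[[nm]], package = "gmews")
    expect_true(nzchar(path))
    m <- read_model(path)
    expect_true(validate_identifiability(m, channels[[nm]])$pass)
  }
})
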