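test_that("registry registers, retrieves and round-trips through config", {
  reg <- model_registry()
  m <- make_simple_model()
  reg <- register_model(reg, m)
  expect_equal(list_models(reg), "simple")
  expect_equal(get_model(reg, "simple")$baseline_survival, 0.95)

  # lossless config round-trip (YAML and JSON)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model_registry(reg, path)
    reg2 <- load_model_registry(path)
    expect_equal(unclass(get_model(reg2, "simple")),
                 unclass(get_model(reg, "simple")))
  }

  expect_error(register_model(reg, m), class = "cvrm_registration_error")
})

test_that("definition invariants are enforced at construction", {
  expect_error(make_simple_model(baseline_survival = 1.2),
               class = "cvrm_schema_error")
  expect_error(make_simple_model(baseline_survival = 0),
               class = "cvrm_schema_error")
  expect_error(
    risk_model("bad", list(list(field = "shoe_size", transform = "identity",
                                coefficient = 1)),
               baseline_survival = 0.9),
    class = "cvrm_schema_error")
  expect_error(
    risk_model("bad", list(list(field = "sbp", transform = "sqrt",
                                coefficient = 1)),
               baseline_survival = 0.9),
    class = "cvrm_schema_error")
  expect_error(
    risk_model("bad",
               list(list(field = "sbp", transform = "identity",
                         coefficient = 1)),
               baseline_survival = 0.9, required_fields = "age"),
    class = "cvrm_schema_error")
})

test_that("the shipped registry carries the four model slots", {
  reg <- default_model_registry()
  expect_setequal(list_models(reg),
                  c("heart_score", "smart", "advance", "elderly"))
  for (id in list_models(reg)) {
    m <- get_model(reg, id)
    expect_equal(m$horizon, 10)
    expect_gt(m$baseline_survival, 0)
    expect_lt(m$baseline_survival, 1)
    expect_true(nzchar(m$citation))
  }
})

test_that("linear predictor follows the declared transforms", {
  profile <- make_profile(age = 70, sbp = 160)

  # hand arithmetic: 0.05 * (70 - 60) + 0.01 * (160 - 140) = 0.7
  m <- make_simple_model()
  expect_equal(linear_predictor(profile, m), 0.7, tolerance = 1e-15)

  # all-zero coefficients give LP = 0
  m0 <- make_simple_model(coefficients = c(age = 0, sbp = 0))
  expect_equal(linear_predictor(profile, m0), 0)

  # indicator on smoking contributes its coefficient only for the level
  mi <- risk_model("smoke",
                   list(list(field = "smoking", transform = "indicator",
                             level = "current", coefficient = 0.6)),
                   baseline_survival = 0.9)
  expect_equal(linear_predictor(make_profile(smoking = "current"), mi), 0.6)
  expect_equal(linear_predictor(make_profile(smoking = "never"), mi), 0)

  # log transform
  ml <- risk_model("crp",
                   list(list(field = "hscrp", transform = "log",
                             coefficient = 2)),
                   baseline_survival = 0.9)
  expect_equal(linear_predictor(make_profile(hscrp = exp(1)), ml), 2)
})

test_that("a missing required field is an error listing the fields", {
  profile <- make_profile(sbp = NULL)
  err <- tryCatch(linear_predictor(profile, make_simple_model()),
                  error = identity)
  expect_s3_class(err, "cvrm_missing_data_error")
  expect_equal(err$fields, "sbp")
})

test_that("ten-year risk follows the Cox closed form", {
  # centered patient: LP = mean LP, S0 = 0.90 -> risk = 0.10
  m <- make_simple_model(baseline_survival = 0.90, mean_linear_predictor = 0)
  centered <- make_profile(age = 60, sbp = 140)
  expect_equal(ten_year_risk(centered, m)$risk, 0.10, tolerance = 1e-15)

  # S0 = 0.95, LP - mean = 0.7 -> 1 - 0.95^exp(0.7) = 0.09813...
  m2 <- make_simple_model(baseline_survival = 0.95)
  est <- ten_year_risk(make_profile(age = 70, sbp = 160), m2)
  expect_equal(est$risk, 1 - 0.95 ^ exp(0.7), tolerance = 1e-15)
  expect_equal(round(est$risk, 4), 0.0981)
  expect_equal(est$linear_predictor, 0.7)

  # S0 -> 1 with finite LP drives risk -> 0
  m3 <- make_simple_model(baseline_survival = 1 - 1e-12)
  expect_lt(ten_year_risk(make_profile(age = 70, sbp = 160), m3)$risk, 1e-10)
})

test_that("engine risk matches a Cox model fitted with the survival package", {
  skip_if_not_installed("survival")
  # fit a Cox model on simulated data, express it as a declarative
  # definition, and compare engine risk with survival's own survfit
  # prediction at the horizon
  withr::local_seed(42)
  n <- 4000
  age <- runif(n, 40, 80)
  sbp <- runif(n, 110, 180)
  lp_true <- 0.04 * (age - 60) + 0.015 * (sbp - 140)
  t_event <- rexp(n, rate = 0.01 * exp(lp_true))
  t_obs <- pmin(t_event, 10)
  status <- as.integer(t_event <= 10)
  fit <- survival::coxph(survival::Surv(t_obs, status) ~ I(age - 60) +
                           I(sbp - 140))
  sf <- survival::survfit(fit, newdata = data.frame(age = 60, sbp = 140))
  s0 <- summary(sf, times = 10)$surv

  def <- risk_model(
    "cox_check",
    predictors = list(
      list(field = "age", transform = "centered", reference = 60,
           coefficient = unname(fit$coefficients[1])),
      list(field = "sbp", transform = "centered", reference = 140,
           coefficient = unname(fit$coefficients[2]))
    ),
    baseline_survival = s0,
    mean_linear_predictor = 0
  )
  for (case in list(c(50, 120), c(65, 150), c(79, 175))) {
    prof <- make_profile(age = case[1], sbp = case[2])
    sf_i <- survival::survfit(fit, newdata = data.frame(age = case[1],
                                                        sbp = case[2]))
    surv_risk <- 1 - summary(sf_i, times = 10)$surv
    expect_equal(ten_year_risk(prof, def)$risk, surv_risk,
                 tolerance = 1e-6)
  }
})

test_that("risk stays in (0,1) and is monotone in positive-coefficient predictors", {
  withr::local_seed(11)
  for (i in 1:200) {
    s0 <- runif(1, 0.05, 0.99)
    # coefficient scale keeps the centered LP within the clinical range,
    # so the strict (0,1) bound is meaningful in floating point too
    coefs <- c(age = runif(1, 0, 0.05), sbp = runif(1, 0, 0.02))
    m <- make_simple_model(baseline_survival = s0,
                           mean_linear_predictor = runif(1, -1, 1),
                           coefficients = coefs)
    age <- runif(1, 30, 90); sbp <- runif(1, 90, 200)
    r1 <- ten_year_risk(make_profile(age = age, sbp = sbp), m)$risk
    r2 <- ten_year_risk(make_profile(age = age + runif(1, 0, 15),
                                     sbp = sbp), m)$risk
    expect_gt(r1, 0); expect_lt(r1, 1)
    expect_gte(r2, r1)
  }
})

test_that("imputed fields propagate into the risk estimate", {
  profile <- make_profile(sbp = NULL)
  cohort <- list(make_profile(sbp = 120), make_profile(sbp = 160))
  imp <- fit_imputation_model(cohort, fields = "sbp")
  profile <- impute(profile, imp, fields_needed = "sbp")
  est <- ten_year_risk(profile, make_simple_model())
  expect_equal(est$fields_imputed, "sbp")
  expect_equal(profile$fields$sbp, 140)
})
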