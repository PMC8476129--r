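make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

toy_wide <- function() {
  data.frame(subject_id = c("a", "b", "c", "d"),
             age_baseline = c(12, 14, 16, 13), age_followup = c(15, 17, 19, 16),
             sex = c(0, 1, 0, 1),
             i1_t1 = c(1, 2, 3, 2), i2_t1 = c(0, 1, 2, 1),
             i1_t2 = c(2, 2, 4, 3), i2_t2 = c(1, 0, 2, 2))
}

test_that("a wide two-wave CSV reads back into the expected cohort", {
  coh <- read_cohort(make_csv(toy_wide()))
  expect_s3_class(coh, "tmsn_cohort")
  expect_equal(length(coh$subject_id), 4)
  expect_equal(ncol(coh$baseline), 2)
  expect_equal(ncol(coh$followup), 2)
  expect_equal(unname(coh$baseline[, "i1"]), c(1, 2, 3, 2))
  expect_equal(unname(coh$followup[, "i2"]), c(1, 0, 2, 2))
})

test_that("subjects with missing items are dropped (or rejected in strict mode)", {
  df <- toy_wide()
  df$i2_t2[2] <- NA
  path <- make_csv(df)
  # complete-case default drops the subject and says so
  expect_message(coh <- read_cohort(path), "dropped 1")
  expect_equal(length(coh$subject_id), 3)
  expect_equal(attr(coh, "drop_log"), 1)
  expect_error(read_cohort(path, strict = TRUE), "missing")
})

test_that("schema violations are named", {
  df <- toy_wide()
  df$sex <- NULL
  expect_error(read_cohort(make_csv(df)), "sex")
  df2 <- toy_wide()
  df2$i1_t1 <- c("1", "2", "high", "2")
  expect_error(read_cohort(make_csv(df2)), "non-numeric")
})

test_that("cohort round-trips through write_cohort/read_cohort", {
  coh <- read_cohort(make_csv(toy_wide()))
  out <- tempfile(fileext = ".csv")
  write_cohort(coh, out)
  coh2 <- read_cohort(out)
  expect_equal(coh2$baseline, coh$baseline)
  expect_equal(coh2$followup, coh$followup)
  expect_equal(coh2$covariates, coh$covariates)
  # the JSON sidecar preserves instruments and scale bounds
  sim <- sample_cohort(generative_spec(n_subjects = 30, p_items = 6,
                                       seed = 44))$cohort
  out2 <- tempfile(fileext = ".csv")
  write_cohort(sim, out2)
  back <- read_cohort(out2)
  expect_equal(back$baseline_items, sim$baseline_items,
               ignore_attr = "row.names")
  expect_equal(sort(unique(back$followup_items$instrument)),
               c("AFF", "NEG"))
})

test_that("prevalence filter removes rare items pairwise, with a strict cut", {
  n <- 100
  set.seed(42)
  mk <- function(k_nonzero) {       # k subjects above the floor of 0
    x <- numeric(n)
    x[seq_len(k_nonzero)] <- 3
    x
  }
  bl <- cbind(common = pmax(rnorm(n, 3, 1), 0.5), rare = mk(0),
              border = mk(1))
  fu <- cbind(common = pmax(rnorm(n, 3, 1), 0.5), rare = mk(2),
              border = mk(1))
  pan <- item_panel(c("common", "rare", "border"), scale_min = 0,
                    scale_max = 8)
  coh <- cohort(bl, fu, data.frame(age_baseline = rnorm(n, 14),
                                   age_followup = rnorm(n, 17),
                                   sex = rep_len(0:1, n)),
                pan, pan)
  filt <- prevalence_filter(coh, 0.01)
  # "rare" fails at baseline only but is removed from both waves;
  # exactly 1% endorsement is not "less than 1%", so "border" stays
  expect_equal(filt$baseline_items$item_id, c("common", "border"))
  expect_equal(filt$followup_items$item_id, c("common", "border"))
  expect_equal(attr(filt, "removed_items"), "rare")
  # idempotent
  refilt <- prevalence_filter(filt, 0.01)
  expect_equal(refilt$baseline, filt$baseline)
  # zero threshold is the identity
  expect_equal(prevalence_filter(coh, 0)$baseline_items$item_id,
               coh$baseline_items$item_id)
})

test_that("a 43-item panel with two rare items yields 41 retained measures", {
  n <- 200
  set.seed(7)
  p <- 43
  X <- matrix(rpois(n * p, 2) + 0.0, n, p)
  ids <- c(sprintf("sips%02d", 1:21), sprintf("bprs%02d", 1:22))
  rare <- c("sips21", "bprs22")   # the two grandiosity-like items
  X[, ids %in% rare] <- 0
  X[1, ids %in% rare] <- 1        # endorsed by 1/200 < 1%
  colnames(X) <- ids
  pan <- item_panel(ids, scale_min = 0, scale_max = 30)
  coh <- cohort(X, X, data.frame(age_baseline = rnorm(n, 14),
                                 age_followup = rnorm(n, 17),
                                 sex = rep_len(0:1, n)), pan, pan)
  filt <- prevalence_filter(coh, 0.01)
  expect_equal(nrow(filt$baseline_items), 41)
  expect_setequal(attr(filt, "removed_items"), rare)
})

test_that("covariate residualization matches the normal-equations oracle", {
  age <- c(10, 11, 12, 13)
  sex <- c(0, 0, 1, 1)
  y <- c(1, 2, 3, 4)
  y2 <- c(2, 0, 5, 1)
  bl <- cbind(a = y, b = y2)
  fu <- cbind(a = y2, b = y)
  coh <- cohort(bl, fu, data.frame(age_baseline = age, age_followup = age + 3,
                                   sex = sex),
                item_panel(c("a", "b"), scale_min = -10, scale_max = 10),
                item_panel(c("a", "b"), scale_min = -10, scale_max = 10))
  res <- residualize_covariates(coh)
  X <- cbind(1, age, sex)
  expect_equal(unname(res$baseline[, "a"]), oracle_ols_residuals(y, X))
  expect_equal(unname(res$baseline[, "b"]), oracle_ols_residuals(y2, X))
  # follow-up wave uses age at follow-up
  Xf <- cbind(1, age + 3, sex)
  expect_equal(unname(res$followup[, "b"]), oracle_ols_residuals(y, Xf))
  # an item exactly linear in age leaves zero residuals
  expect_equal(unname(res$baseline[, "a"]), rep(0, 4), tolerance = 1e-12)
})

test_that("residuals are exactly uncorrelated with age and sex", {
  sim <- sample_cohort(generative_spec(n_subjects = 60, p_items = 6,
                                       seed = 5))
  res <- residualize_covariates(sim$cohort)
  cov <- res$covariates
  for (j in seq_len(ncol(res$baseline))) {
    expect_lt(abs(cor(res$baseline[, j], cov$age_baseline)), 1e-10)
    expect_lt(abs(cor(res$baseline[, j], cov$sex)), 1e-10)
    expect_lt(abs(cor(res$followup[, j], cov$age_followup)), 1e-10)
    expect_lt(abs(cor(res$followup[, j], cov$sex)), 1e-10)
  }
})

test_that("a single-sex cohort drops the sex regressor with a warning", {
  sim <- sample_cohort(generative_spec(n_subjects = 30, p_items = 4,
                                       seed = 9))
  coh <- sim$cohort
  coh$covariates$sex <- 0
  ws <- capture_warnings(res <- residualize_covariates(coh))
  expect_true(any(grepl("sex", ws)))   # warned for each wave
  expect_false(anyNA(res$baseline))
})

test_that("standardize/destandardize round-trip and external stats work", {
  sim <- sample_cohort(generative_spec(n_subjects = 50, p_items = 5,
                                       seed = 3))
  z <- standardize_items(sim$cohort)
  expect_equal(unname(colMeans(z$baseline)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z$followup, 2, sd)), rep(1, 5),
               tolerance = 1e-12)
  back <- destandardize_items(z)
  expect_equal(back$baseline, sim$cohort$baseline, tolerance = 1e-12)
  # training stats applied to a held-out row give (x - mean)/sd elementwise
  st <- attr(z, "stats")
  z2 <- standardize_items(sim$cohort, stats = st)
  expect_equal(z2$baseline, z$baseline)
  manual <- (sim$cohort$baseline[3, ] - st$baseline$mean) / st$baseline$sd
  expect_equal(unname(z2$baseline[3, ]), unname(manual))
})

test_that("panel alignment pairs mapped and verbatim items and reports exclusions", {
  sips <- item_panel(c(sprintf("sips%d", 1:15), "sips_extra"),
                     instrument = "SIPS")
  bprs_a <- item_panel(sprintf("bprs%d", 1:10), instrument = "BPRS",
                       scale_min = 1, scale_max = 7)
  caarms <- item_panel(c(sprintf("caarms%d", 1:15), sprintf("caarms_x%d", 1:13)),
                       instrument = "CAARMS")
  bprs_b <- item_panel(sprintf("bprs%d", 1:10), instrument = "BPRS",
                       scale_min = 1, scale_max = 7)
  mapping <- data.frame(a = sprintf("sips%d", 1:15),
                        b = sprintf("caarms%d", 1:15))
  al <- align_panels(rbind(sips, bprs_a), rbind(caarms, bprs_b), mapping)
  expect_equal(al$n_shared, 15 + 10)   # interview pairs + shared BPRS items
  expect_equal(sum(al$pairs$source == "mapped"), 15)
  expect_equal(sum(al$pairs$source == "verbatim"), 10)
  expect_equal(al$excluded_a, "sips_extra")
  expect_equal(length(al$excluded_b), 13)
  # duplicate mapping is rejected
  bad <- rbind(mapping, data.frame(a = "sips1", b = "caarms_x1"))
  expect_error(align_panels(rbind(sips, bprs_a), rbind(caarms, bprs_b), bad),
               "mapped more than once")
  # disjoint instruments with no mapping share nothing
  expect_equal(align_panels(sips, caarms)$n_shared, 0)
  # identical panels share everything verbatim
  expect_equal(align_panels(sips, sips)$n_shared, nrow(sips))
})
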