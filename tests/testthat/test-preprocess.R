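test_that("preprocessing statistics use the population convention", {
  tab <- toy_table()  # weight = 2, 4, 6
  pp <- fit_preprocessor(tab)
  expect_equal(unname(pp$mu["weight"]), 4)
  expect_equal(unname(pp$sigma["weight"]), sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(unname(pp$sigma["weight"]), 1.633, tolerance = 1e-3)

  pp_s <- fit_preprocessor(tab, sd_type = "sample")
  expect_equal(unname(pp_s$sigma["weight"]), 2)

  # constant continuous property is an error naming the property
  bad <- property_table(toy_schema(), c("a", "b", "c"),
                        c("positive", "unlabeled", "unlabeled"),
                        data.frame(weight = c(5, 5, 5),
                                   soluble = c("yes", "no", "yes")))
  expect_error(fit_preprocessor(bad), "weight.*constant|constant.*weight")

  # nearly-constant column is fine
  ok <- property_table(toy_schema(), c("a", "b", "c"),
                       c("positive", "unlabeled", "unlabeled"),
                       data.frame(weight = c(5, 5, 5.1),
                                  soluble = c("yes", "no", "yes")))
  expect_gt(unname(fit_preprocessor(ok)$sigma["weight"]), 0)
})

test_that("zscore matches direct arithmetic and normalizes columns", {
  expect_equal(zscore(4, 4, 1.633), 0)
  expect_equal(zscore(c(2, 4, 6), 4, sqrt(8 / 3)),
               c(-3, 0, 3) / sqrt(6), tolerance = 1e-12)
  expect_equal(zscore(c(2, 4, 6), 4, 1.633), c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)
  expect_error(zscore(1:3, 0, 0), "sigma")

  set.seed(3)
  x <- rnorm(57, 10, 4)
  mu <- mean(x); sig <- sqrt(mean((x - mu)^2))
  z <- zscore(x, mu, sig)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(mean(z^2), 1, tolerance = 1e-9)
})

test_that("one_hot is a bijection between states and unit bit vectors", {
  expect_identical(one_hot("B", c("A", "B", "C")), c(0L, 1L, 0L))
  expect_identical(one_hot("A", "A"), 1L)
  expect_error(one_hot("C", c("A", "B")), "unknown state")

  states <- c("w", "x", "y", "z")
  for (s in states) {
    v <- one_hot(s, states)
    expect_equal(sum(v), 1L)
    expect_identical(states[which(v == 1L)], s)  # decoding recovers the state
  }
})

test_that("transform concatenates z-scores and one-hot groups in schema order", {
  tab <- toy_table()
  pp <- fit_preprocessor(tab)
  fm <- predict(pp, tab)
  expect_equal(ncol(fm$values), 1 + 2)
  expect_identical(fm$provenance$property, c("weight", "soluble", "soluble"))
  expect_identical(fm$provenance$component, c("zscore", "yes", "no"))
  # one-hot group sums to exactly 1 per row
  expect_equal(rowSums(fm$values[, 2:3]), rep(1, 3))
  # z-scored column has mean 0 and population sd 1
  expect_equal(mean(fm$values[, 1]), 0, tolerance = 1e-12)
  expect_equal(mean(fm$values[, 1]^2), 1, tolerance = 1e-12)

  # mismatch guard
  other <- default_protein_schema(2, c(2))
  tab2 <- simulate_pu_dataset(5, 5, 0, n_continuous = 2, nominal_states = 2,
                              seed = 1)$table
  expect_error(predict(pp, tab2), "schema")
})

test_that("encoded dimension follows the schema for randomized shapes", {
  set.seed(11)
  for (trial in 1:10) {
    n_cont <- sample(0:6, 1)
    n_nom <- sample(1:4, 1)
    st <- sample(2:5, n_nom, replace = TRUE)
    d <- simulate_pu_dataset(n_pos = 4, n_unl = 8, alpha = 0,
                             n_continuous = n_cont, nominal_states = st,
                             effect_size = 1, seed = trial)
    fm <- predict(fit_preprocessor(d$table), d$table)
    expect_equal(ncol(fm$values), n_cont + sum(st))
    expect_equal(feature_dimension(d$table$schema), n_cont + sum(st))
    # every nominal one-hot group sums to one on every row
    for (nm in names(d$table$schema$states)) {
      grp <- fm$provenance$property == nm
      expect_equal(rowSums(fm$values[, grp, drop = FALSE]),
                   rep(1, nrow(fm$values)))
    }
  }
})

test_that("ks_screen agrees with a brute-force ECDF oracle", {
  # identical groups: D = 0, p = 1
  sch <- property_schema("v", "continuous")
  tab <- property_table(sch, id = as.character(1:8),
                        label = rep(c("positive", "unlabeled"), each = 4),
                        values = data.frame(v = rep(c(1, 2, 3, 4), 2)))
  r <- ks_screen(tab)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)

  # hand-checkable case against the double-loop oracle
  pos <- c(1, 2, 3); unl <- c(1, 2, 3, 10)
  tab2 <- property_table(sch, id = as.character(1:7),
                         label = rep(c("positive", "unlabeled"), c(3, 4)),
                         values = data.frame(v = c(pos, unl)))
  r2 <- ks_screen(tab2)
  expect_equal(r2$D, brute_ks_D(pos, unl), tolerance = 1e-12)

  # random instances with n <= 200
  set.seed(5)
  for (trial in 1:8) {
    np <- sample(5:100, 1); nu <- sample(5:100, 1)
    pos <- rnorm(np); unl <- rnorm(nu, mean = runif(1, 0, 1))
    tb <- property_table(sch, id = as.character(seq_len(np + nu)),
                         label = rep(c("positive", "unlabeled"), c(np, nu)),
                         values = data.frame(v = c(pos, unl)))
    expect_equal(ks_screen(tb)$D, brute_ks_D(pos, unl), tolerance = 1e-12)
  }

  # group-size guard and the nominal-index warning
  small <- property_table(sch, c("a", "b", "c"),
                          c("positive", "unlabeled", "unlabeled"),
                          data.frame(v = 1:3))
  expect_error(ks_screen(small), "at least 2")
  mixed <- property_table(toy_schema(), as.character(1:6),
                          rep(c("positive", "unlabeled"), each = 3),
                          data.frame(weight = c(1, 2, 3, 4, 5, 6),
                                     soluble = c("yes", "no", "yes",
                                                 "no", "yes", "no")))
  expect_warning(ks_screen(mixed), "conservative")
})
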