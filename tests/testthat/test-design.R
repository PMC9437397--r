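test_that("unadjusted sample size matches the closed form and rejects degenerate inputs", {
  # symmetric prevalence with unit multiplier: 1 * 0.25 / (0.2*0.5)^2
  expect_equal(base_sample_size(0.5, z = 1, rel_precision = 0.2), 25)
  # frozen high-precision evaluations of z^2 p (1-p) / (r p)^2
  expect_equal(base_sample_size(0.17), 468.90, tolerance = 0.01 / 468.9)
  expect_equal(base_sample_size(0.189), 412.11, tolerance = 0.01 / 412.11)

  expect_error(base_sample_size(0), "outside")
  expect_error(base_sample_size(1), "outside")
  expect_error(base_sample_size(0.2, rel_precision = 0), "outside")
  expect_error(base_sample_size(0.2, z = -1), "outside")
})

test_that("sample size decreases in prevalence and in relative precision", {
  p_grid <- seq(0.02, 0.95, by = 0.031)
  n <- vapply(p_grid, base_sample_size, 0)
  expect_true(all(diff(n) < 0))
  r_grid <- seq(0.05, 0.5, by = 0.05)
  nr <- vapply(r_grid, function(r) base_sample_size(0.17, rel_precision = r), 0)
  expect_true(all(diff(nr) < 0))
})

test_that("the full adjustment chain reproduces the regional design sizes", {
  res <- sample_size(0.17)
  expect_equal(res$n_final, 1126L)
  expect_equal(res$n_clusters, 12L)
  expect_equal(res$n_deff, res$n_base * 2)
  expect_equal(res$n_inflated, res$n_deff * 1.2)

  expect_equal(sample_size(0.039)$n_final, 5680L)
  expect_equal(sample_size(0.189)$n_final, 990L)

  # pass-through design: no clustering, no losses
  triv <- sample_size(0.5, design_parameters(z = 1, deff = 1,
                                             nonresponse_rate = 0))
  expect_equal(triv$n_final, 25L)
  expect_equal(triv$n_clusters, 1L)
})

test_that("sample-size fields are ordered and clusters cover the final size", {
  for (p in c(0.039, 0.17, 0.189, 0.6)) {
    res <- sample_size(p)
    expect_true(res$n_base <= res$n_deff)
    expect_true(res$n_deff <= res$n_inflated)
    expect_true(res$n_inflated <= res$n_final)
    expect_true(res$n_clusters * res$params$cluster_size >= res$n_final)
    expect_true(res$achieved_precision <= res$params$rel_precision)
  }
})

test_that("the chain agrees with a brute-force smallest-n search on a grid", {
  for (p in c(0.039, 0.1, 0.17, 0.189, 0.5)) {
    for (deff in c(1, 1.7, 2)) {
      for (nr in c(0, 0.1, 0.2)) {
        pars <- design_parameters(deff = deff, nonresponse_rate = nr)
        expect_equal(sample_size(p, pars)$n_final,
                     brute_force_n(p, deff = deff, nr = nr),
                     info = sprintf("p=%g deff=%g nr=%g", p, deff, nr))
      }
    }
  }
})

test_that("achievable precision inverts the sizing chain", {
  expect_equal(achievable_precision(25, 0.5,
                                    design_parameters(z = 1, deff = 1,
                                                      nonresponse_rate = 0)),
               0.200)
  expect_equal(achievable_precision(1126, 0.17), 0.19994, tolerance = 1e-4)
  # 1/sqrt(10) scaling law
  expect_equal(achievable_precision(11260, 0.17),
               achievable_precision(1126, 0.17) / sqrt(10))
  expect_error(achievable_precision(0, 0.17), "outside")

  # round trip: the sized survey always meets the requested precision,
  # with equality before the ceiling
  for (p in seq(0.03, 0.9, by = 0.07)) {
    res <- sample_size(p)
    r_ach <- achievable_precision(res$n_final, p)
    expect_true(r_ach <= 0.20)
    expect_equal(achievable_precision(res$n_inflated, p), 0.20)
  }
})

test_that("design-effect sensitivity table is linear in DEFF and consistent", {
  tab <- deff_sensitivity(0.17, deff_values = c(1, 2))
  expect_equal(tab$n_final, c(563L, 1126L))
  expect_equal(deff_sensitivity(0.17, deff_values = 2)$n_final,
               sample_size(0.17)$n_final)
  tab2 <- deff_sensitivity(0.23, deff_values = c(1, 1.5, 2, 3))
  expect_equal(tab2$n_deff / tab2$n_base, c(1, 1.5, 2, 3))
  expect_true(all(diff(tab2$n_final) >= 0))
  expect_error(deff_sensitivity(0.17, deff_values = c(2, 0.5)), ">= 1")
})

test_that("scenario tables keep input order and composite scenarios check their sums", {
  sc <- list(
    prevalence_scenario(0.17, "all-cause VI"),
    prevalence_scenario(0.189, "all conditions",
                        components = c(vi = 0.17, nvic = 0.019)))
  tab <- scenario_table(sc)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$label, c("all-cause VI", "all conditions"))
  expect_equal(tab$n_final, c(1126L, 990L))
  expect_equal(scenario_table(list(prevalence_scenario(0.039)))$n_final,
               sample_size(0.039)$n_final)

  expect_error(scenario_table(list()), "non-empty")
  expect_error(prevalence_scenario(0.19, components = c(0.17, 0.019)),
               "sum to")
})

test_that("design parameters validate their ranges", {
  expect_error(design_parameters(deff = 0.5), "outside")
  expect_error(design_parameters(nonresponse_rate = 1), "outside")
  expect_error(design_parameters(rel_precision = 1), "outside")
  expect_error(design_parameters(cluster_size = 10.5), "whole number")
  expect_s3_class(design_parameters(), "sehra_parameters")
})
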