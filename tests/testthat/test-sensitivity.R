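test_that("grid construction validates its inputs", {
  g <- sensitivity_grid()
  expect_equal(g$beta_R_values, c(1, 0.75, 0.5))
  expect_equal(g$rho_MM_values, c(0, 0.2, 0.4))
  expect_error(sensitivity_grid(beta_R_values = c(1, 1)), "duplicates")
  expect_error(sensitivity_grid(beta_R_values = numeric(0)), "nonempty")
  expect_error(sensitivity_grid(rho_MM_values = c(0, 1)), "\\[0, 1\\)")
})

## one moderate dataset shared by the grid tests below
grid_data <- local({
  d <- NULL
  function() {
    if (is.null(d))
      d <<- residualize(gen_dataset(simulation_spec(
        n = 4000, params = fv_example_params(), seed = 121)))
    d
  }
})

test_that("the full grid fits every cell and scaling/invariance laws hold across cells", {
  res <- run_grid(grid_data(), sensitivity_grid())
  expect_equal(nrow(res$cells), 9L)
  expect_true(all(res$cells$converged))

  cells <- res$cells
  for (rh in unique(cells$rho_MM)) {
    row <- which(cells$rho_MM == rh)
    ## lambda * beta_R constant within a rho_MM row (the scaling law)
    lam <- vapply(row, function(i)
      rdr(res$fits[[i]]$params, res$fits[[i]]$sens, "Q", 1), numeric(1))
    prod <- lam * cells$beta_R[row]
    expect_lt(max(abs(prod / prod[1] - 1)), 1e-6)
  }
  for (b in unique(cells$beta_R)) {
    col <- which(cells$beta_R == b)
    ## beta_Q does not depend on rho_MM
    bq <- vapply(col, function(i) res$fits[[i]]$params$beta_Q, numeric(1))
    expect_lt(max(abs(bq / bq[1] - 1)), 1e-3)
  }
})

test_that("grid results do not depend on grid ordering", {
  d <- grid_data()
  g1 <- sensitivity_grid(beta_R_values = c(1, 0.5), rho_MM_values = 0.2)
  g2 <- sensitivity_grid(beta_R_values = c(0.5, 1), rho_MM_values = 0.2)
  r1 <- run_grid(d, g1)
  r2 <- run_grid(d, g2)
  k1 <- order(r1$cells$beta_R)
  k2 <- order(r2$cells$beta_R)
  expect_equal(r1$cells$loglik[k1], r2$cells$loglik[k2], tolerance = 1e-8)
  expect_equal(r1$fits[[k1[1]]]$params$beta_Q, r2$fits[[k2[1]]]$params$beta_Q,
               tolerance = 1e-4)
})

test_that("warm-started cells agree with cold starts to optimizer tolerance", {
  d <- grid_data()
  g <- sensitivity_grid(beta_R_values = c(1, 0.5), rho_MM_values = 0)
  warm <- run_grid(d, g)                      # second cell warm-started
  cold <- fit_ml(d, sensitivity_setting(0.5, 0))
  i <- which(warm$cells$beta_R == 0.5)
  expect_equal(warm$fits[[i]]$params$beta_Q, cold$params$beta_Q,
               tolerance = 1e-4)
  expect_equal(warm$cells$loglik[i], cold$loglik, tolerance = 1e-8)
})

test_that("the generating cell minimizes parameter-recovery error", {
  s_true <- sensitivity_setting(1, 0)
  d <- grid_data()  # generated at (beta_R = 1, rho_MM = 0)
  res <- run_grid(d, sensitivity_grid(beta_R_values = c(1, 0.5),
                                      rho_MM_values = c(0, 0.4)))
  p0 <- fv_example_params(s_true)
  err <- vapply(seq_len(nrow(res$cells)), function(i) {
    ph <- res$fits[[i]]$params
    sum(abs(log(c(ph$beta_Q, ph$beta_M, ph$sigma2_T) /
                  c(p0$beta_Q, p0$beta_M, p0$sigma2_T))))
  }, numeric(1))
  gen_cell <- which(res$cells$beta_R == 1 & res$cells$rho_MM == 0)
  expect_equal(which.min(err), gen_cell)
})

test_that("summary tables have the documented shape and round-trip via CSV", {
  res <- run_grid(grid_data(), sensitivity_grid())
  tab <- summarize_grid(res, "rdr")
  expect_true(all(c("rho_MM=0", "rho_MM=0.2", "rho_MM=0.4") %in% names(tab)))
  ## rows: (rdr: 2 instruments x 2 times x 2 exposures + corr: 3 x 2 x 2) x 3 beta_R
  expect_equal(nrow(tab), (8 + 12) * 3)

  path <- withr::local_tempfile(fileext = ".csv")
  long <- attr(summarize_grid(res, "rdr", csv = path), "long")
  back <- utils::read.csv(path)
  expect_equal(back$estimate, long$estimate)
  expect_equal(back$rho_MM, long$rho_MM)

  ptab <- summarize_grid(res, "params")
  expect_true("parameter" %in% names(ptab))
})

test_that("failed cells are rendered as NC with their diagnostic retained", {
  res <- run_grid(grid_data(), sensitivity_grid(beta_R_values = 1,
                                                rho_MM_values = c(0, 0.2)))
  ## emulate a non-converged cell as recorded by run_grid
  res$cells$converged[2] <- FALSE
  res$cells$message[2] <- "optimizer did not converge"
  res$derived[2] <- list(NULL)
  res$fits[2] <- list(NULL)
  tab <- summarize_grid(res, "rdr")
  expect_true(all(tab[["rho_MM=0.2"]] == "NC"))
  expect_false(any(tab[["rho_MM=0"]] == "NC"))
})

test_that("subset analysis runs the grid per stratum via row filtering", {
  d <- grid_data()
  g <- sensitivity_grid(beta_R_values = 0.75, rho_MM_values = 0.4)
  half1 <- subset_me_data(d, seq_len(2000))
  half2 <- subset_me_data(d, 2001:4000)
  r1 <- run_grid(half1, g)
  r2 <- run_grid(half2, g)
  expect_true(r1$cells$converged && r2$cells$converged)
  ## strata estimates differ only by sampling noise
  expect_equal(r1$fits[[1]]$params$beta_Q, r2$fits[[1]]$params$beta_Q,
               tolerance = 0.2)
})
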