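make_species_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

base_table <- function() {
  data.frame(
    species = c("sp1", "sp2", "sp3", "sp4", "sp5", "sp6"),
    environment = c("terrestrial", "terrestrial", "semi_aquatic",
                    "semi_aquatic", "fully_aquatic", "fully_aquatic"),
    latitude = c(10, -35, 50, 60, 70, 5),
    hair_density = c(20, 15, 800, NA, NA, NA),
    blubber_section = c("white_adipose", "white_adipose", "outer", "whole",
                        "outer", "outer"),
    delta9_di = c(1.2, 1.5, 3.0, 3.5, 2.8, 3.2),
    dbi = c(0.8, 0.9, 1.6, 1.7, 1.2, 1.3),
    stringsAsFactors = FALSE
  )
}

test_that("species table loading validates and derives columns", {
  tab <- load_species_table(make_species_csv(base_table()))
  expect_equal(nrow(tab), 6)
  expect_s3_class(tab$environment, "factor")
  expect_equal(tab$latitude[2], 35)  # absolute by default
  expect_equal(tab$log_hair_density[1], log(20))
  expect_true(is.na(tab$log_hair_density[5]))
  signed <- load_species_table(make_species_csv(base_table()),
                               latitude_mode = "signed")
  expect_equal(signed$latitude[2], -35)

  bad_env <- base_table(); bad_env$environment[3] <- "marine"
  expect_error(load_species_table(make_species_csv(bad_env)), "row 3")
  bad_lat <- base_table(); bad_lat$latitude[4] <- 95
  expect_error(load_species_table(make_species_csv(bad_lat)), "row 4")
  no_sp <- base_table(); no_sp$species[2] <- ""
  expect_error(load_species_table(make_species_csv(no_sp)), "row 2")

  # primary + secondary hair densities are summed
  two_hair <- base_table(); two_hair$hair_density_secondary <- c(5, NA, 200, NA, NA, NA)
  tab2 <- load_species_table(make_species_csv(two_hair))
  expect_equal(tab2$hair_density[1], 25)
  expect_equal(tab2$hair_density[2], 15)
  expect_equal(tab2$log_hair_density[3], log(1000))
})

test_that("design matrices expand terms as dummy coding plus interactions", {
  tab <- load_species_table(make_species_csv(base_table()))
  null_d <- build_design_matrix(tab, model_spec("null"))
  expect_equal(ncol(null_d$X), 1)
  expect_true(all(null_d$X == 1))
  env_d <- build_design_matrix(tab, model_spec("environment_only"))
  expect_equal(ncol(env_d$X), 3)  # intercept + 2 dummies
  add_d <- build_design_matrix(tab, model_spec("additive"))
  expect_equal(ncol(add_d$X), 4)
  int_d <- build_design_matrix(tab, model_spec("interaction"))
  expect_equal(ncol(int_d$X), 6)  # 1 + 1 + 2 + 2
  # reference level: dummies absent for fully_aquatic rows
  fa_rows <- tab$environment == "fully_aquatic"
  expect_true(all(int_d$X[fa_rows, grepl("environment", colnames(int_d$X))] == 0))
  # nesting: additive columns inside interaction; marginals inside additive
  expect_true(all(colnames(add_d$X) %in% colnames(int_d$X)))
  expect_true(all(colnames(env_d$X) %in% colnames(add_d$X)))
  # incomplete records are dropped with a message
  expect_message(hd <- build_design_matrix(tab, model_spec("hair_density_only")),
                 "dropping")
  expect_equal(nrow(hd$X), 3)
  # a factor with an empty level errors
  sub <- tab[tab$environment != "terrestrial", ]
  expect_error(build_design_matrix(sub, model_spec("environment_only")),
               "terrestrial")
})

test_that("a strong simulated interaction is recovered by the suite ranking", {
  wins <- 0L
  for (i in 1:8) {
    sim <- simulate_study(seed = 900 + i, n_tips = 54, lambda = 0.5,
                          sigma2 = 0.25, beta = strong_interaction_beta(0.08))
    sr <- suppressMessages(run_model_suite(sim$records, sim$binary,
                                           response = "delta9_di",
                                           suite = mammal_suite(),
                                           n_iter = 1, seed = i))
    wins <- wins + (sr$comparison$table$model[1] == "interaction")
  }
  expect_gte(wins, 6)
})

test_that("suite bookkeeping: one model, per-environment slopes, determinism", {
  sim <- simulate_study(seed = 77, n_tips = 40, polytomy_fraction = 0.25,
                        beta = strong_interaction_beta())
  one <- suppressMessages(run_model_suite(sim$records, sim$tree, "delta9_di",
                                          suite = mammal_suite()["latitude_only"],
                                          n_iter = 3, seed = 2))
  expect_equal(one$comparison$table$delta_aicc, 0)
  expect_equal(one$comparison$table$weight, 1, tolerance = 1e-12)

  sr1 <- suppressMessages(run_model_suite(sim$records, sim$tree, "delta9_di",
                                          suite = mammal_suite(), n_iter = 4,
                                          seed = 12))
  sr2 <- suppressMessages(run_model_suite(sim$records, sim$tree, "delta9_di",
                                          suite = mammal_suite(), n_iter = 4,
                                          seed = 12))
  expect_identical(sr1$iterations, sr2$iterations)
  expect_equal(sr1$comparison$table, sr2$comparison$table)
  expect_setequal(sr1$slopes$environment,
                  c("fully_aquatic", "semi_aquatic", "terrestrial"))
  expect_true(all(sr1$slopes$low < sr1$slopes$high))
  # weights sum to one
  expect_equal(sum(sr1$comparison$table$weight), 1, tolerance = 1e-10)
})

test_that("group summaries give per-environment mean, SD, n and are order-invariant", {
  tab <- base_table()
  gs <- group_summary(tab, "delta9_di")
  expect_equal(gs$n, c(2, 2, 2))
  terr <- gs[gs$environment == "terrestrial", ]
  expect_equal(terr$mean, mean(c(1.2, 1.5)))
  expect_equal(terr$sd, sd(c(1.2, 1.5)))
  shuffled <- tab[c(4, 1, 6, 3, 2, 5), ]
  expect_equal(group_summary(shuffled, "delta9_di"), gs)
  # hand case {1,2,3}: mean 2, sd 1
  tri <- data.frame(species = c("a", "b", "c"), environment = "terrestrial",
                    delta9_di = c(1, 2, 3))
  gt <- suppressWarnings(group_summary(tri, "delta9_di"))
  expect_equal(gt$mean[gt$environment == "terrestrial"], 2)
  expect_equal(gt$sd[gt$environment == "terrestrial"], 1)
  # singleton group: SD undefined
  solo <- data.frame(species = "a", environment = "fully_aquatic",
                     delta9_di = 2.2)
  gsolo <- suppressWarnings(group_summary(solo, "delta9_di"))
  expect_true(is.na(gsolo$sd[gsolo$environment == "fully_aquatic"]))
})

test_that("blubber-section subanalysis recovers a shared latitude slope", {
  sim <- simulate_study(seed = 321, n_tips = 40, lambda = 0.3, sigma2 = 0.15,
                        beta = strong_interaction_beta(0.06))
  rec <- sim$records
  rec$pinniped <- rec$environment == "semi_aquatic"
  pin_idx <- which(rec$pinniped)
  rec$blubber_section[pin_idx] <-
    rep(c("outer", "whole"), length.out = length(pin_idx))
  bs <- blubber_section_subanalysis(rec, sim$binary, n_iter = 1, seed = 4)
  expect_named(bs, c("outer", "whole"))
  for (g in bs) {
    expect_gte(g$n, 3)
    # both groups were generated with the same true slope 0.06
    expect_lt(abs(g$slope - 0.06), 0.06)
  }
  # refuses undersized groups
  rec2 <- rec
  rec2$blubber_section[rec2$blubber_section == "whole"] <- "outer"
  rec2$blubber_section[pin_idx[1]] <- "whole"
  expect_error(blubber_section_subanalysis(rec2, sim$binary, n_iter = 1,
                                           seed = 1), "whole")
})

test_that("per-FA latitude regressions detect trends and hold their size", {
  lat <- seq(5, 75, length.out = 20)
  sp <- sprintf("p%02d", 1:20)
  records <- data.frame(species = sp, environment = "semi_aquatic",
                        latitude = lat)
  # an exactly linear MUFA and a flat SFA
  profiles <- lapply(1:20, function(i) {
    fa_profile(sp[i], c(
      "16:1w7" = 5 + 0.2 * lat[i], "18:1w9" = 20, "18:1w7" = 4,
      "14:1w5" = 1, "16:1w9" = 1,
      "14:0" = 4, "16:0" = 30 - 0.15 * lat[i], "18:0" = 10
    ))
  })
  # exactly linear columns make lm warn about a perfect fit; that is the point
  res <- suppressWarnings(fa_vs_latitude_regressions(profiles, records))
  r167 <- res[res$fa == "16:1ω7", ]
  expect_equal(r167$slope, 0.2, tolerance = 1e-10)
  expect_true(r167$significant)
  r160 <- res[res$fa == "16:0", ]
  expect_lt(r160$slope, 0)
  expect_true(r160$significant)
  # constant FA: slope 0, p undefined, flagged
  r189 <- res[res$fa == "18:1ω9", ]
  expect_equal(r189$slope, 0)
  expect_true(is.na(r189$p_value))
  expect_true(r189$constant)

  # type-I error rate near alpha for an FA independent of latitude
  fp <- 0L
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    wt <- with_seed(7000 + i, rnorm(20, 10, 2))
    pr <- lapply(1:20, function(j)
      fa_profile(sp[j], c("16:1w7" = wt[j], "16:0" = 20, "18:0" = 5,
                          "14:0" = 3, "14:1w5" = 1, "16:1w9" = 1,
                          "18:1w9" = 10, "18:1w7" = 2)))
    res_i <- fa_vs_latitude_regressions(pr, records, fas = "16:1ω7")
    fp <- fp + res_i$significant[1]
  }
  expect_lte(fp / n_rep, 0.05)  # nominal 0.01 with binomial slack

  # permuting latitudes destroys a strong trend
  hits <- 0L
  for (i in 1:40) {
    rec_perm <- records
    rec_perm$latitude <- with_seed(8000 + i, sample(records$latitude))
    noisy <- lapply(1:20, function(j) {
      w <- profiles[[j]]$weights
      w["16:1ω7"] <- w["16:1ω7"] + with_seed(9000 + 20 * i + j, rnorm(1, 0, 1))
      fa_profile(sp[j], pmax(w, 0))
    })
    res_p <- fa_vs_latitude_regressions(noisy, rec_perm, fas = "16:1ω7")
    hits <- hits + !res_p$significant[1]
  }
  expect_gte(hits / 40, 0.95)
})
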