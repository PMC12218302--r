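# run a short simulated campaign on the small mixed space
mini_campaign <- function(n0 = 8, seed = 1, batch = 3) {
  sp <- small_mixed_space()
  camp <- campaign_new(sp, acq_config(kind = "ucb", batch_size = batch,
                                      screen_size = 300, restarts = 2),
                       seed = seed)
  camp <- campaign_init(camp, n0, seed = seed)
  pl <- camp$ledger
  ingest(camp, tibble::tibble(experiment_id = pl$experiment_id,
                              target = mixed_test_fun(pl)))
}

test_that("ledger CSVs round-trip and aggregate replicates on read", {
  sp <- yeast_space()
  led <- initial_design(sp, 4, seed = 1)
  led$experiment_id <- paste0("e", 1:4)
  led$iteration <- 0L
  led$role <- "executed"
  led$rep_1 <- c(10, 8, 6, 4)
  led$rep_2 <- c(12, 8, 7, 5)
  led$target <- NA_real_
  led <- led[, c("experiment_id", "iteration", "role", names(sp$factors),
                 "rep_1", "rep_2", "target")]
  path <- tempfile(fileext = ".csv")
  write_ledger(led, path)
  back <- read_ledger(path, sp)
  expect_equal(back$target, c(11, 8, 6.5, 4.5)) # replicate means
  expect_equal(back[, names(sp$factors)], led[, names(sp$factors)],
               tolerance = 1e-12)
  # invalid category and duplicate ids are rejected with row context
  bad <- led
  bad$CoFeedType[2] <- "Maltose"
  write_ledger(bad, path)
  expect_error(read_ledger(path, sp), "Maltose")
  dup <- led
  dup$experiment_id[2] <- "e1"
  write_ledger(dup, path)
  expect_error(read_ledger(path, sp), "duplicate")
})

test_that("ingest updates noise from pooled controls and tracks convergence", {
  camp <- mini_campaign()
  expect_s3_class(camp$model, "bo_gp")
  n0 <- nrow(camp$ledger)
  # control rows enter the noise pool; estimate includes all iterations
  ctrl1 <- tibble::tibble(experiment_id = "ctrl_a", role = "control",
                          x1 = 0.5, x2 = 0.5, cat = "c1",
                          rep_1 = 1.0, rep_2 = 1.2)
  camp <- ingest(camp, ctrl1)
  expect_equal(camp$noise_variance,
               estimate_noise_variance(c(1.0, 1.2)))
  ctrl2 <- tibble::tibble(experiment_id = "ctrl_b", role = "control",
                          x1 = 0.5, x2 = 0.5, cat = "c1",
                          rep_1 = 0.9, rep_2 = 1.3)
  camp <- ingest(camp, ctrl2)
  expect_equal(camp$noise_variance,
               estimate_noise_variance(c(1.0, 1.2, 0.9, 1.3)))
  # validation rows are stored but never trained on
  val <- tibble::tibble(experiment_id = "val_1", role = "validation",
                        x1 = 0.2, x2 = 0.8, cat = "c2", target = 0.5)
  n_before <- length(camp$model$y_raw)
  camp <- ingest(camp, val)
  expect_equal(length(camp$model$y_raw), n_before)
  expect_true("val_1" %in% camp$ledger$experiment_id)
  expect_error(ingest(camp, tibble::tibble(experiment_id = "ghost",
                                           target = 1)),
               "ghost")
  # a well-predicted batch registers a converged entry
  camp2 <- campaign_suggest(camp, seed = 9)
  pl <- dplyr::filter(camp2$ledger, role == "planned")
  preds <- predict(camp2$model, pl)$.pred
  camp2 <- ingest(camp2, tibble::tibble(experiment_id = pl$experiment_id,
                                        target = preds))
  last <- camp2$convergence[[length(camp2$convergence)]]
  expect_true(last$converged)
})

test_that("campaign state round-trips with bit-identical predictions", {
  camp <- mini_campaign(seed = 4)
  camp <- campaign_suggest(camp, seed = 2)
  path <- tempfile(fileext = ".json")
  campaign_save(camp, path)
  back <- campaign_load(path)
  probe <- sample_feasible(camp$space, 10, seed = 77)
  expect_identical(predict(camp$model, probe), predict(back$model, probe))
  expect_equal(back$ledger$experiment_id, camp$ledger$experiment_id)
  expect_equal(back$iteration, camp$iteration)
  # suggesting from the restored state reproduces the same batch
  s1 <- suggest_batch(camp, seed = 31)$points
  s2 <- suggest_batch(back, seed = 31)$points
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-12)
})

test_that("space configs round-trip through YAML and JSON", {
  sp <- yeast_space()
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_space_config(sp, path)
    back <- read_space_config(path)
    expect_equal(names(back$factors), names(sp$factors))
    expect_equal(back$factors$CoFeedType$categories,
                 sp$factors$CoFeedType$categories)
    expect_equal(back$factors$Glycerol$upper, 10)
    expect_equal(back$factors$CoFeedConc$linked_to, "CoFeedType")
  }
  spc <- blend_space()
  path <- tempfile(fileext = ".yaml")
  write_space_config(spc, path)
  backc <- read_space_config(path)
  expect_equal(length(backc$constraints), 1L)
  expect_equal(backc$constraints[[1]]$rhs, 1)
})

test_that("the CLI covers init, ingest, suggest and status", {
  dir <- tempfile(); dir.create(dir)
  cfg_path <- file.path(dir, "campaign.yaml")
  state <- file.path(dir, "state.json")
  sp <- small_mixed_space()
  cfg <- mediabo:::space_to_list(sp)
  cfg$direction <- "maximize"
  cfg$seed <- 3
  cfg$init_size <- 6
  cfg$acquisition <- list(kind = "ucb", batch_size = 3, screen_size = 300,
                          restarts = 2)
  yaml::write_yaml(cfg, cfg_path)

  expect_equal(bo_cli(c("init", "--config", cfg_path, "--state", state)), 0L)
  expect_true(file.exists(state))
  # status before any results: explicit no-model message, still exit 0
  expect_output(code <- bo_cli(c("status", "--state", state)), "no model")
  expect_equal(code, 0L)

  camp <- campaign_load(state)
  pl <- camp$ledger
  results <- file.path(dir, "results.csv")
  utils::write.csv(tibble::tibble(experiment_id = pl$experiment_id,
                                  target = mixed_test_fun(pl)),
                   results, row.names = FALSE)
  expect_equal(bo_cli(c("ingest", "--state", state, "--results", results)),
               0L)
  # identical suggestions from the same state and seed
  state2 <- file.path(dir, "state2.json")
  file.copy(state, state2)
  out1 <- capture.output(bo_cli(c("suggest", "--state", state,
                                  "--seed", "7")))
  out2 <- capture.output(bo_cli(c("suggest", "--state", state2,
                                  "--seed", "7")))
  expect_identical(out1, out2)
  expect_output(bo_cli(c("status", "--state", state)), "best-so-far")
  # doe-size prints the count
  expect_output(bo_cli(c("doe-size", "--method", "ccd", "--k", "4")), "25")
  # errors surface as nonzero status
  expect_output(code <- bo_cli(c("suggest", "--state",
                                 file.path(dir, "missing.json"))), "error")
  expect_equal(code, 1L)
})

test_that("the simulate command emits a trace and summary", {
  dir <- tempfile(); dir.create(dir)
  trace <- file.path(dir, "trace.csv")
  summ <- file.path(dir, "summary.json")
  expect_output(
    code <- bo_cli(c("simulate", "--landscape", "simplex", "--budget", "12",
                     "--batch", "6", "--seed", "2", "--out", trace,
                     "--summary", summ)),
    "best found")
  expect_equal(code, 0L)
  tr <- utils::read.csv(trace)
  expect_equal(nrow(tr), 12L)
  js <- jsonlite::read_json(summ)
  expect_equal(js$n_evaluations, 12L)
})
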