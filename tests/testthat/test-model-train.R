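# Full network assembly, schedules, training mechanics, prediction,
# evaluation and the CLI.

tiny_cfg <- function(...) model_config(profile = "test",
                                       channels = c(2L, 3L, 4L, 5L),
                                       d_state = 2L, h_dim = 8L, seed = 3, ...)

test_that("forward maps dual-modality volumes to voxel probabilities", {
  model <- build_model(tiny_cfg())
  x <- rand_fmap(c(1, 2, 16, 16, 16), seed = 1)
  out <- model_forward(model, x, with_aux = TRUE)
  expect_identical(dim(out$prob), c(1L, 3L, 16L, 16L, 16L))
  sums <- apply(out$prob[1, , , , , drop = FALSE], c(3, 4, 5), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # aux heads live at stages 2 and 3 -> 1/4 and 1/2 resolution
  expect_length(out$aux, 2L)
  expect_identical(dim(out$aux[[1]]$prob)[3:5], c(4L, 4L, 4L))
  expect_identical(dim(out$aux[[2]]$prob)[3:5], c(8L, 8L, 8L))

  expect_error(model_forward(model, rand_fmap(c(1, 2, 24, 16, 16))),
               "divisible by 16")
  expect_error(model_forward(model, rand_fmap(c(1, 1, 16, 16, 16))),
               "input channels")
})

test_that("single-modality and ablation variants assemble and run", {
  m_t1 <- build_model(tiny_cfg(modality = "t1"))
  out <- model_forward(m_t1, rand_fmap(c(1, 1, 16, 16, 16), seed = 2))
  expect_identical(dim(out$prob)[2], 3L)
  # sagittal-only scan directions
  m_sag <- build_model(tiny_cfg(directions = "depth"))
  expect_length(m_sag$encoders[[1]]$stages[[1]]$td$branches, 1L)
  # component switches
  m_min <- build_model(tiny_cfg(use_tdmamba = FALSE, use_gcn = FALSE,
                                use_paaf = FALSE))
  expect_null(m_min$graph); expect_null(m_min$paaf)
  out2 <- model_forward(m_min, rand_fmap(c(1, 2, 16, 16, 16), seed = 3))
  expect_identical(dim(out2$prob), c(1L, 3L, 16L, 16L, 16L))
  # parameter count is config + seed deterministic
  expect_identical(count_parameters(build_model(tiny_cfg())),
                   count_parameters(build_model(tiny_cfg())))
})

test_that("schedules follow the closed forms exactly", {
  cfg <- train_config()
  expect_identical(lr_schedule(0, cfg), 1e-3)
  expect_identical(lr_schedule(29, cfg), 1e-3)
  expect_identical(lr_schedule(30, cfg), 8e-4)
  expect_identical(lr_schedule(60, cfg), 1e-3 * 0.8^2)
  expect_equal(lr_schedule(60, cfg), 6.4e-4)
  expect_identical(ds_alpha_schedule(0, cfg), 0.4)
  expect_identical(ds_alpha_schedule(30, cfg), 0.4 * 0.8)
  expect_equal(ds_alpha_schedule(30, cfg), 0.32)
  e <- 0:100
  expect_equal(sapply(e, lr_schedule, cfg = cfg),
               1e-3 * 0.8^(e %/% 30), tolerance = 1e-15)
})

test_that("every model parameter is reached by one training-step gradient", {
  # 32^3 input: the bottleneck sequences then have length 2, so the state
  # matrices are reachable (with length-1 sequences they provably cannot
  # influence the output)
  model <- build_model(tiny_cfg())
  x <- rand_fmap(c(1, 2, 32, 32, 32), seed = 5)
  labs <- spineseg:::with_seed(6,
    array(sample(0:2, 32^3, TRUE), c(32, 32, 32)))
  out <- spineseg:::model_forward_node(model, spineseg:::ad_const(x),
                                       with_aux = TRUE)
  loss <- spineseg:::hfd_tversky_node(out$prob, spineseg:::one_hot(labs, 3),
                                      loss_config())
  for (a in out$aux) {
    fac <- 2L^(4L - a$stage)
    tgt <- spineseg:::one_hot(spineseg:::downsample_labels(labs, fac), 3)
    loss <- spineseg:::ad_add(loss, spineseg:::ad_mul(
      spineseg:::hfd_tversky_node(a$prob, tgt, loss_config()), 0.4))
  }
  params <- spineseg:::collect_params(model)
  spineseg:::ad_zero_grad(params)
  spineseg:::ad_backward(loss)
  n_missing <- sum(vapply(params, function(p) is.null(p$grad), logical(1)))
  expect_identical(n_missing, 0L)
  n_zero <- sum(vapply(params, function(p) all(p$grad == 0), logical(1)))
  expect_identical(n_zero, 0L)
})

test_that("training is seeded, logged and schedule-conformant", {
  ph <- generate_phantom(phantom_config(shape = c(16, 16, 16), seed = 5))
  m3 <- to_three_class(ph$labels)
  zs <- function(v) (v - mean(v)) / sd(v)
  x <- array(0, c(1, 2, 16, 16, 16))
  x[1, 1, , , ] <- zs(ph$volume$t1); x[1, 2, , , ] <- zs(ph$volume$t2)
  cases <- list(as_case(x, m3$labels))
  logf <- file.path(tempdir(), "log.jsonl")
  unlink(logf)
  run <- function() {
    model <- build_model(tiny_cfg())
    train_model(model, cases,
                train_config(max_epochs = 2, patience = 0, seed = 4),
                val_cases = cases, log_file = logf)
  }
  f1 <- run(); f2 <- run()
  expect_equal(f1$logs$loss, f2$logs$loss, tolerance = 1e-12)
  expect_identical(nrow(f1$logs), 2L)
  expect_equal(f1$logs$lr, lr_schedule(0:1, train_config()))
  expect_equal(f1$logs$ds_alpha, ds_alpha_schedule(0:1, train_config()))
  expect_false(any(is.na(f1$logs$val_dice)))
  lines <- readLines(logf)
  expect_length(lines, 4L)   # two runs x two epochs
  expect_silent(jsonlite::fromJSON(lines[1]))
  expect_error(train_model(build_model(tiny_cfg()), list()), "empty")

  # disabling deep supervision changes the objective to the main loss only
  m3l <- build_model(tiny_cfg())
  fit_nods <- train_model(m3l, cases,
                          train_config(max_epochs = 1, patience = 0, seed = 4,
                                       deep_supervision = FALSE))
  out <- model_forward(build_model(tiny_cfg()), x)
  main_only <- hfd_tversky_loss(out$prob, spineseg:::one_hot(m3$labels, 3))
  expect_equal(fit_nods$logs$loss[1], main_only, tolerance = 1e-9)
})

test_that("prediction and directory evaluation close the loop", {
  ph <- generate_phantom(phantom_config(shape = c(16, 16, 16), seed = 9))
  m3 <- to_three_class(ph$labels)
  model <- build_model(tiny_cfg())
  pred <- predict_volume(model, ph$volume)
  expect_identical(dim(pred$labels), c(16L, 16L, 16L))
  expect_true(all(pred$labels %in% 0:2))
  expect_identical(pred$scheme, "THREE_CLASS")

  gt_dir <- file.path(tempdir(), "gt"); pr_dir <- file.path(tempdir(), "pr")
  unlink(c(gt_dir, pr_dir), recursive = TRUE)
  for (cs in c("a", "b")) {
    write_volume(ph$volume, file.path(gt_dir, cs), m3)
    write_volume(ph$volume, file.path(pr_dir, cs), m3)
  }
  csv <- file.path(tempdir(), "eval.csv")
  res <- evaluate_dirs(pr_dir, gt_dir, out_csv = csv)
  percase <- res[res$case != "AGGREGATE_MEAN", ]
  expect_identical(nrow(percase), 6L)   # 2 cases x 3 rows
  expect_true(all(percase$dsc == 1))
  expect_true(all(percase$hd95 == 0))
  expect_true(file.exists(csv))
  expect_identical(nrow(utils::read.csv(csv)), nrow(res))
})

test_that("the CLI generates phantoms and evaluates masks", {
  out_dir <- file.path(tempdir(), "cliphantom")
  unlink(out_dir, recursive = TRUE)
  run_cli(c("generate-phantom", "--out-dir", out_dir, "--shape", "12,48,24",
            "--seed", "3"))
  expect_true(file.exists(file.path(out_dir, "t1.nii.gz")))
  r <- read_volume(out_dir)
  expect_identical(dim(r$volume$t1), c(12L, 48L, 24L))
  expect_identical(r$labels$scheme, "TEN_CLASS")
  # evaluate gt vs itself through the CLI path
  res <- run_cli(c("evaluate", "--pred", dirname(out_dir), "--gt",
                   dirname(out_dir)))
  expect_true(is.data.frame(res))
  expect_error(run_cli(c("predict")), "required")
})
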