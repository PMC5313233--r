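test_that("XYZ files round-trip exactly and fail loudly when malformed", {
  set.seed(81)
  frames <- lapply(1:10, function(f) matrix(rnorm(15, sd = 5), 5, 3))
  pool <- conformation_pool(frames)
  f <- tempfile(fileext = ".xyz")
  write_conformations(pool, f)
  back <- read_conformations(f)
  expect_equal(back$coords, pool$coords, tolerance = 1e-9)
  expect_identical(back$n_frames, 10L)

  # truncated file: error names the location
  lines <- readLines(f)
  f2 <- tempfile(fileext = ".xyz")
  writeLines(lines[1:(length(lines) - 3)], f2)
  expect_error(read_conformations(f2), "truncated")
  # mixed particle counts
  f3 <- tempfile(fileext = ".xyz")
  writeLines(c("2", "t", "C 0 0 0", "C 1 0 0",
               "3", "t", "C 0 0 0", "C 1 0 0", "C 2 0 0"), f3)
  expect_error(read_conformations(f3), "mixed particle counts")
  # malformed record
  f4 <- tempfile(fileext = ".xyz")
  writeLines(c("2", "t", "C 0 0 0", "C 1 0"), f4)
  expect_error(read_conformations(f4), "line 4")
})

test_that("PDB files round-trip at PDB precision", {
  set.seed(82)
  frames <- lapply(1:4, function(f) matrix(rnorm(9, sd = 8), 3, 3))
  pool <- conformation_pool(frames)
  f <- tempfile(fileext = ".pdb")
  write_conformations(pool, f)
  back <- read_conformations(f)
  expect_identical(back$n_frames, 4L)
  expect_equal(back$coords, pool$coords, tolerance = 1e-3)
})

test_that("paths and trajectories are writable as conformations", {
  p <- make_path(rbind(c(0, 0), c(1, 1), c(2, 0)))
  f <- tempfile(fileext = ".xyz")
  write_conformations(p, f)   # 2D images are zero-padded to 3D
  back <- read_conformations(f)
  expect_equal(back$coords[, 1, 1:2], unclass(p), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("hills logs round-trip through the HILLS text convention", {
  params <- wt_params(width = 0.15, stride = 100)
  hills <- hills_log(2)
  grid <- bias_grid(list(c(-1, 1), c(-1, 1)), 0.01)
  h <- hills; g <- grid
  set.seed(83)
  for (i in 1:5) {
    d <- deposit_hill(runif(2, -0.5, 0.5), h, g, params,
                      time = i * 0.2, walker = (i %% 2) + 1)
    h <- d$hills; g <- d$grid
  }
  f <- tempfile(fileext = ".txt")
  write_hills(h, f, params)
  expect_true(startsWith(readLines(f, n = 1), "#! FIELDS time"))
  back <- read_hills(f)
  expect_equal(as.data.frame(back), as.data.frame(h), tolerance = 1e-12)
  expect_identical(attr(back, "n_cv"), 2L)
})

test_that("contact maps and string checkpoints round-trip as TSV", {
  pairs <- rbind(c(1, 5), c(2, 7))
  d0 <- cbind(inactive = c(4, 10), active = c(9, 5))
  spec <- contact_map_spec(pairs, d0, r0 = 8)
  f <- tempfile(fileext = ".tsv")
  write_contact_map(spec, f)
  back <- read_contact_map(f)
  expect_equal(back$pairs, spec$pairs)
  expect_equal(back$d0, spec$d0)
  expect_equal(back$r0, 8)

  st <- string_state(matrix(rnorm(12), 4, 3), dt = 1)
  f2 <- tempfile(fileext = ".tsv")
  write_string_checkpoint(st, f2)
  expect_equal(read_string_checkpoint(f2), st$targets, tolerance = 1e-12)
})

test_that("config validation rejects unknown keys and missing seeds", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("stages: [cluster]", "bogus_key: 1"), f)
  expect_error(read_run_config(f), "bogus_key")
  writeLines(c("stages: [synth]"), f)
  expect_error(read_run_config(f), "seed")
  writeLines(c("stages: [nosuchstage]", "seed: 1"), f)
  expect_error(read_run_config(f), "nosuchstage")
  writeLines(c("stages: [drive]", "seed: 1"), f)
  expect_s3_class(read_run_config(f), "run_config")
})

test_that("the CLI surface reports usage errors with nonzero status", {
  expect_identical(suppressMessages(run_cli(character())), 1L)
  expect_identical(suppressMessages(run_cli("frobnicate")), 1L)
  expect_identical(suppressMessages(run_cli(c("zts", "--bogus", "x"))), 1L)
  expect_identical(suppressMessages(run_cli("zts")), 1L)  # missing --config
  expect_identical(
    suppressMessages(run_cli(c("zts", "--config", "/nonexistent.yaml"))), 1L)
})

test_that("the bundled demo pipeline runs end to end, reproducibly", {
  cfg_path <- system.file("extdata", "demo-config.yaml", package = "pathdyn")
  out1 <- file.path(tempdir(), "demo-run-1")
  out2 <- file.path(tempdir(), "demo-run-2")
  status <- suppressMessages(suppressWarnings(
    run_cli(c("pipeline", "--config", cfg_path, "--outdir", out1))))
  expect_identical(status, 0L)
  # every expected product exists and re-parses with the package's readers
  pool_back <- read_conformations(file.path(out1, "synth_pool.xyz"))
  expect_identical(pool_back$n_frames, 60L)
  pmf <- read_tsv(file.path(out1, "string_pmf.tsv"))
  expect_identical(names(pmf), c("alpha", "F"))
  expect_identical(pmf$F[1], 0)
  hills <- read_hills(file.path(out1, "metad_hills.txt"))
  expect_gt(nrow(hills), 0)
  fes <- read_tsv(file.path(out1, "fes.tsv"))
  expect_equal(min(fes$F), 0)
  clusters <- read_tsv(file.path(out1, "clusters.tsv"))
  expect_identical(nrow(clusters), 60L)
  expect_true(file.exists(file.path(out1, "network_edges.tsv")))
  expect_true(file.exists(file.path(out1, "density.tsv")))
  rmsf <- read_tsv(file.path(out1, "rmsf.tsv"))
  expect_identical(nrow(rmsf), 12L)
  prof <- read_tsv(file.path(out1, "driving_profile.tsv"))
  expect_identical(nrow(prof), 11L)
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_identical(manifest$package, "pathdyn")
  expect_true(length(manifest$outputs) >= 10)

  # bit-identical numeric outputs on a re-run driven by the manifest alone
  suppressWarnings(
    rerun_from_manifest(file.path(out1, "manifest.json"), outdir = out2))
  for (file in c("string_pmf.tsv", "metad_hills.txt", "fes.tsv",
                 "clusters.tsv", "synth_pool.xyz", "driving_profile.tsv")) {
    expect_identical(readLines(file.path(out1, file)),
                     readLines(file.path(out2, file)), label = file)
  }
  unlink(c(out1, out2), recursive = TRUE)
})
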