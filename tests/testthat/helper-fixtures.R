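# Shared fixtures, generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

test_scheme <- function(J = 32L, b = 700) {
  fixture(sprintf("scheme_%d_%g", J, b),
          gradient_scheme(b, gradient_table_repulsion(J, seed = 7)))
}

# default-protocol phantom on a small grid, moderate noise
test_phantom <- function() {
  fixture("phantom24",
          generate_phantom(phantom_spec(grid_shape = c(24L, 24L, 24L),
                                        seed = 101L)))
}

# noiseless twin of the same geometry
test_phantom_clean <- function() {
  fixture("phantom24_clean",
          generate_phantom(phantom_spec(grid_shape = c(24L, 24L, 24L),
                                        noise_sigma = 0, seed = 101L,
                                        simulate_motion = FALSE)))
}

test_fit <- function() {
  fixture("fit24", fit_study(test_phantom()$study))
}

# one fast full-pipeline run shared by pipeline/report/io tests
test_pipeline_result <- function() {
  fixture("qa24", {
    out <- file.path(tempdir(), "qa24_out")
    suppressMessages(run_qa_pipeline(
      test_phantom()$study, out_dir = out, seed = 11L,
      config = qa_config(fast = TRUE), verbose = FALSE))
  })
}

test_pipeline_outdir <- function() {
  test_pipeline_result()
  file.path(tempdir(), "qa24_out")
}

# random positive-definite tensor with physiologic scale
random_pd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3)
  D <- crossprod(A)
  D <- D / max(eigen(D, symmetric = TRUE, only.values = TRUE)$values) * 2e-3
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

count_pdf_pages <- function(path) {
  txt <- suppressWarnings(readLines(path, warn = FALSE, skipNul = TRUE))
  sum(grepl("/Type /Page[^s]", txt, useBytes = TRUE))
}
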