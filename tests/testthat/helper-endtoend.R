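# Shared scaled-down end-to-end runs, computed once per test session and
# reused by several tests (cross-validation of the full pipeline on the
# planted-motif synthetic dataset).

.e2eCache <- new.env(parent = emptyenv())

# scaled-down experiment configuration: reduced sizes (H = 32, D = 20,
# N as given, 2 epochs) with the learning rate and schedule chosen for
# the reduced update budget (see methods vignette)
e2eConfig <- function(n = 50L, seed = 1L) {
  cmicConfig(n = n, dim = 20L, hidden = 32L, epochs = 2L,
             lr = 2e-3, lrSchedule = "onecycle", seed = seed)
}

# per-CGI F-measure of one full cross-validated run at augmentation
# level N and a given seed, on the standard synthetic dataset
e2eFMeasure <- function(n, seed) {
  key <- sprintf("f_n%d_s%d", n, seed)
  if (!is.null(.e2eCache[[key]])) return(.e2eCache[[key]])
  ds <- generateDataset(syntheticSpec(seed = 100L + seed))
  cv <- crossValidate(ds$seqs, config = e2eConfig(n = n, seed = seed),
                      K = 3L, seed = seed)
  s <- cv$summary
  f <- s$mean[s$level == "per_cgi" & s$metric == "f_measure"]
  .e2eCache[[key]] <- f
  .e2eCache[[paste0(key, "_cv")]] <- cv
  f
}
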