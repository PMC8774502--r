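# The full desk-scale audit experiment shared by several acceptance checks:
# 2,000 images at 128 x 128 (patches in 46% of benign images only), an 80/20
# stratified split (1,600 train / 400 test), vanilla + de-biased training,
# both audits, the validity check and the footprint control, all seeded.
acceptance_run <- function() {
  memo("acceptance_run", {
    ds <- generate_dermo_dataset(dermo_params(
      n_benign = 1000L, n_malignant = 1000L, seed = 101L
    ))
    sp <- split_train_test(ds, 0.8, seed = 102L)
    run <- run_debias_experiment(
      sp$train, sp$test,
      audit_config(seed = 104L),
      train_config(seed = 103L)
    )
    list(split = sp, run = run)
  })
}
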