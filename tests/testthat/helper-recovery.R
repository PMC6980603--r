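# The parameter-recovery simulation study (10 seeded replicates plus their
# permuted-label null counterparts), computed once and shared by the tests
# that assess different aspects of it.
recovery_study <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      reps <- lapply(1:10, function(sd) {
        r <- recovery_replicate(sd)
        n <- recovery_replicate(sd, permute = TRUE)
        list(auc = r$auc, top4 = r$top4, nt = r$model$cv$nt,
             null_auc = n$auc,
             model = if (sd == 1) r$model else NULL)
      })
      val <<- reps
    }
    val
  }
})
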