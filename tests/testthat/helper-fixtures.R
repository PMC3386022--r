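# Fixture builders shared across test files, plus a lazy cache for the
# expensive shared computations (synthetic bundle, GA recovery run) so
# several test blocks can inspect one run.

# Expression matrix from a bare value matrix; instance/compound/batch ids
# default to one instance per compound in a single batch.
make_em <- function(values, compounds = NULL, batches = NULL,
                    centred = FALSE) {
  n <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("i%02d", seq_len(n))
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("ps%02d", seq_len(ncol(values)))
  }
  if (is.null(compounds)) compounds <- sprintf("c%02d", seq_len(n))
  if (is.null(batches)) batches <- rep("b1", n)
  expression_matrix(values,
                    data.frame(instance_id = rownames(values),
                               compound_id = compounds,
                               batch_id = batches,
                               stringsAsFactors = FALSE),
                    centred = centred)
}

# Hand-computed five-instance fixture: i1/i2 are replicates of compound
# cA; signature correlations from i1 rank i3 > i4 > i5 (0.98198, 0.5,
# -0.5). Ground-truth metrics worked out by hand in the tests.
make_hand_fixture <- function() {
  values <- rbind(
    i1 = c(1, 2, 3),
    i2 = c(1, 2, 3),
    i3 = c(1, 2, 4),
    i4 = c(1, 3, 2),
    i5 = c(3, 1, 2)
  )
  colnames(values) <- c("ps1", "ps2", "ps3")
  m <- make_em(values, compounds = c("cA", "cA", "cB", "cC", "cD"))
  annotations <- annotation_table(list(
    cA = c("A", "B"), cB = c("B", "C"), cC = "X", cD = "Y"))
  list(m = m, annotations = annotations,
       sig = gene_signature(c("ps1", "ps2", "ps3")))
}

# Small synthetic dataset for fast GA and property tests.
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(generate_dataset(sim_config(
        n_probesets = 100, n_informative = 8, n_compounds = 20,
        n_targets = 10, replicates_per_compound = 2, n_batches = 2,
        seed = 42)))
    }
    cache
  }
})

# The parameter-recovery experiment at the study conditions (defaults,
# seed 11; GA population 50, 30 generations, signature size 32), computed
# once and shared by the acceptance blocks that inspect it.
recovery_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bundle <- suppressMessages(generate_dataset(sim_config(seed = 11)))
      m <- suppressMessages(batch_mean_center(bundle$expression))
      ga <- evolve(m, bundle$annotations,
                   ga_config(signature_size = 32, population = 50,
                             generations = 30, seed = 11))
      cache <<- list(bundle = bundle, m = m, ga = ga)
    }
    cache
  }
})
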