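# Memoized fixtures shared across test files. Everything is generated in
# code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

coord_cols <- paste0("csr", rep(1:5, each = 2), c("_start", "_end"))

small_counts <- function() {
  setNames(c(20, 15, 20, 15, 20, 20, 5, 10, 1, 10, 10, 20, 20, 15),
           default_catalogue()$group)
}

# ~200-sequence dataset + trained profiles, for unit tests
small_fixture <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- synthetic_config(counts = small_counts(), seed = 421)
    ds <- generate_dataset(cfg)
    pr <- train_profiles(cfg)
    .fixtures$small <- list(cfg = cfg, ds = ds, pr = pr)
  }
  .fixtures$small
}

# the full default study-scale dataset with detection + classification run;
# expensive, shared by the acceptance tests
full_fixture <- function() {
  if (is.null(.fixtures$full)) {
    cfg <- synthetic_config()
    ds <- generate_dataset(cfg)
    pr <- train_profiles(cfg)
    det <- detect_fingerprints(ds$sequences, pr$detect)
    asg <- classify_fingerprints(det, pr$classify)
    .fixtures$full <- list(cfg = cfg, ds = ds, pr = pr, det = det, asg = asg)
  }
  .fixtures$full
}

# random amino-acid sequence of length n from the current RNG
random_aa <- function(n) paste(sample(AA_ALPHABET, n, TRUE), collapse = "")
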