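# Fixture builders used across the test files. All fixtures are built in
# code; nothing is read from disk.

NTS <- c("A", "C", "G", "U")

# Transcript from explicit UTR and CDS strings.
make_tx <- function(utr, cds, id = "tx") {
  transcript(id, paste0(utr, cds), nchar(utr) + 1L)
}

# Random transcript with a well-formed CDS (AUG ... stop, no premature
# in-frame stop) and a random 5' UTR.
random_tx <- function(seed, utr_len = 300, cds_codons = 120, id = NULL,
                      bg = c(0.25, 0.25, 0.25, 0.25)) {
  set.seed(seed)
  utr <- paste(sample(NTS, utr_len, replace = TRUE, prob = bg), collapse = "")
  body_codons <- setdiff(
    apply(expand.grid(NTS, NTS, NTS), 1, paste, collapse = ""),
    c("UAA", "UAG", "UGA")
  )
  cds <- paste0("AUG", paste(sample(body_codons, cds_codons - 1, TRUE),
                             collapse = ""), "UAA")
  make_tx(utr, cds, id = if (is.null(id)) paste0("rtx", seed) else id)
}

# Replace a substring in place (1-based).
plant <- function(seq, at, what) {
  substr(seq, at, at + nchar(what) - 1L) <- what
  seq
}

# A transcript of all-C 5' UTR with one planted CUG (and its in-frame stop):
# the C background forms no other alphabet codon, so the planted CUG is the
# only possible candidate.
planted_cug_tx <- function() {
  utr <- strrep("C", 260)
  utr <- plant(utr, 120, "CUG")
  utr <- plant(utr, 168, "UAA")
  cds <- paste0("AUG", strrep("CCC", 60), "UAA")
  make_tx(utr, cds, id = "planted")
}

# Small deterministic efficiency table covering the contexts of a transcript
# (every 11-nt AUG-substituted context gets a value derived from its
# characters, so lookups are exactly reproducible in tests).
toy_efficiency_for <- function(txs) {
  ctxs <- unlist(lapply(txs, function(tx) {
    n <- nchar(tx$sequence)
    i <- 7:(n - 4)
    ctx <- substring(tx$sequence, i - 6, i + 4)
    substr(ctx, 7, 9) <- "AUG"
    ctx
  }))
  ctxs <- unique(ctxs)
  vals <- vapply(ctxs, function(cx) {
    sum(utf8ToInt(cx)) %% 97 + 10
  }, numeric(1))
  read_efficiency_table(data.frame(context = ctxs, efficiency = unname(vals),
                                   stringsAsFactors = FALSE))
}

# Full parametric efficiency table, built once per test run.
full_efficiency <- local({
  eff <- NULL
  function() {
    if (is.null(eff)) eff <<- read_efficiency_table(generate_efficiency_table(1))
    eff
  }
})

# Hand-built single-feature linear model (confidence = intercept + w * z).
toy_model <- function(feature, weight, intercept = 0.5, center = 0.5,
                      scale = 1, threshold = 0.54) {
  structure(
    list(kind = "linear", feature_names = feature,
         center = stats::setNames(center, feature),
         scale = stats::setNames(scale, feature),
         intercept = intercept,
         coefficients = stats::setNames(weight, feature),
         threshold = threshold, window = 99L),
    class = "tis_model"
  )
}
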